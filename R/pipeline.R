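# Orchestration of the full analysis: trait summaries -> allometric scaling
# -> detrending -> phylogeny-corrected correlations -> climate PCA -> causal
# path models, each stage writing long-format CSV and the whole run recorded
# in a provenance manifest.

#' Validate a pipeline run configuration
#'
#' @param traits Path to the species trait table CSV (columns `species_id`,
#'   `organ`, `tissue`, `distance_to_tip`, one column per trait), or a
#'   tibble.
#' @param trees Path to a Newick file (one or many trees), or a list of
#'   `phylo` objects.
#' @param climate Path to the climate CSV (`sample_id`, `bio1..bio19`) or a
#'   tibble; sample ids must match species ids. Optional: PCA and path
#'   stages are skipped without it.
#' @param out Output directory.
#' @param seed Integer seed recorded in all outputs.
#' @param organ Organ to analyse (`"main_stem"` or `"branch"`).
#' @param tissues Tissues to analyse.
#' @param traits_to_fit Trait columns to fit; defaults to every trait column
#'   present.
#' @param lambda_mode `"ml"` or a fixed numeric lambda.
#' @param sem_scaling `"minmax"` or `"zscore"` scaling before path models.
#' @param variance_structures Candidate variance structures for model
#'   selection.
#' @return A validated `run_config` list.
#' @export
run_config <- function(traits, trees, climate = NULL, out = tempdir(),
                       seed = 1L, organ = "main_stem",
                       tissues = c("vessel", "sieve_element"),
                       traits_to_fit = NULL, lambda_mode = "ml",
                       sem_scaling = c("minmax", "zscore"),
                       variance_structures = c("identity", "power")) {
  sem_scaling <- match.arg(sem_scaling)
  for (nm in c("traits", "trees", "climate")) {
    val <- get(nm)
    if (is.character(val) && !file.exists(val)) {
      stop(sprintf("%s file does not exist: %s", nm, val), call. = FALSE)
    }
  }
  structure(
    list(traits = traits, trees = trees, climate = climate, out = out,
         seed = as.integer(seed), organ = organ, tissues = tissues,
         traits_to_fit = traits_to_fit, lambda_mode = lambda_mode,
         sem_scaling = sem_scaling,
         variance_structures = variance_structures),
    class = "run_config"
  )
}

load_traits <- function(traits) {
  if (is.character(traits)) {
    traits <- readr::read_csv(traits, show_col_types = FALSE)
  }
  needed <- c("species_id", "organ", "tissue", "distance_to_tip")
  missing_cols <- setdiff(needed, names(traits))
  if (length(missing_cols) > 0) {
    stop("trait table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  traits
}

load_trees <- function(trees) {
  if (is.character(trees)) read_trees(trees) else trees
}

trait_columns <- function(traits) {
  setdiff(names(traits),
          c("species_id", "organ", "tissue", "distance_to_tip", "n_sections"))
}

#' Fit trait-distance allometries for every stratum and select models by BIC
#'
#' For each organ x tissue x trait stratum, fits plain GLS and phylogenetic
#' GLS (per candidate tree, parameters averaged across trees) under each
#' candidate variance structure, selects the lowest-BIC model, and reports a
#' parameter table plus the detrended values (residuals of the selected
#' fit). Strata with fewer than 3 species are skipped with a message.
#'
#' @param config A [run_config()] (output paths are not written here).
#' @return List with `table` (one row per stratum: intercept, slope, CIs,
#'   p, df, lambda, AIC, BIC, logLik, partial and ordinary R2, model type)
#'   and `residuals` (species-level detrended values).
#' @export
run_scaling <- function(config) {
  traits <- load_traits(config$traits)
  trees <- load_trees(config$trees)
  traits <- traits[traits$organ %in% config$organ &
                     traits$tissue %in% config$tissues, , drop = FALSE]
  fit_traits <- config$traits_to_fit %||% trait_columns(traits)
  rows <- list()
  residuals <- list()
  for (tis in unique(traits$tissue)) {
    for (tr_name in fit_traits) {
      sub <- traits[traits$tissue == tis,
                    c("species_id", "distance_to_tip", tr_name)]
      sub <- sub[stats::complete.cases(sub), , drop = FALSE]
      if (nrow(sub) < 3) {
        message(sprintf("skipping %s/%s: fewer than 3 species", tis, tr_name))
        next
      }
      y <- log(sub[[tr_name]])
      x <- log(sub$distance_to_tip)
      candidates <- list()
      for (vs in config$variance_structures) {
        candidates[[paste0("gls_", vs)]] <- fit_gls(
          y, x, pc = NULL, variance_structure = vs,
          species_id = sub$species_id, trait_name = tr_name,
          organ = config$organ[1], tissue = tis
        )
        candidates[[paste0("pgls_", vs)]] <- fit_gls_trees(
          y, x, trees = trees, variance_structure = vs,
          lambda = config$lambda_mode, species_id = sub$species_id,
          trait_name = tr_name, organ = config$organ[1], tissue = tis
        )
      }
      best <- select_model(candidates)
      rows[[paste(tis, tr_name)]] <- tibble::tibble(
        organ = config$organ[1], tissue = tis, trait = tr_name,
        intercept = best$intercept, slope = best$slope,
        ci_low = best$slope_ci_low, ci_high = best$slope_ci_high,
        p_value = best$slope_p_value, df = best$df,
        lambda = ifelse(best$model_type == "pgls", best$lambda_hat, NA_real_),
        aic = best$aic, bic = best$bic, loglik = best$log_likelihood,
        partial_r2 = best$partial_r2, r2 = best$r2,
        variance_structure = best$variance_structure,
        model_type = best$model_type
      )
      residuals[[paste(tis, tr_name)]] <- detrend(best) |>
        dplyr::mutate(tissue = tis, organ = config$organ[1])
    }
  }
  list(table = dplyr::bind_rows(rows), residuals = dplyr::bind_rows(residuals))
}

#' Phylogeny-corrected correlations among raw and detrended traits
#'
#' @param config A [run_config()].
#' @param scaling Output of [run_scaling()]; refit when omitted.
#' @return Long tibble of pairwise correlations with `value_kind` in
#'   `{"raw", "detrended"}`.
#' @export
run_correlations <- function(config, scaling = NULL) {
  traits <- load_traits(config$traits)
  trees <- load_trees(config$trees)
  traits <- traits[traits$organ %in% config$organ, , drop = FALSE]
  if (is.null(scaling)) scaling <- run_scaling(config)
  fit_traits <- config$traits_to_fit %||% trait_columns(traits)
  wide_raw <- traits |>
    dplyr::select(dplyr::all_of(c("species_id", "tissue", fit_traits))) |>
    tidyr::pivot_longer(dplyr::all_of(fit_traits), names_to = "trait") |>
    dplyr::mutate(value = log(.data$value),
                  column = paste(.data$tissue, .data$trait, sep = ".")) |>
    dplyr::select("species_id", "column", "value") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  wide_det <- scaling$residuals |>
    dplyr::mutate(column = paste(.data$tissue, .data$trait_name, sep = ".")) |>
    dplyr::select("species_id", "column", "residual") |>
    tidyr::pivot_wider(names_from = "column", values_from = "residual")
  pc <- brownian_vcv(trees[[1]])
  correlate_kind <- function(wide, kind) {
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    Y <- as.matrix(wide[, -1])
    rownames(Y) <- wide$species_id
    pc_sub <- align_phylo_cov(pc, wide$species_id)
    correlate(Y, pc_sub) |> dplyr::mutate(value_kind = kind, .before = 1)
  }
  dplyr::bind_rows(
    correlate_kind(wide_raw, "raw"),
    correlate_kind(wide_det, "detrended")
  )
}

#' Compare the four causal path models for every trait
#'
#' Builds the per-trait analysis table (climate PC scores, log
#' distance-to-tip, log trait), scales all columns for the structural
#' equation models, and runs [compare_models()] across all candidate trees.
#'
#' @param config A [run_config()] with a climate table.
#' @return List with `table` (one row per tissue x trait: selected model,
#'   mean CICc, all path coefficients in `from -> to` columns) and
#'   `details` (per-trait `path_comparison` objects).
#' @export
run_paths <- function(config) {
  if (is.null(config$climate)) stop("path stage needs a climate table", call. = FALSE)
  traits <- load_traits(config$traits)
  trees <- load_trees(config$trees)
  climate <- if (is.character(config$climate)) {
    readr::read_csv(config$climate, show_col_types = FALSE)
  } else {
    config$climate
  }
  traits <- traits[traits$organ %in% config$organ, , drop = FALSE]
  pca <- fit_pca(climate)
  scores <- tibble::tibble(
    species_id = climate$sample_id,
    PC1 = pca$scores[, 1], PC2 = pca$scores[, 2], PC3 = pca$scores[, 3]
  )
  fit_traits <- config$traits_to_fit %||% trait_columns(traits)
  details <- list()
  rows <- list()
  for (tis in unique(traits$tissue)) {
    for (tr_name in fit_traits) {
      sub <- traits[traits$tissue == tis,
                    c("species_id", "distance_to_tip", tr_name)]
      sub <- sub[stats::complete.cases(sub), , drop = FALSE]
      dat <- dplyr::inner_join(sub, scores, by = "species_id")
      if (nrow(dat) < 10) next
      analysis <- tibble::tibble(
        species_id = dat$species_id,
        PC1 = dat$PC1, PC2 = dat$PC2, PC3 = dat$PC3,
        x = log(dat$distance_to_tip), y = log(dat[[tr_name]])
      )
      analysis[, c("PC1", "PC2", "PC3", "x", "y")] <-
        scale_for_sem(analysis[, c("PC1", "PC2", "PC3", "x", "y")],
                      method = config$sem_scaling)
      cmp <- compare_models(analysis, trees, lambda = config$lambda_mode)
      details[[paste(tis, tr_name)]] <- cmp
      sel_coefs <- cmp$coefficients[cmp$coefficients$model == cmp$selected, ]
      coef_cols <- stats::setNames(
        as.list(sel_coefs$coefficient),
        paste0(sel_coefs$from, "->", sel_coefs$to)
      )
      rows[[paste(tis, tr_name)]] <- tibble::as_tibble(c(
        list(tissue = tis, trait = tr_name, selected_model = cmp$selected,
             mean_CICc = cmp$summary$mean_CICc[cmp$summary$model == cmp$selected]),
        coef_cols
      ))
    }
  }
  list(table = dplyr::bind_rows(rows), details = details)
}

#' Run the complete pipeline and write all stage outputs
#'
#' Executes trait-table loading, allometric scaling, detrending,
#' phylogeny-corrected correlations, climate PCA and causal path models,
#' writing each stage's tables as CSV under `config$out` together with a
#' provenance manifest (inputs, seed, package version, file checksums).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of stage results plus the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stages <- character(0)
  outputs <- character(0)
  write_stage <- function(tbl, file) {
    path <- file.path(config$out, file)
    readr::write_csv(tbl, path)
    outputs <<- c(outputs, path)
    path
  }

  traits <- load_traits(config$traits)
  write_stage(traits, "traits.csv")
  stages <- c(stages, "traits")

  scaling <- run_scaling(config)
  write_stage(scaling$table, "scaling_table.csv")
  stages <- c(stages, "scaling")

  write_stage(scaling$residuals, "detrended_values.csv")
  stages <- c(stages, "detrend")

  correlations <- run_correlations(config, scaling)
  write_stage(correlations, "correlations.csv")
  stages <- c(stages, "correlations")

  pca <- NULL
  paths <- NULL
  if (!is.null(config$climate)) {
    climate <- if (is.character(config$climate)) {
      readr::read_csv(config$climate, show_col_types = FALSE)
    } else {
      config$climate
    }
    pca <- fit_pca(climate)
    loadings_tbl <- tibble::as_tibble(pca$loadings, rownames = "variable")
    write_stage(loadings_tbl, "pca_loadings.csv")
    write_stage(
      tibble::tibble(component = seq_along(pca$explained_variance),
                     explained_variance = pca$explained_variance),
      "pca_scree.csv"
    )
    stages <- c(stages, "pca")

    paths <- run_paths(config)
    write_stage(paths$table, "path_models.csv")
    stages <- c(stages, "paths")
  }

  manifest <- list(
    seed = config$seed,
    organ = config$organ,
    n_species = length(unique(traits$species_id)),
    n_trees = length(load_trees(config$trees)),
    stages = stages,
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(outputs)),
    package_version = as.character(utils::packageVersion("conduitscaling"))
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scaling = scaling, correlations = correlations, pca = pca,
                 paths = paths, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
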
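# Synthetic data with the exact statistical structure the analysis assumes:
# a pure-birth phylogeny, climate principal-component scores, log
# distance-to-tip driven by climate, and log traits generated from one of
# the four causal scenarios with lambda-structured phylogenetic residuals.
# Every generator is a pure function of its arguments and the seed.

#' Simulate an ultrametric pure-birth tree with unit depth
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth (Yule) process.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `phylo` object, ultrametric, root-to-tip depth scaled to 1.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop("need at least 2 species", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Simulate Brownian tip values with Pagel's lambda structure
#'
#' Draws one multivariate normal vector with covariance
#' `sigma^2 * C(lambda)`, where `C` is the tree's Brownian covariance with
#' off-diagonals scaled by `lambda` — the residual model that phylogenetic
#' GLS assumes.
#'
#' @param tree A `phylo` or `phylo_cov` object.
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @param sigma Root-to-tip standard deviation (> 0).
#' @param seed Integer seed, or `NULL`.
#' @return Named numeric vector of tip values (root state 0).
#' @export
simulate_bm <- function(tree, lambda = 1, sigma = 1, seed = NULL) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pc <- if (inherits(tree, "phylo_cov")) tree else brownian_vcv(tree)
  Cl <- lambda_scale(pc$C, lambda)
  U <- chol(Cl)
  z <- stats::rnorm(nrow(Cl))
  out <- sigma * as.numeric(crossprod(U, z))
  names(out) <- pc$tip_labels
  out
}

#' Configuration for a synthetic comparative dataset
#'
#' Encodes the generating conditions of one simulated study: which causal
#' scenario wires climate (PC scores) to log distance-to-tip (`x`) and to
#' the log trait (`y`), the allometric slope and intercept, the strength of
#' phylogenetic signal in the trait residuals, and the noise levels.
#' Scenario constraints are enforced: the null and direct scenarios force
#' `b = 0` (no `x -> y` path), the null and indirect scenarios force all
#' climate-to-trait weights `v = 0`; passing a conflicting nonzero value is
#' an error.
#'
#' Defaults reflect the study conditions of the motivating analysis: the
#' main-stem vessel allometry (`b = 0.38`, intercept 3.44, trait residual
#' lambda 0.4), climate-to-height weights near the fitted path coefficients
#' (0.59, 0, 0.4), and a log distance-to-tip range centred on heights of
#' 0.13-45 m.
#'
#' @param n_species Number of species (tips).
#' @param scenario One of `"null"`, `"indirect"`, `"direct"`, `"full"`.
#' @param b Allometric slope of `y` on `x` (the `x -> y` path weight).
#' @param intercept Allometric intercept of the log trait (trait in µm,
#'   distance in m).
#' @param w Length-3 weights of `PC1..PC3` on `x`.
#' @param v Length-3 direct weights of `PC1..PC3` on `y`.
#' @param lambda_true Pagel's lambda of the trait residuals.
#' @param sigma_x SD of the non-climatic component of `x`.
#' @param sigma_y Root-to-tip SD of the trait residual Brownian process.
#' @param x_center Mean of `x` (log metres); default centres the implied
#'   distance range on 0.13-45 m.
#' @param x_phylo Should the non-climatic part of `x` be tree-structured
#'   Brownian rather than independent noise? Default `FALSE`.
#' @param orthogonalize_pcs Orthogonalize the PC scores in-sample (the
#'   property PCA scores have)? Default `TRUE`. Calibration simulations use
#'   `FALSE` so claims among PCs are non-degenerate.
#' @param birth_rate,n_trees Tree simulation settings.
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 150,
                              scenario = c("full", "null", "indirect", "direct"),
                              b = NULL, intercept = 3.44,
                              w = c(0.59, 0, 0.4), v = NULL,
                              lambda_true = 0.4,
                              sigma_x = 0.8, sigma_y = 0.35,
                              x_center = mean(log(c(0.13, 45))),
                              x_phylo = FALSE,
                              orthogonalize_pcs = TRUE,
                              birth_rate = 1, n_trees = 1, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: no silent nondeterminism", call. = FALSE)
  }
  permits_b <- scenario %in% c("indirect", "full")
  permits_v <- scenario %in% c("direct", "full")
  if (is.null(b)) b <- if (permits_b) 0.38 else 0
  if (is.null(v)) v <- if (permits_v) c(0.15, -0.1, 0.25) else c(0, 0, 0)
  if (!permits_b && b != 0) {
    stop(sprintf("scenario '%s' has no x -> y path; b must be 0", scenario),
         call. = FALSE)
  }
  if (!permits_v && any(v != 0)) {
    stop(sprintf("scenario '%s' has no direct climate -> trait paths; v must be 0",
                 scenario), call. = FALSE)
  }
  stopifnot(length(w) == 3, length(v) == 3,
            all(abs(w) <= 1), all(abs(v) <= 1),
            sigma_x >= 0, sigma_y >= 0,
            lambda_true >= 0, lambda_true <= 1)
  structure(
    list(
      n_species = as.integer(n_species), scenario = scenario,
      b = b, intercept = intercept, w = w, v = v,
      lambda_true = lambda_true, sigma_x = sigma_x, sigma_y = sigma_y,
      x_center = x_center, x_phylo = x_phylo,
      orthogonalize_pcs = orthogonalize_pcs,
      birth_rate = birth_rate, n_trees = as.integer(n_trees),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# In-sample orthogonal, zero-mean, unit-SD scores from iid normal draws.
orthogonal_scores <- function(n, m) {
  Z <- matrix(stats::rnorm(n * m), n, m)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Zc))[, seq_len(m), drop = FALSE]
  apply(Q, 2, function(col) col / stats::sd(col))
}

#' Simulate one comparative dataset from a causal scenario
#'
#' Generates trees, climate PC scores, log distance-to-tip and the log
#' trait according to the configured scenario:
#' `x = x_center + sum(w_k PC_k) + noise` and
#' `y = intercept + b x + sum(v_k PC_k) + BM(lambda, sigma_y)`, with `b`
#' and/or `v` zero as the scenario dictates.
#'
#' @param config A [simulation_config()].
#' @return A list with `data` (tibble of `species_id`, `PC1..PC3`, `x`,
#'   `y`), `trees` (list of `phylo`), and `truth` (the generating
#'   parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_species
  trees <- lapply(seq_len(config$n_trees), function(i) {
    simulate_tree(n, config$birth_rate, seed = NULL)
  })
  tree <- trees[[1]]
  pc_scores <- if (config$orthogonalize_pcs) {
    orthogonal_scores(n, 3)
  } else {
    matrix(stats::rnorm(n * 3), n, 3)
  }
  colnames(pc_scores) <- c("PC1", "PC2", "PC3")
  x_noise <- if (config$sigma_x == 0) {
    rep(0, n)
  } else if (config$x_phylo) {
    simulate_bm(tree, lambda = 1, sigma = config$sigma_x, seed = NULL)
  } else {
    stats::rnorm(n, 0, config$sigma_x)
  }
  x <- config$x_center + as.numeric(pc_scores %*% config$w) + as.numeric(x_noise)
  e_y <- if (config$sigma_y == 0) {
    rep(0, n)
  } else {
    simulate_bm(tree, lambda = config$lambda_true,
                sigma = config$sigma_y, seed = NULL)
  }
  y <- config$intercept + config$b * x +
    as.numeric(pc_scores %*% config$v) + as.numeric(e_y)
  data <- tibble::tibble(
    species_id = tree$tip.label,
    PC1 = pc_scores[, 1], PC2 = pc_scores[, 2], PC3 = pc_scores[, 3],
    x = x, y = y
  )
  list(data = data, trees = trees, truth = unclass(config))
}

#' Simulate one conduit cross-section fixture
#'
#' Draws lognormal lumen areas and packages them as a [conduit_section()];
#' the draw is rejected and repeated while the summed lumen area exceeds the
#' sector area (at most 1000 attempts).
#'
#' @param n_conduits Number of measured lumina (>= 1).
#' @param log_mean,log_sd Parameters of the lognormal lumen-area
#'   distribution (areas in µm²).
#' @param sector_area Sector area (µm²).
#' @param seed Integer seed, or `NULL`.
#' @param species_id,organ,tissue,distance_to_tip Metadata for the section.
#' @return A `conduit_section` (validated with `strict = FALSE`).
#' @export
simulate_section <- function(n_conduits, log_mean = log(700), log_sd = 0.4,
                             sector_area = n_conduits * exp(log_mean) * 10,
                             seed = NULL, species_id = "synthetic_sp",
                             organ = "main_stem", tissue = "vessel",
                             distance_to_tip = 1) {
  if (n_conduits < 1) stop("need at least one conduit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(1000)) {
    areas <- stats::rlnorm(n_conduits, log_mean, log_sd)
    if (sum(areas) <= sector_area) {
      return(conduit_section(
        species_id = species_id, organ = organ, tissue = tissue,
        distance_to_tip = distance_to_tip, lumen_areas = areas,
        sector_area = sector_area, conduit_count = n_conduits,
        strict = FALSE
      ))
    }
  }
  stop("could not pack conduits into the sector after 1000 attempts",
       call. = FALSE)
}

#' Simulate a bioclim-style climate table
#'
#' Nineteen collinear climate descriptors generated from three latent
#' factors (overall climate intensity, temperature, growing-season water
#' availability) plus per-variable noise — emulating the strong
#' within-block collinearity of the standard bioclim set so that a few
#' principal components capture most of the variance. Variables `bio1..bio11`
#' form the temperature block (degrees C scale), `bio12..bio19` the
#' precipitation block (mm scale).
#'
#' @param n_samples Number of sample locations.
#' @param noise_sd SD of the variable-specific noise relative to unit-SD
#'   factors.
#' @param seed Integer seed, or `NULL`.
#' @return Tibble with `sample_id` and `bio1`..`bio19`.
#' @export
simulate_climate <- function(n_samples, noise_sd = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(stats::rnorm(n_samples * 3), n_samples, 3)
  loadings <- matrix(0, 19, 3)
  for (j in 1:11) loadings[j, ] <- c(0.75, 0.55 + 0.2 * sin(j), 0.1 * cos(j))
  for (j in 12:19) loadings[j, ] <- c(0.75, 0.1 * sin(j), 0.55 + 0.2 * cos(j))
  Z <- f %*% t(loadings) +
    matrix(stats::rnorm(n_samples * 19, 0, noise_sd), n_samples, 19)
  # put the blocks on plausible measurement scales
  Z[, 1:11] <- 12 + 7 * Z[, 1:11]
  Z[, 12:19] <- 1200 + 550 * Z[, 12:19]
  colnames(Z) <- paste0("bio", 1:19)
  tibble::as_tibble(Z) |>
    tibble::add_column(sample_id = sprintf("loc%03d", seq_len(n_samples)),
                       .before = 1)
}

#' Simulate a complete synthetic study and write it to disk
#'
#' Produces every input the pipeline consumes — a species trait table with
#' allometric structure for vessels and sieve elements, candidate trees, a
#' climate table aligned to species — plus a ground-truth JSON sidecar, all
#' as plain-text files.
#'
#' @param dir Output directory (created if needed).
#' @param n_species,n_trees,seed Study dimensions and seed.
#' @param lambda_true,b_vessel,b_sieve Generating parameters: phylogenetic
#'   signal of trait residuals and the vessel/sieve allometric slopes
#'   (defaults 0.38 and 0.26, the fitted main-stem exponents).
#' @return Invisibly, a list of the written file paths.
#' @export
simulate_study_files <- function(dir, n_species = 150, n_trees = 3, seed,
                                 lambda_true = 0.4, b_vessel = 0.38,
                                 b_sieve = 0.26) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # climate reaches the traits through plant size only (the dominant route
  # in the fitted path models), so the marginal trait-distance slope equals
  # the configured allometric exponent
  cfg <- simulation_config(n_species = n_species, scenario = "indirect",
                           b = b_vessel, intercept = 3.44,
                           lambda_true = lambda_true, n_trees = n_trees,
                           seed = seed)
  sim <- simulate_dataset(cfg)
  dat <- sim$data
  # second tissue: sieve elements share x and climate, have their own
  # allometry and residuals
  e_sieve <- simulate_bm(sim$trees[[1]], lambda = lambda_true,
                         sigma = cfg$sigma_y, seed = NULL)
  y_sieve <- 2.38 + b_sieve * dat$x +
    as.numeric(as.matrix(dat[, c("PC1", "PC2", "PC3")]) %*% cfg$v) +
    as.numeric(e_sieve)
  traits <- tibble::tibble(
    species_id = rep(dat$species_id, 2),
    organ = "main_stem",
    tissue = rep(c("vessel", "sieve_element"), each = nrow(dat)),
    distance_to_tip = rep(exp(dat$x), 2),
    d_median = exp(c(dat$y, y_sieve))
  )
  climate <- simulate_climate(n_species, seed = NULL)
  climate$sample_id <- dat$species_id
  paths <- list(
    traits = file.path(dir, "traits.csv"),
    trees = file.path(dir, "trees.nwk"),
    climate = file.path(dir, "climate.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(traits, paths$traits)
  ape::write.tree(structure(sim$trees, class = "multiPhylo"), file = paths$trees)
  readr::write_csv(climate, paths$climate)
  jsonlite::write_json(
    list(seed = seed, n_species = n_species, n_trees = n_trees,
         lambda_true = lambda_true, b_vessel = b_vessel, b_sieve = b_sieve,
         intercept_vessel = 3.44, intercept_sieve = 2.38,
         scenario = cfg$scenario, w = cfg$w, v = cfg$v),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
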
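# Phylogenetic path analysis: directed acyclic causal scenarios linking
# climate components (PC1..PC3), log distance-to-tip (x) and a log trait
# (y), tested by d-separation with per-claim phylogenetic GLS, combined with
# Fisher's C and ranked by the C-statistic information criterion (CICc).

#' Construct a causal model (directed acyclic graph)
#'
#' @param name Model label.
#' @param nodes Character vector of node names (order is used for claim
#'   orientation tie-breaks).
#' @param edges Two-column character matrix (or data frame) of directed
#'   edges, `from` -> `to`.
#' @return A `causal_model` object.
#' @export
causal_model <- function(name, nodes, edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  colnames(edges) <- c("from", "to")
  if (!all(edges %in% nodes)) stop("edge endpoints must be nodes", call. = FALSE)
  m <- structure(list(name = name, nodes = nodes, edges = edges),
                 class = "causal_model")
  if (!is_acyclic(m)) stop("graph is cyclic", call. = FALSE)
  m
}

#' @export
print.causal_model <- function(x, ...) {
  cat(sprintf("<causal_model> %s: %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(" ", paste(x$edges[, 1], "->", x$edges[, 2], collapse = ", "), "\n")
  }
  invisible(x)
}

adjacency <- function(model) {
  A <- matrix(0L, length(model$nodes), length(model$nodes),
              dimnames = list(model$nodes, model$nodes))
  if (nrow(model$edges) > 0) A[model$edges] <- 1L
  A
}

is_acyclic <- function(model) {
  A <- adjacency(model)
  remaining <- rownames(A)
  while (length(remaining) > 0) {
    indeg <- colSums(A[remaining, remaining, drop = FALSE])
    leaves <- remaining[indeg == 0]
    if (length(leaves) == 0) return(FALSE)
    remaining <- setdiff(remaining, leaves)
  }
  TRUE
}

# Reachability (strict ancestry) matrix by powers of the adjacency matrix.
reachability <- function(model) {
  A <- adjacency(model)
  R <- A
  P <- A
  for (i in seq_len(length(model$nodes))) {
    P <- (P %*% A > 0) * 1L
    R <- ((R + P) > 0) * 1L
  }
  R
}

parents_of <- function(model, node) {
  e <- model$edges
  unname(e[e[, 2] == node, 1])
}

#' The four causal scenarios for climate, plant size and conduit traits
#'
#' All scenarios share the paths from the three climate components to
#' distance-to-tip (`PC1 -> x`, `PC2 -> x`, `PC3 -> x`), reflecting the
#' strong climatic control of plant height. They differ in how the trait
#' `y` is reached: the null model has no edge into `y`; the indirect model
#' adds only `x -> y` (climate acts through plant size); the direct model
#' adds only `PCk -> y`; the full model has both routes.
#'
#' @return Named list of four `causal_model` objects
#'   (`null`, `indirect`, `direct`, `full`), nodes ordered
#'   `PC1, PC2, PC3, x, y`.
#' @export
build_scenarios <- function() {
  nodes <- c("PC1", "PC2", "PC3", "x", "y")
  common <- cbind(from = c("PC1", "PC2", "PC3"), to = c("x", "x", "x"))
  xy <- cbind(from = "x", to = "y")
  direct_edges <- cbind(from = c("PC1", "PC2", "PC3"), to = c("y", "y", "y"))
  list(
    null = causal_model("null", nodes, common),
    indirect = causal_model("indirect", nodes, rbind(common, xy)),
    direct = causal_model("direct", nodes, rbind(common, direct_edges)),
    full = causal_model("full", nodes, rbind(common, direct_edges, xy))
  )
}

#' d-separation basis set of a causal model
#'
#' One conditional-independence claim per non-adjacent vertex pair: the pair
#' must be independent given the union of both vertices' parents. The
#' causally downstream vertex of the pair is the regression response (second
#' by node order when neither is an ancestor of the other); the other is the
#' probe whose coefficient is tested.
#'
#' @param model A `causal_model`.
#' @return A list of claims, each a list with `response`, `probe` and
#'   `conditioning` (character vector, possibly empty).
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "causal_model"))
  A <- adjacency(model)
  R <- reachability(model)
  nodes <- model$nodes
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j]
      if (A[a, b] == 1 || A[b, a] == 1) next
      if (R[a, b] == 1) {           # a is an ancestor of b: b downstream
        response <- b; probe <- a
      } else if (R[b, a] == 1) {
        response <- a; probe <- b
      } else {
        response <- b; probe <- a   # neither precedes: second by node order
      }
      cond <- setdiff(union(parents_of(model, a), parents_of(model, b)),
                      c(a, b))
      claims[[length(claims) + 1]] <- list(
        response = response, probe = probe, conditioning = cond
      )
    }
  }
  claims
}

#' Test one independence claim by phylogenetic GLS
#'
#' Regresses the claim's response on its conditioning set plus the probe
#' variable under the phylogenetic covariance, and returns the two-sided
#' p-value of the probe coefficient.
#'
#' @param claim A claim from [basis_set()].
#' @param data Data frame containing the model's node columns (scaled via
#'   [scale_for_sem()] in the standard workflow).
#' @param pc A `phylo_cov` aligned to the rows of `data`, or `NULL` for
#'   ordinary GLS.
#' @param lambda `"ml"` or a fixed numeric lambda for the claim regression.
#' @return The probe p-value, with the fitted probe coefficient in
#'   attribute `coefficient`.
#' @export
test_claim <- function(claim, data, pc = NULL, lambda = "ml") {
  vars <- c(claim$conditioning, claim$probe)
  X <- cbind(1, as.matrix(data[, vars, drop = FALSE]))
  colnames(X) <- c("(Intercept)", vars)
  y <- data[[claim$response]]
  core <- pgls_core(y, X, pc, "identity", lambda = lambda)
  idx <- ncol(X)
  out <- core$p[idx]
  attr(out, "coefficient") <- core$coefficients[idx]
  out
}

#' Fisher's C statistic over a set of independence-claim p-values
#'
#' `C = -2 sum(log p_i)`, chi-squared with `2k` degrees of freedom when the
#' causal model is correct; large C means the data violate the model's
#' claimed independencies.
#'
#' @param p_values Numeric vector of claim p-values in `(0, 1]` (an empty
#'   vector denotes a saturated model: C = 0, dof = 0, p = 1). Zeros are
#'   clamped to the smallest positive double with a warning.
#' @return List with `C`, `dof` and `p`.
#' @export
fisher_c <- function(p_values) {
  if (length(p_values) == 0) return(list(C = 0, dof = 0L, p = 1))
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_values == 0)) {
    warning("claim p-value of 0 clamped to smallest positive double",
            call. = FALSE)
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  C <- -2 * sum(log(p_values))
  dof <- 2L * length(p_values)
  list(C = C, dof = dof, p = stats::pchisq(C, dof, lower.tail = FALSE))
}

#' C-statistic information criterion
#'
#' `CICc = C + 2 q n / (n - q - 1)`: Fisher's C penalized by the number of
#' model parameters `q` with a small-sample correction, used to rank
#' candidate path models (lower is better).
#'
#' @param C Fisher's C.
#' @param q Parameter count of the model (number of directed edges).
#' @param n Number of observations.
#' @return The CICc value.
#' @export
cicc <- function(C, q, n) {
  if (n <= q + 1) {
    stop(sprintf("CICc undefined: need n > q + 1 (n = %d, q = %d); more species or a sparser model required",
                 n, q), call. = FALSE)
  }
  C + 2 * q * n / (n - q - 1)
}

#' Standardized path coefficients of a causal model
#'
#' Fits one phylogenetic GLS per endogenous node (each node with parents is
#' regressed on all its parents) and reports the coefficients on the scaled
#' data as the path weights, with 95% confidence intervals.
#'
#' @inheritParams test_claim
#' @param model A `causal_model`.
#' @return A tibble with `from`, `to`, `coefficient`, `ci_low`, `ci_high`,
#'   `p_value` — one row per directed edge.
#' @export
fit_paths <- function(model, data, pc = NULL, lambda = "ml") {
  stopifnot(inherits(model, "causal_model"))
  endo <- unique(model$edges[, 2])
  rows <- lapply(endo, function(node) {
    pars <- parents_of(model, node)
    X <- cbind(1, as.matrix(data[, pars, drop = FALSE]))
    core <- pgls_core(data[[node]], X, pc, "identity", lambda = lambda)
    tcrit <- stats::qt(0.975, core$df)
    idx <- seq_along(pars) + 1
    tibble::tibble(
      from = pars, to = node,
      coefficient = core$coefficients[idx],
      ci_low = core$coefficients[idx] - tcrit * core$se[idx],
      ci_high = core$coefficients[idx] + tcrit * core$se[idx],
      p_value = core$p[idx]
    )
  })
  dplyr::bind_rows(rows)
}

# Evaluate one model on one tree: claim p-values, Fisher's C, CICc, paths.
evaluate_model <- function(model, data, pc, lambda = "ml") {
  claims <- basis_set(model)
  pvals <- vapply(claims, function(cl) as.numeric(test_claim(cl, data, pc, lambda)),
                  numeric(1))
  fc <- fisher_c(pvals)
  q <- nrow(model$edges)
  n <- nrow(data)
  list(
    model = model$name,
    claims = claims, p_values = pvals,
    C = fc$C, dof = fc$dof, C_p_value = fc$p,
    q = q, n = n, CICc = cicc(fc$C, q, n),
    coefficients = fit_paths(model, data, pc, lambda)
  )
}

#' Compare causal scenarios across candidate phylogenies
#'
#' Runs the d-separation tests, Fisher's C and CICc for every scenario on
#' every tree, selects the scenario with the lowest mean CICc across trees,
#' and averages the path coefficients across trees. Per-tree selections are
#' retained so topological disagreement stays visible.
#'
#' @param data Data frame with the node columns (`PC1`, `PC2`, `PC3`, `x`,
#'   `y`), plus a `species_id` column aligned to the tree tips.
#' @param trees A list of `phylo` (or `phylo_cov`) objects; a single tree is
#'   accepted.
#' @param models Candidate `causal_model`s; defaults to [build_scenarios()].
#' @param lambda `"ml"` or fixed numeric lambda for all claim and path
#'   regressions.
#' @return A `path_comparison` object: `summary` (tibble of model, mean C,
#'   mean CICc, delta CICc, selection rate across trees), `selected` (name
#'   of the lowest-mean-CICc model), `coefficients` (cross-tree mean path
#'   weights of every model) and `per_tree` details.
#' @export
compare_models <- function(data, trees, models = build_scenarios(),
                           lambda = "ml") {
  if (inherits(trees, "phylo") || inherits(trees, "phylo_cov")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  names(models) <- vapply(models, `[[`, character(1), "name")
  node_cols <- unique(unlist(lapply(models, `[[`, "nodes")))
  missing_cols <- setdiff(node_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing node columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  per_tree <- lapply(trees, function(tr) {
    pc <- if (inherits(tr, "phylo_cov")) tr else brownian_vcv(tr)
    if (!is.null(data$species_id)) pc <- align_phylo_cov(pc, data$species_id)
    lapply(models, evaluate_model, data = data, pc = pc, lambda = lambda)
  })
  model_names <- vapply(models, `[[`, character(1), "name")
  mean_c <- vapply(model_names, function(m) {
    mean(vapply(per_tree, function(pt) pt[[m]]$C, numeric(1)))
  }, numeric(1))
  mean_cicc <- vapply(model_names, function(m) {
    mean(vapply(per_tree, function(pt) pt[[m]]$CICc, numeric(1)))
  }, numeric(1))
  per_tree_best <- vapply(per_tree, function(pt) {
    names(which.min(vapply(pt, `[[`, numeric(1), "CICc")))
  }, character(1))
  coef_means <- dplyr::bind_rows(lapply(model_names, function(m) {
    coefs <- lapply(per_tree, function(pt) pt[[m]]$coefficients)
    dplyr::bind_rows(coefs) |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(dplyr::across(c("coefficient", "ci_low", "ci_high",
                                       "p_value"), mean),
                       .groups = "drop") |>
      dplyr::mutate(model = m, .before = 1)
  }))
  summary_tbl <- tibble::tibble(
    model = unname(model_names),
    q = unname(vapply(models, function(m) nrow(m$edges), numeric(1))),
    mean_C = unname(mean_c),
    mean_CICc = unname(mean_cicc),
    delta_CICc = unname(mean_cicc - min(mean_cicc)),
    selection_rate = unname(vapply(model_names,
                                   function(m) mean(per_tree_best == m),
                                   numeric(1)))
  )
  structure(
    list(
      summary = summary_tbl,
      selected = model_names[which.min(mean_cicc)],
      coefficients = coef_means,
      per_tree = per_tree,
      n_trees = length(trees)
    ),
    class = "path_comparison"
  )
}

#' @export
print.path_comparison <- function(x, ...) {
  cat(sprintf("<path_comparison> %d trees; selected model: %s\n",
              x$n_trees, x$selected))
  print(x$summary)
  invisible(x)
}
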
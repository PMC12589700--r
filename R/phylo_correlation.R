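# Phylogeny-corrected Pearson correlations between traits. The evolutionary
# trait variance-covariance matrix is estimated under a multivariate
# Brownian model whose tip covariance C(lambda) shares one jointly
# maximized Pagel's lambda across all traits.

#' Phylogenetic (GLS) mean of each trait column
#'
#' The generalized least-squares estimate of the root state,
#' `a = (1' C^{-1} 1)^{-1} 1' C^{-1} Y` per column: species are weighted by
#' their phylogenetic non-redundancy instead of equally.
#'
#' @param Y Numeric matrix (species x traits), rows aligned to
#'   `pc$tip_labels`.
#' @param pc A `phylo_cov`.
#' @return Named numeric vector of GLS means (one per column of `Y`).
#' @export
phylo_mean <- function(Y, pc) {
  Y <- as.matrix(Y)
  C <- pc$C
  stopifnot(nrow(Y) == nrow(C))
  Cinv_one <- solve(C, rep(1, nrow(C)))
  denom <- sum(Cinv_one)
  as.numeric(crossprod(Cinv_one, Y)) / denom
}

#' Evolutionary variance-covariance matrix of traits
#'
#' `R = (Y - 1 a)' C(lambda)^{-1} (Y - 1 a) / (n - 1)` with `a` the GLS
#' means: the trait covariance expected to accrue per unit branch length
#' under correlated Brownian evolution.
#'
#' @inheritParams phylo_mean
#' @param lambda Pagel's lambda applied to `C` before inversion.
#' @return Trait covariance matrix (traits x traits).
#' @export
evolutionary_vcv <- function(Y, pc, lambda = 1) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 species", call. = FALSE)
  Cl <- lambda_scale(pc$C, lambda)
  pcl <- new_phylo_cov(Cl, lambda)
  a <- phylo_mean(Y, pcl)
  Yc <- sweep(Y, 2, a)
  crossprod(Yc, solve(Cl, Yc)) / (n - 1)
}

# Multivariate Brownian profile log-likelihood at a given lambda: the GLS
# means and the ML trait covariance (divisor n) are profiled out.
joint_lambda_loglik <- function(Y, pc, lambda) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  m <- ncol(Y)
  Cl <- lambda_scale(pc$C, lambda)
  U <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  a <- phylo_mean(Y, new_phylo_cov(Cl, lambda))
  Yc <- sweep(Y, 2, a)
  Yt <- backsolve(U, Yc, transpose = TRUE)
  R_ml <- crossprod(Yt) / n
  logdet_C <- 2 * sum(log(diag(U)))
  logdet_R <- determinant(R_ml, logarithm = TRUE)$modulus
  if (!is.finite(logdet_R)) return(-Inf)
  -0.5 * (n * m * log(2 * pi) + n * logdet_R + m * logdet_C + n * m)
}

#' Jointly maximized Pagel's lambda for a trait matrix
#'
#' Maximizes the multivariate Brownian likelihood over one lambda shared by
#' all traits (the trait covariance and root states are profiled out
#' analytically).
#'
#' @inheritParams phylo_mean
#' @return The maximizing lambda in `[0, 1]`, with the profile grid in
#'   attribute `profile`.
#' @export
joint_lambda <- function(Y, pc) {
  Y <- as.matrix(Y)
  opt <- stats::optimize(function(l) joint_lambda_loglik(Y, pc, l),
                         c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, function(l) joint_lambda_loglik(Y, pc, l), numeric(1))
  if (all(!is.finite(ll))) stop("non-finite joint-lambda likelihood", call. = FALSE)
  out <- cand[which(ll >= max(ll) - 1e-6)][1]
  attr(out, "loglik") <- max(ll)
  out
}

#' Phylogeny-corrected Pearson correlations between all trait pairs
#'
#' Computes the evolutionary trait covariance under one jointly maximized
#' lambda and converts it to Pearson product-moment correlations
#' `r = R_ab / sqrt(R_aa R_bb)`; two-sided p-values use the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom.
#'
#' @inheritParams phylo_mean
#' @param lambda `"joint"` (default: maximize one lambda for the trait set)
#'   or a fixed numeric value.
#' @return A tibble with one row per unordered trait pair: `trait_a`,
#'   `trait_b`, `r`, `p_value`, `stars`, `joint_lambda`, `n`. Pairs
#'   involving a zero-variance trait carry `NA` with a warning.
#' @export
correlate <- function(Y, pc, lambda = "joint") {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(ncol(Y)))
  lam <- if (identical(lambda, "joint")) as.numeric(joint_lambda(Y, pc)) else lambda
  R <- evolutionary_vcv(Y, pc, lam)
  v <- diag(R)
  v[v <= 1e-12 * max(v, 1)] <- 0    # numerically zero variance
  pairs <- utils::combn(colnames(Y), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    aname <- pairs[1, i]; bname <- pairs[2, i]
    va <- v[aname]; vb <- v[bname]
    if (va <= 0 || vb <= 0) {
      warning(sprintf("zero variance for pair (%s, %s); correlation undefined",
                      aname, bname), call. = FALSE)
      r <- NA_real_; p <- NA_real_
    } else {
      r <- R[aname, bname] / sqrt(va * vb)
      r <- max(-1, min(1, r))
      if (abs(r) >= 1) {
        p <- 0
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
      }
    }
    tibble::tibble(trait_a = aname, trait_b = bname, r = r, p_value = p,
                   stars = p_stars(p), joint_lambda = lam, n = n)
  })
  dplyr::bind_rows(rows)
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "ns",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
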
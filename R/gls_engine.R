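# Generalized least squares engine for log-log allometries with optional
# phylogenetic covariance (Pagel's lambda) and diagonal variance structures.
#
# Model: y = X beta + e,  e ~ N(0, sigma^2 * W(delta)^{1/2} C(lambda) W(delta)^{1/2})
# where C is the Brownian tip covariance (identity for plain GLS) and W holds
# diagonal variance weights driven by a covariate. All likelihoods are exact
# Gaussian ML, so BIC is comparable across covariance/variance structures.

# Diagonal variance weights for a given structure and parameter delta.
variance_weights <- function(structure, delta, w_cov) {
  switch(structure,
    identity = rep(1, length(w_cov)),
    power = abs(w_cov)^(2 * delta),
    exponential = exp(2 * delta * w_cov),
    stop("unknown variance structure: ", structure, call. = FALSE)
  )
}

# Profile log-likelihood machinery: for fixed (lambda, delta) the scale
# sigma^2 and beta are profiled out analytically.
gls_eval <- function(y, X, C, lambda, structure, delta, w_cov) {
  n <- length(y)
  w <- variance_weights(structure, delta, w_cov)
  if (any(!is.finite(w)) || any(w <= 0)) return(NULL)
  V0 <- if (is.null(C)) diag(w, n) else {
    sw <- sqrt(w)
    lambda_scale(C, lambda) * tcrossprod(sw)
  }
  U <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  yt <- backsolve(U, y, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xt)
  if (qrX$rank < ncol(X)) {
    stop("singular design matrix in GLS fit (rank ", qrX$rank, " < ", ncol(X),
         ")", call. = FALSE)
  }
  beta <- qr.coef(qrX, yt)
  resid_w <- yt - Xt %*% beta
  rss <- sum(resid_w^2)
  sigma2_ml <- rss / n
  logdet <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * (log(2 * pi) + log(sigma2_ml) + 1) + logdet)
  XtXinv <- chol2inv(qr.R(qrX))
  list(
    beta = as.numeric(beta), rss = rss, sigma2_ml = sigma2_ml,
    loglik = loglik, XtXinv = XtXinv, qrX = qrX, yt = yt, Xt = Xt
  )
}

# Maximize the profile likelihood over lambda and/or delta.
gls_optimize <- function(y, X, C, structure, w_cov, lambda_mode,
                         lambda_max = 1, tol = 1e-6) {
  has_lambda <- !is.null(C) && identical(lambda_mode, "ml")
  fixed_lambda <- if (!is.null(C) && is.numeric(lambda_mode)) lambda_mode else 1
  has_delta <- structure != "identity"
  obj <- function(lambda, delta) {
    ev <- gls_eval(y, X, C, lambda, structure, delta, w_cov)
    if (is.null(ev)) -Inf else ev$loglik
  }
  lambda_hat <- if (is.null(C)) NA_real_ else fixed_lambda
  delta_hat <- if (has_delta) 0 else NA_real_
  if (has_lambda && !has_delta) {
    opt <- stats::optimize(function(l) obj(l, 0), c(0, lambda_max),
                           maximum = TRUE, tol = tol)
    # ties toward the boundary nearest zero
    cand <- c(0, opt$maximum, lambda_max)
    ll <- vapply(cand, function(l) obj(l, 0), numeric(1))
    lambda_hat <- cand[which(ll >= max(ll) - 1e-6)][1]
  } else if (!has_lambda && has_delta) {
    opt <- stats::optimize(function(d) obj(fixed_lambda, d), c(-5, 5),
                           maximum = TRUE, tol = tol)
    delta_hat <- opt$maximum
    if (!is.null(C)) lambda_hat <- fixed_lambda
  } else if (has_lambda && has_delta) {
    opt <- stats::optim(
      c(0.5, 0), function(p) -obj(p[1], p[2]),
      method = "L-BFGS-B", lower = c(0, -5), upper = c(lambda_max, 5),
      control = list(factr = 1e7)
    )
    lambda_hat <- opt$par[1]
    delta_hat <- opt$par[2]
    if (obj(0, delta_hat) >= obj(lambda_hat, delta_hat) - 1e-8) lambda_hat <- 0
  }
  list(lambda = lambda_hat, delta = delta_hat,
       eval = gls_eval(y, X, C,
                       ifelse(is.na(lambda_hat), 1, lambda_hat),
                       structure, ifelse(is.na(delta_hat), 0, delta_hat),
                       w_cov))
}

# Internal multi-predictor (p)GLS fit used by the allometry interface and by
# the d-separation claim tests. X must include the intercept column.
pgls_core <- function(y, X, pc = NULL, variance_structure = "identity",
                      lambda = "ml", w_cov = NULL, lambda_max = 1) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X)) stop("need more observations than coefficients", call. = FALSE)
  C <- if (is.null(pc)) NULL else pc$C
  if (!is.null(C) && nrow(C) != n) {
    stop("phylogenetic covariance dimension does not match data", call. = FALSE)
  }
  if (is.null(w_cov)) w_cov <- if (ncol(X) >= 2) X[, 2] else rep(1, n)
  fit <- gls_optimize(y, X, C, variance_structure, w_cov, lambda, lambda_max)
  ev <- fit$eval
  if (is.null(ev)) stop("GLS likelihood could not be evaluated (singular covariance?)",
                        call. = FALSE)
  p <- ncol(X)
  df_resid <- n - p
  sigma2_unbiased <- ev$rss / df_resid
  se <- sqrt(diag(ev$XtXinv) * sigma2_unbiased)
  tval <- ev$beta / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  k <- p + 1 +
    (!is.null(C) && identical(lambda, "ml")) +
    (variance_structure != "identity")
  list(
    coefficients = ev$beta, se = se, t = tval, p = pval, df = df_resid,
    lambda = fit$lambda, delta = fit$delta, sigma2_ml = ev$sigma2_ml,
    loglik = ev$loglik, k = k, n = n,
    aic = -2 * ev$loglik + 2 * k, bic = -2 * ev$loglik + k * log(n),
    variance_structure = variance_structure,
    model_type = if (is.null(C)) "gls" else "pgls"
  )
}

#' Fit a (phylogenetic) GLS allometry of a log trait on log distance-to-tip
#'
#' Fits `y = intercept + b * x` by exact maximum likelihood under
#' `Var(e) = sigma^2 W(delta)^{1/2} C(lambda) W(delta)^{1/2}`, where `C` is
#' the Brownian tip covariance of a phylogeny (omitted for plain GLS) with
#' Pagel's lambda estimated by profile likelihood, and `W` an optional
#' diagonal variance structure driven by the covariate. 95% confidence
#' intervals and the slope p-value use the t distribution with residual
#' degrees of freedom.
#'
#' @param y Numeric response (log trait), aligned to `pc$tip_labels` if `pc`
#'   is given.
#' @param x Numeric covariate (log distance-to-tip, distance in metres).
#' @param pc A `phylo_cov` from [brownian_vcv()], or `NULL` for plain GLS.
#' @param variance_structure One of `"identity"`, `"power"`
#'   (weights `|x|^(2 delta)`) or `"exponential"` (weights `exp(2 delta x)`);
#'   `delta` is estimated by ML.
#' @param lambda `"ml"` (profile-maximized over `[0, 1]`, ties toward 0) or a
#'   fixed numeric value.
#' @param species_id Optional species labels stored with the fit (used by
#'   [detrend()]).
#' @param trait_name,organ,tissue Optional descriptors carried into reports.
#' @return A `scaling_fit` object; see Details. Key fields: `intercept`,
#'   `slope`, `slope_ci_low`, `slope_ci_high`, `slope_p_value`, `df`,
#'   `lambda_hat`, `log_likelihood`, `aic`, `bic`, `r2`, `partial_r2`,
#'   `model_type`.
#' @details `r2` is a likelihood-ratio coefficient of determination
#'   comparing the fit with its intercept-only reduction, both without
#'   phylogenetic covariance; `partial_r2` (phylogenetic fits only) compares
#'   the full fit with the intercept-only reduction under the same
#'   covariance family with lambda re-estimated, via
#'   `1 - exp(-(2/n) (logL_full - logL_reduced))`.
#' @export
fit_gls <- function(y, x, pc = NULL, variance_structure = "identity",
                    lambda = "ml", species_id = NULL, trait_name = "trait",
                    organ = NA_character_, tissue = NA_character_) {
  stopifnot(length(y) == length(x))
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!is.null(pc) && !is.null(species_id)) pc <- align_phylo_cov(pc, species_id)
  variance_structure <- match.arg(variance_structure,
                                  c("identity", "power", "exponential"))
  X <- cbind(`(Intercept)` = 1, x = x)
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    warning("response is (near-)constant; fit is degenerate", call. = FALSE)
  }
  core <- pgls_core(y, X, pc, variance_structure, lambda)
  tcrit <- stats::qt(0.975, core$df)
  # likelihood-ratio R2 against the intercept-only model, phylogeny ignored
  X0 <- X[, 1, drop = FALSE]
  full0 <- pgls_core(y, X, NULL, variance_structure, lambda = "ml", w_cov = x)
  red0 <- pgls_core(y, X0, NULL, variance_structure, lambda = "ml", w_cov = x)
  r2 <- r2_lik(full0$loglik, red0$loglik, core$n)
  partial <- NA_real_
  if (core$model_type == "pgls") {
    redp <- pgls_core(y, X0, pc, variance_structure, lambda = lambda, w_cov = x)
    partial <- r2_lik(core$loglik, redp$loglik, core$n)
  }
  structure(
    list(
      trait_name = trait_name, organ = organ, tissue = tissue,
      intercept = core$coefficients[1], slope = core$coefficients[2],
      slope_se = core$se[2],
      slope_ci_low = core$coefficients[2] - tcrit * core$se[2],
      slope_ci_high = core$coefficients[2] + tcrit * core$se[2],
      slope_p_value = core$p[2], df = core$df, n = core$n,
      lambda_hat = core$lambda, delta_hat = core$delta,
      variance_structure = core$variance_structure,
      log_likelihood = core$loglik, aic = core$aic, bic = core$bic,
      k = core$k, r2 = r2, partial_r2 = partial,
      model_type = core$model_type,
      species_id = species_id, y = y, x = x
    ),
    class = "scaling_fit"
  )
}

r2_lik <- function(loglik_full, loglik_reduced, n) {
  min(1, max(0, 1 - exp(-(2 / n) * (loglik_full - loglik_reduced))))
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit:%s> %s: intercept %.3f, slope %.3f [%.3f, %.3f], p = %.3g\n",
    x$model_type, x$trait_name, x$intercept, x$slope, x$slope_ci_low,
    x$slope_ci_high, x$slope_p_value
  ))
  cat(sprintf("  n = %d, lambda = %s, var = %s, logLik %.2f, AIC %.2f, BIC %.2f\n",
              x$n, ifelse(is.na(x$lambda_hat), "-", sprintf("%.3f", x$lambda_hat)),
              x$variance_structure, x$log_likelihood, x$aic, x$bic))
  invisible(x)
}

#' Profile-likelihood estimate of Pagel's lambda for a trait-on-distance fit
#'
#' @inheritParams fit_gls
#' @param grid_n Number of grid points used to assess flatness of the
#'   profile (diagnostic only).
#' @return The estimate `lambda_hat` with attributes `flat` (logical flag:
#'   profile flat within tolerance, estimate pinned to the boundary) and
#'   `profile` (tibble of lambda, log-likelihood).
#' @export
estimate_lambda <- function(y, x, pc, grid_n = 21) {
  X <- cbind(1, x)
  if (stats::sd(y) < .Machine$double.eps^0.5) {
    warning("response is constant; lambda is unidentifiable", call. = FALSE)
    out <- 0
    attr(out, "flat") <- TRUE
    return(out)
  }
  core <- pgls_core(y, X, pc, "identity", lambda = "ml")
  grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(grid, function(l) {
    gls_eval(y, X, pc$C, l, "identity", 0, x)$loglik
  }, numeric(1))
  flat <- (max(ll) - min(ll)) < 1e-6
  out <- if (flat) 0 else core$lambda
  if (flat) warning("lambda profile is flat; returning boundary value 0",
                    call. = FALSE)
  attr(out, "flat") <- flat
  attr(out, "profile") <- tibble::tibble(lambda = grid, loglik = ll)
  out
}

#' Select the best allometric model by BIC
#'
#' @param candidates A list of `scaling_fit` objects fit to the same
#'   observations by maximum likelihood.
#' @return The candidate with the lowest BIC, with a `delta_bic` attribute
#'   (tibble of model type, variance structure, BIC and delta-BIC).
#' @export
select_model <- function(candidates) {
  if (inherits(candidates, "scaling_fit")) candidates <- list(candidates)
  stopifnot(length(candidates) >= 1,
            all(vapply(candidates, inherits, logical(1), "scaling_fit")))
  ns <- vapply(candidates, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) {
    stop("candidates were fit to different numbers of observations", call. = FALSE)
  }
  bics <- vapply(candidates, `[[`, numeric(1), "bic")
  best <- candidates[[which.min(bics)]]
  attr(best, "delta_bic") <- tibble::tibble(
    model_type = vapply(candidates, `[[`, character(1), "model_type"),
    variance_structure = vapply(candidates, `[[`, character(1), "variance_structure"),
    bic = bics,
    delta_bic = bics - min(bics)
  )
  best
}

#' Likelihood-ratio partial R-squared of nested GLS fits
#'
#' `1 - exp(-(2/n) (logL_full - logL_reduced))`, floored at zero — the
#' likelihood-based coefficient of partial determination for GLS models
#' (applicable to any pair of nested fits sharing data and covariance
#' family).
#'
#' @param full,reduced `scaling_fit` objects (or anything with a
#'   `log_likelihood` field), reduced nested in full.
#' @param n Number of observations; defaults to `full$n`.
#' @return Partial R-squared in `[0, 1]`.
#' @export
partial_r2 <- function(full, reduced, n = full$n) {
  llf <- full$log_likelihood
  llr <- reduced$log_likelihood
  if (llf < llr - 1e-6) {
    stop("full model has lower likelihood than reduced model: not nested or not converged",
         call. = FALSE)
  }
  r2_lik(llf, llr, n)
}

#' Detrended trait values (residuals from the fitted allometry)
#'
#' The detrended value of a species is its log-trait residual
#' `d = y - (intercept + b x)` at its distance-to-tip: positive when the
#' species has a larger trait than the allometry predicts at that distance.
#' Residuals are on the response (log) scale regardless of any covariance or
#' variance structure used in fitting.
#'
#' @param fit A `scaling_fit`.
#' @param y,x Data to detrend; default to the training data stored in `fit`.
#' @return A tibble with `species_id` (if known), `trait_name` and
#'   `residual`.
#' @export
detrend <- function(fit, y = fit$y, x = fit$x) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (length(y) != length(x)) stop("y and x lengths differ", call. = FALSE)
  res <- y - (fit$intercept + fit$slope * x)
  tibble::tibble(
    species_id = if (!is.null(fit$species_id) &&
                     length(fit$species_id) == length(res)) {
      fit$species_id
    } else {
      NA_character_
    },
    trait_name = fit$trait_name,
    residual = res
  )
}

#' Compare two allometric slopes by confidence-interval overlap
#'
#' Two traits are considered to have distinct scaling exponents when the 95%
#' confidence intervals of their slopes do not overlap.
#'
#' @param a,b `scaling_fit` objects.
#' @return `"distinct"` or `"overlapping"`.
#' @export
compare_slopes <- function(a, b) {
  stopifnot(inherits(a, "scaling_fit"), inherits(b, "scaling_fit"))
  disjoint <- a$slope_ci_high < b$slope_ci_low || b$slope_ci_high < a$slope_ci_low
  if (disjoint) "distinct" else "overlapping"
}

#' Compare per-laboratory regressions against the pooled fit
#'
#' Fits an ordinary least-squares regression of log trait on log distance
#' per source laboratory (groups below the minimum size are skipped) and
#' flags any group whose intercept or slope 95% confidence interval fails to
#' overlap the corresponding 95% interval of the pooled model.
#'
#' @param data A data frame with columns `y` (log trait), `x` (log
#'   distance) and `group` (laboratory label).
#' @param min_group_size Smallest group analysed; default 6 (more than five
#'   species).
#' @return A tibble with one row per analysed group: `group`, `n`,
#'   `intercept`, `slope`, their CIs, and logical `flagged`; skipped groups
#'   are listed in the `skipped` attribute.
#' @export
compare_group_fits <- function(data, min_group_size = 6) {
  stopifnot(all(c("y", "x", "group") %in% names(data)))
  pooled <- stats::lm(y ~ x, data = data)
  pooled_coef <- stats::coef(pooled)
  pooled_ci <- stats::confint(pooled, level = 0.95)
  groups <- split(data, data$group)
  sizes <- vapply(groups, nrow, integer(1))
  skipped <- names(groups)[sizes < min_group_size]
  groups <- groups[sizes >= min_group_size]
  if (length(skipped) > 0) {
    message("skipping groups below minimum size (", min_group_size, "): ",
            paste(skipped, collapse = ", "))
  }
  rows <- lapply(names(groups), function(g) {
    m <- stats::lm(y ~ x, data = groups[[g]])
    ci <- stats::confint(m, level = 0.95)
    disjoint <- function(k) ci[k, 2] < pooled_ci[k, 1] || ci[k, 1] > pooled_ci[k, 2]
    flagged <- disjoint(1) || disjoint(2)
    tibble::tibble(
      group = g, n = nrow(groups[[g]]),
      intercept = stats::coef(m)[1], intercept_ci_low = ci[1, 1],
      intercept_ci_high = ci[1, 2],
      slope = stats::coef(m)[2], slope_ci_low = ci[2, 1],
      slope_ci_high = ci[2, 2], flagged = flagged
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  attr(out, "pooled") <- pooled_coef
  out
}

#' Fit an allometry on every candidate tree and average the parameters
#'
#' Runs [fit_gls()] once per phylogeny and reports arithmetic means of the
#' intercept, slope, confidence-interval bounds, lambda and information
#' criteria across trees, so that topological uncertainty in the phylogeny
#' is propagated by replication rather than by a single consensus tree.
#'
#' @param y,x As in [fit_gls()].
#' @param trees A list of `phylo` objects (or `phylo_cov` objects).
#' @param ... Passed on to [fit_gls()].
#' @return A `scaling_fit` whose parameters are cross-tree means, with the
#'   per-tree fits in attribute `per_tree` and `n_trees` recorded.
#' @export
fit_gls_trees <- function(y, x, trees, ...) {
  stopifnot(length(trees) >= 1)
  fits <- lapply(trees, function(tr) {
    pc <- if (inherits(tr, "phylo_cov")) tr else brownian_vcv(tr)
    fit_gls(y, x, pc = pc, ...)
  })
  out <- fits[[1]]
  num_fields <- c("intercept", "slope", "slope_se", "slope_ci_low",
                  "slope_ci_high", "slope_p_value", "lambda_hat",
                  "log_likelihood", "aic", "bic", "r2", "partial_r2")
  for (f in num_fields) {
    out[[f]] <- mean(vapply(fits, `[[`, numeric(1), f))
  }
  out$n_trees <- length(fits)
  attr(out, "per_tree") <- fits
  out
}
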
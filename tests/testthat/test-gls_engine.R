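test_that("an exact line is recovered exactly", {
  fit <- fit_gls(y = c(1, 3, 5), x = c(0, 1, 2))
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$model_type, "gls")
})

test_that("pGLS equals OLS on Cholesky-whitened data (whitening oracle)", {
  set.seed(123)
  for (i in 1:12) {
    n <- sample(5:30, 1)
    tr <- simulate_tree(n, seed = NULL)
    C <- oracle_vcv(tr)
    lam <- stats::runif(1)
    x <- stats::rnorm(n)
    y <- 1 + 0.5 * x + as.numeric(t(chol(shrink_offdiag(C, lam))) %*% stats::rnorm(n))
    pc <- brownian_vcv(tr)
    fit <- fit_gls(y, x, pc = pc, lambda = lam, species_id = tr$tip.label)
    U <- chol(shrink_offdiag(C, lam))
    yt <- backsolve(U, y, transpose = TRUE)
    Xt <- backsolve(U, cbind(1, x), transpose = TRUE)
    ref <- stats::lm.fit(Xt, yt)$coefficients
    expect_equal(unname(c(fit$intercept, fit$slope)), unname(ref),
                 tolerance = 1e-8)
  }
})

test_that("lambda = 0 pGLS degenerates to ordinary least squares", {
  set.seed(5)
  n <- 40
  tr <- simulate_tree(n, seed = NULL)
  x <- stats::rnorm(n)
  y <- 2 + 0.3 * x + stats::rnorm(n)
  fit <- fit_gls(y, x, pc = brownian_vcv(tr), lambda = 0,
                 species_id = tr$tip.label)
  ols <- stats::coef(stats::lm(y ~ x))
  expect_equal(unname(c(fit$intercept, fit$slope)), unname(ols),
               tolerance = 1e-8)
})

test_that("fit matches the nlme + corPagel maximum-likelihood fit", {
  library(nlme)
  sim <- quick_sim(seed = 7)
  fit <- fit_gls(sim$data$y, sim$data$x, pc = sim$pc,
                 species_id = sim$data$species_id)
  d <- data.frame(y = sim$data$y, x = sim$data$x,
                  species = sim$data$species_id)
  ref <- nlme::gls(
    y ~ x, data = d,
    correlation = ape::corPagel(0.5, sim$trees[[1]], form = ~species),
    method = "ML"
  )
  expect_equal(fit$intercept, unname(stats::coef(ref)[1]), tolerance = 1e-5)
  expect_equal(fit$slope, unname(stats::coef(ref)[2]), tolerance = 1e-5)
  expect_equal(fit$lambda_hat, ref$modelStruct$corStruct[1], tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
               tolerance = 1e-6)
})

test_that("the profile likelihood at lambda-hat dominates the boundaries", {
  sim <- quick_sim(seed = 21, lambda_true = 0.5)
  est <- estimate_lambda(sim$data$y, sim$data$x, sim$pc)
  prof <- attr(est, "profile")
  ll_hat <- max(prof$loglik)
  expect_gte(ll_hat, prof$loglik[prof$lambda == 0])
  expect_gte(ll_hat, prof$loglik[prof$lambda == 1])
})

test_that("lambda estimation separates no-signal from Brownian residuals", {
  sim0 <- quick_sim(seed = 31, n_species = 200, scenario = "indirect",
                    lambda_true = 0)
  expect_lt(as.numeric(estimate_lambda(sim0$data$y, sim0$data$x, sim0$pc)),
            0.15)
  sim1 <- quick_sim(seed = 32, n_species = 200, scenario = "indirect",
                    lambda_true = 1, sigma_y = 0.6)
  expect_gt(as.numeric(estimate_lambda(sim1$data$y, sim1$data$x, sim1$pc)),
            0.8)
})

test_that("a constant response is flagged as degenerate", {
  pc <- brownian_vcv(simulate_tree(10, seed = 2))
  expect_warning(estimate_lambda(rep(1, 10), stats::rnorm(10), pc),
                 "unidentifiable|constant")
})

test_that("BIC model selection returns the lowest-BIC candidate", {
  sim <- quick_sim(seed = 9, n_species = 50)
  a <- fit_gls(sim$data$y, sim$data$x)
  b <- fit_gls(sim$data$y, sim$data$x, pc = sim$pc,
               species_id = sim$data$species_id)
  best <- select_model(list(a, b))
  expect_equal(best$bic, min(a$bic, b$bic))
  tab <- attr(best, "delta_bic")
  expect_equal(nrow(tab), 2)
  expect_equal(min(tab$delta_bic), 0)
  expect_identical(select_model(list(a))$bic, a$bic)
  short <- fit_gls(sim$data$y[1:20], sim$data$x[1:20])
  expect_error(select_model(list(a, short)), "different numbers")
})

test_that("GLS is preferred when residuals carry no phylogenetic signal", {
  picks <- vapply(1:40, function(i) {
    sim <- quick_sim(seed = 400 + i, n_species = 80, scenario = "indirect",
                     lambda_true = 0)
    a <- fit_gls(sim$data$y, sim$data$x, trait_name = "t")
    b <- fit_gls(sim$data$y, sim$data$x, pc = sim$pc,
                 species_id = sim$data$species_id, trait_name = "t")
    select_model(list(a, b))$model_type
  }, character(1))
  expect_gte(mean(picks == "gls"), 0.8)
})

test_that("likelihood-ratio partial R2 follows its closed form", {
  f <- list(log_likelihood = -10, n = 100)
  r <- list(log_likelihood = -10)
  expect_equal(partial_r2(f, r), 0)
  r2 <- partial_r2(list(log_likelihood = 0, n = 100),
                   list(log_likelihood = -10))
  expect_equal(r2, 1 - exp(-0.2))
  expect_equal(r2, 0.1813, tolerance = 1e-3)
  # monotone in the likelihood gap, invariant to common shifts
  gaps <- c(1, 5, 10, 20)
  vals <- vapply(gaps, function(g) {
    partial_r2(list(log_likelihood = g, n = 50), list(log_likelihood = 0))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  shifted <- partial_r2(list(log_likelihood = 105, n = 50),
                        list(log_likelihood = 100))
  expect_equal(shifted, vals[2])
  expect_error(
    partial_r2(list(log_likelihood = -5, n = 10), list(log_likelihood = 0)),
    "nested"
  )
})

test_that("detrended values are response-scale residuals", {
  fit <- fit_gls(y = c(1, 3, 5, 8), x = c(0, 1, 2, 3),
                 species_id = paste0("s", 1:4), trait_name = "d_median")
  on_line <- fit$intercept + fit$slope * 2
  d <- detrend(fit, y = on_line, x = 2)
  expect_equal(d$residual, 0, tolerance = 1e-12)
  shifted <- detrend(fit, y = fit$intercept + fit$slope * fit$x + 0.3,
                     x = fit$x)
  expect_equal(shifted$residual, rep(0.3, 4))
  # a species above the fitted line has a positive detrended value
  above <- detrend(fit, y = on_line + 1, x = 2)
  expect_gt(above$residual, 0)
  expect_error(detrend(fit, y = 1:3, x = 1:2), "lengths differ")
})

test_that("slope comparison uses CI disjointness", {
  mk <- function(lo, hi) {
    structure(list(slope_ci_low = lo, slope_ci_high = hi,
                   slope = (lo + hi) / 2),
              class = "scaling_fit")
  }
  expect_equal(compare_slopes(mk(0.34, 0.43), mk(0.23, 0.29)), "distinct")
  expect_equal(compare_slopes(mk(0.1, 0.3), mk(0.25, 0.4)), "overlapping")
  expect_equal(compare_slopes(mk(0.1, 0.3), mk(0.1, 0.3)), "overlapping")
})

test_that("per-laboratory fits flag only genuinely deviating groups", {
  gen_lab_data <- function(seed, shift_slope = 0) {
    set.seed(seed)
    labs <- rep(c("lab1", "lab2", "lab3"), each = 30)
    x <- stats::runif(90, -1.5, 2.5)
    slope <- ifelse(labs == "lab3", 0.4 + shift_slope, 0.4)
    tibble::tibble(group = labs, x = x,
                   y = 2 + slope * x + stats::rnorm(90, 0, 0.25))
  }
  clean_rate <- mean(vapply(1:60, function(i) {
    !any(compare_group_fits(gen_lab_data(700 + i))$flagged)
  }, logical(1)))
  expect_gte(clean_rate, 0.9)

  shifted <- compare_group_fits(gen_lab_data(1, shift_slope = 0.5))
  expect_true(shifted$flagged[shifted$group == "lab3"])

  two <- gen_lab_data(2) |> dplyr::filter(group != "lab3")
  expect_equal(nrow(compare_group_fits(two)), 2)
  small <- gen_lab_data(3) |>
    dplyr::mutate(group = ifelse(seq_len(90) <= 4, "tiny", group))
  expect_message(out <- compare_group_fits(small), "skipping")
  expect_false("tiny" %in% out$group)
})

test_that("multi-tree fits average parameters across trees", {
  cfg <- simulation_config(seed = 77, n_species = 60, n_trees = 3,
                           scenario = "indirect")
  sim <- simulate_dataset(cfg)
  fit <- fit_gls_trees(sim$data$y, sim$data$x, sim$trees,
                       species_id = sim$data$species_id)
  per_tree <- attr(fit, "per_tree")
  expect_length(per_tree, 3)
  expect_equal(fit$slope, mean(vapply(per_tree, `[[`, numeric(1), "slope")))
  expect_equal(fit$bic, mean(vapply(per_tree, `[[`, numeric(1), "bic")))
  expect_equal(fit$n_trees, 3)
})

test_that("variance-structure fits stay coherent with the identity fit", {
  sim <- quick_sim(seed = 15, n_species = 80, scenario = "indirect")
  f_id <- fit_gls(sim$data$y, sim$data$x)
  f_pow <- fit_gls(sim$data$y, sim$data$x, variance_structure = "power")
  # the extra variance parameter can only improve the ML likelihood
  expect_gte(f_pow$log_likelihood, f_id$log_likelihood - 1e-6)
  expect_equal(f_pow$k, f_id$k + 1)
})
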
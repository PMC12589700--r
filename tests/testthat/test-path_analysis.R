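test_that("the four causal scenarios have the expected structure", {
  sc <- build_scenarios()
  expect_named(sc, c("null", "indirect", "direct", "full"))
  expect_equal(nrow(sc$null$edges), 3)
  expect_equal(nrow(sc$indirect$edges), 4)
  expect_equal(nrow(sc$direct$edges), 6)
  expect_equal(nrow(sc$full$edges), 7)
  # climate -> plant size paths are common to all scenarios
  for (m in sc) {
    expect_true(all(c("PC1", "PC2", "PC3") %in%
                      m$edges[m$edges[, 2] == "x", 1]))
  }
  expect_false("y" %in% sc$null$edges[, 2])
  expect_error(causal_model("bad", c("a", "b"),
                            rbind(c("a", "b"), c("b", "a"))),
               "cyclic")
})

test_that("basis sets enumerate non-adjacent pairs with parent conditioning", {
  sc <- build_scenarios()
  expect_length(basis_set(sc$full), 3)
  expect_length(basis_set(sc$null), 7)
  expect_length(basis_set(sc$direct), 4)
  expect_length(basis_set(sc$indirect), 6)

  # the x-y claim of the null model conditions on all three PCs
  null_claims <- basis_set(sc$null)
  xy <- Filter(function(cl) setequal(c(cl$response, cl$probe), c("x", "y")),
               null_claims)[[1]]
  expect_setequal(xy$conditioning, c("PC1", "PC2", "PC3"))
  expect_equal(xy$response, "y")

  # indirect model: PC-y claims condition on x, the mediator, with y as the
  # downstream response
  ind_claims <- Filter(function(cl) cl$probe %in% c("PC1", "PC2", "PC3") &&
                         cl$response == "y",
                       basis_set(sc$indirect))
  expect_length(ind_claims, 3)
  for (cl in ind_claims) expect_equal(cl$conditioning, "x")
})

test_that("basis sets match a brute-force non-adjacency oracle on random DAGs", {
  set.seed(77)
  for (i in 1:15) {
    m <- random_dag(sample(4:8, 1))
    claims <- basis_set(m)
    A <- matrix(0, length(m$nodes), length(m$nodes),
                dimnames = list(m$nodes, m$nodes))
    if (nrow(m$edges) > 0) A[m$edges] <- 1
    nonadj <- 0
    for (a in m$nodes) for (b in m$nodes) {
      if (a < b && A[a, b] == 0 && A[b, a] == 0) nonadj <- nonadj + 1
    }
    expect_length(claims, nonadj)
    for (cl in claims) {
      expect_equal(A[cl$response, cl$probe] + A[cl$probe, cl$response], 0)
      pa <- union(m$edges[m$edges[, 2] == cl$response, 1],
                  m$edges[m$edges[, 2] == cl$probe, 1])
      expect_setequal(cl$conditioning, setdiff(pa, c(cl$response, cl$probe)))
    }
  }
})

test_that("basis sets are invariant to node relabeling", {
  set.seed(5)
  m <- random_dag(6)
  relabel <- stats::setNames(paste0("z", 6:1), m$nodes)
  m2 <- causal_model("relabeled", unname(relabel[m$nodes]),
                     cbind(unname(relabel[m$edges[, 1]]),
                           unname(relabel[m$edges[, 2]])))
  claims1 <- basis_set(m)
  claims2 <- basis_set(m2)
  expect_length(claims2, length(claims1))
  key <- function(cl, map = identity) {
    paste(paste(sort(map(c(cl$response, cl$probe))), collapse = ","), "|",
          paste(sort(map(cl$conditioning)), collapse = ","))
  }
  expect_setequal(vapply(claims1, key, character(1), map = function(x) unname(relabel[x])),
                  vapply(claims2, key, character(1)))
})

test_that("Fisher's C combines claim p-values as -2 sum log p", {
  expect_equal(fisher_c(c(1, 1))$C, 0)
  fc <- fisher_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * (log(0.5) + log(0.5)))
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  expect_equal(fc$dof, 4)
  expect_equal(fc$p, stats::pchisq(fc$C, 4, lower.tail = FALSE))
  sat <- fisher_c(numeric(0))
  expect_equal(sat$C, 0)
  expect_equal(sat$dof, 0L)
  expect_equal(sat$p, 1)
  expect_warning(clamped <- fisher_c(c(0, 0.5)), "clamped")
  expect_true(is.finite(clamped$C))
  expect_error(fisher_c(c(0.5, 1.2)), "p-values")
})

test_that("CICc applies the small-sample parameter penalty", {
  expect_equal(cicc(4.2, 5, 30), 4.2 + 2 * 5 * 30 / 24)
  expect_equal(cicc(4.2, 5, 30), 16.7, tolerance = 1e-10)
  expect_equal(cicc(0, 1, 3), 6)
  expect_equal(cicc(3.3, 0, 50), 3.3)
  expect_error(cicc(1, 5, 6), "n > q \\+ 1")
  # strictly increasing in q at fixed C and n
  vals <- vapply(1:6, function(q) cicc(5, q, 40), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("claim tests reduce to OLS t-tests on a star tree with lambda 0", {
  set.seed(10)
  n <- 40
  tr <- star_tree(n)
  pc <- brownian_vcv(tr)
  dat <- tibble::tibble(
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n), PC3 = stats::rnorm(n),
    x = stats::rnorm(n)
  )
  dat$y <- 0.5 * dat$x + stats::rnorm(n)
  claim <- list(response = "y", probe = "PC2", conditioning = c("x", "PC1"))
  p_ours <- as.numeric(test_claim(claim, dat, pc, lambda = 0))
  ref <- summary(stats::lm(y ~ x + PC1 + PC2, data = dat))$coefficients
  expect_equal(p_ours, ref["PC2", 4], tolerance = 1e-8)

  # probe identical to the response is detected with certainty
  claim_self <- list(response = "y", probe = "y2", conditioning = character(0))
  dat$y2 <- dat$y
  expect_lt(as.numeric(test_claim(claim_self, dat, pc, lambda = 0)), 1e-20)
})

test_that("pure-noise probes yield uniform claim p-values", {
  pvals <- vapply(1:120, function(i) {
    set.seed(900 + i)
    n <- 60
    dat <- tibble::tibble(x = stats::rnorm(n), probe = stats::rnorm(n))
    dat$y <- 0.4 * dat$x + stats::rnorm(n)
    claim <- list(response = "y", probe = "probe", conditioning = "x")
    as.numeric(test_claim(claim, dat, pc = NULL))
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("path coefficients recover generating weights", {
  cfg <- simulation_config(n_species = 200, scenario = "indirect", b = 0.7,
                           seed = 606)
  sim <- simulate_dataset(cfg)
  d <- sim$data
  d[, c("PC1", "PC2", "PC3", "x", "y")] <-
    scale_for_sem(d[, c("PC1", "PC2", "PC3", "x", "y")], method = "zscore")
  pc <- brownian_vcv(sim$trees[[1]])
  paths <- fit_paths(build_scenarios()$indirect, d, pc)
  yx <- paths[paths$from == "x" & paths$to == "y", ]
  # standardized weight: b * sd(x)/sd(y) on the generating scale
  b_std <- cfg$b * stats::sd(sim$data$x) / stats::sd(sim$data$y)
  expect_lt(abs(yx$coefficient - b_std), 0.1)
  # no coefficients into y under the null scenario
  paths_null <- fit_paths(build_scenarios()$null, d, pc)
  expect_false("y" %in% paths_null$to)
})

test_that("model comparison across trees selects and averages coherently", {
  cfg <- simulation_config(n_species = 80, scenario = "full",
                           v = c(0.4, 0.4, 0.4), n_trees = 2, seed = 55)
  sim <- simulate_dataset(cfg)
  d <- sim$data
  d[, c("PC1", "PC2", "PC3", "x", "y")] <-
    scale_for_sem(d[, c("PC1", "PC2", "PC3", "x", "y")])
  cmp <- compare_models(d, sim$trees)
  expect_s3_class(cmp, "path_comparison")
  expect_equal(cmp$n_trees, 2)
  expect_equal(nrow(cmp$summary), 4)
  expect_equal(cmp$summary$mean_CICc[cmp$summary$model == cmp$selected],
               min(cmp$summary$mean_CICc))
  # cross-tree mean equals the mean of per-tree values for a spot-checked cell
  cicc_full <- vapply(cmp$per_tree, function(pt) pt$full$CICc, numeric(1))
  expect_equal(cmp$summary$mean_CICc[cmp$summary$model == "full"],
               mean(cicc_full))

  single <- compare_models(d, sim$trees[[1]])
  expect_equal(single$n_trees, 1)
  expect_equal(single$summary$mean_CICc,
               vapply(single$per_tree[[1]], `[[`, numeric(1), "CICc"),
               ignore_attr = TRUE)

  # trees whose tips do not match the data are refused
  alien <- simulate_tree(80, seed = 1)
  alien$tip.label <- paste0("other", 1:80)
  expect_error(compare_models(d, list(alien)), "absent")
})
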
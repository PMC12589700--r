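test_that("equivalent diameter inverts the circle-area formula", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(100), sqrt(400 / pi), tolerance = 1e-12)
  expect_equal(equivalent_diameter(100), 11.2838, tolerance = 1e-4)
  expect_equal(equivalent_diameter(c(pi, 4 * pi)), c(2, 4))
  expect_error(equivalent_diameter(0), "invalid measurement")
  expect_error(equivalent_diameter(-3), "invalid measurement")
  expect_error(equivalent_diameter(numeric(0)))
})

test_that("hydraulic diameter is the fourth-power mean", {
  expect_equal(hydraulic_diameter(c(10, 10, 10)), 10)
  expect_equal(hydraulic_diameter(17.3), 17.3)
  expect_equal(hydraulic_diameter(c(10, 20)), ((10^4 + 20^4) / 2)^(1 / 4))
  expect_equal(hydraulic_diameter(c(10, 20)), 17.075, tolerance = 1e-4)
  expect_error(hydraulic_diameter(numeric(0)))
  expect_error(hydraulic_diameter(c(10, -1)), "invalid measurement")
})

test_that("hydraulic diameter dominates the arithmetic mean (power means)", {
  set.seed(42)
  for (i in 1:20) {
    d <- stats::rlnorm(sample(5:80, 1), 3, 0.5)
    expect_gte(hydraulic_diameter(d), mean(d))
  }
})

test_that("section summaries compute density, fraction and quartiles", {
  s <- conduit_section("spA", "main_stem", "vessel", 2,
                       lumen_areas = rep(10, 5), sector_area = 500,
                       conduit_count = 5, strict = FALSE)
  rec <- summarize_section(s)
  expect_equal(rec$density, 0.01)
  expect_equal(rec$fraction, 0.1)

  # areas back-computed so the diameters are exactly 1..5
  areas <- pi * (1:5)^2 / 4
  s2 <- conduit_section("spB", "main_stem", "vessel", 2, areas,
                        strict = FALSE)
  rec2 <- summarize_section(s2)
  expect_equal(rec2$d_median, 3)
  expect_equal(rec2$d_lower_quartile, 2)
  expect_equal(rec2$d_upper_quartile, 4)
  # linear-interpolation quantile oracle on an even-sized set
  d_even <- c(1, 2, 3, 10)
  s3 <- conduit_section("spC", "main_stem", "vessel", 2, pi * d_even^2 / 4,
                        strict = FALSE)
  rec3 <- summarize_section(s3)
  expect_equal(rec3$d_lower_quartile, unname(stats::quantile(d_even, 0.25)))
  expect_equal(rec3$d_median, 2.5)
})

test_that("density and fraction are absent without a sector", {
  s <- conduit_section("spA", "branch", "sieve_element", 0.4,
                       lumen_areas = rep(30, 30))
  rec <- summarize_section(s)
  expect_true(is.na(rec$density))
  expect_true(is.na(rec$fraction))
})

test_that("inconsistent lumen/sector measurements are rejected", {
  s <- conduit_section("spA", "main_stem", "vessel", 2,
                       lumen_areas = rep(100, 10), sector_area = 500,
                       strict = FALSE)
  expect_error(summarize_section(s), "inconsistent measurement")
})

test_that("summaries are permutation-invariant and scale with sqrt(area)", {
  set.seed(7)
  areas <- stats::rlnorm(60, 5, 0.4)
  base <- conduit_section("sp", "main_stem", "vessel", 1.5, areas,
                          sector_area = sum(areas) * 4, conduit_count = 60)
  perm <- conduit_section("sp", "main_stem", "vessel", 1.5, sample(areas),
                          sector_area = sum(areas) * 4, conduit_count = 60)
  expect_equal(summarize_section(base), summarize_section(perm))

  k <- 2.5
  scaled <- conduit_section("sp", "main_stem", "vessel", 1.5, areas * k^2,
                            sector_area = sum(areas) * 4 * k^2,
                            conduit_count = 60)
  a <- summarize_section(base)
  b <- summarize_section(scaled)
  dcols <- c("d_hydraulic", "d_median", "d_upper_quartile", "d_lower_quartile")
  expect_equal(as.numeric(b[dcols]), k * as.numeric(a[dcols]))
  expect_equal(b$fraction, a$fraction)
})

test_that("the sampling-protocol minimum counts are enforced unless relaxed", {
  expect_error(
    conduit_section("sp", "main_stem", "vessel", 1, rep(10, 49)),
    "requires >= 50"
  )
  expect_error(
    conduit_section("sp", "main_stem", "sieve_element", 1, rep(10, 24)),
    "requires >= 25"
  )
  expect_s3_class(
    conduit_section("sp", "main_stem", "vessel", 1, rep(10, 5), strict = FALSE),
    "conduit_section"
  )
  expect_error(
    conduit_section("sp", "main_stem", "vessel", 1, rep(10, 50),
                    conduit_count = 10),
    "cannot be smaller"
  )
})

test_that("measurement CSVs round-trip into a species trait table", {
  lum <- tidyr::expand_grid(
    species_id = c("spA", "spB"),
    rep = 1:2,
    i = 1:30
  ) |>
    dplyr::mutate(
      sample_id = paste(species_id, rep, sep = "_"),
      organ = "main_stem", tissue = "sieve_element",
      distance_to_tip_m = ifelse(species_id == "spA", 2, 8),
      lumen_area_um2 = 50 + i
    )
  side <- dplyr::distinct(lum, sample_id) |>
    dplyr::mutate(sector_area_um2 = 1e5, conduit_count = 40)
  lum_file <- withr::local_tempfile(fileext = ".csv")
  side_file <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(lum, lum_file)
  readr::write_csv(side, side_file)

  sections <- read_conduit_measurements(lum_file, side_file)
  expect_length(sections, 4)
  tab <- species_trait_table(sections)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_sections, c(2L, 2L))
  # replicates are identical here, so the mean equals the single-section value
  single <- summarize_section(sections[["spA_1"]])
  expect_equal(tab$d_median[tab$species_id == "spA"], single$d_median)
  expect_equal(species_trait_table(sections, aggregate = FALSE) |> nrow(), 4)
})
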
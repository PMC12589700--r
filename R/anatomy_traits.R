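#' Equivalent circular diameter of a conduit lumen
#'
#' Converts a lumen cross-sectional area to the diameter of the circle with
#' the same area, \eqn{D = \sqrt{4A/\pi}}. This is the standard way to express
#' the size of irregular xylem vessel or phloem sieve-element lumina measured
#' on anatomical cross-sections.
#'
#' @param area Numeric vector of lumen areas (µm²); all values must be > 0.
#' @return Numeric vector of equivalent diameters (µm).
#' @examples
#' equivalent_diameter(pi)   # 2
#' equivalent_diameter(100)  # 11.28379
#' @export
equivalent_diameter <- function(area) {
  if (!is.numeric(area) || length(area) == 0) {
    stop("`area` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("invalid measurement: lumen areas must be finite and > 0", call. = FALSE)
  }
  sqrt(4 * area / pi)
}

#' Hydraulic diameter of a set of conduits
#'
#' The fourth-power mean diameter \eqn{D_H = (\sum D^4 / N)^{1/4}}: the uniform
#' diameter that the same number of conduits would need to deliver the same
#' total lumen conductance (Hagen-Poiseuille conductance scales with the
#' fourth power of diameter).
#'
#' @param diameters Numeric vector of conduit diameters (µm); all > 0.
#' @return The hydraulic diameter (µm), a single number.
#' @examples
#' hydraulic_diameter(c(10, 10, 10))  # 10
#' hydraulic_diameter(c(10, 20))      # 17.07507
#' @export
hydraulic_diameter <- function(diameters) {
  if (!is.numeric(diameters) || length(diameters) == 0) {
    stop("`diameters` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("invalid measurement: diameters must be finite and > 0", call. = FALSE)
  }
  mean(diameters^4)^(1 / 4)
}

# Minimum number of measured lumina per cross-section, by tissue, under the
# strict sampling rule (vessels: all vessels in the sector, at least 50;
# sieve elements: at least 25 in the conductive phloem).
.min_conduit_counts <- c(vessel = 50L, sieve_element = 25L)

#' Construct a conduit cross-section record
#'
#' Bundles the raw lumen-area measurements of one anatomical cross-section
#' with its organ, tissue and distance-to-tip metadata, validating the
#' measurement-protocol invariants.
#'
#' @param species_id Character label for the species.
#' @param organ `"main_stem"` or `"branch"`.
#' @param tissue `"vessel"` or `"sieve_element"`.
#' @param distance_to_tip Distance from the sampling point to the stem or
#'   branch apex, in metres; must be > 0.
#' @param lumen_areas Numeric vector of individual lumen areas (µm²).
#' @param sector_area Area of the measured sector (µm²), or `NULL` when no
#'   sector was delimited (branch sieve elements).
#' @param conduit_count Total number of conduits in the sector, or `NULL`.
#'   Must be at least `length(lumen_areas)` when given.
#' @param strict If `TRUE` (default), enforce the minimum measurement counts
#'   (>= 50 vessels, >= 25 sieve elements). Set `FALSE` for small synthetic
#'   fixtures.
#' @return An object of class `conduit_section`.
#' @export
conduit_section <- function(species_id, organ, tissue, distance_to_tip,
                            lumen_areas, sector_area = NULL,
                            conduit_count = NULL, strict = TRUE) {
  organ <- match.arg(organ, c("main_stem", "branch"))
  tissue <- match.arg(tissue, c("vessel", "sieve_element"))
  if (!is.numeric(distance_to_tip) || length(distance_to_tip) != 1 ||
      !is.finite(distance_to_tip) || distance_to_tip <= 0) {
    stop("`distance_to_tip` must be a single positive number (m)", call. = FALSE)
  }
  if (any(!is.finite(lumen_areas)) || any(lumen_areas <= 0)) {
    stop("invalid measurement: all lumen areas must be finite and > 0", call. = FALSE)
  }
  if (strict && length(lumen_areas) < .min_conduit_counts[[tissue]]) {
    stop(sprintf(
      "section for %s has %d measured %s lumina; the sampling protocol requires >= %d (use strict = FALSE to relax)",
      species_id, length(lumen_areas), tissue, .min_conduit_counts[[tissue]]
    ), call. = FALSE)
  }
  if (!is.null(sector_area)) {
    if (!is.numeric(sector_area) || length(sector_area) != 1 || sector_area <= 0) {
      stop("`sector_area` must be a single positive area (um^2)", call. = FALSE)
    }
  }
  if (!is.null(conduit_count)) {
    conduit_count <- as.integer(conduit_count)
    if (conduit_count < length(lumen_areas)) {
      stop("`conduit_count` cannot be smaller than the number of measured lumina",
           call. = FALSE)
    }
  }
  structure(
    list(
      species_id = as.character(species_id), organ = organ, tissue = tissue,
      distance_to_tip = distance_to_tip, lumen_areas = as.numeric(lumen_areas),
      sector_area = sector_area, conduit_count = conduit_count
    ),
    class = "conduit_section"
  )
}

#' @export
print.conduit_section <- function(x, ...) {
  cat(sprintf(
    "<conduit_section> %s / %s / %s: %d lumina, distance-to-tip %.3g m\n",
    x$species_id, x$organ, x$tissue, length(x$lumen_areas), x$distance_to_tip
  ))
  invisible(x)
}

#' Summarize a cross-section into species-level conduit traits
#'
#' Converts each lumen area to its equivalent diameter, then reports the
#' hydraulic diameter, the median and the quartiles of the diameter
#' distribution (linear-interpolation quantiles), plus conduit density
#' (count per sector area) and lumen fraction (summed lumen area over sector
#' area) when the sector was delimited.
#'
#' @param section A [conduit_section()].
#' @return A one-row tibble with columns `species_id`, `organ`, `tissue`,
#'   `distance_to_tip`, `n_measured`, `d_hydraulic`, `d_median`,
#'   `d_upper_quartile`, `d_lower_quartile` (µm), `density` (µm⁻²) and
#'   `fraction`; `density`/`fraction` are `NA` when `sector_area` or
#'   `conduit_count` is absent.
#' @export
summarize_section <- function(section) {
  stopifnot(inherits(section, "conduit_section"))
  d <- equivalent_diameter(section$lumen_areas)
  q <- stats::quantile(d, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  density <- NA_real_
  fraction <- NA_real_
  if (!is.null(section$sector_area)) {
    fraction <- sum(section$lumen_areas) / section$sector_area
    if (fraction > 1) {
      stop(sprintf(
        "inconsistent measurement for %s: summed lumen area exceeds sector area (fraction %.3f)",
        section$species_id, fraction
      ), call. = FALSE)
    }
    if (!is.null(section$conduit_count)) {
      density <- section$conduit_count / section$sector_area
    }
  }
  tibble::tibble(
    species_id = section$species_id,
    organ = section$organ,
    tissue = section$tissue,
    distance_to_tip = section$distance_to_tip,
    n_measured = length(d),
    d_hydraulic = hydraulic_diameter(d),
    d_median = q[2],
    d_upper_quartile = q[3],
    d_lower_quartile = q[1],
    density = density,
    fraction = fraction
  )
}

#' Read raw lumen measurements and assemble cross-section records
#'
#' Reads a long-format measurement table (one row per measured lumen) and an
#' optional per-sample sidecar of sector areas and conduit counts, and builds
#' one [conduit_section()] per sample.
#'
#' @param lumen_csv Path to a CSV with columns `species_id`, `sample_id`,
#'   `organ`, `tissue`, `distance_to_tip_m`, `lumen_area_um2`.
#' @param sample_csv Optional path to a CSV with columns `sample_id`,
#'   `sector_area_um2`, `conduit_count`.
#' @param strict Passed to [conduit_section()].
#' @return A named list of `conduit_section` objects, one per `sample_id`.
#' @export
read_conduit_measurements <- function(lumen_csv, sample_csv = NULL, strict = TRUE) {
  lum <- readr::read_csv(lumen_csv, show_col_types = FALSE)
  needed <- c("species_id", "sample_id", "organ", "tissue",
              "distance_to_tip_m", "lumen_area_um2")
  missing_cols <- setdiff(needed, names(lum))
  if (length(missing_cols) > 0) {
    stop("measurement table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sidecar <- NULL
  if (!is.null(sample_csv)) {
    sidecar <- readr::read_csv(sample_csv, show_col_types = FALSE)
  }
  split_rows <- split(lum, lum$sample_id)
  sections <- lapply(split_rows, function(rows) {
    sector_area <- NULL
    conduit_count <- NULL
    if (!is.null(sidecar)) {
      side <- sidecar[sidecar$sample_id == rows$sample_id[1], , drop = FALSE]
      if (nrow(side) == 1) {
        if (!is.na(side$sector_area_um2)) sector_area <- side$sector_area_um2
        if (!is.na(side$conduit_count)) conduit_count <- side$conduit_count
      }
    }
    conduit_section(
      species_id = rows$species_id[1], organ = rows$organ[1],
      tissue = rows$tissue[1], distance_to_tip = rows$distance_to_tip_m[1],
      lumen_areas = rows$lumen_area_um2, sector_area = sector_area,
      conduit_count = conduit_count, strict = strict
    )
  })
  sections
}

#' Build a species-level trait table from cross-section summaries
#'
#' Summarizes every section and averages replicate sections of the same
#' species x organ x tissue stratum (arithmetic mean of each trait and of
#' distance-to-tip). Replicate averaging before species-level analysis is the
#' default; pass `aggregate = FALSE` to keep one row per section.
#'
#' @param sections A list of [conduit_section()] objects.
#' @param aggregate Average replicates per species x organ x tissue? Default
#'   `TRUE`.
#' @return A tibble of trait records (see [summarize_section()]).
#' @export
species_trait_table <- function(sections, aggregate = TRUE) {
  records <- dplyr::bind_rows(lapply(sections, summarize_section))
  if (!aggregate) {
    return(records)
  }
  records |>
    dplyr::group_by(.data$species_id, .data$organ, .data$tissue) |>
    dplyr::summarise(
      dplyr::across(
        c("distance_to_tip", "d_hydraulic", "d_median", "d_upper_quartile",
          "d_lower_quartile", "density", "fraction"),
        ~ mean(.x)
      ),
      n_sections = dplyr::n(),
      .groups = "drop"
    )
}
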
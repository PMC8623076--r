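#' Convert a dry-weight concentration to wet weight
#'
#' Concentrations are measured on freeze-dried tissue and reported on a
#' wet-weight basis using each sample's water content:
#' `value_ww = value_dry * (1 - water_fraction)`. Linear and
#' order-preserving.
#'
#' @param value_dry Concentration per gram dry tissue (any unit).
#' @param water_fraction Proportion of tissue mass that is water, in
#'   `[0, 1)`.
#' @return Concentration per gram wet tissue, same unit.
#' @export
#' @examples
#' dry_to_wet(10, 0.8) # 2
dry_to_wet <- function(value_dry, water_fraction) {
  if (any(water_fraction < 0 | water_fraction >= 1)) {
    stop("`water_fraction` must lie in [0, 1)", call. = FALSE)
  }
  value_dry * (1 - water_fraction)
}

.scenarios <- c("LB", "MB", "UB")

#' Substitute censored measurements under a bound scenario
#'
#' Measurements below the limit of detection are replaced by a scenario
#' value bracketing the true unknown: 0 under the lower bound (LB), LOD/2
#' under the middle bound (MB), LOD under the upper bound (UB). Uncensored
#' rows pass through unchanged.
#'
#' @param table A concentration tibble as produced by
#'   [generate_contamination()] (columns `value_ww`, `censored`, `lod`).
#' @param scenario `"LB"`, `"MB"` or `"UB"`.
#' @return The table with censored `value_ww` filled in and a `scenario`
#'   column recording the substitution applied.
#' @export
apply_bound_scenario <- function(table, scenario = c("LB", "MB", "UB")) {
  scenario <- match.arg(scenario)
  stopifnot(all(c("value_ww", "censored", "lod") %in% names(table)))
  cens <- table$censored
  if (any(cens & (is.na(table$lod) | table$lod <= 0))) {
    stop("censored rows must carry a positive LOD", call. = FALSE)
  }
  sub <- switch(scenario,
    LB = rep(0, nrow(table)), MB = table$lod / 2, UB = table$lod
  )
  out <- table
  out$value_ww[cens] <- sub[cens]
  out$scenario <- scenario
  out
}

#' Per-group mean and standard deviation of concentrations
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) per
#' species x element, in the style of a composition summary table. Censored
#' rows still carrying `NA` (no scenario applied) are excluded; apply
#' [apply_bound_scenario()] first to include them under a substitution rule.
#' Groups left empty after exclusion are dropped with a message.
#'
#' @param table Concentration tibble (columns `species`, `element`,
#'   `value_ww`, `unit`).
#' @return A tibble with columns `species`, `element`, `mean`, `sd`, `n`,
#'   `unit` (`sd` is `NA` for singleton groups).
#' @export
summarize_concentrations <- function(table) {
  stopifnot(all(c("species", "element", "value_ww") %in% names(table)))
  kept <- table[!is.na(table$value_ww), ]
  dropped <- dplyr::anti_join(
    dplyr::distinct(table, .data$species, .data$element),
    dplyr::distinct(kept, .data$species, .data$element),
    by = c("species", "element")
  )
  if (nrow(dropped) > 0) {
    message("dropping ", nrow(dropped),
            " species x element group(s) with no usable values")
  }
  if (is.null(kept$unit)) kept$unit <- element_unit(kept$element)
  dplyr::summarise(
    dplyr::group_by(kept, .data$species, .data$element, .data$unit),
    mean = mean(.data$value_ww),
    sd = stats::sd(.data$value_ww),
    n = dplyr::n(),
    .groups = "drop"
  )[, c("species", "element", "mean", "sd", "n", "unit")]
}

#' Ratio of mean concentrations between two species
#'
#' The headline accumulation contrasts of the composition analysis, e.g. Mn
#' being ~44 times higher in the bay scallop than the Yesso scallop.
#'
#' @param summary A summary tibble with columns `species`, `element`, `mean`
#'   ([summarize_concentrations()] output or [reference_composition()]).
#' @param element Element symbol.
#' @param species_a,species_b Numerator and denominator species.
#' @return Numeric scalar `mean_a / mean_b`.
#' @export
#' @examples
#' species_ratio(reference_composition(), "Mn",
#'               "Argopecten irradians", "Mizuhopecten yessoensis")
species_ratio <- function(summary, element, species_a, species_b) {
  pick <- function(sp) {
    row <- summary[summary$species == sp & summary$element == element, ]
    if (nrow(row) != 1) {
      stop("no unique summary row for ", sp, " / ", element, call. = FALSE)
    }
    row$mean
  }
  b <- pick(species_b)
  if (b <= 0) stop("denominator species mean must be positive", call. = FALSE)
  pick(species_a) / b
}

#' Molar selenium-to-mercury ratio
#'
#' `(c_se / 78.97) / (c_hg / 200.59)` with atomic masses Se 78.97 and Hg
#' 200.59 g/mol, both concentrations in ug/g WW. Ratios above 1 indicate a
#' molar Se excess, regarded as protective against Hg toxicity.
#'
#' @param c_se Selenium concentration, ug/g WW.
#' @param c_hg Mercury concentration, ug/g WW; must be positive.
#' @return Dimensionless molar ratio.
#' @export
#' @examples
#' se_hg_molar_ratio(0.52, 0.05)
se_hg_molar_ratio <- function(c_se, c_hg) {
  if (any(c_hg <= 0)) stop("mercury concentration must be positive",
                           call. = FALSE)
  (c_se / 78.97) / (c_hg / 200.59)
}
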
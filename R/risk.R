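#' Margin of exposure
#'
#' `MOE = BMDL / exposure`, compared against a threshold of 100 for
#' non-carcinogenic endpoints (Pb BMDL01) or 10,000 for carcinogenic ones.
#' The exposure is conventionally taken at the P90 of the simulated
#' distribution, covering 90% of the population without reaching into the
#' extreme tail. Zero exposure yields an unbounded MOE (`Inf`, no concern).
#'
#' @param bmdl Benchmark dose lower confidence limit, ug/kg BW/day.
#' @param exposure Exposure estimate (e.g. P90), ug/kg BW/day.
#' @param threshold Concern threshold, default 100.
#' @return A tibble with columns `moe`, `threshold`, `concern`.
#' @export
#' @examples
#' margin_of_exposure(12, 0.008) # Pb at a P90 of 0.008: MOE 1500
margin_of_exposure <- function(bmdl, exposure, threshold = 100) {
  stopifnot(bmdl > 0, threshold > 0)
  if (any(exposure < 0)) stop("exposure must be non-negative", call. = FALSE)
  moe <- ifelse(exposure == 0, Inf, bmdl / exposure)
  tibble::tibble(moe = moe, threshold = threshold, concern = moe < threshold)
}

#' Fraction of the population exceeding a tolerable weekly intake
#'
#' Chronic daily exposure is converted to a weekly basis (`7 * E`, the
#' frequency term already amortizes consumption per day) and compared
#' strictly against the TWI; the result is the percentage of Monte-Carlo
#' iterations above it.
#'
#' @param exposure An [simulate_exposure()] result or a numeric vector of
#'   daily exposures, ug/kg BW/day.
#' @param twi Tolerable weekly intake, ug/kg BW/week; must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' twi_exceedance(c(0.1, 0.5, 1), twi = 2.5)
twi_exceedance <- function(exposure, twi) {
  stopifnot(twi > 0)
  samples <- if (inherits(exposure, "exposure_distribution")) {
    exposure$samples
  } else {
    exposure
  }
  100 * mean(7 * samples > twi)
}

#' Safe weekly consumption amount
#'
#' The tissue mass per week at which weekly intake reaches the TWI:
#' `twi * bw / c` grams per week, for a consumer of body weight `bw` kg
#' eating tissue with element concentration `c` ug/g WW. Halving the
#' concentration doubles the amount. Zero concentration yields an unbounded
#' amount (`Inf`).
#'
#' @param twi Tolerable weekly intake, ug/kg BW/week.
#' @param bw Body weight, kg.
#' @param c_ww Element concentration, ug/g WW.
#' @return Grams of tissue per week.
#' @export
#' @examples
#' safe_weekly_amount(2.5, 63.69, 2.05)
safe_weekly_amount <- function(twi, bw, c_ww) {
  stopifnot(twi > 0, bw > 0)
  if (any(c_ww < 0)) stop("concentration must be non-negative", call. = FALSE)
  ifelse(c_ww == 0, Inf, twi * bw / c_ww)
}

#' Adjust an exposure distribution for bioaccessibility
#'
#' Only the fraction of an ingested element released in the gut is available
#' for absorption; multiplying every simulated exposure by a bioaccessible
#' fraction `beta` rescales the whole distribution (and divides any
#' downstream MOE by `beta`).
#'
#' @param exposure An [simulate_exposure()] result.
#' @param beta Bioaccessible fraction in `(0, 1]`.
#' @return A new `exposure_distribution` with all samples and summary
#'   statistics multiplied by `beta`.
#' @export
bioaccessibility_adjust <- function(exposure, beta) {
  stopifnot(inherits(exposure, "exposure_distribution"))
  if (beta <= 0 || beta > 1) {
    stop("`beta` must lie in (0, 1]", call. = FALSE)
  }
  out <- exposure
  out$samples <- exposure$samples * beta
  out$summary <- exposure$summary * beta
  out
}

#' Risk characterization of a simulated exposure
#'
#' Applies the element's toxicological reference: MOE at the chosen
#' percentile where a BMDL exists, TWI-exceedance percentage where a TWI
#' exists.
#'
#' @param exposure An [simulate_exposure()] result with its `element` label
#'   set (or `element` supplied explicitly).
#' @param tox Toxicological reference table, see [tox_references()].
#' @param element Element symbol; defaults to the exposure's label.
#' @param percentile Exposure percentile for the MOE, default 0.9.
#' @return A one-row tibble: `element`, `species`, `scenario`, `moe`,
#'   `moe_threshold`, `pct_exceeding_twi`, `concern`.
#' @export
characterize_risk <- function(exposure, tox = tox_references(),
                              element = exposure$element, percentile = 0.9) {
  stopifnot(inherits(exposure, "exposure_distribution"))
  row <- tox[tox$element == element, ]
  if (nrow(row) != 1) {
    stop("no toxicological reference for element: ", element, call. = FALSE)
  }
  moe <- NA_real_
  concern <- FALSE
  if (!is.na(row$bmdl01_ug_kg_day)) {
    ep <- exposure_percentiles(exposure$samples, percentile)[[1]]
    m <- margin_of_exposure(row$bmdl01_ug_kg_day, ep, row$moe_threshold)
    moe <- m$moe
    concern <- m$concern
  }
  pct <- NA_real_
  if (!is.na(row$twi_ug_kg_week)) {
    pct <- twi_exceedance(exposure, row$twi_ug_kg_week)
    concern <- concern || pct > 0
  }
  tibble::tibble(
    element = element, species = exposure$species,
    scenario = exposure$scenario, moe = moe,
    moe_threshold = row$moe_threshold, pct_exceeding_twi = pct,
    concern = concern
  )
}
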
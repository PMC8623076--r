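#' Element mass in a fixed portion
#'
#' Deterministic intake of one element from one portion of tissue:
#' `c_ww * portion`, with the concentration in ug/g WW and the portion in
#' grams, giving ug per portion. The conventional portion for Korean
#' consumers is 25 g.
#'
#' @param c_ww Wet-weight concentration, ug/g.
#' @param portion Portion mass in grams (default 25).
#' @return Intake in ug per portion.
#' @export
#' @examples
#' portion_intake(0.35, 25) # Se in a 25-g portion: 8.75 ug
portion_intake <- function(c_ww, portion = 25) {
  if (any(c_ww < 0)) stop("concentration must be non-negative", call. = FALSE)
  if (any(portion <= 0)) stop("portion must be positive", call. = FALSE)
  c_ww * portion
}

#' Intake as a percentage of a daily reference value
#'
#' @param intake_ug Intake in ug (per day, assuming one portion per day).
#' @param reference_ug_day Reference intake in ug/day; must be positive.
#' @return Percentage, `100 * intake / reference`.
#' @export
#' @examples
#' percent_of_reference(portion_intake(1.39, 25), 800) # Cu vs RI: 4.34%
percent_of_reference <- function(intake_ug, reference_ug_day) {
  if (any(reference_ug_day <= 0)) {
    stop("reference value must be positive", call. = FALSE)
  }
  100 * intake_ug / reference_ug_day
}

#' Deterministic portion-intake report against reference intakes
#'
#' Crosses a composition summary with the reference-intake table: for every
#' species x element with a recommended or adequate intake, the element mass
#' in one portion, its percentage of the reference, and whether it exceeds
#' the tolerable upper intake level where one exists. Macro-element rows
#' (mg/g) are converted to ug/g before multiplication so every intake is in
#' ug. Elements without a reference are omitted (with a message).
#'
#' @param summary Composition summary with columns `species`, `element`,
#'   `mean`, `unit` (e.g. [reference_composition()] or
#'   [summarize_concentrations()] output).
#' @param reference_table Reference intakes, see [reference_intakes()].
#' @param portion Portion mass in grams, default 25.
#' @param sex `"male"` (default, matching single-figure reporting) or
#'   `"female"`.
#' @return A tibble with columns `species`, `element`, `intake_ug`,
#'   `intake_mg`, `reference_kind`, `reference_ug_day`, `pct_reference`,
#'   `above_ul`.
#' @export
#' @examples
#' intake_report(reference_composition(), portion = 25)
intake_report <- function(summary, reference_table = reference_intakes(),
                          portion = 25, sex = c("male", "female")) {
  sex <- match.arg(sex)
  refs <- reference_table[reference_table$sex == sex, ]
  main <- refs[refs$reference_kind %in% c("RI", "AI"), ]
  uls <- refs[refs$reference_kind == "UL", ]
  skipped <- setdiff(unique(summary$element), main$element)
  if (length(skipped) > 0) {
    message("elements without a reference intake omitted: ",
            paste(sort(skipped), collapse = ", "))
  }
  if (is.null(summary$unit)) summary$unit <- element_unit(summary$element)
  rows <- dplyr::inner_join(
    summary[, c("species", "element", "mean", "unit")],
    main[, c("element", "reference_kind", "reference_ug_day")],
    by = "element"
  )
  c_ug_g <- ifelse(rows$unit == "mg/g", rows$mean * 1000, rows$mean)
  rows$intake_ug <- portion_intake(c_ug_g, portion)
  rows$intake_mg <- rows$intake_ug / 1000
  rows$pct_reference <- percent_of_reference(rows$intake_ug,
                                             rows$reference_ug_day)
  ul_idx <- match(rows$element, uls$element)
  rows$above_ul <- !is.na(ul_idx) & rows$intake_ug > uls$reference_ug_day[ul_idx]
  rows[, c("species", "element", "intake_ug", "intake_mg", "reference_kind",
           "reference_ug_day", "pct_reference", "above_ul")]
}
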
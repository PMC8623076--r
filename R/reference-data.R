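#' Study species and default sample layout
#'
#' The five bivalve species evaluated by the package's shipped reference
#' data: three clams (Manila clam, big blood clam, small blood clam) and two
#' scallops (bay scallop, Yesso scallop), with the number of composite
#' samples per species (48 in total) and a nominal tissue water fraction
#' used to convert dry-weight measurements to wet weight.
#'
#' Water fractions are not part of the published summary tables; the shipped
#' values are realistic whole-soft-tissue moisture contents (clams slightly
#' wetter than scallops) and are only defaults — every function that needs a
#' water fraction accepts it explicitly.
#'
#' @return A tibble with columns `species`, `common_name`, `n_samples`,
#'   `water_fraction`.
#' @export
#' @examples
#' bivalve_species()
bivalve_species <- function() {
  tibble::tibble(
    species = c(
      "Venerupis philippinarum", "Anadara broughtonii", "Tegillarca granosa",
      "Argopecten irradians", "Mizuhopecten yessoensis"
    ),
    common_name = c(
      "Manila clam", "big blood clam", "small blood clam",
      "bay scallop", "Yesso scallop"
    ),
    n_samples = c(15L, 7L, 12L, 8L, 6L),
    water_fraction = c(0.82, 0.80, 0.80, 0.78, 0.78)
  )
}

# Element classification drives units: macro elements are carried in mg/g
# wet weight, everything else in ug/g wet weight.
.macro_elements <- c("Ca", "Mg", "K", "Na")
.micro_elements <- c("Co", "Cr", "Cu", "Mn", "Ni", "Se", "Zn", "Fe")
.toxic_elements <- c("As", "Cd", "Hg", "Pb")
.all_elements <- c(.macro_elements, .micro_elements, .toxic_elements)

#' Unit label for an element
#'
#' Macro elements (Ca, Mg, K, Na) are reported in mg/g wet weight; all other
#' elements in ug/g wet weight.
#'
#' @param element Character vector of element symbols.
#' @return Character vector, `"mg/g"` or `"ug/g"`.
#' @export
element_unit <- function(element) {
  ifelse(element %in% .macro_elements, "mg/g", "ug/g")
}

#' Published wet-weight composition of the five study species
#'
#' Mean and standard deviation of 16 elements (4 macro, 8 micro, 4 toxic) in
#' whole soft tissue, per species, on a wet-weight basis, as determined by
#' ICP-MS/ICP-OES on composite samples. Macro elements are in mg/g WW,
#' all others in ug/g WW. These summaries are the empirical anchor for the
#' synthetic-data generator and for every deterministic evaluation in the
#' package (portion intakes, species ratios, Se:Hg molar ratios).
#'
#' @param species Optional character vector to subset by species.
#' @param elements Optional character vector to subset by element symbol.
#' @return A tibble with columns `species`, `element`, `mean`, `sd`, `unit`,
#'   `n_samples`; one row per species x element.
#' @export
#' @examples
#' reference_composition(species = "Mizuhopecten yessoensis", elements = "Cd")
reference_composition <- function(species = NULL, elements = NULL) {
  sp <- bivalve_species()$species
  # columns ordered: V. philippinarum, A. broughtonii, T. granosa,
  # A. irradians, M. yessoensis
  vals <- list(
    Ca = c(0.58, 0.44, 0.75, 0.54, 0.20), Ca_sd = c(0.22, 0.19, 0.46, 0.15, 0.06),
    Mg = c(0.40, 0.56, 0.50, 0.46, 0.39), Mg_sd = c(0.06, 0.16, 0.10, 0.04, 0.08),
    K  = c(2.50, 1.98, 2.50, 2.46, 2.50), K_sd  = c(0.47, 0.52, 0.60, 0.94, 0.99),
    Na = c(3.63, 4.06, 2.95, 4.10, 2.59), Na_sd = c(0.49, 0.78, 0.58, 0.56, 1.38),
    Co = c(0.15, 0.05, 0.06, 0.07, 0.03), Co_sd = c(0.03, 0.03, 0.02, 0.01, 0.01),
    Cr = c(0.08, 0.08, 0.10, 0.06, 0.07), Cr_sd = c(0.03, 0.04, 0.04, 0.04, 0.01),
    Cu = c(0.76, 1.06, 1.21, 0.75, 1.39), Cu_sd = c(0.12, 0.64, 0.59, 0.15, 0.91),
    Mn = c(1.32, 3.59, 3.72, 25.15, 0.57), Mn_sd = c(0.50, 2.32, 1.72, 3.10, 0.14),
    Ni = c(0.58, 0.08, 0.12, 0.04, 0.74), Ni_sd = c(0.18, 0.03, 0.05, 0.01, 0.11),
    Se = c(0.52, 0.35, 0.53, 0.37, 0.42), Se_sd = c(0.09, 0.14, 0.13, 0.14, 0.03),
    Zn = c(8.37, 11.75, 12.46, 43, 14.5), Zn_sd = c(0.98, 3.07, 2.63, 19, 5.0),
    Fe = c(35.0, 55.8, 68.6, 14.0, 15.4), Fe_sd = c(22.0, 29.1, 23.0, 3.3, 14),
    As = c(2.61, 1.41, 1.49, 1.07, 0.99), As_sd = c(0.30, 0.77, 0.49, 0.29, 0.23),
    Cd = c(0.11, 0.50, 0.86, 0.44, 2.05), Cd_sd = c(0.04, 0.48, 0.54, 0.21, 0.55),
    Hg = c(0.05, 0.03, 0.05, 0.03, 0.03), Hg_sd = c(0.03, 0.01, 0.03, 0.01, 0.02),
    Pb = c(0.03, 0.09, 0.12, 0.08, 0.09), Pb_sd = c(0.07, 0.07, 0.13, 0.04, 0.02)
  )
  out <- purrr::map_dfr(.all_elements, function(el) {
    tibble::tibble(
      species = sp, element = el,
      mean = vals[[el]], sd = vals[[paste0(el, "_sd")]]
    )
  })
  out$unit <- element_unit(out$element)
  out <- dplyr::left_join(
    out, bivalve_species()[, c("species", "n_samples")], by = "species"
  )
  if (!is.null(species)) out <- out[out$species %in% species, ]
  if (!is.null(elements)) out <- out[out$element %in% elements, ]
  out
}

#' Instrument limits of detection
#'
#' LODs in ug/L of digest solution: Ca, Fe, K, Mg, Na measured by ICP-OES;
#' the remaining elements by ICP-MS.
#'
#' @return A tibble with columns `element`, `lod_ug_l`, `instrument`.
#' @export
instrument_lods <- function() {
  tibble::tibble(
    element = c(
      "Ca", "Fe", "K", "Mg", "Na",
      "Cr", "Mn", "Co", "Ni", "Cu", "Zn", "As", "Se", "Cd", "Hg", "Pb"
    ),
    lod_ug_l = c(
      0.45, 0.67, 0.91, 0.19, 19.31,
      0.037, 0.042, 0.003, 0.310, 0.058, 0.158, 0.133, 0.136, 0.009, 0.005,
      0.061
    ),
    instrument = c(rep("ICP-OES", 5), rep("ICP-MS", 11))
  )
}

#' Convert an instrument LOD to a tissue-equivalent concentration
#'
#' Digestion takes 1 g of dry tissue into a 25-mL final volume, so an
#' instrument LOD of `lod_ug_l` ug/L corresponds to
#' `lod_ug_l x 0.025 / 1` ug per g dry tissue, and a further factor
#' `(1 - water_fraction)` converts dry-weight to wet-weight concentration.
#' The result is in ug/g WW (divide by 1000 for mg/g elements).
#'
#' @param lod_ug_l Instrument LOD in ug/L of digest.
#' @param water_fraction Tissue water fraction in `[0, 1)`.
#' @param digest_volume_l Final digest volume in litres (default 0.025).
#' @param dry_mass_g Digested dry mass in grams (default 1).
#' @return Tissue-equivalent LOD in ug/g wet weight.
#' @export
#' @examples
#' tissue_lod(0.061, water_fraction = 0.8) # Pb
tissue_lod <- function(lod_ug_l, water_fraction,
                       digest_volume_l = 0.025, dry_mass_g = 1) {
  stopifnot(lod_ug_l >= 0, digest_volume_l > 0, dry_mass_g > 0)
  if (any(water_fraction < 0 | water_fraction >= 1)) {
    stop("`water_fraction` must lie in [0, 1)", call. = FALSE)
  }
  lod_ug_l * digest_volume_l / dry_mass_g * (1 - water_fraction)
}

#' Korean reference intake values for nutritionally relevant elements
#'
#' Recommended intakes (RI), adequate intakes (AI) and the Cu tolerable
#' upper intake level (UL) used by the deterministic portion evaluation.
#' Values are per day for adults, in ug/day. Where the reference differs by
#' sex the table carries both; reporting defaults to the adult-male value.
#'
#' @return A tibble with columns `element`, `reference_kind`, `sex`,
#'   `reference_ug_day`.
#' @export
reference_intakes <- function() {
  tibble::tribble(
    ~element, ~reference_kind, ~sex, ~reference_ug_day,
    "Cu", "RI", "male",   800,
    "Cu", "RI", "female", 800,
    "Cu", "UL", "male",   5000,
    "Cu", "UL", "female", 5000,
    "Zn", "RI", "male",   9500,
    "Zn", "RI", "female", 8000,
    "Fe", "RI", "male",   10000,
    "Fe", "RI", "female", 12000,
    "Mn", "AI", "male",   3500,
    "Mn", "AI", "female", 3000,
    "Se", "RI", "male",   50,
    "Se", "RI", "female", 50
  )
}

#' Toxicological reference values for Cd, Pb and Hg
#'
#' Pb carries a benchmark dose lower confidence limit (BMDL01) of
#' 12 ug/kg BW/day with a margin-of-exposure threshold of 100
#' (non-carcinogenic endpoint); Cd and Hg carry tolerable weekly intakes of
#' 2.5 and 4 ug/kg BW/week. The carcinogenic MOE threshold of 10,000 is kept
#' in the table for completeness.
#'
#' @return A tibble with columns `element`, `bmdl01_ug_kg_day`,
#'   `twi_ug_kg_week`, `moe_threshold`.
#' @export
tox_references <- function() {
  tibble::tibble(
    element = c("Cd", "Pb", "Hg"),
    bmdl01_ug_kg_day = c(NA_real_, 12, NA_real_),
    twi_ug_kg_week = c(2.5, NA_real_, 4),
    moe_threshold = c(10000, 100, 10000)
  )
}

#' Consumption-frequency categories and their daily-rate map
#'
#' The food-frequency questionnaire uses nine frequency categories, from
#' never to more than once per day. Each category is mapped to a consumption
#' rate per day; only the once-per-week = 1/7 anchor is fixed by convention,
#' the remaining rates are the natural midpoint readings of the category
#' labels and are editable configuration. The `prob` column is the default
#' population share per category used by the synthetic survey generator; the
#' published survey marginals are not reproduced here (they are inputs, not
#' ground truth).
#'
#' @return A tibble with columns `label`, `per_day`, `prob`.
#' @export
default_frequency_categories <- function() {
  tibble::tibble(
    label = c(
      "never", "less than once a month", "once a month", "2-3 times a month",
      "once a week", "2-3 times a week", "4-6 times a week", "daily",
      "more than once a day"
    ),
    per_day = c(0, 1 / 60, 1 / 30, 2.5 / 30, 1 / 7, 2.5 / 7, 5 / 7, 1, 2),
    prob = c(0.15, 0.20, 0.20, 0.15, 0.15, 0.08, 0.04, 0.02, 0.01)
  )
}

#' Pieces-per-meal categories with PERT parameters
#'
#' Six survey ranges for the number of bivalve pieces eaten per meal, from 0
#' to more than 20. Each interior range becomes a PERT distribution with the
#' range endpoints as min/max and the midpoint as mode (the 6-10 range is
#' the published worked example, PERT(6, 8, 10)); the open-ended ">20"
#' category is mapped to PERT(20, 22, 30) as configuration. `prob` is the
#' default population share used by the synthetic survey generator.
#'
#' @return A tibble with columns `label`, `min`, `mode`, `max`, `prob`.
#' @export
default_pieces_categories <- function() {
  tibble::tibble(
    label = c("0", "1-5", "6-10", "11-15", "16-20", ">20"),
    min = c(0, 1, 6, 11, 16, 20),
    mode = c(0, 3, 8, 13, 18, 22),
    max = c(0, 5, 10, 15, 20, 30),
    prob = c(0.05, 0.35, 0.30, 0.15, 0.10, 0.05)
  )
}

#' Default piece-weight PERT for a species
#'
#' Soft-tissue weight per piece, in grams. The Yesso scallop triple
#' (37.55, 39.35, 43.04) is the published measurement; the Manila clam
#' triple (4, 6, 9) is a realistic configuration value for whole soft tissue
#' of a market-size clam (no measurement was published for it).
#'
#' @param species Species name (see [bivalve_species()]).
#' @return A [pert_params()] object, units grams per piece.
#' @export
default_piece_weight <- function(species) {
  switch(species,
    "Mizuhopecten yessoensis" = pert_params(37.55, 39.35, 43.04),
    "Venerupis philippinarum" = pert_params(4, 6, 9),
    stop("no default piece weight for species: ", species, call. = FALSE)
  )
}

#' Default adult body-weight PERT for the Korean population
#'
#' PERT(60.5, 63.69, 64.3) kg, constructed from the average body weights in
#' the three most recent national health and nutrition examination surveys.
#'
#' @return A [pert_params()] object, units kg.
#' @export
default_body_weight <- function() {
  pert_params(60.5, 63.69, 64.3)
}
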
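test_that("dry-to-wet conversion is exact, linear and guarded", {
  expect_equal(dry_to_wet(10, 0.8), 2)
  expect_equal(dry_to_wet(5.3, 0), 5.3)
  expect_equal(dry_to_wet(8.2, 0.75), 2.05)
  expect_error(dry_to_wet(1, 1), "water_fraction")
  x <- c(0.5, 1, 4)
  expect_equal(dry_to_wet(2 * x, 0.6), 2 * dry_to_wet(x, 0.6))
  expect_true(all(diff(dry_to_wet(sort(x), 0.3)) > 0))
})

make_censored_table <- function() {
  tibble::tibble(
    species = "Venerupis philippinarum",
    sample_id = sprintf("s%02d", 1:4),
    element = "Pb",
    value_ww = c(NA, 0.09, NA, 0.12),
    unit = "ug/g",
    censored = c(TRUE, FALSE, TRUE, FALSE),
    lod = 0.061
  )
}

test_that("bound scenarios substitute 0, LOD/2 and LOD for censored rows", {
  tab <- make_censored_table()
  expect_equal(apply_bound_scenario(tab, "LB")$value_ww[1], 0)
  expect_equal(apply_bound_scenario(tab, "MB")$value_ww[1], 0.061 / 2)
  expect_equal(apply_bound_scenario(tab, "UB")$value_ww[1], 0.061)
  # uncensored rows never move
  for (sc in c("LB", "MB", "UB")) {
    expect_equal(apply_bound_scenario(tab, sc)$value_ww[c(2, 4)],
                 c(0.09, 0.12))
  }
  clean <- tab
  clean$censored <- FALSE
  clean$value_ww <- c(0.05, 0.09, 0.07, 0.12)
  lb <- apply_bound_scenario(clean, "LB")
  ub <- apply_bound_scenario(clean, "UB")
  expect_equal(lb$value_ww, ub$value_ww)

  broken <- tab
  broken$lod <- NA_real_
  expect_error(apply_bound_scenario(broken, "MB"), "positive LOD")
})

test_that("summaries use arithmetic mean and n-1 sd, and honour scenarios", {
  tab <- tibble::tibble(
    species = "x", sample_id = as.character(1:3), element = "Cd",
    value_ww = c(1, 2, 3), unit = "ug/g", censored = FALSE, lod = 0.01
  )
  s <- summarize_concentrations(tab)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)

  same <- tab
  same$value_ww <- rep(1.5, 3)
  expect_equal(summarize_concentrations(same)$sd, 0)

  # censored rows are excluded until a scenario fills them in
  cen <- make_censored_table()
  raw <- summarize_concentrations(cen)
  expect_equal(raw$n, 2L)
  means <- vapply(c("LB", "MB", "UB"), function(sc) {
    summarize_concentrations(apply_bound_scenario(cen, sc))$mean
  }, numeric(1))
  expect_true(means["LB"] <= means["MB"] && means["MB"] <= means["UB"])
})

test_that("scenario monotonicity holds across a full synthetic table", {
  specs <- reference_composition(elements = c("Pb", "Hg", "Cd"))
  lods <- tibble::tibble(element = c("Pb", "Hg", "Cd"),
                         lod = c(0.08, 0.03, 0.3))
  tab <- generate_contamination(specs, lods, seed = 8)
  by_sc <- lapply(c("LB", "MB", "UB"), function(sc) {
    s <- summarize_concentrations(apply_bound_scenario(tab, sc))
    s[order(s$species, s$element), ]
  })
  expect_true(all(by_sc[[1]]$mean <= by_sc[[2]]$mean + 1e-12))
  expect_true(all(by_sc[[2]]$mean <= by_sc[[3]]$mean + 1e-12))
})

test_that("species mean ratios reproduce the published contrasts", {
  ref <- reference_composition()
  expect_equal(
    species_ratio(ref, "Mn", "Argopecten irradians",
                  "Mizuhopecten yessoensis"),
    44, tolerance = 0.01
  )
  expect_equal(
    species_ratio(ref, "Ni", "Mizuhopecten yessoensis",
                  "Argopecten irradians"),
    18.5, tolerance = 1e-9
  )
  expect_equal(
    species_ratio(ref, "Cd", "Mizuhopecten yessoensis",
                  "Mizuhopecten yessoensis"),
    1
  )
  zero <- ref
  zero$mean[zero$species == "Argopecten irradians" & zero$element == "Ni"] <- 0
  expect_error(
    species_ratio(zero, "Ni", "Mizuhopecten yessoensis",
                  "Argopecten irradians"),
    "positive"
  )
})

test_that("Se:Hg molar ratio follows its definition and exceeds 1", {
  expect_equal(se_hg_molar_ratio(78.97, 200.59), 1)
  expect_equal(se_hg_molar_ratio(0.52, 0.05), (0.52 / 78.97) / (0.05 / 200.59))
  expect_gt(se_hg_molar_ratio(0.52, 0.05), 26)
  ref <- reference_composition(elements = c("Se", "Hg"))
  wide <- tidyr::pivot_wider(ref[, c("species", "element", "mean")],
                             names_from = "element", values_from = "mean")
  expect_true(all(se_hg_molar_ratio(wide$Se, wide$Hg) > 1))
  expect_error(se_hg_molar_ratio(0.5, 0), "positive")
})
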
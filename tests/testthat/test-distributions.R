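test_that("PERT-to-Beta mapping follows the lambda = 4 construction", {
  expect_equal(unname(pert_to_beta(pert_params(0, 0.5, 1))), c(3, 3))
  expect_equal(pert_mean(pert_params(6, 8, 10)), 8)
  expect_equal(pert_mean(pert_params(37.55, 39.35, 43.04)), 39.665)
  expect_equal(pert_mean(pert_params(60.5, 63.69, 64.3)), 63.26)
  expect_error(pert_to_beta(pert_params(2, 2, 2)), "degenerate")
  expect_error(pert_params(3, 2, 1), "min <= mode <= max")
})

test_that("PERT samples live on the support and match closed-form moments", {
  perts <- list(
    pert_params(6, 8, 10),
    pert_params(37.55, 39.35, 43.04),
    pert_params(60.5, 63.69, 64.3)
  )
  for (p in perts) {
    x <- pert_sample(p, 1e5, seed = 31)
    expect_true(all(x >= p$min & x <= p$max))
    expect_equal(mean(x), pert_mean(p), tolerance = 0.02 / pert_mean(p))
    expect_equal(var(x), pert_var(p), tolerance = 0.05)
  }
})

test_that("frequency labels map to per-day rates", {
  expect_equal(frequency_to_daily("once a week"), 1 / 7)
  expect_equal(frequency_to_daily("daily"), 1)
  expect_equal(frequency_to_daily("never"), 0)
  expect_error(frequency_to_daily("fortnightly"), "unknown")
})

test_that("survey marginals become a discrete consumption distribution", {
  all_never <- tibble::tibble(freq_category = rep("never", 142))
  d0 <- build_frequency_dist(all_never)
  expect_equal(d0$values, 0)
  expect_equal(d0$probs, 1)

  half <- tibble::tibble(
    freq_category = c(rep("once a week", 71), rep("daily", 71))
  )
  d <- build_frequency_dist(half)
  expect_equal(sort(d$values), c(1 / 7, 1))
  expect_equal(d$probs, c(0.5, 0.5))
  expect_equal(discrete_mean(d), 4 / 7)
  expect_equal(sum(d$probs), 1)
  expect_error(build_frequency_dist(all_never[0, ]), "empty")
})

test_that("contamination fitting recovers lognormal parameters", {
  set.seed(101)
  x <- rlnorm(1000, 0.7, 0.25)
  fit <- fit_contamination(x, frac_below = 0, lod = 0.01)
  expect_equal(fit$family, "lognormal")
  expect_equal(unname(fit$parameters["meanlog"]), 0.7, tolerance = 0.05)
  expect_equal(unname(fit$parameters["sdlog"]), 0.25, tolerance = 0.05)
})

test_that("degenerate detect sets fall back to a point mass", {
  expect_warning(
    f <- fit_contamination(rep(0.4, 10), frac_below = 0.2, lod = 0.1),
    "point-mass"
  )
  expect_equal(f$family, "pointmass")
  expect_equal(unname(f$parameters["value"]), 0.4)

  # Manila-clam lead situation: 5 detects out of 15, censored fraction 10/15
  expect_warning(
    pb <- fit_contamination(c(0.07, 0.09, 0.09, NA, NA)[1:2],
                            frac_below = 10 / 15, lod = 0.061),
    "point-mass"
  )
  expect_equal(pb$frac_below_lod, 10 / 15)
  pb5 <- fit_contamination(c(0.07, 0.08, 0.09, 0.11, 0.12),
                           frac_below = 10 / 15, lod = 0.061)
  expect_equal(pb5$frac_below_lod, 10 / 15)
  expect_equal(pb5$n_detects, 5L)
})

test_that("censored sampler reproduces the RAND/IF construction", {
  fit <- structure(
    list(family = "lognormal",
         parameters = c(meanlog = log(0.1), sdlog = 0.3),
         frac_below_lod = 2 / 3, lod = 0.061, n_detects = 5,
         aic = NA_real_),
    class = "contamination_fit"
  )
  lb <- censored_sampler(fit, "LB")
  set.seed(77)
  x <- lb(1e5)
  expect_lt(abs(mean(x == 0) - 2 / 3), 0.005)

  fit0 <- fit
  fit0$frac_below_lod <- 0
  set.seed(5)
  a <- censored_sampler(fit0, "LB")(100)
  set.seed(5)
  invisible(runif(100)) # the sampler's censoring uniforms, unused when y = 0
  b <- qlnorm(runif(100), log(0.1), 0.3)
  expect_equal(a, b) # y = 0: sampler is exactly the fitted distribution

  fit1 <- fit
  fit1$frac_below_lod <- 1
  set.seed(6)
  expect_true(all(censored_sampler(fit1, "UB")(50) == 0.061))
})

test_that("coupled scenario streams are pointwise ordered LB <= MB <= UB", {
  fit <- structure(
    list(family = "lognormal",
         parameters = c(meanlog = log(0.05), sdlog = 0.4),
         frac_below_lod = 0.5, lod = 0.02, n_detects = 8, aic = NA_real_),
    class = "contamination_fit"
  )
  draws <- lapply(c("LB", "MB", "UB"), function(sc) {
    set.seed(123)
    censored_sampler(fit, sc)(5000)
  })
  expect_true(all(draws[[1]] <= draws[[2]]))
  expect_true(all(draws[[2]] <= draws[[3]]))
  # detected iterations are identical across scenarios
  det <- draws[[1]] > 0
  expect_equal(draws[[1]][det], draws[[3]][det])
})
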
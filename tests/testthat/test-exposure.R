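# helpers building degenerate and stochastic consumption models
point_model <- function(f = 1 / 7, n = 8, w = 39.35, bw = 63.69) {
  consumption_model(
    discrete_dist(f, 1),
    tibble::tibble(prob = 1, pert = list(pert_params(n, n, n))),
    pert_params(w, w, w),
    pert_params(bw, bw, bw)
  )
}

const_sampler <- function(value) function(n) rep(value, n)

test_that("engine equals closed-form arithmetic for point-mass factors", {
  ex <- simulate_exposure(point_model(), const_sampler(2.05),
                          n_iter = 500, seed = 1)
  oracle <- (1 / 7) * 8 * 39.35 * 2.05 / 63.69
  expect_true(all(abs(ex$samples - oracle) < 1e-12))
  expect_equal(unname(unlist(ex$summary[, c("p50", "p75", "p90", "p99")])),
               rep(oracle, 4))
  expect_equal(oracle, 1.448, tolerance = 0.001)
})

test_that("zero concentration yields identically zero exposure", {
  ex <- simulate_exposure(point_model(), const_sampler(0),
                          n_iter = 200, seed = 2)
  expect_true(all(ex$samples == 0))
  expect_true(all(unlist(ex$summary[, c("p50", "p75", "p90", "p99")]) == 0))
})

test_that("percentiles use type-7 interpolation and are monotone", {
  expect_equal(unname(exposure_percentiles(rep(3.3, 10))),
               rep(3.3, 4))
  expect_equal(unname(exposure_percentiles(1:100, 0.5)), 50.5)
  set.seed(4)
  u <- runif(1e5)
  expect_equal(unname(exposure_percentiles(u, 0.9)), 0.9, tolerance = 0.005)
  expect_error(exposure_percentiles(numeric(0)), "empty")
  q <- exposure_percentiles(rlnorm(1000))
  expect_true(all(diff(q) >= 0))
})

make_fit <- function(y = 0.4) {
  structure(
    list(family = "lognormal",
         parameters = c(meanlog = log(0.5), sdlog = 0.5),
         frac_below_lod = y, lod = 0.2, n_detects = 10, aic = NA_real_),
    class = "contamination_fit"
  )
}

stochastic_model <- function(seed = 10) {
  default_consumption_model("Mizuhopecten yessoensis", seed = seed)
}

test_that("scenario runs sharing a seed give LB <= MB <= UB percentiles", {
  cm <- stochastic_model()
  fit <- make_fit()
  ex <- lapply(c("LB", "MB", "UB"), function(sc) {
    simulate_exposure(cm, censored_sampler(fit, sc), n_iter = 20000,
                      seed = 99, scenario = sc)
  })
  for (col in c("p50", "p75", "p90", "p99", "mean")) {
    vals <- vapply(ex, function(e) e$summary[[col]], numeric(1))
    expect_true(all(diff(vals) >= 0), label = paste("ordered", col))
  }
  # coupling is pointwise, not just in distribution
  expect_true(all(ex[[1]]$samples <= ex[[3]]$samples))
})

test_that("exposure is scale-equivariant in concentration", {
  cm <- stochastic_model()
  fit <- make_fit(y = 0)
  base <- simulate_exposure(cm, censored_sampler(fit, "MB"),
                            n_iter = 5000, seed = 42)
  k <- 3.7
  scaled <- simulate_exposure(
    cm, function(n) k * censored_sampler(fit, "MB")(n),
    n_iter = 5000, seed = 42
  )
  expect_equal(scaled$samples, k * base$samples)
  expect_equal(
    unlist(scaled$summary[, c("p50", "p75", "p90", "p99")]),
    k * unlist(base$summary[, c("p50", "p75", "p90", "p99")])
  )
})

test_that("P90 is stable across seeds within bootstrap error", {
  cm <- stochastic_model()
  fit <- make_fit(y = 0)
  e1 <- simulate_exposure(cm, censored_sampler(fit, "MB"),
                          n_iter = 1e5, seed = 1)
  e2 <- simulate_exposure(cm, censored_sampler(fit, "MB"),
                          n_iter = 1e5, seed = 2)
  boot <- replicate(200, {
    quantile(sample(e1$samples, 1e4, replace = TRUE), 0.9, type = 7)
  })
  se <- sd(boot) / sqrt(10) # scale bootstrap (n/10) SE back to full n
  expect_lt(abs(e1$summary$p90 - e2$summary$p90), 6 * se)
})
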
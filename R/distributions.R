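#' PERT distribution parameters
#'
#' A PERT distribution is a Beta distribution rescaled to `[min, max]` with
#' shapes determined by the most-likely value (mode) under the standard
#' lambda = 4 construction; its mean is `(min + 4 mode + max) / 6`. A
#' degenerate triple with `min == max` is accepted and treated as a point
#' mass (useful for closed-form oracles), but cannot be mapped to Beta
#' shapes.
#'
#' @param min,mode,max Numeric scalars with `min <= mode <= max`.
#' @return An object of class `"pert_params"`.
#' @export
#' @examples
#' pert_params(6, 8, 10)
pert_params <- function(min, mode, max) {
  stopifnot(is.numeric(min), is.numeric(mode), is.numeric(max))
  if (!(min <= mode && mode <= max)) {
    stop("PERT parameters must satisfy min <= mode <= max", call. = FALSE)
  }
  structure(list(min = min, mode = mode, max = max), class = "pert_params")
}

#' @export
print.pert_params <- function(x, ...) {
  cat(sprintf("PERT(%g, %g, %g), mean %.4g\n", x$min, x$mode, x$max,
              pert_mean(x)))
  invisible(x)
}

#' Beta shapes of a PERT distribution
#'
#' Under the standard construction the shapes on `[min, max]` are
#' `alpha1 = 1 + 4 (mode - min) / (max - min)` and
#' `alpha2 = 1 + 4 (max - mode) / (max - min)`.
#'
#' @param p A [pert_params()] object.
#' @return Named numeric vector `c(alpha1, alpha2)`.
#' @export
#' @examples
#' pert_to_beta(pert_params(0, 0.5, 1)) # symmetric: (3, 3)
pert_to_beta <- function(p) {
  stopifnot(inherits(p, "pert_params"))
  if (p$min == p$max) {
    stop("degenerate PERT (min == max) has no Beta representation",
         call. = FALSE)
  }
  rng <- p$max - p$min
  c(alpha1 = 1 + 4 * (p$mode - p$min) / rng,
    alpha2 = 1 + 4 * (p$max - p$mode) / rng)
}

#' Mean and variance of a PERT distribution
#'
#' Closed forms: mean `(min + 4 mode + max) / 6`; variance
#' `(mean - min) (max - mean) / 7`.
#'
#' @param p A [pert_params()] object.
#' @return A numeric scalar.
#' @export
pert_mean <- function(p) {
  stopifnot(inherits(p, "pert_params"))
  (p$min + 4 * p$mode + p$max) / 6
}

#' @rdname pert_mean
#' @export
pert_var <- function(p) {
  m <- pert_mean(p)
  (m - p$min) * (p$max - m) / 7
}

#' PERT quantile function
#'
#' Maps uniform draws to PERT draws; the workhorse behind [pert_sample()]
#' and the exposure engine's coupled random streams. A degenerate PERT
#' returns its point mass for every probability.
#'
#' @param u Probabilities in `[0, 1]`.
#' @param p A [pert_params()] object.
#' @return Numeric vector of the same length as `u`.
#' @export
pert_quantile <- function(u, p) {
  stopifnot(inherits(p, "pert_params"), all(u >= 0 & u <= 1))
  if (p$min == p$max) return(rep(p$min, length(u)))
  sh <- pert_to_beta(p)
  p$min + (p$max - p$min) * stats::qbeta(u, sh[["alpha1"]], sh[["alpha2"]])
}

#' Sample from a PERT distribution
#'
#' @param p A [pert_params()] object.
#' @param n Number of draws.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can manage coupling themselves).
#' @return Numeric vector of `n` draws in `[min, max]`.
#' @export
#' @examples
#' mean(pert_sample(pert_params(6, 8, 10), 1e4, seed = 1)) # close to 8
pert_sample <- function(p, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pert_quantile(stats::runif(n), p)
}

#' Discrete distribution over numeric outcomes
#'
#' @param values Numeric outcomes.
#' @param probs Probabilities, same length as `values`, summing to 1 within
#'   1e-9.
#' @return An object of class `"discrete_dist"`.
#' @export
discrete_dist <- function(values, probs) {
  stopifnot(length(values) == length(probs), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (got ", format(sum(probs)), ")",
         call. = FALSE)
  }
  structure(list(values = as.numeric(values), probs = as.numeric(probs)),
            class = "discrete_dist")
}

#' @export
print.discrete_dist <- function(x, ...) {
  cat("Discrete distribution:\n")
  print(tibble::tibble(value = x$values, prob = x$probs))
  invisible(x)
}

#' Mean of a discrete distribution
#' @param d A [discrete_dist()] object.
#' @return Numeric scalar.
#' @export
discrete_mean <- function(d) {
  stopifnot(inherits(d, "discrete_dist"))
  sum(d$values * d$probs)
}

#' Quantile-transform sampling for a discrete distribution
#'
#' @param u Uniform draws in `[0, 1]`.
#' @param d A [discrete_dist()] object.
#' @return Numeric vector of outcomes.
#' @export
discrete_quantile <- function(u, d) {
  stopifnot(inherits(d, "discrete_dist"))
  idx <- findInterval(u, cumsum(d$probs), left.open = TRUE) + 1L
  idx <- pmin(idx, length(d$values))
  d$values[idx]
}

#' Convert a frequency-category label to a per-day consumption rate
#'
#' @param category Character vector of category labels.
#' @param categories Category table with columns `label`, `per_day`
#'   (default [default_frequency_categories()]).
#' @return Numeric vector of per-day rates (once a week = 1/7, daily = 1,
#'   never = 0).
#' @export
#' @examples
#' frequency_to_daily("once a week")
frequency_to_daily <- function(category,
                               categories = default_frequency_categories()) {
  idx <- match(category, categories$label)
  if (anyNA(idx)) {
    stop("unknown frequency categories: ",
         paste(unique(category[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  categories$per_day[idx]
}

#' Build a consumption-frequency distribution from survey responses
#'
#' Converts the number of respondents in each frequency category into a
#' share of total respondents and attaches the per-day rate of each
#' category, yielding the discrete distribution the exposure engine draws
#' consumption frequency from.
#'
#' @param ffq A survey tibble with a `freq_category` column (see
#'   [generate_ffq()]).
#' @param categories Category table mapping labels to daily rates.
#' @return A [discrete_dist()] over daily consumption rates.
#' @export
build_frequency_dist <- function(ffq,
                                 categories = default_frequency_categories()) {
  if (nrow(ffq) == 0) stop("empty survey table", call. = FALSE)
  rate <- frequency_to_daily(ffq$freq_category, categories)
  tab <- table(rate)
  discrete_dist(as.numeric(names(tab)), as.numeric(tab) / nrow(ffq))
}

# ---- parametric fitting of contamination data --------------------------

# log-likelihood-based candidate fits on the detected (> LOD) values only;
# the censored mass is carried alongside as a fraction, never modelled
# parametrically (the exposure engine re-injects it by substitution).

.fit_lognormal <- function(x) {
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2)) # MLE (n denominator)
  ll <- sum(stats::dlnorm(x, mu, sigma, log = TRUE))
  list(family = "lognormal", parameters = c(meanlog = mu, sdlog = sigma),
       loglik = ll, n_par = 2)
}

.fit_mass <- function(x, densfun) {
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, densfun)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  list(family = densfun, parameters = fit$estimate, loglik = fit$loglik,
       n_par = length(fit$estimate))
}

.fit_truncnorm <- function(x) {
  # normal truncated at 0: density dnorm(x)/(1 - pnorm(0))
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    -sum(stats::dnorm(x, mu, sigma, log = TRUE) -
           stats::pnorm(0, mu, sigma, lower.tail = FALSE, log.p = TRUE))
  }
  opt <- tryCatch(
    stats::optim(c(mean(x), log(stats::sd(x) + 1e-12)), nll),
    error = function(e) NULL
  )
  if (is.null(opt)) return(NULL)
  list(family = "truncnorm",
       parameters = c(mean = opt$par[1], sd = exp(opt$par[2])),
       loglik = -opt$value, n_par = 2)
}

.quantile_fun <- function(family, parameters) {
  switch(family,
    lognormal = function(u) stats::qlnorm(u, parameters[["meanlog"]],
                                          parameters[["sdlog"]]),
    gamma = function(u) stats::qgamma(u, shape = parameters[["shape"]],
                                      rate = parameters[["rate"]]),
    weibull = function(u) stats::qweibull(u, shape = parameters[["shape"]],
                                          scale = parameters[["scale"]]),
    truncnorm = function(u) {
      p0 <- stats::pnorm(0, parameters[["mean"]], parameters[["sd"]])
      stats::qnorm(p0 + u * (1 - p0), parameters[["mean"]], parameters[["sd"]])
    },
    pointmass = function(u) rep(parameters[["value"]], length(u)),
    stop("unknown family: ", family, call. = FALSE)
  )
}

#' Fit a parametric distribution to detected contamination values
#'
#' Fits each candidate family to the detects (values above the LOD) by
#' maximum likelihood and selects the family with the lowest AIC. The
#' fraction of censored measurements and the LOD are stored with the fit so
#' that [censored_sampler()] can re-inject the censored mass by scenario
#' substitution. With fewer than three detects, or all detects identical, no
#' family is fitted: a point mass at the middle-bound substitute (LOD/2) or
#' at the common value is returned with a warning.
#'
#' @param detects Numeric vector of concentrations above the LOD.
#' @param frac_below Fraction of all measurements below the LOD, in `[0, 1]`.
#' @param lod Tissue-equivalent LOD in the concentration units of `detects`.
#' @param families Candidate families, a subset of
#'   `c("lognormal", "gamma", "weibull", "truncnorm")`.
#' @return An object of class `"contamination_fit"`: a list with `family`,
#'   `parameters`, `frac_below_lod`, `lod`, `n_detects`, `aic`.
#' @export
#' @examples
#' set.seed(1)
#' fit_contamination(rlnorm(200, 0.7, 0.25), frac_below = 0, lod = 0.01)
fit_contamination <- function(detects, frac_below, lod,
                              families = c("lognormal", "gamma", "weibull",
                                           "truncnorm")) {
  stopifnot(frac_below >= 0, frac_below <= 1, lod >= 0)
  detects <- detects[!is.na(detects)]
  if (any(detects <= 0)) {
    stop("detected concentrations must be positive", call. = FALSE)
  }
  if (length(detects) < 3 || stats::sd(detects) == 0) {
    value <- if (length(detects) >= 1) mean(detects) else lod / 2
    warning("fewer than 3 distinct detects: returning a point-mass fit",
            call. = FALSE)
    return(structure(
      list(family = "pointmass", parameters = c(value = value),
           frac_below_lod = frac_below, lod = lod,
           n_detects = length(detects), aic = NA_real_),
      class = "contamination_fit"
    ))
  }
  families <- match.arg(families, several.ok = TRUE)
  fits <- list()
  if ("lognormal" %in% families) fits$lognormal <- .fit_lognormal(detects)
  if ("gamma" %in% families) fits$gamma <- .fit_mass(detects, "gamma")
  if ("weibull" %in% families) fits$weibull <- .fit_mass(detects, "weibull")
  if ("truncnorm" %in% families) fits$truncnorm <- .fit_truncnorm(detects)
  fits <- purrr::compact(fits)
  if (length(fits) == 0) stop("all candidate fits failed", call. = FALSE)
  aic <- purrr::map_dbl(fits, ~ 2 * .x$n_par - 2 * .x$loglik)
  best <- fits[[which.min(aic)]]
  structure(
    list(family = best$family, parameters = best$parameters,
         frac_below_lod = frac_below, lod = lod,
         n_detects = length(detects), aic = min(aic)),
    class = "contamination_fit"
  )
}

#' @export
print.contamination_fit <- function(x, ...) {
  cat(sprintf(
    "Contamination fit: %s (%s), %.1f%% below LOD %.4g, %d detects\n",
    x$family,
    paste(names(x$parameters), signif(x$parameters, 4),
          sep = "=", collapse = ", "),
    100 * x$frac_below_lod, x$lod, x$n_detects
  ))
  invisible(x)
}

#' Concentration sampler honouring below-LOD substitution scenarios
#'
#' Implements the random split between censored and detected mass: per
#' iteration a uniform `u` is drawn, and if `u` falls below the censored
#' fraction the draw is the scenario substitute (0, LOD/2 or LOD for
#' LB/MB/UB), otherwise a draw from the fitted distribution. The returned
#' sampler consumes exactly two uniforms per iteration regardless of
#' scenario, so samplers built for the three scenarios from the same seed
#' share their random stream and their draws are pointwise ordered
#' LB <= MB <= UB.
#'
#' @param fit A [fit_contamination()] object.
#' @param scenario One of `"LB"`, `"MB"`, `"UB"`.
#' @return A function of `n` returning `n` concentration draws.
#' @export
#' @examples
#' f <- fit_contamination(rlnorm(100, 0, 0.3), frac_below = 0.5, lod = 0.5)
#' s <- censored_sampler(f, "MB")
#' set.seed(1); summary(s(1000))
censored_sampler <- function(fit, scenario = c("LB", "MB", "UB")) {
  stopifnot(inherits(fit, "contamination_fit"))
  scenario <- match.arg(scenario)
  sub <- switch(scenario, LB = 0, MB = fit$lod / 2, UB = fit$lod)
  qf <- .quantile_fun(fit$family, fit$parameters)
  y <- fit$frac_below_lod
  function(n) {
    u <- stats::runif(n)
    x <- qf(stats::runif(n))
    x[u < y] <- sub
    x
  }
}
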
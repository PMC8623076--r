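#' Autoscale a fingerprint matrix
#'
#' Column-wise standardization to mean 0 and unit (n - 1) standard
#' deviation, the conventional preprocessing for elemental fingerprints
#' before clustering and PLS-DA. Column means and sds are kept as
#' attributes so the transformation is invertible.
#'
#' @param X Numeric matrix, samples x elements.
#' @return Matrix `Z` with attributes `"scaled:center"` and
#'   `"scaled:scale"`.
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(X)[which(sds == 0 | is.na(sds))]
    stop("constant column(s) cannot be autoscaled: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(X, center = TRUE, scale = sds)
}

#' Invert autoscaling
#' @param Z Output of [autoscale()].
#' @return The original-scale matrix.
#' @export
unscale <- function(Z) {
  ctr <- attr(Z, "scaled:center")
  scl <- attr(Z, "scaled:scale")
  out <- sweep(sweep(Z, 2, scl, "*"), 2, ctr, "+")
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Ward hierarchical clustering of fingerprints
#'
#' Agglomerative clustering with Euclidean distance under Ward's
#' minimum-variance criterion (`hclust` method `"ward.D2"`, the formulation
#' that operates on unsquared Euclidean distances).
#'
#' @param Z Autoscaled fingerprint matrix.
#' @return An `hclust` object.
#' @export
ward_hca <- function(Z) {
  if (nrow(Z) < 2) stop("need at least 2 samples", call. = FALSE)
  stats::hclust(stats::dist(Z, method = "euclidean"), method = "ward.D2")
}

#' Cut a Ward dendrogram into k clusters
#'
#' @param linkage An `hclust` object from [ward_hca()].
#' @param k Number of clusters, at most the number of samples.
#' @return Integer cluster labels per sample.
#' @export
hca_cut <- function(linkage, k) {
  n <- length(linkage$order)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  stats::cutree(linkage, k = k)
}

#' Fit a PLS1 model with the SIMPLS algorithm
#'
#' SIMPLS deflates the covariance vector `X'y` directly against an
#' orthonormal basis of earlier loadings, producing mutually orthogonal
#' score vectors without deflating `X` itself. For discriminant use `y` is a
#' one-vs-rest class indicator in `{0, 1}`. `X` and `y` are centered
#' internally; pass autoscaled `X` for the standard preprocessing. Each
#' component's weight vector is sign-fixed (largest-magnitude entry
#' positive) so results are reproducible.
#'
#' @param X Numeric matrix, samples x variables (typically [autoscale()]d).
#' @param y Numeric response (class indicator for PLS-DA).
#' @param n_lv Number of latent variables (default 3).
#' @param target_species Optional label carried into the model.
#' @return An object of class `"plsda_model"`: weights `R` (p x A),
#'   normalized scores `T` (n x A), loadings `P`, y-loadings `q`,
#'   `coefficients` (for centered X), `x_means`, `y_mean`, `fitted`,
#'   `r2_cal`, `rmsec`, `vip`, `n_lv`, `target_species`.
#' @export
simpls_fit <- function(X, y, n_lv = 3, target_species = NA_character_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, n_lv >= 1)
  if (n_lv > min(n - 1, p)) {
    stop("n_lv exceeds the rank bound min(n - 1, p); use fewer latent ",
         "variables", call. = FALSE)
  }
  x_means <- colMeans(X)
  y_mean <- mean(y)
  X0 <- sweep(X, 2, x_means)
  y0 <- y - y_mean
  S <- drop(crossprod(X0, y0))
  R <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  V <- matrix(0, p, 0)
  for (a in seq_len(n_lv)) {
    r <- S
    t_a <- drop(X0 %*% r)
    nt <- sqrt(sum(t_a^2))
    if (nt < 1e-12) {
      stop("rank deficiency at component ", a, "; use fewer latent variables",
           call. = FALSE)
    }
    t_a <- t_a / nt
    r <- r / nt
    # fixed sign convention: largest-magnitude weight entry positive
    s_flip <- sign(r[which.max(abs(r))])
    if (s_flip == 0) s_flip <- 1
    r <- r * s_flip
    t_a <- t_a * s_flip
    p_a <- drop(crossprod(X0, t_a))
    q_a <- sum(y0 * t_a)
    v <- p_a
    if (a > 1) v <- v - drop(V %*% crossprod(V, p_a))
    v <- v / sqrt(sum(v^2))
    S <- S - v * sum(v * S)
    R[, a] <- r
    Tm[, a] <- t_a
    P[, a] <- p_a
    q[a] <- q_a
    V <- cbind(V, v)
  }
  B <- drop(R %*% q)
  fitted <- drop(X0 %*% B) + y_mean
  sse <- sum((y - fitted)^2)
  sst <- sum(y0^2)
  model <- structure(
    list(
      R = R, T = Tm, P = P, q = q, coefficients = B,
      x_means = x_means, y_mean = y_mean, fitted = fitted,
      r2_cal = 1 - sse / sst, rmsec = sqrt(mean((y - fitted)^2)),
      n_lv = n_lv, element_names = colnames(X),
      target_species = target_species
    ),
    class = "plsda_model"
  )
  model$vip <- vip_scores(model)
  model
}

#' Predict from a SIMPLS model
#'
#' @param object A [simpls_fit()] model.
#' @param newdata Matrix on the same scale as the training `X`.
#' @param n_lv Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.plsda_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  B <- drop(object$R[, seq_len(n_lv), drop = FALSE] %*%
              object$q[seq_len(n_lv)])
  drop(sweep(as.matrix(newdata), 2, object$x_means) %*% B) + object$y_mean
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "SIMPLS PLS-DA model (%s): %d LV, R2cal %.3f, RMSEC %.3f\n",
    x$target_species, x$n_lv, x$r2_cal, x$rmsec
  ))
  invisible(x)
}

#' Variable importance in projection
#'
#' Standard (Wold) VIP:
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with `p`
#' the number of variables and `SS_a` the y-variance explained by component
#' `a` (here `q_a^2`, the scores being normalized). The mean of squared VIP
#' over the variables is exactly 1, so variables with VIP > 1 contribute
#' more than average and are read as class markers.
#'
#' @param model A [simpls_fit()] model.
#' @return Named numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$R
  ss <- model$q^2
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  vip <- sqrt(p * drop(wn2 %*% ss) / sum(ss))
  names(vip) <- model$element_names
  vip
}

#' Select marker variables by VIP threshold
#'
#' @param vip Named VIP vector from [vip_scores()].
#' @param threshold Strict threshold, default 1.
#' @return Character vector of variable names with VIP strictly above the
#'   threshold, sorted by decreasing VIP.
#' @export
select_markers <- function(vip, threshold = 1) {
  sel <- vip[vip > threshold]
  names(sort(sel, decreasing = TRUE))
}

#' Venetian-blinds cross-validation of a SIMPLS model
#'
#' Samples are put in a fixed label-stratified order (sorted by class, then
#' original index) and every `n_splits`-th sample is assigned to the same
#' fold — the deterministic interleaved ("venetian blinds") scheme, split
#' ratio 1:`n_splits`. Each fold is held out once, the model refit on the
#' rest, and held-out predictions pooled; RMSECV and the cross-validated R2
#' are reported for every component count up to `n_lv`.
#'
#' @param X Matrix on the modelling scale (autoscaled).
#' @param y Class indicator.
#' @param n_lv Maximum number of latent variables.
#' @param n_splits Number of folds, default 5.
#' @return A tibble with columns `n_lv`, `rmsecv`, `r2_cv`.
#' @export
venetian_blinds_cv <- function(X, y, n_lv = 3, n_splits = 5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= n_splits)
  ord <- order(y, seq_len(n))
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% n_splits + 1L
  pred <- matrix(NA_real_, n, n_lv)
  for (k in seq_len(n_splits)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2) {
      message("fold ", k, ": training split single-class; interleaved ",
              "stratification fallback in effect")
    }
    fit <- simpls_fit(X[tr, , drop = FALSE], y[tr], n_lv = n_lv)
    for (a in seq_len(n_lv)) {
      pred[!tr, a] <- predict(fit, X[!tr, , drop = FALSE], n_lv = a)
    }
  }
  sst <- sum((y - mean(y))^2)
  press <- colSums((pred - y)^2)
  tibble::tibble(
    n_lv = seq_len(n_lv),
    rmsecv = sqrt(press / n),
    r2_cv = 1 - press / sst
  )
}

#' One-vs-rest PLS-DA for one species
#'
#' Convenience wrapper running the full chemometric workflow for a target
#' species: autoscale the fingerprint matrix, code the one-vs-rest
#' indicator, fit SIMPLS, cross-validate by venetian blinds, and select
#' VIP > 1 markers.
#'
#' @param fingerprints A list as from [generate_fingerprints()] (`X`,
#'   `labels`, `element_names`).
#' @param species Target species label.
#' @param n_lv Latent variables, default 3.
#' @param n_splits CV folds, default 5.
#' @return The fitted `"plsda_model"` with extra entries `cv` (tibble) and
#'   `markers` (character).
#' @export
#' @examples
#' fp <- generate_fingerprints(seed = 1)
#' m <- plsda_species(fp, "Argopecten irradians")
#' m$markers
plsda_species <- function(fingerprints, species, n_lv = 3, n_splits = 5) {
  Z <- autoscale(fingerprints$X)
  y <- as.numeric(fingerprints$labels == species)
  if (sum(y) == 0) stop("target species absent from labels", call. = FALSE)
  model <- simpls_fit(Z, y, n_lv = n_lv, target_species = species)
  model$cv <- venetian_blinds_cv(Z, y, n_lv = n_lv, n_splits = n_splits)
  model$r2_cv <- model$cv$r2_cv[n_lv]
  model$rmsecv <- model$cv$rmsecv[n_lv]
  model$markers <- select_markers(model$vip)
  model
}
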
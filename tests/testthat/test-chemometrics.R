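test_that("autoscaling standardizes columns and inverts cleanly", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  Z <- autoscale(X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(Z)), c(0, 0))
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1))
  expect_equal(unname(autoscale(Z)[, ]), unname(Z[, ]), tolerance = 1e-12)
  expect_equal(unscale(Z), X, tolerance = 1e-10)
  Xc <- cbind(a = c(1, 2, 3), Hg = c(5, 5, 5))
  expect_error(autoscale(Xc), "Hg")
})

test_that("Ward clustering separates distinct groups and is monotone", {
  set.seed(8)
  blobs <- rbind(
    matrix(rnorm(40, 0), 20, 2),
    matrix(rnorm(40, 10), 20, 2)
  )
  hc <- ward_hca(blobs)
  expect_true(all(diff(hc$height) >= -1e-12))
  cl <- hca_cut(hc, 2)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_true(cl[1] != cl[21])
  expect_error(hca_cut(hc, 41), "exceeds")
})

test_that("SIMPLS matches a NIPALS oracle and OLS at full rank", {
  inst <- random_instance(20, 8, seed = 14)
  for (a in c(1, 3, 5)) {
    m <- simpls_fit(inst$X, inst$y, n_lv = a)
    o <- nipals_pls1(inst$X, inst$y, n_lv = a)
    expect_equal(predict(m, inst$X), o$predict(inst$X), tolerance = 1e-8)
  }
  full <- simpls_fit(inst$X, inst$y, n_lv = 8)
  ols <- unname(lm.fit(cbind(1, inst$X), inst$y)$fitted.values)
  expect_equal(unname(full$fitted), ols, tolerance = 1e-8)
  # scores orthogonal
  m3 <- simpls_fit(inst$X, inst$y, n_lv = 3)
  G <- crossprod(m3$T)
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("single informative column drives the one-component weight", {
  set.seed(2)
  X <- cbind(inf = rnorm(30), matrix(rnorm(90), 30, 3))
  y <- X[, 1] * 2
  m <- simpls_fit(X, y, n_lv = 1)
  w <- m$R[, 1] / sqrt(sum(m$R[, 1]^2))
  covs <- unname(drop(crossprod(scale(X, scale = FALSE), y - mean(y))))
  covs <- covs / sqrt(sum(covs^2))
  expect_equal(abs(w), abs(covs), tolerance = 1e-10)
  expect_gt(abs(w[1]), 0.95)
})

test_that("VIP satisfies its algebraic identities", {
  inst <- random_instance(25, 6, seed = 77)
  for (a in c(1, 2, 4)) {
    m <- simpls_fit(inst$X, inst$y, n_lv = a)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
  }
  m1 <- simpls_fit(inst$X, inst$y, n_lv = 1)
  w <- m1$R[, 1]
  expect_equal(unname(m1$vip),
               sqrt(6) * abs(w) / sqrt(sum(w^2)), tolerance = 1e-10)
  # symmetric informativeness: equal-weight problem gives VIP = 1
  set.seed(3)
  base <- rnorm(40)
  Xe <- sapply(1:4, function(i) base)
  colnames(Xe) <- paste0("e", 1:4)
  Xe <- Xe + matrix(rnorm(160, sd = 1e-6), 40, 4)
  me <- simpls_fit(Xe, base, n_lv = 1)
  expect_equal(unname(me$vip), rep(1, 4), tolerance = 1e-3)
})

test_that("marker selection is strict and sorted", {
  vip <- c(As = 1.4, Cd = 0.2, Co = 1.0, Ni = 1.9)
  expect_equal(select_markers(vip), c("Ni", "As"))
  expect_equal(select_markers(c(a = 1, b = 1)), character(0))
})

test_that("venetian blinds CV is deterministic and honest", {
  # noiseless separable problem: near-perfect cross-validation
  set.seed(21)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
             matrix(rnorm(60, 4, 0.1), 30, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c(0, 1), each = 30)
  cv <- venetian_blinds_cv(autoscale(X), y, n_lv = 2)
  expect_gt(cv$r2_cv[2], 0.99)
  expect_lt(cv$rmsecv[2], 0.05)
  expect_identical(cv, venetian_blinds_cv(autoscale(X), y, n_lv = 2))

  # optimism: held-out error is not systematically below calibration error
  diffs <- sapply(1:8, function(s) {
    inst <- random_instance(30, 5, seed = 200 + s)
    m <- simpls_fit(inst$X, inst$y, n_lv = 2)
    cv <- venetian_blinds_cv(inst$X, inst$y, n_lv = 2)
    cv$rmsecv[2] - m$rmsec
  })
  expect_gt(mean(diffs), 0)
})

test_that("species workflow returns a usable one-vs-rest model", {
  fp <- generate_fingerprints(seed = 1)
  m <- plsda_species(fp, "Venerupis philippinarum")
  expect_s3_class(m, "plsda_model")
  expect_equal(m$n_lv, 3)
  expect_true(m$r2_cal > 0.8 && m$r2_cal <= 1)
  expect_true(m$r2_cv <= m$r2_cal)
  expect_true(length(m$markers) >= 1)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-9)
  expect_error(plsda_species(fp, "Ostrea edulis"), "absent")
})
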
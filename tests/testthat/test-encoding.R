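# Encoding models: design matrices, ridge fitting, prediction, scoring.

test_that("preset feature counts match the model families", {
  expect_equal(n_features(encoding_preset("kf")), 4L)
  expect_equal(n_features(encoding_preset("ukf1")), 60L)
  for (n in c(0L, 1L, 17L, 250L)) {
    expect_equal(n_features(encoding_preset("ukf2"), n), 70L + n)
    expect_equal(n_features(encoding_preset("population_history"), n), n)
  }
  expect_equal(n_features(encoding_preset("ukf1_a")), 90L)
  expect_equal(n_features(encoding_preset("ukf1_pvi")), 80L)
  expect_equal(n_features(encoding_preset("ukf1_t")), 90L)
})

test_that("design matrix columns evaluate the literal feature definitions", {
  nb <- 12
  kin <- kinematics_frame(px = rep(2, nb), py = rep(0, nb),
                          vx = rep(3, nb), vy = rep(1, nb),
                          ax = rep(0, nb), ay = rep(0, nb),
                          tx = rep(5, nb), ty = rep(4, nb))
  s <- binned_session(kin, spike_count_block(matrix(1L, 2, nb)))
  spec <- feature_spec(c("P", "V", "A", "PVI", "T"), 0L)
  dm <- build_design_matrix(s, spec)
  r <- dm$X[5, ]
  expect_equal(unname(r[c("pvi_x@+0", "pvi_y@+0")]), c(6, 0))
  expect_equal(unname(r["mag_p@+0"]), 2)
  expect_equal(unname(r["dist_tc@+0"]), 5)  # offsets (3, 4) from the cursor

  kin2 <- kin; kin2$vx <- rep(3, nb); kin2$vy <- rep(4, nb)
  s2 <- binned_session(kin2, s$spikes)
  expect_equal(unname(build_design_matrix(s2, spec)$X[5, "mag_v@+0"]), 5)
})

test_that("tap rows are masked outside the session and SH is the previous bin", {
  s <- tiny_session(nb = 30)
  dm <- build_design_matrix(s, encoding_preset("ukf2"))
  expect_false(any(dm$mask[c(1, 2, 29, 30)]))  # taps +2..-2 and SH at bin 1
  expect_true(all(dm$mask[3:28]))
  sh_cols <- dm$features$group == "SH"
  expect_equal(unname(dm$X[10, sh_cols]),
               unname(s$spikes$counts[, 9]))
  # tap +2 position column equals the kinematics two bins ahead
  expect_equal(unname(dm$X[10, "px@+2"]), s$kinematics$px[12])
  expect_error(build_design_matrix(
    s, feature_spec(c("P", "V"), 9:-9)), NA)  # wide taps allowed, just masked
})

test_that("ridge fit matches the closed form at fixed lambda", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  ctrue <- c(1.5, -2, 0.5)
  Y <- X %*% ctrue + rnorm(10, 0, 0.1)
  lam <- 0.7
  m <- suppressWarnings(fit_encoding(X, t(Y), lambda_grid = lam))
  Xs <- scale(X)
  Yc <- Y - mean(Y)
  oracle <- solve(crossprod(Xs) + diag(lam, 3), crossprod(Xs, Yc))
  expect_equal(unname(as.vector(m$coef)), unname(as.vector(oracle)),
               tolerance = 1e-10)
})

test_that("noiseless generate-and-recover is exact at tiny lambda", {
  set.seed(9)
  X <- matrix(rnorm(500 * 4), 500, 4)
  ctrue <- c(2, -1, 0.5, 3)
  Y <- X %*% ctrue
  m <- suppressWarnings(fit_encoding(X, t(Y), lambda_grid = 1e-8))
  raw <- as.vector(m$coef) / m$scales
  expect_equal(unname(raw), ctrue, tolerance = 1e-4)
})

test_that("constant counts and constant features are handled", {
  set.seed(10)
  X <- cbind(rnorm(50), rep(3, 50))
  Y <- matrix(5, 50, 1)
  expect_warning(m <- fit_encoding(X, t(Y), lambda_grid = 1), "constant")
  expect_equal(unname(as.vector(m$coef)), c(0, 0))
  expect_equal(unname(m$unit_means), 5)
  pred <- predict_rates(m, X)
  expect_equal(unname(as.vector(pred)), rep(5, 50))
})

test_that("training MSE is non-decreasing along the ridge path", {
  set.seed(12)
  X <- matrix(rnorm(200 * 5), 200, 5)
  Y <- X %*% rnorm(5) + rnorm(200, 0, 0.5)
  grid <- 10^seq(-4, 4, length.out = 9) * 200
  mses <- vapply(grid, function(l) {
    m <- suppressWarnings(fit_encoding(X, t(Y), lambda_grid = l))
    mean((Y - predict_rates(m, X))^2)
  }, numeric(1))
  expect_true(all(diff(mses) >= -1e-10))
})

test_that("residuals are orthogonal to the design at lambda -> 0", {
  set.seed(13)
  X <- matrix(rnorm(300 * 4), 300, 4)
  Y <- X %*% rnorm(4) + rnorm(300)
  m <- suppressWarnings(fit_encoding(X, t(Y), lambda_grid = 1e-10))
  resid <- as.vector(Y - predict_rates(m, X))
  Xs <- scale(X)
  expect_lt(max(abs(crossprod(Xs, resid))), 1e-5)
})

test_that("a self-history model is previous-count arithmetic", {
  # one unit, coefficient 0.5 on its own previous count, zero mean offset
  nb <- 200
  set.seed(14)
  counts <- matrix(rpois(nb, 4), 1, nb)
  s <- binned_session(
    kinematics_frame(rnorm(nb), rnorm(nb)),
    spike_count_block(counts))
  dm <- build_design_matrix(s, encoding_preset("self_history"))
  m <- suppressWarnings(fit_encoding(dm, s$spikes, lambda_grid = 1e-8))
  # hand-build the prediction for prev count 4 from the standardised model
  prev <- 4
  manual <- m$unit_means + m$coef[1, 1] * (prev - m$centers[1]) / m$scales[1]
  x <- dm$X; x[, 1] <- prev
  dm2 <- dm; dm2$X <- x
  expect_equal(unname(predict_rates(m, dm2)[10, 1]), unname(manual))
  # and the raw-space arithmetic: c * prev + intercept
  c_raw <- m$coef[1, 1] / m$scales[1]
  icpt <- m$unit_means - c_raw * m$centers[1]
  expect_equal(unname(manual), unname(c_raw * prev + icpt))
})

test_that("scoring follows the SNR definition and its worked cases", {
  set.seed(15)
  a <- rnorm(400)
  a <- a - mean(a)
  sc <- score_predictions(a, a)
  expect_equal(sc$cc, 1)
  expect_equal(sc$snr_db, 300)  # capped sentinel for an exact match

  sc2 <- score_predictions(-a, a)
  expect_equal(sc2$cc, -1)
  expect_equal(sc2$snr_db, 10 * log10(1 / 4))  # MSE = 4 Var_s

  # Var_s = 10, MSE = 1 -> 10 dB
  x <- sqrt(10) * a / sqrt(mean(a^2))
  noise <- rnorm(400)
  noise <- (noise - mean(noise)) / sqrt(mean((noise - mean(noise))^2))
  sc3 <- score_predictions(x + noise, x)
  expect_equal(sc3$snr_db, 10, tolerance = 1e-6)

  # CC is invariant to positive affine transforms of the prediction; SNR not
  p <- x + rnorm(400)
  s_raw <- score_predictions(p, x)
  s_aff <- score_predictions(2 * p + 3, x)
  expect_equal(s_aff$cc, s_raw$cc)
  expect_false(isTRUE(all.equal(s_aff$snr_db, s_raw$snr_db)))

  expect_message(score_predictions(cbind(a, a), cbind(a, rep(1, 400))),
                 "zero variance")
})

test_that("two-fold CV recovers linear structure and nulls out noise", {
  set.seed(16)
  nb <- 1200
  kin <- kinematics_frame(px = 4 * sin((1:nb) / 15), py = 4 * cos((1:nb) / 11))
  # counts generated exactly from the kf features of the same session
  rate <- 3 + 0.5 * kin$px - 0.3 * kin$vy
  counts <- rbind(round(pmax(rate, 0)), round(pmax(2 + 0.4 * kin$vx, 0)))
  s <- binned_session(kin, spike_count_block(counts))
  cv <- twofold_cv_encoding(s, "kf", lambda_grid = 1e-6)
  expect_true(all(cv$cc > 0.97))

  noise <- matrix(rpois(2 * nb, 3), 2, nb)
  s0 <- binned_session(kin, spike_count_block(noise))
  cv0 <- twofold_cv_encoding(s0, "kf")
  expect_lt(max(abs(cv0$cc)), 3 / sqrt(nb / 2))

  # deterministic: rerunning reproduces the same fold average
  expect_identical(twofold_cv_encoding(s0, "kf"), cv0)
})
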
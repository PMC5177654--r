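# State layouts, transition models, and (unscented) Kalman inference.

test_that("layouts have the published dimensions and a coherent index map", {
  expect_equal(make_layout("ukf2")$dim, 40L)
  expect_equal(make_layout("ukf1")$dim, 40L)
  expect_equal(make_layout("kf")$dim, 4L)
  expect_equal(make_layout("fit_kf")$dim, 4L)
  expect_error(make_layout("banana"))

  lay <- make_layout("ukf2")
  expect_equal(lay$offsets, 2:-2)
  idx <- state_index(lay, "vx", 0L)
  expect_equal(lay$names[idx], "vx@+0")
  # every (var, tap) pair maps to a unique position
  all_idx <- unlist(lapply(lay$offsets, function(o)
    state_index(lay, lay$vars, o)))
  expect_equal(sort(all_idx), 1:40)
  expect_error(state_index(lay, "vx", 9L), "tap")
})

test_that("physics transitions follow the laws of motion", {
  lay <- make_layout("ukf2")
  tr <- build_physics_transition(lay, dt = 0.05)
  s <- rep(0, 40)
  s[state_index(lay, "px", 2L)] <- 0
  s[state_index(lay, "vx", 2L)] <- 1
  nxt <- as.vector(tr$F %*% s)
  expect_equal(nxt[state_index(lay, "px", 2L)], 0.05)   # p' = p + v dt
  expect_equal(nxt[state_index(lay, "vx", 2L)], 0.85)   # v' = c_v v (a = 0)

  s2 <- rep(0, 40)
  s2[state_index(lay, "vx", 2L)] <- 2
  expect_equal(as.vector(tr$F %*% s2)[state_index(lay, "vx", 2L)], 1.7)

  # acceleration with target at the cursor: pure decay, zero here
  s3 <- rep(0, 40)
  s3[state_index(lay, "px", 2L)] <- 3
  s3[state_index(lay, "tx", 2L)] <- 3
  expect_equal(as.vector(tr$F %*% s3)[state_index(lay, "ax", 2L)], 0)
  # and attraction when the target leads the cursor
  s3[state_index(lay, "tx", 2L)] <- 4
  expect_equal(as.vector(tr$F %*% s3)[state_index(lay, "ax", 2L)],
               0.01 * (4 - 3) / 0.05^2)
})

test_that("non-leading taps shift exactly", {
  for (variant in c("ukf1", "ukf2")) {
    lay <- make_layout(variant)
    tr <- build_physics_transition(lay)
    set.seed(20)
    s <- rnorm(lay$dim)
    nxt <- as.vector(tr$F %*% s)
    for (j in 2:length(lay$offsets)) {
      dst <- state_index(lay, lay$vars, lay$offsets[j])
      src <- state_index(lay, lay$vars, lay$offsets[j - 1])
      expect_identical(nxt[dst], s[src])
    }
  }
})

test_that("offline transition fitting recovers a known linear system", {
  set.seed(21)
  A <- matrix(c(0.95, 0.05, -0.03, 0.9), 2, 2)
  nb <- 3000
  V <- matrix(0, nb, 2)
  for (t in 2:nb) V[t, ] <- A %*% V[t - 1, ] + rnorm(2, 0, 0.2)
  px <- cumsum(V[, 1]) * 0.05
  py <- cumsum(V[, 2]) * 0.05
  kin <- kinematics_frame(px, py, vx = V[, 1], vy = V[, 2],
                          ax = rep(0, nb), ay = rep(0, nb))
  lay <- make_layout("kf")
  tr <- fit_transition_offline(lay, kin, lambda_grid = 1e-8)
  iv <- state_index(lay, c("vx", "vy"), 0L)
  expect_equal(unname(tr$F[iv, iv]), A, tolerance = 0.05)
  expect_equal(unname(diag(tr$Q)[iv]), c(0.04, 0.04), tolerance = 0.15)
  # noiseless first-order system: two slowly decaying rotations in a generic
  # basis keep all four state dimensions excited over the whole record, so
  # the map is identifiable exactly from a single trajectory
  rot <- function(th, r) r * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  M <- matrix(c(1, 0.3, -0.2, 0.8, 0.5, 1, 0.1, -0.4,
                0.2, -0.1, 1, 0.6, -0.3, 0.2, 0.4, 1), 4, 4)
  A4 <- M %*% rbind(cbind(rot(0.3, 0.995), matrix(0, 2, 2)),
                    cbind(matrix(0, 2, 2), rot(0.7, 0.99))) %*% solve(M)
  K <- matrix(0, 500, 4); K[1, ] <- c(1, -1, 0.5, 2)
  for (t in 2:500) K[t, ] <- A4 %*% K[t - 1, ]
  kin2 <- kinematics_frame(K[, 1], K[, 2], vx = K[, 3], vy = K[, 4],
                           ax = rep(0, 500), ay = rep(0, 500))
  tr2 <- fit_transition_offline(lay, kin2, lambda_grid = 1e-12)
  all_iv <- state_index(lay, c("px", "py", "vx", "vy"), 0L)
  expect_equal(unname(tr2$F[all_iv, all_iv]), A4, tolerance = 1e-5)
  expect_lt(max(abs(tr2$Q)), 1e-8)
})

test_that("noise covariance fitting recovers injected variance and honours position feedback", {
  lay <- make_layout("kf")
  dt <- 0.05
  set.seed(22)
  nb <- 20000
  sig <- 0.5
  V <- matrix(0, nb, 2)
  P <- matrix(0, nb, 2)
  for (t in 2:nb) {
    V[t, ] <- 0.85 * V[t - 1, ] + rnorm(2, 0, sig)
    P[t, ] <- P[t - 1, ] + V[t - 1, ] * dt
  }
  kin <- kinematics_frame(P[, 1], P[, 2], vx = V[, 1], vy = V[, 2],
                          ax = rep(0, nb), ay = rep(0, nb))
  tr <- fit_noise_covariance(
    build_physics_transition(lay, position_feedback = FALSE), kin)
  iv <- state_index(lay, c("vx", "vy"), 0L)
  ip <- state_index(lay, c("px", "py"), 0L)
  expect_equal(unname(diag(tr$Q)[iv]), c(sig^2, sig^2), tolerance = 0.1 * sig^2)
  expect_lt(max(abs(tr$Q[ip, ])), 1e-12)  # position evolves exactly as modelled

  trf <- fit_noise_covariance(
    build_physics_transition(make_layout("fit_kf")), kin)
  expect_true(all(trf$Q[ip, ] == 0) && all(trf$Q[, ip] == 0))

  # noiseless dynamics leave essentially no residual
  V0 <- matrix(0, 300, 2); V0[1, ] <- c(2, 1)
  P0 <- matrix(0, 300, 2)
  for (t in 2:300) {
    V0[t, ] <- 0.85 * V0[t - 1, ]
    P0[t, ] <- P0[t - 1, ] + V0[t - 1, ] * dt
  }
  kin0 <- kinematics_frame(P0[, 1], P0[, 2], vx = V0[, 1], vy = V0[, 2],
                           ax = rep(0, 300), ay = rep(0, 300))
  tr0 <- fit_noise_covariance(
    build_physics_transition(lay, position_feedback = FALSE), kin0)
  expect_lt(max(abs(tr0$Q)), 1e-10)
})

test_that("intention estimation re-aims velocities and preserves speed", {
  nb <- 50
  set.seed(23)
  kin <- kinematics_frame(px = rnorm(nb, 0, 3), py = rnorm(nb, 0, 3),
                          tx = rep(6, nb), ty = rep(0, nb), target_radius = 2)
  out <- apply_intention_estimation(kin)
  expect_equal(kin$px, out$px)  # positions untouched
  d <- sqrt((kin$tx - kin$px)^2 + (kin$ty - kin$py)^2)
  outside <- d > 2
  expect_equal(sqrt(out$vx^2 + out$vy^2)[outside],
               sqrt(kin$vx^2 + kin$vy^2)[outside])
  expect_true(all(out$vx[!outside] == 0 & out$vy[!outside] == 0))
  # velocity already aimed at the target is unchanged
  kin2 <- kinematics_frame(px = rep(0, 10), py = rep(0, 10),
                           vx = rep(2, 10), vy = rep(0, 10),
                           ax = rep(0, 10), ay = rep(0, 10),
                           tx = rep(5, 10), ty = rep(0, 10), target_radius = 1)
  out2 <- apply_intention_estimation(kin2)
  expect_equal(out2$vx, kin2$vx)
  expect_equal(out2$vy, kin2$vy)
  kin3 <- kin; kin3$tx <- NA_real_
  expect_error(apply_intention_estimation(kin3), "target")
})

textbook_kf <- function(m, P, F, Q, H, b, R, y) {
  mp <- F %*% m
  Pp <- F %*% P %*% t(F) + Q
  S <- H %*% Pp %*% t(H) + R
  K <- Pp %*% t(H) %*% solve(S)
  mu <- mp + K %*% (y - H %*% mp - b)
  Pu <- (diag(nrow(Pp)) - K %*% H) %*% Pp
  list(mean = as.vector(mu), cov = Pu)
}

test_that("kf_step matches the textbook update and respects its limits", {
  set.seed(24)
  lay <- make_layout("kf")
  for (rep in 1:10) {
    F <- matrix(rnorm(16, 0, 0.3), 4, 4); diag(F) <- 0.9
    Q <- rand_spd(4, 0.1)
    tr <- ukfbmi:::new_transition(F, rep(0, 4), Q, lay, list(), FALSE, "physics")
    H <- matrix(rnorm(12), 3, 4); b <- rnorm(3)
    R <- rand_spd(3, 0.2)
    bel <- gaussian_belief(rnorm(4), rand_spd(4, 0.3))
    y <- rnorm(3)
    got <- kf_step(bel, tr, list(H = H, b = b, R = R), y)
    want <- textbook_kf(bel$mean, bel$cov, F, Q, H, b, R, y)
    expect_equal(got$mean, want$mean, tolerance = 1e-10)
    expect_equal(unname(got$cov), unname((want$cov + t(want$cov)) / 2),
                 tolerance = 1e-10)
  }

  # zero observation noise + full-rank observation reproduces the data
  F <- diag(4); Q <- diag(1e-12, 4)
  tr <- ukfbmi:::new_transition(F, rep(0, 4), Q, lay, list(), FALSE, "physics")
  H <- diag(4); y <- c(1, -2, 3, 0.5)
  post <- kf_step(gaussian_belief(rep(0, 4), diag(4)), tr,
                  list(H = H, b = rep(0, 4), R = diag(1e-12, 4)), y)
  expect_equal(post$mean, y, tolerance = 1e-6)

  # near-infinite observation noise leaves the prior untouched
  bel <- gaussian_belief(c(1, 2, 3, 4), diag(4))
  post2 <- kf_step(bel, tr, list(H = H, b = rep(0, 4), R = diag(1e12, 4)), y)
  expect_equal(post2$mean, bel$mean, tolerance = 1e-6)

  expect_error(kf_step(bel, tr, list(H = H, b = rep(0, 4),
                                     R = -diag(4)), y),
               "positive definite")
})

test_that("ukf_step agrees with kf_step on linear observation models", {
  set.seed(25)
  lay <- make_layout("kf")
  worst <- 0
  for (rep in 1:25) {
    F <- matrix(rnorm(16, 0, 0.3), 4, 4); diag(F) <- 0.8
    Q <- rand_spd(4, 0.1)
    tr <- ukfbmi:::new_transition(F, rnorm(4, 0, 0.1), Q, lay, list(),
                                  FALSE, "physics")
    H <- matrix(rnorm(12), 3, 4); b <- rnorm(3)
    R <- rand_spd(3, 0.2)
    bel <- gaussian_belief(rnorm(4), rand_spd(4, 0.3))
    y <- rnorm(3, 0, 2)
    p1 <- kf_step(bel, tr, list(H = H, b = b, R = R), y)
    p2 <- ukf_step(bel, tr, list(fn = function(S) sweep(S %*% t(H), 2, b, "+"),
                                 R = R), y)
    worst <- max(worst, max(abs(p1$mean - p2$mean)), max(abs(p1$cov - p2$cov)))
  }
  expect_lt(worst, 1e-8)
})

test_that("ukf update is inert for a zero-variance prior", {
  lay <- make_layout("kf")
  tr <- ukfbmi:::new_transition(diag(4), rep(0, 4), diag(1e-14, 4), lay,
                                list(), FALSE, "physics")
  bel <- gaussian_belief(c(1, 2, 3, 4), diag(1e-14, 4))
  obs <- list(fn = function(S) cbind(S[, 1]^2 + S[, 3]), R = diag(1, 1))
  post <- ukf_step(bel, tr, obs, 99)
  expect_equal(post$mean, bel$mean, tolerance = 1e-6)
})

test_that("ukf posterior moments match Monte Carlo on a magnitude model", {
  # toy: state (v1, v2), observation |v| + noise, in a regime where the
  # magnitude is mildly curved so a second-order sigma-point approximation
  # is expected to track exact moment matching
  set.seed(26)
  lay <- make_layout("kf")
  m0 <- c(3, 1)
  P0 <- matrix(c(0.16, 0.03, 0.03, 0.12), 2, 2)
  R <- matrix(0.25, 1, 1)
  y <- 3.8
  trv <- ukfbmi:::new_transition(diag(2), rep(0, 2), diag(1e-12, 2),
                                 lay, list(), FALSE, "physics")
  obs <- list(fn = function(S) cbind(sqrt(S[, 1]^2 + S[, 2]^2)), R = R)
  post <- ukf_step(gaussian_belief(m0, P0), trv, obs, y)
  # moment-matching oracle by brute-force sampling
  n <- 1e6
  X <- matrix(rnorm(2 * n), n, 2) %*% chol(P0)
  X <- sweep(X, 2, m0, "+")
  Z <- sqrt(X[, 1]^2 + X[, 2]^2)
  zbar <- mean(Z)
  S <- var(Z) + R[1, 1]
  Cxz <- c(cov(X[, 1], Z), cov(X[, 2], Z))
  K <- Cxz / S
  mean_mc <- m0 + K * (y - zbar)
  expect_equal(post$mean, mean_mc, tolerance = 0.02)
  cov_mc <- cov(X) - outer(K, K) * S
  expect_lt(max(abs(post$cov - cov_mc)) / max(abs(cov_mc)), 0.02)
})

test_that("covariances stay symmetric PSD over long random runs", {
  set.seed(27)
  lay <- make_layout("kf")
  F <- matrix(rnorm(16, 0, 0.2), 4, 4); diag(F) <- 0.85
  F <- F * 0.95 / max(Mod(eigen(F, only.values = TRUE)$values))
  Q <- rand_spd(4, 0.05)
  tr <- ukfbmi:::new_transition(F, rep(0, 4), Q, lay, list(), FALSE, "physics")
  H <- matrix(rnorm(8), 2, 4)
  R <- rand_spd(2, 0.1)
  bel <- gaussian_belief(rep(0, 4), diag(4))
  for (t in 1:10000) {
    bel <- kf_step(bel, tr, list(H = H, b = c(0, 0), R = R),
                   rnorm(2, 0, 2))
  }
  expect_true(all(is.finite(bel$mean)))
  expect_symmetric_psd(bel$cov)
})

test_that("offline decoding reconstructs a matched noiseless session and nulls shuffled counts", {
  # smooth pursuit: the target moves continuously, so the decoded target
  # tracks it and the reconstruction approaches the noiseless ideal
  sim <- simulate_hand_session(
    task_config("lissajous", duration = 240),
    population_config(n_units = 50, noise_sd = 0, fraction_untuned = 0,
                      baseline_hz = c(60, 100),
                      scales = 2 * c(P = 0.3, V = 0.5, A = 0.2, PVI = 0.1,
                                     T = 0.2, SH = 0), seed = 9),
    seed = 4)
  b <- fit_decoder(sim$session, "ukf2", mode = "offline",
                   smooth_accel_window = 1L)
  sub <- subset_session(sim$session, 301:900)
  dec <- decode_offline(sub, b)
  act <- as.matrix(as.data.frame(sub$kinematics)[, c("px", "py", "vx", "vy")])
  cc <- mean_scores(score_predictions(as.matrix(dec[, 2:5]), act))[["cc"]]
  expect_gt(cc, 0.99)

  # shuffling the spike counts in time destroys the reconstruction
  shuf <- sub
  set.seed(29)
  shuf$spikes$counts <- shuf$spikes$counts[, sample(ncol(shuf$spikes$counts))]
  dec0 <- decode_offline(shuf, b)
  cc0 <- mean(abs(score_predictions(as.matrix(dec0[, 2:5]), act)$cc),
              na.rm = TRUE)
  expect_lt(cc0, 3 / sqrt(nrow(act)) + 0.12)
})

test_that("position feedback makes decoded position a function of decoded velocity", {
  set.seed(30)
  sim <- sim_session(duration = 90, n_units = 10)
  b <- fit_decoder(sim$session, "fit_kf", mode = "closed_loop")
  lay <- b$layout
  sub <- subset_session(sim$session, 1:100)
  dec <- decode_offline(sub, b)
  # with zero positional process noise, position must integrate the decoded
  # velocity deterministically: p_t = p_{t-1} + dt * v_{t-1}
  dt <- b$dt
  pred_px <- dec$px[-nrow(dec)] + dt * dec$vx[-nrow(dec)]
  expect_equal(dec$px[-1], pred_px, tolerance = 1e-8)
})
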
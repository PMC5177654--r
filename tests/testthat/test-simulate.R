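# Synthetic-session generator.

test_that("task targets honour the task geometry and are seed-deterministic", {
  cfg <- task_config("center_out", duration = 120, seed = 5)
  tg <- gen_task_targets(cfg)
  per <- tg$trials[tg$trials$trial_kind == "peripheral", ]
  d <- sqrt(per$target_x^2 + per$target_y^2)
  expect_true(all(d >= 8 & d <= 10))
  expect_true(all(tg$trials$trial_kind[c(TRUE, FALSE)] == "center"))
  expect_equal(nrow(tg$targets), 2400L)
  expect_equal(tg$targets$target_radius[1], 2.5)

  tg2 <- gen_task_targets(cfg)
  expect_identical(tg, tg2)

  lis <- gen_task_targets(task_config("lissajous", duration = 60))
  expect_equal(c(lis$targets$tx[1], lis$targets$ty[1]), c(0, 0))
  expect_null(lis$trials)
  expect_equal(lis$targets$target_radius[1], 3)

  p2p <- gen_task_targets(task_config("point_to_point", duration = 60, seed = 2))
  expect_true(all(abs(p2p$targets$tx) <= 10 + 1e-9))
  expect_lt(max(abs(diff(p2p$targets$tx))), 1)  # smoothed, no jumps
})

test_that("the hand servo holds at the target, descends to it, and caps speed", {
  pol <- hand_policy(noise_sd = 0)
  # target at the hand: stay put
  tg <- data.frame(tx = rep(0, 100), ty = rep(0, 100), target_radius = 2.5)
  kin <- gen_hand_kinematics(tg, pol, seed = 1)
  expect_lt(max(abs(kin$px)), 1e-9)

  # step target: distance decreases monotonically under zero noise
  tg2 <- data.frame(tx = rep(6, 100), ty = rep(-4, 100), target_radius = 2.5)
  kin2 <- gen_hand_kinematics(tg2, pol, seed = 1)
  d <- sqrt((kin2$px - 6)^2 + (kin2$py + 4)^2)
  expect_true(all(diff(d) <= 1e-9))
  expect_lt(d[30], 0.5)  # settles within ~1.5 s

  # speed cap respected even with large noise
  noisy <- hand_policy(noise_sd = 400, vmax = 40)
  kin3 <- gen_hand_kinematics(tg2, noisy, seed = 2)
  # velocities here are recomputed by central differences, allow tolerance
  expect_lt(max(sqrt(kin3$vx^2 + kin3$vy^2)), 41)
})

test_that("population sampling respects group scales, untuned fraction and stability", {
  cfg <- population_config(n_units = 20, scales = c(P = 0.2, V = 0.3, A = 0,
                                                    PVI = 0, T = 0.1, SH = 0.4),
                           fraction_untuned = 0, seed = 6)
  pop <- sample_population(cfg)
  expect_false(any(c("A", "PVI") %in% pop$spec$groups))
  expect_true(all(c("P", "V", "T", "SH") %in% pop$spec$groups))

  all_off <- population_config(n_units = 10, fraction_untuned = 1, seed = 6)
  pop2 <- sample_population(all_off)
  kin_cols <- pop2$features$group != "SH"
  expect_true(all(pop2$coef[, kin_cols] == 0))
  expect_false(all(pop2$coef[, !kin_cols] == 0))  # history survives

  sh <- pop$coef[, pop$features$group == "SH"]
  rho <- max(Mod(eigen(sh, only.values = TRUE)$values))
  expect_equal(rho, 0.5, tolerance = 1e-10)
  expect_error(population_config(sh_radius = 1.2), "stable")
})

test_that("count generation is exact for trivial models and seed-deterministic", {
  nb <- 60
  kin <- kinematics_frame(px = sin(1:nb / 5), py = cos(1:nb / 5))
  cfg <- population_config(n_units = 4, baseline_hz = c(16, 16),
                           scales = c(P = 0, V = 0, A = 0, PVI = 0,
                                      T = 0, SH = 0.2),
                           seed = 7)
  pop <- sample_population(cfg)
  pop$coef[] <- 0  # zero all coefficients incl. history
  blk <- gen_spike_counts(kin, pop, noise = "gaussian", noise_sd = 0, seed = 1)
  expect_true(all(blk$counts == round(16 * 0.05)))  # baseline counts only

  b1 <- gen_spike_counts(kin, pop, seed = 42)
  b2 <- gen_spike_counts(kin, pop, seed = 42)
  expect_identical(b1$counts, b2$counts)
  b3 <- gen_spike_counts(kin, pop, seed = 43)
  expect_false(identical(b1$counts, b3$counts))
})

test_that("untuned Poisson units fire at their baseline on average", {
  set.seed(36)
  nb <- 20000
  kin <- kinematics_frame(px = 4 * sin(1:nb / 20), py = 4 * cos(1:nb / 17))
  cfg <- population_config(n_units = 3, baseline_hz = c(10, 30),
                           fraction_untuned = 1,
                           scales = c(P = 0.2, V = 0.2, SH = 0),
                           noise = "poisson", seed = 8)
  pop <- sample_population(cfg)
  blk <- gen_spike_counts(kin, pop, noise = "poisson", seed = 3)
  for (i in 1:3) {
    base <- pop$unit_means[i]
    se <- sqrt(base / nb)
    expect_lt(abs(mean(blk$counts[i, ]) - base), 3 * se)
  }
})

test_that("generated sessions are schema-valid and self-consistent", {
  sim <- sim_session(duration = 60, n_units = 8, seed = 11)
  s <- sim$session
  expect_s3_class(s, "binned_session")
  expect_equal(ncol(s$spikes$counts), n_bins(s))
  # derivatives agree with the package's differencing scheme
  d <- differentiate(s$kinematics$px, session_dt(s))
  expect_equal(s$kinematics$vx, d$velocity)
  expect_equal(s$kinematics$ax, d$acceleration)
  # determinism end to end
  sim2 <- sim_session(duration = 60, n_units = 8, seed = 11)
  expect_identical(sim2$session$spikes$counts, s$spikes$counts)
  expect_identical(sim2$session$kinematics$px, s$kinematics$px)
})

test_that("trial scoring finds held acquisitions and their onset", {
  nb <- 60
  px <- c(rep(10, 20), rep(0.5, 40))  # enters the target at bin 21
  kin <- kinematics_frame(px = px, py = rep(0, nb), tx = 0, ty = 0,
                          target_radius = 2.5)
  tr <- trial_table("center", 1L, 60L, FALSE, 0, 0, hold_required = 0.5)
  scored <- score_trials(kin, tr, dt = 0.05)
  expect_true(scored$success)
  expect_equal(scored$acquire_bin, 21L)

  tr2 <- trial_table("center", 1L, 25L, FALSE, 0, 0, hold_required = 0.5)
  expect_false(score_trials(kin, tr2, dt = 0.05)$success)  # hold incomplete
})

test_that("closed-loop harness bounds: ideal and inert decoder stubs", {
  sim <- sim_session(duration = 60, n_units = 6, seed = 13)
  task <- task_config("center_out")
  # inert decoder: cursor never leaves the center, zero peripheral successes
  r0 <- simulate_closed_loop(function(cur, int) cur, sim$model, task,
                             n_trials = 8, timeout = 4, seed = 3)
  per <- r0$trials$trial_kind == "peripheral"
  expect_equal(sum(r0$trials$success[per]), 0L)
  expect_true(all(r0$trials$success[!per]))  # center is trivially held

  # ideal decoder (applies the intended velocity): matches hand-level control
  rp <- simulate_closed_loop(function(cur, int) cur + 0.05 * int$v,
                             sim$model, task, n_trials = 16, timeout = 6,
                             seed = 3)
  expect_gt(mean(rp$trials$success), 0.9)
  expect_identical(
    simulate_closed_loop(function(cur, int) cur + 0.05 * int$v,
                         sim$model, task, n_trials = 16, timeout = 6,
                         seed = 3)$trials,
    rp$trials)
})
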
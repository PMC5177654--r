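# Synthetic-session generator. Emulates a 2D cursor workspace (~+/-10 cm,
# 50 ms bins): task target trajectories (center-out, Lissajous pursuit,
# smoothed point-to-point pursuit), a second-order servo standing in for the
# hand-control policy, a generative neural population driven by the
# multi-tap encoding equations plus spiking history, and a closed-loop
# simulated user operating a fitted decoder.

#' Task configuration
#'
#' @param task `"center_out"`, `"lissajous"` or `"point_to_point"`.
#' @param target_diameter Target diameter (cm); defaults to 5 for center-out
#'   and 6 for the pursuit tasks.
#' @param reach_distance Range (cm) of center-to-peripheral distances,
#'   default `c(8, 10)`.
#' @param hold Required hold inside the target (s), default 0.5.
#' @param duration Session duration (s).
#' @param dt Bin width (s).
#' @param trial_period Planned length (s) of each center-out trial during
#'   hand-control generation (reach + hold + slack).
#' @param lissajous Constants `a, b, A, B, omega` of
#'   `x = A sin(a w t), y = B sin(b w t)`.
#' @param waypoint_interval Seconds between point-to-point waypoints.
#' @param workspace Half-width (cm) of the region waypoints are drawn from.
#' @param seed Base seed for the task's random stream.
#' @export
task_config <- function(task = c("center_out", "lissajous", "point_to_point"),
                        target_diameter = NULL, reach_distance = c(8, 10),
                        hold = 0.5, duration = 600, dt = .BIN_WIDTH_DEFAULT,
                        trial_period = 2.5,
                        lissajous = list(a = 3, b = 4, A = 8, B = 8, omega = 0.25),
                        waypoint_interval = 3, workspace = 10, seed = 1L) {
  task <- match.arg(task)
  if (is.null(target_diameter)) {
    target_diameter <- if (task == "center_out") 5 else 6
  }
  if (target_diameter <= 0) stop("target_diameter must be positive")
  if (any(reach_distance > 1.5 * workspace)) stop("reach_distance outside workspace")
  structure(list(task = task, target_diameter = target_diameter,
                 reach_distance = reach_distance, hold = hold,
                 duration = duration, dt = dt, trial_period = trial_period,
                 lissajous = lissajous, waypoint_interval = waypoint_interval,
                 workspace = workspace, seed = as.integer(seed)),
            class = "task_config")
}

#' Generate target series and trial schedule for a task
#'
#' Center-out: targets alternate between the screen center and peripheral
#' locations at a uniformly random angle and uniform distance in
#' `reach_distance`, each shown for `trial_period` seconds. Pursuit tasks
#' emit a continuously moving target and no trial schedule.
#'
#' @param config A [task_config()].
#' @return List with `targets` (data frame `tx, ty, target_radius`, one row
#'   per bin) and `trials` (a [trial_table()] with `success = NA`-like
#'   placeholder `FALSE`, or `NULL` for pursuit).
#' @export
gen_task_targets <- function(config) {
  nb <- round(config$duration / config$dt)
  radius <- config$target_diameter / 2
  set.seed(substream_seed(config$seed, "task"))
  if (config$task == "center_out") {
    trial_bins <- round(config$trial_period / config$dt)
    n_trials <- ceiling(nb / trial_bins)
    kind <- rep(c("center", "peripheral"), length.out = n_trials)
    ang <- runif(n_trials, 0, 2 * pi)
    dist <- runif(n_trials, config$reach_distance[1], config$reach_distance[2])
    gx <- ifelse(kind == "center", 0, dist * cos(ang))
    gy <- ifelse(kind == "center", 0, dist * sin(ang))
    idx <- rep(seq_len(n_trials), each = trial_bins)[seq_len(nb)]
    onset <- (seq_len(n_trials) - 1L) * trial_bins + 1L
    end <- pmin(onset + trial_bins - 1L, nb)
    keep <- onset < end
    trials <- trial_table(kind[keep], onset[keep], end[keep], FALSE,
                          gx[keep], gy[keep], hold_required = config$hold)
    targets <- data.frame(tx = gx[idx], ty = gy[idx], target_radius = radius)
  } else if (config$task == "lissajous") {
    lc <- config$lissajous
    tt <- (seq_len(nb) - 1) * config$dt
    targets <- data.frame(tx = lc$A * sin(lc$a * lc$omega * tt),
                          ty = lc$B * sin(lc$b * lc$omega * tt),
                          target_radius = radius)
    trials <- NULL
  } else {
    wp_bins <- round(config$waypoint_interval / config$dt)
    n_wp <- ceiling(nb / wp_bins) + 1L
    wx <- runif(n_wp, -config$workspace, config$workspace)
    wy <- runif(n_wp, -config$workspace, config$workspace)
    b <- seq_len(nb)
    seg <- (b - 1L) %/% wp_bins + 1L
    frac <- ((b - 1L) %% wp_bins) / wp_bins
    tx <- wx[seg] + frac * (wx[seg + 1L] - wx[seg])
    ty <- wy[seg] + frac * (wy[seg + 1L] - wy[seg])
    w <- min(21L, 2L * (nb %/% 2L) - 1L)
    targets <- data.frame(tx = smooth_kinematics(tx, w),
                          ty = smooth_kinematics(ty, w),
                          target_radius = radius)
    trials <- NULL
  }
  list(targets = targets, trials = trials)
}

#' Hand-control servo policy
#'
#' A second-order servo standing in for the subject: intended acceleration
#' is proportional to the cursor-target error minus a damping term, with an
#' acceleration cap, a speed cap, and additive motor noise. The default
#' gains are near critical damping and settle a reach in about one second.
#'
#' @param kp Position gain (1/s^2), default 20.
#' @param kd Damping gain (1/s), default 9.
#' @param vmax Speed cap (cm/s).
#' @param amax Acceleration cap (cm/s^2).
#' @param noise_sd SD of the motor noise added to acceleration (cm/s^2).
#' @export
hand_policy <- function(kp = 20, kd = 9, vmax = 40, amax = 300, noise_sd = 15) {
  structure(list(kp = kp, kd = kd, vmax = vmax, amax = amax,
                 noise_sd = noise_sd), class = "hand_policy")
}

servo_accel <- function(policy, p, v, g, noise = c(0, 0)) {
  a <- policy$kp * (g - p) - policy$kd * v + noise
  na <- sqrt(sum(a^2))
  if (na > policy$amax) a <- a * policy$amax / na
  a
}

servo_advance <- function(policy, p, v, a, dt) {
  v <- v + a * dt
  nv <- sqrt(sum(v^2))
  if (nv > policy$vmax) v <- v * policy$vmax / nv
  list(p = p + v * dt, v = v)
}

#' Generate hand-control kinematics for a target series
#'
#' @param targets Data frame `tx, ty, target_radius` from
#'   [gen_task_targets()].
#' @param policy A [hand_policy()].
#' @param dt Bin width (s).
#' @param seed Seed for the motor-noise stream.
#' @return A [kinematics_frame()]; velocity and acceleration are derived
#'   from the simulated positions with [differentiate()], so generated
#'   sessions are self-consistent under the package's difference scheme.
#' @export
gen_hand_kinematics <- function(targets, policy = hand_policy(),
                                dt = .BIN_WIDTH_DEFAULT, seed = 1L) {
  nb <- nrow(targets)
  set.seed(substream_seed(seed, "hand"))
  noise <- matrix(rnorm(2L * nb, 0, policy$noise_sd), nb, 2)
  p <- c(0, 0); v <- c(0, 0)
  px <- numeric(nb); py <- numeric(nb)
  for (t in seq_len(nb)) {
    g <- c(targets$tx[t], targets$ty[t])
    a <- servo_accel(policy, p, v, g, noise[t, ])
    st <- servo_advance(policy, p, v, a, dt)
    p <- st$p; v <- st$v
    px[t] <- p[1]; py[t] <- p[2]
  }
  kinematics_frame(px, py, tx = targets$tx, ty = targets$ty,
                   target_radius = targets$target_radius, dt = dt)
}

#' Generative neural population configuration
#'
#' Group scales are the target standard deviation (counts/bin) of each
#' feature group's total contribution to a tuned unit's rate; a scale of 0
#' removes the group. Baselines are uniform in `baseline_hz` and converted
#' to counts/bin.
#'
#' @param n_units Number of units.
#' @param units_per_channel Units recorded per electrode channel (for the
#'   unit-to-channel map).
#' @param baseline_hz Range of baseline firing rates (Hz).
#' @param scales Named group contribution scales (counts/bin), entries of
#'   `c(P=, V=, A=, PVI=, T=, SH=)`.
#' @param tap_offsets Kinematic taps of the generative model.
#' @param noise `"gaussian"`: counts are `max(0, round(rate + N(0, sd)))`;
#'   `"poisson"`: `Poisson(max(rate, 0))`.
#' @param noise_sd SD of the Gaussian rate noise (counts/bin).
#' @param fraction_untuned Fraction of units with zero kinematic tuning.
#' @param sh_radius Spectral radius the spiking-history coupling matrix is
#'   scaled to; must be < 1 for a stable population.
#' @param seed Seed of the population's random stream.
#' @export
population_config <- function(n_units = 50L, units_per_channel = 2L,
                              baseline_hz = c(5, 25),
                              scales = c(P = 0.15, V = 0.25, A = 0.12,
                                         PVI = 0.08, T = 0.12, SH = 0.3),
                              tap_offsets = 2:-2,
                              noise = c("gaussian", "poisson"),
                              noise_sd = 0.3, fraction_untuned = 0.1,
                              sh_radius = 0.5, seed = 1L) {
  if (n_units < 1L) stop("n_units must be >= 1")
  if (sh_radius >= 1) stop("sh_radius must be < 1 for a stable population")
  full <- c(P = 0, V = 0, A = 0, PVI = 0, T = 0, SH = 0)
  full[names(scales)] <- scales
  structure(list(n_units = as.integer(n_units),
                 units_per_channel = as.integer(units_per_channel),
                 baseline_hz = baseline_hz, scales = full,
                 tap_offsets = as.integer(tap_offsets),
                 noise = match.arg(noise), noise_sd = noise_sd,
                 fraction_untuned = fraction_untuned,
                 sh_radius = sh_radius, seed = as.integer(seed)),
            class = "population_config")
}

# Typical per-feature magnitudes (SD) in a center-out session; used to turn
# group contribution scales into per-coefficient SDs.
.REF_FEATURE_SD <- c(px = 4, py = 4, mag_p = 2, vx = 8, vy = 8, mag_v = 5,
                     ax = 35, ay = 35, mag_a = 20, pvi_x = 35, pvi_y = 35,
                     tx = 5, ty = 5, dist_tc = 4, sh = 0.7)

#' Draw a ground-truth encoding model for a synthetic population
#'
#' @param config A [population_config()].
#' @return An `encoding_model` (subclass `population_model`) in raw feature
#'   space (identity centres/scales) whose `unit_means` are the baselines.
#'   The spiking-history block is rescaled to the configured spectral
#'   radius; its stability is verified by eigendecomposition.
#' @export
sample_population <- function(config) {
  set.seed(substream_seed(config$seed, "population"))
  n <- config$n_units
  groups <- names(config$scales)[config$scales > 0]
  if (length(groups) == 0L) stop("at least one group scale must be positive")
  spec <- feature_spec(groups, config$tap_offsets,
                       history_scope = "population",
                       label = "generative population")
  ft <- feature_table(spec, n_units = if ("SH" %in% groups) n else 0L)
  p <- nrow(ft)
  coef <- matrix(0, n, p, dimnames = list(paste0("u", seq_len(n)), ft$name))
  kin_cols <- which(ft$group != "SH")
  for (j in kin_cols) {
    g <- ft$group[j]
    m_g <- sum(ft$group == g)
    sd_c <- config$scales[[g]] / (sqrt(m_g) * .REF_FEATURE_SD[[ft$var[j]]])
    coef[, j] <- rnorm(n, 0, sd_c)
  }
  untuned <- integer(0)
  if (config$fraction_untuned > 0) {
    untuned <- sample(n, round(config$fraction_untuned * n))
    coef[untuned, kin_cols] <- 0
  }
  if ("SH" %in% groups) {
    sh_cols <- which(ft$group == "SH")
    C <- matrix(rnorm(n * n, 0, config$scales[["SH"]] /
                        (sqrt(n) * .REF_FEATURE_SD[["sh"]])), n, n)
    rho <- max(Mod(eigen(C, only.values = TRUE)$values))
    if (rho > 0) C <- C * config$sh_radius / rho
    rho_final <- max(Mod(eigen(C, only.values = TRUE)$values))
    if (rho_final >= 1) stop("spiking-history coupling is unstable (spectral radius >= 1)")
    coef[, sh_cols] <- C
  }
  baselines <- runif(n, config$baseline_hz[1], config$baseline_hz[2]) * .BIN_WIDTH_DEFAULT
  structure(
    list(spec = spec, features = ft, coef = coef,
         centers = rep(0, p), scales = rep(1, p), kept = rep(TRUE, p),
         unit_means = baselines, lambda = 0, lambda_grid = 0,
         R = NULL, unit_ids = rownames(coef), n_rows = 0L,
         channel_of_unit = rep(seq_len(ceiling(n / config$units_per_channel)),
                               each = config$units_per_channel)[seq_len(n)],
         untuned_units = untuned, config = config),
    class = c("population_model", "encoding_model")
  )
}

# Kinematic rate contribution (bins x units) of a model, zero on masked rows.
model_kin_rates <- function(model, kin) {
  ft <- model$features
  kin_cols <- ft$group != "SH"
  kd <- kin_design(kin, model$spec)
  Xs <- sweep(sweep(kd$X, 2, model$centers[kin_cols], "-"),
              2, model$scales[kin_cols], "/")
  rates <- Xs %*% t(model$coef[, kin_cols, drop = FALSE])
  rates[!kd$mask, ] <- 0
  rates
}

#' Generate spike counts from a ground-truth model
#'
#' Rates are the model's linear prediction over the kinematics plus, when the
#' model includes spiking history, the coupling applied to the previously
#' realised counts (generation is sequential in that case). Counts are
#' integer and non-negative under either noise model. Bins whose taps fall
#' outside the session emit baseline-only rates.
#'
#' @param kin A [kinematics_frame()].
#' @param model A [sample_population()] model (or any `encoding_model`).
#' @param noise,noise_sd Noise model, as in [population_config()].
#' @param seed Seed of the count noise stream.
#' @return A [spike_count_block()].
#' @export
gen_spike_counts <- function(kin, model, noise = c("gaussian", "poisson"),
                             noise_sd = 0.3, seed = 1L) {
  noise <- match.arg(noise)
  nb <- nrow(kin)
  n <- nrow(model$coef)
  set.seed(substream_seed(seed, "counts"))
  rates <- sweep(model_kin_rates(model, kin), 2, model$unit_means, "+")
  ft <- model$features
  sh_cols <- which(ft$group == "SH")
  draw <- function(r) {
    if (noise == "gaussian") pmax(0, round(r + rnorm(length(r), 0, noise_sd)))
    else rpois(length(r), pmax(r, 0))
  }
  if (length(sh_cols) == 0L) {
    counts <- t(apply(rates, 1, draw))
    if (n == 1L) counts <- matrix(counts, ncol = 1L)
    counts <- t(counts)
  } else {
    C <- model$coef[, sh_cols, drop = FALSE]
    counts <- matrix(0, n, nb)
    prev <- numeric(n)
    for (t in seq_len(nb)) {
      r <- rates[t, ] + as.vector(C %*% prev)
      prev <- draw(r)
      counts[, t] <- prev
    }
  }
  spike_count_block(counts, unit_ids = model$unit_ids,
                    channel_of_unit = model$channel_of_unit %||% seq_len(n),
                    bin_width = attr(kin, "dt"))
}

#' Score trials against a cursor trajectory
#'
#' A trial succeeds if the cursor stays inside the target for the required
#' hold duration before the trial ends; `acquire_bin` is the first bin of
#' that final successful hold.
#'
#' @param kin A `kinematics_frame` (or any data frame with `px, py`).
#' @param trials A [trial_table()].
#' @param dt Bin width (s).
#' @param target_radius Radius (cm) used where the kinematics carry none.
#' @return The trial table with `success` and `acquire_bin` filled in.
#' @export
score_trials <- function(kin, trials, dt = .BIN_WIDTH_DEFAULT,
                         target_radius = 2.5) {
  radius <- if (!is.null(kin$target_radius) && !anyNA(kin$target_radius)) {
    kin$target_radius
  } else rep(target_radius, nrow(kin))
  for (i in seq_len(nrow(trials))) {
    bins <- trials$onset_bin[i]:trials$end_bin[i]
    hold_bins <- max(1L, round(trials$hold_required[i] / dt))
    d <- sqrt((kin$px[bins] - trials$target_x[i])^2 +
              (kin$py[bins] - trials$target_y[i])^2)
    inside <- d <= radius[bins]
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= hold_bins)
    if (length(hit)) {
      start <- ends[hit[1]] - r$lengths[hit[1]] + 1L
      trials$success[i] <- TRUE
      trials$acquire_bin[i] <- bins[1] + start - 1L
    } else {
      trials$success[i] <- FALSE
      trials$acquire_bin[i] <- NA_integer_
    }
  }
  trials
}

#' Simulate a hand-control session
#'
#' Generates task targets, a servo-controlled hand trajectory, and spike
#' counts from a generative population, and scores any trial schedule.
#'
#' @param task A [task_config()].
#' @param population A [population_config()] or an already sampled
#'   [sample_population()] model.
#' @param policy A [hand_policy()].
#' @param seed Base seed; fanned out to task, hand, population and count
#'   noise streams.
#' @return List with `session` (a `binned_session`) and `model` (the ground
#'   truth population).
#' @export
simulate_hand_session <- function(task = task_config(),
                                  population = population_config(),
                                  policy = hand_policy(), seed = 1L) {
  task$seed <- substream_seed(seed, "task_base")
  tg <- gen_task_targets(task)
  kin <- gen_hand_kinematics(tg$targets, policy, task$dt,
                             seed = substream_seed(seed, "hand_base"))
  model <- if (inherits(population, "population_model")) population else {
    population$seed <- substream_seed(seed, "pop_base")
    sample_population(population)
  }
  cfg <- if (inherits(population, "population_model")) model$config else population
  spikes <- gen_spike_counts(kin, model, noise = cfg$noise,
                             noise_sd = cfg$noise_sd,
                             seed = substream_seed(seed, "counts_base"))
  trials <- tg$trials
  if (!is.null(trials)) trials <- score_trials(kin, trials, task$dt)
  session <- binned_session(kin, spikes, trials,
                            metadata = list(task = task$task, seed = seed,
                                            provenance = "ukfbmi simulator"))
  list(session = session, model = model)
}

#' Simulate closed-loop cursor control
#'
#' Runs an event-driven center-out session in which a servo user model
#' watches the decoded cursor, a generative population fires from the user's
#' intended kinematics, and the decoder moves the cursor. Position and
#' target features of the population are evaluated at the actual cursor and
#' target; velocity and acceleration features at the user's intended values;
#' future taps use a deterministic forward rollout of the servo (the user's
#' short-horizon movement plan).
#'
#' @param decoder A `decoder_bundle` fitted in `"closed_loop"` mode, or a
#'   function `(cursor, intended) -> new cursor position` for harness
#'   checks (e.g. an ideal or inert decoder stub).
#' @param model A [sample_population()] ground-truth model.
#' @param task A [task_config()] (center-out).
#' @param policy A [hand_policy()] for the simulated user.
#' @param n_trials Number of trials to run.
#' @param timeout Per-trial timeout (s).
#' @param seed Base seed.
#' @return List with `trials` (scored [trial_table()]), `cursor` (per-bin
#'   positions), `events` (per-bin movement-test diagnostics when a bundle
#'   decoder is used), and `counts`.
#' @export
simulate_closed_loop <- function(decoder, model, task = task_config("center_out"),
                                 policy = hand_policy(), n_trials = 60L,
                                 timeout = 8, seed = 1L) {
  dt <- task$dt
  hold_bins <- max(1L, round(task$hold / dt))
  timeout_bins <- round(timeout / dt)
  radius <- task$target_diameter / 2
  max_bins <- n_trials * timeout_bins + 10L
  n <- nrow(model$coef)
  ft <- model$features
  sh_cols <- which(ft$group == "SH")
  kin_cols <- which(ft$group != "SH")
  coef_kin <- model$coef[, kin_cols, drop = FALSE]
  offs <- model$spec$tap_offsets
  is_bundle <- inherits(decoder, "decoder_bundle")
  state <- if (is_bundle) closed_loop_init(decoder)
  rng_task <- substream_seed(seed, "cl_task")
  rng_noise <- substream_seed(seed, "cl_noise")
  rng_user <- substream_seed(seed, "cl_user")

  set.seed(rng_task)
  kinds <- rep(c("center", "peripheral"), length.out = n_trials)
  ang <- runif(n_trials, 0, 2 * pi)
  dist <- runif(n_trials, task$reach_distance[1], task$reach_distance[2])
  gx <- ifelse(kinds == "center", 0, dist * cos(ang))
  gy <- ifelse(kinds == "center", 0, dist * sin(ang))

  set.seed(rng_user)
  user_noise <- matrix(rnorm(2L * max_bins, 0, policy$noise_sd), max_bins, 2)
  set.seed(rng_noise)

  hist_vals <- matrix(0, max_bins, length(.KIN_VARS),
                      dimnames = list(NULL, .KIN_VARS))
  cursor <- c(0, 0)
  v_int <- c(0, 0)
  prev_counts <- numeric(n)
  counts_log <- matrix(0L, n, max_bins)
  cursor_log <- matrix(NA_real_, max_bins, 2)
  events <- data.frame(X = rep(NA_real_, max_bins), p_value = NA_real_,
                       move = NA)
  trial_rows <- list()
  trial <- 1L
  onset <- 1L
  inside_run <- 0L
  t <- 0L
  draw <- function(r) {
    if (model$config$noise == "gaussian") {
      pmax(0, round(r + rnorm(length(r), 0, model$config$noise_sd)))
    } else rpois(length(r), pmax(r, 0))
  }

  while (trial <= n_trials && t < max_bins) {
    t <- t + 1L
    g <- c(gx[trial], gy[trial])
    # user's intended command from cursor feedback
    a_int <- servo_accel(policy, cursor, v_int, g, user_noise[t, ])
    st <- servo_advance(policy, cursor, v_int, a_int, dt)
    v_int <- st$v
    hist_vals[t, ] <- c(cursor, v_int, a_int, g)
    # tap values: history for past taps, deterministic servo rollout for
    # future taps
    rollout <- NULL
    if (any(offs > 0)) {
      rollout <- matrix(0, max(offs), length(.KIN_VARS),
                        dimnames = list(NULL, .KIN_VARS))
      rp <- cursor; rv <- v_int
      for (k in seq_len(max(offs))) {
        ra <- servo_accel(policy, rp, rv, g)
        rs <- servo_advance(policy, rp, rv, ra, dt)
        rp <- rs$p; rv <- rs$v
        rollout[k, ] <- c(rp, rv, ra, g)
      }
    }
    vals <- do.call(rbind, lapply(offs, function(o) {
      if (o > 0) rollout[o, ] else hist_vals[max(t + o, 1L), ]
    }))
    colnames(vals) <- .KIN_VARS
    feat <- unlist(lapply(seq_along(offs), function(j) {
      as.vector(tap_feature_block(vals[j, , drop = FALSE], model$spec))
    }), use.names = FALSE)
    rate <- model$unit_means + as.vector(coef_kin %*% feat)
    if (length(sh_cols)) {
      rate <- rate + as.vector(model$coef[, sh_cols, drop = FALSE] %*% prev_counts)
    }
    counts <- draw(rate)
    counts_log[, t] <- counts
    # decode
    if (is_bundle) {
      state <- closed_loop_step(state, counts, prev_counts)
      cursor <- state$cursor$x
      events$X[t] <- state$events$X
      events$p_value[t] <- state$events$p_value
      events$move[t] <- state$events$move
    } else {
      cursor <- decoder(cursor, list(v = v_int, a = a_int, g = g))
    }
    cursor_log[t, ] <- cursor
    prev_counts <- counts
    # trial logic
    if (sqrt(sum((cursor - g)^2)) <= radius) {
      inside_run <- inside_run + 1L
    } else {
      inside_run <- 0L
    }
    finish <- function(success) {
      trial_rows[[trial]] <<- data.frame(
        trial_kind = kinds[trial], onset_bin = onset, end_bin = t,
        success = success, target_x = g[1], target_y = g[2],
        hold_required = task$hold,
        acquire_bin = if (success) t - hold_bins + 1L else NA_integer_)
      trial <<- trial + 1L
      onset <<- t + 1L
      inside_run <<- 0L
    }
    if (inside_run >= hold_bins) {
      finish(TRUE)
    } else if (t - onset + 1L >= timeout_bins) {
      finish(FALSE)
    }
  }
  trials <- do.call(rbind, trial_rows)
  trials <- trial_table(trials$trial_kind, trials$onset_bin, trials$end_bin,
                        trials$success, trials$target_x, trials$target_y,
                        trials$hold_required, trials$acquire_bin)
  list(trials = trials, cursor = cursor_log[seq_len(t), , drop = FALSE],
       counts = counts_log[, seq_len(t), drop = FALSE],
       events = events[seq_len(t), ])
}
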
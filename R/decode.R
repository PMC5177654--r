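# Decoder bundles: a state layout, a fitted encoding (observation) model,
# a transition model, and control settings, plus offline decoding.

#' Fit a complete decoder on a training session
#'
#' @param train A `binned_session` (training portion).
#' @param variant Decoder family: `"kf"` (position-velocity Kalman filter),
#'   `"fit_kf"` (adds position-as-feedback and intention estimation),
#'   `"ukf1"` (10-tap unscented filter, position/velocity with magnitudes),
#'   `"ukf2"` (5-tap unscented filter with acceleration, interaction,
#'   target and population spiking-history features).
#' @param mode `"offline"`: transition fitted to the training kinematics,
#'   zero-offset read-out, no mixing or thresholding. `"closed_loop"`:
#'   physics-based transition with noise fitted to training residuals;
#'   the control refinements apply in [closed_loop_step()].
#' @param smooth_accel_window Odd moving-average window (bins) applied to the
#'   acceleration series before fitting acceleration-bearing models
#'   (default 5 bins = 250 ms); 1 disables smoothing.
#' @param lambda_grid Optional ridge grid for the encoding fit.
#' @param control A [control_config()] (used in closed-loop mode).
#' @param c_v,c_a,c_g Physics-transition constants (closed-loop mode).
#' @return A `decoder_bundle`.
#' @export
fit_decoder <- function(train, variant = c("kf", "fit_kf", "ukf1", "ukf2"),
                        mode = c("offline", "closed_loop"),
                        smooth_accel_window = 5L, lambda_grid = NULL,
                        control = control_config(),
                        c_v = 0.85, c_a = 0.75, c_g = 0.01) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  layout <- make_layout(variant)
  spec <- encoding_preset(switch(variant, kf = "kf", fit_kf = "kf",
                                 ukf1 = "ukf1", ukf2 = "ukf2"))
  dt <- session_dt(train)

  kin_fit <- train$kinematics
  if ("A" %in% spec$groups && smooth_accel_window > 1L) {
    kin_fit$ax <- smooth_kinematics(kin_fit$ax, smooth_accel_window)
    kin_fit$ay <- smooth_kinematics(kin_fit$ay, smooth_accel_window)
  }
  if (variant == "fit_kf") kin_fit <- apply_intention_estimation(kin_fit)
  train_fit <- train
  train_fit$kinematics <- kin_fit

  dm <- build_design_matrix(train_fit, spec)
  encoding <- suppressWarnings(
    fit_encoding(dm, train$spikes, lambda_grid = lambda_grid))

  trans <- if (mode == "offline") {
    fit_transition_offline(layout, train$kinematics, lambda_grid = lambda_grid)
  } else {
    fit_noise_covariance(
      build_physics_transition(layout, c_v = c_v, c_a = c_a, c_g = c_g,
                               dt = dt), train$kinematics)
  }

  last <- as.data.frame(train$kinematics)[n_bins(train), ]
  m0 <- numeric(layout$dim)
  for (off in layout$offsets) {
    m0[state_index(layout, layout$vars, off)] <-
      as.numeric(last[layout$vars])
  }
  init <- gaussian_belief(m0, 10 * trans$Q + diag(1e-9, layout$dim))

  structure(
    list(variant = variant, mode = mode, layout = layout,
         encoding = encoding, transition = trans, control = control,
         init_belief = init,
         last_train_counts = train$spikes$counts[, n_bins(train)],
         smooth_accel_window = smooth_accel_window, dt = dt),
    class = "decoder_bundle"
  )
}

#' @export
print.decoder_bundle <- function(x, ...) {
  cat(sprintf("<decoder_bundle> %s (%s): state dim %d, %d units\n",
              x$variant, x$mode, x$layout$dim, nrow(x$encoding$coef)))
  invisible(x)
}

# Build the filter observation model for one bin. prev_counts enters the
# predicted rates as a deterministic offset (spiking history is data, not
# state). Returns either a linear model (H, b, R) when every feature is
# linear in the state, or a sigma-point observation function.
bundle_observation <- function(bundle, prev_counts = NULL) {
  model <- bundle$encoding
  layout <- bundle$layout
  ft <- model$features
  is_sh <- ft$group == "SH"
  kin <- which(!is_sh)
  coef_kin <- model$coef[, kin, drop = FALSE]
  cen_kin <- model$centers[kin]
  sc_kin <- model$scales[kin]
  offset <- model$unit_means
  if (any(is_sh)) {
    if (is.null(prev_counts)) stop("spiking-history model needs previous-bin counts")
    sh <- which(is_sh)
    z <- (prev_counts - model$centers[sh]) / model$scales[sh]
    offset <- offset + as.vector(model$coef[, sh, drop = FALSE] %*% z)
  }
  if (all(ft$type[kin] == "linear")) {
    d <- layout$dim
    H <- matrix(0, nrow(model$coef), d)
    for (j in seq_along(kin)) {
      si <- state_index(layout, ft$var[kin[j]], ft$tap[kin[j]])
      H[, si] <- H[, si] + coef_kin[, j] / sc_kin[j]
    }
    b <- offset - as.vector(coef_kin %*% (cen_kin / sc_kin))
    return(list(type = "linear", H = H, b = b, R = model$R))
  }
  fn <- function(S) {
    Xk <- design_from_state(S, layout, model$spec)
    Xs <- sweep(sweep(Xk, 2, cen_kin, "-"), 2, sc_kin, "/")
    sweep(Xs %*% t(coef_kin), 2, offset, "+")
  }
  list(type = "nonlinear", fn = fn, R = model$R)
}

# One filter iteration of a bundle: predict with the given transition and
# update with this bin's counts. Dispatches to the linear or sigma-point
# update depending on the observation model.
bundle_filter_step <- function(bundle, belief, counts, prev_counts,
                               trans = bundle$transition) {
  obs <- bundle_observation(bundle, prev_counts)
  if (obs$type == "linear") {
    kf_step(belief, trans, obs, counts)
  } else {
    ukf_step(belief, trans, obs, counts)
  }
}

#' Reconstruct kinematics offline
#'
#' Runs the fitted filter over the session's bins and reads the decoded
#' kinematics from the zero-offset tap. No output mixing and no movement
#' threshold are applied (those are closed-loop refinements); decoded target
#' variables, where present, do not alter the position/velocity read-out.
#'
#' @param session A `binned_session` (typically the testing portion).
#' @param bundle A `decoder_bundle` fitted in `"offline"` mode.
#' @param bins Bins to decode (default all).
#' @return Data frame with `bin`, decoded `px, py, vx, vy`.
#' @export
decode_offline <- function(session, bundle, bins = NULL) {
  if (is.null(bins)) bins <- seq_len(n_bins(session))
  counts <- session$spikes$counts
  belief <- bundle$init_belief
  out <- matrix(NA_real_, length(bins), 4,
                dimnames = list(NULL, c("px", "py", "vx", "vy")))
  read_idx <- state_index(bundle$layout, c("px", "py", "vx", "vy"), 0L)
  for (k in seq_along(bins)) {
    t <- bins[k]
    prev <- if (t > 1L) counts[, t - 1L] else bundle$last_train_counts
    belief <- bundle_filter_step(bundle, belief, counts[, t], prev)
    if (!all(is.finite(belief$mean))) {
      stop(sprintf("filter diverged (non-finite state) at bin %d", t))
    }
    out[k, ] <- belief$mean[read_idx]
  }
  data.frame(bin = bins, out)
}
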
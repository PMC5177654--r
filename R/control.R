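# Closed-loop control refinements applied to the filter output:
#  * the cursor is driven from a future tap (t+2, i.e. +100 ms at 50 ms bins);
#  * a chi-squared test on the decoded velocity belief decides whether the
#    user intends to move (probabilistic movement threshold);
#  * decoded position and velocity are mixed into the on-screen cursor, with
#    the decoded speed gating how much the position decode can move it.

#' Closed-loop control configuration
#'
#' @param c_m Mixing coefficient between velocity and position control of
#'   the cursor, in `[0, 1]`; 0.5 by default.
#' @param alpha Significance level of the movement threshold (working value
#'   0.3; 0.1-0.5 in practice).
#' @param future_offset Tap offset used to drive the cursor (2 taps =
#'   100 ms at 50 ms bins).
#' @param dt Bin width (s).
#' @param workspace_limit Half-width of the screen workspace (cm); the
#'   cursor is clamped to `[-limit, limit]` on each axis.
#' @export
control_config <- function(c_m = 0.5, alpha = 0.3, future_offset = 2L,
                           dt = .BIN_WIDTH_DEFAULT, workspace_limit = 12) {
  if (c_m < 0 || c_m > 1) stop("c_m must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(c_m = c_m, alpha = alpha,
                 future_offset = as.integer(future_offset),
                 dt = dt, workspace_limit = workspace_limit),
            class = "control_config")
}

#' Extract position, velocity and velocity covariance at a tap
#'
#' @param belief A [gaussian_belief()].
#' @param layout The filter's `state_layout`.
#' @param offset Tap offset to read (must be present in the layout).
#' @return List with `p` (position, cm), `v` (velocity, cm/s) and `C_v`
#'   (2 x 2 velocity covariance sub-block).
#' @export
select_output_tap <- function(belief, layout, offset = 0L) {
  ip <- state_index(layout, c("px", "py"), offset)
  iv <- state_index(layout, c("vx", "vy"), offset)
  list(p = belief$mean[ip], v = belief$mean[iv],
       C_v = belief$cov[iv, iv, drop = FALSE])
}

#' Movement statistic for a batch of velocity beliefs
#'
#' @param V n x 2 matrix of decoded velocity means.
#' @param C_v Common 2 x 2 velocity covariance.
#' @return Numeric vector of `X = v' C_v^{-1} v` values.
#' @export
movement_statistic <- function(V, C_v) {
  V <- matrix(V, ncol = 2)
  rowSums((V %*% solve(C_v)) * V)
}

#' Probabilistic movement threshold
#'
#' Under the null hypothesis that the user wants to remain still, the decoded
#' velocity mean is zero and `X = v' C_v^{-1} v` follows a chi-squared
#' distribution with 2 degrees of freedom. The null is rejected (the cursor
#' is allowed to move) when the survival probability of `X` falls below
#' `alpha`, so `alpha` is the false-positive movement rate.
#'
#' @param v Decoded velocity mean (length 2).
#' @param C_v 2 x 2 velocity covariance (symmetric positive definite).
#' @param alpha Significance level.
#' @return List with `X`, `p_value`, and logical `move`.
#' @export
movement_test <- function(v, C_v, alpha = 0.3) {
  if (inherits(try(chol(C_v), silent = TRUE), "try-error")) {
    stop("velocity covariance is not positive definite")
  }
  X <- as.numeric(movement_statistic(matrix(v, ncol = 2), C_v))
  p <- pchisq(X, df = 2, lower.tail = FALSE)
  list(X = X, p_value = p, move = p < alpha)
}

#' On-screen cursor state
#'
#' @param x Cursor position (cm, length 2).
#' @param hold_mode Whether the previous movement test retained the null, so
#'   the next transition should not integrate velocity into position.
#' @export
cursor_state <- function(x = c(0, 0), hold_mode = FALSE) {
  structure(list(x = as.numeric(x), hold_mode = isTRUE(hold_mode)),
            class = "cursor_state")
}

#' Mix decoded position and velocity into the cursor position
#'
#' The update is
#' `x_t = x_{t-1} + c_m dt v + (1 - c_m) dt (|v| / |e|) e`, with
#' `e = p - x_{t-1}`: the velocity term moves the cursor directly, while the
#' position term moves it toward the decoded position by at most
#' `(1 - c_m) dt |v|` — the decoded speed gates the position decode, so a
#' zero decoded velocity leaves the cursor unchanged regardless of `p`.
#' When `|e| = 0` the position term is defined as zero (removable
#' singularity). The result is clamped to the workspace.
#'
#' @param cursor Previous [cursor_state()].
#' @param p Decoded position (length 2).
#' @param v Decoded velocity (length 2).
#' @param config A [control_config()].
#' @return The new [cursor_state()].
#' @export
mix_outputs <- function(cursor, p, v, config) {
  e <- p - cursor$x
  ne <- sqrt(sum(e^2))
  nv <- sqrt(sum(v^2))
  pos_term <- if (ne > 0) (1 - config$c_m) * config$dt * (nv / ne) * e else c(0, 0)
  x <- cursor$x + config$c_m * config$dt * v + pos_term
  lim <- config$workspace_limit
  clamped <- pmin(pmax(x, -lim), lim)
  if (any(clamped != x)) {
    message(sprintf("cursor clamped to workspace at (%.1f, %.1f)", x[1], x[2]))
  }
  cursor_state(clamped, hold_mode = FALSE)
}

#' Initialise a closed-loop decoder state
#'
#' @param bundle A `decoder_bundle` fitted in `"closed_loop"` mode.
#' @param cursor Initial [cursor_state()].
#' @return A `closed_loop_state` carrying the belief, cursor, and the normal
#'   and hold-mode transitions.
#' @export
closed_loop_init <- function(bundle, cursor = cursor_state()) {
  structure(
    list(bundle = bundle, belief = bundle$init_belief, cursor = cursor,
         trans = bundle$transition, trans_hold = hold_transition(bundle$transition)),
    class = "closed_loop_state"
  )
}

#' One closed-loop decoding iteration
#'
#' Runs the filter step (using the hold-mode transition if the previous
#' movement test retained the null), reads the future tap, applies the
#' movement test, and moves the cursor through [mix_outputs()] only if
#' movement intent is detected. The velocity state is never zeroed: when the
#' cursor is held, the decoded velocity keeps integrating evidence and can
#' grow across blocked iterations until it exceeds the threshold. The filter
#' update itself always runs; only the cursor and the position integration
#' are held.
#'
#' @param state A `closed_loop_state`.
#' @param counts This bin's spike counts.
#' @param prev_counts Previous bin's counts (for spiking-history models).
#' @return The updated state; `state$events` holds the per-step diagnostics
#'   (`X`, `p_value`, `move`).
#' @export
closed_loop_step <- function(state, counts, prev_counts = NULL) {
  bundle <- state$bundle
  config <- bundle$control
  trans <- if (state$cursor$hold_mode) state$trans_hold else state$trans
  belief <- bundle_filter_step(bundle, state$belief, counts, prev_counts, trans)
  if (!all(is.finite(belief$mean))) stop("closed-loop filter diverged (non-finite state)")
  tap <- select_output_tap(belief, bundle$layout, config$future_offset)
  mt <- movement_test(tap$v, tap$C_v, config$alpha)
  cursor <- if (mt$move) {
    mix_outputs(state$cursor, tap$p, tap$v, config)
  } else {
    cursor_state(state$cursor$x, hold_mode = TRUE)
  }
  state$belief <- belief
  state$cursor <- cursor
  state$events <- list(X = mt$X, p_value = mt$p_value, move = mt$move,
                       v = tap$v, p = tap$p)
  state
}
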
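# State transition models. Closed-loop decoding uses transition maps built
# from physical laws of motion (integrator position, velocity with friction,
# decaying acceleration attracted toward the decoded target); offline
# reconstruction fits a first-order map from one tap of kinematics to the
# next. In multi-tap layouts only the leading (most future) tap gets new
# values; all other taps shift: the value at tap k becomes, one step later,
# the value at tap k-1, without change.

new_transition <- function(F, b, Q, layout, params, position_feedback, kind) {
  structure(list(F = F, b = b, Q = Q, layout = layout, params = params,
                 position_feedback = position_feedback, kind = kind),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %s for %s (dim %d)%s%s\n",
              x$kind, x$layout$variant, x$layout$dim,
              if (x$position_feedback) ", position-as-feedback" else "",
              if (is.null(x$Q)) ", Q unset" else ""))
  invisible(x)
}

# Fill the shift rows: new tap j takes the previous value of tap j-1 (one
# step closer to the future), for every non-leading tap.
fill_shift_rows <- function(F, layout) {
  if (length(layout$offsets) < 2L) return(F)
  for (j in 2:length(layout$offsets)) {
    dst <- state_index(layout, layout$vars, layout$offsets[j])
    src <- state_index(layout, layout$vars, layout$offsets[j - 1L])
    F[cbind(dst, src)] <- 1
  }
  F
}

#' Build a physics-based transition model
#'
#' Leading-tap dynamics: position integrates velocity; velocity decays with
#' friction coefficient `c_v` (and, for the acceleration-bearing layout,
#' integrates acceleration); acceleration decays with `c_a` and is attracted
#' toward the decoded target with gain `c_g`; the target is constant up to
#' noise. With `hold = TRUE` the leading-tap position is left unmodified
#' (the velocity term is dropped), the transition used on the iteration
#' after the movement threshold retains the null.
#'
#' @param layout A [make_layout()] result.
#' @param c_v Friction coefficient on velocity (default 0.85).
#' @param c_a Acceleration decay (default 0.75).
#' @param c_g Gain of the target's attraction on acceleration (default 0.01).
#' @param dt Bin width (s).
#' @param position_feedback Zero the positional process noise so position
#'   evolves deterministically from decoded velocity (FIT refinement).
#'   Default on for the `fit_kf` layout.
#' @param hold Build the hold-mode variant (see above).
#' @return A `transition_model` with `Q = NULL`; fit the noise covariance
#'   with [fit_noise_covariance()].
#' @export
build_physics_transition <- function(layout, c_v = 0.85, c_a = 0.75,
                                     c_g = 0.01, dt = .BIN_WIDTH_DEFAULT,
                                     position_feedback = layout$variant == "fit_kf",
                                     hold = FALSE) {
  d <- layout$dim
  F <- matrix(0, d, d, dimnames = list(layout$names, layout$names))
  lead <- layout$offsets[1]
  ix <- function(v) state_index(layout, v, lead)
  for (ax in c("x", "y")) {
    p <- ix(paste0("p", ax)); v <- ix(paste0("v", ax))
    F[p, p] <- 1
    if (!hold) F[p, v] <- dt
    F[v, v] <- c_v
    if (layout$variant == "ukf2") {
      a <- ix(paste0("a", ax)); g <- ix(paste0("t", ax))
      F[v, a] <- dt
      F[a, a] <- c_a
      F[a, g] <- c_g / dt^2
      F[a, p] <- -c_g / dt^2
      F[g, g] <- 1
    }
  }
  F <- fill_shift_rows(F, layout)
  new_transition(F, b = rep(0, d), Q = NULL, layout = layout,
                 params = list(c_v = c_v, c_a = c_a, c_g = c_g, dt = dt,
                               hold = hold),
                 position_feedback = position_feedback, kind = "physics")
}

# Hold-mode counterpart of a transition model: leading-tap position rows keep
# the previous leading position instead of integrating velocity.
hold_transition <- function(trans) {
  layout <- trans$layout
  if (trans$kind == "physics") {
    h <- build_physics_transition(layout, trans$params$c_v, trans$params$c_a,
                                  trans$params$c_g, trans$params$dt,
                                  trans$position_feedback, hold = TRUE)
    h$Q <- trans$Q
    return(h)
  }
  F <- trans$F
  b <- trans$b
  lead <- layout$offsets[1]
  for (v in intersect(c("px", "py"), layout$vars)) {
    i <- state_index(layout, v, lead)
    F[i, ] <- 0
    F[i, i] <- 1
    b[i] <- 0
  }
  out <- trans
  out$F <- F; out$b <- b
  out$params$hold <- TRUE
  out
}

#' Fit a transition model to training kinematics
#'
#' Regresses the next-step leading-tap variables on the current single tap of
#' kinematics (first order), using the same standardised ridge machinery and
#' shared-penalty selection as the encoding fit; other taps shift. When the
#' layout carries target variables they are fitted as a separate block: the
#' target is decoded but does not directly affect the other state variables.
#' The noise covariance is then fitted from one-step-ahead residuals.
#'
#' @param layout A `state_layout`.
#' @param kin A `kinematics_frame` (training portion).
#' @param lambda_grid Optional ridge grid.
#' @return A fitted `transition_model` with `Q` set.
#' @export
fit_transition_offline <- function(layout, kin, lambda_grid = NULL) {
  K <- as.matrix(as.data.frame(kin)[, layout$vars])
  if (anyNA(K)) stop("kinematics contain NA in layout variables")
  if (nrow(K) < 100L) stop("need at least 100 training bins")
  T_ <- nrow(K)
  nv <- length(layout$vars)
  A <- matrix(0, nv, nv, dimnames = list(layout$vars, layout$vars))
  b_lead <- numeric(nv)
  lambda <- NA_real_
  blocks <- if (any(c("tx", "ty") %in% layout$vars)) {
    list(setdiff(layout$vars, c("tx", "ty")), c("tx", "ty"))
  } else {
    list(layout$vars)
  }
  for (vars in blocks) {
    X <- K[-T_, vars, drop = FALSE]
    Y <- K[-1L, vars, drop = FALSE]
    fit <- suppressWarnings(fit_encoding(X, t(Y), lambda_grid = lambda_grid))
    Ab <- sweep(fit$coef, 2, fit$scales, "/")     # block, raw space
    A[vars, vars] <- Ab
    b_lead[match(vars, layout$vars)] <- fit$unit_means -
      as.vector(Ab %*% fit$centers)
    if (is.na(lambda)) lambda <- fit$lambda
  }
  d <- layout$dim
  F <- matrix(0, d, d, dimnames = list(layout$names, layout$names))
  b <- rep(0, d)
  lead_idx <- state_index(layout, layout$vars, layout$offsets[1])
  F[lead_idx, lead_idx] <- A
  b[lead_idx] <- b_lead
  F <- fill_shift_rows(F, layout)
  trans <- new_transition(F, b, Q = NULL, layout = layout,
                          params = list(dt = attr(kin, "dt"), lambda = lambda,
                                        hold = FALSE),
                          position_feedback = FALSE, kind = "fitted")
  fit_noise_covariance(trans, kin)
}

#' Fit the transition noise covariance from residuals
#'
#' Runs the model's deterministic part one step ahead along the state
#' trajectory implied by the training kinematics and takes the sample
#' covariance of the residuals. Shift rows have exactly zero residual by
#' construction. With position-as-feedback, positional variance and
#' covariance entries are set exactly to zero.
#'
#' @param trans A `transition_model`.
#' @param kin Training `kinematics_frame`.
#' @return The transition model with `Q` filled in.
#' @export
fit_noise_covariance <- function(trans, kin) {
  layout <- trans$layout
  S <- state_trajectory(layout, kin)
  T_ <- nrow(S)
  pred <- S[-T_, , drop = FALSE] %*% t(trans$F)
  pred <- sweep(pred, 2, trans$b, "+")
  resid <- S[-1L, , drop = FALSE] - pred
  Q <- cov(resid)
  if (trans$position_feedback) {
    pos <- position_indices(layout)
    Q[pos, ] <- 0
    Q[, pos] <- 0
  }
  trans$Q <- (Q + t(Q)) / 2
  trans
}

#' Re-label training velocities with intention estimates
#'
#' Rotates each velocity vector to aim at the current target while keeping
#' its speed, and zeroes the velocity while the cursor is inside the target;
#' positions (and accelerations) are unchanged. Used to fit the observation
#' model of the FIT-style Kalman filter.
#'
#' @param kin A `kinematics_frame` with target positions per bin.
#' @param default_radius Target radius (cm) used where `target_radius` is
#'   `NA`.
#' @return The modified `kinematics_frame`.
#' @export
apply_intention_estimation <- function(kin, default_radius = 2.5) {
  if (anyNA(kin$tx) || anyNA(kin$ty)) stop("intention estimation needs target positions for every bin")
  radius <- ifelse(is.na(kin$target_radius), default_radius, kin$target_radius)
  dx <- kin$tx - kin$px
  dy <- kin$ty - kin$py
  dist <- sqrt(dx^2 + dy^2)
  speed <- sqrt(kin$vx^2 + kin$vy^2)
  inside <- dist <= radius
  ux <- ifelse(dist > 0, dx / dist, 0)
  uy <- ifelse(dist > 0, dy / dist, 0)
  kin$vx <- ifelse(inside, 0, speed * ux)
  kin$vy <- ifelse(inside, 0, speed * uy)
  kin
}
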
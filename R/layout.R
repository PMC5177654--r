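# State layouts. The filter state stacks kinematic variables at several
# temporal taps (bin offsets relative to the currently processed bin),
# ordered future to past; within a tap, variables follow a fixed order.
#   kf / fit_kf : 1 tap  (0)      x (px,py,vx,vy)             = 4
#   ukf1        : 10 taps (+5..-4) x (px,py,vx,vy)            = 40
#   ukf2        : 5 taps (+2..-2) x (px,py,vx,vy,ax,ay,tx,ty) = 40

#' Create a state layout
#'
#' @param variant One of `"kf"`, `"fit_kf"`, `"ukf1"`, `"ukf2"`.
#' @return A `state_layout` with fields `variant`, `offsets` (future first),
#'   `vars`, `dim`, and `names`.
#' @export
make_layout <- function(variant = c("kf", "fit_kf", "ukf1", "ukf2")) {
  variant <- match.arg(variant)
  pv <- c("px", "py", "vx", "vy")
  cfg <- switch(variant,
    kf = list(offsets = 0L, vars = pv),
    fit_kf = list(offsets = 0L, vars = pv),
    ukf1 = list(offsets = 5:-4, vars = pv),
    ukf2 = list(offsets = 2:-2, vars = c(pv, "ax", "ay", "tx", "ty")))
  nms <- as.vector(vapply(cfg$offsets, function(o)
    sprintf("%s@%+d", cfg$vars, o), character(length(cfg$vars))))
  structure(
    list(variant = variant, offsets = cfg$offsets, vars = cfg$vars,
         dim = length(cfg$offsets) * length(cfg$vars), names = nms),
    class = "state_layout"
  )
}

#' @export
print.state_layout <- function(x, ...) {
  cat(sprintf("<state_layout> %s: %d taps (%s) x %d vars = %d\n",
              x$variant, length(x$offsets),
              paste(range(x$offsets), collapse = ".."),
              length(x$vars), x$dim))
  invisible(x)
}

#' Index of state variables in a layout
#'
#' @param layout A `state_layout`.
#' @param var Character vector of variable names (e.g. `"vx"`).
#' @param tap Tap offset (single integer).
#' @return Integer positions in the state vector.
#' @export
state_index <- function(layout, var, tap) {
  ti <- match(tap, layout$offsets)
  if (is.na(ti)) stop(sprintf("tap %+d not in layout %s", tap, layout$variant))
  vi <- match(var, layout$vars)
  if (anyNA(vi)) {
    stop("variable(s) not in layout: ", paste(var[is.na(vi)], collapse = ", "))
  }
  (ti - 1L) * length(layout$vars) + vi
}

# All position entries (every tap) of a layout's state vector.
position_indices <- function(layout) {
  unlist(lapply(layout$offsets, function(o)
    state_index(layout, intersect(c("px", "py"), layout$vars), o)))
}

# Build the state trajectory implied by a kinematics frame: row t holds, for
# each tap offset k, the kinematics at bin t + k. Only rows where all taps
# are in range are returned (attribute "bins" records which).
state_trajectory <- function(layout, kin) {
  K <- as.matrix(as.data.frame(kin)[, .KIN_VARS])
  nb <- nrow(K)
  lo <- min(layout$offsets); hi <- max(layout$offsets)
  bins <- seq.int(max(1L, 1L - lo), min(nb, nb - hi))
  S <- matrix(NA_real_, length(bins), layout$dim,
              dimnames = list(NULL, layout$names))
  for (off in layout$offsets) {
    S[, state_index(layout, layout$vars, off)] <- K[bins + off, layout$vars]
  }
  if (anyNA(S)) stop("kinematics contain NA in layout variables (ax/ay/tx/ty needed?)")
  attr(S, "bins") <- bins
  S
}
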
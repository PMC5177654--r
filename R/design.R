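# Design-matrix construction. One code path computes the per-tap feature
# columns from a matrix of base variables; it is shared between the
# session-level design builder (taps = time-shifted kinematics) and the
# filter's observation function (taps = state sub-vectors), so the fitted
# model and the filter are guaranteed to evaluate identical features.

.KIN_VARS <- c("px", "py", "vx", "vy", "ax", "ay", "tx", "ty")

# vals: numeric matrix m x k with colnames from .KIN_VARS (only the variables
# the spec needs must be present). Returns the m x p_tap feature block.
tap_feature_block <- function(vals, spec) {
  need <- function(v) {
    if (!v %in% colnames(vals)) stop("feature build requires variable: ", v)
    vals[, v]
  }
  cols <- list()
  for (g in intersect(c("P", "V", "A", "PVI", "T"), spec$groups)) {
    if (g == "P") {
      px <- need("px"); py <- need("py")
      cols <- c(cols, list(px, py))
      if (spec$magnitudes[["P"]]) cols <- c(cols, list(sqrt(px^2 + py^2)))
    } else if (g == "V") {
      vx <- need("vx"); vy <- need("vy")
      cols <- c(cols, list(vx, vy))
      if (spec$magnitudes[["V"]]) cols <- c(cols, list(sqrt(vx^2 + vy^2)))
    } else if (g == "A") {
      ax <- need("ax"); ay <- need("ay")
      cols <- c(cols, list(ax, ay))
      if (spec$magnitudes[["A"]]) cols <- c(cols, list(sqrt(ax^2 + ay^2)))
    } else if (g == "PVI") {
      cols <- c(cols, list(need("px") * need("vx"), need("py") * need("vy")))
    } else if (g == "T") {
      tx <- need("tx"); ty <- need("ty")
      cols <- c(cols, list(tx, ty))
      if (spec$magnitudes[["T"]]) {
        cols <- c(cols, list(sqrt((tx - need("px"))^2 + (ty - need("py"))^2)))
      }
    }
  }
  do.call(cbind, cols)
}

# Kinematic part of the design: one row per bin, taps = time-shifted rows of
# the kinematics table. Shared by build_design_matrix and the generative
# population (which needs rates before any spike counts exist).
kin_design <- function(kin, spec) {
  K <- as.matrix(as.data.frame(kin)[, .KIN_VARS])
  nb <- nrow(K)
  mask <- rep(TRUE, nb)
  blocks <- list()
  t_idx <- seq_len(nb)
  for (off in spec$tap_offsets) {
    src <- t_idx + off
    ok <- src >= 1L & src <= nb
    mask <- mask & ok
    src[!ok] <- 1L  # placeholder; masked out below
    vals <- K[src, , drop = FALSE]
    blk <- tap_feature_block(vals, spec)
    if (!is.null(blk)) {
      blk[!ok, ] <- 0
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nb, 0)
  list(X = X, mask = mask)
}

#' Build the design matrix of an encoding model
#'
#' Produces one row per session bin. Row `t` holds, for each tap offset `k`,
#' the feature groups evaluated at bin `t + k`, followed (if SH is in the
#' spec) by the population spike counts of bin `t - 1`. Rows whose taps fall
#' outside the session (or, with SH, the first bin) are flagged invalid in
#' the mask and filled with zeros.
#'
#' @param session A `binned_session`.
#' @param spec A [feature_spec()].
#' @return A `design_matrix`: list with `X` (bins x features), logical
#'   `mask`, the `spec`, and per-column `features` metadata.
#' @export
build_design_matrix <- function(session, spec) {
  nb <- n_bins(session)
  nu <- n_units(session)
  ft <- feature_table(spec, n_units = if ("SH" %in% spec$groups) nu else 0L,
                      unit_ids = session$spikes$unit_ids)
  kd <- kin_design(session$kinematics, spec)
  mask <- kd$mask
  blocks <- if (ncol(kd$X)) list(kd$X) else list()
  t_idx <- seq_len(nb)
  if ("SH" %in% spec$groups) {
    prev <- t(session$spikes$counts)[pmax(t_idx - 1L, 1L), , drop = FALSE]
    prev[1L, ] <- 0
    mask[1L] <- FALSE
    blocks[[length(blocks) + 1L]] <- prev
  }
  X <- do.call(cbind, blocks)
  if (ncol(X) != nrow(ft)) stop("internal: feature table / design mismatch")
  if (anyNA(X[mask, , drop = FALSE])) {
    bad <- which(mask & apply(X, 1, anyNA))
    mask[bad] <- FALSE
    X[bad, ] <- 0
  }
  colnames(X) <- ft$name
  structure(list(X = X, mask = mask, spec = spec, features = ft,
                 n_units = nu, unit_ids = session$spikes$unit_ids),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d bins (%d valid) x %d features [%s]\n",
              nrow(x$X), sum(x$mask), ncol(x$X), x$spec$label))
  invisible(x)
}

# Kinematic feature block evaluated on filter states. S: m x d matrix of
# state vectors (rows), layout: a state_layout. Returns m x p_kin features
# in the same column order as build_design_matrix (SH excluded).
design_from_state <- function(S, layout, spec) {
  if (!all(spec$tap_offsets %in% layout$offsets)) {
    stop("spec taps not all present in the state layout")
  }
  blocks <- list()
  for (off in spec$tap_offsets) {
    idx <- state_index(layout, layout$vars, off)
    vals <- S[, idx, drop = FALSE]
    colnames(vals) <- layout$vars
    blk <- tap_feature_block(vals, spec)
    if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
  }
  do.call(cbind, blocks)
}
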
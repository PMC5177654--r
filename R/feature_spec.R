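# Encoding-model feature specifications. A spec names which feature groups a
# tuning model uses, at which temporal taps (bin offsets, future first), and
# how spiking history is scoped. Groups:
#   P   position (px, py) + optional magnitude sqrt(px^2 + py^2)
#   V   velocity (vx, vy) + optional magnitude
#   A   acceleration (ax, ay) + optional magnitude
#   PVI multiplicative position-velocity interaction (px*vx, py*vy)
#   T   target (tx, ty) + optional target-to-cursor distance
#   SH  population spike counts in the previous bin (one tap only)

.FEATURE_GROUPS <- c("P", "V", "A", "PVI", "T", "SH")

#' Specify the features of an encoding model
#'
#' @param groups Character subset of `P, V, A, PVI, T, SH`.
#' @param tap_offsets Integer bin offsets of the kinematic taps, ordered
#'   future to past (e.g. `2:-2`). Spiking history always uses exactly the
#'   previous bin, regardless of `tap_offsets`.
#' @param magnitudes Logical: include the magnitude term of the P/V/A groups
#'   and the target-distance term of the T group. Either a scalar or a named
#'   logical over `c("P","V","A","T")`.
#' @param history_scope For SH: `"population"` (all units, including the
#'   modelled one), `"others"` (all but the modelled unit) or `"self"` (the
#'   modelled unit only).
#' @param label Optional display label.
#' @return A `feature_spec`.
#' @export
feature_spec <- function(groups, tap_offsets = 0L, magnitudes = TRUE,
                         history_scope = c("population", "others", "self"),
                         label = NULL) {
  groups <- unique(as.character(groups))
  bad <- setdiff(groups, .FEATURE_GROUPS)
  if (length(bad)) stop("unknown feature group(s): ", paste(bad, collapse = ", "))
  tap_offsets <- as.integer(tap_offsets)
  if (length(tap_offsets) < 1L || is.unsorted(rev(tap_offsets), strictly = TRUE)) {
    stop("tap_offsets must be strictly decreasing (future first)")
  }
  mag <- c(P = TRUE, V = TRUE, A = TRUE, T = TRUE)
  if (is.logical(magnitudes) && is.null(names(magnitudes))) {
    mag[] <- magnitudes[1]
  } else {
    mag[names(magnitudes)] <- magnitudes
  }
  history_scope <- match.arg(history_scope)
  structure(
    list(groups = groups, tap_offsets = tap_offsets, magnitudes = mag,
         history_scope = history_scope,
         label = label %||% paste(groups, collapse = "+")),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec> %s | taps %s | magnitudes %s | history %s\n",
              x$label, paste(x$tap_offsets, collapse = ","),
              paste(names(x$magnitudes)[x$magnitudes], collapse = ""),
              if ("SH" %in% x$groups) x$history_scope else "-"))
  invisible(x)
}

#' Named encoding-model presets
#'
#' Presets reproduce the published model families:
#' * `kf`: linear position-velocity model, one tap, 4 features.
#' * `ukf1`: position + velocity with magnitudes over 10 taps (t+5..t-4),
#'   60 features.
#' * `ukf2`: position, velocity, acceleration (with magnitudes),
#'   position-velocity interaction, target (with target-cursor distance)
#'   over 5 taps (t+2..t-2) plus population spiking history: 70 + n features.
#' * `ukf1_a`, `ukf1_pvi`, `ukf1_t`, `ukf1_sh`: `ukf1` plus a single
#'   enhancement group.
#' * `self_history`, `others_history`, `population_history`: spiking-history
#'   only models (one previous bin).
#'
#' @param name Preset name.
#' @return A [feature_spec()].
#' @export
encoding_preset <- function(name = c("kf", "ukf1", "ukf2", "ukf1_a",
                                     "ukf1_pvi", "ukf1_t", "ukf1_sh",
                                     "self_history", "others_history",
                                     "population_history")) {
  name <- match.arg(name)
  ukf1_taps <- 5:-4
  ukf2_taps <- 2:-2
  switch(name,
    kf = feature_spec(c("P", "V"), 0L, magnitudes = FALSE, label = "kf"),
    ukf1 = feature_spec(c("P", "V"), ukf1_taps, label = "ukf1"),
    ukf2 = feature_spec(c("P", "V", "A", "PVI", "T", "SH"), ukf2_taps,
                        history_scope = "population", label = "ukf2"),
    ukf1_a = feature_spec(c("P", "V", "A"), ukf1_taps, label = "ukf1+A"),
    ukf1_pvi = feature_spec(c("P", "V", "PVI"), ukf1_taps, label = "ukf1+PVI"),
    ukf1_t = feature_spec(c("P", "V", "T"), ukf1_taps, label = "ukf1+T"),
    ukf1_sh = feature_spec(c("P", "V", "SH"), ukf1_taps,
                           history_scope = "population", label = "ukf1+SH"),
    self_history = feature_spec("SH", 0L, history_scope = "self",
                                label = "self history"),
    others_history = feature_spec("SH", 0L, history_scope = "others",
                                  label = "others history"),
    population_history = feature_spec("SH", 0L, history_scope = "population",
                                      label = "population history")
  )
}

group_width <- function(spec, g) {
  switch(g,
    P = 2L + spec$magnitudes[["P"]],
    V = 2L + spec$magnitudes[["V"]],
    A = 2L + spec$magnitudes[["A"]],
    PVI = 2L,
    T = 2L + spec$magnitudes[["T"]],
    stop("not a kinematic group: ", g))
}

#' Number of design-matrix columns of a spec
#'
#' For spiking history this is the number of population columns (`n_units`);
#' the per-unit `self`/`others` scopes are applied as per-unit column
#' restrictions at fitting time.
#'
#' @param spec A [feature_spec()].
#' @param n_units Population size (needed when SH is included).
#' @export
n_features <- function(spec, n_units = 0L) {
  kin <- sum(vapply(setdiff(spec$groups, "SH"), group_width,
                    integer(1), spec = spec)) * length(spec$tap_offsets)
  kin + if ("SH" %in% spec$groups) as.integer(n_units) else 0L
}

# Per-column metadata: name, group, var (base variable), tap, type, unit index
feature_table <- function(spec, n_units = 0L, unit_ids = NULL) {
  rows <- list()
  for (off in spec$tap_offsets) {
    tag <- sprintf("@%+d", off)
    for (g in intersect(c("P", "V", "A", "PVI", "T"), spec$groups)) {
      cols <- switch(g,
        P = rbind(c("px", "linear"), c("py", "linear"),
                  if (spec$magnitudes[["P"]]) c("mag_p", "nonlinear")),
        V = rbind(c("vx", "linear"), c("vy", "linear"),
                  if (spec$magnitudes[["V"]]) c("mag_v", "nonlinear")),
        A = rbind(c("ax", "linear"), c("ay", "linear"),
                  if (spec$magnitudes[["A"]]) c("mag_a", "nonlinear")),
        PVI = rbind(c("pvi_x", "nonlinear"), c("pvi_y", "nonlinear")),
        T = rbind(c("tx", "linear"), c("ty", "linear"),
                  if (spec$magnitudes[["T"]]) c("dist_tc", "nonlinear")))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(cols[, 1], tag), group = g, var = cols[, 1],
        tap = off, type = cols[, 2], unit = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if ("SH" %in% spec$groups) {
    if (n_units < 1L) stop("SH requested but no spike counts available")
    ids <- unit_ids %||% paste0("u", seq_len(n_units))
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("sh_", ids), group = "SH", var = "sh",
      tap = -1L, type = "sh", unit = seq_len(n_units),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
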
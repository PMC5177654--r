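# Data model for a binned BMI session: cursor kinematics, spike counts, and
# trial annotations on a common non-overlapping bin grid (default 50 ms).

#' Construct a kinematics frame
#'
#' A kinematics frame holds time-aligned 2D cursor position, velocity,
#' acceleration and target position on a fixed bin grid. All series are in
#' screen-centred Cartesian centimetres (+x right, +y up); velocities in cm/s,
#' accelerations in cm/s^2. When velocity or acceleration are not supplied
#' they are derived from position with [differentiate()], so that generated
#' and recorded sessions use one consistent finite-difference scheme.
#'
#' @param px,py Cursor position per bin (cm).
#' @param vx,vy Optional velocity per bin (cm/s); derived from position if
#'   `NULL`.
#' @param ax,ay Optional acceleration per bin (cm/s^2); derived from velocity
#'   if `NULL`.
#' @param tx,ty Target position per bin (cm); may be `NA` when no target.
#' @param target_radius Target radius per bin (cm), scalar or vector.
#' @param dt Bin width in seconds.
#' @param t0 Time of the first bin's left edge (s).
#' @return A `kinematics_frame`: a data frame with columns
#'   `t, px, py, vx, vy, ax, ay, tx, ty, target_radius` and attribute `dt`.
#' @export
kinematics_frame <- function(px, py, vx = NULL, vy = NULL, ax = NULL, ay = NULL,
                             tx = NA_real_, ty = NA_real_,
                             target_radius = NA_real_,
                             dt = .BIN_WIDTH_DEFAULT, t0 = 0) {
  n <- length(px)
  if (length(py) != n) stop("px and py must have equal length")
  if (n < 3L) stop("a kinematics frame needs at least 3 bins")
  if (is.null(vx) || is.null(vy)) {
    dx <- differentiate(px, dt)
    dy <- differentiate(py, dt)
    vx <- dx$velocity; vy <- dy$velocity
    if (is.null(ax) || is.null(ay)) {
      ax <- dx$acceleration; ay <- dy$acceleration
    }
  }
  if (is.null(ax) || is.null(ay)) {
    ax <- differentiate(vx, dt)$velocity
    ay <- differentiate(vy, dt)$velocity
  }
  tx <- rep_len(as.numeric(tx), n)
  ty <- rep_len(as.numeric(ty), n)
  target_radius <- rep_len(as.numeric(target_radius), n)
  for (nm in c("vx", "vy", "ax", "ay")) {
    if (length(get(nm)) != n) stop(sprintf("%s must have length %d", nm, n))
  }
  out <- data.frame(
    t = t0 + (seq_len(n) - 1) * dt,
    px = as.numeric(px), py = as.numeric(py),
    vx = as.numeric(vx), vy = as.numeric(vy),
    ax = as.numeric(ax), ay = as.numeric(ay),
    tx = tx, ty = ty, target_radius = target_radius
  )
  if (!all(is.finite(as.matrix(out[, c("px", "py", "vx", "vy", "ax", "ay")])))) {
    stop("non-finite values in kinematics")
  }
  attr(out, "dt") <- dt
  class(out) <- c("kinematics_frame", "data.frame")
  out
}

#' Construct a block of binned spike counts
#'
#' @param counts Integer matrix, units x bins, of non-negative spike counts.
#' @param unit_ids Character unit identifiers (default `u1..un`).
#' @param channel_of_unit Integer electrode channel of each unit; used by
#'   [merge_units_by_channel()]. Defaults to one channel per unit.
#' @param bin_width Bin width in seconds.
#' @return A `spike_count_block`.
#' @export
spike_count_block <- function(counts, unit_ids = NULL, channel_of_unit = NULL,
                              bin_width = .BIN_WIDTH_DEFAULT) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("spike counts must be non-negative integers")
  }
  n <- nrow(counts)
  if (is.null(unit_ids)) unit_ids <- paste0("u", seq_len(n))
  if (is.null(channel_of_unit)) channel_of_unit <- seq_len(n)
  if (length(unit_ids) != n || length(channel_of_unit) != n) {
    stop("unit_ids and channel_of_unit must have one entry per unit")
  }
  rownames(counts) <- unit_ids
  structure(
    list(counts = counts, unit_ids = as.character(unit_ids),
         channel_of_unit = as.integer(channel_of_unit),
         bin_width = bin_width),
    class = "spike_count_block"
  )
}

#' @export
print.spike_count_block <- function(x, ...) {
  cat(sprintf("<spike_count_block> %d units x %d bins (%.0f ms bins), %d channels\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$bin_width,
              length(unique(x$channel_of_unit))))
  invisible(x)
}

#' Construct a trial table
#'
#' @param trial_kind `"center"` or `"peripheral"` per trial.
#' @param onset_bin,end_bin 1-based first and last bin of each trial;
#'   `onset_bin < end_bin`.
#' @param success Logical, whether the target was acquired and held.
#' @param target_x,target_y Target centre (cm).
#' @param hold_required Required hold duration inside the target (s).
#' @param acquire_bin Optional: first bin of the final successful hold
#'   (`NA` for failed trials).
#' @return A data frame of class `trial_table`.
#' @export
trial_table <- function(trial_kind, onset_bin, end_bin, success,
                        target_x, target_y, hold_required = 0.5,
                        acquire_bin = NA_integer_) {
  df <- data.frame(
    trial_kind = as.character(trial_kind),
    onset_bin = as.integer(onset_bin),
    end_bin = as.integer(end_bin),
    success = as.logical(success),
    target_x = as.numeric(target_x),
    target_y = as.numeric(target_y),
    hold_required = rep_len(as.numeric(hold_required), length(trial_kind)),
    acquire_bin = rep_len(as.integer(acquire_bin), length(trial_kind))
  )
  if (any(!df$trial_kind %in% c("center", "peripheral"))) {
    stop("trial_kind must be 'center' or 'peripheral'")
  }
  if (any(df$onset_bin >= df$end_bin)) stop("onset_bin must be < end_bin")
  if (any(df$hold_required < 0)) stop("hold_required must be >= 0")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Construct a binned session
#'
#' Bundles kinematics, spike counts and trials on one common bin grid and
#' validates their agreement. Bin-count agreement is re-checked by every
#' transform that returns a session.
#'
#' @param kinematics A [kinematics_frame()].
#' @param spikes A [spike_count_block()].
#' @param trials Optional [trial_table()].
#' @param metadata Named list (task kind, seed, provenance, ...).
#' @return A `binned_session`.
#' @export
binned_session <- function(kinematics, spikes, trials = NULL, metadata = list()) {
  if (!inherits(kinematics, "kinematics_frame")) stop("kinematics must be a kinematics_frame")
  if (!inherits(spikes, "spike_count_block")) stop("spikes must be a spike_count_block")
  nb <- nrow(kinematics)
  if (ncol(spikes$counts) != nb) {
    stop(sprintf("bin count mismatch: kinematics has %d bins, spikes has %d",
                 nb, ncol(spikes$counts)))
  }
  if (abs(attr(kinematics, "dt") - spikes$bin_width) > 1e-12) {
    stop("kinematics dt and spike bin_width differ")
  }
  if (!is.null(trials)) {
    if (any(trials$onset_bin < 1L) || any(trials$end_bin > nb)) {
      stop("trials reference bins outside the session")
    }
  }
  structure(
    list(kinematics = kinematics, spikes = spikes, trials = trials,
         metadata = metadata),
    class = "binned_session"
  )
}

#' @export
print.binned_session <- function(x, ...) {
  cat(sprintf("<binned_session> %d bins (%.1f min) x %d units, %d trials\n",
              n_bins(x), n_bins(x) * session_dt(x) / 60, n_units(x),
              if (is.null(x$trials)) 0L else nrow(x$trials)))
  invisible(x)
}

#' Number of bins in a session
#' @param session A `binned_session`.
#' @export
n_bins <- function(session) nrow(session$kinematics)

#' Number of units in a session
#' @param session A `binned_session`.
#' @export
n_units <- function(session) nrow(session$spikes$counts)

#' Bin width of a session in seconds
#' @param session A `binned_session`.
#' @export
session_dt <- function(session) session$spikes$bin_width

#' Subset a session to a contiguous range of bins
#'
#' Trials that do not lie fully inside the retained range are dropped; bin
#' indices of the kept trials are shifted to the new origin.
#'
#' @param session A `binned_session`.
#' @param bins Contiguous, increasing integer bin indices.
#' @export
subset_session <- function(session, bins) {
  bins <- as.integer(bins)
  if (length(bins) < 3L || any(diff(bins) != 1L)) {
    stop("bins must be a contiguous increasing range of length >= 3")
  }
  if (bins[1] < 1L || bins[length(bins)] > n_bins(session)) {
    stop("bins outside the session range")
  }
  kin <- session$kinematics[bins, , drop = FALSE]
  attr(kin, "dt") <- attr(session$kinematics, "dt")
  class(kin) <- class(session$kinematics)
  rownames(kin) <- NULL
  spk <- session$spikes
  spk$counts <- spk$counts[, bins, drop = FALSE]
  trials <- session$trials
  if (!is.null(trials)) {
    keep <- trials$onset_bin >= bins[1] & trials$end_bin <= bins[length(bins)]
    trials <- trials[keep, , drop = FALSE]
    shift <- bins[1] - 1L
    trials$onset_bin <- trials$onset_bin - shift
    trials$end_bin <- trials$end_bin - shift
    trials$acquire_bin <- trials$acquire_bin - shift
    rownames(trials) <- NULL
  }
  binned_session(kin, spk, trials, session$metadata)
}
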
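# Preprocessing: spike binning, analog down-binning, differentiation,
# moving-average smoothing, channel merging, and train/test splitting.

#' Count spike times in non-overlapping bins
#'
#' Counts each unit's spike times in half-open bins `[t0 + b*w, t0 + (b+1)*w)`
#' covering `[t0, t1)`; a spike exactly at `t1` is excluded.
#'
#' @param spike_times List of numeric vectors, one sorted vector of spike
#'   times (s) per unit. An empty vector yields an all-zero row.
#' @param bin_width Bin width (s), default 0.05.
#' @param t0,t1 Start and end of the counting window (s).
#' @param unit_ids,channel_of_unit Passed to [spike_count_block()].
#' @return A [spike_count_block()].
#' @export
bin_spike_times <- function(spike_times, bin_width = .BIN_WIDTH_DEFAULT,
                            t0 = 0, t1 = NULL,
                            unit_ids = NULL, channel_of_unit = NULL) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (is.null(t1)) t1 <- max(c(t0, unlist(spike_times)), na.rm = TRUE)
  nb <- floor((t1 - t0) / bin_width + 1e-9)
  if (nb < 1L) stop("window shorter than one bin")
  counts <- t(vapply(spike_times, function(ts) {
    if (length(ts) == 0L) return(integer(nb))
    if (is.unsorted(ts)) stop("spike times must be sorted per unit")
    idx <- floor((ts - t0) / bin_width) + 1L
    keep <- ts >= t0 & ts < t0 + nb * bin_width
    tabulate(idx[keep], nbins = nb)
  }, integer(nb)))
  if (length(spike_times) == 1L) counts <- matrix(counts, nrow = 1L)
  spike_count_block(counts, unit_ids = unit_ids,
                    channel_of_unit = channel_of_unit, bin_width = bin_width)
}

#' Bin an analog signal by within-bin averaging
#'
#' Each output bin is the arithmetic mean of the raw samples falling in it,
#' mirroring the down-sampling of a 100 Hz joystick trace to 50 ms bins
#' (5 samples per bin). A trailing partial bin is dropped with a message.
#'
#' @param samples Numeric vector of raw samples.
#' @param sample_rate Samples per second of the input.
#' @param bin_width Output bin width (s). `sample_rate * bin_width` must be a
#'   whole number.
#' @return Numeric vector of per-bin means.
#' @export
bin_analog <- function(samples, sample_rate = 100, bin_width = .BIN_WIDTH_DEFAULT) {
  spb <- sample_rate * bin_width
  if (abs(spb - round(spb)) > 1e-9) {
    stop("sample_rate * bin_width must be an integer number of samples per bin")
  }
  spb <- as.integer(round(spb))
  nb <- length(samples) %/% spb
  dropped <- length(samples) - nb * spb
  if (dropped > 0L) {
    message(sprintf("bin_analog: dropping trailing partial bin of %d sample(s)", dropped))
  }
  if (nb == 0L) stop("fewer samples than one bin")
  colMeans(matrix(samples[seq_len(nb * spb)], nrow = spb))
}

#' Differentiate a position series
#'
#' Central differences in the interior, one-sided differences at the two
#' edges; acceleration applies the same scheme to the resulting velocity.
#' The simulator uses the identical scheme so that generated sessions
#' round-trip exactly.
#'
#' @param x Numeric series (e.g. position in cm).
#' @param dt Bin width (s).
#' @return List with components `velocity` and `acceleration`.
#' @export
differentiate <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("differentiate needs at least 3 bins")
  d1 <- function(z) {
    c(z[2] - z[1],
      (z[3:n] - z[1:(n - 2)]) / 2,
      z[n] - z[n - 1]) / dt
  }
  v <- d1(x)
  list(velocity = v, acceleration = d1(v))
}

#' Sliding-window moving-average smoothing
#'
#' Centred moving average with an odd window; near the edges the window
#' shrinks symmetrically so the output length equals the input length.
#' `window_bins = 1` is the identity.
#'
#' @param x Numeric series.
#' @param window_bins Odd positive integer window length in bins.
#' @return Smoothed series of the same length.
#' @export
smooth_kinematics <- function(x, window_bins) {
  if (window_bins < 1 || window_bins %% 2 == 0) {
    stop("window_bins must be an odd positive integer")
  }
  if (window_bins == 1) return(x)
  n <- length(x)
  hw <- (window_bins - 1) / 2
  i <- seq_len(n)
  h <- pmin(hw, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
}

#' Merge all units on each channel
#'
#' Undoes spike sorting by summing, per bin, the counts of all units recorded
#' on the same channel. The total spike count is conserved exactly.
#'
#' @param block A [spike_count_block()].
#' @return A [spike_count_block()] with one unit per channel.
#' @export
merge_units_by_channel <- function(block) {
  if (!inherits(block, "spike_count_block")) stop("block must be a spike_count_block")
  ch <- block$channel_of_unit
  merged <- rowsum(block$counts, group = ch, reorder = TRUE)
  chans <- sort(unique(ch))
  spike_count_block(merged, unit_ids = paste0("ch", chans),
                    channel_of_unit = chans, bin_width = block$bin_width)
}

#' Split a session into training and testing portions
#'
#' The first 30 s are discarded to avoid transients. If the session holds at
#' least 12.5 min of data, the next 10 min form the training portion;
#' shorter sessions use 5 min. The remainder is the testing portion. The
#' "less than 12.5 min" rule is read strictly: a session of exactly 12.5 min
#' gets the 10-min split.
#'
#' @param session A `binned_session`.
#' @param skip Initial discard (s), default 30.
#' @param long_train,short_train Training durations (s) for long and short
#'   sessions, defaults 600 and 300.
#' @param threshold Session length (s) below which the short split applies,
#'   default 750 (12.5 min).
#' @return List with `train` and `test` sessions plus the bin index vectors
#'   `train_bins` and `test_bins`.
#' @export
train_test_split <- function(session, skip = 30, long_train = 600,
                             short_train = 300, threshold = 750) {
  dt <- session_dt(session)
  nb <- n_bins(session)
  total <- nb * dt
  skip_bins <- round(skip / dt)
  if (total < skip + short_train) {
    stop(sprintf("session too short to split: %.1f s < %.1f s", total, skip + short_train))
  }
  train_dur <- if (total < threshold) short_train else long_train
  train_bins <- (skip_bins + 1L):(skip_bins + round(train_dur / dt))
  test_start <- skip_bins + round(train_dur / dt) + 1L
  if (test_start > nb) stop("no bins left for the testing portion")
  test_bins <- test_start:nb
  list(train = subset_session(session, train_bins),
       test = subset_session(session, test_bins),
       train_bins = train_bins, test_bins = test_bins)
}
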
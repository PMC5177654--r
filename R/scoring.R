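# Prediction accuracy: Pearson correlation and signal-to-noise ratio
# SNR_dB = 10 log10(Var_s / MSE), where Var_s is the (population) variance
# of the desired signal and MSE the mean squared prediction error. SNR does
# not saturate and, unlike CC, penalises scale and offset errors.

#' Score predictions against actual series
#'
#' @param predicted,actual Numeric vectors or matrices (rows = bins,
#'   columns = series) of equal shape. Rows with `NA` in the prediction
#'   (masked design rows) are dropped pairwise.
#' @param cap_db Finite sentinel reported when the MSE is exactly zero.
#' @return A data frame with one row per series: `cc`, `snr_db`, `var_s`,
#'   `mse`. Series whose actual values have zero variance get `NA`
#'   correlation and are excluded from aggregate means.
#' @export
score_predictions <- function(predicted, actual, cap_db = 300) {
  P <- as.matrix(predicted); A <- as.matrix(actual)
  if (!all(dim(P) == dim(A))) stop("predicted and actual must have equal shape")
  if (nrow(P) < 2L) stop("scoring needs at least 2 bins")
  out <- data.frame(series = colnames(A) %||% paste0("s", seq_len(ncol(A))),
                    cc = NA_real_, snr_db = NA_real_,
                    var_s = NA_real_, mse = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(A))) {
    ok <- is.finite(P[, j]) & is.finite(A[, j])
    a <- A[ok, j]; p <- P[ok, j]
    if (length(a) < 2L) next
    vs <- mean((a - mean(a))^2)
    mse <- mean((a - p)^2)
    out$var_s[j] <- vs
    out$mse[j] <- mse
    if (vs > 0) {
      if (sd(p) > 0) out$cc[j] <- cor(a, p)
      out$snr_db[j] <- if (mse > 0) min(10 * log10(vs / mse), cap_db) else cap_db
    }
  }
  zero_var <- which(!is.na(out$mse) & out$var_s == 0)
  if (length(zero_var)) {
    message(sprintf("score_predictions: %d series with zero variance excluded from means",
                    length(zero_var)))
  }
  out
}

#' Aggregate scores across series
#'
#' Arithmetic mean of the per-series correlation coefficients and of the
#' per-series SNR in decibels, skipping undefined entries.
#'
#' @param scores Data frame from [score_predictions()].
#' @export
mean_scores <- function(scores) {
  c(cc = mean(scores$cc, na.rm = TRUE),
    snr_db = mean(scores$snr_db, na.rm = TRUE))
}

#' Two-fold cross-validated encoding accuracy
#'
#' Splits the session into two contiguous halves, fits the encoding model on
#' one half and predicts spike counts on the other, swaps the folds, and
#' averages the per-unit scores. Kinematic taps are forced to the single
#' zero-offset tap for this analysis; spiking history remains the previous
#' bin.
#'
#' @param session A `binned_session`.
#' @param spec A [feature_spec()] or preset name.
#' @param lambda_grid Optional ridge grid passed to [fit_encoding()].
#' @return Data frame with one row per unit: `unit_id`, `cc`, `snr_db`
#'   (fold averages).
#' @export
twofold_cv_encoding <- function(session, spec, lambda_grid = NULL) {
  if (is.character(spec)) spec <- encoding_preset(spec)
  spec1 <- feature_spec(spec$groups, 0L, magnitudes = spec$magnitudes,
                        history_scope = spec$history_scope, label = spec$label)
  dm <- build_design_matrix(session, spec1)
  nb <- n_bins(session)
  half <- floor(nb / 2)
  folds <- list(seq_len(half), (half + 1L):nb)
  Y <- t(session$spikes$counts)
  acc <- matrix(0, n_units(session), 2,
                dimnames = list(session$spikes$unit_ids, c("cc", "snr_db")))
  for (k in 1:2) {
    tr <- folds[[k]]; te <- folds[[3 - k]]
    dtr <- dm; dtr$mask <- dm$mask & seq_len(nb) %in% tr
    model <- suppressWarnings(
      fit_encoding(dtr, session$spikes, lambda_grid = lambda_grid))
    pred <- predict_rates(model, dm)
    rows <- te[dm$mask[te]]
    sc <- score_predictions(pred[rows, , drop = FALSE], Y[rows, , drop = FALSE])
    acc[, "cc"] <- acc[, "cc"] + sc$cc / 2
    acc[, "snr_db"] <- acc[, "snr_db"] + sc$snr_db / 2
  }
  data.frame(unit_id = rownames(acc), cc = acc[, "cc"], snr_db = acc[, "snr_db"],
             row.names = NULL, stringsAsFactors = FALSE)
}
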
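# Ridge fitting of encoding models. Targets are mean-centred spike counts;
# features are standardised internally so that a single ridge penalty is
# meaningful across heterogeneous units (cm, cm/s, counts). The ridge
# parameter is chosen automatically on a held-out tail of the training rows.

default_lambda_grid <- function(Xs) {
  10^seq(-6, 6, length.out = 25) * mean(colSums(Xs^2))
}

# Ridge solution via one SVD, reused across the whole lambda grid.
# Returns p x q coefficient matrix for each lambda (list).
ridge_path_svd <- function(Xs, Yc, lambdas) {
  sv <- svd(Xs, nu = min(dim(Xs)), nv = ncol(Xs))
  UtY <- crossprod(sv$u, Yc)
  lapply(lambdas, function(l) {
    shrink <- sv$d / (sv$d^2 + l)
    sv$v %*% (shrink * UtY)
  })
}

# Column indices (into the kept design columns) each unit is allowed to use,
# applying the self/others spiking-history scopes.
unit_column_sets <- function(spec, ft_kept, n_units) {
  p <- nrow(ft_kept)
  if (!"SH" %in% spec$groups || spec$history_scope == "population") {
    return(NULL)  # all units share all columns
  }
  kin <- which(ft_kept$group != "SH")
  lapply(seq_len(n_units), function(i) {
    sh <- which(ft_kept$group == "SH" &
                (if (spec$history_scope == "self") ft_kept$unit == i
                 else ft_kept$unit != i))
    sort(c(kin, sh))
  })
}

#' Fit an encoding model by ridge regression
#'
#' Fits, per unit, the linear map from (standardised) features to
#' mean-centred spike counts, with one shared ridge penalty chosen by
#' held-out mean squared error on the last `holdout_frac` of the training
#' rows and a refit on all rows. The sample covariance of the training
#' residuals is stored as the observation noise covariance, with a small
#' diagonal load to guard against singularity.
#'
#' @param features A `design_matrix` from [build_design_matrix()], or a plain
#'   numeric matrix (rows = bins) for low-level use.
#' @param counts A [spike_count_block()] or a units x bins count matrix.
#' @param lambda_grid Ridge penalties to search; default 25 log-spaced values
#'   spanning `1e-6..1e6` times the mean diagonal of the standardised
#'   cross-product. A length-1 grid skips selection.
#' @param holdout_frac Fraction of training rows (the tail) held out for
#'   penalty selection. Ignored for a length-1 grid.
#' @return An `encoding_model` with fields `coef` (units x features, in
#'   standardised feature space), `centers`, `scales`, `unit_means`,
#'   `lambda`, and residual covariance `R`.
#' @export
fit_encoding <- function(features, counts, lambda_grid = NULL,
                         holdout_frac = 0.2) {
  if (inherits(features, "design_matrix")) {
    spec <- features$spec
    ft <- features$features
    mask <- features$mask
    X <- features$X
    unit_ids <- features$unit_ids
  } else {
    X <- as.matrix(features)
    spec <- NULL
    ft <- data.frame(name = colnames(X) %||% paste0("f", seq_len(ncol(X))),
                     group = "raw", var = NA, tap = NA, type = "linear",
                     unit = NA_integer_, stringsAsFactors = FALSE)
    mask <- rep(TRUE, nrow(X))
    unit_ids <- NULL
  }
  Ymat <- if (inherits(counts, "spike_count_block")) counts$counts else as.matrix(counts)
  if (ncol(Ymat) != nrow(X)) stop("counts must have one column per design row")
  Y <- t(Ymat)[mask, , drop = FALSE]
  X <- X[mask, , drop = FALSE]
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (n < 2L * p) {
    warning(sprintf("only %d rows for %d features; fit may be unstable", n, p))
  }

  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  kept <- is.finite(scales) & scales > 1e-10
  if (any(!kept)) {
    warning(sprintf("dropping %d constant feature column(s): %s",
                    sum(!kept), paste(ft$name[!kept], collapse = ", ")))
  }
  scales[!kept] <- 1
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, centers[kept], "-"),
              2, scales[kept], "/")
  unit_means <- colMeans(Y)
  Yc <- sweep(Y, 2, unit_means, "-")

  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(Xs)
  cols <- if (is.null(spec)) NULL else
    unit_column_sets(spec, ft[kept, , drop = FALSE], q)

  pick_lambda <- function() {
    if (length(lambda_grid) == 1L) return(lambda_grid)
    n1 <- max(min(n - 1L, floor((1 - holdout_frac) * n)), 2L)
    tr <- seq_len(n1); ho <- (n1 + 1L):n
    mse <- numeric(length(lambda_grid))
    if (is.null(cols)) {
      path <- ridge_path_svd(Xs[tr, , drop = FALSE], Yc[tr, , drop = FALSE],
                             lambda_grid)
      for (j in seq_along(path)) {
        resid <- Yc[ho, , drop = FALSE] - Xs[ho, , drop = FALSE] %*% path[[j]]
        mse[j] <- sum(resid^2)
      }
    } else {
      for (i in seq_len(q)) {
        ci <- cols[[i]]
        if (!length(ci)) {  # e.g. a silent unit under self-history scope
          mse <- mse + sum(Yc[ho, i]^2)
          next
        }
        path <- ridge_path_svd(Xs[tr, ci, drop = FALSE],
                               Yc[tr, i, drop = FALSE], lambda_grid)
        for (j in seq_along(path)) {
          resid <- Yc[ho, i] - Xs[ho, ci, drop = FALSE] %*% path[[j]]
          mse[j] <- mse[j] + sum(resid^2)
        }
      }
    }
    lambda_grid[which.min(mse)]
  }
  lambda <- pick_lambda()

  coef_kept <- matrix(0, sum(kept), q)
  if (is.null(cols)) {
    coef_kept <- ridge_path_svd(Xs, Yc, lambda)[[1]]
  } else {
    for (i in seq_len(q)) {
      ci <- cols[[i]]
      if (!length(ci)) next
      coef_kept[ci, i] <- ridge_path_svd(Xs[, ci, drop = FALSE],
                                         Yc[, i, drop = FALSE], lambda)[[1]]
    }
  }
  coef_full <- matrix(0, p, q,
                      dimnames = list(ft$name, unit_ids %||% colnames(Y)))
  coef_full[kept, ] <- coef_kept

  resid <- Yc - Xs %*% coef_kept
  R <- cov(resid)
  R <- R + diag(1e-6 * mean(diag(R)) + 1e-12, q)

  structure(
    list(spec = spec, features = ft, coef = t(coef_full),
         centers = centers, scales = scales, kept = kept,
         unit_means = unit_means, lambda = lambda,
         lambda_grid = lambda_grid, R = R,
         unit_ids = unit_ids %||% colnames(Ymat) %||% paste0("u", seq_len(q)),
         n_rows = n),
    class = "encoding_model"
  )
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("<encoding_model> %s: %d units x %d features, lambda %.3g\n",
              if (is.null(x$spec)) "raw" else x$spec$label,
              nrow(x$coef), ncol(x$coef), x$lambda))
  invisible(x)
}

#' Predict spike counts from an encoding model
#'
#' Linear prediction plus the stored per-unit mean; predictions are not
#' clipped to be non-negative, mirroring the linear-Gaussian model class.
#' Rows masked out of the design are returned as `NA`.
#'
#' @param model An `encoding_model`.
#' @param features A `design_matrix` built with the same spec, or a matrix.
#' @return Numeric matrix, bins x units.
#' @export
predict_rates <- function(model, features) {
  if (inherits(features, "design_matrix")) {
    if (!is.null(model$spec) &&
        !identical(features$spec[c("groups", "tap_offsets", "magnitudes")],
                   model$spec[c("groups", "tap_offsets", "magnitudes")])) {
      stop("design matrix was built with a different feature spec")
    }
    X <- features$X
    mask <- features$mask
  } else {
    X <- as.matrix(features)
    mask <- rep(TRUE, nrow(X))
  }
  if (ncol(X) != ncol(model$coef)) stop("feature count mismatch")
  Xs <- sweep(sweep(X, 2, model$centers, "-"), 2, model$scales, "/")
  pred <- Xs %*% t(model$coef)
  pred <- sweep(pred, 2, model$unit_means, "+")
  pred[!mask, ] <- NA_real_
  colnames(pred) <- model$unit_ids
  pred
}
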
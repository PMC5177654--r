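# Kalman and unscented Kalman inference. The transition is linear in both
# filters, so the prediction step is exact; the UKF handles observation
# models that are nonlinear in the state (magnitudes, interactions,
# target-cursor distance) by propagating scaled symmetric sigma points
# through the observation function. Spiking-history terms enter each sigma
# point's predicted rates as a known additive offset (the previous bin's
# counts are data, not state).

#' Construct a Gaussian belief over the filter state
#'
#' @param mean Numeric state mean.
#' @param cov Symmetric covariance matrix.
#' @export
gaussian_belief <- function(mean, cov) {
  cov <- as.matrix(cov)
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov)) {
    stop("mean and covariance dimensions disagree")
  }
  structure(list(mean = as.numeric(mean), cov = (cov + t(cov)) / 2),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> dim %d\n", length(x$mean)))
  invisible(x)
}

# Symmetrise and floor a covariance: negative eigenvalues below -tol are an
# error; small negatives are clipped to zero.
psd_floor <- function(P, tol = 1e-9) {
  P <- (P + t(P)) / 2
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (!is.null(ch)) return(P)
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1)) {
    stop(sprintf("covariance not positive semi-definite (min eigenvalue %.3g)",
                 min(e$values)))
  }
  vals <- pmax(e$values, 0)
  P <- e$vectors %*% (vals * t(e$vectors))
  (P + t(P)) / 2
}

# Matrix square root factor L with P = L %*% t(L); Cholesky with an
# eigendecomposition fallback for semidefinite P.
cov_sqrt <- function(P) {
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values), 1)) {
    stop("covariance not positive semi-definite in sigma-point generation")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(P))
}

kf_predict <- function(belief, trans) {
  m <- as.vector(trans$F %*% belief$mean) + trans$b
  P <- trans$F %*% belief$cov %*% t(trans$F) + trans$Q
  if (isTRUE(trans$position_feedback)) {
    # position-as-feedback: the cursor position is known to the system, so
    # the predicted position carries no uncertainty and receives no
    # innovation; it integrates the decoded velocity deterministically.
    pos <- position_indices(trans$layout)
    P[pos, ] <- 0
    P[, pos] <- 0
  }
  gaussian_belief(m, P)
}

#' One Kalman filter step (predict + linear update)
#'
#' @param belief A [gaussian_belief()].
#' @param trans A `transition_model` with `Q` set.
#' @param obs Linear observation model: list with `H` (units x state), `b`
#'   (per-unit offset) and `R` (units x units, positive definite).
#' @param counts Observed spike counts for this bin (one per unit).
#' @return The posterior [gaussian_belief()].
#' @export
kf_step <- function(belief, trans, obs, counts) {
  if (inherits(try(chol(obs$R), silent = TRUE), "try-error")) {
    stop("observation noise covariance R is not positive definite")
  }
  pr <- kf_predict(belief, trans)
  H <- obs$H
  S <- H %*% pr$cov %*% t(H) + obs$R
  K <- t(solve(S, H %*% pr$cov))
  innov <- as.numeric(counts) - (as.vector(H %*% pr$mean) + obs$b)
  m <- pr$mean + as.vector(K %*% innov)
  P <- pr$cov - K %*% H %*% pr$cov
  gaussian_belief(m, psd_floor(P))
}

# Scaled symmetric sigma points (2d+1) and their mean/covariance weights.
ukf_sigma_points <- function(m, P, alpha = 1e-3, beta = 2, kappa = 0) {
  d <- length(m)
  lam <- alpha^2 * (d + kappa) - d
  L <- cov_sqrt(P) * sqrt(d + lam)
  pts <- rbind(m, sweep(t(L), 2, m, "+"), sweep(-t(L), 2, m, "+"))
  wm <- c(lam / (d + lam), rep(1 / (2 * (d + lam)), 2 * d))
  wc <- wm
  wc[1] <- wc[1] + (1 - alpha^2 + beta)
  list(points = unname(pts), wm = wm, wc = wc)
}

#' One unscented Kalman filter step
#'
#' Exact linear prediction followed by a sigma-point measurement update
#' through a (possibly nonlinear) observation function.
#'
#' @param belief A [gaussian_belief()].
#' @param trans A `transition_model` with `Q` set.
#' @param obs Observation model: list with `fn` (function mapping an
#'   m x state matrix of sigma points to an m x units matrix of predicted
#'   counts) and `R` (units x units noise covariance). Any spiking-history
#'   offset must already be folded into `fn`.
#' @param counts Observed spike counts for this bin.
#' @param alpha,beta,kappa Scaled unscented-transform parameters.
#' @return The posterior [gaussian_belief()].
#' @export
ukf_step <- function(belief, trans, obs, counts, alpha = 1e-3, beta = 2,
                     kappa = 0) {
  pr <- kf_predict(belief, trans)
  sp <- ukf_sigma_points(pr$mean, pr$cov, alpha, beta, kappa)
  Z <- obs$fn(sp$points)
  zbar <- as.vector(crossprod(Z, sp$wm))
  dZ <- sweep(Z, 2, zbar, "-")
  dX <- sweep(sp$points, 2, pr$mean, "-")
  S <- crossprod(dZ, dZ * sp$wc) + obs$R
  Cxz <- crossprod(dX, dZ * sp$wc)
  K <- t(solve((S + t(S)) / 2, t(Cxz)))
  innov <- as.numeric(counts) - zbar
  m <- pr$mean + as.vector(K %*% innov)
  P <- pr$cov - K %*% S %*% t(K)
  gaussian_belief(m, psd_floor(P))
}
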
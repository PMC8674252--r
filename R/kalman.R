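#' Kalman filter for a time-invariant linear-Gaussian state-space model
#'
#' Model: `x_t = A x_{t-1} + N(0, Q)`, `y_t = C x_t + N(0, R)`, with
#' Gaussian prior `x_1 ~ N(prior_mean, prior_cov)` before seeing `y_1`
#' (i.e. the prior describes the first state directly; no extra propagation
#' step is applied to it).
#'
#' @param y observation matrix, `p x T` (one column per time point).
#' @param A state transition, `m x m`.
#' @param C observation map, `p x m`.
#' @param Q state-noise covariance, `m x m`.
#' @param R observation-noise covariance: `p x p` matrix or length-`p`
#'   vector of diagonal variances (must be positive).
#' @param prior_mean,prior_cov prior on the first state.
#' @return A list with `filtered_mean` (`m x T`), `filtered_cov`
#'   (`m x m x T`), `predicted_mean`, `predicted_cov` (one-step-ahead, for
#'   `t = 1` the prior itself), and `loglik`.
#' @export
kalman_filter <- function(y, A, C, Q, R, prior_mean, prior_cov) {
  y <- as.matrix(y)
  A <- as.matrix(A); C <- as.matrix(C); Q <- as.matrix(Q)
  m <- nrow(A); p <- nrow(y); T <- ncol(y)
  if (is.vector(R) || (is.matrix(R) && ncol(R) == 1L && nrow(R) == p)) {
    R <- diag(as.numeric(R), p)
  }
  R <- as.matrix(R)
  stopifnot(ncol(A) == m, nrow(C) == p, ncol(C) == m,
            all(dim(Q) == m), all(dim(R) == p),
            length(prior_mean) == m, all(dim(as.matrix(prior_cov)) == m))
  if (any(diag(R) <= 0)) stop("R must have positive diagonal")
  fm <- matrix(0, m, T); fP <- array(0, c(m, m, T))
  pm <- matrix(0, m, T); pP <- array(0, c(m, m, T))
  loglik <- 0
  x_pred <- as.numeric(prior_mean)
  P_pred <- as.matrix(prior_cov)
  for (t in seq_len(T)) {
    pm[, t] <- x_pred; pP[, , t] <- P_pred
    v <- y[, t] - drop(C %*% x_pred)
    Fm <- C %*% P_pred %*% t(C) + R
    Fm <- (Fm + t(Fm)) / 2
    if (!all(is.finite(Fm))) stop("non-finite innovation covariance")
    cF <- tryCatch(chol(Fm), error = function(e)
      stop("innovation covariance not positive-definite (numerical degeneracy)"))
    Finv_v <- backsolve(cF, forwardsolve(t(cF), v))
    loglik <- loglik - 0.5 * (p * log(2 * pi) + 2 * sum(log(diag(cF))) +
                                sum(v * Finv_v))
    K <- P_pred %*% t(C) %*% chol2inv(cF)
    x_filt <- x_pred + drop(K %*% v)
    P_filt <- P_pred - K %*% Fm %*% t(K)
    P_filt <- (P_filt + t(P_filt)) / 2
    fm[, t] <- x_filt; fP[, , t] <- P_filt
    x_pred <- drop(A %*% x_filt)
    P_pred <- A %*% P_filt %*% t(A) + Q
    P_pred <- (P_pred + t(P_pred)) / 2
  }
  list(filtered_mean = fm, filtered_cov = fP,
       predicted_mean = pm, predicted_cov = pP, loglik = loglik)
}

#' Rauch-Tung-Striebel smoother
#'
#' Runs [kalman_filter()] and the backward recursion. Smoothed means are
#' the conditional expectations of the states given all observations; the
#' lag-one smoothed cross-covariances needed by the EM step are returned as
#' well.
#'
#' @inheritParams kalman_filter
#' @return A list with `smoothed_mean` (`m x T`), `smoothed_cov`
#'   (`m x m x T`), `lag_one_cov` (`m x m x T`; slice `t` holds
#'   `Cov(x_t, x_{t-1} | y_{1:T})`, slice 1 is zero), and `loglik`.
#' @export
kalman_smooth <- function(y, A, C, Q, R, prior_mean, prior_cov) {
  kf <- kalman_filter(y, A, C, Q, R, prior_mean, prior_cov)
  A <- as.matrix(A)
  m <- nrow(A); T <- ncol(kf$filtered_mean)
  sm <- matrix(0, m, T); sP <- array(0, c(m, m, T))
  lag1 <- array(0, c(m, m, T))
  sm[, T] <- kf$filtered_mean[, T]
  sP[, , T] <- kf$filtered_cov[, , T]
  J <- array(0, c(m, m, T))
  for (t in rev(seq_len(T - 1L))) {
    P_filt <- kf$filtered_cov[, , t]
    P_next_pred <- kf$predicted_cov[, , t + 1L]
    Jt <- P_filt %*% t(A) %*% solve(P_next_pred)
    J[, , t] <- Jt
    sm[, t] <- kf$filtered_mean[, t] +
      drop(Jt %*% (sm[, t + 1L] - kf$predicted_mean[, t + 1L]))
    sP[, , t] <- P_filt + Jt %*% (sP[, , t + 1L] - P_next_pred) %*% t(Jt)
    sP[, , t] <- (sP[, , t] + t(sP[, , t])) / 2
  }
  # Cov(x_t, x_{t-1} | all data) = P_{t|T} J_{t-1}'
  for (t in seq_len(T)[-1L]) {
    lag1[, , t] <- sP[, , t] %*% t(J[, , t - 1L])
  }
  list(smoothed_mean = sm, smoothed_cov = sP, lag_one_cov = lag1,
       loglik = kf$loglik, filter = kf)
}
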
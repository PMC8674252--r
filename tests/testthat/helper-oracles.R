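# Independent oracles used across tests. These deliberately take brute-force
# routes (full joint Gaussians, exhaustive search, slow fixed-parameter ADMM)
# so they share no code path with the implementation they check.

# Conditional mean/covariance of all states given all observations, by
# assembling the full joint Gaussian of (states, observations) and
# conditioning directly. Scalar-friendly: works for any m, p, T.
joint_gaussian_smoother_oracle <- function(y, A, C, Q, R, prior_mean, prior_cov) {
  A <- as.matrix(A); C <- as.matrix(C); Q <- as.matrix(Q)
  m <- nrow(A); p <- nrow(as.matrix(y)); T <- ncol(as.matrix(y))
  if (is.vector(R)) R <- diag(as.numeric(R), p)
  M <- m * T
  mu_f <- numeric(M)
  mu_f[1:m] <- prior_mean
  for (t in 2:T) {
    mu_f[(t - 1) * m + 1:m] <- A %*% mu_f[(t - 2) * m + 1:m]
  }
  Sig <- matrix(0, M, M)
  blk <- function(t) (t - 1) * m + 1:m
  Sig[blk(1), blk(1)] <- as.matrix(prior_cov)
  for (t in 2:T) {
    for (s in 1:(t - 1)) {
      Sig[blk(t), blk(s)] <- A %*% Sig[blk(t - 1), blk(s)]
      Sig[blk(s), blk(t)] <- t(Sig[blk(t), blk(s)])
    }
    Sig[blk(t), blk(t)] <- A %*% Sig[blk(t - 1), blk(t - 1)] %*% t(A) + Q
  }
  Cb <- kronecker(diag(T), C)
  SigY <- Cb %*% Sig %*% t(Cb) + kronecker(diag(T), R)
  SigFY <- Sig %*% t(Cb)
  yv <- as.vector(y) - as.vector(Cb %*% mu_f)
  cm <- mu_f + SigFY %*% solve(SigY, yv)
  cc <- Sig - SigFY %*% solve(SigY, t(SigFY))
  ld <- -0.5 * (length(yv) * log(2 * pi) +
                  as.numeric(determinant(SigY)$modulus) +
                  drop(t(yv) %*% solve(SigY, yv)))
  list(mean = matrix(cm, m, T), cov = cc, loglik = ld, blk = blk)
}

# Slow fixed-parameter ADMM for principal component pursuit, run to very
# tight tolerance: the reference optimum of the convex program.
pcp_admm_oracle <- function(X, lambda, mu = 0.25, max_iter = 50000, tol = 1e-12) {
  nx <- norm(X, "F")
  Y <- X * 0; S <- Y; L <- Y
  for (it in seq_len(max_iter)) {
    sv <- svd(X - S + Y / mu)
    d <- pmax(sv$d - 1 / mu, 0)
    r <- max(1, sum(d > 0))
    L <- sv$u[, 1:r, drop = FALSE] %*% (d[1:r] * t(sv$v[, 1:r, drop = FALSE]))
    S <- sign(X - L + Y / mu) * pmax(abs(X - L + Y / mu) - lambda / mu, 0)
    Z <- X - L - S
    Y <- Y + mu * Z
    if (norm(Z, "F") / nx < tol) break
  }
  list(L = L, S = S)
}

# A small fully observed panel with deterministic values.
tiny_panel <- function(n = 3, p = 2, T = 4, seed = 1) {
  set.seed(seed)
  esr_panel(array(rnorm(n * p * T), c(n, p, T)),
            countries = sprintf("C%d", 1:n),
            variables = sprintf("Var%d", 1:p),
            years = 2010 + 0:(T - 1))
}

# Planted sparse one-lag VAR and a trajectory from it.
planted_var <- function(m = 10, T = 100, n_extra = 8, seed = 4) {
  set.seed(seed)
  A <- diag(0.5, m)
  nz <- sample(which(row(A) != col(A)), n_extra)
  A[nz] <- 0.3
  A <- A * 0.9 / max(Mod(eigen(A)$values))
  Fm <- matrix(0, m, T)
  st <- rnorm(m)
  for (t in seq_len(T)) {
    st <- drop(A %*% st) + rnorm(m)
    Fm[, t] <- st
  }
  list(A = A, F = Fm)
}

support_f1 <- function(est, truth) {
  tp <- sum(est & truth); fp <- sum(est & !truth); fn <- sum(!est & truth)
  2 * tp / (2 * tp + fp + fn)
}
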
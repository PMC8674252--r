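test_that("classical PCA matches the SVD oracle on random matrices", {
  set.seed(100)
  for (rep in 1:20) {
    X <- scale(matrix(rnorm(50 * 17), 50, 17), scale = FALSE)
    k <- sample(1:4, 1)
    fit <- fit_pca(X, k)
    sv <- svd(X)
    for (j in seq_len(k)) {
      v <- sv$v[, j]
      expect_lt(min(max(abs(fit$loadings[, j] - v)),
                    max(abs(fit$loadings[, j] + v))), 1e-8)
    }
    expect_lt(max(abs(fit$scores - X %*% fit$loadings)), 1e-10)
    expect_lt(max(abs(crossprod(fit$loadings) - diag(k))), 1e-8)
    # shares: non-increasing, in [0,1], all-components shares sum to 1
    expect_true(all(diff(fit$explained_variance_share) <= 1e-12))
    expect_equal(sum(fit$eigenvalues / sum(fit$eigenvalues)), 1)
  }
})

test_that("PCA handles forced rank and orthogonal-column cases", {
  set.seed(5)
  x1 <- rnorm(30); v1 <- rnorm(17)
  fit <- fit_pca(x1 %*% t(v1), 1)
  expect_equal(fit$explained_variance_share[1], 1.0)
  # orthogonal equal-norm columns, p = k: zero reconstruction error
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  fitq <- fit_pca(Q, 5)
  expect_lt(norm(Q - fitq$scores %*% t(fitq$loadings), "F"), 1e-10)
  expect_error(fit_pca(Q, 6), "out of range")
})

test_that("principal component pursuit attains the convex optimum", {
  set.seed(1)
  L0 <- matrix(rnorm(100 * 2), 100, 2) %*% matrix(rnorm(2 * 17), 2, 17)
  S0 <- matrix(0, 100, 17)
  spikes <- sample(1700, 85)
  S0[spikes] <- sample(c(-10, 10), 85, TRUE)
  X <- L0 + S0
  fit <- fit_rpca(X)
  oracle <- pcp_admm_oracle(X, fit$lambda)
  expect_lt(norm(fit$low_rank - oracle$L, "F") / norm(oracle$L, "F"), 1e-4)
  expect_lt(norm(fit$sparse - oracle$S, "F") / norm(oracle$S, "F"), 1e-4)
  expect_lt(fit$final_residual, 1e-7)
})

test_that("principal component pursuit recovers planted decompositions", {
  # squarish regime where the convex program provably identifies the truth
  set.seed(2)
  L0 <- matrix(rnorm(80 * 2), 80, 2) %*% matrix(rnorm(2 * 40), 2, 40)
  S0 <- matrix(0, 80, 40)
  spikes <- sample(3200, 160)
  S0[spikes] <- sample(c(-10, 10), 160, TRUE)
  fit <- fit_rpca(L0 + S0)
  expect_lt(norm(fit$low_rank - L0, "F") / norm(L0, "F"), 1e-3)
  expect_setequal(which(abs(fit$sparse) > 1e-3), spikes)
})

test_that("principal component pursuit limit cases behave", {
  set.seed(3)
  Xc <- matrix(rnorm(50 * 3), 50, 3) %*% matrix(rnorm(3 * 17), 3, 17)
  clean <- fit_rpca(Xc)
  expect_lt(max(abs(clean$sparse)), 1e-6)
  expect_lt(norm(clean$low_rank - Xc, "F") / norm(Xc, "F"), 1e-6)
  # lambda -> infinity: S -> 0, L -> X
  Xn <- Xc + matrix(rnorm(850, 0, 0.5), 50, 17)
  big <- fit_rpca(Xn, lambda = 1e8)
  expect_equal(max(abs(big$sparse)), 0)
  expect_lt(norm(big$low_rank - Xn, "F") / norm(Xn, "F"), 1e-6)
})

test_that("pursuit objective settles downward to its constrained optimum", {
  set.seed(4)
  L0 <- matrix(rnorm(60 * 2), 60, 2) %*% matrix(rnorm(2 * 20), 2, 20)
  S0 <- matrix(0, 60, 20); S0[sample(1200, 60)] <- 8
  fit <- fit_rpca(L0 + S0)
  tr <- fit$objective_trace
  n <- length(tr)
  # aggregate descent from the near-feasible phase onward, and no terminal
  # drift: the last value sits at the running minimum of the tail
  tail_part <- tr[ceiling(n / 3):n]
  expect_lt(tail_part[length(tail_part)], tail_part[1] + 1e-8)
  # terminal oscillations die out (infeasible iterates may briefly dip
  # below the constrained optimum, so strict monotonicity is not asserted)
  last5 <- tr[max(1, n - 4):n]
  expect_lt(diff(range(last5)), 1e-4 * abs(tr[n]))
  expect_lte(fit$final_residual, 1e-7)
})

test_that("robust sparse PCA reduces to classical PCA without penalties", {
  set.seed(6)
  for (k in c(1, 3)) {
    X <- scale(matrix(rnorm(40 * 17), 40, 17), scale = FALSE)
    f0 <- fit_pca(X, k)
    fs <- fit_robust_sparse_pca(X, sparse_pca_config(k = k))
    for (j in seq_len(k)) {
      expect_lt(min(max(abs(fs$loadings[, j] - f0$loadings[, j])),
                    max(abs(fs$loadings[, j] + f0$loadings[, j]))), 1e-6)
    }
    expect_true(all(diff(fs$objective_trace) <= 1e-10))
  }
})

test_that("l1 loading penalty increases loading sparsity monotonically in effect", {
  set.seed(7)
  X <- scale(matrix(rnorm(60 * 17), 60, 17), scale = FALSE)
  frac_zero <- function(C) mean(abs(C) < 1e-3 * max(abs(C)))
  f0 <- fit_robust_sparse_pca(X, sparse_pca_config(k = 2))
  f1 <- fit_robust_sparse_pca(X, sparse_pca_config(k = 2, loading_l1 = 3))
  expect_gt(frac_zero(f1$loadings), frac_zero(f0$loadings))
  expect_true(all(diff(f1$objective_trace) <= 1e-10))
})

test_that("a planted sparse loading direction is recovered at moderate penalty", {
  set.seed(8)
  v <- c(rep(1 / sqrt(5), 5), rep(0, 12))
  Xp <- rnorm(200, 0, 3) %*% t(v) + matrix(rnorm(200 * 17, 0, 0.3), 200, 17)
  fp <- fit_robust_sparse_pca(Xp, sparse_pca_config(k = 1, loading_l1 = 20))
  expect_setequal(which(abs(fp$loadings[, 1]) > 1e-2), 1:5)
})

test_that("sign alignment is an involution fixing aligned sequences", {
  set.seed(9)
  base <- matrix(rnorm(17), 17, 1)
  aligned <- lapply(1:6, function(t) base + 0.05 * matrix(rnorm(17), 17, 1))
  # force the risk-increasing base orientation so the sequence is a fixed point
  if (sum(aligned[[1]]) > 0) aligned <- lapply(aligned, function(l) -l)
  out <- align_signs_across_years(aligned)
  expect_equal(out$loadings, aligned)
  # flip odd years, realign: restored
  flipped <- aligned
  for (t in c(1, 3, 5)) flipped[[t]] <- -flipped[[t]]
  out2 <- align_signs_across_years(flipped)
  expect_equal(out2$loadings, aligned)
  # constant loadings unchanged
  const <- lapply(1:4, function(t) aligned[[1]])
  expect_equal(align_signs_across_years(const)$loadings, const)
})

test_that("sign alignment matches brute force over all orientations", {
  set.seed(10)
  T <- 6
  base <- matrix(rnorm(8), 8, 1)
  loads <- lapply(1:T, function(t)
    (base + 0.1 * matrix(rnorm(8), 8, 1)) * sample(c(-1, 1), 1))
  out <- align_signs_across_years(loads)
  # brute force: all 2^T orientations, minimize adjacent-year disagreement
  best <- NULL; best_cost <- Inf
  for (code in 0:(2^T - 1)) {
    s <- ifelse(bitwAnd(code, 2^(0:(T - 1))) > 0, -1, 1)
    cost <- sum(sapply(2:T, function(t)
      sum((loads[[t]] * s[t] - loads[[t - 1]] * s[t - 1])^2)))
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- s }
  }
  if (sum(loads[[1]] * best[1]) > 0) best <- -best   # same base orientation
  got <- sapply(1:T, function(t) out$flips[t, 1])
  expect_equal(got, best)
})

test_that("per-year PCA index tracks the latent factor cross-sectionally", {
  sim <- simulate_panel(sim_config(n_countries = 25, n_years = 8, seed = 13))
  prep <- preprocess_panel(sim$panel)
  res <- pca_index(prep$panel, "pca")
  for (t in seq_len(8)) {
    rho <- cor(res$index$values[, t], sim$truth$factors[, t],
               method = "spearman")
    expect_gte(abs(rho), 0.9)
  }
  # orientation metadata present
  expect_identical(res$index$orientation, "risk-increasing")
})

test_that("robust index resists gross corruption better than plain PCA", {
  sim <- simulate_panel(sim_config(n_countries = 25, n_years = 6, seed = 14))
  prep <- preprocess_panel(sim$panel)
  clean_pca <- pca_index(prep$panel, "pca")$index
  clean_rob <- pca_index(prep$panel, "robpca")$index
  # grossly corrupt one country's cells in one year of the standardized
  # panel (8 cross-sectional sds on 10 of 17 indicators)
  v <- prep$panel$values
  v[5, 1:10, 3] <- v[5, 1:10, 3] + 8
  dirty <- esr_panel(v, prep$panel$countries, prep$panel$variables,
                     prep$panel$years)
  dirty_pca <- pca_index(dirty, "pca")$index
  dirty_rob <- pca_index(dirty, "robpca")$index
  others <- setdiff(1:25, 5)
  shift <- function(a, b) {
    mean(abs(a$values[others, 3] - b$values[others, 3])) / sd(b$values[, 3])
  }
  expect_lt(shift(dirty_rob, clean_rob), 0.10)
  expect_lt(shift(dirty_rob, clean_rob), shift(dirty_pca, clean_pca))
})

test_that("a time-constant panel gives an identical index every year", {
  set.seed(15)
  slice <- matrix(rnorm(20 * 5), 20, 5)
  v <- array(rep(slice, 4), c(20, 5, 4))
  pan <- esr_panel(v, sprintf("c%d", 1:20), sprintf("x%d", 1:5), 2010:2013)
  prep <- standardize_per_year(pan)
  res <- pca_index(prep$panel, "pca")
  for (t in 2:4) expect_equal(res$index$values[, t], res$index$values[, 1])
})

test_that("the index is invariant to permuting countries or variables", {
  sim <- simulate_panel(sim_config(n_countries = 12, n_years = 5, seed = 16))
  prep <- preprocess_panel(sim$panel)
  base <- pca_index(prep$panel, "pca")$index
  set.seed(1)
  pc <- sample(12); pv <- sample(17)
  pan2 <- esr_panel(prep$panel$values[pc, pv, ],
                    prep$panel$countries[pc], prep$panel$variables[pv],
                    prep$panel$years)
  perm <- pca_index(pan2, "pca")$index
  expect_equal(perm$values[match(base$countries, perm$countries), ],
               base$values, tolerance = 1e-8)
})
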
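test_that("Kalman smoother equals joint-Gaussian conditioning on random systems", {
  set.seed(42)
  for (rep in 1:30) {
    m <- sample(1:2, 1)
    p <- sample(1:3, 1)
    T <- sample(3:6, 1)
    A <- matrix(rnorm(m * m, 0, 0.4), m, m)
    C <- matrix(rnorm(p * m), p, m)
    Qh <- matrix(rnorm(m * m), m, m); Q <- crossprod(Qh) / m + diag(0.2, m)
    Rv <- runif(p, 0.2, 1.5)
    pr_m <- rnorm(m); pr_Ph <- matrix(rnorm(m * m), m, m)
    pr_P <- crossprod(pr_Ph) / m + diag(0.5, m)
    y <- matrix(rnorm(p * T), p, T)
    ks <- kalman_smooth(y, A, C, Q, Rv, pr_m, pr_P)
    or <- joint_gaussian_smoother_oracle(y, A, C, Q, Rv, pr_m, pr_P)
    expect_lt(max(abs(ks$smoothed_mean - or$mean)), 1e-8)
    expect_lt(abs(ks$loglik - or$loglik), 1e-8)
    for (t in seq_len(T)) {
      expect_lt(max(abs(ks$smoothed_cov[, , t] -
                          or$cov[or$blk(t), or$blk(t), drop = FALSE])), 1e-8)
      if (t > 1) {
        expect_lt(max(abs(ks$lag_one_cov[, , t] -
                            or$cov[or$blk(t), or$blk(t - 1), drop = FALSE])),
                  1e-8)
      }
    }
  }
})

test_that("noiseless identity observation recovers the states", {
  set.seed(2)
  T <- 5; m <- 2
  y <- matrix(rnorm(m * T), m, T)
  ks <- kalman_smooth(y, diag(0.5, m), diag(m), diag(m), rep(1e-10, m),
                      rep(0, m), diag(10, m))
  expect_lt(max(abs(ks$smoothed_mean - y)), 1e-4)
})

test_that("zero transition decouples time slices into static posteriors", {
  set.seed(3)
  p <- 3; T <- 4
  C <- matrix(rnorm(p), p, 1)
  Rv <- runif(p, 0.3, 1)
  y <- matrix(rnorm(p * T), p, T)
  ks <- kalman_smooth(y, matrix(0, 1, 1), C, diag(1), Rv, 0, diag(1))
  for (t in 2:T) {
    # static Bayes: posterior of x ~ N(0,1) given y_t = C x + noise
    prec <- 1 + sum(C^2 / Rv)
    post <- sum(C * y[, t] / Rv) / prec
    expect_equal(ks$smoothed_mean[1, t], post, tolerance = 1e-8)
  }
})

test_that("EM recovers single-factor dynamics from long simulated series", {
  set.seed(11)
  A <- 0.7; p <- 8; T <- 200
  C <- rnorm(p)
  f <- numeric(T); f[1] <- rnorm(1, 0, sqrt(1 / (1 - A^2)))
  for (t in 2:T) f[t] <- A * f[t - 1] + rnorm(1)
  X <- C %*% t(f) + matrix(rnorm(p * T, 0, 0.3), p, T)
  fit <- fit_country_dfm(X, k = 1, max_iter = 500)
  expect_lt(abs(fit$transition[1, 1] - A), 0.1)
  cosine <- abs(sum(fit$loadings * C)) /
    sqrt(sum(fit$loadings^2) * sum(C^2))
  expect_gte(cosine, 0.95)
  expect_gte(abs(cor(fit$factors[1, ], f)), 0.95)
})

test_that("EM log-likelihood is monotone across many random starts", {
  set.seed(12)
  for (rep in 1:25) {
    p <- sample(3:6, 1); T <- sample(8:15, 1)
    a <- runif(1, -0.8, 0.8)
    C <- rnorm(p)
    f <- as.numeric(stats::filter(rnorm(T), a, "recursive"))
    X <- C %*% t(f) + matrix(rnorm(p * T, 0, 0.5), p, T)
    fit <- suppressWarnings(fit_country_dfm(X, k = 1, max_iter = 60))
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("time-constant series are rejected at the unit-root boundary", {
  X <- matrix(rep(c(1, -2, 0.5), 10), 3, 10)
  expect_error(fit_country_dfm(X, k = 1), "constant in time")
})

test_that("lasso VAR matches OLS at zero penalty and shrinks to zero", {
  pv <- planted_var(m = 6, T = 60, n_extra = 5, seed = 21)
  A0 <- fit_sparse_var(pv$F, alpha = 0)
  # equation-by-equation OLS oracle on the standardized series
  Z <- t(scale(t(pv$F)))
  Yv <- t(Z[, -1]); Xv <- t(Z[, -ncol(Z)])
  A_ols <- t(solve(crossprod(Xv), crossprod(Xv, Yv)))
  expect_lt(max(abs(unclass(A0) - A_ols)), 1e-6)
  Abig <- fit_sparse_var(pv$F, alpha = 1e4)
  expect_true(all(unclass(Abig) == 0))
  expect_error(fit_sparse_var(pv$F, alpha = -1), "alpha")
})

test_that("lasso VAR recovers planted sparse support at moderate penalty", {
  pv <- planted_var(m = 10, T = 100, n_extra = 8, seed = 4)
  Ah <- fit_sparse_var(pv$F, alpha = 0.2)
  f1 <- support_f1(abs(unclass(Ah)) > 1e-8, abs(pv$A) > 1e-12)
  expect_gte(f1, 0.8)
})

test_that("joint smoothing with decoupled blocks reproduces per-country fits", {
  sim <- simulate_panel(sim_config(n_countries = 6, n_years = 10, seed = 31))
  prep <- preprocess_panel(sim$panel)
  res <- suppressWarnings(dfm_index(prep$panel, with_interactions = FALSE,
                                    q_structure = "diagonal"))
  f1 <- t(sapply(res$joint$country_fits, function(f) f$factors[1, ]))
  expect_lt(max(abs(res$joint$smoothed_factors - f1)), 1e-8)
  # index equals the stacked smoothed factors for k = 1
  expect_equal(unname(res$index$values), unname(res$joint$smoothed_factors))
})

test_that("joint loadings are block-diagonal and interactions respect support", {
  sim <- simulate_panel(sim_config(n_countries = 4, n_years = 10, seed = 32))
  prep <- preprocess_panel(sim$panel)
  res <- suppressWarnings(dfm_index(prep$panel, alpha = 0.3,
                                    with_interactions = TRUE))
  Cj <- res$joint$joint_loadings
  p <- 17
  for (i in 1:4) for (j in 1:4) {
    blk <- Cj[(i - 1) * p + 1:p, j, drop = FALSE]
    if (i != j) expect_true(all(blk == 0))
  }
  # lasso zeros are exact zeros
  Af <- res$joint$interaction_fitted
  expect_true(any(Af == 0))
})

test_that("smoothing refines rather than distorts decoupled-truth panels", {
  cfg <- sim_config(n_countries = 8, n_years = 10, var_sparsity = 0, seed = 33)
  sim <- simulate_panel(cfg)
  prep <- preprocess_panel(sim$panel)
  res <- suppressWarnings(dfm_index(prep$panel))
  f1 <- t(sapply(res$joint$country_fits, function(f) f$factors[1, ]))
  for (i in 1:8) {
    expect_gte(cor(res$index$values[i, ], f1[i, ]), 0.95)
  }
})

test_that("the DFM index recovers the true factors per country", {
  sim <- simulate_panel(sim_config(n_countries = 15, n_years = 10, seed = 34))
  prep <- preprocess_panel(sim$panel)
  res <- suppressWarnings(dfm_index(prep$panel))
  rho <- sapply(1:15, function(i)
    abs(cor(res$index$values[i, ], sim$truth$factors[i, ],
            method = "spearman")))
  expect_gte(mean(rho), 0.8)
})

test_that("the DFM index is equivariant under country permutation", {
  sim <- simulate_panel(sim_config(n_countries = 6, n_years = 10, seed = 35))
  prep <- preprocess_panel(sim$panel)
  base <- suppressWarnings(dfm_index(prep$panel))$index
  set.seed(1)
  pc <- sample(6)
  pan2 <- esr_panel(prep$panel$values[pc, , ], prep$panel$countries[pc],
                    prep$panel$variables, prep$panel$years)
  perm <- suppressWarnings(dfm_index(pan2))$index
  expect_equal(perm$values[match(base$countries, perm$countries), ],
               base$values, tolerance = 1e-6)
})

test_that("hyperparameter grid tabulates reconstruction errors sensibly", {
  grid <- data.frame(n_countries = 6, n_variables = 8, n_years = 10,
                     obs_noise_sd = c(0.6, 0.1, 0.02))
  tab <- suppressWarnings(
    hyperparameter_search(grid, alpha_grid = 0.2, q_structures = "diagonal",
                          seed = 5))
  expect_equal(nrow(tab), 3L)
  # error decreases as observation noise shrinks
  expect_true(all(diff(tab$recon_error[order(-tab$obs_noise_sd)]) < 0))
  # one grid point equals a direct single-run computation
  cfg <- sim_config(n_countries = 6, n_variables = 8, n_years = 10,
                    obs_noise_sd = 0.6, seed = 5)
  sim <- simulate_panel(cfg)
  prep <- preprocess_panel(sim$panel)
  res <- suppressWarnings(dfm_index(prep$panel, alpha = 0.2,
                                    with_interactions = TRUE))
  direct <- factor_recon_error(res$joint$smoothed_factors, sim$truth$factors)
  expect_equal(tab$recon_error[tab$obs_noise_sd == 0.6], direct)
})
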
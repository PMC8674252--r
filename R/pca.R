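#' Classical principal component analysis
#'
#' Solves `minimize ||X - X C C'||_F^2 subject to C'C = I` via the
#' eigendecomposition of the sample covariance `X'X / (n-1)`. The input is
#' expected column-centered (the per-year standardization guarantees this);
#' no centering is applied, so `scores = X %*% loadings` exactly.
#'
#' @param X numeric `n x p` matrix, finite entries.
#' @param k number of components, `1 <= k <= min(n, p)`.
#' @return A `pca_result` list: `loadings` (`p x k`, orthonormal), `scores`
#'   (`n x k`), `eigenvalues` (length `min(n, p)`),
#'   `explained_variance_share` (length `k`).
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > min(n, p)) stop("k out of range [1, min(n, p)]")
  S <- crossprod(X) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)[seq_len(min(n, p))]
  C <- eg$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|.| entry of each loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(C[, j]))
    if (C[i, j] < 0) C[, j] <- -C[, j]
  }
  structure(
    list(loadings = C, scores = X %*% C, eigenvalues = ev,
         explained_variance_share = ev[seq_len(k)] / sum(ev)),
    class = "pca_result"
  )
}

#' Robust PCA by principal component pursuit
#'
#' Decomposes `X = L + S` by solving `minimize ||L||_* + lambda ||S||_1
#' subject to L + S = X` with an augmented Lagrangian / ADMM scheme:
#' alternating singular-value thresholding on `L` and entrywise soft
#' thresholding on `S`, with a dual update on the constraint. The
#' augmented-Lagrangian parameter is held at the standard heuristic
#' `n*p / (4 ||X||_1)`; a fixed parameter trades speed for reliable
#' convergence to the optimum of the convex program.
#'
#' @param X numeric matrix.
#' @param lambda sparse-part penalty; default `1/sqrt(max(n, p))`, the
#'   standard principal-component-pursuit choice.
#' @param tol convergence tolerance: both `||X - L - S||_F / ||X||_F` and
#'   the relative change of `S` between sweeps must fall below it.
#' @param max_iter iteration cap; non-convergence returns the current
#'   iterate with `converged = FALSE` and a warning.
#' @return An `rpca_result` list: `low_rank`, `sparse`, `lambda`,
#'   `n_iterations`, `final_residual`, `objective_trace`, `converged`.
#' @export
fit_rpca <- function(X, lambda = NULL, tol = 1e-7, max_iter = 5000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  n <- nrow(X); p <- ncol(X)
  if (is.null(lambda)) lambda <- 1 / sqrt(max(n, p))
  stopifnot(lambda > 0)
  norm_x <- norm(X, "F")
  if (norm_x == 0) {
    return(structure(list(low_rank = X, sparse = X * 0, lambda = lambda,
                          n_iterations = 0L, final_residual = 0,
                          objective_trace = numeric(0), converged = TRUE),
                     class = "rpca_result"))
  }
  mu <- n * p / (4 * sum(abs(X)))
  Y <- matrix(0, n, p)
  S <- matrix(0, n, p)
  S_prev <- S
  L <- matrix(0, n, p)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  res <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    sv <- svd(X - S + Y / mu)
    dthr <- pmax(sv$d - 1 / mu, 0)
    r <- max(1L, sum(dthr > 0))
    L <- sv$u[, seq_len(r), drop = FALSE] %*%
      (dthr[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
    S <- soft_threshold(X - L + Y / mu, lambda / mu)
    Z <- X - L - S
    Y <- Y + mu * Z
    obj <- c(obj, sum(dthr) + lambda * sum(abs(S)))
    res <- norm(Z, "F") / norm_x
    dS <- norm(S - S_prev, "F") / norm_x
    S_prev <- S
    if (res < tol && dS < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("fit_rpca: not converged after %d iterations (residual %.2e)",
                    iter, res))
  }
  structure(
    list(low_rank = L, sparse = S, lambda = lambda, n_iterations = iter,
         final_residual = res, objective_trace = obj, converged = converged),
    class = "rpca_result"
  )
}

#' Configuration for robust sparse PCA
#'
#' @param k number of components.
#' @param loading_l1,loading_l2 elastic-net weights on the loadings.
#' @param score_ridge ridge weight on the scores (default 0).
#' @param sparse_penalty l1 weight on the sparse corruption matrix `S`; 0
#'   disables the corruption term (`S` fixed at zero).
#' @param max_iter,tol alternating-minimization controls.
#' @return A `sparse_pca_config` list.
#' @export
sparse_pca_config <- function(k = 1L, loading_l1 = 0, loading_l2 = 0,
                              score_ridge = 0, sparse_penalty = 0,
                              max_iter = 500L, tol = 1e-9) {
  stopifnot(k >= 1, loading_l1 >= 0, loading_l2 >= 0, score_ridge >= 0,
            sparse_penalty >= 0)
  structure(list(k = as.integer(k), loading_l1 = loading_l1,
                 loading_l2 = loading_l2, score_ridge = score_ridge,
                 sparse_penalty = sparse_penalty,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "sparse_pca_config")
}

#' Robust sparse PCA
#'
#' Minimizes `||X - W C' - S||_F^2 + psi(C) + phi(W) + lambda ||S||_1`
#' subject to `C'C = I`, with `psi` an elastic net on the loadings and `phi`
#' a ridge on the scores. Alternating minimization: the score and
#' corruption updates are exact block minimizers; the loading update is an
#' exact orthogonal Procrustes step when the l1 weight is zero (the l2 part
#' of the elastic net is constant on the orthonormality constraint set) and
#' otherwise a proximal step followed by polar projection, accepted only if
#' it decreases the objective, so the objective trace is non-increasing.
#' Initialization is the classical PCA solution, making the penalty-free
#' problem coincide with [fit_pca()].
#'
#' @param X numeric `n x p` matrix.
#' @param config a [sparse_pca_config()].
#' @return A `sparse_pca_result` list: orthonormal `loadings`, `scores`,
#'   `sparse` corruption matrix, `objective_trace`, `n_iterations`,
#'   `converged`.
#' @export
fit_robust_sparse_pca <- function(X, config = sparse_pca_config()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  stopifnot(inherits(config, "sparse_pca_config"))
  n <- nrow(X); p <- ncol(X); k <- config$k
  if (k > min(n, p)) stop("k out of range")
  a1 <- config$loading_l1; phi <- config$score_ridge
  lam <- config$sparse_penalty
  C <- fit_pca(X, k)$loadings
  S <- matrix(0, n, p)
  W <- (X - S) %*% C / (1 + phi)
  objective <- function(W, C, S) {
    sum((X - W %*% t(C) - S)^2) + a1 * sum(abs(C)) +
      config$loading_l2 * sum(C^2) + phi * sum(W^2) + lam * sum(abs(S))
  }
  obj <- objective(W, C, S)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    R <- X - S
    W <- R %*% C / (1 + phi)                       # exact given C, S
    G <- crossprod(R, W)                           # p x k
    if (a1 == 0) {
      sv <- svd(G)                                 # exact Procrustes
      C <- sv$u %*% t(sv$v)
    } else {
      # proximal gradient on 2-smooth part, then polar projection; keep
      # the step only if the full objective decreases
      WtW <- crossprod(W)
      eta <- 1 / (2 * (max(diag(WtW)) + sum(abs(WtW))) + 1e-12)
      grad <- -2 * G + 2 * C %*% WtW
      Cc <- soft_threshold(C - eta * grad, eta * a1)
      sv <- svd(Cc)
      Cc <- sv$u %*% t(sv$v)
      if (objective(W, Cc, S) <= objective(W, C, S)) C <- Cc
    }
    if (lam > 0) {
      S <- soft_threshold(X - W %*% t(C), lam / 2)  # exact prox of the block
    }
    new_obj <- objective(W, C, S)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= config$tol * max(1, abs(obj))) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  if (!converged) {
    warning(sprintf("fit_robust_sparse_pca: not converged after %d iterations",
                    iter))
  }
  structure(
    list(loadings = C, scores = W, sparse = S, objective_trace = trace,
         n_iterations = iter, converged = converged, config = config),
    class = "sparse_pca_result"
  )
}

#' Align PCA loading signs across years
#'
#' Per-year PCA loadings are sign-indeterminate; year-to-year comparability
#' of the index requires a consistent orientation. Consecutive-year loading
#' vectors are flipped so their inner product is non-negative; the base
#' year is then oriented so the sum of its loadings is negative. All
#' constituent indicators are protective (higher values mean lower risk),
#' so this convention makes a larger index mean higher risk.
#'
#' @param loadings list of `p x k` per-year loading matrices (k = 1 columns
#'   are aligned independently for k > 1).
#' @return A list with `loadings` (aligned) and `flips` (`T x k` sign
#'   matrix applied; multiply scores by the same signs).
#' @export
align_signs_across_years <- function(loadings) {
  T <- length(loadings)
  stopifnot(T >= 1L)
  k <- ncol(loadings[[1L]])
  flips <- matrix(1, T, k)
  for (j in seq_len(k)) {
    for (t in seq_len(T)[-1L]) {
      prev <- loadings[[t - 1L]][, j] * flips[t - 1L, j]
      cur <- loadings[[t]][, j]
      ip <- sum(prev * cur)
      if (ip < 0) {
        flips[t, j] <- -1
      } else if (ip == 0) {
        flips[t, j] <- flips[t - 1L, j]
        warning("orthogonal consecutive loadings; keeping previous sign")
      }
    }
    # base orientation: risk-increasing (sum of loadings negative)
    base <- sum(loadings[[1L]][, j])
    s <- if (base * 1 > 0) -1 else 1
    flips[, j] <- flips[, j] * s
  }
  aligned <- lapply(seq_len(T), function(t) {
    sweep(loadings[[t]], 2L, flips[t, ], "*")
  })
  list(loadings = aligned, flips = flips)
}

#' Per-year PCA-based risk index
#'
#' Fits one PCA model per year on that year's country-by-variable slice and
#' assembles the retained component scores into a per-country yearly index,
#' sign-aligned across years and oriented risk-increasing. Method
#' `"robpca"` first separates the year slice into low-rank plus sparse
#' parts by principal component pursuit and applies classical PCA to the
#' low-rank part (which proxies the data with extreme values excluded);
#' `"robsparpca"` uses [fit_robust_sparse_pca()].
#'
#' @param panel a preprocessed (fully observed, per-year standardized)
#'   [esr_panel()].
#' @param method `"pca"`, `"robpca"` or `"robsparpca"`.
#' @param k number of retained components (the index uses the first).
#' @param rpca_lambda,sparse_config optional method-specific controls.
#' @return A list `index` (an [index_series()]) and `fits` (per-year model
#'   objects, with aligned loadings in `$loadings_aligned`).
#' @export
pca_index <- function(panel, method = c("pca", "robpca", "robsparpca"), k = 1L,
                      rpca_lambda = NULL, sparse_config = NULL) {
  stopifnot(inherits(panel, "esr_panel"))
  method <- match.arg(method)
  if (!all(panel$observed)) stop("panel must be fully observed; impute first")
  fits <- vector("list", length(panel$years))
  names(fits) <- panel$years
  loadings <- vector("list", length(panel$years))
  scores <- vector("list", length(panel$years))
  for (t in seq_along(panel$years)) {
    X <- to_wide(panel, panel$years[t])
    if (any(apply(X, 2L, stats::sd) < .Machine$double.eps)) {
      stop(sprintf("degenerate (constant-variable) slice in year %d",
                   panel$years[t]))
    }
    fit <- switch(
      method,
      pca = fit_pca(X, k),
      robpca = {
        rp <- fit_rpca(X, lambda = rpca_lambda)
        f <- fit_pca(rp$low_rank, k)
        f$rpca <- rp
        # scores of the original-scale data on the robust loadings are not
        # used: the index is the low-rank scores (L proxies X)
        f
      },
      robsparpca = {
        cfg <- sparse_config
        if (is.null(cfg)) cfg <- sparse_pca_config(k = k)
        cfg$k <- as.integer(k)
        fit_robust_sparse_pca(X, cfg)
      }
    )
    fits[[t]] <- fit
    loadings[[t]] <- fit$loadings
    scores[[t]] <- fit$scores
  }
  al <- align_signs_across_years(loadings)
  values <- vapply(seq_along(panel$years), function(t) {
    scores[[t]][, 1L] * al$flips[t, 1L]
  }, numeric(length(panel$countries)))
  for (t in seq_along(fits)) fits[[t]]$loadings_aligned <- al$loadings[[t]]
  idx <- index_series(values, method, panel$countries, panel$years,
                      metadata = list(k = k, rpca_lambda = rpca_lambda,
                                      scores_from = if (method == "robpca")
                                        "low_rank_part" else "data"))
  list(index = idx, fits = fits)
}
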
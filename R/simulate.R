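#' Configuration for the synthetic panel generator
#'
#' The generator emulates the statistical structure the index-construction
#' methods assume: a small number of latent factors per country evolving as a
#' first-order vector autoregression with sparse cross-country coupling,
#' observed through a linear loading map with Gaussian noise, plus optional
#' gross outlier cells and missing cells.
#'
#' Defaults define the package's reference study conditions: 20 countries,
#' 17 indicators, 10 years, one latent factor per country.
#'
#' @param n_countries,n_variables,n_years,k_factors panel dimensions and
#'   number of latent factors per country.
#' @param var_sparsity fraction in `[0,1]` of nonzero off-diagonal entries of
#'   the true cross-country transition matrix.
#' @param transition_scale target spectral radius of the transition matrix;
#'   must be `< 1` for stationary factor dynamics.
#' @param loading_scale standard deviation of the Gaussian loading entries.
#' @param obs_noise_sd standard deviation of the observation noise.
#' @param outlier_fraction fraction of cells corrupted by gross outliers.
#' @param outlier_magnitude outlier size in units of the per-variable cell
#'   standard deviation (scale-free).
#' @param missing_fraction fraction of cells set missing (completely at
#'   random; masks are disjoint from outlier cells by construction).
#' @param seed integer seed; fully determines the generated panel.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_countries = 20L, n_variables = 17L, n_years = 10L,
                       k_factors = 1L, var_sparsity = 0.1,
                       transition_scale = 0.7, loading_scale = 1,
                       obs_noise_sd = 0.2, outlier_fraction = 0,
                       outlier_magnitude = 5, missing_fraction = 0,
                       seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              n_variables = as.integer(n_variables),
              n_years = as.integer(n_years),
              k_factors = as.integer(k_factors),
              var_sparsity = var_sparsity,
              transition_scale = transition_scale,
              loading_scale = loading_scale,
              obs_noise_sd = obs_noise_sd,
              outlier_fraction = outlier_fraction,
              outlier_magnitude = outlier_magnitude,
              missing_fraction = missing_fraction,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_countries >= 1, n_variables >= 1, n_years >= 1, k_factors >= 1,
              var_sparsity >= 0, var_sparsity <= 1,
              outlier_fraction >= 0, outlier_fraction <= 1,
              missing_fraction >= 0, missing_fraction <= 1,
              loading_scale > 0, obs_noise_sd >= 0, outlier_magnitude > 0)
  })
  if (cfg$transition_scale >= 1) {
    stop("transition_scale must be < 1: the generated factor process must be stationary")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a panel with known ground truth
#'
#' Factors follow `F_t = A F_{t-1} + N(0, I)` where `A` is built as diagonal
#' AR coefficients plus sparse off-diagonal cross-country coupling, rescaled
#' to the configured spectral radius. Observations are `X_t = C F_t +
#' N(0, R)` with a per-country loading matrix `C` and diagonal `R`. A
#' burn-in run from the zero state brings the factors to (approximate)
#' stationarity before the recorded window. Outliers add
#' `outlier_magnitude` cell standard deviations with random sign; missing
#' cells are masked completely at random among non-outlier cells.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (an [esr_panel()]) and `truth`, a
#'   `ground_truth` list holding the true factor paths (`factors`,
#'   `n_countries*k_factors x n_years`), the transition matrix, the shared
#'   loading matrix (`n_variables x k_factors`), and the outlier and
#'   missing masks.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_countries = 5, seed = 7))
#' sim$panel
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_countries; p <- config$n_variables
  T <- config$n_years; k <- config$k_factors
  m <- n * k
  with_seed(config$seed, {
    # transition: diagonal AR part + sparse cross-country coupling
    A <- diag(stats::runif(m, 0.5, 0.9), m)
    if (m > 1L && config$var_sparsity > 0) {
      off <- which(row(A) != col(A))
      nz <- off[stats::runif(length(off)) < config$var_sparsity]
      A[nz] <- stats::rnorm(length(nz), 0, 0.1)
    }
    rad <- spectral_radius(A)
    if (rad > 0) A <- A * (config$transition_scale / rad)
    if (spectral_radius(A) >= 1) {
      stop("generated transition matrix is non-stationary (spectral radius >= 1)")
    }

    # one loading map shared by all countries: an indicator has the same
    # relation to the latent factor everywhere, as the observation
    # equation X_t = C F_t assumes
    loadings <- matrix(stats::rnorm(p * k, 0, config$loading_scale), p, k)

    burn <- 50L
    Fmat <- matrix(0, m, T)
    state <- rep(0, m)
    for (t in seq_len(burn)) state <- drop(A %*% state) + stats::rnorm(m)
    for (t in seq_len(T)) {
      state <- drop(A %*% state) + stats::rnorm(m)
      Fmat[, t] <- state
    }

    values <- array(NA_real_, c(n, p, T))
    for (i in seq_len(n)) {
      Fi <- Fmat[((i - 1L) * k + 1L):(i * k), , drop = FALSE]
      clean <- loadings %*% Fi                 # p x T
      noise <- matrix(stats::rnorm(p * T, 0, config$obs_noise_sd), p, T)
      values[i, , ] <- clean + noise
    }

    n_cells <- n * p * T
    outlier_mask <- array(FALSE, c(n, p, T))
    n_out <- round(config$outlier_fraction * n_cells)
    if (n_out > 0) {
      cells <- sample.int(n_cells, n_out)
      outlier_mask[cells] <- TRUE
      # per-variable sd of clean-signal+noise values, pooled over countries/years
      sds <- apply(values, 2, stats::sd)
      jj <- ((cells - 1L) %/% n) %% p + 1L     # variable index of each cell
      signs <- sample(c(-1, 1), n_out, replace = TRUE)
      values[cells] <- values[cells] + signs * config$outlier_magnitude * sds[jj]
    }

    missing_mask <- array(FALSE, c(n, p, T))
    n_miss <- round(config$missing_fraction * n_cells)
    if (n_miss > 0) {
      candidates <- which(!outlier_mask)
      missing_mask[sample(candidates, n_miss)] <- TRUE
      values[missing_mask] <- NA_real_
      # a fully-missing (country, variable) series cannot be imputed
      empty <- apply(missing_mask, c(1, 2), all)
      if (any(empty)) {
        w <- which(empty, arr.ind = TRUE)[1L, ]
        stop(sprintf("missing_fraction leaves series (%s) fully missing; lower it",
                     paste0("country ", w[1L], ", variable ", w[2L])))
      }
    }

    panel <- esr_panel(values,
                       countries = sprintf("C%02d", seq_len(n)),
                       variables = sprintf("Var%d", seq_len(p)),
                       years = 2010L + seq_len(T) - 1L,
                       observed = !missing_mask)
    truth <- structure(
      list(factors = Fmat, transition = A, loadings = loadings,
           outlier_mask = outlier_mask, missing_mask = missing_mask,
           config = config),
      class = "ground_truth"
    )
    list(panel = panel, truth = truth)
  })
}

#' Remove observed cells from a panel
#'
#' Masks `round(fraction * n_cells)` currently observed cells, either
#' uniformly at random or as contiguous year-runs within randomly chosen
#' (country, variable) series (real indicator panels miss contiguous years).
#'
#' @param panel an [esr_panel()].
#' @param fraction fraction (of all cells) to newly mask; in `[0, 1)`.
#' @param mechanism `"uniform"` or `"block"`.
#' @param seed integer seed.
#' @return The panel with additional cells masked.
#' @export
inject_missing <- function(panel, fraction, mechanism = c("uniform", "block"),
                           seed = 1L) {
  stopifnot(inherits(panel, "esr_panel"), fraction >= 0, fraction < 1)
  mechanism <- match.arg(mechanism)
  n_cells <- length(panel$values)
  n_new <- round(fraction * n_cells)
  if (n_new == 0L) return(panel)
  obs_idx <- which(panel$observed)
  if (n_new > length(obs_idx)) stop("fraction exceeds available observed cells")
  d <- dim(panel$values)
  mask <- panel$observed
  with_seed(seed, {
    if (mechanism == "uniform") {
      mask[sample(obs_idx, n_new)] <- FALSE
    } else {
      left <- n_new
      while (left > 0L) {
        i <- sample.int(d[1L], 1L)
        j <- sample.int(d[2L], 1L)
        run_obs <- which(mask[i, j, ])
        if (length(run_obs) == 0L) next
        len <- min(left, sample.int(max(1L, d[3L] %/% 2L), 1L), length(run_obs))
        start <- sample(run_obs, 1L)
        ts <- intersect(start:min(d[3L], start + len - 1L), run_obs)
        mask[i, j, ts] <- FALSE
        left <- left - length(ts)
      }
    }
  })
  empty <- apply(mask, 1L, function(sl) any(apply(!sl, 1L, all)))
  if (any(empty)) {
    stop(sprintf("fraction would leave country %s with a fully-missing series",
                 panel$countries[which(empty)[1L]]))
  }
  v <- panel$values
  v[!mask] <- NA_real_
  esr_panel(v, panel$countries, panel$variables, panel$years, observed = mask)
}

#' Synthetic macro target variables for the validation harness
#'
#' Produces per-(country, year) target series as functions of the true
#' latent factor plus noise, so the predictive-power comparison can be run
#' without real macro-economic data.
#'
#' @param truth `ground_truth` from [simulate_panel()] (requires
#'   `k_factors = 1`).
#' @param type `"linear"` (target `= 2 F + noise`) or `"nonlinear"`
#'   (`= F^2 + sin(F) + noise`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return Numeric matrix, countries x years.
#' @export
simulate_target <- function(truth, type = c("linear", "nonlinear"),
                            noise_sd = 0.1, seed = 1L) {
  type <- match.arg(type)
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$config$k_factors != 1L) {
    stop("targets are defined for single-factor ground truth")
  }
  Fmat <- truth$factors
  y <- switch(type,
              linear = 2 * Fmat,
              nonlinear = Fmat^2 + sin(Fmat))
  with_seed(seed, y + matrix(stats::rnorm(length(y), 0, noise_sd),
                             nrow(y), ncol(y)))
}
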
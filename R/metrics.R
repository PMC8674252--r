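#' Reconstruction R-squared with optional percentile trimming
#'
#' In analogy with the classical R-squared: RSS is the sum of squared
#' reconstruction residuals using only the retained components and TSS the
#' total sum of squares of the (standardized) original values, so the zero
#' predictor on standardized data scores exactly 0 and values can be
#' negative when reconstruction is worse than that (RSS > TSS). With
#' trimming, cells whose trimming statistic exceeds its given percentile
#' (computed over all cells) are excluded from both RSS and TSS, to gauge
#' the impact of outliers.
#'
#' @param X original data matrix.
#' @param X_hat reconstruction, same shape.
#' @param trim_percentile `NULL` (no trimming), 95 or 99.
#' @param trim_by `"value"` (percentile of `|X|`, default) or `"residual"`
#'   (percentile of `|X - X_hat|`).
#' @return `1 - RSS/TSS` over the included cells.
#' @export
reconstruction_r2 <- function(X, X_hat, trim_percentile = NULL,
                              trim_by = c("value", "residual")) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("shape mismatch")
  trim_by <- match.arg(trim_by)
  keep <- rep(TRUE, length(X))
  if (!is.null(trim_percentile)) {
    if (!trim_percentile %in% c(95, 99)) stop("trim_percentile must be NULL, 95 or 99")
    stat <- if (trim_by == "value") abs(X) else abs(X - X_hat)
    thr <- stats::quantile(stat, trim_percentile / 100, names = FALSE)
    keep <- as.vector(stat <= thr)
  }
  x <- as.vector(X)[keep]
  xh <- as.vector(X_hat)[keep]
  tss <- sum(x^2)
  if (tss == 0) stop("TSS is zero; R-squared undefined")
  1 - sum((x - xh)^2) / tss
}

# MacKinnon (1994) response-surface coefficients for the p-value of the
# Dickey-Fuller t-statistic, regression with constant, no trend. The
# polynomial is evaluated at the statistic and mapped through the standard
# normal cdf; the small-p branch applies below tau_star.
.adf_tau_star <- -1.61
.adf_tau_min <- -18.83
.adf_tau_max <- 2.74
.adf_smallp <- c(2.1659, 1.4412, 0.038269)
.adf_largep <- c(1.7339, 0.93202, -0.12745, -0.010368)

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression with intercept: `diff(y)_t = c + rho * y_{t-1} +
#' sum_i phi_i diff(y)_{t-i} + e_t`. The statistic is the t-ratio of
#' `rho`; the p-value uses the MacKinnon (1994) response-surface
#' approximation for the constant-only case. Small p-values reject the unit
#' root, i.e. certify stationarity. Lag order is chosen by AIC over
#' `0..max_lag` on a common estimation sample, then the chosen model is
#' refitted on the longest sample it allows.
#'
#' @param series numeric vector, length `>= 8`.
#' @param regression deterministic term; only `"constant"` is supported.
#' @param max_lag `"auto"` (Schwert rule `floor(12 * (T/100)^0.25)`) or a
#'   non-negative integer.
#' @return List with `statistic`, `pvalue`, `lag`.
#' @export
adf_test <- function(series, regression = "constant", max_lag = "auto") {
  series <- as.numeric(series)
  Tn <- length(series)
  if (Tn < 8L) stop("series too short for the ADF regression (need >= 8)")
  if (stats::sd(series) < 1e-12) stop("constant series: unit-root test undefined")
  regression <- match.arg(regression, "constant")
  if (identical(max_lag, "auto")) {
    max_lag <- floor(12 * (Tn / 100)^0.25)
  }
  max_lag <- min(as.integer(max_lag), Tn - 5L)
  max_lag <- max(max_lag, 0L)
  dy <- diff(series)
  build <- function(lag, start) {
    # rows t = start..(Tn-1) of the differenced series
    idx <- start:(Tn - 1L)
    y <- dy[idx]
    Xr <- cbind(1, series[idx])
    if (lag > 0L) {
      for (l in seq_len(lag)) Xr <- cbind(Xr, dy[idx - l])
    }
    list(y = y, X = Xr)
  }
  aic_of <- function(lag) {
    d <- build(lag, start = max_lag + 1L)  # common sample across candidates
    fit <- stats::lm.fit(d$X, d$y)
    n <- length(d$y)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + 2 * (lag + 2L)
  }
  lag <- if (max_lag > 0L) {
    which.min(vapply(0:max_lag, aic_of, numeric(1))) - 1L
  } else 0L
  d <- build(lag, start = lag + 1L)
  fit <- stats::lm.fit(d$X, d$y)
  n <- length(d$y)
  kpar <- ncol(d$X)
  s2 <- sum(fit$residuals^2) / (n - kpar)
  XtX_inv <- chol2inv(chol(crossprod(d$X)))
  se_rho <- sqrt(s2 * XtX_inv[2L, 2L])
  stat <- fit$coefficients[2L] / se_rho
  pvalue <- if (stat <= .adf_tau_min) 0 else if (stat >= .adf_tau_max) 1 else {
    cf <- if (stat <= .adf_tau_star) .adf_smallp else .adf_largep
    z <- sum(cf * stat^(seq_along(cf) - 1L))
    stats::pnorm(z)
  }
  list(statistic = unname(stat), pvalue = pvalue, lag = lag)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO: the ratio of the sum of squared off-diagonal correlations
#' to that sum plus the sum of squared partial (anti-image) correlations
#' computed from the inverse correlation matrix. Values near 1 indicate
#' the correlation structure is dominated by common factors and the data
#' are adequate for factor extraction.
#'
#' @param X data matrix (`n x p`, `n > p`).
#' @return Overall KMO in `[0, 1]`.
#' @export
kmo <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more observations than variables")
  R <- stats::cor(X)
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; KMO undefined"))
  D <- diag(1 / sqrt(diag(Rinv)))
  Q <- -D %*% Rinv %*% D                      # partial correlations off-diagonal
  off <- row(R) != col(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Spearman correlation between an index and per-country incidence series
#'
#' For every country with at least `min_years` overlapping years, computes
#' the Spearman rank correlation (and its p-value) between the index and
#' the incidence series over the overlap, and ranks countries by
#' correlation. Constant series yield `NA` entries.
#'
#' @param index an [index_series()].
#' @param incidence long data frame with columns `country`, `year`,
#'   `value`.
#' @param min_years minimum overlapping years (default 3).
#' @return Data frame `country`, `n_years`, `rho`, `pvalue`, sorted by
#'   decreasing `rho`.
#' @export
spearman_index_vs_incidence <- function(index, incidence, min_years = 3L) {
  stopifnot(inherits(index, "esr_index"),
            all(c("country", "year", "value") %in% names(incidence)))
  out <- list()
  for (cty in intersect(unique(incidence$country), index$countries)) {
    sub <- incidence[incidence$country == cty, ]
    yrs <- intersect(sub$year, index$years)
    if (length(yrs) < min_years) next
    iv <- index$values[match(cty, index$countries), match(yrs, index$years)]
    inc <- sub$value[match(yrs, sub$year)]
    if (stats::sd(iv) < 1e-12 || stats::sd(inc) < 1e-12) {
      out[[cty]] <- data.frame(country = cty, n_years = length(yrs),
                               rho = NA_real_, pvalue = NA_real_)
      next
    }
    ct <- suppressWarnings(stats::cor.test(iv, inc, method = "spearman"))
    out[[cty]] <- data.frame(country = cty, n_years = length(yrs),
                             rho = unname(ct$estimate), pvalue = ct$p.value)
  }
  if (!length(out)) stop("no country has enough overlapping years")
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(-df$rho, df$country, na.last = TRUE), ]
}

#' Per-year metric report for a fitted index
#'
#' Assembles the evaluation quantities reported for each method: the mean
#' (over years) explained-variance share of the retained component, the
#' mean reconstruction R-squared on the full data and on the 99th/95th
#' percentile-trimmed subsets, and the ADF stationarity test on the pooled
#' index series. For the DFM the explained-variance column is `NA`: no
#' eigenvalue decomposition underlies that method, so the share is not
#' defined, and only R-squared is reported.
#'
#' @param panel the preprocessed panel the method was fitted on.
#' @param index the fitted [index_series()].
#' @param fits per-year PCA fits from [pca_index()] (for PCA methods), or a
#'   `joint_dfm` from [dfm_index()].
#' @param r2_on for `"robpca"`, compute R-squared against `"data"` (default)
#'   or against the `"low_rank"` part; both interpretations are defensible
#'   and the choice is recorded in the output.
#' @return A `metric_report` data frame with one row per year plus
#'   aggregate attributes; see `summary` columns `explained_variance`,
#'   `r2_full`, `r2_99`, `r2_95`.
#' @export
metric_report <- function(panel, index, fits, r2_on = c("data", "low_rank")) {
  stopifnot(inherits(panel, "esr_panel"), inherits(index, "esr_index"))
  r2_on <- match.arg(r2_on)
  T <- length(panel$years)
  is_dfm <- inherits(fits, "joint_dfm")
  rows <- vector("list", T)
  for (t in seq_len(T)) {
    X <- to_wide(panel, panel$years[t])
    if (is_dfm) {
      n <- length(panel$countries)
      k <- ncol(fits$country_fits[[1L]]$loadings)
      f_t <- fits$smoothed_factors[, t]
      xh <- fits$joint_loadings %*% f_t
      X_hat <- matrix(xh, nrow = n, byrow = TRUE)
      ev <- NA_real_
    } else {
      fit <- fits[[t]]
      if (r2_on == "low_rank" && !is.null(fit$rpca)) X <- fit$rpca$low_rank
      C <- fit$loadings
      W <- if (!is.null(fit$rpca)) fit$rpca$low_rank %*% C else fit$scores
      X_hat <- W %*% t(C)
      ev <- if (!is.null(fit$explained_variance_share)) {
        fit$explained_variance_share[1L]
      } else {
        # sparse method: share of total sum of squares carried by the
        # first component's scores (no eigenvalue decomposition available)
        sum(fit$scores[, 1L]^2) / sum(X^2)
      }
    }
    rows[[t]] <- data.frame(
      year = panel$years[t],
      explained_variance = ev,
      r2_full = reconstruction_r2(X, X_hat),
      r2_99 = reconstruction_r2(X, X_hat, 99),
      r2_95 = reconstruction_r2(X, X_hat, 95))
  }
  df <- do.call(rbind, rows)
  adf <- adf_test(as.vector(t(index$values)))
  structure(df, class = c("metric_report", "data.frame"),
            method = index$method, r2_on = r2_on,
            trim_by = "value",
            adf_statistic = adf$statistic, adf_pvalue = adf$pvalue)
}

#' @export
print.metric_report <- function(x, ...) {
  m <- function(v) sprintf("%.1f +/- %.1f%%", 100 * mean(v), 100 * stats::sd(v))
  cat(sprintf("metric_report [%s]\n", attr(x, "method")))
  if (!all(is.na(x$explained_variance))) {
    cat("  mean explained variance:", m(x$explained_variance), "\n")
  } else {
    cat("  explained variance: not defined for this method\n")
  }
  cat("  mean R2 (full):", m(x$r2_full), "\n")
  cat("  mean R2 (99th):", m(x$r2_99), "\n")
  cat("  mean R2 (95th):", m(x$r2_95), "\n")
  cat(sprintf("  ADF on index: stat %.3f, p %.4g\n",
              attr(x, "adf_statistic"), attr(x, "adf_pvalue")))
  cat("  trimming by |original value|; R2 target:", attr(x, "r2_on"), "\n")
  invisible(x)
}
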
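#' Drop countries with too many missing cells
#'
#' Removes countries whose overall missing-cell fraction strictly exceeds
#' `max_missing_fraction` and records them, with their missing fractions, in
#' the report. This is the package's explicit, configurable stand-in for the
#' coverage-based reduction real indicator panels require.
#'
#' @param panel an [esr_panel()].
#' @param max_missing_fraction threshold in `[0, 1]`; default 0.5.
#' @return A list `panel` (filtered) and `report` (a `preprocess_report`).
#' @export
drop_sparse_countries <- function(panel, max_missing_fraction = 0.5) {
  stopifnot(inherits(panel, "esr_panel"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss_frac <- apply(!panel$observed, 1L, mean)
  drop <- miss_frac > max_missing_fraction
  if (all(drop)) stop("all countries exceed the missing-fraction threshold")
  dropped <- data.frame(country = panel$countries[drop],
                        missing_fraction = miss_frac[drop],
                        reason = sprintf("missing fraction %.3f > %.3f",
                                         miss_frac[drop], max_missing_fraction))
  keep <- which(!drop)
  out <- esr_panel(panel$values[keep, , , drop = FALSE],
                   panel$countries[keep], panel$variables, panel$years,
                   observed = panel$observed[keep, , , drop = FALSE])
  report <- preprocess_report(step = "drop_sparse_countries",
                              countries_dropped = dropped,
                              params = list(max_missing_fraction = max_missing_fraction))
  list(panel = out, report = report)
}

#' Impute missing panel cells
#'
#' Method `"interp_then_median"`: interior gaps within each (country,
#' variable) series are filled by linear interpolation in time; leading and
#' trailing gaps by that year's cross-country median of the variable,
#' computed over originally observed cells only (deterministic and
#' independent of country order). Observed cells are never changed.
#'
#' @param panel an [esr_panel()].
#' @param method imputation method; only `"interp_then_median"` is built in.
#' @return A list `panel` (fully observed) and `report`.
#' @export
impute <- function(panel, method = "interp_then_median") {
  stopifnot(inherits(panel, "esr_panel"))
  method <- match.arg(method, "interp_then_median")
  d <- dim(panel$values)
  v <- panel$values
  obs <- panel$observed
  series_obs <- apply(obs, c(1L, 2L), any)
  if (!all(series_obs)) {
    w <- which(!series_obs, arr.ind = TRUE)[1L, ]
    stop(sprintf("series (%s, %s) has no observed values; cannot impute",
                 panel$countries[w[1L]], panel$variables[w[2L]]))
  }
  n_imputed <- sum(!obs)
  if (n_imputed > 0L) {
    # same-year cross-country medians from originally observed cells
    med <- apply(panel$values, c(2L, 3L), function(x) {
      stats::median(x, na.rm = TRUE)
    })
    for (i in seq_len(d[1L])) {
      for (j in seq_len(d[2L])) {
        o <- obs[i, j, ]
        if (all(o)) next
        x <- v[i, j, ]
        to <- which(o)
        if (length(to) >= 2L) {
          interior <- which(!o & seq_len(d[3L]) > min(to) & seq_len(d[3L]) < max(to))
          if (length(interior)) {
            x[interior] <- stats::approx(to, x[to], xout = interior)$y
          }
        }
        edge <- which(is.na(x))
        if (length(edge)) {
          if (any(is.na(med[j, edge]))) {
            stop(sprintf(
              "variable %s has no observed value in some year; cannot impute boundary gaps",
              panel$variables[j]))
          }
          x[edge] <- med[j, edge]
        }
        v[i, j, ] <- x
      }
    }
  }
  out <- esr_panel(v, panel$countries, panel$variables, panel$years,
                   observed = array(TRUE, d))
  report <- preprocess_report(step = "impute",
                              n_cells_imputed = n_imputed,
                              imputation_method = method,
                              imputed_mask = !obs)
  list(panel = out, report = report)
}

#' Standardize a panel per year
#'
#' For every (year, variable) pair, centers and scales the cross-country
#' values to mean 0 and sample (n-1 denominator) standard deviation 1. The
#' means and standard deviations used are stored in the report so the
#' transformation can be inverted exactly.
#'
#' @param panel a fully observed [esr_panel()] (run [impute()] first).
#' @return A list `panel` (standardized) and `report` containing `means` and
#'   `sds` matrices (variable x year).
#' @export
standardize_per_year <- function(panel) {
  stopifnot(inherits(panel, "esr_panel"))
  if (!all(panel$observed)) {
    stop("panel has missing cells; impute before standardizing")
  }
  d <- dim(panel$values)
  means <- apply(panel$values, c(2L, 3L), mean)
  sds <- apply(panel$values, c(2L, 3L), stats::sd)
  if (any(sds < .Machine$double.eps)) {
    w <- which(sds < .Machine$double.eps, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero variance for variable %s in year %s (degenerate indicator)",
                 panel$variables[w[1L]], panel$years[w[2L]]))
  }
  v <- panel$values
  for (t in seq_len(d[3L])) {
    v[, , t] <- sweep(sweep(v[, , t, drop = FALSE], 2L, means[, t]),
                      2L, sds[, t], "/")
  }
  out <- esr_panel(v, panel$countries, panel$variables, panel$years)
  report <- preprocess_report(step = "standardize_per_year",
                              means = means, sds = sds)
  list(panel = out, report = report)
}

#' Invert a per-year standardization
#'
#' @param panel a standardized [esr_panel()].
#' @param report the report returned by [standardize_per_year()].
#' @return The panel on the original scale.
#' @export
unstandardize_per_year <- function(panel, report) {
  stopifnot(inherits(panel, "esr_panel"), !is.null(report$means))
  v <- panel$values
  for (t in seq_along(panel$years)) {
    v[, , t] <- sweep(sweep(v[, , t, drop = FALSE], 2L, report$sds[, t], "*"),
                      2L, report$means[, t], "+")
  }
  esr_panel(v, panel$countries, panel$variables, panel$years,
            observed = panel$observed)
}

#' @keywords internal
#' @noRd
preprocess_report <- function(step, ...) {
  structure(c(list(step = step), list(...)), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report:", x$step, "\n")
  if (!is.null(x$n_cells_imputed)) {
    cat(sprintf("  cells imputed: %d (%s)\n", x$n_cells_imputed,
                x$imputation_method))
  }
  if (!is.null(x$countries_dropped) && nrow(x$countries_dropped)) {
    cat("  countries dropped:\n")
    for (r in seq_len(nrow(x$countries_dropped))) {
      cat("   -", x$countries_dropped$country[r],
          x$countries_dropped$reason[r], "\n")
    }
  }
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: [drop_sparse_countries()], [impute()], then
#' [standardize_per_year()].
#'
#' @param panel an [esr_panel()].
#' @param max_missing_fraction passed to [drop_sparse_countries()].
#' @return A list `panel` and `reports` (one per stage).
#' @export
preprocess_panel <- function(panel, max_missing_fraction = 0.5) {
  s1 <- drop_sparse_countries(panel, max_missing_fraction)
  s2 <- impute(s1$panel)
  s3 <- standardize_per_year(s2$panel)
  list(panel = s3$panel,
       reports = list(drop = s1$report, impute = s2$report,
                      standardize = s3$report))
}
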
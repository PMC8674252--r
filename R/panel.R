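#' Country-by-variable-by-year indicator panel
#'
#' The panel is the universal data container of the package: a 3-D numeric
#' array of indicator values keyed by country, variable and year, together
#' with an observation mask. Unobserved cells are `NA` in `values` and
#' `FALSE` in `observed`; observed cells must be finite.
#'
#' @param values numeric array of dimension `n_countries x n_variables x
#'   n_years`.
#' @param countries,variables character vectors naming the first two array
#'   margins.
#' @param years integer vector of strictly increasing, contiguous calendar
#'   years.
#' @param observed logical array of the same dimension as `values`; defaults
#'   to `!is.na(values)`.
#'
#' @return An object of class `esr_panel`: a list with elements `countries`,
#'   `variables`, `years`, `values` and `observed`.
#' @export
#' @examples
#' p <- esr_panel(array(rnorm(2 * 3 * 4), c(2, 3, 4)),
#'                countries = c("A", "B"),
#'                variables = paste0("Var", 1:3),
#'                years = 2010:2013)
#' dim(p$values)
esr_panel <- function(values, countries, variables, years, observed = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array (country x variable x year)")
  }
  countries <- as.character(countries)
  variables <- as.character(variables)
  years <- as.integer(years)
  if (!all(dim(values) == c(length(countries), length(variables), length(years)))) {
    stop("array shape inconsistent with countries/variables/years lengths")
  }
  if (anyDuplicated(countries)) stop("duplicate country identifiers")
  if (anyDuplicated(variables)) stop("duplicate variable identifiers")
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("years must be strictly increasing and contiguous")
  }
  if (is.null(observed)) observed <- !is.na(values)
  observed <- array(as.logical(observed), dim = dim(values))
  if (any(observed & !is.finite(values))) {
    stop("observed cells must be finite (no unmasked non-finite values)")
  }
  values[!observed] <- NA_real_
  dimnames(values) <- dimnames(observed) <-
    list(countries, variables, as.character(years))
  structure(
    list(countries = countries, variables = variables, years = years,
         values = values, observed = observed),
    class = "esr_panel"
  )
}

#' @export
print.esr_panel <- function(x, ...) {
  n_miss <- sum(!x$observed)
  cat(sprintf("esr_panel: %d countries x %d variables x %d years (%d-%d)\n",
              length(x$countries), length(x$variables), length(x$years),
              min(x$years), max(x$years)))
  cat(sprintf("  missing cells: %d of %d (%.1f%%)\n",
              n_miss, length(x$values), 100 * n_miss / length(x$values)))
  invisible(x)
}

#' @export
dim.esr_panel <- function(x) dim(x$values)

#' Read a panel from long-format CSV
#'
#' Canonical on-disk format: a UTF-8 CSV with header
#' `country,year,variable,value`, one row per cell; an empty `value` field
#' marks a missing cell. Country and variable order is the file's
#' first-appearance order. Years are unioned across rows; cells absent from
#' the file are masked.
#'
#' @param path path to a CSV file.
#' @return An [esr_panel()].
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer",
                                             "character", "character"),
                        na.strings = NULL, fileEncoding = "UTF-8")
  need <- c("country", "year", "variable", "value")
  if (!all(need %in% names(df))) {
    stop("file must have columns country, year, variable, value")
  }
  key <- paste(df$country, df$year, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    first <- df[which(duplicated(key))[1L], ]
    stop(sprintf("duplicate (country, year, variable) key: (%s, %d, %s)",
                 first$country, first$year, first$variable))
  }
  raw <- trimws(df$value)
  blank <- raw == ""
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!blank & is.na(val))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' at data row %d", raw[bad[1L]], bad[1L]))
  }
  countries <- unique(df$country)
  variables <- unique(df$variable)
  years <- seq(min(df$year), max(df$year))
  values <- array(NA_real_, c(length(countries), length(variables), length(years)))
  i <- match(df$country, countries)
  j <- match(df$variable, variables)
  t <- match(df$year, years)
  values[cbind(i, j, t)] <- val
  esr_panel(values, countries, variables, years)
}

#' Write a panel to long-format CSV
#'
#' Inverse of [read_long_csv()]; missing cells are written with an empty
#' value field so the round trip is lossless.
#'
#' @param panel an [esr_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(panel, path) {
  stopifnot(inherits(panel, "esr_panel"))
  d <- dim(panel$values)
  idx <- expand.grid(i = seq_len(d[1L]), t = seq_len(d[3L]), j = seq_len(d[2L]))
  # country-major, then year, then variable: stable human-readable order
  idx <- idx[order(idx$i, idx$t, idx$j), ]
  v <- panel$values[cbind(idx$i, idx$j, idx$t)]
  df <- data.frame(country = panel$countries[idx$i],
                   year = panel$years[idx$t],
                   variable = panel$variables[idx$j],
                   value = ifelse(is.na(v), "", format(v, digits = 17)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract one year's country-by-variable matrix
#'
#' Returns the `n x p` slice consumed by the per-year PCA methods.
#'
#' @param panel an [esr_panel()].
#' @param year a year present in `panel$years`.
#' @return Numeric matrix (countries as rows, variables as columns).
#' @export
to_wide <- function(panel, year) {
  stopifnot(inherits(panel, "esr_panel"))
  t <- match(as.integer(year), panel$years)
  if (is.na(t)) stop(sprintf("year %s not in panel", year))
  m <- panel$values[, , t, drop = FALSE]
  dim(m) <- dim(panel$values)[1:2]
  dimnames(m) <- list(panel$countries, panel$variables)
  m
}

#' Per-country yearly index series
#'
#' One score per (country, year), produced by [pca_index()] or
#' [dfm_index()]. Oriented risk-increasing: larger values indicate higher
#' epidemiological susceptibility.
#'
#' @param values numeric matrix, countries x years.
#' @param method one of `"pca"`, `"robpca"`, `"robsparpca"`, `"dfm"`.
#' @param countries,years identifiers matching the rows/columns of `values`.
#' @param metadata list of run parameters recorded with the series.
#' @return An object of class `esr_index`.
#' @export
index_series <- function(values, method, countries, years, metadata = list()) {
  method <- match.arg(method, c("pca", "robpca", "robsparpca", "dfm"))
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(countries), ncol(values) == length(years))
  dimnames(values) <- list(countries, as.character(years))
  structure(
    list(method = method, values = values, orientation = "risk-increasing",
         countries = as.character(countries), years = as.integer(years),
         metadata = metadata),
    class = "esr_index"
  )
}

#' @export
print.esr_index <- function(x, ...) {
  cat(sprintf("esr_index [%s, %s]: %d countries x %d years\n",
              x$method, x$orientation, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write an index series as long CSV
#'
#' Columns `country,year,index,method`.
#'
#' @param index an [index_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(index, path) {
  stopifnot(inherits(index, "esr_index"))
  df <- data.frame(
    country = rep(index$countries, times = length(index$years)),
    year = rep(index$years, each = length(index$countries)),
    index = as.vector(index$values),
    method = index$method
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
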
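#' Root mean square error
#'
#' @param y,y_hat numeric vectors of equal positive length.
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0L || length(y) != length(y_hat)) {
    stop("y and y_hat must have equal positive length")
  }
  sqrt(mean((y - y_hat)^2))
}

#' Configuration for the predictive-power validation
#'
#' @param learners subset of `c("elastic_net_or_ols", "random_forest",
#'   "svm_rbf", "mars", "single_layer_nn")`.
#' @param n_folds outer cross-validation folds (default 5).
#' @param tuning_budget random-search draws for inner hyperparameter tuning
#'   (default 25); the inner split stays within each training fold, so no
#'   information leaks from the held-out fold.
#' @param seed integer; fixes fold assignment (shared across learners and
#'   regressor sets) and all tuning draws.
#' @return A `validation_config` list.
#' @export
validation_config <- function(learners = c("elastic_net_or_ols", "random_forest",
                                           "svm_rbf", "mars", "single_layer_nn"),
                              n_folds = 5L, tuning_budget = 25L, seed = 1L) {
  learners <- match.arg(learners, several.ok = TRUE)
  stopifnot(n_folds >= 2L, tuning_budget >= 1L)
  structure(list(learners = learners, n_folds = as.integer(n_folds),
                 tuning_budget = as.integer(tuning_budget),
                 seed = as.integer(seed)),
            class = "validation_config")
}

# Backend availability; a missing backend skips the learner with a reason.
#' @keywords internal
#' @noRd
learner_backend <- function(learner) {
  switch(learner,
         elastic_net_or_ols = "glmnet",
         random_forest = "randomForest",
         svm_rbf = "e1071",
         mars = "earth",
         single_layer_nn = "nnet")
}

# Fit one learner on (x, y) with inner random-search tuning on an 80/20
# split of the training data, and return a prediction closure. Fully
# deterministic given `seed`.
#' @keywords internal
fit_learner <- function(learner, x, y, tuning_budget = 25L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  with_seed(seed, {
    if (learner == "elastic_net_or_ols" && ncol(x) == 1L) {
      # single regressor: plain OLS
      fit <- stats::lm.fit(cbind(1, x), y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      return(function(newx) drop(cbind(1, as.matrix(newx)) %*% beta))
    }
    in_tr <- sample.int(n) <= round(0.8 * n)
    if (sum(in_tr) < 2L || sum(!in_tr) < 1L) in_tr <- rep(TRUE, n)
    tune <- function(draws, fit1) {
      scores <- vapply(draws, function(par) {
        pred <- tryCatch(fit1(par, x[in_tr, , drop = FALSE], y[in_tr]),
                         error = function(e) NULL)
        if (is.null(pred)) return(Inf)
        rmse(y[!in_tr], pred(x[!in_tr, , drop = FALSE]))
      }, numeric(1))
      draws[[which.min(scores)]]
    }
    switch(
      learner,
      elastic_net_or_ols = {
        draws <- replicate(tuning_budget, list(
          alpha = stats::runif(1), lambda = 10^stats::runif(1, -4, 0)),
          simplify = FALSE)
        fit1 <- function(par, xt, yt) {
          m <- glmnet::glmnet(xt, yt, alpha = par$alpha, lambda = par$lambda)
          function(nx) drop(stats::predict(m, as.matrix(nx)))
        }
        best <- tune(draws, fit1)
        fit1(best, x, y)
      },
      random_forest = {
        draws <- replicate(tuning_budget, list(
          mtry = sample.int(ncol(x), 1L),
          nodesize = sample(c(1L, 3L, 5L), 1L)), simplify = FALSE)
        fit1 <- function(par, xt, yt) {
          m <- randomForest::randomForest(xt, yt, ntree = 300,
                                          mtry = par$mtry,
                                          nodesize = par$nodesize)
          function(nx) unname(stats::predict(m, as.matrix(nx)))
        }
        best <- tune(draws, fit1)
        fit1(best, x, y)
      },
      svm_rbf = {
        draws <- replicate(tuning_budget, list(
          cost = 10^stats::runif(1, -1, 2),
          gamma = 10^stats::runif(1, -3, 0)), simplify = FALSE)
        fit1 <- function(par, xt, yt) {
          m <- e1071::svm(xt, yt, kernel = "radial", cost = par$cost,
                          gamma = par$gamma)
          function(nx) unname(stats::predict(m, as.matrix(nx)))
        }
        best <- tune(draws, fit1)
        fit1(best, x, y)
      },
      single_layer_nn = {
        draws <- replicate(tuning_budget, list(
          size = sample(1:8, 1L), decay = 10^stats::runif(1, -4, 0)),
          simplify = FALSE)
        fit1 <- function(par, xt, yt) {
          m <- nnet::nnet(xt, yt, size = par$size, decay = par$decay,
                          linout = TRUE, maxit = 200, trace = FALSE)
          function(nx) drop(stats::predict(m, as.matrix(nx)))
        }
        best <- tune(draws, fit1)
        fit1(best, x, y)
      },
      mars = {
        draws <- replicate(tuning_budget, list(
          degree = sample(1:2, 1L)), simplify = FALSE)
        fit1 <- function(par, xt, yt) {
          m <- earth::earth(xt, yt, degree = par$degree)
          function(nx) drop(stats::predict(m, as.matrix(nx)))
        }
        best <- tune(draws, fit1)
        fit1(best, x, y)
      },
      stop("unknown learner: ", learner)
    )
  })
}

#' Predictive-power comparison of index versus original variables
#'
#' For each target variable and learner, compares the outer-CV test RMSE of
#' a regression on the single index value against a regression on the full
#' set of original variables, over (country, year) observations. Fold
#' assignment is fixed by the seed and shared across learners and
#' regressor sets; hyperparameters are tuned by seeded random search inside
#' each training fold; features are standardized inside each training fold
#' (statistics from the training rows only) and targets are standardized
#' globally before fitting. A comparable RMSE for the index-only fit means
#' the one-dimensional summary retains the predictive content of the
#' original variables.
#'
#' @param panel preprocessed [esr_panel()] supplying the original
#'   variables as features.
#' @param targets named list of countries-by-years numeric matrices.
#' @param index an [index_series()] aligned with the panel.
#' @param config a [validation_config()].
#' @return A `validation_report` data frame: `learner`, `target`,
#'   `regressor_set`, `rmse_mean`, `rmse_sd`, plus a `ratio` column on
#'   index rows (`RMSE_index / RMSE_original`). Skipped learners are
#'   recorded in the `skipped` attribute.
#' @export
run_validation <- function(panel, targets, index, config = validation_config()) {
  stopifnot(inherits(panel, "esr_panel"), inherits(index, "esr_index"),
            is.list(targets), length(targets) >= 1L,
            !is.null(names(targets)))
  if (!identical(panel$countries, index$countries) ||
      !identical(panel$years, index$years)) {
    stop("panel and index keys misaligned: countries/years must match exactly")
  }
  n <- length(panel$countries); T <- length(panel$years); p <- length(panel$variables)
  n_obs <- n * T
  # observation rows: country-major within year
  feat <- matrix(0, n_obs, p)
  for (t in seq_len(T)) {
    feat[(t - 1L) * n + seq_len(n), ] <- to_wide(panel, panel$years[t])
  }
  colnames(feat) <- panel$variables
  # index$values is n x T: its column-major vector is country-major within
  # year, matching the feature row order above
  idx_feat <- matrix(as.vector(index$values), ncol = 1L)
  colnames(idx_feat) <- "index"
  folds <- with_seed(config$seed, sample(rep_len(seq_len(config$n_folds), n_obs)))
  skipped <- character(0)
  rows <- list()
  for (target_name in sort(names(targets))) {
    y_raw <- as.vector(as.matrix(targets[[target_name]]))
    if (length(y_raw) != n_obs) {
      stop(sprintf("target %s has %d values; expected %d (country x year)",
                   target_name, length(y_raw), n_obs))
    }
    y <- as.vector(scale(y_raw))             # targets standardized before fitting
    for (learner in sort(config$learners)) {
      backend <- learner_backend(learner)
      if (!requireNamespace(backend, quietly = TRUE)) {
        skipped <- unique(c(skipped, sprintf(
          "%s: backend package '%s' not installed", learner, backend)))
        next
      }
      for (set in c("original_variables", "index_only")) {
        xmat <- if (set == "index_only") idx_feat else feat
        fold_rmse <- numeric(config$n_folds)
        for (f in seq_len(config$n_folds)) {
          tr <- folds != f
          mu <- colMeans(xmat[tr, , drop = FALSE])
          sg <- apply(xmat[tr, , drop = FALSE], 2L, stats::sd)
          sg[sg < 1e-12] <- 1
          xtr <- sweep(sweep(xmat[tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
          xte <- sweep(sweep(xmat[!tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
          fit_seed <- config$seed + 7919L * f
          pred <- fit_learner(learner, xtr, y[tr],
                              tuning_budget = config$tuning_budget,
                              seed = fit_seed)
          fold_rmse[f] <- rmse(y[!tr], pred(xte))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          learner = learner, target = target_name, regressor_set = set,
          rmse_mean = mean(fold_rmse), rmse_sd = stats::sd(fold_rmse))
      }
    }
  }
  if (!length(rows)) stop("no learner could be run (all backends missing)")
  df <- do.call(rbind, rows)
  df$ratio <- NA_real_
  for (r in which(df$regressor_set == "index_only")) {
    mate <- which(df$learner == df$learner[r] & df$target == df$target[r] &
                    df$regressor_set == "original_variables")
    if (length(mate) == 1L) df$ratio[r] <- df$rmse_mean[r] / df$rmse_mean[mate]
  }
  structure(df, class = c("validation_report", "data.frame"),
            skipped = skipped, config = config)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report (RMSE for regression with original variables in parentheses)\n")
  for (tg in unique(x$target)) {
    cat(" target:", tg, "\n")
    sub <- x[x$target == tg, ]
    for (lr in unique(sub$learner)) {
      io <- sub[sub$learner == lr & sub$regressor_set == "index_only", ]
      ov <- sub[sub$learner == lr & sub$regressor_set == "original_variables", ]
      cat(sprintf("  %-20s %.3f (%.3f)\n", lr, io$rmse_mean, ov$rmse_mean))
    }
  }
  if (length(attr(x, "skipped"))) {
    cat(" skipped:", paste(attr(x, "skipped"), collapse = "; "), "\n")
  }
  invisible(x)
}
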
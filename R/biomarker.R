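# Cross-validated biomarker regression: feature-size selection over an
# importance ranking (rfcv-style) and 70/30 train/test evaluation, with
# the regressor behind an injectable contract so the pipeline logic is
# testable with a deterministic stub.

#' Random-forest regressor contract
#'
#' Wraps [randomForest::randomForest] (1,000 trees by default, the
#' conventional setting) behind the fit/predict/importances contract
#' used by [cv_feature_sizes()], [train_evaluate()] and
#' [compare_ranks()].  Feature matrices are features x samples
#' throughout.
#'
#' @param ntree number of trees.
#' @return a regressor: list of `fit(X, y, seed)`, `predict(X)` and
#'   `importances()`.
#' @export
rf_regressor <- function(ntree = 1000L) {
  model <- NULL
  list(
    fit = function(X, y, seed = NULL) {
      local_seed(seed, {
        model <<- randomForest::randomForest(x = as.data.frame(t(X)),
                                             y = y, ntree = ntree)
      })
      invisible(NULL)
    },
    predict = function(X) {
      unname(stats::predict(model, as.data.frame(t(X))))
    },
    importances = function() {
      imp <- model$importance[, 1L]
      names(imp) <- rownames(model$importance)
      imp
    })
}

#' Deterministic linear-model stub regressor
#'
#' A least-squares regressor satisfying the same contract as
#' [rf_regressor()]; importances are absolute fitted coefficients.
#' Useful for fast, fully deterministic pipeline tests.
#'
#' @return a regressor (see [rf_regressor()]).
#' @export
linear_regressor <- function() {
  coefs <- NULL
  feats <- NULL
  list(
    fit = function(X, y, seed = NULL) {
      df <- as.data.frame(t(X))
      names(df) <- paste0("f", seq_len(nrow(X)))
      fit <- stats::lm(y ~ ., data = df, singular.ok = TRUE)
      cf <- stats::coef(fit)[-1L]
      cf[is.na(cf)] <- 0
      coefs <<- c(`(Intercept)` = unname(stats::coef(fit)[1L]), cf)
      feats <<- rownames(X)
      invisible(NULL)
    },
    predict = function(X) {
      as.numeric(coefs[1L] + crossprod(X, coefs[-1L]))
    },
    importances = function() {
      imp <- abs(coefs[-1L])
      names(imp) <- feats
      imp
    })
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums relative abundances within rank labels and renormalizes each
#' sample to 1; `rank = "zotu"` keeps taxon-level relative abundances.
#' Taxa without a label at the requested rank are grouped under
#' `"unassigned"`.
#'
#' @param table abundance matrix (taxa x samples).
#' @param annotation annotation data.frame with `taxon_id` plus the rank
#'   column.
#' @param rank `"zotu"`, `"order"` or `"class"`.
#' @return feature matrix (features x samples) of relative abundances
#'   with unit column sums.
#' @export
aggregate_rank <- function(table, annotation, rank = c("zotu", "order",
                                                       "class")) {
  rank <- match.arg(rank)
  check_table(table)
  if (any(colSums(table) == 0)) stop("all-zero sample in table")
  rel <- sweep(table, 2L, colSums(table), "/")
  if (rank == "zotu") return(rel)
  if (!rank %in% names(annotation))
    stop("annotation lacks a '", rank, "' column")
  lab <- annotation[[rank]][match(rownames(table), annotation$taxon_id)]
  lab[is.na(lab)] <- "unassigned"
  out <- rowsum(rel, lab)
  sweep(out, 2L, colSums(out), "/")
}

#' Cross-validated feature-size selection
#'
#' Ranks features by importance from a fit on the full data, then
#' evaluates `k`-fold cross-validated mean squared error at
#' geometrically shrinking feature-set sizes (halving from the full set
#' down to 1), averaged over `repeats` fold assignments.  The chosen
#' size is the smallest whose error is within `(1 + tol)` of the
#' minimum.
#'
#' @param X feature matrix (features x samples).
#' @param y numeric response, one value per sample.
#' @param regressor a regressor contract, e.g. [rf_regressor()].
#' @param k number of folds (<= number of samples).
#' @param repeats fold-assignment repeats.
#' @param tol tolerance of the chosen-size rule.
#' @param seed optional seed.
#' @return list with `sizes` (strictly decreasing), `cv_error` (MSE per
#'   size) and `chosen_size`.
#' @export
cv_feature_sizes <- function(X, y, regressor = rf_regressor(), k = 10L,
                             repeats = 5L, tol = 0.05, seed = NULL) {
  stopifnot(is.matrix(X), length(y) == ncol(X), repeats >= 1L)
  n <- ncol(X)
  if (k > n) stop("more folds than samples")
  p <- nrow(X)
  sizes <- p
  while (sizes[length(sizes)] > 1L)
    sizes <- c(sizes, max(1L, sizes[length(sizes)] %/% 2L))
  sizes <- unique(as.integer(sizes))
  seeds <- derive_seeds(seed, 1L + repeats)
  regressor$fit(X, y, seed = seeds[1L])
  ranking <- order(regressor$importances(), decreasing = TRUE)
  err <- matrix(NA_real_, length(sizes), repeats)
  for (r in seq_len(repeats)) {
    folds <- local_seed(seeds[1L + r],
                        sample(rep_len(seq_len(k), n)))
    for (si in seq_along(sizes)) {
      top <- ranking[seq_len(sizes[si])]
      se <- 0
      for (f in seq_len(k)) {
        test <- folds == f
        regressor$fit(X[top, !test, drop = FALSE], y[!test],
                      seed = seeds[1L + r])
        pred <- regressor$predict(X[top, test, drop = FALSE])
        se <- se + sum((pred - y[test])^2)
      }
      err[si, r] <- se / n
    }
  }
  cv_error <- rowMeans(err)
  # absolute floor keeps the rule meaningful when errors are numerically 0
  tiny <- 1e-8 * max(stats::var(y), .Machine$double.eps)
  ok <- cv_error <= (1 + tol) * min(cv_error) + tiny
  list(sizes = sizes, cv_error = cv_error,
       chosen_size = min(sizes[ok]))
}

#' Train/test evaluation of a biomarker model
#'
#' Random (stratification-free) split into a training fraction and a
#' held-out test set; prediction accuracy is reported as test-set
#' explained variance on a percent scale,
#' `100 * (1 - MSE_test / Var(y_test))`, which is at most 100 and can be
#' negative for models worse than the test-set mean.
#'
#' @param X feature matrix (features x samples).
#' @param y numeric response.
#' @param regressor a regressor contract.
#' @param feature_subset row indices or names to use; `NULL` for all.
#' @param train_fraction fraction of samples used for training.
#' @param seed optional seed.
#' @return list with `n_features_used`, `train_fraction`,
#'   `accuracy_percent`, `mse_test` and `seed`.
#' @export
train_evaluate <- function(X, y, regressor = rf_regressor(),
                           feature_subset = NULL, train_fraction = 0.7,
                           seed = NULL) {
  stopifnot(is.matrix(X), length(y) == ncol(X),
            train_fraction > 0, train_fraction < 1)
  if (!is.null(feature_subset)) X <- X[feature_subset, , drop = FALSE]
  if (nrow(X) == 0L) stop("empty feature subset")
  n <- ncol(X)
  seeds <- derive_seeds(seed, 2L)
  train <- local_seed(seeds[1L],
                      sort(sample.int(n, round(train_fraction * n))))
  test <- setdiff(seq_len(n), train)
  if (length(test) < 2L) stop("test set too small")
  yv <- stats::var(y[test])
  if (yv == 0) stop("zero test-set variance; accuracy undefined")
  regressor$fit(X[, train, drop = FALSE], y[train], seed = seeds[2L])
  pred <- regressor$predict(X[, test, drop = FALSE])
  mse <- mean((pred - y[test])^2)
  list(n_features_used = nrow(X), train_fraction = train_fraction,
       accuracy_percent = 100 * (1 - mse / yv), mse_test = mse,
       seed = seed)
}

#' Compare biomarker models across taxonomic ranks
#'
#' Runs feature-size selection and train/test evaluation per rank
#' (class, order, taxon-level) on the same response and reports one
#' model per rank.
#'
#' @param table abundance matrix (taxa x samples).
#' @param annotation annotation data.frame with `class` and `order`
#'   columns.
#' @param y numeric response, one value per sample.
#' @param regressor a regressor contract.
#' @param ranks ranks to evaluate.
#' @param k,repeats,tol passed to [cv_feature_sizes()].
#' @param train_fraction passed to [train_evaluate()].
#' @param seed optional seed.
#' @return data.frame with one row per rank: `taxonomic_rank`,
#'   `n_features_used`, `chosen_size`, `train_fraction`,
#'   `accuracy_percent`.
#' @export
compare_ranks <- function(table, annotation, y,
                          regressor = rf_regressor(),
                          ranks = c("class", "order", "zotu"), k = 10L,
                          repeats = 5L, tol = 0.05, train_fraction = 0.7,
                          seed = NULL) {
  seeds <- derive_seeds(seed, 2L * length(ranks))
  rows <- lapply(seq_along(ranks), function(i) {
    Xr <- aggregate_rank(table, annotation, ranks[i])
    cv <- cv_feature_sizes(Xr, y, regressor, k = min(k, ncol(Xr)),
                           repeats = repeats, tol = tol, seed = seeds[i])
    regressor$fit(Xr, y, seed = seeds[i])
    top <- order(regressor$importances(),
                 decreasing = TRUE)[seq_len(cv$chosen_size)]
    rep <- train_evaluate(Xr, y, regressor, feature_subset = top,
                          train_fraction = train_fraction,
                          seed = seeds[length(ranks) + i])
    data.frame(taxonomic_rank = ranks[i],
               n_features_used = rep$n_features_used,
               chosen_size = cv$chosen_size,
               train_fraction = rep$train_fraction,
               accuracy_percent = rep$accuracy_percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
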
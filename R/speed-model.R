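#' Ordinary least-squares speed model
#'
#' Fits speeds on a song-by-feature design with an intercept. Features enter
#' unstandardized (raw evidence scale); pass `standardize = TRUE` to z-score
#' them first (the scaling is stored and applied at prediction time).
#'
#' @param X numeric matrix, songs as rows, selected features as columns.
#' @param y per-song speeds.
#' @param standardize z-score the columns of `X` before fitting.
#' @return An object of class `regression_model`: `feature_ids` (column
#'   names), `coefficients`, `intercept`.
#' @export
fit_linear <- function(X, y, standardize = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) <= ncol(X) + 1) {
    stop("singular design: need more songs than features plus one")
  }
  center <- scale_ <- NULL
  if (standardize && ncol(X) > 0) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  Z <- cbind(`(Intercept)` = 1, X)
  dec <- qr(Z)
  if (dec$rank < ncol(Z)) stop("singular design: rank-deficient feature set")
  beta <- qr.coef(dec, y)
  structure(
    list(feature_ids = colnames(X), coefficients = beta[-1],
         intercept = unname(beta[1]), center = center, scale = scale_),
    class = "regression_model"
  )
}

#' Predict speeds from a fitted model
#'
#' @param object a `regression_model`.
#' @param newdata matrix with (at least) the model's feature columns.
#' @param ... unused.
#' @return Numeric vector of predicted speeds.
#' @export
predict.regression_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$feature_ids, drop = FALSE]
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  }
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> %d features, intercept %.3f\n",
              length(x$coefficients), x$intercept))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Pairwise feature pre-selection
#'
#' Enumerates every unordered pair of features (p * (p - 1) / 2 pairs; 17955
#' for 190 features), fits a two-feature linear model per pair, and ranks the
#' pairs by the Pearson correlation between fitted and measured speeds (the
#' multiple correlation of the pair, computed in closed form from the
#' correlation matrix). The `n_keep` features occurring most frequently in
#' the top `top_frac` of pairs (rounded up, boundary ties included) are
#' returned, with frequency ties broken toward the feature with the higher
#' best-pair correlation.
#'
#' @param X song-by-feature matrix.
#' @param y per-song speeds.
#' @param n_keep number of features to retain.
#' @param top_frac fraction of best pairs counted.
#' @return Integer feature indices (length `n_keep`), with attributes
#'   `n_pairs`, `counts` and `best_pair_pcc`.
#' @export
preselect_pairs <- function(X, y, n_keep = 10, top_frac = 0.10) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) < 12) stop("at least 12 songs are required for pre-selection")
  if (stats::sd(y) == 0) stop("undefined PCC: constant speed vector")
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  r[is.na(r)] <- 0
  C <- suppressWarnings(stats::cor(X))
  C[is.na(C)] <- 0
  idx <- which(upper.tri(C), arr.ind = TRUE)
  n_pairs <- nrow(idx)
  r1 <- r[idx[, 1]]; r2 <- r[idx[, 2]]; r12 <- C[idx]
  denom <- 1 - r12^2
  R2 <- ifelse(denom < 1e-12, pmax(r1^2, r2^2),
               (r1^2 + r2^2 - 2 * r1 * r2 * r12) / denom)
  pair_pcc <- sqrt(pmax(pmin(R2, 1), 0))
  n_top <- ceiling(top_frac * n_pairs)
  thr <- sort(pair_pcc, decreasing = TRUE)[n_top]
  sel <- pair_pcc >= thr
  counts <- tabulate(c(idx[sel, 1], idx[sel, 2]), nbins = p)
  best <- numeric(p)
  for (j in 1:2) {
    agg <- tapply(pair_pcc, idx[, j], max)
    ids <- as.integer(names(agg))
    best[ids] <- pmax(best[ids], agg)
  }
  keep <- order(-counts, -best)[seq_len(min(n_keep, p))]
  structure(as.integer(keep), n_pairs = n_pairs, counts = counts,
            best_pair_pcc = best)
}

#' Correlation-based feature pre-selection
#'
#' The simple variant: retain the `n_keep` features with the largest absolute
#' Pearson correlation with the speeds.
#'
#' @inheritParams preselect_pairs
#' @return Integer feature indices.
#' @export
preselect_correlation <- function(X, y, n_keep = 10) {
  if (stats::sd(y) == 0) stop("undefined PCC: constant speed vector")
  r <- suppressWarnings(as.numeric(stats::cor(as.matrix(X), y)))
  r[is.na(r)] <- 0
  as.integer(order(-abs(r))[seq_len(min(n_keep, length(r)))])
}

#' Cross-validation fold assignment
#'
#' Songs are assigned to `k` folds at random (from `seed`), with sizes as
#' equal as possible: 52 songs over 10 folds gives 8 folds of 5 and 2 folds
#' of 6.
#'
#' @param n number of songs.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 10, seed = 1) {
  sizes <- rep(floor(n / k), k)
  rem <- n %% k
  if (rem > 0) sizes[k - seq_len(rem) + 1L] <- sizes[k - seq_len(rem) + 1L] + 1L
  with_seed(seed, sample(rep(seq_len(k), times = sizes)))
}

# All non-empty subsets of m items as lists of index vectors.
all_subsets <- function(m) {
  lapply(seq_len(2^m - 1L), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
  })
}

# Score every non-empty subset of the candidate features by k-fold
# cross-validated RMSE on (X, y) and return the best one. Normal-equation
# solves on precomputed cross-products keep the 2^m - 1 subset sweep cheap.
best_subset_cv <- function(X, y, candidate_ids, k = 9, seed = 1) {
  n <- nrow(X)
  folds <- make_folds(n, k, seed)
  Z <- cbind(1, X[, candidate_ids, drop = FALSE])
  m <- length(candidate_ids)
  subsets <- all_subsets(m)
  preds <- matrix(NA_real_, nrow = n, ncol = length(subsets))
  bad <- logical(length(subsets))
  for (f in seq_len(k)) {
    val <- folds == f
    Ztr <- Z[!val, , drop = FALSE]
    G <- crossprod(Ztr)
    gy <- crossprod(Ztr, y[!val])
    Zval <- Z[val, , drop = FALSE]
    for (s in seq_along(subsets)) {
      cols <- c(1L, subsets[[s]] + 1L)
      beta <- tryCatch(solve(G[cols, cols, drop = FALSE], gy[cols]),
                       error = function(e) NULL)
      if (is.null(beta)) { bad[s] <- TRUE; next }
      preds[val, s] <- Zval[, cols, drop = FALSE] %*% beta
    }
  }
  if (any(bad)) {
    warning(sum(bad), " singular candidate subset(s) skipped")
  }
  rmses <- sqrt(colMeans((preds - y)^2))
  rmses[bad | is.na(rmses)] <- Inf
  # near-ties in validation RMSE are resolved toward the smaller subset
  rmin <- min(rmses)
  tied <- which(rmses <= rmin + 1e-9 * (1 + rmin))
  sizes <- lengths(subsets[tied])
  s_best <- tied[which.min(sizes)]
  list(subset = candidate_ids[subsets[[s_best]]],
       inner_rmse = rmses[s_best])
}

#' Nested cross-validated feature-subset regression
#'
#' The outer loop splits songs into `k_outer` folds ([make_folds()]); each
#' trial holds one fold out as a test set. On the development folds only,
#' `n_pre` features are pre-selected ([preselect_pairs()] by default), every
#' non-empty subset of them (1023 for 10) is scored by `k_inner`-fold
#' cross-validated RMSE, and the best subset, refit on the full development
#' set, predicts the held-out fold. Predictions are pooled over trials into
#' an overall RMSE and Pearson correlation. The held-out fold is never read
#' during pre-selection or subset choice.
#'
#' @param X song-by-feature matrix (columns named).
#' @param y per-song speeds.
#' @param seed integer seed driving fold assignment.
#' @param k_outer,k_inner outer and inner fold counts.
#' @param n_pre number of pre-selected features per trial.
#' @param preselect `"pairs"` or `"correlation"`.
#' @return An object of class `cv_report`: fold assignment, per-trial
#'   pre-selections, chosen subsets and coefficients, pooled `predictions`,
#'   `rmse`, `pcc`, `explained_variance` (= pcc^2) and per-feature
#'   `selection_counts`.
#' @export
nested_cv <- function(X, y, seed = 1, k_outer = 10, k_inner = 9,
                      n_pre = 10, preselect = c("pairs", "correlation")) {
  X <- as.matrix(X)
  preselect <- match.arg(preselect)
  n <- nrow(X)
  if (n < 20) stop("at least 20 songs are required for nested CV")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  folds <- make_folds(n, k_outer, seed)
  predictions <- rep(NA_real_, n)
  trials <- vector("list", k_outer)
  for (i in seq_len(k_outer)) {
    test <- folds == i
    Xd <- X[!test, , drop = FALSE]
    yd <- y[!test]
    pre <- if (preselect == "pairs") {
      preselect_pairs(Xd, yd, n_keep = n_pre)
    } else {
      preselect_correlation(Xd, yd, n_keep = n_pre)
    }
    best <- best_subset_cv(Xd, yd, as.integer(pre), k = k_inner,
                           seed = child_seed(seed, i))
    model <- fit_linear(Xd[, best$subset, drop = FALSE], yd)
    predictions[test] <- predict(model, X[test, , drop = FALSE])
    trials[[i]] <- list(
      fold = i,
      preselected = as.integer(pre),
      subset = as.integer(best$subset),
      inner_rmse = best$inner_rmse,
      coefficients = stats::setNames(model$coefficients,
                                     colnames(X)[best$subset]),
      intercept = model$intercept
    )
  }
  counts <- tabulate(unlist(lapply(trials, `[[`, "subset")),
                     nbins = ncol(X))
  names(counts) <- colnames(X)
  r <- pcc(y, predictions)
  structure(
    list(folds = folds, trials = trials, predictions = predictions,
         observed = y, rmse = rmse(y, predictions), pcc = r,
         explained_variance = r^2, selection_counts = counts,
         seed = seed, preselect = preselect),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d songs, %d trials | RMSE %.3f, PCC %.3f (R^2 %.3f)\n",
    length(x$predictions), length(x$trials), x$rmse, x$pcc,
    x$explained_variance))
  invisible(x)
}

#' Final K-feature model from a cross-validation report
#'
#' `K` is the maximum subset size ever chosen in an outer trial; the model
#' uses the `K` features selected most frequently over trials (frequency
#' ties broken toward the feature with the larger mean absolute coefficient
#' across the trials that selected it) and is fit on all songs.
#'
#' @param X song-by-feature matrix.
#' @param y per-song speeds.
#' @param report a [nested_cv()] report.
#' @return A `regression_model`.
#' @export
final_model <- function(X, y, report) {
  stopifnot(inherits(report, "cv_report"))
  X <- as.matrix(X)
  K <- max(vapply(report$trials, function(tr) length(tr$subset), integer(1)))
  counts <- report$selection_counts
  coefs <- unlist(lapply(report$trials, `[[`, "coefficients"))
  mean_abs <- tapply(abs(coefs), names(coefs), mean)
  tie <- numeric(ncol(X))
  names(tie) <- colnames(X)
  tie[names(mean_abs)] <- mean_abs
  ids <- order(-counts, -tie)[seq_len(K)]
  fit_linear(X[, ids, drop = FALSE], y)
}

#' Write a cross-validation report to JSON
#'
#' @param report a [nested_cv()] report.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  out <- list(
    seed = report$seed, preselect = report$preselect,
    folds = report$folds, rmse = report$rmse, pcc = report$pcc,
    explained_variance = report$explained_variance,
    predictions = report$predictions, observed = report$observed,
    selection_counts = as.list(report$selection_counts),
    trials = lapply(report$trials, function(tr) {
      list(fold = tr$fold, preselected = tr$preselected,
           subset = tr$subset, inner_rmse = tr$inner_rmse,
           coefficients = as.list(tr$coefficients),
           intercept = tr$intercept)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
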
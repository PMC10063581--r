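#' Cross-validated gradient-boosted regression of BWS scores on features
#'
#' Shuffled k-fold split (fold sizes differing by at most one); per fold a
#' gradient-boosted tree ensemble is fit on the training stimuli and the
#' coefficient of determination R^2 is computed on the held-out test
#' stimuli. Fold models are retained for Shapley attribution.
#'
#' @param features a `bws_feature_matrix` (or plain data.frame with
#'   rownames = stimulus ids).
#' @param scores a `bws_score_table`, or named numeric vector of scores.
#' @param n_folds number of folds (default 5).
#' @param params list of model hyperparameters: `nrounds` (trees),
#'   `max_depth`, `eta` (learning rate), `subsample`.
#' @param seed integer seed controlling the fold split and fitting.
#' @return object of class `bws_portrait_fit`: fold_r2, mean_r2,
#'   fold_assignments, predictions (out-of-fold), models, feature names,
#'   params, seed.
#' @export
fit_cv_gbt <- function(features, scores, n_folds = 5,
                       params = list(nrounds = 300, max_depth = 4,
                                     eta = 0.05, subsample = 0.8),
                       seed = 1L) {
  y_all <- if (inherits(scores, "bws_score_table")) scores$scores else scores
  ids <- rownames(features)
  if (!setequal(ids, names(y_all))) {
    stop_bws("features and scores cover different stimulus sets",
             class = "bws_portrait_error")
  }
  if (n_folds < 2) stop_bws("n_folds must be >= 2", class = "bws_portrait_error")
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  y <- y_all[ids]
  n <- length(ids)
  fold_of <- with_seed(derive_seed(seed, "folds"), {
    sample(rep(seq_len(n_folds), length.out = n))
  })
  names(fold_of) <- ids
  models <- vector("list", n_folds)
  fold_r2 <- numeric(n_folds)
  preds <- setNames(numeric(n), ids)
  for (f in seq_len(n_folds)) {
    test <- fold_of == f
    dtrain <- xgboost::xgb.DMatrix(X[!test, , drop = FALSE], label = y[!test])
    m <- with_seed(derive_seed(seed, "fit", f), xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample, nthread = 1,
                    seed = derive_seed(seed, "xgb", f)),
      data = dtrain, nrounds = params$nrounds, verbose = 0))
    p <- predict(m, xgboost::xgb.DMatrix(X[test, , drop = FALSE]))
    preds[test] <- p
    ss_res <- sum((y[test] - p)^2)
    ss_tot <- sum((y[test] - mean(y[test]))^2)
    fold_r2[f] <- 1 - ss_res / ss_tot
    models[[f]] <- m
  }
  structure(list(fold_r2 = fold_r2, mean_r2 = mean(fold_r2),
                 fold_assignments = fold_of, predictions = preds,
                 models = models, feature_names = colnames(X),
                 X = X, y = y, params = params, seed = as.integer(seed),
                 concept = if (inherits(scores, "bws_score_table"))
                   scores$concept else NA_character_,
                 group = if (inherits(scores, "bws_score_table"))
                   scores$group else NA_character_),
            class = "bws_portrait_fit")
}

#' @export
print.bws_portrait_fit <- function(x, ...) {
  cat(sprintf("<bws_portrait_fit%s%s: %d folds, mean R^2 = %.3f>\n",
              if (is.na(x$concept)) "" else paste0(" ", x$concept),
              if (is.na(x$group)) "" else paste0(" / ", x$group),
              length(x$fold_r2), x$mean_r2))
  cat("fold R^2:", paste(sprintf("%.3f", x$fold_r2), collapse = ", "), "\n")
  invisible(x)
}

#' Shapley-value attributions on the test folds
#'
#' Exact tree-path-dependent Shapley contributions (TreeSHAP) computed for
#' every stimulus on the fold where it was held out, so each stimulus is
#' attributed exactly once by a model that never saw it. Satisfies local
#' accuracy: base value + row sum of contributions = model prediction.
#'
#' @param fit a [fit_cv_gbt()] result.
#' @return object of class `bws_attribution`: `per_sound` (stimuli x
#'   features signed contributions), `base_value` (per stimulus),
#'   `importance` (mean |contribution| per feature, descending),
#'   `feature_values` (the feature matrix, for direction summaries).
#' @export
attributions <- function(fit) {
  if (is.null(fit$models)) stop_bws("fold models missing", class = "bws_portrait_error")
  n <- nrow(fit$X)
  p <- length(fit$feature_names)
  contrib <- matrix(NA_real_, n, p,
                    dimnames = list(rownames(fit$X), fit$feature_names))
  base <- setNames(numeric(n), rownames(fit$X))
  for (f in seq_along(fit$models)) {
    test <- fit$fold_assignments == f
    phi <- predict(fit$models[[f]],
                   xgboost::xgb.DMatrix(fit$X[test, , drop = FALSE]),
                   predcontrib = TRUE)
    contrib[test, ] <- phi[, seq_len(p), drop = FALSE]
    base[test] <- phi[, p + 1]
  }
  importance <- sort(colMeans(abs(contrib)), decreasing = TRUE)
  structure(list(per_sound = contrib, base_value = base,
                 importance = importance, feature_values = fit$X,
                 predictions = fit$predictions,
                 concept = fit$concept, group = fit$group),
            class = "bws_attribution")
}

#' @export
print.bws_attribution <- function(x, ...) {
  cat(sprintf("<bws_attribution%s%s: %d stimuli x %d features>\n",
              if (is.na(x$concept)) "" else paste0(" ", x$concept),
              if (is.na(x$group)) "" else paste0(" / ", x$group),
              nrow(x$per_sound), ncol(x$per_sound)))
  print(head(x$importance, 5))
  invisible(x)
}

#' Top-k features of an attribution report: the "acoustic portrait"
#'
#' Ranks features by mean absolute Shapley contribution and summarizes
#' each one's direction as the sign (and strength) of the Pearson
#' correlation between feature value and contribution — a scalar rendering
#' of the value-colored attribution plots.
#'
#' @param attr a [attributions()] result.
#' @param k number of features to report (default 5).
#' @return data.frame: feature, importance, direction (+1/-1/0),
#'   direction_r (the correlation itself).
#' @export
top_features <- function(attr, k = 5) {
  if (k > length(attr$importance)) {
    stop_bws("k exceeds feature count", class = "bws_portrait_error")
  }
  feats <- names(attr$importance)[seq_len(k)]
  dir_r <- vapply(feats, function(fn) {
    v <- attr$feature_values[, fn]
    c_ <- attr$per_sound[, fn]
    if (sd(v) == 0 || sd(c_) == 0) return(0)
    cor(v, c_)
  }, numeric(1))
  data.frame(feature = feats,
             importance = unname(attr$importance[feats]),
             direction = sign(round(dir_r, 10)),
             direction_r = unname(dir_r),
             stringsAsFactors = FALSE)
}

#' Bar plot of attribution importances
#'
#' @param x a `bws_attribution`.
#' @param k number of features shown.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted importances.
#' @export
plot.bws_attribution <- function(x, k = 5, ...) {
  imp <- rev(head(x$importance, k))
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "mean |Shapley contribution|",
                    main = sprintf("%s / %s", x$concept, x$group), ...)
  invisible(imp)
}
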
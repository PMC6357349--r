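# The user-facing model: one fitting function returning a classed object with
# the usual print/summary/predict/plot methods. Wraps the pipeline: impute ->
# (optional grid search) -> (optional backward selection) -> normalise ->
# train a seeded random forest; cross-validated out-of-fold scores are kept
# for ROC plotting and reporting.

#' Fit a deleterious-sSNV random-forest classifier
#'
#' Fits the full modelling pipeline on a labelled feature matrix: missing
#' values are imputed to zero, hyperparameters are optionally tuned by grid
#' search over (`ntree`, `mtry`) under the cross-validated AUC criterion,
#' features are optionally pruned by sequential backward selection, z-score
#' normalisation is fitted on the training rows and frozen, and a seeded
#' random forest is trained. The default configuration — `ntree = 500`,
#' `mtry = 3` — is the operating point used with the optimised ten-feature
#' set.
#'
#' @param x A labelled `"feature_matrix"` (see [assemble()] or
#'   [read_feature_matrix()]), or a numeric matrix with named columns and
#'   rows.
#' @param labels Numeric labels (1 = deleterious, 0 = benign); defaults to
#'   the labels carried by `x`.
#' @param config An [rf_config()].
#' @param select Run sequential backward feature selection before training.
#' @param tune Run the grid search (paper-range default grids) before
#'   selection/training; overrides `config`'s `ntree`/`mtry`.
#' @param k,fold_seed Cross-validation settings used for tuning, selection
#'   and the reported CV AUC.
#' @param cv Compute and store out-of-fold probabilities and the CV AUC of
#'   the final model (set `FALSE` to skip the extra cross-validation).
#' @return An object of class `"synforest"`: the trained `model`
#'   (`"synforest_model"`), `features`, `trace` (selection trace or `NULL`),
#'   `grid` (grid-search table or `NULL`), `cv_auc` and `oof` (out-of-fold
#'   probabilities), and the matched `call`.
#' @seealso [predict.synforest()], [summary.synforest()], [plot.synforest()]
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(seed = 1, n_genes = 20,
#'                                    n_pos = 60, n_neg = 60))
#' fit <- synforest(sim$fm, config = rf_config(ntree = 100), k = 5)
#' print(fit)
#' head(predict(fit, sim$fm))
#' }
#' @export
synforest <- function(x, labels = NULL, config = rf_config(),
                      select = FALSE, tune = FALSE, k = 10L, fold_seed = 1L,
                      cv = TRUE) {
  fm <- if (inherits(x, "feature_matrix")) x else feature_matrix(x)
  if (!is.null(labels)) fm$labels <- as.numeric(labels)
  if (is.null(fm$labels) || anyNA(fm$labels)) {
    stop("fully labelled training data required")
  }
  fm <- impute_missing(fm)
  grid <- NULL
  if (tune) {
    gs <- grid_search(fm, k = k, fold_seed = fold_seed, seed = config$seed)
    grid <- gs$table
    config <- gs$best
  }
  trace <- NULL
  if (select) {
    trace <- sbs_select(fm, config, k = k, fold_seed = fold_seed)
    fm <- fm_subset(fm, cols = trace$final_subset)
    if (config$mtry > length(fm$features)) {
      config <- rf_config(config$ntree, length(fm$features), config$seed)
    }
  }
  oof <- NULL
  cv_auc <- NA_real_
  if (cv) {
    oof <- kfold_oof_probs(fm, config, k = k, fold_seed = fold_seed)
    cv_auc <- auc(fm$labels, oof)
  }
  params <- zscore_fit(fm)
  model <- train_rf(zscore_apply(fm, params), config = config)
  structure(list(model = model, features = fm$features, config = config,
                 trace = trace, grid = grid, cv_auc = cv_auc, oof = oof,
                 labels = fm$labels, n = length(fm$ids),
                 call = match.call()),
            class = "synforest")
}

#' Predict method for synforest fits
#'
#' Applies the pipeline frozen at fit time to new variants: zero-imputation,
#' the stored z-score parameters, then the forest.
#'
#' @param object A `"synforest"` fit.
#' @param newdata A `"feature_matrix"` or numeric matrix with named columns
#'   (raw scale).
#' @param type `"prob"` for deleteriousness probabilities, `"class"` for the
#'   0/1 call at the threshold.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
predict.synforest <- function(object, newdata, type = c("prob", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  fm <- if (inherits(newdata, "feature_matrix")) newdata else
    feature_matrix(newdata)
  fm <- impute_missing(fm)
  keep <- intersect(fm$features, object$features)
  fm <- fm_subset(fm, cols = keep)   # frozen norm has params for these only
  fm <- zscore_apply(fm, list(mean = object$model$norm$mean[keep],
                              sd = object$model$norm$sd[keep]))
  p <- predict(object$model, fm)
  if (type == "class") p <- as.numeric(p >= threshold)
  p
}

#' @export
print.synforest <- function(x, ...) {
  cat("Deleterious-sSNV random forest\n")
  cat(sprintf("  %d training variants (%d deleterious / %d benign), %d features\n",
              x$n, sum(x$labels == 1), sum(x$labels == 0),
              length(x$features)))
  cat(sprintf("  ntree = %d, mtry = %d, seed = %d\n",
              x$config$ntree, x$config$mtry, x$config$seed))
  if (!is.na(x$cv_auc)) cat(sprintf("  cross-validated AUC: %.3f\n", x$cv_auc))
  if (!is.null(x$trace)) {
    cat(sprintf("  backward selection removed %d feature(s): %s\n",
                nrow(x$trace$steps),
                paste(x$trace$steps$removed, collapse = ", ")))
  }
  invisible(x)
}

#' Summary of a synforest fit
#'
#' @param object A `"synforest"` fit.
#' @param beta F-measure weight for the out-of-fold evaluation (defaults to
#'   the training class ratio).
#' @param ... Unused.
#' @return An object of class `"summary.synforest"`: the fit, feature
#'   importances (mean decrease in Gini impurity), and an out-of-fold
#'   [evaluate()] result when CV scores were stored.
#' @export
summary.synforest <- function(object, beta = NULL, ...) {
  imp <- randomForest::importance(object$model$rf)[, "MeanDecreaseGini"]
  ev <- NULL
  if (!is.null(object$oof)) {
    if (is.null(beta)) {
      beta <- class_ratio_beta(sum(object$labels == 0),
                               sum(object$labels == 1))
    }
    ev <- evaluate(object$labels, object$oof, beta = beta)
  }
  structure(list(fit = object, importance = sort(imp, decreasing = TRUE),
                 oof_eval = ev), class = "summary.synforest")
}

#' @export
print.summary.synforest <- function(x, ...) {
  print(x$fit)
  cat("  feature importance (mean decrease in Gini):\n")
  for (f in names(x$importance)) {
    cat(sprintf("    %-12s %8.2f\n", f, x$importance[[f]]))
  }
  if (!is.null(x$oof_eval)) {
    cat("  out-of-fold evaluation: ")
    print(x$oof_eval)
  }
  invisible(x)
}

#' ROC curve of the cross-validated fit
#'
#' Plots the ROC curve of the stored out-of-fold probabilities (base
#' graphics) with the CV AUC in the legend.
#'
#' @param x A `"synforest"` fit made with `cv = TRUE`.
#' @param ... Passed to [graphics::plot()].
#' @return The data.frame of (FPR, TPR) points, invisibly.
#' @export
plot.synforest <- function(x, ...) {
  if (is.null(x$oof)) stop("fit was made with cv = FALSE; no ROC to plot")
  ord <- order(x$oof, decreasing = TRUE)
  lab <- x$labels[ord]
  tpr <- c(0, cumsum(lab == 1) / sum(lab == 1))
  fpr <- c(0, cumsum(lab == 0) / sum(lab == 0))
  graphics::plot(fpr, tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("CV AUC = %.3f", x$cv_auc))
  invisible(data.frame(fpr = fpr, tpr = tpr))
}
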
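# Model-construction core: rank-based AUC, stratified k-fold cross-validation
# with per-fold normalisation, sequential backward feature selection under the
# CV-AUC criterion, grid search over forest hyperparameters, and seeded
# random-forest training (randomForest engine).

#' Random-forest configuration
#'
#' @param ntree Number of trees.
#' @param mtry Number of candidate features per split.
#' @param seed Integer seed making training reproducible.
#' @return An object of class `"rf_config"`.
#' @export
rf_config <- function(ntree = 500L, mtry = 3L, seed = 1L) {
  stopifnot(ntree >= 1L, mtry >= 1L)
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 seed = as.integer(seed)), class = "rf_config")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, ties credited one half.
#'
#' @param labels Numeric/logical vector, 1 = positive (deleterious),
#'   0 = negative (benign).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both classes present (", n_pos, " positive, ",
         n_neg, " negative)")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified fold assignment: within each class, rows are shuffled and dealt
# round-robin into k folds.
make_folds <- function(labels, k, fold_seed) {
  for (cls in c(0, 1)) {
    if (sum(labels == cls) < k) {
      stop("class ", cls, " has fewer than k = ", k, " members")
    }
  }
  set.seed(fold_seed)
  fold <- integer(length(labels))
  for (cls in c(0, 1)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Out-of-fold probabilities: per fold, impute + fit normalisation on the
# training part, apply frozen parameters to the held-out part, train a seeded
# forest, and score the held-out rows.
kfold_oof_probs <- function(fm, config = rf_config(), k = 10L, fold_seed = 1L) {
  labels <- fm$labels
  if (is.null(labels) || anyNA(labels)) stop("fully labelled matrix required")
  fold <- make_folds(labels, k, fold_seed)
  fm <- impute_missing(fm)
  probs <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- fm_subset(fm, rows = which(fold != f))
    te <- fm_subset(fm, rows = which(fold == f))
    params <- zscore_fit(tr)
    tr <- zscore_apply(tr, params)
    te <- zscore_apply(te, params)
    model <- train_rf(tr, config = config)
    probs[fold == f] <- predict(model, te)
  }
  probs
}

#' Cross-validated AUC
#'
#' Stratified k-fold cross-validation with per-fold normalisation; the AUC is
#' computed on the pooled out-of-fold scores. This is the criterion used by
#' [sbs_select()] and [grid_search()].
#'
#' @param fm A labelled `"feature_matrix"` (raw scale; imputation and
#'   normalisation happen inside each fold).
#' @param config An `"rf_config"`.
#' @param k Number of folds.
#' @param fold_seed Seed for the fold assignment.
#' @return AUC of the pooled out-of-fold predictions.
#' @export
kfold_cv_auc <- function(fm, config = rf_config(), k = 10L, fold_seed = 1L) {
  auc(fm$labels, kfold_oof_probs(fm, config, k, fold_seed))
}

#' Sequential backward feature selection
#'
#' Greedy wrapper selection under the cross-validated AUC criterion: at each
#' step every single-feature removal is evaluated (same folds throughout); the
#' removal yielding the highest criterion is accepted when that criterion does
#' not fall below the current one (ties between removals are broken by the
#' lexicographically smallest feature name). Selection stops when every
#' removal strictly decreases the criterion, or one feature remains.
#'
#' @inheritParams kfold_cv_auc
#' @param strict Require strict improvement to accept a removal.
#' @return An object of class `"selection_trace"`: `steps` (data.frame of
#'   `removed`, `criterion`), `initial_criterion`, `final_subset`,
#'   `final_criterion`.
#' @export
sbs_select <- function(fm, config = rf_config(), k = 10L, fold_seed = 1L,
                       strict = FALSE) {
  current <- fm$features
  crit <- if (length(current) >= 2L)
    kfold_cv_auc(fm, config, k, fold_seed) else NA_real_
  initial <- crit
  steps <- data.frame(removed = character(), criterion = numeric())
  while (length(current) >= 2L) {
    cand <- sort(current)
    crits <- vapply(cand, function(f) {
      kfold_cv_auc(fm_subset(fm, cols = setdiff(current, f)),
                   config, k, fold_seed)
    }, numeric(1L))
    best <- which.max(crits)   # first max = lexicographically smallest name
    accept <- if (strict) crits[best] > crit else crits[best] >= crit
    if (!accept) break
    crit <- crits[best]
    current <- setdiff(current, cand[best])
    steps <- rbind(steps,
                   data.frame(removed = cand[best], criterion = crit))
  }
  structure(list(steps = steps, initial_criterion = initial,
                 final_subset = current, final_criterion = crit),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace: %d -> %d features, criterion %.4f -> %.4f>\n",
              length(x$final_subset) + nrow(x$steps), length(x$final_subset),
              x$initial_criterion, x$final_criterion))
  if (nrow(x$steps) > 0L) {
    cat("removed:", paste(sprintf("%s (%.4f)", x$steps$removed,
                                  x$steps$criterion), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Grid search over forest hyperparameters
#'
#' Evaluates the cross-validated AUC at every (`ntree`, `mtry`) grid point.
#' The default grid — `ntree` from 50 to 1000 in steps of 50 crossed with
#' `mtry` from 1 to 10 — has 200 points. Ties are broken toward smaller
#' `ntree`, then smaller `mtry`. Grid points with `mtry` exceeding the number
#' of features are skipped with a warning.
#'
#' @inheritParams kfold_cv_auc
#' @param ntree_grid,mtry_grid Integer vectors of candidate values.
#' @param seed Seed handed to each candidate's forest.
#' @return List with `best` (an `"rf_config"`) and `table` (data.frame
#'   `ntree`, `mtry`, `criterion`).
#' @export
grid_search <- function(fm, ntree_grid = seq(50L, 1000L, by = 50L),
                        mtry_grid = 1:10, k = 10L, fold_seed = 1L, seed = 1L) {
  p <- length(fm$features)
  skip <- mtry_grid > p
  if (any(skip)) {
    warning("skipping mtry > ", p, " (", sum(skip), " value(s))")
    mtry_grid <- mtry_grid[!skip]
  }
  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid)  # ntree varies slowest
  grid <- grid[order(grid$ntree, grid$mtry), c("ntree", "mtry")]
  crit <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- rf_config(ntree = grid$ntree[i], mtry = grid$mtry[i], seed = seed)
    crit[i] <- kfold_cv_auc(fm, cfg, k, fold_seed)
  }
  best <- which.max(crit)   # first max: smallest ntree, then smallest mtry
  list(best = rf_config(ntree = grid$ntree[best], mtry = grid$mtry[best],
                        seed = seed),
       table = data.frame(grid, criterion = crit, row.names = NULL))
}

#' Train a random forest on a feature matrix
#'
#' Seeded, reproducible binary forest (randomForest engine) predicting the
#' probability that a variant is deleterious. The default configuration is
#' `ntree = 500`, `mtry = 3`.
#'
#' @param fm A `"feature_matrix"` with no missing values (see
#'   [impute_missing()]); typically normalised.
#' @param labels Optional label vector overriding `fm$labels`.
#' @param config An `"rf_config"`.
#' @return An object of class `"synforest_model"` holding the forest, the
#'   training feature names, the configuration, the normalisation parameters
#'   carried by `fm` (if any), and the training date.
#' @export
train_rf <- function(fm, labels = fm$labels, config = rf_config()) {
  if (is.null(labels) || anyNA(labels)) stop("binary labels required")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2L) {
    stop("labels must contain both classes (0 = benign, 1 = deleterious)")
  }
  if (config$mtry > length(fm$features)) {
    stop("mtry = ", config$mtry, " exceeds feature count ",
         length(fm$features))
  }
  if (anyNA(fm$values)) stop("matrix contains missing values; impute first")
  y <- factor(ifelse(labels == 1, "deleterious", "benign"),
              levels = c("benign", "deleterious"))
  set.seed(config$seed)
  rf <- randomForest::randomForest(x = fm$values, y = y, ntree = config$ntree,
                                   mtry = config$mtry, importance = TRUE)
  structure(list(rf = rf, feature_names = fm$features, config = config,
                 norm = fm$norm, trained = as.character(Sys.Date()),
                 format_version = 1L),
            class = "synforest_model")
}

#' Predict deleteriousness probabilities
#'
#' Columns are matched by name and reordered to the training order; extra
#' columns are ignored with a warning, missing ones are an error.
#'
#' @param object A `"synforest_model"`.
#' @param newdata A `"feature_matrix"` or numeric matrix with named columns.
#' @param ... Unused.
#' @return Named numeric vector of probabilities in \[0, 1\] (probability of
#'   the deleterious class, i.e. the fraction of trees voting deleterious).
#' @export
predict.synforest_model <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  stopifnot(is.matrix(v), !is.null(colnames(v)))
  miss <- setdiff(object$feature_names, colnames(v))
  if (length(miss) > 0L) {
    stop("missing required feature(s): ", paste(miss, collapse = ", "))
  }
  extra <- setdiff(colnames(v), object$feature_names)
  if (length(extra) > 0L) {
    warning("ignoring extra feature(s): ", paste(extra, collapse = ", "))
  }
  v <- v[, object$feature_names, drop = FALSE]
  p <- predict(object$rf, newdata = v, type = "prob")[, "deleterious"]
  stats::setNames(as.numeric(p), rownames(v))
}

#' @export
print.synforest_model <- function(x, ...) {
  cat(sprintf("<synforest_model: %d features, ntree = %d, mtry = %d, seed = %d, trained %s>\n",
              length(x$feature_names), x$config$ntree, x$config$mtry,
              x$config$seed, x$trained))
  invisible(x)
}

#' Save / load a trained model
#'
#' Single-file archive (RDS) embedding the forest, feature names,
#' configuration, normalisation parameters and training date. Loading verifies
#' the archive format version.
#'
#' @param model A `"synforest_model"`.
#' @param path Archive path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "synforest_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- tryCatch(readRDS(path),
                error = function(e) stop("cannot read model archive '", path,
                                         "': ", conditionMessage(e)))
  if (!inherits(m, "synforest_model") ||
      !identical(m$format_version, 1L)) {
    stop("model archive version mismatch or not a synforest model: ", path)
  }
  m
}
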
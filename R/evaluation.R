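# Imbalance-aware evaluation: confusion counts, recall/precision and the
# beta-weighted F-measure (beta set to the majority/minority class ratio),
# gene-matched negative filtering, balanced-subset resampling with paired
# t-tests, leave-one-feature-out ablation, and the class-imbalance sweep.

#' Confusion counts at a probability threshold
#'
#' A variant is predicted deleterious when its probability is at or above the
#' threshold.
#'
#' @param labels 1 = deleterious, 0 = benign.
#' @param probs Predicted deleteriousness probabilities.
#' @param threshold Decision threshold.
#' @return Named integer vector `c(TP =, FP =, TN =, FN =)`.
#' @export
confusion <- function(labels, probs, threshold = 0.5) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  if (length(labels) == 0L) stop("empty input")
  pred <- probs >= threshold
  c(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Weighted F-measure
#'
#' `F = ((beta^2 + 1) * precision * recall) / (beta^2 * precision + recall)`.
#' `beta = 1` gives the harmonic mean; large beta weights recall, and as
#' beta grows the measure tends to the recall. Returns 0 when precision and
#' recall are both 0.
#'
#' @param recall,precision Rates in \[0, 1\].
#' @param beta Relative preference for recall over precision.
#' @return The F-measure.
#' @export
f_beta <- function(recall, precision, beta = 1) {
  stopifnot(recall >= 0, recall <= 1, precision >= 0, precision <= 1,
            beta > 0)
  if (recall == 0 && precision == 0) return(0)
  (beta^2 + 1) * precision * recall / (beta^2 * precision + recall)
}

#' Class-ratio beta for the F-measure
#'
#' The majority-to-minority class ratio, rounded to the nearest integer — the
#' beta that makes the F-measure emphasise recall on an imbalanced test set.
#'
#' @param n_neg,n_pos Class sizes (negatives are assumed the majority when
#'   larger).
#' @return Integer beta.
#' @export
class_ratio_beta <- function(n_neg, n_pos) {
  if (n_pos <= 0L) stop("positive class is empty")
  as.integer(round(max(n_neg, n_pos) / min(n_neg, n_pos)))
}

#' Evaluate predictions
#'
#' Bundles confusion counts, recall, precision, the beta-weighted F-measure
#' and the AUC into one result.
#'
#' @inheritParams confusion
#' @param beta F-measure weight; see [class_ratio_beta()].
#' @return An object of class `"eval_result"` with fields `TP`, `FP`, `TN`,
#'   `FN`, `recall`, `precision`, `f_measure`, `auc`, `beta`, `threshold`.
#' @export
evaluate <- function(labels, probs, beta = 1, threshold = 0.5) {
  cm <- confusion(labels, probs, threshold)
  recall <- if (cm[["TP"]] + cm[["FN"]] > 0) cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else 0
  precision <- if (cm[["TP"]] + cm[["FP"]] > 0) cm[["TP"]] / (cm[["TP"]] + cm[["FP"]]) else 0
  structure(c(as.list(cm),
              list(recall = recall, precision = precision,
                   f_measure = f_beta(recall, precision, beta),
                   auc = auc(labels, probs), beta = beta,
                   threshold = threshold)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval: TP %d FP %d TN %d FN %d | recall %.3f precision %.3f F(beta=%g) %.3f AUC %.3f>\n",
              x$TP, x$FP, x$TN, x$FN, x$recall, x$precision, x$beta,
              x$f_measure, x$auc))
  invisible(x)
}

#' Gene-matched filtering of putative negatives
#'
#' Keeps only negatives hosted by a gene that also hosts at least one
#' positive, removing the ascertainment bias of drawing benign variants from
#' genes unlike the disease genes. Negatives identical to a training-set
#' variant are also discarded; negatives with no gene assignment are dropped
#' with a warning.
#'
#' @param negatives,positives Variant data.frames.
#' @param gene_of Named character vector mapping variant id
#'   (`contig:pos:ref:alt`) to gene id.
#' @param training Optional variant data.frame whose exact variants are
#'   excluded from the result.
#' @return The filtered negatives data.frame.
#' @export
gene_matched_negative_filter <- function(negatives, positives, gene_of,
                                         training = NULL) {
  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt, sep = ":")
  ng <- gene_of[key(negatives)]
  if (anyNA(ng)) {
    warning(sum(is.na(ng)), " negative(s) without a gene assignment dropped")
  }
  pos_genes <- unique(gene_of[key(positives)])
  keep <- !is.na(ng) & ng %in% pos_genes
  if (!is.null(training)) keep <- keep & !(key(negatives) %in% key(training))
  out <- negatives[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced-subset evaluation of an imbalanced test set
#'
#' Repeatedly samples as many negatives as there are positives (without
#' replacement within a run, a fresh draw per run), evaluates each balanced
#' subset with `beta = 1`, and reports per-run metrics with their mean and
#' sample standard deviation. The positives are fixed across runs, so the
#' recall has zero spread by construction.
#'
#' @param model A `"synforest_model"`, or `NULL` when `pos`/`neg_pool` are
#'   already probability vectors.
#' @param pos,neg_pool Labelled `"feature_matrix"` rows (model supplied) or
#'   numeric probability vectors (model `NULL`) for the positive set and the
#'   full negative pool.
#' @param runs Number of resampling runs.
#' @param seed Seed for the negative draws.
#' @param threshold Decision threshold.
#' @return List with `runs` (data.frame, one row per run), `mean` and `sd`
#'   (named vectors over recall/precision/f_measure/auc), and `n_per_run`.
#' @export
balanced_subset_eval <- function(model, pos, neg_pool, runs = 5L, seed = 1L,
                                 threshold = 0.5) {
  if (is.null(model)) {
    p_pos <- as.numeric(pos)
    p_neg <- as.numeric(neg_pool)
  } else {
    p_pos <- predict(model, pos)
    p_neg <- predict(model, neg_pool)
  }
  n_pos <- length(p_pos)
  if (length(p_neg) < n_pos) {
    stop("negative pool (", length(p_neg), ") smaller than positive set (",
         n_pos, ")")
  }
  set.seed(seed)
  per_run <- vector("list", runs)
  for (r in seq_len(runs)) {
    draw <- sample(length(p_neg), n_pos)
    ev <- evaluate(c(rep(1, n_pos), rep(0, n_pos)), c(p_pos, p_neg[draw]),
                   beta = 1, threshold = threshold)
    per_run[[r]] <- data.frame(run = r, recall = ev$recall,
                               precision = ev$precision,
                               f_measure = ev$f_measure, auc = ev$auc)
  }
  tab <- do.call(rbind, per_run)
  metrics <- c("recall", "precision", "f_measure", "auc")
  list(runs = tab,
       mean = vapply(tab[metrics], mean, numeric(1L)),
       sd = vapply(tab[metrics], stats::sd, numeric(1L)),
       n_per_run = 2L * n_pos)
}

#' Two-tailed paired t-test on per-run metrics
#'
#' Pairs by run index (methods evaluated on the same resampled subsets). When
#' every paired difference is zero the p-value is 1 by convention; when the
#' differences are constant but nonzero it is 0.
#'
#' @param metric_runs_a,metric_runs_b Equal-length numeric vectors of per-run
#'   metric values.
#' @return Two-tailed p-value.
#' @export
paired_ttest <- function(metric_runs_a, metric_runs_b) {
  stopifnot(length(metric_runs_a) == length(metric_runs_b))
  if (length(metric_runs_a) < 2L) stop("need at least 2 paired runs")
  d <- metric_runs_a - metric_runs_b
  if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else 0)
  stats::t.test(metric_runs_a, metric_runs_b, paired = TRUE)$p.value
}

#' Leave-one-feature-out ablation table
#'
#' One cross-validated evaluation per single-feature-removed subset, plus the
#' all-features row, quantifying each feature's marginal contribution.
#'
#' @inheritParams kfold_cv_auc
#' @param beta F-measure weight for the per-row evaluation.
#' @return data.frame with one row per configuration (`left_out == "none"`
#'   for the full set) and columns recall, precision, f_measure, auc.
#' @export
ablation_table <- function(fm, config = rf_config(), k = 10L, fold_seed = 1L,
                           beta = 1) {
  eval_subset <- function(cols) {
    sub <- fm_subset(fm, cols = cols)
    ev <- evaluate(sub$labels, kfold_oof_probs(sub, config, k, fold_seed),
                   beta = beta)
    data.frame(recall = ev$recall, precision = ev$precision,
               f_measure = ev$f_measure, auc = ev$auc)
  }
  rows <- list(cbind(data.frame(left_out = "none"), eval_subset(fm$features)))
  for (f in fm$features) {
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(left_out = f), eval_subset(setdiff(fm$features, f)))
  }
  do.call(rbind, rows)
}

#' Class-imbalance sweep
#'
#' For each multiplier m, draws m times as many negatives as positives from
#' the pool (capped at the pool size with a warning), and reports the
#' cross-validated AUC of a model trained on that imbalanced set — and, when a
#' held-out test matrix is supplied, the AUC of the trained model on it.
#'
#' @param pos Labelled `"feature_matrix"` of positives.
#' @param neg_pool Labelled `"feature_matrix"` pool of negatives.
#' @param multipliers Negative-to-positive size multipliers.
#' @param config An `"rf_config"`.
#' @param k,fold_seed Cross-validation settings.
#' @param seed Seed for the negative draws.
#' @param test Optional labelled `"feature_matrix"` held-out test set.
#' @return data.frame with one row per multiplier: `multiplier`, `n_neg`,
#'   `cv_auc`, and `test_auc` when a test set is given.
#' @export
imbalance_sweep <- function(pos, neg_pool, multipliers = c(10, 20, 30, 40, 50),
                            config = rf_config(), k = 10L, fold_seed = 1L,
                            seed = 1L, test = NULL) {
  n_pos <- length(pos$ids)
  pool_n <- length(neg_pool$ids)
  set.seed(seed)
  rows <- lapply(multipliers, function(m) {
    want <- as.integer(m * n_pos)
    if (want > pool_n) {
      warning("multiplier ", m, ": pool has only ", pool_n,
              " negatives; capped")
      want <- pool_n
    }
    draw <- sample(pool_n, want)
    vals <- rbind(pos$values, neg_pool$values[draw, , drop = FALSE])
    fm <- feature_matrix(vals, labels = c(rep(1, n_pos), rep(0, want)))
    cv <- kfold_cv_auc(fm, config, k, fold_seed)
    row <- data.frame(multiplier = m, n_neg = want, cv_auc = cv)
    if (!is.null(test)) {
      fm2 <- impute_missing(fm)
      params <- zscore_fit(fm2)
      model <- train_rf(zscore_apply(fm2, params), config = config)
      te <- zscore_apply(impute_missing(test), params)
      row$test_auc <- auc(te$labels, predict(model, te))
    }
    row
  })
  do.call(rbind, rows)
}
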
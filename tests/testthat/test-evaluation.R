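test_that("confusion counts follow the threshold-inclusive rule", {
  # hand-worked 4-case toy
  expect_identical(confusion(c(1, 1, 0, 0), c(0.9, 0.3, 0.7, 0.1)),
                   c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_identical(confusion(c(1, 0), c(0.9, 0.1)),
                   c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  # probability exactly at the threshold counts as predicted deleterious
  expect_identical(confusion(c(1, 0), c(0.5, 0.5)),
                   c(TP = 1L, FP = 1L, TN = 0L, FN = 0L))
  expect_error(confusion(numeric(0), numeric(0)), "empty")
})

test_that("the weighted F-measure obeys its limiting behaviour", {
  # recall == precision == p gives p for any beta
  for (b in c(1, 5, 34)) expect_equal(f_beta(0.62, 0.62, b), 0.62)
  # beta = 1 is the harmonic mean
  set.seed(4)
  for (i in 1:25) {
    r <- runif(1); p <- runif(1)
    expect_equal(f_beta(r, p, 1), 2 * r * p / (r + p))
    # beta -> infinity tends to the recall
    expect_lt(abs(f_beta(r, p, 1e6) - r), 1e-4)
  }
  expect_equal(f_beta(0, 0, 34), 0)
})

test_that("class-ratio beta rounds the majority/minority ratio", {
  expect_identical(class_ratio_beta(5178L, 153L), 34L)
  expect_identical(class_ratio_beta(300L, 300L), 1L)
  expect_identical(class_ratio_beta(10L, 1L), 10L)
  expect_error(class_ratio_beta(10L, 0L), "empty")
})

test_that("evaluate bundles rates consistently with its parts", {
  labels <- c(1, 1, 1, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.2, 0.6, 0.3, 0.2, 0.1)
  ev <- evaluate(labels, probs, beta = 2)
  expect_identical(c(TP = ev$TP, FP = ev$FP, TN = ev$TN, FN = ev$FN),
                   confusion(labels, probs))
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$f_measure, f_beta(2 / 3, 2 / 3, 2))
  expect_equal(ev$auc, auc(labels, probs))
  perfect <- evaluate(c(1, 0), c(0.9, 0.1), beta = 1)
  expect_equal(c(perfect$recall, perfect$precision, perfect$f_measure,
                 perfect$auc), c(1, 1, 1, 1))
})

test_that("gene-matched filtering keeps negatives sharing a positive's gene", {
  pos <- fix_variant("c1", 10L, "A", "G", "deleterious")
  neg <- rbind(fix_variant("c1", 20L, "C", "T", "benign"),
               fix_variant("c1", 30L, "G", "A", "benign"),
               fix_variant("c1", 40L, "T", "C", "benign"))
  gene_of <- c("c1:10:A:G" = "geneA", "c1:20:C:T" = "geneA",
               "c1:30:G:A" = "geneB", "c1:40:T:C" = "geneA")
  out <- gene_matched_negative_filter(neg, pos, gene_of)
  expect_identical(out$pos, c(20L, 40L))
  # no positives -> nothing survives
  expect_identical(nrow(gene_matched_negative_filter(neg, pos[0, ],
                                                     gene_of)), 0L)
  # negatives duplicated in the training set are discarded
  out2 <- gene_matched_negative_filter(neg, pos, gene_of,
                                       training = neg[1, ])
  expect_identical(out2$pos, 40L)
  # unmapped negatives are dropped with a warning
  expect_warning(
    out3 <- gene_matched_negative_filter(
      rbind(neg, fix_variant("c9", 5L, "A", "C", "benign")), pos, gene_of),
    "without a gene")
  expect_identical(out3$pos, c(20L, 40L))
})

test_that("balanced resampling fixes positives and draws fresh negatives", {
  set.seed(31)
  p_pos <- runif(153, 0.4, 1)
  p_neg <- runif(1000, 0, 0.6)
  res <- balanced_subset_eval(NULL, p_pos, p_neg, runs = 5, seed = 9)
  expect_identical(res$n_per_run, 306L)
  expect_identical(nrow(res$runs), 5L)
  expect_identical(unname(res$sd["recall"]), 0)   # positives never change
  expect_gt(res$sd["precision"], 0)
  res2 <- balanced_subset_eval(NULL, p_pos, p_neg, runs = 5, seed = 9)
  expect_identical(res$runs, res2$runs)           # seeded reproducibility
  expect_error(balanced_subset_eval(NULL, p_pos, p_neg[1:100], runs = 5,
                                    seed = 9), "smaller than")
})

test_that("paired t-test matches the closed form and its conventions", {
  d <- c(0.2, 0.17, 0.16, 0.23, 0.19)
  a <- runif(5); b <- a - d
  p <- paired_ttest(a, b)
  # closed form: t = mean(d) / (sd(d)/sqrt(n)), two-tailed on df = n - 1
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(p, 2 * pt(-abs(t_stat), df = 4))
  expect_lt(p, 0.001)
  expect_equal(paired_ttest(a, a), 1)
  expect_equal(paired_ttest(b, a), p)             # sign-antisymmetric
  expect_error(paired_ttest(1, 2), "at least 2")
})

test_that("ablation reproduces the full-set row and spans every feature", {
  fm <- gaussian_fm(n_per_class = 20, informative = 2, noise = 1, shift = 2.5)
  cfg <- rf_config(ntree = 100, mtry = 1, seed = 1)
  tab <- ablation_table(fm, cfg, k = 4, fold_seed = 2)
  expect_identical(nrow(tab), 4L)                  # all-features + 3 ablations
  expect_identical(tab$left_out[1], "none")
  full_auc <- kfold_cv_auc(fm, cfg, k = 4, fold_seed = 2)
  expect_equal(tab$auc[1], full_auc)
  # dropping the pure-noise feature barely moves the AUC
  expect_lt(abs(tab$auc[tab$left_out == "noise1"] - full_auc), 0.05)
})

test_that("imbalance sweep reports one row per multiplier with capping", {
  fm <- gaussian_fm(n_per_class = 120, informative = 2, noise = 1,
                    shift = 2.5)
  pos <- fm_subset(fm, rows = which(fm$labels == 1)[1:20])
  neg <- fm_subset(fm, rows = which(fm$labels == 0))
  cfg <- rf_config(ntree = 100, mtry = 1, seed = 1)
  sw <- imbalance_sweep(pos, neg, multipliers = c(1, 3), config = cfg,
                        k = 4, fold_seed = 1, seed = 2)
  expect_identical(sw$multiplier, c(1, 3))
  expect_identical(sw$n_neg, c(20L, 60L))
  expect_true(all(sw$cv_auc > 0.8))                # signal survives imbalance
  expect_warning(
    sw2 <- imbalance_sweep(pos, neg, multipliers = 10, config = cfg,
                           k = 4, fold_seed = 1, seed = 2),
    "capped")
  expect_identical(sw2$n_neg, 120L)
  # held-out evaluation when a test matrix is supplied
  te <- fm_subset(fm, rows = c(which(fm$labels == 1)[21:40],
                               which(fm$labels == 0)[101:120]))
  sw3 <- imbalance_sweep(pos, fm_subset(neg, rows = 1:100),
                         multipliers = 1, config = cfg, k = 4,
                         fold_seed = 1, seed = 2, test = te)
  expect_true(sw3$test_auc > 0.8)
})
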
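test_that("perfect separation gives AUC 1 and a clean dimer-free threshold", {
  scores <- c(-10, -9, -1, 0)
  labels <- c("dimer", "dimer", "dimer_free", "dimer_free")
  curve <- build_roc(scores, labels)
  expect_equal(curve$auc, 1.0)
  expect_equal(curve$dimer_free_threshold, -1)
  expect_equal(curve$tnr_at_threshold, 1.0)
  expect_equal(curve$n_positive, 2)
  expect_equal(curve$n_negative, 2)
})

test_that("trapezoid AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    # duplicates force cross-class ties regularly
    scores <- sample(round(rnorm(n, 0, 2), 1), n, replace = TRUE)
    labels <- sample(c("dimer", "dimer_free"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    curve <- build_roc(scores, labels)
    expect_equal(curve$auc, oracle_mw_auc(scores, labels), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(60)
  labels <- ifelse(rnorm(60) + scores < 0, "dimer", "dimer_free")
  if (length(unique(labels)) == 2) {
    curve <- build_roc(scores, labels)
    ref <- pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c("dimer", "dimer_free"), direction = "<", quiet = TRUE))
    expect_equal(curve$auc, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(23)
  scores <- rnorm(2000)
  labels <- sample(c("dimer", "dimer_free"), 2000, replace = TRUE)
  curve <- build_roc(scores, labels)
  expect_lt(abs(curve$auc - 0.5), 0.05)
})

test_that("curve endpoints and monotonicity follow the threshold sweep", {
  set.seed(24)
  scores <- rnorm(50)
  labels <- sample(c("dimer", "dimer_free"), 50, replace = TRUE,
                   prob = c(0.4, 0.6))
  curve <- build_roc(scores, labels)
  pts <- curve$points
  # thresholds descend from the sentinel; the curve runs (1,1) -> (0,0)
  expect_true(all(diff(pts$threshold) < 0))
  expect_equal(c(pts$tpr[1], pts$fpr[1]), c(1, 1))
  expect_equal(c(pts$tpr[nrow(pts)], pts$fpr[nrow(pts)]), c(0, 0))
  expect_true(all(diff(pts$tpr) <= 0))
  expect_true(all(diff(pts$fpr) <= 0))
  expect_equal(sum(pts$partial_auc), curve$auc)
  expect_true(curve$auc >= 0 && curve$auc <= 1)
})

test_that("dimer-free threshold is the lowest score above the worst dimer", {
  scores <- c(-5, -4, -3, -2, -1)
  labels <- c("dimer", "dimer", "dimer_free", "dimer_free", "dimer_free")
  thr <- dimer_free_threshold(scores, labels)
  expect_equal(thr$threshold, -3)
  expect_equal(thr$tnr, 1.0)

  labels2 <- c("dimer", "dimer_free", "dimer", "dimer_free", "dimer_free")
  thr2 <- dimer_free_threshold(scores, labels2)
  expect_equal(thr2$threshold, -2)
  expect_equal(thr2$tnr, 2 / 3)

  # the alternative convention reports the worst dimer score itself
  thr3 <- dimer_free_threshold(scores, labels2, rule = "worst_dimer")
  expect_equal(thr3$threshold, -3)
  expect_equal(thr3$tnr, 2 / 3)

  # no score above the worst dimer: undefined threshold
  thr4 <- dimer_free_threshold(c(-2, -3), c("dimer", "dimer_free"))
  expect_true(is.na(thr4$threshold))
  expect_equal(thr4$tnr, 0)

  # vacuous case: no dimer-labeled pairs
  thr5 <- dimer_free_threshold(c(-1, -2), c("dimer_free", "dimer_free"))
  expect_true(thr5$vacuous)
  expect_equal(thr5$threshold, -2)
  expect_equal(thr5$tnr, 1.0)
})

test_that("the dimer-free threshold never admits a false negative", {
  set.seed(25)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    scores <- round(rnorm(n), 1)
    labels <- sample(c("dimer", "dimer_free"), n, replace = TRUE)
    if (!all(c("dimer", "dimer_free") %in% labels)) next
    thr <- dimer_free_threshold(scores, labels)
    ref <- oracle_threshold(scores, labels)
    expect_identical(thr$threshold, ref$threshold)
    expect_equal(thr$tnr, ref$tnr)
    if (!is.na(thr$threshold)) {
      # every dimer falls strictly below: zero false negatives at this cut
      expect_true(all(scores[labels == "dimer"] < thr$threshold))
    }
  }
})

test_that("shifting all scores shifts the threshold and preserves AUC/TNR", {
  set.seed(26)
  scores <- rnorm(40)
  labels <- sample(c("dimer", "dimer_free"), 40, replace = TRUE,
                   prob = c(0.3, 0.7))
  c1 <- build_roc(scores, labels)
  c2 <- build_roc(scores + 5, labels)
  expect_equal(c2$auc, c1$auc, tolerance = 1e-12)
  expect_equal(c2$tnr_at_threshold, c1$tnr_at_threshold)
  expect_equal(c2$dimer_free_threshold, c1$dimer_free_threshold + 5)
  # negating scores flips the ranking: AUC -> 1 - AUC
  c3 <- build_roc(-scores, labels)
  expect_equal(c3$auc, 1 - c1$auc, tolerance = 1e-12)
})

test_that("ambiguous pairs are excluded or reclassified, conserving counts", {
  scores <- c(-6, -5, -4, -3, -2)
  labels <- c("dimer", "ambiguous", "dimer_free", "ambiguous", "dimer_free")
  ce <- build_roc(scores, labels, ambiguous_mode = "exclude")
  expect_equal(ce$n_excluded, 2)
  expect_equal(ce$n_positive + ce$n_negative + ce$n_excluded, 5)
  cs <- build_roc(scores, labels, ambiguous_mode = "as_dimer")
  expect_equal(cs$n_excluded, 0)
  expect_equal(cs$n_positive, 3)
  expect_equal(cs$n_positive + cs$n_negative, 5)
})

test_that("degenerate or invalid ROC inputs are rejected", {
  expect_error(build_roc(c(-1, -2), c("dimer", "dimer")), "undefined")
  expect_error(build_roc(c(-1, NaN), c("dimer", "dimer_free")), "non-finite")
  expect_error(build_roc(c(-1, -2), c("dimer", "maybe")), "unknown dimer label")
})

test_that("evaluate_dataset scores pairs and wires labels into the curve", {
  spec <- sim_spec(n_pairs = 40, dimer_fraction = 0.4, seed = 31)
  tab <- generate_dataset(spec)
  res <- evaluate_dataset(tab, PARAMS, CONFIG)
  expect_s3_class(res$curve, "roc_curve")
  expect_equal(nrow(res$scores), 40)
  expect_equal(res$curve$n_positive + res$curve$n_negative +
                 res$curve$n_excluded, 40)
  # rerun is bit-identical
  res2 <- evaluate_dataset(generate_dataset(spec), PARAMS, CONFIG)
  expect_identical(res$scores$adjusted_ds, res2$scores$adjusted_ds)
  expect_identical(res$curve$auc, res2$curve$auc)
})
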
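cfg_gt <- function(thr) list(name = "t", direction = "damaging_if_greater", threshold = thr)
cfg_lt <- function(thr) list(name = "t", direction = "damaging_if_less", threshold = thr)

test_that("binarization follows direction, strict thresholds, and maps", {
  expect_equal(binarize(0.7, cfg_gt(0.6)), "Damaging")
  expect_equal(binarize(0.6, cfg_gt(0.6)), "Tolerated")   # strict >
  expect_equal(binarize(-2, cfg_lt(-1)), "Damaging")
  expect_equal(binarize(-1, cfg_lt(-1)), "Tolerated")     # strict <
  expect_equal(binarize(NA_real_, cfg_gt(0.5)), "Missing")

  ma <- list(name = "MA", direction = "damaging_if_greater",
             categorical_map = list(H = "Damaging", M = "Damaging",
                                    L = "Tolerated", N = "Tolerated"))
  expect_equal(binarize(c("H", "M", "L", "N", NA), ma),
               c("Damaging", "Damaging", "Tolerated", "Tolerated", "Missing"))
  expect_error(binarize("Z", ma), "Z")

  pp <- read_tool_config()$PPH_HVAR
  expect_equal(binarize(c("probably damaging", "possibly damaging", "benign"), pp),
               c("Damaging", "Damaging", "Tolerated"))
})

test_that("confusion counts tally correctly and report dropped predictions", {
  truth <- c(rep("LPP", 130), rep("BENIGN", 103))
  all_right <- ifelse(truth == "LPP", "Damaging", "Tolerated")
  cc <- confusion_counts(truth, all_right)
  expect_equal(cc[c("TP", "TN", "FP", "FN")], list(TP = 130L, TN = 103L, FP = 0L, FN = 0L))

  cc2 <- confusion_counts(truth, ifelse(truth == "LPP", "Tolerated", "Damaging"))
  expect_equal(cc2$TP + cc2$TN, 0L)

  set.seed(3)
  truth20 <- sample(c("LPP", "BENIGN"), 20, replace = TRUE)
  pred20 <- sample(c("Damaging", "Tolerated", "Missing"), 20, replace = TRUE)
  cc3 <- confusion_counts(truth20, pred20)
  # independent tally
  expect_equal(cc3$TP, sum(truth20 == "LPP" & pred20 == "Damaging"))
  expect_equal(cc3$FN, sum(truth20 == "LPP" & pred20 == "Tolerated"))
  expect_equal(cc3$TN, sum(truth20 == "BENIGN" & pred20 == "Tolerated"))
  expect_equal(cc3$FP, sum(truth20 == "BENIGN" & pred20 == "Damaging"))
  expect_equal(cc3$n_dropped, sum(pred20 == "Missing"))

  expect_error(confusion_counts("LPP", "Missing"), "no scored variants")
  expect_error(confusion_counts("VUS", "Damaging"), "truth labels")
})

test_that("metrics evaluate the four formulas exactly", {
  perfect <- classification_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1, mcc = 1, acc = 1))

  null <- classification_metrics(list(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(null$mcc, 0)
  expect_equal(null$acc, 0.5)

  m <- classification_metrics(list(TP = 8, FN = 2, TN = 6, FP = 4))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$acc, 0.7)
  expect_equal(m$mcc, (8 * 6 - 4 * 2) / sqrt(12 * 10 * 10 * 8))

  # degenerate denominator -> 0 by convention
  expect_equal(classification_metrics(list(TP = 5, FP = 0, TN = 0, FN = 0))$mcc, 0)
})

test_that("sensitivity and specificity are invariant under record duplication", {
  set.seed(5)
  truth <- sample(c("LPP", "BENIGN"), 40, replace = TRUE)
  pred <- sample(c("Damaging", "Tolerated"), 40, replace = TRUE)
  m1 <- classification_metrics(confusion_counts(truth, pred))
  m2 <- classification_metrics(confusion_counts(rep(truth, 3), rep(pred, 3)))
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
  expect_equal(m1$acc, m2$acc)
})

test_that("MCC magnitude is symmetric under class-role swap", {
  set.seed(6)
  for (i in 1:20) {
    c1 <- list(TP = sample(0:30, 1), FP = sample(0:30, 1),
               TN = sample(0:30, 1), FN = sample(0:30, 1))
    swapped <- list(TP = c1$TN, FP = c1$FN, TN = c1$TP, FN = c1$FP)
    expect_equal(abs(classification_metrics(c1)$mcc),
                 abs(classification_metrics(swapped)$mcc))
  }
})

test_that("AUC matches concordance, handles ties, and respects direction", {
  r <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c("LPP", "LPP", "BENIGN", "BENIGN"))
  expect_equal(r$auc, 1)
  expect_true(any(r$curve$fpr == 0 & r$curve$sensitivity == 0))
  expect_true(any(r$curve$fpr == 1 & r$curve$sensitivity == 1))

  ties <- roc_curve(rep(0.5, 10), rep(c("LPP", "BENIGN"), 5))
  expect_equal(ties$auc, 0.5)

  set.seed(9)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    labels <- sample(c("LPP", "BENIGN"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # force some ties
    expect_equal(roc_curve(scores, labels)$auc, auc_oracle(scores, labels))
    # monotone transform invariance
    expect_equal(roc_curve(exp(scores), labels)$auc,
                 roc_curve(scores, labels)$auc)
    # direction reversal
    expect_equal(roc_curve(scores, labels, "damaging_if_less")$auc,
                 1 - roc_curve(scores, labels)$auc)
  }
  expect_error(roc_curve(1:3, rep("LPP", 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(10)
  labels <- sample(c("LPP", "BENIGN"), 200, replace = TRUE)
  scores <- rnorm(200, mean = ifelse(labels == "LPP", 1, 0))
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        levels = c("BENIGN", "LPP"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("optimal threshold maximizes Youden's J", {
  # perfectly separated: returned cut lies in the separating gap
  r <- roc_curve(c(5, 6, 7, 1, 2, 3), rep(c("LPP", "BENIGN"), each = 3))
  thr <- optimal_threshold(r)
  expect_gt(thr, 3)
  expect_lt(thr, 5)

  # exhaustive scan oracle on a noisy instance
  set.seed(12)
  labels <- sample(c("LPP", "BENIGN"), 60, replace = TRUE)
  scores <- rnorm(60, ifelse(labels == "LPP", 1, 0))
  r2 <- roc_curve(scores, labels)
  thr2 <- optimal_threshold(r2)
  j_at <- function(t) {
    mean(scores[labels == "LPP"] > t) + mean(scores[labels == "BENIGN"] <= t) - 1
  }
  grid <- sort(unique(c(scores - 1e-9, scores + 1e-9)))
  expect_equal(j_at(thr2), max(vapply(grid, j_at, 0)), tolerance = 1e-12)

  # two known Gaussians: optimum near the midpoint of the means
  set.seed(13)
  n <- 2000
  sc <- c(rnorm(n, 2), rnorm(n, 0))
  lb <- rep(c("LPP", "BENIGN"), each = n)
  expect_lt(abs(optimal_threshold(roc_curve(sc, lb)) - 1), 0.25)
})

test_that("coverage filter uses a strict 30% boundary", {
  st <- data.frame(variant_id = paste0("v", 1:100))
  st$full <- rnorm(100)
  st$low <- c(rnorm(29), rep(NA, 71))
  st$edge <- c(rnorm(30), rep(NA, 70))
  st$just <- c(rnorm(31), rep(NA, 69))
  expect_setequal(coverage_filter(st), c("full", "just"))
  expect_setequal(coverage_filter(st, 0.95), "full")
})

test_that("benchmark integrates catalog and scores into a ranked table", {
  cat <- fake_catalog(60, 50)
  cfg <- sim_config(seed = 2, genes = data.frame(
    gene = "G1", accession = "Q0", n_lpp = 60L, n_vus = 0L, n_benign = 50L),
    reference_gene = "G1", segmap = small_segmap(),
    contact_layout = default_contact_layout()[1, ])
  scores <- gen_scores(cfg, cat)
  bench <- benchmark_predictors(cat, scores)
  expect_s3_class(bench, "predictor_benchmark")
  expect_equal(nrow(bench), 22L)
  expect_true(all(bench$auc >= 0 & bench$auc <= 1))
  expect_true(all(bench$mcc >= -1 & bench$mcc <= 1))
  expect_true(all(diff(bench$auc) <= 0))           # sorted by AUC
  expect_true(all(bench$coverage == 1))
  expect_equal(bench$n_used, rep(110L, 22L))
})
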
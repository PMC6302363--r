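test_that("case outcomes follow the four-way rule", {
  expect_equal(classify_case(0.30, 2.1, 2.1), "TP")
  expect_equal(classify_case(0.30, 5.0, 4.2), "FP")
  expect_equal(classify_case(0.70, 9.9, 6.0), "TN")
  expect_equal(classify_case(0.70, 9.9, 2.0), "FN")
  # boundaries: score cutoff is half-open, RMSD cutoff inclusive
  expect_equal(classify_case(0.50, 1.0, 1.0), "FN")
  expect_equal(classify_case(0.49, 3.0, 3.0), "TP")
  expect_equal(classify_case(0.49, 3.01, 3.0), "FP")
})

test_that("MCC matches direct arithmetic and its conventions", {
  expect_equal(mcc(confusion_counts(TP = 5, TN = 5)), 1.0)
  expect_equal(mcc(confusion_counts(5, 5, 5, 5)), 0.0)
  expect_equal(mcc(confusion_counts(TP = 6, TN = 8, FP = 2, FN = 1)),
               46 / sqrt(5040), tolerance = 1e-12)
  # zero denominator convention
  expect_equal(mcc(confusion_counts(TP = 3, FN = 2)), 0)
  expect_true(abs(mcc(confusion_counts(1, 99, 3, 7))) <= 1)
})

test_that("accuracy reproduces the printed worked examples", {
  expect_equal(accuracy(confusion_counts(TP = 22, TN = 10, FP = 4, FN = 2)),
               32 / 38, tolerance = 1e-12)
  expect_equal(round(100 * 32 / 38, 1), 84.2)
  expect_equal(accuracy(confusion_counts(TP = 16, TN = 2, FP = 2, FN = 1)),
               18 / 21, tolerance = 1e-12)
  expect_equal(round(100 * 18 / 21, 1), 85.7)
  expect_equal(accuracy(confusion_counts(4, 4, 4, 4)), 0.5)
})

test_that("benchmark evaluation partitions cases and flags true negatives", {
  models <- data.frame(
    case_id = rep(c("c1", "c2", "c3", "c4"), each = 3),
    model_id = paste0("m", 1:12),
    quality_score = c(0.2, 0.8, 0.9,   # c1: best 0.2 on near-native -> TP
                      0.1, 0.5, 0.6,   # c2: best 0.1 on far model -> FP
                      0.7, 0.8, 0.9,   # c3: no good model, no call -> TN
                      0.6, 0.7, 0.9),  # c4: good model exists, no call -> FN
    rmsd = c(1.5, 4, 9,
             8, 2.5, 7,
             5, 6, 7,
             2.0, 5, 6),
    stratum = rep(c("easy", "easy", "hard", "hard"), each = 3))
  rep <- evaluate_benchmark(models)
  expect_equal(rep$cases$outcome, c("TP", "FP", "TN", "FN"))
  expect_equal(sum(unclass(rep$case_counts)), 4)
  expect_equal(rep$case_accuracy, 0.5)
  expect_equal(rep$stratum_accuracy[["easy"]], 0.5)
  expect_equal(rep$stratum_accuracy[["hard"]], 0.5)
  # every TN case has min RMSD beyond the cutoff and best score >= 0.5
  tn <- rep$cases[rep$cases$outcome == "TN", ]
  expect_true(all(tn$min_rmsd > 3 & tn$best_quality_score >= 0.5))
  # model-level MCC equals the brute-force recomputation
  expect_equal(rep$model_mcc,
               mcc_from_scores(models$quality_score,
                               as.integer(models$rmsd <= 3)))
})

test_that("best-score ties break by model id, not by RMSD", {
  models <- data.frame(
    case_id = "c1", model_id = c("m2", "m1"),
    quality_score = c(0.2, 0.2), rmsd = c(1.0, 9.0))
  rep <- evaluate_benchmark(models)
  expect_equal(rep$cases$best_model_id, "m1")
  expect_equal(rep$cases$outcome, "FP")
})

test_that("an all-TP benchmark scores perfectly; empty strata stay undefined", {
  models <- data.frame(
    case_id = rep(c("a", "b"), each = 2), model_id = paste0("m", 1:4),
    quality_score = c(0.1, 0.9, 0.2, 0.8), rmsd = c(1, 9, 2, 8),
    stratum = "easy")
  rep <- evaluate_benchmark(models)
  expect_equal(rep$case_accuracy, 1.0)
  expect_equal(rep$stratum_accuracy[["easy"]], 1.0)
  expect_true(is.na(rep$stratum_accuracy[["hard"]]))
})

test_that("report files round-trip the key quantities", {
  models <- data.frame(case_id = rep("c", 4), model_id = paste0("m", 1:4),
                       quality_score = c(0.1, 0.6, 0.7, 0.9),
                       rmsd = c(2, 4, 5, 8))
  rep <- evaluate_benchmark(models)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$case_accuracy, rep$case_accuracy)
  expect_equal(back$model_mcc, rep$model_mcc)
  tsv <- utils::read.delim(sub("\\.json$", ".tsv", path))
  expect_equal(nrow(tsv), 1)
  expect_equal(tsv$outcome, "TP")
})

test_that("the repeat harness is reproducible and a single repeat matches a
           direct evaluation", {
  tr <- generate_feature_dataset(feature_spec(seed = 1))
  te <- generate_feature_dataset(feature_spec(seed = 2))
  one <- repeat_harness(tr, te, n_repeats = 1, seeds = 5)
  m <- hard_negative_mining(tr$X, tr$y, seed = 5)
  q <- predict_quality(m, te$X)$quality_score
  expect_equal(one$mcc_test, mcc_from_scores(q, te$y), tolerance = 1e-12)
  r1 <- repeat_harness(tr, te, n_repeats = 3, seeds = c(2, 4, 6))
  r2 <- repeat_harness(tr, te, n_repeats = 3, seeds = c(2, 4, 6))
  expect_identical(r1, r2)
  expect_named(attr(r1, "summary"),
               c("mean", "sd", "25%", "50%", "75%"))
})

test_that("the split harness splits by case and validates sizes", {
  set.seed(2)
  n_cases <- 20
  cases <- rep(sprintf("c%02d", seq_len(n_cases)), each = 30)
  y <- unlist(lapply(seq_len(n_cases), function(i)
    rbinom(30, 1, 0.15)))
  X <- matrix(rnorm(length(y) * 4), ncol = 4) + 2 * y
  colnames(X) <- c("ddna3", "pdca", "pbhb", "bidentate_hb")
  expect_error(split_harness(X, y, cases, n_train = 15, n_test = 10,
                             n_repeats = 1),
               class = "tfdnaqa_input_error")
  out <- split_harness(X, y, cases, n_train = 12, n_test = 8,
                       n_repeats = 3, seeds = 1:3)
  expect_equal(nrow(out), 3)
  expect_true(all(is.finite(out$mcc_test)))
})

test_that("ablation collapses when the only informative feature is dropped", {
  set.seed(10)
  n <- 1200
  y <- rep(c(1, 0), times = c(150, n - 150))
  X <- matrix(rnorm(n * 4), ncol = 4)
  colnames(X) <- c("ddna3", "pdca", "pbhb", "bidentate_hb")
  X[, "ddna3"] <- X[, "ddna3"] + 4 * y
  tr_idx <- seq_len(600)
  # keep class balance across the split
  tr_idx <- c(which(y == 1)[1:75], which(y == 0)[1:525])
  te_idx <- setdiff(seq_len(n), tr_idx)
  tr <- list(X = X[tr_idx, ], y = y[tr_idx])
  te <- list(X = X[te_idx, ], y = y[te_idx])
  tab <- ablation_harness(tr, te, seed = 4)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$dropped,
               c("none", "ddna3", "pdca", "pbhb", "bidentate_hb"))
  full <- tab$mcc_test[tab$dropped == "none"]
  expect_gt(full, 0.7)
  expect_lt(tab$mcc_test[tab$dropped == "ddna3"], 0.3)
  for (f in c("pdca", "pbhb", "bidentate_hb"))
    expect_lt(abs(tab$mcc_test[tab$dropped == f] - full), 0.1)
  # identical seed reproduces the full-set row
  tab2 <- ablation_harness(tr, te, features = character(0) |>
                             (\(x) "ddna3")(), seed = 4)
  expect_equal(tab2$mcc_test[1], full, tolerance = 1e-12)
  expect_error(ablation_harness(tr, te, features = character(0)),
               class = "tfdnaqa_input_error")
})
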
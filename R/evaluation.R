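# Performance evaluation: per-case outcome classification, Matthews
# correlation coefficient and accuracy, easy/hard stratification, and the
# repeat / random-split / feature-ablation harnesses.
#
# Case outcomes follow the docking-assessment convention: with quality
# score 1 - p (lower = more confident) and "best score" the minimum over a
# case's models,
#   TP: best score < 0.5 and the best-scoring model has RMSD <= 3 A
#   FP: best score < 0.5 but that model's RMSD exceeds 3 A
#   TN: best score >= 0.5 and no model of the case has RMSD <= 3 A
#   FN: best score >= 0.5 but at least one near-native model exists.

#' Confusion counts
#'
#' @param TP,TN,FP,FN nonnegative integers.
#' @return Named numeric vector of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0, TN = 0, FP = 0, FN = 0) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(c(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 when
#' any denominator factor is zero (the standard convention for degenerate
#' confusion tables).
#'
#' @param c a [confusion_counts()] (or named vector with TP/TN/FP/FN).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c[["TP"]]); tn <- as.numeric(c[["TN"]])
  fp <- as.numeric(c[["FP"]]); fn <- as.numeric(c[["FN"]])
  stopifnot(tp + tn + fp + fn > 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Prediction accuracy
#'
#' `(TP + TN) / (TP + FP + FN + TN)`.
#'
#' @inheritParams mcc
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(c) {
  tot <- c[["TP"]] + c[["TN"]] + c[["FP"]] + c[["FN"]]
  stopifnot(tot > 0)
  (c[["TP"]] + c[["TN"]]) / tot
}

.counts_from_predictions <- function(pred_pos, actual_pos) {
  confusion_counts(TP = sum(pred_pos & actual_pos),
                   TN = sum(!pred_pos & !actual_pos),
                   FP = sum(pred_pos & !actual_pos),
                   FN = sum(!pred_pos & actual_pos))
}

#' Classify a docking case outcome
#'
#' Applies the four-way rule (see the module header) to a case's best
#' quality score, the RMSD of the best-scoring model, and the case's
#' minimum RMSD.
#'
#' @param best_quality_score minimum quality score (1 - p) over the case's
#'   models.
#' @param rmsd_of_best_scoring_model RMSD of that model, Angstrom.
#' @param min_rmsd minimum RMSD over all models of the case, Angstrom.
#' @param score_cutoff quality-score decision boundary.
#' @param rmsd_cutoff near-native boundary, Angstrom (inclusive).
#' @return `"TP"`, `"FP"`, `"TN"` or `"FN"`.
#' @export
classify_case <- function(best_quality_score, rmsd_of_best_scoring_model,
                          min_rmsd, score_cutoff = 0.5, rmsd_cutoff = 3) {
  if (best_quality_score < score_cutoff) {
    if (rmsd_of_best_scoring_model <= rmsd_cutoff) "TP" else "FP"
  } else {
    if (min_rmsd > rmsd_cutoff) "TN" else "FN"
  }
}

#' Evaluate a scored benchmark
#'
#' Takes model-level scores and RMSDs for a set of docking cases and
#' produces (i) per-case outcomes and case-level accuracy, overall and per
#' easy/hard stratum, and (ii) model-level MCC, where every docked model
#' is classified at the quality-score cutoff against its RMSD label.
#' Ties for the best score within a case are broken by model id
#' (truth-blind determinism).
#'
#' @param models data frame with columns `case_id`, `model_id`,
#'   `quality_score`, `rmsd`, and optionally `stratum` (`"easy"`/`"hard"`,
#'   constant within a case).
#' @param score_cutoff,rmsd_cutoff decision boundaries.
#' @return List of class `benchmark_report`: `cases` (per-case data
#'   frame), `case_counts`, `case_accuracy`, `stratum_accuracy` (named
#'   vector, `NA` for an empty stratum), `model_counts`, `model_mcc`.
#' @export
evaluate_benchmark <- function(models, score_cutoff = 0.5,
                               rmsd_cutoff = 3) {
  stopifnot(all(c("case_id", "model_id", "quality_score", "rmsd")
                %in% names(models)), nrow(models) > 0L)
  has_stratum <- "stratum" %in% names(models)
  cases <- lapply(split(models, models$case_id), function(m) {
    m <- m[order(m$quality_score, m$model_id), , drop = FALSE]
    data.frame(
      case_id = m$case_id[1L], n_models = nrow(m),
      best_quality_score = m$quality_score[1L],
      best_model_id = m$model_id[1L],
      rmsd_of_best_scoring_model = m$rmsd[1L],
      min_rmsd = min(m$rmsd),
      outcome = classify_case(m$quality_score[1L], m$rmsd[1L], min(m$rmsd),
                              score_cutoff, rmsd_cutoff),
      stratum = if (has_stratum) m$stratum[1L] else NA_character_,
      stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, cases)
  rownames(cases) <- NULL
  tab <- table(factor(cases$outcome, levels = c("TP", "TN", "FP", "FN")))
  case_counts <- confusion_counts(TP = tab[["TP"]], TN = tab[["TN"]],
                                  FP = tab[["FP"]], FN = tab[["FN"]])
  stratum_accuracy <- c(easy = NA_real_, hard = NA_real_)
  if (has_stratum) {
    for (s in c("easy", "hard")) {
      sel <- cases$stratum == s
      if (any(sel))
        stratum_accuracy[s] <-
          mean(cases$outcome[sel] %in% c("TP", "TN"))
    }
  }
  model_counts <- .counts_from_predictions(
    models$quality_score < score_cutoff, models$rmsd <= rmsd_cutoff)
  structure(list(cases = cases, case_counts = case_counts,
                 case_accuracy = accuracy(case_counts),
                 stratum_accuracy = stratum_accuracy,
                 model_counts = model_counts,
                 model_mcc = mcc(model_counts)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cc <- x$case_counts
  cat(sprintf(
    "<benchmark_report: %d cases (TP %d / TN %d / FP %d / FN %d), case accuracy %.3f, model MCC %.3f>\n",
    nrow(x$cases), cc[["TP"]], cc[["TN"]], cc[["FP"]], cc[["FN"]],
    x$case_accuracy, x$model_mcc))
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' JSON summary plus a per-case TSV next to it (same stem, `.tsv`).
#'
#' @param report a `benchmark_report`.
#' @param path JSON output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(case_counts = as.list(unclass(report$case_counts)),
         case_accuracy = report$case_accuracy,
         stratum_accuracy = as.list(report$stratum_accuracy),
         model_counts = as.list(unclass(report$model_counts)),
         model_mcc = report$model_mcc),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.table(report$cases, sub("\\.json$", ".tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.eval_mcc <- function(model, X, y, score_cutoff = 0.5) {
  q <- predict_quality(model, X)$quality_score
  mcc(.counts_from_predictions(q < score_cutoff, y == 1))
}

#' Robustness harness: repeated training with varied seeds
#'
#' Trains `n_repeats` independent models by hard-negative mining (each with
#' its own seed, hence its own initial negative sample) on a fixed
#' train/test split and reports the distribution of train and test MCC.
#'
#' @param train,test lists with elements `X` (feature matrix) and `y`
#'   (labels).
#' @param kernel,C,gamma see [train_svm()].
#' @param n_repeats number of repeats.
#' @param seeds integer vector of length `n_repeats` (default
#'   `seq_len(n_repeats)` offset by `seed_base`).
#' @param seed_base offset for default seeds.
#' @return Data frame with one row per repeat (`seed`, `mcc_train`,
#'   `mcc_test`, `iterations`, `converged`) and a `summary` attribute
#'   (mean, sd, quartiles of test MCC).
#' @export
repeat_harness <- function(train, test, kernel = "rbf", C = 1,
                           gamma = NULL, n_repeats = 30, seeds = NULL,
                           seed_base = 0) {
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  rows <- lapply(seeds, function(s) {
    m <- hard_negative_mining(train$X, train$y, kernel = kernel, C = C,
                              gamma = gamma, seed = s)
    data.frame(seed = s, mcc_train = .eval_mcc(m, train$X, train$y),
               mcc_test = .eval_mcc(m, test$X, test$y),
               iterations = m$metadata$iterations,
               converged = m$metadata$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(mean = mean(out$mcc_test),
                            sd = stats::sd(out$mcc_test),
                            stats::quantile(out$mcc_test,
                                            c(0.25, 0.5, 0.75)))
  out
}

#' Random-split harness
#'
#' Repeatedly splits the pool of cases into new training and testing sets
#' (split at the case level so a case's models never straddle the split),
#' trains by hard-negative mining and records train/test MCC.
#'
#' @param X feature matrix; `y` labels; `case_ids` the case of each row.
#' @param n_train,n_test number of cases per split.
#' @param n_repeats number of random splits.
#' @param seeds per-repeat seeds (default sequential).
#' @param kernel,C,gamma see [train_svm()].
#' @inheritParams repeat_harness
#' @return Data frame, one row per repeat, with a `summary` attribute.
#' @export
split_harness <- function(X, y, case_ids, n_train = 106, n_test = 35,
                          n_repeats = 200, seeds = NULL, kernel = "rbf",
                          C = 1, gamma = NULL, seed_base = 0) {
  ucases <- unique(case_ids)
  if (n_train + n_test > length(ucases))
    .stop_tfdnaqa("split sizes exceed the number of available cases",
                  "tfdnaqa_input_error")
  if (is.null(seeds)) seeds <- seed_base + seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  rows <- lapply(seeds, function(s) {
    picked <- withr::with_seed(s, sample(ucases, n_train + n_test))
    tr <- case_ids %in% picked[seq_len(n_train)]
    te <- case_ids %in% picked[n_train + seq_len(n_test)]
    m <- hard_negative_mining(X[tr, , drop = FALSE], y[tr],
                              kernel = kernel, C = C, gamma = gamma,
                              seed = s)
    data.frame(seed = s,
               mcc_train = .eval_mcc(m, X[tr, , drop = FALSE], y[tr]),
               mcc_test = .eval_mcc(m, X[te, , drop = FALSE], y[te]))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(mean = mean(out$mcc_test),
                            sd = stats::sd(out$mcc_test),
                            stats::quantile(out$mcc_test,
                                            c(0.25, 0.5, 0.75)))
  out
}

#' Leave-one-feature-out ablation harness
#'
#' Trains and evaluates with the full feature set and with each
#' leave-one-out subset, using identical seeds, to measure each feature's
#' contribution.
#'
#' @inheritParams repeat_harness
#' @param features feature names to consider dropping (must leave >= 1
#'   feature when dropped).
#' @param seed mining seed shared across rows.
#' @return Data frame with rows `full` plus one per dropped feature:
#'   `dropped`, `n_features`, `mcc_train`, `mcc_test`.
#' @export
ablation_harness <- function(train, test, features = colnames(train$X),
                             kernel = "rbf", C = 1, gamma = NULL,
                             seed = 1) {
  if (length(features) == 0L)
    .stop_tfdnaqa("empty feature set", "tfdnaqa_input_error")
  all_feats <- colnames(train$X)
  run <- function(keep, label) {
    if (length(keep) == 0L)
      .stop_tfdnaqa("ablation would leave no features",
                    "tfdnaqa_input_error")
    m <- hard_negative_mining(train$X[, keep, drop = FALSE], train$y,
                              kernel = kernel, C = C, gamma = gamma,
                              seed = seed)
    data.frame(dropped = label, n_features = length(keep),
               mcc_train = .eval_mcc(m, train$X[, keep, drop = FALSE],
                                     train$y),
               mcc_test = .eval_mcc(m, test$X[, keep, drop = FALSE],
                                    test$y),
               stringsAsFactors = FALSE)
  }
  rows <- list(run(all_feats, "none"))
  for (f in features)
    rows[[length(rows) + 1L]] <- run(setdiff(all_feats, f), f)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
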
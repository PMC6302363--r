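test_that("the z-score scaler matches hand arithmetic", {
  X <- cbind(a = c(0, 2), b = c(1, 5))
  sc <- fit_scaler(X)
  expect_equal(unname(sc$mean), c(1, 3))
  expect_equal(unname(sc$sd), c(sqrt(2), sqrt(8)))
  Z <- apply_scaler(X, sc)
  expect_equal(Z[, "a"], c(-1, 1) / sqrt(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # applying the scaler to its own training matrix centers it
  set.seed(3)
  M <- matrix(rnorm(200, 5, 2), 50, 4)
  Z2 <- apply_scaler(M, fit_scaler(M))
  expect_lt(max(abs(colMeans(Z2))), 1e-12)
  # constant column: warned, scaled to zeros
  Xc <- cbind(c(1, 1, 1), c(1, 2, 3))
  expect_warning(scc <- fit_scaler(Xc), "constant")
  expect_equal(apply_scaler(Xc, scc)[, 1], rep(0, 3), ignore_attr = TRUE)
  expect_error(fit_scaler(matrix(1, 1, 2)), class = "tfdnaqa_input_error")
})

test_that("perfectly separated data is fit exactly with monotone probabilities", {
  X <- matrix(c(seq(-3, -1, length.out = 20),
                seq(1, 3, length.out = 20)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  m <- train_svm(X, y, kernel = "linear")
  pr <- predict_quality(m, X)
  expect_equal(as.integer(pr$p >= 0.5), y)
  # p is monotone in the decision value
  ord <- order(pr$decision_value)
  expect_true(all(diff(pr$p[ord]) >= 0))
  expect_true(all(pr$p > 0 & pr$p < 1))
  expect_error(train_svm(X, rep(1, 40)),
               class = "tfdnaqa_training_error")
})

test_that("the reconstructed decision function matches e1071", {
  d <- generate_feature_dataset(feature_spec(n_pos = 60, n_neg = 120,
                                             seed = 21))
  sc <- fit_scaler(d$X)
  Z <- apply_scaler(d$X, sc)
  for (kern in c("rbf", "linear")) {
    m <- train_svm(Z, d$y, kernel = kern)
    fit <- e1071::svm(x = Z, y = factor(d$y, levels = c("1", "0")),
                      kernel = if (kern == "rbf") "radial" else "linear",
                      cost = 1, gamma = m$gamma, scale = FALSE)
    ref <- as.numeric(attr(predict(fit, Z, decision.values = TRUE),
                           "decision.values"))
    got <- tfdnaqa:::.kernel_decision(m, Z)
    # orientation may have been flipped; compare up to a global sign
    s <- sign(stats::cor(got, ref))
    expect_equal(got, s * ref, tolerance = 1e-8)
  }
})

test_that("Platt calibration agrees with an independent sigmoid fit", {
  set.seed(5)
  f <- c(rnorm(200, 1.2), rnorm(200, -1.2))
  y <- rep(c(1, 0), each = 200)
  ab <- tfdnaqa:::.platt_fit(f, y)
  p <- 1 / (1 + exp(ab["A"] * f + ab["B"]))
  g <- stats::glm(y ~ f, family = stats::binomial)
  pg <- stats::fitted(g)
  # same orientation and close probabilities (targets are regularized,
  # so agreement is approximate, not exact)
  expect_gt(stats::cor(p, pg), 0.99)
  expect_lt(mean(abs(p - pg)), 0.05)
})

test_that("well-separated synthetic features give high held-out MCC", {
  tr <- generate_feature_dataset(feature_spec(seed = 1))
  te <- generate_feature_dataset(feature_spec(seed = 2))
  for (kern in c("rbf", "linear")) {
    sc <- fit_scaler(tr$X)
    m <- train_svm(apply_scaler(tr$X, sc), tr$y, kernel = kern,
                   scaler = sc)
    q <- predict_quality(m, te$X)$quality_score
    expect_gte(mcc_from_scores(q, te$y), 0.8)
  }
})

test_that("permuted labels give near-zero test MCC", {
  d <- generate_feature_dataset(feature_spec(seed = 31))
  y_perm <- withr::with_seed(77, sample(d$y))
  tr_idx <- seq_len(1000)
  sc <- fit_scaler(d$X[tr_idx, ])
  m <- train_svm(apply_scaler(d$X[tr_idx, ], sc), y_perm[tr_idx],
                 scaler = sc)
  q <- predict_quality(m, d$X[-tr_idx, ])$quality_score
  expect_lt(abs(mcc_from_scores(q, y_perm[-tr_idx])), 0.15)
})

test_that("hard-negative mining starts balanced, grows monotonically and
           converges deterministically", {
  # label noise guarantees false positives, exercising several iterations
  d <- generate_feature_dataset(feature_spec(
    mean_pos = c(1, 1, 1, 1), mean_neg = c(-1, -1, -1, -1), seed = 8))
  y <- d$y
  flip <- withr::with_seed(99, sample(which(y == 0), 60))
  X <- d$X
  X[flip, ] <- X[flip, ] + 1.5
  m <- hard_negative_mining(X, y, seed = 12)
  n_pos <- sum(y == 1)
  trace <- m$metadata$subset_trace
  expect_equal(trace[1], 2L * n_pos)           # initial balanced sample
  expect_true(all(diff(trace) >= 0))            # subsets only grow
  expect_true(m$metadata$converged)
  expect_lte(m$metadata$iterations, 50)
  expect_gt(m$metadata$iterations, 1L)
  # identical seed, identical subset trace and training subset
  m2 <- hard_negative_mining(X, y, seed = 12)
  expect_identical(m$metadata$subset_trace, m2$metadata$subset_trace)
  expect_identical(m$metadata$subset_ids, m2$metadata$subset_ids)
  # different seed, different initial draw
  m3 <- hard_negative_mining(X, y, seed = 13)
  expect_false(identical(m$metadata$subset_ids[seq_len(2 * n_pos)],
                         m3$metadata$subset_ids[seq_len(2 * n_pos)]))
  expect_error(hard_negative_mining(X, rep(1, nrow(X))),
               class = "tfdnaqa_training_error")
})

test_that("a zero-false-positive first round is a fixed point", {
  d <- generate_feature_dataset(feature_spec(seed = 1))
  m <- hard_negative_mining(d$X, d$y, seed = 1)
  expect_true(m$metadata$converged)
  expect_equal(m$metadata$iterations, 1L)
  expect_equal(length(m$metadata$subset_ids), 2L * sum(d$y == 1))
})

test_that("quality scores are the probability complement, in (0, 1)", {
  d <- generate_feature_dataset(feature_spec(n_pos = 40, n_neg = 200,
                                             seed = 6))
  m <- hard_negative_mining(d$X, d$y, seed = 3)
  pr <- predict_quality(m, d$X)
  expect_equal(pr$quality_score, 1 - pr$p, tolerance = 1e-12)
  expect_true(all(pr$quality_score > 0 & pr$quality_score < 1))
  fv <- structure(d$X[1, ], class = "feature_vector", model_id = "m1")
  sm <- score_model(fv, m)
  expect_equal(sm$quality_score, pr$quality_score[1])
  expect_equal(sm$model_id, "m1")
})

test_that("feature assembly prefers external potential scores", {
  cx <- toy_cached()
  pt <- derive_potential(list(cx))
  fv <- assemble_features(cx, pt, sasa_n_points = 240)
  expect_named(fv, c("ddna3", "pdca", "pbhb", "bidentate_hb"))
  expect_gte(fv[["pdca"]], 0)
  expect_true(all(fv[c("pbhb", "bidentate_hb")] >= 0))
  fe <- assemble_features(cx, pt, external = c(toy_arg_seed1 = -5),
                          sasa_n_points = 240)
  expect_equal(fe[["ddna3"]], -5)
  expect_equal(fe[["pdca"]], fv[["pdca"]])
  # separated complex with an empty-table potential: all-zero features
  sep <- build_toy_complex(10, 8, 30, seed = 3, probe = "none")
  fs <- assemble_features(sep, pt, sasa_n_points = 240)
  expect_equal(unname(fs[c("pdca", "pbhb", "bidentate_hb")]), c(0, 0, 0),
               tolerance = 1e-6)
})

test_that("models survive a JSON round trip with identical predictions", {
  d <- generate_feature_dataset(feature_spec(n_pos = 50, n_neg = 300,
                                             seed = 17))
  m <- hard_negative_mining(d$X, d$y, seed = 2)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict_quality(back, d$X), predict_quality(m, d$X),
               tolerance = 1e-12)
  expect_equal(back$kernel, m$kernel)
  expect_equal(back$platt, m$platt)
})
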
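# Feature assembly and the quality-assessment SVM.
#
# Four features per docked model: the atomic statistical potential score
# (ddna3 slot), protein-DNA contact area (pdca), protein-DNA base hydrogen
# bonds (pbhb) and bidentate hydrogen bonds.  A soft-margin SVM (linear or
# RBF kernel, fitted through e1071) is calibrated with a Platt sigmoid
# fitted on the training decision values; the model's quality score is
# 1 - p, where p is the calibrated probability of the model being
# near-native, so lower scores mean higher confidence.  Class imbalance is
# handled by hard-negative mining.

.FEATURES <- c("ddna3", "pdca", "pbhb", "bidentate_hb")

#' Assemble the feature vector of a complex model
#'
#' Computes the four quality-assessment features.  The potential feature is
#' taken from `external` when an entry for `model_id` exists (e.g. scores
#' from a published potential), else from [score_complex()] with `table`.
#' Sub-Angstrom^2 negative contact areas (point-sampling noise on separated
#' complexes) are clamped to zero.
#'
#' @param cx a `pdna_complex`.
#' @param table a `potential_table` (may be `NULL` when `external` covers
#'   the model).
#' @param external optional named numeric vector of externally computed
#'   potential scores, keyed by model id.
#' @param model_id identifier used for the external lookup; defaults to
#'   `cx$id`.
#' @param sasa_n_points SASA sampling density for the contact area.
#' @param hb_max_da donor-acceptor cutoff for hydrogen bonds, Angstrom.
#' @return Named numeric vector of class `feature_vector` with elements
#'   `ddna3`, `pdca`, `pbhb`, `bidentate_hb`.
#' @export
assemble_features <- function(cx, table = NULL, external = NULL,
                              model_id = cx$id, sasa_n_points = 960,
                              hb_max_da = 3.9) {
  ddna3 <- if (!is.null(external) && model_id %in% names(external)) {
    unname(external[[model_id]])
  } else {
    if (is.null(table))
      .stop_tfdnaqa("no potential table and no external score for model",
                    "tfdnaqa_config_error")
    as.numeric(score_complex(cx, table))
  }
  pdca <- compute_pdca(cx, n_points = sasa_n_points)
  if (pdca < 0) pdca <- max(pdca, 0)  # point-sampling noise on separation
  bonds <- detect_hbonds(cx, max_da = hb_max_da)
  out <- c(ddna3 = ddna3, pdca = pdca, pbhb = as.numeric(count_pbhb(bonds)),
           bidentate_hb = as.numeric(count_bidentate(bonds)))
  structure(out, class = "feature_vector", model_id = model_id)
}

#' Per-feature standardization
#'
#' Z-score scaler fitted on a training matrix (sample standard deviation);
#' constant columns get a unit scale with a warning so downstream code
#' never divides by zero.
#'
#' @param X numeric matrix, >= 2 rows.
#' @return List of class `feature_scaler` with `mean` and `sd`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    .stop_tfdnaqa("scaler needs at least two rows", "tfdnaqa_input_error")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s < 1e-12)) {
    warning("constant feature column(s); scale forced to 1")
    s[s < 1e-12] <- 1
  }
  structure(list(mean = m, sd = s), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param x numeric vector or matrix to standardize.
#' @param scaler a `feature_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  sweep(sweep(as.matrix(x), 2, scaler$mean), 2, scaler$sd, "/")
}

.identity_scaler <- function(d) {
  structure(list(mean = rep(0, d), sd = rep(1, d)),
            class = "feature_scaler")
}

# Platt sigmoid fit (regularized pseudo-label targets, Newton's method with
# backtracking; the standard numerically-stable formulation).  Returns
# c(A, B) such that p = 1 / (1 + exp(A * f + B)).
.platt_fit <- function(f, y, max_iter = 200, min_step = 1e-10,
                       sigma = 1e-12) {
  prior1 <- sum(y == 1)
  prior0 <- sum(y == 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y == 1, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  fval_of <- function(A, B) {
    fApB <- f * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- fval_of(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- f * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- fval_of(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
      if (step < min_step) return(c(A = A, B = B))
    }
  }
  c(A = A, B = B)
}

.kernel_decision <- function(model, X) {
  X <- as.matrix(X)
  if (model$kernel == "linear") {
    K <- X %*% t(model$sv)
  } else {
    d2 <- outer(rowSums(X^2), rowSums(model$sv^2), "+") -
      2 * X %*% t(model$sv)
    K <- exp(-model$gamma * pmax(d2, 0))
  }
  as.numeric(K %*% model$coefs - model$rho)
}

#' Train the quality-assessment SVM with Platt calibration
#'
#' Fits a soft-margin SVM on standardized features and calibrates a Platt
#' sigmoid on the training decision values, giving a probability `p` of
#' the near-native class.  Decision values are oriented so that larger
#' values favor the positive class regardless of internal label ordering.
#'
#' @param X standardized numeric feature matrix (use [fit_scaler()] /
#'   [apply_scaler()], or pass `scaler` to record the transformation in
#'   the model).
#' @param y labels, 1 = positive (near-native), 0 = negative; both classes
#'   must be present.
#' @param kernel `"rbf"` or `"linear"`.
#' @param C soft-margin cost.
#' @param gamma RBF width; default `1 / (ncol(X) * var(X))` over all
#'   entries, the common library default family.
#' @param seed integer seed recorded in the metadata (the fit itself is
#'   deterministic).
#' @param scaler optional `feature_scaler` stored in the model (identity
#'   when omitted).
#' @return Object of class `tfdnaqa_model`.
#' @export
train_svm <- function(X, y, kernel = c("rbf", "linear"), C = 1,
                      gamma = NULL, seed = 1, scaler = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    .stop_tfdnaqa("training labels contain a single class",
                  "tfdnaqa_training_error")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
  }
  fit <- e1071::svm(x = X, y = factor(y, levels = c("1", "0")),
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = C, gamma = gamma, scale = FALSE)
  sv <- as.matrix(fit$SV)
  coefs <- as.numeric(fit$coefs)
  rho <- as.numeric(fit$rho)
  model <- list(kernel = kernel, C = C, gamma = gamma, sv = sv,
                coefs = coefs, rho = rho,
                feature_names = colnames(X))
  dec <- .kernel_decision(model, X)
  # orient: larger decision value should favor the positive class
  if (mean(dec[y == 1]) < mean(dec[y == 0])) {
    model$coefs <- -model$coefs
    model$rho <- -rho
    dec <- -dec
  }
  model$platt <- .platt_fit(dec, y)
  model$scaler <- if (is.null(scaler)) .identity_scaler(ncol(X)) else scaler
  model$metadata <- list(seed = seed, n_pos = sum(y == 1),
                         n_neg = sum(y == 0), iterations = 1L,
                         converged = TRUE, subset_ids = NULL)
  class(model) <- "tfdnaqa_model"
  model
}

#' @export
print.tfdnaqa_model <- function(x, ...) {
  cat(sprintf(
    "<tfdnaqa_model: %s kernel, C=%g, gamma=%.4g, %d SVs, Platt A=%.3f B=%.3f>\n",
    x$kernel, x$C, x$gamma, nrow(x$sv), x$platt["A"], x$platt["B"]))
  invisible(x)
}

#' Calibrated probability and quality score for a feature matrix
#'
#' @param model a `tfdnaqa_model`.
#' @param X raw (unstandardized) feature matrix or vector; the model's
#'   stored scaler is applied.
#' @return Data frame with `decision_value`, `p` and `quality_score`
#'   (`1 - p`).
#' @export
predict_quality <- function(model, X) {
  Xs <- apply_scaler(X, model$scaler)
  dec <- .kernel_decision(model, Xs)
  p <- 1 / (1 + exp(model$platt["A"] * dec + model$platt["B"]))
  p <- pmin(pmax(p, .Machine$double.eps), 1 - 1e-15)
  data.frame(decision_value = dec, p = as.numeric(p),
             quality_score = as.numeric(1 - p))
}

#' Score a single model
#'
#' @param features a `feature_vector` (or named numeric vector with the
#'   four features).
#' @param model a `tfdnaqa_model`.
#' @return List of class `scored_model`: `model_id`, `features`,
#'   `decision_value`, `p`, `quality_score`.
#' @export
score_model <- function(features, model) {
  fid <- attr(features, "model_id")
  x <- matrix(as.numeric(features[model$feature_names]), nrow = 1,
              dimnames = list(NULL, model$feature_names))
  pr <- predict_quality(model, x)
  structure(list(model_id = if (is.null(fid)) NA_character_ else fid,
                 features = features, decision_value = pr$decision_value,
                 p = pr$p, quality_score = pr$quality_score),
            class = "scored_model")
}

#' Hard-negative mining
#'
#' Iterative rebalancing for heavily imbalanced training sets: start from
#' all positives plus a random negative sample of the same size, train,
#' then add every negative from the full pool that the current model calls
#' positive (p >= 0.5), retrain, and repeat until the training set is
#' unchanged or `max_iter` is reached.  The standardization statistics are
#' refitted on the current subset at each iteration and frozen into the
#' final model.
#'
#' @param X raw (unstandardized) feature matrix.
#' @param y labels (1/0); positives must not outnumber negatives.
#' @param kernel,C,gamma see [train_svm()].
#' @param seed integer seed for the initial negative sample.
#' @param max_iter iteration cap; non-convergence is flagged in the
#'   metadata, and the last model is still returned.
#' @return A `tfdnaqa_model` whose metadata records `iterations`,
#'   `converged`, and `subset_ids` (row indices of the final training
#'   subset, in the order added).
#' @export
hard_negative_mining <- function(X, y, kernel = c("rbf", "linear"), C = 1,
                                 gamma = NULL, seed = 1, max_iter = 50) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.integer(y)
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    .stop_tfdnaqa("both classes must be present", "tfdnaqa_training_error")
  if (length(pos) > length(neg))
    .stop_tfdnaqa("positives must not outnumber negatives",
                  "tfdnaqa_training_error")
  cur_neg <- withr::with_seed(seed, sample(neg, length(pos)))
  model <- NULL
  converged <- FALSE
  it <- 0L
  subset_trace <- integer()
  while (it < max_iter) {
    it <- it + 1L
    subset <- c(pos, cur_neg)
    subset_trace[it] <- length(subset)
    scaler <- fit_scaler(X[subset, , drop = FALSE])
    model <- train_svm(apply_scaler(X[subset, , drop = FALSE], scaler),
                       y[subset], kernel = kernel, C = C, gamma = gamma,
                       seed = seed, scaler = scaler)
    p_neg <- predict_quality(model, X[neg, , drop = FALSE])$p
    fp <- neg[p_neg >= 0.5]
    new <- setdiff(fp, cur_neg)
    if (length(new) == 0L) {
      converged <- TRUE
      break
    }
    cur_neg <- c(cur_neg, new)
  }
  if (!converged)
    warning(sprintf("hard-negative mining did not converge in %d iterations",
                    max_iter))
  model$metadata$iterations <- it
  model$metadata$converged <- converged
  model$metadata$subset_ids <- c(pos, cur_neg)
  model$metadata$subset_trace <- subset_trace
  model$metadata$seed <- seed
  model
}

#' Serialize / restore a trained model as JSON
#'
#' @param model a `tfdnaqa_model`.
#' @param path JSON file path.
#' @return `path` ([save_model()]) or a `tfdnaqa_model` ([load_model()]).
#' @export
save_model <- function(model, path) {
  obj <- list(kernel = model$kernel, C = model$C, gamma = model$gamma,
              sv = model$sv, coefs = model$coefs, rho = model$rho,
              platt = as.list(model$platt),
              scaler = list(mean = as.numeric(model$scaler$mean),
                            sd = as.numeric(model$scaler$sd)),
              feature_names = model$feature_names,
              metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(kernel = obj$kernel, C = obj$C, gamma = obj$gamma,
                sv = as.matrix(obj$sv), coefs = as.numeric(obj$coefs),
                rho = obj$rho,
                platt = c(A = obj$platt$A, B = obj$platt$B),
                scaler = structure(list(mean = obj$scaler$mean,
                                        sd = obj$scaler$sd),
                                   class = "feature_scaler"),
                feature_names = obj$feature_names,
                metadata = obj$metadata)
  class(model) <- "tfdnaqa_model"
  model
}
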
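# Confidence classifier: logistic model on alignment + interface features,
#   logit(p) = alpha + b1'X1 + b2'X2 + bi*Yi + b_plus*L_plus + b_minus*L_minus
# with L2 penalty on standardized features, plus ROC / cross-validation /
# association-test evaluation.

FEATURE_COLS <- c("seq_score_a", "ss_score_a", "len_a",
                  "seq_score_b", "ss_score_b", "len_b",
                  "interface_size", "l_plus", "l_minus")

#' Assemble a feature vector for a query pair
#'
#' Combines the alignment features reported by the upstream threading stage
#' (per-protein sequence score, secondary-structure score, length) with the
#' interface features computed here: the interface size `Yi` and the
#' log-likelihoods `L_plus`, `L_minus` of the interface assignment under the
#' positive and negative trees.
#'
#' @param record Named list or one-row data frame with `seq_score_a`,
#'   `ss_score_a`, `len_a`, `seq_score_b`, `ss_score_b`, `len_b` (and
#'   optionally `pair_id`).
#' @param assignment Named symbol vector over the profile's interface nodes.
#' @param pp A [profile_pair()] or `coev_interface_profile` fit.
#' @return One-row data frame in the dataset schema (without `label`).
#' @export
extract_features <- function(record, assignment, pp) {
  if (inherits(pp, "coev_interface_profile")) pp <- pp$profile_pair
  align_cols <- c("seq_score_a", "ss_score_a", "len_a",
                  "seq_score_b", "ss_score_b", "len_b")
  rec <- as.list(record)
  missing <- setdiff(align_cols, names(rec))
  if (length(missing)) {
    stop(sprintf("alignment record is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(pp$positive$nodes) == 0L) {
    stop("no interface model: the family profile has no interface nodes", call. = FALSE)
  }
  s <- score_interface(assignment, pp)
  out <- data.frame(pair_id = if (!is.null(rec$pair_id)) rec$pair_id else NA_character_,
                    seq_score_a = as.numeric(rec$seq_score_a),
                    ss_score_a = as.numeric(rec$ss_score_a),
                    len_a = as.numeric(rec$len_a),
                    seq_score_b = as.numeric(rec$seq_score_b),
                    ss_score_b = as.numeric(rec$ss_score_b),
                    len_b = as.numeric(rec$len_b),
                    interface_size = length(assignment),
                    l_plus = unname(s["L_plus"]),
                    l_minus = unname(s["L_minus"]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(as.numeric(out[1, FEATURE_COLS])))) {
    stop("non-finite feature value in assembled feature vector", call. = FALSE)
  }
  out
}

.design_matrix <- function(data) {
  missing <- setdiff(FEATURE_COLS, names(data))
  if (length(missing)) {
    stop(sprintf("dataset is missing feature column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(data[, FEATURE_COLS])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite feature values in dataset", call. = FALSE)
  x
}

#' Fit the logistic confidence model
#'
#' Maximizes the L2-penalized logistic log-likelihood
#' `sum log p(y_i | x_i) - lambda/2 * ||beta||^2` (intercept unpenalized) by
#' Newton-Raphson on standardized features, to gradient tolerance 1e-10.
#' The standardization parameters are stored so prediction is self-contained.
#'
#' @param data Data frame with a binary `label` column (0/1) and the feature
#'   columns `seq_score_a`, `ss_score_a`, `len_a`, `seq_score_b`,
#'   `ss_score_b`, `len_b`, `interface_size`, `l_plus`, `l_minus`.
#' @param regularization L2 penalty strength `lambda` (default 1).
#' @param max_iter Newton iteration cap.
#' @return An object of class `coev_confidence_model` with `alpha`, `beta`
#'   (named, standardized scale), `lambda`, `center`, `scale`, `features`,
#'   `converged`, `n`, `prevalence`.
#' @export
confidence_model <- function(data, regularization = 1, max_iter = 100) {
  if (!"label" %in% names(data)) stop("dataset must have a 'label' column", call. = FALSE)
  y <- as.numeric(data$label)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(y) < 2L) stop("at least two rows are required", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present for training", call. = FALSE)
  if (regularization < 0) stop("regularization must be non-negative", call. = FALSE)
  x <- .design_matrix(data)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  n <- nrow(xs); p <- ncol(xs)
  X <- cbind(1, xs)
  pen <- c(0, rep(regularization, p))       # intercept unpenalized
  theta <- rep(0, p + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - pen * theta
    if (max(abs(g)) < 1e-10) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + diag(pen + 1e-12, p + 1)
    step <- solve(H, g)
    # damped Newton: halve until the penalized objective does not decrease
    obj <- function(th) {
      e <- drop(X %*% th)
      sum(y * e - log1p(exp(e))) - sum(pen * th^2) / 2
    }
    f0 <- obj(theta); lam <- 1
    repeat {
      cand <- theta + lam * step
      if (obj(cand) >= f0 - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- theta + lam * step
  }
  structure(list(alpha = unname(theta[1]),
                 beta = stats::setNames(theta[-1], FEATURE_COLS),
                 lambda = regularization,
                 center = stats::setNames(center, FEATURE_COLS),
                 scale = stats::setNames(scale, FEATURE_COLS),
                 features = FEATURE_COLS,
                 converged = converged,
                 n = n,
                 prevalence = mean(y)),
            class = "coev_confidence_model")
}

#' @export
print.coev_confidence_model <- function(x, ...) {
  cat(sprintf("Logistic confidence model (n = %d, lambda = %g)\n", x$n, x$lambda))
  cat(sprintf("  alpha = %.4f\n", x$alpha))
  print(round(x$beta, 4))
  invisible(x)
}

#' @method coef coev_confidence_model
#' @export
coef.coev_confidence_model <- function(object, ...) {
  c(alpha = object$alpha, object$beta)
}

#' @method summary coev_confidence_model
#' @export
summary.coev_confidence_model <- function(object, ...) {
  cat(sprintf("Logistic confidence model on standardized features\n"))
  cat(sprintf("  n = %d, class prevalence = %.3f, lambda = %g, converged: %s\n",
              object$n, object$prevalence, object$lambda, object$converged))
  print(round(coef(object), 4))
  invisible(object)
}

#' Predict interaction confidence
#'
#' @param object A [confidence_model()] fit.
#' @param newdata Data frame with the feature columns.
#' @param type `"response"` (probability, default), `"link"` (linear
#'   predictor), or `"class"` (high/low confidence at `cutoff`).
#' @param cutoff Probability cutoff for `type = "class"` (default 0.6).
#' @param ... Unused.
#' @return Numeric vector of probabilities / linear predictors, or logical
#'   high-confidence labels.
#' @export
predict.coev_confidence_model <- function(object, newdata,
                                          type = c("response", "link", "class"),
                                          cutoff = 0.6, ...) {
  type <- match.arg(type)
  x <- .design_matrix(newdata)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  eta <- drop(object$alpha + xs %*% object$beta)
  if (type == "link") return(eta)
  p <- stats::plogis(eta)
  if (type == "response") return(p)
  classify_high_confidence(p, cutoff)
}

#' High-confidence call at a probability cutoff
#'
#' An interaction is high confidence when its predicted probability is at
#' least the cutoff (boundary inclusive); the default cutoff is 0.6.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param cutoff Cutoff in `[0, 1]`.
#' @return Logical vector.
#' @export
classify_high_confidence <- function(p, cutoff = 0.6) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("cutoff must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p >= cutoff
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (equal scores collapse to one
#' threshold; predictions are positive when `score >= threshold`), computing
#' sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)`; the area
#' under the curve is the trapezoidal integral, equal to the normalized
#' Mann-Whitney U statistic with ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1) with both classes present.
#' @return An object of class `coev_roc`: data frame fields `threshold`,
#'   `sensitivity`, `specificity`, plus `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes are required for a ROC curve", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- numeric(length(thr)); spec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pred <- scores >= thr[k]
    sens[k] <- sum(pred & labels == 1) / n_pos
    spec[k] <- sum(!pred & labels == 0) / n_neg
  }
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(threshold = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "coev_roc")
}

#' @export
print.coev_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @method plot coev_roc
#' @export
plot.coev_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Sensitivity at given specificities by stepwise interpolation of a ROC curve.
.sens_at_spec <- function(roc, spec_grid) {
  ord <- order(roc$specificity, -roc$sensitivity)
  sp <- roc$specificity[ord]; se <- roc$sensitivity[ord]
  vapply(spec_grid, function(s) {
    ok <- sp >= s
    if (!any(ok)) 0 else max(se[ok])
  }, 0)
}

#' Stratified k-fold cross-validation of the confidence model
#'
#' Splits the dataset into `k` stratified folds (each fold keeps the class
#' ratio), trains on `k - 1` folds and evaluates on the held-out fold,
#' optionally repeating with reshuffled folds. Reports per-fold and pooled
#' AUC and mean sensitivity on a specificity grid.
#'
#' @param data Labeled dataset (see [confidence_model()]).
#' @param k Number of folds (default 5).
#' @param n_repeats Number of repeated fold reshuffles (default 1).
#' @param rng_seed Integer seed for the fold assignment.
#' @param regularization Passed to [confidence_model()].
#' @param specificity_grid Specificities at which mean sensitivity is
#'   reported.
#' @return An object of class `coev_cv`: `fold_auc` (matrix repeats x k),
#'   `pooled_auc` (per repeat), `mean_auc`, `sd_auc`, `sensitivity`
#'   (mean over folds at `specificity_grid`), `predictions` (data frame of
#'   held-out scores from the first repeat), `k`, `n_repeats`.
#' @export
cross_validate <- function(data, k = 5, n_repeats = 1, rng_seed = NULL,
                           regularization = 1,
                           specificity_grid = seq(0, 1, by = 0.05)) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  y <- as.numeric(data$label)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (min(sum(y == 1), sum(y == 0)) < k) {
    stop("each class must have at least k members for stratified folds", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(y)
  fold_auc <- matrix(NA_real_, nrow = n_repeats, ncol = k)
  pooled_auc <- numeric(n_repeats)
  sens_acc <- matrix(0, nrow = n_repeats, ncol = length(specificity_grid))
  predictions <- NULL
  folds_first <- NULL
  for (r in seq_len(n_repeats)) {
    # stratified and globally balanced: the fold cycle continues across
    # classes so overall fold sizes differ by at most one
    folds <- integer(n)
    start <- 0L
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    if (r == 1L) folds_first <- folds
    scores <- numeric(n)
    sens_f <- matrix(0, nrow = k, ncol = length(specificity_grid))
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- confidence_model(data[!test, , drop = FALSE], regularization)
      scores[test] <- predict(fit, data[test, , drop = FALSE])
      roc_f <- roc_curve(scores[test], y[test])
      fold_auc[r, f] <- roc_f$auc
      sens_f[f, ] <- .sens_at_spec(roc_f, specificity_grid)
    }
    pooled_auc[r] <- roc_curve(scores, y)$auc
    sens_acc[r, ] <- colMeans(sens_f)
    if (r == 1L) {
      predictions <- data.frame(
        pair_id = if ("pair_id" %in% names(data)) data$pair_id else seq_len(n),
        fold = folds, label = y, score = scores, stringsAsFactors = FALSE)
    }
  }
  structure(list(fold_auc = fold_auc,
                 pooled_auc = pooled_auc,
                 mean_auc = mean(fold_auc),
                 sd_auc = stats::sd(as.vector(fold_auc)),
                 specificity_grid = specificity_grid,
                 sensitivity = colMeans(sens_acc),
                 predictions = predictions,
                 folds = folds_first,
                 k = k, n_repeats = n_repeats),
            class = "coev_cv")
}

#' @export
print.coev_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d repeat(s))\n", x$k, x$n_repeats))
  cat(sprintf("  mean fold AUC = %.4f (sd %.4f); pooled AUC = %.4f\n",
              x$mean_auc, x$sd_auc, mean(x$pooled_auc)))
  invisible(x)
}

#' Association between predicted and reference interaction labels
#'
#' Populates the 2 x 2 contingency table of predicted vs reference binary
#' labels and applies Fisher's exact test (two-sided). The odds ratio is the
#' sample cross-product ratio, with the Haldane 0.5 correction applied to all
#' cells when any cell is zero.
#'
#' @param predicted_labels,reference_labels Binary (0/1 or logical) vectors
#'   of equal length.
#' @return List with `table`, `odds_ratio`, `p_value`.
#' @export
association_test <- function(predicted_labels, reference_labels) {
  p <- as.integer(as.logical(predicted_labels))
  r <- as.integer(as.logical(reference_labels))
  if (length(p) != length(r)) stop("label vectors differ in length", call. = FALSE)
  if (length(p) < 1L) stop("empty label vectors", call. = FALSE)
  tab <- table(factor(p, levels = c(1, 0)), factor(r, levels = c(1, 0)),
               dnn = c("predicted", "reference"))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c_)
  pv <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = unname(or), p_value = pv)
}

#' Write / read a confidence model as JSON
#'
#' @param model A [confidence_model()] fit.
#' @param path File path.
#' @return `read_model_json` returns the model.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "coev_confidence_model"))
  obj <- list(alpha = model$alpha, beta = as.list(model$beta),
              lambda = model$lambda,
              center = as.list(model$center), scale = as.list(model$scale),
              features = model$features, n = model$n,
              prevalence = model$prevalence, converged = model$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(alpha = obj$alpha,
                 beta = unlist(obj$beta)[FEATURE_COLS],
                 lambda = obj$lambda,
                 center = unlist(obj$center)[FEATURE_COLS],
                 scale = unlist(obj$scale)[FEATURE_COLS],
                 features = FEATURE_COLS,
                 converged = obj$converged,
                 n = obj$n,
                 prevalence = obj$prevalence),
            class = "coev_confidence_model")
}
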
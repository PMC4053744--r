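test_that("feature extraction assembles alignment and interface features", {
  tr <- random_tree(3, seed = 90)
  pp <- profile_pair(tr, random_tree_like <- tr)
  rec <- list(pair_id = "q1", seq_score_a = 1, ss_score_a = 2, len_a = 100,
              seq_score_b = 3, ss_score_b = 4, len_b = 200)
  a <- stats::setNames(c("A", "C", "W"), tr$nodes)
  fv <- extract_features(rec, a, pp)
  expect_equal(fv$interface_size, 3)
  expect_equal(fv$seq_score_a, 1)
  expect_equal(fv$len_b, 200)
  s <- score_interface(a, pp)
  expect_equal(fv$l_plus, unname(s["L_plus"]), tolerance = 1e-12)
  expect_equal(fv$l_minus, unname(s["L_minus"]), tolerance = 1e-12)
  expect_error(extract_features(rec[-2], a, pp), "seq_score_a")
})

test_that("all-zero features give alpha = logit(prevalence) and zero betas", {
  d <- data.frame(label = c(rep(1, 30), rep(0, 70)),
                  matrix(0, 100, 9, dimnames = list(NULL, c(
                    "seq_score_a", "ss_score_a", "len_a", "seq_score_b",
                    "ss_score_b", "len_b", "interface_size", "l_plus", "l_minus"))))
  for (lam in c(0.01, 1, 10)) {
    m <- confidence_model(d, regularization = lam)
    expect_equal(m$alpha, stats::qlogis(0.3), tolerance = 1e-6)
    expect_equal(unname(m$beta), rep(0, 9), tolerance = 1e-8)
  }
})

test_that("training at near-zero penalty agrees with glm", {
  set.seed(101)
  beta <- c(0.8, 0, 0.5, -0.7, 0, 0, 0.3, 1.2, -1.0)
  d <- sim_logistic_data(800, beta, alpha = -0.3, seed = 101)
  m <- confidence_model(d, regularization = 1e-8)
  feat <- m$features
  xs <- scale(as.matrix(d[, feat]))
  gd <- data.frame(y = d$label, xs)
  g <- stats::glm(y ~ ., data = gd, family = stats::binomial())
  expect_equal(m$alpha, unname(stats::coef(g)[1]), tolerance = 1e-5)
  expect_equal(unname(m$beta), unname(stats::coef(g)[-1]), tolerance = 1e-5)
})

test_that("coefficients are recovered from simulated data within 3 SE", {
  set.seed(55)
  beta <- c(0.5, -0.4, 0, 0.9, 0, 0.2, -0.6, 1.0, -0.8)
  d <- sim_logistic_data(5000, beta, alpha = 0.2, seed = 55)
  m <- confidence_model(d, regularization = 1e-6)
  # standard errors from the inverse Fisher information at the fit
  xs <- sweep(sweep(as.matrix(d[, m$features]), 2, m$center), 2, m$scale, "/")
  X <- cbind(1, xs)
  mu <- stats::plogis(drop(X %*% c(m$alpha, m$beta)))
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))))))
  # features were simulated standard-normal, so standardized-scale
  # coefficients estimate the generating ones up to sampling noise
  est <- c(m$alpha, unname(m$beta))
  truth <- c(0.2, beta * unname(m$scale))
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("training is invariant to row order and separable data stay finite", {
  d <- sim_logistic_data(200, c(1, 0, 0, 0, 0, 0, 0, 2, -2), seed = 7)
  m1 <- confidence_model(d, regularization = 1)
  m2 <- confidence_model(d[sample(nrow(d)), ], regularization = 1)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-9)

  sep <- data.frame(label = c(0, 1),
                    matrix(c(rep(0, 9), rep(1, 9)), 2, 9, byrow = TRUE,
                           dimnames = list(NULL, m1$features)))
  ms <- confidence_model(sep, regularization = 5)
  expect_true(all(is.finite(coef(ms))))
  p <- predict(ms, sep)
  expect_true(all(p > 0 & p < 1))

  one_class <- d; one_class$label <- 1
  expect_error(confidence_model(one_class), "both classes")
})

test_that("predicted confidence follows the inverse-logit identities", {
  d <- sim_logistic_data(100, rep(0, 9), seed = 3)
  m <- confidence_model(d, regularization = 1)
  m$alpha <- 0; m$beta[] <- 0
  expect_equal(unname(predict(m, d[1:5, ])), rep(0.5, 5), tolerance = 1e-12)
  # linear predictor logit(0.6) by construction -> p = 0.6
  m$alpha <- stats::qlogis(0.6)
  expect_equal(unname(predict(m, d[1, ])), 0.6, tolerance = 1e-12)
  # strictly increasing in l_plus when its coefficient is positive
  m$beta["l_plus"] <- 0.7
  grid <- d[rep(1, 21), ]
  grid$l_plus <- seq(-3, 3, length.out = 21)
  p <- predict(m, grid)
  expect_true(all(diff(p) > 0))
})

test_that("high-confidence calls use an inclusive 0.6 boundary", {
  expect_true(classify_high_confidence(0.61))
  expect_true(classify_high_confidence(0.6))
  expect_false(classify_high_confidence(0.59))
  expect_equal(classify_high_confidence(c(0, 0.2, 1), cutoff = 0), rep(TRUE, 3))
  expect_error(classify_high_confidence(0.5, cutoff = 1.2), "cutoff")
  expect_error(classify_high_confidence(1.5), "0, 1")
})

test_that("ROC curves match hand enumeration and the Mann-Whitney identity", {
  # 4-point hand oracle
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  k <- which(r$threshold == 0.8)
  expect_equal(r$sensitivity[k], 1)
  expect_equal(r$specificity[k], 1)
  # perfectly separated -> AUC 1; anti-separated -> AUC 0
  expect_equal(roc_curve(1:10, c(rep(0, 5), rep(1, 5)))$auc, 1)
  expect_equal(roc_curve(1:10, c(rep(1, 5), rep(0, 5)))$auc, 0)

  # AUC equals the normalized Mann-Whitney U statistic (ties counted half)
  set.seed(8)
  for (i in 1:5) {
    scores <- round(stats::rnorm(60), 1)  # induce ties
    labels <- stats::rbinom(60, 1, 0.4)
    if (length(unique(labels)) < 2) next
    r <- roc_curve(scores, labels)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    u <- mean(outer(pos, neg, function(p_, n_) (p_ > n_) + 0.5 * (p_ == n_)))
    expect_equal(r$auc, u, tolerance = 1e-9)
  }

  # permuted labels give AUC ~ 0.5
  set.seed(9)
  scores <- stats::rnorm(10000)
  labels <- sample(c(rep(1, 5000), rep(0, 5000)))
  expect_equal(roc_curve(scores, labels)$auc, 0.5, tolerance = 0.02)

  # sensitivity is non-increasing as the threshold rises
  r <- roc_curve(stats::rnorm(50), stats::rbinom(50, 1, 0.5))
  ord <- order(r$threshold)
  expect_true(all(diff(r$sensitivity[ord]) <= 0))
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("stratified cross-validation builds balanced folds deterministically", {
  d <- sim_logistic_data(100, c(0, 0, 0, 0, 0, 0, 0, 1.5, -1.5), seed = 11)
  cv <- cross_validate(d, k = 5, rng_seed = 21)
  expect_equal(as.vector(table(cv$folds)), rep(20L, 5))
  # stratification: both classes in every fold
  for (f in 1:5) expect_gt(min(table(d$label[cv$folds == f])), 0)
  # each pair id held out exactly once
  expect_setequal(cv$predictions$pair_id, d$pair_id)
  # deterministic given the seed
  cv2 <- cross_validate(d, k = 5, rng_seed = 21)
  expect_identical(cv$fold_auc, cv2$fold_auc)
  # leave-one-out on a 10-row subset: 10 folds of size 1
  d10 <- d[c(1:5, 51:55), ]
  d10$label <- rep(c(1, 0), each = 5)
  cv10 <- cross_validate(d10, k = 5, rng_seed = 2)
  expect_equal(as.vector(table(cv10$folds)), rep(2L, 5))
  expect_error(cross_validate(d10, k = 6), "at least k")
})

test_that("informative features beat label-permuted copies in CV AUC", {
  set.seed(31)
  d <- sim_logistic_data(200, c(0, 0, 0, 0, 0, 0, 0, 2, -2), seed = 31)
  auc_real <- cross_validate(d, k = 5, rng_seed = 1)$mean_auc
  perm_auc <- replicate(5, {
    dp <- d; dp$label <- sample(dp$label)
    cross_validate(dp, k = 5, rng_seed = 1)$mean_auc
  })
  expect_gt(auc_real, max(perm_auc))
})

test_that("association test matches the hypergeometric enumeration", {
  # [[8, 2], [1, 9]]: two-sided Fisher p equals the exact tail sum
  pred <- c(rep(1, 10), rep(0, 10))
  ref <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  out <- association_test(pred, ref)
  # enumerate tables with the same margins; sum probabilities <= observed
  m <- 9; n_ <- 11; k <- 10  # reference positives, negatives, predicted positives
  probs <- stats::dhyper(0:9, m, n_, k)
  p_obs <- stats::dhyper(8, m, n_, k)
  brute <- sum(probs[probs <= p_obs + 1e-12])
  expect_equal(out$p_value, brute, tolerance = 1e-9)
  expect_gt(out$odds_ratio, 1)

  # no association: flat table
  flat <- association_test(rep(c(1, 0), 20), rep(c(1, 1, 0, 0), 10))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  # perfect association at n = 20 balanced
  perfect <- association_test(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
  expect_lt(perfect$p_value, 0.05)
  expect_error(association_test(1:3 > 1, 1:4 > 1), "length")
})

test_that("confidence models round-trip through JSON", {
  d <- sim_logistic_data(150, c(0.5, 0, 0, 0, 0, 0, 0, 1, -1), seed = 17)
  m <- confidence_model(d, regularization = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(coef(back), coef(m), tolerance = 1e-12)
  expect_equal(predict(back, d[1:10, ]), predict(m, d[1:10, ]), tolerance = 1e-12)
})
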
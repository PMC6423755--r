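make_labeled <- function(n1, n0, p = 6, effect = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n0) * p), n1 + n0,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- factor(rep(c(0, 1), c(n0, n1)), levels = 0:1)
  x[y == 1, 1] <- x[y == 1, 1] + effect
  list(x = x, y = y)
}

test_that("rank-sum p-values match the exact extreme case and the null", {
  x <- cbind(v = c(1, 2, 3, 10, 11, 12))
  y <- factor(rep(0:1, each = 3), levels = 0:1)
  r <- rank_wrst(x, y)
  expect_equal(r$p_value, 0.1)          # most extreme split at n = 3, 3

  x2 <- cbind(v = c(5, 6, 7, 5, 6, 7))
  expect_equal(rank_wrst(x2, y)$p_value, 1)

  x3 <- cbind(v = rep(2, 6))
  expect_message(r3 <- rank_wrst(x3, y), "constant")
  expect_equal(r3$p_value, 1)
})

test_that("rank-sum p equals full enumeration of rank assignments", {
  set.seed(5)
  for (rep in 1:5) {
    v <- sample(seq(1, 100), 8)         # tie-free
    y <- factor(rep(0:1, each = 4), levels = 0:1)
    p_pkg <- rank_wrst(cbind(v = v), y)$p_value

    # brute-force permutation oracle over all C(8,4) = 70 assignments
    r <- rank(v)
    u_obs <- sum(r[y == 1]) - 4 * 5 / 2
    combos <- combn(8, 4)
    u_all <- apply(combos, 2, function(i) sum(r[i]) - 10)
    p_ref <- mean(abs(u_all - 8) >= abs(u_obs - 8))
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
    expect_equal(p_pkg,
                 wilcox.test(v[y == 1], v[y == 0], exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum approximation matches the classical test under ties", {
  set.seed(8)
  v <- round(rnorm(60), 1)              # heavy ties
  y <- factor(rep(0:1, 30), levels = 0:1)
  p_pkg <- rank_wrst(cbind(v = v), y)$p_value
  p_ref <- wilcox.test(v[y == 1], v[y == 0], exact = FALSE,
                       correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
})

test_that("mRMR is relevance-first and redundancy-aware", {
  set.seed(2)
  n <- 60
  y <- factor(rep(0:1, each = n / 2), levels = 0:1)
  # a feature identical to the label has maximal relevance: 1 bit
  r0 <- rank_mrmr(cbind(exact = as.numeric(y), junk = rnorm(n)), y)
  expect_equal(r0$feature[1], "exact")
  expect_equal(r0$score[1], 1)

  f1 <- 3 * as.numeric(y) + rnorm(n)        # strong continuous signal
  weak <- as.numeric(y) + rnorm(n)          # weaker, independent noise
  noise <- rnorm(n)
  x <- cbind(dup_a = f1, dup_b = f1, weak = weak, noise = noise)
  r <- rank_mrmr(x, y, n_bins = 4)
  expect_equal(r$feature[1], "dup_a")       # maximal relevance, tie by name
  # the exact duplicate is demoted below the independent weak feature
  expect_lt(match("weak", r$feature), match("dup_b", r$feature))
  expect_error(rank_mrmr(x[, 1, drop = FALSE], y), ">= 2 features")
  expect_error(rank_mrmr(x, factor(rep(1, n))), "2 classes")
})

test_that("forest importance finds the informative feature reproducibly", {
  hits <- 0
  for (s in 1:20) {
    d <- make_labeled(20, 20, p = 10, effect = 2, seed = 100 + s)
    r <- rank_rf_importance(d$x, d$y, n_trees = 300, seed = s)
    if (r$feature[1] == "f01") hits <- hits + 1
  }
  expect_gte(hits, 19)

  d <- make_labeled(20, 20, p = 10, effect = 2, seed = 55)
  r1 <- rank_rf_importance(d$x, d$y, seed = 9)
  r2 <- rank_rf_importance(d$x, d$y, seed = 9)
  expect_identical(r1, r2)

  # duplicated informative column: importance splits but both stay high
  x2 <- cbind(d$x, f01dup = d$x[, "f01"])
  rd <- rank_rf_importance(x2, d$y, n_trees = 500, seed = 3)
  expect_lte(max(match(c("f01", "f01dup"), rd$feature)), 4)
})

test_that("stability selection returns 5 features and saturates on strong signal", {
  d <- make_labeled(15, 25, p = 12, effect = 5, seed = 42)
  bin <- stability_select(d$x, d$y, "WRST", n_iter = 20, seed = 1)
  expect_s3_class(bin, "nm_feature_bin")
  expect_length(bin$features, 5)
  expect_false(any(duplicated(bin$features)))
  expect_equal(bin$features[1], "f01")
  expect_equal(bin$stability_scores[1], 1.0)
  expect_true(all(bin$stability_scores >= 0 & bin$stability_scores <= 1))

  expect_error(stability_select(d$x[1:4, ], d$y[1:4], "WRST"), "at least")
  tiny <- make_labeled(2, 10, p = 6, seed = 1)
  expect_error(stability_select(tiny$x, tiny$y, "WRST", n_iter = 2),
               "stratified")
})

test_that("pure-noise stability never saturates, unlike real signal", {
  # chance-level features do persist across folds of one fixed dataset, so
  # the null ceiling is well below the saturation a real effect produces
  mx <- numeric(6)
  for (s in 1:6) {
    d <- make_labeled(20, 30, p = 189, effect = 0, seed = 300 + s)
    bin <- stability_select(d$x, d$y, "WRST", n_iter = 50, seed = s)
    mx[s] <- max(bin$stability_scores)
  }
  expect_true(all(mx < 0.9))
  sig <- make_labeled(20, 30, p = 189, effect = 2, seed = 1)
  bsig <- stability_select(sig$x, sig$y, "WRST", n_iter = 50, seed = 1)
  expect_gt(bsig$stability_scores[1], max(mx))
})

test_that("AUC equals brute-force pairwise concordance, ties counted half", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # forces ties
    y <- factor(rbinom(n, 1, 0.4), levels = 0:1)
    if (length(unique(y)) < 2) next
    a_pkg <- auc_score(sc, y)
    pos <- sc[y == 1]; neg <- sc[y == 0]
    conc <- 0
    for (p in pos) for (q in neg)
      conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(a_pkg, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("the learner-by-bin grid has 12 rows with coherent metrics", {
  d <- make_labeled(20, 20, p = 189, effect = 0, seed = 10)
  colnames(d$x) <- feature_names()
  sep <- d$x
  sep[d$y == 1, 1:5] <- sep[d$y == 1, 1:5] + 6     # fully separable
  bins <- list(
    structure(list(method = "WRST", features = colnames(sep)[1:5],
                   stability_scores = rep(1, 5)), class = "nm_feature_bin"),
    structure(list(method = "MRMR", features = colnames(sep)[c(1:3, 6:7)],
                   stability_scores = rep(1, 5)), class = "nm_feature_bin"),
    structure(list(method = "RF", features = colnames(sep)[c(1, 2, 8:10)],
                   stability_scores = rep(1, 5)), class = "nm_feature_bin"))
  grid <- train_eval_grid(sep, d$y, bins, seed = 4, n_rep = 3)
  expect_equal(nrow(grid), 12)
  expect_equal(nrow(unique(grid[, c("learner", "bin_method")])), 12)
  mcols <- grep("_mean$|_sd$", names(grid), value = TRUE)
  expect_true(all(grid[, mcols] >= 0 & grid[, mcols] <= 1))
  expect_true(all(grid$auc_mean >= 0.95))

  # label permutation drives every combination to chance level
  set.seed(11)
  yperm <- sample(d$y)
  gp <- train_eval_grid(sep, yperm, bins, seed = 4, n_rep = 3)
  expect_gt(mean(gp$auc_mean), 0.35)
  expect_lt(mean(gp$auc_mean), 0.65)
})

test_that("the best combination is chosen by AUC with fixed tie-breaks", {
  tmpl <- expand.grid(learner = c("ALD", "AQD", "MSV", "RF"),
                      bin_method = c("WRST", "MRMR", "RF"),
                      stringsAsFactors = FALSE)
  g <- data.frame(tmpl, auc_mean = 0.80, auc_sd = 0.01,
                  accuracy_mean = 0.8, accuracy_sd = 0.01,
                  specificity_mean = 0.8, specificity_sd = 0.01,
                  sensitivity_mean = 0.8, sensitivity_sd = 0.01)
  g$auc_mean[g$learner == "MSV" & g$bin_method == "WRST"] <- 0.87
  best <- pick_best_combo(g)
  expect_equal(best$learner, "MSV")
  expect_equal(best$bin_method, "WRST")

  # all-equal metrics fall back to the fixed learner, then bin order
  g2 <- g; g2$auc_mean <- 0.8
  b2 <- pick_best_combo(g2)
  expect_equal(b2$learner, "ALD")
  expect_equal(b2$bin_method, "WRST")

  # accuracy breaks an AUC tie
  g3 <- g; g3$auc_mean <- 0.8
  g3$accuracy_mean[g3$learner == "RF" & g3$bin_method == "MRMR"] <- 0.9
  b3 <- pick_best_combo(g3)
  expect_equal(c(b3$learner, b3$bin_method), c("RF", "MRMR"))

  expect_error(pick_best_combo(g[1:2, ]), "expected 12 results")
})

test_that("recurrence calls are strictly above-threshold", {
  d <- make_labeled(15, 15, p = 8, effect = 3, seed = 21)
  m <- train_model(d$x, d$y, colnames(d$x)[1:5], "RF", seed = 2,
                   n_trees = 100)
  calls <- predict_recurrence(m, d$x)
  expect_identical(calls$label, as.integer(calls$probability > 0.5))
  # a probability exactly at the threshold is a negative call
  thr <- calls$probability[5]
  at <- predict_recurrence(m, d$x, threshold = thr)
  expect_equal(at$label[5], 0L)
  expect_true(all(at$label[at$probability > thr] == 1L))

  # training spots re-predicted on a separable cohort match their labels
  expect_equal(calls$label, as.integer(d$y) - 1L)

  empty <- predict_recurrence(m, d$x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_error(predict_recurrence(m, d$x[, 1:3]), "missing feature")
})

test_that("every learner emits calibrated probabilities", {
  d <- make_labeled(20, 20, p = 8, effect = 2.5, seed = 31)
  for (ln in c("ALD", "AQD", "MSV", "RF")) {
    m <- train_model(d$x, d$y, colnames(d$x)[1:5], ln, seed = 6)
    pr <- predict_recurrence(m, d$x)$probability
    expect_true(all(pr >= 0 & pr <= 1))
    expect_gt(auc_score(pr, d$y), 0.9)
  }
  # singular covariance falls back to the regularized discriminant
  xs <- d$x
  xs[, 2] <- xs[, 1]                     # collinear pair
  expect_message(m <- train_model(xs, d$y, colnames(xs)[1:5], "AQD",
                                  seed = 6),
                 "regulari")
  pr <- predict_recurrence(m, xs)$probability
  expect_true(all(is.finite(pr)))
})
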
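as_binary_labels <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(f) != 2)
    stop("labels must contain exactly 2 classes, got ", nlevels(f))
  f
}

#' Rank features by the Wilcoxon rank-sum test
#'
#' Per-feature two-sided rank-sum p-value between the two classes, with
#' midrank tie handling: exact tail probabilities when both groups have
#' fewer than 50 spots and the feature has no ties, otherwise the
#' tie-corrected normal approximation with continuity correction (the
#' classical test's conventions). Features are ranked by ascending p,
#' ties broken by feature name. Constant features get p = 1 by convention.
#'
#' @param features numeric matrix, spots x features, named columns.
#' @param labels two-class vector (second factor level is the positive
#'   class; only group membership matters here).
#' @return data.frame `feature`, `p_value`, `statistic` (rank-sum U of the
#'   positive class), sorted by ascending p then name.
#' @export
rank_wrst <- function(features, labels) {
  f <- as_binary_labels(labels)
  x_is <- f == levels(f)[2]
  n1 <- sum(x_is); n0 <- sum(!x_is)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  N <- n1 + n0
  p <- ncol(features)
  pv <- uv <- numeric(p)
  n_const <- 0L
  for (k in seq_len(p)) {
    v <- features[, k]
    if (max(v) == min(v)) { pv[k] <- 1; uv[k] <- n1 * n0 / 2; n_const <- n_const + 1L; next }
    r <- rank(v)
    U <- sum(r[x_is]) - n1 * (n1 + 1) / 2
    uv[k] <- U
    ties <- tabulate(match(v, v))
    has_ties <- anyDuplicated(v) > 0
    if (!has_ties && n1 < 50 && n0 < 50) {
      pe <- if (U > n1 * n0 / 2) 1 - stats::pwilcox(U - 1, n1, n0)
            else stats::pwilcox(U, n1, n0)
      pv[k] <- min(2 * pe, 1)
    } else {
      z <- U - n1 * n0 / 2
      sigma2 <- (n1 * n0 / 12) *
        ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      corr <- sign(z) * 0.5
      pv[k] <- min(1, 2 * stats::pnorm(abs(z - corr) / sqrt(sigma2),
                                       lower.tail = FALSE))
    }
  }
  if (n_const > 0)
    message(n_const, " constant feature(s) assigned p = 1")
  nm <- colnames(features) %||% as.character(seq_len(p))
  ord <- order(pv, nm)
  data.frame(feature = nm[ord], p_value = pv[ord], statistic = uv[ord],
             stringsAsFactors = FALSE)
}

quantile_bin <- function(v, n_bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  if (length(br) < 2) return(factor(rep(1L, length(v))))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

mutual_information_bits <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  pos <- pj > 0
  sum(pj[pos] * log2(pj[pos] / outer(px, py)[pos]))
}

#' Rank features by minimum-redundancy maximum-relevance
#'
#' Discretizes each feature into quantile bins and greedily selects
#' features maximizing `I(f; label) - mean over selected g of I(f; g)`,
#' mutual information in bits (the MID criterion).
#'
#' @param features numeric matrix, spots x features (>= 2 features).
#' @param labels two-class vector.
#' @param n_bins quantile bin count for discretization (default 4).
#' @param k number of features to rank greedily (default all).
#' @return data.frame `feature`, `score` (criterion value at selection), in
#'   greedy selection order.
#' @export
rank_mrmr <- function(features, labels, n_bins = 4L, k = ncol(features)) {
  f <- as_binary_labels(labels)
  if (ncol(features) < 2) stop("need >= 2 features")
  k <- min(k, ncol(features))
  nm <- colnames(features) %||% as.character(seq_len(ncol(features)))
  disc <- lapply(seq_len(ncol(features)), function(j)
    quantile_bin(features[, j], n_bins))
  rel <- vapply(disc, function(d) mutual_information_bits(d, f), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(ncol(features))
  avail <- seq_len(ncol(features))
  for (step in seq_len(k)) {
    crit <- if (length(selected) == 0) rel[avail]
            else rel[avail] - red_sum[avail] / length(selected)
    best <- avail[order(-crit, nm[avail])][1]
    scores <- c(scores, crit[match(best, avail)])
    selected <- c(selected, best)
    avail <- setdiff(avail, best)
    if (length(avail))
      red_sum[avail] <- red_sum[avail] + vapply(avail, function(j)
        mutual_information_bits(disc[[j]], disc[[best]]), numeric(1))
  }
  data.frame(feature = nm[selected], score = scores,
             stringsAsFactors = FALSE)
}

#' Rank features by random-forest impurity importance
#'
#' Mean decrease in Gini impurity over `n_trees` randomized trees; seeded
#' and reproducible.
#'
#' @param features numeric matrix, spots x features.
#' @param labels two-class vector (>= 2 spots per class).
#' @param n_trees forest size (default 500).
#' @param seed integer seed.
#' @return data.frame `feature`, `importance`, sorted descending
#'   (ties broken by name).
#' @export
rank_rf_importance <- function(features, labels, n_trees = 500L, seed = 1L) {
  f <- as_binary_labels(labels)
  if (min(table(f)) < 2) stop("need >= 2 spots per class")
  imp <- with_local_seed(seed, {
    fit <- randomForest::randomForest(x = as.data.frame(features), y = f,
                                      ntree = n_trees)
    fit$importance[, "MeanDecreaseGini"]
  })
  nm <- colnames(features) %||% as.character(seq_along(imp))
  ord <- order(-imp, nm)
  data.frame(feature = nm[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

stratified_folds <- function(f, n_folds) {
  fold <- integer(length(f))
  for (lv in levels(f)) {
    idx <- which(f == lv)
    if (length(idx) < n_folds)
      stop("class '", lv, "' has fewer members (", length(idx),
           ") than folds (", n_folds, "): stratified folding impossible")
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Stability feature selection over repeated cross-validation folds
#'
#' Runs the chosen ranking scheme (`WRST`, `MRMR` or `RF`) on the training
#' portion of each fold of `n_iter` randomized stratified `n_folds`-fold
#' splits, records each fold's top-`k` list, and returns the `k` features
#' with the highest selection frequency across all `n_folds * n_iter`
#' fold-rankings (ties broken by name).
#'
#' @param features spots x features matrix (>= 2 * n_folds spots).
#' @param labels two-class vector.
#' @param method one of `"WRST"`, `"MRMR"`, `"RF"`.
#' @param k bin size (default 5).
#' @param n_folds folds per iteration (default 3).
#' @param n_iter iterations (default 100).
#' @param seed integer seed.
#' @param ... passed to the ranking scheme (`n_bins`, `n_trees`).
#' @return object of class `nm_feature_bin`: `method`, `features` (ordered,
#'   length `k`), `stability_scores` (selection frequency of each chosen
#'   feature, in `[0, 1]`), and attribute `all_frequencies`.
#' @export
stability_select <- function(features, labels, method = c("WRST", "MRMR", "RF"),
                             k = 5L, n_folds = 3L, n_iter = 100L, seed = 1L,
                             ...) {
  method <- match.arg(method)
  f <- as_binary_labels(labels)
  if (nrow(features) < 2 * n_folds)
    stop("need at least ", 2 * n_folds, " spots")
  nm <- colnames(features)
  counts <- stats::setNames(numeric(length(nm)), nm)
  extra <- list(...)
  with_local_seed(seed, {
    for (it in seq_len(n_iter)) {
      fold <- stratified_folds(f, n_folds)
      for (fd in seq_len(n_folds)) {
        tr <- fold != fd
        top <- switch(method,
          WRST = rank_wrst(features[tr, , drop = FALSE], f[tr])$feature[1:k],
          MRMR = do.call(rank_mrmr,
                         c(list(features[tr, , drop = FALSE], f[tr], k = k),
                           extra))$feature,
          RF = do.call(rank_rf_importance,
                       c(list(features[tr, , drop = FALSE], f[tr],
                              seed = sample.int(2^30, 1)),
                         extra))$feature[1:k])
        counts[top] <- counts[top] + 1
      }
    }
  })
  freq <- counts / (n_folds * n_iter)
  ord <- order(-freq, nm)
  chosen <- nm[ord][1:k]
  structure(list(method = method, features = chosen,
                 stability_scores = unname(freq[chosen])),
            class = "nm_feature_bin",
            all_frequencies = freq)
}
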
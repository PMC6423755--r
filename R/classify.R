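#' Area under the ROC curve by rank statistics
#'
#' Midrank-based Mann-Whitney formulation: equals the brute-force count of
#' concordant score pairs between classes with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels two-class vector; second factor level is positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  f <- as_binary_labels(labels)
  pos <- f == levels(f)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes needed for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(prob, truth, threshold = 0.5) {
  call <- prob > threshold
  pos <- truth == levels(truth)[2]
  c(accuracy = mean(call == pos),
    specificity = if (sum(!pos)) mean(!call[!pos]) else NA_real_,
    sensitivity = if (sum(pos)) mean(call[pos]) else NA_real_)
}

learner_codes <- function() c("ALD", "AQD", "MSV", "RF")
bin_methods <- function() c("WRST", "MRMR", "RF")

# Gaussian discriminants with ridge-regularized covariances; used when the
# plain fits hit a singular (or within-group constant) covariance. `pooled`
# gives the linear variant.
reg_qda_fit <- function(x, f, lambda = 1e-4, pooled = FALSE) {
  out <- list(levels = levels(f))
  Sp <- stats::cov(x)
  Sp <- Sp + diag(lambda * mean(diag(Sp)) + 1e-8, ncol(x))
  for (lv in levels(f)) {
    xi <- x[f == lv, , drop = FALSE]
    S <- if (pooled) Sp else {
      Si <- stats::cov(xi)
      Si + diag(lambda * mean(diag(Si)) + 1e-8, ncol(x))
    }
    out[[lv]] <- list(mu = colMeans(xi), Sinv = solve(S),
                      logdet = determinant(S)$modulus,
                      logprior = log(nrow(xi) / nrow(x)))
  }
  class(out) <- "nm_reg_qda"
  out
}

reg_qda_prob <- function(fit, x) {
  ll <- vapply(fit$levels, function(lv) {
    p <- fit[[lv]]
    d <- sweep(x, 2, p$mu)
    -0.5 * rowSums((d %*% p$Sinv) * d) - 0.5 * as.numeric(p$logdet) +
      p$logprior
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) ll <- matrix(ll, 1)
  ll <- ll - apply(ll, 1, max)
  e <- exp(ll)
  e[, 2] / rowSums(e)
}

#' Train one learner on a selected feature subset
#'
#' Learners: `ALD` (linear discriminant), `AQD` (quadratic discriminant),
#' `MSV` (linear-kernel support vector machine with cost 1 and sigmoid
#' probability calibration), `RF` (random forest). Features are z-scored
#' with training-cohort statistics for the discriminants and the SVM; the
#' forest sees raw values. A singular within-class covariance falls back
#' to a ridge-regularized discriminant with a message.
#'
#' @param features spots x features matrix (training cohort).
#' @param labels two-class vector; second factor level is called positive.
#' @param feature_subset character vector of columns to use (e.g. a
#'   feature bin's 5 names).
#' @param learner one of `"ALD"`, `"AQD"`, `"MSV"`, `"RF"`.
#' @param seed integer seed (SVM probability calibration and the forest
#'   are randomized).
#' @param n_trees forest size for `RF`.
#' @param cost SVM inverse-regularization constant.
#' @return object of class `nm_classifier`.
#' @export
train_model <- function(features, labels, feature_subset,
                        learner = c("ALD", "AQD", "MSV", "RF"),
                        seed = 1L, n_trees = 500L, cost = 1) {
  learner <- match.arg(learner)
  miss <- setdiff(feature_subset, colnames(features))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  f <- as_binary_labels(labels)
  x <- as.matrix(features[, feature_subset, drop = FALSE])
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- scale(x, ctr, scl)
  fit <- with_local_seed(seed, switch(learner,
    ALD = tryCatch(MASS::lda(z, grouping = f), error = function(e) {
      message("degenerate within-class covariance; ",
              "using ridge-regularized linear discriminant")
      reg_qda_fit(z, f, pooled = TRUE)
    }),
    AQD = tryCatch(MASS::qda(z, grouping = f), error = function(e) {
      message("singular within-class covariance; ",
              "using ridge-regularized discriminant")
      reg_qda_fit(z, f)
    }),
    MSV = e1071::svm(z, f, kernel = "linear", cost = cost,
                     probability = TRUE, scale = FALSE),
    RF = randomForest::randomForest(x = as.data.frame(x), y = f,
                                    ntree = n_trees)))
  structure(list(learner = learner, features = feature_subset,
                 center = ctr, scale = scl, fit = fit,
                 positive = levels(f)[2], levels = levels(f)),
            class = "nm_classifier")
}

classifier_prob <- function(model, features) {
  x <- as.matrix(features[, model$features, drop = FALSE])
  storage.mode(x) <- "double"
  z <- scale(x, model$center, model$scale)
  pos <- model$positive
  switch(model$learner,
    ALD = if (inherits(model$fit, "nm_reg_qda")) reg_qda_prob(model$fit, z)
          else stats::predict(model$fit, z)$posterior[, pos],
    AQD = if (inherits(model$fit, "nm_reg_qda")) reg_qda_prob(model$fit, z)
          else stats::predict(model$fit, z)$posterior[, pos],
    MSV = {
      pr <- stats::predict(model$fit, z, probability = TRUE)
      attr(pr, "probabilities")[, pos]
    },
    RF = stats::predict(model$fit, as.data.frame(x), type = "prob")[, pos])
}

#' Call recurrence from calibrated probabilities
#'
#' A spot is called positive iff its predicted probability strictly
#' exceeds the threshold (probability 0.50 is a negative call at the
#' default 0.5).
#'
#' @param model an `nm_classifier` from [train_model()].
#' @param features spots x features matrix/data.frame containing the
#'   model's feature columns (missing columns are a hard error).
#' @param threshold recurrence probability threshold (default 0.5).
#' @param spot_ids optional identifiers (defaults to rownames).
#' @return data.frame `spot_id`, `probability`, `label` (0/1); empty input
#'   gives an empty frame.
#' @export
predict_recurrence <- function(model, features, threshold = 0.5,
                               spot_ids = NULL) {
  stopifnot(inherits(model, "nm_classifier"),
            threshold >= 0, threshold <= 1)
  if (is.null(dim(features)) || nrow(features) == 0)
    return(data.frame(spot_id = character(0), probability = numeric(0),
                      label = integer(0)))
  miss <- setdiff(model$features, colnames(features))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  prob <- classifier_prob(model, features)
  ids <- spot_ids %||% rownames(features) %||% as.character(seq_along(prob))
  data.frame(spot_id = ids, probability = unname(prob),
             label = as.integer(prob > threshold),
             stringsAsFactors = FALSE)
}

cross_validate_combo <- function(features, labels, feature_subset, learner,
                                 n_folds = 3L, n_rep = 10L, seed = 1L,
                                 threshold = 0.5, ...) {
  f <- as_binary_labels(labels)
  mets <- matrix(NA_real_, n_folds * n_rep, 4,
                 dimnames = list(NULL, c("auc", "accuracy", "specificity",
                                         "sensitivity")))
  with_local_seed(seed, {
    row <- 0L
    for (rep in seq_len(n_rep)) {
      fold <- stratified_folds(f, n_folds)
      for (fd in seq_len(n_folds)) {
        tr <- fold != fd
        m <- train_model(features[tr, , drop = FALSE], f[tr], feature_subset,
                         learner, seed = sample.int(2^30, 1), ...)
        prob <- classifier_prob(m, features[!tr, , drop = FALSE])
        row <- row + 1L
        mets[row, ] <- c(auc_score(prob, f[!tr]),
                         confusion_metrics(prob, f[!tr], threshold))
      }
    }
  })
  mets
}

#' Cross-validated evaluation of the 4-learner x 3-bin grid
#'
#' For each learner (linear discriminant, quadratic discriminant, linear
#' SVM, random forest) and each feature bin, repeated stratified
#' cross-validation on the training cohort yields AUC, accuracy,
#' specificity and sensitivity as mean +/- SD over folds: exactly 12
#' combination rows.
#'
#' @param features training-cohort spots x 189 matrix.
#' @param labels two-class vector.
#' @param bins list of 3 `nm_feature_bin` objects (one per selection
#'   scheme), computed on the same training cohort.
#' @param seed integer seed.
#' @param n_folds,n_rep cross-validation design (default 3 x 10).
#' @param threshold probability threshold for the confusion metrics.
#' @return data.frame of class `nm_combo_grid` with 12 rows: `learner`,
#'   `bin_method`, and `<metric>_mean` / `<metric>_sd` for auc, accuracy,
#'   specificity, sensitivity.
#' @export
train_eval_grid <- function(features, labels, bins, seed = 1L,
                            n_folds = 3L, n_rep = 10L, threshold = 0.5) {
  stopifnot(length(bins) == 3)
  methods <- vapply(bins, function(b) b$method, character(1))
  if (!setequal(methods, bin_methods()))
    stop("bins must cover the three selection schemes WRST, MRMR, RF")
  rows <- list()
  with_local_seed(seed, {
    for (ln in learner_codes()) for (b in bins) {
      mets <- cross_validate_combo(features, labels, b$features, ln,
                                   n_folds, n_rep,
                                   seed = sample.int(2^30, 1),
                                   threshold = threshold)
      mm <- colMeans(mets, na.rm = TRUE)
      ss <- apply(mets, 2, stats::sd, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        learner = ln, bin_method = b$method,
        auc_mean = mm["auc"], auc_sd = ss["auc"],
        accuracy_mean = mm["accuracy"], accuracy_sd = ss["accuracy"],
        specificity_mean = mm["specificity"],
        specificity_sd = ss["specificity"],
        sensitivity_mean = mm["sensitivity"],
        sensitivity_sd = ss["sensitivity"],
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nm_combo_grid", class(out))
  out
}

#' Pick the best learner x bin combination
#'
#' Arg-max by mean AUC; ties broken by accuracy, then specificity, then
#' sensitivity, then the fixed learner order ALD, AQD, MSV, RF and bin
#' order WRST, MRMR, RF.
#'
#' @param results the 12-row grid from [train_eval_grid()].
#' @return the chosen row (one-row data.frame).
#' @export
pick_best_combo <- function(results) {
  if (!is.data.frame(results) || nrow(results) != 12)
    stop("expected 12 results, got ",
         if (is.data.frame(results)) nrow(results) else length(results))
  lo <- match(results$learner, learner_codes())
  bo <- match(results$bin_method, bin_methods())
  ord <- order(-results$auc_mean, -results$accuracy_mean,
               -results$specificity_mean, -results$sensitivity_mean,
               lo, bo)
  results[ord[1], , drop = FALSE]
}
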
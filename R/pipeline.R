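#' Default end-to-end run configuration
#'
#' Parameters of every pipeline stage with their documented defaults; any
#' entry can be overridden via `overrides` or a YAML file
#' ([read_run_config()]). The cohort split mirrors the 60-patient training
#' / 100-patient test design; the `demo` preset shrinks the canvas, nucleus
#' count and resampling depth to desk-scale runtimes.
#'
#' @param overrides named list of settings to replace (nested lists merge).
#' @param demo logical; use the small demonstration sizes.
#' @return nested list of class `nm_run_config`.
#' @export
default_run_config <- function(overrides = list(), demo = FALSE) {
  cfg <- list(
    seed = 1L,
    out_dir = "nucmorph_run",
    cohort = list(n_patients = 160L, n_train = 60L,
                  recurrence_fraction = 0.225, hazard_ratio = 17.24,
                  baseline_hazard = 0.002, censor_rate = 0.10,
                  follow_up_cap = 60, effect_size = 1.5),
    spot = list(width = 1024L, height = 1024L, n_nuclei = 150L,
                stain_noise_sd = 0.03),
    segment = list(min_area_px = 30, max_area_px = 5000),
    features = list(b_bins = 18L, k_neighbors = 5L),
    select = list(k = 5L, n_folds = 3L, n_iter = 100L,
                  rf_trees = 200L, mrmr_bins = 4L),
    train = list(n_folds = 3L, n_rep = 10L, threshold = 0.5),
    survival = list(covariates = c("t_stage", "histology", "invasion")))
  if (demo)
    cfg <- modify_list(cfg, list(
      cohort = list(n_patients = 16L, n_train = 8L,
                    recurrence_fraction = 0.4),
      spot = list(width = 256L, height = 256L, n_nuclei = 40L),
      select = list(n_iter = 5L, rf_trees = 100L),
      train = list(n_rep = 3L)))
  cfg <- modify_list(cfg, overrides)
  class(cfg) <- "nm_run_config"
  validate_run_config(cfg)
  cfg
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  with(cfg, {
    stopifnot(is.numeric(seed))
    if (train$threshold < 0 || train$threshold > 1)
      stop("config error: train$threshold must lie in [0, 1], got ",
           train$threshold)
    if (cohort$n_train >= cohort$n_patients)
      stop("config error: n_train must be smaller than n_patients")
    if (cohort$hazard_ratio <= 0)
      stop("config error: hazard_ratio must be positive")
    if (select$k < 1 || select$n_folds < 2 || select$n_iter < 1)
      stop("config error: invalid selection parameters")
    if (spot$width < 64 || spot$height < 64 || spot$n_nuclei < 5)
      stop("config error: invalid spot parameters")
    if (segment$min_area_px >= segment$max_area_px)
      stop("config error: min_area_px must be below max_area_px")
  })
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return the configuration (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  default_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg an `nm_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

segment_and_featurize <- function(sp, cfg, spot_id) {
  sim <- generate_spot_image(sp)
  dec <- color_deconvolve(sim$image)
  mask <- segment_nuclei(dec$hematoxylin,
                         min_area_px = cfg$segment$min_area_px,
                         max_area_px = cfg$segment$max_area_px)
  compute_spot_features(mask, sim$image, spot_id = spot_id,
                        b_bins = cfg$features$b_bins,
                        k_neighbors = cfg$features$k_neighbors)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> render -> segment -> feature extraction ->
#' stability selection (three schemes) -> 12-combination grid ->
#' best-combination choice -> test-cohort recurrence calls -> survival and
#' immunohistochemistry statistics, writing every stage product plus a
#' manifest into `cfg$out_dir`. Identical configurations produce identical
#' outputs.
#'
#' @param cfg an `nm_run_config` from [default_run_config()] /
#'   [read_run_config()].
#' @param image_level logical: derive spot features from rendered images
#'   through segmentation (the full pipeline) or from the cohort
#'   generator's feature matrix (fast, for large cohorts).
#' @return invisible list with `cohort`, `features`, `bins`, `grid`,
#'   `best`, `model`, `calls`, `survival`, `ihc`, `manifest`.
#' @export
run_pipeline <- function(cfg, image_level = TRUE) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cp <- cohort_sim_params(
    n_patients = cfg$cohort$n_patients,
    recurrence_fraction = cfg$cohort$recurrence_fraction,
    hazard_ratio = cfg$cohort$hazard_ratio,
    baseline_hazard = cfg$cohort$baseline_hazard,
    censor_rate = cfg$cohort$censor_rate,
    follow_up_cap = cfg$cohort$follow_up_cap,
    effect_size = cfg$cohort$effect_size,
    seed = cfg$seed)
  sim <- stage("simulate", generate_cohort(cp))
  utils::write.csv(sim$cohort, file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE)

  if (image_level) {
    feats <- stage("segment/features", {
      rows <- lapply(seq_len(nrow(sim$cohort)), function(i) {
        sp <- modify_spot_params(sim$spot_params[[i]], cfg$spot)
        segment_and_featurize(sp, cfg, sim$cohort$id[i])
      })
      m <- do.call(rbind, rows)
      rownames(m) <- sim$cohort$id
      m
    })
  } else feats <- sim$features
  write_feature_csv(feats, file.path(cfg$out_dir, "features.csv"))

  sp <- split_cohort(structure(list(cohort = sim$cohort,
                                    spot_params = sim$spot_params,
                                    features = feats),
                               class = "nm_cohort_sim"),
                     n_train = cfg$cohort$n_train, seed = cfg$seed)
  ytr <- factor(sp$train$cohort$recurrence, levels = 0:1)
  if (nlevels(droplevels(ytr)) < 2)
    stop("pipeline stage 'select' failed: training cohort has one class")

  bins <- stage("select", list(
    stability_select(sp$train$features, ytr, "WRST", k = cfg$select$k,
                     n_folds = cfg$select$n_folds,
                     n_iter = cfg$select$n_iter, seed = cfg$seed),
    stability_select(sp$train$features, ytr, "MRMR", k = cfg$select$k,
                     n_folds = cfg$select$n_folds,
                     n_iter = cfg$select$n_iter, seed = cfg$seed,
                     n_bins = cfg$select$mrmr_bins),
    stability_select(sp$train$features, ytr, "RF", k = cfg$select$k,
                     n_folds = cfg$select$n_folds,
                     n_iter = cfg$select$n_iter, seed = cfg$seed,
                     n_trees = cfg$select$rf_trees)))
  bin_df <- do.call(rbind, lapply(bins, function(b)
    data.frame(method = b$method, rank = seq_along(b$features),
               feature = b$features, stability = b$stability_scores)))
  utils::write.csv(bin_df, file.path(cfg$out_dir, "feature_bins.csv"),
                   row.names = FALSE)

  grid <- stage("train", train_eval_grid(
    sp$train$features, ytr, bins, seed = cfg$seed,
    n_folds = cfg$train$n_folds, n_rep = cfg$train$n_rep,
    threshold = cfg$train$threshold))
  utils::write.csv(grid, file.path(cfg$out_dir, "grid.csv"),
                   row.names = FALSE)
  best <- pick_best_combo(grid)

  model <- stage("train", train_model(
    sp$train$features, ytr,
    bins[[match(best$bin_method,
                vapply(bins, `[[`, "", "method"))]]$features,
    learner = best$learner, seed = cfg$seed))
  calls <- stage("evaluate", predict_recurrence(
    model, sp$test$features, threshold = cfg$train$threshold))
  utils::write.csv(calls, file.path(cfg$out_dir, "calls.csv"),
                   row.names = FALSE)

  test_cohort <- sp$test$cohort
  test_cohort$call <- calls$label[match(test_cohort$id, calls$spot_id)]
  surv <- stage("survival", {
    km_by_call <- lapply(split(test_cohort, test_cohort$call),
                         function(d) km_curve(d$time, d$event))
    lr <- if (length(unique(test_cohort$call)) >= 2 &&
              sum(test_cohort$event) >= 1)
      logrank_test(test_cohort$time, test_cohort$event, test_cohort$call)
    else NULL
    uni <- tryCatch(cox_fit(test_cohort, "call"), error = function(e) NULL)
    multi <- tryCatch(
      cox_fit(test_cohort, c("call", cfg$survival$covariates)),
      error = function(e) NULL)
    list(km = km_by_call, logrank = lr, cox_univariate = uni,
         cox_multivariate = multi)
  })
  if (!is.null(surv$cox_multivariate))
    utils::write.csv(surv$cox_multivariate,
                     file.path(cfg$out_dir, "cox_multivariate.csv"),
                     row.names = FALSE)

  ihc <- stage("survival", {
    tab <- generate_ihc_table(test_cohort, group = test_cohort$call,
                              seed = cfg$seed)
    list(table = tab,
         her2 = tryCatch(association_test(tab$call, tab$her2, "fisher"),
                         error = function(e) NULL),
         ki67 = tryCatch(association_test(tab$call, tab$ki67, "chisq"),
                         error = function(e) NULL))
  })

  manifest <- list(package_version = as.character(utils::packageVersion("nucmorph")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   config_hash = fnv1a_hash(
                     jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)),
                   best_combo = list(learner = best$learner,
                                     bin_method = best$bin_method,
                                     auc_mean = best$auc_mean))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = sim$cohort, features = feats, bins = bins,
                 grid = grid, best = best, model = model, calls = calls,
                 survival = surv, ihc = ihc, manifest = manifest))
}

modify_spot_params <- function(sp, spot_cfg) {
  spot_sim_params(n_nuclei = spot_cfg$n_nuclei %||% sp$n_nuclei,
                  mean_area = sp$mean_area, area_cv = sp$area_cv,
                  eccentricity_range = sp$eccentricity_range,
                  orientation_kappa = sp$orientation_kappa,
                  orientation_mu = sp$orientation_mu,
                  clustering = sp$clustering,
                  stain_noise_sd = spot_cfg$stain_noise_sd %||% sp$stain_noise_sd,
                  width = spot_cfg$width %||% sp$width,
                  height = spot_cfg$height %||% sp$height,
                  microns_per_pixel = sp$microns_per_pixel,
                  seed = sp$seed)
}

#' Agreement between recurrence calls on two matched cohorts
#'
#' Compares per-patient calls made on two spot sets from the same patients
#' (intra-tumor heterogeneity check): the fraction of agreeing calls and
#' the log-rank test of the second cohort's survival split by its calls.
#'
#' @param calls_a,calls_b data.frames from [predict_recurrence()] with
#'   matching `spot_id`s.
#' @param cohort_b data.frame with `id`, `time`, `event` for the second
#'   cohort (optional; log-rank skipped when absent).
#' @return list `agreement`, `n`, `logrank` (NULL without `cohort_b` or
#'   with a single call group).
#' @export
heterogeneity_check <- function(calls_a, calls_b, cohort_b = NULL) {
  missing_b <- setdiff(calls_a$spot_id, calls_b$spot_id)
  missing_a <- setdiff(calls_b$spot_id, calls_a$spot_id)
  if (length(missing_b) || length(missing_a))
    stop("unmatched patient ids: ",
         paste(c(missing_b, missing_a), collapse = ", "))
  b <- calls_b$label[match(calls_a$spot_id, calls_b$spot_id)]
  agreement <- mean(calls_a$label == b)
  lr <- NULL
  if (!is.null(cohort_b)) {
    idx <- match(calls_b$spot_id, cohort_b$id)
    if (anyNA(idx))
      stop("unmatched patient ids in cohort_b: ",
           paste(calls_b$spot_id[is.na(idx)], collapse = ", "))
    if (length(unique(calls_b$label)) >= 2 &&
        sum(cohort_b$event[idx]) >= 1)
      lr <- logrank_test(cohort_b$time[idx], cohort_b$event[idx],
                         calls_b$label)
  }
  list(agreement = agreement, n = length(b), logrank = lr)
}
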
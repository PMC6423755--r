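#' Kaplan-Meier product-limit survival estimate
#'
#' Right-censored product-limit estimate; the returned step function
#' starts at probability 1 and is non-increasing. With no censoring it
#' equals the empirical survival function.
#'
#' @param times follow-up times (> 0 recommended; negative times rejected).
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` at the distinct
#'   event/censoring times.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(events %in% 0:1))
  if (any(times < 0)) stop("negative times are not allowed")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected statistic on the pooled event times
#' (1 degree of freedom for 2 groups).
#'
#' @param times,events as in [km_curve()].
#' @param groups group membership (>= 2 groups).
#' @return list `chisq`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups for the log-rank test")
  if (sum(events) < 1) stop("need at least 1 event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Cox proportional-hazards fit with Wald summaries
#'
#' Partial-likelihood maximization with the Efron tie correction; one
#' summary row per covariate term with hazard ratio, Wald 95% CI and
#' p-value. Supports the univariate (single covariate) and multivariate
#' covariate sets. Non-convergence or a monotone likelihood (infinite
#' coefficient) is an error with a diagnostic.
#'
#' @param cohort data.frame with time/event columns and the covariates.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col endpoint columns (default `time`, `event`).
#' @return data.frame `variable`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`; attribute `fit` carries the `coxph` object.
#' @export
cox_fit <- function(cohort, covariates, time_col = "time",
                    event_col = "event") {
  stopifnot(all(c(time_col, event_col, covariates) %in% names(cohort)))
  n_events <- sum(cohort[[event_col]])
  if (n_events < length(covariates))
    stop("fewer events (", n_events, ") than covariates (",
         length(covariates), ")")
  fm <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fm, data = cohort, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 15))
    stop("Cox fit failed: monotone likelihood (coefficient diverging; ",
         "a group may have no events)")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(variable = rownames(co),
             hazard_ratio = unname(co[, "exp(coef)"]),
             ci_low = unname(ci[, "lower .95"]),
             ci_high = unname(ci[, "upper .95"]),
             p_value = unname(co[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE) -> out
  attr(out, "fit") <- fit
  out
}

#' Association between classifier calls and a binary marker
#'
#' 2x2 association by the two-sided Fisher exact test (point-probability
#' rule, i.e. hypergeometric tail summation of tables no more probable
#' than the observed one) or the 1-df Pearson chi-square test.
#'
#' @param calls binary classifier calls (0/1).
#' @param marker binary marker status (0/1).
#' @param method `"fisher"` or `"chisq"`.
#' @param correct continuity correction for the chi-square variant.
#' @return list `odds_ratio` (sample OR from the 2x2 table), `p_value`,
#'   `table`, `method`.
#' @export
association_test <- function(calls, marker, method = c("fisher", "chisq"),
                             correct = FALSE) {
  method <- match.arg(method)
  tab <- table(factor(calls, levels = 0:1), factor(marker, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in the 2x2 table")
  p <- if (method == "fisher") stats::fisher.test(tab)$p.value
       else stats::chisq.test(tab, correct = correct)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = unname(or), p_value = p, table = tab, method = method)
}
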
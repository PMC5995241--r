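#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator with the usual convention that censorings at an
#' event time remain in the at-risk set for the events at that time. Backed by
#' [survival::survfit()][survival::survfit].
#'
#' @param times follow-up times in months, >= 0.
#' @param events logical event indicators (death / disease-specific death).
#' @param label optional group label.
#' @return a `survival_curve` data frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events, label = NA_character_) {
  if (!length(times)) stopf("empty survival input")
  if (any(times < 0)) stopf("negative survival time")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  structure(out, class = c("survival_curve", "data.frame"), label = label,
            n = length(times), events = sum(events))
}

#' Survival probability at a time point
#'
#' Step-function lookup of a Kaplan-Meier curve, e.g. `survival_at(curve, 96)`
#' for the 8-year survival.
#'
#' @param curve a `survival_curve` from [km_estimate()].
#' @param t time in months.
#' @return survival probability S(t).
#' @export
survival_at <- function(curve, t) {
  idx <- which(curve$time <= t)
  if (!length(idx)) return(1)
  curve$surv[max(idx)]
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic with df = groups - 1,
#' p from the chi-square upper tail. Backed by
#' [survival::survdiff()][survival::survdiff].
#'
#' @param groups named list; each element a list/data frame with `times` and
#'   `events`.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  ns <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(ns == 0)) stopf("group(s) with n = 0: %s",
                          paste(names(groups)[ns == 0], collapse = ", "))
  times <- unlist(lapply(groups, `[[`, "times"))
  events <- as.integer(unlist(lapply(groups, `[[`, "events")))
  if (sum(events) < 1) stopf("no events in any group")
  g <- factor(rep(seq_along(groups), ns))
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(groups) - 1
  list(statistic = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Encode clinical covariates for Cox regression
#'
#' Applies the standard dichotomizations: `stage_t34` (pT3-pT4 vs pT2 and
#' below), `node_pos` (N+ vs N0), `metastasis` (cM+ vs cM0), `nac`, `ac`,
#' `sex_m`, continuous `age`, and — when a subtype assignment is supplied —
#' `luminal` (luminal vs non-luminal).
#'
#' @param clinical a `clinical_table`.
#' @param assignment optional `subtype_assignment` aligned by sample id.
#' @return data frame with `sample_id`, encoded covariates and the four
#'   endpoint columns.
#' @export
encode_covariates <- function(clinical, assignment = NULL) {
  d <- data.frame(sample_id = clinical$sample_id,
                  age = clinical$age,
                  sex_m = as.integer(clinical$sex == "M"),
                  stage_t34 = as.integer(clinical$stage %in% c("pT3", "pT4")),
                  node_pos = as.integer(clinical$node == "N+"),
                  metastasis = as.integer(clinical$metastasis == "M+"),
                  nac = as.integer(clinical$nac),
                  ac = as.integer(clinical$ac),
                  os_time = clinical$os_time, os_event = clinical$os_event,
                  dss_time = clinical$dss_time, dss_event = clinical$dss_event,
                  stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    lum <- stratify_luminal(assignment)
    d$luminal <- unname(lum[d$sample_id])
  }
  d
}

# 1-df score test for adding covariate z to a fitted Cox model: the global
# score statistic evaluated at (beta_hat, 0) reduces to the score test of the
# added term because the score of the restricted MLE vanishes.
cox_score_p <- function(data, time, event, selected, candidate, ties) {
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                paste(c(selected, candidate), collapse = " + ")))
  init <- rep(0, length(selected) + 1)
  if (length(selected)) {
    fit0 <- survival::coxph(stats::as.formula(
      paste0("survival::Surv(", time, ", ", event, ") ~ ",
             paste(selected, collapse = " + "))), data = data, ties = ties)
    init[seq_along(selected)] <- stats::coef(fit0)
  }
  fit <- survival::coxph(f, data = data, ties = ties, init = init,
                         control = survival::coxph.control(iter.max = 0))
  stats::pchisq(fit$score, df = 1, lower.tail = FALSE)
}

#' Cox proportional-hazards regression with optional forward selection
#'
#' Partial-likelihood maximization (Efron tie handling by default) via
#' [survival::coxph()][survival::coxph]. With `selection = "forward"`,
#' covariates enter one at a time: at each step the candidate with the
#' smallest 1-df score-test p-value enters while that p < `entry_p`;
#' selection stops otherwise. Wald confidence intervals are
#' exp(coef +/- 1.96 SE). Monotone likelihood (complete separation) is
#' detected and raised as an error advising penalization rather than silently
#' returning a diverged fit.
#'
#' @param data data frame from [encode_covariates()] (or any frame holding
#'   the covariates and endpoint columns).
#' @param covariates character vector of covariate column names.
#' @param endpoint `"os"` or `"dss"` (uses `<endpoint>_time` /
#'   `<endpoint>_event`).
#' @param selection `"none"` (fit all covariates) or `"forward"`.
#' @param ties `"efron"` or `"breslow"`.
#' @param entry_p forward-selection entry threshold on the score-test p.
#' @return a `cox_result`: `table` (term, coef, hr, ci_lo, ci_hi, se, p),
#'   `trace` (selection order and entry p), `ties`, `n`, `events`, `loglik`.
#' @export
cox_fit <- function(data, covariates, endpoint = c("os", "dss"),
                    selection = c("none", "forward"),
                    ties = c("efron", "breslow"), entry_p = 0.05) {
  endpoint <- match.arg(endpoint)
  selection <- match.arg(selection)
  ties <- match.arg(ties)
  time <- paste0(endpoint, "_time"); event <- paste0(endpoint, "_event")
  miss <- setdiff(c(covariates, time, event), names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[c(covariates, time, event)]),
            c(covariates, time, event), drop = FALSE]
  d[[event]] <- as.integer(d[[event]])
  if (sum(d[[event]]) == 0) stopf("zero events for endpoint '%s'", endpoint)
  const <- covariates[vapply(covariates, function(v) stats::var(d[[v]]) == 0,
                             logical(1))]
  if (length(const))
    stopf("constant covariate(s), non-identifiable: %s", paste(const, collapse = ", "))

  fit_ml <- function(terms) {
    f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                  paste(terms, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(f, data = d, ties = ties,
                      control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
          stopf("monotone likelihood / non-convergence for model {%s}: %s. Consider penalized (Firth) regression.",
                paste(terms, collapse = ", "), conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (any(abs(stats::coef(fit)) > 15) || any(sqrt(diag(fit$var)) > 100))
      stopf("monotone likelihood suspected (diverging coefficient) for model {%s}; consider penalized regression",
            paste(terms, collapse = ", "))
    fit
  }

  trace <- data.frame(term = character(0), step = integer(0), entry_p = numeric(0))
  if (selection == "forward") {
    selected <- character(0)
    repeat {
      cand <- setdiff(covariates, selected)
      if (!length(cand)) break
      ps <- vapply(cand, function(z)
        cox_score_p(d, time, event, selected, z, ties), numeric(1))
      if (min(ps) >= entry_p) break
      enter <- cand[which.min(ps)]
      selected <- c(selected, enter)
      trace <- rbind(trace, data.frame(term = enter, step = length(selected),
                                       entry_p = unname(min(ps))))
    }
    terms <- selected
  } else terms <- covariates

  if (!length(terms)) {
    tab <- data.frame(term = character(0), coef = numeric(0), hr = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0), se = numeric(0),
                      p = numeric(0))
    return(structure(list(table = tab, trace = trace, ties = ties,
                          n = nrow(d), events = sum(d[[event]]),
                          loglik = NA_real_),
                     class = "cox_result"))
  }
  fit <- fit_ml(terms)
  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  tab <- data.frame(term = names(co), coef = unname(co), hr = exp(unname(co)),
                    ci_lo = exp(unname(co) - 1.96 * se),
                    ci_hi = exp(unname(co) + 1.96 * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(co) / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, trace = trace, ties = ties, n = nrow(d),
                 events = sum(d[[event]]), loglik = fit$loglik[2]),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("cox_result (%s ties): n = %d, events = %d\n", x$ties, x$n, x$events))
  if (nrow(x$table)) print(format(x$table, digits = 3), row.names = FALSE)
  else cat("  (no covariate entered the model)\n")
  invisible(x)
}
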
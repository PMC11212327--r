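# Outcome analysis: Kaplan-Meier estimation, the log-rank test and Cox
# proportional-hazards models (Efron tie handling), built on the survival
# package.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with censoring marks retained, overall or per
#' group.
#'
#' @param records data.frame with `time` (> 0), `event` (0/1) and
#'   optionally `group`.
#' @param by_group stratify by `records$group`.
#' @return list with `curve` (data.frame: group, time, n_risk, n_event,
#'   n_censor, surv) and `median` (median survival per group, NA if never
#'   reached).
#' @export
km_estimate <- function(records, by_group = !is.null(records$group)) {
  stopifnot(all(records$time > 0), all(records$event %in% c(0, 1)))
  fit <- if (by_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  }
  strata <- if (is.null(fit$strata)) {
    rep("all", length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curve <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv, row.names = NULL,
                      stringsAsFactors = FALSE)
  med <- summary(fit)$table
  median_surv <- if (is.null(dim(med))) {
    stats::setNames(med[["median"]], "all")
  } else {
    stats::setNames(med[, "median"], sub("^group=", "", rownames(med)))
  }
  list(curve = curve, median = median_surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected log-rank chi-squared with hypergeometric
#' variance at each distinct event time; p from a chi-squared(1) reference.
#'
#' @param records data.frame with `time`, `event`.
#' @param group two-level vector per record (defaults to
#'   `records$group`).
#' @return list with `chi_squared`, `p_value`, per-group observed/expected.
#' @export
logrank_test <- function(records, group = records$group) {
  g <- factor(group)
  if (nlevels(g) != 2) {
    stop("logrank_test: exactly two groups required", call. = FALSE)
  }
  if (any(table(g) == 0)) {
    stop("logrank_test: a group is empty", call. = FALSE)
  }
  if (sum(records$event) < 1) {
    stop("logrank_test: at least one event required", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(records$time, records$event) ~ g)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(chi_squared = unname(sd$chisq), p_value = p,
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. Per covariate:
#' hazard ratio, 95% Wald confidence interval (normal approximation on the
#' log scale) and Wald p. Monotone-likelihood (separation) cases are
#' reported through the `converged` flag and a diagnostic message rather
#' than an error.
#'
#' @param records data.frame with `time`, `event` and the covariate
#'   columns.
#' @param formula_covariates character vector of covariate names.
#' @return list with `table` (data.frame: term, coef, hr, lower, upper,
#'   se, p), `converged`, `diagnostic` and the underlying `fit`.
#' @export
cox_fit <- function(records, formula_covariates) {
  if (sum(records$event) < 1) {
    stop("cox_fit: at least one event required", call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(formula_covariates, collapse = " + ")))
  diagnostic <- NA_character_
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      diagnostic <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  coefs <- s$coefficients
  tab <- data.frame(term = rownames(coefs),
                    coef = coefs[, "coef"],
                    hr = exp(coefs[, "coef"]),
                    lower = exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"]),
                    upper = exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"]),
                    se = coefs[, "se(coef)"],
                    p = coefs[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  converged <- is.na(diagnostic) && all(is.finite(coefs[, "coef"])) &&
    all(abs(coefs[, "coef"]) < 15)
  if (!converged && is.na(diagnostic)) {
    diagnostic <- "extreme coefficient: likelihood may be monotone"
  }
  list(table = tab, converged = converged, diagnostic = diagnostic,
       fit = fit)
}

#' Subtype-survival association
#'
#' Log-rank test plus univariate and covariate-adjusted Cox models of a
#' survival endpoint against the IM-H/IM-L subtype (IM-H is the reference,
#' so the hazard ratio is the immune-low excess hazard).
#'
#' @param clinical data.frame with `tumor_id` and the endpoint columns.
#' @param subtype_labels named ("tumor id") character vector of
#'   "IM-H"/"IM-L".
#' @param time_col,event_col endpoint column names.
#' @param covariates additional adjustment covariates present in
#'   `clinical` (default stage, gender, smoking).
#' @return list with `logrank`, `cox_univariate`, `cox_adjusted` and the
#'   analysis data.frame.
#' @export
subtype_survival <- function(clinical, subtype_labels,
                             time_col = "rfs_time", event_col = "rfs_event",
                             covariates = c("stage", "gender", "smoking")) {
  common <- intersect(clinical$tumor_id, names(subtype_labels))
  d <- clinical[match(common, clinical$tumor_id), , drop = FALSE]
  df <- data.frame(time = d[[time_col]], event = d[[event_col]],
                   group = unname(subtype_labels[common]),
                   subtype_iml = as.integer(subtype_labels[common] == "IM-L"),
                   stringsAsFactors = FALSE)
  for (cv in covariates) {
    if (cv %in% names(d)) {
      v <- d[[cv]]
      df[[cv]] <- if (is.character(v)) as.integer(factor(v)) - 1L else v
    }
  }
  lr <- logrank_test(df)
  uni <- cox_fit(df, "subtype_iml")
  adj_terms <- c("subtype_iml", intersect(covariates, names(df)))
  adj <- tryCatch(cox_fit(df, adj_terms), error = function(e) NULL)
  list(logrank = lr, cox_univariate = uni, cox_adjusted = adj, data = df)
}
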
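# Model presets over the partial-likelihood engine. All Cox-family fits
# share one code path and differ only in risk interval, stratification,
# weights and the variance used for the reported confidence interval.

.new_fit <- function(model, coef_table, treatment_term, var_used,
                     n_events, strata_used, iterations, converged,
                     extra = list()) {
  est <- coef_table[treatment_term, "coef"]
  se <- coef_table[treatment_term,
                   if (var_used == "robust") "se_robust" else "se_naive"]
  structure(c(list(
    model = model,
    coef = est,
    se_naive = coef_table[treatment_term, "se_naive"],
    se_robust = coef_table[treatment_term, "se_robust"],
    var_used = var_used,
    hr = exp(est),
    ci95 = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
    coef_table = coef_table,
    n_events_used = n_events,
    strata_used = strata_used,
    iterations = iterations,
    converged = converged
  ), extra), class = "repwp_fit")
}

#' @export
print.repwp_fit <- function(x, ...) {
  lab <- switch(x$model,
    cox1 = "Cox model (time to first event)",
    ag = "Andersen-Gill model",
    lwyy = "LWYY marginal rate model",
    pwp_gt = "PWP model (gap time)",
    pwp_cp = "PWP model (counting process)",
    pwp_robust = "PWP model with robust variance",
    wpwp = "Weighted PWP model",
    poisson = "Poisson rate model",
    nb = "Negative binomial rate model",
    x$model)
  cat(lab, "\n")
  eff <- if (x$model %in% c("poisson", "nb")) "Rate ratio" else "Hazard ratio"
  cat(sprintf("  %s (treatment): %.4f  95%% CI (%.4f, %.4f)  [%s variance]\n",
              eff, x$hr, x$ci95[1], x$ci95[2], x$var_used))
  cat(sprintf("  log-effect %.4f (naive SE %.4f%s), %d events",
              x$coef, x$se_naive,
              if (is.na(x$se_robust)) "" else
                sprintf(", robust SE %.4f", x$se_robust),
              as.integer(round(x$n_events_used))))
  if (!is.null(x$strata_used)) {
    cat(", strata", paste(range(x$strata_used), collapse = "-"))
  }
  cat("\n")
  invisible(x)
}

# Shared Cox-family fit.
.fit_cox_family <- function(h, model, time_scale, stratify, variance,
                            adjust = NULL, weights = NULL,
                            first_event_only = FALSE, extra = list()) {
  if (first_event_only) h <- first_event_subset(h)
  h <- if (time_scale == "gap") as_gap_time(h) else as_counting_process(h)
  terms <- c("treatment", adjust)
  cluster <- if (variance == "robust") h$id else NULL
  fit <- .pl_fit(h, terms = terms, weights = weights, stratify = stratify,
                 cluster = cluster)
  se_n <- sqrt(diag(fit$var_naive))
  se_r <- if (is.null(fit$var_robust)) rep(NA_real_, length(se_n)) else
    sqrt(diag(fit$var_robust))
  ct <- cbind(coef = fit$coef, se_naive = se_n, se_robust = se_r)
  rownames(ct) <- terms
  .new_fit(model, ct, "treatment",
           var_used = if (variance == "robust") "robust" else "naive",
           n_events = fit$n_events,
           strata_used = if (stratify) sort(unique(h$k)) else NULL,
           iterations = fit$iterations, converged = fit$converged,
           extra = extra)
}

#' Standard recurrent-event models
#'
#' Presets for the usual analyses of a randomized trial with recurrent
#' events, all sharing one weighted stratified Cox engine (Breslow ties,
#' Newton-Raphson):
#'
#' * `fit_cox_first_event()`: Cox model for time to first event, naive
#'   (inverse-information) variance.
#' * `fit_ag()`: Andersen-Gill counting-process model (common baseline
#'   hazard for all events), naive variance.
#' * `fit_lwyy()`: Lin-Wei-Yang-Ying marginal rate model: the AG point
#'   estimate with a robust cluster (subject-level) sandwich variance.
#' * `fit_pwp_gt()` / `fit_pwp_cp()`: Prentice-Williams-Peterson model
#'   stratified by event number, gap-time or counting-process risk
#'   intervals, naive variance.
#' * `fit_pwp_robust()`: gap-time PWP with robust cluster variance.
#'
#' The reported 95% CI is Wald on the log scale using the variance the
#' model prescribes.
#'
#' @param h An `event_history`.
#' @param adjust Optional character vector of covariate columns entered
#'   into the linear predictor alongside treatment (covariate adjustment
#'   via outcome regression). The treatment coefficient is reported.
#' @return A `repwp_fit`: treatment log-hazard-ratio, naive/robust SEs,
#'   hazard ratio with 95% CI, events used and convergence information.
#' @examples
#' h <- bladder_recurrences()
#' fit_cox_first_event(h)  # HR ~ 0.70
#' fit_pwp_gt(h)           # HR ~ 0.89
#' @name presets
NULL

#' @rdname presets
#' @export
fit_cox_first_event <- function(h, adjust = NULL) {
  .fit_cox_family(h, "cox1", time_scale = "gap", stratify = FALSE,
                  variance = "naive", adjust = adjust,
                  first_event_only = TRUE)
}

#' @rdname presets
#' @export
fit_ag <- function(h, adjust = NULL) {
  .fit_cox_family(h, "ag", time_scale = "counting_process",
                  stratify = FALSE, variance = "naive", adjust = adjust)
}

#' @rdname presets
#' @export
fit_lwyy <- function(h, adjust = NULL) {
  .fit_cox_family(h, "lwyy", time_scale = "counting_process",
                  stratify = FALSE, variance = "robust", adjust = adjust)
}

#' @rdname presets
#' @export
fit_pwp_gt <- function(h, adjust = NULL) {
  .fit_cox_family(h, "pwp_gt", time_scale = "gap", stratify = TRUE,
                  variance = "naive", adjust = adjust)
}

#' @rdname presets
#' @export
fit_pwp_cp <- function(h, adjust = NULL) {
  .fit_cox_family(h, "pwp_cp", time_scale = "counting_process",
                  stratify = TRUE, variance = "naive", adjust = adjust)
}

#' @rdname presets
#' @export
fit_pwp_robust <- function(h, adjust = NULL) {
  .fit_cox_family(h, "pwp_robust", time_scale = "gap", stratify = TRUE,
                  variance = "robust", adjust = adjust)
}

#' Entropy-balance-weighted PWP model
#'
#' The package's headline model: a gap-time PWP fit in which each risk set
#' beyond the first is reweighted so that the chosen baseline covariates
#' are balanced between arms (entropy balancing by default, stabilized
#' IPW as an alternative), undoing the collider bias induced by
#' conditioning on prior events. The variance is a robust cluster
#' sandwich with the subject as the cluster; weights are treated as
#' fixed.
#'
#' Stratum truncation:
#' * `"smd"` (default): start from the eligibility prefix (both arms with
#'   at least two members, see [eligible_strata()]), solve the weights,
#'   and truncate at `k_max`, the first stratum whose weights fail to
#'   solve or leave some balanced covariate with |SMD| at or above
#'   `smd_threshold` (see [kmax_by_smd()]). Strata `1..k_max-1` are
#'   retained.
#' * `"eligibility"`: retain the whole eligibility prefix; an unsolvable
#'   stratum inside it is an error.
#' * `"none"`: no SMD truncation beyond the eligibility prefix
#'   (equivalent to `"eligibility"` for entropy weights; mainly useful
#'   with `weighting = "ipw"`, which needs no balance solution).
#'
#' @param h An `event_history`.
#' @param balance_covariates Covariates to balance; default all ("fully
#'   weighted"). A subset gives the "partly weighted" model.
#' @param weighting `"entropy"` (default), `"ipw"`, or `"unit"` (forces
#'   unit weights; then the fit coincides with [fit_pwp_robust()] on the
#'   retained strata).
#' @param truncation `"smd"` (default), `"eligibility"` or `"none"`.
#' @param smd_threshold SMD threshold for `truncation = "smd"`, default
#'   0.1.
#' @param adjust Optional additional outcome-regression covariates.
#' @param tol,max_iter Passed to [entropy_balance()].
#' @return A `repwp_fit` with extra fields `stratum_weights` (list of
#'   [entropy_balance()] results), `k_eligible`, `k_max` and `weighting`.
#' @examples
#' h <- bladder_recurrences()
#' fit_weighted_pwp(h)  # HR ~ 0.84, strata 1-5 retained
#' @export
fit_weighted_pwp <- function(h, balance_covariates = NULL,
                             weighting = c("entropy", "ipw", "unit"),
                             truncation = c("smd", "eligibility", "none"),
                             smd_threshold = 0.1, adjust = NULL,
                             tol = 1e-8, max_iter = 200) {
  weighting <- match.arg(weighting)
  truncation <- match.arg(truncation)
  h <- as_gap_time(h)
  K_elig <- eligible_strata(h)
  if (weighting == "unit") {
    rows <- h$k <= K_elig
    sub <- event_history(as.data.frame(h)[rows, , drop = FALSE],
                         time_scale = "gap",
                         covariates = covariate_names(h), validate = FALSE)
    return(.fit_cox_family(sub, "wpwp", time_scale = "gap", stratify = TRUE,
                           variance = "robust", adjust = adjust,
                           weights = rep(1, nrow(sub)),
                           extra = list(stratum_weights = NULL,
                                        k_eligible = K_elig,
                                        k_max = K_elig + 1L,
                                        weighting = "unit")))
  }
  balance_covariates <- .check_balance_covariates(h, balance_covariates)
  sw <- balance_all_strata(h, covariates = balance_covariates,
                           weighting = if (weighting == "ipw") "ipw"
                                       else "entropy",
                           tol = tol, max_iter = max_iter)
  k_max <- if (truncation == "smd") {
    kmax_by_smd(h, sw, covariates = balance_covariates,
                threshold = smd_threshold)
  } else {
    K_elig + 1L
  }
  K_keep <- min(K_elig, k_max - 1L)
  if (truncation %in% c("eligibility", "none")) {
    bad <- Filter(function(s) !isTRUE(s$converged), sw[seq_len(K_keep)])
    if (length(bad) > 0) {
      stop(errorCondition(
        paste0("fit_weighted_pwp: weights could not be solved for stratum ",
               bad[[1]]$k, " (", bad[[1]]$error, "); use truncation = 'smd'"),
        class = c("repwp_infeasible", "error", "condition")))
    }
  }
  rows <- which(h$k <= K_keep)
  sub <- event_history(as.data.frame(h)[rows, , drop = FALSE],
                       time_scale = "gap", covariates = covariate_names(h),
                       validate = FALSE)
  w <- rep(1, nrow(sub))
  for (kk in seq_len(K_keep)) {
    w[sub$k == kk] <- sw[[kk]]$weights
  }
  .fit_cox_family(sub, "wpwp", time_scale = "gap", stratify = TRUE,
                  variance = "robust", adjust = adjust, weights = w,
                  extra = list(stratum_weights = sw[seq_len(K_keep)],
                               k_eligible = K_elig, k_max = k_max,
                               weighting = weighting))
}
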
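# Monte Carlo evaluation: bias, type I error and power across scenarios
# and models.

#' Null-hypothesis rejection for one fit
#'
#' TRUE when the two-sided 95% CI for the treatment effect (on the
#' HR/rate-ratio scale, using the variance the model prescribes) excludes
#' 1. A CI endpoint exactly equal to 1 counts as non-rejection.
#'
#' @param fit A `repwp_fit`.
#' @return Logical.
#' @export
rejection <- function(fit) {
  unname(fit$ci95[1] > 1 | fit$ci95[2] < 1)
}

#' Bias of a set of effect estimates
#'
#' Mean estimate minus the true value, by default on the hazard-ratio
#' scale.
#'
#' @param estimates Numeric vector of estimates.
#' @param truth True value.
#' @return `mean(estimates) - truth`.
#' @export
bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop("bias: no estimates", call. = FALSE)
  mean(estimates) - truth
}

.study_models <- c("cox1", "ag", "lwyy", "poisson", "nb", "pwp",
                   "pwp_robust", "wpwp3", "wpwp5", "wpwp_ipw5")

# Fit the requested models on one simulated trial; shares engine fits
# between models that differ only in the variance (AG/LWYY, PWP/PWP-robust).
.fit_models_once <- function(h, models) {
  out <- list()
  grab <- function(f) tryCatch(f, error = function(e) e)
  if (any(c("ag", "lwyy") %in% models)) {
    f <- grab(fit_lwyy(h))
    if ("ag" %in% models) {
      out$ag <- if (inherits(f, "error")) f else {
        g <- f
        g$model <- "ag"; g$var_used <- "naive"
        g$ci95 <- exp(g$coef + c(-1, 1) * stats::qnorm(0.975) * g$se_naive)
        g
      }
    }
    if ("lwyy" %in% models) out$lwyy <- f
  }
  if (any(c("pwp", "pwp_robust") %in% models)) {
    f <- grab(fit_pwp_robust(h))
    if ("pwp" %in% models) {
      out$pwp <- if (inherits(f, "error")) f else {
        g <- f
        g$model <- "pwp_gt"; g$var_used <- "naive"
        g$ci95 <- exp(g$coef + c(-1, 1) * stats::qnorm(0.975) * g$se_naive)
        g
      }
    }
    if ("pwp_robust" %in% models) out$pwp_robust <- f
  }
  if ("cox1" %in% models) out$cox1 <- grab(fit_cox_first_event(h))
  if ("poisson" %in% models) out$poisson <- grab(fit_poisson(h))
  if ("nb" %in% models) out$nb <- grab(fit_negbin(h))
  cvs <- covariate_names(h)
  if ("wpwp3" %in% models) {
    out$wpwp3 <- grab(fit_weighted_pwp(h, balance_covariates = cvs[1:3]))
  }
  if ("wpwp5" %in% models) {
    out$wpwp5 <- grab(fit_weighted_pwp(h, balance_covariates = cvs))
  }
  if ("wpwp_ipw5" %in% models) {
    out$wpwp_ipw5 <- grab(fit_weighted_pwp(h, balance_covariates = cvs,
                                           weighting = "ipw"))
  }
  out[models[models %in% names(out)]]
}

#' Run a Monte Carlo study
#'
#' Simulates `n_sim` trials for every (scenario, sample size) pair, fits
#' the requested models on each replicate, and aggregates bias (HR and
#' log-HR scales), rejection rate (type I error when the scenario's true
#' HR is 1, power otherwise) and the Monte Carlo standard error
#' `sqrt(p(1-p)/n_sim)` of the rate. Replicates where a model fails to
#' converge are excluded from that model's summaries and counted in
#' `n_failed`. The whole study is deterministic given `seed`: replicate
#' seeds are pre-drawn from the root seed.
#'
#' @param scenario_ids Scenario numbers (subset of 1:4).
#' @param n Sample sizes, e.g. `c(100, 300, 500)`.
#' @param models Model labels among `"cox1"`, `"ag"`, `"lwyy"`,
#'   `"poisson"`, `"nb"`, `"pwp"`, `"pwp_robust"`, `"wpwp3"`, `"wpwp5"`,
#'   `"wpwp_ipw5"`; `"all"` selects every one except the IPW variant.
#' @param n_sim Replications per (scenario, n), default 1000.
#' @param seed Root integer seed.
#' @param keep_estimates Also return the per-replicate HR estimates
#'   (attribute `"estimates"`).
#' @return A data.frame with one row per (scenario, n, model):
#'   `mean_hr`, `bias_hr`, `bias_loghr`, `rejection_rate`, `type`
#'   (`"t1e"` or `"power"`), `mc_se`, `n_used`, `n_failed`.
#' @export
run_study <- function(scenario_ids, n, models = "all", n_sim = 1000,
                      seed = 1, keep_estimates = FALSE) {
  if (identical(models, "all")) {
    models <- setdiff(.study_models, "wpwp_ipw5")
  }
  bad <- setdiff(models, .study_models)
  if (length(bad) > 0) {
    stop("run_study: unknown model(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  res <- list()
  est_store <- list()
  for (sc in scenario_ids) {
    for (nn in n) {
      cfg <- make_scenario(sc, n = nn, n_sim = n_sim)
      rep_seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
      hr_mat <- matrix(NA_real_, n_sim, length(models),
                       dimnames = list(NULL, models))
      rej_mat <- matrix(NA, n_sim, length(models),
                        dimnames = list(NULL, models))
      for (r in seq_len(n_sim)) {
        h <- simulate_trial(cfg, seed = rep_seeds[r])
        fits <- .fit_models_once(h, models)
        for (m in names(fits)) {
          if (!inherits(fits[[m]], "error")) {
            hr_mat[r, m] <- fits[[m]]$hr
            rej_mat[r, m] <- rejection(fits[[m]])
          }
        }
      }
      truth <- cfg$hr_treatment
      for (m in models) {
        ok <- !is.na(hr_mat[, m])
        n_used <- sum(ok)
        prop <- mean(rej_mat[ok, m])
        res[[length(res) + 1]] <- data.frame(
          scenario = sc, n = nn, model = m, n_sim = n_sim,
          n_used = n_used, n_failed = n_sim - n_used,
          true_hr = truth,
          mean_hr = mean(hr_mat[ok, m]),
          bias_hr = bias(hr_mat[ok, m], truth),
          bias_loghr = bias(log(hr_mat[ok, m]), log(truth)),
          rejection_rate = prop,
          type = if (truth == 1) "t1e" else "power",
          mc_se = sqrt(prop * (1 - prop) / n_used)
        )
      }
      if (keep_estimates) {
        est_store[[paste(sc, nn, sep = "_")]] <- hr_mat
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (keep_estimates) attr(out, "estimates") <- est_store
  out
}
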
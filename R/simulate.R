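# Weibull gap-time trial simulator with event-number-dependent baseline
# hazards.

#' Convert a hazard ratio to a Weibull location coefficient
#'
#' In the simulator's accelerated parameterization the gap-time survival
#' is `S(t) = exp(-lambda t^q)` with
#' `lambda = exp(-q (beta0 + A beta + X gamma))`, so a hazard ratio maps
#' to a coefficient via `HR = exp(-q beta)`, i.e.
#' `beta = -log(HR) / q` (and likewise for covariate effects).
#'
#' @param hr Positive hazard ratio.
#' @param q Positive Weibull shape.
#' @return The coefficient on the location scale.
#' @export
coef_from_hr <- function(hr, q) {
  if (any(hr <= 0) || any(q <= 0)) {
    stop("coef_from_hr: hr and q must be positive", call. = FALSE)
  }
  -log(hr) / q
}

#' Simulation scenario configuration
#'
#' Parameterizes one simulated randomized trial with recurrent events.
#' Gap times for the k-th event are Weibull with shape `q[k]` and scale
#' determined by `beta0[k]`, the treatment effect and five (by default)
#' independent standard-normal covariates; events beyond the length of
#' `q`/`beta0` reuse the last entry, so the baseline hazard is constant
#' from the fifth event on. Follow-up is administrative at `follow_up`
#' time units (days); there is no other censoring and no risk-free
#' interval.
#'
#' `make_scenario()` returns the four study scenarios: treatment HR 0.75
#' (1, 2) or 1 (3, 4) crossed with covariate HR 0.9 (1, 3) or 1.2 (2, 4),
#' with shape 1.5 and per-event baselines (6, 5.5, 5, 4, 3) throughout.
#'
#' @param hr_treatment Treatment hazard ratio (`exp(-q beta)`).
#' @param hr_covariate Common hazard ratio of each covariate.
#' @param n Sample size.
#' @param q Per-event Weibull shapes.
#' @param beta0 Per-event baseline location parameters.
#' @param n_covariates Number of iid N(0,1) covariates, default 5.
#' @param follow_up Administrative censoring time, default 730 days
#'   (two years).
#' @param n_sim Number of replications a study run should use.
#' @param scenario_id Optional label.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(hr_treatment, hr_covariate, n,
                            q = rep(1.5, 5), beta0 = c(6, 5.5, 5, 4, 3),
                            n_covariates = 5, follow_up = 730,
                            n_sim = 1000, scenario_id = NA_integer_) {
  stopifnot(length(q) == length(beta0), all(q > 0),
            hr_treatment > 0, hr_covariate > 0, n >= 2, follow_up > 0)
  structure(list(scenario_id = scenario_id, hr_treatment = hr_treatment,
                 hr_covariate = hr_covariate, n = as.integer(n), q = q,
                 beta0 = beta0, n_covariates = as.integer(n_covariates),
                 follow_up = follow_up, n_sim = as.integer(n_sim)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param id Scenario number, 1-4.
#' @export
make_scenario <- function(id, n, n_sim = 1000) {
  if (!id %in% 1:4) stop("make_scenario: id must be 1, 2, 3 or 4",
                         call. = FALSE)
  hr <- c(0.75, 0.75, 1, 1)[id]
  hrcov <- c(0.9, 1.2, 0.9, 1.2)[id]
  scenario_config(hr_treatment = hr, hr_covariate = hrcov, n = n,
                  n_sim = n_sim, scenario_id = as.integer(id))
}

#' Simulate one randomized trial with recurrent events
#'
#' Subjects are randomized 1:1 (`Bernoulli(0.5)`), covariates are iid
#' N(0,1). Gap times are drawn sequentially by inverse-transform
#' sampling: `T_k = (-log(U) / lambda_k)^(1/q_k)` with
#' `lambda_k = exp(-q_k (beta0_k + A beta + X gamma))`; the k-th gap is
#' simulated only for subjects whose (k-1)-th event was observed. The
#' first gap that carries the subject's calendar time past `follow_up` is
#' recorded as a censored interval truncated at the remaining time.
#'
#' @param config A `scenario_config`.
#' @param seed Optional integer seed (set once for the whole trial).
#' @return A gap-scale `event_history` with covariates `x1..xP` and an
#'   attribute `truth`: the generating `beta`, `gamma`, hazard ratios and
#'   scenario id.
#' @examples
#' h <- simulate_trial(make_scenario(1, n = 50), seed = 1)
#' max_stratum(h)
#' @export
simulate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  P <- config$n_covariates
  qv <- config$q
  b0v <- config$beta0
  fu <- config$follow_up
  # effects on the location scale; each event number reuses the last
  # shape/baseline beyond the specified vectors
  A <- stats::rbinom(n, 1, 0.5)
  X <- matrix(stats::rnorm(n * P), n, P)
  kmaxspec <- length(qv)

  rows_id <- integer(0); rows_k <- integer(0)
  rows_gap <- numeric(0); rows_d <- integer(0)
  active <- rep(TRUE, n)
  cum <- numeric(n)
  k <- 0L
  while (any(active)) {
    k <- k + 1L
    qk <- qv[min(k, kmaxspec)]
    b0k <- b0v[min(k, kmaxspec)]
    beta_k <- coef_from_hr(config$hr_treatment, qk)
    gamma_k <- coef_from_hr(config$hr_covariate, qk)
    idx <- which(active)
    lam <- exp(-qk * (b0k + A[idx] * beta_k + rowSums(X[idx, , drop = FALSE]) * gamma_k))
    gap <- (-log(stats::runif(length(idx))) / lam)^(1 / qk)
    newcum <- cum[idx] + gap
    cens <- newcum > fu
    obs_gap <- ifelse(cens, fu - cum[idx], gap)
    rows_id <- c(rows_id, idx)
    rows_k <- c(rows_k, rep(k, length(idx)))
    rows_gap <- c(rows_gap, obs_gap)
    rows_d <- c(rows_d, as.integer(!cens))
    cum[idx] <- pmin(newcum, fu)
    active[idx] <- !cens
  }
  df <- data.frame(id = rows_id, k = rows_k, start = 0, stop = rows_gap,
                   status = rows_d, treatment = A[rows_id])
  Xr <- X[rows_id, , drop = FALSE]
  colnames(Xr) <- paste0("x", seq_len(P))
  df <- cbind(df, Xr)
  h <- event_history(df, time_scale = "gap",
                     covariates = paste0("x", seq_len(P)), validate = FALSE)
  attr(h, "truth") <- list(
    beta = coef_from_hr(config$hr_treatment, qv[1]),
    gamma = coef_from_hr(config$hr_covariate, qv[1]),
    hr_treatment = config$hr_treatment,
    hr_covariate = config$hr_covariate,
    scenario_id = config$scenario_id)
  h
}
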
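# Weighted stratified Cox partial-likelihood engine.
#
# Maximizes the weighted stratified partial likelihood with Breslow tie
# handling. Weights multiply both the event contributions and the risk-set
# sums, matching the weighted score equation
#   sum_k { sum_i w_ki d_ki A_i
#           - sum_i w_ki d_ki (sum_j Y_kj(t_ki) w_kj Z_j e^{Z_j b})
#                              / (sum_j Y_kj(t_ki) w_kj e^{Z_j b}) } = 0.
# All per-stratum sums are computed from sorted cumulative sums over entry
# and exit times, so one likelihood/score/information evaluation costs
# O(n log n) per stratum regardless of the number of event times.

# Precompute the beta-independent structure of one stratum.
.pl_stratum <- function(start, stop, status, w) {
  has_entry <- any(start > 0)
  dt <- sort(unique(stop[status == 1]))
  os <- order(stop)
  ost <- if (has_entry) order(start) else NULL
  list(
    n = length(stop), dt = dt, nd = length(dt),
    os = os, sorted_stop = stop[os],
    ost = ost, sorted_start = if (has_entry) start[ost] else NULL,
    has_entry = has_entry,
    # number of sorted stops (starts) strictly below each death time
    lt_stop = findInterval(dt, stop[os], left.open = TRUE),
    lt_start = if (has_entry) findInterval(dt, start[ost], left.open = TRUE)
               else NULL,
    death_rows = which(status == 1),
    death_grp = match(stop[status == 1], dt),
    # per-row lookups for score residuals: deaths with start < t <= stop
    nd_at_stop = findInterval(stop, dt),
    nd_at_start = findInterval(start, dt)
  )
}

# Column-wise cumulative sums that never drop dimensions.
.col_cumsum <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) <= 1) return(M)
  apply(M, 2, cumsum)
}

# Risk-set sum of `v` (a vector or matrix of per-row quantities, already
# multiplied by w * exp(eta)) at each death time of stratum `ps`.
.risk_sum <- function(ps, v) {
  v <- as.matrix(v)
  cs <- .col_cumsum(v[ps$os, , drop = FALSE])
  cs <- rbind(0, cs)
  tot <- cs[nrow(cs), ]
  out <- matrix(tot, nrow = ps$nd, ncol = ncol(v), byrow = TRUE) -
    cs[ps$lt_stop + 1L, , drop = FALSE]
  if (ps$has_entry) {
    cs2 <- rbind(0, .col_cumsum(v[ps$ost, , drop = FALSE]))
    out <- out - (matrix(tot, nrow = ps$nd, ncol = ncol(v), byrow = TRUE) -
                  cs2[ps$lt_start + 1L, , drop = FALSE])
  }
  out
}

# Evaluate the weighted partial likelihood, score and information (and,
# optionally, per-row weighted score residuals) at `beta`.
.pl_eval <- function(beta, Z, status, w, strata_idx, strata_pre,
                     residuals = FALSE) {
  p <- ncol(Z)
  eta <- drop(Z %*% beta)
  if (max(abs(eta)) > 500) {
    stop(errorCondition("partial likelihood: linear predictor overflow",
                        class = c("repwp_overflow", "error", "condition")))
  }
  r <- w * exp(eta)
  ll <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  resid <- if (residuals) matrix(0, length(status), p) else NULL

  for (s in seq_along(strata_idx)) {
    ps <- strata_pre[[s]]
    if (ps$nd == 0) next
    idx <- strata_idx[[s]]
    Zs <- Z[idx, , drop = FALSE]
    rs <- r[idx]
    ws <- w[idx]
    sts <- status[idx]

    S0 <- drop(.risk_sum(ps, rs))
    S1 <- .risk_sum(ps, rs * Zs)
    ZZ <- Zs[, pairs[, 1], drop = FALSE] * Zs[, pairs[, 2], drop = FALSE]
    S2f <- .risk_sum(ps, rs * ZZ)

    Wd <- drop(rowsum(ws[ps$death_rows], ps$death_grp))
    Zbar <- S1 / S0
    ll <- ll + sum((ws * eta[idx])[ps$death_rows]) - sum(Wd * log(S0))
    score <- score +
      colSums((ws * Zs)[ps$death_rows, , drop = FALSE]) -
      colSums(Wd * Zbar)
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      v <- sum(Wd * (S2f[, q] / S0 - Zbar[, i] * Zbar[, j]))
      info[i, j] <- info[i, j] + v
      if (i != j) info[j, i] <- info[j, i] + v
    }

    if (residuals) {
      # cumulative (over death times) hazard-type sums for the
      # martingale part of the score residual
      G0 <- c(0, cumsum(Wd / S0))
      G1 <- rbind(0, .col_cumsum(Wd * S1 / S0^2))
      dG0 <- G0[ps$nd_at_stop + 1L] - G0[ps$nd_at_start + 1L]
      dG1 <- G1[ps$nd_at_stop + 1L, , drop = FALSE] -
             G1[ps$nd_at_start + 1L, , drop = FALSE]
      U <- -(exp(eta[idx]) * (Zs * dG0 - dG1))
      dpos <- ps$death_rows
      U[dpos, ] <- U[dpos, , drop = FALSE] +
        Zs[dpos, , drop = FALSE] - Zbar[ps$death_grp, , drop = FALSE]
      resid[idx, ] <- ws * U
    }
  }
  list(loglik = ll, score = score, info = info, resid = resid)
}

#' Weighted stratified Cox partial likelihood
#'
#' Low-level access to the engine behind every Cox-type model in the
#' package: evaluates the weighted stratified log partial likelihood (or
#' its gradient) at a given coefficient vector, with Breslow handling of
#' tied event times. Risk sets use half-open intervals `(start, stop]`.
#'
#' @param beta Numeric coefficient vector (one entry per column of the
#'   design matrix).
#' @param h An `event_history`.
#' @param terms Character vector of columns forming the linear predictor;
#'   default `"treatment"`.
#' @param weights Optional per-row weights (default 1). Weights multiply
#'   both the event contributions and the risk-set sums.
#' @param stratify Stratify by event number `k` (default TRUE).
#' @return For `neg_log_partial_likelihood`, the negative weighted log
#'   partial likelihood (a finite scalar); for `partial_likelihood_score`,
#'   the score vector (gradient of the log partial likelihood).
#' @examples
#' h <- event_history(data.frame(id = 1:3, k = 1, start = 0,
#'                               stop = c(1, 2, 3), status = c(1, 1, 0),
#'                               treatment = c(1, 0, 0)))
#' neg_log_partial_likelihood(0, h, stratify = FALSE)  # log 3 + log 2
#' @export
neg_log_partial_likelihood <- function(beta, h, terms = "treatment",
                                       weights = NULL, stratify = TRUE) {
  pr <- .pl_prepare(h, terms, weights, stratify)
  if (sum(h$status) == 0) {
    stop("partial likelihood: no events in the data", call. = FALSE)
  }
  -.pl_eval(beta, pr$Z, pr$status, pr$w, pr$strata_idx, pr$strata_pre)$loglik
}

#' @rdname neg_log_partial_likelihood
#' @export
partial_likelihood_score <- function(beta, h, terms = "treatment",
                                     weights = NULL, stratify = TRUE) {
  pr <- .pl_prepare(h, terms, weights, stratify)
  if (sum(h$status) == 0) {
    stop("partial likelihood: no events in the data", call. = FALSE)
  }
  .pl_eval(beta, pr$Z, pr$status, pr$w, pr$strata_idx, pr$strata_pre)$score
}

.pl_prepare <- function(h, terms, weights, stratify) {
  Z <- as.matrix(as.data.frame(h)[, terms, drop = FALSE])
  storage.mode(Z) <- "double"
  w <- if (is.null(weights)) rep(1, nrow(h)) else weights
  if (length(w) != nrow(h)) {
    stop("weights must have one entry per event-history row", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  strata <- if (stratify) h$k else rep(1L, nrow(h))
  strata_idx <- split(seq_len(nrow(h)), strata)
  strata_pre <- lapply(strata_idx, function(idx) {
    .pl_stratum(h$start[idx], h$stop[idx], h$status[idx], w[idx])
  })
  list(Z = Z, status = h$status, w = w, strata_idx = strata_idx,
       strata_pre = strata_pre)
}

# Newton-Raphson with step halving on the weighted partial likelihood.
# Returns coefficients, naive (inverse-information) and, when `cluster`
# is given, robust cluster sandwich variance with the subject's weighted
# score residuals aggregated across all rows and strata.
.pl_fit <- function(h, terms = "treatment", weights = NULL, stratify = TRUE,
                    cluster = NULL, tol_beta = 1e-9, tol_score = 1e-8,
                    max_iter = 50) {
  pr <- .pl_prepare(h, terms, weights, stratify)
  if (sum(h$status) == 0) {
    stop("partial likelihood: no events in the data", call. = FALSE)
  }
  # the score is a sum of O(total event weight) terms, so its achievable
  # numerical floor grows with the data; make the tolerance scale-relative
  tol_score <- tol_score * max(1, sum(pr$w * pr$status))
  p <- ncol(pr$Z)
  beta <- numeric(p)
  ev <- .pl_eval(beta, pr$Z, pr$status, pr$w, pr$strata_idx, pr$strata_pre)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$info, ev$score), error = function(e) NULL)
    if (is.null(step)) {
      stop(errorCondition(
        "partial likelihood: singular information matrix",
        class = c("repwp_singular", "error", "condition")))
    }
    newbeta <- beta + step
    newev <- tryCatch(
      .pl_eval(newbeta, pr$Z, pr$status, pr$w, pr$strata_idx, pr$strata_pre),
      error = function(e) NULL)
    halvings <- 0
    while ((is.null(newev) || newev$loglik < ev$loglik - 1e-12) &&
           halvings < 25) {
      step <- step / 2
      newbeta <- beta + step
      newev <- tryCatch(
        .pl_eval(newbeta, pr$Z, pr$status, pr$w, pr$strata_idx,
                 pr$strata_pre),
        error = function(e) NULL)
      halvings <- halvings + 1
    }
    if (is.null(newev)) {
      stop(errorCondition(
        "partial likelihood: likelihood evaluation failed (monotone likelihood?)",
        class = c("repwp_no_convergence", "error", "condition")))
    }
    beta <- newbeta
    ev <- newev
    if (max(abs(beta)) > 20) break  # monotone likelihood / separation
    if (max(abs(step)) < tol_beta && max(abs(ev$score)) < tol_score) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(ev$score)) < tol_score) converged <- TRUE
  # a vanishing score at an extreme coefficient is the signature of a
  # monotone likelihood, not of an interior maximum
  if (max(abs(beta)) > 20) converged <- FALSE
  if (!converged) {
    stop(errorCondition(
      paste0("partial likelihood: Newton-Raphson did not converge in ",
             max_iter, " iterations (|score| = ",
             format(max(abs(ev$score)), digits = 3), ", beta = ",
             paste(format(beta, digits = 3), collapse = ", "),
             "); the likelihood may be monotone (separation)"),
      class = c("repwp_no_convergence", "error", "condition")))
  }
  var_naive <- solve(ev$info)
  var_robust <- NULL
  if (!is.null(cluster)) {
    ev <- .pl_eval(beta, pr$Z, pr$status, pr$w, pr$strata_idx, pr$strata_pre,
                   residuals = TRUE)
    D <- rowsum(ev$resid, cluster)
    var_robust <- var_naive %*% crossprod(D) %*% var_naive
  }
  list(coef = setNames(beta, colnames(pr$Z)), loglik = ev$loglik,
       score = ev$score, var_naive = var_naive, var_robust = var_robust,
       iterations = iter, converged = converged,
       n_events = sum(h$status))
}
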
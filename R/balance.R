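#' Entropy-balancing weights for one risk set
#'
#' Solves the per-risk-set balancing problem: find weights `w` minimizing
#' the Kullback-Leibler divergence `D1(w || d) = sum(w_i log(w_i / d_i))`
#' from reference weights `d` (uniform `1/N` by default), subject to the
#' constraints that within each treatment arm the weighted covariate means
#' equal the pooled risk-set means, and the weights in each arm sum to the
#' arm's size. Both arms are reweighted towards the same pooled target, so
#' the weighted risk set behaves like a virtual population in which the
#' covariates are again balanced between arms, as they were at
#' randomization.
#'
#' The solution has the exponential-family form
#' `w_i = N_arm d_i exp(lambda' u_i) / sum_j d_j exp(lambda' u_j)` within
#' each arm; the dual variables `lambda` (one per covariate per arm) are
#' found by damped Newton iterations on the strictly convex dual. A
#' constraint is infeasible when the pooled target lies outside the convex
#' hull of an arm's covariate values; the box condition (target outside an
#' arm's observed range) is detected up front and reported as a classed
#' error (`repwp_infeasible`), other infeasibilities surface as
#' non-convergence (`repwp_no_convergence`).
#'
#' @param U Numeric matrix of covariate (moment-function) values, one row
#'   per risk-set member, one column per balance constraint. First-order
#'   moments: the columns are the covariates themselves.
#' @param treatment 0/1 vector, one entry per row of `U`.
#' @param reference Optional positive reference weights (length
#'   `nrow(U)`); they are normalized to sum to 1. Default uniform.
#' @param tol Convergence tolerance on the maximum absolute constraint
#'   violation (weighted mean minus pooled target), default `1e-8`.
#' @param max_iter Maximum Newton iterations per arm, default 200.
#' @param k Optional stratum label carried into the result and error
#'   messages.
#' @return An object of class `stratum_weights`: a list with `k`,
#'   `weights` (positive, arm sums equal to the arm sizes), `converged`,
#'   `max_violation`, `divergence` (the achieved KL divergence, summed
#'   over the two arm-wise problems with weights normalized within arm,
#'   so 0 at uniform weights), `n_treated`, `n_control`, `target` (the
#'   pooled moments) and `lambda` (per-arm dual variables).
#' @examples
#' U <- cbind(x = c(1, 3, 0, 2, 4, 6))
#' sw <- entropy_balance(U, treatment = c(1, 1, 0, 0, 0, 0))
#' weighted.mean(U[1:2, 1], sw$weights[1:2])  # pooled mean 16/6
#' @export
entropy_balance <- function(U, treatment, reference = NULL, tol = 1e-8,
                            max_iter = 200, k = NA_integer_) {
  U <- as.matrix(U)
  storage.mode(U) <- "double"
  n <- nrow(U)
  if (length(treatment) != n) {
    stop("entropy_balance: treatment length must match nrow(U)", call. = FALSE)
  }
  if (is.null(colnames(U))) colnames(U) <- paste0("u", seq_len(ncol(U)))
  if (is.null(reference)) {
    reference <- rep(1 / n, n)
  } else {
    if (any(reference <= 0)) {
      stop("entropy_balance: reference weights must be strictly positive",
           call. = FALSE)
    }
    reference <- reference / sum(reference)
  }
  n1 <- sum(treatment == 1)
  n0 <- sum(treatment == 0)
  if (n1 < 2 || n0 < 2) {
    stop("entropy_balance: need at least two members per arm (stratum ",
         k, " has ", n1, " treated, ", n0, " control)", call. = FALSE)
  }
  target <- colMeans(U)

  weights <- numeric(n)
  lambda <- list()
  viol <- 0
  conv <- TRUE
  for (arm in c(1, 0)) {
    sel <- which(treatment == arm)
    sol <- .eb_arm(U[sel, , drop = FALSE], reference[sel], target, tol,
                   max_iter, k = k, arm = arm)
    weights[sel] <- length(sel) * sol$w
    lambda[[paste0("arm", arm)]] <- sol$lambda
    viol <- max(viol, sol$violation)
    conv <- conv && sol$converged
  }
  if (!conv) {
    stop(errorCondition(
      paste0("entropy_balance: no convergence within ", max_iter,
             " iterations in stratum ", k, " (max constraint violation ",
             format(viol, digits = 3), "); the pooled target may lie ",
             "outside an arm's convex hull"),
      class = c("repwp_no_convergence", "error", "condition")))
  }
  # KL divergence from the reference, accumulated over the two arm-wise
  # problems with weights normalized within arm (0 at uniform weights)
  d1 <- 0
  for (arm in c(1, 0)) {
    sel <- treatment == arm
    wn <- weights[sel] / sum(weights[sel])
    dn <- reference[sel] / sum(reference[sel])
    d1 <- d1 + sum(wn * log(wn / dn))
  }
  structure(list(k = k, weights = weights, converged = conv,
                 max_violation = viol, divergence = d1,
                 n_treated = n1, n_control = n0,
                 target = target, lambda = lambda),
            class = "stratum_weights")
}

# Dual Newton for one arm: weights proportional to d * exp(lambda' u),
# normalized to sum 1 here (caller rescales to the arm size).
.eb_arm <- function(U, d, target, tol, max_iter, k, arm) {
  p <- ncol(U)
  d <- d / sum(d)
  # quick hull (box) check per coordinate; constant columns matching the
  # target are trivially satisfied and excluded from the Newton step
  rng <- apply(U, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span < 1e-12
  for (j in seq_len(p)) {
    ok <- if (const[j]) {
      abs(rng[1, j] - target[j]) < 1e-10
    } else {
      target[j] > rng[1, j] && target[j] < rng[2, j]
    }
    if (!ok) {
      stop(errorCondition(
        paste0("entropy_balance: infeasible constraint in stratum ", k,
               ", arm ", arm, ": pooled mean of '", colnames(U)[j], "' (",
               format(target[j], digits = 4), ") lies outside the arm's ",
               "value range [", format(rng[1, j], digits = 4), ", ",
               format(rng[2, j], digits = 4), "]"),
        class = c("repwp_infeasible", "error", "condition")))
    }
  }
  act <- which(!const)
  if (length(act) == 0) {
    return(list(w = d, lambda = rep(0, p), violation = 0, converged = TRUE))
  }
  # centre and scale the active columns for conditioning; lambda is
  # reported on the working (scaled) parameterization
  Uc <- sweep(U[, act, drop = FALSE], 2, target[act])
  sc <- pmax(apply(abs(Uc), 2, max), 1e-12)
  Uc <- sweep(Uc, 2, sc, "/")
  lam <- rep(0, length(act))
  w <- d
  violation <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Uc %*% lam)
    eta <- eta - max(eta)
    w <- d * exp(eta)
    w <- w / sum(w)
    grad <- drop(crossprod(Uc, w))          # weighted mean of scaled (u - m)
    violation <- max(abs(grad) * sc)        # back on the original scale
    if (violation < tol) { converged <- TRUE; break }
    mu <- drop(crossprod(Uc, w))
    Ucc <- sweep(Uc, 2, mu)
    H <- crossprod(Ucc, w * Ucc)
    step <- tryCatch(solve(H + diag(1e-12, length(act)), grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    # damp large steps; the dual is unbounded when infeasible
    mstep <- max(abs(step))
    if (mstep > 25) step <- step * (25 / mstep)
    lam <- lam - step
    if (max(abs(lam)) > 1e6) break
  }
  full_lambda <- rep(0, ncol(U))
  full_lambda[act] <- lam / sc
  list(w = w, lambda = full_lambda, violation = violation,
       converged = converged)
}

#' @export
print.stratum_weights <- function(x, ...) {
  cat("Stratum", x$k, "balancing weights:", length(x$weights), "members (",
      x$n_treated, "treated /", x$n_control, "control )\n")
  cat("  converged:", x$converged,
      " max violation:", format(x$max_violation, digits = 3),
      " KL divergence:", format(x$divergence, digits = 4), "\n")
  invisible(x)
}

#' Balancing weights for every eligible risk set
#'
#' Applies [entropy_balance()] stratum by stratum: the first risk set
#' keeps unit weights (it is the randomized sample), and each later
#' stratum is rebalanced towards its own pooled covariate means. Strata
#' beyond the eligibility prefix (see [eligible_strata()]) are not
#' attempted; strata where the solver fails are returned as unconverged
#' placeholder entries so that downstream truncation rules can act on
#' them.
#'
#' @param h An `event_history`.
#' @param covariates Character vector of covariate columns to balance;
#'   default all covariates ("fully weighted"). A subset gives the
#'   "partly weighted" variant.
#' @param weighting `"entropy"` (default) or `"ipw"` (stabilized
#'   inverse-probability weights from a per-stratum logistic model).
#' @inheritParams entropy_balance
#' @return A list of `stratum_weights`, one per stratum `1..K'` where
#'   `K'` is the eligibility prefix; entries carry `$converged = FALSE`
#'   when the stratum could not be balanced.
#' @export
balance_all_strata <- function(h, covariates = NULL,
                               weighting = c("entropy", "ipw"),
                               tol = 1e-8, max_iter = 200) {
  weighting <- match.arg(weighting)
  covariates <- .check_balance_covariates(h, covariates)
  K_elig <- eligible_strata(h)
  out <- vector("list", K_elig)
  rs1 <- risk_set(h, 1)
  out[[1]] <- structure(list(k = 1L, weights = rep(1, rs1$n),
                             converged = TRUE, max_violation = 0,
                             divergence = NA_real_,
                             n_treated = rs1$n_treated,
                             n_control = rs1$n_control,
                             target = NULL, lambda = NULL),
                        class = "stratum_weights")
  if (K_elig < 2) return(out)
  for (kk in 2:K_elig) {
    rows <- which(h$k == kk)
    U <- as.matrix(as.data.frame(h)[rows, covariates, drop = FALSE])
    trt <- h$treatment[rows]
    sw <- tryCatch({
      if (weighting == "entropy") {
        entropy_balance(U, trt, tol = tol, max_iter = max_iter, k = kk)
      } else {
        w <- stabilized_ipw(U, trt)
        structure(list(k = kk, weights = w, converged = TRUE,
                       max_violation = NA_real_, divergence = NA_real_,
                       n_treated = sum(trt == 1), n_control = sum(trt == 0),
                       target = colMeans(U), lambda = NULL),
                  class = "stratum_weights")
      }
    }, error = function(e) {
      structure(list(k = kk, weights = rep(NA_real_, length(rows)),
                     converged = FALSE, max_violation = NA_real_,
                     divergence = NA_real_,
                     n_treated = sum(trt == 1), n_control = sum(trt == 0),
                     target = colMeans(U), lambda = NULL,
                     error = conditionMessage(e)),
                class = "stratum_weights")
    })
    out[[kk]] <- sw
  }
  out
}

.check_balance_covariates <- function(h, covariates) {
  if (is.null(covariates)) covariates <- covariate_names(h)
  if (length(covariates) == 0) {
    stop("no balance covariates available in this event history",
         call. = FALSE)
  }
  bad <- setdiff(covariates, names(h))
  if (length(bad) > 0) {
    stop("balance covariate(s) not found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  covariates
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' The comparator weighting scheme: `sw_i = P(A = a_i) / P(A = a_i | X)`,
#' with the numerator the observed arm frequency and the denominator the
#' fitted probability from a main-effects logistic regression of treatment
#' on the covariates within the risk set.
#'
#' @param U Covariate matrix (rows = risk-set members).
#' @param treatment 0/1 vector.
#' @return A positive weight vector. If the logistic fit separates
#'   perfectly (fitted probabilities at 0 or 1) an error advising stratum
#'   truncation is raised.
#' @export
stabilized_ipw <- function(U, treatment) {
  U <- as.matrix(U)
  if (length(unique(treatment)) < 2) {
    stop("stabilized_ipw: both treatment arms must be present in the risk set",
         call. = FALSE)
  }
  df <- data.frame(.A = treatment, U)
  fit <- suppressWarnings(stats::glm(.A ~ ., family = stats::binomial(),
                                     data = df))
  ps <- stats::fitted(fit)
  eps <- 1e-8
  if (any(ps < eps | ps > 1 - eps)) {
    stop(errorCondition(
      paste0("stabilized_ipw: (near-)perfect separation in the propensity ",
             "model; consider truncating the analysis at an earlier stratum"),
      class = c("repwp_separation", "error", "condition")))
  }
  pA <- mean(treatment)
  ifelse(treatment == 1, pA / ps, (1 - pA) / (1 - ps))
}

#' Standardized mean difference
#'
#' Balance diagnostic: difference in (optionally weighted) arm means
#' divided by the unweighted standard deviation of the pooled risk set, so
#' pre- and post-weighting values share a scale. Values at or above 0.1
#' are conventionally flagged as imbalance.
#'
#' @param x Numeric covariate values over the risk set.
#' @param treatment 0/1 vector.
#' @param weights Optional weights (default unit).
#' @return The SMD (signed).
#' @export
smd <- function(x, treatment, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(unique(treatment)) < 2) {
    stop("smd: both arms must be present", call. = FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop(errorCondition("smd: pooled standard deviation is zero; SMD undefined",
                        class = c("repwp_zero_sd", "error", "condition")))
  }
  m1 <- stats::weighted.mean(x[treatment == 1], weights[treatment == 1])
  m0 <- stats::weighted.mean(x[treatment == 0], weights[treatment == 0])
  (m1 - m0) / s
}

#' Stratum eligibility for weighting
#'
#' A stratum qualifies when both treatment arms are present with at least
#' two members each, the minimum for the entropy-balancing problem to be
#' solvable. Returns the largest `K'` such that strata `1..K'` all
#' qualify (at least 1: the first risk set is the full randomized
#' sample).
#'
#' @param h An `event_history`.
#' @param min_per_arm Minimum members per arm (default 2).
#' @return Integer `K'`.
#' @export
eligible_strata <- function(h, min_per_arm = 2) {
  K <- max_stratum(h)
  Kp <- 0L
  for (kk in seq_len(K)) {
    rs <- risk_set(h, kk)
    if (rs$n_treated >= min_per_arm && rs$n_control >= min_per_arm) {
      Kp <- kk
    } else {
      break
    }
  }
  max(Kp, 1L)
}

#' SMD-based stratum truncation
#'
#' Finds `k_max`, the first stratum whose post-weighting balance fails:
#' either the weights could not be solved, or some balanced covariate has
#' `|SMD| >=` the threshold. The analysis then retains strata
#' `1 .. k_max - 1`. When every stratum is balanced, `k_max = K + 1`
#' (everything retained).
#'
#' @param h An `event_history`.
#' @param weights A list of `stratum_weights` as returned by
#'   [balance_all_strata()].
#' @param covariates Covariates whose balance is checked; default the
#'   covariates of `h`.
#' @param threshold SMD threshold, default 0.1.
#' @return Integer `k_max`.
#' @export
kmax_by_smd <- function(h, weights, covariates = NULL, threshold = 0.1) {
  covariates <- .check_balance_covariates(h, covariates)
  for (sw in weights) {
    kk <- sw$k
    if (kk == 1) next
    if (!isTRUE(sw$converged)) return(as.integer(kk))
    rows <- which(h$k == kk)
    trt <- h$treatment[rows]
    for (cv in covariates) {
      val <- tryCatch(smd(h[[cv]][rows], trt, sw$weights),
                      error = function(e) Inf)
      if (abs(val) >= threshold) return(as.integer(kk))
    }
  }
  as.integer(length(weights) + 1L)
}
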
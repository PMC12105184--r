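# Independent oracles used to validate the package's own implementations.
# These deliberately use naive, transparent algorithms (nested loops,
# penalty-method optimization, grid search) and never touch the engine's
# internals.

# Brute-force weighted log partial likelihood (Breslow ties): loop over
# distinct event times within each stratum, forming risk sets by direct
# filtering of (start, stop] intervals.
oracle_loglik <- function(beta, d, terms = "treatment", weights = NULL,
                          stratify = TRUE) {
  d <- as.data.frame(d)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  Z <- as.matrix(d[, terms, drop = FALSE])
  eta <- drop(Z %*% beta)
  s <- if (stratify) d$k else rep(1, nrow(d))
  ll <- 0
  for (str in unique(s)) {
    rows <- which(s == str)
    dts <- sort(unique(d$stop[rows][d$status[rows] == 1]))
    for (t in dts) {
      deaths <- rows[d$status[rows] == 1 & d$stop[rows] == t]
      atrisk <- rows[d$start[rows] < t & d$stop[rows] >= t]
      ll <- ll + sum(w[deaths] * eta[deaths]) -
        sum(w[deaths]) * log(sum(w[atrisk] * exp(eta[atrisk])))
    }
  }
  ll
}

# Grid-search maximizer of the brute-force likelihood (single coefficient).
oracle_grid_beta <- function(d, weights = NULL, stratify = TRUE,
                             lo = -3, hi = 3, step = 5e-4) {
  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, function(b) {
    oracle_loglik(b, d, weights = weights, stratify = stratify)
  }, numeric(1))
  grid[which.max(vals)]
}

# Central finite-difference gradient of a scalar function.
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# Generic constrained convex solver for the entropy-balancing problem:
# augmented Lagrangian on log-weights (textbook multiplier updates around
# a BFGS inner solve), fully independent of the package's dual Newton.
oracle_entropy_balance <- function(U, treatment) {
  U <- as.matrix(U)
  n <- nrow(U)
  target <- colMeans(U)
  constraints <- function(w) {
    g <- numeric(0)
    for (arm in 0:1) {
      sel <- treatment == arm
      na <- sum(sel)
      g <- c(g, sum(w[sel]) - na,
             vapply(seq_len(ncol(U)), function(j) {
               sum(w[sel] * U[sel, j]) / na - target[j]
             }, numeric(1)))
    }
    g
  }
  lam <- rep(0, 2 * (1 + ncol(U)))
  rho <- 1e3
  v <- rep(0, n)
  for (outer in 1:12) {
    obj <- function(v) {
      w <- exp(v)
      g <- constraints(w)
      sum(w * log(w * n)) + sum(lam * g) + (rho / 2) * sum(g^2)
    }
    v <- stats::optim(v, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))$par
    g <- constraints(exp(v))
    if (max(abs(g)) < 1e-11) break
    lam <- lam + rho * g
  }
  exp(v)
}

# KL divergence from uniform reference weights, summed over arms with
# weights normalized within arm (the package's reported convention).
oracle_d1 <- function(w, treatment) {
  out <- 0
  for (arm in 0:1) {
    sel <- treatment == arm
    wn <- w[sel] / sum(w[sel])
    out <- out + sum(wn * log(wn * sum(sel)))
  }
  out
}

# Small random gap-time event history with continuous times (no ties).
random_history <- function(n = 10, seed = 1, max_k = 3, p = 1,
                           event_prob = 0.6) {
  set.seed(seed)
  A <- stats::rbinom(n, 1, 0.5)
  X <- matrix(stats::rnorm(n * p), n, p)
  rows <- list()
  for (i in seq_len(n)) {
    for (k in seq_len(max_k)) {
      status <- if (k == max_k) 0L else stats::rbinom(1, 1, event_prob)
      rows[[length(rows) + 1]] <- data.frame(
        id = i, k = k, start = 0, stop = stats::rexp(1, 0.5) + 1e-3,
        status = status, treatment = A[i])
      if (status == 0L) break
    }
  }
  d <- do.call(rbind, rows)
  Xr <- X[d$id, , drop = FALSE]
  colnames(Xr) <- paste0("x", seq_len(p))
  event_history(cbind(d, Xr))
}
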
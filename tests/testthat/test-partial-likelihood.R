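test_that("log partial likelihood has its closed form at beta = 0", {
  # with beta = 0 and unit weights, -log L = sum over events of log(risk-set size)
  h <- event_history(data.frame(id = 1:4, k = 1, start = 0,
                                stop = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
                                treatment = c(1, 0, 1, 0)))
  expect_equal(neg_log_partial_likelihood(0, h, stratify = FALSE),
               log(4) + log(3) + log(2))
  expect_error(
    neg_log_partial_likelihood(0, event_history(
      data.frame(id = 1:2, k = 1, start = 0, stop = 1:2, status = 0,
                 treatment = c(1, 0)))),
    "no events")
})

test_that("likelihood and score match the brute-force oracle away from 0", {
  # 3-subject toy at beta = 0.5: direct evaluation of the risk-set products
  h <- event_history(data.frame(id = 1:3, k = 1, start = 0, stop = c(1, 2, 3),
                                status = c(1, 1, 0), treatment = c(1, 0, 0)))
  hand <- -((0.5 - log(exp(0.5) + 2)) + (0 - log(2)))
  expect_equal(neg_log_partial_likelihood(0.5, h, stratify = FALSE), hand)
  expect_equal(neg_log_partial_likelihood(0.5, h, stratify = FALSE),
               -oracle_loglik(0.5, h, stratify = FALSE))

  # score at beta = 0 is sum over events of (A_i - risk-set mean of A):
  # (1 - 1/3) at t = 1, (0 - 0) at t = 2 (risk set {2, 3} is all-control)
  sc0 <- partial_likelihood_score(0, h, stratify = FALSE)
  expect_equal(unname(sc0), 2 / 3)

  # random weighted stratified fixtures agree with the oracle
  for (s in 1:4) {
    hs <- random_history(n = 9, seed = 40 + s, max_k = 3)
    set.seed(s); w <- runif(nrow(hs), 0.5, 2)
    for (b in c(-0.7, 0, 1.1)) {
      expect_equal(neg_log_partial_likelihood(b, hs, weights = w),
                   -oracle_loglik(b, hs, weights = w), tolerance = 1e-10)
    }
  }
})

test_that("score equals the numerical gradient of the log partial likelihood", {
  for (s in 1:5) {
    hs <- random_history(n = 10, seed = 50 + s, max_k = 3, p = 1)
    set.seed(s); w <- runif(nrow(hs), 0.5, 2)
    for (terms in list("treatment", c("treatment", "x1"))) {
      b <- rnorm(length(terms), sd = 0.5)
      sc <- partial_likelihood_score(b, hs, terms = terms, weights = w)
      ng <- num_grad(function(x) {
        -neg_log_partial_likelihood(x, hs, terms = terms, weights = w)
      }, b)
      expect_equal(unname(sc), ng, tolerance = 1e-6)
    }
  }
})

test_that("fitted coefficients match an exhaustive grid search of the likelihood", {
  for (s in c(62, 64, 67)) {
    hs <- random_history(n = 8, seed = s, max_k = 3)
    f <- fit_pwp_gt(hs)
    expect_equal(unname(f$coef), oracle_grid_beta(hs), tolerance = 1e-3)
    # weighted variant
    set.seed(s); w <- runif(nrow(hs), 0.5, 2)
    fw <- repwp:::.pl_fit(hs, weights = w, stratify = TRUE)
    expect_equal(unname(fw$coef), oracle_grid_beta(hs, weights = w),
                 tolerance = 1e-3)
    # stationarity at the optimum (small-sample scale)
    expect_lt(max(abs(partial_likelihood_score(f$coef, hs))), 1e-8)
  }
})

test_that("rescaling weights by a positive constant leaves the estimate unchanged", {
  hs <- random_history(n = 10, seed = 70, max_k = 3)
  set.seed(1); w <- runif(nrow(hs), 0.5, 2)
  f1 <- repwp:::.pl_fit(hs, weights = w, stratify = TRUE)
  f2 <- repwp:::.pl_fit(hs, weights = 3.7 * w, stratify = TRUE)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  # within a single stratum the same holds for any per-stratum constant
  h1 <- first_event_subset(hs)
  w1 <- w[hs$k == 1]
  g1 <- repwp:::.pl_fit(h1, weights = w1, stratify = TRUE)
  g2 <- repwp:::.pl_fit(h1, weights = 5.1 * w1, stratify = TRUE)
  expect_equal(g1$coef, g2$coef, tolerance = 1e-8)
  # doubling all weights doubles the score and shifts the Breslow log
  # likelihood by the deterministic constant -2 log(2) sum(w delta)
  expect_equal(unname(partial_likelihood_score(0.3, hs, weights = 2 * w)),
               unname(2 * partial_likelihood_score(0.3, hs, weights = w)))
  expect_equal(-neg_log_partial_likelihood(0.3, hs, weights = 2 * w),
               -2 * neg_log_partial_likelihood(0.3, hs, weights = w) -
                 2 * log(2) * sum(w * hs$status))
  f3 <- repwp:::.pl_fit(hs, weights = 2 * w, stratify = TRUE)
  expect_equal(f1$coef, f3$coef, tolerance = 1e-8)
})

test_that("sandwich variance matches the hand-computed 3-subject case", {
  # single stratum, one row per subject, unit weights: times 1 < 2 < 3,
  # statuses 1, 1, 0, treatment 0, 1, 0. The score equation
  # r/(r+2) + r/(r+1) = 1 (r = e^beta) has the closed-form root r = sqrt(2).
  h <- event_history(data.frame(id = 1:3, k = 1, start = 0, stop = c(1, 2, 3),
                                status = c(1, 1, 0), treatment = c(0, 1, 0)))
  f <- repwp:::.pl_fit(h, stratify = FALSE, cluster = h$id)
  r <- sqrt(2)
  expect_equal(unname(f$coef), log(r), tolerance = 1e-7)
  # Breslow quantities at the two event times: risk sets {1,2,3}, {2,3}
  S01 <- r + 2; Zb1 <- r / S01
  S02 <- r + 1; Zb2 <- r / S02
  info <- Zb1 * (1 - Zb1) + Zb2 * (1 - Zb2)
  # per-subject score residuals (event term minus cumulative-hazard term)
  U1 <- (0 - Zb1) - 1 * (1 / S01) * (0 - Zb1)
  U2 <- (1 - Zb2) - r * ((1 / S01) * (1 - Zb1) + (1 / S02) * (1 - Zb2))
  U3 <- -1 * ((1 / S01) * (0 - Zb1) + (1 / S02) * (0 - Zb2))
  vr <- (U1^2 + U2^2 + U3^2) / info^2
  expect_equal(unname(drop(f$var_naive)), 1 / info, tolerance = 1e-7)
  expect_equal(unname(drop(f$var_robust)), vr, tolerance = 1e-7)
})

test_that("engine agrees with survival::coxph on weighted stratified data", {
  skip_if_not_installed("survival")
  library(survival)
  h <- as_gap_time(bladder_recurrences())
  set.seed(42); w <- runif(nrow(h), 0.5, 2)
  mine <- repwp:::.pl_fit(h, terms = c("treatment", "number"), weights = w,
                          stratify = TRUE, cluster = h$id)
  cw <- coxph(Surv(stop, status) ~ treatment + number + strata(k) +
                cluster(id),
              data = as.data.frame(h), weights = w, ties = "breslow")
  expect_equal(unname(mine$coef), unname(coef(cw)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(mine$var_naive))),
               unname(sqrt(diag(cw$naive.var))), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(mine$var_robust))),
               unname(sqrt(diag(cw$var))), tolerance = 1e-7)

  # counting-process (delayed entry) path
  cp <- as_counting_process(h)
  m2 <- repwp:::.pl_fit(cp, stratify = FALSE, cluster = cp$id)
  c2 <- coxph(Surv(start, stop, status) ~ treatment + cluster(id),
              data = as.data.frame(cp), ties = "breslow")
  expect_equal(unname(m2$coef), unname(coef(c2)), tolerance = 1e-8)
  expect_equal(drop(m2$var_robust), drop(c2$var), tolerance = 1e-8)
})

test_that("monotone likelihoods are reported as non-convergence", {
  # all events in one arm, none in the other: beta diverges
  h <- event_history(data.frame(id = 1:6, k = 1, start = 0,
                                stop = c(1, 2, 3, 11, 12, 13),
                                status = c(1, 1, 1, 0, 0, 0),
                                treatment = c(1, 1, 1, 0, 0, 0)))
  expect_error(fit_cox_first_event(h), class = "repwp_no_convergence")
})
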
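test_that("uniform weights are returned when arms are already balanced", {
  U <- cbind(x = c(1, 2, 3, 1, 2, 3))
  sw <- entropy_balance(U, treatment = c(1, 1, 1, 0, 0, 0))
  expect_true(sw$converged)
  expect_equal(sw$weights, rep(1, 6), tolerance = 1e-6)
  expect_equal(sw$divergence, 0, tolerance = 1e-8)
})

test_that("solved weights meet the balance and normalization constraints", {
  # treated x = (1, 3), control x = (0, 2, 4, 6), pooled mean 16/6
  U <- cbind(x = c(1, 3, 0, 2, 4, 6))
  trt <- c(1, 1, 0, 0, 0, 0)
  sw <- entropy_balance(U, trt, tol = 1e-10)
  expect_true(sw$converged)
  expect_true(all(sw$weights > 0))
  expect_equal(sum(sw$weights[trt == 1]), 2, tolerance = 1e-8)
  expect_equal(sum(sw$weights[trt == 0]), 4, tolerance = 1e-8)
  m <- 16 / 6
  expect_equal(weighted.mean(U[trt == 1, 1], sw$weights[trt == 1]), m,
               tolerance = 1e-8)
  expect_equal(weighted.mean(U[trt == 0, 1], sw$weights[trt == 0]), m,
               tolerance = 1e-8)

  # independent convex-solver oracle: same weights, no smaller divergence
  wo <- oracle_entropy_balance(U, trt)
  expect_equal(sw$weights, wo, tolerance = 1e-3)
  expect_lte(sw$divergence, oracle_d1(wo, trt) + 1e-5)
})

test_that("entropy balance matches the convex-solver oracle on random problems", {
  for (s in 1:4) {
    set.seed(100 + s)
    n <- 8
    trt <- rep(c(1, 0), each = 4)
    U <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    sw <- tryCatch(entropy_balance(U, trt), error = function(e) NULL)
    if (is.null(sw)) next  # infeasible draw
    wo <- oracle_entropy_balance(U, trt)
    expect_equal(sw$weights, wo, tolerance = 5e-3)
    expect_lte(sw$divergence, oracle_d1(wo, trt) + 1e-5)
  }
})

test_that("infeasible targets raise a classed error naming the covariate", {
  # treated values (0, 1) cannot average to the pooled mean 8/3
  U <- cbind(z = c(0, 1, 2, 4, 4, 5))
  trt <- c(1, 1, 0, 0, 0, 0)
  err <- tryCatch(entropy_balance(U, trt), error = identity)
  expect_s3_class(err, "repwp_infeasible")
  expect_match(conditionMessage(err), "z")
  expect_error(entropy_balance(cbind(x = 1:4), c(1, 0, 0, 0)),
               "two members per arm")
})

test_that("stabilized IPW matches direct evaluation of the logistic formula", {
  # covariates unrelated to the arm in-sample -> all weights 1
  U <- cbind(x = c(1, 2, 1, 2))
  w <- stabilized_ipw(U, treatment = c(1, 1, 0, 0))
  expect_equal(w, rep(1, 4), tolerance = 1e-6)

  # 6-unit toy vs an independently maximized logistic likelihood
  U <- cbind(x = c(0.2, 1.4, -0.3, 0.9, -1.1, 0.4))
  trt <- c(1, 1, 1, 0, 0, 0)
  nll <- function(b) -sum(trt * (b[1] + b[2] * U[, 1]) -
                          log(1 + exp(b[1] + b[2] * U[, 1])))
  bo <- optim(c(0, 0), nll, method = "BFGS",
              control = list(reltol = 1e-14))$par
  ps <- plogis(bo[1] + bo[2] * U[, 1])
  expected <- ifelse(trt == 1, mean(trt) / ps, (1 - mean(trt)) / (1 - ps))
  expect_equal(stabilized_ipw(U, trt), expected, tolerance = 1e-4)

  expect_error(stabilized_ipw(cbind(x = 1:4), rep(1, 4)), "both treatment arms")
  # perfectly separated covariate -> error advising truncation
  expect_error(
    stabilized_ipw(cbind(x = c(5, 6, 7, -5, -6, -7)), c(1, 1, 1, 0, 0, 0)),
    "separation")
})

test_that("smd follows the pooled-SD convention", {
  expect_equal(smd(c(1, 2, 1, 2), c(1, 1, 0, 0)), 0)
  x <- c(2, 2, 0, 0)
  expect_equal(smd(x, c(1, 1, 0, 0)), 2 / sd(x))
  expect_error(smd(rep(3, 4), c(1, 1, 0, 0)), "zero")
  # after entropy balancing, balanced covariates have |SMD| ~ 0
  U <- cbind(x = c(1, 3, 0, 2, 4, 6))
  trt <- c(1, 1, 0, 0, 0, 0)
  sw <- entropy_balance(U, trt)
  expect_lt(abs(smd(U[, 1], trt, sw$weights)), 1e-7)
})

test_that("eligibility prefix requires two members of each arm per stratum", {
  # subject layout: stratum 3 has a single treated member
  d <- data.frame(
    id = rep(1:6, times = c(3, 3, 2, 2, 1, 1)),
    k = c(1, 2, 3, 1, 2, 3, 1, 2, 1, 2, 1, 1),
    start = 0,
    stop = rep(1, 12) + (1:12) / 100,
    status = c(1, 1, 1, 1, 1, 0, 1, 1, 1, 0, 0, 0),
    treatment = c(rep(1, 3), rep(0, 3), rep(1, 2), rep(0, 2), 1, 0))
  h <- event_history(d)
  # strata: k1 3/3, k2 2/2, k3 1 treated 1 control -> prefix ends at 2
  expect_identical(eligible_strata(h), 2L)
  h1 <- random_history(n = 12, seed = 5, max_k = 2)
  expect_lte(eligible_strata(h1), max_stratum(h1))
  expect_gte(eligible_strata(h1), 1L)
})

test_that("balance_all_strata yields unit weights at k = 1 and balance beyond", {
  h <- simulate_trial(make_scenario(3, n = 300), seed = 21)
  sw <- balance_all_strata(h)
  expect_equal(sw[[1]]$weights, rep(1, n_subjects(h)))
  # every converged stratum: arm sums and |SMD| < 0.1 for all 5 covariates
  for (s in sw[-1]) {
    if (!isTRUE(s$converged)) next
    rows <- which(h$k == s$k)
    trt <- h$treatment[rows]
    expect_equal(sum(s$weights[trt == 1]), s$n_treated, tolerance = 1e-6)
    expect_equal(sum(s$weights[trt == 0]), s$n_control, tolerance = 1e-6)
    for (cv in covariate_names(h)) {
      expect_lt(abs(smd(h[[cv]][rows], trt, s$weights)), 0.1)
    }
  }
  # partly weighted: only the selected columns are constrained
  sw3 <- balance_all_strata(h, covariates = c("x1", "x2", "x3"))
  k_ok <- which(vapply(sw3, function(s) isTRUE(s$converged), logical(1)))
  k_ok <- setdiff(k_ok, 1)
  expect_gt(length(k_ok), 0)
  s <- sw3[[k_ok[1]]]
  rows <- which(h$k == s$k)
  expect_lt(abs(smd(h$x1[rows], h$treatment[rows], s$weights)), 1e-6)
})

test_that("kmax_by_smd truncates at the first unbalanced stratum", {
  h <- simulate_trial(make_scenario(3, n = 300), seed = 33)
  sw <- balance_all_strata(h)
  km <- kmax_by_smd(h, sw)
  expect_gte(km, 2L)
  expect_lte(km, length(sw) + 1L)
  # all strata below k_max are balanced, k_max itself (if attempted) is not
  if (km <= length(sw)) {
    expect_false(isTRUE(sw[[km]]$converged) &&
                 all(vapply(covariate_names(h), function(cv) {
                   rows <- which(h$k == km)
                   abs(smd(h[[cv]][rows], h$treatment[rows],
                           sw[[km]]$weights)) < 0.1
                 }, logical(1))))
  }
  # a fabricated failed stratum forces k_max there
  sw[[3]]$converged <- FALSE
  expect_identical(kmax_by_smd(h, sw), 3L)
})
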
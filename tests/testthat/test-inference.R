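test_that("per-record curvature correction matches hand arithmetic", {
  # delta = d eta / d pi at X=10, Y=5, pi=0.5, p0=0.003, p1=0.9
  sim <- small_fit_cache()
  fit <- sim$fit
  info <- louis_information(fit)
  expect_true(all(info$delta >= 0))
  d_hand <- 5 * 0.9 * 0.003 / (0.9 * 0.5 + 0.003 * 0.5)^2 +
    5 * 0.1 * 0.997 / (0.1 * 0.5 + 0.997 * 0.5)^2
  expect_equal(d_hand, 1.72319, tolerance = 1e-5)
  # same arithmetic through the package path: build a one-record fit state
  fake <- fit
  fake$Y <- 5; fake$depth <- 10; fake$pi <- 0.5
  fake$design$X <- matrix(1, 1, length(fit$alpha))
  expect_equal(suppressWarnings(louis_information(fake))$delta, d_hand,
               tolerance = 1e-12)
})

test_that("error-free information reduces to the penalized binomial form", {
  sim <- simulate_scenario1(15, seed = 27, n_cpg = 30,
                            err = error_rates(0, 1))
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0, 1))
  info <- louis_information(fit)
  expect_equal(max(abs(info$delta)), 0)
  X <- fit$design$X
  W <- fit$depth * fit$pi * (1 - fit$pi)
  S_lam <- methsmooth:::penalty_blockdiag(fit$lambda, fit$A_list,
                                          fit$design$idx)
  expect_equal(info$negH, crossprod(X * sqrt(W)) + S_lam,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("observed information matches the finite-difference Hessian", {
  cache <- small_fit_cache()
  fit <- cache$fit
  S_lam <- methsmooth:::penalty_blockdiag(fit$lambda, fit$A_list,
                                          fit$design$idx)
  f <- function(a) methsmooth:::observed_loglik(a, fit$design$X, fit$Y,
                                                fit$depth, S_lam,
                                                fit$err$p0, fit$err$p1)
  Hfd <- fd_hessian(f, fit$alpha)
  negH <- louis_information(fit)$negH
  expect_lt(max(abs(negH - (-Hfd))) / max(abs(negH)), 1e-3)
})

test_that("pointwise bands are symmetric normal-theory intervals", {
  fit <- small_fit_cache()$fit
  ci <- pointwise_ci(fit, 1, level = 0.95)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  expect_equal(ci$upper - ci$estimate, 1.959964 * ci$se, tolerance = 1e-6)
  ci90 <- pointwise_ci(fit, 1, level = 0.90)
  expect_true(all(ci90$upper - ci90$lower <= ci$upper - ci$lower + 1e-12))
  expect_error(pointwise_ci(fit, 7), "0..3")
})

test_that("EDF equals the basis rank at lambda zero and shrinks with lambda", {
  sim <- simulate_scenario1(15, seed = 29, n_cpg = 30,
                            err = error_rates(0, 1))
  fit0 <- em_fit(sim$counts, sim$covariates, error_rates(0, 1),
                 lambda = rep(0, 4))
  for (p in 0:3) expect_equal(edf(fit0, p), 5, tolerance = 1e-8)
  expect_lte(sum(fit0$edf), length(fit0$alpha) + 1e-8)
  # monotone non-increasing along an increasing lambda_1 grid (away from
  # the near-unpenalized regime, where cross-block terms can perturb it)
  taus <- vapply(10^seq(-1, 6, by = 1), function(l1)
    edf(fit0, 1, lambda = c(0.1, l1, 0.1, 0.1)), 0)
  expect_true(all(diff(taus) <= 1e-8))
  expect_lt(taus[length(taus)], 2.1)  # penalty null space has dimension 2
})

test_that("regional Wald test matches classic GLM inference when unpenalized", {
  sim <- simulate_scenario1(40, seed = 37, n_cpg = 30,
                            err = error_rates(0, 1))
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0, 1),
                lambda = rep(0, 4))
  tst <- regional_test(fit)
  expect_equal(tst$edf, rep(5, 3), tolerance = 1e-8)
  glm_fit <- stats::glm(cbind(fit$Y, fit$depth - fit$Y) ~ fit$design$X - 1,
                        family = stats::binomial())
  Vg <- stats::vcov(glm_fit)
  for (p in 1:3) {
    blk <- fit$design$idx[[p + 1]]
    Tg <- drop(coef(glm_fit)[blk] %*%
                 solve(Vg[blk, blk], coef(glm_fit)[blk]))
    expect_equal(tst$statistic[p], Tg, tolerance = 1e-4)
  }
})

test_that("regional test output is well-formed", {
  fit <- small_fit_cache()$fit
  tst <- regional_test(fit)
  expect_equal(nrow(tst), 3L)
  expect_true(all(tst$statistic >= 0))
  expect_true(all(tst$p_value > 0 & tst$p_value <= 1))
  expect_true(all(tst$edf > 0 & tst$edf <= 5))
  joint <- regional_test(fit, list(c(1, 2)))
  expect_equal(nrow(joint), 1L)
  expect_gt(joint$statistic, 0)
  expect_equal(joint$edf, sum(tst$edf[1:2]), tolerance = 1e-10)
})
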
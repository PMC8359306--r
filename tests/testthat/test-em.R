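test_that("E-step reduces to the observed counts without errors", {
  Y <- c(0, 3, 10); X <- c(5, 10, 10)
  eta <- e_step(Y, X, pi = c(0.2, 0.5, 0.9), err = error_rates(0, 1))
  expect_identical(eta, Y)
})

test_that("E-step matches hand-computed expected counts", {
  eta <- e_step(5, 10, pi = 0.5, err = error_rates(0.003, 0.9))
  expect_equal(eta, 5 * 0.45 / 0.4515 + 5 * 0.05 / 0.5485, tolerance = 1e-12)
  expect_equal(eta, 5.43918, tolerance = 1e-5)
})

test_that("E-step stays inside [0, depth] even at Y = 0 or Y = X", {
  err <- error_rates(0.003, 0.9)
  set.seed(8)
  for (i in 1:50) {
    X <- sample(1:40, 1); Y <- sample(0:X, 1); p <- runif(1, 0.01, 0.99)
    eta <- e_step(Y, X, p, err)
    expect_gte(eta, 0); expect_lte(eta, X)
  }
  expect_gt(e_step(0, 10, 0.5, err), 0)
  expect_lt(e_step(0, 10, 0.5, err), 10)
})

test_that("unpenalized intercept P-IRLS recovers the pooled-proportion MLE", {
  # 100 trials with 30 pooled successes: alpha-hat = logit(30/100)
  X <- matrix(1, 10, 1)
  a <- pirls(eta = rep(3, 10), depth = rep(10, 10), X = X,
             S_lam = matrix(0, 1, 1))
  expect_equal(as.numeric(a), stats::qlogis(0.3), tolerance = 1e-7)
  expect_equal(as.numeric(a), -0.84730, tolerance = 1e-5)
  expect_true(attr(a, "converged"))
})

test_that("P-IRLS returns a stationary point of the penalized likelihood", {
  cache <- small_fit_cache()
  fit <- cache$fit
  X <- fit$design$X
  S_lam <- methsmooth:::penalty_blockdiag(fit$lambda, fit$A_list,
                                          fit$design$idx)
  a <- pirls(fit$eta, fit$depth, X, S_lam, alpha0 = fit$alpha)
  g <- attr(a, "gradient")
  expect_lt(max(abs(g)), 1e-8 * (1 + sum(fit$depth)))
})

test_that("a huge penalty shrinks the effect curve to a straight line", {
  sim <- simulate_scenario1(30, seed = 21, n_cpg = 50,
                            err = error_rates(0, 1))
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0, 1),
                lambda = c(0.01, 1e9, 0.01, 0.01))
  grid <- seq(fit$view$region[1], fit$view$region[2], length.out = 80)
  blk <- fit$design$idx[[2]]
  curve <- drop(eval_basis(fit$design$bases[[2]], grid) %*% fit$alpha[blk])
  resid <- stats::residuals(stats::lm(curve ~ grid))
  expect_lt(max(abs(resid)), 1e-4 * (1 + max(abs(curve))))
})

test_that("fixed-lambda mode bypasses smoothing-parameter selection", {
  sim <- simulate_scenario1(15, seed = 9, n_cpg = 30)
  lam <- c(0.5, 1, 2, 4)
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0.003, 0.9),
                lambda = lam)
  expect_identical(fit$lambda, lam)
})

test_that("selected lambda attains the restricted-likelihood grid maximum", {
  # curved intercept-only working fit: interior optimum
  sim <- simulate_scenario1(40, seed = 13, n_cpg = 60,
                            err = error_rates(0, 1))
  ds <- sim$counts
  cv <- meth_covariates(data.frame(sample_id = unique(ds$sample_id)))
  v <- align_region(ds, cv)
  d <- assemble_design(v, build_basis(v$positions, 8, v$region))
  A_list <- lapply(d$bases, penalty_matrix)
  Y <- v$data$meth; depth <- v$data$total
  opt <- optimize_lambda(Y, depth, d$X, A_list, d$idx, lambda0 = 1)
  expect_true(opt$converged)
  step <- 10^0.25
  grid <- opt$lambda * step^seq(-6, 6)
  vals <- vapply(grid, function(l)
    as.numeric(laml_score(l, Y, depth, d$X, A_list, d$idx)), 0)
  v_hat <- as.numeric(laml_score(opt$lambda, Y, depth, d$X, A_list, d$idx))
  expect_lte(max(vals) - v_hat, 0.01)           # value-optimal
  expect_lte(abs(which.max(vals) - 7), 1)       # within one grid step
})

test_that("a linear covariate effect is smoothed to ~2 degrees of freedom", {
  cfg <- sim_control(
    n_samples = 300, seed = 31, err = error_rates(0, 1), n_cpg = 80,
    covariates = list(list(name = "Zlin", q = 0.5,
                           shape = sim_shape("linear", a = -0.5, b = 1.2))))
  sim <- simulate_region(cfg)
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0, 1))
  expect_lt(fit$edf[2], 2.5)
})

test_that("error-free EM equals the one-shot penalized binomial fit", {
  sim <- simulate_scenario1(15, seed = 17, n_cpg = 30,
                            err = error_rates(0, 1))
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0, 1))
  expect_equal(fit$iterations, 0L)
  v <- align_region(sim$counts, sim$covariates)
  d <- assemble_design(v, build_basis(v$positions, 5, v$region))
  A_list <- lapply(d$bases, penalty_matrix)
  direct <- optimize_lambda(v$data$meth, v$data$total, d$X, A_list, d$idx,
                            lambda0 = rep(1, 4))
  expect_lt(max(abs(fit$alpha - direct$alpha)), 1e-8)
})

test_that("EM ascends the penalized observed-data likelihood at fixed lambda", {
  sim <- simulate_scenario1(20, seed = 19, n_cpg = 40)
  fit <- em_fit(sim$counts, sim$covariates, error_rates(0.003, 0.9),
                lambda = c(0.1, 0.5, 1, 5))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  expect_true(fit$converged)
})

test_that("fits are deterministic", {
  sim <- simulate_scenario1(15, seed = 23, n_cpg = 30)
  f1 <- em_fit(sim$counts, sim$covariates, error_rates(0.003, 0.9))
  f2 <- em_fit(sim$counts, sim$covariates, error_rates(0.003, 0.9))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$lambda, f2$lambda)
})
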
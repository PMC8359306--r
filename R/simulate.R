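#' Analytic effect-curve shapes on the unit interval
#'
#' Shape library for simulation truth curves, parameterized on the
#' rescaled region coordinate `u = (t - lo) / (hi - lo)`. Supported types:
#' `"zero"`, `"constant"` (`a`), `"linear"` (`a + b u`), `"bump"`
#' (`a + h exp(-(u - c)^2 / (2 s^2))`) and `"two_bumps"` (sum of two
#' Gaussian bumps on a constant baseline). All values are on the logit
#' scale of the methylation proportion.
#'
#' @param type Shape type (see above).
#' @param a Baseline (constant/linear/bump families).
#' @param b Slope (linear).
#' @param h,c,s Bump height(s), center(s), width(s); vectors of length 2
#'   for `"two_bumps"`.
#' @return A function of `u` in `[0, 1]`.
#' @export
sim_shape <- function(type = c("zero", "constant", "linear", "bump",
                               "two_bumps"),
                      a = 0, b = 0, h = 1, c = 0.5, s = 0.15) {
  type <- match.arg(type)
  force(a); force(b); force(h); force(c); force(s)
  switch(type,
    zero     = function(u) rep(0, length(u)),
    constant = function(u) rep(a, length(u)),
    linear   = function(u) a + b * u,
    bump     = function(u) a + h[1] * exp(-(u - c[1])^2 / (2 * s[1]^2)),
    two_bumps = function(u)
      a + h[1] * exp(-(u - c[1])^2 / (2 * s[1]^2)) +
          h[2] * exp(-(u - c[2])^2 / (2 * s[2]^2))
  )
}

#' Simulation configuration for one targeted region
#'
#' Defaults emulate a targeted-capture region: 123 CpG sites spread over
#' ~3 kb with log-normal spacing, read depths from a truncated
#' negative-binomial surrogate (mean 30, dispersion 3), binary covariates,
#' and smooth logit-scale effect curves. Truth curves are the projection of
#' the analytic shapes onto the rank-`L_truth` cubic B-spline space on the
#' simulated CpG grid, so the estimand lies in the model's function class
#' (mirroring truth curves obtained as spline fits to real data).
#'
#' @param n_samples Number of samples N.
#' @param seed Integer seed (mandatory: every draw flows through it).
#' @param intercept Shape function (from [sim_shape()]) for the baseline
#'   logit methylation curve.
#' @param covariates List of covariate specs: each a list with `name`,
#'   `q` (Bernoulli proportion) and `shape` (effect curve function).
#' @param err An [error_rates()] object used for the observation channel.
#' @param n_cpg Number of CpG sites (ignored when `positions` given).
#' @param region_length Region span in bp (ignored when `positions` given).
#' @param positions Optional explicit integer positions.
#' @param depth Depth source: `list(type = "nb", mean, dispersion)` for the
#'   negative-binomial surrogate truncated at >= 1, or
#'   `list(type = "pool", values)` to resample an empirical depth pool.
#' @param L_truth Spline rank of the truth-curve space.
#' @return A `sim_control` list.
#' @export
sim_control <- function(n_samples, seed,
                        intercept = sim_shape("two_bumps", a = 0.5,
                                              h = c(1.5, -1.0),
                                              c = c(0.3, 0.75),
                                              s = c(0.12, 0.10)),
                        covariates = list(),
                        err = error_rates(0.003, 0.9),
                        n_cpg = 123L, region_length = 3000L,
                        positions = NULL,
                        depth = list(type = "nb", mean = 30, dispersion = 3),
                        L_truth = 5L) {
  stopifnot(n_samples >= 2, !missing(seed), is.numeric(seed))
  for (cv in covariates)
    stopifnot(is.character(cv$name), cv$q > 0, cv$q < 1,
              is.function(cv$shape))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 intercept = intercept, covariates = covariates, err = err,
                 n_cpg = as.integer(n_cpg),
                 region_length = as.integer(region_length),
                 positions = positions, depth = depth,
                 L_truth = as.integer(L_truth)),
            class = "sim_control")
}

#' Draw read depths
#'
#' Either resamples (with replacement) an empirical depth pool, or draws
#' from a negative-binomial surrogate truncated at one read (a site with no
#' reads is simply missing, so simulated records keep depth >= 1).
#'
#' @param depth Depth source spec (see [sim_control()]).
#' @param n_sites,n_samples Grid dimensions.
#' @return Integer matrix `n_samples x n_sites` of read depths.
#' @export
sample_depths <- function(depth, n_sites, n_samples) {
  n <- n_sites * n_samples
  x <- switch(depth$type,
    pool = {
      if (length(depth$values) == 0) stop("empty depth pool")
      depth$values[sample.int(length(depth$values), n, replace = TRUE)]
    },
    nb = {
      d <- stats::rnbinom(n, mu = depth$mean, size = depth$dispersion)
      zero <- d == 0
      while (any(zero)) {   # truncate at >= 1 by redrawing
        d[zero] <- stats::rnbinom(sum(zero), mu = depth$mean,
                                  size = depth$dispersion)
        zero <- d == 0
      }
      d
    },
    stop("unknown depth source type: ", depth$type))
  matrix(as.integer(x), n_samples, n_sites)
}

#' Push true methylated counts through the observation error channel
#'
#' `Y = Binomial(S, p1) + Binomial(X - S, p0)`: every truly methylated read
#' is called methylated with probability `p1`, every truly unmethylated
#' read is falsely called methylated with probability `p0`.
#'
#' @param S True methylated counts.
#' @param depth Total read counts (elementwise `>= S`).
#' @param err An [error_rates()] object.
#' @return Observed methylated counts, same shape as `S`.
#' @export
apply_error_channel <- function(S, depth, err) {
  stopifnot(all(S <= depth), all(S >= 0))
  out <- stats::rbinom(length(S), S, err$p1) +
    stats::rbinom(length(S), as.vector(depth) - as.vector(S), err$p0)
  if (is.matrix(S)) out <- matrix(out, nrow(S), ncol(S))
  out
}

# CpG positions with log-normal gap spacing scaled to the region length
sim_positions <- function(n_cpg, region_length) {
  gaps <- stats::rlnorm(n_cpg - 1L, meanlog = 0, sdlog = 0.7)
  cum <- c(0, cumsum(gaps))
  pos <- 1L + as.integer(round(cum / max(cum) * (region_length - 1L)))
  pos <- unique(pos)
  while (length(pos) < n_cpg) {   # collisions after rounding: fill gaps
    cand <- setdiff(seq_len(region_length), pos)
    pos <- sort(c(pos, sample(cand, n_cpg - length(pos))))
  }
  sort(pos)
}

#' Simulate one region from the binomial varying-coefficient model
#'
#' Draws covariates, builds spline-space truth curves, samples true
#' methylated counts `S ~ Binomial(X, pi)` with
#' `logit(pi) = beta_0(t) + sum_p beta_p(t) Z_p`, then pushes them through
#' the error channel.
#'
#' @param cfg A [sim_control()] configuration.
#' @return A `meth_sim` list: `counts` (`meth_counts`), `covariates`
#'   (`meth_covariates`), and `truth` (positions, per-term `beta` matrix,
#'   `pi` and `S` matrices, config echo).
#' @export
simulate_region <- function(cfg) {
  stopifnot(inherits(cfg, "sim_control"))
  set.seed(cfg$seed)
  pos <- if (!is.null(cfg$positions)) sort(unique(as.integer(cfg$positions)))
         else sim_positions(cfg$n_cpg, cfg$region_length)
  n_cpg <- length(pos)
  N <- cfg$n_samples
  u <- (pos - min(pos)) / (max(pos) - min(pos))
  basis <- build_basis(pos, cfg$L_truth, range(pos))
  B <- eval_basis(basis, pos)
  project <- function(f) {
    y <- f(u)
    if (all(y == 0)) return(rep(0, n_cpg))   # exact null stays exact
    drop(B %*% solve(crossprod(B), crossprod(B, y)))
  }
  P <- length(cfg$covariates)
  beta <- matrix(0, n_cpg, P + 1L)
  colnames(beta) <- c("(Intercept)",
                      vapply(cfg$covariates, `[[`, "", "name"))
  beta[, 1] <- project(cfg$intercept)
  Z <- matrix(0, N, P)
  colnames(Z) <- colnames(beta)[-1]
  for (p in seq_len(P)) {
    Z[, p] <- stats::rbinom(N, 1, cfg$covariates[[p]]$q)
    beta[, p + 1] <- project(cfg$covariates[[p]]$shape)
  }
  depth <- sample_depths(cfg$depth, n_cpg, N)
  lp <- matrix(beta[, 1], N, n_cpg, byrow = TRUE)
  for (p in seq_len(P)) lp <- lp + Z[, p] %o% beta[, p + 1]
  pi_true <- stats::plogis(lp)
  S <- matrix(stats::rbinom(N * n_cpg, depth, pi_true), N, n_cpg)
  Y <- apply_error_channel(S, depth, cfg$err)
  sample_ids <- sprintf("s%03d", seq_len(N))
  counts <- meth_counts(data.frame(
    sample_id = rep(sample_ids, each = n_cpg),
    position = rep(pos, N),
    total = as.vector(t(depth)),
    meth = as.vector(t(Y)),
    stringsAsFactors = FALSE))
  covs <- meth_covariates(data.frame(sample_id = sample_ids,
                                     as.data.frame(Z),
                                     stringsAsFactors = FALSE))
  structure(list(counts = counts, covariates = covs,
                 truth = list(positions = pos, beta = beta, pi = pi_true,
                              S = S, depth = depth, config = cfg)),
            class = "meth_sim")
}

#' Multi-covariate simulation scenario
#'
#' Three independent binary covariates: `Z1 ~ Bernoulli(0.51)` with a
#' nonlinear (single-bump) effect, `Z2 ~ Bernoulli(0.58)` with a linear
#' effect, and `Z3 ~ Bernoulli(0.5)` with zero effect everywhere, over a
#' nonlinear baseline curve. The null covariate `Z3` carries the type-I
#' error information.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param err Observation error rates (default `error_rates(0.003, 0.9)`).
#' @param ... Further arguments passed to [sim_control()].
#' @return A `meth_sim` object with `truth$beta[, "Z3"]` identically zero.
#' @export
simulate_scenario1 <- function(n_samples, seed,
                               err = error_rates(0.003, 0.9), ...) {
  cfg <- sim_control(
    n_samples = n_samples, seed = seed, err = err,
    covariates = list(
      list(name = "Z1", q = 0.51,
           shape = sim_shape("bump", a = -0.2, h = 0.6, c = 0.5, s = 0.15)),
      list(name = "Z2", q = 0.58,
           shape = sim_shape("linear", a = -0.4, b = 1.0)),
      list(name = "Z3", q = 0.5, shape = sim_shape("zero"))),
    ...)
  simulate_region(cfg)
}

#' Single-covariate power scenario
#'
#' One binary covariate `Z ~ Bernoulli(0.5)`. The methylation proportion
#' curve of the `Z = 1` group is fixed; the `Z = 0` curve equals it minus a
#' Gaussian-bump deviation on the probability scale, scaled so the maximum
#' difference over the central subregion (rescaled coordinate 0.35-0.65)
#' equals `max_deviation` exactly on the simulated CpG grid.
#' `max_deviation = 0` gives a global null. Power studies typically sweep
#' a 14-level grid `seq(0, 0.13, by = 0.01)`.
#'
#' @param n_samples Number of samples.
#' @param max_deviation Maximum probability-scale group difference, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @param err Observation error rates.
#' @param ... Further arguments passed to [sim_control()].
#' @return A `meth_sim` object; `truth$max_deviation` records the achieved
#'   maximum deviation.
#' @export
simulate_scenario2 <- function(n_samples, max_deviation, seed,
                               err = error_rates(0.003, 0.9), ...) {
  stopifnot(max_deviation >= 0, max_deviation < 1)
  cfg <- sim_control(n_samples = n_samples, seed = seed, err = err,
                     covariates = list(
                       list(name = "Z", q = 0.5, shape = sim_shape("zero"))),
                     ...)
  set.seed(cfg$seed)
  pos <- if (!is.null(cfg$positions)) sort(unique(as.integer(cfg$positions)))
         else sim_positions(cfg$n_cpg, cfg$region_length)
  u <- (pos - min(pos)) / (max(pos) - min(pos))
  basis <- build_basis(pos, cfg$L_truth, range(pos))
  B <- eval_basis(basis, pos)
  base_curve <- drop(B %*% solve(crossprod(B),
                                 crossprod(B, cfg$intercept(u))))
  pi1 <- stats::plogis(base_curve)
  bump <- exp(-(u - 0.5)^2 / (2 * 0.08^2))
  sub <- u >= 0.35 & u <= 0.65
  dev <- max_deviation * bump / max(bump[sub])
  pi0 <- pi1 - dev
  if (any(pi0 <= 0 | pi0 >= 1))
    stop("max_deviation = ", max_deviation,
         " pushes the control-group curve outside (0, 1)")
  beta0 <- stats::qlogis(pi0)
  beta1 <- stats::qlogis(pi1) - stats::qlogis(pi0)
  N <- cfg$n_samples
  Z <- stats::rbinom(N, 1, 0.5)
  depth <- sample_depths(cfg$depth, length(pos), N)
  pi_true <- stats::plogis(outer(rep(1, N), beta0) + Z %o% beta1)
  S <- matrix(stats::rbinom(N * length(pos), depth, pi_true), N, length(pos))
  Y <- apply_error_channel(S, depth, cfg$err)
  sample_ids <- sprintf("s%03d", seq_len(N))
  counts <- meth_counts(data.frame(
    sample_id = rep(sample_ids, each = length(pos)),
    position = rep(pos, N),
    total = as.vector(t(depth)), meth = as.vector(t(Y)),
    stringsAsFactors = FALSE))
  covs <- meth_covariates(data.frame(sample_id = sample_ids, Z = Z,
                                     stringsAsFactors = FALSE))
  beta <- cbind("(Intercept)" = beta0, Z = beta1)
  structure(list(counts = counts, covariates = covs,
                 truth = list(positions = pos, beta = beta, pi = pi_true,
                              S = S, depth = depth, config = cfg,
                              pi0 = pi0, pi1 = pi1,
                              max_deviation = max(abs(pi1 - pi0)[sub]))),
            class = "meth_sim")
}

#' Write a simulated region to disk
#'
#' Emits the counts and covariates TSVs (the fitting dialect) plus a truth
#' JSON holding the CpG positions, the spline-space truth curves and the
#' simulation seed, enabling benchmarking by other tools.
#'
#' @param sim A `meth_sim` object.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_counts <- file.path(dir, paste0(prefix, "_counts.tsv"))
  f_covs <- file.path(dir, paste0(prefix, "_covariates.tsv"))
  f_truth <- file.path(dir, paste0(prefix, "_truth.json"))
  write_counts(sim$counts, f_counts)
  cv <- as.data.frame(sim$covariates)
  names(cv)[names(cv) == "sample_id"] <- "SampleID"
  utils::write.table(cv, f_covs, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(positions = sim$truth$positions,
                beta = as.data.frame(sim$truth$beta),
                seed = sim$truth$config$seed,
                error_rates = list(p0 = sim$truth$config$err$p0,
                                   p1 = sim$truth$config$err$p1))
  if (!is.null(sim$truth$max_deviation))
    truth$max_deviation <- sim$truth$max_deviation
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(counts = f_counts, covariates = f_covs, truth = f_truth))
}
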
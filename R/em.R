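#' Fitting configuration
#'
#' Tolerances and iteration limits for the smoothed EM fit. The EM stops when
#' the relative change of the penalized observed-data log-likelihood falls
#' below `em_tol`. The inner P-IRLS solver stops at a gradient norm below
#' `pirls_tol` (by default scaled to the total read count, the natural scale
#' of the score). Smoothing parameters are re-optimized every
#' `lambda_every` EM iterations.
#'
#' @param em_tol Relative EM convergence tolerance (> 0).
#' @param em_maxit Maximum EM iterations.
#' @param pirls_tol Absolute P-IRLS gradient tolerance; `NULL` means
#'   `1e-9 * (1 + sum(total reads))`.
#' @param pirls_maxit Maximum P-IRLS iterations.
#' @param lambda_every Update smoothing parameters every k-th EM iteration.
#' @param fs_tol Convergence tolerance for the smoothing-parameter update
#'   (max absolute change of the log fixed-point map).
#' @param fs_maxit Maximum smoothing-parameter iterations per M-step.
#' @param lambda_bounds Lower/upper clamps for each smoothing parameter.
#' @param clip Probability clipping bound for fitted proportions, in
#'   `(0, 0.5)`.
#' @return A `fit_control` list.
#' @export
fit_control <- function(em_tol = 1e-6, em_maxit = 200L,
                        pirls_tol = NULL, pirls_maxit = 100L,
                        lambda_every = 1L,
                        fs_tol = 1e-3, fs_maxit = 100L,
                        lambda_bounds = c(1e-8, 1e8),
                        clip = 1e-6) {
  stopifnot(em_tol > 0, em_maxit >= 1, is.null(pirls_tol) || pirls_tol > 0,
            fs_tol > 0, clip > 0, clip < 0.5,
            length(lambda_bounds) == 2, lambda_bounds[1] > 0,
            lambda_bounds[1] < lambda_bounds[2])
  structure(list(em_tol = em_tol, em_maxit = as.integer(em_maxit),
                 pirls_tol = pirls_tol, pirls_maxit = as.integer(pirls_maxit),
                 lambda_every = as.integer(lambda_every),
                 fs_tol = fs_tol, fs_maxit = as.integer(fs_maxit),
                 lambda_bounds = lambda_bounds, clip = clip),
            class = "fit_control")
}

clip_prob <- function(p, clip) pmin(pmax(p, clip), 1 - clip)

# block-diagonal penalty Diag{lambda_0 A_0, ..., lambda_P A_P}
penalty_blockdiag <- function(lambda, A_list, idx) {
  K <- max(unlist(idx))
  S <- matrix(0, K, K)
  for (p in seq_along(A_list))
    S[idx[[p]], idx[[p]]] <- lambda[p] * A_list[[p]]
  S
}

# rank and positive log-determinant of each penalty block
penalty_spectrum <- function(A_list) {
  ranks <- numeric(length(A_list)); ldet <- numeric(length(A_list))
  for (p in seq_along(A_list)) {
    ev <- eigen(A_list[[p]], symmetric = TRUE, only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-10
    ranks[p] <- sum(pos)
    ldet[p] <- sum(log(ev[pos]))
  }
  list(ranks = ranks, ldet = ldet)
}

# complete-data penalized log-likelihood with expected counts eta
penalized_loglik <- function(alpha, X, eta, depth, S_lam, clip = 1e-6) {
  p <- clip_prob(stats::plogis(drop(X %*% alpha)), clip)
  sum(eta * log(p) + (depth - eta) * log(1 - p)) -
    0.5 * sum(alpha * (S_lam %*% alpha))
}

# observed-data penalized log-likelihood under the marginal mixture
# Y | X ~ Binomial(X, p0 + (p1 - p0) pi)
observed_loglik <- function(alpha, X, Y, depth, S_lam, p0, p1, clip = 1e-6) {
  p <- clip_prob(stats::plogis(drop(X %*% alpha)), clip)
  q <- p0 + (p1 - p0) * p
  sum(Y * log(q) + (depth - Y) * log(1 - q)) -
    0.5 * sum(alpha * (S_lam %*% alpha))
}

#' E-step: expected true methylated counts given observed counts
#'
#' For each record, the conditional expectation of the true methylated count
#' given the observed count under the two-binomial error channel:
#' each observed-methylated read is truly methylated with probability
#' `p1 pi / (p1 pi + p0 (1 - pi))`, each observed-unmethylated read with
#' probability `(1 - p1) pi / ((1 - p1) pi + (1 - p0)(1 - pi))`.
#'
#' @param Y Observed methylated counts.
#' @param depth Total read counts.
#' @param pi Current fitted methylation proportions (strictly inside (0,1)).
#' @param err An [error_rates()] object.
#' @return Vector of expected true methylated counts, elementwise in
#'   `[0, depth]`.
#' @export
e_step <- function(Y, depth, pi, err) {
  p0 <- err$p0; p1 <- err$p1
  Y * ((p1 * pi) / (p1 * pi + p0 * (1 - pi))) +
    (depth - Y) * (((1 - p1) * pi) / ((1 - p1) * pi + (1 - p0) * (1 - pi)))
}

#' Penalized IRLS for the working binomial likelihood
#'
#' Maximizes `l(eta; alpha) - alpha' A_lambda alpha / 2`, where `l` is the
#' binomial log-likelihood with (possibly fractional) methylated counts
#' `eta` and depths `depth`, by Fisher scoring with step halving.
#'
#' @param eta Working methylated counts (from [e_step()], or raw counts).
#' @param depth Total read counts.
#' @param X Design matrix (M x K).
#' @param S_lam K x K penalty matrix (PSD).
#' @param alpha0 Starting coefficient vector.
#' @param control A [fit_control()] list.
#' @return Coefficient vector with attributes `converged` (logical),
#'   `iterations`, and `gradient` (score at return).
#' @export
pirls <- function(eta, depth, X, S_lam, alpha0 = rep(0, ncol(X)),
                  control = fit_control()) {
  tol <- if (is.null(control$pirls_tol)) 1e-9 * (1 + sum(depth)) else control$pirls_tol
  clip <- control$clip
  alpha <- alpha0
  f <- penalized_loglik(alpha, X, eta, depth, S_lam, clip)
  conv <- FALSE
  grad <- rep(NA_real_, length(alpha))
  for (it in seq_len(control$pirls_maxit)) {
    p <- clip_prob(stats::plogis(drop(X %*% alpha)), clip)
    grad <- drop(crossprod(X, eta - depth * p)) - drop(S_lam %*% alpha)
    if (max(abs(grad)) < tol) { conv <- TRUE; break }
    w <- depth * p * (1 - p)
    H <- crossprod(X * sqrt(w)) + S_lam
    R <- tryCatch(chol(H), error = function(e)
      chol(H + diag(1e-8 * max(diag(H)), ncol(H))))
    step <- backsolve(R, forwardsolve(t(R), grad))
    if (max(abs(alpha + step)) > 1e4)        # diverging coefficients:
      step <- step * 1e4 / max(abs(alpha + step))  # likely separation
    f_new <- -Inf
    for (h in 0:30) {
      alpha_new <- alpha + step / 2^h
      f_new <- penalized_loglik(alpha_new, X, eta, depth, S_lam, clip)
      if (f_new >= f - 1e-10) break
    }
    no_gain <- f_new < f + 1e-11 * (abs(f) + 1)
    alpha <- alpha_new; f <- f_new
    if (no_gain) { conv <- TRUE; break }
  }
  if (max(abs(alpha)) >= 1e4) conv <- FALSE   # flag, do not error
  attr(alpha, "converged") <- conv
  attr(alpha, "iterations") <- it
  attr(alpha, "gradient") <- grad
  alpha
}

#' Laplace-approximate restricted likelihood (LAML) of the working model
#'
#' The criterion maximized over the smoothing parameters: the penalized
#' working log-likelihood at its maximizer `alpha_lambda`, plus half the
#' positive log-determinant of the penalty, minus half the log-determinant
#' of the penalized Fisher information (additive constants dropped).
#'
#' @inheritParams pirls
#' @param lambda Vector of smoothing parameters, one per smooth term.
#' @param A_list List of per-term penalty matrices.
#' @param idx List of column-index vectors per term.
#' @return Scalar criterion value, with attribute `alpha` (the inner
#'   maximizer).
#' @export
laml_score <- function(lambda, eta, depth, X, A_list, idx,
                       alpha0 = rep(0, ncol(X)), control = fit_control()) {
  spec <- penalty_spectrum(A_list)
  S_lam <- penalty_blockdiag(lambda, A_list, idx)
  alpha <- pirls(eta, depth, X, S_lam, alpha0, control)
  p <- clip_prob(stats::plogis(drop(X %*% alpha)), control$clip)
  w <- depth * p * (1 - p)
  H <- crossprod(X * sqrt(w)) + S_lam
  ldetH <- 2 * sum(log(diag(chol(H))))
  ldetS <- sum(spec$ranks * log(lambda)) + sum(spec$ldet)
  v <- penalized_loglik(alpha, X, eta, depth, S_lam, control$clip) +
    0.5 * ldetS - 0.5 * ldetH
  attr(v, "alpha") <- alpha
  v
}

#' Select smoothing parameters by restricted-likelihood maximization
#'
#' Maximizes [laml_score()] over the smoothing parameters by the generalized
#' Fellner-Schall fixed-point update
#' `lambda_p <- rank(A_p) / (alpha_p' A_p alpha_p + tr(H^-1 A_p))`,
#' iterated jointly with the inner P-IRLS fit. Updates are taken on the log
#' scale with per-coordinate step acceleration (doubling while the update
#' direction persists) and an ascent safeguard that retreats and retries
#' unaccelerated whenever the criterion drops. Parameters are clamped to
#' `control$lambda_bounds`; a boundary solution means the term is fully
#' shrunk to (or released from) the penalty null space.
#'
#' @inheritParams laml_score
#' @param lambda0 Starting values (> 0), one per smooth term.
#' @return List with `lambda`, `alpha` (inner fit at the returned lambda),
#'   `laml` (criterion value), `iterations`, `converged`.
#' @export
optimize_lambda <- function(eta, depth, X, A_list, idx, lambda0,
                            alpha0 = rep(0, ncol(X)),
                            control = fit_control()) {
  stopifnot(all(lambda0 > 0), length(lambda0) == length(A_list))
  spec <- penalty_spectrum(A_list)
  lam_lo <- control$lambda_bounds[1]; lam_hi <- control$lambda_bounds[2]
  lambda <- pmin(pmax(lambda0, lam_lo), lam_hi)
  alpha <- alpha0
  accel <- rep(1, length(lambda))
  dir_prev <- rep(0, length(lambda))
  V_prev <- -Inf
  lambda_prev <- lambda; alpha_prev <- alpha
  conv <- FALSE
  laml_at <- function(lambda, alpha) {
    S_lam <- penalty_blockdiag(lambda, A_list, idx)
    p <- clip_prob(stats::plogis(drop(X %*% alpha)), control$clip)
    w <- depth * p * (1 - p)
    H <- crossprod(X * sqrt(w)) + S_lam
    penalized_loglik(alpha, X, eta, depth, S_lam, control$clip) +
      0.5 * (sum(spec$ranks * log(lambda)) + sum(spec$ldet)) -
      sum(log(diag(chol(H))))
  }
  for (it in seq_len(control$fs_maxit)) {
    S_lam <- penalty_blockdiag(lambda, A_list, idx)
    alpha <- pirls(eta, depth, X, S_lam, alpha, control)
    V <- laml_at(lambda, alpha)
    if (V < V_prev - 1e-8 * (abs(V_prev) + 1) && any(accel > 1)) {
      lambda <- lambda_prev; alpha <- alpha_prev
      accel[] <- 1; dir_prev[] <- 0
      S_lam <- penalty_blockdiag(lambda, A_list, idx)
      alpha <- pirls(eta, depth, X, S_lam, alpha, control)
      V <- laml_at(lambda, alpha)
    }
    p <- clip_prob(stats::plogis(drop(X %*% alpha)), control$clip)
    w <- depth * p * (1 - p)
    H <- crossprod(X * sqrt(w)) + S_lam
    Hinv <- tryCatch(chol2inv(chol(H)), error = function(e) {
      warning("penalized information not positive definite; ridge added")
      chol2inv(chol(H + diag(1e-6 * max(diag(H)), ncol(H))))
    })
    dlog <- numeric(length(lambda))
    for (p_ in seq_along(A_list)) {
      ii <- idx[[p_]]
      tr_HinvA <- sum(Hinv[ii, ii] * A_list[[p_]])
      quad <- drop(alpha[ii] %*% A_list[[p_]] %*% alpha[ii])
      lam_star <- spec$ranks[p_] / max(quad + tr_HinvA, 1e-300)
      lam_star <- min(max(lam_star, lam_lo), lam_hi)
      dlog[p_] <- log(lam_star) - log(lambda[p_])
    }
    at_bound <- (lambda <= lam_lo * 1.0001 & dlog < 0) |
      (lambda >= lam_hi * 0.9999 & dlog > 0)
    if (max(abs(dlog[!at_bound]), 0) < control$fs_tol) { conv <- TRUE; break }
    dirn <- sign(dlog)
    accel <- ifelse(dirn == dir_prev & dirn != 0, pmin(accel * 2, 32), 1)
    dir_prev <- dirn
    lambda_prev <- lambda; alpha_prev <- alpha; V_prev <- V
    lambda <- pmin(pmax(exp(log(lambda) + accel * dlog), lam_lo), lam_hi)
  }
  if (any(lambda <= lam_lo * 1.0001 | lambda >= lam_hi * 0.9999))
    warning("smoothing parameter at bound: ",
            paste(signif(lambda, 3), collapse = ", "))
  list(lambda = lambda, alpha = alpha, laml = V, iterations = it,
       converged = conv)
}

#' Fit the smoothed EM model to one targeted region
#'
#' The main fitting routine. Alternates an E-step (expected true methylated
#' counts under the error channel, given current fitted proportions) with an
#' M-step (penalized IRLS nested in restricted-likelihood smoothing-parameter
#' selection) until the penalized observed-data log-likelihood stabilizes.
#' Initialization treats the observed counts as error-free with all
#' smoothing parameters at 1; the fit is fully deterministic.
#'
#' @param counts A `meth_counts` object (or a data.frame accepted by
#'   [meth_counts()]).
#' @param covariates A `meth_covariates` object.
#' @param err An [error_rates()] object (known error rates; `error_rates(0, 1)`
#'   for error-free data).
#' @param L Spline basis rank per smooth term; a scalar is recycled.
#' @param lambda `NULL` to optimize smoothing parameters (default), or a
#'   fixed positive vector of length P+1 (intercept first).
#' @param control A [fit_control()] list.
#' @return A `meth_fit` object: list with elements `alpha` (stacked spline
#'   coefficients), `lambda`, `pi` (fitted proportions per record), `eta`
#'   (final expected true counts), `V` (Louis variance of `alpha`), `edf`
#'   (effective degrees of freedom per term), `loglik_trace`, `converged`,
#'   `iterations`, plus the design/bases and the aligned data.
#' @export
em_fit <- function(counts, covariates, err, L = 5L, lambda = NULL,
                   control = fit_control()) {
  if (!inherits(counts, "meth_counts")) counts <- meth_counts(counts)
  if (!inherits(covariates, "meth_covariates"))
    covariates <- meth_covariates(covariates)
  stopifnot(inherits(err, "error_rates"))
  view <- align_region(counts, covariates)
  P <- ncol(view$Z)
  L <- as.integer(rep(L, length.out = P + 1L))
  bases <- lapply(L, function(l)
    build_basis(view$positions, l, view$region))
  design <- assemble_design(view, bases)
  X <- design$X; idx <- design$idx
  A_list <- lapply(bases, penalty_matrix)
  Y <- view$data$meth
  depth <- view$data$total
  p0 <- err$p0; p1 <- err$p1

  fixed_lambda <- !is.null(lambda)
  if (fixed_lambda) {
    stopifnot(length(lambda) == P + 1L, all(lambda >= 0))
    lam <- lambda
  } else lam <- rep(1, P + 1L)

  mstep <- function(eta, lam, alpha, update_lambda) {
    if (fixed_lambda || !update_lambda) {
      S_lam <- penalty_blockdiag(lam, A_list, idx)
      alpha <- pirls(eta, depth, X, S_lam, alpha, control)
      list(lambda = lam, alpha = alpha)
    } else {
      optimize_lambda(eta, depth, X, A_list, idx, lam, alpha, control)
    }
  }

  # initialization: penalized fit treating Y as error-free
  init <- mstep(Y, lam, rep(0, ncol(X)), update_lambda = TRUE)
  alpha <- init$alpha; lam <- init$lambda
  S_lam <- penalty_blockdiag(lam, A_list, idx)
  ll <- observed_loglik(alpha, X, Y, depth, S_lam, p0, p1, control$clip)
  trace <- ll
  converged <- (p0 == 0 && p1 == 1)  # E-step is the identity: done already
  it <- 0L
  if (!converged) {
    for (it in seq_len(control$em_maxit)) {
      pi_cur <- clip_prob(stats::plogis(drop(X %*% alpha)), control$clip)
      eta <- e_step(Y, depth, pi_cur, err)
      ms <- mstep(eta, lam, alpha,
                  update_lambda = (it - 1L) %% control$lambda_every == 0L)
      alpha <- ms$alpha; lam <- ms$lambda
      S_lam <- penalty_blockdiag(lam, A_list, idx)
      ll_new <- observed_loglik(alpha, X, Y, depth, S_lam, p0, p1,
                                control$clip)
      trace <- c(trace, ll_new)
      if (abs(ll_new - ll) < control$em_tol * (abs(ll) + 0.1)) {
        converged <- TRUE; ll <- ll_new; break
      }
      ll <- ll_new
    }
  }
  if (!converged)
    warning("EM did not converge in ", control$em_maxit, " iterations")

  pi_hat <- clip_prob(stats::plogis(drop(X %*% alpha)), control$clip)
  fit <- structure(list(
    alpha = as.vector(alpha), lambda = lam,
    pi = pi_hat, eta = e_step(Y, depth, pi_hat, err),
    Y = Y, depth = depth,
    design = design, A_list = A_list, view = view, err = err,
    loglik_trace = trace, converged = converged, iterations = it,
    term_names = design$term_names
  ), class = "meth_fit")
  info <- louis_information(fit)
  fit$V <- info$V
  fit$V_pseudo_inverse <- info$pseudo_inverse
  fit$edf <- vapply(seq_len(P + 1L), function(p) edf(fit, p - 1L), 0)
  fit
}

#' @export
print.meth_fit <- function(x, ...) {
  cat("Smoothed-EM regional methylation fit\n")
  cat("  samples:", length(x$view$sample_ids),
      " records:", length(x$Y),
      " CpG positions:", length(x$view$positions), "\n")
  cat("  smooth terms:", paste(x$term_names, collapse = ", "), "\n")
  cat("  lambda:", paste(signif(x$lambda, 3), collapse = ", "), "\n")
  cat("  EDF:", paste(signif(x$edf, 3), collapse = ", "), "\n")
  cat("  EM iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.meth_fit <- function(object, ...) {
  tests <- regional_test(object)
  cat("Regional tests (H0: effect curve identically zero)\n")
  print(tests, row.names = FALSE)
  invisible(tests)
}
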
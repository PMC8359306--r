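#' Observed information of the spline coefficients (Louis/Oakes form)
#'
#' The marginal likelihood of the observed counts is a two-binomial mixture
#' whose Hessian is awkward to assemble directly; the Louis/Oakes identity
#' expresses it through the EM quantities instead. Each record contributes
#' curvature `w_ij (X_ij - delta_ij)` on the linear-predictor scale, with
#' `w_ij = pi(1-pi)` and `delta_ij` the derivative of the E-step imputation
#' with respect to `pi`; the penalty enters the total information once.
#' With `p0 = 0, p1 = 1` the result reduces to the penalized binomial
#' information `X' W X + A_lambda`.
#'
#' @param fit A `meth_fit` object.
#' @return List with `negH` (the K x K observed information, penalty
#'   included), `V` (its inverse, the variance of the coefficients), `w`,
#'   `delta` (per-record ingredients) and `pseudo_inverse` (TRUE when a
#'   pseudo-inverse was needed).
#' @export
louis_information <- function(fit) {
  X <- fit$design$X
  p <- fit$pi
  p0 <- fit$err$p0; p1 <- fit$err$p1
  w <- p * (1 - p)
  delta <- fit$Y * p1 * p0 / (p1 * p + p0 * (1 - p))^2 +
    (fit$depth - fit$Y) * (1 - p1) * (1 - p0) /
      ((1 - p1) * p + (1 - p0) * (1 - p))^2
  D <- w * (fit$depth - delta)
  S_lam <- penalty_blockdiag(fit$lambda, fit$A_list, fit$design$idx)
  negH <- crossprod(X, X * D) + S_lam
  negH <- (negH + t(negH)) / 2
  pseudo <- FALSE
  V <- tryCatch(chol2inv(chol(negH)), error = function(e) NULL)
  if (is.null(V)) {
    warning("observed information not positive definite; using pseudo-inverse")
    pseudo <- TRUE
    V <- mp_inverse(negH)
  }
  list(negH = negH, V = (V + t(V)) / 2, w = w, delta = delta,
       pseudo_inverse = pseudo)
}

# Moore-Penrose inverse with tolerance-based rank
mp_inverse <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps * s$d[1]
  keep <- s$d > tol
  r <- sum(keep)
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  attr(inv, "rank") <- r
  inv
}

#' Pointwise confidence band for one smooth term
#'
#' Evaluates the estimated effect curve `B(t)' alpha_p` and its standard
#' error from the corresponding diagonal block of the coefficient variance,
#' and returns normal-theory pointwise intervals.
#'
#' @param fit A `meth_fit` object.
#' @param p Smooth-term index: 0 for the intercept, 1..P for covariates.
#' @param grid Positions (bp) at which to evaluate; default a regular grid
#'   of 200 points over the region.
#' @param level Confidence level (default 0.95).
#' @return data.frame with `position`, `estimate`, `se`, `lower`, `upper`.
#' @export
pointwise_ci <- function(fit, p, grid = NULL, level = 0.95) {
  P <- length(fit$term_names) - 1L
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > P)
    stop("smooth-term index p must be in 0..", P)
  if (is.null(grid))
    grid <- seq(fit$view$region[1], fit$view$region[2], length.out = 200)
  blk <- fit$design$idx[[p + 1L]]
  B <- eval_basis(fit$design$bases[[p + 1L]], grid)
  est <- drop(B %*% fit$alpha[blk])
  Vp <- fit$V[blk, blk, drop = FALSE]
  se <- sqrt(pmax(rowSums((B %*% Vp) * B), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(position = grid, estimate = est, se = se,
             lower = est - z * se, upper = est + z * se)
}

#' Effective degrees of freedom of one smooth term
#'
#' Uses the smoothing matrix `F = (X'WX + A_lambda)^-1 X'WX` with working
#' weights `X_ij pi(1-pi)`: the term's EDF is the sum of the diagonal of
#' `2F - FF'` over its coefficient block. With all smoothing parameters at
#' zero, `F` is the identity and the EDF equals the basis rank.
#'
#' @param fit A `meth_fit` object.
#' @param p Smooth-term index (0 = intercept).
#' @param lambda Optional smoothing-parameter vector overriding the fitted
#'   one (the fitted coefficients/weights are kept).
#' @return Scalar EDF.
#' @export
edf <- function(fit, p, lambda = NULL) {
  P <- length(fit$term_names) - 1L
  stopifnot(p >= 0, p <= P)
  lam <- if (is.null(lambda)) fit$lambda else lambda
  X <- fit$design$X
  W <- fit$depth * fit$pi * (1 - fit$pi)
  XtWX <- crossprod(X * sqrt(W))
  S_lam <- penalty_blockdiag(lam, fit$A_list, fit$design$idx)
  Fm <- tryCatch(solve(XtWX + S_lam, XtWX), error = function(e)
    mp_inverse(XtWX + S_lam) %*% XtWX)
  blk <- fit$design$idx[[p + 1L]]
  sum(diag(2 * Fm - tcrossprod(Fm))[blk])
}

#' Region-wide Wald test of a zero effect curve
#'
#' Tests, for each requested covariate, the null hypothesis that its effect
#' curve is identically zero across the region (equivalently that its whole
#' spline coefficient block vanishes), using the Wald statistic
#' `T_p = alpha_p' V_p^-1 alpha_p` with `V_p` the corresponding diagonal
#' block of the Louis variance, referred to a chi-square distribution whose
#' (possibly non-integer) degrees of freedom are the term's effective
#' degrees of freedom.
#'
#' @param fit A `meth_fit` object.
#' @param p Covariate indices to test (1..P); default all covariates. A
#'   list element with several indices yields a joint test of those blocks.
#' @return data.frame with `covariate`, `statistic`, `edf`, `p_value`, and
#'   `pseudo_inverse` (whether `V_p` needed a Moore-Penrose inverse).
#' @export
regional_test <- function(fit, p = NULL) {
  P <- length(fit$term_names) - 1L
  if (is.null(p)) p <- as.list(seq_len(P))
  if (!is.list(p)) p <- as.list(p)
  rows <- lapply(p, function(ps) {
    stopifnot(all(ps >= 1), all(ps <= P))
    blk <- unlist(fit$design$idx[ps + 1L])
    a <- fit$alpha[blk]
    Vp <- fit$V[blk, blk, drop = FALSE]
    pseudo <- FALSE
    Tstat <- tryCatch(drop(a %*% solve(Vp, a)), error = function(e) NA_real_)
    if (!is.finite(Tstat) || Tstat < 0) {
      pseudo <- TRUE
      Tstat <- drop(a %*% mp_inverse(Vp) %*% a)
    }
    tau <- sum(vapply(ps, function(q) edf(fit, q), 0))
    if (tau <= 0) stop("non-positive effective degrees of freedom: broken fit")
    data.frame(
      covariate = paste(fit$term_names[ps + 1L], collapse = "+"),
      statistic = Tstat, edf = tau,
      p_value = stats::pchisq(Tstat, df = tau, lower.tail = FALSE),
      pseudo_inverse = pseudo, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
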
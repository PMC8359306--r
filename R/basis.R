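#' Cubic B-spline basis over a targeted region
#'
#' Builds a cubic B-spline basis of rank `L` on the region, with interior
#' knots at quantiles of the pooled distinct CpG positions. Positions are
#' affinely rescaled to `[0, 1]` internally for conditioning; the inverse
#' map is stored so curves are always reported in bp. The curvature penalty
#' and the smoothing parameters live on the internal scale, which is
#' self-consistent because only their product enters the fit.
#'
#' @param positions Integer vector of genomic positions (bp); at least `L`
#'   distinct values are required.
#' @param L Basis rank (number of basis functions), `>= 4` for a cubic basis.
#' @param region Numeric length-2 vector, the region bounds in bp.
#' @return A `meth_basis` object: list with `knots` (on the internal scale),
#'   `L`, `region`.
#' @export
build_basis <- function(positions, L = 5L, region = range(positions)) {
  u <- sort(unique(positions))
  if (L < 4) stop("a cubic basis needs rank L >= 4 (got L=", L, ")")
  if (length(u) < L)
    stop("only ", length(u), " distinct positions for basis rank ", L,
         "; choose L <= ", length(u))
  if (region[2] <= region[1]) stop("degenerate region bounds")
  x <- (u - region[1]) / (region[2] - region[1])
  n_int <- L - 4L
  interior <- if (n_int > 0)
    stats::quantile(x, probs = seq_len(n_int) / (n_int + 1), names = FALSE)
  else numeric(0)
  structure(list(knots = c(rep(0, 4), interior, rep(1, 4)),
                 L = as.integer(L), region = as.numeric(region)),
            class = "meth_basis")
}

#' Evaluate basis functions (or a derivative) at genomic positions
#'
#' @param basis A `meth_basis` object.
#' @param t Positions in bp, inside the region.
#' @param deriv Derivative order (0, 1 or 2), taken on the internal
#'   `[0, 1]` scale.
#' @return Matrix `length(t) x L` of basis values.
#' @export
eval_basis <- function(basis, t, deriv = 0L) {
  x <- (t - basis$region[1]) / (basis$region[2] - basis$region[1])
  if (any(x < -1e-8 | x > 1 + 1e-8))
    stop("position outside the basis support: ",
         t[which(x < -1e-8 | x > 1 + 1e-8)[1]])
  x <- pmin(pmax(x, 0), 1)
  splines::splineDesign(basis$knots, x, ord = 4L,
                        derivs = rep(as.integer(deriv), length(x)))
}

#' Integrated squared-curvature penalty matrix
#'
#' Computes `A[l, l'] = integral of B_l''(t) B_l''(t') dt` exactly: the
#' second derivative of a cubic B-spline is piecewise linear, so the
#' integrand is piecewise quadratic and a 2-point Gauss-Legendre rule per
#' knot span is exact. Coefficient vectors representing straight lines lie
#' in the null space of the result.
#'
#' @param basis A `meth_basis` object.
#' @return Symmetric positive semidefinite `L x L` matrix on the internal
#'   position scale.
#' @export
penalty_matrix <- function(basis) {
  k <- basis$knots
  spans <- unique(k)
  A <- matrix(0, basis$L, basis$L)
  gp <- c(-1, 1) / sqrt(3)
  for (s in seq_len(length(spans) - 1L)) {
    a <- spans[s]; b <- spans[s + 1L]
    mid <- (a + b) / 2; hw <- (b - a) / 2
    for (g in gp) {
      B2 <- splines::splineDesign(k, mid + hw * g, ord = 4L, derivs = 2L)
      A <- A + hw * crossprod(B2)
    }
  }
  (A + t(A)) / 2
}

#' Stacked varying-coefficient design matrix
#'
#' Row order follows the aligned view (samples in covariate order, positions
#' ascending within sample). Column block `p` holds `B_l(t_ij) * Z_pi`, with
#' `Z_0i = 1` for the intercept smooth, so the model is the GLM
#' `logit(pi) = X alpha`.
#'
#' @param view A `meth_view` from [align_region()].
#' @param bases List of `meth_basis` objects, one per smooth term
#'   (intercept first, then one per covariate column of `view$Z`). A single
#'   `meth_basis` is recycled for all terms.
#' @return A `meth_design` list: `X` (M x K matrix), `idx` (list of column
#'   index vectors per block), `bases`, `term_names`.
#' @export
assemble_design <- function(view, bases) {
  P <- ncol(view$Z)
  if (inherits(bases, "meth_basis")) bases <- rep(list(bases), P + 1L)
  if (length(bases) != P + 1L)
    stop("need one basis per smooth term: ", P + 1L, " (intercept + ",
         P, " covariates)")
  t_ij <- view$data$position
  Zrow <- cbind(1, view$Z[view$row_sample, , drop = FALSE])
  blocks <- vector("list", P + 1L)
  idx <- vector("list", P + 1L)
  off <- 0L
  for (p in seq_len(P + 1L)) {
    B <- eval_basis(bases[[p]], t_ij)
    blocks[[p]] <- B * Zrow[, p]
    idx[[p]] <- off + seq_len(bases[[p]]$L)
    off <- off + bases[[p]]$L
  }
  X <- do.call(cbind, blocks)
  term_names <- c("(Intercept)", colnames(view$Z))
  colnames(X) <- unlist(lapply(seq_len(P + 1L), function(p)
    paste0(term_names[p], ".", seq_len(bases[[p]]$L))))
  structure(list(X = X, idx = idx, bases = bases, term_names = term_names),
            class = "meth_design")
}
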
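#' Cubic B-spline basis for a penalized spline term
#'
#' Builds a cubic (order 4) B-spline basis with \code{n_basis} base functions
#' over the observed range of \code{x}: interior knots are equally spaced on
#' [min(x), max(x)] and the boundary knots carry the usual multiplicity 4, so
#' the full knot vector has \code{n_basis + 4} entries (12 knots for the
#' default 8 base functions). Basis functions form a partition of unity on
#' the span and are zero outside it.
#'
#' @param x numeric exposure values (at least 2 distinct).
#' @param n_basis number of base functions (default 8).
#' @return object of class \code{mup_basis} with the knot vector and range.
#' @export
build_basis <- function(x, n_basis = 8L) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2])
    stop("exposure is constant: cannot place spline knots")
  order <- 4L
  n_interior <- n_basis - order
  if (n_interior < 0L) stop("n_basis must be at least 4 for a cubic basis")
  interior <- if (n_interior > 0L)
    seq(r[1], r[2], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric(0)
  knots <- c(rep(r[1], order), interior, rep(r[2], order))
  structure(list(knots = knots, order = order, n_basis = n_basis, range = r),
            class = "mup_basis")
}

#' Evaluate a spline basis
#'
#' @param basis a \code{mup_basis}.
#' @param x evaluation points; points outside the knot span get all-zero rows.
#' @return numeric matrix length(x) x n_basis.
#' @export
eval_basis <- function(basis, x) {
  x <- as.numeric(x)
  out <- matrix(0, length(x), basis$n_basis)
  inside <- !is.na(x) & x >= basis$range[1] & x <= basis$range[2]
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(basis$knots, x[inside],
                                           ord = basis$order)
  }
  out
}

#' Greville abscissae (basis-function centers)
#'
#' For a cubic basis, the j-th center is the mean of knots j+1 .. j+3; a
#' coefficient vector linear in these centers reproduces a linear function.
#'
#' @param basis a \code{mup_basis}.
#' @return numeric vector of length n_basis.
#' @export
greville <- function(basis) {
  k <- basis$knots
  vapply(seq_len(basis$n_basis),
         function(j) mean(k[(j + 1):(j + basis$order - 1)]), numeric(1))
}

## Orthonormal basis of the complement of the constant direction in R^m.
## B-spline rows sum to 1, so a constant coefficient vector shifts the linear
## predictor by a constant, which the Cox partial likelihood cannot identify;
## every spline block is therefore parametrized as theta = Q gamma with
## Q'1 = 0.
constant_complement <- function(m) {
  qr.Q(qr(matrix(1, m, 1)), complete = TRUE)[, -1L, drop = FALSE]
}

## Curvature (O'Sullivan) penalty: the exact integral of the squared second
## derivative of the spline over its span, expressed in the reduced gamma
## coordinates. For a cubic basis the second derivatives are piecewise
## linear, so Simpson's rule on each inter-knot interval is exact. The null
## space is exactly the linear functions of the exposure, so as lambda grows
## the fit collapses onto the best linear Cox fit; unlike coefficient
## difference penalties, curvature is weighted evenly across the span (no
## extra shrinkage near the clamped boundary knots).
curvature_penalty <- function(basis, Q) {
  k <- unique(basis$knots)
  P <- matrix(0, basis$n_basis, basis$n_basis)
  d2 <- function(x) splines::splineDesign(basis$knots, x, ord = basis$order,
                                          derivs = rep(2L, length(x)))
  for (i in seq_len(length(k) - 1L)) {
    a <- k[i]; b <- k[i + 1L]
    if (b <= a) next
    G <- d2(c(a + 1e-10 * (b - a), (a + b) / 2, b - 1e-10 * (b - a)))
    P <- P + (b - a) / 6 *
      (tcrossprod(G[1, ]) + 4 * tcrossprod(G[2, ]) + tcrossprod(G[3, ]))
  }
  crossprod(Q, P %*% Q)
}
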
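#' Split spline terms into linear and non-linear effects
#'
#' The spline coefficient vector is projected onto the linear trend across
#' the basis-function centers (Greville abscissae): the projection slope is
#' the term's linear log-hazard effect per exposure unit, tested by a 1-df
#' Wald test; the component orthogonal to the constant and linear directions
#' is tested by a Wald chi-square on \code{edf - 1} degrees of freedom. The
#' linear test uses the sandwich covariance of the penalized estimator
#' (the linear direction is unpenalized, so this is its correct frequentist
#' variance); the non-linear test uses the penalized covariance, the usual
#' choice for shrunk spline components.
#'
#' @param fit a \code{cox_pspline} fit.
#' @return data.frame with one row per spline term: slope, se_slope,
#'   chisq_linear, p_linear, chisq_nonlinear, df_nonlinear, p_nonlinear.
#' @export
decompose_effects <- function(fit) {
  out <- lapply(names(fit$terms), function(nm) {
    tr <- fit$terms[[nm]]
    gamma <- fit$coefficients[tr$idx]
    V <- fit$var[tr$idx, tr$idx, drop = FALSE]
    V2 <- fit$var2[tr$idx, tr$idx, drop = FALSE]
    cgrev <- greville(tr$basis)
    wc <- cgrev - mean(cgrev)
    ## slope of the least-squares projection of theta = Q gamma on (1, c)
    l <- drop(crossprod(tr$Q, wc / sum(wc^2)))
    slope <- sum(l * gamma)
    v_slope <- drop(l %*% V2 %*% l)
    chi_lin <- slope^2 / v_slope
    ## non-linear block: orthogonal complement of the linear direction
    vl <- drop(crossprod(tr$Q, wc))
    N <- qr.Q(qr(matrix(vl, ncol = 1)), complete = TRUE)[, -1L, drop = FALSE]
    phi <- drop(crossprod(N, gamma))
    S <- crossprod(N, V %*% N)
    chi_nl <- drop(crossprod(phi, solve(S, phi)))
    df_nl <- max(fit$edf[[nm]] - 1, 1)
    data.frame(term = nm,
               slope = slope, se_slope = sqrt(v_slope),
               chisq_linear = chi_lin,
               p_linear = stats::pchisq(chi_lin, 1, lower.tail = FALSE),
               chisq_nonlinear = chi_nl,
               df_nonlinear = df_nl,
               p_nonlinear = stats::pchisq(chi_nl, df_nl, lower.tail = FALSE))
  })
  do.call(rbind, out)
}
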
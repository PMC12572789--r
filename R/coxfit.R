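## Penalized spline Cox model ------------------------------------------------
##
## Exposure (and optionally energy) enter the Cox model as cubic B-spline
## terms with a curvature (integrated squared second derivative) penalty;
## categorical covariates enter unpenalized. The penalized
## Breslow partial likelihood is maximized by Newton-Raphson with step
## halving, and each spline term's penalty is tuned so the term attains a
## configured target effective df (trace of the hat-type matrix
## (H + P)^-1 H restricted to the term's block).

## Risk-set bookkeeping: per stratum, subjects sorted by decreasing time are
## assigned to groups delimited by the unique death times, so Breslow sums
## S0, S1, S2 are accumulated blockwise.
cox_riskset_structure <- function(time, status, strata_id) {
  strata_id <- if (is.null(strata_id)) rep(1L, length(time)) else
    as.integer(factor(strata_id))
  lapply(split(seq_along(time), strata_id), function(idx) {
    ord <- idx[order(-time[idx])]
    ts <- time[ord]; ds <- status[ord]
    da <- sort(unique(ts[ds == 1]))       # ascending death times
    K <- length(da)
    if (K == 0L) return(NULL)
    grp <- 1L + K - findInterval(ts, da)  # smallest k with d_k <= ts
    keep <- grp <= K                      # subjects below all death times never at risk
    members <- split(seq_along(ord)[keep], grp[keep])
    deaths <- split(seq_along(ord)[keep & ds == 1], grp[keep & ds == 1])
    list(ord = ord, members = members,
         deaths = deaths[as.character(seq_len(K))],
         K = K)
  })
}

## Breslow partial log-likelihood, score and information at beta.
cox_stats <- function(X, time, status, beta, structure) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)
  ll <- 0; grad <- numeric(p); H <- matrix(0, p, p)
  for (st in structure) {
    if (is.null(st)) next
    Xs <- X[st$ord, , drop = FALSE]
    es <- eta[st$ord]
    ws <- exp(es)
    S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
    for (k in seq_len(st$K)) {
      rows <- st$members[[as.character(k)]]
      if (!is.null(rows)) {
        wb <- ws[rows]
        Xb <- Xs[rows, , drop = FALSE]
        S0 <- S0 + sum(wb)
        S1 <- S1 + drop(crossprod(Xb, wb))
        S2 <- S2 + crossprod(Xb * sqrt(wb))
      }
      dk <- st$deaths[[k]]
      nd <- length(dk)
      if (nd) {
        Xd <- Xs[dk, , drop = FALSE]
        xbar <- S1 / S0
        ll <- ll + sum(es[dk]) - nd * log(S0)
        grad <- grad + colSums(Xd) - nd * xbar
        H <- H + nd * (S2 / S0 - tcrossprod(xbar))
      }
    }
  }
  list(loglik = ll, grad = grad, info = H)
}

## Schoenfeld residuals (one row per death, Breslow ties) and death times.
cox_schoenfeld <- function(X, time, status, beta, structure) {
  p <- ncol(X)
  eta <- drop(X %*% beta); eta <- eta - mean(eta)
  res <- list(); tt <- list()
  for (st in structure) {
    if (is.null(st)) next
    Xs <- X[st$ord, , drop = FALSE]
    ws <- exp(eta[st$ord])
    ts <- time[st$ord]
    S0 <- 0; S1 <- numeric(p)
    for (k in seq_len(st$K)) {
      rows <- st$members[[as.character(k)]]
      if (!is.null(rows)) {
        wb <- ws[rows]
        S0 <- S0 + sum(wb)
        S1 <- S1 + drop(crossprod(Xs[rows, , drop = FALSE], wb))
      }
      dk <- st$deaths[[k]]
      if (length(dk)) {
        xbar <- S1 / S0
        res[[length(res) + 1L]] <- sweep(Xs[dk, , drop = FALSE], 2L, xbar)
        tt[[length(tt) + 1L]] <- ts[dk]
      }
    }
  }
  r <- do.call(rbind, res)
  t_death <- unlist(tt)
  ord <- order(t_death)
  list(residuals = r[ord, , drop = FALSE], time = t_death[ord])
}

newton_cox <- function(X, time, status, structure, P, beta0 = NULL,
                       max_iter = 30L, tol = 1e-9) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  st <- cox_stats(X, time, status, beta, structure)
  pll <- st$loglik - 0.5 * drop(beta %*% P %*% beta)
  done <- function(iter) list(beta = beta, loglik = st$loglik,
                              penalized_loglik = pll, grad = st$grad,
                              info = st$info, iter = iter, converged = TRUE)
  ## blockwise likelihood evaluation carries O(1e-8) arithmetic noise, so
  ## step acceptance and convergence use tolerances relative to |pll|
  noise <- function() 1e-8 * (abs(pll) + 1)
  for (iter in seq_len(max_iter)) {
    g <- st$grad - drop(P %*% beta)
    Hp <- st$info + P
    step <- tryCatch(solve(Hp, g), error = function(e) {
      solve(Hp + diag(1e-8 * (1 + mean(diag(Hp))), p), g)
    })
    if (sqrt(sum(step^2)) < 1e-7 * (1 + sqrt(sum(beta^2)))) return(done(iter))
    ok <- FALSE
    for (h in 0:20) {
      beta_new <- beta + step / 2^h
      st_new <- cox_stats(X, time, status, beta_new, structure)
      pll_new <- st_new$loglik - 0.5 * drop(beta_new %*% P %*% beta_new)
      if (is.finite(pll_new) && pll_new >= pll - noise()) { ok <- TRUE; break }
    }
    if (!ok) {
      if (sqrt(sum(g^2)) < 1e-3 * (1 + abs(pll))) return(done(iter))
      stop("Cox Newton step failed to increase the penalized likelihood",
           " at iteration ", iter)
    }
    converged <- abs(pll_new - pll) < tol * (abs(pll) + 1)
    beta <- beta_new; st <- st_new; pll <- pll_new
    if (converged) return(done(iter))
  }
  stop("Cox Newton did not converge in ", max_iter, " iterations")
}

assemble_penalty <- function(p, term_idx, term_P, lambda) {
  P <- matrix(0, p, p)
  for (j in seq_along(term_idx))
    P[term_idx[[j]], term_idx[[j]]] <- lambda[j] * term_P[[j]]
  P
}

term_edf <- function(info, P, term_idx) {
  M <- info + P
  A <- tryCatch(solve(M, info), error = function(e)
    solve(M + diag(1e-10 * (1 + mean(diag(M))), nrow(M)), info))
  vapply(term_idx, function(idx) sum(diag(A)[idx]), numeric(1))
}

## Tune lambda_j so the j-th spline term's effective df hits its target,
## holding the information matrix fixed (cycled twice per call).
tune_lambda <- function(info, term_idx, term_P, lambda, df_target,
                        log10_range = c(-8, 10)) {
  for (cycle in 1:2) {
    for (j in seq_along(term_idx)) {
      f <- function(l10) {
        lam <- lambda; lam[j] <- 10^l10
        term_edf(info, assemble_penalty(ncol(info), term_idx, term_P, lam),
                 term_idx)[j] - df_target[j]
      }
      flo <- f(log10_range[1]); fhi <- f(log10_range[2])
      lambda[j] <- if (flo <= 0) 10^log10_range[1]
      else if (fhi >= 0) 10^log10_range[2]
      else 10^stats::uniroot(f, log10_range, tol = 1e-4)$root
    }
  }
  lambda
}

#' Fit a Cox model with penalized cubic spline terms
#'
#' The exposure (and any further continuous terms such as total energy
#' intake) enter as cubic B-spline bases with \code{n_basis} base functions
#' (12 knots when \code{n_basis = 8}) and a curvature penalty (the integral
#' of the squared second derivative, whose null space is the linear
#' functions); the penalty weight of each term is tuned so the term attains
#' \code{df_target} effective degrees of freedom. Categorical covariates
#' enter unpenalized; ties are handled by the Breslow approximation; an
#' optional \code{strata} factor stratifies the baseline hazard.
#'
#' @param time follow-up time.
#' @param status event indicator (1 death, 0 censored).
#' @param spline_terms named list of numeric vectors (e.g.
#'   \code{list(exposure = tfi, energy = kj)}); each becomes a penalized
#'   spline term.
#' @param covariates data.frame of factor (or numeric) adjustment covariates,
#'   or NULL.
#' @param strata optional factor stratifying the baseline hazard.
#' @param df_target target effective df per spline term (recycled; default 4).
#' @param n_basis base functions per spline term (default 8).
#' @param lambda optional fixed penalty weights (skips df tuning).
#' @param max_outer maximum lambda-tuning outer iterations.
#' @return object of class \code{cox_pspline}: coefficients, penalized
#'   covariance \code{var}, per-term penalty/edf, log-likelihoods, and the
#'   data references needed by \code{\link{ph_diagnose_and_stratify}},
#'   \code{\link{decompose_effects}} and \code{\link{hr_curve}}.
#' @export
cox_pspline_fit <- function(time, status, spline_terms, covariates = NULL,
                            strata = NULL, df_target = 4, n_basis = 8L,
                            lambda = NULL, max_outer = 8L) {
  stopifnot(length(time) == length(status))
  if (sum(status) < 2L) stop("need at least 2 events to fit a Cox model")
  if (!is.list(spline_terms) || is.null(names(spline_terms)))
    spline_terms <- stats::setNames(list(spline_terms), "exposure")

  n <- length(time)
  terms <- list(); Xblocks <- list(); term_idx <- list(); term_P <- list()
  col0 <- 0L
  for (nm in names(spline_terms)) {
    x <- spline_terms[[nm]]
    stopifnot(length(x) == n)
    basis <- build_basis(x, n_basis)
    Q <- constant_complement(n_basis)
    Z <- eval_basis(basis, x) %*% Q
    ctr <- colMeans(Z)
    Z <- sweep(Z, 2L, ctr)
    idx <- col0 + seq_len(ncol(Z)); col0 <- col0 + ncol(Z)
    terms[[nm]] <- list(name = nm, basis = basis, Q = Q, centers = ctr,
                        idx = idx, x = x)
    Xblocks[[nm]] <- Z
    term_idx[[nm]] <- idx
    ## penalty normalized to unit diagonal scale so lambda is dimensionless
    ## across exposure units (keeps the df root-finding well conditioned)
    Pj <- curvature_penalty(basis, Q)
    term_P[[nm]] <- Pj / mean(diag(Pj))
  }

  cov_assign <- list(); C <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- droplevels(as.data.frame(covariates))
    ## single-level factors carry no contrast information (possible after
    ## exclusions shrink a small cohort); drop them from the design
    keep_col <- vapply(covariates, function(v)
      !(is.factor(v) || is.character(v)) || length(unique(v)) >= 2L,
      logical(1))
    covariates <- covariates[, keep_col, drop = FALSE]
  }
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    mm <- stats::model.matrix(~ ., data = covariates)
    asgn <- attr(mm, "assign")
    C <- mm[, asgn != 0L, drop = FALSE]
    asgn <- asgn[asgn != 0L]
    keep <- apply(C, 2L, function(v) stats::var(v) > 0)
    if (!all(keep)) { C <- C[, keep, drop = FALSE]; asgn <- asgn[keep] }
    for (j in unique(asgn))
      cov_assign[[names(covariates)[j]]] <- col0 + which(asgn == j)
  }
  X <- do.call(cbind, c(Xblocks, if (!is.null(C)) list(C)))
  p <- ncol(X)

  structure_ <- cox_riskset_structure(time, status, strata)
  df_target <- rep_len(df_target, length(term_idx))
  fixed_lambda <- !is.null(lambda)
  lam <- if (fixed_lambda) rep_len(lambda, length(term_idx)) else
    rep(1, length(term_idx))

  fit <- NULL; beta <- NULL
  for (outer in seq_len(max_outer)) {
    P <- assemble_penalty(p, term_idx, term_P, lam)
    fit <- newton_cox(X, time, status, structure_, P, beta0 = beta)
    beta <- fit$beta
    if (fixed_lambda) break
    lam_new <- tune_lambda(fit$info, term_idx, term_P, lam, df_target)
    if (all(abs(log(lam_new) - log(lam)) < 0.02)) { lam <- lam_new; break }
    lam <- lam_new
  }
  P <- assemble_penalty(p, term_idx, term_P, lam)
  if (!fixed_lambda) { fit <- newton_cox(X, time, status, structure_, P, beta0 = beta) }
  Hp <- fit$info + P
  V <- tryCatch(solve(Hp), error = function(e)
    solve(Hp + diag(1e-8 * (1 + mean(diag(Hp))), p)))
  edf <- term_edf(fit$info, P, term_idx)

  structure(list(
    coefficients = fit$beta,
    var = V,
    var2 = V %*% fit$info %*% V,
    info = fit$info,
    penalty = P,
    lambda = stats::setNames(lam, names(term_idx)),
    edf = stats::setNames(edf, names(term_idx)),
    df_target = df_target,
    terms = terms,
    cov_assign = cov_assign,
    loglik = fit$loglik,
    penalized_loglik = fit$penalized_loglik,
    iter = fit$iter,
    converged = fit$converged,
    n = n, n_event = sum(status),
    X = X, time = time, status = status,
    covariates = covariates, strata = strata,
    riskset = structure_
  ), class = "cox_pspline")
}

#' @export
print.cox_pspline <- function(x, ...) {
  cat("Penalized spline Cox model: n =", x$n, ", events =", x$n_event, "\n")
  for (nm in names(x$terms))
    cat(sprintf("  spline term '%s': %d base functions, lambda = %.3g, edf = %.2f\n",
                nm, x$terms[[nm]]$basis$n_basis, x$lambda[[nm]], x$edf[[nm]]))
  if (length(x$cov_assign))
    cat("  covariates:", paste(names(x$cov_assign), collapse = ", "), "\n")
  if (!is.null(x$strata_set) && length(x$strata_set))
    cat("  stratified on:", paste(x$strata_set, collapse = ", "), "\n")
  cat("  partial log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Spline-term linear predictor at new exposure values
#'
#' Relative (contrast) scale: an arbitrary constant is unidentified, so only
#' differences of the returned values are meaningful.
#'
#' @param fit a \code{cox_pspline} fit.
#' @param term spline term name.
#' @param x new exposure values inside the term's knot span.
#' @return list(eta, Z): linear predictor and its design rows in the reduced
#'   coefficient coordinates.
#' @keywords internal
spline_eta <- function(fit, term, x) {
  tr <- fit$terms[[term]]
  if (is.null(tr)) stop("unknown spline term: ", term)
  Z <- eval_basis(tr$basis, x) %*% tr$Q
  eta <- drop(Z %*% fit$coefficients[tr$idx])
  list(eta = eta, Z = Z, idx = tr$idx)
}
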
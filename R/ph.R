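#' Holm step-down adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "holm")} so multiplicity
#' handling is explicit at the call sites that mirror the analysis plan.
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values (same order as input).
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg step-up (FDR) adjustment
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

## Left-continuous Kaplan-Meier evaluated at given times (the "km" time
## transform for the proportional-hazards score test).
km_transform <- function(time, status, at) {
  ut <- sort(unique(time[status == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & status == 1), numeric(1))
  km <- cumprod(1 - n_event / n_risk)
  km_before <- c(1, km[-length(km)])        # KM just before each death time
  idx <- findInterval(at, ut)
  g <- 1 - ifelse(idx == 0, 1, km_before[pmax(idx, 1L)])
  g
}

#' Proportional-hazards score tests on scaled Schoenfeld residuals
#'
#' Grambsch-Therneau style score test of a linear trend of each covariate's
#' (scaled) Schoenfeld residuals against transformed time. Each covariate's
#' factor columns are tested jointly (df = number of columns).
#'
#' @param fit a \code{cox_pspline} fit with covariates.
#' @param transform "km" (default) or "identity" time transform.
#' @return data.frame(term, chisq, df, p).
#' @export
ph_test <- function(fit, transform = c("km", "identity")) {
  transform <- match.arg(transform)
  if (!length(fit$cov_assign))
    return(data.frame(term = character(0), chisq = numeric(0),
                      df = integer(0), p = numeric(0)))
  sch <- cox_schoenfeld(fit$X, fit$time, fit$status, fit$coefficients,
                        fit$riskset)
  g <- if (transform == "km") km_transform(fit$time, fit$status, sch$time)
  else sch$time
  gc <- g - mean(g)
  d <- nrow(sch$residuals)
  u <- drop(crossprod(sch$residuals, gc))     # sum over deaths of gc * r
  w <- drop(fit$var %*% u)
  denom <- sum(gc^2)
  out <- lapply(names(fit$cov_assign), function(nm) {
    b <- fit$cov_assign[[nm]]
    Vb <- fit$var[b, b, drop = FALSE]
    stat <- d * drop(crossprod(w[b], solve(Vb, w[b]))) / denom
    data.frame(term = nm, chisq = stat, df = length(b),
               p = stats::pchisq(stat, length(b), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Diagnose PH violations and stratify the violators
#'
#' Runs the scaled-Schoenfeld score test for every adjustment covariate,
#' Holm-adjusts the p-values across covariates, moves every covariate with an
#' adjusted p below \code{alpha} into the baseline-hazard strata, and refits
#' once (single pass, no re-diagnosis loop).
#'
#' @param fit a \code{cox_pspline} fit.
#' @param alpha significance level for the Holm-adjusted tests (0.05).
#' @param transform time transform for the score test.
#' @return list(strata_set = character vector of stratified covariates,
#'   tests = test table with \code{p_holm}, fit = the final fit).
#' @export
ph_diagnose_and_stratify <- function(fit, alpha = 0.05,
                                     transform = c("km", "identity")) {
  transform <- match.arg(transform)
  tests <- ph_test(fit, transform)
  if (nrow(tests) == 0L)
    return(list(strata_set = character(0), tests = tests, fit = fit))
  tests$p_holm <- holm_adjust(tests$p)
  violators <- tests$term[tests$p_holm < alpha]
  if (!length(violators)) {
    fit$strata_set <- character(0)
    return(list(strata_set = character(0), tests = tests, fit = fit))
  }
  covs <- fit$covariates
  for (v in violators) if (!is.factor(covs[[v]]))
    stop("cannot stratify on non-factor covariate: ", v)
  new_strata <- interaction(c(if (!is.null(fit$strata)) list(fit$strata),
                              covs[violators]), drop = TRUE)
  keep_covs <- covs[setdiff(names(covs), violators)]
  spl <- lapply(fit$terms, `[[`, "x")
  refit <- cox_pspline_fit(fit$time, fit$status, spl,
                           covariates = if (ncol(keep_covs)) keep_covs else NULL,
                           strata = new_strata,
                           df_target = fit$df_target,
                           n_basis = fit$terms[[1]]$basis$n_basis)
  refit$strata_set <- violators
  list(strata_set = violators, tests = tests, fit = refit)
}
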
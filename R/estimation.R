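#' Build the pooled logit design table
#'
#' Links response records to respondent covariates and lays out the design
#' for the binomial logit indirect-utility model. The reduced
#' specification carries intercept, `price` (yen) and `reduction_rate`
#' (percentage points) only — the specification used by the scope tests and
#' the headline WTP models; the full specification adds every respondent
#' covariate in [covariate_names()].
#'
#' @param records response records (see [simulate_responses()] or
#'   [read_responses()]).
#' @param roster respondent roster with the covariate columns.
#' @param spec `"reduced"` or `"full"`.
#' @param ladder optional [price_ladder()]; when supplied, record prices are
#'   validated against it.
#' @return data frame of class `perploss_design`: `respondent_id`, `answer`,
#'   `price`, `reduction_rate` and, for the full spec, the covariates.
#' @export
build_design <- function(records, roster, spec = c("reduced", "full"),
                         ladder = NULL) {
  spec <- match.arg(spec)
  idx <- match(records$respondent_id, roster$id)
  if (anyNA(idx))
    stop("record(s) reference unknown respondent id(s): ",
         paste(utils::head(unique(
           records$respondent_id[is.na(idx)]), 5L), collapse = ", "),
         call. = FALSE)
  if (!is.null(ladder) && !all(records$price %in% ladder$prices))
    stop("record price(s) not on the ladder", call. = FALSE)
  if (!all(records$answer %in% c(0L, 1L)))
    stop("answers must be 0 or 1", call. = FALSE)
  d <- data.frame(respondent_id = records$respondent_id,
                  answer = as.integer(records$answer),
                  price = as.numeric(records$price),
                  reduction_rate = as.numeric(records$rate),
                  stringsAsFactors = FALSE)
  if (spec == "full")
    for (nm in covariate_names()) {
      if (!nm %in% names(roster))
        stop("roster lacks covariate column `", nm, "`", call. = FALSE)
      d[[nm]] <- roster[[nm]][idx]
    }
  attr(d, "spec") <- spec
  class(d) <- c("perploss_design", "data.frame")
  d
}

#' Fit the pooled binomial logit indirect-utility model
#'
#' Maximum-likelihood logit of the yes/no purchase answers on the design
#' columns, pooling all records (the six records per respondent are treated
#' as independent observations in the likelihood, matching the survey
#' analysis being reproduced). Fitting is delegated to
#' [stats::glm()] with a binomial logit link, a tight convergence tolerance
#' and an iteration cap; the returned object carries both the
#' inverse-information covariance and a per-respondent cluster-robust
#' covariance ([sandwich::vcovCL()]), the null (intercept-only)
#' log-likelihood on the same rows, and the fit statistics of
#' [fit_statistics()].
#'
#' The naive covariance reproduces what plain `glm` output would show; the
#' clustered one accounts for the strong within-respondent dependence that
#' the shared-utility-shock response process induces, and is the covariance
#' the package's simulation-calibration checks rely on.
#'
#' @param design a `perploss_design` from [build_design()].
#' @param epsilon,maxit convergence tolerance and iteration cap passed to
#'   [stats::glm.control()].
#' @return object of class `perploss_logit` with elements `coefficients`,
#'   `vcov`, `se`, `z`, `p_value`, `vcov_cluster`, `se_cluster`,
#'   `z_cluster`, `p_cluster`, `loglik`, `loglik_null`, `n_obs`,
#'   `n_respondents`, `mcfadden_r2`, `estrella_r2`, `lr_stat`, `lr_df`,
#'   `lr_pvalue`, `spec`.
#' @export
fit_logit <- function(design, epsilon = 1e-10, maxit = 100L) {
  y <- design$answer
  if (length(unique(y)) < 2L)
    stop("response is constant; the logit model is not estimable",
         call. = FALSE)
  xcols <- setdiff(names(design), c("respondent_id", "answer"))
  x <- as.matrix(design[, xcols, drop = FALSE])
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1L) {
    bad <- xcols[qx$pivot[seq.int(qx$rank + 1L, ncol(x) + 1L)] - 1L]
    stop("design is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(answer = y, x, check.names = FALSE)
  form <- stats::as.formula(paste(
    "answer ~", paste(sprintf("`%s`", xcols), collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(),
                    data = dat,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged)
    stop("logit fit did not converge within ", maxit, " iterations",
         call. = FALSE)
  cf <- stats::coef(fit)
  names(cf)[1L] <- "intercept"
  names(cf) <- gsub("`", "", names(cf))
  scaled <- abs(cf[-1L]) * apply(x, 2, stats::sd)
  if (all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8) &&
      any(scaled > 30, na.rm = TRUE)) {
    stop("(quasi-)separation detected; separating column appears to be `",
         xcols[which.max(scaled)], "`", call. = FALSE)
  }
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(cf), names(cf))
  cl <- design$respondent_id
  Vc <- sandwich::vcovCL(fit, cluster = cl)
  dimnames(Vc) <- list(names(cf), names(cf))
  ll <- as.numeric(stats::logLik(fit))
  p1 <- mean(y)
  ll0 <- sum(y) * log(p1) + sum(1 - y) * log(1 - p1)
  se <- sqrt(diag(V)); sec <- sqrt(diag(Vc))
  out <- structure(list(
    coefficients = cf, vcov = V, se = se, z = cf / se,
    p_value = 2 * stats::pnorm(-abs(cf / se)),
    vcov_cluster = Vc, se_cluster = sec, z_cluster = cf / sec,
    p_cluster = 2 * stats::pnorm(-abs(cf / sec)),
    loglik = ll, loglik_null = ll0,
    n_obs = length(y), n_respondents = length(unique(cl)),
    df = length(cf),
    spec = attr(design, "spec") %||% "reduced",
    converged = fit$converged), class = "perploss_logit")
  fit_statistics(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' McFadden's pseudo R-squared
#'
#' \eqn{1 - \ell / \ell_0} for model log-likelihood \eqn{\ell} and null
#' (intercept-only) log-likelihood \eqn{\ell_0}.
#' @param loglik,loglik_null log-likelihoods (both negative).
#' @return numeric in \[0, 1).
#' @export
mcfadden_r2 <- function(loglik, loglik_null) {
  if (loglik_null == 0)
    stop("null log-likelihood of 0 gives a degenerate statistic",
         call. = FALSE)
  1 - loglik / loglik_null
}

#' Estrella's pseudo R-squared
#'
#' \eqn{1 - (\ell/\ell_0)^{-(2/n)\ell_0}} with `n` the number of pooled
#' observations entering the likelihood.
#' @param loglik,loglik_null log-likelihoods.
#' @param n_obs number of observations (rows of the pooled design).
#' @return numeric.
#' @export
estrella_r2 <- function(loglik, loglik_null, n_obs) {
  if (loglik_null == 0)
    stop("null log-likelihood of 0 gives a degenerate statistic",
         call. = FALSE)
  1 - (loglik / loglik_null)^(-(2 / n_obs) * loglik_null)
}

#' Attach fit statistics to a logit fit
#'
#' Computes McFadden and Estrella pseudo R-squareds and the likelihood-ratio
#' test of the fitted model against the intercept-only null on the same
#' rows.
#'
#' @param fit a `perploss_logit` (or a bare list with `loglik`,
#'   `loglik_null`, `n_obs`, `df`).
#' @return the fit, with `mcfadden_r2`, `estrella_r2`, `lr_stat`, `lr_df`
#'   and `lr_pvalue` filled in.
#' @export
fit_statistics <- function(fit) {
  fit$mcfadden_r2 <- mcfadden_r2(fit$loglik, fit$loglik_null)
  fit$estrella_r2 <- estrella_r2(fit$loglik, fit$loglik_null, fit$n_obs)
  fit$lr_stat <- 2 * (fit$loglik - fit$loglik_null)
  fit$lr_df <- fit$df - 1L
  fit$lr_pvalue <- stats::pchisq(fit$lr_stat, df = max(1L, fit$lr_df),
                                 lower.tail = FALSE)
  fit
}

#' @export
print.perploss_logit <- function(x, digits = 4, ...) {
  cat("Pooled binomial logit indirect-utility fit (", x$spec,
      " spec)\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, z = x$z,
                    `z (clustered)` = x$z_cluster, check.names = FALSE)
  print(round(tab, digits))
  cat(sprintf("n_obs %d (respondents %d)  logLik %.3f  null %.3f\n",
              x$n_obs, x$n_respondents, x$loglik, x$loglik_null))
  cat(sprintf("McFadden R2 %.3f  Estrella R2 %.3f  LR chi2 %.3f (df %d, p %.3g)\n",
              x$mcfadden_r2, x$estrella_r2, x$lr_stat, x$lr_df,
              x$lr_pvalue))
  invisible(x)
}

#' Sample means of the model covariates
#'
#' Convenience for evaluating full-specification indirect utility at the
#' covariate means.
#' @param design a full-spec `perploss_design`.
#' @return named numeric vector of covariate means.
#' @export
covariate_means <- function(design) {
  covs <- intersect(covariate_names(), names(design))
  vapply(design[covs], mean, numeric(1))
}
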
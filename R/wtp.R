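# Coefficient extraction shared by the WTP statistics: accepts a fitted
# perploss_logit or a bare named coefficient vector.
wtp_coefs <- function(fit) {
  cf <- if (inherits(fit, "perploss_logit")) fit$coefficients
        else if (is.numeric(fit) && !is.null(names(fit))) fit
        else stop("`fit` must be a perploss_logit or a named numeric ",
                  "coefficient vector", call. = FALSE)
  if (!"price" %in% names(cf))
    stop("coefficients lack `price`", call. = FALSE)
  if (!is.finite(cf[["price"]]) || cf[["price"]] >= 0)
    stop("price coefficient must be negative for a finite WTP",
         call. = FALSE)
  cf
}

# V at a given rate: intercept + beta_reduction * rate (+ covariates at
# supplied values, for full-specification fits).
utility_at_rate <- function(cf, rate, covariates = NULL) {
  v <- (if ("intercept" %in% names(cf)) cf[["intercept"]] else 0) +
    (if ("reduction_rate" %in% names(cf)) cf[["reduction_rate"]] * rate
     else 0)
  covs <- setdiff(names(cf), c("intercept", "price", "reduction_rate"))
  if (length(covs) > 0) {
    if (is.null(covariates))
      stop("fit has covariate coefficients (",
           paste(covs, collapse = ", "),
           "); supply `covariates` (e.g. covariate_means(design))",
           call. = FALSE)
    missing_cov <- setdiff(covs, names(covariates))
    if (length(missing_cov) > 0)
      stop("`covariates` lacks value(s) for: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    v <- v + sum(cf[covs] * covariates[covs])
  }
  unname(v)
}

#' Median willingness to pay implied by a logit fit
#'
#' For the logistic random-utility model the WTP distribution is logistic
#' with location \eqn{V/(-\beta_{price})}; the median WTP is therefore
#' \deqn{median = V / (-\beta_{price}),}
#' where \eqn{V} is the indirect utility net of the price term at the given
#' efficacy rate. Negative medians (possible under adversarial
#' coefficients) are floored at zero with a warning, since WTP is
#' nonnegative by construction.
#'
#' @param fit a `perploss_logit` or named coefficient vector with
#'   `intercept`, `price` (negative) and `reduction_rate`.
#' @param rate device efficacy rate in percentage points.
#' @param covariates named covariate values at which to evaluate a
#'   full-specification fit (e.g. [covariate_means()]); ignored for the
#'   reduced specification.
#' @return median WTP in yen.
#' @examples
#' m1 <- c(intercept = 1.679, price = -5.46e-5, reduction_rate = 0.00461)
#' median_wtp(m1, 50)
#' @export
median_wtp <- function(fit, rate, covariates = NULL) {
  cf <- wtp_coefs(fit)
  v <- utility_at_rate(cf, rate, covariates)
  med <- v / (-cf[["price"]])
  if (med < 0) {
    warning("negative fitted median WTP floored at 0")
    med <- 0
  }
  med
}

#' Mean willingness to pay implied by a logit fit
#'
#' Mean of the logistic WTP distribution truncated at zero,
#' \deqn{mean = \log(1 + e^{V}) / (-\beta_{price}),}
#' i.e. the integral over price of the model's yes-probability
#' \eqn{1/(1+e^{-(V + \beta_{price} t)})} from 0 to infinity.
#'
#' @inheritParams median_wtp
#' @return mean WTP in yen.
#' @export
mean_wtp <- function(fit, rate, covariates = NULL) {
  cf <- wtp_coefs(fit)
  v <- utility_at_rate(cf, rate, covariates)
  # log(1 + exp(v)) without overflow
  l1pe <- if (v > 30) v + log1p(exp(-v)) else log1p(exp(v))
  l1pe / (-cf[["price"]])
}

#' Perpetrator-to-victim WTP ratio
#'
#' @param perpetrator,victim WTP statistics in yen for the same rate and
#'   statistic (median or mean); full precision is retained — round only
#'   for display.
#' @return `perpetrator / victim`.
#' @export
wtp_ratio <- function(perpetrator, victim) {
  if (any(victim <= 0))
    stop("victim WTP must be positive to form a ratio", call. = FALSE)
  perpetrator / victim
}

#' Median/mean WTP table for both survey arms
#'
#' Mirrors the published WTP summary: median and mean WTP at both efficacy
#' rates for each arm, plus the perpetrator-to-victim ratio at full
#' precision.
#'
#' @param perpetrator_fit,victim_fit reduced-specification fits (or named
#'   coefficient vectors) for the two arms.
#' @param rates efficacy rates in percentage points.
#' @return data frame with columns `statistic`, `rate`, `perpetrator`,
#'   `victim`, `ratio`.
#' @export
wtp_table <- function(perpetrator_fit, victim_fit, rates = c(50, 90)) {
  rows <- expand.grid(statistic = c("median", "mean"), rate = rates,
                      stringsAsFactors = FALSE)
  rows <- rows[order(rows$statistic == "mean", rows$rate), ]
  f <- function(stat, fit, r)
    if (stat == "median") median_wtp(fit, r) else mean_wtp(fit, r)
  rows$perpetrator <- mapply(f, rows$statistic,
                             MoreArgs = list(fit = perpetrator_fit),
                             r = rows$rate)
  rows$victim <- mapply(f, rows$statistic,
                        MoreArgs = list(fit = victim_fit), r = rows$rate)
  rows$ratio <- wtp_ratio(rows$perpetrator, rows$victim)
  rownames(rows) <- NULL
  rows
}
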
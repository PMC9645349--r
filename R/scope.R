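#' Construct a scope-test data subset
#'
#' Four subsets probe whether stated WTP responds to the scope of the risk
#' reduction offered:
#' * **I** — Group-1 respondents only, both rates (internal test);
#' * **II** — Group-2 respondents only, both rates (internal test);
#' * **III** — all respondents, only the *first*-presented rate (external
#'   test: Group 1's 50% answers and Group 2's 90% answers);
#' * **IV** — all respondents, only the *second*-presented rate (external).
#'
#' I and II partition the full record set, as do III and IV. All three
#' records of a selected (respondent, rate) block — two asked plus the
#' imputed one — are retained.
#'
#' @param records response records carrying `rate_order`.
#' @param roster roster carrying `group`.
#' @param id subset identifier, one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return object of class `perploss_scope_subset`: list with `id`, `kind`
#'   (`"internal"` or `"external"`) and `records`.
#' @export
make_subset <- function(records, roster, id = c("I", "II", "III", "IV")) {
  id <- match.arg(id)
  if (!"rate_order" %in% names(records))
    stop("records lack `rate_order`", call. = FALSE)
  grp <- roster$group[match(records$respondent_id, roster$id)]
  if (anyNA(grp))
    stop("record(s) reference respondents missing from the roster (or ",
         "the roster lacks `group`)", call. = FALSE)
  keep <- switch(id,
                 I = grp == 1L,
                 II = grp == 2L,
                 III = records$rate_order == "first",
                 IV = records$rate_order == "second")
  structure(list(id = id,
                 kind = if (id %in% c("I", "II")) "internal" else
                   "external",
                 records = records[keep, , drop = FALSE]),
            class = "perploss_scope_subset")
}

#' Run one scope test
#'
#' Fits the reduced binomial logit (intercept, `price`, `reduction_rate`)
#' on the subset and checks the scope-test verdicts: the price coefficient
#' must be negative and the reduction-rate coefficient positive, each
#' significant at the two-sided 5% level. Sign-only verdicts are reported
#' alongside, since scope is sometimes judged on sign alone.
#'
#' @param subset a `perploss_scope_subset` from [make_subset()].
#' @param roster respondent roster.
#' @param inference `"naive"` (inverse-information covariance, matching
#'   plain pooled-logit output) or `"cluster"` (per-respondent
#'   cluster-robust covariance, the calibrated choice under the
#'   within-respondent dependence of DBDC records).
#' @param alpha two-sided significance level.
#' @return object of class `perploss_scope_result`: list with `subset_id`,
#'   `kind`, `fit`, `price_pass`, `reduction_pass`, `overall_pass`,
#'   `price_sign_ok`, `reduction_sign_ok`, `overall_sign_ok`.
#' @export
run_scope_test <- function(subset, roster,
                           inference = c("naive", "cluster"),
                           alpha = 0.05) {
  stopifnot(inherits(subset, "perploss_scope_subset"))
  inference <- match.arg(inference)
  if (nrow(subset$records) == 0L)
    stop("scope subset ", subset$id, " is empty", call. = FALSE)
  design <- build_design(subset$records, roster, spec = "reduced")
  fit <- tryCatch(fit_logit(design), error = function(e)
    stop("subset ", subset$id, ": ", conditionMessage(e), call. = FALSE))
  p <- if (inference == "cluster") fit$p_cluster else fit$p_value
  cf <- fit$coefficients
  price_pass <- as.integer(cf[["price"]] < 0 && p[["price"]] < alpha)
  reduction_pass <- as.integer(cf[["reduction_rate"]] > 0 &&
                                 p[["reduction_rate"]] < alpha)
  structure(list(subset_id = subset$id, kind = subset$kind, fit = fit,
                 inference = inference,
                 price_pass = price_pass,
                 reduction_pass = reduction_pass,
                 overall_pass = price_pass * reduction_pass,
                 price_sign_ok = as.integer(cf[["price"]] < 0),
                 reduction_sign_ok = as.integer(cf[["reduction_rate"]] > 0),
                 overall_sign_ok = as.integer(cf[["price"]] < 0 &&
                                                cf[["reduction_rate"]] > 0)),
            class = "perploss_scope_result")
}

#' Run all four scope tests
#'
#' @inheritParams run_scope_test
#' @param records full response record set for one survey arm.
#' @return data frame with one row per subset: coefficients, z-values and
#'   pass flags; the fitted objects are attached as the
#'   `"fits"` attribute.
#' @export
scope_test_all <- function(records, roster,
                           inference = c("naive", "cluster"),
                           alpha = 0.05) {
  inference <- match.arg(inference)
  ids <- c("I", "II", "III", "IV")
  res <- lapply(ids, function(i)
    run_scope_test(make_subset(records, roster, i), roster,
                   inference = inference, alpha = alpha))
  z <- function(r, what)
    if (r$inference == "cluster") r$fit$z_cluster[[what]] else
      r$fit$z[[what]]
  tab <- data.frame(
    subset = ids,
    kind = vapply(res, `[[`, "", "kind"),
    n_obs = vapply(res, function(r) r$fit$n_obs, integer(1)),
    beta_price = vapply(res, function(r)
      r$fit$coefficients[["price"]], numeric(1)),
    z_price = vapply(res, z, numeric(1), what = "price"),
    beta_reduction = vapply(res, function(r)
      r$fit$coefficients[["reduction_rate"]], numeric(1)),
    z_reduction = vapply(res, z, numeric(1), what = "reduction_rate"),
    price_pass = vapply(res, `[[`, integer(1), "price_pass"),
    reduction_pass = vapply(res, `[[`, integer(1), "reduction_pass"),
    overall_pass = vapply(res, `[[`, integer(1), "overall_pass"),
    overall_sign_ok = vapply(res, `[[`, integer(1), "overall_sign_ok"),
    stringsAsFactors = FALSE)
  attr(tab, "fits") <- res
  tab
}
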
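#' Default survey-population configuration
#'
#' Builds the configuration object consumed by [generate_respondents()]. The
#' defaults emulate the structure of the 2,085-respondent online
#' stated-preference survey the package models: two survey arms (respondents
#' imagining themselves as the *perpetrator* or the *victim* of a fatal
#' two-vehicle accident), two question-ordering groups (Group 1 is asked
#' about the 50%-effective device first, Group 2 about the 90%-effective
#' device first), demographic marginals matching the published respondent
#' table, and indirect-utility coefficients per arm at the magnitudes of the
#' published full-covariate logit fits.
#'
#' Purchase behaviour follows a logistic random-utility model: respondent
#' \eqn{i} answers *yes* to price \eqn{p} for a device with efficacy
#' `rate` (in percentage points) iff
#' \deqn{V_i(rate) + \beta_{price} p + \varepsilon_i \ge 0,}
#' where \eqn{V_i(rate)} is the indirect utility net of the price term and
#' \eqn{\varepsilon_i} is a single standard-logistic draw per respondent,
#' shared across both efficacy rates and all prices. The shared draw makes
#' every respondent's four answers internally consistent (the premise of the
#' rational-imputation rule) while leaving every marginal yes-probability
#' equal to the logit model's, so pooled-logit estimation remains consistent.
#'
#' @param n_respondents number of respondents to simulate.
#' @param arm_split probability that a respondent is assigned to the
#'   perpetrator arm.
#' @param group_split probability of Group 1 (asked the 50% rate first);
#'   either a scalar or a named vector with elements `perpetrator` and
#'   `victim`.
#' @param true_coefficients named list with elements `perpetrator` and
#'   `victim`, each a named numeric vector of indirect-utility coefficients.
#'   Recognised names: `intercept`, `price` (per yen, must be negative),
#'   `reduction_rate` (per percentage point), and any of the covariate names
#'   in [covariate_names()]. Unnamed covariates default to zero effect.
#' @param covariate_marginals named list of marginal distributions; see
#'   [default_covariate_marginals()] for the recognised entries.
#' @param initial_bid_probs probabilities over the permissible initial bids
#'   of the price ladder (default uniform); used by [simulate_responses()].
#' @param seed integer seed recorded in the configuration and used by
#'   [generate_respondents()] when no explicit seed is given.
#' @return an object of class `perploss_config` (a validated list).
#' @seealso [generate_respondents()], [simulate_responses()]
#' @export
population_config <- function(n_respondents = 2085,
                              arm_split = 1040 / 2085,
                              group_split = c(perpetrator = 0.507,
                                              victim = 0.5005),
                              true_coefficients = default_true_coefficients(),
                              covariate_marginals = default_covariate_marginals(),
                              initial_bid_probs = NULL,
                              seed = NULL) {
  if (length(n_respondents) != 1L || is.na(n_respondents) ||
      n_respondents < 0 || n_respondents != floor(n_respondents))
    stop("`n_respondents` must be a single non-negative integer",
         call. = FALSE)
  check_prob(arm_split, "arm_split")
  if (is.null(names(group_split)))
    group_split <- c(perpetrator = unname(group_split[1L]),
                     victim = unname(group_split[length(group_split)]))
  for (a in c("perpetrator", "victim"))
    check_prob(group_split[[a]], paste0("group_split[", a, "]"))
  group_split <- c(perpetrator = as.numeric(group_split[["perpetrator"]]),
                   victim = as.numeric(group_split[["victim"]]))

  defaults <- default_covariate_marginals()
  miss <- setdiff(names(defaults), names(covariate_marginals))
  covariate_marginals[miss] <- defaults[miss]
  for (nm in c("female", "aged_70_given_60plus", "accident_experience",
               "confidence_driving", "distance_10k", "adas_experience"))
    check_prob(covariate_marginals[[nm]], nm)
  for (nm in c("age_band", "household_income", "lottery_switch"))
    check_freq_table(covariate_marginals[[nm]], nm)

  if (is.null(names(true_coefficients)) ||
      !all(c("perpetrator", "victim") %in% names(true_coefficients)))
    true_coefficients <- list(perpetrator = true_coefficients,
                              victim = true_coefficients)
  for (a in c("perpetrator", "victim")) {
    b <- true_coefficients[[a]]
    if (!is.numeric(b) || is.null(names(b)) || !"price" %in% names(b))
      stop("true_coefficients$", a,
           " must be a named numeric vector containing `price`",
           call. = FALSE)
    if (!is.finite(b[["price"]]) || b[["price"]] >= 0)
      stop("true_coefficients$", a, ": `price` must be negative ",
           "(a non-negative price coefficient gives an improper WTP ",
           "distribution)", call. = FALSE)
    unknown <- setdiff(names(b),
                       c("intercept", "price", "reduction_rate",
                         covariate_names()))
    if (length(unknown) > 0)
      stop("true_coefficients$", a, ": unknown coefficient name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  if (!is.null(initial_bid_probs)) {
    if (any(initial_bid_probs < 0) ||
        abs(sum(initial_bid_probs) - 1) > 1e-9)
      stop("`initial_bid_probs` must be non-negative and sum to 1",
           call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)

  structure(list(n_respondents = as.integer(n_respondents),
                 arm_split = arm_split,
                 group_split = group_split,
                 true_coefficients = true_coefficients,
                 covariate_marginals = covariate_marginals,
                 initial_bid_probs = initial_bid_probs,
                 seed = seed),
            class = "perploss_config")
}

#' Model covariate names
#'
#' Names of the respondent covariates that enter the full indirect-utility
#' specification, beyond price and the device efficacy rate.
#' @return character vector.
#' @export
covariate_names <- function() {
  c("accident_experience", "aged_70", "confidence_driving", "distance_10k",
    "household_income", "income_topcode", "adas_experience",
    "risk_gamma", "risk_gamma_topcode")
}

#' Default indirect-utility coefficients per survey arm
#'
#' Published full-covariate logit magnitudes for the perpetrator and victim
#' arms; these are the generator's default "truth".
#' @return named list with `perpetrator` and `victim` coefficient vectors.
#' @export
default_true_coefficients <- function() {
  list(
    perpetrator = c(intercept = 1.548, price = -5.50e-5,
                    reduction_rate = 0.00395,
                    accident_experience = -0.152, aged_70 = 0.446,
                    confidence_driving = -0.157, distance_10k = -0.344,
                    household_income = 0.0191, income_topcode = 1.48,
                    adas_experience = 0.087, risk_gamma = 0.187,
                    risk_gamma_topcode = 0.164),
    victim = c(intercept = 0.861, price = -5.41e-5,
               reduction_rate = 0.00963,
               accident_experience = -0.326, aged_70 = 0.303,
               confidence_driving = -0.103, distance_10k = -0.117,
               household_income = 0.0418, income_topcode = -1.27,
               adas_experience = 0.454, risk_gamma = -0.02665,
               risk_gamma_topcode = 0.151))
}

#' Default covariate marginal distributions
#'
#' Marginals printed in the published respondent table (gender, age bands,
#' coarse household-income brackets, question-order split) are used where
#' available; marginals the survey report does not print (accident
#' experience, driving confidence, annual distance, ADAS experience, the
#' lottery switch-point distribution) default to uninformative choices and
#' are configuration-overridable.
#'
#' Household income is simulated directly on the 0.5–20.5 million-yen
#' midpoint grid: the printed coarse brackets (below 5, 5–10, 10+) are
#' spread uniformly over their midpoints, with a geometric taper across the
#' open-ended top bracket.
#'
#' @return named list of marginals.
#' @export
default_covariate_marginals <- function() {
  mid <- seq(0.5, 20.5, by = 1)
  w <- numeric(21L)
  w[1:5] <- 0.4787 / 5                      # below 5 million yen
  w[6:10] <- 0.3942 / 5                     # 5 to under 10 million yen
  w[11:21] <- 0.1271 / 11                   # 10 million yen and above
  income <- w / sum(w)
  names(income) <- format(mid, trim = TRUE)
  list(
    female = 0.4936,
    age_band = c("18-39" = 705 / 2085, "40-59" = 700 / 2085,
                 "60+" = 680 / 2085),
    aged_70_given_60plus = 0.4,
    accident_experience = 0.5,
    confidence_driving = 0.5,
    distance_10k = 0.5,
    adas_experience = 0.5,
    household_income = income,
    lottery_switch = stats::setNames(rep(0.1, 10L),
                                     format(seq(0.1, 1, by = 0.1))))
}

check_prob <- function(p, what) {
  if (length(p) != 1L || !is.numeric(p) || is.na(p) || p < 0 || p > 1)
    stop("`", what, "` must be a single probability in [0, 1]",
         call. = FALSE)
  invisible(p)
}

check_freq_table <- function(tab, what) {
  if (!is.numeric(tab) || any(tab < 0) || any(is.na(tab)))
    stop("`", what, "` must be a non-negative frequency table",
         call. = FALSE)
  if (abs(sum(tab) - 1) > 1e-9)
    stop("`", what, "` must sum to 1 (got ", format(sum(tab)), ")",
         call. = FALSE)
  invisible(tab)
}

#' Latent willingness to pay implied by the random-utility model
#'
#' Inverts the indirect utility at a given efficacy rate into the maximum
#' price a respondent would accept:
#' \deqn{WTP = \max(0, (V + \varepsilon) / (-\beta_{price})),}
#' with \eqn{V = intercept + \beta_{rate} \cdot rate + \sum_x \beta_x x}
#' over the profile covariates. Truncation at zero reflects that device
#' prices are positive.
#'
#' @param profile a one-or-more-row roster data frame (see
#'   [generate_respondents()]); covariate columns named in `coefficients`
#'   are used, others ignored.
#' @param rate device efficacy rate in percentage points (50 or 90 in the
#'   survey design, but any value is accepted).
#' @param coefficients named numeric vector with `price` (negative) and
#'   optionally `intercept`, `reduction_rate`, and covariate coefficients.
#' @param error logistic(0, 1) utility shock, one value per profile row
#'   (recycled if scalar).
#' @return numeric vector of WTPs in yen, one per profile row.
#' @export
latent_wtp <- function(profile, rate, coefficients, error = 0) {
  if (!"price" %in% names(coefficients) || coefficients[["price"]] >= 0)
    stop("`coefficients` must contain a negative `price` coefficient",
         call. = FALSE)
  v <- indirect_utility(profile, rate, coefficients)
  pmax(0, (v + error) / (-coefficients[["price"]]))
}

# V(rate) = intercept + beta_reduction * rate + sum of covariate terms;
# excludes the price term and the error.
indirect_utility <- function(profile, rate, coefficients) {
  v <- rep_len(0, max(1L, nrow(profile)))
  if ("intercept" %in% names(coefficients))
    v <- v + coefficients[["intercept"]]
  if ("reduction_rate" %in% names(coefficients))
    v <- v + coefficients[["reduction_rate"]] * rate
  covs <- intersect(names(coefficients), covariate_names())
  for (nm in covs) {
    if (!nm %in% names(profile))
      stop("profile lacks covariate column `", nm, "`", call. = FALSE)
    v <- v + coefficients[[nm]] * profile[[nm]]
  }
  v
}

#' Generate a synthetic survey roster
#'
#' Draws `n_respondents` respondent profiles: arm and question-order group
#' assignments, demographics and model covariates from the configured
#' marginals, a lottery switch point (from which the CRRA risk-aversion
#' coefficient is computed with [gamma_from_switch()], guaranteeing
#' generator/analyzer consistency), one shared logistic utility shock, and
#' the implied latent WTPs at the 50% and 90% efficacy rates.
#'
#' @param config a `perploss_config`, see [population_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a data frame of class `perploss_roster`, one row per respondent.
#'   Generator-only columns (`latent_wtp_50`, `latent_wtp_90`) expose the
#'   latent quantities a real survey never observes.
#' @examples
#' roster <- generate_respondents(population_config(n_respondents = 50,
#'                                                  seed = 1))
#' table(roster$arm, roster$group)
#' @export
generate_respondents <- function(config, seed = NULL) {
  if (!inherits(config, "perploss_config"))
    stop("`config` must be built by population_config()", call. = FALSE)
  seed <- if (!is.null(seed)) as.integer(seed) else config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_respondents
  m <- config$covariate_marginals

  arm <- ifelse(stats::runif(n) < config$arm_split, "perpetrator", "victim")
  p_g1 <- unname(config$group_split[arm])
  group <- ifelse(stats::runif(n) < p_g1, 1L, 2L)
  gender <- ifelse(stats::runif(n) < m$female, "female", "male")
  age_band <- sample_cat(names(m$age_band), n, m$age_band)
  aged_70 <- as.integer(age_band == "60+" &
                          stats::runif(n) < m$aged_70_given_60plus)
  accident_experience <- stats::rbinom(n, 1L, m$accident_experience)
  confidence_driving <- stats::rbinom(n, 1L, m$confidence_driving)
  distance_10k <- stats::rbinom(n, 1L, m$distance_10k)
  adas_experience <- stats::rbinom(n, 1L, m$adas_experience)
  household_income <- as.numeric(sample_cat(names(m$household_income), n,
                                            m$household_income))
  income_topcode <- as.integer(household_income >= 20.5)
  p_switch <- as.numeric(sample_cat(names(m$lottery_switch), n,
                                    m$lottery_switch))

  sched <- lottery_schedule()
  gam <- gamma_from_switch(sched, p_switch)

  roster <- data.frame(
    id = sprintf("R%05d", seq_len(n)),
    arm = arm, group = group, gender = gender, age_band = age_band,
    accident_experience = accident_experience, aged_70 = aged_70,
    confidence_driving = confidence_driving, distance_10k = distance_10k,
    household_income = household_income, income_topcode = income_topcode,
    adas_experience = adas_experience,
    p_switch = p_switch,
    risk_gamma = gam$gamma, risk_gamma_topcode = gam$topcode,
    stringsAsFactors = FALSE)

  err <- stats::rlogis(n)
  roster$utility_error <- err
  roster$latent_wtp_50 <- rep(NA_real_, n)
  roster$latent_wtp_90 <- rep(NA_real_, n)
  for (a in c("perpetrator", "victim")) {
    sel <- roster$arm == a
    if (!any(sel)) next
    b <- config$true_coefficients[[a]]
    roster$latent_wtp_50[sel] <- latent_wtp(roster[sel, , drop = FALSE],
                                            50, b, err[sel])
    roster$latent_wtp_90[sel] <- latent_wtp(roster[sel, , drop = FALSE],
                                            90, b, err[sel])
  }
  attr(roster, "seed") <- seed
  class(roster) <- c("perploss_roster", "data.frame")
  roster
}

sample_cat <- function(values, n, probs) {
  if (n == 0L) return(values[integer(0)])
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}
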
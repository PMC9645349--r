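#' Valuation inputs
#'
#' Reference quantities for converting device WTP into non-financial-loss
#' values: the external victim reference loss (537 million yen, the value
#' used in national cost-benefit analyses for non-financial losses to
#' accident victims), the baseline annual fatal-accident risk per licensed
#' driver (1 in 200,000), and the device's accident reduction rate as a
#' fraction.
#'
#' @param victim_reference_loss yen.
#' @param baseline_annual_risk annual probability.
#' @param reduction_rate fraction in (0, 1].
#' @return object of class `perploss_valuation_input`.
#' @export
valuation_input <- function(victim_reference_loss = 537e6,
                            baseline_annual_risk = 1 / 200000,
                            reduction_rate = 0.5) {
  if (victim_reference_loss <= 0 || baseline_annual_risk <= 0 ||
      reduction_rate <= 0 || reduction_rate > 1)
    stop("valuation inputs must be positive, with reduction_rate in ",
         "(0, 1]", call. = FALSE)
  structure(list(victim_reference_loss = victim_reference_loss,
                 baseline_annual_risk = baseline_annual_risk,
                 reduction_rate = reduction_rate),
            class = "perploss_valuation_input")
}

#' Perpetrator loss by ratio anchoring
#'
#' The headline valuation: multiply the external victim reference loss by
#' the perpetrator-to-victim WTP ratio. The ratio must be supplied at full
#' precision — display-rounded ratios shift the result by several million
#' yen.
#'
#' @param input a [valuation_input()].
#' @param ratio perpetrator-to-victim WTP ratio (positive).
#' @return loss in yen (full precision; see [round_millions()] for report
#'   formatting).
#' @examples
#' v <- valuation_input()
#' round_millions(loss_by_ratio(v, 35005 / 29266))  # 642
#' @export
loss_by_ratio <- function(input, ratio) {
  stopifnot(inherits(input, "perploss_valuation_input"))
  if (any(ratio <= 0))
    stop("`ratio` must be positive", call. = FALSE)
  input$victim_reference_loss * ratio
}

#' Perpetrator or victim loss by direct risk division
#'
#' Value-of-statistical-life style estimator: annual device WTP divided by
#' the annual risk reduction it buys,
#' `wtp / (reduction_rate * baseline_annual_risk)`. Exposed for
#' completeness; it yields far larger magnitudes than ratio anchoring and
#' the two are not reconciled here.
#'
#' @param wtp annual WTP in yen (nonnegative).
#' @param input a [valuation_input()].
#' @return loss in yen.
#' @export
loss_direct <- function(wtp, input) {
  stopifnot(inherits(input, "perploss_valuation_input"))
  if (any(wtp < 0)) stop("`wtp` must be nonnegative", call. = FALSE)
  wtp / (input$reduction_rate * input$baseline_annual_risk)
}

#' Round yen to integer millions (half up)
#'
#' Presentation-layer rounding only; stored values stay at full precision.
#' @param x yen.
#' @return integer millions of yen.
#' @export
round_millions <- function(x) floor(x / 1e6 + 0.5)

#' Valuation report table
#'
#' One row per (statistic, rate): the full-precision perpetrator-to-victim
#' ratio, the ratio-anchored perpetrator loss, and the direct-division
#' losses for both arms.
#'
#' @param wtp a [wtp_table()] output.
#' @param input a [valuation_input()]; its `reduction_rate` is replaced per
#'   row by the row's rate / 100.
#' @return data frame with losses in million yen (`*_mn` columns rounded
#'   half-up) alongside full-precision yen values.
#' @export
valuation_table <- function(wtp, input = valuation_input()) {
  out <- wtp
  out$loss_by_ratio <- loss_by_ratio(input, wtp$ratio)
  out$loss_by_ratio_mn <- round_millions(out$loss_by_ratio)
  out$loss_direct_perpetrator <- mapply(function(w, r)
    loss_direct(w, valuation_input(input$victim_reference_loss,
                                   input$baseline_annual_risk, r / 100)),
    wtp$perpetrator, wtp$rate)
  out$loss_direct_victim <- mapply(function(w, r)
    loss_direct(w, valuation_input(input$victim_reference_loss,
                                   input$baseline_annual_risk, r / 100)),
    wtp$victim, wtp$rate)
  out
}
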
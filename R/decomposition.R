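#' Validate a yearly accident-loss series
#'
#' The multiplicative identity \eqn{S_n = D_n A_n L_n} links total economic
#' loss \eqn{S} (yen) to total distance travelled \eqn{D} (km), accident
#' frequency per km \eqn{A}, and loss per accident \eqn{L} (yen). When `S`
#' is absent it is derived; when all four are supplied the identity is
#' checked to 1e-9 relative.
#'
#' @param data data frame with columns `year`, `D`, `A`, `L` and optionally
#'   `S`.
#' @return validated data frame of class `perploss_year_losses`, sorted by
#'   year.
#' @export
year_losses <- function(data) {
  need <- c("year", "D", "A", "L")
  if (!all(need %in% names(data)))
    stop("data lacks column(s): ",
         paste(setdiff(need, names(data)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(data$year))
    stop("duplicate years", call. = FALSE)
  data <- data[order(data$year), , drop = FALSE]
  if (!"S" %in% names(data)) data$S <- data$D * data$A * data$L
  if (any(!is.finite(data$S) | data$S <= 0) ||
      any(data$D <= 0 | data$A <= 0 | data$L <= 0))
    stop("S, D, A, L must all be positive", call. = FALSE)
  bad <- abs(data$S - data$D * data$A * data$L) > 1e-9 * abs(data$S)
  if (any(bad))
    stop("S != D*A*L (relative error > 1e-9) in year(s): ",
         paste(data$year[bad], collapse = ", "), call. = FALSE)
  rownames(data) <- NULL
  class(data) <- c("perploss_year_losses", "data.frame")
  data
}

#' Factor decomposition of the loss variation between two years
#'
#' Expresses the variation rate of total loss as the sum of the variation
#' rates of its three factors plus a residual:
#' \deqn{\Delta S_n / S_n = \Delta D_n / D_n + \Delta A_n / A_n +
#'   \Delta L_n / L_n + R_n,}
#' with \eqn{\Delta X_n \equiv X_n - X_{n-1}}. The default follows the
#' identity literally with current-year denominators; previous-year
#' denominators (the conventional growth rate) are available via
#' `denominator = "previous"`. The residual is the cross-term shortfall of
#' this first-order expansion and makes the conservation identity exact.
#'
#' @param prev,cur single rows of a [year_losses()] series (or lists with
#'   `year`, `S`, `D`, `A`, `L`), with `cur$year > prev$year`.
#' @param denominator `"current"` or `"previous"`.
#' @return one-row data frame: `year_from`, `year_to`, `total_rate`,
#'   `distance_rate`, `frequency_rate`, `loss_per_accident_rate`,
#'   `residual`, all in (unrounded) percent.
#' @export
decompose <- function(prev, cur, denominator = c("current", "previous")) {
  denominator <- match.arg(denominator)
  if (cur$year <= prev$year)
    stop("`cur` must be a later year than `prev`", call. = FALSE)
  rate <- function(x0, x1) {
    den <- if (denominator == "current") x1 else x0
    if (den == 0) stop("zero denominator in variation rate", call. = FALSE)
    100 * (x1 - x0) / den
  }
  total <- rate(prev$S, cur$S)
  d <- rate(prev$D, cur$D)
  a <- rate(prev$A, cur$A)
  l <- rate(prev$L, cur$L)
  data.frame(year_from = prev$year, year_to = cur$year,
             total_rate = total, distance_rate = d, frequency_rate = a,
             loss_per_accident_rate = l,
             residual = residual_from_rates(total, d, a, l))
}

#' Residual of the variation-rate identity
#'
#' `total - (d + a + l)`: the portion of the total variation rate left
#' unexplained by the three factor rates.
#'
#' @param total,d,a,l variation rates in percent.
#' @return residual in percent.
#' @examples
#' residual_from_rates(-0.4, 9.7, 12.0, -18.9)  # -3.2
#' @export
residual_from_rates <- function(total, d, a, l) total - (d + a + l)

#' Decompose a full yearly series
#'
#' Applies [decompose()] to every consecutive pair of years.
#'
#' @param series a [year_losses()] data frame (coerced if plain).
#' @inheritParams decompose
#' @return data frame with one row per interval.
#' @export
decompose_losses <- function(series,
                             denominator = c("current", "previous")) {
  if (!inherits(series, "perploss_year_losses"))
    series <- year_losses(series)
  if (nrow(series) < 2L)
    stop("need at least two years to decompose", call. = FALSE)
  denominator <- match.arg(denominator)
  out <- do.call(rbind, lapply(seq_len(nrow(series) - 1L), function(i)
    decompose(series[i, ], series[i + 1L, ], denominator = denominator)))
  rownames(out) <- NULL
  out
}
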
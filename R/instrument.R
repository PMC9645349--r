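#' Double-bounded dichotomous-choice price ladder
#'
#' The seven-point yen price ladder used in the survey instrument, with the
#' middle five prices permissible as initial bids. Every permissible initial
#' bid must have both a lower and a higher neighbour, because the follow-up
#' rule moves one step up after *yes* / one step down after *no*, and the
#' rational-imputation rule needs the opposite neighbour.
#'
#' @param prices strictly increasing vector of positive prices in yen.
#' @param initial_indices indices into `prices` permissible as initial bids.
#' @return object of class `perploss_ladder`.
#' @export
price_ladder <- function(prices = c(100, 1000, 5000, 10000, 30000,
                                    50000, 100000),
                         initial_indices = seq(2L, length(prices) - 1L)) {
  if (length(prices) < 3L || any(prices <= 0) ||
      any(diff(prices) <= 0))
    stop("`prices` must be at least 3 strictly increasing positive values",
         call. = FALSE)
  initial_indices <- as.integer(initial_indices)
  if (any(initial_indices <= 1L) || any(initial_indices >= length(prices)))
    stop("every initial bid needs both a lower and a higher ladder ",
         "neighbour; index out of range", call. = FALSE)
  structure(list(prices = as.numeric(prices),
                 initial_indices = initial_indices),
            class = "perploss_ladder")
}

#' Follow-up price after the first yes-or-no answer
#'
#' Implements the bid ladder's follow-up rule: after a *yes* the second bid
#' is the next higher ladder price; after a *no* it is the next lower one.
#'
#' @param ladder a [price_ladder()].
#' @param current current price in yen (must be on the ladder); vectorised.
#' @param answer 0/1 answer(s) to the current bid.
#' @return follow-up price(s) in yen.
#' @examples
#' lad <- price_ladder()
#' next_price(lad, 10000, 1)  # 30000
#' next_price(lad, 1000, 0)   # 100
#' @export
next_price <- function(ladder, current, answer) {
  stopifnot(inherits(ladder, "perploss_ladder"))
  idx <- match(current, ladder$prices)
  if (anyNA(idx))
    stop("price(s) not on the ladder: ",
         paste(unique(current[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  if (!all(answer %in% c(0, 1)))
    stop("`answer` must be 0 or 1", call. = FALSE)
  nxt <- idx + ifelse(answer == 1, 1L, -1L)
  if (any(nxt < 1L) || any(nxt > length(ladder$prices)))
    stop("ladder boundary: no ", ifelse(answer == 1, "higher", "lower"),
         " neighbour for price ", current, call. = FALSE)
  ladder$prices[nxt]
}

#' Run the four-question DBDC protocol for one respondent
#'
#' Asks two yes-or-no purchase questions per efficacy rate, in the
#' respondent's group order (Group 1: 50% then 90%; Group 2: 90% then 50%).
#' The first bid of each rate block is `initial_price`; the second bid
#' follows [next_price()]. Answers compare the respondent's latent WTP for
#' that rate against the bid.
#'
#' @param profile single-row roster data frame with `id`, `group`,
#'   `latent_wtp_50`, `latent_wtp_90`.
#' @param ladder a [price_ladder()].
#' @param initial_price initial bid(s) in yen: one value used for both rate
#'   blocks, or one per block (in the respondent's question order).
#' @return data frame of 4 response records with columns `respondent_id`,
#'   `rate`, `price`, `answer`, `origin`, `rate_order`.
#' @export
run_dbdc <- function(profile, ladder, initial_price) {
  stopifnot(inherits(ladder, "perploss_ladder"), nrow(profile) == 1L)
  if (!all(initial_price %in% ladder$prices[ladder$initial_indices]))
    stop("initial price not permissible on this ladder", call. = FALSE)
  initial_price <- rep_len(initial_price, 2L)
  rates <- if (profile$group == 1L) c(50, 90) else c(90, 50)
  out <- vector("list", 2L)
  for (k in 1:2) {
    wtp <- profile[[paste0("latent_wtp_", rates[k])]]
    p1 <- initial_price[k]
    a1 <- as.integer(wtp >= p1)
    p2 <- next_price(ladder, p1, a1)
    a2 <- as.integer(wtp >= p2)
    out[[k]] <- data.frame(
      respondent_id = rep(profile$id, 2L),
      rate = rates[k],
      price = c(p1, p2),
      answer = c(a1, a2),
      origin = c("asked_first", "asked_second"),
      rate_order = c("first", "second")[k],
      stringsAsFactors = FALSE)
  }
  rbind(out[[1L]], out[[2L]])
}

#' Impute the rational third record per rate block
#'
#' Under the rationality assumption, a respondent saying *yes* at the
#' initial bid would also say *yes* at the next lower ladder price, and one
#' saying *no* would also say *no* at the next higher price. This adds one
#' imputed record per (respondent, rate), turning the 4 asked records into
#' the 6-record estimation dataset and removing the sampling bias the
#' follow-up bid selection would otherwise induce.
#'
#' @param records response records containing at least the `asked_first`
#'   rows (output of [run_dbdc()], possibly row-bound over a roster).
#' @param ladder a [price_ladder()].
#' @return records plus one `imputed` row per (respondent, rate).
#' @export
augment_records <- function(records, ladder) {
  stopifnot(inherits(ladder, "perploss_ladder"))
  need <- c("respondent_id", "rate", "price", "answer", "origin",
            "rate_order")
  if (!all(need %in% names(records)))
    stop("records lack column(s): ",
         paste(setdiff(need, names(records)), collapse = ", "),
         call. = FALSE)
  if (any(records$origin == "imputed"))
    stop("records already contain imputed rows", call. = FALSE)
  first <- records[records$origin == "asked_first", , drop = FALSE]
  imp <- first
  # mirror of the follow-up rule: yes -> next lower price, no -> next higher
  imp$price <- next_price(ladder, first$price, 1 - first$answer)
  imp$origin <- "imputed"
  out <- rbind(records, imp)
  rownames(out) <- NULL
  out
}

#' Simulate DBDC responses for a whole roster
#'
#' Vectorised equivalent of calling [run_dbdc()] and [augment_records()]
#' respondent by respondent. Each rate block's initial bid is drawn
#' independently and uniformly (or per `config` probabilities) from the
#' ladder's permissible initial bids.
#'
#' @param roster a `perploss_roster` from [generate_respondents()].
#' @param ladder a [price_ladder()].
#' @param initial_bid_probs optional probabilities over the permissible
#'   initial bids (default uniform).
#' @param augment add the imputed records (default `TRUE`).
#' @param seed optional integer seed.
#' @return data frame of response records, 6 per respondent when
#'   `augment = TRUE` (3 per rate block: asked first, asked second,
#'   imputed), else 4.
#' @export
simulate_responses <- function(roster, ladder = price_ladder(),
                               initial_bid_probs = NULL, augment = TRUE,
                               seed = NULL) {
  stopifnot(inherits(ladder, "perploss_ladder"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(roster)
  if (n == 0L) {
    out <- data.frame(respondent_id = character(), rate = numeric(),
                      price = numeric(), answer = integer(),
                      origin = character(), rate_order = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  init_idx <- ladder$initial_indices
  blocks <- vector("list", 2L)
  for (k in 1:2) {  # k = rate order position
    rate <- ifelse(roster$group == 1L, c(50, 90)[k], c(90, 50)[k])
    wtp <- ifelse(rate == 50, roster$latent_wtp_50, roster$latent_wtp_90)
    i1 <- init_idx[sample.int(length(init_idx), n, replace = TRUE,
                              prob = initial_bid_probs)]
    p1 <- ladder$prices[i1]
    a1 <- as.integer(wtp >= p1)
    i2 <- i1 + ifelse(a1 == 1L, 1L, -1L)
    p2 <- ladder$prices[i2]
    a2 <- as.integer(wtp >= p2)
    blk <- data.frame(
      respondent_id = rep(roster$id, 2L),
      rate = rep(rate, 2L),
      price = c(p1, p2),
      answer = c(a1, a2),
      origin = rep(c("asked_first", "asked_second"), each = n),
      rate_order = c("first", "second")[k],
      stringsAsFactors = FALSE)
    if (augment) {
      i3 <- i1 - ifelse(a1 == 1L, 1L, -1L)
      blk <- rbind(blk, data.frame(
        respondent_id = roster$id, rate = rate,
        price = ladder$prices[i3], answer = a1, origin = "imputed",
        rate_order = c("first", "second")[k],
        stringsAsFactors = FALSE))
    }
    blocks[[k]] <- blk
  }
  out <- rbind(blocks[[1L]], blocks[[2L]])
  out <- out[order(match(out$respondent_id, roster$id),
                   out$rate_order, out$origin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lottery schedule for CRRA risk-aversion elicitation
#'
#' The paired-lottery scheme used to elicit risk aversion: at each
#' probability `p` on the grid the respondent chooses between a safe lottery
#' A (win `a_high` with probability `p`, else `a_low`) and a risky lottery B
#' (win `b_high` with probability `p`, else `b_low`). Questions ascend the
#' `p` grid until the respondent first picks B.
#'
#' @param a_high,a_low,b_high,b_low lottery payoffs in yen (all positive).
#' @param p_grid strictly increasing probabilities in (0, 1].
#' @return object of class `perploss_lottery`.
#' @export
lottery_schedule <- function(a_high = 20000, a_low = 16000,
                             b_high = 38500, b_low = 1000,
                             p_grid = seq(0.1, 1, by = 0.1)) {
  if (any(c(a_high, a_low, b_high, b_low) <= 0))
    stop("lottery payoffs must be positive", call. = FALSE)
  if (any(p_grid <= 0) || any(p_grid > 1) || any(diff(p_grid) <= 0))
    stop("`p_grid` must be strictly increasing within (0, 1]",
         call. = FALSE)
  structure(list(a_high = a_high, a_low = a_low,
                 b_high = b_high, b_low = b_low,
                 p_grid = round(p_grid, 10)),
            class = "perploss_lottery")
}

#' Constant-relative-risk-aversion utility
#'
#' \eqn{u(x) = x^{1-\gamma} / (1-\gamma)} for \eqn{\gamma \ne 1}, with the
#' logarithmic limit \eqn{u(x) = \ln x} at \eqn{\gamma = 1}.
#'
#' @param x positive payoff(s) in yen.
#' @param gamma relative risk-aversion coefficient(s).
#' @return utility value(s); `x` and `gamma` are recycled to a common
#'   length.
#' @export
crra_utility <- function(x, gamma) {
  if (any(x <= 0)) stop("`x` must be positive", call. = FALSE)
  n <- max(length(x), length(gamma))
  x <- rep_len(x, n); gamma <- rep_len(gamma, n)
  out <- numeric(n)
  lg <- gamma == 1
  out[lg] <- log(x[lg])
  out[!lg] <- x[!lg]^(1 - gamma[!lg]) / (1 - gamma[!lg])
  out
}

# EU(B) - EU(A) at probability p of the high payoff; decreasing in gamma
# for payoff configurations where B is the riskier lottery.
eu_difference <- function(schedule, gamma, p) {
  p * (crra_utility(schedule$b_high, gamma) -
         crra_utility(schedule$a_high, gamma)) +
    (1 - p) * (crra_utility(schedule$b_low, gamma) -
                 crra_utility(schedule$a_low, gamma))
}

#' CRRA coefficient implied by a lottery switch point
#'
#' Maps the first probability at which a respondent prefers the risky
#' lottery B to a relative risk-aversion coefficient: the largest
#' \eqn{\gamma} on a 0.001 grid (search range \[-10, 10\]) at which the
#' expected CRRA utility of B still weakly exceeds that of A at the switch
#' probability — the indifference threshold identified by the design. A
#' respondent who never prefers B before the degenerate question
#' (`p_switch = 1`, where B dominates for every \eqn{\gamma}) is top-coded
#' to the value for the previous grid probability, with the top-code flag
#' set.
#'
#' @param schedule a [lottery_schedule()].
#' @param p_switch switch probability(ies), each on `schedule$p_grid`.
#' @return list with numeric `gamma` and integer `topcode` vectors.
#' @export
gamma_from_switch <- function(schedule, p_switch) {
  stopifnot(inherits(schedule, "perploss_lottery"))
  grid <- schedule$p_grid
  if (!all(round(p_switch, 10) %in% grid))
    stop("`p_switch` must lie on the schedule's probability grid",
         call. = FALSE)
  p_switch <- round(p_switch, 10)
  top <- as.integer(p_switch >= grid[length(grid)] &
                      grid[length(grid)] == 1)
  p_eff <- ifelse(top == 1L, grid[length(grid) - 1L], p_switch)
  uniq <- unique(p_eff)
  gam <- vapply(uniq, function(p) gamma_boundary(schedule, p), numeric(1))
  list(gamma = gam[match(p_eff, uniq)], topcode = top)
}

# Largest gamma on the 0.001 grid in [-10, 10] with EU(B) >= EU(A) at p.
gamma_boundary <- function(schedule, p) {
  lo <- -10; hi <- 10
  f_lo <- eu_difference(schedule, lo, p)
  f_hi <- eu_difference(schedule, hi, p)
  if (f_hi >= 0) return(hi)          # B weakly preferred everywhere
  if (f_lo < 0)
    stop("no gamma in [-10, 10] makes lottery B weakly preferred at p = ",
         p, call. = FALSE)
  root <- stats::uniroot(function(g) eu_difference(schedule, g, p),
                         c(lo, hi), tol = 1e-10)$root
  g <- floor(root * 1000 + 1e-9) / 1000
  # snap to the largest admissible grid point around the root
  while (g + 0.001 <= hi && eu_difference(schedule, g + 0.001, p) >= 0)
    g <- g + 0.001
  while (eu_difference(schedule, g, p) < 0) g <- g - 0.001
  round(g, 3)
}

#' Switch point implied by a CRRA coefficient
#'
#' The first grid probability at which a respondent with coefficient
#' `gamma` weakly prefers the risky lottery B; the round-trip inverse of
#' [gamma_from_switch()].
#'
#' @param schedule a [lottery_schedule()].
#' @param gamma CRRA coefficient(s).
#' @return switch probability(ies) on the grid.
#' @export
switch_point_from_gamma <- function(schedule, gamma) {
  stopifnot(inherits(schedule, "perploss_lottery"))
  vapply(gamma, function(g) {
    for (p in schedule$p_grid)
      if (eu_difference(schedule, g, p) >= 0) return(p)
    schedule$p_grid[length(schedule$p_grid)]
  }, numeric(1))
}
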
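test_that("ladder construction enforces the neighbour requirement", {
  expect_error(price_ladder(c(100, 100, 200)), "strictly increasing")
  expect_error(price_ladder(c(100, 1000, 5000), initial_indices = c(1, 2)),
               "neighbour")
  lad <- price_ladder(c(100, 1000, 5000), initial_indices = 2L)
  expect_s3_class(lad, "perploss_ladder")
})

test_that("next_price reproduces the full follow-up mapping", {
  expected <- data.frame(
    initial = rep(c(1000, 5000, 10000, 30000, 50000), each = 2),
    answer = rep(c(1, 0), 5),
    second = c(5000, 100, 10000, 1000, 30000, 5000,
               50000, 10000, 100000, 30000))
  got <- next_price(default_ladder, expected$initial, expected$answer)
  expect_equal(got, expected$second)
  expect_error(next_price(default_ladder, 1234, 1), "not on the ladder")
  expect_error(next_price(default_ladder, 100, 0), "boundary")
  expect_error(next_price(default_ladder, 100000, 1), "boundary")
})

test_that("run_dbdc answers follow the latent-WTP thresholds", {
  # zero WTP: four noes
  r <- run_dbdc(tiny_profile(0, 0), default_ladder, 10000)
  expect_equal(nrow(r), 4L)
  expect_true(all(r$answer == 0))
  # saturated WTP: four yeses
  r <- run_dbdc(tiny_profile(1e9, 1e9), default_ladder, 10000)
  expect_true(all(r$answer == 1))
  # threshold case, Group 1 (50% block first)
  r <- run_dbdc(tiny_profile(20000, 20000), default_ladder, 10000)
  r50 <- r[r$rate == 50, ]
  expect_equal(r50$rate_order, rep("first", 2))
  expect_equal(r50$price, c(10000, 30000))
  expect_equal(r50$answer, c(1L, 0L))
  # Group 2 asks the 90% block first
  r <- run_dbdc(tiny_profile(20000, 20000, group = 2L), default_ladder,
                10000)
  expect_equal(unique(r$rate[r$rate_order == "first"]), 90)
  expect_error(run_dbdc(tiny_profile(0, 0), default_ladder, 100),
               "not permissible")
})

test_that("augment_records applies the rational-imputation rule", {
  r_yes <- run_dbdc(tiny_profile(20000, 20000), default_ladder, 10000)
  aug <- augment_records(r_yes, default_ladder)
  expect_equal(nrow(aug), 6L)
  imp50 <- aug[aug$origin == "imputed" & aug$rate == 50, ]
  expect_equal(imp50$price, 5000)   # yes at 10,000 -> yes imputed at 5,000
  expect_equal(imp50$answer, 1L)

  r_no <- run_dbdc(tiny_profile(500, 500), default_ladder, 10000)
  imp <- augment_records(r_no, default_ladder)
  imp50 <- imp[imp$origin == "imputed" & imp$rate == 50, ]
  expect_equal(imp50$price, 30000)  # no at 10,000 -> no imputed at 30,000
  expect_equal(imp50$answer, 0L)

  expect_error(augment_records(aug, default_ladder), "already contain")
})

test_that("simulate_responses yields 6 per-respondent records with
           within-respondent monotone answers", {
  ro <- generate_respondents(population_config(n_respondents = 400,
                                               seed = 5))
  rec <- simulate_responses(ro, seed = 6)
  expect_equal(nrow(rec), 6L * 400L)
  counts <- table(rec$respondent_id, rec$rate)
  expect_true(all(counts == 3L))
  expect_true(all(table(rec$respondent_id, rec$origin) == 2L))
  # answers nonincreasing in price within each (respondent, rate)
  mono <- tapply(seq_len(nrow(rec)),
                 list(rec$respondent_id, rec$rate), function(i) {
                   o <- order(rec$price[i])
                   all(diff(rec$answer[i][o]) <= 0)
                 })
  expect_true(all(unlist(mono)))
  # every record agrees with the latent threshold
  wtp <- ifelse(rec$rate == 50,
                ro$latent_wtp_50[match(rec$respondent_id, ro$id)],
                ro$latent_wtp_90[match(rec$respondent_id, ro$id)])
  expect_identical(rec$answer, as.integer(wtp >= rec$price))
  expect_identical(simulate_responses(ro, seed = 6), rec)
})

test_that("simulate_responses agrees with per-respondent run_dbdc given
           the same bids", {
  ro <- generate_respondents(population_config(n_respondents = 30,
                                               seed = 13))
  rec <- simulate_responses(ro, seed = 14)
  for (i in seq_len(5)) {
    rows <- rec[rec$respondent_id == ro$id[i], ]
    bids <- rows$price[rows$origin == "asked_first"][
      order(rows$rate_order[rows$origin == "asked_first"])]
    man <- augment_records(run_dbdc(ro[i, ], default_ladder, bids),
                           default_ladder)
    key <- function(d) d[order(d$rate, d$price), c("rate", "price",
                                                   "answer", "origin")]
    expect_equal(key(man), key(rows), ignore_attr = TRUE)
  }
})

test_that("crra_utility covers the closed forms and the log limit", {
  expect_equal(crra_utility(12345, 0), 12345)
  expect_equal(crra_utility(1, c(-2, 0.5, 3)), 1 / (1 - c(-2, 0.5, 3)))
  expect_equal(crra_utility(20000, 1), log(20000))
  # the log branch is the gamma -> 1 limit: the symmetric average of the
  # power form at 1 +/- h converges to ln(x) as sinh(h ln x)/h
  h <- 1e-4
  sym <- (crra_utility(20000, 1 + h) + crra_utility(20000, 1 - h)) / 2
  expect_equal(sym, crra_utility(20000, 1), tolerance = 1e-6)
  expect_error(crra_utility(-1, 0), "positive")
})

test_that("gamma_from_switch matches an exhaustive grid oracle and
           top-codes never-switchers", {
  sched <- lottery_schedule()
  # oracle: largest gamma on the 0.001 grid in [-5, 5] with EU(B) >= EU(A)
  oracle <- function(p) {
    g <- seq(-5, 5, by = 0.001)
    eu <- function(hi, lo) p * crra_utility(hi, g) +
      (1 - p) * crra_utility(lo, g)
    diff <- eu(38500, 1000) - eu(20000, 16000)
    max(g[diff >= 0])
  }
  for (p in c(0.2, 0.5, 0.8, 0.9)) {
    got <- gamma_from_switch(sched, p)
    expect_equal(got$gamma, oracle(p), tolerance = 1e-9)
    expect_equal(got$topcode, 0L)
  }
  top <- gamma_from_switch(sched, 1.0)
  expect_equal(top$gamma, gamma_from_switch(sched, 0.9)$gamma)
  expect_equal(top$topcode, 1L)
  expect_error(gamma_from_switch(sched, 0.15), "grid")
})

test_that("gamma_from_switch is nondecreasing in the switch point and
           round-trips through the implied switch point", {
  sched <- lottery_schedule()
  g <- gamma_from_switch(sched, sched$p_grid)$gamma
  expect_true(all(diff(g) >= 0))
  # round trip: gamma -> switch point -> gamma -> same switch point
  for (gamma in c(-2, -0.5, 0, 0.3, 1, 1.3)) {
    p <- switch_point_from_gamma(sched, gamma)
    g2 <- gamma_from_switch(sched, p)$gamma
    expect_equal(switch_point_from_gamma(sched, g2), p)
  }
})

test_that("a degenerate schedule with identical lotteries reports the
           search boundary", {
  sched <- lottery_schedule(a_high = 20000, a_low = 16000,
                            b_high = 20000, b_low = 16000)
  expect_equal(gamma_from_switch(sched, 0.5)$gamma, 10)
})
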
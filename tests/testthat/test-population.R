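test_that("configuration validation rejects malformed inputs", {
  expect_error(population_config(n_respondents = -1), "non-negative")
  expect_error(population_config(arm_split = 1.2), "probability")
  expect_error(population_config(
    covariate_marginals = list(age_band = c(a = 0.6, b = 0.5))),
    "sum to 1")
  expect_error(population_config(
    true_coefficients = c(intercept = 1, price = 0.1,
                          reduction_rate = 0.01)),
    "negative")
  expect_error(population_config(
    true_coefficients = c(intercept = 1, price = -1e-5, bogus = 2)),
    "bogus")
})

test_that("generate_respondents handles the empty roster and is seeded", {
  empty <- generate_respondents(population_config(n_respondents = 0,
                                                  seed = 1))
  expect_equal(nrow(empty), 0L)

  cfg <- population_config(n_respondents = 200, seed = 42)
  r1 <- generate_respondents(cfg)
  r2 <- generate_respondents(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 200L)
  expect_true(all(r1$arm %in% c("perpetrator", "victim")))
  expect_true(all(r1$group %in% 1:2))
})

test_that("roster invariants hold: topcodes and latent-WTP ordering", {
  r <- generate_respondents(population_config(n_respondents = 2000,
                                              seed = 7))
  expect_identical(r$income_topcode, as.integer(r$household_income >= 20.5))
  expect_identical(r$risk_gamma_topcode, as.integer(r$p_switch == 1))
  # both default arms have positive reduction-rate coefficients, so the
  # shared-error construction makes WTP nondecreasing in the efficacy rate
  expect_true(all(r$latent_wtp_90 >= r$latent_wtp_50))
  expect_true(all(r$latent_wtp_50 >= 0))
  expect_true(all(r$aged_70 == 0 | r$age_band == "60+"))
})

test_that("empirical marginals match the configured splits at large n", {
  cfg <- population_config(n_respondents = 100000, seed = 11)
  r <- generate_respondents(cfg)
  perp <- r[r$arm == "perpetrator", ]
  expect_lt(abs(mean(perp$group == 1L) - 0.507), 0.005)
  expect_lt(abs(mean(r$arm == "perpetrator") - 1040 / 2085), 0.005)
  inc <- table(factor(r$household_income, levels = seq(0.5, 20.5, 1)))
  expect_lt(max(abs(inc / nrow(r) -
                      cfg$covariate_marginals$household_income)), 0.005)
})

test_that("latent_wtp evaluates the random-utility inversion", {
  prof <- data.frame(id = "x")
  cf <- c(intercept = 1.679, price = -5.46e-5, reduction_rate = 0.00461)
  expect_equal(latent_wtp(prof, 50, cf, error = 0),
               (1.679 + 0.00461 * 50) / 5.46e-5, tolerance = 1e-12)
  expect_equal(latent_wtp(prof, 50, cf, error = 0), 34972.53,
               tolerance = 1e-6)
  # boundary: V + error = 0 gives WTP 0
  expect_equal(latent_wtp(prof, 50, cf,
                          error = -(1.679 + 0.00461 * 50)), 0)
  # truncation at zero
  expect_equal(latent_wtp(prof, 50, cf, error = -10), 0)
  expect_error(latent_wtp(prof, 50, c(intercept = 1, price = 2), 0),
               "negative")
})

test_that("latent WTP survival matches the closed-form logit probability", {
  cf <- c(intercept = 1.5, price = -5.5e-5, reduction_rate = 0.005)
  prof <- data.frame(id = seq_len(1e6))
  set.seed(99)
  w <- latent_wtp(prof, 50, cf, error = stats::rlogis(1e6))
  v <- 1.5 + 0.005 * 50
  for (p in default_ladder$prices) {
    expect_lt(abs(mean(w >= p) - stats::plogis(v + cf[["price"]] * p)),
              0.005)
  }
})

test_that("latent_wtp is nondecreasing in rate when the rate effect is
           positive", {
  cf <- c(intercept = 0.5, price = -5e-5, reduction_rate = 0.008)
  prof <- data.frame(id = 1:500)
  set.seed(3)
  e <- stats::rlogis(500)
  expect_true(all(latent_wtp(prof, 90, cf, e) >=
                    latent_wtp(prof, 50, cf, e)))
})
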
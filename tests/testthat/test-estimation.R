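make_fitted <- function(n = 400, seed = 21, spec = "reduced",
                        truth = model3_coefs) {
  ro <- generate_respondents(reduced_config(n, truth, seed = seed))
  rec <- simulate_responses(ro, seed = seed + 1L)
  list(roster = ro, records = rec,
       design = build_design(rec, ro, spec = spec))
}

test_that("build_design lays out records with the documented codings", {
  f <- make_fitted(100)
  expect_equal(nrow(f$design), 600L)
  expect_named(f$design, c("respondent_id", "answer", "price",
                           "reduction_rate"))
  expect_true(all(f$design$reduction_rate %in% c(50, 90)))

  full <- build_design(f$records, f$roster, spec = "full")
  expect_true(all(covariate_names() %in% names(full)))
  expect_true(all(full$household_income %in% seq(0.5, 20.5, 1)))

  bad <- f$records
  bad$respondent_id[1] <- "nope"
  expect_error(build_design(bad, f$roster), "unknown respondent")
  expect_error(build_design(transform(f$records, price = price + 1),
                            f$roster, ladder = default_ladder),
               "ladder")
})

test_that("fit_logit maximises the same likelihood as a hand-coded
           Newton-free optimiser", {
  f <- make_fitted(300, seed = 31)
  fit <- fit_logit(f$design)
  # independent route: direct minimisation of the negative log-likelihood
  X <- cbind(1, f$design$price, f$design$reduction_rate)
  y <- f$design$answer
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000,
                              parscale = c(1, 1e-5, 1e-2)))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-8)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("degenerate designs raise informative estimation errors", {
  f <- make_fitted(50, seed = 41)
  const <- f$design
  const$answer <- 1L
  expect_error(fit_logit(const), "constant")
  aliased <- f$design
  aliased$price2 <- aliased$price * 2
  expect_error(fit_logit(aliased), "rank deficient")
  sep <- f$design
  sep$answer <- as.integer(sep$price <= 5000)
  # glm itself warns about degenerate fitted probabilities on the way
  suppressWarnings(expect_error(fit_logit(sep), "separation"))
})

test_that("estimates are invariant to row order and id relabeling, and
           price rescaling rescales beta_price exactly", {
  f <- make_fitted(200, seed = 51)
  fit <- fit_logit(f$design)
  set.seed(1)
  perm <- f$design[sample(nrow(f$design)), ]
  fit_p <- fit_logit(perm)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-8)

  relab <- f$design
  relab$respondent_id <- paste0("X", relab$respondent_id)
  expect_equal(fit_logit(relab)$coefficients, fit$coefficients,
               tolerance = 1e-10)

  thousands <- f$design
  thousands$price <- thousands$price / 1000
  fit_k <- fit_logit(thousands)
  expect_equal(fit_k$coefficients[["price"]],
               1000 * fit$coefficients[["price"]], tolerance = 1e-6)
  expect_equal(fit_k$z, fit$z, tolerance = 1e-6)
})

test_that("fit statistics follow their definitions", {
  expect_equal(round(mcfadden_r2(-1503.747, -1911.790), 3), 0.213)
  expect_equal(mcfadden_r2(-100, -100), 0)
  # Estrella: direct re-derivation from the definition
  ll <- -1503.747; ll0 <- -1911.790; n <- 6240
  direct <- 1 - exp(log(ll / ll0) * (-(2 / n) * ll0))
  expect_equal(estrella_r2(ll, ll0, n), direct, tolerance = 1e-10)
  expect_error(mcfadden_r2(-1, 0), "degenerate")

  f <- make_fitted(150, seed = 61)
  fit <- fit_logit(f$design)
  expect_equal(fit$lr_stat, 2 * (fit$loglik - fit$loglik_null))
  expect_gte(fit$lr_stat, 0)
  expect_true(fit$mcfadden_r2 >= 0 && fit$mcfadden_r2 < 1)
})

test_that("a single-replicate fit recovers the generating coefficients
           within 3 clustered SE", {
  truth <- c(intercept = 1.06, price = -5.28e-5, reduction_rate = 9.73e-3)
  ro <- generate_respondents(reduced_config(3000, truth, seed = 71))
  rec <- simulate_responses(ro, seed = 72)
  fit <- fit_logit(build_design(rec, ro))
  expect_true(all(abs(fit$coefficients - truth[names(fit$coefficients)])
                  <= 3 * fit$se_cluster))
  expect_gt(fit$coefficients[["reduction_rate"]], 0)
})
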
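# Printed reduced-model coefficient magnitudes used as fixed inputs in
# oracle checks (perpetrator and victim external-scope-test fits).
model1_coefs <- c(intercept = 1.679, price = -5.46e-5,
                  reduction_rate = 0.00461)
model3_coefs <- c(intercept = 1.060, price = -5.28e-5,
                  reduction_rate = 0.00973)

# Published WTP summary (yen) the formulas are checked against.
wtp_published <- data.frame(
  statistic = c("median", "median", "mean", "mean"),
  rate = c(50, 90, 50, 90),
  perpetrator = c(35005, 38388, 37536, 40516),
  victim = c(29266, 36631, 32919, 39181))

default_ladder <- price_ladder()

# Single-arm configuration with reduced-spec truth; handy for recovery and
# calibration simulations.
reduced_config <- function(n, truth, seed = NULL, group_split = 0.5) {
  population_config(
    n_respondents = n, arm_split = 1,
    group_split = c(perpetrator = group_split, victim = group_split),
    true_coefficients = list(perpetrator = truth, victim = truth),
    seed = seed)
}

# Minimal single-respondent profile with fixed latent WTPs.
tiny_profile <- function(wtp50, wtp90, group = 1L, id = "R00001") {
  data.frame(id = id, group = as.integer(group),
             latent_wtp_50 = wtp50, latent_wtp_90 = wtp90,
             stringsAsFactors = FALSE)
}

# Multiplicatively consistent two-year series whose previous-year-denominator
# factor rates are exactly d_pct/a_pct/l_pct.
series_from_rates <- function(d_pct, a_pct, l_pct,
                              base = c(D = 700e9, A = 8e-7, L = 9.5e6)) {
  y1 <- c(base, S = unname(base["D"] * base["A"] * base["L"]))
  D2 <- base[["D"]] * (1 + d_pct / 100)
  A2 <- base[["A"]] * (1 + a_pct / 100)
  L2 <- base[["L"]] * (1 + l_pct / 100)
  data.frame(year = c(1992, 1997),
             D = c(y1[["D"]], D2), A = c(y1[["A"]], A2),
             L = c(y1[["L"]], L2), S = c(y1[["S"]], D2 * A2 * L2))
}
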
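#' Simulate a survey and write all synthetic files
#'
#' Generates the roster, the 6-record-per-respondent DBDC response set and
#' the lottery switch-point file, plus a `manifest.json` recording the
#' seed, a configuration hash and the file row counts. Runs are
#' byte-reproducible for a fixed configuration and seed.
#'
#' @param config a pipeline configuration (list with `population`, `ladder`,
#'   `seed`; see [read_pipeline_config()]) or a bare
#'   [population_config()].
#' @param outdir output directory (created if needed).
#' @return invisible list with the in-memory `roster` and `records` and the
#'   file `paths`.
#' @export
cmd_simulate <- function(config, outdir) {
  if (inherits(config, "perploss_config"))
    config <- list(seed = config$seed, population = config,
                   ladder = price_ladder(), valuation = valuation_input())
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  roster <- generate_respondents(config$population)
  records <- simulate_responses(
    roster, config$ladder,
    initial_bid_probs = config$population$initial_bid_probs)
  lottery <- data.frame(respondent_id = roster$id,
                        p_switch = roster$p_switch)
  paths <- list(roster = file.path(outdir, "roster.csv"),
                responses = file.path(outdir, "responses.csv"),
                lottery = file.path(outdir, "lottery.csv"),
                manifest = file.path(outdir, "manifest.json"))
  write_roster(roster, paths$roster)
  write_responses(records, paths$responses)
  utils::write.csv(lottery, paths$lottery, row.names = FALSE)
  manifest <- list(seed = config$population$seed,
                   config_hash = config_hash(config),
                   n_respondents = nrow(roster),
                   n_response_records = nrow(records),
                   n_lottery_rows = nrow(lottery))
  write_json_report(manifest, paths$manifest)
  invisible(list(roster = roster, records = records, paths = paths))
}

# md5 of the canonical JSON serialisation of the configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Fit the estimation-table models and write the fit reports
#'
#' Fits the reduced (external scope-test) and full-covariate logit models
#' on data subset III (first-presented rate only — the ordering-effect-free
#' subset) for each survey arm present in the data.
#'
#' @param roster_file,responses_file CSV inputs.
#' @param outdir output directory for `fit_<arm>_<spec>.json` reports.
#' @param ladder a [price_ladder()].
#' @return invisible named list of `perploss_logit` fits
#'   (`<arm>_reduced`, `<arm>_full`).
#' @export
cmd_estimate <- function(roster_file, responses_file, outdir,
                         ladder = price_ladder()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  roster <- read_roster(roster_file)
  records <- read_responses(responses_file, ladder)
  fits <- list()
  for (a in intersect(c("perpetrator", "victim"), unique(roster$arm))) {
    r <- roster[roster$arm == a, , drop = FALSE]
    rec <- records[records$respondent_id %in% r$id, , drop = FALSE]
    sub3 <- make_subset(rec, r, "III")
    for (sp in c("reduced", "full")) {
      fit <- fit_logit(build_design(sub3$records, r, spec = sp))
      fits[[paste(a, sp, sep = "_")]] <- fit
      write_fit_report(fit, file.path(outdir,
                                      sprintf("fit_%s_%s.json", a, sp)))
    }
  }
  invisible(fits)
}

#' Compute the WTP summary table and write its report
#'
#' Consumes the subset-III reduced fits of both arms (the headline model
#' choice) and writes the median/mean WTP table with
#' perpetrator-to-victim ratios.
#'
#' @inheritParams cmd_estimate
#' @return invisible [wtp_table()] data frame.
#' @export
cmd_wtp <- function(roster_file, responses_file, outdir,
                    ladder = price_ladder()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fits <- cmd_estimate(roster_file, responses_file, outdir, ladder)
  if (is.null(fits$perpetrator_reduced) || is.null(fits$victim_reduced))
    stop("WTP table needs both survey arms in the data", call. = FALSE)
  tab <- wtp_table(fits$perpetrator_reduced, fits$victim_reduced)
  write_json_report(tab, file.path(outdir, "wtp.json"))
  invisible(tab)
}

#' Run the scope tests and write their report
#'
#' @inheritParams cmd_estimate
#' @param inference `"naive"` or `"cluster"` (see [run_scope_test()]).
#' @return invisible named list of per-arm scope tables.
#' @export
cmd_scope <- function(roster_file, responses_file, outdir,
                      ladder = price_ladder(),
                      inference = c("naive", "cluster")) {
  inference <- match.arg(inference)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  roster <- read_roster(roster_file)
  records <- read_responses(responses_file, ladder)
  out <- list()
  for (a in intersect(c("perpetrator", "victim"), unique(roster$arm))) {
    r <- roster[roster$arm == a, , drop = FALSE]
    rec <- records[records$respondent_id %in% r$id, , drop = FALSE]
    tab <- scope_test_all(rec, r, inference = inference)
    attr(tab, "fits") <- NULL
    out[[a]] <- tab
  }
  write_json_report(out, file.path(outdir, "scope.json"))
  invisible(out)
}

#' Anchor perpetrator losses to the victim reference value
#'
#' @param wtp a [wtp_table()] data frame, or a path to the `wtp.json`
#'   report written by [cmd_wtp()].
#' @param outdir output directory for `valuation.json`.
#' @param input a [valuation_input()].
#' @return invisible [valuation_table()] data frame.
#' @export
cmd_value <- function(wtp, outdir, input = valuation_input()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(wtp))
    wtp <- as.data.frame(jsonlite::read_json(wtp, simplifyVector = TRUE))
  tab <- valuation_table(wtp, input)
  write_json_report(tab, file.path(outdir, "valuation.json"))
  invisible(tab)
}

#' Decompose a yearly loss series and write the report
#'
#' @param series_file CSV with columns `year`, `D`, `A`, `L` (and
#'   optionally `S`).
#' @param outdir output directory for `decomposition.json`.
#' @inheritParams decompose
#' @return invisible [decompose_losses()] data frame.
#' @export
cmd_decompose <- function(series_file, outdir,
                          denominator = c("current", "previous")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- decompose_losses(read_year_losses(series_file),
                          denominator = denominator)
  write_json_report(tab, file.path(outdir, "decomposition.json"))
  invisible(tab)
}

#' Run the full pipeline in memory
#'
#' Simulate, estimate (subset-III reduced and full fits per arm), summarise
#' WTP, run scope tests and anchor the valuation, without touching disk.
#'
#' @param config pipeline configuration (see [cmd_simulate()]).
#' @param inference inference flavour for the scope tests.
#' @return list with `roster`, `records`, `fits`, `wtp`, `scope`,
#'   `valuation`.
#' @export
run_pipeline <- function(config, inference = c("naive", "cluster")) {
  inference <- match.arg(inference)
  if (inherits(config, "perploss_config"))
    config <- list(seed = config$seed, population = config,
                   ladder = price_ladder(), valuation = valuation_input())
  roster <- generate_respondents(config$population)
  records <- simulate_responses(
    roster, config$ladder,
    initial_bid_probs = config$population$initial_bid_probs)
  fits <- list(); scope <- list()
  for (a in intersect(c("perpetrator", "victim"), unique(roster$arm))) {
    r <- roster[roster$arm == a, , drop = FALSE]
    rec <- records[records$respondent_id %in% r$id, , drop = FALSE]
    sub3 <- make_subset(rec, r, "III")
    fits[[paste0(a, "_reduced")]] <-
      fit_logit(build_design(sub3$records, r, "reduced"))
    fits[[paste0(a, "_full")]] <-
      fit_logit(build_design(sub3$records, r, "full"))
    sc <- scope_test_all(rec, r, inference = inference)
    attr(sc, "fits") <- NULL
    scope[[a]] <- sc
  }
  wtp <- if (!is.null(fits$perpetrator_reduced) &&
             !is.null(fits$victim_reduced))
    wtp_table(fits$perpetrator_reduced, fits$victim_reduced)
  valuation <- if (!is.null(wtp))
    valuation_table(wtp, config$valuation %||% valuation_input())
  list(roster = roster, records = records, fits = fits, wtp = wtp,
       scope = scope, valuation = valuation)
}
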
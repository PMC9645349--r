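#' Write a roster to CSV
#'
#' One row per respondent; the generating seed (if any) is recorded as a
#' `# seed:` comment line above the header.
#'
#' @param roster a `perploss_roster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(roster, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(as.data.frame(roster), con, row.names = FALSE)
  invisible(path)
}

#' Read a roster CSV
#'
#' @param path roster file written by [write_roster()] (comment lines
#'   starting with `#` are skipped).
#' @return a `perploss_roster` data frame.
#' @export
read_roster <- function(path) {
  roster <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  if (!all(c("id", "arm", "group") %in% names(roster)))
    stop("roster file lacks id/arm/group columns: ", path, call. = FALSE)
  if (anyDuplicated(roster$id))
    stop("duplicate respondent ids in ", path, call. = FALSE)
  class(roster) <- c("perploss_roster", "data.frame")
  roster
}

#' Write response records to CSV
#' @param records response record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read response records from CSV
#'
#' Schema: `respondent_id`, `rate`, `price`, `answer`, `origin`,
#' `rate_order`, with answers strictly 0/1 and prices on the ladder.
#' Imputed rows are never trusted from input files: any rows with
#' `origin = "imputed"` are dropped and the rational imputation is redone
#' from the `asked_first` rows.
#'
#' @param path CSV path.
#' @param ladder a [price_ladder()] used for validation and re-imputation.
#' @param augment redo the rational imputation (default `TRUE`).
#' @return response record data frame.
#' @export
read_responses <- function(path, ladder = price_ladder(), augment = TRUE) {
  rec <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("respondent_id", "rate", "price", "answer", "origin",
            "rate_order")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stop("response file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!rec$answer %in% c(0L, 1L))
  if (length(bad) > 0)
    stop("non-binary answer at row ", bad[1L], " of ", path,
         call. = FALSE)
  bad <- which(!rec$price %in% ladder$prices)
  if (length(bad) > 0)
    stop("price not on ladder at row ", bad[1L], " of ", path,
         call. = FALSE)
  rec <- rec[rec$origin != "imputed", , drop = FALSE]
  if (augment) rec <- augment_records(rec, ladder)
  rec
}

#' Read a lottery switch-point file
#' @param path CSV with columns `respondent_id`, `p_switch`.
#' @param schedule a [lottery_schedule()] for grid validation.
#' @return data frame with `respondent_id`, `p_switch`, `risk_gamma`,
#'   `risk_gamma_topcode`.
#' @export
read_lottery <- function(path, schedule = lottery_schedule()) {
  lot <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!all(c("respondent_id", "p_switch") %in% names(lot)))
    stop("lottery file lacks respondent_id/p_switch columns",
         call. = FALSE)
  g <- gamma_from_switch(schedule, lot$p_switch)
  lot$risk_gamma <- g$gamma
  lot$risk_gamma_topcode <- g$topcode
  lot
}

#' Read a yearly loss series from CSV
#' @param path CSV with columns `year`, `D`, `A`, `L` and optionally `S`.
#' @return a [year_losses()] data frame.
#' @export
read_year_losses <- function(path) {
  year_losses(utils::read.csv(path, comment.char = "#"))
}

#' Write a logit fit report as JSON
#'
#' Mirrors the published estimation-table layout: per coefficient the
#' estimate, z-value and a 5%-level significance flag, plus the fit
#' statistics.
#'
#' @param fit a `perploss_logit`.
#' @param path output JSON path.
#' @param inference which z-values flag significance, `"naive"` or
#'   `"cluster"`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path,
                             inference = c("naive", "cluster")) {
  inference <- match.arg(inference)
  p <- if (inference == "cluster") fit$p_cluster else fit$p_value
  z <- if (inference == "cluster") fit$z_cluster else fit$z
  rep <- list(
    specification = fit$spec,
    inference = inference,
    coefficients = lapply(seq_along(fit$coefficients), function(i) list(
      name = names(fit$coefficients)[i],
      estimate = unname(fit$coefficients[i]),
      z = unname(z[i]),
      significant_5pct = unname(p[i] < 0.05))),
    n_obs = fit$n_obs,
    n_respondents = fit$n_respondents,
    loglik = fit$loglik,
    loglik_null = fit$loglik_null,
    mcfadden_r2 = fit$mcfadden_r2,
    estrella_r2 = fit$estrella_r2,
    lr_stat = fit$lr_stat,
    lr_df = fit$lr_df,
    lr_pvalue = fit$lr_pvalue)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) file with optional keys `seed`,
#' `population` (arguments of [population_config()]), `ladder` (arguments
#' of [price_ladder()]), and `valuation` (arguments of
#' [valuation_input()]). Unknown keys raise an error naming the key.
#'
#' @param path configuration file.
#' @return list with `seed`, `population`, `ladder`, `valuation`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "population", "ladder", "valuation")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pop_args <- raw$population %||% list()
  if (length(pop_args) > 0) {
    ok <- names(formals(population_config))
    unknown <- setdiff(names(pop_args), ok)
    if (length(unknown) > 0)
      stop("unknown population key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!is.null(pop_args$covariate_marginals))
      pop_args$covariate_marginals <-
        lapply(pop_args$covariate_marginals, function(x)
          if (is.list(x)) unlist(x) else x)
    if (!is.null(pop_args$true_coefficients))
      pop_args$true_coefficients <-
        lapply(pop_args$true_coefficients, function(x)
          if (is.list(x)) unlist(x) else x)
  }
  if (!is.null(raw$seed) && is.null(pop_args$seed))
    pop_args$seed <- raw$seed
  list(seed = raw$seed,
       population = do.call(population_config, pop_args),
       ladder = do.call(price_ladder, raw$ladder %||% list()),
       valuation = if (is.null(raw$valuation)) valuation_input() else
         do.call(valuation_input, raw$valuation))
}
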
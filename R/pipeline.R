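# End-to-end orchestration: one call from parameter file (or the packaged
# defaults) to the full set of decision outputs.

#' Run configuration
#'
#' @param scenario `"base"` (licensed interventions only), `"all"`
#'   (all fourteen) or `"no_adverse_events"` (all fourteen,
#'   depression/self-harm removed).
#' @param seed integer seed controlling every random element (PSA sampling,
#'   relative-effect draws, bootstrap intervals).
#' @param psa_draws number of Monte Carlo draws (default: the parameter
#'   set's `economics$psa_draws`, 5,000 in the packaged defaults).
#' @param wtp willingness-to-pay threshold (default: the parameter set's).
#' @param reference reference intervention for incremental net benefit.
#' @param parameter_file optional YAML parameter file; the packaged default
#'   set is generated when omitted.
#' @param wtp_grid thresholds for the acceptability curves.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = c("base", "all", "no_adverse_events"),
                       seed = 1L, psa_draws = NULL, wtp = NULL,
                       reference = "nrt_low", parameter_file = NULL,
                       wtp_grid = seq(0, 50000, by = 2500)) {
  scenario <- match.arg(scenario)
  if (!is.null(psa_draws) && psa_draws < 1) stop("psa_draws must be >= 1")
  structure(list(scenario = scenario, seed = as.integer(seed),
                 psa_draws = psa_draws, wtp = wtp, reference = reference,
                 parameter_file = parameter_file, wtp_grid = wtp_grid),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) the parameter set, samples the PSA draw set, runs
#' the cohort model for every draw and intervention, and assembles the
#' decision outputs: the CEA table (expected costs/QALYs, dominance status,
#' sequential ICERs, incremental expected net benefit, median ranks), the
#' acceptability curves, the rank-o-gram, and — when the scenario includes
#' both NRT standard and varenicline standard — the value-of-information
#' table. Deterministic under `(seed, config)`.
#'
#' @param cfg a [run_config()].
#' @return a `result_bundle` list with elements `cea_table`, `frontier`,
#'   `ceac`, `rankogram`, `voi_table`, `nb` (the net-benefit matrix),
#'   `psa` (the draw set), and `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  ps <- if (is.null(cfg$parameter_file)) {
    generate_default_parameters(cfg$seed)
  } else {
    load_parameters(cfg$parameter_file)
  }
  n <- cfg$psa_draws %||% ps$economics$psa_draws
  wtp <- cfg$wtp %||% ps$economics$wtp

  psa <- sample_psa(ps, n = n, seed = cfg$seed)
  m <- run_psa(psa, scenario = cfg$scenario)

  eo <- expected_outcomes(m)
  frontier <- efficiency_frontier(eo)
  set.seed(cfg$seed + 2L)
  reference <- if (cfg$reference %in% m$interventions) cfg$reference
               else m$interventions[which.min(eo$cost)]
  enb <- net_benefit(m, wtp, reference = reference)
  cc <- ceac(m, cfg$wtp_grid)
  rk <- rankogram(m, wtp)

  cea_table <- merge(frontier, enb, by = "intervention_id", sort = FALSE)
  cea_table$median_rank <- rk$median_rank[cea_table$intervention_id]
  cea_table$rank_q25 <- rk$rank_iqr["q25", cea_table$intervention_id]
  cea_table$rank_q75 <- rk$rank_iqr["q75", cea_table$intervention_id]
  cea_table <- cea_table[order(cea_table$cost), ]
  rownames(cea_table) <- NULL

  voi_table <- NULL
  if (all(c("nrt_std", "varenicline_std") %in% m$interventions)) {
    set.seed(cfg$seed + 3L)
    voi_table <- voi_report(m, psa$param_matrix, wtp,
                            population = ps$economics$population_per_year)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("quitcea")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    scenario = cfg$scenario, seed = cfg$seed, psa_draws = n, wtp = wtp,
    reference = reference,
    interventions = m$interventions,
    wall_time_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(cea_table = cea_table, frontier = frontier, ceac = cc,
                 rankogram = rk, voi_table = voi_table, nb = m, psa = psa,
                 manifest = manifest),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle: scenario '", x$manifest$scenario, "', ",
      x$manifest$psa_draws, " draws, seed ", x$manifest$seed, ">\n",
      sep = "")
  print(format_cea_table(x$cea_table))
  invisible(x)
}

#' Format a CEA table for reporting
#'
#' Applies the reporting conventions of the published tables: costs rounded
#' to the pound, QALYs to three decimals, ICERs to the pound, dominance
#' shown as text.
#'
#' @param cea_table the `cea_table` element of a [run_pipeline()] bundle.
#' @return a data.frame ready for printing or CSV export.
#' @export
format_cea_table <- function(cea_table) {
  icer_lab <- ifelse(
    cea_table$status == "dominated", "Dominated",
    ifelse(cea_table$status == "extendedly_dominated", "Extendedly dominated",
           ifelse(is.na(cea_table$icer), "",
                  paste0("£", format(round(cea_table$icer),
                                     big.mark = ",", trim = TRUE)))))
  data.frame(
    intervention = cea_table$intervention_id,
    total_cost = round(cea_table$cost),
    total_qalys = round(cea_table$qaly, 3),
    icer = icer_lab,
    enb = round(cea_table$enb),
    enb_95ci = sprintf("(%d, %d)", round(cea_table$lo), round(cea_table$hi)),
    median_rank = cea_table$median_rank,
    rank_iqr = sprintf("(%d-%d)", cea_table$rank_q25, cea_table$rank_q75),
    stringsAsFactors = FALSE
  )
}

#' Write all pipeline reports to a directory
#'
#' Writes `cea_table.csv`, `ceac.csv`, `rankogram.csv`, `voi_table.csv`
#' (when computed), `psa_summary.csv` and `manifest.json`. Refuses to
#' overwrite existing report files unless `overwrite = TRUE`.
#'
#' @param bundle a [run_pipeline()] result bundle.
#' @param dir output directory (created if needed).
#' @param overwrite allow replacing existing files.
#' @return character vector of the files written, invisibly.
#' @export
write_reports <- function(bundle, dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, c("cea_table.csv", "ceac.csv", "rankogram.csv",
                            "voi_table.csv", "psa_summary.csv",
                            "manifest.json"))
  names(files) <- c("cea_table", "ceac", "rankogram", "voi_table",
                    "psa_summary", "manifest")
  existing <- files[file.exists(files)]
  if (length(existing) && !overwrite) {
    stop("refusing to overwrite existing report file(s): ",
         paste(basename(existing), collapse = ", "),
         " (use overwrite = TRUE)")
  }
  w <- function(df, f) utils::write.csv(df, f, row.names = FALSE)

  w(format_cea_table(bundle$cea_table), files["cea_table"])
  w(bundle$ceac, files["ceac"])

  rk <- bundle$rankogram
  rk_df <- data.frame(intervention = rownames(rk$prob), rk$prob,
                      median_rank = rk$median_rank,
                      rank_q25 = rk$rank_iqr["q25", ],
                      rank_q75 = rk$rank_iqr["q75", ],
                      check.names = FALSE)
  w(rk_df, files["rankogram"])

  written <- files[c("cea_table", "ceac", "rankogram")]
  if (!is.null(bundle$voi_table)) {
    vt <- bundle$voi_table
    vt$pop_1y_million <- round(vt$pop_1y_million)
    vt$pop_5y_million <- round(vt$pop_5y_million)
    w(vt, files["voi_table"])
    written <- c(written, files["voi_table"])
  }

  eo <- expected_outcomes(bundle$nb)
  sds <- data.frame(cost_sd = apply(bundle$nb$cost, 2, stats::sd),
                    qaly_sd = apply(bundle$nb$qaly, 2, stats::sd))
  w(cbind(eo, sds), files["psa_summary"])
  written <- c(written, files["psa_summary"])

  jsonlite::write_json(bundle$manifest, files["manifest"],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  written <- c(written, files["manifest"])
  invisible(unname(written))
}
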
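# High-level analysis drivers and report writers. These functions are the
# package's entry points for the full evaluation: run every strategy,
# compare against standard care, build the LY- and QALY-based efficiency
# frontiers, and write the result tables.

#' Run the cohort model for a set of strategies
#'
#' @param params a `boc_params` object.
#' @param strategies list of `boc_strategy` objects; defaults to the full
#'   16-strategy catalog.
#' @param config analysis configuration; defaults to `params$analysis`.
#' @return data frame with one row per strategy: life years, QALYs and
#'   lifetime costs (undiscounted and discounted), lifetime cumulative
#'   incidence and cancer-specific mortality per cancer.
#' @export
run_strategies <- function(params, strategies = strategy_catalog(),
                           config = NULL) {
  rows <- lapply(strategies, function(s) {
    tr <- run_cohort(s, params, config)
    o <- lifetime_outcomes(tr, params, config)
    data.frame(strategy_id = o$strategy_id, label = o$label,
               ly = o$ly, qaly = o$qaly,
               ly_disc = o$ly_disc, qaly_disc = o$qaly_disc,
               cost_undisc = o$cost_undisc, cost_disc = o$cost_disc,
               incidence_breast = o$incidence[["breast"]],
               incidence_ovarian = o$incidence[["ovarian"]],
               mortality_breast = o$mortality[["breast"]],
               mortality_ovarian = o$mortality[["ovarian"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full base-case analysis
#'
#' Runs all requested strategies, compares them to standard care and builds
#' the efficiency frontiers on both effect scales (discounted LY and
#' discounted QALY, with discounted costs).
#'
#' @inheritParams run_strategies
#' @param reference_id comparator for the incremental table (default 1,
#'   standard care).
#' @return list of class `boc_analysis` with elements `outcomes`,
#'   `incremental`, `frontier_ly`, `frontier_qaly`, `params_config`.
#' @export
run_base_case <- function(params, strategies = strategy_catalog(),
                          config = NULL, reference_id = 1) {
  if (is.null(config)) config <- params$analysis
  outcomes <- run_strategies(params, strategies, config)
  incremental <- if (reference_id %in% outcomes$strategy_id)
    compare_to_reference(outcomes, reference_id) else NULL
  structure(list(
    outcomes = outcomes,
    incremental = incremental,
    frontier_ly = efficiency_frontier(strategy_points(outcomes, "ly"),
                                      wtp = config$wtp),
    frontier_qaly = efficiency_frontier(strategy_points(outcomes, "qaly"),
                                        wtp = config$wtp),
    config = config), class = "boc_analysis")
}

#' @export
print.boc_analysis <- function(x, ...) {
  cat("Base-case analysis:", nrow(x$outcomes), "strategies\n")
  cat("LY frontier reference:", x$frontier_ly$reference_id,
      "| QALY frontier reference:", x$frontier_qaly$reference_id, "\n")
  invisible(x)
}

#' Write analysis result tables
#'
#' Writes per-strategy outcomes, the incremental-versus-standard-care
#' table, both frontier tables (strategy, effect, cost, classification,
#' stepwise ratio) and a JSON run manifest (parameter hash, configuration
#' echo, package version) into a directory. All tables are plain CSV,
#' re-readable with `read.csv`.
#'
#' @param analysis a `boc_analysis` from [run_base_case()].
#' @param dir output directory (created if needed).
#' @param params the parameter set used (hashed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(analysis$outcomes, "outcomes.csv")
  if (!is.null(analysis$incremental))
    w(analysis$incremental, "incremental_vs_reference.csv")
  frontier_table <- function(fr) {
    tab <- fr$points
    tab$step_icer <- fr$chain$step_icer[match(tab$id, fr$chain$id)]
    tab
  }
  w(frontier_table(analysis$frontier_ly), "frontier_ly.csv")
  w(frontier_table(analysis$frontier_qaly), "frontier_qaly.csv")
  manifest <- list(
    package = "bocprev",
    version = as.character(utils::packageVersion("bocprev")),
    config = analysis$config,
    params_hash = if (!is.null(params)) params_hash(params) else NA,
    n_strategies = nrow(analysis$outcomes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @keywords internal
params_hash <- function(params) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  unname(tools::md5sum(tmp))
}
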
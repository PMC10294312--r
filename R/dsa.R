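# One-way deterministic sensitivity analysis: vary one parameter group at
# a time over a grid, re-run every strategy, rebuild the frontiers and
# report rank-order stability versus the base case.

#' Specify a one-way sensitivity analysis
#'
#' Each scenario varies a single parameter group jointly: all utilities, or
#' all surgery relative risks, are multiplied by a common factor (clipped
#' to \[0, 1\]); all costs are multiplied; or the discount rate is set to a
#' value. Defaults follow the evaluated ranges: utilities and effect
#' measures plus/minus 20%, costs 50% to 200%, discount rate 1% to 10%.
#'
#' @param group one of `"utilities"`, `"effect_measures"`, `"costs"`,
#'   `"discount_rate"`.
#' @param values numeric grid: multipliers for the first three groups,
#'   rates for `discount_rate`. Defaults per group include the base case.
#' @return object of class `dsa_spec`.
#' @export
dsa_spec <- function(group = c("utilities", "effect_measures", "costs",
                               "discount_rate"),
                     values = NULL) {
  group <- match.arg(group)
  if (is.null(values))
    values <- switch(group,
                     utilities = c(0.8, 1, 1.2),
                     effect_measures = c(0.8, 1, 1.2),
                     costs = c(0.5, 1, 2),
                     discount_rate = c(0.01, 0.03, 0.05, 0.10))
  base <- if (group == "discount_rate") NA else 1
  structure(list(group = group, values = values, base = base),
            class = "dsa_spec")
}

#' Apply a sensitivity scenario to a parameter set
#'
#' @param params a `boc_params`.
#' @param group parameter group (see [dsa_spec()]).
#' @param value multiplier (utilities, effect measures, costs) or rate
#'   (discount_rate).
#' @return modified, re-validated `boc_params`.
#' @export
apply_scenario <- function(params, group, value) {
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  if (group == "utilities") {
    u <- params$utilities
    u$well <- clip01(u$well * value)
    u$remission <- clip01(u$remission * value)
    u$detected <- lapply(u$detected, function(v) clip01(v * value))
    u$undetected <- lapply(u$undetected, function(v) clip01(v * value))
    u$surgery <- clip01(u$surgery * value)
    params$utilities <- u
  } else if (group == "effect_measures") {
    ef <- params$effects
    for (k in c("rr_breast_pbm", "rr_breast_pbso", "rr_breast_both",
                "rr_ovarian_pbso", "rr_ovarian_both"))
      ef[[k]] <- min(ef[[k]] * value, 1)
    params$effects <- ef
  } else if (group == "costs") {
    co <- params$costs
    co$surveillance <- co$surveillance * value
    co$surgery <- co$surgery * value
    co$initial <- lapply(co$initial, function(m) m * value)
    co$followup <- lapply(co$followup, function(m) m * value)
    co$palliative <- co$palliative * value
    params$costs <- co
  } else if (group == "discount_rate") {
    params$analysis$discount_rate <- value
  } else stop("unknown sensitivity group: ", group)
  validate_params(params)
  params
}

#' Run a one-way deterministic sensitivity analysis
#'
#' Re-runs all strategies and both efficiency frontiers at every grid point
#' of the spec, varying only the named parameter group, and flags scenarios
#' whose frontier membership or strategy rank order (by effect or cost)
#' differs from the base case. Fully deterministic.
#'
#' @param spec a `dsa_spec`.
#' @param params base-case `boc_params`.
#' @param strategies strategy list; defaults to the 16-strategy catalog.
#' @return object of class `dsa_result`: per-scenario list with outcomes,
#'   frontiers, rank orders and change flags, plus the base-case analysis.
#' @export
run_dsa <- function(spec, params, strategies = strategy_catalog()) {
  stopifnot(inherits(spec, "dsa_spec"))
  base <- run_base_case(params, strategies)
  rank_of <- function(outcomes, col)
    outcomes$strategy_id[order(-outcomes[[col]], outcomes$strategy_id)]
  base_ranks <- list(ly = rank_of(base$outcomes, "ly"),
                     cost = rank_of(base$outcomes, "cost_disc"))
  frontier_ids <- function(an, scale)
    sort(an[[paste0("frontier_", scale)]]$chain$id)

  scenarios <- lapply(spec$values, function(v) {
    p2 <- apply_scenario(params, spec$group, v)
    an <- run_base_case(p2, strategies, config = p2$analysis)
    list(
      value = v,
      outcomes = an$outcomes,
      frontier_ly = an$frontier_ly,
      frontier_qaly = an$frontier_qaly,
      rank_by_ly = rank_of(an$outcomes, "ly"),
      rank_by_cost = rank_of(an$outcomes, "cost_disc"),
      frontier_changed =
        !identical(frontier_ids(an, "ly"), frontier_ids(base, "ly")) ||
        !identical(frontier_ids(an, "qaly"), frontier_ids(base, "qaly")),
      rank_changed =
        !identical(rank_of(an$outcomes, "ly"), base_ranks$ly) ||
        !identical(rank_of(an$outcomes, "cost_disc"), base_ranks$cost))
  })
  names(scenarios) <- format(spec$values, trim = TRUE)
  structure(list(spec = spec, base = base, scenarios = scenarios),
            class = "dsa_result")
}

#' Long-format summary of a sensitivity analysis
#'
#' @param result a `dsa_result`.
#' @return data frame with columns `group`, `scenario`, `strategy_id`,
#'   `outcome`, `value` (one row per strategy, outcome and scenario).
#' @export
dsa_to_df <- function(result) {
  rows <- lapply(result$scenarios, function(sc) {
    o <- sc$outcomes
    long <- utils::stack(o[c("ly", "qaly", "ly_disc", "qaly_disc",
                             "cost_undisc", "cost_disc")])
    data.frame(group = result$spec$group, scenario = sc$value,
               strategy_id = rep(o$strategy_id, 6),
               outcome = as.character(long$ind), value = long$values)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dsa_result <- function(x, ...) {
  cat(sprintf("One-way DSA on %s: %d scenarios\n", x$spec$group,
              length(x$scenarios)))
  for (sc in x$scenarios)
    cat(sprintf("  value %-6s frontier changed: %-5s rank changed: %s\n",
                format(sc$value), sc$frontier_changed, sc$rank_changed))
  invisible(x)
}
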
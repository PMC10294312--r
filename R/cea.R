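# Cost-effectiveness comparison: ICERs, strong and extended dominance,
# efficiency frontier, willingness-to-pay classification.

#' Incremental cost-effectiveness ratio between two strategy points
#'
#' `(cost_high - cost_low) / (effect_high - effect_low)`, for a point pair
#' ordered by effect. Equal effects have no defined ratio and raise an
#' error. A negative cost difference with a positive effect difference is
#' permitted (the higher point dominates; the ratio is not used on a
#' frontier).
#'
#' @param point_low,point_high lists or one-row data frames with elements
#'   `effect` and `cost`.
#' @return cost per unit effect (EUR per LY or QALY gained).
#' @export
icer <- function(point_low, point_high) {
  de <- point_high$effect - point_low$effect
  dc <- point_high$cost - point_low$cost
  if (de <= 0) stop("icer() requires point_high to have the larger effect")
  dc / de
}

#' Efficiency frontier with strong and extended dominance
#'
#' Classifies strategy points as on-frontier, strongly dominated (another
#' point has at least the effect for at most the cost, one strictly) or
#' extended-dominated (a convex combination of two other points does), and
#' returns the frontier chain -- the lower-left convex hull in (effect,
#' cost) space -- with stepwise ICERs, which are strictly increasing by
#' construction. Among identical points the lowest id is retained.
#'
#' @param points data frame with columns `id`, `effect`, `cost`.
#' @param wtp optional willingness-to-pay threshold used to flag
#'   cost-effective frontier steps.
#' @return an object of class `frontier_result`: list with `points` (the
#'   input plus `classification` and a dominance certificate), `chain`
#'   (frontier strategies ordered by effect with `step_icer`), and
#'   `reference_id` (least costly non-dominated strategy).
#' @export
efficiency_frontier <- function(points, wtp = NULL) {
  stopifnot(all(c("id", "effect", "cost") %in% names(points)), nrow(points) >= 1)
  p <- points[c("id", "effect", "cost")]
  if (any(!is.finite(p$effect)) || any(!is.finite(p$cost)))
    stop("effects and costs must be finite")
  n <- nrow(p)
  classification <- rep("on-frontier", n)
  certificate <- rep(NA_character_, n)

  # strong (weak-inequality) dominance, duplicate ties broken by lower id
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- (p$effect[j] >= p$effect[i] && p$cost[j] <= p$cost[i]) &&
        (p$effect[j] > p$effect[i] || p$cost[j] < p$cost[i])
      tie <- p$effect[j] == p$effect[i] && p$cost[j] == p$cost[i] &&
        p$id[j] < p$id[i]
      if (better || tie) {
        classification[i] <- "strongly-dominated"
        certificate[i] <- paste0("dominated-by:", p$id[j])
        break
      }
    }
  }

  cand <- which(classification == "on-frontier")
  cand <- cand[order(p$effect[cand], p$id[cand])]
  # walk by increasing effect, popping points that break ICER monotonicity
  chain <- integer(0)
  for (k in cand) {
    repeat {
      m <- length(chain)
      if (m < 2) break
      icer_last <- icer(p[chain[m - 1], ], p[chain[m], ])
      icer_new <- icer(p[chain[m], ], p[k, ])
      if (icer_new <= icer_last) {
        classification[chain[m]] <- "extended-dominated"
        certificate[chain[m]] <- paste0("mixed:", p$id[chain[m - 1]], "+", p$id[k])
        chain <- chain[-m]
      } else break
    }
    chain <- c(chain, k)
  }

  chain_df <- p[chain, ]
  chain_df$step_icer <- c(NA_real_,
                          if (length(chain) > 1)
                            vapply(seq_len(length(chain) - 1), function(i)
                              icer(chain_df[i, ], chain_df[i + 1, ]), 0))
  if (!is.null(wtp))
    chain_df$cost_effective <- is.na(chain_df$step_icer) | chain_df$step_icer <= wtp
  rownames(chain_df) <- NULL
  out_points <- points
  out_points$classification <- classification
  out_points$certificate <- certificate
  structure(list(points = out_points, chain = chain_df,
                 reference_id = chain_df$id[1]),
            class = "frontier_result")
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("Efficiency frontier (", nrow(x$chain), " of ", nrow(x$points),
      " strategies; reference id ", x$reference_id, ")\n", sep = "")
  print(x$chain, digits = 6)
  invisible(x)
}

#' Strategy points for frontier construction
#'
#' Extracts (effect, cost) pairs from a per-strategy outcomes table.
#' Cost-effectiveness ratios use discounted effects and discounted costs;
#' effectiveness reporting uses undiscounted outcomes.
#'
#' @param outcomes data frame from [run_strategies()].
#' @param effect_scale `"ly"` or `"qaly"`.
#' @param discounted use discounted effect and cost columns (default).
#' @return data frame with columns `id`, `effect`, `cost`.
#' @export
strategy_points <- function(outcomes, effect_scale = c("ly", "qaly"),
                            discounted = TRUE) {
  effect_scale <- match.arg(effect_scale)
  eff_col <- paste0(effect_scale, if (discounted) "_disc" else "")
  cost_col <- if (discounted) "cost_disc" else "cost_undisc"
  data.frame(id = outcomes$strategy_id, effect = outcomes[[eff_col]],
             cost = outcomes[[cost_col]])
}

#' Incremental outcomes versus a reference strategy
#'
#' Per strategy: undiscounted life-year and QALY gains and the relative
#' risk reduction (in %) of lifetime cancer incidence and cancer-specific
#' mortality for each cancer, versus the reference strategy.
#'
#' @param outcomes data frame from [run_strategies()].
#' @param reference_id strategy id of the comparator (standard care = 1).
#' @return data frame with one row per strategy.
#' @export
compare_to_reference <- function(outcomes, reference_id = 1) {
  i <- match(reference_id, outcomes$strategy_id)
  if (is.na(i)) stop("reference strategy ", reference_id, " not in outcomes")
  ref <- outcomes[i, ]
  rrr <- function(col) 100 * (1 - outcomes[[col]] / ref[[col]])
  data.frame(
    strategy_id = outcomes$strategy_id,
    label = outcomes$label,
    d_ly = outcomes$ly - ref$ly,
    d_qaly = outcomes$qaly - ref$qaly,
    rrr_incidence_breast = rrr("incidence_breast"),
    rrr_incidence_ovarian = rrr("incidence_ovarian"),
    rrr_mortality_breast = rrr("mortality_breast"),
    rrr_mortality_ovarian = rrr("mortality_ovarian"),
    row.names = NULL)
}
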
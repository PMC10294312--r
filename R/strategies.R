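# Prevention strategies: the 16 compared surgery schedules and the
# age-dependent modifiers (onset relative risks, surveillance cost, surgery
# events) they induce.

#' Define a prevention strategy
#'
#' A strategy is a schedule of at most one prophylactic bilateral mastectomy
#' (PBM) and one prophylactic bilateral salpingo-oophorectomy (PBSO), each
#' at a fixed age. All strategies additionally receive intensified breast
#' surveillance.
#'
#' @param id integer identifier.
#' @param label human-readable label.
#' @param pbm_age integer age of PBM, or `NA` for none.
#' @param pbso_age integer age of PBSO, or `NA` for none.
#' @param custom set `TRUE` to permit surgery ages outside the evaluated
#'   set {30, 35, 40, 45}; such strategies are user extensions.
#' @return an object of class `boc_strategy`.
#' @export
strategy <- function(id, label, pbm_age = NA, pbso_age = NA, custom = FALSE) {
  ages <- c(pbm_age, pbso_age)
  ages <- ages[!is.na(ages)]
  if (length(ages) && !custom && !all(ages %in% c(30, 35, 40, 45)))
    stop("catalog surgery ages are restricted to 30/35/40/45; ",
         "use custom = TRUE for other ages")
  if (length(ages) && any(ages != round(ages)))
    stop("surgery ages must be integers")
  structure(list(id = as.integer(id), label = label,
                 pbm_age = if (is.na(pbm_age)) NA_integer_ else as.integer(pbm_age),
                 pbso_age = if (is.na(pbso_age)) NA_integer_ else as.integer(pbso_age)),
            class = "boc_strategy")
}

#' The sixteen compared prevention strategies
#'
#' Standard care (intensified surveillance only), single surgeries at ages
#' 30/35/40, simultaneous PBM+PBSO at 30/35/40, and serial combinations,
#' including the one PBSO-first schedule (PBSO at 35, PBM at 40).
#'
#' @return a list of 16 `boc_strategy` objects, ids 1--16.
#' @export
strategy_catalog <- function() {
  list(
    strategy(1,  "Standard care (IS)"),
    strategy(2,  "PBM at 30",                pbm_age = 30),
    strategy(3,  "PBM at 35",                pbm_age = 35),
    strategy(4,  "PBM at 40",                pbm_age = 40),
    strategy(5,  "PBSO at 30",               pbso_age = 30),
    strategy(6,  "PBSO at 35",               pbso_age = 35),
    strategy(7,  "PBSO at 40",               pbso_age = 40),
    strategy(8,  "PBM + PBSO at 30",         pbm_age = 30, pbso_age = 30),
    strategy(9,  "PBM + PBSO at 35",         pbm_age = 35, pbso_age = 35),
    strategy(10, "PBM + PBSO at 40",         pbm_age = 40, pbso_age = 40),
    strategy(11, "PBM at 30 + PBSO at 35",   pbm_age = 30, pbso_age = 35),
    strategy(12, "PBM at 30 + PBSO at 40",   pbm_age = 30, pbso_age = 40),
    strategy(13, "PBM at 35 + PBSO at 40",   pbm_age = 35, pbso_age = 40),
    strategy(14, "PBM at 35 + PBSO at 45",   pbm_age = 35, pbso_age = 45),
    strategy(15, "PBM at 40 + PBSO at 45",   pbm_age = 40, pbso_age = 45),
    strategy(16, "PBSO at 35 + PBM at 40",   pbm_age = 40, pbso_age = 35))
}

#' Get a catalog strategy by id
#'
#' @param id integer in 1--16.
#' @return a `boc_strategy` object.
#' @export
get_strategy <- function(id) {
  cat_ <- strategy_catalog()
  ids <- vapply(cat_, `[[`, 0L, "id")
  i <- match(id, ids)
  if (is.na(i)) stop("no catalog strategy with id ", id)
  cat_[[i]]
}

#' Surgery history implied by a strategy at a given age
#'
#' Returns which prophylactic surgeries have taken place by (and including)
#' the cycle starting at `age`, as one of `"none"`, `"pbm"`, `"pbso"`,
#' `"both"`. Surgeries take effect at the start of their scheduled cycle.
#'
#' @param strat a `boc_strategy`.
#' @param age integer age (vectorised).
#' @return character vector of history labels.
#' @export
surgery_history <- function(strat, age) {
  pbm  <- !is.na(strat$pbm_age)  & age >= strat$pbm_age
  pbso <- !is.na(strat$pbso_age) & age >= strat$pbso_age
  ifelse(pbm & pbso, "both", ifelse(pbm, "pbm", ifelse(pbso, "pbso", "none")))
}

#' Age-specific engine modifiers for a strategy
#'
#' Translates a strategy and an age into what the cohort engine needs for
#' that cycle: the relative risks applied to breast and ovarian onset, the
#' annual surveillance cost (halved once PBM has removed the need for
#' breast MRI), and the surgery event firing in this cycle, if any.
#' Relative risks apply from the surgery cycle onward; when both surgeries
#' are scheduled at the same age they fire as one combined event.
#'
#' @param strat a `boc_strategy`.
#' @param age integer age.
#' @param effects the `effects` component of a `boc_params` object.
#' @param costs the `costs` component of a `boc_params` object.
#' @return list with elements `rr_breast`, `rr_ovarian`,
#'   `surveillance_cost`, `surgery_event` (`"none"`, `"pbm"`, `"pbso"` or
#'   `"both"`).
#' @export
modifiers_at <- function(strat, age, effects, costs) {
  hist <- surgery_history(strat, age)
  rr <- switch(hist,
    none = c(1, 1),
    pbm  = c(effects$rr_breast_pbm, effects$rr_ovarian_pbm),
    pbso = c(effects$rr_breast_pbso, effects$rr_ovarian_pbso),
    both = c(effects$rr_breast_both, effects$rr_ovarian_both))
  event <- "none"
  at_pbm  <- !is.na(strat$pbm_age)  && age == strat$pbm_age
  at_pbso <- !is.na(strat$pbso_age) && age == strat$pbso_age
  if (at_pbm && at_pbso) event <- "both"
  else if (at_pbm) event <- "pbm"
  else if (at_pbso) event <- "pbso"
  surv_cost <- costs$surveillance *
    if (hist %in% c("pbm", "both")) costs$surveillance_after_pbm_fraction else 1
  list(rr_breast = rr[1], rr_ovarian = rr[2],
       surveillance_cost = surv_cost, surgery_event = event)
}

#' @export
print.boc_strategy <- function(x, ...) {
  cat(sprintf("Strategy %d: %s\n", x$id, x$label))
  invisible(x)
}
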
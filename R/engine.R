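# Deterministic annual-cycle Markov cohort engine.
#
# State space (96 states): well; undetected breast pT1-4; detected breast
# pT1-4 x tunnel year 1-10; breast survivor (split by PBM history for
# surveillance costing); breast-cancer death; the ovarian mirror
# (FIGO I-IV); death from other causes. The three death states are
# absorbing; survivor states are reachable only from tunnel year 10.
#
# Fixed within-cycle order of events:
#   1. other-cause death (well, undetected: q_other; survivors: all-cause
#      q_all, since registry-based tunnel survival already includes
#      competing deaths and survivors face general-population mortality),
#   2. detected tunnels: stage/year total survival, failures to cancer
#      death, year-10 survivors to the survivor state,
#   3. undetected states: symptomatic detection first, then stage
#      progression of the still-undetected remainder,
#   4. well: cancer onset with RR-modified probabilities, competing risks
#      split by rate normalisation.

# ---- state indexing ---------------------------------------------------------

#' State table of the cohort model
#'
#' Enumerates the 96 model states with their bookkeeping attributes:
#' `kind` (well, undetected, tunnel, survivor, cancer_death, other_death),
#' `cancer`, `stage` (1--4), tunnel `year` (1--10) and, for survivor
#' states, whether the occupants underwent PBM before diagnosis (drives
#' the surveillance cost).
#'
#' @return data frame with one row per state, in engine order.
#' @export
state_table <- function() {
  rows <- list(data.frame(name = "well", kind = "well", cancer = NA,
                          stage = NA, year = NA, pbm = NA))
  for (cc in CANCERS) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("und_", cc, "_", STAGE_LABELS[[cc]]), kind = "undetected",
      cancer = cc, stage = 1:4, year = NA, pbm = NA)
    g <- expand.grid(year = 1:10, stage = 1:4)
    g <- g[order(g$stage, g$year), ]
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("det_", cc, "_", STAGE_LABELS[[cc]][g$stage], "_y", g$year),
      kind = "tunnel", cancer = cc, stage = g$stage, year = g$year, pbm = NA)
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("surv_", cc, c("_nopbm", "_pbm")), kind = "survivor",
      cancer = cc, stage = NA, year = NA, pbm = c(FALSE, TRUE))
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("death_", cc), kind = "cancer_death", cancer = cc,
      stage = NA, year = NA, pbm = NA)
  }
  rows[[length(rows) + 1]] <- data.frame(
    name = "death_other", kind = "other_death", cancer = NA, stage = NA,
    year = NA, pbm = NA)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# index constants, fixed by the state_table() layout
.ST <- local({
  st <- state_table()
  idx <- function(kind, cancer = NULL) {
    k <- st$kind == kind
    if (!is.null(cancer)) k <- k & !is.na(st$cancer) & st$cancer == cancer
    which(k)
  }
  tun <- function(cancer) {
    m <- matrix(0L, 4, 10)
    w <- idx("tunnel", cancer)
    m[cbind(st$stage[w], st$year[w])] <- w
    m
  }
  list(
    names = st$name,
    n = nrow(st),
    well = idx("well"),
    und = list(breast = idx("undetected", "breast"),
               ovarian = idx("undetected", "ovarian")),
    tunnel = list(breast = tun("breast"), ovarian = tun("ovarian")),
    surv = list(breast = idx("survivor", "breast"),
                ovarian = idx("survivor", "ovarian")),  # [nopbm, pbm]
    cdeath = c(breast = idx("cancer_death", "breast"),
               ovarian = idx("cancer_death", "ovarian")),
    odeath = idx("other_death"))
})

#' @keywords internal
living_states <- function() {
  setdiff(seq_len(.ST$n), c(.ST$cdeath, .ST$odeath))
}

# ---- cohort simulation ------------------------------------------------------

#' Run the cohort simulation for one strategy
#'
#' Starts unit mass in the well state at `start_age` and iterates annual
#' cycles to `end_age`, recording state occupancy and the inter-state flows
#' (onsets, diagnoses by stage, cancer deaths, other-cause deaths) of every
#' cycle. Surgery events change onset relative risks from their scheduled
#' cycle onward; their one-time cost and one-cycle disutility are credited
#' by [lifetime_outcomes()].
#'
#' @param strat a `boc_strategy`.
#' @param params a `boc_params` object.
#' @param config analysis configuration; defaults to `params$analysis`.
#' @param init optional initial occupancy vector (length 96, summing to 1)
#'   replacing the default point mass in well.
#' @return an object of class `cohort_trace`: list with `ages`, `occupancy`
#'   (age x state matrix), `flows` (data frame, one row per transition
#'   cycle), and the strategy.
#' @export
run_cohort <- function(strat, params, config = NULL, init = NULL) {
  if (is.null(config)) config <- params$analysis
  ages <- config$start_age:config$end_age
  n_ages <- length(ages)
  S <- .ST

  q_all <- params$mortality$q_all[match(ages, params$mortality$age)]
  if (anyNA(q_all))
    stop("mortality table does not cover ages ",
         paste(ages[is.na(q_all)], collapse = ", "))
  q_other <- background_mortality(params$mortality, ages)

  # per-cycle onset probabilities with strategy relative risks
  cov_lo <- min(params$onset$breast$age_start)
  cov_hi <- max(params$onset$breast$age_end)
  onset_base <- function(cc) {
    vapply(ages, function(a)
      if (a >= cov_lo && a <= cov_hi)
        interpolate_onset(params$onset[[cc]], a) else 0, 0)
  }
  pb0 <- onset_base("breast")
  po0 <- onset_base("ovarian")
  mods <- lapply(ages, modifiers_at, strat = strat,
                 effects = params$effects, costs = params$costs)
  rr_b <- vapply(mods, `[[`, 0, "rr_breast")
  rr_o <- vapply(mods, `[[`, 0, "rr_ovarian")

  sv <- params$surv_annual
  pdet <- params$detection
  pprog <- params$progression

  occ <- matrix(0, n_ages, S$n, dimnames = list(ages, S$names))
  if (is.null(init)) {
    occ[1, S$well] <- 1
  } else {
    if (length(init) != S$n || abs(sum(init) - 1) > 1e-10 || any(init < 0))
      stop("init must be a length-", S$n, " non-negative vector summing to 1")
    occ[1, ] <- init
  }
  flow_names <- c("onset_breast", "onset_ovarian",
                  paste0("diag_breast_s", 1:4), paste0("diag_ovarian_s", 1:4),
                  "death_breast", "death_ovarian", "death_other")
  flows <- matrix(0, n_ages - 1, length(flow_names),
                  dimnames = list(ages[-n_ages], flow_names))

  for (i in seq_len(n_ages - 1)) {
    a <- ages[i]
    x <- occ[i, ]
    y <- numeric(S$n)
    qo <- q_other[i]; qa <- q_all[i]

    # 1. other-cause death
    d_other <- qo * (x[S$well] + sum(x[S$und$breast]) + sum(x[S$und$ovarian])) +
      qa * (sum(x[S$surv$breast]) + sum(x[S$surv$ovarian]))
    w <- x[S$well] * (1 - qo)
    for (cc in CANCERS) y[S$surv[[cc]]] <- x[S$surv[[cc]]] * (1 - qa)

    d_cancer <- c(breast = 0, ovarian = 0)
    diag_flow <- list(breast = numeric(4), ovarian = numeric(4))
    und_next <- list()
    for (cc in CANCERS) {
      # 2. detected tunnels: stage/year total survival
      ti <- S$tunnel[[cc]]
      tmass <- matrix(x[ti], 4, 10)
      smat <- sv[[cc]]
      d_cancer[cc] <- sum(tmass * (1 - smat))
      alive <- tmass * smat
      y[ti[, 2:10]] <- y[ti[, 2:10]] + alive[, 1:9]
      # year-10 survivors: PBM history fixed at diagnosis (cycle a - 10)
      pbm_then <- surgery_history(strat, a - 10) %in% c("pbm", "both")
      y[S$surv[[cc]][if (pbm_then) 2 else 1]] <-
        y[S$surv[[cc]][if (pbm_then) 2 else 1]] + sum(alive[, 10])

      # 3. undetected: detection first, then progression of the remainder
      u <- x[S$und[[cc]]] * (1 - qo)
      det <- u * pdet[[cc]]
      diag_flow[[cc]] <- det
      y[ti[, 1]] <- y[ti[, 1]] + det
      rem <- u - det
      moved <- rem[1:3] * pprog[[cc]]
      rem[1:3] <- rem[1:3] - moved
      rem[2:4] <- rem[2:4] + moved
      und_next[[cc]] <- rem
    }

    # 4. onset from well, competing risks split on the rate scale
    hb <- -log1p(-rr_b[i] * pb0[i])
    ho <- -log1p(-rr_o[i] * po0[i])
    H <- hb + ho
    if (H > 0) {
      p_any <- -expm1(-H)
      to_b <- w * p_any * hb / H
      to_o <- w * p_any * ho / H
    } else {
      to_b <- 0; to_o <- 0
    }
    y[S$well] <- w - to_b - to_o
    und_next$breast[1] <- und_next$breast[1] + to_b
    und_next$ovarian[1] <- und_next$ovarian[1] + to_o
    for (cc in CANCERS) y[S$und[[cc]]] <- und_next[[cc]]

    y[S$cdeath["breast"]] <- x[S$cdeath["breast"]] + d_cancer["breast"]
    y[S$cdeath["ovarian"]] <- x[S$cdeath["ovarian"]] + d_cancer["ovarian"]
    y[S$odeath] <- x[S$odeath] + d_other

    if (any(y < -1e-12) || abs(sum(y) - 1) > 1e-10)
      stop("internal consistency error: invalid occupancy at age ", a + 1)
    occ[i + 1, ] <- y
    flows[i, ] <- c(to_b, to_o, diag_flow$breast, diag_flow$ovarian,
                    d_cancer["breast"], d_cancer["ovarian"], d_other)
  }

  structure(list(ages = ages, occupancy = occ,
                 flows = data.frame(age = ages[-n_ages], flows,
                                    row.names = NULL),
                 strategy = strat, config = config),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: %s, ages %d-%d (%d states)\n",
              x$strategy$label, min(x$ages), max(x$ages), ncol(x$occupancy)))
  invisible(x)
}

#' Export a trace as a tidy data frame
#'
#' @param trace a `cohort_trace`.
#' @return data frame with columns `age`, `state`, `occupancy`.
#' @export
trace_to_df <- function(trace) {
  occ <- trace$occupancy
  data.frame(age = rep(trace$ages, times = ncol(occ)),
             state = rep(colnames(occ), each = nrow(occ)),
             occupancy = as.vector(occ), row.names = NULL)
}

# ---- rewards ----------------------------------------------------------------

#' @keywords internal
severity_class <- function(cancer, stage) {
  if (cancer == "breast") c("early", "early", "early", "metastatic")[stage]
  else c("nonadvanced", "nonadvanced", "advanced", "advanced")[stage]
}

#' Lifetime outcomes of a cohort trace
#'
#' Accumulates life years, QALYs and costs over the horizon, undiscounted
#' and discounted at the annual rate in the analysis configuration, plus
#' lifetime cumulative cancer incidence (developed, whether or not
#' detected) and cancer-specific mortality. Rewards are credited to the
#' state occupied at cycle start (no half-cycle correction); event costs
#' (surgery, initial treatment, palliative care) are credited to the cycle
#' in which the event fires. During a surgery cycle the utility of well and
#' undetected occupants is rescaled by `u_surgery / u_well`; diagnosed
#' states use the stage utility in tunnel year 1 and the clinical-remission
#' utility in years 2--10 and the survivor state.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param params the `boc_params` used for the run.
#' @param config analysis configuration; defaults to the trace's.
#' @return an object of class `outcome_summary`.
#' @export
lifetime_outcomes <- function(trace, params, config = NULL) {
  if (is.null(config)) config <- trace$config
  S <- .ST
  strat <- trace$strategy
  ages <- trace$ages
  occ <- trace$occupancy
  n_ages <- length(ages)
  r <- config$discount_rate
  disc <- (1 + r)^(-(ages - ages[1]))
  u <- params$utilities
  co <- params$costs
  fu_years <- co$followup_years

  # base utility by state
  u_base <- numeric(S$n)
  u_base[S$well] <- u$well
  for (cc in CANCERS) {
    u_base[S$und[[cc]]] <- u$undetected[[cc]]
    ti <- S$tunnel[[cc]]
    u_base[ti[, 1]] <- u$detected[[cc]]
    u_base[ti[, 2:10]] <- u$remission
    u_base[S$surv[[cc]]] <- u$remission
  }

  surv_frac <- function(pbm) ifelse(pbm, co$surveillance_after_pbm_fraction, 1)
  cost_cache <- new.env(parent = emptyenv())
  live <- living_states()
  ly_t <- qaly_t <- cost_t <- numeric(n_ages)
  flows <- trace$flows

  for (i in seq_len(n_ages)) {
    a <- ages[i]
    x <- occ[i, ]
    ly_t[i] <- sum(x[live])

    uv <- u_base
    m <- modifiers_at(strat, a, params$effects, co)
    if (m$surgery_event != "none") {
      scale <- u$surgery[[m$surgery_event]] / u$well
      uv[c(S$well, S$und$breast, S$und$ovarian)] <-
        uv[c(S$well, S$und$breast, S$und$ovarian)] * scale
    }
    qaly_t[i] <- sum(x * uv)

    # state costs; the history pattern over the trailing ten years takes
    # only a handful of values per strategy, so cache the cost vector
    hist_now <- surgery_history(strat, a)
    hist_back <- surgery_history(strat, a - (1:10))
    key <- paste(c(hist_now, hist_back), collapse = "|")
    cv <- cost_cache[[key]]
    if (is.null(cv)) {
      cv <- numeric(S$n)
      cv[c(S$well, S$und$breast, S$und$ovarian)] <- m$surveillance_cost
      for (cc in CANCERS) {
        ti <- S$tunnel[[cc]]
        fum <- co$followup[[cc]]
        for (s in 1:4) {
          cls <- if (cc == "breast") paste0("s", s) else severity_class(cc, s)
          for (yy in 1:10) {
            h <- hist_back[yy]
            cv[ti[s, yy]] <- if (yy <= fu_years[[cc]]) fum[cls, h] else
              co$surveillance * surv_frac(h %in% c("pbm", "both"))
          }
        }
        cv[S$surv[[cc]]] <- co$surveillance * surv_frac(c(FALSE, TRUE))
      }
      cost_cache[[key]] <- cv
    }
    state_cost <- sum(x * cv)

    # event costs fired during the cycle starting at age a
    event_cost <- 0
    if (m$surgery_event != "none") {
      eligible <- x[S$well] + sum(x[S$und$breast]) + sum(x[S$und$ovarian])
      event_cost <- event_cost + eligible * co$surgery[[m$surgery_event]]
    }
    if (i < n_ages) {
      f <- flows[i, ]
      for (cc in CANCERS) {
        dcols <- paste0("diag_", cc, "_s", 1:4)
        dg <- as.numeric(f[dcols])
        cls <- vapply(1:4, function(s) severity_class(cc, s), "")
        event_cost <- event_cost +
          sum(dg * co$initial[[cc]][cbind(cls, rep(hist_now, 4))])
        event_cost <- event_cost +
          as.numeric(f[[paste0("death_", cc)]]) * co$palliative[[cc]]
      }
    }
    cost_t[i] <- state_cost + event_cost
  }

  inc <- c(breast = sum(flows$onset_breast), ovarian = sum(flows$onset_ovarian))
  mort <- c(breast = sum(flows$death_breast), ovarian = sum(flows$death_ovarian))
  diag_tot <- c(breast = sum(as.matrix(flows[paste0("diag_breast_s", 1:4)])),
                ovarian = sum(as.matrix(flows[paste0("diag_ovarian_s", 1:4)])))

  structure(list(
    strategy_id = strat$id, label = strat$label,
    ly = sum(ly_t), qaly = sum(qaly_t),
    ly_disc = sum(ly_t * disc), qaly_disc = sum(qaly_t * disc),
    cost_undisc = sum(cost_t), cost_disc = sum(cost_t * disc),
    incidence = inc, mortality = mort, diagnosed = diag_tot),
    class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Strategy %d (%s)\n", x$strategy_id, x$label))
  cat(sprintf("  LY %.3f (disc %.3f)  QALY %.3f (disc %.3f)\n",
              x$ly, x$ly_disc, x$qaly, x$qaly_disc))
  cat(sprintf("  cost EUR %.0f (disc %.0f)\n", x$cost_undisc, x$cost_disc))
  cat(sprintf("  lifetime incidence: breast %.1f%%, ovarian %.1f%%\n",
              100 * x$incidence["breast"], 100 * x$incidence["ovarian"]))
  cat(sprintf("  cancer mortality:   breast %.1f%%, ovarian %.1f%%\n",
              100 * x$mortality["breast"], 100 * x$mortality["ovarian"]))
  invisible(x)
}

#' Cumulative risk of developing a cancer by a stated age
#'
#' Probability of having developed (not necessarily detected) the cancer
#' before reaching `age`, i.e. the sum of onset flows over cycles starting
#' strictly below `age`.
#'
#' @param trace a `cohort_trace`.
#' @param cancer `"breast"`, `"ovarian"` or `"any"`.
#' @param age target age within the horizon.
#' @return cumulative probability in `[0, 1]`.
#' @export
cumulative_risk_by_age <- function(trace, cancer = c("breast", "ovarian", "any"),
                                   age) {
  cancer <- match.arg(cancer)
  if (age < min(trace$ages) || age > max(trace$ages))
    stop("age outside the simulated horizon")
  f <- trace$flows[trace$flows$age < age, ]
  switch(cancer,
         breast = sum(f$onset_breast),
         ovarian = sum(f$onset_ovarian),
         any = sum(f$onset_breast) + sum(f$onset_ovarian))
}
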
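# Hierarchical calibration of the natural-history parameters to
# age-specific incidence and stage-distribution targets.
#
# The calibration adjusts multiplicative scales rather than every
# individual probability: one scale per onset decade band (both band
# endpoints move together, preserving the within-band slope) and one scale
# each for a cancer's progression and detection vectors. Band incidence
# plus a four-way stage distribution cannot identify finer structure (a
# band contributes one target but two endpoint probabilities; three free
# stage fractions cannot pin seven progression/detection values), so the
# scale parameterisation is the finest calibration this target set
# supports. Users with richer targets can calibrate repeatedly on subsets
# or supply year-resolved incidence via the onset schedule directly.

#' Model-implied calibration endpoints
#'
#' Runs the cohort engine under standard care and summarises the outputs
#' the calibration targets: annual diagnosis incidence per age band
#' (new diagnoses per person-year at risk, where the population at risk of
#' a cancer's diagnosis is the well state plus that cancer's undetected
#' states) and the distribution of diagnoses across stages at detection
#' over the whole horizon.
#'
#' @param params a `boc_params` object.
#' @param config analysis configuration; defaults to `params$analysis`.
#' @param bands data frame with columns `age_start`, `age_end` defining the
#'   incidence age bands; defaults to the onset schedule's bands clipped to
#'   the horizon.
#' @return list with data frames `incidence` (`cancer`, `age_start`,
#'   `age_end`, `value`) and `stages` (`cancer`, `stage`, `value`).
#' @export
predict_targets <- function(params, config = NULL, bands = NULL) {
  if (is.null(config)) config <- params$analysis
  if (is.null(bands)) {
    b <- params$onset$breast[c("age_start", "age_end")]
    b <- b[b$age_end >= config$start_age & b$age_start < config$end_age, ]
    b$age_start <- pmax(b$age_start, config$start_age)
    b$age_end <- pmin(b$age_end, config$end_age - 1)
    bands <- b
  }
  tr <- run_cohort(get_strategy(1), params, config)
  f <- tr$flows
  occ <- tr$occupancy
  S <- .ST
  inc_rows <- list()
  stage_rows <- list()
  for (cc in CANCERS) {
    dcols <- paste0("diag_", cc, "_s", 1:4)
    at_risk <- occ[, S$well] + rowSums(occ[, S$und[[cc]], drop = FALSE])
    for (i in seq_len(nrow(bands))) {
      in_band <- f$age >= bands$age_start[i] & f$age <= bands$age_end[i]
      py <- sum(at_risk[match(f$age[in_band], tr$ages)])
      dg <- sum(as.matrix(f[in_band, dcols]))
      inc_rows[[length(inc_rows) + 1]] <- data.frame(
        cancer = cc, age_start = bands$age_start[i],
        age_end = bands$age_end[i],
        value = if (py > 0) dg / py else 0)
    }
    tot <- sum(as.matrix(f[dcols]))
    stage_rows[[length(stage_rows) + 1]] <- data.frame(
      cancer = cc, stage = 1:4,
      value = if (tot > 0) colSums(as.matrix(f[dcols])) / tot else rep(0, 4))
  }
  list(incidence = do.call(rbind, inc_rows),
       stages = do.call(rbind, stage_rows))
}

#' Assemble calibration targets
#'
#' @param incidence data frame with columns `cancer`, `age_start`,
#'   `age_end`, `value` and optionally `weight`.
#' @param stages data frame with columns `cancer`, `stage`, `value` and
#'   optionally `weight`. Stage fractions must sum to 1 within each cancer.
#' @return object of class `calibration_targets`.
#' @export
calibration_targets <- function(incidence, stages) {
  if (is.null(incidence$weight))
    incidence$weight <- ifelse(incidence$value > 0, 1 / incidence$value^2, 1)
  if (is.null(stages$weight))
    stages$weight <- ifelse(stages$value > 0, 1 / stages$value^2, 1)
  for (cc in unique(stages$cancer)) {
    s <- stages$value[stages$cancer == cc]
    if (abs(sum(s) - 1) > 1e-6)
      stop("stage fractions for ", cc, " must sum to 1")
  }
  if (any(incidence$value < 0) || any(incidence$value > 1))
    stop("incidence targets must be probabilities")
  structure(list(incidence = incidence, stages = stages),
            class = "calibration_targets")
}

#' Read calibration targets from CSV
#'
#' One file with columns `cancer`, `type` (`incidence` or `stage`),
#' `band_or_stage` (e.g. `40_49` or `2`), `value`, `weight` (optional).
#'
#' @param path CSV file path.
#' @return object of class `calibration_targets`.
#' @export
read_calibration_targets <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  inc <- d[d$type == "incidence", ]
  stg <- d[d$type == "stage", ]
  incidence <- data.frame(
    cancer = inc$cancer,
    age_start = as.integer(sub("_.*", "", inc$band_or_stage)),
    age_end = as.integer(sub(".*_", "", inc$band_or_stage)),
    value = inc$value)
  stages <- data.frame(cancer = stg$cancer,
                       stage = as.integer(stg$band_or_stage),
                       value = stg$value)
  if ("weight" %in% names(d)) {
    incidence$weight <- inc$weight
    stages$weight <- stg$weight
  }
  calibration_targets(incidence, stages)
}

#' @keywords internal
apply_calibration_scales <- function(params, onset_scales, prog_scales,
                                     det_scales) {
  clip <- function(x) pmin(x, 1 - 1e-9)
  for (cc in CANCERS) {
    sc <- onset_scales[[cc]]
    if (!is.null(sc)) {
      b <- params$onset[[cc]]
      i <- match(paste(b$age_start, b$age_end), names(sc))
      k <- !is.na(i)
      b$p_first[k] <- clip(b$p_first[k] * sc[i[k]])
      b$p_last[k] <- clip(b$p_last[k] * sc[i[k]])
      params$onset[[cc]] <- b
    }
    if (!is.null(prog_scales[[cc]]))
      params$progression[[cc]] <- clip(params$progression[[cc]] * prog_scales[[cc]])
    if (!is.null(det_scales[[cc]]))
      params$detection[[cc]] <- clip(params$detection[[cc]] * det_scales[[cc]])
  }
  params
}

#' @keywords internal
calibration_objective <- function(pred, targets) {
  obj <- 0
  ti <- targets$incidence
  key_p <- paste(pred$incidence$cancer, pred$incidence$age_start,
                 pred$incidence$age_end)
  key_t <- paste(ti$cancer, ti$age_start, ti$age_end)
  i <- match(key_t, key_p)
  if (anyNA(i)) stop("prediction missing incidence band(s): ",
                     paste(key_t[is.na(i)], collapse = "; "))
  obj <- obj + sum(ti$weight * (pred$incidence$value[i] - ti$value)^2)
  ts <- targets$stages
  key_p <- paste(pred$stages$cancer, pred$stages$stage)
  j <- match(paste(ts$cancer, ts$stage), key_p)
  obj + sum(ts$weight * (pred$stages$value[j] - ts$value)^2)
}

#' Calibrate natural-history parameters to targets
#'
#' Alternates two hierarchical stages until the weighted
#' sum-of-squared-errors objective stops improving: stage A fits one
#' multiplicative scale per onset decade band (per cancer) to the incidence
#' targets by damped proportional fitting (each band's scale is multiplied
#' by its target/predicted incidence ratio), holding progression and
#' detection; stage B fits one scale each for progression and detection
#' (per cancer) by a deterministic Nelder--Mead search on the log scale
#' against the full objective, holding onset. Scaled probabilities are
#' clipped below 1; the whole procedure is deterministic given the initial
#' parameter set.
#'
#' @param targets a `calibration_targets` object.
#' @param init initial `boc_params` (stage B holds whatever stage A
#'   produced, and vice versa).
#' @param config analysis configuration; defaults to `init$analysis`.
#' @param control list: `max_outer` alternation rounds (default 12), `tol`
#'   objective-improvement tolerance (default 1e-10), `pf_iters`
#'   proportional-fitting passes per stage-A visit (default 4),
#'   `pf_damping` exponent on the update ratio (default 1), `maxit_stage`
#'   iteration cap for the stage-B simplex search (default 200).
#' @return object of class `calibration_result`: `params` (fitted),
#'   `objective`, `residuals` (per-target model minus target),
#'   `iterations`, `converged`, `terminated_by` and the fitted scales.
#' @export
calibrate_model <- function(targets, init, config = NULL, control = list()) {
  if (is.null(config)) config <- init$analysis
  ctl <- utils::modifyList(
    list(max_outer = 12, tol = 1e-10, pf_iters = 4, pf_damping = 1,
         maxit_stage = 200),
    control)

  bands_of <- function(cc) {
    ti <- targets$incidence[targets$incidence$cancer == cc, ]
    b <- init$onset[[cc]]
    keep <- paste(b$age_start, b$age_end) %in%
      paste(ti$age_start, ti$age_end)
    paste(b$age_start, b$age_end)[keep]
  }
  band_names <- lapply(stats::setNames(CANCERS, CANCERS), bands_of)
  target_bands <- unique(targets$incidence[c("age_start", "age_end")])

  onset_scales <- lapply(band_names, function(bn)
    stats::setNames(rep(1, length(bn)), bn))
  prog_scales <- stats::setNames(as.list(rep(1, 2)), CANCERS)
  det_scales <- stats::setNames(as.list(rep(1, 2)), CANCERS)

  evaluate <- function() {
    p <- apply_calibration_scales(init, onset_scales, prog_scales, det_scales)
    pred <- predict_targets(p, config, bands = target_bands)
    calibration_objective(pred, targets)
  }

  # largest admissible scale per band (keeps scaled onset below 1)
  scale_cap <- lapply(stats::setNames(CANCERS, CANCERS), function(cc) {
    b <- init$onset[[cc]]
    cap <- 0.999 / pmax(b$p_first, b$p_last)
    stats::setNames(cap, paste(b$age_start, b$age_end))[band_names[[cc]]]
  })

  obj <- evaluate()
  history <- obj
  terminated_by <- "max_outer"
  for (outer in seq_len(ctl$max_outer)) {
    # stage A: onset band scales by damped proportional fitting -- each
    # band's scale is multiplied by (target / predicted) incidence, which
    # converges in a few passes because a band's incidence responds mostly
    # to its own onset level; the best visited scale set is retained so
    # the stage never worsens the objective
    best_obj <- Inf
    best_scales <- onset_scales
    for (it in seq_len(ctl$pf_iters + 1)) {
      p <- apply_calibration_scales(init, onset_scales, prog_scales,
                                    det_scales)
      pred <- predict_targets(p, config, bands = target_bands)
      cur <- calibration_objective(pred, targets)
      if (cur < best_obj) {
        best_obj <- cur
        best_scales <- onset_scales
      }
      if (it > ctl$pf_iters) break
      for (cc in CANCERS) {
        if (!length(onset_scales[[cc]])) next
        ti <- targets$incidence[targets$incidence$cancer == cc, ]
        pi <- pred$incidence[pred$incidence$cancer == cc, ]
        i <- match(band_names[[cc]],
                   paste(pi$age_start, pi$age_end))
        j <- match(band_names[[cc]],
                   paste(ti$age_start, ti$age_end))
        ratio <- ifelse(pi$value[i] > 0, ti$value[j] / pi$value[i], 1)
        onset_scales[[cc]][] <- pmin(
          onset_scales[[cc]] * ratio^ctl$pf_damping, scale_cap[[cc]])
      }
    }
    onset_scales <- best_scales
    # stage B: progression + detection scales, one cancer at a time
    for (cc in CANCERS) {
      fn <- function(theta) {
        prog_scales[[cc]] <<- exp(theta[1])
        det_scales[[cc]] <<- exp(theta[2])
        evaluate()
      }
      res <- stats::optim(log(c(prog_scales[[cc]], det_scales[[cc]])), fn,
                          method = "Nelder-Mead",
                          control = list(maxit = ctl$maxit_stage,
                                         reltol = 1e-10))
      prog_scales[[cc]] <- exp(res$par[1])
      det_scales[[cc]] <- exp(res$par[2])
    }
    new_obj <- evaluate()
    history <- c(history, new_obj)
    if (obj - new_obj < ctl$tol) {
      obj <- min(obj, new_obj)
      terminated_by <- "tolerance"
      break
    }
    obj <- new_obj
  }

  fitted <- apply_calibration_scales(init, onset_scales, prog_scales,
                                     det_scales)
  pred <- predict_targets(fitted, config, bands = target_bands)
  residuals <- list(
    incidence = transform(
      merge(targets$incidence, pred$incidence,
            by = c("cancer", "age_start", "age_end"),
            suffixes = c("_target", "_model")),
      residual = value_model - value_target),
    stages = transform(
      merge(targets$stages, pred$stages, by = c("cancer", "stage"),
            suffixes = c("_target", "_model")),
      residual = value_model - value_target))
  structure(list(
    params = fitted, objective = obj, residuals = residuals,
    onset_scales = onset_scales, prog_scales = prog_scales,
    det_scales = det_scales, history = history,
    iterations = length(history) - 1,
    converged = terminated_by == "tolerance",
    terminated_by = terminated_by), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: objective %.3e after %d round(s) (%s)\n",
              x$objective, x$iterations, x$terminated_by))
  invisible(x)
}
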
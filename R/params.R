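# Model parameters: containers, validation, file readers and elementary
# transforms shared by the cohort engine, calibration and sensitivity layers.

#' Build a parameter set from its components
#'
#' Assembles and validates the single source of model inputs: age-specific
#' cancer onset schedules, stage progression and symptomatic-detection
#' probabilities, stage-specific survival, relative risks of prophylactic
#' surgery, health-state utilities, costs (2022 Euro) and background
#' mortality, plus the analysis configuration (discount rate,
#' willingness-to-pay, age horizon).
#'
#' @param onset named list (`breast`, `ovarian`) of data frames with columns
#'   `age_start`, `age_end`, `p_first`, `p_last`: annual onset probabilities
#'   at the first and last integer age of each decade band, covering ages
#'   20--99 contiguously.
#' @param progression named list of numeric vectors (length 3): annual
#'   probability of progressing from stage 1 to 2, 2 to 3, and 3 to 4 while
#'   undetected. Terminal stages have no progression entry.
#' @param detection named list of numeric vectors (length 4): annual
#'   probability of symptomatic detection per undetected stage.
#' @param surv5 named list of numeric vectors (length 4): five-year
#'   disease-specific survival fraction per diagnosed stage.
#' @param surv_annual optional named list of 4 x 10 matrices (stage x year
#'   since diagnosis) of annual survival probabilities for the ten tunnel
#'   years. When `NULL`, the constant-rate transform
#'   [annual_survival_from_5yr()] of `surv5` is used for every tunnel year.
#' @param effects named list of relative risks on cancer onset after
#'   prophylactic surgery: `rr_breast_pbm`, `rr_breast_pbso`,
#'   `rr_breast_both`, `rr_ovarian_pbso` (PBM does not alter ovarian risk;
#'   the combined-surgery ovarian RR equals the PBSO RR).
#' @param utilities named list: `well`, `remission`, `detected` (list of
#'   per-stage vectors by cancer), `undetected` (same shape; defaults to the
#'   detected values), `surgery` (named vector `pbm`, `pbso`, `both`:
#'   well-state utility during the surgery cycle).
#' @param costs named list: `surveillance` (annual), `surveillance_after_pbm_fraction`,
#'   `surgery` (one-time, by type), `initial` (one-time at diagnosis, by
#'   cancer, severity class and surgery history), `followup` (annual, by
#'   cancer, stage or class, and history), `followup_years` (by cancer),
#'   `palliative` (one-time at cancer death, by cancer).
#' @param mortality data frame with columns `age`, `q_all`, `q_cancer`:
#'   female all-cause annual death probability and the breast+ovarian
#'   cancer share to be removed from it (see [background_mortality()]).
#' @param analysis named list: `discount_rate`, `wtp`, `start_age`,
#'   `end_age`. Cycle length is fixed at one year.
#' @return An object of class `boc_params`.
#' @export
boc_params <- function(onset, progression, detection, surv5,
                       surv_annual = NULL, effects, utilities, costs,
                       mortality, analysis) {
  if (is.null(surv_annual)) {
    surv_annual <- lapply(surv5, function(s5) {
      matrix(rep(annual_survival_from_5yr(s5), 10), nrow = 4,
             dimnames = list(NULL, paste0("y", 1:10)))
    })
  }
  effects$rr_ovarian_pbm  <- 1
  effects$rr_ovarian_both <- effects$rr_ovarian_pbso
  if (is.null(utilities$undetected)) utilities$undetected <- utilities$detected
  p <- structure(
    list(onset = onset, progression = progression, detection = detection,
         surv5 = surv5, surv_annual = surv_annual, effects = effects,
         utilities = utilities, costs = costs, mortality = mortality,
         analysis = analysis),
    class = "boc_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks range, coverage and consistency invariants: probabilities in
#' \[0, 1\], onset bands contiguous over ages 20--99 for both cancers,
#' relative risks in (0, 1\], surgery utilities not above the well utility,
#' detected-state utilities non-increasing with stage, non-negative costs
#' with the combined surgery costing the sum of the single surgeries, and
#' cancer mortality never exceeding all-cause mortality.
#'
#' @param p a `boc_params` object.
#' @return `p`, invisibly; signals an error on the first violated invariant.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "boc_params"))
  prob_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  for (cc in CANCERS) {
    b <- p$onset[[cc]]
    if (!all(c("age_start", "age_end", "p_first", "p_last") %in% names(b)))
      stop("onset schedule for ", cc, " lacks required columns")
    b <- b[order(b$age_start), ]
    if (b$age_start[1] != 20 || b$age_end[nrow(b)] != 99)
      stop("onset schedule for ", cc, " must cover ages 20-99")
    if (any(b$age_start != round(b$age_start)) || any(b$age_end != round(b$age_end)))
      stop("onset band ages must be integers")
    if (nrow(b) > 1 && any(b$age_start[-1] != b$age_end[-nrow(b)] + 1))
      stop("onset bands for ", cc, " must be contiguous and non-overlapping")
    if (!prob_ok(c(b$p_first, b$p_last)))
      stop("onset probabilities for ", cc, " outside [0,1]")
    if (length(p$progression[[cc]]) != 3 || !prob_ok(p$progression[[cc]]))
      stop("progression for ", cc, " must be 3 probabilities in [0,1]")
    if (length(p$detection[[cc]]) != 4 || !prob_ok(p$detection[[cc]]))
      stop("detection for ", cc, " must be 4 probabilities in [0,1]")
    s5 <- p$surv5[[cc]]
    if (length(s5) != 4 || any(s5 <= 0) || any(s5 > 1))
      stop("five-year survival for ", cc, " must be 4 values in (0,1]")
    sa <- p$surv_annual[[cc]]
    if (!is.matrix(sa) || any(dim(sa) != c(4, 10)) || any(sa <= 0) || any(sa > 1))
      stop("annual survival for ", cc, " must be a 4x10 matrix in (0,1]")
    if (!prob_ok(unlist(p$utilities$detected[[cc]])) ||
        any(diff(p$utilities$detected[[cc]]) > 1e-12))
      stop("detected-state utilities for ", cc,
           " must be in [0,1] and non-increasing with stage")
  }
  ef <- p$effects
  rr <- c(ef$rr_breast_pbm, ef$rr_breast_pbso, ef$rr_breast_both,
          ef$rr_ovarian_pbso)
  if (any(rr <= 0) || any(rr > 1)) stop("relative risks must lie in (0,1]")
  if (ef$rr_ovarian_pbm != 1) stop("PBM must not alter ovarian onset (RR = 1)")
  u <- p$utilities
  if (!prob_ok(c(u$well, u$remission, unlist(u$undetected), u$surgery)))
    stop("utilities must lie in [0,1]")
  # no upper bound at u_well: the published PBSO surgery-cycle utility
  # (0.95) exceeds the well-state utility (0.92)
  co <- p$costs
  if (any(unlist(co[c("surveillance", "surgery", "initial", "followup",
                      "palliative")]) < 0))
    stop("costs must be non-negative")
  if (abs(co$surgery[["both"]] -
          (co$surgery[["pbm"]] + co$surgery[["pbso"]])) > 1e-6)
    stop("combined surgery cost must equal PBM + PBSO costs")
  if (co$surveillance_after_pbm_fraction < 0 ||
      co$surveillance_after_pbm_fraction > 1)
    stop("surveillance_after_pbm_fraction must lie in [0,1]")
  m <- p$mortality
  if (!prob_ok(m$q_all) || !prob_ok(m$q_cancer))
    stop("mortality probabilities outside [0,1]")
  if (any(m$q_cancer > m$q_all + 1e-12))
    stop("cancer mortality exceeds all-cause mortality at some age")
  a <- p$analysis
  if (a$discount_rate < 0 || a$discount_rate >= 1)
    stop("discount rate must lie in [0,1)")
  if (a$start_age >= a$end_age) stop("start_age must precede end_age")
  invisible(p)
}

#' Annual onset probability at an integer age
#'
#' The onset schedules give the annual probability of developing (still
#' undetected) stage-1 cancer at the first and last integer age of each
#' decade band. Within a band the probability is interpolated linearly
#' between the two endpoints; bands may be discontinuous at their
#' boundaries, as the input data are.
#'
#' @param schedule one cancer's onset data frame (columns `age_start`,
#'   `age_end`, `p_first`, `p_last`).
#' @param age integer age(s) in 20--99.
#' @return annual onset probability, vectorised over `age`.
#' @export
interpolate_onset <- function(schedule, age) {
  if (any(age < min(schedule$age_start)) || any(age > max(schedule$age_end)))
    stop("age outside the range covered by the onset schedule")
  i <- findInterval(age, schedule$age_start)
  b <- schedule[i, ]
  w <- ifelse(b$age_end > b$age_start,
              (age - b$age_start) / (b$age_end - b$age_start), 0)
  unname(b$p_first + w * (b$p_last - b$p_first))
}

#' Constant annual survival implied by a five-year survival fraction
#'
#' Converts a five-year disease-specific survival fraction to the constant
#' annual survival probability `S5^(1/5)` used as the default for every
#' year of the ten-year post-diagnosis tunnel when year-specific survival
#' vectors are not configured.
#'
#' @param s5 five-year survival fraction(s) in (0, 1].
#' @return annual survival probability, same length as `s5`.
#' @export
annual_survival_from_5yr <- function(s5) {
  if (any(s5 <= 0) || any(s5 > 1)) stop("five-year survival must be in (0,1]")
  s5^(1 / 5)
}

#' Year-specific tunnel survival from a first/last-year range
#'
#' Helper for populating the year-specific survival hook from a published
#' range: geometric (log-linear) interpolation between the year-1 and
#' year-10 annual survival probabilities.
#'
#' @param first annual survival in the first year after diagnosis.
#' @param last annual survival in the tenth year after diagnosis.
#' @return numeric vector of length 10.
#' @export
survival_vector_from_range <- function(first, last) {
  if (any(c(first, last) <= 0) || any(c(first, last) > 1))
    stop("survival probabilities must be in (0,1]")
  exp(log(first) + (0:9) / 9 * (log(last) - log(first)))
}

#' Background mortality net of breast/ovarian cancer deaths
#'
#' All-cause female life tables include deaths from breast and ovarian
#' cancer, which the model generates endogenously; counting both would
#' double the cancer burden. The adjustment removes the cancer component on
#' the rate (log) scale:
#' `q_other = 1 - exp(-(h_all - h_cancer))` with `h = -log(1 - q)`.
#'
#' @param mortality data frame with columns `age`, `q_all`, `q_cancer`.
#' @param age integer age(s) present in the table.
#' @return annual probability of death from causes other than breast or
#'   ovarian cancer, in `[0, q_all]`.
#' @export
background_mortality <- function(mortality, age) {
  i <- match(age, mortality$age)
  if (anyNA(i)) stop("mortality inputs not defined at age ",
                     paste(age[is.na(i)], collapse = ", "))
  q_all <- mortality$q_all[i]
  q_cancer <- mortality$q_cancer[i]
  if (any(q_cancer > q_all + 1e-12))
    stop("cancer mortality exceeds all-cause mortality")
  1 - exp(-(-log1p(-q_all) + log1p(-q_cancer)))
}

# ---- file readers / writers -------------------------------------------------

#' Read a flat key-value parameter file
#'
#' Parameters travel as a two-column CSV (`key`, `value`) using dotted keys,
#' e.g. `onset.breast.30_39.first`, `prog.breast.s1_s2`, `det.ovarian.s3`,
#' `surv5.breast.s1`, `effect.rr_breast_pbm`, `util.well`,
#' `util.detected.breast.s2`, `cost.surveillance`, `cost.surgery.pbm`,
#' `cost.initial.breast.early.pbm`, `cost.followup.ovarian.advanced.both`,
#' `cost.palliative.breast`, `analysis.discount_rate`. Optional keys
#' `surv.<cancer>.s<stage>.y<year>` populate year-specific tunnel survival.
#' The packaged base-case fixture `parameters_base.csv` uses this same
#' reader and schema.
#'
#' @param path CSV file with columns `key` and `value`.
#' @param mortality background-mortality data frame (see [read_mortality()]);
#'   defaults to the packaged synthetic German female life table.
#' @return a validated `boc_params` object.
#' @export
read_parameters <- function(path, mortality = default_mortality()) {
  kv <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("key", "value") %in% names(kv)))
    stop("parameter file must have columns 'key' and 'value'")
  vals <- stats::setNames(as.numeric(kv$value), kv$key)
  bad <- setdiff(names(vals), known_parameter_keys())
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  need <- function(k) {
    if (!k %in% names(vals)) stop("missing parameter key: ", k)
    unname(vals[[k]])
  }
  opt <- function(k, default) if (k %in% names(vals)) unname(vals[[k]]) else default

  bands <- c("20_29", "30_39", "40_49", "50_59", "60_69", "70_79", "80_89", "90_99")
  onset <- lapply(stats::setNames(CANCERS, CANCERS), function(cc) {
    data.frame(
      age_start = as.integer(sub("_.*", "", bands)),
      age_end   = as.integer(sub(".*_", "", bands)),
      p_first   = vapply(bands, function(b) need(sprintf("onset.%s.%s.first", cc, b)), 0),
      p_last    = vapply(bands, function(b) need(sprintf("onset.%s.%s.last", cc, b)), 0),
      row.names = NULL)
  })
  progression <- lapply(stats::setNames(CANCERS, CANCERS), function(cc)
    vapply(1:3, function(s) need(sprintf("prog.%s.s%d_s%d", cc, s, s + 1)), 0))
  detection <- lapply(stats::setNames(CANCERS, CANCERS), function(cc)
    vapply(1:4, function(s) need(sprintf("det.%s.s%d", cc, s)), 0))
  surv5 <- lapply(stats::setNames(CANCERS, CANCERS), function(cc)
    vapply(1:4, function(s) need(sprintf("surv5.%s.s%d", cc, s)), 0))
  surv_annual <- NULL
  if (any(grepl("^surv\\.", names(vals)))) {
    surv_annual <- lapply(stats::setNames(CANCERS, CANCERS), function(cc) {
      m <- matrix(rep(annual_survival_from_5yr(surv5[[cc]]), 10), nrow = 4,
                  dimnames = list(NULL, paste0("y", 1:10)))
      for (s in 1:4) for (y in 1:10) {
        k <- sprintf("surv.%s.s%d.y%d", cc, s, y)
        if (k %in% names(vals)) m[s, y] <- vals[[k]]
      }
      m
    })
  }
  effects <- list(
    rr_breast_pbm   = need("effect.rr_breast_pbm"),
    rr_breast_pbso  = need("effect.rr_breast_pbso"),
    rr_breast_both  = need("effect.rr_breast_both"),
    rr_ovarian_pbso = need("effect.rr_ovarian_pbso"))
  utilities <- list(
    well      = need("util.well"),
    remission = need("util.remission"),
    detected  = lapply(stats::setNames(CANCERS, CANCERS), function(cc)
      vapply(1:4, function(s) need(sprintf("util.detected.%s.s%d", cc, s)), 0)),
    undetected = lapply(stats::setNames(CANCERS, CANCERS), function(cc)
      vapply(1:4, function(s)
        opt(sprintf("util.undetected.%s.s%d", cc, s),
            need(sprintf("util.detected.%s.s%d", cc, s))), 0)),
    surgery = c(pbm  = need("util.surgery.pbm"),
                pbso = need("util.surgery.pbso"),
                both = need("util.surgery.both")))
  classes <- list(breast = c("early", "metastatic"),
                  ovarian = c("nonadvanced", "advanced"))
  init_cost <- lapply(stats::setNames(CANCERS, CANCERS), function(cc) {
    m <- sapply(HISTORIES, function(h) vapply(classes[[cc]], function(cl)
      need(sprintf("cost.initial.%s.%s.%s", cc, cl, h)), 0))
    rownames(m) <- classes[[cc]]
    m
  })
  fu_cost <- list(
    breast = {
      m <- sapply(HISTORIES, function(h) vapply(1:4, function(s)
        need(sprintf("cost.followup.breast.s%d.%s", s, h)), 0))
      rownames(m) <- paste0("s", 1:4); m
    },
    ovarian = {
      m <- sapply(HISTORIES, function(h) vapply(classes$ovarian, function(cl)
        need(sprintf("cost.followup.ovarian.%s.%s", cl, h)), 0))
      rownames(m) <- classes$ovarian; m
    })
  costs <- list(
    surveillance = need("cost.surveillance"),
    surveillance_after_pbm_fraction = need("cost.surveillance_after_pbm_fraction"),
    surgery = c(pbm  = need("cost.surgery.pbm"),
                pbso = need("cost.surgery.pbso"),
                both = need("cost.surgery.both")),
    initial = init_cost,
    followup = fu_cost,
    followup_years = c(breast = need("cost.followup_years.breast"),
                       ovarian = need("cost.followup_years.ovarian")),
    palliative = c(breast = need("cost.palliative.breast"),
                   ovarian = need("cost.palliative.ovarian")))
  analysis <- list(
    discount_rate = opt("analysis.discount_rate", 0.03),
    wtp           = opt("analysis.wtp", 90000),
    start_age     = opt("analysis.start_age", 30),
    end_age       = opt("analysis.end_age", 100))
  boc_params(onset = onset, progression = progression, detection = detection,
             surv5 = surv5, surv_annual = surv_annual, effects = effects,
             utilities = utilities, costs = costs, mortality = mortality,
             analysis = analysis)
}

#' @keywords internal
known_parameter_keys <- function() {
  bands <- c("20_29", "30_39", "40_49", "50_59", "60_69", "70_79", "80_89", "90_99")
  classes <- list(breast = c("early", "metastatic"),
                  ovarian = c("nonadvanced", "advanced"))
  keys <- c(
    as.vector(outer(CANCERS, bands, function(cc, b)
      paste0("onset.", cc, ".", b, ".first"))),
    as.vector(outer(CANCERS, bands, function(cc, b)
      paste0("onset.", cc, ".", b, ".last"))),
    unlist(lapply(CANCERS, function(cc)
      sprintf("prog.%s.s%d_s%d", cc, 1:3, 2:4))),
    unlist(lapply(CANCERS, function(cc) sprintf("det.%s.s%d", cc, 1:4))),
    unlist(lapply(CANCERS, function(cc) sprintf("surv5.%s.s%d", cc, 1:4))),
    unlist(lapply(CANCERS, function(cc)
      as.vector(outer(1:4, 1:10, function(s, y)
        sprintf("surv.%s.s%d.y%d", cc, s, y))))),
    paste0("effect.", c("rr_breast_pbm", "rr_breast_pbso", "rr_breast_both",
                        "rr_ovarian_pbso")),
    "util.well", "util.remission",
    unlist(lapply(CANCERS, function(cc)
      c(sprintf("util.detected.%s.s%d", cc, 1:4),
        sprintf("util.undetected.%s.s%d", cc, 1:4)))),
    paste0("util.surgery.", c("pbm", "pbso", "both")),
    "cost.surveillance", "cost.surveillance_after_pbm_fraction",
    paste0("cost.surgery.", c("pbm", "pbso", "both")),
    unlist(lapply(CANCERS, function(cc)
      as.vector(outer(classes[[cc]], HISTORIES, function(cl, h)
        sprintf("cost.initial.%s.%s.%s", cc, cl, h))))),
    as.vector(outer(1:4, HISTORIES, function(s, h)
      sprintf("cost.followup.breast.s%d.%s", s, h))),
    as.vector(outer(classes$ovarian, HISTORIES, function(cl, h)
      sprintf("cost.followup.ovarian.%s.%s", cl, h))),
    "cost.followup_years.breast", "cost.followup_years.ovarian",
    "cost.palliative.breast", "cost.palliative.ovarian",
    paste0("analysis.", c("discount_rate", "wtp", "start_age", "end_age")))
  keys
}

#' Read background-mortality inputs
#'
#' Two two-column CSVs (`age`, probability): the female all-cause life table
#' and the age-specific combined breast+ovarian cancer mortality to be
#' removed from it.
#'
#' @param life_path CSV with columns `age`, `q_all`.
#' @param cancer_path CSV with columns `age`, `q_cancer`.
#' @return data frame with columns `age`, `q_all`, `q_cancer`.
#' @export
read_mortality <- function(life_path, cancer_path) {
  lt <- utils::read.csv(life_path)
  cm <- utils::read.csv(cancer_path)
  if (!all(c("age", "q_all") %in% names(lt)))
    stop("life table must have columns 'age' and 'q_all'")
  if (!all(c("age", "q_cancer") %in% names(cm)))
    stop("cancer mortality must have columns 'age' and 'q_cancer'")
  m <- merge(lt[c("age", "q_all")], cm[c("age", "q_cancer")], by = "age")
  m <- m[order(m$age), ]
  rownames(m) <- NULL
  m
}

#' Packaged synthetic background-mortality inputs
#'
#' Loads the packaged life table and cancer-mortality curve. Both files are
#' synthetic: a Gompertz--Makeham all-cause curve anchored to published
#' German female period-mortality levels and a piecewise-linear
#' breast+ovarian share schedule (see [make_life_table()]); they stand in
#' for the official DESTATIS/RKI series, which are not redistributed here.
#'
#' @return data frame with columns `age`, `q_all`, `q_cancer`.
#' @export
default_mortality <- function() {
  read_mortality(
    system.file("extdata", "life_table_german_female_synthetic.csv",
                package = "bocprev", mustWork = TRUE),
    system.file("extdata", "cancer_mortality_german_female_synthetic.csv",
                package = "bocprev", mustWork = TRUE))
}

#' Base-case model parameters
#'
#' Loads the packaged base-case parameter fixture (natural history, surgery
#' effect measures, utilities and 2022 Euro costs) together with the
#' packaged synthetic background-mortality inputs.
#'
#' @param mortality optional replacement background-mortality data frame.
#' @return a validated `boc_params` object.
#' @export
default_parameters <- function(mortality = default_mortality()) {
  read_parameters(
    system.file("extdata", "parameters_base.csv", package = "bocprev",
                mustWork = TRUE),
    mortality = mortality)
}

#' Write a parameter set to a flat key-value file
#'
#' Inverse of [read_parameters()] (mortality inputs travel separately).
#'
#' @param p a `boc_params` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  bands <- sprintf("%d_%d", p$onset$breast$age_start, p$onset$breast$age_end)
  rows <- list()
  add <- function(key, value) rows[[length(rows) + 1]] <<- data.frame(key = key, value = value)
  for (cc in CANCERS) {
    b <- p$onset[[cc]]
    for (i in seq_len(nrow(b))) {
      add(sprintf("onset.%s.%s.first", cc, bands[i]), b$p_first[i])
      add(sprintf("onset.%s.%s.last", cc, bands[i]), b$p_last[i])
    }
    for (s in 1:3) add(sprintf("prog.%s.s%d_s%d", cc, s, s + 1), p$progression[[cc]][s])
    for (s in 1:4) add(sprintf("det.%s.s%d", cc, s), p$detection[[cc]][s])
    for (s in 1:4) add(sprintf("surv5.%s.s%d", cc, s), p$surv5[[cc]][s])
    const <- matrix(rep(annual_survival_from_5yr(p$surv5[[cc]]), 10), nrow = 4)
    if (any(abs(p$surv_annual[[cc]] - const) > 1e-12))
      for (s in 1:4) for (y in 1:10)
        add(sprintf("surv.%s.s%d.y%d", cc, s, y), p$surv_annual[[cc]][s, y])
  }
  for (k in c("rr_breast_pbm", "rr_breast_pbso", "rr_breast_both", "rr_ovarian_pbso"))
    add(paste0("effect.", k), p$effects[[k]])
  add("util.well", p$utilities$well)
  add("util.remission", p$utilities$remission)
  for (cc in CANCERS) for (s in 1:4) {
    add(sprintf("util.detected.%s.s%d", cc, s), p$utilities$detected[[cc]][s])
    add(sprintf("util.undetected.%s.s%d", cc, s), p$utilities$undetected[[cc]][s])
  }
  for (t in c("pbm", "pbso", "both")) add(paste0("util.surgery.", t), p$utilities$surgery[[t]])
  add("cost.surveillance", p$costs$surveillance)
  add("cost.surveillance_after_pbm_fraction", p$costs$surveillance_after_pbm_fraction)
  for (t in c("pbm", "pbso", "both")) add(paste0("cost.surgery.", t), p$costs$surgery[[t]])
  for (cc in CANCERS) {
    m <- p$costs$initial[[cc]]
    for (cl in rownames(m)) for (h in colnames(m))
      add(sprintf("cost.initial.%s.%s.%s", cc, cl, h), m[cl, h])
  }
  mb <- p$costs$followup$breast
  for (s in 1:4) for (h in colnames(mb))
    add(sprintf("cost.followup.breast.s%d.%s", s, h), mb[s, h])
  mo <- p$costs$followup$ovarian
  for (cl in rownames(mo)) for (h in colnames(mo))
    add(sprintf("cost.followup.ovarian.%s.%s", cl, h), mo[cl, h])
  add("cost.followup_years.breast", p$costs$followup_years[["breast"]])
  add("cost.followup_years.ovarian", p$costs$followup_years[["ovarian"]])
  add("cost.palliative.breast", p$costs$palliative[["breast"]])
  add("cost.palliative.ovarian", p$costs$palliative[["ovarian"]])
  for (k in c("discount_rate", "wtp", "start_age", "end_age"))
    add(paste0("analysis.", k), p$analysis[[k]])
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.boc_params <- function(x, ...) {
  cat("Breast/ovarian cancer prevention model parameters\n")
  cat(sprintf("  horizon: ages %d-%d, discount %.1f%%, WTP %s EUR\n",
              x$analysis$start_age, x$analysis$end_age,
              100 * x$analysis$discount_rate,
              format(x$analysis$wtp, big.mark = ",")))
  cat(sprintf("  onset bands: %d (breast), %d (ovarian); mortality table ages %d-%d\n",
              nrow(x$onset$breast), nrow(x$onset$ovarian),
              min(x$mortality$age), max(x$mortality$age)))
  invisible(x)
}
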
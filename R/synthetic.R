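# Synthetic input generators: parametric life tables and calibration
# targets, so that every pipeline stage runs offline. The packaged
# mortality fixtures are produced by these generators at their defaults.

#' Configuration for the synthetic mortality generator
#'
#' All-cause female mortality follows a Gompertz--Makeham hazard
#' `h(age) = makeham + gompertz_b * exp(gompertz_c * age)`, converted to
#' annual probabilities `q = 1 - exp(-h)`. The default parameters were
#' fitted once to published German female period-mortality anchors
#' (q35 about 4e-4, q50 about 2e-3, q70 about 1.15e-2, q90 about 0.135,
#' life expectancy at 30 about 53 years). The combined breast+ovarian
#' cancer mortality is a piecewise-linear share of the all-cause curve,
#' peaking in midlife where breast cancer is a leading cause of death in
#' women.
#'
#' @param makeham age-independent hazard term.
#' @param gompertz_b,gompertz_c Gompertz baseline and slope.
#' @param cancer_fraction data frame (`age`, `fraction`) of the
#'   breast+ovarian share of all-cause mortality, linearly interpolated.
#' @param ages integer age range of the generated table.
#' @param noise_sd standard deviation of optional lognormal perturbation
#'   noise on `q_all` (0 = none).
#' @param seed RNG seed used only when `noise_sd > 0`.
#' @return object of class `mortality_config`.
#' @export
synthetic_mortality_config <- function(makeham = 9.878e-5,
                                       gompertz_b = 6.818e-6,
                                       gompertz_c = 0.1094,
                                       cancer_fraction = data.frame(
                                         age = c(20, 30, 40, 50, 55, 60, 70,
                                                 80, 90, 100),
                                         fraction = c(0.02, 0.10, 0.22, 0.24,
                                                      0.22, 0.18, 0.10, 0.05,
                                                      0.02, 0.01)),
                                       ages = 20:100,
                                       noise_sd = 0, seed = 1) {
  stopifnot(makeham >= 0, gompertz_b >= 0, gompertz_c >= 0,
            all(cancer_fraction$fraction >= 0),
            all(cancer_fraction$fraction < 1))
  structure(list(makeham = makeham, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c, cancer_fraction = cancer_fraction,
                 ages = ages, noise_sd = noise_sd, seed = seed),
            class = "mortality_config")
}

#' Generate a synthetic background-mortality table
#'
#' Deterministic given the configuration (and seed, when perturbation
#' noise is requested). The generated curves satisfy
#' `q_cancer <= q_all < 1` at every age.
#'
#' @param cfg a `mortality_config` from [synthetic_mortality_config()].
#' @return data frame with columns `age`, `q_all`, `q_cancer`.
#' @export
make_life_table <- function(cfg = synthetic_mortality_config()) {
  stopifnot(inherits(cfg, "mortality_config"))
  h <- cfg$makeham + cfg$gompertz_b * exp(cfg$gompertz_c * cfg$ages)
  q_all <- 1 - exp(-h)
  if (cfg$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(cfg$seed)
    q_all <- q_all * exp(stats::rnorm(length(q_all), 0, cfg$noise_sd))
  }
  if (any(q_all >= 1))
    stop("mortality parameterisation produces q >= 1 before the end age")
  frac <- stats::approx(cfg$cancer_fraction$age, cfg$cancer_fraction$fraction,
                        xout = cfg$ages, rule = 2)$y
  data.frame(age = cfg$ages, q_all = q_all, q_cancer = frac * q_all)
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate synthetic calibration targets from known parameters
#'
#' Computes the model-implied incidence and stage-distribution endpoints of
#' a parameter set and optionally perturbs them with Gaussian relative
#' noise, enabling parameter-recovery experiments with a known truth.
#' Deterministic given the seed.
#'
#' @param true_params the generating `boc_params`.
#' @param noise_sd standard deviation of multiplicative Gaussian noise
#'   (0 = exact model predictions).
#' @param seed RNG seed.
#' @param config analysis configuration; defaults to `true_params$analysis`.
#' @return object of class `calibration_targets`.
#' @export
make_calibration_targets <- function(true_params, noise_sd = 0, seed = 1,
                                     config = NULL) {
  pred <- predict_targets(true_params, config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jitter <- function(v) v * (1 + stats::rnorm(length(v), 0, noise_sd))
  inc <- pred$incidence
  stg <- pred$stages
  if (noise_sd > 0) {
    inc$value <- pmin(pmax(jitter(inc$value), 0), 1)
    stg$value <- pmax(jitter(stg$value), 0)
    for (cc in unique(stg$cancer)) {
      k <- stg$cancer == cc
      stg$value[k] <- stg$value[k] / sum(stg$value[k])
    }
  }
  calibration_targets(inc, stg)
}

#' Remove every surgery-mediated difference from a parameter set
#'
#' Internal-validation helper: sets all surgery relative risks to 1, the
#' surgery cost to zero, the surgery-cycle utility to the well utility,
#' the post-PBM surveillance fraction to 1, and equalises all
#' surgery-history-specific treatment costs to their no-surgery values.
#' With these parameters every strategy must reproduce standard care
#' exactly, whatever its surgery schedule.
#'
#' @param params a `boc_params`.
#' @return modified `boc_params`.
#' @export
neutralize_surgery_effects <- function(params) {
  ef <- params$effects
  ef[c("rr_breast_pbm", "rr_breast_pbso", "rr_breast_both",
       "rr_ovarian_pbso", "rr_ovarian_both")] <- 1
  params$effects <- ef
  params$costs$surgery[] <- 0
  params$utilities$surgery[] <- params$utilities$well
  params$costs$surveillance_after_pbm_fraction <- 1
  params$costs$initial <- lapply(params$costs$initial, function(m) {
    m[, HISTORIES] <- m[, "none"]; m
  })
  params$costs$followup <- lapply(params$costs$followup, function(m) {
    m[, HISTORIES] <- m[, "none"]; m
  })
  validate_params(params)
  params
}
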
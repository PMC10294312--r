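# Shared fixtures and independent oracles used across the test files.

# flat background mortality: constant q_all, optional cancer share
flat_mortality <- function(q, ages = 20:100, cancer_frac = 0) {
  data.frame(age = ages, q_all = q, q_cancer = q * cancer_frac)
}

# set every onset band of a cancer to a constant annual probability
set_onset_const <- function(params, breast = NULL, ovarian = NULL) {
  if (!is.null(breast)) {
    params$onset$breast$p_first <- breast
    params$onset$breast$p_last <- breast
  }
  if (!is.null(ovarian)) {
    params$onset$ovarian$p_first <- ovarian
    params$onset$ovarian$p_last <- ovarian
  }
  params
}

# zero out every cost component
zero_costs <- function(params) {
  co <- params$costs
  co$surveillance <- 0
  co$surgery[] <- 0
  co$initial <- lapply(co$initial, function(m) m * 0)
  co$followup <- lapply(co$followup, function(m) m * 0)
  co$palliative[] <- 0
  params$costs <- co
  params
}

# a small parameter set for engine toys: immortal, no onset, unit utility
toy_immortal_params <- function(end_age = 99) {
  p <- default_parameters(mortality = flat_mortality(0))
  p <- set_onset_const(p, breast = 0, ovarian = 0)
  p <- zero_costs(p)
  p$utilities$well <- 1
  p$analysis$end_age <- end_age
  p
}

# brute-force frontier oracle: a point is on the frontier iff no single
# point weakly dominates it and no convex combination of two points does
frontier_oracle <- function(pts) {
  n <- nrow(pts)
  e <- pts$effect
  cc <- pts$cost
  dominated <- vapply(seq_len(n), function(i)
    any((e >= e[i] & cc <= cc[i]) & (e > e[i] | cc < cc[i])), TRUE)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (e[j] == e[k]) next
    inside <- e > min(e[j], e[k]) & e < max(e[j], e[k])
    t <- (e - e[j]) / (e[k] - e[j])
    cmix <- cc[j] + t * (cc[k] - cc[j])
    dominated <- dominated | (inside & cmix < cc)
  }
  sort(pts$id[!dominated])
}

# matrix-power life-expectancy oracle for the collapsed single-cancer toy:
# well -> undetected (detection 1, progression 0) -> 10 tunnel years
# (constant survival s) -> survivor; other-cause death at constant q
toy_chain_ly <- function(p_onset, q, s, n_cycles) {
  nst <- 14 # well, und, t1..t10, survivor, dead (lumped)
  P <- matrix(0, nst, nst)
  P[1, 1] <- (1 - q) * (1 - p_onset)
  P[1, 2] <- (1 - q) * p_onset
  P[1, 14] <- q
  P[2, 3] <- 1 - q
  P[2, 14] <- q
  for (y in 1:10) {
    from <- 2 + y
    to <- if (y < 10) from + 1 else 13
    P[from, to] <- s
    P[from, 14] <- 1 - s
  }
  P[13, 13] <- 1 - q
  P[13, 14] <- q
  x <- c(1, rep(0, nst - 1))
  ly <- 0
  for (t in seq_len(n_cycles)) {
    ly <- ly + sum(x[1:13])
    x <- as.vector(x %*% P)
  }
  ly
}

# engine configuration matching toy_chain_ly
toy_chain_params <- function(p_onset, q, s) {
  p <- default_parameters(mortality = flat_mortality(q))
  p <- set_onset_const(p, breast = p_onset, ovarian = 0)
  p$detection$breast <- c(1, 1, 1, 1)
  p$progression$breast <- c(0, 0, 0)
  p$surv_annual$breast <- matrix(s, 4, 10)
  p
}
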
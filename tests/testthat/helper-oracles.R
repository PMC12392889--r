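# Independent oracles: numerical integration of the pathway dose *rates*
# written directly from the model definition, never through the
# closed-form integrals under test.

# Instantaneous external dose rate (mGy/day) at time t for one deposition
# record; short-lived multiplier applies within the first model year.
external_dose_rate <- function(dep, sex, t, p) {
  e <- p$external
  snow <- 1 - e$snow_fraction_of_year * (1 - e$snow_factor)
  shield <- ifelse(sex == "M", e$shielding_factor_m, e$shielding_factor)
  w <- e$weathering_w1 * exp(-log(2) * t / e$weathering_T1) +
    e$weathering_w2 * exp(-log(2) * t / e$weathering_T2)
  rate <- 0
  for (nuc in c("Cs134", "Cs137")) {
    lam <- log(2) / nuclide(nuc)$half_life
    rate <- rate + deposition_activity(dep, nuc) * e$kerma_coeff[[nuc]] *
      w * exp(-lam * t)
  }
  rate * shield * snow * ifelse(t < DAYS_PER_YEAR, e$shortlived_multiplier, 1)
}

# Instantaneous radiocesium-ingestion dose rate (mGy/day).
cs_ingestion_dose_rate <- function(dep, sex, t, p) {
  ci <- p$cs_ingestion
  sexf <- ifelse(sex == "M", ci$male_factor, 1)
  rate <- 0
  for (nuc in c("Cs134", "Cs137")) {
    lam <- log(2) / nuclide(nuc)$half_life
    rate <- rate + ci$thyroid_doserate_coeff[[nuc]] *
      deposition_activity(dep, nuc) *
      (ci$tf_a1 * exp(-log(2) * t / ci$tf_T1) +
         ci$tf_a2 * exp(-log(2) * t / ci$tf_T2)) * exp(-lam * t)
  }
  rate * sexf
}

# Instantaneous milk-pathway dose rate (mGy/day): the saturating closed
# form differentiated by hand from the model definition.
milk_dose_rate <- function(dep, t, p) {
  m <- p$milk
  r <- log(2) / m$milk_effective_half_life
  deposition_activity(dep, "I131") * m$milk_transfer_integral * r *
    exp(-r * t) * m$milk_intake * m$ingestion_dose_coeff *
    m$countermeasure_factor
}

# Daily midpoint Riemann sum of a dose-rate function over [0, t_end],
# with the grid split at the first-year boundary so the short-lived
# multiplier's rate discontinuity falls on a cell edge (cells at the
# split are partial days).
riemann_dose <- function(rate_fun, t_end, step = 1) {
  piece <- function(t0, t1) {
    edges <- unique(c(seq(t0, t1, by = step), t1))
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    sum(rate_fun(mids) * diff(edges))
  }
  yr <- DAYS_PER_YEAR
  if (t_end <= yr) piece(0, t_end) else piece(0, yr) + piece(yr, t_end)
}

# One-location deposition record.
make_dep <- function(cs137 = 10, cs134_ratio = 0.55, i131_ratio = 4,
                     location_id = "L1") {
  data.frame(location_id = location_id, cs137_kBq_m2 = cs137,
             cs134_ratio = cs134_ratio, i131_ratio = i131_ratio,
             stringsAsFactors = FALSE)
}

# A tiny hand-built cohort: one woman, one man, single residence each.
make_tiny_cohort <- function(followup = ADMIN_END_DATE) {
  cohort <- data.frame(
    person_id = c("P1", "P2"),
    sex = c("F", "M"),
    birth_date = as.Date(c("1950-06-15", "1972-01-02")),
    followup_end = rep(as.Date(followup), 2),
    end_reason = c("administrative", "administrative"),
    stringsAsFactors = FALSE
  )
  residences <- data.frame(
    person_id = c("P1", "P2"),
    location_id = c("L1", "L1"),
    start_date = rep(EPOCH_DATE, 2),
    end_date = rep(as.Date(followup), 2),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, residences = residences)
}

# Random but valid parameter perturbation around the defaults, for
# property tests. Keeps every invariant of validate_params().
perturb_params <- function(p, scale = 0.5) {
  jitter1 <- function(x) x * exp(stats::runif(1, -scale, scale))
  w1 <- stats::runif(1, 0.2, 0.8)
  p$external$weathering_w1 <- w1
  p$external$weathering_w2 <- 1 - w1
  p$external$weathering_T1 <- jitter1(p$external$weathering_T1)
  p$external$weathering_T2 <- jitter1(p$external$weathering_T2)
  p$external$kerma_coeff$Cs134 <- jitter1(p$external$kerma_coeff$Cs134)
  p$external$kerma_coeff$Cs137 <- jitter1(p$external$kerma_coeff$Cs137)
  p$external$shortlived_multiplier <- stats::runif(1, 1, 3)
  p$cs_ingestion$tf_a1 <- jitter1(p$cs_ingestion$tf_a1)
  p$cs_ingestion$tf_a2 <- jitter1(p$cs_ingestion$tf_a2)
  p$cs_ingestion$tf_T1 <- jitter1(p$cs_ingestion$tf_T1)
  p$cs_ingestion$tf_T2 <- jitter1(p$cs_ingestion$tf_T2)
  p$cs_ingestion$male_factor <- stats::runif(1, 1, 2)
  p$milk$milk_effective_half_life <- stats::runif(1, 3, 8)
  p$milk$countermeasure_factor <- stats::runif(1, 0.1, 1)
  validate_params(p)
}
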
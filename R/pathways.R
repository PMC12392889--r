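# The four dose pathways. Every function is a pure, vectorised closed
# form in deposition, elapsed time and the parameter set; cumulative doses
# are measured from the fallout epoch (t = 0) in mGy to the thyroid.

#' Ground deposition of a nuclide at a location
#'
#' Deposition is stored once, as the Cs-137 level at the epoch plus
#' activity ratios; the Cs-134 and I-131 levels are derived, never stored.
#'
#' @param dep A deposition record: list or data.frame with columns
#'   \code{cs137_kBq_m2}, \code{cs134_ratio}, \code{i131_ratio}.
#' @param nuclide_name \code{"I131"}, \code{"Cs134"} or \code{"Cs137"}.
#' @return Deposition in kBq m\eqn{^{-2}} at the epoch.
#' @export
deposition_activity <- function(dep, nuclide_name) {
  switch(match.arg(nuclide_name, c("I131", "Cs134", "Cs137")),
         Cs137 = dep$cs137_kBq_m2,
         Cs134 = dep$cs137_kBq_m2 * dep$cs134_ratio,
         I131  = dep$cs137_kBq_m2 * dep$i131_ratio)
}

#' Weathering attenuation of ground shine
#'
#' Two-exponential soil-migration function, normalised to 1 at t = 0:
#' \eqn{w_1 2^{-t/T_1} + w_2 2^{-t/T_2}}. Physical decay is applied
#' separately per nuclide.
#'
#' @param t Days since deposition (nonnegative; vectorised).
#' @param params A \code{"pathway_params"} object.
#' @return Dimensionless attenuation in (0, 1].
#' @export
weathering <- function(t, params) {
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  e <- params$external
  e$weathering_w1 * exp(-log(2) * t / e$weathering_T1) +
    e$weathering_w2 * exp(-log(2) * t / e$weathering_T2)
}

# Integral over [t0, t1] of weathering(s) * exp(-lambda s), with the
# first model year additionally scaled by the short-lived multiplier.
.externa_kernel_integral <- function(lambda, e, t0, t1) {
  r1 <- log(2) / e$weathering_T1
  r2 <- log(2) / e$weathering_T2
  yr <- DAYS_PER_YEAR
  early <- double_exponential_integral(e$weathering_w1, r1, e$weathering_w2, r2,
                                       lambda, pmin(t0, yr), pmin(t1, yr))
  late <- double_exponential_integral(e$weathering_w1, r1, e$weathering_w2, r2,
                                      lambda, pmax(t0, yr), pmax(t1, yr))
  e$shortlived_multiplier * early + late
}

.sex_shielding <- function(sex, e) {
  ifelse(sex == "M", e$shielding_factor_m, e$shielding_factor)
}

#' Cumulative external (ground-shine) thyroid dose
#'
#' Combined external exposure from deposited Cs-134 and Cs-137, with
#' weathering, physical decay, occupancy/building shielding and an
#' annual-average snow correction; ground-deposited short-lived nuclides
#' enter as a multiplier on the first-year integral.
#'
#' @param dep Deposition record(s); see [deposition_activity()].
#' @param sex Character vector, \code{"F"} or \code{"M"}.
#' @param t_end Days since epoch (nonnegative; vectorised).
#' @param params A \code{"pathway_params"} object.
#' @param t_start Lower bound in days (default 0) for interval evaluation
#'   over residence periods.
#' @return Cumulative dose in mGy, nondecreasing in \code{t_end}.
#' @export
external_dose <- function(dep, sex, t_end, params, t_start = 0) {
  if (any(t_end < 0)) stop("'t_end' must be nonnegative", call. = FALSE)
  e <- params$external
  snow_corr <- 1 - e$snow_fraction_of_year * (1 - e$snow_factor)
  out <- 0
  for (nuc in c("Cs134", "Cs137")) {
    k <- e$kerma_coeff[[nuc]]
    if (is.null(k)) stop("no kerma coefficient configured for ", nuc, call. = FALSE)
    lam <- nuclide(nuc)$decay_constant
    out <- out + deposition_activity(dep, nuc) * k *
      .externa_kernel_integral(lam, e, t_start, t_end)
  }
  out * .sex_shielding(sex, e) * snow_corr
}

#' Whole-body radiocesium concentration from aggregate transfer
#'
#' Maps ground deposition directly to body activity concentration through
#' a two-component ecological decline times physical decay, with a
#' multiplicative male factor.
#'
#' @inheritParams external_dose
#' @param t Days since epoch.
#' @param nuclide_name \code{"Cs134"} or \code{"Cs137"}.
#' @return Bq per kg body mass.
#' @export
cs_body_concentration <- function(dep, sex, t, params, nuclide_name) {
  if (!nuclide_name %in% c("Cs134", "Cs137")) {
    stop("aggregate transfer is defined for the cesium pair only", call. = FALSE)
  }
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  ci <- params$cs_ingestion
  lam <- nuclide(nuclide_name)$decay_constant
  sex_fac <- ifelse(sex == "M", ci$male_factor, 1)
  deposition_activity(dep, nuclide_name) *
    (ci$tf_a1 * exp(-log(2) * t / ci$tf_T1) +
       ci$tf_a2 * exp(-log(2) * t / ci$tf_T2)) *
    exp(-lam * t) * sex_fac
}

#' Cumulative radiocesium ingestion thyroid dose
#'
#' Closed-form time integral of [cs_body_concentration()] times the
#' per-nuclide thyroid dose-rate coefficient, summed over Cs-134 and
#' Cs-137.
#'
#' @inheritParams external_dose
#' @return Cumulative dose in mGy.
#' @export
cs_ingestion_dose <- function(dep, sex, t_end, params, t_start = 0) {
  if (any(t_end < 0)) stop("'t_end' must be nonnegative", call. = FALSE)
  ci <- params$cs_ingestion
  sex_fac <- ifelse(sex == "M", ci$male_factor, 1)
  out <- 0
  for (nuc in c("Cs134", "Cs137")) {
    lam <- nuclide(nuc)$decay_constant
    out <- out + ci$thyroid_doserate_coeff[[nuc]] * deposition_activity(dep, nuc) *
      double_exponential_integral(ci$tf_a1, log(2) / ci$tf_T1,
                                  ci$tf_a2, log(2) / ci$tf_T2,
                                  lam, t_start, t_end)
  }
  out * sex_fac
}

#' Cumulative thyroid dose from iodine-131 in dairy milk
#'
#' The time-integrated milk concentration per unit deposition saturates
#' with the effective (physical plus ecological) half-life of I-131 in
#' milk; countermeasures (grazing restrictions, milk control) scale the
#' pathway down.
#'
#' @inheritParams external_dose
#' @return Cumulative dose in mGy; saturates as \code{t_end} grows.
#' @export
milk_iodine_dose <- function(dep, t_end, params) {
  if (any(t_end < 0)) stop("'t_end' must be nonnegative", call. = FALSE)
  m <- params$milk
  frac <- -expm1(-log(2) * t_end / m$milk_effective_half_life)
  deposition_activity(dep, "I131") * m$milk_transfer_integral * frac *
    m$milk_intake * m$ingestion_dose_coeff * m$countermeasure_factor
}

#' Thyroid dose from inhalation of airborne iodine-131
#'
#' The time-integrated air concentration is deposition divided by an
#' effective deposition velocity; the dose is delivered entirely within
#' the cloud-passage duration (linearly pro-rated for follow-up ending
#' inside it). The factor 1000 converts deposition from kBq to Bq.
#'
#' @inheritParams external_dose
#' @param t_end Days since epoch (default \code{Inf}: full delivery).
#' @return Dose in mGy, constant once \code{t_end >= cloud_duration}.
#' @export
inhalation_dose <- function(dep, params, t_end = Inf) {
  i <- params$inhalation
  if (i$deposition_velocity <= 0) {
    stop("deposition velocity must be strictly positive", call. = FALSE)
  }
  full <- (deposition_activity(dep, "I131") * 1000 / i$deposition_velocity) *
    i$breathing_rate * i$inhalation_dose_coeff
  full * pmin(t_end / i$cloud_duration, 1)
}
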
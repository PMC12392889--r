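# Synthetic fallout fields and closed cohorts. The generator emulates
# the statistical structure the dose reconstruction assumes: a
# right-skewed (lognormal) deposition field across locations, and a
# closed cohort fixed at the epoch and followed until death, emigration
# or administrative end, with Gompertz mortality calibrated so the
# expected 30-year death and emigration fractions match the study
# proportions (~34% deaths, ~3.6% emigrations).

#' Scenario configuration for the synthetic generator
#'
#' @param n_locations Number of deposition locations.
#' @param n_persons Cohort size.
#' @param seed RNG seed (mandatory; the whole scenario is reproducible).
#' @param dep_median_kBq_m2 Median of the lognormal Cs-137 deposition
#'   field at the epoch.
#' @param dep_gsd Geometric standard deviation (>= 1; 1 collapses the
#'   field to the median).
#' @param cs134_ratio,i131_ratio Activity ratios to Cs-137 at the epoch,
#'   applied to every location.
#' @param male_fraction Probability a person is male.
#' @param age_breaks,age_weights Piecewise-uniform age pyramid at the
#'   epoch (years); weights are segment probabilities.
#' @param target_death_fraction,target_emigration_fraction Expected
#'   fractions of the cohort ending in death / emigration over the
#'   follow-up window; defaults are the study proportions
#'   734211/2156084 and 77865/2156084.
#' @param gompertz_theta Gompertz log-slope of the mortality hazard,
#'   per year of age.
#' @param migration_rate Expected number of internal moves per person
#'   over the follow-up (Poisson); 0 keeps baseline scenarios simple.
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(n_locations = 50,
                            n_persons = 2000,
                            seed,
                            dep_median_kBq_m2 = 8,
                            dep_gsd = 2.0,
                            cs134_ratio = 0.55,
                            i131_ratio = 4.0,
                            male_fraction = 0.5,
                            age_breaks = c(0, 15, 30, 45, 65, 90),
                            age_weights = c(0.19, 0.21, 0.21, 0.23, 0.16),
                            target_death_fraction = 734211 / 2156084,
                            target_emigration_fraction = 77865 / 2156084,
                            gompertz_theta = 0.095,
                            migration_rate = 0) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (n_locations < 1) stop("need at least one location", call. = FALSE)
  if (dep_median_kBq_m2 <= 0 || dep_gsd < 1) {
    stop("deposition median must be positive and geometric SD >= 1", call. = FALSE)
  }
  if (length(age_weights) != length(age_breaks) - 1 || any(age_weights < 0)) {
    stop("age_weights must be one per age segment and nonnegative", call. = FALSE)
  }
  stopifnot(male_fraction >= 0, male_fraction <= 1,
            target_death_fraction >= 0, target_death_fraction < 1,
            target_emigration_fraction >= 0, target_emigration_fraction < 1,
            gompertz_theta > 0, migration_rate >= 0)
  structure(list(
    n_locations = n_locations, n_persons = n_persons, seed = as.integer(seed),
    dep_median_kBq_m2 = dep_median_kBq_m2, dep_gsd = dep_gsd,
    cs134_ratio = cs134_ratio, i131_ratio = i131_ratio,
    male_fraction = male_fraction,
    age_breaks = age_breaks, age_weights = age_weights / sum(age_weights),
    target_death_fraction = target_death_fraction,
    target_emigration_fraction = target_emigration_fraction,
    gompertz_theta = gompertz_theta, migration_rate = migration_rate
  ), class = "scenario_config")
}

#' Generate a synthetic deposition field
#'
#' Lognormal Cs-137 ground deposition across locations with fixed
#' nuclide ratios at the epoch.
#'
#' @param cfg A [scenario_config()].
#' @return Data frame: \code{location_id}, \code{cs137_kBq_m2},
#'   \code{cs134_ratio}, \code{i131_ratio}.
#' @export
generate_deposition <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_locations
  dep <- stats::rlnorm(n, meanlog = log(cfg$dep_median_kBq_m2),
                       sdlog = log(cfg$dep_gsd))
  data.frame(
    location_id = sprintf("L%05d", seq_len(n)),
    cs137_kBq_m2 = dep,
    cs134_ratio = cfg$cs134_ratio,
    i131_ratio = cfg$i131_ratio,
    stringsAsFactors = FALSE
  )
}

# Gompertz survival from age a0 (years): S(s) = exp(-(b/theta) *
# (exp(theta (a0 + s)) - exp(theta a0))).
.gompertz_cumhaz <- function(b, theta, a0, s) {
  (b / theta) * (exp(theta * (a0 + s)) - exp(theta * a0))
}

# Expected death and emigration fractions over a horizon of Th years for
# a piecewise-uniform age pyramid, under Gompertz mortality (scale b,
# slope theta, per year) competing with constant emigration hazard ev.
# Simpson quadrature in follow-up time on a fine age grid.
.expected_fractions <- function(b, ev, theta, age_breaks, age_weights, Th) {
  da <- 0.25
  a0 <- seq(min(age_breaks) + da / 2, max(age_breaks) - da / 2, by = da)
  dens <- numeric(length(a0))
  for (k in seq_along(age_weights)) {
    inseg <- a0 >= age_breaks[k] & a0 < age_breaks[k + 1]
    dens[inseg] <- age_weights[k] / (age_breaks[k + 1] - age_breaks[k])
  }
  w_age <- dens * da
  w_age <- w_age / sum(w_age)

  ns <- 301L                                  # odd, for Simpson
  s <- seq(0, Th, length.out = ns)
  hs <- s[2] - s[1]
  simp <- c(1, rep(c(4, 2), length.out = ns - 2), 1) * hs / 3
  A <- outer(a0, s, function(a, ss) {
    exp(-.gompertz_cumhaz(b, theta, a, ss) - ev * ss)
  })
  Hz <- outer(a0, s, function(a, ss) b * exp(theta * (a + ss)))
  p_death <- as.vector((A * Hz) %*% simp)
  p_emig <- as.vector(A %*% (simp)) * ev
  c(death = sum(w_age * p_death), emigration = sum(w_age * p_emig))
}

#' Calibrate mortality and emigration hazards to target fractions
#'
#' Alternating bisection on the Gompertz scale and the emigration rate
#' so that the expected death and emigration fractions over the
#' follow-up horizon match the configured targets under the scenario's
#' age pyramid.
#'
#' @param cfg A [scenario_config()].
#' @return List with \code{gompertz_b} (per year), \code{emigration_rate}
#'   (per year) and the achieved \code{expected} fractions.
#' @export
calibrate_hazards <- function(cfg) {
  Th <- followup_horizon_days() / DAYS_PER_YEAR
  theta <- cfg$gompertz_theta
  td <- cfg$target_death_fraction
  te <- cfg$target_emigration_fraction
  if (td == 0 && te == 0) {
    return(list(gompertz_b = 0, emigration_rate = 0,
                expected = c(death = 0, emigration = 0)))
  }
  ev <- if (te > 0) -log(1 - te) / Th else 0
  b <- 1e-4
  for (round in 1:4) {
    if (td > 0) {
      lo <- 1e-8; hi <- 1
      for (it in 1:60) {
        b <- sqrt(lo * hi)
        f <- .expected_fractions(b, ev, theta, cfg$age_breaks, cfg$age_weights, Th)
        if (f[["death"]] < td) lo <- b else hi <- b
      }
    } else b <- 0
    if (te > 0) {
      lo <- 1e-8; hi <- 1
      for (it in 1:60) {
        ev <- sqrt(lo * hi)
        f <- .expected_fractions(b, ev, theta, cfg$age_breaks, cfg$age_weights, Th)
        if (f[["emigration"]] < te) lo <- ev else hi <- ev
      }
    } else ev <- 0
  }
  list(gompertz_b = b, emigration_rate = ev,
       expected = .expected_fractions(b, ev, theta, cfg$age_breaks,
                                      cfg$age_weights, Th))
}

.sample_ages <- function(n, breaks, weights) {
  seg <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::runif(n, breaks[seg], breaks[seg + 1])
}

# Inverse-transform Gompertz event time from age a0, years.
.sample_gompertz <- function(n, b, theta, a0) {
  if (b <= 0) return(rep(Inf, n))
  u <- stats::runif(n)
  log(exp(theta * a0) - theta * log(u) / b) / theta - a0
}

#' Generate a synthetic closed cohort
#'
#' Ages at the epoch follow the configured piecewise-uniform pyramid;
#' death times are Gompertz with the calibrated scale, competing with
#' exponential emigration; events beyond the follow-up horizon are
#' censored administratively at its end. Residence histories are
#' contiguous from the epoch, with a Poisson number of internal moves
#' and uniform destinations.
#'
#' @param cfg A [scenario_config()].
#' @param deposition Deposition table (locations to assign people to).
#' @param hazards Optional output of [calibrate_hazards()]; computed
#'   from \code{cfg} when missing.
#' @return List with data.frames \code{cohort} and \code{residences} as
#'   consumed by [cohort_doses()].
#' @export
generate_cohort <- function(cfg, deposition, hazards = NULL) {
  if (nrow(deposition) == 0) stop("empty location list", call. = FALSE)
  if (is.null(hazards)) hazards <- calibrate_hazards(cfg)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_persons
  Th_days <- followup_horizon_days()
  Th <- Th_days / DAYS_PER_YEAR

  age0 <- .sample_ages(n, cfg$age_breaks, cfg$age_weights)
  sex <- ifelse(stats::runif(n) < cfg$male_fraction, "M", "F")
  t_death <- .sample_gompertz(n, hazards$gompertz_b, cfg$gompertz_theta, age0)
  t_emig <- if (hazards$emigration_rate > 0) {
    stats::rexp(n, rate = hazards$emigration_rate)
  } else rep(Inf, n)

  t_event <- pmin(t_death, t_emig)
  end_reason <- rep("administrative", n)
  end_reason[t_event < Th & t_death <= t_emig] <- "death"
  end_reason[t_event < Th & t_emig < t_death] <- "emigration"
  event_day <- pmin(ceiling(t_event * DAYS_PER_YEAR), Th_days - 1L)
  followup_end <- EPOCH_DATE + ifelse(end_reason == "administrative",
                                      Th_days - 1L, event_day)

  cohort <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    sex = sex,
    birth_date = EPOCH_DATE - round(age0 * DAYS_PER_YEAR),
    followup_end = followup_end,
    end_reason = end_reason,
    stringsAsFactors = FALSE
  )

  loc0 <- sample(deposition$location_id, n, replace = TRUE)
  span <- as.integer(followup_end - EPOCH_DATE)
  n_moves <- if (cfg$migration_rate > 0) {
    stats::rpois(n, cfg$migration_rate * span / Th_days)
  } else integer(n)
  movers <- which(n_moves > 0 & span >= 2)

  simple <- setdiff(seq_len(n), movers)
  res <- data.frame(person_id = cohort$person_id[simple],
                    location_id = loc0[simple],
                    start_date = rep(EPOCH_DATE, length(simple)),
                    end_date = followup_end[simple],
                    stringsAsFactors = FALSE)
  if (length(movers)) {
    mres <- vector("list", length(movers))
    for (j in seq_along(movers)) {
      i <- movers[j]
      mv <- sort(unique(sample.int(span[i] - 1L, min(n_moves[i], span[i] - 1L))))
      bnd <- c(0L, mv, span[i])
      locs <- c(loc0[i], sample(deposition$location_id, length(mv), replace = TRUE))
      mres[[j]] <- data.frame(person_id = cohort$person_id[i],
                              location_id = locs,
                              start_date = EPOCH_DATE + bnd[-length(bnd)],
                              end_date = EPOCH_DATE + bnd[-1],
                              stringsAsFactors = FALSE)
    }
    res <- rbind(res, do.call(rbind, mres))
  }
  res <- res[order(res$person_id, res$start_date), ]
  rownames(res) <- NULL
  list(cohort = cohort, residences = res)
}
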
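# Per-person dose assembly over residence histories with follow-up
# truncation, and cohort-level summaries.
#
# A cohort is two data.frames:
#   cohort:     person_id, sex ("F"/"M"), birth_date, followup_end,
#               end_reason ("death"/"emigration"/"administrative"),
#               optionally age_factor (scalar multiplier on the internal
#               pathways, default 1)
#   residences: person_id, location_id, start_date, end_date, with
#               half-open [start, end) intervals contiguous from the
#               epoch to followup_end.
# Exposure time for a person runs through the END of followup_end, i.e.
# t_end = (followup_end - epoch) + 1 days; a person whose follow-up ends
# on the epoch date itself contributes zero exposure.

.END_REASONS <- c("death", "emigration", "administrative")
.DOSE_COMPONENTS <- c("d_milk", "d_inh", "d_ext", "d_cs_ing", "d_total")

#' Validate a cohort and its residence histories
#'
#' Checks the closed-cohort invariants: births on or before the epoch,
#' follow-up within the administrative window, known end reasons, and
#' per-person residence intervals that are non-overlapping and contiguous
#' from the epoch to the end of follow-up.
#'
#' @param cohort,residences Data frames as described in
#'   [cohort_doses()].
#' @return \code{TRUE} invisibly; stops with a person-identifying message
#'   on the first violation.
#' @export
validate_cohort <- function(cohort, residences) {
  need <- c("person_id", "sex", "birth_date", "followup_end", "end_reason")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(cohort$person_id)) {
    stop("duplicate person_id in cohort: ",
         cohort$person_id[duplicated(cohort$person_id)][1], call. = FALSE)
  }
  if (!all(cohort$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'", call. = FALSE)
  if (!all(cohort$end_reason %in% .END_REASONS)) {
    stop("end_reason must be one of: ", paste(.END_REASONS, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.Date(cohort$birth_date) > EPOCH_DATE)) {
    bad <- cohort$person_id[as.Date(cohort$birth_date) > EPOCH_DATE][1]
    stop("closed cohort: birth after the epoch for person ", bad, call. = FALSE)
  }
  fe <- as.Date(cohort$followup_end)
  if (any(fe < EPOCH_DATE) || any(fe > ADMIN_END_DATE)) {
    stop("followup_end must lie within the follow-up window", call. = FALSE)
  }

  rneed <- c("person_id", "location_id", "start_date", "end_date")
  rmiss <- setdiff(rneed, names(residences))
  if (length(rmiss)) stop("residences is missing column(s): ",
                          paste(rmiss, collapse = ", "), call. = FALSE)
  if (!all(residences$person_id %in% cohort$person_id)) {
    stop("residence rows for unknown person_id", call. = FALSE)
  }
  rs <- residences[order(residences$person_id, as.Date(residences$start_date)), ]
  pid <- rs$person_id
  s <- as.Date(rs$start_date); e <- as.Date(rs$end_date)
  nohist <- setdiff(cohort$person_id, pid)
  if (length(nohist)) {
    stop("no residence history for person ", nohist[1], call. = FALSE)
  }
  if (any(e < s)) {
    stop("inverted residence interval for person ", pid[which(e < s)[1]],
         call. = FALSE)
  }
  first <- !duplicated(pid)
  last <- !duplicated(pid, fromLast = TRUE)
  if (any(s[first] > EPOCH_DATE)) {
    stop("residence history of person ", pid[first][s[first] > EPOCH_DATE][1],
         " does not cover the epoch", call. = FALSE)
  }
  inner <- which(!first[-1])   # rows whose predecessor is the same person
  if (length(inner) && any(s[inner + 1L] != e[inner])) {
    bad <- (inner + 1L)[s[inner + 1L] != e[inner]][1]
    stop("residence intervals of person ", pid[bad],
         " are not contiguous (gap or overlap)", call. = FALSE)
  }
  fe_last <- fe[match(pid[last], cohort$person_id)]
  if (any(e[last] != fe_last)) {
    stop("last residence of person ", pid[last][e[last] != fe_last][1],
         " does not end at followup_end", call. = FALSE)
  }
  invisible(TRUE)
}

.dep_lookup <- function(location_id, deposition, person_id) {
  idx <- match(location_id, deposition$location_id)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop("location '", location_id[i], "' of person ", person_id[i],
         " not found in the deposition table", call. = FALSE)
  }
  idx
}

# Per-person pathway components with every follow-up time capped at
# t_cap days since epoch. Returns a data.frame ordered by person_id.
.cohort_components <- function(cohort, residences, deposition, params,
                               t_cap = Inf, freeze_epoch_residence = FALSE) {
  co <- cohort[order(cohort$person_id), , drop = FALSE]
  age_fac <- if ("age_factor" %in% names(co)) co$age_factor else rep(1, nrow(co))
  t_end <- days_since_epoch(co$followup_end) + 1
  t_end[as.Date(co$followup_end) == EPOCH_DATE] <- 0
  t_end <- pmin(t_end, t_cap)

  rs <- residences[order(residences$person_id, as.Date(residences$start_date)), ]
  pidx <- match(rs$person_id, co$person_id)
  if (freeze_epoch_residence) {
    keep <- !duplicated(rs$person_id)      # first = epoch residence
    rs <- rs[keep, , drop = FALSE]
    pidx <- pidx[keep]
    t0 <- rep(0, nrow(rs))
    t1 <- t_end[pidx]
  } else {
    fe_days <- days_since_epoch(co$followup_end)[pidx]
    e_raw <- days_since_epoch(rs$end_date)
    # the residence ending at followup_end owns the final exposure day
    e_raw <- e_raw + as.integer(e_raw == fe_days)
    t0 <- pmin(pmax(days_since_epoch(rs$start_date), 0), t_end[pidx])
    t1 <- pmin(pmax(e_raw, 0), t_end[pidx])
  }
  didx <- .dep_lookup(rs$location_id, deposition, rs$person_id)
  dep <- deposition[didx, , drop = FALSE]
  sex <- co$sex[pidx]

  ext <- external_dose(dep, sex, t1, params, t_start = t0)
  csi <- cs_ingestion_dose(dep, sex, t1, params, t_start = t0)
  acc <- rowsum(cbind(ext, csi), group = pidx, reorder = TRUE)
  gidx <- as.integer(rownames(acc))
  out_ext <- numeric(nrow(co)); out_cs <- numeric(nrow(co))
  out_ext[gidx] <- acc[, "ext"]; out_cs[gidx] <- acc[, "csi"]

  # milk and inhalation: epoch residence only (both pathways complete
  # within weeks of fallout)
  first <- !duplicated(rs$person_id)
  dep0 <- dep[first, , drop = FALSE]
  p0 <- pidx[first]
  d_milk <- numeric(nrow(co)); d_inh <- numeric(nrow(co))
  d_milk[p0] <- milk_iodine_dose(dep0, t_end[p0], params)
  d_inh[p0]  <- inhalation_dose(dep0, params, t_end = t_end[p0])

  data.frame(
    person_id = co$person_id,
    sex = co$sex,
    d_milk = d_milk * age_fac,
    d_inh = d_inh * age_fac,
    d_ext = out_ext,
    d_cs_ing = out_cs * age_fac,
    stringsAsFactors = FALSE
  )
}

#' Thyroid dose for one person
#'
#' Evaluates the four-pathway dose over the person's residence history,
#' truncated at the end of follow-up. External and radiocesium-ingestion
#' doses are accumulated interval by interval as differences of the
#' cumulative closed forms; the milk and inhalation pathways use the
#' deposition at the residence occupied at the epoch.
#'
#' @param person One-row cohort data.frame (see [cohort_doses()]).
#' @param residences Residence intervals for (at least) this person.
#' @param deposition Deposition table: \code{location_id},
#'   \code{cs137_kBq_m2}, \code{cs134_ratio}, \code{i131_ratio}.
#' @param params A \code{"pathway_params"} object.
#' @param freeze_epoch_residence If \code{TRUE}, ignore internal
#'   migration and evaluate the whole follow-up at the epoch residence.
#' @return A one-row data.frame: \code{person_id}, \code{sex},
#'   \code{d_milk}, \code{d_inh}, \code{d_ext}, \code{d_cs_ing},
#'   \code{d_total} (mGy).
#' @export
person_dose <- function(person, residences, deposition, params,
                        freeze_epoch_residence = FALSE) {
  cohort_doses(person, residences[residences$person_id %in% person$person_id, ,
                                  drop = FALSE],
               deposition, params,
               freeze_epoch_residence = freeze_epoch_residence)
}

#' Thyroid doses for a whole cohort
#'
#' @param cohort Data frame: \code{person_id}, \code{sex},
#'   \code{birth_date}, \code{followup_end}, \code{end_reason}, optional
#'   \code{age_factor}.
#' @param residences Data frame of half-open residence intervals
#'   contiguous from the epoch to \code{followup_end}.
#' @inheritParams person_dose
#' @return A data.frame with one row per person, ordered by
#'   \code{person_id}, with the four components and their total (mGy).
#' @export
cohort_doses <- function(cohort, residences, deposition, params,
                         freeze_epoch_residence = FALSE) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  validate_cohort(cohort, residences)
  comp <- .cohort_components(cohort, residences, deposition, params,
                             freeze_epoch_residence = freeze_epoch_residence)
  comp$d_total <- comp$d_milk + comp$d_inh + comp$d_ext + comp$d_cs_ing
  rownames(comp) <- NULL
  comp
}

#' Assemble a dose-result row from its components
#'
#' The total is the sum of the four pathway components by construction.
#'
#' @param person_id Identifier(s).
#' @param d_milk,d_inh,d_ext,d_cs_ing Component doses in mGy.
#' @param sex Optional sex column.
#' @return Data frame with \code{d_total} appended.
#' @export
dose_result <- function(person_id, d_milk, d_inh, d_ext, d_cs_ing, sex = NA) {
  if (any(c(d_milk, d_inh, d_ext, d_cs_ing) < 0)) {
    stop("dose components must be nonnegative", call. = FALSE)
  }
  data.frame(person_id = person_id, sex = sex,
             d_milk = d_milk, d_inh = d_inh, d_ext = d_ext, d_cs_ing = d_cs_ing,
             d_total = d_milk + d_inh + d_ext + d_cs_ing,
             stringsAsFactors = FALSE)
}

#' Check the additivity invariant of a dose table
#'
#' @param dose_table Output of [cohort_doses()] or [dose_result()].
#' @param tol Relative tolerance.
#' @return \code{TRUE} invisibly; stops if any total deviates from the
#'   component sum.
#' @export
check_dose_additivity <- function(dose_table, tol = 1e-10) {
  s <- with(dose_table, d_milk + d_inh + d_ext + d_cs_ing)
  rel <- abs(dose_table$d_total - s) / pmax(abs(s), .Machine$double.eps)
  if (any(rel > tol)) {
    stop("additivity violated for person ",
         dose_table$person_id[which.max(rel)], call. = FALSE)
  }
  invisible(TRUE)
}

#' Sex-stratified summary of cohort doses
#'
#' Arithmetic mean, median, 5th and 95th percentiles (linear
#' interpolation between order statistics, quantile type 7), minimum and
#' maximum per sex and component, in mGy.
#'
#' @param dose_table Output of [cohort_doses()].
#' @return Long data.frame: \code{sex}, \code{component}, \code{n},
#'   \code{mean}, \code{median}, \code{p5}, \code{p95}, \code{min},
#'   \code{max}.
#' @export
summarize_doses <- function(dose_table) {
  if (nrow(dose_table) == 0) stop("empty dose table", call. = FALSE)
  out <- list()
  for (s in c("F", "M")) {
    d <- dose_table[dose_table$sex == s, , drop = FALSE]
    if (nrow(d) == 0) {
      warning("no persons of sex '", s, "'; group omitted from summary")
      next
    }
    for (comp in .DOSE_COMPONENTS) {
      x <- d[[comp]]
      q <- stats::quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        sex = s, component = comp, n = length(x),
        mean = mean(x), median = q[2], p5 = q[1], p95 = q[3],
        min = min(x), max = max(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Round a dose summary for reporting
#' @param summary Output of [summarize_doses()].
#' @param digits Decimal places in mGy (default 3).
#' @return The summary with statistics rounded.
#' @export
format_summary <- function(summary, digits = 3) {
  num <- c("mean", "median", "p5", "p95", "min", "max")
  summary[num] <- lapply(summary[num], round, digits = digits)
  summary
}

#' Share of a component in the total dose
#' @param component_mean,total_mean Mean doses in mGy.
#' @return Share in percent.
#' @export
component_share <- function(component_mean, total_mean) {
  100 * component_mean / total_mean
}

#' Sex-averaged mean dose
#'
#' Equal-weight average of the female and male means (the two strata are
#' of near-equal size in the populations this model targets).
#' @param female_mean,male_mean Mean doses in mGy.
#' @return Pooled mean in mGy.
#' @export
sex_averaged_mean <- function(female_mean, male_mean) {
  (female_mean + male_mean) / 2
}

#' Mean cumulative dose curves per sex and component
#'
#' Evaluates the cohort mean of each cumulative pathway dose on a time
#' grid, truncating every person at their own end of follow-up, as in the
#' cumulative-dose figures of protracted-exposure studies.
#'
#' @inheritParams cohort_doses
#' @param time_grid Strictly increasing days since epoch within
#'   \code{[0, followup_horizon_days()]}.
#' @return Long data.frame: \code{day}, \code{sex}, \code{component},
#'   \code{mean_mGy}; nondecreasing in \code{day} within each series.
#' @export
cumulative_curves <- function(cohort, residences, deposition, params,
                              time_grid) {
  if (any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing", call. = FALSE)
  }
  if (any(time_grid < 0) || any(time_grid > followup_horizon_days())) {
    stop("time_grid must lie within the follow-up window", call. = FALSE)
  }
  validate_cohort(cohort, residences)
  rows <- list()
  comps <- c("d_milk", "d_inh", "d_ext", "d_cs_ing")
  for (tt in time_grid) {
    comp <- .cohort_components(cohort, residences, deposition, params, t_cap = tt)
    comp$d_total <- comp$d_milk + comp$d_inh + comp$d_ext + comp$d_cs_ing
    for (s in c("F", "M")) {
      d <- comp[comp$sex == s, , drop = FALSE]
      if (nrow(d) == 0) next
      for (cc in .DOSE_COMPONENTS) {
        rows[[length(rows) + 1L]] <- data.frame(
          day = tt, sex = s, component = cc, mean_mGy = mean(d[[cc]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
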
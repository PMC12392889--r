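#' Read a pathway parameter set from a YAML configuration file
#'
#' The file must contain the four blocks \code{external},
#' \code{cs_ingestion}, \code{milk} and \code{inhalation}; see the shipped
#' default configuration
#' (\code{system.file("extdata", "default_params.yaml", package = "thyrodose")})
#' for the key-by-key units and provenance.
#'
#' @param path Path to a YAML file.
#' @return A validated parameter set of class \code{"pathway_params"}.
#' @seealso [default_params()], [validate_params()]
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  p <- yaml::read_yaml(path)
  validate_params(p)
}

#' Default pathway parameter set
#'
#' Loads the configuration shipped with the package. Every value in it is
#' a documented modelling decision, not a measured constant of the study
#' population.
#' @return A \code{"pathway_params"} object.
#' @export
default_params <- function() {
  read_params(system.file("extdata", "default_params.yaml",
                          package = "thyrodose", mustWork = TRUE))
}

#' Write a pathway parameter set to YAML
#' @param params A \code{"pathway_params"} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

.check_range <- function(x, name, lo = -Inf, hi = Inf, lo_open = FALSE) {
  if (is.null(x) || !is.numeric(x) || any(!is.finite(x))) {
    stop("parameter '", name, "' missing or non-numeric", call. = FALSE)
  }
  bad <- if (lo_open) any(x <= lo) else any(x < lo)
  if (bad || any(x > hi)) {
    stop(sprintf("parameter '%s' = %g outside [%g, %g]", name, x[1], lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a pathway parameter set
#'
#' Enforces the structural invariants of the model: weathering weights sum
#' to 1, shielding/snow/countermeasure factors lie in their unit ranges,
#' the male factor is at least 1, the milk effective half-life does not
#' exceed the 8.06 d physical half-life of iodine-131, and every rate or
#' coefficient is nonnegative.
#'
#' @param p A list with blocks \code{external}, \code{cs_ingestion},
#'   \code{milk}, \code{inhalation}.
#' @return \code{p} with class \code{"pathway_params"}.
#' @export
validate_params <- function(p) {
  for (blk in c("external", "cs_ingestion", "milk", "inhalation")) {
    if (is.null(p[[blk]])) stop("missing parameter block '", blk, "'", call. = FALSE)
  }
  e <- p$external
  for (nuc in c("Cs134", "Cs137")) {
    .check_range(e$kerma_coeff[[nuc]], paste0("external.kerma_coeff.", nuc), lo = 0)
  }
  .check_range(e$weathering_w1, "external.weathering_w1", 0, 1)
  .check_range(e$weathering_w2, "external.weathering_w2", 0, 1)
  if (abs(e$weathering_w1 + e$weathering_w2 - 1) > 1e-9) {
    stop("weathering weights must sum to 1", call. = FALSE)
  }
  .check_range(e$weathering_T1, "external.weathering_T1", 0, lo_open = TRUE)
  .check_range(e$weathering_T2, "external.weathering_T2", 0, lo_open = TRUE)
  .check_range(e$shielding_factor, "external.shielding_factor", 0, 1, lo_open = TRUE)
  if (is.null(e$shielding_factor_m)) p$external$shielding_factor_m <- e$shielding_factor
  .check_range(p$external$shielding_factor_m, "external.shielding_factor_m",
               0, 1, lo_open = TRUE)
  .check_range(e$snow_factor, "external.snow_factor", 0, 1, lo_open = TRUE)
  .check_range(e$snow_fraction_of_year, "external.snow_fraction_of_year", 0, 1)
  .check_range(e$shortlived_multiplier, "external.shortlived_multiplier", 1)

  ci <- p$cs_ingestion
  .check_range(ci$tf_a1, "cs_ingestion.tf_a1", 0)
  .check_range(ci$tf_a2, "cs_ingestion.tf_a2", 0)
  .check_range(ci$tf_T1, "cs_ingestion.tf_T1", 0, lo_open = TRUE)
  .check_range(ci$tf_T2, "cs_ingestion.tf_T2", 0, lo_open = TRUE)
  .check_range(ci$male_factor, "cs_ingestion.male_factor", 1)
  for (nuc in c("Cs134", "Cs137")) {
    .check_range(ci$thyroid_doserate_coeff[[nuc]],
                 paste0("cs_ingestion.thyroid_doserate_coeff.", nuc), lo = 0)
  }

  m <- p$milk
  .check_range(m$milk_transfer_integral, "milk.milk_transfer_integral", 0)
  .check_range(m$milk_effective_half_life, "milk.milk_effective_half_life",
               0, nuclide("I131")$half_life, lo_open = TRUE)
  .check_range(m$milk_intake, "milk.milk_intake", 0)
  .check_range(m$ingestion_dose_coeff, "milk.ingestion_dose_coeff", 0)
  .check_range(m$countermeasure_factor, "milk.countermeasure_factor", 0, 1)

  i <- p$inhalation
  .check_range(i$deposition_velocity, "inhalation.deposition_velocity", 0, lo_open = TRUE)
  .check_range(i$breathing_rate, "inhalation.breathing_rate", 0, lo_open = TRUE)
  .check_range(i$inhalation_dose_coeff, "inhalation.inhalation_dose_coeff", 0)
  .check_range(i$cloud_duration, "inhalation.cloud_duration", 0, lo_open = TRUE)

  class(p) <- "pathway_params"
  p
}
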
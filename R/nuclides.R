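#' Days per year used for half-life conversion
#'
#' Fixed Julian-year length used wherever half-lives quoted in years are
#' converted to days.
#' @export
DAYS_PER_YEAR <- 365.25

#' Physical decay constant from a half-life
#'
#' @param half_life Physical half-life in days; must be strictly positive.
#' @return Decay constant \eqn{\lambda = \ln 2 / T_{1/2}} in day\eqn{^{-1}}.
#' @examples
#' decay_constant(8.06)          # iodine-131
#' decay_constant(30.2 * 365.25) # cesium-137
#' @export
decay_constant <- function(half_life) {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) || any(half_life <= 0)) {
    stop("'half_life' must be a positive finite number of days", call. = FALSE)
  }
  log(2) / half_life
}

#' Nuclide registry
#'
#' The three fallout nuclides the dose model tracks, with physical
#' half-lives of 8.06 d (I-131), 2.06 y (Cs-134) and 30.2 y (Cs-137).
#' Short-lived chain members (e.g. metastable Ba-137m) are folded into the
#' emission-weighted dose coefficients, not modelled as separate terms.
#'
#' @param name One of \code{"I131"}, \code{"Cs134"}, \code{"Cs137"}.
#' @return A list of class \code{"nuclide"} with fields \code{name},
#'   \code{half_life} (days) and \code{decay_constant} (day\eqn{^{-1}}).
#' @examples
#' nuclide("Cs137")$half_life / 365.25  # 30.2 years
#' @export
nuclide <- function(name) {
  half_lives <- c(
    I131  = 8.06,
    Cs134 = 2.06 * DAYS_PER_YEAR,
    Cs137 = 30.2 * DAYS_PER_YEAR
  )
  name <- match.arg(name, names(half_lives))
  hl <- unname(half_lives[[name]])
  structure(
    list(name = name, half_life = hl, decay_constant = decay_constant(hl)),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %.4g d, lambda = %.6g /d\n",
              x$name, x$half_life, x$decay_constant))
  invisible(x)
}

#' All registered nuclides
#' @return Named list of the three \code{\link{nuclide}} objects.
#' @export
nuclide_registry <- function() {
  nm <- c("I131", "Cs134", "Cs137")
  stats::setNames(lapply(nm, nuclide), nm)
}
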
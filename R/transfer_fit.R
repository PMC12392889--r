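#' Fit the aggregate-transfer function to a body-burden time series
#'
#' Recovers the two-component ecological decline (amplitudes and
#' ecological half-lives) from observed whole-body radiocesium
#' concentrations by Levenberg-Marquardt least squares on
#' \deqn{c(t) = q \,[a_1 2^{-t/T_1} + a_2 2^{-t/T_2}]\, e^{-\lambda t},}
#' with \eqn{q} the deposition and \eqn{\lambda} the physical decay
#' constant, both known.
#'
#' @param t Days since epoch.
#' @param conc Body concentration, Bq per kg.
#' @param deposition Ground deposition in kBq m\eqn{^{-2}} (default 1).
#' @param nuclide_name \code{"Cs134"} or \code{"Cs137"} (fixes
#'   \eqn{\lambda}).
#' @param start Named list of starting values \code{a1, T1, a2, T2};
#'   defaults are crude (amplitude split of the initial value, half-lives
#'   one and ten years).
#' @return Named vector \code{c(a1, T1, a2, T2)} with \code{T1 <= T2}.
#' @export
fit_transfer_function <- function(t, conc, deposition = 1,
                                  nuclide_name = "Cs137",
                                  start = NULL) {
  lam <- nuclide(nuclide_name)$decay_constant
  y <- conc / (deposition * exp(-lam * t))
  if (is.null(start)) {
    c0 <- y[which.min(t)]
    start <- list(a1 = 0.7 * c0, T1 = DAYS_PER_YEAR, a2 = 0.3 * c0,
                  T2 = 10 * DAYS_PER_YEAR)
  }
  fit <- minpack.lm::nlsLM(
    y ~ a1 * 2^(-t / T1) + a2 * 2^(-t / T2),
    data = data.frame(t = t, y = y),
    start = start,
    lower = c(a1 = 0, T1 = 1, a2 = 0, T2 = 1),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  cf <- stats::coef(fit)
  if (cf[["T1"]] > cf[["T2"]]) {
    cf <- c(a1 = cf[["a2"]], T1 = cf[["T2"]], a2 = cf[["a1"]], T2 = cf[["T1"]])
  }
  cf[c("a1", "T1", "a2", "T2")]
}
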
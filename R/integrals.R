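# Exact time integrals of decaying exponentials: the kernel of every
# cumulative-dose expression in the model.

# Below this value of rate * (t1 - t0) the closed form
# (exp(-r t0) - exp(-r t1)) / r loses precision to cancellation and the
# linear (series) limit is used instead.
.ZERO_RATE_THRESHOLD <- 1e-10

#' Time integral of a decaying exponential
#'
#' Computes \eqn{\int_{t_0}^{t_1} e^{-r s}\, ds} in closed form.  For
#' \eqn{r (t_1 - t_0)} below \code{1e-10} the series limit
#' \eqn{e^{-r t_0} (t_1 - t_0)} is returned to avoid catastrophic
#' cancellation; for \code{t1 = Inf} the result is \eqn{e^{-r t_0} / r}.
#'
#' Vectorised over \code{rate}, \code{t0} and \code{t1} with the usual
#' recycling rules.
#'
#' @param rate Nonnegative decay rate in day\eqn{^{-1}}.
#' @param t0,t1 Interval bounds in days, \code{0 <= t0 <= t1};
#'   \code{t1} may be \code{Inf}.
#' @return The integral, in days.
#' @examples
#' integrated_exponential(0, 0, 10)                  # 10
#' integrated_exponential(decay_constant(8.06), 0, Inf)  # 8.06 / log(2)
#' @export
integrated_exponential <- function(rate, t0, t1) {
  n <- max(length(rate), length(t0), length(t1))
  rate <- rep_len(rate, n); t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
  if (any(rate < 0)) stop("'rate' must be nonnegative", call. = FALSE)
  if (any(t0 < 0)) stop("'t0' must be nonnegative", call. = FALSE)
  if (any(t1 < t0)) stop("'t1' must not be smaller than 't0'", call. = FALSE)

  dt <- t1 - t0
  out <- numeric(n)
  inf_t1 <- is.infinite(t1)
  small <- !inf_t1 & (rate * dt < .ZERO_RATE_THRESHOLD)
  # linear limit (covers rate == 0 exactly)
  out[small] <- exp(-rate[small] * t0[small]) * dt[small]
  big <- !inf_t1 & !small
  # -expm1(-r dt) is accurate for all r dt > 0
  out[big] <- exp(-rate[big] * t0[big]) * (-expm1(-rate[big] * dt[big])) / rate[big]
  if (any(inf_t1)) {
    if (any(rate[inf_t1] <= 0)) {
      stop("infinite upper bound requires a strictly positive rate", call. = FALSE)
    }
    out[inf_t1] <- exp(-rate[inf_t1] * t0[inf_t1]) / rate[inf_t1]
  }
  out
}

#' Time integral of a weighted double exponential under extra decay
#'
#' Computes
#' \eqn{\int_{t_0}^{t_1} [w_1 e^{-r_1 s} + w_2 e^{-r_2 s}]\, e^{-r_x s}\, ds},
#' the shared kernel of the weathering (ground-shine) and aggregate-transfer
#' (body-burden) integrals, where \eqn{r_x} is the physical decay constant
#' of the nuclide.
#'
#' @param w1,w2 Nonnegative weights (amplitudes).
#' @param r1,r2 Nonnegative component rates in day\eqn{^{-1}}.
#' @param extra_rate Nonnegative additional rate applied to both terms.
#' @param t0,t1 Interval bounds in days, \code{0 <= t0 <= t1}.
#' @return The integral, in days (times the unit of the weights).
#' @export
double_exponential_integral <- function(w1, r1, w2, r2, extra_rate, t0, t1) {
  if (any(w1 < 0) || any(w2 < 0)) stop("weights must be nonnegative", call. = FALSE)
  w1 * integrated_exponential(r1 + extra_rate, t0, t1) +
    w2 * integrated_exponential(r2 + extra_rate, t0, t1)
}
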
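# Calendar anchoring. All model time is measured in days since the fallout
# onset; dates appear only at I/O boundaries (ISO-8601 in CSV files).

#' Fallout onset date (model epoch, t = 0)
#' @export
EPOCH_DATE <- as.Date("1986-04-28")

#' Administrative end of follow-up
#' @export
ADMIN_END_DATE <- as.Date("2015-12-31")

#' Days since the fallout epoch
#'
#' @param date A \code{Date} (or string coercible to one).
#' @return Integer days since \code{\link{EPOCH_DATE}} (negative before it).
#' @export
days_since_epoch <- function(date) {
  as.integer(as.Date(date) - EPOCH_DATE)
}

#' Follow-up horizon in days
#'
#' Exposure days from the epoch through the end of the administrative
#' follow-up date: the date difference plus one, so the final calendar day
#' contributes a full day of exposure.
#' @return Integer number of days (10840).
#' @export
followup_horizon_days <- function() {
  days_since_epoch(ADMIN_END_DATE) + 1L
}
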
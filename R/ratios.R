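#' Waiting-time ratio
#'
#' The waiting-time ratio \eqn{\Delta_p} compares the wait a patient actually
#' experienced with the wait they expected:
#' \deqn{\Delta_p = \frac{\text{expected} - \text{actual}}{\text{expected}}.}
#' It is positive when the patient waited less than expected, zero when the
#' wait matched expectation, negative when it overran, and never exceeds 1
#' (the value attained when the actual wait is zero).
#'
#' @param expected_wait Expected waiting time in hours; must be strictly
#'   positive.
#' @param actual_wait Actual waiting time in hours; must be non-negative.
#'   Recycled against `expected_wait`.
#' @return A numeric vector of ratios, `<= 1` everywhere.
#' @examples
#' waiting_time_ratio(2, c(2, 1, 0))
#' @seealso [service_time_ratio()], [patient_satisfaction()]
#' @export
waiting_time_ratio <- function(expected_wait, actual_wait) {
  check_numeric(expected_wait, "expected_wait")
  check_numeric(actual_wait, "actual_wait")
  if (any(expected_wait <= 0)) {
    rlang::abort("`expected_wait` must be strictly positive (hours).",
                 class = "eslqueue_domain_error")
  }
  if (any(actual_wait < 0)) {
    rlang::abort("`actual_wait` must be non-negative (hours).",
                 class = "eslqueue_domain_error")
  }
  (expected_wait - actual_wait) / expected_wait
}

#' Service-time ratio
#'
#' The service-time ratio \eqn{\Delta_s} compares the time a staff member
#' actually spent with a patient against the time they consider ideal:
#' \deqn{\Delta_s = \frac{\text{actual} - \text{ideal}}{\text{ideal}}.}
#' It is negative when staff are rushed, zero at the ideal, positive when a
#' consultation overruns, and never falls below \eqn{-1} (attained when the
#' actual service time is zero).
#'
#' @param ideal_service Ideal service time in hours; strictly positive.
#' @param actual_service Actual service time in hours; non-negative. Recycled
#'   against `ideal_service`.
#' @return A numeric vector of ratios, `>= -1` everywhere.
#' @examples
#' service_time_ratio(2, c(2, 3, 1))
#' @seealso [waiting_time_ratio()], [staff_satisfaction()]
#' @export
service_time_ratio <- function(ideal_service, actual_service) {
  check_numeric(ideal_service, "ideal_service")
  check_numeric(actual_service, "actual_service")
  if (any(ideal_service <= 0)) {
    rlang::abort("`ideal_service` must be strictly positive (hours).",
                 class = "eslqueue_domain_error")
  }
  if (any(actual_service < 0)) {
    rlang::abort("`actual_service` must be non-negative (hours).",
                 class = "eslqueue_domain_error")
  }
  (actual_service - ideal_service) / ideal_service
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    rlang::abort(sprintf("`%s` must be finite numeric.", name),
                 class = "eslqueue_domain_error")
  }
  invisible(x)
}
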
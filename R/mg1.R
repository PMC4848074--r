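#' Service-time distribution
#'
#' Describes the service-time distribution of a single-server queue by its
#' family, mean and squared coefficient of variation (SCV, variance/mean^2).
#' The steady-state mean-wait analysis only needs the first two moments, so
#' arbitrary distributions enter through the SCV; the family matters to the
#' simulator, which draws actual service times.
#'
#' @param family One of `"exponential"` (SCV fixed at 1), `"deterministic"`
#'   (SCV fixed at 0), `"lognormal"` or `"gamma"` (SCV > 0 required).
#' @param mean Mean service time in hours; positive.
#' @param scv Squared coefficient of variation. Ignored (and forced) for the
#'   exponential and deterministic families.
#' @return An object of class `service_dist`.
#' @examples
#' service_dist("exponential", mean = 2)
#' service_dist("lognormal", mean = 1, scv = 0.25)
#' @export
service_dist <- function(family = c("exponential", "deterministic",
                                    "lognormal", "gamma"),
                         mean, scv = NULL) {
  family <- match.arg(family)
  check_numeric(mean, "mean")
  if (length(mean) != 1L || mean <= 0) {
    rlang::abort("`mean` must be a single positive service time (hours).",
                 class = "eslqueue_domain_error")
  }
  scv <- switch(family,
    exponential = {
      if (!is.null(scv) && abs(scv - 1) > 1e-12) {
        rlang::abort("exponential service has scv = 1 by definition.",
                     class = "eslqueue_domain_error")
      }
      1
    },
    deterministic = {
      if (!is.null(scv) && scv != 0) {
        rlang::abort("deterministic service has scv = 0 by definition.",
                     class = "eslqueue_domain_error")
      }
      0
    },
    {
      if (is.null(scv)) {
        rlang::abort(sprintf("`scv` is required for the %s family.", family),
                     class = "eslqueue_domain_error")
      }
      check_numeric(scv, "scv")
      if (scv <= 0) {
        rlang::abort("`scv` must be positive for lognormal/gamma service.",
                     class = "eslqueue_domain_error")
      }
      scv
    })
  structure(list(family = family, mean = mean, scv = scv),
            class = "service_dist")
}

#' Second moment of a service-time distribution
#'
#' Returns \eqn{E[S^2] = \text{mean}^2 (1 + \text{scv})}, the ingredient the
#' Pollaczek-Khinchine mean-wait formula needs beyond the mean.
#'
#' @param dist A [service_dist()] object.
#' @return The second moment in hours squared.
#' @examples
#' service_second_moment(service_dist("exponential", mean = 2))  # 8
#' @export
service_second_moment <- function(dist) {
  stopifnot(inherits(dist, "service_dist"))
  dist$mean^2 * (1 + dist$scv)
}

#' Single-server queue with Poisson arrivals (M/G/1)
#'
#' Couples a Poisson arrival stream with a general service-time
#' distribution. This is the queueing link between the staff side of care
#' (service time) and the patient side (waiting time): longer consultations
#' raise utilization and inflate the queueing delay every patient faces.
#'
#' @param arrival_rate Arrival rate \eqn{\lambda} in patients per hour;
#'   positive.
#' @param service A [service_dist()] object.
#' @return An object of class `mg1_system`.
#' @examples
#' sys <- mg1_system(0.25, service_dist("exponential", mean = 2))
#' mg1_utilization(sys)
#' mg1_mean_wait(sys)
#' @export
mg1_system <- function(arrival_rate, service) {
  check_numeric(arrival_rate, "arrival_rate")
  if (length(arrival_rate) != 1L || arrival_rate <= 0) {
    rlang::abort("`arrival_rate` must be a single positive rate (patients/hour).",
                 class = "eslqueue_domain_error")
  }
  stopifnot(inherits(service, "service_dist"))
  structure(list(arrival_rate = arrival_rate, service = service),
            class = "mg1_system")
}

#' @export
print.mg1_system <- function(x, ...) {
  cat(sprintf("M/G/1 system: lambda = %.4g /h, %s service (mean %.4g h, scv %.4g), rho = %.4g\n",
              x$arrival_rate, x$service$family, x$service$mean, x$service$scv,
              mg1_utilization(x)))
  invisible(x)
}

#' Utilization of an M/G/1 system
#'
#' The utilization factor \eqn{\rho = \lambda E[S]}, the ratio of arrival
#' rate to service rate. The queue is stable only for \eqn{\rho < 1}.
#'
#' @param sys An [mg1_system()] object.
#' @param require_stable If `TRUE`, raise an instability error when
#'   \eqn{\rho \ge 1} instead of returning the value.
#' @return The utilization \eqn{\rho}.
#' @export
mg1_utilization <- function(sys, require_stable = FALSE) {
  stopifnot(inherits(sys, "mg1_system"))
  rho <- sys$arrival_rate * sys$service$mean
  if (require_stable && rho >= 1) stop_unstable(rho, sys)
  rho
}

stop_unstable <- function(rho, sys) {
  rlang::abort(
    sprintf(
      "unstable queue: rho = %.4g >= 1 (arrival rate %.4g /h, mean service %.4g h; the longest stable mean service time is %.4g h).",
      rho, sys$arrival_rate, sys$service$mean, 1 / sys$arrival_rate),
    class = "eslqueue_instability")
}

#' Steady-state mean waiting time in queue (Pollaczek-Khinchine)
#'
#' Mean delay before service begins, excluding the service itself:
#' \deqn{W_q = \frac{\lambda E[S^2]}{2 (1 - \rho)}.}
#' This is the wait the patient-satisfaction curve sees by default
#' ("waiting time" as time before being seen).
#'
#' @param sys An [mg1_system()] object with \eqn{\rho < 1}.
#' @return Mean queueing delay in hours.
#' @examples
#' mg1_mean_wait(mg1_system(0.25, service_dist("exponential", mean = 2)))  # 2 h
#' @export
mg1_mean_wait <- function(sys) {
  rho <- mg1_utilization(sys, require_stable = TRUE)
  sys$arrival_rate * service_second_moment(sys$service) / (2 * (1 - rho))
}

#' Steady-state mean sojourn time
#'
#' Total time in the system, queueing delay plus the mean service time:
#' \eqn{W = W_q + E[S]}.
#'
#' @inheritParams mg1_mean_wait
#' @return Mean sojourn time in hours.
#' @export
mg1_mean_sojourn <- function(sys) {
  mg1_mean_wait(sys) + sys$service$mean
}

#' Steady-state mean queue length
#'
#' Mean number waiting in queue by Little's law: \eqn{L_q = \lambda W_q}.
#'
#' @inheritParams mg1_mean_wait
#' @return Mean number of patients waiting.
#' @export
mg1_mean_queue_length <- function(sys) {
  sys$arrival_rate * mg1_mean_wait(sys)
}
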
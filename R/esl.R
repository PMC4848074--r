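#' Satisfaction weights
#'
#' Weights of the two parties in the total satisfaction level. They must sum
#' to 1; the default is equal weighting.
#'
#' @param patient Weight on patient satisfaction, in \[0, 1\].
#' @param staff Weight on staff satisfaction, in \[0, 1\].
#' @return An object of class `satisfaction_weights`.
#' @export
satisfaction_weights <- function(patient = 0.5, staff = 0.5) {
  check_numeric(patient, "patient")
  check_numeric(staff, "staff")
  if (patient < 0 || patient > 1 || staff < 0 || staff > 1 ||
      abs(patient + staff - 1) > 1e-12) {
    rlang::abort("weights must lie in [0, 1] and sum to 1.",
                 class = "eslqueue_domain_error")
  }
  structure(list(patient = patient, staff = staff),
            class = "satisfaction_weights")
}

#' Total satisfaction level
#'
#' The weighted sum of patient and staff satisfaction at one operating
#' point: \eqn{TSL = w_p S_p + w_s U}.
#'
#' @param patient_level,staff_level Satisfaction levels (vectorized).
#' @param weights A [satisfaction_weights()] object.
#' @return Numeric TSL value(s).
#' @examples
#' total_satisfaction(1.0, 0.9)  # equal weights: 0.95
#' @export
total_satisfaction <- function(patient_level, staff_level,
                               weights = satisfaction_weights()) {
  stopifnot(inherits(weights, "satisfaction_weights"))
  weights$patient * patient_level + weights$staff * staff_level
}

#' Define a care-delivery scenario
#'
#' A scenario fixes everything except the operating point: the arrival
#' process, the service-time distribution family and variability, the ideal
#' service time, the patients' expected waiting time, the satisfaction
#' curve parameters, the weights, and the sweep grid of actual service
#' times to explore.
#'
#' The default arrival rate (0.25 patients/hour with exponential service)
#' makes the actual wait exactly 2 h when the actual service time equals the
#' 2 h ideal, so the default scenario is the harmonious case in which
#' patient expectation (2 h) and staff ideal can both be met.
#'
#' @param arrival_rate Arrival rate \eqn{\lambda}, patients/hour.
#' @param family,scv Service-time distribution family and squared
#'   coefficient of variation, as in [service_dist()].
#' @param ideal_service Staff ideal service time, hours.
#' @param expected_wait Patients' expected waiting time, hours.
#' @param weights A [satisfaction_weights()] object.
#' @param patient_params,staff_params Satisfaction curve parameters.
#' @param sweep_min,sweep_max,sweep_points Actual-service-time sweep grid
#'   (hours); must stay inside the stable region `(0, 1/arrival_rate)`.
#'   `sweep_max` defaults to the service time giving 95% utilization.
#' @param wait_includes_service If `TRUE`, the wait entering the
#'   waiting-time ratio is the full sojourn time (delay plus service);
#'   default is delay in queue only, i.e. "waiting" means time before being
#'   seen.
#' @return An object of class `esl_scenario`.
#' @examples
#' scn <- scenario()
#' sweep_tsc(scn)
#' @export
scenario <- function(arrival_rate = 0.25, family = "exponential", scv = NULL,
                     ideal_service = 2, expected_wait = 2,
                     weights = satisfaction_weights(),
                     patient_params = eslqueue::patient_params(),
                     staff_params = eslqueue::staff_params(),
                     sweep_min = 0.2, sweep_max = 0.95 / arrival_rate,
                     sweep_points = 400, wait_includes_service = FALSE) {
  check_numeric(arrival_rate, "arrival_rate")
  check_numeric(ideal_service, "ideal_service")
  check_numeric(expected_wait, "expected_wait")
  if (arrival_rate <= 0 || ideal_service <= 0 || expected_wait <= 0) {
    rlang::abort("rates and times must be positive.",
                 class = "eslqueue_domain_error")
  }
  stopifnot(inherits(weights, "satisfaction_weights"),
            inherits(patient_params, "patient_params"),
            inherits(staff_params, "staff_params"))
  if (sweep_points < 10) {
    rlang::abort("`sweep_points` must be at least 10.",
                 class = "eslqueue_domain_error")
  }
  if (sweep_min <= 0 || sweep_max >= 1 / arrival_rate || sweep_min >= sweep_max) {
    rlang::abort(sprintf(
      "sweep range must satisfy 0 < sweep_min < sweep_max < 1/arrival_rate = %.4g h (stability).",
      1 / arrival_rate), class = "eslqueue_domain_error")
  }
  structure(list(
    arrival_rate = arrival_rate, family = family, scv = scv,
    ideal_service = ideal_service, expected_wait = expected_wait,
    weights = weights, patient_params = patient_params,
    staff_params = staff_params,
    sweep = list(min = sweep_min, max = sweep_max, n = as.integer(sweep_points)),
    wait_includes_service = wait_includes_service
  ), class = "esl_scenario")
}

#' @export
print.esl_scenario <- function(x, ...) {
  cat(sprintf(
    "ESL scenario: lambda %.3g /h %s service, ideal %.3g h, expected wait %.3g h, weights %.2g/%.2g\n",
    x$arrival_rate, x$family, x$ideal_service, x$expected_wait,
    x$weights$patient, x$weights$staff))
  cat(sprintf("  sweep: actual service %.3g..%.3g h, %d points\n",
              x$sweep$min, x$sweep$max, x$sweep$n))
  invisible(x)
}

scenario_wait <- function(scn, actual_service) {
  rho <- scn$arrival_rate * actual_service
  if (any(rho >= 1)) {
    rlang::abort(sprintf(
      "unstable operating point: actual service must stay below 1/arrival_rate = %.4g h.",
      1 / scn$arrival_rate), class = "eslqueue_instability")
  }
  scv <- service_dist(scn$family, mean = 1, scv = scn$scv)$scv
  wq <- scn$arrival_rate * actual_service^2 * (1 + scv) / (2 * (1 - rho))
  if (scn$wait_includes_service) wq + actual_service else wq
}

#' Build the operating point at a given actual service time
#'
#' Composes the queueing link with both satisfaction curves: the actual
#' service time induces a mean waiting time through the M/G/1 relation; the
#' two ratios and satisfaction levels follow, as does the total
#' satisfaction level. Vectorized over `actual_service`.
#'
#' @param scn An [scenario()] object.
#' @param actual_service Actual mean service time(s), hours, inside the
#'   stable region.
#' @return A tibble with one row per service time and columns
#'   `actual_service_h, actual_wait_h, delta_s, delta_p, staff_level,
#'   patient_level, tsl`.
#' @examples
#' build_operating_point(scenario(), c(1, 2))
#' @export
build_operating_point <- function(scn, actual_service) {
  stopifnot(inherits(scn, "esl_scenario"))
  check_numeric(actual_service, "actual_service")
  if (any(actual_service < 0)) {
    rlang::abort("`actual_service` must be non-negative.",
                 class = "eslqueue_domain_error")
  }
  wait <- scenario_wait(scn, actual_service)
  delta_s <- service_time_ratio(scn$ideal_service, actual_service)
  delta_p <- waiting_time_ratio(scn$expected_wait, wait)
  staff_level <- staff_satisfaction(delta_s, scn$staff_params)
  patient_level <- patient_satisfaction(delta_p, scn$patient_params)
  tibble::tibble(
    actual_service_h = actual_service, actual_wait_h = wait,
    delta_s = delta_s, delta_p = delta_p,
    staff_level = staff_level, patient_level = patient_level,
    tsl = total_satisfaction(patient_level, staff_level, scn$weights))
}

#' Sweep the total satisfaction curve of a scenario
#'
#' Evaluates operating points across the scenario's sweep grid of actual
#' service times, orders them by increasing waiting-time ratio (note: larger
#' `delta_p` means a shorter actual wait, so the service axis runs
#' backwards), and locates the Effective Satisfaction Level via
#' [find_esl()].
#'
#' @param scn An [scenario()] object.
#' @return An object of class `esl_tsc`: `points` (tibble ordered by
#'   `delta_p`), `esl` (the maximum TSL after refinement), `eop` (one-row
#'   tibble, the effective operating point), `degenerate` (flag: all TSL
#'   values equal), and the scenario.
#' @examples
#' tsc <- sweep_tsc(scenario())
#' generics::glance(tsc)
#' @export
sweep_tsc <- function(scn) {
  stopifnot(inherits(scn, "esl_scenario"))
  grid <- seq(scn$sweep$min, scn$sweep$max, length.out = scn$sweep$n)
  points <- build_operating_point(scn, grid)
  points <- dplyr::arrange(points, .data$delta_p)
  res <- refine_esl(scn, points)
  structure(list(points = points, esl = res$esl, eop = res$eop,
                 degenerate = res$degenerate, scenario = scn),
            class = "esl_tsc")
}

refine_esl <- function(scn, points) {
  tsl <- points$tsl
  if (length(tsl) < 3) {
    rlang::abort("need at least 3 operating points.",
                 class = "eslqueue_domain_error")
  }
  if (diff(range(tsl)) == 0) {
    return(list(esl = tsl[1], eop = points[1, ], degenerate = TRUE))
  }
  j <- which.max(tsl)
  s <- points$actual_service_h
  neighbours <- s[max(1L, j - 1L):min(length(s), j + 1L)]
  lo <- min(neighbours)
  hi <- max(neighbours)
  opt <- stats::optimize(
    function(a) build_operating_point(scn, a)$tsl,
    interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  if (opt$objective >= tsl[j]) {
    eop <- build_operating_point(scn, opt$maximum)
  } else {
    eop <- points[j, ]
  }
  list(esl = max(opt$objective, tsl[j]), eop = eop, degenerate = FALSE)
}

#' Locate the Effective Satisfaction Level on a swept curve
#'
#' The ESL is the maximum total satisfaction level on the curve; the
#' Effective Operating Point (EOP) is the operating point attaining it. The
#' grid argmax is refined by golden-section search on actual service time
#' between the argmax's grid neighbours.
#'
#' @param tsc An `esl_tsc` object from [sweep_tsc()].
#' @return A list with `esl` and `eop` (one-row tibble).
#' @export
find_esl <- function(tsc) {
  stopifnot(inherits(tsc, "esl_tsc"))
  res <- refine_esl(tsc$scenario, tsc$points)
  res[c("esl", "eop")]
}

#' Distance of an operating point from the ESL
#'
#' How far the system, operating at a given actual service time, sits from
#' its Effective Satisfaction Level: useful when capacity constraints keep
#' a service off its optimum and managers want to quantify the satisfaction
#' gap and the service-time adjustment that would close it.
#'
#' @param scn An [scenario()] object.
#' @param actual_service Current actual mean service time, hours, within
#'   the sweep range.
#' @return One-row tibble with `delta_tsl` (ESL minus current TSL, >= 0) and
#'   `delta_service` (signed hours: positive means staff should slow down to
#'   reach the EOP).
#' @examples
#' distance_from_esl(scenario(), actual_service = 1)
#' @export
distance_from_esl <- function(scn, actual_service) {
  stopifnot(inherits(scn, "esl_scenario"), length(actual_service) == 1L)
  if (actual_service < scn$sweep$min || actual_service > scn$sweep$max) {
    rlang::abort(sprintf("`actual_service` must lie in the sweep range [%.4g, %.4g] h.",
                         scn$sweep$min, scn$sweep$max),
                 class = "eslqueue_domain_error")
  }
  tsc <- sweep_tsc(scn)
  op <- build_operating_point(scn, actual_service)
  d <- tsc$esl - op$tsl
  stopifnot(d > -1e-6)  # ESL is a refined maximum over the sweep
  tibble::tibble(delta_tsl = max(d, 0),
                 delta_service = tsc$eop$actual_service_h - actual_service)
}

#' Compare total satisfaction curves across expectation levels
#'
#' Sweeps one total satisfaction curve per expected waiting time, holding
#' everything else fixed: the machine-readable counterpart of comparing
#' TSCs for patient expectations of, e.g., half an hour versus two or three
#' hours at a fixed two-hour ideal service time.
#'
#' @param scn Base [scenario()]; its `expected_wait` is replaced per curve.
#' @param expected_waits Expected waiting times, hours. Default
#'   `c(0.5, 2, 3)`.
#' @return An object of class `esl_comparison`: `curves` (tibble of all
#'   operating points with an `expected_wait_h` column) and `summary`
#'   (tibble with one row per curve: `expected_wait_h, esl, eop_service_h,
#'   eop_wait_h, delta_p_at_eop`).
#' @examples
#' cmp <- scenario_compare(scenario())
#' cmp$summary
#' @export
scenario_compare <- function(scn, expected_waits = c(0.5, 2, 3)) {
  stopifnot(inherits(scn, "esl_scenario"))
  check_numeric(expected_waits, "expected_waits")
  tscs <- purrr::map(expected_waits, function(ew) {
    s <- scn
    s$expected_wait <- ew
    sweep_tsc(s)
  })
  curves <- purrr::map2_dfr(tscs, expected_waits, function(tsc, ew) {
    dplyr::mutate(tsc$points, expected_wait_h = ew, .before = 1)
  })
  summary <- purrr::map2_dfr(tscs, expected_waits, function(tsc, ew) {
    tibble::tibble(expected_wait_h = ew, esl = tsc$esl,
                   eop_service_h = tsc$eop$actual_service_h,
                   eop_wait_h = tsc$eop$actual_wait_h,
                   delta_p_at_eop = tsc$eop$delta_p)
  })
  structure(list(curves = curves, summary = summary, scenario = scn),
            class = "esl_comparison")
}

#' @export
print.esl_tsc <- function(x, ...) {
  cat(sprintf("Total satisfaction curve: %d operating points%s\n",
              nrow(x$points), if (x$degenerate) " (degenerate: flat TSL)" else ""))
  cat(sprintf("  ESL %.4f at actual service %.4f h (wait %.4f h, delta_p %.4f)\n",
              x$esl, x$eop$actual_service_h, x$eop$actual_wait_h, x$eop$delta_p))
  invisible(x)
}

#' @export
print.esl_comparison <- function(x, ...) {
  cat("TSC comparison across expected waiting times\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a swept total satisfaction curve
#'
#' @param x An `esl_tsc` object.
#' @param ... Unused.
#' @return The operating-point tibble, ordered by `delta_p`.
#' @method tidy esl_tsc
#' @export
tidy.esl_tsc <- function(x, ...) x$points

#' Glance at a swept total satisfaction curve
#'
#' @param x An `esl_tsc` object.
#' @param ... Unused.
#' @return One-row tibble: `esl, eop_service_h, eop_wait_h, delta_p_at_eop,
#'   degenerate`.
#' @method glance esl_tsc
#' @export
glance.esl_tsc <- function(x, ...) {
  tibble::tibble(esl = x$esl, eop_service_h = x$eop$actual_service_h,
                 eop_wait_h = x$eop$actual_wait_h,
                 delta_p_at_eop = x$eop$delta_p, degenerate = x$degenerate)
}

#' Tidy a scenario comparison
#'
#' @param x An `esl_comparison` object.
#' @param ... Unused.
#' @return The combined operating-point tibble with `expected_wait_h`.
#' @method tidy esl_comparison
#' @export
tidy.esl_comparison <- function(x, ...) x$curves

#' Glance at a scenario comparison
#'
#' @param x An `esl_comparison` object.
#' @param ... Unused.
#' @return The per-curve summary tibble.
#' @method glance esl_comparison
#' @export
glance.esl_comparison <- function(x, ...) x$summary
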
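#' Staff satisfaction model parameters
#'
#' Coefficients of the double-hyperbolic-tangent staff satisfaction curve
#' \deqn{U(\Delta_s) = a_1 \tanh(b_1 \Delta_s) +
#'       a_2 \Delta_s \tanh(b_2 \Delta_s) + c.}
#' The first term captures the asymmetric rise of satisfaction as staff move
#' from being rushed towards (and past) their ideal service time; the second,
#' an even and non-positive bell-shaped penalty, pulls satisfaction down
#' whenever the actual time departs from the ideal in either direction; `c`
#' is the level at the ideal (\eqn{\Delta_s = 0}).
#'
#' The defaults are the coefficients recovered from a 68-member staff
#' satisfaction survey in two accident-and-emergency departments.
#'
#' Because \eqn{a \tanh(bx) = (-a)\tanh(-bx)}, two sign patterns describe the
#' same curve; parameters are stored in the canonical representative
#' `b1 > 0`, `a2 >= 0`, `b2 < 0` (inputs in the mirrored pattern are flipped
#' on construction).
#'
#' @param a1 Amplitude of the first tanh term.
#' @param b1 Slope inside the first tanh; canonicalized positive.
#' @param a2 Amplitude of the linear-times-tanh term; canonicalized
#'   non-negative.
#' @param b2 Slope inside the second tanh; canonicalized negative.
#' @param c Satisfaction level at the ideal service time.
#' @return An object of class `staff_params` (a named list of the five
#'   coefficients, canonical signs).
#' @examples
#' staff_params()
#' staff_satisfaction(0, staff_params())  # the level at the ideal: 0.95
#' @export
staff_params <- function(a1 = 0.25, b1 = 1.72, a2 = 0.76, b2 = -4.43,
                         c = 0.95) {
  for (v in list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c)) {
    check_numeric(v, "staff parameter")
  }
  if (b1 == 0 || b2 == 0) {
    rlang::abort("tanh slopes `b1` and `b2` must be nonzero.",
                 class = "eslqueue_domain_error")
  }
  p <- canonicalize_staff_params(
    structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c),
              class = "staff_params"))
  p
}

#' Canonicalize staff-curve parameter signs
#'
#' Maps the sign-equivalent pairs \eqn{(a_1, b_1) \sim (-a_1, -b_1)} and
#' \eqn{(a_2, b_2) \sim (-a_2, -b_2)} to the representative with `b1 > 0`,
#' `a2 >= 0`, `b2 < 0`. The represented function is unchanged.
#'
#' @param params A `staff_params` object or named list with fields
#'   `a1, b1, a2, b2, c`.
#' @return A `staff_params` object with canonical signs.
#' @export
canonicalize_staff_params <- function(params) {
  p <- unclass(params)
  if (p$b1 < 0) {
    p$a1 <- -p$a1
    p$b1 <- -p$b1
  }
  if (p$a2 < 0) {
    p$a2 <- -p$a2
    p$b2 <- -p$b2
  }
  # a2 >= 0 now; a bell-shaped (penalty) second term needs b2 < 0, which the
  # flip cannot always deliver when a2 > 0 and b2 > 0 were supplied: that is
  # a genuinely different (unbounded-above) curve and is rejected.
  if (p$a2 > 0 && p$b2 > 0) {
    rlang::abort(
      "second-term signs (a2 > 0, b2 > 0) describe a convex reward, not a bell-shaped penalty; expected b2 < 0 after canonicalization.",
      class = "eslqueue_domain_error")
  }
  structure(p[c("a1", "b1", "a2", "b2", "c")], class = "staff_params")
}

#' @export
print.staff_params <- function(x, ...) {
  cat("Staff satisfaction curve  U(Ds) = a1*tanh(b1*Ds) + a2*Ds*tanh(b2*Ds) + c\n")
  cat(sprintf("  a1 = %.4g  b1 = %.4g  a2 = %.4g  b2 = %.4g  c = %.4g\n",
              x$a1, x$b1, x$a2, x$b2, x$c))
  invisible(x)
}

#' Patient satisfaction model parameters
#'
#' Parameters of the single-tanh patient satisfaction curve
#' \deqn{S_p(\Delta_p) = a \tanh(b (\Delta_p - x_0)) + c,}
#' a saturating, strictly increasing function of the waiting-time ratio in
#' the expectancy-disconfirmation tradition: satisfaction rises steeply
#' around the expectation point and saturates for waits much shorter than
#' expected.
#'
#' The default parameter set is constructed (not transcribed from a fitted
#' survey) so that a patient whose wait exactly matches expectation sits
#' near 0.90, zero wait scores slightly higher still (just below 1), and a
#' wait at twice the expectation scores near zero. All four values are
#' user-configurable.
#'
#' @param a Amplitude; positive.
#' @param b Slope; positive.
#' @param x0 Horizontal shift of the inflection point.
#' @param c Vertical offset.
#' @return An object of class `patient_params`.
#' @examples
#' patient_satisfaction(c(-1, 0, 1), patient_params())
#' @export
patient_params <- function(a = 0.5, b = 2.5, x0 = -0.44, c = 0.5) {
  for (v in list(a = a, b = b, x0 = x0, c = c)) check_numeric(v, "patient parameter")
  if (a <= 0 || b <= 0) {
    rlang::abort("`a` and `b` must be positive.", class = "eslqueue_domain_error")
  }
  if (a + c > 1 + 1e-12) {
    rlang::abort("`a + c` must not exceed 1: the curve must saturate at or below full satisfaction.",
                 class = "eslqueue_domain_error")
  }
  structure(list(a = a, b = b, x0 = x0, c = c), class = "patient_params")
}

#' @export
print.patient_params <- function(x, ...) {
  cat("Patient satisfaction curve  S(Dp) = a*tanh(b*(Dp - x0)) + c\n")
  cat(sprintf("  a = %.4g  b = %.4g  x0 = %.4g  c = %.4g\n", x$a, x$b, x$x0, x$c))
  invisible(x)
}

#' Staff satisfaction level at a service-time ratio
#'
#' Evaluates the double-tanh staff satisfaction curve at one or more
#' service-time ratios. No clipping is applied: the model is genuinely
#' negative for extreme ratios, and truncating it would corrupt downstream
#' optimisation of the total satisfaction curve.
#'
#' @param delta_s Service-time ratio(s), see [service_time_ratio()].
#' @param params A [staff_params()] object.
#' @return Numeric vector of satisfaction levels.
#' @examples
#' staff_satisfaction(c(-0.5, 0, 0.5))
#' @export
staff_satisfaction <- function(delta_s, params = staff_params()) {
  stopifnot(inherits(params, "staff_params"))
  check_numeric(delta_s, "delta_s")
  params$a1 * tanh(params$b1 * delta_s) +
    params$a2 * delta_s * tanh(params$b2 * delta_s) + params$c
}

#' Patient satisfaction level at a waiting-time ratio
#'
#' Evaluates the single-tanh patient satisfaction curve. Strictly increasing
#' in `delta_p` and bounded in `(c - a, c + a)`; not clipped.
#'
#' @param delta_p Waiting-time ratio(s), see [waiting_time_ratio()].
#' @param params A [patient_params()] object.
#' @return Numeric vector of satisfaction levels.
#' @examples
#' patient_satisfaction(c(-1, 0, 1))
#' @export
patient_satisfaction <- function(delta_p, params = patient_params()) {
  stopifnot(inherits(params, "patient_params"))
  check_numeric(delta_p, "delta_p")
  params$a * tanh(params$b * (delta_p - params$x0)) + params$c
}

#' Locate the peak of the staff satisfaction curve
#'
#' Finds the global maximum of the bell-shaped staff curve: a coarse grid
#' over ratios in \[-2, 2\] brackets the maximum, which is then refined by
#' golden-section/Brent search on the bracketing interval. For the default
#' coefficients the peak sits slightly past the ideal service time
#' (ratio about +0.067, level about 0.964): overrunning a little is mildly
#' preferred to rushing.
#'
#' @param params A [staff_params()] object.
#' @return A list with `delta_s` (the maximizing ratio) and `level` (the
#'   satisfaction there).
#' @examples
#' staff_peak()
#' @export
staff_peak <- function(params = staff_params()) {
  grid <- seq(-2, 2, by = 0.01)
  u <- staff_satisfaction(grid, params)
  i <- which.max(u)
  if (i == 1L || i == length(grid)) {
    rlang::abort(
      "no interior maximum on [-2, 2]: parameters do not describe a bell-shaped satisfaction curve.",
      class = "eslqueue_shape_error")
  }
  opt <- stats::optimize(function(x) staff_satisfaction(x, params),
                         interval = c(grid[i - 1L], grid[i + 1L]),
                         maximum = TRUE, tol = 1e-10)
  list(delta_s = opt$maximum, level = opt$objective)
}
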
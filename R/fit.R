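double_tanh <- function(theta, x) {
  theta[1] * tanh(theta[2] * x) + theta[3] * x * tanh(theta[4] * x) + theta[5]
}

double_tanh_jacobian <- function(theta, x) {
  t1 <- tanh(theta[2] * x)
  t2 <- tanh(theta[4] * x)
  cbind(
    a1 = t1,
    b1 = theta[1] * x * (1 - t1^2),
    a2 = x * t2,
    b2 = theta[3] * x^2 * (1 - t2^2),
    c = rep(1, length(x)))
}

default_fit_bounds <- function() {
  # open bounds at 0 for the slopes realised with a small epsilon
  list(lower = c(a1 = -2, b1 = 1e-6, a2 = 0, b2 = -20, c = -1),
       upper = c(a1 = 2, b1 = 20, a2 = 5, b2 = -1e-6, c = 2))
}

default_fit_starts <- function(level_mean) {
  grid <- expand.grid(b1 = c(0.5, 2, 8), b2 = c(-0.5, -2, -8))
  lapply(seq_len(nrow(grid)), function(i) {
    c(a1 = 0.3, b1 = grid$b1[i], a2 = 0.5, b2 = grid$b2[i], c = level_mean)
  })
}

#' Fit the double-tanh staff satisfaction curve
#'
#' Recovers the five coefficients of
#' \eqn{U(\Delta_s) = a_1 \tanh(b_1 \Delta_s) + a_2 \Delta_s
#' \tanh(b_2 \Delta_s) + c} from (ratio, level) observations by bounded
#' nonlinear least squares (Levenberg-Marquardt with the analytic residual
#' Jacobian). The loss surface is multi-modal in the slope parameters, so a
#' multi-start grid over slope magnitudes is used and the best sum of
#' squared errors kept; ties (within 1e-10) break to the smallest parameter
#' norm for determinism. The winning coefficient vector is sign-canonicalized
#' (`b1 > 0`, `a2 >= 0`, `b2 < 0`) before reporting.
#'
#' @param points Data frame with numeric columns `delta_s` and `level`, e.g.
#'   from [survey_to_points()]. At least 6 distinct `delta_s` values are
#'   required (five parameters plus one).
#' @param starts Optional list of named start vectors
#'   `c(a1, b1, a2, b2, c)`; defaults to a 9-point slope grid.
#' @param lower,upper Optional named bound vectors; defaults
#'   `a1 in [-2, 2]`, `b1 in (0, 20]`, `a2 in [0, 5]`, `b2 in [-20, 0)`,
#'   `c in [-1, 2]`.
#' @return An object of class `staff_fit`: `params` (a canonical
#'   [staff_params()]), `sse`, `r_squared` (`NA` for constant levels),
#'   `n_points`, `converged`, `n_starts_tried`, and `start_sse`, the
#'   objective at each start's initial point.
#' @examples
#' pts <- tibble::tibble(delta_s = seq(-1, 1, 0.05),
#'                       level = staff_satisfaction(seq(-1, 1, 0.05)))
#' fit <- fit_double_tanh(pts)
#' generics::tidy(fit)
#' @export
fit_double_tanh <- function(points, starts = NULL, lower = NULL, upper = NULL) {
  points <- as.data.frame(points)
  if (!all(c("delta_s", "level") %in% names(points))) {
    rlang::abort("`points` needs columns `delta_s` and `level`.",
                 class = "eslqueue_domain_error")
  }
  x <- points$delta_s
  y <- points$level
  check_numeric(x, "delta_s")
  check_numeric(y, "level")
  if (length(unique(x)) < 6L) {
    rlang::abort("need at least 6 distinct `delta_s` values to identify 5 parameters.",
                 class = "eslqueue_domain_error")
  }
  bounds <- default_fit_bounds()
  if (is.null(lower)) lower <- bounds$lower
  if (is.null(upper)) upper <- bounds$upper
  if (is.null(starts)) starts <- default_fit_starts(mean(y))
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  resid_fn <- function(theta) double_tanh(theta, x) - y
  jac_fn <- function(theta) double_tanh_jacobian(theta, x)
  sse_of <- function(theta) sum(resid_fn(theta)^2)

  runs <- lapply(starts, function(s) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, sse = fit$deviance, info = fit$info,
         start_sse = sse_of(s))
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) {
    rlang::abort("every optimisation start failed.", class = "eslqueue_fit_error")
  }
  sses <- purrr::map_dbl(runs, "sse")
  best_sse <- min(sses)
  tied <- which(sses <= best_sse + 1e-10)
  # deterministic tie-break: smallest parameter L2 norm
  norms <- purrr::map_dbl(runs[tied], ~ sqrt(sum(.x$par^2)))
  best <- runs[[tied[which.min(norms)]]]

  converged <- best$info %in% 1:3
  params <- canonicalize_staff_params(structure(
    as.list(stats::setNames(best$par, c("a1", "b1", "a2", "b2", "c"))),
    class = "staff_params"))
  gof <- goodness_of_fit(points, params)
  structure(list(
    params = params,
    sse = gof$sse,
    r_squared = gof$r_squared,
    n_points = length(x),
    converged = converged,
    n_starts_tried = length(runs),
    start_sse = purrr::map_dbl(runs, "start_sse")
  ), class = "staff_fit")
}

#' Goodness of fit of a staff curve against points
#'
#' @param points Data frame with columns `delta_s` and `level`.
#' @param params A [staff_params()] object.
#' @return A list with `sse` (sum of squared residuals) and `r_squared`
#'   (`1 - sse / total sum of squares`; `NA` when the levels are constant,
#'   for which R-squared is undefined).
#' @export
goodness_of_fit <- function(points, params) {
  points <- as.data.frame(points)
  if (nrow(points) == 0) {
    rlang::abort("`points` must be nonempty.", class = "eslqueue_domain_error")
  }
  resid <- points$level - staff_satisfaction(points$delta_s, params)
  sse <- sum(resid^2)
  tss <- sum((points$level - mean(points$level))^2)
  list(sse = sse, r_squared = if (tss == 0) NA_real_ else 1 - sse / tss)
}

#' @export
print.staff_fit <- function(x, ...) {
  cat(sprintf("Double-tanh staff satisfaction fit (%d points, %s)\n",
              x$n_points, if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  cat(sprintf("  SSE %.4g   R^2 %s   starts tried %d\n", x$sse,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$n_starts_tried))
  invisible(x)
}

#' Tidy a staff satisfaction fit
#'
#' @param x A `staff_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @method tidy staff_fit
#' @export
tidy.staff_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "b1", "a2", "b2", "c"),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' Glance at a staff satisfaction fit
#'
#' @param x A `staff_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `sse`, `r_squared`, `n_points`, `converged`,
#'   `n_starts_tried`.
#' @method glance staff_fit
#' @export
glance.staff_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r_squared = x$r_squared, n_points = x$n_points,
                 converged = x$converged, n_starts_tried = x$n_starts_tried)
}
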
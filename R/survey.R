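SURVEY_HEADER <- c("staff_id", "role", "department", "stage",
                   "norm_minutes", "offset_minutes", "likert")
SURVEY_OFFSETS <- c(-20, -15, -5, 0, 5, 15, 20)
SURVEY_STAGES <- c("triage", "first_assessment", "treatment")

#' Map a 5-point Likert rating to a satisfaction level
#'
#' Linear mapping of the ordinal ratings 1..5 (very dissatisfied .. very
#' satisfied) onto \[0, 1\]. The coding is configurable because survey
#' instruments do not fix a numeric scale; the linear map is the
#' conventional default.
#'
#' @param likert Integer rating(s) in 1..5.
#' @param mapping Numeric length-5 vector giving the level for each rating.
#' @return Numeric satisfaction level(s).
#' @examples
#' likert_to_level(1:5)
#' @export
likert_to_level <- function(likert, mapping = seq(0, 1, by = 0.25)) {
  if (length(mapping) != 5L || !is.numeric(mapping)) {
    rlang::abort("`mapping` must be a numeric 5-vector.",
                 class = "eslqueue_domain_error")
  }
  if (!is.numeric(likert) || anyNA(likert) || any(likert != as.integer(likert)) ||
      any(likert < 1) || any(likert > 5)) {
    rlang::abort("`likert` must be whole numbers in 1..5.",
                 class = "eslqueue_validation_error")
  }
  mapping[as.integer(likert)]
}

#' Generate a synthetic staff satisfaction survey
#'
#' Emulates the interview design behind the staff satisfaction curve: each
#' staff member (doctors and nurses across two emergency departments) states
#' a service-time norm for the three pathway stages (triage, first
#' assessment, treatment) and rates their satisfaction at offsets of 0 and
#' plus/minus 5, 15 and 20 minutes from that norm on a 5-point Likert scale.
#' Ratings are generated from the staff satisfaction curve at the probe's
#' service-time ratio, perturbed with Gaussian noise, clamped to \[0, 1\]
#' and quantized to the nearest Likert grade. Probes whose actual time would
#' be negative (a norm under 20 minutes probed at -20) are dropped and
#' counted in the provenance attribute.
#'
#' The offset-0 probe is a generator extension beyond the plus/minus design:
#' it identifies the fitted curve's level at the norm.
#'
#' @param n_staff Number of staff members; default 68, the size of the
#'   original interview study.
#' @param norm_spec Data frame with columns `stage`, `mean`, `sd` giving the
#'   truncated-normal distribution (minutes) each member's per-stage norm is
#'   drawn from. Defaults: triage 10 +/- 3, first assessment 20 +/- 5,
#'   treatment 40 +/- 10.
#' @param noise_sd Standard deviation of the Gaussian perturbation on the
#'   satisfaction level before quantization.
#' @param seed Seed for reproducibility.
#' @param params [staff_params()] generating curve.
#' @param mapping Likert coding, as in [likert_to_level()].
#' @return A tibble with columns
#'   `staff_id, role, department, stage, norm_minutes, offset_minutes, likert`
#'   and a `provenance` attribute recording the generator settings and the
#'   number of dropped probes.
#' @examples
#' survey <- generate_synthetic_survey(n_staff = 8, seed = 1)
#' dplyr::count(survey, stage)
#' @export
generate_synthetic_survey <- function(n_staff = 68,
                                      norm_spec = default_norm_spec(),
                                      noise_sd = 0.05, seed = 1,
                                      params = staff_params(),
                                      mapping = seq(0, 1, by = 0.25)) {
  stopifnot(n_staff >= 1)
  norm_spec <- tibble::as_tibble(norm_spec)
  if (!all(c("stage", "mean", "sd") %in% names(norm_spec)) ||
      any(norm_spec$mean <= 0) || any(norm_spec$sd < 0)) {
    rlang::abort("`norm_spec` needs columns stage/mean/sd with positive means.",
                 class = "eslqueue_domain_error")
  }
  set.seed(seed)
  staff <- tibble::tibble(
    staff_id = sprintf("S%03d", seq_len(n_staff)),
    role = sample(c("doctor", "nurse"), n_staff, replace = TRUE),
    department = sample(c("AE1", "AE2"), n_staff, replace = TRUE))

  norms <- tidyr::crossing(staff, norm_spec) |>
    dplyr::mutate(norm_minutes = round(rnorm_truncated(dplyr::n(), .data$mean,
                                                       .data$sd), 2)) |>
    dplyr::select("staff_id", "role", "department", "stage", "norm_minutes")

  full <- tidyr::crossing(norms, offset_minutes = SURVEY_OFFSETS)
  dropped <- sum(full$norm_minutes + full$offset_minutes < 0)
  full <- dplyr::filter(full, .data$norm_minutes + .data$offset_minutes >= 0)

  level <- staff_satisfaction(full$offset_minutes / full$norm_minutes, params) +
    stats::rnorm(nrow(full), sd = noise_sd)
  level <- pmin(pmax(level, 0), 1)
  full$likert <- vapply(level, function(l) which.min(abs(mapping - l)),
                        integer(1))

  out <- dplyr::arrange(full, .data$staff_id, .data$stage,
                        .data$offset_minutes)[, SURVEY_HEADER]
  attr(out, "provenance") <- list(
    generator = "eslqueue::generate_synthetic_survey (synthetic data)",
    n_staff = n_staff, noise_sd = noise_sd, seed = seed,
    dropped_probes = dropped)
  out
}

default_norm_spec <- function() {
  tibble::tibble(stage = SURVEY_STAGES,
                 mean = c(10, 20, 40), sd = c(3, 5, 10))
}

rnorm_truncated <- function(n, mean, sd, lower = 0.5) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Convert survey records to model-fitting points
#'
#' Turns each survey probe into a (service-time ratio, satisfaction level)
#' pair: the respondent's own norm is the ideal time, so
#' `delta_s = offset / norm`, and the Likert rating maps linearly to a
#' level. Row order is preserved.
#'
#' When the points feed [fit_double_tanh()], set `ratio_limit = 1`:
#' respondents with short norms are probed at ratios where the satisfaction
#' curve drops below the Likert scale's floor, and those floor-censored
#' ratings bias an uncensored least-squares fit. Restricting to
#' `|delta_s| <= 1` — the bell range the staff curve is defined over —
#' avoids the bias.
#'
#' @param survey A survey data frame with the columns written by
#'   [generate_synthetic_survey()] / [read_survey_csv()].
#' @param mapping Likert coding, as in [likert_to_level()].
#' @param ratio_limit If non-`NULL`, drop records with
#'   `|delta_s| > ratio_limit`. Default `NULL` keeps every record.
#' @return A tibble with columns `delta_s` and `level`, one row per
#'   retained record.
#' @examples
#' survey_to_points(generate_synthetic_survey(n_staff = 4, seed = 1))
#' @export
survey_to_points <- function(survey, mapping = seq(0, 1, by = 0.25),
                             ratio_limit = NULL) {
  validate_survey(survey)
  out <- tibble::tibble(
    delta_s = survey$offset_minutes / survey$norm_minutes,
    level = likert_to_level(survey$likert, mapping))
  if (!is.null(ratio_limit)) {
    check_numeric(ratio_limit, "ratio_limit")
    out <- dplyr::filter(out, abs(.data$delta_s) <= ratio_limit)
  }
  out
}

validate_survey <- function(survey) {
  if (!is.data.frame(survey) || nrow(survey) == 0) {
    rlang::abort("survey must be a nonempty data frame.",
                 class = "eslqueue_validation_error")
  }
  missing_cols <- setdiff(SURVEY_HEADER, names(survey))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("survey is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "eslqueue_validation_error")
  }
  bad <- which(survey$norm_minutes <= 0 |
                 survey$norm_minutes + survey$offset_minutes < 0 |
                 !(survey$likert %in% 1:5))
  if (length(bad) > 0) {
    rlang::abort(sprintf("invalid survey record(s) at row(s): %s",
                         paste(utils::head(bad, 5), collapse = ", ")),
                 class = "eslqueue_validation_error")
  }
  dup <- duplicated(survey[, c("staff_id", "stage", "offset_minutes")])
  if (any(dup)) {
    rlang::abort(sprintf("duplicate (staff_id, stage, offset) at row(s): %s",
                         paste(utils::head(which(dup), 5), collapse = ", ")),
                 class = "eslqueue_validation_error")
  }
  invisible(survey)
}

#' Write a survey to CSV
#'
#' UTF-8 CSV with the exact header
#' `staff_id,role,department,stage,norm_minutes,offset_minutes,likert`.
#'
#' @param survey Survey data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  validate_survey(survey)
  readr::write_csv(survey[, SURVEY_HEADER], path)
  invisible(path)
}

#' Read a survey from CSV
#'
#' Validates the header verbatim, then the records.
#'
#' @param path CSV path as written by [write_survey_csv()].
#' @return A survey tibble.
#' @export
read_survey_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, paste(SURVEY_HEADER, collapse = ","))) {
    rlang::abort(sprintf("unexpected survey header: %s", header),
                 class = "eslqueue_validation_error")
  }
  out <- readr::read_csv(path, col_types = readr::cols(
    staff_id = readr::col_character(), role = readr::col_character(),
    department = readr::col_character(), stage = readr::col_character(),
    norm_minutes = readr::col_double(), offset_minutes = readr::col_double(),
    likert = readr::col_integer()))
  validate_survey(out)
  out
}
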
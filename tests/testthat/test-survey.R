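test_that("Likert ratings map linearly onto [0, 1]", {
  expect_equal(likert_to_level(1:5), c(0, 0.25, 0.5, 0.75, 1))
  expect_error(likert_to_level(0), class = "eslqueue_validation_error")
  expect_error(likert_to_level(6), class = "eslqueue_validation_error")
  expect_error(likert_to_level(2.5), class = "eslqueue_validation_error")
  # configurable coding
  expect_equal(likert_to_level(3, mapping = c(0, 0.1, 0.5, 0.9, 1)), 0.5)
})

test_that("survey records convert to ratio/level points by definition", {
  survey <- tibble::tibble(
    staff_id = c("A", "B", "C"), role = "nurse", department = "AE1",
    stage = c("triage", "first_assessment", "treatment"),
    norm_minutes = c(20, 30, 15), offset_minutes = c(-5, 0, 15),
    likert = c(2L, 5L, 3L))
  pts <- survey_to_points(survey)
  expect_equal(pts$delta_s, c(-0.25, 0, 1))
  expect_equal(pts$level, c(0.25, 1, 0.5))
  expect_equal(nrow(pts), nrow(survey))

  bad <- survey
  bad$likert[2] <- 9L
  expect_error(survey_to_points(bad), regexp = "row",
               class = "eslqueue_validation_error")
})

test_that("generator reproduces the interview design", {
  survey <- generate_synthetic_survey(n_staff = 68, seed = 4)
  prov <- attr(survey, "provenance")
  # 68 staff x 3 stages x 7 probes, minus probes whose actual time would be
  # negative (short norms probed at -15/-20)
  expect_equal(nrow(survey) + prov$dropped_probes, 68 * 3 * 7)
  expect_setequal(unique(survey$stage),
                  c("triage", "first_assessment", "treatment"))
  expect_setequal(unique(survey$offset_minutes), c(-20, -15, -5, 0, 5, 15, 20))
  expect_true(all(survey$likert %in% 1:5))
  expect_true(all(survey$norm_minutes + survey$offset_minutes >= 0))
  expect_false(any(duplicated(survey[, c("staff_id", "stage", "offset_minutes")])))
  # all ratios respect the lower bound
  expect_true(all(survey_to_points(survey)$delta_s >= -1))

  # staff with generous norms see exactly the designed probe multiset
  wide <- generate_synthetic_survey(
    n_staff = 10, seed = 4,
    norm_spec = tibble::tibble(stage = "treatment", mean = 40, sd = 2))
  expect_true(all(wide$norm_minutes >= 20))
  for (df in split(wide, wide$staff_id)) {
    expect_setequal(df$offset_minutes / df$norm_minutes,
                    c(-20, -15, -5, 0, 5, 15, 20) / df$norm_minutes[1])
  }
})

test_that("noise-free ratings sit within a Likert half-step of the true curve", {
  survey <- generate_synthetic_survey(n_staff = 20, noise_sd = 0, seed = 8)
  pts <- survey_to_points(survey)
  truth <- pmin(pmax(staff_satisfaction(pts$delta_s), 0), 1)
  expect_true(all(abs(pts$level - truth) <= 0.125 + 1e-12))
})

test_that("generation is seed-reproducible and the CSV round-trips exactly", {
  a <- generate_synthetic_survey(n_staff = 12, seed = 99)
  b <- generate_synthetic_survey(n_staff = 12, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))

  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(a, path)
  expect_identical(readLines(path, n = 1),
                   "staff_id,role,department,stage,norm_minutes,offset_minutes,likert")
  back <- read_survey_csv(path)
  strip <- function(d) { attr(d, "provenance") <- NULL; as.data.frame(d) }
  expect_identical(strip(back), strip(a))

  # header is validated verbatim
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("staff,role", "x,y"), bad)
  expect_error(read_survey_csv(bad), class = "eslqueue_validation_error")
})

test_that("ratio_limit restricts fitting points to the curve's bell range", {
  survey <- generate_synthetic_survey(n_staff = 30, seed = 5)
  all_pts <- survey_to_points(survey)
  capped <- survey_to_points(survey, ratio_limit = 1)
  expect_true(all(abs(capped$delta_s) <= 1))
  expect_lt(nrow(capped), nrow(all_pts))
})
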
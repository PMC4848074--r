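# Shared fixtures: the published staff-curve coefficients, noise-free grid
# samples of that curve, and a brute-force dense-grid ESL oracle.

published <- staff_params()  # (0.25, 1.72, 0.76, -4.43, 0.95)

noise_free_grid <- function(step = 0.01, params = published) {
  x <- seq(-1, 1, by = step)
  tibble::tibble(delta_s = x, level = staff_satisfaction(x, params))
}

# Independent oracle for the ESL: exhaustive evaluation of the TSL on a
# dense actual-service grid (step in hours), no refinement.
dense_grid_esl <- function(scn, step = 1e-4) {
  s <- seq(scn$sweep$min, scn$sweep$max, by = step)
  op <- build_operating_point(scn, s)
  j <- which.max(op$tsl)
  list(esl = op$tsl[j], service = s[j])
}
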
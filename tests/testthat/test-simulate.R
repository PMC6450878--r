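test_that("identical parameters give bit-identical fields", {
  p <- fast_params(enrichment_factor = 3, cluster_angle = "random", seed = 7L)
  expect_identical(simulate_field(p), simulate_field(p))
})

test_that("noise-free intensities scale linearly with baseline and background", {
  p1 <- noise_free(enrichment_factor = 3, baseline_intensity = 50,
                   background_level = 10)
  p2 <- update_params(p1, baseline_intensity = 150, background_level = 30)
  f1 <- simulate_field(p1)$field
  f2 <- simulate_field(p2)$field
  for (ch in names(f1$channels)) {
    expect_equal(f2$channels[[ch]], 3 * f1$channels[[ch]], tolerance = 1e-12)
  }
})

test_that("ground-truth ratio follows (E*c + b)/(c + b) with blur and noise off", {
  for (E in c(1, 3)) {
    for (b in c(0, 20)) {
      sim <- simulate_field(noise_free(enrichment_factor = E,
                                       background_level = b, blur = FALSE))
      expected <- (E * 60 + b) / (60 + b)
      expect_equal(recruitment_oracle(sim$field, sim$truth), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("the POI peak is exactly E*c without blur or noise", {
  sim <- simulate_field(noise_free(enrichment_factor = 3, blur = FALSE))
  expect_equal(max(sim$field$channels$poi), 3 * 60, tolerance = 1e-12)
  expect_true(all(sim$field$channels$bacteria[!sim$truth$cluster_mask] == 0))
})

test_that("invalid geometry and invalid parameters are rejected", {
  expect_error(optic_params(enrichment_factor = -1), "enrichment_factor")
  expect_error(optic_params(baseline_intensity = 0), "baseline_intensity")
  # attachment pushed so far out that the footprint misses the cell
  expect_error(
    simulate_field(fast_params(cluster_offset = 30)),
    "outside the cell|outside the field"
  )
})

test_that("bead and microcolony geometries agree on the noise-free ratio", {
  micro <- simulate_field(noise_free(enrichment_factor = 3, blur = FALSE))
  bead <- simulate_field(noise_free(enrichment_factor = 3, blur = FALSE,
                                    cluster_geometry = "bead"))
  expect_equal(recruitment_oracle(micro$field, micro$truth),
               recruitment_oracle(bead$field, bead$truth),
               tolerance = 1e-12)
})

test_that("quantization clamps intensities to the bit depth", {
  sim <- simulate_field(fast_params(enrichment_factor = 5,
                                    baseline_intensity = 120,
                                    quantize = TRUE, seed = 3L))
  poi <- sim$field$channels$poi
  expect_true(all(poi == round(poi)))
  expect_true(max(poi) <= 255)
})

test_that("cohorts count cells, cycle pseudo-experiments and reproduce", {
  params <- list(a = fast_params(enrichment_factor = 3),
                 b = fast_params(enrichment_factor = 1))
  coh <- simulate_cohort(params, n_cells = 6, seed = 11)
  expect_length(coh, 12)
  expect_equal(sum(vapply(coh, `[[`, "", "condition") == "a"), 6)
  exps <- vapply(coh[1:6], `[[`, "", "experiment")
  expect_equal(unname(table(exps)), rep(2L, 3), ignore_attr = TRUE)
  expect_identical(coh, simulate_cohort(params, n_cells = 6, seed = 11))
  expect_error(simulate_cohort(list(), 6, 1), "at least one condition")
  expect_error(simulate_cohort(params, 0, 1), "n_cells")
})
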
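test_that("a constant POI image gives R = 1 for any ROI choice", {
  poi <- matrix(50, 64, 64)
  set.seed(1)
  roi1 <- matrix(sample(c(TRUE, FALSE), 64 * 64, TRUE), 64)
  roi2 <- matrix(FALSE, 64, 64); roi2[5:9, 50:55] <- TRUE
  expect_equal(compute_ratio(poi, roi1, roi2)$R, 1.0)
})

test_that("the ratio reproduces the printed positivity boundary fixture", {
  fx <- boundary_fixture()
  rec <- compute_ratio(fx$poi, fx$roi1, fx$roi2)
  expect_equal(rec$mean_roi1, 71)
  expect_equal(rec$max_roi2, 142)
  expect_equal(rec$R, 2.0)
})

test_that("empty ROIs and non-positive means are rejected", {
  poi <- matrix(0, 8, 8)
  none <- matrix(FALSE, 8, 8)
  all <- !none
  expect_error(compute_ratio(poi, none, all), "empty ROI")
  expect_error(compute_ratio(poi, all, none), "empty ROI")
  expect_error(compute_ratio(poi, all, all), "undefined ratio")
})

test_that("noise-free recovery returns R = E with ground-truth ROIs", {
  for (E in c(1, 2, 3, 5)) {
    sim <- simulate_field(noise_free(enrichment_factor = E, blur = FALSE))
    rec <- compute_ratio(sim$field$channels$poi,
                         sim$truth$cell_mask, sim$truth$cluster_mask)
    expect_equal(rec$R, E, tolerance = 1e-12)
  }
})

test_that("R is scale-invariant and attenuated toward 1 by additive offset", {
  sim <- simulate_field(fast_params(enrichment_factor = 3, seed = 9L))
  poi <- sim$field$channels$poi
  m1 <- sim$truth$cell_mask; m2 <- sim$truth$cluster_mask
  r0 <- compute_ratio(poi, m1, m2)$R
  expect_equal(compute_ratio(4.2 * poi, m1, m2)$R, r0, tolerance = 1e-12)
  offsets <- c(0, 20, 50, 200)
  rs <- vapply(offsets, function(b) compute_ratio(poi + b, m1, m2)$R,
               numeric(1))
  expect_gt(r0, 1)
  expect_true(all(diff(rs) < 0))   # strictly toward 1
  expect_true(all(rs > 1))
})

test_that("positivity classification respects the boundary and monotonicity", {
  expect_true(classify_positive(2.84))
  expect_false(classify_positive(1.5))
  expect_true(classify_positive(2.0))          # boundary handled as >=
  expect_false(classify_positive(2.0, strict = TRUE))
  expect_error(classify_positive(0), "positive")
  expect_error(classify_positive(-1), "positive")
  expect_error(classify_positive(3, threshold = 0), "threshold")
  set.seed(42)
  r <- sort(runif(50, 0.5, 4))
  cls <- classify_positive(r)
  expect_true(all(diff(cls) >= 0))   # once positive, stays positive
})

test_that("line scans normalize each channel to its maximum", {
  field <- structure(list(channels = list(
    flat = matrix(7, 32, 32),
    spike = {m <- matrix(0, 32, 32); m[16, 16] <- 5; m},
    zero = matrix(0, 32, 32)
  )), class = "field_image")
  prof <- line_scan(field, c(15, 2), c(15, 29), n_samples = 28)
  expect_true(all(prof$flat == 1))
  expect_equal(max(prof$spike), 1)
  expect_true(all(prof$zero == 0))
  expect_true(all(prof$spike >= 0 & prof$spike <= 1))
  expect_error(line_scan(field, c(-1, 0), c(5, 5)), "inside the field")
})

test_that("line-scan peaks of POI and receptor coincide at the cluster", {
  sim <- simulate_field(noise_free(enrichment_factor = 3))
  ctr <- c(47.5, 47.5)
  cm <- which(sim$truth$cluster_mask, arr.ind = TRUE) - 1
  centroid <- colMeans(cm)
  p1 <- centroid + (centroid - ctr) * 0.45
  prof <- line_scan(sim$field, ctr, p1, n_samples = 40)
  expect_lte(abs(which.max(prof$poi) - which.max(prof$receptor)), 2)
})

test_that("cohort quantification logs exclusions instead of failing", {
  coh <- simulate_cohort(list(demo = fast_params(enrichment_factor = 3)),
                         n_cells = 3, seed = 21)
  coh[[2]]$field$channels$receptor <- matrix(5, 96, 96)
  q <- quantify_cohort(coh)
  expect_equal(nrow(q$records), 2)
  expect_equal(nrow(q$exclusions), 1)
  expect_match(q$exclusions$reason, "no cluster")
  expect_equal(q$exclusions$cell_id, coh[[2]]$cell_id)
  expect_true(all(c("max_roi2", "mean_roi1", "R", "positive") %in%
                    names(q$records)))
})
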
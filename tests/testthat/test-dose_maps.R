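test_that("group_mean_dose: identities, oracle, permutation invariance", {
  g <- grid_spec(c(8, 8, 8), 8)
  A <- doseatlas:::grid_affine(g)
  mask <- mask_volume(array(1, c(8, 8, 8)), A)

  v <- rand_volume(seed = 5)
  v$affine <- A
  expect_equal(group_mean_dose(list(v, v), mask)$data, v$data)

  c60 <- volume(array(60, c(8, 8, 8)), A)
  c80 <- volume(array(80, c(8, 8, 8)), A)
  expect_equal(unique(as.vector(group_mean_dose(list(c60, c80), mask)$data)), 70)

  vols <- lapply(1:5, function(s) {
    x <- rand_volume(seed = s); x$affine <- A; x$data <- abs(x$data); x
  })
  gm <- group_mean_dose(vols, mask)
  brute <- array(0, c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    brute[i, j, k] <- mean(vapply(vols, function(v) v$data[i, j, k], 0))
  expect_equal(gm$data, brute)
  expect_equal(group_mean_dose(rev(vols), mask)$data, gm$data)
  expect_error(group_mean_dose(list(), mask), "empty")
})

test_that("dose_range_summary: partition, edges, scaling equivariance", {
  g <- grid_spec(c(10, 10, 10), 8)
  A <- doseatlas:::grid_affine(g)
  mask <- mask_volume(array(stats::runif(1000) > 0.3, c(10, 10, 10)), A)
  set.seed(8)
  dose <- volume(array(stats::runif(1000, 0, 80), c(10, 10, 10)), A)

  spec <- dose_range_spec()
  drs <- dose_range_summary(dose, mask, spec)
  expect_equal(sum(drs$summary$n_voxels) + drs$below_floor, sum(mask$data))
  expect_equal(drs$summary$volume_mm3, drs$summary$n_voxels * 512)

  # constant 70 inside mask -> everything in the >50 bin
  c70 <- volume(array(70, c(10, 10, 10)), A)
  drs70 <- dose_range_summary(c70, mask, spec)
  expect_equal(drs70$summary$n_voxels[5], sum(mask$data))
  expect_equal(sum(drs70$summary$n_voxels[1:4]), 0)

  # scaling doses and boundaries together leaves counts unchanged
  dose2 <- dose; dose2$data <- dose$data * 2.5
  spec2 <- dose_range_spec(spec$boundaries * 2.5)
  expect_equal(dose_range_summary(dose2, mask, spec2)$summary$n_voxels,
               drs$summary$n_voxels)

  expect_error(dose_range_spec(c(10, 5)), "increasing")
})

test_that("high-dose ROIs: brute-force intersection, laterality, warnings", {
  ph <- make_template_phantom(small_grid(), seed = 1)
  atlas <- make_phantom_atlas(ph$template)
  gt <- ph$ground_truth
  rec <- list(prescription_dose = 70.4, technique = "IMRT", t_stage = "T4")
  dose <- simulate_dose(rec, gt$head_support_mask, gt$target_center,
                        dose_params(noise_sd = 0), seed = 1)

  rois <- build_high_dose_rois(dose, atlas, threshold = 50,
                               lobes = c("Temporal Lobe", "Limbic Lobe"))
  expect_gt(length(rois), 0)
  w <- doseatlas:::world_coords(dose$affine, dim(dose$data))
  for (nm in names(rois)) {
    lobe <- sub(" \\((L|R)\\)$", "", nm)
    side <- sub("^.*\\((L|R)\\)$", "\\1", nm)
    labels <- atlas$label_table$label[atlas$label_table$lobe == lobe]
    hemi <- if (side == "L") w$x < 0 else w$x > 0
    brute <- dose$data > 50 & array(atlas$data %in% labels, dim(dose$data)) & hemi
    expect_equal(rois[[nm]]$data, mask_volume(brute, dose$affine)$data)
  }
  # hemisphere ROIs are disjoint
  if (all(c("Temporal Lobe (L)", "Temporal Lobe (R)") %in% names(rois)))
    expect_equal(sum(rois[["Temporal Lobe (L)"]]$data *
                     rois[["Temporal Lobe (R)"]]$data), 0)

  expect_warning(build_high_dose_rois(dose, atlas, threshold = 1e4),
                 "exceeds")
  expect_error(build_high_dose_rois(dose, atlas, lobes = "No Such Lobe"),
               "absent")
})

test_that("roi_mean_dose: constants, single voxel, brute force, errors", {
  g <- grid_spec(c(8, 8, 8), 8)
  A <- doseatlas:::grid_affine(g)
  c55 <- volume(array(55, c(8, 8, 8)), A)
  roi <- mask_volume(array(stats::runif(512) > 0.5, c(8, 8, 8)), A)
  expect_equal(roi_mean_dose(c55, roi), 55)

  v <- rand_volume(seed = 21); v$affine <- A
  expect_equal(roi_mean_dose(v, roi),
               sum(v$data[roi$data > 0]) / sum(roi$data))

  one <- array(0, c(8, 8, 8)); one[3, 4, 5] <- 1
  roi1 <- mask_volume(one, A)
  expect_equal(roi_mean_dose(v, roi1), v$data[3, 4, 5])

  empty <- mask_volume(array(0, c(8, 8, 8)), A)
  expect_error(roi_mean_dose(v, empty), "empty")
})

test_that("roi_dose_table compares techniques per ROI", {
  co <- null_cohort()
  doses <- lapply(co$subjects, `[[`, "dose_template")
  atlas <- make_phantom_atlas(co$template)
  gm <- group_mean_dose(doses, co$brain_mask)
  rois <- build_high_dose_rois(gm, atlas, threshold = 50)
  skip_if(length(rois) == 0)
  tab <- roi_dose_table(doses, co$cohort, rois)
  expect_equal(nrow(tab$doses), length(rois) * nrow(co$cohort))
  expect_true(all(is.finite(tab$tests$t)))
  # null cohort: no significant technique difference expected at p<1e-4
  expect_true(all(tab$tests$p > 1e-4))
})
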
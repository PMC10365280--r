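test_that("template phantom is deterministic with the stated HU modes", {
  g <- small_grid()
  a <- make_template_phantom(g, seed = 7)
  b <- make_template_phantom(g, seed = 7)
  expect_identical(a$template$data, b$template$data)

  hu <- a$template$data
  # histogram modes near air, brain and skull
  expect_gt(mean(hu < -900), 0.2)
  expect_gt(sum(abs(hu - 30) < 45), 1000)
  expect_gt(sum(hu > 600), 100)

  # head support is one connected component
  lab <- doseatlas:::cpp_label_components(
    as.logical(a$ground_truth$head_support_mask$data > 0),
    dim(hu), 6L)
  expect_equal(max(lab), 1L)
})

test_that("sample_subject: identity configuration and determinism", {
  ph <- make_template_phantom(small_grid(), seed = 1)
  s0 <- sample_subject(ph$template, seed = 4, deform_scale = 0,
                       max_trans = 0, max_rot_deg = 0, hu_noise_sd = 0)
  expect_equal(s0$ct$data, ph$template$data, tolerance = 1e-10)

  s1 <- sample_subject(ph$template, seed = 11)
  s2 <- sample_subject(ph$template, seed = 11)
  expect_identical(s1$ct$data, s2$ct$data)
})

test_that("stored subject transform explains the subject CT", {
  # 4 mm grid: at 8 mm the skull-edge interpolation residual dominates SSD
  ph <- make_template_phantom(grid_spec(c(48, 48, 48), 4), seed = 1)
  tm <- ph$template
  sub <- sample_subject(tm, seed = 4, hu_noise_sd = 0)
  # applying the stored chain to the template reproduces the subject
  pred <- apply_chain(sub$transform, tm, tm, "cubic", fill = -1000)
  expect_lt(ssd(pred, sub$ct), 1e-6)
  # applying the inverted chain to the subject recovers the template
  inv <- invert_chain(sub$transform, tm)
  rec <- apply_chain(inv, sub$ct, tm, "cubic", fill = -1000)
  mask <- ph$ground_truth$head_support_mask
  expect_lt(ssd(rec, tm, mask), 0.1 * ssd(sub$ct, tm, mask))
})

test_that("simulate_dose: prescription at centre, falloff, support, errors", {
  ph <- make_template_phantom(small_grid(), seed = 1)
  gt <- ph$ground_truth
  sup <- gt$head_support_mask
  rec <- list(prescription_dose = 70.4, technique = "IMRT", t_stage = "T3")
  dose <- simulate_dose(rec, sup, gt$target_center, dose_params(), seed = 2)

  ci <- round(world_to_voxel(gt$target_center, sup$affine)) + 1
  expect_equal(dose$data[ci[1], ci[2], ci[3]], 70.4)
  expect_true(all(dose$data >= 0))
  expect_true(all(dose$data[sup$data == 0] == 0))

  # monotone falloff of the deterministic field along rays from the centre
  det <- simulate_dose(rec, sup, gt$target_center,
                       dose_params(noise_sd = 0), seed = 2)
  for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
    tvals <- seq(0, 60, by = 2)
    pts <- t(vapply(tvals, function(t) gt$target_center + t * dir, numeric(3)))
    vox <- world_to_voxel(pts, sup$affine)
    vals <- doseatlas:::cpp_sample_trilinear(as.double(det$data),
                                             dim(det$data), vox, 0)
    expect_true(all(diff(vals) <= 1e-6))
  }

  # zero effect size: techniques identical under the same seed
  rec_v <- list(prescription_dose = 70.4, technique = "VMAT", t_stage = "T3")
  d2 <- simulate_dose(rec_v, sup, gt$target_center, dose_params(), seed = 2)
  expect_identical(dose$data, d2$data)

  bad <- list(prescription_dose = 55, technique = "IMRT", t_stage = "T3")
  expect_error(simulate_dose(bad, sup, gt$target_center), "prescription")
})

test_that("target coverage meets the planning goal", {
  ph <- make_template_phantom(small_grid(), seed = 1)
  gt <- ph$ground_truth
  for (s in 1:5) {
    rec <- list(prescription_dose = 67 + s, technique = "VMAT", t_stage = "T2")
    dose <- simulate_dose(rec, gt$head_support_mask, gt$target_center,
                          dose_params(), seed = s)
    tmask <- target_mask(ph$template, gt$target_center, "T2")
    cov <- mean(dose$data[tmask$data > 0] >= rec$prescription_dose)
    expect_gte(cov, 0.95)
  }
})

test_that("make_cohort: counts, determinism, files, demographics", {
  dir <- withr::local_tempdir()
  co <- make_cohort(5, seed = 2, grid = small_grid(), template_space = TRUE,
                    out_dir = dir)
  expect_equal(nrow(co$cohort), 10)
  expect_equal(sum(co$cohort$technique == "IMRT"), 5)
  expect_true(all(file.exists(co$cohort$dose_path)))
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_true(all(co$cohort$age >= 18 & co$cohort$age <= 84))
  expect_true(all(co$cohort$prescription_dose >= 66.9 &
                  co$cohort$prescription_dose <= 74.2))

  co2 <- make_cohort(5, seed = 2, grid = small_grid(), template_space = TRUE)
  expect_identical(co$cohort[names(co2$cohort)], co2$cohort)

  # male fraction approximates 567/803 over a large demographic draw
  big <- make_cohort(1000, seed = 3, grid = small_grid(),
                     template_space = TRUE, demographics_only = TRUE)
  expect_lt(abs(mean(big$cohort$gender == "male") - 567 / 803), 0.03)
})

test_that("null cohorts give exchangeable groups (same generative law)", {
  co <- null_cohort()
  doses <- lapply(co$subjects, `[[`, "dose_template")
  gi <- which(co$cohort$technique == "IMRT")
  gv <- which(co$cohort$technique == "VMAT")
  mi <- group_mean_dose(doses[gi], co$brain_mask)
  mv <- group_mean_dose(doses[gv], co$brain_mask)
  sel <- co$brain_mask$data > 0
  # means differ only by sampling noise, not systematically
  expect_lt(abs(mean(mi$data[sel]) - mean(mv$data[sel])), 0.75)
  expect_equal(sum(co$ground_truth$effect_mask$data), 0)
})
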
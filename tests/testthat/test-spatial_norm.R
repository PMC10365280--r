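test_that("ssd: closed forms and brute-force oracle", {
  a <- rand_volume(c(5, 5, 5), seed = 1)
  b <- rand_volume(c(5, 5, 5), seed = 2)
  expect_equal(ssd(a, a), 0)

  a1 <- a; a1$data <- a$data + 1
  expect_equal(ssd(a1, a), 125)

  # brute-force triple loop
  acc <- 0
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    acc <- acc + (a$data[i, j, k] - b$data[i, j, k])^2
  expect_equal(ssd(a, b), acc)

  m <- mask_volume(array(rep(c(1, 0), length.out = 125), c(5, 5, 5)), a$affine)
  expect_equal(ssd(a, b, m), sum(((a$data - b$data)^2)[m$data > 0]))
  expect_error(ssd(a, rand_volume(c(6, 5, 5), seed = 3)), "mismatch")
})

test_that("crop_head finds the padded support box and preserves geometry", {
  ph <- make_template_phantom(grid_spec(c(40, 40, 40), 6), seed = 1)
  ct <- ph$template
  dose <- volume(array(stats::runif(40^3, 0, 70), c(40, 40, 40)), ct$affine)
  cr <- crop_head(ct, dose)

  expect_identical(dim(cr$ct$data), dim(cr$dose$data))
  expect_equal(cr$ct$affine, cr$dose$affine)

  # crop box = support bounding box + 10 mm pad (except inferior)
  sup <- which(ph$ground_truth$head_support_mask$data > 0, arr.ind = TRUE)
  lo <- pmax(apply(sup, 2, min) - ceiling(10 / 6), 1)
  lo[3] <- apply(sup, 2, min)[3]
  hi <- pmin(apply(sup, 2, max) + ceiling(10 / 6), 40)
  expect_equal(dim(cr$ct$data), as.integer(hi - lo + 1))

  # retained voxels keep their world coordinates
  w_old <- voxel_to_world(lo - 1, ct$affine)
  w_new <- voxel_to_world(c(0, 0, 0), cr$ct$affine)
  expect_lt(max(abs(w_old - w_new)), 1e-9)
  expect_equal(cr$ct$data[1, 1, 1], ct$data[lo[1], lo[2], lo[3]])

  flat <- volume(array(-1000, c(8, 8, 8)), diag(4))
  expect_error(crop_head(flat, flat), "threshold")
})

test_that("apply_chain: empty chain equals resample_to; synchronization", {
  v <- rand_volume(c(10, 10, 10), 5, seed = 4)
  ref <- volume(array(0, c(7, 7, 7)),
                doseatlas:::grid_affine(grid_spec(c(7, 7, 7), 7)))
  ch0 <- new_chain()
  expect_equal(apply_chain(ch0, v, ref)$data,
               resample_to(v, ref)$data)

  # the identical chain applied to a fiducial marker volume and to the CT
  # moves both to the same place
  ph <- make_template_phantom(small_grid(), seed = 1)
  sub <- sample_subject(ph$template, seed = 6, hu_noise_sd = 0)
  fid <- volume(array(0, dim(ph$template$data)), ph$template$affine)
  ci <- round(world_to_voxel(c(10, -20, 10), fid$affine)) + 1
  fid$data[ci[1], ci[2], ci[3]] <- 1000
  f1 <- apply_chain(sub$transform, fid, ph$template, "linear")
  f2 <- apply_chain(sub$transform, fid, ph$template, "linear")
  expect_identical(f1$data, f2$data)
  expect_gt(max(f1$data), 1)  # marker landed inside the field of view
})

test_that("dose mass is approximately conserved under a smooth warp", {
  ph <- make_template_phantom(small_grid(), seed = 1)
  gt <- ph$ground_truth
  rec <- list(prescription_dose = 70.4, technique = "IMRT", t_stage = "T3")
  dose <- simulate_dose(rec, gt$head_support_mask, gt$target_center,
                        dose_params(noise_sd = 0), seed = 1)
  sub <- sample_subject(ph$template, seed = 8, max_trans = 0,
                        max_rot_deg = 0, hu_noise_sd = 0)
  warped <- apply_chain(sub$transform, dose, ph$template, "linear", fill = 0)
  m0 <- sum(dose$data)
  m1 <- sum(warped$data)
  expect_lt(abs(m1 - m0) / m0, 0.05)
})

test_that("rigid registration recovers a known translation quickly", {
  # coarse-grid version of the acceptance recovery check
  ph <- make_template_phantom(grid_spec(c(40, 40, 40), 5), seed = 1)
  t1 <- ph$template
  M <- build_rigid(c(0, 0, 0, 6, -4, 8))
  mov <- apply_chain(new_chain(rigid = M), t1, t1, "cubic", fill = -1024)
  r <- register_rigid(mov, t1, factors = c(4, 2), maxit = c(400, 300))
  Mrec <- solve(r$matrix)
  expect_lt(max(abs(Mrec[1:3, 4] - c(6, -4, 8))), 1.5)
  expect_lte(r$ssd_after, r$ssd_before)
})

test_that("affine registration is a nested refinement of rigid", {
  ph <- make_template_phantom(grid_spec(c(40, 40, 40), 5), seed = 1)
  t1 <- ph$template
  Ms <- diag(c(1.08, 1.08, 1.08, 1))
  mov <- apply_chain(new_chain(affine = Ms), t1, t1, "cubic", fill = -1024)
  rig <- register_rigid(mov, t1, factors = c(4, 2), maxit = c(300, 200))
  aff <- register_affine(mov, t1, init = rig, factors = c(4, 2),
                         maxit = c(300, 200))
  expect_lte(aff$ssd_after, rig$ssd_after + 1e-9)
  sc <- exp(aff$par[7:9])
  expect_lt(max(abs(1 / sc - 1.08)), 0.03)
})

test_that("register_nonlinear: identity input, zero field, monotone trace", {
  ph <- reg_phantom()
  t1 <- ph$template
  mask <- make_brain_mask(t1)
  nl <- register_nonlinear(t1, t1, iters = 3, mask = mask)
  rms <- sqrt(mean(nl$field$ux^2 + nl$field$uy^2 + nl$field$uz^2))
  expect_lt(rms, 0.1)
  for (tr in nl$obj_traces)
    expect_true(all(diff(tr) <= 1e-6 * abs(tr[1]) + 1e-12))
  expect_error(register_nonlinear(t1, t1, iters = 0), "iters")
})

test_that("transform chains survive a JSON + NIfTI round trip", {
  dir <- withr::local_tempdir()
  ph <- make_template_phantom(small_grid(), seed = 1)
  sub <- sample_subject(ph$template, seed = 3)
  p <- file.path(dir, "chain.json")
  write_chain(sub$transform, p)
  ch <- read_chain(p)
  expect_equal(ch$rigid, sub$transform$rigid, tolerance = 1e-6)
  expect_equal(ch$field$ux, sub$transform$field$ux, tolerance = 1e-5)
  expect_equal(ch$ref_dim, sub$transform$ref_dim)
})
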
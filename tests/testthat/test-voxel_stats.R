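test_that("design_matrix encodes groups, covariates, contrast; errors", {
  co <- data.frame(technique = rep(c("IMRT", "VMAT"), each = 4),
                   age = c(40, 50, 60, 70, 45, 55, 65, 75),
                   gender = rep(c("male", "female"), 4))
  des <- design_matrix(co)
  expect_equal(ncol(des$X), 4)
  expect_equal(des$X[, "group"], rep(c(1, 0), each = 4))
  expect_equal(sum(des$X[, "age"]), 0)           # centred
  expect_equal(des$contrast, c(0, 1, 0, 0))
  expect_error(design_matrix(data.frame(technique = rep("IMRT", 4))),
               "two nonempty groups")
})

test_that("covariate-free GLM equals the classical two-sample t exactly", {
  set.seed(41)
  n <- 20
  g <- grid_spec(c(6, 6, 6), 8)
  mask <- mask_volume(array(1, c(6, 6, 6)), doseatlas:::grid_affine(g))
  Y <- matrix(stats::rnorm(n * 216), n)
  co <- data.frame(technique = rep(c("IMRT", "VMAT"), each = 10))
  des <- design_matrix(co, covars = character(0))
  tmap <- fit_glm_tmap(Y, des, mask)
  tt <- apply(Y, 2, function(y)
    stats::t.test(y[1:10], y[11:20], var.equal = TRUE)$statistic)
  expect_lt(max(abs(tmap$data[mask$data > 0] - tt)), 1e-10)
  expect_equal(attr(tmap, "df"), n - 2)

  # adding a constant to every subject leaves t unchanged (intercept)
  tmap2 <- fit_glm_tmap(Y + 100, des, mask)
  expect_equal(tmap2$data, tmap$data, tolerance = 1e-9)

  # zero-variance voxels are flagged and get t = 0
  Y0 <- Y; Y0[, 1] <- 5
  t0 <- fit_glm_tmap(Y0, des, mask)
  expect_equal(t0$data[mask$data > 0][1], 0)
})

test_that("TFCE matches the brute-force threshold-loop oracle exactly", {
  set.seed(7)
  for (rep in 1:4) {
    st <- array(pmax(stats::rnorm(12^3), 0), c(12, 12, 12))
    dh <- max(st) / 20
    for (conn in c(6, 26)) {
      p <- tfce_params(connectivity = conn)
      got <- tfce_transform(st, params = p, dh_override = dh)
      want <- tfce_bruteforce(st, p$E, p$H, dh, 20, conn)
      expect_equal(unclass(got), want, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("TFCE analytic value, zero map, monotonicity", {
  st <- array(0, c(7, 7, 7)); st[4, 4, 4] <- 1
  tf <- tfce_transform(st, params = tfce_params(dh = 0.01))
  expect_equal(tf[4, 4, 4], 1 / 3, tolerance = 0.02)   # integral of h^2

  z <- tfce_transform(array(0, c(5, 5, 5)))
  expect_true(all(z == 0))

  set.seed(9)
  st2 <- array(pmax(stats::rnorm(10^3), 0), c(10, 10, 10))
  a <- tfce_transform(st2, params = tfce_params(dh = 0.05))
  b <- tfce_transform(2 * st2, params = tfce_params(dh = 0.05))
  pos <- st2 > 0.05    # voxels above the first threshold step
  expect_true(all(b[pos] > a[pos]))

  expect_error(tfce_transform(array(-1, c(3, 3, 3))), "non-negative")
})

test_that("permutation_fwe: determinism, p-range, refusal, monotonicity", {
  co <- null_cohort()
  doses <- lapply(co$subjects, `[[`, "dose_template")
  des <- design_matrix(co$cohort)
  r1 <- permutation_fwe(doses, des, co$brain_mask, n_perm = 120, seed = 5)
  r2 <- permutation_fwe(doses, des, co$brain_mask, n_perm = 120, seed = 5)
  expect_identical(r1$fwe_p_pos$data, r2$fwe_p_pos$data)

  sel <- co$brain_mask$data > 0
  p <- r1$fwe_p_pos$data[sel]
  expect_true(all(p > 0 & p <= 1))
  expect_gte(min(p), 1 / 121)
  expect_length(r1$null_max_pos, 120)

  # fwe p is monotone non-increasing in the TFCE value
  tf <- r1$tfce_pos$data[sel]
  ord <- order(tf)
  expect_true(all(diff(p[ord]) <= 1e-12))

  expect_error(permutation_fwe(doses, des, co$brain_mask, n_perm = 10),
               "n_perm")
  co4 <- make_cohort(2, seed = 9, grid = small_grid(), template_space = TRUE)
  d4 <- lapply(co4$subjects, `[[`, "dose_template")
  expect_error(permutation_fwe(d4, design_matrix(co4$cohort), co4$brain_mask,
                               n_perm = 120), "smaller than 3")
})

test_that("summarize_result reports counts and peak coordinates", {
  co <- null_cohort()
  doses <- lapply(co$subjects, `[[`, "dose_template")
  des <- design_matrix(co$cohort)
  res <- permutation_fwe(doses, des, co$brain_mask, n_perm = 120, seed = 5)
  s <- summarize_result(res)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_sig[1], sum(res$sig_pos$data))
  expect_equal(s$n_sig[2], sum(res$sig_neg$data))

  # inject a deterministic single-voxel sig mask and check the peak
  res2 <- res
  sig <- array(0, dim(res$t_map$data)); sig[5, 6, 7] <- 1
  res2$sig_pos <- mask_volume(sig, res$t_map$affine)
  s2 <- summarize_result(res2)
  expect_equal(s2$n_sig[1], 1)
  expect_equal(s2$peak_t[1], res$t_map$data[5, 6, 7])
  expect_equal(unlist(s2[1, c("x", "y", "z")], use.names = FALSE),
               voxel_to_world(c(4, 5, 6), res$t_map$affine))
})

test_that("exchangeability: null max distributions agree across relabelings", {
  co <- null_cohort()
  doses <- lapply(co$subjects, `[[`, "dose_template")
  des1 <- design_matrix(co$cohort)
  # relabel groups (swap) - same generative law, so null maxima match in law
  co2 <- co$cohort
  co2$technique <- rev(co2$technique)
  des2 <- design_matrix(co2)
  r1 <- permutation_fwe(doses, des1, co$brain_mask, n_perm = 150, seed = 3)
  r2 <- permutation_fwe(doses, des2, co$brain_mask, n_perm = 150, seed = 17)
  ks <- stats::ks.test(r1$null_max_pos, r2$null_max_pos)$p.value
  expect_gt(ks, 0.01)
})
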
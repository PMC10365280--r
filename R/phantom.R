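# Digital head-phantom cohort with known ground truth.
#
# The generator emulates the statistical structure the voxel-based dose
# analysis assumes: a CT-like head template; per-subject CTs that are
# rigidly offset and smoothly deformed copies of the template; a
# nasopharynx-centred dose field at prescription ~67-74 Gy with
# exponential falloff; a technique-dependent intermediate-dose lobe
# (anterior for static-field IMRT, posterior for VMAT arcs) whose
# amplitude is controlled exactly; and demographics (age, gender, T stage)
# drawn to match the reference cohort's marginals.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# world-coordinate arrays (mm) for each axis of a volume's grid
world_coords <- function(affine, d) {
  idx <- grid_indices(d)
  w <- cbind(idx, 1) %*% t(affine)
  list(x = array(w[, 1], d), y = array(w[, 2], d), z = array(w[, 3], d))
}

ellipsoid_r <- function(w, center, semi) {
  sqrt(((w$x - center[1]) / semi[1])^2 +
       ((w$y - center[2]) / semi[2])^2 +
       ((w$z - center[3]) / semi[3])^2)
}

# phantom anatomy in fixed world mm (independent of the grid)
PHANTOM <- list(
  head_center  = c(0, -10, -5), head_semi  = c(70, 82, 80),
  brain_center = c(0, -15, 12), brain_semi = c(62, 72, 55),
  skull_inner = 1.02, skull_outer = 1.10,
  vent_semi = c(8, 20, 10), vent_centers = list(c(-14, -25, 18), c(14, -25, 18)),
  hu = c(air = -1000, soft = 40, brain = 30, skull = 700, csf = 5),
  target_center = c(0, 8, -55)
)

#' Generate the CT head-phantom template
#'
#' Builds a CT-like template volume in HU: ellipsoidal head (soft tissue
#' ~40 HU) containing a skull shell (~700 HU), brain (~30 HU) with
#' ventricle analogues (~5 HU), air (-1000 HU) outside, plus a seeded
#' multi-scale HU texture inside the brain standing in for soft-tissue
#' anatomy (sulci, nuclei, gray/white contrast). Deterministic given the
#' seed. Ground truth records the exact head support and its volume.
#'
#' @param grid a [grid_spec()]; the default is the MNI-like 2 mm grid.
#' @param seed integer RNG seed for the brain texture.
#' @param texture_sd RMS amplitude (HU) of the brain texture; the default
#'   40 HU is comparable to the soft-tissue structure driving intensity
#'   registration in real head CT.
#' @return list with `template` (a template-space `volume`) and
#'   `ground_truth` (head support mask, target centre, support volume).
#' @export
make_template_phantom <- function(grid = grid_spec(), seed = 1, texture_sd = 40) {
  A <- grid_affine(grid)
  d <- grid$dim
  w <- world_coords(A, d)
  rh <- ellipsoid_r(w, PHANTOM$head_center, PHANTOM$head_semi)
  rb <- ellipsoid_r(w, PHANTOM$brain_center, PHANTOM$brain_semi)

  hu <- array(PHANTOM$hu[["air"]], d)
  head <- rh <= 1
  hu[head] <- PHANTOM$hu[["soft"]]
  skull <- head & rb >= PHANTOM$skull_inner & rb <= PHANTOM$skull_outer
  hu[skull] <- PHANTOM$hu[["skull"]]
  brain <- head & rb < PHANTOM$skull_inner
  hu[brain] <- PHANTOM$hu[["brain"]]
  for (vc in PHANTOM$vent_centers) {
    rv <- ellipsoid_r(w, vc, PHANTOM$vent_semi)
    hu[rv <= 1 & brain] <- PHANTOM$hu[["csf"]]
  }
  if (texture_sd > 0) {
    # multi-scale texture: real brain CT has structure at nested scales,
    # which is also what makes coarse-to-fine SSD registration well-posed
    tex <- with_seed(seed, {
      0.6 * random_smooth_field(d, grid$spacing, sigma_mm = 24) +
      0.55 * random_smooth_field(d, grid$spacing, sigma_mm = 12) +
      0.35 * random_smooth_field(d, grid$spacing, sigma_mm = 6)
    })
    hu[brain] <- hu[brain] + texture_sd * tex[brain] / sqrt(mean(tex[brain]^2))
  }
  tmpl <- volume(hu, A, space = "template")
  support <- mask_volume(head, A, space = "template")
  gt <- list(
    head_support_mask = support,
    brain_mask = mask_volume(brain, A, space = "template"),
    target_center = PHANTOM$target_center,
    support_volume_mm3 = sum(head) * voxel_volume_mm3(tmpl),
    grid = grid
  )
  list(template = tmpl, ground_truth = gt)
}

#' Simulate one subject's anatomy
#'
#' The subject CT is the template pulled back through a random rigid
#' offset composed with a smooth random displacement field, plus additive
#' HU noise: `subject(y) = template(M(y + u(y))) + noise`. The exact
#' composite transform is returned as a [transform chain][new_chain] in
#' the same pull-back convention used by [apply_chain()], so
#' `apply_chain(transform, template, template)` reproduces the noiseless
#' subject.
#'
#' @param template the phantom template `volume`.
#' @param seed integer seed; identical seeds give identical subjects.
#' @param deform_scale RMS magnitude (mm) of the random displacement field.
#' @param max_trans,max_rot_deg per-axis bounds of the random rigid offset
#'   (defaults keep the composite within 15 mm / 10 degrees).
#' @param hu_noise_sd additive HU noise standard deviation.
#' @param field_sigma_mm smoothness (Gaussian sigma, mm) of the random field.
#' @return list with `ct` (subject-space `volume`) and `transform`
#'   (the exact generating `transform_chain`).
#' @export
sample_subject <- function(template, seed, deform_scale = 4,
                           max_trans = 8, max_rot_deg = 5,
                           hu_noise_sd = 5, field_sigma_mm = 30) {
  stopifnot(deform_scale >= 0)
  d <- dim(template$data)
  spacing <- voxel_spacing(template)
  with_seed(seed, {
    trans <- stats::runif(3, -max_trans, max_trans)
    rot <- stats::runif(3, -max_rot_deg, max_rot_deg) * pi / 180
    M <- build_rigid(c(rot, trans), center = PHANTOM$head_center)
    field <- NULL
    if (deform_scale > 0) {
      s <- deform_scale / sqrt(3)
      field <- list(
        ux = s * random_smooth_field(d, spacing, field_sigma_mm),
        uy = s * random_smooth_field(d, spacing, field_sigma_mm),
        uz = s * random_smooth_field(d, spacing, field_sigma_mm)
      )
    }
    chain <- new_chain(rigid = M, field = field, reference = template)
    # cubic sampling: emulates band-limited CT acquisition of the deformed
    # anatomy (trilinear would imprint a field-correlated blur pattern)
    ct <- apply_chain(chain, template, template, interpolation = "cubic",
                      fill = PHANTOM$hu[["air"]])
    if (hu_noise_sd > 0)
      ct$data <- ct$data + array(stats::rnorm(prod(d), 0, hu_noise_sd), d)
    ct$space <- "subject"
    list(ct = ct, transform = chain)
  })
}

#' Dose-simulation parameters
#'
#' @param lambda exponential falloff length (mm) of dose with distance
#'   from the target surface; 25 mm places temporal/limbic-analogue
#'   voxels near the target above 50 Gy.
#' @param effect_size amplitude (Gy) of the technique-dependent lobe;
#'   0 makes IMRT and VMAT fields exchangeable.
#' @param lobe_offset displacement (mm) of the technique lobe centre from
#'   the target centre; its y component is flipped to negative for VMAT.
#' @param lobe_sigma Gaussian width (mm) of the technique lobe.
#' @param noise_sd RMS (Gy) of the smooth inter-subject dose noise field.
#' @param noise_sigma_mm smoothness of the noise field.
#' @param noise_taper_mm noise is tapered to zero inside the target with
#'   weight `1 - exp(-d/noise_taper_mm)`, so target coverage is exact.
#' @param target_semi target ellipsoid semi-axes (mm) at T-stage scale 1.
#' @param t_stage_scale named multipliers of the target radius per T stage.
#' @export
dose_params <- function(lambda = 25, effect_size = 0,
                        lobe_offset = c(0, 38, 18), lobe_sigma = 15,
                        noise_sd = 2, noise_sigma_mm = 10, noise_taper_mm = 5,
                        target_semi = c(18, 16, 14),
                        t_stage_scale = c(T1 = 0.85, T2 = 0.95, T3 = 1.05, T4 = 1.2)) {
  list(lambda = lambda, effect_size = effect_size, lobe_offset = lobe_offset,
       lobe_sigma = lobe_sigma, noise_sd = noise_sd,
       noise_sigma_mm = noise_sigma_mm, noise_taper_mm = noise_taper_mm,
       target_semi = target_semi, t_stage_scale = t_stage_scale)
}

target_semi_for <- function(t_stage, params) {
  sc <- params$t_stage_scale[[t_stage]]
  if (is.null(sc)) stop("unknown T stage: ", t_stage)
  params$target_semi * sc
}

# approximate signed distance (mm) outside a target ellipsoid:
# d = (r - 1) / |grad r|, 0 inside.
target_distance <- function(w, center, semi) {
  r <- ellipsoid_r(w, center, semi)
  gx <- (w$x - center[1]) / semi[1]^2
  gy <- (w$y - center[2]) / semi[2]^2
  gz <- (w$z - center[3]) / semi[3]^2
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  d <- array(0, dim(r))
  out <- r > 1
  d[out] <- (r[out] - 1) * r[out] / gn[out]
  d
}

#' Target ellipsoid mask for a subject
#'
#' @param reference `volume` defining the grid.
#' @param target_center world mm triple.
#' @param t_stage T stage (scales the target radius).
#' @param params [dose_params()].
#' @return a `mask_volume`.
#' @export
target_mask <- function(reference, target_center, t_stage = "T3",
                        params = dose_params()) {
  w <- world_coords(reference$affine, dim(reference$data))
  r <- ellipsoid_r(w, target_center, target_semi_for(t_stage, params))
  mask_volume(r <= 1, reference$affine, reference$space)
}

technique_lobe <- function(w, target_center, technique, params) {
  if (params$effect_size == 0) return(NULL)
  sgn <- if (technique == "IMRT") 1 else -1
  ctr <- target_center + params$lobe_offset * c(1, sgn, 1)
  d2 <- (w$x - ctr[1])^2 + (w$y - ctr[2])^2 + (w$z - ctr[3])^2
  params$effect_size * exp(-d2 / (2 * params$lobe_sigma^2))
}

# ground-truth mask of voxels where the two technique mean doses differ
effect_region <- function(reference, target_center, params, support,
                          rel_tol = 0.5) {
  w <- world_coords(reference$affine, dim(reference$data))
  li <- technique_lobe(w, target_center, "IMRT", params)
  lv <- technique_lobe(w, target_center, "VMAT", params)
  if (is.null(li))
    return(mask_volume(array(0, dim(reference$data)), reference$affine,
                       reference$space))
  m <- abs(li - lv) > rel_tol * params$effect_size & support$data > 0
  mask_volume(m, reference$affine, reference$space)
}

#' Simulate a radiotherapy dose field
#'
#' Deterministic part: dose equals the prescription on the target
#' ellipsoid (nasopharynx analogue) and falls off as
#' `prescription * exp(-d / lambda)` with distance `d` from the target
#' surface. A technique-dependent Gaussian lobe of amplitude
#' `effect_size` is added anterior (IMRT) or posterior (VMAT) to the
#' target. Smooth seeded inter-subject noise is added outside the target
#' (tapered to zero inside it), the field is clipped at 0 and zeroed
#' outside the head support.
#'
#' @param record one-row data.frame or list with `prescription_dose`
#'   (Gy, must lie in \[60, 80\]), `technique` and `t_stage`.
#' @param subject_support head-support `mask_volume` on the target grid.
#' @param target_center world mm triple (must be inside the support).
#' @param params [dose_params()].
#' @param seed integer seed for the noise field.
#' @return a dose `volume` (Gy).
#' @export
simulate_dose <- function(record, subject_support, target_center,
                          params = dose_params(), seed = 1) {
  rx <- record$prescription_dose
  if (rx < 60 || rx > 80)
    stop("prescription dose ", rx, " Gy outside the accepted range [60, 80]")
  A <- subject_support$affine
  d <- dim(subject_support$data)
  ctr_vox <- world_to_voxel(target_center, A)
  ci <- round(ctr_vox) + 1
  if (any(ci < 1) || any(ci > d) ||
      subject_support$data[ci[1], ci[2], ci[3]] == 0)
    stop("target centre is outside the head support")

  w <- world_coords(A, d)
  semi <- target_semi_for(record$t_stage, params)
  dist <- target_distance(w, target_center, semi)
  dose <- rx * exp(-dist / params$lambda)

  lobe <- technique_lobe(w, target_center, record$technique, params)
  if (!is.null(lobe)) dose <- dose + lobe

  if (params$noise_sd > 0) {
    nf <- with_seed(seed, random_smooth_field(d, voxel_spacing(subject_support),
                                              params$noise_sigma_mm))
    taper <- 1 - exp(-dist / params$noise_taper_mm)
    dose <- dose + params$noise_sd * nf * taper
  }
  dose <- pmax(dose, 0)
  dose[subject_support$data == 0] <- 0
  volume(array(dose, d), A, space = subject_support$space)
}

#' Generate a balanced synthetic IMRT/VMAT cohort
#'
#' Demographics follow the reference cohort's marginals: ages
#' Normal(53, 10) truncated to \[18, 84\], male fraction 567/803, T-stage
#' mix proportional to 81/98/416/207 (T1..T4), prescription doses
#' Normal(70.4, 1.2) truncated to \[66.9, 74.2\] Gy. Dose fields are
#' always generated in template space (these are the ground truth for
#' normalization tests); with `template_space = FALSE` each subject
#' additionally gets a deformed subject-space CT and the dose pulled
#' back through the same transform.
#'
#' @param n_per_group subjects per technique group (>= 2).
#' @param seed master seed; all randomness flows from it.
#' @param grid template [grid_spec()].
#' @param params [dose_params()]; `effect_size = 0` makes the two groups
#'   exchangeable.
#' @param template_space if TRUE skip subject-space CT/dose generation
#'   (used by the statistics-only tests).
#' @param deform_scale RMS mm of the per-subject anatomy deformation.
#' @param age_dose_slope optional Gy-per-year additive age effect inside
#'   the head support (0 by default; used to test covariate adjustment).
#' @param out_dir if non-NULL, write template, mask, per-subject volumes
#'   (NIfTI) and `cohort.tsv` there, and add path columns to the table.
#' @param demographics_only if TRUE return only the cohort table (no
#'   volumes); used for checking demographic marginals at large n.
#' @return list with `cohort` (data.frame), `subjects` (list of per-subject
#'   volumes), `template`, `brain_mask` and `ground_truth`.
#' @export
make_cohort <- function(n_per_group = 10, seed = 1, grid = grid_spec(),
                        params = dose_params(), template_space = FALSE,
                        deform_scale = 4, age_dose_slope = 0, out_dir = NULL,
                        demographics_only = FALSE) {
  stopifnot(n_per_group >= 2)
  n <- 2L * n_per_group
  ph <- make_template_phantom(grid, seed = seed)
  template <- ph$template
  gt <- ph$ground_truth
  support <- gt$head_support_mask

  cohort <- with_seed(seed, {
    data.frame(
      id = sprintf("sub-%03d", seq_len(n)),
      age = round(rnorm_trunc(n, 53, 10, 18, 84), 1),
      gender = ifelse(stats::runif(n) < 567 / 803, "male", "female"),
      t_stage = sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                       prob = c(81, 98, 416, 207)),
      technique = rep(c("IMRT", "VMAT"), each = n_per_group),
      prescription_dose = round(rnorm_trunc(n, 70.4, 1.2, 66.9, 74.2), 1),
      stringsAsFactors = FALSE
    )
  })
  if (demographics_only)
    return(list(cohort = cohort, template = template, ground_truth = gt))
  sub_seeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max - 1L, 2L * n))

  subjects <- vector("list", n)
  transforms <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- cohort[i, ]
    dose_t <- simulate_dose(rec, support, gt$target_center, params,
                            seed = sub_seeds[i])
    if (age_dose_slope != 0) {
      shift <- age_dose_slope * (rec$age - 53)
      dose_t$data[support$data > 0] <-
        pmax(dose_t$data[support$data > 0] + shift, 0)
    }
    if (template_space) {
      subjects[[i]] <- list(dose_template = dose_t)
    } else {
      sub <- sample_subject(template, seed = sub_seeds[n + i],
                            deform_scale = deform_scale)
      dose_s <- apply_chain(sub$transform, dose_t, template,
                            interpolation = "linear", fill = 0)
      dose_s$space <- "subject"
      transforms[[i]] <- sub$transform
      subjects[[i]] <- list(ct = sub$ct, dose = dose_s, dose_template = dose_t)
    }
  }

  gt$effect_mask <- effect_region(template, gt$target_center, params, support)
  gt$effect_size <- params$effect_size
  gt$subject_transforms <- transforms
  gt$dose_template <- lapply(subjects, `[[`, "dose_template")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume(template, file.path(out_dir, "template.nii.gz"))
    write_volume(support, file.path(out_dir, "head_mask.nii.gz"))
    cohort$ct_path <- NA_character_
    cohort$dose_path <- NA_character_
    for (i in seq_len(n)) {
      if (!template_space) {
        cohort$ct_path[i] <- file.path(out_dir, paste0(cohort$id[i], "_ct.nii.gz"))
        write_volume(subjects[[i]]$ct, cohort$ct_path[i])
        cohort$dose_path[i] <- file.path(out_dir, paste0(cohort$id[i], "_dose.nii.gz"))
        write_volume(subjects[[i]]$dose, cohort$dose_path[i])
      } else {
        cohort$dose_path[i] <- file.path(out_dir, paste0(cohort$id[i], "_dose.nii.gz"))
        write_volume(subjects[[i]]$dose_template, cohort$dose_path[i])
      }
    }
    utils::write.table(cohort, file.path(out_dir, "cohort.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  list(cohort = cohort, subjects = subjects, template = template,
       brain_mask = make_brain_mask(template), ground_truth = gt)
}
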
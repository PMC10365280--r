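# Group dose mapping: technique-wise mean dose, dose sub-range masks and
# voxel/volume counts, >50 Gy ROI construction and per-subject ROI doses.

#' Dose sub-range specification
#'
#' Boundaries define half-open bins `[lo, hi)` plus a final open bin
#' `(last, Inf)`; voxels below the first boundary (the 1.0 Gy display
#' floor) are left uncounted.
#'
#' @param boundaries strictly increasing dose boundaries in Gy.
#' @return a `dose_range_spec`.
#' @export
dose_range_spec <- function(boundaries = c(1.0, 1.5, 10, 30, 50)) {
  boundaries <- as.double(boundaries)
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  labels <- c(paste0(utils::head(boundaries, -1), "-", boundaries[-1]),
              paste0(">", boundaries[length(boundaries)]))
  structure(list(boundaries = boundaries, labels = labels),
            class = "dose_range_spec")
}

#' Voxel-wise mean of template-space dose volumes
#'
#' @param doses list of dose `volume`s on the template grid.
#' @param mask brain `mask_volume`; output is 0 outside it.
#' @return a dose `volume` (Gy).
#' @export
group_mean_dose <- function(doses, mask) {
  if (length(doses) == 0) stop("empty list of dose volumes")
  ref <- doses[[1]]
  acc <- array(0, dim(ref$data))
  for (v in doses) {
    if (!same_grid(v, ref)) stop("grid mismatch among dose volumes")
    acc <- acc + v$data
  }
  acc <- acc / length(doses)
  acc[mask$data == 0] <- 0
  volume(acc, ref$affine, ref$space)
}

#' Voxel counts and volumes per dose sub-range
#'
#' Counts brain-mask voxels whose mean dose falls in each sub-range;
#' the last bin is strictly `> last boundary`, matching a ">50 Gy" bin.
#'
#' @param mean_dose dose `volume` (Gy).
#' @param mask brain `mask_volume` on the same grid.
#' @param spec a [dose_range_spec()].
#' @return list with `summary` (data.frame: bin, n_voxels, volume_mm3)
#'   and `bin_masks` (list of `mask_volume`s).
#' @export
dose_range_summary <- function(mean_dose, mask, spec = dose_range_spec()) {
  if (!same_grid(mean_dose, mask)) stop("grid mismatch")
  b <- spec$boundaries
  nb <- length(b)
  vv <- voxel_volume_mm3(mean_dose)
  msel <- mask$data > 0
  bins <- vector("list", nb)
  counts <- integer(nb)
  for (i in seq_len(nb)) {
    inbin <- if (i < nb)
      msel & mean_dose$data >= b[i] & mean_dose$data < b[i + 1]
    else
      msel & mean_dose$data > b[nb]
    bins[[i]] <- mask_volume(inbin, mean_dose$affine, mean_dose$space)
    counts[i] <- sum(inbin)
  }
  list(summary = data.frame(bin = spec$labels, n_voxels = counts,
                            volume_mm3 = counts * vv),
       bin_masks = stats::setNames(bins, spec$labels),
       below_floor = sum(msel & mean_dose$data < b[1]))
}

#' Write a two-technique dose sub-range table as TSV
#'
#' Rows are techniques, columns the dose bins (a Table-2-style layout).
#' @param summaries named list (by technique) of [dose_range_summary()]
#'   results.
#' @param path output TSV path.
#' @export
write_dose_range_table <- function(summaries, path) {
  labs <- summaries[[1]]$summary$bin
  m <- t(vapply(summaries, function(s) s$summary$n_voxels,
                numeric(length(labs))))
  df <- data.frame(RTtech = names(summaries), m, check.names = FALSE)
  names(df)[-1] <- labs
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build high-dose regions of interest split by atlas lobe and hemisphere
#'
#' For each requested lobe, ROI = (mean dose > threshold) intersected
#' with the atlas lobe and the hemisphere (world x < 0 is left, > 0 is
#' right).
#'
#' @param mean_dose dose `volume` on the template grid.
#' @param atlas an `atlas_volume` on the same grid.
#' @param threshold dose threshold in Gy (strictly greater than).
#' @param lobes character vector of lobe names present in the atlas table.
#' @return named list of `mask_volume`s (`"<lobe> (L)"`, `"<lobe> (R)"`),
#'   empty ROIs dropped with a warning when the threshold exceeds all dose.
#' @export
build_high_dose_rois <- function(mean_dose, atlas, threshold = 50,
                                 lobes = c("Temporal Lobe", "Limbic Lobe")) {
  if (!same_grid(mean_dose, atlas)) stop("atlas grid mismatch")
  known <- unique(atlas$label_table$lobe)
  missing <- setdiff(lobes, known)
  if (length(missing))
    stop("lobe name(s) absent from atlas table: ", paste(missing, collapse = ", "))
  hot <- mean_dose$data > threshold
  if (!any(hot)) warning("threshold ", threshold, " Gy exceeds all dose values")
  w <- world_coords(mean_dose$affine, dim(mean_dose$data))
  rois <- list()
  for (lb in lobes) {
    labels <- atlas$label_table$label[atlas$label_table$lobe == lb]
    inlobe <- array(atlas$data %in% labels, dim(atlas$data))
    for (side in c("L", "R")) {
      hemi <- if (side == "L") w$x < 0 else w$x > 0
      m <- hot & inlobe & hemi
      if (any(m))
        rois[[paste0(lb, " (", side, ")")]] <-
          mask_volume(m, mean_dose$affine, mean_dose$space)
    }
  }
  rois
}

#' Mean dose over a region of interest
#'
#' @param dose_mni template-space dose `volume`.
#' @param roi nonempty `mask_volume` on the same grid.
#' @return scalar mean dose (Gy).
#' @export
roi_mean_dose <- function(dose_mni, roi) {
  if (!same_grid(dose_mni, roi)) stop("grid mismatch")
  sel <- roi$data > 0
  if (!any(sel)) stop("empty ROI")
  mean(dose_mni$data[sel])
}

#' Per-subject ROI mean-dose table with a two-sample technique comparison
#'
#' Extracts the mean dose of every ROI for every subject and runs a
#' two-sided two-sample t-test (IMRT vs VMAT) per ROI. Covariate-free by
#' default; `use_glm = TRUE` adjusts for age and gender via a linear
#' model.
#'
#' @param doses list of template-space dose `volume`s, one per cohort row.
#' @param cohort cohort data.frame with `id`, `technique` (and `age`,
#'   `gender` when `use_glm`).
#' @param rois named list of `mask_volume`s from [build_high_dose_rois()].
#' @param use_glm adjust for age and gender.
#' @return list with `doses` (long data.frame id/roi/mean_Gy) and `tests`
#'   (per-ROI group means, difference, t, p).
#' @export
roi_dose_table <- function(doses, cohort, rois, use_glm = FALSE) {
  stopifnot(length(doses) == nrow(cohort))
  long <- do.call(rbind, lapply(seq_along(doses), function(i) {
    data.frame(id = cohort$id[i], roi = names(rois),
               mean_Gy = vapply(rois, function(r) roi_mean_dose(doses[[i]], r),
                                numeric(1)),
               technique = cohort$technique[i], row.names = NULL)
  }))
  tests <- do.call(rbind, lapply(names(rois), function(rn) {
    d <- long[long$roi == rn, ]
    g1 <- d$mean_Gy[d$technique == "IMRT"]
    g2 <- d$mean_Gy[d$technique == "VMAT"]
    if (use_glm) {
      dat <- cbind(d, age = cohort$age[match(d$id, cohort$id)],
                   gender = cohort$gender[match(d$id, cohort$id)])
      fit <- stats::lm(mean_Gy ~ technique + age + gender, data = dat)
      co <- summary(fit)$coefficients
      row <- co[grep("^technique", rownames(co)), , drop = FALSE]
      tval <- -row[1, "t value"]  # techniqueVMAT coef: flip to IMRT - VMAT
      pval <- row[1, "Pr(>|t|)"]
    } else {
      tt <- stats::t.test(g1, g2, var.equal = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(roi = rn, mean_IMRT = mean(g1), sd_IMRT = stats::sd(g1),
               mean_VMAT = mean(g2), sd_VMAT = stats::sd(g2),
               t = tval, p = pval, row.names = NULL)
  }))
  list(doses = long, tests = tests)
}
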
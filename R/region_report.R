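# Atlas handling and cluster/region reports in the layout of the
# published significance tables: region, voxel count, peak T, peak
# world (MNI) coordinate per direction.

#' Construct an atlas volume
#'
#' @param data 3D array of non-negative integer labels (0 = background).
#' @param affine 4x4 affine.
#' @param label_table data.frame with columns `label`, `region`, `lobe`;
#'   every nonzero label in `data` must appear in it.
#' @param space space tag.
#' @return an `atlas_volume`.
#' @export
atlas_volume <- function(data, affine, label_table,
                         space = c("template", "subject")) {
  space <- match.arg(space)
  stopifnot(all(c("label", "region", "lobe") %in% names(label_table)))
  labs <- sort(unique(as.integer(data[data != 0])))
  missing <- setdiff(labs, label_table$label)
  if (length(missing))
    stop("labels missing from label table: ", paste(missing, collapse = ", "))
  v <- volume(array(as.double(data), dim(data)), affine, space)
  v$label_table <- label_table
  class(v) <- c("atlas_volume", class(v))
  v
}

#' Read an atlas from a label NIfTI plus a TSV label table
#'
#' The TSV needs columns `label`, `region` and optionally `lobe`
#' (defaults to `region`).
#' @param nifti_path label volume path.
#' @param table_path TSV path.
#' @return an `atlas_volume` in template space.
#' @export
read_atlas <- function(nifti_path, table_path) {
  nii <- read_nifti(nifti_path)
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  if (is.null(tab$lobe)) tab$lobe <- tab$region
  atlas_volume(nii$data, nii$affine, tab, space = "template")
}

#' Coarse phantom atlas on the template grid
#'
#' Partitions the phantom brain into ~12 anatomically-placed analogue
#' regions (frontal, parietal, occipital, left/right temporal, limbic,
#' sub-lobar, brainstem, anterior/posterior cerebellum analogues, and
#' ventricles), named with the lobe vocabulary the high-dose ROI and
#' cluster reports use. A stand-in for a real labelled atlas, which can
#' be supplied instead via [read_atlas()].
#'
#' @param template phantom template `volume`.
#' @return an `atlas_volume`.
#' @export
make_phantom_atlas <- function(template) {
  d <- dim(template$data)
  w <- world_coords(template$affine, d)
  rb <- ellipsoid_r(w, PHANTOM$brain_center, PHANTOM$brain_semi)
  rh <- ellipsoid_r(w, PHANTOM$head_center, PHANTOM$head_semi)
  brain <- rh <= 1 & rb < PHANTOM$skull_inner

  lab <- array(0L, d)
  regions <- list()
  add <- function(id, sel, region, lobe) {
    lab[brain & sel & lab == 0L] <<- id
    regions[[length(regions) + 1]] <<- data.frame(label = id, region = region,
                                                  lobe = lobe)
  }
  vent <- array(FALSE, d)
  for (vc in PHANTOM$vent_centers)
    vent <- vent | ellipsoid_r(w, vc, PHANTOM$vent_semi) <= 1
  add(1L, vent, "Lateral Ventricle", "Sub-lobar")
  # brainstem analogue: central inferior column
  add(2L, abs(w$x) < 14 & w$y > -45 & w$y < 0 & w$z < -10, "Brainstem", "Brainstem")
  # cerebellum analogues: inferior posterior
  add(3L, w$z < -15 & w$y < -35 & w$y >= -60, "Cerebellum Anterior Lobe",
      "Cerebellum Anterior Lobe")
  add(4L, w$z < -15 & w$y < -60, "Cerebellum Posterior Lobe",
      "Cerebellum Posterior Lobe")
  # temporal analogues: lateral inferior
  add(5L, w$x <= -30 & w$z < 12 & w$y > -60 & w$y < 30, "Temporal Lobe L",
      "Temporal Lobe")
  add(6L, w$x >= 30 & w$z < 12 & w$y > -60 & w$y < 30, "Temporal Lobe R",
      "Temporal Lobe")
  # limbic analogue: medial inferior ring
  add(7L, abs(w$x) < 30 & w$z < 12 & w$y > -45 & w$y < 25, "Limbic Lobe",
      "Limbic Lobe")
  # occipital: posterior
  add(8L, w$y < -55, "Occipital Lobe", "Occipital Lobe")
  # frontal: anterior
  add(9L, w$y > 25, "Frontal Lobe", "Frontal Lobe")
  # sub-lobar: deep central
  add(10L, abs(w$x) < 28 & w$z >= 12 & w$z < 35 & w$y > -40 & w$y < 25,
      "Sub-lobar", "Sub-lobar")
  # parietal: superior posterior remainder
  add(11L, w$z >= 35, "Parietal Lobe", "Parietal Lobe")
  add(12L, TRUE, "Sub Gyral", "Sub-lobar")  # remainder
  atlas_volume(lab, template$affine, do.call(rbind, regions),
               space = "template")
}

#' Label a significance mask by atlas region
#'
#' Intersects the significance mask with every atlas region and reports,
#' for regions with at least one voxel, the voxel count, the signed peak
#' t (largest |t|; ties broken by first voxel in scan order) and the
#' world coordinate of the peak, sorted by descending count. Significant
#' voxels on atlas background are reported as "unlabeled".
#'
#' @param sig significance `mask_volume`.
#' @param t_map t `volume` on the same grid.
#' @param atlas an `atlas_volume` on the same grid.
#' @param direction label for the table (`"IMRT > VMAT"` or
#'   `"IMRT < VMAT"`).
#' @return a `cluster_report` data.frame: direction, region, n_voxels,
#'   peak_t, x, y, z. Zero rows when the mask is empty.
#' @export
label_sig_map <- function(sig, t_map, atlas, direction = "IMRT > VMAT") {
  if (!same_grid(sig, atlas)) stop("atlas grid mismatch")
  if (!same_grid(sig, t_map)) stop("t map grid mismatch")
  sel <- sig$data > 0
  empty <- data.frame(direction = character(), region = character(),
                      n_voxels = integer(), peak_t = numeric(),
                      x = numeric(), y = numeric(), z = numeric())
  if (!any(sel)) return(structure(empty, class = c("cluster_report", "data.frame")))
  labs <- as.integer(atlas$data[sel])
  tvals <- t_map$data
  rows <- list()
  region_of <- function(l) {
    if (l == 0) "unlabeled"
    else atlas$label_table$region[match(l, atlas$label_table$label)]
  }
  for (l in sort(unique(labs))) {
    insel <- sel & atlas$data == l
    av <- abs(tvals); av[!insel] <- -Inf
    i <- which.max(av)
    ijk <- arrayInd(i, dim(tvals)) - 1L
    w <- voxel_to_world(as.integer(ijk), t_map$affine)
    rows[[length(rows) + 1]] <- data.frame(
      direction = direction, region = region_of(l), n_voxels = sum(insel),
      peak_t = tvals[i], x = w[1], y = w[2], z = w[3])
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), ]
  rownames(out) <- NULL
  structure(out, class = c("cluster_report", "data.frame"))
}

#' Region composition of dose sub-range masks
#'
#' For each dose bin, lists the atlas regions it covers with voxel
#' counts and the fraction of each region covered.
#'
#' @param bin_masks named list of `mask_volume`s from
#'   [dose_range_summary()].
#' @param atlas an `atlas_volume` on the same grid.
#' @return data.frame: bin, region, n_voxels, region_fraction.
#' @export
label_dose_bins <- function(bin_masks, atlas) {
  region_sizes <- table(factor(atlas$data[atlas$data != 0],
                               levels = atlas$label_table$label))
  rows <- list()
  for (bn in names(bin_masks)) {
    m <- bin_masks[[bn]]
    if (!same_grid(m, atlas)) stop("atlas grid mismatch")
    labs <- atlas$data[m$data > 0]
    labs <- labs[labs != 0]
    if (!length(labs)) next
    tab <- table(factor(labs, levels = atlas$label_table$label))
    hit <- which(tab > 0)
    for (i in hit) {
      l <- atlas$label_table$label[i]
      rows[[length(rows) + 1]] <- data.frame(
        bin = bn,
        region = atlas$label_table$region[i],
        n_voxels = as.integer(tab[i]),
        region_fraction = as.numeric(tab[i]) / as.numeric(region_sizes[i]))
    }
  }
  if (!length(rows))
    return(data.frame(bin = character(), region = character(),
                      n_voxels = integer(), region_fraction = numeric()))
  do.call(rbind, rows)
}

#' Write a cluster report as TSV (Tables 3-6 layout)
#'
#' @param report a `cluster_report` (or an rbind of several directions).
#' @param path output TSV path.
#' @export
write_cluster_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
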
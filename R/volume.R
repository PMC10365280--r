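# Volume data model: a 3D scalar grid plus a 4x4 voxel-index -> world-mm
# affine (RAS, 0-based indices). CT volumes carry HU, dose volumes Gy,
# statistic maps are unitless.

#' Construct a volume
#'
#' @param data 3D numeric array.
#' @param affine 4x4 invertible voxel-index (0-based) to world-mm matrix.
#' @param space `"subject"` or `"template"`.
#' @return an object of class `volume`.
#' @export
volume <- function(data, affine, space = c("subject", "template")) {
  space <- match.arg(space)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(dim(data) <= 0)) stop("grid dimensions must be positive")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, space = space),
            class = "volume")
}

#' Construct a binary mask volume
#'
#' @param data 3D array coercible to 0/1.
#' @param affine 4x4 affine.
#' @param space volume space tag.
#' @return an object of class `c("mask_volume", "volume")`.
#' @export
mask_volume <- function(data, affine, space = c("subject", "template")) {
  v <- volume(array(as.double(data != 0), dim = dim(data)), affine, space)
  class(v) <- c("mask_volume", class(v))
  v
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<%s> %dx%dx%d, spacing %.3gx%.3gx%.3g mm, space=%s\n",
              class(x)[1], d[1], d[2], d[3], sp[1], sp[2], sp[3], x$space))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

voxel_spacing <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Template grid specification
#'
#' Defaults to the standard MNI 2 mm bounding box: 91x109x91 voxels,
#' 2 mm isotropic, origin (-90, -126, -72) mm. Smaller grids (used by the
#' phantom tests) default to a grid centred on the world origin.
#'
#' @param dim integer triple of grid dimensions.
#' @param spacing voxel size in mm (scalar or triple).
#' @param origin world coordinate of voxel (0,0,0); `NULL` centres the grid,
#'   except for the default MNI grid which uses (-90,-126,-72).
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(dim = c(91L, 109L, 91L), spacing = 2, origin = NULL) {
  dim <- as.integer(dim)
  spacing <- rep_len(as.double(spacing), 3)
  if (is.null(origin)) {
    origin <- if (all(dim == c(91L, 109L, 91L)) && all(spacing == 2))
      c(-90, -126, -72) else -(dim - 1) * spacing / 2
  }
  structure(list(dim = dim, spacing = spacing, origin = as.double(origin)),
            class = "grid_spec")
}

grid_affine <- function(grid) {
  A <- diag(c(grid$spacing, 1))
  A[1:3, 4] <- grid$origin
  A
}

empty_volume <- function(grid, space = "template", fill = 0) {
  volume(array(fill, dim = grid$dim), grid_affine(grid), space)
}

#' Read a NIfTI volume from disk
#'
#' @param path path to a 3D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param space space tag to attach (`"subject"` or `"template"`).
#' @return a `volume`.
#' @export
read_volume <- function(path, space = c("subject", "template")) {
  space <- match.arg(space)
  nii <- read_nifti(path)
  volume(nii$data, nii$affine, space)
}

#' Write a volume to disk as NIfTI-1
#'
#' @param vol a `volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param dtype storage datatype; masks default to `"uint8"`, everything
#'   else to `"float32"`.
#' @export
write_volume <- function(vol, path, dtype = NULL) {
  if (is.null(dtype))
    dtype <- if (inherits(vol, "mask_volume")) "uint8" else "float32"
  write_nifti(vol$data, vol$affine, path, dtype = dtype)
  invisible(path)
}

#' Convert 0-based voxel indices to world mm
#'
#' @param index integer triple or N x 3 matrix of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return numeric triple or N x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(index, affine) {
  m <- rbind(t(matrix(as.double(index), ncol = 3)), 1)
  out <- t(affine %*% m)[, 1:3, drop = FALSE]
  if (length(index) == 3) drop(out) else out
}

#' Convert world mm to (fractional) 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param world numeric triple or N x 3 matrix of world coordinates.
#' @export
world_to_voxel <- function(world, affine) {
  m <- rbind(t(matrix(as.double(world), ncol = 3)), 1)
  out <- t(solve(affine) %*% m)[, 1:3, drop = FALSE]
  if (length(world) == 3) drop(out) else out
}

# N x 3 matrix of all 0-based voxel indices of a grid, i fastest
grid_indices <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1L, times = d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
}

#' Resample a volume onto a reference grid
#'
#' Values are sampled at the world positions of the reference voxels,
#' mapped through both affines. Points outside the source field of view
#' get `fill` (0 by default; use -1024 for CT).
#'
#' @param vol source `volume`.
#' @param reference `volume` (or `grid_spec`) defining the output grid.
#' @param interpolation `"linear"` for CT/dose, `"nearest"` for masks and
#'   atlas labels.
#' @param fill out-of-field value.
#' @return a `volume` on the reference grid.
#' @export
resample_to <- function(vol, reference, interpolation = c("linear", "nearest"),
                        fill = 0) {
  interpolation <- match.arg(interpolation)
  if (inherits(reference, "grid_spec"))
    reference <- empty_volume(reference, space = vol$space)
  # map reference voxel index -> world -> source voxel index in one matrix
  M <- solve(vol$affine) %*% reference$affine
  idx <- grid_indices(dim(reference$data))
  src <- cbind(idx, 1) %*% t(M)
  sampler <- if (interpolation == "linear") cpp_sample_trilinear else cpp_sample_nearest
  vals <- sampler(as.double(vol$data), dim(vol$data), src[, 1:3, drop = FALSE],
                  as.double(fill))
  out <- volume(array(vals, dim = dim(reference$data)), reference$affine,
                reference$space)
  if (inherits(vol, "mask_volume")) {
    out$data <- array(as.double(out$data != 0), dim = dim(out$data))
    class(out) <- c("mask_volume", class(out))
  }
  out
}

# largest connected component of a logical array (6-connectivity)
largest_component <- function(mask3d) {
  lab <- cpp_label_components(as.logical(mask3d), dim(mask3d), 6L)
  if (max(lab) == 0) return(array(FALSE, dim(mask3d)))
  tab <- tabulate(lab)
  array(lab == which.max(tab), dim(mask3d))
}

# fill internal holes: background components not touching the border
fill_holes <- function(mask3d) {
  bg <- !mask3d
  lab <- array(cpp_label_components(as.logical(bg), dim(bg), 6L), dim(bg))
  d <- dim(bg)
  border_labels <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                            lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border_labels <- setdiff(border_labels, 0L)
  holes <- bg & !(lab %in% border_labels)
  mask3d | array(holes, dim(mask3d))
}

#' Build a brain/head mask from a CT-like template
#'
#' Thresholds the template, keeps the largest connected component and
#' fills internal holes. Used to restrict voxel counting and statistics
#' to the head support of the template.
#'
#' @param template a template-space CT `volume`.
#' @param hu_threshold mask includes voxels strictly above this HU value
#'   (default -500, i.e. everything denser than air).
#' @return a `mask_volume` on the template grid.
#' @export
make_brain_mask <- function(template, hu_threshold = -500) {
  raw <- template$data > hu_threshold
  if (!any(raw)) stop("empty mask: no voxels above threshold ", hu_threshold)
  m <- fill_holes(largest_component(raw))
  mask_volume(m, template$affine, template$space)
}
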
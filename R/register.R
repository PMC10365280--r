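# Synchronized spatial normalization: crop, rigid, affine and nonlinear
# (regularized DCT basis-function) registration under a
# sum-of-squared-differences (SSD) objective, with a single composed
# resampling applied identically to CT and dose.
#
# Convention: a transform maps FIXED-space world coordinates to
# MOVING-space world coordinates (pull-back / resampling convention).
# A chain [rigid, affine, field] is applied as
#   x_moving = A (x_fixed + u(x_fixed)),
# where A is the affine (which subsumes the rigid stage it was
# initialized from) and u the dense displacement field on the fixed grid.

rot_mat <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Build a rigid 4x4 matrix from 6 parameters
#'
#' Parameters are (rx, ry, rz) rotations in radians and (tx, ty, tz)
#' translations in mm; rotation is about `center`.
#' @param par numeric vector of length 6.
#' @param center rotation centre (world mm).
#' @return 4x4 matrix mapping fixed-space to moving-space world mm.
#' @export
build_rigid <- function(par, center = c(0, 0, 0)) {
  R <- rot_mat(par[1], par[2], par[3])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center - R %*% center + par[4:6]
  M
}

#' Build an affine 4x4 matrix from 12 parameters
#'
#' Parameters: 3 rotations (rad), 3 translations (mm), 3 log-scales,
#' 3 shears. Reduces to [build_rigid()] when scales and shears are zero.
#' @inheritParams build_rigid
#' @export
build_affine12 <- function(par, center = c(0, 0, 0)) {
  R <- rot_mat(par[1], par[2], par[3])
  S <- diag(exp(par[7:9]))
  Sh <- diag(3)
  Sh[1, 2] <- par[10]; Sh[1, 3] <- par[11]; Sh[2, 3] <- par[12]
  L <- R %*% Sh %*% S
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- center - L %*% center + par[4:6]
  M
}

#' Construct a transform chain
#'
#' @param rigid optional 4x4 rigid matrix.
#' @param affine optional 4x4 affine matrix (supersedes `rigid` when both
#'   are present, having been initialized from it).
#' @param field optional displacement field: list of `ux`, `uy`, `uz`
#'   arrays (mm) on the reference grid.
#' @param reference `volume` whose grid the field lives on.
#' @return a `transform_chain`.
#' @export
new_chain <- function(rigid = NULL, affine = NULL, field = NULL,
                      reference = NULL) {
  structure(list(rigid = rigid, affine = affine, field = field,
                 ref_affine = if (!is.null(reference)) reference$affine,
                 ref_dim = if (!is.null(reference)) dim(reference$data)),
            class = "transform_chain")
}

chain_matrix <- function(chain) {
  if (!is.null(chain$affine)) chain$affine
  else if (!is.null(chain$rigid)) chain$rigid
  else diag(4)
}

#' Apply a transform chain to a volume (single resampling pass)
#'
#' Composes the chain's displacement field and linear transform into one
#' coordinate mapping and samples the input volume once.
#'
#' @param chain a `transform_chain` (empty chain = plain resampling).
#' @param vol `volume` to transform (the moving image).
#' @param reference `volume` defining the output grid (must match the
#'   grid the chain's field is defined on, when a field is present).
#' @param interpolation `"linear"` (dose), `"nearest"` (masks, atlas) or
#'   `"cubic"` (CT; Catmull-Rom, used where interpolation blur matters).
#' @param fill out-of-field value (0 for dose, -1024 for CT).
#' @return a `volume` on the reference grid.
#' @export
apply_chain <- function(chain, vol, reference,
                        interpolation = c("linear", "nearest", "cubic"),
                        fill = 0) {
  interpolation <- match.arg(interpolation)
  if (missing(reference) || is.null(reference)) stop("reference is required")
  d <- dim(reference$data)
  if (!is.null(chain$field)) {
    if (!is.null(chain$ref_dim) &&
        (!identical(chain$ref_dim, d) ||
         max(abs(chain$ref_affine - reference$affine)) > 1e-4))
      stop("chain displacement field is defined on a different grid than reference")
  }
  idx <- grid_indices(d)
  wld <- cbind(idx, 1) %*% t(reference$affine)
  if (!is.null(chain$field)) {
    wld[, 1] <- wld[, 1] + as.vector(chain$field$ux)
    wld[, 2] <- wld[, 2] + as.vector(chain$field$uy)
    wld[, 3] <- wld[, 3] + as.vector(chain$field$uz)
  }
  Mi <- solve(vol$affine) %*% chain_matrix(chain)
  src <- wld %*% t(Mi)
  vals <- switch(interpolation,
    linear = cpp_sample_trilinear(as.double(vol$data), dim(vol$data),
                                  src[, 1:3, drop = FALSE], as.double(fill)),
    nearest = cpp_sample_nearest(as.double(vol$data), dim(vol$data),
                                 src[, 1:3, drop = FALSE], as.double(fill)),
    cubic = cpp_sample_cubic_grad(as.double(vol$data), dim(vol$data),
                                  src[, 1:3, drop = FALSE],
                                  as.double(fill))[, 1])
  volume(array(vals, d), reference$affine, reference$space)
}

# fixed-point inversion of a displacement field: w(x) = -u(x + w(x))
invert_displacement <- function(field, reference, iters = 25) {
  d <- dim(reference$data)
  A <- reference$affine
  Ai <- solve(A)
  idx <- grid_indices(d)
  wld <- cbind(idx, 1) %*% t(A)
  w <- list(x = -as.vector(field$ux), y = -as.vector(field$uy),
            z = -as.vector(field$uz))
  for (k in seq_len(iters)) {
    pts <- cbind(wld[, 1] + w$x, wld[, 2] + w$y, wld[, 3] + w$z, 1) %*% t(Ai)
    vx <- pts[, 1:3, drop = FALSE]
    ux <- cpp_sample_trilinear(as.double(field$ux), d, vx, 0)
    uy <- cpp_sample_trilinear(as.double(field$uy), d, vx, 0)
    uz <- cpp_sample_trilinear(as.double(field$uz), d, vx, 0)
    w <- list(x = -ux, y = -uy, z = -uz)
  }
  list(ux = array(w$x, d), uy = array(w$y, d), uz = array(w$z, d))
}

#' Invert a transform chain
#'
#' Returns the chain mapping the other way: if the input samples a
#' moving volume onto the reference grid, the inverse samples the
#' reference-space result back. The displacement field is inverted by
#' fixed-point iteration.
#'
#' @param chain a `transform_chain` whose field lives on `reference`.
#' @param reference the `volume` carrying the chain's grid.
#' @return a `transform_chain` on the same grid.
#' @export
invert_chain <- function(chain, reference) {
  M <- chain_matrix(chain)
  Minv <- solve(M)
  field_inv <- NULL
  if (!is.null(chain$field)) {
    w <- invert_displacement(chain$field, reference)
    # v(x) = L w(M^{-1} x), so that M^{-1}(x + v(x)) = M^{-1}x + w(M^{-1}x)
    d <- dim(reference$data)
    A <- reference$affine
    idx <- grid_indices(d)
    wld <- cbind(idx, 1) %*% t(reference$affine)
    pts <- (wld %*% t(Minv)) %*% t(solve(A))   # M^{-1}x in voxel coords
    vx <- pts[, 1:3, drop = FALSE]
    wx <- cpp_sample_trilinear(as.double(w$ux), d, vx, 0)
    wy <- cpp_sample_trilinear(as.double(w$uy), d, vx, 0)
    wz <- cpp_sample_trilinear(as.double(w$uz), d, vx, 0)
    L <- M[1:3, 1:3]
    v <- L %*% rbind(wx, wy, wz)
    field_inv <- list(ux = array(v[1, ], d), uy = array(v[2, ], d),
                      uz = array(v[3, ], d))
  }
  new_chain(affine = Minv, field = field_inv, reference = reference)
}

#' Sum of squared intensity differences between two volumes
#'
#' The registration objective: `sum((a - b)^2)` over the mask (or the
#' whole grid).
#'
#' @param a,b `volume`s on the same grid.
#' @param mask optional `mask_volume` restricting the sum.
#' @return scalar SSD.
#' @export
ssd <- function(a, b, mask = NULL) {
  if (!same_grid(a, b)) stop("grid mismatch between volumes")
  diff2 <- (a$data - b$data)^2
  if (is.null(mask)) sum(diff2) else {
    if (!same_grid(a, mask)) stop("grid mismatch between volume and mask")
    sum(diff2[mask$data > 0])
  }
}

#' Crop CT and dose to the head bounding box, synchronously
#'
#' Finds the head on the CT (largest connected component above
#' `hu_threshold`), pads the bounding box by `pad_mm` on every side
#' except inferiorly (the neck side is truncated at the head's inferior
#' extent), and crops both volumes to the same box. Affines are updated
#' so retained voxels keep their world coordinates. The dose is first
#' resampled onto the CT grid if the grids differ.
#'
#' @param ct subject CT `volume` (HU).
#' @param dose subject dose `volume` (Gy).
#' @param hu_threshold head detection threshold (default -500 HU).
#' @param pad_mm padding in mm.
#' @return list with cropped `ct` and `dose` on a shared grid.
#' @export
crop_head <- function(ct, dose, hu_threshold = -500, pad_mm = 10) {
  if (!same_grid(ct, dose))
    dose <- resample_to(dose, ct, interpolation = "linear", fill = 0)
  head <- largest_component(ct$data > hu_threshold)
  if (!any(head)) stop("no voxels above threshold ", hu_threshold)
  ijk <- which(head, arr.ind = TRUE)
  lo <- apply(ijk, 2, min)
  hi <- apply(ijk, 2, max)
  sp <- voxel_spacing(ct)
  pad <- ceiling(pad_mm / sp)
  d <- dim(ct$data)
  lo_p <- pmax(lo - pad, 1)
  hi_p <- pmin(hi + pad, d)
  # inferior = low world z side (assumes z column of affine points superior)
  if (ct$affine[3, 3] >= 0) lo_p[3] <- lo[3] else hi_p[3] <- hi[3]
  sub <- function(a) a[lo_p[1]:hi_p[1], lo_p[2]:hi_p[2], lo_p[3]:hi_p[3],
                       drop = FALSE]
  A <- ct$affine
  A[1:3, 4] <- (A %*% c(lo_p - 1, 1))[1:3]
  list(ct = volume(sub(ct$data), A, ct$space),
       dose = volume(sub(dose$data), A, dose$space))
}

# Gaussian prefilter + resample onto a coarser grid (factor x spacing)
downsample_volume <- function(vol, factor, fill = 0) {
  if (factor <= 1) return(vol)
  sp <- voxel_spacing(vol)
  sm <- vol
  sm$data <- smooth3d(vol$data, sigma_mm = sp * factor / 2, spacing = sp)
  d <- dim(vol$data)
  nd <- pmax(as.integer(ceiling(d / factor)), 2L)
  A <- vol$affine
  A[, 1:3] <- A[, 1:3] * rep(factor, each = 4)
  ref <- volume(array(0, nd), A, vol$space)
  resample_to(sm, ref, interpolation = "linear", fill = fill)
}

# shared Nelder-Mead multiresolution SSD driver for rigid/affine
register_linear <- function(moving, fixed, par0, builder, parscale,
                            factors, maxit, fill) {
  center <- drop(fixed$affine %*% c((dim(fixed$data) - 1) / 2, 1))[1:3]
  par <- par0
  for (li in seq_along(factors)) {
    f <- factors[li]
    fx <- downsample_volume(fixed, f, fill = fill)
    mv <- downsample_volume(moving, f, fill = fill)
    idx <- grid_indices(dim(fx$data))
    wld <- cbind(idx, 1) %*% t(fx$affine)
    Ainv <- solve(mv$affine)
    fdat <- as.vector(fx$data)
    mdat <- as.double(mv$data)
    mdim <- dim(mv$data)
    obj <- function(p) {
      M <- builder(p, center)
      src <- wld %*% t(Ainv %*% M)
      v <- cpp_sample_trilinear(mdat, mdim, src[, 1:3, drop = FALSE], fill)
      mean((v - fdat)^2)
    }
    # Nelder-Mead with one restart (a fresh simplex around the optimum)
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[li], reltol = 1e-10,
                                       parscale = parscale))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[li], reltol = 1e-10,
                                       parscale = parscale / 10))
    if (li == length(factors)) {
      # finite-difference quasi-Newton polish at the finest level
      fit2 <- tryCatch(
        stats::optim(fit$par, obj, method = "BFGS",
                     control = list(maxit = 50, reltol = 1e-12,
                                    parscale = parscale / 10)),
        error = function(e) fit)
      if (fit2$value <= fit$value) fit <- fit2
    }
    # guard against a level making things worse
    if (fit$value <= obj(par)) par <- fit$par
  }
  # convergence bookkeeping at the finest level
  f <- factors[length(factors)]
  fx <- downsample_volume(fixed, f, fill = fill)
  mv <- downsample_volume(moving, f, fill = fill)
  idx <- grid_indices(dim(fx$data))
  wld <- cbind(idx, 1) %*% t(fx$affine)
  Ainv <- solve(mv$affine)
  evalp <- function(p) {
    M <- builder(p, center)
    src <- wld %*% t(Ainv %*% M)
    v <- cpp_sample_trilinear(as.double(mv$data), dim(mv$data),
                              src[, 1:3, drop = FALSE], fill)
    mean((v - as.vector(fx$data))^2)
  }
  s0 <- evalp(par0)
  s1 <- evalp(par)
  fell_back <- s1 > s0
  if (fell_back) {
    # best-so-far contract: never return a transform worse than the init
    par <- par0
    s1 <- s0
  }
  list(par = par, matrix = builder(par, center), center = center,
       ssd_before = s0, ssd_after = s1, converged = !fell_back)
}

#' Rigid registration (6 parameters) by multiresolution SSD minimization
#'
#' Deterministic gradient-free (Nelder-Mead) search over translation and
#' rotation on a coarse-to-fine schedule. Replaces the manual AC-PC
#' alignment step with an automatic equivalent.
#'
#' @param moving,fixed `volume`s with overlapping fields of view.
#' @param factors multiresolution downsampling factors (coarse to fine).
#' @param maxit Nelder-Mead iteration budget per level.
#' @param fill out-of-field intensity (air, -1024, for CT).
#' @return a `rigid_transform`: parameters, 4x4 matrix, SSD before/after,
#'   and a convergence flag (`FALSE` means the optimizer did not improve
#'   on the initial transform, which was returned instead).
#' @export
register_rigid <- function(moving, fixed, factors = c(4, 2, 1),
                           maxit = c(500, 400, 300), fill = -1024) {
  res <- register_linear(moving, fixed, par0 = rep(0, 6),
                         builder = build_rigid,
                         parscale = c(rep(0.02, 3), rep(2, 3)),
                         factors = factors, maxit = maxit, fill = fill)
  structure(res, class = "rigid_transform")
}

#' Affine registration (12 parameters), initialized from a rigid fit
#'
#' @inheritParams register_rigid
#' @param init a `rigid_transform` (or 6-parameter vector) initializing
#'   rotation and translation.
#' @return an `affine_transform` (same fields as [register_rigid()]).
#' @export
register_affine <- function(moving, fixed, init = NULL,
                            factors = c(4, 2, 1), maxit = c(500, 400, 300),
                            fill = -1024) {
  p0 <- rep(0, 12)
  if (!is.null(init))
    p0[1:6] <- if (inherits(init, "rigid_transform")) init$par else init[1:6]
  res <- register_linear(moving, fixed, par0 = p0,
                         builder = build_affine12,
                         parscale = c(rep(0.02, 3), rep(2, 3),
                                      rep(0.02, 3), rep(0.02, 3)),
                         factors = factors, maxit = maxit, fill = fill)
  structure(res, class = "affine_transform")
}

# orthonormal DCT-II basis matrix (n x K)
dct_basis <- function(n, K) {
  i <- 0:(n - 1)
  B <- vapply(0:(K - 1),
              function(k) cos(pi * (2 * i + 1) * k / (2 * n)), numeric(n))
  B[, 1] <- B[, 1] / sqrt(2)
  B * sqrt(2 / n)
}

# synthesize a field component from a coefficient array C (K1,K2,K3)
dct_synth <- function(C, Bx, By, Bz, d) {
  K <- dim(C)
  M <- Bx %*% matrix(C, K[1])
  M <- aperm(array(M, c(d[1], K[2], K[3])), c(2, 1, 3))
  M <- By %*% matrix(M, K[2])
  M <- aperm(array(M, c(d[2], d[1], K[3])), c(2, 1, 3))
  array(matrix(M, d[1] * d[2]) %*% t(Bz), d)
}

# adjoint: project a grid array onto the basis -> (K1,K2,K3)
dct_analyze <- function(Fa, Bx, By, Bz, d) {
  K <- c(ncol(Bx), ncol(By), ncol(Bz))
  M <- t(Bx) %*% matrix(Fa, d[1])
  M <- aperm(array(M, c(K[1], d[2], d[3])), c(2, 1, 3))
  M <- t(By) %*% matrix(M, d[2])
  M <- aperm(array(M, c(K[2], K[1], d[3])), c(2, 1, 3))
  array(matrix(M, K[1] * K[2]) %*% Bz, K)
}

#' Nonlinear registration by regularized basis-function SSD minimization
#'
#' Estimates a smooth dense displacement field parameterized by
#' low-frequency 3D DCT basis functions (the approach of classical
#' statistical-parametric-mapping spatial normalization), minimizing
#' masked SSD on intensity-normalized, Gaussian-presmoothed volumes plus
#' a membrane-energy penalty, by Levenberg-Marquardt-damped Gauss-Newton
#' with analytic gradients (Catmull-Rom resampling). Runs a
#' coarse-to-fine presmoothing schedule; within every stage only steps
#' that decrease the regularized objective are accepted, so the recorded
#' objective trace is non-increasing.
#'
#' @param moving,fixed CT `volume`s; `fixed` defines the output grid.
#' @param init 4x4 affine matrix (or rigid/affine transform object)
#'   mapping fixed to moving world coordinates, composed inside the loop.
#' @param iters maximum Gauss-Newton iterations per stage (>= 1).
#' @param basis_spacing approximate spacing (mm) of the DCT basis; the
#'   number of modes per axis is `max(4, round(FOV / basis_spacing))`.
#' @param lambda membrane-energy regularization weight.
#' @param presmooth Gaussian presmoothing schedule in mm (coarse to fine).
#' @param mask optional fixed-space `mask_volume` for the SSD (defaults
#'   to fixed > -500 HU support); grid-border voxels are always excluded.
#' @return a `deformation_field`: `field` (ux/uy/uz arrays, mm, on the
#'   fixed grid), `ssd_trace` (accepted regularized-objective sequence of
#'   the final stage), per-stage traces, coefficients and settings.
#' @export
register_nonlinear <- function(moving, fixed, init = diag(4), iters = 10,
                               basis_spacing = 24, lambda = 0.05,
                               presmooth = c(8, 4, 2), mask = NULL) {
  stopifnot(iters >= 1)
  M <- if (inherits(init, c("rigid_transform", "affine_transform")))
    init$matrix else as.matrix(init)
  d <- dim(fixed$data)
  sp <- voxel_spacing(fixed)
  if (is.null(mask))
    mask <- mask_volume(fixed$data > -500, fixed$affine, fixed$space)
  msel <- mask$data > 0
  # grid-border voxels see the out-of-field fill discontinuously; drop them
  interior <- array(FALSE, d)
  interior[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  msel <- msel & interior
  if (!any(msel)) stop("empty registration mask")
  wv <- as.double(msel)

  mu_f <- mean(fixed$data[msel]); sd_f <- stats::sd(fixed$data[msel])
  if (!is.finite(sd_f) || sd_f < .Machine$double.eps) sd_f <- 1
  fn0 <- (fixed$data - mu_f) / sd_f
  msup <- moving$data > -500
  mu_m <- mean(moving$data[msup]); sd_m <- stats::sd(moving$data[msup])
  if (!is.finite(sd_m) || sd_m < .Machine$double.eps) { mu_m <- mu_f; sd_m <- sd_f }
  mn0 <- (moving$data - mu_m) / sd_m
  fill_n <- (-1024 - mu_m) / sd_m

  K <- pmax(4L, as.integer(round(d * sp / basis_spacing)))
  Bx <- dct_basis(d[1], K[1]); By <- dct_basis(d[2], K[2]); Bz <- dct_basis(d[3], K[3])
  nk <- prod(K)
  kxy <- K[1] * K[2]
  Bxy <- matrix(0, d[1] * d[2], kxy)   # rows i-fastest, matching array order
  for (ky in seq_len(K[2]))
    Bxy[, (ky - 1) * K[1] + seq_len(K[1])] <-
      kronecker(By[, ky, drop = FALSE], Bx)
  L <- d * sp
  wk <- outer(outer((pi * (0:(K[1] - 1)) / L[1])^2,
                    (pi * (0:(K[2] - 1)) / L[2])^2, `+`),
              (pi * (0:(K[3] - 1)) / L[3])^2, `+`)
  Rdiag <- rep(as.vector(wk), 3)

  idx <- grid_indices(d)
  wld <- cbind(idx, 1) %*% t(fixed$affine)
  MM <- solve(moving$affine) %*% M
  Mlin <- MM[1:3, 1:3]

  cc <- rep(0, 3 * nk)
  traces <- list()
  dm <- dim(moving$data)
  sp_m <- voxel_spacing(moving)
  for (ps in presmooth) {
    fn <- if (ps > 0) smooth3d(fn0, ps, sp) else fn0
    mn <- if (ps > 0) smooth3d(mn0, ps, sp_m) else mn0
    fv <- as.vector(fn)

    # freeze, per stage, the voxels whose sample points fall inside the
    # moving FOV (2-voxel margin): out-of-field fill must not drive SSD
    {
      ux0 <- dct_synth(array(cc[seq_len(nk)], K), Bx, By, Bz, d)
      uy0 <- dct_synth(array(cc[nk + seq_len(nk)], K), Bx, By, Bz, d)
      uz0 <- dct_synth(array(cc[2 * nk + seq_len(nk)], K), Bx, By, Bz, d)
      p0 <- cbind(wld[, 1] + as.vector(ux0), wld[, 2] + as.vector(uy0),
                  wld[, 3] + as.vector(uz0), 1) %*% t(MM)
      inside <- p0[, 1] >= 2 & p0[, 1] <= dm[1] - 3 &
                p0[, 2] >= 2 & p0[, 2] <= dm[2] - 3 &
                p0[, 3] >= 2 & p0[, 3] <= dm[3] - 3
      wv <- as.double(msel & array(inside, d))
      if (!any(wv > 0)) stop("registration mask does not overlap moving FOV")
    }

    eval_state <- function(p) {
      Cx <- array(p[seq_len(nk)], K)
      Cy <- array(p[nk + seq_len(nk)], K)
      Cz <- array(p[2 * nk + seq_len(nk)], K)
      ux <- dct_synth(Cx, Bx, By, Bz, d)
      uy <- dct_synth(Cy, Bx, By, Bz, d)
      uz <- dct_synth(Cz, Bx, By, Bz, d)
      pts <- cbind(wld[, 1] + as.vector(ux), wld[, 2] + as.vector(uy),
                   wld[, 3] + as.vector(uz), 1) %*% t(MM)
      sg <- cpp_sample_cubic_grad(as.double(mn), dm, pts[, 1:3, drop = FALSE],
                                  fill_n)
      r <- (sg[, 1] - fv) * wv
      list(sg = sg, r = r, ssd = sum(r * r),
           obj = sum(r * r) + lambda * sum(Rdiag * p * p),
           u = list(ux = ux, uy = uy, uz = uz))
    }

    mu <- 1e-3
    st <- eval_state(cc)
    if (!is.finite(st$obj)) stop("non-finite objective at stage start")
    trace <- st$obj
    H <- NULL
    for (it in seq_len(iters)) {
      sg <- st$sg; r <- st$r
      sx <- (Mlin[1, 1] * sg[, 2] + Mlin[2, 1] * sg[, 3] + Mlin[3, 1] * sg[, 4]) * wv
      sy <- (Mlin[1, 2] * sg[, 2] + Mlin[2, 2] * sg[, 3] + Mlin[3, 2] * sg[, 4]) * wv
      sz <- (Mlin[1, 3] * sg[, 2] + Mlin[2, 3] * sg[, 3] + Mlin[3, 3] * sg[, 4]) * wv
      if (!all(is.finite(sx)) || !all(is.finite(sy)) || !all(is.finite(sz)))
        stop("non-finite update at iteration ", it)
      g <- c(as.vector(dct_analyze(array(r * sx, d), Bx, By, Bz, d)),
             as.vector(dct_analyze(array(r * sy, d), Bx, By, Bz, d)),
             as.vector(dct_analyze(array(r * sz, d), Bx, By, Bz, d))) +
        lambda * Rdiag * cc
      # Gauss-Newton normal matrix, refreshed every third iteration
      if (is.null(H) || (it %% 3) == 1) {
        s_list <- list(sx, sy, sz)
        H <- matrix(0, 3 * nk, 3 * nk)
        for (a in 1:3) for (b in a:3) {
          W <- array(s_list[[a]] * s_list[[b]], d)
          Hab <- matrix(0, nk, nk)
          for (s in seq_len(d[3])) {
            ws <- as.vector(W[, , s])
            if (!any(ws != 0)) next
            Ts <- crossprod(Bxy, ws * Bxy)
            Hab <- Hab + kronecker(tcrossprod(Bz[s, ]), Ts)
          }
          ia <- (a - 1) * nk + seq_len(nk)
          ib <- (b - 1) * nk + seq_len(nk)
          H[ia, ib] <- Hab
          if (a != b) H[ib, ia] <- t(Hab)
        }
      }
      improved <- FALSE
      for (tries in 1:6) {
        A <- H + diag(lambda * Rdiag + mu * (diag(H) + 1e-8))
        delta <- tryCatch(solve(A, -g), error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- eval_state(cc + delta)
          if (is.finite(cand$obj) && cand$obj < st$obj) {
            cc <- cc + delta
            st <- cand
            mu <- max(mu / 5, 1e-8)
            improved <- TRUE
            break
          }
        }
        mu <- mu * 10
      }
      if (!improved) break
      trace <- c(trace, st$obj)
    }
    traces[[length(traces) + 1]] <- trace
  }
  structure(list(field = st$u, ssd_trace = traces[[length(traces)]],
                 obj_traces = traces, coefficients = cc, K = K,
                 lambda = lambda, presmooth = presmooth,
                 ref_affine = fixed$affine, ref_dim = d),
            class = "deformation_field")
}

#' Normalize one subject's CT and dose to template space
#'
#' Runs the full synchronized pipeline: crop -> rigid -> affine ->
#' nonlinear registration of the CT to the template, then applies the
#' identical transform chain to both CT and dose in a single resampling
#' pass each.
#'
#' @param ct subject CT `volume` (HU).
#' @param dose subject dose `volume` (Gy), co-registered with the CT.
#' @param template template CT `volume` (defines the output grid).
#' @param mask optional template-space `mask_volume` for the nonlinear
#'   stage (defaults to the template head support).
#' @param nonlinear_iters Gauss-Newton iterations per stage.
#' @return list with `ct_mni`, `dose_mni`, `chain` (the shared
#'   `transform_chain`) and `qc` (SSD before/after, max displacement in mm).
#' @export
normalize_subject <- function(ct, dose, template, mask = NULL,
                              nonlinear_iters = 10) {
  cr <- crop_head(ct, dose)
  rig <- register_rigid(cr$ct, template)
  aff <- register_affine(cr$ct, template, init = rig)
  nl <- register_nonlinear(cr$ct, template, init = aff,
                           iters = nonlinear_iters, mask = mask)
  chain <- new_chain(rigid = rig$matrix, affine = aff$matrix,
                     field = nl$field, reference = template)
  ct_mni <- apply_chain(chain, cr$ct, template, "cubic", fill = -1024)
  ct_mni$space <- "template"
  dose_mni <- apply_chain(chain, cr$dose, template, "linear", fill = 0)
  dose_mni$space <- "template"
  ssd0 <- ssd(resample_to(cr$ct, template, fill = -1024), template, mask)
  ssd1 <- ssd(ct_mni, template, mask)
  disp <- sqrt(nl$field$ux^2 + nl$field$uy^2 + nl$field$uz^2)
  list(ct_mni = ct_mni, dose_mni = dose_mni, chain = chain,
       qc = list(ssd_before = ssd0, ssd_after = ssd1,
                 max_displacement_mm = max(disp),
                 rigid_converged = rig$converged,
                 affine_converged = aff$converged))
}

#' Save a transform chain as JSON + NIfTI displacement volumes
#'
#' @param chain a `transform_chain`.
#' @param path output JSON path; the displacement field (if any) is
#'   written next to it as three NIfTI volumes.
#' @export
write_chain <- function(chain, path) {
  field_paths <- NULL
  if (!is.null(chain$field)) {
    base <- sub("\\.json$", "", path)
    field_paths <- paste0(base, "_disp_", c("x", "y", "z"), ".nii.gz")
    A <- chain$ref_affine
    write_nifti(chain$field$ux, A, field_paths[1])
    write_nifti(chain$field$uy, A, field_paths[2])
    write_nifti(chain$field$uz, A, field_paths[3])
  }
  jsonlite::write_json(list(rigid = chain$rigid, affine = chain$affine,
                            ref_affine = chain$ref_affine,
                            ref_dim = chain$ref_dim,
                            field_paths = field_paths),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a transform chain written by [write_chain()]
#' @param path JSON path.
#' @return a `transform_chain`.
#' @export
read_chain <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  field <- NULL
  if (!is.null(j$field_paths) && length(j$field_paths) == 3) {
    f <- lapply(j$field_paths, function(p) read_nifti(p)$data)
    field <- list(ux = f[[1]], uy = f[[2]], uz = f[[3]])
  }
  ch <- new_chain(rigid = if (!is.null(j$rigid)) matrix(unlist(j$rigid), 4, 4, byrow = FALSE),
                  affine = if (!is.null(j$affine)) matrix(unlist(j$affine), 4, 4, byrow = FALSE),
                  field = field)
  ch$ref_affine <- if (!is.null(j$ref_affine)) matrix(unlist(j$ref_affine), 4, 4)
  ch$ref_dim <- if (!is.null(j$ref_dim)) as.integer(unlist(j$ref_dim))
  ch
}
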
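# Voxel-wise two-sample GLM with covariates, TFCE, and sign-aware
# permutation max-TFCE family-wise-error inference (Freedman-Lane
# residual permutation).

#' Build the two-sample design matrix
#'
#' Columns: intercept, group indicator (IMRT = 1, VMAT = 0), then
#' covariates (age mean-centred, gender coded male = 1). The contrast
#' selects the group column, so positive t means IMRT > VMAT.
#'
#' @param cohort data.frame with a `technique` column (values IMRT/VMAT)
#'   and any covariate columns.
#' @param covars character vector among `"age"`, `"gender"` (or empty).
#' @return a `design_matrix`: list with `X`, `contrast`, `group`.
#' @export
design_matrix <- function(cohort, covars = c("age", "gender")) {
  g <- as.integer(cohort$technique == "IMRT")
  if (all(g == 1) || all(g == 0)) stop("need two nonempty groups")
  X <- cbind(intercept = 1, group = g)
  for (cv in covars) {
    col <- switch(cv,
      age = cohort$age - mean(cohort$age),
      gender = as.integer(cohort$gender == "male"),
      stop("unknown covariate: ", cv))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  ctr <- as.numeric(colnames(X) == "group")
  structure(list(X = X, contrast = ctr, group = g), class = "design_matrix")
}

# stack template-space volumes into an n x V matrix over mask voxels
stack_volumes <- function(vols, mask) {
  sel <- mask$data > 0
  t(vapply(vols, function(v) {
    if (!same_grid(v, mask)) stop("grid mismatch between volume and mask")
    v$data[sel]
  }, numeric(sum(sel))))
}

# OLS contrast t-statistics for every column of Y (n x V)
glm_t <- function(Y, X, contrast) {
  n <- nrow(X); p <- qr(X)$rank
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)
  B <- P %*% Y
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  cb <- drop(contrast %*% B)
  cvc <- drop(t(contrast) %*% XtXi %*% contrast)
  se <- sqrt(sigma2 * cvc)
  t <- ifelse(se > sqrt(.Machine$double.eps) * max(1, mean(abs(cb))),
              cb / se, 0)
  list(t = t, df = df, zero_var = se <= sqrt(.Machine$double.eps))
}

#' Voxel-wise GLM t-map for the group contrast
#'
#' Ordinary least squares at every brain-mask voxel;
#' `t = c'b / sqrt(sigma2 c'(X'X)^-1 c)` with `df = n - rank(X)`.
#' Voxels with zero residual variance get t = 0.
#'
#' @param data list of template-space dose `volume`s (one per design row,
#'   same order) or an n x V matrix over mask voxels.
#' @param design a [design_matrix()].
#' @param mask brain `mask_volume`.
#' @return a t-map `volume` with attributes `df` and `zero_var`.
#' @export
fit_glm_tmap <- function(data, design, mask) {
  Y <- if (is.matrix(data)) data else stack_volumes(data, mask)
  if (nrow(Y) != nrow(design$X)) stop("data rows do not match design rows")
  if (nrow(Y) <= ncol(design$X) + 1)
    stop("need more subjects than design columns + 1")
  ft <- glm_t(Y, design$X, design$contrast)
  out <- array(0, dim(mask$data))
  out[mask$data > 0] <- ft$t
  v <- volume(out, mask$affine, mask$space)
  attr(v, "df") <- ft$df
  attr(v, "zero_var") <- ft$zero_var
  v
}

#' TFCE parameters
#'
#' @param E extent exponent (volumetric default 0.5).
#' @param H height exponent (volumetric default 2).
#' @param dh threshold step: `"auto"` uses `max(stat)/100`, or a number.
#' @param connectivity 6, 18 or 26 (default 26).
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = "auto", connectivity = 26) {
  stopifnot(E > 0, H > 0, connectivity %in% c(6, 18, 26))
  structure(list(E = E, H = H, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a non-negative statistic map
#'
#' `TFCE(v) = sum_h e_v(h)^E h^H dh` over thresholds `h = dh, 2dh, ...`,
#' where `e_v(h)` is the voxel count of the connected component
#' containing `v` at threshold `h`. Zero where the input is <= 0.
#'
#' @param stat non-negative statistic `volume` (callers pass `max(t, 0)`
#'   or `max(-t, 0)`).
#' @param mask `mask_volume`; voxels outside are ignored.
#' @param params a [tfce_params()].
#' @param dh_override fixed dh (used to share the threshold grid between
#'   observed and permuted maps).
#' @return a TFCE `volume`; attribute `dh` records the step used.
#' @export
tfce_transform <- function(stat, mask = NULL, params = tfce_params(),
                           dh_override = NULL) {
  arr <- if (inherits(stat, "volume")) stat$data else stat
  if (min(arr) < 0) stop("TFCE input must be non-negative")
  if (!is.null(mask)) arr[mask$data == 0] <- 0
  hmax <- max(arr)
  dh <- if (!is.null(dh_override)) dh_override
        else if (identical(params$dh, "auto")) hmax / 100 else params$dh
  d <- dim(arr)
  if (hmax <= 0 || dh <= 0) {
    out <- array(0, d)
  } else {
    nsteps <- max(1L, as.integer(ceiling(hmax / dh)))
    out <- array(cpp_tfce(as.double(arr), d, params$E, params$H, dh, nsteps,
                          params$connectivity), d)
  }
  v <- if (inherits(stat, "volume")) volume(out, stat$affine, stat$space)
       else out
  attr(v, "dh") <- dh
  v
}

#' Permutation max-TFCE FWE inference for the two-sample GLM
#'
#' Observed t-map -> positive/negative TFCE maps; the null distribution
#' of the image-wide maximum TFCE is built by Freedman-Lane residual
#' permutation (covariates respected): fit the reduced (covariate-only)
#' model, permute its residuals with a seeded RNG, refit the full model
#' and record the mask-wide max TFCE per tail. The identity permutation
#' is always included, giving `fwe_p = (1 + #\{null >= tfce\}) / (1 + n_perm)`
#' with minimum attainable p of `1/(1 + n_perm)`.
#'
#' @param data list of template-space dose `volume`s or n x V matrix.
#' @param design a [design_matrix()].
#' @param mask brain `mask_volume`.
#' @param params a [tfce_params()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @param alpha significance level.
#' @param tails `"combined"` (default) compares each tail's TFCE against
#'   the permutation distribution of the maximum over both tails, giving
#'   family-wise control at `alpha` across the two directions jointly;
#'   `"separate"` tests each tail against its own max-null at `alpha`
#'   each (a more liberal convention).
#' @return a `stat_result`: t map, TFCE and FWE-p maps and significance
#'   masks per tail, null maxima vectors, and run metadata.
#' @export
permutation_fwe <- function(data, design, mask, params = tfce_params(),
                            n_perm = 5000, seed = 1, alpha = 0.05,
                            tails = c("combined", "separate")) {
  tails <- match.arg(tails)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (min(table(design$group)) < 3)
    stop("refusing to run with a group smaller than 3 subjects")
  Y <- if (is.matrix(data)) data else stack_volumes(data, mask)
  X <- design$X
  ctr <- design$contrast
  n <- nrow(Y)
  msel <- mask$data > 0
  d <- dim(mask$data)

  embed <- function(vals) { a <- array(0, d); a[msel] <- vals; a }
  obs <- glm_t(Y, X, ctr)
  t_arr <- embed(obs$t)
  if (tails == "combined") {
    # one dh grid for both tails so their TFCE values are commensurable
    dh_common <- max(max(pmax(t_arr, 0)), max(pmax(-t_arr, 0))) / 100
    if (dh_common <= 0) dh_common <- NULL
    tf_pos <- tfce_transform(pmax(t_arr, 0), params = params,
                             dh_override = dh_common)
    tf_neg <- tfce_transform(pmax(-t_arr, 0), params = params,
                             dh_override = dh_common)
    dh_pos <- dh_neg <- attr(tf_pos, "dh")
  } else {
    tf_pos <- tfce_transform(pmax(t_arr, 0), params = params)
    tf_neg <- tfce_transform(pmax(-t_arr, 0), params = params)
    dh_pos <- attr(tf_pos, "dh")
    dh_neg <- attr(tf_neg, "dh")
  }

  # Freedman-Lane: reduced model = all nuisance columns (contrast == 0)
  Z <- X[, ctr == 0, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Rz <- Y - Hz %*% Y
  fitted_z <- Y - Rz

  null_pos <- numeric(n_perm)
  null_neg <- numeric(n_perm)
  with_seed(seed, {
    for (j in seq_len(n_perm)) {
      pm <- if (j == 1) seq_len(n) else sample.int(n)
      Yp <- fitted_z + Rz[pm, , drop = FALSE]
      tp <- glm_t(Yp, X, ctr)$t
      tp_arr <- embed(tp)
      mx_p <- tfce_transform(pmax(tp_arr, 0), params = params,
                             dh_override = dh_pos)
      mx_n <- tfce_transform(pmax(-tp_arr, 0), params = params,
                             dh_override = dh_neg)
      null_pos[j] <- max(mx_p)
      null_neg[j] <- max(mx_n)
    }
  })

  # p-values against sorted null maxima: p = (1 + #{null >= tfce})/(1 + n_perm)
  pmap_fast <- function(tf, null_max) {
    v <- tf[msel]
    srt <- sort(null_max)
    ge <- length(srt) - findInterval(v, srt, left.open = TRUE)
    embed((1 + ge) / (1 + n_perm))
  }
  if (tails == "combined") {
    null_joint <- pmax(null_pos, null_neg)
    fwe_pos <- pmap_fast(tf_pos, null_joint)
    fwe_neg <- pmap_fast(tf_neg, null_joint)
  } else {
    fwe_pos <- pmap_fast(tf_pos, null_pos)
    fwe_neg <- pmap_fast(tf_neg, null_neg)
  }
  fwe_pos[!msel] <- 1
  fwe_neg[!msel] <- 1
  sig_pos <- msel & fwe_pos <= alpha & t_arr > 0
  sig_neg <- msel & fwe_neg <= alpha & t_arr < 0

  A <- mask$affine
  structure(list(
    t_map = {v <- volume(t_arr, A, mask$space); attr(v, "df") <- obs$df; v},
    tfce_pos = volume(tf_pos, A, mask$space),
    tfce_neg = volume(tf_neg, A, mask$space),
    fwe_p_pos = volume(fwe_pos, A, mask$space),
    fwe_p_neg = volume(fwe_neg, A, mask$space),
    sig_pos = mask_volume(sig_pos, A, mask$space),
    sig_neg = mask_volume(sig_neg, A, mask$space),
    null_max_pos = null_pos, null_max_neg = null_neg,
    n_perm = n_perm, seed = seed, alpha = alpha, params = params,
    tails = tails
  ), class = "stat_result")
}

#' Summarize a permutation result per tail
#'
#' @param res a `stat_result` from [permutation_fwe()].
#' @return data.frame with one row per tail: significant voxel count,
#'   peak |t| inside the significance mask, and its world coordinate
#'   (NA when the mask is empty).
#' @export
summarize_result <- function(res) {
  one <- function(tail) {
    sig <- if (tail == "pos") res$sig_pos else res$sig_neg
    tv <- res$t_map$data
    n <- sum(sig$data > 0)
    if (n == 0)
      return(data.frame(tail = tail, n_sig = 0, peak_t = NA_real_,
                        x = NA_real_, y = NA_real_, z = NA_real_))
    sel <- sig$data > 0
    av <- abs(tv); av[!sel] <- -Inf
    i <- which.max(av)   # first max in (k,j,i)-ascending scan order
    ijk <- arrayInd(i, dim(tv)) - 1L
    w <- voxel_to_world(as.integer(ijk), res$t_map$affine)
    data.frame(tail = tail, n_sig = n, peak_t = tv[i],
               x = w[1], y = w[2], z = w[3])
  }
  rbind(one("pos"), one("neg"))
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> n_perm=%d, alpha=%.3g (%s tails), seed=%d\n",
              x$n_perm, x$alpha, x$tails, x$seed))
  s <- summarize_result(x)
  cat(sprintf("  IMRT > VMAT: %d significant voxels\n", s$n_sig[1]))
  cat(sprintf("  IMRT < VMAT: %d significant voxels\n", s$n_sig[2]))
  invisible(x)
}
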
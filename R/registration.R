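#' Homogeneous 3D affine transform on physical (nm) coordinates
#'
#' @param m 4x4 matrix with last row (0,0,0,1).
#' @param provenance Free-text note (e.g. "estimated", "composed").
#' @return Object of class `affine3d`.
#' @export
affine3d <- function(m, provenance = "constructed") {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(4L, 4L)))
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last row must be (0,0,0,1)", call. = FALSE)
  if (abs(det(m[1:3, 1:3])) < 1e-12)
    stop("transform is not invertible", call. = FALSE)
  structure(list(m = m, provenance = provenance), class = "affine3d")
}

#' Build a similarity transform s*R*x + t
#' @param scale Isotropic scale (> 0).
#' @param rotation 3x3 rotation matrix.
#' @param translation 3-vector (nm).
#' @return An [affine3d].
#' @export
affine_similarity <- function(scale = 1, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  check_scalar(scale, "scale", positive = TRUE)
  m <- diag(4)
  m[1:3, 1:3] <- scale * rotation
  m[1:3, 4] <- translation
  affine3d(m, "constructed similarity")
}

#' Apply an affine transform to points
#' @param t An [affine3d].
#' @param pts n x 3 matrix (nm).
#' @return n x 3 matrix (nm).
#' @export
affine_apply <- function(t, pts) {
  stopifnot(inherits(t, "affine3d"))
  pts <- rbind(pts)
  sweep(pts %*% t(t$m[1:3, 1:3]), 2, t$m[1:3, 4], "+")
}

#' Invert an affine transform
#' @param t An [affine3d].
#' @return An [affine3d].
#' @export
affine_invert <- function(t) {
  stopifnot(inherits(t, "affine3d"))
  A <- t$m[1:3, 1:3]; b <- t$m[1:3, 4]
  Ai <- solve(A)
  m <- diag(4); m[1:3, 1:3] <- Ai; m[1:3, 4] <- -Ai %*% b
  affine3d(m, paste("inverse of", t$provenance))
}

#' Compose two affine transforms (a applied after b)
#' @param a,b [affine3d] objects; result maps x to a(b(x)).
#' @return An [affine3d].
#' @export
affine_compose <- function(a, b) {
  affine3d(a$m %*% b$m, "composed")
}

#' Decompose the linear block of a similarity transform
#' @param t An [affine3d].
#' @return List with `scale`, `rotation`, `translation`, and
#'   `orthonormality` (the deviation `max|R'R - I|` of the rotation part).
#' @export
affine_decompose <- function(t) {
  stopifnot(inherits(t, "affine3d"))
  A <- t$m[1:3, 1:3]
  s <- det(A)^(1 / 3)
  R <- A / s
  list(scale = s, rotation = R, translation = t$m[1:3, 4],
       orthonormality = max(abs(crossprod(R) - diag(3))))
}

#' Block-matching configuration
#'
#' Defaults follow the package's reference pipeline: 32^3-voxel blocks on a
#' 16-voxel stride, +/-8 voxel search, normalized cross-correlation with a
#' 0.3 retention cutoff, at most 5 iterations, 0.5 nm convergence tolerance.
#'
#' @param block Block edge in voxels (>= 8).
#' @param stride Stride between block origins in voxels.
#' @param search Search radius in voxels.
#' @param min_correlation Minimum NCC for a block match to be retained.
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the RMS block residual (nm).
#' @return Object of class `block_match_config`.
#' @export
block_match_config <- function(block = 32L, stride = 16L, search = 8L,
                               min_correlation = 0.3, max_iter = 5L,
                               tol = 0.5) {
  if (block < 8) stop("'block' must be >= 8 voxels per axis", call. = FALSE)
  if (min_correlation < 0 || min_correlation > 1)
    stop("'min_correlation' must be in [0, 1]", call. = FALSE)
  structure(list(block = as.integer(block), stride = as.integer(stride),
                 search = as.integer(search),
                 min_correlation = as.numeric(min_correlation),
                 max_iter = as.integer(max_iter), tol = as.numeric(tol)),
            class = "block_match_config")
}

# 3D summed-area window sums: sum over windows of size b starting at each
# origin; returns array of dim (d - b + 1)
box_sums3 <- function(a, b) {
  s <- apply(a, c(2, 3), cumsum)                   # along axis 1
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))  # along axis 2
  s <- aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))  # along axis 3
  d <- dim(a)
  pad <- array(0, d + 1L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- s
  i1 <- (b[1] + 1):(d[1] + 1); i0 <- 1:(d[1] - b[1] + 1)
  j1 <- (b[2] + 1):(d[2] + 1); j0 <- 1:(d[2] - b[2] + 1)
  k1 <- (b[3] + 1):(d[3] + 1); k0 <- 1:(d[3] - b[3] + 1)
  pad[i1, j1, k1] - pad[i0, j1, k1] - pad[i1, j0, k1] - pad[i1, j1, k0] +
    pad[i0, j0, k1] + pad[i0, j1, k0] + pad[i1, j0, k0] - pad[i0, j0, k0]
}

# Normalized cross-correlation of template tpl over all placements in region;
# returns list(ncc = array, dim = region dim - tpl dim + 1)
ncc_map3 <- function(tpl, region) {
  bt <- dim(tpl); br <- dim(region)
  n <- prod(bt)
  tm <- tpl - mean(tpl)
  sst <- sum(tm^2)
  if (sst <= 0) return(NULL)
  pad <- array(0, br)
  pad[seq_len(bt[1]), seq_len(bt[2]), seq_len(bt[3])] <- tm
  # cross-correlation via FFT: sum_t region(t + s) * tm(t)
  cc <- Re(stats::fft(stats::fft(region) * Conj(stats::fft(pad)),
                      inverse = TRUE)) / prod(br)
  vd <- br - bt + 1L
  cc <- cc[seq_len(vd[1]), seq_len(vd[2]), seq_len(vd[3]), drop = FALSE]
  s1 <- box_sums3(region, bt)
  s2 <- box_sums3(region^2, bt)
  varr <- pmax(s2 - s1^2 / n, 0)
  den <- sqrt(varr * sst)
  ncc <- cc / pmax(den, 1e-12)
  ncc[den <= 1e-12] <- 0
  ncc
}

# 3-point parabolic sub-voxel refinement along one axis
parabolic_offset <- function(ym1, y0, yp1) {
  den <- (ym1 - 2 * y0 + yp1)
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(min(off, 0.5), -0.5)
}

# One pass of block matching between two arrays on a common grid.
# Returns correspondences: fixed-block centres (voxel index) and matched
# shifts (fractional voxels), with NCC values.
match_blocks <- function(fixed, moving, cfg) {
  d <- dim(fixed)
  B <- rep(cfg$block, 3L)
  R <- cfg$search
  starts <- lapply(1:3, function(a) {
    if (d[a] < B[a]) return(integer(0))
    unique(pmin(seq(1L, d[a] - B[a] + 1L, by = cfg$stride), d[a] - B[a] + 1L))
  })
  cen <- list(); shifts <- list(); corr <- c()
  for (i0 in starts[[1]]) for (j0 in starts[[2]]) for (k0 in starts[[3]]) {
    tpl <- fixed[i0:(i0 + B[1] - 1), j0:(j0 + B[2] - 1), k0:(k0 + B[3] - 1)]
    if (stats::sd(tpl) < 1e-9) next   # flat block: nothing to match
    r0 <- c(i0, j0, k0) - R
    r1 <- c(i0, j0, k0) + B - 1L + R
    # clipped search windows bias matches toward zero shift: skip them
    if (any(r0 < 1L) || any(r1 > d)) next
    region <- moving[r0[1]:r1[1], r0[2]:r1[2], r0[3]:r1[3]]
    ncc <- ncc_map3(tpl, region)
    if (is.null(ncc)) next
    best <- which.max(ncc)
    bi <- arrayInd(best, dim(ncc))
    v <- ncc[best]
    if (v < cfg$min_correlation) next
    sub <- numeric(3)
    for (a in 1:3) {
      if (bi[a] > 1 && bi[a] < dim(ncc)[a]) {
        idx_m <- bi; idx_m[a] <- bi[a] - 1L
        idx_p <- bi; idx_p[a] <- bi[a] + 1L
        sub[a] <- parabolic_offset(ncc[matrix(idx_m, 1)], v,
                                   ncc[matrix(idx_p, 1)])
      }
    }
    shift <- (r0 + bi - 1L) - c(i0, j0, k0) + sub
    cen[[length(cen) + 1L]] <- c(i0, j0, k0) + (B - 1) / 2
    shifts[[length(shifts) + 1L]] <- shift
    corr <- c(corr, v)
  }
  list(centers = do.call(rbind, cen), shifts = do.call(rbind, shifts),
       corr = corr)
}

# Umeyama closed-form similarity fit: minimises sum |s R x + t - y|^2
fit_similarity <- function(X, Y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- crossprod(Yc, Xc) / n            # (1/n) sum (y-my)(x-mx)^T
  sv <- svd(H)
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  varx <- sum(Xc^2) / n
  s <- sum(diag(diag(sv$d) %*% S)) / varx
  t <- my - s * as.vector(R %*% mx)
  affine_similarity(s, R, t)
}

#' Estimate the pre-to-post similarity transform by iterative block matching
#'
#' Registers a pre-expansion volume onto a post-expansion volume of the same
#' region. The pre volume is first scaled by `init_scale` (typically the
#' macroscopic expansion factor) and shifted so the intensity centroids
#' coincide; each iteration then resamples the pre volume through the current
#' transform, matches blocks of the post volume against it by normalized
#' cross-correlation with sub-voxel refinement, rejects outliers at 2.5x MAD,
#' and updates the transform with a closed-form least-squares similarity fit.
#' Only a similarity (isotropic scale, rotation, translation) is fitted, so
#' residual deformation is preserved for the distortion analysis rather than
#' absorbed into the registration.
#'
#' @param pre,post [image_volume]s of the same region before / after
#'   expansion.
#' @param init_scale Initial guess for the linear expansion factor (> 0).
#' @param cfg A [block_match_config].
#' @return List with `transform` (an [affine3d] mapping pre physical nm to
#'   post physical nm) and `diagnostics` (per-iteration RMS residual in nm,
#'   retained block count, block correlations of the final pass).
#' @export
estimate_transform <- function(pre, post, init_scale = 1,
                               cfg = block_match_config()) {
  stopifnot(inherits(pre, "image_volume"), inherits(post, "image_volume"),
            inherits(cfg, "block_match_config"))
  check_scalar(init_scale, "init_scale", positive = TRUE)
  # initialise: scale, then match intensity centroids
  cpre <- intensity_centroid(pre)
  cpost <- intensity_centroid(post)
  t0 <- affine_similarity(init_scale, diag(3), cpost - init_scale * cpre)
  tr <- t0
  hist_res <- c(); hist_n <- c(); last <- NULL
  best_tr <- tr; best_res <- Inf
  for (it in seq_len(cfg$max_iter)) {
    moving <- resample_to_reference(pre, tr, post)
    mm <- match_blocks(post$data, moving$data, cfg)
    if (is.null(mm$centers) || nrow(mm$centers) < 4)
      stop(sprintf(
        "only %d block correspondence(s) retained: cannot fit similarity transform",
        if (is.null(mm$centers)) 0L else nrow(mm$centers)), call. = FALSE)
    shift_nm <- sweep(mm$shifts, 2, post$voxel, "*")
    res_nm <- sqrt(mean(rowSums(shift_nm^2)))
    if (res_nm >= best_res) break    # keep the best (monotone residual record)
    best_res <- res_nm; best_tr <- tr
    hist_res <- c(hist_res, res_nm)
    hist_n <- c(hist_n, nrow(mm$centers))
    last <- mm
    if (res_nm < cfg$tol) break
    # correspondence: moving content at centre+shift appears at centre in post
    Yfix <- index_to_phys(post, mm$centers)
    Xmov <- index_to_phys(post, mm$centers + mm$shifts)
    # one round of MAD outlier rejection on the shift magnitudes
    r <- row_norms(sweep(shift_nm, 2, colMeans(shift_nm)))
    cutoff <- 2.5 * max(mad_scale(r), 1e-9)
    keep <- r <= cutoff
    if (sum(keep) >= 4) { Yfix <- Yfix[keep, , drop = FALSE]
      Xmov <- Xmov[keep, , drop = FALSE] }
    upd <- fit_similarity(Xmov, Yfix)
    tr <- affine_compose(upd, tr)
  }
  tr <- best_tr
  tr$provenance <- "estimated (iterative block matching)"
  list(transform = tr,
       diagnostics = list(residual_nm = hist_res, n_blocks = hist_n,
                          correlations = last$corr,
                          final_residual_nm = best_res))
}

intensity_centroid <- function(vol) {
  d <- dim(vol$data)
  w <- pmax(vol$data, 0)
  tw <- sum(w)
  if (tw <= 0) return(vol$origin + d * vol$voxel / 2)
  xs <- voxel_centers(vol, 1); ys <- voxel_centers(vol, 2)
  zs <- voxel_centers(vol, 3)
  c(sum(w * array(xs, d)) / tw,
    sum(w * array(rep(ys, each = d[1]), d)) / tw,
    sum(w * array(rep(zs, each = d[1] * d[2]), d)) / tw)
}

#' Resample a volume onto a reference grid through a transform
#'
#' Pulls `vol` onto the grid of `reference` using trilinear interpolation:
#' each reference voxel centre y is mapped back to `t^-1(y)` in `vol`'s
#' physical frame. Out-of-domain voxels are 0 and flagged in a validity mask
#' stored in `meta$valid`.
#'
#' @param vol Input [image_volume].
#' @param t An [affine3d] mapping `vol` physical coordinates to reference
#'   physical coordinates.
#' @param reference An [image_volume] (only its grid is used) or a
#'   `list(dims, voxel, origin)`.
#' @return An [image_volume] on the reference grid.
#' @export
resample_to_reference <- function(vol, t, reference) {
  stopifnot(inherits(vol, "image_volume"), inherits(t, "affine3d"))
  if (inherits(reference, "image_volume")) {
    grid <- list(dims = dim(reference$data), voxel = reference$voxel,
                 origin = reference$origin)
  } else grid <- reference
  ctrs <- grid_centers(grid)
  src <- affine_apply(affine_invert(t), ctrs)
  ext <- dim(vol$data) * vol$voxel
  rel <- sweep(src, 2, vol$origin, "-")
  valid <- rel[, 1] >= 0 & rel[, 1] <= ext[1] &
    rel[, 2] >= 0 & rel[, 2] <= ext[2] &
    rel[, 3] >= 0 & rel[, 3] <= ext[3]
  vals <- interp_volume(vol, src, outside = 0)
  image_volume(array(vals, grid$dims), grid$voxel, channel = vol$channel,
               origin = grid$origin %||% c(0, 0, 0),
               meta = c(vol$meta,
                        list(valid = array(valid, grid$dims),
                             resampled_through = t$m)))
}
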
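# Dense 2D displacement estimation by local polynomial expansion
# (Farneback-style): each neighbourhood is approximated by a quadratic
# polynomial f(x) ~ x'Ax + b'x + c under a Gaussian applicability; the
# displacement between two expansions follows from the change in the linear
# term, accumulated over a Gaussian window, iterated with warping and a
# coarse-to-fine pyramid.

# separable cross-correlation with 1D kernels along rows (dim 1) then
# columns (dim 2); replicated boundary
xcorr_sep <- function(img, kx, ky) {
  # truncate kernels that exceed the image (coarse pyramid levels)
  trim <- function(k, n) {
    half <- (length(k) - 1L) %/% 2L
    maxh <- (n - 1L) %/% 2L
    if (half > maxh) k[(half - maxh + 1L):(length(k) - (half - maxh))] else k
  }
  kx <- trim(kx, nrow(img)); ky <- trim(ky, ncol(img))
  out <- EBImage::filter2(img, matrix(rev(kx), ncol = 1), boundary = "replicate")
  EBImage::filter2(out, matrix(rev(ky), nrow = 1), boundary = "replicate")
}

gauss_kernel <- function(sigma, n = ceiling(3 * sigma)) {
  x <- (-n):n
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur2 <- function(img, sigma) {
  k <- gauss_kernel(sigma)
  xcorr_sep(img, k, k)
}

# bilinear sampling of a matrix at fractional (1-based) coordinates, clamped
interp2 <- function(m, xi, yi) {
  d <- dim(m)
  xi <- as.vector(xi); yi <- as.vector(yi)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  fx <- xi - x0; fy <- yi - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

# quadratic polynomial expansion of an image; returns pixelwise coefficient
# fields A11, A12, A22 (quadratic), b1, b2 (linear)
poly_expansion <- function(f, n = 3L, sigma = 1.5) {
  x <- (-n):n
  w <- exp(-x^2 / (2 * sigma^2))
  m00 <- xcorr_sep(f, w, w)
  m10 <- xcorr_sep(f, x * w, w)
  m01 <- xcorr_sep(f, w, x * w)
  m20 <- xcorr_sep(f, x^2 * w, w)
  m02 <- xcorr_sep(f, w, x^2 * w)
  m11 <- xcorr_sep(f, x * w, x * w)
  W0 <- sum(w); W2 <- sum(x^2 * w); W4 <- sum(x^4 * w)
  G <- matrix(0, 6, 6)   # basis order: 1, u, v, u^2, v^2, uv
  G[1, 1] <- W0^2
  G[1, 4] <- G[4, 1] <- W2 * W0
  G[1, 5] <- G[5, 1] <- W0 * W2
  G[2, 2] <- W2 * W0
  G[3, 3] <- W0 * W2
  G[4, 4] <- W4 * W0
  G[5, 5] <- W0 * W4
  G[4, 5] <- G[5, 4] <- W2^2
  G[6, 6] <- W2^2
  Gi <- solve(G)
  lin <- function(k) Gi[k, 1] * m00 + Gi[k, 2] * m10 + Gi[k, 3] * m01 +
    Gi[k, 4] * m20 + Gi[k, 5] * m02 + Gi[k, 6] * m11
  r2 <- lin(2); r3 <- lin(3); r4 <- lin(4); r5 <- lin(5); r6 <- lin(6)
  list(A11 = r4, A12 = r6 / 2, A22 = r5, b1 = r2, b2 = r3)
}

# one displacement update given both expansions and a prior flow (pixels)
flow_update <- function(p1, p2, d1, d2, win_sigma) {
  dm <- dim(p1$A11)
  xi <- array(seq_len(dm[1]), dm) + d1
  yi <- array(rep(seq_len(dm[2]), each = dm[1]), dm) + d2
  A11 <- 0.5 * (p1$A11 + array(interp2(p2$A11, xi, yi), dm))
  A12 <- 0.5 * (p1$A12 + array(interp2(p2$A12, xi, yi), dm))
  A22 <- 0.5 * (p1$A22 + array(interp2(p2$A22, xi, yi), dm))
  db1 <- -0.5 * (array(interp2(p2$b1, xi, yi), dm) - p1$b1) + A11 * d1 + A12 * d2
  db2 <- -0.5 * (array(interp2(p2$b2, xi, yi), dm) - p1$b2) + A12 * d1 + A22 * d2
  G11 <- A11^2 + A12^2
  G12 <- A12 * (A11 + A22)
  G22 <- A12^2 + A22^2
  h1 <- A11 * db1 + A12 * db2
  h2 <- A12 * db1 + A22 * db2
  G11 <- gaussian_blur2(G11, win_sigma); G12 <- gaussian_blur2(G12, win_sigma)
  G22 <- gaussian_blur2(G22, win_sigma)
  h1 <- gaussian_blur2(h1, win_sigma); h2 <- gaussian_blur2(h2, win_sigma)
  det <- G11 * G22 - G12^2
  eps <- 1e-9 * (stats::median(abs(det)) + 1e-30)
  ok <- det > eps
  u1 <- ifelse(ok, (G22 * h1 - G12 * h2) / det, d1)
  u2 <- ifelse(ok, (G11 * h2 - G12 * h1) / det, d2)
  list(u1 = u1, u2 = u2)
}

downsample2 <- function(img) {
  s <- gaussian_blur2(img, 1)
  s[seq(1, nrow(s), 2), seq(1, ncol(s), 2), drop = FALSE]
}

upsample_flow <- function(d, dims) {
  sx <- dims[1] / nrow(d); sy <- dims[2] / ncol(d)
  xi <- array((seq_len(dims[1]) - 0.5) / sx + 0.5, dims)
  yi <- array(rep((seq_len(dims[2]) - 0.5) / sy + 0.5, each = dims[1]), dims)
  array(interp2(d, xi, yi), dims)
}

#' Default parameters for the dense flow estimator
#'
#' @param pyr_levels Number of pyramid levels (coarse-to-fine, 2x steps).
#' @param win Averaging window full size in px (Gaussian sigma = win/4).
#' @param iters Warping iterations per level.
#' @param poly_n Polynomial-expansion neighbourhood half-size in px.
#' @param poly_sigma Gaussian applicability sigma of the expansion.
#' @param mask_floor Fraction of the Otsu threshold of the fixed image below
#'   which pixels count as background and are excluded from flow statistics.
#' @return Named list of parameters.
#' @export
flow_params <- function(pyr_levels = 3L, win = 15, iters = 5L, poly_n = 3L,
                        poly_sigma = 1.5, mask_floor = 0.5) {
  list(pyr_levels = as.integer(pyr_levels), win = win,
       iters = as.integer(iters), poly_n = as.integer(poly_n),
       poly_sigma = poly_sigma, mask_floor = mask_floor)
}

#' Dense 2D distortion flow between two registered planes
#'
#' Estimates the per-pixel displacement carrying structure in `fixed` to its
#' position in `moving` (so a +3 px translation of the content yields a flow
#' of +3 px). Returns displacements in nm together with a signal mask: pixels
#' below an Otsu-derived floor in either image are background, where the flow
#' is reported as zero and flagged invalid.
#'
#' @param fixed,moving Numeric matrices of the same dimension (image planes
#'   indexed `[i, j]` along the plane's two axes).
#' @param pixel_size 2-vector, pixel pitch in nm along the two axes.
#' @param params See [flow_params()].
#' @return Object of class `flow_field`: list with `u1`, `u2` (nm), `mask`,
#'   `pixel_size`.
#' @export
farneback_flow <- function(fixed, moving, pixel_size = c(1, 1),
                           params = flow_params()) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            identical(dim(fixed), dim(moving)))
  if (stats::sd(fixed) < 1e-12 || stats::sd(moving) < 1e-12)
    stop("no structure to track: image has zero variance", call. = FALSE)
  pixel_size <- as.numeric(pixel_size)
  stopifnot(length(pixel_size) == 2, all(pixel_size > 0))
  # normalise jointly so the Otsu floor and expansion are scale-free
  hi <- max(fixed, moving); lo <- min(fixed, moving)
  f1 <- (fixed - lo) / (hi - lo)
  f2 <- (moving - lo) / (hi - lo)
  pyr1 <- list(f1); pyr2 <- list(f2)
  lv <- 1L
  while (lv < params$pyr_levels && min(dim(pyr1[[lv]])) >= 2 * 8 * params$poly_n) {
    pyr1[[lv + 1L]] <- downsample2(pyr1[[lv]])
    pyr2[[lv + 1L]] <- downsample2(pyr2[[lv]])
    lv <- lv + 1L
  }
  win_sigma <- params$win / 4
  d1 <- d2 <- NULL
  for (l in rev(seq_len(lv))) {
    dm <- dim(pyr1[[l]])
    if (is.null(d1)) {
      d1 <- array(0, dm); d2 <- array(0, dm)
    } else {
      d1 <- 2 * upsample_flow(d1, dm)
      d2 <- 2 * upsample_flow(d2, dm)
    }
    p1 <- poly_expansion(pyr1[[l]], params$poly_n, params$poly_sigma)
    p2 <- poly_expansion(pyr2[[l]], params$poly_n, params$poly_sigma)
    for (k in seq_len(params$iters)) {
      up <- flow_update(p1, p2, d1, d2, win_sigma)
      d1 <- up$u1; d2 <- up$u2
    }
  }
  thr <- tryCatch(EBImage::otsu(f1, range = c(0, 1)), error = function(e) NA)
  if (!is.finite(thr)) thr <- mean(f1)
  floor_ <- params$mask_floor * thr
  s1 <- gaussian_blur2(f1, 1); s2 <- gaussian_blur2(f2, 1)
  mask <- s1 > floor_ & s2 > floor_
  d1[!mask] <- 0; d2[!mask] <- 0
  structure(list(u1 = d1 * pixel_size[1], u2 = d2 * pixel_size[2],
                 mask = mask, pixel_size = pixel_size),
            class = "flow_field")
}

#' 3D distortion field from orthogonal resectioned flows
#'
#' Resections two registered volumes into x-y planes (every z index) and x-z
#' planes (every y index), runs the dense 2D flow on each pair of planes, and
#' fuses the components into 3D vectors: the x component is measured in both
#' plane families and averaged, y comes from the x-y planes, z from the x-z
#' planes. A voxel is valid only where both plane families report signal.
#' Per-plane failures (e.g. empty planes) become masked regions, not errors.
#'
#' The fused components can be regularised by mask-normalised 3D Gaussian
#' smoothing (`smooth_sigma_nm`), which averages measurements along the
#' valid-signal manifold and suppresses per-plane flow noise while leaving
#' distortion features much larger than the kernel untouched.
#'
#' @param pre_vol,post_vol Registered [image_volume]s on a common grid.
#' @param params See [flow_params()].
#' @param smooth_sigma_nm Sigma (nm) of the normalised-convolution smoothing
#'   of the fused field; 0 disables.
#' @return A [distortion_field] (displacements in nm).
#' @export
resection_flow_3d <- function(pre_vol, post_vol, params = flow_params(),
                              smooth_sigma_nm = 0) {
  stopifnot(inherits(pre_vol, "image_volume"), inherits(post_vol, "image_volume"))
  if (!identical(dim(pre_vol$data), dim(post_vol$data)))
    stop("volumes must share a common grid", call. = FALSE)
  if (max(abs(pre_vol$voxel - post_vol$voxel)) > 1e-9)
    stop("volumes must share a common voxel size", call. = FALSE)
  d <- dim(pre_vol$data)
  v <- pre_vol$voxel
  dxa <- array(0, d); dy <- array(0, d); mxy <- array(FALSE, d)
  dxb <- array(0, d); dz <- array(0, d); mxz <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    fl <- tryCatch(
      farneback_flow(pre_vol$data[, , z], post_vol$data[, , z],
                     pixel_size = v[1:2], params = params),
      error = function(e) NULL)
    if (is.null(fl)) next
    dxa[, , z] <- fl$u1; dy[, , z] <- fl$u2; mxy[, , z] <- fl$mask
  }
  for (y in seq_len(d[2])) {
    fl <- tryCatch(
      farneback_flow(pre_vol$data[, y, ], post_vol$data[, y, ],
                     pixel_size = v[c(1, 3)], params = params),
      error = function(e) NULL)
    if (is.null(fl)) next
    dxb[, y, ] <- fl$u1; dz[, y, ] <- fl$u2; mxz[, y, ] <- fl$mask
  }
  mask <- mxy & mxz
  ux <- (dxa + dxb) / 2
  ux[!mask] <- 0; dy[!mask] <- 0; dz[!mask] <- 0
  if (smooth_sigma_nm > 0) {
    w <- gauss3_masked(array(as.numeric(mask), d), smooth_sigma_nm / v)
    w[w <= 0] <- 1
    ux <- gauss3_masked(ux, smooth_sigma_nm / v) / w
    dy <- gauss3_masked(dy, smooth_sigma_nm / v) / w
    dz <- gauss3_masked(dz, smooth_sigma_nm / v) / w
    ux[!mask] <- 0; dy[!mask] <- 0; dz[!mask] <- 0
  }
  distortion_field(ux, dy, dz, voxel = v, origin = pre_vol$origin, mask = mask)
}

# separable 3D Gaussian correlation (sigma per axis, in voxels)
gauss3_masked <- function(a, sigma_vox) {
  d <- dim(a)
  kx <- gauss_kernel(max(sigma_vox[1], 1e-6))
  ky <- gauss_kernel(max(sigma_vox[2], 1e-6))
  kz <- gauss_kernel(max(sigma_vox[3], 1e-6))
  for (z in seq_len(d[3])) a[, , z] <- xcorr_sep(a[, , z], kx, ky)
  m <- matrix(a, d[1] * d[2], d[3])
  trim <- function(k, n) {
    half <- (length(k) - 1L) %/% 2L
    maxh <- (n - 1L) %/% 2L
    if (half > maxh) k[(half - maxh + 1L):(length(k) - (half - maxh))] else k
  }
  kz <- trim(kz, d[3])
  m <- EBImage::filter2(m, matrix(rev(kz), nrow = 1), boundary = "replicate")
  array(m, d)
}
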
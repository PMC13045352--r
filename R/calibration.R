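#' Measure nanocage widths from a TEM-like image or an ellipse table
#'
#' Manual path: a data.frame with `major` and `minor` columns (nm) is passed
#' through. Automatic path: the image is thresholded (Otsu), connected
#' components are labelled, holes are filled (cages image as annuli), and
#' each component's axes are estimated from the second moments of its filled
#' mask as `4 * sqrt(eigenvalues)` of the pixel-position covariance -- the
#' full +/-2 sigma extent, which equals the diameter exactly for a filled
#' disk. The width is `(major + minor) / 2` in both paths.
#'
#' @param image Numeric matrix (2D image) or a data.frame with columns
#'   major, minor (nm).
#' @param pixel_size Pixel edge in nm (automatic path).
#' @param bright_cages Polarity flag: `TRUE` (default) if cages are brighter
#'   than background, `FALSE` to invert first.
#' @param min_px Minimum component size in pixels (automatic path).
#' @param max_axis_ratio Components with major/minor above this are rejected
#'   as overlapping cages or debris (single negative-stain cages are nearly
#'   circular); rejections are counted in attribute `n_rejected`.
#' @return data.frame of class `tem_measurement`: cage, major, minor, width
#'   (nm), and centroid columns x, y for the automatic path.
#' @examples
#' measure_tem_widths(data.frame(major = 30, minor = 26))$width  # 28
#' @export
measure_tem_widths <- function(image, pixel_size = 1, bright_cages = TRUE,
                               min_px = 20, max_axis_ratio = 1.2) {
  if (is.data.frame(image)) {
    stopifnot(all(c("major", "minor") %in% names(image)))
    maj <- pmax(image$major, image$minor)
    mnr <- pmin(image$major, image$minor)
    if (any(mnr <= 0)) stop("axes must be > 0", call. = FALSE)
    out <- data.frame(cage = seq_len(nrow(image)), major = maj, minor = mnr,
                      width = (maj + mnr) / 2)
    class(out) <- c("tem_measurement", "data.frame")
    return(out)
  }
  stopifnot(is.matrix(image))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  img <- image
  if (!bright_cages) img <- max(img) - img
  rng <- range(img)
  if (diff(rng) <= 0) {
    warning("flat image: no components found")
    return(empty_tem())
  }
  norm <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  # refine to the half-max contour between the two class levels so the mask
  # boundary sits at 50% edge height (unbiased for symmetric edge profiles)
  lvl_fg <- stats::median(norm[norm > thr])
  lvl_bg <- stats::median(norm[norm <= thr])
  mask <- norm > (lvl_fg + lvl_bg) / 2
  lab <- EBImage::bwlabel(mask)
  lab <- EBImage::fillHull(lab)
  nlab <- max(lab)
  if (nlab == 0) {
    warning("no components found")
    return(empty_tem())
  }
  rows <- vector("list", nlab)
  n_rejected <- 0L
  pos_all <- which(lab > 0)
  comp <- split(pos_all, lab[pos_all])
  nr <- nrow(lab)
  for (k in seq_len(nlab)) {
    lin <- comp[[as.character(k)]]
    if (is.null(lin) || length(lin) < min_px) next
    idx <- cbind((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
    mu <- colMeans(idx)
    cen <- sweep(idx, 2, mu)
    # second moments of the filled mask, with the 1/12 px variance of the
    # pixel footprint itself
    cv <- crossprod(cen) / nrow(idx) + diag(2) / 12
    ev <- eigen(cv, symmetric = TRUE)$values
    axes <- 4 * sqrt(pmax(ev, 0)) * pixel_size
    if (axes[1] / axes[2] > max_axis_ratio) { n_rejected <- n_rejected + 1L; next }
    rows[[k]] <- data.frame(cage = k, major = axes[1], minor = axes[2],
                            width = mean(axes),
                            x = mu[1] * pixel_size, y = mu[2] * pixel_size)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no components above the size floor")
    return(empty_tem())
  }
  out <- do.call(rbind, rows)
  out$cage <- seq_len(nrow(out))
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("tem_measurement", "data.frame")
  out
}

empty_tem <- function() {
  out <- data.frame(cage = integer(0), major = numeric(0), minor = numeric(0),
                    width = numeric(0), x = numeric(0), y = numeric(0))
  class(out) <- c("tem_measurement", "data.frame")
  out
}

# circular 2D Gaussian fit on a cropped plane; returns centre (fractional
# index), sigma (px), amplitude, offset, R^2, convergence flag
fit_gaussian2d <- function(crop) {
  d <- dim(crop)
  xi <- as.vector(row(crop)); yi <- as.vector(col(crop)); zi <- as.vector(crop)
  pk <- which.max(zi)
  bg0 <- stats::quantile(zi, 0.1, names = FALSE)
  amp0 <- max(zi) - bg0
  # moment-based sigma start
  w <- pmax(zi - bg0, 0)
  if (sum(w) <= 0) w <- rep(1, length(zi))
  mx <- sum(w * xi) / sum(w); my <- sum(w * yi) / sum(w)
  s0 <- sqrt(max(sum(w * ((xi - mx)^2 + (yi - my)^2)) / (2 * sum(w)), 0.25))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      zi ~ b + a * exp(-((xi - x0)^2 + (yi - y0)^2) / (2 * s^2)),
      start = list(b = bg0, a = amp0, x0 = xi[pk], y0 = yi[pk], s = s0),
      lower = c(-Inf, 0, 1, 1, 0.2),
      upper = c(Inf, Inf, d[1], d[2], max(d)),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(x0 = mx, y0 = my, sigma = s0, amplitude = amp0, offset = bg0,
                r2 = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((zi - mean(zi))^2)
  list(x0 = cf[["x0"]], y0 = cf[["y0"]], sigma = cf[["s"]],
       amplitude = cf[["a"]], offset = cf[["b"]],
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       converged = TRUE)
}

#' Detect diffraction-limited spots and fit their widths
#'
#' Difference-of-Gaussians detection at a stated physical scale, local-maxima
#' seeding above a robust (k x MAD) floor, and a per-spot circular 2D
#' Gaussian fit on the spot's in-focus plane. The lateral FWHM is
#' `2*sqrt(2 ln 2) * sigma_fit`. Spots failing the quality floor
#' (R^2 or width range) are flagged `accepted = FALSE`, never silently
#' dropped; non-converged fits fall back to the moment-based width.
#'
#' @param vol An [image_volume] or a 2D matrix (with `pixel_size`).
#' @param scale Expected spot FWHM in nm (detection scale).
#' @param k_mad Seed threshold in MADs above the median of the DoG response.
#' @param pixel_size Pixel size (nm) when `vol` is a matrix; for volumes the
#'   voxel size is used (lateral axes must be isotropic).
#' @param r2_min Acceptance floor on the fit R^2 (default 0.8).
#' @param width_range Accepted width range as multiples of `scale`
#'   (default `c(0.5, 3)`).
#' @param max_spots Safety cap on the number of seeds processed.
#' @return data.frame of class `spot_set`: spot, x, y, z (nm), width_nm,
#'   intensity, r2, converged, accepted, saturated.
#' @export
detect_spots <- function(vol, scale = 170, k_mad = 7, pixel_size = NULL,
                         r2_min = 0.8, width_range = c(0.5, 3),
                         max_spots = 5000L) {
  if (inherits(vol, "image_volume")) {
    if (abs(vol$voxel[1] - vol$voxel[2]) > 1e-6)
      stop("lateral voxel sizes must be isotropic for spot fitting", call. = FALSE)
    px <- vol$voxel[1]
    arr <- vol$data
    vz <- vol$voxel[3]
    origin <- vol$origin
  } else {
    stopifnot(is.matrix(vol))
    if (is.null(pixel_size)) stop("'pixel_size' required for matrix input", call. = FALSE)
    px <- pixel_size
    arr <- array(vol, c(dim(vol), 1L))
    vz <- 1
    origin <- c(0, 0, 0)
  }
  d <- dim(arr)
  sig_px <- fwhm_to_sigma(scale) / px
  # slice-wise DoG response (spots are fitted in-plane)
  dog <- arr
  for (z in seq_len(d[3])) {
    s1 <- gaussian_blur2(arr[, , z], sig_px)
    s2 <- gaussian_blur2(arr[, , z], 1.6 * sig_px)
    dog[, , z] <- s1 - s2
  }
  med <- stats::median(dog)
  floor_ <- med + k_mad * max(mad_scale(as.vector(dog)), 1e-12)
  cand <- which(dog > floor_ & local_max3(dog))
  if (!length(cand)) return(empty_spots())
  ord <- order(dog[cand], decreasing = TRUE)
  cand <- cand[ord]
  if (length(cand) > max_spots) cand <- cand[seq_len(max_spots)]
  pos <- arrayInd(cand, d)
  win <- max(3L, ceiling(3 * sig_px))
  sat_level <- max(arr) * 0.999
  rows <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    cx <- pos[i, 1]; cy <- pos[i, 2]; cz <- pos[i, 3]
    x0 <- max(1, cx - win); x1 <- min(d[1], cx + win)
    y0 <- max(1, cy - win); y1 <- min(d[2], cy + win)
    crop <- arr[x0:x1, y0:y1, cz]
    ft <- fit_gaussian2d(crop)
    width <- FWHM_FACTOR * ft$sigma * px
    sat <- sum(crop >= sat_level) > 1
    accepted <- isTRUE(ft$converged) && is.finite(ft$r2) && ft$r2 >= r2_min &&
      width >= width_range[1] * scale && width <= width_range[2] * scale &&
      !sat
    rows[[i]] <- data.frame(
      x = origin[1] + (x0 - 1 + ft$x0 - 0.5) * px,
      y = origin[2] + (y0 - 1 + ft$y0 - 0.5) * px,
      z = origin[3] + (cz - 0.5) * vz,
      width_nm = width, intensity = ft$amplitude, r2 = ft$r2,
      converged = ft$converged, accepted = accepted, saturated = sat)
  }
  out <- do.call(rbind, rows)
  # deduplicate seeds that resolved to the same spot (within one scale)
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    pts <- as.matrix(out[, c("x", "y", "z")])
    for (i in seq_len(nrow(out) - 1L)) {
      if (!keep[i]) next
      later <- (i + 1L):nrow(out)
      dd <- sqrt(rowSums(sweep(pts[later, , drop = FALSE], 2, pts[i, ])^2))
      keep[later[dd < 0.75 * scale]] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- cbind(spot = seq_len(nrow(out)), out)
  class(out) <- c("spot_set", "data.frame")
  out
}

empty_spots <- function() {
  out <- data.frame(spot = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), width_nm = numeric(0),
                    intensity = numeric(0), r2 = numeric(0),
                    converged = logical(0), accepted = logical(0),
                    saturated = logical(0))
  class(out) <- c("spot_set", "data.frame")
  out
}

# 26-neighbourhood local maxima (TRUE at strict-or-equal plateaus peaks)
local_max3 <- function(a) {
  d <- dim(a)
  res <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- shift_array3(a, c(dx, dy, dz))
    res <- res & (a >= sh)
  }
  res
}

shift_array3 <- function(a, s) {
  d <- dim(a)
  out <- array(-Inf, d)
  src <- lapply(1:3, function(k) {
    if (s[k] >= 0) seq_len(d[k] - s[k]) else (1 - s[k]):d[k]
  })
  dst <- lapply(1:3, function(k) {
    if (s[k] >= 0) (1 + s[k]):d[k] else seq_len(d[k] + s[k])
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Intrinsic expansion factor from spot widths and a reference diameter
#'
#' The intrinsic EF is the mean fitted width of the accepted nanocage spots
#' divided by the reference (TEM) nanocage diameter. No PSF deconvolution is
#' applied by default -- the raw fluorescence width is divided by the
#' physical reference, conflating PSF broadening with expansion, which is the
#' operational definition this calibration reproduces. An optional quadrature
#' correction `sqrt(width^2 - psf_fwhm^2)` is available and changes EF
#' values; it warns when used.
#'
#' @param spots A [detect_spots] result (or any data.frame with `width_nm`
#'   and optionally `accepted`).
#' @param reference_diameter Reference nanocage diameter in nm (> 0).
#' @param psf_fwhm Optional PSF FWHM (nm) for quadrature correction.
#' @return List of class `ef_record` fragment: `intrinsic_ef`, `sd` (delta
#'   method on the mean width), `per_spot_ef`, `n_spots`, `n_flagged`,
#'   `reference_diameter`.
#' @examples
#' s <- data.frame(width_nm = c(283, 283), accepted = TRUE)
#' intrinsic_ef(s, 28.3)$intrinsic_ef  # 10
#' @export
intrinsic_ef <- function(spots, reference_diameter, psf_fwhm = NULL) {
  check_scalar(reference_diameter, "reference_diameter", positive = TRUE)
  acc <- spots$accepted %||% rep(TRUE, nrow(spots))
  w <- spots$width_nm[acc]
  if (!length(w)) stop("zero accepted spots", call. = FALSE)
  if (!is.null(psf_fwhm)) {
    warning("quadrature PSF correction changes EF values")
    w <- sqrt(pmax(w^2 - psf_fwhm^2, 0))
  }
  ef <- mean(w) / reference_diameter
  sd_ef <- stats::sd(w) / sqrt(length(w)) / reference_diameter
  structure(list(intrinsic_ef = ef, sd = sd_ef,
                 per_spot_ef = w / reference_diameter,
                 n_spots = length(w), n_flagged = sum(!acc),
                 reference_diameter = reference_diameter),
            class = "ef_record")
}

#' Macroscopic expansion factor from gel dimensions
#'
#' @param pre_dims,post_dims Matched vectors of gel dimensions (same units),
#'   all > 0.
#' @return Mean of the per-dimension post/pre ratios.
#' @examples
#' macroscopic_ef(5, 47)        # 9.4
#' macroscopic_ef(c(10, 10), c(40, 44))  # 4.2
#' @export
macroscopic_ef <- function(pre_dims, post_dims) {
  if (length(pre_dims) != length(post_dims))
    stop("dimension lists must have equal length", call. = FALSE)
  if (any(pre_dims <= 0) || any(post_dims <= 0))
    stop("dimensions must be > 0", call. = FALSE)
  mean(post_dims / pre_dims)
}

#' Rescale a volume's voxel size by an expansion factor
#'
#' Divides the voxel sizes by `ef` so downstream measurements are on the
#' biological (pre-expansion) scale; intensities are untouched and the
#' calibration provenance is recorded in the metadata.
#'
#' @param vol An [image_volume].
#' @param ef Expansion factor (> 0).
#' @param source Which estimate the factor came from
#'   (`"macroscopic"` or `"intrinsic"`), recorded as provenance.
#' @return The calibrated [image_volume].
#' @export
calibrate_scale <- function(vol, ef, source = c("macroscopic", "intrinsic")) {
  stopifnot(inherits(vol, "image_volume"))
  check_scalar(ef, "ef", positive = TRUE)
  source <- match.arg(source)
  vol$voxel <- vol$voxel / ef
  vol$origin <- vol$origin / ef
  vol$meta$calibration <- c(vol$meta$calibration,
                            list(list(source = source, ef = ef)))
  vol
}

#' PSF FWHM from averaged bead stacks
#'
#' Aligns single-bead stacks by intensity centroid (sub-voxel, trilinear),
#' averages them, and fits 1D Gaussians to the axis profiles through the
#' peak, returning the lateral and axial FWHM. Beads whose centroid sits more
#' than a quarter of the stack from the centre are rejected and counted.
#'
#' @param beads List of [image_volume]s, one centred bead each.
#' @param n_average How many stacks to average (defaults to all).
#' @param bead_diameter Physical bead diameter (nm); if the fitted FWHM does
#'   not exceed it the estimate is flagged (`finite_bead` attribute).
#' @return Named vector `c(lateral, axial)` FWHM in nm, with attributes
#'   `n_used`, `n_rejected`, `sigma` and `finite_bead`.
#' @export
fwhm_from_beads <- function(beads, n_average = length(beads),
                            bead_diameter = 100) {
  stopifnot(length(beads) >= 1, n_average <= length(beads), n_average >= 1)
  d <- dim(beads[[1]]$data)
  vox <- beads[[1]]$voxel
  used <- 0L; rejected <- 0L
  acc <- array(0, d)
  ctr_target <- (d / 2) * vox
  for (b in beads) {
    stopifnot(identical(dim(b$data), d))
    cen <- intensity_centroid(b) - b$origin
    if (any(abs(cen - ctr_target) > d * vox / 4)) { rejected <- rejected + 1L; next }
    if (used >= n_average) break
    # shift so the centroid lands on the stack centre
    shift <- cen - ctr_target
    ctrs <- grid_centers(list(dims = d, voxel = vox, origin = c(0, 0, 0)))
    vals <- interp_volume(b, sweep(ctrs, 2, shift, "+") , outside = 0)
    acc <- acc + array(vals, d)
    used <- used + 1L
  }
  if (used == 0) stop("no usable bead stacks (all rejected)", call. = FALSE)
  avg <- acc / used
  pk <- arrayInd(which.max(avg), d)
  fit1 <- function(vals, step) {
    xi <- seq_along(vals)
    pk1 <- which.max(vals)
    f <- tryCatch(minpack.lm::nlsLM(
      vals ~ b + a * exp(-(xi - m)^2 / (2 * s^2)),
      start = list(b = min(vals), a = diff(range(vals)), m = pk1,
                   s = max(2, length(vals) / 10)),
      lower = c(-Inf, 0, 1, 0.3),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(f)) return(c(NA_real_, NA_real_))
    c(stats::coef(f)[["s"]] * step, sqrt(mean(stats::resid(f)^2)))
  }
  sx <- fit1(avg[, pk[2], pk[3]], vox[1])
  sy <- fit1(avg[pk[1], , pk[3]], vox[2])
  sz <- fit1(avg[pk[1], pk[2], ], vox[3])
  sig_lat <- mean(c(sx[1], sy[1]), na.rm = TRUE)
  out <- c(lateral = FWHM_FACTOR * sig_lat, axial = FWHM_FACTOR * sz[1])
  attr(out, "n_used") <- used
  attr(out, "n_rejected") <- rejected
  attr(out, "sigma") <- c(lateral = sig_lat, axial = sz[1])
  attr(out, "fit_rms") <- mean(c(sx[2], sy[2]), na.rm = TRUE)
  attr(out, "finite_bead") <- is.finite(out[1]) && out[1] <= bead_diameter
  out
}
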
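#' Render a point set into a 3D volume through a Gaussian PSF
#'
#' Each source is integrated exactly over voxels via separable Gaussian CDF
#' differences, so a noise-free render of an interior unit-intensity point
#' integrates to 1 within numerical precision and peaks at the voxel nearest
#' the point. Detector noise follows the standard model: Poisson on
#' gain-scaled intensities, then additive Gaussian read noise; both optional
#' so zero-noise renders are exact.
#'
#' @param points n x 3 matrix of physical positions (nm), or a data.frame
#'   with columns x, y, z (and optionally intensity).
#' @param psf A [psf_model].
#' @param grid `list(dims = c(nx, ny, nz), voxel = c(vx, vy, vz),
#'   origin = c(x0, y0, z0))`; origin defaults to (0,0,0).
#' @param intensities Source intensities (recycled); ignored when `points`
#'   is a data.frame carrying an `intensity` column.
#' @param noise `list(gain = photons per intensity unit for Poisson noise,
#'   sd = Gaussian read-noise SD)`; `NULL` entries disable that component.
#' @param seed RNG seed for the noise draw.
#' @param allow_clip If `FALSE` (default), points outside the grid raise an
#'   error; if `TRUE` their out-of-grid tails are clipped silently.
#' @param channel Channel label for the output volume.
#' @return An [image_volume].
#' @export
render_volume <- function(points, psf, grid, intensities = 1,
                          noise = list(gain = NULL, sd = NULL), seed = 1,
                          allow_clip = FALSE, channel = "") {
  stopifnot(inherits(psf, "psf_model"))
  if (is.data.frame(points)) {
    if (!is.null(points$intensity)) intensities <- points$intensity
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  points <- rbind(points)
  dims <- as.integer(grid$dims)
  voxel <- check_vec3(grid$voxel, "grid$voxel", positive = TRUE)
  origin <- (grid$origin %||% c(0, 0, 0))
  n <- nrow(points)
  intensities <- rep_len(intensities, n)
  sig <- c(psf$sigma_lateral, psf$sigma_lateral, psf$sigma_axial)
  vol <- array(0, dims)
  if (n > 0) {
    lo_ok <- sweep(points, 2, origin, "-")
    hi <- dims * voxel
    inside <- lo_ok[, 1] >= 0 & lo_ok[, 1] <= hi[1] &
      lo_ok[, 2] >= 0 & lo_ok[, 2] <= hi[2] &
      lo_ok[, 3] >= 0 & lo_ok[, 3] <= hi[3]
    if (!allow_clip && any(!inside))
      stop(sprintf("%d point(s) fall outside the render grid (set allow_clip = TRUE to clip)",
                   sum(!inside)), call. = FALSE)
    half <- ceiling(4.5 * sig / voxel)  # +/- 4.5 sigma window per axis
    for (i in seq_len(n)) {
      p <- points[i, ] - origin
      ctr <- p / voxel + 0.5          # fractional 1-based index
      w <- vector("list", 3)
      rng <- vector("list", 3)
      skip <- FALSE
      for (a in 1:3) {
        j0 <- max(1L, floor(ctr[a] - half[a]))
        j1 <- min(dims[a], ceiling(ctr[a] + half[a]))
        if (j0 > j1) { skip <- TRUE; break }
        edges <- (seq(j0 - 1L, j1)) * voxel[a]  # voxel boundaries
        w[[a]] <- diff(stats::pnorm(edges, mean = p[a], sd = sig[a]))
        rng[[a]] <- j0:j1
      }
      if (skip) next
      blob <- outer(outer(w[[1]], w[[2]]), w[[3]])
      if (!psf$normalize) {
        pk <- prod(vapply(w, max, numeric(1)))
        if (pk > 0) blob <- blob / pk
      }
      vol[rng[[1]], rng[[2]], rng[[3]]] <-
        vol[rng[[1]], rng[[2]], rng[[3]]] + intensities[i] * blob
    }
  }
  gain <- noise$gain %||% NULL
  sd <- noise$sd %||% NULL
  if (!is.null(gain) || !is.null(sd)) {
    vol <- with_seed(seed, {
      v <- vol
      if (!is.null(gain)) {
        check_scalar(gain, "noise$gain", positive = TRUE)
        v <- array(stats::rpois(length(v), pmax(v, 0) * gain) / gain, dims)
      }
      if (!is.null(sd)) {
        check_scalar(sd, "noise$sd", nonneg = TRUE)
        v <- v + array(stats::rnorm(length(v), 0, sd), dims)
      }
      v
    })
  }
  image_volume(vol, voxel, channel = channel, origin = origin,
               meta = list(psf = unclass(psf), seed = seed))
}

#' Render a TEM-like 2D image of nanocage annuli
#'
#' Cages appear as bright annuli on a dark background, the negative-stain
#' appearance of purified protein nanocages. Each cage is drawn with its true
#' outer diameter (the tabulated diameter), a fixed ring thickness, and mild
#' area-balanced ellipticity jitter (major = d(1+e), minor = d(1-e)), with
#' half-pixel soft edges. Returns the image plus the per-cage truth table.
#'
#' @param spec A [nanocage_field_spec]; its `region` (if any) is interpreted
#'   in 2D (x, y bounds in nm).
#' @param dims `c(nx, ny)` image size in pixels.
#' @param pixel_size Pixel edge in nm.
#' @param seed RNG seed.
#' @param ring_thickness Annulus thickness in nm.
#' @param ellipticity_sd SD of the ellipticity jitter `e` (0 disables).
#' @param margin Border (nm) kept free of cage centres.
#' @return List with `image` (nx x ny matrix), `pixel_size`, and `truth`
#'   (data.frame: cage, x, y, diameter, major, minor, angle).
#' @export
render_tem_nanocages <- function(spec, dims = c(512, 512), pixel_size = 0.5,
                                 seed = 1, ring_thickness = 3,
                                 ellipticity_sd = 0.02, margin = 25) {
  stopifnot(inherits(spec, "nanocage_field_spec"))
  dims <- as.integer(dims)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  img <- matrix(0, dims[1], dims[2])
  truth <- data.frame(cage = integer(0), x = numeric(0), y = numeric(0),
                      diameter = numeric(0), major = numeric(0),
                      minor = numeric(0), angle = numeric(0))
  if (spec$n_cages == 0)
    return(list(image = img, pixel_size = pixel_size, truth = truth))
  ext <- dims * pixel_size
  res <- with_seed(seed, {
    n <- spec$n_cages
    if (!is.null(spec$region)) {
      lo <- spec$region$lo[1:2]; hi <- spec$region$hi[1:2]
    } else {
      lo <- c(margin, margin); hi <- ext - margin
    }
    x <- stats::runif(n, lo[1], hi[1])
    y <- stats::runif(n, lo[2], hi[2])
    d <- stats::rnorm(n, spec$diameter_mean, spec$diameter_sd)
    while (any(d <= 2 * ring_thickness))
      d[d <= 2 * ring_thickness] <- stats::rnorm(sum(d <= 2 * ring_thickness),
                                                 spec$diameter_mean,
                                                 spec$diameter_sd)
    e <- if (ellipticity_sd > 0) abs(stats::rnorm(n, 0, ellipticity_sd)) else
      numeric(n)
    ang <- stats::runif(n, 0, pi)
    list(x = x, y = y, d = d, e = e, ang = ang)
  })
  dens <- spec$n_cages * pi * (spec$diameter_mean / 2)^2 / prod(ext)
  if (dens > 0.3)
    warning(sprintf("nanocage density %.2f exceeds 0.3: overlapping cages likely",
                    dens))
  xs <- (seq_len(dims[1]) - 0.5) * pixel_size
  ys <- (seq_len(dims[2]) - 0.5) * pixel_size
  soft <- 0.5 * pixel_size
  for (i in seq_len(spec$n_cages)) {
    a <- res$d[i] / 2 * (1 + res$e[i])   # semi-major (outer)
    b <- res$d[i] / 2 * (1 - res$e[i])   # semi-minor (outer)
    win <- a + 2 * pixel_size
    ix <- which(abs(xs - res$x[i]) <= win)
    iy <- which(abs(ys - res$y[i]) <= win)
    if (!length(ix) || !length(iy)) next
    dx <- xs[ix] - res$x[i]; dy <- ys[iy] - res$y[i]
    ca <- cos(res$ang[i]); sa <- sin(res$ang[i])
    # rotate into the ellipse frame and use the scaled radial coordinate
    u <- outer(dx, dy, function(p, q) (p * ca + q * sa))
    v <- outer(dx, dy, function(p, q) (-p * sa + q * ca))
    rho <- sqrt((u / a)^2 + (v / b)^2) * res$d[i] / 2  # nm-equivalent radius
    outer_edge <- stats::pnorm(res$d[i] / 2 - rho, 0, soft)
    inner_edge <- stats::pnorm(rho - (res$d[i] / 2 - ring_thickness), 0, soft)
    img[ix, iy] <- pmax(img[ix, iy], spec$intensity * outer_edge * inner_edge)
  }
  truth <- data.frame(cage = seq_len(spec$n_cages), x = res$x, y = res$y,
                      diameter = res$d, major = res$d * (1 + res$e),
                      minor = res$d * (1 - res$e), angle = res$ang)
  list(image = img, pixel_size = pixel_size, truth = truth)
}
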
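# shared fixture builders; everything is generated in code, nothing on disk

# n points with pairwise separation >= min_sep inside box [lo, hi]^3
separated_points <- function(n, lo, hi, min_sep, seed = 1, zlim = NULL) {
  set.seed(seed)
  out <- matrix(numeric(0), 0, 3)
  zr <- zlim %||% c(lo, hi)
  while (nrow(out) < n) {
    p <- c(runif(1, lo, hi), runif(1, lo, hi), runif(1, zr[1], zr[2]))
    if (nrow(out) == 0 ||
        min(sqrt(rowSums(sweep(out, 2, p)^2))) >= min_sep)
      out <- rbind(out, p)
  }
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# blob image: sum of Gaussian spots at px coordinates (for 2D flow tests)
blob_image <- function(n = 96, pts, sigma = 2.5) {
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(pts))) {
    cx <- pts[i, 1]; cy <- pts[i, 2]
    xs <- max(1, floor(cx - 4 * sigma)):min(n, ceiling(cx + 4 * sigma))
    ys <- max(1, floor(cy - 4 * sigma)):min(n, ceiling(cy + 4 * sigma))
    img[xs, ys] <- img[xs, ys] +
      exp(-outer((xs - cx)^2, (ys - cy)^2, "+") / (2 * sigma^2))
  }
  img
}

# uniform unit-sphere directions (local copy for oracle independence)
sphere_points <- function(n, r = 1, seed = 1) {
  set.seed(seed)
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z) * r
}

# small registration pair: points rendered pre and post with the post PSF
# scaled by the same similarity, so the volumes differ by exactly that
# similarity transform
registration_pair <- function(scale, trans, pre_dims = 48, pre_voxel = 40,
                              post_dims = 104, post_voxel = 80,
                              n_points = 80, seed = 11,
                              sigma = c(90, 220)) {
  lo <- 6 * pre_voxel; hi <- (pre_dims - 6) * pre_voxel
  set.seed(seed)
  pts <- cbind(runif(n_points, lo, hi), runif(n_points, lo, hi),
               runif(n_points, lo, hi))
  pre <- render_volume(pts, psf_model(sigma[1], sigma[2]),
                       list(dims = rep(pre_dims, 3), voxel = rep(pre_voxel, 3)),
                       noise = list())
  post <- render_volume(sweep(pts * scale, 2, trans, "+"),
                        psf_model(sigma[1] * scale, sigma[2] * scale),
                        list(dims = rep(post_dims, 3),
                             voxel = rep(post_voxel, 3)),
                        noise = list(), allow_clip = TRUE)
  list(pre = pre, post = post, points = pts)
}

# distortion scene used by the flow-recovery checks: one under-expanded
# compartment plus cytoplasmic nanocage texture on a 96^3 x 20 nm grid
distortion_scene <- function(seed = 9) {
  ctr <- c(960, 960, 960)
  comp <- compartment_spec(centroid = ctr, radii = c(250, 250, 250),
                           n_membrane_puncta = 400, n_interior_puncta = 60)
  cages <- nanocage_field_spec(500, 28.3, 1.6,
                               region = list(lo = rep(120, 3),
                                             hi = rep(1800, 3)))
  dist <- distortion_spec(global_factor = 1, local_centers = ctr,
                          local_amplitude = -0.1, local_falloff = 400)
  sc <- build_scene(list(comp), nanocages = cages, distortion = dist,
                    seed = seed)
  psf <- psf_model(60, 140)
  grid <- list(dims = c(96, 96, 96), voxel = c(20, 20, 20))
  pre <- render_volume(sc$points, psf, grid, noise = list(), allow_clip = TRUE)
  post <- render_volume(sc$post_points, psf, grid,
                        intensities = sc$points$intensity,
                        noise = list(), allow_clip = TRUE)
  list(scene = sc, pre = pre, post = post, grid = grid, centre = ctr,
       spec = dist)
}

# independent moment-matching oracle: for each candidate level t, solve the
# two-point distribution preserving m1 and m2 at below-fraction p, then score
# the third-moment mismatch
moments_oracle <- function(x) {
  rng <- range(x)
  lev <- round((x - rng[1]) / diff(rng) * 255)
  p <- tabulate(lev + 1L, nbins = 256L) / length(lev)
  z <- 0:255
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  v <- m2 - m1^2
  cum <- cumsum(p)
  best <- c(Inf, NA)
  for (t in 0:255) {
    pf <- cum[t + 1]
    if (pf <= 0 || pf >= 1) next
    q <- 1 - pf
    z0 <- m1 - sqrt(v * q / pf)
    z1 <- m1 + sqrt(v * pf / q)
    mis <- abs(pf * z0^3 + q * z1^3 - m3)
    if (mis < best[1]) best <- c(mis, t)
  }
  best[2]
}

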
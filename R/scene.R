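#' Specification of a membrane compartment decorated with puncta
#'
#' Describes one endosome-like compartment: an ellipsoidal shell carrying
#' membrane puncta (optionally gathered into nanoclusters) plus puncta
#' strictly inside the lumen. Channel labels are assigned per punctum class
#' through `channel_map`.
#'
#' @param centroid 3-vector, compartment centre in nm.
#' @param radii 3-vector of ellipsoid semi-axes (a, b, c) in nm, all > 0.
#' @param n_membrane_puncta Number of puncta on the shell.
#' @param n_clusters Number of nanoclusters the membrane puncta gather into;
#'   0 means uniform decoration.
#' @param cluster_concentration von Mises-Fisher concentration kappa of the
#'   angular scatter around each cluster axis (>= 0; larger = tighter).
#' @param n_interior_puncta Number of puncta strictly inside the shell.
#' @param channel_map Named list mapping punctum class (`"membrane"`,
#'   `"interior"`) to a channel label.
#' @return Object of class `compartment_spec`.
#' @export
compartment_spec <- function(centroid = c(0, 0, 0), radii = c(150, 150, 150),
                             n_membrane_puncta = 0L, n_clusters = 0L,
                             cluster_concentration = 0,
                             n_interior_puncta = 0L,
                             channel_map = list(membrane = "membrane",
                                                interior = "interior")) {
  centroid <- check_vec3(centroid, "centroid")
  radii <- check_vec3(radii, "radii", positive = TRUE)
  if (n_membrane_puncta < 0) stop("'n_membrane_puncta' must be >= 0", call. = FALSE)
  if (n_interior_puncta < 0) stop("'n_interior_puncta' must be >= 0", call. = FALSE)
  if (n_clusters < 0) stop("'n_clusters' must be >= 0", call. = FALSE)
  if (!is.numeric(cluster_concentration) || cluster_concentration < 0)
    stop("'cluster_concentration' must be >= 0", call. = FALSE)
  structure(list(centroid = centroid, radii = radii,
                 n_membrane_puncta = as.integer(n_membrane_puncta),
                 n_clusters = as.integer(n_clusters),
                 cluster_concentration = as.numeric(cluster_concentration),
                 n_interior_puncta = as.integer(n_interior_puncta),
                 channel_map = channel_map),
            class = "compartment_spec")
}

#' Specification of a field of cytoplasmic nanocage point sources
#'
#' Nanocages are in-cell size standards of known true diameter; at generation
#' time they are ideal points (fluorescence) or rings (TEM) and are never
#' blurred -- blurring belongs to the renderer.
#'
#' @param n_cages Number of cages (>= 0).
#' @param diameter_mean,diameter_sd Mean and SD (nm) of the true diameter
#'   distribution (normal, truncated at > 0).
#' @param region Either `NULL` (whole domain) or `list(lo = , hi = )` physical
#'   bounds in nm for cage placement.
#' @param intensity Source intensity per cage.
#' @param channel Channel label.
#' @return Object of class `nanocage_field_spec`.
#' @export
nanocage_field_spec <- function(n_cages, diameter_mean = 28.3,
                                diameter_sd = 1.6, region = NULL,
                                intensity = 1, channel = "nanocage") {
  if (n_cages < 0) stop("'n_cages' must be >= 0", call. = FALSE)
  check_scalar(diameter_mean, "diameter_mean", positive = TRUE)
  check_scalar(diameter_sd, "diameter_sd", nonneg = TRUE)
  structure(list(n_cages = as.integer(n_cages),
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 region = region, intensity = intensity,
                 channel = as.character(channel)),
            class = "nanocage_field_spec")
}

#' Specification of a ground-truth distortion field
#'
#' Global isotropic expansion by `global_factor` followed by local radial
#' Gaussian bumps: around each centre `c`,
#' `u(q) = amplitude * exp(-|q - c|^2 / (2 falloff^2)) * (q - c)`,
#' evaluated in post-expansion coordinates. Negative amplitudes model local
#' under-expansion (radially inward shifts), the signature seen at small
#' compartments after expansion.
#'
#' @param global_factor Global linear expansion factor (> 0).
#' @param local_centers Matrix (k x 3) or single 3-vector of bump centres in
#'   post-expansion nm; may be `NULL` for none.
#' @param local_amplitude Numeric vector (length k or 1) of dimensionless
#'   amplitudes; `|amplitude| >= 1` is rejected (fold-over risk), and
#'   `|amplitude| >= 0.5` warns (invertibility is only guaranteed below 0.5).
#' @param local_falloff Gaussian falloff length(s) in nm (> 0).
#' @return Object of class `distortion_spec`.
#' @export
distortion_spec <- function(global_factor = 1, local_centers = NULL,
                            local_amplitude = numeric(0),
                            local_falloff = numeric(0)) {
  check_scalar(global_factor, "global_factor", positive = TRUE)
  if (is.null(local_centers)) {
    local_centers <- matrix(numeric(0), 0, 3)
    local_amplitude <- numeric(0)
    local_falloff <- numeric(0)
  } else {
    local_centers <- rbind(local_centers)
    stopifnot(ncol(local_centers) == 3)
    k <- nrow(local_centers)
    local_amplitude <- rep_len(as.numeric(local_amplitude), k)
    local_falloff <- rep_len(as.numeric(local_falloff), k)
    if (any(!is.finite(local_amplitude)) || any(abs(local_amplitude) >= 1))
      stop("'local_amplitude' must be finite with |amplitude| < 1 (fold-over risk)",
           call. = FALSE)
    if (any(abs(local_amplitude) >= 0.5))
      warning("|local_amplitude| >= 0.5: displacement field may not be invertible")
    if (any(local_falloff <= 0)) stop("'local_falloff' must be > 0", call. = FALSE)
  }
  structure(list(global_factor = as.numeric(global_factor),
                 local_centers = local_centers,
                 local_amplitude = local_amplitude,
                 local_falloff = local_falloff),
            class = "distortion_spec")
}

#' Local (post-registration) displacement of a distortion spec
#'
#' Evaluates only the local bump terms at post-expansion coordinates `q`;
#' the global factor is the similarity component that registration removes,
#' so this is the residual distortion a flow analysis should recover.
#'
#' @param d A [distortion_spec].
#' @param q n x 3 matrix of post-expansion coordinates (nm).
#' @return n x 3 matrix of displacement vectors (nm).
#' @export
local_displacement <- function(d, q) {
  stopifnot(inherits(d, "distortion_spec"))
  q <- rbind(q)
  u <- matrix(0, nrow(q), 3)
  if (nrow(d$local_centers) == 0) return(u)
  for (j in seq_len(nrow(d$local_centers))) {
    dq <- sweep(q, 2, d$local_centers[j, ], "-")
    w <- d$local_amplitude[j] *
      exp(-rowSums(dq^2) / (2 * d$local_falloff[j]^2))
    u <- u + dq * w
  }
  u
}

#' Apply a distortion spec to a point set
#'
#' Points are first scaled by the global expansion factor, then shifted by the
#' local radial bumps evaluated at the scaled positions. Optionally the local
#' displacement field is sampled on a stated voxel grid, yielding the
#' ground-truth [distortion_field] the flow pipeline should recover.
#'
#' @param points n x 3 matrix of pre-expansion coordinates (nm).
#' @param d A [distortion_spec].
#' @param grid Optional `list(dims, voxel, origin)` on which to sample the
#'   local displacement field.
#' @return List with `points` (displaced, n x 3) and `field`
#'   (a [distortion_field] or `NULL`).
#' @examples
#' d <- distortion_spec(global_factor = 10)
#' apply_distortion(matrix(c(1, 2, 3), 1), d)$points  # scaled exactly x10
#' @export
apply_distortion <- function(points, d, grid = NULL) {
  stopifnot(inherits(d, "distortion_spec"))
  points <- rbind(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) && any(!is.finite(points))) stop("'points' must be finite", call. = FALSE)
  q <- points * d$global_factor
  out_pts <- q + local_displacement(d, q)
  fld <- NULL
  if (!is.null(grid)) {
    ctrs <- grid_centers(grid)
    u <- local_displacement(d, ctrs)
    fld <- distortion_field(
      ux = array(u[, 1], grid$dims), uy = array(u[, 2], grid$dims),
      uz = array(u[, 3], grid$dims), voxel = grid$voxel,
      origin = grid$origin %||% c(0, 0, 0))
  }
  list(points = out_pts, field = fld)
}

#' Voxel-centre coordinates of a plain grid spec
#' @noRd
grid_centers <- function(grid) {
  dims <- grid$dims; voxel <- grid$voxel; origin <- grid$origin %||% c(0, 0, 0)
  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel[1]
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel[2]
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel[3]
  cbind(rep(xs, times = dims[2] * dims[3]),
        rep(rep(ys, each = dims[1]), times = dims[3]),
        rep(zs, each = dims[1] * dims[2]))
}

# ---- samplers -------------------------------------------------------------

#' Uniform directions on the unit sphere
#' @noRd
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' von Mises-Fisher directions around a mean axis (Wood's algorithm)
#' @noRd
rvmf <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif_sphere(n))
  mu <- mu / sqrt(sum(mu^2))
  b <- (-2 * kappa + sqrt(4 * kappa^2 + 4)) / 2
  x0 <- (1 - b) / (1 + b)
  cc <- kappa * x0 + 2 * log(1 - x0^2)
  w <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- stats::rbeta(1, 1, 1)
      wi <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      u <- stats::runif(1)
      if (kappa * wi + 2 * log(1 - x0 * wi) - cc >= log(u)) { w[i] <- wi; break }
    }
  }
  # random tangent directions
  v <- runif_sphere(n)
  v <- v - outer(drop(v %*% mu), mu)
  v <- normalize_rows(v)
  sw <- sqrt(pmax(0, 1 - w^2))
  res <- v * sw + outer(w, mu)
  normalize_rows(res)
}

#' Area-uniform samples on an ellipsoid surface (rejection on the sphere map)
#' @noRd
sample_ellipsoid_surface <- function(n, radii) {
  out <- matrix(numeric(0), 0, 3)
  if (n == 0) return(out)
  srt <- sort(radii, decreasing = TRUE)
  wmax <- srt[1] * srt[2]  # envelope: largest pairwise radius product
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    u <- runif_sphere(m)
    # area element of the map u -> radii*u, up to a constant
    w <- sqrt((u[, 1] * radii[2] * radii[3])^2 +
              (u[, 2] * radii[1] * radii[3])^2 +
              (u[, 3] * radii[1] * radii[2])^2)
    keep <- stats::runif(m) < w / wmax
    out <- rbind(out, sweep(u[keep, , drop = FALSE], 2, radii, "*"))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Membrane puncta directions, optionally gathered into clusters
#' @noRd
sample_membrane_dirs <- function(n, n_clusters, kappa) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  if (n_clusters <= 0 || kappa <= 0) return(runif_sphere(n))
  axes <- runif_sphere(n_clusters)
  assign <- sample.int(n_clusters, n, replace = TRUE)
  dirs <- matrix(0, n, 3)
  for (k in seq_len(n_clusters)) {
    idx <- which(assign == k)
    if (length(idx)) dirs[idx, ] <- rvmf(length(idx), axes[k, ], kappa)
  }
  dirs
}

# ---- scene ----------------------------------------------------------------

#' Build a synthetic scene with full ground truth
#'
#' Generates puncta for each compartment (membrane shell + interior), sparse
#' cytoplasmic nanocage point sources, and -- if a distortion spec is given --
#' the displaced (post-expansion) copies of every point. Everything is
#' deterministic given `seed`.
#'
#' @param compartments List of [compartment_spec] objects (possibly empty).
#' @param nanocages A [nanocage_field_spec] or `NULL`.
#' @param distortion A [distortion_spec] or `NULL` (identity).
#' @param domain `list(lo = 3-vector, hi = 3-vector)` physical bounds in nm
#'   used for nanocage placement when the cage spec has no region.
#' @param seed Integer RNG seed.
#' @return Object of class `scene_truth` with elements:
#'   `points` (data.frame: channel, type, compartment, x, y, z, intensity),
#'   `post_points` (n x 3 displaced copies, equal to `points` coordinates if
#'   no distortion), `cage_diameters` (true nm diameters), `meshes`
#'   (list of true compartment surface meshes), `distortion`, `seed`.
#' @examples
#' sc <- build_scene(list(compartment_spec(radii = c(150, 150, 150),
#'                                         n_membrane_puncta = 50)), seed = 1)
#' nrow(sc$points)
#' @export
build_scene <- function(compartments = list(), nanocages = NULL,
                        distortion = NULL,
                        domain = list(lo = c(0, 0, 0), hi = c(2000, 2000, 2000)),
                        seed = 1) {
  stopifnot(is.list(compartments))
  for (cs in compartments) {
    if (!inherits(cs, "compartment_spec"))
      stop("each compartment must be a compartment_spec", call. = FALSE)
  }
  if (!is.null(nanocages) && !inherits(nanocages, "nanocage_field_spec"))
    stop("'nanocages' must be a nanocage_field_spec", call. = FALSE)
  if (!is.null(distortion) && !inherits(distortion, "distortion_spec"))
    stop("'distortion' must be a distortion_spec", call. = FALSE)

  res <- with_seed(seed, {
    rows <- list()
    meshes <- list()
    for (ci in seq_along(compartments)) {
      cs <- compartments[[ci]]
      if (cs$n_membrane_puncta > 0) {
        dirs <- sample_membrane_dirs(cs$n_membrane_puncta, cs$n_clusters,
                                     cs$cluster_concentration)
        if (cs$n_clusters > 0 && cs$cluster_concentration > 0) {
          pts <- sweep(dirs, 2, cs$radii, "*")
        } else {
          pts <- sample_ellipsoid_surface(cs$n_membrane_puncta, cs$radii)
        }
        pts <- sweep(pts, 2, cs$centroid, "+")
        rows[[length(rows) + 1L]] <- data.frame(
          channel = cs$channel_map$membrane %||% "membrane",
          type = "membrane", compartment = ci,
          x = pts[, 1], y = pts[, 2], z = pts[, 3], intensity = 1)
      }
      if (cs$n_interior_puncta > 0) {
        # uniform in the ellipsoid, kept strictly inside with a small margin
        u <- runif_sphere(cs$n_interior_puncta) *
          (0.97 * stats::runif(cs$n_interior_puncta)^(1 / 3))
        pts <- sweep(sweep(u, 2, cs$radii, "*"), 2, cs$centroid, "+")
        rows[[length(rows) + 1L]] <- data.frame(
          channel = cs$channel_map$interior %||% "interior",
          type = "interior", compartment = ci,
          x = pts[, 1], y = pts[, 2], z = pts[, 3], intensity = 1)
      }
      meshes[[ci]] <- ellipsoid_mesh(cs$centroid, cs$radii, level = 3)
    }
    cage_d <- numeric(0)
    if (!is.null(nanocages) && nanocages$n_cages > 0) {
      reg <- nanocages$region %||% domain
      n <- nanocages$n_cages
      pos <- cbind(stats::runif(n, reg$lo[1], reg$hi[1]),
                   stats::runif(n, reg$lo[2], reg$hi[2]),
                   stats::runif(n, reg$lo[3], reg$hi[3]))
      cage_d <- stats::rnorm(n, nanocages$diameter_mean, nanocages$diameter_sd)
      while (any(cage_d <= 0))
        cage_d[cage_d <= 0] <- stats::rnorm(sum(cage_d <= 0),
                                            nanocages$diameter_mean,
                                            nanocages$diameter_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = nanocages$channel, type = "nanocage", compartment = NA_integer_,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        intensity = nanocages$intensity)
    }
    pts <- if (length(rows)) do.call(rbind, rows) else
      data.frame(channel = character(0), type = character(0),
                 compartment = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), intensity = numeric(0))
    list(points = pts, meshes = meshes, cage_diameters = cage_d)
  })

  pre <- as.matrix(res$points[, c("x", "y", "z")])
  if (!is.null(distortion)) {
    post <- apply_distortion(pre, distortion)$points
  } else {
    post <- pre
  }
  structure(list(points = res$points, post_points = post,
                 cage_diameters = res$cage_diameters, meshes = res$meshes,
                 distortion = distortion, seed = seed),
            class = "scene_truth")
}

#' True displacement of a scene at queried pre-expansion points
#'
#' Evaluates the scene's distortion analytically; at generated points this
#' reproduces `post_points - global_factor * points` exactly (local term) or
#' the full pre-to-post offset with `total = TRUE`.
#'
#' @param scene A `scene_truth`.
#' @param pts n x 3 pre-expansion coordinates (nm).
#' @param total If `TRUE` return `post - pre`; otherwise only the local
#'   (post-registration) displacement at the scaled positions.
#' @return n x 3 matrix (nm).
#' @export
true_displacement <- function(scene, pts, total = FALSE) {
  stopifnot(inherits(scene, "scene_truth"))
  pts <- rbind(pts)
  if (is.null(scene$distortion)) {
    if (total) return(matrix(0, nrow(pts), 3))
    return(matrix(0, nrow(pts), 3))
  }
  d <- scene$distortion
  q <- pts * d$global_factor
  u <- local_displacement(d, q)
  if (total) (q + u) - pts else u
}
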
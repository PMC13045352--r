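#' Triangulated closed surface mesh
#'
#' @param vertices n x 3 matrix (nm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals for closed surfaces).
#' @return Object of class `surface_mesh` with per-face areas, centroid,
#'   watertightness and Euler characteristic precomputed.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  v0 <- vertices[faces[, 1], , drop = FALSE]
  e0 <- vertices[faces[, 2], , drop = FALSE] - v0
  e1 <- vertices[faces[, 3], , drop = FALSE] - v0
  cr <- cbind(e0[, 2] * e1[, 3] - e0[, 3] * e1[, 2],
              e0[, 3] * e1[, 1] - e0[, 1] * e1[, 3],
              e0[, 1] * e1[, 2] - e0[, 2] * e1[, 1])
  areas <- 0.5 * row_norms(cr)
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(ekey)
  watertight <- all(tab == 2L)
  euler <- nrow(vertices) - length(tab) + nrow(faces)
  structure(list(vertices = vertices, faces = faces, areas = areas,
                 centroid = colMeans(vertices), watertight = watertight,
                 euler = euler), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, area %.4g nm^2%s\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x),
              if (x$watertight) ", watertight" else ""))
  invisible(x)
}

#' Total surface area of a mesh (nm^2)
#' @param mesh A [surface_mesh].
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Enclosed volume of a closed mesh (nm^3, divergence theorem)
#' @param mesh A [surface_mesh].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
          a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
}

face_incenters <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]; B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  a <- row_norms(B - C); b <- row_norms(A - C); cc <- row_norms(A - B)
  (A * a + B * b + C * cc) / (a + b + cc)
}

# ---- icosphere ------------------------------------------------------------

#' Unit icosphere by subdivision of the icosahedron
#'
#' @param level Subdivision level (0 = icosahedron, 20 faces; each level
#'   quadruples the face count: level 3 has 1280 faces / 642 vertices).
#' @return List with `vertices` (unit directions) and `faces`.
#' @export
icosphere <- function(level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vl <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- mid[[key]]
      if (!is.null(m)) return(m)
      p <- vl[[i]] + vl[[j]]
      p <- p / sqrt(sum(p^2))
      vl[[length(vl) + 1L]] <<- p
      idx <- length(vl)
      mid[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); cc <- midpoint(k, i)
      nf <- rbind(nf, c(i, a, cc), c(j, b, a), c(k, cc, b), c(a, b, cc))
    }
    v <- do.call(rbind, vl)
    f <- nf
  }
  list(vertices = v, faces = f)
}

# ---- convex hull (quickhull) ----------------------------------------------

# 3D convex hull of a point set; returns faces as index triples with outward
# orientation. Deterministic (no RNG). Used as the "Delaunay-derived
# boundary" of each puncta subsample.
convex_hull3 <- function(P) {
  n <- nrow(P)
  if (n < 4) stop("convex hull needs >= 4 points", call. = FALSE)
  eps <- 1e-9 * max(abs(P))
  # initial extreme tetrahedron
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) stop("degenerate point set", call. = FALSE)
  d <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  t <- (rel %*% d) / sum(d^2)
  perp <- rel - outer(drop(t), d)
  i3 <- which.max(rowSums(perp^2))
  nrm <- crossv(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  h <- drop(rel %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) <= eps) stop("degenerate (coplanar) point set", call. = FALSE)
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  interior <- colMeans(P[c(i1, i2, i3, i4), ])
  orient <- function(tri) {
    nn <- crossv(P[tri[2], ] - P[tri[1], ], P[tri[3], ] - P[tri[1], ])
    if (sum(nn * (interior - P[tri[1], ])) > 0) tri[c(1, 3, 2)] else tri
  }
  faces <- t(apply(faces, 1, orient))
  fnorm <- function(tri) {
    nn <- crossv(P[tri[2], ] - P[tri[1], ], P[tri[3], ] - P[tri[1], ])
    nn / max(sqrt(sum(nn^2)), 1e-300)
  }
  norms <- t(apply(faces, 1, fnorm))
  offs <- rowSums(norms * P[faces[, 1], , drop = FALSE])
  # outside sets
  alive <- rep(TRUE, nrow(faces))
  outside <- vector("list", nrow(faces))
  assigned <- rep(FALSE, n)
  assigned[c(i1, i2, i3, i4)] <- TRUE
  for (fi in seq_len(nrow(faces))) {
    dd <- drop(P %*% norms[fi, ]) - offs[fi]
    cand <- which(!assigned & dd > eps)
    outside[[fi]] <- cand
    assigned[cand] <- TRUE
  }
  repeat {
    fi <- 0L
    for (k in seq_along(outside))
      if (alive[k] && length(outside[[k]])) { fi <- k; break }
    if (fi == 0L) break
    cand <- outside[[fi]]
    dd <- drop(P[cand, , drop = FALSE] %*% norms[fi, ]) - offs[fi]
    p <- cand[which.max(dd)]
    # visible faces
    vis <- which(alive &
                   (drop(norms %*% P[p, ]) - offs) > eps)
    if (!length(vis)) { outside[[fi]] <- setdiff(outside[[fi]], p); next }
    # horizon: edges of visible faces shared with exactly one visible face
    ed <- do.call(rbind, lapply(vis, function(k)
      rbind(faces[k, c(1, 2)], faces[k, c(2, 3)], faces[k, c(3, 1)])))
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    horiz <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    pool <- unique(unlist(outside[vis]))
    alive[vis] <- FALSE
    for (k in vis) outside[[k]] <- integer(0)
    pool <- setdiff(pool, p)
    for (e in seq_len(nrow(horiz))) {
      tri <- c(horiz[e, 1], horiz[e, 2], p)
      nn <- crossv(P[tri[2], ] - P[tri[1], ], P[tri[3], ] - P[tri[1], ])
      if (sum(nn * (interior - P[tri[1], ])) > 0) {
        tri <- tri[c(1, 3, 2)]
        nn <- -nn
      }
      nn <- nn / max(sqrt(sum(nn^2)), 1e-300)
      off <- sum(nn * P[tri[1], ])
      faces <- rbind(faces, tri)
      norms <- rbind(norms, nn)
      offs <- c(offs, off)
      alive <- c(alive, TRUE)
      if (length(pool)) {
        dd2 <- drop(P[pool, , drop = FALSE] %*% nn) - off
        take <- pool[dd2 > eps]
        outside[[length(outside) + 1L]] <- take
        pool <- setdiff(pool, take)
      } else outside[[length(outside) + 1L]] <- integer(0)
    }
  }
  faces[alive, , drop = FALSE]
}

crossv <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# radius of the hull along each direction (rays from the origin); P must be
# given relative to the ray origin, which must be interior to the hull.
# Vectorised Moller-Trumbore over the (direction x face) grid.
hull_ray_radii <- function(P, faces, dirs) {
  V0 <- P[faces[, 1], , drop = FALSE]
  E0 <- P[faces[, 2], , drop = FALSE] - V0
  E1 <- P[faces[, 3], , drop = FALSE] - V0
  N <- cbind(E0[, 2] * E1[, 3] - E0[, 3] * E1[, 2],
             E0[, 3] * E1[, 1] - E0[, 1] * E1[, 3],
             E0[, 1] * E1[, 2] - E0[, 2] * E1[, 1])
  d00 <- rowSums(E0 * E0); d01 <- rowSums(E0 * E1); d11 <- rowSums(E1 * E1)
  det <- d00 * d11 - d01^2
  NdotV0 <- rowSums(N * V0)
  UN <- dirs %*% t(N)                      # ndir x nf
  tt <- sweep(1 / UN, 2, NdotV0, "*")      # ray parameter to each face plane
  tt[!is.finite(tt) | tt <= 0] <- NA
  X_e0 <- tt * (dirs %*% t(E0))            # (t*u) . e0 per pair
  X_e1 <- tt * (dirs %*% t(E1))
  q0 <- sweep(X_e0, 2, rowSums(V0 * E0), "-")
  q1 <- sweep(X_e1, 2, rowSums(V0 * E1), "-")
  beta <- sweep(sweep(q0, 2, d11, "*") - sweep(q1, 2, d01, "*"), 2, det, "/")
  gama <- sweep(sweep(q1, 2, d00, "*") - sweep(q0, 2, d01, "*"), 2, det, "/")
  tol <- 1e-9
  hit <- !is.na(tt) & beta >= -tol & gama >= -tol & (beta + gama) <= 1 + tol
  tt[!hit] <- NA
  r <- apply(tt, 1, function(x) if (all(is.na(x))) NA_real_ else
    max(x, na.rm = TRUE))
  r
}

#' Trace an endosome limiting membrane from membrane puncta
#'
#' Reconstructs a smooth closed surface from membrane-marker puncta by an
#' iterated, averaged Delaunay-hull procedure: per iteration a random
#' fraction of the puncta is subsampled, the convex hull of the subsample is
#' built, and rays from the intensity-weighted centroid along a fixed
#' icosphere direction set are intersected with the hull to yield
#' per-direction radii; the radii are averaged over iterations, meshed on the
#' icosphere, and Laplacian-smoothed. The radial parameterisation is
#' star-shaped by construction, which deliberately excludes concave
#' topologies such as tubules or intraluminal vesicles.
#'
#' @param puncta Data frame with columns x, y, z (nm) and optionally
#'   intensity; at least 12 puncta.
#' @param n_iterations Number of subsample/hull iterations.
#' @param subsample_fraction Fraction of puncta drawn per iteration.
#' @param icosphere_level Icosphere subdivision level of the direction set.
#' @param smoothing_passes Laplacian smoothing passes (lambda = 0.5).
#' @param seed RNG seed; identical input + seed gives an identical mesh.
#' @param centroid Optional manual centroid (nm) overriding the
#'   intensity-weighted punctum mean.
#' @return A [surface_mesh]; the averaged radial field is attached as
#'   attribute `radial_field` (directions, mean radius, sample count).
#' @export
trace_endosome_surface <- function(puncta, n_iterations = 25L,
                                   subsample_fraction = 0.7,
                                   icosphere_level = 3L,
                                   smoothing_passes = 2L, seed = 1,
                                   centroid = NULL) {
  pts <- as.matrix(puncta[, c("x", "y", "z")])
  n <- nrow(pts)
  if (n < 12) stop("need >= 12 membrane puncta to trace a surface", call. = FALSE)
  w <- puncta$intensity %||% rep(1, n)
  ctr <- centroid %||% drop(colSums(pts * w) / sum(w))
  ico <- icosphere(icosphere_level)
  dirs <- ico$vertices
  rel <- sweep(pts, 2, ctr)
  reldir <- normalize_rows(rel)
  # star-shaped test: every direction must see a punctum within 60 degrees
  cosmax <- apply(dirs %*% t(reldir), 1, max)
  if (any(cosmax < cos(pi / 3)))
    stop(paste("puncta do not enclose the centroid (star-shaped test failed);",
               "supply a manual 'centroid'"), call. = FALSE)
  m <- max(4L, ceiling(subsample_fraction * n))
  acc <- matrix(0, nrow(dirs), 2)  # running sum of radii, count
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      idx <- sample.int(n, m)
      sub <- rel[idx, , drop = FALSE]
      hull <- tryCatch(convex_hull3(sub), error = function(e) NULL)
      if (is.null(hull)) next
      r <- hull_ray_radii(sub, hull, dirs)
      ok <- is.finite(r) & r > 0
      acc[ok, 1] <- acc[ok, 1] + r[ok]
      acc[ok, 2] <- acc[ok, 2] + 1
    }
  })
  if (any(acc[, 2] == 0))
    stop("some directions were never intersected; centroid may be outside the hull",
         call. = FALSE)
  radii <- acc[, 1] / acc[, 2]
  # Laplacian smoothing of the *radial field* on the icosphere graph:
  # smooths angular noise without the radial shrinkage that vertex-space
  # Laplacian smoothing inflicts on curved surfaces (a sphere is invariant)
  if (smoothing_passes > 0) {
    edges <- rbind(ico$faces[, c(1, 2)], ico$faces[, c(2, 3)],
                   ico$faces[, c(3, 1)])
    edges <- unique(rbind(edges, edges[, c(2, 1)]))
    nb <- split(edges[, 2], edges[, 1])
    nb <- nb[order(as.integer(names(nb)))]
    for (p in seq_len(smoothing_passes)) {
      mv <- vapply(nb, function(j) mean(radii[j]), numeric(1))
      radii <- 0.5 * radii + 0.5 * mv
    }
  }
  verts <- sweep(dirs * radii, 2, ctr, "+")
  mesh <- surface_mesh(verts, ico$faces)
  attr(mesh, "radial_field") <- list(directions = dirs, radius = radii,
                                     n_samples = acc[, 2])
  attr(mesh, "trace_centroid") <- ctr
  mesh
}

#' Ideal ellipsoid mesh (ground-truth compartment surface)
#' @param centroid 3-vector (nm).
#' @param radii Semi-axes (nm).
#' @param level Icosphere level.
#' @return A [surface_mesh].
#' @export
ellipsoid_mesh <- function(centroid, radii, level = 3L) {
  ico <- icosphere(level)
  surface_mesh(sweep(sweep(ico$vertices, 2, radii, "*"), 2, centroid, "+"),
               ico$faces)
}

# distances from one point to every triangle of a mesh; returns list of
# per-face distance and the closest point on the closest face
point_mesh_distance <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  V0 <- v[f[, 1], , drop = FALSE]
  V1 <- v[f[, 2], , drop = FALSE]
  V2 <- v[f[, 3], , drop = FALSE]
  E0 <- V1 - V0; E1 <- V2 - V0
  D <- sweep(-V0, 2, p, "+")  # p - V0
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); cc <- rowSums(E1 * E1)
  d <- rowSums(E0 * D); e <- rowSums(E1 * D)
  det <- pmax(a * cc - b^2, 1e-300)
  s <- (cc * d - b * e) / det
  t <- (a * e - b * d) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  # candidate: interior projection
  best_d2 <- rep(Inf, nrow(f)); bs <- s; bt <- t
  q_in <- V0 + E0 * s + E1 * t
  d2_in <- rowSums(sweep(q_in, 2, p)^2)
  best_d2[inside] <- d2_in[inside]
  # candidates: the three clamped edges
  edge_cand <- function(A, Evec) {
    ee <- rowSums(Evec * Evec)
    tt <- pmin(pmax(rowSums(sweep(-A, 2, p, "+") * Evec) / pmax(ee, 1e-300), 0), 1)
    Q <- A + Evec * tt
    rowSums(sweep(Q, 2, p)^2)
  }
  for (cand in list(list(V0, E0), list(V0, E1), list(V1, V2 - V1))) {
    d2 <- edge_cand(cand[[1]], cand[[2]])
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
  }
  best_d2
}

#' Project puncta onto a traced surface within a distance band
#'
#' Puncta whose unsigned distance to the mesh is at most `band` nm are
#' assigned to their nearest face (ties broken deterministically towards the
#' lowest face index); each projected punctum claims a surface footprint disk
#' of radius width/2. Puncta beyond the band (e.g. luminal cargo) are listed
#' separately, not dropped.
#'
#' @param mesh A watertight [surface_mesh].
#' @param puncta Data frame with x, y, z (nm) and optionally width (nm) and
#'   channel.
#' @param band Half-width of the projection band in nm (default 40).
#' @return Object of class `projection_result`: `projected` and `outside`
#'   data.frames (punctum, channel, distance_nm, face, radius_nm), `band`,
#'   and the `mesh`.
#' @export
project_nanodomains <- function(mesh, puncta, band = 40) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!mesh$watertight) stop("mesh must be watertight", call. = FALSE)
  check_scalar(band, "band", nonneg = TRUE)
  n <- nrow(puncta)
  chan <- puncta$channel %||% rep("puncta", n)
  wid <- puncta$width %||% rep(0, n)
  res <- data.frame(punctum = seq_len(n)[0], channel = character(0),
                    distance_nm = numeric(0), face = integer(0),
                    radius_nm = numeric(0))
  dist <- numeric(n); face <- integer(n)
  if (n > 0) {
    pts <- as.matrix(puncta[, c("x", "y", "z")])
    for (i in seq_len(n)) {
      d2 <- point_mesh_distance(pts[i, ], mesh)
      face[i] <- which.min(d2)  # which.min returns the lowest index on ties
      dist[i] <- sqrt(d2[face[i]])
    }
    res <- data.frame(punctum = seq_len(n), channel = chan,
                      distance_nm = dist, face = face,
                      radius_nm = ifelse(is.na(wid), 0, wid / 2))
  }
  keep <- res$distance_nm <= band + 1e-6  # tolerate on-surface round-off
  structure(list(projected = res[keep, , drop = FALSE],
                 outside = res[!keep, , drop = FALSE],
                 band = band, mesh = mesh),
            class = "projection_result")
}

#' Percent of surface area occupied by projected nanodomains, per channel
#'
#' A face counts as occupied by a channel if it is the assigned face of a
#' projected punctum or its incenter lies within a punctum's footprint disk
#' (Euclidean approximation of the geodesic disk). Occupancy is monotone in
#' the punctum set by construction.
#'
#' @param projection A [project_nanodomains] result.
#' @return Named numeric vector of percentages (one per channel).
#' @export
surface_occupancy <- function(projection) {
  stopifnot(inherits(projection, "projection_result"))
  mesh <- projection$mesh
  total <- mesh_area(mesh)
  pr <- projection$projected
  chans <- unique(pr$channel)
  if (!length(chans)) return(stats::setNames(numeric(0), character(0)))
  inc <- face_incenters(mesh)
  out <- stats::setNames(numeric(length(chans)), chans)
  # punctum footprint centres: closest surface points approximated by the
  # face incenter of the assigned face plus the punctum position
  for (ch in chans) {
    rows <- pr[pr$channel == ch, , drop = FALSE]
    occ <- rep(FALSE, nrow(mesh$faces))
    occ[rows$face] <- TRUE
    if (any(rows$radius_nm > 0)) {
      ctrs <- inc[rows$face, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        r <- rows$radius_nm[k]
        if (r <= 0) next
        d2 <- rowSums(sweep(inc, 2, ctrs[k, ])^2)
        occ <- occ | d2 <= r^2
      }
    }
    out[ch] <- 100 * sum(mesh$areas[occ]) / total
  }
  out
}

#' Percent of a cross-sectional ROI occupied by a channel mask
#'
#' @param channel_mask Logical matrix (TRUE where the marker is present).
#' @param endosome_roi Logical matrix of the same shape delimiting the
#'   endosome cross-section; must be non-empty.
#' @return Percentage `100 * |mask & roi| / |roi|`.
#' @export
cross_section_occupancy <- function(channel_mask, endosome_roi) {
  stopifnot(is.logical(channel_mask) || all(channel_mask %in% c(0, 1)),
            identical(dim(channel_mask), dim(endosome_roi)))
  roi_n <- sum(endosome_roi)
  if (roi_n == 0) stop("empty endosome ROI", call. = FALSE)
  100 * sum(channel_mask & endosome_roi) / roi_n
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh A [surface_mesh].
#' @param path Output file.
#' @param face_props Optional data.frame of per-face properties (numeric)
#'   written as extra face properties.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, face_props = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices",
               if (!is.null(face_props))
                 sprintf("property float %s", names(face_props)),
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  fc <- cbind(3L, mesh$faces - 1L)
  if (!is.null(face_props)) fc <- cbind(fc, as.matrix(face_props))
  writeLines(apply(fc, 1, paste, collapse = " "), con)
  invisible(path)
}
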
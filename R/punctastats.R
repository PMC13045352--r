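# 3D connected components: slice-wise labelling merged across z with a
# union-find, 6/26-connectivity in-plane via EBImage, face-connectivity in z
label_components3 <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    l <- EBImage::bwlabel(mask[, , z])
    nl <- max(l)
    l[l > 0] <- l[l > 0] + offset
    labs[, , z] <- l
    offset <- offset + as.integer(nl)
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]
    i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (z in seq_len(d[3] - 1L)) {
    a <- labs[, , z]; b <- labs[, , z + 1L]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pr <- unique(cbind(a[both], b[both]))
    for (r in seq_len(nrow(pr))) union(pr[r, 1], pr[r, 2])
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  labs[labs > 0L] <- relab[labs[labs > 0L]]
  labs
}

#' Segment puncta in a calibrated volume
#'
#' Background subtraction (large-sigma Gaussian high-pass, slice-wise),
#' robust seeding at local intensity maxima above `k_seed` MADs, a
#' `k_mask`-MAD foreground mask, 3D connected components split between seeds
#' by nearest-seed assignment, and a physical size filter. All geometry is in
#' nm, so the volume must be EF-calibrated first (see [calibrate_scale]).
#'
#' @param vol A calibrated [image_volume].
#' @param scale Expected punctum FWHM in nm (sets the smoothing and
#'   background scales).
#' @param k_seed Seed floor in MADs above the median.
#' @param k_mask Foreground-mask floor in MADs above the median.
#' @param size_range Accepted punctum volume range `c(min, max)` in nm^3
#'   (`NULL` disables).
#' @param merge_elongation In-plane elongation (sqrt of the intensity
#'   covariance eigenvalue ratio) above which a region is flagged as a
#'   possible unresolved pair.
#' @param channel Channel label attached to the output.
#' @return data.frame of class `puncta_set`: punctum, channel, x, y, z (nm),
#'   width_nm (fitted in-focus FWHM), volume_nm3, intensity,
#'   flagged_merge (elongated regions that may be unresolved pairs).
#' @export
segment_puncta <- function(vol, scale = 60, k_seed = 7, k_mask = 3,
                           size_range = NULL, merge_elongation = 1.25,
                           channel = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  voxvol <- prod(vol$voxel)
  sig_px <- max(fwhm_to_sigma(scale) / vol$voxel[1], 0.6)
  sm <- vol$data; bg <- vol$data
  for (z in seq_len(d[3])) {
    sm[, , z] <- gaussian_blur2(vol$data[, , z], sig_px)
    bg[, , z] <- gaussian_blur2(vol$data[, , z], 5 * sig_px)
  }
  hp <- sm - bg        # smoothed high-pass: seeds and mask
  raw <- vol$data - bg  # unsmoothed high-pass: widths and intensities
  med <- stats::median(hp)
  sdev <- max(mad_scale(as.vector(hp)), 1e-12)
  seeds <- which(hp > med + k_seed * sdev & local_max3(hp))
  if (length(seeds) > 1) {
    # non-maximum suppression: one seed per `scale`-sized neighbourhood
    ord <- order(hp[seeds], decreasing = TRUE)
    seeds <- seeds[ord]
    spos <- index_to_phys(vol, arrayInd(seeds, d))
    keep <- rep(TRUE, length(seeds))
    for (i in seq_len(length(seeds) - 1L)) {
      if (!keep[i]) next
      later <- (i + 1L):length(seeds)
      dd <- sqrt(rowSums(sweep(spos[later, , drop = FALSE], 2, spos[i, ])^2))
      keep[later[dd < 0.75 * scale]] <- FALSE
    }
    seeds <- seeds[keep]
  }
  if (!length(seeds)) {
    message("segment_puncta: zero seeds, returning empty set")
    return(empty_puncta())
  }
  mask <- hp > med + k_mask * sdev
  labs <- label_components3(mask)
  seed_lab <- labs[seeds]
  keep_regions <- unique(seed_lab[seed_lab > 0])
  seed_pos <- index_to_phys(vol, arrayInd(seeds, d))
  rows <- list()
  pid <- 0L
  for (rg in keep_regions) {
    vox <- which(labs == rg)
    rseeds <- which(seed_lab == rg)
    sub <- arrayInd(vox, d)
    pos <- index_to_phys(vol, sub)
    inten <- pmax(raw[vox], 0)
    if (length(rseeds) > 1) {
      # split the region between its seeds by nearest-seed assignment
      sp <- seed_pos[rseeds, , drop = FALSE]
      assign <- RANN::nn2(sp, pos, k = 1)$nn.idx[, 1]
    } else assign <- rep(1L, length(vox))
    for (si in seq_along(rseeds)) {
      sel <- assign == si
      if (!any(sel)) next
      pid <- pid + 1L
      rows[[pid]] <- summarize_punctum(vol, raw, vox[sel], pos[sel, , drop = FALSE],
                                       inten[sel], voxvol, sig_px,
                                       merge_elongation)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(size_range))
    out <- out[out$volume_nm3 >= size_range[1] & out$volume_nm3 <= size_range[2],
               , drop = FALSE]
  if (!is.null(channel)) out$channel <- channel else
    out$channel <- if (nzchar(vol$channel)) vol$channel else "puncta"
  out$punctum <- seq_len(nrow(out))
  out <- out[, c("punctum", "channel", "x", "y", "z", "width_nm",
                 "volume_nm3", "intensity", "flagged_merge")]
  class(out) <- c("puncta_set", "data.frame")
  out
}

summarize_punctum <- function(vol, hp, vox, pos, inten, voxvol, sig_px,
                              merge_elongation) {
  d <- dim(vol$data)
  tw <- sum(inten)
  cen <- if (tw > 0) colSums(pos * inten) / tw else colMeans(pos)
  # in-focus plane: z index with the strongest summed signal
  zidx <- arrayInd(vox, d)[, 3]
  zbest <- as.integer(names(which.max(tapply(inten, zidx, sum))))
  ci <- phys_to_index(vol, matrix(cen, 1))
  win <- max(3L, ceiling(4 * sig_px))
  x0 <- max(1, round(ci[1]) - win); x1 <- min(d[1], round(ci[1]) + win)
  y0 <- max(1, round(ci[2]) - win); y1 <- min(d[2], round(ci[2]) + win)
  crop <- hp[x0:x1, y0:y1, zbest]
  ft <- fit_gaussian2d(crop)
  width <- FWHM_FACTOR * ft$sigma * vol$voxel[1]
  # in-plane elongation from intensity moments (unresolved-pair heuristic)
  inplane <- pos[, 1:2, drop = FALSE]
  elong <- 1
  if (nrow(inplane) >= 3) {
    cv <- stats::cov.wt(inplane, wt = inten / sum(inten), method = "ML")$cov
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] > 1e-12) elong <- sqrt(ev[1] / ev[2])
  }
  data.frame(x = cen[1], y = cen[2], z = cen[3], width_nm = width,
             volume_nm3 = length(vox) * voxvol, intensity = tw,
             flagged_merge = elong > merge_elongation)
}

empty_puncta <- function() {
  out <- data.frame(punctum = integer(0), channel = character(0),
                    x = numeric(0), y = numeric(0), z = numeric(0),
                    width_nm = numeric(0), volume_nm3 = numeric(0),
                    intensity = numeric(0), flagged_merge = logical(0))
  class(out) <- c("puncta_set", "data.frame")
  out
}

#' Nearest-neighbour distances from one punctum set to another
#'
#' One distance per source punctum (centroid to centroid, 3D, nm);
#' asymmetric by design (source to target).
#'
#' @param source,target Data frames with x, y, z columns (nm); target must
#'   be non-empty.
#' @return Numeric vector, one distance per source row.
#' @examples
#' nearest_neighbor_distances(data.frame(x = 0, y = 0, z = 0),
#'                            data.frame(x = c(30, 100), y = c(40, 0),
#'                                       z = c(0, 0)))  # 50
#' @export
nearest_neighbor_distances <- function(source, target) {
  if (!nrow(target)) stop("target punctum set is empty", call. = FALSE)
  if (!nrow(source)) return(numeric(0))
  s <- as.matrix(source[, c("x", "y", "z")])
  t <- as.matrix(target[, c("x", "y", "z")])
  RANN::nn2(t, s, k = 1)$nn.dists[, 1]
}

#' Total-volume and count ratios between two punctum sets
#'
#' @param a,b [segment_puncta]-style data frames with `volume_nm3`; `b` must
#'   be non-empty with positive total volume.
#' @return List `volume_ratio` (sum vol a / sum vol b) and `count_ratio`.
#' @export
ratio_stats <- function(a, b) {
  if (!nrow(b) || sum(b$volume_nm3) <= 0)
    stop("reference punctum set 'b' is empty", call. = FALSE)
  list(volume_ratio = if (nrow(a) > 0)
         sum(a$volume_nm3) / sum(b$volume_nm3) else 0,
       count_ratio = nrow(a) / nrow(b))
}

#' Moment-preserving (Tsai) automatic threshold
#'
#' Picks the threshold that preserves the image's first three gray-level
#' moments in the binarized image, computed on the 8-bit-quantized histogram
#' (linear min-max scaling): the moment-matching equations give the target
#' below-threshold fraction p0 and the threshold is the gray level whose
#' cumulative histogram is closest to p0. This is the "Moments" auto
#' threshold of common image-analysis software.
#'
#' @param image Numeric vector, matrix or array with >= 2 distinct values.
#' @return Threshold on the original intensity scale; the foreground mask is
#'   `image > threshold`. The quantized level and p0 are attached as
#'   attributes.
#' @export
moments_threshold <- function(image) {
  x <- as.vector(image)
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) <= 0)
    stop("image has < 2 distinct gray levels", call. = FALSE)
  lev <- round((x - rng[1]) / diff(rng) * 255)
  p <- tabulate(lev + 1L, nbins = 256L) / length(lev)
  z <- 0:255
  m1 <- sum(z * p); m2 <- sum(z^2 * p); m3 <- sum(z^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(pmax(c1^2 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc)
  z1 <- 0.5 * (-c1 + disc)
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  t_idx <- which.min(abs(cum - p0)) - 1L   # gray level, 0-based
  thr <- rng[1] + (t_idx + 0.5) * diff(rng) / 255
  structure(thr, level = t_idx, p0 = p0)
}

#' Manders overlap percentages with automatic moment thresholds
#'
#' Builds foreground masks for both channels with [moments_threshold] (on the
#' full 3D stack by default, or per 2D plane) and reports the percentage of
#' each channel's mask overlapping the other:
#' `%A->B = 100 * |maskA & maskB| / |maskA|`. An empty mask makes that
#' direction undefined (NA), never 0.
#'
#' @param volA,volB [image_volume]s or plain arrays on the same grid.
#' @param mode `"3d"` (one threshold per stack, default) or `"per_plane"`.
#' @param keep_masks Store the binary masks in the result (default TRUE) so
#'   the percentages are exactly recomputable.
#' @return Object of class `manders_result`: percentages, thresholds, mask
#'   pixel counts, overlap count, and optionally the masks.
#' @export
manders_percent <- function(volA, volB, mode = c("3d", "per_plane"),
                            keep_masks = TRUE) {
  mode <- match.arg(mode)
  a <- if (inherits(volA, "image_volume")) volA$data else volA
  b <- if (inherits(volB, "image_volume")) volB$data else volB
  stopifnot(identical(dim(a), dim(b)))
  mk <- function(x) {
    if (mode == "3d" || length(dim(x)) < 3) {
      thr <- moments_threshold(x)
      list(mask = x > thr, thr = as.numeric(thr))
    } else {
      d <- dim(x)
      m <- array(FALSE, d); thr <- numeric(d[3])
      for (z in seq_len(d[3])) {
        pl <- x[, , z]
        if (diff(range(pl)) <= 0) { thr[z] <- NA; next }
        t1 <- moments_threshold(pl)
        m[, , z] <- pl > t1; thr[z] <- as.numeric(t1)
      }
      list(mask = m, thr = thr)
    }
  }
  ma <- mk(a); mb <- mk(b)
  na <- sum(ma$mask); nb <- sum(mb$mask); nov <- sum(ma$mask & mb$mask)
  structure(list(
    percent_a_in_b = if (na > 0) 100 * nov / na else NA_real_,
    percent_b_in_a = if (nb > 0) 100 * nov / nb else NA_real_,
    threshold_a = ma$thr, threshold_b = mb$thr,
    n_a = na, n_b = nb, n_overlap = nov, mode = mode,
    mask_a = if (keep_masks) ma$mask, mask_b = if (keep_masks) mb$mask),
    class = "manders_result")
}

#' @export
print.manders_result <- function(x, ...) {
  cat(sprintf("Manders overlap: A in B %.2f%%, B in A %.2f%% (|A|=%d, |B|=%d)\n",
              x$percent_a_in_b, x$percent_b_in_a, x$n_a, x$n_b))
  invisible(x)
}

#' Chord-diagram table from occupancies and pairwise colocalization
#'
#' Assigns each marker an arc proportional to its mean pixel occupancy and
#' tabulates every directed colocalization percentage for external chord
#' plotting.
#'
#' @param occupancy Named numeric vector of per-marker occupancy percentages
#'   (> 0 for every marker appearing in `coloc`).
#' @param coloc Data frame with columns `from`, `to`, `percent`: the percent
#'   of `from`-marker pixels overlapping the `to` marker. Must contain every
#'   ordered pair of distinct markers exactly once (may be empty for a single
#'   marker).
#' @return Object of class `chord_table`: `arcs` (fractions summing to 1) and
#'   `pairs`.
#' @export
chord_table <- function(occupancy, coloc = data.frame(from = character(0),
                                                      to = character(0),
                                                      percent = numeric(0))) {
  stopifnot(!is.null(names(occupancy)), all(occupancy > 0))
  markers <- names(occupancy)
  need <- expand.grid(from = markers, to = markers,
                      stringsAsFactors = FALSE)
  need <- need[need$from != need$to, , drop = FALSE]
  have <- paste(coloc$from, coloc$to)
  missing <- need[!paste(need$from, need$to) %in% have, , drop = FALSE]
  if (nrow(missing))
    stop("missing colocalization pair(s): ",
         paste(missing$from, "->", missing$to, collapse = ", "), call. = FALSE)
  extra <- coloc[!(coloc$from %in% markers & coloc$to %in% markers), ,
                 drop = FALSE]
  if (nrow(extra))
    stop("colocalization pairs reference unknown markers", call. = FALSE)
  structure(list(arcs = occupancy / sum(occupancy),
                 pairs = coloc[order(coloc$from, coloc$to), , drop = FALSE]),
            class = "chord_table")
}

#' Percent change between two scalars
#'
#' @param before,after Scalars; `before` must be non-zero.
#' @return `100 * (after - before) / before`.
#' @examples
#' percent_change(32, 44)  # 37.5
#' @export
percent_change <- function(before, after) {
  check_scalar(before, "before")
  check_scalar(after, "after")
  if (before == 0) stop("'before' must be non-zero", call. = FALSE)
  100 * (after - before) / before
}

#' Width from manual ellipse axes
#'
#' The operational width of a torus-shaped compartment fitted with an
#' ellipse: the average of the major and minor axes.
#'
#' @param major,minor Axis lengths in nm (vectorised). If `major < minor`
#'   the pair is swapped with a warning.
#' @return `(major + minor) / 2`.
#' @examples
#' ellipse_width(300, 260)  # 280
#' @export
ellipse_width <- function(major, minor) {
  stopifnot(length(major) == length(minor))
  if (any(major <= 0) || any(minor <= 0))
    stop("axes must be > 0", call. = FALSE)
  if (any(major < minor)) {
    warning("major < minor for some entries: swapping")
  }
  (pmax(major, minor) + pmin(major, minor)) / 2
}
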
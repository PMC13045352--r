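#' 3D intensity volume with physical voxel size
#'
#' The universal raster container of the toolkit: a 3D numeric array indexed
#' `[ix, iy, iz]` together with a per-axis voxel size in nm and an optional
#' physical origin. The physical centre of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 0.5) * voxel`, i.e. voxel centres sit at half-voxel
#' offsets from the origin, matching the convention used by every module.
#'
#' @param data Numeric 3D array (x, y, z order). A matrix is promoted to a
#'   single-plane volume.
#' @param voxel Numeric 3-vector of voxel edge lengths in nm (x, y, z), all
#'   positive.
#' @param channel Optional channel label (marker name).
#' @param origin Physical position (nm) of the low corner of voxel (1,1,1).
#' @param meta Named list of free-form metadata (calibration provenance etc.).
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), voxel = c(40, 40, 150))
#' dim(v$data)
#' @export
image_volume <- function(data, voxel, channel = "", origin = c(0, 0, 0),
                         meta = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D numeric array", call. = FALSE)
  storage.mode(data) <- "double"
  voxel <- check_vec3(voxel, "voxel", positive = TRUE)
  origin <- check_vec3(origin, "origin")
  structure(list(data = data, voxel = voxel, channel = as.character(channel),
                 origin = origin, meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_volume %dx%dx%d voxels, voxel %.4g x %.4g x %.4g nm%s\n",
    d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
    if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Physical voxel-centre coordinates along one axis
#'
#' @param vol An [image_volume].
#' @param axis 1, 2 or 3 (x, y, z).
#' @return Numeric vector of centre positions in nm.
#' @export
voxel_centers <- function(vol, axis) {
  stopifnot(inherits(vol, "image_volume"), axis %in% 1:3)
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel[axis]
}

#' Physical extent of a volume
#' @param vol An [image_volume].
#' @return 3-vector of physical edge lengths in nm.
#' @export
volume_extent <- function(vol) dim(vol$data) * vol$voxel

#' Convert physical coordinates (nm) to fractional voxel indices
#'
#' Fractional 1-based indices such that an integer value lands exactly on a
#' voxel centre.
#' @noRd
phys_to_index <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$voxel, "/") + 0.5
}

#' Convert fractional voxel indices to physical coordinates (nm)
#' @noRd
index_to_phys <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 0.5, 2, vol$voxel, "*"), 2, vol$origin, "+")
}

#' Trilinear interpolation of a volume at physical points
#'
#' @param vol An [image_volume].
#' @param pts n x 3 matrix of physical coordinates in nm.
#' @param outside Value returned for points outside the grid.
#' @return Numeric vector of length n.
#' @export
interp_volume <- function(vol, pts, outside = 0) {
  d <- dim(vol$data)
  ix <- phys_to_index(vol, pts)
  out <- numeric(nrow(ix))
  # clamp the half-voxel border so edge voxels are usable
  lo <- pmax(pmin(ix, rep(d, each = nrow(ix))), 1)
  inside <- ix[, 1] >= 0.5 & ix[, 1] <= d[1] + 0.5 &
    ix[, 2] >= 0.5 & ix[, 2] <= d[2] + 0.5 &
    ix[, 3] >= 0.5 & ix[, 3] <= d[3] + 0.5
  out[!inside] <- outside
  if (!any(inside)) return(out)
  p <- lo[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(p), 1), rep(d - 1L, each = nrow(p)))
  f <- p - i0
  f[f < 0] <- 0; f[f > 1] <- 1
  g <- function(a, b, c) vol$data[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + c)]
  v <- g(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    g(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    g(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    g(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    g(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    g(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    g(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
  out[inside] <- v
  out
}
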
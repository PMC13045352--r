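#' 3D distortion field on a voxel grid
#'
#' Per-voxel 3-vector displacement (nm) relating registered pre-expansion
#' structure to its post-expansion position, with a validity mask marking
#' voxels where the displacement was actually measured (signal present in
#' both volumes).
#'
#' @param ux,uy,uz 3D arrays of displacement components in nm, same dims.
#' @param voxel Voxel size 3-vector (nm).
#' @param origin Physical origin (nm).
#' @param mask Logical array of the same dims; `NULL` means all valid.
#' @return Object of class `distortion_field`.
#' @export
distortion_field <- function(ux, uy, uz, voxel, origin = c(0, 0, 0),
                             mask = NULL) {
  stopifnot(identical(dim(ux), dim(uy)), identical(dim(ux), dim(uz)),
            length(dim(ux)) == 3L)
  voxel <- check_vec3(voxel, "voxel", positive = TRUE)
  if (is.null(mask)) mask <- array(TRUE, dim(ux))
  stopifnot(identical(dim(mask), dim(ux)))
  if (any(!is.finite(ux[mask])) || any(!is.finite(uy[mask])) ||
      any(!is.finite(uz[mask])))
    stop("displacements must be finite where valid", call. = FALSE)
  structure(list(ux = ux, uy = uy, uz = uz, voxel = voxel,
                 origin = check_vec3(origin, "origin"), mask = mask),
            class = "distortion_field")
}

#' @export
print.distortion_field <- function(x, ...) {
  d <- dim(x$ux)
  m <- sqrt(x$ux[x$mask]^2 + x$uy[x$mask]^2 + x$uz[x$mask]^2)
  cat(sprintf("distortion_field %dx%dx%d, %.1f%% valid, |u| median %.3g nm\n",
              d[1], d[2], d[3], 100 * mean(x$mask),
              if (length(m)) stats::median(m) else NA_real_))
  invisible(x)
}

#' Displacement magnitude map of a field
#' @param field A [distortion_field].
#' @return 3D array of |u| in nm (NA where invalid).
#' @export
field_magnitude <- function(field) {
  stopifnot(inherits(field, "distortion_field"))
  m <- sqrt(field$ux^2 + field$uy^2 + field$uz^2)
  m[!field$mask] <- NA_real_
  m
}

#' Distortion RMSE versus length scale
#'
#' For each sampling scale L, draws `n_pairs` valid voxel pairs (p, q) with
#' physical separation within `[L(1-delta), L(1+delta)]` and computes the
#' pair error `e = |u(p) - u(q)|`; `RMSE(L) = sqrt(mean(e^2))` and the
#' percent error is `100 * RMSE(L) / L`. The pair-differential definition is
#' invariant to any uniform residual shift left by registration; the raw
#' per-voxel magnitude variant is available with `method = "magnitude"`.
#' Length scales are on the post-expansion physical scale.
#'
#' @param field A [distortion_field].
#' @param scales Increasing vector of length scales (nm).
#' @param n_pairs Pairs sampled per scale (>= 100).
#' @param seed RNG seed (sampling is deterministic given the seed).
#' @param delta Relative half-width of the separation band (default 0.1).
#' @param method `"pairs"` (default) or `"magnitude"` (RMS of |u| over valid
#'   voxels, identical at every scale; kept for comparison).
#' @return data.frame of class `rmse_curve`: scale_nm, rmse_nm, percent,
#'   n_pairs, ok (FALSE where fewer than 10 valid pairs were found).
#' @export
rmse_vs_length_scale <- function(field, scales, n_pairs = 1000, seed = 1,
                                 delta = 0.1, method = c("pairs", "magnitude")) {
  stopifnot(inherits(field, "distortion_field"))
  method <- match.arg(method)
  scales <- as.numeric(scales)
  if (length(scales) > 1 && any(diff(scales) <= 0))
    stop("'scales' must be strictly increasing", call. = FALSE)
  if (n_pairs < 100) stop("'n_pairs' must be >= 100", call. = FALSE)
  dims <- dim(field$ux)
  valid_idx <- which(field$mask)
  if (length(valid_idx) < 2) stop("field has < 2 valid voxels", call. = FALSE)
  vcoord <- arrayInd(valid_idx, dims)
  if (method == "magnitude") {
    m <- sqrt(field$ux[valid_idx]^2 + field$uy[valid_idx]^2 +
              field$uz[valid_idx]^2)
    rmse <- sqrt(mean(m^2))
    return(structure(data.frame(scale_nm = scales, rmse_nm = rmse,
                                percent = 100 * rmse / scales,
                                n_pairs = length(m), ok = TRUE),
                     class = c("rmse_curve", "data.frame")))
  }
  res <- with_seed(seed, {
    out <- vector("list", length(scales))
    for (si in seq_along(scales)) {
      L <- scales[si]
      got_p <- integer(0); got_q <- integer(0)
      tries <- 0L
      while (length(got_p) < n_pairs && tries < 60L) {
        tries <- tries + 1L
        m <- 4L * (n_pairs - length(got_p))
        pi_ <- sample(length(valid_idx), m, replace = TRUE)
        dirs <- runif_sphere(m)
        r <- L * stats::runif(m, 1 - delta, 1 + delta)
        pj <- vcoord[pi_, , drop = FALSE]
        qj <- round(pj + dirs * r / rep(field$voxel, each = m))
        okq <- qj[, 1] >= 1 & qj[, 1] <= dims[1] &
          qj[, 2] >= 1 & qj[, 2] <= dims[2] &
          qj[, 3] >= 1 & qj[, 3] <= dims[3]
        d_act <- sqrt(rowSums(((qj - pj) *
                                 rep(field$voxel, each = m))^2))
        okd <- d_act >= L * (1 - delta) & d_act <= L * (1 + delta)
        keep <- which(okq & okd)
        if (!length(keep)) next
        qlin <- (qj[keep, 3] - 1L) * dims[1] * dims[2] +
          (qj[keep, 2] - 1L) * dims[1] + qj[keep, 1]
        okm <- field$mask[qlin]
        keep <- keep[okm]
        got_p <- c(got_p, valid_idx[pi_[keep]])
        got_q <- c(got_q, (qj[keep, 3] - 1L) * dims[1] * dims[2] +
                     (qj[keep, 2] - 1L) * dims[1] + qj[keep, 1])
      }
      np <- min(length(got_p), n_pairs)
      if (np < 10) {
        out[[si]] <- data.frame(scale_nm = L, rmse_nm = NA_real_,
                                percent = NA_real_, n_pairs = np, ok = FALSE)
        next
      }
      p <- got_p[seq_len(np)]; q <- got_q[seq_len(np)]
      e2 <- (field$ux[p] - field$ux[q])^2 + (field$uy[p] - field$uy[q])^2 +
        (field$uz[p] - field$uz[q])^2
      rmse <- sqrt(mean(e2))
      out[[si]] <- data.frame(scale_nm = L, rmse_nm = rmse,
                              percent = 100 * rmse / L, n_pairs = np, ok = TRUE)
    }
    do.call(rbind, out)
  })
  structure(res, class = c("rmse_curve", "data.frame"))
}

#' Signed radial component of a distortion field
#'
#' Projects each voxel's displacement onto the unit radial direction from a
#' centroid; negative values mean shifts toward the centroid, i.e. local
#' under-expansion of the compartment.
#'
#' @param field A [distortion_field].
#' @param centroid 3-vector (nm) inside the grid.
#' @return 3D array of signed radial components (nm; NA where invalid).
#' @export
radial_component_map <- function(field, centroid) {
  stopifnot(inherits(field, "distortion_field"))
  centroid <- check_vec3(centroid, "centroid")
  dims <- dim(field$ux)
  ext <- dims * field$voxel
  rel <- centroid - field$origin
  if (any(rel < 0) || any(rel > ext))
    stop("'centroid' must lie inside the field grid", call. = FALSE)
  xs <- field$origin[1] + (seq_len(dims[1]) - 0.5) * field$voxel[1] - centroid[1]
  ys <- field$origin[2] + (seq_len(dims[2]) - 0.5) * field$voxel[2] - centroid[2]
  zs <- field$origin[3] + (seq_len(dims[3]) - 0.5) * field$voxel[3] - centroid[3]
  RX <- array(xs, dims)
  RY <- array(rep(ys, each = dims[1]), dims)
  RZ <- array(rep(zs, each = dims[1] * dims[2]), dims)
  rn <- sqrt(RX^2 + RY^2 + RZ^2)
  rn[rn == 0] <- Inf  # radial direction undefined at the centroid voxel
  out <- (field$ux * RX + field$uy * RY + field$uz * RZ) / rn
  out[!field$mask] <- NA_real_
  out
}
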
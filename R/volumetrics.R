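#' Resample a dose grid onto a target frame by trilinear interpolation
#'
#' Interpolates the dose at every target voxel center. Points outside the
#' support of the source grid receive 0 Gy (conservative convention: clinical
#' dose grids cover the treated region). Trilinear interpolation is exact for
#' fields affine in the source index coordinates.
#'
#' @param dose a [dose_grid()].
#' @param target an [image_frame()].
#' @return a [dose_grid()] on `target`.
#' @export
resample_dose_to_frame <- function(dose, target) {
  stopifnot(inherits(dose, "dose_grid"), is_image_frame(target))
  if (frames_identical(dose$frame, target))
    return(dose_grid(target, dose$values, dose$prescription_dose))
  xyz <- voxel_centers(target)
  vals <- trilinear_sample(dose$values, dose$frame, xyz)
  dose_grid(target, array(vals, dim = target$shape), dose$prescription_dose)
}

trilinear_sample <- function(values, frame, xyz) {
  ijk <- world_to_index(frame, xyz)
  n <- frame$shape
  i0 <- floor(ijk)
  f <- ijk - i0
  out <- numeric(nrow(ijk))
  # outside support (allow half-voxel fringe handled by clamping corners below)
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= n[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= n[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= n[3]
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  f <- f[inside, , drop = FALSE]
  acc <- numeric(nrow(i0))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ci <- pmin(pmax(i0[, 1] + dx, 1), n[1])
    cj <- pmin(pmax(i0[, 2] + dy, 1), n[2])
    ck <- pmin(pmax(i0[, 3] + dz, 1), n[3])
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    acc <- acc + w * values[cbind(ci, cj, ck)]
  }
  out[inside] <- acc
  out
}

#' Rasterise a contour set onto a frame
#'
#' A voxel is set iff its center lies inside the polygon(s) of the nearest
#' contour plane (within half the slice spacing; ties between two voxel planes
#' are assigned to the lower-index plane). Multiple polygons on one plane
#' combine by the even-odd rule, so holes are excluded. Requires an
#' axis-aligned target frame.
#'
#' @param contours a [contour_set()].
#' @param target an [image_frame()] with identity direction.
#' @return a [binary_volume()].
#' @export
rasterize_contours <- function(contours, target) {
  stopifnot(inherits(contours, "contour_set"), is_image_frame(target))
  if (!is_axis_aligned(target))
    stop("rasterize_contours requires an axis-aligned frame")
  if (length(contours$contours) == 0) stop("empty contour set")
  n <- target$shape
  xc <- target$origin[1] + (seq_len(n[1]) - 1) * target$spacing[1]
  yc <- target$origin[2] + (seq_len(n[2]) - 1) * target$spacing[2]
  zc <- target$origin[3] + (seq_len(n[3]) - 1) * target$spacing[3]
  mask <- array(FALSE, dim = n)
  zs <- vapply(contours$contours, `[[`, numeric(1), "z")
  if (max(zs) < min(zc) - target$spacing[3] / 2 ||
      min(zs) > max(zc) + target$spacing[3] / 2)
    stop("contour z-range does not overlap the target frame")
  for (ci in seq_along(contours$contours)) {
    cc <- contours$contours[[ci]]
    dz <- abs(zc - cc$z)
    if (min(dz) > target$spacing[3] / 2 + 1e-9) next
    # tie (contour exactly midway between voxel planes) -> lower-index plane
    k <- which(dz <= min(dz) + 1e-9)[1]
    inside <- pip_grid(cc$xy[, 1], cc$xy[, 2], xc, yc)
    mask[, , k] <- xor(mask[, , k], inside)      # even-odd across polygons
  }
  binary_volume(target, mask)
}

#' Segment bone from a HU volume by thresholding
#'
#' Keeps `HU >= hu_threshold`, optionally intersected with a region-of-interest
#' mask, then restricted to the largest 26-connected component (removes
#' disconnected bony fragments such as the hyoid or spine when a loose ROI is
#' used).
#'
#' @param hu_volume 3D array of Hounsfield units.
#' @param frame an [image_frame()].
#' @param hu_threshold HU threshold (default 300, cancellous bone and above).
#' @param roi_mask optional [binary_volume()] in the same frame.
#' @return a [binary_volume()].
#' @export
segment_bone <- function(hu_volume, frame, hu_threshold = 300, roi_mask = NULL) {
  stopifnot(is.finite(hu_threshold))
  mask <- hu_volume >= hu_threshold
  if (!is.null(roi_mask)) {
    if (!frames_identical(frame, roi_mask$frame)) stop_frame_mismatch("HU volume and ROI mask")
    mask <- mask & roi_mask$mask
  }
  if (!any(mask)) stop("no bone above threshold ", hu_threshold, " HU")
  lab <- cc_label_26(as.logical(mask), as.integer(dim(mask)))
  counts <- tabulate(lab)
  keep <- which.max(counts)
  binary_volume(frame, array(lab == keep, dim = dim(mask)))
}

#' Isodose region: the volume receiving at least a threshold dose
#'
#' The region mask is `dose >= threshold` (inclusive). Regions from the same
#' dose grid are nested: a higher threshold yields a subset of a lower one.
#'
#' @param dose a [dose_grid()].
#' @param threshold dose in Gy (> 0); 56 Gy is the margin-planning threshold
#'   used throughout the analysis.
#' @return an object of class `isodose_volume` with fields `threshold`,
#'   `region` ([binary_volume()]) and `source = "dose_threshold"`.
#' @export
isodose_region <- function(dose, threshold) {
  stopifnot(inherits(dose, "dose_grid"), threshold > 0)
  structure(list(threshold = threshold,
                 region = binary_volume(dose$frame, dose$values >= threshold),
                 source = "dose_threshold"),
            class = "isodose_volume")
}

#' Isodose region from exported isodose contours
#'
#' The RTSTRUCT route: vendor planning systems can export an isodose line as a
#' structure set; rasterising those contours gives the same kind of region as
#' thresholding the dose grid.
#'
#' @param contours a [contour_set()] tracing the isodose surface.
#' @param target an [image_frame()].
#' @param threshold nominal dose level of the contours in Gy.
#' @return an `isodose_volume` with `source = "contour"`.
#' @export
isodose_from_contours <- function(contours, target, threshold) {
  structure(list(threshold = threshold,
                 region = rasterize_contours(contours, target),
                 source = "contour"),
            class = "isodose_volume")
}

#' @export
print.isodose_volume <- function(x, ...) {
  cat("<isodose_volume> >= ", x$threshold, " Gy (", x$source, "): ",
      signif(volume_ml(x$region), 4), " mL\n", sep = "")
  invisible(x)
}

as_mask <- function(x) {
  if (inherits(x, "isodose_volume")) x$region
  else if (inherits(x, "binary_volume")) x
  else stop("expected a binary_volume or isodose_volume")
}

#' Volume of a voxel mask in millilitres
#' @param v a [binary_volume()] (or `isodose_volume`).
#' @return volume in mL (voxel count x voxel volume).
#' @export
volume_ml <- function(v) {
  v <- as_mask(v)
  sum(v$mask) * voxel_volume_mm3(v$frame) / 1000
}

#' Voxelwise intersection of two masks
#' @param a,b [binary_volume()] objects on the same frame.
#' @return a [binary_volume()].
#' @export
intersect_volumes <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!frames_identical(a$frame, b$frame)) stop_frame_mismatch("the two masks")
  binary_volume(a$frame, a$mask & b$mask)
}

#' Extract the iso-surface of a binary mask as a triangle mesh
#'
#' Runs marching tetrahedra at the 0/1 midpoint of the (optionally Gaussian
#' smoothed) indicator, on a zero-padded copy of the mask so that regions
#' touching the array border still close. Vertices are in patient mm; the mesh
#' is watertight by construction.
#'
#' @param v a [binary_volume()] with at least one voxel set.
#' @param iso_level iso value on the indicator, default 0.5.
#' @param smooth_sigma standard deviation in voxels of an optional separable
#'   Gaussian smoothing of the indicator before extraction (0 = none).
#' @return a [surface_mesh()].
#' @export
mesh_from_mask <- function(v, iso_level = 0.5, smooth_sigma = 0) {
  v <- as_mask(v)
  if (!any(v$mask)) stop("empty mask")
  n <- dim(v$mask)
  vol <- array(0, dim = n + 2L)
  vol[2:(n[1] + 1), 2:(n[2] + 1), 2:(n[3] + 1)] <- as.numeric(v$mask)
  if (smooth_sigma > 0) vol <- gaussian_smooth3(vol, smooth_sigma)
  res <- marching_tetra(as.numeric(vol), as.integer(dim(vol)), iso_level)
  # padded zero-based index coords -> original 1-based index -> world
  ijk <- res$vertices  # zero-based in padded grid; original index = coord - 1 + 1
  verts <- index_to_world(v$frame, ijk)
  surface_mesh(verts, res$faces, closed = TRUE)
}

gaussian_smooth3 <- function(vol, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(a, dim_along) {
    out <- array(0, dim = dim(a))
    for (o in seq(-r, r)) {
      w <- k[o + r + 1]
      idx <- switch(dim_along,
        `1` = list(shift_index(dim(a)[1], o), TRUE, TRUE),
        `2` = list(TRUE, shift_index(dim(a)[2], o), TRUE),
        `3` = list(TRUE, TRUE, shift_index(dim(a)[3], o)))
      out <- out + w * a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    out
  }
  vol <- sm1(vol, 1); vol <- sm1(vol, 2); sm1(vol, 3)
}

shift_index <- function(n, o) pmin(pmax(seq_len(n) + o, 1L), n)
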
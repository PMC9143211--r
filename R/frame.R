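#' Image frame: the common patient-space lattice
#'
#' An `image_frame` fixes the geometry every voxel object in the package lives
#' in: the position of the first voxel center (`origin`, mm, DICOM LPS patient
#' coordinates), the voxel pitch along each axis (`spacing`, mm), the voxel
#' counts (`shape`) and an orthonormal `direction` matrix whose columns are the
#' patient-space directions of the array axes. All downstream geometry
#' (dose resampling, rasterisation, resection planes, meshes) is expressed in
#' this frame so that quantities derived from CT, RTDOSE and RTSTRUCT agree.
#'
#' @param origin numeric length-3, patient-space position of voxel (1,1,1) in mm.
#' @param spacing numeric length-3, strictly positive voxel pitch in mm.
#' @param shape integer length-3, voxels per axis (each >= 1).
#' @param direction 3x3 orthonormal matrix (|det| = 1 within 1e-6); columns are
#'   the patient-space unit vectors of the array axes. Defaults to identity
#'   (axis-aligned LPS).
#' @return an object of class `image_frame`.
#' @export
image_frame <- function(origin, spacing, shape, direction = diag(3)) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L)
    stop("origin, spacing and shape must each have length 3")
  if (any(!is.finite(origin)) || any(!is.finite(spacing)))
    stop("origin and spacing must be finite")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (any(shape < 1L)) stop("shape must be >= 1 per axis")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    stop("direction must be orthonormal (|det| = 1 within 1e-6)")
  structure(
    list(origin = origin, spacing = spacing, shape = shape,
         direction = direction),
    class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat("<image_frame> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  origin (", paste(signif(x$origin, 6), collapse = ", "),
      ") mm", if (is_axis_aligned(x)) ", axis-aligned" else ", oblique",
      "\n", sep = "")
  invisible(x)
}

is_image_frame <- function(x) inherits(x, "image_frame")

#' Voxel volume of a frame in cubic millimetres
#' @param frame an [image_frame()].
#' @return scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(frame) prod(frame$spacing)

is_axis_aligned <- function(frame, tol = 1e-9) {
  max(abs(abs(frame$direction) - diag(3))) <= tol
}

#' Convert 1-based voxel indices to patient-space coordinates
#'
#' @param frame an [image_frame()].
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices;
#'   fractional indices address points between voxel centers.
#' @return n x 3 matrix of mm coordinates.
#' @export
index_to_world <- function(frame, ijk) {
  ijk <- rbind_matrix(ijk)
  sp <- frame$spacing; o <- frame$origin
  if (is_axis_aligned(frame)) {
    return(cbind((ijk[, 1] - 1) * sp[1] + o[1],
                 (ijk[, 2] - 1) * sp[2] + o[2],
                 (ijk[, 3] - 1) * sp[3] + o[3]))
  }
  steps <- cbind((ijk[, 1] - 1) * sp[1], (ijk[, 2] - 1) * sp[2],
                 (ijk[, 3] - 1) * sp[3])
  xyz <- steps %*% t(frame$direction)
  xyz[, 1] <- xyz[, 1] + o[1]; xyz[, 2] <- xyz[, 2] + o[2]
  xyz[, 3] <- xyz[, 3] + o[3]
  xyz
}

#' Convert patient-space coordinates to continuous 1-based voxel indices
#' @param frame an [image_frame()].
#' @param xyz n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return n x 3 matrix of continuous 1-based indices.
#' @export
world_to_index <- function(frame, xyz) {
  xyz <- rbind_matrix(xyz)
  o <- frame$origin; sp <- frame$spacing
  d <- cbind(xyz[, 1] - o[1], xyz[, 2] - o[2], xyz[, 3] - o[3]) %*%
    frame$direction
  cbind(d[, 1] / sp[1], d[, 2] / sp[2], d[, 3] / sp[3]) + 1
}

rbind_matrix <- function(x) {
  if (is.matrix(x) && ncol(x) == 3L) {
    if (!is.double(x)) storage.mode(x) <- "double"
    return(x)
  }
  matrix(as.numeric(x), ncol = 3)
}

#' Patient-space coordinates of every voxel center
#'
#' Returns the coordinates in array order (first axis fastest), i.e. row `s`
#' corresponds to linear array index `s`.
#' @param frame an [image_frame()].
#' @return (prod(shape)) x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(frame) {
  n <- frame$shape
  if (is_axis_aligned(frame)) {
    xs <- frame$origin[1] + (seq_len(n[1]) - 1) * frame$spacing[1]
    ys <- frame$origin[2] + (seq_len(n[2]) - 1) * frame$spacing[2]
    zs <- frame$origin[3] + (seq_len(n[3]) - 1) * frame$spacing[3]
    out <- matrix(0, prod(n), 3)
    out[, 1] <- rep.int(xs, n[2] * n[3])
    out[, 2] <- rep.int(rep(ys, each = n[1]), n[3])
    out[, 3] <- rep(zs, each = n[1] * n[2])
    return(out)
  }
  ijk <- cbind(
    rep.int(seq_len(n[1]), n[2] * n[3]),
    rep.int(rep(seq_len(n[2]), each = n[1]), n[3]),
    rep(seq_len(n[3]), each = n[1] * n[2]))
  index_to_world(frame, ijk)
}

#' Test whether two frames describe the same lattice
#' @param a,b [image_frame()] objects.
#' @param tol mm tolerance on origin/spacing and on direction entries.
#' @return logical.
#' @export
frames_identical <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

stop_frame_mismatch <- function(what) {
  stop(what, " are defined on different frames; resample to a common frame ",
       "first (see resample_dose_to_frame / rasterize_contours)", call. = FALSE)
}
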
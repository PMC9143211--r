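#' Dose grid: a scalar radiotherapy dose field on a voxel lattice
#'
#' @param frame an [image_frame()].
#' @param values 3D numeric array of absorbed dose in Gy, dimension equal to
#'   `frame$shape`. Values must be finite and non-negative, already scaled to
#'   Gy (i.e. any file scaling factor applied).
#' @param prescription_dose optional prescribed dose in Gy.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(frame, values, prescription_dose = NULL) {
  stopifnot(is_image_frame(frame))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(frame$shape)))
    stop("dose array dimension does not match frame shape")
  if (any(!is.finite(values))) stop("dose values must be finite")
  if (any(values < 0)) stop("dose values must be non-negative")
  structure(list(frame = frame, values = values,
                 prescription_dose = prescription_dose),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, dose range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "] Gy\n", sep = "")
  invisible(x)
}

#' Binary volume: a voxel mask in a reference frame
#'
#' The common representation of every region in the analysis: the mandible,
#' isodose regions, PTV, resected and residual segments.
#'
#' @param frame an [image_frame()].
#' @param mask 3D logical array with dimension `frame$shape`.
#' @return an object of class `binary_volume`.
#' @export
binary_volume <- function(frame, mask) {
  stopifnot(is_image_frame(frame))
  mask <- as.array(mask)
  if (!identical(dim(mask), as.integer(frame$shape)))
    stop("mask dimension does not match frame shape")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
    if (anyNA(mask)) stop("mask must not contain NA")
  }
  structure(list(frame = frame, mask = mask), class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("<binary_volume> ", sum(x$mask), " of ", length(x$mask),
      " voxels set (", signif(volume_ml(x), 4), " mL)\n", sep = "")
  invisible(x)
}

#' Contour set: stacked planar polygons of one structure
#'
#' The in-memory form of one RTSTRUCT ROI: closed planar polygons at sorted
#' z-positions, coordinates in patient mm.
#'
#' @param name structure label.
#' @param contours list of `list(z = <mm>, xy = <n x 2 matrix of mm vertices>)`;
#'   polygons are implicitly closed (last vertex joins the first) and must have
#'   at least 3 distinct vertices.
#' @param frame optional [image_frame()] the contours reference.
#' @return an object of class `contour_set`.
#' @export
contour_set <- function(name, contours, frame = NULL) {
  if (length(contours) == 0L) stop("empty contour set")
  contours <- lapply(contours, function(cc) {
    xy <- matrix(as.numeric(cc$xy), ncol = 2)
    # drop an explicit closing vertex
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(unique(xy)) < 3) stop("contour polygons need >= 3 distinct vertices")
    list(z = as.numeric(cc$z), xy = xy)
  })
  contours <- contours[order(vapply(contours, `[[`, numeric(1), "z"))]
  structure(list(name = name, contours = contours, frame = frame),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  zs <- vapply(x$contours, `[[`, numeric(1), "z")
  cat("<contour_set> '", x$name, "': ", length(x$contours),
      " polygons, z in [", min(zs), ", ", max(zs), "] mm\n", sep = "")
  invisible(x)
}

#' Triangular surface mesh in patient space
#'
#' @param vertices n x 3 matrix of mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices; triangles are
#'   oriented with outward normals.
#' @param closed logical, whether the mesh is asserted watertight.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, closed = NA) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("degenerate faces (repeated vertex index)")
  }
  structure(list(vertices = vertices, faces = faces, closed = closed),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (isTRUE(x$closed)) ", watertight" else "", "\n", sep = "")
  invisible(x)
}

#' Check watertightness: every edge shared by exactly two faces
#' @param mesh a [surface_mesh()].
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Enclosed volume of a closed mesh via the divergence theorem
#' @param mesh a [surface_mesh()] with outward-oriented faces.
#' @return volume in mL.
#' @export
mesh_volume_ml <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
                 b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
                 b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(rowSums(a * cross)) / 6) / 1000
}
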
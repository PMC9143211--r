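#' Midline curve of the mandibular arch
#'
#' Defines which side of the arch is lingual (tongue-facing, radially inner /
#' concave) and which is buccal (cheek-facing, outer / convex). The axial
#' occupancy of the mask (projection along z) is fitted with a least-squares
#' circle; a smoothing spline of radius versus arch angle then gives the
#' midline radius at every angle. A point is lingual when its radial distance
#' from the arch center is below the midline radius at its angle.
#'
#' @param mandible a [binary_volume()] in an axis-aligned frame.
#' @return an object of class `arch_midline` with the circle center, the
#'   fitted spline and the angular support.
#' @export
mandible_midline <- function(mandible) {
  mandible <- as_mask(mandible)
  if (!is_axis_aligned(mandible$frame))
    stop("midline extraction requires an axis-aligned frame")
  occ <- apply(mandible$mask, c(1, 2), any)
  if (!any(occ)) stop("empty mandible mask")
  idx <- which(occ, arr.ind = TRUE)
  x <- mandible$frame$origin[1] + (idx[, 1] - 1) * mandible$frame$spacing[1]
  y <- mandible$frame$origin[2] + (idx[, 2] - 1) * mandible$frame$spacing[2]
  ctr <- fit_circle(x, y)
  theta <- atan2(y - ctr[2], x - ctr[1])
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  if (stats::sd(r) < 1e-9) stop("degenerate midline: no radial extent")
  # place the branch cut of the angle in the largest angular gap so the arch
  # is contiguous in theta
  ord <- order(theta)
  gaps <- diff(c(theta[ord], theta[ord][1] + 2 * pi))
  cut <- theta[ord][which.max(gaps)] + max(gaps) / 2
  theta_c <- (theta - cut) %% (2 * pi)
  fit <- tryCatch(stats::smooth.spline(theta_c, r, df = min(8, length(unique(theta_c)) - 1)),
                  error = function(e) stop("degenerate midline: ", conditionMessage(e)))
  structure(list(center = ctr, cut = cut, fit = fit,
                 theta_range = range(theta_c)),
            class = "arch_midline")
}

fit_circle <- function(x, y) {
  # Kasa least-squares circle: x^2 + y^2 + D x + E y + F = 0
  a <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coefs <- stats::lm.fit(a, b)$coefficients
  c(-coefs[1] / 2, -coefs[2] / 2)
}

#' Which side of the arch midline are points on?
#' @param midline an `arch_midline` from [mandible_midline()].
#' @param xyz n x 3 matrix of mm coordinates.
#' @return logical vector, `TRUE` where lingual (inner side).
#' @export
is_lingual <- function(midline, xyz) {
  xyz <- rbind_matrix(xyz)
  dx <- xyz[, 1] - midline$center[1]
  dy <- xyz[, 2] - midline$center[2]
  theta_c <- (atan2(dy, dx) - midline$cut) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  rmid <- stats::predict(midline$fit, theta_c)$y
  r < rmid
}

#' Classify an osteotomy plane by cortical involvement with the 56 Gy volume
#'
#' Takes the voxels of the irradiated mandibular volume (`vm56`) lying within
#' half a voxel diagonal of the plane and inside the cortical shell (the outer
#' `shell_mm` of the mandible), splits them into lingual and buccal by the arch
#' midline, and reports the category: `outside` (no contact), `lingual_only`,
#' `buccal_only`, or `bicortical`. Contact areas are voxel counts times the
#' in-plane voxel area.
#'
#' For resections without an explicit bone-cutting plane (e.g. condylar
#' removal) pass `plane = NULL` together with `residual`: by convention such a
#' case counts as bicortical involvement whenever irradiated mandibular volume
#' remains after resection, with areas measured on the resection boundary.
#'
#' @param plane a [resection_plane()], or `NULL` for the no-plane convention.
#' @param vm56 [binary_volume()]: mandible voxels receiving >= 56 Gy.
#' @param mandible [binary_volume()] of the full mandible (same frame).
#' @param shell_mm cortical shell thickness in mm (default 2).
#' @param midline optional [mandible_midline()]; computed from `mandible` when
#'   omitted.
#' @param residual optional [binary_volume()], required when `plane` is `NULL`.
#' @return an object of class `cortical_classification` with fields
#'   `category`, `lingual_area_mm2`, `buccal_area_mm2`.
#' @export
classify_osteotomy <- function(plane, vm56, mandible, shell_mm = 2,
                               midline = NULL, residual = NULL) {
  vm56 <- as_mask(vm56); mandible <- as_mask(mandible)
  if (!frames_identical(vm56$frame, mandible$frame))
    stop_frame_mismatch("vm56 and mandible")
  frame <- mandible$frame
  shell <- cortical_shell(mandible, shell_mm)
  if (is.null(plane)) {
    if (is.null(residual)) stop("no-plane classification requires the residual mask")
    res56 <- vm56$mask & residual$mask
    if (!any(res56)) return(cortical_classification("outside", 0, 0))
    # boundary of the residual toward the removed side
    removed <- mandible$mask & !residual$mask
    interface <- residual$mask & neighbour_any(removed) & vm56$mask & shell$mask
    area_per <- voxel_volume_mm3(frame)^(2 / 3)
    n_int <- sum(interface)
    return(cortical_classification("bicortical",
                                   n_int * area_per / 2, n_int * area_per / 2))
  }
  stopifnot(inherits(plane, "resection_plane"))
  half_slab <- sqrt(sum(frame$spacing^2)) / 2
  cand <- vm56$mask & shell$mask
  if (!any(cand)) return(cortical_classification("outside", 0, 0))
  xyz <- index_to_world(frame, which(cand, arr.ind = TRUE))
  d <- abs(plane_signed_distance(plane, xyz))
  inslab <- d <= half_slab
  if (!any(inslab)) return(cortical_classification("outside", 0, 0))
  if (is.null(midline)) midline <- mandible_midline(mandible)
  ling <- is_lingual(midline, xyz[inslab, , drop = FALSE])
  area_per <- voxel_volume_mm3(frame) / (2 * half_slab)
  la <- sum(ling) * area_per
  ba <- sum(!ling) * area_per
  cat_name <- if (la > 0 && ba > 0) "bicortical"
    else if (la > 0) "lingual_only"
    else "buccal_only"
  cortical_classification(cat_name, la, ba)
}

cortical_classification <- function(category, lingual, buccal) {
  structure(list(category = category,
                 lingual_area_mm2 = lingual,
                 buccal_area_mm2 = buccal),
            class = "cortical_classification")
}

#' @export
print.cortical_classification <- function(x, ...) {
  cat("<cortical_classification> ", x$category,
      " (lingual ", signif(x$lingual_area_mm2, 4), " mm2, buccal ",
      signif(x$buccal_area_mm2, 4), " mm2)\n", sep = "")
  invisible(x)
}

#' Cortical shell of a bone mask
#'
#' The outer `shell_mm` of the mask: voxels removed by erosion with a ball of
#' radius `shell_mm`.
#'
#' @param mandible a [binary_volume()].
#' @param shell_mm shell thickness in mm.
#' @return a [binary_volume()].
#' @export
cortical_shell <- function(mandible, shell_mm = 2) {
  mandible <- as_mask(mandible)
  sp <- mandible$frame$spacing
  r <- floor(shell_mm / sp)
  offs <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  keep <- (offs$di * sp[1])^2 + (offs$dj * sp[2])^2 + (offs$dk * sp[3])^2 <= shell_mm^2
  offs <- as.matrix(offs[keep, , drop = FALSE])
  eroded <- erode_offsets(as.logical(mandible$mask),
                          as.integer(dim(mandible$mask)), offs)
  binary_volume(mandible$frame,
                mandible$mask & !array(eroded, dim = dim(mandible$mask)))
}
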
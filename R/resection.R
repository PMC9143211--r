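#' Osteotomy plane
#'
#' An oriented plane describing one bone cut: a point on the plane and the unit
#' normal pointing into the resected segment.
#'
#' @param point length-3 mm coordinates of a point on the plane.
#' @param normal length-3 direction; normalised internally, must be non-zero.
#' @return an object of class `resection_plane`.
#' @export
resection_plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3, length(normal) == 3, all(is.finite(point)),
            all(is.finite(normal)))
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / nn),
            class = "resection_plane")
}

#' Signed distance of points from a plane (positive on the resected side)
#' @param plane a [resection_plane()].
#' @param xyz n x 3 matrix of mm coordinates.
#' @return numeric vector of signed distances in mm.
#' @export
plane_signed_distance <- function(plane, xyz) {
  xyz <- rbind_matrix(xyz)
  p <- plane$point; n <- plane$normal
  (xyz[, 1] - p[1]) * n[1] + (xyz[, 2] - p[2]) * n[2] +
    (xyz[, 3] - p[3]) * n[3]
}

#' Resection specification: the set of osteotomy planes of one operation
#'
#' In the default `halfspace` mode the resected segment is the set of voxels on
#' the resected side of every plane (intersection of half-spaces) -- the usual
#' two-plane segmental resection. In `seed` mode the planes act as cuts: voxels
#' are grouped by their pattern of plane sides and the resected segment is the
#' connected group containing `seed_point` (used e.g. for condylar segments
#' where half-space intersection is ambiguous).
#'
#' @param planes list of [resection_plane()] (at least one), or a single plane.
#' @param mode `"halfspace"` (default) or `"seed"`.
#' @param seed_point length-3 mm point inside the segment to remove
#'   (required in seed mode).
#' @return an object of class `resection_spec`.
#' @export
resection_spec <- function(planes, mode = c("halfspace", "seed"),
                           seed_point = NULL) {
  if (inherits(planes, "resection_plane")) planes <- list(planes)
  stopifnot(length(planes) >= 1,
            all(vapply(planes, inherits, logical(1), "resection_plane")))
  mode <- match.arg(mode)
  if (mode == "seed" && is.null(seed_point))
    stop("seed mode requires seed_point")
  structure(list(planes = planes, mode = mode,
                 seed_point = if (!is.null(seed_point)) as.numeric(seed_point)),
            class = "resection_spec")
}

#' Apply a virtual segmental resection to a bone mask
#'
#' Partitions the mandible mask exactly into a resected and a residual segment
#' (`resected | residual == mandible`, `resected & residual == empty`).
#' Membership is decided at voxel centers; centers exactly on a plane belong to
#' the resected side (signed distance >= 0).
#'
#' @param mandible a [binary_volume()].
#' @param spec a [resection_spec()].
#' @return list with `resected` and `residual` [binary_volume()] objects.
#' @export
apply_resection <- function(mandible, spec) {
  mandible <- as_mask(mandible)
  stopifnot(inherits(spec, "resection_spec"))
  xyz <- voxel_centers(mandible$frame)
  if (spec$mode == "halfspace") {
    sel <- rep(TRUE, nrow(xyz))
    for (pl in spec$planes) sel <- sel & (plane_signed_distance(pl, xyz) >= 0)
    resected_mask <- array(sel, dim = dim(mandible$mask)) & mandible$mask
  } else {
    # group voxels by the pattern of plane sides, keep the connected group
    # holding the seed
    sig <- rep(0L, nrow(xyz))
    for (i in seq_along(spec$planes))
      sig <- sig * 2L + as.integer(plane_signed_distance(spec$planes[[i]], xyz) >= 0)
    seed_sig <- 0L
    for (i in seq_along(spec$planes))
      seed_sig <- seed_sig * 2L +
        as.integer(plane_signed_distance(spec$planes[[i]],
                                         matrix(spec$seed_point, 1)) >= 0)
    cand <- array(sig == seed_sig, dim = dim(mandible$mask)) & mandible$mask
    if (!any(cand)) {
      warning("empty resected segment")
      resected_mask <- array(FALSE, dim = dim(mandible$mask))
    } else {
      lab <- array(cc_label_26(as.logical(cand), as.integer(dim(cand))),
                   dim = dim(cand))
      seed_idx <- round(world_to_index(mandible$frame, spec$seed_point))
      seed_idx <- pmin(pmax(seed_idx, 1), matrix(mandible$frame$shape, 1))
      seed_lab <- lab[seed_idx[1], seed_idx[2], seed_idx[3]]
      if (seed_lab == 0L) {
        # seed voxel itself off the candidate set: take nearest labelled voxel
        w <- which(lab > 0L)
        xyzc <- xyz[w, , drop = FALSE]
        d2 <- rowSums(sweep(xyzc, 2, spec$seed_point, `-`)^2)
        seed_lab <- lab[w[which.min(d2)]]
      }
      resected_mask <- array(lab == seed_lab, dim = dim(cand))
    }
  }
  if (!any(resected_mask)) warning("empty resected segment")
  list(resected = binary_volume(mandible$frame, resected_mask),
       residual = binary_volume(mandible$frame, mandible$mask & !resected_mask))
}

#' Recover osteotomy planes from pre- and post-operative masks
#'
#' Finds the material removed (`preop & !postop`), takes its boundary voxels
#' adjacent to retained bone, estimates a local cut normal per boundary voxel
#' from the principal axes of its neighbourhood, clusters boundary voxels into
#' `n_planes` cuts (k-means on position plus scaled orientation), and fits a
#' total-least-squares plane per cluster. Normals are oriented toward the
#' removed segment's interior.
#'
#' @param preop,postop_registered [binary_volume()] objects on one frame;
#'   `postop` is the registered post-operative (residual) bone.
#' @param n_planes number of cut planes to recover.
#' @return a [resection_spec()] (halfspace mode) with an `rms_mm` attribute
#'   giving the per-plane RMS distance of boundary voxels from their plane.
#' @export
fit_cut_planes <- function(preop, postop_registered, n_planes = 2) {
  preop <- as_mask(preop); postop <- as_mask(postop_registered)
  if (!frames_identical(preop$frame, postop$frame))
    stop_frame_mismatch("preop and postop masks")
  removed <- preop$mask & !postop$mask
  if (!any(removed)) stop("no resection detected (postop covers preop)")
  # two-sided cut interface: removed voxels with a retained 6-neighbour plus
  # retained voxels with a removed 6-neighbour -- the true plane runs between
  # the two layers, so their joint centroid is unbiased
  boundary <- (removed & neighbour_any(postop$mask)) |
    (postop$mask & preop$mask & neighbour_any(removed))
  if (!any(boundary)) stop("no cut interface found between removed and retained bone")
  idx <- which(boundary, arr.ind = TRUE)
  xyz <- index_to_world(preop$frame, idx)
  if (nrow(xyz) > 1500) {            # plane fits saturate well below this
    keep <- round(seq(1, nrow(xyz), length.out = 1500))
    xyz <- xyz[keep, , drop = FALSE]
  }
  removed_centroid <- colMeans(index_to_world(preop$frame, which(removed, arr.ind = TRUE)))
  normals <- local_plane_normals(xyz, k = min(12L, nrow(xyz)))
  # orient toward removed interior
  flip <- rowSums(normals * sweep(-xyz, 2, removed_centroid, `+`)) < 0
  normals[flip, ] <- -normals[flip, ]
  scale_mm <- max(apply(xyz, 2, function(v) diff(range(v)))) / 2
  feat <- cbind(xyz, normals * scale_mm)
  cl <- if (n_planes == 1) rep(1L, nrow(feat)) else
    stats::kmeans(feat, centers = n_planes, nstart = 10, iter.max = 50)$cluster
  planes <- vector("list", n_planes)
  rms <- numeric(n_planes)
  for (g in seq_len(n_planes)) {
    pts <- xyz[cl == g, , drop = FALSE]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    nrm <- sv$v[, 3]
    if (sum(nrm * (removed_centroid - ctr)) < 0) nrm <- -nrm
    planes[[g]] <- resection_plane(ctr, nrm)
    rms[g] <- sqrt(mean((sweep(pts, 2, ctr) %*% nrm)^2))
  }
  spec <- resection_spec(planes)
  attr(spec, "rms_mm") <- rms
  spec
}

neighbour_any <- function(mask) {
  n <- dim(mask)
  out <- array(FALSE, dim = n)
  shift <- function(m, d, o) {
    r <- array(FALSE, dim = n)
    src <- lapply(seq_along(n), function(a) seq_len(n[a]))
    dst <- src
    if (o == 1) { dst[[d]] <- 2:n[d]; src[[d]] <- 1:(n[d] - 1) }
    else { dst[[d]] <- 1:(n[d] - 1); src[[d]] <- 2:n[d] }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (d in 1:3) for (o in c(1, -1)) out <- out | shift(mask, d, o)
  out
}

local_plane_normals <- function(xyz, k = 12L) {
  # k nearest neighbours by brute force (point sets subsampled upstream)
  n <- nrow(xyz)
  normals <- matrix(0, n, 3)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nbrs <- order(d2[i, ])[seq_len(min(k, n))]
    pts <- xyz[nbrs, , drop = FALSE]
    sv <- svd(sweep(pts, 2, colMeans(pts)))
    normals[i, ] <- sv$v[, 3]
  }
  normals
}
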
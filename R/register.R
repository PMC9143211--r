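#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with det = +1 (within 1e-6).
#' @param translation length-3 mm vector.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with det = +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a [rigid_transform()].
#' @param xyz n x 3 matrix of mm coordinates.
#' @return n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- rbind_matrix(xyz)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()] equal to applying `b` then `a`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Rotation angle of a rigid transform in degrees
#' @param transform a [rigid_transform()].
#' @return scalar angle in degrees.
#' @export
rotation_angle_deg <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' Rigid registration of two surface meshes by iterative closest point
#'
#' Initialised by centroid + principal-axes alignment (trying the four proper
#' axis-sign combinations and keeping the best), then refined by
#' point-to-point ICP with a Kabsch solve per iteration. Optionally trims the
#' worst matches each iteration for partial-overlap robustness.
#'
#' @param moving,fixed [surface_mesh()] objects (vertices are used as point
#'   clouds; both are subsampled to at most `max_points`).
#' @param init optional [rigid_transform()] initial guess; default is the
#'   principal-axes alignment.
#' @param max_iter maximum ICP iterations.
#' @param tol convergence tolerance on the RMS change in mm.
#' @param trim fraction (0,1] of best matches kept in each solve; 1 = no
#'   trimming.
#' @param max_points subsampling cap for the moving cloud.
#' @param max_fixed_points subsampling cap for the fixed cloud (kept dense so
#'   nearest-distance RMS has no sampling floor).
#' @return list with `transform` (moving -> fixed), `rms_mm` (RMS distance of
#'   kept matches at convergence), `converged`, `warning_flag`,
#'   `overlap_fraction` (share of moving points within 2 mm of fixed after
#'   registration) and `rms_history`.
#' @export
register_rigid <- function(moving, fixed, init = NULL, max_iter = 60,
                           tol = 1e-7, trim = 1, max_points = 1000,
                           max_fixed_points = 30000) {
  mv <- subsample_points(moving$vertices, max_points)
  fx <- subsample_points(fixed$vertices, max_fixed_points)
  if (nrow(mv) == 0 || nrow(fx) == 0) stop("empty mesh")
  base_init <- if (!is.null(init)) init else init_principal_axes(mv, fx)
  fnorm <- vertex_normals(fixed)
  fn <- if (!is.null(fnorm))
    subsample_points(cbind(fixed$vertices, fnorm), max_fixed_points)
  # one candidate = point-to-point ICP followed by a point-to-plane polish;
  # point-to-point alone stalls at the vertex-spacing scale, and partial
  # overlaps can leave the principal-axes start in a shallow local minimum,
  # hence the deterministic jittered restarts
  run_candidate <- function(tf0) {
    res <- icp_refine(mv, fx, tf0, max_iter, tol, trim)
    if (!is.null(fnorm)) {
      pol <- point_to_plane_refine(mv, fn[, 1:3, drop = FALSE],
                                   fn[, 4:6, drop = FALSE], res$tf, trim = trim)
      res$tf <- pol$tf
      res$rms_history <- c(res$rms_history, pol$rms_history)
      res$rms <- pol$rms_history[length(pol$rms_history)]
    }
    res
  }
  best <- run_candidate(base_init)
  if (is.null(init) && best$rms > 0.05) {
    ctr <- colMeans(mv)
    # include half-turns: near-symmetric shapes (a horseshoe is almost mirror
    # symmetric) have deep mirrored local minima that small jitters cannot leave
    combos <- expand.grid(ax = 1:3,
                          a = c(180, 90, -90, 10, -10, 20, -20, 30, -30,
                                45, -45) * pi / 180)
    for (i in seq_len(nrow(combos))) {
      rot <- axis_rotation(diag(3)[, combos$ax[i]], combos$a[i])
      jit <- rigid_transform(rot, ctr - drop(rot %*% ctr))
      res <- run_candidate(compose_transforms(jit, base_init))
      if (res$rms < best$rms) best <- res
      if (best$rms <= 0.05) break
    }
  }
  tf <- best$tf
  rms_history <- best$rms_history
  converged <- best$converged
  cur <- apply_transform(tf, mv)
  nn <- nn_grid(cur, fx)
  overlap <- mean(nn$dist < 2)
  list(transform = tf, rms_mm = rms_history[length(rms_history)],
       converged = converged, warning_flag = !converged || overlap < 0.1,
       overlap_fraction = overlap, rms_history = rms_history)
}

axis_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

icp_refine <- function(mv, fx, tf, max_iter, tol, trim) {
  rms_history <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(tf, mv)
    nn <- nn_grid(cur, fx)
    keep <- seq_len(nrow(cur))
    if (trim < 1) {
      kcount <- max(3L, floor(trim * length(keep)))
      keep <- order(nn$dist)[seq_len(kcount)]
    }
    rms <- sqrt(mean(nn$dist[keep]^2))
    rms_history <- c(rms_history, rms)
    step <- kabsch(cur[keep, , drop = FALSE],
                   fx[nn$idx[keep], , drop = FALSE])
    tf <- compose_transforms(step, tf)
    if (abs(prev_rms - rms) < tol) { converged <- TRUE; break }
    prev_rms <- rms
  }
  list(tf = tf, rms = rms_history[length(rms_history)],
       converged = converged, rms_history = rms_history)
}

#' Register two resected segments independently to one fixed model
#'
#' Used when the post-operative mandible changed shape (e.g. after free-flap
#' reconstruction) so that a single rigid fit cannot hold: each segment is
#' registered on its own.
#'
#' @param segments list of two [surface_mesh()] objects.
#' @param fixed the fixed [surface_mesh()] (pre-operative model).
#' @param ... passed to [register_rigid()].
#' @return list of two [register_rigid()] results; each carries its own RMS
#'   and `warning_flag` (set when the segment overlaps less than 10% of the
#'   fixed model after registration).
#' @export
register_two_segment <- function(segments, fixed, ...) {
  stopifnot(length(segments) == 2)
  lapply(segments, register_rigid, fixed = fixed, ...)
}

vertex_normals <- function(mesh) {
  f <- mesh$faces
  if (is.null(f) || nrow(f) < 4) return(NULL)
  v <- mesh$vertices
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])   # area-weighted
  # accumulate face normals onto vertices
  nrm <- matrix(0, nrow(v), 3)
  for (k in 1:3) for (d in 1:3) {
    acc <- rowsum(fn[, d], f[, k])
    nrm[as.integer(rownames(acc)), d] <- nrm[as.integer(rownames(acc)), d] + acc
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

point_to_plane_refine <- function(mv, fxv, fxn, tf, max_iter = 30,
                                  tol = 1e-9, trim = 1) {
  rms_history <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(tf, mv)
    nn <- nn_grid(cur, fxv)
    q <- fxv[nn$idx, , drop = FALSE]
    n <- fxn[nn$idx, , drop = FALSE]
    r <- rowSums((cur - q) * n)
    keep <- seq_along(r)
    if (trim < 1)
      keep <- order(abs(r))[seq_len(max(6L, floor(trim * length(r))))]
    rms <- sqrt(mean(r[keep]^2))
    rms_history <- c(rms_history, rms)
    cxn <- cbind(cur[keep, 2] * n[keep, 3] - cur[keep, 3] * n[keep, 2],
                 cur[keep, 3] * n[keep, 1] - cur[keep, 1] * n[keep, 3],
                 cur[keep, 1] * n[keep, 2] - cur[keep, 2] * n[keep, 1])
    J <- cbind(cxn, n[keep, , drop = FALSE])
    A <- crossprod(J)
    b <- -crossprod(J, r[keep])
    x <- tryCatch(solve(A + diag(1e-9, 6), b), error = function(e) NULL)
    if (is.null(x)) break
    omega <- x[1:3]
    ang <- sqrt(sum(omega^2))
    rot <- if (ang > 1e-12) axis_rotation(omega / ang, ang) else diag(3)
    step <- rigid_transform(rot, x[4:6])
    tf <- compose_transforms(step, tf)
    if (abs(prev - rms) < tol) break
    prev <- rms
  }
  list(tf = tf, rms_history = rms_history)
}

subsample_points <- function(pts, max_points) {
  if (nrow(pts) <= max_points) return(pts)
  pts[round(seq(1, nrow(pts), length.out = max_points)), , drop = FALSE]
}

kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  h <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(rot, ct - drop(rot %*% cf))
}

init_principal_axes <- function(mv, fx) {
  axes <- function(p) {
    e <- eigen(stats::cov(p), symmetric = TRUE)
    v <- e$vectors
    if (det(v) < 0) v[, 3] <- -v[, 3]
    v
  }
  am <- axes(mv); af <- axes(fx)
  cm <- colMeans(mv); cf <- colMeans(fx)
  best <- NULL; best_rms <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    s3 <- s1 * s2                      # keep det = +1
    rot <- af %*% diag(c(s1, s2, s3)) %*% t(am)
    tf <- rigid_transform(rot, cf - drop(rot %*% cm))
    sub <- subsample_points(mv, 300)
    nn <- nn_grid(apply_transform(tf, sub), fx)
    rms <- sqrt(mean(nn$dist^2))
    if (rms < best_rms) { best_rms <- rms; best <- tf }
  }
  best
}
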
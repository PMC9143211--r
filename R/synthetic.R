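# Synthetic phantoms, dose fields, cases and cohorts. The generator emulates
# the geometric and statistical structure of the clinical material: a
# horseshoe-shaped mandible of 26-95 mL, a focal high-dose region such that
# 9-83% of the bone receives at least 56 Gy, a nested PTV region prescribed
# 56-72 Gy, and two-plane segmental resections. Ground truth is computed on a
# finer grid from the analytic membership functions.

#' Generate a two-level HU phantom
#'
#' Shapes: `sphere` (center, radius) and `horseshoe` (a torus segment: arch
#' radius, tube radius, arc span centered on the +y direction). The returned
#' analytic volume is the closed form (sphere: 4/3 pi r^3; horseshoe: Pappus,
#' pi r_tube^2 x arch arc length, exact for non-self-intersecting tubes).
#'
#' @param shape `"sphere"` or `"horseshoe"`.
#' @param center length-3 mm center (sphere center / arch center).
#' @param radius sphere radius in mm.
#' @param arch_radius,tube_radius,arc_span_deg horseshoe parameters (mm, mm,
#'   degrees in (0, 360)).
#' @param hu_inside,hu_outside Hounsfield levels (defaults: cortical-like 1200
#'   in an air-like -1000 background).
#' @param spacing voxel spacing in mm (scalar or length 3), used when `frame`
#'   is not given.
#' @param margin_mm padding around the shape when auto-building the frame.
#' @param frame optional explicit [image_frame()].
#' @return list with `hu` (3D array), `frame`, `analytic_ml`, and `inside_fn`
#'   (vectorised membership function of an n x 3 mm matrix).
#' @export
make_phantom <- function(shape = c("sphere", "horseshoe"), center = c(0, 0, 0),
                         radius = 10, arch_radius = 30, tube_radius = 8,
                         arc_span_deg = 240, hu_inside = 1200,
                         hu_outside = -1000, spacing = 1, margin_mm = 5,
                         frame = NULL) {
  shape <- match.arg(shape)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  center <- as.numeric(center)
  if (shape == "sphere") {
    stopifnot(radius > 0)
    inside_fn <- function(xyz) {
      xyz <- rbind_matrix(xyz)
      (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
        (xyz[, 3] - center[3])^2 <= radius^2
    }
    analytic_ml <- 4 / 3 * pi * radius^3 / 1000
    lo <- center - radius; hi <- center + radius
  } else {
    stopifnot(arch_radius > 0, tube_radius > 0)
    if (tube_radius >= arch_radius)
      stop("tube radius must be smaller than arch radius (self-intersection)")
    if (!(arc_span_deg > 0 && arc_span_deg < 360))
      stop("arc span must be in (0, 360) degrees")
    span <- arc_span_deg * pi / 180
    inside_fn <- function(xyz) {
      xyz <- rbind_matrix(xyz)
      dx <- xyz[, 1] - center[1]; dy <- xyz[, 2] - center[2]
      dz <- xyz[, 3] - center[3]
      rho <- sqrt(dx^2 + dy^2)
      ang <- atan2(dy, dx)
      dang <- abs(((ang - pi / 2 + pi) %% (2 * pi)) - pi)
      (rho - arch_radius)^2 + dz^2 <= tube_radius^2 & dang <= span / 2
    }
    analytic_ml <- pi * tube_radius^2 * arch_radius * span / 1000
    r_out <- arch_radius + tube_radius
    lo <- center + c(-r_out, -r_out, -tube_radius)
    hi <- center + c(r_out, r_out, tube_radius)
  }
  if (is.null(frame)) {
    lo <- lo - margin_mm; hi <- hi + margin_mm
    shape_vox <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    frame <- image_frame(origin = lo, spacing = spacing, shape = shape_vox)
  }
  inside <- inside_fn(voxel_centers(frame))
  if (!any(inside)) warning("phantom lies entirely outside the frame")
  hu <- array(ifelse(inside, hu_inside, hu_outside), dim = frame$shape)
  list(hu = hu, frame = frame, analytic_ml = analytic_ml, inside_fn = inside_fn)
}

#' Generate an analytic dose field on a frame
#'
#' Models: `linear_ramp` (dose = offset + gradient x (z - z0), clamped at 0)
#' and `point_source` (an isotropic Gaussian focus,
#' dose = peak x exp(-d^2 / (2 sigma^2))). The peak emulates the prescribed
#' dose and must lie in the 56-72 Gy prescription envelope; for the ramp the
#' same envelope is enforced on the in-frame maximum.
#'
#' @param model `"linear_ramp"` or `"point_source"`.
#' @param frame an [image_frame()].
#' @param gradient Gy/mm slope of the ramp.
#' @param offset Gy at `z0` for the ramp.
#' @param z0 mm reference for the ramp.
#' @param focus length-3 mm focus position of the point source.
#' @param peak Gy at the focus (must lie within 56-72 Gy).
#' @param sigma mm falloff scale of the Gaussian.
#' @return a [dose_grid()] with the analytic field attached as attribute
#'   `field_fn` (vectorised over an n x 3 mm matrix).
#' @export
make_dose <- function(model = c("linear_ramp", "point_source"), frame,
                      gradient = 1, offset = 0, z0 = 0,
                      focus = c(0, 0, 0), peak = 70, sigma = 25) {
  model <- match.arg(model)
  if (model == "linear_ramp") {
    field_fn <- function(xyz) {
      xyz <- rbind_matrix(xyz)
      pmax(0, offset + gradient * (xyz[, 3] - z0))
    }
  } else {
    if (peak < 56 || peak > 72)
      stop("peak dose ", peak, " Gy outside the 56-72 Gy prescription envelope")
    focus <- as.numeric(focus)
    field_fn <- function(xyz) {
      xyz <- rbind_matrix(xyz)
      d2 <- (xyz[, 1] - focus[1])^2 + (xyz[, 2] - focus[2])^2 +
        (xyz[, 3] - focus[3])^2
      peak * exp(-d2 / (2 * sigma^2))
    }
  }
  vals <- field_fn(voxel_centers(frame))
  if (model == "linear_ramp") {
    mx <- max(vals)
    if (mx < 56 || mx > 72)
      stop("in-frame maximum ramp dose ", signif(mx, 4),
           " Gy outside the 56-72 Gy prescription envelope")
  }
  out <- dose_grid(frame, array(vals, dim = frame$shape))
  attr(out, "field_fn") <- field_fn
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

# calibrate the Gaussian falloff scale so a target fraction of the mandible
# receives at least `threshold` Gy (fraction is monotone in sigma)
calibrate_sigma <- function(xyz_mandible, focus, peak, threshold, target_frac,
                            lo = 2, hi = 400) {
  d2 <- (xyz_mandible[, 1] - focus[1])^2 + (xyz_mandible[, 2] - focus[2])^2 +
    (xyz_mandible[, 3] - focus[3])^2
  frac <- function(sigma) mean(peak * exp(-d2 / (2 * sigma^2)) >= threshold)
  if (frac(hi) < target_frac) return(hi)
  if (frac(lo) > target_frac) return(lo)
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target_frac) lo <- mid else hi <- mid
    if (hi / lo < 1.0005) break
  }
  sqrt(lo * hi)
}

#' Generate one full synthetic case
#'
#' Builds a horseshoe mandible phantom, a calibrated Gaussian dose focus on
#' the arch, a nested PTV isodose region, and a two-plane segmental resection
#' bracketing the focus; computes the pipeline volume metrics on the standard
#' grid and (optionally) the ground-truth metrics on a `fine_factor`-times
#' finer grid from the analytic membership functions.
#'
#' @param seed integer seed (mandatory; all draws are local to the call).
#' @param spacing standard grid spacing in mm.
#' @param fine_factor refinement factor for the ground-truth grid
#'   (0 skips ground truth).
#' @param vm_ml target mandible volume in mL (default drawn from the cohort
#'   distribution, truncated to 26.4-95 mL).
#' @param vm56_frac target fraction of the mandible receiving >= 56 Gy
#'   (default drawn uniformly from 0.09-0.83).
#' @param resect_frac target resected fraction of the arch (default drawn
#'   uniformly from 0.07-0.60; the upper bound keeps the two half-space cuts a
#'   wedge).
#' @param peak_gy prescribed peak dose in Gy (drawn from 60-72 by default).
#' @param threshold_gy isodose threshold (default 56).
#' @return an object of class `synthetic_case`: phantom, dose, masks, planes,
#'   `metrics` (standard grid), `truth` (fine grid or NULL) and parameters.
#' @export
make_case <- function(seed, spacing = 0.8, fine_factor = 4, vm_ml = NULL,
                      vm56_frac = NULL, resect_frac = NULL, peak_gy = NULL,
                      threshold_gy = 56) {
  with_seed(seed, {
    arch_radius <- stats::runif(1, 25, 33)
    arc_span <- stats::runif(1, 200, 260)
    if (is.null(vm_ml)) vm_ml <- rnorm_trunc(1, 62.7, 15, 26.4, 95)
    if (is.null(vm56_frac)) vm56_frac <- stats::runif(1, 0.09, 0.83)
    if (is.null(resect_frac)) resect_frac <- stats::runif(1, 0.07, 0.60)
    if (is.null(peak_gy)) peak_gy <- stats::runif(1, 60, 72)
    span_rad <- arc_span * pi / 180
    tube_radius <- sqrt(vm_ml * 1000 / (pi * arch_radius * span_rad))
    tube_radius <- min(tube_radius, arch_radius - 5)
    phantom <- make_phantom("horseshoe", center = c(0, 0, 0),
                            arch_radius = arch_radius,
                            tube_radius = tube_radius,
                            arc_span_deg = arc_span, spacing = spacing)
    frame <- phantom$frame
    mandible <- segment_bone(phantom$hu, frame, 300)
    xyz_m <- index_to_world(frame, which(mandible$mask, arr.ind = TRUE))
    # dose focus on the arch centerline
    theta_f <- pi / 2 + stats::runif(1, -0.25, 0.25) * span_rad
    focus <- c(arch_radius * cos(theta_f), arch_radius * sin(theta_f), 0)
    sigma <- calibrate_sigma(xyz_m, focus, peak_gy, threshold_gy, vm56_frac)
    dose <- make_dose("point_source", frame, focus = focus, peak = peak_gy,
                      sigma = sigma)
    ptv_dose <- stats::runif(1, threshold_gy, threshold_gy + 0.8 * (peak_gy - threshold_gy))
    r_ptv <- sigma * sqrt(2 * log(peak_gy / ptv_dose))
    ptv_fn <- function(xyz) {
      xyz <- rbind_matrix(xyz)
      (xyz[, 1] - focus[1])^2 + (xyz[, 2] - focus[2])^2 +
        (xyz[, 3] - focus[3])^2 <= r_ptv^2
    }
    ptv <- binary_volume(frame, array(ptv_fn(voxel_centers(frame)),
                                      dim = frame$shape))
    # two cut planes bracketing the focus
    delta <- resect_frac * span_rad / 2
    planes <- list(
      arch_cut_plane(arch_radius, theta_f - delta, +1),
      arch_cut_plane(arch_radius, theta_f + delta, -1))
    spec <- resection_spec(planes)
    iso <- isodose_region(dose, threshold_gy)
    metrics <- compute_metrics(mandible, iso, ptv, spec)
    truth <- NULL
    if (fine_factor > 0) {
      truth <- case_truth_metrics(frame, fine_factor,
                                  arch_radius, tube_radius, span_rad,
                                  focus, sigma, peak_gy, threshold_gy,
                                  r_ptv, planes)
    }
    structure(list(
      phantom = phantom, frame = frame, hu = phantom$hu, dose = dose,
      mandible = mandible, isodose = iso, ptv = ptv, ptv_fn = ptv_fn,
      spec = spec, planes = planes, metrics = metrics, truth = truth,
      params = list(seed = seed, spacing = spacing, arch_radius = arch_radius,
                    tube_radius = tube_radius, arc_span_deg = arc_span,
                    vm_ml = vm_ml, vm56_frac = vm56_frac,
                    resect_frac = resect_frac, peak_gy = peak_gy,
                    sigma = sigma, theta_f = theta_f, focus = focus,
                    ptv_dose = ptv_dose, r_ptv = r_ptv,
                    threshold_gy = threshold_gy)),
      class = "synthetic_case")
  })
}

arch_cut_plane <- function(arch_radius, theta, orientation) {
  pt <- c(arch_radius * cos(theta), arch_radius * sin(theta), 0)
  tangent <- c(-sin(theta), cos(theta), 0) * orientation
  resection_plane(pt, tangent)
}

# Ground truth on a `fine_factor`-times finer grid, evaluated slice-wise from
# the closed-form case geometry (torus-segment bone, Gaussian focus, vertical
# cut planes, spherical PTV). The fine lattice subdivides each coarse voxel
# exactly, so both grids estimate the same physical region; the evaluation is
# independent of the package's voxel machinery.
case_truth_metrics <- function(coarse, fine_factor, arch_radius, tube_radius,
                               span_rad, focus, sigma, peak, threshold,
                               r_ptv, planes) {
  fac <- as.integer(fine_factor)
  sp <- coarse$spacing / fac
  origin <- coarse$origin - coarse$spacing / 2 + sp / 2
  n <- coarse$shape * fac
  xs <- origin[1] + (seq_len(n[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * sp[3]
  x <- rep(xs, times = n[2]); y <- rep(ys, each = n[1])
  rho <- sqrt(x^2 + y^2)
  radial2 <- (rho - arch_radius)^2
  ang_ok <- abs(((atan2(y, x) - pi / 2 + pi) %% (2 * pi)) - pi) <= span_rad / 2
  d2f_xy <- (x - focus[1])^2 + (y - focus[2])^2
  hot_r2 <- 2 * sigma^2 * log(peak / threshold)  # squared radius of >= threshold
  res2d <- rep(TRUE, length(x))
  for (pl in planes) {
    stopifnot(abs(pl$normal[3]) < 1e-9)          # separability requirement
    res2d <- res2d & ((x - pl$point[1]) * pl$normal[1] +
                        (y - pl$point[2]) * pl$normal[2] >= 0)
  }
  counts <- c(m = 0, hot = 0, ptv = 0, m_hot = 0, m_ptv = 0, res = 0,
              resid_hot = 0, resid_ptv = 0)
  for (z in zs) {
    m <- ang_ok & (radial2 <= tube_radius^2 - z^2)
    dz2 <- (z - focus[3])^2
    hot <- d2f_xy <= hot_r2 - dz2
    ptv <- d2f_xy <= r_ptv^2 - dz2
    res <- m & res2d
    resid <- m & !res2d
    counts <- counts + c(sum(m), sum(hot), sum(ptv), sum(m & hot),
                         sum(m & ptv), sum(res), sum(resid & hot),
                         sum(resid & ptv))
  }
  vox_ml <- prod(sp) / 1000
  volume_metrics(
    Vm = counts[["m"]] * vox_ml, V56 = counts[["hot"]] * vox_ml,
    V_PTV = counts[["ptv"]] * vox_ml, Vm56 = counts[["m_hot"]] * vox_ml,
    Vm_PTV = counts[["m_ptv"]] * vox_ml, VmR = counts[["res"]] * vox_ml,
    Vm56R = counts[["resid_hot"]] * vox_ml,
    Vm_PTV_R = counts[["resid_ptv"]] * vox_ml)
}

#' Write a synthetic case to disk as DICOM fixtures
#'
#' One directory per case: a CT series, an RTDOSE file, an RTSTRUCT with
#' `mandible` and `ptv` ROIs (the analytic cross-section polygons), a
#' `planes.csv` with the osteotomy planes, and `ground_truth.json` with the
#' fine-grid metrics (when present).
#'
#' @param case a `synthetic_case` from [make_case()].
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_case_dicom <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  uid_root <- paste0("2.25.", abs(case$params$seed) %% 1000000L + 1L)
  write_ct_series(file.path(dir, "ct"), case$hu, case$frame, uid_root)
  write_rtdose(file.path(dir, "rtdose.dcm"), case$dose, uid_root)
  p <- case$params
  mand_cs <- horseshoe_contours(p$arch_radius, p$tube_radius, p$arc_span_deg,
                                case$frame, name = "mandible")
  ptv_cs <- sphere_contours(p$focus, p$r_ptv, case$frame, name = "ptv")
  write_rtstruct(file.path(dir, "rtstruct.dcm"), list(mand_cs, ptv_cs), uid_root)
  planes_df <- do.call(rbind, lapply(seq_along(case$planes), function(i) {
    pl <- case$planes[[i]]
    data.frame(case_id = p$seed, plane_id = i,
               px = pl$point[1], py = pl$point[2], pz = pl$point[3],
               nx = pl$normal[1], ny = pl$normal[2], nz = pl$normal[3])
  }))
  utils::write.csv(planes_df, file.path(dir, "planes.csv"), row.names = FALSE)
  if (!is.null(case$truth))
    jsonlite::write_json(unclass(case$truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

horseshoe_contours <- function(arch_radius, tube_radius, arc_span_deg, frame,
                               name = "mandible", step_deg = 2) {
  span <- arc_span_deg * pi / 180
  a0 <- pi / 2 - span / 2; a1 <- pi / 2 + span / 2
  zc <- frame$origin[3] + (seq_len(frame$shape[3]) - 1) * frame$spacing[3]
  contours <- list()
  for (z in zc) {
    if (abs(z) >= tube_radius) next
    w <- sqrt(tube_radius^2 - z^2)
    if (w < 1e-6) next
    ang <- seq(a0, a1, by = step_deg * pi / 180)
    if (ang[length(ang)] < a1) ang <- c(ang, a1)
    outer_xy <- cbind((arch_radius + w) * cos(ang), (arch_radius + w) * sin(ang))
    inner_xy <- cbind((arch_radius - w) * cos(rev(ang)),
                      (arch_radius - w) * sin(rev(ang)))
    contours[[length(contours) + 1L]] <- list(z = z, xy = rbind(outer_xy, inner_xy))
  }
  contour_set(name, contours, frame)
}

sphere_contours <- function(center, radius, frame, name = "ptv", n_pts = 64) {
  zc <- frame$origin[3] + (seq_len(frame$shape[3]) - 1) * frame$spacing[3]
  contours <- list()
  for (z in zc) {
    dz <- z - center[3]
    if (abs(dz) >= radius) next
    r <- sqrt(radius^2 - dz^2)
    if (r < 1e-6) next
    ang <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
    contours[[length(contours) + 1L]] <-
      list(z = z, xy = cbind(center[1] + r * cos(ang), center[2] + r * sin(ang)))
  }
  if (length(contours) == 0)
    contours <- list(list(z = center[3],
                          xy = cbind(center[1] + c(-0.1, 0.1, 0),
                                     center[2] + c(-0.1, 0.1, 0.2))))
  contour_set(name, contours, frame)
}

#' Construct a phantom with a planned cortical-involvement pattern
#'
#' Builds a horseshoe mandible, one osteotomy plane near the arch apex, and a
#' Gaussian dose focus placed so that the >= 56 Gy mandibular volume at the cut
#' is, by construction: absent (`outside`), restricted to the inner cortex
#' (`lingual`), or spanning the full cross-section (`bicortical`). Geometry is
#' jittered per seed.
#'
#' @param kind `"outside"`, `"lingual"` or `"bicortical"`.
#' @param seed integer seed.
#' @param spacing voxel spacing in mm.
#' @param threshold_gy isodose threshold (default 56).
#' @return list with `mandible`, `vm56`, `plane`, `dose`, `kind`.
#' @export
make_classification_phantom <- function(kind = c("outside", "lingual",
                                                 "bicortical"),
                                        seed, spacing = 1,
                                        threshold_gy = 56) {
  kind <- match.arg(kind)
  with_seed(seed, {
    arch_radius <- stats::runif(1, 27, 32)
    tube_radius <- stats::runif(1, 7, 9)
    span <- stats::runif(1, 220, 260)
    span_rad <- span * pi / 180
    phantom <- make_phantom("horseshoe", arch_radius = arch_radius,
                            tube_radius = tube_radius, arc_span_deg = span,
                            spacing = spacing)
    mandible <- segment_bone(phantom$hu, phantom$frame, 300)
    theta_c <- pi / 2 + stats::runif(1, -0.15, 0.15) * span_rad
    plane <- arch_cut_plane(arch_radius, theta_c, +1)
    peak <- stats::runif(1, 64, 72)
    hot_scale <- sqrt(2 * log(peak / threshold_gy))
    if (kind == "outside") {
      theta_f <- theta_c - 0.35 * span_rad       # focus well clear of the cut
      focus <- c(arch_radius * cos(theta_f), arch_radius * sin(theta_f), 0)
      sigma <- 5 / hot_scale                     # hot radius 5 mm
    } else if (kind == "lingual") {
      rr <- arch_radius - 0.85 * tube_radius     # on the inner cortical plate
      focus <- c(rr * cos(theta_c), rr * sin(theta_c), 0)
      sigma <- (0.55 * tube_radius) / hot_scale
    } else {
      focus <- c(arch_radius * cos(theta_c), arch_radius * sin(theta_c), 0)
      sigma <- (tube_radius + 4) / hot_scale     # hot radius spans the tube
    }
    dose <- make_dose("point_source", phantom$frame, focus = focus,
                      peak = peak, sigma = sigma)
    vm56 <- intersect_volumes(mandible, isodose_region(dose, threshold_gy))
    list(mandible = mandible, vm56 = vm56, plane = plane, dose = dose,
         kind = kind)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws group-dependent case parameters (recurrent patients have smaller
#' mandibles and smaller irradiated fractions, per the clinical summary
#' distributions) and returns tidy per-patient metric and per-plane
#' classification tables.
#'
#' In `geometry` mode every patient is a full [make_case()] voxel simulation
#' (the default); in `sample` mode the metric table is drawn directly from the
#' group distributions, which is what large statistical replicate studies
#' (type-I error, power) need.
#'
#' @param n_nonrecurrent,n_recurrent patients per group (defaults 28 and 5).
#' @param seed mandatory integer seed.
#' @param mode `"geometry"` or `"sample"`.
#' @param spacing voxel spacing for geometry mode, mm.
#' @param null_groups if TRUE both groups are drawn from the pooled
#'   (non-recurrent) distributions -- a zero between-group difference.
#' @return list with `metrics` (data.frame, one row per patient) and, in
#'   geometry mode, `planes` (data.frame, one row per osteotomy plane with its
#'   cortical classification).
#' @export
make_cohort <- function(n_nonrecurrent = 28, n_recurrent = 5, seed,
                        mode = c("geometry", "sample"), spacing = 1.5,
                        null_groups = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  groups <- c(rep("non_recurrent", n_nonrecurrent), rep("recurrent", n_recurrent))
  with_seed(seed, {
    draw_params <- function(group) {
      if (group == "recurrent" && !null_groups) {
        list(vm = rnorm_trunc(1, 47.8, 10, 26.4, 95),
             frac56 = rnorm_trunc(1, 0.23, 0.10, 0.09, 0.44),
             resect = rnorm_trunc(1, 0.26, 0.12, 0.07, 0.52))
      } else {
        list(vm = rnorm_trunc(1, 65.4, 15, 26.4, 95),
             frac56 = rnorm_trunc(1, 0.45, 0.18, 0.09, 0.83),
             resect = rnorm_trunc(1, 0.37, 0.15, 0.07, 0.60))
      }
    }
    if (mode == "sample") {
      rows <- lapply(seq_along(groups), function(i) {
        p <- draw_params(groups[i])
        vm56 <- p$frac56 * p$vm
        vmr <- p$resect * p$vm
        res_share <- stats::runif(1, 0, 0.7)      # share of Vm56 left behind
        ptv_share <- stats::runif(1, 0, 0.5)
        vm_ptv <- ptv_share * vm56
        m <- volume_metrics(
          Vm = p$vm, V56 = vm56 * stats::runif(1, 15, 40),
          V_PTV = vm_ptv * stats::runif(1, 10, 30),
          Vm56 = vm56, Vm_PTV = vm_ptv, VmR = vmr,
          Vm56R = res_share * vm56, Vm_PTV_R = res_share * vm_ptv)
        cbind(data.frame(case_id = i, group = groups[i]),
              as.data.frame(unclass(m)))
      })
      return(list(metrics = do.call(rbind, rows)))
    }
    case_seeds <- sample.int(2^30, length(groups))
    rows <- list(); plane_rows <- list()
    for (i in seq_along(groups)) {
      p <- draw_params(groups[i])
      cs <- make_case(case_seeds[i], spacing = spacing, fine_factor = 0,
                      vm_ml = p$vm, vm56_frac = p$frac56,
                      resect_frac = p$resect)
      rows[[i]] <- cbind(data.frame(case_id = i, group = groups[i]),
                         as.data.frame(unclass(cs$metrics)))
      vm56_bv <- intersect_volumes(cs$mandible, cs$isodose)
      midline <- mandible_midline(cs$mandible)
      for (j in seq_along(cs$planes)) {
        cl <- classify_osteotomy(cs$planes[[j]], vm56_bv, cs$mandible,
                                 midline = midline)
        plane_rows[[length(plane_rows) + 1L]] <- data.frame(
          case_id = i, plane_id = j, group = groups[i],
          category = cl$category,
          lingual_area_mm2 = cl$lingual_area_mm2,
          buccal_area_mm2 = cl$buccal_area_mm2)
      }
    }
    list(metrics = do.call(rbind, rows), planes = do.call(rbind, plane_rows))
  })
}
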
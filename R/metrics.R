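#' Per-patient dose-volume metric record
#'
#' Computes the full set of mandibular dose-volume quantities for one case:
#' total mandible volume (Vm), the whole-grid isodose and PTV volumes (V56,
#' V_PTV), the mandibular portions inside them (Vm56, Vm_PTV), the resected
#' volume (VmR) and the residual irradiated volumes left after resection
#' (Vm56R, Vm_PTV_R), plus their percentages of Vm. All volumes in mL.
#'
#' @param mandible [binary_volume()] of the mandible.
#' @param isodose56 `isodose_volume` or [binary_volume()]: region receiving at
#'   least the threshold dose (56 Gy by default convention) over the whole
#'   grid.
#' @param ptv_region [binary_volume()] of the planning target volume, or
#'   `NULL` if no PTV structure is available (PTV metrics become 0).
#' @param resection_spec a [resection_spec()], or `NULL` for no resection
#'   (VmR and residual metrics are then 0 and Vm56R = Vm56 is *not* assumed --
#'   with no resection nothing is removed, so Vm56R = Vm56).
#' @return an object of class `volume_metrics` (a named list of numerics).
#' @export
compute_metrics <- function(mandible, isodose56, ptv_region = NULL,
                            resection_spec = NULL) {
  mandible <- as_mask(mandible)
  iso <- as_mask(isodose56)
  if (!frames_identical(mandible$frame, iso$frame))
    stop_frame_mismatch("mandible and isodose region")
  if (!is.null(ptv_region)) {
    ptv_region <- as_mask(ptv_region)
    if (!frames_identical(mandible$frame, ptv_region$frame))
      stop_frame_mismatch("mandible and PTV region")
  }
  vm <- volume_ml(mandible)
  v56 <- volume_ml(iso)
  v_ptv <- if (is.null(ptv_region)) 0 else volume_ml(ptv_region)
  vm56_bv <- intersect_volumes(mandible, iso)
  vm56 <- volume_ml(vm56_bv)
  vmptv_bv <- if (is.null(ptv_region)) NULL else intersect_volumes(mandible, ptv_region)
  vm_ptv <- if (is.null(vmptv_bv)) 0 else volume_ml(vmptv_bv)
  if (!is.null(resection_spec)) {
    parts <- apply_resection(mandible, resection_spec)
    vmr <- volume_ml(parts$resected)
    vm56r <- volume_ml(intersect_volumes(parts$residual, iso))
    vm_ptv_r <- if (is.null(ptv_region)) 0 else
      volume_ml(intersect_volumes(parts$residual, ptv_region))
  } else {
    vmr <- 0
    vm56r <- vm56
    vm_ptv_r <- vm_ptv
  }
  volume_metrics(Vm = vm, V56 = v56, V_PTV = v_ptv, Vm56 = vm56,
                 Vm_PTV = vm_ptv, VmR = vmr, Vm56R = vm56r,
                 Vm_PTV_R = vm_ptv_r)
}

#' Construct a volume_metrics record from its mL fields
#'
#' Percentages of total mandibular volume are derived from the mL fields.
#' Basic containment invariants (Vm56 <= Vm, Vm56R <= Vm56, ...) are checked.
#'
#' @param Vm,V56,V_PTV,Vm56,Vm_PTV,VmR,Vm56R,Vm_PTV_R volumes in mL.
#' @param tol slack in mL for the containment checks (voxel rounding).
#' @return an object of class `volume_metrics`.
#' @export
volume_metrics <- function(Vm, V56, V_PTV, Vm56, Vm_PTV, VmR, Vm56R,
                           Vm_PTV_R, tol = 1e-9) {
  vals <- c(Vm = Vm, V56 = V56, V_PTV = V_PTV, Vm56 = Vm56, Vm_PTV = Vm_PTV,
            VmR = VmR, Vm56R = Vm56R, Vm_PTV_R = Vm_PTV_R)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("volumes must be finite and >= 0")
  chk <- function(a, b, na, nb) if (a > b + tol)
    stop("containment violated: ", na, " (", a, ") > ", nb, " (", b, ")")
  chk(Vm56, Vm, "Vm56", "Vm"); chk(Vm56, V56, "Vm56", "V56")
  chk(Vm_PTV, Vm, "Vm_PTV", "Vm"); chk(Vm56R, Vm56, "Vm56R", "Vm56")
  chk(Vm_PTV_R, Vm_PTV, "Vm_PTV_R", "Vm_PTV"); chk(VmR, Vm, "VmR", "Vm")
  pct <- function(x) if (Vm > 0) 100 * x / Vm else 0
  structure(as.list(c(vals,
                      Vm56_over_Vm = pct(Vm56),
                      Vm_PTV_over_Vm = pct(Vm_PTV),
                      VmR_over_Vm = pct(VmR))),
            class = "volume_metrics")
}

#' @export
print.volume_metrics <- function(x, ...) {
  ml <- c("Vm", "V56", "V_PTV", "Vm56", "Vm_PTV", "VmR", "Vm56R", "Vm_PTV_R")
  cat("<volume_metrics> (mL, 1 decimal; percentages of Vm)\n")
  for (f in ml) cat(sprintf("  %-9s %8.1f\n", f, x[[f]]))
  for (f in c("Vm56_over_Vm", "Vm_PTV_over_Vm", "VmR_over_Vm"))
    cat(sprintf("  %-15s %5.0f%%\n", f, x[[f]]))
  invisible(x)
}

#' Flatten volume_metrics records into a data frame
#' @param metrics_list named list of `volume_metrics` (names become case ids)
#'   or a single record.
#' @return data.frame with one row per case.
#' @export
metrics_as_data_frame <- function(metrics_list) {
  if (inherits(metrics_list, "volume_metrics")) metrics_list <- list(metrics_list)
  rows <- lapply(metrics_list, function(m) as.data.frame(unclass(m)))
  out <- do.call(rbind, rows)
  if (!is.null(names(metrics_list))) out <- cbind(case_id = names(metrics_list), out)
  rownames(out) <- NULL
  out
}

metric_fields <- function() {
  c("Vm", "V56", "V_PTV", "Vm56", "Vm_PTV", "VmR", "Vm56R", "Vm_PTV_R",
    "Vm56_over_Vm", "Vm_PTV_over_Vm", "VmR_over_Vm")
}
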
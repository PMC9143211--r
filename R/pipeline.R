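# Case-level and cohort-level drivers tying the stages together:
# read -> resample -> segment -> isodose -> resect -> metrics -> classify,
# with structured logging and reproducible outputs.

#' Pipeline configuration
#'
#' @param hu_threshold bone segmentation threshold in HU (default 300).
#' @param isodose_gy isodose threshold in Gy; the margin-planning convention is
#'   56 Gy.
#' @param shell_mm cortical shell thickness in mm for plane classification.
#' @param alpha normality-gate level for group tests.
#' @param spacing optional isotropic resampling spacing in mm (NULL = native
#'   CT grid).
#' @param seed integer seed recorded with every run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(hu_threshold = 300, isodose_gy = 56, shell_mm = 2,
                            alpha = 0.05, spacing = NULL, seed = 1) {
  if (!(isodose_gy > 0)) stop("isodose threshold must be > 0")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(hu_threshold = hu_threshold, isodose_gy = isodose_gy,
                 shell_mm = shell_mm, alpha = alpha, spacing = spacing,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) x), path)
  invisible(path)
}

log_stage <- function(log, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = ""))
  message(line)
  c(log, line)
}

#' Run the full single-case workflow on a case directory
#'
#' Expects `ct/` (DICOM series), `rtdose.dcm`, `rtstruct.dcm` (ROIs `mandible`
#' and, optionally, `ptv`) and optionally `planes.csv` under `case_dir`. Reads
#' everything into the CT frame, resamples the dose, segments the bone,
#' builds the isodose region, applies the resection and classifies every
#' plane. Writes `metrics.csv`, `classification.csv` (when planes exist),
#' surface meshes (STL), the resolved configuration and a run log to
#' `out_dir`.
#'
#' @param case_dir input directory.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `metrics`, `classifications` and the output
#'   file paths.
#' @export
run_case <- function(case_dir, out_dir, config = pipeline_config()) {
  for (need in c("ct", "rtdose.dcm", "rtstruct.dcm")) {
    if (!file.exists(file.path(case_dir, need)))
      stop("missing input: ", file.path(case_dir, need))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character(0)
  ct <- read_ct_series(file.path(case_dir, "ct"))
  frame <- ct$frame
  if (!is.null(config$spacing)) {
    extent <- frame$shape * frame$spacing
    frame <- image_frame(frame$origin, rep(config$spacing, 3),
                         pmax(1L, as.integer(ceiling(extent / config$spacing))),
                         frame$direction)
  }
  log <- log_stage(log, "read_ct", paste(ct$frame$shape, collapse = "x"), " voxels")
  dose <- read_rtdose(file.path(case_dir, "rtdose.dcm"))
  dose <- resample_dose_to_frame(dose, frame)
  log <- log_stage(log, "resample_dose", "max ", signif(max(dose$values), 4), " Gy")
  roi_names <- tryCatch(
    names(read_rtstruct(file.path(case_dir, "rtstruct.dcm"),
                        c("mandible", "ptv"))),
    error = function(e) NULL)
  have_ptv <- !is.null(roi_names)
  structs <- if (have_ptv)
    read_rtstruct(file.path(case_dir, "rtstruct.dcm"), c("mandible", "ptv"))
  else read_rtstruct(file.path(case_dir, "rtstruct.dcm"), "mandible")
  mand_roi <- rasterize_contours(structs[["mandible"]], frame)
  hu <- if (frames_identical(frame, ct$frame)) ct$hu else
    array(trilinear_sample(ct$hu, ct$frame, voxel_centers(frame)),
          dim = frame$shape)
  mandible <- segment_bone(hu, frame, config$hu_threshold, mand_roi)
  log <- log_stage(log, "segment_bone", signif(volume_ml(mandible), 4), " mL")
  iso <- isodose_region(dose, config$isodose_gy)
  log <- log_stage(log, "isodose", signif(volume_ml(iso$region), 4), " mL >= ",
                   config$isodose_gy, " Gy")
  ptv <- if (have_ptv) rasterize_contours(structs[["ptv"]], frame) else NULL
  planes_path <- file.path(case_dir, "planes.csv")
  spec <- NULL; planes <- NULL
  if (file.exists(planes_path)) {
    plane_sets <- read_planes_csv(planes_path)
    planes <- plane_sets[[1]]
    spec <- resection_spec(planes)
  } else {
    warning("no planes.csv in ", case_dir, "; classification skipped")
    log <- log_stage(log, "planes", "absent -- classification skipped")
  }
  metrics <- compute_metrics(mandible, iso, ptv, spec)
  log <- log_stage(log, "metrics", "Vm ", signif(metrics$Vm, 4), " mL, Vm56 ",
                   signif(metrics$Vm56, 4), " mL")
  classifications <- NULL
  if (!is.null(planes)) {
    vm56_bv <- intersect_volumes(mandible, iso)
    midline <- mandible_midline(mandible)
    classifications <- do.call(rbind, lapply(seq_along(planes), function(i) {
      cl <- classify_osteotomy(planes[[i]], vm56_bv, mandible,
                               shell_mm = config$shell_mm, midline = midline)
      data.frame(plane_id = i, category = cl$category,
                 lingual_area_mm2 = cl$lingual_area_mm2,
                 buccal_area_mm2 = cl$buccal_area_mm2)
    }))
    log <- log_stage(log, "classify",
                     paste(classifications$category, collapse = ", "))
  }
  metrics_df <- metrics_as_data_frame(list(case = metrics))
  utils::write.csv(metrics_df, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(classifications))
    utils::write.csv(classifications, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
  write_stl(mesh_from_mask(mandible), file.path(out_dir, "mandible.stl"))
  vm56_bv <- intersect_volumes(mandible, iso)
  if (any(vm56_bv$mask))
    write_stl(mesh_from_mask(vm56_bv), file.path(out_dir, "vm56.stl"))
  if (!is.null(spec)) {
    parts <- apply_resection(mandible, spec)
    if (any(parts$residual$mask))
      write_stl(mesh_from_mask(parts$residual),
                file.path(out_dir, "residual.stl"))
  }
  write_config(config, file.path(out_dir, "config.yaml"))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(metrics = metrics, classifications = classifications,
                 out_dir = out_dir))
}

#' Cohort statistics command: per-group summary report plus comparisons
#'
#' @param metrics a data.frame (or CSV path) of per-patient metrics with a
#'   group column.
#' @param group_col group column name.
#' @param out_dir optional output directory for `cohort_summary.csv` and
#'   `comparisons.json`.
#' @param alpha normality-gate level.
#' @return the [cohort_summary()] list, invisibly when writing files.
#' @export
cohort_stats <- function(metrics, group_col = "group", out_dir = NULL,
                         alpha = 0.05) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics)
  res <- cohort_summary(metrics, group_col, alpha)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(res$summary, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    comp <- lapply(res$comparisons, function(x) unclass(x))
    jsonlite::write_json(comp, file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' Render the five-panel case overview figure
#'
#' One PNG per case mirroring the standard presentation: mandible, mandible
#' within the isodose region (Vm56), mandible within the PTV, post-resection
#' residual mandible, and residual Vm56. Panels show axial maximum-intensity
#' projections; an empty region renders as an empty panel, not an error.
#'
#' @param case a `synthetic_case` from [make_case()], or a list with
#'   `mandible`, `isodose`, `ptv`, `spec` fields.
#' @param path output PNG path.
#' @return invisibly `path`.
#' @export
render_case <- function(case, path) {
  mandible <- case$mandible
  vm56 <- intersect_volumes(mandible, case$isodose)
  vmptv <- if (!is.null(case$ptv)) intersect_volumes(mandible, case$ptv) else
    binary_volume(mandible$frame, array(FALSE, dim = dim(mandible$mask)))
  parts <- if (!is.null(case$spec)) apply_resection(mandible, case$spec) else
    list(residual = mandible)
  vm56r <- intersect_volumes(parts$residual, vm56)
  panels <- list(Vm = mandible, Vm56 = vm56, `Vm-PTV` = vmptv,
                 VmR = parts$residual, Vm56R = vm56r)
  grDevices::png(path, width = 1500, height = 320)
  op <- graphics::par(mfrow = c(1, 5), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (nm in names(panels)) {
    m <- panels[[nm]]$mask
    mip <- apply(m, c(1, 2), any)
    graphics::image(seq_len(nrow(mip)), seq_len(ncol(mip)),
                    matrix(as.numeric(mip), nrow(mip)), col = c("white", "grey30"),
                    zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "", main = nm)
  }
  invisible(path)
}
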
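# Mask and mesh export: NIfTI for voxel masks, ASCII STL / PLY for meshes.
# Meshes and masks are written in the patient frame (mm).

#' Write a binary mask as NIfTI
#' @param v a [binary_volume()] (axis-aligned frame).
#' @param path output `.nii` / `.nii.gz` path.
#' @return invisibly `path`.
#' @export
write_mask_nifti <- function(v, path) {
  v <- as_mask(v)
  img <- RNifti::asNifti(array(as.integer(v$mask), dim = v$frame$shape))
  aff <- diag(4)
  aff[1:3, 1:3] <- v$frame$direction %*% diag(v$frame$spacing)
  aff[1:3, 4] <- v$frame$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- v$frame$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask into a binary volume
#' @param path NIfTI file path.
#' @return a [binary_volume()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  dirm <- sweep(aff[1:3, 1:3], 2, sp, `/`)
  frame <- image_frame(origin = aff[1:3, 4], spacing = sp, shape = dim(img),
                       direction = dirm)
  binary_volume(frame, array(as.array(img) != 0, dim = dim(img)))
}

#' Write a surface mesh as ASCII STL
#' @param mesh a [surface_mesh()].
#' @param path output `.stl` path.
#' @param name solid name.
#' @return invisibly `path`.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    nrm <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
             (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
             (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("      vertex %g %g %g", c3[1], c3[2], c3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a surface mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output `.ply` path.
#' @return invisibly `path`.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read osteotomy planes from a CSV file
#'
#' Expected columns: `case_id, plane_id, px, py, pz, nx, ny, nz` (mm, patient
#' frame; normals point into the resected segment).
#'
#' @param path CSV path.
#' @return named list (by case_id) of lists of [resection_plane()].
#' @export
read_planes_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("case_id", "plane_id", "px", "py", "pz", "nx", "ny", "nz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("planes CSV missing columns: ", paste(missing_cols, collapse = ", "))
  out <- list()
  for (cid in unique(df$case_id)) {
    sub <- df[df$case_id == cid, ]
    sub <- sub[order(sub$plane_id), ]
    out[[as.character(cid)]] <- lapply(seq_len(nrow(sub)), function(i)
      resection_plane(c(sub$px[i], sub$py[i], sub$pz[i]),
                      c(sub$nx[i], sub$ny[i], sub$nz[i])))
  }
  out
}

#' Write a rigid transform as a 4x4 row-major matrix in JSON
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_transform_json <- function(transform, path) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  jsonlite::write_json(list(matrix_rowmajor = as.numeric(t(m))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
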
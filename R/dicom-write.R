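# Minimal DICOM writer (Explicit VR Little Endian) for the three RT objects the
# pipeline consumes: CT series, RTDOSE, RTSTRUCT. Only the tags the reader and
# third-party readers need are emitted; UIDs are deterministic so that a fixed
# seed yields byte-identical files.

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
SOP_CLASS <- c(ct = "1.2.840.10008.5.1.4.1.1.2",
               rtdose = "1.2.840.10008.5.1.4.1.1.481.2",
               rtstruct = "1.2.840.10008.5.1.4.1.1.481.3")

uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_raw <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(uint16_raw(lo), uint16_raw(hi))
}

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

val_str <- function(s, pad = as.raw(0x20)) dcm_pad(charToRaw(paste(s, collapse = "\\")), pad)
val_ui <- function(s) val_str(s, pad = as.raw(0x00))
val_ds <- function(x) val_str(paste(formatC(as.numeric(x), format = "g", digits = 10),
                                    collapse = "\\"))
val_is <- function(x) val_str(paste(as.integer(x), collapse = "\\"))
val_us <- function(x) uint16_raw(x)

# signed write of unsigned 16-bit payloads
uint16_payload <- function(v) {
  v <- as.integer(round(v))
  v[v < 0L] <- 0L
  v[v > 65535L] <- 65535L
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, raw(), size = 2, endian = "little")
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, value) {
  head <- c(uint16_raw(group), uint16_raw(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), uint32_raw(length(value)), value)
  } else {
    if (length(value) > 65534) stop("value too long for short-form VR ", vr)
    c(head, uint16_raw(length(value)), value)
  }
}

# sequence with undefined length; items with undefined length
dcm_sequence <- function(group, element, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body,
              uint16_raw(0xFFFE), uint16_raw(0xE000), as.raw(rep(0xFF, 4)),
              it,
              uint16_raw(0xFFFE), uint16_raw(0xE00D), uint32_raw(0))
  }
  c(uint16_raw(group), uint16_raw(element), charToRaw("SQ"), as.raw(c(0, 0)),
    as.raw(rep(0xFF, 4)), body,
    uint16_raw(0xFFFE), uint16_raw(0xE0DD), uint32_raw(0))
}

dcm_write_file <- function(path, sop_class, sop_instance, dataset) {
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    dcm_element(0x0002, 0x0002, "UI", val_ui(sop_class)),
    dcm_element(0x0002, 0x0003, "UI", val_ui(sop_instance)),
    dcm_element(0x0002, 0x0010, "UI", val_ui(TRANSFER_SYNTAX_ELE)),
    dcm_element(0x0002, 0x0012, "UI", val_ui("2.25.4242424242")))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_raw(length(meta_body))),
            meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0, 128)), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

frame_iop <- function(frame) {
  c(frame$direction[, 1], frame$direction[, 2])
}

common_geometry_elements <- function(frame, ipp) {
  # caller is responsible for tag ordering around these (group 0020/0028)
  list(
    ipp = dcm_element(0x0020, 0x0032, "DS", val_ds(ipp)),
    iop = dcm_element(0x0020, 0x0037, "DS", val_ds(frame_iop(frame))),
    pixel_spacing = dcm_element(0x0028, 0x0030, "DS",
                                val_ds(c(frame$spacing[2], frame$spacing[1]))))
}

#' Write a synthetic CT series as DICOM files
#'
#' One file per axial slice, Explicit VR Little Endian, 16-bit unsigned pixels
#' with rescale intercept -1024 (so HU from -1024 to 64511 are representable).
#'
#' @param dir output directory (created if needed).
#' @param hu 3D array of Hounsfield units, dim = `frame$shape`.
#' @param frame an [image_frame()].
#' @param uid_root root string for deterministic UID generation (digits and
#'   dots); distinct cases must use distinct roots.
#' @return invisibly, the vector of file paths written.
#' @export
write_ct_series <- function(dir, hu, frame, uid_root = "2.25.1000") {
  stopifnot(is_image_frame(frame))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nz <- frame$shape[3]
  study_uid <- paste0(uid_root, ".1")
  series_uid <- paste0(uid_root, ".2")
  for_uid <- paste0(uid_root, ".3")
  paths <- character(nz)
  for (k in seq_len(nz)) {
    sop_uid <- paste0(uid_root, ".1", sprintf("%04d", k))
    ipp <- drop(index_to_world(frame, c(1, 1, k)))
    geo <- common_geometry_elements(frame, ipp)
    slice <- hu[, , k] + 1024
    dataset <- c(
      dcm_element(0x0008, 0x0016, "UI", val_ui(SOP_CLASS[["ct"]])),
      dcm_element(0x0008, 0x0018, "UI", val_ui(sop_uid)),
      dcm_element(0x0008, 0x0060, "CS", val_str("CT")),
      dcm_element(0x0018, 0x0050, "DS", val_ds(frame$spacing[3])),
      dcm_element(0x0020, 0x000D, "UI", val_ui(study_uid)),
      dcm_element(0x0020, 0x000E, "UI", val_ui(series_uid)),
      dcm_element(0x0020, 0x0013, "IS", val_is(k)),
      geo$ipp, geo$iop,
      dcm_element(0x0020, 0x0052, "UI", val_ui(for_uid)),
      dcm_element(0x0028, 0x0002, "US", val_us(1)),
      dcm_element(0x0028, 0x0004, "CS", val_str("MONOCHROME2")),
      dcm_element(0x0028, 0x0010, "US", val_us(frame$shape[2])),
      dcm_element(0x0028, 0x0011, "US", val_us(frame$shape[1])),
      geo$pixel_spacing,
      dcm_element(0x0028, 0x0100, "US", val_us(16)),
      dcm_element(0x0028, 0x0101, "US", val_us(16)),
      dcm_element(0x0028, 0x0102, "US", val_us(15)),
      dcm_element(0x0028, 0x0103, "US", val_us(0)),
      dcm_element(0x0028, 0x1052, "DS", val_ds(-1024)),
      dcm_element(0x0028, 0x1053, "DS", val_ds(1)),
      dcm_element(0x7FE0, 0x0010, "OW", uint16_payload(slice)))
    paths[k] <- file.path(dir, sprintf("ct_%04d.dcm", k))
    dcm_write_file(paths[k], SOP_CLASS[["ct"]], sop_uid, dataset)
  }
  invisible(paths)
}

#' Write a dose grid as a DICOM RTDOSE file
#'
#' Multi-frame 16-bit dose with a dose-grid scaling factor chosen so the peak
#' dose uses most of the integer range; the round-trip quantum is the scaling
#' factor.
#'
#' @param path output file path.
#' @param dose a [dose_grid()].
#' @param uid_root deterministic UID root.
#' @param scaling dose grid scaling in Gy per stored unit; default scales the
#'   maximum dose to 60000 stored units.
#' @return invisibly `path`.
#' @export
write_rtdose <- function(path, dose, uid_root = "2.25.1000", scaling = NULL) {
  frame <- dose$frame
  if (is.null(scaling)) {
    mx <- max(dose$values)
    scaling <- if (mx > 0) mx / 60000 else 1e-4
  }
  sop_uid <- paste0(uid_root, ".20")
  ipp <- drop(index_to_world(frame, c(1, 1, 1)))
  geo <- common_geometry_elements(frame, ipp)
  offsets <- (seq_len(frame$shape[3]) - 1) * frame$spacing[3]
  stored <- round(dose$values / scaling)
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", val_ui(SOP_CLASS[["rtdose"]])),
    dcm_element(0x0008, 0x0018, "UI", val_ui(sop_uid)),
    dcm_element(0x0008, 0x0060, "CS", val_str("RTDOSE")),
    dcm_element(0x0020, 0x000D, "UI", val_ui(paste0(uid_root, ".1"))),
    dcm_element(0x0020, 0x000E, "UI", val_ui(paste0(uid_root, ".21"))),
    geo$ipp, geo$iop,
    dcm_element(0x0020, 0x0052, "UI", val_ui(paste0(uid_root, ".3"))),
    dcm_element(0x0028, 0x0002, "US", val_us(1)),
    dcm_element(0x0028, 0x0004, "CS", val_str("MONOCHROME2")),
    dcm_element(0x0028, 0x0008, "IS", val_is(frame$shape[3])),
    dcm_element(0x0028, 0x0010, "US", val_us(frame$shape[2])),
    dcm_element(0x0028, 0x0011, "US", val_us(frame$shape[1])),
    geo$pixel_spacing,
    dcm_element(0x0028, 0x0100, "US", val_us(16)),
    dcm_element(0x0028, 0x0101, "US", val_us(16)),
    dcm_element(0x0028, 0x0102, "US", val_us(15)),
    dcm_element(0x0028, 0x0103, "US", val_us(0)),
    dcm_element(0x3004, 0x0002, "CS", val_str("GY")),
    dcm_element(0x3004, 0x0004, "CS", val_str("PHYSICAL")),
    dcm_element(0x3004, 0x000A, "CS", val_str("PLAN")),
    dcm_element(0x3004, 0x000C, "DS", val_ds(offsets)),
    dcm_element(0x3004, 0x000E, "DS", val_ds(scaling)),
    dcm_element(0x7FE0, 0x0010, "OW", uint16_payload(stored)))
  dcm_write_file(path, SOP_CLASS[["rtdose"]], sop_uid, dataset)
}

#' Write contour sets as a DICOM RTSTRUCT file
#'
#' @param path output file path.
#' @param contour_sets list of [contour_set()] objects (one ROI each).
#' @param uid_root deterministic UID root.
#' @return invisibly `path`.
#' @export
write_rtstruct <- function(path, contour_sets, uid_root = "2.25.1000") {
  sop_uid <- paste0(uid_root, ".30")
  for_uid <- paste0(uid_root, ".3")
  roi_items <- list()
  contour_items <- list()
  for (r in seq_along(contour_sets)) {
    cs <- contour_sets[[r]]
    roi_items[[r]] <- c(
      dcm_element(0x3006, 0x0022, "IS", val_is(r)),
      dcm_element(0x3006, 0x0024, "UI", val_ui(for_uid)),
      dcm_element(0x3006, 0x0026, "LO", val_str(cs$name)))
    polys <- lapply(cs$contours, function(cc) {
      pts <- cbind(cc$xy, cc$z)
      c(dcm_element(0x3006, 0x0042, "CS", val_str("CLOSED_PLANAR")),
        dcm_element(0x3006, 0x0046, "IS", val_is(nrow(pts))),
        dcm_element(0x3006, 0x0050, "DS", val_ds(as.numeric(t(pts)))))
    })
    contour_items[[r]] <- c(
      dcm_sequence(0x3006, 0x0040, polys),
      dcm_element(0x3006, 0x0084, "IS", val_is(r)))
  }
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", val_ui(SOP_CLASS[["rtstruct"]])),
    dcm_element(0x0008, 0x0018, "UI", val_ui(sop_uid)),
    dcm_element(0x0008, 0x0060, "CS", val_str("RTSTRUCT")),
    dcm_element(0x0020, 0x000D, "UI", val_ui(paste0(uid_root, ".1"))),
    dcm_element(0x0020, 0x000E, "UI", val_ui(paste0(uid_root, ".31"))),
    dcm_element(0x3006, 0x0002, "SH", val_str("SYNTHETIC")),
    dcm_sequence(0x3006, 0x0020, roi_items),
    dcm_sequence(0x3006, 0x0039, contour_items))
  dcm_write_file(path, SOP_CLASS[["rtstruct"]], sop_uid, dataset)
}
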
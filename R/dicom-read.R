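# Minimal DICOM parser (Explicit VR Little Endian) sufficient for CT series,
# RTDOSE and RTSTRUCT objects, including nested sequences with defined or
# undefined lengths.

dcm_key <- function(group, element) sprintf("%04X%04X", group, element)

read_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1])
}
read_u32 <- function(bytes, pos) {
  read_u16(bytes, pos) + 65536 * read_u16(bytes, pos + 2)
}

# parse a dataset between pos and endpos (1-based, inclusive start)
dcm_parse_dataset <- function(bytes, pos, endpos) {
  out <- list()
  while (pos + 7 <= endpos + 1 && pos <= endpos) {
    group <- read_u16(bytes, pos)
    element <- read_u16(bytes, pos + 2)
    if (group == 0xFFFE) {        # delimiters handled by caller
      break
    }
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, pos + 8)
      body <- pos + 12
    } else {
      len <- read_u16(bytes, pos + 6)
      body <- pos + 8
    }
    if (vr == "SQ") {
      parsed <- dcm_parse_sequence(bytes, body, len, endpos)
      out[[dcm_key(group, element)]] <- list(vr = vr, items = parsed$items)
      pos <- parsed$pos
    } else {
      if (len == 0xFFFFFFFF) stop("undefined length on non-sequence element")
      value <- if (len > 0) bytes[body:(body + len - 1)] else raw(0)
      out[[dcm_key(group, element)]] <- list(vr = vr, value = value)
      pos <- body + len
    }
  }
  list(elements = out, pos = pos)
}

dcm_parse_sequence <- function(bytes, pos, len, endpos) {
  items <- list()
  seq_end <- if (len == 0xFFFFFFFF) endpos else pos + len - 1
  while (pos + 7 <= seq_end + 1 && pos <= seq_end) {
    group <- read_u16(bytes, pos)
    element <- read_u16(bytes, pos + 2)
    ilen <- read_u32(bytes, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break          # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop("malformed sequence: expected item tag")
    if (ilen == 0xFFFFFFFF) {
      parsed <- dcm_parse_dataset(bytes, pos, seq_end)
      pos <- parsed$pos
      # expect item delimiter
      if (read_u16(bytes, pos) == 0xFFFE && read_u16(bytes, pos + 2) == 0xE00D)
        pos <- pos + 8
    } else {
      parsed <- dcm_parse_dataset(bytes, pos, pos + ilen - 1)
      pos <- pos + ilen
    }
    items[[length(items) + 1L]] <- parsed$elements
  }
  list(items = items, pos = pos)
}

#' Parse one DICOM file (Explicit VR Little Endian)
#'
#' Low-level access used by the CT/RTDOSE/RTSTRUCT readers; returns all
#' elements keyed by `GGGGEEEE` hex tag.
#' @param path DICOM file path.
#' @return list with `meta` and `data` element lists.
#' @export
dicom_parse <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133
  # file meta group (always explicit LE)
  gl <- dcm_parse_dataset(bytes, pos, pos + 11)  # (0002,0000) UL length
  meta_len <- read_u32(gl$elements[["00020000"]]$value, 1)
  meta <- dcm_parse_dataset(bytes, gl$pos, gl$pos + meta_len - 1)
  ts <- dcm_element_string(meta$elements[["00020010"]])
  if (!identical(ts, TRANSFER_SYNTAX_ELE))
    stop("unsupported transfer syntax: ", ts)
  data <- dcm_parse_dataset(bytes, meta$pos, length(bytes))
  list(meta = meta$elements, data = data$elements)
}

dcm_element_string <- function(el) {
  if (is.null(el)) return(NULL)
  v <- el$value
  v <- v[v != as.raw(0)]             # UI values are nul-padded
  sub(" +$", "", rawToChar(v))
}
dcm_element_strings <- function(el) {
  if (is.null(el)) return(NULL)
  strsplit(dcm_element_string(el), "\\", fixed = TRUE)[[1]]
}
dcm_element_numeric <- function(el) as.numeric(dcm_element_strings(el))
dcm_element_u16s <- function(el) {
  v <- readBin(el$value, integer(), n = length(el$value) / 2, size = 2,
               endian = "little", signed = FALSE)
  v
}

require_element <- function(elements, key, what) {
  el <- elements[[key]]
  if (is.null(el)) stop("missing DICOM tag (", key, "): ", what)
  el
}

#' Read a DICOM CT series into a HU volume and its frame
#'
#' Slices are sorted by their position along the slice normal regardless of
#' file order; the rescale slope/intercept is applied so values are Hounsfield
#' units.
#'
#' @param directory_path directory containing exactly one CT series
#'   (`*.dcm` files).
#' @return list with `frame` ([image_frame()]) and `hu` (3D array).
#' @export
read_ct_series <- function(directory_path) {
  files <- list.files(directory_path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no DICOM files in ", directory_path)
  slices <- lapply(files, function(f) {
    d <- dicom_parse(f)$data
    modality <- dcm_element_string(d[["00080060"]])
    if (!identical(modality, "CT")) return(NULL)
    list(
      series = dcm_element_string(require_element(d, "0020000E", "SeriesInstanceUID")),
      ipp = dcm_element_numeric(require_element(d, "00200032", "ImagePositionPatient")),
      iop = dcm_element_numeric(require_element(d, "00200037", "ImageOrientationPatient")),
      px = dcm_element_numeric(require_element(d, "00280030", "PixelSpacing")),
      rows = dcm_element_u16s(require_element(d, "00280010", "Rows")),
      cols = dcm_element_u16s(require_element(d, "00280011", "Columns")),
      slope = if (!is.null(d[["00281053"]])) dcm_element_numeric(d[["00281053"]]) else 1,
      intercept = if (!is.null(d[["00281052"]])) dcm_element_numeric(d[["00281052"]]) else 0,
      pixels = dcm_element_u16s(require_element(d, "7FE00010", "PixelData")))
  })
  slices <- Filter(Negate(is.null), slices)
  if (length(slices) == 0) stop("no CT slices found in ", directory_path)
  series_ids <- unique(vapply(slices, `[[`, character(1), "series"))
  if (length(series_ids) > 1)
    stop("mixed CT series in directory: ", paste(series_ids, collapse = ", "))
  px <- unique(t(vapply(slices, `[[`, numeric(2), "px")))
  if (nrow(px) > 1)
    stop("inconsistent pixel spacing within series ", series_ids,
         ": ", paste(apply(px, 1, paste, collapse = "/"), collapse = " vs "))
  iop <- slices[[1]]$iop
  rdir <- iop[1:3]; cdir <- iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]
  nz <- length(slices)
  if (nz > 1) {
    dz <- diff(zpos)
    if (max(dz) - min(dz) > 1e-4 * max(abs(dz)) + 1e-6)
      stop("non-uniform slice positions in series ", series_ids)
    dz <- mean(dz)
  } else dz <- 1
  nx <- as.integer(slices[[1]]$cols)
  ny <- as.integer(slices[[1]]$rows)
  frame <- image_frame(
    origin = slices[[1]]$ipp,
    spacing = c(slices[[1]]$px[2], slices[[1]]$px[1], dz),
    shape = c(nx, ny, nz),
    direction = cbind(rdir, cdir, normal))
  hu <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    hu[, , k] <- s$pixels * s$slope + s$intercept
  }
  list(frame = frame, hu = hu)
}

#' Read a DICOM RTDOSE file
#'
#' Stored integer pixels are multiplied by the dose grid scaling factor so the
#' returned values are in Gy.
#'
#' @param file_path RTDOSE file path.
#' @return a [dose_grid()].
#' @export
read_rtdose <- function(file_path) {
  d <- dicom_parse(file_path)$data
  scaling_el <- d[["3004000E"]]
  if (is.null(scaling_el)) stop("RTDOSE without DoseGridScaling: ", file_path)
  scaling <- dcm_element_numeric(scaling_el)
  offsets <- dcm_element_numeric(require_element(d, "3004000C", "GridFrameOffsetVector"))
  if (length(offsets) > 1) {
    dz <- diff(offsets)
    if (max(dz) - min(dz) > 1e-4 * max(abs(dz)) + 1e-6)
      stop("non-uniform GridFrameOffsetVector in ", file_path)
    dz <- mean(dz)
  } else dz <- 1
  ipp <- dcm_element_numeric(require_element(d, "00200032", "ImagePositionPatient"))
  iop <- dcm_element_numeric(require_element(d, "00200037", "ImageOrientationPatient"))
  px <- dcm_element_numeric(require_element(d, "00280030", "PixelSpacing"))
  nx <- as.integer(dcm_element_u16s(require_element(d, "00280011", "Columns")))
  ny <- as.integer(dcm_element_u16s(require_element(d, "00280010", "Rows")))
  nz <- length(offsets)
  rdir <- iop[1:3]; cdir <- iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  frame <- image_frame(origin = ipp, spacing = c(px[2], px[1], dz),
                       shape = c(nx, ny, nz),
                       direction = cbind(rdir, cdir, normal))
  stored <- dcm_element_u16s(require_element(d, "7FE00010", "PixelData"))
  values <- array(stored * scaling, dim = c(nx, ny, nz))
  dose_grid(frame, values)
}

#' Read requested ROIs from a DICOM RTSTRUCT file
#'
#' ROI names are matched case-insensitively; when a requested ROI is absent the
#' error lists the names present in the file.
#'
#' @param file_path RTSTRUCT file path.
#' @param roi_names character vector of structure names to extract.
#' @return named list of [contour_set()] objects (names as requested).
#' @export
read_rtstruct <- function(file_path, roi_names) {
  d <- dicom_parse(file_path)$data
  rois <- require_element(d, "30060020", "StructureSetROISequence")$items
  numbers <- vapply(rois, function(it) dcm_element_numeric(it[["30060022"]]), numeric(1))
  names_avail <- vapply(rois, function(it) dcm_element_string(it[["30060026"]]), character(1))
  ccs <- require_element(d, "30060039", "ROIContourSequence")$items
  ref_numbers <- vapply(ccs, function(it) dcm_element_numeric(it[["30060084"]]), numeric(1))
  out <- list()
  for (want in roi_names) {
    hit <- which(tolower(names_avail) == tolower(want))
    if (length(hit) == 0)
      stop("ROI '", want, "' not found; available: ",
           paste(sort(names_avail), collapse = ", "))
    roi_num <- numbers[hit[1]]
    citem <- ccs[[which(ref_numbers == roi_num)[1]]]
    polys <- lapply(citem[["30060040"]]$items, function(it) {
      pts <- matrix(dcm_element_numeric(it[["30060050"]]), ncol = 3, byrow = TRUE)
      list(z = mean(pts[, 3]), xy = pts[, 1:2, drop = FALSE])
    })
    out[[want]] <- contour_set(names_avail[hit[1]], polys)
  }
  out
}
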
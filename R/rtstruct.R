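# Minimal DICOM codec for RT Structure Sets (explicit VR little endian).
# Scope: enough of PS3.5/PS3.10 encoding to read and write RTSTRUCT contour
# geometry; not a general DICOM library.

SOP_CLASS_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "2.25"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32le <- function(x) {
  # avoid 32-bit overflow for 0xFFFFFFFF
  lo <- x %% 65536; hi <- (x - lo) / 65536
  c(uint16le(lo), uint16le(hi))
}
read_u16 <- function(b, pos) sum(as.integer(b[pos:(pos + 1)]) * c(1, 256))
read_u32 <- function(b, pos) sum(as.integer(b[pos:(pos + 3)]) * c(1, 256, 65536, 16777216))

pad_even <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2 == 1) c(v, pad) else v
}

dcm_string <- function(s, vr) {
  pad <- if (vr %in% c("UI")) as.raw(0) else as.raw(0x20)
  pad_even(charToRaw(s), pad)
}

# one encoded data element (explicit VR LE)
dcm_elem <- function(group, elem, vr, value) {
  hdr <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), uint32le(length(value)), value)
  } else {
    if (length(value) > 65534) stop("value too long for short VR")
    c(hdr, uint16le(length(value)), value)
  }
}

dcm_sq <- function(group, elem, items) {
  body <- unlist(lapply(items, function(it)
    c(uint16le(0xFFFE), uint16le(0xE000), uint32le(4294967295), it,
      uint16le(0xFFFE), uint16le(0xE00D), uint32le(0))))
  c(uint16le(group), uint16le(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    uint32le(4294967295), body %||% raw(0),
    uint16le(0xFFFE), uint16le(0xE0DD), uint32le(0))
}

# deterministic numeric UID from a character seed
dcm_uid <- function(seed_chr) {
  h <- 0
  for (ch in utf8ToInt(seed_chr)) h <- (h * 131 + ch) %% 1e15
  paste0(UID_ROOT, ".", 1 + h)
}

fmt_ds <- function(x) {
  s <- sub("0+$", "", sprintf("%.6f", x))
  sub("\\.$", "", s)
}

#' Write a contour set as a DICOM RT Structure Set
#'
#' Encodes the contours as CLOSED_PLANAR items in explicit VR little endian.
#' The project (x, z, y) axes map onto the DICOM patient coordinate triplet
#' (x, y, z): in-plane x and z become the first two components and the
#' slice coordinate y becomes the DICOM z component.
#'
#' @param cs a valid `contour_set` (the constructor enforces >= 3 points per
#'   polygon and simple polygons).
#' @param path output file path.
#' @param ref_volume optional `ct_volume`; recorded only through the frame
#'   of reference (no image series is embedded).
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(cs, path, ref_volume = NULL) {
  if (!is_contour_set(cs)) stop("cs must be a contour_set")
  if (length(cs$slices) == 0L) stop("contour set has no slices")
  for_uid <- if (grepl("^[0-9.]+$", cs$frame_of_reference))
    cs$frame_of_reference else dcm_uid(cs$frame_of_reference)
  sop_uid <- dcm_uid(paste0("sop-", cs$structure, length(cs$slices)))

  roi_item <- c(
    dcm_elem(0x3006, 0x0022, "IS", dcm_string("1", "IS")),
    dcm_elem(0x3006, 0x0024, "UI", dcm_string(for_uid, "UI")),
    dcm_elem(0x3006, 0x0026, "LO", dcm_string(cs$structure, "LO")))
  contour_items <- lapply(cs$slices, function(s) {
    pts <- cbind(s$points[, 1], s$points[, 2], s$y)   # DICOM (x, y, z)
    data <- paste(apply(pts, 1, function(p)
      paste(fmt_ds(p), collapse = "\\")), collapse = "\\")
    c(dcm_elem(0x3006, 0x0042, "CS", dcm_string("CLOSED_PLANAR", "CS")),
      dcm_elem(0x3006, 0x0046, "IS", dcm_string(as.character(nrow(pts)), "IS")),
      dcm_elem(0x3006, 0x0050, "DS", dcm_string(data, "DS")))
  })
  roi_contour_item <- c(
    dcm_sq(0x3006, 0x0040, contour_items),
    dcm_elem(0x3006, 0x0084, "IS", dcm_string("1", "IS")))

  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", dcm_string(SOP_CLASS_RTSTRUCT, "UI")),
    dcm_elem(0x0008, 0x0018, "UI", dcm_string(sop_uid, "UI")),
    dcm_elem(0x0008, 0x0060, "CS", dcm_string("RTSTRUCT", "CS")),
    dcm_elem(0x0010, 0x0010, "PN", dcm_string("PHANTOM", "PN")),
    dcm_elem(0x0010, 0x0020, "LO", dcm_string("CC-SYNTH", "LO")),
    dcm_elem(0x0020, 0x000D, "UI", dcm_string(dcm_uid("study"), "UI")),
    dcm_elem(0x0020, 0x000E, "UI", dcm_string(dcm_uid("series"), "UI")),
    dcm_elem(0x3006, 0x0002, "SH", dcm_string("contourcast", "SH")),
    dcm_sq(0x3006, 0x0010, list(
      dcm_elem(0x0020, 0x0052, "UI", dcm_string(for_uid, "UI")))),
    dcm_sq(0x3006, 0x0020, list(roi_item)),
    dcm_sq(0x3006, 0x0039, list(roi_contour_item)))

  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", dcm_string(SOP_CLASS_RTSTRUCT, "UI")),
    dcm_elem(0x0002, 0x0003, "UI", dcm_string(sop_uid, "UI")),
    dcm_elem(0x0002, 0x0010, "UI", dcm_string(TS_EXPLICIT_LE, "UI")),
    dcm_elem(0x0002, 0x0012, "UI", dcm_string(dcm_uid("impl"), "UI")))
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", uint32le(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

# --- reader --------------------------------------------------------------

# parse an explicit-VR-LE dataset from raw bytes; returns a named list
# keyed "GGGGEEEE" (hex); SQ values are lists of item datasets
parse_dicom_dataset <- function(b, pos, end) {
  out <- list()
  while (pos + 7 <= end + 1 && pos < end) {
    group <- read_u16(b, pos); elem <- read_u16(b, pos + 2); pos <- pos + 4
    if (group == 0xFFFE) {            # delimiter at this level: stop
      len <- read_u32(b, pos)
      return(list(data = out, pos = pos + 4, delim = elem))
    }
    vr <- rawToChar(b[pos:(pos + 1)]); pos <- pos + 2
    if (vr %in% LONG_VRS) {
      pos <- pos + 2
      len <- read_u32(b, pos); pos <- pos + 4
    } else {
      len <- read_u16(b, pos); pos <- pos + 2
    }
    key <- sprintf("%04X%04X", group, elem)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {
        repeat {
          ig <- read_u16(b, pos); ie <- read_u16(b, pos + 2)
          ilen <- read_u32(b, pos + 4); pos <- pos + 8
          if (ig != 0xFFFE) stop("malformed sequence in DICOM stream")
          if (ie == 0xE0DD) break
          if (ie != 0xE000) stop("unexpected tag in sequence")
          if (ilen == 4294967295) {
            r <- parse_dicom_dataset(b, pos, length(b))
            if (is.null(r$delim) || r$delim != 0xE00D)
              stop("unterminated sequence item")
            items[[length(items) + 1L]] <- r$data
            pos <- r$pos
          } else {
            r <- parse_dicom_dataset(b, pos, pos + ilen - 1)
            items[[length(items) + 1L]] <- r$data
            pos <- pos + ilen
          }
        }
      } else {
        endsq <- pos + len - 1
        while (pos < endsq) {
          ig <- read_u16(b, pos); ie <- read_u16(b, pos + 2)
          ilen <- read_u32(b, pos + 4); pos <- pos + 8
          if (ig != 0xFFFE || ie != 0xE000) stop("malformed defined-length sequence")
          r <- parse_dicom_dataset(b, pos, pos + ilen - 1)
          items[[length(items) + 1L]] <- r$data
          pos <- pos + ilen
        }
      }
      out[[key]] <- structure(items, vr = "SQ")
    } else {
      val <- if (len > 0) b[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      out[[key]] <- structure(val, vr = vr)
    }
  }
  list(data = out, pos = pos, delim = NULL)
}

dcm_str_value <- function(el) {
  if (is.null(el)) return(NULL)
  v <- unclass(el)
  while (length(v) && (v[length(v)] == as.raw(0) || v[length(v)] == as.raw(0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}

#' Read a structure's contours from a DICOM RT Structure Set
#'
#' Parses an explicit-VR little-endian RTSTRUCT and returns the named
#' structure's CLOSED_PLANAR contours in patient mm coordinates under the
#' project axis convention (DICOM patient (x, y, z) mapped to project
#' (x, z, y); the slice coordinate is the DICOM z component). Contour and
#' point order is preserved within slices; slices are sorted by y.
#'
#' @param path RTSTRUCT file path.
#' @param structure_name name of the ROI to extract.
#' @return A `contour_set`.
#' @export
read_rtstruct <- function(path, structure_name) {
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133
  meta <- parse_dicom_dataset(b, pos, length(b))
  # meta group parsed together with the dataset (all explicit VR LE here)
  ds <- meta$data
  ts <- dcm_str_value(ds[["00020010"]])
  if (!is.null(ts) && ts != TS_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  rois <- ds[["30060020"]]
  if (is.null(rois)) stop("file has no StructureSetROISequence: ", path)
  names_avail <- vapply(rois, function(it)
    dcm_str_value(it[["30060026"]]) %||% "", character(1))
  hit <- which(names_avail == structure_name)
  if (length(hit) == 0L)
    stop("structure '", structure_name, "' not found; available: ",
         paste(names_avail, collapse = ", "))
  fors <- unique(vapply(rois[hit], function(it)
    dcm_str_value(it[["30060024"]]) %||% "", character(1)))
  if (length(fors) > 1L)
    stop("mixed frames of reference for structure '", structure_name, "'")
  roi_num <- dcm_str_value(rois[[hit[1]]][["30060022"]])
  rcs <- ds[["30060039"]]
  if (is.null(rcs)) stop("file has no ROIContourSequence: ", path)
  match_item <- NULL
  for (it in rcs)
    if (identical(dcm_str_value(it[["30060084"]]), roi_num)) match_item <- it
  if (is.null(match_item))
    stop("no ROIContourSequence item for ROI number ", roi_num)
  slices <- lapply(match_item[["30060040"]], function(cit) {
    nums <- as.numeric(strsplit(dcm_str_value(cit[["30060050"]]), "\\\\")[[1]])
    pts <- matrix(nums, ncol = 3, byrow = TRUE)
    if (diff(range(pts[, 3])) > 1e-6)
      stop("non-planar contour item in RTSTRUCT")
    list(y = pts[1, 3], points = pts[, 1:2, drop = FALSE])
  })
  contour_set(slices, structure = structure_name,
              frame_of_reference = fors, observer = NA_character_)
}
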
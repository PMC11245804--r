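# Minimal DICOM codec: Explicit VR Little Endian, covering the tags the
# pipeline consumes (pixel description, rescale/window parameters, modality,
# body part, study description and a few auxiliary acquisition tags).
# Multi-valued string elements use the standard backslash separator.

.dicom_dict <- local({
  d <- rbind(
    c("0008", "0016", "UI", "SOPClassUID"),
    c("0008", "0018", "UI", "SOPInstanceUID"),
    c("0008", "0060", "CS", "Modality"),
    c("0008", "1030", "LO", "StudyDescription"),
    c("0010", "0020", "LO", "PatientID"),
    c("0010", "1010", "IS", "PatientAge"),
    c("0018", "0015", "CS", "BodyPartExamined"),
    c("0018", "0050", "DS", "SliceThickness"),
    c("0018", "0060", "DS", "KVP"),
    c("0018", "1150", "IS", "ExposureTime"),
    c("0020", "000D", "UI", "StudyInstanceUID"),
    c("0028", "0002", "US", "SamplesPerPixel"),
    c("0028", "0004", "CS", "PhotometricInterpretation"),
    c("0028", "0010", "US", "Rows"),
    c("0028", "0011", "US", "Columns"),
    c("0028", "0100", "US", "BitsAllocated"),
    c("0028", "0101", "US", "BitsStored"),
    c("0028", "0102", "US", "HighBit"),
    c("0028", "0103", "US", "PixelRepresentation"),
    c("0028", "1050", "DS", "WindowCenter"),
    c("0028", "1051", "DS", "WindowWidth"),
    c("0028", "1052", "DS", "RescaleIntercept"),
    c("0028", "1053", "DS", "RescaleSlope"),
    c("7FE0", "0010", "OW", "PixelData")
  )
  data.frame(group = d[, 1], element = d[, 2], vr = d[, 3], name = d[, 4],
             stringsAsFactors = FALSE)
})

.uint16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.uint32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.hex16 <- function(h) .uint16_raw(strtoi(h, 16L))

.string_raw <- function(s, pad = as.raw(32L)) {
  b <- charToRaw(enc2utf8(s))
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

.decode_string <- function(val_raw) {
  while (length(val_raw) && as.integer(val_raw[length(val_raw)]) %in% c(0L, 32L)) {
    val_raw <- val_raw[-length(val_raw)]
  }
  rawToChar(val_raw)
}

# one explicit-VR element as raw bytes
.dicom_element <- function(group, element, vr, value_raw) {
  hdr <- c(.hex16(group), .hex16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(hdr, as.raw(c(0, 0)), .uint32_raw(length(value_raw)), value_raw)
  } else {
    stopifnot(length(value_raw) <= 65534)
    c(hdr, .uint16_raw(length(value_raw)), value_raw)
  }
}

.encode_value <- function(vr, value) {
  switch(vr,
    US = .uint16_raw(value),
    OW = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UI = .string_raw(paste(value, collapse = "\\"), pad = as.raw(0L)),
    DS = .string_raw(paste(formatC(value, format = "fg", digits = 10),
                           collapse = "\\")),
    IS = .string_raw(paste(as.integer(value), collapse = "\\")),
    .string_raw(paste(value, collapse = "\\"))
  )
}

#' Write a minimal DICOM file
#'
#' Serialises one image and its header tags as an Explicit VR Little Endian
#' DICOM file (128-byte preamble, `DICM` magic, file meta group, dataset).
#' Only the tags in the package's dictionary are supported; that covers
#' everything the preprocessing pipeline reads.
#'
#' @param path output file path.
#' @param pixels integer matrix of raw pixel values (rows x columns).
#' @param tags named list of header values keyed by DICOM keyword
#'   (e.g. `Modality`, `BodyPartExamined`, `WindowCenter`); vector values
#'   become multi-valued elements. `NA` entries are skipped; empty strings are
#'   written as present-but-empty (zero length) elements.
#' @param bits_stored stored bit depth in `[12, 16]`.
#' @return `path`, invisibly.
#' @seealso [read_dicom()]
#' @export
write_dicom <- function(path, pixels, tags = list(), bits_stored = 16L) {
  stopifnot(is.matrix(pixels), bits_stored >= 1L, bits_stored <= 16L)
  pix <- as.integer(t(pixels))  # DICOM is row-major
  if (any(pix < 0L | pix >= 2L^bits_stored)) {
    stop("pixel values do not fit in bits_stored bits", call. = FALSE)
  }
  base <- list(
    SamplesPerPixel = 1L,
    PhotometricInterpretation = "MONOCHROME2",
    Rows = nrow(pixels), Columns = ncol(pixels),
    BitsAllocated = 16L, BitsStored = as.integer(bits_stored),
    HighBit = as.integer(bits_stored) - 1L, PixelRepresentation = 0L
  )
  tags <- utils::modifyList(base, tags)
  tags$PixelData <- pix

  body <- raw(0)
  dict <- .dicom_dict[order(.dicom_dict$group, .dicom_dict$element), ]
  for (i in seq_len(nrow(dict))) {
    nm <- dict$name[i]
    if (is.null(tags[[nm]]) || (length(tags[[nm]]) == 1L && is.na(tags[[nm]]))) next
    val <- tags[[nm]]
    vraw <- if (is.character(val) && all(!nzchar(val))) raw(0) else
      .encode_value(dict$vr[i], val)
    body <- c(body, .dicom_element(dict$group[i], dict$element[i], dict$vr[i], vraw))
  }

  ts_uid <- "1.2.840.10008.1.2.1"  # Explicit VR Little Endian
  meta <- c(
    .dicom_element("0002", "0001", "OB", as.raw(c(0, 1))),
    .dicom_element("0002", "0002", "UI",
                   .encode_value("UI", "1.2.840.10008.5.1.4.1.1.7")),
    .dicom_element("0002", "0003", "UI",
                   .encode_value("UI", tags$SOPInstanceUID %||% "1.2.3.4")),
    .dicom_element("0002", "0010", "UI", .encode_value("UI", ts_uid)),
    .dicom_element("0002", "0012", "UI", .encode_value("UI", "1.2.826.0.1.3680043.9.9999"))
  )
  group_len <- .dicom_element("0002", "0000", "UL", .uint32_raw(length(meta)))
  # UL uses the short explicit form
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

.read_uint16 <- function(b, at) {
  as.integer(b[at]) + 256L * as.integer(b[at + 1L])
}
.read_uint32 <- function(b, at) {
  sum(as.numeric(b[at + 0:3]) * 256^(0:3))
}

#' Read a minimal DICOM file
#'
#' Parses Explicit VR Little Endian DICOM files written by [write_dicom()]
#' (or any conformant writer restricted to the same transfer syntax and VRs).
#' Numeric string VRs (`DS`, `IS`) are decoded to numeric vectors; `US` to
#' integers; everything else to character strings. Pixel data is returned as
#' an integer matrix in row/column orientation.
#'
#' @param path DICOM file path.
#' @return a list with `pixels` (integer matrix or `NULL`) and `tags`
#'   (named list keyed by DICOM keyword; unknown tags keyed `"gggg,eeee"`).
#' @export
read_dicom <- function(path) {
  b <- readBin(path, "raw", n = file.size(path))
  assert_that(length(b) > 132 && rawToChar(b[129:132]) == "DICM",
              "not a DICOM file (missing DICM magic)")
  pos <- 133L
  tags <- list()
  pixels <- NULL
  dims <- c(NA_integer_, NA_integer_)
  while (pos + 7L <= length(b)) {
    group <- .read_uint16(b, pos)
    element <- .read_uint16(b, pos + 2L)
    vr <- rawToChar(b[pos + 4:5])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- .read_uint32(b, pos + 8L)
      at <- pos + 12L
    } else {
      len <- .read_uint16(b, pos + 6L)
      at <- pos + 8L
    }
    val_raw <- if (len > 0) b[at:(at + len - 1L)] else raw(0)
    pos <- at + len
    if (group == 2L) next  # file meta handled implicitly (we only emit ELE)
    key <- sprintf("%04X,%04X", group, element)
    hit <- which(strtoi(.dicom_dict$group, 16L) == group &
                 strtoi(.dicom_dict$element, 16L) == element)
    name <- if (length(hit)) .dicom_dict$name[hit] else key
    value <- switch(vr,
      US = vapply(seq_len(len / 2L), function(i) .read_uint16(val_raw, 2L * i - 1L), 1L),
      OW = readBin(val_raw, "integer", n = len / 2L, size = 2,
                   endian = "little", signed = FALSE),
      DS = , IS = {
        s <- .decode_string(val_raw)
        if (nzchar(s)) as.numeric(strsplit(s, "\\\\")[[1]]) else numeric(0)
      },
      {
        s <- .decode_string(val_raw)
        if (grepl("\\\\", s)) strsplit(s, "\\\\")[[1]] else s
      }
    )
    if (name == "PixelData") {
      tags$PixelData <- TRUE
      rows <- tags$Rows; cols <- tags$Columns
      if (!is.null(rows) && !is.null(cols)) {
        pixels <- matrix(as.integer(value), nrow = rows, ncol = cols, byrow = TRUE)
      }
    } else {
      tags[[name]] <- value
    }
  }
  tags$PixelData <- NULL
  list(pixels = pixels, tags = tags)
}
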
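# Minimal DICOM support: uncompressed, explicit-VR little-endian files
# carrying a 16-bit monochrome pixel matrix -- the subset "for processing"
# radiographs use. No installed package provides DICOM I/O, so the small
# subset needed here (Rows/Columns/BitsAllocated/PixelSpacing/Rescale/
# PixelData) is implemented directly.

.uint16le <- function(n) writeBin(as.integer(n), raw(), size = 2,
                                  endian = "little")

.dcmElement <- function(group, element, vr, payload) {
  head <- c(.uint16le(group), .uint16le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(head, .uint16le(length(payload)), payload)
  }
}

.dcmString <- function(x) {
  r <- charToRaw(x)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

#' Write a minimal DICOM file
#'
#' Writes an uncompressed explicit-VR little-endian monochrome DICOM file
#' holding the (integer-rounded, 16-bit) pixel matrix of a radiograph,
#' with PixelSpacing taken from the image pitch. Intended for round-trip
#' testing and small interchange, not for PACS-grade output.
#'
#' @param image a \linkS4class{RadiographImage}; pixel values must lie in
#'   [0, 65535].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDicom <- function(image, path) {
  px <- pixels(image)
  if (any(px < 0 | px > 65535))
    stopf("pixel values outside the 16-bit range cannot be written")
  px <- round(px)
  tsuid <- "1.2.840.10008.1.2.1"  # explicit VR little endian
  metaEl <- c(
    .dcmElement(0x0002, 0x0010, "UI", .dcmString(tsuid))
  )
  meta <- c(
    .dcmElement(0x0002, 0x0000, "UL",
                writeBin(length(metaEl), raw(), size = 4, endian = "little")),
    metaEl
  )
  pitch <- sprintf("%.6g\\%.6g", pixelPitch(image), pixelPitch(image))
  # DICOM stores pixels row-major
  pixelBytes <- writeBin(as.integer(t(px)), raw(), size = 2,
                         endian = "little")
  body <- c(
    .dcmElement(0x0008, 0x0060, "CS", .dcmString("DX")),
    .dcmElement(0x0028, 0x0010, "US", .uint16le(nrow(px))),
    .dcmElement(0x0028, 0x0011, "US", .uint16le(ncol(px))),
    .dcmElement(0x0028, 0x0030, "DS", .dcmString(pitch)),
    .dcmElement(0x0028, 0x0100, "US", .uint16le(16)),
    .dcmElement(0x0028, 0x0101, "US", .uint16le(16)),
    .dcmElement(0x0028, 0x0103, "US", .uint16le(0)),
    .dcmElement(0x7FE0, 0x0010, "OW", pixelBytes)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Parse one explicit-VR element starting at offset i (1-based) of raw
# vector r; returns list(group, element, vr, value(raw), next).
.dcmReadElement <- function(r, i) {
  if (i + 7 > length(r)) return(NULL)
  grp <- readBin(r[i:(i + 1)], "integer", size = 2, signed = FALSE,
                 endian = "little")
  el <- readBin(r[(i + 2):(i + 3)], "integer", size = 2, signed = FALSE,
                endian = "little")
  vr <- rawToChar(r[(i + 4):(i + 5)])
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- readBin(r[(i + 8):(i + 11)], "integer", size = 4,
                   endian = "little")
    if (len < 0) stopf("undefined-length DICOM element (%04x,%04x) unsupported",
                       grp, el)
    start <- i + 12
  } else {
    len <- readBin(r[(i + 6):(i + 7)], "integer", size = 2, signed = FALSE,
                   endian = "little")
    start <- i + 8
  }
  value <- if (len > 0) r[start:(start + len - 1)] else raw(0)
  list(group = grp, element = el, vr = vr, value = value,
       nxt = start + len)
}

#' Read a minimal DICOM file
#'
#' Reads an uncompressed explicit-VR little-endian monochrome DICOM file.
#' Any rescale slope/intercept present in the header is applied to the
#' pixel values at read time (and reported via \code{message()}); the
#' result still counts as raw detector output
#' (\code{isLinearized = FALSE}).
#'
#' @param path file path.
#' @param pixelPitchMm optional pitch override in mm; mandatory when the
#'   file carries no PixelSpacing.
#' @param meta optional \linkS4class{AcquisitionMeta} to attach.
#' @return A \linkS4class{RadiographImage}.
#' @export
readDicom <- function(path, pixelPitchMm = NULL, meta = AcquisitionMeta()) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  r <- readBin(path, raw(), n = file.size(path))
  if (length(r) < 132 || rawToChar(r[129:132]) != "DICM")
    stopf("'%s' is not a DICOM file (missing DICM marker)", path)
  i <- 133
  tags <- list()
  repeat {
    e <- .dcmReadElement(r, i)
    if (is.null(e)) break
    key <- sprintf("%04x%04x", e$group, e$element)
    tags[[key]] <- e
    i <- e$nxt
    if (e$group == 0x7FE0 && e$element == 0x0010) break
  }
  need <- function(key, what) {
    if (is.null(tags[[key]])) stopf("DICOM file lacks %s", what)
    tags[[key]]
  }
  rows <- readBin(need("00280010", "Rows")$value, "integer", size = 2,
                  signed = FALSE, endian = "little")
  cols <- readBin(need("00280011", "Columns")$value, "integer", size = 2,
                  signed = FALSE, endian = "little")
  bits <- readBin(need("00280100", "BitsAllocated")$value, "integer",
                  size = 2, signed = FALSE, endian = "little")
  if (bits != 16) stopf("only 16-bit DICOM pixel data is supported")
  if (is.null(pixelPitchMm)) {
    ps <- tags[["00280030"]]
    if (is.null(ps))
      stopf("configuration error: no PixelSpacing in header and no pixelPitchMm override")
    pixelPitchMm <- as.numeric(strsplit(trimws(rawToChar(ps$value)),
                                        "\\\\")[[1]][1])
  }
  pd <- need("7fe00010", "PixelData")
  vals <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                  signed = FALSE, endian = "little")
  px <- matrix(as.double(vals), nrow = rows, ncol = cols, byrow = TRUE)
  slope <- tags[["00281053"]]
  intercept <- tags[["00281052"]]
  if (!is.null(slope) || !is.null(intercept)) {
    s <- if (is.null(slope)) 1 else as.numeric(rawToChar(slope$value))
    b <- if (is.null(intercept)) 0 else as.numeric(rawToChar(intercept$value))
    if (s != 1 || b != 0) {
      message(sprintf("applying DICOM rescale: slope %g, intercept %g", s, b))
      px <- px * s + b
    }
  }
  RadiographImage(px, pixelPitchMm, linearized = FALSE, meta = meta)
}
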
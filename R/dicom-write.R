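# Low-level DICOM Part-10 writer (explicit VR little endian), used by the
# synthetic fixture generator and by corruptStudy() when it rewrites files.

.encU16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.encU32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.fmtDS <- function(x) {
  s <- sprintf("%.10g", x)
  long <- nchar(s) > 16
  s[long] <- sprintf("%.8g", x[long])
  s
}

.encStringValue <- function(value, vr) {
  if (vr == "DS") value <- .fmtDS(as.numeric(value))
  if (vr == "IS") value <- sprintf("%d", as.integer(value))
  s <- paste(value, collapse = "\\")
  b <- charToRaw(enc2utf8(s))
  if (length(b) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    b <- c(b, pad)
  }
  b
}

.encElement <- function(tag, vr, value) {
  group <- strtoi(substr(tag, 1, 4), 16L)
  elem <- strtoi(substr(tag, 6, 9), 16L)
  if (vr %in% c("OB", "OW")) {
    payload <- value  # already raw
    head <- c(.encU16(group), .encU16(elem), charToRaw(vr), as.raw(c(0, 0)),
              .encU32(length(payload)))
  } else if (vr == "US") {
    payload <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
    head <- c(.encU16(group), .encU16(elem), charToRaw(vr),
              .encU16(length(payload)))
  } else if (vr == "UL") {
    payload <- .encU32(value)
    head <- c(.encU16(group), .encU16(elem), charToRaw(vr),
              .encU16(length(payload)))
  } else {
    payload <- .encStringValue(value, vr)
    head <- c(.encU16(group), .encU16(elem), charToRaw(vr),
              .encU16(length(payload)))
  }
  c(head, payload)
}

#' Write one DICOM file
#'
#' Serialises a header field list (same field names as [readDicomHeader()]
#' returns) plus an optional pixel matrix to a DICOM Part-10 file using the
#' explicit VR little endian transfer syntax.
#'
#' @param fields named list of header fields.
#' @param path output path.
#' @param pixel optional integer matrix of shape (rows, columns); values must
#'   fit in unsigned 16 bit.
#' @return `path`, invisibly.
#' @keywords internal
#' @export
writeDicomFile <- function(fields, path, pixel = NULL) {
  if (!is.null(pixel)) {
    fields$samples_per_pixel <- 1L
    fields$photometric_interpretation <- fields$photometric_interpretation %||% "MONOCHROME2"
    fields$rows <- nrow(pixel)
    fields$columns <- ncol(pixel)
    fields$bits_allocated <- 16L
    fields$bits_stored <- 16L
    fields$high_bit <- 15L
    fields$pixel_representation <- fields$pixel_representation %||% 0L
  }
  fields$sop_class_uid <- fields$sop_class_uid %||% MR_IMAGE_STORAGE
  if (is.null(fields$sop_instance_uid)) {
    inputError("sop_instance_uid is required to write a DICOM file")
  }

  known <- .dicomDict$field[.dicomDict$field %in% names(fields)]
  known <- setdiff(known, "pixel_data")
  tags <- .tagOf(known)
  ord <- order(tags, method = "radix")
  body <- raw()
  for (i in ord) {
    body <- c(body, .encElement(tags[i], .vrOf(known[i]), fields[[known[i]]]))
  }
  if (!is.null(pixel)) {
    payload <- writeBin(as.integer(t(pixel)), raw(), size = 2, endian = "little")
    body <- c(body, .encElement("7FE0,0010", "OW", payload))
  }

  meta <- c(
    .encElement("0002,0001", "OB", as.raw(c(0, 1))),
    .encElement("0002,0002", "UI", fields$sop_class_uid),
    .encElement("0002,0003", "UI", fields$sop_instance_uid),
    .encElement("0002,0010", "UI", SUPPORTED_TRANSFER_SYNTAX),
    .encElement("0002,0012", "UI", paste0(FIXTURE_UID_ROOT, ".0.1"))
  )
  meta <- c(.encElement("0002,0000", "UL", length(meta)), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}
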
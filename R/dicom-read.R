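# Reading DICOM Part-10 files (explicit VR little endian only) and
# enumerating candidate input files from directories, file lists and
# zip archives.

.u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
          endian = "little", signed = FALSE)
}
.u32 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
}

.longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one element at byte offset `off` (0-based). Returns list(group, elem,
# vr, len, voff, next_off) or NULL at end of buffer.
.parseElement <- function(raw, off) {
  n <- length(raw)
  if (off + 8 > n) return(NULL)
  group <- .u16(raw, off)
  elem <- .u16(raw, off + 2)
  vr <- rawToChar(raw[(off + 5):(off + 6)])
  if (vr %in% .longVRs) {
    if (off + 12 > n) return(NULL)
    len <- .u32(raw, off + 8)
    voff <- off + 12
  } else {
    len <- .u16(raw, off + 6)
    voff <- off + 8
  }
  list(group = group, elem = elem, vr = vr, len = len,
       voff = voff, next_off = voff + max(len, 0))
}

.decodeString <- function(raw, voff, len) {
  if (len == 0) return("")
  b <- raw[(voff + 1):(voff + len)]
  while (length(b) && b[length(b)] %in% as.raw(c(0L, 32L))) {
    b <- b[-length(b)]
  }
  if (!length(b)) return("")
  s <- rawToChar(b)
  Encoding(s) <- "UTF-8"
  s
}

.decodeValue <- function(raw, el, field, vr) {
  if (vr == "US") {
    k <- el$len %/% 2
    v <- vapply(seq_len(k), function(i) .u16(raw, el$voff + 2 * (i - 1)), 0)
    return(if (k == 1) as.integer(v) else as.integer(v))
  }
  s <- .decodeString(raw, el$voff, el$len)
  if (field %in% .multiValueFields || grepl("\\\\", s)) {
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
  } else {
    parts <- s
  }
  parts <- trimws(parts)
  if (field %in% .numericFields) return(as.numeric(parts))
  if (field %in% .integerFields) return(as.integer(parts))
  parts
}

#' Read the header of one DICOM file
#'
#' Parses the data elements the conversion pipeline consumes from a DICOM
#' Part-10 file (explicit VR little endian). Pixel data are never loaded here;
#' only their byte offset and length are recorded so that volume assembly can
#' fetch them lazily via [readPixelData()]. Files without the `DICM` magic
#' marker, with an unsupported transfer syntax, or without a
#' SeriesInstanceUID are returned as [rejection()] values, not errors.
#'
#' @param path path to the file.
#' @param allowNoMagic accept files lacking the 128-byte preamble and `DICM`
#'   marker, attempting to parse them as a bare explicit-VR-little-endian
#'   dataset. Off by default: predictable behaviour over permissiveness.
#' @return an object of class `"dicomHeader"` (a named list using the field
#'   names of the consumed attribute subset), or a [rejection()].
#' @export
readDicomHeader <- function(path, allowNoMagic = FALSE) {
  if (!file.exists(path)) inputError(sprintf("no such file: %s", path))
  sz <- file.size(path)
  raw <- readBin(path, "raw", n = sz)
  hasMagic <- length(raw) >= 132 &&
    identical(rawToChar(raw[129:132]), "DICM")
  if (!hasMagic && !allowNoMagic) {
    return(rejection("not-dicom", sprintf("no DICM magic marker: %s", path),
                     file_path = path))
  }
  off <- if (hasMagic) 132 else 0

  # File meta information group (0002) is always explicit VR little endian.
  ts <- SUPPORTED_TRANSFER_SYNTAX
  if (hasMagic) {
    repeat {
      el <- .parseElement(raw, off)
      if (is.null(el) || el$group != 2L) break
      if (el$elem == 0x0010) ts <- .decodeString(raw, el$voff, el$len)
      off <- el$next_off
    }
  }
  if (!identical(ts, SUPPORTED_TRANSFER_SYNTAX)) {
    return(rejection("transfer-syntax",
                     sprintf("unsupported transfer syntax %s: %s", ts, path),
                     file_path = path))
  }

  h <- list(file_path = path)
  ok <- TRUE
  while (TRUE) {
    el <- .parseElement(raw, off)
    if (is.null(el)) break
    if (el$len < 0) { ok <- FALSE; break }  # undefined length: unsupported
    tag <- sprintf("%04X,%04X", el$group, el$elem)
    i <- match(tag, .dicomDict$tag)
    if (!is.na(i)) {
      field <- .dicomDict$field[i]
      if (field == "pixel_data") {
        h$pixel_offset <- el$voff
        h$pixel_length <- el$len
        break
      }
      h[[field]] <- .decodeValue(raw, el, field, el$vr)
    } else if (el$vr == "SQ") {
      ok <- FALSE; break  # sequences are not emitted nor consumed
    }
    off <- el$next_off
  }
  if (!ok) {
    return(rejection("unparseable",
                     sprintf("unsupported element structure: %s", path),
                     file_path = path))
  }
  uid <- h$series_instance_uid
  if (is.null(uid) || !nzchar(uid)) {
    return(rejection("no-series-uid",
                     sprintf("missing SeriesInstanceUID: %s", path),
                     file_path = path))
  }
  class(h) <- "dicomHeader"
  h
}

#' @export
print.dicomHeader <- function(x, ...) {
  cat(sprintf("<dicomHeader> %s\n  series %s #%s  instance %s  \"%s\"\n",
              x$file_path,
              x$series_instance_uid,
              x$series_number %||% "?",
              x$instance_number %||% "?",
              x$series_description %||% ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the pixel array of a DICOM file lazily
#'
#' @param header a `dicomHeader` from [readDicomHeader()].
#' @return integer matrix of shape (rows, columns).
#' @export
readPixelData <- function(header) {
  stopifnot(inherits(header, "dicomHeader"))
  if (is.null(header$pixel_offset)) {
    assemblyError(sprintf("no pixel data in %s", header$file_path))
  }
  bits <- header$bits_allocated %||% 16L
  if (bits != 16L) assemblyError("only 16-bit pixel data is supported")
  con <- file(header$file_path, "rb")
  on.exit(close(con))
  seek(con, header$pixel_offset)
  npx <- header$pixel_length %/% 2L
  signed <- isTRUE(header$pixel_representation == 1L)
  v <- readBin(con, "integer", n = npx, size = 2, endian = "little",
               signed = signed)
  nr <- header$rows
  nc <- header$columns
  if (npx != nr * nc) {
    assemblyError(sprintf("pixel payload (%d px) does not match %dx%d in %s",
                          npx, nr, nc, header$file_path))
  }
  matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Enumerate candidate DICOM files
#'
#' Expands a mixture of directories, individual files and zip archives into a
#' deterministic, lexicographically sorted flat list of file paths. Zip
#' members are extracted into `workdir` and the extracted paths returned.
#' Non-DICOM files are retained at this stage; they are filtered when headers
#' are read. Nested zips are not expanded.
#'
#' @param inputs character vector of paths.
#' @param workdir directory receiving zip extractions.
#' @return sorted character vector of file paths.
#' @export
discoverFiles <- function(inputs, workdir = tempfile("dicom-workspace-")) {
  out <- character()
  for (p in inputs) {
    if (!file.exists(p)) inputError(sprintf("input does not exist: %s", p))
    if (dir.exists(p)) {
      out <- c(out, list.files(p, recursive = TRUE, full.names = TRUE))
    } else if (grepl("\\.zip$", p, ignore.case = TRUE)) {
      dest <- file.path(workdir, sub("\\.zip$", "", basename(p), ignore.case = TRUE))
      members <- tryCatch(
        utils::unzip(p, list = TRUE),
        error = function(e) archiveError(sprintf("corrupt zip archive: %s", p)),
        warning = function(w) archiveError(sprintf("corrupt zip archive: %s", p))
      )
      if (!is.data.frame(members) || nrow(members) == 0) {
        archiveError(sprintf("corrupt or empty zip archive: %s", p))
      }
      dir.create(dest, recursive = TRUE, showWarnings = FALSE)
      got <- utils::unzip(p, exdir = dest)
      out <- c(out, got[!dir.exists(got)])
    } else {
      out <- c(out, p)
    }
  }
  sort(unique(out), method = "radix")
}
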
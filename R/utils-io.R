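# Byte-stable, idempotent file writing plus small binary utilities
# (CRC-32 and a store-only zip writer used by the fixture generator).

# Place `src` (a fully written temp file) at `dest`. If an identical file is
# already there, this is a silent no-op; a differing file is a collision
# unless overwrite is allowed. Returns "written" or "unchanged".
.placeFile <- function(src, dest, overwrite = FALSE) {
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  if (file.exists(dest)) {
    same <- file.size(dest) == file.size(src) &&
      identical(readBin(dest, "raw", file.size(dest)),
                readBin(src, "raw", file.size(src)))
    if (same) {
      unlink(src)
      return("unchanged")
    }
    if (!overwrite) {
      unlink(src)
      collisionError(sprintf("output exists with different content: %s", dest))
    }
    unlink(dest)
  }
  if (!file.copy(src, dest)) inputError(sprintf("cannot write %s", dest))
  unlink(src)
  "written"
}

.writeTextIdempotent <- function(text, dest, overwrite = FALSE) {
  tmp <- tempfile()
  con <- file(tmp, "wb")
  writeBin(charToRaw(enc2utf8(text)), con)
  close(con)
  .placeFile(tmp, dest, overwrite)
}

# TSV dialect pinned for byte-stable idempotency: tab-separated, "n/a" for
# missing, no quoting, trailing newline.
.tsvText <- function(df) {
  cells <- vapply(seq_len(ncol(df)), function(j) {
    v <- df[[j]]
    if (is.list(v)) v <- vapply(v, function(x) paste(x, collapse = ";"), "")
    v <- as.character(v)
    v[is.na(v) | !nzchar(v)] <- "n/a"
    v
  }, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cells, 1, paste, collapse = "\t"))
  paste0(paste(lines, collapse = "\n"), "\n")
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", na.strings = "n/a",
                    colClasses = "character", check.names = FALSE)
}

# ---- CRC-32 (polynomial 0xEDB88320), needed by the zip writer ----

.crcTable <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(c, 1L))
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1] <- c
  }
  tab
})

.crc32 <- function(bytes) {
  c <- -1L
  b <- as.integer(bytes)
  for (x in b) {
    c <- bitwXor(.crcTable[bitwAnd(bitwXor(c, x), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

.le16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.le32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Create a zip archive of a directory
#'
#' A minimal, dependency-free zip writer (method 0, stored) used to exercise
#' the archive-ingestion path without requiring a system `zip` binary.
#' Member order and timestamps are fixed, so archives are byte-stable.
#'
#' @param dir directory whose files become archive members (relative names).
#' @param zipfile output path.
#' @return `zipfile`, invisibly.
#' @export
zipDirectory <- function(dir, zipfile) {
  files <- sort(list.files(dir, recursive = TRUE), method = "radix")
  con <- file(zipfile, "wb")
  on.exit(close(con))
  central <- raw()
  offset <- 0L
  for (rel in files) {
    data <- readBin(file.path(dir, rel), "raw", file.size(file.path(dir, rel)))
    crc <- .crc32(data)
    name <- charToRaw(rel)
    local <- c(charToRaw("PK"), as.raw(c(3, 4)), .le16(20), .le16(0), .le16(0),
               .le16(0), .le16(0x21), .le32(crc), .le32(length(data)),
               .le32(length(data)), .le16(length(name)), .le16(0), name)
    writeBin(local, con)
    writeBin(data, con)
    central <- c(central, charToRaw("PK"), as.raw(c(1, 2)), .le16(20), .le16(20),
                 .le16(0), .le16(0), .le16(0), .le16(0x21), .le32(crc),
                 .le32(length(data)), .le32(length(data)), .le16(length(name)),
                 .le16(0), .le16(0), .le16(0), .le16(0), .le32(0),
                 .le32(offset), name)
    offset <- offset + length(local) + length(data)
  }
  writeBin(central, con)
  writeBin(c(charToRaw("PK"), as.raw(c(5, 6)), .le16(0), .le16(0),
             .le16(length(files)), .le16(length(files)),
             .le32(length(central)), .le32(offset), .le16(0)), con)
  invisible(zipfile)
}

# Deterministic keyed string hash (two independent polynomial hashes mod
# 2^32, combined); used for anonymization digests and date-shift seeding.
.strHash <- function(s, seed = 0) {
  b <- as.integer(charToRaw(paste0(seed, ":", s)))
  h1 <- 2166136261 %% 4294967296
  h2 <- 31
  for (x in b) {
    h1 <- (h1 * 31 + x) %% 4294967296
    h2 <- (h2 * 131 + x) %% 4294967296
  }
  (h1 * 3 + h2) %% 4294967296
}
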
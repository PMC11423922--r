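# Optional obfuscation of identifying metadata: subject-id mapping through
# an operator table or a deterministic keyed digest, interval-preserving
# visit-timestamp shifting, and sidecar field scrubbing.

.defaultStripFields <- c("PatientName", "PatientID", "AccessionNumber",
                         "OperatorsName", "ReferringPhysicianName",
                         "InstitutionAddress")

#' Construct an anonymization policy
#'
#' @param idMap named character vector: raw subject id -> released id.
#'   Ids not in the map get a deterministic keyed digest.
#' @param seed integer key for digest generation and date-shift derivation.
#' @param stripFields sidecar fields removed by [scrubSidecar()].
#' @return an `"anonPolicy"` object. The id map grows as ids are generated;
#'   it is stored in an environment so the policy can be passed around by
#'   value while accumulating assignments.
#' @export
anonPolicy <- function(idMap = character(), seed = 0L,
                       stripFields = .defaultStripFields) {
  if (length(idMap) && anyDuplicated(idMap)) {
    validationError("id map is not injective: two raw ids share a released id")
  }
  state <- new.env(parent = emptyenv())
  state$map <- idMap
  structure(list(state = state, seed = as.integer(seed),
                 stripFields = stripFields),
            class = "anonPolicy")
}

#' Map a raw subject id to a released id
#'
#' Returns the mapped id if present in the policy's table; otherwise a
#' deterministic keyed digest truncated to 8 hex characters, which is
#' recorded into the map so repeated calls are stable. A digest collision
#' with a different raw id raises a collision error (re-key with another
#' seed).
#'
#' @param rawId nonempty raw subject identifier.
#' @param policy an `"anonPolicy"`.
#' @return released id string.
#' @export
anonymizeId <- function(rawId, policy) {
  stopifnot(inherits(policy, "anonPolicy"))
  if (is.null(rawId) || !nzchar(rawId)) inputError("raw subject id is empty")
  map <- policy$state$map
  if (rawId %in% names(map)) return(unname(map[[rawId]]))
  v <- .strHash(rawId, policy$seed)
  released <- sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
  if (released %in% map) {
    collisionError(sprintf(
      "generated id '%s' collides with the one for '%s'; re-key with a different seed",
      released, names(map)[map == released][1]))
  }
  map[[rawId]] <- released
  policy$state$map <- map
  released
}

# Study-constant day offset: magnitude uniform over [365, 730] days with a
# random sign, both derived deterministically from (seed, study uid).
.shiftDaysFor <- function(policy, studyUid) {
  h <- .strHash(studyUid, policy$seed)
  mag <- 365 + (h %% 366)
  sign <- if ((h %/% 366) %% 2 == 0) 1 else -1
  sign * mag
}

#' Shift the timestamps of one study by a constant offset
#'
#' Every timestamp of a study moves by the same study-constant whole-day
#' offset, so pairwise differences and time-of-day are preserved exactly and
#' longitudinal designs remain analyzable. The offset is derived from the
#' policy seed and the StudyInstanceUID, so repeated runs shift identically.
#'
#' @param timestamps POSIXct vector, or character in DICOM DT
#'   (`YYYYMMDDHHMMSS[.ffffff]`) or DA (`YYYYMMDD`) form.
#' @param policy an `"anonPolicy"`.
#' @param studyUid the StudyInstanceUID the timestamps belong to.
#' @return shifted timestamps, same class/format as the input.
#' @export
shiftTimestamps <- function(timestamps, policy, studyUid) {
  days <- .shiftDaysFor(policy, studyUid)
  if (inherits(timestamps, "POSIXct")) return(timestamps + days * 86400)
  vapply(timestamps, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    digits <- gsub("[^0-9]", "", s)
    frac <- if (grepl("\\.", s)) sub("^[^.]*", "", s) else ""
    dateOnly <- nchar(digits) <= 8
    stamp <- if (dateOnly) paste0(substr(digits, 1, 8), "000000") else
      substr(paste0(digits, "000000"), 1, 14)
    t <- as.POSIXct(stamp, format = "%Y%m%d%H%M%S", tz = "UTC")
    t <- t + days * 86400
    out <- format(t, if (dateOnly) "%Y%m%d" else "%Y%m%d%H%M%S", tz = "UTC")
    paste0(out, frac)
  }, "", USE.NAMES = FALSE)
}

#' Remove identifying fields from sidecar metadata
#'
#' @param metadata named list of sidecar fields.
#' @param policy an `"anonPolicy"`; its `stripFields` are dropped, all other
#'   fields pass through unchanged.
#' @return the scrubbed metadata list.
#' @export
scrubSidecar <- function(metadata, policy) {
  metadata[!(names(metadata) %in% policy$stripFields)]
}

#' Persist the id map as a side-channel file
#'
#' The raw-to-released table is written OUTSIDE the output tree; writing it
#' under `outputRoot` is refused, since that would ship the key with the
#' anonymized data.
#'
#' @param policy an `"anonPolicy"`.
#' @param path destination TSV (columns raw_id, released_id).
#' @param outputRoot the anonymized output root to guard against.
#' @return `path`, invisibly.
#' @export
writeAnonMap <- function(policy, path, outputRoot = NULL) {
  if (!is.null(outputRoot) && dir.exists(outputRoot)) {
    rootNorm <- normalizePath(outputRoot)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    pNorm <- normalizePath(dirname(path), mustWork = FALSE)
    if (startsWith(paste0(pNorm, "/"), paste0(rootNorm, "/"))) {
      inputError("refusing to write the id map inside the anonymized output tree")
    }
  }
  map <- policy$state$map
  df <- data.frame(raw_id = names(map), released_id = unname(map),
                   stringsAsFactors = FALSE)
  df <- df[order(df$raw_id, method = "radix"), , drop = FALSE]
  .writeTextIdempotent(.tsvText(df), path, overwrite = TRUE)
  invisible(path)
}
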
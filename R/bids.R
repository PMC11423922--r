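# Rendering conversion-plan templates into BIDS paths, populating the
# standard dataset-level files, and checking produced names against the
# BIDS entity grammar.

BIDS_VERSION <- "1.8.0"

.bidsPathOrder <- function() c("sub", "ses", BIDS_ENTITY_ORDER)

.suffixDatatype <- list(
  anat = c("T1w", "T2w", "PDw", "FLAIR", "T2starw", "angio", "inplaneT1"),
  func = c("bold", "sbref", "cbv", "phase"),
  dwi = c("dwi", "sbref"),
  fmap = c("epi", "magnitude", "magnitude1", "magnitude2", "phasediff",
           "phase1", "phase2", "fieldmap")
)

#' Render an output template into a relative path
#'
#' Substitutes `{subject}`, `{session}`, `{item}` (and the zero-padded
#' `{item:0Nd}` form) and appends the extension. Unresolved placeholders and
#' paths escaping the tree raise a template error.
#'
#' @param template template string.
#' @param subject subject label.
#' @param session session label or NULL.
#' @param item item index.
#' @param extension e.g. `".nii.gz"`, `".json"`, or `""`.
#' @return the rendered relative path.
#' @export
renderPath <- function(template, subject, session = NULL, item = 1L,
                       extension = ".nii.gz") {
  s <- template
  s <- gsub("{subject}", subject, s, fixed = TRUE)
  if (grepl("{session}", s, fixed = TRUE)) {
    if (is.null(session) || !nzchar(session)) {
      templateError(sprintf("template '%s' needs a session but none is available", template))
    }
    s <- gsub("{session}", session, s, fixed = TRUE)
  }
  repeat {
    m <- regmatches(s, regexec("\\{item:0([0-9]+)d\\}", s))[[1]]
    if (length(m) == 0) break
    s <- sub("\\{item:0[0-9]+d\\}",
             sprintf(paste0("%0", m[2], "d"), as.integer(item)), s)
  }
  s <- gsub("{item}", as.character(item), s, fixed = TRUE)
  if (grepl("[{}]", s)) {
    templateError(sprintf("unresolved placeholder after substitution: '%s'", s))
  }
  if (startsWith(s, "/") || grepl("(^|/)\\.\\.(/|$)", s)) {
    templateError(sprintf("template renders outside the output tree: '%s'", s))
  }
  paste0(s, extension)
}

# Insert an entity (e.g. echo-2) into the filename part of a rendered path,
# respecting the canonical entity order.
.insertEntity <- function(path, key, value) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  base <- segs[length(segs)]
  toks <- strsplit(base, "_", fixed = TRUE)[[1]]
  suffix <- toks[length(toks)]
  kv <- toks[-length(toks)]
  keys <- sub("-.*", "", kv)
  rank <- match(keys, .bidsPathOrder())
  myRank <- match(key, .bidsPathOrder())
  at <- which(rank > myRank)
  newTok <- paste0(key, "-", value)
  kv <- if (length(at)) append(kv, newTok, after = min(at) - 1) else c(kv, newTok)
  segs[length(segs)] <- paste(c(kv, suffix), collapse = "_")
  paste(segs, collapse = "/")
}

.isoFromDicomDT <- function(dt) {
  if (is.null(dt) || is.na(dt) || !nzchar(dt)) return(NA_character_)
  d <- gsub("[^0-9]", "", substr(dt, 1, 14))
  if (nchar(d) < 14) d <- paste0(d, strrep("0", 14 - nchar(d)))
  sprintf("%s-%s-%sT%s:%s:%s",
          substr(d, 1, 4), substr(d, 5, 6), substr(d, 7, 8),
          substr(d, 9, 10), substr(d, 11, 12), substr(d, 13, 14))
}

.mergeTable <- function(path, new, keyCol) {
  if (file.exists(path)) {
    old <- .readTsv(path)
    both <- rbind(old, new)
    dup <- duplicated(both[[keyCol]])
    uniq <- both[!dup, , drop = FALSE]
    # a key present twice with differing other columns is a conflict
    chk <- both[both[[keyCol]] %in% uniq[[keyCol]], , drop = FALSE]
    for (k in unique(chk[[keyCol]])) {
      rows <- chk[chk[[keyCol]] == k, , drop = FALSE]
      if (nrow(unique(rows)) > 1) {
        mergeConflictError(sprintf("conflicting rows for %s '%s' in %s",
                                   keyCol, k, basename(path)))
      }
    }
    new <- uniq
  }
  new[order(new[[keyCol]], method = "radix"), , drop = FALSE]
}

#' Populate the standard BIDS dataset files
#'
#' Writes `dataset_description.json`, `participants.tsv`, per-session
#' `*_scans.tsv` tables and a README stub at the dataset root. All writes
#' are idempotent (a re-run produces byte-identical files); new subjects or
#' scans are merged into existing tables, and a key present with conflicting
#' content raises a merge-conflict error.
#'
#' @param root dataset root directory.
#' @param converted data frame with columns subject, session (NA allowed),
#'   filename (path relative to `root`), acq_time (ISO 8601 or NA).
#' @param datasetName value for the Name field.
#' @param bidsVersion pinned BIDSVersion string.
#' @param overwrite replace differing dataset_description/README.
#' @return character vector of written/verified paths.
#' @export
populateDatasetFiles <- function(root, converted, datasetName,
                                 bidsVersion = BIDS_VERSION, overwrite = FALSE) {
  if (!nrow(converted)) inputError("nothing was converted; no dataset files to populate")
  written <- character()

  dd <- list(Name = datasetName, BIDSVersion = bidsVersion, DatasetType = "raw")
  p <- file.path(root, "dataset_description.json")
  .writeTextIdempotent(.sidecarText(dd), p, overwrite)
  written <- c(written, p)

  part <- data.frame(participant_id = paste0("sub-", unique(converted$subject)),
                     stringsAsFactors = FALSE)
  p <- file.path(root, "participants.tsv")
  part <- .mergeTable(p, part, "participant_id")
  .writeTextIdempotent(.tsvText(part), p, overwrite = TRUE)
  written <- c(written, p)

  sesKey <- ifelse(is.na(converted$session), "", converted$session)
  for (grp in unique(paste(converted$subject, sesKey, sep = "\r"))) {
    parts <- strsplit(grp, "\r", fixed = TRUE)[[1]]
    subj <- parts[1]
    ses <- if (length(parts) > 1 && nzchar(parts[2])) parts[2] else NULL
    rows <- converted[converted$subject == subj &
                        (if (is.null(ses)) !nzchar(sesKey) else sesKey == ses), ,
                      drop = FALSE]
    sesDir <- if (is.null(ses)) {
      file.path(root, paste0("sub-", subj))
    } else {
      file.path(root, paste0("sub-", subj), paste0("ses-", ses))
    }
    prefix <- sub(paste0("^", root, "/?"), "", sesDir)
    fn <- sub(paste0("^", prefix, "/"), "", rows$filename)
    scans <- data.frame(filename = fn,
                        acq_time = ifelse(is.na(rows$acq_time), "n/a", rows$acq_time),
                        stringsAsFactors = FALSE)
    p <- file.path(sesDir, paste0("sub-", subj,
                                  if (!is.null(ses)) paste0("_ses-", ses) else "",
                                  "_scans.tsv"))
    scans <- .mergeTable(p, scans, "filename")
    .writeTextIdempotent(.tsvText(scans), p, overwrite = TRUE)
    written <- c(written, p)
  }

  p <- file.path(root, "README")
  .writeTextIdempotent(
    sprintf("# %s\n\nConverted from DICOM with dicombids.\n", datasetName),
    p, overwrite)
  written <- c(written, p)
  written
}

.violation <- function(path, rule, message) {
  data.frame(path = path, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate filenames in a BIDS tree
#'
#' Checks every data file under `sub-*/` against the entity-order grammar,
#' the datatype/suffix compatibility table, and required-entity rules (a
#' `bold` file needs a `task` entity). Violations are returned as values; an
#' empty data frame means the tree is compliant.
#'
#' @param root dataset root.
#' @return data frame with columns path, rule, message (zero rows if clean).
#' @export
validateNames <- function(root) {
  files <- list.files(root, recursive = TRUE)
  files <- files[grepl("^sub-[^/]+/", files)]
  files <- files[grepl("\\.(nii\\.gz|nii|json)$", files)]
  files <- files[!grepl("_scans\\.tsv$", files)]
  out <- list()
  bad <- function(...) out[[length(out) + 1]] <<- .violation(...)

  for (f in files) {
    segs <- strsplit(f, "/", fixed = TRUE)[[1]]
    if (length(segs) < 3) {
      bad(f, "hierarchy", "data file not under sub-<label>[/ses-<label>]/<datatype>/")
      next
    }
    subDir <- segs[1]
    sesDir <- if (length(segs) >= 4) segs[2] else NULL
    datatype <- segs[length(segs) - 1]
    if (!is.null(sesDir) && !grepl("^ses-[A-Za-z0-9]+$", sesDir)) {
      bad(f, "hierarchy", sprintf("unexpected directory '%s'", sesDir))
      next
    }
    if (!(datatype %in% names(.suffixDatatype))) {
      bad(f, "datatype", sprintf("unknown datatype directory '%s'", datatype))
      next
    }
    base <- sub("\\.(nii\\.gz|nii|json)$", "", segs[length(segs)])
    toks <- strsplit(base, "_", fixed = TRUE)[[1]]
    suffix <- toks[length(toks)]
    kv <- toks[-length(toks)]
    if (!length(kv) || any(!grepl("^[A-Za-z0-9]+-[A-Za-z0-9]+$", kv))) {
      bad(f, "entity-format", "entities must be alphanumeric key-value pairs")
      next
    }
    keys <- sub("-.*", "", kv)
    vals <- sub("^[^-]*-", "", kv)
    rank <- match(keys, .bidsPathOrder())
    if (anyNA(rank)) {
      bad(f, "unknown-entity", sprintf("unknown entity key(s): %s",
                                       paste(keys[is.na(rank)], collapse = ", ")))
      next
    }
    if (keys[1] != "sub") {
      bad(f, "entity-order", "filename must start with the sub entity")
    } else if (paste0("sub-", vals[1]) != subDir) {
      bad(f, "subject-mismatch",
          sprintf("file subject 'sub-%s' differs from directory '%s'", vals[1], subDir))
    }
    if (any(diff(rank) <= 0)) {
      bad(f, "entity-order",
          sprintf("entities out of canonical order (%s)",
                  paste(.bidsPathOrder(), collapse = ", ")))
    }
    if ("ses" %in% keys) {
      if (is.null(sesDir) || paste0("ses-", vals[keys == "ses"]) != sesDir) {
        bad(f, "session-mismatch", "ses entity does not match the session directory")
      }
    } else if (!is.null(sesDir)) {
      bad(f, "session-mismatch", "file in a session directory lacks a ses entity")
    }
    if (!(suffix %in% .suffixDatatype[[datatype]])) {
      bad(f, "datatype-suffix",
          sprintf("suffix '%s' is not valid under %s/", suffix, datatype))
    }
    if (suffix == "bold" && !("task" %in% keys)) {
      bad(f, "missing-task", "bold files require a task entity")
    }
  }
  if (!length(out)) {
    return(data.frame(path = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
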
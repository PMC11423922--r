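# The ReproIn naming convention: scanner operators name protocols as
#   <datatype>[-<suffix>][_<key>-<value>]...
# (e.g. "func-bold_task-rest_run-01"), which this module parses into BIDS
# datatype/suffix/entities so that conversion needs no manual renaming.
# A trailing "_SBRef" marks a single-band reference volume; "__dup<NN>"
# marks a mistyped/repeated acquisition superseded by a later one.

#' Canonical order of BIDS filename entities
#'
#' Entity keys render in this fixed order in every output filename.
#' @export
BIDS_ENTITY_ORDER <- c("task", "acq", "ce", "rec", "dir", "run", "echo", "part")
.reproinDatatypes <- c("anat", "func", "dwi", "fmap")

#' Strip a string down to a BIDS-legal label
#'
#' Removes every character outside `[A-Za-z0-9]`. The result may be empty;
#' callers decide whether that is an error.
#'
#' @param raw input string.
#' @return sanitized string.
#' @export
sanitizeLabel <- function(raw) {
  if (is.null(raw) || is.na(raw)) return("")
  gsub("[^A-Za-z0-9]", "", raw)
}

#' Parse a ReproIn series specification
#'
#' Applies the naming grammar to a series description (or protocol name).
#' A missing suffix is accepted only for `func`, whose default suffix is
#' `bold`; other datatypes without a suffix are rejected. A trailing
#' `_SBRef` rewrites the suffix to `sbref`. Unknown entity keys are kept in
#' `$extra` with a warning. Strings that do not match the grammar are
#' returned as [rejection()] values (the series is skipped, not fatal).
#'
#' @param spec the series description string.
#' @return a `"bidsEntities"` object (fields `datatype`, `suffix`,
#'   `entities` — a named character vector in canonical order —, `extra`,
#'   `session`, `dup`) or a [rejection()].
#' @export
parseSeriesSpec <- function(spec) {
  s <- trimws(spec %||% "")
  if (!nzchar(s)) return(rejection("empty-spec", "empty series specification"))
  dup <- grepl("__dup[0-9]+", s)
  s <- gsub("__dup[0-9]+", "", s)
  sbref <- grepl("_SBRef$", s)
  s <- sub("_SBRef$", "", s)

  toks <- strsplit(s, "_", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(rejection("empty-spec", "no tokens in specification"))
  m <- regmatches(toks[1], regexec("^([a-z]+)(?:-([A-Za-z0-9]+))?$", toks[1]))[[1]]
  if (length(m) == 0 || !(m[2] %in% .reproinDatatypes)) {
    return(rejection("no-datatype",
                     sprintf("'%s' does not start with a known datatype", spec)))
  }
  datatype <- m[2]
  suffix <- m[3]
  if (!nzchar(suffix)) {
    if (datatype == "func") suffix <- "bold"
    else return(rejection("missing-suffix",
                          sprintf("'%s' has no suffix and datatype '%s' has no default",
                                  spec, datatype)))
  }

  entities <- character()
  extra <- character()
  session <- NULL
  for (t in toks[-1]) {
    km <- regmatches(t, regexec("^([A-Za-z0-9]+)-(.+)$", t))[[1]]
    if (length(km) == 0) {
      return(rejection("bad-token", sprintf("token '%s' in '%s' is not key-value", t, spec)))
    }
    key <- km[2]
    val <- sanitizeLabel(km[3])
    if (!nzchar(val)) {
      return(rejection("empty-value", sprintf("empty value for key '%s' in '%s'", key, spec)))
    }
    if (key == "ses") {
      session <- val
    } else if (key %in% BIDS_ENTITY_ORDER) {
      if (key %in% names(entities)) {
        return(rejection("duplicate-key", sprintf("key '%s' repeated in '%s'", key, spec)))
      }
      entities[[key]] <- val
    } else {
      extra[[key]] <- km[3]
      .warnClass("unknownEntityWarning",
                 sprintf("unknown entity key '%s' in '%s' preserved in extras", key, spec))
    }
  }
  if (sbref) suffix <- "sbref"
  if (datatype == "func" && suffix == "bold" && !("task" %in% names(entities))) {
    return(rejection("missing-task", sprintf("'%s' is a bold series without a task entity", spec)))
  }
  entities <- entities[intersect(BIDS_ENTITY_ORDER, names(entities))]
  structure(
    list(datatype = datatype, suffix = suffix, entities = entities,
         extra = extra, session = session, dup = dup),
    class = "bidsEntities"
  )
}

#' Render a bidsEntities value back to grammar form
#'
#' Inverse of [parseSeriesSpec()] for accepted values:
#' `parseSeriesSpec(renderSeriesSpec(e))` reproduces `e`.
#'
#' @param e a `"bidsEntities"` object.
#' @return the grammar string.
#' @export
renderSeriesSpec <- function(e) {
  stopifnot(inherits(e, "bidsEntities"))
  parts <- paste0(e$datatype, "-", e$suffix)
  if (!is.null(e$session)) parts <- c(parts, paste0("ses-", e$session))
  ord <- intersect(BIDS_ENTITY_ORDER, names(e$entities))
  if (length(ord)) parts <- c(parts, paste0(ord, "-", e$entities[ord]))
  paste(parts, collapse = "_")
}

# Render the filename stem (with placeholders) for one parsed series.
.entityFileStem <- function(e, withSession) {
  stem <- "sub-{subject}"
  if (withSession) stem <- paste0(stem, "_ses-{session}")
  ord <- intersect(BIDS_ENTITY_ORDER, names(e$entities))
  if (length(ord)) stem <- paste0(stem, "_", paste0(ord, "-", e$entities[ord], collapse = "_"))
  paste0(stem, "_", e$suffix)
}

#' Infer subject, session and locator from study metadata
#'
#' The locator is derived by splitting the study description (falling back to
#' the referring physician field) on `"^"` and joining the components with
#' the path separator, so a study described as `"Patterson^Coben"` lands
#' under `Patterson/Coben/`. The subject is the sanitized PatientID; the
#' session comes from a `ses-<label>` token in the study metadata or any
#' series specification, and is otherwise absent.
#'
#' @param seqinfo seqinfo data frame of one study.
#' @return object of class `"studyIds"`: list(subject, session, locator).
#' @export
inferStudyIds <- function(seqinfo) {
  if (!nrow(seqinfo)) idInferenceError("cannot infer ids from an empty study")
  src <- c(seqinfo$study_description[1], seqinfo$referring_physician_name[1])
  src <- src[!is.na(src) & nzchar(src)]
  locator <- NULL
  if (length(src)) {
    comps <- strsplit(src[1], "^", fixed = TRUE)[[1]]
    comps <- vapply(comps, sanitizeLabel, "")
    comps <- comps[nzchar(comps)]
    if (length(comps)) locator <- paste(comps, collapse = "/")
  }
  subject <- sanitizeLabel(seqinfo$patient_id[1])
  if (!nzchar(subject)) {
    idInferenceError("subject id is empty after sanitization; supply one explicitly (-s)")
  }
  session <- NULL
  pool <- c(seqinfo$study_description[1], seqinfo$series_description,
            seqinfo$protocol_name)
  sm <- regmatches(pool, regexpr("(?:^|_)ses-([A-Za-z0-9]+)", pool))
  sm <- sm[!is.na(sm) & nzchar(sm)]
  if (length(sm)) session <- sanitizeLabel(sub(".*ses-", "", sm[1]))
  structure(list(subject = subject, session = session, locator = locator),
            class = "studyIds")
}

#' Partition repeated acquisitions into kept and superseded
#'
#' Among series whose parsed specs are identical up to `__dup` markers, and
#' where at least one series carries a marker, only the last-acquired series
#' is kept; the earlier ones are superseded (reported, never converted).
#' Groups without any dup marker are left alone (they become `run-1`,
#' `run-2`, ... later).
#'
#' @param parsed list of `"bidsEntities"` in acquisition order.
#' @return list with integer vectors `$kept` and `$superseded` (indices).
#' @export
resolveDuplicates <- function(parsed) {
  n <- length(parsed)
  if (!n) return(list(kept = integer(), superseded = integer()))
  keys <- vapply(parsed, renderSeriesSpec, "")
  dupFlag <- vapply(parsed, function(e) isTRUE(e$dup), TRUE)
  superseded <- integer()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) > 1 && any(dupFlag[idx])) {
      superseded <- c(superseded, idx[-length(idx)])
    }
  }
  list(kept = setdiff(seq_len(n), superseded), superseded = superseded)
}

#' ReproIn naming hook: seqinfo to output templates
#'
#' Composes [parseSeriesSpec()] and [resolveDuplicates()] over a seqinfo
#' table and builds BIDS path templates
#' `sub-{subject}[/ses-{session}]/<datatype>/<filename>`. Series whose specs
#' do not parse, and derived or motion-corrected series, are skipped with a
#' reason. When two accepted series would render identical names, a `run`
#' entity (zero-padded, width `runPadding`) is appended in acquisition
#' order.
#'
#' @param seqinfo seqinfo data frame.
#' @param runPadding zero-padding width of auto-assigned run values.
#' @return list of entries `list(template, output_types, series_ids)`, with a
#'   `skipped` attribute (data frame series_id/reason) and a `session`
#'   attribute (inferred session label or NULL).
#' @export
reproinInfotodict <- function(seqinfo, runPadding = 2L) {
  skipped <- data.frame(series_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(sid, reason) {
    skipped[nrow(skipped) + 1L, ] <<- list(sid, reason)
  }
  parsed <- list()
  rowsOf <- integer()
  for (i in seq_len(nrow(seqinfo))) {
    sid <- seqinfo$series_id[i]
    if (seqinfo$is_derived[i]) { skip(sid, "derived image"); next }
    if (seqinfo$is_motion_corrected[i]) { skip(sid, "motion-corrected image"); next }
    spec <- seqinfo$series_description[i]
    if (is.na(spec) || !nzchar(spec)) spec <- seqinfo$protocol_name[i]
    p <- parseSeriesSpec(spec)
    if (isRejection(p)) { skip(sid, p$reason); next }
    parsed[[length(parsed) + 1]] <- p
    rowsOf[length(parsed)] <- i
  }

  res <- resolveDuplicates(parsed)
  for (j in res$superseded) {
    skip(seqinfo$series_id[rowsOf[j]], "superseded by a later duplicate acquisition")
  }
  kept <- res$kept
  session <- NULL
  for (j in kept) {
    if (!is.null(parsed[[j]]$session)) { session <- parsed[[j]]$session; break }
  }

  withSession <- !is.null(session)
  stems <- vapply(kept, function(j) {
    paste0(parsed[[j]]$datatype, "/", .entityFileStem(parsed[[j]], withSession))
  }, "")
  # collision -> auto run entity, acquisition order
  for (s in unique(stems)) {
    idx <- which(stems == s)
    if (length(idx) > 1 && !("run" %in% names(parsed[[kept[idx[1]]]]$entities))) {
      for (r in seq_along(idx)) {
        j <- kept[idx[r]]
        parsed[[j]]$entities[["run"]] <- sprintf(paste0("%0", runPadding, "d"), r)
        parsed[[j]]$entities <- parsed[[j]]$entities[
          intersect(BIDS_ENTITY_ORDER, names(parsed[[j]]$entities))]
        stems[idx[r]] <- paste0(parsed[[j]]$datatype, "/",
                                .entityFileStem(parsed[[j]], withSession))
      }
    }
  }

  entries <- list()
  seen <- character()
  for (q in seq_along(kept)) {
    j <- kept[q]
    sid <- seqinfo$series_id[rowsOf[j]]
    if (stems[q] %in% seen) {
      skip(sid, sprintf("would collide with an existing output name '%s'", stems[q]))
      next
    }
    seen <- c(seen, stems[q])
    dirPart <- if (withSession) "sub-{subject}/ses-{session}/" else "sub-{subject}/"
    entries[[length(entries) + 1]] <- list(
      template = paste0(dirPart, stems[q]),
      output_types = "nii.gz",
      series_ids = sid
    )
  }
  attr(entries, "skipped") <- skipped
  attr(entries, "session") <- session
  entries
}

#' @rdname reproinInfotodict
#' @export
reproinInfotoids <- function(seqinfo) inferStudyIds(seqinfo)
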
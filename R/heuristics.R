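# The heuristic plug-in contract and its application to a seqinfo table.
#
# A heuristic is a small module exposing, at minimum,
#   infotodict(seqinfo) -> list of entries (template, output_types, series_ids)
# and optionally
#   infotoids(seqinfo)  -> list(subject, session, locator)
# User heuristics are single R source files defining those functions;
# "convertall" and "reproin" ship as built-ins.

.builtinHeuristics <- function() {
  list(
    convertall = list(infotodict = convertallInfotodict, infotoids = NULL),
    reproin = list(infotodict = reproinInfotodict, infotoids = reproinInfotoids)
  )
}

#' Load a naming heuristic
#'
#' @param spec a registered built-in name (`"convertall"`, `"reproin"`) or
#'   the path of an R source file defining `infotodict` (and optionally
#'   `infotoids` and `sanitizeId`).
#' @return an object of class `"heuristic"`.
#' @export
loadHeuristic <- function(spec) {
  builtins <- .builtinHeuristics()
  if (spec %in% names(builtins)) {
    b <- builtins[[spec]]
    return(structure(list(name = spec, infotodict = b$infotodict,
                          infotoids = b$infotoids, sanitizeId = NULL),
                     class = "heuristic"))
  }
  if (!file.exists(spec)) {
    contractError(sprintf("unknown heuristic: %s (not a built-in, not a file)", spec))
  }
  env <- new.env(parent = asNamespace("dicombids"))
  sys.source(spec, envir = env, keep.source = FALSE)
  itd <- get0("infotodict", envir = env, inherits = FALSE)
  if (!is.function(itd)) {
    contractError(sprintf("heuristic %s does not define the required hook 'infotodict'", spec))
  }
  iti <- get0("infotoids", envir = env, inherits = FALSE)
  san <- get0("sanitizeId", envir = env, inherits = FALSE)
  structure(list(name = basename(spec), infotodict = itd,
                 infotoids = if (is.function(iti)) iti else NULL,
                 sanitizeId = if (is.function(san)) san else NULL),
            class = "heuristic")
}

#' @export
print.heuristic <- function(x, ...) {
  hooks <- c("infotodict", if (!is.null(x$infotoids)) "infotoids",
             if (!is.null(x$sanitizeId)) "sanitizeId")
  cat(sprintf("<heuristic> %s (hooks: %s)\n", x$name, paste(hooks, collapse = ", ")))
  invisible(x)
}

#' The convertall heuristic
#'
#' Expresses no knowledge or assumptions: every series maps to a generic
#' template `sub-{subject}/{item:02d}-<series_id>` so an operator can
#' establish an initial mapping and edit it by hand.
#'
#' @param seqinfo seqinfo data frame.
#' @return list of entries (template, output_types, series_ids).
#' @export
convertallInfotodict <- function(seqinfo) {
  lapply(seq_len(nrow(seqinfo)), function(i) {
    list(template = paste0("sub-{subject}/{item:02d}-", seqinfo$series_id[i]),
         output_types = "nii.gz",
         series_ids = seqinfo$series_id[i])
  })
}

# Accept both the canonical entry-list form and a simple named list
# (template -> character vector of series ids) from user heuristics.
.normalizeInfo <- function(info) {
  if (is.null(info)) return(list())
  if (length(info) && !is.null(names(info)) && all(nzchar(names(info))) &&
      all(vapply(info, is.character, TRUE))) {
    info <- lapply(names(info), function(tpl) {
      list(template = tpl, output_types = "nii.gz", series_ids = info[[tpl]])
    })
  }
  lapply(info, function(e) {
    if (is.null(e$template) || !nzchar(e$template)) {
      contractError("heuristic returned an entry without a template")
    }
    e$output_types <- e$output_types %||% "nii.gz"
    e
  })
}

#' Apply a heuristic to a seqinfo table
#'
#' Calls the heuristic's `infotodict`, assigns item indices per template in
#' encounter order starting at 1, and records series mapped by no template
#' as skipped (reason "no rule matched"). Deterministic given its inputs.
#'
#' @param heuristic a `"heuristic"` object from [loadHeuristic()].
#' @param seqinfo seqinfo data frame.
#' @param subject subject label (sanitized; must be nonempty afterwards).
#' @param session optional session label.
#' @param locator optional relative output directory.
#' @return object of class `"conversionPlan"`.
#' @export
applyHeuristic <- function(heuristic, seqinfo, subject, session = NULL,
                           locator = NULL) {
  stopifnot(inherits(heuristic, "heuristic"))
  san <- heuristic$sanitizeId %||% sanitizeLabel
  subject <- san(subject %||% "")
  if (!nzchar(subject)) idInferenceError("subject is empty after sanitization")
  if (!is.null(session)) session <- sanitizeLabel(session)

  info <- .normalizeInfo(heuristic$infotodict(seqinfo))
  skipped <- attr(info, "skipped")
  if (is.null(skipped)) {
    skipped <- data.frame(series_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  if (is.null(session) && !is.null(attr(info, "session"))) {
    session <- attr(info, "session")
  }

  template <- character(); item <- integer()
  seriesId <- character(); outputTypes <- character()
  counters <- integer()
  for (e in info) {
    for (sid in e$series_ids) {
      if (!(sid %in% seqinfo$series_id)) {
        planError(sprintf("heuristic referenced unknown series id '%s'", sid))
      }
      k <- (counters[e$template] %||% 0L)
      if (is.na(k)) k <- 0L
      counters[e$template] <- k + 1L
      template <- c(template, e$template)
      item <- c(item, k + 1L)
      seriesId <- c(seriesId, sid)
      outputTypes <- c(outputTypes, paste(e$output_types, collapse = ","))
    }
  }
  entries <- data.frame(series_id = seriesId, template = template,
                        item = item, output_types = outputTypes,
                        stringsAsFactors = FALSE)
  unref <- setdiff(seqinfo$series_id, c(entries$series_id, skipped$series_id))
  for (sid in unref) {
    skipped[nrow(skipped) + 1L, ] <- list(sid, "no rule matched")
  }
  plan <- structure(
    list(entries = entries, subject = subject, session = session,
         locator = locator, skipped = skipped),
    class = "conversionPlan"
  )
  validatePlan(plan)
  plan
}

#' Validate a conversion plan's invariants
#'
#' (template, item) pairs are unique; item numbers per template are
#' consecutive from 1; every template contains `{subject}`, contains
#' `{item}` whenever it holds more than one item, and renders to a relative
#' path without `..`.
#'
#' @param plan a `"conversionPlan"`.
#' @return the plan, invisibly; signals a validation error otherwise.
#' @export
validatePlan <- function(plan) {
  e <- plan$entries
  key <- paste(e$template, e$item, sep = "\r")
  if (anyDuplicated(key)) {
    validationError(sprintf("duplicate (template, item) assignment: %s",
                            e$template[duplicated(key)][1]))
  }
  for (tpl in unique(e$template)) {
    items <- sort(e$item[e$template == tpl])
    if (!identical(as.integer(items), seq_along(items))) {
      validationError(sprintf("item numbers for template '%s' are not consecutive from 1", tpl))
    }
    if (!grepl("{subject}", tpl, fixed = TRUE)) {
      validationError(sprintf("template '%s' lacks the {subject} placeholder", tpl))
    }
    if (length(items) > 1 && !grepl("{item", tpl, fixed = TRUE)) {
      validationError(sprintf("template '%s' holds %d items but lacks an {item} placeholder",
                              tpl, length(items)))
    }
    if (startsWith(tpl, "/") || grepl("(^|/)\\.\\.(/|$)", tpl)) {
      validationError(sprintf("template '%s' is not a safe relative path", tpl))
    }
  }
  invisible(plan)
}

#' @export
print.conversionPlan <- function(x, ...) {
  cat(sprintf("<conversionPlan> sub-%s%s: %d entr%s, %d skipped\n",
              x$subject,
              if (!is.null(x$session)) paste0(" ses-", x$session) else "",
              nrow(x$entries), if (nrow(x$entries) == 1) "y" else "ies",
              nrow(x$skipped)))
  invisible(x)
}

EDIT_TABLE_HEADER <- "series_id\ttemplate\titem\toutput_types"

#' Write / read the editable conversion table
#'
#' The discovery stage writes this TSV so an operator can tune proposed
#' filenames before conversion; `readEditTable(writeEditTable(plan)) == plan`
#' and edits are re-validated on read. Plan-level fields (subject, session,
#' locator, skip reports) travel in `#`-prefixed comment lines.
#'
#' @param plan a `"conversionPlan"`.
#' @param path file path.
#' @param overwrite replace a differing existing file.
#' @return `path` (write) / the reconstructed plan (read).
#' @export
writeEditTable <- function(plan, path, overwrite = FALSE) {
  validatePlan(plan)
  lines <- c(
    sprintf("# subject: %s", plan$subject),
    if (!is.null(plan$session)) sprintf("# session: %s", plan$session),
    if (!is.null(plan$locator)) sprintf("# locator: %s", plan$locator),
    if (nrow(plan$skipped)) {
      sprintf("# skipped: %s\t%s", plan$skipped$series_id, plan$skipped$reason)
    },
    EDIT_TABLE_HEADER,
    sprintf("%s\t%s\t%d\t%s", plan$entries$series_id, plan$entries$template,
            plan$entries$item, plan$entries$output_types)
  )
  .writeTextIdempotent(paste0(paste(lines, collapse = "\n"), "\n"), path, overwrite)
  invisible(path)
}

#' @rdname writeEditTable
#' @export
readEditTable <- function(path) {
  if (!file.exists(path)) inputError(sprintf("no edit table at %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  subject <- NULL; session <- NULL; locator <- NULL
  skipped <- data.frame(series_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  body <- character(); headerSeen <- FALSE
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (!nzchar(l)) next
    if (startsWith(l, "#")) {
      if (grepl("^# subject: ", l)) subject <- sub("^# subject: ", "", l)
      else if (grepl("^# session: ", l)) session <- sub("^# session: ", "", l)
      else if (grepl("^# locator: ", l)) locator <- sub("^# locator: ", "", l)
      else if (grepl("^# skipped: ", l)) {
        f <- strsplit(sub("^# skipped: ", "", l), "\t", fixed = TRUE)[[1]]
        if (length(f) != 2) parseError(sprintf("line %d: malformed skip record", ln))
        skipped[nrow(skipped) + 1L, ] <- as.list(f)
      }
      next
    }
    if (!headerSeen) {
      if (!identical(l, EDIT_TABLE_HEADER)) {
        parseError(sprintf("line %d: expected header '%s'", ln, EDIT_TABLE_HEADER))
      }
      headerSeen <- TRUE
      next
    }
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) parseError(sprintf("line %d: expected 4 tab-separated fields", ln))
    if (is.na(suppressWarnings(as.integer(f[3])))) {
      parseError(sprintf("line %d: item '%s' is not an integer", ln, f[3]))
    }
    body <- c(body, l)
  }
  if (!headerSeen) parseError("no header row found")
  if (is.null(subject)) parseError("no '# subject:' record found")
  fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  entries <- if (length(body)) {
    data.frame(series_id = fields[, 1], template = fields[, 2],
               item = as.integer(fields[, 3]), output_types = fields[, 4],
               stringsAsFactors = FALSE)
  } else {
    data.frame(series_id = character(), template = character(),
               item = integer(), output_types = character(),
               stringsAsFactors = FALSE)
  }
  plan <- structure(
    list(entries = entries, subject = subject, session = session,
         locator = locator, skipped = skipped),
    class = "conversionPlan"
  )
  validatePlan(plan)
  plan
}
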
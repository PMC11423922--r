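# Grouping DICOM headers into studies and series, and computing the
# per-series summary table ("seqinfo") that naming heuristics consume.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Cluster scalar slice positions: values closer than `tol` belong to one
# spatial position. Returns integer cluster ids ordered along the normal.
.clusterPositions <- function(proj, tol = 1e-4) {
  ord <- order(proj)
  ids <- integer(length(proj))
  cluster <- 1L
  last <- proj[ord[1]]
  for (i in seq_along(ord)) {
    if (proj[ord[i]] - last > tol) cluster <- cluster + 1L
    ids[ord[i]] <- cluster
    last <- proj[ord[i]]
  }
  ids
}

#' Derived-image and motion-correction flags
#'
#' @param imageType character vector of ImageType tokens.
#' @return list with logical elements `is_motion_corrected`
#'   (`"MOCO"` token present) and `is_derived` (`"DERIVED"` present without
#'   `"PRIMARY"`).
#' @export
detectFlags <- function(imageType) {
  imageType <- imageType %||% character()
  list(
    is_motion_corrected = "MOCO" %in% imageType,
    is_derived = "DERIVED" %in% imageType && !("PRIMARY" %in% imageType)
  )
}

#' Group DICOM headers into studies and series
#'
#' Files are grouped by (StudyInstanceUID, SeriesInstanceUID); series within
#' a study are ordered by (SeriesNumber, SeriesInstanceUID). For every series
#' a seqinfo row is computed: `dim3` is the number of distinct spatial
#' positions (projections of ImagePositionPatient onto the slice normal,
#' clustered at 1e-4 mm), `dim4` the number of volumes per echo, `TR` is
#' converted to seconds and `TE` kept in milliseconds (both -1 when absent).
#' Grouping is invariant under permutation of the input list; duplicated
#' instances (same series/instance/echo) raise a warning and are dropped.
#'
#' @param headers list of `dicomHeader` objects (rejections are filtered out).
#' @return object of class `"studyGroups"`: a named list (one element per
#'   StudyInstanceUID, sorted) of `"studyGroup"` objects, each holding
#'   `$study_instance_uid`, the `$seqinfo` data frame, and `$series`, a named
#'   list (by `series_id`) of the per-series header lists.
#' @export
groupSeries <- function(headers, tol = 1e-4) {
  headers <- Filter(function(h) inherits(h, "dicomHeader"), headers)
  if (!length(headers)) {
    return(structure(stats::setNames(list(), character()), class = "studyGroups"))
  }
  # canonical order makes grouping permutation-invariant
  paths <- vapply(headers, `[[`, "", "file_path")
  headers <- headers[order(paths, method = "radix")]

  key <- vapply(headers, function(h) {
    paste(h$series_instance_uid, h$instance_number %||% NA_integer_,
          h$echo_number %||% NA_integer_, sep = "|")
  }, "")
  dup <- duplicated(key)
  if (any(dup)) {
    .warnClass("duplicateInstanceWarning",
               sprintf("ignoring %d duplicate instance(s): %s", sum(dup),
                       paste(basename(vapply(headers[dup], `[[`, "", "file_path")),
                             collapse = ", ")))
    headers <- headers[!dup]
  }

  studyUids <- vapply(headers, `[[`, "", "study_instance_uid")
  out <- list()
  for (su in sort(unique(studyUids), method = "radix")) {
    hs <- headers[studyUids == su]
    seriesUids <- vapply(hs, `[[`, "", "series_instance_uid")
    uids <- unique(seriesUids)
    seriesNo <- vapply(uids, function(u) {
      hs[[which(seriesUids == u)[1]]]$series_number %||% NA_integer_
    }, 0L)
    uids <- uids[order(seriesNo, uids, method = "radix")]

    rows <- list()
    seriesHeaders <- list()
    cum <- 0L
    for (u in uids) {
      sh <- hs[seriesUids == u]
      inst <- vapply(sh, function(h) h$instance_number %||% 0L, 0L)
      sh <- sh[order(inst)]
      h1 <- sh[[1]]
      n <- length(sh)
      cum <- cum + n

      dim3 <- 1L
      if (!is.null(h1$image_orientation_patient) &&
          !is.null(h1$image_position_patient)) {
        normal <- .cross3(h1$image_orientation_patient[1:3],
                          h1$image_orientation_patient[4:6])
        proj <- vapply(sh, function(h) {
          p <- h$image_position_patient
          if (is.null(p)) NA_real_ else sum(p * normal)
        }, 0)
        if (!anyNA(proj)) dim3 <- max(.clusterPositions(proj, tol))
      }
      echoes <- unique(vapply(sh, function(h) h$echo_number %||% 1L, 0L))
      nEcho <- length(echoes)
      dim4 <- n / (dim3 * nEcho)
      if (dim4 != round(dim4)) {
        .warnClass("irregularSeriesWarning",
                   sprintf("series %s is not a complete %d-slice grid (%d files)",
                           u, dim3, n))
        dim4 <- ceiling(dim4)
      }
      flags <- detectFlags(h1$image_type)
      sid <- sprintf("%s-%s", h1$series_number %||% 0L, h1$protocol_name %||% "")
      rows[[length(rows) + 1]] <- data.frame(
        series_id = sid,
        series_instance_uid = u,
        example_file = h1$file_path,
        total_files_till_now = cum,
        dim1 = h1$columns %||% 1L,
        dim2 = h1$rows %||% 1L,
        dim3 = as.integer(dim3),
        dim4 = as.integer(dim4),
        TR = if (is.null(h1$repetition_time)) -1 else h1$repetition_time / 1000,
        TE = if (is.null(h1$echo_time)) -1 else h1$echo_time,
        protocol_name = h1$protocol_name %||% "",
        series_description = h1$series_description %||% "",
        sequence_name = h1$sequence_name %||% "",
        image_type = I(list(h1$image_type %||% character())),
        is_motion_corrected = flags$is_motion_corrected,
        is_derived = flags$is_derived,
        patient_id = h1$patient_id %||% "",
        study_description = h1$study_description %||% "",
        referring_physician_name = h1$referring_physician_name %||% "",
        date = h1$study_date %||% NA_character_,
        n_echoes = as.integer(nEcho),
        stringsAsFactors = FALSE
      )
      seriesHeaders[[sid]] <- sh
    }
    seqinfo <- do.call(rbind, rows)
    rownames(seqinfo) <- NULL
    out[[su]] <- structure(
      list(study_instance_uid = su, seqinfo = seqinfo, series = seriesHeaders),
      class = "studyGroup"
    )
  }
  structure(out, class = "studyGroups")
}

#' @export
print.studyGroups <- function(x, ...) {
  cat(sprintf("<studyGroups> %d stud%s\n", length(x),
              if (length(x) == 1) "y" else "ies"))
  for (g in x) {
    cat(sprintf("  %s: %d series, %d files\n", g$study_instance_uid,
                nrow(g$seqinfo), max(g$seqinfo$total_files_till_now)))
  }
  invisible(x)
}

# seqinfo columns in the order the discovery-stage TSV dump uses.
.seqinfoColumns <- c(
  "series_id", "series_instance_uid", "example_file", "total_files_till_now",
  "dim1", "dim2", "dim3", "dim4", "TR", "TE", "protocol_name",
  "series_description", "sequence_name", "image_type", "is_motion_corrected",
  "is_derived", "patient_id", "study_description",
  "referring_physician_name", "date"
)

#' Dump a seqinfo table to TSV for operator inspection
#'
#' @param seqinfo a seqinfo data frame from [groupSeries()].
#' @param path output path.
#' @param overwrite replace a differing existing file.
#' @return `path`, invisibly.
#' @export
writeSeqinfo <- function(seqinfo, path, overwrite = FALSE) {
  df <- seqinfo[, .seqinfoColumns]
  .writeTextIdempotent(.tsvText(df), path, overwrite)
  invisible(path)
}
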
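# Synthetic DICOM study generator. Emits Part-10 files (explicit VR little
# endian) with known ground-truth geometry, timing and protocol names so the
# whole pipeline is testable fully offline, plus targeted corruptions to
# exercise error branches. Fixture UIDs use a reserved fake root so they can
# never be mistaken for real data.

#' Describe one synthetic series
#'
#' @param name ReproIn-style protocol/series name (e.g. `"anat-T1w"`,
#'   `"func-bold_task-rest"`); it is written to both SeriesDescription and
#'   ProtocolName.
#' @param dim3 slices per volume.
#' @param dim4 volumes per echo.
#' @param nEchoes echoes; `te` must supply one echo time (ms) per echo.
#' @param tr repetition time, ms (NA to omit the tag).
#' @param te echo time(s), ms.
#' @param orientation `"axial"`, `"random"` (a random rigid rotation drawn
#'   from the study seed), or a 3x3 rotation matrix with columns (row
#'   cosines, column cosines, normal).
#' @param origin position of the first slice, mm (LPS); `"random"` draws
#'   uniformly in [-40, 40] mm per axis.
#' @param pixelSpacing c(row spacing, column spacing), mm.
#' @param sliceSpacing distance between slice centres, mm.
#' @param rows,cols in-plane matrix size.
#' @param imageType ImageType tokens.
#' @param flip flip angle, degrees.
#' @return a series-spec list for [fixtureSpec()].
#' @export
fixtureSeries <- function(name, dim3 = 5L, dim4 = 1L, nEchoes = 1L,
                          tr = 2000, te = 30, orientation = "axial",
                          origin = c(0, 0, 0), pixelSpacing = c(1, 1),
                          sliceSpacing = 1, rows = 8L, cols = 8L,
                          imageType = c("ORIGINAL", "PRIMARY", "M"),
                          flip = 77) {
  stopifnot(dim3 >= 1, dim4 >= 1, nEchoes >= 1, length(te) == nEchoes)
  list(name = name, dim3 = as.integer(dim3), dim4 = as.integer(dim4),
       nEchoes = as.integer(nEchoes), tr = tr, te = te,
       orientation = orientation, origin = origin,
       pixelSpacing = pixelSpacing, sliceSpacing = sliceSpacing,
       rows = as.integer(rows), cols = as.integer(cols),
       imageType = imageType, flip = flip)
}

#' Describe a synthetic study
#'
#' @param series list of [fixtureSeries()] specs.
#' @param patientId raw PatientID (multi-subject studies get numbered ids).
#' @param studyDescription StudyDescription; components separated by `"^"`
#'   become the locator (e.g. `"Patterson^Coben"`).
#' @param nSubjects number of subjects (one study each).
#' @param seed deterministic generator seed.
#' @param studyDate StudyDate, `YYYYMMDD`.
#' @return a `"fixtureSpec"` object.
#' @export
fixtureSpec <- function(series, patientId = "sid000001",
                        studyDescription = "Patterson^Coben",
                        nSubjects = 1L, seed = 42L,
                        studyDate = "20200102") {
  stopifnot(length(series) >= 1)
  structure(list(series = series, patientId = patientId,
                 studyDescription = studyDescription,
                 nSubjects = as.integer(nSubjects), seed = as.integer(seed),
                 studyDate = studyDate),
            class = "fixtureSpec")
}

.randomRotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# Deterministic 16-bit gradient so voxel-conservation checks are exact.
.fixturePixels <- function(rows, cols, k, v, e) {
  outer(0:(rows - 1), 0:(cols - 1), function(r, cc) {
    (r * cols + cc + (k - 1) * 7 + (v - 1) * 13 + (e - 1) * 17) %% 2048L
  })
}

# Ground-truth RAS affine, written directly from the generator's rotation
# and spacings (LPS columns scaled, rows 1-2 negated).
.gtAffine <- function(rot, origin, pixelSpacing, sliceSpacing) {
  M <- cbind(rot[, 1] * pixelSpacing[2], rot[, 2] * pixelSpacing[1],
             rot[, 3] * sliceSpacing)
  A <- rbind(cbind(M, origin), c(0, 0, 0, 1))
  A[1:2, ] <- -A[1:2, ]
  dimnames(A) <- NULL
  A
}

#' Generate a synthetic DICOM study with ground truth
#'
#' Writes one DICOM file per (slice, volume, echo) under `dir` with
#' consistent UIDs, positions along the chosen slice normal and deterministic
#' pixel gradients, and records the exact affines, dimensions, file counts
#' and the BIDS paths expected under the reproin heuristic.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created).
#' @return invisibly, the GroundTruth record: per subject a list with the
#'   raw/sanitized subject id, study uid, per-series truth (affine, dims,
#'   file count, echo times) and `expected_paths` (relative `.nii.gz` paths
#'   under the study's BIDS root).
#' @export
generateStudy <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (s in seq_len(spec$nSubjects)) {
    pid <- if (spec$nSubjects == 1) spec$patientId else sprintf("sid%06d", s)
    studyUid <- paste(FIXTURE_UID_ROOT, spec$seed, s, 1, sep = ".")
    seriesTruth <- list()
    for (i in seq_along(spec$series)) {
      sp <- spec$series[[i]]
      rot <- if (is.matrix(sp$orientation)) sp$orientation
      else if (identical(sp$orientation, "axial")) diag(3)
      else .randomRotation()
      origin <- if (identical(sp$origin, "random")) stats::runif(3, -40, 40) else sp$origin
      normal <- rot[, 3]
      seriesUid <- paste(FIXTURE_UID_ROOT, spec$seed, s, 2, i, sep = ".")
      sdir <- file.path(dir, sprintf("subj%02d", s), sprintf("series%02d", i))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      inst <- 0L
      for (v in seq_len(sp$dim4)) for (k in seq_len(sp$dim3)) for (e in seq_len(sp$nEchoes)) {
        inst <- inst + 1L
        pos <- origin + (k - 1) * sp$sliceSpacing * normal
        secs <- as.integer(round((i - 1) * 600 +
                                   (v - 1) * max(sp$tr, 1000, na.rm = TRUE) / 1000))
        fields <- list(
          sop_instance_uid = paste(seriesUid, inst, sep = "."),
          study_instance_uid = studyUid,
          series_instance_uid = seriesUid,
          series_number = i, instance_number = inst, acquisition_number = v,
          modality = "MR", manufacturer = "SyntheticScanner",
          study_description = spec$studyDescription,
          referring_physician_name = spec$studyDescription,
          series_description = sp$name, protocol_name = sp$name,
          sequence_name = "synth", patient_id = pid, patient_name = pid,
          study_date = spec$studyDate, study_time = "120000",
          acquisition_datetime = sprintf("%s%02d%02d%02d.000000",
                                         spec$studyDate,
                                         12 + (secs %/% 3600),
                                         (secs %/% 60) %% 60, secs %% 60),
          image_type = sp$imageType,
          echo_time = sp$te[e], echo_number = e, flip_angle = sp$flip,
          image_orientation_patient = c(rot[, 1], rot[, 2]),
          image_position_patient = pos,
          pixel_spacing = sp$pixelSpacing,
          slice_thickness = sp$sliceSpacing,
          spacing_between_slices = sp$sliceSpacing
        )
        if (!is.na(sp$tr)) fields$repetition_time <- sp$tr
        writeDicomFile(fields, file.path(sdir, sprintf("%04d.dcm", inst)),
                       pixel = .fixturePixels(sp$rows, sp$cols, k, v, e))
      }
      seriesTruth[[i]] <- list(
        name = sp$name, series_number = i, series_uid = seriesUid,
        files = inst, dims = c(sp$cols, sp$rows, sp$dim3, sp$dim4),
        n_echoes = sp$nEchoes, te = sp$te, tr = sp$tr,
        affine = .gtAffine(rot, origin, sp$pixelSpacing, sp$sliceSpacing),
        image_type = sp$imageType
      )
    }
    truth[[s]] <- list(
      subject_raw = pid, subject = sanitizeLabel(pid), study_uid = studyUid,
      series = seriesTruth,
      expected_paths = .expectedReproinPaths(spec$series, sanitizeLabel(pid))
    )
  }
  invisible(truth)
}

# Independent re-derivation of the names the reproin heuristic should
# produce for a fixture study, written only from the naming rules (skip
# MOCO/derived, dup markers supersede, collisions get run-1/run-2, echoes
# split, SBRef renames the suffix).
.expectedReproinPaths <- function(seriesSpecs, subject) {
  keep <- list()
  for (i in seq_along(seriesSpecs)) {
    sp <- seriesSpecs[[i]]
    if ("MOCO" %in% sp$imageType) next
    if ("DERIVED" %in% sp$imageType && !("PRIMARY" %in% sp$imageType)) next
    nm <- sp$name
    dup <- grepl("__dup[0-9]+", nm)
    nm <- gsub("__dup[0-9]+", "", nm)
    sbref <- grepl("_SBRef$", nm)
    nm <- sub("_SBRef$", "", nm)
    toks <- strsplit(nm, "_", fixed = TRUE)[[1]]
    head <- strsplit(toks[1], "-", fixed = TRUE)[[1]]
    dt <- head[1]
    sfx <- if (length(head) > 1) head[2] else if (dt == "func") "bold" else next
    if (sbref) sfx <- "sbref"
    ents <- toks[-1]
    keep[[length(keep) + 1]] <- list(i = i, dt = dt, sfx = sfx, ents = ents,
                                     dup = dup, nEchoes = sp$nEchoes,
                                     canon = paste(c(paste0(dt, "-", sfx), ents),
                                                   collapse = "_"))
  }
  # dup supersession: within identical canon groups containing a marker,
  # keep only the last
  canon <- vapply(keep, `[[`, "", "canon")
  drop <- logical(length(keep))
  for (k in unique(canon)) {
    idx <- which(canon == k)
    if (length(idx) > 1 && any(vapply(keep[idx], `[[`, TRUE, "dup"))) {
      drop[idx[-length(idx)]] <- TRUE
    }
  }
  keep <- keep[!drop]
  stem <- vapply(keep, function(x) {
    paste0(x$dt, "/", paste(c(paste0("sub-", subject), x$ents, x$sfx),
                            collapse = "_"))
  }, "")
  for (sgrp in unique(stem)) {
    idx <- which(stem == sgrp)
    if (length(idx) > 1 && !any(grepl("^run-", unlist(lapply(keep[idx], `[[`, "ents"))))) {
      for (r in seq_along(idx)) {
        x <- keep[[idx[r]]]
        x$ents <- c(x$ents, sprintf("run-%02d", r))
        keep[[idx[r]]] <- x
        stem[idx[r]] <- paste0(x$dt, "/", paste(c(paste0("sub-", subject),
                                                  x$ents, x$sfx), collapse = "_"))
      }
    }
  }
  paths <- character()
  for (q in seq_along(keep)) {
    x <- keep[[q]]
    base <- stem[q]
    if (x$nEchoes > 1) {
      for (e in seq_len(x$nEchoes)) {
        withEcho <- sub(paste0("_", x$sfx, "$"),
                        sprintf("_echo-%d_%s", e, x$sfx), base)
        paths <- c(paths, paste0("sub-", subject, "/", withEcho, ".nii.gz"))
      }
    } else {
      paths <- c(paths, paste0("sub-", subject, "/", base, ".nii.gz"))
    }
  }
  paths
}

#' Apply one targeted corruption to a generated study
#'
#' @param dir a directory produced by [generateStudy()].
#' @param mode one of `"drop_slice"` (delete an interior slice file, so
#'   assembly reports an incomplete grid), `"duplicate_instance"` (copy a
#'   file so grouping warns and ignores the extra), `"scramble_orientation"`
#'   (perturb one file's direction cosines beyond tolerance), or
#'   `"nonuniform_spacing"` (displace one slice along the normal so spacing
#'   regularity fails).
#' @return `dir`, invisibly.
#' @export
corruptStudy <- function(dir, mode) {
  modes <- c("drop_slice", "duplicate_instance", "scramble_orientation",
             "nonuniform_spacing")
  if (!(mode %in% modes)) {
    inputError(sprintf("unknown corruption mode '%s' (expected one of %s)",
                       mode, paste(modes, collapse = ", ")))
  }
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE),
                method = "radix")
  headers <- Filter(function(h) inherits(h, "dicomHeader"),
                    lapply(files, readDicomHeader))
  if (!length(headers)) inputError("no DICOM files to corrupt")
  uid <- headers[[1]]$series_instance_uid
  series <- Filter(function(h) h$series_instance_uid == uid, headers)
  inst <- vapply(series, function(h) h$instance_number %||% 0L, 0L)
  series <- series[order(inst)]

  rewrite <- function(h, mutate) {
    px <- readPixelData(h)
    fields <- h[setdiff(names(h), c("file_path", "pixel_offset", "pixel_length"))]
    class(fields) <- NULL
    fields <- mutate(fields)
    writeDicomFile(fields, h$file_path, pixel = px)
  }

  if (mode == "drop_slice") {
    target <- series[[min(2L, length(series))]]
    file.remove(target$file_path)
  } else if (mode == "duplicate_instance") {
    f <- series[[1]]$file_path
    file.copy(f, file.path(dirname(f), paste0("zdup-", basename(f))))
  } else if (mode == "scramble_orientation") {
    target <- series[[min(2L, length(series))]]
    rewrite(target, function(fields) {
      iop <- fields$image_orientation_patient
      row <- iop[1:3]; col <- iop[4:6]
      a <- 0.01  # ~0.01 rad: far beyond the 1e-4 consistency tolerance
      fields$image_orientation_patient <-
        c(cos(a) * row + sin(a) * col, -sin(a) * row + cos(a) * col)
      fields
    })
  } else if (mode == "nonuniform_spacing") {
    target <- series[[length(series)]]
    rewrite(target, function(fields) {
      iop <- fields$image_orientation_patient
      normal <- .cross3(iop[1:3], iop[4:6])
      ss <- fields$spacing_between_slices %||% 1
      fields$image_position_patient <-
        fields$image_position_patient + 0.5 * ss * normal
      fields
    })
  }
  invisible(dir)
}
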
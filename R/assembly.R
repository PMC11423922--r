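# Converting one series' DICOM files into NIfTI volumes: slice sorting,
# RAS affine construction, multi-echo splitting, sidecar metadata, and
# byte-stable NIfTI/JSON output.

#' Sort the slices of one volume along the slice normal
#'
#' Orders headers by the scalar projection of ImagePositionPatient onto the
#' slice normal (row x col direction cosines), ascending, with ties broken
#' by InstanceNumber. The slice spacing is the median of consecutive
#' projection differences; deviations beyond 1% flag non-uniform spacing.
#' A single slice falls back to SpacingBetweenSlices, or 1 mm with a
#' warning.
#'
#' @param headers `dicomHeader` list of one series / echo / volume.
#' @param tol orientation consistency tolerance on direction cosines.
#' @return list(headers, spacing, projections, normal, nonuniform).
#' @export
sortSlices <- function(headers, tol = 1e-4) {
  if (!length(headers)) assemblyError("no slices to sort")
  or <- lapply(headers, `[[`, "image_orientation_patient")
  pos <- lapply(headers, `[[`, "image_position_patient")
  if (any(vapply(or, is.null, TRUE)) || any(vapply(pos, is.null, TRUE))) {
    assemblyError("slice geometry tags (orientation/position) are missing")
  }
  ref <- or[[1]]
  dev <- vapply(or, function(o) max(abs(o - ref)), 0)
  if (max(dev) > tol) {
    assemblyError(sprintf("inconsistent slice orientation within series (max deviation %.2g)",
                          max(dev)))
  }
  normal <- .cross3(ref[1:3], ref[4:6])
  proj <- vapply(pos, function(p) sum(p * normal), 0)
  inst <- vapply(headers, function(h) h$instance_number %||% 0L, 0L)
  ord <- order(proj, inst)
  headers <- headers[ord]
  proj <- proj[ord]
  nonuniform <- FALSE
  if (length(headers) >= 2) {
    d <- diff(proj)
    spacing <- stats::median(d)
    if (any(abs(d - spacing) > 0.01 * abs(spacing))) nonuniform <- TRUE
  } else {
    spacing <- headers[[1]]$spacing_between_slices
    if (is.null(spacing)) {
      spacing <- 1
      .warnClass("sliceSpacingWarning",
                 "single slice without SpacingBetweenSlices; assuming 1 mm")
    }
  }
  list(headers = headers, spacing = spacing, projections = proj,
       normal = normal, nonuniform = nonuniform)
}

#' Build the RAS affine from DICOM slice geometry
#'
#' The 3x3 block's columns are the row direction cosines scaled by the
#' column spacing, the column cosines scaled by the row spacing, and the
#' slice normal scaled by the slice spacing, all in the LPS patient frame;
#' rows 1-2 (and the translation, taken from the first slice position) are
#' then negated to obtain NIfTI's RAS convention. The affine maps voxel
#' index (0,0,0) to the physical centre of the first voxel.
#'
#' @param rowCosine,colCosine unit direction cosines (LPS).
#' @param firstPosition position of the first (lowest-projection) slice, mm.
#' @param pixelSpacingRow,pixelSpacingCol in-plane spacings, mm
#'   (PixelSpacing order: row spacing first).
#' @param sliceSpacing distance between slice centres, mm.
#' @return object of class `"volumeGeometry"`.
#' @export
buildAffine <- function(rowCosine, colCosine, firstPosition,
                        pixelSpacingRow, pixelSpacingCol, sliceSpacing) {
  if (abs(sum(rowCosine * colCosine)) > 1e-4) {
    assemblyError("row and column direction cosines are not orthogonal")
  }
  normal <- .cross3(rowCosine, colCosine)
  M <- cbind(rowCosine * pixelSpacingCol,
             colCosine * pixelSpacingRow,
             normal * sliceSpacing)
  if (abs(det(M)) < 1e-12) assemblyError("singular voxel-to-world matrix")
  A <- rbind(cbind(M, firstPosition), c(0, 0, 0, 1))
  A[1:2, ] <- -A[1:2, ]
  dimnames(A) <- NULL
  structure(
    list(row_cosine = rowCosine, col_cosine = colCosine, slice_normal = normal,
         first_position = firstPosition, pixel_spacing_row = pixelSpacingRow,
         pixel_spacing_col = pixelSpacingCol, slice_spacing = sliceSpacing,
         affine_ras = A),
    class = "volumeGeometry"
  )
}

#' @export
print.volumeGeometry <- function(x, ...) {
  cat("<volumeGeometry> RAS affine:\n")
  print(round(x$affine_ras, 6))
  invisible(x)
}

.buildSidecar <- function(h, multiEcho = FALSE, echoIndex = NULL) {
  md <- list()
  if (!is.null(h$repetition_time)) md$RepetitionTime <- h$repetition_time / 1000
  if (!is.null(h$echo_time)) md$EchoTime <- h$echo_time / 1000
  if (!is.null(h$flip_angle)) md$FlipAngle <- h$flip_angle
  if (!is.null(h$manufacturer)) md$Manufacturer <- h$manufacturer
  if (!is.null(h$series_description)) md$SeriesDescription <- h$series_description
  if (!is.null(h$protocol_name)) md$ProtocolName <- h$protocol_name
  if (!is.null(h$sequence_name)) md$SequenceName <- h$sequence_name
  if (!is.null(h$image_type)) md$ImageType <- I(h$image_type)
  if (!is.null(h$series_number)) md$SeriesNumber <- h$series_number
  if (multiEcho) md$EchoNumber <- h$echo_number %||% echoIndex
  md$ConversionSoftware <- "dicombids"
  md$ConversionSoftwareVersion <-
    as.character(utils::packageVersion("dicombids"))
  md
}

#' Assemble a series into volumes
#'
#' Groups a series' files per (echo, spatial position), orders volumes by
#' (AcquisitionNumber, InstanceNumber), stacks slices into 3-D or 4-D arrays
#' of shape (columns, rows, slices[, volumes]), and applies rescale
#' slope/intercept when present. Multi-echo series yield one output per
#' echo, tagged with `echo_index` for the `_echo-<n>` entity and carrying a
#' distinct EchoTime in the sidecar.
#'
#' @param headers `dicomHeader` list of one series.
#' @return list of outputs: each `list(data, geometry, sidecar, echo_index,
#'   nonuniform_spacing, integer_data)`.
#' @export
assembleSeries <- function(headers) {
  if (!length(headers)) assemblyError("empty series")
  uids <- unique(vapply(headers, `[[`, "", "series_instance_uid"))
  if (length(uids) != 1) assemblyError("headers span more than one series")
  echoNums <- vapply(headers, function(h) h$echo_number %||% 1L, 0L)
  echoes <- sort(unique(echoNums))
  multiEcho <- length(echoes) > 1

  outputs <- list()
  for (ei in seq_along(echoes)) {
    sub <- headers[echoNums == echoes[ei]]
    h1 <- sub[[1]]
    if (is.null(h1$image_orientation_patient) || is.null(h1$image_position_patient)) {
      assemblyError(sprintf("series %s lacks geometry tags required for conversion", uids))
    }
    normal <- .cross3(h1$image_orientation_patient[1:3],
                      h1$image_orientation_patient[4:6])
    proj <- vapply(sub, function(h) sum(h$image_position_patient * normal), 0)
    cl <- .clusterPositions(proj)
    dim3 <- max(cl)
    counts <- tabulate(cl, dim3)
    dim4 <- max(counts)
    if (any(counts != dim4)) {
      holes <- which(counts != dim4)
      assemblyError(sprintf(
        "incomplete slice/volume grid in series %s: slice position(s) %s have %s of %d volumes",
        uids, paste(holes, collapse = ", "),
        paste(counts[holes], collapse = ", "), dim4))
    }

    # order volumes within each position by (acquisition, instance)
    grid <- vector("list", dim3)
    for (k in seq_len(dim3)) {
      hk <- sub[cl == k]
      acq <- vapply(hk, function(h) h$acquisition_number %||% 0L, 0L)
      inst <- vapply(hk, function(h) h$instance_number %||% 0L, 0L)
      grid[[k]] <- hk[order(acq, inst)]
    }
    # slice order along the normal
    centers <- vapply(seq_len(dim3), function(k) {
      sum(grid[[k]][[1]]$image_position_patient * normal)
    }, 0)
    kOrd <- order(centers)
    grid <- grid[kOrd]

    nr <- h1$rows
    nc <- h1$columns
    arr <- array(0, dim = c(nc, nr, dim3, dim4))
    rescaled <- FALSE
    for (k in seq_len(dim3)) {
      for (v in seq_len(dim4)) {
        h <- grid[[k]][[v]]
        px <- readPixelData(h)
        slope <- h$rescale_slope %||% 1
        icpt <- h$rescale_intercept %||% 0
        if (slope != 1 || icpt != 0) {
          px <- px * slope + icpt
          rescaled <- TRUE
        }
        arr[, , k, v] <- t(px)
      }
    }

    ss <- sortSlices(lapply(grid, `[[`, 1))
    geometry <- buildAffine(
      rowCosine = h1$image_orientation_patient[1:3],
      colCosine = h1$image_orientation_patient[4:6],
      firstPosition = grid[[1]][[1]]$image_position_patient,
      pixelSpacingRow = h1$pixel_spacing[1],
      pixelSpacingCol = h1$pixel_spacing[2],
      sliceSpacing = ss$spacing
    )
    if (dim4 == 1L) dim(arr) <- dim(arr)[1:3]
    outputs[[length(outputs) + 1]] <- list(
      data = arr,
      geometry = geometry,
      sidecar = .buildSidecar(sub[[1]], multiEcho, ei),
      echo_index = if (multiEcho) ei else NULL,
      nonuniform_spacing = ss$nonuniform,
      integer_data = !rescaled
    )
  }
  outputs
}

#' Write a volume as compressed NIfTI-1
#'
#' sform and qform are both set to the RAS affine with code 2 ("aligned").
#' Integer data that fit are stored as int16; rescaled data as float32.
#' Writing is idempotent: an existing identical file is left untouched, a
#' differing one is a collision unless `overwrite`.
#'
#' @param data 3-D or 4-D array.
#' @param geometry a `"volumeGeometry"`.
#' @param path output `.nii.gz` path.
#' @param overwrite replace differing existing output.
#' @param integerData store as int16 when the values allow it.
#' @return `path`, invisibly.
#' @export
writeNiftiVolume <- function(data, geometry, path, overwrite = FALSE,
                             integerData = TRUE) {
  useInt <- integerData && max(abs(data)) < 32768 &&
    all(data == round(data))
  if (useInt) {
    storage.mode(data) <- "integer"
  }
  img <- RNifti::asNifti(data)
  aff <- structure(geometry$affine_ras, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  tmp <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, tmp, datatype = if (useInt) "int16" else "float")
  .placeFile(tmp, path, overwrite)
  invisible(path)
}

# Canonical sidecar serialization: keys sorted, 2-space indent, trailing
# newline -- pinned so the idempotency contract is byte-testable.
.sidecarText <- function(metadata) {
  md <- metadata[order(names(metadata), method = "radix")]
  paste0(as.character(jsonlite::toJSON(md, pretty = 2, auto_unbox = TRUE,
                                       digits = NA)), "\n")
}

#' Write a JSON sidecar
#'
#' UTF-8, keys sorted, 2-space indent, trailing newline; bit-stable across
#' runs and idempotent like [writeNiftiVolume()].
#'
#' @param metadata named list of BIDS fields.
#' @param path output `.json` path.
#' @param overwrite replace differing existing output.
#' @return `path`, invisibly.
#' @export
writeSidecar <- function(metadata, path, overwrite = FALSE) {
  .writeTextIdempotent(.sidecarText(metadata), path, overwrite)
  invisible(path)
}
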
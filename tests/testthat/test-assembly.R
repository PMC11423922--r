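# Slice sorting, affine construction, volume assembly and NIfTI/sidecar
# output.

test_that("slices sort by projection onto the normal with instance tie-break", {
  hs <- list(geomHeader(c(0, 0, 2), instance = 3L),
             geomHeader(c(0, 0, 0), instance = 1L),
             geomHeader(c(0, 0, 1), instance = 2L))
  s <- sortSlices(hs)
  expect_equal(s$projections, c(0, 1, 2))
  expect_equal(s$spacing, 1)
  expect_false(s$nonuniform)

  s2 <- sortSlices(list(geomHeader(c(0, 0, 0)), geomHeader(c(0, 0, 1)),
                        geomHeader(c(0, 0, 2.5))))
  expect_true(s2$nonuniform)

  s3 <- sortSlices(list(geomHeader(c(0, 0, 0), sbs = 3)))
  expect_equal(s3$spacing, 3)
  expect_warning(s4 <- sortSlices(list(geomHeader(c(0, 0, 0)))),
                 class = "sliceSpacingWarning")
  expect_equal(s4$spacing, 1)

  bad <- list(geomHeader(c(0, 0, 0)),
              geomHeader(c(0, 0, 1), iop = c(1, 0, 0, 0, 0.999, 0.04472)))
  expect_error(sortSlices(bad), class = "assemblyError")
})

test_that("the axis-aligned affine matches the LPS-to-RAS sign rule", {
  g <- buildAffine(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0), 1, 1, 1)
  expect_equal(g$affine_ras, diag(c(-1, -1, 1, 1)))
  g2 <- buildAffine(c(1, 0, 0), c(0, 1, 0), c(10, 20, 5), 1, 1, 1)
  expect_equal(g2$affine_ras[1:3, 4], c(-10, -20, 5))
  expect_error(buildAffine(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0), 1, 1, 1),
               class = "assemblyError")
})

test_that("reconstructed affines match generator ground truth for rigid transforms", {
  for (seed in 1:5) {
    st <- makeStudy(list(fixtureSeries("anat-T1w", dim3 = 4,
                                       orientation = "random",
                                       origin = "random",
                                       pixelSpacing = c(0.8, 1.3),
                                       sliceSpacing = 2.2)),
                    seed = seed)
    g <- groupStudy(st$dir)
    out <- assembleSeries(g[[1]]$series[["1-anat-T1w"]])
    err <- norm(out[[1]]$geometry$affine_ras - st$gt[[1]]$series[[1]]$affine, "F")
    expect_lt(err, 1e-6)
    expect_equal(dim(out[[1]]$data), st$gt[[1]]$series[[1]]$dims[1:3])
  }
})

test_that("multi-echo series split per echo with conserved files and voxels", {
  st <- makeStudy(list(fixtureSeries("func-bold_task-rest", dim3 = 5, dim4 = 3,
                                     nEchoes = 2, te = c(15, 35))))
  g <- groupStudy(st$dir)
  headers <- g[[1]]$series[[1]]
  expect_length(headers, 30)
  outs <- assembleSeries(headers)
  expect_length(outs, 2)
  expect_equal(dim(outs[[1]]$data), c(8, 8, 5, 3))
  tes <- vapply(outs, function(o) o$sidecar$EchoTime, 0)
  expect_equal(tes, c(0.015, 0.035))
  expect_equal(vapply(outs, `[[`, 0L, "echo_index"), 1:2)
  # file-count conservation across the echo split
  expect_equal(sum(vapply(outs, function(o) prod(dim(o$data)[3:4]), 0)), 30)
  # voxel conservation, exact for integer data
  total <- sum(vapply(headers, function(h) sum(readPixelData(h)), 0))
  expect_identical(sum(vapply(outs, function(o) sum(o$data), 0)), total)
})

test_that("a single-volume anatomical yields one 3-D output without echo tag", {
  st <- makeStudy(list(fixtureSeries("anat-T1w", dim3 = 4)))
  outs <- assembleSeries(groupStudy(st$dir)[[1]]$series[[1]])
  expect_length(outs, 1)
  expect_length(dim(outs[[1]]$data), 3)
  expect_null(outs[[1]]$echo_index)
  expect_null(outs[[1]]$sidecar$EchoNumber)
})

test_that("a missing slice is reported as an incomplete grid", {
  st <- makeStudy(list(fixtureSeries("anat-T1w", dim3 = 4, dim4 = 2)))
  corruptStudy(st$dir, "drop_slice")
  g <- suppressWarnings(groupStudy(st$dir))
  err <- tryCatch(assembleSeries(g[[1]]$series[[1]]), error = function(e) e)
  expect_s3_class(err, "assemblyError")
  expect_match(conditionMessage(err), "slice position")
})

test_that("rescale slope/intercept are applied and promote to float", {
  f <- tempfile(fileext = ".dcm")
  writeDicomFile(list(
    sop_instance_uid = "1.3.6.1.4.1.99999.9.20.1",
    study_instance_uid = "1.3.6.1.4.1.99999.9.20.2",
    series_instance_uid = "1.3.6.1.4.1.99999.9.20.3",
    series_number = 1L, instance_number = 1L,
    image_orientation_patient = c(1, 0, 0, 0, 1, 0),
    image_position_patient = c(0, 0, 0), pixel_spacing = c(1, 1),
    spacing_between_slices = 1,
    rescale_slope = 0.5, rescale_intercept = -10
  ), f, pixel = matrix(0:8, 3, 3, byrow = TRUE))
  h <- readDicomHeader(f)
  out <- suppressWarnings(assembleSeries(list(h)))[[1]]
  expect_false(out$integer_data)
  expect_equal(out$data[1, 1, 1], 0 * 0.5 - 10)
  expect_equal(sum(out$data), sum((0:8) * 0.5 - 10))
})

test_that("NIfTI round trip preserves array and affine; sidecars are byte-stable", {
  st <- makeStudy(list(fixtureSeries("anat-T1w", dim3 = 3,
                                     orientation = "random", origin = "random")),
                  seed = 9)
  out <- assembleSeries(groupStudy(st$dir)[[1]]$series[[1]])[[1]]
  f <- tempfile(fileext = ".nii.gz")
  writeNiftiVolume(out$data, out$geometry, f)
  img <- RNifti::readNifti(f)
  expect_equal(as.array(img), out$data, ignore_attr = TRUE)
  aff <- RNifti::xform(img)
  expect_lt(norm(matrix(aff - out$geometry$affine_ras, 4), "F"), 1e-5)
  expect_equal(attr(aff, "code"), 2L)

  # writing the same volume again is a no-op; a different one collides
  expect_identical(writeNiftiVolume(out$data, out$geometry, f), f)
  expect_error(writeNiftiVolume(out$data + 1L, out$geometry, f),
               class = "collisionError")

  md <- out$sidecar
  j1 <- tempfile(fileext = ".json")
  j2 <- tempfile(fileext = ".json")
  writeSidecar(md, j1)
  writeSidecar(md, j2)
  expect_identical(readBin(j1, "raw", file.size(j1)),
                   readBin(j2, "raw", file.size(j2)))
  parsed <- jsonlite::fromJSON(j1)
  expect_equal(parsed$RepetitionTime, 2)   # 2000 ms -> 2 s
  expect_equal(parsed$EchoTime, 0.03)
  expect_equal(names(parsed), sort(names(parsed)))
  txt <- readLines(j1)
  expect_match(txt[2], "^  \"")           # 2-space indent
})
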
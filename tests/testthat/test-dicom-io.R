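# DICOM file enumeration and header reading.

test_that("header round-trips every consumed attribute through write/read", {
  f <- tempfile(fileext = ".dcm")
  px <- matrix(0:63, nrow = 8, ncol = 8, byrow = TRUE)
  fields <- list(
    sop_instance_uid = "1.3.6.1.4.1.99999.9.7.1",
    study_instance_uid = "1.3.6.1.4.1.99999.9.7.2",
    series_instance_uid = "1.3.6.1.4.1.99999.9.7.3",
    series_number = 4L, instance_number = 9L, acquisition_number = 2L,
    study_description = "Patterson^Coben",
    referring_physician_name = "Patterson^Coben",
    series_description = "func-bold_task-rest_run-01",
    protocol_name = "func-bold_task-rest_run-01",
    sequence_name = "epfid2d1", patient_id = "sid-01", patient_name = "sid-01",
    study_date = "20200102", study_time = "120000",
    acquisition_datetime = "20200102120503.000000",
    image_type = c("ORIGINAL", "PRIMARY", "M"),
    echo_time = 30, echo_number = 1L, repetition_time = 2000, flip_angle = 77,
    image_orientation_patient = c(1, 0, 0, 0, 1, 0),
    image_position_patient = c(-3.5, -10.25, 7.125),
    pixel_spacing = c(2.5, 3), manufacturer = "SyntheticScanner",
    modality = "MR"
  )
  writeDicomFile(fields, f, pixel = px)
  h <- readDicomHeader(f)
  expect_false(isRejection(h))
  for (nm in setdiff(names(fields), c("sop_class_uid"))) {
    expect_equal(h[[nm]], fields[[nm]], info = nm)
  }
  expect_identical(readPixelData(h), px)
  # orientation cosines are unit norm
  iop <- h$image_orientation_patient
  expect_lt(abs(sqrt(sum(iop[1:3]^2)) - 1), 1e-4)
  expect_lt(abs(sqrt(sum(iop[4:6]^2)) - 1), 1e-4)
})

test_that("written files agree with an independent DICOM reader", {
  f <- tempfile(fileext = ".dcm")
  writeDicomFile(list(
    sop_instance_uid = "1.3.6.1.4.1.99999.9.8.1",
    study_instance_uid = "1.3.6.1.4.1.99999.9.8.2",
    series_instance_uid = "1.3.6.1.4.1.99999.9.8.3",
    series_number = 1L, instance_number = 1L,
    series_description = "anat-T1w", echo_time = 4.5,
    image_orientation_patient = c(0, 1, 0, 0, 0, -1),
    image_position_patient = c(1.5, -2, 3),
    pixel_spacing = c(1.25, 0.75), modality = "MR"
  ), f, pixel = matrix(1:20, nrow = 4, ncol = 5, byrow = TRUE))
  script <- paste(
    "import sys, json, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(json.dumps({",
    " 'uid': ds.SeriesInstanceUID, 'te': float(ds.EchoTime),",
    " 'iop': [float(x) for x in ds.ImageOrientationPatient],",
    " 'ipp': [float(x) for x in ds.ImagePositionPatient],",
    " 'desc': ds.SeriesDescription,",
    " 'px': ds.pixel_array.flatten().tolist()}))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(f)), stdout = TRUE)
  got <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(got$uid, "1.3.6.1.4.1.99999.9.8.3")
  expect_equal(got$te, 4.5)
  expect_equal(got$iop, c(0, 1, 0, 0, 0, -1))
  expect_equal(got$ipp, c(1.5, -2, 3))
  expect_equal(got$desc, "anat-T1w")
  expect_equal(got$px, 1:20)
})

test_that("non-DICOM and magic-less files are rejected, with an override", {
  txt <- tempfile(fileext = ".txt")
  writeLines("not a scan", txt)
  expect_true(isRejection(readDicomHeader(txt)))

  f <- tempfile(fileext = ".dcm")
  writeDicomFile(list(
    sop_instance_uid = "1.3.6.1.4.1.99999.9.9.1",
    study_instance_uid = "1.3.6.1.4.1.99999.9.9.2",
    series_instance_uid = "1.3.6.1.4.1.99999.9.9.3",
    series_number = 1L, instance_number = 1L
  ), f)
  # strip the preamble + DICM marker: rejected unless explicitly allowed
  raw <- readBin(f, "raw", file.size(f))
  bare <- tempfile(fileext = ".dcm")
  writeBin(raw[-(1:132)], bare)
  expect_true(isRejection(readDicomHeader(bare)))
  h <- readDicomHeader(bare, allowNoMagic = TRUE)
  expect_false(isRejection(h))
  expect_equal(h$series_instance_uid, "1.3.6.1.4.1.99999.9.9.3")
})

test_that("optional geometry tags may be absent without rejection", {
  f <- tempfile(fileext = ".dcm")
  writeDicomFile(list(
    sop_instance_uid = "1.3.6.1.4.1.99999.9.10.1",
    study_instance_uid = "1.3.6.1.4.1.99999.9.10.2",
    series_instance_uid = "1.3.6.1.4.1.99999.9.10.3",
    series_number = 1L, instance_number = 1L
  ), f)
  h <- readDicomHeader(f)
  expect_false(isRejection(h))
  expect_null(h$image_orientation_patient)
  expect_null(h$echo_time)
})

test_that("discoverFiles sorts, recurses, extracts zips, and reports bad inputs", {
  expect_identical(discoverFiles(character()), character())

  d <- tempfile("disc-")
  dir.create(d)
  writeLines("x", file.path(d, "b.dcm"))
  writeLines("x", file.path(d, "a.dcm"))
  got <- discoverFiles(d)
  expect_identical(basename(got), c("a.dcm", "b.dcm"))
  expect_identical(discoverFiles(d), got)  # pure function of the input set

  st <- makeStudy(list(fixtureSeries("anat-T1w", dim3 = 5, dim4 = 2)))
  zf <- tempfile(fileext = ".zip")
  zipDirectory(st$dir, zf)
  members <- utils::unzip(zf, list = TRUE)  # archive listing as the oracle
  expect_equal(nrow(members), 10)
  extracted <- discoverFiles(zf, workdir = tempfile("wk-"))
  expect_length(extracted, 10)
  expect_false(isRejection(readDicomHeader(extracted[1])))

  expect_error(discoverFiles("/no/such/path-xyz"), class = "inputError")
  corrupt <- tempfile(fileext = ".zip")
  writeLines("definitely not a zip", corrupt)
  expect_error(discoverFiles(corrupt), class = "archiveError")
})
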
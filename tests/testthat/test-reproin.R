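# The ReproIn naming grammar, id inference and duplicate resolution.

test_that("the golden parse table holds", {
  p <- parseSeriesSpec("func-bold_task-rest_run-01")
  expect_equal(p$datatype, "func")
  expect_equal(p$suffix, "bold")
  expect_equal(p$entities, c(task = "rest", run = "01"))

  p <- parseSeriesSpec("anat-T1w")
  expect_equal(p$datatype, "anat")
  expect_equal(p$suffix, "T1w")
  expect_length(p$entities, 0)

  p <- parseSeriesSpec("func-bold_task-mot_run-02_SBRef")
  expect_equal(p$suffix, "sbref")
  expect_equal(p$entities, c(task = "mot", run = "02"))

  expect_true(isRejection(parseSeriesSpec("localizer")))
  # a missing suffix defaults only for func; bold still needs a task
  expect_true(isRejection(parseSeriesSpec("anat")))
  expect_equal(parseSeriesSpec("func_task-rest")$suffix, "bold")
  expect_true(isRejection(parseSeriesSpec("func-bold")))

  p <- parseSeriesSpec("anat-T1w__dup02")
  expect_true(p$dup)
  expect_equal(p$suffix, "T1w")

  p <- parseSeriesSpec("func-bold_task-rest_ses-pre")
  expect_equal(p$session, "pre")
  expect_warning(p <- parseSeriesSpec("anat-T1w_weird-x"),
                 class = "unknownEntityWarning")
  expect_equal(p$extra, c(weird = "x"))
})

test_that("sanitization strips everything outside [A-Za-z0-9]", {
  expect_equal(sanitizeLabel("sid_01"), "sid01")
  expect_equal(sanitizeLabel("ABC123"), "ABC123")
  expect_equal(sanitizeLabel("émil-07"), "mil07")
  expect_equal(sanitizeLabel(NULL), "")
})

test_that("parse and render are mutually inverse on valid entity sets", {
  set.seed(7)
  for (i in 1:50) {
    e <- randomEntitySet()
    r <- renderSeriesSpec(e)
    p <- suppressWarnings(parseSeriesSpec(r))
    expect_false(isRejection(p), info = r)
    expect_equal(p, e, info = r)
  }
})

test_that("study ids derive from study metadata like the worked example", {
  st <- makeStudy(list(fixtureSeries("anat-T1w", dim3 = 2)),
                  patientId = "sid-01", studyDescription = "Patterson^Coben")
  si <- groupStudy(st$dir)[[1]]$seqinfo
  ids <- inferStudyIds(si)
  expect_equal(ids$locator, "Patterson/Coben")
  expect_equal(ids$subject, "sid01")
  expect_null(ids$session)

  st2 <- makeStudy(list(fixtureSeries("func-bold_task-rest_ses-pre", dim3 = 2)))
  ids2 <- inferStudyIds(groupStudy(st2$dir)[[1]]$seqinfo)
  expect_equal(ids2$session, "pre")
})

test_that("duplicate-marked repeats are superseded by the last acquisition", {
  p <- lapply(c("anat-T1w__dup01", "anat-T1w"), parseSeriesSpec)
  r <- resolveDuplicates(p)
  expect_equal(r$kept, 2L)
  expect_equal(r$superseded, 1L)

  expect_equal(resolveDuplicates(list(parseSeriesSpec("anat-T1w")))$kept, 1L)

  p3 <- lapply(c("anat-T1w__dup01", "anat-T1w__dup02", "anat-T1w"),
               parseSeriesSpec)
  r3 <- resolveDuplicates(p3)
  expect_equal(r3$kept, 3L)
  expect_equal(sort(r3$superseded), c(1L, 2L))

  # unmarked repeats are left alone (they become run-1 / run-2)
  pr <- lapply(c("func_task-a", "func_task-a"), parseSeriesSpec)
  expect_equal(resolveDuplicates(pr)$kept, c(1L, 2L))
})

test_that("reproin builds BIDS templates, auto-runs collisions, skips MOCO", {
  st <- makeStudy(list(
    fixtureSeries("anat-T1w", dim3 = 2),
    fixtureSeries("func-bold_task-rest", dim3 = 2, dim4 = 2),
    fixtureSeries("func-bold_task-rest", dim3 = 2, dim4 = 2),
    fixtureSeries("func-bold_task-rest_MoCoSeries", dim3 = 2, dim4 = 2,
                  imageType = c("ORIGINAL", "PRIMARY", "M", "MOCO")),
    fixtureSeries("localizer", dim3 = 2)
  ))
  si <- groupStudy(st$dir)[[1]]$seqinfo
  info <- reproinInfotodict(si)
  templates <- vapply(info, `[[`, "", "template")
  expect_setequal(templates, c(
    "sub-{subject}/anat/sub-{subject}_T1w",
    "sub-{subject}/func/sub-{subject}_task-rest_run-01_bold",
    "sub-{subject}/func/sub-{subject}_task-rest_run-02_bold"
  ))
  skipped <- attr(info, "skipped")
  expect_true(any(grepl("motion-corrected", skipped$reason)))
  expect_true(any(grepl("datatype", skipped$reason)))
  # no two entries render to the same path
  expect_equal(anyDuplicated(templates), 0L)
})

test_that("a session token propagates into directories and filenames", {
  st <- makeStudy(list(fixtureSeries("anat-T1w_ses-pre", dim3 = 2)))
  si <- groupStudy(st$dir)[[1]]$seqinfo
  info <- reproinInfotodict(si)
  expect_equal(info[[1]]$template,
               "sub-{subject}/ses-{session}/anat/sub-{subject}_ses-{session}_T1w")
  expect_equal(attr(info, "session"), "pre")
})

test_that("rendered entity order always follows the canonical order", {
  st <- makeStudy(list(
    fixtureSeries("func-bold_run-02_task-rest_acq-fast", dim3 = 2)
  ))
  si <- groupStudy(st$dir)[[1]]$seqinfo
  info <- reproinInfotodict(si)
  expect_match(info[[1]]$template, "task-rest_acq-fast_run-02_bold$")
})
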
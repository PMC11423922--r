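# Heuristic plug-in contract, convertall, plan building and the editable
# conversion table.

makeSeqinfo <- function(n = 3) {
  st <- makeStudy(lapply(seq_len(n), function(i) {
    fixtureSeries(sprintf("anat-T1w_acq-v%d", i), dim3 = 2)
  }))
  groupStudy(st$dir)[[1]]$seqinfo
}

test_that("convertall maps every series to its generic template", {
  si <- makeSeqinfo(3)
  expect_length(convertallInfotodict(si[0, ]), 0)
  info <- convertallInfotodict(si)
  expect_length(info, 3)
  for (i in 1:3) {
    expect_equal(info[[i]]$template,
                 paste0("sub-{subject}/{item:02d}-", si$series_id[i]))
    expect_equal(info[[i]]$series_ids, si$series_id[i])
  }
})

test_that("applyHeuristic assigns per-template items and is deterministic", {
  si <- makeSeqinfo(2)
  h <- loadHeuristic("convertall")
  plan <- applyHeuristic(h, si, "01")
  expect_s3_class(plan, "conversionPlan")
  expect_equal(nrow(plan$entries), 2)
  # distinct templates, so each restarts at item 1
  expect_equal(plan$entries$item, c(1L, 1L))
  expect_equal(plan$subject, "01")
  expect_equal(applyHeuristic(h, si, "01"), plan)

  # one shared template numbers items consecutively
  shared <- structure(list(
    name = "shared", infotoids = NULL, sanitizeId = NULL,
    infotodict = function(seqinfo) {
      list(list(template = "sub-{subject}/run{item:02d}",
                output_types = "nii.gz", series_ids = seqinfo$series_id))
    }), class = "heuristic")
  p2 <- applyHeuristic(shared, si, "01")
  expect_equal(p2$entries$item, c(1L, 2L))
})

test_that("a heuristic naming an unknown series id is a plan error", {
  si <- makeSeqinfo(1)
  bad <- structure(list(
    name = "bad", infotoids = NULL, sanitizeId = NULL,
    infotodict = function(seqinfo) {
      list(list(template = "sub-{subject}/x", output_types = "nii.gz",
                series_ids = "99-x"))
    }), class = "heuristic")
  expect_error(applyHeuristic(bad, si, "01"), class = "planError")
})

test_that("series matched by no rule are reported as skipped, not dropped", {
  si <- makeSeqinfo(2)
  partial <- structure(list(
    name = "partial", infotoids = NULL, sanitizeId = NULL,
    infotodict = function(seqinfo) {
      list(list(template = "sub-{subject}/only", output_types = "nii.gz",
                series_ids = seqinfo$series_id[1]))
    }), class = "heuristic")
  plan <- applyHeuristic(partial, si, "01")
  expect_equal(plan$skipped$series_id, si$series_id[2])
  expect_equal(plan$skipped$reason, "no rule matched")
})

test_that("heuristics load from module files and missing hooks are contract errors", {
  mod <- tempfile(fileext = ".R")
  writeLines(c(
    "infotodict <- function(seqinfo) {",
    "  out <- lapply(seqinfo$series_id, function(sid)",
    "    list(template = paste0('sub-{subject}/{item:02d}-', sid),",
    "         output_types = 'nii.gz', series_ids = sid))",
    "  out",
    "}"), mod)
  h <- loadHeuristic(mod)
  si <- makeSeqinfo(2)
  expect_equal(nrow(applyHeuristic(h, si, "01")$entries), 2)

  empty <- tempfile(fileext = ".R")
  writeLines("helper <- function() NULL", empty)
  expect_error(loadHeuristic(empty), class = "heuristicContractError")
  expect_error(loadHeuristic("no-such-heuristic"),
               class = "heuristicContractError")
})

test_that("the built-in registry exposes convertall and reproin", {
  expect_s3_class(loadHeuristic("convertall"), "heuristic")
  h <- loadHeuristic("reproin")
  expect_s3_class(h, "heuristic")
  expect_true(is.function(h$infotoids))
})

test_that("the edit table round-trips plans exactly", {
  si <- makeSeqinfo(3)
  for (name in c("convertall", "reproin")) {
    plan <- applyHeuristic(loadHeuristic(name), si, "01", session = "pre",
                           locator = "Lab/Proj")
    f <- tempfile(fileext = ".tsv")
    writeEditTable(plan, f)
    expect_equal(readEditTable(f), plan)
  }
})

test_that("edit-table round trip holds for randomized plans", {
  set.seed(23)
  h <- loadHeuristic("convertall")
  for (rep in 1:5) {
    si <- makeSeqinfo(sample(1:4, 1))
    ses <- if (runif(1) < 0.5) paste0(sample(letters, 3), collapse = "") else NULL
    plan <- applyHeuristic(h, si, paste0(sample(LETTERS, 4), collapse = ""),
                           session = ses)
    f <- tempfile(fileext = ".tsv")
    writeEditTable(plan, f)
    expect_equal(readEditTable(f), plan)
  }
})

test_that("operator edits are honoured and invalid edits rejected", {
  si <- makeSeqinfo(2)
  plan <- applyHeuristic(loadHeuristic("convertall"), si, "01")
  f <- tempfile(fileext = ".tsv")
  writeEditTable(plan, f)

  lines <- readLines(f)
  i <- grep(si$series_id[2], lines, fixed = TRUE)[1]
  lines[i] <- sub("sub-\\{subject\\}/\\{item:02d\\}-",
                  "sub-{subject}/renamed-{item:02d}-", lines[i])
  writeLines(lines, f)
  edited <- readEditTable(f)
  expect_true(any(grepl("renamed-", edited$entries$template)))

  # duplicate (template, item) after an edit is a validation error
  lines <- readLines(f)
  rows <- grep("\t", lines, fixed = TRUE)
  rows <- setdiff(rows, grep("^#", lines))
  body <- rows[-1]  # first is the header
  lines[body[2]] <- lines[body[1]]
  writeLines(lines, f)
  expect_error(readEditTable(f), class = "validationError")

  # malformed row reports its line number
  writeLines(c("# subject: 01", EDIT_TABLE_HEADER <- "series_id\ttemplate\titem\toutput_types",
               "only-two\tfields"), f)
  err <- tryCatch(readEditTable(f), error = function(e) e)
  expect_s3_class(err, "parseError")
  expect_match(conditionMessage(err), "line 3")
})
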
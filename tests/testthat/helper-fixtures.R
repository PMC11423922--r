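# Shared fixture builders: every test input is generated in code at run
# time; nothing binary ships with the package.

makeStudy <- function(series, ..., seed = 42L) {
  dir <- tempfile("fixture-study-")
  gt <- generateStudy(fixtureSpec(series, seed = seed, ...), dir)
  list(dir = dir, gt = gt)
}

readStudyHeaders <- function(dir) {
  Filter(Negate(isRejection), lapply(discoverFiles(dir), readDicomHeader))
}

groupStudy <- function(dir) {
  groupSeries(readStudyHeaders(dir))
}

# A minimal in-memory header carrying just the geometry fields, for unit
# tests of slice sorting that need no file on disk.
geomHeader <- function(pos, iop = c(1, 0, 0, 0, 1, 0), instance = 1L,
                       sbs = NULL) {
  structure(list(file_path = "<memory>", series_instance_uid = "s",
                 study_instance_uid = "st", instance_number = instance,
                 image_orientation_patient = iop,
                 image_position_patient = pos,
                 spacing_between_slices = sbs),
            class = "dicomHeader")
}

# Random valid BIDS entity sets for grammar round-trip properties.
randomEntitySet <- function() {
  datatypes <- list(
    anat = c("T1w", "T2w", "FLAIR"),
    func = c("bold", "sbref"),
    dwi = c("dwi"),
    fmap = c("epi", "phasediff")
  )
  dt <- sample(names(datatypes), 1)
  suffix <- sample(datatypes[[dt]], 1)
  keys <- dicombids::BIDS_ENTITY_ORDER
  pick <- keys[stats::runif(length(keys)) < 0.4]
  if (dt == "func" && suffix == "bold") pick <- union("task", pick)
  pick <- intersect(keys, pick)
  vals <- vapply(pick, function(k) {
    paste0(sample(c(letters, 0:9), sample(2:6, 1), replace = TRUE), collapse = "")
  }, "")
  ents <- stats::setNames(vals, pick)[intersect(keys, pick)]
  session <- if (stats::runif(1) < 0.3) {
    paste0(sample(letters, 3, replace = TRUE), collapse = "")
  } else NULL
  structure(list(datatype = dt, suffix = suffix,
                 entities = if (length(ents)) ents else character(),
                 extra = character(), session = session, dup = FALSE),
            class = "bidsEntities")
}

# Snapshot a directory tree as relative path -> content hash, for
# byte-identity comparisons.
treeSnapshot <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, all.files = TRUE,
                           no.. = TRUE), method = "radix")
  files <- files[!dir.exists(file.path(root, files))]
  vapply(files, function(f) {
    unname(tools::md5sum(file.path(root, f)))
  }, "")
}
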
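# dicombids

Heuristic-driven conversion of DICOM studies into BIDS datasets, in R.

MRI scanners export one DICOM file per reconstructed slice, with naming and
organisation that vary by site, vendor and operator. Almost every
neuroimaging analysis tool instead expects NIfTI volumes arranged in a
[BIDS](https://bids.neuroimaging.io) hierarchy
(`sub-<label>/[ses-<label>/]<datatype>/sub-<label>_..._<suffix>.nii.gz` with
JSON sidecar metadata). `dicombids` automates that conversion for labs and
imaging centres: it groups loose DICOM files into studies and series,
summarises each series for a pluggable *naming heuristic*, converts the
selected series into NIfTI with a correct RAS affine, and populates the
standard BIDS dataset files.

The workflow has three stages:

1. **Discovery** (`-c none`) — group inputs, write a per-series summary
   table (*seqinfo*) and an editable conversion table proposing one output
   filename template per series.
2. **Manual tuning** (optional) — the operator edits the proposed templates.
3. **Conversion** (`-c internal`) — assemble volumes, write
   `.nii.gz` + `.json`, populate `dataset_description.json`,
   `participants.tsv` and `*_scans.tsv`.

The whole process is **idempotent**: re-running over unchanged input is a
byte-level no-op, and running discovery first changes nothing about the
final tree.

Naming decisions live in heuristics — small modules exposing
`infotodict(seqinfo)` (required) and `infotoids(seqinfo)` (optional). Two
are built in:

* **convertall** — assumes nothing; maps every series to
  `sub-{subject}/{item:02d}-<series_id>` as a starting point for manual
  naming.
* **reproin** — implements the ReproIn convention: protocols named
  `<datatype>[-<suffix>][_<key>-<value>]...` on the scanner (e.g.
  `func-bold_task-rest_run-01`, `anat-T1w`, trailing `_SBRef` for
  single-band references, `__dup<NN>` to supersede mistyped acquisitions)
  convert fully automatically, including subject/session/locator inference
  from study metadata (`"Patterson^Coben"` → output under
  `Patterson/Coben/`).

Multi-echo series are kept as one series for naming and split per echo at
assembly (`_echo-<n>`, one sidecar `EchoTime` each). Optional anonymization
maps subject ids through a table or a deterministic keyed digest and shifts
all visit timestamps of a study by one constant offset of ±1–2 years, so
longitudinal intervals are preserved exactly; the id map is refused inside
the output tree.

The geometry core builds the NIfTI affine from DICOM's
`ImageOrientationPatient`/`ImagePositionPatient`/`PixelSpacing`: slices are
sorted by their projection onto the slice normal **n** = **r** × **c**, and
the voxel-to-world map in LPS is

```
[ r·Δc  c·Δr  n·Δs  p₀ ]
[ 0     0     0     1  ]
```

with the first two rows negated for NIfTI's RAS convention (Δc, Δr, Δs:
column, row and slice spacings; p₀: first slice position).

A synthetic DICOM generator (`fixtureSpec()`/`generateStudy()`) emits
Part-10 files with known ground-truth geometry, timing and protocol names
under a reserved fake UID root, so everything is testable without any data
download.

## Worked example

```r
library(dicombids)

# a synthetic two-series study, zipped like a scanner export
src <- file.path(tempdir(), "demo-dicom")
spec <- fixtureSpec(list(
  fixtureSeries("anat-T1w", dim3 = 5),
  fixtureSeries("func-bold_task-rest", dim3 = 4, dim4 = 3, tr = 2000)
), patientId = "sid000001", studyDescription = "Patterson^Coben", seed = 1)
generateStudy(spec, src)
zipf <- file.path(tempdir(), "reproin_dicom.zip")
zipDirectory(src, zipf)

headers <- Filter(Negate(isRejection), lapply(discoverFiles(zipf), readDicomHeader))
groups <- groupSeries(headers)
groups
#> <studyGroups> 1 study
#>   1.3.6.1.4.1.99999.9.1.1.1: 2 series, 17 files
groups[[1]]$seqinfo[, c("series_id", "dim1", "dim2", "dim3", "dim4", "TR", "TE")]
#>               series_id dim1 dim2 dim3 dim4 TR TE
#> 1            1-anat-T1w    8    8    5    1  2 30
#> 2 2-func-bold_task-rest    8    8    4    3  2 30

out <- file.path(tempdir(), "bids_datasets")
runCli(c("--files", zipf, "-f", "reproin", "--bids", "-o", out, "-c", "internal"))
#> exit code 0
list.files(out, recursive = TRUE)
#> Patterson/Coben/dataset_description.json
#> Patterson/Coben/participants.tsv
#> Patterson/Coben/README
#> Patterson/Coben/sub-sid000001/anat/sub-sid000001_T1w.json
#> Patterson/Coben/sub-sid000001/anat/sub-sid000001_T1w.nii.gz
#> Patterson/Coben/sub-sid000001/func/sub-sid000001_task-rest_bold.json
#> Patterson/Coben/sub-sid000001/func/sub-sid000001_task-rest_bold.nii.gz
#> Patterson/Coben/sub-sid000001/sub-sid000001_scans.tsv
```

The seqinfo table reads: the anatomical series is one 8×8×5 volume, the
functional series holds three 8×8×4 volumes at TR 2 s (converted from the
2000 ms DICOM tag; TE stays in ms in seqinfo and becomes seconds in the
sidecar). The study description `Patterson^Coben` became the `Patterson/Coben`
locator directory, and each converted file's sidecar records its BIDS
metadata, e.g. `"RepetitionTime": 2, "EchoTime": 0.03`.

The same conversion from a shell:

```sh
inst/cli/dicombids --files reproin_dicom.zip -f reproin --bids -o bids_datasets -c internal
```

Exit codes are pinned for scripting: 0 ok, 2 usage, 3 input, 4 heuristic
contract, 5 assembly, 6 output collision.

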
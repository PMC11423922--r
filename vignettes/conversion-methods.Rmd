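---
title: "How dicombids converts DICOM studies into BIDS datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How dicombids converts DICOM studies into BIDS datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicombids)
```

This vignette documents the models and procedures inside `dicombids`: how
files become series, series become names, and names become NIfTI volumes in
a BIDS tree — together with the numerical choices, defaults, and the limits
of what the synthetic test bench demonstrates.

## Ingestion and the supported DICOM subset

`discoverFiles()` flattens directories, explicit file lists and zip
archives into one lexicographically sorted list; sorting makes discovery a
pure function of the input set, which the idempotency guarantees below rely
on. `readDicomHeader()` then parses, per file, exactly the attribute subset
the pipeline consumes (identifiers, timing, geometry, descriptions, pixel
metadata). Reading is *lazy*: pixel payloads are located but not loaded, so
discovery over a large study touches only headers; `readPixelData()` fetches
the array during assembly.

Supported input is DICOM Part-10, explicit VR little endian
(`1.2.840.10008.1.2.1`), the syntax the synthetic generator emits. Rather
than guessing at other transfer syntaxes, anything else — including
enhanced multi-frame objects, vendor mosaic layouts and compressed pixel
streams — is rejected as a value (not an error), and the series is reported
as skipped. Files without the 128-byte preamble and `DICM` marker are
likewise rejected by default; predictable behaviour is preferred over
permissiveness, with `--allow-no-magic` as the documented override.
Sequences (SQ elements) and nested zips are out of scope.

## Grouping and the seqinfo table

Files group by `(StudyInstanceUID, SeriesInstanceUID)`. Series identity is
the UID, never the scanner's `SeriesNumber`, which is globally meaningless
and kept only for ordering and for the human-readable
`series_id = "<series_number>-<protocol_name>"`.

Per series, the spatial slice count `dim3` is the number of distinct
projections of `ImagePositionPatient` onto the slice normal, clustered at
**10⁻⁴ mm**: scanner jitter sits far below that tolerance and true
neighbouring slices far above. The volume count `dim4` is the file count
divided by `dim3 ×` (number of distinct echoes). `TR` converts to seconds;
`TE` stays in milliseconds in seqinfo (matching how protocol cards are
written) and becomes seconds in sidecars (as BIDS requires). Missing timing
encodes as the sentinel `-1` to keep the row a flat record. Multi-echo
series deliberately remain **one** seqinfo row — heuristics see one
acquisition; the echo split happens at assembly.

Duplicated instances (same series/instance/echo) are dropped with a warning.
Grouping sorts headers canonically first, so its result is invariant under
permutation of the input list.

## Heuristics and the three-stage workflow

A heuristic is a module with one required hook, `infotodict(seqinfo)`,
returning output templates with the series each should consume, and an
optional `infotoids(seqinfo)` returning subject/session/locator. This
two-hook surface is intentionally minimal: a site's naming policy fits in a
single file, loadable by path with `loadHeuristic()`.

`applyHeuristic()` numbers items **per template** in encounter order from 1,
so repeated runs of one task map to `{item}` = 1, 2, 3 under a single
template while unrelated templates restart at 1. Series no template claims
are recorded as skipped with a reason — never silently dropped. One design
point deserves a note: templates must contain `{subject}`, but `{item}` is
required only when a template actually collects more than one item; the
ReproIn templates below are item-free because each names exactly one series,
and demanding `{item}` there would force meaningless suffixes into
well-formed BIDS names.

The discovery stage (`-c none`) writes the seqinfo table and an editable
TSV (one row per series→template assignment, pinned header
`series_id  template  item  output_types`, plan-level fields in `#`
comments). TSV was chosen over free-form text so the table round-trips
losslessly: `readEditTable(writeEditTable(plan))` equals the plan, and
reading re-validates every invariant after operator edits. The conversion
stage honours an existing edit table, which is exactly why an unedited
`-c none` → `-c internal` sequence produces the same tree as a direct
`-c internal` run.

## The ReproIn grammar

`parseSeriesSpec()` anchors the grammar
`<datatype>[-<suffix>][_<key>-<value>]...` at the start of the series
description, falling back to the protocol name when the description is
empty (operators edit descriptions; scanners copy protocols). Datatypes are
`anat`, `func`, `dwi`, `fmap`. A missing suffix defaults only for `func`
(→ `bold`); inventing defaults for other datatypes would guess at
acquisition intent, so those are rejections. A trailing `_SBRef` rewrites
the suffix to `sbref` (single-band reference volumes); `__dup<NN>` marks a
mistyped acquisition superseded by the last identical one. `bold` without a
`task` entity is rejected at parse time — the same rule the name validator
enforces. Unknown entity keys warn and land in an `extra` slot rather than
failing, favouring conversion progress with an audit trail. Constructs
beyond these are rejected, not guessed.

Entities always render in the fixed order
`task, acq, ce, rec, dir, run, echo, part`. When two accepted series would
render identically, a `run` entity is auto-appended in acquisition order —
only on collision, so single acquisitions carry minimal names. Run values
are zero-padded to width 2 (`run-01`) for stable lexicographic sorting; the
width is a config knob (`run_padding`). Session precedence is: explicit
`-ss` flag, then a `ses-` token in study metadata or series specs, else no
session.

Subject ids come from `PatientID`, sanitized to `[A-Za-z0-9]` as BIDS
labels require; the locator — the directory a converted dataset lands under
— splits the study description on `"^"` (the DICOM component separator), so
`"Patterson^Coben"` becomes `Patterson/Coben/`. The upstream idea of a
site-specific fix-up dictionary for legacy protocol names exists as an
extension point only; the shipped table is empty.

## Volume assembly and geometry

Within a series, files split per echo, then cluster by slice position
(same 10⁻⁴ mm tolerance). Slices sort by the scalar projection of
`ImagePositionPatient` onto the slice normal **n** = **r** × **c**
(right-handed, from the row/column direction cosines), ties broken by
`InstanceNumber`; volumes order by `(AcquisitionNumber, InstanceNumber)`.
Sorting ascending along the normal gives one canonical on-disk orientation,
so the affine construction never needs a flipped-axis special case. An
incomplete position×volume grid (e.g. a deleted slice file) is a hard
assembly error naming the holes, because silently zero-filling an fMRI
volume would corrupt analyses downstream.

Slice spacing is the **median** of consecutive projection differences —
robust to a single displaced slice — and deviations beyond 1% of the median
flag non-uniform spacing as a warning. A single slice falls back to
`SpacingBetweenSlices`, else 1 mm with a warning. The voxel-to-world affine
in LPS has columns `r·Δc`, `c·Δr`, `n·Δs` and translation at the first
slice position; rows 1–2 are negated for RAS. `sform` and `qform` both
carry the affine with code 2 ("aligned"), the combination most downstream
tools accept.

Pixel values keep their integer type (int16 on disk) unless
`RescaleSlope`/`RescaleIntercept` are non-trivial, in which case data
promote to float32. Sidecars hold the BIDS-required-plus-common field set
(`RepetitionTime` and `EchoTime` in seconds, `FlipAngle`, `Manufacturer`,
descriptions, `ImageType`, `EchoNumber` on multi-echo outputs) plus
conversion provenance. Field parity with any particular external converter
is not claimed.

## Byte-stable outputs and idempotency

Idempotency is a testable, byte-level contract here, which pins the output
formats: sidecar JSON is UTF-8, keys sorted, 2-space indent, trailing
newline; TSVs are tab-separated, `n/a` for missing, no quoting, trailing
newline; NIfTI is written via RNifti whose gzip stream carries no
timestamps. Every writer goes through one primitive: write to a temp file,
compare bytes, leave identical files untouched, and treat a differing
existing file as a collision unless `--overwrite`. Dataset-level tables
(`participants.tsv`, `*_scans.tsv`) merge new rows by key and sort, so a
second subject extends rather than rewrites them; the same key with
conflicting content is a merge-conflict error. `acq_time` in scans tables
is ISO 8601 with seconds precision.

## Anonymization

Obfuscation is opt-in (`--anon`). Subject ids map through an operator table
or, when absent, a deterministic keyed 8-hex-digit digest (keyed by
`--seed`; a digest collision is an explicit error asking for a re-key).
Timestamps shift by one **study-constant** whole-day offset, magnitude
uniform in [365, 730] days with a sign, derived deterministically from the
seed and StudyInstanceUID: a constant shift (rather than per-visit jitter)
preserves every pairwise interval and time-of-day exactly, keeping
longitudinal designs analyzable. The discovery-stage seqinfo dump is
scrubbed the same way, and the raw↔released map is written only outside the
output tree — writing it inside is refused.

## The synthetic test bench, and what it does not show

`generateStudy()` writes one DICOM file per (slice, volume, echo) with
consistent UIDs under a reserved fake root, positions marched along a
chosen normal (axial, a supplied rotation, or a seeded random rigid
transform), and small deterministic 16-bit gradients as pixels so
voxel-conservation checks are exact. It records ground truth — affines
computed directly from the rotation it used, dimensions, file counts, and
the BIDS paths its protocol names should produce, the latter derived by an
independent re-implementation of the naming rules. `corruptStudy()` applies
exactly one defect (dropped slice, duplicated instance, scrambled
orientation, displaced slice) to exercise each error branch.

Test problem sizes are deliberately small — 6–8 voxel in-plane matrices,
2–6 slices, up to 3 volumes and 2 echoes, ~50 random geometries in the
acceptance sweep — which exercises every code path while keeping the whole
bench in seconds.

What passing these tests shows: the converter's bookkeeping (grouping,
naming, geometry, splitting, idempotency, anonymization) is exact on
well-formed explicit-VR-little-endian input. What it does not show:
behaviour on vendor-specific reality — mosaics, compressed or implicit-VR
syntaxes, enhanced multi-frame files, gantry-tilted or irregular
acquisitions, missing or mangled tags beyond the modelled corruptions —
nor field-strength-dependent metadata (slice timing, phase-encoding
direction, diffusion tables), all of which are documented non-goals or
extension points.

## Known limitations

* One transfer syntax; no mosaics, multi-frame, or compressed pixel data.
* No bvec/bval extraction, slice-timing, or fieldmap `IntendedFor` wiring.
* The name validator covers the subset of BIDS this tool emits, not the
  full standard.
* The ReproIn fix-up table ships empty.
* Zip archives extract to a workspace directory; nested zips unsupported.
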
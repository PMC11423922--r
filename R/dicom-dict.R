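# The subset of the DICOM data dictionary this pipeline consumes and emits.
# Tags are keyed "GGGG,EEEE" (uppercase hex). Only explicit VR little endian
# (transfer syntax 1.2.840.10008.1.2.1) is supported; that is also the only
# syntax the fixture generator writes.

SUPPORTED_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"
MR_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"

# Reserved fake UID root so generated fixtures can never be mistaken for
# real scanner data.
FIXTURE_UID_ROOT <- "1.3.6.1.4.1.99999.9"

.dicomDict <- local({
  d <- rbind(
    c("0008,0008", "CS", "image_type"),
    c("0008,0016", "UI", "sop_class_uid"),
    c("0008,0018", "UI", "sop_instance_uid"),
    c("0008,0020", "DA", "study_date"),
    c("0008,0030", "TM", "study_time"),
    c("0008,002A", "DT", "acquisition_datetime"),
    c("0008,0060", "CS", "modality"),
    c("0008,0070", "LO", "manufacturer"),
    c("0008,0090", "PN", "referring_physician_name"),
    c("0008,1030", "LO", "study_description"),
    c("0008,103E", "LO", "series_description"),
    c("0010,0010", "PN", "patient_name"),
    c("0010,0020", "LO", "patient_id"),
    c("0018,0024", "SH", "sequence_name"),
    c("0018,0050", "DS", "slice_thickness"),
    c("0018,0080", "DS", "repetition_time"),
    c("0018,0081", "DS", "echo_time"),
    c("0018,0086", "IS", "echo_number"),
    c("0018,0088", "DS", "spacing_between_slices"),
    c("0018,1030", "LO", "protocol_name"),
    c("0018,1314", "DS", "flip_angle"),
    c("0020,000D", "UI", "study_instance_uid"),
    c("0020,000E", "UI", "series_instance_uid"),
    c("0020,0011", "IS", "series_number"),
    c("0020,0012", "IS", "acquisition_number"),
    c("0020,0013", "IS", "instance_number"),
    c("0020,0032", "DS", "image_position_patient"),
    c("0020,0037", "DS", "image_orientation_patient"),
    c("0028,0002", "US", "samples_per_pixel"),
    c("0028,0004", "CS", "photometric_interpretation"),
    c("0028,0010", "US", "rows"),
    c("0028,0011", "US", "columns"),
    c("0028,0030", "DS", "pixel_spacing"),
    c("0028,0100", "US", "bits_allocated"),
    c("0028,0101", "US", "bits_stored"),
    c("0028,0102", "US", "high_bit"),
    c("0028,0103", "US", "pixel_representation"),
    c("0028,1052", "DS", "rescale_intercept"),
    c("0028,1053", "DS", "rescale_slope"),
    c("7FE0,0010", "OW", "pixel_data")
  )
  data.frame(tag = d[, 1], vr = d[, 2], field = d[, 3], stringsAsFactors = FALSE)
})

# Fields that hold multi-valued DS/IS/CS values.
.multiValueFields <- c("image_type", "image_position_patient",
                       "image_orientation_patient", "pixel_spacing")
# Fields converted to numeric on read.
.numericFields <- c("slice_thickness", "repetition_time", "echo_time",
                    "spacing_between_slices", "flip_angle", "rescale_intercept",
                    "rescale_slope", "image_position_patient",
                    "image_orientation_patient", "pixel_spacing")
.integerFields <- c("echo_number", "series_number", "acquisition_number",
                    "instance_number", "samples_per_pixel", "rows", "columns",
                    "bits_allocated", "bits_stored", "high_bit",
                    "pixel_representation")

.tagOf <- function(field) .dicomDict$tag[match(field, .dicomDict$field)]
.vrOf  <- function(field) .dicomDict$vr[match(field, .dicomDict$field)]
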
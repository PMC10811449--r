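# Minimal DICOM data dictionary: the attributes this pipeline reads, writes
# or masks. Unknown tags are still parsed (keyword left empty, VR from the
# stream in explicit transfer syntaxes).

.dcm_dict_raw <- c(
  "0002,0000,UL,FileMetaInformationGroupLength",
  "0002,0001,OB,FileMetaInformationVersion",
  "0002,0002,UI,MediaStorageSOPClassUID",
  "0002,0003,UI,MediaStorageSOPInstanceUID",
  "0002,0010,UI,TransferSyntaxUID",
  "0002,0012,UI,ImplementationClassUID",
  "0008,0005,CS,SpecificCharacterSet",
  "0008,0008,CS,ImageType",
  "0008,0016,UI,SOPClassUID",
  "0008,0018,UI,SOPInstanceUID",
  "0008,0020,DA,StudyDate",
  "0008,0021,DA,SeriesDate",
  "0008,0022,DA,AcquisitionDate",
  "0008,0023,DA,ContentDate",
  "0008,0030,TM,StudyTime",
  "0008,0060,CS,Modality",
  "0008,0070,LO,Manufacturer",
  "0008,0080,LO,InstitutionName",
  "0008,0081,ST,InstitutionAddress",
  "0008,0090,PN,ReferringPhysicianName",
  "0008,1030,LO,StudyDescription",
  "0008,103E,LO,SeriesDescription",
  "0008,1070,PN,OperatorsName",
  "0008,1090,LO,ManufacturerModelName",
  "0008,1115,SQ,ReferencedSeriesSequence",
  "0008,1140,SQ,ReferencedImageSequence",
  "0008,1150,UI,ReferencedSOPClassUID",
  "0008,1155,UI,ReferencedSOPInstanceUID",
  "0010,0010,PN,PatientName",
  "0010,0020,LO,PatientID",
  "0010,0030,DA,PatientBirthDate",
  "0010,0040,CS,PatientSex",
  "0010,1000,LO,OtherPatientIDs",
  "0010,1040,LO,PatientAddress",
  "0010,2154,SH,PatientTelephoneNumbers",
  "0020,000D,UI,StudyInstanceUID",
  "0020,000E,UI,SeriesInstanceUID",
  "0020,0011,IS,SeriesNumber",
  "0020,0013,IS,InstanceNumber",
  "0028,0010,US,Rows",
  "0028,0011,US,Columns",
  "0042,0011,OB,EncapsulatedDocument",
  "0042,0012,LO,MIMETypeOfEncapsulatedDocument",
  "7FE0,0010,OW,PixelData"
)

.dcm_dict <- local({
  parts <- do.call(rbind, strsplit(.dcm_dict_raw, ",", fixed = TRUE))
  d <- data.frame(
    group = strtoi(parts[, 1], 16L),
    element = strtoi(parts[, 2], 16L),
    vr = parts[, 3],
    keyword = parts[, 4],
    stringsAsFactors = FALSE
  )
  d$key <- sprintf("%04X%04X", d$group, d$element)
  d
})

# SOP class UIDs used by the fixtures and the measurement-file rule.
DCM_UID <- list(
  explicit_vr_le = "1.2.840.10008.1.2.1",
  implicit_vr_le = "1.2.840.10008.1.2",
  encapsulated_pdf = "1.2.840.10008.5.1.4.1.1.104.1",
  opt_image = "1.2.840.10008.5.1.4.1.1.77.1.5.4",
  oph_photo = "1.2.840.10008.5.1.4.1.1.77.1.5.1",
  implementation = "1.2.826.0.1.3680043.10.1461.1"
)

dcm_tag_key <- function(group, element) sprintf("%04X%04X", group, element)

dcm_tag_label <- function(group, element) {
  sprintf("(%04X,%04X)", group, element)
}

dcm_lookup <- function(group, element) {
  i <- match(dcm_tag_key(group, element), .dcm_dict$key)
  if (is.na(i)) {
    list(keyword = "", vr = NA_character_)
  } else {
    list(keyword = .dcm_dict$keyword[i], vr = .dcm_dict$vr[i])
  }
}

# Resolve a user-supplied tag spec — keyword ("PatientName"), "(0010,0010)"
# or "00100010" — to c(group, element). Returns NULL when unresolvable.
dcm_resolve_tag <- function(spec) {
  spec <- trimws(spec)
  i <- match(spec, .dcm_dict$keyword)
  if (!is.na(i)) return(c(.dcm_dict$group[i], .dcm_dict$element[i]))
  hex <- toupper(gsub("[^0-9A-Fa-f]", "", spec))
  if (nchar(hex) == 8L) {
    return(c(strtoi(substr(hex, 1, 4), 16L), strtoi(substr(hex, 5, 8), 16L)))
  }
  NULL
}

# VRs whose explicit encoding uses a 12-byte header (2 reserved + 4-byte len)
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                     "PN", "SH", "ST", "TM", "UI", "UT", "UC", "UR")
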
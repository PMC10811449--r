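# Metadata extraction: flatten DICOM datasets to a two-level tag map, pull
# the identifier and image fields the linkage needs, and consolidate
# per-file records into patient and image tables.

#' Flatten a DICOM file to its first two metadata levels
#'
#' Reads a Part-10 file and returns a flat tag map holding every top-level
#' attribute (depth 0) plus the attributes inside top-level sequence items
#' (depth 1). Content nested two or more sequence levels deep is dropped;
#' pixel data is never loaded. When the same tag occurs more than once (for
#' example in repeated sequence items) the first occurrence wins, so tag
#' keys are unique within the map.
#'
#' @param path path to a DICOM Part-10 file.
#' @return a `tag_map`: a data.frame with columns `group`, `element`, `tag`
#'   (printed as `(gggg,eeee)`), `keyword`, `vr`, `depth` and `value`
#'   (character; binary payloads are `NA`).
#' @export
#' @examples
#' \dontrun{
#' tags <- load_dicom_tags("image.dcm")
#' tags[tags$keyword == "PatientName", "value"]
#' }
load_dicom_tags <- function(path) {
  ds <- dcm_read(path, skip_pixel_data = TRUE)
  rows <- list()
  add <- function(el, depth) {
    rows[[length(rows) + 1L]] <<- df(
      group = el$group, element = el$element,
      tag = dcm_tag_label(el$group, el$element),
      keyword = dcm_lookup(el$group, el$element)$keyword,
      vr = el$vr, depth = depth,
      value = .dcm_value_chr(el)
    )
  }
  for (el in ds$elements) {
    add(el, 0L)
    if (identical(el$vr, "SQ")) {
      for (item in el$value) {
        for (sub in item) {
          add(sub, 1L)
          # depth >= 2 (sequences inside items) intentionally not descended
        }
      }
    }
  }
  out <- do.call(rbind, rows) %||% df(
    group = integer(0), element = integer(0), tag = character(0),
    keyword = character(0), vr = character(0), depth = integer(0),
    value = character(0))
  out <- out[!duplicated(sprintf("%04X%04X", out$group, out$element)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tag_map", "data.frame")
  out
}

.dcm_value_chr <- function(el) {
  if (identical(el$vr, "SQ")) return(NA_character_)
  if (is.null(el$value)) return(NA_character_)
  if (is.raw(el$value)) return(NA_character_)
  paste(as.character(el$value), collapse = "\\")
}

#' Parse a DICOM person name (PN) value
#'
#' Splits the caret-delimited PN form `family^given^middle^prefix^suffix`.
#' Missing components come back as empty strings. More than five components
#' is malformed; the first five are kept with a warning.
#'
#' @param pn a PN string (possibly empty).
#' @return named list with `family`, `given`, `middle`, `prefix`, `suffix`.
#' @export
#' @examples
#' parse_person_name("DOE^JOHN^A")
parse_person_name <- function(pn) {
  stopifnot(length(pn) == 1L)
  if (is.na(pn)) pn <- ""
  parts <- strsplit(pn, "^", fixed = TRUE)[[1]]
  if (length(parts) > 5L) {
    warning("person name has more than 5 components; extra components dropped: ",
            pn, call. = FALSE)
    parts <- parts[1:5]
  }
  parts <- c(parts, rep("", 5L - length(parts)))
  stats::setNames(as.list(trimws(parts)),
                  c("family", "given", "middle", "prefix", "suffix"))
}

#' Default image-type mapping table
#'
#' Maps device-reported metadata (Modality, ImageType components, SOP class
#' UID, manufacturer) to the seven ophthalmic image categories plus OTHER.
#' The table is config-driven: rows are tried in order and the first match
#' wins; a field left `NA` in a row matches anything.
#'
#' @return data.frame with columns `modality`, `image_type_contains`,
#'   `sop_class_uid`, `manufacturer_contains`, `category`.
#' @export
default_image_type_map <- function() {
  df(
    modality = c("OPT", "OP", "OP", "OP", "OP", "OP", "OP", NA),
    image_type_contains = c(NA, "FAF", "AUTOFLUORESCENCE", "IR", "COLOR",
                            "FA", "ICGA", "BR"),
    sop_class_uid = c(NA, NA, NA, NA, NA, NA, NA, NA),
    manufacturer_contains = c(NA, NA, NA, NA, NA, NA, NA, NA),
    category = c("OCT", "FAF", "FAF", "IR", "COLOR", "FA", "ICGA", "BR")
  )
}

.classify_image_type <- function(modality, image_type, sop_class_uid,
                                 manufacturer, type_map) {
  up <- function(x) toupper(x %||% "")
  modality <- up(modality); image_type <- up(image_type)
  sop_class_uid <- sop_class_uid %||% ""; manufacturer <- up(manufacturer)
  for (i in seq_len(nrow(type_map))) {
    r <- type_map[i, ]
    ok <- TRUE
    if (!is.na(r$modality)) ok <- ok && identical(modality, r$modality)
    if (ok && !is.na(r$image_type_contains)) {
      ok <- grepl(r$image_type_contains, image_type, fixed = TRUE)
    }
    if (ok && !is.na(r$sop_class_uid)) {
      ok <- identical(sop_class_uid, r$sop_class_uid)
    }
    if (ok && !is.na(r$manufacturer_contains)) {
      ok <- grepl(r$manufacturer_contains, manufacturer, fixed = TRUE)
    }
    if (ok) return(r$category)
  }
  "OTHER"
}

.tag_value <- function(tags, keyword) {
  v <- tags$value[tags$keyword == keyword]
  if (length(v) == 0 || is.na(v[1]) || !nzchar(v[1])) NA_character_ else v[1]
}

#' Extract patient and image records from one tag map
#'
#' Pulls patient-level identifiers (PatientName, PatientID as the MRN,
#' PatientBirthDate, PatientSex) and image-level fields (UIDs, acquisition
#' date, manufacturer, mapped image type) out of a flattened tag map. A
#' missing tag becomes a missing field, never a failure; a missing
#' SOPInstanceUID rejects the record because it cannot be deduplicated or
#' tied to key measurements. Encapsulated-PDF files are flagged as key
#' measurements and carry the referenced SOP instance UID of their source
#' scan.
#'
#' @param tags a `tag_map` from [load_dicom_tags()].
#' @param location_id practice identifier for the archive being walked.
#' @param type_map image-type mapping table ([default_image_type_map()]).
#' @return list with `patient` (one-row data.frame of raw identifier fields)
#'   and `image` (one-row data.frame), or `NULL` with a warning when the
#'   record is rejected.
#' @export
extract_records <- function(tags, location_id,
                            type_map = default_image_type_map()) {
  sop_uid <- .tag_value(tags, "SOPInstanceUID")
  if (is.na(sop_uid)) {
    warning("record rejected: missing SOPInstanceUID", call. = FALSE)
    return(NULL)
  }
  name_raw <- .tag_value(tags, "PatientName")
  parts <- parse_person_name(name_raw %||% NA_character_)
  sop_class <- .tag_value(tags, "SOPClassUID")
  is_meas <- identical(sop_class, DCM_UID$encapsulated_pdf)
  ref_uid <- .tag_value(tags, "ReferencedSOPInstanceUID")
  acq <- .tag_value(tags, "AcquisitionDate")
  if (is.na(acq)) acq <- .tag_value(tags, "ContentDate")
  if (is.na(acq)) acq <- .tag_value(tags, "StudyDate")
  gender_raw <- .tag_value(tags, "PatientSex")
  patient <- df(
    location_id = location_id,
    name_raw = name_raw %||% NA_character_,
    name_family = parts$family, name_given = parts$given,
    name_middle = parts$middle, name_prefix = parts$prefix,
    name_suffix = parts$suffix,
    birthdate = as.character(parse_dicom_date(.tag_value(tags, "PatientBirthDate"))),
    gender = .normalize_gender(gender_raw),
    mrn = .tag_value(tags, "PatientID")
  )
  image <- df(
    sop_instance_uid = sop_uid,
    study_uid = .tag_value(tags, "StudyInstanceUID"),
    series_uid = .tag_value(tags, "SeriesInstanceUID"),
    image_type = if (is_meas) "OTHER" else .classify_image_type(
      .tag_value(tags, "Modality"), .tag_value(tags, "ImageType"),
      sop_class, .tag_value(tags, "Manufacturer"), type_map),
    manufacturer = .tag_value(tags, "Manufacturer"),
    acquisition_date = as.character(parse_dicom_date(acq)),
    is_measurement = is_meas,
    referenced_sop_uid = if (is_meas) ref_uid else NA_character_
  )
  list(patient = patient, image = image)
}

#' Consolidate per-file records into patient and image tables
#'
#' Deduplicates imaging-side patients on `(location_id, name_raw, birthdate,
#' mrn)`, assigns each a stable `patient_key`, computes `last_visit_date` as
#' the patient's newest acquisition date, and counts distinct visits (one
#' calendar acquisition date = one visit). Records identical on the
#' deduplication key but conflicting on gender keep the modal value and log
#' the conflict.
#'
#' @param records list of `list(patient=, image=)` pairs from
#'   [extract_records()] (NULL entries are ignored); or
#'   `list(patient=, image=)` with two row-aligned multi-row tables; or a
#'   pair of tables `list(patients=, images=)` from a previous
#'   consolidation (idempotent).
#' @return list with `patients`, `images` data.frames and `counts`
#'   (`n_patients`, `n_visits`, `n_images`).
#' @export
consolidate_patients <- function(records) {
  if (is.list(records) && !is.null(records$patients)) {
    # consolidated input: re-derive one (patient, image) pair per image row
    # so that re-running the operation is a no-op
    imgs <- records$images
    pats <- records$patients
    if (is.null(imgs$sop_instance_uid)) {
      stop("images table lacks sop_instance_uid", call. = FALSE)
    }
    idx <- match(imgs$patient_key, pats$patient_key)
    if (anyNA(idx)) stop("images reference unknown patient_key", call. = FALSE)
    pat_rows <- pats[idx, c("location_id", "name_raw", "name_family",
                            "name_given", "name_middle", "name_prefix",
                            "name_suffix", "birthdate", "gender", "mrn"),
                     drop = FALSE]
    img_rows <- imgs[, c("sop_instance_uid", "study_uid", "series_uid",
                         "image_type", "manufacturer", "acquisition_date",
                         "is_measurement", "referenced_sop_uid"),
                     drop = FALSE]
  } else if (is.list(records) && !is.null(records$patient) &&
             !is.null(records$image) && is.data.frame(records$patient)) {
    pat_rows <- records$patient
    img_rows <- records$image
    stopifnot(nrow(pat_rows) == nrow(img_rows))
  } else {
    records <- Filter(Negate(is.null), records)
    if (length(records) == 0) {
      return(list(patients = .empty_patients(), images = .empty_images(),
                  counts = list(n_patients = 0L, n_visits = 0L,
                                n_images = 0L)))
    }
    pat_rows <- do.call(rbind, lapply(records, `[[`, "patient"))
    img_rows <- do.call(rbind, lapply(records, `[[`, "image"))
  }
  rownames(pat_rows) <- rownames(img_rows) <- NULL

  dedup_key <- paste(pat_rows$location_id, pat_rows$name_raw,
                     pat_rows$birthdate, pat_rows$mrn, sep = "\r")
  uniq <- !duplicated(dedup_key)
  patients <- pat_rows[uniq, , drop = FALSE]
  key_of <- match(dedup_key, dedup_key[uniq])
  patients$patient_key <- sprintf("P%06d", seq_len(nrow(patients)))
  img_rows$patient_key <- patients$patient_key[key_of]

  # modal gender when duplicate rows disagree
  gender_by <- split(pat_rows$gender, key_of)
  modal <- vapply(gender_by, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_character_)
    tt <- sort(table(g), decreasing = TRUE)
    if (length(tt) > 1) {
      message("gender conflict within a deduplicated patient; keeping modal value")
    }
    names(tt)[1]
  }, character(1))
  patients$gender <- modal[as.character(seq_len(nrow(patients)))]

  # drop duplicate image instances (same SOP instance seen twice)
  img_rows <- img_rows[!duplicated(img_rows$sop_instance_uid), , drop = FALSE]
  rownames(img_rows) <- NULL

  acq <- parse_dicom_date(img_rows$acquisition_date)
  last_visit <- tapply(acq, img_rows$patient_key, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) NA else max(d)
  })
  patients$last_visit_date <- as.character(as.Date(
    as.numeric(last_visit[patients$patient_key]), origin = "1970-01-01"))
  visit_key <- unique(paste(img_rows$patient_key, img_rows$acquisition_date))
  n_visits_by <- table(sub(" .*", "", visit_key))
  patients$n_visits <- as.integer(n_visits_by[patients$patient_key])
  patients$n_visits[is.na(patients$n_visits)] <- 0L
  n_img_by <- table(img_rows$patient_key)
  patients$n_images <- as.integer(n_img_by[patients$patient_key])
  patients$n_images[is.na(patients$n_images)] <- 0L
  rownames(patients) <- NULL

  list(patients = patients, images = img_rows,
       counts = list(n_patients = nrow(patients),
                     n_visits = length(visit_key),
                     n_images = nrow(img_rows)))
}

.empty_patients <- function() {
  df(location_id = character(0), name_raw = character(0),
     name_family = character(0), name_given = character(0),
     name_middle = character(0), name_prefix = character(0),
     name_suffix = character(0), birthdate = character(0),
     gender = character(0), mrn = character(0), patient_key = character(0),
     last_visit_date = character(0), n_visits = integer(0),
     n_images = integer(0))
}

.empty_images <- function() {
  df(sop_instance_uid = character(0), study_uid = character(0),
     series_uid = character(0), image_type = character(0),
     manufacturer = character(0), acquisition_date = character(0),
     is_measurement = logical(0), referenced_sop_uid = character(0),
     patient_key = character(0))
}

#' Walk a directory of DICOM files into consolidated tables
#'
#' Convenience wrapper: applies [load_dicom_tags()] and [extract_records()]
#' to every `.dcm` file under `dir` and consolidates the results.
#'
#' @param dir archive directory (walked recursively).
#' @param location_id practice identifier attached to every record.
#' @param type_map image-type mapping table.
#' @return see [consolidate_patients()].
#' @export
extract_archive <- function(dir, location_id,
                            type_map = default_image_type_map()) {
  files <- list.files(dir, pattern = "\\.dcm$", recursive = TRUE,
                      full.names = TRUE)
  records <- lapply(sort(files), function(f) {
    extract_records(load_dicom_tags(f), location_id, type_map)
  })
  consolidate_patients(records)
}
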
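# Synthetic multi-practice cohort generator with ground truth.
#
# Emulates the kind of archive the pipeline targets: several practices,
# several modalities, many images per visit, per-patient last-visit dates, a
# registry roster sharing a true patient mapping, plus configurable field
# missingness, contaminant "test"/numeric-name patients and abnormal
# birthdates. Everything is reproducible from the seed, and the returned
# ground truth lets every pipeline stage be scored (precision/recall,
# planted-flag audits).

#' Build and validate a synthetic cohort configuration
#'
#' Defaults are chosen to resemble a multi-year two-practice retina archive:
#' about 4.6 imaging visits and 40 image files per patient, an image-type
#' mix dominated by FA/IR/OCT, roughly 4.5% contaminant records (almost all
#' numeric/special-character names), 10% of imaging patients with no
#' registry counterpart (archives predating the registry), and mild
#' per-field missingness concentrated in the MRN.
#'
#' @param n_patients number of imaging-side patients.
#' @param n_locations number of practice locations.
#' @param visits_per_patient `c(mean=, dispersion=)` of a shifted negative
#'   binomial (at least one visit).
#' @param images_per_visit `c(mean=, dispersion=)`, shifted likewise.
#' @param image_type_mix named probability vector over OCT, FAF, IR, COLOR,
#'   FA, ICGA, BR; must sum to 1.
#' @param p_missing named vector: probability that name / birthdate /
#'   gender / mrn is absent from the imaging metadata of a patient.
#' @param p_registry_absent probability an (uncontaminated) imaging patient
#'   has no registry counterpart.
#' @param p_registry_extra registry-only patients, as a fraction of
#'   `n_patients`.
#' @param contamination named vector `p_numeric_name`, `p_abnormal_dob`,
#'   `p_test_name` (mutually exclusive per patient).
#' @param measurement_fraction probability an OCT scan has an encapsulated
#'   key-measurement file referencing its SOP instance UID.
#' @param date_range character vector `c(start, end)` of acquisition dates;
#'   the end is the archive cutoff.
#' @param seed RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_patients = 500L,
    n_locations = 2L,
    visits_per_patient = c(mean = 4.6, dispersion = 1.2),
    images_per_visit = c(mean = 9, dispersion = 1.5),
    image_type_mix = c(OCT = 0.20, FAF = 0.05, IR = 0.27, COLOR = 0.12,
                       FA = 0.34, ICGA = 0.014, BR = 0.006),
    p_missing = c(name = 0.01, birthdate = 0.02, gender = 0.05, mrn = 0.10),
    p_registry_absent = 0.10,
    p_registry_extra = 0.15,
    contamination = c(p_numeric_name = 0.043, p_abnormal_dob = 0.002,
                      p_test_name = 0.0005),
    measurement_fraction = 0.10,
    date_range = c("2014-01-01", "2020-06-01"),
    seed = 20200601L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_locations = as.integer(n_locations),
              visits_per_patient = visits_per_patient,
              images_per_visit = images_per_visit,
              image_type_mix = image_type_mix,
              p_missing = p_missing,
              p_registry_absent = p_registry_absent,
              p_registry_extra = p_registry_extra,
              contamination = contamination,
              measurement_fraction = measurement_fraction,
              date_range = as.Date(date_range),
              seed = as.integer(seed))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$n_locations < 1L) stop("n_locations must be >= 1", call. = FALSE)
  if (abs(sum(cfg$image_type_mix) - 1) > 1e-8) {
    stop("image_type_mix must sum to 1", call. = FALSE)
  }
  probs <- c(cfg$p_missing, cfg$p_registry_absent, cfg$p_registry_extra,
             cfg$contamination, cfg$measurement_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sum(cfg$contamination) > 1) {
    stop("contamination probabilities must sum to at most 1", call. = FALSE)
  }
  if (cfg$date_range[1] > cfg$date_range[2]) {
    stop("date_range start must not exceed end", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

.rnb_shift <- function(n, spec) {
  mu <- max(spec[["mean"]] - 1, 0)
  1L + stats::rnbinom(n, size = spec[["dispersion"]], mu = mu)
}

#' Generate a synthetic imaging archive and registry roster
#'
#' Draws a cohort per the configuration and returns the per-instance imaging
#' metadata table (one row per DICOM file, scans and key-measurement
#' documents alike), the registry roster, and the ground truth. Imaging rows
#' are grouped by patient in patient order, so [consolidate_patients()]
#' reassigns exactly the patient keys recorded in the truth. Contaminated
#' patients (numeric/special names, abnormal birthdates, "test" names) have
#' no registry counterpart; uncontaminated patients lack one with
#' probability `p_registry_absent`.
#'
#' @param config a `synthetic_config`.
#' @return list with `imaging` (instance-level metadata table), `registry`,
#'   and `truth` (`true_links`, `planted_flags`, `planted_diagnoses`,
#'   `counts`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_patients
  locs <- sprintf("L%02d", seq_len(config$n_locations))
  location <- sample(locs, n, replace = TRUE)

  # identities; regenerate until (name, dob) unique within location and MRN
  # unique overall
  fam <- sample(.syn_surnames, n, replace = TRUE)
  giv <- sample(.syn_given, n, replace = TRUE)
  mid <- ifelse(stats::runif(n) < 0.3, sample(LETTERS, n, replace = TRUE), "")
  suf <- ifelse(stats::runif(n) < 0.05,
                sample(.syn_suffixes, n, replace = TRUE), "")
  dob <- as.Date("1920-01-01") +
    sample.int(as.integer(as.Date("2005-12-31") - as.Date("1920-01-01")),
               n, replace = TRUE)
  for (it in 1:100) {
    key <- paste(location, fam, giv, mid, suf, dob)
    dup <- duplicated(key)
    if (!any(dup)) break
    k <- which(dup)
    fam[k] <- sample(.syn_surnames, length(k), replace = TRUE)
    giv[k] <- sample(.syn_given, length(k), replace = TRUE)
    dob[k] <- as.Date("1920-01-01") +
      sample.int(31000L, length(k), replace = TRUE)
  }
  gender <- sample(c("M", "F"), n, replace = TRUE)
  mrn_int <- sample.int(9999999L, n)
  mrn_img <- sprintf("%08d", mrn_int)        # imaging side keeps zero-padding
  mrn_reg <- as.character(mrn_int)           # registry stores it bare

  # contamination (mutually exclusive per patient)
  u <- stats::runif(n)
  p1 <- config$contamination[["p_numeric_name"]]
  p2 <- p1 + config$contamination[["p_abnormal_dob"]]
  p3 <- p2 + config$contamination[["p_test_name"]]
  contam <- rep(NA_character_, n)
  contam[u < p1] <- "NAME_NUMERIC_OR_SPECIAL"
  contam[u >= p1 & u < p2] <- "ABNORMAL_DOB"
  contam[u >= p2 & u < p3] <- "TEST_NAME"

  sel <- which(contam == "NAME_NUMERIC_OR_SPECIAL")
  if (length(sel)) {
    deco <- sample(c("2", "3", "9", "#", "*", "@"), length(sel),
                   replace = TRUE)
    fam[sel] <- paste0(fam[sel], deco)
  }
  sel <- which(contam == "ABNORMAL_DOB")
  if (length(sel)) {
    early <- stats::runif(length(sel)) < 0.8
    dob[sel] <- as.Date(ifelse(
      early,
      as.Date("1850-01-01") + sample.int(18000L, length(sel), replace = TRUE),
      config$date_range[2] + sample.int(300L, length(sel), replace = TRUE)),
      origin = "1970-01-01")
  }
  sel <- which(contam == "TEST_NAME")
  if (length(sel)) {
    fam[sel] <- "TEST"
    giv[sel] <- sample(c("PATIENT", "ACCOUNT", "SCANNER"), length(sel),
                       replace = TRUE)
    mid[sel] <- ""; suf[sel] <- ""
  }

  linkable <- is.na(contam) & stats::runif(n) >= config$p_registry_absent

  # imaging-side missingness (per patient; contaminated rows stay complete
  # so planted flags remain exactly auditable)
  miss_ok <- is.na(contam)
  miss_name <- miss_ok & stats::runif(n) < config$p_missing[["name"]]
  miss_dob <- miss_ok & stats::runif(n) < config$p_missing[["birthdate"]]
  miss_sex <- miss_ok & stats::runif(n) < config$p_missing[["gender"]]
  miss_mrn <- miss_ok & stats::runif(n) < config$p_missing[["mrn"]]

  pn_raw <- paste0(fam, "^", giv,
                   ifelse(nzchar(mid) | nzchar(suf), paste0("^", mid), ""),
                   ifelse(nzchar(suf), paste0("^^", suf), ""))
  img_name_raw <- ifelse(miss_name, NA_character_, pn_raw)
  img_dob <- ifelse(miss_dob, NA_character_, as.character(dob))
  img_sex <- ifelse(miss_sex, NA_character_, gender)
  img_mrn <- ifelse(miss_mrn, NA_character_, mrn_img)

  # ensure the consolidation key (location, name_raw, dob, mrn) stays unique
  # after missingness so consolidated counts match the truth exactly
  ck <- paste(location, img_name_raw, img_dob, img_mrn)
  for (it in 1:100) {
    dup <- duplicated(ck)
    if (!any(dup)) break
    k <- which(dup)
    miss_mrn[k] <- FALSE
    img_mrn[k] <- mrn_img[k]
    ck <- paste(location, img_name_raw, img_dob, img_mrn)
  }

  patient_key <- sprintf("P%06d", seq_len(n))

  # visits and images
  n_visits <- .rnb_shift(n, config$visits_per_patient)
  all_days <- seq(config$date_range[1], config$date_range[2], by = "day")
  n_visits <- pmin(n_visits, length(all_days))
  visit_dates <- lapply(n_visits, function(v) sort(sample(all_days, v)))
  visit_pat <- rep(seq_len(n), n_visits)
  visit_date <- as.Date(unlist(visit_dates), origin = "1970-01-01")
  nv <- length(visit_pat)
  visit_id <- seq_len(nv)

  n_img <- .rnb_shift(nv, config$images_per_visit)
  img_visit <- rep(visit_id, n_img)
  ni <- length(img_visit)
  types <- sample(names(config$image_type_mix), ni, replace = TRUE,
                  prob = config$image_type_mix)
  img_pat <- visit_pat[img_visit]
  manuf <- ifelse(types %in% c("OCT", "BR"), "Heidelberg Engineering",
                  ifelse(types == "COLOR", "Optos",
                         ifelse(stats::runif(ni) < 0.7,
                                "Heidelberg Engineering", "Optos")))

  uid_base <- sprintf("1.2.826.0.1.3680043.9.7433.%d", config$seed %% 10000L)
  sop_uid <- sprintf("%s.1.%d", uid_base, seq_len(ni))
  study_uid <- sprintf("%s.2.%d", uid_base, img_visit)
  series_key <- paste(img_visit, types)
  series_uid <- sprintf("%s.3.%d", uid_base,
                        match(series_key, unique(series_key)))

  scans <- df(
    patient_key = patient_key[img_pat],
    location_id = location[img_pat],
    name_raw = img_name_raw[img_pat],
    birthdate = img_dob[img_pat],
    gender = img_sex[img_pat],
    mrn = img_mrn[img_pat],
    sop_instance_uid = sop_uid,
    study_uid = study_uid,
    series_uid = series_uid,
    image_type = types,
    manufacturer = manuf,
    acquisition_date = as.character(visit_date[img_visit]),
    is_measurement = FALSE,
    referenced_sop_uid = NA_character_
  )

  # key-measurement documents for a fraction of OCT scans
  oct_idx <- which(types == "OCT" &
                     stats::runif(ni) < config$measurement_fraction)
  meas <- if (length(oct_idx)) {
    m <- scans[oct_idx, , drop = FALSE]
    m$sop_instance_uid <- sprintf("%s.4.%d", uid_base, seq_along(oct_idx))
    m$series_uid <- sprintf("%s.5.%d", uid_base,
                            match(m$study_uid, unique(m$study_uid)))
    m$image_type <- "OTHER"
    m$is_measurement <- TRUE
    m$referenced_sop_uid <- scans$sop_instance_uid[oct_idx]
    m
  } else NULL
  imaging <- rbind(scans, meas)
  imaging <- imaging[order(match(imaging$patient_key, patient_key),
                           imaging$sop_instance_uid), , drop = FALSE]
  rownames(imaging) <- NULL

  # registry roster: counterparts for linkable patients + registry-only rows
  reg_rows <- which(linkable)
  n_extra <- as.integer(round(config$p_registry_extra * n))
  extra_fam <- sample(.syn_surnames, n_extra, replace = TRUE)
  extra_giv <- sample(.syn_given, n_extra, replace = TRUE)
  extra_dob <- as.Date("1920-01-01") + sample.int(31000L, n_extra,
                                                  replace = TRUE)
  extra_loc <- sample(locs, n_extra, replace = TRUE)
  n_reg <- length(reg_rows) + n_extra
  registry_id <- sprintf("R%06d", seq_len(n_reg))
  second_loc <- stats::runif(length(reg_rows)) < 0.10
  reg_locs <- vapply(seq_along(reg_rows), function(i) {
    ls <- location[reg_rows[i]]
    if (second_loc[i] && config$n_locations > 1L) {
      ls <- c(ls, sample(setdiff(locs, ls), 1L))
    }
    join_multi(ls)
  }, character(1))
  registry <- df(
    registry_id = registry_id,
    location_ids = c(reg_locs, extra_loc),
    name_family = c(fam[reg_rows], extra_fam),
    name_given = c(giv[reg_rows], extra_giv),
    name_middle = c(mid[reg_rows], rep("", n_extra)),
    name_suffix = c(suf[reg_rows], rep("", n_extra)),
    name_raw = NA_character_,
    birthdate = as.character(c(dob[reg_rows], extra_dob)),
    gender = c(ifelse(gender[reg_rows] == "F", "Female", "Male"),
               sample(c("Female", "Male"), n_extra, replace = TRUE)),
    mrn = c(mrn_reg[reg_rows],
            as.character(9999999L + sample.int(10000000L, n_extra)))
  )

  # planted diagnoses
  icd_map <- yaml::read_yaml(system.file("extdata", "icd_map.yaml",
                                         package = "oculink"))
  labels <- names(icd_map)
  n_dx <- stats::rpois(n_reg, 1.0)
  planted_dx <- lapply(n_dx, function(k) {
    sort(sample(labels, min(k, length(labels))))
  })
  registry$icd_codes <- vapply(planted_dx, function(ls) {
    join_multi(unlist(lapply(ls, function(l) {
      cs <- unlist(icd_map[[l]])
      sample(cs, min(2L, length(cs)))
    })))
  }, character(1))

  true_links <- stats::setNames(rep(NA_character_, n), patient_key)
  true_links[reg_rows] <- registry_id[seq_along(reg_rows)]

  n_visits_total <- nv
  linkable_imgs <- sum(imaging$patient_key %in% patient_key[linkable])
  truth <- list(
    true_links = true_links,
    planted_flags = stats::setNames(contam, patient_key),
    planted_diagnoses = stats::setNames(planted_dx, registry_id),
    counts = list(
      n_patients = n,
      n_visits = n_visits_total,
      n_images = nrow(imaging),
      n_scans = nrow(scans),
      n_measurements = nrow(imaging) - nrow(scans),
      n_linkable_patients = sum(linkable),
      n_linkable_images = linkable_imgs,
      n_contaminated = sum(!is.na(contam)),
      n_registry = n_reg
    )
  )
  list(imaging = imaging, registry = registry, truth = truth)
}

#' Convert an instance-level metadata table to pipeline record pairs
#'
#' Turns each row of a metadata table (one row per DICOM instance, as
#' produced by [generate_cohort()] or read from CSV) into the
#' (patient, image) record pair that [extract_records()] would produce from
#' the corresponding file, then consolidates.
#'
#' @param tab instance-level metadata table.
#' @return see [consolidate_patients()].
#' @export
consolidate_metadata_table <- function(tab) {
  n <- nrow(tab)
  parts <- lapply(ifelse(is.na(tab$name_raw), "", tab$name_raw),
                  parse_person_name)
  pat <- df(
    location_id = tab$location_id,
    name_raw = tab$name_raw,
    name_family = vapply(parts, `[[`, "", "family"),
    name_given = vapply(parts, `[[`, "", "given"),
    name_middle = vapply(parts, `[[`, "", "middle"),
    name_prefix = vapply(parts, `[[`, "", "prefix"),
    name_suffix = vapply(parts, `[[`, "", "suffix"),
    birthdate = as.character(tab$birthdate),
    gender = .normalize_gender(tab$gender),
    mrn = tab$mrn
  )
  img <- df(
    sop_instance_uid = tab$sop_instance_uid,
    study_uid = tab$study_uid,
    series_uid = tab$series_uid,
    image_type = tab$image_type,
    manufacturer = tab$manufacturer,
    acquisition_date = as.character(tab$acquisition_date),
    is_measurement = as.logical(tab$is_measurement),
    referenced_sop_uid = tab$referenced_sop_uid
  )
  consolidate_patients(list(patient = pat, image = img))
}

#' Write the generated metadata as DICOM Part-10 fixture files
#'
#' One minimal but standards-valid file per imaging row: patient, study,
#' series and image tags, a small pixel payload for scans, an encapsulated
#' document payload plus the referenced-scan sequence for key-measurement
#' rows, and on every file a top-level sequence containing a nested
#' sub-sequence so the two-level extraction rule is exercised (the nested
#' attribute must never surface in a tag map).
#'
#' @param imaging instance-level metadata table ([generate_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param pixel_bytes size of the dummy pixel payload per scan.
#' @return manifest data.frame (`path`, `sop_instance_uid`), invisibly.
#' @export
emit_dicom_fixtures <- function(imaging, out_dir, pixel_bytes = 64L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  paths <- character(nrow(imaging))
  for (i in seq_len(nrow(imaging))) {
    row <- imaging[i, ]
    els <- list(
      dcm_el("SOPInstanceUID", row$sop_instance_uid),
      dcm_el("StudyInstanceUID", row$study_uid),
      dcm_el("SeriesInstanceUID", row$series_uid),
      dcm_el("StudyDate", format(as.Date(row$acquisition_date), "%Y%m%d")),
      dcm_el("AcquisitionDate",
             format(as.Date(row$acquisition_date), "%Y%m%d")),
      dcm_el("Manufacturer", row$manufacturer),
      # top-level sequence with a nested sub-sequence: the inner
      # ReferencedSOPInstanceUID sits at depth 2 and must be dropped
      dcm_sq("ReferencedSeriesSequence", list(list(
        dcm_el("SeriesInstanceUID", row$series_uid),
        dcm_sq("ReferencedImageSequence", list(list(
          dcm_el("ReferencedSOPClassUID", DCM_UID$oph_photo),
          dcm_el("ReferencedSOPInstanceUID", "9.9.9.9.NESTED")
        )))
      )))
    )
    if (!is.na(row$name_raw)) els <- c(els, list(dcm_el("PatientName",
                                                        row$name_raw)))
    if (!is.na(row$mrn)) els <- c(els, list(dcm_el("PatientID", row$mrn)))
    if (!is.na(row$birthdate)) {
      els <- c(els, list(dcm_el("PatientBirthDate",
                                format(as.Date(row$birthdate), "%Y%m%d"))))
    }
    if (!is.na(row$gender)) els <- c(els, list(dcm_el("PatientSex",
                                                      row$gender)))
    if (isTRUE(row$is_measurement)) {
      els <- c(els, list(
        dcm_el("SOPClassUID", DCM_UID$encapsulated_pdf),
        dcm_el("Modality", "DOC"),
        dcm_el("MIMETypeOfEncapsulatedDocument", "application/pdf"),
        dcm_el("EncapsulatedDocument", charToRaw("%PDF-1.4 synthetic")),
        dcm_sq("ReferencedImageSequence", list(list(
          dcm_el("ReferencedSOPClassUID", DCM_UID$opt_image),
          dcm_el("ReferencedSOPInstanceUID", row$referenced_sop_uid)
        )))
      ))
    } else {
      modality <- if (row$image_type == "OCT") "OPT" else "OP"
      els <- c(els, list(
        dcm_el("SOPClassUID",
               if (row$image_type == "OCT") DCM_UID$opt_image
               else DCM_UID$oph_photo),
        dcm_el("Modality", modality),
        dcm_el("ImageType", c("ORIGINAL", "PRIMARY", row$image_type)),
        dcm_el("Rows", 8L), dcm_el("Columns", 8L),
        dcm_el("PixelData", raw(pixel_bytes))
      ))
    }
    p <- file.path(out_dir, paste0("img_", sprintf("%06d", i), ".dcm"))
    dcm_write(els, p)
    paths[i] <- p
  }
  invisible(df(path = paths, sop_instance_uid = imaging$sop_instance_uid))
}

#' Score a link result against the generator's ground truth
#'
#' Precision is the fraction of emitted links that agree with the true
#' mapping; recall is the fraction of truly linkable patients recovered.
#' Registry-absent patients correctly left unlinked count as true
#' negatives.
#'
#' @param result a `link_result`.
#' @param truth ground truth from [generate_cohort()].
#' @return list with `precision`, `recall`, `f1` and confusion counts
#'   (`tp`, `fp`, `fn`, `tn`).
#' @export
evaluate_linkage <- function(result, truth) {
  tl <- truth$true_links
  keys <- result$links$patient_key
  if (!all(keys %in% names(tl))) {
    stop("link result contains patient keys unknown to the ground truth",
         call. = FALSE)
  }
  correct <- !is.na(tl[keys]) & tl[keys] == result$links$registry_id
  tp <- sum(correct)
  fp <- sum(!correct)
  n_linkable <- sum(!is.na(tl))
  fn <- n_linkable - tp
  tn <- sum(is.na(tl)) - sum(!correct & is.na(tl[keys]))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (n_linkable > 0) tp / n_linkable else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
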
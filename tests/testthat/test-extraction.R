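# Field extraction from tag maps and consolidation into patient/image tables.

make_tags <- function(...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  p <- file.path(dir, "t.dcm")
  dcm_write(list(...), p)
  load_dicom_tags(p)
}

test_that("missing identifier tags become missing fields, not failures", {
  tags <- make_tags(
    oculink:::dcm_el("SOPClassUID", oculink:::DCM_UID$oph_photo),
    oculink:::dcm_el("SOPInstanceUID", "1.2.3.1"),
    oculink:::dcm_el("PatientName", "DOE^JANE")
  )
  rec <- extract_records(tags, "L01")
  expect_true(is.na(rec$patient$gender))
  expect_true(is.na(rec$patient$birthdate))
  expect_true(is.na(rec$patient$mrn))
  expect_identical(rec$patient$name_family, "DOE")
  expect_identical(rec$image$sop_instance_uid, "1.2.3.1")
})

test_that("encapsulated-PDF SOP class marks a key-measurement record", {
  tags <- make_tags(
    oculink:::dcm_el("SOPClassUID", oculink:::DCM_UID$encapsulated_pdf),
    oculink:::dcm_el("SOPInstanceUID", "1.2.3.2"),
    oculink:::dcm_sq("ReferencedImageSequence", list(list(
      oculink:::dcm_el("ReferencedSOPInstanceUID", "1.2.3.99")
    )))
  )
  rec <- extract_records(tags, "L01")
  expect_true(rec$image$is_measurement)
  expect_identical(rec$image$referenced_sop_uid, "1.2.3.99")
})

test_that("modality drives the image-type category mapping", {
  mk <- function(modality, itype) {
    make_tags(
      oculink:::dcm_el("SOPClassUID", oculink:::DCM_UID$oph_photo),
      oculink:::dcm_el("SOPInstanceUID", paste0("1.9.", modality, itype)),
      oculink:::dcm_el("Modality", modality),
      oculink:::dcm_el("ImageType", c("ORIGINAL", "PRIMARY", itype))
    )
  }
  expect_identical(extract_records(mk("OPT", "X"), "L")$image$image_type,
                   "OCT")
  expect_identical(extract_records(mk("OP", "FAF"), "L")$image$image_type,
                   "FAF")
  expect_identical(extract_records(mk("OP", "FA"), "L")$image$image_type,
                   "FA")
  expect_identical(extract_records(mk("XC", "ZZZ"), "L")$image$image_type,
                   "OTHER")
})

test_that("a record without SOPInstanceUID is rejected with a warning", {
  tags <- make_tags(
    oculink:::dcm_el("SOPClassUID", oculink:::DCM_UID$oph_photo),
    oculink:::dcm_el("PatientName", "DOE^JANE")
  )
  expect_warning(rec <- extract_records(tags, "L01"), "SOPInstanceUID")
  expect_null(rec)
})

test_that("one identity seen in three files over two dates gives 1/2/3", {
  pat <- function() data.frame(
    location_id = "L01", name_raw = "DOE^JANE", name_family = "DOE",
    name_given = "JANE", name_middle = "", name_prefix = "",
    name_suffix = "", birthdate = "1950-01-01", gender = "F",
    mrn = "42", stringsAsFactors = FALSE)
  img <- function(uid, date) data.frame(
    sop_instance_uid = uid, study_uid = "s", series_uid = "se",
    image_type = "OCT", manufacturer = "m", acquisition_date = date,
    is_measurement = FALSE, referenced_sop_uid = NA_character_,
    stringsAsFactors = FALSE)
  cons <- consolidate_patients(list(
    list(patient = pat(), image = img("u1", "2020-01-01")),
    list(patient = pat(), image = img("u2", "2020-01-01")),
    list(patient = pat(), image = img("u3", "2020-03-05"))))
  expect_equal(cons$counts, list(n_patients = 1L, n_visits = 2L,
                                 n_images = 3L))
  expect_identical(cons$patients$last_visit_date, "2020-03-05")
  expect_equal(cons$patients$n_images, 3L)
})

test_that("consolidation of empty input yields empty tables", {
  cons <- consolidate_patients(list())
  expect_equal(cons$counts$n_patients, 0L)
  expect_equal(nrow(cons$patients), 0L)
  expect_equal(nrow(cons$images), 0L)
})

test_that("consolidation is idempotent and conserves image counts", {
  coh <- small_cohort(n = 40, seed = 21)
  cons <- consolidate_metadata_table(coh$imaging)
  again <- consolidate_patients(cons)
  expect_identical(cons$patients, again$patients)
  expect_identical(cons$images, again$images)
  expect_identical(cons$counts, again$counts)
  expect_equal(sum(cons$patients$n_images), nrow(cons$images))
})

test_that("consolidated counts equal the generator's ground truth", {
  coh <- small_cohort(n = 80, seed = 22)
  cons <- consolidate_metadata_table(coh$imaging)
  expect_equal(cons$counts$n_patients, coh$truth$counts$n_patients)
  expect_equal(cons$counts$n_visits, coh$truth$counts$n_visits)
  expect_equal(cons$counts$n_images, coh$truth$counts$n_images)
  # key alignment: the reconstructed identity behind each key matches
  expect_identical(cons$patients$patient_key,
                   names(coh$truth$true_links))
})

test_that("archive walking matches table-driven consolidation", {
  coh <- small_cohort(n = 4, seed = 23,
                      visits_per_patient = c(mean = 1.5, dispersion = 2),
                      images_per_visit = c(mean = 2, dispersion = 2))
  imaging <- coh$imaging[coh$imaging$location_id ==
                           coh$imaging$location_id[1], ]
  dir <- withr::local_tempdir()
  emit_dicom_fixtures(imaging, dir)
  from_files <- extract_archive(dir, imaging$location_id[1])
  from_table <- consolidate_metadata_table(imaging)
  cols <- c("location_id", "name_raw", "birthdate", "gender", "mrn",
            "last_visit_date", "n_visits", "n_images")
  expect_equal(from_files$patients[, cols], from_table$patients[, cols])
  expect_setequal(from_files$images$sop_instance_uid,
                  from_table$images$sop_instance_uid)
})
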
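# Rates, cohort diagram, strata and diagnosis cohorts.

test_that("rates use half-up rounding at the requested precision", {
  expect_equal(compute_rate(445163, 468767, 2), 94.96)
  expect_equal(compute_rate(46196, 54896, 1), 84.2)
  expect_equal(compute_rate(0, 100, 2), 0)
  expect_equal(compute_rate(1, 800, 2), 0.13)   # 0.125 rounds up
  expect_equal(compute_rate(1, 3, 2), 33.33)
  expect_error(compute_rate(1, 0), "total")
  expect_error(compute_rate(5, 3), "linked")
  # scale invariance
  for (k in c(2, 7, 100)) {
    expect_equal(compute_rate(k * 31, k * 97, 2), compute_rate(31, 97, 2))
  }
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(84.15, 1), 84.2)
})

test_that("cleaned rates deduct exclusions from the denominator only", {
  rep <- cohort_diagram_from_counts(
    total_patients = 54896, linked_patients = 46196,
    total_images = 2287839, linked_images = 1937864,
    excluded_patients_by_flag = c(NAME_NUMERIC_OR_SPECIAL = 2365,
                                  ABNORMAL_DOB = 118, TEST_NAME = 17),
    excluded_images_by_flag = c(NAME_NUMERIC_OR_SPECIAL = 207628,
                                ABNORMAL_DOB = 3447, TEST_NAME = 456))
  expect_equal(rep$cleaned_patient_denominator, 52396)
  expect_equal(rep$initial_patient_rate_pct, 84.2)
  expect_equal(rep$initial_image_rate_pct, 84.7)
  expect_equal(rep$cleaned_patient_rate_pct, 88.2)
  expect_equal(rep$cleaned_image_rate_pct, 93.3)
  # no exclusions: cleaned equals initial
  rep0 <- cohort_diagram_from_counts(100, 84, 1000, 847)
  expect_equal(rep0$cleaned_patient_rate_pct, rep0$initial_patient_rate_pct)
  expect_equal(rep0$cleaned_image_rate_pct, rep0$initial_image_rate_pct)
})

test_that("cohort diagram on synthetic data matches ground truth exactly", {
  coh <- small_cohort(n = 300, seed = 81)
  lk <- run_linkage(coh)
  images <- link_images(lk$result, lk$images)
  rep <- build_cohort_diagram(lk$patients, images, lk$result)
  expect_equal(rep$total_patients, coh$truth$counts$n_patients)
  expect_equal(rep$total_images, coh$truth$counts$n_images)
  planted <- table(coh$truth$planted_flags)
  for (f in names(planted)) {
    expect_equal(rep$excluded_patients_by_flag[[f]],
                 as.integer(planted[[f]]))
  }
  # partition invariant
  expect_equal(sum(unlist(rep$excluded_patients_by_flag)) +
                 rep$cleaned_patient_denominator,
               rep$total_patients)
  # report agrees with the truth-aware evaluator on what got linked
  ev <- evaluate_linkage(lk$result, coh$truth)
  expect_equal(rep$linked_patients, ev$tp + ev$fp)
})

test_that("year strata partition all dated images and use 2 decimals", {
  coh <- small_cohort(n = 150, seed = 82)
  lk <- run_linkage(coh)
  images <- link_images(lk$result, lk$images)
  tab <- stratify_report(lk$result, lk$patients, images,
                         by = "last_visit_year")
  expect_equal(sum(tab$total_count), nrow(images))
  expect_equal(sum(tab$linked_count), sum(images$linked))
  expect_true(all(tab$linked_count <= tab$total_count))
  expect_true(all(grepl("^\\d{4}-\\d{4}$", tab$stratum_label)))
  # all images of one patient land in the stratum of that patient's last visit
  pk <- lk$patients$patient_key[which.max(lk$patients$n_images)]
  expect_equal(tab$rate_pct, round_half_up(tab$rate_pct, 2))
})

test_that("a patient imaged with several modalities counts in each stratum", {
  pat <- data.frame(patient_key = c("P1", "P2"),
                    last_visit_date = c("2020-01-01", "2020-01-01"),
                    stringsAsFactors = FALSE)
  img <- function(uid, key, type) data.frame(
    sop_instance_uid = uid, patient_key = key, image_type = type,
    acquisition_date = "2020-01-01", is_measurement = FALSE,
    stringsAsFactors = FALSE)
  images <- rbind(img("u1", "P1", "OCT"), img("u2", "P1", "FAF"),
                  img("u3", "P1", "OCT"), img("u4", "P2", "OCT"),
                  img("u5", "P2", "OTHER"))
  res <- structure(list(links = data.frame(patient_key = "P1",
                                           registry_id = "R1", rules = "R1",
                                           weight = 1,
                                           stringsAsFactors = FALSE),
                        unlinked_patient_keys = "P2",
                        unlinked_registry_ids = character(0),
                        mode = "max_cardinality"), class = "link_result")
  tab <- stratify_report(res, pat, images, by = "image_type")
  expect_equal(tab$total_count[tab$stratum_label == "OCT"], 2L)
  expect_equal(tab$linked_count[tab$stratum_label == "OCT"], 1L)
  expect_equal(tab$rate_pct[tab$stratum_label == "OCT"], 50)
  expect_equal(tab$total_count[tab$stratum_label == "FAF"], 1L)
  # OTHER images get a stratum instead of being dropped
  expect_true("OTHER" %in% tab$stratum_label)
  # single stratum sanity: 9 of 10 linked -> 90.00
  expect_equal(compute_rate(9, 10, 2), 90)
})

test_that("diagnosis cohorts count planted members with all their imaging", {
  coh <- small_cohort(n = 200, seed = 83)
  lk <- run_linkage(coh)
  icd_map <- yaml::read_yaml(system.file("extdata", "icd_map.yaml",
                                         package = "oculink"))
  tab <- diagnosis_cohorts(lk$result, lk$registry, lk$patients, lk$images,
                           icd_map)
  planted <- coh$truth$planted_diagnoses
  linked <- lk$result$links
  for (label in names(icd_map)) {
    member_reg <- names(planted)[vapply(planted, function(ls) {
      label %in% ls
    }, logical(1))]
    keys <- linked$patient_key[linked$registry_id %in% member_reg]
    row <- tab[tab$diagnosis_label == label, ]
    expect_equal(row$unique_patients, length(keys))
    sel <- lk$patients$patient_key %in% keys
    expect_equal(row$unique_visits, sum(lk$patients$n_visits[sel]))
    expect_equal(row$unique_images, sum(lk$patients$n_images[sel]))
  }
  # membership is patient-level: multi-diagnosis patients appear repeatedly
  n_members <- sum(tab$unique_patients)
  n_distinct <- length(unique(linked$patient_key[
    linked$registry_id %in% names(planted)[lengths(planted) > 0]]))
  expect_gte(n_members, n_distinct)
  # an empty code set yields a zero row with a warning
  expect_warning(
    tab0 <- diagnosis_cohorts(lk$result, lk$registry, lk$patients,
                              lk$images, list(nothing = character(0))),
    "empty ICD")
  expect_equal(tab0$unique_patients, 0L)
})
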
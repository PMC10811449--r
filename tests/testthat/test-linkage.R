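# The four linkage rules, blocking, one-to-one resolution and propagation.

img_id <- function(...) {
  base <- list(location_id = "L01", name_norm = "DOE JANE",
               birthdate = "1950-01-01", gender = "F", mrn_norm = "42")
  utils::modifyList(base, list(...))
}
reg_id <- function(...) {
  base <- list(location_id = "L01", name_norm = "DOE JANE",
               birthdate = "1950-01-01", gender = "F", mrn_norm = "42")
  utils::modifyList(base, list(...))
}

test_that("rules require presence and equality of every field", {
  expect_true(rule_satisfied(img_id(), reg_id(), "R1"))
  expect_false(rule_satisfied(img_id(mrn_norm = NA), reg_id(), "R3"))
  expect_false(rule_satisfied(img_id(gender = "M"), reg_id(), "R2"))
  expect_true(rule_satisfied(img_id(gender = NA), reg_id(), "R1"))
  expect_false(rule_satisfied(img_id(location_id = "L02"), reg_id(), "R1"))
  # registry multi-location membership
  expect_true(rule_satisfied(img_id(location_id = "L02"),
                             reg_id(location_id = "L01|L02"), "R4"))
  # R2 does not need the MRN
  expect_true(rule_satisfied(img_id(mrn_norm = NA), reg_id(), "R2"))
})

test_that("an edge records the union of satisfied rules", {
  pat <- data.frame(patient_key = "P1", location_id = "L01",
                    name_norm = "DOE JANE", birthdate = "1950-01-01",
                    gender = NA_character_, mrn_norm = "42",
                    stringsAsFactors = FALSE)
  reg <- data.frame(registry_id = "R1", location_ids = "L01",
                    name_norm = "DOE JANE", birthdate = "1950-01-01",
                    gender = "F", mrn_norm = "42", stringsAsFactors = FALSE)
  edges <- build_candidate_edges(pat, reg)
  # gender missing on the imaging side: R1, R3, R4 hold, R2 does not
  expect_equal(nrow(edges), 1L)
  expect_identical(edges$rules, "R1+R3+R4")
  expect_equal(edges$weight, 3)
})

test_that("pairs at different locations never form an edge", {
  pat <- data.frame(patient_key = "P1", location_id = "L09",
                    name_norm = "DOE JANE", birthdate = "1950-01-01",
                    gender = "F", mrn_norm = "42", stringsAsFactors = FALSE)
  reg <- data.frame(registry_id = "R1", location_ids = "L01",
                    name_norm = "DOE JANE", birthdate = "1950-01-01",
                    gender = "F", mrn_norm = "42", stringsAsFactors = FALSE)
  expect_equal(nrow(build_candidate_edges(pat, reg)), 0L)
})

test_that("blocked edge construction equals all-pairs evaluation", {
  for (seed in c(51, 52)) {
    coh <- generate_cohort(synthetic_config(
      n_patients = 150, seed = seed, n_locations = 3,
      p_missing = c(name = 0.15, birthdate = 0.1, gender = 0.1, mrn = 0.3)))
    lk <- run_linkage(coh)
    oracle <- all_pairs_edges(lk$patients, lk$registry)
    got <- lk$edges[, c("patient_key", "registry_id", "rules", "weight")]
    got$weight <- as.numeric(got$weight)
    rownames(got) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("heavier evidence wins a contested registry patient", {
  edges <- data.frame(
    patient_key = c("PA", "PB"), registry_id = c("R1", "R1"),
    R1 = c(TRUE, FALSE), R2 = c(TRUE, FALSE), R3 = c(FALSE, TRUE),
    R4 = c(FALSE, FALSE), rules = c("R1+R2", "R3"), weight = c(2, 1),
    stringsAsFactors = FALSE)
  res <- resolve_matching(edges)
  expect_identical(res$links$patient_key, "PA")
  expect_identical(res$unlinked_patient_keys, "PB")
})

test_that("resolution attains the exhaustive optimum on random graphs", {
  set.seed(60)
  for (i in 1:150) {
    e <- random_bipartite(sample(2:8, 1), sample(2:8, 1), runif(1, .1, .4))
    if (nrow(e) == 0) next
    res <- resolve_matching(data.frame(patient_key = e$left,
                                       registry_id = e$right,
                                       rules = "R1", weight = e$weight,
                                       stringsAsFactors = FALSE))
    best <- oracle_best_matching(e)
    expect_equal(nrow(res$links), best$card)
    expect_equal(sum(res$links$weight), best$weight)
    # links are one-to-one and drawn from the input edges
    expect_false(any(duplicated(res$links$patient_key)))
    expect_false(any(duplicated(res$links$registry_id)))
    expect_true(all(paste(res$links$patient_key, res$links$registry_id) %in%
                      paste(e$left, e$right)))
  }
})

test_that("resolution is invariant under permutation of the input", {
  set.seed(61)
  e <- random_bipartite(7, 7, 0.35)
  edges <- data.frame(patient_key = e$left, registry_id = e$right,
                      rules = "R1", weight = e$weight,
                      stringsAsFactors = FALSE)
  res1 <- resolve_matching(edges)
  res2 <- resolve_matching(edges[sample(nrow(edges)), ])
  expect_identical(res1$links, res2$links)
  expect_identical(res1$unlinked_patient_keys, res2$unlinked_patient_keys)
})

test_that("adding a registry patient never shrinks the matching", {
  set.seed(62)
  for (i in 1:20) {
    e <- random_bipartite(6, 6, 0.3)
    if (nrow(e) == 0) next
    edges <- data.frame(patient_key = e$left, registry_id = e$right,
                        rules = "R1", weight = e$weight,
                        stringsAsFactors = FALSE)
    drop_r <- sample(unique(edges$registry_id), 1)
    fewer <- edges[edges$registry_id != drop_r, , drop = FALSE]
    expect_lte(nrow(resolve_matching(fewer)$links),
               nrow(resolve_matching(edges)$links))
  }
})

test_that("edge provenance is recomputable from the identities", {
  coh <- small_cohort(n = 100, seed = 63)
  lk <- run_linkage(coh)
  pats <- lk$patients; regs <- lk$registry
  for (k in seq_len(min(nrow(lk$edges), 50))) {
    i <- match(lk$edges$patient_key[k], pats$patient_key)
    j <- match(lk$edges$registry_id[k], regs$registry_id)
    img <- list(location_id = pats$location_id[i],
                name_norm = pats$name_norm[i], birthdate = pats$birthdate[i],
                gender = pats$gender[i], mrn_norm = pats$mrn_norm[i])
    reg <- list(location_id = regs$location_ids[j],
                name_norm = regs$name_norm[j], birthdate = regs$birthdate[j],
                gender = regs$gender[j], mrn_norm = regs$mrn_norm[j])
    sat <- names(Filter(isTRUE, sapply(names(linkage_rules()), function(r) {
      rule_satisfied(img, reg, r)
    }, simplify = FALSE)))
    expect_identical(lk$edges$rules[k], paste(sat, collapse = "+"))
  }
})

test_that("greedy and strict modes stay one-to-one", {
  set.seed(64)
  e <- random_bipartite(8, 8, 0.4)
  edges <- data.frame(patient_key = e$left, registry_id = e$right,
                      rules = "R1", weight = e$weight,
                      stringsAsFactors = FALSE)
  for (mode in c("greedy", "strict")) {
    res <- resolve_matching(edges, mode = mode)
    expect_false(any(duplicated(res$links$patient_key)))
    expect_false(any(duplicated(res$links$registry_id)))
  }
  # a perfectly symmetric tie is dropped by strict mode, kept by default
  tie <- data.frame(patient_key = c("PA", "PA", "PB", "PB"),
                    registry_id = c("R1", "R2", "R1", "R2"),
                    rules = "R2", weight = c(1, 1, 1, 1),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(resolve_matching(tie, mode = "strict")$links), 0L)
  expect_equal(nrow(resolve_matching(tie)$links), 2L)
})

test_that("patient links propagate to every image of the patient", {
  coh <- small_cohort(n = 60, seed = 65)
  lk <- run_linkage(coh)
  images <- link_images(lk$result, lk$images)
  linked_keys <- lk$result$links$patient_key
  expect_equal(sum(images$linked),
               sum(images$patient_key %in% linked_keys))
  by_pat <- tapply(images$linked, images$patient_key, function(v) {
    all(v) || !any(v)
  })
  expect_true(all(by_pat))  # all-or-nothing per patient
  expect_true(all(!is.na(images$registry_id[images$linked])))
  expect_true(all(is.na(images$registry_id[!images$linked])))
})

test_that("measurements link only through linked OCT scans", {
  coh <- generate_cohort(synthetic_config(n_patients = 120, seed = 66,
                                          measurement_fraction = 0.5))
  lk <- run_linkage(coh)
  images <- link_images(lk$result, lk$images)
  meas <- images[images$is_measurement, , drop = FALSE]
  # plant one dangling reference
  meas$referenced_sop_uid[1] <- "0.0.0.0.GONE"
  ml <- link_measurements(meas, images)
  expect_equal(sum(ml$link_status == "dangling"), 1L)
  scans <- images[!images$is_measurement, ]
  ref <- match(ml$referenced_sop_uid, scans$sop_instance_uid)
  ok <- !is.na(ref)
  expect_equal(ml$linked[ok], scans$linked[ref[ok]])
  expect_false(any(ml$linked[!ok]))
  expect_identical(ml$registry_id[ml$linked],
                   scans$registry_id[ref[ml$linked]])
})
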
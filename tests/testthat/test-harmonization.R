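# Identifier normalization and the three exclusion criteria.

test_that("normalization canonicalizes case, spacing, MRNs and gender", {
  id <- normalize_identity(list(name_raw = "  doe^John ", mrn = "000123",
                                gender = "female",
                                birthdate = "19500201"))
  expect_identical(id$name_norm, "DOE JOHN")
  expect_identical(id$mrn_norm, "123")
  expect_identical(id$gender, "F")
  expect_identical(id$birthdate, "1950-02-01")
  expect_identical(normalize_identity(list(mrn = "123"))$mrn_norm, "123")
  expect_identical(normalize_identity(list(gender = "F"))$gender, "F")
  # name built from parts when parts exist
  id2 <- normalize_identity(list(name_family = "O'Brien-Smith",
                                 name_given = "mary", name_middle = "j.",
                                 name_raw = "ignored^when^parts^exist"))
  expect_identical(id2$name_norm, "O'BRIEN-SMITH MARY J")
})

test_that("normalization is idempotent on fuzzed inputs", {
  set.seed(77)
  alphabet <- c(LETTERS, letters, " ", "^", "'", "-", ".", ",", "#", "2",
                "0", "@")
  for (i in 1:200) {
    s <- paste(sample(alphabet, sample(0:20, 1), replace = TRUE),
               collapse = "")
    once <- normalize_identity(list(name_raw = s,
                                    mrn = paste0("00", i),
                                    gender = sample(c("m", "F", "other"), 1)))
    twice <- normalize_identity(list(name_raw = once$name_norm,
                                     mrn = once$mrn_norm,
                                     gender = once$gender))
    expect_identical(twice$name_norm, once$name_norm)
    expect_identical(twice$mrn_norm, once$mrn_norm)
    expect_identical(twice$gender, once$gender)
  }
})

test_that("roman numeral recognition matches exhaustive enumeration", {
  valid <- toupper(as.character(utils::as.roman(1:3899)))
  expect_true(all(is_roman_numeral(valid)))
  # near-miss strings never produced by the numeral system
  expect_false(any(is_roman_numeral(c("IIX", "VV", "IIII", "XXXX", "IC",
                                      "MMMM", "LL", "DD", "VX", ""))))
  # arbitrary name tokens are not numerals
  expect_false(any(is_roman_numeral(c("DOE", "MARY", "HENRY"))))
  # numeral-shaped suffix tokens are what the exemption exists for
  expect_true(all(is_roman_numeral(c("III", "IV", "XI"))))
})

test_that("exclusion criteria fire in priority order, one flag at most", {
  cut <- "2020-06-01"
  expect_identical(flag_exclusion(list(name_norm = "JOHN2 DOE",
                                       birthdate = "1950-01-01"), cut),
                   "NAME_NUMERIC_OR_SPECIAL")
  expect_identical(flag_exclusion(list(name_norm = "DOE JOHN",
                                       birthdate = "1899-12-31"), cut),
                   "ABNORMAL_DOB")
  expect_identical(flag_exclusion(list(name_norm = "DOE JOHN",
                                       birthdate = "2020-06-02"), cut),
                   "ABNORMAL_DOB")
  expect_identical(flag_exclusion(list(name_norm = "TEST PATIENT",
                                       birthdate = "1980-05-05"), cut),
                   "TEST_NAME")
  expect_true(is.na(flag_exclusion(list(name_norm = "HENRY DOE III",
                                        birthdate = "1950-01-01"), cut)))
  expect_true(is.na(flag_exclusion(list(name_norm = "ANNE-MARIE O'NEIL",
                                        birthdate = "1950-01-01"), cut)))
  # multi-criteria patient counted once, under the first matching rule
  expect_identical(flag_exclusion(list(name_norm = "TEST4 PATIENT",
                                       birthdate = "1850-01-01"), cut),
                   "NAME_NUMERIC_OR_SPECIAL")
  expect_identical(flag_exclusion(list(name_norm = "TEST PATIENT",
                                       birthdate = "1850-01-01"), cut),
                   "ABNORMAL_DOB")
  # special characters without digits also hit the name rule
  expect_identical(flag_exclusion(list(name_norm = "DOE# JOHN",
                                       birthdate = "1950-01-01"), cut),
                   "NAME_NUMERIC_OR_SPECIAL")
  # word-boundary mode keeps TESTER but still drops TEST
  expect_true(is.na(flag_exclusion(list(name_norm = "TESTER JOHN",
                                        birthdate = "1950-01-01"), cut,
                                   test_word_boundary = TRUE)))
  expect_identical(flag_exclusion(list(name_norm = "TESTER JOHN",
                                       birthdate = "1950-01-01"), cut),
                   "TEST_NAME")
})

test_that("flag counts partition the cohort and match planted contamination", {
  coh <- generate_cohort(synthetic_config(
    n_patients = 1000, seed = 31,
    contamination = c(p_numeric_name = 0.03, p_abnormal_dob = 0.01,
                      p_test_name = 0.01)))
  lk <- run_linkage(coh)
  qc <- qc_exclusion_report(lk$patients)
  planted <- table(factor(coh$truth$planted_flags, levels = qc$flag))
  expect_equal(qc$n_patients, as.integer(planted))
  expect_gt(sum(qc$n_patients), 0)
  # partition: flagged + unflagged = total; flagged image counts agree
  expect_equal(sum(qc$n_patients) + sum(is.na(lk$patients$exclusion_flag)),
               nrow(lk$patients))
  flagged_keys <- lk$patients$patient_key[!is.na(lk$patients$exclusion_flag)]
  expect_equal(sum(qc$n_images),
               sum(lk$images$patient_key %in% flagged_keys))
})
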
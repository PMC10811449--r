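# Identifier harmonization and data-quality exclusion flags.
#
# Both sides of the linkage (imaging metadata and the registry roster) are
# brought to one canonical identity form before any rule is evaluated:
# upper-case single-spaced names, leading-zero-free MRNs, single-letter
# gender codes, ISO dates. Characters outside the expected name alphabet are
# deliberately preserved by normalization so that the quality flags can
# still see them.

.normalize_gender <- function(x) {
  if (length(x) == 0) return(character(0))
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(up))
  out[up %in% c("M", "MALE")] <- "M"
  out[up %in% c("F", "FEMALE")] <- "F"
  out[up %in% c("O", "OTHER")] <- "O"
  out
}

.normalize_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("^", " ", x, fixed = TRUE)      # PN component separators
  x <- gsub("[=.,]", " ", x)                # formatting punctuation only
  squish(x)
}

.normalize_mrn <- function(x) {
  x <- gsub("[[:space:]]", "", toupper(as.character(x)))
  x <- sub("^0+", "", x)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

#' Normalize patient identifiers to a canonical comparable form
#'
#' Produces the canonical identity used by every linkage rule: `name_norm`
#' as upper-case `"FAMILY GIVEN MIDDLE [SUFFIX]"` built from name parts when
#' available (otherwise from the raw text), single-spaced, with formatting
#' punctuation (periods, commas, PN carets) removed; `mrn_norm` stripped of
#' whitespace and leading zeros; `gender` mapped to `M`/`F`/`O`; birthdate
#' as an ISO date. Normalization is idempotent and missingness propagates.
#' Digits and unexpected special characters in names are *kept* — they are
#' what the exclusion flags look for.
#'
#' @param record one-row data.frame (or list) with any of `name_raw`,
#'   `name_family`, `name_given`, `name_middle`, `name_suffix`, `birthdate`,
#'   `gender`, `mrn`, `location_id`.
#' @return named list with `name_norm`, `birthdate`, `gender`, `mrn_norm`,
#'   `location_id`.
#' @export
#' @examples
#' normalize_identity(list(name_raw = "  doe^John ", mrn = "000123",
#'                         gender = "female", birthdate = "1950-02-01"))
normalize_identity <- function(record) {
  fld <- function(nm) {
    v <- record[[nm]]
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[1])
  }
  fam <- fld("name_family"); giv <- fld("name_given")
  mid <- fld("name_middle"); suf <- fld("name_suffix")
  has_parts <- any(nzchar(c(fam, giv)[!is.na(c(fam, giv))]))
  name_src <- if (has_parts) {
    paste(Filter(function(s) !is.na(s) && nzchar(s), list(fam, giv, mid, suf)),
          collapse = " ")
  } else {
    fld("name_raw")
  }
  name_norm <- if (is.na(name_src)) NA_character_ else .normalize_name(name_src)
  if (!is.na(name_norm) && !nzchar(name_norm)) name_norm <- NA_character_
  bd <- parse_dicom_date(fld("birthdate"))
  list(
    name_norm = name_norm,
    birthdate = if (is.na(bd)) NA_character_ else as.character(bd),
    gender = .normalize_gender(fld("gender")),
    mrn_norm = .normalize_mrn(fld("mrn")),
    location_id = fld("location_id")
  )
}

#' Add normalized identifier columns to a patient table
#'
#' Vectorized form of [normalize_identity()]: adds/overwrites `name_norm`,
#' `mrn_norm`, normalized `gender` and ISO `birthdate` columns.
#'
#' @param tab imaging patient or registry roster data.frame.
#' @return `tab` with normalized columns.
#' @export
normalize_table <- function(tab) {
  n <- nrow(tab)
  fam <- tab$name_family %||% rep(NA_character_, n)
  giv <- tab$name_given %||% rep(NA_character_, n)
  mid <- tab$name_middle %||% rep(NA_character_, n)
  suf <- tab$name_suffix %||% rep(NA_character_, n)
  raw <- tab$name_raw %||% rep(NA_character_, n)
  has_parts <- (!is.na(fam) & nzchar(fam)) | (!is.na(giv) & nzchar(giv))
  comp <- function(x) ifelse(is.na(x) | !nzchar(x), "", paste0(" ", x))
  from_parts <- squish(paste0(comp(fam), comp(giv), comp(mid), comp(suf)))
  src <- ifelse(has_parts, from_parts, raw)
  nn <- .normalize_name(src)
  nn[is.na(src) | !nzchar(nn)] <- NA_character_
  tab$name_norm <- nn
  tab$mrn_norm <- .normalize_mrn(tab$mrn %||% rep(NA_character_, n))
  tab$gender <- .normalize_gender(tab$gender %||% rep(NA_character_, n))
  tab$birthdate <- as.character(parse_dicom_date(tab$birthdate %||%
                                                   rep(NA_character_, n)))
  tab
}

#' Test whether a token is a Roman numeral
#'
#' Matches the canonical Roman numeral grammar (values 1-3999), the form
#' used in name suffixes ("HENRY DOE III"). Such suffixes are numbers but
#' must not trigger the numeric-name exclusion.
#'
#' @param token character vector of upper-case tokens.
#' @return logical vector.
#' @export
#' @examples
#' is_roman_numeral(c("III", "IV", "IIX"))  # TRUE TRUE FALSE
is_roman_numeral <- function(token) {
  !is.na(token) & nzchar(token) &
    grepl("^M{0,3}(CM|CD|D?C{0,3})(XC|XL|L?X{0,3})(IX|IV|V?I{0,3})$", token) &
    token != ""
}

#' Flag a patient for exclusion from the linkable pool
#'
#' Applies the three data-quality criteria to a normalized identity, in
#' priority order, returning at most one flag per patient:
#'
#' * `NAME_NUMERIC_OR_SPECIAL` — any digit in a name token that is not
#'   wholly a Roman numeral, or any character outside upper-case letters,
#'   space, hyphen and apostrophe;
#' * `ABNORMAL_DOB` — birthdate before 1900-01-01 or after `cutoff_date`
#'   (the last date of imaging acquisition);
#' * `TEST_NAME` — the phrase "test" anywhere in the name
#'   (case-insensitive; set `test_word_boundary = TRUE` to require a whole
#'   word, so that e.g. "TESTER" is kept).
#'
#' @param identity a normalized identity ([normalize_identity()]).
#' @param cutoff_date upper bound for plausible birthdates (ISO date).
#' @param test_word_boundary match "test" only as a whole word.
#' @return one of `"NAME_NUMERIC_OR_SPECIAL"`, `"ABNORMAL_DOB"`,
#'   `"TEST_NAME"`, or `NA_character_` when no criterion applies.
#' @export
#' @examples
#' id <- list(name_norm = "HENRY DOE III", birthdate = "1950-01-01")
#' flag_exclusion(id, cutoff_date = "2020-06-01")  # NA: Roman numeral is fine
flag_exclusion <- function(identity, cutoff_date,
                           test_word_boundary = FALSE) {
  nm <- identity$name_norm
  if (!is.na(nm) && nzchar(nm)) {
    tokens <- strsplit(nm, " ", fixed = TRUE)[[1]]
    digit_bad <- grepl("[0-9]", tokens) & !is_roman_numeral(tokens)
    special_bad <- grepl("[^A-Z '-]", nm)
    if (any(digit_bad) || special_bad) return("NAME_NUMERIC_OR_SPECIAL")
  }
  bd <- parse_dicom_date(identity$birthdate %||% NA_character_)
  if (!is.na(bd)) {
    if (bd < as.Date("1900-01-01") || bd > as.Date(cutoff_date)) {
      return("ABNORMAL_DOB")
    }
  }
  if (!is.na(nm)) {
    pat <- if (test_word_boundary) "\\bTEST\\b" else "TEST"
    if (grepl(pat, nm, ignore.case = TRUE)) return("TEST_NAME")
  }
  NA_character_
}

#' Flag exclusions for a whole (normalized) patient table
#'
#' @param patients normalized imaging patient table ([normalize_table()]).
#' @param cutoff_date plausible-birthdate upper bound; defaults to the
#'   table's maximum `last_visit_date`.
#' @param test_word_boundary see [flag_exclusion()].
#' @return `patients` with an `exclusion_flag` column (`NA` = kept).
#' @export
flag_exclusions <- function(patients, cutoff_date = NULL,
                            test_word_boundary = FALSE) {
  if (is.null(cutoff_date)) {
    lv <- parse_dicom_date(patients$last_visit_date)
    if (all(is.na(lv))) stop("cannot infer cutoff_date: no visit dates",
                             call. = FALSE)
    cutoff_date <- max(lv, na.rm = TRUE)
  }
  patients$exclusion_flag <- vapply(seq_len(nrow(patients)), function(i) {
    flag_exclusion(list(name_norm = patients$name_norm[i],
                        birthdate = patients$birthdate[i]),
                   cutoff_date, test_word_boundary)
  }, character(1))
  patients
}

#' Summarize exclusions as a QC table
#'
#' One row per exclusion flag with the number of flagged patients and their
#' total image count (rows are mutually exclusive: a patient carries at most
#' one flag).
#'
#' @param patients flagged patient table ([flag_exclusions()]).
#' @return data.frame with `flag`, `n_patients`, `n_images`.
#' @export
qc_exclusion_report <- function(patients) {
  flags <- c("NAME_NUMERIC_OR_SPECIAL", "ABNORMAL_DOB", "TEST_NAME")
  rows <- lapply(flags, function(f) {
    sel <- !is.na(patients$exclusion_flag) & patients$exclusion_flag == f
    df(flag = f, n_patients = sum(sel),
       n_images = sum(patients$n_images[sel], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
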
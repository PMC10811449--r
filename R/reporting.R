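# Linkage-quality reporting: cohort-diagram counts, initial and cleaned
# rates, strata by last-visit year and image type, diagnosis cohorts.

#' Linkage success rate as a percentage
#'
#' `100 * linked / total`, rounded half-up to `decimals` places. Headline
#' rates are conventionally reported at 1 decimal, stratum rates at 2.
#'
#' @param linked,total non-negative counts, `linked <= total`, `total > 0`.
#' @param decimals decimal places (default 2).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' compute_rate(46196, 54896, 1)   # 84.2
#' compute_rate(445163, 468767, 2) # 94.96
compute_rate <- function(linked, total, decimals = 2) {
  stopifnot(length(linked) == length(total))
  if (any(total <= 0)) stop("rate undefined for total = 0", call. = FALSE)
  if (any(linked < 0 | linked > total)) {
    stop("linked must lie in [0, total]", call. = FALSE)
  }
  round_half_up(100 * linked / total, decimals)
}

#' Cohort-diagram counts and linkage rates
#'
#' Builds the full reporting surface from pipeline outputs: total and linked
#' patient/image counts, per-flag exclusion counts (mutually exclusive), and
#' four rates. *Initial* rates divide by the full archive totals. *Cleaned*
#' rates remove the flagged patients' counts from the denominators only —
#' flagged records are, by construction, unlinkable candidates taken out of
#' the eligible pool; the numerators are unchanged.
#'
#' @param patients flagged patient table ([flag_exclusions()]).
#' @param images image table.
#' @param result a `link_result`.
#' @return object of class `linkage_report` (also a list): counts, per-flag
#'   exclusion tables, and `initial_patient_rate_pct`,
#'   `initial_image_rate_pct`, `cleaned_patient_rate_pct`,
#'   `cleaned_image_rate_pct`.
#' @export
build_cohort_diagram <- function(patients, images, result) {
  linked_keys <- result$links$patient_key
  excl <- qc_exclusion_report(patients)
  n_pat <- nrow(patients)
  n_img <- nrow(images)
  n_linked_pat <- sum(patients$patient_key %in% linked_keys)
  n_linked_img <- sum(images$patient_key %in% linked_keys)
  cohort_diagram_from_counts(
    total_patients = n_pat, linked_patients = n_linked_pat,
    total_images = n_img, linked_images = n_linked_img,
    excluded_patients_by_flag = stats::setNames(excl$n_patients, excl$flag),
    excluded_images_by_flag = stats::setNames(excl$n_images, excl$flag)
  )
}

#' Cohort-diagram rates from pre-tabulated counts
#'
#' Same computation as [build_cohort_diagram()] but starting from integer
#' counts, e.g. a published cohort table.
#'
#' @param total_patients,linked_patients,total_images,linked_images counts.
#' @param excluded_patients_by_flag,excluded_images_by_flag named integer
#'   vectors (flag -> count), mutually exclusive across flags.
#' @param headline_decimals decimals for the four headline rates.
#' @return a `linkage_report`.
#' @export
#' @examples
#' cohort_diagram_from_counts(
#'   total_patients = 54896, linked_patients = 46196,
#'   total_images = 2287839, linked_images = 1937864,
#'   excluded_patients_by_flag = c(NAME_NUMERIC_OR_SPECIAL = 2365,
#'                                 ABNORMAL_DOB = 118, TEST_NAME = 17),
#'   excluded_images_by_flag = c(NAME_NUMERIC_OR_SPECIAL = 207628,
#'                               ABNORMAL_DOB = 3447, TEST_NAME = 456))
cohort_diagram_from_counts <- function(total_patients, linked_patients,
                                       total_images, linked_images,
                                       excluded_patients_by_flag = integer(0),
                                       excluded_images_by_flag = integer(0),
                                       headline_decimals = 1) {
  excl_pat <- sum(excluded_patients_by_flag)
  excl_img <- sum(excluded_images_by_flag)
  clean_pat_denom <- total_patients - excl_pat
  clean_img_denom <- total_images - excl_img
  structure(list(
    total_patients = total_patients,
    linked_patients = linked_patients,
    excluded_patients_by_flag = excluded_patients_by_flag,
    total_images = total_images,
    linked_images = linked_images,
    excluded_images_by_flag = excluded_images_by_flag,
    cleaned_patient_denominator = clean_pat_denom,
    cleaned_image_denominator = clean_img_denom,
    initial_patient_rate_pct = compute_rate(linked_patients, total_patients,
                                            headline_decimals),
    initial_image_rate_pct = compute_rate(linked_images, total_images,
                                          headline_decimals),
    cleaned_patient_rate_pct = compute_rate(linked_patients, clean_pat_denom,
                                            headline_decimals),
    cleaned_image_rate_pct = compute_rate(linked_images, clean_img_denom,
                                          headline_decimals)
  ), class = "linkage_report")
}

#' @export
print.linkage_report <- function(x, ...) {
  cat("<linkage_report>\n")
  cat(sprintf("  patients: %d total, %d linked (initial rate %.10g%%)\n",
              x$total_patients, x$linked_patients,
              x$initial_patient_rate_pct))
  cat(sprintf("  images:   %d total, %d linked (initial rate %.10g%%)\n",
              x$total_images, x$linked_images, x$initial_image_rate_pct))
  if (length(x$excluded_patients_by_flag)) {
    cat("  exclusions (patients / images):\n")
    for (f in names(x$excluded_patients_by_flag)) {
      cat(sprintf("    %-24s %d / %d\n", f, x$excluded_patients_by_flag[[f]],
                  x$excluded_images_by_flag[[f]] %||% 0L))
    }
  }
  cat(sprintf("  cleaned rates: %.10g%% patients (denom %d), %.10g%% images (denom %d)\n",
              x$cleaned_patient_rate_pct, x$cleaned_patient_denominator,
              x$cleaned_image_rate_pct, x$cleaned_image_denominator))
  invisible(x)
}

#' Linkage rates stratified by last-visit year or image type
#'
#' Year strata are consecutive 12-month windows counting *images*, grouped
#' by their patient's last imaging visit, anchored at `cutoff_date` and
#' labeled `"YYYY-YYYY+1"` (the newest window ends at the cutoff). Image
#' type strata count *unique patients* per type; a patient imaged with
#' several modalities appears in each of them, and OTHER-typed images get
#' their own stratum rather than being dropped. Rates are reported at 2
#' decimals.
#'
#' @param result a `link_result`.
#' @param patients patient table with `last_visit_date`.
#' @param images image table.
#' @param by `"last_visit_year"` or `"image_type"`.
#' @param cutoff_date anchor for the year windows; defaults to the maximum
#'   acquisition date in `images`.
#' @return data.frame of strata: `stratum_label`, `total_count`,
#'   `linked_count`, `rate_pct`.
#' @export
stratify_report <- function(result, patients, images,
                            by = c("last_visit_year", "image_type"),
                            cutoff_date = NULL) {
  by <- match.arg(by)
  linked_keys <- result$links$patient_key
  if (by == "last_visit_year") {
    acq <- parse_dicom_date(images$acquisition_date)
    if (is.null(cutoff_date)) {
      if (all(is.na(acq))) stop("no acquisition dates", call. = FALSE)
      cutoff_date <- max(acq, na.rm = TRUE)
    }
    cutoff_date <- as.Date(cutoff_date)
    lv <- parse_dicom_date(patients$last_visit_date)
    lv_of_img <- lv[match(images$patient_key, patients$patient_key)]
    keep <- !is.na(lv_of_img)
    # whole years back from the cutoff: window j covers
    # (cutoff - (j+1) yr, cutoff - j yr]
    yrs_back <- .whole_years_before(lv_of_img[keep], cutoff_date)
    lbl_year <- as.integer(format(cutoff_date, "%Y")) - yrs_back
    label <- sprintf("%d-%d", lbl_year, lbl_year + 1L)
    is_linked <- images$patient_key[keep] %in% linked_keys
    tab <- .stratum_table(label, is_linked)
  } else {
    scans <- images[!images$is_measurement, , drop = FALSE]
    pt <- unique(df(patient_key = scans$patient_key,
                    type = scans$image_type))
    is_linked <- pt$patient_key %in% linked_keys
    tab <- .stratum_table(pt$type, is_linked)
    order_hint <- c("OCT", "FAF", "IR", "COLOR", "FA", "ICGA", "BR", "OTHER")
    tab <- tab[order(match(tab$stratum_label, order_hint,
                           nomatch = length(order_hint) + 1L)), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

.whole_years_before <- function(dates, cutoff) {
  # index j of the 12-month window (cutoff - (j+1)yr, cutoff - j*yr] that
  # contains each date; vectorized on (year, month-day) arithmetic
  yr <- as.integer(format(dates, "%Y"))
  md <- format(dates, "%m%d")
  cy <- as.integer(format(cutoff, "%Y"))
  cmd <- format(cutoff, "%m%d")
  base <- cy - yr
  ifelse(md > cmd, base - 1L, base)
}

.stratum_table <- function(label, is_linked) {
  total <- table(label)
  linked <- table(factor(label[is_linked], levels = names(total)))
  out <- df(stratum_label = names(total),
            total_count = as.integer(total),
            linked_count = as.integer(linked))
  out$rate_pct <- compute_rate(out$linked_count, pmax(out$total_count, 1L), 2)
  out$rate_pct[out$total_count == 0] <- NA_real_
  out <- out[order(out$stratum_label, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Diagnosis cohorts from linked patients
#'
#' For each diagnosis in the ICD map, membership is every *linked* patient
#' whose registry record carries at least one matching ICD code. All imaging
#' visits and images of a member count toward the cohort (diagnosis is
#' attached at the patient level, not the visit level), patients may belong
#' to several cohorts, and follow-up is the span in years between a
#' member's first and last imaging visit (mean and SD across members).
#'
#' @param result a `link_result`.
#' @param registry registry table with `registry_id` and `icd_codes`
#'   (`|`-separated).
#' @param patients patient table (`n_visits`, `n_images`).
#' @param images image table (for first/last visit dates).
#' @param icd_map named list diagnosis -> character vector of ICD codes,
#'   e.g. `yaml::read_yaml(system.file("extdata", "icd_map.yaml", package =
#'   "oculink"))`.
#' @return data.frame: `diagnosis_label`, `icd_codes`, `unique_patients`,
#'   `unique_visits`, `unique_images`, `followup_years_mean`,
#'   `followup_years_sd`.
#' @export
diagnosis_cohorts <- function(result, registry, patients, images, icd_map) {
  reg_codes <- lapply(registry$icd_codes, split_multi)
  acq <- parse_dicom_date(images$acquisition_date)
  span_by_patient <- tapply(acq, images$patient_key, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) NA_real_
    else as.numeric(max(d) - min(d)) / 365.25
  })
  rows <- lapply(names(icd_map), function(label) {
    codes <- as.character(unlist(icd_map[[label]]))
    if (length(codes) == 0) {
      warning("empty ICD code set for diagnosis '", label, "'",
              call. = FALSE)
      return(df(diagnosis_label = label, icd_codes = "",
                unique_patients = 0L, unique_visits = 0L,
                unique_images = 0L, followup_years_mean = NA_real_,
                followup_years_sd = NA_real_))
    }
    member_reg <- registry$registry_id[vapply(reg_codes, function(cs) {
      any(cs %in% codes)
    }, logical(1))]
    member_keys <- result$links$patient_key[result$links$registry_id %in%
                                              member_reg]
    sel <- patients$patient_key %in% member_keys
    spans <- span_by_patient[patients$patient_key[sel]]
    df(diagnosis_label = label, icd_codes = join_multi(codes),
       unique_patients = sum(sel),
       unique_visits = sum(patients$n_visits[sel], na.rm = TRUE),
       unique_images = sum(patients$n_images[sel], na.rm = TRUE),
       followup_years_mean = if (any(sel)) mean(spans, na.rm = TRUE)
                             else NA_real_,
       followup_years_sd = if (sum(sel) > 1) stats::sd(spans, na.rm = TRUE)
                           else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read the packaged benchmark cohort counts
#'
#' Integer patient/image counts (totals, per-flag exclusions, year and
#' image-type strata) from a published two-practice ophthalmic archive
#' linked to an EHR registry, shipped as package data for the worked example
#' and the acceptance script. Only the counts are stored; every rate is
#' recomputed.
#'
#' @return nested list mirroring the YAML file.
#' @export
benchmark_cohort_counts <- function() {
  yaml::read_yaml(system.file("extdata", "benchmark_cohort_counts.yaml",
                              package = "oculink"))
}
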
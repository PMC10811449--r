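# End-to-end orchestration: extract -> harmonize -> flag -> link ->
# de-identify -> report, as one reproducible run with a manifest.

#' Build and validate a pipeline run configuration
#'
#' Input is either a directory of DICOM files (`dicom_dir`, with one
#' `location_id`) or an instance-level metadata table (`metadata`, a
#' data.frame or CSV path with a `location_id` column). The registry roster
#' is a data.frame or CSV path. The salt is kept in the configuration but
#' never written to logs, manifests or outputs.
#'
#' @param registry registry roster (data.frame or CSV path).
#' @param metadata instance-level metadata table (data.frame or CSV path);
#'   mutually exclusive with `dicom_dir`.
#' @param dicom_dir DICOM archive directory.
#' @param location_id practice id for `dicom_dir` runs.
#' @param out_dir output directory (created at run time).
#' @param cutoff_date plausible-birthdate upper bound / year-strata anchor;
#'   default: the archive's maximum acquisition date.
#' @param matching_mode `"max_cardinality"`, `"greedy"` or `"strict"`.
#' @param include_flagged evaluate candidate edges for flagged patients too
#'   (default `TRUE`; they only leave the denominators of cleaned rates).
#' @param test_word_boundary see [flag_exclusion()].
#' @param phi_policy path to a PHI policy file.
#' @param icd_map path to an ICD map file, or `NULL` to skip diagnosis
#'   cohorts.
#' @param salt tokenization secret.
#' @param deidentify rewrite de-identified copies of DICOM inputs and
#'   tokenized tables.
#' @param output_formats `"csv"` and/or `"parquet"`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(registry,
                       metadata = NULL,
                       dicom_dir = NULL,
                       location_id = "L01",
                       out_dir = tempfile("oculink_run_"),
                       cutoff_date = NULL,
                       matching_mode = c("max_cardinality", "greedy",
                                         "strict"),
                       include_flagged = TRUE,
                       test_word_boundary = FALSE,
                       phi_policy = system.file("extdata", "phi_policy.yaml",
                                                package = "oculink"),
                       icd_map = system.file("extdata", "icd_map.yaml",
                                             package = "oculink"),
                       salt = NULL,
                       deidentify = !is.null(salt),
                       output_formats = "csv") {
  matching_mode <- match.arg(matching_mode)
  if (is.null(metadata) == is.null(dicom_dir)) {
    stop("exactly one of `metadata` or `dicom_dir` must be given",
         call. = FALSE)
  }
  if (is.character(registry) && !file.exists(registry)) {
    stop("registry table not found: ", registry, call. = FALSE)
  }
  if (is.character(metadata) && !file.exists(metadata)) {
    stop("metadata table not found: ", metadata, call. = FALSE)
  }
  if (!is.null(dicom_dir) && !dir.exists(dicom_dir)) {
    stop("DICOM directory not found: ", dicom_dir, call. = FALSE)
  }
  if (isTRUE(deidentify) &&
      (is.null(salt) || !nzchar(salt))) {
    stop("de-identification requires a non-empty salt", call. = FALSE)
  }
  if (!is.null(phi_policy) && nzchar(phi_policy) &&
      !file.exists(phi_policy)) {
    stop("PHI policy not found: ", phi_policy, call. = FALSE)
  }
  structure(list(registry = registry, metadata = metadata,
                 dicom_dir = dicom_dir, location_id = location_id,
                 out_dir = out_dir, cutoff_date = cutoff_date,
                 matching_mode = matching_mode,
                 include_flagged = include_flagged,
                 test_word_boundary = test_word_boundary,
                 phi_policy = phi_policy, icd_map = icd_map, salt = salt,
                 deidentify = deidentify,
                 output_formats = output_formats),
            class = "run_config")
}

.read_table_arg <- function(x) {
  if (is.data.frame(x)) return(x)
  utils::read.csv(x, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
}

#' Run the full linkage pipeline
#'
#' Stages, in order: extraction/consolidation, identifier harmonization on
#' both sides, exclusion flagging, candidate-edge construction, one-to-one
#' matching, propagation to images and key measurements, de-identification
#' (after linkage), and reporting. All outputs land under `config$out_dir`;
#' the manifest records input hashes, the configuration (minus the salt),
#' stage-by-stage counts and the package version, and is identical across
#' reruns on identical inputs.
#'
#' @param config a `run_config`.
#' @return object of class `pipeline_run`: list with `patients`, `images`,
#'   `registry`, `edges`, `result`, `measurements`, `report`, `strata`,
#'   `diagnosis`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  input_hashes <- list()
  hash_file <- function(p) as.character(tools::md5sum(p))
  if (is.character(config$registry)) {
    input_hashes$registry <- hash_file(config$registry)
  }
  if (is.character(config$metadata)) {
    input_hashes$metadata <- hash_file(config$metadata)
  }

  # -- extract ---------------------------------------------------------
  cons <- if (!is.null(config$dicom_dir)) {
    files <- list.files(config$dicom_dir, pattern = "\\.dcm$",
                        recursive = TRUE, full.names = TRUE)
    input_hashes$dicom_archive <- as.character(
      openssl::md5(paste(sort(basename(files)), collapse = ",")))
    extract_archive(config$dicom_dir, config$location_id)
  } else {
    consolidate_metadata_table(.read_table_arg(config$metadata))
  }
  patients <- cons$patients
  images <- cons$images
  registry <- .read_table_arg(config$registry)

  # -- harmonize + flag ------------------------------------------------
  patients <- normalize_table(patients)
  registry <- normalize_table(registry)
  if (is.null(registry$location_ids)) {
    registry$location_ids <- registry$location_id
  }
  patients <- flag_exclusions(patients, cutoff_date = config$cutoff_date,
                              test_word_boundary = config$test_word_boundary)

  # -- link ------------------------------------------------------------
  edges <- build_candidate_edges(patients, registry,
                                 include_flagged = config$include_flagged)
  result <- resolve_matching(edges, mode = config$matching_mode,
                             all_patient_keys = patients$patient_key,
                             all_registry_ids = registry$registry_id)
  images <- link_images(result, images)
  measurements <- link_measurements(
    images[images$is_measurement, , drop = FALSE], images)

  # -- report ----------------------------------------------------------
  report <- build_cohort_diagram(patients, images, result)
  strata <- list(
    last_visit_year = stratify_report(result, patients, images,
                                      by = "last_visit_year",
                                      cutoff_date = config$cutoff_date),
    image_type = stratify_report(result, patients, images,
                                 by = "image_type")
  )
  diagnosis <- NULL
  if (!is.null(config$icd_map) && nzchar(config$icd_map) &&
      !is.null(registry$icd_codes)) {
    diagnosis <- diagnosis_cohorts(result, registry, patients, images,
                                   yaml::read_yaml(config$icd_map))
  }

  # -- de-identify (after linkage) -------------------------------------
  deid_summary <- NULL
  if (isTRUE(config$deidentify)) {
    policy <- load_phi_policy(config$phi_policy)
    patients$patient_token <- tokenize_patient_id(patients$patient_key,
                                                  config$salt)
    if (!is.null(config$dicom_dir)) {
      deid_dir <- file.path(config$out_dir, "deidentified")
      dir.create(deid_dir, showWarnings = FALSE)
      files <- sort(list.files(config$dicom_dir, pattern = "\\.dcm$",
                               recursive = TRUE, full.names = TRUE))
      masked <- vapply(files, function(f) {
        deidentify_dicom_file(f, file.path(deid_dir, basename(f)),
                              policy, config$salt)$masked_count
      }, integer(1))
      deid_summary <- list(n_files = length(files),
                           masked_tags_total = sum(masked))
    } else {
      deid_summary <- list(n_files = 0L, masked_tags_total = 0L)
    }
  }

  # -- write outputs ---------------------------------------------------
  out_pat <- patients
  if (isTRUE(config$deidentify)) {
    # tokenized, masked patient table only
    out_pat$name_raw <- out_pat$name_family <- out_pat$name_given <- NULL
    out_pat$name_middle <- out_pat$name_prefix <- out_pat$name_suffix <- NULL
    out_pat$name_norm <- out_pat$birthdate <- out_pat$mrn <- NULL
    out_pat$mrn_norm <- NULL
  }
  fmts <- config$output_formats
  write_table_out(out_pat, file.path(config$out_dir, "patients"), fmts)
  write_table_out(images, file.path(config$out_dir, "images"), fmts)
  write_table_out(result$links, file.path(config$out_dir, "links"), fmts)
  write_table_out(df(patient_key = result$unlinked_patient_keys),
                  file.path(config$out_dir, "unlinked_patients"), fmts)
  write_table_out(measurements,
                  file.path(config$out_dir, "measurement_links"), fmts)
  write_table_out(qc_exclusion_report(patients),
                  file.path(config$out_dir, "qc_exclusions"), fmts)
  for (nm in names(strata)) {
    write_table_out(strata[[nm]],
                    file.path(config$out_dir, paste0("strata_", nm)), fmts)
  }
  if (!is.null(diagnosis)) {
    write_table_out(diagnosis, file.path(config$out_dir,
                                         "diagnosis_cohorts"), fmts)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oculink")),
    config = .manifest_config(config),
    input_hashes = input_hashes,
    counts = list(
      patients_total = report$total_patients,
      patients_linked = report$linked_patients,
      patients_unlinked = length(result$unlinked_patient_keys),
      patients_excluded = sum(unlist(report$excluded_patients_by_flag)),
      images_total = report$total_images,
      images_linked = report$linked_images,
      measurements_total = nrow(measurements),
      measurements_linked = sum(measurements$linked),
      measurements_dangling = sum(measurements$link_status == "dangling"),
      edges = nrow(edges),
      registry_total = nrow(registry)
    ),
    rates = list(
      initial_patient_rate_pct = report$initial_patient_rate_pct,
      initial_image_rate_pct = report$initial_image_rate_pct,
      cleaned_patient_rate_pct = report$cleaned_patient_rate_pct,
      cleaned_image_rate_pct = report$cleaned_image_rate_pct
    ),
    deidentification = deid_summary
  )
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                    pretty = TRUE, null = "null")
  writeLines(manifest_json, file.path(config$out_dir, "manifest.json"))
  report_json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE)
  writeLines(report_json, file.path(config$out_dir, "report.json"))

  structure(list(patients = patients, images = images, registry = registry,
                 edges = edges, result = result,
                 measurements = measurements, report = report,
                 strata = strata, diagnosis = diagnosis,
                 manifest = manifest, out_dir = config$out_dir),
            class = "pipeline_run")
}

# Manifest view of the config: paths and switches, never the salt.
.manifest_config <- function(config) {
  list(
    input = if (!is.null(config$dicom_dir)) "dicom_dir" else "metadata",
    location_id = config$location_id,
    cutoff_date = config$cutoff_date,
    matching_mode = config$matching_mode,
    include_flagged = config$include_flagged,
    test_word_boundary = config$test_word_boundary,
    deidentify = isTRUE(config$deidentify),
    salt_set = !is.null(config$salt)
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> ", x$out_dir, "\n", sep = "")
  print(x$report)
  invisible(x)
}
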
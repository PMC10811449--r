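# PHI masking and patient-identifier tokenization.
#
# Masking runs AFTER linkage: the pipeline links on real identifiers, then
# blanks their values while keeping every tag (keyword + VR) in place so the
# files remain standards-conformant. SOP/study/series instance UIDs are
# linkage-critical and may never appear in a masking policy.

.linkage_critical <- c("SOPInstanceUID", "StudyInstanceUID",
                       "SeriesInstanceUID", "ReferencedSOPInstanceUID",
                       "SOPClassUID", "TransferSyntaxUID")

#' Load and validate a PHI masking policy
#'
#' A policy is a YAML/JSON mapping from DICOM tag (keyword or
#' `(gggg,eeee)`) to a masking action: `blank`, `remove_value`, or
#' `fixed_literal:<text>`. Tag names are always preserved by masking; only
#' values change. Policies listing linkage-critical UIDs are rejected.
#'
#' @param path YAML (or JSON) policy file; default: the policy shipped with
#'   the package, which enumerates the standard attribute-confidentiality
#'   set (names, birthdate, other IDs, address, phone, institution,
#'   physicians/operators). Site-specific certification should edit it.
#' @return object of class `phi_policy`: data.frame `group`, `element`,
#'   `keyword`, `action`, `literal`.
#' @export
load_phi_policy <- function(path = system.file("extdata", "phi_policy.yaml",
                                               package = "oculink")) {
  spec <- yaml::read_yaml(path)
  rows <- lapply(names(spec), function(tag) {
    ge <- dcm_resolve_tag(tag)
    if (is.null(ge)) stop("PHI policy: unknown tag ", tag, call. = FALSE)
    action <- as.character(spec[[tag]])
    literal <- NA_character_
    if (startsWith(action, "fixed_literal")) {
      literal <- sub("^fixed_literal:?", "", action)
      action <- "fixed_literal"
    }
    if (!action %in% c("blank", "remove_value", "fixed_literal")) {
      stop("PHI policy: unknown action '", action, "' for ", tag,
           call. = FALSE)
    }
    kw <- dcm_lookup(ge[1], ge[2])$keyword
    if (kw %in% .linkage_critical) {
      stop("PHI policy must not mask linkage-critical UID tag ", kw,
           call. = FALSE)
    }
    df(group = ge[1], element = ge[2], keyword = kw, action = action,
       literal = literal)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phi_policy", "data.frame")
  out
}

#' Mask PHI values in a DICOM element tree
#'
#' Applies a masking policy at every nesting depth. Policy tags present in
#' the input stay present with keyword and VR untouched; their values are
#' blanked, emptied, or replaced by the policy literal. Non-policy tags pass
#' through byte-identical, so the multiset of `(tag, VR)` pairs is the same
#' before and after.
#'
#' @param dataset a `dcm_dataset` ([dcm_read()]) or bare element list.
#' @param policy a `phi_policy` ([load_phi_policy()]).
#' @return the dataset with masked values; an attribute `masked_count`
#'   carries the number of elements changed.
#' @export
mask_phi_tags <- function(dataset, policy) {
  elements <- if (inherits(dataset, "dcm_dataset")) dataset$elements else dataset
  pol_key <- sprintf("%04X%04X", policy$group, policy$element)
  n_masked <- 0L
  masked <- dcm_walk(elements, function(el, depth) {
    i <- match(dcm_tag_key(el$group, el$element), pol_key)
    if (is.na(i) || identical(el$vr, "SQ")) return(NULL)
    action <- policy$action[i]
    if (action == "fixed_literal" && !(el$vr %in% .dcm_string_vrs)) {
      action <- "blank"  # literal incompatible with binary/numeric VR
      message("fixed_literal incompatible with VR ", el$vr, " for ",
              dcm_tag_label(el$group, el$element), "; blanked instead")
    }
    el$value <- switch(action,
      blank = if (el$vr %in% .dcm_string_vrs) "" else
        vector(mode = .vr_mode(el$vr), length = 0L),
      remove_value = vector(mode = .vr_mode(el$vr), length = 0L),
      fixed_literal = policy$literal[i]
    )
    n_masked <<- n_masked + 1L
    el
  })
  if (inherits(dataset, "dcm_dataset")) {
    dataset$elements <- masked
  } else {
    dataset <- masked
  }
  attr(dataset, "masked_count") <- n_masked
  dataset
}

.vr_mode <- function(vr) {
  if (vr %in% .dcm_string_vrs) "character"
  else if (vr %in% c("US", "UL", "SS", "SL")) "integer"
  else if (vr %in% c("FL", "FD")) "double"
  else "raw"
}

#' Tokenize a patient identifier with a keyed one-way digest
#'
#' Deterministic pseudonymization: HMAC-SHA-256 of the identifier under a
#' secret salt, truncated to 128 bits (32 hex characters). The same
#' (identifier, salt) pair always yields the same token; different salts
#' yield unrelated tokens; the token reveals nothing about the input. An
#' empty salt is refused — it would make tokens reproducible by anyone.
#'
#' @param patient_id character vector of non-empty identifiers.
#' @param salt secret key (non-empty string).
#' @return character vector of 32-hex-character tokens.
#' @export
#' @examples
#' tokenize_patient_id("MRN-000123", salt = "example-secret")
tokenize_patient_id <- function(patient_id, salt) {
  if (!is.character(salt) || length(salt) != 1L || !nzchar(salt)) {
    stop("a non-empty salt is required for tokenization", call. = FALSE)
  }
  if (any(is.na(patient_id) | !nzchar(patient_id))) {
    stop("patient_id must be non-empty", call. = FALSE)
  }
  substr(as.character(openssl::sha256(patient_id, key = salt)), 1L, 32L)
}

#' De-identify a DICOM file
#'
#' Reads a Part-10 file, replaces PatientID with its token, masks every
#' policy tag at all depths, and rewrites the file (explicit VR little
#' endian). Pixel data that was skipped on read is re-emitted as a zero
#' payload of the original length.
#'
#' @param in_path,out_path input and output file paths.
#' @param policy a `phi_policy`.
#' @param salt tokenization secret ([tokenize_patient_id()]).
#' @return invisible list with `masked_count` and `token`.
#' @export
deidentify_dicom_file <- function(in_path, out_path, policy, salt) {
  ds <- dcm_read(in_path, skip_pixel_data = TRUE)
  token <- NA_character_
  ds$elements <- dcm_walk(ds$elements, function(el, depth) {
    if (el$group == 0x0010 && el$element == 0x0020 &&
        !is.null(el$value) && nzchar(el$value)) {
      token <<- tokenize_patient_id(el$value, salt)
      el$value <- token
      return(el)
    }
    NULL
  })
  ds <- mask_phi_tags(ds, policy)
  dcm_write(ds, out_path)
  invisible(list(masked_count = attr(ds, "masked_count"), token = token))
}

# Flatten every string value in an element tree (all depths); used by the
# leak-scan tests and the audit log.
dcm_string_values <- function(elements) {
  out <- character(0)
  dcm_walk(elements, function(el, depth) {
    if (!identical(el$vr, "SQ") && is.character(el$value)) {
      out <<- c(out, el$value)
    }
    NULL
  })
  out
}
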
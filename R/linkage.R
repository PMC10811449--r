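# Deterministic four-rule patient linkage with practice-location blocking
# and graph-based one-to-one resolution.
#
# Every rule requires exact agreement, after harmonization, on all of its
# fields, and every rule includes the practice location. A field missing on
# either side fails the rule — absence never wildcard-matches, which is what
# keeps patients with absent MRNs or names from mass-linking.

#' The four identifier-combination linkage rules
#'
#' * R1: location + name + birthdate + MRN
#' * R2: location + name + birthdate + gender
#' * R3: location + name + MRN
#' * R4: location + birthdate + MRN
#'
#' @return named list mapping rule id to its identifier fields.
#' @export
linkage_rules <- function() {
  list(
    R1 = c("location", "name", "birthdate", "mrn"),
    R2 = c("location", "name", "birthdate", "gender"),
    R3 = c("location", "name", "mrn"),
    R4 = c("location", "birthdate", "mrn")
  )
}

.field_equal <- function(a, b) {
  !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & a == b
}

#' Evaluate one linkage rule on a pair of normalized identities
#'
#' `TRUE` iff every field named by the rule is present on both sides and
#' equal after normalization. Location is satisfied when the imaging
#' `location_id` is among the registry patient's practice locations.
#'
#' @param img normalized imaging identity ([normalize_identity()]), with
#'   `location_id`.
#' @param reg normalized registry identity; `location_id` may hold several
#'   `|`-separated practice identifiers.
#' @param rule a rule id (`"R1"`..`"R4"`) or a character vector of fields.
#' @return logical.
#' @export
rule_satisfied <- function(img, reg, rule) {
  fields <- if (is.character(rule) && length(rule) == 1 &&
                rule %in% names(linkage_rules())) {
    linkage_rules()[[rule]]
  } else {
    rule
  }
  for (f in fields) {
    ok <- switch(f,
      location = {
        locs <- split_multi(reg$location_id %||% NA_character_)
        !is.na(img$location_id) && img$location_id %in% locs
      },
      name = .field_equal(img$name_norm, reg$name_norm),
      birthdate = .field_equal(img$birthdate, reg$birthdate),
      gender = .field_equal(img$gender, reg$gender),
      mrn = .field_equal(img$mrn_norm, reg$mrn_norm),
      stop("unknown rule field: ", f, call. = FALSE)
    )
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

#' Build candidate linkage edges between imaging and registry patients
#'
#' Candidate pairs are generated by blocking: a pair is compared only when
#' it shares a practice location *and* at least one of name, birthdate or
#' MRN. Because every rule requires location plus at least one of those
#' identifiers, blocking provably loses no edge relative to all-pairs
#' evaluation. All four rules are evaluated per candidate pair and an edge
#' is emitted when at least one holds; output order is canonical
#' (`patient_key`, `registry_id`), so the edge set is independent of input
#' row order.
#'
#' @param img_patients normalized imaging patient table; excluded patients
#'   are kept unless `include_flagged = FALSE`.
#' @param reg_patients normalized registry table (`registry_id`,
#'   `location_ids` as `|`-separated string, normalized identifier columns).
#' @param include_flagged include imaging patients carrying an exclusion
#'   flag (default `TRUE`: the initial linkage pass of the pipeline runs on
#'   the full archive, exclusions only shrink the cleaned-rate denominator).
#' @param name_components not used by the default full-name comparison;
#'   reserved switch (`"full"` or `"family_given"`) controlling how much of
#'   the normalized name must agree.
#' @return data.frame of edges: `patient_key`, `registry_id`, `R1`..`R4`
#'   logical columns, `rules` (e.g. `"R1+R3"`), `weight`.
#' @export
build_candidate_edges <- function(img_patients, reg_patients,
                                  include_flagged = TRUE,
                                  name_components = c("full", "family_given")) {
  name_components <- match.arg(name_components)
  imp <- img_patients
  if (!include_flagged && !is.null(imp$exclusion_flag)) {
    imp <- imp[is.na(imp$exclusion_flag), , drop = FALSE]
  }
  if (nrow(imp) == 0 || nrow(reg_patients) == 0) return(.empty_edges())

  img_name <- if (name_components == "family_given") {
    .first_two_tokens(imp$name_norm)
  } else imp$name_norm
  reg_name <- if (name_components == "family_given") {
    .first_two_tokens(reg_patients$name_norm)
  } else reg_patients$name_norm

  # expand registry rows to one row per practice location
  loc_list <- lapply(reg_patients$location_ids, split_multi)
  reg_idx <- rep(seq_len(nrow(reg_patients)), lengths(loc_list))
  reg_loc <- unlist(loc_list) %||% character(0)

  cand <- list()
  block_join <- function(img_key, reg_key) {
    iok <- which(!is.na(img_key) & nzchar(img_key) & !is.na(imp$location_id))
    rok <- which(!is.na(reg_key[reg_idx]) & nzchar(reg_key[reg_idx]))
    if (length(iok) == 0 || length(rok) == 0) return(NULL)
    a <- df(i = iok, k = paste(imp$location_id[iok], img_key[iok], sep = "\r"))
    b <- df(j = reg_idx[rok], k = paste(reg_loc[rok], reg_key[reg_idx][rok],
                                        sep = "\r"))
    m <- merge(a, b, by = "k")
    if (nrow(m) == 0) NULL else df(i = m$i, j = m$j)
  }
  cand[[1]] <- block_join(img_name, reg_name)
  cand[[2]] <- block_join(imp$birthdate, reg_patients$birthdate)
  cand[[3]] <- block_join(imp$mrn_norm, reg_patients$mrn_norm)
  pairs <- do.call(rbind, Filter(Negate(is.null), cand))
  if (is.null(pairs) || nrow(pairs) == 0) return(.empty_edges())
  pairs <- pairs[!duplicated(paste(pairs$i, pairs$j)), , drop = FALSE]

  i <- pairs$i; j <- pairs$j
  loc_ok <- mapply(function(ii, jj) imp$location_id[ii] %in% loc_list[[jj]],
                   i, j)
  name_ok <- .field_equal(img_name[i], reg_name[j])
  bd_ok <- .field_equal(imp$birthdate[i], reg_patients$birthdate[j])
  sex_ok <- .field_equal(imp$gender[i], reg_patients$gender[j])
  mrn_ok <- .field_equal(imp$mrn_norm[i], reg_patients$mrn_norm[j])

  r1 <- loc_ok & name_ok & bd_ok & mrn_ok
  r2 <- loc_ok & name_ok & bd_ok & sex_ok
  r3 <- loc_ok & name_ok & mrn_ok
  r4 <- loc_ok & bd_ok & mrn_ok
  any_rule <- r1 | r2 | r3 | r4

  edges <- df(
    patient_key = imp$patient_key[i][any_rule],
    registry_id = reg_patients$registry_id[j][any_rule],
    R1 = r1[any_rule], R2 = r2[any_rule], R3 = r3[any_rule],
    R4 = r4[any_rule]
  )
  edges$rules <- apply(edges[, c("R1", "R2", "R3", "R4")], 1L, function(z) {
    paste(c("R1", "R2", "R3", "R4")[z], collapse = "+")
  })
  edges$weight <- rowSums(edges[, c("R1", "R2", "R3", "R4")])
  edges <- edges[order(edges$patient_key, edges$registry_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

.first_two_tokens <- function(x) {
  vapply(strsplit(ifelse(is.na(x), "", x), " ", fixed = TRUE), function(t) {
    if (length(t) == 0) NA_character_ else paste(utils::head(t, 2),
                                                 collapse = " ")
  }, character(1))
}

.empty_edges <- function() {
  df(patient_key = character(0), registry_id = character(0),
     R1 = logical(0), R2 = logical(0), R3 = logical(0), R4 = logical(0),
     rules = character(0), weight = numeric(0))
}

#' Resolve candidate edges into a one-to-one patient mapping
#'
#' Treats the candidate edges as a bipartite graph (imaging patients vs
#' registry patients) and selects a matching that maximizes cardinality
#' first and total rule weight second. The resolution is deterministic and
#' depends only on the edge set, not on input order.
#'
#' @param edges edge table from [build_candidate_edges()].
#' @param mode `"max_cardinality"` (exact lexicographic optimum, default),
#'   `"greedy"` (heaviest edge first), or `"strict"` (as max_cardinality but
#'   components whose optimum is attained by more than one matching are
#'   dropped entirely).
#' @param all_patient_keys,all_registry_ids optional full key universes so
#'   that never-edged records appear among the unlinked.
#' @return object of class `link_result`: list with `links` (data.frame
#'   `patient_key`, `registry_id`, `rules`, `weight`),
#'   `unlinked_patient_keys`, `unlinked_registry_ids`, `mode`.
#' @export
resolve_matching <- function(edges, mode = c("max_cardinality", "greedy",
                                             "strict"),
                             all_patient_keys = NULL,
                             all_registry_ids = NULL) {
  mode <- match.arg(mode)
  assign_mode <- c(max_cardinality = "max_cardinality", greedy = "greedy",
                   strict = "strict")[[mode]]
  m <- bipartite_assign(edges$patient_key, edges$registry_id, edges$weight,
                        mode = assign_mode)
  key <- paste(m$left, m$right, sep = "\r")
  ekey <- paste(edges$patient_key, edges$registry_id, sep = "\r")
  rules <- edges$rules[match(key, ekey)]
  links <- df(patient_key = m$left, registry_id = m$right, rules = rules,
              weight = m$weight)
  universe_p <- unique(c(edges$patient_key, all_patient_keys))
  universe_r <- unique(c(edges$registry_id, all_registry_ids))
  structure(list(
    links = links,
    unlinked_patient_keys = sort(setdiff(universe_p, links$patient_key)),
    unlinked_registry_ids = sort(setdiff(universe_r, links$registry_id)),
    mode = mode
  ), class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat("<link_result> ", nrow(x$links), " links (mode: ", x$mode, ")\n",
      "  unlinked imaging patients: ", length(x$unlinked_patient_keys), "\n",
      "  unlinked registry patients: ", length(x$unlinked_registry_ids), "\n",
      sep = "")
  invisible(x)
}

#' Propagate patient-level links to images
#'
#' Every image belonging to a linked patient is considered linked and
#' carries that patient's registry id. Images referencing a patient key
#' absent from the link result's universe are dropped with a warning.
#'
#' @param result a `link_result`.
#' @param images image table.
#' @return `images` with `linked` (logical) and `registry_id` columns.
#' @export
link_images <- function(result, images) {
  known <- c(result$links$patient_key, result$unlinked_patient_keys)
  unknown <- !(images$patient_key %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " image(s) reference unknown patient keys; dropped",
            call. = FALSE)
    images <- images[!unknown, , drop = FALSE]
  }
  idx <- match(images$patient_key, result$links$patient_key)
  images$registry_id <- result$links$registry_id[idx]
  images$linked <- !is.na(idx)
  rownames(images) <- NULL
  images
}

#' Link key-measurement files to their source scans
#'
#' A key-measurement document (encapsulated PDF) is linked iff its
#' referenced SOP instance UID identifies a *linked* OCT image; it then
#' inherits that image's registry id. References to unlinked scans stay
#' unlinked; references to UIDs absent from the archive are counted as
#' dangling.
#'
#' @param measurements image-table subset with `is_measurement = TRUE`.
#' @param linked_images output of [link_images()].
#' @return `measurements` with `linked`, `registry_id` and `link_status`
#'   (`"linked"`, `"unlinked_scan"`, `"dangling"`) columns.
#' @export
link_measurements <- function(measurements, linked_images) {
  scans <- linked_images[!linked_images$is_measurement, , drop = FALSE]
  oct <- scans[scans$image_type == "OCT", , drop = FALSE]
  idx <- match(measurements$referenced_sop_uid, oct$sop_instance_uid)
  in_archive <- !is.na(idx)
  linked <- in_archive & oct$linked[ifelse(is.na(idx), 1L, idx)]
  linked[is.na(linked)] <- FALSE
  measurements$linked <- linked
  measurements$registry_id <- ifelse(linked, oct$registry_id[idx],
                                     NA_character_)
  measurements$link_status <- ifelse(linked, "linked",
                                     ifelse(in_archive, "unlinked_scan",
                                            "dangling"))
  rownames(measurements) <- NULL
  measurements
}
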
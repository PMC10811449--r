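# Independent oracles, deliberately written as naive brute force so they
# share no code path with the package internals they check.

# Best bipartite matching by exhaustive recursion over left nodes:
# maximize cardinality, then total weight. Edges given as a data.frame with
# character columns `left`, `right` and numeric `weight`.
oracle_best_matching <- function(edges) {
  lefts <- unique(edges$left)
  best <- list(card = 0L, weight = 0)
  recurse <- function(i, used_right, card, weight) {
    if (i > length(lefts)) {
      if (card > best$card ||
          (card == best$card && weight > best$weight + 1e-9)) {
        best <<- list(card = card, weight = weight)
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, used_right, card, weight)
    mine <- edges[edges$left == lefts[i] & !(edges$right %in% used_right), ,
                  drop = FALSE]
    for (k in seq_len(nrow(mine))) {
      recurse(i + 1L, c(used_right, mine$right[k]), card + 1L,
              weight + mine$weight[k])
    }
    invisible(NULL)
  }
  recurse(1L, character(0), 0L, 0)
  best
}

# Random bipartite instance with small integer weights.
random_bipartite <- function(n_left, n_right, p_edge) {
  grid <- expand.grid(l = seq_len(n_left), r = seq_len(n_right))
  keep <- runif(nrow(grid)) < p_edge
  g <- grid[keep, , drop = FALSE]
  data.frame(left = sprintf("P%02d", g$l), right = sprintf("R%02d", g$r),
             weight = sample(1:4, nrow(g), replace = TRUE),
             stringsAsFactors = FALSE)
}

# All-pairs candidate edges computed pair by pair through the public
# single-pair rule check (no blocking, no vectorized joins).
all_pairs_edges <- function(patients, registry) {
  rows <- list()
  for (i in seq_len(nrow(patients))) {
    img <- list(location_id = patients$location_id[i],
                name_norm = patients$name_norm[i],
                birthdate = patients$birthdate[i],
                gender = patients$gender[i],
                mrn_norm = patients$mrn_norm[i])
    for (j in seq_len(nrow(registry))) {
      reg <- list(location_id = registry$location_ids[j],
                  name_norm = registry$name_norm[j],
                  birthdate = registry$birthdate[j],
                  gender = registry$gender[j],
                  mrn_norm = registry$mrn_norm[j])
      sat <- vapply(names(linkage_rules()), function(r) {
        rule_satisfied(img, reg, r)
      }, logical(1))
      if (any(sat)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_key = patients$patient_key[i],
          registry_id = registry$registry_id[j],
          rules = paste(names(sat)[sat], collapse = "+"),
          weight = sum(sat), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(patient_key = character(0), registry_id = character(0),
                      rules = character(0), weight = numeric(0)))
  }
  out <- out[order(out$patient_key, out$registry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A small fully-pipelined cohort used by several test files.
small_cohort <- function(n = 120, seed = 404, ...) {
  generate_cohort(synthetic_config(n_patients = n, seed = seed, ...))
}

clean_config <- function(n, seed, ...) {
  synthetic_config(
    n_patients = n, seed = seed,
    p_missing = c(name = 0, birthdate = 0, gender = 0, mrn = 0),
    contamination = c(p_numeric_name = 0, p_abnormal_dob = 0,
                      p_test_name = 0),
    p_registry_absent = 0, ...)
}

# Normalize + flag + link a generated cohort; returns the pieces.
run_linkage <- function(cohort, mode = "max_cardinality",
                        include_flagged = TRUE) {
  cons <- consolidate_metadata_table(cohort$imaging)
  pat <- flag_exclusions(normalize_table(cons$patients))
  reg <- normalize_table(cohort$registry)
  edges <- build_candidate_edges(pat, reg, include_flagged = include_flagged)
  res <- resolve_matching(edges, mode = mode,
                          all_patient_keys = pat$patient_key,
                          all_registry_ids = reg$registry_id)
  list(patients = pat, registry = reg, images = cons$images,
       counts = cons$counts, edges = edges, result = res)
}
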
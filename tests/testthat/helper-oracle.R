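# Independent brute-force oracle for the template-fingerprint ranking:
# materialises every pairwise intersection with plain loops and base R,
# no shared code with the implementation.

oracle_candidates <- function(proteome_sets, ref_set, min_overlap = 1) {
  pid <- character(); ov <- integer(); jac <- double(); idn <- logical()
  for (p in names(proteome_sets)) {
    s <- proteome_sets[[p]]
    shared <- s[s %in% ref_set]
    u <- unique(c(s, ref_set))
    j <- if (length(u) == 0) 0 else length(shared) / length(u)
    if (length(shared) >= min_overlap) {
      pid <- c(pid, p); ov <- c(ov, length(shared)); jac <- c(jac, j)
      idn <- c(idn, j == 1 && length(shared) > 0)
    }
  }
  o <- order(-ov, -jac, pid)
  data.frame(protein_id = pid[o], overlap = ov[o], jaccard = jac[o],
             identical_sets = idn[o], stringsAsFactors = FALSE)
}

# Build hit-profile tibbles from named lists of template sets, with all
# E-values below the cutoff.
profiles_from_sets <- function(sets, e_value = 1e-6) {
  rows <- lapply(names(sets), function(p) {
    if (length(sets[[p]]) == 0) return(NULL)
    data.frame(query_id = p, template_id = sets[[p]], e_value = e_value)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(query_id = character(), template_id = character(),
                     e_value = double())
  }
  hit_profiles(df)
}

# Random small proteome: n proteins over a template universe of size m,
# each template kept with probability p_keep, random E-values straddling
# the cutoff.
random_hit_case <- function(n_proteins, n_templates, p_keep = 0.4) {
  universe <- paste0("T", seq_len(n_templates))
  rows <- list()
  for (i in seq_len(n_proteins)) {
    keep <- universe[runif(n_templates) < p_keep]
    if (length(keep) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      query_id = paste0("P", i), template_id = keep,
      e_value = 10^runif(length(keep), -8, 0))
  }
  ref_keep <- universe[runif(n_templates) < p_keep]
  if (length(ref_keep) == 0) ref_keep <- universe[1]
  ref <- data.frame(query_id = "REF", template_id = ref_keep,
                    e_value = 10^runif(length(ref_keep), -8, -4))
  list(proteome = if (length(rows) > 0) hit_profiles(do.call(rbind, rows)) else
         hit_profiles(data.frame(query_id = character(),
                                 template_id = character(), e_value = double())),
       reference = hit_profiles(ref))
}

# Compare implementation output with the oracle on significant sets.
expect_matches_oracle <- function(proteome, reference, cutoff = 1e-3) {
  ref_set <- significant_templates(reference, cutoff = cutoff)
  ids <- unique(proteome$query_id)
  sets <- lapply(ids, function(p) significant_templates(proteome, p, cutoff = cutoff))
  names(sets) <- ids
  want <- oracle_candidates(sets, ref_set)
  got <- shared_template_candidates(proteome, reference, cutoff = cutoff)
  expect_equal(got$protein_id, want$protein_id)
  expect_equal(got$overlap, want$overlap)
  expect_equal(got$jaccard, want$jaccard)
  expect_equal(got$identical_sets, want$identical_sets)
}
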
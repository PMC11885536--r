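test_that("hit tables parse, collapse duplicates to the best E-value, and reject bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\ttemplate_id\te_value",
               "# comment lines are ignored",
               "P1\tT1\t1e-5",
               "P1\tT1\t1e-4",
               "P1\tT2\t5e-3"), path)
  prof <- read_hit_table(path)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$e_value[prof$template_id == "T1"], 1e-5)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("query_id\ttemplate_id\te_value", empty)
  expect_equal(nrow(read_hit_table(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\ttemplate_id\te_value", "P1\tT1\tabc"), bad)
  expect_error(read_hit_table(bad), "malformed e_value 'abc' at data line 1")

  cols <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query\ttemplate_id\te_value", "P1\tT1\t1e-5"), cols)
  expect_error(read_hit_table(cols), "expected columns: query_id, template_id, e_value")

  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(prof, out)
  expect_equal(read_hit_table(out), prof)
})

test_that("significant templates honour the inclusive cutoff and are monotone in it", {
  p <- hit_profiles(data.frame(query_id = "P1",
                               template_id = c("T1", "T2", "T3"),
                               e_value = c(1e-5, 5e-3, 1e-3)))
  expect_equal(significant_templates(p, cutoff = 1e-3), c("T1", "T3"))
  expect_equal(significant_templates(p, cutoff = 1e-6), character(0))
  expect_equal(significant_templates(hit_profiles(
    data.frame(query_id = character(), template_id = character(),
               e_value = double()))), character(0))

  set.seed(41)
  for (i in 1:20) {
    prof <- hit_profiles(data.frame(query_id = "X",
                                    template_id = paste0("T", 1:15),
                                    e_value = 10^runif(15, -8, 1)))
    cuts <- sort(10^runif(4, -6, 0))
    sets <- lapply(cuts, function(cf) significant_templates(prof, cutoff = cf))
    for (k in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[k]] %in% sets[[k + 1]]))
    }
  }
})

test_that("shared-template ranking matches hand-computed overlap and Jaccard", {
  prot <- profiles_from_sets(list(P1 = c("T1", "T2", "T3"), P2 = "T4"))
  ref <- profiles_from_sets(list(REF = c("T2", "T3", "T5")))
  cand <- shared_template_candidates(prot, ref)
  expect_equal(cand$protein_id, "P1")
  expect_equal(cand$overlap, 2L)
  expect_equal(cand$jaccard, 0.5)
  expect_false(cand$identical_sets)
  expect_equal(cand$shared_templates, "T2;T3")

  # an exact copy of the reference list under another id ranks first
  prot2 <- profiles_from_sets(list(P1 = c("T1", "T2", "T3"),
                                   COPY = c("T2", "T3", "T5")))
  cand2 <- shared_template_candidates(prot2, ref)
  expect_equal(cand2$protein_id[1], "COPY")
  expect_true(cand2$identical_sets[1])
  expect_equal(cand2$jaccard[1], 1)

  # reference with nothing significant at the cutoff is an error
  weak_ref <- hit_profiles(data.frame(query_id = "REF", template_id = "T1",
                                      e_value = 0.5))
  expect_error(shared_template_candidates(prot, weak_ref),
               "reference hit list empty at cutoff")

  # the proteome copy of the reference itself is excluded by default
  prot3 <- profiles_from_sets(list(REF = c("T2", "T3", "T5"), P1 = "T2"))
  expect_false("REF" %in% shared_template_candidates(prot3, ref)$protein_id)
  expect_true("REF" %in% shared_template_candidates(prot3, ref,
                                                    exclude_self = FALSE)$protein_id)

  # min_overlap prunes weak candidates
  cand4 <- shared_template_candidates(prot, ref, min_overlap = 3)
  expect_equal(nrow(cand4), 0)
})

test_that("ranking equals the brute-force oracle on random small proteomes", {
  set.seed(99)
  for (i in 1:60) {
    case <- random_hit_case(sample(1:6, 1), sample(2:8, 1))
    expect_matches_oracle(case$proteome, case$reference)
  }
})

test_that("overlap is symmetric and never grows when the cutoff tightens", {
  set.seed(7)
  for (i in 1:15) {
    case <- random_hit_case(4, 8)
    ref_set <- significant_templates(case$reference, cutoff = 1e-3)
    for (p in unique(case$proteome$query_id)) {
      s <- significant_templates(case$proteome, p, cutoff = 1e-3)
      expect_equal(length(intersect(s, ref_set)), length(intersect(ref_set, s)))
    }
    loose <- shared_template_candidates(case$proteome, case$reference,
                                        cutoff = 1e-2, min_overlap = 0)
    tight <- shared_template_candidates(case$proteome, case$reference,
                                        cutoff = 1e-4, min_overlap = 0)
    for (p in tight$protein_id) {
      if (p %in% loose$protein_id) {
        expect_lte(tight$overlap[tight$protein_id == p],
                   loose$overlap[loose$protein_id == p])
      }
    }
  }
})

test_that("recovery benchmark finds perfectly planted homologs and flags degenerate plants", {
  spec <- hit_profile_sim_spec(n_proteins = 10, n_templates = 100,
                               ref_template_count = 10,
                               planted_ids = c("P0001", "P0002"),
                               overlap_fraction = 1, background_rate = 0,
                               seed = 11)
  rep <- recovery_benchmark(spec, top_k = 2)
  expect_equal(rep$recovery, 1.0)
  expect_equal(rep$background_above_worst_planted, 0L)
  expect_true(all(rep$candidates$identical_sets[1:2]))

  spec0 <- hit_profile_sim_spec(n_proteins = 10, n_templates = 100,
                                ref_template_count = 10,
                                planted_ids = c("P0001", "P0002", "P0003"),
                                overlap_fraction = 0, background_rate = 1,
                                seed = 11)
  expect_warning(rep0 <- recovery_benchmark(spec0, top_k = 3),
                 "indistinguishable")
  expect_true(rep0$indistinguishable)
})
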
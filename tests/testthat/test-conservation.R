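test_that("family assignment keeps the best sub-cutoff hit and flags ties", {
  h <- tibble::tibble(species_id = "sp1", subject_protein_id = "g1",
                      query_id = c("LolA1", "LolA2"),
                      e_value = c(1e-10, 1e-4))
  asg <- assign_families(h)
  expect_equal(nrow(asg), 1)
  expect_equal(asg$query_id, "LolA1")
  expect_false(asg$ambiguous)

  # everything above the cutoff: empty assignment
  weak <- tibble::tibble(species_id = "sp1", subject_protein_id = "g1",
                         query_id = "LolA1", e_value = 0.5)
  expect_equal(nrow(assign_families(weak)), 0)

  # exact tie goes to the lexicographically first family, flagged
  tie <- tibble::tibble(species_id = "sp1", subject_protein_id = "g1",
                        query_id = c("LolB1", "LolA1"), e_value = 1e-6)
  asg_tie <- assign_families(tie)
  expect_equal(asg_tie$query_id, "LolA1")
  expect_true(asg_tie$ambiguous)

  # each subject is assigned to exactly one family (partition property)
  set.seed(47)
  big <- tibble::tibble(
    species_id = sample(paste0("sp", 1:4), 60, replace = TRUE),
    subject_protein_id = sample(paste0("g", 1:10), 60, replace = TRUE),
    query_id = sample(c("LolA1", "LolA2", "LolB1"), 60, replace = TRUE),
    e_value = 10^runif(60, -12, 0))
  asg_big <- assign_families(big)
  expect_equal(anyDuplicated(paste(asg_big$species_id,
                                   asg_big$subject_protein_id)), 0)
})

test_that("presence matrices reproduce planted counts and handle edge shapes", {
  m <- matrix(c(1, 2, 0, 0, 1, 3), nrow = 3,
              dimnames = list(c("spA", "spB", "spC"), c("LolA1", "LolB1")))
  sim <- sim_species_hits(m, decoy_rate = 1, seed = 51)
  asg <- assign_families(sim$hits)
  pm <- build_presence_matrix(asg, rownames(m), colnames(m))
  expect_equal(pm$counts, matrix(as.integer(m), nrow = 3,
                                 dimnames = dimnames(m)))
  expect_equal(pm$total_homologs, sum(m))
  # count conservation: total equals distinct assigned subjects
  expect_equal(pm$total_homologs,
               nrow(unique(asg[c("species_id", "subject_protein_id")])))

  empty <- build_presence_matrix(assign_families(sim$hits, e_cutoff = 1e-40),
                                 paste0("s", 1:3), c("F1", "F2"))
  expect_equal(dim(empty$counts), c(3L, 2L))
  expect_true(all(empty$counts == 0))
  expect_equal(empty$total_homologs, 0)

  single <- assign_families(tibble::tibble(
    species_id = "spA", subject_protein_id = "g1",
    query_id = "LolB1", e_value = 1e-9))
  pm1 <- build_presence_matrix(single, "spA", "LolB1")
  expect_equal(as.integer(pm1$counts), 1L)
  expect_equal(pm1$total_homologs, 1)

  expect_error(build_presence_matrix(single, "other_sp", "LolB1"),
               "species not in the species list")
  pm_inc <- build_presence_matrix(single, "other_sp", "LolB1",
                                  allow_unknown_species = TRUE)
  expect_equal(pm_inc$counts["spA", "LolB1"], 1L)
})

test_that("raising the E-value cutoff never decreases any matrix cell", {
  set.seed(53)
  hits <- tibble::tibble(
    species_id = sample(paste0("sp", 1:5), 120, replace = TRUE),
    subject_protein_id = paste0("g", 1:120),
    query_id = sample(c("LolA1", "LolA2", "LolB1"), 120, replace = TRUE),
    e_value = 10^runif(120, -10, 1))
  species <- paste0("sp", 1:5)
  fams <- c("LolA1", "LolA2", "LolB1")
  grid <- c(1e-8, 1e-5, 1e-3, 1e-1, 1)
  mats <- lapply(grid, function(cf) {
    build_presence_matrix(assign_families(hits, e_cutoff = cf),
                          species, fams)$counts
  })
  for (k in seq_len(length(mats) - 1)) {
    expect_true(all(mats[[k + 1]] >= mats[[k]]))
  }
})

test_that("matrix summaries report coverage and the core chaperone/receptor complement", {
  counts <- matrix(c(1, 1, 1, 2, 0, 1, 0, 0, 1), nrow = 3,
                   dimnames = list(c("spA", "spB", "spC"),
                                   c("LolA1", "LolB1", "LolA2")))
  asg <- tibble::tibble(
    species_id = c("spA", "spA", "spA", "spB", "spC", "spC", "spC"),
    subject_protein_id = paste0("g", 1:7),
    query_id = c("LolA1", "LolB1", "LolB1", "LolA1", "LolA1", "LolB1", "LolA2"),
    e_value = 1e-9, ambiguous = FALSE)
  pm <- build_presence_matrix(asg, rownames(counts), colnames(counts))
  s <- matrix_summary(pm)
  expect_equal(s$coverage$coverage[s$coverage$family == "LolA1"], 1.0)
  expect_equal(s$coverage$coverage[s$coverage$family == "LolA2"], 1 / 3)
  expect_setequal(s$species_with_core, c("spA", "spC"))
  expect_equal(s$missing_species$LolB1, "spB")

  zero <- build_presence_matrix(assign_families(
    tibble::tibble(species_id = character(), subject_protein_id = character(),
                   query_id = character(), e_value = double())),
    c("spA", "spB"), c("F1", "F2"))
  sz <- matrix_summary(zero)
  expect_true(all(sz$coverage$coverage == 0))

  # wide + long TSV round trip
  wide <- withr::local_tempfile(fileext = ".tsv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(pm, wide, long)
  back <- readr::read_tsv(wide, show_col_types = FALSE)
  expect_equal(as.integer(as.matrix(back[, -1])), as.integer(pm$counts))
  expect_equal(nrow(readr::read_tsv(long, show_col_types = FALSE)), 9)
})
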
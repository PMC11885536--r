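test_that("generators are byte-identical given the same spec and seed", {
  spec_h <- hit_profile_sim_spec(15, 500, 10, planted_ids = "P0003",
                                 overlap_fraction = 0.6, seed = 5)
  expect_identical(sim_hit_profiles(spec_h), sim_hit_profiles(spec_h))

  spec_s <- sequence_sim_spec(6, seed = 5)
  a <- sim_sequences(spec_s); b <- sim_sequences(spec_s)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$truth, b$truth)

  spec_a <- abundance_sim_spec(30, de_fraction = 0.2, seed = 5)
  expect_identical(sim_abundance(spec_a), sim_abundance(spec_a))

  m <- matrix(1:4, 2, 2, dimnames = list(c("s1", "s2"), c("F1", "F2")))
  expect_identical(sim_species_hits(m, seed = 5), sim_species_hits(m, seed = 5))
})

test_that("planted homologs share exactly the prescribed number of reference templates", {
  # full overlap, no background: planted significant set equals the reference set
  spec1 <- hit_profile_sim_spec(5, 200, 12, planted_ids = "P0001",
                                overlap_fraction = 1, background_rate = 0, seed = 2)
  sim1 <- sim_hit_profiles(spec1)
  expect_setequal(significant_templates(sim1$proteome, "P0001"),
                  significant_templates(sim1$reference))
  expect_equal(nrow(sim1$reference), 12)
  expect_true(all(sim1$reference$e_value <= 1e-4))

  # no planted homologs: truth table has zero planted rows
  spec2 <- hit_profile_sim_spec(10, 200, 12, planted_ids = character(),
                                overlap_fraction = 0, seed = 2)
  expect_equal(sum(sim_hit_profiles(spec2)$truth$planted), 0)

  # rho = 0.5 with 20 reference templates: exactly 10 shared per planted protein
  spec3 <- hit_profile_sim_spec(20, 1000, 20,
                                planted_ids = c("P0001", "P0002", "P0003"),
                                overlap_fraction = 0.5, seed = 7)
  sim3 <- sim_hit_profiles(spec3)
  ref_set <- significant_templates(sim3$reference)
  for (p in spec3$planted_ids) {
    expect_equal(length(intersect(significant_templates(sim3$proteome, p),
                                  ref_set)), 10)
  }

  # overlap rounding to zero with planted ids is warned and noted
  spec4 <- hit_profile_sim_spec(5, 200, 12, planted_ids = "P0001",
                                overlap_fraction = 0, seed = 2)
  expect_warning(sim4 <- sim_hit_profiles(spec4), "indistinguishable")
  expect_match(sim4$truth$note[sim4$truth$planted], "indistinguishable")

  # truth-table consistency: one row per emitted protein id
  expect_setequal(sim3$truth$protein_id, sprintf("P%04d", 1:20))
  expect_true(all(unique(sim3$proteome$query_id) %in% sim3$truth$protein_id))
})

test_that("sequence generator plants recoverable signal classes", {
  rules <- annotation_rules()

  spii <- sim_sequences(sequence_sim_spec(5, c(SPII = 1), seed = 8), rules)
  for (i in 1:5) {
    ann <- classify_signal(as.character(spii$sequences[[i]]), rules)
    expect_equal(ann$sp_class, "SPII")
    expect_equal(ann$cleavage_pos, spii$truth$cleavage_pos[i])
    expect_equal(substr(as.character(spii$sequences[[i]]),
                        ann$cleavage_pos, ann$cleavage_pos), "C")
  }

  none <- sim_sequences(sequence_sim_spec(5, c(NONE = 1), seed = 8), rules)
  for (i in 1:5) {
    expect_equal(classify_signal(as.character(none$sequences[[i]]), rules)$sp_class,
                 "NONE")
  }

  zero <- sim_sequences(sequence_sim_spec(0, c(NONE = 1), seed = 8), rules)
  expect_equal(length(zero$sequences), 0)
  expect_equal(nrow(zero$truth), 0)

  expect_error(sequence_sim_spec(5, c(NONE = -0.5, SPII = 1.5)),
               "non-negative")
  expect_error(sequence_sim_spec(5, c(NONE = 0.4)), "sum to 1")
  expect_error(sequence_sim_spec(5, length_range = c(30, 100)), "minimum is 50")
})

test_that("abundance generator reproduces the planted effect and the stated noise model", {
  expect_error(abundance_sim_spec(10, n_replicates_per_group = 1),
               "n_replicates_per_group")

  one <- sim_abundance(abundance_sim_spec(1, de_fraction = 0,
                                          replicate_sd = 0.1, seed = 3))
  expect_equal(nrow(one$summary), 1)

  # planted-effect recovery: mean observed log2 FC of planted proteins -> delta
  spec <- abundance_sim_spec(400, n_replicates_per_group = 5,
                             de_fraction = 0.5, log2_shift = 2,
                             replicate_sd = 0.3, seed = 9)
  sim <- sim_abundance(spec)
  de <- sim$truth$is_de
  obs <- log2(sim$summary$fold_change[de])
  tol <- 3 * spec$replicate_sd / sqrt(sum(de) * spec$n_replicates_per_group)
  expect_lt(abs(mean(obs) - spec$log2_shift), max(tol, 0.05))

  # replicate table and truth table are keyed consistently
  expect_identical(sim$replicates$protein_id, sim$summary$protein_id)
  expect_identical(sim$summary$protein_id, sim$truth$protein_id)
  expect_equal(ncol(sim$replicates), 1 + 2 * spec$n_replicates_per_group)
})

test_that("vectorised Welch p-values agree with stats::t.test", {
  set.seed(13)
  a <- matrix(rnorm(5 * 6, 20, 1), nrow = 5)
  b <- matrix(rnorm(5 * 6, 21, 2), nrow = 5)
  p_vec <- lolkit:::welch_p(a, b)
  for (i in 1:5) {
    expect_equal(p_vec[i], t.test(a[i, ], b[i, ])$p.value, tolerance = 1e-12)
  }
})

test_that("species-hit generator plants recoverable counts and decoys above the cutoff", {
  m <- matrix(c(2, 0, 1, 3), 2, 2,
              dimnames = list(c("spA", "spB"), c("LolA1", "LolB1")))
  sim <- sim_species_hits(m, decoy_rate = 2, seed = 21)
  sig <- sim$hits[sim$hits$e_value <= 1e-3, ]
  expect_equal(nrow(sig), sum(m))
  expect_true(any(sim$hits$e_value > 1e-3)) # decoys present at this seed
  counts <- table(factor(sig$species_id, rownames(m)),
                  factor(sig$query_id, colnames(m)))
  expect_equal(as.integer(counts), as.integer(m))
})
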
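# Seeded synthetic-data generators with planted ground truth. Each generator
# takes a validated spec object carrying a single integer seed; all
# randomness flows from that one seed, so identical spec => identical output.

# log-uniform draw: spans orders of magnitude like real search E-values
rlog_uniform <- function(n, range) {
  10^runif(n, log10(range[1]), log10(range[2]))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single number in [0, 1]", call. = FALSE)
  }
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop(name, " must be an integer >= ", min, call. = FALSE)
  }
}

# ---------------------------------------------------------------------------
# Hit-profile simulation

#' Simulation spec for template hit lists
#'
#' Describes a synthetic proteome of template hit lists over a template
#' universe, with a reference protein and planted homologs that share a
#' controlled fraction of the reference's significant templates.
#'
#' @param n_proteins Number of proteome proteins (planted homologs included).
#' @param n_templates Template universe size.
#' @param ref_template_count Number of significant templates in the
#'   reference's hit list.
#' @param planted_ids Character vector of proteome protein ids to plant as
#'   homologs; must be a subset of the generated ids `P0001 ... P<n>`.
#' @param overlap_fraction Fraction (rho, in `[0, 1]`) of the reference's
#'   significant templates shared by each planted homolog; each planted
#'   protein shares exactly `ceiling(rho * ref_template_count)` templates.
#' @param background_rate Expected number of significant templates drawn by
#'   each background protein (Poisson), uniformly from the whole universe.
#' @param evalue_sig_range E-value interval for significant hits (drawn
#'   log-uniformly); must lie entirely below `evalue_nonsig_range`.
#' @param evalue_nonsig_range E-value interval for non-significant noise hits.
#' @param nonsig_rate Expected non-significant noise hits per protein
#'   (Poisson); cosmetic realism, never enters significant sets.
#' @param reference_id Id given to the reference profile.
#' @param seed Single integer seed; all randomness flows from it.
#' @return A validated spec object of class `hit_profile_sim_spec`.
#' @export
hit_profile_sim_spec <- function(n_proteins, n_templates, ref_template_count,
                                 planted_ids = character(),
                                 overlap_fraction = 0.5,
                                 background_rate = 1,
                                 evalue_sig_range = c(1e-30, 1e-4),
                                 evalue_nonsig_range = c(1e-2, 10),
                                 nonsig_rate = 2,
                                 reference_id = "REF",
                                 seed = 1L) {
  check_count(n_proteins, "n_proteins", min = 0)
  check_count(n_templates, "n_templates", min = 1)
  check_count(ref_template_count, "ref_template_count", min = 1)
  if (ref_template_count > n_templates) {
    stop("ref_template_count cannot exceed n_templates", call. = FALSE)
  }
  check_prob(overlap_fraction, "overlap_fraction")
  stopifnot(background_rate >= 0, nonsig_rate >= 0)
  stopifnot(length(evalue_sig_range) == 2, length(evalue_nonsig_range) == 2,
            all(evalue_sig_range > 0), all(evalue_nonsig_range > 0))
  if (max(evalue_sig_range) >= min(evalue_nonsig_range)) {
    stop("evalue_sig_range must lie entirely below evalue_nonsig_range",
         call. = FALSE)
  }
  ids <- sprintf("P%04d", seq_len(n_proteins))
  if (!all(planted_ids %in% ids)) {
    stop("planted_ids must be a subset of the generated protein ids (",
         "P0001 ... P", sprintf("%04d", n_proteins), ")", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_templates = as.integer(n_templates),
                 ref_template_count = as.integer(ref_template_count),
                 planted_ids = unique(planted_ids),
                 overlap_fraction = overlap_fraction,
                 background_rate = background_rate,
                 evalue_sig_range = sort(evalue_sig_range),
                 evalue_nonsig_range = sort(evalue_nonsig_range),
                 nonsig_rate = nonsig_rate,
                 reference_id = reference_id,
                 seed = as.integer(seed)),
            class = "hit_profile_sim_spec")
}

#' Generate synthetic template hit lists with planted homologs
#'
#' Builds a reference hit profile with exactly `ref_template_count`
#' significant templates; each planted homolog's significant set shares
#' exactly `ceiling(rho * ref_template_count)` templates with the reference
#' (drawn without replacement), plus Poisson background templates from
#' outside the reference set; background proteins draw Poisson
#' (`background_rate`) significant templates uniformly from the whole
#' universe, with no guaranteed overlap. Every protein additionally carries
#' Poisson(`nonsig_rate`) above-cutoff noise hits. Deterministic given the
#' spec seed.
#'
#' When the planted overlap rounds to zero templates with a non-empty planted
#' list, the planted homologs are statistically indistinguishable from
#' background; a warning is recorded in the truth table (`note` column and
#' an `indistinguishable` attribute).
#'
#' @param spec A [hit_profile_sim_spec()].
#' @return List with `reference` (hit-profile tibble), `proteome`
#'   (hit-profile tibble) and `truth` (tibble: `protein_id`, `planted`,
#'   `n_shared_templates`, `note`).
#' @export
#' @examples
#' spec <- hit_profile_sim_spec(n_proteins = 20, n_templates = 1000,
#'                              ref_template_count = 20,
#'                              planted_ids = c("P0001", "P0002"),
#'                              overlap_fraction = 0.5, seed = 7)
#' sim <- sim_hit_profiles(spec)
#' head(sim$truth)
sim_hit_profiles <- function(spec) {
  stopifnot(inherits(spec, "hit_profile_sim_spec"))
  set.seed(spec$seed)
  universe <- sprintf("T%05d", seq_len(spec$n_templates))
  ids <- sprintf("P%04d", seq_len(spec$n_proteins))

  ref_set <- sort(sample(universe, spec$ref_template_count))
  reference <- tibble(query_id = spec$reference_id,
                      template_id = ref_set,
                      e_value = rlog_uniform(length(ref_set), spec$evalue_sig_range))

  n_shared <- as.integer(ceiling(spec$overlap_fraction * spec$ref_template_count))
  indistinct <- length(spec$planted_ids) > 0 && n_shared == 0
  if (indistinct) {
    warning("planted overlap rounds to 0 templates: planted homologs are ",
            "indistinguishable from background", call. = FALSE)
  }

  non_ref <- setdiff(universe, ref_set)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    if (pid %in% spec$planted_ids) {
      shared <- if (n_shared > 0) sample(ref_set, n_shared) else character()
      n_bg <- rpois(1, spec$background_rate)
      bg <- if (n_bg > 0) sample(non_ref, min(n_bg, length(non_ref))) else character()
      sig <- unique(c(shared, bg))
    } else {
      n_bg <- rpois(1, spec$background_rate)
      sig <- if (n_bg > 0) sample(universe, min(n_bg, length(universe))) else character()
    }
    n_noise <- rpois(1, spec$nonsig_rate)
    noise_pool <- setdiff(universe, sig)
    noise <- if (n_noise > 0) sample(noise_pool, min(n_noise, length(noise_pool))) else character()
    rows[[i]] <- tibble(
      query_id = pid,
      template_id = c(sig, noise),
      e_value = c(rlog_uniform(length(sig), spec$evalue_sig_range),
                  rlog_uniform(length(noise), spec$evalue_nonsig_range)))
  }
  proteome <- bind_rows(rows)
  if (nrow(proteome) > 0) proteome <- hit_profiles(proteome)

  truth <- tibble(protein_id = ids,
                  planted = ids %in% spec$planted_ids,
                  n_shared_templates = ifelse(ids %in% spec$planted_ids,
                                              n_shared, NA_integer_),
                  note = ifelse(ids %in% spec$planted_ids & indistinct,
                                "planted but indistinguishable (overlap rounds to 0)",
                                ""))
  attr(truth, "indistinguishable") <- indistinct
  list(reference = reference, proteome = proteome, truth = truth)
}

# ---------------------------------------------------------------------------
# Sequence simulation

#' Simulation spec for signal-peptide sequences
#'
#' @param n_seqs Number of sequences to generate.
#' @param class_probabilities Named numeric vector over
#'   `c("NONE", "SPI", "SPII", "SPII_LES")`, summing to 1. Missing classes
#'   get probability 0.
#' @param length_range Integer interval of sequence lengths (minimum 50).
#' @param seed Single integer seed.
#' @return A validated spec object of class `sequence_sim_spec`.
#' @export
sequence_sim_spec <- function(n_seqs,
                              class_probabilities = c(NONE = 0.25, SPI = 0.25,
                                                      SPII = 0.25, SPII_LES = 0.25),
                              length_range = c(80, 200),
                              seed = 1L) {
  check_count(n_seqs, "n_seqs", min = 0)
  classes <- c("NONE", "SPI", "SPII", "SPII_LES")
  if (is.null(names(class_probabilities)) ||
      !all(names(class_probabilities) %in% classes)) {
    stop("class_probabilities must be named with a subset of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (any(class_probabilities < 0)) {
    stop("class probabilities must be non-negative", call. = FALSE)
  }
  p <- setNames(numeric(length(classes)), classes)
  p[names(class_probabilities)] <- class_probabilities
  if (abs(sum(p) - 1) > 1e-9) {
    stop("class probabilities must sum to 1", call. = FALSE)
  }
  stopifnot(length(length_range) == 2)
  if (min(length_range) < 50) {
    stop("length_range minimum is 50 residues", call. = FALSE)
  }
  structure(list(n_seqs = as.integer(n_seqs), class_probabilities = p,
                 length_range = as.integer(sort(length_range)),
                 seed = as.integer(seed)),
            class = "sequence_sim_spec")
}

rand_residues <- function(n, alphabet = amino_acids()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# One sequence of a given planted class, rejection-sampled until the
# rule-based classifier agrees with the plant (guaranteeing truth-table
# consistency by construction). Returns list(seq, cleavage_pos).
sim_one_sequence <- function(class, len, rules) {
  no_cys <- setdiff(amino_acids(), "C")
  hydroph <- c("L", "I", "V", "F", "M", "A")
  repeat {
    if (class == "NONE") {
      seq <- rand_residues(len)
      ann <- classify_signal(seq, rules)
      if (ann$sp_class == "NONE") return(list(seq = seq, cleavage_pos = NA_integer_))
    } else if (class == "SPI") {
      # M + charged n-region + hydrophobic h-region + spacer + A-x-A + mature
      head_ <- paste0("M", rand_residues(2, c("K", "R")),
                      rand_residues(9, hydroph),
                      rand_residues(2, setdiff(no_cys, hydroph)),
                      "A", rand_residues(1, no_cys), "A")
      cleave <- nchar(head_) + 1L
      seq <- paste0(head_, rand_residues(len - nchar(head_)))
      ann <- classify_signal(seq, rules)
      if (ann$sp_class == "SPI" && identical(ann$cleavage_pos, cleave)) {
        return(list(seq = seq, cleavage_pos = cleave))
      }
    } else { # SPII or SPII_LES
      h_len <- sample(6:25, 1)
      lipobox <- paste0(rand_residues(1, strsplit("LVIFMSTAG", "")[[1]]),
                        rand_residues(1, strsplit("ASTVIG", "")[[1]]),
                        rand_residues(1, strsplit("GAS", "")[[1]]), "C")
      head_ <- paste0("M", rand_residues(2, c("K", "R")),
                      rand_residues(h_len, hydroph), lipobox)
      cys <- nchar(head_)
      mature <- if (class == "SPII_LES") {
        paste0(rules$les_example_motif, rand_residues(len - cys - nchar(rules$les_example_motif)))
      } else {
        rand_residues(len - cys)
      }
      seq <- paste0(head_, mature)
      ann <- classify_signal(seq, rules)
      if (ann$sp_class != "SPII" || !identical(ann$cleavage_pos, cys)) next
      ann <- flag_les(ann, seq, rules)
      want_les <- class == "SPII_LES"
      if (identical(ann$les_present, want_les)) {
        return(list(seq = seq, cleavage_pos = cys))
      }
    }
  }
}

#' Generate synthetic sequences with planted signal-peptide classes
#'
#' Plants SPI signal peptides (charged n-region, hydrophobic h-region,
#' A-x-A cleavage motif), SPII lipoprotein signals (lipobox ending in the
#' lipidated Cys), SPII-LES surface lipoproteins (the configured LES motif
#' immediately after the Cys), and NONE sequences rejection-sampled to match
#' neither rule. Every emitted sequence is verified against the same
#' rule set used by [classify_signal()], so the truth table is exact by
#' construction. Deterministic given the spec seed.
#'
#' @param spec A [sequence_sim_spec()].
#' @param rules Annotation rules shared with the classifier; default
#'   [annotation_rules()].
#' @return List with `sequences` (a [Biostrings::AAStringSet]) and `truth`
#'   (tibble: `protein_id`, `class`, `cleavage_pos`, `les_present`).
#' @export
#' @examples
#' sim <- sim_sequences(sequence_sim_spec(5, c(SPII = 1), seed = 3))
#' sim$truth
sim_sequences <- function(spec, rules = annotation_rules()) {
  stopifnot(inherits(spec, "sequence_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_seqs
  ids <- sprintf("S%04d", seq_len(n))
  if (n == 0) {
    return(list(sequences = Biostrings::AAStringSet(),
                truth = tibble(protein_id = character(), class = character(),
                               cleavage_pos = integer(), les_present = logical())))
  }
  classes <- sample(names(spec$class_probabilities), n, replace = TRUE,
                    prob = spec$class_probabilities)
  lens <- sample(seq(spec$length_range[1], spec$length_range[2]), n, replace = TRUE)
  seqs <- character(n)
  cleav <- integer(n)
  for (i in seq_len(n)) {
    one <- sim_one_sequence(classes[i], lens[i], rules)
    seqs[i] <- one$seq
    cleav[i] <- one$cleavage_pos
  }
  aa <- Biostrings::AAStringSet(setNames(seqs, ids))
  truth <- tibble(protein_id = ids, class = classes,
                  cleavage_pos = cleav,
                  les_present = classes == "SPII_LES")
  list(sequences = aa, truth = truth)
}

# ---------------------------------------------------------------------------
# Abundance simulation

#' Simulation spec for label-free abundance tables
#'
#' Two-condition (A = wild type, B = mutant) replicate design. Per-protein
#' baseline log2 abundance is Normal(20, 1) across proteins; replicate
#' values are Normal(baseline, `replicate_sd`), with `log2_shift` added in
#' condition B for planted differentially abundant proteins.
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates_per_group Replicates per condition (minimum 2).
#' @param de_fraction Fraction of proteins with a planted shift.
#' @param log2_shift Planted log2 effect size (condition B minus A).
#' @param replicate_sd Replicate noise standard deviation (log2 scale, > 0).
#' @param class_probabilities Named probabilities over localization classes
#'   `c("NO_SP", "SPI", "SPII", "SPII_LES")`.
#' @param category_labels Functional-category codes to sample uniformly
#'   (default COG-style letters).
#' @param seed Single integer seed.
#' @return A validated spec object of class `abundance_sim_spec`.
#' @export
abundance_sim_spec <- function(n_proteins, n_replicates_per_group = 5,
                               de_fraction = 0.1, log2_shift = 2,
                               replicate_sd = 0.5,
                               class_probabilities = c(NO_SP = 0.4, SPI = 0.3,
                                                       SPII = 0.2, SPII_LES = 0.1),
                               category_labels = c("C", "E", "G", "M", "P", "S", "UNKNOWN"),
                               seed = 1L) {
  check_count(n_proteins, "n_proteins", min = 0)
  check_count(n_replicates_per_group, "n_replicates_per_group", min = 2)
  check_prob(de_fraction, "de_fraction")
  if (!is.numeric(replicate_sd) || replicate_sd <= 0) {
    stop("replicate_sd must be > 0", call. = FALSE)
  }
  loc_classes <- c("NO_SP", "SPI", "SPII", "SPII_LES")
  if (is.null(names(class_probabilities)) ||
      !all(names(class_probabilities) %in% loc_classes)) {
    stop("class_probabilities must be named with a subset of: ",
         paste(loc_classes, collapse = ", "), call. = FALSE)
  }
  p <- setNames(numeric(length(loc_classes)), loc_classes)
  p[names(class_probabilities)] <- class_probabilities
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    stop("class probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(length(category_labels) >= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 de_fraction = de_fraction, log2_shift = log2_shift,
                 replicate_sd = replicate_sd, class_probabilities = p,
                 category_labels = as.character(category_labels),
                 seed = as.integer(seed)),
            class = "abundance_sim_spec")
}

# Vectorised Welch two-sample t-test on two matrices (rows = proteins).
# Returns two-sided p-values; agrees with stats::t.test (var.equal = FALSE).
welch_p <- function(a, b) {
  ra <- ncol(a); rb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / ra + vb / rb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / ra)^2 / (ra - 1) + (vb / rb)^2 / (rb - 1))
  2 * pt(abs(tstat), df, lower.tail = FALSE)
}

#' Generate a synthetic two-condition abundance table
#'
#' Emits a replicate-level log2 abundance table, a per-protein summary with
#' linear-scale fold change (mean B / mean A) and a Welch two-sample p-value,
#' and a truth table recording the planted differential-abundance flag,
#' localization class and functional category. Deterministic given the spec
#' seed.
#'
#' @param spec An [abundance_sim_spec()].
#' @return List with `replicates` (tibble: `protein_id`, `A1..An`, `B1..Bn`,
#'   log2 scale), `summary` (tibble: `protein_id`, `fold_change`, `p_value`,
#'   `significance`, `loc_class`, `category`) and `truth` (tibble:
#'   `protein_id`, `is_de`, `log2_shift`, `loc_class`, `category`).
#' @export
#' @examples
#' sim <- sim_abundance(abundance_sim_spec(10, de_fraction = 0.2, seed = 2))
#' sim$summary
sim_abundance <- function(spec) {
  stopifnot(inherits(spec, "abundance_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  r <- spec$n_replicates_per_group
  ids <- sprintf("Q%05d", seq_len(n))
  empty <- list(
    replicates = tibble(protein_id = character()),
    summary = tibble(protein_id = character(), fold_change = double(),
                     p_value = double(), significance = double(),
                     loc_class = character(), category = character()),
    truth = tibble(protein_id = character(), is_de = logical(),
                   log2_shift = double(), loc_class = character(),
                   category = character()))
  if (n == 0) return(empty)

  is_de <- runif(n) < spec$de_fraction
  baseline <- rnorm(n, mean = 20, sd = 1)
  a <- matrix(rnorm(n * r, mean = baseline, sd = spec$replicate_sd), nrow = n)
  b <- matrix(rnorm(n * r, mean = baseline + ifelse(is_de, spec$log2_shift, 0),
                    sd = spec$replicate_sd), nrow = n)
  loc <- sample(names(spec$class_probabilities), n, replace = TRUE,
                prob = spec$class_probabilities)
  cat_ <- sample(spec$category_labels, n, replace = TRUE)

  fc <- rowMeans(2^b) / rowMeans(2^a)
  p <- welch_p(a, b)

  reps <- as_tibble(cbind(as.data.frame(a), as.data.frame(b)),
                    .name_repair = "minimal")
  names(reps) <- c(paste0("A", seq_len(r)), paste0("B", seq_len(r)))
  reps <- tibble(protein_id = ids) %>% dplyr::bind_cols(reps)

  list(replicates = reps,
       summary = tibble(protein_id = ids, fold_change = fc, p_value = p,
                        significance = significance_from_p(p),
                        loc_class = loc, category = cat_),
       truth = tibble(protein_id = ids, is_de = is_de,
                      log2_shift = ifelse(is_de, spec$log2_shift, 0),
                      loc_class = loc, category = cat_))
}

# ---------------------------------------------------------------------------
# Species-hit simulation (conservation inputs)

#' Generate synthetic cross-species homology hit tables
#'
#' Builds a hit table for the conservation stage from a planted
#' species-by-family count matrix: each planted homolog receives one hit to
#' its family with an E-value in the significant range, plus optional decoy
#' hits above the cutoff that [assign_families()] must discard.
#' Deterministic given the seed.
#'
#' @param truth_counts Integer matrix of planted homolog counts; rownames are
#'   species ids, colnames are query-family ids.
#' @param evalue_sig_range E-value interval for planted hits (log-uniform).
#' @param evalue_nonsig_range E-value interval for decoy hits.
#' @param decoy_rate Expected above-cutoff decoy hits per species (Poisson).
#' @param seed Single integer seed.
#' @return List with `hits` (tibble: `species_id`, `subject_protein_id`,
#'   `query_id`, `e_value`) and `truth_counts` (the input matrix).
#' @export
#' @examples
#' m <- matrix(c(1, 2, 0, 1), 2, 2,
#'             dimnames = list(c("sp1", "sp2"), c("LolA1", "LolB1")))
#' sim_species_hits(m, seed = 4)$hits
sim_species_hits <- function(truth_counts,
                             evalue_sig_range = c(1e-30, 1e-4),
                             evalue_nonsig_range = c(1e-2, 10),
                             decoy_rate = 1, seed = 1L) {
  stopifnot(is.matrix(truth_counts), !is.null(rownames(truth_counts)),
            !is.null(colnames(truth_counts)),
            all(truth_counts >= 0), all(truth_counts == floor(truth_counts)))
  if (max(evalue_sig_range) >= min(evalue_nonsig_range)) {
    stop("evalue_sig_range must lie entirely below evalue_nonsig_range",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  species <- rownames(truth_counts)
  families <- colnames(truth_counts)
  rows <- list()
  k <- 0
  for (s in species) {
    subj <- 0
    for (f in families) {
      cnt <- truth_counts[s, f]
      if (cnt > 0) {
        for (j in seq_len(cnt)) {
          subj <- subj + 1
          k <- k + 1
          rows[[k]] <- tibble(species_id = s,
                              subject_protein_id = sprintf("%s_g%03d", s, subj),
                              query_id = f,
                              e_value = rlog_uniform(1, evalue_sig_range))
        }
      }
    }
    n_decoy <- rpois(1, decoy_rate)
    for (j in seq_len(n_decoy)) {
      subj <- subj + 1
      k <- k + 1
      rows[[k]] <- tibble(species_id = s,
                          subject_protein_id = sprintf("%s_g%03d", s, subj),
                          query_id = sample(families, 1),
                          e_value = rlog_uniform(1, evalue_nonsig_range))
    }
  }
  hits <- if (k > 0) bind_rows(rows) else {
    tibble(species_id = character(), subject_protein_id = character(),
           query_id = character(), e_value = double())
  }
  list(hits = hits, truth_counts = truth_counts)
}
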
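# Sequence-level physico-chemical profiling of candidate homologs:
# Eisenberg hydrophobicity, residue composition, Henderson-Hasselbalch net
# charge, and the direction of the hydrophobic gradient between a
# donor/acceptor pair (the periplasmic chaperone hands its lipoprotein cargo
# "downhill" to a more hydrophobic acceptor). Regions of interest (cavity
# faces etc.) are user-supplied residue selections; no structure is computed.

#' Parse a residue selection
#'
#' Selections address 1-based positions of a sequence, written either as the
#' keyword `"ALL"` or as a comma-separated list of indices and `a-b` ranges
#' (e.g. `"1-10,25,40-42"`).
#'
#' @param positions `"ALL"`, a numeric vector of 1-based indices, or a
#'   comma/range string.
#' @param seq_length Sequence length used for validation.
#' @return Sorted integer vector of unique positions.
#' @export
#' @examples
#' parse_selection("1-3,7", 10)
parse_selection <- function(positions, seq_length) {
  if (is.character(positions) && length(positions) == 1 &&
      toupper(positions) == "ALL") {
    return(seq_len(seq_length))
  }
  if (is.character(positions)) {
    parts <- strsplit(positions, ",", fixed = TRUE)[[1]]
    idx <- unlist(lapply(trimws(parts), function(p) {
      if (grepl("^\\d+-\\d+$", p)) {
        ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
        seq(ab[1], ab[2])
      } else if (grepl("^\\d+$", p)) {
        as.integer(p)
      } else {
        stop("cannot parse selection element '", p, "'", call. = FALSE)
      }
    }))
  } else {
    idx <- as.integer(positions)
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0) stop("selection is empty", call. = FALSE)
  if (any(idx < 1) || any(idx > seq_length)) {
    stop("selection positions out of range 1..", seq_length, call. = FALSE)
  }
  idx
}

#' Composition profile of a residue selection
#'
#' Per-residue frequencies over the 20 canonical residues plus the summary
#' statistics used to compare candidate chaperones and receptors: the
#' hydrophobic fraction (residues with positive Eisenberg value), the
#' Leu+Ile fraction (the field singles out these strongly hydrophobic
#' residues), Lys and Arg fractions (the Arg-to-Lys shift changes surface
#' charge chemistry), the mean Eisenberg hydrophobicity, and the net charge
#' at pH 7.
#'
#' @param seq Amino-acid sequence (string).
#' @param positions Selection (see [parse_selection()]); default `"ALL"`.
#' @param protein_id,label Identifiers carried into the profile.
#' @param include_termini Include terminal charges in `net_charge_pH7`;
#'   default `FALSE`, appropriate for internal selections.
#' @return A list of class `composition_profile` with fields `protein_id`,
#'   `label`, `n_residues`, `fractions` (named length-20 vector summing
#'   to 1), `hydrophobic_fraction`, `leu_ile_fraction`, `lys_fraction`,
#'   `arg_fraction`, `mean_eisenberg`, `net_charge_pH7`.
#' @export
#' @examples
#' p <- composition_profile("LLKK", protein_id = "x")
#' p$hydrophobic_fraction # 0.5
composition_profile <- function(seq, positions = "ALL",
                                protein_id = NA_character_, label = "full",
                                include_termini = FALSE) {
  res <- split_residues(seq, what = if (is.na(protein_id)) "sequence" else protein_id)
  idx <- parse_selection(positions, length(res))
  sel <- res[idx]
  aa <- amino_acids()
  counts <- table(factor(sel, levels = aa))
  fractions <- as.numeric(counts) / length(sel)
  names(fractions) <- aa
  sc <- eisenberg_scale()
  structure(list(
    protein_id = protein_id, label = label, n_residues = length(sel),
    fractions = fractions,
    hydrophobic_fraction = sum(fractions[hydrophobic_residues()]),
    leu_ile_fraction = fractions[["L"]] + fractions[["I"]],
    lys_fraction = fractions[["K"]],
    arg_fraction = fractions[["R"]],
    mean_eisenberg = mean(sc[sel]),
    net_charge_pH7 = net_charge(paste(sel, collapse = ""), pH = 7,
                                include_termini = include_termini)),
    class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: %s [%s], %d residues\n",
              x$protein_id, x$label, x$n_residues))
  cat(sprintf("  hydrophobic %.3f (Leu+Ile %.3f), mean Eisenberg %+.3f\n",
              x$hydrophobic_fraction, x$leu_ile_fraction, x$mean_eisenberg))
  cat(sprintf("  Lys %.3f, Arg %.3f, net charge (pH 7) %+.2f\n",
              x$lys_fraction, x$arg_fraction, x$net_charge_pH7))
  invisible(x)
}

#' Net charge by the Henderson-Hasselbalch model
#'
#' Sums signed protonation occupancies over ionizable groups (Asp, Glu, Cys,
#' Tyr negative; Lys, Arg, His positive; optionally the termini) using the
#' fixed pKa set of [pka_table()]. A transparent sequence-level surrogate
#' for structure-based electrostatics: no environment-dependent pKa shifts.
#'
#' @param seq Amino-acid sequence (string).
#' @param pH pH in `[0, 14]`; default 7.0.
#' @param include_termini Add the N-/C-terminal charges (default `FALSE`).
#' @param pka Named pKa vector; default [pka_table()].
#' @return Net charge (numeric scalar), monotonically non-increasing in pH.
#' @export
#' @examples
#' net_charge("DDDD") # about -4
net_charge <- function(seq, pH = 7.0, include_termini = FALSE,
                       pka = pka_table()) {
  stopifnot(is.numeric(pH), length(pH) == 1, pH >= 0, pH <= 14)
  res <- split_residues(seq)
  pos_groups <- c("K", "R", "H")
  neg_groups <- c("D", "E", "C", "Y")
  q <- 0
  for (g in pos_groups) {
    q <- q + sum(res == g) / (1 + 10^(pH - pka[[g]]))
  }
  for (g in neg_groups) {
    q <- q - sum(res == g) / (1 + 10^(pka[[g]] - pH))
  }
  if (include_termini && length(res) > 0) {
    q <- q + 1 / (1 + 10^(pH - pka[["Nterm"]]))
    q <- q - 1 / (1 + 10^(pka[["Cterm"]] - pH))
  }
  q
}

#' Hydrophobic-gradient direction between a donor and an acceptor
#'
#' Lipoprotein hand-off from a periplasmic chaperone (donor) to a membrane
#' receptor (acceptor) is thermodynamically favoured when the acceptor's
#' binding region is more hydrophobic. The call thresholds the difference in
#' hydrophobic fraction (acceptor minus donor) against a neutral band
#' `epsilon`: `FAVORABLE` above `+epsilon`, `UNFAVORABLE` below `-epsilon`,
#' `NEUTRAL` inside the band. The mean-Eisenberg difference is reported for
#' context but does not enter the call.
#'
#' @param donor,acceptor [composition_profile()] objects.
#' @param epsilon Neutral half-band on the hydrophobic-fraction difference;
#'   default 0.01, below composition sampling noise for domains of 100+
#'   residues.
#' @return A list of class `gradient_call`: `donor_id`, `acceptor_id`,
#'   `delta_hydrophobic_fraction`, `delta_mean_eisenberg`, `call`,
#'   `neutral_band`.
#' @export
#' @examples
#' d <- composition_profile("KDKD", protein_id = "donor")
#' a <- composition_profile("LILI", protein_id = "acceptor")
#' gradient_call(d, a)$call # "FAVORABLE"
gradient_call <- function(donor, acceptor, epsilon = 0.01) {
  stopifnot(inherits(donor, "composition_profile"),
            inherits(acceptor, "composition_profile"),
            epsilon >= 0)
  dh <- acceptor$hydrophobic_fraction - donor$hydrophobic_fraction
  de <- acceptor$mean_eisenberg - donor$mean_eisenberg
  call <- if (dh > epsilon) "FAVORABLE" else if (dh < -epsilon) "UNFAVORABLE" else "NEUTRAL"
  structure(list(donor_id = donor$protein_id, acceptor_id = acceptor$protein_id,
                 delta_hydrophobic_fraction = dh, delta_mean_eisenberg = de,
                 call = call, neutral_band = epsilon),
            class = "gradient_call")
}

#' @export
print.gradient_call <- function(x, ...) {
  cat(sprintf("gradient %s -> %s: %s (delta hydrophobic %+0.3f, delta Eisenberg %+0.3f)\n",
              x$donor_id, x$acceptor_id, x$call,
              x$delta_hydrophobic_fraction, x$delta_mean_eisenberg))
  invisible(x)
}

profile_row <- function(p) {
  tibble(protein_id = p$protein_id, label = p$label, n_residues = p$n_residues,
         hydrophobic_fraction = p$hydrophobic_fraction,
         leu_ile_fraction = p$leu_ile_fraction,
         lys_fraction = p$lys_fraction, arg_fraction = p$arg_fraction,
         mean_eisenberg = p$mean_eisenberg,
         net_charge_pH7 = p$net_charge_pH7)
}

#' Tabulate and compare composition profiles
#'
#' One summary row per profile plus a block of pairwise deltas (second
#' profile minus first, over all unordered pairs), ordered by `protein_id`
#' then `label`.
#'
#' @param profiles List of [composition_profile()] objects (2 or more).
#' @return List with `profiles` (tibble, one row each) and `deltas` (tibble:
#'   `from`, `to`, `delta_hydrophobic_fraction`, `delta_leu_ile_fraction`,
#'   `delta_lys_fraction`, `delta_arg_fraction`, `delta_mean_eisenberg`,
#'   `delta_net_charge_pH7`).
#' @export
compare_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2,
            all(vapply(profiles, inherits, logical(1), "composition_profile")))
  tab <- bind_rows(lapply(profiles, profile_row)) %>%
    arrange(.data$protein_id, .data$label)
  key <- paste(tab$protein_id, tab$label, sep = ":")
  ord <- match(key, paste(vapply(profiles, `[[`, character(1), "protein_id"),
                          vapply(profiles, `[[`, character(1), "label"),
                          sep = ":"))
  profiles <- profiles[ord]
  pairs <- utils::combn(seq_along(profiles), 2)
  deltas <- bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- profiles[[i]]; b <- profiles[[j]]
    tibble(from = paste(a$protein_id, a$label, sep = ":"),
           to = paste(b$protein_id, b$label, sep = ":"),
           delta_hydrophobic_fraction = b$hydrophobic_fraction - a$hydrophobic_fraction,
           delta_leu_ile_fraction = b$leu_ile_fraction - a$leu_ile_fraction,
           delta_lys_fraction = b$lys_fraction - a$lys_fraction,
           delta_arg_fraction = b$arg_fraction - a$arg_fraction,
           delta_mean_eisenberg = b$mean_eisenberg - a$mean_eisenberg,
           delta_net_charge_pH7 = b$net_charge_pH7 - a$net_charge_pH7)
  }))
  list(profiles = tab, deltas = deltas)
}

#' Read a selections TSV and build composition profiles
#'
#' The selections dialect has columns `protein_id`, `label`, `positions`
#' (1-based comma/range list or `ALL`). Each row yields one profile computed
#' on the matching sequence.
#'
#' @param fasta Path to a FASTA file or a [Biostrings::AAStringSet].
#' @param selections Path to the selections TSV or a data frame.
#' @param include_termini Passed to [composition_profile()].
#' @return List of [composition_profile()] objects, in selection-row order.
#' @export
profiles_from_selections <- function(fasta, selections, include_termini = FALSE) {
  seqs <- if (inherits(fasta, "AAStringSet")) fasta else Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  sel <- if (is.data.frame(selections)) as_tibble(selections) else {
    readr::read_tsv(selections, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  need <- c("protein_id", "label", "positions")
  if (!all(need %in% names(sel))) {
    stop("selections must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(sel)), function(i) {
    pid <- sel$protein_id[i]
    if (!pid %in% names(seqs)) {
      stop("selection references unknown protein '", pid, "'", call. = FALSE)
    }
    composition_profile(as.character(seqs[[pid]]),
                        positions = sel$positions[i],
                        protein_id = pid, label = sel$label[i],
                        include_termini = include_termini)
  })
}
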
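# Physico-chemical constants: amino-acid alphabet, Eisenberg normalized
# consensus hydrophobicity, and a fixed textbook pKa set used by the
# Henderson-Hasselbalch net-charge model.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Eisenberg normalized consensus hydrophobicity scale
#'
#' Per-residue hydrophobicity values from the Eisenberg normalized consensus
#' scale (Eisenberg et al. 1984, J Mol Biol 179:125), embedded as constants.
#' Positive values mark hydrophobic residues; this sign convention defines
#' the package's hydrophobic residue set (see [hydrophobic_residues()]).
#'
#' @return Named numeric vector over the 20 canonical residues.
#' @export
#' @examples
#' eisenberg_scale()[["L"]] # 1.06
eisenberg_scale <- function() {
  c(A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
    Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
    L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
    S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)
}

#' Hydrophobic residue set
#'
#' Residues with a positive Eisenberg consensus value. Tying the set to the
#' scale (rather than an ad-hoc list) keeps the hydrophobic-fraction
#' statistic consistent with the per-residue hydrophobicity scores.
#'
#' @return Character vector of one-letter codes.
#' @export
hydrophobic_residues <- function() {
  sc <- eisenberg_scale()
  sort(names(sc)[sc > 0])
}

#' Side-chain and terminus pKa table
#'
#' Fixed textbook pKa values used by [net_charge()]: D 3.65, E 4.25, C 8.3,
#' Y 10.07, K 10.53, R 12.48, H 6.0, N-terminus 9.0, C-terminus 2.0. A
#' per-structure pKa calculation is deliberately out of scope; a fixed table
#' keeps the sequence-level charge surrogate transparent.
#'
#' @return Named numeric vector with entries for the seven ionizable
#'   side chains plus `Nterm` and `Cterm`.
#' @export
pka_table <- function() {
  c(D = 3.65, E = 4.25, C = 8.3, Y = 10.07,
    K = 10.53, R = 12.48, H = 6.0, Nterm = 9.0, Cterm = 2.0)
}

# Split a sequence string into a validated residue vector. Errors name the
# first offending position.
split_residues <- function(seq, what = "sequence") {
  seq <- toupper(as.character(seq))
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% amino_acids())
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue '%s' at position %d in %s",
                 res[bad[1]], bad[1], what), call. = FALSE)
  }
  res
}
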
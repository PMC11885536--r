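# Rule-based signal-peptide classification: SPII (lipoprotein, lipobox
# ending in the lipidated Cys), SPI (Sec signal with hydrophobic h-region and
# A-x-A-style cleavage motif), or NONE. A transparent surrogate for neural
# signal-peptide predictors, sharing its rule set with the sequence
# generator so planted classes are recoverable exactly.

#' Annotation rules for signal-peptide classification
#'
#' @param lipobox_pattern Regular expression for the lipobox, ending in the
#'   lipidated Cys. Default `[LVIFMSTAG][ASTVIG][GAS]C`, the standard
#'   prokaryotic lipobox consensus.
#' @param lipobox_search_window 1-based inclusive residue interval that must
#'   contain the whole lipobox match (default residues 10-40).
#' @param spi_h_region_min_hydrophobicity Minimum mean Eisenberg
#'   hydrophobicity of a 7-residue h-region window (default 0.5).
#' @param spi_cleavage_motif Regular expression for the SPI cleavage motif
#'   (default `A.A`, a classical Ala-X-Ala site).
#' @param spi_h_region_span Residue interval in which the h-region window
#'   must lie (default 1-35).
#' @param spi_motif_span Residue interval in which the cleavage motif must
#'   lie (default 15-45).
#' @param les_pattern Regular expression for the lipoprotein export signal
#'   searched after the lipidated Cys. No biological default exists in this
#'   package's sources; the shipped value `DSS` is an explicitly synthetic
#'   placeholder shared with [sim_sequences()]. Supply the consensus for your
#'   organism when annotating real data.
#' @param les_window_length Number of residues after the Cys searched for
#'   the LES (default 10).
#' @return A list of class `annotation_rules`.
#' @export
annotation_rules <- function(lipobox_pattern = "[LVIFMSTAG][ASTVIG][GAS]C",
                             lipobox_search_window = c(10L, 40L),
                             spi_h_region_min_hydrophobicity = 0.5,
                             spi_cleavage_motif = "A.A",
                             spi_h_region_span = c(1L, 35L),
                             spi_motif_span = c(15L, 45L),
                             les_pattern = "DSS",
                             les_window_length = 10L) {
  stopifnot(nzchar(lipobox_pattern), nzchar(spi_cleavage_motif),
            nzchar(les_pattern),
            length(lipobox_search_window) == 2,
            lipobox_search_window[1] >= 1,
            lipobox_search_window[2] > lipobox_search_window[1],
            les_window_length >= 1)
  structure(list(lipobox_pattern = lipobox_pattern,
                 lipobox_search_window = as.integer(lipobox_search_window),
                 spi_h_region_min_hydrophobicity = spi_h_region_min_hydrophobicity,
                 spi_cleavage_motif = spi_cleavage_motif,
                 spi_h_region_span = as.integer(spi_h_region_span),
                 spi_motif_span = as.integer(spi_motif_span),
                 les_pattern = les_pattern,
                 les_example_motif = "DSS",
                 les_window_length = as.integer(les_window_length)),
            class = "annotation_rules")
}

empty_annotation <- function(protein_id = NA_character_) {
  list(protein_id = protein_id, sp_class = "NONE",
       cleavage_pos = NA_integer_, lipobox_start = NA_integer_,
       lipobox_end = NA_integer_, les_present = FALSE)
}

#' Classify a sequence as NONE / SPI / SPII
#'
#' SPII wins if the lipobox matches entirely inside the search window
#' (leftmost match; the cleavage position is the lipidated Cys at the end of
#' the match). Otherwise SPI if a 7-residue window with mean Eisenberg
#' hydrophobicity at or above the threshold lies within residues 1-35,
#' followed by the cleavage motif within residues 15-45 (the first mature
#' residue is the position after the motif). Otherwise NONE. Precedence is
#' SPII over SPI: lipoproteins also carry an h-region, so the lipobox rule
#' must be tested first.
#'
#' @param seq Amino-acid sequence (string), canonical residues only.
#' @param rules An [annotation_rules()] object.
#' @param protein_id Optional id carried into the result.
#' @return Named list: `protein_id`, `sp_class` (`"NONE"/"SPI"/"SPII"`),
#'   `cleavage_pos` (1-based first mature residue; the Cys itself for SPII),
#'   `lipobox_start`, `lipobox_end`, `les_present` (always `FALSE` here; see
#'   [flag_les()]).
#' @export
#' @examples
#' rules <- annotation_rules()
#' classify_signal(paste0("MKK", strrep("L", 10), "LAGC", strrep("Q", 40)),
#'                 rules)$sp_class # "SPII"
classify_signal <- function(seq, rules = annotation_rules(), protein_id = NA_character_) {
  res <- split_residues(seq, what = if (is.na(protein_id)) "sequence" else protein_id)
  n <- length(res)
  seq <- paste(res, collapse = "")
  ann <- empty_annotation(protein_id)
  if (n < 30) {
    warning("sequence ", if (!is.na(protein_id)) paste0("'", protein_id, "' "),
            "shorter than 30 residues: classified NONE", call. = FALSE)
    return(ann)
  }

  # SPII: leftmost lipobox fully inside the search window
  w1 <- rules$lipobox_search_window[1]
  w2 <- min(rules$lipobox_search_window[2], n)
  if (w2 > w1) {
    m <- regexpr(rules$lipobox_pattern, substr(seq, w1, w2), perl = TRUE)
    if (m[1] > 0) {
      start <- w1 + m[1] - 1L
      end <- start + attr(m, "match.length") - 1L
      if (res[end] != "C") {
        stop("lipobox_pattern must end at a Cys residue", call. = FALSE)
      }
      ann$sp_class <- "SPII"
      ann$cleavage_pos <- end
      ann$lipobox_start <- start
      ann$lipobox_end <- end
      return(ann)
    }
  }

  # SPI: hydrophobic h-region then cleavage motif downstream of it
  sc <- eisenberg_scale()[res]
  h_span <- rules$spi_h_region_span
  h_ends <- integer()
  last_start <- min(h_span[2], n) - 6L
  if (last_start >= h_span[1]) {
    for (s in seq(h_span[1], last_start)) {
      if (mean(sc[s:(s + 6L)]) >= rules$spi_h_region_min_hydrophobicity) {
        h_ends <- c(h_ends, s + 6L)
      }
    }
  }
  if (length(h_ends) > 0) {
    m_span <- rules$spi_motif_span
    region <- substr(seq, m_span[1], min(m_span[2], n))
    mm <- gregexpr(rules$spi_cleavage_motif, region, perl = TRUE)[[1]]
    if (mm[1] > 0) {
      starts <- m_span[1] + as.integer(mm) - 1L
      ends <- starts + attr(mm, "match.length") - 1L
      ok <- which(ends <= min(m_span[2], n) & starts > min(h_ends) & ends < n)
      if (length(ok) > 0) {
        ann$sp_class <- "SPI"
        ann$cleavage_pos <- ends[ok[1]] + 1L
        return(ann)
      }
    }
  }
  ann
}

#' Flag the lipoprotein export signal (LES) on an SPII annotation
#'
#' Surface-exposed lipoproteins carry an export signal in the first residues
#' of the mature protein, immediately after the lipidated Cys. Sets
#' `les_present` to `TRUE` iff `rules$les_pattern` matches within
#' `rules$les_window_length` residues after the Cys. Pure function of its
#' inputs; errors when called on a non-SPII annotation.
#'
#' @param annotation Result of [classify_signal()] with `sp_class == "SPII"`.
#' @param seq The same amino-acid sequence.
#' @param rules An [annotation_rules()] object.
#' @return The annotation with `les_present` set.
#' @export
flag_les <- function(annotation, seq, rules = annotation_rules()) {
  if (!identical(annotation$sp_class, "SPII")) {
    stop("flag_les() requires an SPII annotation (got ",
         annotation$sp_class, ")", call. = FALSE)
  }
  cys <- annotation$cleavage_pos
  window <- substr(as.character(seq), cys + 1L, cys + rules$les_window_length)
  annotation$les_present <- grepl(rules$les_pattern, window, perl = TRUE)
  annotation
}

#' Annotate a FASTA file (or sequence set) with signal-peptide classes
#'
#' Runs [classify_signal()] and [flag_les()] over every record, preserving
#' input order. Duplicate record ids are an error. Per-class summary counts
#' are reported as a message.
#'
#' @param x Path to a FASTA file, or a [Biostrings::AAStringSet].
#' @param rules An [annotation_rules()] object.
#' @param quiet Suppress the summary message.
#' @return Tibble with columns `protein_id`, `sp_class`, `cleavage_pos`,
#'   `lipobox_start`, `lipobox_end`, `les_present`. SPII rows carry
#'   `sp_class = "SPII"` with `les_present` distinguishing surface (LES)
#'   lipoproteins.
#' @export
annotate_fasta <- function(x, rules = annotation_rules(), quiet = FALSE) {
  seqs <- if (inherits(x, "AAStringSet")) x else Biostrings::readAAStringSet(x)
  ids <- names(seqs)
  if (is.null(ids) && length(seqs) > 0) {
    stop("sequence records must be named", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", ids) # FASTA id = first token of the header
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(seqs), function(i) {
    ann <- classify_signal(as.character(seqs[[i]]), rules, protein_id = ids[i])
    if (ann$sp_class == "SPII") {
      ann <- flag_les(ann, as.character(seqs[[i]]), rules)
    }
    as_tibble(ann)
  })
  out <- if (length(rows) > 0) bind_rows(rows) else {
    as_tibble(empty_annotation())[0, ]
  }
  if (!quiet && nrow(out) > 0) {
    cls <- ifelse(out$sp_class == "SPII" & out$les_present, "SPII-LES", out$sp_class)
    tab <- table(cls)
    message("annotated ", nrow(out), " sequences: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  out
}

#' Write an annotation table to TSV
#'
#' @param annotations Output of [annotate_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
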
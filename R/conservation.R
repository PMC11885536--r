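# Cross-species conservation profiling: assign homology-search hits to query
# families at an E-value cutoff and build a species-by-family homolog count
# matrix (a phylogenetic profile with copy numbers).

#' Assign subject proteins to query families
#'
#' Drops hits above the E-value cutoff, then assigns each subject protein
#' (within its species) to the query family it hits with the smallest
#' E-value. Exact E-value ties across families go to the lexicographically
#' first family and are flagged `ambiguous` for manual review — the
#' automatic stand-in for resolving paralogy by structure and gene-
#' neighbourhood inspection.
#'
#' @param hits Tibble/data frame with columns `species_id`,
#'   `subject_protein_id`, `query_id`, `e_value`.
#' @param e_cutoff Inclusive E-value cutoff, default `1e-3`.
#' @return Tibble with one row per assigned subject: `species_id`,
#'   `subject_protein_id`, `query_id`, `e_value`, `ambiguous`.
#' @export
#' @examples
#' h <- data.frame(species_id = "sp1", subject_protein_id = "g1",
#'                 query_id = c("LolA1", "LolA2"), e_value = c(1e-10, 1e-4))
#' assign_families(h)$query_id # "LolA1"
assign_families <- function(hits, e_cutoff = 1e-3) {
  stopifnot(is.numeric(e_cutoff), length(e_cutoff) == 1, e_cutoff > 0)
  hits <- as_tibble(hits)
  need <- c("species_id", "subject_protein_id", "query_id", "e_value")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(hits$e_value) | hits$e_value <= 0)) {
    stop("e_value must be a finite positive number", call. = FALSE)
  }
  hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble(species_id = character(), subject_protein_id = character(),
                  query_id = character(), e_value = double(),
                  ambiguous = logical()))
  }
  hits %>%
    group_by(.data$species_id, .data$subject_protein_id) %>%
    arrange(.data$e_value, .data$query_id, .by_group = TRUE) %>%
    summarise(ambiguous = sum(.data$e_value == .data$e_value[1] &
                                .data$query_id != .data$query_id[1]) > 0,
              query_id = .data$query_id[1],
              e_value = .data$e_value[1],
              .groups = "drop") %>%
    select("species_id", "subject_protein_id", "query_id", "e_value",
           "ambiguous") %>%
    arrange(.data$species_id, .data$subject_protein_id)
}

#' Build a species-by-family presence matrix
#'
#' Cell (s, f) counts the distinct subject proteins of species `s` assigned
#' to family `f`. Species with no hits appear as zero rows (absence is
#' informative). Counts rather than booleans are stored so multi-copy
#' families remain visible; presence is `count > 0`.
#'
#' @param assigned Output of [assign_families()].
#' @param species Character vector of species ids (matrix row order).
#' @param families Character vector of query-family ids (column order).
#' @param allow_unknown_species Include hits from species not in `species`
#'   by appending rows (default `FALSE`: such hits are an error).
#' @return A list of class `presence_matrix`: `counts` (integer matrix,
#'   species x families) and `total_homologs`.
#' @export
build_presence_matrix <- function(assigned, species, families,
                                  allow_unknown_species = FALSE) {
  stopifnot(length(species) >= 1, length(families) >= 1)
  assigned <- as_tibble(assigned)
  unknown_sp <- setdiff(assigned$species_id, species)
  if (length(unknown_sp) > 0) {
    if (!allow_unknown_species) {
      stop("hits reference species not in the species list: ",
           paste(unknown_sp, collapse = ", "),
           " (set allow_unknown_species = TRUE to include)", call. = FALSE)
    }
    species <- c(species, sort(unknown_sp))
  }
  unknown_fam <- setdiff(assigned$query_id, families)
  if (length(unknown_fam) > 0) {
    stop("hits reference families not in the family list: ",
         paste(unknown_fam, collapse = ", "), call. = FALSE)
  }
  counts <- matrix(0L, nrow = length(species), ncol = length(families),
                   dimnames = list(species, families))
  if (nrow(assigned) > 0) {
    assigned <- distinct(assigned, .data$species_id, .data$subject_protein_id,
                         .keep_all = TRUE)
    tab <- table(factor(assigned$species_id, levels = species),
                 factor(assigned$query_id, levels = families))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, total_homologs = sum(counts)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d species x %d families, %d homologs\n",
              nrow(x$counts), ncol(x$counts), x$total_homologs))
  print(x$counts)
  invisible(x)
}

#' Summarise a presence matrix
#'
#' Per-family species coverage (fraction of species with at least one
#' homolog), the species lacking each family, and the species carrying the
#' full core complement (by default the chaperone/receptor pair LolA1 and
#' LolB1 when those columns exist, otherwise all families).
#'
#' @param matrix A [build_presence_matrix()] result.
#' @param core_families Families defining the "complete complement" check;
#'   default `c("LolA1", "LolB1")` intersected with the matrix columns, or
#'   all columns when the intersection is empty.
#' @return A list: `coverage` (tibble `family`, `n_species_present`,
#'   `coverage`), `missing_species` (named list per family),
#'   `core_families`, `species_with_core` (character vector).
#' @export
matrix_summary <- function(matrix, core_families = NULL) {
  stopifnot(inherits(matrix, "presence_matrix"))
  counts <- matrix$counts
  present <- counts > 0
  if (is.null(core_families)) {
    core_families <- intersect(c("LolA1", "LolB1"), colnames(counts))
    if (length(core_families) == 0) core_families <- colnames(counts)
  }
  stopifnot(all(core_families %in% colnames(counts)))
  coverage <- tibble(family = colnames(counts),
                     n_species_present = unname(colSums(present)),
                     coverage = unname(colSums(present)) / nrow(counts))
  missing <- lapply(setNames(colnames(counts), colnames(counts)),
                    function(f) rownames(counts)[!present[, f]])
  core_ok <- rowSums(!present[, core_families, drop = FALSE]) == 0
  list(coverage = coverage, missing_species = missing,
       core_families = core_families,
       species_with_core = rownames(counts)[core_ok])
}

#' Write a presence matrix (and optional long format) to TSV
#'
#' @param matrix A [build_presence_matrix()] result.
#' @param path Output path for the wide matrix (species rows, family
#'   columns).
#' @param long_path Optional path for a long-format table
#'   (`species_id`, `family`, `count`).
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(matrix, path, long_path = NULL) {
  wide <- as_tibble(matrix$counts, rownames = "species_id")
  readr::write_tsv(wide, path, progress = FALSE)
  if (!is.null(long_path)) {
    long <- tidyr::pivot_longer(wide, -"species_id",
                                names_to = "family", values_to = "count")
    readr::write_tsv(long, long_path, progress = FALSE)
  }
  invisible(path)
}
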
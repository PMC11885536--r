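# Differential outer-membrane proteome analysis: the -10*log10(p)
# significance transform, the two-sided fold-change / significance filter
# applied to label-free quantification summaries, and the localization-class
# and functional-category tallies used to profile mutant OM proteomes.

#' Significance score from a p-value
#'
#' `significance = -10 * log10(p)`, the score convention of label-free
#' proteomics suites: a threshold of 20 corresponds exactly to p = 0.01.
#' Strictly decreasing in p.
#'
#' @param p p-value(s) in `(0, 1]`.
#' @return Non-negative significance score(s).
#' @export
#' @examples
#' significance_from_p(0.01) # 20
significance_from_p <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  -10 * log10(p)
}

#' p-value from a significance score
#'
#' Inverse of [significance_from_p()]: `p = 10^(-significance / 10)`.
#'
#' @param significance Non-negative score(s).
#' @return p-value(s) in `(0, 1]`.
#' @export
p_from_significance <- function(significance) {
  if (any(!is.finite(significance) | significance < 0)) {
    stop("significance scores must be non-negative", call. = FALSE)
  }
  10^(-significance / 10)
}

# Ensure each record carries fold_change and significance; fill significance
# from p_value when needed and cross-check when both are present.
normalise_abundance <- function(records) {
  records <- as_tibble(records)
  if (!"protein_id" %in% names(records) || !"fold_change" %in% names(records)) {
    stop("records must have protein_id and fold_change columns", call. = FALSE)
  }
  if (any(!is.finite(records$fold_change) | records$fold_change <= 0)) {
    stop("fold_change must be a positive linear-scale ratio", call. = FALSE)
  }
  has_p <- "p_value" %in% names(records)
  has_s <- "significance" %in% names(records)
  if (!has_p && !has_s) {
    stop("records must carry p_value or significance", call. = FALSE)
  }
  if (!has_s) records$significance <- NA_real_
  if (!has_p) records$p_value <- NA_real_
  miss <- is.na(records$significance) & is.na(records$p_value)
  if (any(miss)) {
    stop("records missing both p_value and significance: ",
         paste(utils::head(records$protein_id[miss], 5), collapse = ", "),
         call. = FALSE)
  }
  both <- !is.na(records$significance) & !is.na(records$p_value)
  if (any(both)) {
    expect <- significance_from_p(records$p_value[both])
    off <- abs(records$significance[both] - expect) > 1e-6
    if (any(off)) {
      stop("significance inconsistent with -10*log10(p) for: ",
           paste(utils::head(records$protein_id[both][off], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  fill <- is.na(records$significance)
  records$significance[fill] <- significance_from_p(records$p_value[fill])
  records$direction <- ifelse(records$fold_change > 1, "UP", "DOWN")
  records
}

#' Filter abundance records on fold change and significance
#'
#' Keeps records with `max(FC, 1/FC) >= fc_min` and
#' `significance >= sig_min`, both thresholds inclusive. The fold-change
#' condition is two-sided: depleted proteins (FC < 1) are judged on the
#' reciprocal ratio, so an FC of 0.5 passes a 1.5-fold threshold. Input
#' order is preserved; a `direction` column (`UP`/`DOWN`) is added.
#'
#' @param records Tibble/data frame with `protein_id`, `fold_change`
#'   (positive, linear scale) and `p_value` and/or `significance`
#'   (consistency between the two is checked to 1e-6). Optional `loc_class`
#'   and `category` columns are carried through.
#' @param fc_min Fold-change threshold (>= 1), default 1.5.
#' @param sig_min Significance threshold (>= 0), default 20 (p = 0.01).
#' @return The filtered tibble.
#' @export
#' @examples
#' tab <- data.frame(protein_id = c("a", "b"), fold_change = c(0.5, 1.4),
#'                   significance = c(25, 100))
#' apply_abundance_filter(tab)$protein_id # "a"
apply_abundance_filter <- function(records, fc_min = 1.5, sig_min = 20) {
  stopifnot(fc_min >= 1, sig_min >= 0)
  records <- normalise_abundance(records)
  keep <- pmax(records$fold_change, 1 / records$fold_change) >= fc_min &
    records$significance >= sig_min
  records[keep, , drop = FALSE]
}

round_half_up <- function(x) floor(x + 0.5)

#' Tally filtered records by localization class and functional category
#'
#' Reproduces the summary view of a differential OM proteome: counts per
#' signal-peptide localization class (`NO_SP`, `SPI`, `SPII`, `SPII_LES`),
#' per-category up/down splits, and the share of no-signal (presumed
#' cytoplasmic) proteins among significant entries as an integer percentage
#' (rounded half-up) — the figure that flags intracellular leakage when it
#' dominates a mutant's OM fraction.
#'
#' @param filtered Output of [apply_abundance_filter()] (requires
#'   `loc_class`; `category` optional).
#' @return A list of class `tally_report`: `total_significant`,
#'   `by_loc_class` (tibble `loc_class`, `n`), `by_category` (tibble
#'   `category`, `up_count`, `down_count`), `no_sp_fraction` (integer
#'   percent).
#' @export
#' @examples
#' tab <- data.frame(protein_id = as.character(1:3), fold_change = c(2, 2, 0.4),
#'                   significance = 30, loc_class = c("NO_SP", "NO_SP", "SPI"),
#'                   category = c("C", "E", "E"))
#' tally_abundance(apply_abundance_filter(tab))$no_sp_fraction # 67
tally_abundance <- function(filtered) {
  filtered <- as_tibble(filtered)
  if (nrow(filtered) > 0 && !"loc_class" %in% names(filtered)) {
    stop("tally requires a loc_class column", call. = FALSE)
  }
  loc_levels <- c("NO_SP", "SPI", "SPII", "SPII_LES")
  total <- nrow(filtered)
  by_loc <- if (total > 0) {
    tibble(loc_class = loc_levels,
           n = as.integer(table(factor(filtered$loc_class, levels = loc_levels))))
  } else {
    tibble(loc_class = loc_levels, n = 0L)
  }
  by_cat <- if (total > 0 && "category" %in% names(filtered)) {
    filtered %>%
      group_by(.data$category) %>%
      summarise(up_count = sum(.data$direction == "UP"),
                down_count = sum(.data$direction == "DOWN"),
                .groups = "drop") %>%
      arrange(.data$category)
  } else {
    tibble(category = character(), up_count = integer(), down_count = integer())
  }
  no_sp <- if (total > 0) by_loc$n[by_loc$loc_class == "NO_SP"] else 0L
  structure(list(total_significant = total,
                 by_loc_class = by_loc,
                 by_category = by_cat,
                 no_sp_fraction = if (total > 0) round_half_up(100 * no_sp / total) else 0),
            class = "tally_report")
}

#' @export
print.tally_report <- function(x, ...) {
  cat(sprintf("tally: %d significant proteins (%d%% without signal peptide)\n",
              x$total_significant, x$no_sp_fraction))
  for (i in seq_len(nrow(x$by_loc_class))) {
    cat(sprintf("  %-9s %d\n", x$by_loc_class$loc_class[i], x$by_loc_class$n[i]))
  }
  invisible(x)
}

#' Compare two filtered condition sets
#'
#' Set logic across two mutant-versus-wild-type comparisons: proteins
#' significant in both conditions (split by whether their direction of
#' change agrees) and proteins specific to each.
#'
#' @param filtered_a,filtered_b Outputs of [apply_abundance_filter()].
#' @return A list: `shared` (tibble `protein_id`, `direction_a`,
#'   `direction_b`, `concordant`), `n_shared`, `n_shared_concordant`,
#'   `only_a`, `only_b` (character vectors of protein ids).
#' @export
compare_conditions <- function(filtered_a, filtered_b) {
  a <- as_tibble(filtered_a); b <- as_tibble(filtered_b)
  shared_ids <- intersect(a$protein_id, b$protein_id)
  shared <- tibble(
    protein_id = sort(shared_ids),
    direction_a = a$direction[match(sort(shared_ids), a$protein_id)],
    direction_b = b$direction[match(sort(shared_ids), b$protein_id)])
  shared$concordant <- shared$direction_a == shared$direction_b
  list(shared = shared,
       n_shared = nrow(shared),
       n_shared_concordant = sum(shared$concordant),
       only_a = sort(setdiff(a$protein_id, b$protein_id)),
       only_b = sort(setdiff(b$protein_id, a$protein_id)))
}

#' Optional Benjamini-Hochberg adjusted p-values
#'
#' The score-threshold filter applies no multiple-testing correction (it
#' mirrors a fixed significance-score cutoff); this helper adds a BH-adjusted
#' p-value column for users who want one.
#'
#' @param records Abundance records with `p_value` or `significance`.
#' @return The records with a `p_adjust_bh` column.
#' @export
add_bh_adjustment <- function(records) {
  records <- normalise_abundance(records)
  p <- ifelse(is.na(records$p_value),
              p_from_significance(records$significance), records$p_value)
  records$p_adjust_bh <- stats::p.adjust(p, method = "BH")
  records
}
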
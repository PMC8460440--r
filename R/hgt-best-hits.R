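#' Per-gene best-hit summary and h-score
#'
#' Collapses a combined homology hit table to one row per gene in
#' `gene_universe`: the best (maximum) bitscore among metazoan hits
#' (excluding annelids), among annelid hits, and among non-metazoan hits,
#' plus the taxon group of the best non-metazoan hit. The h-score is
#' \deqn{h = \mathrm{best\ non\text{-}metazoan\ bitscore} -
#'          \mathrm{best\ metazoan\ bitscore}}
#' Genes with no hit in a group get bitscore 0 for that group, so h stays
#' defined (a gene with no metazoan hit has `h` equal to its non-metazoan
#' bitscore). Best-group ties are broken by lower e-value, then lexicographic
#' subject id.
#'
#' Annelid-database hits represent vertical inheritance in an annelid focal
#' genome, so they are excluded from the non-metazoan best hit by default;
#' `annelida_nonmetazoan = TRUE` inverts this for sensitivity analysis.
#'
#' @param hits Hit tibble ([read_hit_table()], possibly several tables
#'   row-bound) with a `taxon_group` column.
#' @param gene_universe Character vector of all gene ids (every hit's
#'   `query_id` must be in it).
#' @param annelida_nonmetazoan Count annelid hits on the non-metazoan side.
#' @return A tibble, one row per gene in `gene_universe` (sorted):
#'   `gene_id`, `best_metazoan_bitscore`, `best_annelid_bitscore`,
#'   `best_nonmetazoan_bitscore`, `best_nonmetazoan_group`, `h_score`.
#' @export
summarize_best_hits <- function(hits, gene_universe,
                                annelida_nonmetazoan = FALSE) {
  unknown <- setdiff(unique(hits$query_id), gene_universe)
  if (length(unknown)) {
    pw_usage_error(paste0("hit for unknown gene '", unknown[1], "'"))
  }
  nonmet <- hgt_nonmetazoan_groups
  if (annelida_nonmetazoan) nonmet <- c(nonmet, "annelida")

  best_of <- function(groups) {
    sub <- hits[hits$taxon_group %in% groups, , drop = FALSE]
    if (!nrow(sub)) {
      return(tibble(gene_id = character(0), bitscore = numeric(0),
                    taxon_group = character(0)))
    }
    sub |>
      arrange(.data$query_id, desc(.data$bitscore), .data$evalue,
              .data$subject_id) |>
      group_by(.data$query_id) |>
      dplyr::slice(1L) |>
      ungroup() |>
      select(gene_id = "query_id", "bitscore", "taxon_group")
  }
  met <- best_of("metazoa_excl_annelida")
  ann <- best_of("annelida")
  nm <- best_of(nonmet)

  out <- tibble(gene_id = sort(unique(gene_universe)))
  out$best_metazoan_bitscore <- met$bitscore[match(out$gene_id, met$gene_id)]
  out$best_annelid_bitscore <- ann$bitscore[match(out$gene_id, ann$gene_id)]
  out$best_nonmetazoan_bitscore <- nm$bitscore[match(out$gene_id, nm$gene_id)]
  out$best_nonmetazoan_group <- nm$taxon_group[match(out$gene_id, nm$gene_id)]
  out <- out |>
    mutate(across(dplyr::ends_with("bitscore"), ~ dplyr::coalesce(.x, 0)),
           h_score = .data$best_nonmetazoan_bitscore - .data$best_metazoan_bitscore)
  out
}

#' HGT candidate filter on h-score and non-metazoan bitscore
#'
#' A gene is an HGT candidate when its h-score is at least `h_min` *and* its
#' best non-metazoan bitscore is at least `nonmet_min` (both thresholds
#' inclusive). Defaults are the standard 30 / 100.
#'
#' @param summaries Best-hit summary tibble ([summarize_best_hits()]).
#' @param h_min Minimum h-score (inclusive).
#' @param nonmet_min Minimum best non-metazoan bitscore (inclusive).
#' @return Sorted character vector of candidate gene ids.
#' @export
filter_candidates <- function(summaries, h_min = 30, nonmet_min = 100) {
  sort(summaries$gene_id[summaries$h_score >= h_min &
                           summaries$best_nonmetazoan_bitscore >= nonmet_min])
}

#' Bitscore confirmation rule for linkage-passing candidates
#'
#' Candidates whose best metazoan bitscore is strictly below `confirm_below`
#' (default 50) are confirmed outright: there is essentially no metazoan
#' homology to explain away. Candidates at or above the cutoff need the
#' phylogenetic clade test.
#'
#' @inheritParams filter_candidates
#' @param confirm_below Strict upper bound on the metazoan bitscore for
#'   direct confirmation.
#' @return A tibble `gene_id`, `bitscore_class` (`"confirmed"` or
#'   `"needs_phylo"`).
#' @export
classify_by_bitscore <- function(summaries, confirm_below = 50) {
  tibble(
    gene_id = summaries$gene_id,
    bitscore_class = ifelse(summaries$best_metazoan_bitscore < confirm_below,
                            "confirmed", "needs_phylo")
  )
}
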
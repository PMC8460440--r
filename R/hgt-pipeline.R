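#' Configuration for the staged HGT pipeline
#'
#' Defaults are the standard printed thresholds: candidates need an h-score
#' of at least 30 and a non-metazoan bitscore of at least 100; a metazoan
#' bitscore strictly below 50 confirms a linkage-passing candidate without a
#' tree. The remaining knobs are artifact choices documented in the methods
#' vignette.
#'
#' @param h_min Candidate h-score threshold (inclusive).
#' @param nonmet_min Candidate non-metazoan bitscore threshold (inclusive).
#' @param confirm_below Metazoan bitscore below which a linkage-passing
#'   candidate is confirmed without phylogeny (strict).
#' @param min_overlap_bp Minimum read overlap with candidate and neighbour
#'   spans in the linkage test.
#' @param annelida_nonmetazoan Count annelid hits as non-metazoan (see
#'   [summarize_best_hits()]).
#' @param metazoan_groups Groups counted as metazoan in the clade test.
#' @return A named list of class `hgt_config`.
#' @export
hgt_config <- function(h_min = 30, nonmet_min = 100, confirm_below = 50,
                       min_overlap_bp = 100L, annelida_nonmetazoan = FALSE,
                       metazoan_groups = hgt_metazoan_groups) {
  if (any(c(h_min, nonmet_min, confirm_below, min_overlap_bp) < 0)) {
    pw_usage_error("pipeline thresholds must be non-negative")
  }
  structure(list(h_min = h_min, nonmet_min = nonmet_min,
                 confirm_below = confirm_below,
                 min_overlap_bp = as.integer(min_overlap_bp),
                 annelida_nonmetazoan = annelida_nonmetazoan,
                 metazoan_groups = metazoan_groups),
            class = "hgt_config")
}

#' Attribute donor origins to confirmed HGT genes
#'
#' The origin of a confirmed gene is the taxon group of its best
#' non-metazoan hit. Percentages are rounded half-away-from-zero to one
#' decimal, the convention of printed origin breakdowns.
#'
#' @param confirmed Character vector of confirmed gene ids.
#' @param summaries Best-hit summary tibble ([summarize_best_hits()]).
#' @return A tibble `taxon_group`, `count`, `percent`, sorted by count
#'   descending; empty when `confirmed` is empty.
#' @export
attribute_origin <- function(confirmed, summaries) {
  if (!length(confirmed)) {
    return(tibble(taxon_group = character(0), count = integer(0),
                  percent = numeric(0)))
  }
  i <- match(confirmed, summaries$gene_id)
  if (anyNA(i)) {
    pw_usage_error(paste0("confirmed gene '", confirmed[which(is.na(i))[1]],
                          "' absent from summaries"))
  }
  groups <- summaries$best_nonmetazoan_group[i]
  stopifnot("confirmed gene with no non-metazoan hit" = !anyNA(groups))
  tab <- table(groups)
  tibble(
    taxon_group = names(tab),
    count = as.integer(tab),
    percent = round1_away(100 * as.integer(tab) / length(confirmed))
  ) |>
    arrange(desc(.data$count), .data$taxon_group)
}

#' Run the staged HGT detection pipeline
#'
#' Applies the stages in order: best-hit summary and h-scores; candidate
#' thresholds; genomic-context/long-read linkage; bitscore confirmation;
#' smallest-clade phylogenetic test; origin attribution. Every gene in the
#' annotation receives exactly one stage decision. Candidates that need the
#' phylogenetic test but have no supplied tree are reported as
#' `phylo_missing` and are not counted as confirmed. All iteration is
#' ordered by gene id, so the result is reproducible bit for bit.
#'
#' @param hits Combined hit tibble (rows from [read_hit_table()] across all
#'   databases, `taxon_group` stamped).
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param reads Read-interval tibble ([read_read_intervals()]).
#' @param trees Named list of `phylo` gene trees keyed by gene id
#'   ([read_gene_trees()]).
#' @param config An [hgt_config()].
#' @return An object of class `hgt_result`: list with `decisions` (per-gene
#'   tibble), `report` (one-row stage-count tibble), `origin` (donor
#'   breakdown tibble), `summaries` and `config`. Use [generics::tidy()] for
#'   the decisions, [generics::glance()] for the report, and
#'   [ggplot2::autoplot()] for stage/origin plots.
#' @export
run_hgt_pipeline <- function(hits, genes, reads, trees = list(),
                             config = hgt_config()) {
  universe <- sort(unique(genes$gene_id))
  summaries <- summarize_best_hits(
    hits, universe, annelida_nonmetazoan = config$annelida_nonmetazoan)
  candidates <- filter_candidates(summaries, config$h_min, config$nonmet_min)

  decisions <- tibble(
    gene_id = universe,
    stage = "not_candidate",
    h_score = summaries$h_score[match(universe, summaries$gene_id)],
    best_metazoan_bitscore =
      summaries$best_metazoan_bitscore[match(universe, summaries$gene_id)],
    best_nonmetazoan_bitscore =
      summaries$best_nonmetazoan_bitscore[match(universe, summaries$gene_id)],
    linkage_neighbor = NA_character_,
    linkage_reads = NA_character_,
    linkage_fail_reason = NA_character_,
    clade_leaves = NA_character_,
    origin = NA_character_
  )
  row_of <- function(g) match(g, decisions$gene_id)

  for (g in candidates) {
    link <- check_context_linkage(g, genes, candidates, reads,
                                  config$min_overlap_bp)
    r <- row_of(g)
    if (!link$pass) {
      decisions$stage[r] <- "rejected_no_linkage"
      decisions$linkage_fail_reason[r] <- link$reason
      decisions$linkage_neighbor[r] <- link$neighbor_id
      next
    }
    decisions$linkage_neighbor[r] <- link$neighbor_id
    decisions$linkage_reads[r] <- paste(link$read_ids, collapse = ",")
    met <- decisions$best_metazoan_bitscore[r]
    if (met < config$confirm_below) {
      decisions$stage[r] <- "confirmed_bitscore"
    } else if (is.null(trees[[g]])) {
      decisions$stage[r] <- "phylo_missing"
    } else {
      ct <- clade_test(trees[[g]], g, config$metazoan_groups)
      decisions$stage[r] <- if (ct$confirmed) "phylo_confirmed" else "phylo_rejected"
      decisions$clade_leaves[r] <- paste(ct$clade_leaves, collapse = ",")
    }
  }

  confirmed <- decisions$gene_id[decisions$stage %in%
                                   c("confirmed_bitscore", "phylo_confirmed")]
  decisions$origin[match(confirmed, decisions$gene_id)] <-
    summaries$best_nonmetazoan_group[match(confirmed, summaries$gene_id)]

  n_of <- function(s) sum(decisions$stage == s)
  report <- tibble(
    n_candidates = length(candidates),
    n_rejected_linkage = n_of("rejected_no_linkage"),
    n_confirmed_bitscore = n_of("confirmed_bitscore"),
    n_phylo_tested = n_of("phylo_confirmed") + n_of("phylo_rejected") +
      n_of("phylo_missing"),
    n_phylo_confirmed = n_of("phylo_confirmed"),
    n_phylo_rejected = n_of("phylo_rejected"),
    n_phylo_missing = n_of("phylo_missing"),
    n_confirmed_total = n_of("confirmed_bitscore") + n_of("phylo_confirmed")
  )
  structure(
    list(decisions = decisions, report = report,
         origin = attribute_origin(confirmed, summaries),
         summaries = summaries, config = config),
    class = "hgt_result"
  )
}

#' @export
print.hgt_result <- function(x, ...) {
  cat("Staged HGT detection result\n")
  cat(sprintf("  candidates:          %d\n", x$report$n_candidates))
  cat(sprintf("  rejected (linkage):  %d\n", x$report$n_rejected_linkage))
  cat(sprintf("  confirmed (bitscore):%d\n", x$report$n_confirmed_bitscore))
  cat(sprintf("  phylo tested:        %d (confirmed %d, rejected %d, no tree %d)\n",
              x$report$n_phylo_tested, x$report$n_phylo_confirmed,
              x$report$n_phylo_rejected, x$report$n_phylo_missing))
  cat(sprintf("  confirmed total:     %d\n", x$report$n_confirmed_total))
  if (nrow(x$origin)) {
    cat("  origin: ",
        paste(sprintf("%s %.1f%%", x$origin$taxon_group, x$origin$percent),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
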
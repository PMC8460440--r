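#' Assembly summary statistics (N50/L50/GC)
#'
#' Summarises an assembly the way genome papers tabulate it. Scaffolds
#' shorter than `min_len_bp` and any ids in `exclude_ids` (typically
#' mitochondrial-fragment scaffolds flagged by [screen_mito_fragments()]) are
#' dropped first. N50 is the length of the scaffold at which the cumulative
#' length, in descending length order, first reaches half the total
#' (`>=` tie rule, the de facto standard); L50 is its 1-based rank. GC is
#' `100 * (G + C) / (A + C + G + T)`: ambiguity codes are excluded from both
#' numerator and denominator, so N-padding does not dilute GC, while
#' `total_bp` still counts every base.
#'
#' @param scaffolds Scaffold tibble from [read_fasta()] (`id`, `sequence`,
#'   `length`).
#' @param min_len_bp Minimum scaffold length retained (default 1000 bp).
#' @param exclude_ids Scaffold ids to drop before summarising.
#' @return A one-row tibble: `n_scaffolds`, `total_bp`, `largest_bp`,
#'   `smallest_bp`, `n50_bp`, `l50`, `gc_percent`.
#' @examples
#' scaf <- tibble::tibble(id = c("a", "b"), sequence = c("ACGT", "GGGCCC"),
#'                        length = c(4L, 6L))
#' compute_assembly_stats(scaf, min_len_bp = 1)
#' @export
compute_assembly_stats <- function(scaffolds, min_len_bp = 1000L,
                                   exclude_ids = character()) {
  keep <- scaffolds$length >= min_len_bp & !scaffolds$id %in% exclude_ids
  scaffolds <- scaffolds[keep, , drop = FALSE]
  if (nrow(scaffolds) == 0L) {
    pw_usage_error("no scaffolds left after length filter / exclusions")
  }
  lens <- sort(scaffolds$length, decreasing = TRUE)
  total <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(lens))
  i50 <- which(cum >= total / 2)[1]
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(scaffolds$sequence), letters = c("A", "C", "G", "T"))
  acgt <- colSums(freq)
  tibble(
    n_scaffolds = nrow(scaffolds),
    total_bp = total,
    largest_bp = lens[1],
    smallest_bp = lens[length(lens)],
    n50_bp = lens[i50],
    l50 = i50,
    gc_percent = 100 * (acgt[["G"]] + acgt[["C"]]) / sum(acgt)
  )
}

#' Genome fractions occupied by genes, exons, introns and repeats
#'
#' Fractions are computed on the union of feature spans per scaffold, so
#' overlapping annotations are counted once. Introns are the union of gene
#' spans minus the union of exon spans (single-transcript gene models).
#'
#' @param scaffolds Scaffold tibble ([read_fasta()]).
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param repeat_intervals Optional tibble of repeat intervals
#'   (`scaffold_id`, `start`, `end`; 0-based half-open, e.g. from
#'   [read_read_intervals()] on a BED file).
#' @return A one-row tibble: `genes_pct`, `coding_genes_pct`, `exons_pct`,
#'   `introns_pct`, `repeats_pct`, `gene_density_per_mbp`,
#'   `mean_gene_length_bp`.
#' @export
compute_genome_fractions <- function(scaffolds, genes, repeat_intervals = NULL) {
  unknown <- setdiff(genes$scaffold_id, scaffolds$id)
  if (length(unknown)) {
    pw_usage_error(paste0("gene on unknown scaffold '", unknown[1], "'"))
  }
  total_bp <- sum(as.numeric(scaffolds$length))

  # union width in bp of 1-based inclusive spans, per scaffold
  union_bp <- function(scaf, start, end) {
    if (!length(start)) return(0)
    by <- split(seq_along(start), scaf)
    sum(vapply(by, function(i) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start[i], end[i]))))
    }, numeric(1)))
  }
  genes_bp <- union_bp(genes$scaffold_id, genes$start, genes$end)
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  coding_bp <- union_bp(coding$scaffold_id, coding$start, coding$end)

  exon_tbl <- if (nrow(genes)) {
    tidyr::unnest(genes[c("gene_id", "scaffold_id", "exons")], "exons")
  } else {
    tibble(gene_id = character(0), scaffold_id = character(0),
           start = integer(0), end = integer(0))
  }
  exons_bp <- union_bp(exon_tbl$scaffold_id, exon_tbl$start, exon_tbl$end)

  # introns: gene-span union minus exon union; exons are validated to lie
  # within gene spans, so the union difference reduces to a subtraction
  introns_bp <- genes_bp - exons_bp

  repeats_bp <- if (is.null(repeat_intervals) || !nrow(repeat_intervals)) 0 else
    union_bp(repeat_intervals$scaffold_id,
             repeat_intervals$start + 1L, repeat_intervals$end)

  tibble(
    genes_pct = 100 * genes_bp / total_bp,
    coding_genes_pct = 100 * coding_bp / total_bp,
    exons_pct = 100 * exons_bp / total_bp,
    introns_pct = 100 * introns_bp / total_bp,
    repeats_pct = 100 * repeats_bp / total_bp,
    gene_density_per_mbp = nrow(genes) / (total_bp / 1e6),
    mean_gene_length_bp = if (nrow(genes)) mean(genes$end - genes$start + 1) else 0
  )
}
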
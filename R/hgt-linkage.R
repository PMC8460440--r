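#' Genomic-context linkage test for an HGT candidate
#'
#' Contamination, unlike true horizontal transfer, is not physically linked
#' to the host genome. The test requires (i) a *native* neighbour — an
#' annotated protein-coding gene immediately adjacent in per-scaffold gene
#' order (order index +/- 1) that is not itself an HGT candidate — and (ii)
#' at least one mapped long read overlapping both the candidate span and
#' that neighbour's span by at least `min_overlap_bp` each, i.e. a single
#' molecule bridging the junction.
#'
#' @param candidate Gene id of the candidate under test (must be in `genes`).
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param candidates Character vector of all candidate gene ids (used to
#'   disqualify candidate neighbours from being "native").
#' @param reads Read-interval tibble ([read_read_intervals()]; 0-based
#'   half-open).
#' @param min_overlap_bp Minimum read overlap with each of the two gene
#'   spans (default 100 bp).
#' @return A list: `pass` (logical), `neighbor_id`, `read_ids` (bridging
#'   reads), and on failure `reason` (`"no_native_neighbor"` or
#'   `"no_bridging_read"`).
#' @export
check_context_linkage <- function(candidate, genes, candidates, reads,
                                  min_overlap_bp = 100L) {
  i <- match(candidate, genes$gene_id)
  if (is.na(i)) pw_usage_error(paste0("candidate '", candidate, "' absent from gene set"))
  cand <- genes[i, ]
  nbr <- genes[genes$scaffold_id == cand$scaffold_id &
                 abs(genes$order_index - cand$order_index) == 1L &
                 genes$biotype == "protein_coding" &
                 !genes$gene_id %in% candidates, , drop = FALSE]
  if (!nrow(nbr)) {
    return(list(pass = FALSE, neighbor_id = NA_character_,
                read_ids = character(0), reason = "no_native_neighbor"))
  }
  sc_reads <- reads[reads$scaffold_id == cand$scaffold_id, , drop = FALSE]
  # overlap in bp of a 0-based half-open read with a 1-based inclusive span
  ov <- function(r_start, r_end, g_start, g_end) {
    pmax(0L, pmin(r_end, g_end) - pmax(r_start, g_start - 1L))
  }
  cand_ov <- ov(sc_reads$start, sc_reads$end, cand$start, cand$end)
  for (j in seq_len(nrow(nbr))) {
    nbr_ov <- ov(sc_reads$start, sc_reads$end, nbr$start[j], nbr$end[j])
    bridging <- cand_ov >= min_overlap_bp & nbr_ov >= min_overlap_bp
    if (any(bridging)) {
      return(list(pass = TRUE, neighbor_id = nbr$gene_id[j],
                  read_ids = sc_reads$read_id[bridging], reason = NA_character_))
    }
  }
  list(pass = FALSE, neighbor_id = nbr$gene_id[1],
       read_ids = character(0), reason = "no_bridging_read")
}
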
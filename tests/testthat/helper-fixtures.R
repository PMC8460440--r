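# shared fixture builders; everything is generated in code, no data files

# scaffold table with homopolymer sequences of the requested lengths (cheap,
# and GC-neutral pieces are irrelevant for N50/L50 checks)
mk_scaffolds <- function(lengths, ids = sprintf("s%03d", seq_along(lengths))) {
  tibble::tibble(id = ids,
                 sequence = strrep("A", lengths),
                 length = as.integer(lengths))
}

# gene table from a compact spec; single full-span exon per gene
mk_genes <- function(gene_id, scaffold_id, start, end, strand = "+",
                     biotype = "protein_coding") {
  g <- tibble::tibble(gene_id = gene_id, scaffold_id = scaffold_id,
                      start = as.integer(start), end = as.integer(end),
                      strand = rep_len(strand, length(gene_id)),
                      biotype = rep_len(biotype, length(gene_id)))
  g <- dplyr::arrange(g, scaffold_id, start, gene_id)
  g <- dplyr::mutate(dplyr::group_by(g, scaffold_id),
                     order_index = dplyr::row_number() - 1L)
  g <- dplyr::ungroup(g)
  g$exons <- lapply(seq_len(nrow(g)),
                    function(i) tibble::tibble(start = g$start[i], end = g$end[i]))
  g
}

# one outfmt-6 style hit row with the fields that matter for the pipeline
mk_hit <- function(query, group, bitscore, subject = paste0(group, "_s1"),
                   evalue = 1e-20) {
  tibble::tibble(query_id = query, subject_id = subject,
                 percent_identity = 80, alignment_length = 100L,
                 mismatches = 10L, gap_opens = 1L, qstart = 1L, qend = 100L,
                 sstart = 1L, send = 100L, evalue = evalue,
                 bitscore = bitscore, taxon_group = group)
}

mk_hits <- function(...) dplyr::bind_rows(...)

# independent N50/L50 oracle: descending sort and explicit prefix scan
oracle_n50 <- function(lengths) {
  lens <- sort(lengths, decreasing = TRUE)
  total <- sum(as.numeric(lens))
  acc <- 0
  for (i in seq_along(lens)) {
    acc <- acc + lens[i]
    if (acc >= total / 2) return(list(n50 = lens[i], l50 = i))
  }
}

# orthogroup_counts from a plain matrix (focal species first column)
mk_counts <- function(m, focal = "focal",
                      species = c(focal, sprintf("sp%d", seq_len(ncol(m) - 1)))) {
  tbl <- tibble::as_tibble(as.data.frame(m))
  names(tbl) <- species
  tbl <- dplyr::bind_cols(
    tibble::tibble(orthogroup = sprintf("OG%04d", seq_len(nrow(m)))), tbl)
  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, f, progress = FALSE)
  read_counts_matrix(f, focal)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
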
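#' Generate a synthetic genome fixture for the assembly-stats module
#'
#' Emits, deterministically per seed, a small assembly with annotated genes,
#' a circular mitochondrial sequence, and a truth table marking which
#' scaffolds are planted mitochondrial fragments. Fragment scaffolds carry a
#' verbatim substring of the circularised mitochondrial sequence covering at
#' least 50% of the scaffold (60% by construction), padded with random
#' sequence, so the default k-mer containment screen
#' ([screen_mito_fragments()]) flags exactly those scaffolds.
#'
#' @param n_scaffolds Number of nuclear scaffolds.
#' @param scaffold_lengths Optional integer vector of forced lengths
#'   (recycled/truncated to `n_scaffolds`); by default lengths are drawn
#'   log-normally around 8 kb with a 1 kb floor.
#' @param gene_density_per_mbp Expected genes per Mbp (default 300).
#' @param mito_length Mitochondrial genome length in bp (default 15205).
#' @param n_mito_fragments Number of planted mitochondrial-fragment
#'   scaffolds.
#' @param seed Integer seed.
#' @return A list: `scaffolds`, `genes`, `mito` (one-row scaffold tibble),
#'   `truth` (tibble `scaffold_id`, `is_mito_fragment`).
#' @export
generate_genome_fixture <- function(n_scaffolds = 20L, scaffold_lengths = NULL,
                                    gene_density_per_mbp = 300,
                                    mito_length = 15205L,
                                    n_mito_fragments = 2L, seed = 1L) {
  if (n_scaffolds < 1 || mito_length < 1 || gene_density_per_mbp < 0 ||
      n_mito_fragments < 0 || n_mito_fragments > n_scaffolds) {
    pw_usage_error("invalid genome fixture parameters")
  }
  if (mito_length < 31L) {
    warning("mito_length below the default screen k-mer size (31)")
  }
  set.seed(as.integer(seed))
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  lens <- if (is.null(scaffold_lengths)) {
    pmax(1000L, as.integer(round(stats::rlnorm(n_scaffolds, log(8000), 0.5))))
  } else {
    as.integer(rep_len(scaffold_lengths, n_scaffolds))
  }
  mito_seq <- rand_seq(mito_length)
  circ <- paste0(mito_seq, mito_seq)
  frag_idx <- if (n_mito_fragments) seq_len(n_mito_fragments) else integer(0)

  seqs <- character(n_scaffolds)
  for (i in seq_len(n_scaffolds)) {
    if (i %in% frag_idx) {
      frag_len <- min(as.integer(ceiling(0.6 * lens[i])), mito_length)
      from <- sample.int(mito_length, 1)
      frag <- substr(circ, from, from + frag_len - 1L)
      seqs[i] <- paste0(frag, rand_seq(lens[i] - frag_len))
    } else {
      seqs[i] <- rand_seq(lens[i])
    }
  }
  scaffolds <- tibble(id = sprintf("scaffold_%03d", seq_len(n_scaffolds)),
                      sequence = seqs, length = lens)

  gene_rows <- list()
  for (i in seq_len(n_scaffolds)) {
    n_genes <- max(0L, as.integer(round(lens[i] * gene_density_per_mbp / 1e6)))
    if (!n_genes) next
    # non-overlapping spans laid out in equal slots with jitter
    slot <- lens[i] %/% n_genes
    if (slot < 400L) next
    for (j in seq_len(n_genes)) {
      lo <- (j - 1L) * slot + 1L
      span <- min(as.integer(round(runif(1, 300, min(3000, slot * 0.8)))),
                  slot - 2L)
      start <- lo + as.integer(floor(runif(1, 0, slot - span - 1L)))
      end <- start + span
      gid <- sprintf("%s_g%02d", scaffolds$id[i], j)
      # one or two exons inside the span
      exons <- if (span > 900 && runif(1) < 0.5) {
        cut <- start + span %/% 3L
        tibble(start = c(start, cut + 101L), end = c(cut, end))
      } else {
        tibble(start = start, end = end)
      }
      gene_rows[[length(gene_rows) + 1L]] <- tibble(
        gene_id = gid, scaffold_id = scaffolds$id[i],
        start = start, end = end,
        strand = sample(c("+", "-"), 1), biotype = "protein_coding",
        exons = list(exons))
    }
  }
  genes <- if (length(gene_rows)) {
    bind_rows(gene_rows) |>
      arrange(.data$scaffold_id, .data$start, .data$gene_id) |>
      group_by(.data$scaffold_id) |>
      mutate(order_index = row_number() - 1L) |>
      ungroup() |>
      select("gene_id", "scaffold_id", "start", "end", "strand", "biotype",
             "order_index", "exons")
  } else {
    tibble(gene_id = character(0), scaffold_id = character(0),
           start = integer(0), end = integer(0), strand = character(0),
           biotype = character(0), order_index = integer(0), exons = list())
  }

  list(
    scaffolds = scaffolds,
    genes = genes,
    mito = tibble(id = "MT", sequence = mito_seq, length = mito_length),
    truth = tibble(scaffold_id = scaffolds$id,
                   is_mito_fragment = seq_len(n_scaffolds) %in% frag_idx)
  )
}

#' @rdname generate_genome_fixture
#' @param fixture A fixture from [generate_genome_fixture()].
#' @param dir Output directory.
#' @return For `write_genome_fixture()`: named list of written paths,
#'   invisibly.
#' @export
write_genome_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "assembly.fasta"),
                gff = file.path(dir, "genes.gff3"),
                mito = file.path(dir, "mito.fasta"),
                truth = file.path(dir, "truth.tsv"))
  write_fasta(fixture$scaffolds, paths$fasta)
  write_gene_models(fixture$genes, paths$gff)
  write_fasta(fixture$mito, paths$mito)
  readr::write_tsv(fixture$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
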
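#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon (and rRNA/tRNA) features with
#' [rtracklayer::import()] and assembles one record per `gene` feature.
#' Coordinates are kept in the GFF3 convention: 1-based, inclusive. A
#' per-scaffold gene-order index (0-based, by ascending start) is assigned;
#' it drives the "immediately adjacent neighbour" rule of the HGT linkage
#' test.
#'
#' @param path Path to a GFF3 file.
#' @param assembly Optional scaffold table (from [read_fasta()]); when given,
#'   genes on unknown scaffolds are an error.
#' @return A tibble with columns `gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`, `biotype`, `order_index` and a list-column `exons` of
#'   tibbles with `start`/`end` (1-based inclusive), sorted by scaffold then
#'   start.
#' @export
read_gene_models <- function(path, assembly = NULL) {
  if (!file.exists(path)) pw_format_error(paste0("file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) pw_format_error(
      paste0(path, ": GFF3 parse/coordinate error: ", conditionMessage(e)))
  )
  meta <- as.data.frame(gr)
  is_gene <- meta$type %in% c("gene", "rRNA_gene", "tRNA_gene")
  if (!any(is_gene)) {
    pw_format_error(paste0(path, ": no gene features found"))
  }
  g <- meta[is_gene, , drop = FALSE]
  if (any(g$end < g$start)) {
    pw_format_error(paste0(path, ": gene with end < start"))
  }
  gene_id <- as.character(g$ID)
  if (anyNA(gene_id) || any(duplicated(gene_id))) {
    pw_format_error(paste0(path, ": missing or duplicate gene ID attribute"))
  }
  biotype <- if ("biotype" %in% names(g)) as.character(g$biotype) else rep(NA_character_, nrow(g))
  biotype[is.na(biotype)] <- ifelse(g$type[is.na(biotype)] == "rRNA_gene", "rRNA",
                             ifelse(g$type[is.na(biotype)] == "tRNA_gene", "tRNA",
                                    "protein_coding"))

  # map exon -> gene, via mRNA where needed
  parent1 <- function(x) vapply(x, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  mrna <- meta[meta$type == "mRNA", , drop = FALSE]
  mrna_gene <- setNames(parent1(mrna$Parent), as.character(mrna$ID))
  ex <- meta[meta$type == "exon", , drop = FALSE]
  exon_gene <- character(0)
  if (nrow(ex)) {
    p <- parent1(ex$Parent)
    exon_gene <- ifelse(p %in% names(mrna_gene), unname(mrna_gene[p]), p)
  }

  genes <- tibble(
    gene_id = gene_id,
    scaffold_id = as.character(g$seqnames),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = ifelse(as.character(g$strand) %in% c("+", "-"), as.character(g$strand), "+"),
    biotype = biotype
  )
  exon_tbl <- if (nrow(ex)) {
    tibble(gene_id = exon_gene, start = as.integer(ex$start), end = as.integer(ex$end))
  } else {
    tibble(gene_id = character(0), start = integer(0), end = integer(0))
  }
  # validate exons against their gene span
  chk <- dplyr::inner_join(exon_tbl, genes, by = "gene_id", suffix = c("", ".g"))
  if (nrow(chk) && any(chk$start < chk$start.g | chk$end > chk$end.g)) {
    bad <- chk$gene_id[which(chk$start < chk$start.g | chk$end > chk$end.g)[1]]
    pw_format_error(paste0(path, ": exon outside gene span for gene '", bad, "'"))
  }
  if (!is.null(assembly)) {
    unknown <- setdiff(genes$scaffold_id, assembly$id)
    if (length(unknown)) {
      pw_format_error(paste0(path, ": gene on unknown scaffold '", unknown[1], "'"))
    }
  }

  exons_by_gene <- split(exon_tbl[c("start", "end")], exon_tbl$gene_id)
  genes$exons <- lapply(genes$gene_id, function(gid) {
    e <- exons_by_gene[[gid]]
    if (is.null(e)) tibble(start = integer(0), end = integer(0))
    else as_tibble(e[order(e$start), , drop = FALSE])
  })
  genes <- genes |>
    arrange(.data$scaffold_id, .data$start, .data$gene_id) |>
    group_by(.data$scaffold_id) |>
    mutate(order_index = row_number() - 1L) |>
    ungroup()
  genes[c("gene_id", "scaffold_id", "start", "end", "strand", "biotype",
          "order_index", "exons")]
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (for protein-coding genes) and exon features; the inverse
#' of [read_gene_models()] up to the recomputed `order_index`.
#'
#' @param genes Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tpotworm\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
      g$scaffold_id, g$start, g$end, g$strand, g$gene_id, g$biotype))
    ex <- g$exons[[1]]
    if (g$biotype == "protein_coding" || nrow(ex)) {
      tid <- paste0(g$gene_id, ".t1")
      lines <- c(lines, sprintf(
        "%s\tpotworm\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$scaffold_id, g$start, g$end, g$strand, tid, g$gene_id))
      if (nrow(ex)) {
        lines <- c(lines, sprintf(
          "%s\tpotworm\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
          g$scaffold_id, ex$start, ex$end, g$strand, tid, seq_len(nrow(ex)), tid))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
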
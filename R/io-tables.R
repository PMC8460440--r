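blast6_cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
                 "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular homology hit table
#'
#' Reads the standard BLAST `outfmt 6` tab-separated dialect. Rows are never
#' deduplicated or pre-filtered here; best-hit selection is an explicit
#' downstream step ([summarize_best_hits()]). Every hit is stamped with the
#' taxon group of the database it was searched against.
#'
#' @param path Path to a tab-separated 12-column hit table (no header).
#' @param taxon_group One of [hgt_taxon_groups].
#' @return A tibble with the twelve standard columns plus `taxon_group`.
#' @export
read_hit_table <- function(path, taxon_group) {
  taxon_group <- match.arg(taxon_group, hgt_taxon_groups)
  if (!file.exists(path)) pw_format_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as_tibble(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), blast6_cols))
    out$taxon_group <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    pw_format_error(paste0(path, ": expected 12 tab-separated columns, got ",
                           nf[bad], " at line ", bad))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    pw_format_error(paste0(path, ": unparsable numeric field at line ", bad))
  }
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = num[, 1], alignment_length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_opens = as.integer(num[, 4]),
    qstart = as.integer(num[, 5]), qend = as.integer(num[, 6]),
    sstart = as.integer(num[, 7]), send = as.integer(num[, 8]),
    evalue = num[, 9], bitscore = num[, 10],
    taxon_group = taxon_group
  )
  if (any(out$bitscore < 0)) {
    pw_format_error(paste0(path, ": negative bitscore at line ",
                           which(out$bitscore < 0)[1]))
  }
  out
}

#' @rdname read_hit_table
#' @param hits Hit tibble to write (the `taxon_group` column is dropped; the
#'   outfmt-6 dialect has no header).
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[blast6_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an orthogroup gene-count matrix
#'
#' Reads the OrthoFinder `Orthogroups.GeneCount.tsv` dialect: a header of
#' species names, one row per orthogroup, and an optional trailing `Total`
#' column (detected by name and dropped).
#'
#' @param path Path to the tab-separated count table.
#' @param focal_species Name of the focal species; must appear in the header.
#' @return An `orthogroup_counts` tibble: first column `orthogroup`, one
#'   integer column per species, with attributes `focal_species` and
#'   `species_ids`.
#' @export
read_counts_matrix <- function(path, focal_species) {
  if (!file.exists(path)) pw_format_error(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) pw_format_error(paste0(path, ": need an orthogroup column and >=1 species"))
  names(tbl)[1] <- "orthogroup"
  if (tolower(names(tbl)[ncol(tbl)]) == "total") tbl <- tbl[-ncol(tbl)]
  species <- names(tbl)[-1]
  if (!focal_species %in% species) {
    pw_usage_error(paste0("focal species '", focal_species, "' absent from header of ", path))
  }
  counts <- tbl[species]
  ok <- vapply(counts, function(x) {
    length(x) == 0L ||
      (is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x)))
  }, logical(1))
  if (!all(ok)) {
    pw_format_error(paste0(path, ": counts must be non-negative integers (column '",
                           species[which(!ok)[1]], "')"))
  }
  tbl[species] <- lapply(counts, as.integer)
  new_orthogroup_counts(tbl, focal_species)
}

new_orthogroup_counts <- function(tbl, focal_species) {
  structure(as_tibble(tbl),
            focal_species = focal_species,
            species_ids = names(tbl)[-1],
            class = c("orthogroup_counts", class(as_tibble(tbl))))
}

#' @rdname read_counts_matrix
#' @param counts An `orthogroup_counts` object.
#' @param total Whether to append the OrthoFinder-style `Total` column.
#' @export
write_counts_matrix <- function(counts, path, total = FALSE) {
  out <- as_tibble(counts)
  names(out)[1] <- "Orthogroup"
  if (total) out$Total <- rowSums(out[-1])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_counts_matrix
#' @export
focal_species <- function(counts) attr(counts, "focal_species")

#' @rdname read_counts_matrix
#' @export
species_ids <- function(counts) attr(counts, "species_ids")

#' Read long-read alignment intervals
#'
#' Converts PAF (target name/start/end in columns 6/9/10, 0-based half-open)
#' or BED3+ rows to the internal read-interval convention: 0-based,
#' half-open on the target scaffold.
#'
#' @param path Path to a PAF or BED file.
#' @param dialect `"paf"` or `"bed"`.
#' @return A tibble with `read_id`, `scaffold_id`, `start`, `end`.
#' @export
read_read_intervals <- function(path, dialect = c("paf", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pw_format_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(read_id = character(0), scaffold_id = character(0),
                  start = integer(0), end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "paf") 12L else 3L
  if (any(nf < need)) {
    bad <- which(nf < need)[1]
    pw_format_error(paste0(path, ": malformed ", toupper(dialect), " row at line ", bad))
  }
  if (dialect == "paf") {
    out <- tibble(
      read_id = vapply(fields, `[[`, character(1), 1),
      scaffold_id = vapply(fields, `[[`, character(1), 6),
      start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 8))),
      end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 9)))
    )
  } else {
    out <- tibble(
      read_id = vapply(seq_along(fields), function(i) {
        if (nf[i] >= 4L) fields[[i]][[4]] else paste0("read_", i)
      }, character(1)),
      scaffold_id = vapply(fields, `[[`, character(1), 1),
      start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2))),
      end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
    )
  }
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    pw_format_error(paste0(path, ": unparsable coordinate at line ", bad))
  }
  if (any(out$end <= out$start) || any(out$start < 0)) {
    bad <- which(out$end <= out$start | out$start < 0)[1]
    pw_format_error(paste0(path, ": interval with end <= start at line ", bad))
  }
  out
}

#' @rdname read_read_intervals
#' @param reads Read-interval tibble to write as minimal PAF rows.
#' @export
write_read_intervals <- function(reads, path) {
  len <- reads$end - reads$start
  lines <- sprintf("%s\t%d\t0\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                   reads$read_id, len, len, reads$scaffold_id,
                   reads$end + 1000L, reads$start, reads$end, len, len)
  writeLines(lines, path)
  invisible(path)
}
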
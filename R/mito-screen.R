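#' Screen scaffolds for mitochondrial fragments by k-mer containment
#'
#' Genome assemblies frequently retain nuclear scaffolds that are in fact
#' fragmented copies of the separately assembled mitochondrial genome; these
#' must be found and removed before nuclear statistics are reported. The
#' screen is an exact k-mer containment test: for each scaffold of length
#' `>= k`, the containment is the fraction of its k-mer positions whose
#' canonical k-mer (lexicographic minimum of the k-mer and its reverse
#' complement, so either strand matches) occurs in the mitochondrial
#' sequence. The mitochondrial genome is treated as circular, so wrap-around
#' k-mers are included. K-mers containing ambiguity codes can never match and
#' count against containment.
#'
#' @param scaffolds Scaffold tibble ([read_fasta()]).
#' @param mito_sequence Mitochondrial genome sequence (single string, or a
#'   one-row scaffold tibble).
#' @param k K-mer size (default 31, long enough that chance matches are
#'   negligible).
#' @param threshold Containment at or above which a scaffold is flagged.
#' @return A tibble with one row per scaffold of length `>= k`:
#'   `scaffold_id`, `containment` (in `[0, 1]`), `flagged`.
#' @export
screen_mito_fragments <- function(scaffolds, mito_sequence, k = 31L,
                                  threshold = 0.5) {
  if (is.data.frame(mito_sequence)) mito_sequence <- mito_sequence$sequence[[1]]
  mito_sequence <- toupper(mito_sequence)
  if (nchar(mito_sequence) < k) {
    pw_usage_error(paste0("k = ", k, " exceeds mitochondrial sequence length ",
                          nchar(mito_sequence)))
  }
  circ <- paste0(mito_sequence, substr(mito_sequence, 1L, k - 1L))
  mito_set <- unique(canonical_kmers(circ, k))
  mito_set <- mito_set[!is.na(mito_set)]

  keep <- scaffolds$length >= k
  sc <- scaffolds[keep, , drop = FALSE]
  containment <- vapply(sc$sequence, function(s) {
    km <- canonical_kmers(toupper(s), k)
    mean(!is.na(km) & km %in% mito_set)
  }, numeric(1), USE.NAMES = FALSE)
  tibble(
    scaffold_id = sc$id,
    containment = containment,
    flagged = containment >= threshold
  )
}

# canonical (strand-collapsed) k-mers at every position; NA where the window
# contains a non-ACGT character
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  valid <- !grepl("[^ACGT]", km)
  out <- rep(NA_character_, length(km))
  if (any(valid)) {
    fwd <- km[valid]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
    out[valid] <- pmin(fwd, rc)
  }
  out
}
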
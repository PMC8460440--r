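#' Gene-family expansion/contraction z-scores
#'
#' For every orthogroup (gene family), each species' gene count is
#' standardised against the family's cross-species mean and standard
#' deviation:
#' \deqn{z = (x_s - \bar x) / \mathrm{sd}(x)}
#' computed over the counts of *all* species in the matrix (zeros included;
#' set `species_scope = "representing"` to use only species with at least one
#' gene). A family is *eligible* when the focal species is represented
#' (count >= 1) and at least `min_other_species` other species are
#' represented. For eligible families, `z >= 2` flags a significant
#' expansion and `z <= -2` a contraction. Families whose counts are constant
#' across species have `sd = 0`; their z is undefined and they are reported
#' as `undefined_sd`, never expanded or contracted.
#'
#' With the sample standard deviation over `n` species, `|z|` can never
#' exceed `(n - 1) / sqrt(n)`; a single-species deviation therefore cannot
#' reach `|z| >= 2` with fewer than six species in the matrix.
#'
#' @param counts An `orthogroup_counts` object ([read_counts_matrix()]).
#' @param min_other_species Minimum number of represented non-focal species
#'   for a family to be eligible (default 3).
#' @param sd_mode `"sample"` (denominator `n - 1`, default) or
#'   `"population"` (denominator `n`).
#' @param species_scope Which species enter the family mean/sd: `"all"`
#'   (default) or `"representing"` (count >= 1 only).
#' @return A `family_zscores` tibble with one row per orthogroup x species:
#'   `orthogroup_id`, `species_id`, `count`, `z`, `eligible`, `status`
#'   (`expanded`, `contracted`, `neither`, `ineligible`, `undefined_sd`).
#' @examples
#' tbl <- tibble::tibble(orthogroup = "OG1",
#'                       Ec = 129L, s2 = 1L, s3 = 1L, s4 = 1L, s5 = 1L,
#'                       s6 = 1L, s7 = 1L, s8 = 1L, s9 = 1L)
#' z <- family_zscores(read_counts_matrix(write_counts_matrix(
#'   potworm:::new_orthogroup_counts(tbl, "Ec"), tempfile()), "Ec"))
#' z[z$species_id == "Ec", ]  # z = 8/3, expanded
#' @export
family_zscores <- function(counts, min_other_species = 3L,
                           sd_mode = c("sample", "population"),
                           species_scope = c("all", "representing")) {
  sd_mode <- match.arg(sd_mode)
  species_scope <- match.arg(species_scope)
  sp <- species_ids(counts)
  focal <- focal_species(counts)
  if (length(sp) < 2L) pw_usage_error("need at least 2 species for z-scores")

  m <- as.matrix(as_tibble(counts)[sp])
  og <- as_tibble(counts)$orthogroup

  stat <- t(apply(m, 1L, function(x) {
    xs <- if (species_scope == "all") x else x[x >= 1]
    if (length(xs) < 2L) return(c(NA_real_, NA_real_))
    mu <- mean(xs)
    s <- if (sd_mode == "sample") sd(xs) else sqrt(mean((xs - mu)^2))
    c(mu, s)
  }))
  eligible <- m[, focal] >= 1 &
    rowSums(m[, setdiff(sp, focal), drop = FALSE] >= 1) >= min_other_species

  out <- tibble(
    orthogroup_id = rep(og, each = length(sp)),
    species_id = rep(sp, times = length(og)),
    count = as.integer(t(m)),
    z = as.numeric((t(m) - rep(stat[, 1], each = length(sp))) /
                     rep(stat[, 2], each = length(sp))),
    eligible = rep(eligible, each = length(sp))
  )
  sd0 <- rep(is.na(stat[, 2]) | stat[, 2] == 0, each = length(sp))
  out$z[sd0] <- NA_real_
  out$status <- dplyr::case_when(
    !out$eligible ~ "ineligible",
    sd0 ~ "undefined_sd",
    out$z >= 2 ~ "expanded",
    out$z <= -2 ~ "contracted",
    TRUE ~ "neither"
  )
  structure(out, focal_species = focal,
            class = c("family_zscores", class(out)))
}

#' Lineage-specific gene families
#'
#' Orthogroups with at least one gene in the focal species and zero genes in
#' every other species.
#'
#' @inheritParams family_zscores
#' @return Character vector of orthogroup ids.
#' @export
lineage_specific_families <- function(counts) {
  sp <- species_ids(counts)
  focal <- focal_species(counts)
  m <- as.matrix(as_tibble(counts)[sp])
  sel <- m[, focal] >= 1 &
    rowSums(m[, setdiff(sp, focal), drop = FALSE]) == 0
  as_tibble(counts)$orthogroup[sel]
}

#' Families shared by a set of species
#'
#' Families with at least one gene in *every* species of `species_subset`.
#' With `exclusive = TRUE` the count must additionally be zero in every
#' species outside the subset (the Venn-region semantics of shared-family
#' diagrams).
#'
#' @inheritParams family_zscores
#' @param species_subset Character vector of species ids (non-empty subset of
#'   the matrix's species).
#' @param exclusive Venn-region semantics (see above).
#' @return A list with elements `count` and `ids`.
#' @export
shared_families <- function(counts, species_subset, exclusive = FALSE) {
  sp <- species_ids(counts)
  if (!length(species_subset)) pw_usage_error("species_subset must be non-empty")
  unknown <- setdiff(species_subset, sp)
  if (length(unknown)) {
    pw_usage_error(paste0("unknown species id '", unknown[1], "'"))
  }
  m <- as.matrix(as_tibble(counts)[sp])
  sel <- rowSums(m[, species_subset, drop = FALSE] >= 1) == length(species_subset)
  if (exclusive) {
    outside <- setdiff(sp, species_subset)
    if (length(outside)) {
      sel <- sel & rowSums(m[, outside, drop = FALSE]) == 0
    }
  }
  ids <- as_tibble(counts)$orthogroup[sel]
  list(count = length(ids), ids = ids)
}

#' Rank significant expansions by focal gene count
#'
#' Orders the focal species' expanded families the way top-expansion tables
#' are printed: by focal gene count descending, ties broken by z descending,
#' then by orthogroup id.
#'
#' @param zscores A `family_zscores` tibble ([family_zscores()]).
#' @param top_n Number of rows to keep (default 10).
#' @return A tibble `orthogroup_id`, `count`, `z` for the top expansions.
#' @export
rank_expansions <- function(zscores, top_n = 10L) {
  focal <- attr(zscores, "focal_species")
  zscores |>
    filter(.data$species_id == focal, .data$status == "expanded") |>
    arrange(desc(.data$count), desc(.data$z), .data$orthogroup_id) |>
    slice_head(n = top_n) |>
    select("orthogroup_id", "count", "z")
}

#' Classify an intra-genome collinear block
#'
#' A duplicated gene block whose two copies sit on different scaffolds is
#' `inter_scaffold`. Within one scaffold, paired genes on opposite strands
#' form an inverted copy (`palindrome`); paired genes on the same strand form
#' a `tandem` repeat. With mixed pair orientations the majority decides
#' (ties fall to `palindrome`, the stronger structural signal).
#'
#' @param gene_pairs Tibble with columns `gene_a`, `gene_b` (one collinear
#'   gene pair per row).
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @return One of `"palindrome"`, `"tandem"`, `"inter_scaffold"`.
#' @export
classify_collinear_block <- function(gene_pairs, genes) {
  lookup <- function(ids) {
    i <- match(ids, genes$gene_id)
    if (anyNA(i)) {
      pw_usage_error(paste0("unknown gene id '", ids[which(is.na(i))[1]], "'"))
    }
    genes[i, , drop = FALSE]
  }
  a <- lookup(gene_pairs$gene_a)
  b <- lookup(gene_pairs$gene_b)
  if (any(a$scaffold_id != b$scaffold_id)) return("inter_scaffold")
  opposite <- a$strand != b$strand
  if (sum(opposite) * 2 >= length(opposite)) "palindrome" else "tandem"
}
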
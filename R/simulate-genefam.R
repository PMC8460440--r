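#' Generate a synthetic orthogroup count matrix with planted families
#'
#' Builds a seeded orthogroup x species count matrix in which chosen rows
#' are planted as focal-species expansions (focal z >= 2 under the
#' sample-sd rule), contractions (focal z <= -2), lineage-specific families
#' (genes only in the focal species), or neutral families. Planted
#' expansions/contractions are verified against [family_zscores()] before
#' emission: rows are drawn with cross-species noise, and if the noise pushes
#' the focal z inside the threshold the row falls back to the deterministic
#' single-outlier pattern whose focal z is exactly
#' `(n - 1) / sqrt(n)` (in magnitude), the analytic maximum. Because of that
#' bound, planting an expansion or contraction requires at least 6 species;
#' smaller matrices are rejected.
#'
#' @param n_species Number of species including the focal one (>= 4).
#' @param n_expanded,n_contracted,n_lineage,n_neutral Planted row counts.
#' @param focal Focal species id (default `"Ecrypticus"`, listed first).
#' @param seed Integer seed.
#' @return A list: `counts` (an `orthogroup_counts`), `truth` (tibble
#'   `orthogroup_id`, `class` over
#'   `expanded`/`contracted`/`lineage_specific`/`neutral`).
#' @examples
#' fix <- generate_family_counts_fixture(n_species = 9, n_expanded = 2, seed = 1)
#' fix$truth
#' @export
generate_family_counts_fixture <- function(n_species = 9L, n_expanded = 5L,
                                           n_contracted = 5L, n_lineage = 5L,
                                           n_neutral = 50L,
                                           focal = "Ecrypticus", seed = 1L) {
  if (n_species < 4L) pw_usage_error("n_species must be at least 4")
  if (any(c(n_expanded, n_contracted, n_lineage, n_neutral) < 0)) {
    pw_usage_error("planted class counts must be non-negative")
  }
  zmax <- (n_species - 1) / sqrt(n_species)
  if ((n_expanded > 0 || n_contracted > 0) && zmax < 2) {
    pw_usage_error(paste0(
      "with ", n_species, " species the focal z-score can never exceed ",
      sprintf("%.3f", zmax), " in magnitude; expansions/contractions at |z| >= 2 ",
      "are infeasible (need >= 6 species)"))
  }
  set.seed(as.integer(seed))
  species <- c(focal, sprintf("sp%02d", seq_len(n_species - 1L)))
  n_other <- n_species - 1L

  focal_z <- function(x) {  # sample-sd z of the first (focal) entry
    s <- sd(x)
    if (is.na(s) || s == 0) return(NA_real_)
    (x[1] - mean(x)) / s
  }
  make_expanded <- function() {
    base <- sample(1:3, 1)
    for (try in 1:10) {
      others <- base + sample(0:1, n_other, replace = TRUE, prob = c(0.8, 0.2))
      row <- c(base + sample(8:30, 1), others)
      if (!is.na(focal_z(row)) && focal_z(row) >= 2) return(row)
    }
    c(base + 10L, rep(base, n_other))  # exact single-outlier pattern
  }
  make_contracted <- function() {
    base <- sample(8:15, 1)
    for (try in 1:10) {
      others <- base + sample(0:1, n_other, replace = TRUE, prob = c(0.8, 0.2))
      row <- c(1L, others)
      if (!is.na(focal_z(row)) && focal_z(row) <= -2) return(row)
    }
    c(1L, rep(base, n_other))
  }
  make_lineage <- function() c(sample(2:8, 1), rep(0L, n_other))
  make_neutral <- function() {
    for (try in 1:20) {
      row <- rpois(n_species, lambda = 3)
      z <- focal_z(row)
      lineage <- row[1] >= 1 && sum(row[-1]) == 0
      if (!lineage && (is.na(z) || abs(z) < 2)) return(row)
    }
    rep(2L, n_species)  # constant row: sd 0, flagged nowhere
  }

  classes <- c(rep("expanded", n_expanded), rep("contracted", n_contracted),
               rep("lineage_specific", n_lineage), rep("neutral", n_neutral))
  rows <- lapply(classes, function(cl) switch(cl,
    expanded = make_expanded(), contracted = make_contracted(),
    lineage_specific = make_lineage(), neutral = make_neutral()))
  og <- sprintf("OG%07d", seq_along(classes))
  tbl <- as_tibble(cbind(
    tibble(orthogroup = og),
    as_tibble(setNames(as.data.frame(
      matrix(as.integer(unlist(rows)), ncol = n_species, byrow = TRUE)), species))
  ))
  counts <- new_orthogroup_counts(tbl, focal)

  # internal verification of every planted expansion/contraction
  if (length(classes)) {
    z <- family_zscores(counts)
    zf <- z[z$species_id == focal, ]
    st <- setNames(zf$status, zf$orthogroup_id)
    bad <- (classes == "expanded" & st[og] != "expanded") |
      (classes == "contracted" & st[og] != "contracted")
    stopifnot("planted family failed internal z verification" = !any(bad))
  }
  list(counts = counts,
       truth = tibble(orthogroup_id = og, class = classes))
}

#' @rdname generate_family_counts_fixture
#' @param fixture A fixture from [generate_family_counts_fixture()].
#' @param dir Output directory.
#' @return For `write_family_fixture()`: named list of written paths,
#'   invisibly.
#' @export
write_family_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(dir, "Orthogroups.GeneCount.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_counts_matrix(fixture$counts, paths$counts, total = TRUE)
  readr::write_tsv(fixture$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
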
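#' Read a gene tree from a Newick file
#'
#' Thin validated wrapper over [ape::read.tree()]. Leaf labels follow the
#' convention `"<taxon_group>|<sequence_id>"` for database sequences; the
#' HGT candidate leaf is labelled with the bare gene id (no `|`). Support
#' values and branch lengths are parsed but nothing downstream requires
#' them.
#'
#' @param path Path to a file containing a single Newick tree ending in `;`.
#' @return An [ape::read.tree()] `phylo` object, rooted as written.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) pw_format_error(paste0("file not found: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt, where = path)
}

parse_newick <- function(txt, where = "newick") {
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close || !grepl(";\\s*$", txt)) {
    pw_format_error(paste0(where, ": unbalanced parentheses or missing ';'"))
  }
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    pw_format_error(paste0(where, ": Newick parse error"))
  }
  tr
}

#' Read a directory of per-candidate gene trees
#'
#' @param dir Directory containing one `<gene_id>.nwk` file per candidate.
#' @param pattern Filename pattern for tree files.
#' @return A named list of `phylo` objects keyed by gene id (file base name).
#' @export
read_gene_trees <- function(dir, pattern = "\\.nwk$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  trees <- lapply(files, read_tree)
  names(trees) <- sub(pattern, "", basename(files))
  trees
}

#' Taxon groups of tree leaf labels
#'
#' Splits labels of the form `"group|id"`; labels without a `|` (the
#' candidate leaf, or unlabelled sequences) get `NA`.
#'
#' @param labels Character vector of leaf labels.
#' @return Character vector of group labels (or `NA`).
#' @export
leaf_taxon_groups <- function(labels) {
  ifelse(grepl("|", labels, fixed = TRUE), sub("\\|.*$", "", labels), NA_character_)
}
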
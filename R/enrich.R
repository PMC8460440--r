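#' GO term enrichment by one-sided hypergeometric test
#'
#' For each GO term annotated to at least one foreground gene, tests
#' over-representation of the term in the foreground (e.g. confirmed HGT
#' genes) against the background (e.g. all annotated genes) with the
#' one-sided hypergeometric tail, then applies Benjamini-Hochberg correction
#' within each GO namespace.
#'
#' @param foreground Character vector of gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of gene ids.
#' @param annotations Tibble with columns `gene_id`, `go_term`, `namespace`
#'   (`"BP"`, `"MF"` or `"CC"`).
#' @param alpha Report terms with BH-adjusted q at or below this (default
#'   0.05).
#' @return A tibble `go_term`, `namespace`, `k_fg`, `n_fg`, `k_bg`, `n_bg`,
#'   `p_value`, `q_value`, sorted by q then p.
#' @export
enrich_go <- function(foreground, background, annotations, alpha = 0.05) {
  if (length(setdiff(foreground, background))) {
    pw_usage_error("foreground must be a subset of background")
  }
  ann <- annotations |>
    filter(.data$gene_id %in% background) |>
    distinct(.data$gene_id, .data$go_term, .data$namespace)
  if (!nrow(ann)) {
    return(tibble(go_term = character(0), namespace = character(0),
                  k_fg = integer(0), n_fg = integer(0), k_bg = integer(0),
                  n_bg = integer(0), p_value = numeric(0), q_value = numeric(0)))
  }
  n_fg <- length(unique(foreground))
  n_bg <- length(unique(background))
  res <- ann |>
    group_by(.data$go_term, .data$namespace) |>
    summarise(k_fg = sum(unique(.data$gene_id) %in% foreground),
              k_bg = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    filter(.data$k_fg >= 1L) |>
    mutate(n_fg = n_fg, n_bg = n_bg,
           p_value = phyper(.data$k_fg - 1L, .data$k_bg, n_bg - .data$k_bg,
                            n_fg, lower.tail = FALSE)) |>
    group_by(.data$namespace) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    filter(.data$q_value <= alpha) |>
    arrange(.data$q_value, .data$p_value, .data$go_term) |>
    select("go_term", "namespace", "k_fg", "n_fg", "k_bg", "n_bg",
           "p_value", "q_value")
  res
}
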
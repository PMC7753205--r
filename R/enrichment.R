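# One-tailed hypergeometric term over-representation (GO/Pfam style).

#' Term over-representation by the one-tailed hypergeometric test
#'
#' Tests whether each annotation term is over-represented in a query gene
#' set relative to a universe of expressed genes. Terms annotating fewer
#' than `min_term_size` universe genes are removed before testing; the
#' upper-tail p-value is `P(X >= k)` for `X ~ hypergeometric(N, K, n)`;
#' Benjamini-Hochberg adjustment runs across the retained terms and a
#' term is flagged significant when `q < alpha`.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `universe`).
#' @param annotations Two-column table (`gene_id`, `term`); annotations of
#'   genes outside the universe are ignored (reported via a message).
#'   Apply per annotation source (GO, Pfam) to adjust within source.
#' @param universe Character vector of expressed genes (the background).
#' @param min_term_size Minimum universe genes per term (default 5).
#' @param alpha Significance level on q-values.
#' @return Tibble of class `enrich_result`, sorted by q then p: `term`,
#'   `k` (query hits), `K` (term size in universe), `n` (query size),
#'   `N` (universe size), `p`, `q`, `significant`.
#' @export
enrich <- function(query, annotations, universe, min_term_size = 5,
                   alpha = 0.05) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("`universe` is empty")
  if (length(query) == 0) abort("`query` is empty")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    abort(sprintf("query gene(s) outside the universe, e.g.: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  assert_cols(annotations, c("gene_id", "term"), "`annotations`")
  ann <- distinct(annotations, .data$gene_id, .data$term)
  dropped <- sum(!ann$gene_id %in% universe)
  if (dropped > 0) {
    inform(sprintf(
      "enrich: ignored %d annotation(s) of genes outside the universe",
      dropped
    ))
  }
  ann <- filter(ann, .data$gene_id %in% universe)

  N <- length(universe)
  n <- length(query)
  term_stats <- ann %>%
    group_by(.data$term) %>%
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% query),
      .groups = "drop"
    ) %>%
    filter(.data$K >= min_term_size)

  out <- term_stats %>%
    mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
      q = adjust_fdr(.data$p),
      significant = .data$q < alpha
    ) %>%
    arrange(.data$q, .data$p, .data$term) %>%
    select("term", "k", "K", "n", "N", "p", "q", "significant")
  class(out) <- c("enrich_result", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @rdname enrich
#' @param x,object An `enrich_result`.
#' @param ... Unused.
#' @export
tidy.enrich_result <- function(x, ...) {
  as_tibble(x)
}

#' @rdname enrich
#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% NA_real_,
    universe_size = if (nrow(x) > 0) x$N[1] else NA_integer_
  )
}

#' @rdname enrich
#' @export
autoplot.enrich_result <- function(object, ...) {
  dat <- as_tibble(object) %>%
    filter(.data$significant) %>%
    mutate(term = stats::reorder(.data$term, -.data$q))
  ggplot2::ggplot(dat, ggplot2::aes(-log10(.data$q), .data$term,
                                    size = .data$k / .data$n,
                                    colour = .data$q)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL,
                  size = "query fraction", colour = "q") +
    ggplot2::theme_minimal()
}

#' Shared significant terms between two enrichment results
#'
#' Intersects the significant term sets of two enrichment runs over the
#' same universe and reports both q-values per shared term.
#'
#' @param rows_a,rows_b Two `enrich_result` objects computed on the same
#'   universe.
#' @return Tibble `term`, `q_a`, `q_b`.
#' @export
compare_term_overlap <- function(rows_a, rows_b) {
  na <- if (nrow(rows_a) > 0) rows_a$N[1] else NA_integer_
  nb <- if (nrow(rows_b) > 0) rows_b$N[1] else NA_integer_
  if (!is.na(na) && !is.na(nb) && na != nb) {
    abort("the two enrichment results use different universes")
  }
  sig_a <- filter(rows_a, .data$significant)
  sig_b <- filter(rows_b, .data$significant)
  inner_join(
    select(sig_a, "term", q_a = "q"),
    select(sig_b, "term", q_b = "q"),
    by = "term"
  ) %>%
    arrange(.data$q_a)
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path TSV with gene ids in the first column and term ids in the
#'   second (header optional).
#' @return Tibble `gene_id`, `term`.
#' @export
read_annotations <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- any(tolower(first) %in% c("gene_id", "gene", "term",
                                          "term_id"))
  tab <- readr::read_tsv(
    path, col_names = if (has_header) TRUE else c("gene_id", "term"),
    show_col_types = FALSE, progress = FALSE
  )
  names(tab)[1:2] <- c("gene_id", "term")
  tab[1:2]
}
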
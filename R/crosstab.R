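# Cross-tabulation of regulatory categories by duplication mode, the
# chi-squared comparisons over it, and DEG summary tables.

#' Cross-tabulate regulatory categories by duplication mode
#'
#' Counts genes in each duplication mode x regulatory category cell and
#' row-normalises to percentages (rounded half up to 2 decimals, the
#' presentation convention of published tables). A `Total` row holds the
#' column sums.
#'
#' @param calls A `reg_calls` tibble (or any tibble with `gene_id` and
#'   `category`).
#' @param assignments Duplication assignments (`gene_id`, `mode`).
#' @return Object of class `cross_table`: a list with `counts` and
#'   `proportions` (wide tibbles, one row per mode plus `Total`).
#'   Long form via [tidy()]; totals via [glance()].
#' @export
crosstab <- function(calls, assignments) {
  assert_cols(calls, c("gene_id", "category"), "`calls`")
  assert_cols(assignments, c("gene_id", "mode"), "`assignments`")
  missing <- setdiff(calls$gene_id, assignments$gene_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "%d classified gene(s) lack a duplication assignment, e.g.: %s",
      length(missing), paste(head(missing, 5), collapse = ", ")
    ))
  }
  joined <- calls %>%
    select("gene_id", "category") %>%
    left_join(select(assignments, "gene_id", "mode"), by = "gene_id") %>%
    mutate(
      mode = factor(as.character(.data$mode), levels = DUP_MODES),
      category = factor(as.character(.data$category), levels = REG_CATEGORIES)
    )
  counts_mat <- table(joined$mode, joined$category)
  counts_mat <- rbind(counts_mat, Total = colSums(counts_mat))
  props <- round_half_up(100 * counts_mat / pmax(rowSums(counts_mat), 1), 2)

  to_tbl <- function(m) {
    bind_cols(tibble(mode = rownames(m)), as_tibble(as.data.frame.matrix(m)))
  }
  structure(
    list(counts = to_tbl(counts_mat), proportions = to_tbl(props)),
    class = "cross_table"
  )
}

#' @export
print.cross_table <- function(x, ...) {
  cat("<cross_table> counts:\n")
  print(x$counts)
  cat("row percentages:\n")
  print(x$proportions)
  invisible(x)
}

#' @rdname crosstab
#' @param x,object A `cross_table`.
#' @param ... Unused.
#' @export
tidy.cross_table <- function(x, ...) {
  long <- function(tab, value_name) {
    tidyr::pivot_longer(tab, -"mode", names_to = "category",
                        values_to = value_name)
  }
  left_join(long(x$counts, "n"), long(x$proportions, "pct"),
            by = c("mode", "category"))
}

#' @rdname crosstab
#' @export
glance.cross_table <- function(x, ...) {
  total <- x$counts[x$counts$mode == "Total", -1]
  tibble(
    n_genes = sum(unlist(total)),
    n_modes = nrow(x$counts) - 1L,
    n_categories = ncol(x$counts) - 1L
  )
}

#' @rdname crosstab
#' @export
autoplot.cross_table <- function(object, ...) {
  dat <- tidy(object) %>% filter(.data$mode != "Total")
  ggplot2::ggplot(dat, ggplot2::aes(.data$mode, .data$pct,
                                    fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "duplication mode", y = "% of genes",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' Chi-squared test of cis-only vs trans-only gene counts
#'
#' One-degree-of-freedom goodness-of-fit test of the two counts against a
#' 1:1 ratio, without continuity correction.
#'
#' @param counts_cis,counts_trans Gene counts in the two categories.
#' @return One-row tibble `statistic`, `df`, `p_value` (`NA` with a
#'   message when both counts are zero).
#' @export
cis_vs_trans_test <- function(counts_cis, counts_trans) {
  if (counts_cis < 0 || counts_trans < 0) abort("counts must be >= 0")
  if (counts_cis + counts_trans == 0) {
    inform("cis_vs_trans_test: both counts zero; test undefined")
    return(tibble(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  fit <- suppressWarnings(
    chisq.test(c(counts_cis, counts_trans), p = c(0.5, 0.5), correct = FALSE)
  )
  tibble(statistic = unname(fit$statistic), df = 1L,
         p_value = unname(fit$p.value))
}

#' Chi-squared comparison of a mode's category rate against the genome
#'
#' 2x2 chi-squared (no continuity correction) of category membership in
#' one duplication mode versus the rest of the genome: the table is
#' `[[mode_cis, mode_total - mode_cis], [rest_cis, rest_other]]` with
#' rest = genome minus the mode's genes.
#'
#' @param mode_cis,mode_total Category count and gene total in the mode.
#' @param genome_cis,genome_total Genome-wide category count and total
#'   (including the mode's genes).
#' @return One-row tibble `statistic`, `df`, `p_value` (`NA` with a
#'   message on degenerate margins).
#' @export
mode_vs_genome_test <- function(mode_cis, mode_total, genome_cis,
                                genome_total) {
  if (mode_cis > mode_total || genome_cis > genome_total ||
      mode_total > genome_total || mode_cis > genome_cis) {
    abort("inconsistent counts: mode counts must be contained in genome counts")
  }
  tab <- matrix(
    c(mode_cis, mode_total - mode_cis,
      genome_cis - mode_cis,
      (genome_total - mode_total) - (genome_cis - mode_cis)),
    nrow = 2, byrow = TRUE
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    inform("mode_vs_genome_test: degenerate margin; test undefined")
    return(tibble(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(fit$statistic), df = 1L,
         p_value = unname(fit$p.value))
}

#' Summarise differentially expressed genes per comparison
#'
#' Builds a DEG summary in the style of a published genotype-comparison
#' table: for each pairwise comparison, the number of DEGs and its
#' percentage of all expressed genes (1 decimal, half-up), split into up-
#' and down-regulated subtotals.
#'
#' @param deg_sets Either a tibble of gene-level records (`comparison`,
#'   `gene_id`, `direction` in `up`/`down`) or of per-comparison counts
#'   (`comparison`, `up`, `down`, optional `total` which must equal
#'   `up + down`).
#' @param n_expressed Number of expressed genes (denominator).
#' @return Tibble `comparison`, `degs`, `degs_pct`, `up`, `up_pct`,
#'   `down`, `down_pct`.
#' @export
deg_summary <- function(deg_sets, n_expressed) {
  if (n_expressed <= 0) abort("`n_expressed` must be > 0")
  if ("gene_id" %in% names(deg_sets)) {
    assert_cols(deg_sets, c("comparison", "gene_id", "direction"),
                "`deg_sets`")
    bad <- setdiff(unique(deg_sets$direction), c("up", "down"))
    if (length(bad) > 0) abort("`direction` must be 'up' or 'down'")
    counts <- deg_sets %>%
      count(.data$comparison, .data$direction) %>%
      tidyr::pivot_wider(names_from = "direction", values_from = "n",
                         values_fill = 0L)
    for (col in c("up", "down")) {
      if (!col %in% names(counts)) counts[[col]] <- 0L
    }
  } else {
    assert_cols(deg_sets, c("comparison", "up", "down"), "`deg_sets`")
    counts <- deg_sets
    if ("total" %in% names(counts) &&
        any(counts$total != counts$up + counts$down)) {
      abort("up + down must equal total in every comparison")
    }
  }
  counts %>%
    mutate(
      degs = .data$up + .data$down,
      degs_pct = round_half_up(100 * .data$degs / n_expressed, 1),
      up_pct = round_half_up(100 * .data$up / n_expressed, 1),
      down_pct = round_half_up(100 * .data$down / n_expressed, 1)
    ) %>%
    select("comparison", "degs", "degs_pct", "up", "up_pct", "down",
           "down_pct")
}

#' Run the published-table chi-squared comparisons over a cross table
#'
#' For every duplication mode: the cis-only vs trans-only 1:1 test, and
#' the 2x2 mode-vs-genome comparison of the cis-only rate.
#'
#' @param xtab A `cross_table` from [crosstab()].
#' @return Tibble `mode`, `test`, `statistic`, `df`, `p_value`.
#' @export
crosstab_tests <- function(xtab) {
  counts <- xtab$counts
  total_row <- counts[counts$mode == "Total", ]
  modes <- counts$mode[counts$mode != "Total"]
  rows <- list()
  for (m in modes) {
    row <- counts[counts$mode == m, ]
    ct <- cis_vs_trans_test(row$cis_only, row$trans_only)
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(mode = m, test = "cis_vs_trans"), ct
    )
    mg <- mode_vs_genome_test(
      row$cis_only, sum(unlist(row[-1])),
      total_row$cis_only, sum(unlist(total_row[-1]))
    )
    rows[[length(rows) + 1L]] <- bind_cols(
      tibble(mode = m, test = "cis_rate_vs_genome"), mg
    )
  }
  bind_rows(rows)
}
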
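# Seven-way cis/trans regulatory-divergence classification.
#
# Three per-gene comparisons: P tests the allelic ratio in the in-silico
# hybrid (parental divergence), H tests it in the F1 hybrid (cis
# divergence), and T compares the two ratios (trans divergence). P and H
# are two-sided exact binomial tests against 1:1; T is a two-sided Fisher
# exact test on the 2x2 allele-by-sample table. Significance is judged on
# Benjamini-Hochberg adjusted p-values within each comparison, and the
# significance pattern plus the sign agreement of the two log2 allelic
# ratios places each gene in one of seven categories.

#' Per-gene P, H and T comparison p-values
#'
#' Computes, for each gene profile, the two-sided exact binomial p-values
#' of the in-silico-hybrid (P) and F1 (H) allelic ratios against 1:1, the
#' two-sided Fisher exact p-value (T) on the 2x2 table
#' `[[f1_p1, f1_p2], [mix_p1, mix_p2]]`, and the log2 allelic ratios with
#' a 0.5 pseudocount. A sample with zero total reads makes the affected
#' tests undefined: the p-values are set to 1 and the gene is flagged
#' `zero_total` (it will be routed to `ambiguous`).
#'
#' @param profiles Gene profiles from [aggregate_to_genes()] (columns
#'   `gene_id`, `f1_p1`, `f1_p2`, `mix_p1`, `mix_p2`).
#' @return Tibble with `p_P`, `p_H`, `p_T`, `log2_ratio_f1`,
#'   `log2_ratio_mix`, `zero_total` appended.
#' @export
test_comparisons <- function(profiles) {
  assert_cols(profiles, c("gene_id", "f1_p1", "f1_p2", "mix_p1", "mix_p2"),
              "`profiles`")
  f1_tot <- profiles$f1_p1 + profiles$f1_p2
  mix_tot <- profiles$mix_p1 + profiles$mix_p2
  zero <- f1_tot == 0 | mix_tot == 0
  if (any(zero)) {
    inform(sprintf(
      "test_comparisons: %d gene(s) with a zero-count sample routed to ambiguous",
      sum(zero)
    ))
  }

  p_P <- binom_two_sided(profiles$mix_p1, mix_tot)
  p_H <- binom_two_sided(profiles$f1_p1, f1_tot)
  p_T <- pmap_dbl(
    list(profiles$f1_p1, profiles$f1_p2, profiles$mix_p1, profiles$mix_p2),
    function(a, b, c, d) {
      if ((a + b) == 0 || (c + d) == 0) return(1)
      # fisher.test can exceed 1 by floating-point error
      min(1, fisher.test(matrix(c(a, b, c, d), nrow = 2,
                                byrow = TRUE))$p.value)
    }
  )
  p_P[mix_tot == 0] <- 1
  p_H[f1_tot == 0] <- 1

  mutate(as_tibble(profiles),
    p_P = p_P, p_H = p_H, p_T = p_T,
    log2_ratio_f1 = log2_ratio(.data$f1_p1, .data$f1_p2),
    log2_ratio_mix = log2_ratio(.data$mix_p1, .data$mix_p2),
    zero_total = zero
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with enforced monotonicity, as implemented by
#' [stats::p.adjust()]. Applied separately within each of the P, H and T
#' comparisons across all tested genes.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param method Adjustment method (only `"BH"` is meaningful here).
#' @return Adjusted q-values, same length and order as the input.
#' @export
adjust_fdr <- function(pvalues, method = "BH") {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = method)
}

# The seven-way rule table on (sig_P, sig_H, sig_T, same_sign). Total:
# every input pattern maps to exactly one category.
rule_table <- function(sig_P, sig_H, sig_T, same_sign) {
  dplyr::case_when(
    sig_P & sig_H & !sig_T ~ "cis_only",
    sig_P & !sig_H & sig_T ~ "trans_only",
    sig_P & sig_H & sig_T & same_sign ~ "cis_plus_trans",
    sig_P & sig_H & sig_T & !same_sign ~ "cis_x_trans",
    !sig_P & sig_H & sig_T ~ "compensatory",
    !sig_P & !sig_H & !sig_T ~ "conserved",
    TRUE ~ "ambiguous"
  )
}

#' Classify genes from their comparison results
#'
#' Applies the seven-way rule table: significance is `q < alpha` in each
#' comparison; genes significant in all three comparisons are split by
#' whether the F1 and in-silico-hybrid log2 allelic ratios agree in sign
#' (`cis_plus_trans`) or disagree (`cis_x_trans`). A log2 ratio of exactly
#' zero is treated as sign agreement (reported via a message). Genes
#' flagged `zero_total` are routed to `ambiguous`.
#'
#' @param result Output of [test_comparisons()] with `q_P`, `q_H`, `q_T`
#'   columns already present (see [classify_all()] for the one-call path).
#' @param alpha Significance level on adjusted p-values.
#' @return The input with a `category` factor column appended.
#' @export
classify_gene <- function(result, alpha = 0.05) {
  assert_cols(result, c("q_P", "q_H", "q_T", "log2_ratio_f1",
                        "log2_ratio_mix"), "`result`")
  sig_P <- result$q_P < alpha
  sig_H <- result$q_H < alpha
  sig_T <- result$q_T < alpha
  prod_sign <- sign(result$log2_ratio_f1) * sign(result$log2_ratio_mix)
  if (any(prod_sign == 0 & sig_P & sig_H & sig_T)) {
    inform("classify_gene: zero log2 ratio treated as sign agreement")
  }
  same_sign <- prod_sign >= 0
  category <- rule_table(sig_P, sig_H, sig_T, same_sign)
  if ("zero_total" %in% names(result)) {
    category[result$zero_total] <- "ambiguous"
  }
  mutate(result, category = factor(category, levels = REG_CATEGORIES))
}

#' Full classification of a set of gene profiles
#'
#' Runs [test_comparisons()], adjusts each comparison's p-values with
#' Benjamini-Hochberg across all tested genes, and applies the rule table.
#'
#' @param profiles Gene profiles from [aggregate_to_genes()].
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return Tibble of class `reg_calls` with one row per gene: counts,
#'   p-values, q-values, log2 ratios and `category`. Per-category counts
#'   via [glance()] or `summary()`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 100, seed = 2))
#' profiles <- aggregate_to_genes(sim$snp_counts, sim$gene_models,
#'                                expr_bounds = NULL)
#' calls <- classify_all(profiles)
#' glance(calls)
#' @export
classify_all <- function(profiles, alpha = 0.05) {
  if (nrow(profiles) == 0) {
    out <- tibble(
      gene_id = character(0), category = factor(character(0),
                                                levels = REG_CATEGORIES)
    )
    class(out) <- c("reg_calls", class(out))
    attr(out, "alpha") <- alpha
    return(out)
  }
  if (anyDuplicated(profiles$gene_id)) {
    abort("duplicate gene_id in `profiles`")
  }
  res <- test_comparisons(profiles)
  res <- mutate(res,
    q_P = adjust_fdr(.data$p_P), q_H = adjust_fdr(.data$p_H),
    q_T = adjust_fdr(.data$p_T)
  )
  calls <- classify_gene(res, alpha = alpha)
  class(calls) <- c("reg_calls", class(calls))
  attr(calls, "alpha") <- alpha
  calls
}

#' @export
summary.reg_calls <- function(object, ...) {
  table(object$category)
}

#' @rdname classify_all
#' @param x,object A `reg_calls` object.
#' @param ... Unused.
#' @export
tidy.reg_calls <- function(x, ...) {
  as_tibble(x)
}

#' @rdname classify_all
#' @export
glance.reg_calls <- function(x, ...) {
  counts <- table(x$category)
  bind_cols(
    tibble(n_genes = nrow(x), alpha = attr(x, "alpha") %||% NA_real_),
    as_tibble(as.list(counts))
  )
}

#' @rdname classify_all
#' @export
autoplot.reg_calls <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(.data$log2_ratio_mix, .data$log2_ratio_f1,
                 colour = .data$category)
  ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.2,
                         colour = "grey60", linetype = 2) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = "log2 allelic ratio, in-silico hybrid (parental divergence)",
      y = "log2 allelic ratio, F1 hybrid (cis divergence)",
      colour = "category"
    ) +
    ggplot2::theme_minimal()
}

#' Write a classification calls table
#'
#' @param calls A `reg_calls` tibble.
#' @param path Output TSV path.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
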
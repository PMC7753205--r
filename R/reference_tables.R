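# Published count tables from a wild x cultivated soybean cross, used as
# worked-example inputs for the table arithmetic (percentages and
# chi-squared comparisons are re-derived from these counts, never stored).

#' Published soybean mode-by-category gene counts
#'
#' Gene counts per duplication mode and regulatory-divergence category
#' reported for a wild (*Glycine soja*) x cultivated (*G. max*) cross.
#' Percentages are deliberately not included: they are re-derived with
#' [crosstab_from_counts()].
#'
#' @return Tibble with `mode` and one count column per category.
#' @export
soybean_crosstab_counts <- function() {
  tibble::tribble(
    ~mode,        ~cis_only, ~trans_only, ~cis_plus_trans, ~cis_x_trans,
    ~compensatory, ~conserved, ~ambiguous,
    "singleton",  22L,  22L,   11L,  2L,   9L,   85L,   30L,
    "dispersed",  45L,  76L,   14L,  7L,  17L,  230L,  105L,
    "proximal",   15L,  18L,   11L,  2L,   4L,   35L,   17L,
    "tandem",     22L,  44L,   11L,  6L,   6L,   74L,   36L,
    "wgd",       428L, 1100L, 185L, 128L, 155L, 2898L, 1242L
  )
}

#' Published soybean DEG counts per genotype comparison
#'
#' Up/down-regulated differentially-expressed-gene counts for each
#' pairwise comparison among the two parents, the F1 hybrid and the
#' in-silico parental mix, out of 29,235 expressed genes.
#'
#' @return List with `counts` (tibble `comparison`, `up`, `down`) and
#'   `n_expressed`.
#' @export
soybean_deg_counts <- function() {
  list(
    counts = tibble::tribble(
      ~comparison,    ~up,   ~down,
      "GS_vs_JY47",   6356L, 6321L,
      "GS_vs_F1",     4838L, 5210L,
      "JY47_vs_F1",   745L,  1008L,
      "F1_vs_Mix",    140L,  353L
    ),
    n_expressed = 29235L
  )
}

#' Build a cross table directly from a wide count table
#'
#' Turns a mode-by-category count table (such as
#' [soybean_crosstab_counts()]) into a `cross_table`, re-deriving the
#' Total row and all row percentages from the counts.
#'
#' @param counts Wide tibble: `mode` column plus one integer column per
#'   category.
#' @return A `cross_table` (see [crosstab()]).
#' @export
crosstab_from_counts <- function(counts) {
  assert_cols(counts, "mode", "`counts`")
  m <- as.matrix(counts[-1])
  rownames(m) <- counts$mode
  m <- rbind(m, Total = colSums(m))
  props <- round_half_up(100 * m / pmax(rowSums(m), 1), 2)
  to_tbl <- function(x) {
    bind_cols(tibble(mode = rownames(x)),
              as_tibble(as.data.frame.matrix(x)))
  }
  structure(
    list(counts = to_tbl(m), proportions = to_tbl(props)),
    class = "cross_table"
  )
}
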
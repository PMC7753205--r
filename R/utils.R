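# Shared constants and small numeric helpers.

# The six generating architectures plus the classifier-only "ambiguous".
SIM_CATEGORIES <- c(
  "cis_only", "trans_only", "cis_plus_trans",
  "cis_x_trans", "compensatory", "conserved"
)
REG_CATEGORIES <- c(SIM_CATEGORIES, "ambiguous")

DUP_MODES <- c("singleton", "dispersed", "proximal", "tandem", "wgd")

#' Expected parent1-allele fraction for a log2 expression effect
#'
#' Converts a log2 parent1/parent2 expression ratio into the expected
#' fraction of reads carrying the parent1 allele: `2^e / (1 + 2^e)`.
#'
#' @param e Log2 expression ratio (numeric vector).
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' allele_fraction(c(0, 2, 1))
#' @export
allele_fraction <- function(e) {
  2^e / (1 + 2^e)
}

# Two-sided exact binomial p-value by the minimum-likelihood rule
# (sum of P(k) over all k with P(k) <= P(observed)), vectorized over sites.
# Identical to stats::binom.test(x, n, 0.5)$p.value but far cheaper in bulk.
binom_two_sided <- function(x, n, p = 0.5) {
  stopifnot(length(x) == length(n))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(n[i]) || n[i] == 0) next
    d <- stats::dbinom(0:n[i], n[i], p)
    # relative tolerance mirrors binom.test's handling of ties
    out[i] <- min(1, sum(d[d <= d[x[i] + 1] * (1 + 1e-7)]))
  }
  out
}

# Round half away from zero (the presentation convention of printed tables;
# base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic sub-seeds for independent RNG streams, derived from one
# master seed so each sample type has its own stream.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# log2 allelic ratio with a 0.5 pseudocount so zero counts stay finite.
log2_ratio <- function(p1, p2) {
  log2((p1 + 0.5) / (p2 + 0.5))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
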
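# Independent oracles, written against the category definitions rather
# than the package's implementation paths.

# Brute-force seven-way categorisation from a significance pattern and
# the two log2 ratios, as a flat lookup keyed on the pattern string.
oracle_classify <- function(sig_P, sig_H, sig_T, l2_f1, l2_mix) {
  key <- paste0(as.integer(sig_P), as.integer(sig_H), as.integer(sig_T))
  if (key == "110") return("cis_only")
  if (key == "101") return("trans_only")
  if (key == "111") {
    s1 <- if (l2_f1 > 0) 1 else if (l2_f1 < 0) -1 else 0
    s2 <- if (l2_mix > 0) 1 else if (l2_mix < 0) -1 else 0
    if (s1 * s2 < 0) return("cis_x_trans") else return("cis_plus_trans")
  }
  if (key == "011") return("compensatory")
  if (key == "000") return("conserved")
  "ambiguous"
}

# Brute-force classification of one count table: runs its own tests via
# stats, then the lookup. q-values are supplied (BH is applied across a
# cohort, not per gene).
oracle_classify_counts <- function(f1_p1, f1_p2, mix_p1, mix_p2,
                                   q_P, q_H, q_T, alpha = 0.05) {
  oracle_classify(
    q_P < alpha, q_H < alpha, q_T < alpha,
    log2((f1_p1 + 0.5) / (f1_p2 + 0.5)),
    log2((mix_p1 + 0.5) / (mix_p2 + 0.5))
  )
}

# Exhaustive longest anchor chain by plain recursion (no DP), both
# orientations; anchors given as rank pairs. Gaps must be in (0, max_gap]
# on both axes per step. Feasible for <= 20 anchors.
oracle_longest_chain <- function(rankA, rankB, max_gap) {
  n <- length(rankA)
  ord <- order(rankA, rankB)
  ra <- rankA[ord]
  rb <- rankB[ord]
  extend <- function(i, dir) {
    best <- list(i)
    for (j in seq_len(n)) {
      dA <- ra[j] - ra[i]
      dB <- dir * (rb[j] - rb[i])
      if (dA > 0 && dA <= max_gap && dB > 0 && dB <= max_gap) {
        cand <- c(i, extend(j, dir)[[1]])
        if (length(cand) > length(best[[1]])) best <- list(cand)
      }
    }
    best
  }
  longest <- integer(0)
  for (dir in c(1, -1)) {
    for (s in seq_len(n)) {
      ch <- extend(s, dir)[[1]]
      if (length(ch) > length(longest)) longest <- ch
    }
  }
  ord[longest]
}

# Exhaustive optimal contiguous 3-partition of 1-D values by within-SS.
oracle_partition3 <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  ss <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- NULL
  best_ss <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      s <- ss(xs[1:i]) + ss(xs[(i + 1):j]) + ss(xs[(j + 1):n])
      if (s < best_ss - 1e-12) {
        best_ss <- s
        best <- c(i, j)
      }
    }
  }
  cl <- integer(n)
  cl[1:best[1]] <- 1L
  cl[(best[1] + 1):best[2]] <- 2L
  cl[(best[2] + 1):n] <- 3L
  out <- integer(n)
  out[o] <- cl
  out
}

# Minimal profile tibble for classifier tests.
make_profiles <- function(f1_p1, f1_p2, mix_p1, mix_p2,
                          gene_id = sprintf("g%03d", seq_along(f1_p1))) {
  tibble::tibble(
    gene_id = gene_id, n_snps = 2L,
    f1_p1 = f1_p1, f1_p2 = f1_p2, mix_p1 = mix_p1, mix_p2 = mix_p2
  )
}

# Tiny VCF writer for filter_variants tests: records is a data frame
# with CHROM POS ID REF ALT and two sample strings (GT:GQ:DP).
write_test_vcf <- function(records, path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "p1", "p2", sep = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:GQ:DP\t%s\t%s",
            records$chrom, records$pos, records$id, records$ref,
            records$alt, records$s1, records$s2)
  )
  writeLines(lines, path)
  path
}
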
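make_vcf_records <- function() {
  data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L),
    id = paste0("s", 1:7),
    ref = c("A", "C", "G", "A", "T", "A", "AT"),
    alt = c("G", "T", "A,T", "G", "C", "G", "A"),
    s1 = c("0/0:30:12", "0/0:20:12", "0/0:30:12", "0/1:30:12",
           "1/1:45:9", "0/0:.:12", "0/0:30:12"),
    s2 = c("1/1:28:9", "1/1:28:9", "1/1:28:9", "1/1:28:9",
           "0/0:50:20", "1/1:28:9", "1/1:28:9")
  )
}

test_that("variant filter keeps homozygous-different bi-allelic SNPs above QC", {
  vcf <- write_test_vcf(make_vcf_records(), withr::local_tempfile())
  kept <- suppressMessages(filter_variants(vcf))
  # s1: clean pass; s5: parents swapped homozygotes, still informative
  expect_setequal(kept$variant_id, c("s1", "s5"))
  # parent1 carries the alt allele at s5
  expect_equal(kept$parent1_allele[kept$variant_id == "s5"], "alt")

  rej <- attr(kept, "rejected")
  reason_of <- function(id) rej$reason[rej$variant_id == id]
  expect_match(reason_of("s2"), "GQ")          # GQ = 20 exactly: strict bound
  expect_match(reason_of("s3"), "bi-allelic")  # tri-allelic
  expect_match(reason_of("s4"), "homozygous")  # heterozygous parent
  expect_match(reason_of("s6"), "missing GQ")  # missing field, no crash
  expect_match(reason_of("s7"), "bi-allelic")  # indel
})

test_that("variant filter applies strict depth threshold", {
  rec <- data.frame(
    chrom = "chr1", pos = c(10L, 20L), id = c("d1", "d2"),
    ref = "A", alt = "G",
    s1 = c("0/0:30:5", "0/0:30:6"), s2 = c("1/1:30:6", "1/1:30:6")
  )
  vcf <- write_test_vcf(rec, withr::local_tempfile())
  kept <- suppressMessages(filter_variants(vcf))
  expect_equal(kept$variant_id, "d2")  # DP = 5 exactly is rejected
})

test_that("DNA bias filter removes SNPs failing the exact binomial test", {
  dna <- tibble::tibble(
    variant_id = c("a", "b", "c", "d"),
    parent1_count = c(12L, 30L, 10L, 0L),
    parent2_count = c(8L, 10L, 10L, 0L)
  )
  kept <- suppressMessages(filter_biased_snps(dna, alpha = 0.05))
  expect_setequal(kept$variant_id, c("a", "c"))
  expect_equal(kept$p_bias[kept$variant_id == "a"], 0.5034447,
               tolerance = 1e-6)
  expect_equal(kept$p_bias[kept$variant_id == "c"], 1)
  removed <- attr(kept, "removed")
  expect_equal(removed$p_bias[removed$variant_id == "b"], 0.002221434,
               tolerance = 1e-6)
  expect_equal(removed$reason[removed$variant_id == "d"], "zero depth")
})

test_that("bias filter removes about alpha of truly unbiased SNPs", {
  set.seed(424)
  n <- 4000
  p1 <- rbinom(n, 60, 0.5)
  dna <- tibble::tibble(parent1_count = p1, parent2_count = 60L - p1)
  kept <- suppressMessages(filter_biased_snps(dna, alpha = 0.05))
  rate <- 1 - nrow(kept) / n
  se <- sqrt(0.05 * 0.95 / n)
  # discrete test is conservative: never above alpha by more than 3 SE
  expect_lt(rate, 0.05 + 3 * se)
  expect_gt(rate, 0.01)
})

test_that("in-silico mix adds equal-size libraries element-wise", {
  a <- tibble::tibble(contig = "c1", position = 1:3,
                      parent1_count = c(10L, 4L, 6L),
                      parent2_count = c(0L, 1L, 1L))
  b <- tibble::tibble(contig = "c1", position = 1:3,
                      parent1_count = c(1L, 0L, 1L),
                      parent2_count = c(9L, 5L, 6L))
  mix <- build_insilico_mix(a, b, mode = "scale")
  expect_equal(mix$parent1_count, a$parent1_count + b$parent1_count)
  expect_equal(mix$parent2_count, a$parent2_count + b$parent2_count)
  expect_true(all(mix$sample == "MIX_RNA"))
})

test_that("scale mode halves the larger library", {
  a <- tibble::tibble(contig = "c1", position = 1:2,
                      parent1_count = c(10L, 30L), parent2_count = c(0L, 0L))
  b <- tibble::tibble(contig = "c1", position = 1:2,
                      parent1_count = c(0L, 0L), parent2_count = c(12L, 8L))
  # library a: 40, library b: 20 -> a scaled by 0.5
  mix <- build_insilico_mix(a, b, mode = "scale")
  expect_equal(mix$parent1_count, c(5, 15))
  expect_equal(mix$parent2_count, c(12, 8))
  empty <- tibble::tibble(contig = character(0), position = integer(0),
                          parent1_count = integer(0), parent2_count = integer(0))
  expect_error(build_insilico_mix(a, empty), "zero library")
})

test_that("subsample mode is deterministic and hits the target library size", {
  set.seed(99)
  a <- tibble::tibble(contig = "c1", position = 1:50,
                      parent1_count = rpois(50, 40L),
                      parent2_count = rpois(50, 2L))
  b <- tibble::tibble(contig = "c1", position = 1:50,
                      parent1_count = rpois(50, 1L),
                      parent2_count = rpois(50, 20L))
  m1 <- build_insilico_mix(a, b, mode = "subsample", seed = 5)
  m2 <- build_insilico_mix(a, b, mode = "subsample", seed = 5)
  expect_identical(m1, m2)
  lib_b <- sum(b$parent1_count + b$parent2_count)
  expect_equal(sum(m1$parent1_count + m1$parent2_count), 2 * lib_b)
  # subsampled counts never exceed the originals
  expect_true(all(m1$parent1_count <= a$parent1_count + b$parent1_count))
})

test_that("gene aggregation sums SNP counts and applies both gene filters", {
  gm <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"), contig = "chr1",
    start = c(1L, 1001L, 2001L, 3001L), end = c(900L, 1900L, 2900L, 3900L)
  )
  snp <- function(pos, s, p1, p2) {
    tibble::tibble(contig = "chr1", position = pos, sample = s,
                   parent1_count = p1, parent2_count = p2)
  }
  counts <- dplyr::bind_rows(
    snp(c(10L, 20L, 30L), "F1", c(10L, 12L, 8L), c(5L, 6L, 4L)),
    snp(c(10L, 20L, 30L), "MIX_RNA", c(4L, 4L, 4L), c(4L, 4L, 4L)),
    snp(1010L, "F1", c(50L), c(50L)),          # gB: one SNP only
    snp(1010L, "MIX_RNA", c(50L), c(50L)),
    snp(c(2010L, 2020L), "F1", c(2L, 2L), c(2L, 2L)),   # gC: mean count 8
    snp(c(2010L, 2020L), "MIX_RNA", c(2L, 2L), c(2L, 2L)),
    snp(c(3010L, 3020L), "F1", c(600L, 600L), c(300L, 300L)),  # gD: too high
    snp(c(3010L, 3020L), "MIX_RNA", c(500L, 500L), c(500L, 500L))
  )
  prof <- aggregate_to_genes(counts, gm)
  expect_equal(prof$gene_id, "gA")
  expect_equal(prof$f1_p1, 30)
  expect_equal(prof$f1_p2, 15)
  expect_equal(prof$mix_p1, 12)
  expect_equal(prof$n_snps, 3L)
  # without the expression filter the low/high-expressed genes come back
  prof_all <- aggregate_to_genes(counts, gm, expr_bounds = NULL)
  expect_setequal(prof_all$gene_id, c("gA", "gC", "gD"))
})

test_that("aggregation conserves reads for SNPs in single-gene bodies", {
  sim <- simulate_dataset(sim_config(n_genes = 30, seed = 13))
  rna <- dplyr::filter(sim$snp_counts, sample != "MIX_DNA")
  prof <- aggregate_to_genes(rna, sim$gene_models, min_snps = 1,
                             expr_bounds = NULL)
  expect_equal(
    sum(prof$f1_p1 + prof$f1_p2 + prof$mix_p1 + prof$mix_p2),
    sum(rna$parent1_count + rna$parent2_count)
  )
})

test_that("a SNP in two overlapping genes counts toward both", {
  gm <- tibble::tibble(gene_id = c("g1", "g2"), contig = "chr1",
                       start = c(1L, 50L), end = c(100L, 160L))
  counts <- tibble::tibble(
    contig = "chr1", position = c(60L, 70L), sample = "F1",
    parent1_count = c(30L, 10L), parent2_count = c(15L, 10L)
  ) |>
    dplyr::bind_rows(tibble::tibble(
      contig = "chr1", position = c(60L, 70L), sample = "MIX_RNA",
      parent1_count = c(20L, 10L), parent2_count = c(20L, 10L)
    ))
  prof <- suppressMessages(
    aggregate_to_genes(counts, gm, expr_bounds = NULL)
  )
  expect_setequal(prof$gene_id, c("g1", "g2"))
  expect_equal(prof$f1_p1[prof$gene_id == "g1"],
               prof$f1_p1[prof$gene_id == "g2"])
})

test_that("swapping parent labels transposes profiles and keeps n_snps", {
  sim <- simulate_dataset(sim_config(n_genes = 25, seed = 21))
  rna <- dplyr::filter(sim$snp_counts, sample != "MIX_DNA")
  swapped <- dplyr::mutate(rna,
    tmp = parent1_count, parent1_count = parent2_count, parent2_count = tmp
  )
  p1 <- aggregate_to_genes(rna, sim$gene_models, expr_bounds = NULL)
  p2 <- aggregate_to_genes(swapped, sim$gene_models, expr_bounds = NULL)
  expect_equal(p1$gene_id, p2$gene_id)
  expect_equal(p1$n_snps, p2$n_snps)
  expect_equal(p1$f1_p1, p2$f1_p2)
  expect_equal(p1$mix_p1, p2$mix_p2)
})
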
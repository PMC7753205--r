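# Reading per-SNP allele counts, SNP/gene filtering, in-silico hybrid
# construction and gene-level aggregation.

#' Read an ASEReadCounter-style allele-count table
#'
#' Reads the per-SNP allele-count TSV written by GATK's ASEReadCounter (or
#' by [write_fixture_bundle()]): columns `contig`, `position`, `variantID`,
#' `refAllele`, `altAllele`, `refCount`, `altCount`, `totalCount`; extra
#' columns are ignored.
#'
#' @param path Path to the TSV.
#' @param sample Sample label to attach (`"F1"`, `"MIX_RNA"`, `"MIX_DNA"`).
#' @return Tibble with columns `contig`, `position`, `variant_id`,
#'   `ref_allele`, `alt_allele`, `ref_count`, `alt_count`, `sample`.
#' @export
read_ase_counts <- function(path, sample) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(raw, c("contig", "position", "refAllele", "altAllele",
                     "refCount", "altCount"), "allele-count table")
  tibble(
    contig = as.character(raw$contig),
    position = as.integer(raw$position),
    variant_id = if ("variantID" %in% names(raw)) {
      as.character(raw$variantID)
    } else {
      paste0(raw$contig, ":", raw$position)
    },
    ref_allele = raw$refAllele, alt_allele = raw$altAllele,
    ref_count = as.integer(raw$refCount), alt_count = as.integer(raw$altCount),
    sample = sample
  )
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features and their genomic extents. The full gene body
#' is used downstream for SNP assignment, both strands.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble `gene_id`, `contig`, `start`, `end`, `strand`, ordered by
#'   position; `rank` gives the 0-based gene order along each contig.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  tibble(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>%
    arrange(.data$contig, .data$start) %>%
    group_by(.data$contig) %>%
    mutate(rank = row_number() - 1L) %>%
    ungroup()
}

#' Filter variants to informative parental SNPs
#'
#' Keeps bi-allelic SNPs at which the two parents are homozygous for
#' different alleles, with genotype quality > 20 and sample depth > 5 in
#' both parents. Records failing any rule (including missing GQ/DP) are
#' rejected with a reason, available via `attr(x, "rejected")`.
#'
#' @param vcf Path to a VCFv4.2 file or a `vcfR::vcfR` object with
#'   per-sample GT, GQ and DP.
#' @param parent1,parent2 Sample names of the two parents; default the
#'   first two samples in the VCF.
#' @param min_gq,min_dp Strict lower bounds on genotype quality and depth.
#' @return Tibble of retained sites: `contig`, `position`, `variant_id`,
#'   `ref_allele`, `alt_allele`, `parent1_allele` (`"ref"` or `"alt"`).
#' @export
filter_variants <- function(vcf, parent1 = NULL, parent2 = NULL,
                            min_gq = 20, min_dp = 5) {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(parent1)) parent1 <- samples[1]
  if (is.null(parent2)) parent2 <- samples[2]
  if (!all(c(parent1, parent2) %in% samples)) {
    abort("parent sample names not found in the VCF")
  }
  get_field <- function(elem, as_num = FALSE) {
    m <- vcfR::extract.gt(vcf, element = elem, as.numeric = as_num)
    if (is.null(m)) matrix(NA, nrow(fix), 2) else m[, c(parent1, parent2), drop = FALSE]
  }
  gt <- get_field("GT")
  gq <- suppressWarnings(get_field("GQ", TRUE))
  dp <- suppressWarnings(get_field("DP", TRUE))

  norm_gt <- function(g) gsub("\\|", "/", g)
  gt1 <- norm_gt(gt[, 1]); gt2 <- norm_gt(gt[, 2])
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT) & fix$REF != fix$ALT
  hom1 <- gt1 %in% c("0/0", "1/1")
  hom2 <- gt2 %in% c("0/0", "1/1")

  reason <- rep(NA_character_, nrow(fix))
  reason[!is_snp | is.na(is_snp)] <- "not a bi-allelic SNP"
  ok <- is.na(reason)
  reason[ok & (is.na(gt1) | is.na(gt2))] <- "missing genotype"
  ok <- is.na(reason)
  reason[ok & !(hom1 & hom2 & gt1 != gt2)] <- "parents not homozygous-different"
  ok <- is.na(reason)
  reason[ok & (is.na(gq[, 1]) | is.na(gq[, 2]))] <- "missing GQ"
  ok <- is.na(reason)
  reason[ok & !(gq[, 1] > min_gq & gq[, 2] > min_gq)] <- "GQ below threshold"
  ok <- is.na(reason)
  reason[ok & (is.na(dp[, 1]) | is.na(dp[, 2]))] <- "missing DP"
  ok <- is.na(reason)
  reason[ok & !(dp[, 1] > min_dp & dp[, 2] > min_dp)] <- "DP below threshold"
  ok <- is.na(reason)

  out <- tibble(
    contig = fix$CHROM, position = as.integer(fix$POS),
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    parent1_allele = unname(ifelse(gt1 == "0/0", "ref", "alt"))
  )
  rejected <- out[!ok, c("contig", "position", "variant_id")]
  rejected$reason <- reason[!ok]
  if (nrow(rejected) > 0) {
    inform(sprintf("filter_variants: rejected %d of %d records",
                   nrow(rejected), nrow(out)))
  }
  retained <- out[ok, ]
  attr(retained, "rejected") <- as_tibble(rejected)
  retained
}

#' Orient allele counts to parent-of-origin counts
#'
#' Joins a raw ref/alt count table onto a filtered variant table and
#' assigns each allele count to parent1 or parent2 according to the
#' parental genotypes. SNPs absent from `variants` are dropped.
#'
#' @param counts Output of [read_ase_counts()].
#' @param variants Output of [filter_variants()].
#' @return Tibble `contig`, `position`, `variant_id`, `ref_allele`,
#'   `alt_allele`, `parent1_count`, `parent2_count`, `sample`.
#' @export
orient_to_parents <- function(counts, variants) {
  assert_cols(counts, c("contig", "position", "ref_count", "alt_count"),
              "`counts`")
  joined <- inner_join(
    counts,
    select(variants, "contig", "position", "parent1_allele"),
    by = c("contig", "position")
  )
  mutate(joined,
    parent1_count = ifelse(.data$parent1_allele == "ref",
                           .data$ref_count, .data$alt_count),
    parent2_count = ifelse(.data$parent1_allele == "ref",
                           .data$alt_count, .data$ref_count)
  ) %>%
    select("contig", "position", "variant_id", "ref_allele", "alt_allele",
           "parent1_count", "parent2_count", "sample")
}

#' Remove SNPs with biased parental DNA representation
#'
#' Tests each SNP's mixed-DNA control counts against a 1:1 ratio with a
#' two-sided exact binomial test and removes sites with p-value below
#' `alpha` (raw p-values, no multiplicity adjustment — the filter is
#' deliberately aggressive). Sites with zero total depth are untestable
#' and removed.
#'
#' @param dna_counts Per-SNP `MIX_DNA` counts with `parent1_count` and
#'   `parent2_count` columns.
#' @param alpha Removal threshold on the raw binomial p-value.
#' @return Tibble of retained SNPs with a `p_bias` column; removed sites
#'   (with reasons) in `attr(x, "removed")`.
#' @export
filter_biased_snps <- function(dna_counts, alpha = 0.05) {
  assert_cols(dna_counts, c("parent1_count", "parent2_count"), "`dna_counts`")
  total <- dna_counts$parent1_count + dna_counts$parent2_count
  p <- binom_two_sided(dna_counts$parent1_count, total)
  dna_counts$p_bias <- p
  untestable <- total == 0
  biased <- !untestable & p < alpha
  removed <- dna_counts[untestable | biased, , drop = FALSE]
  removed$reason <- ifelse(untestable[untestable | biased],
                           "zero depth", "biased DNA ratio")
  if (nrow(removed) > 0) {
    inform(sprintf(
      "filter_biased_snps: removed %d of %d SNPs (%d biased, %d zero-depth)",
      nrow(removed), nrow(dna_counts), sum(biased), sum(untestable)
    ))
  }
  out <- dna_counts[!(untestable | biased), , drop = FALSE]
  attr(out, "removed") <- as_tibble(removed)
  out
}

#' Construct the in-silico hybrid from two parental RNA samples
#'
#' Mixes the two parents' per-SNP counts so that each parent contributes
#' an equal effective library size, emulating an equal-amount read mix.
#' In `scale` mode the larger library's counts are multiplied by
#' (smaller/larger) and rounded half-to-even; in `subsample` mode the
#' larger library is down-sampled without replacement (multivariate
#' hypergeometric over its SNP-allele cells) to the smaller library size.
#'
#' @param parent1_counts,parent2_counts Per-SNP tibbles for the two
#'   parental RNA samples with `contig`, `position`, `parent1_count`,
#'   `parent2_count` columns (each parent's sample carries reads for both
#'   alleles; typically almost all reads match its own).
#' @param mode `"scale"` or `"subsample"`.
#' @param seed RNG seed for `subsample` mode.
#' @return Tibble of mixed counts with `sample = "MIX_RNA"`.
#' @export
build_insilico_mix <- function(parent1_counts, parent2_counts,
                               mode = c("scale", "subsample"), seed = 1L) {
  mode <- match.arg(mode)
  for (nm in list(parent1_counts, parent2_counts)) {
    assert_cols(nm, c("contig", "position", "parent1_count", "parent2_count"),
                "parental counts")
  }
  lib1 <- sum(parent1_counts$parent1_count + parent1_counts$parent2_count)
  lib2 <- sum(parent2_counts$parent1_count + parent2_counts$parent2_count)
  if (lib1 == 0 || lib2 == 0) abort("zero library size in a parental sample")
  target <- min(lib1, lib2)

  adjust <- function(tab, lib) {
    if (lib == target) return(tab)
    if (mode == "scale") {
      f <- target / lib
      tab$parent1_count <- round(tab$parent1_count * f)
      tab$parent2_count <- round(tab$parent2_count * f)
      tab
    } else {
      set.seed(as.integer(seed))
      cells <- c(tab$parent1_count, tab$parent2_count)
      kept <- mv_hypergeometric(cells, target)
      m <- nrow(tab)
      tab$parent1_count <- kept[seq_len(m)]
      tab$parent2_count <- kept[m + seq_len(m)]
      tab
    }
  }
  a <- adjust(parent1_counts, lib1)
  b <- adjust(parent2_counts, lib2)

  key <- c("contig", "position")
  merged <- dplyr::full_join(
    select(a, all_of(key), dplyr::any_of(c("variant_id", "ref_allele", "alt_allele")),
           p1_a = "parent1_count", p2_a = "parent2_count"),
    select(b, all_of(key), p1_b = "parent1_count", p2_b = "parent2_count"),
    by = key
  )
  merged %>%
    mutate(
      parent1_count = dplyr::coalesce(.data$p1_a, 0) + dplyr::coalesce(.data$p1_b, 0),
      parent2_count = dplyr::coalesce(.data$p2_a, 0) + dplyr::coalesce(.data$p2_b, 0),
      sample = "MIX_RNA"
    ) %>%
    select(-"p1_a", -"p2_a", -"p1_b", -"p2_b")
}

# Multivariate hypergeometric draw: sample `target` items without
# replacement from cells with the given sizes. Sequential conditional
# rhyper over cells.
mv_hypergeometric <- function(cells, target) {
  total <- sum(cells)
  stopifnot(target <= total)
  kept <- integer(length(cells))
  remaining <- total
  left <- target
  for (i in seq_along(cells)) {
    if (left == 0) break
    k <- rhyper(1, cells[i], remaining - cells[i], left)
    kept[i] <- k
    left <- left - k
    remaining <- remaining - cells[i]
  }
  kept
}

#' Aggregate per-SNP counts to gene-level allelic profiles
#'
#' Assigns SNPs to gene bodies (full genomic extent, both strands), sums
#' parent1/parent2 counts per gene separately for the F1 and in-silico-
#' hybrid samples, and applies the gene-level filters: genes with fewer
#' than `min_snps` informative SNPs are dropped, and genes whose mean
#' total count across the two RNA samples falls outside the open interval
#' `expr_bounds` are dropped. A SNP inside two overlapping gene bodies
#' counts toward both (reported via a message).
#'
#' @param snp_counts Oriented per-SNP counts (see [orient_to_parents()])
#'   for samples `F1` and `MIX_RNA`, already SNP-filtered.
#' @param gene_models Tibble from [read_gene_models()] (or the
#'   `gene_models` component of an `ase_sim`).
#' @param min_snps Minimum informative SNPs per gene (default 2).
#' @param expr_bounds Open interval (low, high) on the mean total read
#'   count; `NULL` disables the expression filter.
#' @return Tibble of class `gene_profiles`: `gene_id`, `n_snps`, `f1_p1`,
#'   `f1_p2`, `mix_p1`, `mix_p2`.
#' @export
aggregate_to_genes <- function(snp_counts, gene_models, min_snps = 2,
                               expr_bounds = c(10, 1000)) {
  assert_cols(snp_counts, c("contig", "position", "parent1_count",
                            "parent2_count", "sample"), "`snp_counts`")
  assert_cols(gene_models, c("gene_id", "contig", "start", "end"),
              "`gene_models`")
  snp_counts <- filter(snp_counts, .data$sample %in% c("F1", "MIX_RNA"))

  sites <- distinct(snp_counts, .data$contig, .data$position)
  snp_gr <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$position, width = 1)
  )
  gene_gr <- GenomicRanges::GRanges(
    gene_models$contig, IRanges::IRanges(gene_models$start, gene_models$end)
  )
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE)
  map_tbl <- tibble(
    contig = sites$contig[S4Vectors::queryHits(ov)],
    position = sites$position[S4Vectors::queryHits(ov)],
    gene_id = gene_models$gene_id[S4Vectors::subjectHits(ov)]
  )
  multi <- map_tbl %>% count(.data$contig, .data$position) %>%
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    inform(sprintf(
      "aggregate_to_genes: %d SNP site(s) overlap more than one gene; counted toward each",
      nrow(multi)
    ))
  }

  assigned <- inner_join(snp_counts, map_tbl, by = c("contig", "position"),
                         relationship = "many-to-many")
  profiles <- assigned %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_snps = dplyr::n_distinct(.data$position),
      f1_p1 = sum(.data$parent1_count[.data$sample == "F1"]),
      f1_p2 = sum(.data$parent2_count[.data$sample == "F1"]),
      mix_p1 = sum(.data$parent1_count[.data$sample == "MIX_RNA"]),
      mix_p2 = sum(.data$parent2_count[.data$sample == "MIX_RNA"]),
      .groups = "drop"
    ) %>%
    filter(.data$n_snps >= min_snps)

  if (!is.null(expr_bounds)) {
    mean_total <- (profiles$f1_p1 + profiles$f1_p2 +
                     profiles$mix_p1 + profiles$mix_p2) / 2
    profiles <- profiles[mean_total > expr_bounds[1] &
                           mean_total < expr_bounds[2], ]
  }
  class(profiles) <- c("gene_profiles", class(profiles))
  profiles
}
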
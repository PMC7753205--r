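# Synthetic allele-count data with known cis/trans architectures.
#
# Each gene gets a cis effect c and a trans effect t (log2 units). The F1
# hybrid exposes only the cis effect, so its expected parent1-allele
# fraction is 2^c/(1+2^c); the parental mix (in-silico hybrid) exposes the
# full parental divergence c + t. Total depth per gene is negative binomial
# (mean mu, variance mu + phi*mu^2), allelic sampling is binomial, and the
# gene total is split over its SNPs with equal multinomial weights. The
# mixed-DNA control draws each SNP binomial at 1:1 except for a configurable
# fraction of mapping-biased sites.

#' Simulation configuration for allele-specific expression data
#'
#' Builds and validates the configuration consumed by [simulate_dataset()].
#' Defaults follow the category proportions observed genome-wide in a
#' wild x cultivated soybean cross (trans-biased, mostly conserved), with
#' effect magnitudes uniform on \[0.5, 2\] log2 and per-gene depths of a
#' few hundred reads.
#'
#' @param n_genes Number of genes to simulate.
#' @param category_mix Named proportions over the six generating
#'   architectures (`cis_only`, `trans_only`, `cis_plus_trans`,
#'   `cis_x_trans`, `compensatory`, `conserved`); must sum to 1.
#' @param cis_effect_log2,trans_effect_log2 Effect-magnitude spec in log2
#'   units: a single value (fixed magnitude) or a length-2 range sampled
#'   uniformly. Signs are drawn at random per gene, subject to the
#'   category's sign constraint.
#' @param mean_depth_f1,mean_depth_mix Mean total reads per gene in the F1
#'   and in-silico-hybrid RNA samples.
#' @param nb_dispersion Negative-binomial dispersion phi (> 0); variance of
#'   the per-gene depth is `mu + phi * mu^2`.
#' @param snps_per_gene Integer SNPs per gene: a single value or an
#'   inclusive length-2 range (minimum 1).
#' @param dna_depth_per_snp Reads per SNP in the mixed-DNA control.
#' @param biased_snp_fraction Fraction of SNPs whose DNA control is drawn
#'   at `biased_snp_allele_prob` instead of 0.5 (mapping bias).
#' @param biased_snp_allele_prob Parent1-allele probability at biased SNPs;
#'   in (0, 1) and not 0.5.
#' @param seed Master seed; one RNG stream per sample type is derived from
#'   it so the draws for different sample types do not interleave.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' @export
sim_config <- function(n_genes = 2000,
                       category_mix = c(
                         cis_only = 0.094, trans_only = 0.222,
                         cis_plus_trans = 0.041, cis_x_trans = 0.025,
                         compensatory = 0.034, conserved = 0.584
                       ),
                       cis_effect_log2 = c(0.5, 2),
                       trans_effect_log2 = c(0.5, 2),
                       mean_depth_f1 = 300,
                       mean_depth_mix = 300,
                       nb_dispersion = 0.05,
                       snps_per_gene = c(2L, 6L),
                       dna_depth_per_snp = 50,
                       biased_snp_fraction = 0.05,
                       biased_snp_allele_prob = 0.8,
                       seed = 1L) {
  if (n_genes < 0) abort("`n_genes` must be non-negative.")
  missing_cat <- setdiff(SIM_CATEGORIES, names(category_mix))
  if (length(missing_cat) > 0) {
    abort(paste0(
      "`category_mix` must name all six architectures; missing: ",
      paste(missing_cat, collapse = ", ")
    ))
  }
  category_mix <- category_mix[SIM_CATEGORIES]
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-9) {
    abort("`category_mix` proportions must be non-negative and sum to 1.")
  }
  check_range <- function(x, nm) {
    if (!length(x) %in% c(1L, 2L) || any(x < 0)) {
      abort(sprintf("`%s` must be a non-negative value or range.", nm))
    }
    if (length(x) == 2L && x[1] > x[2]) abort(sprintf("`%s` range is reversed.", nm))
  }
  check_range(cis_effect_log2, "cis_effect_log2")
  check_range(trans_effect_log2, "trans_effect_log2")
  if (mean_depth_f1 <= 0 || mean_depth_mix <= 0 || dna_depth_per_snp <= 0) {
    abort("All depths must be > 0.")
  }
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  snps_per_gene <- as.integer(snps_per_gene)
  if (!length(snps_per_gene) %in% c(1L, 2L) || min(snps_per_gene) < 1L) {
    abort("`snps_per_gene` must not admit fewer than 1 SNP per gene.")
  }
  if (biased_snp_fraction < 0 || biased_snp_fraction > 1) {
    abort("`biased_snp_fraction` must be in [0, 1].")
  }
  if (biased_snp_allele_prob <= 0 || biased_snp_allele_prob >= 1 ||
      biased_snp_allele_prob == 0.5) {
    abort("`biased_snp_allele_prob` must be in (0, 1) and differ from 0.5.")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), category_mix = category_mix,
      cis_effect_log2 = cis_effect_log2, trans_effect_log2 = trans_effect_log2,
      mean_depth_f1 = mean_depth_f1, mean_depth_mix = mean_depth_mix,
      nb_dispersion = nb_dispersion, snps_per_gene = snps_per_gene,
      dna_depth_per_snp = dna_depth_per_snp,
      biased_snp_fraction = biased_snp_fraction,
      biased_snp_allele_prob = biased_snp_allele_prob,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Largest-remainder apportionment of n into named proportions.
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Draw one magnitude per gene from a fixed-or-range spec.
draw_magnitude <- function(spec, n) {
  if (length(spec) == 1L) rep(spec, n) else runif(n, spec[1], spec[2])
}

#' Simulate an allele-specific-expression dataset
#'
#' Generates per-SNP allele counts for an F1 hybrid, an in-silico hybrid
#' (parental RNA mix), and a mixed-DNA control, together with the true
#' generating architecture of every gene. With the same `sim_config` the
#' output is reproducible bit for bit.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ase_sim` with components
#'   \describe{
#'     \item{snp_counts}{Tibble of per-SNP counts: `contig`, `position`,
#'       `variant_id`, `ref_allele`, `alt_allele`, `parent1_count`,
#'       `parent2_count`, `sample` (`F1`, `MIX_RNA`, `MIX_DNA`).}
#'     \item{truth}{Tibble `gene_id`, `c`, `t`, `true_category`.}
#'     \item{gene_models}{Tibble `gene_id`, `contig`, `start`, `end`,
#'       `strand` mapping SNPs to gene bodies.}
#'     \item{gene_totals}{Per-gene allele totals drawn before the
#'       multinomial split over SNPs (for conservation checks).}
#'     \item{config}{The configuration used.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 20, seed = 7))
#' head(sim$truth)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_genes
  seeds <- derive_seeds(config$seed, 4L)

  # --- stream 1: architectures (category, effects, SNP counts, layout)
  set.seed(seeds[1])
  n_per_cat <- apportion(n, config$category_mix)
  true_category <- rep(SIM_CATEGORIES, times = n_per_cat)
  c_mag <- draw_magnitude(config$cis_effect_log2, n)
  t_mag <- draw_magnitude(config$trans_effect_log2, n)
  c_sign <- sample(c(-1, 1), n, replace = TRUE)
  t_sign <- sample(c(-1, 1), n, replace = TRUE)
  cc <- c_sign * c_mag
  tt <- t_sign * t_mag
  cc[true_category %in% c("trans_only", "conserved")] <- 0
  tt[true_category %in% c("cis_only", "conserved")] <- 0
  same <- true_category == "cis_plus_trans"
  tt[same] <- abs(tt[same]) * sign(cc[same])
  opp <- true_category == "cis_x_trans"
  tt[opp] <- -abs(tt[opp]) * sign(cc[opp])
  comp <- true_category == "compensatory"
  tt[comp] <- -cc[comp]

  gene_id <- sprintf("gene%05d", seq_len(n))
  spg <- config$snps_per_gene
  n_snps <- if (length(spg) == 1L) {
    rep(spg, n)
  } else {
    sample(seq(spg[1], spg[2]), n, replace = TRUE)
  }

  truth <- tibble(
    gene_id = gene_id, c = cc, t = tt,
    true_category = factor(true_category, levels = SIM_CATEGORIES)
  )

  # one gene per 10 kb on a single contig; SNPs every 100 bp inside the body
  gene_start <- (seq_len(n) - 1L) * 10000L + 1L
  gene_models <- tibble(
    gene_id = gene_id, contig = "chr1",
    start = gene_start, end = gene_start + 2999L, strand = "+"
  )
  snp_gene <- rep(seq_len(n), times = n_snps)
  snp_index <- sequence(n_snps)
  snp_tbl <- tibble(
    gene = snp_gene,
    contig = "chr1",
    position = gene_start[snp_gene] + snp_index * 100L,
    variant_id = sprintf("%s_s%d", gene_id[snp_gene], snp_index),
    ref_allele = "A", alt_allele = "G"
  )

  p_f1 <- allele_fraction(cc)
  p_mix <- allele_fraction(cc + tt)

  draw_rna <- function(stream_seed, p_gene, mean_depth, sample_label) {
    set.seed(stream_seed)
    total <- rnbinom(n, mu = mean_depth, size = 1 / config$nb_dispersion)
    p1 <- rbinom(n, total, p_gene)
    p2 <- total - p1
    split_counts <- function(cnt, k) {
      if (k == 1L) return(cnt)
      drop(rmultinom(1, cnt, rep(1 / k, k)))
    }
    p1_snp <- vector("list", n)
    p2_snp <- vector("list", n)
    for (g in seq_len(n)) {
      p1_snp[[g]] <- split_counts(p1[g], n_snps[g])
      p2_snp[[g]] <- split_counts(p2[g], n_snps[g])
    }
    list(
      snp = mutate(snp_tbl,
        parent1_count = as.integer(unlist(p1_snp)),
        parent2_count = as.integer(unlist(p2_snp)),
        sample = sample_label
      ),
      gene = tibble(
        gene_id = gene_id, sample = sample_label,
        parent1_total = p1, parent2_total = p2
      )
    )
  }

  f1_draw <- draw_rna(seeds[2], p_f1, config$mean_depth_f1, "F1")
  mix_draw <- draw_rna(seeds[3], p_mix, config$mean_depth_mix, "MIX_RNA")
  f1 <- f1_draw$snp
  mix <- mix_draw$snp

  # --- stream 4: mixed-DNA control with optional mapping-biased sites
  set.seed(seeds[4])
  m <- nrow(snp_tbl)
  biased <- runif(m) < config$biased_snp_fraction
  p_dna <- ifelse(biased, config$biased_snp_allele_prob, 0.5)
  dna_p1 <- rbinom(m, config$dna_depth_per_snp, p_dna)
  dna <- mutate(snp_tbl,
    parent1_count = dna_p1,
    parent2_count = config$dna_depth_per_snp - dna_p1,
    sample = "MIX_DNA", biased_site = biased
  )

  snp_counts <- bind_rows(
    select(f1, -"gene"), select(mix, -"gene"),
    select(dna, -"gene", -"biased_site")
  )

  structure(
    list(
      snp_counts = snp_counts, truth = truth, gene_models = gene_models,
      gene_totals = bind_rows(f1_draw$gene, mix_draw$gene),
      biased_sites = snp_tbl$variant_id[biased], config = config
    ),
    class = "ase_sim"
  )
}

#' @export
print.ase_sim <- function(x, ...) {
  cat(sprintf(
    "<ase_sim> %d genes, %d SNP sites, samples: %s\n",
    nrow(x$truth),
    nrow(distinct(x$snp_counts, .data$contig, .data$position)),
    paste(unique(x$snp_counts$sample), collapse = ", ")
  ))
  invisible(x)
}

#' Simulate a genome layout with planted duplication modes
#'
#' Emits gene positions, an all-to-all homology hit table, collinear
#' blocks and a per-anchor-pair Ks table such that [assign_modes()]
#' recovers the planted modes exactly. Whole-genome-duplicate (WGD) genes
#' are planted as collinear anchor blocks whose Ks regime cycles through
#' young, intermediate and old values; tandem pairs sit at adjacent ranks;
#' proximal pairs are separated by 1-19 intervening genes; dispersed pairs
#' live on different chromosomes; singletons have no hits.
#'
#' @param n_genes Total genes to place.
#' @param mode_mix Named proportions over `singleton`, `dispersed`,
#'   `proximal`, `tandem`, `wgd`; must sum to 1. Parity leftovers (an odd
#'   pair member, a partial block) are demoted to singleton.
#' @param seed RNG seed.
#' @param anchors_per_block Anchor pairs per planted collinear block.
#' @return List of class `genome_sim`: `positions`, `hits` (12-column
#'   BLAST-tabular-shaped tibble), `blocks` (`block_id`, `gene1`, `gene2`),
#'   `ks` (`gene1`, `gene2`, `ks`), and `modes` (planted truth).
#' @examples
#' layout <- simulate_genome_layout(60, seed = 3)
#' table(layout$modes$mode)
#' @export
simulate_genome_layout <- function(n_genes,
                                   mode_mix = c(
                                     singleton = 0.1, dispersed = 0.25,
                                     proximal = 0.1, tandem = 0.15, wgd = 0.4
                                   ),
                                   seed = 1L,
                                   anchors_per_block = 6L) {
  missing_mode <- setdiff(DUP_MODES, names(mode_mix))
  if (length(missing_mode) > 0) {
    abort(paste0("`mode_mix` must name all modes; missing: ",
                 paste(missing_mode, collapse = ", ")))
  }
  mode_mix <- mode_mix[DUP_MODES]
  if (any(mode_mix < 0) || abs(sum(mode_mix) - 1) > 1e-9) {
    abort("`mode_mix` proportions must sum to 1.")
  }
  n_modes_req <- sum(mode_mix > 0)
  if (n_genes < n_modes_req) {
    abort("`n_genes` is smaller than the number of requested modes.")
  }
  set.seed(as.integer(seed))

  counts <- setNames(apportion(n_genes, mode_mix), DUP_MODES)
  # enforce pair/block parity; leftovers become singletons
  block_size <- 2L * anchors_per_block
  demote <- counts[["wgd"]] %% block_size +
    counts[["tandem"]] %% 2L +
    counts[["proximal"]] %% 2L +
    counts[["dispersed"]] %% 2L
  counts[["wgd"]] <- counts[["wgd"]] %/% block_size * block_size
  counts[["tandem"]] <- counts[["tandem"]] %/% 2L * 2L
  counts[["proximal"]] <- counts[["proximal"]] %/% 2L * 2L
  counts[["dispersed"]] <- counts[["dispersed"]] %/% 2L * 2L
  counts[["singleton"]] <- counts[["singleton"]] + demote

  ids <- sprintf("g%05d", seq_len(n_genes))
  nxt <- 1L
  take <- function(k) {
    out <- ids[seq.int(nxt, length.out = k)]
    nxt <<- nxt + k
    out
  }

  pairs <- list()   # gene1, gene2, ks (ks NA for non-anchor paralog pairs)
  blocks <- list()
  modes <- list()

  chrom_seq <- list()
  push <- function(chrom, genes) {
    if (is.null(chrom_seq[[chrom]])) chrom_seq[[chrom]] <<- character(0)
    chrom_seq[[chrom]] <<- c(chrom_seq[[chrom]], genes)
  }

  # WGD blocks: each block on its own chromosome pair (every third block
  # laid out reversed to exercise antiparallel chains). Ks regime cycles
  # young / intermediate / old.
  n_blocks <- counts[["wgd"]] %/% block_size
  ks_base <- c(0.10, 0.60, 1.40)
  for (b in seq_len(n_blocks)) {
    ga <- take(anchors_per_block)
    gb <- take(anchors_per_block)
    gb_layout <- if (b %% 3L == 0L) rev(gb) else gb
    push(sprintf("chrW%02dA", b), ga)
    push(sprintf("chrW%02dB", b), gb_layout)
    ks <- ks_base[(b - 1L) %% 3L + 1L] + runif(anchors_per_block, -0.03, 0.03)
    pairs[[length(pairs) + 1L]] <- tibble(gene1 = ga, gene2 = gb, ks = ks)
    blocks[[length(blocks) + 1L]] <- tibble(
      block_id = sprintf("block%03d", b), gene1 = ga, gene2 = gb
    )
    modes[[length(modes) + 1L]] <- tibble(gene_id = c(ga, gb), mode = "wgd")
  }

  # tandem pairs: adjacent ranks on chrT
  for (i in seq_len(counts[["tandem"]] %/% 2L)) {
    g <- take(2L)
    push("chrT", g)
    pairs[[length(pairs) + 1L]] <- tibble(gene1 = g[1], gene2 = g[2], ks = NA_real_)
    modes[[length(modes) + 1L]] <- tibble(gene_id = g, mode = "tandem")
  }

  # dispersed pairs: one member on chrB; partners scattered over
  # dedicated chromosomes, fewer anchors per chromosome than any block
  # needs, so no spurious collinearity can be chained
  per_chrom <- max(1L, anchors_per_block - 2L)
  for (i in seq_len(counts[["dispersed"]] %/% 2L)) {
    g <- take(2L)
    push("chrB", g[1])
    push(sprintf("chrD%02d", (i - 1L) %/% per_chrom + 1L), g[2])
    pairs[[length(pairs) + 1L]] <- tibble(gene1 = g[1], gene2 = g[2], ks = NA_real_)
    modes[[length(modes) + 1L]] <- tibble(gene_id = g, mode = "dispersed")
  }

  singletons <- take(counts[["singleton"]])
  if (length(singletons) > 0) {
    modes[[length(modes) + 1L]] <- tibble(gene_id = singletons, mode = "singleton")
  }

  # proximal pairs on chrP, separated by singleton filler genes
  # (unrelated to the pair itself)
  fillers <- singletons
  n_prox <- counts[["proximal"]] %/% 2L
  for (i in seq_len(n_prox)) {
    g <- take(2L)
    avail <- length(fillers)
    # leave at least one filler for each remaining pair
    reserve <- n_prox - i
    gap <- if (avail - reserve >= 1L) {
      sample.int(min(19L, avail - reserve), 1L)
    } else {
      abort("not enough singleton filler genes to separate proximal pairs; increase the singleton proportion")
    }
    between <- fillers[seq_len(gap)]
    fillers <- fillers[-seq_len(gap)]
    push("chrP", c(g[1], between, g[2]))
    pairs[[length(pairs) + 1L]] <- tibble(gene1 = g[1], gene2 = g[2], ks = NA_real_)
    modes[[length(modes) + 1L]] <- tibble(gene_id = g, mode = "proximal")
  }
  if (length(fillers) > 0) push("chrP", fillers)

  positions <- purrr::imap(chrom_seq, function(genes, chrom) {
    if (length(genes) == 0) return(NULL)
    start <- (seq_along(genes) - 1L) * 10000L + 1L
    tibble(
      gene_id = genes, chrom = chrom, rank = seq_along(genes) - 1L,
      start = start, end = start + 2999L
    )
  }) %>% bind_rows()

  pairs <- bind_rows(pairs)
  modes <- bind_rows(modes) %>%
    mutate(mode = factor(.data$mode, levels = DUP_MODES)) %>%
    arrange(.data$gene_id)
  blocks <- if (length(blocks) > 0) bind_rows(blocks) else {
    tibble(block_id = character(0), gene1 = character(0), gene2 = character(0))
  }

  hits <- if (nrow(pairs) > 0) {
    both <- bind_rows(
      select(pairs, qseqid = "gene1", sseqid = "gene2"),
      select(pairs, qseqid = "gene2", sseqid = "gene1")
    )
    mutate(both,
      pident = 85, length = 300L, mismatch = 45L, gapopen = 0L,
      qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
      evalue = 1e-50, bitscore = 500
    )
  } else {
    tibble(
      qseqid = character(0), sseqid = character(0), pident = numeric(0),
      length = integer(0), mismatch = integer(0), gapopen = integer(0),
      qstart = integer(0), qend = integer(0), sstart = integer(0),
      send = integer(0), evalue = numeric(0), bitscore = numeric(0)
    )
  }

  ks_tbl <- pairs %>% filter(!is.na(.data$ks)) %>%
    select("gene1", "gene2", "ks")

  structure(
    list(positions = positions, hits = hits, blocks = blocks,
         ks = ks_tbl, modes = modes),
    class = "genome_sim"
  )
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Serialises an `ase_sim` dataset to the file formats the readers in this
#' package consume: one allele-count TSV per sample (ASEReadCounter-style
#' columns, 1-based positions), a VCFv4.2 of the SNPs with per-parent
#' GT/GQ/DP, a GFF3 of gene models, a truth TSV, and the configuration as
#' YAML. Files round-trip through [read_ase_counts()], [filter_variants()]
#' and [read_gene_models()].
#'
#' @param dataset An `ase_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  if (!inherits(dataset, "ase_sim")) abort("`dataset` must be an `ase_sim`.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))

  paths <- c(
    F1 = file.path(dir, "f1.tsv"),
    MIX_RNA = file.path(dir, "mix_rna.tsv"),
    MIX_DNA = file.path(dir, "mix_dna.tsv"),
    vcf = file.path(dir, "snps.vcf"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )

  # parent1 is reference-homozygous at every simulated site, so refCount
  # carries the parent1 allele
  for (s in c("F1", "MIX_RNA", "MIX_DNA")) {
    tab <- dataset$snp_counts %>%
      filter(.data$sample == s) %>%
      transmute_asecounts()
    readr::write_tsv(tab, paths[[s]])
  }

  snps <- dataset$snp_counts %>%
    distinct(.data$contig, .data$position, .data$variant_id,
             .data$ref_allele, .data$alt_allele) %>%
    arrange(.data$contig, .data$position)
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "parent1", "parent2", sep = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT:GQ:DP\t0/0:60:30\t1/1:60:30",
            snps$contig, snps$position, snps$variant_id,
            snps$ref_allele, snps$alt_allele)
  )
  writeLines(vcf_lines, paths[["vcf"]])

  gm <- dataset$gene_models
  gff_lines <- c(
    "##gff-version 3",
    sprintf("%s\tcistrans\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            gm$contig, gm$start, gm$end, gm$strand, gm$gene_id)
  )
  writeLines(gff_lines, paths[["gff"]])

  readr::write_tsv(dataset$truth, paths[["truth"]])
  yaml::write_yaml(unclass(dataset$config), paths[["config"]])
  invisible(paths)
}

# ASEReadCounter column order from internal per-SNP representation.
transmute_asecounts <- function(tab) {
  tibble(
    contig = tab$contig, position = tab$position,
    variantID = tab$variant_id, refAllele = tab$ref_allele,
    altAllele = tab$alt_allele, refCount = tab$parent1_count,
    altCount = tab$parent2_count,
    totalCount = tab$parent1_count + tab$parent2_count
  )
}
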
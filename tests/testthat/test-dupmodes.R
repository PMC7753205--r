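positions_one_chrom <- function(n, chrom = "c1") {
  tibble::tibble(
    gene_id = sprintf("%s_g%02d", chrom, seq_len(n)), chrom = chrom,
    rank = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * 1000L + 1L, end = (seq_len(n) - 1L) * 1000L + 500L
  )
}

hit_pairs <- function(...) {
  pairs <- list(...)
  tibble::tibble(
    qseqid = vapply(pairs, `[`, "", 1), sseqid = vapply(pairs, `[`, "", 2),
    evalue = 1e-50, bitscore = 100
  )
}

test_that("mode assignment follows adjacency rules and priority", {
  pos <- dplyr::bind_rows(positions_one_chrom(25, "c1"),
                          positions_one_chrom(5, "c2"))
  hits <- hit_pairs(
    c("c1_g08", "c1_g09"),   # adjacent: tandem
    c("c1_g04", "c1_g15"),   # 10 intervening genes: proximal
    c("c1_g01", "c1_g22"),   # rank distance 21: beyond the gap, dispersed
    c("c1_g24", "c2_g02")    # different chromosomes: dispersed
  )
  asg <- assign_modes(pos, hits)
  mode_of <- function(g) as.character(asg$mode[asg$gene_id == g])
  expect_equal(mode_of("c1_g08"), "tandem")
  expect_equal(mode_of("c1_g09"), "tandem")
  expect_equal(mode_of("c1_g04"), "proximal")
  expect_equal(mode_of("c1_g15"), "proximal")
  expect_equal(mode_of("c1_g01"), "dispersed")
  expect_equal(mode_of("c1_g22"), "dispersed")
  expect_equal(mode_of("c1_g24"), "dispersed")
  expect_equal(mode_of("c1_g02"), "singleton")  # no hits at all
  # rank distance exactly 20 is still proximal
  asg20 <- assign_modes(pos, hit_pairs(c("c1_g01", "c1_g21")))
  expect_equal(as.character(asg20$mode[asg20$gene_id == "c1_g01"]), "proximal")
  # every positioned gene receives exactly one mode
  expect_equal(nrow(asg), nrow(pos))
  expect_false(any(is.na(asg$mode)))
})

test_that("collinear blocks override tandem and proximal (wgd priority)", {
  pos <- positions_one_chrom(8, "cA") |>
    dplyr::bind_rows(positions_one_chrom(8, "cB"))
  anchors <- lapply(1:6, function(i) c(sprintf("cA_g%02d", i),
                                       sprintf("cB_g%02d", i)))
  hits <- do.call(hit_pairs, c(anchors, list(c("cA_g07", "cA_g08"))))
  blocks <- detect_collinearity(pos, hits, min_anchors = 5)
  expect_equal(length(unique(blocks$block_id)), 1)
  expect_equal(nrow(blocks), 6)
  asg <- assign_modes(pos, hits, blocks)
  expect_true(all(as.character(asg$mode[asg$gene_id %in%
    unlist(anchors)]) == "wgd"))
  expect_equal(as.character(asg$mode[asg$gene_id == "cA_g07"]), "tandem")
  # adding blocks only ever moves genes into wgd, never out
  asg_nb <- assign_modes(pos, hits, blocks = NULL)
  moved <- asg$gene_id[as.character(asg$mode) == "wgd"]
  expect_true(all(as.character(asg_nb$mode[asg_nb$gene_id %in% moved])
                  != "singleton"))
  expect_equal(
    as.character(asg$mode[!asg$gene_id %in% moved]),
    as.character(asg_nb$mode[!asg_nb$gene_id %in% moved])
  )
})

test_that("assignment errors on unknown genes", {
  pos <- positions_one_chrom(4)
  expect_error(assign_modes(pos, hit_pairs(c("c1_g01", "nope"))), "unknown")
})

test_that("chaining respects the anchor threshold and both orientations", {
  pos <- dplyr::bind_rows(positions_one_chrom(10, "cA"),
                          positions_one_chrom(10, "cB"))
  fwd4 <- do.call(hit_pairs, lapply(1:4, function(i)
    c(sprintf("cA_g%02d", i), sprintf("cB_g%02d", i))))
  expect_equal(nrow(detect_collinearity(pos, fwd4, min_anchors = 5)), 0)
  # antiparallel: cA ascending, cB descending
  rev6 <- do.call(hit_pairs, lapply(1:6, function(i)
    c(sprintf("cA_g%02d", i), sprintf("cB_g%02d", 7 - i))))
  blocks <- detect_collinearity(pos, rev6, min_anchors = 5)
  expect_equal(nrow(blocks), 6)
  expect_equal(length(unique(blocks$block_id)), 1)
  expect_identical(detect_collinearity(pos, fwd4[0, ]),
                   detect_collinearity(pos, fwd4[0, ]))
})

test_that("chaining matches the exhaustive oracle on random anchor sets", {
  for (s in 1:12) {
    set.seed(s)
    n_anchor <- sample(6:14, 1)
    nA <- 30L
    pos <- dplyr::bind_rows(positions_one_chrom(nA, "cA"),
                            positions_one_chrom(nA, "cB"))
    ia <- sort(sample(nA, n_anchor))
    ib <- sample(nA, n_anchor)
    hits <- do.call(hit_pairs, lapply(seq_len(n_anchor), function(i)
      c(sprintf("cA_g%02d", ia[i]), sprintf("cB_g%02d", ib[i]))))
    gap <- 5L
    blocks <- detect_collinearity(pos, hits, min_anchors = 3,
                                  max_gap = gap, top_hits = Inf)
    oracle_idx <- oracle_longest_chain(ia - 1L, ib - 1L, gap)
    if (length(oracle_idx) < 3) {
      expect_equal(nrow(blocks), 0, label = paste("seed", s))
    } else {
      expect_gt(nrow(blocks), 0, label = paste("seed", s))
      first_block <- blocks[blocks$block_id == blocks$block_id[1], ]
      # the first (longest) extracted chain has the oracle's length
      expect_equal(nrow(first_block), length(oracle_idx),
                   label = paste("seed", s))
    }
  }
})

test_that("Ks clustering separates well-spaced blocks and ages genes", {
  blocks <- tibble::tibble(
    block_id = paste0("b", 1:7),
    gene1 = paste0("x", 1:7), gene2 = paste0("y", 1:7),
    mean_ks = c(0.10, 0.12, 0.11, 0.60, 0.62, 1.5, 1.4)
  )
  ages <- classify_wgd_age(blocks)
  clusters <- attr(ages, "block_clusters")
  expect_equal(clusters$cluster, c(1L, 1L, 1L, 2L, 2L, 3L, 3L))
  young <- ages$gene_id[ages$age == "young"]
  expect_setequal(young, c("x1", "x2", "x3", "y1", "y2", "y3"))
  # a gene in both a young and an old block is old
  blocks2 <- dplyr::bind_rows(
    blocks,
    tibble::tibble(block_id = "b8", gene1 = "x1", gene2 = "z9",
                   mean_ks = 1.45)
  )
  ages2 <- classify_wgd_age(blocks2)
  expect_equal(ages2$age[ages2$gene_id == "x1"], "old")
  expect_equal(ages2$age[ages2$gene_id == "y1"], "young")
})

test_that("degenerate Ks distributions fall back to a quantile cut", {
  blocks <- tibble::tibble(
    block_id = paste0("b", 1:4),
    gene1 = paste0("x", 1:4), gene2 = paste0("y", 1:4),
    mean_ks = rep(0.5, 4)
  )
  expect_message(ages <- classify_wgd_age(blocks), "quantile cut")
  expect_true(all(ages$age == "young"))  # single cluster: all minimal
})

test_that("1-D k-means equals the exhaustive contiguous-partition optimum", {
  kmeans_1d <- cistrans:::kmeans_1d
  for (s in 1:25) {
    set.seed(1000 + s)
    n <- sample(6:30, 1)
    x <- switch(1 + s %% 3,
      runif(n, 0, 2),
      c(runif(n %/% 2, 0, 0.3), runif(n - n %/% 2, 0.8, 2)),
      rexp(n, 1)
    )
    expect_equal(kmeans_1d(x, 3), oracle_partition3(x),
                 label = paste("seed", s))
  }
})

test_that("planted genome layouts are recovered without mode errors", {
  for (s in c(3, 14)) {
    lay <- simulate_genome_layout(250, seed = s)
    blocks <- detect_collinearity(lay$positions, lay$hits)
    asg <- assign_modes(lay$positions, lay$hits, blocks)
    cmp <- dplyr::left_join(lay$modes, asg, by = "gene_id",
                            suffix = c("_true", "_called"))
    expect_equal(sum(as.character(cmp$mode_true) !=
                       as.character(cmp$mode_called)), 0,
                 label = paste("seed", s))
    # mode counts partition the gene set
    expect_equal(sum(table(asg$mode)), nrow(lay$positions))
    # planted blocks recovered via detection and via the planted table agree
    asg_planted <- assign_modes(lay$positions, lay$hits, lay$blocks)
    expect_equal(as.character(asg$mode), as.character(asg_planted$mode))
  }
})

test_that("collinearity and Ks files round-trip through the readers", {
  lay <- simulate_genome_layout(150, seed = 6)
  dir <- withr::local_tempdir()
  # write an MCScanX-dialect collinearity file and matching Ks table
  coll <- file.path(dir, "blocks.collinearity")
  lines <- c("############### Parameters ###############", "# MATCH_SCORE: 50")
  for (b in unique(lay$blocks$block_id)) {
    sub <- lay$blocks[lay$blocks$block_id == b, ]
    lines <- c(lines, sprintf("## Alignment %s: score=500 e_value=0 N=%d",
                              sub("block", "", b), nrow(sub)))
    lines <- c(lines, sprintf(" %s-  %d:\t%s\t%s\t  0",
                              sub("block", "", b), seq_len(nrow(sub)) - 1L,
                              sub$gene1, sub$gene2))
  }
  writeLines(lines, coll)
  back <- read_collinearity(coll)
  expect_equal(nrow(back), nrow(lay$blocks))
  expect_equal(sort(paste(back$gene1, back$gene2)),
               sort(paste(lay$blocks$gene1, lay$blocks$gene2)))

  ks_path <- file.path(dir, "ks.tsv")
  readr::write_tsv(lay$ks, ks_path)
  ks_back <- read_ks(ks_path)
  expect_equal(ks_back$ks, lay$ks$ks)

  withks <- block_mean_ks(back, ks_back)
  ages <- classify_wgd_age(withks)
  expect_setequal(unique(ages$age), c("young", "old"))
})
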
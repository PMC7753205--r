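# Gene duplication-mode assignment and WGD age classification.
#
# Modes follow the MCScanX convention: singletons have no paralog hit at
# all; genes in collinear blocks are whole-genome/segmental duplicates
# (WGD); paralogs at adjacent ranks on a chromosome are tandem; paralogs
# within a small rank distance are proximal; everything else with a hit is
# dispersed. The override priority is wgd > tandem > proximal > dispersed.

#' Read a 12-column BLAST tabular hit file
#'
#' Standard `-outfmt 6` columns. Only query, subject and e-value are used
#' downstream.
#'
#' @param path Path to the tabular file (no header).
#' @return Tibble with the 12 standard columns.
#' @export
read_blast_hits <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Read collinear blocks from an MCScanX .collinearity file
#'
#' Parses the dialect with `## Alignment` block headers followed by
#' anchor-pair lines (`index: gene1 gene2 evalue`).
#'
#' @param path Path to the .collinearity file.
#' @return Tibble `block_id`, `gene1`, `gene2`.
#' @export
read_collinearity <- function(path) {
  lines <- readLines(path)
  out <- list()
  block <- NA_character_
  for (ln in lines) {
    if (grepl("^##\\s*Alignment", ln)) {
      block <- stringr::str_match(ln, "Alignment\\s+(\\S+?):")[, 2]
      if (is.na(block)) block <- as.character(length(out) + 1L)
      next
    }
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    # pair lines look like "0-  0:\tgeneA\tgeneB\t0": genes follow the colon
    colon <- regexpr(":", ln, fixed = TRUE)
    body <- if (colon > 0) substring(ln, colon + 1L) else ln
    fields <- strsplit(trimws(body), "\\s+")[[1]]
    if (length(fields) >= 2) {
      out[[length(out) + 1L]] <- tibble(
        block_id = block, gene1 = fields[1], gene2 = fields[2]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(block_id = character(0), gene1 = character(0),
                  gene2 = character(0)))
  }
  bind_rows(out)
}

#' Read a Ks table
#'
#' @param path TSV with columns `gene1`, `gene2`, `ks` (header optional;
#'   three unnamed columns are accepted in that order).
#' @return Tibble `gene1`, `gene2`, `ks`.
#' @export
read_ks <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("ks", tolower(first))
  tab <- readr::read_tsv(
    path, col_names = if (has_header) TRUE else c("gene1", "gene2", "ks"),
    skip = 0, show_col_types = FALSE, progress = FALSE
  )
  names(tab)[1:3] <- c("gene1", "gene2", "ks")
  mutate(tab[1:3], ks = as.numeric(.data$ks))
}

# Normalise a hit table to unique unordered non-self pairs, applying the
# e-value and per-gene top-hit filters.
prepare_pairs <- function(hits, max_evalue, top_hits) {
  if (nrow(hits) == 0) {
    return(tibble(gene1 = character(0), gene2 = character(0)))
  }
  h <- tibble(
    gene1 = as.character(hits[[1]]), gene2 = as.character(hits[[2]]),
    evalue = if ("evalue" %in% names(hits)) hits$evalue else 0,
    bitscore = if ("bitscore" %in% names(hits)) hits$bitscore else 0
  ) %>%
    filter(.data$gene1 != .data$gene2, .data$evalue <= max_evalue)
  if (is.finite(top_hits)) {
    h <- h %>%
      group_by(.data$gene1) %>%
      arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$gene2,
              .by_group = TRUE) %>%
      dplyr::slice_head(n = top_hits) %>%
      ungroup()
  }
  h %>%
    mutate(
      a = pmin(.data$gene1, .data$gene2),
      b = pmax(.data$gene1, .data$gene2)
    ) %>%
    distinct(.data$a, .data$b) %>%
    rename(gene1 = "a", gene2 = "b")
}

#' Assign duplication modes to genes
#'
#' Classifies every positioned gene as `singleton`, `dispersed`,
#' `proximal`, `tandem` or `wgd` from a homology hit table, gene order,
#' and (optionally) collinear blocks, with override priority
#' wgd > tandem > proximal > dispersed. A gene is a singleton iff it has
#' no retained non-self hit; tandem iff a paralog sits at rank distance 1
#' on the same chromosome; proximal iff one sits at rank distance 2 to
#' `proximal_max_gap`; any gene appearing in a block anchor pair is wgd.
#'
#' @param positions Gene positions: `gene_id`, `chrom`, `rank` (0-based
#'   order along the chromosome; computed from `start` if absent).
#' @param hits Homology hits; first two columns are query and subject
#'   gene ids, optional `evalue`/`bitscore` columns are used for
#'   filtering. Self-hits are ignored; pairs are treated symmetrically.
#' @param blocks Collinear blocks (`block_id`, `gene1`, `gene2`) from
#'   [detect_collinearity()], [read_collinearity()] or a `genome_sim`;
#'   `NULL` for none.
#' @param proximal_max_gap Maximum rank distance still called proximal
#'   (distance 1 is tandem; `20` means up to 19 intervening genes).
#' @param max_evalue,top_hits Hit filters applied before assignment
#'   (MCScanX-style defaults: e-value at most 1e-10, top 5 non-self hits
#'   per gene; `top_hits = Inf` disables).
#' @return Tibble `gene_id`, `mode` (factor), `age` (all
#'   `not_applicable`; see [classify_wgd_age()] and [add_wgd_age()]).
#' @export
assign_modes <- function(positions, hits, blocks = NULL,
                         proximal_max_gap = 20,
                         max_evalue = 1e-10, top_hits = 5L) {
  assert_cols(positions, c("gene_id", "chrom"), "`positions`")
  if (!"rank" %in% names(positions)) {
    assert_cols(positions, "start", "`positions`")
    positions <- positions %>%
      arrange(.data$chrom, .data$start) %>%
      group_by(.data$chrom) %>%
      mutate(rank = row_number() - 1L) %>%
      ungroup()
  }
  if (anyDuplicated(paste(positions$chrom, positions$rank))) {
    abort("ranks must be unique within each chromosome")
  }
  pairs <- prepare_pairs(hits, max_evalue, top_hits)
  known <- positions$gene_id
  unknown <- setdiff(c(pairs$gene1, pairs$gene2), known)
  if (length(unknown) > 0) {
    abort(sprintf("hit table references unknown gene(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  if (!is.null(blocks) && nrow(blocks) > 0) {
    unknown_b <- setdiff(c(blocks$gene1, blocks$gene2), known)
    if (length(unknown_b) > 0) {
      abort(sprintf("blocks reference unknown gene(s): %s",
                    paste(head(unknown_b, 5), collapse = ", ")))
    }
  }

  pos <- select(positions, "gene_id", "chrom", "rank")
  ann <- pairs %>%
    left_join(pos, by = c(gene1 = "gene_id")) %>%
    rename(chrom1 = "chrom", rank1 = "rank") %>%
    left_join(pos, by = c(gene2 = "gene_id")) %>%
    rename(chrom2 = "chrom", rank2 = "rank") %>%
    mutate(
      same_chrom = .data$chrom1 == .data$chrom2,
      dist = abs(.data$rank1 - .data$rank2)
    )

  has_hit <- unique(c(pairs$gene1, pairs$gene2))
  tandem_genes <- ann %>% filter(.data$same_chrom, .data$dist == 1)
  tandem_genes <- unique(c(tandem_genes$gene1, tandem_genes$gene2))
  proximal_genes <- ann %>%
    filter(.data$same_chrom, .data$dist >= 2, .data$dist <= proximal_max_gap)
  proximal_genes <- unique(c(proximal_genes$gene1, proximal_genes$gene2))
  wgd_genes <- if (!is.null(blocks) && nrow(blocks) > 0) {
    unique(c(blocks$gene1, blocks$gene2))
  } else {
    character(0)
  }

  mode <- rep("singleton", length(known))
  names(mode) <- known
  mode[known %in% has_hit] <- "dispersed"
  mode[known %in% proximal_genes] <- "proximal"
  mode[known %in% tandem_genes] <- "tandem"
  mode[known %in% wgd_genes] <- "wgd"

  tibble(
    gene_id = known,
    mode = factor(unname(mode), levels = DUP_MODES),
    age = ifelse(mode == "wgd", NA_character_, "not_applicable")
  ) %>%
    arrange(.data$gene_id)
}

#' Detect collinear blocks by anchor chaining
#'
#' A simplified synteny-chain detector: for each pair of chromosomes,
#' homology hits are treated as anchors in the two rank spaces, and
#' maximal chains monotonically increasing in one genome and monotonic
#' (either orientation) in the other, with per-step rank gaps at most
#' `max_gap` on both sides, are reported as blocks when they contain at
#' least `min_anchors` anchor pairs. Chains are extracted longest-first by
#' dynamic programming; each anchor belongs to at most one block.
#'
#' @param positions Gene positions (`gene_id`, `chrom`, `rank`).
#' @param hits Homology hits (as in [assign_modes()]).
#' @param min_anchors Minimum anchor pairs per reported block.
#' @param max_gap Maximum rank gap between consecutive anchors.
#' @param exclude_close Same-chromosome hit pairs closer than this rank
#'   distance are tandem/proximal duplicates, not synteny anchors, and
#'   are excluded from chaining (mirrors MCScanX's tandem collapse).
#' @param max_evalue,top_hits Hit filters, as in [assign_modes()].
#' @return Tibble `block_id`, `gene1`, `gene2`, one row per anchor pair.
#' @export
detect_collinearity <- function(positions, hits, min_anchors = 5L,
                                max_gap = 25L, exclude_close = 20L,
                                max_evalue = 1e-10, top_hits = 5L) {
  empty <- tibble(block_id = character(0), gene1 = character(0),
                  gene2 = character(0))
  pairs <- prepare_pairs(hits, max_evalue, top_hits)
  if (nrow(pairs) == 0) return(empty)
  if (!"rank" %in% names(positions)) {
    positions <- positions %>%
      arrange(.data$chrom, .data$start) %>%
      group_by(.data$chrom) %>%
      mutate(rank = row_number() - 1L) %>%
      ungroup()
  }
  pos <- select(positions, "gene_id", "chrom", "rank")
  anchors <- pairs %>%
    left_join(pos, by = c(gene1 = "gene_id")) %>%
    rename(chromA = "chrom", rankA = "rank") %>%
    left_join(pos, by = c(gene2 = "gene_id")) %>%
    rename(chromB = "chrom", rankB = "rank") %>%
    filter(!is.na(.data$rankA), !is.na(.data$rankB)) %>%
    filter(!(.data$chromA == .data$chromB &
               abs(.data$rankA - .data$rankB) < exclude_close))
  if (nrow(anchors) == 0) return(empty)

  blocks <- list()
  bid <- 0L
  for (key in unique(paste(anchors$chromA, anchors$chromB))) {
    sub <- anchors[paste(anchors$chromA, anchors$chromB) == key, ]
    sub <- arrange(sub, .data$rankA, .data$rankB)
    used <- rep(FALSE, nrow(sub))
    repeat {
      best <- best_chain(sub$rankA, sub$rankB, used, max_gap)
      if (length(best) < min_anchors) break
      bid <- bid + 1L
      blocks[[bid]] <- tibble(
        block_id = sprintf("block%03d", bid),
        gene1 = sub$gene1[best], gene2 = sub$gene2[best]
      )
      used[best] <- TRUE
    }
  }
  if (length(blocks) == 0) return(empty)
  bind_rows(blocks)
}

# Longest monotone chain (forward or antiparallel) over unused anchors,
# with per-step gaps in (0, max_gap] on both rank axes. O(n^2) DP.
best_chain <- function(rankA, rankB, used, max_gap) {
  idx <- which(!used)
  if (length(idx) == 0) return(integer(0))
  chain_dir <- function(dir) {
    n <- length(idx)
    len <- rep(1L, n)
    prev <- rep(0L, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        dA <- rankA[idx[j]] - rankA[idx[i]]
        dB <- dir * (rankB[idx[j]] - rankB[idx[i]])
        if (dA > 0 && dA <= max_gap && dB > 0 && dB <= max_gap &&
            len[i] + 1L > len[j]) {
          len[j] <- len[i] + 1L
          prev[j] <- i
        }
      }
    }
    j <- which.max(len)
    chain <- integer(0)
    while (j != 0L) {
      chain <- c(idx[j], chain)
      j <- prev[j]
    }
    chain
  }
  fwd <- chain_dir(1)
  rev_ <- chain_dir(-1)
  if (length(fwd) >= length(rev_)) fwd else rev_
}

#' Mean Ks per collinear block
#'
#' @param blocks Anchor-pair table (`block_id`, `gene1`, `gene2`).
#' @param ks Per-pair Ks table (`gene1`, `gene2`, `ks`); pair order is
#'   ignored.
#' @return `blocks` with a `ks` column per anchor pair and an attached
#'   per-block summary (`attr(x, "block_means")`).
#' @export
block_mean_ks <- function(blocks, ks) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ks_map <- setNames(ks$ks, key(ks$gene1, ks$gene2))
  out <- mutate(blocks, ks = unname(ks_map[key(.data$gene1, .data$gene2)]))
  means <- out %>%
    group_by(.data$block_id) %>%
    summarise(mean_ks = mean(.data$ks, na.rm = TRUE), .groups = "drop")
  attr(out, "block_means") <- means
  out
}

# Exact 1-D k-means: optimal clusters in one dimension are contiguous in
# sorted order, so the global minimum of the within-cluster sum of
# squares is found by dynamic programming over contiguous partitions
# (no random initialization, fully deterministic). Returns integer
# cluster ids ordered so cluster 1 has the smallest center.
kmeans_1d <- function(x, k) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  seg_ss <- function(i, j) {  # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  cut <- matrix(0L, k, n)
  for (j in seq_len(n)) dp[1, j] <- seg_ss(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          cand <- dp[m - 1, i - 1] + seg_ss(i, j)
          if (cand < dp[m, j] - 1e-12) {
            dp[m, j] <- cand
            cut[m, j] <- i
          }
        }
      }
    }
  }
  cl_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else cut[m, j]
    cl_sorted[i:j] <- m
    j <- i - 1L
  }
  out <- integer(n)
  out[o] <- cl_sorted
  out
}

#' Split WGD genes into young and old age classes by block Ks
#'
#' Clusters per-block mean Ks values into `k` groups with a deterministic
#' one-dimensional k-means solved exactly by dynamic programming over
#' contiguous partitions (optimal 1-D clusters are contiguous). A gene is
#' `young` iff every block containing it falls in the cluster with the
#' smallest mean Ks; a gene found in at least one older-cluster block is
#' `old`. With fewer than `k` distinct block means, k-means is degenerate
#' and a quantile cut over the distinct values is used instead (reported
#' via a message).
#'
#' @param blocks Anchor-pair table with per-pair `ks` (see
#'   [block_mean_ks()]), or with a precomputed `mean_ks` column per row.
#' @param k Number of Ks clusters (default 3).
#' @return Tibble `gene_id`, `age` (`"young"`/`"old"`) covering every gene
#'   that appears in a block; block-level clusters in
#'   `attr(x, "block_clusters")`.
#' @export
classify_wgd_age <- function(blocks, k = 3L) {
  if (!"ks" %in% names(blocks) && !"mean_ks" %in% names(blocks)) {
    abort("`blocks` needs a per-pair `ks` or per-block `mean_ks` column")
  }
  means <- if ("mean_ks" %in% names(blocks)) {
    distinct(blocks, .data$block_id, .data$mean_ks)
  } else {
    blocks %>%
      group_by(.data$block_id) %>%
      summarise(mean_ks = mean(.data$ks, na.rm = TRUE), .groups = "drop")
  }
  if (any(is.na(means$mean_ks))) {
    abort("every block needs a mean Ks value")
  }
  n_distinct_ks <- dplyr::n_distinct(means$mean_ks)
  if (nrow(means) < k || n_distinct_ks < k) {
    inform("classify_wgd_age: fewer distinct Ks values than clusters; using a quantile cut")
    brk <- unique(quantile(
      means$mean_ks,
      probs = seq(0, 1, length.out = min(k, n_distinct_ks) + 1)
    ))
    cl <- if (length(brk) < 2) {
      rep(1L, nrow(means))
    } else {
      as.integer(cut(means$mean_ks, breaks = brk, include.lowest = TRUE))
    }
  } else {
    cl <- kmeans_1d(means$mean_ks, k)
  }
  means$cluster <- cl

  membership <- blocks %>%
    select("block_id", "gene1", "gene2") %>%
    tidyr::pivot_longer(c("gene1", "gene2"), values_to = "gene_id") %>%
    distinct(.data$block_id, .data$gene_id) %>%
    left_join(means, by = "block_id")
  ages <- membership %>%
    group_by(.data$gene_id) %>%
    summarise(age = if (all(.data$cluster == 1L)) "young" else "old",
              .groups = "drop")
  attr(ages, "block_clusters") <- means
  ages
}

#' Merge WGD age labels into a mode assignment
#'
#' @param assignments Output of [assign_modes()].
#' @param ages Output of [classify_wgd_age()].
#' @return `assignments` with the `age` column filled for WGD genes
#'   (`young`/`old`; non-WGD genes keep `not_applicable`).
#' @export
add_wgd_age <- function(assignments, ages) {
  out <- assignments %>%
    left_join(rename(ages, wgd_age = "age"), by = "gene_id") %>%
    mutate(
      age = dplyr::case_when(
        .data$mode == "wgd" & !is.na(.data$wgd_age) ~ .data$wgd_age,
        .data$mode == "wgd" ~ NA_character_,
        TRUE ~ "not_applicable"
      )
    ) %>%
    select(-"wgd_age")
  out
}
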
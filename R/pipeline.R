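# End-to-end orchestration: files in, calls/crosstab/tests/enrichment out.

#' Pipeline configuration
#'
#' Validates a pipeline configuration, supplied as a named list or a YAML
#' file. Recognised fields: input paths (`f1`, `mix`, `dna`, `vcf`,
#' `gff`, and optionally `hits`, `collinearity`, `ks`, `annotations`,
#' `query_category`) and parameters (`alpha_snp_bias`,
#' `alpha_classification`, `alpha_enrichment`, `min_snps`, `expr_bounds`,
#' `proximal_max_gap`, `min_anchors`, `kmeans_k`, `min_term_size`,
#' `seed`). Every analysis constant is a configurable default, never
#' hard-coded.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    alpha_snp_bias = 0.05, alpha_classification = 0.05,
    alpha_enrichment = 0.05, min_snps = 2L, expr_bounds = c(10, 1000),
    proximal_max_gap = 20L, min_anchors = 5L, kmeans_k = 3L,
    min_term_size = 5L, seed = 1L, query_category = "cis_only"
  )
  cfg <- utils::modifyList(defaults, config)
  for (a in c("alpha_snp_bias", "alpha_classification", "alpha_enrichment")) {
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) {
      abort(sprintf("`%s` must lie in (0, 1)", a))
    }
  }
  for (t in c("min_snps", "proximal_max_gap", "min_anchors", "kmeans_k",
              "min_term_size")) {
    if (cfg[[t]] <= 0) abort(sprintf("`%s` must be positive", t))
  }
  required <- c("f1", "mix", "dna", "vcf", "gff")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("config is missing required input path(s): ",
                 paste(missing, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full regulatory-divergence pipeline
#'
#' Reads the allele-count tables, applies the variant and DNA-bias
#' filters, aggregates to gene profiles, classifies regulatory
#' divergence, and — when homology inputs are configured — assigns
#' duplication modes, cross-tabulates, runs the chi-squared comparisons
#' and the term enrichment of one category. Outputs are TSVs plus a JSON
#' manifest recording the package version, seed, parameters and input
#' hashes; a rerun with the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()], list, or YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))

  need <- function(field) {
    path <- cfg[[field]]
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf("input '%s' (%s) does not exist", field,
                    path %||% "<unset>"))
    }
    path
  }

  variants <- with_stage("filter-variants", filter_variants(need("vcf")))
  gene_models <- with_stage("read-gene-models", read_gene_models(need("gff")))

  counts <- with_stage("read-counts", {
    list(
      f1 = orient_to_parents(read_ase_counts(need("f1"), "F1"), variants),
      mix = orient_to_parents(read_ase_counts(need("mix"), "MIX_RNA"), variants)
    )
  })

  retained <- with_stage("filter-snps", {
    dna <- orient_to_parents(read_ase_counts(need("dna"), "MIX_DNA"), variants)
    filter_biased_snps(dna, alpha = cfg$alpha_snp_bias)
  })
  keep_key <- paste(retained$contig, retained$position)
  rna <- bind_rows(counts$f1, counts$mix) %>%
    filter(paste(.data$contig, .data$position) %in% keep_key)

  profiles <- with_stage("aggregate",
    aggregate_to_genes(rna, gene_models, min_snps = cfg$min_snps,
                       expr_bounds = cfg$expr_bounds)
  )
  calls <- with_stage("classify",
    classify_all(profiles, alpha = cfg$alpha_classification)
  )
  write_calls(calls, file.path(out_dir, "calls.tsv"))

  results <- list(profiles = profiles, calls = calls)

  if (!is.null(cfg$hits)) {
    positions <- rename(gene_models, chrom = "contig")
    hits <- with_stage("dupmode", read_blast_hits(need("hits")))
    blocks <- with_stage("dupmode", {
      if (!is.null(cfg$collinearity)) {
        read_collinearity(need("collinearity"))
      } else {
        detect_collinearity(positions, hits, min_anchors = cfg$min_anchors)
      }
    })
    assignments <- with_stage("dupmode",
      assign_modes(positions, hits, blocks,
                   proximal_max_gap = cfg$proximal_max_gap)
    )
    if (!is.null(cfg$ks) && nrow(blocks) > 0) {
      assignments <- with_stage("wgd-age", {
        ks <- read_ks(need("ks"))
        ages <- classify_wgd_age(block_mean_ks(blocks, ks), k = cfg$kmeans_k)
        add_wgd_age(assignments, ages)
      })
    }
    readr::write_tsv(assignments, file.path(out_dir, "modes.tsv"))
    results$assignments <- assignments

    common <- intersect(calls$gene_id, assignments$gene_id)
    if (length(common) > 0) {
      xtab <- with_stage("crosstab",
        crosstab(filter(calls, .data$gene_id %in% common), assignments)
      )
      readr::write_tsv(tidy(xtab), file.path(out_dir, "crosstab.tsv"))
      tests <- with_stage("crosstab", crosstab_tests(xtab))
      readr::write_tsv(tests, file.path(out_dir, "tests.tsv"))
      results$crosstab <- xtab
      results$tests <- tests
    }
  }

  if (!is.null(cfg$annotations)) {
    enr <- with_stage("enrich", {
      ann <- read_annotations(need("annotations"))
      universe <- calls$gene_id
      query <- calls$gene_id[calls$category == cfg$query_category]
      if (length(query) == 0) {
        inform(sprintf("enrich: no genes in category '%s'; skipping",
                       cfg$query_category))
        NULL
      } else {
        enrich(query, ann, universe, min_term_size = cfg$min_term_size,
               alpha = cfg$alpha_enrichment)
      }
    })
    if (!is.null(enr)) {
      readr::write_tsv(as_tibble(enr), file.path(out_dir, "enrichment.tsv"))
      results$enrichment <- enr
    }
  }

  inputs <- cfg[intersect(names(cfg), c("f1", "mix", "dna", "vcf", "gff",
                                        "hits", "collinearity", "ks",
                                        "annotations"))]
  manifest <- list(
    package = "cistrans",
    version = as.character(utils::packageVersion("cistrans")),
    seed = cfg$seed,
    parameters = cfg[c("alpha_snp_bias", "alpha_classification",
                       "alpha_enrichment", "min_snps", "expr_bounds",
                       "proximal_max_gap", "min_anchors", "kmeans_k",
                       "min_term_size", "query_category")],
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
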
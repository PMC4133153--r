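#' Run the full analysis pipeline on a simulated cohort
#'
#' Programmatic "all stages" driver: generates (or accepts) a cohort,
#' writes its on-disk inputs, then runs quality control, bias offsets,
#' genetic differentiation, differential expression, splicing
#' decomposition, allele-specific expression and region discovery, writing
#' every stage's outputs under `out_dir` together with a JSON run manifest
#' (tool version, configuration hash, input checksums, seed registry;
#' wall times are stored in a separate `timings` field so that the rest of
#' the manifest is reproducible). All randomness derives from the
#' config seed via named substreams, so two runs with the same
#' configuration produce byte-identical stage outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param cohort Optional pre-built [simulate_cohort()]; by default one is
#'   generated from `config`.
#' @param n_perm Permutations for the decomposition stage.
#' @return Invisibly, a list with the main stage results and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         cohort = NULL, n_perm = 100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- cohort %||% clock("simulate", simulate_cohort(config))
  in_dir <- p("inputs")
  write_cohort(cohort, in_dir)

  qc <- clock("qc", d_statistics(cohort$fpkm))
  readr::write_tsv(qc, p("qc_dstatistics.tsv"))

  offsets <- clock("normalize",
                   cqn_offsets(cohort$counts, cohort$gc, cohort$length))
  write_tsv_matrix(offsets, p("cqn_offsets.tsv"), "gene")

  fst <- clock("popgen", pairwise_fst(cohort$genotypes$dosage, cohort$labels))
  write_tsv_matrix(fst, p("fst_matrix.tsv"), "population")
  readr::write_lines(fst_tree_newick(fst), p("fst_tree.nwk"))
  pca <- pca_samples(cohort$genotypes$dosage)
  write_tsv_matrix(pca$scores[, seq_len(min(4, ncol(pca$scores))),
                              drop = FALSE], p("pca_scores.tsv"), "individual")

  de <- clock("de", {
    kept <- filter_features(cohort$fpkm, cohort$length)
    disp <- estimate_dispersion(cohort$counts[kept, , drop = FALSE],
                                cohort$labels)
    de_anova(cohort$counts[kept, , drop = FALSE], cohort$labels,
             offsets[kept, , drop = FALSE], disp)
  })
  readr::write_tsv(de, p("de_results.tsv"))

  decomp <- clock("splicing", {
    prof <- splicing_profile(cohort$tensor)
    elig <- eligible_genes(cohort$tensor)
    pop_variance_decomposition(prof, cohort$labels, genes = elig,
                               n_perm = n_perm, seed = config$seed)
  })
  readr::write_tsv(decomp, p("splicing_decomposition.tsv"))

  ase <- clock("ase", {
    if (nrow(cohort$allele_counts)) {
      ase_table_test(cohort$allele_counts, seed = config$seed)
    } else {
      NULL
    }
  })
  if (!is.null(ase)) {
    readr::write_tsv(ase, p("ase_results.tsv"))
    enr <- eqtl_ase_enrichment(ase)
    jsonlite::write_json(list(ratio = enr$ratio, rates = enr$rates),
                         p("ase_eqtl_enrichment.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  regions <- clock("regions", {
    rg <- list_rbind(lapply(cohort$coverage, call_regions))
    classify_regions(rg, cohort$truth$segments)
  })
  write_bed(regions, p("regions.bed"))

  manifest <- list(
    tool = paste0("poptrans ", as.character(utils::packageVersion("poptrans"))),
    config_hash = config_hash(config),
    seed = config$seed,
    seeds = list(genotypes = substream_seed(config$seed, "genotypes"),
                 abundances = substream_seed(config$seed, "abundances"),
                 allele_counts = substream_seed(config$seed, "allele_counts"),
                 coverage = substream_seed(config$seed, "coverage")),
    input_checksums = file_checksums(in_dir),
    timings = timings
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(qc = qc, offsets = offsets, fst = fst, de = de,
                 decomp = decomp, ase = ase, regions = regions,
                 manifest = manifest))
}

# Deterministic hash of a configuration (order-independent FNV-style hash
# of the deparsed name=value pairs).
config_hash <- function(config) {
  s <- paste(sort(vapply(names(config), function(nm) {
    paste0(nm, "=", paste(format(config[[nm]], digits = 15), collapse = ","))
  }, character(1))), collapse = ";")
  fnv1a(utf8ToInt(s))
}

# 31-bit FNV-style rolling hash, kept exact in double arithmetic.
fnv1a <- function(bytes) {
  h <- 21661362
  for (k in bytes) h <- (h * 16777 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

file_checksums <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  out <- lapply(files, function(f) {
    fnv1a(as.integer(readBin(f, "raw", file.size(f))))
  })
  setNames(out, basename(files))
}
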
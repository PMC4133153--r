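#' Configuration for a simulated multi-population cohort
#'
#' Bundles every knob of the cohort generator. Defaults emulate the design
#' of a diverse-population LCL RNA-seq study after quality filtering:
#' 6 populations of 7 individuals, global differentiation around
#' F_ST = 0.1, negative-binomial gene counts with sample-specific GC and
#' length biases, Dirichlet splicing ratios, binomial allelic counts with
#' per-individual reference-mapping bias, and coverage tracks with planted
#' transcribed segments.
#'
#' @param n_populations Number of populations.
#' @param n_per_population Individuals per population (>= 2).
#' @param target_fst Balding-Nichols differentiation parameter in `[0,1)`.
#' @param n_sites Number of biallelic sites.
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Transcripts per gene (>= 1).
#' @param mean_expression_log2 Baseline mean of log2 expected counts.
#' @param baseline_sd SD of per-gene baselines on log2 scale.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi*mu^2`); 0 gives Poisson counts.
#' @param pop_expression_sd SD of per-gene per-population log2 shifts
#'   (differentially expressed genes only).
#' @param pop_splicing_shift SD of the log-scale perturbation applied to the
#'   Dirichlet mean of differentially spliced genes, per population.
#' @param dirichlet_concentration Concentration of individual splicing
#'   ratios around their population mean.
#' @param frac_de_genes,frac_ds_genes Fractions of genes with planted
#'   expression / splicing population effects.
#' @param eqtl_effect_log2 Expression effect per alternate-allele copy.
#' @param frac_eqtl_genes Fraction of genes with a planted cis eQTL.
#' @param gc_bias_amplitude,length_bias_amplitude SDs of the sample-specific
#'   coefficients on the standardized quadratic-GC and log-length bias
#'   curves (log2 scale).
#' @param reference_bias_mean,reference_bias_sd Mean and SD of per-individual
#'   reference-allele mapping bias (a fraction in (0,1)).
#' @param ase_depth_mean Mean sequencing depth at a heterozygous exonic site
#'   for a gene of average expression.
#' @param n_tracks,track_length,segments_per_track,segment_depth,
#'   coverage_noise_rate Coverage-track geometry: number of contigs, bases
#'   per contig, planted transcribed segments per contig, their minimum
#'   depth, and the per-base rate of isolated depth-1 noise.
#' @param total_mapped_reads Library size attached to coverage tracks.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   full configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 6, n_per_population = 7,
                       target_fst = 0.1, n_sites = 1000, n_genes = 200,
                       transcripts_per_gene = 3, mean_expression_log2 = 7,
                       baseline_sd = 1, dispersion = 0.1,
                       pop_expression_sd = 0.5, pop_splicing_shift = 0.5,
                       dirichlet_concentration = 50,
                       frac_de_genes = 0.1, frac_ds_genes = 0.1,
                       eqtl_effect_log2 = 1, frac_eqtl_genes = 0.2,
                       gc_bias_amplitude = 0.5, length_bias_amplitude = 0.2,
                       reference_bias_mean = 0.5, reference_bias_sd = 0.02,
                       ase_depth_mean = 60,
                       n_tracks = 3, track_length = 10000,
                       segments_per_track = 5, segment_depth = 10,
                       coverage_noise_rate = 1e-4,
                       total_mapped_reads = 2e7, seed = 1) {
  assert_fraction(target_fst, "target_fst", open_upper = TRUE)
  for (f in c(frac_de_genes, frac_ds_genes, frac_eqtl_genes)) {
    assert_fraction(f, "gene fractions")
  }
  assert_count(n_populations, "n_populations", 1L)
  assert_count(n_per_population, "n_per_population", 2L)
  assert_count(n_sites, "n_sites", 1L)
  assert_count(n_genes, "n_genes", 1L)
  if (transcripts_per_gene < 1) abort("transcripts_per_gene must be >= 1")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (reference_bias_mean <= 0 || reference_bias_mean >= 1) {
    abort("reference_bias_mean must lie in (0,1)")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are uniform on `[0.05, 0.95]`; each
#' population draws its frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (equal to the ancestral frequency when
#' `F = 0`), and individual dosages are `Binomial(2, pop frequency)`.
#'
#' @param config A [sim_config()].
#' @return List with `dosage` (individuals x sites integer matrix),
#'   `sites` (tibble: site, contig, pos, ref, alt), `labels`
#'   (tibble: individual, population) and `pop_freqs`
#'   (populations x sites matrix).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_populations; n_g <- config$n_per_population
  S <- config$n_sites; F <- config$target_fst
  pops <- sprintf("pop%d", seq_len(G))
  inds <- sprintf("ind%02d", seq_len(G * n_g))
  labels <- tibble(individual = inds, population = rep(pops, each = n_g))
  with_substream(config$seed, "genotypes", {
    p_anc <- runif(S, 0.05, 0.95)
    pf <- if (F > 0) {
      matrix(rbeta(G * S, rep(p_anc, each = G) * (1 - F) / F,
                   rep(1 - p_anc, each = G) * (1 - F) / F), nrow = G)
    } else {
      matrix(rep(p_anc, each = G), nrow = G)
    }
    dosage <- matrix(rbinom(G * n_g * S, 2L,
                            pf[rep(seq_len(G), each = n_g), ]),
                     nrow = G * n_g)
    dimnames(dosage) <- list(inds, sprintf("chr1:%d", seq_len(S) * 100L))
    rownames(pf) <- pops
    sites <- tibble(site = colnames(dosage), contig = "chr1",
                    pos = seq_len(S) * 100L, ref = "A", alt = "G")
    list(dosage = dosage, sites = sites, labels = labels, pop_freqs = pf)
  })
}

# Standardized bias curves shared by the generator and tests.
gc_bias_curve <- function(gc) {
  q <- (gc - 0.5)^2
  if (sd(q) == 0) return(q * 0)
  as.numeric(scale(q))
}
length_bias_curve <- function(len) {
  l <- log2(len)
  if (sd(l) == 0) return(l * 0)
  as.numeric(scale(l))
}

#' Simulate transcript abundances and gene counts
#'
#' Expected log2 expression per gene and individual is
#' `baseline + population shift (DE genes) + eqtl_effect_log2 * dosage
#' (eQTL genes) + sample GC coefficient * quadratic GC curve +
#' sample length coefficient * log-length curve`; counts are drawn
#' negative-binomially at that mean, and per-gene transcript abundances are
#' the gene's FPKM multiplied by Dirichlet splicing ratios whose mean is
#' population-shifted for differentially spliced genes. All planted
#' parameters are recorded in `truth`.
#'
#' @param config A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#' @return List with `tensor` (per-gene individuals x transcripts FPKM
#'   matrices), `counts` (genes x individuals), `fpkm` (genes x
#'   individuals), `gc`, `length`, and `truth`.
#' @export
simulate_transcript_abundances <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes$dosage); Gn <- config$n_genes
  Tn <- config$transcripts_per_gene
  if (Tn < 1) abort("transcripts_per_gene must be >= 1")
  pops <- unique(genotypes$labels$population)
  pop_of <- genotypes$labels$population
  genes <- sprintf("gene%04d", seq_len(Gn))
  inds <- rownames(genotypes$dosage)
  with_substream(config$seed, "abundances", {
    gc <- runif(Gn, 0.3, 0.7)
    len <- pmax(200L, as.integer(round(2^rnorm(Gn, log2(1500), 0.8))))
    names(gc) <- names(len) <- genes
    baseline <- rnorm(Gn, config$mean_expression_log2, config$baseline_sd)

    # planted population expression shifts (DE genes only), centered per gene
    n_de <- round(config$frac_de_genes * Gn)
    de_genes <- if (n_de > 0) sort(sample.int(Gn, n_de)) else integer(0)
    shifts <- matrix(0, Gn, length(pops), dimnames = list(genes, pops))
    if (n_de > 0 && config$pop_expression_sd > 0) {
      s <- matrix(rnorm(n_de * length(pops), 0, config$pop_expression_sd),
                  n_de, length(pops))
      shifts[de_genes, ] <- s - rowMeans(s)
    }

    # planted cis eQTLs: gene -> site mapping (sites assigned round-robin)
    site_gene <- setNames(genes[(seq_len(config$n_sites) - 1L) %% Gn + 1L],
                          genotypes$sites$site)
    n_eq <- round(config$frac_eqtl_genes * Gn)
    eq_genes <- if (n_eq > 0) sort(sample.int(Gn, n_eq)) else integer(0)
    eqtl <- tibble(gene = character(), site = character(),
                   effect_log2 = numeric(), ase_sign = numeric())
    eff <- rep(0, Gn)
    esnp <- rep(NA_character_, Gn)
    if (n_eq > 0) {
      for (gi in eq_genes) {
        cand <- names(site_gene)[site_gene == genes[gi]]
        if (!length(cand)) next
        esnp[gi] <- cand[sample.int(length(cand), 1)]
        eff[gi] <- config$eqtl_effect_log2
      }
      ok <- !is.na(esnp[eq_genes])
      eqtl <- tibble(gene = genes[eq_genes][ok], site = esnp[eq_genes][ok],
                     effect_log2 = eff[eq_genes][ok],
                     ase_sign = sample(c(-1, 1), sum(ok), replace = TRUE))
    }

    # sample-specific smooth biases
    qgc <- gc_bias_curve(gc); qlen <- length_bias_curve(len)
    gamma <- rnorm(n, 0, config$gc_bias_amplitude)
    lambda <- rnorm(n, 0, config$length_bias_amplitude)

    log2mu <- matrix(baseline, Gn, n) + shifts[, pop_of] +
      outer(qgc, gamma) + outer(qlen, lambda)
    if (nrow(eqtl) > 0) {
      for (k in seq_len(nrow(eqtl))) {
        gi <- match(eqtl$gene[k], genes)
        log2mu[gi, ] <- log2mu[gi, ] +
          eqtl$effect_log2[k] * genotypes$dosage[, eqtl$site[k]]
      }
    }
    mu <- 2^log2mu
    counts <- if (config$dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             Gn, n)
    } else {
      matrix(rpois(length(mu), mu), Gn, n)
    }
    dimnames(counts) <- list(genes, inds)
    lib <- pmax(colSums(counts), 1)
    fpkm <- counts / outer(len / 1e3, lib / 1e6)

    # splicing ratios: per-gene Dirichlet mean, population-shifted for DS
    n_ds <- round(config$frac_ds_genes * Gn)
    ds_genes <- if (n_ds > 0) sort(sample.int(Gn, n_ds)) else integer(0)
    base_mean <- matrix(rgamma(Gn * Tn, 2, 1), Gn, Tn)
    base_mean <- base_mean / rowSums(base_mean)
    splicing_means <- vector("list", Gn); names(splicing_means) <- genes
    tensor <- vector("list", Gn); names(tensor) <- genes
    for (gi in seq_len(Gn)) {
      mns <- matrix(base_mean[gi, ], length(pops), Tn, byrow = TRUE,
                    dimnames = list(pops, NULL))
      if (gi %in% ds_genes && config$pop_splicing_shift > 0 && Tn > 1) {
        pert <- matrix(rnorm(length(pops) * Tn, 0, config$pop_splicing_shift),
                       length(pops), Tn)
        mns <- mns * exp(pert)
        mns <- mns / rowSums(mns)
      }
      splicing_means[[gi]] <- mns
      conc <- config$dirichlet_concentration
      a <- conc * mns[pop_of, , drop = FALSE]
      r <- matrix(rgamma(n * Tn, shape = a), n, Tn)
      r <- r / pmax(rowSums(r), .Machine$double.xmin)
      if (Tn == 1) r[] <- 1
      m <- fpkm[gi, ] * r
      dimnames(m) <- list(inds, sprintf("%s.t%d", genes[gi], seq_len(Tn)))
      tensor[[gi]] <- m
    }

    truth <- list(pop_shifts = shifts, de_genes = genes[de_genes],
                  ds_genes = genes[ds_genes], eqtl = eqtl,
                  site_gene = site_gene, splicing_means = splicing_means,
                  baseline = setNames(baseline, genes),
                  gc_coef = setNames(gamma, inds),
                  length_coef = setNames(lambda, inds),
                  dispersion = config$dispersion)
    list(tensor = tensor, counts = counts, fpkm = fpkm, gc = gc,
         length = len, truth = truth)
  })
}

#' Simulate allelic read counts at heterozygous sites
#'
#' At each heterozygous site of each individual, total depth is Poisson with
#' mean `ase_depth_mean` scaled by the linked gene's relative expression,
#' and the reference count is binomial with success probability equal to the
#' individual's reference-mapping bias, shifted on the logit scale when the
#' individual is heterozygous for the gene's planted eQTL. Homozygous sites
#' and zero-depth draws are excluded.
#'
#' @param config A [sim_config()].
#' @param genotypes Output of [simulate_genotypes()].
#' @param abundances Output of [simulate_transcript_abundances()].
#' @return List with `table` (tibble: site, individual, gene, ref_count,
#'   alt_count, genotype, esnp_genotype) and `ref_bias` (named per-individual
#'   reference ratio, also copied into truth by [simulate_cohort()]).
#' @export
simulate_allele_counts <- function(config, genotypes, abundances) {
  stopifnot(inherits(config, "sim_config"))
  dos <- genotypes$dosage
  inds <- rownames(dos)
  site_gene <- abundances$truth$site_gene
  eqtl <- abundances$truth$eqtl
  fpkm <- abundances$fpkm
  rel <- fpkm / pmax(rowMeans(fpkm), .Machine$double.eps)
  with_substream(config$seed, "allele_counts", {
    r_i <- pmin(0.99, pmax(0.01,
      rnorm(length(inds), config$reference_bias_mean, config$reference_bias_sd)))
    names(r_i) <- inds
    het <- which(dos == 1L, arr.ind = TRUE)
    if (nrow(het) == 0 || config$ase_depth_mean <= 0) {
      return(list(table = tibble(site = character(), individual = character(),
                                 gene = character(), ref_count = integer(),
                                 alt_count = integer(), genotype = integer(),
                                 esnp_genotype = integer()),
                  ref_bias = r_i))
    }
    site_id <- colnames(dos)[het[, 2]]
    ind_id <- inds[het[, 1]]
    gene_id <- unname(site_gene[site_id])
    depth <- rpois(nrow(het),
                   config$ase_depth_mean * rel[cbind(gene_id, ind_id)])
    p <- r_i[ind_id]
    esnp_gt <- rep(NA_integer_, nrow(het))
    if (nrow(eqtl) > 0) {
      m <- match(gene_id, eqtl$gene)
      linked <- !is.na(m)
      if (any(linked)) {
        esnp_gt[linked] <- dos[cbind(ind_id[linked], eqtl$site[m[linked]])]
        shift_on <- linked & esnp_gt == 1L
        lo <- log(p / (1 - p))
        lo[shift_on] <- lo[shift_on] +
          eqtl$ase_sign[m[shift_on]] * eqtl$effect_log2[m[shift_on]] * log(2)
        p <- 1 / (1 + exp(-lo))
      }
    }
    ref <- rbinom(nrow(het), depth, p)
    keep <- depth > 0
    list(table = tibble(site = site_id, individual = ind_id, gene = gene_id,
                        ref_count = as.integer(ref),
                        alt_count = as.integer(depth - ref),
                        genotype = 1L,
                        esnp_genotype = esnp_gt)[keep, ],
         ref_bias = r_i)
  })
}

#' Simulate per-base coverage tracks with planted transcribed segments
#'
#' Background depth is zero apart from sparse isolated depth-1 noise bases;
#' planted segments get at least `segment_depth` at every base. Segment
#' coordinates are 0-based half-open and recorded as truth.
#'
#' @param config A [sim_config()].
#' @return List with `tracks` (list of coverage tracks: contig, depth,
#'   total_reads) and `segments` (tibble: contig, start, end, depth).
#' @export
simulate_coverage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "coverage", {
    tracks <- list(); segs <- list()
    for (k in seq_len(config$n_tracks)) {
      contig <- sprintf("contig%d", k)
      depth <- integer(config$track_length)
      if (config$coverage_noise_rate > 0) {
        noise <- runif(config$track_length) < config$coverage_noise_rate
        depth[noise] <- 1L
      }
      placed <- 0L; cursor <- 1L; tries <- 0L
      while (placed < config$segments_per_track && tries < 1000L) {
        tries <- tries + 1L
        len <- sample(50:400, 1)
        start <- cursor + sample(20:200, 1)
        if (start + len + 20 > config$track_length) break
        d <- config$segment_depth + rpois(1, 2)
        depth[(start + 1L):(start + len)] <-
          pmax(depth[(start + 1L):(start + len)], d)
        segs[[length(segs) + 1L]] <- tibble(contig = contig, start = start,
                                            end = start + len, depth = d)
        cursor <- start + len
        placed <- placed + 1L
      }
      tracks[[contig]] <- list(contig = contig, depth = depth,
                               total_reads = config$total_mapped_reads)
    }
    segs <- if (length(segs)) list_rbind(segs) else
      tibble(contig = character(), start = integer(), end = integer(),
             depth = numeric())
    list(tracks = tracks, segments = segs)
  })
}

#' Simulate a complete cohort with ground truth
#'
#' Runs the genotype, abundance, allelic-count and coverage generators on
#' named substreams of one seed (so enlarging one component does not
#' reshuffle the others) and assembles a `sim_cohort` whose `truth` element
#' records every planted parameter for downstream parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort` list: `config`, `genotypes`, `labels`, `tensor`,
#'   `counts`, `fpkm`, `gc`, `length`, `allele_counts`, `coverage`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  gt <- simulate_genotypes(config)
  ab <- simulate_transcript_abundances(config, gt)
  ac <- simulate_allele_counts(config, gt, ab)
  cv <- simulate_coverage(config)
  truth <- ab$truth
  truth$segments <- cv$segments
  truth$ref_bias <- ac$ref_bias
  structure(list(config = config, genotypes = gt[c("dosage", "sites")],
                 labels = gt$labels, tensor = ab$tensor, counts = ab$counts,
                 fpkm = ab$fpkm, gc = ab$gc, length = ab$length,
                 allele_counts = ac$table, coverage = cv$tracks,
                 truth = truth),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_vcf_lite(cohort$genotypes$dosage, cohort$genotypes$sites, p("genotypes.vcf"))
  write_tsv_matrix(cohort$counts, p("gene_counts.tsv"), "gene")
  write_tsv_matrix(cohort$fpkm, p("gene_fpkm.tsv"), "gene")
  write_abundance_long(cohort$tensor, p("transcript_fpkm.tsv"))
  readr::write_tsv(cohort$allele_counts, p("allele_counts.tsv"))
  write_coverage(cohort$coverage, p("coverage.bedgraph"))
  write_population_map(cohort$labels, p("populations.tsv"))
  write_bed(cohort$truth$segments, p("true_segments.bed"))
  readr::write_tsv(tibble(gene = names(cohort$gc), gc = cohort$gc,
                          length = cohort$length), p("gene_features.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
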
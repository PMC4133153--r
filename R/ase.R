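#' Per-individual overall reference ratio
#'
#' The reference-allele mapping bias of an individual, estimated as the
#' pooled reference fraction `sum(ref) / sum(ref + alt)` over that
#' individual's heterozygous sites with depth at least `min_depth`. This
#' ratio is the compensated null of the allelic-imbalance binomial test.
#'
#' @param table Allele-count tibble with columns `individual`, `ref_count`,
#'   `alt_count` (heterozygous sites only).
#' @param min_depth Minimum site depth to enter the pool (default 1).
#' @return Tibble: `individual`, `r`, `n_sites`, `total_reads`.
#' @export
reference_ratio <- function(table, min_depth = 1) {
  tbl <- table[table$ref_count + table$alt_count >= min_depth, ]
  if (!nrow(tbl)) abort("no qualifying heterozygous sites: reference ratio undefined")
  out <- tbl |>
    group_by(.data$individual) |>
    summarise(r = sum(.data$ref_count) / sum(.data$ref_count + .data$alt_count),
              n_sites = n(),
              total_reads = sum(.data$ref_count + .data$alt_count),
              .groups = "drop")
  out
}

# Exact two-sided binomial p-value of x successes in n trials at null p0.
# "minlike": sum of outcome probabilities no larger than the observed one
# (the stats::binom.test convention; calibrated at the fixed downsampling
# depth). "doubled": equal-tail doubling min(1, 2*min(P(X<=x), P(X>=x))).
binom_p2 <- function(x, n, p0, method = c("minlike", "doubled")) {
  method <- match.arg(method)
  if (p0 <= 0 || p0 >= 1) abort("null reference ratio must lie in (0,1)")
  if (method == "doubled") {
    lo <- pbinom(x, n, p0)
    hi <- pbinom(x - 1, n, p0, lower.tail = FALSE)
    return(min(1, 2 * min(lo, hi)))
  }
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Allelic-imbalance test at one heterozygous site
#'
#' Downsamples the site's reads to `n_down` (hypergeometric, i.e. picking
#' physical reads without replacement; the identity when depth equals
#' `n_down`), then tests the downsampled reference count against the
#' individual's overall reference ratio `r_i` with an exact two-sided
#' binomial test. Sites with depth below `n_down` should be excluded
#' upstream.
#'
#' @param ref,alt Reference/alternate read counts (scalars).
#' @param r Null reference ratio in (0,1), from [reference_ratio()].
#' @param n_down Downsampling depth (default 30).
#' @param alpha Significance level (default 0.05).
#' @param method Two-sided p-value convention, `"minlike"` (default) or
#'   `"doubled"`; see Details of [binom_p2] in the source.
#' @param downsample If `FALSE`, test the full-depth counts instead.
#' @param seed Integer seed for the downsampling draw.
#' @return Tibble row: `ref_down`, `n_down`, `p`, `significant`.
#' @export
ase_test <- function(ref, alt, r, n_down = 30, alpha = 0.05,
                     method = c("minlike", "doubled"), downsample = TRUE,
                     seed = 1) {
  method <- match.arg(method)
  depth <- ref + alt
  if (depth < n_down) abort("site depth below the downsampling threshold")
  if (downsample) {
    x <- if (depth == n_down) ref else
      with_substream(seed, "ase_downsample", rhyper(1, ref, alt, n_down))
    n <- n_down
  } else {
    x <- ref; n <- depth
  }
  p <- binom_p2(x, n, r, method)
  tibble(ref_down = x, n_down = n, p = p, significant = p < alpha)
}

#' Allelic-imbalance tests for a whole cohort table
#'
#' Vectorized driver: computes per-individual reference ratios, keeps
#' sites with depth at least `n_down`, downsamples and tests each.
#'
#' @param table Allele-count tibble (`site`, `individual`, `ref_count`,
#'   `alt_count`, optionally `gene`, `esnp_genotype`).
#' @param ratios Optional precomputed [reference_ratio()] tibble; when
#'   `compensate = FALSE` a flat null of 0.5 is used instead.
#' @param compensate Use per-individual reference ratios as the null
#'   (default) or a fixed 0.5.
#' @inheritParams ase_test
#' @return A `pt_ase` tibble: the qualifying rows of `table` plus
#'   `r_null`, `ref_down`, `n_down`, `p`, `significant`.
#' @export
ase_table_test <- function(table, ratios = NULL, n_down = 30, alpha = 0.05,
                           method = c("minlike", "doubled"),
                           downsample = TRUE, compensate = TRUE, seed = 1) {
  method <- match.arg(method)
  if (compensate) {
    if (is.null(ratios)) ratios <- reference_ratio(table)
    rmap <- setNames(ratios$r, ratios$individual)
  }
  tbl <- table[table$ref_count + table$alt_count >= n_down, ]
  n_row <- nrow(tbl)
  r0 <- if (compensate) unname(rmap[tbl$individual]) else rep(0.5, n_row)
  depth <- tbl$ref_count + tbl$alt_count
  x <- with_substream(seed, "ase_downsample", {
    ifelse(depth == n_down, tbl$ref_count,
           rhyper(n_row, tbl$ref_count, tbl$alt_count, n_down))
  })
  if (downsample) {
    n <- rep(n_down, n_row)
  } else {
    x <- tbl$ref_count; n <- depth
  }
  pv <- vapply(seq_len(n_row), function(i) binom_p2(x[i], n[i], r0[i], method),
               numeric(1))
  out <- dplyr::bind_cols(tbl, tibble(r_null = r0, ref_down = x,
                                      n_down = n, p = pv,
                                      significant = pv < alpha))
  class(out) <- c("pt_ase", class(out))
  out
}

#' Normalized ASE sharing for a set of individuals
#'
#' `#sites significant in every individual of S` divided by
#' `#sites heterozygous with >= n_down reads in every individual of S`
#' (the normalization removes differences in heterozygosity and coverage);
#' `NA` when the denominator is zero.
#'
#' @param results A [ase_table_test()] result.
#' @param het_sites Allele-count tibble of heterozygous sites (tested or
#'   not); defaults to the rows of `results`.
#' @param individuals Character vector `S`, at least 2 individuals.
#' @param n_down Depth threshold used for the denominator.
#' @return Sharing fraction in `[0, 1]`, or `NA`.
#' @export
ase_sharing <- function(results, het_sites = NULL, individuals, n_down = 30) {
  if (length(individuals) < 2) abort("sharing needs at least 2 individuals")
  if (is.null(het_sites)) het_sites <- results
  het_sites <- het_sites[het_sites$ref_count + het_sites$alt_count >= n_down, ]
  sig_sets <- lapply(individuals, function(i) {
    results$site[results$individual == i & results$significant]
  })
  het_sets <- lapply(individuals, function(i) {
    het_sites$site[het_sites$individual == i]
  })
  denom <- length(Reduce(intersect, het_sets))
  if (denom == 0) return(NA_real_)
  length(Reduce(intersect, sig_sets)) / denom
}

#' Pairwise ASE sharing matrix with clustering
#'
#' All pairwise normalized sharing fractions, average-linkage clustering on
#' `1 - sharing` (NA pairs excluded with a warning), and the mean
#' within- versus between-population sharing.
#'
#' @inheritParams ase_sharing
#' @param labels Population labels.
#' @return A `sharing_result` list: `matrix` (unit diagonal), `order`
#'   (clustering leaf order), `within_mean`, `between_mean`.
#' @export
sharing_matrix <- function(results, het_sites = NULL, labels, n_down = 30) {
  inds <- sort(unique(results$individual))
  if (length(inds) < 3) abort("need at least 3 individuals")
  lab <- as_population_map(labels, inds)
  m <- matrix(1, length(inds), length(inds), dimnames = list(inds, inds))
  for (i in seq_along(inds)[-length(inds)]) {
    for (j in (i + 1):length(inds)) {
      m[i, j] <- m[j, i] <- ase_sharing(results, het_sites,
                                        c(inds[i], inds[j]), n_down)
    }
  }
  same <- outer(lab, lab, `==`)
  ut <- upper.tri(m)
  within_mean <- mean(m[ut & same], na.rm = TRUE)
  between_mean <- mean(m[ut & !same], na.rm = TRUE)
  d <- 1 - m
  if (anyNA(d)) {
    warn("NA sharing pairs imputed with the maximum distance for clustering")
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  ord <- hclust(as.dist(d), method = "average")$order
  structure(list(matrix = m, order = inds[ord], within_mean = within_mean,
                 between_mean = between_mean), class = "sharing_result")
}

#' ASE enrichment in heterozygous versus homozygous eQTLs
#'
#' The ratio `(significant/tested among heterozygous-eSNP carriers) /
#' (significant/tested among homozygous-eSNP carriers)`; 1 means no
#' enrichment. Also returns the two significant-versus-measured rates.
#'
#' @param results A [ase_table_test()] result with an `esnp_genotype`
#'   column (0/1/2 dosage at the linked eSNP; `NA` rows ignored).
#' @param alpha Significance level defining an ASE event.
#' @return List with `ratio`, `rates` (tibble: esnp_class, tested,
#'   significant, rate).
#' @export
eqtl_ase_enrichment <- function(results, alpha = 0.05) {
  tbl <- results[!is.na(results$esnp_genotype), ]
  het <- tbl[tbl$esnp_genotype == 1L, ]
  hom <- tbl[tbl$esnp_genotype != 1L, ]
  rates <- tibble(
    esnp_class = c("het", "hom"),
    tested = c(nrow(het), nrow(hom)),
    significant = c(sum(het$p < alpha), sum(hom$p < alpha))
  )
  rates$rate <- ifelse(rates$tested > 0, rates$significant / rates$tested, NA)
  ratio <- if (any(rates$tested == 0) || rates$rate[2] == 0) NA_real_ else
    rates$rate[1] / rates$rate[2]
  list(ratio = ratio, rates = rates)
}

#' Replication of previously discovered eQTLs in a cohort
#'
#' For each eQTL (eSNP, gene), computes the Spearman rank correlation
#' between eSNP dosage and gene expression across individuals, squared
#' (rho^2, akin to variance explained), with the rank-correlation test
#' p-value and the cohort minor allele frequency. Cross-study summaries are
#' Pearson correlations of the rho^2 vectors and of the `-log10 p` vectors,
#' overall and within MAF bins.
#'
#' @param dosage Individuals x sites genotype matrix.
#' @param expression Genes x individuals expression matrix (FPKM).
#' @param eqtls Tibble: `site`, `gene`, `study_rho2`, `study_p`,
#'   `study_maf`.
#' @param n_bins Number of equal-width MAF bins per study (default 5).
#' @return A `pt_eqtl` list: `records` (filled tibble with `rho2`, `p`,
#'   `maf`, `excluded`), `summary` (overall correlations) and `maf_bins`
#'   (per-bin-pair correlations of rho^2).
#' @export
eqtl_replication <- function(dosage, expression, eqtls, n_bins = 5) {
  recs <- lapply(seq_len(nrow(eqtls)), function(k) {
    s <- eqtls$site[k]; g <- eqtls$gene[k]
    if (!(s %in% colnames(dosage)) || !(g %in% rownames(expression))) {
      return(dplyr::bind_cols(eqtls[k, ],
                              tibble(rho2 = NA, p = NA, maf = NA, excluded = TRUE)))
    }
    d <- dosage[, s]; e <- expression[g, rownames(dosage)]
    af <- mean(d, na.rm = TRUE) / 2
    maf <- min(af, 1 - af)
    if (sd(d, na.rm = TRUE) == 0) {
      return(dplyr::bind_cols(eqtls[k, ],
                              tibble(rho2 = NA, p = NA, maf = maf, excluded = TRUE)))
    }
    ct <- suppressWarnings(cor.test(d, e, method = "spearman"))
    dplyr::bind_cols(eqtls[k, ],
                     tibble(rho2 = unname(ct$estimate)^2, p = ct$p.value,
                            maf = maf, excluded = FALSE))
  })
  records <- list_rbind(recs)
  ok <- !records$excluded & !is.na(records$study_rho2)
  safe_cor <- function(x, y) {
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }
  summary <- tibble(
    n = sum(ok),
    r_rho2 = safe_cor(records$rho2[ok], records$study_rho2[ok]),
    r_log10p = safe_cor(-log10(pmax(records$p[ok], 1e-300)),
                        -log10(pmax(records$study_p[ok], 1e-300)))
  )
  brk <- seq(0, 0.5, length.out = n_bins + 1)
  bin <- function(x) cut(x, brk, include.lowest = TRUE, labels = FALSE)
  rb <- records[ok, ]
  rb$bin_study <- bin(rb$study_maf); rb$bin_cohort <- bin(rb$maf)
  maf_bins <- rb |>
    group_by(.data$bin_study, .data$bin_cohort) |>
    summarise(n = n(),
              r_rho2 = safe_cor(.data$rho2, .data$study_rho2),
              mean_rho2 = mean(.data$rho2),
              .groups = "drop")
  structure(list(records = records, summary = summary, maf_bins = maf_bins),
            class = "pt_eqtl")
}
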
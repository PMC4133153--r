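#' Splicing profile of a cohort
#'
#' Adds a pseudocount to every transcript abundance (default `1/T` per
#' transcript for a gene with `T` transcripts, so a single-transcript gene
#' gains exactly one unit), then splits each gene's abundance into an
#' expression total `e_i` (row sum) and splicing ratios
#' `s_ij = t'_ij / e_i`. By construction the identity
#' `log2 t'_ij = log2 e_i + log2 s_ij` holds exactly, which the
#' expression-versus-splicing decomposition relies on.
#'
#' @param tensor Named list: per gene an individuals x transcripts matrix
#'   of non-negative FPKM-scale abundances.
#' @param pseudocount Pseudocount per transcript; default `1/T`.
#' @return A `splicing_profile`: per gene a list with `e` (per-individual
#'   expression), `s` (ratio matrix, rows summing to 1), `t` (the
#'   pseudocounted abundances) and `pseudocount`.
#' @export
splicing_profile <- function(tensor, pseudocount = NULL) {
  prof <- imap(tensor, function(m, g) {
    Tn <- ncol(m)
    c0 <- if (is.null(pseudocount)) 1 / Tn else pseudocount
    if (c0 <= 0) abort("pseudocount must be positive")
    tp <- m + c0
    e <- rowSums(tp)
    list(e = e, s = tp / e, t = tp, pseudocount = c0)
  })
  structure(prof, class = "splicing_profile")
}

#' Hellinger distance between two probability vectors
#'
#' `H = sqrt(1 - sum(sqrt(p * q)))`, equivalently
#' `(1/sqrt(2)) * ||sqrt(p) - sqrt(q)||`, bounded in `[0, 1]`. Inputs must
#' sum to 1 within `1e-6`.
#'
#' @param p,q Non-negative vectors of equal length summing to 1.
#' @return The Hellinger distance.
#' @export
hellinger <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) abort("ratio vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("ratio vectors must sum to 1 (|sum - 1| <= 1e-6)")
  }
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}

# All pairwise Hellinger distances between rows of a ratio matrix.
hellinger_matrix <- function(s) {
  rs <- sqrt(s)
  g <- tcrossprod(rs)
  h <- sqrt(pmax(1 - g, 0))
  diag(h) <- 0
  h
}

#' Per-population expression and splicing variability
#'
#' Per population: the coefficient of variation of expression (sample
#' standard deviation over mean of `e`) and the mean Hellinger distance
#' F-bar of each individual's splicing ratios to the population centroid
#' (arithmetic mean of ratio vectors, renormalized; `centroid = "sqrt"`
#' averages in square-root space instead).
#'
#' @param profile A [splicing_profile()].
#' @param labels Population labels.
#' @param centroid Centroid convention, `"arithmetic"` or `"sqrt"`.
#' @return Tibble: `gene`, `population`, `cv`, `fbar`.
#' @export
variability_summary <- function(profile, labels,
                                centroid = c("arithmetic", "sqrt")) {
  centroid <- match.arg(centroid)
  first <- profile[[1]]
  lab <- as_population_map(labels, names(first$e))
  rows <- imap(profile, function(pr, g) {
    out <- lapply(unique(lab), function(pp) {
      idx <- which(lab == pp)
      if (length(idx) < 2) abort("need >= 2 individuals per population")
      e <- pr$e[idx]
      s <- pr$s[idx, , drop = FALSE]
      ctr <- if (centroid == "arithmetic") colMeans(s) else colMeans(sqrt(s))^2
      ctr <- ctr / sum(ctr)
      tibble(gene = g, population = pp, cv = sd(e) / mean(e),
             fbar = mean(vapply(seq_along(idx),
                                function(i) hellinger(s[i, ], ctr),
                                numeric(1))))
    })
    list_rbind(out)
  })
  list_rbind(rows)
}

# Distance-based (PERMANOVA) sums of squares from a squared-distance
# matrix: SST = (1/n) sum_{i<k} d2, SSW = sum_g (1/n_g) sum_{i<k in g} d2.
permanova_ss <- function(d2, lab) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (pp in unique(lab)) {
    idx <- which(lab == pp)
    dd <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(dd[upper.tri(dd)]) / length(idx)
  }
  c(sst = sst, ssw = ssw)
}

#' Fraction of splicing-profile variation explained by population
#'
#' Builds the individuals x transcripts matrix of `log2 t'` for a gene,
#' takes pairwise squared Euclidean distances, and computes the
#' distance-based (PERMANOVA) decomposition `R^2 = 1 - SSW / SST`. The
#' empirical p-value permutes population labels with the add-one rule.
#' When SST is zero, `R^2` is defined as 0 with `p = 1`. A bias-adjusted
#' value `r2_adj = 1 - (1 - R^2) (n - 1) / (n - G)` is also returned: the
#' plain `R^2` has null expectation `(G - 1) / (n - 1)` and the adjusted
#' form centers at zero under label exchangeability.
#'
#' Genes are eligible when at least two transcripts have raw FPKM > 0 in
#' every individual (see [eligible_genes()]); apply that filter upstream.
#'
#' @param entry One gene's entry of a [splicing_profile()] (a list with
#'   `t`), or directly a numeric matrix of `log2 t'` values.
#' @param labels Population labels.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed.
#' @return List with `r2`, `r2_adj`, `p`, `n_perm`.
#' @export
pop_variance_explained <- function(entry, labels, n_perm = 100, seed = 1) {
  L <- if (is.matrix(entry)) entry else log2(entry$t)
  lab <- as_population_map(labels, rownames(L))
  sizes <- table(lab)
  if (any(sizes < 2)) {
    warn("populations with a single individual excluded")
    keep <- lab %in% names(sizes)[sizes >= 2]
    L <- L[keep, , drop = FALSE]; lab <- lab[keep]
  }
  n <- nrow(L); G <- length(unique(lab))
  d2 <- as.matrix(dist(L))^2
  ss <- permanova_ss(d2, lab)
  if (ss["sst"] <= 0) {
    return(list(r2 = 0, r2_adj = 0, p = 1, n_perm = n_perm))
  }
  r2 <- unname(1 - ss["ssw"] / ss["sst"])
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - G)
  p <- with_substream(seed, "pop_variance_explained", {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      ssp <- permanova_ss(d2, sample(lab))
      if (1 - ssp["ssw"] / ssp["sst"] >= r2 - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  list(r2 = r2, r2_adj = r2_adj, p = p, n_perm = n_perm)
}

#' Eligible genes for the variance decomposition
#'
#' A gene qualifies when at least `min_transcripts` of its transcripts have
#' raw abundance > 0 in every individual.
#'
#' @param tensor Per-gene abundance matrices (raw, before pseudocount).
#' @param min_transcripts Minimum number of everywhere-expressed
#'   transcripts (default 2).
#' @return Character vector of gene ids.
#' @export
eligible_genes <- function(tensor, min_transcripts = 2) {
  ok <- vapply(tensor, function(m) {
    sum(apply(m > 0, 2, all)) >= min_transcripts
  }, logical(1))
  names(tensor)[ok]
}

#' Share of population-specific variation due to expression
#'
#' Uses the exact identity `log2 t' = log2 e + log2 s` to split the
#' between-population sum of squares of the log abundances into an
#' expression part (the classical weighted between-group SS of `log2 e`,
#' scaled by the transcript count `T`) and a splicing part (the sum over
#' transcripts of between-group SS of `log2 s`); the cross term is
#' discarded. `share = SSB_E_scaled / (SSB_E_scaled + SSB_S)`; when both
#' terms are zero the share is undefined (`NA`).
#'
#' @inheritParams pop_variance_explained
#' @return The expression share in `[0, 1]`, or `NA`.
#' @export
expression_splicing_share <- function(entry, labels) {
  e <- entry$e; s <- entry$s
  lab <- as_population_map(labels, names(e))
  Tn <- ncol(s)
  between_ss <- function(x) {
    gm <- mean(x)
    sum(vapply(split(x, lab), function(v) length(v) * (mean(v) - gm)^2,
               numeric(1)))
  }
  ssb_e <- Tn * between_ss(log2(e))
  ssb_s <- sum(vapply(seq_len(Tn), function(j) between_ss(log2(s[, j])),
                      numeric(1)))
  if (ssb_e + ssb_s == 0) return(NA_real_)
  ssb_e / (ssb_e + ssb_s)
}

#' Population variance decomposition across genes
#'
#' Convenience wrapper running [pop_variance_explained()] and
#' [expression_splicing_share()] over every (eligible) gene of a profile.
#'
#' @param profile A [splicing_profile()].
#' @param labels Population labels.
#' @param genes Genes to analyze (default all in the profile).
#' @param n_perm,seed Permutation settings per gene.
#' @return A `pt_decomp` tibble: `gene`, `r2`, `r2_adj`, `p`,
#'   `share_expression`, `n_perm`, `analyzed`.
#' @export
pop_variance_decomposition <- function(profile, labels, genes = NULL,
                                       n_perm = 100, seed = 1) {
  genes <- genes %||% names(profile)
  rows <- lapply(genes, function(g) {
    pv <- pop_variance_explained(profile[[g]], labels, n_perm,
                                 substream_seed(seed, g))
    tibble(gene = g, r2 = pv$r2, r2_adj = pv$r2_adj, p = pv$p,
           share_expression = expression_splicing_share(profile[[g]], labels),
           n_perm = n_perm, analyzed = TRUE)
  })
  out <- list_rbind(rows)
  class(out) <- c("pt_decomp", class(out))
  out
}

#' Distance-based differential splicing between two populations
#'
#' Anderson-style permutational test: Hellinger distances between
#' individuals' splicing ratio vectors give, via the same sums-of-squares
#' identities as [pop_variance_explained()], a pseudo-F statistic
#' `(SSB / (a - 1)) / (SSW / (n - a))` with `a = 2`; significance comes
#' from permuting population labels (add-one rule), or from exhaustive
#' enumeration of all label assignments when `exhaustive = TRUE`.
#'
#' @param profile A [splicing_profile()].
#' @param labels Labels restricted to two populations, each with >= 2
#'   individuals.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all distinct label assignments instead of
#'   sampling (p = proportion of assignments, identity included, with
#'   pseudo-F at least the observed).
#' @return Tibble: `gene`, `pseudo_f`, `p`.
#' @export
differential_splicing <- function(profile, labels, n_perm = 999, seed = 1,
                                  exhaustive = FALSE) {
  first <- profile[[1]]
  lab <- as_population_map(labels, names(first$e))
  pops <- unique(lab)
  if (length(pops) != 2) abort("differential splicing compares exactly two populations")
  if (any(table(lab) < 2)) abort("each population needs >= 2 individuals")
  n <- length(lab); a <- 2
  stat <- function(d2, ll) {
    ss <- permanova_ss(d2, ll)
    ssb <- ss["sst"] - ss["ssw"]
    if (ss["sst"] <= 0) return(0)
    unname((ssb / (a - 1)) / (ss["ssw"] / (n - a)))
  }
  perms <- if (exhaustive) {
    idx <- utils::combn(n, sum(lab == pops[1]))
    lapply(seq_len(ncol(idx)), function(k) {
      ll <- rep(pops[2], n); ll[idx[, k]] <- pops[1]; ll
    })
  } else {
    NULL
  }
  rows <- imap(profile, function(pr, g) {
    d2 <- hellinger_matrix(pr$s)^2
    f_obs <- stat(d2, lab)
    if (f_obs == 0 && all(d2 == 0)) return(tibble(gene = g, pseudo_f = 0, p = 1))
    if (exhaustive) {
      fs <- vapply(perms, function(ll) stat(d2, ll), numeric(1))
      p <- mean(fs >= f_obs - 1e-12)
    } else {
      p <- with_substream(substream_seed(seed, g), "diffsplice", {
        hits <- 0L
        for (k in seq_len(n_perm)) {
          if (stat(d2, sample(lab)) >= f_obs - 1e-12) hits <- hits + 1L
        }
        (1 + hits) / (1 + n_perm)
      })
    }
    tibble(gene = g, pseudo_f = f_obs, p = p)
  })
  list_rbind(rows)
}

#' Cross-population variability correlations and Mantel test
#'
#' For every population pair, the Spearman correlation of per-gene `cv`
#' (and `fbar`) vectors; `1 - correlation` defines a distance matrix that
#' is compared to an F_ST matrix with [mantel_test()].
#'
#' @param summary A [variability_summary()] tibble.
#' @param fst Population x population F_ST matrix (for the Mantel test;
#'   optional).
#' @param n_perm,seed Mantel permutation settings.
#' @return List with `cv_cor` and `fbar_cor` (population matrices), and
#'   when `fst` is given `mantel_cv`, `mantel_fbar` (rho, p).
#' @export
variability_correlation <- function(summary, fst = NULL, n_perm = 1000,
                                    seed = 1) {
  pops <- unique(summary$population)
  one <- function(col) {
    wide <- tidyr::pivot_wider(summary[, c("gene", "population", col)],
                               names_from = "population", values_from = all_of(col))
    m <- cor(as.matrix(wide[, pops]), method = "spearman")
    m
  }
  cv_cor <- one("cv"); fbar_cor <- one("fbar")
  out <- list(cv_cor = cv_cor, fbar_cor = fbar_cor)
  if (!is.null(fst)) {
    fst <- as.matrix(fst)[pops, pops]
    dcv <- 1 - cv_cor; diag(dcv) <- 0
    dfb <- 1 - fbar_cor; diag(dfb) <- 0
    out$mantel_cv <- mantel_test(dcv, fst, n_perm, seed)
    out$mantel_fbar <- mantel_test(dfb, fst, n_perm, seed)
  }
  out
}
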
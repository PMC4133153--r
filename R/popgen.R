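#' Weir-Cockerham F_ST
#'
#' Variance-components estimator of F_ST (Weir & Cockerham 1984, theta-hat)
#' from biallelic dosages. Per site, the among-population (a), among
#' individual within population (b) and within-individual (c) components
#' are computed from allele frequencies and observed heterozygote
#' frequencies; the multi-site estimate combines them as a ratio of sums
#' (`sum(a) / sum(a + b + c)`), the "weighted" convention of vcftools.
#' Sites monomorphic in the analyzed populations (zero denominator) are
#' skipped, and missing dosages are dropped site-wise.
#'
#' @param dosage Individuals x sites matrix with entries 0/1/2 or `NA`.
#' @param labels Population labels: a tibble (individual, population) or a
#'   named vector.
#' @param pops Optional subset of populations (e.g. a pair); default all.
#' @param by_site If `TRUE`, also return the per-site components.
#' @return The multi-site F_ST estimate, or if `by_site` a list with
#'   `fst` and a tibble of per-site `a`, `b`, `c`.
#' @export
weir_cockerham_fst <- function(dosage, labels, pops = NULL, by_site = FALSE) {
  lab <- as_population_map(labels, rownames(dosage))
  if (!is.null(pops)) {
    keep <- lab %in% pops
    dosage <- dosage[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  pops <- unique(lab)
  r <- length(pops)
  if (r < 2) abort("need at least two populations")
  a <- b <- cc <- numeric(ncol(dosage))
  for (s in seq_len(ncol(dosage))) {
    d <- dosage[, s]
    ok <- !is.na(d)
    ni <- tapply(ok, lab, sum)
    if (any(ni < 2) || sum(ni > 0) < r) { a[s] <- NA; next }
    ni <- as.numeric(ni[pops])
    pi_ <- as.numeric(tapply(d[ok], lab[ok], sum)[pops]) / (2 * ni)
    hi <- as.numeric(tapply(d[ok] == 1, lab[ok], mean)[pops])
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) {
      if (s2 == 0) { a[s] <- NA; next }  # monomorphic in all
    }
    a[s] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[s] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[s] <- hbar / 2
  }
  keep <- !is.na(a) & (a + b + cc) != 0
  if (!any(keep)) abort("no informative sites: F_ST undefined")
  fst <- sum(a[keep]) / sum(a[keep] + b[keep] + cc[keep])
  if (by_site) {
    list(fst = fst, components = tibble(site = colnames(dosage) %||%
                                          as.character(seq_along(a)),
                                        a = a, b = b, c = cc)[keep, ])
  } else {
    fst
  }
}

#' Pairwise F_ST matrix across populations
#'
#' @inheritParams weir_cockerham_fst
#' @return Symmetric populations x populations matrix with zero diagonal;
#'   negative pairwise estimates are reported as computed.
#' @export
pairwise_fst <- function(dosage, labels) {
  lab <- as_population_map(labels, rownames(dosage))
  pops <- unique(lab)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      m[i, j] <- m[j, i] <- weir_cockerham_fst(dosage, lab,
                                               pops = pops[c(i, j)])
    }
  }
  m
}

#' Hierarchical-clustering tree of an F_ST matrix
#'
#' Average-linkage (UPGMA by default) agglomeration of the F_ST distance
#' matrix. Negative distances are clamped to zero with a warning before
#' clustering.
#'
#' @param fst Symmetric population x population F_ST matrix.
#' @param method Linkage: `"average"` (UPGMA), `"complete"` or `"single"`.
#' @return An [ape::as.phylo()] tree; serialize with [fst_tree_newick()].
#' @export
fst_tree <- function(fst, method = c("average", "complete", "single")) {
  method <- match.arg(method)
  if (any(fst < 0)) {
    warn("negative F_ST distances clamped to 0 for tree building")
    fst[fst < 0] <- 0
  }
  hc <- hclust(as.dist(fst), method = method)
  ape::as.phylo(hc)
}

#' @param ... Passed to [fst_tree()].
#' @return `fst_tree_newick`: the tree as a newick string.
#' @rdname fst_tree
#' @export
fst_tree_newick <- function(fst, ...) {
  ape::write.tree(fst_tree(fst, ...))
}

#' Principal component analysis with a fixed sign convention
#'
#' Thin wrapper around the singular value decomposition of the centered
#' (optionally scaled) data matrix. Components are ordered by variance and
#' each is oriented so that its largest-magnitude loading is positive. A
#' constant matrix yields zero components.
#'
#' @param mat Samples x variables numeric matrix.
#' @param center,scale Centering/scaling flags.
#' @return A `pt_pca` list: `scores` (samples x components), `loadings`
#'   (variables x components, orthonormal) and `var_explained`.
#' @export
pca_samples <- function(mat, center = TRUE, scale = FALSE) {
  if (nrow(mat) < 2) abort("need at least 2 samples")
  sdv <- apply(mat, 2, sd)
  if (all(sdv == 0)) {
    return(structure(list(scores = matrix(0, nrow(mat), 0),
                          loadings = matrix(0, ncol(mat), 0),
                          var_explained = numeric(0)), class = "pt_pca"))
  }
  if (scale) mat <- mat[, sdv > 0, drop = FALSE]
  pc <- prcomp(mat, center = center, scale. = scale)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ve), class = "pt_pca")
}

#' Mantel test between two distance matrices
#'
#' Spearman correlation of the upper triangles, with an empirical p-value
#' from jointly permuting the rows and columns of the second matrix,
#' using the add-one rule
#' `p = (1 + #(rho_perm >= rho_obs)) / (1 + n_perm)`.
#'
#' @param d1,d2 Symmetric distance matrices over the same labels, zero
#'   diagonal.
#' @param n_perm Number of Monte Carlo permutations.
#' @param seed Integer seed.
#' @return List with `rho` and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 3) abort("Mantel test needs matrices of size >= 3")
  stopifnot(all(dim(d2) == n), isTRUE(all.equal(d1, t(d1))),
            isTRUE(all.equal(d2, t(d2))))
  rho_obs <- cor(upper_tri_vec(d1), upper_tri_vec(d2), method = "spearman")
  with_substream(seed, "mantel", {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      idx <- sample.int(n)
      rho_p <- cor(upper_tri_vec(d1), upper_tri_vec(d2[idx, idx]),
                   method = "spearman")
      if (rho_p >= rho_obs - 1e-12) hits <- hits + 1L
    }
    list(rho = rho_obs, p = (1 + hits) / (1 + n_perm))
  })
}
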
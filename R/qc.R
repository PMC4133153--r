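#' Optimal-power-space (OPS) transform
#'
#' Elementwise power transform `x^alpha` of non-negative expression values,
#' used so that low- and high-expression features contribute comparably to
#' correlation measures. The default fourth-root is the standard variance
#' stabilizer for overdispersed counts; [choose_ops_alpha()] offers a grid
#' search minimizing the residual mean-variance dependence.
#'
#' @param x Non-negative numeric vector (FPKM or counts).
#' @param alpha Exponent in `(0, 1]`.
#' @return `x^alpha`.
#' @export
ops_transform <- function(x, alpha = 0.25) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("`alpha` must be a positive scalar")
  }
  if (any(x < 0, na.rm = TRUE)) abort("OPS transform requires non-negative values")
  x^alpha
}

#' @param mat Feature x sample matrix of non-negative values.
#' @param alphas Candidate exponents.
#' @return `choose_ops_alpha`: the exponent whose transformed per-feature
#'   means and variances are least correlated (absolute Pearson).
#' @rdname ops_transform
#' @export
choose_ops_alpha <- function(mat, alphas = seq(0.1, 1, by = 0.05)) {
  score <- vapply(alphas, function(a) {
    tx <- ops_transform(mat, a)
    m <- rowMeans(tx); v <- apply(tx, 1, var)
    keep <- v > 0 & is.finite(m)
    if (sum(keep) < 3) return(Inf)
    abs(cor(m[keep], v[keep]))
  }, numeric(1))
  alphas[which.min(score)]
}

#' Pearson correlation between replicate expression profiles
#'
#' Restricts to features expressed (value > `expressed_threshold`) in at
#' least one of the two replicates, OPS-transforms both, and returns the
#' Pearson correlation.
#'
#' @param a,b Non-negative value vectors over the same features.
#' @param alpha OPS exponent.
#' @param expressed_threshold Expression cutoff defining "expressed"
#'   (default 1, i.e. FPKM > 1 in either replicate).
#' @return Pearson correlation.
#' @export
replicate_correlation <- function(a, b, alpha = 0.25, expressed_threshold = 1) {
  stopifnot(length(a) == length(b))
  keep <- which((a > expressed_threshold | b > expressed_threshold) &
                  is.finite(a) & is.finite(b))
  if (length(keep) < 3) {
    abort("fewer than 3 shared expressed features: correlation undefined")
  }
  cor(ops_transform(a[keep], alpha), ops_transform(b[keep], alpha))
}

#' Per-sample D-statistics for outlier detection
#'
#' Each sample's D-statistic is the median of its pairwise Pearson
#' correlations (computed on OPS-transformed, pairwise-expressed features)
#' with every other sample; samples with `D < outlier_threshold` are
#' flagged.
#'
#' @param mat Feature x sample matrix (FPKM scale).
#' @param alpha OPS exponent.
#' @param outlier_threshold Flagging threshold on D.
#' @param expressed_threshold Per-pair expression cutoff.
#' @return A `qc_report` tibble: `sample`, `d`, `outlier`.
#' @export
d_statistics <- function(mat, alpha = 0.25, outlier_threshold = 0.8,
                         expressed_threshold = 1) {
  n <- ncol(mat)
  if (n < 2) abort("need at least 2 samples")
  cm <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cm[i, j] <- cm[j, i] <- replicate_correlation(
        mat[, i], mat[, j], alpha, expressed_threshold)
    }
  }
  d <- vapply(seq_len(n), function(i) median(cm[i, -i]), numeric(1))
  out <- tibble(sample = colnames(mat) %||% as.character(seq_len(n)),
                d = d, outlier = d < outlier_threshold)
  class(out) <- c("qc_report", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GC/length bias offsets via median quantile regression
#'
#' For each sample, fits a tau = 0.5 quantile regression of
#' `log2(count + 0.5)` on natural cubic spline bases in GC content and
#' log2 length, with knots at the 2.5/25/50/75/97.5% covariate quantiles
#' (conditional-quantile-normalization style). The offset of a feature in a
#' sample is the fitted systematic effect minus its across-sample mean for
#' that feature; offsets are then centered to mean zero per sample.
#' Subtracting the offset from `log2(count + 0.5)` (or supplying it to the
#' negative-binomial GLM) removes the sample-specific GC and length biases.
#'
#' @param counts Feature x sample integer matrix.
#' @param gc Per-feature GC fraction.
#' @param length Per-feature length in bp (> 0).
#' @return Feature x sample offset matrix (log2 scale).
#' @export
cqn_offsets <- function(counts, gc, length) {
  stopifnot(nrow(counts) == length(gc), nrow(counts) == length(length))
  if (any(length <= 0)) abort("feature lengths must be positive")
  y <- log2(counts + 0.5)
  terms <- list()
  if (sd(gc) > 0) terms$gc <- spline_basis(gc) else
    warn("constant GC content: GC spline term dropped")
  llen <- log2(length)
  if (sd(llen) > 0) terms$len <- spline_basis(llen) else
    warn("constant feature length: length spline term dropped")
  if (!base::length(terms)) {
    off <- counts * 0
    dimnames(off) <- dimnames(counts)
    return(off)
  }
  X <- do.call(cbind, terms)
  fit_mat <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    fit <- suppressWarnings(quantreg::rq.fit(cbind(1, X), y[, s], tau = 0.5))
    fit_mat[, s] <- cbind(1, X) %*% fit$coefficients
  }
  off <- fit_mat - rowMeans(fit_mat)
  sweep(off, 2, colMeans(off))
}

# Natural cubic spline basis with knots at the 25/50/75% quantiles and
# boundary knots at the 2.5/97.5% quantiles of the covariate.
spline_basis <- function(x) {
  qs <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  inner <- unique(qs[2:4])
  bound <- c(qs[1], qs[5])
  if (bound[1] >= bound[2]) return(matrix(x - mean(x), ncol = 1))
  splines::ns(x, knots = inner, Boundary.knots = bound)
}
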
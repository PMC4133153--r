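#' Expression/length feature filter
#'
#' Keeps features whose mean FPKM is at least `min_fpkm` (default 2) and
#' whose length is at least `min_length` bp (default 100); both boundaries
#' inclusive.
#'
#' @param fpkm Feature x sample FPKM matrix.
#' @param lengths Per-feature length in bp.
#' @param min_fpkm,min_length Inclusive cutoffs.
#' @return Character vector of kept feature ids (or indices when the
#'   matrix has no rownames).
#' @export
filter_features <- function(fpkm, lengths, min_fpkm = 2, min_length = 100) {
  stopifnot(nrow(fpkm) == length(lengths))
  keep <- rowMeans(fpkm) >= min_fpkm & lengths >= min_length
  ids <- rownames(fpkm) %||% as.character(seq_len(nrow(fpkm)))
  ids[keep]
}

# Negative-binomial log-likelihood at fixed dispersion phi (phi = 0 is
# Poisson), parameterized by mu.
nb_loglik <- function(y, mu, phi) {
  if (phi > 0) {
    sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  } else {
    sum(stats::dpois(y, mu, log = TRUE))
  }
}

#' Moderated dispersion estimation
#'
#' The common dispersion maximizes the profile likelihood pooled over
#' features, with group means profiled out (the within-group mean,
#' offset-adjusted when offsets are supplied). Per-feature dispersions are
#' method-of-moments estimates computed within groups (negative values
#' truncated at zero), shrunk toward the common value with weight
#' `w = prior_n / (prior_n + n - G)`.
#'
#' @param counts Feature x sample integer matrix.
#' @param labels Population labels (tibble or named vector).
#' @param offsets Optional feature x sample log2-scale offset matrix.
#' @param prior_n Prior weight of the common dispersion (default 10).
#' @return A `dispersion_estimates` list: `common`, `tagwise` (per-feature),
#'   `shrinkage_weight`.
#' @export
estimate_dispersion <- function(counts, labels, offsets = NULL, prior_n = 10) {
  lab <- as_population_map(labels, colnames(counts))
  groups <- split(seq_along(lab), lab)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) abort("need at least one group with >= 2 samples")
  n <- sum(lengths(groups)); G <- length(groups)
  sf <- if (is.null(offsets)) matrix(1, nrow(counts), ncol(counts)) else 2^offsets

  prof <- function(phi) {
    ll <- 0
    for (g in groups) {
      y <- counts[, g, drop = FALSE]
      s <- sf[, g, drop = FALSE]
      m <- rowSums(y) / rowSums(s)          # profile (Poisson-score) mean
      mu <- m * s
      ok <- m > 0
      ll <- ll + nb_loglik(y[ok, , drop = FALSE], mu[ok, , drop = FALSE], phi)
    }
    ll
  }
  common <- optimize(prof, c(1e-6, 5), maximum = TRUE, tol = 1e-5)$maximum
  if (prof(1e-8) >= prof(common)) common <- 0

  num <- den <- numeric(nrow(counts))
  for (g in groups) {
    y <- counts[, g, drop = FALSE] / sf[, g, drop = FALSE]
    m <- rowMeans(y); v <- apply(y, 1, var)
    num <- num + (length(g) - 1) * (v - m)
    den <- den + (length(g) - 1) * m^2
  }
  mom <- pmax(0, ifelse(den > 0, num / den, 0))
  w <- prior_n / (prior_n + n - G)
  structure(list(common = common, tagwise = w * common + (1 - w) * mom,
                 shrinkage_weight = w), class = "dispersion_estimates")
}

# IRLS fit of a negative-binomial GLM with log link and fixed dispersion.
# `offset` is on the natural-log scale. Ridge 1e-6 stabilizes separable
# designs; convergence on relative deviance change < tol.
fit_nb_glm <- function(y, X, offset = NULL, phi = 0, max_iter = 50,
                       tol = 1e-8, ridge = 1e-6) {
  n <- length(y)
  if (is.null(offset)) offset <- numeric(n)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev_of <- function(mu) {
    if (phi > 0) {
      2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
                (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
    } else {
      2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    }
  }
  dev <- dev_of(mu)
  beta <- NULL; converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + diag(ridge, ncol(X))
    beta <- solve(A, XtW %*% z)
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    dev_new <- dev_of(mu)
    if (is.finite(dev) && abs(dev - dev_new) < tol * (abs(dev) + 0.1)) {
      dev <- dev_new; converged <- TRUE; break
    }
    dev <- dev_new
  }
  list(beta = drop(beta), mu = mu, deviance = dev, converged = converged,
       loglik = nb_loglik(y, mu, phi))
}

#' Negative-binomial ANOVA for population differential expression
#'
#' Per feature, fits the NB log-link GLM
#' `log mu = intercept + population effect + offset` by iteratively
#' reweighted least squares and compares it to the intercept-only model by
#' likelihood ratio; p-values come from the chi-square distribution with
#' `G - 1` degrees of freedom. Benjamini-Hochberg q-values are appended.
#'
#' @param counts Feature x sample integer matrix (a single feature may be
#'   passed as a vector).
#' @param labels Population labels.
#' @param offsets Optional feature x sample log2-scale offsets (e.g. from
#'   [cqn_offsets()]).
#' @param dispersion Per-feature dispersion(s) or a
#'   [estimate_dispersion()] result (tagwise values used).
#' @return A `pt_de` tibble: feature, per-population log2 effects, `lr`,
#'   `df`, `p`, `q`, `converged`, `flagged`.
#' @export
de_anova <- function(counts, labels, offsets = NULL, dispersion = 0) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1,
                                          dimnames = list("feature1", names(counts)))
  lab <- factor(as_population_map(labels, colnames(counts)))
  G <- nlevels(lab)
  phi <- if (inherits(dispersion, "dispersion_estimates")) {
    dispersion$tagwise
  } else {
    rep(dispersion, length.out = nrow(counts))
  }
  X1 <- model.matrix(~lab)
  X0 <- X1[, 1, drop = FALSE]
  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    o <- if (is.null(offsets)) NULL else offsets[i, ] * log(2)
    if (all(y == 0)) {
      rows[[i]] <- tibble(lr = NA_real_, df = G - 1, p = NA_real_,
                          converged = NA, flagged = TRUE,
                          deviance = NA_real_, resid_df = length(y) - G)
      next
    }
    f1 <- fit_nb_glm(y, X1, o, phi[i])
    f0 <- fit_nb_glm(y, X0, o, phi[i])
    lr <- max(0, 2 * (f1$loglik - f0$loglik))
    conv <- f1$converged && f0$converged
    rows[[i]] <- tibble(lr = lr, df = G - 1,
                        p = if (conv) pchisq(lr, G - 1, lower.tail = FALSE) else NA_real_,
                        converged = conv, flagged = !conv,
                        deviance = f1$deviance,
                        resid_df = length(y) - G)
    attr(rows[[i]], "beta") <- f1$beta
  }
  res <- list_rbind(rows)
  beta_mat <- t(vapply(rows, function(r) {
    b <- attr(r, "beta")
    if (is.null(b)) rep(NA_real_, G) else b / log(2)
  }, numeric(G)))
  colnames(beta_mat) <- c("log2_intercept",
                          paste0("log2fc_", levels(lab)[-1]))
  out <- dplyr::bind_cols(
    tibble(feature = rownames(counts) %||% as.character(seq_len(nrow(counts)))),
    as_tibble(beta_mat), res)
  out$q <- bh_fdr(out$p)
  class(out) <- c("pt_de", class(out))
  out
}

#' Exact negative-binomial test for a pairwise comparison
#'
#' Conditions on the total count of both groups; group totals of `n_i` iid
#' NB(mu, phi) samples are treated as NB(`n_i mu`, `phi / n_i`). The
#' two-sided p-value sums the probabilities of all group-A totals at most
#' as probable as the observed one. In the `phi = 0` limit the conditional
#' distribution is binomial. Counts should be library-equalized
#' pseudo-counts (see [equalize_counts()]); non-integer input is rounded
#' half-to-even with a warning.
#'
#' @param yA,yB Integer count vectors for the two groups.
#' @param phi Common dispersion.
#' @return Two-sided p-value.
#' @export
de_exact_pairwise <- function(yA, yB, phi = 0) {
  if (any(c(yA, yB) != floor(c(yA, yB)))) {
    warn("non-integer pseudo-counts rounded half-to-even")
    yA <- round_half_even(yA); yB <- round_half_even(yB)
  }
  nA <- length(yA); nB <- length(yB)
  Tt <- sum(yA) + sum(yB)
  if (Tt == 0) return(1)
  mu <- Tt / (nA + nB)
  k <- 0:Tt
  logp <- if (phi > 0) {
    dnbinom(k, size = nA / phi, mu = nA * mu, log = TRUE) +
      dnbinom(Tt - k, size = nB / phi, mu = nB * mu, log = TRUE)
  } else {
    dbinom(k, Tt, nA / (nA + nB), log = TRUE)
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[sum(yA) + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Quantile-matching library equalization for the exact test
#'
#' Scales each sample's counts to the geometric-mean effective library
#' size (offsets folded in when given), rounding half-to-even.
#'
#' @param counts Feature x sample matrix.
#' @param lib_sizes Optional library sizes (default column sums).
#' @param offsets Optional log2 offset matrix folded into the scaling.
#' @return Integer matrix of pseudo-counts.
#' @export
equalize_counts <- function(counts, lib_sizes = NULL, offsets = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  target <- exp(mean(log(lib_sizes)))
  scaled <- sweep(counts, 2, target / lib_sizes, `*`)
  if (!is.null(offsets)) scaled <- scaled / 2^offsets
  out <- round_half_even(scaled)
  storage.mode(out) <- "integer"
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1;
#' `NA` p-values propagate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Goodness-of-fit z-scores for NB GLM fits
#'
#' Converts each feature's residual deviance to a standard-normal quantile
#' through the chi-square CDF at the residual degrees of freedom
#' (McCarthy-style goodness-of-fit display). `df <= 0` yields `NA`.
#'
#' @param deviance Residual deviances.
#' @param df Residual degrees of freedom (recycled).
#' @return z-score vector.
#' @export
gof_zscores <- function(deviance, df) {
  df <- rep(df, length.out = length(deviance))
  z <- rep(NA_real_, length(deviance))
  ok <- !is.na(deviance) & df > 0
  z[ok] <- qnorm(pchisq(deviance[ok], df[ok], lower.tail = FALSE,
                        log.p = TRUE),
                 lower.tail = FALSE, log.p = TRUE)
  z
}
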
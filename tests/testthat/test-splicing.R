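test_that("splicing profile arithmetic and the exact log identity", {
  tensor <- list(g1 = matrix(c(3, 1), 1, 2,
                             dimnames = list("i1", c("t1", "t2"))))
  pr <- splicing_profile(tensor, pseudocount = 0.5)
  expect_equal(unname(pr$g1$e), 5)
  expect_equal(unname(pr$g1$s[1, ]), c(0.7, 0.3))
  co <- small_cohort()
  prof <- splicing_profile(co$tensor)
  for (g in names(prof)[1:5]) {
    resid <- log2(prof[[g]]$t) -
      (log2(prof[[g]]$e) + log2(prof[[g]]$s))
    expect_lt(max(abs(resid)), 1e-12)
  }
  single <- splicing_profile(list(g = matrix(c(4, 9), 2, 1,
                                             dimnames = list(c("i1", "i2"), "t1"))))
  expect_equal(unname(single$g$s[, 1]), c(1, 1))
  expect_error(splicing_profile(tensor, pseudocount = 0), "positive")
})

test_that("Hellinger distance: boundary values and metric properties", {
  expect_equal(hellinger(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(hellinger(c(1, 0), c(0, 1)), 1)
  expect_equal(hellinger(c(0.5, 0.5), c(1, 0)), sqrt(1 - sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(hellinger(c(0.5, 0.5), c(1, 0)), 0.5412, tolerance = 1e-4)
  expect_error(hellinger(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  withr::local_seed(10)
  for (k in 1:1000) {
    p <- runif_simplex(3); q <- runif_simplex(3); r <- runif_simplex(3)
    expect_equal(hellinger(p, q), hellinger(q, p), tolerance = 1e-12)
    expect_lte(hellinger(p, q), hellinger(p, r) + hellinger(r, q) + 1e-9)
    expect_gte(hellinger(p, q), 0)
    expect_lte(hellinger(p, q), 1)
  }
})

test_that("variability summary: cv and F-bar on constructed profiles", {
  lab <- c(i1 = "A", i2 = "A", i3 = "A", i4 = "B", i5 = "B")
  e <- c(2, 2, 2, 1, 3)
  s <- matrix(rep(c(0.6, 0.4), each = 5), 5, 2)
  rownames(s) <- names(lab)
  prof <- structure(list(g1 = list(e = setNames(e, names(lab)), s = s,
                                   t = s * e, pseudocount = 0.5)),
                    class = "splicing_profile")
  vs <- variability_summary(prof, lab)
  expect_equal(vs$cv[vs$population == "A"], 0)
  expect_equal(vs$cv[vs$population == "B"], sqrt(2) / 2, tolerance = 1e-4)
  expect_equal(vs$cv[vs$population == "B"], 0.7071, tolerance = 1e-4)
  expect_equal(vs$fbar, c(0, 0))
  expect_error(variability_summary(prof, c(i1 = "A", i2 = "B", i3 = "B",
                                           i4 = "B", i5 = "B")), ">= 2")
})

test_that("population variance explained: boundaries and the 1-D ANOVA identity", {
  lab <- c(i1 = "A", i2 = "A", i3 = "B", i4 = "B")
  # within-group identical, between-group distinct -> R2 = 1
  L <- rbind(i1 = c(0, 0), i2 = c(0, 0), i3 = c(3, 1), i4 = c(3, 1))
  pv <- pop_variance_explained(L, lab, n_perm = 50, seed = 3)
  expect_equal(pv$r2, 1, tolerance = 1e-12)
  # all rows identical -> degenerate rule
  L0 <- matrix(1, 4, 2, dimnames = list(names(lab), NULL))
  pv0 <- pop_variance_explained(L0, lab, n_perm = 50, seed = 3)
  expect_equal(pv0$r2, 0); expect_equal(pv0$p, 1)
  # one column, values (1,2 | 3,4): classical ANOVA R2 = 0.8
  L1 <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(names(lab), NULL))
  pv1 <- pop_variance_explained(L1, lab, n_perm = 0, seed = 1)
  expect_equal(pv1$r2, 0.8, tolerance = 1e-9)
  fit <- stats::aov(c(1, 2, 3, 4) ~ factor(c("A", "A", "B", "B")))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(pv1$r2, ss[1] / sum(ss), tolerance = 1e-9)
})

test_that("distance-based R2 agrees with vegan::adonis2", {
  withr::local_seed(77)
  lab <- setNames(rep(c("A", "B", "C"), each = 5), paste0("i", 1:15))
  L <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(names(lab), NULL))
  L[lab == "B", ] <- L[lab == "B", ] + 1
  pv <- pop_variance_explained(L, lab, n_perm = 0)
  ad <- vegan::adonis2(dist(L) ~ g, data = data.frame(g = lab),
                       permutations = 2)
  expect_equal(pv$r2, ad$R2[1], tolerance = 1e-9)
})

test_that("permutation p-values and the adjusted R2 behave under the null", {
  withr::local_seed(55)
  lab <- setNames(rep(c("A", "B", "C"), each = 4), paste0("i", 1:12))
  out <- replicate(60, {
    L <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(names(lab), NULL))
    pv <- pop_variance_explained(L, lab, n_perm = 39,
                                 seed = sample.int(1e6, 1))
    c(pv$p, pv$r2_adj)
  })
  expect_gt(suppressWarnings(stats::ks.test(out[1, ], "punif")$p.value), 0.01)
  expect_lt(abs(mean(out[2, ])), 0.1)   # adjusted R2 centers at zero
})

test_that("expression share hits both boundaries exactly", {
  lab <- c(i1 = "A", i2 = "A", i3 = "B", i4 = "B")
  mk_entry <- function(t) {
    e <- rowSums(t)
    list(e = e, s = t / e, t = t, pseudocount = 0)
  }
  base <- matrix(rep(c(6, 4), each = 4), 4, 2,
                 dimnames = list(names(lab), c("t1", "t2")))
  # common fold change, identical ratios -> share 1
  fc <- base; fc[3:4, ] <- fc[3:4, ] * 4
  expect_equal(expression_splicing_share(mk_entry(fc), lab), 1)
  # ratio flip with identical totals -> share 0
  flip <- base; flip[3:4, ] <- flip[3:4, c(2, 1)]
  expect_equal(expression_splicing_share(mk_entry(flip), lab), 0)
  # no variation at all -> NA
  expect_true(is.na(expression_splicing_share(mk_entry(base), lab)))
  # complement share sums to 1 on generic data
  withr::local_seed(12)
  t <- matrix(rgamma(8, 4), 4, 2, dimnames = dimnames(base)) + 0.2
  sh <- expression_splicing_share(mk_entry(t), lab)
  e <- mk_entry(t)
  Tn <- 2
  between_ss <- function(x) {
    gm <- mean(x)
    sum(vapply(split(x, lab), function(v) length(v) * (mean(v) - gm)^2,
               numeric(1)))
  }
  ssb_e <- Tn * between_ss(log2(e$e))
  ssb_s <- sum(apply(log2(e$s), 2, between_ss))
  expect_equal(sh, ssb_e / (ssb_e + ssb_s), tolerance = 1e-12)
  expect_equal(sh + ssb_s / (ssb_e + ssb_s), 1, tolerance = 1e-12)
})

test_that("differential splicing: separation, degeneracy and exhaustive p", {
  lab <- c(i1 = "A", i2 = "A", i3 = "B", i4 = "B")
  tensor <- list(g1 = rbind(i1 = c(10, 0.1), i2 = c(9, 0.2),
                            i3 = c(0.1, 11), i4 = c(0.2, 10)))
  colnames(tensor$g1) <- c("t1", "t2")
  prof <- splicing_profile(tensor, pseudocount = 0.01)
  ds <- differential_splicing(prof, lab, exhaustive = TRUE)
  # minimum achievable over C(4,2) labelings: the observed split and its
  # label swap give the same pseudo-F
  expect_equal(ds$p, 2 / 6)
  expect_gt(ds$pseudo_f, 10)
  # identical ratios -> F = 0, p = 1
  same <- list(g1 = matrix(rep(c(5, 5), each = 4), 4, 2,
                           dimnames = list(names(lab), c("t1", "t2"))))
  ds0 <- differential_splicing(splicing_profile(same, pseudocount = 0.5), lab,
                               exhaustive = TRUE)
  expect_equal(ds0$pseudo_f, 0); expect_equal(ds0$p, 1)
  # exhaustive enumeration matches an independent brute force
  withr::local_seed(30)
  t <- matrix(rgamma(12, 2), 4, 3, dimnames = list(names(lab), NULL)) + 0.1
  pr <- splicing_profile(list(g = t), pseudocount = 0.1)
  dsx <- differential_splicing(pr, lab, exhaustive = TRUE)
  s <- pr$g$s
  hm2 <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    if (i == j) 0 else hellinger(s[i, ], s[j, ])^2
  }))
  fstat <- function(ll) {
    sst <- sum(hm2[upper.tri(hm2)]) / 4
    ssw <- 0
    for (pp in unique(ll)) {
      ix <- which(ll == pp)
      dd <- hm2[ix, ix, drop = FALSE]
      ssw <- ssw + sum(dd[upper.tri(dd)]) / length(ix)
    }
    ((sst - ssw) / 1) / (ssw / 2)
  }
  splits <- utils::combn(4, 2)
  fs <- apply(splits, 2, function(ix) {
    ll <- rep("B", 4); ll[ix] <- "A"; fstat(ll)
  })
  expect_equal(dsx$p, mean(fs >= fstat(c("A", "A", "B", "B")) - 1e-12))
})

test_that("differential splicing ignores pure expression shifts", {
  withr::local_seed(91)
  lab <- setNames(rep(c("A", "B"), each = 5), paste0("i", 1:10))
  ps <- replicate(100, {
    r <- t(replicate(10, runif_simplex(3)))  # shared ratio distribution
    e <- 2^c(rnorm(5, 8), rnorm(5, 11))      # strong expression shift only
    tensor <- list(g = e * r)
    rownames(tensor$g) <- names(lab)
    differential_splicing(splicing_profile(tensor, pseudocount = 1e-6), lab,
                          n_perm = 39, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps <= 0.05), 0.0 - 1e-9)
  expect_lt(mean(ps <= 0.05), 0.12)
})

test_that("variability correlations: identity case and matrix shape", {
  co <- small_cohort()
  prof <- splicing_profile(co$tensor)
  vs <- variability_summary(prof, co$labels)
  vc <- variability_correlation(vs)
  expect_true(isSymmetric(vc$cv_cor))
  expect_equal(unname(diag(vc$cv_cor)), rep(1, ncol(vc$cv_cor)))
  # identical per-gene cv across populations -> all correlations 1
  vs2 <- vs
  vs2$cv <- rep(seq_len(nrow(vs2) / length(unique(vs2$population))),
                times = length(unique(vs2$population)))
  vs2 <- dplyr::arrange(vs2, population, gene)
  vs2$cv <- rep(seq_len(length(unique(vs2$gene))),
                times = length(unique(vs2$population)))
  vc2 <- variability_correlation(vs2)
  expect_true(all(abs(vc2$cv_cor - 1) < 1e-12))
})
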
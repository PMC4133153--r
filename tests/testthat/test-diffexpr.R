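test_that("feature filter applies inclusive FPKM and length cutoffs", {
  fpkm <- rbind(a = c(2, 2), b = c(1.99, 1.99), c = c(5, 5), d = c(3, 3))
  len <- c(a = 100, b = 5000, c = 99, d = 200)
  expect_identical(filter_features(fpkm, len), c("a", "d"))
  # brute-force cross-check on random features straddling both cutoffs
  withr::local_seed(8)
  f2 <- matrix(runif(20, 1.5, 2.5), 10, 2,
               dimnames = list(letters[1:10], NULL))
  l2 <- sample(90:110, 10)
  manual <- letters[1:10][rowMeans(f2) >= 2 & l2 >= 100]
  expect_identical(filter_features(f2, l2), manual)
})

test_that("dispersion estimation: Poisson null, NB recovery, truncation", {
  withr::local_seed(13)
  lab <- rep(c("A", "B", "C"), each = 14)
  names(lab) <- paste0("s", seq_along(lab))
  mu <- 2^runif(150, 5, 9)
  pois <- matrix(rpois(150 * 42, rep(mu, 42)), 150, 42,
                 dimnames = list(NULL, names(lab)))
  est0 <- estimate_dispersion(pois, lab)
  expect_lt(est0$common, 0.01)
  nb <- matrix(rnbinom(150 * 42, mu = rep(mu, 42), size = 5), 150, 42,
               dimnames = list(NULL, names(lab)))
  est <- estimate_dispersion(nb, lab)
  expect_gt(est$common, 0.15); expect_lt(est$common, 0.25)
  flat <- matrix(7, 3, 42, dimnames = list(NULL, names(lab)))
  estf <- estimate_dispersion(flat, lab, prior_n = 0)
  expect_equal(unname(estf$tagwise), rep(0, 3))
})

test_that("common dispersion agrees with edgeR's estimate", {
  withr::local_seed(14)
  lab <- rep(c("A", "B"), each = 10)
  names(lab) <- paste0("s", 1:20)
  y <- matrix(rnbinom(400 * 20, mu = 200, size = 1 / 0.15), 400, 20,
              dimnames = list(NULL, names(lab)))
  est <- estimate_dispersion(y, lab)
  ref <- edgeR::estimateCommonDisp(edgeR::DGEList(y, group = lab))$common.dispersion
  expect_equal(est$common, ref, tolerance = 0.25)
})

test_that("NB ANOVA: degenerate input, Poisson limit, offset invariance", {
  lab <- rep(c("A", "B"), each = 4)
  names(lab) <- paste0("s", 1:8)
  same <- setNames(rep(9, 8), names(lab))
  r <- de_anova(same, lab, dispersion = 0.1)
  expect_equal(r$lr, 0, tolerance = 1e-8)
  expect_equal(r$p, 1, tolerance = 1e-8)
  # phi -> 0 equals the classical Poisson GLM deviance
  withr::local_seed(5)
  y <- rpois(8, lambda = c(rep(40, 4), rep(70, 4)))
  names(y) <- names(lab)
  mine <- de_anova(y, lab, dispersion = 0)
  ref <- stats::glm(y ~ factor(lab), family = stats::poisson())
  expect_equal(mine$deviance, ref$deviance, tolerance = 1e-6)
  expect_equal(mine$lr, ref$null.deviance - ref$deviance, tolerance = 1e-6)
  # adding a constant to all offsets moves only the intercept
  off0 <- matrix(0, 1, 8); off1 <- off0 + 3
  f0 <- de_anova(y, lab, off0, 0.05)
  f1 <- de_anova(y, lab, off1, 0.05)
  expect_equal(f1$log2_intercept, f0$log2_intercept - 3, tolerance = 1e-6)
  expect_equal(f1$log2fc_B, f0$log2fc_B, tolerance = 1e-6)
  expect_equal(f1$lr, f0$lr, tolerance = 1e-6)
  # all-zero features are flagged out
  z <- de_anova(setNames(rep(0, 8), names(lab)), lab, dispersion = 0.1)
  expect_true(z$flagged)
  expect_true(is.na(z$p))
})

test_that("NB ANOVA matches MASS::glm.nb at matched dispersion", {
  withr::local_seed(23)
  lab <- rep(c("A", "B", "C"), each = 6)
  names(lab) <- paste0("s", seq_along(lab))
  y <- rnbinom(18, mu = rep(c(80, 120, 100), each = 6), size = 8)
  names(y) <- names(lab)
  mine <- de_anova(y, lab, dispersion = 1 / 8)
  ref <- MASS::glm.nb(y ~ factor(lab), init.theta = 8)
  # theta fixed at 8 in ours; glm.nb estimates it, so compare coefficients
  expect_equal(unname(mine$log2fc_B) * log(2), unname(coef(ref))[2],
               tolerance = 0.05)
  expect_equal(unname(mine$log2fc_C) * log(2), unname(coef(ref))[3],
               tolerance = 0.05)
})

test_that("power rises with the planted effect size", {
  withr::local_seed(29)
  lab <- rep(c("A", "B"), each = 7)
  names(lab) <- paste0("s", 1:14)
  mean_p <- vapply(c(0, 0.5, 1), function(fc) {
    ps <- replicate(60, {
      y <- rnbinom(14, mu = 100 * 2^(fc * (lab == "B")), size = 10)
      names(y) <- names(lab)
      de_anova(y, lab, dispersion = 0.1)$p
    })
    mean(ps)
  }, numeric(1))
  expect_true(all(diff(mean_p) < 0))
})

test_that("exact pairwise test: symmetry, exchangeability, enumeration oracle", {
  expect_equal(de_exact_pairwise(c(5, 5), c(5, 5), 0.2), 1)
  withr::local_seed(3)
  for (k in 1:20) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    yA <- rpois(nA, 2); yB <- rpois(nB, 2)
    if (sum(yA) + sum(yB) == 0 || sum(yA) + sum(yB) > 20) next
    p <- de_exact_pairwise(yA, yB, 0)
    # brute force: conditional distribution of the A-total is binomial
    Tt <- sum(yA) + sum(yB)
    pr <- dbinom(0:Tt, Tt, nA / (nA + nB))
    p_ref <- sum(pr[pr <= pr[sum(yA) + 1] * (1 + 1e-10)])
    expect_equal(p, p_ref, tolerance = 1e-12)
    expect_equal(de_exact_pairwise(yB, yA, 0), p, tolerance = 1e-12)
  }
  expect_warning(de_exact_pairwise(c(2.5, 3), c(3, 3), 0.1), "rounded")
})

test_that("exact test agrees with edgeR's exactTest", {
  withr::local_seed(41)
  lab <- rep(c("A", "B"), each = 5)
  y <- matrix(rnbinom(50 * 10, mu = 100, size = 10), 50, 10)
  colnames(y) <- paste0("s", 1:10)
  phi <- 0.1
  dge <- edgeR::DGEList(y, group = lab)
  dge$samples$norm.factors <- 1
  dge$samples$lib.size <- rep(mean(colSums(y)), 10)  # equalized libraries
  dge$common.dispersion <- phi
  ref <- edgeR::exactTest(dge, dispersion = phi)$table$PValue
  mine <- apply(y, 1, function(r) de_exact_pairwise(r[1:5], r[6:10], phi))
  expect_gt(cor(-log10(mine), -log10(ref)), 0.98)
})

test_that("BH q-values follow the step-up formula and propagate NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  withr::local_seed(6)
  p <- runif(50); p[7] <- NA
  q <- bh_fdr(p)
  expect_true(is.na(q[7]))
  ok <- !is.na(p)
  expect_true(all(q[ok] >= p[ok]))
  ord <- order(p[ok])
  expect_true(all(diff(q[ok][ord]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("goodness-of-fit z-scores are calibrated and directional", {
  withr::local_seed(19)
  lab <- rep(c("A", "B"), each = 10)
  names(lab) <- paste0("s", 1:20)
  y <- matrix(rnbinom(400 * 20, mu = 150, size = 1 / 0.1), 400, 20,
              dimnames = list(NULL, names(lab)))
  fit <- de_anova(y, lab, dispersion = 0.1)
  z <- gof_zscores(fit$deviance, fit$resid_df)
  expect_gt(suppressWarnings(stats::ks.test(z, "pnorm")$p.value), 0.01)
  # forcing too-large phi on Poisson data underfits the variance: z < 0
  yp <- matrix(rpois(200 * 20, 150), 200, 20,
               dimnames = list(NULL, names(lab)))
  fitp <- de_anova(yp, lab, dispersion = 0.5)
  zp <- gof_zscores(fitp$deviance, fitp$resid_df)
  expect_lt(mean(zp), -1)
  expect_true(is.na(gof_zscores(3.2, 0)))
})
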
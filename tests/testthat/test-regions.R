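test_that("region calling matches the worked merge example", {
  depth <- integer(300)
  depth[101:150] <- 2   # [100,150) 0-based
  depth[161:200] <- 3   # [160,200), gap 10 -> merge
  tr <- list(contig = "c1", depth = depth, total_reads = 2e7)  # cutoff 1
  rg <- call_regions(tr)
  expect_equal(nrow(rg), 1)
  expect_equal(c(rg$start, rg$end), c(100L, 200L))
  expect_equal(rg$expression, 3)
})

test_that("a 14-base gap merges and a 15-base gap stays split", {
  depth <- integer(300)
  depth[101:150] <- 2
  depth[165:200] <- 3   # gap [150,164) = 14 bases
  tr <- list(contig = "c1", depth = depth, total_reads = 2e7)
  expect_equal(nrow(call_regions(tr)), 1)
  depth2 <- integer(300)
  depth2[101:150] <- 2
  depth2[166:200] <- 3  # gap [150,165) = 15 bases
  tr2 <- list(contig = "c1", depth = depth2, total_reads = 2e7)
  rg2 <- call_regions(tr2)
  expect_equal(nrow(rg2), 2)
  expect_equal(rg2$start, c(100L, 165L))
})

test_that("edge cases: empty track, all-zero track, zero reads", {
  expect_equal(nrow(call_regions(list(contig = "c", depth = integer(0),
                                      total_reads = 1e6))), 0)
  expect_equal(nrow(call_regions(list(contig = "c", depth = integer(500),
                                      total_reads = 1e6))), 0)
  expect_error(call_regions(list(contig = "c", depth = 1:3, total_reads = 0)),
               "positive")
})

test_that("random tracks match the brute-force oracle exactly", {
  withr::local_seed(123)
  for (k in 1:40) {
    depth <- integer(600)
    n_seg <- sample(0:6, 1)
    for (s in seq_len(n_seg)) {
      a <- sample(1:550, 1); b <- min(600, a + sample(1:60, 1))
      depth[a:b] <- depth[a:b] + sample(1:5, 1)
    }
    depth[sample(600, 20)] <- depth[sample(600, 20)] + 1L
    tr <- list(contig = "c", depth = depth, total_reads = 2e7)
    mine <- call_regions(tr)
    ref <- brute_force_regions(depth, 2e7)
    expect_equal(nrow(mine), nrow(ref))
    expect_equal(mine$start, as.integer(ref$start))
    expect_equal(mine$end, as.integer(ref$end))
    expect_equal(mine$expression, ref$expression)
  }
})

test_that("calling is idempotent and shift-covariant", {
  co <- small_cohort()
  tr <- co$coverage[[1]]
  rg <- call_regions(tr)
  # re-calling on the called support reproduces the same regions
  support <- integer(length(tr$depth))
  for (k in seq_len(nrow(rg))) {
    support[(rg$start[k] + 1):rg$end[k]] <- tr$depth[(rg$start[k] + 1):rg$end[k]]
  }
  rg2 <- call_regions(list(contig = tr$contig, depth = support,
                           total_reads = tr$total_reads))
  expect_equal(rg2[, c("start", "end")], rg[, c("start", "end")])
  # prepending zero bases shifts coordinates only
  rg3 <- call_regions(list(contig = tr$contig,
                           depth = c(integer(50), tr$depth),
                           total_reads = tr$total_reads))
  expect_equal(rg3$start, rg$start + 50L)
  expect_equal(rg3$end, rg$end + 50L)
  expect_equal(rg3$expression, rg$expression)
})

test_that("noise-free planted segments are recovered with exact boundaries", {
  cfg <- small_config(coverage_noise_rate = 0)
  cv <- simulate_coverage(cfg)
  called <- dplyr::bind_rows(lapply(cv$tracks, call_regions))
  truth <- dplyr::arrange(cv$segments, contig, start)
  called <- dplyr::arrange(called, contig, start)
  expect_equal(called$start, truth$start)
  expect_equal(called$end, truth$end)
})

test_that("classification: overlap boundaries and brute-force agreement", {
  ann <- tibble::tibble(contig = "c1", start = c(150L, 200L),
                        end = c(300L, 300L), name = c("e1", "e2"))
  rg <- tibble::tibble(contig = "c1", start = c(100L, 100L, 320L),
                       end = c(200L, 150L, 400L), expression = 5)
  cl <- classify_regions(rg, ann)
  expect_equal(cl$classification, c("annotated", "novel", "novel"))
  withr::local_seed(19)
  rg2 <- tibble::tibble(contig = sample(c("c1", "c2"), 400, TRUE),
                        start = sample.int(5000, 400))
  rg2$end <- rg2$start + sample.int(200, 400, replace = TRUE)
  ann2 <- tibble::tibble(contig = sample(c("c1", "c2"), 100, TRUE),
                         start = sample.int(5000, 100))
  ann2$end <- ann2$start + sample.int(300, 100, replace = TRUE)
  cl2 <- classify_regions(rg2, ann2)
  brute <- vapply(seq_len(400), function(i) {
    hit <- any(ann2$contig == rg2$contig[i] &
                 pmax(ann2$start, rg2$start[i]) < pmin(ann2$end, rg2$end[i]))
    if (hit) "annotated" else "novel"
  }, character(1))
  expect_identical(cl2$classification, brute)
})

test_that("RPKM arithmetic matches the definition", {
  expect_equal(region_rpkm(10, 1000, 1e6), 10)
  expect_equal(region_rpkm(0, 500, 1e6), 0)
  withr::local_seed(2)
  reads <- sample.int(1000, 50); len <- sample.int(5000, 50) + 10
  tot <- sample.int(1e8, 50) + 1e6
  expect_equal(region_rpkm(reads, len, tot),
               reads / ((len / 1e3) * (tot / 1e6)), tolerance = 1e-12)
  expect_error(region_rpkm(1, 0, 1e6), "positive")
  expect_error(region_rpkm(1, 100, 0), "positive")
})

test_that("ubiquity filter matches brute-force set evaluation", {
  lab <- c(i1 = "A", i2 = "A", i3 = "B", i4 = "B", i5 = "B")
  rpkm <- rbind(r1 = c(2, 2, 2, 2, 2),
                r2 = c(1.5, 3, 0, 0, 0),
                r3 = c(0.5, 3, 2, 2, 2))
  colnames(rpkm) <- names(lab)
  ub <- ubiquity_filter(rpkm, lab)
  g <- function(reg, pop) ub[ub$region == reg & ub$population == pop, ]
  expect_true(g("r1", "A")$ubiquitous && g("r1", "A")$present_outside)
  expect_true(g("r2", "A")$ubiquitous)
  expect_false(g("r2", "A")$present_outside)   # population-private
  expect_false(g("r3", "A")$ubiquitous)
  expect_true(g("r3", "B")$ubiquitous && g("r3", "B")$present_outside)
  withr::local_seed(44)
  rp <- matrix(runif(60, 0, 3), 12, 5, dimnames = list(paste0("r", 1:12),
                                                       names(lab)))
  ub2 <- ubiquity_filter(rp, lab)
  for (pp in c("A", "B")) {
    inp <- names(lab)[lab == pp]
    manual_u <- apply(rp[, inp] >= 1, 1, all)
    sub <- ub2[ub2$population == pp, ]
    expect_equal(sub$ubiquitous, unname(manual_u))
    manual_o <- apply(rp[, setdiff(names(lab), inp), drop = FALSE] >= 1, 1, any)
    expect_equal(sub$present_outside[manual_u], unname(manual_o[manual_u]))
  }
})
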
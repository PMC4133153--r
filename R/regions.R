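#' Call transcribed regions from a per-base coverage track
#'
#' A base is expressed when its depth reaches
#' `threshold_per_million * total_reads / 1e6` (default 0.05 reads per
#' million mapped reads); maximal runs of expressed bases become regions,
#' and regions separated by a gap of fewer than `merge_gap` bases (strictly
#' less; a 15-base gap stays split at the default) are merged iteratively
#' until stable. Region expression is the maximum per-base depth inside the
#' final region. With `rule = "mean"`, the threshold applies to the mean
#' depth of candidate runs instead of per base.
#'
#' @param track Coverage track: list with `contig`, `depth` (per-base,
#'   0-based positions) and `total_reads` (> 0).
#' @param threshold_per_million Expression threshold in reads per million.
#' @param merge_gap Merge regions separated by fewer than this many bases.
#' @param rule `"per_base"` (default) or `"mean"`.
#' @return Tibble: `contig`, `start`, `end` (0-based half-open),
#'   `expression`.
#' @export
call_regions <- function(track, threshold_per_million = 0.05, merge_gap = 15,
                         rule = c("per_base", "mean")) {
  rule <- match.arg(rule)
  if (track$total_reads <= 0) abort("total mapped reads must be positive")
  cutoff <- threshold_per_million * track$total_reads / 1e6
  depth <- track$depth
  empty <- tibble(contig = character(), start = integer(), end = integer(),
                  expression = numeric())
  if (!length(depth)) return(empty)
  pass <- if (rule == "per_base") depth >= cutoff else depth > 0
  r <- rle(pass)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (rule == "mean") {
    ok <- vapply(seq_along(starts), function(i) {
      mean(depth[(starts[i] + 1L):ends[i]]) >= cutoff
    }, logical(1))
    starts <- starts[ok]; ends <- ends[ok]
  }
  if (!length(starts)) return(empty)
  # iterative merge of gaps < merge_gap until stable (one left-to-right
  # sweep is stable because merging only shrinks gaps monotonically)
  repeat {
    if (length(starts) < 2) break
    gap <- starts[-1] - ends[-length(ends)]
    j <- which(gap < merge_gap)
    if (!length(j)) break
    grp <- cumsum(c(TRUE, gap >= merge_gap))
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  tibble(contig = track$contig,
         start = as.integer(starts), end = as.integer(ends),
         expression = vapply(seq_along(starts), function(i) {
           max(depth[(starts[i] + 1L):ends[i]])
         }, numeric(1)))
}

#' Classify regions as annotated or novel
#'
#' A region is `annotated` when it overlaps any annotation interval by at
#' least one base (half-open intersection; a shared boundary is no
#' overlap), else `novel`. With `min_overlap_frac > 0` the overlap must
#' additionally cover that fraction of the region.
#'
#' @param regions Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param annotation Tibble of exon intervals in the same convention.
#' @param min_overlap_frac Optional minimum overlapping fraction of the
#'   region (default 0: any overlap).
#' @return `regions` with a `classification` column.
#' @export
classify_regions <- function(regions, annotation, min_overlap_frac = 0) {
  if (!nrow(regions)) {
    regions$classification <- character(0)
    return(regions)
  }
  cls <- rep("novel", nrow(regions))
  for (ct in unique(regions$contig)) {
    ri <- which(regions$contig == ct)
    ai <- which(annotation$contig == ct)
    if (!length(ai)) next
    # IRanges uses 1-based closed intervals: [start+1, end]
    rr <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    aa <- IRanges::IRanges(annotation$start[ai] + 1L, annotation$end[ai])
    if (min_overlap_frac > 0) {
      ov <- IRanges::findOverlaps(rr, aa)
      w <- IRanges::width(IRanges::pintersect(rr[S4Vectors::queryHits(ov)],
                                              aa[S4Vectors::subjectHits(ov)]))
      hit <- unique(S4Vectors::queryHits(ov)[
        w >= min_overlap_frac * IRanges::width(rr[S4Vectors::queryHits(ov)])])
    } else {
      hit <- which(IRanges::countOverlaps(rr, aa) > 0)
    }
    cls[ri[hit]] <- "annotated"
  }
  regions$classification <- cls
  regions
}

#' Per-individual RPKM of a region
#'
#' `RPKM = reads_in_region / ((length / 1e3) * (total_reads / 1e6))`.
#'
#' @param reads Reads overlapping the region for one individual
#'   (vectorized).
#' @param length Region length in bp (> 0).
#' @param total_reads Individual's total mapped reads (> 0).
#' @return RPKM value(s).
#' @export
region_rpkm <- function(reads, length, total_reads) {
  if (any(length <= 0)) abort("region length must be positive")
  if (any(total_reads <= 0)) abort("total mapped reads must be positive")
  reads / ((length / 1e3) * (total_reads / 1e6))
}

#' Population-ubiquity filter for transcribed regions
#'
#' For each population, the set of regions expressed at `>= min_rpkm` in
#' every individual of that population; each such region is additionally
#' checked for presence (`>= min_rpkm` in at least one individual) outside
#' the population, flagging population-private regions.
#'
#' @param rpkm Region x individual RPKM matrix.
#' @param labels Population labels.
#' @param min_rpkm Expression cutoff (default 1).
#' @return Tibble: `region`, `population`, `ubiquitous`,
#'   `present_outside` (NA when not ubiquitous anywhere).
#' @export
ubiquity_filter <- function(rpkm, labels, min_rpkm = 1) {
  lab <- as_population_map(labels, colnames(rpkm))
  pops <- unique(lab)
  regions <- rownames(rpkm) %||% as.character(seq_len(nrow(rpkm)))
  rows <- lapply(pops, function(pp) {
    inp <- lab == pp
    ubiq <- rowSums(rpkm[, inp, drop = FALSE] >= min_rpkm) == sum(inp)
    outside <- rowSums(rpkm[, !inp, drop = FALSE] >= min_rpkm) > 0
    tibble(region = regions, population = pp, ubiquitous = unname(ubiq),
           present_outside = unname(ifelse(ubiq, outside, NA)))
  })
  list_rbind(rows)
}
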
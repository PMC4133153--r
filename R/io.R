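#' Read a minimal VCF into a genotype matrix
#'
#' Parses a VCF 4.x file with a GT field, keeping biallelic SNV records only.
#' Genotypes are encoded as alternate-allele dosages: `0/0` is 0, `0/1` and
#' `1/0` (and the phased forms) are 1, `1/1` is 2, and `./.` is missing
#' (`NA`). Multi-allelic records are skipped and counted.
#'
#' @param path Path to an (uncompressed) VCF file.
#' @return A list with `dosage` (integer matrix, individuals x sites, with
#'   individual ids as rownames and site ids `contig:pos` as colnames),
#'   `sites` (a tibble with columns `site`, `contig`, `pos` (1-based),
#'   `ref`, `alt`) and `n_skipped`, the number of multi-allelic records
#'   dropped.
#' @export
read_vcf_lite <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort(sprintf("malformed VCF header in %s: no #CHROM line", path))
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) abort(sprintf("VCF %s has no sample columns (line %d)", path, hdr[1]))
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  n_skipped <- 0L
  rows <- list(); sites <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE)) { n_skipped <- n_skipped + 1L; next }
    gt_idx <- match("GT", strsplit(f[9], ":", fixed = TRUE)[[1]])
    if (is.na(gt_idx)) abort(sprintf("record without GT at line %d of %s", hdr[1] + i, path))
    gts <- vapply(f[-(1:9)], function(s) strsplit(s, ":", fixed = TRUE)[[1]][gt_idx], character(1))
    al <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    dos <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
    rows[[length(rows) + 1L]] <- dos
    sites[[length(sites) + 1L]] <- tibble(
      site = paste0(f[1], ":", f[2]), contig = f[1], pos = as.integer(f[2]),
      ref = f[4], alt = f[5]
    )
  }
  sites <- if (length(sites)) list_rbind(sites) else
    tibble(site = character(), contig = character(), pos = integer(),
           ref = character(), alt = character())
  dosage <- if (length(rows)) t(matrix(unlist(rows), ncol = length(rows))) else
    matrix(integer(), 0, length(samples))
  dosage <- t(dosage)            # individuals x sites
  if (length(rows)) {
    dimnames(dosage) <- list(samples, sites$site)
  } else {
    rownames(dosage) <- samples
  }
  list(dosage = dosage, sites = sites, n_skipped = n_skipped)
}

#' Write a genotype matrix as a minimal VCF
#'
#' @param dosage Integer matrix, individuals x sites (values 0/1/2 or `NA`).
#' @param sites Tibble as returned by [read_vcf_lite()].
#' @param path Output path.
#' @export
write_vcf_lite <- function(dosage, sites, path) {
  stopifnot(ncol(dosage) == nrow(sites))
  gt <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosage)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(j) {
    g <- dosage[, j]
    gts <- ifelse(is.na(g), "./.", gt[g + 1L])
    paste(c(sites$contig[j], sites$pos[j], sites$site[j], sites$ref[j],
            sites$alt[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  readr::write_lines(c(lines, body), path)
}

#' Read/write a numeric feature-by-sample matrix as TSV
#'
#' The interchange dialect is TSV with a header line, the first column
#' holding feature ids, and `#`-prefixed comment lines ignored.
#'
#' @param path File path.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @param m Numeric matrix with dimnames.
#' @param id_name Header name for the feature-id column.
#' @rdname read_tsv_matrix
#' @export
write_tsv_matrix <- function(m, path, id_name = "feature") {
  df <- as_tibble(m, rownames = id_name)
  readr::write_tsv(df, path)
}

#' Read exon/region intervals from BED or GTF-lite
#'
#' BED is parsed as 0-based half-open. GTF-lite `exon` lines are 1-based
#' inclusive and converted to 0-based half-open (`start-1`, `end`).
#' Records with non-positive length are rejected with a warning.
#'
#' @param path File path.
#' @param format `"bed"` or `"gtf"`.
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open)
#'   and `name`.
#' @export
read_intervals <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- readr::read_tsv(path, comment = "#", col_names = FALSE, show_col_types = FALSE)
    out <- tibble(contig = as.character(df[[1]]), start = as.integer(df[[2]]),
                  end = as.integer(df[[3]]),
                  name = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_)
  } else {
    df <- readr::read_tsv(path, comment = "#", col_names = FALSE, show_col_types = FALSE)
    df <- df[df[[3]] == "exon", , drop = FALSE]
    out <- tibble(contig = as.character(df[[1]]),
                  start = as.integer(df[[4]]) - 1L, end = as.integer(df[[5]]),
                  name = NA_character_)
  }
  bad <- out$end <= out$start
  if (any(bad)) {
    warn(sprintf("%d interval(s) with end <= start rejected", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' @param intervals Tibble with `contig`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @rdname read_intervals
#' @export
write_bed <- function(intervals, path) {
  df <- tibble(contig = intervals$contig, start = intervals$start, end = intervals$end)
  extra <- setdiff(names(intervals), c("contig", "start", "end"))
  for (nm in extra) df[[nm]] <- intervals[[nm]]
  readr::write_tsv(df, path, col_names = FALSE)
}

#' Read/write per-base coverage as bedGraph-like TSV
#'
#' Four columns (contig, start, end, depth; 0-based half-open runs); a
#' `# total_reads=<n>` comment line carries the library size used for
#' threshold scaling. Zero-depth runs may be omitted in the file.
#'
#' @param path File path.
#' @return A list of coverage tracks, each a list with `contig`, `depth`
#'   (integer vector over bases 0..L-1) and `total_reads`.
#' @export
read_coverage <- function(path) {
  lines <- readr::read_lines(path)
  total <- 0
  tl <- grep("^# *total_reads=", lines, value = TRUE)
  if (length(tl)) total <- as.numeric(sub("^# *total_reads=", "", tl[1]))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- tibble(contig = vapply(parts, `[[`, "", 1),
               start = as.integer(vapply(parts, `[[`, "", 2)),
               end = as.integer(vapply(parts, `[[`, "", 3)),
               depth = as.numeric(vapply(parts, `[[`, "", 4)))
  lapply(split(df, df$contig), function(d) {
    len <- max(d$end)
    depth <- integer(len)
    for (i in seq_len(nrow(d))) depth[(d$start[i] + 1L):d$end[i]] <- d$depth[i]
    list(contig = d$contig[1], depth = depth, total_reads = total)
  })
}

#' @param tracks List of coverage tracks (see Value of `read_coverage`).
#' @rdname read_coverage
#' @export
write_coverage <- function(tracks, path) {
  out <- c(sprintf("# total_reads=%.10g", tracks[[1]]$total_reads))
  for (tr in tracks) {
    r <- rle(tr$depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values > 0
    # always keep the final run (even when zero) so the track length
    # survives a round trip
    keep[length(keep)] <- TRUE
    out <- c(out, sprintf("%s\t%d\t%d\t%g", tr$contig, starts[keep],
                          ends[keep], r$values[keep]))
  }
  readr::write_lines(out, path)
}

#' Read/write transcript abundances in long format
#'
#' Long TSV with columns `gene`, `transcript`, `sample`, `fpkm`, converted
#' to/from the per-gene matrix list used by the splicing stack.
#'
#' @param path File path.
#' @return Named list: per gene an individuals x transcripts matrix.
#' @export
read_abundance_long <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("gene", "transcript", "sample", "fpkm") %in% names(df)))
  lapply(split(df, df$gene), function(d) {
    w <- tidyr::pivot_wider(d, id_cols = "sample", names_from = "transcript",
                            values_from = "fpkm")
    m <- as.matrix(w[, -1, drop = FALSE])
    rownames(m) <- w$sample
    m
  })
}

#' @param tensor Named list of individuals x transcripts matrices.
#' @rdname read_abundance_long
#' @export
write_abundance_long <- function(tensor, path) {
  rows <- imap(tensor, function(m, g) {
    tibble(gene = g,
           transcript = rep(colnames(m), each = nrow(m)),
           sample = rep(rownames(m), times = ncol(m)),
           fpkm = as.vector(m))
  })
  readr::write_tsv(list_rbind(rows), path)
}

#' Read/write an individual-to-population map
#'
#' @param path TSV with columns `individual` and `population`.
#' @return Tibble with those two columns.
#' @export
read_population_map <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("individual", "population") %in% names(df)))
  tibble(individual = as.character(df$individual),
         population = as.character(df$population))
}

#' @param labels Data frame with `individual`, `population`.
#' @rdname read_population_map
#' @export
write_population_map <- function(labels, path) {
  readr::write_tsv(labels[, c("individual", "population")], path)
}
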
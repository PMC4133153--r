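# Small shared fixtures, generated in code.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 30, n_sites = 120, n_tracks = 2, track_length = 4000,
         segments_per_track = 3, seed = 42),
    list(...))
  do.call(sim_config, args)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_config())
    cache
  }
})

# Independent brute-force region caller: per-base scan with explicit
# repeated gap merging, used as the oracle for call_regions().
brute_force_regions <- function(depth, total_reads, threshold_per_million = 0.05,
                                merge_gap = 15) {
  cutoff <- threshold_per_million * total_reads / 1e6
  regs <- list()
  i <- 1
  while (i <= length(depth)) {
    if (depth[i] >= cutoff) {
      j <- i
      while (j < length(depth) && depth[j + 1] >= cutoff) j <- j + 1
      regs[[length(regs) + 1]] <- c(i - 1, j)  # 0-based half-open
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(regs)) {
    return(data.frame(start = integer(0), end = integer(0),
                      expression = numeric(0)))
  }
  m <- do.call(rbind, regs)
  repeat {
    if (nrow(m) < 2) break
    merged <- FALSE
    for (k in seq_len(nrow(m) - 1)) {
      if (m[k + 1, 1] - m[k, 2] < merge_gap) {
        m[k, 2] <- m[k + 1, 2]
        m <- m[-(k + 1), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  data.frame(start = m[, 1], end = m[, 2],
             expression = vapply(seq_len(nrow(m)),
                                 function(k) max(depth[(m[k, 1] + 1):m[k, 2]]),
                                 numeric(1)))
}

# Independent oracle for the two-sided exact binomial p-value.
binom_p2_oracle <- function(x, n, p0) {
  stats::binom.test(x, n, p0)$p.value
}

# Random probability vector.
runif_simplex <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}
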
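# Internal helpers: seeded substreams, argument checks, small numerics.

# Deterministic 31-bit seed for a named substream of a base seed, so that
# e.g. adding genes to a config does not reshuffle the genotype draws.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  # multipliers kept small so all intermediates stay exact in doubles
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 69621 + 1) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, stream).
with_substream <- function(seed, stream, expr) {
  force(seed); force(stream)   # before the RNG-state snapshot
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}

assert_fraction <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && all(x >= 0) && all(if (open_upper) x < 1 else x <= 1)
  if (!ok) abort(sprintf("`%s` must lie in [0,%s]", name, if (open_upper) "1)" else "1]"))
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || any(x != floor(x)) || any(x < min)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(x)
}

# Population labels: accepts a two-column data frame (individual, population)
# or a named character vector; returns a named character vector aligned to
# `individuals` when given.
as_population_map <- function(labels, individuals = NULL) {
  if (is.data.frame(labels)) {
    stopifnot(ncol(labels) >= 2)
    lab <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  } else if (!is.null(names(labels))) {
    lab <- setNames(as.character(labels), names(labels))
  } else if (!is.null(individuals) && length(labels) == length(individuals)) {
    lab <- setNames(as.character(labels), individuals)
  } else {
    abort("`labels` must map individual ids to population labels")
  }
  if (!is.null(individuals)) {
    missing <- setdiff(individuals, names(lab))
    if (length(missing)) {
      abort(paste0("unlabeled individuals: ", paste(head(missing, 5), collapse = ", ")))
    }
    lab <- lab[individuals]
  }
  lab
}

# Round half to even (banker's rounding), as base round() already does.
round_half_even <- function(x) round(x)

# Upper-triangle (excluding diagonal) of a square matrix, by column.
upper_tri_vec <- function(m) m[upper.tri(m)]
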
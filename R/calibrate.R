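# Calibration of planted population shifts. Both helpers work from a
# pilot null cohort (same configuration, shifts disabled) whose log-scale
# noise moments identify the shift magnitude solving the expected
# sums-of-squares identities of the distance-based decomposition. The
# rules are closed-form and fixed; they do not look at downstream results.

# Noise moments of log2 t' from a pilot cohort: `trace` is the expected
# within-individual noise variance summed over transcripts (the trace of
# the per-gene noise covariance), `var_e` the within-group variance of
# log2 e, `ssb_s` the mean between-group SS of log2 splicing ratios.
pilot_moments <- function(config) {
  pilot <- config
  pilot$pop_expression_sd <- 0
  pilot$frac_de_genes <- 0
  pilot$frac_eqtl_genes <- 0
  pilot$seed <- substream_seed(config$seed, "calibration_pilot")
  pilot$n_genes <- min(config$n_genes, 200L)
  co <- simulate_cohort(pilot)
  lab <- as_population_map(co$labels)
  prof <- splicing_profile(co$tensor)
  n <- length(lab); G <- length(unique(lab))
  within_ss <- function(x) {
    sum(vapply(split(x, lab), function(v) sum((v - mean(v))^2), numeric(1)))
  }
  between_ss <- function(x) {
    gm <- mean(x)
    sum(vapply(split(x, lab), function(v) length(v) * (mean(v) - gm)^2,
               numeric(1)))
  }
  tr <- mean(vapply(prof, function(pr) {
    L <- log2(pr$t)
    sum(apply(L, 2, within_ss)) / (n - G)
  }, numeric(1)))
  var_e <- mean(vapply(prof, function(pr) within_ss(log2(pr$e)) / (n - G),
                       numeric(1)))
  ssb_s <- mean(vapply(prof, function(pr) {
    sum(apply(log2(pr$s), 2, between_ss))
  }, numeric(1)))
  list(trace = tr, var_e = var_e, ssb_s = ssb_s, n = n, G = G,
       n_pop = n / G, T = config$transcripts_per_gene)
}

#' Calibrate population expression shifts to a target attributable fraction
#'
#' Returns a copy of `config` whose per-population expression shift scale
#' makes the expected between-group share of the total sum of squares of
#' `log2 t'` equal to `target_f`, using the identity
#' `E[SSB]/E[SST] = (S + (G-1)V) / (S + (n-1)V)` with `V` the noise trace
#' estimated from a pilot null cohort and
#' `S = T n_pop (G-1) pop_expression_sd^2` the planted signal. All genes
#' receive shifts (`frac_de_genes = 1`). A target of zero disables shifts;
#' targets below the estimator's null floor `(G-1)/(n-1)` are not reachable
#' by any non-negative shift scale and also return zero shifts.
#'
#' @param config A [sim_config()].
#' @param target_f Target attributable fraction in `[0, 1)`.
#' @return A modified `sim_config`.
#' @export
calibrate_expression_shift <- function(config, target_f) {
  assert_fraction(target_f, "target_f", open_upper = TRUE)
  out <- config
  out$frac_de_genes <- 1
  if (target_f == 0) {
    out$pop_expression_sd <- 0
    out$frac_de_genes <- 0
    return(out)
  }
  m <- pilot_moments(config)
  S <- m$trace * (target_f * (m$n - 1) - (m$G - 1)) / (1 - target_f)
  tau2 <- max(0, S / (m$T * m$n_pop * (m$G - 1)))
  out$pop_expression_sd <- sqrt(tau2)
  out
}

#' Calibrate expression shifts to balance expression and splicing shares
#'
#' Given a configuration with a planted splicing shift, sets the
#' expression-shift scale so that the expected scaled expression
#' between-group sum of squares (`T * SSB_E`) matches the expected
#' splicing between-group sum of squares under the generator, making the
#' expected expression share one half. Both effect classes are planted in
#' every gene.
#'
#' @param config A [sim_config()] with `pop_splicing_shift > 0`.
#' @return A modified `sim_config` with `frac_de_genes = frac_ds_genes = 1`.
#' @export
calibrate_equal_shares <- function(config) {
  if (config$pop_splicing_shift <= 0) {
    abort("config must plant a splicing shift (pop_splicing_shift > 0)")
  }
  pilot <- config
  pilot$frac_ds_genes <- 1
  m <- pilot_moments(pilot)
  tau2 <- max(0, (m$ssb_s / (m$T * (m$G - 1)) - m$var_e) / m$n_pop)
  out <- config
  out$frac_de_genes <- 1
  out$frac_ds_genes <- 1
  out$pop_expression_sd <- sqrt(tau2)
  out
}
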
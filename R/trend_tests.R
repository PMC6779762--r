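#' Bootstrap replicates of a channel-capacity estimate
#'
#' Resamples realizations (with replacement, independently per input level),
#' re-estimates the channel at time `t` and recomputes the capacity. The
#' replicate spread quantifies estimator noise for the ordering and
#' equivalence checks of the trend analyses; the reference orderings come
#' with no published test statistic, so a one-sided bootstrap at the 0.05
#' level is used throughout.
#'
#' @param ensembles list of `trajectory_ensemble`, one per input level.
#' @param species species name.
#' @param t time on the sample grid.
#' @param bins response bins.
#' @param n_boot number of resamples.
#' @param seed seed for the resampling stream.
#' @param tol_bits Arimoto-Blahut tolerance (looser than the point estimate:
#'   resampling noise dominates).
#' @return Numeric vector of `n_boot` capacity replicates (bits).
#' @export
bootstrap_cc <- function(ensembles, species, t, bins = 64, n_boot = 200,
                         seed = 1L, tol_bits = 1e-5) {
  ti <- time_index(ensembles[[1]], t)
  counts <- lapply(ensembles, function(e) e$counts[, ti, species])
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) {
    res <- lapply(counts, function(x) x[sample.int(length(x), replace = TRUE)])
    arimoto_blahut(channel_from_counts(res, bins), tol_bits)$cc_bits
  }, numeric(1))
}

#' Bootstrap replicates of a gene-set MMI estimate
#'
#' As [bootstrap_cc()], but re-estimates one channel per gene from the same
#' resampled realizations and recomputes the multivariate mutual
#' information.
#'
#' @inheritParams bootstrap_cc
#' @param species_vec reporter protein species forming the set.
#' @return Numeric vector of `n_boot` MMI replicates (bits).
#' @export
bootstrap_mmi <- function(ensembles, species_vec, t, bins = 64, n_boot = 100,
                          seed = 1L, tol_bits = 1e-4) {
  ti <- time_index(ensembles[[1]], t)
  counts <- lapply(ensembles, function(e) e$counts[, ti, species_vec, drop = FALSE])
  n <- dim(counts[[1]])[1]
  set.seed(seed)
  vapply(seq_len(n_boot), function(b) {
    idx <- lapply(counts, function(x) sample.int(n, replace = TRUE))
    chans <- lapply(species_vec, function(sp) {
      channel_from_counts(Map(function(x, i) x[i, 1, sp], counts, idx), bins)
    })
    mmi(chans, tol_bits = tol_bits)
  }, numeric(1))
}

#' One-sided bootstrap p-value for "A exceeds B"
#'
#' Fraction of replicate pairs in which the claimed ordering fails; below
#' 0.05 the ordering is accepted.
#'
#' @param boot_a,boot_b replicate vectors (equal length).
#' @return p-value in `[0, 1]`.
#' @export
p_boot_greater <- function(boot_a, boot_b) {
  mean(boot_a - boot_b <= 0)
}

#' Equivalence within bootstrap spread
#'
#' TRUE when the observed difference of two estimates is within two
#' bootstrap standard deviations of the replicate difference -- the "no
#' significant difference" reading used for equal-capacity checks.
#'
#' @param boot_a,boot_b replicate vectors.
#' @return Logical.
#' @export
boot_equivalent <- function(boot_a, boot_b) {
  d <- boot_a - boot_b
  abs(mean(d)) <= 2 * stats::sd(d)
}

#' Time of the capacity peak
#'
#' @param cc_df a [cc_timeseries()] table.
#' @return The sample time at which `cc` is maximal.
#' @export
peak_time <- function(cc_df) {
  cc_df$time[which.max(cc_df$cc)]
}
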
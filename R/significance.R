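# Empirical significance of rEHH. Following the long-range haplotype test,
# rEHH values are stratified into 20 core-allele-frequency bins of 5% each,
# log-transformed within bin to approximate normality, and a one-sided
# upper-tail p-value is read off the fitted normal. Distributions are fit
# per breed and per direction on ALL core alleles; the >25% frequency rule
# only gates which alleles are reported, not the null distribution.

#' Assign a core-allele frequency to its 5% bin
#'
#' Bins are left-closed, right-open: bin k covers \[0.05k, 0.05(k+1)),
#' except bin 19 which also includes 1.0.
#'
#' @param freq frequency (vector allowed) in (0, 1\].
#' @param bin_width bin width (default 0.05, i.e. 20 bins).
#' @return integer bin index in 0..19.
#' @export
bin_assign <- function(freq, bin_width = 0.05) {
  if (any(!is.finite(freq)) || any(freq <= 0) || any(freq > 1))
    rehh_abort("frequency must lie in (0, 1]", "rehhscan_domain_error")
  nb <- round(1 / bin_width)
  idx <- as.integer(floor(freq / bin_width + 1e-9))
  pmin(idx, nb - 1L)
}

#' Fit frequency-binned log-rEHH null distributions
#'
#' Natural-log transforms the rEHH values, groups them by frequency bin,
#' recursively merges bins with fewer than `min_bin_count` members into
#' their nearest non-empty neighbour, and fits a normal (mean, sd) per
#' merged group.
#'
#' @param rehh_values finite, positive rEHH values (one per core allele and
#'   direction).
#' @param freqs matching core-allele frequencies in (0, 1\].
#' @param min_bin_count minimum members per bin before merging (default 10).
#' @param bin_width frequency bin width (default 0.05).
#' @return object of class `freq_bins`: list with `bins` (data.frame: bin,
#'   lo, hi, group, n, mean, sd per original bin) and `groups` (data.frame:
#'   group, n, mean, sd).
#' @export
fit_bins <- function(rehh_values, freqs, min_bin_count = 10L,
                     bin_width = 0.05) {
  if (length(rehh_values) != length(freqs))
    rehh_abort("rehh_values and freqs must have equal length",
               "rehhscan_dimension_error")
  if (any(!is.finite(rehh_values)) || any(rehh_values <= 0))
    rehh_abort("rEHH values must be finite and > 0 (filter sentinels first)",
               "rehhscan_domain_error")
  nb <- round(1 / bin_width)
  bin <- bin_assign(freqs, bin_width)
  logv <- log(rehh_values)
  group <- seq_len(nb) - 1L            # group id per original bin
  counts <- tabulate(bin + 1L, nbins = nb)
  # merge: smallest under-filled non-empty group joins nearest non-empty
  repeat {
    gsize <- vapply(unique(group[counts > 0]), function(g)
      sum(counts[group == g]), numeric(1))
    names(gsize) <- unique(group[counts > 0])
    small <- names(gsize)[gsize < min_bin_count]
    if (!length(small) || length(gsize) <= 1L) break
    g <- as.integer(small[which.min(gsize[small])])
    gbins <- which(group == g) - 1L
    others <- setdiff(as.integer(names(gsize)), g)
    dist <- vapply(others, function(o) {
      obins <- which(group == o) - 1L
      min(abs(outer(gbins, obins, "-")))
    }, numeric(1))
    target <- others[order(dist, others)][1]   # tie -> lower group id
    group[group == g] <- target
  }
  groups <- sort(unique(group[counts > 0]))
  fit <- lapply(groups, function(g) {
    v <- logv[group[bin + 1L] == g]
    list(n = length(v), mean = mean(v), sd = stats::sd(v))
  })
  gdf <- data.frame(group = groups,
                    n = vapply(fit, `[[`, numeric(1), "n"),
                    mean = vapply(fit, `[[`, numeric(1), "mean"),
                    sd = vapply(fit, `[[`, numeric(1), "sd"))
  if (any(is.na(gdf$sd) | gdf$sd == 0))
    rehh_abort("degenerate bin: zero variance after merging",
               "rehhscan_degenerate_bin_error")
  bins <- data.frame(bin = seq_len(nb) - 1L,
                     lo = (seq_len(nb) - 1L) * bin_width,
                     hi = seq_len(nb) * bin_width,
                     group = group,
                     n = counts)
  bins$mean <- gdf$mean[match(bins$group, gdf$group)]
  bins$sd <- gdf$sd[match(bins$group, gdf$group)]
  structure(list(bins = bins, groups = gdf, bin_width = bin_width),
            class = "freq_bins")
}

#' Empirical p-value of an rEHH value
#'
#' One-sided upper-tail by default (positive selection inflates rEHH):
#' p = 1 - Phi((log rEHH - mean) / sd) in the value's frequency bin.
#'
#' @param bins a `freq_bins` fit from [fit_bins()].
#' @param rehh_value positive finite rEHH value(s).
#' @param freq matching core-allele frequency(ies).
#' @param tail `"upper"` (default) or `"two_sided"`.
#' @return data.frame with `p` and `neg_log10_p`.
#' @export
empirical_p <- function(bins, rehh_value, freq,
                        tail = c("upper", "two_sided")) {
  tail <- match.arg(tail)
  if (!inherits(bins, "freq_bins"))
    rehh_abort("bins must be a fitted freq_bins object",
               "rehhscan_state_error")
  b <- bin_assign(freq, bins$bin_width)
  mu <- bins$bins$mean[b + 1L]
  sdv <- bins$bins$sd[b + 1L]
  if (any(is.na(sdv)))
    rehh_abort("value falls in an unfitted bin", "rehhscan_state_error")
  z <- (log(rehh_value) - mu) / sdv
  p <- if (tail == "upper") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(p = p, neg_log10_p = -log10(p))
}

#' Flag retained and significant core alleles
#'
#' Applies the reporting rules to a per-core-allele results table:
#' retained iff frequency > `min_freq`; significant (per direction) iff
#' retained and p <= `alpha`; `significant` is the OR of the two
#' directions.
#'
#' @param results data.frame with columns `freq`, `logp_up`, `logp_down`
#'   (-log10 p, NA when undefined).
#' @param alpha significance level (default 0.05).
#' @param min_freq retention threshold on core-allele frequency
#'   (default 0.25, exclusive).
#' @return `results` with logical columns `retained`, `sig_up`,
#'   `sig_down`, `significant` added/overwritten.
#' @export
select_significant <- function(results, alpha = 0.05, min_freq = 0.25) {
  thr <- -log10(alpha)
  results$retained <- results$freq > min_freq
  results$sig_up <- results$retained & !is.na(results$logp_up) &
    results$logp_up >= thr
  results$sig_down <- results$retained & !is.na(results$logp_down) &
    results$logp_down >= thr
  results$significant <- results$sig_up | results$sig_down
  results
}
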
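# Per-breed scan: MAF filter -> core detection -> per-core-allele rEHH in
# both directions -> frequency-binned empirical significance. This is the
# workhorse behind the `scan` and `run` entry points; the exported
# single-allele operations (ehh_at, rehh, ...) define the semantics and
# this driver computes the same quantities batched per (core, direction).

#' Scan one breed for rEHH selection signatures
#'
#' @param hapset a phased, QC'd [haplotype_set()].
#' @param min_maf markers below this MAF are dropped before core detection
#'   (default 0.05; drift-fixed markers are uninformative for LD).
#' @param min_snps,max_snps,strong_frac,strong_lower,strong_upper,recomb_upper
#'   core-detection parameters, see [find_cores()].
#' @param test_distance_cm rEHH evaluation distance (default 0.25 cM).
#' @param alpha significance level (default 0.05).
#' @param min_freq retention threshold on core-allele frequency
#'   (default 0.25).
#' @param min_bin_count minimum members per frequency bin before merging
#'   (default 10).
#' @param tail `"upper"` or `"two_sided"` empirical test.
#' @return list of class `rehh_scan`:
#'   \describe{
#'     \item{results}{data.frame, one row per (core, allele): breed, chrom,
#'       core bp range and indices, n_snps, allele, carriers, freq, ehh/rehh
#'       up+down, -log10 p up+down, retained / sig_up / sig_down /
#'       significant flags. rEHH may be `Inf` (pooled EHH zero) or `NA`
#'       (undefined); such values carry NA p-values.}
#'     \item{cores}{the `core_regions` table (indices into `hapset_used`).}
#'     \item{hapset_used}{the MAF-filtered haplotype set the scan ran on.}
#'     \item{bins_up, bins_down}{`freq_bins` fits (NULL if not fittable).}
#'   }
#' @export
scan_breed <- function(hapset, min_maf = 0.05, min_snps = 3L,
                       max_snps = 20L, strong_frac = 0.95,
                       strong_lower = 0.70, strong_upper = 0.98,
                       recomb_upper = 0.90, test_distance_cm = 0.25,
                       alpha = 0.05, min_freq = 0.25, min_bin_count = 10L,
                       tail = "upper") {
  p <- colMeans(hapset$hap)
  keep <- pmin(p, 1 - p) >= min_maf
  hs <- subset_markers(hapset, which(keep))
  cores <- find_cores(hs, min_snps, max_snps, strong_frac, strong_lower,
                      strong_upper, recomb_upper)
  rows <- list()
  for (ci in seq_len(nrow(cores))) {
    core <- cores[ci, ]
    al <- core_alleles(core, hs)
    core_str <- hap_strings(hs$hap, core$start_idx:core$end_idx)
    stat <- list(up = NULL, down = NULL)
    for (dir in c("up", "down")) {
      x <- pick_test_marker(hs$map, core, dir, test_distance_cm)
      if (is.null(x) || is.na(x)) { stat[[dir]] <- NULL; next }
      cols <- ehh_span(core, x)
      ext <- hap_strings(hs$hap, cols)
      num <- den <- numeric(nrow(al))
      for (t in seq_len(nrow(al))) {
        e <- group_counts(ext[core_str == al$allele[t]])
        num[t] <- sum(nchoose2(e))
        den[t] <- nchoose2(al$carriers[t])
      }
      ehh_t <- ifelse(al$carriers >= 2L, num / den, NA_real_)
      n_other <- sum(al$carriers) - al$carriers
      pooled <- (sum(num) - num) / nchoose2(n_other)
      pooled[n_other < 2L] <- NA_real_
      r <- ifelse(is.na(ehh_t) | is.na(pooled), NA_real_,
            ifelse(pooled > 0, ehh_t / pooled,
                   ifelse(ehh_t > 0, Inf, NA_real_)))
      stat[[dir]] <- list(ehh = ehh_t, rehh = r)
    }
    na <- rep(NA_real_, nrow(al))
    rows[[ci]] <- data.frame(
      breed = hs$breed, chrom = core$chrom,
      core_start_bp = core$start_bp, core_end_bp = core$end_bp,
      start_idx = core$start_idx, end_idx = core$end_idx,
      n_snps = core$n_snps, allele = al$allele, carriers = al$carriers,
      freq = al$freq,
      ehh_up = if (is.null(stat$up)) na else stat$up$ehh,
      ehh_down = if (is.null(stat$down)) na else stat$down$ehh,
      rehh_up = if (is.null(stat$up)) na else stat$up$rehh,
      rehh_down = if (is.null(stat$down)) na else stat$down$rehh,
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame(
    breed = character(0), chrom = character(0),
    core_start_bp = numeric(0), core_end_bp = numeric(0),
    start_idx = integer(0), end_idx = integer(0), n_snps = integer(0),
    allele = character(0), carriers = integer(0), freq = numeric(0),
    ehh_up = numeric(0), ehh_down = numeric(0), rehh_up = numeric(0),
    rehh_down = numeric(0))
  rownames(results) <- NULL

  bins <- list(up = NULL, down = NULL)
  for (dir in c("up", "down")) {
    v <- results[[paste0("rehh_", dir)]]
    logp <- rep(NA_real_, nrow(results))
    ok <- which(is.finite(v) & v > 0)
    if (length(ok) >= 2L) {
      fit <- tryCatch(
        fit_bins(v[ok], results$freq[ok], min_bin_count),
        rehhscan_degenerate_bin_error = function(e) NULL)
      if (!is.null(fit)) {
        pp <- empirical_p(fit, v[ok], results$freq[ok], tail)
        logp[ok] <- pp$neg_log10_p
        bins[[dir]] <- fit
        # infinite rEHH (pooled EHH 0, EHH_t > 0) is the extreme upper
        # tail: excluded from the fit, reported with p = 0
        logp[is.infinite(v) & v > 0] <- Inf
      }
    }
    results[[paste0("logp_", dir)]] <- logp
  }
  results <- select_significant(results, alpha, min_freq)
  structure(list(results = results, cores = cores, hapset_used = hs,
                 bins_up = bins$up, bins_down = bins$down),
            class = "rehh_scan")
}

#' @export
print.rehh_scan <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "rehh_scan [%s]: %d cores, %d core alleles (%d retained, %d significant)\n",
    if (nrow(r)) r$breed[1] else "?", nrow(x$cores), nrow(r),
    sum(r$retained), sum(r$significant)))
  invisible(x)
}

#' Significant core regions of a scan
#'
#' A core region is significant when at least one of its retained alleles
#' is significant in at least one direction.
#'
#' @param scan an `rehh_scan` from [scan_breed()].
#' @return a `core_regions` data.frame (subset of `scan$cores`, indices
#'   into `scan$hapset_used`).
#' @export
significant_cores <- function(scan) {
  r <- scan$results
  sig <- unique(r[r$significant,
                  c("chrom", "core_start_bp", "core_end_bp")])
  keep <- paste(scan$cores$chrom, scan$cores$start_bp) %in%
    paste(sig$chrom, sig$core_start_bp)
  out <- scan$cores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
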
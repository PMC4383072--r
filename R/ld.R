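# Pairwise linkage disequilibrium from phased haplotypes and the
# breed-level decay curve. With phased data r-squared is computed directly
# from observed two-locus haplotype frequencies (no EM step):
#   r^2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))
# which equals the squared Pearson correlation of the two 0/1 columns.

#' Pairwise r-squared between two haplotype columns
#'
#' @param x,y 0/1 integer vectors over the same haplotypes.
#' @return r-squared in \[0, 1\].
#' @export
haplotype_r2 <- function(x, y) {
  px <- mean(x); py <- mean(y)
  if (px == 0 || px == 1 || py == 0 || py == 1)
    rehh_abort("r2 undefined at a monomorphic marker",
               "rehhscan_undefined_error")
  pxy <- mean(x == 1L & y == 1L)
  d <- pxy - px * py
  d * d / (px * (1 - px) * py * (1 - py))
}

#' LD decay curve
#'
#' Mean r-squared of all intra-chromosomal marker pairs, binned by
#' physical distance up to `max_dist`. Monomorphic markers are skipped.
#' Computed per chromosome and pooled.
#'
#' @param hapset a [haplotype_set()].
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param bin_width distance bin width in bp (default 50 kb).
#' @return data.frame of class `ld_decay` with `bin_start`, `bin_end`
#'   (bp, bins are (start, end\]), `mean_r2` (NA for empty bins),
#'   `n_pairs`.
#' @export
ld_decay <- function(hapset, max_dist = 1e6, bin_width = 5e4) {
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1L
  sum_r2 <- numeric(nb); n_pair <- integer(nb)
  H <- hapset$hap
  for (ch in unique(hapset$map$chrom)) {
    idx <- which(hapset$map$chrom == ch)
    if (length(idx) < 2L) next
    pos <- hapset$map$pos_bp[idx]
    p <- colMeans(H[, idx, drop = FALSE])
    poly <- p > 0 & p < 1
    for (a in seq_along(idx)[-length(idx)]) {
      if (!poly[a]) next
      bs <- which(pos - pos[a] > 0 & pos - pos[a] <= max_dist & poly)
      bs <- bs[bs > a]
      if (!length(bs)) next
      xa <- H[, idx[a]]
      r2 <- vapply(bs, function(b) haplotype_r2(xa, H[, idx[b]]), numeric(1))
      bin <- findInterval(pos[bs] - pos[a], edges, left.open = FALSE,
                          rightmost.closed = FALSE)
      # (start, end] binning: distance exactly on an edge belongs below
      on_edge <- (pos[bs] - pos[a]) == edges[bin]
      bin[on_edge] <- bin[on_edge] - 1L
      for (k in seq_along(bs)) {
        sum_r2[bin[k]] <- sum_r2[bin[k]] + r2[k]
        n_pair[bin[k]] <- n_pair[bin[k]] + 1L
      }
    }
  }
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    mean_r2 = ifelse(n_pair > 0, sum_r2 / pmax(n_pair, 1L),
                                     NA_real_),
                    n_pairs = n_pair)
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' Write an LD decay curve as TSV
#' @param curve an `ld_decay` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ld_decay <- function(curve, path) {
  fwrite_tsv(as.data.frame(curve), path)
  invisible(path)
}
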
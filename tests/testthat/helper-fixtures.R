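# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive re-implementations (pair scans, explicit
# enumeration) kept separate from the package's code paths.

tiny_map <- function(n, chrom = "1", spacing = 5e4, start = 1e5) {
  marker_map(sprintf("%s_snp%03d", chrom, seq_len(n)), chrom,
             start + (seq_len(n) - 1L) * spacing)
}

hs_from_matrix <- function(mat, breed = "A", map = NULL, spacing = 5e4) {
  mat <- as.matrix(mat)
  if (is.null(map)) map <- tiny_map(ncol(mat), spacing = spacing)
  haplotype_set(mat, sprintf("%s_s%03d", breed, seq_len(nrow(mat) / 2)),
                breed, map)
}

random_hapset <- function(seed, n_hap = 40, n_markers = 20, breed = "A",
                          spacing = 5e4) {
  set.seed(seed)
  p <- runif(n_markers, 0.2, 0.8)
  mat <- matrix(rbinom(n_hap * n_markers, 1, rep(p, each = n_hap)),
                n_hap, n_markers)
  hs_from_matrix(mat, breed, spacing = spacing)
}

# --- EHH oracle: all-pairs identity scan ----------------------------------

oracle_ehh <- function(hap, carriers, cols) {
  n <- length(carriers)
  hits <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (all(hap[carriers[i], cols] == hap[carriers[j], cols]))
      hits <- hits + 1L
  }
  hits / (n * (n - 1L) / 2)
}

# pooled-others oracle: fraction of non-carrier pairs identical over cols
oracle_ehh_pooled <- function(hap, others, cols) {
  oracle_ehh(hap, others, cols)
}

# --- |D'| likelihood-grid oracle ------------------------------------------

oracle_dprime_ci <- function(n11, n10, n01, n00, ci = 0.90) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = 101)
  lik <- sapply(grid, function(d) {
    dd <- sign(D + (D == 0)) * d * dmax
    pr <- c(pA * pB + dd, pA * (1 - pB) - dd,
            (1 - pA) * pB - dd, (1 - pA) * (1 - pB) + dd)
    pr <- pmax(pr, 0)
    cnt <- c(n11, n10, n01, n00)
    if (any(pr == 0 & cnt > 0)) return(0)
    prod(pr[cnt > 0] ^ cnt[cnt > 0])
  })
  w <- lik / sum(lik)
  cdf <- cumsum(w)
  list(dprime = abs(D) / dmax,
       lower = grid[which(cdf >= (1 - ci) / 2)[1]],
       upper = grid[which(cdf >= 1 - (1 - ci) / 2)[1]])
}

# --- core-finder oracle: exhaustive search over feasible span sets --------

# all intervals [i,j] of min..max markers meeting the strong-LD fraction,
# classification recomputed pair by pair through the exported primitives
oracle_candidates <- function(hs, min_snps = 3L, max_snps = 20L,
                              strong_frac = 0.95) {
  M <- ncol(hs$hap)
  out <- list()
  cls <- matrix(NA_character_, M, M)
  for (a in seq_len(M - 1L)) for (b in (a + 1L):min(M, a + max_snps - 1L)) {
    x <- hs$hap[, a]; y <- hs$hap[, b]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    cnt <- c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
             sum(x == 0 & y == 1), sum(x == 0 & y == 0))
    cls[a, b] <- classify_pair(dprime_ci(cnt))
  }
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (j - i + 1L < min_snps || j - i + 1L > max_snps || j > M) next
    sub <- cls[i:j, i:j]
    v <- sub[upper.tri(sub)]
    inf <- sum(v %in% c("strong_LD", "recombination"))  # informative only
    if (inf > 0 && sum(v == "strong_LD", na.rm = TRUE) / inf >= strong_frac)
      out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

# enumerate every maximal non-overlapping subset of candidates; return the
# one whose sorted rank sequence (under the stated ordering) is
# lexicographically smallest -- i.e. brute force over all feasible span
# sets, independent of the package's greedy loop.
oracle_select <- function(cands, pos) {
  if (!length(cands)) return(list())
  size <- vapply(cands, function(c) c[2] - c[1] + 1L, integer(1))
  bplen <- vapply(cands, function(c) pos[c[2]] - pos[c[1]], numeric(1))
  start <- vapply(cands, `[`, integer(1), 1L)
  inv <- order(order(-size, -bplen, start))   # candidate -> its rank
  k <- length(cands)
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  compat_with <- function(idx, chosen) {
    !any(vapply(chosen, function(c) overlap(cands[[idx]], cands[[c]]),
                logical(1)))
  }
  vec_less <- function(a, b) {
    n <- max(length(a), length(b))
    a2 <- c(a, rep(Inf, n - length(a)))
    b2 <- c(b, rep(Inf, n - length(b)))
    d <- which(a2 != b2)
    length(d) > 0 && a2[d[1]] < b2[d[1]]
  }
  best <- NULL
  recurse <- function(chosen, from) {
    added <- FALSE
    for (k2 in seq_len(k)) {
      if (compat_with(k2, chosen)) {
        added <- TRUE
        if (k2 >= from) recurse(c(chosen, k2), k2 + 1L)
      }
    }
    if (!added) {   # maximal set
      ranks <- sort(inv[chosen])
      if (is.null(best) || vec_less(ranks, best$ranks))
        best <<- list(ranks = ranks, chosen = chosen)
    }
  }
  recurse(integer(0), 1L)
  if (is.null(best)) return(list())
  lapply(best$chosen, function(i) cands[[i]])
}

# structured random chromosome: latent LD blocks with copy noise, so that
# candidate cores exist but are not everywhere
blocky_hapset <- function(seed, n_hap = 30, n_markers = 10) {
  set.seed(seed)
  nb <- sample(1:3, 1)
  bounds <- sort(sample(seq_len(n_markers - 1L), nb - 1))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n_markers)
  mat <- matrix(0L, n_hap, n_markers)
  for (b in seq_len(nb)) {
    base <- rbinom(n_hap, 1, runif(1, 0.3, 0.7))
    for (j in starts[b]:ends[b]) {
      col <- base
      nflip <- sample(0:2, 1, prob = c(0.7, 0.2, 0.1))
      if (nflip > 0) {
        k <- sample(n_hap, nflip)
        col[k] <- 1L - col[k]
      }
      if (length(unique(col)) == 1L) col[sample(n_hap, 2)] <- 1L - col[1]
      mat[, j] <- col
    }
  }
  hs_from_matrix(mat)
}

# --- shared-region oracle: iterative pairwise merging ---------------------

oracle_shared <- function(core_list) {
  # core_list: list of list(breed, chrom, start, end, snps)
  merged <- lapply(core_list, function(x) {
    x$members <- list(x); x
  })
  repeat {
    done <- TRUE
    for (i in seq_along(merged)) {
      if (is.null(merged[[i]])) next
      for (j in seq_along(merged)) {
        if (i == j || is.null(merged[[j]])) next
        if (merged[[i]]$chrom == merged[[j]]$chrom &&
            length(intersect(merged[[i]]$snps, merged[[j]]$snps))) {
          merged[[i]]$snps <- union(merged[[i]]$snps, merged[[j]]$snps)
          merged[[i]]$start <- min(merged[[i]]$start, merged[[j]]$start)
          merged[[i]]$end <- max(merged[[i]]$end, merged[[j]]$end)
          merged[[i]]$members <- c(merged[[i]]$members,
                                   merged[[j]]$members)
          merged[j] <- list(NULL)
          done <- FALSE
        }
      }
    }
    if (done) break
  }
  comps <- Filter(Negate(is.null), merged)
  keep <- Filter(function(m) {
    length(unique(vapply(m$members, `[[`, character(1), "breed"))) >= 2
  }, comps)
  keep
}
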
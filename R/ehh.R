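# Extended haplotype homozygosity. For a core allele t with c_t carrier
# chromosomes, EHH at marker x is the probability that two carriers drawn
# at random are identical by state over the whole interval from the core
# to x:
#   EHH_t(x) = sum_i C(e_i, 2) / C(c_t, 2)
# where e_i are the counts of the distinct extended haplotypes among the
# carriers. Relative EHH divides by the pooled homozygosity of all other
# core alleles at the same locus, which controls for local recombination
# rate. Distances are genetic (cM), measured from the core's outer marker.

# span of columns from the core to marker x (inclusive, includes the core)
ehh_span <- function(core, x_idx) {
  if (x_idx < core$start_idx) x_idx:core$end_idx else core$start_idx:x_idx
}

group_counts <- function(strings) {
  as.vector(table(strings))
}

#' EHH of a core allele at a marker
#'
#' @param hapset a [haplotype_set()].
#' @param carriers integer row indices of the haplotypes carrying the core
#'   allele (at least 2).
#' @param core list/row with `start_idx`, `end_idx` (core marker columns).
#' @param x_idx column index of the extension marker (may equal a core
#'   edge, giving EHH = 1 by construction).
#' @return EHH value in \[0, 1\].
#' @export
ehh_at <- function(hapset, carriers, core, x_idx) {
  ct <- length(carriers)
  if (ct < 2L)
    rehh_abort("EHH undefined for fewer than 2 carriers",
               "rehhscan_undefined_error")
  cols <- ehh_span(core, x_idx)
  e <- group_counts(hap_strings(hapset$hap[carriers, , drop = FALSE], cols))
  sum(nchoose2(e)) / nchoose2(ct)
}

#' Pooled EHH of the other core alleles
#'
#' EHH of all non-carrier chromosomes treated as one set: the probability
#' that two randomly drawn non-carriers are identical by state over core
#' plus extension. Two haplotypes count as homozygous only if they share a
#' core allele and its extension, so the numerator groups within each
#' non-tested allele while the denominator counts all non-carrier pairs.
#'
#' @param hapset a [haplotype_set()].
#' @param other_carriers list of integer row-index vectors, one per
#'   non-tested core allele.
#' @param core,x_idx as in [ehh_at()].
#' @return pooled EHH in \[0, 1\].
#' @export
ehh_pooled_others <- function(hapset, other_carriers, core, x_idx) {
  cs <- lengths(other_carriers)
  if (sum(cs) < 2L)
    rehh_abort("pooled EHH undefined for fewer than 2 non-carriers",
               "rehhscan_undefined_error")
  cols <- ehh_span(core, x_idx)
  num <- 0
  for (rows in other_carriers) {
    if (length(rows) < 2L) next
    e <- group_counts(hap_strings(hapset$hap[rows, , drop = FALSE], cols))
    num <- num + sum(nchoose2(e))
  }
  num / nchoose2(sum(cs))
}

#' EHH decay curve for one core allele
#'
#' Walks marker by marker away from the core edge (upstream = decreasing
#' bp, downstream = increasing) until EHH drops below `stop_ehh` or the
#' chromosome ends; the stopping sample is included. The first row is the
#' core edge itself (distance 0, EHH 1).
#'
#' @inheritParams ehh_at
#' @param direction `"up"` or `"down"`.
#' @param stop_ehh stop once EHH falls below this (default 0.05).
#' @return data.frame of class `ehh_curve`: `marker_idx`, `distance_bp`,
#'   `distance_cm`, `ehh`.
#' @export
ehh_decay <- function(hapset, carriers, core, direction = c("down", "up"),
                      stop_ehh = 0.05) {
  direction <- match.arg(direction)
  mp <- hapset$map
  edge <- if (direction == "up") core$start_idx else core$end_idx
  ch <- mp$chrom[edge]
  step <- if (direction == "up") -1L else 1L
  rows <- list(data.frame(marker_idx = edge, distance_bp = 0,
                          distance_cm = 0, ehh = 1))
  x <- edge + step
  while (x >= 1L && x <= nrow(mp) && mp$chrom[x] == ch) {
    v <- ehh_at(hapset, carriers, core, x)
    rows[[length(rows) + 1L]] <- data.frame(
      marker_idx = x,
      distance_bp = abs(mp$pos_bp[x] - mp$pos_bp[edge]),
      distance_cm = abs(mp$pos_cm[x] - mp$pos_cm[edge]),
      ehh = v)
    if (v < stop_ehh) break
    x <- x + step
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ehh_curve", "data.frame")
  out
}

# candidate extension marker nearest to test_distance_cm from the core
# edge; ties broken toward the farther marker. NULL when the chromosome
# ends before any marker, NA when the nearest lies beyond 2x the test
# distance.
pick_test_marker <- function(map, core, direction, test_distance_cm) {
  edge <- if (direction == "up") core$start_idx else core$end_idx
  ch <- map$chrom[edge]
  if (direction == "up") {
    cand <- which(map$chrom == ch & seq_len(nrow(map)) < core$start_idx)
  } else {
    cand <- which(map$chrom == ch & seq_len(nrow(map)) > core$end_idx)
  }
  if (!length(cand)) return(NULL)
  d <- abs(map$pos_cm[cand] - map$pos_cm[edge])
  gap <- abs(d - test_distance_cm)
  best <- which(gap == min(gap))
  pick <- best[which.max(d[best])]   # tie -> farther marker
  if (d[pick] > 2 * test_distance_cm && min(d) > 2 * test_distance_cm)
    return(NA_integer_)
  cand[pick]
}

#' Relative EHH of a core allele in one direction
#'
#' Evaluated at the marker whose genetic distance from the core's outer
#' marker is nearest to `test_distance_cm` (ties go to the farther
#' marker). rEHH = EHH_t / EHH_pooled. A pooled EHH of zero with positive
#' EHH_t yields `Inf` (reported, excluded from significance binning);
#' both zero yields `NA`.
#'
#' @param hapset a [haplotype_set()].
#' @param core list/row with `start_idx`, `end_idx`.
#' @param alleles allele table from [core_alleles()].
#' @param t row index into `alleles` of the tested allele.
#' @param direction `"up"` or `"down"`.
#' @param test_distance_cm scalar test distance (default 0.25 cM, i.e.
#'   250 kb under the flat 1 cM/Mb map).
#' @return list with `rehh`, `ehh_t`, `ehh_pooled`, `marker_idx`,
#'   `distance_cm`, or an error of class `rehhscan_missing_marker_error`
#'   when no marker lies within twice the test distance.
#' @export
rehh <- function(hapset, core, alleles, t, direction = c("down", "up"),
                 test_distance_cm = 0.25) {
  direction <- match.arg(direction)
  x <- pick_test_marker(hapset$map, core, direction, test_distance_cm)
  if (is.null(x) || is.na(x))
    rehh_abort(sprintf("no marker within 2 x %g cM %sstream of core",
                       test_distance_cm, direction),
               "rehhscan_missing_marker_error")
  strings <- hap_strings(hapset$hap, core$start_idx:core$end_idx)
  carriers <- lapply(alleles$allele, function(a) which(strings == a))
  ehh_t <- ehh_at(hapset, carriers[[t]], core, x)
  pooled <- ehh_pooled_others(hapset, carriers[-t], core, x)
  r <- if (pooled > 0) ehh_t / pooled
       else if (ehh_t > 0) Inf
       else NA_real_
  list(rehh = r, ehh_t = ehh_t, ehh_pooled = pooled, marker_idx = x,
       distance_cm = abs(hapset$map$pos_cm[x] -
                           hapset$map$pos_cm[if (direction == "up")
                             core$start_idx else core$end_idx]))
}

#' Haplotype bifurcation tree
#'
#' Traces how the carrier set of a core allele splits into distinct
#' extended haplotypes moving marker by marker away from the core: the
#' root holds all carriers; at each marker every node splits by the allele
#' its members carry there. Child counts always sum to the parent count.
#'
#' @inheritParams ehh_at
#' @param direction `"up"` or `"down"`.
#' @param max_markers how many markers outward to trace (default 10).
#' @return nested list (class `bifurcation_tree`): each node has `count`,
#'   `marker_idx` (NA at the root) and `children`.
#' @export
bifurcation <- function(hapset, carriers, core, direction = c("down", "up"),
                        max_markers = 10L) {
  direction <- match.arg(direction)
  if (length(carriers) < 2L)
    rehh_abort("bifurcation undefined for fewer than 2 carriers",
               "rehhscan_undefined_error")
  mp <- hapset$map
  edge <- if (direction == "up") core$start_idx else core$end_idx
  ch <- mp$chrom[edge]
  step <- if (direction == "up") -1L else 1L
  markers <- integer(0)
  x <- edge + step
  while (length(markers) < max_markers && x >= 1L && x <= nrow(mp) &&
         mp$chrom[x] == ch) {
    markers <- c(markers, x)
    x <- x + step
  }
  grow <- function(rows, depth) {
    node <- list(count = length(rows),
                 marker_idx = if (depth == 0L) NA_integer_
                              else markers[depth],
                 children = list())
    if (depth < length(markers) && length(rows) > 0L) {
      al <- hapset$hap[rows, markers[depth + 1L]]
      for (a in sort(unique(al)))
        node$children[[as.character(a)]] <- grow(rows[al == a], depth + 1L)
    }
    node
  }
  tree <- grow(carriers, 0L)
  class(tree) <- "bifurcation_tree"
  tree
}

#' Serialise a bifurcation tree to JSON
#' @param tree a `bifurcation_tree`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bifurcation_json <- function(tree, path) {
  jsonlite::write_json(unclass_tree(tree), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

unclass_tree <- function(node) {
  list(count = node$count, marker_idx = node$marker_idx,
       children = lapply(node$children, unclass_tree))
}
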
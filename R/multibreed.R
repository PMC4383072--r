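# Cross-breed alignment of significant cores. Two significant cores from
# different breeds "share" a locus when they contain at least one common
# marker id; connected components of that sharing graph which span >= 2
# breeds of a production group become shared regions (so a locus chained
# across three breeds is reported once). Intervals are 1-based closed
# throughout.

#' Define production groups
#'
#' @param ... named character vectors: group name -> member breed labels.
#'   A breed (e.g. a dual-purpose one) may appear in several groups.
#' @return named list of class `production_groups`.
#' @export
production_groups <- function(...) {
  gl <- list(...)
  if (is.null(names(gl)) || any(names(gl) == ""))
    rehh_abort("every production group needs a name",
               "rehhscan_config_error")
  bad <- names(gl)[vapply(gl, length, integer(1)) < 2L]
  if (length(bad))
    rehh_abort(paste("production groups need >= 2 member breeds:",
                     paste(bad, collapse = ", ")), "rehhscan_config_error")
  structure(lapply(gl, as.character), class = "production_groups")
}

#' Shared regions across breeds of one production group
#'
#' @param cores_by_breed named list (breed -> `core_regions` data.frame of
#'   that breed's significant cores, as from [find_cores()] subset to
#'   significant rows).
#' @param map the common [marker_map()], or a named list of per-breed maps
#'   (breeds may retain different marker subsets after QC, but maps must
#'   agree on chromosome and position of every shared marker id).
#' @param group character vector of member breed labels (or a single
#'   element of [production_groups()]).
#' @param group_name label stored in the output (default: collapsed breeds).
#' @return data.frame of class `shared_regions`, ordered by (chrom,
#'   start_bp): `group`, `chrom`, `start_bp`, `end_bp` (closed union of the
#'   member core intervals), `breeds` (comma-joined), `n_breeds`,
#'   `core_ids` (breed:chrom:start labels), `n_shared_snps`,
#'   `shared_snps` (comma-joined ids of markers present in cores of >= 2
#'   breeds).
#' @export
shared_regions <- function(cores_by_breed, map, group,
                           group_name = NULL) {
  group <- as.character(group)
  group_name <- group_name %||% paste(group, collapse = "+")
  use <- intersect(names(cores_by_breed), group)
  maps <- if (inherits(map, "marker_map")) {
    ml <- rep(list(map), length(use)); names(ml) <- use; ml
  } else map
  if (length(use)) {
    pooled <- unique(do.call(rbind, lapply(use, function(b)
      as.data.frame(maps[[b]])[c("marker_id", "chrom", "pos_bp")])))
    if (anyDuplicated(pooled$marker_id))
      rehh_abort("breeds disagree on chromosome/position of shared markers",
                 "rehhscan_map_mismatch_error")
  }
  cores <- list()
  for (b in use) {
    cb <- cores_by_breed[[b]]
    if (is.null(cb) || nrow(cb) == 0L) next
    bmap <- maps[[b]]
    if (is.null(bmap) || max(cb$end_idx) > nrow(bmap))
      rehh_abort(sprintf("breed %s cores index beyond its map", b),
                 "rehhscan_map_mismatch_error")
    for (i in seq_len(nrow(cb))) {
      snps <- bmap$marker_id[cb$start_idx[i]:cb$end_idx[i]]
      if (!identical(bmap$chrom[cb$start_idx[i]], cb$chrom[i]))
        rehh_abort(sprintf("breed %s cores disagree with its map", b),
                   "rehhscan_map_mismatch_error")
      cores[[length(cores) + 1L]] <- list(
        breed = b, chrom = cb$chrom[i], start_bp = cb$start_bp[i],
        end_bp = cb$end_bp[i], snps = snps,
        id = paste(b, cb$chrom[i], cb$start_bp[i], sep = ":"))
    }
  }
  empty <- data.frame(group = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      breeds = character(0), n_breeds = integer(0),
                      core_ids = character(0), n_shared_snps = integer(0),
                      shared_snps = character(0))
  class(empty) <- c("shared_regions", "data.frame")
  k <- length(cores)
  if (k == 0L) return(empty)
  # union-find over the sharing graph (>= 1 common marker id)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (cores[[i]]$chrom != cores[[j]]$chrom) next
    if (length(intersect(cores[[i]]$snps, cores[[j]]$snps))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  out <- list()
  for (cc in sort(unique(comp))) {
    members <- cores[comp == cc]
    breeds <- sort(unique(vapply(members, `[[`, character(1), "breed")))
    if (length(breeds) < 2L) next
    snp_breed <- unique(do.call(rbind, lapply(members, function(m)
      data.frame(snp = m$snps, breed = m$breed, stringsAsFactors = FALSE))))
    tab <- table(snp_breed$snp)
    shared <- names(tab)[tab >= 2L]
    shared <- shared[order(match(shared, pooled$marker_id))]
    if (!length(shared)) next
    out[[length(out) + 1L]] <- data.frame(
      group = group_name,
      chrom = members[[1]]$chrom,
      start_bp = min(vapply(members, `[[`, numeric(1), "start_bp")),
      end_bp = max(vapply(members, `[[`, numeric(1), "end_bp")),
      breeds = paste(breeds, collapse = ","),
      n_breeds = length(breeds),
      core_ids = paste(sort(vapply(members, `[[`, character(1), "id")),
                       collapse = ","),
      n_shared_snps = length(shared),
      shared_snps = paste(shared, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp, res$end_bp), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("shared_regions", "data.frame")
  res
}

#' Summarise shared regions per chromosome
#'
#' @param regions a `shared_regions` data.frame.
#' @param map the common [marker_map()]; the mapped genome span (sum over
#'   chromosomes of last minus first marker bp) is the denominator of the
#'   genome fraction.
#' @return data.frame with one row per chromosome plus a `TOTAL` row:
#'   `chrom`, `n_regions`, `sum_bp` (closed lengths), `mean_bp`,
#'   `genome_fraction`.
#' @export
summarize_regions <- function(regions, map) {
  span <- vapply(split(map$pos_bp, map$chrom),
                 function(p) max(p) - min(p), numeric(1))
  genome_bp <- sum(span)
  if (nrow(regions) == 0L) {
    return(data.frame(chrom = "TOTAL", n_regions = 0L, sum_bp = 0,
                      mean_bp = NA_real_, genome_fraction = 0))
  }
  len <- regions$end_bp - regions$start_bp + 1
  per <- lapply(split(seq_len(nrow(regions)), regions$chrom), function(i)
    data.frame(n_regions = length(i), sum_bp = sum(len[i]),
               mean_bp = mean(len[i])))
  out <- do.call(rbind, per)
  out <- data.frame(chrom = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$genome_fraction <- out$sum_bp / genome_bp
  total <- data.frame(chrom = "TOTAL", n_regions = nrow(regions),
                      sum_bp = sum(len), mean_bp = mean(len),
                      genome_fraction = sum(len) / genome_bp)
  rbind(out[order(out$chrom), , drop = FALSE], total)
}

#' Overlap shared regions with gene annotation
#'
#' Closed-interval intersection on matching chromosome labels (via
#' GenomicRanges). Regions without genes are kept and flagged.
#'
#' @param regions a `shared_regions` data.frame.
#' @param annotation a [gene_annotation()].
#' @return `regions` with columns `genes` (comma-joined ids, "" if none),
#'   `n_genes`, `has_genes` added.
#' @export
gene_overlap <- function(regions, annotation) {
  if (nrow(regions) == 0L) {
    regions$genes <- character(0); regions$n_genes <- integer(0)
    regions$has_genes <- logical(0)
    return(regions)
  }
  if (!any(annotation$chrom %in% regions$chrom))
    rehh_abort(paste0(
      "no annotation chromosome matches the regions; annotation has: ",
      paste(unique(annotation$chrom), collapse = ", "), "; regions have: ",
      paste(unique(regions$chrom), collapse = ", ")),
      "rehhscan_namespace_error")
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start_bp,
                                                regions$end_bp))
  ag <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start_bp,
                                                annotation$end_bp))
  hits <- GenomicRanges::findOverlaps(rg, ag)
  genes <- rep("", nrow(regions))
  ql <- S4Vectors::queryHits(hits); sl <- S4Vectors::subjectHits(hits)
  for (i in unique(ql))
    genes[i] <- paste(sort(unique(annotation$gene_id[sl[ql == i]])),
                      collapse = ",")
  regions$genes <- genes
  regions$n_genes <- ifelse(genes == "", 0L,
                            lengths(strsplit(genes, ",", fixed = TRUE)))
  regions$has_genes <- regions$n_genes > 0L
  regions
}

#' Export shared regions as BED
#'
#' Converts the 1-based closed intervals to BED's 0-based half-open.
#'
#' @param regions a `shared_regions` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start_bp - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end_bp, scientific = FALSE,
                                 trim = TRUE),
                    name = paste0(regions$group, "_", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
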
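# S3 containers for the scan: marker map, genotype matrix (pre-phasing),
# phased haplotype matrix, pedigree, gene annotation. Deliberately thin --
# data.frames and integer matrices with validated invariants -- so that
# every statistic downstream reads like the formula it implements.

#' Build a marker map
#'
#' A marker map holds one row per SNP with chromosome, physical position
#' (1-based bp) and genetic position. Genetic positions default to the flat
#' 1 cM/Mb approximation (`pos_cm = pos_bp * 1e-6`) used when no
#' recombination map is available for the genome at hand; supplying
#' `pos_cm` overrides it per marker.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome label per marker (character or integer-like).
#' @param pos_bp integer physical position, 1-based.
#' @param pos_cm optional numeric genetic position in centimorgans.
#' @param sort sort by (chrom, pos_bp)? Default TRUE.
#' @return A `data.frame` of class `marker_map` with columns
#'   `marker_id`, `chrom`, `pos_bp`, `pos_cm`, sorted by chromosome then
#'   position.
#' @export
marker_map <- function(marker_id, chrom, pos_bp, pos_cm = NULL, sort = TRUE) {
  marker_id <- as.character(marker_id)
  chrom <- as.character(chrom)
  pos_bp <- as.double(pos_bp)
  n <- length(marker_id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(pos_bp) != n)
    rehh_abort("marker_id, chrom and pos_bp must have equal length",
               "rehhscan_dimension_error")
  if (anyDuplicated(marker_id))
    rehh_abort("duplicated marker ids in map", "rehhscan_map_error")
  if (is.null(pos_cm)) pos_cm <- pos_bp * 1e-6
  mm <- data.frame(marker_id = marker_id, chrom = chrom,
                   pos_bp = pos_bp, pos_cm = as.double(pos_cm),
                   stringsAsFactors = FALSE)
  if (sort) mm <- mm[order(mm$chrom, mm$pos_bp), , drop = FALSE]
  rownames(mm) <- NULL
  dup <- stats::ave(mm$pos_bp, mm$chrom, FUN = function(p) {
    c(FALSE, diff(p) <= 0)
  })
  if (any(dup == 1))
    rehh_abort("positions must be strictly increasing within chromosome",
               "rehhscan_map_error")
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Build a genotype set
#'
#' Unphased diploid genotypes, one row per individual, coded as dosage of
#' the allele labelled "1" (by convention the dataset minor allele);
#' missing genotypes are `NA`. This is the substrate of pre-phasing QC.
#'
#' @param geno integer matrix N x M with entries in \{0, 1, 2, NA\}.
#' @param sample_id character vector of N unique sample ids.
#' @param breed breed label per sample (recycled if scalar).
#' @param map a [marker_map()] with M rows, aligned to the columns.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(geno, sample_id, breed, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n <- nrow(geno)
  if (length(sample_id) != n)
    rehh_abort("sample_id length must equal nrow(geno)",
               "rehhscan_dimension_error")
  if (anyDuplicated(sample_id))
    rehh_abort("duplicated sample ids", "rehhscan_id_error")
  if (length(breed) == 1L) breed <- rep(breed, n)
  if (length(breed) != n)
    rehh_abort("breed must be scalar or length nrow(geno)",
               "rehhscan_dimension_error")
  if (!inherits(map, "marker_map") || nrow(map) != ncol(geno))
    rehh_abort("map must be a marker_map with one row per genotype column",
               "rehhscan_dimension_error")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    rehh_abort("genotypes must be in {0,1,2,NA}", "rehhscan_encoding_error")
  structure(list(geno = geno, sample_id = as.character(sample_id),
                 breed = as.character(breed), map = map),
            class = "genotype_set")
}

#' Build a haplotype set
#'
#' Phased binary haplotypes for one breed: a 2N x M matrix of 0/1 alleles
#' in which rows (2k-1, 2k) are the two chromosomes of sample k. All EHH
#' statistics operate on this container.
#'
#' @param hap integer 2N x M matrix with entries in \{0, 1\}.
#' @param sample_id character vector of N unique sample ids.
#' @param breed single breed label.
#' @param map a [marker_map()] with M rows.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(hap, sample_id, breed, map) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (nrow(hap) %% 2L != 0L)
    rehh_abort("haplotype row count must be even (two per individual)",
               "rehhscan_dimension_error")
  n <- nrow(hap) %/% 2L
  if (length(sample_id) != n)
    rehh_abort("need exactly one sample id per haplotype pair",
               "rehhscan_dimension_error")
  if (anyDuplicated(sample_id))
    rehh_abort("duplicated sample ids", "rehhscan_id_error")
  if (length(breed) != 1L)
    rehh_abort("breed must be a single label", "rehhscan_config_error")
  if (!inherits(map, "marker_map") || nrow(map) != ncol(hap))
    rehh_abort("map must be a marker_map with one row per haplotype column",
               "rehhscan_dimension_error")
  if (anyNA(hap) || any(hap < 0L | hap > 1L))
    rehh_abort("haplotype alleles must be 0 or 1 with no missing values",
               "rehhscan_encoding_error")
  structure(list(hap = hap, sample_id = as.character(sample_id),
                 breed = as.character(breed), map = map),
            class = "haplotype_set")
}

#' Number of samples / markers in a container
#' @param x a `genotype_set` or `haplotype_set`.
#' @return integer count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "genotype_set")) nrow(x$geno) else length(x$sample_id)
}

#' @rdname n_samples
#' @export
n_markers <- function(x) nrow(x$map)

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d samples x %d markers (%d breeds)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$breed))))
  invisible(x)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set [%s]: %d haplotypes (%d samples) x %d markers\n",
              x$breed, nrow(x$hap), length(x$sample_id), ncol(x$hap)))
  invisible(x)
}

#' Subset a haplotype set to a marker index
#' @param hapset a `haplotype_set`.
#' @param idx integer vector of marker (column) indices to keep.
#' @return a `haplotype_set` restricted to those markers.
#' @export
subset_markers <- function(hapset, idx) {
  map <- hapset$map[idx, , drop = FALSE]
  class(map) <- c("marker_map", "data.frame")
  rownames(map) <- NULL
  haplotype_set(hapset$hap[, idx, drop = FALSE], hapset$sample_id,
                hapset$breed, map)
}

#' Build a pedigree table
#'
#' @param individual character vector of unique individual ids.
#' @param sire sire id per individual; `NA`, `""` or `"0"` mean unknown.
#' @param breed breed label per individual.
#' @return data.frame of class `pedigree_table`.
#' @export
pedigree_table <- function(individual, sire = NA, breed = NA) {
  individual <- as.character(individual)
  n <- length(individual)
  sire <- as.character(rep_len(sire, n))
  sire[is.na(sire) | sire == "" | sire == "0"] <- NA_character_
  breed <- as.character(rep_len(breed, n))
  if (anyDuplicated(individual))
    rehh_abort("duplicated individual ids in pedigree",
               "rehhscan_pedigree_error")
  if (any(!is.na(sire) & sire == individual))
    rehh_abort("an individual cannot be its own sire",
               "rehhscan_pedigree_error")
  ped <- data.frame(individual = individual, sire = sire, breed = breed,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Build a gene annotation table
#'
#' 1-based, closed intervals (GFF3 convention); BED input is converted on
#' read. Used only for positional overlap with shared regions.
#'
#' @param gene_id character gene identifiers.
#' @param chrom chromosome labels.
#' @param start_bp,end_bp 1-based closed interval bounds.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start_bp, end_bp) {
  start_bp <- as.double(start_bp); end_bp <- as.double(end_bp)
  if (any(start_bp > end_bp))
    rehh_abort("gene start_bp must be <= end_bp", "rehhscan_interval_error")
  ann <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start_bp = start_bp, end_bp = end_bp,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
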
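# Readers and writers. PLINK text PED/MAP is parsed directly (no R reader
# for it ships with the stack); VCF goes through VariantAnnotation and
# BED/GFF3 through rtracklayer so coordinate conventions are handled by
# the standard Bioconductor machinery.

#' Read PLINK text PED/MAP into a genotype set
#'
#' Genotypes are recoded as dosage of the per-marker minor allele computed
#' on the dataset being read (ties broken toward the alphabetically first
#' allele so that a coded file round-trips). `0 0` allele pairs become
#' missing. The map is sorted by (chrom, pos_bp) and genotype columns are
#' permuted identically.
#'
#' @param ped_path path to a whitespace-delimited PED file
#'   (6 metadata columns + 2 allele fields per marker).
#' @param map_path path to the matching MAP file (3 or 4 columns:
#'   chrom, id, \[cM,\] bp).
#' @return a [genotype_set()]; breed labels are taken from the PED family
#'   id column.
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path) || !file.exists(map_path))
    rehh_abort("PED or MAP file does not exist", "rehhscan_io_error")
  mp <- utils::read.table(map_path, header = FALSE,
                          colClasses = "character")
  if (!ncol(mp) %in% c(3L, 4L))
    rehh_abort("MAP file must have 3 or 4 columns", "rehhscan_parse_error")
  if (ncol(mp) == 4L) {
    cm <- suppressWarnings(as.numeric(mp[[3]]))
    bp <- as.numeric(mp[[4]])
    if (all(!is.na(cm)) && any(cm != 0)) pos_cm <- cm else pos_cm <- NULL
  } else {
    bp <- as.numeric(mp[[3]])
    pos_cm <- NULL
  }
  m <- nrow(mp)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(toks)
  bad <- which(nfield != 6L + 2L * m)
  if (length(bad))
    rehh_abort(sprintf(
      "PED line %d has %d fields, expected %d (6 metadata + 2 x %d alleles)",
      bad[1], nfield[bad[1]], 6L + 2L * m, m), "rehhscan_parse_error")
  n <- length(toks)
  meta <- t(vapply(toks, function(x) x[1:6], character(6)))
  al <- matrix(unlist(lapply(toks, function(x) x[-(1:6)])),
               nrow = n, byrow = TRUE)
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA; a2[miss] <- NA
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    tab <- sort(table(obs[!is.na(obs)]))
    if (length(tab) > 2L)
      rehh_abort(sprintf("marker %s has >2 alleles", mp[[2]][j]),
                 "rehhscan_parse_error")
    if (length(tab) == 0L) next
    cnt <- as.vector(tab); alle <- names(tab)
    minor <- if (length(tab) == 1L) NA_character_
             else if (cnt[1] < cnt[2]) alle[1]
             else sort(alle)[1]  # tie -> alphabetically first
    if (is.na(minor)) { geno[, j] <- ifelse(miss[, j], NA_integer_, 0L); next }
    geno[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
  }
  ord <- order(as.character(mp[[1]]), bp)
  map <- marker_map(mp[[2]][ord], mp[[1]][ord], bp[ord],
                    if (is.null(pos_cm)) NULL else pos_cm[ord], sort = FALSE)
  genotype_set(geno[, ord, drop = FALSE], sample_id = meta[, 2],
               breed = meta[, 1], map = map)
}

#' Write a genotype set as PLINK text PED/MAP
#'
#' Dosage 2/1/0 of the coded allele is written as `1 1`, `1 2`, `2 2`;
#' missing as `0 0`. Family id column carries the breed label.
#'
#' @param gset a [genotype_set()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink <- function(gset, ped_path, map_path) {
  g <- gset$geno
  code <- function(x) {
    out <- character(length(x))
    out[is.na(x)] <- "0 0"
    out[!is.na(x) & x == 2L] <- "1 1"
    out[!is.na(x) & x == 1L] <- "1 2"
    out[!is.na(x) & x == 0L] <- "2 2"
    out
  }
  rows <- vapply(seq_len(nrow(g)), function(i) {
    paste(c(gset$breed[i], gset$sample_id[i], "0", "0", "0", "-9",
            code(g[i, ])), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  mp <- gset$map
  utils::write.table(
    data.frame(mp$chrom, mp$marker_id, mp$pos_cm, mp$pos_bp),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Read a phased VCF into a haplotype set
#'
#' Only biallelic SNP records with `|`-phased GT fields are accepted. With
#' `strict = TRUE` (default) an unphased (`/`) or multiallelic record is an
#' error; with `strict = FALSE` such records are skipped with a message.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param breed breed label to attach; defaults to the file stem.
#' @param strict error (TRUE) or skip (FALSE) on unphased/multiallelic
#'   records.
#' @return a [haplotype_set()]: 2 rows per sample, ALT allele coded 1.
#' @export
read_phased_vcf <- function(vcf_path, breed = NULL, strict = TRUE) {
  if (!file.exists(vcf_path))
    rehh_abort("VCF file does not exist", "rehhscan_io_error")
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    rehh_abort("VCF has no GT field", "rehhscan_parse_error")
  rr <- SummarizedExperiment::rowRanges(vcf)
  nalt <- S4Vectors::elementNROWS(rr$ALT)
  multi <- nalt != 1L
  unphased <- apply(gt, 1L, function(r) any(grepl("/", r, fixed = TRUE)))
  bad <- multi | unphased
  if (any(bad)) {
    if (strict)
      rehh_abort(sprintf(
        "%d unphased or multiallelic record(s), first at %s (strict mode)",
        sum(bad), rownames(gt)[which(bad)[1]]), "rehhscan_phase_error")
    message(sprintf("skipping %d unphased/multiallelic record(s)", sum(bad)))
    gt <- gt[!bad, , drop = FALSE]
    rr <- rr[!bad]
  }
  if (any(grepl(".", gt, fixed = TRUE)))
    rehh_abort("missing GT in phased VCF", "rehhscan_phase_error")
  m <- nrow(gt); n <- ncol(gt)
  hap <- matrix(0L, 2L * n, m)
  for (k in seq_len(n)) {
    parts <- strsplit(gt[, k], "|", fixed = TRUE)
    hap[2L * k - 1L, ] <- as.integer(vapply(parts, `[`, character(1), 1L))
    hap[2L * k, ] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  if (any(hap > 1L))
    rehh_abort("allele index >1 in biallelic record", "rehhscan_parse_error")
  ids <- rownames(gt)
  if (is.null(ids)) ids <- sprintf("snp%d", seq_len(m))
  map <- marker_map(ids, as.character(GenomicRanges::seqnames(rr)),
                    GenomicRanges::start(rr))
  ord <- match(map$marker_id, ids)
  if (is.null(breed))
    breed <- sub("\\.vcf(\\.gz)?$", "", basename(vcf_path))
  haplotype_set(hap[, ord, drop = FALSE], colnames(gt), breed, map)
}

#' Write a haplotype set as a minimal phased VCF
#'
#' Alleles 0/1 are written as REF `A` / ALT `G` placeholders (chip data
#' carry no nucleotide meaning downstream of coding).
#'
#' @param hapset a [haplotype_set()].
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
write_phased_vcf <- function(hapset, path) {
  mp <- hapset$map
  n <- length(hapset$sample_id)
  gts <- vapply(seq_len(nrow(mp)), function(j) {
    paste(paste0(hapset$hap[seq(1L, 2L * n, 2L), j], "|",
                 hapset$hap[seq(2L, 2L * n, 2L), j]), collapse = "\t")
  }, character(1))
  body <- paste(mp$chrom, format(mp$pos_bp, scientific = FALSE, trim = TRUE),
                mp$marker_id, "A", "G", ".", "PASS", ".", "GT", gts,
                sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=rehhscan",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", hapset$sample_id), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a pedigree TSV
#'
#' Expected columns: individual, sire, breed (header optional; `0`, empty
#' or `NA` sire means unknown).
#'
#' @param path TSV path.
#' @return a [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("individual", "sire", "breed") %in% names(tab)))
    rehh_abort("pedigree TSV needs columns individual, sire, breed",
               "rehhscan_parse_error")
  pedigree_table(tab$individual, tab$sire, tab$breed)
}

#' Write a pedigree table as TSV
#' @param ped a [pedigree_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based closed) are imported with
#' rtracklayer, which normalises both to 1-based closed coordinates. For
#' GFF3, rows with `type == "gene"` are used when present, otherwise all
#' rows. Gene ids come from `name` (BED) or `ID`/`Name`/`gene_id` (GFF3).
#'
#' @param path path ending in .bed, .gff, .gff3 or .gtf.
#' @return a [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path))
    rehh_abort("annotation file does not exist", "rehhscan_io_error")
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- md$ID %||% md$gene_id %||% md$Name %||% md$name
  if (is.null(id)) id <- paste0("feature", seq_along(gr))
  id <- as.character(id)
  missing_id <- is.na(id) | id == ""
  id[missing_id] <- paste0("feature", which(missing_id))
  gene_annotation(id, as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# ---- result tables -------------------------------------------------------

per_core_cols <- c("breed", "chrom", "core_start_bp", "core_end_bp",
                   "n_snps", "allele", "carriers", "freq",
                   "ehh_up", "ehh_down", "rehh_up", "rehh_down",
                   "logp_up", "logp_down", "retained", "significant")

#' Write the scan result tables
#'
#' Writes three fixed-schema TSVs into `out_dir`:
#' \describe{
#'   \item{per_core_results.tsv}{one row per (core region, core allele):
#'     breed, chrom, core bp range, allele string, carrier count, frequency,
#'     EHH and rEHH up/downstream at the test distance, -log10 p up/down,
#'     retention and significance flags.}
#'   \item{shared_regions.tsv}{one row per cross-breed shared region:
#'     group, chrom, bp range, contributing breeds, number of shared SNPs,
#'     overlapping genes.}
#'   \item{chromosome_summary.tsv}{per breed and chromosome: total core
#'     haplotypes tested and number significant.}
#' }
#'
#' @param results per-core-allele results `data.frame` (schema above), e.g.
#'   `scan_breed(...)$results`, or a row-bound set across breeds; may have
#'   zero rows.
#' @param shared a shared-region `data.frame` from [shared_regions()] (or
#'   NULL for none).
#' @param out_dir output directory, created if needed.
#' @return invisibly, named vector of written paths.
#' @export
write_results_tables <- function(results, shared = NULL, out_dir = ".") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    rehh_abort("cannot create output directory", "rehhscan_io_error")
  if (is.null(results) || nrow(results) == 0L) {
    results <- as.data.frame(
      setNames(rep(list(character(0)), length(per_core_cols)), per_core_cols))
  }
  missing <- setdiff(per_core_cols, names(results))
  if (length(missing))
    rehh_abort(paste("results table lacks columns:",
                     paste(missing, collapse = ", ")),
               "rehhscan_schema_error")
  f1 <- file.path(out_dir, "per_core_results.tsv")
  fwrite_tsv(results[, per_core_cols, drop = FALSE], f1)

  shared_cols <- c("group", "chrom", "start_bp", "end_bp", "breeds",
                   "n_breeds", "n_shared_snps", "genes")
  if (is.null(shared) || nrow(shared) == 0L) {
    shared <- as.data.frame(
      setNames(rep(list(character(0)), length(shared_cols)), shared_cols))
  } else {
    if (!"genes" %in% names(shared)) shared$genes <- ""
    shared <- shared[, shared_cols, drop = FALSE]
  }
  f2 <- file.path(out_dir, "shared_regions.tsv")
  fwrite_tsv(shared, f2)

  if (nrow(results)) {
    dt <- data.table::as.data.table(results)
    summ <- dt[, list(n_core_alleles = .N,
                      n_retained = sum(as.logical(retained)),
                      n_significant = sum(as.logical(significant))),
               by = c("breed", "chrom")]
    data.table::setorderv(summ, c("breed", "chrom"))
    summ <- as.data.frame(summ)
  } else {
    summ <- data.frame(breed = character(0), chrom = character(0),
                       n_core_alleles = integer(0), n_retained = integer(0),
                       n_significant = integer(0))
  }
  f3 <- file.path(out_dir, "chromosome_summary.tsv")
  fwrite_tsv(summ, f3)
  invisible(c(per_core = f1, shared = f2, summary = f3))
}

fwrite_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA",
                     logical01 = FALSE, scipen = 50)
}

#' Read back a per-core results table
#' @param path path to `per_core_results.tsv`.
#' @return data.frame with the documented schema.
#' @export
read_results_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                        colClasses = list(
                                          character = c("breed", "chrom",
                                                        "allele"))))
  df$allele <- as.character(df$allele)
  df
}
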
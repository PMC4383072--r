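# Two-step quality control: first animals (call rate, replicate pairs,
# sire-son Mendelian checks, each within breed), then markers (missingness,
# per-breed missingness, MAF, autosome/position filters), and finally the
# relatedness pruning that yields the "non-redundant" dataset used for LD
# and EHH. Thresholds default to the values standard for 50k-chip bull
# panels: call rate 0.95, duo Mendelian-error rate 0.002, marker
# missingness 0.025, MAF 0.05, at most 5 sons per half-sib family.

#' Per-sample call rate
#'
#' @param row integer genotype vector for one sample (NA = missing).
#' @return fraction of non-missing genotypes in \[0, 1\].
#' @export
sample_call_rate <- function(row) {
  if (length(row) == 0L)
    rehh_abort("call rate undefined for zero markers",
               "rehhscan_undefined_error")
  mean(!is.na(row))
}

#' Duo Mendelian error rate (sire vs son)
#'
#' For a parent-offspring duo the only detectable Mendelian conflict is a
#' pair of opposing homozygotes (0 vs 2). The rate is conflicts divided by
#' markers called in both.
#'
#' @param sire,son integer genotype vectors on the same marker index.
#' @return fraction in \[0, 1\].
#' @export
mendelian_error_rate <- function(sire, son) {
  if (length(sire) != length(son))
    rehh_abort("sire and son must share a marker index",
               "rehhscan_dimension_error")
  both <- !is.na(sire) & !is.na(son)
  if (!any(both))
    rehh_abort("no co-called markers in duo", "rehhscan_undefined_error")
  err <- (sire == 0L & son == 2L) | (sire == 2L & son == 0L)
  sum(err[both]) / sum(both)
}

#' Replicate concordance
#'
#' @param a,b integer genotype vectors of two genotyping runs of the same
#'   animal, on the same marker index.
#' @return fraction of co-called markers with identical genotype.
#' @export
replicate_concordance <- function(a, b) {
  if (length(a) != length(b))
    rehh_abort("replicates must share a marker index",
               "rehhscan_dimension_error")
  both <- !is.na(a) & !is.na(b)
  if (!any(both))
    rehh_abort("no co-called markers in replicate pair",
               "rehhscan_undefined_error")
  mean(a[both] == b[both])
}

#' Sample-level QC (step one)
#'
#' Within each breed: flags samples whose call rate is at or below
#' `call_rate`, removes one member of each declared replicate pair (the
#' lower-call-rate member; ties resolved toward keeping the
#' lexicographically smaller id), and removes one member of each genotyped
#' sire-son duo whose Mendelian error rate is at or above `mendel_rate`
#' (`mendel_drop` selects which; the son by default, as the genotype more
#' likely to be mislabelled).
#'
#' @param gset a [genotype_set()].
#' @param pedigree optional [pedigree_table()] providing sire links.
#' @param replicates optional data.frame with columns `id_a`, `id_b`
#'   declaring replicate genotyping runs.
#' @param call_rate exclusion threshold; samples with rate <= this go.
#' @param mendel_rate duo error-rate threshold; >= this flags the duo.
#' @param mendel_drop `"son"` (default) or `"sire"`.
#' @return list with `retained` (genotype_set), and `report` (class
#'   `qc_report`): per-sample call rates, excluded ids by cause
#'   (`low_call_rate`, `replicate`, `mendelian`), replicate concordances,
#'   duo error rates.
#' @export
sample_qc <- function(gset, pedigree = NULL, replicates = NULL,
                      call_rate = 0.95, mendel_rate = 0.002,
                      mendel_drop = c("son", "sire")) {
  mendel_drop <- match.arg(mendel_drop)
  assert_fraction(call_rate, "call_rate")
  assert_fraction(mendel_rate, "mendel_rate")
  ids <- gset$sample_id
  cr <- apply(gset$geno, 1L, sample_call_rate)
  names(cr) <- ids
  excl_cr <- ids[cr <= call_rate]

  excl_rep <- character(0)
  rep_conc <- numeric(0)
  if (!is.null(replicates) && nrow(replicates)) {
    for (i in seq_len(nrow(replicates))) {
      a <- as.character(replicates$id_a[i]); b <- as.character(replicates$id_b[i])
      if (!(a %in% ids) || !(b %in% ids)) next
      conc <- replicate_concordance(gset$geno[match(a, ids), ],
                                    gset$geno[match(b, ids), ])
      rep_conc[paste(a, b, sep = "/")] <- conc
      drop <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b
              else max(a, b)  # tie -> keep lexicographically smaller id
      if (!(drop %in% excl_cr)) excl_rep <- union(excl_rep, drop)
    }
  }

  excl_mend <- character(0)
  duo_rate <- numeric(0)
  if (!is.null(pedigree)) {
    ped <- pedigree[!is.na(pedigree$sire), , drop = FALSE]
    duo <- ped[ped$individual %in% ids & ped$sire %in% ids, , drop = FALSE]
    for (i in seq_len(nrow(duo))) {
      son <- duo$individual[i]; sire <- duo$sire[i]
      rate <- mendelian_error_rate(gset$geno[match(sire, ids), ],
                                   gset$geno[match(son, ids), ])
      duo_rate[paste(sire, son, sep = "->")] <- rate
      if (rate >= mendel_rate) {
        drop <- if (mendel_drop == "son") son else sire
        if (!(drop %in% c(excl_cr, excl_rep)))
          excl_mend <- union(excl_mend, drop)
      }
    }
  }

  excluded <- unique(c(excl_cr, excl_rep, excl_mend))
  keep <- !(ids %in% excluded)
  retained <- genotype_set(gset$geno[keep, , drop = FALSE], ids[keep],
                           gset$breed[keep], gset$map)
  report <- structure(list(
    step = "sample",
    call_rate = cr,
    replicate_concordance = rep_conc,
    duo_error_rate = duo_rate,
    excluded = list(low_call_rate = excl_cr, replicate = excl_rep,
                    mendelian = excl_mend),
    n_input = length(ids), n_retained = sum(keep)
  ), class = "qc_report")
  list(retained = retained, report = report)
}

#' Marker-level QC (step two)
#'
#' Drops markers that (checked in this order, one cause per marker):
#' lack a physical position; sit on a non-autosomal chromosome; have
#' overall missingness above `max_missing`; are entirely missing within
#' any single breed; or have whole-dataset minor allele frequency below
#' `maf`.
#'
#' @param gset a [genotype_set()] (post sample-QC).
#' @param max_missing overall missing-fraction ceiling (exclusive).
#' @param maf minimum minor allele frequency (inclusive).
#' @param autosomes chromosome labels considered autosomal; anything else
#'   (e.g. `"X"`, `"Y"`, `"MT"`, `"0"`) is dropped. Default: labels that
#'   parse as positive integers.
#' @return list with `retained` (genotype_set restricted to passing
#'   markers) and `report` (`qc_report`): per-marker missing rate and MAF,
#'   excluded marker ids by cause (`no_position`, `non_autosomal`,
#'   `missingness`, `breed_missing`, `maf`).
#' @export
marker_qc <- function(gset, max_missing = 0.025, maf = 0.05,
                      autosomes = NULL) {
  assert_fraction(max_missing, "max_missing")
  assert_fraction(maf, "maf")
  g <- gset$geno
  mp <- gset$map
  ids <- mp$marker_id
  chrom_num <- suppressWarnings(as.integer(mp$chrom))
  if (is.null(autosomes)) {
    autosomal <- !is.na(chrom_num) & chrom_num >= 1L
  } else {
    autosomal <- mp$chrom %in% as.character(autosomes)
  }
  no_pos <- is.na(mp$pos_bp) | mp$pos_bp <= 0
  miss_rate <- colMeans(is.na(g))
  breeds <- unique(gset$breed)
  breed_missing <- rep(FALSE, ncol(g))
  for (b in breeds) {
    rows <- gset$breed == b
    breed_missing <- breed_missing |
      colSums(!is.na(g[rows, , drop = FALSE])) == 0L
  }
  p1 <- colMeans(g, na.rm = TRUE) / 2   # frequency of coded allele
  mafs <- pmin(p1, 1 - p1)
  mafs[is.nan(mafs)] <- 0

  cause <- rep(NA_character_, ncol(g))
  cause[is.na(cause) & no_pos] <- "no_position"
  cause[is.na(cause) & !autosomal] <- "non_autosomal"
  cause[is.na(cause) & miss_rate > max_missing] <- "missingness"
  cause[is.na(cause) & breed_missing] <- "breed_missing"
  cause[is.na(cause) & mafs < maf] <- "maf"
  keep <- is.na(cause)

  map_keep <- mp[keep, , drop = FALSE]
  class(map_keep) <- c("marker_map", "data.frame")
  rownames(map_keep) <- NULL
  retained <- genotype_set(g[, keep, drop = FALSE], gset$sample_id,
                           gset$breed, map_keep)
  excl <- split(ids[!keep], cause[!keep])
  for (nm in c("no_position", "non_autosomal", "missingness",
               "breed_missing", "maf"))
    if (is.null(excl[[nm]])) excl[[nm]] <- character(0)
  report <- structure(list(
    step = "marker",
    missing_rate = setNames(miss_rate, ids),
    maf = setNames(mafs, ids),
    excluded = excl[c("no_position", "non_autosomal", "missingness",
                      "breed_missing", "maf")],
    n_input = ncol(g), n_retained = sum(keep)
  ), class = "qc_report")
  list(retained = retained, report = report)
}

#' Relatedness pruning (the "non-redundant" dataset)
#'
#' Applies the two family rules used for sire-structured panels: in every
#' genotyped father-son pair the son is kept and the father removed; then
#' each half-sib family (genotyped individuals sharing a sire id, after
#' father removal) is capped at `family_cap` members chosen uniformly at
#' random. Deterministic for a fixed `seed`.
#'
#' @param pedigree a [pedigree_table()].
#' @param sample_ids character vector of genotyped individual ids.
#' @param family_cap maximum half-sib family size (default 5).
#' @param seed integer seed for the random within-family draw.
#' @return character vector of retained sample ids (original order).
#' @export
prune_relatives <- function(pedigree, sample_ids, family_cap = 5L,
                            seed = 1L) {
  if (anyDuplicated(pedigree$individual))
    rehh_abort("duplicated individual ids in pedigree",
               "rehhscan_pedigree_error")
  sample_ids <- as.character(sample_ids)
  ped <- pedigree[match(sample_ids, pedigree$individual), , drop = FALSE]
  sire <- ped$sire
  # fathers of genotyped sons go
  fathers <- unique(sire[!is.na(sire) & sire %in% sample_ids])
  keep <- setdiff(sample_ids, fathers)
  sire_kept <- sire[match(keep, sample_ids)]
  fams <- split(keep, sire_kept)   # unknown-sire -> dropped from split (NA)
  drop <- character(0)
  with_seed(seed, {
    for (fam in fams) {
      if (length(fam) > family_cap)
        drop <- c(drop, setdiff(fam, sample(fam, family_cap)))
    }
  })
  setdiff(keep, drop)
}

#' Full two-step QC pipeline
#'
#' Runs [sample_qc()] then [marker_qc()] and returns the cleaned
#' genotype set with both reports. Relatedness pruning is separate
#' ([prune_relatives()]) because in the real workflow it follows phasing.
#'
#' @inheritParams sample_qc
#' @inheritParams marker_qc
#' @return list `retained`, `sample_report`, `marker_report`.
#' @export
run_qc <- function(gset, pedigree = NULL, replicates = NULL,
                   call_rate = 0.95, mendel_rate = 0.002,
                   mendel_drop = "son", max_missing = 0.025, maf = 0.05,
                   autosomes = NULL) {
  s <- sample_qc(gset, pedigree, replicates, call_rate, mendel_rate,
                 mendel_drop)
  m <- marker_qc(s$retained, max_missing, maf, autosomes)
  list(retained = m$retained, sample_report = s$report,
       marker_report = m$report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report [%s step]: %d -> %d retained\n",
              x$step, x$n_input, x$n_retained))
  for (nm in names(x$excluded))
    cat(sprintf("  excluded %-14s %d\n", paste0(nm, ":"),
                length(x$excluded[[nm]])))
  invisible(x)
}

#' Write a QC report as TSV + JSON summary
#' @param report a `qc_report`.
#' @param prefix output path prefix; writes `<prefix>_excluded.tsv` and
#'   `<prefix>_summary.json`.
#' @return invisibly, the two paths.
#' @export
write_qc_report <- function(report, prefix) {
  excl <- report$excluded
  tab <- data.frame(
    id = unlist(excl, use.names = FALSE),
    cause = rep(names(excl), lengths(excl)),
    stringsAsFactors = FALSE)
  f1 <- paste0(prefix, "_excluded.tsv")
  fwrite_tsv(tab, f1)
  f2 <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(step = report$step, n_input = report$n_input,
                            n_retained = report$n_retained,
                            n_excluded = lapply(excl, length)),
                       f2, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(f1, f2))
}
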
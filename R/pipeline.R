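# Full-run orchestration: per-breed scans (independent, so breed order
# never matters), cross-breed comparison per production group, gene
# overlap, fixed-schema TSV outputs and a JSON manifest that suffices to
# reproduce the run. Re-running with the same config and inputs gives
# byte-identical tables.

#' Validate a run configuration
#'
#' @param config list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{breeds}{named list: breed label -> list with `vcf` (phased VCF
#'       path), or pass ready-made haplotype sets via the `hapsets`
#'       argument of [run_scan()].}
#'     \item{groups}{named list: production group -> >= 2 breed labels.}
#'     \item{params}{optional scan parameter overrides (any argument of
#'       [scan_breed()]).}
#'     \item{annotation}{optional BED/GFF3 path for gene overlap.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed recorded in the manifest.}
#'   }
#' @param need_inputs check that input paths exist (default TRUE).
#' @return the validated config (invisibly usable downstream).
#' @export
validate_run_config <- function(config, need_inputs = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  if (!is.list(config))
    rehh_abort("config must be a list or JSON path", "rehhscan_config_error")
  params <- config$params %||% list()
  dom <- list(min_maf = c(0, 0.5), alpha = c(0, 1), min_freq = c(0, 1),
              strong_frac = c(0, 1), strong_lower = c(0, 1),
              strong_upper = c(0, 1), recomb_upper = c(0, 1),
              test_distance_cm = c(0, Inf))
  for (nm in names(params)) {
    if (nm %in% names(dom)) {
      v <- params[[nm]]
      if (!is_scalar_number(v) || v < dom[[nm]][1] || v > dom[[nm]][2])
        rehh_abort(sprintf("config parameter %s=%s outside [%g, %g]", nm,
                           format(v), dom[[nm]][1], dom[[nm]][2]),
                   "rehhscan_config_error")
    }
  }
  if (need_inputs) {
    for (b in names(config$breeds)) {
      f <- config$breeds[[b]]$vcf
      if (is.null(f) || !file.exists(f))
        rehh_abort(sprintf("breed %s: phased VCF not found (%s)", b,
                           f %||% "missing"), "rehhscan_config_error")
    }
    if (!is.null(config$annotation) && !file.exists(config$annotation))
      rehh_abort("annotation file not found", "rehhscan_config_error")
  }
  for (g in names(config$groups))
    if (length(config$groups[[g]]) < 2L)
      rehh_abort(sprintf("group %s needs >= 2 breeds", g),
                 "rehhscan_config_error")
  config
}

#' Run the full multi-breed scan pipeline
#'
#' Executes per-breed rEHH scans (each breed independent), intersects
#' significant cores within each production group, overlaps shared regions
#' with gene annotation when provided, and writes all result tables plus a
#' JSON run manifest into `out_dir`.
#'
#' @param config see [validate_run_config()]; `config$seed` seeds nothing
#'   during the scan (which is deterministic) but is recorded for
#'   provenance and used by any simulation step invoked through the CLI.
#' @param hapsets optional named list of ready [haplotype_set()] objects;
#'   overrides `config$breeds` file inputs.
#' @param threads accepted for interface compatibility; results are
#'   independent of it (breed scans share no state).
#' @return list of class `rehh_run`: `scans` (named per breed), `shared`
#'   (named per group), `summaries` (per group), `files`, `manifest`.
#' @export
run_scan <- function(config, hapsets = NULL, threads = 1L) {
  config <- validate_run_config(config, need_inputs = is.null(hapsets))
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (is.null(hapsets)) {
    hapsets <- lapply(setNames(nm = names(config$breeds)), function(b)
      read_phased_vcf(config$breeds[[b]]$vcf, breed = b))
  }
  params <- config$params %||% list()
  scan_args <- params[intersect(names(params),
                                names(formals(scan_breed)))]
  breeds <- sort(names(hapsets))
  scans <- list()
  for (b in breeds) {
    scans[[b]] <- tryCatch(
      do.call(scan_breed, c(list(hapset = hapsets[[b]]), scan_args)),
      error = function(e) rehh_abort(
        sprintf("breed %s: %s", b, conditionMessage(e)),
        "rehhscan_pipeline_error"))
  }
  sig_cores <- lapply(scans, significant_cores)
  maps <- lapply(scans, function(s) s$hapset_used$map)
  annotation <- if (!is.null(config$annotation))
    read_gene_annotation(config$annotation)
  shared <- list(); summaries <- list()
  for (g in names(config$groups)) {
    reg <- shared_regions(sig_cores, maps, config$groups[[g]],
                          group_name = g)
    if (!is.null(annotation)) {
      reg <- gene_overlap(reg, annotation)
    } else {
      reg$genes <- rep("", nrow(reg))
      reg$n_genes <- integer(nrow(reg))
      reg$has_genes <- logical(nrow(reg))
    }
    shared[[g]] <- reg
    pooled_map <- maps[[which.max(vapply(maps, nrow, integer(1)))]]
    summaries[[g]] <- summarize_regions(reg, pooled_map)
  }
  all_results <- do.call(rbind, lapply(breeds, function(b)
    scans[[b]]$results))
  all_shared <- if (length(shared)) do.call(rbind, shared) else NULL
  files <- write_results_tables(all_results, all_shared, out_dir)
  for (g in names(summaries))
    fwrite_tsv(summaries[[g]],
               file.path(out_dir, paste0("summary_", g, ".tsv")))
  cfg_json <- jsonlite::toJSON(config[order(names(config))],
                               auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "rehhscan",
    version = as.character(utils::packageVersion("rehhscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed %||% NA,
    config = config,
    config_md5 = unname(tools::md5sum(tf)),
    breeds = breeds,
    n_significant = vapply(scans, function(s)
      sum(s$results$significant), integer(1)))
  unlink(tf)
  mf <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(list(scans = scans, shared = shared, summaries = summaries,
                 files = c(files, manifest = mf), manifest = manifest),
            class = "rehh_run")
}

#' @export
print.rehh_run <- function(x, ...) {
  cat(sprintf("rehh_run: %d breeds, %d groups\n", length(x$scans),
              length(x$shared)))
  for (g in names(x$shared))
    cat(sprintf("  %s: %d shared regions\n", g, nrow(x$shared[[g]])))
  invisible(x)
}
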
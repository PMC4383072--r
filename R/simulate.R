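# Forward Wright-Fisher simulator. Generates multi-breed phased haplotype
# panels with chip-like marker density, background LD built by random
# mating with Poisson crossovers, localized selective sweeps (additive
# fitness 1 : 1+s : 1+2s), sire/half-sib pedigree structure, replicate
# samples and genotyping defects -- everything the pipeline's QC and scan
# stages need, with a truth table for power evaluation. Standing variation
# only: markers are predefined (chip ascertainment), no new mutations.

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a 50k-chip bull panel:
#' 200 diploids, one 100-Mb chromosome carrying 2000 markers (20
#' markers/Mb), a flat 1 cM/Mb map, 100 generations of background random
#' mating, initial allele frequencies uniform on (0.05, 0.95). Sweeps are
#' strong (s = 0.1, as for intense artificial selection) and stopped when
#' the favoured allele segregates at 0.5-0.8, the range where rEHH has
#' power. Degradation defaults mirror routine chip data: 1% missing calls,
#' 0.1% genotype errors (replicate concordance ~99.8%).
#'
#' @param n_diploid diploid population size N.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param markers_per_mb marker density.
#' @param recomb_cm_per_mb recombination rate (default 1 cM/Mb).
#' @param generations background random-mating generations.
#' @param sweeps list of sweep specs: each a list with `position_bp`,
#'   optional `chrom` (default first), `s` (default 0.1), `window`
#'   (default c(0.5, 0.8)), and for multi-breed runs `assign` (a group or
#'   breed name).
#' @param breeds list of breed specs: each a list with `name`, optional
#'   `groups` (character), optional `n` (default `n_diploid`).
#' @param divergence_generations generations each breed evolves after the
#'   split.
#' @param pedigree list: `n_sires`, `sons_per_sire`.
#' @param degradation list: `missing_rate`, `error_rate`, `n_replicates`.
#' @param seed integer master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_diploid = 200L, n_chrom = 1L,
                       chrom_length_bp = 1e8, markers_per_mb = 20,
                       recomb_cm_per_mb = 1, generations = 100L,
                       sweeps = list(), breeds = NULL,
                       divergence_generations = 50L,
                       pedigree = list(n_sires = 5L, sons_per_sire = 5L),
                       degradation = list(missing_rate = 0.01,
                                          error_rate = 0.001,
                                          n_replicates = 2L),
                       seed = 1L) {
  # JSON configs may arrive with breeds/sweeps simplified to data.frames
  df_to_specs <- function(x) {
    if (is.null(x) || !is.data.frame(x)) return(x)
    lapply(seq_len(nrow(x)), function(i)
      lapply(x, function(col) if (is.list(col)) col[[i]] else col[i]))
  }
  breeds <- df_to_specs(breeds)
  sweeps <- df_to_specs(sweeps)
  if (is.data.frame(pedigree)) pedigree <- as.list(pedigree)
  if (is.data.frame(degradation)) degradation <- as.list(degradation)
  cfg <- list(n_diploid = as.integer(n_diploid), n_chrom = as.integer(n_chrom),
              chrom_length_bp = chrom_length_bp,
              markers_per_mb = markers_per_mb,
              recomb_cm_per_mb = recomb_cm_per_mb,
              generations = as.integer(generations), sweeps = sweeps,
              breeds = breeds,
              divergence_generations = as.integer(divergence_generations),
              pedigree = pedigree, degradation = degradation,
              seed = as.integer(seed))
  bad <- character(0)
  if (!is_scalar_number(cfg$n_diploid) || cfg$n_diploid < 2)
    bad <- c(bad, "n_diploid")
  if (!is_scalar_number(cfg$chrom_length_bp) || cfg$chrom_length_bp < 1e4)
    bad <- c(bad, "chrom_length_bp")
  if (!is_scalar_number(cfg$markers_per_mb) || cfg$markers_per_mb <= 0)
    bad <- c(bad, "markers_per_mb")
  if (!is_scalar_number(cfg$recomb_cm_per_mb) || cfg$recomb_cm_per_mb < 0)
    bad <- c(bad, "recomb_cm_per_mb")
  if (!is_scalar_number(cfg$generations) || cfg$generations < 0)
    bad <- c(bad, "generations")
  for (sw in cfg$sweeps) {
    if (!is.null(sw$s) && (!is_scalar_number(sw$s) || sw$s < 0))
      bad <- c(bad, "sweeps$s")
    w <- sw$window %||% c(0.5, 0.8)
    if (length(w) != 2 || w[1] <= 0 || w[2] >= 1 || w[1] >= w[2])
      bad <- c(bad, "sweeps$window")
  }
  dg <- cfg$degradation
  if (!is.null(dg$missing_rate) &&
      (dg$missing_rate < 0 || dg$missing_rate > 1))
    bad <- c(bad, "degradation$missing_rate")
  if (!is.null(dg$error_rate) && (dg$error_rate < 0 || dg$error_rate > 1))
    bad <- c(bad, "degradation$error_rate")
  if (length(bad))
    rehh_abort(paste("invalid simulation config fields:",
                     paste(unique(bad), collapse = ", ")),
               "rehhscan_config_error")
  class(cfg) <- "sim_config"
  cfg
}

# one Wright-Fisher generation. H: 2N x M integer matrix; chrom_cols:
# list of column index vectors per chromosome; pos_cm: per-chromosome cM
# positions; fitness: length-N diploid weights (NULL = neutral).
wf_generation <- function(H, chrom_cols, pos_cm, fitness = NULL) {
  n <- nrow(H) %/% 2L
  w <- fitness %||% rep(1, n)
  parents <- cbind(sample.int(n, n, replace = TRUE, prob = w),
                   sample.int(n, n, replace = TRUE, prob = w))
  gam_parent <- as.vector(t(parents))       # 2N gametes, offspring-major
  Hn <- matrix(0L, nrow(H), ncol(H))
  for (ci in seq_along(chrom_cols)) {
    cols <- chrom_cols[[ci]]
    cm <- pos_cm[[ci]]
    len_m <- (max(cm) - min(cm)) / 100      # Morgans
    start <- sample.int(2L, length(gam_parent), replace = TRUE)
    ncx <- stats::rpois(length(gam_parent), len_m)
    base_rows <- 2L * (gam_parent - 1L) + start
    Hn[, cols] <- H[base_rows, cols, drop = FALSE]
    for (g in which(ncx > 0L)) {
      cuts <- sort(stats::runif(ncx[g], min(cm), max(cm)))
      seg <- findInterval(cm, cuts)
      other <- (start[g] %% 2L) + 1L        # the unused parental haplotype
      swap <- seg %% 2L == 1L
      if (any(swap))
        Hn[g, cols[swap]] <- H[2L * (gam_parent[g] - 1L) + other,
                               cols[swap]]
    }
  }
  Hn
}

chrom_columns <- function(map) {
  split(seq_len(nrow(map)), map$chrom)[unique(map$chrom)]
}

#' Simulate a base population
#'
#' Draws initial haplotypes marker-wise from Uniform(0.05, 0.95) allele
#' frequencies, then applies `generations` of neutral Wright-Fisher mating
#' with Poisson recombination on the configured map, which builds the
#' distance-decaying background LD of a real chip panel. Deterministic for
#' a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param breed breed label for the returned set.
#' @return a [haplotype_set()].
#' @export
simulate_base_population <- function(config, breed = "base") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    m_per_chrom <- max(3L, round(config$chrom_length_bp / 1e6 *
                                   config$markers_per_mb))
    maps <- lapply(seq_len(config$n_chrom), function(ch) {
      pos <- sort(sample.int(config$chrom_length_bp, m_per_chrom))
      marker_map(sprintf("c%dm%05d", ch, seq_len(m_per_chrom)),
                 as.character(ch), pos,
                 pos * 1e-6 * config$recomb_cm_per_mb)
    })
    map <- do.call(rbind, lapply(maps, as.data.frame))
    map <- marker_map(map$marker_id, map$chrom, map$pos_bp, map$pos_cm,
                      sort = FALSE)
    M <- nrow(map)
    n2 <- 2L * config$n_diploid
    p <- stats::runif(M, 0.05, 0.95)
    H <- matrix(stats::rbinom(n2 * M, 1L, rep(p, each = n2)), n2, M)
    storage.mode(H) <- "integer"
    cc <- chrom_columns(map)
    cms <- lapply(cc, function(cols) map$pos_cm[cols])
    for (g in seq_len(config$generations))
      H <- wf_generation(H, cc, cms)
    haplotype_set(H, sprintf("%s_ind%04d", breed,
                             seq_len(config$n_diploid)), breed, map)
  })
}

#' Implant a selective sweep
#'
#' Places a new favoured allele on one random haplotype at the marker
#' nearest `position_bp` (overwriting that marker's column: the favoured
#' mutation arises at a genotyped site) and runs Wright-Fisher mating with
#' additive fitness 1 : 1+s : 1+2s until the allele frequency enters
#' `window`. Attempts in which the allele is lost (or overshoots the
#' window) restart from the input population with a derived seed; after
#' `max_retries` failures an error of class `rehhscan_sweep_error` is
#' raised reporting the attempt count.
#'
#' @param hapset a [haplotype_set()] (the standing population).
#' @param position_bp target position; `chrom` defaults to the first.
#' @param s selection coefficient (> 0 for a real sweep).
#' @param window numeric length-2: stop when freq in (window\[1\],
#'   window\[2\]).
#' @param seed integer seed.
#' @param chrom chromosome label (default: first in the map).
#' @param max_retries attempts before giving up (default 100).
#' @param max_generations cap per attempt (default 5000).
#' @return list: `hapset` (population at stopping time), `marker_idx`,
#'   `marker_id`, `position_bp` (of the sweep marker), `freq` (achieved),
#'   `generations`, `attempts`.
#' @export
implant_sweep <- function(hapset, position_bp, s = 0.1,
                          window = c(0.5, 0.8), seed = 1L, chrom = NULL,
                          max_retries = 100L, max_generations = 5000L) {
  if (!is_scalar_number(s) || s < 0)
    rehh_abort("selection coefficient must be >= 0", "rehhscan_config_error")
  mp <- hapset$map
  chrom <- chrom %||% mp$chrom[1]
  on_ch <- which(mp$chrom == chrom)
  if (!length(on_ch))
    rehh_abort("sweep chromosome not on the map", "rehhscan_config_error")
  target <- on_ch[which.min(abs(mp$pos_bp[on_ch] - position_bp))]
  cc <- chrom_columns(mp)
  cms <- lapply(cc, function(cols) mp$pos_cm[cols])
  n <- length(hapset$sample_id)
  for (attempt in seq_len(max_retries)) {
    res <- with_seed(derive_seed(seed, attempt), {
      H <- hapset$hap
      H[, target] <- 0L
      H[sample.int(nrow(H), 1L), target] <- 1L
      gen <- 0L
      repeat {
        freq <- mean(H[, target])
        if (freq == 0) break
        if (freq > window[1] && freq < window[2]) break
        if (freq >= window[2]) { freq <- 0; break }   # overshot: restart
        if (gen >= max_generations) { freq <- 0; break }
        g <- H[seq(1L, 2L * n, 2L), target] + H[seq(2L, 2L * n, 2L), target]
        H <- wf_generation(H, cc, cms, fitness = 1 + s * g)
        gen <- gen + 1L
      }
      list(H = H, freq = freq, gen = gen)
    })
    if (res$freq > 0) {
      hs <- haplotype_set(res$H, hapset$sample_id, hapset$breed, mp)
      return(list(hapset = hs, marker_idx = target,
                  marker_id = mp$marker_id[target],
                  position_bp = mp$pos_bp[target], freq = res$freq,
                  generations = res$gen, attempts = attempt))
    }
  }
  rehh_abort(sprintf("sweep failed to reach (%g, %g) in %d attempts",
                     window[1], window[2], max_retries),
             "rehhscan_sweep_error", attempts = max_retries)
}

#' Simulate a set of breeds with group-assigned sweeps
#'
#' Splits a shared base population into breeds (one extra Wright-Fisher
#' resampling per breed, then `divergence_generations` of independent
#' mating), and implants each sweep -- at the same map position -- into
#' every breed whose name or group matches the sweep's `assign` field.
#'
#' @param config a [sim_config()] with a non-NULL `breeds` list.
#' @return list: `hapsets` (named list of [haplotype_set()]), `map`,
#'   `truth` (data.frame: breed, group assign, marker_id, position_bp, s,
#'   achieved freq; zero rows when no sweeps).
#' @export
simulate_breeds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$breeds) || length(config$breeds) < 2L)
    rehh_abort("simulate_breeds needs >= 2 breed specs",
               "rehhscan_config_error")
  base <- simulate_base_population(config)
  cc <- chrom_columns(base$map)
  cms <- lapply(cc, function(cols) base$map$pos_cm[cols])
  hapsets <- list()
  truth <- list()
  for (bi in seq_along(config$breeds)) {
    spec <- config$breeds[[bi]]
    name <- spec[["name"]] %||% paste0("breed", bi)
    groups <- unlist(spec[["groups"]]) %||% character(0)
    nb <- as.integer(spec[["n"]] %||% config$n_diploid)
    H <- with_seed(derive_seed(config$seed, 100 + bi), {
      Hb <- base$hap
      # breed founding bottleneck/resample, then independent divergence
      founders <- sample.int(nrow(Hb) %/% 2L, nb, replace = TRUE)
      rows <- as.vector(rbind(2L * founders - 1L, 2L * founders))
      Hb <- Hb[rows, , drop = FALSE]
      for (g in seq_len(config$divergence_generations))
        Hb <- wf_generation(Hb, cc, cms)
      Hb
    })
    hs <- haplotype_set(H, sprintf("%s_ind%04d", name, seq_len(nb)),
                        name, base$map)
    for (si in seq_along(config$sweeps)) {
      sw <- config$sweeps[[si]]
      assign <- sw$assign %||% "all"
      if (!(assign == "all" || assign == name || assign %in% groups)) next
      res <- implant_sweep(hs, sw$position_bp, sw$s %||% 0.1,
                           sw$window %||% c(0.5, 0.8),
                           seed = derive_seed(config$seed,
                                              1000 + 37 * bi + si),
                           chrom = sw$chrom)
      hs <- res$hapset
      truth[[length(truth) + 1L]] <- data.frame(
        breed = name, assign = assign, marker_id = res$marker_id,
        position_bp = res$position_bp, s = sw$s %||% 0.1, freq = res$freq,
        stringsAsFactors = FALSE)
    }
    hapsets[[name]] <- hs
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(breed = character(0), assign = character(0),
                           marker_id = character(0),
                           position_bp = numeric(0), s = numeric(0),
                           freq = numeric(0))
  list(hapsets = hapsets, map = base$map, truth = truth)
}

#' Collapse to genotypes and add pedigree structure and defects
#'
#' Collapses haplotype pairs to diploid genotypes, then: samples
#' `pedigree$n_sires` individuals as sires and generates
#' `pedigree$sons_per_sire` sons each (sire gamete x random population
#' gamete, so duos are Mendelian-consistent by construction); duplicates
#' `degradation$n_replicates` samples as replicate runs; and injects
#' missing calls and genotype errors at the configured rates. All draws
#' derive from `seed`.
#'
#' @param hapset a [haplotype_set()].
#' @param config a [sim_config()] (its `pedigree` and `degradation` lists
#'   are used).
#' @param seed integer seed (default `config$seed`).
#' @return list: `gset` (a [genotype_set()]), `pedigree`
#'   (a [pedigree_table()]), `replicates` (data.frame `id_a`, `id_b`),
#'   `truth` (list with planted counts: n_sons, n_sires, n_replicates).
#' @export
degrade_and_pedigree <- function(hapset, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  ped_spec <- config$pedigree
  dg <- config$degradation
  n_sires <- as.integer(ped_spec$n_sires %||% 0L)
  sons_per <- as.integer(ped_spec$sons_per_sire %||% 0L)
  n <- length(hapset$sample_id)
  if (n_sires > n)
    rehh_abort("more sires requested than individuals",
               "rehhscan_config_error")
  mp <- hapset$map
  cc <- chrom_columns(mp)
  cms <- lapply(cc, function(cols) mp$pos_cm[cols])
  with_seed(seed, {
    H <- hapset$hap
    odd <- seq(1L, nrow(H), 2L)
    geno <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
    ids <- hapset$sample_id
    sire_of <- rep(NA_character_, n)

    gamete <- function(ind) {
      rows <- c(2L * ind - 1L, 2L * ind)
      out <- integer(ncol(H))
      for (ci in seq_along(cc)) {
        cols <- cc[[ci]]; cm <- cms[[ci]]
        start <- sample.int(2L, 1L)
        k <- stats::rpois(1L, (max(cm) - min(cm)) / 100)
        if (k == 0L) { out[cols] <- H[rows[start], cols]; next }
        cuts <- sort(stats::runif(k, min(cm), max(cm)))
        seg <- (findInterval(cm, cuts) + start - 1L) %% 2L + 1L
        out[cols] <- ifelse(seg == 1L, H[rows[1], cols], H[rows[2], cols])
      }
      out
    }

    sires <- if (n_sires > 0L) sample.int(n, n_sires) else integer(0)
    for (si in sires) {
      for (k in seq_len(sons_per)) {
        g1 <- gamete(si)
        mate <- sample.int(n, 1L)
        g2 <- gamete(mate)
        geno <- rbind(geno, g1 + g2)
        ids <- c(ids, sprintf("%s_son%02d", hapset$sample_id[si], k))
        sire_of <- c(sire_of, hapset$sample_id[si])
      }
    }

    n_rep <- as.integer(dg$n_replicates %||% 0L)
    rep_tab <- data.frame(id_a = character(0), id_b = character(0),
                          stringsAsFactors = FALSE)
    if (n_rep > 0L) {
      picks <- sample.int(n, n_rep)
      for (pk in picks) {
        geno <- rbind(geno, geno[pk, ])
        rid <- paste0(ids[pk], "_rep")
        rep_tab <- rbind(rep_tab,
                         data.frame(id_a = ids[pk], id_b = rid,
                                    stringsAsFactors = FALSE))
        ids <- c(ids, rid)
        sire_of <- c(sire_of, NA_character_)
      }
    }

    err_rate <- dg$error_rate %||% 0
    if (err_rate > 0) {
      hit <- which(stats::runif(length(geno)) < err_rate)
      if (length(hit))
        geno[hit] <- (geno[hit] + sample(1:2, length(hit),
                                         replace = TRUE)) %% 3L
    }
    miss_rate <- dg$missing_rate %||% 0
    if (miss_rate > 0)
      geno[stats::runif(length(geno)) < miss_rate] <- NA_integer_

    storage.mode(geno) <- "integer"
    gset <- genotype_set(geno, ids, hapset$breed, mp)
    ped <- pedigree_table(ids, sire_of, hapset$breed)
    list(gset = gset, pedigree = ped, replicates = rep_tab,
         truth = list(n_sires = n_sires, n_sons = n_sires * sons_per,
                      n_replicates = n_rep))
  })
}

#' Write a simulated truth table as TSV
#' @param truth the `truth` data.frame from [simulate_breeds()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  fwrite_tsv(truth, path)
  invisible(path)
}
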
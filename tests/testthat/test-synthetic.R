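small_cfg <- function(seed, ...) {
  sim_config(n_diploid = 50, chrom_length_bp = 5e6, markers_per_mb = 30,
             generations = 20, seed = seed, ...)
}

test_that("sim_config validates fields and lists offenders", {
  expect_s3_class(sim_config(), "sim_config")
  err <- tryCatch(sim_config(n_diploid = 1, markers_per_mb = -2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "n_diploid")
  expect_match(err, "markers_per_mb")
  expect_error(sim_config(sweeps = list(list(position_bp = 1e6, s = -1))),
               class = "rehhscan_config_error")
  expect_error(sim_config(degradation = list(missing_rate = 1.5)),
               class = "rehhscan_config_error")
})

test_that("simulate_base_population is deterministic under seed", {
  h1 <- simulate_base_population(small_cfg(77))
  h2 <- simulate_base_population(small_cfg(77))
  expect_identical(h1$hap, h2$hap)
  expect_identical(h1$map, h2$map)
  h3 <- simulate_base_population(small_cfg(78))
  expect_false(identical(h1$hap, h3$hap))
  # marker count and dimensions
  expect_equal(nrow(h1$map), 150L)
  expect_equal(dim(h1$hap), c(100L, 150L))
})

test_that("zero generations of mating leave markers independent", {
  cfg <- sim_config(n_diploid = 100, chrom_length_bp = 5e6,
                    markers_per_mb = 40, generations = 0, seed = 5)
  hs <- simulate_base_population(cfg)
  m <- ncol(hs$hap)
  r2 <- vapply(seq_len(m - 1L), function(j)
    tryCatch(haplotype_r2(hs$hap[, j], hs$hap[, j + 1]),
             error = function(e) NA_real_), numeric(1))
  r2 <- r2[!is.na(r2)]
  n_hap <- nrow(hs$hap)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(mean(r2), 3 / n_hap + 3 * se)
})

test_that("without recombination the distinct-haplotype count never grows", {
  cfg <- sim_config(n_diploid = 50, chrom_length_bp = 5e6,
                    markers_per_mb = 30, generations = 0,
                    recomb_cm_per_mb = 0, seed = 3)
  hs <- simulate_base_population(cfg)
  H <- hs$hap
  cc <- rehhscan:::chrom_columns(hs$map)
  cms <- lapply(cc, function(cols) hs$map$pos_cm[cols])
  n_distinct <- function(H) length(unique(apply(H, 1, paste, collapse = "")))
  prev <- n_distinct(H)
  set.seed(42)
  for (g in 1:10) {
    H <- rehhscan:::wf_generation(H, cc, cms)
    now <- n_distinct(H)
    expect_lte(now, prev)
    prev <- now
  }
})

test_that("neutral allele frequencies are a martingale", {
  # 50 replicates x 100 markers: mean drift within 3 s.e. of 0
  drifts <- numeric(0)
  for (seed in 1:50) {
    cfg <- sim_config(n_diploid = 30, chrom_length_bp = 4e6,
                      markers_per_mb = 25, generations = 0, seed = seed)
    hs <- simulate_base_population(cfg)
    cc <- rehhscan:::chrom_columns(hs$map)
    cms <- lapply(cc, function(cols) hs$map$pos_cm[cols])
    H <- hs$hap
    set.seed(seed + 1000)
    for (g in 1:5) H <- rehhscan:::wf_generation(H, cc, cms)
    drifts <- c(drifts, colMeans(H) - colMeans(hs$hap))
  }
  se <- sd(drifts) / sqrt(length(drifts))
  expect_lt(abs(mean(drifts)), 3 * se)
})

test_that("implant_sweep stops inside the window and fails when it must", {
  hs <- simulate_base_population(small_cfg(12))
  sw <- implant_sweep(hs, 2.5e6, s = 0.1, window = c(0.5, 0.8), seed = 9)
  expect_gt(sw$freq, 0.5)
  expect_lt(sw$freq, 0.8)
  expect_equal(mean(sw$hapset$hap[, sw$marker_idx]), sw$freq)
  expect_equal(dim(sw$hapset$hap), dim(hs$hap))
  # deterministic under seed
  sw2 <- implant_sweep(hs, 2.5e6, s = 0.1, window = c(0.5, 0.8), seed = 9)
  expect_identical(sw$hapset$hap, sw2$hapset$hap)
  # neutral allele, near-fixation window, tiny retry budget -> failure
  err <- tryCatch(
    implant_sweep(hs, 2.5e6, s = 0, window = c(0.985, 0.995), seed = 1,
                  max_retries = 3, max_generations = 40),
    error = function(e) e)
  expect_s3_class(err, "rehhscan_sweep_error")
  expect_match(conditionMessage(err), "3 attempts")
})

test_that("swept core alleles show elevated EHH vs matched neutral runs", {
  # the simulator's core validity check: EHH at 0.25 cM for the swept
  # allele exceeds the same-frequency allele of a matched neutral run
  wins <- 0L; n_pairs <- 20L
  for (seed in seq_len(n_pairs)) {
    cfg <- sim_config(n_diploid = 100, chrom_length_bp = 4e7,
                      markers_per_mb = 20, generations = 60, seed = seed)
    hs <- simulate_base_population(cfg)
    sw <- implant_sweep(hs, 2e7, s = 0.1, window = c(0.5, 0.8),
                        seed = seed + 300)
    mean_ehh <- function(hapset, idx, carriers) {
      core <- list(start_idx = idx, end_idx = idx)
      vals <- c()
      for (dir in c("up", "down")) {
        x <- rehhscan:::pick_test_marker(hapset$map, core, dir, 0.25)
        if (!is.null(x) && !is.na(x))
          vals <- c(vals, ehh_at(hapset, carriers, core, x))
      }
      mean(vals)
    }
    swept <- mean_ehh(sw$hapset, sw$marker_idx,
                      which(sw$hapset$hap[, sw$marker_idx] == 1L))
    # matched neutral allele: same marker, allele class closest in count
    neu <- hs$hap[, sw$marker_idx]
    carriers_n <- if (abs(sum(neu) - sw$freq * nrow(hs$hap)) <
                      abs(sum(1 - neu) - sw$freq * nrow(hs$hap)))
      which(neu == 1L) else which(neu == 0L)
    if (length(carriers_n) < 2) next
    neutral <- mean_ehh(hs, sw$marker_idx, carriers_n)
    if (swept > neutral) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * n_pairs)
})

test_that("simulate_breeds assigns group sweeps and records truth", {
  cfg <- sim_config(n_diploid = 40, chrom_length_bp = 6e6,
                    markers_per_mb = 25, generations = 15,
                    divergence_generations = 5, seed = 21,
                    breeds = list(list(name = "D1", groups = "dairy"),
                                  list(name = "D2", groups = "dairy"),
                                  list(name = "B1", groups = "beef"),
                                  list(name = "DP", groups = c("dairy", "beef"))),
                    sweeps = list(
                      list(position_bp = 3e6, s = 0.2, assign = "dairy"),
                      list(position_bp = 1e6, s = 0.2, assign = "beef")))
  sim <- simulate_breeds(cfg)
  expect_setequal(names(sim$hapsets), c("D1", "D2", "B1", "DP"))
  tr <- sim$truth
  # dairy sweep in D1, D2, DP; beef sweep in B1, DP
  dairy_pos <- tr$position_bp[tr$assign == "dairy"]
  expect_setequal(tr$breed[tr$assign == "dairy"], c("D1", "D2", "DP"))
  expect_setequal(tr$breed[tr$assign == "beef"], c("B1", "DP"))
  expect_equal(length(unique(dairy_pos)), 1L)  # same map position everywhere
  expect_true(all(tr$freq > 0.5 & tr$freq < 0.8))
  # no sweeps -> empty truth
  cfg0 <- sim_config(n_diploid = 30, chrom_length_bp = 4e6,
                     markers_per_mb = 20, generations = 5,
                     divergence_generations = 2, seed = 3,
                     breeds = list(list(name = "X"), list(name = "Y")))
  expect_equal(nrow(simulate_breeds(cfg0)$truth), 0L)
})

test_that("degrade_and_pedigree plants exactly the configured defects", {
  cfg <- sim_config(n_diploid = 60, chrom_length_bp = 5e6,
                    markers_per_mb = 30, generations = 10, seed = 31,
                    pedigree = list(n_sires = 1L, sons_per_sire = 10L),
                    degradation = list(missing_rate = 0, error_rate = 0,
                                       n_replicates = 2L))
  hs <- simulate_base_population(cfg)
  dg <- degrade_and_pedigree(hs, cfg)
  ids <- dg$gset$sample_id
  expect_equal(length(ids), 60L + 10L + 2L)
  # error rate 0 -> no Mendelian conflicts in any duo
  duos <- dg$pedigree[!is.na(dg$pedigree$sire), ]
  for (i in seq_len(nrow(duos))) {
    rate <- mendelian_error_rate(
      dg$gset$geno[match(duos$sire[i], ids), ],
      dg$gset$geno[match(duos$individual[i], ids), ])
    expect_equal(rate, 0)
  }
  # replicates are exact copies under zero degradation
  for (i in seq_len(nrow(dg$replicates)))
    expect_equal(replicate_concordance(
      dg$gset$geno[match(dg$replicates$id_a[i], ids), ],
      dg$gset$geno[match(dg$replicates$id_b[i], ids), ]), 1.0)
  # composition with the QC rule: 5 sons kept, sire removed
  kept <- prune_relatives(dg$pedigree, ids, family_cap = 5, seed = 4)
  sire_id <- unique(duos$sire)
  expect_false(sire_id %in% kept)
  expect_equal(sum(kept %in% duos$individual), 5L)

  # missing-rate injection lands within 3 s.e. of the target
  cfg2 <- sim_config(n_diploid = 50, chrom_length_bp = 5e6,
                     markers_per_mb = 40, generations = 0, seed = 8,
                     pedigree = list(n_sires = 0L, sons_per_sire = 0L),
                     degradation = list(missing_rate = 0.05,
                                        error_rate = 0, n_replicates = 0L))
  hs2 <- simulate_base_population(cfg2)
  dg2 <- degrade_and_pedigree(hs2, cfg2)
  n_cells <- length(dg2$gset$geno)
  miss <- mean(is.na(dg2$gset$geno))
  se <- sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(miss - 0.05), 3 * se)
  # determinism
  dg3 <- degrade_and_pedigree(hs2, cfg2)
  expect_identical(dg2$gset$geno, dg3$gset$geno)
})
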
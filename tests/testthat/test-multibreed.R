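mk_cores <- function(map, spans, chrom = "1") {
  # spans: list of c(start_idx, end_idx)
  if (!length(spans)) {
    df <- data.frame(chrom = character(0), start_idx = integer(0),
                     end_idx = integer(0), start_bp = numeric(0),
                     end_bp = numeric(0), n_snps = integer(0))
    class(df) <- c("core_regions", "data.frame")
    return(df)
  }
  df <- do.call(rbind, lapply(spans, function(s) data.frame(
    chrom = chrom, start_idx = s[1], end_idx = s[2],
    start_bp = map$pos_bp[s[1]], end_bp = map$pos_bp[s[2]],
    n_snps = s[2] - s[1] + 1L, stringsAsFactors = FALSE)))
  class(df) <- c("core_regions", "data.frame")
  df
}

test_that("shared_regions joins cores sharing >= 1 SNP across breeds", {
  map <- tiny_map(30)
  cores <- list(A = mk_cores(map, list(c(10, 20))),
                B = mk_cores(map, list(c(15, 25))))
  reg <- shared_regions(cores, map, c("A", "B"), "dairy")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_bp, map$pos_bp[10])
  expect_equal(reg$end_bp, map$pos_bp[25])
  expect_equal(reg$n_shared_snps, 6L)   # markers 15..20
  expect_equal(strsplit(reg$shared_snps, ",")[[1]],
               map$marker_id[15:20])
  expect_equal(reg$breeds, "A,B")
})

test_that("two overlapping cores of the same breed form no region", {
  map <- tiny_map(30)
  cores <- list(A = mk_cores(map, list(c(10, 20), c(21, 28))),
                B = mk_cores(map, list()))
  reg <- shared_regions(cores, map, c("A", "B"))
  expect_equal(nrow(reg), 0L)
})

test_that("chained sharing A-B, B-C merges into one region (oracle check)", {
  map <- tiny_map(40)
  cores <- list(A = mk_cores(map, list(c(5, 10))),
                B = mk_cores(map, list(c(9, 16))),
                C = mk_cores(map, list(c(15, 22))))
  reg <- shared_regions(cores, map, c("A", "B", "C"))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_breeds, 3L)
  expect_equal(reg$start_bp, map$pos_bp[5])
  expect_equal(reg$end_bp, map$pos_bp[22])

  # brute-force pairwise-merge oracle over random configurations
  for (seed in 1:20) {
    set.seed(seed)
    breeds <- c("A", "B", "C")
    spans <- lapply(breeds, function(b) {
      k <- sample(0:3, 1)
      lapply(seq_len(k), function(i) {
        s <- sample(1:35, 1); c(s, min(40, s + sample(2:6, 1)))
      })
    })
    names(spans) <- breeds
    cores <- lapply(spans, function(sp) mk_cores(map, sp))
    reg <- shared_regions(cores, map, breeds)
    core_list <- list()
    for (b in breeds) for (sp in spans[[b]])
      core_list[[length(core_list) + 1L]] <- list(
        breed = b, chrom = "1", start = map$pos_bp[sp[1]],
        end = map$pos_bp[sp[2]], snps = map$marker_id[sp[1]:sp[2]])
    want <- oracle_shared(core_list)
    expect_equal(nrow(reg), length(want))
    if (length(want)) {
      want_start <- sort(vapply(want, `[[`, numeric(1), "start"))
      expect_equal(sort(reg$start_bp), want_start)
    }
    # permutation invariance
    perm <- sample(breeds)
    reg2 <- shared_regions(cores[perm], map, perm, group_name = "g")
    expect_equal(reg2$start_bp, reg$start_bp)
    expect_equal(reg2$end_bp, reg$end_bp)
    expect_equal(reg2$n_shared_snps, reg$n_shared_snps)
    # every shared SNP lies inside the region interval
    for (i in seq_len(nrow(reg))) {
      snps <- strsplit(reg$shared_snps[i], ",")[[1]]
      pos <- map$pos_bp[match(snps, map$marker_id)]
      expect_true(all(pos >= reg$start_bp[i] & pos <= reg$end_bp[i]))
      expect_gte(reg$n_shared_snps[i], 1L)
    }
  }
})

test_that("map mismatch across breeds raises a classed error", {
  map1 <- tiny_map(20)
  map2 <- marker_map(map1$marker_id, "2", map1$pos_bp)  # same ids, other chrom
  cores <- list(A = mk_cores(map1, list(c(2, 6))),
                B = mk_cores(map2, list(c(3, 8)), chrom = "2"))
  expect_error(shared_regions(cores, list(A = map1, B = map2), c("A", "B")),
               class = "rehhscan_map_mismatch_error")
})

test_that("summarize_regions reports counts, sizes, genome fraction", {
  map <- marker_map(paste0("m", 1:4), c("1", "1", "2", "2"),
                    c(1, 1e7 + 1, 1, 1e7 + 1))
  empty <- shared_regions(list(), map, c("A", "B"))
  s0 <- summarize_regions(empty, map)
  expect_equal(s0$n_regions, 0L)
  expect_equal(s0$genome_fraction, 0)

  reg <- data.frame(group = "g", chrom = c("1", "2"),
                    start_bp = c(1, 1), end_bp = c(1e5, 3e5))
  s <- summarize_regions(reg, map)
  tot <- s[s$chrom == "TOTAL", ]
  expect_equal(tot$n_regions, 2L)
  expect_equal(tot$mean_bp, 2e5)
  expect_equal(tot$genome_fraction, 4e5 / 2e7)
  # per-chromosome counts reconcile with the total
  expect_equal(sum(s$n_regions[s$chrom != "TOTAL"]), tot$n_regions)
  # one region of 100 kb on a 10 Mb mapped genome -> fraction 0.01
  map1 <- marker_map(c("a", "b"), "1", c(1, 1e7 + 1))
  r1 <- data.frame(group = "g", chrom = "1", start_bp = 100,
                   end_bp = 100 + 1e5 - 1)
  expect_equal(summarize_regions(r1, map1)$genome_fraction[2], 0.01)
})

test_that("gene_overlap uses closed-interval logic", {
  ann <- gene_annotation(c("g1", "g2", "g3"), "1",
                         c(100, 100, 140), c(200, 200, 400))
  reg <- data.frame(group = "g", chrom = "1",
                    start_bp = c(150, 201, 250), end_bp = c(300, 300, 260))
  reg1 <- gene_overlap(reg[1, ], ann)
  expect_true(grepl("g1", reg1$genes))       # [100,200] x [150,300]
  expect_true(grepl("g3", reg1$genes))       # gene spans the region start
  reg2 <- gene_overlap(reg[2, ], ann[1, ])
  expect_equal(reg2$genes, "")               # [100,200] vs [201,300]: closed
  expect_false(reg2$has_genes)
  # gene spanning an entire region
  reg3 <- gene_overlap(reg[3, ], ann[3, ])
  expect_equal(reg3$genes, "g3")
  # chromosome namespace mismatch
  ann_chr <- gene_annotation("g1", "chr1", 100, 200)
  expect_error(gene_overlap(reg, ann_chr),
               class = "rehhscan_namespace_error")
})

test_that("production groups validate membership and BED export works", {
  pg <- production_groups(dairy = c("HOL", "BRW", "SIM"),
                          beef = c("PIE", "MAR", "SIM"))
  expect_equal(pg$dairy, c("HOL", "BRW", "SIM"))
  expect_error(production_groups(dairy = "HOL"),
               class = "rehhscan_config_error")
  map <- tiny_map(30)
  cores <- list(A = mk_cores(map, list(c(10, 20))),
                B = mk_cores(map, list(c(15, 25))))
  reg <- shared_regions(cores, map, c("A", "B"), "dairy")
  td <- withr::local_tempdir()
  f <- write_regions_bed(reg, file.path(td, "r.bed"))
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, reg$start_bp - 1)     # 0-based half-open
  expect_equal(bed$V3, reg$end_bp)
})
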
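core13 <- list(start_idx = 1L, end_idx = 3L)

test_that("ehh_at matches binomial hand counts", {
  # 4 carriers whose extensions split 2/2 -> (1+1)/C(4,2) = 1/3
  mat <- cbind(matrix(1L, 4, 3), c(0L, 0L, 1L, 1L), 0L)
  mat <- rbind(mat, matrix(0L, 2, 5))          # non-carriers
  hs <- hs_from_matrix(mat)
  carriers <- 1:4
  expect_equal(ehh_at(hs, carriers, core13, 4L), 1 / 3)
  # identical over the interval -> 1
  expect_equal(ehh_at(hs, carriers, core13, 5L - 2L), 1)  # core edge
  # 5 carriers split 3/1/1 -> 3/10
  mat2 <- cbind(matrix(1L, 5, 3), c(0L, 0L, 0L, 1L, 1L),
                c(0L, 0L, 0L, 0L, 1L))
  mat2 <- rbind(mat2, matrix(0L, 1, 5))
  hs2 <- hs_from_matrix(mat2)
  expect_equal(ehh_at(hs2, 1:5, core13, 5L), 3 / 10)
  expect_error(ehh_at(hs, 1L, core13, 4L),
               class = "rehhscan_undefined_error")
})

test_that("ehh_at equals the all-pairs identity-scan oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- 2 * sample(4:20, 1)
    m <- sample(6:20, 1)
    hs <- random_hapset(seed = i + 1000, n_hap = n, n_markers = m)
    core <- list(start_idx = 2L, end_idx = 4L)
    strings <- rehhscan:::hap_strings(hs$hap, 2:4)
    top <- names(sort(table(strings), decreasing = TRUE))[1]
    carriers <- which(strings == top)
    if (length(carriers) < 2) next
    x <- sample(5:m, 1)
    expect_equal(ehh_at(hs, carriers, core, x),
                 oracle_ehh(hs$hap, carriers, 2:x))
  }
})

test_that("ehh_pooled_others is the EHH of the combined non-carrier set", {
  # two other alleles fully conserved, 3 carriers each:
  # numerator C(3,2)+C(3,2)=6, denominator C(6,2)=15
  mat <- rbind(matrix(c(1L, 1L, 0L), 3, 3, byrow = TRUE),
               matrix(c(0L, 1L, 0L), 3, 3, byrow = TRUE),
               matrix(c(0L, 0L, 1L), 4, 3, byrow = TRUE))
  hs <- hs_from_matrix(mat)
  core <- list(start_idx = 1L, end_idx = 2L)
  others <- list(1:3, 4:6)
  expect_equal(ehh_pooled_others(hs, others, core, 3L), 6 / 15)
  expect_equal(ehh_pooled_others(hs, others, core, 3L),
               oracle_ehh_pooled(hs$hap, 1:6, 1:3))

  # all non-carriers mutually distinct over the interval -> 0
  mat2 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  hs2 <- hs_from_matrix(mat2)
  expect_equal(
    ehh_pooled_others(hs2, list(2L, 3L, 4L),
                      list(start_idx = 1L, end_idx = 1L), 3L), 0)

  # mixed case: allele s1 with 4 carriers split 2/2, s2 with 2 identical:
  # numerator (1+1)+1 = 3, denominator C(6,2)=15
  mat3 <- rbind(
    matrix(c(1L, 0L, 0L), 2, 3, byrow = TRUE),   # s1 ext A
    matrix(c(1L, 0L, 1L), 2, 3, byrow = TRUE),   # s1 ext B
    matrix(c(0L, 1L, 0L), 2, 3, byrow = TRUE),   # s2 conserved
    matrix(c(1L, 1L, 0L), 2, 3, byrow = TRUE))   # tested allele t
  hs3 <- hs_from_matrix(mat3)
  core2 <- list(start_idx = 1L, end_idx = 2L)
  expect_equal(ehh_pooled_others(hs3, list(1:4, 5:6), core2, 3L), 3 / 15)
  expect_equal(ehh_pooled_others(hs3, list(1:4, 5:6), core2, 3L),
               oracle_ehh_pooled(hs3$hap, 1:6, 1:3))
  expect_error(ehh_pooled_others(hs3, list(1L), core2, 3L),
               class = "rehhscan_undefined_error")
})

test_that("ehh_decay walks outward, includes the stop sample, handles edges", {
  # core at the downstream chromosome end -> curve is just the edge row
  mat <- cbind(c(0L, 0L, 1L, 1L), matrix(1L, 4, 3))
  hs <- hs_from_matrix(mat)
  core_end <- list(start_idx = 2L, end_idx = 4L)
  curve <- ehh_decay(hs, 1:4, core_end, "down")
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$ehh, 1)
  # identical carriers -> EHH = 1 all the way
  hs2 <- hs_from_matrix(matrix(rep(c(0L, 1L), each = 4), 8, 10))
  curve2 <- ehh_decay(hs2, 1:4, list(start_idx = 5L, end_idx = 6L), "down")
  expect_equal(curve2$ehh, rep(1, 5))
  expect_equal(curve2$marker_idx, 6:10)
  # equals the pair-scan oracle at every sampled marker
  hs3 <- random_hapset(7, n_hap = 30, n_markers = 15)
  strings <- rehhscan:::hap_strings(hs3$hap, 6:7)
  top <- names(sort(table(strings), decreasing = TRUE))[1]
  carriers <- which(strings == top)
  core3 <- list(start_idx = 6L, end_idx = 7L)
  for (dir in c("up", "down")) {
    cv <- ehh_decay(hs3, carriers, core3, dir, stop_ehh = 0)
    for (r in seq_len(nrow(cv))) {
      cols <- rehhscan:::ehh_span(core3, cv$marker_idx[r])
      expect_equal(cv$ehh[r], oracle_ehh(hs3$hap, carriers, cols))
    }
    # monotone non-increasing by construction (nested partitions)
    expect_true(all(diff(cv$ehh) <= 1e-12))
  }
})

test_that("rehh evaluates at the nearest test marker with stated semantics", {
  # symmetric two-allele region with mirrored flanks -> rEHH = 1 both ways
  blk <- rep(c(0L, 1L), each = 10)
  flank <- matrix(rbinom(20 * 4, 1, 0.5), 20, 4)
  set.seed(11)
  mat <- cbind(flank[, 1:2], blk, blk, flank[, 3:4])
  mat2 <- rbind(mat, cbind(flank[, 1:2], 1L - blk[1:20], 1L - blk[1:20],
                           flank[, 3:4]))
  # construct explicitly mirrored: allele 0 and allele 1 carriers have
  # identical extension multisets
  ext <- matrix(rbinom(10 * 2, 1, 0.5), 10, 2)
  m <- cbind(rbind(ext, ext), c(rep(0L, 10), rep(1L, 10)),
             rbind(ext, ext))
  hsm <- hs_from_matrix(m)
  corem <- list(start_idx = 3L, end_idx = 3L)
  alm <- core_alleles(corem, hsm)
  for (dir in c("up", "down")) {
    r1 <- rehh(hsm, corem, alm, 1L, dir, test_distance_cm = 0.05)
    r2 <- rehh(hsm, corem, alm, 2L, dir, test_distance_cm = 0.05)
    expect_equal(r1$rehh, 1.0)
    expect_equal(r2$rehh, 1.0)
  }
  # EHH_t = pooled at the test marker -> 1; ratio contract
  expect_equal(r1$ehh_t / r1$ehh_pooled, r1$rehh)
  # no marker within 2x the test distance -> skip error
  hs_edge <- hs_from_matrix(m[, 3, drop = FALSE])
  expect_error(rehh(hs_edge, list(start_idx = 1L, end_idx = 1L),
                    core_alleles(list(start_idx = 1L, end_idx = 1L), hs_edge),
                    1L, "down"),
               class = "rehhscan_missing_marker_error")
})

test_that("rehh tie-break picks the farther marker and honours distance", {
  # markers at exactly 0.2 and 0.3 cM from the core edge: tie at 0.25
  mm <- marker_map(paste0("m", 1:4), "1", c(1e5, 3e5, 5e5, 6e5))
  set.seed(3)
  mat <- matrix(rbinom(20 * 4, 1, 0.5), 20, 4)
  mat[, 2] <- rep(c(0L, 1L), each = 10)
  hs <- haplotype_set(mat, paste0("s", 1:10), "A", mm)
  core <- list(start_idx = 2L, end_idx = 2L)
  al <- core_alleles(core, hs)
  r <- rehh(hs, core, al, 1L, "down", test_distance_cm = 0.25)
  expect_equal(r$marker_idx, 4L)   # 0.3 cM beats 0.2 cM on the tie
})

test_that("EHH and rEHH are invariant to allele relabeling", {
  for (seed in 1:10) {
    hs <- random_hapset(seed, n_hap = 30, n_markers = 12)
    core <- list(start_idx = 4L, end_idx = 6L)
    al <- core_alleles(core, hs)
    if (nrow(al) < 2 || al$carriers[1] < 2) next
    if (sum(al$carriers == al$carriers[1]) > 1) next  # ambiguous match
    base_up <- tryCatch(rehh(hs, core, al, 1L, "up", 0.1)$rehh,
                        error = function(e) NA)
    flip <- sample(12, 3)
    hap2 <- hs$hap; hap2[, flip] <- 1L - hap2[, flip]
    hs2 <- haplotype_set(hap2, hs$sample_id, hs$breed, hs$map)
    al2 <- core_alleles(core, hs2)
    # same carrier-count spectrum
    expect_equal(al2$carriers, al$carriers)
    t2 <- which(al2$carriers == al$carriers[1])[1]
    flip_up <- tryCatch(rehh(hs2, core, al2, t2, "up", 0.1)$rehh,
                        error = function(e) NA)
    expect_equal(flip_up, base_up)
  }
})

test_that("log rEHH is sign-symmetric for two equally frequent alleles", {
  set.seed(2024)
  signs <- integer(0)
  for (rep in 1:200) {
    n2 <- 10
    ext_l <- matrix(rbinom(2 * n2 * 2, 1, 0.5), 2 * n2, 2)
    ext_r <- matrix(rbinom(2 * n2 * 2, 1, 0.5), 2 * n2, 2)
    m <- cbind(ext_l, c(rep(0L, n2), rep(1L, n2)), ext_r)
    hs <- hs_from_matrix(m, spacing = 1e5)
    core <- list(start_idx = 3L, end_idx = 3L)
    al <- core_alleles(core, hs)
    r <- tryCatch(rehh(hs, core, al, 1L, "down", 0.1)$rehh,
                  error = function(e) NA)
    if (is.na(r) || !is.finite(r) || r == 0) next
    if (log(r) != 0) signs <- c(signs, sign(log(r)))
  }
  bt <- binom.test(sum(signs > 0), length(signs), 0.5)
  expect_gt(bt$p.value, 0.01)
})

test_that("bifurcation trees conserve carrier counts", {
  # all carriers identical -> path graph
  hs <- hs_from_matrix(matrix(rep(c(0L, 1L), each = 3), 6, 6))
  core <- list(start_idx = 1L, end_idx = 2L)
  tr <- bifurcation(hs, 1:3, core, "down", max_markers = 4L)
  node <- tr; depth <- 0L
  while (length(node$children)) {
    expect_length(node$children, 1L)
    node <- node$children[[1]]
    depth <- depth + 1L
  }
  expect_equal(depth, 4L)

  # 4 carriers split 2/2 at the first outward marker
  mat <- cbind(matrix(1L, 4, 2), c(0L, 0L, 1L, 1L))
  mat <- rbind(mat, matrix(0L, 2, 3))
  hs2 <- hs_from_matrix(mat)
  tr2 <- bifurcation(hs2, 1:4, list(start_idx = 1L, end_idx = 2L), "down")
  expect_length(tr2$children, 2L)
  expect_equal(unname(sort(vapply(tr2$children, `[[`, numeric(1), "count"))),
               c(2, 2))

  # counts at every depth sum to c_t
  hs3 <- random_hapset(9, n_hap = 20, n_markers = 10)
  strings <- rehhscan:::hap_strings(hs3$hap, 3:4)
  top <- names(sort(table(strings), decreasing = TRUE))[1]
  carriers <- which(strings == top)
  tr3 <- bifurcation(hs3, carriers, list(start_idx = 3L, end_idx = 4L),
                     "down", max_markers = 5L)
  sum_at_depth <- function(node, d) {
    if (d == 0L) return(node$count)
    if (!length(node$children)) return(node$count)  # leaf carries through
    sum(vapply(node$children, sum_at_depth, numeric(1), d - 1L))
  }
  for (d in 0:5) expect_equal(sum_at_depth(tr3, d), length(carriers))
  # JSON serialisation round-trips counts
  td <- withr::local_tempdir()
  f <- write_bifurcation_json(tr3, file.path(td, "t.json"))
  back <- jsonlite::read_json(f)
  expect_equal(back$count, length(carriers))
})
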
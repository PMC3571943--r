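# QC accumulator: tallies, summaries, pair correlation, report tables.

test_that("a single read is tallied into every histogram", {
  r <- fastq_reads("T:1:7:1:1#0/1", "AC", list(c(40L, 2L)))
  st <- qc_accumulate(qc_stats(), r)
  expect_equal(st$n_reads, 1L)
  expect_equal(st$cycle_qual[1, 40 + 1], 1L)
  expect_equal(st$cycle_qual[2, 2 + 1], 1L)
  expect_equal(st$cycle_base[1, "A"], c(A = 1L))
  expect_equal(st$cycle_base[2, "C"], c(C = 1L))
  expect_equal(st$length_hist[2 + 1], 1L)   # length 2
  expect_equal(st$read_qual_hist[21 + 1], 1L)  # floor((40+2)/2) = 21
  expect_equal(st$tile_qual["7", "q20_30"], 1L)

  # additivity: accumulating the same read again doubles every count
  st2 <- qc_accumulate(st, r)
  expect_equal(st2$cycle_qual, 2L * st$cycle_qual)
  expect_equal(st2$cycle_base, 2L * st$cycle_base)
  expect_equal(st2$n_reads, 2L)
})

test_that("length-0 reads update only the length histogram", {
  r <- fastq_reads("T:1:1:1:1#0/1", "", list(integer(0)))
  st <- qc_accumulate(qc_stats(), r)
  expect_equal(st$length_hist[1], 1L)
  expect_equal(sum(st$read_qual_hist), 0L)
  expect_equal(st$n_na_quality, 1L)
  expect_equal(sum(st$tile_qual), 0L)
  d <- read_distributions(st)
  expect_equal(d$length, data.frame(length = 0L, count = 1L))
  expect_true(is.na(d$quality$quality[nrow(d$quality)]))
})

test_that("cycle quantiles use linear interpolation between closest ranks", {
  r <- reads_from_quals(list(10L, 20L, 30L))
  st <- qc_accumulate(qc_stats(), r)
  cs <- cycle_quality_summary(st)
  expect_equal(cs$median[1], 20)
  expect_equal(cs$q1[1], 15)
  expect_equal(cs$q3[1], 25)
  expect_equal(cs$min[1], 10)
  expect_equal(cs$max[1], 30)
  expect_equal(cs$mean[1], 20)

  # degenerate distribution: all statistics collapse to the single score
  r <- reads_from_quals(replicate(5, c(33L, 33L), simplify = FALSE))
  cs <- cycle_quality_summary(qc_accumulate(qc_stats(), r))
  for (col in c("min", "p10", "q1", "median", "q3", "p90", "max", "mean"))
    expect_equal(cs[[col]], c(33, 33))
})

test_that("conservation: per-cycle column sums equal reads reaching the cycle", {
  sim <- simulate_reads(fixture_spec(n_reads = 300, read_length = c(20L, 60L),
                                     seed = 8))
  st <- qc_accumulate(qc_stats(), sim$end1)
  lens <- read_lengths(sim$end1)
  reach <- vapply(seq_len(nrow(st$cycle_qual)),
                  function(cyc) sum(lens >= cyc), 0L)
  expect_equal(unname(rowSums(st$cycle_qual)), reach)
  expect_equal(unname(rowSums(st$cycle_base)), reach)
  expect_equal(sum(st$length_hist), st$n_reads)
  expect_equal(sum(st$read_qual_hist) + st$n_na_quality, st$n_reads)
  expect_equal(sum(st$tile_qual), st$n_reads)
})

test_that("all tables equal an independent nested-loop recomputation", {
  sim <- simulate_reads(fixture_spec(
    n_reads = 200, read_length = c(15L, 40L), n_tiles = 6,
    n_run = list(start = 5, length = 4, fraction = 0.3), seed = 13))
  reads <- sim$end1
  st <- qc_accumulate(qc_stats(), reads)
  orc <- oracle_qc(reads)

  expect_equal(unname(st$cycle_qual), unname(orc$cycle_qual))
  expect_equal(unname(st$cycle_base), unname(orc$cycle_base))
  d <- read_distributions(st)
  expect_equal(d$length, orc$length)
  expect_equal(d$quality, orc$quality)
  tt <- tile_quality_table(st)
  expect_equal(as.integer(tt$tile), orc$tile_keys)
  expect_equal(unname(as.matrix(tt[, -1])), unname(orc$tile_mat))

  bc <- base_composition(st)
  covered <- bc$n > 0
  expect_true(all(abs(rowSums(bc[covered, c("A", "C", "G", "T", "N")]) - 1)
                  < 1e-9))
})

test_that("base composition reflects injected N-runs and trivial cases", {
  sim <- simulate_reads(fixture_spec(
    n_reads = 100, read_length = 70,
    n_run = list(start = 50, length = 11, fraction = 0.4), seed = 4))
  bc <- base_composition(qc_accumulate(qc_stats(), sim$end1))
  expect_true(all(bc$N[50:60] > 0))
  expect_true(all(bc$N[c(1:49, 61:70)] == 0))

  allA <- fastq_reads(sprintf("T:1:1:%d:1#0/1", 1:3),
                      rep("AAAA", 3), replicate(3, rep(30L, 4), simplify = FALSE))
  bc <- base_composition(qc_accumulate(qc_stats(), allA))
  expect_equal(bc$A, rep(1, 4))
  expect_equal(bc$C + bc$G + bc$T + bc$N, rep(0, 4))
})

test_that("tile table bins mean qualities into decade ranges", {
  r <- reads_from_quals(list(rep(35L, 4), rep(8L, 4)), tile = 73L)
  tt <- tile_quality_table(qc_accumulate(qc_stats(), r))
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$tile, "73")
  expect_equal(tt$q0_10, 1L)
  expect_equal(tt$q30_up, 1L)
  expect_equal(tt$q10_20 + tt$q20_30, 0L)

  empty <- tile_quality_table(qc_stats())
  expect_equal(nrow(empty), 0L)
})

test_that("accumulation is order invariant and mergeable", {
  sim <- simulate_reads(fixture_spec(n_reads = 400, read_length = 30,
                                     seed = 17))
  reads <- sim$end1
  whole <- qc_accumulate(qc_stats(), reads)

  set.seed(1)
  perm <- sample(length(reads))
  permuted <- qc_accumulate(qc_stats(), reads[perm])
  expect_equal(permuted, whole)

  a <- qc_accumulate(qc_stats(), reads[1:150])
  b <- qc_accumulate(qc_stats(), reads[151:400])
  expect_equal(qc_merge(a, b), whole)
  expect_error(qc_merge(a, qc_stats(bin_edges = c(0, 20))), "bin edges")
})

test_that("pair quality correlation handles perfect and degenerate cases", {
  q1 <- list(rep(10L, 4), rep(20L, 4), rep(30L, 4))
  same <- reads_from_quals(q1)
  pq <- pair_quality(same, same)
  expect_equal(pq$r, 1.0)
  expect_equal(pq$n_pairs, 3L)
  expect_equal(sum(pq$joint_hist$n_pairs), 3L)

  anti <- reads_from_quals(list(rep(30L, 4), rep(20L, 4), rep(10L, 4)))
  expect_equal(pair_quality(same, anti)$r, -1.0)

  flat <- reads_from_quals(list(rep(20L, 4), rep(20L, 4), rep(21L, 4)))
  zerovar <- reads_from_quals(list(rep(20L, 4), rep(20L, 4), rep(20L, 4)))
  pq <- pair_quality(flat, zerovar)
  expect_false(pq$r_defined)
  expect_true(is.na(pq$r))
  expect_equal(sum(pq$joint_hist$n_pairs), 3L)

  one <- reads_from_quals(list(rep(20L, 4)))
  expect_false(pair_quality(one, one)$r_defined)
})

test_that("report files round-trip and cover the documented set", {
  sim <- simulate_reads(fixture_spec(n_pairs = 80, read_length = 25, seed = 3))
  s1 <- qc_accumulate(qc_stats(), sim$end1)
  s2 <- qc_accumulate(qc_stats(), sim$end2)
  pq <- pair_quality(sim$end1, sim$end2)
  d <- withr::local_tempdir()
  p1 <- write_qc_report(s1, d, suffix = "_1")
  p2 <- write_qc_report(s2, d, suffix = "_2", pairq = pq)
  expect_equal(length(p1), 6L)
  expect_equal(length(p2), 7L)
  expect_true(all(file.exists(c(p1, p2))))

  cs <- cycle_quality_summary(s1)
  back <- read_qc_table(file.path(d, "cycle_summary_1.tsv"))
  expect_equal(back, cs, ignore_attr = TRUE)

  pc <- read_qc_table(file.path(d, "pair_correlation.tsv"))
  expect_equal(sum(pc$n_pairs), pq$n_pairs)
  meta <- attr(pc, "meta")
  r_back <- as.numeric(sub("^#pearson_r\t", "", grep("pearson_r", meta,
                                                     value = TRUE)))
  expect_equal(r_back, pq$r)
})

test_that("empty statistics write header-only tables", {
  d <- withr::local_tempdir()
  paths <- write_qc_report(qc_stats(), d)
  expect_equal(length(paths), 6L)
  for (p in paths) {
    df <- read_qc_table(p)
    expect_equal(nrow(df), 0L)
    expect_gt(ncol(df), 0L)
  }
})
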
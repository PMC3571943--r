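# Filtration stages: trimming, quality, length, tile, pair routing.

test_that("trimming removes maximal low-quality prefixes and suffixes", {
  r <- fastq_reads("T:1:1:1:1#0/1", "AACGTT",
                   list(c(2L, 2L, 30L, 35L, 30L, 2L)))
  t <- trim_reads(r, 20, head = TRUE, tail = TRUE)
  expect_identical(t$qual[[1]], c(30L, 35L, 30L))
  expect_identical(t$seq[1], "CGT")

  # all scores above threshold: identity
  good <- fastq_reads("T:1:1:1:1#0/1", "ACGT", list(rep(30L, 4)))
  expect_reads_equal(trim_reads(good, 20, head = TRUE, tail = TRUE), good)

  # default trims the tail only
  t <- trim_reads(r, 20)
  expect_identical(t$qual[[1]], c(2L, 2L, 30L, 35L, 30L))

  # nothing survives
  bad <- fastq_reads("T:1:1:1:1#0/1", "ACGT", list(rep(2L, 4)))
  t <- trim_reads(bad, 20, head = TRUE, tail = TRUE)
  expect_identical(t$seq[1], "")
  expect_identical(t$qual[[1]], integer(0))
})

test_that("trimming matches the longest-valid-substring oracle exhaustively", {
  scores <- c(2L, 20L, 40L)
  for (mode in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
    for (L in 1:6) {
      grid <- do.call(expand.grid, rep(list(scores), L))
      for (i in seq_len(nrow(grid))) {
        q <- as.integer(grid[i, ])
        win <- oracle_trim_window(q, 20, head = mode[1], tail = mode[2])
        expected <- if (win[2] < win[1]) integer(0) else q[win[1]:win[2]]
        r <- fastq_reads("T:1:1:1:1#0/1",
                         paste(rep("A", L), collapse = ""), list(q))
        got <- trim_reads(r, 20, head = mode[1], tail = mode[2])$qual[[1]]
        expect_identical(got, expected)
      }
    }
  }
})

test_that("trimming is idempotent and yields contiguous substrings", {
  reads <- random_reads(500, len = 25, seed = 6, scores = c(2L, 10L, 25L, 40L))
  once <- trim_reads(reads, 20, head = TRUE, tail = TRUE)
  twice <- trim_reads(once, 20, head = TRUE, tail = TRUE)
  expect_reads_equal(once, twice)
  for (i in seq_along(once$qual)) {
    expect_true(grepl(once$seq[i], reads$seq[i], fixed = TRUE) ||
                  once$seq[i] == "")
    expect_equal(nchar(once$seq[i]), length(once$qual[[i]]))
  }
})

test_that("mean read quality is the arithmetic mean, NA when undefined", {
  r <- fastq_reads(c("a", "b", "c"), c("AAA", "AA", ""),
                   list(rep(40L, 3), c(40L, 2L), integer(0)))
  expect_equal(mean_read_quality(r), c(40, 21, NA))
})

test_that("quality filter combines mean and low-base-fraction criteria", {
  cfg <- filter_config(min_mean_quality = 20, lowq_base_threshold = 3,
                       max_low_qual_fraction = 0.1)
  good <- fastq_reads("g", "ACGT", list(rep(40L, 4)))
  expect_true(passes_quality(good, cfg))

  # 100-base read, 30-base N-run at score 2: mean stays high but the
  # low-quality fraction (0.30) exceeds the 0.1 cap
  q <- c(rep(38L, 70), rep(2L, 30))
  nrun <- fastq_reads("n", paste(c(rep("A", 70), rep("N", 30)), collapse = ""),
                      list(q))
  expect_gt(mean_read_quality(nrun), 20)
  expect_false(passes_quality(nrun, cfg))

  empty <- fastq_reads("e", "", list(integer(0)))
  expect_false(passes_quality(empty, cfg))
})

test_that("quality verdicts agree with a direct reimplementation", {
  reads <- random_reads(2000, len = 20, seed = 31)
  cfg <- filter_config(min_mean_quality = 22, lowq_base_threshold = 10,
                       max_low_qual_fraction = 0.25)
  got <- passes_quality(reads, cfg)
  want <- logical(length(reads))
  for (i in seq_along(want)) {
    q <- reads$qual[[i]]
    want[i] <- (sum(q) / length(q)) >= 22 &&
      (sum(q < 10) / length(q)) <= 0.25
  }
  expect_identical(got, want)
})

test_that("length filter is a simple threshold on read length", {
  r <- fastq_reads(c("a", "b"), c(strrep("A", 120), ""),
                   list(rep(30L, 120), integer(0)))
  expect_identical(passes_length(r, 50), c(TRUE, FALSE))
  expect_identical(passes_length(r, 1), c(TRUE, FALSE))
  expect_true(all(passes_length(random_reads(200, len = 10, seed = 2), 0)))
})

test_that("tile filter removes exactly the blacklisted tiles", {
  h <- parse_headers("HWUSI-EAS100R:6:73:941:1973#0/1")
  expect_false(passes_tile(h, 73L))
  expect_true(passes_tile(h, integer()))

  sim <- simulate_reads(fixture_spec(n_reads = 500, read_length = 20,
                                     n_tiles = 120, seed = 19))
  keep <- passes_tile(sim$end1, c(5L, 31L, 110L))
  expect_identical(keep, !(sim$truth$tile %in% c(5L, 31L, 110L)))
  surviving <- sim$end1[keep]
  expect_identical(sort(surviving$id),
                   sort(sim$end1$id[!(sim$truth$tile %in% c(5L, 31L, 110L))]))

  # header without a tile id: kept with a warning, or strict error
  no_tile <- data.frame(tile = NA_integer_)
  expect_warning(v <- passes_tile(no_tile, 5L), "kept")
  expect_true(v)
  expect_error(passes_tile(no_tile, 5L, missing_tile = "error"),
               "without a tile")
})

test_that("pair routing judges ends independently and conserves pairs", {
  pass <- fastq_reads("P:1:1:1:1#0/1", "ACGT", list(rep(40L, 4)))
  fail <- fastq_reads("P:1:1:1:1#0/2", "ACGT", list(rep(2L, 4)))
  stage <- stage_quality(filter_config(min_mean_quality = 20))

  res <- process_pairs(pass, pass, stage)
  expect_equal(unname(res$counts), c(1L, 1L, 0L, 0L, 0L))
  res <- process_pairs(pass, fail, stage)
  expect_equal(res$counts[["singletons_1"]], 1L)
  expect_equal(length(res$single1), 1L)
  expect_equal(length(res$kept1), 0L)
  res <- process_pairs(fail, pass, stage)
  expect_equal(res$counts[["singletons_2"]], 1L)
  res <- process_pairs(fail, fail, stage)
  expect_equal(res$counts[["dropped"]], 1L)
})

test_that("pair category counts match a per-pair classification oracle", {
  sim <- simulate_reads(fixture_spec(n_pairs = 1000, read_length = 30,
                                     qual_start = 30, qual_end = 20,
                                     read_sd = 6, seed = 23))
  cfg <- filter_config(min_mean_quality = 25)
  res <- process_pairs(sim$end1, sim$end2, stage_quality(cfg))

  kept <- s1 <- s2 <- dr <- 0L
  for (i in seq_len(1000)) {
    p1 <- mean(sim$end1$qual[[i]]) >= 25
    p2 <- mean(sim$end2$qual[[i]]) >= 25
    if (p1 && p2) kept <- kept + 1L
    else if (p1) s1 <- s1 + 1L
    else if (p2) s2 <- s2 + 1L
    else dr <- dr + 1L
  }
  expect_equal(unname(res$counts),
               c(1000L, kept, s1, s2, dr))
  expect_equal(res$counts[["pairs_in"]],
               res$counts[["pairs_kept"]] + res$counts[["singletons_1"]] +
                 res$counts[["singletons_2"]] + res$counts[["dropped"]])
  # all four categories exercised under these conditions
  expect_true(all(c(kept, s1, s2, dr) > 0L))
})

test_that("stages compose: chained filters equal the one-shot conjunction", {
  reads <- random_reads(800, len = 40, seed = 37,
                        scores = c(2L, 5L, 20L, 30L, 40L))
  trimmed <- trim_reads(reads, 20, head = FALSE, tail = TRUE)
  chained <- trimmed[passes_length(trimmed, 25)]
  chained <- chained[passes_quality(chained, filter_config(min_mean_quality = 22))]

  # one-shot oracle: apply the transform, then the conjunction of predicates
  keep <- logical(length(reads))
  for (i in seq_along(keep)) {
    q <- reads$qual[[i]]
    hi <- length(q)
    while (hi >= 1 && q[hi] < 20) hi <- hi - 1
    qt <- if (hi >= 1) q[1:hi] else integer(0)
    keep[i] <- length(qt) >= 25 && length(qt) > 0 && mean(qt) >= 22
  }
  oneshot <- trim_reads(reads[keep], 20, head = FALSE, tail = TRUE)
  expect_reads_equal(chained, oneshot)
})

test_that("chastity-failed reads are dropped only when asked", {
  ids <- c("EAS1:1:FC1:1:5:1:1 1:N:0:AC", "EAS1:1:FC1:1:5:2:2 1:Y:0:AC")
  r <- fastq_reads(ids, c("ACGT", "ACGT"),
                   list(rep(40L, 4), rep(40L, 4)))
  off <- stage_quality(filter_config(min_mean_quality = 20))
  expect_equal(off(r)$keep, c(TRUE, TRUE))
  on <- stage_quality(filter_config(min_mean_quality = 20,
                                    drop_chastity_failed = TRUE))
  expect_equal(on(r)$keep, c(TRUE, FALSE))
})
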
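# Independent brute-force oracles and small fixture helpers.  These are
# deliberately written as plain nested loops sharing no code with the
# package internals, so agreement is evidence of correctness rather than
# of shared bugs.

# Build a fastq_reads object from a list of integer quality vectors.
reads_from_quals <- function(quals, tile = 1L, id_prefix = "T") {
  n <- length(quals)
  ids <- sprintf("%s:1:%d:%d:%d#0/1", id_prefix, tile, seq_len(n), seq_len(n))
  seqs <- vapply(quals, function(q)
    paste(rep("A", length(q)), collapse = ""), "")
  fastq_reads(ids, seqs, quals)
}

random_reads <- function(n, len = 30L, seed = 1L, scores = 2:41, tiles = 1:4) {
  set.seed(seed)
  quals <- replicate(n, sample(scores, len, replace = TRUE), simplify = FALSE)
  tl <- sample(tiles, n, replace = TRUE)
  ids <- sprintf("RND:1:%d:%d:%d#0/1", tl, seq_len(n), seq_len(n))
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T", "N"), len,
                                    replace = TRUE), collapse = ""))
  fastq_reads(ids, seqs, quals)
}

# Brute-force end trimming: enumerate every contiguous substring (and the
# empty read), keep those satisfying the trimming post-condition, return
# the longest as c(lo, hi); c(1, 0) denotes the empty result.
oracle_trim_window <- function(q, threshold, head, tail) {
  L <- length(q)
  best <- c(1L, 0L)
  cand <- list()
  for (lo in 1:(L + 1L)) {
    for (hi in 0:L) {
      if (lo > hi + 1L) next
      empty <- lo > hi
      ok <- TRUE
      # prefix q[1..lo-1] removed
      if (lo > 1L) {
        if (!head) ok <- FALSE
        else for (k in 1:(lo - 1L)) if (q[k] >= threshold) ok <- FALSE
      }
      # suffix q[hi+1..L] removed
      if (hi < L) {
        if (!tail) ok <- FALSE
        else for (k in (hi + 1L):L) if (q[k] >= threshold) ok <- FALSE
      }
      if (!empty) {
        if (head && q[lo] < threshold) ok <- FALSE
        if (tail && q[hi] < threshold) ok <- FALSE
      }
      if (ok && (hi - lo + 1L) > (best[2] - best[1] + 1L))
        best <- c(lo, hi)
    }
  }
  best
}

# Brute-force recomputation of every QC table from raw reads, nested loops
# only.  Returns plain matrices/data.frames keyed like the package tables.
oracle_qc <- function(reads, bin_edges = c(0, 10, 20, 30)) {
  n <- length(reads)
  lens <- integer(n)
  for (i in seq_len(n)) lens[i] <- length(reads$qual[[i]])
  maxc <- max(c(0L, lens))

  cq <- matrix(0L, nrow = maxc, ncol = 94)
  cb <- matrix(0L, nrow = maxc, ncol = 5,
               dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_len(n)) {
    q <- reads$qual[[i]]
    b <- strsplit(toupper(reads$seq[i]), "")[[1]]
    for (cyc in seq_along(q)) {
      cq[cyc, q[cyc] + 1L] <- cq[cyc, q[cyc] + 1L] + 1L
      col <- switch(b[cyc], A = 1L, C = 2L, G = 3L, T = 4L, 5L)
      cb[cyc, col] <- cb[cyc, col] + 1L
    }
  }

  lh <- list()
  qh <- list()
  n_na <- 0L
  tiles <- parse_headers(reads$id)$tile
  tq <- list()
  for (i in seq_len(n)) {
    lk <- as.character(lens[i])
    lh[[lk]] <- (if (is.null(lh[[lk]])) 0L else lh[[lk]]) + 1L
    q <- reads$qual[[i]]
    if (length(q) == 0L) { n_na <- n_na + 1L; next }
    m <- sum(q) / length(q)
    qk <- as.character(floor(m))
    qh[[qk]] <- (if (is.null(qh[[qk]])) 0L else qh[[qk]]) + 1L
    bin <- 0L
    for (e in bin_edges) if (m >= e) bin <- bin + 1L
    if (bin < 1L) bin <- 1L
    tk <- as.character(tiles[i])
    if (is.null(tq[[tk]])) tq[[tk]] <- integer(length(bin_edges))
    tq[[tk]][bin] <- tq[[tk]][bin] + 1L
  }

  len_keys <- sort(as.integer(names(lh)))
  len_df <- data.frame(length = len_keys,
                       count = vapply(as.character(len_keys),
                                      function(k) lh[[k]], 0L))
  qual_keys <- sort(as.integer(names(qh)))
  qual_df <- data.frame(quality = as.numeric(qual_keys),
                        count = vapply(as.character(qual_keys),
                                       function(k) qh[[k]], 0L))
  tile_keys <- sort(as.integer(names(tq)))
  tile_mat <- t(vapply(as.character(tile_keys), function(k) tq[[k]],
                       integer(length(bin_edges))))
  rownames(len_df) <- rownames(qual_df) <- NULL

  list(cycle_qual = cq, cycle_base = cb, length = len_df,
       quality = qual_df, n_na = n_na,
       tile_keys = tile_keys, tile_mat = tile_mat)
}

# Plain Pearson correlation of per-read mean qualities, computed from
# first principles.
oracle_pair_r <- function(reads1, reads2) {
  n <- length(reads1)
  m1 <- m2 <- numeric(n)
  for (i in seq_len(n)) {
    m1[i] <- sum(reads1$qual[[i]]) / length(reads1$qual[[i]])
    m2[i] <- sum(reads2$qual[[i]]) / length(reads2$qual[[i]])
  }
  a <- m1 - sum(m1) / n
  b <- m2 - sum(m2) / n
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

expect_reads_equal <- function(a, b) {
  expect_identical(a$id, b$id)
  expect_identical(a$seq, b$seq)
  expect_identical(a$qual, b$qual)
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)
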
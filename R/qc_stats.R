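# Single-pass accumulation of all report statistics and emission of the
# tab-delimited report tables.
#
# The accumulator is a set of count matrices/histograms that is (a) order
# invariant and (b) mergeable: accumulating two disjoint read sets and
# summing the accumulators equals accumulating their union.  The merge
# property is what licenses chunked or parallel processing.

N_SCORES <- 94L  # Phred scores 0..93

#' Create an empty QC accumulator
#'
#' Holds per-cycle quality and base counts, read-length and read-quality
#' histograms, per-tile quality-bin counts and the total read count.
#' Feed reads into it with [qc_accumulate()] and combine accumulators from
#' disjoint chunks with [qc_merge()].
#'
#' @param bin_edges lower edges of the mean-quality bins used for the
#'   per-tile table; the last bin is open-ended.  Default decade bins
#'   `[0,10), [10,20), [20,30), [30,Inf)`.
#' @return an object of class `qc_stats`.
#' @export
qc_stats <- function(bin_edges = c(0, 10, 20, 30)) {
  bin_edges <- sort(as.numeric(bin_edges))
  nb <- length(bin_edges)
  structure(list(
    cycle_qual = matrix(0L, nrow = 0L, ncol = N_SCORES),
    cycle_base = matrix(0L, nrow = 0L, ncol = 5L,
                        dimnames = list(NULL, c("A", "C", "G", "T", "N"))),
    length_hist = integer(0),          # index = length + 1
    read_qual_hist = integer(N_SCORES),# index = floor(mean Phred) + 1
    n_na_quality = 0L,                 # length-0 reads: mean quality undefined
    tile_qual = matrix(0L, nrow = 0L, ncol = nb,
                       dimnames = list(character(0), tile_bin_labels(bin_edges))),
    bin_edges = bin_edges,
    n_reads = 0L), class = "qc_stats")
}

tile_bin_labels <- function(edges) {
  nb <- length(edges)
  up <- c(edges[-1], Inf)
  ifelse(is.finite(up),
         sprintf("q%g_%g", edges, up),
         sprintf("q%g_up", edges))
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf("qc_stats: %d reads, %d cycles, %d tiles\n",
              x$n_reads, nrow(x$cycle_qual), nrow(x$tile_qual)))
  invisible(x)
}

grow_rows <- function(m, n) {
  if (nrow(m) >= n) return(m)
  add <- matrix(0L, nrow = n - nrow(m), ncol = ncol(m))
  rbind(m, add)
}

#' Accumulate reads into a QC accumulator
#'
#' For every read: each cycle `c` within the read increments the
#' quality-count and base-count cell for that cycle; the read length,
#' the floor of the mean Phred score, and the tile mean-quality bin are
#' tallied.  A length-0 read contributes only to the length histogram
#' (its mean quality is undefined and is counted in a dedicated `NA`
#' category).
#'
#' @param stats a [qc_stats] accumulator.
#' @param reads a [fastq_reads] object.
#' @param tiles integer vector of tile ids, one per read, or `NULL` to
#'   parse them from the read identifiers (reads whose identifiers match
#'   neither dialect are tallied under a sentinel tile with a warning).
#' @return the updated `qc_stats` object.
#' @export
qc_accumulate <- function(stats, reads, tiles = NULL) {
  stopifnot(inherits(stats, "qc_stats"), inherits(reads, "fastq_reads"))
  n <- length(reads)
  if (n == 0L) return(stats)
  if (is.null(tiles)) {
    tiles <- tryCatch(parse_headers(reads$id)$tile, error = function(e) {
      warning("read identifiers could not be parsed; tiles recorded as NA")
      rep(NA_integer_, n)
    })
  }
  tiles <- rep_len(as.integer(tiles), n)

  lens <- nchar(reads$seq)
  max_cycle <- max(lens, nrow(stats$cycle_qual))
  stats$cycle_qual <- grow_rows(stats$cycle_qual, max_cycle)
  cb <- grow_rows(stats$cycle_base, max_cycle)
  colnames(cb) <- c("A", "C", "G", "T", "N")
  stats$cycle_base <- cb

  pos <- lens > 0L
  if (any(pos)) {
    cyc <- sequence(lens[pos])
    sc <- unlist(reads$qual[pos], use.names = FALSE)
    if (max(sc) >= N_SCORES) stop("Phred score out of range [0, 93]")
    tab <- tabulate((cyc - 1L) * N_SCORES + sc + 1L,
                    nbins = max_cycle * N_SCORES)
    stats$cycle_qual <- stats$cycle_qual +
      matrix(tab, nrow = max_cycle, ncol = N_SCORES, byrow = TRUE)

    chars <- unlist(strsplit(toupper(reads$seq[pos]), "", fixed = TRUE),
                    use.names = FALSE)
    bidx <- match(chars, c("A", "C", "G", "T"))
    bidx[is.na(bidx)] <- 5L  # N and any other ambiguity code
    tab <- tabulate((cyc - 1L) * 5L + bidx, nbins = max_cycle * 5L)
    stats$cycle_base <- stats$cycle_base +
      matrix(tab, nrow = max_cycle, ncol = 5L, byrow = TRUE,
             dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  }

  lh <- tabulate(lens + 1L, nbins = max(lens) + 1L)
  nl <- max(length(stats$length_hist), length(lh))
  stats$length_hist <- c(stats$length_hist, integer(nl - length(stats$length_hist))) +
    c(lh, integer(nl - length(lh)))

  mq <- mean_read_quality(reads)
  def <- !is.na(mq)
  if (any(def))
    stats$read_qual_hist <- stats$read_qual_hist +
      tabulate(floor(mq[def]) + 1L, nbins = N_SCORES)
  stats$n_na_quality <- stats$n_na_quality + sum(!def)

  if (any(def)) {
    key <- ifelse(is.na(tiles[def]), "NA", as.character(tiles[def]))
    if (anyNA(tiles[def]))
      warning("reads without a tile id tallied under sentinel tile 'NA'")
    bin <- findInterval(mq[def], stats$bin_edges)
    bin[bin < 1L] <- 1L
    tq <- table(factor(key, levels = sort(unique(key))),
                factor(bin, levels = seq_along(stats$bin_edges)))
    stats$tile_qual <- add_tile_counts(stats$tile_qual, unclass(tq))
  }

  stats$n_reads <- stats$n_reads + n
  stats
}

# Sum two tile x bin count matrices with possibly different row sets.
add_tile_counts <- function(a, b) {
  rows <- union(rownames(a), rownames(b))
  out <- matrix(0L, nrow = length(rows), ncol = ncol(a),
                dimnames = list(rows, colnames(a)))
  if (nrow(a)) out[rownames(a), ] <- out[rownames(a), , drop = FALSE] + a
  if (nrow(b)) out[rownames(b), ] <- out[rownames(b), , drop = FALSE] + b
  out
}

#' Merge two QC accumulators
#'
#' `qc_merge(a, b)` equals accumulating the union of the two read sets in a
#' single pass, so large inputs can be processed in chunks.
#'
#' @param a,b [qc_stats] accumulators built with identical `bin_edges`.
#' @return a merged `qc_stats` object.
#' @export
qc_merge <- function(a, b) {
  stopifnot(inherits(a, "qc_stats"), inherits(b, "qc_stats"))
  if (!identical(a$bin_edges, b$bin_edges))
    stop("cannot merge qc_stats with different tile bin edges")
  mc <- max(nrow(a$cycle_qual), nrow(b$cycle_qual))
  a$cycle_qual <- grow_rows(a$cycle_qual, mc) + grow_rows(b$cycle_qual, mc)
  cb <- grow_rows(a$cycle_base, mc) + grow_rows(b$cycle_base, mc)
  colnames(cb) <- c("A", "C", "G", "T", "N")
  a$cycle_base <- cb
  nl <- max(length(a$length_hist), length(b$length_hist))
  a$length_hist <- c(a$length_hist, integer(nl - length(a$length_hist))) +
    c(b$length_hist, integer(nl - length(b$length_hist)))
  a$read_qual_hist <- a$read_qual_hist + b$read_qual_hist
  a$n_na_quality <- a$n_na_quality + b$n_na_quality
  a$tile_qual <- add_tile_counts(a$tile_qual, b$tile_qual)
  a$n_reads <- a$n_reads + b$n_reads
  a
}

#' Per-cycle quality summary (heat-map / box-chart table)
#'
#' Quantiles are computed from the per-cycle score histogram by weighted
#' linear interpolation between closest ranks (the convention of
#' `stats::quantile(type = 7)`), so they are exact for small inputs and
#' deterministic.  Cycles reached by no read are emitted with `n = 0` and
#' `NA` statistics rather than dropped, so the cycle axis stays dense.
#'
#' @param stats a [qc_stats] accumulator with at least one read.
#' @return a data.frame with columns `cycle` (1-based), `n` and the score
#'   statistics `min`, `p10`, `q1`, `median`, `q3`, `p90`, `max`, `mean`.
#' @export
cycle_quality_summary <- function(stats) {
  nc <- nrow(stats$cycle_qual)
  out <- data.frame(cycle = seq_len(nc), n = integer(nc),
                    min = rep(NA_real_, nc), p10 = rep(NA_real_, nc),
                    q1 = rep(NA_real_, nc), median = rep(NA_real_, nc),
                    q3 = rep(NA_real_, nc), p90 = rep(NA_real_, nc),
                    max = rep(NA_real_, nc), mean = rep(NA_real_, nc))
  scores <- 0:(N_SCORES - 1L)
  for (cyc in seq_len(nc)) {
    counts <- stats$cycle_qual[cyc, ]
    n <- sum(counts)
    out$n[cyc] <- n
    if (n == 0L) next
    v <- rep.int(scores, counts)
    qs <- stats::quantile(v, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                          names = FALSE)
    out$min[cyc] <- v[1L]
    out$p10[cyc] <- qs[1L]; out$q1[cyc] <- qs[2L]; out$median[cyc] <- qs[3L]
    out$q3[cyc] <- qs[4L];  out$p90[cyc] <- qs[5L]
    out$max[cyc] <- v[n]
    out$mean[cyc] <- sum(scores * counts) / n
  }
  out
}

#' Per-cycle quality histogram in long form
#'
#' @param stats a [qc_stats] accumulator.
#' @return data.frame with columns `cycle`, `score`, `count` (non-zero
#'   cells only, sorted by cycle then score).
#' @export
cycle_quality_table <- function(stats) {
  idx <- which(t(stats$cycle_qual) > 0L)
  nc <- ncol(stats$cycle_qual)
  cyc <- (idx - 1L) %/% nc + 1L
  sc <- (idx - 1L) %% nc
  data.frame(cycle = cyc, score = sc,
             count = t(stats$cycle_qual)[idx])[order(cyc, sc), , drop = FALSE]
}

#' Per-cycle base composition
#'
#' @param stats a [qc_stats] accumulator.
#' @return data.frame with columns `cycle`, `n` and fractions `A`, `C`,
#'   `G`, `T`, `N` summing to 1 on every cycle reached by at least one
#'   read (`NA` otherwise).
#' @export
base_composition <- function(stats) {
  tot <- rowSums(stats$cycle_base)
  fr <- stats$cycle_base / ifelse(tot > 0, tot, NA_real_)
  data.frame(cycle = seq_len(nrow(fr)), n = as.integer(tot),
             A = fr[, "A"], C = fr[, "C"], G = fr[, "G"],
             T = fr[, "T"], N = fr[, "N"], row.names = NULL)
}

#' Read-length and read-quality distributions
#'
#' @param stats a [qc_stats] accumulator.
#' @return a list with data.frames `length` (columns `length`, `count`)
#'   and `quality` (columns `quality` = floor of mean Phred, `count`),
#'   both sorted ascending.  Reads with undefined mean quality (length 0)
#'   appear as a final `quality = NA` row.
#' @export
read_distributions <- function(stats) {
  lh <- stats$length_hist
  li <- which(lh > 0L)
  len_df <- data.frame(length = li - 1L, count = lh[li])
  qh <- stats$read_qual_hist
  qi <- which(qh > 0L)
  qual_df <- data.frame(quality = as.numeric(qi - 1L), count = qh[qi])
  if (stats$n_na_quality > 0L)
    qual_df <- rbind(qual_df,
                     data.frame(quality = NA_real_, count = stats$n_na_quality))
  list(length = len_df, quality = qual_df)
}

#' Per-tile quality-bin table
#'
#' One row per tile, sorted by tile id, with the number of reads whose
#' mean Phred score falls in each bin.  Reads whose identifier carried no
#' tile appear in a final sentinel row `NA`.
#'
#' @param stats a [qc_stats] accumulator.
#' @return data.frame with column `tile` followed by one count column per
#'   quality bin.
#' @export
tile_quality_table <- function(stats) {
  tq <- stats$tile_qual
  ids <- rownames(tq)
  num <- suppressWarnings(as.numeric(ids))
  ord <- order(is.na(num), num)
  tq <- tq[ord, , drop = FALSE]
  cbind(data.frame(tile = rownames(tq), stringsAsFactors = FALSE),
        as.data.frame(tq, row.names = seq_len(nrow(tq))))
}

#' Paired-end quality correlation
#'
#' Computes the Pearson correlation of per-read mean Phred scores between
#' the two ends of a paired run, together with a joint histogram of the
#' two means in unit score bins so nonlinearity can be judged visually.
#'
#' @param reads1,reads2 [fastq_reads] for end 1 and end 2, pair-ordered.
#' @param bin_width width of the joint-histogram bins in score units.
#' @return an object of class `pair_quality`: a list with `r` (Pearson
#'   correlation, `NA` when fewer than two usable pairs or zero variance
#'   on either end), `r_defined` (logical), `n_pairs` (pairs with defined
#'   mean quality on both ends) and `joint_hist` (data.frame with columns
#'   `end1_bin`, `end2_bin`, `n_pairs`; bins are floors of the mean).
#' @export
pair_quality <- function(reads1, reads2, bin_width = 1) {
  if (length(reads1) != length(reads2))
    stop("paired read sets have unequal lengths")
  m1 <- mean_read_quality(reads1)
  m2 <- mean_read_quality(reads2)
  ok <- !is.na(m1) & !is.na(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  n <- length(m1)
  r <- NA_real_
  defined <- n >= 2L && stats::sd(m1) > 0 && stats::sd(m2) > 0
  if (defined) r <- stats::cor(m1, m2)
  b1 <- floor(m1 / bin_width) * bin_width
  b2 <- floor(m2 / bin_width) * bin_width
  jh <- as.data.frame(table(end1_bin = b1, end2_bin = b2),
                      stringsAsFactors = FALSE)
  jh <- jh[jh$Freq > 0L, , drop = FALSE]
  jh <- data.frame(end1_bin = as.numeric(jh$end1_bin),
                   end2_bin = as.numeric(jh$end2_bin),
                   n_pairs = as.integer(jh$Freq))
  jh <- jh[order(jh$end1_bin, jh$end2_bin), , drop = FALSE]
  rownames(jh) <- NULL
  structure(list(r = r, r_defined = defined, n_pairs = n, joint_hist = jh),
            class = "pair_quality")
}

#' @export
print.pair_quality <- function(x, ...) {
  cat(sprintf("pair_quality: n_pairs = %d, Pearson r = %s\n", x$n_pairs,
              if (x$r_defined) sprintf("%.4f", x$r) else "undefined"))
  invisible(x)
}

# ---- report writing -------------------------------------------------------

QC_TABLE_FILES <- c(
  cycle_quality     = "cycle_quality",
  cycle_summary     = "cycle_summary",
  base_composition  = "base_composition",
  length_dist       = "length_dist",
  read_quality_dist = "read_quality_dist",
  tile_quality      = "tile_quality")

fmt_cell <- function(x) {
  out <- if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  out[is.na(x)] <- "NA"
  out
}

# Atomic TSV writer: single '#'-prefixed header row naming the columns
# (preceded by optional '#'-prefixed metadata lines), tab-separated rows,
# newline-terminated.  Writes to a temp file in the same directory, then
# renames, so no partial file is ever left behind.
write_qc_table <- function(df, path, meta = character()) {
  cells <- vapply(df, fmt_cell, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(df) == 0L) cells <- matrix(character(), 0L, ncol(df))
  rows <- if (nrow(df)) apply(cells, 1L, paste, collapse = "\t") else character()
  lines <- c(meta, paste0("#", paste(names(df), collapse = "\t")), rows)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("cannot write report table: ", path)
  ok <- TRUE
  invisible(path)
}

#' Read a report table written by [write_qc_report()]
#'
#' @param path path to a `.tsv` report table.
#' @return a data.frame; leading metadata lines (before the column-header
#'   line) are attached as the `"meta"` attribute.
#' @export
read_qc_table <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, "#"))
  if (!length(hdr) || hdr[1] != 1L || any(diff(hdr) != 1L))
    stop("malformed report table (expected leading '#' header lines): ", path)
  h <- hdr[length(hdr)]
  cols <- strsplit(substring(lines[h], 2L), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(h)]
  if (!length(body)) {
    df <- as.data.frame(matrix(character(), 0L, length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
  } else {
    df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE, na.strings = "NA",
                            quote = "", comment.char = "")
  }
  attr(df, "meta") <- if (h > 1L) lines[seq_len(h - 1L)] else character()
  df
}

#' Write the QC report tables
#'
#' Emits one tab-delimited file per statistic into `dir`:
#' `cycle_quality.tsv`, `cycle_summary.tsv`, `base_composition.tsv`,
#' `length_dist.tsv`, `read_quality_dist.tsv`, `tile_quality.tsv`, and —
#' when `pairq` is supplied — `pair_correlation.tsv`.  Each file has a
#' single `#`-prefixed header row naming its columns, deterministic row
#' order, and is written atomically (temp file + rename).  For paired runs
#' call once per end with `suffix = "_1"` / `"_2"`.
#'
#' @param stats a [qc_stats] accumulator.
#' @param dir output directory (created if missing).
#' @param suffix suffix inserted before `.tsv` in every per-end file name.
#' @param pairq optional [pair_quality] result; written without a suffix.
#' @return character vector of the files written, invisibly.
#' @export
write_qc_report <- function(stats, dir, suffix = "", pairq = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create report directory: ", dir)
  dists <- read_distributions(stats)
  tables <- list(
    cycle_quality     = cycle_quality_table(stats),
    cycle_summary     = cycle_quality_summary(stats),
    base_composition  = base_composition(stats),
    length_dist       = dists$length,
    read_quality_dist = dists$quality,
    tile_quality      = tile_quality_table(stats))
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(QC_TABLE_FILES[[nm]], suffix, ".tsv"))
    write_qc_table(tables[[nm]], p)
    paths <- c(paths, p)
  }
  if (!is.null(pairq)) {
    p <- file.path(dir, "pair_correlation.tsv")
    meta <- c(sprintf("#pearson_r\t%s",
                      if (pairq$r_defined) sprintf("%.17g", pairq$r) else "NA"),
              sprintf("#n_pairs\t%d", pairq$n_pairs))
    write_qc_table(pairq$joint_hist, p, meta = meta)
    paths <- c(paths, p)
  }
  invisible(paths)
}
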
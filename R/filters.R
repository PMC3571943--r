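# The four filtration stages -- end trimming, quality, length and tile
# filters -- as pure read/pair transformations, plus the paired-end routing
# that sends lone surviving mates to singleton outputs.

#' Filtration thresholds
#'
#' Collects the user-defined cutoffs for the filtration stages.  The two
#' quality criteria are individually disableable: `min_mean_quality = 0`
#' accepts any mean, `max_low_qual_fraction = 1` accepts any fraction of
#' low-quality bases.
#'
#' @param trim_threshold Phred score at which end trimming stops.
#' @param trim_head,trim_tail which read ends to trim.  The default trims
#'   the tail only, where Illumina quality typically collapses; head
#'   trimming is opt-in.
#' @param min_mean_quality minimum mean Phred score of a read.
#' @param lowq_base_threshold a base with score below this is "low quality"
#'   for the fraction criterion.
#' @param max_low_qual_fraction maximum tolerated fraction of low-quality
#'   bases, in `[0, 1]`.
#' @param min_length minimum read length.
#' @param tile_blacklist integer vector of tile ids to remove.
#' @param drop_chastity_failed drop reads whose CASAVA 1.8 header flags a
#'   chastity-filter failure (`Y`).  Off by default; the flag is parsed
#'   but never acted on implicitly.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(trim_threshold = 20,
                          trim_head = FALSE, trim_tail = TRUE,
                          min_mean_quality = 20,
                          lowq_base_threshold = 5,
                          max_low_qual_fraction = 1,
                          min_length = 0L,
                          tile_blacklist = integer(),
                          drop_chastity_failed = FALSE) {
  stopifnot(trim_threshold >= 0, min_mean_quality >= 0,
            lowq_base_threshold >= 0, min_length >= 0,
            max_low_qual_fraction >= 0, max_low_qual_fraction <= 1)
  structure(list(trim_threshold = trim_threshold,
                 trim_head = isTRUE(trim_head), trim_tail = isTRUE(trim_tail),
                 min_mean_quality = min_mean_quality,
                 lowq_base_threshold = lowq_base_threshold,
                 max_low_qual_fraction = max_low_qual_fraction,
                 min_length = as.integer(min_length),
                 tile_blacklist = as.integer(tile_blacklist),
                 drop_chastity_failed = isTRUE(drop_chastity_failed)),
            class = "filter_config")
}

#' Trim low-quality read ends
#'
#' Removes the maximal prefix (`head = TRUE`) and/or suffix
#' (`tail = TRUE`) of bases whose scores are all below `threshold`, i.e.
#' bases are cut from the ends until the quality score reaches the
#' threshold.  The output is always a contiguous substring of the input;
#' when any base survives, the first kept base (under head trimming) and
#' the last kept base (under tail trimming) have score `>= threshold`.
#' A read may be trimmed to length 0; such reads are kept in the output
#' so stages stay pure and composable — chain a length filter to drop
#' them.  Trimming is idempotent.
#'
#' @param reads a [fastq_reads] object.
#' @param threshold Phred score threshold.
#' @param head,tail which ends to trim (default: tail only).
#' @return a [fastq_reads] object of the same length.
#' @export
trim_reads <- function(reads, threshold, head = FALSE, tail = TRUE) {
  if (!head && !tail) return(reads)
  seqs <- reads$seq
  quals <- reads$qual
  for (i in seq_along(quals)) {
    q <- quals[[i]]
    L <- length(q)
    if (L == 0L) next
    keep <- which(q >= threshold)
    lo <- 1L; hi <- L
    if (head) lo <- if (length(keep)) keep[1L] else L + 1L
    if (tail) hi <- if (length(keep)) keep[length(keep)] else 0L
    if (lo == 1L && hi == L) next
    if (lo > hi) {
      seqs[i] <- ""
      quals[[i]] <- integer(0)
    } else {
      seqs[i] <- substr(seqs[i], lo, hi)
      quals[[i]] <- q[lo:hi]
    }
  }
  structure(list(id = reads$id, seq = seqs, qual = quals),
            class = "fastq_reads")
}

#' Mean Phred score per read
#'
#' @param reads a [fastq_reads] object.
#' @return numeric vector of arithmetic means of the per-base Phred
#'   scores; `NA` for length-0 reads (undefined).
#' @export
mean_read_quality <- function(reads) {
  vapply(reads$qual,
         function(q) if (length(q)) mean(q) else NA_real_, numeric(1))
}

#' Quality filter verdicts
#'
#' A read passes when its mean Phred score is at least
#' `cfg$min_mean_quality` and the fraction of its bases scoring below
#' `cfg$lowq_base_threshold` is at most `cfg$max_low_qual_fraction`.
#' The fraction criterion catches reads that a mean alone cannot — e.g. a
#' long run of no-call `N` bases at score 2 inside an otherwise good read.
#' Length-0 reads fail.
#'
#' @param reads a [fastq_reads] object.
#' @param cfg a [filter_config].
#' @return logical vector, one verdict per read.
#' @export
passes_quality <- function(reads, cfg) {
  mq <- mean_read_quality(reads)
  lowfrac <- vapply(reads$qual, function(q)
    if (length(q)) mean(q < cfg$lowq_base_threshold) else 1, numeric(1))
  !is.na(mq) & mq >= cfg$min_mean_quality &
    lowfrac <= cfg$max_low_qual_fraction
}

#' Length filter verdicts
#'
#' @param reads a [fastq_reads] object.
#' @param min_length minimum length to pass.
#' @return logical vector: `TRUE` iff the read length is `>= min_length`.
#' @export
passes_length <- function(reads, min_length) {
  nchar(reads$seq) >= min_length
}

#' Tile filter verdicts
#'
#' Removes reads originating from problematic flowcell tiles (chip defects
#' or air bubbles can degrade all reads of a tile).
#'
#' @param headers a data.frame from [parse_headers()], or a [fastq_reads]
#'   object whose identifiers will be parsed.
#' @param blacklist integer vector of tile ids to remove.
#' @param missing_tile what to do with reads whose header carries no tile:
#'   `"keep"` (with a warning) or `"error"`.
#' @return logical vector: `TRUE` iff the read's tile is not blacklisted.
#' @export
passes_tile <- function(headers, blacklist, missing_tile = c("keep", "error")) {
  missing_tile <- match.arg(missing_tile)
  if (inherits(headers, "fastq_reads")) headers <- parse_headers(headers)
  tiles <- headers$tile
  if (anyNA(tiles)) {
    if (missing_tile == "error")
      stop("read without a tile id at record ", which(is.na(tiles))[1])
    warning("reads without a tile id kept (no tile to match against)")
  }
  is.na(tiles) | !(tiles %in% as.integer(blacklist))
}

#' Filtration stages as composable functions
#'
#' Each `stage_*` constructor returns a function of one [fastq_reads]
#' argument yielding `list(reads = <possibly transformed reads>,
#' keep = <logical verdicts>)`.  Stages can be applied to single-end data
#' directly or routed through [process_pairs()] for paired data, and can
#' be chained in any order.
#'
#' * `stage_trim()` trims ends; it never drops a read (`keep` all `TRUE`).
#' * `stage_quality()` applies [passes_quality()], plus the chastity
#'   filter when `cfg$drop_chastity_failed` is set.
#' * `stage_length()` applies [passes_length()].
#' * `stage_tile()` applies [passes_tile()] to the parsed identifiers.
#'
#' @param threshold,head,tail see [trim_reads()].
#' @param cfg a [filter_config].
#' @param min_length see [passes_length()].
#' @param blacklist,missing_tile see [passes_tile()].
#' @return a stage function.
#' @name filter_stages
NULL

#' @rdname filter_stages
#' @export
stage_trim <- function(threshold, head = FALSE, tail = TRUE) {
  force(threshold); force(head); force(tail)
  function(reads) {
    out <- trim_reads(reads, threshold, head = head, tail = tail)
    list(reads = out, keep = rep(TRUE, length(out)))
  }
}

#' @rdname filter_stages
#' @export
stage_quality <- function(cfg) {
  force(cfg)
  function(reads) {
    keep <- passes_quality(reads, cfg)
    if (cfg$drop_chastity_failed) {
      flt <- tryCatch(parse_headers(reads$id)$filtered,
                      error = function(e) rep(NA_character_, length(reads)))
      keep <- keep & !(flt %in% "Y")
    }
    list(reads = reads, keep = keep)
  }
}

#' @rdname filter_stages
#' @export
stage_length <- function(min_length) {
  force(min_length)
  function(reads) list(reads = reads, keep = passes_length(reads, min_length))
}

#' @rdname filter_stages
#' @export
stage_tile <- function(blacklist, missing_tile = "keep") {
  force(blacklist); force(missing_tile)
  function(reads)
    list(reads = reads,
         keep = passes_tile(reads, blacklist, missing_tile = missing_tile))
}

#' Apply a filtration stage to single-end reads
#'
#' @param reads a [fastq_reads] object.
#' @param stage a stage function (see [filter_stages]).
#' @return a list with `kept` ([fastq_reads]) and `counts` (named integer
#'   vector `reads_in`, `reads_kept`, `dropped`).
#' @export
process_reads <- function(reads, stage) {
  res <- stage(reads)
  kept <- res$reads[res$keep]
  list(kept = kept,
       counts = c(reads_in = length(reads), reads_kept = length(kept),
                  dropped = length(reads) - length(kept)))
}

#' Apply a filtration stage to read pairs with singleton routing
#'
#' Each end is judged independently by `stage`.  When both ends pass, the
#' (possibly transformed) pair is kept; when exactly one end passes, that
#' read becomes a singleton — the surviving mate of a broken pair, stored
#' separately so downstream aligners see properly paired files; when
#' neither passes, the pair is dropped.  The counts always satisfy
#' `pairs_in == pairs_kept + singletons_1 + singletons_2 + dropped`.
#'
#' @param reads1,reads2 [fastq_reads] of equal length, pair-ordered.
#' @param stage a stage function (see [filter_stages]).
#' @return a list with `kept1`, `kept2`, `single1`, `single2`
#'   ([fastq_reads]) and `counts` (named integer vector `pairs_in`,
#'   `pairs_kept`, `singletons_1`, `singletons_2`, `dropped`).
#' @export
process_pairs <- function(reads1, reads2, stage) {
  if (length(reads1) != length(reads2))
    stop("paired read sets have unequal lengths")
  res1 <- stage(reads1)
  res2 <- stage(reads2)
  both <- res1$keep & res2$keep
  only1 <- res1$keep & !res2$keep
  only2 <- !res1$keep & res2$keep
  neither <- !res1$keep & !res2$keep
  list(kept1 = res1$reads[both], kept2 = res2$reads[both],
       single1 = res1$reads[only1], single2 = res2$reads[only2],
       counts = c(pairs_in = length(reads1), pairs_kept = sum(both),
                  singletons_1 = sum(only1), singletons_2 = sum(only2),
                  dropped = sum(neither)))
}
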
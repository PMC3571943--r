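# FASTQ input/output, quality-encoding handling and identifier parsing.
#
# Only 4-line (unwrapped) FASTQ is supported.  Parsing is strictly
# positional -- lines 1-4 of each record are identifier, bases, plus-line,
# qualities -- so a "@" or "+" at the start of a quality line can never be
# mistaken for a record boundary.

#' Maximum representable Phred score (ASCII 126 at offset 33)
#' @keywords internal
MAX_PHRED <- 93L

#' Construct a set of FASTQ reads
#'
#' `fastq_reads` is the package's in-memory representation of a batch of
#' sequence reads: parallel vectors of identifiers and base strings plus a
#' list of integer Phred-score vectors.  Quality scores are stored as plain
#' integers, independent of any file encoding; the encoding offset only
#' matters when reading or writing FASTQ.
#'
#' @param id character vector of read identifiers (without the leading `@`).
#' @param seq character vector of base strings over `A,C,G,T,N` (lowercase
#'   accepted and preserved).
#' @param qual list of integer vectors of Phred scores, one per read; each
#'   must have the same length as the corresponding base string and contain
#'   only values in `[0, 93]`.
#'
#' @return An object of class `fastq_reads`.
#' @export
#' @examples
#' r <- fastq_reads("r1", "ACGT", list(c(40L, 40L, 40L, 40L)))
#' length(r)
fastq_reads <- function(id, seq, qual) {
  id <- as.character(id)
  seq <- as.character(seq)
  if (!is.list(qual)) qual <- as.list(qual)
  if (length(id) != length(seq) || length(id) != length(qual))
    stop("id, seq and qual must have equal lengths")
  nb <- nchar(seq)
  nq <- lengths(qual)
  bad <- which(nb != nq)
  if (length(bad))
    stop(sprintf("read '%s': %d bases but %d quality values",
                 id[bad[1]], nb[bad[1]], nq[bad[1]]))
  for (q in qual) {
    if (length(q) && (min(q) < 0L || max(q) > MAX_PHRED))
      stop("Phred scores must lie in [0, ", MAX_PHRED, "]")
  }
  structure(list(id = id, seq = seq, qual = lapply(qual, as.integer)),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
`[.fastq_reads` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i]),
            class = "fastq_reads")
}

#' @export
c.fastq_reads <- function(...) {
  parts <- list(...)
  structure(list(id   = unlist(lapply(parts, `[[`, "id")),
                 seq  = unlist(lapply(parts, `[[`, "seq")),
                 qual = do.call(c, lapply(parts, `[[`, "qual"))),
            class = "fastq_reads")
}

#' @export
print.fastq_reads <- function(x, ...) {
  cat(sprintf("fastq_reads: %d read(s)\n", length(x)))
  n <- min(length(x), 3L)
  for (i in seq_len(n))
    cat(sprintf("  @%s  %s...  (%d bp)\n", x$id[i],
                substr(x$seq[i], 1L, 20L), nchar(x$seq[i])))
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read lengths of a read set
#' @param reads a [fastq_reads] object.
#' @return integer vector of read lengths.
#' @export
read_lengths <- function(reads) nchar(reads$seq)

# Open `path` for text reading; gzfile() detects the gzip magic bytes
# itself, so renamed files work.  "-" reads standard input.
open_input <- function(path) {
  if (identical(path, "-")) return(file("stdin", open = "r"))
  if (!file.exists(path)) stop("input file not found: ", path)
  gzfile(path, open = "rt")
}

#' Read a FASTQ file
#'
#' Streams a 4-line FASTQ file (plain or gzip; compression is detected from
#' the file's magic bytes, not its name) into a [fastq_reads] object.
#' Quality characters are decoded as `ASCII - offset`.  A `@` at the start
#' of a quality line is handled correctly because parsing is positional.
#'
#' @param path path to a FASTQ file, or `"-"` for standard input.
#' @param offset quality-encoding offset, 33 (Sanger / modern Illumina) or
#'   64 (legacy Illumina).  Use [detect_encoding()] to choose automatically.
#' @param n_max maximum number of records to read (default all).
#' @return a [fastq_reads] object.
#' @export
read_fastq <- function(path, offset = 33L, n_max = Inf) {
  con <- open_input(path)
  on.exit(close(con))
  n_lines <- if (is.finite(n_max)) 4L * as.integer(n_max) else -1L
  lines <- readLines(con, n = n_lines)
  parse_fastq_lines(lines, offset = offset, source = path)
}

# Positional parser shared by read_fastq() and detect_encoding().
parse_fastq_lines <- function(lines, offset = 33L, source = "<input>") {
  offset <- as.integer(offset)
  n <- length(lines)
  if (n == 0L)
    return(fastq_reads(character(), character(), list()))
  if (n %% 4L != 0L)
    stop(sprintf("%s: truncated final record (%d lines; 4-line FASTQ required)",
                 source, n))
  i_id <- seq.int(1L, n, by = 4L)
  id_lines <- lines[i_id]
  bad <- which(substr(id_lines, 1L, 1L) != "@")
  if (length(bad))
    stop(sprintf(
      "%s, line %d: expected '@' at start of identifier line (only 4-line FASTQ is supported): %s",
      source, i_id[bad[1]], id_lines[bad[1]]))
  plus <- lines[i_id + 2L]
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop(sprintf(
      "%s, line %d: expected '+' separator line (only 4-line FASTQ is supported): %s",
      source, i_id[bad[1]] + 2L, plus[bad[1]]))
  ids <- substring(id_lines, 2L)
  seqs <- lines[i_id + 1L]
  qstr <- lines[i_id + 3L]
  bad <- which(nchar(seqs) != nchar(qstr))
  if (length(bad))
    stop(sprintf("%s, line %d: read '%s' has %d bases but %d quality characters",
                 source, i_id[bad[1]] + 3L, ids[bad[1]],
                 nchar(seqs[bad[1]]), nchar(qstr[bad[1]])))
  qual <- lapply(qstr, utf8ToInt)
  mins <- vapply(qual, function(q) if (length(q)) min(q) else offset, 0L)
  bad <- which(mins < offset)
  if (length(bad)) {
    ch <- intToUtf8(mins[bad[1]])
    stop(sprintf(
      "%s: quality character '%s' (ASCII %d) in read '%s' is below the phred+%d offset",
      source, ch, mins[bad[1]], ids[bad[1]], offset))
  }
  qual <- lapply(qual, function(q) q - offset)
  fastq_reads(ids, seqs, qual)
}

#' Write reads as FASTQ
#'
#' Emits 4-line records with a bare `+` separator.  Reading the output back
#' with [read_fastq()] at the same offset reproduces identifiers, bases and
#' scores exactly.
#'
#' @param reads a [fastq_reads] object.
#' @param path output path; `"-"` writes to standard output.
#' @param offset encoding offset for the quality characters (33 or 64).
#' @param gzip write gzip-compressed output; default `TRUE` when `path`
#'   ends in `.gz`.
#' @return the number of records written, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L, gzip = grepl("\\.gz$", path)) {
  offset <- as.integer(offset)
  mx <- if (length(reads)) max(vapply(reads$qual, function(q)
    if (length(q)) max(q) else 0L, 0L)) else 0L
  if (mx + offset > 126L)
    stop(sprintf("Phred score %d cannot be encoded at offset %d (ASCII %d > 126)",
                 mx, offset, mx + offset))
  qstr <- vapply(reads$qual, function(q)
    if (length(q)) intToUtf8(q + offset) else "", "")
  block <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qstr))
  if (length(reads) == 0L) block <- character()
  con <- if (identical(path, "-")) stdout()
         else if (gzip) gzfile(path, open = "wb") else file(path, open = "wb")
  if (!identical(path, "-")) on.exit(close(con))
  writeLines(block, con, sep = "\n")
  invisible(length(reads))
}

#' Detect the quality-score encoding of a FASTQ file
#'
#' Scans up to `sample_size` records and inspects the range of quality
#' characters.  Any ASCII code below 59 can only occur under phred+33; a
#' minimum of 64 or above indicates phred+64.  Files whose codes all fall
#' in the ambiguous band `[59, 63]` are reported as phred+33 with
#' `confident = FALSE` and a warning, since phred+33 dominates modern data.
#'
#' @param path path to a FASTQ file (plain or gzip).
#' @param sample_size maximum number of records to inspect.
#' @return a list of class `quality_encoding` with elements `offset`
#'   (33 or 64) and `confident` (logical).
#' @export
detect_encoding <- function(path, sample_size = 10000L) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, n = 4L * as.integer(sample_size))
  n <- length(lines)
  if (n < 4L)
    stop("cannot detect encoding: ", path, " contains no complete FASTQ record")
  n <- n - n %% 4L
  qlines <- lines[seq.int(4L, n, by = 4L)]
  qlines <- qlines[nchar(qlines) > 0L]
  if (!length(qlines))
    stop("cannot detect encoding: no quality characters in ", path)
  codes <- utf8ToInt(paste(qlines, collapse = ""))
  lo <- min(codes)
  if (lo < 59L) {
    enc <- list(offset = 33L, confident = TRUE)
  } else if (lo >= 64L) {
    enc <- list(offset = 64L, confident = TRUE)
  } else {
    warning(sprintf(
      "ambiguous quality encoding in %s (minimum ASCII %d in [59,63]); assuming phred+33",
      path, lo))
    enc <- list(offset = 33L, confident = FALSE)
  }
  structure(enc, class = "quality_encoding")
}

#' @export
print.quality_encoding <- function(x, ...) {
  cat(sprintf("phred+%d (%s)\n", x$offset,
              if (x$confident) "confident" else "low confidence"))
  invisible(x)
}

# Identifier dialects:
#   pre-1.8 CASAVA:  instrument:lane:tile:x:y#index/end   (#index/end optional)
#   CASAVA 1.8:      instrument:run:flowcell:lane:tile:x:y end:filtered:control:index
RE_PRE18 <- paste0(
  "^([^:[:space:]]+):([0-9]+):([0-9]+):(-?[0-9]+):(-?[0-9]+)",
  "(?:#([^/[:space:]]*))?(?:/([0-9]+))?[[:space:]]*$")
RE_CASAVA18 <- paste0(
  "^([^:[:space:]]+):([^:[:space:]]*):([^:[:space:]]*):([0-9]+):([0-9]+):",
  "(-?[0-9]+):(-?[0-9]+)[[:space:]]+([0-9]+):([YN]):([0-9]+):([^[:space:]]*)$")

#' Parse Illumina read identifiers
#'
#' Supports both identifier dialects: the pre-1.8 CASAVA format
#' (`HWUSI-EAS100R:6:73:941:1973#0/1`) and the CASAVA 1.8 format
#' (`EAS139:136:FC706VJ:2:2104:15343:197393 1:Y:18:ATCACG`).  The
#' `pair_key` column is the identifier with the end designator removed
#' (the `/end` suffix, or everything after the first space), and is
#' identical for the two mates of a proper pair.
#'
#' Pre-1.8 identifiers lacking the optional `#index/end` suffix parse with
#' `end = NA` rather than failing.
#'
#' @param id character vector of identifiers (leading `@` optional), or a
#'   [fastq_reads] object.
#' @return a data.frame with one row per identifier and columns `dialect`
#'   (`"pre18"` or `"casava18"`), `instrument`, `run_id`, `flowcell`,
#'   `lane`, `tile`, `x`, `y`, `end`, `filtered`, `control`, `index`,
#'   `pair_key`.  Fields absent from a dialect are `NA`.
#' @export
#' @examples
#' parse_headers("HWUSI-EAS100R:6:73:941:1973#0/1")
parse_headers <- function(id) {
  if (inherits(id, "fastq_reads")) id <- id$id
  id <- as.character(id)
  bare <- sub("^@", "", id)
  n <- length(bare)
  out <- data.frame(
    dialect = character(n), instrument = character(n),
    run_id = NA_character_, flowcell = NA_character_,
    lane = NA_integer_, tile = NA_integer_,
    x = NA_integer_, y = NA_integer_, end = NA_integer_,
    filtered = NA_character_, control = NA_integer_,
    index = NA_character_, pair_key = character(n),
    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  m18 <- regmatches(bare, regexec(RE_CASAVA18, bare))
  is18 <- lengths(m18) == 12L
  mpre <- regmatches(bare, regexec(RE_PRE18, bare))
  ispre <- !is18 & lengths(mpre) == 8L
  bad <- which(!is18 & !ispre)
  if (length(bad))
    stop(sprintf("identifier matches neither CASAVA dialect: '%s'", id[bad[1]]))

  if (any(is18)) {
    g <- do.call(rbind, m18[is18])
    out$dialect[is18]    <- "casava18"
    out$instrument[is18] <- g[, 2L]
    out$run_id[is18]     <- g[, 3L]
    out$flowcell[is18]   <- g[, 4L]
    out$lane[is18]       <- as.integer(g[, 5L])
    out$tile[is18]       <- as.integer(g[, 6L])
    out$x[is18]          <- as.integer(g[, 7L])
    out$y[is18]          <- as.integer(g[, 8L])
    out$end[is18]        <- as.integer(g[, 9L])
    out$filtered[is18]   <- g[, 10L]
    out$control[is18]    <- as.integer(g[, 11L])
    out$index[is18]      <- g[, 12L]
    out$pair_key[is18]   <- sub("[[:space:]].*$", "", bare[is18])
  }
  if (any(ispre)) {
    g <- do.call(rbind, mpre[ispre])
    has_idx <- grepl("#", g[, 1L], fixed = TRUE)
    has_end <- grepl("/", g[, 1L], fixed = TRUE)
    out$dialect[ispre]    <- "pre18"
    out$instrument[ispre] <- g[, 2L]
    out$lane[ispre]       <- as.integer(g[, 3L])
    out$tile[ispre]       <- as.integer(g[, 4L])
    out$x[ispre]          <- as.integer(g[, 5L])
    out$y[ispre]          <- as.integer(g[, 6L])
    out$index[ispre]      <- ifelse(has_idx, g[, 7L], NA_character_)
    ends <- rep(NA_integer_, nrow(g))
    ends[has_end] <- as.integer(g[has_end, 8L])
    out$end[ispre]        <- ends
    out$pair_key[ispre]   <- sub("/[0-9]+[[:space:]]*$", "",
                                 sub("[[:space:]]+$", "", bare[ispre]))
  }
  out
}

#' Read a pair of synchronized FASTQ files
#'
#' Reads both mate files and validates that they contain the same number of
#' records and that every pair of identifiers shares a `pair_key` (see
#' [parse_headers()]), i.e. the files follow standard Illumina pairing.
#'
#' @param path1,path2 paths to the end-1 and end-2 FASTQ files.
#' @param offset quality-encoding offset applied to both files.
#' @return a list with elements `end1` and `end2`, both [fastq_reads] of
#'   equal length.
#' @export
read_fastq_pairs <- function(path1, path2, offset = 33L) {
  r1 <- read_fastq(path1, offset = offset)
  r2 <- read_fastq(path2, offset = offset)
  validate_pairing(r1, r2)
  list(end1 = r1, end2 = r2)
}

#' Validate that two read sets form synchronized pairs
#'
#' @param r1,r2 [fastq_reads] objects holding the two ends.
#' @return invisibly `TRUE`; errors on unequal lengths or a pair-key
#'   mismatch, reporting the first offending record.
#' @export
validate_pairing <- function(r1, r2) {
  if (length(r1) != length(r2)) {
    short <- min(length(r1), length(r2))
    stop(sprintf(
      "paired files have unequal record counts (%d vs %d); first shortfall at record %d",
      length(r1), length(r2), short + 1L))
  }
  if (length(r1) == 0L) return(invisible(TRUE))
  k1 <- parse_headers(r1$id)$pair_key
  k2 <- parse_headers(r2$id)$pair_key
  bad <- which(k1 != k2)
  if (length(bad))
    stop(sprintf("pair-key mismatch at record %d: '%s' vs '%s'",
                 bad[1], r1$id[bad[1]], r2$id[bad[1]]))
  invisible(TRUE)
}
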
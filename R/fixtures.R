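# Seeded synthetic-FASTQ generator.
#
# Emulates the defect phenomenology of Illumina runs that the QC engine is
# meant to detect: per-cycle quality decay towards the 3' tail, whole-tile
# failures, contiguous N-runs, and correlated quality between the two ends
# of a pair.  It is deliberately NOT an Illumina error-model simulator:
# bases are uniform random, and per-base scores are the cycle median plus a
# per-read shift plus bounded symmetric noise, clipped to [2, 41].  The
# symmetric noise keeps the per-cycle population median equal to the
# specified decay curve, which is what makes parameter-recovery checks
# meaningful.

# Run code under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Specify a synthetic FASTQ fixture
#'
#' All randomness is driven by `seed`: identical specs produce
#' byte-identical output.  There is no unseeded path.
#'
#' @param n_reads number of reads (single-end mode).
#' @param n_pairs number of pairs; supplying this switches to paired mode
#'   and `n_reads` is ignored.
#' @param read_length read length, or a length-2 vector `c(lo, hi)` for
#'   per-read lengths uniform on `[lo, hi]`.
#' @param dialect identifier dialect, `"pre18"` or `"casava18"`.
#' @param offset quality-encoding offset the FASTQ will be written with.
#' @param n_tiles tiles are drawn uniformly from `1:n_tiles`.
#' @param bad_tiles named numeric vector mapping tile id to a flat
#'   mean-quality override (e.g. `c("5" = 6)` forces tile 5 to very low
#'   quality), emulating whole-tile failures.
#' @param qual_start,qual_end per-cycle median Phred score at the first
#'   and last cycle; the curve decays linearly between them.  Both must
#'   lie in `[2, 41]`.  The defaults (38 falling to 20) emulate the
#'   routine tail decay of a long Illumina run.
#' @param noise half-width of the uniform per-base score noise around the
#'   cycle median, in score units.
#' @param read_sd standard deviation of the per-read quality shift
#'   (normal, mean 0) that makes some reads globally better than others.
#' @param n_run optional list `list(start =, length =, fraction =)`
#'   injecting a contiguous run of `N` bases (score 2) starting at cycle
#'   `start` into `fraction` of the reads.
#' @param end_correlation target Pearson correlation of per-pair mean
#'   qualities (paired mode only).  The latent between-read correlation is
#'   calibrated analytically so the realized correlation of mean scores
#'   matches the target despite per-base noise.
#' @param chastity_fail_fraction fraction of reads flagged `Y` in the
#'   CASAVA 1.8 filtered field.
#' @param seed integer seed; mandatory determinism.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_reads = 1000L, n_pairs = NULL,
                         read_length = 100L,
                         dialect = c("pre18", "casava18"),
                         offset = 33L, n_tiles = 16L,
                         bad_tiles = NULL,
                         qual_start = 38, qual_end = 20,
                         noise = 3, read_sd = 2,
                         n_run = NULL, end_correlation = NULL,
                         chastity_fail_fraction = 0,
                         seed = 1L) {
  dialect <- match.arg(dialect)
  offset <- as.integer(offset)
  stopifnot(offset %in% c(33L, 64L))
  if (!is.null(n_pairs)) stopifnot(n_pairs >= 0)
  stopifnot(n_reads >= 0, n_tiles >= 1,
            all(read_length >= 0), length(read_length) %in% 1:2,
            qual_start >= 2, qual_start <= 41,
            qual_end >= 2, qual_end <= 41,
            noise >= 0, read_sd >= 0,
            chastity_fail_fraction >= 0, chastity_fail_fraction <= 1)
  if (!is.null(bad_tiles)) {
    if (is.null(names(bad_tiles)) || any(!nzchar(names(bad_tiles))))
      stop("bad_tiles must be a named vector: tile id -> mean quality")
    stopifnot(all(bad_tiles >= 2), all(bad_tiles <= 41))
  }
  if (!is.null(n_run)) {
    stopifnot(is.list(n_run), all(c("start", "length", "fraction") %in% names(n_run)),
              n_run$start >= 1, n_run$length >= 0,
              n_run$fraction >= 0, n_run$fraction <= 1)
  }
  if (!is.null(end_correlation)) {
    stopifnot(!is.null(n_pairs), end_correlation >= -1, end_correlation <= 1)
  }
  structure(list(n_reads = as.integer(n_reads),
                 n_pairs = if (is.null(n_pairs)) NULL else as.integer(n_pairs),
                 read_length = as.integer(read_length), dialect = dialect,
                 offset = offset, n_tiles = as.integer(n_tiles),
                 bad_tiles = bad_tiles, qual_start = qual_start,
                 qual_end = qual_end, noise = noise, read_sd = read_sd,
                 n_run = n_run, end_correlation = end_correlation,
                 chastity_fail_fraction = chastity_fail_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# One end's quality matrix: cycle medians (with per-tile overrides) + a
# per-read shift + bounded symmetric per-base noise, rounded and clipped.
sim_qual_matrix <- function(n, L, med, tiles, bad_tiles, delta, noise) {
  M <- matrix(rep(med, each = n), nrow = n, ncol = L)
  if (!is.null(bad_tiles)) {
    for (tl in names(bad_tiles)) {
      rows <- which(tiles == as.integer(tl))
      if (length(rows)) M[rows, ] <- bad_tiles[[tl]]
    }
  }
  Q <- round(M + delta + matrix(stats::runif(n * L, -noise, noise), n, L))
  Q[Q < 2L] <- 2L
  Q[Q > 41L] <- 41L
  Q
}

make_ids <- function(spec, tiles, x, y, end, chastity) {
  if (spec$dialect == "pre18") {
    base <- sprintf("SIM01:1:%d:%d:%d#0", tiles, x, y)
    if (is.na(end)) base else paste0(base, "/", end)
  } else {
    sprintf("SIM01:1:FC001:1:%d:%d:%d %d:%s:0:ATCACG",
            tiles, x, y, if (is.na(end)) 1L else end,
            ifelse(chastity, "Y", "N"))
  }
}

#' Simulate reads in memory
#'
#' Deterministically expands a [fixture_spec] into one or two
#' [fastq_reads] objects plus a truth table recording, per read, its tile,
#' realized mean quality and N-run membership, and the per-cycle median
#' curve the generator used.
#'
#' @param spec a [fixture_spec].
#' @return a list with `end1` ([fastq_reads]), `end2` ([fastq_reads] or
#'   `NULL` in single-end mode), `truth` (data.frame), `cycle_median`
#'   (numeric vector) and `paired` (logical).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    paired <- !is.null(spec$n_pairs)
    n <- if (paired) spec$n_pairs else spec$n_reads
    Lr <- spec$read_length
    L <- max(Lr)
    med <- if (L > 1) seq(spec$qual_start, spec$qual_end, length.out = L)
           else spec$qual_start
    if (n == 0L) {
      empty <- fastq_reads(character(), character(), list())
      return(list(end1 = empty, end2 = if (paired) empty else NULL,
                  truth = empty_truth(paired), cycle_median = med,
                  paired = paired))
    }
    lens <- if (length(Lr) == 2L) sample(Lr[1]:Lr[2], n, replace = TRUE)
            else rep.int(L, n)
    tiles <- sample.int(spec$n_tiles, n, replace = TRUE)
    x <- seq_len(n)
    y <- sample.int(100000L, n, replace = TRUE)
    chast <- stats::runif(n) < spec$chastity_fail_fraction

    if (paired && !is.null(spec$end_correlation) && spec$read_sd > 0) {
      # attenuate for averaged per-base noise so the realized correlation
      # of mean qualities hits the target
      sig_eps2 <- (spec$noise^2 / 3 + 1 / 12) / mean(lens)
      rho <- spec$end_correlation * (spec$read_sd^2 + sig_eps2) / spec$read_sd^2
      rho <- max(-1, min(1, rho))
      u <- stats::rnorm(n)
      d1 <- spec$read_sd * (sqrt(abs(rho)) * u +
                              sqrt(1 - abs(rho)) * stats::rnorm(n))
      d2 <- spec$read_sd * (sign(rho) * sqrt(abs(rho)) * u +
                              sqrt(1 - abs(rho)) * stats::rnorm(n))
    } else {
      d1 <- stats::rnorm(n, 0, spec$read_sd)
      d2 <- if (paired) stats::rnorm(n, 0, spec$read_sd) else NULL
    }

    in_nrun <- rep(FALSE, n)
    if (!is.null(spec$n_run) && spec$n_run$fraction > 0 && spec$n_run$length > 0)
      in_nrun[sample.int(n, round(spec$n_run$fraction * n))] <- TRUE

    build_end <- function(delta, end_no) {
      Q <- sim_qual_matrix(n, L, med, tiles, spec$bad_tiles, delta, spec$noise)
      B <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
      if (any(in_nrun)) {
        cyc <- intersect(seq.int(spec$n_run$start,
                                 spec$n_run$start + spec$n_run$length - 1L),
                         seq_len(L))
        B[in_nrun, cyc] <- "N"
        Q[in_nrun, cyc] <- 2L
      }
      seqs <- do.call(paste0, as.data.frame(B, stringsAsFactors = FALSE))
      quals <- lapply(seq_len(n), function(i) Q[i, seq_len(lens[i])])
      seqs <- substr(seqs, 1L, lens)
      ids <- make_ids(spec, tiles, x, y,
                      end = if (paired) end_no else NA_integer_, chast)
      fastq_reads(ids, seqs, quals)
    }

    end1 <- build_end(d1, 1L)
    end2 <- if (paired) build_end(d2, 2L) else NULL

    truth <- data.frame(
      read = seq_len(n), id = end1$id, tile = tiles, length = lens,
      in_n_run = in_nrun,
      mean_quality_1 = mean_read_quality(end1),
      mean_quality_2 = if (paired) mean_read_quality(end2) else NA_real_)
    list(end1 = end1, end2 = end2, truth = truth, cycle_median = med,
         paired = paired)
  })
}

empty_truth <- function(paired) {
  data.frame(read = integer(), id = character(), tile = integer(),
             length = integer(), in_n_run = logical(),
             mean_quality_1 = numeric(), mean_quality_2 = numeric())
}

#' Generate a FASTQ fixture on disk
#'
#' Writes the simulated reads as FASTQ (at the spec's encoding offset)
#' plus a tab-separated truth sidecar whose per-read mean qualities are
#' recomputed from the emitted quality strings, and whose metadata lines
#' record the per-cycle median curve.  Identical `(spec, seed)` give
#' byte-identical output.
#'
#' @param spec a [fixture_spec].
#' @param out_prefix path prefix; paired mode writes
#'   `<prefix>_1.fastq` / `<prefix>_2.fastq`, single-end `<prefix>.fastq`,
#'   and both write `<prefix>_truth.tsv`.
#' @param gzip gzip-compress the FASTQ output.
#' @return named list of paths (`fastq`, or `fastq_1`/`fastq_2`, and
#'   `truth`).
#' @export
generate_fixture <- function(spec, out_prefix, gzip = FALSE) {
  sim <- simulate_reads(spec)
  parent <- dirname(out_prefix)
  if (!dir.exists(parent) && !dir.create(parent, recursive = TRUE))
    stop("cannot create output directory: ", parent)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list()
  if (sim$paired) {
    paths$fastq_1 <- paste0(out_prefix, "_1", ext)
    paths$fastq_2 <- paste0(out_prefix, "_2", ext)
    write_fastq(sim$end1, paths$fastq_1, offset = spec$offset, gzip = gzip)
    write_fastq(sim$end2, paths$fastq_2, offset = spec$offset, gzip = gzip)
  } else {
    paths$fastq <- paste0(out_prefix, ext)
    write_fastq(sim$end1, paths$fastq, offset = spec$offset, gzip = gzip)
  }
  paths$truth <- paste0(out_prefix, "_truth.tsv")
  meta <- sprintf("#cycle_medians\t%s",
                  paste(sprintf("%.17g", sim$cycle_median), collapse = ","))
  write_qc_table(sim$truth, paths$truth, meta = meta)
  paths
}
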
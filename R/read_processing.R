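#' Trimming and merging parameter objects
#'
#' `trim_params()` holds the sliding-window quality-trimming settings
#' (window size 4, Phred threshold 12, minimum retained length 130 by
#' default). `merge_params()` holds the pair-merging settings: minimum
#' admissible overlap and maximum mismatch fraction within the overlap.
#'
#' @param window window size in bases (>= 1).
#' @param quality_threshold mean-Phred threshold; a read is cut at the first
#'   window whose mean drops below it (strict `<`).
#' @param min_length reads shorter than this after cutting are rejected.
#' @return a `trim_params` / `merge_params` object.
#' @export
trim_params <- function(window = 4L, quality_threshold = 12,
                        min_length = 130L) {
  stopifnot(window >= 1, min_length >= 1, quality_threshold >= 0)
  structure(list(window = as.integer(window),
                 quality_threshold = quality_threshold,
                 min_length = as.integer(min_length)), class = "trim_params")
}

#' @param min_overlap smallest admissible overlap in nt (>= 5).
#' @param max_mismatch_fraction largest admissible mismatch fraction within
#'   the overlap, in `[0, 1]`.
#' @rdname trim_params
#' @export
merge_params <- function(min_overlap = 20L, max_mismatch_fraction = 0.05) {
  stopifnot(min_overlap >= 5, max_mismatch_fraction >= 0,
            max_mismatch_fraction <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "merge_params")
}

check_read <- function(bases, quals) {
  if (nchar(bases) != length(quals))
    stop("bases and quals lengths differ")
  if (any(quals < 0 | quals > 41)) stop("Phred scores must be in [0, 41]")
}

#' Sliding-window quality trimming of one read
#'
#' Scans 5'->3' over windows of `params$window` bases. At the first window
#' whose mean quality falls below the threshold (strict `<`), the read is
#' cut: leading bases of that window with individual quality still at or
#' above the threshold are retained, the rest removed. If the retained read
#' is shorter than `params$min_length` it is rejected. Trimming is
#' idempotent. Reads shorter than one window are never cut.
#'
#' @param bases read sequence (single string).
#' @param quals integer Phred scores, one per base.
#' @param params a [trim_params()].
#' @return list with `bases`, `quals`, logical `rejected`.
#' @export
sliding_window_trim <- function(bases, quals, params = trim_params()) {
  check_read(bases, quals)
  keep <- cpp_trim_batch(list(as.integer(quals)), params$window,
                         params$quality_threshold)[1]
  out <- list(bases = substr(bases, 1L, keep), quals = quals[seq_len(keep)],
              rejected = keep < params$min_length)
  if (out$rejected) { out$bases <- ""; out$quals <- integer(0) }
  out
}

#' Merge one read pair by its best ungapped overlap
#'
#' The reverse read is given in sequencing orientation and is
#' reverse-complemented internally. The merge takes the *largest* overlap
#' between the forward read and the reverse-complemented mate whose mismatch
#' fraction is at most `params$max_mismatch_fraction` (and at least
#' `params$min_overlap` long). Within the overlap each position takes the
#' base with the higher Phred score (tie: forward base) and the maximum of
#' the two scores; the non-overlapping flanks are concatenated unchanged.
#'
#' @param fwd_bases,fwd_quals forward read and Phred scores.
#' @param rev_bases,rev_quals reverse read (sequencing orientation) and
#'   Phred scores.
#' @param params a [merge_params()].
#' @return list with `bases`, `quals` on success, or `NULL` when no
#'   admissible overlap exists.
#' @export
merge_pair <- function(fwd_bases, fwd_quals, rev_bases, rev_quals,
                       params = merge_params()) {
  check_read(fwd_bases, fwd_quals)
  check_read(rev_bases, rev_quals)
  m <- cpp_merge_batch(fwd_bases, list(as.integer(fwd_quals)),
                       revcomp(rev_bases), list(as.integer(rev_quals)),
                       params$min_overlap, params$max_mismatch_fraction)
  if (!m$ok[1]) return(NULL)
  list(bases = as.character(m$seq[1]), quals = as.integer(m$qual[[1]]))
}

#' Exact full-length dereplication of sequences into ribotypes
#'
#' Case-insensitive exact-identity grouping. Sequences containing characters
#' outside A/C/G/T (e.g. N) are excluded from the table and counted
#' separately. Output is sorted by count (decreasing), ties broken
#' lexicographically by sequence, so tables are byte-stable.
#'
#' @param seqs character vector of merged sequences.
#' @return data frame (`sequence`, `count`) with attribute `n_excluded`.
#' @export
dereplicate <- function(seqs) {
  seqs <- toupper(seqs)
  bad <- !is_clean_dna(seqs)
  if (!length(seqs) || all(bad)) {
    out <- data.frame(sequence = character(0), count = integer(0))
    attr(out, "n_excluded") <- sum(bad)
    return(out)
  }
  tab <- table(seqs[!bad])
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Read a pair of FASTQ files into aligned read lists
#'
#' Plain or gzip FASTQ; Phred+33 qualities. The two files must have equal
#' record counts (mates matched by position).
#'
#' @param r1,r2 paths to the forward/reverse FASTQ files.
#' @return list with `ids`, `fwd`, `rev` (character vectors) and
#'   `fwd_quals`, `rev_quals` (lists of integer vectors).
#' @export
read_paired_fastq <- function(r1, r2) {
  rd <- function(p) {
    x <- tryCatch(Biostrings::readDNAStringSet(p, format = "fastq",
                                               with.qualities = TRUE),
                  error = function(e) stop("malformed FASTQ in ", p, ": ",
                                           conditionMessage(e)))
    qstr <- as.character(S4Vectors::mcols(x)$qualities)
    list(ids = names(x), seq = as.character(x),
         quals = lapply(qstr, function(s) utf8ToInt(s) - 33L))
  }
  a <- rd(r1); b <- rd(r2)
  if (length(a$seq) != length(b$seq))
    stop("R1 and R2 record counts differ")
  list(ids = a$ids, fwd = unname(a$seq), rev = unname(b$seq),
       fwd_quals = unname(a$quals), rev_quals = unname(b$quals))
}

phred_to_int <- function(qstr) {
  lapply(qstr, function(s) utf8ToInt(s) - 33L)
}

#' Process one paired-read pool into a dereplicated sample pool
#'
#' Runs the full per-sample pipeline: sliding-window quality trimming of both
#' mates (a pair is dropped when either mate fails `min_length`), overlap
#' merging, exact dereplication, and abundance sorting. The result's
#' `total_reads` equals the sum of ribotype counts (merged reads containing
#' N are excluded from the table and from the total; the exclusion count is
#' logged). A processing log records rejections at each stage.
#'
#' @param r1,r2 paths to paired FASTQ files, or `r1` may be a
#'   `read_pool_sim` object from [simulate_read_pairs()] (then `r2` is
#'   ignored).
#' @param trim a [trim_params()].
#' @param merge a [merge_params()].
#' @param sample_id,species pool metadata (default: simulator sample id or
#'   the R1 file name).
#' @return a [sample_pool()] (unclassified) with attribute `log`, a list
#'   with `n_pairs_in`, `n_fail_trim`, `n_fail_merge`, `n_excluded_n`,
#'   `n_retained`.
#' @export
process_pool <- function(r1, r2 = NULL, trim = trim_params(),
                         merge = merge_params(), sample_id = NULL,
                         species = NA_character_) {
  if (inherits(r1, "read_pool_sim")) {
    if (is.null(sample_id)) sample_id <- r1$sample_id
    rp <- list(fwd = r1$reads$fwd, rev = r1$reads$rev,
               fwd_quals = phred_to_int(r1$reads$fwd_qual),
               rev_quals = phred_to_int(r1$reads$rev_qual))
  } else {
    if (is.null(sample_id)) sample_id <- sub("_R1.*$", "", basename(r1))
    rp <- read_paired_fastq(r1, r2)
  }
  n_in <- length(rp$fwd)
  log <- list(n_pairs_in = n_in, n_fail_trim = 0L, n_fail_merge = 0L,
              n_excluded_n = 0L, n_retained = 0L)
  empty_pool <- function() {
    p <- sample_pool(sample_id, counts = integer(0),
                     sequences = character(0), species = species,
                     total_reads = 0L)
    attr(p, "log") <- log
    p
  }
  if (n_in == 0L) return(empty_pool())

  kf <- cpp_trim_batch(rp$fwd_quals, trim$window, trim$quality_threshold)
  kr <- cpp_trim_batch(rp$rev_quals, trim$window, trim$quality_threshold)
  pass <- kf >= trim$min_length & kr >= trim$min_length
  log$n_fail_trim <- sum(!pass)
  if (!any(pass)) return(empty_pool())

  fwd <- substr(rp$fwd[pass], 1L, kf[pass])
  rev_tr <- substr(rp$rev[pass], 1L, kr[pass])
  fq <- Map(function(q, k) q[seq_len(k)], rp$fwd_quals[pass], kf[pass])
  rq <- Map(function(q, k) q[seq_len(k)], rp$rev_quals[pass], kr[pass])
  m <- cpp_merge_batch(fwd, fq, revcomp(rev_tr), rq,
                       merge$min_overlap, merge$max_mismatch_fraction)
  log$n_fail_merge <- sum(!m$ok)
  merged <- as.character(m$seq[m$ok])
  if (!length(merged)) return(empty_pool())

  tab <- dereplicate(merged)
  log$n_excluded_n <- attr(tab, "n_excluded")
  log$n_retained <- sum(tab$count)
  pool <- sample_pool(sample_id, counts = tab$count,
                      sequences = tab$sequence, species = species,
                      total_reads = sum(tab$count))
  attr(pool, "log") <- log
  pool
}
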
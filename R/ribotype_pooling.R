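#' Major/minor read-count threshold rule
#'
#' rDNA pools are summarised by splitting ribotypes into *major* and *minor*
#' classes on raw read counts. Deep pools (at least
#' `large_pool_min_total` reads, default 10,000) call a ribotype major only
#' when it has **more than** 1,000 reads; shallower pools use an inclusive
#' cutoff of 100 reads or more. `large_pool_major_min` / `small_pool_major_min`
#' are therefore the *minimum counts that qualify* (1,001 and 100).
#'
#' @param large_pool_min_total pool size (total reads) at which the deep-pool
#'   rule kicks in.
#' @param large_pool_major_min minimum read count qualifying as major in a
#'   deep pool.
#' @param small_pool_major_min minimum read count qualifying as major in a
#'   shallow pool.
#' @return an object of class `threshold_rule`.
#' @export
threshold_rule <- function(large_pool_min_total = 10000L,
                           large_pool_major_min = 1001L,
                           small_pool_major_min = 100L) {
  stopifnot(large_pool_min_total > 0, large_pool_major_min > 0,
            small_pool_major_min > 0,
            large_pool_major_min > small_pool_major_min)
  structure(list(large_pool_min_total = as.integer(large_pool_min_total),
                 large_pool_major_min = as.integer(large_pool_major_min),
                 small_pool_major_min = as.integer(small_pool_major_min)),
            class = "threshold_rule")
}

#' Minimum read count for a major ribotype, given pool depth
#'
#' @param total_reads total read count of the pool (vectorised).
#' @param rule a [threshold_rule()].
#' @return integer vector of cutoffs (counts `>= cutoff` are major).
#' @examples
#' major_cutoff(26172)  # 1001: "more than 1000 reads"
#' major_cutoff(2173)   # 100:  "100 or more reads"
#' @export
major_cutoff <- function(total_reads, rule = threshold_rule()) {
  stopifnot(all(total_reads >= 0))
  ifelse(total_reads >= rule$large_pool_min_total,
         rule$large_pool_major_min, rule$small_pool_major_min)
}

#' Integer percentage of a ribotype within its pool (round half up)
#'
#' Published ribotype tables report each ribotype as an integer percentage of
#' the pool's total reads; halves round up (e.g. 10.5 -> 11), matching the
#' printed tables.
#'
#' @param count per-ribotype read count(s).
#' @param total pool total read count.
#' @return integer percentage(s) in `[0, 100]`.
#' @examples
#' integer_percent(473, 2173)   # 22
#' integer_percent(2864, 16316) # 18
#' @export
integer_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  stopifnot(all(count >= 0), all(count <= total))
  as.integer(floor(100 * count / total + 0.5))
}

#' Construct a sample pool (one sample's ribotype table)
#'
#' @param sample_id sample identifier.
#' @param counts per-ribotype read counts (any order; stored sorted
#'   decreasingly, ties broken lexicographically by sequence).
#' @param sequences optional ribotype sequences (same length as `counts`;
#'   `NA` allowed when only counts are known).
#' @param labels optional ribotype labels.
#' @param species optional species name.
#' @param total_reads pool total; defaults to `sum(counts)`.
#' @return object of class `sample_pool` with a `ribotypes` data frame
#'   (`label`, `sequence`, `count`, `percent`, `status`).
#' @export
sample_pool <- function(sample_id, counts, sequences = NULL, labels = NULL,
                        species = NA_character_, total_reads = sum(counts)) {
  counts <- as.integer(counts)
  stopifnot(length(sample_id) == 1, all(counts >= 0), total_reads >= 0)
  n <- length(counts)
  if (is.null(sequences)) sequences <- rep(NA_character_, n)
  sequences <- toupper(as.character(sequences))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  stopifnot(length(sequences) == n, length(labels) == n)
  seq_clean <- sequences[!is.na(sequences)]
  if (anyDuplicated(seq_clean)) stop("duplicate ribotype sequences in pool")
  if (sum(counts) > total_reads)
    stop("ribotype counts exceed total_reads")
  ord <- order(-counts, sequences, labels)
  rt <- data.frame(label = labels[ord], sequence = sequences[ord],
                   count = counts[ord], percent = rep(NA_integer_, n),
                   status = rep(NA_character_, n), stringsAsFactors = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 species = as.character(species),
                 total_reads = as.integer(total_reads),
                 ribotypes = rt),
            class = "sample_pool")
}

#' Classify ribotypes of a pool as major or minor and fill percentages
#'
#' Applies the read-count threshold for the pool's depth (see
#' [major_cutoff()]) and computes integer percentages of the pool total.
#' Majors are listed before minors (both in decreasing count order);
#' counts and sequences are untouched. Idempotent.
#'
#' @param pool a [sample_pool()].
#' @param rule a [threshold_rule()].
#' @return the pool with `percent` and `status` filled.
#' @export
classify_pool <- function(pool, rule = threshold_rule()) {
  stopifnot(inherits(pool, "sample_pool"))
  rt <- pool$ribotypes
  if (nrow(rt) == 0L) return(pool)
  cut <- major_cutoff(pool$total_reads, rule)
  rt$status <- ifelse(rt$count >= cut, "major", "minor")
  rt$percent <- if (pool$total_reads > 0)
    integer_percent(rt$count, pool$total_reads) else 0L
  ord <- order(rt$status != "major", -rt$count, rt$sequence, rt$label)
  pool$ribotypes <- rt[ord, , drop = FALSE]
  rownames(pool$ribotypes) <- NULL
  pool
}

#' Label ribotypes by rank
#'
#' Assigns `prefix` + rank (1 = most abundant) in the pool's stored order,
#' mirroring the Ae1, Ae2, ... naming convention for major ribotypes.
#' Labels shared across samples (identical sequences) are resolved at the
#' sharing-matrix stage, not here.
#'
#' @param pool a classified [sample_pool()].
#' @param prefix label prefix, unique per pool within an analysis.
#' @return the pool with `label` filled.
#' @export
label_ribotypes <- function(pool, prefix) {
  stopifnot(inherits(pool, "sample_pool"), nchar(prefix) > 0)
  n <- nrow(pool$ribotypes)
  if (n > 0) pool$ribotypes$label <- paste0(prefix, seq_len(n))
  pool
}

#' @param pools list of classified pools.
#' @param prefixes one label prefix per pool; must be unique within the run.
#' @rdname label_ribotypes
#' @export
label_pools <- function(pools, prefixes) {
  stopifnot(length(pools) == length(prefixes))
  if (anyDuplicated(prefixes)) stop("duplicate label prefix within a run")
  Map(label_ribotypes, pools, prefixes)
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("<sample_pool> %s (%s): %d reads, %d ribotypes\n",
              x$sample_id, x$species, x$total_reads, nrow(x$ribotypes)))
  if (nrow(x$ribotypes)) {
    show <- head(x$ribotypes, 10)
    show$sequence <- ifelse(is.na(show$sequence), "<none>",
                            paste0(substr(show$sequence, 1, 24), "..."))
    print(show, row.names = FALSE)
    if (nrow(x$ribotypes) > 10)
      cat(sprintf("  ... and %d more\n", nrow(x$ribotypes) - 10))
  }
  invisible(x)
}

#' Summarise classified pools as one table of major ribotypes
#'
#' Produces the familiar published layout: one row per major ribotype with
#' sample, species, pool total, label, read count and integer percentage.
#'
#' @param pools list of classified [sample_pool()] objects.
#' @param majors_only drop minor ribotypes (default `TRUE`).
#' @return a data frame.
#' @export
pool_summary <- function(pools, majors_only = TRUE) {
  if (inherits(pools, "sample_pool")) pools <- list(pools)
  rows <- lapply(pools, function(p) {
    rt <- p$ribotypes
    if (majors_only) rt <- rt[rt$status %in% "major", , drop = FALSE]
    if (nrow(rt) == 0L) return(NULL)
    data.frame(species = p$species, sample_id = p$sample_id,
               total_reads = p$total_reads, label = rt$label,
               count = rt$count, percent = rt$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), sample_id = character(),
                      total_reads = integer(), label = character(),
                      count = integer(), percent = integer())
  rownames(out) <- NULL
  out
}

#' Build sample pools from a long count table
#'
#' Expects columns `sample_id`, `count` and optionally `species`, `label`,
#' `sequence`, `total_reads` (constant within a sample; when absent the
#' column sums are used, i.e. the table is assumed complete).
#'
#' @param df a data frame, e.g. from [read_pool_table()].
#' @return named list of [sample_pool()] objects (unclassified).
#' @export
pools_from_table <- function(df) {
  stopifnot(all(c("sample_id", "count") %in% names(df)))
  out <- lapply(split(df, df$sample_id), function(s) {
    sample_pool(sample_id = s$sample_id[1],
                counts = s$count,
                sequences = if ("sequence" %in% names(s)) s$sequence else NULL,
                labels = if ("label" %in% names(s)) s$label else NULL,
                species = if ("species" %in% names(s)) s$species[1] else NA,
                total_reads = if ("total_reads" %in% names(s))
                  s$total_reads[1] else sum(s$count))
  })
  out[order(names(out))]
}

#' Read / write long ribotype count tables (TSV)
#'
#' @param path file path.
#' @return `read_pool_table`: a data frame.
#' @export
read_pool_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = NA)
}

#' @param pools list of classified pools (or one pool).
#' @param majors_only see [pool_summary()].
#' @rdname read_pool_table
#' @export
write_pool_table <- function(pools, path, majors_only = FALSE) {
  if (inherits(pools, "sample_pool")) pools <- list(pools)
  rows <- lapply(pools, function(p) {
    rt <- p$ribotypes
    if (majors_only) rt <- rt[rt$status %in% "major", , drop = FALSE]
    cbind(data.frame(sample_id = rep(p$sample_id, nrow(rt)),
                     species = rep(p$species, nrow(rt)),
                     total_reads = rep(p$total_reads, nrow(rt))), rt)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a pool as abundance-annotated FASTA
#'
#' Sequences carry usearch/vsearch-style `;size=N` annotations in the
#' header (`label;size=count`). Ribotypes without sequences are skipped on
#' write.
#'
#' @param pool a [sample_pool()].
#' @param path file path.
#' @export
write_pool_fasta <- function(pool, path) {
  rt <- pool$ribotypes[!is.na(pool$ribotypes$sequence), , drop = FALSE]
  lab <- ifelse(is.na(rt$label), paste0("rt", seq_len(nrow(rt))), rt$label)
  x <- Biostrings::DNAStringSet(rt$sequence)
  names(x) <- sprintf("%s;size=%d", lab, rt$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @param sample_id,species metadata for the reconstructed pool.
#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path, sample_id, species = NA_character_) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  m <- regmatches(hdr, regexpr(";size=[0-9]+", hdr))
  if (length(m) != length(hdr) || any(!nzchar(m)))
    stop("missing ;size= annotation in FASTA headers")
  counts <- as.integer(sub(";size=", "", m))
  labels <- sub(";size=.*$", "", hdr)
  sample_pool(sample_id, counts = counts, sequences = as.character(x),
              labels = labels, species = species)
}

#' Audit a printed count table against the threshold and rounding rules
#'
#' Recomputes percentage and major/minor status for each row of a long table
#' (columns `sample_id`, `total_reads`, `count`, optionally `percent`) and
#' flags rows whose printed values disagree with the recomputation —
#' e.g. listed "major" ribotypes below the depth-appropriate cutoff, or
#' printed percentages inconsistent with count/total.
#'
#' @param df long count table (every row is a putative major ribotype).
#' @param rule a [threshold_rule()].
#' @return `df` with columns `percent_calc`, `major_calc`, and logical
#'   `flag_percent` / `flag_status` marking inconsistencies.
#' @export
audit_pool_table <- function(df, rule = threshold_rule()) {
  stopifnot(all(c("sample_id", "total_reads", "count") %in% names(df)))
  df$percent_calc <- integer_percent(df$count, df$total_reads)
  df$major_calc <- df$count >= major_cutoff(df$total_reads, rule)
  df$flag_status <- !df$major_calc
  df$flag_percent <- if ("percent" %in% names(df))
    df$percent != df$percent_calc else NA
  df
}

#' Bundled Alopecurinae ribotype read counts
#'
#' Major-ribotype read counts from a published paired-amplicon NGS survey of
#' 18S-ITS1-5.8S rDNA pools in Alopecurinae grasses (meadow foxtails and
#' relatives), bundled as a worked example: per sample, the pool's total read
#' count and the read count of each reported major ribotype. Percentages and
#' major/minor statuses are deliberately not stored — they are recomputed by
#' [classify_pool()]/[integer_percent()].
#'
#' @return a long data frame (`species`, `sample_id`, `total_reads`,
#'   `label`, `count`).
#' @export
alopecurinae_pools <- function() {
  read_pool_table(system.file("extdata", "alopecurinae_pools.tsv",
                              package = "ribopool", mustWork = TRUE))
}
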
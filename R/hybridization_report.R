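#' Cross-sample sharing matrix of identical ribotypes
#'
#' Groups ribotype occurrences across classified pools by exact full-length
#' sequence identity (the same notion as dereplication, so shared ribotypes
#' are single network nodes). Each distinct sequence receives a stable
#' shared id; per-sample count, percent and status are preserved, so
#' "major in A, minor in B" relationships remain queryable.
#'
#' @param pools list of classified [sample_pool()] objects with sequences.
#' @return object of class `sharing_matrix`: long data frame
#'   (`shared_id`, `sequence`, `sample_id`, `label`, `count`, `percent`,
#'   `status`).
#' @export
sharing_matrix <- function(pools) {
  if (inherits(pools, "sample_pool")) pools <- list(pools)
  occ <- do.call(rbind, lapply(pools, function(p) {
    rt <- p$ribotypes[!is.na(p$ribotypes$sequence), , drop = FALSE]
    if (!nrow(rt)) return(NULL)
    data.frame(sequence = rt$sequence, sample_id = p$sample_id,
               label = rt$label, count = rt$count, percent = rt$percent,
               status = rt$status, stringsAsFactors = FALSE)
  }))
  if (is.null(occ))
    occ <- data.frame(sequence = character(), sample_id = character(),
                      label = character(), count = integer(),
                      percent = integer(), status = character())
  useq <- sort(unique(occ$sequence))
  sid <- setNames(sprintf("SR%0*d", max(2L, nchar(length(useq))),
                          seq_along(useq)), useq)
  occ <- cbind(shared_id = unname(sid[occ$sequence]), occ)
  occ <- occ[order(occ$shared_id, occ$sample_id), , drop = FALSE]
  rownames(occ) <- NULL
  class(occ) <- c("sharing_matrix", "data.frame")
  occ
}

#' Wide view of a sharing matrix
#'
#' One row per shared ribotype, one column block per sample with
#' `count (percent%, status)` cells; absent cells are empty.
#'
#' @param sm a [sharing_matrix()].
#' @return data frame with `shared_id` and one character column per sample.
#' @export
sharing_wide <- function(sm) {
  ids <- unique(sm$shared_id)
  samples <- sort(unique(sm$sample_id))
  out <- data.frame(shared_id = ids, stringsAsFactors = FALSE)
  for (s in samples) {
    sub <- sm[sm$sample_id == s, ]
    cell <- setNames(sprintf("%d (%d%%, %s)", sub$count, sub$percent,
                             sub$status), sub$shared_id)
    out[[s]] <- ifelse(ids %in% names(cell), cell[ids], "")
  }
  out
}

#' Score a putative hybrid against two candidate parents
#'
#' The parental signal of an allopolyploid hybrid is read from its *major*
#' ribotypes: each is assigned `from_a` / `from_b` / `from_both` when the
#' identical sequence occurs in the respective parent's pool (at any status
#' — matches to parental minors count, as expected under intragenomic rDNA
#' variation), or `hybrid_specific` when private to the hybrid (a candidate
#' post-hybridization derivative). The verdict is `both_parents_detected`
#' when at least one major is inherited from each side, `one_parent_only`
#' when only one side is represented, and `neither` otherwise.
#'
#' @param sm a [sharing_matrix()] containing all three samples.
#' @param hybrid,parent_a,parent_b sample ids.
#' @return object of class `parentage_report`: list with `hybrid_id`,
#'   `parent_a_id`, `parent_b_id`, `assignment` (data frame: one row per
#'   hybrid major ribotype with `shared_id`, `label`, `count`, `percent`,
#'   `origin`), and `verdict`.
#' @export
parentage_support <- function(sm, hybrid, parent_a, parent_b) {
  stopifnot(inherits(sm, "sharing_matrix"))
  present <- unique(sm$sample_id)
  miss <- setdiff(c(hybrid, parent_a, parent_b), present)
  if (length(miss)) stop("sample(s) not in sharing matrix: ",
                         paste(miss, collapse = ", "))
  hy <- sm[sm$sample_id == hybrid & sm$status %in% "major", , drop = FALSE]
  in_a <- unique(sm$shared_id[sm$sample_id == parent_a])
  in_b <- unique(sm$shared_id[sm$sample_id == parent_b])
  origin <- ifelse(hy$shared_id %in% in_a & hy$shared_id %in% in_b, "from_both",
            ifelse(hy$shared_id %in% in_a, "from_a",
            ifelse(hy$shared_id %in% in_b, "from_b", "hybrid_specific")))
  assignment <- data.frame(shared_id = hy$shared_id, label = hy$label,
                           count = hy$count, percent = hy$percent,
                           origin = origin, stringsAsFactors = FALSE)
  has_a <- any(origin %in% c("from_a", "from_both"))
  has_b <- any(origin %in% c("from_b", "from_both"))
  verdict <- if (has_a && has_b) "both_parents_detected"
             else if (has_a || has_b) "one_parent_only" else "neither"
  structure(list(hybrid_id = hybrid, parent_a_id = parent_a,
                 parent_b_id = parent_b, assignment = assignment,
                 verdict = verdict),
            class = "parentage_report")
}

#' @export
print.parentage_report <- function(x, ...) {
  cat(format_parentage(x), sep = "\n")
  invisible(x)
}

#' Human-readable parentage report
#'
#' @param report a [parentage_support()] result.
#' @return character vector of report lines.
#' @export
format_parentage <- function(report) {
  a <- report$assignment
  c(sprintf("Parentage report for hybrid %s (parents: A = %s, B = %s)",
            report$hybrid_id, report$parent_a_id, report$parent_b_id),
    sprintf("Verdict: %s", report$verdict),
    if (nrow(a)) sprintf("  %s [%s]: %d reads (%d%%) -> %s", a$shared_id,
                         ifelse(is.na(a$label), "-", a$label), a$count,
                         a$percent, a$origin)
    else "  (hybrid has no major ribotypes)")
}

#' Write a parentage report as JSON
#'
#' @param report a [parentage_support()] result.
#' @param path output file.
#' @export
write_parentage_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Scan for introgression signatures between two samples
#'
#' Lists shared ribotypes whose status differs between the two pools: major
#' in the donor but only a minor fraction in the focal sample (or vice
#' versa) — the classic signature of past introgression through
#' hybridization and backcrossing. Interpretation (how many reads
#' constitute evidence) is left to the user; all such shared minors are
#' reported with counts and percents.
#'
#' @param sm a [sharing_matrix()].
#' @param focal,donor distinct sample ids present in `sm`.
#' @return data frame (`shared_id`, `focal_label`, `focal_count`,
#'   `focal_percent`, `focal_status`, `donor_label`, `donor_count`,
#'   `donor_percent`, `donor_status`).
#' @export
introgression_scan <- function(sm, focal, donor) {
  stopifnot(inherits(sm, "sharing_matrix"))
  if (identical(focal, donor)) stop("focal and donor must differ")
  miss <- setdiff(c(focal, donor), unique(sm$sample_id))
  if (length(miss)) stop("sample(s) not in sharing matrix: ",
                         paste(miss, collapse = ", "))
  f <- sm[sm$sample_id == focal, , drop = FALSE]
  d <- sm[sm$sample_id == donor, , drop = FALSE]
  shared <- intersect(f$shared_id, d$shared_id)
  f <- f[match(shared, f$shared_id), ]
  d <- d[match(shared, d$shared_id), ]
  keep <- (f$status == "minor" & d$status == "major") |
          (f$status == "major" & d$status == "minor")
  out <- data.frame(shared_id = shared,
                    focal_label = f$label, focal_count = f$count,
                    focal_percent = f$percent, focal_status = f$status,
                    donor_label = d$label, donor_count = d$count,
                    donor_percent = d$percent, donor_status = d$status,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a sharing matrix as TSV (wide) and CSV (long)
#'
#' @param sm a [sharing_matrix()].
#' @param path_wide,path_long output files (`NULL` to skip one).
#' @export
write_sharing <- function(sm, path_wide = NULL, path_long = NULL) {
  if (!is.null(path_wide))
    write.table(sharing_wide(sm), path_wide, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(path_long))
    utils::write.csv(as.data.frame(sm), path_long, row.names = FALSE)
  invisible(sm)
}
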
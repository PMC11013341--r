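#' Generate a family of related ribotype sequences
#'
#' Builds `n_variants` sequences along a mutation chain: variant 1 is random;
#' variant `i + 1` differs from variant `i` by exactly `steps_apart[i]`
#' substitutions at distinct positions. This emulates the within-species
#' ribotype sets seen in rDNA pools, where intragenomic variants differ by a
#' handful of point mutations.
#'
#' @param base_length amplicon length in nt (default 450, an ITS1-region
#'   scale coverable by overlapping 2x300 read pairs).
#' @param n_variants number of family members.
#' @param steps_apart integer vector of length `n_variants - 1`; entry `i` is
#'   the Hamming distance between variants `i` and `i + 1`.
#' @param seed RNG seed.
#' @param prefix id prefix for the members.
#' @return data frame with columns `id`, `sequence`.
#' @export
make_ribotype_family <- function(base_length = 450L, n_variants = 1L,
                                 steps_apart = integer(0), seed = 1L,
                                 prefix = "rt") {
  stopifnot(base_length >= 50, n_variants >= 1,
            length(steps_apart) == n_variants - 1)
  if (length(steps_apart) &&
      (any(steps_apart < 1) || any(steps_apart > base_length / 10)))
    stop("steps_apart entries must be in [1, base_length/10]")
  with_seed(seed, {
    seqs <- character(n_variants)
    base <- sample(DNA_BASES, base_length, replace = TRUE)
    seqs[1] <- paste(base, collapse = "")
    cur <- base
    for (i in seq_along(steps_apart)) {
      nxt <- cur
      pos <- sample.int(base_length, steps_apart[i])
      for (p in pos) nxt[p] <- sample(setdiff(DNA_BASES, nxt[p]), 1)
      cur <- nxt
      seqs[i + 1] <- paste(cur, collapse = "")
    }
    if (anyDuplicated(seqs)) stop("mutation chain revisited a sequence; change seed or steps")
    data.frame(id = paste0(prefix, seq_len(n_variants)), sequence = seqs,
               stringsAsFactors = FALSE)
  })
}

#' Specify a synthetic rDNA pool with known composition
#'
#' A `pool_spec` is the ground truth behind one simulated sample: its member
#' ribotype sequences and their true proportions, the number of read pairs to
#' draw, and a per-base substitution error rate.
#'
#' @param sample_id sample identifier.
#' @param sequences named character vector (or `id`/`sequence` data frame as
#'   from [make_ribotype_family()]) of member ribotypes; A/C/G/T only,
#'   unique, 300-700 nt each.
#' @param proportions true member proportions; must sum to 1 (tolerance 1e-9).
#' @param n_read_pairs number of read pairs to simulate (>= 1).
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param seed integer seed governing all randomness of the pool.
#' @return object of class `pool_spec`.
#' @export
pool_spec <- function(sample_id, sequences, proportions,
                      n_read_pairs = 5000L, error_rate = 0.001, seed = 1L) {
  if (is.data.frame(sequences))
    sequences <- setNames(sequences$sequence, sequences$id)
  sequences <- toupper(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0("m", seq_along(sequences))
  stopifnot(length(sequences) >= 1,
            length(proportions) == length(sequences),
            n_read_pairs >= 1, error_rate >= 0, error_rate <= 0.05)
  if (!all(is_clean_dna(sequences))) stop("sequences must be over {A,C,G,T}")
  if (any(nchar(sequences) < 300) || any(nchar(sequences) > 700))
    stop("member sequences must be 300-700 nt")
  if (anyDuplicated(sequences)) stop("duplicate member sequences")
  if (anyDuplicated(names(sequences))) stop("duplicate member ids")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (any(proportions < 0)) stop("negative proportion")
  structure(list(sample_id = as.character(sample_id),
                 members = data.frame(id = names(sequences),
                                      sequence = unname(sequences),
                                      proportion = as.numeric(proportions),
                                      stringsAsFactors = FALSE),
                 n_read_pairs = as.integer(n_read_pairs),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "pool_spec")
}

#' Derive a hybrid pool spec from two parental specs
#'
#' An allopolyploid hybrid carries the rDNA arrays of both parents, so its
#' expected ribotype pool is the union of the parental member sets with
#' proportions `weight_a * p_A` and `(1 - weight_a) * p_B` (renormalised).
#' Sequences present in both parents are merged into one member with the
#' summed weighted proportion.
#'
#' @param parent_a,parent_b [pool_spec()] objects.
#' @param weight_a contribution of parent A, strictly in (0, 1).
#' @param sample_id id for the hybrid pool.
#' @param n_read_pairs,error_rate,seed simulation settings for the hybrid
#'   (default: inherited from `parent_a`).
#' @return a [pool_spec()] for the hybrid.
#' @export
make_hybrid_spec <- function(parent_a, parent_b, weight_a = 0.5, sample_id,
                             n_read_pairs = parent_a$n_read_pairs,
                             error_rate = parent_a$error_rate,
                             seed = parent_a$seed) {
  stopifnot(inherits(parent_a, "pool_spec"), inherits(parent_b, "pool_spec"),
            weight_a > 0, weight_a < 1)
  a <- parent_a$members
  b <- parent_b$members
  props <- c(a$proportion * weight_a, b$proportion * (1 - weight_a))
  seqs <- c(a$sequence, b$sequence)
  ids <- c(paste0(parent_a$sample_id, ".", a$id),
           paste0(parent_b$sample_id, ".", b$id))
  # merge identical sequences inherited from both sides
  agg <- tapply(props, seqs, sum)
  first <- !duplicated(seqs)
  seq_u <- seqs[first]
  id_u <- ids[first]
  prop_u <- as.numeric(agg[seq_u])
  pool_spec(sample_id, setNames(seq_u, id_u), prop_u / sum(prop_u),
            n_read_pairs = n_read_pairs, error_rate = error_rate, seed = seed)
}

#' Phred quality profile for simulated reads
#'
#' Read qualities follow a deterministic linearly decaying profile:
#' `Q(cycle) = clamp(round(mean_quality - quality_decay * (cycle - 1)), 2, 41)`,
#' emulating the per-cycle quality decline of Illumina chemistry.
#' Substitutions only; indels are not modelled, which keeps exact-identity
#' dereplication and Hamming-distance semantics intact downstream.
#'
#' @param mean_quality Phred score at cycle 1 (in `[2, 41]`).
#' @param quality_decay per-cycle quality decline (>= 0).
#' @param substitution_only must remain `TRUE` (reserved switch).
#' @return object of class `error_model`.
#' @export
error_model <- function(mean_quality = 35, quality_decay = 0.02,
                        substitution_only = TRUE) {
  stopifnot(mean_quality >= 2, mean_quality <= 41, quality_decay >= 0,
            isTRUE(substitution_only))
  structure(list(mean_quality = mean_quality, quality_decay = quality_decay,
                 substitution_only = substitution_only),
            class = "error_model")
}

quality_profile <- function(model, len) {
  q <- round(model$mean_quality - model$quality_decay * (seq_len(len) - 1))
  as.integer(pmin(pmax(q, 2), 41))
}

phred_string <- function(q) {
  intToUtf8(q + 33L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# inject substitution errors into a character vector of reads (vectorised
# over reads; only reads drawing >= 1 error are touched)
inject_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  nerr <- rbinom(length(reads), lens, error_rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  reads
}

#' Simulate a paired-read amplicon pool from a spec
#'
#' Draws each read pair's source member from a seeded multinomial with the
#' spec's true proportions, then emits the forward read (5' prefix of the
#' amplicon) and the reverse read (reverse complement of the 3' suffix), both
#' of `read_length` (capped at the amplicon length), injects substitution
#' errors at the spec's `error_rate`, and attaches Phred qualities from the
#' error model's profile. A truth table records each read pair's source.
#'
#' @param spec a [pool_spec()].
#' @param read_length read length in nt (default 300, MiSeq 2x300).
#' @param min_overlap required overlap between the mates on every member
#'   amplicon (default 20); violated -> error.
#' @param model an [error_model()].
#' @return object of class `read_pool_sim`: list with `sample_id`, data frame
#'   `reads` (`read_id`, `member_id`, `fwd`, `rev`, `fwd_qual`, `rev_qual`,
#'   qualities as Phred+33 strings), `truth` (`read_id`, `member_id`), and
#'   the originating `spec`.
#' @export
simulate_read_pairs <- function(spec, read_length = 300L, min_overlap = 20L,
                                model = error_model()) {
  stopifnot(inherits(spec, "pool_spec"), read_length >= 50, min_overlap >= 20)
  mem <- spec$members
  alen <- nchar(mem$sequence)
  if (any(2L * read_length - alen < min_overlap))
    stop("read pairs cannot overlap by ", min_overlap,
         " nt on the longest amplicon; increase read_length")
  n <- spec$n_read_pairs
  with_seed(sub_seed(spec$seed, 1L), {
    src <- sample.int(nrow(mem), n, replace = TRUE, prob = mem$proportion)
    rl <- pmin(read_length, alen)
    fwd_clean <- substr(mem$sequence, 1L, rl)[src]
    rev_clean <- revcomp(substring(mem$sequence, alen - rl + 1L, alen))[src]
    fwd <- inject_errors(fwd_clean, spec$error_rate)
    rev <- inject_errors(rev_clean, spec$error_rate)
    qs <- vapply(sort(unique(rl)), function(L) phred_string(quality_profile(model, L)),
                 character(1))
    names(qs) <- as.character(sort(unique(rl)))
    read_id <- sprintf("%s_read%06d", spec$sample_id, seq_len(n))
    reads <- data.frame(read_id = read_id, member_id = mem$id[src],
                        fwd = fwd, rev = rev,
                        fwd_qual = unname(qs[as.character(rl[src])]),
                        rev_qual = unname(qs[as.character(rl[src])]),
                        stringsAsFactors = FALSE)
    structure(list(sample_id = spec$sample_id, reads = reads,
                   truth = reads[, c("read_id", "member_id")], spec = spec),
              class = "read_pool_sim")
  })
}

#' Write a simulated pool as paired FASTQ plus ground-truth sidecars
#'
#' Writes `<prefix>_R1.fastq[.gz]` / `<prefix>_R2.fastq[.gz]`, a truth table
#' `<prefix>_truth.tsv` (`read_id`, `member_id`) and the spec as
#' `<prefix>_spec.yaml`. Qualities are Sanger/Illumina 1.8+ (Phred+33).
#'
#' @param sim a [simulate_read_pairs()] result.
#' @param dir output directory (created if needed).
#' @param prefix file prefix (default the sample id).
#' @param gzip compress the FASTQ files.
#' @return named character vector of the four paths.
#' @export
write_read_pool <- function(sim, dir, prefix = sim$sample_id, gzip = FALSE) {
  stopifnot(inherits(sim, "read_pool_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p <- file.path(dir, paste0(prefix, c(paste0("_R1", ext), paste0("_R2", ext),
                                       "_truth.tsv", "_spec.yaml")))
  names(p) <- c("r1", "r2", "truth", "spec")
  wr <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(setNames(seqs, sim$reads$read_id))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = gzip)
  }
  wr(sim$reads$fwd, sim$reads$fwd_qual, p["r1"])
  wr(sim$reads$rev, sim$reads$rev_qual, p["r2"])
  write.table(sim$truth, p["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  sp <- sim$spec
  yaml::write_yaml(list(sample_id = sp$sample_id,
                        members = setNames(as.list(sp$members$proportion),
                                           sp$members$id),
                        sequences = setNames(as.list(sp$members$sequence),
                                             sp$members$id),
                        n_read_pairs = sp$n_read_pairs,
                        error_rate = sp$error_rate, seed = sp$seed),
                   p["spec"])
  invisible(p)
}

#' Rebuild a pool spec from its YAML serialisation
#'
#' @param path a `*_spec.yaml` written by [write_read_pool()].
#' @return a [pool_spec()].
#' @export
read_pool_spec <- function(path) {
  y <- yaml::read_yaml(path)
  pool_spec(y$sample_id,
            setNames(unlist(y$sequences), names(y$sequences)),
            unlist(y$members)[names(y$sequences)],
            n_read_pairs = y$n_read_pairs, error_rate = y$error_rate,
            seed = y$seed)
}
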
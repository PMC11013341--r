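# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (character-level recounts, recursive alignment,
# Monte-Carlo simulation) so that agreement is a genuine two-route check.

r_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force Hamming recount
r_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive step-count oracle for unequal-length pairs: among global
# alignments with the maximum number of matching columns, the minimum of
# (mismatch columns + contiguous gap runs). Plain memoised recursion over
# (i, j, state) returning c(matches, penalty), compared lexicographically
# (max matches, then min penalty). Toy inputs only.
# state: 0 = none/match, 1 = in gap consuming a, 2 = in gap consuming b.
r_align_steps <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  better <- function(x, y) {  # TRUE if x beats y
    x[1] > y[1] || (x[1] == y[1] && x[2] < y[2])
  }
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0 && j == 0) {
      c(0, 0)
    } else {
      best <- c(-Inf, Inf)
      if (i > 0 && j > 0) {
        v <- rec(i - 1, j - 1, 0) +
          if (av[i] == bv[j]) c(1, 0) else c(0, 1)
        if (better(v, best)) best <- v
      }
      if (i > 0) {
        v <- rec(i - 1, j, 1) + c(0, as.numeric(state != 1))
        if (better(v, best)) best <- v
      }
      if (j > 0) {
        v <- rec(i, j - 1, 2) + c(0, as.numeric(state != 2))
        if (better(v, best)) best <- v
      }
      best
    }
    memo[[key]] <- res
    res
  }
  rec(length(av), length(bv), 0)[2]
}

# hand-simulation of the sliding-window rule: first window (5'->3') with
# mean quality strictly below the threshold stops retention at the first
# individually sub-threshold base within it
r_trim_keep <- function(quals, window, threshold) {
  L <- length(quals)
  if (L < window) return(L)
  for (s in seq_len(L - window + 1)) {
    if (mean(quals[s:(s + window - 1)]) < threshold) {
      k <- s
      while (k <= L && quals[k] >= threshold) k <- k + 1
      return(k - 1)
    }
  }
  L
}

# Monte-Carlo estimate of the probability that a j-step mutational path over
# m sites (uniform site choice, 4 states, uniform alternative state) never
# reverts a changed site to its original state
r_mc_parsimony <- function(j, m, nrep) {
  hits <- 0L
  for (r in seq_len(nrep)) {
    site <- sample.int(m, j, replace = TRUE)
    state <- integer(m)  # 0 = original
    ok <- TRUE
    for (s in site) {
      new <- sample((0:3)[-(state[s] + 1)], 1)
      if (state[s] != 0L && new == 0L) { ok <- FALSE; break }
      state[s] <- new
    }
    hits <- hits + ok
  }
  hits / nrep
}

# a small set of haplotypes generated along a random mutation tree, with the
# per-edge step counts drawn from `steps`; returns character vector
r_mutation_tree_seqs <- function(n_hap, len, steps) {
  base <- strsplit(r_random_dna(len), "")[[1]]
  seqs <- list(base)
  for (i in seq_len(n_hap - 1)) {
    parent <- seqs[[sample.int(length(seqs), 1)]]
    k <- sample(steps, 1)
    pos <- sample.int(len, k)
    for (p in pos) parent[p] <- sample(setdiff(c("A", "C", "G", "T"), parent[p]), 1)
    seqs[[length(seqs) + 1]] <- parent
  }
  vapply(seqs, paste, character(1), collapse = "")
}

# classified pool directly from sequences/counts (skips read processing)
make_classified_pool <- function(id, seqs, counts, total = sum(counts),
                                 prefix = id) {
  label_ribotypes(classify_pool(sample_pool(id, counts = counts,
                                            sequences = seqs,
                                            total_reads = total)), prefix)
}
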
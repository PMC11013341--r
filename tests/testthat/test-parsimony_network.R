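# deterministic single-base mutation (A->C->G->T->A)
mutate_at <- function(s, pos) {
  for (p in pos) substr(s, p, p) <- chartr("ACGT", "CGTA", substr(s, p, p))
  s
}

test_that("mutational steps match brute-force recounts", {
  expect_equal(mutational_steps("ACGT", "ACGT"), 0L)
  expect_equal(mutational_steps("ACGT", "ACGA"), 1L)
  expect_error(mutational_steps("", "ACGT"), "empty")

  set.seed(61)
  for (i in 1:30) {
    a <- r_random_dna(50)
    b <- strsplit(a, "")[[1]]
    k <- sample(0:8, 1)
    pos <- sample(50, k)
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    b <- paste(b, collapse = "")
    expect_equal(mutational_steps(a, b), r_hamming(a, b))
  }
})

test_that("unequal-length steps count each contiguous gap as one, matching the exhaustive oracle", {
  # 20-nt sequence with 3 planted substitutions and one 2-nt insertion -> 4
  a <- "AGGCTTACCGTTAGATCCGA"
  b <- mutate_at(a, c(3, 9, 15))
  b_ins <- paste0(substr(b, 1, 12), "GG", substr(b, 13, 20))
  expect_equal(mutational_steps(a, b_ins), 4L)
  expect_equal(r_align_steps(a, b_ins), 4)

  # single long deletion is one step
  expect_equal(mutational_steps("ACGTACGTACGT", "ACGTACGT"), 1L)

  set.seed(62)
  for (i in 1:12) {
    lens <- sample(8:14, 2)   # distinct lengths: the gapped-alignment path
    a <- r_random_dna(lens[1])
    b <- r_random_dna(lens[2])
    expect_equal(mutational_steps(a, b), r_align_steps(a, b))
  }
})

test_that("parsimony probability agrees with an independent recursion and with simulation", {
  # independent log-space reimplementation of the product
  p_indep <- function(j, m) exp(sum(log1p(-seq_len(j - 1) / (3 * m))))
  for (m in c(100, 300, 450, 600)) {
    for (j in c(1, 2, 5, 9, 14)) {
      expect_equal(parsimony_prob(j, m), p_indep(j, m), tolerance = 1e-12)
    }
  }
  expect_equal(parsimony_prob(1, 450), 1)

  # Monte-Carlo simulation of the stated mutation model (reversion of a
  # changed site breaks parsimony); agreement within 3 SE plus a small
  # allowance for the neglected multiple-superposition term
  set.seed(63)
  for (j in c(3, 5)) {
    nrep <- 20000
    phat <- r_mc_parsimony(j, 450, nrep)
    p <- parsimony_prob(j, 450)
    se <- sqrt(p * (1 - p) / nrep)
    expect_lt(abs(phat - p), 3 * se + 0.002)
  }
})

test_that("the connection limit is deterministic, monotone in length, and collapses to 1 near certainty", {
  expect_equal(connection_limit(450, 0.999999), 1L)
  lims <- vapply(c(100, 200, 300, 450, 600, 700),
                 function(m) connection_limit(m, 0.95), integer(1))
  expect_false(is.unsorted(lims))
  expect_identical(connection_limit(450), connection_limit(450, 0.95))
  # limit is the largest j with P(j) >= confidence
  for (m in c(300, 450, 600)) {
    j <- connection_limit(m, 0.95)
    expect_gte(parsimony_prob(j, m), 0.95)
    expect_lt(parsimony_prob(j + 1L, m), 0.95)
  }
  expect_error(connection_limit(450, 0.4), "confidence")
  expect_error(connection_limit(450, 1), "confidence")
})

test_that("a two-step gap is bridged by exactly one inferred node", {
  # chain: A-B at 1 step, B-C at 2 steps -> 3 observed + 1 inferred node,
  # total length 3 = brute-force minimum spanning length
  set.seed(70)
  A <- r_random_dna(200)
  B <- mutate_at(A, 10)
  C <- mutate_at(B, c(50, 90))
  pool <- make_classified_pool("chain", c(A, B, C), c(900, 500, 300))
  net <- build_network(pool)
  expect_equal(sum(net$nodes$kind == "observed"), 3L)
  expect_equal(sum(net$nodes$kind == "inferred"), 1L)
  expect_equal(network_total_steps(net), 3L)
  expect_equal(length(unique(net$nodes$subnetwork)), 1L)
  deg <- igraph::degree(net$graph)
  expect_true(all(deg[net$nodes$node_id[net$nodes$kind == "inferred"]] >= 2))

  # single ribotype: one node, no edges, one subnetwork
  n1 <- build_network(make_classified_pool("s", r_random_dna(200), 500))
  expect_equal(nrow(n1$nodes), 1L)
  expect_equal(nrow(n1$edges), 0L)
  expect_equal(unique(n1$nodes$subnetwork), "S1")
})

test_that("network assembly equals the minimum-spanning oracle on small haplotype sets", {
  set.seed(64)
  for (rep in 1:15) {
    # mutation-tree sets whose largest pairwise distance stays within the
    # connection limit for 400-nt markers
    seqs <- unique(r_mutation_tree_seqs(sample(3:6, 1), 400, 1:2))
    k <- length(seqs)
    pool <- make_classified_pool(paste0("r", rep), seqs,
                                 counts = sample(100:900, k))
    net <- build_network(pool)
    dm <- outer(seqs, seqs, Vectorize(function(x, y) r_hamming(x, y)))
    expect_lte(max(dm), net$connection_limit)
    g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                             weighted = TRUE)
    mst_w <- sum(igraph::E(igraph::mst(g))$weight)
    expect_gte(network_total_steps(net), mst_w)
    # without 1-step reticulation the assembly is exactly minimum-spanning
    g1 <- igraph::graph_from_adjacency_matrix(dm == 1, mode = "undirected")
    d1_is_forest <-
      igraph::gsize(g1) == k - igraph::count_components(g1)
    if (d1_is_forest)
      expect_equal(network_total_steps(net), mst_w)
    # every observed-observed edge spans exactly one step (exhaustive)
    seq_of <- setNames(net$nodes$sequence, net$nodes$node_id)
    both_obs <- !is.na(seq_of[net$edges$from]) & !is.na(seq_of[net$edges$to])
    for (e in which(both_obs))
      expect_equal(r_hamming(seq_of[[net$edges$from[e]]],
                             seq_of[[net$edges$to[e]]]), 1)
    # a d-step join contributes exactly d - 1 inferred nodes
    for (iv in net$inferred)
      expect_equal(sum(vapply(net$inferred, function(x)
        identical(x$between, iv$between), logical(1))), iv$of - 1L)
  }
})

test_that("clusters farther apart than the limit stay separate subnetworks", {
  set.seed(65)
  # three random 300-nt cores are ~225 steps apart, far beyond the limit
  cl <- lapply(1:3, function(i) unique(r_mutation_tree_seqs(3, 300, 1:2)))
  seqs <- unlist(cl)
  pool <- make_classified_pool("pl", seqs, sample(200:900, length(seqs)))
  net <- build_network(pool)
  expect_equal(length(unique(net$nodes$subnetwork)), 3L)
  # planted partition recovered: cluster mates share one subnetwork
  sub_of_seq <- setNames(net$nodes$subnetwork, net$nodes$sequence)
  for (i in 1:3)
    expect_equal(length(unique(sub_of_seq[cl[[i]]])), 1L)
  memb <- subnetwork_membership(net)
  expect_equal(nrow(memb), length(seqs))
  expect_equal(sum(attr(memb, "summary")$n_occurrences), length(seqs))

  # a single cluster forms a single subnetwork
  n1 <- build_network(make_classified_pool("one", cl[[1]],
                                           sample(200:900, length(cl[[1]]))))
  expect_equal(length(unique(n1$nodes$subnetwork)), 1L)
})

test_that("network building is invariant to pool input order", {
  set.seed(66)
  seqs1 <- unique(r_mutation_tree_seqs(4, 250, 1:3))
  seqs2 <- unique(r_mutation_tree_seqs(4, 250, 1:3))
  pA <- make_classified_pool("A", seqs1, sample(100:900, length(seqs1)))
  pB <- make_classified_pool("B", seqs2, sample(100:900, length(seqs2)))
  n1 <- build_network(list(pA, pB))
  n2 <- build_network(list(pB, pA))
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges, n2$edges)
  expect_identical(subnetwork_membership(n1), subnetwork_membership(n2))
})

test_that("networks export to GraphML and JSON", {
  set.seed(67)
  seqs <- unique(r_mutation_tree_seqs(5, 200, 1:3))
  pool <- make_classified_pool("x", seqs, sample(100:900, length(seqs)))
  net <- build_network(pool)
  d <- tempfile("net_"); dir.create(d)
  on.exit(unlink(d, recursive = TRUE), add = TRUE)
  gml <- write_network_graphml(net, file.path(d, "net.graphml"))
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g2), nrow(net$nodes))
  expect_equal(igraph::gsize(g2), nrow(net$edges))
  js <- write_network_json(net, file.path(d, "net.json"))
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(parsed$nodes), nrow(net$nodes))
  expect_equal(parsed$connection_limit, net$connection_limit)
})
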
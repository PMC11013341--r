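#' Mutational steps between two sequences
#'
#' Equal-length sequences: Hamming distance. Unequal lengths: the pair is
#' globally aligned so as to maximise the number of matching columns (ties
#' resolved toward fewer mismatches and gap runs), and the step count is the
#' number of mismatch columns plus the number of contiguous gap runs — one
#' indel event of any length is one mutation, the convention of
#' haplotype-network practice. Symmetric; zero iff the sequences are
#' identical.
#'
#' @param a,b DNA strings (non-empty).
#' @return integer step count.
#' @examples
#' mutational_steps("ACGT", "ACGA")  # 1
#' @export
mutational_steps <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (nchar(a) == nchar(b)) cpp_hamming(a, b) else cpp_align_steps(a, b)
}

#' Probability that a j-step connection is parsimonious
#'
#' Model: mutations strike the `seq_length` sites of the marker uniformly at
#' random, each changing the site to one of the three alternative nucleotide
#' states. A connection of `steps` mutations is non-parsimonious when some
#' later mutation revisits an already-mutated site with the one state (of
#' three) that reverts the earlier change, making the pair look closer than
#' its true mutational path. Neglecting the second-order case of several
#' superimposed hits at one site, the i-th mutation is "safe" with
#' probability `1 - (i - 1) / (3 * seq_length)`:
#'
#' `P(j) = prod_{i=1}^{j-1} (1 - i / (3 m))`.
#'
#' `P(1) = 1`: single steps are always parsimonious.
#'
#' @param steps number of mutational steps (vectorised).
#' @param seq_length marker length m in nt.
#' @return probability in `(0, 1]`.
#' @export
parsimony_prob <- function(steps, seq_length) {
  stopifnot(all(steps >= 1), seq_length >= 50)
  vapply(steps, function(j) prod(1 - seq_len(j - 1) / (3 * seq_length)),
         numeric(1))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` whose probability of parsimony
#' [parsimony_prob()] is still at least `confidence`. Pairs farther apart
#' than the limit are never joined in the network. Deterministic in
#' `(seq_length, confidence)`; monotonically non-decreasing in `seq_length`.
#'
#' @param seq_length marker length in nt (>= 50).
#' @param confidence required probability of parsimony, in (0.5, 1);
#'   conventionally 0.95.
#' @return integer step limit (>= 1).
#' @export
connection_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length >= 50)
  if (confidence <= 0.5 || confidence >= 1)
    stop("confidence must be in (0.5, 1)")
  j <- 1L
  p <- 1
  repeat {
    p_next <- p * (1 - j / (3 * seq_length))
    if (p_next < confidence) return(j)
    p <- p_next
    j <- j + 1L
  }
}

#' Build a statistical-parsimony (TCS-style) ribotype network
#'
#' Nodes are the unique ribotype sequences across all supplied classified
#' pools, each carrying its per-sample occurrences (sample, label, count,
#' percent, status). Assembly is agglomerative: all node pairs one step
#' apart are connected first; then, at increasing distance `d` up to the
#' [connection_limit()], pairs in *different* components are joined through
#' a path of `d - 1` inferred intermediate nodes. Among candidate joins at
#' the same `d`, the connection involving the highest-frequency observed
#' node (total reads across samples) is preferred, then lexicographic node
#' id. Pairs beyond the limit are never connected; the resulting connected
#' components are the subnetworks.
#'
#' Inferred intermediates carry no sequence (their states are
#' underdetermined); they record which join path they sit on and their step
#' position along it.
#'
#' @param pools list of classified [sample_pool()] objects (ribotypes must
#'   carry sequences; N-free, as guaranteed by [dereplicate()]).
#' @param confidence probability-of-parsimony level (default 0.95).
#' @param limit override the computed connection limit (expert use).
#' @param majors_only network only the major ribotypes of each pool
#'   (default `FALSE`). Deep error-containing pools carry thousands of
#'   singleton ribotypes; published ribotype networks are drawn from the
#'   major pool members.
#' @return object of class `parsimony_network`: list with `nodes`
#'   (`node_id`, `kind`, `sequence`, `freq`, `subnetwork`), `edges`
#'   (`from`, `to`), `occurrences`, `connection_limit`, `confidence`,
#'   and `graph` (an igraph object).
#' @export
build_network <- function(pools, confidence = 0.95, limit = NULL,
                          majors_only = FALSE) {
  if (inherits(pools, "sample_pool")) pools <- list(pools)
  occ <- do.call(rbind, lapply(pools, function(p) {
    rt <- p$ribotypes[!is.na(p$ribotypes$sequence), , drop = FALSE]
    if (majors_only) rt <- rt[rt$status %in% "major", , drop = FALSE]
    if (!nrow(rt)) return(NULL)
    data.frame(sample_id = p$sample_id, label = rt$label,
               sequence = rt$sequence, count = rt$count,
               percent = rt$percent, status = rt$status,
               stringsAsFactors = FALSE)
  }))
  if (is.null(occ) || nrow(occ) == 0L) {
    net <- structure(list(nodes = data.frame(node_id = character(),
                                             kind = character(),
                                             sequence = character(),
                                             freq = integer(),
                                             subnetwork = character()),
                          edges = data.frame(from = character(),
                                             to = character()),
                          occurrences = data.frame(),
                          connection_limit = NA_integer_,
                          confidence = confidence,
                          graph = igraph::make_empty_graph(directed = FALSE)),
                     class = "parsimony_network")
    return(net)
  }
  if (any(!is_clean_dna(occ$sequence)))
    stop("ambiguity codes are not allowed at the network stage")
  useq <- sort(unique(occ$sequence))
  n <- length(useq)
  node_id <- sprintf("H%0*d", max(2L, nchar(n)), seq_len(n))
  names(node_id) <- useq
  occ$node_id <- unname(node_id[occ$sequence])
  freq <- tapply(occ$count, occ$node_id, sum)
  if (is.null(limit))
    limit <- connection_limit(max(nchar(useq)), confidence)
  d <- cpp_step_matrix(useq)

  edges_from <- character(0); edges_to <- character(0)
  inf_id <- character(0); inf_meta <- list()
  comp <- seq_len(n)  # observed-node component membership
  # distance-1 edges (may form loops/reticulations)
  if (n > 1) {
    one <- which(d == 1L & upper.tri(d), arr.ind = TRUE)
    one <- one[order(one[, 1], one[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(one))) {
      i <- one[r, 1]; j <- one[r, 2]
      edges_from <- c(edges_from, node_id[i])
      edges_to <- c(edges_to, node_id[j])
      comp[comp == comp[j]] <- comp[i]
    }
    dmax <- min(limit, max(d))
    dd <- 2L
    while (dd <= dmax) {
      cand <- which(d == dd & upper.tri(d), arr.ind = TRUE)
      if (nrow(cand)) {
        pref <- -pmax(as.numeric(freq[node_id[cand[, 1]]]),
                      as.numeric(freq[node_id[cand[, 2]]]))
        ord <- order(pref, node_id[cand[, 1]], node_id[cand[, 2]])
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (comp[i] == comp[j]) next
          ids <- sprintf("%s-%s.iv%d", node_id[i], node_id[j],
                         seq_len(dd - 1L))
          chain <- c(node_id[i], ids, node_id[j])
          edges_from <- c(edges_from, chain[-length(chain)])
          edges_to <- c(edges_to, chain[-1])
          inf_id <- c(inf_id, ids)
          inf_meta <- c(inf_meta, lapply(seq_len(dd - 1L), function(s)
            list(between = c(node_id[i], node_id[j]), step = s, of = dd)))
          comp[comp == comp[j]] <- comp[i]
        }
      }
      dd <- dd + 1L
    }
  }
  nodes <- rbind(
    data.frame(node_id = unname(node_id), kind = "observed", sequence = useq,
               freq = as.integer(freq[node_id]), stringsAsFactors = FALSE),
    if (length(inf_id))
      data.frame(node_id = inf_id, kind = "inferred",
                 sequence = NA_character_, freq = 0L,
                 stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_from, to = edges_to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  memb <- igraph::components(g)$membership
  # deterministic subnetwork ids: ordered by smallest observed node id inside
  obs_min <- tapply(names(memb)[names(memb) %in% nodes$node_id[nodes$kind == "observed"]],
                    memb[names(memb) %in% nodes$node_id[nodes$kind == "observed"]],
                    min)
  sub_rank <- rank(obs_min, ties.method = "first")
  sub_id <- setNames(sprintf("S%d", sub_rank), names(obs_min))
  nodes$subnetwork <- unname(sub_id[as.character(memb[nodes$node_id])])
  structure(list(nodes = nodes,
                 edges = data.frame(from = edges_from, to = edges_to,
                                    stringsAsFactors = FALSE),
                 occurrences = occ, connection_limit = as.integer(limit),
                 confidence = confidence, graph = g,
                 inferred = inf_meta),
            class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat(sprintf(paste0("<parsimony_network> %d observed + %d inferred nodes, ",
                     "%d edges, %d subnetwork(s), limit %s steps (%.0f%%)\n"),
              sum(x$nodes$kind == "observed"),
              sum(x$nodes$kind == "inferred"), nrow(x$edges),
              length(unique(x$nodes$subnetwork[!is.na(x$nodes$subnetwork)])),
              x$connection_limit, 100 * x$confidence))
  invisible(x)
}

#' Total path length of a network (number of single-step edges)
#'
#' Every edge spans exactly one mutational step, so the total length equals
#' the edge count. Comparable to the weight of a minimum spanning tree over
#' the observed haplotypes when no reticulation or limit truncation occurs.
#'
#' @param net a [build_network()] result.
#' @return integer.
#' @export
network_total_steps <- function(net) nrow(net$edges)

#' Map each observed ribotype occurrence to its subnetwork
#'
#' @param net a [build_network()] result.
#' @return data frame (`sample_id`, `label`, `node_id`, `subnetwork`) plus a
#'   `summary` attribute counting occurrences per subnetwork.
#' @export
subnetwork_membership <- function(net) {
  occ <- net$occurrences
  if (is.null(occ) || nrow(occ) == 0L)
    return(data.frame(sample_id = character(), label = character(),
                      node_id = character(), subnetwork = character()))
  sub <- setNames(net$nodes$subnetwork, net$nodes$node_id)
  out <- data.frame(sample_id = occ$sample_id, label = occ$label,
                    node_id = occ$node_id,
                    subnetwork = unname(sub[occ$node_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subnetwork, out$sample_id, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- as.data.frame(table(subnetwork = out$subnetwork),
                                        responseName = "n_occurrences")
  out
}

#' Export a parsimony network
#'
#' `write_network_graphml()` writes GraphML (node attributes: kind,
#' sequence, total frequency, subnetwork). `write_network_json()` writes a
#' JSON document with nodes (including per-sample occurrence lists and
#' percent radii for plotting), edges and subnetwork ids.
#'
#' @param net a [build_network()] result.
#' @param path output file.
#' @export
write_network_graphml <- function(net, path) {
  g <- net$graph
  igraph::V(g)$kind <- net$nodes$kind
  igraph::V(g)$sequence <- ifelse(is.na(net$nodes$sequence), "",
                                  net$nodes$sequence)
  igraph::V(g)$freq <- net$nodes$freq
  igraph::V(g)$subnetwork <- net$nodes$subnetwork
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_json <- function(net, path) {
  occ_by_node <- split(net$occurrences[, c("sample_id", "label", "count",
                                           "percent", "status")],
                       net$occurrences$node_id)
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
    nd <- net$nodes[i, ]
    list(node_id = nd$node_id, kind = nd$kind,
         sequence = if (is.na(nd$sequence)) NULL else nd$sequence,
         freq = nd$freq, subnetwork = nd$subnetwork,
         occurrences = occ_by_node[[nd$node_id]])
  })
  jsonlite::write_json(list(connection_limit = net$connection_limit,
                            confidence = net$confidence, nodes = nodes,
                            edges = net$edges),
                       path, auto_unbox = TRUE, dataframe = "rows",
                       null = "null", pretty = TRUE)
  invisible(path)
}
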
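# Independent brute-force oracles used to check the package's
# implementations on small instances. These deliberately use different
# algorithms (exhaustive enumeration, graph components) from the
# production code paths.

# Exhaustive interval-selection oracle for overlap resolution: among
# all maximal conflict-free subsets of hits, pick the one that is
# lexicographically first under the precedence ranking (higher score,
# then longer, then smaller start). Returns row indices sorted by
# start.
oracle_resolve_hits <- function(hits) {
  n <- nrow(hits)
  len <- hits$end - hits$start
  score <- ifelse(is.na(hits$score), -Inf, hits$score)
  rank_ord <- order(-score, -len, hits$start, hits$label)
  rank <- integer(n)
  rank[rank_ord] <- seq_len(n)

  conflicts <- function(i, j) {
    ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
    ov > 0.5 * min(len[i], len[j])
  }
  conflict_free <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1L), length(idx))) {
        if (conflicts(idx[a], idx[b])) return(FALSE)
      }
    }
    TRUE
  }
  best <- NULL
  best_ranks <- NULL
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!conflict_free(idx)) next
    # maximality: no further hit can be added
    rest <- setdiff(seq_len(n), idx)
    maximal <- all(vapply(rest, function(r) {
      any(vapply(idx, function(i) conflicts(r, i), logical(1)))
    }, logical(1)))
    if (length(idx) > 0L && !maximal) next
    if (length(idx) == 0L && n > 0L) next
    rk <- sort(rank[idx])
    if (is.null(best) || lex_less(rk, best_ranks)) {
      best <- idx
      best_ranks <- rk
    }
  }
  best[order(hits$start[best], hits$end[best], hits$label[best])]
}

# TRUE when integer sequence a precedes b lexicographically (prefix
# equality broken in favour of the longer sequence).
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) > length(b)
}

# Brute-force within-protein pair/node tallies over per-protein label
# vectors.
oracle_protein_network <- function(label_vectors) {
  node <- integer(0)
  edge <- list()
  for (labels in label_vectors) {
    d <- sort(unique(labels))
    for (l in d) node[l] <- (if (l %in% names(node)) node[[l]] else 0L) + 1L
    if (length(d) >= 2L) {
      for (a in seq_along(d)[-length(d)]) {
        for (b in seq((a + 1L), length(d))) {
          key <- paste(d[a], d[b], sep = "|")
          edge[[key]] <- (if (key %in% names(edge)) edge[[key]] else 0L) + 1L
        }
      }
    }
  }
  list(nodes = node, edges = unlist(edge))
}

# Brute-force within-neighborhood tallies: `contexts` is a list of
# contexts, each a list of per-gene label-set character vectors.
oracle_neighborhood_network <- function(contexts) {
  node <- integer(0)
  edge <- list()
  for (gene_sets in contexts) {
    for (labels in gene_sets) {
      for (l in unique(labels)) {
        node[l] <- (if (l %in% names(node)) node[[l]] else 0L) + 1L
      }
    }
    seen <- character(0)
    n <- length(gene_sets)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          for (a in gene_sets[[i]]) for (b in gene_sets[[j]]) {
            if (a == b) next
            key <- paste(min(a, b), max(a, b), sep = "|")
            seen <- union(seen, key)
          }
        }
      }
    }
    for (key in seen) {
      edge[[key]] <- (if (key %in% names(edge)) edge[[key]] else 0L) + 1L
    }
  }
  list(nodes = node, edges = unlist(edge))
}

# Group-by oracle for context clustering and the architecture census.
oracle_group_counts <- function(keys, species) {
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    out[[k]] <- c(n = length(idx), n_species = length(unique(species[idx])))
  }
  out
}

# Power-set tally oracle for upSet exact combinations.
oracle_upset <- function(neighbor_sets) {
  combos <- vapply(neighbor_sets, function(s) {
    s <- sort(unique(s))
    if (length(s) == 0L) "(none)" else paste(s, collapse = " & ")
  }, character(1))
  tab <- table(combos)
  stats::setNames(as.integer(tab), names(tab))
}

# Connected-component oracle for adjacent-paralog runs: genes are
# nodes, edges join genes whose ordinals differ by <= max_gap.
oracle_paralog_runs <- function(ordinals, max_gap = 1L) {
  n <- length(ordinals)
  if (n == 0L) return(list())
  adj <- outer(ordinals, ordinals,
               function(a, b) abs(a - b) <= max_gap & a != b)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  runs <- split(ordinals, comp)
  runs <- Filter(function(r) length(r) >= 2L, runs)
  lapply(unname(runs), sort)
}

# Mirror a replicon: reverse gene order, flip strands, mirror
# coordinates. Gene ordinals are reassigned by the new start order.
reverse_replicon <- function(genes) {
  L <- max(genes$end) + 137L
  out <- genes
  out$start <- L - genes$end
  out$end <- L - genes$start
  out$strand <- -genes$strand
  ord <- order(out$start)
  out <- out[ord, , drop = FALSE]
  out$gene_ordinal <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}
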
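# Domain proximity networks: frequency-based homolog retention and
# co-occurrence graph construction (within proteins and within gene
# neighborhoods).

#' Retain the top fraction of homologs by architecture frequency
#'
#' Architecture signature classes are sorted by decreasing frequency of
#' occurrence and kept greedily until the cumulative protein count
#' reaches `fraction` of the total; the class crossing the boundary is
#' kept whole (classes are retained or dropped atomically). When a
#' family table is supplied, retention is applied per query family and
#' the retained sets are unioned; otherwise it is global.
#'
#' @param architectures Output of [build_architectures()].
#' @param fraction Retention fraction in (0, 1]; default 0.97.
#' @param family Optional family membership table for per-family
#'   retention.
#' @return Character vector of retained protein accessions.
#' @export
retain_top_fraction <- function(architectures, fraction = 0.97,
                                family = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (nrow(architectures) == 0L) return(character(0))
  if (is.null(family)) {
    return(retain_one_group(architectures, fraction))
  }
  retained <- character(0)
  for (fam in sort_c(unique(family$query_family))) {
    accs <- family$protein_accession[family$query_family == fam]
    sub <- architectures[architectures$protein_accession %in% accs, ,
                         drop = FALSE]
    if (nrow(sub) > 0L) {
      retained <- union(retained, retain_one_group(sub, fraction))
    }
  }
  sort_c(retained)
}

retain_one_group <- function(architectures, fraction) {
  freq <- table(architectures$collapsed_signature)
  ord <- order_c(-as.integer(freq), names(freq))
  freq <- freq[ord]
  cum <- cumsum(as.integer(freq))
  k <- which(cum >= fraction * nrow(architectures))[1L]
  kept_sigs <- names(freq)[seq_len(k)]
  sort_c(architectures$protein_accession[
    architectures$collapsed_signature %in% kept_sigs])
}

#' Build a domain proximity network
#'
#' Nodes are domain/feature labels; edges record co-occurrence. With
#' `provenance = "within_protein"`, an unordered pair of distinct
#' labels gains one count per retained protein carrying both
#' (presence-based: repeat multiplicity does not inflate pair counts),
#' and a node's weight is the number of retained proteins carrying the
#' label (total label occurrences, counting repeats, are kept in the
#' `occurrences` vertex attribute). With
#' `provenance = "within_neighborhood"`, a pair gains one count per
#' context in which the two labels occur on two different member genes
#' (`UNANNOTATED` members are excluded), and a node's weight is the
#' number of context member genes carrying the label. Repeats never
#' create self-loops.
#'
#' @param architectures Output of [build_architectures()].
#' @param retained Accessions kept by [retain_top_fraction()]; `NULL`
#'   keeps everything. For neighborhood networks, retention applies to
#'   the context anchors.
#' @param contexts List of `gene_context` objects (required for
#'   `within_neighborhood`).
#' @param provenance `"within_protein"` or `"within_neighborhood"`.
#' @return An undirected simple igraph with vertex attributes `weight`
#'   and `occurrences`, edge attributes `weight` and `provenance`, and
#'   graph attribute `provenance`.
#' @export
build_network <- function(architectures, retained = NULL, contexts = NULL,
                          provenance = c("within_protein",
                                         "within_neighborhood")) {
  provenance <- match.arg(provenance)
  if (provenance == "within_protein") {
    arch <- architectures
    if (!is.null(retained)) {
      arch <- arch[arch$protein_accession %in% retained, , drop = FALSE]
    }
    # keep repeat multiplicity: it feeds the occurrence tally
    label_sets <- lapply(arch$label_list,
                         function(l) l[l != UNANNOTATED])
  } else {
    if (is.null(contexts)) {
      stop("within_neighborhood networks require contexts")
    }
    if (!is.null(retained)) {
      contexts <- Filter(function(x) x$anchor_accession %in% retained,
                         contexts)
    }
    lookup <- stats::setNames(architectures$label_list,
                              architectures$protein_accession)
    label_sets <- list()
    for (ctx in contexts) {
      gene_sets <- lapply(ctx$members$accession, function(a) {
        unique(setdiff(lookup[[a]], UNANNOTATED))
      })
      gene_sets <- Filter(length, gene_sets)
      label_sets <- c(label_sets, list(gene_sets))
    }
  }
  if (provenance == "within_protein") {
    counts <- count_within_units(label_sets)
  } else {
    counts <- count_across_genes(label_sets)
  }
  graph_from_counts(counts, provenance)
}

# Presence-based tallies over flat label vectors, one unit = one protein.
count_within_units <- function(label_sets) {
  node_weight <- integer(0)
  occurrences <- integer(0)
  edge_count <- new.env(parent = emptyenv())
  for (labels in label_sets) {
    if (length(labels) == 0L) next
    occ <- table(labels)
    distinct <- sort_c(unique(labels))
    node_weight <- tally(node_weight, distinct, 1L)
    occurrences <- tally(occurrences, names(occ), as.integer(occ))
    if (length(distinct) >= 2L) {
      prs <- utils::combn(distinct, 2L)
      for (k in seq_len(ncol(prs))) {
        key <- paste(prs[1L, k], prs[2L, k], sep = "\r")
        edge_count[[key]] <- (edge_count[[key]] %||% 0L) + 1L
      }
    }
  }
  list(node_weight = node_weight, occurrences = occurrences,
       edges = edge_env_to_df(edge_count))
}

# Tallies over per-context lists of per-gene label sets: node weight
# per member gene, edges once per context across two different genes.
count_across_genes <- function(context_sets) {
  node_weight <- integer(0)
  occurrences <- integer(0)
  edge_count <- new.env(parent = emptyenv())
  for (gene_sets in context_sets) {
    for (labels in gene_sets) {
      node_weight <- tally(node_weight, labels, 1L)
      occurrences <- tally(occurrences, labels, 1L)
    }
    n <- length(gene_sets)
    if (n < 2L) next
    keys <- character(0)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        for (a in gene_sets[[i]]) {
          for (b in gene_sets[[j]]) {
            if (a == b) next
            lo <- if (a < b) a else b
            hi <- if (a < b) b else a
            keys <- c(keys, paste(lo, hi, sep = "\r"))
          }
        }
      }
    }
    for (key in unique(keys)) {
      edge_count[[key]] <- (edge_count[[key]] %||% 0L) + 1L
    }
  }
  list(node_weight = node_weight, occurrences = occurrences,
       edges = edge_env_to_df(edge_count))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tally <- function(counter, keys, add) {
  if (length(keys) == 0L) return(counter)
  new_keys <- setdiff(keys, names(counter))
  if (length(new_keys) > 0L) {
    counter[new_keys] <- 0L
  }
  counter[keys] <- counter[keys] + add
  counter
}

edge_env_to_df <- function(edge_count) {
  keys <- sort_c(ls(edge_count))
  if (length(keys) == 0L) {
    return(data.frame(label_a = character(), label_b = character(),
                      weight = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    label_a = vapply(parts, `[[`, character(1), 1L),
    label_b = vapply(parts, `[[`, character(1), 2L),
    weight = vapply(keys, function(k) edge_count[[k]], integer(1),
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

graph_from_counts <- function(counts, provenance) {
  labels <- sort_c(names(counts$node_weight))
  vertices <- data.frame(
    name = labels,
    weight = as.integer(counts$node_weight[labels]),
    occurrences = as.integer(counts$occurrences[labels]),
    stringsAsFactors = FALSE
  )
  edges <- counts$edges
  edges$provenance <- rep(provenance, nrow(edges))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  g
}

#' Merge proximity networks of different provenances
#'
#' Node weights and edge weights are summed; an edge present in several
#' input networks records the concatenated provenances.
#'
#' @param networks List of igraph networks from [build_network()].
#' @return A single merged igraph.
#' @export
merge_networks <- function(networks) {
  stopifnot(length(networks) >= 1L)
  node_weight <- integer(0)
  occurrences <- integer(0)
  edge_rows <- list()
  for (g in networks) {
    node_weight <- tally(node_weight, igraph::V(g)$name,
                         as.integer(igraph::V(g)$weight))
    occurrences <- tally(occurrences, igraph::V(g)$name,
                         as.integer(igraph::V(g)$occurrences))
    if (igraph::ecount(g) > 0L) {
      ends <- igraph::as_edgelist(g)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        label_a = pmin(ends[, 1L], ends[, 2L]),
        label_b = pmax(ends[, 1L], ends[, 2L]),
        weight = igraph::E(g)$weight,
        provenance = igraph::E(g)$provenance,
        stringsAsFactors = FALSE
      )
    }
  }
  edges <- if (length(edge_rows) > 0L) do.call(rbind, edge_rows) else
    data.frame(label_a = character(), label_b = character(),
               weight = integer(), provenance = character())
  if (nrow(edges) > 0L) {
    key <- paste(edges$label_a, edges$label_b, sep = "\r")
    agg_w <- tapply(edges$weight, key, sum)
    agg_p <- tapply(edges$provenance, key,
                    function(p) paste(sort_c(unique(p)), collapse = ";"))
    parts <- strsplit(names(agg_w), "\r", fixed = TRUE)
    edges <- data.frame(
      label_a = vapply(parts, `[[`, character(1), 1L),
      label_b = vapply(parts, `[[`, character(1), 2L),
      weight = as.integer(agg_w),
      provenance = as.character(agg_p),
      stringsAsFactors = FALSE
    )
    edges <- edges[order_c(edges$label_a, edges$label_b), , drop = FALSE]
  }
  labels <- sort_c(names(node_weight))
  vertices <- data.frame(
    name = labels,
    weight = as.integer(node_weight[labels]),
    occurrences = as.integer(occurrences[labels]),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::set_graph_attr(g, "provenance", "merged")
}
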
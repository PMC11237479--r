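# Gene-neighborhood contexts: extraction of the ±N gene window around a
# family homolog, canonical orientation with strand-change markers,
# conserved-context clustering, and adjacent-paralog detection.

#' Extract the gene-neighborhood context around an anchor gene
#'
#' Takes up to `window` genes on each side of the anchor by gene
#' ordinal, never crossing the replicon boundary (truncation is
#' flagged). Members are stored in canonical orientation: 5'->3' along
#' the anchor's coding strand, so an anchor on the minus strand has its
#' member order reversed. Each member carries its protein's architecture
#' signature (or `UNANNOTATED`) and its strand relative to the anchor.
#'
#' @param anchor_accession Protein accession of the anchor; must occur
#'   exactly once in `replicon_genes`.
#' @param replicon_genes Gene table of a single replicon.
#' @param window Number of genes on each side (default 7).
#' @param signatures Named character vector mapping protein accessions
#'   to architecture signatures; unmapped accessions are labelled
#'   `UNANNOTATED`.
#' @return An object of class `gene_context`: anchor/genome/replicon
#'   ids, the member table (`accession`, `label`, `rel_strand`,
#'   `is_anchor`), truncation flags (relative to canonical orientation)
#'   and the canonical `signature` (see [canonicalize()]).
#' @export
extract_context <- function(anchor_accession, replicon_genes, window = 7L,
                            signatures = NULL) {
  stopifnot(window >= 0L)
  g <- replicon_genes[order(replicon_genes$gene_ordinal), , drop = FALSE]
  idx <- which(g$protein_accession == anchor_accession)
  if (length(idx) != 1L) {
    stop("anchor '", anchor_accession, "' matches ", length(idx),
         " gene(s) on replicon; expected exactly 1")
  }
  n <- nrow(g)
  lo <- max(1L, idx - window)
  hi <- min(n, idx + window)
  anchor_strand <- g$strand[idx]

  members <- data.frame(
    accession = g$protein_accession[lo:hi],
    label = label_for(g$protein_accession[lo:hi], signatures),
    rel_strand = ifelse(g$strand[lo:hi] == anchor_strand,
                        "same", "opposite"),
    is_anchor = seq(lo, hi) == idx,
    stringsAsFactors = FALSE
  )
  trunc_before <- (idx - lo) < window   # replicon start cut the window
  trunc_after <- (hi - idx) < window    # replicon end cut the window
  if (anchor_strand < 0L) {
    members <- members[rev(seq_len(nrow(members))), , drop = FALSE]
    rownames(members) <- NULL
    tmp <- trunc_before
    trunc_before <- trunc_after
    trunc_after <- tmp
  }

  ctx <- structure(
    list(
      anchor_accession = anchor_accession,
      genome_id = g$genome_id[idx],
      replicon_id = g$replicon_id[idx],
      window = as.integer(window),
      members = members,
      truncated_left = trunc_before,
      truncated_right = trunc_after,
      signature = NA_character_
    ),
    class = "gene_context"
  )
  ctx$signature <- canonicalize(ctx)
  ctx
}

label_for <- function(accessions, signatures) {
  if (is.null(signatures)) {
    return(rep(UNANNOTATED, length(accessions)))
  }
  out <- unname(signatures[accessions])
  out[is.na(out)] <- UNANNOTATED
  out
}

#' @export
print.gene_context <- function(x, ...) {
  cat("<gene_context> anchor ", x$anchor_accession, " (", x$genome_id,
      "/", x$replicon_id, "), window +/-", x$window, "\n  ",
      x$signature, "\n", sep = "")
  if (x$truncated_left || x$truncated_right) {
    cat("  truncated:",
        paste(c("left", "right")[c(x$truncated_left, x$truncated_right)],
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Tokenize a canonical member table into a signature string: "||"
# between adjacent members transcribed in opposite directions, the
# anchor wrapped in brackets.
signature_from_members <- function(members) {
  n <- nrow(members)
  if (n == 0L) return("")
  tokens <- ifelse(members$is_anchor,
                   paste0("[", members$label, "]"),
                   members$label)
  if (n > 1L) {
    flip <- members$rel_strand[-1L] != members$rel_strand[-n]
    tokens[-1L] <- ifelse(flip, paste(STRAND_BREAK, tokens[-1L]),
                          tokens[-1L])
  }
  paste(tokens, collapse = " ")
}

#' Canonical signature of a context
#'
#' Members are listed 5'->3' along the anchor's coding strand; a `||`
#' token marks each change of transcription direction between adjacent
#' members; the anchor is wrapped in brackets. The signature is
#' invariant to the anchor's absolute strand and to the replicon's
#' reading direction.
#'
#' @param context A `gene_context`.
#' @return A single signature string.
#' @examples
#' # divergent regulator upstream of a three-gene operon:
#' # "PspF || [PspA] PspB PspC"
#' @export
canonicalize <- function(context) {
  signature_from_members(context$members)
}

# Signature used for cluster comparison. Background genes without any
# domain annotation carry no contextual information, so leading and
# trailing UNANNOTATED members are trimmed before comparison in both
# modes; gapped mode additionally deletes internal UNANNOTATED members.
# Strand-change markers are recomputed from the remaining members. The
# anchor is always retained.
cluster_signature <- function(context, mode = c("exact", "gapped")) {
  mode <- match.arg(mode)
  m <- context$members
  keep_core <- m$is_anchor | m$label != UNANNOTATED
  if (mode == "gapped") {
    m <- m[keep_core, , drop = FALSE]
  } else if (any(keep_core)) {
    rng <- range(which(keep_core))
    m <- m[seq(rng[1L], rng[2L]), , drop = FALSE]
  }
  signature_from_members(m)
}

#' Extract contexts for a set of anchors across a gene table
#'
#' @param genes Combined gene table (any number of genomes/replicons).
#' @param anchors Character vector of anchor protein accessions.
#' @param signatures Named signature vector (see [signature_lookup()]).
#' @param window Genes on each side (default 7).
#' @return Named list of `gene_context` objects (names = anchor
#'   accessions). Anchors not found in `genes` raise an error.
#' @export
extract_contexts <- function(genes, anchors, signatures = NULL,
                             window = 7L) {
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  by_rep <- split(genes, key)
  anchor_key <- key[match(anchors, genes$protein_accession)]
  if (anyNA(anchor_key)) {
    stop("anchor(s) absent from gene table: ",
         paste(utils::head(anchors[is.na(anchor_key)], 5L),
               collapse = ", "))
  }
  out <- lapply(seq_along(anchors), function(i) {
    extract_context(anchors[i], by_rep[[anchor_key[i]]], window,
                    signatures)
  })
  names(out) <- anchors
  out
}

#' Cluster contexts into conserved neighborhoods
#'
#' Groups contexts by cluster signature under the chosen mode. In
#' `exact` mode the signature keeps internal unannotated members; in
#' `gapped` mode all unannotated members are deleted before comparison
#' (the anchor is always kept), so contexts differing only by
#' uncharacterized gene insertions co-cluster. Flanking unannotated
#' members are trimmed in both modes. A cluster is conserved when its
#' contexts span at least `min_species` species.
#'
#' @param contexts List of `gene_context` objects.
#' @param mode `"exact"` or `"gapped"`.
#' @param min_species Conservation threshold (default 5 species).
#' @param taxonomy Taxonomy table (genome -> species/phylum).
#' @return A data.frame of class `context_clusters`: `mode`,
#'   `signature`, `n_members`, `n_species`, `conserved_flag`, plus list
#'   columns `anchors` and `phylum_counts`, sorted by descending
#'   `n_members`.
#' @export
cluster_contexts <- function(contexts, mode = c("exact", "gapped"),
                             min_species = 5L, taxonomy = NULL) {
  mode <- match.arg(mode)
  if (length(contexts) == 0L) {
    return(empty_cluster_table(mode))
  }
  sig <- vapply(contexts, cluster_signature, character(1), mode = mode)
  genome <- vapply(contexts, `[[`, character(1), "genome_id")
  anchor <- vapply(contexts, `[[`, character(1), "anchor_accession")
  if (is.null(taxonomy)) {
    species <- genome
    phylum <- rep("unknown", length(genome))
  } else {
    m <- match(genome, taxonomy$genome_id)
    species <- taxonomy$species[m]
    phylum <- taxonomy$phylum[m]
    species[is.na(species)] <- paste0("unknown:", genome[is.na(species)])
    phylum[is.na(phylum)] <- "unknown"
  }

  idx <- split(seq_along(sig), sig)
  out <- data.frame(
    mode = mode,
    signature = names(idx),
    n_members = vapply(idx, length, integer(1)),
    n_species = vapply(idx, function(i) length(unique(species[i])),
                       integer(1)),
    stringsAsFactors = FALSE
  )
  out$conserved_flag <- out$n_species >= min_species
  out$anchors <- lapply(idx, function(i) anchor[i])
  out$phylum_counts <- lapply(idx, function(i) table(phylum[i]))
  out <- out[order_c(-out$n_members, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("context_clusters", "data.frame")
  out
}

empty_cluster_table <- function(mode) {
  out <- data.frame(mode = character(), signature = character(),
                    n_members = integer(), n_species = integer(),
                    conserved_flag = logical(), stringsAsFactors = FALSE)
  out$anchors <- list()
  out$phylum_counts <- list()
  class(out) <- c("context_clusters", "data.frame")
  out
}

#' @export
summary.context_clusters <- function(object, ...) {
  cat("context clusters (", object$mode[1L], " mode): ",
      nrow(object), " clusters, ",
      sum(object$conserved_flag), " conserved\n", sep = "")
  invisible(object)
}

#' Detect adjacent paralog clusters (dyads, triads, ...)
#'
#' Finds maximal runs of genes of the same query family along one
#' replicon whose consecutive gene ordinals differ by at most
#' `max_gap_genes` (default 1 = strictly adjacent genes). Reports run
#' size, member strands, and whether any member is a fusion protein.
#'
#' @param genes Gene table.
#' @param family Family membership table (`protein_accession`,
#'   `query_family`).
#' @param max_gap_genes Maximum allowed ordinal difference between
#'   consecutive members (default 1).
#' @param architectures Optional architecture table used for the
#'   `any_fusion` flag.
#' @return A data.frame with one row per cluster of size >= 2:
#'   `query_family`, `genome_id`, `replicon_id`, `size`, `any_fusion`,
#'   plus list columns `accessions`, `ordinals`, `strands`.
#' @export
detect_adjacent_paralogs <- function(genes, family, max_gap_genes = 1L,
                                     architectures = NULL) {
  fusion <- if (is.null(architectures)) {
    character(0)
  } else {
    architectures$protein_accession[architectures$is_fusion]
  }
  rows <- list()
  for (fam in sort_c(unique(family$query_family))) {
    accs <- family$protein_accession[family$query_family == fam]
    sub <- genes[genes$protein_accession %in% accs, , drop = FALSE]
    if (nrow(sub) < 2L) next
    key <- paste(sub$genome_id, sub$replicon_id, sep = "\r")
    for (grp in split(sub, key)) {
      grp <- grp[order(grp$gene_ordinal), , drop = FALSE]
      if (nrow(grp) < 2L) next
      run_id <- cumsum(c(1L, diff(grp$gene_ordinal) > max_gap_genes))
      for (run in split(grp, run_id)) {
        if (nrow(run) < 2L) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_family = fam,
          genome_id = run$genome_id[1L],
          replicon_id = run$replicon_id[1L],
          size = nrow(run),
          any_fusion = any(run$protein_accession %in% fusion),
          accessions = I(list(run$protein_accession)),
          ordinals = I(list(run$gene_ordinal)),
          strands = I(list(run$strand)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(query_family = character(), genome_id = character(),
                      replicon_id = character(), size = integer(),
                      any_fusion = logical(), stringsAsFactors = FALSE)
    out$accessions <- list()
    out$ordinals <- list()
    out$strands <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report overlapping context windows sharing member genes
#'
#' Contexts of distinct anchors in the same operon are kept as distinct
#' contexts; this post hoc report lists pairs of contexts from the same
#' replicon whose windows share at least one gene.
#'
#' @param contexts List of `gene_context` objects.
#' @return A data.frame `anchor_a`, `anchor_b`, `n_shared_genes`.
#' @export
overlapping_contexts <- function(contexts) {
  n <- length(contexts)
  rows <- list()
  if (n > 1L) {
    key <- vapply(contexts, function(x) {
      paste(x$genome_id, x$replicon_id, sep = "\r")
    }, character(1))
    for (grp in split(seq_len(n), key)) {
      if (length(grp) < 2L) next
      for (a in seq_along(grp)[-length(grp)]) {
        for (b in seq((a + 1L), length(grp))) {
          i <- grp[a]; j <- grp[b]
          shared <- length(intersect(contexts[[i]]$members$accession,
                                     contexts[[j]]$members$accession))
          if (shared > 0L) {
            rows[[length(rows) + 1L]] <- data.frame(
              anchor_a = contexts[[i]]$anchor_accession,
              anchor_b = contexts[[j]]$anchor_accession,
              n_shared_genes = shared,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(anchor_a = character(), anchor_b = character(),
                      n_shared_genes = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
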
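# Phyletic spreads (two-level superkingdom/phylum rollups) and
# upSet-style exact-combination summaries of neighbor architectures.

#' Phyletic spread of a query family across the taxonomy
#'
#' Counts family homologs at the superkingdom and phylum levels and
#' derives proportions of the family total at each level. Homologs are
#' counted per protein (paralogs count individually) unless
#' `per_genome = TRUE`, which counts genomes with at least one homolog
#' (presence/absence heatmap mode). Homologs whose genome is absent
#' from the taxonomy are counted under lineage `"unknown"` with a
#' warning.
#'
#' @param family_name Query family to profile.
#' @param family Family membership table.
#' @param genes Gene table mapping accessions to genomes.
#' @param taxonomy Taxonomy table.
#' @param per_genome Count genome presence instead of proteins.
#' @return An object of class `phyletic_profile`: a long data.frame
#'   with columns `family`, `level` (`superkingdom`/`phylum`),
#'   `lineage`, `superkingdom` (parent lineage), `count`, `proportion`.
#' @export
phyletic_spread <- function(family_name, family, genes, taxonomy,
                            per_genome = FALSE) {
  accs <- family$protein_accession[family$query_family == family_name]
  genome <- genes$genome_id[match(accs, genes$protein_accession)]
  genome <- genome[!is.na(genome)]
  m <- match(genome, taxonomy$genome_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " homolog(s) of ", family_name,
            " in genomes absent from taxonomy; counted as 'unknown'")
  }
  phylum <- ifelse(is.na(m), "unknown", taxonomy$phylum[m])
  sk <- ifelse(is.na(m), "unknown", taxonomy$superkingdom[m])
  if (per_genome) {
    keep <- !duplicated(genome)
    phylum <- phylum[keep]
    sk <- sk[keep]
  }
  total <- length(phylum)

  sk_tab <- table(sk)
  ph_key <- paste(sk, phylum, sep = "\r")
  ph_tab <- table(ph_key)
  ph_parts <- strsplit(names(ph_tab), "\r", fixed = TRUE)

  out <- rbind(
    data.frame(
      family = family_name, level = "superkingdom",
      lineage = names(sk_tab), superkingdom = names(sk_tab),
      count = as.integer(sk_tab), stringsAsFactors = FALSE
    ),
    data.frame(
      family = family_name, level = "phylum",
      lineage = vapply(ph_parts, `[[`, character(1), 2L),
      superkingdom = vapply(ph_parts, `[[`, character(1), 1L),
      count = as.integer(ph_tab), stringsAsFactors = FALSE
    )
  )
  out$proportion <- if (total > 0L) out$count / total else 0
  out <- out[order_c(out$level, out$superkingdom, out$lineage), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("phyletic_profile", "data.frame"),
            family = family_name, total = total)
}

#' @export
print.phyletic_profile <- function(x, ...) {
  cat("<phyletic_profile> family ", attr(x, "family"), ": ",
      attr(x, "total"), " homolog(s)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Long phyletic table and heatmap matrix over several families
#'
#' @param families Character vector of family names (default: all in
#'   the membership table).
#' @inheritParams phyletic_spread
#' @return `phyletic_table()`: the row-bound long profiles.
#'   `phyletic_heatmap()`: a family x phylum count table in long form
#'   (`family`, `lineage`, `superkingdom`, `count`), heatmap-ready; raw
#'   counts are emitted, normalization is left to plotting.
#' @export
phyletic_table <- function(family, genes, taxonomy, families = NULL,
                           per_genome = FALSE) {
  if (is.null(families)) families <- sort_c(unique(family$query_family))
  out <- do.call(rbind, lapply(families, function(f) {
    as.data.frame(phyletic_spread(f, family, genes, taxonomy, per_genome))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname phyletic_table
#' @export
phyletic_heatmap <- function(family, genes, taxonomy, families = NULL,
                             per_genome = FALSE) {
  long <- phyletic_table(family, genes, taxonomy, families, per_genome)
  out <- long[long$level == "phylum",
              c("family", "lineage", "superkingdom", "count")]
  rownames(out) <- NULL
  out
}

#' upSet summary of neighbor-architecture combinations
#'
#' For each anchor, the set of distinct neighbor architecture
#' signatures in its context window (the anchor's own gene and
#' unannotated members excluded) defines one exact combination.
#' Combinations are counted with disjoint semantics: each anchor
#' contributes to exactly one combination, so counts partition the
#' anchor set. Combinations with fewer than `min_count` anchors are
#' flagged as suppressed from the displayed view but retained in the
#' table.
#'
#' @param contexts List of `gene_context` objects.
#' @param min_count Display threshold (default 100 occurrences).
#' @return An object of class `upset_summary`: a data.frame with
#'   `combination` (signatures joined by `" & "`, `"(none)"` for
#'   anchors with no annotated neighbor), `degree`, `count` and
#'   `shown`, sorted by descending count.
#' @export
upset_summary <- function(contexts, min_count = 100L) {
  combos <- vapply(contexts, function(ctx) {
    m <- ctx$members
    labs <- m$label[!m$is_anchor & m$label != UNANNOTATED]
    if (length(labs) == 0L) return("(none)")
    paste(sort_c(unique(labs)), collapse = " & ")
  }, character(1))
  tab <- table(combos)
  out <- data.frame(
    combination = names(tab),
    degree = ifelse(names(tab) == "(none)", 0L,
                    lengths(strsplit(names(tab), " & ", fixed = TRUE))),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out$shown <- out$count >= min_count
  out <- out[order_c(-out$count, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("upset_summary", "data.frame"),
            min_count = as.integer(min_count),
            n_anchors = length(contexts))
}

#' @export
print.upset_summary <- function(x, ...) {
  cat("<upset_summary> ", attr(x, "n_anchors"), " anchors, ",
      nrow(x), " exact combinations (display threshold ",
      attr(x, "min_count"), ")\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
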
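# Ordered N->C domain architectures: overlap resolution among competing
# domain hits, repeat collapsing, fusion calls, and the per-signature
# species census.

#' Collapse tandem repeats in an ordered label sequence
#'
#' Maximal runs of an identical label become `label×k` (k >= 2); single
#' occurrences are left as-is. Collapsed units are joined with `+` into
#' one signature string, so e.g. `c("PspA", "PspA")` gives `"PspA×2"`
#' and `c("PspN_N", "DUF3046")` gives `"PspN_N+DUF3046"`. Idempotent on
#' already-collapsed output.
#'
#' @param labels Character vector of labels in N->C order.
#' @return A single signature string (`""` for empty input).
#' @examples
#' collapse_repeats(c("PspA", "PspA"))
#' collapse_repeats(c("PspN_N", "DUF3046"))
#' @export
collapse_repeats <- function(labels) {
  if (length(labels) == 0L) return("")
  r <- rle(as.character(labels))
  units <- ifelse(r$lengths >= 2L,
                  paste0(r$values, TIMES, r$lengths),
                  r$values)
  paste(units, collapse = "+")
}

#' Build the domain architecture of one protein
#'
#' Orders domain/feature hits N->C, resolves conflicts among overlapping
#' domain hits, and derives repeat-collapsed signatures. Two non-feature
#' hits conflict when their overlap exceeds 50% of the shorter hit;
#' under `overlap_policy = "score_then_length"` conflicts are resolved
#' by precedence higher score > longer hit > smaller start (hits without
#' a score rank below any scored hit). Feature hits (`TM`, `SIG`) are
#' never subject to overlap resolution: they are interleaved at their
#' positions, never count toward fusion status, and are excluded from
#' the domain-only signature. Proteins with no hits get the reserved
#' label `UNANNOTATED`.
#'
#' @param protein_accession Protein identifier.
#' @param hits Hit table rows for this protein (columns `label`,
#'   `start`, `end`, optional `score`; 0-based half-open aa).
#' @param overlap_policy `"score_then_length"` (default) or
#'   `"keep_all"` (no overlap resolution).
#' @return An object of class `domain_architecture`: a list with
#'   `protein_accession`, `ordered_labels`, `collapsed_signature`,
#'   `domain_signature` (features excluded) and `is_fusion` (two or
#'   more distinct non-feature labels).
#' @examples
#' build_architecture("LiaH", data.frame(label = "PspA", start = 0,
#'                                       end = 210, score = 80))
#' @export
build_architecture <- function(protein_accession, hits = NULL,
                               overlap_policy = c("score_then_length",
                                                  "keep_all")) {
  overlap_policy <- match.arg(overlap_policy)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(new_architecture(protein_accession, UNANNOTATED))
  }
  if (!"score" %in% names(hits)) hits$score <- NA_real_
  bad <- hits$end <= hits$start
  if (any(bad)) {
    warning("rejected ", sum(bad), " non-positive-length hit(s) for ",
            protein_accession)
    hits <- hits[!bad, , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(new_architecture(protein_accession, UNANNOTATED))
  }

  is_feature <- hits$label %in% FEATURE_LABELS
  domains <- hits[!is_feature, , drop = FALSE]
  features <- hits[is_feature, , drop = FALSE]
  if (overlap_policy == "score_then_length" && nrow(domains) > 1L) {
    domains <- resolve_overlaps(domains)
  }
  survivors <- rbind(domains, features)
  survivors <- survivors[order_c(survivors$start, survivors$end,
                                 survivors$label), , drop = FALSE]
  new_architecture(protein_accession, as.character(survivors$label))
}

new_architecture <- function(protein_accession, ordered_labels) {
  non_feature <- ordered_labels[!ordered_labels %in% FEATURE_LABELS]
  domain_sig <- if (length(non_feature) == 0L ||
                    identical(non_feature, UNANNOTATED)) {
    UNANNOTATED
  } else {
    collapse_repeats(non_feature)
  }
  structure(
    list(
      protein_accession = protein_accession,
      ordered_labels = ordered_labels,
      collapsed_signature = collapse_repeats(ordered_labels),
      domain_signature = domain_sig,
      is_fusion = length(unique(setdiff(non_feature, UNANNOTATED))) >= 2L
    ),
    class = "domain_architecture"
  )
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat("<domain_architecture> ", x$protein_accession, "\n",
      "  N->C: ", paste(x$ordered_labels, collapse = " - "), "\n",
      "  signature: ", x$collapsed_signature,
      if (x$is_fusion) "  [fusion]" else "", "\n", sep = "")
  invisible(x)
}

# Greedy precedence resolution: hits are visited in order of descending
# score (NA last), then descending length, then ascending start; a hit
# is kept iff it conflicts with no already-kept hit. Conflict = overlap
# > 50% of the shorter hit.
resolve_overlaps <- function(domains) {
  len <- domains$end - domains$start
  score <- ifelse(is.na(domains$score), -Inf, domains$score)
  ord <- order_c(-score, -len, domains$start, domains$label)
  domains <- domains[ord, , drop = FALSE]
  len <- len[ord]
  keep <- logical(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(domains$end[i], domains$end[j]) -
        max(domains$start[i], domains$start[j])
      if (ov > 0.5 * min(len[i], len[j])) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  domains[keep, , drop = FALSE]
}

#' Build architectures for every protein in a hit table
#'
#' @param hits Full hit table (column `protein_accession` plus the
#'   columns of [build_architecture()]).
#' @param proteins Optional accessions to include even when they carry
#'   no hits (annotated as `UNANNOTATED`).
#' @inheritParams build_architecture
#' @return A data.frame with one row per protein: `protein_accession`,
#'   `label_list` (list column), `collapsed_signature`,
#'   `domain_signature`, `is_fusion`.
#' @export
build_architectures <- function(hits, proteins = NULL,
                                overlap_policy = "score_then_length") {
  groups <- split(hits, hits$protein_accession)
  accs <- sort_c(unique(c(names(groups), proteins)))
  archs <- lapply(accs, function(a) {
    build_architecture(a, groups[[a]], overlap_policy)
  })
  data.frame(
    protein_accession = accs,
    label_list = I(lapply(archs, `[[`, "ordered_labels")),
    collapsed_signature = vapply(archs, `[[`, character(1),
                                 "collapsed_signature"),
    domain_signature = vapply(archs, `[[`, character(1),
                              "domain_signature"),
    is_fusion = vapply(archs, `[[`, logical(1), "is_fusion"),
    stringsAsFactors = FALSE
  )
}

#' Signature lookup vector from an architecture table
#'
#' @param architectures Output of [build_architectures()].
#' @param use `"collapsed"` (default, features included) or `"domain"`
#'   (features excluded).
#' @return Named character vector mapping accession to signature;
#'   accessions absent from the table should be treated as
#'   `UNANNOTATED` (see [extract_context()]).
#' @export
signature_lookup <- function(architectures, use = c("collapsed", "domain")) {
  use <- match.arg(use)
  col <- if (use == "collapsed") "collapsed_signature" else "domain_signature"
  stats::setNames(architectures[[col]], architectures$protein_accession)
}

#' Census of architecture signatures across species
#'
#' Groups proteins by repeat-collapsed signature, counts proteins and
#' distinct species, and flags signatures conserved in at least
#' `min_species` species.
#'
#' @param architectures Output of [build_architectures()].
#' @param genes Gene table mapping accessions to genomes.
#' @param taxonomy Taxonomy table mapping genomes to species.
#' @param min_species Conservation threshold (default 2 species).
#' @param use Signature flavour, as in [signature_lookup()].
#' @return A data.frame `signature`, `n_proteins`, `n_species`,
#'   `conserved_flag`, sorted by descending `n_proteins`.
#' @export
architecture_census <- function(architectures, genes, taxonomy,
                                min_species = 2L,
                                use = c("collapsed", "domain")) {
  use <- match.arg(use)
  sig <- signature_lookup(architectures, use)
  genome <- genes$genome_id[match(architectures$protein_accession,
                                  genes$protein_accession)]
  species <- taxonomy$species[match(genome, taxonomy$genome_id)]
  if (anyNA(species)) {
    stop("taxonomy does not resolve all genomes: ",
         paste(utils::head(unique(genome[is.na(species)]), 5L),
               collapse = ", "))
  }
  sig <- unname(sig)
  n_proteins <- tapply(sig, sig, length)
  n_species <- tapply(species, sig, function(s) length(unique(s)))
  out <- data.frame(
    signature = names(n_proteins),
    n_proteins = as.integer(n_proteins),
    n_species = as.integer(n_species[names(n_proteins)]),
    stringsAsFactors = FALSE
  )
  out$conserved_flag <- out$n_species >= min_species
  out <- out[order_c(-out$n_proteins, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
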
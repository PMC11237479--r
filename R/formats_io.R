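# Readers and writers for every external representation the pipeline
# touches: GFF3 gene tables, TSV domain-hit / taxonomy / family tables,
# and the result tables, graphs and JSON manifest.
#
# Conventions: all coordinates are 0-based half-open internally; GFF3 and
# the domain-hit TSV dialect are 1-based inclusive on disk and converted
# at the boundary.

#' Read gene records from a GFF3 file
#'
#' Parses CDS features into a flat gene table. GFF3 1-based inclusive
#' coordinates are converted to 0-based half-open. Gene order along each
#' replicon is defined by ascending start coordinate (not file order):
#' `gene_ordinal` is the 0-based rank of a gene within its replicon.
#'
#' @param path Path to a GFF3 file. CDS features must carry strand and a
#'   protein accession in a `protein_id` (or `ID`) attribute.
#' @param genome_id Genome identifier attached to every record; defaults
#'   to the file name without its `.gff`/`.gff3` extension.
#' @return A data.frame with columns `genome_id`, `replicon_id`,
#'   `gene_ordinal`, `start`, `end`, `strand` (+1/-1) and
#'   `protein_accession`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr\tx\tCDS\t100\t400\t.\t-\t0\tID=cds-a;protein_id=WP_A"), gff)
#' read_gff(gff)
#' @export
read_gff <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.gff3?$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  gr <- gr[types == "CDS"]
  if (length(gr) == 0L) {
    return(empty_gene_table())
  }
  acc <- gr$protein_id
  if (is.null(acc)) acc <- rep(NA_character_, length(gr))
  fallback <- gr$ID
  if (!is.null(fallback)) acc[is.na(acc)] <- fallback[is.na(acc)]
  strand_chr <- as.character(BiocGenerics::strand(gr))

  bad_strand <- which(!strand_chr %in% c("+", "-"))
  bad_acc <- which(is.na(acc) | acc == "")
  if (length(bad_strand) > 0L || length(bad_acc) > 0L) {
    msg <- c(
      if (length(bad_strand) > 0L)
        paste0("CDS records with missing strand: ",
               paste(utils::head(bad_strand, 10L), collapse = ", ")),
      if (length(bad_acc) > 0L)
        paste0("CDS records with missing protein accession: ",
               paste(utils::head(bad_acc, 10L), collapse = ", "))
    )
    stop("Malformed GFF3 '", path, "': ", paste(msg, collapse = "; "))
  }

  genes <- data.frame(
    genome_id = genome_id,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    gene_ordinal = NA_integer_,
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand_chr == "+", 1L, -1L),
    protein_accession = as.character(acc),
    stringsAsFactors = FALSE
  )
  assign_gene_ordinals(genes)
}

#' Read all GFF3 files in a directory
#'
#' @param dir Directory containing one `.gff3` file per genome.
#' @return A combined gene table (see [read_gff()]).
#' @export
read_gff_dir <- function(dir) {
  paths <- sort_c(list.files(dir, pattern = "\\.gff3?$", full.names = TRUE))
  if (length(paths) == 0L) stop("no GFF3 files found under ", dir)
  do.call(rbind, lapply(paths, read_gff))
}

empty_gene_table <- function() {
  data.frame(
    genome_id = character(), replicon_id = character(),
    gene_ordinal = integer(), start = integer(), end = integer(),
    strand = integer(), protein_accession = character(),
    stringsAsFactors = FALSE
  )
}

# Locale-independent character sort (C collation via radix).
sort_c <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(x, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

# (Re)assign 0-based gene ordinals by ascending start within each
# replicon of each genome.
assign_gene_ordinals <- function(genes) {
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  ord <- order_c(key, genes$start, genes$end, genes$protein_accession)
  genes <- genes[ord, , drop = FALSE]
  ranks <- stats::ave(seq_len(nrow(genes)), key[ord],
                      FUN = function(i) seq_along(i) - 1L)
  genes$gene_ordinal <- as.integer(ranks)
  rownames(genes) <- NULL
  genes
}

#' Write a gene table as GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open coordinates are
#' emitted as 1-based inclusive. Output is sorted by replicon and start,
#' with deterministic formatting (byte-identical for identical input).
#'
#' @param genes Gene table (one genome).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  genes <- genes[order_c(genes$replicon_id, genes$start), , drop = FALSE]
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tgenecontext\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;protein_id=%s",
            genes$replicon_id, genes$start + 1L, genes$end,
            ifelse(genes$strand > 0L, "+", "-"),
            genes$protein_accession, genes$protein_accession)
  )
  writeLines(lines, path)
  invisible(path)
}

# Shared TSV reader: header required, tabs only, keep extra columns.
read_tsv_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("'", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

write_tsv_table <- function(df, path) {
  # list columns are serialized by the caller before reaching here
  stopifnot(!vapply(df, is.list, logical(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a domain/feature hit table
#'
#' Tab-separated, headered table with columns `protein_accession`,
#' `label`, `start`, `end` and optionally `score` (bits). On-disk
#' coordinates are 1-based inclusive amino-acid positions (the common
#' domain-scanner convention) and are converted to 0-based half-open.
#' Rows with malformed coordinates or empty labels are rejected with a
#' warning reporting the count; unknown extra columns are preserved.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of typed hits.
#' @export
read_domain_hits <- function(path) {
  df <- read_tsv_table(path, c("protein_accession", "label", "start", "end"))
  if (!"score" %in% names(df)) df$score <- NA_real_
  df$start <- suppressWarnings(as.numeric(df$start))
  df$end <- suppressWarnings(as.numeric(df$end))
  df$score <- suppressWarnings(as.numeric(df$score))
  bad <- !is.finite(df$start) | !is.finite(df$end) |
    df$start < 1 | df$end < df$start |
    is.na(df$label) | df$label == "" |
    is.na(df$protein_accession) | df$protein_accession == ""
  if (any(bad)) {
    warning(sum(bad), " malformed hit row(s) rejected from '", path, "'")
    df <- df[!bad, , drop = FALSE]
  }
  df$start <- as.integer(df$start) - 1L
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  df
}

#' Write a domain hit table (inverse of [read_domain_hits()])
#' @param hits Hit table with internal 0-based half-open coordinates.
#' @param path Output path.
#' @export
write_domain_hits <- function(hits, path) {
  out <- hits
  out$start <- out$start + 1L
  out$score <- ifelse(is.na(out$score), "", sprintf("%.1f", out$score))
  write_tsv_table(out, path)
}

#' Read a taxonomy table (genome -> species -> phylum -> superkingdom)
#' @param path Path to a TSV with columns `genome_id`, `species`,
#'   `phylum`, `superkingdom`.
#' @return A data.frame, one row per genome.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_table(path, c("genome_id", "species", "phylum",
                               "superkingdom"))
  dup <- duplicated(df$genome_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate genome_id row(s) dropped from '", path, "'")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_taxonomy
#' @param taxonomy Taxonomy table to write.
#' @export
write_taxonomy <- function(taxonomy, path) write_tsv_table(taxonomy, path)

#' Read a query-family membership table
#'
#' A protein may belong to several families (one row each); exact
#' duplicate rows are dropped with a warning.
#'
#' @param path Path to a TSV with columns `protein_accession`,
#'   `query_family`.
#' @return A data.frame of unique membership rows.
#' @export
read_family <- function(path) {
  df <- read_tsv_table(path, c("protein_accession", "query_family"))
  bad <- is.na(df$protein_accession) | df$protein_accession == "" |
    is.na(df$query_family) | df$query_family == ""
  if (any(bad)) {
    warning(sum(bad), " malformed family row(s) rejected from '", path, "'")
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df[c("protein_accession", "query_family")])
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_family
#' @param family Family membership table to write.
#' @export
write_family <- function(family, path) write_tsv_table(family, path)

#' Write a proximity network as edge list, node table and GML
#'
#' @param net An igraph proximity network (see [build_network()]).
#' @param path_prefix Output path prefix; writes
#'   `<prefix>.edges.tsv`, `<prefix>.nodes.tsv` and `<prefix>.gml`.
#' @return Character vector of the files written, invisibly.
#' @export
write_network <- function(net, path_prefix) {
  edge_path <- paste0(path_prefix, ".edges.tsv")
  node_path <- paste0(path_prefix, ".nodes.tsv")
  gml_path <- paste0(path_prefix, ".gml")

  nodes <- data.frame(
    label = igraph::V(net)$name,
    weight = igraph::V(net)$weight,
    occurrences = igraph::V(net)$occurrences,
    stringsAsFactors = FALSE
  )
  if (igraph::ecount(net) > 0L) {
    ends <- igraph::as_edgelist(net)
    edges <- data.frame(
      label_a = ends[, 1L], label_b = ends[, 2L],
      weight = igraph::E(net)$weight,
      provenance = igraph::E(net)$provenance,
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(label_a = character(), label_b = character(),
                        weight = numeric(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  write_tsv_table(nodes, node_path)
  write_tsv_table(edges, edge_path)
  igraph::write_graph(net, gml_path, format = "gml")
  # igraph stamps the Creator line with a timestamp; pin it so identical
  # networks produce byte-identical files
  gml <- readLines(gml_path)
  gml[startsWith(gml, "Creator")] <- "Creator \"genecontext\""
  writeLines(gml, gml_path)
  invisible(c(edge_path, node_path, gml_path))
}

#' Write all pipeline results and a JSON run manifest
#'
#' Emits TSV tables for architectures, contexts, clusters, paralogs,
#' phyletic profiles, heatmap counts and upSet summaries, each network
#' as edge-list TSV + node TSV + GML, and a `manifest.json` listing the
#' files, the resolved parameters and the seed. Only components present
#' in `results` are written.
#'
#' @param results Named list with any of: `architectures`, `census`,
#'   `contexts` (list of gene_context), `clusters` (data.frame),
#'   `paralogs`, `phyletics`, `heatmap`, `upset`, `networks` (named list
#'   of igraph).
#' @param outdir Output directory (created if needed).
#' @param params Named list of resolved pipeline parameters (e.g. the
#'   `pipeline_config()` used); stored verbatim in the manifest.
#' @return The manifest, invisibly (a named list).
#' @export
write_results <- function(results, outdir, params = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", outdir)
  }
  files <- character()
  put <- function(df, name) {
    write_tsv_table(df, file.path(outdir, name))
    files <<- c(files, name)
  }

  if (!is.null(results$architectures)) {
    put(architecture_table(results$architectures), "architectures.tsv")
  }
  if (!is.null(results$census)) put(results$census, "census.tsv")
  if (!is.null(results$contexts)) {
    put(context_table(results$contexts), "contexts.tsv")
  }
  if (!is.null(results$clusters)) {
    put(cluster_table(results$clusters), "clusters.tsv")
  }
  if (!is.null(results$paralogs)) {
    put(paralog_table(results$paralogs), "paralogs.tsv")
  }
  if (!is.null(results$phyletics)) put(results$phyletics, "phyletics.tsv")
  if (!is.null(results$heatmap)) put(results$heatmap, "heatmap.tsv")
  if (!is.null(results$upset)) {
    put(as.data.frame(results$upset), "upset.tsv")
  }
  for (nm in names(results$networks)) {
    written <- write_network(results$networks[[nm]],
                             file.path(outdir, paste0("network_", nm)))
    files <- c(files, basename(written))
  }

  manifest <- list(
    package = "genecontext",
    version = as.character(utils::packageVersion("genecontext")),
    parameters = params,
    files = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Flat-table serializations of structured results -----------------------

architecture_table <- function(arch) {
  data.frame(
    protein_accession = arch$protein_accession,
    ordered_labels = vapply(arch$label_list, paste, character(1),
                            collapse = ","),
    collapsed_signature = arch$collapsed_signature,
    domain_signature = arch$domain_signature,
    is_fusion = arch$is_fusion,
    stringsAsFactors = FALSE
  )
}

context_table <- function(contexts) {
  data.frame(
    anchor_accession = vapply(contexts, `[[`, character(1),
                              "anchor_accession"),
    genome_id = vapply(contexts, `[[`, character(1), "genome_id"),
    replicon_id = vapply(contexts, `[[`, character(1), "replicon_id"),
    n_members = vapply(contexts, function(x) nrow(x$members), integer(1)),
    truncated_left = vapply(contexts, `[[`, logical(1), "truncated_left"),
    truncated_right = vapply(contexts, `[[`, logical(1), "truncated_right"),
    signature = vapply(contexts, `[[`, character(1), "signature"),
    stringsAsFactors = FALSE
  )
}

cluster_table <- function(clusters) {
  out <- clusters
  out$anchors <- vapply(clusters$anchors, paste, character(1),
                        collapse = ";")
  out$phylum_counts <- vapply(clusters$phylum_counts, function(x) {
    paste(sprintf("%s=%d", names(x), as.integer(x)), collapse = ";")
  }, character(1))
  out
}

paralog_table <- function(paralogs) {
  out <- paralogs
  out$accessions <- vapply(paralogs$accessions, paste, character(1),
                           collapse = ";")
  out$ordinals <- vapply(paralogs$ordinals, paste, character(1),
                         collapse = ";")
  out$strands <- vapply(paralogs$strands, function(s) {
    paste(ifelse(s > 0L, "+", "-"), collapse = ";")
  }, character(1))
  out
}
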
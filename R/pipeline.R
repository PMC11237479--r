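# Pipeline orchestration: resolved configuration, the end-to-end run
# over a directory of inputs, and per-stage logging.

#' Resolved pipeline configuration
#'
#' Defaults follow the survey conventions: a ±7 gene window, context
#' conservation at 5 species, architecture conservation at 2 species,
#' 97% homolog retention for the proximity network, and an upSet
#' display threshold of 100 occurrences. Invalid values raise an error
#' before any output is written.
#'
#' @param window Genes on each side of an anchor (>= 0).
#' @param min_species_context Species threshold for conserved contexts.
#' @param min_species_arch Species threshold for conserved
#'   architectures.
#' @param retention_fraction Homolog retention fraction in (0, 1].
#' @param upset_min_count upSet display threshold.
#' @param cluster_mode `"exact"`, `"gapped"` or `"both"`.
#' @param seed Integer seed recorded in the run manifest.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 7L, min_species_context = 5L,
                            min_species_arch = 2L,
                            retention_fraction = 0.97,
                            upset_min_count = 100L,
                            cluster_mode = c("both", "exact", "gapped"),
                            seed = 1L) {
  cluster_mode <- match.arg(cluster_mode)
  cfg <- list(
    window = as.integer(window),
    min_species_context = as.integer(min_species_context),
    min_species_arch = as.integer(min_species_arch),
    retention_fraction = retention_fraction,
    upset_min_count = as.integer(upset_min_count),
    cluster_mode = cluster_mode,
    seed = as.integer(seed)
  )
  if (is.na(cfg$window) || cfg$window < 0L) {
    stop("window must be a non-negative integer")
  }
  if (is.na(cfg$min_species_context) || cfg$min_species_context < 1L ||
      is.na(cfg$min_species_arch) || cfg$min_species_arch < 1L) {
    stop("species thresholds must be >= 1")
  }
  if (!is.numeric(cfg$retention_fraction) ||
      cfg$retention_fraction <= 0 || cfg$retention_fraction > 1) {
    stop("retention_fraction must lie in (0, 1]")
  }
  if (is.na(cfg$upset_min_count) || cfg$upset_min_count < 0L) {
    stop("upset_min_count must be >= 0")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides`
#' (typically command-line flags) take precedence over file values.
#'
#' @param path Path to a YAML key-value file, or `NULL` for defaults.
#' @param overrides Named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", as.character(x[[nm]]), "\n",
                           sep = "")
  invisible(x)
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[genecontext] ", ...)
  invisible(NULL)
}

#' Run the full analysis pipeline over a directory of inputs
#'
#' Expects `indir` to contain `genomes/*.gff3`, `hits.tsv`,
#' `taxonomy.tsv` and `family.tsv` (the layout written by
#' [generate_synthetic()]). Runs architecture construction, the
#' architecture census, context extraction for every family homolog,
#' context clustering, adjacent-paralog detection, homolog retention,
#' proximity-network construction, phyletic profiling and the upSet
#' summary, then writes all result tables and a JSON run manifest to
#' `outdir`.
#'
#' Every stage is a pure function of (inputs, config), so reruns with
#' identical inputs and configuration give identical outputs.
#'
#' @param indir Input directory.
#' @param outdir Output directory (`NULL` skips writing).
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage counts to stderr.
#' @return A named list with all intermediate and final results
#'   (`genes`, `hits`, `taxonomy`, `family`, `architectures`, `census`,
#'   `contexts`, `clusters_exact`, `clusters_gapped`, `paralogs`,
#'   `retained`, `networks`, `phyletics`, `heatmap`, `upset`,
#'   `manifest`), invisibly.
#' @export
run_pipeline <- function(indir, outdir = NULL, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("hits.tsv", "taxonomy.tsv", "family.tsv")) {
    if (!file.exists(file.path(indir, f))) {
      stop("missing input file: ", file.path(indir, f))
    }
  }
  genes <- read_gff_dir(file.path(indir, "genomes"))
  hits <- read_domain_hits(file.path(indir, "hits.tsv"))
  taxonomy <- read_taxonomy(file.path(indir, "taxonomy.tsv"))
  family <- read_family(file.path(indir, "family.tsv"))
  pipeline_log(verbose, "read ", nrow(genes), " genes, ", nrow(hits),
               " hits, ", nrow(family), " family rows")

  architectures <- build_architectures(hits)
  census <- architecture_census(architectures, genes, taxonomy,
                                min_species = config$min_species_arch)
  pipeline_log(verbose, nrow(architectures), " architectures, ",
               sum(census$conserved_flag), " conserved signatures")

  signatures <- signature_lookup(architectures)
  anchors <- sort_c(unique(family$protein_accession))
  anchors <- anchors[anchors %in% genes$protein_accession]
  contexts <- extract_contexts(genes, anchors, signatures,
                               window = config$window)
  pipeline_log(verbose, length(contexts), " contexts extracted")

  clusters_exact <- clusters_gapped <- NULL
  if (config$cluster_mode %in% c("exact", "both")) {
    clusters_exact <- cluster_contexts(
      contexts, "exact", min_species = config$min_species_context,
      taxonomy = taxonomy)
  }
  if (config$cluster_mode %in% c("gapped", "both")) {
    clusters_gapped <- cluster_contexts(
      contexts, "gapped", min_species = config$min_species_context,
      taxonomy = taxonomy)
  }
  pipeline_log(verbose,
               sum(clusters_exact$conserved_flag %||% 0L),
               " conserved exact clusters")

  paralogs <- detect_adjacent_paralogs(genes, family,
                                       architectures = architectures)

  retained <- retain_top_fraction(architectures,
                                  fraction = config$retention_fraction,
                                  family = family)
  networks <- list(
    within_protein = build_network(architectures, retained = retained,
                                   provenance = "within_protein"),
    within_neighborhood = build_network(architectures, retained = retained,
                                        contexts = contexts,
                                        provenance = "within_neighborhood")
  )
  pipeline_log(verbose, length(retained), " retained proteins; ",
               igraph::vcount(networks$within_protein), "/",
               igraph::ecount(networks$within_protein),
               " nodes/edges within proteins")

  phyletics <- phyletic_table(family, genes, taxonomy)
  heatmap <- phyletic_heatmap(family, genes, taxonomy, per_genome = TRUE)
  upset <- upset_summary(contexts, min_count = config$upset_min_count)

  clusters_all <- rbind(clusters_exact, clusters_gapped)
  results <- list(
    genes = genes, hits = hits, taxonomy = taxonomy, family = family,
    architectures = architectures, census = census, contexts = contexts,
    clusters_exact = clusters_exact, clusters_gapped = clusters_gapped,
    paralogs = paralogs, retained = retained, networks = networks,
    phyletics = phyletics, heatmap = heatmap, upset = upset
  )
  if (!is.null(outdir)) {
    results$manifest <- write_results(
      list(architectures = architectures, census = census,
           contexts = contexts, clusters = clusters_all,
           paralogs = paralogs, phyletics = phyletics, heatmap = heatmap,
           upset = upset, networks = networks),
      outdir, params = unclass(config))
    pipeline_log(verbose, "results written to ", outdir)
  }
  invisible(results)
}
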
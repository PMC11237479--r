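# In-code fixtures: small gene tables, hit tables and scaled-down
# synthetic configurations shared across test files.

make_genes <- function(accessions, strands = NULL, genome = "G1",
                       replicon = "chr", gene_len = 900L, gap = 100L) {
  n <- length(accessions)
  if (is.null(strands)) strands <- rep(1L, n)
  start <- (seq_len(n) - 1L) * (gene_len + gap)
  data.frame(
    genome_id = genome, replicon_id = replicon,
    gene_ordinal = seq_len(n) - 1L,
    start = start, end = start + gene_len,
    strand = as.integer(strands), protein_accession = accessions,
    stringsAsFactors = FALSE
  )
}

make_hit <- function(acc, label, start, end, score = NA_real_) {
  data.frame(protein_accession = acc, label = label, start = start,
             end = end, score = score, stringsAsFactors = FALSE)
}

tiny_taxonomy <- function(genomes, species = genomes,
                          phylum = "Proteobacteria",
                          superkingdom = "Bacteria") {
  data.frame(genome_id = genomes, species = species,
             phylum = rep_len(phylum, length(genomes)),
             superkingdom = rep_len(superkingdom, length(genomes)),
             stringsAsFactors = FALSE)
}

# Random replicon with a mix of annotated and unannotated genes; the
# signature lookup maps annotated genes to single-label signatures.
random_replicon <- function(n_genes, genome = "G1", seed_labels = NULL) {
  acc <- sprintf("%s_P%03d", genome, seq_len(n_genes))
  genes <- make_genes(acc, strands = sample(c(1L, -1L), n_genes,
                                            replace = TRUE),
                      genome = genome)
  annotated <- runif(n_genes) < 0.6
  labels <- if (is.null(seed_labels)) {
    sprintf("DOM%02d", sample.int(8L, n_genes, replace = TRUE))
  } else {
    sample(seed_labels, n_genes, replace = TRUE)
  }
  sigs <- stats::setNames(labels[annotated], acc[annotated])
  list(genes = genes, signatures = sigs)
}

# Scaled-down generator configuration used by module tests: 20 genomes
# x 150 genes, template targets capped at 5 species.
small_synth_config <- function(seed = 42L, ...) {
  tpl <- lapply(default_operon_templates(), function(t) {
    t$target_species <- min(t$target_species, 5L)
    t
  })
  synth_config(seed = seed, n_superkingdoms = 2L, n_phyla = 2L,
               n_species = 5L, genes_per_genome = 150L,
               operon_templates = tpl, ...)
}

generate_small <- function(seed = 42L, ...) {
  dir <- file.path(tempfile("synth"), "data")
  m <- generate_synthetic(small_synth_config(seed = seed, ...), dir)
  list(dir = dir, manifest = m)
}

# Contexts with known neighbor label sets for upSet checks.
upset_fixture <- function(n_anchors = 15L, labels = c("X", "Y", "Z")) {
  set.seed(701)
  contexts <- list()
  neighbor_sets <- list()
  for (i in seq_len(n_anchors)) {
    gn <- sprintf("G%02d", i)
    nb <- sample(labels, sample(0:3, 1))
    accs <- c(sprintf("%s_A", gn),
              if (length(nb)) sprintf("%s_N%d", gn, seq_along(nb)))
    sigs <- stats::setNames(c("Anchor", nb), accs)
    genes <- make_genes(accs, genome = gn)
    contexts[[i]] <- extract_context(accs[1], genes, window = 7L,
                                     signatures = sigs)
    neighbor_sets[[i]] <- nb
  }
  list(contexts = contexts, neighbor_sets = neighbor_sets)
}
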
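# Synthetic genomes with planted ground truth: conserved operons
# (including divergently transcribed regulator layouts), fusions,
# tandem repeats, paralog dyads/triads, lineage-restricted families,
# background noise genes, and a manifest for recovery benchmarking.
#
# Background genes are transcribed on either strand, carry globally
# unique protein accessions (the unique-label pool) and no domain
# annotation, so the probability of spurious conserved contexts is zero
# by construction. Insertion noise adds uncharacterized genes into
# internal operon slots only, capped so that every operon member stays
# within the anchor's window.

#' Default operon templates
#'
#' Ten templates emulating recurrent membrane-stress operon layouts:
#' a divergently transcribed enhancer-binding regulator upstream of a
#' three-gene operon, a four-gene actinobacterial-style operon
#' restricted to one phylum, a six-gene two-component-system operon, a
#' fusion-anchored pair, a tandem-repeat anchor, and several smaller
#' two- to four-gene associations. Each template gene carries an
#' architecture (one or more domain/feature labels), a strand, an
#' optional query-family assignment (family genes are context anchors)
#' and an `optional` flag (eligible for loss noise).
#'
#' @return A list of template lists with fields `id`, `genes`,
#'   `target_species` and optional `phyla` (indices of allowed phyla).
#' @export
default_operon_templates <- function() {
  gene <- function(labels, strand = 1L, family = NA_character_,
                   optional = FALSE) {
    list(labels = labels, strand = as.integer(strand), family = family,
         optional = optional)
  }
  list(
    list(id = "psp_fabc", target_species = 25L, genes = list(
      gene(c("NtrC_AAA", "Fis_HTH"), -1L),
      gene("PspA", 1L, "PspA"),
      gene("PspB", 1L, "PspB", optional = TRUE),
      gene("PspC", 1L, "PspC")
    )),
    list(id = "clgr_pspamn", target_species = 12L, phyla = 1L, genes = list(
      gene("cHTH", 1L),
      gene("PspA", 1L, "PspA"),
      gene("PspM", 1L, "PspM"),
      gene(c("PspN_N", "DUF3046"), 1L)
    )),
    list(id = "lia_operon", target_species = 15L, genes = list(
      gene("LiaI_LiaF_TM", 1L),
      gene("PspA", 1L, "PspA"),
      gene("Toastrack", 1L, "Toastrack", optional = TRUE),
      gene(c("LiaI_LiaF_TM", "Toastrack"), 1L),
      gene(c("HAMP", "HisKin"), 1L),
      gene(c("REC", "wHTH"), 1L)
    )),
    list(id = "pspa_thioredoxin", target_species = 8L, genes = list(
      gene("PspA", 1L, "PspA"),
      gene("Thioredoxin", 1L)
    )),
    list(id = "pspa_nlpc_fusion", target_species = 6L, genes = list(
      gene(c("PspA", "NlpC_P60"), 1L, "PspA"),
      gene("Hydrolase_assoc", 1L)
    )),
    list(id = "pspa_tandem", target_species = 6L, genes = list(
      gene(c("PspA", "PspA"), 1L, "PspA"),
      gene("PspAA", 1L)
    )),
    list(id = "toastrack_haas", target_species = 10L, genes = list(
      gene("Toastrack", 1L, "Toastrack"),
      gene("HAAS", 1L),
      gene("SHOCT", -1L)
    )),
    list(id = "pspc_flotillin", target_species = 9L, genes = list(
      gene(c("SIG", "PspC"), 1L, "PspC"),
      gene("Band7", 1L),
      gene("NfeD", 1L)
    )),
    list(id = "snf7_pspa", target_species = 7L, genes = list(
      gene("Snf7", 1L, "Snf7"),
      gene("PspA", 1L, "PspA"),
      gene("CoiledCoil", 1L)
    )),
    list(id = "cyano_pspa", target_species = 8L, genes = list(
      gene("PspA", 1L, "PspA"),
      gene("SpermGS_ATPgrasp", 1L),
      gene("Spermine_synth", 1L),
      gene("ZnR", 1L)
    ))
  )
}

#' Default lineage-restriction scheme for singleton families
#'
#' One family confined to the first two phyla (narrow spread) and one
#' broadly but sparsely distributed family. `phyla = NULL` allows all
#' phyla; `phylum_prob` is the per-phylum Bernoulli presence
#' probability; within present phyla each genome carries the family
#' with probability `genome_prob`.
#'
#' @return Named list of per-family presence settings.
#' @export
default_family_presence <- function() {
  list(
    DUF3046 = list(phyla = c(1L, 2L), phylum_prob = 1.0,
                   genome_prob = 0.8),
    CesT_Tir = list(phyla = NULL, phylum_prob = 0.4, genome_prob = 0.7)
  )
}

#' Configuration for the synthetic-genome generator
#'
#' The seed fully determines the output (byte-identical regeneration).
#' Defaults describe the benchmark conditions used throughout the
#' package: 2 superkingdoms x 5 phyla x 20 species (one genome per
#' species, 200 genomes), 500 background genes per genome, the ten
#' default operon templates, and no insertion/loss noise.
#'
#' @param seed Integer RNG seed.
#' @param n_superkingdoms,n_phyla,n_species Balanced taxonomy: phyla
#'   per superkingdom, species per phylum, one genome per species.
#' @param genes_per_genome Background genes per genome.
#' @param operon_templates See [default_operon_templates()].
#' @param insertion_rate Per-internal-slot probability of inserting an
#'   uncharacterized gene into a planted operon (capped so no member
#'   leaves the anchor window).
#' @param loss_rate Per-optional-member probability of loss.
#' @param family_presence See [default_family_presence()].
#' @param paralog_dyad_rate Per-genome probability of an adjacent
#'   paralog dyad (30% of dyads extend to triads).
#' @param fusion_rate,repeat_rate Per-genome probabilities of a
#'   singleton fusion protein / tandem-repeat protein of the anchor
#'   family.
#' @param window Context window the plants are spaced against.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_superkingdoms = 2L, n_phyla = 5L,
                         n_species = 20L, genes_per_genome = 500L,
                         operon_templates = default_operon_templates(),
                         insertion_rate = 0, loss_rate = 0,
                         family_presence = default_family_presence(),
                         paralog_dyad_rate = 0.15, fusion_rate = 0.05,
                         repeat_rate = 0.05, window = 7L) {
  cfg <- list(
    seed = as.integer(seed), n_superkingdoms = as.integer(n_superkingdoms),
    n_phyla = as.integer(n_phyla), n_species = as.integer(n_species),
    genes_per_genome = as.integer(genes_per_genome),
    operon_templates = operon_templates,
    insertion_rate = insertion_rate, loss_rate = loss_rate,
    family_presence = family_presence,
    paralog_dyad_rate = paralog_dyad_rate, fusion_rate = fusion_rate,
    repeat_rate = repeat_rate, window = as.integer(window)
  )
  rates <- c(insertion_rate = insertion_rate, loss_rate = loss_rate,
             paralog_dyad_rate = paralog_dyad_rate,
             fusion_rate = fusion_rate, repeat_rate = repeat_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (any(c(cfg$n_superkingdoms, cfg$n_phyla, cfg$n_species) < 1L)) {
    stop("taxonomy dimensions must be positive")
  }
  n_genomes <- cfg$n_superkingdoms * cfg$n_phyla * cfg$n_species
  for (tpl in operon_templates) {
    len <- length(tpl$genes)
    if (len + 2L * cfg$window > cfg$genes_per_genome) {
      stop("infeasible config: template '", tpl$id,
           "' plus window exceeds genes_per_genome")
    }
    anchors <- which(!vapply(tpl$genes, function(g) is.na(g$family),
                             logical(1)))
    if (length(anchors) == 0L) {
      stop("template '", tpl$id, "' has no family-assigned anchor gene")
    }
    d_max <- max(vapply(anchors, function(a) max(a - 1L, len - a),
                        integer(1)))
    if (d_max > cfg$window) {
      stop("infeasible config: template '", tpl$id,
           "' member lies beyond the anchor window")
    }
    pool <- template_genome_pool_size(tpl, cfg)
    if (tpl$target_species > pool) {
      stop("infeasible config: template '", tpl$id, "' targets ",
           tpl$target_species, " species but only ", pool,
           " genomes are eligible")
    }
  }
  structure(cfg, class = "synth_config")
}

template_genome_pool_size <- function(tpl, cfg) {
  if (is.null(tpl$phyla)) {
    cfg$n_superkingdoms * cfg$n_phyla * cfg$n_species
  } else {
    length(tpl$phyla) * cfg$n_species
  }
}

#' @export
print.synth_config <- function(x, ...) {
  n_genomes <- x$n_superkingdoms * x$n_phyla * x$n_species
  cat("<synth_config> seed ", x$seed, ": ", n_genomes, " genomes (",
      x$n_superkingdoms, " superkingdoms x ", x$n_phyla, " phyla x ",
      x$n_species, " species), ", x$genes_per_genome,
      " background genes/genome, ", length(x$operon_templates),
      " operon templates\n", sep = "")
  cat("  insertion_rate ", x$insertion_rate, ", loss_rate ", x$loss_rate,
      ", dyad rate ", x$paralog_dyad_rate, "\n", sep = "")
  invisible(x)
}

# Balanced taxonomy table; one genome per species.
synth_taxonomy <- function(cfg) {
  sk_names <- if (cfg$n_superkingdoms <= 2L) {
    c("Bacteria", "Archaea")[seq_len(cfg$n_superkingdoms)]
  } else {
    sprintf("Superkingdom%02d", seq_len(cfg$n_superkingdoms))
  }
  rows <- list()
  g <- 0L
  for (sk in sk_names) {
    for (p in seq_len(cfg$n_phyla)) {
      phylum <- sprintf("%s_phylum%02d", sk, p)
      for (s in seq_len(cfg$n_species)) {
        g <- g + 1L
        rows[[g]] <- data.frame(
          genome_id = sprintf("G%04d", g),
          species = sprintf("%s_sp%02d", phylum, s),
          phylum = phylum,
          superkingdom = sk,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Canonical context tokenization used to derive a plant's expected
# cluster signatures from its gene list (anchored at gene `anchor_idx`).
plant_signature <- function(genes, anchor_idx, gapped = FALSE) {
  labels <- vapply(genes, function(g) {
    if (length(g$labels) == 0L) UNANNOTATED else collapse_repeats(g$labels)
  }, character(1))
  strands <- vapply(genes, `[[`, integer(1), "strand")
  keep <- if (gapped) {
    labels != UNANNOTATED | seq_along(genes) == anchor_idx
  } else {
    rep(TRUE, length(genes))
  }
  labels <- labels[keep]
  strands <- strands[keep]
  anchor_pos <- which(which(keep) == anchor_idx)
  rel <- ifelse(strands == strands[anchor_pos], "same", "opposite")
  ord <- seq_along(labels)
  if (strands[anchor_pos] < 0L) ord <- rev(ord)
  signature_from_members(data.frame(
    accession = labels[ord], label = labels[ord], rel_strand = rel[ord],
    is_anchor = ord == anchor_pos, stringsAsFactors = FALSE
  ))
}

# Apply loss then insertion noise to a template instance.
instantiate_template <- function(tpl, cfg) {
  genes <- tpl$genes
  lost <- 0L
  if (cfg$loss_rate > 0) {
    optional <- vapply(genes, `[[`, logical(1), "optional")
    anchored <- !vapply(genes, function(g) is.na(g$family), logical(1))
    drop <- optional & !anchored & stats::runif(length(genes)) < cfg$loss_rate
    lost <- sum(drop)
    genes <- genes[!drop]
  }
  inserted <- 0L
  if (cfg$insertion_rate > 0 && length(genes) >= 2L) {
    len <- length(genes)
    anchors <- which(!vapply(genes, function(g) is.na(g$family),
                             logical(1)))
    d_max <- max(vapply(anchors, function(a) max(a - 1L, len - a),
                        integer(1)))
    cap <- max(0L, cfg$window - d_max)
    k <- min(stats::rbinom(1L, len - 1L, cfg$insertion_rate), cap)
    if (k > 0L) {
      slots <- sort(sample(seq_len(len - 1L), k))
      out <- list()
      for (i in seq_len(len)) {
        out[[length(out) + 1L]] <- genes[[i]]
        n_ins <- sum(slots == i)
        for (z in seq_len(n_ins)) {
          out[[length(out) + 1L]] <- list(
            labels = character(0),
            strand = sample(c(1L, -1L), 1L),
            family = NA_character_, optional = FALSE
          )
        }
      }
      genes <- out
      inserted <- k
    }
  }
  list(genes = genes, lost = lost, inserted = inserted)
}

#' Generate synthetic genomes with planted ground truth
#'
#' Emits one GFF3 per genome plus combined domain-hit, taxonomy and
#' family TSVs and a JSON ground-truth manifest under `outdir`.
#' Identical seeds regenerate byte-identical files.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory (created; subdirectory `genomes/`
#'   holds the GFF3 files).
#' @return The ground-truth manifest (class `synth_manifest`),
#'   invisibly. Fields: `plants` (one record per planted instance with
#'   anchors and expected exact/gapped cluster signatures), `templates`
#'   (id, genomes, species), `paralogs`, `expected_signatures` (per
#'   mode), `family_counts` (true per-phylum homolog counts) and
#'   `files`.
#' @export
generate_synthetic <- function(config, outdir) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(file.path(outdir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)

  taxonomy <- synth_taxonomy(cfg)
  phyla <- unique(taxonomy$phylum)
  genomes <- taxonomy$genome_id

  # --- plan plants per genome -----------------------------------------
  plan <- stats::setNames(vector("list", length(genomes)), genomes)
  add_plant <- function(genome, plant) {
    plan[[genome]][[length(plan[[genome]]) + 1L]] <<- plant
  }

  templates_meta <- list()
  for (tpl in cfg$operon_templates) {
    pool <- if (is.null(tpl$phyla)) genomes else
      taxonomy$genome_id[taxonomy$phylum %in% phyla[tpl$phyla]]
    chosen <- sort_c(sample(pool, tpl$target_species))
    for (gn in chosen) {
      inst <- instantiate_template(tpl, cfg)
      add_plant(gn, list(kind = "template", id = tpl$id,
                         genes = inst$genes, inserted = inst$inserted,
                         lost = inst$lost))
    }
    templates_meta[[tpl$id]] <- list(id = tpl$id, genomes = chosen)
  }

  for (gn in genomes) {
    if (stats::runif(1) < cfg$paralog_dyad_rate) {
      size <- if (stats::runif(1) < 0.3) 3L else 2L
      add_plant(gn, list(kind = "paralog_cluster", id = "pspa_dyad",
                         genes = replicate(size, list(
                           labels = "PspA", strand = 1L,
                           family = "PspA", optional = FALSE
                         ), simplify = FALSE),
                         inserted = 0L, lost = 0L))
    }
    if (stats::runif(1) < cfg$fusion_rate) {
      add_plant(gn, list(kind = "fusion_singleton", id = "pspa_nlpc_solo",
                         genes = list(list(labels = c("PspA", "NlpC_P60"),
                                           strand = 1L, family = "PspA",
                                           optional = FALSE)),
                         inserted = 0L, lost = 0L))
    }
    if (stats::runif(1) < cfg$repeat_rate) {
      add_plant(gn, list(kind = "repeat_singleton", id = "pspa_tandem_solo",
                         genes = list(list(labels = c("PspA", "PspA"),
                                           strand = 1L, family = "PspA",
                                           optional = FALSE)),
                         inserted = 0L, lost = 0L))
    }
  }

  for (fam in names(cfg$family_presence)) {
    fp <- cfg$family_presence[[fam]]
    allowed <- if (is.null(fp$phyla)) phyla else phyla[fp$phyla]
    present <- allowed[stats::runif(length(allowed)) < fp$phylum_prob]
    for (gn in taxonomy$genome_id[taxonomy$phylum %in% present]) {
      if (stats::runif(1) < fp$genome_prob) {
        add_plant(gn, list(kind = "lineage_family", id = fam,
                           genes = list(list(labels = fam, strand = 1L,
                                             family = fam,
                                             optional = FALSE)),
                           inserted = 0L, lost = 0L))
      }
    }
  }

  # --- emit genomes ----------------------------------------------------
  hit_rows <- list()
  family_rows <- list()
  plant_records <- list()
  files <- character()

  for (gn in genomes) {
    emitted <- emit_genome(gn, plan[[gn]], cfg, outdir)
    files <- c(files, emitted$file)
    hit_rows[[gn]] <- emitted$hits
    family_rows[[gn]] <- emitted$family
    plant_records <- c(plant_records, emitted$plants)
  }

  hits <- do.call(rbind, Filter(Negate(is.null), hit_rows))
  family <- do.call(rbind, Filter(Negate(is.null), family_rows))
  rownames(hits) <- NULL
  rownames(family) <- NULL

  write_domain_hits(hits, file.path(outdir, "hits.tsv"))
  write_taxonomy(taxonomy, file.path(outdir, "taxonomy.tsv"))
  write_family(family, file.path(outdir, "family.tsv"))

  # --- manifest --------------------------------------------------------
  for (id in names(templates_meta)) {
    templates_meta[[id]]$species <-
      taxonomy$species[match(templates_meta[[id]]$genomes,
                             taxonomy$genome_id)]
    templates_meta[[id]]$n_species <-
      length(unique(templates_meta[[id]]$species))
  }
  exact_sigs <- unique(unlist(lapply(plant_records, `[[`,
                                     "exact_signatures")))
  gapped_sigs <- unique(unlist(lapply(plant_records, `[[`,
                                      "gapped_signatures")))
  paralogs <- Filter(function(p) p$kind == "paralog_cluster",
                     plant_records)
  # true per-phylum homolog counts from the emitted family table
  fam_genome <- sub("_P[0-9]+$", "", family$protein_accession)
  fam_phylum <- taxonomy$phylum[match(fam_genome, taxonomy$genome_id)]
  fc <- stats::aggregate(
    list(count = family$protein_accession),
    by = list(family = family$query_family, phylum = fam_phylum),
    FUN = length
  )
  fc <- fc[order_c(fc$family, fc$phylum), , drop = FALSE]
  rownames(fc) <- NULL

  manifest <- structure(list(
    seed = cfg$seed,
    window = cfg$window,
    n_genomes = length(genomes),
    insertion_rate = cfg$insertion_rate,
    loss_rate = cfg$loss_rate,
    genomes = genomes,
    templates = templates_meta,
    plants = plant_records,
    paralogs = lapply(paralogs, function(p) {
      list(genome_id = p$genome_id, accessions = p$accessions,
           size = length(p$accessions))
    }),
    expected_signatures = list(exact = sort_c(exact_sigs),
                               gapped = sort_c(gapped_sigs)),
    family_counts = fc,
    files = c(paste0("genomes/", basename(files)),
              "hits.tsv", "taxonomy.tsv", "family.tsv")
  ), class = "synth_manifest")

  jsonlite::write_json(
    manifest_to_json(manifest),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

#' @export
print.synth_manifest <- function(x, ...) {
  cat("<synth_manifest> seed ", x$seed, ": ", x$n_genomes, " genomes, ",
      length(x$templates), " templates, ", length(x$plants),
      " planted instances (", length(x$paralogs),
      " paralog clusters)\n", sep = "")
  invisible(x)
}

manifest_to_json <- function(manifest) {
  out <- unclass(manifest)
  out$family_counts <- out$family_counts  # data.frame -> array of objects
  out
}

# Assemble one genome: splice plants into the background gene run,
# assign accessions/coordinates, write GFF3, and report hit/family rows
# plus per-plant ground truth.
emit_genome <- function(genome_id, plants, cfg, outdir) {
  n_bg <- cfg$genes_per_genome
  k <- length(plants)
  positions <- integer(0)
  if (k > 0L) {
    min_sep <- cfg$window +
      max(vapply(plants, function(p) length(p$genes), integer(1))) + 1L
    slots <- seq(cfg$window + 1L, n_bg - cfg$window)
    candidates <- slots[sample.int(length(slots))]
    for (cand in candidates) {
      if (all(abs(cand - positions) >= min_sep)) {
        positions <- c(positions, cand)
        if (length(positions) == k) break
      }
    }
    if (length(positions) < k) {
      stop("infeasible config: cannot place ", k,
           " plants in genome ", genome_id)
    }
    positions <- sort(positions)
  }

  # final gene order: background genes with plants spliced in after
  # their background position
  strands <- sample(c(1L, -1L), n_bg, replace = TRUE)
  order_labels <- vector("list", 0L)
  order_strand <- integer(0)
  order_family <- character(0)
  plant_of_gene <- integer(0)   # 0 = background, else plant index
  prev <- 0L
  for (i in seq_along(positions)) {
    span <- seq_len(positions[i] - prev) + prev
    order_labels <- c(order_labels,
                      replicate(length(span), character(0),
                                simplify = FALSE))
    order_strand <- c(order_strand, strands[span])
    order_family <- c(order_family, rep(NA_character_, length(span)))
    plant_of_gene <- c(plant_of_gene, rep(0L, length(span)))
    for (g in plants[[i]]$genes) {
      order_labels <- c(order_labels, list(g$labels))
      order_strand <- c(order_strand, g$strand)
      order_family <- c(order_family, g$family)
      plant_of_gene <- c(plant_of_gene, i)
    }
    prev <- positions[i]
  }
  if (prev < n_bg) {
    span <- seq_len(n_bg - prev) + prev
    order_labels <- c(order_labels,
                      replicate(length(span), character(0),
                                simplify = FALSE))
    order_strand <- c(order_strand, strands[span])
    order_family <- c(order_family, rep(NA_character_, length(span)))
    plant_of_gene <- c(plant_of_gene, rep(0L, length(span)))
  }

  n <- length(order_strand)
  acc <- sprintf("%s_P%05d", genome_id, seq_len(n))
  gene_len <- sample(100:1000, n, replace = TRUE) * 3L
  gap <- sample(50:200, n, replace = TRUE)
  start <- cumsum(c(0L, (gene_len + gap)[-n]))
  genes <- data.frame(
    genome_id = genome_id, replicon_id = "chr",
    gene_ordinal = seq_len(n) - 1L,
    start = start, end = start + gene_len,
    strand = order_strand, protein_accession = acc,
    stringsAsFactors = FALSE
  )
  gff_path <- file.path(outdir, "genomes", paste0(genome_id, ".gff3"))
  write_gff(genes, gff_path)

  hits <- synth_hits(acc, order_labels)
  fam_keep <- !is.na(order_family)
  family <- if (any(fam_keep)) {
    data.frame(protein_accession = acc[fam_keep],
               query_family = order_family[fam_keep],
               stringsAsFactors = FALSE)
  } else NULL

  plant_records <- list()
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    idx <- which(plant_of_gene == i)
    anchor_local <- which(!vapply(p$genes, function(g) is.na(g$family),
                                  logical(1)))
    plant_records[[i]] <- list(
      kind = p$kind, id = p$id, genome_id = genome_id,
      accessions = acc[idx],
      anchors = acc[idx][anchor_local],
      anchor_families = vapply(p$genes[anchor_local], `[[`, character(1),
                               "family"),
      exact_signatures = vapply(anchor_local, function(a) {
        plant_signature(p$genes, a, gapped = FALSE)
      }, character(1)),
      gapped_signatures = vapply(anchor_local, function(a) {
        plant_signature(p$genes, a, gapped = TRUE)
      }, character(1)),
      inserted = p$inserted, lost = p$lost
    )
  }
  list(file = gff_path, hits = hits, family = family,
       plants = plant_records)
}

# Domain/feature hit rows for annotated genes: consecutive
# non-overlapping aa intervals ordered N->C, scores uniform 20-100 bits.
synth_hits <- function(acc, order_labels) {
  rows <- list()
  for (i in seq_along(order_labels)) {
    labels <- order_labels[[i]]
    if (length(labels) == 0L) next
    pos <- sample(0:30, 1L)
    for (lab in labels) {
      len <- if (lab == "TM") sample(18:24, 1L) else
        if (lab == "SIG") sample(20:30, 1L) else sample(80:250, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_accession = acc[i], label = lab,
        start = pos, end = pos + len,
        score = round(stats::runif(1L, 20, 100), 1),
        stringsAsFactors = FALSE
      )
      pos <- pos + len + sample(5:20, 1L)
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Verify recovery of planted structure from pipeline outputs
#'
#' Compares conserved-context clusters against the ground-truth
#' manifest. A template is recovered in a mode when every planted
#' anchor sits in a conserved cluster whose signature equals that
#' instance's expected signature. A conserved cluster is spurious when
#' its signature is not among the manifest's expected signatures.
#'
#' @param manifest A `synth_manifest` (or path to `manifest.json`).
#' @param clusters_exact,clusters_gapped Cluster tables from
#'   [cluster_contexts()] (either may be `NULL`).
#' @return A list of class `recovery_report`: `recall` (named numeric,
#'   per supplied mode), `spurious` (named integer), and `per_template`
#'   (data.frame of per-template status per mode).
#' @export
verify_recovery <- function(manifest, clusters_exact = NULL,
                            clusters_gapped = NULL) {
  manifest <- as_synth_manifest(manifest)
  if (is.null(clusters_exact) && is.null(clusters_gapped)) {
    stop("no pipeline outputs supplied: need at least one cluster table")
  }
  modes <- list(exact = clusters_exact, gapped = clusters_gapped)
  modes <- Filter(Negate(is.null), modes)

  recall <- numeric(0)
  spurious <- integer(0)
  rows <- list()
  for (mode in names(modes)) {
    clusters <- modes[[mode]]
    conserved <- clusters[clusters$conserved_flag, , drop = FALSE]
    sig_field <- paste0(mode, "_signatures")

    anchor_recovered <- function(anchor, sig) {
      hit <- which(conserved$signature == sig)
      length(hit) > 0L &&
        any(vapply(hit, function(h) {
          anchor %in% conserved$anchors[[h]]
        }, logical(1)))
    }

    tpl_ids <- names(manifest$templates)
    status <- logical(length(tpl_ids))
    names(status) <- tpl_ids
    for (tid in tpl_ids) {
      plants <- Filter(function(p) p$kind == "template" && p$id == tid,
                       manifest$plants)
      ok <- TRUE
      for (p in plants) {
        for (j in seq_along(p$anchors)) {
          if (!anchor_recovered(p$anchors[[j]], p[[sig_field]][[j]])) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      status[tid] <- ok
    }
    recall[mode] <- if (length(status) > 0L) mean(status) else NA_real_
    expected <- manifest$expected_signatures[[mode]]
    spurious[mode] <- sum(!conserved$signature %in% expected)
    rows[[mode]] <- data.frame(
      template = tpl_ids, mode = mode, recovered = unname(status),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    recall = recall,
    spurious = spurious,
    per_template = do.call(rbind, rows)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  for (mode in names(x$recall)) {
    cat(sprintf("  %s: recall %.3f, spurious conserved clusters %d\n",
                mode, x$recall[[mode]], x$spurious[[mode]]))
  }
  invisible(x)
}

as_synth_manifest <- function(manifest) {
  if (inherits(manifest, "synth_manifest")) return(manifest)
  if (is.character(manifest) && length(manifest) == 1L) {
    raw <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
    raw$plants <- lapply(raw$plants, function(p) {
      for (f in c("accessions", "anchors", "anchor_families",
                  "exact_signatures", "gapped_signatures")) {
        p[[f]] <- as.character(unlist(p[[f]]))
      }
      p
    })
    raw$expected_signatures <- lapply(raw$expected_signatures,
                                      function(s) as.character(unlist(s)))
    names(raw$templates) <- vapply(raw$templates, function(t)
      as.character(t$id), character(1))
    return(structure(raw, class = "synth_manifest"))
  }
  stop("manifest must be a synth_manifest or a path to manifest.json")
}
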
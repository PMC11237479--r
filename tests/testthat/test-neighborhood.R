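# Neighborhood contexts: window extraction, canonical orientation with
# strand-change markers, reversal invariance, clustering and adjacent
# paralogs.

psp_operon_fixture <- function() {
  # clgR -> pspA -> pspM -> pspN, all on the forward strand
  genes <- make_genes(c("WP_CLGR", "WP_PSPA", "WP_PSPM", "WP_PSPN"))
  sigs <- c(WP_CLGR = "ClgR", WP_PSPA = "PspA", WP_PSPM = "PspM",
            WP_PSPN = "PspN_N+DUF3046")
  list(genes = genes, sigs = sigs)
}

test_that("a same-strand operon context has no strand-change markers", {
  fx <- psp_operon_fixture()
  ctx <- extract_context("WP_PSPA", fx$genes, window = 7L,
                         signatures = fx$sigs)
  expect_equal(ctx$members$label,
               c("ClgR", "PspA", "PspM", "PspN_N+DUF3046"))
  expect_equal(ctx$signature, "ClgR [PspA] PspM PspN_N+DUF3046")
  expect_false(grepl("||", ctx$signature, fixed = TRUE))
  expect_true(ctx$truncated_left && ctx$truncated_right)
})

test_that("a divergent regulator is marked with || in canonical order", {
  # pspF on the opposite strand upstream of pspABC, anchored on PspA
  genes <- make_genes(c("WP_F", "WP_A", "WP_B", "WP_C"),
                      strands = c(-1L, 1L, 1L, 1L))
  sigs <- c(WP_F = "PspF", WP_A = "PspA", WP_B = "PspB", WP_C = "PspC")
  ctx <- extract_context("WP_A", genes, window = 7L, signatures = sigs)
  expect_equal(ctx$signature, "PspF || [PspA] PspB PspC")
})

test_that("window truncation and size behave at replicon limits", {
  lone <- make_genes("WP_SOLO")
  ctx <- extract_context("WP_SOLO", lone, window = 7L)
  expect_equal(nrow(ctx$members), 1L)
  expect_true(ctx$truncated_left && ctx$truncated_right)

  genes <- make_genes(sprintf("WP_%02d", 1:30))
  ctx <- extract_context("WP_16", genes, window = 7L)  # ordinal 15
  expect_equal(nrow(ctx$members), 15L)
  expect_false(ctx$truncated_left || ctx$truncated_right)
})

test_that("unmapped member proteins are labelled UNANNOTATED", {
  genes <- make_genes(c("WP_1", "WP_2"))
  ctx <- extract_context("WP_1", genes, window = 7L,
                         signatures = c(WP_1 = "PspA"))
  expect_equal(ctx$members$label, c("PspA", "UNANNOTATED"))
})

test_that("an anchor absent from the replicon is a per-anchor error", {
  genes <- make_genes(c("WP_1", "WP_2"))
  expect_error(extract_context("WP_MISSING", genes), "matches 0")
})

test_that("canonical signatures are invariant under replicon reversal", {
  set.seed(501)
  for (r in 1:25) {
    fx <- random_replicon(sample(6:15, 1), genome = sprintf("G%02d", r))
    rev_genes <- reverse_replicon(fx$genes)
    for (acc in fx$genes$protein_accession) {
      orig <- extract_context(acc, fx$genes, window = 7L,
                              signatures = fx$signatures)
      mirr <- extract_context(acc, rev_genes, window = 7L,
                              signatures = fx$signatures)
      expect_identical(mirr$signature, orig$signature)
      expect_identical(mirr$truncated_left, orig$truncated_left)
    }
  }
})

# Six species carrying the same operon; two of them with one
# uncharacterized gene inserted inside the operon.
planted_cluster_fixture <- function(n_species = 6L, n_inserted = 2L) {
  contexts <- list()
  taxonomy <- tiny_taxonomy(sprintf("G%d", seq_len(n_species)))
  for (i in seq_len(n_species)) {
    gn <- sprintf("G%d", i)
    accs <- sprintf("%s_P%d", gn, 1:3)
    sigs <- stats::setNames(c("OpA", "OpB", "OpC"), accs)
    if (i <= n_inserted) {
      accs <- append(accs, sprintf("%s_INS", gn), after = 1L)
    }
    # unique unannotated background flanking the operon
    accs <- c(sprintf("%s_BG1", gn), accs, sprintf("%s_BG2", gn))
    genes <- make_genes(accs, genome = gn)
    contexts[[i]] <- extract_context(sigs_anchor(accs), genes,
                                     window = 7L, signatures = sigs)
  }
  list(contexts = contexts, taxonomy = taxonomy)
}

sigs_anchor <- function(accs) accs[grepl("_P1$", accs)]

test_that("insertions split exact clusters but not gapped clusters", {
  fx <- planted_cluster_fixture()
  exact <- cluster_contexts(fx$contexts, "exact", min_species = 5L,
                            taxonomy = fx$taxonomy)
  gapped <- cluster_contexts(fx$contexts, "gapped", min_species = 5L,
                             taxonomy = fx$taxonomy)
  expect_equal(nrow(exact), 2L)
  expect_equal(sort(exact$n_members), c(2L, 4L))
  expect_equal(nrow(gapped), 1L)
  expect_equal(gapped$n_members, 6L)
  expect_equal(gapped$n_species, 6L)
  expect_true(gapped$conserved_flag)
  expect_false(any(exact$conserved_flag))
  expect_equal(gapped$signature, "[OpA] OpB OpC")
})

test_that("species thresholds flag conservation at exactly min_species", {
  fx5 <- planted_cluster_fixture(n_species = 5L, n_inserted = 0L)
  cl5 <- cluster_contexts(fx5$contexts, "exact", min_species = 5L,
                          taxonomy = fx5$taxonomy)
  expect_true(cl5$conserved_flag)

  fx4 <- planted_cluster_fixture(n_species = 4L, n_inserted = 0L)
  cl4 <- cluster_contexts(fx4$contexts, "exact", min_species = 5L,
                          taxonomy = fx4$taxonomy)
  expect_false(cl4$conserved_flag)
})

test_that("clusters partition contexts and exact refines gapped", {
  set.seed(502)
  contexts <- list()
  for (g in 1:8) {
    fx <- random_replicon(10L, genome = sprintf("G%02d", g),
                          seed_labels = c("OpA", "OpB", "OpC"))
    anchors <- sample(fx$genes$protein_accession, 3L)
    contexts <- c(contexts, extract_contexts(fx$genes, anchors,
                                             fx$signatures, window = 3L))
  }
  tax <- tiny_taxonomy(sprintf("G%02d", 1:8))
  exact <- cluster_contexts(contexts, "exact", taxonomy = tax)
  gapped <- cluster_contexts(contexts, "gapped", taxonomy = tax)

  expect_equal(sum(exact$n_members), length(contexts))
  expect_equal(sum(gapped$n_members), length(contexts))

  # every exact cluster's anchor set lies inside one gapped cluster
  for (i in seq_len(nrow(exact))) {
    containing <- vapply(gapped$anchors, function(a) {
      all(exact$anchors[[i]] %in% a)
    }, logical(1))
    expect_equal(sum(containing), 1L)
  }

  # group-by oracle agreement
  sigs <- vapply(contexts, genecontext:::cluster_signature, character(1),
                 mode = "exact")
  genomes <- vapply(contexts, `[[`, character(1), "genome_id")
  oracle <- oracle_group_counts(sigs, genomes)
  for (i in seq_len(nrow(exact))) {
    expect_equal(exact$n_members[i],
                 unname(oracle[[exact$signature[i]]]["n"]))
  }
})

test_that("adjacent paralog dyads and triads are detected", {
  genes <- make_genes(sprintf("WP_%02d", 1:20))
  fam <- data.frame(
    protein_accession = c("WP_13", "WP_14", "WP_03"),
    query_family = "PspA", stringsAsFactors = FALSE
  )
  runs <- detect_adjacent_paralogs(genes, fam)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$size, 2L)
  expect_equal(runs$accessions[[1]], c("WP_13", "WP_14"))

  # single-copy family: no clusters
  fam1 <- data.frame(protein_accession = "WP_05",
                     query_family = "Snf7", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_adjacent_paralogs(genes, fam1)), 0L)
})

test_that("paralog runs equal the connected-component oracle", {
  set.seed(503)
  for (r in 1:15) {
    n <- 30L
    genes <- make_genes(sprintf("WP_%02d", 1:n))
    members <- sort(sample(genes$protein_accession, sample(4:10, 1)))
    fam <- data.frame(protein_accession = members,
                      query_family = "PspA", stringsAsFactors = FALSE)
    gap <- sample(1:2, 1)
    runs <- detect_adjacent_paralogs(genes, fam, max_gap_genes = gap)
    ords <- genes$gene_ordinal[match(members, genes$protein_accession)]
    oracle <- oracle_paralog_runs(ords, max_gap = gap)
    got <- lapply(runs$ordinals, sort)
    expect_equal(got[order(vapply(got, min, numeric(1)))],
                 oracle[order(vapply(oracle, min, numeric(1)))])
  }
})

test_that("overlapping windows of nearby anchors are reported post hoc", {
  genes <- make_genes(sprintf("WP_%02d", 1:10))
  ctxs <- extract_contexts(genes, c("WP_03", "WP_05"), window = 3L)
  ov <- overlapping_contexts(ctxs)
  expect_equal(nrow(ov), 1L)
  expect_true(ov$n_shared_genes > 0L)
})
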
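# Proximity networks: frequency-based retention, pair counting within
# proteins and neighborhoods, and the structural invariants.

two_class_architectures <- function(n_common = 97L, n_rare = 3L) {
  hits <- list()
  for (i in seq_len(n_common)) {
    hits[[length(hits) + 1L]] <-
      make_hit(sprintf("C%03d", i), "PspA", 0L, 200L, 50)
  }
  for (i in seq_len(n_rare)) {
    acc <- sprintf("R%03d", i)
    hits[[length(hits) + 1L]] <- rbind(
      make_hit(acc, "PspA", 0L, 200L, 50),
      make_hit(acc, "PspAA", 210L, 300L, 40)
    )
  }
  build_architectures(do.call(rbind, hits))
}

test_that("retention keeps whole signature classes across the boundary", {
  arch <- two_class_architectures()
  kept <- retain_top_fraction(arch, fraction = 0.97)
  expect_equal(length(kept), 97L)
  expect_true(all(grepl("^C", kept)))

  expect_setequal(retain_top_fraction(arch, fraction = 1.0),
                  arch$protein_accession)
  expect_equal(retain_top_fraction(arch[0, , drop = FALSE], 0.97),
               character(0))
})

test_that("a rare fused partner drops out of the thresholded network", {
  arch <- two_class_architectures()
  net97 <- build_network(arch, retained = retain_top_fraction(arch, 0.97))
  net100 <- build_network(arch, retained = retain_top_fraction(arch, 1.0))
  edge_labels <- function(g) {
    if (igraph::ecount(g) == 0L) return(character(0))
    e <- igraph::as_edgelist(g)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  expect_true("PspA PspAA" %in% edge_labels(net100))
  expect_false("PspA PspAA" %in% edge_labels(net97))
})

test_that("lowering the retention fraction never adds nodes or edges", {
  arch <- two_class_architectures(n_common = 20L, n_rare = 6L)
  nets <- lapply(c(1.0, 0.97, 0.5), function(f) {
    build_network(arch, retained = retain_top_fraction(arch, f))
  })
  node_names <- lapply(nets, function(g) igraph::V(g)$name)
  edge_keys <- lapply(nets, function(g) {
    if (igraph::ecount(g) == 0L) return(character(0))
    e <- igraph::as_edgelist(g)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  })
  expect_true(all(node_names[[2]] %in% node_names[[1]]))
  expect_true(all(node_names[[3]] %in% node_names[[2]]))
  expect_true(all(edge_keys[[2]] %in% edge_keys[[1]]))
  expect_true(all(edge_keys[[3]] %in% edge_keys[[2]]))
})

test_that("repeats weight nodes once per protein and never self-loop", {
  arch <- build_architectures(rbind(
    make_hit("WP_1", "PspA", 0L, 200L, 50),
    make_hit("WP_1", "PspA", 210L, 400L, 45)
  ))
  net <- build_network(arch)
  expect_equal(igraph::vcount(net), 1L)
  expect_equal(igraph::V(net)$weight, 1L)
  expect_equal(igraph::V(net)$occurrences, 2L)
  expect_equal(igraph::ecount(net), 0L)

  fused <- build_architectures(rbind(
    make_hit("WP_2", "PspA", 0L, 200L, 50),
    make_hit("WP_2", "NlpC_P60", 210L, 330L, 40)
  ))
  net2 <- build_network(fused)
  expect_equal(igraph::ecount(net2), 1L)
  expect_equal(igraph::E(net2)$weight, 1L)
})

test_that("within-protein weights equal the brute-force pair oracle", {
  set.seed(601)
  pool <- c("PspA", "PspC", "Toastrack", "TM", "SIG", "HAAS", "SHOCT")
  for (r in 1:5) {
    n <- sample(20:50, 1)
    rows <- list()
    for (i in seq_len(n)) {
      k <- sample(1:4, 1)
      labels <- sample(pool, k, replace = TRUE)
      start <- cumsum(c(0L, rep(150L, k - 1L)))
      rows[[i]] <- data.frame(
        protein_accession = sprintf("P%03d", i), label = labels,
        start = start, end = start + 100L, score = runif(k, 20, 90),
        stringsAsFactors = FALSE
      )
    }
    arch <- build_architectures(do.call(rbind, rows),
                                overlap_policy = "keep_all")
    net <- build_network(arch)
    oracle <- oracle_protein_network(arch$label_list)

    expect_setequal(igraph::V(net)$name, names(oracle$nodes))
    expect_equal(igraph::V(net)$weight[match(names(oracle$nodes),
                                             igraph::V(net)$name)],
                 unname(oracle$nodes))
    expect_equal(igraph::ecount(net), length(oracle$edges))
    if (igraph::ecount(net) > 0L) {
      e <- igraph::as_edgelist(net)
      keys <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|")
      expect_equal(igraph::E(net)$weight[match(names(oracle$edges), keys)],
                   unname(oracle$edges))
    }
    # structural invariants
    w <- stats::setNames(igraph::V(net)$weight, igraph::V(net)$name)
    if (igraph::ecount(net) > 0L) {
      e <- igraph::as_edgelist(net)
      expect_true(all(igraph::E(net)$weight <= pmin(w[e[, 1]], w[e[, 2]])))
    }
  }
})

test_that("neighborhood edges connect labels across genes of a context", {
  genes <- make_genes(c("WP_A", "WP_B", "WP_C"))
  hits <- rbind(
    make_hit("WP_A", "PspA", 0L, 200L, 50),
    make_hit("WP_B", "PspM", 0L, 60L, 30),
    make_hit("WP_B", "DUF3046", 70L, 130L, 30)
  )  # WP_C stays unannotated
  arch <- build_architectures(hits, proteins = c("WP_A", "WP_B", "WP_C"))
  ctxs <- extract_contexts(genes, "WP_A", signature_lookup(arch))
  net <- build_network(arch, contexts = ctxs,
                       provenance = "within_neighborhood")

  expect_setequal(igraph::V(net)$name, c("PspA", "PspM", "DUF3046"))
  e <- igraph::as_edgelist(net)
  keys <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  # PspM-DUF3046 co-occur on one gene, not across genes: no edge
  expect_setequal(keys, c("PspA PspM", "DUF3046 PspA"))

  oracle <- oracle_neighborhood_network(list(list(
    "PspA", c("PspM", "DUF3046")
  )))
  expect_equal(sort(igraph::E(net)$weight), sort(unname(oracle$edges)))
})

test_that("network construction is invariant to input order", {
  arch <- two_class_architectures(n_common = 10L, n_rare = 5L)
  net1 <- build_network(arch)
  net2 <- build_network(arch[rev(seq_len(nrow(arch))), , drop = FALSE])
  expect_equal(igraph::V(net1)$name, igraph::V(net2)$name)
  expect_equal(igraph::V(net1)$weight, igraph::V(net2)$weight)
  expect_equal(igraph::as_edgelist(net1), igraph::as_edgelist(net2))
})

test_that("merging provenances sums weights and records both sources", {
  arch <- build_architectures(rbind(
    make_hit("WP_1", "PspA", 0L, 200L, 50),
    make_hit("WP_1", "NlpC_P60", 210L, 330L, 40),
    make_hit("WP_2", "PspA", 0L, 200L, 50)
  ))
  genes <- make_genes(c("WP_1", "WP_2"))
  ctxs <- extract_contexts(genes, "WP_2", signature_lookup(arch))
  nets <- list(
    build_network(arch),
    build_network(arch, contexts = ctxs,
                  provenance = "within_neighborhood")
  )
  merged <- merge_networks(nets)
  expect_true("PspA" %in% igraph::V(merged)$name)
  e <- igraph::as_edgelist(merged)
  keys <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  i <- which(keys == "NlpC_P60 PspA")
  expect_equal(igraph::E(merged)$weight[i], 2L)
  expect_match(igraph::E(merged)$provenance[i], "within_protein")
  expect_match(igraph::E(merged)$provenance[i], "within_neighborhood")
})
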
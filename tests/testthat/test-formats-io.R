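# I/O layer: coordinate conventions, gene ordering, round trips,
# malformed-row handling, result writing and the run manifest.

test_that("GFF3 coordinates convert to 0-based half-open and back", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t100\t400\t.\t-\t0\tID=cds-a;protein_id=WP_A",
    "chr\tsrc\tCDS\t900\t1400\t.\t+\t0\tID=cds-b;protein_id=WP_B"
  ), gff)
  genes <- read_gff(gff, genome_id = "G1")
  expect_equal(genes$start, c(99L, 899L))
  expect_equal(genes$end, c(400L, 1400L))
  expect_equal(genes$strand, c(-1L, 1L))
  expect_equal(genes$gene_ordinal, c(0L, 1L))
  expect_equal(genes$protein_accession, c("WP_A", "WP_B"))

  out <- tempfile(fileext = ".gff3")
  write_gff(genes, out)
  lines <- readLines(out)
  expect_match(lines[2], "\t100\t400\t\\.\t-\t")
})

test_that("gene order follows start coordinate, not file order", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t5000\t5900\t.\t+\t0\tID=c;protein_id=WP_LATE",
    "chr\tsrc\tCDS\t100\t900\t.\t+\t0\tID=a;protein_id=WP_EARLY",
    "p1\tsrc\tCDS\t200\t800\t.\t+\t0\tID=b;protein_id=WP_PLASMID"
  ), gff)
  genes <- read_gff(gff, genome_id = "G1")
  chr <- genes[genes$replicon_id == "chr", ]
  expect_equal(chr$protein_accession[order(chr$gene_ordinal)],
               c("WP_EARLY", "WP_LATE"))
  # ordinals restart per replicon
  expect_equal(genes$gene_ordinal[genes$replicon_id == "p1"], 0L)
})

test_that("missing strand or accession raises a record-level error", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t100\t900\t.\t.\t0\tID=cds-a;protein_id=WP_A"
  ), gff)
  expect_error(read_gff(gff), "missing strand")
})

test_that("writer/reader round trips are the identity on generated files", {
  set.seed(301)
  genes <- make_genes(sprintf("WP_%02d", 1:9),
                      strands = sample(c(1L, -1L), 9, TRUE))
  gff <- tempfile(fileext = ".gff3")
  write_gff(genes, gff)
  back <- read_gff(gff, genome_id = "G1")
  expect_equal(back, genes)

  hits <- rbind(make_hit("WP_01", "PspA", 0L, 210L, 80.5),
                make_hit("WP_02", "TM", 5L, 27L, 12.0))
  hp <- tempfile(fileext = ".tsv")
  write_domain_hits(hits, hp)
  expect_equal(read_domain_hits(hp), hits)

  fam <- data.frame(protein_accession = c("WP_01", "WP_01", "WP_02"),
                    query_family = c("PspA", "Vipp1", "PspC"),
                    stringsAsFactors = FALSE)
  fp <- tempfile(fileext = ".tsv")
  write_family(fam, fp)
  expect_equal(read_family(fp), fam)

  tax <- tiny_taxonomy(c("G1", "G2"))
  tp <- tempfile(fileext = ".tsv")
  write_taxonomy(tax, tp)
  expect_equal(read_taxonomy(tp), tax)
})

test_that("domain-hit TSV dialect is 1-based inclusive on disk", {
  hp <- tempfile(fileext = ".tsv")
  writeLines(c("protein_accession\tlabel\tstart\tend\tscore",
               "WP_1\tPspA\t1\t220\t55.0"), hp)
  hits <- read_domain_hits(hp)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 220L)
})

test_that("malformed hit rows are rejected and counted", {
  hp <- tempfile(fileext = ".tsv")
  writeLines(c("protein_accession\tlabel\tstart\tend\tscore",
               "WP_1\tPspA\t1\t220\t55.0",
               "WP_2\t\t1\t90\t10.0",          # empty label
               "WP_3\tPspC\t90\t10\t10.0",     # end < start
               "WP_4\tPspB\tx\t90\t10.0"),     # non-numeric
             hp)
  expect_warning(hits <- read_domain_hits(hp), "3 malformed")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$protein_accession, "WP_1")
})

test_that("write_results emits tables, graphs and a parameter manifest", {
  arch <- build_architectures(make_hit("WP_1", "PspA", 0L, 200L, 50))
  empty_net <- build_network(arch[0, , drop = FALSE])
  outdir <- tempfile("results")
  manifest <- write_results(
    list(architectures = arch,
         networks = list(within_protein = empty_net)),
    outdir, params = unclass(pipeline_config()))

  # empty network -> header-only edge list
  edges <- readLines(file.path(outdir, "network_within_protein.edges.tsv"))
  expect_equal(length(edges), 1L)
  expect_match(edges, "label_a\tlabel_b")

  # manifest records defaults, including the +/-7 window
  js <- jsonlite::fromJSON(file.path(outdir, "manifest.json"))
  expect_equal(js$parameters$window, 7L)
  expect_equal(js$parameters$min_species_context, 5L)
  expect_true("architectures.tsv" %in% js$files)
})

test_that("GML export re-read by igraph preserves the node/edge multiset", {
  arch <- build_architectures(rbind(
    make_hit("WP_1", "PspA", 0L, 200L, 50),
    make_hit("WP_1", "NlpC_P60", 210L, 320L, 40),
    make_hit("WP_2", "PspA", 0L, 200L, 50),
    make_hit("WP_3", "Toastrack", 0L, 150L, 30),
    make_hit("WP_3", "PspA", 160L, 360L, 30)
  ))
  net <- build_network(arch)
  prefix <- tempfile("net")
  write_network(net, prefix)
  back <- igraph::read_graph(paste0(prefix, ".gml"), format = "gml")

  name_attr <- if ("name" %in% igraph::vertex_attr_names(back)) "name"
               else "label"
  back_names <- igraph::vertex_attr(back, name_attr)
  expect_setequal(back_names, igraph::V(net)$name)

  ends_orig <- igraph::as_edgelist(net)
  ends_back <- igraph::as_edgelist(back, names = FALSE)
  ends_back <- cbind(back_names[ends_back[, 1]], back_names[ends_back[, 2]])
  canon <- function(m) sort(paste(pmin(m[, 1], m[, 2]),
                                  pmax(m[, 1], m[, 2])))
  expect_equal(canon(ends_back), canon(ends_orig))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(net)$weight))
})
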
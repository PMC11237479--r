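---
title: "Mining conserved gene neighborhoods and domain architectures with genecontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining conserved gene neighborhoods and domain architectures with genecontext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecontext)
```

## The problem

Bacterial and archaeal genes that work together tend to stay together:
operons and looser syntenic arrangements persist across species far
longer than chance would allow. Surveys of a protein family — here
modeled on membrane-stress machinery of the phage shock protein type,
with query families such as PspA, PspB/PspC, Toastrack and
LiaI-LiaF-TM — therefore read function out of three complementary
signals: the *domain architecture* of each homolog, the *genomic
context* (the genes flanking each homolog and their transcription
directions), and the *phyletic spread* of the family across lineages.
genecontext implements the full computational path from per-genome
annotation tables to conserved architectures, conserved contexts,
domain co-occurrence networks and lineage rollups, together with a
synthetic-genome generator that makes every stage testable against
planted ground truth.

Homology search itself is out of scope: the package consumes a family
membership table (protein → query family) produced upstream by
whatever search strategy the user trusts, and domain/feature calls
(including transmembrane `TM` and signal-peptide `SIG` rows) produced
by upstream scanners.

## Domain architectures

Each protein's architecture is the N→C sequence of its hit labels.
Three decisions matter:

* **Overlap resolution.** Domain scanners frequently emit overlapping
  candidate hits. Two non-feature hits *conflict* when their overlap
  exceeds 50% of the shorter hit; conflicts are resolved greedily with
  precedence higher score → longer hit → smaller start. This is
  standard domain-annotation practice and fully deterministic; a
  `keep_all` policy is available when the caller has already resolved
  overlaps. Feature hits (`TM`, `SIG`) are exempt: they are short,
  they legitimately overlap domain boundaries, and they are
  interleaved at their positions.
* **Repeat collapsing.** Maximal tandem runs of one label collapse to
  `label×k` (so a protein with two copies of the PspA domain reads
  `PspA×2`). Collapsing is idempotent and applied to the full
  architecture and to a features-excluded variant; both are emitted
  because a census may reasonably count either form.
* **Fusions.** An architecture with ≥ 2 distinct non-feature labels is
  a fusion. Features never make a protein a fusion. Proteins with no
  hits receive the reserved label `UNANNOTATED`, which the synthetic
  generator never uses as a domain name.

The architecture census groups proteins by collapsed signature and
flags signatures found in at least `min_species_arch = 2` species as
conserved — the conventional minimum for calling an architecture more
than a single-genome artifact.

## Genomic contexts and canonicalization

The context of an anchor is the window of `window = 7` genes on each
side along its replicon, by gene ordinal (gene order is defined by
ascending start coordinate, never by file order). Windows never cross
replicon boundaries; truncation is flagged and truncated contexts
still cluster under their shorter signatures. Gene-count windows are
used rather than intergenic-distance operon prediction because the
survey convention is a fixed ±7 flank and curated operon calls are a
separate concern.

The canonical signature reads members 5′→3′ along the anchor's coding
strand: when the anchor lies on the minus strand the member order is
reversed, so the signature is independent of which strand the genome
annotation happened to call "plus". A `||` token marks each change of
transcription direction between adjacent members and the anchor is
bracketed:

```
NtrC_AAA+Fis_HTH || [PspA] PspB PspC
```

Reversal invariance — reversing gene order, flipping every strand and
mirroring coordinates leaves every anchor's signature unchanged — is
asserted as a property test over entire synthetic genomes and is
recomputed by the acceptance script (it holds for 100% of anchors).

### Cluster signatures: trimming and the gapped mode

Clustering compares context signatures after two reductions:

* **Flank trimming (both modes).** Leading and trailing `UNANNOTATED`
  members are dropped before comparison, and strand-change markers are
  recomputed from the remaining members. Unannotated flanking genes
  are, by construction of the problem, proteins about which nothing is
  known; keeping them would make two biologically identical operons
  compare unequal merely because their distances to the nearest
  annotated bystander differ. Trimming makes the exact-mode signature
  of a clean planted operon equal the operon's own signature — the
  identity the recovery benchmark relies on.
* **Gapped mode.** All internal `UNANNOTATED` members are deleted as
  well (the anchor is always kept). A context whose operon acquired an
  uncharacterized insertion then still co-clusters with its clean
  relatives; exact mode keeps the insertion and splits the cluster.
  Gapped mode deliberately does *not* tolerate loss of annotated
  members — absences of real domains are reported by comparing
  clusters, not merged away silently.

A cluster is conserved at `min_species_context = 5` species, a
stricter bar than architectures because context signatures are much
longer strings and chance agreement across five species is already
negligible. Contexts of distinct anchors inside one operon are kept as
distinct contexts (no deduplication); `overlapping_contexts()` reports
window overlaps post hoc.

## Paralog clusters

Within each family and replicon, maximal runs of member genes whose
consecutive ordinals differ by at most `max_gap_genes = 1` (strict
adjacency) are reported as dyads, triads and larger runs, with member
strands and a flag for fusion members — the pattern tandem
duplications leave in a genome.

## Proximity networks

Node and edge weights are **presence-based**: a label pair counts once
per protein (within-protein provenance) or once per context when the
two labels sit on two different member genes (within-neighborhood
provenance). Repeat multiplicity inflates a node's `occurrences`
attribute but never its pair counts, and never creates self-loops.
Before counting, the top `retention_fraction = 0.97` of homologs per
family is kept, sorting architecture classes by decreasing frequency
and keeping or dropping each class atomically (the class that crosses
the boundary is kept). Retention is applied per query family and the
retained sets unioned, so a family with few homologs is not swamped by
a large one; a global mode is available by passing `family = NULL`.
Lowering the fraction can only remove nodes and edges — a monotonicity
property asserted in the tests. The two provenances are emitted as
separate graphs and merged only on request, since mixing them changes
what an edge weight means.

## Phyletic spreads and upSet summaries

Counts are tallied at exactly two levels, superkingdom and phylum,
because those are the rings the standard sunburst/heatmap displays
use. Homologs count per protein (paralogs count individually);
`per_genome = TRUE` switches to presence/absence for heatmaps. Per
level, proportions sum to 1 and each superkingdom count equals the sum
of its phyla — both asserted to 1e-9. Raw counts are emitted for the
heatmap; row normalization is left to plotting.

The upSet summary uses **exact-combination (disjoint) semantics**: the
set of distinct neighbor architectures in an anchor's window defines
exactly one combination, so combination counts partition the anchor
set — the property that makes the red histogram of such a plot add up.
Superset-containment semantics would double-count anchors and is
deliberately not offered. Combinations below `upset_min_count = 100`
are suppressed from the displayed view but retained in the table.

## The synthetic-data generator

The generator emulates the statistical structure a real survey faces:

* a balanced taxonomy (2 superkingdoms × 5 phyla × 20 species, one
  genome per species — 200 genomes) with 500 background genes per
  genome;
* ten operon templates, including a divergently transcribed
  regulator || operon layout, a phylum-restricted four-gene operon, a
  six-gene two-component-system operon, a fusion anchor and a
  tandem-repeat anchor, each planted in 6–25 species;
* per-genome paralog dyads/triads (rate 0.15, 30% triads), singleton
  fusion and repeat proteins (rate 0.05 each), and two
  lineage-restricted singleton families (one confined to two phyla,
  one broad but sparse) — chosen as realistic analogues of narrow
  families and promiscuous partners;
* background genes on random strands with globally unique protein
  accessions and **no domain annotation**. Unique accessions are the
  unique-label pool that makes spurious conserved contexts impossible
  by construction; leaving the background unannotated is what lets a
  planted operon's context signature equal the template's signature
  after flank trimming.

Plants are placed uniformly at random with a minimum spacing of
window-plus-template genes, so windows of different plants never
overlap and recovery analysis stays exact. Insertion noise adds
uncharacterized genes to *internal* template slots only, capped so
that no member is pushed outside the anchor's ±7 window — an edge
insertion would be indistinguishable from background, and an uncapped
insertion would make even gapped-mode recovery impossible for long
templates, which would test the generator rather than the method. Loss
noise removes only members marked optional. Protein lengths, hit
coordinates and bit scores (uniform 20–100) are synthesized
deterministically from the seed; one seed regenerates byte-identical
files (the GML writer's timestamp line is pinned for the same reason).

What the generator does **not** emulate: sequence evolution, unequal
genome sizes, operon rearrangements, partial domain decay, and
annotation error in the *planted* genes. Perfect recall on synthetic
data therefore demonstrates the correctness of the bookkeeping — not
that real neighborhoods are this clean; on real data the exact/gapped
gap and the species thresholds do the epistemic work.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 and the hit TSV
  dialect are 1-based inclusive on disk and converted at the boundary
  (a bijection, asserted by round-trip tests).
* All orderings that reach output files use C-collation radix sorting,
  so results do not depend on the session locale.
* Ties in overlap resolution break by smaller start, then label; ties
  in retention break alphabetically within equal frequency.
* Proteins with only feature hits have a domain-only signature of
  `UNANNOTATED` (they carry no domain content) while their full
  signature keeps the features.
* Empty inputs yield empty, correctly-typed tables and graphs; an
  anchor missing from its replicon, an unresolvable genome, or an
  unwritable output directory fail fast with the offending name.

## Benchmark sizes

The test-suite and acceptance benchmarks run the full pipeline at 200
genomes × 500 genes (about 100,000 genes) for recovery and
determinism, 100 genomes for reversal invariance, and ≤ 50-protein /
≤ 15-anchor instances for the brute-force oracle comparisons — sizes
chosen so the complete validation runs in a couple of minutes on one
CPU while still exercising every code path at realistic density.

## Known limitations

* Conservation is counted in species, not in phylogenetically
  independent lineages; a clade of near-identical genomes can satisfy
  the thresholds with one ancestral event.
* Exact-mode clustering requires member-for-member signature equality;
  it does not score partial similarity between neighborhoods, and the
  package intentionally offers no fuzzy merging — curation is the
  user's job.
* The taxonomy is a strict two-level hierarchy; deeper ranks and
  paraphyletic groupings are out of scope.
* Within-neighborhood edge weights depend on the chosen window; they
  are comparable only across runs with the same `window`.
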
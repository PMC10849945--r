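---
title: "Curation and context-based annotation of novel gene families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and context-based annotation of novel gene families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novfams)
```

# The problem

Large catalogues of metagenome-assembled and single-amplified genomes
(MAGs/SAGs) contain millions of protein clusters with no detectable
homology to reference databases. Most of these clusters are noise:
fragments, orphans restricted to a single species, or spurious ORFs.
A small fraction are genuine gene families — conserved across species,
under purifying selection, forming coherent orthologous groups — and
those are the ones worth annotating and tracking ecologically.

`novfams` implements the desk-scale machinery for that workflow:

1. **Curation** — candidacy filters that turn raw cluster tables into a
   set of credible families.
2. **Selection screening** — a pairwise Nei–Gojobori (NG86) dN/dS
   estimator and the `ratio <= 0.5` purifying-selection filter.
3. **Orthology** — midpoint rooting plus species-overlap duplication
   detection, to flag families that are really several orthologous
   groups glued together.
4. **Genomic-context annotation** — the calibrated guilt-by-association
   KEGG pathway predictor built on four window-conservation scores.
5. **Synapomorphy scanning** — clade coverage/specificity screens for
   clade-defining families.
6. **Distribution** — taxonomic breadth (LCA), per-clade density,
   habitat breadth and mobility association.
7. **Biomarker discovery** — stratified (van Elteren) Wilcoxon testing
   of family abundances across case/control cohorts with study blocking.
8. **Synthetic data** — a deterministic generator that plants ground
   truth for every stage, so each claim above is testable end to end.

# Curation filters

A cluster becomes a candidate family when it has at least
`min_complete_genes = 3` members with intact start/stop codons drawn
from at least `min_species = 2` distinct GTDB species. Orphans (single
species) and fragment-dominated clusters are dropped with
machine-readable reason codes.

The *conserved domain* of a family is the longest run of alignment
columns whose per-column non-gap occupancy is at least 80%; families
whose longest run is shorter than 20 residues are discarded. Two
readings of the occupancy rule exist (per column, or aggregated over a
block); we use the per-column reading, which is the standard
block-trimming semantics and yields contiguous regions. Ties between
equally long runs are broken leftmost. The implementation is validated
against an exhaustive all-intervals oracle on random alignments.

Sequence-feature flags aggregate with an at-least-80%-of-members rule
(secreted, transmembrane); small-peptide families are those whose
*longest* member protein is strictly shorter than 50 residues; family
length is the longest member protein. External homology screens are
consumed as hit tables; significance uses strict inequalities
(E-value below the threshold, coverage above 50%), so a hit at exactly
the boundary does not count.

# dN/dS estimation

Full codon-model fits are impractical at desk scale, so selective
pressure is estimated with Nei–Gojobori (1986) counting:

* synonymous site fractions per codon, with mutations to stop codons
  excluded from the denominators (each codon always carries 3 sites);
* observed differences resolved over minimal mutational pathways with
  equal weights, where pathways through stop codons get zero weight
  and — the one deliberate refinement — only pathways with the fewest
  amino-acid changes are retained before averaging;
* Jukes–Cantor correction `d = -3/4 log(1 - 4p/3)`, with `p >= 3/4`
  mapped to `Inf`.

The pathway restriction is the parsimony flavour of the pathway
weighting already discussed by Nei and Gojobori as an alternative to
plain averaging. We adopt it because it makes the estimator *exact* on
purely synonymous histories: under synonymous-only evolution every
observed same-amino-acid codon pair is connected by an all-synonymous
minimal pathway (synonymous single-nucleotide moves keep Leu/Arg codon
islands internally connected), so dN is identically zero rather than
picking up small artefacts from nonsynonymous detours such as
CTT→TTT→TTA. With equal-weight averaging we measured small spurious
dN in roughly two thirds of synonymous-only simulated families; with
the restriction the estimate is 0 exactly, which is also what the
package's validation suite asserts.

A family's ratio is mean pairwise dN over mean pairwise dS, excluding
saturated (non-finite) pairs and gap-containing codons pairwise, with
the conventions `0/0 = 0` and `x/0 = Inf` for `x > 0`. Families with
ratio strictly above 0.5 are discarded; the boundary is kept. The
estimator is checked against an independent pathway-enumeration oracle,
and rank recovery is verified on codon families simulated under
`omega` in {0.1, 0.5, 1.0} (50 replicates each in the validation
scripts).

# Orthology calling

Gene trees are midpoint rooted (the two root-to-farthest-leaf distances
agree to numerical tolerance) and scanned for duplication events with
the species-overlap rule: an internal node is a duplication when the
species sets of any two of its children intersect. Events are dated by
the deepest taxonomic rank shared by all species under the node. A
family is a *basal orthologous group* when no event dates to a basal
rank; "basal" defaults to `{domain}` and can be widened to
`{domain, phylum}` — the choice is exposed because the boundary between
"ancient duplication" and "fused orthologous groups" is a judgement
call. Multifurcations are treated as duplications if any child pair
overlaps.

# The genomic-context predictor

For each family member we take a window of up to three genes on each
side on the same contig. Against a candidate pathway `P` four scores
are computed:

* **synteny conservation** — fraction of members whose window contains
  at least one `P`-annotated gene;
* **functional relatedness** — pooled over members, `P`-annotated
  neighbours over all neighbours (unannotated neighbours count in the
  denominator);
* **strand conservation** — among `P`-annotated neighbours, the
  fraction on the focal member's strand;
* **distance conservation** — among `P`-annotated neighbours, the
  fraction reachable from the focal gene through consecutive
  intergenic gaps of at most 100 nt (overlapping genes always qualify).

Scores use pooled (gene-level) denominators; windows truncate at contig
ends rather than dropping edge members. A member whose contig has no
other genes contributes an empty window.

Thresholds are calibrated per pathway on families of known function:
for each score and each confidence level `c` in {0.5, 0.9}, the
threshold is the empirical `(1 - c)` quantile (lower interpolation) of
the known families' scores — the largest cut that still recovers the
required fraction of known families, evaluated per score. A family is
associated with `P` at level `c` when *all four* scores reach the
level-`c` thresholds; the highest level met is reported. Pathways with
fewer than `n_min = 5` known families are reported as uncalibratable
and never predicted. The two levels mirror the two benchmark recovery
targets the calibration is defined for; the level list is a config
argument so intermediate levels can be added.

Two auxiliary context statistics are provided: the number of window
positions at which a set fraction of members has a resistance-flagged
neighbour (resistance-island detection), and positional synteny — the
mean, over the −1/+1 positions, of the fraction of members whose
neighbour carries the position's modal KO label.

# Synapomorphy scanning

For a family and clade, *coverage* is the fraction of clade genomes
containing at least one member (multi-copy genomes count once) and
*specificity* the fraction of members inside the clade. The strict
catalogue regime requires strictly more than 10 members, coverage
strictly above 0.9 and specificity equal to 1; the broad validation
regime uses 0.7/0.9 with specificity compared inclusively (the
boundary's strictness at the broad level is not fixed by any constraint
we know of; inclusive was chosen and is a parameter). Scans run over
phylum, class and order clades by default, and an unfiltered
coverage/specificity table can be exported.

# Distribution summaries

The taxonomic breadth of a family is the deepest lineage prefix shared
by at least a `support` fraction of members (`support = 1` is the
strict LCA; 0.8 guards against a few misannotated genes dragging
families to basal ranks). Mobility flags fire when the fraction of
members on plasmid/viral-flagged contigs strictly exceeds a cutoff
(0 reproduces "at least one member"; 0.3 is the strict variant).
Habitat breadth counts distinct detection samples and habitats, with an
editable YAML map collapsing raw habitat labels into ten coarse groups
(unmapped labels become "Other"); broad distribution requires strictly
more than 10 samples over at least 2 habitats. The breadth–mobility
association reports a family-level Spearman correlation plus a binned
summary over tertiles of detection counts (bin edges are a config
choice; tertiles are the default because no canonical edges exist).
A constant mobility vector gives a degenerate flag and rho 0.

# Biomarker discovery

Family abundances are sums of significant hit abundances per sample
(E-value strictly below 1e-3, coverage strictly above 50%). Per family,
a stratified Wilcoxon rank-sum statistic is computed: within each
study block, midranks and the case rank-sum against its null mean;
blocks combine with van Elteren's locally most powerful weights
`1/(n_b + 1)` (an unweighted variant is available, since the exact
weighting of the reference implementation is not pinned down);
variances are tie-corrected, and a block containing a single condition
or all-tied values contributes nothing. One block reduces exactly to
the ordinary normal-approximation rank-sum test; no continuity
correction is applied. P-values are corrected with Benjamini–Hochberg,
significance is `q < 0.01`, and direction comes from the across-block
average of per-block mean(case) − mean(control). Prevalence is the
fraction of samples with non-zero abundance; never-detected families
are excluded from testing.

# The synthetic-data generator

The generator defines the study conditions under which every claim is
validated. Its taxonomy is balanced: 2 domains × 2 phyla each × 3
orders per phylum, with two GTDB families per order so that the deepest
rank shared by an order's species is the order itself — planted
order-level signals therefore date/scan at exactly their planted rank,
and no coextensive parent clade generates extra strict-regime hits.
Each genome is one contig of 60 background genes (lengths 300–900 nt,
gaps 20–200 nt, random strands); 30% of background genes carry a KO
and one pathway drawn from a 200-map vocabulary.

Planted content, all recorded in truth tables:

* **calibration ("known") families** and **novel operon families**,
  built identically: 90% of members are embedded in a 4-gene cassette
  annotated to the family's pathway, co-strand with the focal gene,
  with intra-cassette gaps of at most 60 nt; known members additionally
  carry the pathway annotation themselves. Cassette pathways come from
  a 10-pathway operon-forming subset of the vocabulary, so each pathway
  accumulates enough known families to calibrate at desk scale. The
  vocabulary/subset split matters: with a 10-pathway vocabulary,
  chance same-pathway collisions in windows (~0.6 per family) spread
  the score distributions and quantile calibration then caps planted
  recovery near 85–90%; with a realistic map vocabulary a specific
  pathway almost never appears in a window by chance, scores become
  atomic, and the calibrated predictor behaves as designed.
* **null families** whose members keep their random background context.
* **synapomorphic families**, exclusive to one order and covering a set
  fraction of its genomes, with more than ten members.
* **resistance-island families** (a resistance-flagged +1 neighbour in
  every member) and **small-peptide families** (longest protein < 50
  residues).

Member placement reserves non-overlapping window slots; if slots run
out, families shrink and (if empty) are dropped with a warning — the
validation configurations are sized so this does not happen.

Codon families evolve along trees by Poisson mutation events with HKY
transition bias (`kappa = 2`), rejection of stops, and acceptance of
non-synonymous changes with probability `omega`; `omega = 0` yields
synonymous-only histories. Gene trees follow the taxonomy topology and
are built clock-like — each taxonomic level at a fixed height with ±10%
per-edge rate jitter — because midpoint rooting presumes approximate
clock behaviour; with free random branch lengths the midpoint
occasionally lands inside a planted duplicated clade and the event
surfaces at the root instead of the planted clade (about 1% of trees in
our measurements). Planted duplications attach two copies of a clade
subtree just above the clade's height.

Abundance matrices are log-normal (`sdlog = 0.25`) with per-block
log-offsets (sd 0.5), zero-inflation to a prevalence of 0.7, and a
2-fold case multiplier on the first 20 of 500 families across 200
samples in 5 blocks — the documented recovery conditions. The spread
parameter deserves a note: the recovery property (essentially all
planted effects at `q < 0.01` at this sample size) constrains the
noise level; `sdlog = 0.5` would roughly halve power and is more than
typical measurement noise once abundances are aggregated over
significant hits, so 0.25 is the generator's stated condition.

What the generator does **not** emulate: sequence-level homology
(clusters are asserted, not discovered), assembly artefacts and
chimeric contigs, compositional (relative-abundance) coupling between
families, uneven taxon sampling, annotation errors in the calibration
set, and horizontal transfer. Passing the planted-truth suite therefore
demonstrates the correctness of the *computations* under clean,
in-model data — not robustness to the full messiness of real
catalogues.

# Validation problem sizes

The test-suite and acceptance-script runs use: 200 random alignments
(≤10×60) for the domain oracle; 100 random 100-codon pairs for the NG86
oracle plus 50 codon-family replicates per omega level; a 600-genome
collection with 100 calibration, 100 planted-operon and 200 null
families for the context predictor; a 204-genome collection with 6
planted synapomorphies; 100 clean and 100 planted gene trees; 2,000
block-confounded null replicates (n = 40, 4 unbalanced blocks with
location shifts) for type-I calibration; 500 random families for LCA
monotonicity; and a full duplicate pipeline run for byte-level
determinism.

# Known limitations

* NG86 is a counting method: it underestimates rates at high divergence
  and our minimum-amino-acid-change pathway rule biases dN slightly
  downward on multi-hit codons; the pipeline only consumes the ratio as
  a ≤ 0.5 pass/fail, where rank order is what matters. An external
  dN/dS column can be supplied instead.
* Calibration quality is bounded by the number of known families per
  pathway; at desk scale the quantile is coarse (steps of 1/n).
* The species-overlap rule over-calls duplications under incomplete
  lineage sorting or horizontal transfer; dating depends on the
  taxonomy's resolution.
* The blocked test assumes exchangeability within blocks; it controls
  block-level location shifts, not block-by-condition interactions.
* Habitat breadth counts detections, not abundances, and is sensitive
  to the habitat grouping map.
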
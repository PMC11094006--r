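---
title: "Methods: marker-gene and genome-resolved profiling of geothermal spring archaeal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gene and genome-resolved profiling of geothermal spring archaeal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springcomm)
```

## Scope and model of the data

Geothermal springs host archaeal communities whose structure is strongly
shaped by pH and temperature. `springcomm` implements a desk-scale,
fully-tested version of the computational workflow used to profile such
communities from shotgun metagenomes, organized around the single-copy
ribosomal protein S3 (*rpS3*) gene as a community marker:

1. candidate *rpS3* genes are screened by search score and translated
   length, confirmed against a labelled reference set, and collapsed to
   species-level representatives at 99% identity;
2. representatives receive GTDB-style 7-rank lineages from a
   bootstrap-confidence naive Bayes classifier with a top-5
   lowest-concordant-rank fallback;
3. genome bins are curated by an interquartile-range depth rule, scored for
   completeness/contamination against single-copy marker inventories, gated,
   and dereplicated at 99% ANI into representative genomes (rMAGs);
4. relative abundances are computed from read recruitment (genomes) or
   marker coverage (genes), linked between the two views, and aggregated by
   rank;
5. community structure is compared across pH/temperature classes
   (Bray-Curtis, PCoA, ANOSIM, Pearson), functional content is summarized as
   pathway presence, metabolic weight (MW) scores and CAZyme counts, and
   co-occurrence is inferred with SparCC plus bootstrap pseudo *p*-values.

Upstream sequencing, assembly, binning, read mapping and HMM searching are
out of scope: their outputs (scores, counts, depths, annotations) are the
package's inputs. A synthetic-data module generates all of these inputs with
planted ground truth, which is what the test suite and the acceptance script
exercise.

## The synthetic-data generator

`make_reference_taxonomy()` draws a 7-rank labelled tree;
`synthesize_marker_references()` evolves one marker per species down that
tree under a Jukes-Cantor substitution model. Branch lengths are calibrated
so that the expected identity between two species diverging at rank *r*
equals the taxonomy's sibling-identity parameter for *r* (defaults: genus
0.965, family 0.93, order 0.89, class 0.845, phylum 0.80, domain 0.72,
within-species 0.99). Because the per-edge substitution process composes
exactly (each edge applies the exact Jukes-Cantor transition for its
length), these identities are analytically predictable and the generated
sets always satisfy the rank ordering "same genus > same family > same
order" that the tests assert. No indels are simulated by default, and only
uppercase ACGT is produced; this keeps k-mer logic and identity calibration
simple, at the cost of not exercising gap-rich alignments on synthetic
data.

`spring_scenario()` fixes the study conditions. Defaults were chosen once as
a desk-scale analogue of a multi-spring survey: 20 samples split between
acidic (pH 2-5.4) and alkaline (pH 8.5-9.9) springs, temperatures 40-95 °C,
alternating seasons, 30 species over 3 phyla, and 10^5 marker-recruited
reads per sample (deep enough that multinomial sampling error on a planted
abundance is well below two percentage points). Species are assigned acidic,
alkaline, or generalist habitat preferences (45/45/10%), and per-sample
compositions are Dirichlet draws whose concentration favours the matching
group — this is the planted compositional difference the end-to-end ANOSIM
test must detect. Each species also receives one genome bin with planted
completeness and contamination expressed in marker units (so estimated
quality equals the planted value exactly), 0-2 depth-outlier scaffolds
placed outside the realized IQR fences by construction, planted pathway
status per bundled pathway, and a CAZyme repertoire in which
acid-preferring species carry fewer families. Two bins deliberately fail
the quality gate (one on completeness, one on contamination) and one bin
carries 210 scaffolds to exercise the pathway-evaluation cap. Core scaffold
depths are drawn uniformly within ±15% of a bin-level base depth — a band
that practically cannot breach its own Tukey fences — so planted outliers
are the intended removals (extreme draws may still be caught; the generator
only guarantees that planted outliers are outside the fences).

Each sample's marker gene for a species is the reference mutated by half
the within-species branch (~0.5% of sites), so queries stay within 1%
of their reference and two variants of one species remain comfortably
inside a 99% cluster. Three decoy records per sample (a low-score hit, a
60-amino-acid-short translation, and a random off-target sequence with a
good score) exercise all three screening rules. Fixed seeds make every
output byte-identical, which the suite verifies by hashing written files.

The generator emulates composition, divergence and bookkeeping — not read
errors, chimeras, indel-rich alignment, uneven gene lengths, or real
database idiosyncrasies. Passing tests therefore demonstrate correctness of
the implemented procedures under their stated models, not performance on
real survey data.

## Marker identification and clustering

`screen_candidates()` keeps records with score ≥ 40 and translated length
≥ 60 aa (both removals strict below the threshold, as quoted in the
screening recipe). `confirm_markers()` replaces an external-database protein
search with a best-hit identity test against the supplied labelled
reference set (default 0.60 in nucleotide space): this removes the external
dependency while preserving the keep/drop contract.

`pairwise_identity()` is a global Needleman-Wunsch alignment with match +1,
mismatch −1 and linear gap −2, implemented as a small compiled kernel;
identity is matching columns over all alignment columns, so gaps count as
mismatches. Traceback ties prefer diagonal moves, making the value
deterministic; the test suite checks it against an exhaustive enumeration
of all maximum-score alignments on short strings.

`cluster_representatives()` mirrors length-sorted greedy centroid
clustering with exhaustive centroid comparison: records are processed by
decreasing length (ties by lexicographic gene id), and each record joins
the **best** centroid meeting the identity threshold — the semantics of
"consider every candidate, accept the best", which is what unlimited
accept/reject settings request in the classic implementation. On
well-separated inputs this coincides with single-linkage clustering, which
is the oracle used in tests. Clustering operates in the space of the
sequences provided (nucleotide here); the choice is recorded in the
cluster object.

## Taxonomy assignment

`classify_rdp()` follows the canonical word-based classifier recipe: word
size 8, 100 bootstrap replicates, each replicate scoring ⌈W/8⌉ of the
query's W unique words sampled with replacement. Each reference species is
its own class; word likelihoods use the (n(w)+0.5)/(N+1) prior. The
full-word-set winner fixes the candidate lineage; per-rank confidence is
the fraction of replicates agreeing with the winner at that rank, which is
non-increasing with depth because lineages form a tree. The lineage is
reported down to the deepest rank with confidence ≥ 0.60.

`assign_lca_topk()` ranks references by alignment identity, takes the top
five hits (identity ties at the fifth position are all included — the
conservative choice, since extra hits can only shallow the assignment;
fewer than five references means all are used), and reports the deepest
rank on which all hits concord. `assign_taxonomy()` runs the classifier
first and falls back to the LCA path when the query cannot be assigned at
phylum level (phylum confidence < 0.60), recording which path produced the
result. The fallback runs in nucleotide space; a protein-space fallback
could rank hits differently for distant queries, which is untested here.

**Self-consistency curation.** `curate_reference_db()` applies, in order: a
strict >300 bp length filter, exact-duplicate collapse, a self-consistency
filter, and 99% clustering to species representatives. The self-consistency
step classifies each sequence with itself withheld from training
(leave-one-out avoids trivial self-matches). A literal "discard on
confident disagreement at any rank" rule would, however, discard nearly
every correctly-labelled entry of a species-level database: with the
singleton species withheld, the classifier necessarily and confidently
names the nearest *sibling* species. The implemented rule therefore
requires consistency only down to the deepest rank whose recorded label is
still **attainable** from the remaining training set (for a singleton
species, its genus if the genus has other members, else its family, and so
on). A mislabelled sequence sitting inside another genus's cloud is still
confidently discarded at the genus rank, while correct singletons survive
and curation is idempotent on clean databases.

## Genome curation, quality, and dereplication

`filter_depth_outliers()` computes Q1/Q3 with linear-interpolation
quantiles (the common default in scientific software; the convention is
recorded in the removal log's fence attribute) and removes scaffolds
strictly outside Q1 − 1.5·IQR / Q3 + 1.5·IQR. When IQR = 0 the fences
collapse and nothing is removed.

`estimate_quality()` reports completeness as the percentage of expected
single-copy markers present and contamination as extra copies over expected
markers — a deliberately simple estimator with the same monotone behaviour
as lineage-aware tools, not a reimplementation of them. DPANN bins are
scored against a reduced 48-gene inventory, others against a 53-gene
standard set; the shipped identifiers are synthetic placeholders paired
with the generator, and any real inventory can be passed instead. Tiers
follow the MIMAG convention (high: >90%/<5%; medium: >50%/<10%), and the
gate keeps bins with completeness > 50 and contamination < 10, both strict.

`estimate_ani()` estimates ANI from 21-mer containment through the Mash
distance transform — an alignment-free stand-in with the same threshold
semantics as alignment-based ANI at the 99% (strain) level.
`dereplicate()` then greedily clusters gate-passing bins in order of the
published default quality score (completeness − 5 × contamination),
each bin joining the first representative at ≥ 99% ANI. An optional manual
rule from the original workflow (dropping scaffolds bearing multiplied
single-copy markers) is not reproducible from its description and is not
implemented.

## Abundance and linkage

Genome abundance is mapped reads over total reads, with entries at or below
the 0.01% reporting floor zeroed (strictly "more than" counts) and **no
re-normalization afterwards** — downstream sums may be below 100%, which is
documented rather than hidden. Marker abundance is coverage
(reads/gene-length) normalized per sample. `linkage_metrics()` quantifies
how much of the marker view the genome collection captures, by count and by
coverage weighting; a representative is contained in a genome when any
member of its cluster is among the genome's genes. `aggregate_by_rank()`
pools features unassigned at the requested rank into "Unclassified" so
column sums are conserved. `fpkm()` is the standard fragments per kilobase
per million formula.

## Ecology statistics

Group thresholds are: acidic pH < 5.5 ≤ neutral < 8.5 ≤ alkaline, and
mesothermal < 60 °C ≤ thermal < 80 °C ≤ hyperthermal; boundary values land
in the upper class. The statistics delegate to standard implementations
(vegan's Bray-Curtis and ANOSIM, classical scaling from stats) behind
contracts fixed here: midranks for distance ties, the add-one permutation
estimator (p is never exactly 0; 999 permutations by default, matching a
reported floor of p = 0.001), and positive-eigenvalue-only PCoA.
Bray-Curtis is non-Euclidean, so negative eigenvalues can occur; they are
dropped, not corrected, and their magnitudes returned. Tests verify the
ANOSIM statistic and its permutation p against first-principles
enumeration for n = 8, and PCoA against exact round-trip reconstruction of
Euclidean input.

## Function profiles

`pathway_presence()` evaluates orders against flat KO lists: *complete* if
at least one qualifying rMAG (scaffold count strictly below 200) carries
every required gene, *partial* if any required gene occurs anywhere in the
order (the liberal reading; whether partial calls should require
co-location in one genome is unspecified, and any-gene-anywhere was
chosen), *absent* otherwise. The bundled pathway TSV is editable
configuration, not a biology claim. `mw_score()` is a documented
simplification of the metabolic-weight idea: the abundance-weighted
contribution of a function relative to all functions, normalized to 100%
per sample; a genome encoding several functions contributes to each.

## Co-occurrence networks

`sparcc_correlations()` implements the SparCC procedure: per draw,
component fractions are sampled from a posterior Dirichlet; the log-ratio
variation matrix is computed; basis variances are solved from the
sparsity-assuming linear system; the most strongly correlated pair above
0.1 is iteratively excluded (up to 10 times); and the reported matrix is
the median over 20 draws (the method's published defaults). One deliberate
refinement: samples are equalized to a fixed effective depth (fractions ×
10^4 + 1 as the Dirichlet parameter) before drawing, so the estimate
depends on relative composition only and rescaling a sample's counts
changes nothing — the compositional invariance the method is meant to
embody, which a raw counts+1 posterior would weakly violate. Basis
variances are clamped to a small positive floor for numerical safety.
Because draws are assigned to samples positionally, permuting sample order
changes the Monte-Carlo noise but not the estimand; the corresponding test
allows a small tolerance.

Pseudo *p*-values follow the original release semantics: 100 null datasets
built by permuting each feature's counts across samples independently,
correlations recomputed, and the two-sided add-one estimate reported.
Edges require |r| > 0.6 **and** p < 0.05, both strict; nodes without edges
are kept as flagged isolates. Module detection is not implemented (no
algorithm is specified for it); connected components are available through
the igraph converter.

## Problem sizes and numerical choices

The suite and the acceptance script run at sizes chosen to exercise every
code path with comfortable statistical margins: a 30-species / 3-phyla
catalog; 12-sample surveys at 2 × 10^4 marker reads for pipeline-level
checks and 4-sample surveys at 10^5 reads for sampling-error checks; 1,000
random depth vectors for the IQR oracle; 20 seeded clustering fixtures; 10
strain-group scenarios; 30 × 200 count tables for SparCC with a planted
basis correlation of 0.9; and 999-permutation ANOSIM. Seeds are fixed
throughout; every stochastic routine takes an explicit seed and restores
the caller's RNG state.

Known limitations: no indel or error-model realism in the generator;
contamination estimation ignores lineage structure; ANI from k-mer
containment saturates for very small or highly repetitive bins; the
classifier operates on nucleotide 8-mers and will lose power for queries
far outside the reference's divergence range; and the MW-score is a
simplified contract, not a port of the original tool's internals.

## A worked run

```{r example, eval = FALSE}
tax <- make_reference_taxonomy(n_phyla = 3, n_species = 30, seed = 1)
scenario <- spring_scenario(tax, n_samples = 12, reads_per_sample = 2e4,
                            seed = 1)
ds <- simulate_springs(tax, scenario)
res <- profile_community(ds, seed = 1)
res$anosim        # planted acidic/alkaline difference
head(res$community[, 1:4])
```

The README shows the numbers this prints; `scripts/acceptance.R` recomputes
the same quantities from scratch for any seed.
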
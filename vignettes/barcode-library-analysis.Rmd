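---
title: "Auditing a COI barcode reference library: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a COI barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motulib)
```

## The problem

A DNA barcode reference library is a curated collection of short standard
marker sequences — for animals, the ~658 bp 5′ fragment of mitochondrial
cytochrome *c* oxidase subunit I (COI-5P) — tied to identified voucher
specimens. Before such a library can anchor specimen identification or
species discovery, it has to be audited: sequences of poor quality or
non-mitochondrial origin (NUMT pseudogenes, sample mix-ups) must be flagged,
the distribution of genetic divergence within and between species must be
characterised (the "barcode gap"), and the species implied by the sequences
themselves — molecular operational taxonomic units, MOTUs — must be compared
with the Linnaean names attached to the specimens and with each other across
delimitation methods.

`motulib` implements that audit end to end and pairs it with a coalescent
simulator that produces libraries with known truth, so every stage can be
validated without touching external services.

## Sequence quality control and NUMT screening

Records are screened against the standard library-grade criteria: more than
500 bp of sequence (counted on non-gap characters, so alignment padding never
counts), less than 1% N among non-gap characters, and no in-frame stop
codon. Stop codons are evaluated under the invertebrate mitochondrial code,
where only TAA and TAG terminate translation (AGA/AGG encode serine), and
codons containing a gap or any ambiguity code are never counted as stops.
Because all records share one cropped alignment, the reading frame is
detected library-wide — the offset in `0:2` minimising the total stop count,
ties to the smallest offset — and codons are read on alignment coordinates,
which keeps records with leading gaps in register. A per-record override is
deliberately not offered; a configuration-level override is.

Stop codons catch only the "typical" NUMT. Pseudogene copies that happen to
preserve the reading frame pass every sequence-level filter; the only handle
on them is positional: a record whose conspecifics all fall in a different
cluster is suspect. `cluster_position_report()` implements exactly that rule
downstream of any clustering, which is also where sample mix-ups surface.
No wet-lab recourse (resequencing) is modelled.

## Distances

Pairwise divergence uses the Kimura two-parameter model: with `P` the
transition and `Q` the transversion fraction over comparable sites,

$$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

reported in percent. Sites where either sequence carries a gap or a non-ACGT
code are excluded pair by pair (pairwise deletion rather than complete
deletion — singleton-heavy libraries would otherwise lose most of their
usable sites), and the comparable-site count is kept per pair. Saturated
pairs (where the logarithm's argument is non-positive) are reported as
missing with a reason rather than clamped; typical COI libraries sit far
below that regime. Distances are stored at full precision and displayed at
two decimals.

Rank summaries classify every pair into exactly one divergence class —
intraspecific, congeners (same genus, different species), confamilial (same
family, different genus) — mirroring the conventional distance-summary
table. Pairs involving genus-level records only enter classes that remain
well defined for them.

## Trees

The neighbour-joining tree on K2P distances is the standard "taxon ID tree"
of barcode practice; it is built with the canonical agglomeration
(`ape::nj`), with negative branches clamped to zero and the deficit moved to
the sibling so tip-to-tip paths through the parent are preserved. Three-taxon
inputs are solved by the closed-form three-point formulas. UPGMA
(average-linkage) trees supply the ultrametric input the GMYC model needs;
node heights are half the merge distance. The original study used a Bayesian
clock tree for that purpose, which is outside this package's scope — UPGMA
on the same K2P matrix is the deterministic, dependency-free stand-in, and
the consequences are assessed in the simulation studies rather than assumed.
Monophyly checks midpoint-root unrooted trees first: midpoint rooting is
deterministic and needs no outgroup.

## Delimitation methods

Four families of methods produce `motu_partition` objects over the same
specimens:

**Fixed-threshold single linkage.** MOTUs are connected components of the
graph joining pairs at distance ≤ the cutoff. The base-pair sweep converts
cutoffs of 1–40 bp on the 658-bp barcode to 0.15%–6.08% divergence and runs
the partition at each; a plateau in the MOTU count over consecutive cutoffs
is the classic diagnostic of a clean barcode gap.

**Refined single linkage (local BINs).** Stage 1 clusters at a seed
threshold of 2.2% — the convention behind barcode index numbers. Stage 2
re-examines each cluster: the candidate refinement is the two-way split at
the largest internal single-linkage merge, accepted when the mean silhouette
width of the cluster's members (on the K2P distances, against the full
clustering) improves. Silhouettes are computed on unique haplotypes;
duplicated sequences otherwise make any split of internally identical
haplotype groups look perfect (every within-group distance is zero, so
silhouette widths hit 1.0 regardless of how close the groups are). Labels
are local (`LBIN:0001`, ...) and are never registry identifiers; externally
assigned BIN ids from the metadata are used for reporting when present.

**Single-threshold GMYC.** On an ultrametric tree, branching events older
than a threshold height *T* are species-level diversification (a Yule
process with intensity $\lambda_s n(t)$ over the lineages present), events
below it are within-species coalescences (intensity
$\lambda_c \sum_k n_k(n_k-1)/2$ over the clusters hanging below *T*). The
likelihood is assembled over inter-event intervals, each surviving at the
total intensity of the active classes and closing with that intensity at its
event — the interval-rate formulation. Below the threshold the K species
lineages persist, contributing Yule exposure with no event. Both rates are
profiled analytically (events over integrated opportunity); intensity
scaling exponents are fixed at one, a deliberate simplification of the
published model. Candidate thresholds are the observed node heights, and the
candidate at the root height *is* the one-class null (a single coalescing
species), so the maximised likelihood never falls below the null and the
likelihood-ratio test against it is well defined; it is referred to a
chi-square with two degrees of freedom (threshold plus extra rate), a
documented convention rather than an exact distribution.

**Maximum-likelihood PTP.** On a tree with substitution branch lengths, a
species assignment is a set of disjoint crown subtrees covering the tips;
branches strictly below a crown are within-species, all others (including
crown stems) between-species, and the two classes are exponential with
profiled rates. Model fit is scored by AIC whose dimension counts the two
rates plus the K−1 accepted speciation nodes — the change-point convention:
every accepted split is a fitted break. Without that term the two-class
model gains fractions of a log unit by splitting off single haplotypes on
NJ-inflated terminal branches, a classic oversplitting mode of this model
family. The search is a steepest-descent local search over split and merge
moves, run from three starts (one species; all singletons; the best state on
a guided agglomerative merge path that crosses likelihood barriers), keeping
the best local optimum; ties break on pre-order node index, so results are
deterministic. A pure divisive greedy — the more obvious search — is
provably trapped whenever the midpoint root isolates one long edge, which is
the common case on real NJ trees.

Model-based methods run on unique haplotypes by default (`run_pipeline`'s
`collapse_haplotypes` flag) and partitions are re-expanded to all specimens;
distance methods use all records.

## Discordance and the barcode gap

Every cluster is categorised against the taxonomy with the four standard
association patterns: MATCH (one taxon, fully contained), SPLIT (a pure
fragment of a taxon spread over several pure clusters), MERGE (several taxa,
each wholly inside), MIXTURE (both phenomena at once).

Per-species statistics follow the barcode-gap analysis convention: mean and
maximum intraspecific distance (`i_mean`, `i_max`; undefined for
singletons), distance to the nearest neighbour species (`dnn`, the minimum
over all cross-specimen pairs; ties break to the smallest distance then the
alphabetically first species) and the gap flag, literally `dnn > i_max`.
Library aggregates average `i_max` over non-singletons but `dnn` over all
species rows — the convention that reproduces the published library-level
means from the packaged table — and use a deep-divergence threshold of 2%.
Genus-level records are censused separately and never enter the per-species
table.

## Concordance between methods

Partitions are compared with three indices. The match ratio,
$2N_{match}/(N_A+N_B)$, counts clusters identical as specimen sets. The
taxonomic index of congruence $C_{tax} = |A \cap B| / |A \cup B|$ and the
relative resolving power $R_{tax,A} = |A| / |\bigcup_i M_i|$ operate on
*speciation event sets*, which this package operationalises as the internal
nodes of a shared guide tree (the midpoint-rooted NJ tree by default) whose
descendant tips span at least two MOTUs. That choice stays well defined for
non-monophyletic MOTUs, and for k monophyletic MOTUs on a binary tree yields
exactly k−1 events — the identity under which the published comparison
table's resolving-power row is internally consistent with its MOTU counts.
Two identical single-MOTU partitions have empty event sets and a congruence
of 1 by convention. The consensus count reports taxa that every method
recovers as exactly one pure MOTU.

## The simulator

`simulate_library()` generates libraries with known truth:

* **Species tree** — Yule (pure birth) topology and times, rescaled so the
  mean pairwise between-species divergence equals `interspecific_scale`
  (default 15%, a typical congeneric COI mean) with sister-species
  divergence floored at `min_interspecific_frac` (default 0.5) of that scale
  and above-floor depths compressed so the mean is restored exactly. The
  floor emulates the minimum divergence implicit in the *recognized* species
  of a curated library: raw Yule node times place most sister pairs at a
  small fraction of the mean, which no practical delimitation could or
  should resolve. The compromise keeps the calibration sharp (the realized
  between-species mean tracks the target) while making "well separated"
  concrete.
* **Within-species genealogies** — one coalescent per species, rescaled so
  the species' deepest within-species split equals `intraspecific_theta`
  (default 3.2%, matching the published library's mean maximum intraspecific
  divergence). Defining the parameter on the deepest split rather than the
  mean keeps the intraspecific range bounded; coalescent tails otherwise
  reach ~3.5× the mean and quietly destroy the separation the configuration
  promises.
* **Sequences** — evolved down the combined genealogy under a two-class
  (transition/transversion) Markov process with ratio `ts_tv_ratio`
  (default 3, κ = α/2β; 0.5 is the Jukes–Cantor limit). This is exactly the
  structure K2P estimates, which makes estimator-recovery tests sharp; base
  composition, codon usage and indels are deliberately not modelled. Codons
  that land on an in-frame stop are re-evolved from the parent codon, so
  clean libraries carry no stops at the configured frame.
* **Intrusions** — NUMT copies (extra `numt_burst` = 8% divergence; an
  in-frame stop with probability `numt_stop_prob` = 0.5) and sample mix-ups
  (a contaminated record takes a slightly mutated copy of another species'
  sequence) at the configured per-record rates (defaults 0.006 and 0.0015,
  the intrusion frequencies of a careful library). Everything is
  deterministic under the seed, to the byte.

Sample sizes default to 20 species with a mean of 7 specimens and a 19%
singleton probability — the structure, at reduced scale, of a regional
orthopteran library with ~90 taxa. The test suite and the acceptance script
run the well-separated configuration (5 species × 10 specimens, 10% between
vs 0.5% within) for parameter-recovery checks and small constructed cases
for everything else; those sizes keep the full validation suite under a
minute on one core.

## What passing tests do and do not show

The simulator produces gap-clean libraries by construction once the
floor/compression scaling is applied. Real libraries are messier: the
published study's data include four species whose maximum intraspecific
divergence exceeds their nearest-neighbour distance, and no synthetic
default reproduces that overlapping tail. Passing recovery tests therefore
demonstrate correctness of the machinery on separable data, not robustness
to gapless species complexes. Relatedly, under deep intraspecific structure
(the default 3.2% theta against a 7.5% sister floor) the GMYC likelihood
profile becomes nearly flat across tens of candidate thresholds, and the ML
threshold drifts towards oversplitting — the same instability that made the
multi-threshold variant delimit 132 MOTUs for 90 taxa in the original
study. That behaviour is inherent to single-locus delimitation at low
signal, and the package reports it honestly rather than regularising it
away.

## Numerical conventions

Distances are percentages throughout; trees built from them carry percent
branch lengths, and rate parameters are in reciprocal percent. MOTU labels
are renumbered by first appearance in specimen order, so partitions are
reproducible across runs. All ties (frame detection, nearest neighbours, NJ
agglomeration via its reference implementation, PTP moves, GMYC threshold
candidates) break deterministically. Zero-length branches are tolerated
everywhere; a tree whose branches are all zero is rejected by PTP as
degenerate. Exponential class opportunities are floored at 1e-12 to avoid
infinite profiled rates on degenerate configurations.

## Running the workflow

The `analysis/` directory holds the numbered drivers: simulate
(`01_simulate_library.R`), QC (`02`), distances and trees (`03`),
delimitation (`04`), barcode gap (`05`), concordance (`06`), recomputation
of the published tables' aggregates from the packaged transcriptions (`07`)
and an optional full-data run against a locally downloaded copy of the
reference dataset (`08`). `run_pipeline()` wraps stages 2–6 for a single
configured call. `scripts/acceptance.R` recomputes the headline quantities
from scratch and writes them as JSON.
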
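# motulib

Auditing tools for DNA barcode reference libraries, written for the
workflow a curator runs on a regional COI-5P collection: sequence quality
control with NUMT (nuclear mitochondrial pseudogene) screening, Kimura
two-parameter distances, neighbour-joining and UPGMA trees, molecular
species delimitation by four method families, per-species barcode-gap
statistics, cluster–taxon discordance categories, and concordance indices
that compare delimitation methods with each other. A coalescent simulator
with known truth makes every stage testable offline.

The intended users are researchers assembling or validating barcode
libraries — entomologists, molecular ecologists, curators of BOLD-style
collections — and anyone who wants transparent, scriptable implementations
of the delimitation methods those platforms run as black boxes.

## The models at the core

**K2P distance.** With `P` the transition and `Q` the transversion fraction
over the comparable sites of a pair (pairwise deletion of gaps and
ambiguities),

```
d = -1/2 · ln( (1 - 2P - Q) · sqrt(1 - 2Q) )
```

reported in percent.

**Barcode gap.** For each species, `I_mean`/`I_max` are the mean/maximum
intraspecific K2P distance and `DNN` the minimum distance to any other
species' specimen; a gap is present when `DNN > I_max`.

**Delimitation.** MOTUs (molecular operational taxonomic units) are drawn
by (i) single-linkage clustering at fixed divergence thresholds, including
the 1–40 bp cutoff sweep on the 658-bp barcode (0.15%–6.08%); (ii) refined
single linkage seeded at 2.2% with a silhouette-guided second pass (local
BIN analogues); (iii) the single-threshold general mixed Yule–coalescent
model (GMYC) on an ultrametric tree, with branching events older than a
threshold modelled as a Yule process (intensity `λ_spec · n(t)`) and younger
events as within-species coalescences (intensity
`λ_coal · Σ_k n_k(n_k-1)/2`), both rates profiled analytically and the
threshold chosen by maximum likelihood against the one-species coalescent
null; (iv) a maximum-likelihood Poisson tree process (PTP), two exponential
branch-length classes separated by speciation nodes, scored by AIC and
searched by a deterministic split/merge descent.

**Concordance.** Match ratio `2·N_match/(N_A+N_B)` on clusters; the
taxonomic index of congruence `C_tax = |A∩B|/|A∪B|` and relative resolving
power `R_tax = |A|/|A∪B∪…|` on speciation-event sets, operationalised as
guide-tree nodes whose descendants span ≥2 MOTUs.

## Worked example

Simulate a small library of 5 species × 10 specimens (10% between-species,
0.5% within-species divergence) with a 4% NUMT injection rate, then audit
it:

```r
library(motulib)
sim <- simulate_library(sim_config(n_species = 5, specimens_per_species = 10,
                                   singleton_prob = 0, n_jitter = FALSE,
                                   interspecific_scale = 10,
                                   intraspecific_theta = 0.5,
                                   numt_rate = 0.04, seed = 42))
lib <- qc_screen(sim$library, detect_reading_frame(sim$library))
lib <- filter_passing(lib)
dm  <- build_matrix(lib)
bins <- resl_bins(dm)
species_summaries(dm, lib$records, bins = bins$assignment)
```

which prints

```
QC: 48 of 50 records pass; stop codons in: SIM02-009, SIM04-004
      species  n n_bins i_mean i_max   dnn   gap
 Genus01 sp01 10      1   0.17  0.61 15.16  TRUE
 Genus01 sp02  9      1   0.40  0.61  2.95  TRUE
 Genus01 sp03 10      2   1.37  6.92  4.40 FALSE
 Genus02 sp04  9      1   0.26  0.61  2.95  TRUE
 Genus02 sp05 10      1   0.37  0.76  3.43  TRUE
```

Two injected NUMTs carried in-frame stop codons and were removed by QC. A
third pseudogene copy kept its reading frame and sailed through: it shows up
instead as fake deep intraspecific divergence in `sp03` (`I_max` 6.92%
against a true within-species variation of ~0.6%), erasing that species'
barcode gap and splitting it into two local BINs. The positional screen
pins it down:

```r
taxon <- setNames(lib$records$species, lib$records$specimen_id)
cluster_position_report(threshold_partition(dm, 3), taxon)
#  specimen_id        taxon   cluster conspecific_clusters
#    SIM03-004 Genus01 sp03 MOTU:0004            MOTU:0003
```

`SIM03-004` is indeed the stop-free NUMT the simulator injected. GMYC on
the haplotype-collapsed UPGMA tree delimits 6 MOTUs (the 5 species plus the
pseudogene lineage), agreeing with the generating truth at an adjusted Rand
index of 0.97.

## The analysis workflow

Numbered drivers under `analysis/` run the full audit on a simulated
library and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_library.R    # library + truth
Rscript analysis/02_quality_control.R     # frame detection, QC report
Rscript analysis/03_distances_and_trees.R # K2P matrix, rank summary, NJ/UPGMA
Rscript analysis/04_delimitation.R        # threshold sweep, BINs, GMYC, PTP
Rscript analysis/05_barcode_gap.R         # per-species gap table + aggregates
Rscript analysis/06_concordance.R         # match ratio / C_tax / R_tax table
Rscript analysis/07_published_tables.R    # aggregates of the packaged tables
Rscript analysis/08_full_reference_data.R # optional: a downloaded reference set
```

`run_pipeline()` wraps stages 2–6 as one configured call. The packaged
transcriptions of the reference study's per-species and genus-level tables
live in `inst/extdata/` and are loaded by `table2_fixture()` /
`table3_fixture()`.

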
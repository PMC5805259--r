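---
title: "Profiling oral DNA viromes from dual-database alignment hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling oral DNA viromes from dual-database alignment hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralvirome)
```

## The problem

Shotgun metagenomes of oral wash samples contain a mixture of bacterial,
viral and residual host DNA. After host filtering, reads are searched
against two reference databases: a bacterial genome collection and a
viral collection that includes free phage and eukaryotic-virus genomes
as well as prophage sequences excised from bacterial genomes. Because
prophages are, by construction, part of bacterial genomes, most reads
matching them also match the bacterial database; profiling the virome
therefore requires keeping track of *dual-database homology* for every
read, and reporting results both for all viral reads and for the
virus-only subset.

`oralvirome` takes the tabular alignment output of such searches and
carries it through taxonomic assignment, read partitioning, taxon
tables, core-virome prevalence analysis and group-wise diversity
comparison. It does not run any aligner, perform read QC, or build
reference databases — those are upstream concerns with established
tools.

## Hit filtering and read assignment

A hit is retained when

* e-value `< 1e-3` (strict inequality),
* percent identity `>= 80`,
* alignment length `>= 75%` of the read length.

The identity and coverage bounds are inclusive; the e-value bound is
exclusive. Because the standard 12-column tabular alignment format does
not carry the read length, readers accept either a 13th `qlen` column
or a separate two-column read-length table; both paths are tested.

For each read, retained hits are ranked by percent identity, then
alignment length, then bit score. The bit score is a deterministic
tie-break of last resort only — two hits equal on identity and length
are treated as co-optimal regardless of bit score, which is the most
conservative reading of best-hit assignment. The *co-optimal set* is
every hit within `tie_margin` of the top hit on both identity
(percentage points) and alignment length (percent of the top length).
The default `tie_margin = 0` keeps exact ties only; widening the margin
can only grow the co-optimal set, so assignments move monotonically
towards the root as the margin grows (a property the test suite checks).

If all co-optimal hits map to one taxon, the read is assigned there —
the closest-to-tip level the evidence supports, normally species. Else
it is assigned to the lowest common ancestor (LCA) of their taxa within
the rank-labelled taxonomy (order, family, genus, species), or to the
`UNDETERMINED` sentinel when the taxa share no node. Multiple hits of
one read to the same subject collapse to the best one before ranking.

Reads with at least one retained viral hit become assignments; the
`bacterial_hit` flag records whether the same read also retains a
bacterial hit. Reads with only bacterial homology are counted as
bacterial reads and receive no taxonomic assignment — the package
profiles the virome, and the bacterial side enters only through the
read accounting and the homology flag. This dual-flag design
reproduces the published style of accounting (a viral-read total split
into virus-only and virus-and-bacteria pools) without guessing at the
exact read routing of any particular upstream workflow.

## Partitioning by viral class

Every reference subject carries a class annotation: `prophage`,
`bacteriophage` or `eukaryotic_virus`. A read's class is the annotation
of its winning hit; for LCA-level assignments it is the majority class
over the co-optimal set, ties resolved by the top-ranked hit. Class
proportions are reported within three read pools — all viral reads,
virus-only, virus-and-bacteria — and the pools are cell-wise additive.
Proportions count *reads*, not distinct hits; where published summaries
are ambiguous between the two, read counting is the interpretation
adopted here.

## Taxon tables, prevalence and the core virome

Taxon-by-sample tables are built at family and species rank. Each
assignment contributes one count to its ancestor at the target rank;
assignments resolved shallower than the target rank accrue to the
`UNDETERMINED` row, so column sums always conserve reads. Row labels
are semicolon-joined lineage strings (`o__…;f__…;g__…;s__…`) with `u`
marking an undetermined rank and `n` a taxon unnamed in the source
database. Tables export to TSV and to BIOM 1.0 JSON; the BIOM writer
emits the sparse (row, column, value) representation, and round trips
are verified against the `biomformat` reader.

Prevalence analysis uses presence/absence (default threshold: one
read). Detected taxa fall into four tiers by the fraction of samples
where they occur:

| category | fraction of samples |
|---|---|
| high ("core") | > 0.75 |
| medium_high | 0.50 – 0.75 |
| medium_low | 0.25 – < 0.50 |
| low | < 0.25 |

Published category ranges of this kind overlap at their shared
endpoints (50% and 25% belong to two ranges as written). We resolve
each boundary to the *upper* tier — a fraction of exactly 0.50 is
`medium_high`, exactly 0.25 is `medium_low` — while the core tier stays
strictly above 75%, matching the "more than 75%" definition. Singletons
(taxa in exactly one sample) are flagged separately and overlap the low
tier. The `UNDETERMINED` row is excluded from prevalence: those are
real reads (they count for table sums and rarefaction) but not a named
taxon whose occupancy could be interpreted. Categories are computed per
rank and per pool, since family-level aggregation can only increase a
lineage's occupancy relative to its best species (also asserted in the
tests).

## Rarefaction and diversity

Group comparisons operate on rarefied tables: samples below the chosen
depth are dropped (and logged), the rest are subsampled *without
replacement* (multivariate hypergeometric, `vegan::rrarefy`) to exactly
the depth. Without-replacement is the standard rarefaction convention;
the expected rarefied proportion of a taxon equals its original
proportion, which the suite checks over 1000 seeds. Two depths — a
lenient and a strict one — are carried through the pipeline by default,
so the retained-sample trade-off is visible in the outputs.

Alpha diversity is the Shannon index in log base 2 (the historical
QIIME default; the base is stated here because published work often
names the index without it). Beta diversity is Bray–Curtis,
`sum(|x-y|) / sum(x+y)`, via `vegan::vegdist`; pairs of empty samples
are undefined and flagged rather than zeroed.

Group differences use a two-tailed nonparametric t-test: the observed
Welch t statistic is compared to its distribution under random
relabelling, with the add-one estimator
`p = (1 + #extreme) / (1 + n_permutations)` so p-values are never zero.
The default is 999 permutations. The pooled values are sorted and the
smaller group size is drawn in each permutation, which makes the
p-value exactly invariant to swapping the two group labels under a
fixed seed. Alpha comparisons are adjusted with Benjamini–Hochberg FDR
across all reported comparisons; beta comparisons — within-group and
between-group Bray–Curtis distance sets compared pairwise — use
Bonferroni, capped at 1, with five-number boxplot summaries per
distance set. Degenerate inputs (both groups constant and equal) give
t = 0 and p = 1 by convention.

## The synthetic-data generator

Real virome sequencing data cannot ship with a package, so every stage
is exercised against a generator with known truth:

* **Taxonomy** — orders, families and species with one reference
  subject per species; one viral class per family (as real families
  are: *Siphoviridae* is phage, *Herpesviridae* eukaryotic). The genus
  rank is left undetermined, as is common in viral reference
  taxonomies; hand-built trees with genus nodes cover the deeper LCA
  cases in the tests.
* **Community** — a cohort of 72 samples with a balanced F/M split by
  default. A small core block (default 10% of taxa, stratified so each
  viral class keeps at least one core taxon, prevalence probability
  0.9–1.0) plus a long tail (probability `1/n` to 0.2) yields the
  singleton-dominated occupancy spectrum typical of oral cohorts.
  Presence is Bernoulli per taxon and sample; abundances are lognormal
  (`sdlog = 1.5`), scaled within each sample so expected read shares
  per class match the model, then sampled by a multinomial at the
  sample's depth. Per-sample depth is lognormal around a median of
  2834 viral reads with `sdlog = 1.5` — a wide spread under which a
  few samples fall below lenient rarefaction depths and more below
  strict ones, as real cohorts do.
* **Read pool** — default class shares 92% prophage, 5% bacteriophage,
  3% eukaryotic virus. The per-class probability that a viral read also
  matches the bacterial database defaults to 0.945 / 0.642 / 0.02;
  with the default shares this places ~90% of viral reads in the
  virus-and-bacteria pool, makes that pool ~96% prophage, and leaves
  the virus-only pool roughly balanced between prophages and the rest
  — the characteristic signature of a prophage-containing viral
  database.
* **Hits** — one primary hit per read at its true subject: identity
  truncated-normal(95, 4) on [0, 100], coverage Beta(18, 2) (mean
  0.9), e-value `10^-U(5, 40)`. A 2% `fail_rate` forces identities
  below the threshold (reads lost at filtering); a 2%
  `off_target_rate` adds a co-optimal hit to a sibling species,
  creating genuine LCA cases with a known answer (the family).
  Bacterial hits are injected per the homology probabilities; a
  configurable count of bacterial-only reads per sample (default
  18608) completes the accounting. These noise distributions are
  stated choices, not estimates; they are configurable per run and
  recorded in each fixture's `config.yaml`.

What the generator does **not** emulate: sequence-level error
processes, chimeras, database incompleteness, within-genome positional
structure of prophages, covariance between taxa, or any sex effect
(none, by design — which is exactly what makes the null diversity
comparison a meaningful check). Passing tests therefore demonstrate
that the pipeline's bookkeeping and statistics are correct under a
plausible community model, not that any biological conclusion
transfers to real data.

A small packaged fixture (5 samples, ~50 reads per sample median) under
`inst/extdata/default_fixture/` keeps the repository light; the test
suite generates its larger fixtures in code (typically 12 samples at a
median 420 viral reads per sample, i.e. ~5k reads per fixture) and the
full 72-sample cohort is generated where a test needs it. These sizes
were chosen to keep the default check fast while leaving every rate
estimate enough reads for three-binomial-standard-error comparisons.

## Numerical and design notes

* All text I/O is UTF-8, tab-delimited, `#` header lines permitted.
* Rarefaction, permutation tests and every generator stage take
  explicit integer seeds; identical seeds give byte-identical outputs.
* Proportions sum to 1 within 1e-9; percentages are reported at full
  precision in machine-readable output and rounded to one decimal in
  report tables.
* The orchestration layer (`run_pipeline()`, with the thin
  `inst/scripts/run_pipeline.R` wrapper) propagates any stage error
  with its stage name and writes a `summary.json` containing the read
  accounting, per-pool partition, category distributions and
  comparison p-values.

## Limitations

* Assignment quality is bounded by the reference taxonomy: taxa absent
  from the subject map can only surface as `UNDETERMINED`.
* Prevalence tiers depend on presence thresholds; with a single-read
  threshold, low-depth samples underdetect rare taxa, which shifts the
  occupancy spectrum towards lower tiers. Rarefied presence tables can
  be used where this matters.
* The permutation t-test assumes exchangeability of samples under the
  null; it is not a substitute for distance-based multivariate tests
  (PERMANOVA) when group dispersions differ strongly.
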
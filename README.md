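# oralvirome

Profiling oral DNA virome communities from tabular alignment hits
against paired viral and bacterial reference databases.

Shotgun metagenomes of oral samples yield reads that may match a viral
database (free phages, eukaryotic viruses, and prophages excised from
bacterial genomes), a bacterial database, or both. `oralvirome` is for
microbiome researchers who have such hit tables (BLAST outfmt-6 style)
and want a tested, reproducible path from them to:

* **hit filtering** — e-value < 10⁻³, identity ≥ 80%, alignment over
  ≥ 75% of the read length;
* **best-hit / LCA taxonomic assignment** — hits ranked by identity,
  then alignment length, then bit score; co-optimal hits resolved to
  the lowest common ancestor in an order/family/genus/species
  taxonomy, or `UNDETERMINED`;
* **read partitioning** — prophage vs bacteriophage vs eukaryotic
  virus, crossed with dual-database homology (virus-only vs
  virus-and-bacteria pools);
* **taxon-by-sample tables** at family and species rank, with sparse
  BIOM 1.0 JSON and TSV export;
* **core-virome prevalence** — four occupancy tiers (core > 75% of
  samples; 50–75%; 25–50%; < 25%) plus singleton detection;
* **diversity comparisons** on rarefied tables — Shannon alpha
  diversity (log base 2) and Bray–Curtis beta diversity, compared
  between groups with two-tailed Monte Carlo permutation t-tests
  (`p = (1 + #extreme) / (1 + n_perm)`), Benjamini–Hochberg FDR for
  alpha and Bonferroni for beta;
* a **synthetic fixture generator** with ground truth (core + long-tail
  prevalence spectrum, lognormal abundances, class-dependent bacterial
  homology, configurable hit noise), so the whole pipeline is testable
  without sequencing data.

The methods vignette (`vignettes/virome-profiling-methods.Rmd`)
documents the model, every tunable parameter, and the design
decisions.

## Worked example

Generate a 12-sample fixture, assign reads, and partition:

```r
library(oralvirome)

fx <- simulate_fixture(n_samples = 12, reads_per_sample = 420,
                       bacterial_only_per_sample = 60,
                       n_families = 10, species_per_family = 4, seed = 1)
write_fixture(fx, "fixture")

md   <- read_sample_metadata("fixture/metadata.tsv")
tree <- read_taxonomy("fixture/taxonomy_nodes.tsv",
                      "fixture/taxonomy_subjects.tsv")
asg <- do.call(rbind, lapply(md$sample_id, function(s) {
  v <- read_hit_table(paste0("fixture/viral_hits_", s, ".tsv"), "viral")
  b <- read_hit_table(paste0("fixture/bacterial_hits_", s, ".tsv"),
                      "bacterial")
  assign_all(v, b, tree, sample_id = s)$assignments
}))
partition_summary(asg)
#> Viral read partition (counts):
#>                    prophage bacteriophage eukaryotic_virus
#> virus_only             1638           616              972
#> virus_and_bacteria    27964          1082               19
#> all                   29602          1698              991
#>
#> Within-pool percentages:
#>                    prophage bacteriophage eukaryotic_virus
#> virus_only             50.8          19.1             30.1
#> virus_and_bacteria     96.2           3.7              0.1
#> all                    91.7           5.3              3.1
```

Reads hitting prophage references dominate the pool (91.7% of all
viral reads) and almost all of them also match bacteria (the
virus-and-bacteria pool is 96.2% prophage), while the virus-only pool
is roughly balanced — the characteristic signature of a
prophage-containing viral database.

Prevalence and diversity:

```r
tt <- build_taxon_table(asg, tree, rank = "species", metadata = md)
cd <- category_distribution(occurrence_counts(presence_absence(tt)))
round(cd$fractions, 3)
#>        high medium_high  medium_low         low
#>       0.088       0.029       0.206       0.676
cd$singleton_fraction
#> [1] 0.412

rt <- subsample_table(tt, depth = 100, seed = 1)   # rarefy, drop shallow
alpha <- alpha_diversity(rt)                       # Shannon, bits
compare_alpha(alpha, setNames(rt$metadata$sex, rt$metadata$sample_id),
              n_permutations = 999, seed = 1)
#>   group_a group_b observed_t p_raw p_adjusted
#> 1       F       M  -2.825815 0.028      0.028
```

Most detected species sit in the low-occupancy tier (67.6%, with 41.2%
singletons) while a small core (8.8%) is shared by more than 75% of
samples — the occupancy spectrum the generator is built to emulate.
Note the alpha comparison: this fixture has *no* sex effect, yet at 12
samples the permutation test dips below 0.05 — a reminder that
small-cohort p-values are noisy. The same computation at the full
72-sample default scale (see the acceptance script below) is
comfortably non-significant.

`run_pipeline(pipeline_config("fixture"))` chains all stages and
writes per-stage TSVs plus a `summary.json`;
`inst/scripts/run_pipeline.R` wraps it for the shell.

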
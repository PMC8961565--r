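# aarecruit

Genome-wide amino-acid and codon usage-bias analysis, and the inference
chain that turns usage bias into a model of the order in which amino acids
were recruited into early proteins.

## What it does, and for whom

For molecular-evolution researchers working with coding-sequence data, the
package computes per-species usage profiles and the downstream statistics
built on them:

* amino-acid usage `F_i = N_i / N_t` and codon usage `F_c = N_c / N_tc`
  (stop codons counted in the total; ambiguous codons and non-canonical
  residues excluded), plus the theoretical expectation `F_i^t = C_i / 61`
  from codon multiplicity — e.g. arginine's six codons predict 9.8% usage,
  far above what real proteomes show;
* GC-stratified **fold change** per codon,
  `FC = mean usage (GC >= 45%) / mean usage (GC < 45%)`;
* per-species usage **ranking** (20 = most used ... 1 = least used) with
  group-summed scores, and the coefficient of variation `CV = sd / mean`;
* Pearson usage **correlation** between codons or amino acids across
  species, with two-cluster extraction at `r > 0.5`, plus the crosstalk
  between amino-acid clusters and degenerate codon-family clusters;
* Spearman correlation of z-scored **physicochemical properties** (AAindex1
  flat files are parsed natively) and the hydrophobic/hydrophilic grouping;
* **species dendrograms** from usage vectors (correlation distance,
  average linkage), with Newick export and tree-agreement measures;
* **quasi-evolutionary time**: ICA of log codon usage + a minimum spanning
  tree, geodesic pseudotime from a max-GC root, and per-amino-acid
  gain/loss **trend classification** (`R^2 >= 0.5`);
* the **recruitment rules**: a deterministic, logged cascade producing the
  old/new amino-acid partition and one recruitment route per
  physicochemical group.

A seeded synthetic-cohort generator (`cohort_spec()` / `simulate_cohort()`)
plants known latent evolution time, GC drift and usage trends, so every
stage has a parameter-recovery test with no downloads. All user-facing
functions take and return tibbles and compose with the pipe; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate the default 60-species cohort (40 Bacteria, 10 Archaea,
10 Eukaryota; GC declining along latent evolution time; planted loss trends
on A, G, P, R, V, W and gains on F, I, K, N, Y), then run the full chain:

```r
library(aarecruit)
library(dplyr)

co <- simulate_cohort(cohort_spec(seed = 1))
cu <- cohort_usage(co, "codon")
au <- cohort_usage(co, "aa")
gc <- setNames(co$metadata$gc_percent, co$metadata$species_id)

fold_change(cu, gc) |>
  filter(codon %in% c("AAT", "AAC", "GCG", "TTA"))
#>   codon aa    is_stop mean_lt sd_lt mean_ge sd_ge    fc
#> 1 TTA   L     FALSE      2.42  0.34    0.98  0.43  0.41
#> 2 AAT   N     FALSE      3.9   0.67    1.41  0.7   0.36
#> 3 AAC   N     FALSE      1.34  0.46    3.16  0.48  2.36
#> 4 GCG   A     FALSE      0.95  0.38    2.78  0.6   2.93
```

A/T-ending codons (TTA, AAT) are depleted in high-GC species (FC < 1) and
their G/C-ending synonyms enriched (FC > 1) — the same asymmetry real
cohorts show between, say, AAT and AAC.

```r
pt <- order_pseudotime(cu, gc_percent = gc, seed = 1)
fit_trends(au, pt) |> filter(class != "neutral")
#>    amino_acid  slope r_squared class
#>  1 A          -1.51      0.795 lost
#>  2 F           1.89      0.837 gained
#>  ... (11 rows: exactly the planted lost/gained sets, R^2 near 0.8)
```

The trend fits recover the planted structure: usage is in percent, so a
slope of −1.5 means that amino acid loses 1.5 percentage points over the
full quasi-evolution span. Feeding the rank scores, trends and property
groups into the rule engine:

```r
rs <- rank_scores(rank_usage(au)) |> filter(group == "Total")
pg <- property_grouping(normalize_properties(
  simulate_property_table(200, seed = 1)))
recruitment_model(evidence_table(rs, fit_trends(au, pt), pg))
#> <recruitment_model>
#>   old: A, D, E, G, L, P, R, S, T, V
#>   new: C, F, H, I, K, M, N, Q, W, Y
#>   route (hydrophilic): K -> N -> Q -> H
#>   route (hydrophobic): I -> F -> Y -> C -> M -> W
```

The ten "old" amino acids are the prebiotic baseline minus isoleucine
(demoted: significantly gained usage) plus arginine (promoted:
significantly lost usage); tryptophan's loss trend is vetoed by the
UV-absorption rule. Every decision is in `$rationale`. The same model run
on the packaged `reference_evidence()` reproduces the published partition
and both routes.

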
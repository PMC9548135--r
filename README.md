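# contamsim

Simulation and benchmarking of contamination in low-input shotgun
metagenomics.

## The problem

When the DNA input to a metagenomic library drops to the sub-nanogram range
— sorted cells, biopsies, low-biomass swabs — background DNA from the
library-preparation reagents ("kitome") rivals or exceeds the template.
Benchmarking library kits and in silico decontamination methods in this
regime requires data where the truth is known: which reads come from the
sample, which from the reagents, and how much contaminating DNA was
introduced in absolute terms.

`contamsim` builds that ground truth in silico. It simulates the classified
read counts of a synthetic spike-in ("sequins") mock community — 83
components on 8 staggered twofold concentration tiers, GC 29.4–71.06%,
lengths 1929–9120 bp — measured across a dilution series
(5000…0.5 pg plus negative controls, two replicates) with kit-specific
contaminant pools, input-proportional endogenous contaminants, GC/length
amplification bias and finite-complexity duplication. On top of the
simulator it implements:

* **Compositional metrics** — total sum scaling, the Jensen-Shannon
  distance `JSD(p, q) = sqrt( [KL(p‖m) + KL(q‖m)] / 2 )` with `m = (p+q)/2`
  and base-2 logs (bounded in [0, 1]), fidelity and reproducibility as
  `1 − JSD`, proportion of designated reads, duplication rate, and the
  conversion rate `Q_lib · R_designated / (Q_input · E_primer^N_pcr)`.
* **Absolute contaminant quantification** against the spike-in scale:
  `mass = input · contaminant reads / sequins reads`, plus an endogenous
  contaminant screen (per-kit regression on log₁₀ input, BH-corrected,
  flagged at p.adj < 0.05 and R² > 0.55 in ≥ 4 kits), core/dominant
  contaminant catalogues and remaining-contamination curves.
* **Decontamination** — fivefold/tenfold-over-negative-control filtering,
  and frequency (slope −1 log–log model vs constant, F-CDF score) /
  prevalence (hypergeometric NC-enrichment tail) scores with
  frequency / prevalence / either thresholding.
* **Evaluation** — read-weighted confusion counts, precision/recall, a
  40-point threshold sweep on [0.1, 0.5] optimised for best recall under
  100% precision, JSD of the decontaminated profile to the actual signal,
  and a one-factor PERMANOVA (cross-checked against `vegan::adonis2`) for
  variance attribution.

## Worked example

```r
library(contamsim)

config <- default_run_config(seed = 1)
report <- run_pipeline(config, quiet = TRUE)
report
#> contamsim run report (seed 1, config 1f063f08)
#>   60 libraries, 5 kits; 250 evaluation rows
```

At 0.5 pg input the sonication-based kit is swamped by contamination while
tagmentation is barely touched — visible in the designated-read proportion
and in the spike-in mass estimates (the configured load medians are
15.59 pg for Son_Q and 0.01 pg for Tn5_V):

```r
subset(report$library_metrics, input_pg == 0.5 & kit %in% c("Son_Q", "Tn5_V"))
#>        library_id proportion_designated fidelity_sequins duplication_rate contaminant_mass_pg
#> 9  Son_Q_0.5pg_r1                0.0393            0.957            0.988             12.2217
#> 10 Son_Q_0.5pg_r2                0.0866            0.957            0.995              5.2767
#> 57 Tn5_V_0.5pg_r1                0.9579            0.957            0.996              0.0220
#> 58 Tn5_V_0.5pg_r2                0.9665            0.957            0.996              0.0173
```

Either-mode decontamination fully recovers the lightly contaminated
libraries (JSD to the actual signal ≈ 0) but cannot rescue the heavy,
highly varied ones even while removing ~90–97% of contaminant reads:

```r
subset(report$evaluation, input_pg == 0.5 & method == "either" &
         kit %in% c("Son_Q", "Tn5_V"))
#>         library_id precision recall jsd_before jsd_after
#> 49  Son_Q_0.5pg_r1         1  0.898      0.938     0.713
#> 50  Son_Q_0.5pg_r2         1  0.969      0.884     0.370
#> 249 Tn5_V_0.5pg_r1         1  1.000      0.129     0.000
#> 250 Tn5_V_0.5pg_r2         1  1.000      0.110     0.000
```

The kit explains the largest share of contaminant-composition variance, and
removing the five flagged endogenous genera (Escherichia, Gammaretrovirus,
Citrobacter, Mastadenovirus, Shigella — the set planted by the simulator)
collapses the input-attributable share:

```r
report$variance$kit
#> PERMANOVA: R2 = 0.452, pseudo-F = 5.151, p = 0.001 (999 permutations)
report$variance$input
#> PERMANOVA: R2 = 0.135, pseudo-F = 2.107, p = 0.042 (999 permutations)
report$variance$input_filtered
#> PERMANOVA: R2 = 0.052, pseudo-F = 0.746, p = 0.978 (999 permutations)
```

With `config$out_dir` set, `run_pipeline()` writes `profiles.tsv`,
`design.json`, `library_metrics.tsv`, `evaluation.tsv` and `report.json`.
A thin command-line front end is included at `inst/cli/contamsim.R`
(`simulate` and `pipeline` subcommands over the same functions).

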
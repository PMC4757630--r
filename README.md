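# foundertrace

Phylogeographic founder analysis of mtDNA HVS-I haplotypes and
Y-chromosome STR profiles in R.

## What it is for

Given haplotype samples from an assumed *source* region and a *sink*
region, founder analysis identifies the lineage types carried into the
sink by past migrations, dates each derived cluster, and estimates how
much each migration episode contributed to the present-day sink
population. The motivating system is the settlement of Island Southeast
Asia and the Pacific — testing, for example, whether a haplogroup's
history fits a Neolithic "out-of-Taiwan" dispersal at ~4.5 ka or older
postglacial movements — but the machinery applies to any source/sink
design.

The analysis chain, all implemented here:

* **Haplotype networks** — median-joining networks with per-character
  weights and an iterative STR reweighting scheme (weight 1 for the
  fastest locus, 10 for the slowest, iterated until the network is
  stable), and reduced-median networks for binary HVS-I data, with
  reticulations resolved in favour of faster characters recurring.
* **Rooting** — midpoint or outgroup-consensus rooting of the extracted
  minimum-cost spanning tree.
* **Founder identification** — candidate founders are source-observed
  states; the *f1*/*f2* criteria demand ≥1/≥2 source-side derived
  branches to guard against back-migration.
* **Dating** — the rho statistic ρ = m/n, Saillard's error
  σ² = Σ bᵢ² lᵢ / n², the star-equivalent effective sample size
  ñ = ρ/σ², and clock conversion (HVS-I: one mutation per 16,677 years;
  whole-mtDNA: 3,624; synonymous: 7,884; calibrated 19-locus Y-STR:
  4.08 × 10⁻⁵ per locus per year).
* **Migration-time inference** — a continuous-Poisson likelihood
  L(T) ∝ λ^m̃ e^(−λ) with λ = ñT/Q and m̃ = ñρ, scanned at 200-year
  intervals over 0–70 ka and partitioned over fixed event times
  (presets 0.5/4.5/8/50 ka for mtDNA, 0.5/4.5/8/20 ka for Y-STRs).
* **Rate calibration** — Y-STR average mutation rates from clades of
  externally known age, r = ρ/(age × n_loci).
* **Marker screening** — a five-point phylogeographic criteria test for
  candidate dispersal markers, plus Bayesian-skyline post-processing
  into expansion increments, onsets and peaks.
* **Simulation** — a two-deme generator with known migration pulses for
  parameter-recovery validation of every stage.

## Worked example

Simulate a two-deme world with a single migration pulse 4,500 years ago
and run the full founder analysis:

```r
library(foundertrace)

sc  <- sim_scenario(data.frame(time_years = 4500, fraction = 1),
                    n_source = 300, n_sink = 150, seed = 42)
sim <- simulate_two_deme(sc)
fit <- founder_analysis(sim$data)   # HVS-I clock, f1 criterion, mtDNA preset
fit
```

```
Founder analysis (mtDNA HVS-I, criterion f1)
  network: 71 nodes, cost 700 ; root ' ref '
  founders: 5 clusters, 150 sink samples
  scan mode: 4600 years BP
  partition fractions:
0.5 ka 4.5 ka   8 ka  50 ka 
 0.125  0.711  0.164  0.000 
```

The aggregate migration-time scan peaks at 4,600 years BP — within one
grid step of the simulated pulse at 4,500 — and the four-migration
partition assigns about 70% of the sink lineages to the 4.5 ka
Neolithic event, with the remainder spilling into the neighbouring
0.5 ka and 8 ka windows, the expected behaviour for clusters whose
Poisson mutation counts happen to run young or old.  `coef(fit)`
returns the fraction vector, `summary(fit)` the per-founder table
(ρ, σ, ñ, age), and `plot(fit)` the scan profile.

Screening a candidate dispersal marker against the five criteria:

```r
ages <- marker_ages(clade_age = 5.2, ancestor_age = 11.8,
                    founder_age_sink = 4.4,
                    founder_age_extended_source = 4.2,
                    expansion_onset_source = 7.5,
                    expansion_onset_sink = 5.2)
evaluate_criteria(ages)
```

```
Dispersal-marker criteria: 5 / 5 passed
  (a) pass
  (b) pass
  (c) pass
  (d) pass
  (e) pass
```

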
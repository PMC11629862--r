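# replimet

Bacterial chromosome replication continuously changes the copy number of
every locus: in a population dividing every τ minutes, a gene at fractional
ori–ter position *p* is present on average in

    n(p) = 2^(((1 − p)·C + D)/τ)

copies (C = replication period, D = division delay), so the log2 ori:ter
coverage ratio — the peak-to-trough ratio (PTR) — equals C/τ. Whenever the
division time changes, the *relative* dosage of genes at different
positions changes too, enzyme abundances follow, and metabolite pools are
pushed off their steady state. `replimet` implements the full chain of
computation behind this idea, for quantitative modelers of bacterial
physiology and genome evolution:

* **replication arithmetic** — average and per-cell locus copy numbers,
  log2 PTR, transcript dosage coupling (`average_copy_number()`,
  `instantaneous_copy_number()`, `log2_ptr()`);
* **metabolic control analysis** — finite-change flux amplification
  `J_r/J_0 = 1/(1 − Σ C_Ei^J (r_i−1)/r_i)`, metabolite responses, the
  replication-coupled flux response and its co-located limit, numerical
  control coefficients with summation-theorem checks
  (`flux_amplification()`, `control_coefficients_from_linlog()`);
* **a linlog steady-state engine** — rates `v = E(A′ + B′ log x + C′ log c)`
  with the analytic steady state
  `log x = −(N E B′)⁻¹(N E A′ + N E C′ log c)`, plus a packaged
  34-reaction / 26-metabolite central-carbon benchmark
  (`linlog_steady_state()`, `carbon_fixture()`);
* **homeostasis-driven optimization** — the objective
  `F = mean_i(σ_i/μ_i)` (average CV of metabolite concentrations across
  division times; fitness ∝ 1/F), optimized over gene positions or promoter
  strengths (`objective_F()`, `optimize_positions()`,
  `optimize_promoters()`);
* **gene-order evolution** — a population simulation with inversions,
  translocations, median-filter selection and fitness-proportional
  resampling, tracking pure and mixed gene clusters (`evolve()`,
  `detect_clusters()`);
* **genomic statistics** — the proximity score `PS = −log2 Q1` of pooled
  within-module gene distances, PTR estimation from coverage windows, and
  the PS ~ PTR association tests (`proximity_score()`,
  `ptr_from_coverage()`, `ps_ptr_association()`);
* **synthetic data generators** for every input: coverage profiles,
  annotated genomes with planted clustered/scattered modules, and random
  valid linlog models (`simulate_coverage()`,
  `generate_annotated_genome()`, `random_linlog()`).

The methods vignette (`vignettes/replication-homeostasis.Rmd`) documents the
model, parameter choices, numerical decisions and limitations.

## Worked example

```r
library(replimet)

# dosage at fast vs slow growth (C = 40, D = 20 min)
average_copy_number(replication_params(40, 20, 20), 0)   # 8.0  copies at ori
average_copy_number(replication_params(40, 20, 20), 1)   # 2.0  copies at ter
log2_ptr(replication_params(40, 20, 20))                 # 2.0  = C/tau

# per-cell view: three nested forks put ori and ter at 4:1
instantaneous_copy_number(c(0.9, 0.2), 0.01)             # 4
instantaneous_copy_number(c(0.9, 0.2), 0.99)             # 1

# control coefficients of the carbon benchmark obey the summation theorems
cc <- control_coefficients_from_linlog(carbon_fixture())
sum(cc$fcc)                 # 1.0000000
max(abs(colSums(cc$ccc)))   # ~1e-09

# co-located genes buffer a division-time switch; scattered genes do not
cfg <- objective_config(carbon_fixture())
objective_F(rep(0.3, 34), cfg)            # ~1e-16: perfect homeostasis
set.seed(1); objective_F(runif(34), cfg)  # 0.14:  scattered layout breaks it
```

The numbered scripts under `analysis/` run the full experiments and write
tables under `results/`. Their printed output on this machine:

* `01_copy_number.R` — dosage profiles; growth rates 2.079/h (τ = 20 min)
  and 0.347/h (τ = 120 min); per-cell ori:ter ratios 4:1 (three forks) and
  2:1 (one fork).
* `02_toy_scan.R` — two-enzyme scan: CV = 0 on the diagonal (co-located
  genes), 0.413 at maximal ori/ter separation.
* `03_mca_report.R` — ΣFCC = 1.00000000, max |ΣCCC| = 1.3e-09; flux
  response for τ 60→30 min: 1.58 scattered vs 1.78 co-located.
* `04_optimize_positions.R` — 20 matched runs: mean converged F = 3.0e-07
  (positions) vs 3.2e-03 (promoters), paired one-sided p = 0.037; genes
  collapse into 1–5 position clusters.
* `05_evolve.R` — population 2000, 2000 generations: fittest-strain fitness
  11.7 → 19.3 (1.6-fold), 2 pure and 4 mixed clusters in the fittest
  strain.
* `06_genomic_stats.R` — PTR recovery: noiseless exact, MAE 0.0017 under
  Poisson noise at depth 100; mean PS rises monotonically with planted
  clustering θ (−17.0 → −9.6); PS predicts log2 PTR across 60 simulated
  species (slope 0.14, adj R² = 0.59).

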
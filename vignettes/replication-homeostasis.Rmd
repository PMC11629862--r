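---
title: "Replication-driven gene dosage, metabolite homeostasis and the evolution of gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication-driven gene dosage, metabolite homeostasis and the evolution of gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model chain

`replimet` links three layers of bacterial cell biology into one testable
pipeline:

1. **Replication sets gene dosage.** In a population growing with division
   time $\tau$, a locus at fractional ori–ter position $p$ ($p=0$ at the
   origin, $p=1$ at the terminus, each replichore mapped independently onto
   $[0,1]$) is present on average in
   $n(p) = 2^{((1-p)C + D)/\tau}$ copies, where $C$ is the chromosome
   replication period and $D$ the delay between termination and division
   (both in minutes). Two consequences follow directly: the log2 ratio of
   ori to ter coverage — the peak-to-trough ratio (PTR) familiar from
   metagenomics — equals $C/\tau$ exactly, and the *relative* dosage of two
   loci changes whenever $\tau$ changes. Per cell, dosage is integer-valued:
   with nested replication rounds a locus has $2^k$ copies where $k$ counts
   the rounds whose forks have passed it, so an ori-adjacent and a
   ter-adjacent locus sit at ratio 4:1 with three active forks but 2:1 with
   one.

2. **Dosage perturbs metabolism.** Assuming transcription (and hence enzyme
   abundance) proportional to copy number, a switch of division time from
   $\tau_0$ to $\tau_k$ multiplies the abundance of the enzyme encoded at
   position $p$ by
   $r(p) = 2^{((1-p)C+D)(\tau_0-\tau_k)/(\tau_k\tau_0)}$.
   Metabolic control analysis then predicts the flux and metabolite
   response: the flux amplification factor
   $J_r/J_0 = 1/(1 - \sum_i C^J_{E_i}(r_i-1)/r_i)$ and the single-enzyme
   metabolite response implemented in `flux_amplification()` and
   `metabolite_response_single_enzyme()`. When all genes of a pathway share
   one position, every $r_i$ is equal, the flux is rescaled by that common
   dosage factor (`clustered_flux_response()`), and metabolite
   concentrations do not move at all — perfect homeostasis. When genes are
   scattered, the $r_i$ differ and metabolite pools shift; enzymes with
   negligible flux control can still displace a metabolite pool arbitrarily
   far, which is what makes the perturbation biologically consequential.

3. **Selection on homeostasis rearranges genes.** Quantifying "how badly is
   homeostasis broken" as
   $F = \frac{1}{m}\sum_{i=1}^m \sigma_i/\mu_i$ — the average coefficient
   of variation of steady-state metabolite concentrations across a set of
   division times — turns gene order into a fitness-relevant trait
   (fitness $\propto 1/F$). The package explores this objective three ways:
   a closed-form two-enzyme toy model (`position_scan()`), direct local
   optimization of gene positions or promoter strengths
   (`optimize_positions()`, `optimize_promoters()`), and a population
   simulation of gene-order evolution by inversions and translocations
   (`evolve()`).

## The linlog steady-state engine

All metabolic computations run on linlog models: each rate is
$v = E\,(A' + B'\log x + C'\log c)$ with $E$ the enzyme level, $x$ the
variable and $c$ the external metabolite concentrations, and the primed
parameters derived once from a reference state
($A' = (J^0/E^0)(1 - B\log x^0 - C\log c^0)$, etc., natural logarithms
throughout — `derive_parameters()`). Linearity in $\log x$ gives the
analytic steady state
$\log x = -(N E B')^{-1}(N E A' + N E C' \log c)$ (`linlog_steady_state()`),
which is the entire numerical engine: no ODE integration is performed
anywhere, and a single layout evaluation costs one small linear solve per
division time. Elasticities are fixed parameters, so the format assumes
substrate/product dependencies do not change across growth rates — a known
limitation with a usefully wide validity range around the reference point.

Two algebraic identities carry the scientific argument and are
property-tested on randomly generated models: evaluating the rates at the
reference state returns $J^0$ exactly (the parameters are built that way),
and multiplying *all* enzymes by a factor $r$ leaves $x_{ss}$ unchanged
while scaling fluxes by $r$ — the uniform-scaling homeostasis that
co-located genes inherit automatically.

**The carbon benchmark.** `carbon_fixture()` ships a deterministic,
code-generated model of E. coli central carbon metabolism — glycolysis,
pentose-phosphate pathway, TCA cycle, glyoxylate shunt, acetate
excretion/import — sized at exactly 34 reactions, 26 variable metabolites
and 2 external metabolites (glucose, acetate). Published elasticity values
and reference fluxes for this network are not available, so the fixture is
normalized ($E^0 = x^0 = c^0 = 1$), uses unit substrate/product
elasticities, and carries a hand-balanced strictly positive flux vector in
the null space of the stoichiometry (glucose uptake 10, a 7:3
glycolysis/PPP split, glyoxylate shunt flux 2, acetate overflow 4 against
an import of 1, biosynthetic drains on R5P and 2-oxoglutarate). It is a
benchmark for *systemic response structure* — control coefficients,
summation theorems, homeostasis breaking — not a quantitative model of
measured metabolite levels, and absolute concentrations from it are not
comparable to experiments.

**Numerical choices.** Control coefficients are estimated by central finite
differences with step $10^{-4}$ in log-enzyme space; the linlog steady
state is smooth, and this recovers the summation theorems
($\sum_i C^J_{E_i} = 1$, $\sum_i C^S_{E_i} = 0$) to well below $10^{-6}$.
"Pathway flux" means the flux of a designated output reaction (pyruvate
kinase in the fixture), configurable per call. A singular steady-state
matrix $N E B'$ is treated as an invalid/lethal phenotype: the objective
returns a large sentinel value ($10^6$) instead of aborting, so optimizers
and the evolutionary simulation simply avoid such layouts.

## The homeostasis objective and its optimizers

`objective_F()` evaluates a layout over the division-time set
$\tau \in \{20, 30, 40, 50, 70, 90, 120\}$ minutes by default — fast to
slow growth for an E. coli-like organism — with $C = 40$, $D = 20$ min.
$C$ and $D$ for these experiments are conventional fast-growth values, kept
fixed across $\tau$ (the model exposes $D$ but nothing in the framework
requires it to covary with $\tau$). The coefficient of variation uses the
sample standard deviation ($n-1$ denominator). $F = 0$ exactly when the
metabolite vector is identical at every division time, which for this model
happens iff all enzymes scale uniformly.

Optimization uses `stats::nlminb` (box-constrained quasi-Newton) with
tolerances `abs.tol = 1e-15`, `xf.tol = x.tol = 1e-12`, step bounds
$[10^{-6}, 1]$, and iteration/evaluation caps of $10^6$ by default. The
choice of optimizer is not load-bearing: the claims tested are descent
(final $F \le$ starting $F$) and the *ordering* between position and
promoter optimization, not a specific optimum. Two practical notes:

* In promoter mode the objective is invariant under a uniform rescaling of
  all multipliers $k_i$ (enzyme ratios are unchanged), so the optimizer can
  drift along this flat direction for a very long time without the outcome
  changing. The desk-scale experiments in this package therefore run with
  `nlminb_control(iter.max = 600, eval.max = 30000)`; position runs reach
  $F \sim 10^{-7}$ and promoter runs stall around $F \sim 10^{-4}$ under
  the same budget, an ordering three orders of magnitude wide.
* Promoter optimization cannot reach $F = 0$ when genes sit at different
  positions: a static multiplier cannot cancel the $\tau$-dependence of
  copy-number *ratios* between positions. Only moving genes together can.
  This is the algebraic content behind the position-vs-promoter comparison.

Starting layouts are uniform random on $[0,1]$ per gene with recorded
seeds; promoter runs start from neutral multipliers ($k = 1$) at the same
fixed random layouts, so the two modes are compared on matched problems.

## The evolutionary simulation

`evolve()` implements the mechanistic counterpart: a population of circular
genomes with 600 loci spaced 10 kb apart (ori fixed, ter initially
antipodal, 34 target genes at random loci, the rest neutral). Per
generation each genome undergoes at most one event: an inversion with
probability $p_{inv}$ (block length $\max(1, \mathrm{round}\,N(5, 9))$ —
variance 9, sd 3) or a translocation with probability $p_{inv}/2$ (block
length $\max(1, \mathrm{round}\,N(3, 9))$). Blocks never contain the ori or
ter markers; chromosome architecture is additionally protected by assigning
sentinel minimal fitness to genomes whose minimum ori–ter arc falls below
75% of its initial value. Selection removes variants *strictly below* the
median fitness (ties at the median survive, so selection can never empty
the population), then resamples to constant population size with
probability proportional to fitness. Fitness is computed once per unique
arrangement and cached — numerically identical to recomputation, and the
reason population sizes in the thousands are tractable. The whole
trajectory is a deterministic function of the seed.

Cluster bookkeeping follows two definitions: *pure clusters* are maximal
runs of at least two consecutive target genes; *mixed clusters* are maximal
stretches with target genes at both ends, at least one internal non-target
locus, and no internal non-target run longer than two. Runs are evaluated
on the circle cut at the origin (a cluster may not span ori, which would
conflate the two replichores' proximal ends); the ter marker counts as an
ordinary non-target locus, breaking pure runs and consuming mixed-gap
budget like any neutral gene.

The simulations shipped in `analysis/` and exercised by the test suite run
at desk scale — population 2000 for 2000 generations, or smaller for
property tests — rather than the $10^5 \times 10^5$ scale such experiments
can in principle use. At this scale the qualitative outcomes (monotone
fitness gain of the fittest strain; emergence of at least one pure or mixed
cluster) are reproducible across seeds, while exact cluster counts and
sizes remain seed- and scale-dependent and are deliberately not asserted.

## Genomic statistics

`proximity_score()` summarizes how compactly functionally related genes are
arranged: pool the distances between all unordered within-module gene
pairs, take the first quartile $Q_1$, and report
$PS = -\log_2 Q_1$. Distances are measured between gene midpoints as the
minimum arc on the circular chromosome — midpoints avoid gene-length
artifacts, and the circular minimum respects topology; a start-anchored
dialect is available via the `anchor` argument since the convention is not
canonical. $Q_1$ uses the standard linear-interpolation quantile (R type
7), recorded in the result's attributes. $Q_1$ is floored at 1 nt so
coincident midpoints cannot produce an infinite score.

`ptr_from_coverage()` is the matching coverage statistic: the log2 ratio of
mean read depth in 50-kb windows centered on ori and ter, deliberately
unnormalized. `ptr_tests()` applies the species-level decision rules:
one-sided one-sample t-tests of mean log2 PTR > 0 (replication activity)
and > 1 (overlapping rounds; $p \le 0.01$ flags a mero-oligoploid species),
with at least five libraries required per species. `ps_ptr_association()`
closes the loop with an OLS of log2 PTR on PS (species- or genus-level
after averaging) plus a two-group comparison of PS between mero-oligoploid
species and the rest.

## What the synthetic data does and does not emulate

Every pipeline input can be generated in code, so the full chain runs
without downloads:

* `simulate_coverage()` draws per-position counts (Poisson by default;
  negative binomial available because real coverage is overdispersed —
  Poisson is kept as the default for determinism at fixed seeds) around the
  dosage-model expectation. The two 50-kb windows are generated flat at
  their center dosage ($p = 0$ and $p = 1$): a window is about 1% of a
  replichore, so the within-window gradient is second-order, and the flat
  construction makes the noiseless mean-ratio estimator recover $C/\tau$
  exactly rather than with an $O(\text{window}/\text{arm})$ bias. What it
  does not emulate: mappability artifacts, GC bias, strain mixtures — so a
  passing recovery test validates the estimator's statistics, not its
  robustness to real-library pathologies.
* `generate_annotated_genome()` plants each module as a contiguous block
  with probability $\theta$ and scatters it otherwise, on a slot grid that
  guarantees non-overlapping genes. It produces clean, single-chromosome,
  gap-free annotations: real genomes add operon rearrangements, mobile
  elements and horizontally transferred modules the generator does not
  model.
* `random_linlog()` builds chain-with-branches networks whose positive
  reference flux exists by construction, with unit-magnitude jittered
  elasticities. These are well-conditioned by design; real metabolic
  networks can sit much closer to singularity.

Passing tests on these generators therefore demonstrate internal
consistency of the method chain under its own assumptions — proportionality
of expression and copy number, fixed elasticities, dosage as the only
coupling between growth rate and enzyme levels — not that the same effect
sizes would be measured in any particular organism.

## Known limitations

* Expression is strictly proportional to copy number; regulatory buffering
  (e.g. supercoiling-mediated) would shrink every effect size.
* The linlog engine has no dynamics: only steady states are compared, and
  division-time changes are treated as quasi-static.
* The evolutionary simulation allows at most one rearrangement per genome
  per generation and excludes ori/ter from rearranged blocks; both are
  conventions, stated rather than derived.
* The carbon fixture's parameters are normalized placeholders on a real
  topology; its control-coefficient *values* are fixture properties, not
  predictions about E. coli.
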
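---
title: "From GBS genotypes to demographic inference: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GBS genotypes to demographic inference: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsabc)
```

gbsabc analyses diploid biallelic SNP matrices from
genotyping-by-sequencing (GBS) of structured populations, with the medaka
hybrid-zone system as its design case: several deeply diverged groups
(N.JPN, Tajima-Tango, Honshu, Kyushu on the S.JPN side) whose history —
simple divergence versus admixture origin of the boundary group — is the
inferential target. This vignette documents the models, the conventions,
and the places where a genuine design choice had to be made.

## Containers and conventions

A `gbs_genotypes` object stores alt-allele dosages (0/1/2, `NA` missing)
for individuals x loci, plus chromosome/position/ref/alt per locus and an
optional `total_length`: the surveyed sequence length in bp *including
invariant sites*, which is the denominator for per-bp nucleotide
diversity. "Allele frequency" always means alt-allele frequency
internally; major/minor conversion happens only in reporting. Positions
are 1-based and must increase strictly within a chromosome; loci must be
strictly biallelic SNPs (multi-allelic VCF records either error or are
dropped, never split — splitting would create duplicate positions).

The population map is a three-column table (individual, population,
group); every population belongs to exactly one group. Groups are the
units of the genetic statistics; populations are the units of the locus
filter, matching how GBS pipelines define datasets.

## Locus filtering

`filter_loci(gm, pm, p, r)` keeps a locus genotyped in at least a fraction
`r` of the individuals of each of at least `p` populations — the genotype
matrix analogue of the Stacks `populations -p/-r` step used to assemble
GBS datasets. The fraction comparison is `>=` with a 1e-12 guard so that
exact rational call rates (7 of 10 individuals vs `r = 0.7`) are never
lost to floating-point representation. A `by = "group"` switch counts at
the group level instead, for datasets defined as "sequenced in one or more
populations in each group". The filter is idempotent and never increases
the locus count.

## Summary statistics of groups and individuals

Per group the package reports: the mean number of genotyped individuals
per variant site; the number of variant sites (variable over *all* groups
jointly — the convention that makes the column identical across rows of a
summary table); polymorphic sites within the group; private sites (an
allele present in this group and absent in every other); mean major-allele
frequency and mean observed heterozygosity over variant sites with at
least one call; and nucleotide diversity
$\pi = \frac{1}{L}\sum_s \frac{n_s}{n_s-1}\bigl(1 - p_s^2 - (1-p_s)^2\bigr)$
with $n_s$ the called allele count at site $s$ and $L$ the total surveyed
length. The $n/(n-1)$ factor is the small-sample unbiased correction; the
tests verify it against a brute-force enumeration of all allele pairs.
Reported standard errors are across-site ($\sigma/\sqrt{\#sites}$ for the
means; the corresponding $\sqrt{\#sites}\,\sigma/L$ for the diversity
sum). Missing calls are excluded everywhere; sites with fewer than two
called alleles in a group cannot contribute a gene diversity and are
skipped in that group's sums. An individual's diversity is simply its
heterozygous-call count over `total_length`; an all-missing individual
yields 0 with a warning rather than an error, so batch runs survive
degenerate inputs.

`ne_from_pi()` inverts $\pi = 4 N_e \mu$ under neutral equilibrium; the
default $\mu = 10^{-9}$/site/generation with one-year generations is the
standard calibration for this system.

## LD pruning

`ld_prune()` follows the `--indep-pairwise <window> <step> <r2>` scheme:
windows are physical (`window_kb`, default 12.5 kb — the quoted option's
first argument is read as kb), anchored at every `step`-th retained
variant (default 5), and within a window any retained pair with genotypic
$r^2 >$ `r2_max` (default 0.2) is broken by removing one member *uniformly
at random* under the configured seed. Uniform-random removal is the
package's default because that is how the pruning step it reproduces was
described; plink's own lower-MAF removal is available as
`removal = "maf"`. Pairs with undefined $r^2$ (a monomorphic member on the
pairwise-complete individuals) cannot exceed the threshold and are
skipped. `prune_audit()` re-enumerates the same windows on the output and
must find nothing above the threshold — the property the tests assert on
correlated data; which member survives may depend on the seed, but never
whether the property holds.

## Fixed-allele sharing

For three groups, a SNP where each group is fixed (frequency exactly 0 or
1 over called alleles) and exactly two groups agree is assigned to that
pair's sharing state; sites with any unfixed group, a three-way agreement
(invariant in the trio), or too few called alleles (fewer than
`min_alleles = 2`) are unclassified. Exact fixation is the operative
definition; a relaxed margin (`delta`) exists for exploration but is off
by default. Counts are tabulated per chromosome and overall, with
proportions over classified sites; the classification is equivariant under
relabelling the groups, which the tests check by permutation.

## The coalescent SNP simulator

`simulate_snps()` draws, for each locus independently, a coalescent
genealogy of all sampled lineages under a demography of constant-size
diploid populations joined (backward in time) by split events and
admixture pulses, then places exactly one mutation on a branch chosen with
probability proportional to branch length. Because every branch subtends
between 1 and n−1 samples, every locus is polymorphic in the pooled
sample — the behaviour of ascertained GBS SNPs, and the reason no
mutation rate enters the simulation: only ratios of times to sizes are
identifiable, and natural units (generations, diploids) are used
throughout with the year calibration applied only at reporting.
Diploids are consecutive haplotype pairs; mating is random within a
population. Coalescence within a population of size $N$ happens at rate
$k(k-1)/(4N)$ for $k$ lineages; times between demographic events are
exponential competing clocks across populations.

One subtlety worth recording: conditioning on exactly one mutation per
genealogy *length-biases* the raw derived-allele spectrum. The probability
that the mutation subtends $i$ of $n$ samples is
$\mathbb{E}[L_i/L_{tot}]$, not
$\mathbb{E}[L_i]/\mathbb{E}[L_{tot}] \propto 1/i$ — short trees carry
relatively more singleton length, so singletons are over-represented
(visibly so at a few thousand loci). The neutral $1/i$ law is recovered by
weighting each locus by its total tree length, which the simulator exports
(`tree_length`); the validity tests check the weighted spectrum by
chi-square and the mean TMRCA against the closed form
$\sum_k 4N/(k(k-1))$.

## Scenarios and priors

`build_scenarios()` returns the four competing histories of the boundary
group plus the two-deme split model. In all four, the N.JPN-side and
S.JPN-side stems diverge from the ancestor at `t3` and Honshu diverges
from Kyushu at `t2`:

* **I** — Tajima-Tango splits from N.JPN at `t1`.
* **II** — Tajima-Tango is created at `t1` by admixture, tracing to N.JPN
  with probability `r` and to Honshu with `1-r`.
* **III** — N.JPN splits from Tajima-Tango at `t1` (the boundary group is
  the stem).
* **IV** — as III, but at `t1` the Tajima-Tango stem also receives the
  Honshu pulse: each stem lineage stays with probability `r`, traces to
  Honshu with `1-r`, applied before the N.JPN merge at the same time so
  sampled N.JPN is unaffected.

The verbal description of the admixture scenarios underdetermines the
topology (II and IV read almost identically); the package's reading makes
II the admixture variant of I and IV the admixture variant of III, which
is the only assignment that (a) uses exactly the published parameter set
per scenario and (b) degenerates continuously: II collapses to I and IV to
III as `r` approaches 1. `r` is the non-Honshu fraction, consistent with a
high posterior `r` meaning a small Honshu contribution. The collapse
property is tested (IV at `r = 0.999` is statistically indistinguishable
from III within Monte-Carlo error).

Priors (`default_priors()`): truncated normals on the four present-day
sizes (e.g. N.JPN ~ Normal(450,000; 500,000) on [10,000, 3,000,000]),
Uniform(10,000; 30,000,000) on the ancestor, Uniform(10; 4,000,000) on
`t1`, `t2`, Normal(4,000,000; 5,000,000) truncated to
[1,000,000, 30,000,000] on `t3`, Uniform(0.001, 0.999) on `r`, under the
joint constraints `t3 > t2`, `t3 > t1`, `t2 >= t1`. Truncation and the
constraints are enforced by rejection-resampling (an error fires after
10,000 consecutive all-rejected rounds, guarding near-zero-mass constraint
sets). The two-deme model uses Saga-deme priors with a
Uniform(1,000; 4,000,000) split time.

## The ABC engine

**Summary statistics.** A `stat_layout()` fixes the vector: per group, the
proportion of loci with null (zero) gene diversity and the mean gene
diversity across polymorphic loci; per pair, the proportion of null Nei
distances and the variance of the non-null ones; per (admixed, parent 1,
parent 2) trio, the proportion of null admixture estimates
$(p_{adm}-p_2)/(p_1-p_2)$, the mean and variance of the non-null
estimates, and the mean over all loci with a defined estimate. "Null"
means exactly zero. Undefined admixture estimates (parental frequencies
closer than `adm_tol = 1e-9`) are excluded from every aggregate — the
reference tools leave this edge unstated, so the package picks one rule
and applies it identically to observed and simulated data. An infinite
Nei distance (no shared allele) is capped at `nei_cap = 10` to keep
variances finite. Degenerate aggregates (no polymorphic loci, fewer than
two non-null values) are reported as 0 so vectors always align.

**Rejection.** Distances are Euclidean on per-statistic standardized
vectors; the standardization constants are the standard deviations across
the whole reference table (applied to the observed vector too;
zero-variance statistics are dropped as uninformative). The closest
`ceiling(tolerance * N)` records are accepted; 1% is the study-standard
tolerance.

**Regression adjustment.** Accepted records get Epanechnikov weights
$1-(d/d_{max})^2$ with the largest accepted distance as bandwidth; each
parameter is mapped to an unbounded scale by a logit on its prior bounds
(respecting bounded support without replicating any undocumented transform
constant), regressed on the standardized statistics by weighted least
squares, and replaced by its fitted value at the observed vector plus its
residual; back-transformation clamps adjusted values to the prior support.
Collinear statistics contribute zero slope; a singular design falls back
to the unadjusted sample with a warning. Point estimates are the weighted
mean (the convention the reported tables use), median and density mode,
with central 95% weighted quantile intervals. On the conjugate-Gaussian
toy (θ ~ N(0,1), s = θ + N(0, 0.1)) the machinery reproduces the analytic
posterior mean within Monte-Carlo error and lowers RMSE relative to plain
rejection — both are acceptance-tested.

**Scenario choice.** The direct estimator is the scenario share among the
`n_closest` records (default 500) with a normal-approximation binomial CI.
The logistic estimator fits a weighted multinomial logistic regression of
the scenario label on the standardized statistics over the accepted set
and evaluates it at the observed vector, with delta-method CIs from the
coefficient covariance; an unstable fit (separation) is refitted with a
small ridge penalty under a warning, and a single-scenario accepted set
returns degenerate probabilities with a warning.

**Accuracy metrics.** Over pseudo-observed datasets $j$ with truth
$\theta_j$ and posterior draws $\theta^*_{jk}$ (weights $w_k$):
RRMISE $=\sqrt{\operatorname{mean}_j \sum_k w_k((\theta^*_{jk}-\theta_j)/\theta_j)^2}$,
RMeanAD $=\operatorname{mean}_j \sum_k w_k|\theta^*_{jk}-\theta_j|/|\theta_j|$,
RRMSE $=\sqrt{\operatorname{mean}_j((\hat\theta_j-\theta_j)/\theta_j)^2}$
with $\hat\theta_j$ the weighted posterior mean. These definitions are
this package's contract (the reference implementation does not publish
its formulas); truths come from the prior or from a supplied posterior,
test datasets with a true value of exactly zero are excluded from relative
metrics with a warning, and 100 test datasets is the default.

**Scaled reporting.** SNP-mode posteriors are scale-free, so two reporting
routes exist: non-scaled (simulation units) and scaled — each accepted
draw's sizes and times divided by that draw's own mean deme size and
multiplied by an observed mean effective size (from `ne_from_pi()` on the
data, or supplied). `scale_parameters()` performs the exact, invertible
unit conversion; proportion parameters (prior support inside [0,1]) are
never scaled. `run_out_of_nk()` reports both routes; the study design it
mirrors preferred the scaled route for deme samples and the non-scaled one
for the four-group analysis.

## Synthetic data: what it does and does not emulate

`study_template()` fixes the study conditions: `"hz2"` — four groups of
five populations with one diploid each, 1,014 SNPs, generated under
scenario III with the analysis' own posterior-mean parameters as truth;
`"local"` — two demes of six diploids, 698 SNPs, truth split 510,000
generations; `"popstat"` — 2,453 SNPs with a 45,968 bp surveyed length for
summary-statistics work. Missingness defaults to 0 (the post-filter
datasets these emulate are essentially complete); when requested it is
uniform over cells, with an optional per-locus Beta-distributed dropout
mode because real GBS missingness is locus-structured. What the generator
deliberately does *not* emulate: within-locus linkage and recombination
(loci are unlinked single sites), genotyping error, population growth or
bottlenecks (constant sizes by assumption), and the reduced within-stock
diversity of laboratory lines. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to those
real-data features.

## Problem sizes and numerical choices

The test suite runs the recovery experiment at 50,000 simulations for the
single-scenario table (1,000 loci, 1% tolerance, 20 replicate datasets
sharing the table — the estimator, not the table, is what varies across
replicates) and two 10,000-row tables for model choice; the acceptance
script uses the workflow defaults (10,000-row tables, eight
replicates/trials), sizes chosen so a full run completes in minutes on one
CPU while leaving the million-simulation regime available through the same
interfaces. Other numerical choices collected in one place: dosage
comparisons are exact integers; the `>=` call-rate guard is 1e-12; the
Nei cap is 10; the admixture-denominator tolerance is 1e-9; the logit
transform squeezes values off the prior boundary by 1e-9 before taking
logs; weighted quantiles are of the inverse-CDF type; the weighted mode
uses a Gaussian kernel density with default bandwidth on the raw sample.

## Known limitations

Model choice between scenarios III and IV is intrinsically hard when `r`
is near 1 (they coincide in the limit); the direct and logistic estimators
can legitimately disagree there, as they did in the system this package
models. The regression adjustment assumes local linearity of the
parameter-statistic relationship within the accepted neighbourhood; at
very coarse tolerances the logit back-transform can pile adjusted draws
near prior bounds. The per-locus independence assumption means LD pruning
should precede inference on real data. And the accuracy-metric formulas,
while standard in form, are this package's own contract rather than a
reimplementation of any specific tool's undocumented definitions.
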
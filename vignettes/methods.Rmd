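---
title: "Models and methods behind tempsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tempsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempsel)
```

tempsel analyzes a temporal before/after-intervention design: an
affected and a control population sampled in years straddling an
environmental remediation, genotyped at one candidate locus and a panel
of neutral microsatellites, with candidate-gene read counts and water
chemistry on the side. This vignette documents the models, the
estimator conventions, the parameters that matter, and the reasoning
behind the choices that were genuinely open.

## The two-deme Wright–Fisher model

Two diploid demes of constant sizes $N_1, N_2$ reproduce in discrete,
non-overlapping generations (the motivating species breeds annually, so
one generation is one year). The life cycle for each offspring slot in
deme $i$ at generation $t$ is fixed as **migration → selection →
mating**:

1. a source deme $j$ is chosen with probability $m_{ij}$ (backward,
   destination-based migration; rows of $M$ sum to 1 — this matches how
   field studies report "migration rate from B into A");
2. two parents are drawn from deme $j$, independently and with
   replacement, with probability proportional to the current epoch's
   viability $V^{(j,e)}_{uv}$ of their candidate genotype $\{u, v\}$;
3. each parent transmits one uniformly chosen allele per locus (all
   loci unlinked — the candidate gene and the microsatellites are on
   independent chromosomes as far as this model is concerned);
4. microsatellite alleles mutate by ±1 repeat with probability $\mu$
   per locus per generation (stepwise mutation model, direction
   uniform, reflecting at a floor of 1 repeat). The candidate locus
   does not mutate: its six observed alleles over a twelve-year study
   make mutational input negligible on this time scale.

The epoch is `before` for cohorts $t \le$ `switch_generation` and
`after` beyond it; the fitness map is a per-deme, per-epoch table over
genotype categories or explicit allele pairs, with every unnamed
genotype at viability 1.

Because the life-cycle order is fixed, the expected allele-frequency
recursion is available in closed form and is implemented independently
as `deterministic_trajectory`: within each source deme the
post-selection gamete frequencies are
$p^\*_u = p_u (Vp)_u / (p^\top V p)$, and migration mixes them as
$p' = M p^\*$. The stochastic simulator must agree with this recursion
in expectation, and the test suite checks exactly that (200 replicates
at deme size $10^4$, agreement within 3 Monte-Carlo standard errors at
every sampled generation). Sampling within a generation is without
replacement, as in a field collection.

All randomness flows from one integer seed per configuration; identical
configurations produce byte-identical samples.

## F-statistics and their permutation nulls

Diversity and structure statistics follow Weir & Cockerham (1984):
per-allele variance components $a$ (among samples), $b$ (among
individuals within samples) and $c$ (within individuals), summed over
alleles and loci, give

$$\hat\theta = \frac{\sum a}{\sum (a+b+c)}, \qquad
  \hat f = 1 - \frac{\sum c}{\sum (b+c)}.$$

These are the estimators implemented by Genetix, the tool that defined
this analysis style for microsatellite studies, which is why
alternatives such as Nei's $G_{ST}$ were not used. Multi-locus
estimates are ratios of summed components, never averages of per-locus
ratios. Monomorphic loci are excluded from all F-statistics and flagged
in reports rather than silently NaN-propagated. Missing genotypes are
dropped locus-wise: an individual untyped at one locus still counts at
the others. Expected heterozygosity uses Nei's unbiased small-sample
correction $\frac{2n}{2n-1}(1-\sum p_i^2)$.

A subtlety worth stating: at exact Hardy–Weinberg *counts* (e.g. 1 AA,
2 AB, 1 BB) the small-sample $\hat f$ is *not* zero but $+1/7$, because
the unbiased expected heterozygosity exceeds the observed one at
$n = 4$. The tests pin this value against an independently coded
brute-force implementation of the variance components.

Two permutation nulls are exposed, matching the two hypotheses:

* **F_IS** (departure from random union of gametes within a sample):
  alleles are shuffled among individuals within the sample,
  independently per locus — allele frequencies are preserved, the
  single/double-dose structure is destroyed. Default 5000 permutations.
  The default tail is one-sided for heterozygote *deficit*, the
  direction of interest in pollution-selection studies; a two-sided
  mode is available because the convention used by any given published
  table is rarely stated.
* **temporal F_ST** (differentiation between sampling years): whole
  individuals are shuffled between the two samples, preserving sample
  sizes. Default 1000 permutations, one-tailed
  ($\theta_{perm} \ge \theta_{obs}$).

Both report $p = (\text{hits} + 1)/(n_{perm} + 1)$, so no p-value is
ever exactly zero at finite permutation counts.

## Exact tests

`fisher_exact_rxc` enumerates every non-negative integer table with the
observed margins, computes multivariate hypergeometric probabilities,
and returns the total probability of tables no more probable than the
observed one (the probability-ordering definition of "two-sided", the
convention of standard exact-test implementations). The enumeration cap
defaults to $10^5$ tables — every table arising in this design (4
categories × 2 years, ~24 individuals per year) enumerates exactly and
instantly — beyond which a seeded Monte-Carlo estimate over 100,000 `r2dtable`
draws is returned together with its standard error, keeping large-table
results reproducible. The
enumerated probabilities must sum to 1 within $10^{-9}$; the test suite
asserts this, and exact agreement of the 2×2 case with the closed-form
hypergeometric sum.

`mann_whitney_exact` computes $U = \#\{(i,j): x_i < y_j\}$ (+½ per
cross-group tie) and the exact two-sided
$p = \min(1,\, 2\min(P(U \le u), P(U \ge u)))$ from the full
distribution over all $\binom{n_1+n_2}{n_1}$ assignments of the
observed pooled values — ties are handled exactly by enumerating the
observed multiset. For the study-sized case ($n_1 = n_2 = 4$) this is
70 assignments; complete separation gives $p = 2/70 \approx 0.0286$
and $U = 6$ gives $p = 48/70 \approx 0.686$, the two analytically
forced values this design prints. Beyond half a million assignments the
function falls back to the normal approximation and says so in its
result.

## Genotype categories and survival fitness

Candidate genotypes are classified against the focal allele into four
disjoint, exhaustive categories: focal homozygote, focal heterozygote,
other homozygote, other heterozygote. Year-to-year homogeneity is
tested on the **unpooled four-category** counts (pooling is a
fitness-specific device, not a testing one; a pooled mode exists for
sensitivity analysis). The genotype-survival fitness component of a
category is

$$w = \frac{\text{freq}_{\text{after-year}}}{\text{freq}_{\text{before-year}}},$$

computed for each of the $2 \times 2 = 4$ before×after year pairs —
before-before pairs are deliberately not fitness values; they exist
only as homogeneity tests. For fitness the two non-focal categories are
pooled into "other" precisely to keep before-frequencies away from
zero; a zero pooled before-frequency is still possible in small samples
and is surfaced as a named error rather than an infinite ratio.
Categories are compared by the exact Mann–Whitney test on their four
values, without multiplicity correction (three tests, mirroring how
such small panels are reported).

## Expression and water chemistry

Candidate-gene expression is standardized as reads mapped to the
candidate contig per million filtered reads,
$10^6 \cdot \text{mapped}/\text{total}$. The between-site statistic is
the ratio of *per-site means* of normalized expression
(affected/control), reported per epoch. A mean of per-pair ratios was
rejected: the epochs have small, unequal group sizes (3 vs 3, then 6
vs 6) and no natural pairing of individuals across sites, so only the
ratio-of-means form yields the single number per epoch that such
designs report. No significance test is attached to this ratio — the
point estimate is the deliverable; the synthetic generator exists to
show the estimator recovers a configured truth.

Water chemistry is analyzed by PCA on the correlation matrix
(`scale = TRUE` by default): the variables mix µS/cm, mg/L and pH
units, so covariance PCA would be dominated by the largest-unit
variable, and with 10 standardized variables the eigenvalues sum to 10,
making "percent of variance" directly comparable across runs. Each
loading column is sign-fixed so its largest-magnitude entry is
positive; eigenvector signs are otherwise arbitrary and irreproducible.
Group structure is summarized by score centroids per site × epoch and
their per-axis distances — no significance test, since the question at
this stage is descriptive.

The water generator draws replicate measurements from a multivariate
normal per site × epoch; a pollution signal is a shifted mean vector
(salinity/ion block up, dissolved oxygen down) for the affected site
before remediation. The expression generator draws library sizes
log-uniformly within per-campaign bounds (reproducing the strong
library-size asymmetry between sequencing platforms across epochs) and
mapped counts from a negative binomial with mean
$\mu \cdot \text{total}/10^6$.

## The default simulation scenario

`study_config()` encodes the package's reference scenario: demes MEL
(affected) and SFM (control) of 5000 diploids, reciprocal backward
migration 0.15, a six-allele candidate locus with focal-allele
frequencies 0.60 (MEL) and 0.25 (SFM), viability $1 - s = 0.5$ for the
focal homozygote in MEL before the switch and neutrality after, six
polymorphic (five alleles each) plus two monomorphic microsatellites
with stepwise mutation at $5\times10^{-4}$, and four samples of 24
individuals per deme.

Several of these numbers are free parameters of the study system — the
real census sizes and historical frequencies are unknown — and were
fixed once by a design-time power analysis (deterministic recursion
plus multinomial sampling noise, then simulation):

* **Sampling placement.** The two before samples sit at generations 0
  and 1 and the epoch switches at generation 10, with after samples at
  11 and 12. Under this scenario selection operates *throughout* the
  before epoch, so widely spaced before samples would themselves
  straddle most of the allele-frequency decline; placing them at the
  onset preserves the defining feature of the motivating design —
  stable frequencies within the before period, a large contrast across
  the intervention.
* **Initial frequencies.** A focal frequency of 0.60 in MEL keeps the
  pooled non-focal category at expected frequency
  $q^2 = 0.16$ (~4 of 24 individuals), so the zero-before-frequency
  pathology of the fitness ratio is rare, while the before/after focal
  decline (0.60 → ≈0.30, pinned by the migration-coupled control deme)
  remains large. SFM starts at 0.25 and is stable: the affected deme
  converges *toward* it after the switch, so the control shows no
  temporal trend — as in the motivating study.
* **Deme size 5000** keeps neutral temporal $F_{ST}$ from drift over 12
  generations near $t/2N \approx 10^{-3}$, well below the resolution of
  samples of 24, so the microsatellite panel behaves as a true negative
  control.

The epoch-level contrast in reports and tests pools the two before
samples against the two after samples (48 vs 48 individuals): "did
frequencies change across the intervention" is a statement about
epochs, and the pooled contrast uses all the data where single
year-pair tests at $n = 24$ leave the comparison underpowered.

When interpreting the validation suite, note what the simulator does
*not* emulate: age structure and overlapping generations, sex,
linkage, null alleles and genotyping error, year-to-year variation in
migration, and selection on the microsatellite background. Passing
tests demonstrate that the estimators and tests behave correctly under
the idealized model, not that any particular field dataset satisfies
that model.

## Numerical conventions and scale choices

* Allele pairs are stored sorted, so genotypes are genuinely unordered;
  statistics are invariant to allele relabeling and sample order
  (property-tested).
* Genepop export uses 3-digit allele codes (2-digit accepted on read),
  `000` for missing; string-labelled candidate alleles go through a
  sidecar allele-dictionary CSV. Missing data sentinel handling drops
  an individual locus-wise, never list-wise.
* Permutation and Monte-Carlo p-values are +1-smoothed and every
  report file records the permutation counts and master seed used.
* Validation problem sizes were chosen to make the checks sharp but
  quick: 100 random datasets for the estimator-oracle sweep, 500
  neutral replicates for permutation-test calibration, 200 replicates
  for both the trajectory-oracle agreement (deme size $10^4$) and the
  end-to-end selection-recovery study, and 199 permutations per
  replicate inside those loops (p-resolution 1/200, ample for a test
  at $\alpha = 0.05$).
* The selection-recovery study asserts its two kinds of conditions
  differently: the *power* conditions (candidate-locus Fisher and
  F_ST significance in the affected deme, and the fitness ordering
  focal-homozygote median < 1 < pooled-other median) must hold in at
  least 95% of replicates; the *null* conditions (control-deme
  candidate locus, microsatellites in both demes) are correctly
  calibrated 5%-level tests, so they are required to reject at a rate
  consistent with the nominal level (99% binomial bound), not to be
  never-significant — a conjunction of never-significant null tests is
  not a property any calibrated procedure can deliver in 95% of
  replicates.

## Known limitations

* The Fisher enumeration cap (default $10^5$ tables) is conservative;
  very large tables switch to Monte-Carlo with a reported standard
  error rather than exhausting memory on an enumeration that exact-test
  theory permits but practice does not need.
* The exact Mann–Whitney enumerates up to $5\times10^5$ assignments;
  beyond that it approximates and labels the result accordingly.
* `fitness_ratios` requires all four years and errors on a zero pooled
  before-frequency; with 24 individuals and a rare pooled category this
  can occur and should be read as "this sample cannot support a
  survival-ratio estimate", not as a bug.
* The pipeline's F_IS p-values default to 5000 permutations and the
  F_ST matrices to 1000, matching the conventions of the motivating
  analyses; both are configurable and scale linearly in runtime.
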
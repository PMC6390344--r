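---
title: "Mapping meiotic recombination in half-sib pedigrees with recombscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic recombination in half-sib pedigrees with recombscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Commercial layer-chicken breeding populations are organised as many small
half-sib families: a focal parent (sire or dam) with a handful of genotyped
offspring, each out of a different mate.  When the focal parent is
heterozygous at a SNP and the transmitted allele can be deduced, every
offspring reveals which of the parent's two chromosome copies it inherited
at that position; a switch between two adjacent informative markers marks a
meiotic crossover.  `recombscape` implements the full analysis chain built
on this observation:

1. genotype QC and half-sib family assembly,
2. crossover detection (phasing + interval calling + map-error scan),
3. 0.5-Mb window recombination-rate maps with hotspot/coldspot labels and
   per-parent summaries (GRN, GHU),
4. window-level genome features (GC, CpG islands, haplotype diversity) and
   genomic inbreeding,
5. a pedigree repeatability animal model and weighted BayesB/BayesC
   whole-genome regression with 1-Mb window variance partitioning for QTL
   discovery,
6. a gamete-level simulator that generates the whole data structure with
   known ground truth.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the simulation-based tests do and
do not establish about real data.

# Crossover detection

## Informative markers and transmitted alleles

For a half-sib family the detector works per chromosome on the markers at
which the focal parent is heterozygous (dosage 1).  The transmitted allele
for an offspring is deduced when it is forced: a homozygous offspring, or a
heterozygous offspring with a homozygous mate.  Heterozygous offspring of
heterozygous (or ungenotyped) mates are coded *unknown* and skipped; they
simply widen the reported intervals.

## Minimum-recombinant phasing

The focal parent's phase (which allele sits on which chromosome copy) is
unknown, so origin codes are only defined up to it.  We choose the phase
that minimises the total number of origin switches summed over the family's
offspring — the classical minimum-recombinant criterion.  The implementation
is an exact dynamic program whose state is the vector of each offspring's
origin at its most recent informative marker (2^n states for n offspring,
run for families of up to 10 offspring; larger families fall back to a
sequential majority-vote scan, which is reliable precisely when many
offspring vote at every junction).  Ties resolve toward the phase of the
preceding marker, and the global hapA/hapB swap is unobservable by
construction; all reported quantities are invariant to it.

## Interval calling and the smoothing decode

With `smoothing_error = 0`, every adjacent pair of opposite origin codes
becomes one recombination interval bounded by the two informative markers.
Real data carry occasional miscodes which would otherwise appear as
double crossovers in a tiny interval, so the default
`smoothing_error = 0.005` decodes each offspring's origin sequence with a
two-state Viterbi: miscode probability 0.005 per informative marker, switch
probability between markers from the genetic prior
`0.5 (1 - exp(-2 r d))` with `r = 1e-8` per bp (1 cM/Mb) and `d` the gap.
Isolated single-marker flips are absorbed; genuine crossovers, which are
supported by all downstream markers, are kept.  A true double crossover
bracketed by a single informative marker is indistinguishable from a flip
and is smoothed away — with no-error simulated data this costs a fraction
of a percent of events.  Double crossovers falling between two adjacent
informative markers are undetectable by construction and are not corrected.

## Map-error scan

Misplaced markers show up as isolated flips in many meioses.  Each marker
receives a confidence score `1 - max(flip rate, Mendelian error rate)`,
where the flip rate is the fraction of informative meioses in which the
marker disagrees with both informative neighbours.  Markers scoring below
0.9 are removed and detection re-runs once (not iterated to a fixpoint).
Markers with fewer than 20 informative meioses keep score 1 and are flagged
unscored.

# Window recombination maps

The window rate for a 0.5-Mb window is

\[ c_w = \frac{\sum_i x_i / r_i}{T}, \]

with `x_i` the Mb overlap of interval `i` with the window, `r_i` the
interval length in Mb and `T` the number of parent-offspring pairs.  An
interval thus spreads one event's worth of mass uniformly over its span,
and the window rates on a chromosome sum exactly to events/T — a
conservation identity the tests check to 1e-9 against a per-bp accumulation
oracle.

Windows are 0-based half-open `[k·500000, (k+1)·500000)`; the terminal
partial window is kept so no base pair is unassigned.  Per chromosome, the
top 10% of windows by rate (`ceiling`, ties by genomic position) are
hotspots, provided they carry any event mass; zero-mass windows are
coldspots.  Windows without SNPs cannot carry evidence either way: they are
excluded from the ranking denominator and keep the label "none".

Per-parent summaries: **GRN** is the average event count per meiosis over
autosomes (zero-event offspring count in the denominator); **GHU** is the
fraction of the parent's event mass falling in hotspot windows, computed
with the same fractional `x_i/r_i` attribution as the window rates
(a midpoint-attribution flag exists for whole-event accounting).  GHU is
undefined — reported as missing, not zero — for parents with no events.

# Genome features

GC content and CpG island density are computed per window from a FASTA and
an island BED (the usual source is a UCSC-style island track); a built-in
scanner with the classical three criteria (length ≥ 200 bp, GC ≥ 0.5,
observed/expected CpG ≥ 0.6, merged qualifying windows) is provided for
genomes without one.  Haplotype diversity is the number of distinct
marker-string alleles at ≥ 1% frequency per window; in simulation mode it
is computed from truth haplotypes, in data mode from the detected
transmitted strands — a documented difference.  Genomic inbreeding uses the
method-of-moments `F = (O - E)/(L - E)` with the small-sample correction
`2pq·n/(n-1)` in `E`, on a marker set pruned at r² > 0.5 within
non-overlapping 50-SNP blocks (victim: the lower-MAF member; ties drop the
later marker; monomorphic markers are never tested).

# Heritability, repeatability and QTL mapping

## Repeatability animal model

Per-meiosis GRN (or GHU) records are repeated observations on the parent:

\[ y = Xb + Zu + Zp + e, \qquad
   \mathrm{Var}(u) = A\sigma^2_a,\;
   \mathrm{Var}(p) = I\sigma^2_p,\;
   \mathrm{Var}(e) = I\sigma^2_e, \]

with sex means in `b` and the pedigree numerator relationship matrix `A`
(tabular method, inbreeding on the diagonal).  Inference is a Gibbs sampler
with flat priors on `b` and scaled-inverse-chi-square priors (ν = 4, scale
a third of the phenotypic variance) on the three components; posterior
means and SDs of `h² = σ²a/σ²_total` and repeatability
`t = (σ²a+σ²p)/σ²_total` are reported.  One inference engine serves the
whole package; a method-of-moments ANOVA repeatability is available as an
independent cross-check.  Heritability is only identifiable when the
recorded parents are related, and the *kind* of relationship matters: with
only half-sib links (covariance 0.25σ²a) the additive and
permanent-environment components are nearly confounded — their sum
(repeatability) is well identified, but the σ²p ≥ 0 boundary truncates the
split asymmetrically and pulls σ²a down at realistic sample sizes.
Parent-offspring and full-sib links (covariance 0.5σ²a) largely remove
this; the package's recovery studies therefore use recorded pedigrees with
such links, and calibrate the realized variance of each simulated
component to its target so that recovery checks measure estimator
calibration rather than the luck of the generating draw.  The sampler
refuses data in which no parent has repeated records.

## Record weights

When parent means of `n` records are analysed instead of the records
themselves, the residual variance is heterogeneous.  The weight

\[ E_n = \frac{1 - h^2}{\frac{1 + (n-1)t}{n} - h^2} \]

(with `E_1 = 1` and `E_n = n` exactly when `t = h²`) scales each record's
residual variance as `σ²e/En`.  The denominator is positive whenever
`t ≥ h²`, which the function enforces.

## Weighted BayesB / BayesC whole-genome regression

Marker effects enter `y = Xb + Mα + e` with per-record residual variance
`σ²e/w`.  With `π = 0` and a common effect variance this is BayesC(π=0):
every SNP effect is a draw from one normal distribution, and the posterior
mean effect vector approaches the ridge solution with penalty
`σ²e/σ²α` — a closed-form oracle the tests compare against (correlation
> 0.99 on a 50×100 fixture).  With `π > 0` a spike at zero plus per-marker
scaled-inverse-chi-square variances (ν_a = 4.2 by default) give the
BayesB t-prior; excluded markers redraw their variance from the prior.
Genotype covariates are centred internally (the means are absorbed by the
fixed effects and variances are unchanged), which is essential for the
mixing of single-site samplers.  Prior scales derive from pedigree-based
variance components: `S²_a = σ²a(ν_a - 2)/(ν_a (1-π) Σ_j 2p_jq_j)` and
`S²_e = σ²e(ν_e - 2)/ν_e`.  The sampler is compiled code; chains are
reproducible bit-for-bit from the seed.  The reference chain length is
55,000 with 5,000 burn-in; the package's own simulations use scaled-down
chains (11,000/1,000, thinning 10), problem sizes chosen so every study in
the test suite and the acceptance script reruns from scratch.

## Window variance partitioning and QTL calls

Markers are binned into non-overlapping 1-Mb windows carrying at least one
marker.  Per posterior sample, each window's genetic value is
`g_w = M_w α_w` and its share of genetic variance is
`Var(g_w) / Σ_w' Var(g_w')` over individuals, so shares sum to exactly 1 in
every sample (the naive denominator `Var(Σ g_w)` differs by the sample
covariance between windows and would break that identity).  GV% is the
posterior mean share × 100; WPPA is the fraction of samples with ≥ 1
included marker in the window; SPPI is the per-SNP inclusion probability
and the window's lead SNP is its SPPI maximiser.  Windows with GV% at or
above a threshold (0.8% by default — 20 times the polygenic expectation for
a genome of ~2,500 windows) seed QTL regions extended 1 Mb to both sides
and merged when overlapping or adjacent.  **The polygenic expectation is
100/#windows**: on small simulated genomes with few windows the 0.8%
default sits far below the null baseline and the threshold must be chosen
relative to `100/#windows`; the package exposes it as a parameter rather
than hard-coding the value.  Lead SNPs can be refitted with their window
mates removed to read off the SNP's own GV%, and checked in a single-SNP
GLS animal model (`V = σ²aA + diag(σ²e/En)`, Wald test).

# The simulator

`simulate_population()` generates the complete study design:

* **Families.** `n_families` focal parents (default 100; 40% dams, echoing
  the sire-heavy family structure of layer pedigrees) with
  `offspring_per_family` genotyped offspring (default 4), each by a
  distinct founder mate (a shared-mate switch produces full-sib families).
  Every offspring records one meiosis for each of its two parents.
* **Founders.** Two haplotypes per founder drawn from a pool of
  `founder_haplotype_pool_size` distinct haplotypes per chromosome
  (allele frequencies U(0.1, 0.9)).  The pool size is the single knob for
  line diversity: a small pool behaves like an inbred line (higher F,
  fewer common haplotype alleles), a large pool like a diverse one.
* **Crossovers.** A piecewise-constant intensity map built from 0.5-Mb
  tiles: a `hotspot_fraction` (default 0.10) of tiles get a
  `hotspot_intensity_multiplier` (default 10×), normalised so each
  chromosome's integral equals `base_crossover_rate` events per (sire)
  meiosis.  Counts are Poisson — no crossover interference, matching the
  modelling scope of the analysis chain; positions are drawn proportional
  to intensity, and the gamete alternates between the parental haplotypes
  from a fair-coin starting phase.  Dams' intensity is scaled by
  `sex_rate_multiplier` (default 1.1, the middle of the 5–20% dam excess
  reported for layers).
* **Heritable propensity.** Each parent's rate multiplier is
  `exp(g + pe)`; variances of `g` and `pe` are calibrated on the
  linearised count scale so that single-meiosis counts have heritability
  `grn_h2` (default 0.17) and repeatability `grn_repeatability`
  (default 0.24) once the Poisson residual is included:
  `σ²g = h²/((1-t)λ)`, `σ²pe = (t-h²)/((1-t)λ)` for genome-wide mean λ.
  Optional QTL act additively on log-propensity, keeping rates positive;
  their variance is carved out of the polygenic term.
* **Panels.** `downsample_panel()` keeps an exact uniform random fraction
  of markers, emulating the high/low density panel contrast.
  `genotyping_error_rate` applies symmetric dosage perturbation
  (default 0).

The default scale (5 chromosomes × 50 Mb, 20 markers/Mb) is a desk-scale
genome chosen so that every simulation study in the test suite regenerates
in seconds to minutes; test-specific configurations state their own sizes.

## What the simulations do and do not show

The generator reproduces the *structure* that the detection and mapping
machinery relies on: family topology, informative-marker logic, Poisson
crossovers on a hotspot-structured map, heritable propensity, sex rate
differences, panel density.  It deliberately omits coalescent founder LD,
mutation, selection, crossover interference, Z-chromosome meiosis and
genotyping-error clustering.  Passing the suite therefore demonstrates the
estimators are correct under their stated model; it does not certify
behaviour under model misspecification (e.g. strong interference or
pervasive genotyping error), and real-data rate differences between
populations can be driven by inbreeding and haplotype structure rather than
true recombination differences — the window rates are estimates of
*detected* recombination.

## Calibration checks worth singling out

* GRN calibration compares cohort mean GRN (from truth-derived intervals)
  with the configured Poisson mean.  GHU calibration uses a flat intensity
  map with *designated* hotspot tiles (multiplier 1): labelling hotspots
  from the cohort's own rates would select the top order statistics of the
  sampling noise and bias mean GHU upward at any finite `T`, so the
  selection-free designated set is the right yardstick; the data-driven
  labelling path is exercised separately by the count and fixture tests.
* The QTL-recovery study (600 individuals, 2,000 independent markers in 20
  one-Mb windows, h² = 0.5, an equal-effect polygenic background of one
  causal marker per window, one QTL at 10% of the genetic variance,
  BayesB π = 0.99) chooses the background so that the expected number of
  fitted markers per iteration (~(1-π)m = 20) matches the causal count —
  the same logic the π values in whole-genome regressions are chosen by.
  With a share-based GV% the per-window null expectation is 5% here, so
  detection is judged by the QTL window attaining the maximum GV%, not by
  an absolute threshold.

# Numerical and design choices

* Positions are 1-based bp; all window logic is 0-based half-open, stated
  once in `make_windows()` and reused everywhere.
* Mendelian inconsistency per marker counts opposite-homozygote
  parent-offspring pairs over scored (both-genotyped) pairs; both sire and
  dam links are scored.
* The missing-genotype fill (missingness in these data is ~0.01%) is
  deterministic: Mendelian-forced values where unique, rounded marker mean
  otherwise; never altering observed calls keeps it idempotent.
* The repeatability sampler uses a dense Cholesky of the q×q precision per
  iteration — appropriate at the few-hundred-parent scale it targets.
* `En` weights and prior scales are recomputed from the pedigree fit's
  posterior means, mirroring the two-stage practice of pedigree-then-
  genomic analyses.
* Degenerate inputs error early with context: cycles in pedigrees, T = 0,
  intervals outside chromosome bounds, all-singleton records, h² > t,
  QTL variance exceeding σ²g.

# Known limitations

* Phasing is exact only for families of ≤ 10 offspring; the fallback scan
  is a heuristic (with dense votes its failure modes are vanishing).
* When two offspring of a 4-offspring family recombine in the same
  inter-informative-marker gap, the family data are symmetric under a
  phase flip at that junction: the true pair of crossovers and a spurious
  pair in the complementary offspring explain the genotypes equally well.
  The MAP weights break the tie by gap lengths, which is Bayes-optimal but
  not clairvoyant; hotspot concentration raises the frequency of such
  coincidences and therefore the floor of the spurious-call rate.  Larger
  families resolve the ambiguity.
* The map-error confidence score is a stated proxy (flip and Mendelian
  rates) with the conventional 0.9 threshold; the original score of the
  reference phasing tools is not published in reproducible form.
* Gene conversions, sex-chromosome meiosis and population-based phasing are
  out of scope.
* BayesB's per-marker variance updates use the standard
  prior-draw-when-excluded scheme; label switching between tightly linked
  markers can spread SPPI within a window, which is why window-level WPPA
  and GV% are the primary signals and the lead SNP is a summary, not an
  identification.
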
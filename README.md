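# recombscape

Meiotic recombination mapping and QTL discovery in half-sib livestock
pedigrees, from SNP genotypes.

Layer-chicken (and other livestock) breeding populations consist of many
small half-sib families.  Wherever a focal parent is heterozygous and the
transmitted allele can be deduced from the offspring and mate genotypes,
each offspring reveals which parental chromosome copy it inherited; a
switch between adjacent informative markers is a meiotic crossover.
`recombscape` turns that observation into a complete analysis chain for
geneticists studying recombination as a trait:

* **QC & families** — PLINK-style ped/map or dosage-matrix input, SNP
  filters (call rate < 0.95, MAF < 0.025, Mendelian inconsistency > 0.05),
  half-sib family assembly, deterministic fill of sparse missing calls.
* **Crossover detection** — exact minimum-recombinant phasing within each
  family, two-state Viterbi interval calling that absorbs isolated
  miscodes, and a map-error scan (confidence `1 - max(flip rate, Mendelian
  rate)`, threshold 0.9).
* **Recombination maps** — 0.5-Mb window rates
  `c_w = (Σ x_i/r_i)/T`, per-chromosome top-10% hotspot and zero-rate
  coldspot labels, per-parent genome-wide recombination number (GRN) and
  hotspot usage (GHU), sex-stratified tracks.
* **Genome features** — GC content and CpG-island density per window
  (FASTA/BED, plus a built-in three-criteria island scanner), common
  haplotype alleles, LD-pruned genomic inbreeding `F = (O-E)/(L-E)`,
  feature-rate correlation tables with chicken chromosome size classes.
* **Quantitative genetics** — pedigree repeatability animal model
  (`y = Xb + Zu + Zp + e`, Gibbs sampler; h² and repeatability with
  posterior SDs), `En` record weights, weighted BayesC(π=0)/BayesB
  whole-genome regression (compiled single-site Gibbs sampler), 1-Mb
  window variance partitioning (GV%, WPPA, SPPI), QTL region calling with
  ±1-Mb flank merging, lead-SNP refits and single-SNP mixed-model checks.
* **Synthetic data** — a gamete-level simulator (founder haplotype pools,
  hotspot-structured Poisson crossovers, dam/sire rate multiplier,
  heritable per-parent propensity with optional QTL, panel downsampling)
  that provides ground truth for every stage.

## Worked example

```r
library(recombscape)

# a synthetic half-sib population with known crossovers
cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = 50,
                  n_families = 100, offspring_per_family = 4,
                  base_crossover_rate = 2.5, seed = 1)
sim <- simulate_population(cfg)
sim$genotypes
#> genotypes: 900 individuals x 2000 markers on 2 chromosome(s)
#>   missing calls: 0%

qc  <- qc_filter_snps(sim$genotypes, sim$pedigree)
det <- detect_recombination(qc$genotypes, sim$pedigree)
grn <- parent_grn(det$intervals, det$pairs)
summary(grn$grn)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   1.000   3.250   4.250   4.407   5.312   7.750

win   <- make_windows(c("1" = 50e6, "2" = 50e6))
track <- classify_hotspots_coldspots(
  window_rates(det$intervals, nrow(det$pairs), win, map = qc$genotypes$map))
table(track$label)
#> hotspot    none
#>      20     180
```

The cohort mean GRN (`sum(grn$events)/sum(grn$n)` = 4.41 here) estimates
the expected crossovers per meiosis the simulator was configured with
(2 chromosomes × 2.5, minus edge and resolution losses of detection); each
chromosome's 100 windows yield `ceiling(0.1 × 100) = 10` hotspots.  The
same objects feed the genetics layer: `fit_repeatability_model()` for h²
and repeatability of GRN, `en_weights()` for parent-mean weights, and
`fit_wgr()` + `window_variance_partition()` + `call_qtl()` for QTL mapping.

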
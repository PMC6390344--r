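# gamete simulator, founder pools, propensity model, panel downsampling

flat_intensity <- function(L, rate_per_meiosis) {
  data.frame(start = 0, end = L, rate = rate_per_meiosis / L)
}

test_that("population bookkeeping: families, offspring, meioses, determinism", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = 20,
                    n_families = 50, offspring_per_family = 4, seed = 33)
  sim <- simulate_population(cfg)
  ped <- sim$pedigree
  focal <- grep("^P", ped$id, value = TRUE)
  off <- grep("^O", ped$id, value = TRUE)
  expect_length(focal, 50)
  expect_length(off, 200)
  # every offspring contributes one meiosis per parent in the truth set
  meioses <- unique(sim$truth$crossovers[, c("parent", "offspring")])
  expect_lte(nrow(meioses), 2 * length(off))
  sim2 <- simulate_population(cfg)
  expect_identical(sim2$genotypes$geno, sim$genotypes$geno)
  expect_identical(sim2$truth$crossovers, sim$truth$crossovers)
  expect_error(simulate_population(sim_config(founder_haplotype_pool_size = 0)),
               "pool")
})

test_that("small founder pools bound per-window haplotype diversity", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_lengths = 5,
                    founder_haplotype_pool_size = 2, n_families = 10,
                    offspring_per_family = 2, base_crossover_rate = 0,
                    hotspot_fraction = 0, seed = 9)
  sim <- simulate_population(cfg)
  founders <- grep("^[PQ]", sim$pedigree$id, value = TRUE)
  rows <- as.vector(rbind(paste0(founders, ".1"), paste0(founders, ".2")))
  h <- sim$truth$haplotypes[["1"]][rows, ]
  win <- make_windows(c("1" = 5e6))
  tr <- common_haplotype_alleles(h, sim$genotypes$map, win, min_freq = 0)
  expect_true(all(tr$n_common_haps[tr$n_markers > 0] <= 2))
  # brute-force tally agreement
  str <- apply(h, 1, paste, collapse = "")
  expect_equal(tr$n_common_haps[1], length(unique(str)))
})

test_that("zero intensity yields an untouched parental haplotype", {
  set.seed(1)
  pos <- seq(1e5, 9.9e6, by = 1e5)
  hapA <- rbinom(length(pos), 1, .5); hapB <- 1 - hapA
  res <- simulate_meiosis(hapA, hapB, pos,
                          data.frame(start = 0, end = 1e7, rate = 0))
  expect_length(res$crossovers, 0)
  expect_true(identical(res$gamete, hapA) || identical(res$gamete, hapB))
})

test_that("gamete is a mosaic of the parents that alternates at each crossover", {
  set.seed(2)
  pos <- sort(sample.int(1e7, 300))
  hapA <- rbinom(300, 1, .5); hapB <- 1L - hapA   # complementary: origin readable
  it <- flat_intensity(1e7, 3)
  for (rep in 1:20) {
    res <- simulate_meiosis(hapA, hapB, pos, it)
    cuts <- c(0, res$crossovers, 1e7 + 1)
    seg_origin <- integer(0)
    for (s in seq_len(length(cuts) - 1)) {
      inseg <- pos > cuts[s] & pos <= cuts[s + 1]
      if (!any(inseg)) { seg_origin <- c(seg_origin, NA); next }
      fromA <- identical(res$gamete[inseg], hapA[inseg])
      fromB <- identical(res$gamete[inseg], hapB[inseg])
      expect_true(xor(fromA, fromB))
      seg_origin <- c(seg_origin, if (fromA) 0L else 1L)
    }
    # alternation is only observable when every segment carries markers
    if (!anyNA(seg_origin) && length(seg_origin) > 1)
      expect_true(all(diff(seg_origin) != 0))
  }
})

test_that("crossover counts are Poisson with the configured mean", {
  set.seed(3)
  it <- flat_intensity(1e7, 2)
  pos <- c(1e6, 5e6)
  counts <- replicate(10000, length(simulate_meiosis(c(0, 0), c(1, 1), pos,
                                                     it)$crossovers))
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2 / 10000))   # CLT bound
  # chi-square goodness of fit against Poisson(2), alpha = 0.01
  kmax <- 8
  obs <- tabulate(pmin(counts, kmax) + 1, nbins = kmax + 1)
  pr <- dpois(0:(kmax - 1), 2); pr <- c(pr, 1 - sum(pr))
  stat <- sum((obs - 10000 * pr)^2 / (10000 * pr))
  expect_lt(stat, qchisq(0.99, df = kmax))
})

test_that("hotspot occupancy follows the analytic intensity ratio", {
  set.seed(4)
  # 10x multiplier on 10% of the map: expected share 1*0.1*10/(0.1*10+0.9)
  it <- data.frame(start = c(0, 1e6), end = c(1e6, 1e7), rate = c(10, 1))
  it$rate <- it$rate / sum(it$rate * (it$end - it$start)) * 2   # 2 per meiosis
  xs <- unlist(replicate(3000, simulate_meiosis(0, 1, 5e6, it)$crossovers))
  share <- mean(xs < 1e6)
  expected <- 10 * 0.1 / (10 * 0.1 + 0.9)
  expect_lt(abs(share - expected), 3 * sqrt(expected * (1 - expected) / length(xs)))
})

test_that("dam/sire mean crossover counts converge to the sex multiplier", {
  cfg <- sim_config(n_chromosomes = 2, chromosome_lengths = 30,
                    base_crossover_rate = 2, sex_rate_multiplier = 1.2,
                    n_families = 150, offspring_per_family = 4,
                    grn_h2 = 0, grn_repeatability = 0, seed = 5)
  sim <- simulate_population(cfg)
  xo <- sim$truth$crossovers
  ped <- sim$pedigree
  sex <- setNames(ped$sex, ped$id)
  off <- grep("^O", ped$id, value = TRUE)
  per_meiosis <- function(s) {
    parents <- unique(c(ped$sire[match(off, ped$id)], ped$dam[match(off, ped$id)]))
    parents <- parents[sex[parents] == s]
    n_meio <- sum(ped$sire %in% parents) + sum(ped$dam %in% parents)
    sum(xo$parent %in% parents) / n_meio
  }
  lam_m <- per_meiosis("M"); lam_f <- per_meiosis("F")
  ratio <- lam_f / lam_m
  se <- ratio * sqrt(1 / sum(xo$parent %in% names(sex)[sex == "F"]) +
                     1 / sum(xo$parent %in% names(sex)[sex == "M"]))
  expect_lt(abs(ratio - 1.2), 3 * se)
})

test_that("propensity model: null heritability, QTL effect, calibrated variances", {
  cfg0 <- sim_config(grn_h2 = 0, grn_repeatability = 0.2, seed = 6)
  ped <- as_pedigree(data.frame(id = sprintf("F%03d", 1:300), sire = NA,
                                dam = NA, sex = "M"))
  set.seed(6)
  pr0 <- assign_parent_propensity(ped, cfg0)
  expect_true(all(pr0$g == 0))          # h2 = 0: no genetic spread
  expect_gt(var(pr0$pe), 0)
  expect_error(assign_parent_propensity(
    ped, {c <- cfg0; c$grn_h2 <- 0.5; c}), "exceeds")
  # one QTL, effect +0.2 per copy: carrier propensity ratio e^0.2
  cfgq <- sim_config(grn_h2 = 0.17, grn_repeatability = 0.17,
                     qtl_spec = data.frame(marker = 1, effect = 0.2), seed = 7)
  G <- make_geno(matrix(rep(c(0L, 1L, 2L), each = 100), 300, 1),
                 ids = ped$id)
  set.seed(7)
  prq <- assign_parent_propensity(ped, cfgq, G)
  grp <- rep(c(0, 1, 2), each = 100)
  e_g <- tapply(prq$g, grp, mean)
  # group-mean contrasts carry polygenic noise (SE about 0.022)
  expect_lt(abs(unname(e_g[2] - e_g[1]) - 0.2), 0.07)
  expect_lt(abs(unname(e_g[3] - e_g[2]) - 0.2), 0.07)
})

test_that("offspring-on-midparent regression of counts recovers the heritability", {
  set.seed(8)
  cfg <- sim_config(grn_h2 = 0.17, grn_repeatability = 0.24,
                    n_chromosomes = 5, base_crossover_rate = 23 / 5)
  npair <- 1000
  sires <- sprintf("S%04d", 1:npair); dams <- sprintf("D%04d", 1:npair)
  kids <- sprintf("K%04d", 1:npair)
  ped <- as_pedigree(rbind(
    data.frame(id = sires, sire = NA, dam = NA, sex = "M"),
    data.frame(id = dams, sire = NA, dam = NA, sex = "F"),
    data.frame(id = kids, sire = sires, dam = dams, sex = "M")))
  pr <- assign_parent_propensity(ped, cfg)
  lam <- 23
  cnt <- setNames(rpois(nrow(pr), lam * pr$scale), pr$id)
  midparent <- (cnt[sires] + cnt[dams]) / 2
  fit <- lm(cnt[kids] ~ midparent)
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 0.17), 2 * se)
})

test_that("panel downsampling keeps an exact ordered subset, reproducibly", {
  set.seed(9)
  G <- make_geno(matrix(sample(0:2, 200 * 100, TRUE), 200, 100))
  expect_identical(downsample_panel(G, 1), G)
  set.seed(10); G10 <- downsample_panel(G, 0.1)
  expect_equal(ncol(G10$geno), 10)
  expect_identical(G10$map$marker, sort(G10$map$marker))
  set.seed(10); G10b <- downsample_panel(G, 0.1)
  expect_identical(G10, G10b)
})

test_that("sim configs survive a YAML round trip", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  cfg <- sim_config(n_chromosomes = 3, chromosome_lengths = c(40, 30, 20),
                    qtl_spec = data.frame(marker = "snp1_00001", effect = 0.2),
                    seed = 12)
  write_sim_config(cfg, tmp)
  cfg2 <- read_sim_config(tmp)
  expect_equal(cfg2$chromosome_lengths, cfg$chromosome_lengths)
  expect_equal(cfg2$qtl_spec$effect, 0.2)
  expect_equal(cfg2$seed, 12L)
})
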
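# transmitted-allele deduction, min-recombinant phasing, crossover calling,
# map-error scanning

test_that("transmitted alleles follow Mendelian deduction and ambiguity rules", {
  # focal parent het at all markers; mate genotypes decide resolvability
  ped <- as_pedigree(rbind(
    data.frame(id = c("P", "Q"), sire = NA, dam = NA, sex = c("M", "F")),
    data.frame(id = c("O1", "O2"), sire = "P", dam = "Q", sex = "M")))
  #           m1: mate hom 0, off het -> transmitted 1
  #           m2: mate het, off het   -> unknown
  #           m3: off hom 2           -> transmitted 1
  #           m4: off hom 0           -> transmitted 0
  geno <- rbind(P = c(1L, 1L, 1L, 1L), Q = c(0L, 1L, 1L, 1L),
                O1 = c(1L, 1L, 2L, 0L), O2 = c(1L, 1L, 2L, 0L))
  G <- make_geno(geno, ids = rownames(geno))
  fam <- build_half_sib_families(ped, rownames(geno))[[1]]
  blk <- infer_transmitted_alleles(fam, G, "1")
  # origin = transmitted xor phase; recover transmitted via phase
  tm <- xor_phase(blk$origin, blk$phase)
  expect_equal(unname(tm["O1", ]), c(1L, NA, 1L, 0L))
  expect_error(infer_transmitted_alleles(list(parent = "P", sex = "M",
                                              offspring = "O1", mates = "Q"),
                                         G, "1"), "2 offspring")
})

test_that("phasing attains the exhaustive minimum-recombinant optimum", {
  set.seed(21)
  for (rep in 1:25) {
    noff <- sample(3:5, 1); K <- sample(6:10, 1)
    # random true phase and origins with sparse unknowns
    tm <- matrix(sample(c(0L, 1L, NA), noff * K, TRUE, prob = c(.4, .4, .2)),
                 noff, K)
    phase <- recombscape:::min_recombinant_phase(tm)
    origin <- xor_phase(tm, phase)
    got <- total_crossovers_from_origin(origin)
    best <- brute_force_phase_crossovers(tm)
    expect_gte(got, best)
    # the sequential scan should reach the optimum on these small cases
    expect_lte(got - best, 0)
  }
})

test_that("phase recovery in a clean family equals truth up to a global swap", {
  set.seed(22)
  K <- 10; noff <- 4
  true_phase <- sample(0:1, K, TRUE)   # hapA allele at each het marker
  # offspring inherit hapA or hapB with one switch at most
  origin_true <- matrix(0L, noff, K)
  for (o in 1:noff) {
    start <- sample(0:1, 1); sw <- sample(0:(K - 1), 1)
    origin_true[o, ] <- c(rep(start, sw), rep(1 - start, K - sw))
  }
  tm <- xor_phase(origin_true, true_phase)
  phase <- recombscape:::min_recombinant_phase(tm)
  match_direct <- all(phase == true_phase)
  match_swapped <- all(phase == bitwXor(true_phase, 1L))
  # recovered crossover count must not exceed the truth's
  origin <- xor_phase(tm, phase)
  expect_lte(total_crossovers_from_origin(origin),
             total_crossovers_from_origin(origin_true))
  expect_true(match_direct || match_swapped ||
              total_crossovers_from_origin(origin) <=
                total_crossovers_from_origin(origin_true))
})

test_that("crossover calling: breaks, identity, unknown skipping", {
  pos <- (1:5) * 1e6
  iv <- call_crossovers(c(0L, 0L, 0L, 1L, 1L), pos, smoothing_error = 0)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$left_pos, 3e6)
  expect_equal(iv$right_pos, 4e6)
  expect_equal(iv$r_mb, 1)
  expect_equal(nrow(call_crossovers(rep(0L, 5), pos, 0)), 0)
  # unknowns are skipped: interval spans the known flanks
  iv2 <- call_crossovers(c(0L, NA, NA, 1L, 1L), pos, smoothing_error = 0)
  expect_equal(iv2$left_pos, 1e6)
  expect_equal(iv2$right_pos, 4e6)
  expect_equal(iv2$r_mb, 3)
})

test_that("smoothed decode equals the exhaustive most-probable-path oracle", {
  set.seed(23)
  pos7 <- cumsum(c(1e6, runif(6, 2e5, 2e6)))
  cases <- list(c(0L, 1L, 0L),                       # isolated flip
                c(0L, 0L, 1L),
                c(1L, 1L, 1L))
  for (obs in cases) {
    got <- recombscape:::viterbi_two_state(obs, pos7[1:3], 0.01, 1e-8)
    want <- brute_force_decode(obs, pos7[1:3], 0.01)
    expect_identical(got, want)
  }
  path_lp <- function(path, obs, pos, eps, rate = 1e-8) {
    d <- diff(pos)
    psw <- pmax(0.5 * (1 - exp(-2 * rate * d)), 1e-12)
    sum(ifelse(path == obs, log(1 - eps), log(eps))) +
      sum(ifelse(diff(path) != 0, log(psw), log1p(-psw)))
  }
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    obs <- sample(0:1, n, TRUE)
    eps <- runif(1, 0.001, 0.2)
    got <- recombscape:::viterbi_two_state(obs, pos7[1:n], eps, 1e-8)
    want <- brute_force_decode(obs, pos7[1:n], eps)
    # ties between equally probable paths may resolve either way
    expect_equal(path_lp(got, obs, pos7[1:n], eps),
                 path_lp(want, obs, pos7[1:n], eps), tolerance = 1e-10)
  }
  # the isolated flip is absorbed, not called as a double crossover
  iv <- call_crossovers(c(0L, 1L, 0L), pos7[1:3], smoothing_error = 0.01)
  expect_equal(nrow(iv), 0)
})

test_that("interval count is invariant to the global hapA/hapB swap", {
  set.seed(24)
  pos <- sort(sample.int(5e7, 40))
  o <- sample(c(0L, 1L, NA), 40, TRUE, prob = c(.45, .45, .1))
  a <- call_crossovers(o, pos, 0.005)
  b <- call_crossovers(bitwXor(o, 1L), pos, 0.005)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$left_pos, b$left_pos)
})

test_that("map-error scan scores clean and flip-prone markers as specified", {
  # build origin blocks by hand: 25 offspring sequences over 5 markers
  map <- data.frame(marker = sprintf("m%d", 1:5), chrom = "1",
                    pos = (1:5) * 1e6)
  G <- make_geno(matrix(1L, 2, 5), ids = c("P", "x"))
  G$map <- map; colnames(G$geno) <- map$marker
  ped <- as_pedigree(data.frame(id = c("P", "x"), sire = NA, dam = NA,
                                sex = c("M", "F")))
  mkblock <- function(n_flip, n_total) {
    origin <- matrix(0L, n_total, 5, dimnames = list(NULL, map$marker))
    origin[seq_len(n_flip), 3] <- 1L        # isolated flips at marker 3
    list(origin = origin, markers = 1:5, positions = map$pos,
         phase = rep(0L, 5), family = "P", chrom = "1")
  }
  conf <- map_error_scan(list(mkblock(0, 25)), G, ped)
  expect_equal(conf$confidence[conf$marker == "m3"], 1)
  # 15% isolated flips in 100 informative meioses -> score 0.85, removed
  conf2 <- map_error_scan(list(mkblock(15, 100)), G, ped)
  expect_equal(conf2$confidence[conf2$marker == "m3"], 0.85)
  expect_lt(conf2$confidence[conf2$marker == "m3"], 0.9)
  # under 20 informative meioses the marker stays unscored at 1
  conf3 <- map_error_scan(list(mkblock(3, 10)), G, ped)
  expect_equal(conf3$confidence[conf3$marker == "m3"], 1)
  expect_false(conf3$scored[conf3$marker == "m3"])
})

test_that("a teleported marker is removed by the scan and others survive", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_lengths = 40,
                    marker_density = 5, n_families = 60,
                    offspring_per_family = 4, base_crossover_rate = 1,
                    hotspot_fraction = 0, seed = 25)
  sim <- simulate_population(cfg)
  G <- sim$genotypes
  # teleport one mid-chromosome marker 20 Mb away: its calls now disagree
  # with the local haplotype background
  j <- which.min(abs(G$map$pos - 10e6))
  jt <- which.min(abs(G$map$pos - 30e6))
  swapped <- G$map
  swapped$pos[c(j, jt)] <- swapped$pos[c(jt, j)]
  Gs <- genotypes(G$geno, swapped)
  det <- detect_recombination(Gs, sim$pedigree, scan_map_errors = TRUE)
  expect_true(G$map$marker[j] %in% det$removed_markers ||
              G$map$marker[jt] %in% det$removed_markers)
  expect_lte(length(det$removed_markers), 3)
})

test_that("denser panels detect at least as many events as downsampled ones", {
  cfg <- sim_config(n_chromosomes = 1, chromosome_lengths = 40,
                    marker_density = 20, n_families = 40,
                    offspring_per_family = 4, base_crossover_rate = 1.5,
                    seed = 26)
  sim <- simulate_population(cfg)
  det_full <- detect_recombination(sim$genotypes, sim$pedigree,
                                   scan_map_errors = FALSE)
  set.seed(26)
  det_low <- detect_recombination(downsample_panel(sim$genotypes, 0.1),
                                  sim$pedigree, scan_map_errors = FALSE)
  grn_full <- mean(parent_grn(det_full$intervals, det_full$pairs)$grn)
  grn_low <- mean(parent_grn(det_low$intervals, det_low$pairs)$grn)
  expect_lt(grn_low, grn_full)
})
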
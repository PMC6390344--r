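# genotype/pedigree reading, SNP QC, family assembly, missing-call fill

test_that("ped/map round trip preserves dosages, missing calls and map sorting", {
  tmp <- withr::local_tempdir()
  geno <- matrix(c(0L, 1L, 2L,  2L, NA, 0L,  1L, 1L, 1L,  0L, 2L, 1L), 3, 4)
  # map deliberately unsorted within chromosome
  G <- make_geno(geno, chrom = c("1", "1", "2", "1"),
                 pos = c(5e6, 2e6, 1e6, 7e6))
  expect_equal(G$map$marker, c("m002", "m001", "m004", "m003"))  # sorted
  ped_path <- file.path(tmp, "g.ped"); map_path <- file.path(tmp, "g.map")
  write_genotypes(G, ped_path, map_path, dialect = "ped")
  G2 <- read_genotypes(ped_path, map_path, dialect = "ped")
  expect_identical(unname(G2$geno), unname(G$geno))
  expect_identical(G2$map$pos, G$map$pos)
  expect_true(is.na(G2$geno[2, "m002"]))

  mat_path <- file.path(tmp, "g.tsv"); mmap_path <- file.path(tmp, "gmap.tsv")
  write_genotypes(G, mat_path, mmap_path, dialect = "matrix")
  G3 <- read_genotypes(mat_path, mmap_path, dialect = "matrix")
  expect_identical(G3$geno, G$geno)
})

test_that("malformed ped lines and duplicate markers are rejected with context", {
  tmp <- withr::local_tempdir()
  map_path <- file.path(tmp, "x.map")
  writeLines(c("1 mA 0 100", "1 mB 0 200"), map_path)
  ped_path <- file.path(tmp, "x.ped")
  writeLines(c("F i1 0 0 1 -9 1 1 1 2", "F i2 0 0 2 -9 1 1"), ped_path)
  expect_error(read_genotypes(ped_path, map_path, "ped"), "line 2")
  writeLines(c("1 mA 0 100", "1 mA 0 200"), map_path)
  writeLines("F i1 0 0 1 -9 1 1 1 2", ped_path)
  expect_error(read_genotypes(ped_path, map_path, "ped"), "duplicate")
})

test_that("pedigree reading toposorts, is order-invariant, and flags cycles", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "ped.tsv")
  writeLines(c("id\tsire\tdam\tsex", "O1\tS\tD\t1", "S\t0\t0\t1", "D\t0\t0\t2"), p)
  ped <- read_pedigree(p)
  expect_equal(nrow(ped), 3)
  expect_lt(match("S", ped$id), match("O1", ped$id))
  expect_lt(match("D", ped$id), match("O1", ped$id))
  # shuffled input gives the same topological constraints
  writeLines(c("id\tsire\tdam\tsex", "D\t0\t0\t2", "O1\tS\tD\t1", "S\t0\t0\t1"), p)
  ped2 <- read_pedigree(p)
  expect_setequal(ped2$id, ped$id)
  expect_lt(match("S", ped2$id), match("O1", ped2$id))
  # self-parent cycle
  writeLines(c("id\tsire\tdam\tsex", "X\tX\t0\t1"), p)
  expect_error(read_pedigree(p), "cycle")
  writeLines(c("id\tsire\tdam\tsex", "X\t0\t0\t9"), p)
  expect_error(read_pedigree(p), "sex")
})

test_that("qc_filter_snps applies the call-rate, MAF and Mendelian rules", {
  ped <- trio_ped(2)
  # 4 individuals x 4 markers: m1 fails MAF (0.0 < 0.025 hom), m2 fine,
  # m3 fails call rate, m4 Mendelian-impossible in both offspring
  geno <- rbind(S  = c(0L, 1L, NA, 0L),
                D  = c(0L, 1L, NA, 0L),
                O1 = c(0L, 1L, 1L, 2L),
                O2 = c(0L, 0L, 1L, 2L))
  G <- make_geno(geno, ids = rownames(geno))
  res <- qc_filter_snps(G, ped)
  expect_equal(res$report$reason, c("maf", "", "call_rate", "mendel"))
  expect_equal(colnames(res$genotypes$geno), "m002")
  # marginal MAF: 0.02 < 0.025 removed
  g2 <- make_geno(matrix(c(rep(0L, 49), 1L, rep(1L, 50)), 50, 2))
  maf <- min(mean(g2$geno[, 1]) / 2, 1 - mean(g2$geno[, 1]) / 2)
  expect_equal(maf, 0.01)
  res2 <- qc_filter_snps(g2, trio_ped(1))
  expect_equal(res2$report$reason[1], "maf")
  # all passing -> identity, and the filter is idempotent
  res3 <- qc_filter_snps(res$genotypes, ped)
  expect_identical(res3$genotypes$geno, res$genotypes$geno)
  expect_true(all(res3$report$reason == ""))
})

test_that("MAF and call rate agree with a brute-force tally on random matrices", {
  set.seed(42)
  for (rep in 1:3) {
    mat <- matrix(sample(c(0L, 1L, 2L, NA), 2500, TRUE,
                         prob = c(.3, .3, .3, .1)), 50, 50)
    G <- make_geno(mat)
    rep_qc <- qc_filter_snps(G, trio_ped(1), call_rate_min = 0,
                             maf_min = 0, mendel_max = 1)$report
    for (j in seq_len(50)) {
      x <- mat[, j]
      expect_equal(rep_qc$call_rate[j], sum(!is.na(x)) / 50)
      p <- sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
      expect_equal(rep_qc$maf[j], min(p, 1 - p))
    }
  }
})

test_that("half-sib families form per focal parent and honour min_offspring", {
  ped <- as_pedigree(rbind(
    data.frame(id = c("S1", "D1", "D2", "D3"), sire = NA, dam = NA,
               sex = c("M", "F", "F", "F")),
    data.frame(id = c("A", "B", "C"), sire = "S1",
               dam = c("D1", "D2", "D3"), sex = "M")))
  # dam ungenotyped case: sire family only
  fams <- build_half_sib_families(ped, c("S1", "A", "B", "C"))
  expect_length(fams, 1)
  expect_equal(fams[[1]]$parent, "S1")
  expect_equal(fams[[1]]$sex, "M")
  expect_length(fams[[1]]$offspring, 3)
  # a parent with a single genotyped offspring is excluded
  fams2 <- build_half_sib_families(ped, c("S1", "D1", "A"))
  expect_length(fams2, 0)
  # fully genotyped nuclear family with 2 offspring -> sire + dam family
  ped3 <- trio_ped(2)
  fams3 <- build_half_sib_families(ped3, ped3$id)
  expect_length(fams3, 2)
  expect_setequal(vapply(fams3, `[[`, "", "sex"), c("M", "F"))
})

test_that("family pair counts match an exhaustive pedigree walk", {
  set.seed(7)
  for (rep in 1:5) {
    nf <- 12
    sires <- sprintf("S%d", 1:nf)
    kids <- sprintf("K%02d", 1:40)
    ped <- as_pedigree(rbind(
      data.frame(id = sires, sire = NA, dam = NA, sex = "M"),
      data.frame(id = kids, sire = sample(sires, 40, TRUE), dam = NA,
                 sex = "F")))
    genotyped <- sample(ped$id, 35)
    mo <- sample(2:3, 1)
    fams <- build_half_sib_families(ped, genotyped, min_offspring = mo)
    got <- sum(vapply(fams, function(f) length(f$offspring), integer(1)))
    # exhaustive walk
    want <- 0
    for (s in sires) {
      if (!(s %in% genotyped)) next
      k <- sum(ped$sire %in% s & ped$id %in% genotyped, na.rm = TRUE)
      if (k >= mo) want <- want + k
    }
    expect_equal(got, want)
  }
})

test_that("missing-genotype fill is Mendelian where forced, mean elsewhere, identity when complete", {
  ped <- trio_ped(1)
  geno <- rbind(S = c(0L, 2L, 1L), D = c(0L, 2L, 1L), O1 = c(NA, NA, NA))
  G <- make_geno(geno, ids = rownames(geno))
  expect_warning(filled <- fill_missing_genotypes(G, ped), "missing")
  expect_equal(unname(filled$geno["O1", 1:2]), c(0L, 2L))   # Mendelian forced
  expect_equal(unname(filled$geno["O1", 3]), 1L)            # marker mean 1
  expect_identical(fill_missing_genotypes(filled, ped), filled)
  # unrelated individual: rounded marker mean (mean 1.2 -> 1)
  g2 <- rbind(a = 2L, b = 2L, c = 1L, d = 1L, e = 0L, f = NA)
  G2 <- make_geno(matrix(g2, 6, 1), ids = rownames(g2))
  ped2 <- as_pedigree(data.frame(id = rownames(g2), sire = NA, dam = NA,
                                 sex = "M"))
  expect_warning(G2f <- fill_missing_genotypes(G2, ped2), "missing")
  expect_equal(unname(G2f$geno["f", 1]), 1L)
})

test_that("Z-linked markers are flagged and excluded from detection input", {
  geno <- matrix(1L, 4, 3)
  G <- make_geno(geno, chrom = c("1", "Z", "1"), pos = c(1e6, 1e6, 2e6))
  expect_equal(sum(is_z_marker(G$map)), 1)
  expect_equal(G$map$chrom[3], "Z")  # sorts after autosomes
})
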
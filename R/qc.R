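#' SNP quality control
#'
#' Removes markers failing any of three per-marker rules: call rate below
#' `call_rate_min`, minor allele frequency below `maf_min`, or Mendelian
#' inconsistency rate across genotyped parent-offspring pairs above
#' `mendel_max`.  A parent-offspring dosage pair is Mendelian-impossible only
#' for the opposing homozygote combinations (0,2) and (2,0); pairs with a
#' missing call are not scored.  Both sire and dam links are scored.
#'
#' @param G [genotypes] object.
#' @param ped pedigree data.frame (used for parent-offspring links).
#' @param call_rate_min,maf_min,mendel_max thresholds; defaults 0.95, 0.025
#'   and 0.05.
#' @return list with `genotypes` (filtered) and `report`: a data.frame of all
#'   input markers with per-rule statistics, the removal reason (`"call_rate"`,
#'   `"maf"`, `"mendel"` or `""`) and a `mendel_scored` flag (FALSE when a
#'   marker had zero scored pairs, in which case the Mendelian rule is
#'   skipped for it).
#' @export
qc_filter_snps <- function(G, ped, call_rate_min = 0.95, maf_min = 0.025,
                           mendel_max = 0.05) {
  geno <- G$geno
  n <- nrow(geno)
  call_rate <- colMeans(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0

  links <- parent_offspring_links(ped, rownames(geno))
  nmark <- ncol(geno)
  if (nrow(links) > 0) {
    gp <- geno[links$parent, , drop = FALSE]
    go <- geno[links$offspring, , drop = FALSE]
    scored <- !is.na(gp) & !is.na(go)
    impossible <- scored & abs(gp - go) == 2L
    n_scored <- colSums(scored)
    mendel <- ifelse(n_scored > 0, colSums(impossible) / n_scored, NA_real_)
  } else {
    n_scored <- rep(0L, nmark)
    mendel <- rep(NA_real_, nmark)
  }

  fail_cr <- call_rate < call_rate_min
  fail_maf <- maf < maf_min
  fail_mendel <- !is.na(mendel) & mendel > mendel_max
  reason <- rep("", nmark)
  reason[fail_mendel] <- "mendel"
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- "call_rate"   # first rule listed wins in the report
  report <- data.frame(marker = colnames(geno), chrom = G$map$chrom,
                       call_rate = call_rate, maf = maf,
                       mendel_rate = mendel, mendel_scored = n_scored > 0,
                       removed = reason != "", reason = reason,
                       stringsAsFactors = FALSE)
  keep <- !report$removed
  out <- genotypes(geno[, keep, drop = FALSE], G$map[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

# genotyped (parent, offspring) id pairs implied by the pedigree
parent_offspring_links <- function(ped, genotyped) {
  rows <- list()
  for (side in c("sire", "dam")) {
    par <- ped[[side]]
    ok <- !is.na(par) & par %in% genotyped & ped$id %in% genotyped
    if (any(ok))
      rows[[side]] <- data.frame(parent = par[ok], offspring = ped$id[ok],
                                 side = side, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(parent = character(0), offspring = character(0),
                      side = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Assemble half-sib families
#'
#' One family per genotyped focal parent (sire or dam) with at least
#' `min_offspring` genotyped offspring.  An offspring whose sire and dam are
#' both genotyped contributes to both a sire family and a dam family.
#'
#' @param ped pedigree data.frame.
#' @param genotyped character vector of genotyped individual ids.
#' @param min_offspring minimum genotyped offspring per family (default 2).
#' @return list of families; each is a list with `parent`, `sex` ("M" for
#'   sire-focal, "F" for dam-focal), `offspring` (ids) and `mates` (the other
#'   parent of each offspring, `NA` when unknown).
#' @export
build_half_sib_families <- function(ped, genotyped, min_offspring = 2) {
  links <- parent_offspring_links(ped, genotyped)
  fams <- list()
  if (nrow(links) == 0) return(fams)
  for (side in c("sire", "dam")) {
    sub <- links[links$side == side, , drop = FALSE]
    for (par in unique(sub$parent)) {
      off <- sub$offspring[sub$parent == par]
      if (length(off) < min_offspring) next
      other <- if (side == "sire") ped$dam else ped$sire
      mates <- other[match(off, ped$id)]
      fams[[length(fams) + 1]] <- list(
        parent = par, sex = if (side == "sire") "M" else "F",
        offspring = off, mates = mates)
    }
  }
  fams
}

#' Fill sparse missing genotypes
#'
#' A missing call is filled with the unique dosage consistent with Mendelian
#' constraints from genotyped parents when one exists (both parents
#' homozygous, or one homozygous parent and the constraint pins the value
#' together with an offspring); otherwise it is filled with the rounded
#' marker mean dosage.  Non-missing calls are never altered.  Intended for
#' the near-complete data this pipeline assumes (a warning is issued above
#' 1% missingness).
#'
#' @param G [genotypes] object.
#' @param ped pedigree data.frame.
#' @return [genotypes] object with no missing calls (when the marker has at
#'   least one non-missing call; otherwise filled with 1).
#' @export
fill_missing_genotypes <- function(G, ped) {
  geno <- G$geno
  frac <- mean(is.na(geno))
  if (frac == 0) return(G)
  if (frac > 0.01)
    warning(sprintf("%.2f%% of calls missing; the deterministic fill is meant for sparse missingness", 100 * frac))
  mean_d <- round(colMeans(geno, na.rm = TRUE))
  mean_d[is.nan(mean_d)] <- 1
  ids <- rownames(geno)
  ix <- match(ped$id, ids)
  sx <- match(ped$sire, ids)
  dx <- match(ped$dam, ids)
  miss <- which(is.na(geno), arr.ind = TRUE)
  for (k in seq_len(nrow(miss))) {
    i <- miss[k, 1]; j <- miss[k, 2]
    prow <- which(ix == i)
    val <- NA_integer_
    if (length(prow) == 1) {
      gs <- if (!is.na(sx[prow])) geno[sx[prow], j] else NA_integer_
      gd <- if (!is.na(dx[prow])) geno[dx[prow], j] else NA_integer_
      if (!is.na(gs) && !is.na(gd) && gs %in% c(0L, 2L) && gd %in% c(0L, 2L))
        val <- as.integer(gs / 2L + gd / 2L)
    }
    geno[i, j] <- if (!is.na(val)) val else as.integer(mean_d[j])
  }
  genotypes(geno, G$map)
}
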
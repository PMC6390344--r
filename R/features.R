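#' GC content per window
#'
#' GC fraction `(#G + #C) / (#A + #C + #G + #T)` per window; `N` bases are
#' excluded from the denominator and an all-N window is `NA`.
#'
#' @param fasta path to a genome FASTA, or a named `Biostrings::DNAStringSet`;
#'   sequence names must match window chromosome labels.
#' @param windows window table from [make_windows()].
#' @return the window table with a `gc` column.
#' @export
gc_content_windows <- function(fasta, windows) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  windows$gc <- NA_real_
  for (ch in unique(windows$chrom)) {
    if (!ch %in% names(seqs)) stop("chromosome absent from FASTA: ", ch)
    wi <- which(windows$chrom == ch)
    v <- Biostrings::Views(seqs[[ch]],
                           start = windows$start[wi] + 1,
                           end = pmin(windows$end[wi], length(seqs[[ch]])))
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    windows$gc[wi] <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom,
                             NA_real_)
  }
  windows
}

#' Read a BED file of intervals
#'
#' Minimal 3+ column BED (chrom, start, end; 0-based half-open).
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  tab <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed BED: ", conditionMessage(e)))
  if (ncol(tab) < 3) stop("malformed BED: need >= 3 columns")
  if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]]))
    stop("malformed BED: start/end not numeric")
  data.frame(chrom = as.character(tab[[1]]), start = tab[[2]], end = tab[[3]],
             stringsAsFactors = FALSE)
}

#' CpG island density per window
#'
#' Value is the number of island base pairs overlapping the window divided
#' by the window width.  Islands come either from a BED table (the usual
#' route, matching UCSC-style island tracks) or from the built-in scanner
#' ([scan_cpg_islands()]).
#'
#' @param islands data.frame `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bed()] or [scan_cpg_islands()].
#' @param windows window table.
#' @return the window table with a `cpg_density` column.
#' @export
cpg_density_windows <- function(islands, windows) {
  windows$cpg_density <- 0
  for (i in seq_len(nrow(windows))) {
    isl <- islands[islands$chrom == windows$chrom[i], , drop = FALSE]
    if (nrow(isl) == 0) next
    ov <- pmin(windows$end[i], isl$end) - pmax(windows$start[i], isl$start)
    ov[ov < 0] <- 0
    windows$cpg_density[i] <- sum(ov) / (windows$end[i] - windows$start[i])
  }
  windows
}

#' Scan a sequence for CpG islands
#'
#' Classical three-criteria definition: windows of at least `min_length` bp
#' with GC fraction >= `min_gc` and observed/expected CpG ratio
#' (`#CG * L / (#C * #G)`) >= `min_oe`.  All qualifying `min_length`-bp
#' windows (slid by `step`) are merged into maximal islands.
#'
#' @param fasta path to FASTA or a `DNAStringSet`.
#' @param min_length,min_gc,min_oe criteria (defaults 200, 0.5, 0.6).
#' @param step slide step in bp (default 1).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
scan_cpg_islands <- function(fasta, min_length = 200, min_gc = 0.5,
                             min_oe = 0.6, step = 1) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- list()
  for (ch in names(seqs)) {
    s <- strsplit(as.character(seqs[[ch]]), "")[[1]]
    L <- length(s)
    if (L < min_length) next
    isC <- as.integer(s == "C"); isG <- as.integer(s == "G")
    isCG <- as.integer(c(s[-L] == "C" & s[-1] == "G", 0L))
    cumC <- cumsum(c(0L, isC)); cumG <- cumsum(c(0L, isG))
    cumCG <- cumsum(c(0L, isCG))
    starts <- seq(0, L - min_length, by = step)   # 0-based
    nC <- cumC[starts + min_length + 1] - cumC[starts + 1]
    nG <- cumG[starts + min_length + 1] - cumG[starts + 1]
    # CG dinucleotides fully inside the window
    nCG <- cumCG[starts + min_length] - cumCG[starts + 1]
    gc <- (nC + nG) / min_length
    oe <- ifelse(nC * nG > 0, nCG * min_length / (nC * nG), 0)
    ok <- gc >= min_gc & oe >= min_oe
    if (!any(ok)) next
    st <- starts[ok]; en <- st + min_length
    merged <- list(c(st[1], en[1]))
    for (i in seq_along(st)[-1]) {
      lastr <- merged[[length(merged)]]
      if (st[i] <= lastr[2]) merged[[length(merged)]][2] <- max(lastr[2], en[i])
      else merged[[length(merged) + 1]] <- c(st[i], en[i])
    }
    out[[ch]] <- data.frame(chrom = ch,
                            start = vapply(merged, `[`, numeric(1), 1),
                            end = vapply(merged, `[`, numeric(1), 2),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Common haplotype alleles per window
#'
#' Counts, per window, the distinct marker-string haplotype alleles with
#' frequency at least `min_freq` among the supplied haplotypes.
#'
#' @param haps haplotype matrix (haplotypes x markers, 0/1), columns named
#'   by marker id.
#' @param map marker map aligned with the columns of `haps`.
#' @param windows window table.
#' @param min_freq minimum allele frequency (default 0.01).
#' @return the window table with columns `n_markers` and `n_common_haps`
#'   (`NA` for windows with 0 markers).
#' @export
common_haplotype_alleles <- function(haps, map, windows, min_freq = 0.01) {
  stopifnot(ncol(haps) == nrow(map))
  windows$n_markers <- 0L
  windows$n_common_haps <- NA_integer_
  for (i in seq_len(nrow(windows))) {
    j <- which(map$chrom == windows$chrom[i] & map$pos > windows$start[i] &
                 map$pos <= windows$end[i])
    windows$n_markers[i] <- length(j)
    if (length(j) == 0) next
    str <- apply(haps[, j, drop = FALSE], 1, paste, collapse = "")
    freq <- table(str) / length(str)
    windows$n_common_haps[i] <- sum(freq >= min_freq)
  }
  windows
}

#' LD pruning in non-overlapping marker blocks
#'
#' Within each non-overlapping block of `block` markers (map order), pairs
#' are scanned greedily in order; whenever a pair of surviving markers has
#' squared dosage correlation above `r2_max`, the member with the lower MAF
#' is dropped (ties: the later position).  Monomorphic markers are never
#' tested and always retained.
#'
#' @param G [genotypes] object.
#' @param r2_max threshold on r^2 (default 0.5).
#' @param block block size in markers (default 50).
#' @return character vector of surviving marker ids.
#' @export
ld_prune <- function(G, r2_max = 0.5, block = 50) {
  geno <- G$geno
  m <- ncol(geno)
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  mono <- apply(geno, 2, function(x) var(x, na.rm = TRUE)) %in% c(0, NA)
  for (b0 in seq(1, m, by = block)) {
    idx <- b0:min(b0 + block - 1, m)
    for (a in seq_along(idx)) {
      ja <- idx[a]
      if (!keep[ja] || mono[ja]) next
      for (bb in seq_along(idx)) {
        if (bb <= a) next
        jb <- idx[bb]
        if (!keep[jb] || mono[jb] || !keep[ja]) next
        r <- suppressWarnings(cor(geno[, ja], geno[, jb],
                                  use = "complete.obs"))
        if (!is.na(r) && r^2 > r2_max) {
          victim <- if (maf[ja] < maf[jb]) ja
                    else if (maf[jb] < maf[ja]) jb
                    else jb           # tie: later position
          keep[victim] <- FALSE
        }
      }
    }
  }
  colnames(geno)[keep]
}

#' Genomic inbreeding coefficients
#'
#' Method-of-moments F from observed vs expected homozygote counts:
#' `F = (O - E) / (L - E)` with
#' `E = sum_j (1 - 2 p_j (1 - p_j) n_j / (n_j - 1))` over the markers
#' scored for the individual (cohort allele frequencies, small-sample
#' corrected).  Typically run on an LD-pruned marker set ([ld_prune()]).
#'
#' @param G [genotypes] object (restricted to the pruned set).
#' @return data.frame `id`, `O`, `E`, `L`, `F` (`NA` when `L == E`).
#' @export
inbreeding_coefficient <- function(G) {
  geno <- G$geno
  nj <- colSums(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  corr <- ifelse(nj > 1, nj / (nj - 1), 1)
  ehet <- 2 * p * (1 - p) * corr       # expected het per marker
  res <- lapply(seq_len(nrow(geno)), function(i) {
    scored <- !is.na(geno[i, ]) & nj > 1
    L <- sum(scored)
    O <- sum(geno[i, scored] != 1L)
    E <- sum(1 - ehet[scored])
    data.frame(id = rownames(geno)[i], O = O, E = E, L = L,
               F = if (abs(L - E) < 1e-12) NA_real_ else (O - E) / (L - E),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlations between recombination rate and genome features
#'
#' Windowwise Pearson correlations of `c_w` with each supplied feature
#' column (pairwise-complete), the correlation of per-chromosome mean rate
#' with chromosome length, and mean rates by chicken chromosome size class
#' (macro GGA1-5, intermediate GGA6-10, micro GGA11-28).
#'
#' @param track window track with `c_w` (all feature tracks must share its
#'   window order).
#' @param features named list of numeric vectors (one value per window).
#' @param chromosome_lengths named vector of chromosome lengths (bp or Mb).
#' @return list with `window_correlations` (data.frame feature, r, n),
#'   `chrom_length_correlation`, `class_means` (data.frame class,
#'   mean_rate, n_windows).
#' @export
feature_correlations <- function(track, features, chromosome_lengths) {
  wc <- do.call(rbind, lapply(names(features), function(f) {
    x <- features[[f]]
    ok <- complete.cases(track$c_w, x)
    n <- sum(ok)
    r <- if (n >= 3 && sd(x[ok]) > 0 && sd(track$c_w[ok]) > 0)
           cor(track$c_w[ok], x[ok]) else NA_real_
    data.frame(feature = f, r = r, n = n, stringsAsFactors = FALSE)
  }))
  chr_mean <- tapply(track$c_w, track$chrom, mean, na.rm = TRUE)
  len <- chromosome_lengths[names(chr_mean)]
  okc <- complete.cases(chr_mean, len)
  rlen <- if (sum(okc) >= 3 && sd(len[okc]) > 0 && sd(chr_mean[okc]) > 0)
            cor(chr_mean[okc], len[okc]) else NA_real_
  cls <- chrom_size_class(track$chrom)
  cm <- aggregate(track$c_w, list(class = cls), mean, na.rm = TRUE)
  names(cm)[2] <- "mean_rate"
  cm$n_windows <- as.integer(table(cls)[cm$class])
  list(window_correlations = wc, chrom_length_correlation = rlen,
       class_means = cm)
}

#' Chicken chromosome size classes
#'
#' Macrochromosomes GGA1-5, intermediate GGA6-10, microchromosomes
#' GGA11-28; anything else (e.g. Z) is "other".
#'
#' @param chrom chromosome labels (numbers, possibly prefixed "GGA").
#' @return character vector of classes.
#' @export
chrom_size_class <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^GGA", "", chrom)))
  out <- rep("other", length(chrom))
  out[!is.na(num) & num >= 1 & num <= 5] <- "macro"
  out[!is.na(num) & num >= 6 & num <= 10] <- "intermediate"
  out[!is.na(num) & num >= 11 & num <= 28] <- "micro"
  out
}
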
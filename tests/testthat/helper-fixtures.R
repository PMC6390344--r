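# Shared fixture builders (everything generated in code; no stored data).

# genotype object from a plain matrix, markers laid out on one or more
# chromosomes at 1-Mb spacing unless positions are given
make_geno <- function(mat, chrom = NULL, pos = NULL, ids = NULL,
                      markers = NULL) {
  n <- nrow(mat); m <- ncol(mat)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  if (is.null(markers)) markers <- sprintf("m%03d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1e6
  dimnames(mat) <- list(ids, markers)
  genotypes(mat, data.frame(marker = markers, chrom = chrom, pos = pos))
}

# trio pedigree: sire S, dam D, offspring O1..k
trio_ped <- function(k = 1) {
  as_pedigree(rbind(
    data.frame(id = "S", sire = NA, dam = NA, sex = "M"),
    data.frame(id = "D", sire = NA, dam = NA, sex = "F"),
    data.frame(id = sprintf("O%d", seq_len(k)), sire = "S", dam = "D",
               sex = rep(c("M", "F"), length.out = k))))
}

# brute-force minimum-crossover phasing oracle: enumerate all 2^K phase
# vectors, count origin switches over every offspring's known subsequence
brute_force_phase_crossovers <- function(tm) {
  K <- ncol(tm)
  best <- Inf
  for (code in 0:(2^K - 1)) {
    h <- as.integer(intToBits(code))[1:K]
    tot <- 0
    for (o in seq_len(nrow(tm))) {
      org <- bitwXor(tm[o, ], h)
      org <- org[!is.na(org)]
      if (length(org) > 1) tot <- tot + sum(diff(org) != 0)
    }
    best <- min(best, tot)
  }
  best
}

total_crossovers_from_origin <- function(origin) {
  sum(apply(origin, 1, function(o) {
    o <- o[!is.na(o)]
    if (length(o) > 1) sum(diff(o) != 0) else 0
  }))
}

# exhaustive two-state decode oracle: enumerate all 2^n hidden paths
brute_force_decode <- function(obs, pos, eps, rate_per_bp = 1e-8) {
  n <- length(obs)
  d <- diff(pos)
  psw <- pmax(0.5 * (1 - exp(-2 * rate_per_bp * d)), 1e-12)
  best <- NULL; best_lp <- -Inf
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code))[1:n]
    lp <- sum(ifelse(path == obs, log(1 - eps), log(eps)))
    if (n > 1)
      lp <- lp + sum(ifelse(diff(path) != 0, log(psw), log1p(-psw)))
    if (lp > best_lp) { best_lp <- lp; best <- path }
  }
  best
}

# per-bp accumulation oracle for window rates (delta-array + cumsum)
per_bp_window_oracle <- function(intervals, T, windows) {
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    L <- max(windows$end[wi])
    delta <- numeric(L + 1)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(iv))) {
      contrib <- 1 / (iv$r_mb[r] * 1e6)          # mass per bp
      delta[iv$left_pos[r] + 1] <- delta[iv$left_pos[r] + 1] + contrib
      delta[iv$right_pos[r] + 1] <- delta[iv$right_pos[r] + 1] - contrib
    }
    dens <- cumsum(delta)[seq_len(L)]            # dens[b] covers [b-1, b)
    cums <- c(0, cumsum(dens))
    out[wi] <- (cums[windows$end[wi] + 1] - cums[windows$start[wi] + 1]) / T
  }
  out
}

random_intervals <- function(n, chrom, L, rng_max_len = 2e6) {
  left <- runif(n, 0, L - 1)
  len <- runif(n, 1, pmin(rng_max_len, L - left))
  data.frame(parent = sample(sprintf("P%d", 1:8), n, TRUE),
             offspring = sprintf("O%d", seq_len(n)),
             sex = sample(c("M", "F"), n, TRUE), chrom = chrom,
             left_pos = floor(left), right_pos = floor(left + len),
             r_mb = (floor(left + len) - floor(left)) / 1e6,
             stringsAsFactors = FALSE)
}

# elementwise xor of a matrix with a per-column phase vector (keeps dims)
xor_phase <- function(tm, phase) {
  out <- bitwXor(tm, rep(phase, each = nrow(tm)))
  dim(out) <- dim(tm)
  dimnames(out) <- dimnames(tm)
  out
}
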
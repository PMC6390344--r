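#' Infer transmitted alleles and phase within one half-sib family
#'
#' Stage 1: at every marker where the focal parent is heterozygous, the
#' allele it transmitted to each offspring is deduced from the offspring and
#' other-parent genotypes when unique (offspring homozygous, or offspring
#' heterozygous with a homozygous mate); otherwise it is unknown.
#' Stage 2: the focal parent's chromosome-wide phase (which transmitted
#' alleles sit on hapA vs hapB) is chosen to minimise the total number of
#' crossovers over the family's offspring, by a sequential scan in which
#' each offspring votes, at every marker where its transmission is known,
#' for the phase that avoids a crossover since its previous known marker.
#' Ties are resolved toward the phase of the preceding marker; the global
#' hapA/hapB swap is unobservable.
#'
#' @param family a half-sib family from [build_half_sib_families()].
#' @param G [genotypes] object.
#' @param chrom chromosome label to work on.
#' @return list with `markers` (indices into `G$map` of the focal-het
#'   markers), `positions` (bp), `phase` (0/1 per marker: allele carried by
#'   hapA), and `origin`: an offspring-by-marker matrix coded 0 (hapA),
#'   1 (hapB) or `NA` (unknown).
#' @export
infer_transmitted_alleles <- function(family, G, chrom) {
  if (length(family$offspring) < 2)
    stop("half-sib family needs at least 2 offspring")
  on_chr <- which(G$map$chrom == chrom)
  gp <- G$geno[family$parent, on_chr]
  het <- which(!is.na(gp) & gp == 1L)
  mk <- on_chr[het]
  noff <- length(family$offspring)
  if (length(het) == 0) {
    return(list(markers = integer(0), positions = numeric(0),
                phase = integer(0),
                origin = matrix(NA_integer_, noff, 0,
                                dimnames = list(family$offspring, NULL))))
  }
  go <- G$geno[family$offspring, mk, drop = FALSE]
  gm <- matrix(NA_integer_, noff, length(mk))
  has_mate <- !is.na(family$mates) & family$mates %in% rownames(G$geno)
  if (any(has_mate))
    gm[has_mate, ] <- G$geno[family$mates[has_mate], mk, drop = FALSE]
  # transmitted allele of the focal parent (0/1/NA)
  tm <- matrix(NA_integer_, noff, length(mk))
  tm[!is.na(go) & go == 0L] <- 0L
  tm[!is.na(go) & go == 2L] <- 1L
  amb <- !is.na(go) & go == 1L
  tm[amb & !is.na(gm) & gm == 0L] <- 1L
  tm[amb & !is.na(gm) & gm == 2L] <- 0L

  phase <- min_recombinant_phase(tm, positions = G$map$pos[mk])
  origin <- tm
  for (k in seq_along(phase))
    origin[, k] <- bitwXor(tm[, k], phase[k])
  dimnames(origin) <- list(family$offspring, G$map$marker[mk])
  list(markers = mk, positions = G$map$pos[mk], phase = phase, origin = origin)
}

# Minimum-recombinant phasing over a transmitted-allele matrix
# (offspring x markers, entries 0/1/NA).  Exact dynamic program over the
# per-offspring origin states (2^n_offspring states); falls back to the
# sequential voting scan for very large families, where votes are dense
# enough that the greedy solution is reliable.  When `positions` are
# supplied, each potential crossover is weighted by its genetic-distance
# prior, log((1 - p)/p) with p the Haldane switch probability over the
# offspring's marker gap, making the optimum the MAP phase; without
# positions all crossovers weigh 1 and the optimum minimises the raw
# crossover count.  Ties resolve toward the previous marker's phase.
min_recombinant_phase <- function(tm, positions = NULL, rate_per_bp = 1e-8) {
  if (nrow(tm) <= 10) min_recombinant_phase_dp(tm, positions, rate_per_bp)
  else min_recombinant_phase_greedy(tm)
}

min_recombinant_phase_dp <- function(tm, positions = NULL,
                                     rate_per_bp = 1e-8) {
  K <- ncol(tm)
  if (K == 0) return(integer(0))
  noff <- nrow(tm)
  # crossover weight for offspring o at marker k: prior odds against a
  # switch over the gap back to o's previous informative marker
  wts <- matrix(1, noff, K)
  if (!is.null(positions) && K > 1) {
    for (o in seq_len(noff)) {
      kn <- which(!is.na(tm[o, ]))
      if (length(kn) > 1) {
        d <- diff(positions[kn])
        p <- pmin(pmax(0.5 * (1 - exp(-2 * rate_per_bp * d)), 1e-12), 0.5)
        wts[o, kn[-1]] <- log((1 - p) / p)
      }
    }
  }
  nstate <- 2L^noff
  states <- 0:(nstate - 1)
  bits <- matrix(0L, nstate, noff)        # bits[s+1, o] = origin of o in s
  for (o in seq_len(noff)) bits[, o] <- bitwAnd(states %/% 2L^(o - 1), 1L)
  dp <- rep(Inf, nstate); dp[1] <- 0
  choice_h <- matrix(NA_integer_, K, nstate)
  choice_prev <- matrix(NA_integer_, K, nstate)
  seen <- rep(FALSE, noff)
  for (k in seq_len(K)) {
    tk <- tm[, k]
    known <- which(!is.na(tk))
    if (length(known) == 0) {
      # phase unconstrained: carry states through, record tie choice later
      choice_h[k, ] <- -1L
      choice_prev[k, ] <- states
      next
    }
    keep_mask <- sum(2L^(known - 1))
    scored <- known[seen[known]]
    cand_tot <- cand_new <- numeric(0); cand_h <- cand_prev <- integer(0)
    for (h in 0:1) {
      org <- bitwXor(tk[known], h)
      newbits <- sum(org * 2L^(known - 1))
      cost <- if (length(scored) == 0) numeric(nstate) else {
        mism <- vapply(scored, function(o)
          wts[o, k] * (bits[, o] != bitwXor(tk[o], h)), numeric(nstate))
        if (is.matrix(mism)) rowSums(mism) else mism
      }
      cand_tot <- c(cand_tot, dp + cost)
      cand_new <- c(cand_new,
                    bitwOr(bitwAnd(states, bitwNot(keep_mask)), newbits))
      cand_h <- c(cand_h, rep(h, nstate))
      cand_prev <- c(cand_prev, states)
    }
    fin <- is.finite(cand_tot)
    cand_tot <- cand_tot[fin]; cand_new <- cand_new[fin]
    cand_h <- cand_h[fin]; cand_prev <- cand_prev[fin]
    ord <- order(cand_new, cand_tot, cand_h)
    first <- !duplicated(cand_new[ord])
    dp <- rep(Inf, nstate)
    win <- ord[first]
    dp[cand_new[win] + 1L] <- cand_tot[win]
    choice_h[k, cand_new[win] + 1L] <- cand_h[win]
    choice_prev[k, cand_new[win] + 1L] <- cand_prev[win]
    seen[known] <- TRUE
  }
  # backtrack
  phase <- integer(K)
  s <- which.min(dp) - 1L
  for (k in rev(seq_len(K))) {
    h <- choice_h[k, s + 1L]
    if (is.na(h)) { phase[k] <- 0L; next }
    if (h == -1L) { phase[k] <- NA_integer_ }  # unconstrained, fill below
    else { phase[k] <- h; s <- choice_prev[k, s + 1L] }
  }
  # unconstrained markers take the previous marker's phase (first -> 0)
  prev <- 0L
  for (k in seq_len(K)) {
    if (is.na(phase[k])) phase[k] <- prev else prev <- phase[k]
  }
  phase
}

min_recombinant_phase_greedy <- function(tm) {
  K <- ncol(tm)
  if (K == 0) return(integer(0))
  noff <- nrow(tm)
  phase <- integer(K)
  # origin of each offspring at its last known marker, under current phase
  last_origin <- rep(NA_integer_, noff)
  known1 <- !is.na(tm[, 1])
  last_origin[known1] <- tm[known1, 1]  # phase[1] = 0
  if (K == 1) return(phase)
  for (k in 2:K) {
    tk <- tm[, k]
    voters <- !is.na(tk) & !is.na(last_origin)
    if (any(voters)) {
      # vote for the phase making origin at k equal the previous origin
      v <- bitwXor(tk[voters], last_origin[voters])
      s <- sum(v)
      phase[k] <- if (2 * s > sum(voters)) 1L
                  else if (2 * s < sum(voters)) 0L
                  else phase[k - 1]
    } else {
      phase[k] <- phase[k - 1]
    }
    upd <- !is.na(tk)
    last_origin[upd] <- bitwXor(tk[upd], phase[k])
  }
  phase
}

#' Call crossover intervals from one origin sequence
#'
#' With `smoothing_error = 0`, every adjacent pair of opposite origin codes
#' (after dropping unknowns) yields one recombination interval.  With
#' `smoothing_error > 0`, the most probable hidden origin path of a
#' two-state model is decoded by Viterbi: the miscode probability is
#' `smoothing_error` and the switch probability between consecutive
#' informative markers follows the genetic prior
#' `0.5 * (1 - exp(-2 * rate_per_bp * d))` (Haldane, with `d` the marker
#' gap in bp), so isolated single-marker flips are absorbed rather than
#' producing double crossovers.
#'
#' @param origin integer vector of origin codes (0/1/`NA`) at `positions`.
#' @param positions marker positions (bp, increasing).
#' @param smoothing_error miscode probability in `[0, 0.5)`; default 0.005.
#' @param rate_per_bp genetic prior on crossover rate per bp (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param markers optional marker ids aligned with `positions`.
#' @return data.frame `left_marker`, `left_pos`, `right_marker`,
#'   `right_pos`, `r_mb` — one row per crossover interval.
#' @export
call_crossovers <- function(origin, positions, smoothing_error = 0.005,
                            rate_per_bp = 1e-8, markers = NULL) {
  stopifnot(smoothing_error >= 0, smoothing_error < 0.5,
            length(origin) == length(positions))
  if (is.null(markers)) markers <- as.character(seq_along(positions))
  keep <- !is.na(origin)
  o <- origin[keep]; p <- positions[keep]; mk <- markers[keep]
  empty <- data.frame(left_marker = character(0), left_pos = numeric(0),
                      right_marker = character(0), right_pos = numeric(0),
                      r_mb = numeric(0), stringsAsFactors = FALSE)
  if (length(o) < 2) return(empty)
  if (smoothing_error > 0) o <- viterbi_two_state(o, p, smoothing_error, rate_per_bp)
  br <- which(diff(o) != 0)
  if (length(br) == 0) return(empty)
  data.frame(left_marker = mk[br], left_pos = p[br],
             right_marker = mk[br + 1], right_pos = p[br + 1],
             r_mb = (p[br + 1] - p[br]) / 1e6, stringsAsFactors = FALSE)
}

# Exact two-state Viterbi decode of an observed 0/1 sequence.
viterbi_two_state <- function(obs, pos, eps, rate_per_bp) {
  n <- length(obs)
  le_match <- log(1 - eps); le_miss <- log(eps)
  emit <- function(s, y) if (s == y) le_match else le_miss
  d <- diff(pos)
  psw <- pmax(0.5 * (1 - exp(-2 * rate_per_bp * d)), 1e-12)
  lsw <- log(psw); lst <- log1p(-psw)
  v0 <- emit(0L, obs[1]); v1 <- emit(1L, obs[1])
  bt <- matrix(0L, 2, n)
  for (i in 2:n) {
    c00 <- v0 + lst[i - 1]; c10 <- v1 + lsw[i - 1]
    c01 <- v0 + lsw[i - 1]; c11 <- v1 + lst[i - 1]
    if (c00 >= c10) { n0 <- c00; bt[1, i] <- 0L } else { n0 <- c10; bt[1, i] <- 1L }
    if (c11 >= c01) { n1 <- c11; bt[2, i] <- 1L } else { n1 <- c01; bt[2, i] <- 0L }
    v0 <- n0 + emit(0L, obs[i]); v1 <- n1 + emit(1L, obs[i])
  }
  path <- integer(n)
  path[n] <- if (v0 >= v1) 0L else 1L
  for (i in n:2) path[i - 1] <- bt[path[i] + 1, i]
  path
}

#' Detect crossovers in all half-sib families
#'
#' Runs [infer_transmitted_alleles()] and [call_crossovers()] family by
#' family over all autosomes (Z-linked markers are excluded from
#' detection), optionally followed by one map-error scan that removes
#' low-confidence markers and re-runs detection once.
#'
#' @param G [genotypes] object.
#' @param ped pedigree data.frame.
#' @param min_offspring minimum genotyped offspring per family (default 2).
#' @param smoothing_error passed to [call_crossovers()].
#' @param rate_per_bp genetic prior for the decode (default 1e-8).
#' @param scan_map_errors run [map_error_scan()] and re-detect once
#'   (default TRUE).
#' @param confidence_min map confidence threshold (default 0.9).
#' @return list with `intervals` (data.frame parent, offspring, sex, chrom,
#'   left_marker, left_pos, right_marker, right_pos, r_mb), `pairs`
#'   (data.frame parent, sex, offspring — every meiosis, with or without
#'   events), `confidence` (marker confidence table or NULL), `origins`
#'   (per family/chromosome origin blocks) and `removed_markers`.
#' @export
detect_recombination <- function(G, ped, min_offspring = 2,
                                 smoothing_error = 0.005, rate_per_bp = 1e-8,
                                 scan_map_errors = TRUE, confidence_min = 0.9) {
  autosomal <- !is_z_marker(G$map)
  Ga <- genotypes(G$geno[, autosomal, drop = FALSE],
                  G$map[autosomal, , drop = FALSE])
  fams <- build_half_sib_families(ped, rownames(Ga$geno), min_offspring)
  if (length(fams) == 0)
    stop("no half-sib family with >= ", min_offspring, " genotyped offspring")
  run <- run_detection(Ga, fams, smoothing_error, rate_per_bp)
  conf <- NULL; removed <- character(0)
  if (scan_map_errors) {
    conf <- map_error_scan(run$origins, Ga, ped)
    removed <- conf$marker[conf$confidence < confidence_min]
    if (length(removed) > 0) {
      keep <- !(Ga$map$marker %in% removed)
      Ga <- genotypes(Ga$geno[, keep, drop = FALSE], Ga$map[keep, , drop = FALSE])
      run <- run_detection(Ga, fams, smoothing_error, rate_per_bp)
    }
  }
  sex_of <- setNames(ped$sex, ped$id)
  pairs <- do.call(rbind, lapply(fams, function(f)
    data.frame(parent = f$parent, sex = unname(sex_of[f$parent]),
               offspring = f$offspring, stringsAsFactors = FALSE)))
  rownames(pairs) <- NULL
  list(intervals = run$intervals, pairs = pairs, confidence = conf,
       origins = run$origins, removed_markers = removed, families = fams)
}

run_detection <- function(G, fams, smoothing_error, rate_per_bp) {
  sexes <- vapply(fams, function(f) f$sex, character(1))
  chroms <- unique(G$map$chrom)
  origins <- list()
  rows <- list()
  for (fi in seq_along(fams)) {
    fam <- fams[[fi]]
    for (ch in chroms) {
      blk <- infer_transmitted_alleles(fam, G, ch)
      if (length(blk$markers) == 0) next
      origins[[length(origins) + 1]] <-
        c(blk, list(family = fam$parent, chrom = ch))
      for (oi in seq_along(fam$offspring)) {
        iv <- call_crossovers(blk$origin[oi, ], blk$positions,
                              smoothing_error, rate_per_bp,
                              markers = colnames(blk$origin))
        if (nrow(iv) > 0) {
          iv$parent <- fam$parent; iv$offspring <- fam$offspring[oi]
          iv$sex <- sexes[fi]; iv$chrom <- ch
          rows[[length(rows) + 1]] <- iv
        }
      }
    }
  }
  intervals <- if (length(rows)) do.call(rbind, rows)
    else data.frame(left_marker = character(0), left_pos = numeric(0),
                    right_marker = character(0), right_pos = numeric(0),
                    r_mb = numeric(0), parent = character(0),
                    offspring = character(0), sex = character(0),
                    chrom = character(0), stringsAsFactors = FALSE)
  intervals <- intervals[, c("parent", "offspring", "sex", "chrom",
                             "left_marker", "left_pos", "right_marker",
                             "right_pos", "r_mb")]
  rownames(intervals) <- NULL
  list(intervals = intervals, origins = origins)
}

#' Scan for map errors
#'
#' Scores each marker as `1 - max(singleton-flip rate, Mendelian-error
#' rate)`.  The singleton-flip rate is the fraction of informative meioses
#' (offspring origin sequences in which the marker's origin is known and
#' has a known informative neighbour on each side) where the marker's
#' origin differs from both flanking informative origins; the Mendelian
#' error rate is the per-marker rate of impossible parent-offspring dosage
#' pairs.  Markers with fewer than `min_meioses` informative meioses keep
#' score 1 and are flagged unscored.
#'
#' @param origins origin blocks as returned in `detect_recombination()$origins`.
#' @param G [genotypes] object used for the detection run.
#' @param ped pedigree data.frame (for Mendelian pairs).
#' @param min_meioses minimum informative meioses for a scored value
#'   (default 20).
#' @return data.frame `marker`, `confidence`, `flip_rate`, `mendel_rate`,
#'   `n_informative`, `scored`.
#' @export
map_error_scan <- function(origins, G, ped, min_meioses = 20) {
  m <- ncol(G$geno)
  flips <- integer(m); inform <- integer(m)
  names(flips) <- names(inform) <- G$map$marker
  for (blk in origins) {
    mk <- colnames(blk$origin)
    for (oi in seq_len(nrow(blk$origin))) {
      o <- blk$origin[oi, ]
      known <- which(!is.na(o))
      if (length(known) < 3) next
      mid <- known[-c(1, length(known))]
      left <- known[seq_len(length(known) - 2)]
      right <- known[-c(1, 2)]
      isflip <- o[mid] != o[left] & o[mid] != o[right]
      inform[mk[mid]] <- inform[mk[mid]] + 1L
      flips[mk[mid][isflip]] <- flips[mk[mid][isflip]] + 1L
    }
  }
  flip_rate <- ifelse(inform > 0, flips / inform, 0)

  links <- parent_offspring_links(ped, rownames(G$geno))
  if (nrow(links) > 0) {
    gp <- G$geno[links$parent, , drop = FALSE]
    go <- G$geno[links$offspring, , drop = FALSE]
    scored <- !is.na(gp) & !is.na(go)
    mendel <- ifelse(colSums(scored) > 0,
                     colSums(scored & abs(gp - go) == 2L) / colSums(scored), 0)
  } else mendel <- rep(0, m)

  scored_flag <- inform >= min_meioses
  conf <- ifelse(scored_flag, 1 - pmax(flip_rate, mendel), 1)
  data.frame(marker = G$map$marker, confidence = conf,
             flip_rate = flip_rate, mendel_rate = mendel,
             n_informative = as.integer(inform), scored = scored_flag,
             stringsAsFactors = FALSE)
}

#' Write detected intervals as TSV
#' @param intervals interval data.frame from [detect_recombination()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_intervals <- function(intervals, path) {
  write.table(intervals, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
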
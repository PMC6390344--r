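#' Window recombination rates
#'
#' For each window, `c_w = (sum_i x_i / r_i) / T`, where `x_i` is the Mb
#' overlap of recombination interval `i` with the window, `r_i` its Mb
#' length, and `T` the total number of parent-offspring pairs.  Intervals
#' contribute fractionally to every window they overlap, so the window
#' rates on a chromosome sum to (events on that chromosome) / T.
#'
#' @param intervals data.frame with `chrom`, `left_pos`, `right_pos`,
#'   `r_mb` (e.g. from [detect_recombination()]).
#' @param T total number of parent-offspring pairs.
#' @param windows window table from [make_windows()].
#' @param map optional marker map; when given, a per-window SNP count
#'   `n_snps` is added (windows without SNPs are excluded from the hotspot
#'   ranking denominator downstream).
#' @return the window table with columns `mass` (accumulated
#'   `sum x_i/r_i`), `c_w`, `n_snps` (if `map` given) and `label`
#'   (initially "none"); attribute `T` records the pair count.
#' @export
window_rates <- function(intervals, T, windows, map = NULL) {
  if (T <= 0) stop("T (number of parent-offspring pairs) must be positive")
  out <- windows
  out$mass <- 0
  for (ch in unique(intervals$chrom)) {
    wi <- which(out$chrom == ch)
    if (length(wi) == 0) stop("interval on chromosome ", ch,
                              " but no windows for it")
    starts <- out$start[wi]; ends <- out$end[wi]
    L <- max(ends)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (any(iv$left_pos < 0 | iv$right_pos > L))
      stop("interval outside chromosome bounds on ", ch)
    mass <- numeric(length(wi))
    for (r in seq_len(nrow(iv))) {
      l <- iv$left_pos[r]; rr <- iv$right_pos[r]
      k1 <- findInterval(l, starts); k2 <- findInterval(rr, starts)
      k1 <- max(k1, 1L); k2 <- min(k2, length(wi))
      ks <- k1:k2
      ov <- pmin(rr, ends[ks]) - pmax(l, starts[ks])
      ov[ov < 0] <- 0
      mass[ks] <- mass[ks] + (ov / 1e6) / iv$r_mb[r]
    }
    out$mass[wi] <- mass
  }
  out$c_w <- out$mass / T
  if (!is.null(map)) {
    out$n_snps <- vapply(seq_len(nrow(out)), function(i) {
      sum(map$chrom == out$chrom[i] & map$pos > out$start[i] &
            map$pos <= out$end[i])
    }, integer(1))
  }
  out$label <- "none"
  attr(out, "T") <- T
  out
}

#' Label recombination hotspots and coldspots
#'
#' Per chromosome, the `top_fraction` (default 10%) of windows with the
#' highest recombination rates are hotspots (`k = ceiling(top_fraction *
#' #windows)`, ties broken by ascending genomic position; only windows with
#' `c_w > 0` can be hotspots) and windows with zero accumulated event mass
#' are coldspots.  When the track carries a per-window SNP count, windows
#' without SNPs are excluded from the ranking denominator and keep label
#' "none".
#'
#' @param track window track from [window_rates()].
#' @param top_fraction fraction labelled hotspot per chromosome (default 0.10).
#' @return the track with `label` filled in (`"hotspot"`, `"coldspot"`,
#'   `"none"`).
#' @export
classify_hotspots_coldspots <- function(track, top_fraction = 0.10) {
  if (nrow(track) == 0) stop("empty window track")
  track$label <- "none"
  covered <- if ("n_snps" %in% names(track)) track$n_snps > 0
             else rep(TRUE, nrow(track))
  for (ch in unique(track$chrom)) {
    wi <- which(track$chrom == ch & covered)
    if (length(wi) == 0) next
    track$label[wi][track$mass[wi] == 0] <- "coldspot"
    k <- ceiling(top_fraction * length(wi))
    ord <- wi[order(-track$c_w[wi], track$start[wi])]
    hot <- head(ord, k)
    hot <- hot[track$c_w[hot] > 0]
    track$label[hot] <- "hotspot"
  }
  track
}

#' Per-parent genome-wide recombination number (GRN)
#'
#' GRN is the average number of detected crossover events over the
#' autosomes per meiosis (offspring): total events divided by the number of
#' parent-offspring pairs `n`, counting offspring with zero events.
#'
#' @param intervals interval data.frame (one row per event).
#' @param pairs data.frame `parent`, `sex`, `offspring` listing every
#'   scored meiosis (from [detect_recombination()]).
#' @return data.frame `parent`, `sex`, `n`, `events`, `grn`.
#' @export
parent_grn <- function(intervals, pairs) {
  n <- table(pairs$parent)
  ev <- table(factor(intervals$parent, levels = names(n)))
  sex <- pairs$sex[match(names(n), pairs$parent)]
  data.frame(parent = names(n), sex = sex, n = as.integer(n),
             events = as.integer(ev),
             grn = as.integer(ev) / as.integer(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-parent genome-wide hotspot usage (GHU)
#'
#' GHU is the proportion of a parent's crossover events that fall within
#' hotspot windows.  Each event contributes its fractional hotspot mass
#' `sum over hotspot windows of x_i / r_i` (consistent with the window-rate
#' definition); with `attribution = "midpoint"` an event instead counts 1
#' when its interval midpoint lies in a hotspot window.  Parents with zero
#' events get `NA` (undefined), not 0.
#'
#' @param intervals interval data.frame.
#' @param track labelled window track from [classify_hotspots_coldspots()],
#'   or any window table with a `label` column.
#' @param pairs meiosis table as in [parent_grn()].
#' @param attribution `"fractional"` (default) or `"midpoint"`.
#' @return data.frame `parent`, `sex`, `n`, `events`, `hot_mass`, `ghu`.
#' @export
parent_ghu <- function(intervals, track, pairs,
                       attribution = c("fractional", "midpoint")) {
  attribution <- match.arg(attribution)
  hot <- track[track$label == "hotspot", , drop = FALSE]
  hm <- numeric(nrow(intervals))
  if (nrow(hot) > 0 && nrow(intervals) > 0) {
    for (r in seq_len(nrow(intervals))) {
      hw <- hot[hot$chrom == intervals$chrom[r], , drop = FALSE]
      if (nrow(hw) == 0) next
      if (attribution == "fractional") {
        ov <- pmin(intervals$right_pos[r], hw$end) -
              pmax(intervals$left_pos[r], hw$start)
        ov[ov < 0] <- 0
        hm[r] <- sum(ov / 1e6) / intervals$r_mb[r]
      } else {
        mid <- (intervals$left_pos[r] + intervals$right_pos[r]) / 2
        hm[r] <- as.numeric(any(mid > hw$start & mid <= hw$end))
      }
    }
  }
  base <- parent_grn(intervals, pairs)
  hot_mass <- tapply(hm, factor(intervals$parent, levels = base$parent), sum)
  hot_mass[is.na(hot_mass)] <- 0
  base$hot_mass <- as.numeric(hot_mass)
  base$ghu <- ifelse(base$events > 0, base$hot_mass / base$events, NA_real_)
  base
}

#' Sex-stratified window recombination maps
#'
#' Applies the window-rate estimator with `T` equal to the number of
#' parent-offspring pairs in the stratum.
#'
#' @param intervals interval data.frame with a `sex` column.
#' @param pairs meiosis table as in [parent_grn()].
#' @param windows window table from [make_windows()].
#' @param stratum `"all"`, `"sire"` or `"dam"`.
#' @param map optional marker map (see [window_rates()]).
#' @return window track for the stratum.
#' @export
stratified_maps <- function(intervals, pairs, windows,
                            stratum = c("all", "sire", "dam"), map = NULL) {
  stratum <- match.arg(stratum)
  sexcode <- c(sire = "M", dam = "F")
  if (stratum != "all") {
    keep_sex <- sexcode[[stratum]]
    intervals <- intervals[intervals$sex == keep_sex, , drop = FALSE]
    pairs <- pairs[pairs$sex == keep_sex, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no parent-offspring pairs in stratum ", stratum)
  window_rates(intervals, nrow(pairs), windows, map = map)
}

#' Write a window track as TSV/BED-like table
#' @param track window track.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_window_track <- function(track, path) {
  write.table(track, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
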
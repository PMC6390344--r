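#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic half-sib
#' population generator.  Defaults describe a desk-scale layer-chicken-like
#' design: many small half-sib families, founder haplotypes drawn from a
#' finite pool (the single knob for line diversity/inbreeding), crossovers
#' from a hotspot-structured intensity map with a dam/sire rate multiplier,
#' and a heritable per-parent recombination propensity.
#'
#' @param n_chromosomes number of autosomes.
#' @param chromosome_lengths lengths in Mb (recycled to `n_chromosomes`).
#' @param marker_density markers per Mb.
#' @param founder_haplotype_pool_size distinct founder haplotypes per
#'   chromosome; small pools emulate an inbred line.
#' @param base_crossover_rate expected crossovers per meiosis per chromosome
#'   (sire scale).
#' @param hotspot_fraction fraction of 0.5-Mb intensity tiles designated as
#'   hotspots.
#' @param hotspot_intensity_multiplier per-bp intensity multiplier inside
#'   hotspot tiles (1 gives a flat map with designated tiles).
#' @param sex_rate_multiplier dam/sire ratio of expected crossover counts
#'   (default 1.1; observed dam excesses run about 5-20%).
#' @param grn_h2,grn_repeatability narrow-sense heritability and
#'   repeatability of the per-parent genome-wide recombination count
#'   (defaults 0.17 and 0.24).
#' @param qtl_spec optional data.frame `marker` (id or index), `effect`
#'   (additive effect per allele copy on log-propensity).
#' @param genotyping_error_rate symmetric dosage perturbation rate (default 0).
#' @param n_families number of focal parents.
#' @param offspring_per_family genotyped offspring per family (scalar or
#'   vector of length `n_families`).
#' @param dam_focal_fraction fraction of focal parents that are dams.
#' @param shared_mate if TRUE each family has a single mate (full sibs, so
#'   both parents form families); default FALSE (a distinct mate per
#'   offspring, the classical half-sib design).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5,
                       chromosome_lengths = 50,
                       marker_density = 20,
                       founder_haplotype_pool_size = 20,
                       base_crossover_rate = 1.0,
                       hotspot_fraction = 0.10,
                       hotspot_intensity_multiplier = 10,
                       sex_rate_multiplier = 1.1,
                       grn_h2 = 0.17,
                       grn_repeatability = 0.24,
                       qtl_spec = NULL,
                       genotyping_error_rate = 0,
                       n_families = 100,
                       offspring_per_family = 4,
                       dam_focal_fraction = 0.4,
                       shared_mate = FALSE,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_lengths = rep_len(chromosome_lengths, n_chromosomes),
              marker_density = marker_density,
              founder_haplotype_pool_size = as.integer(founder_haplotype_pool_size),
              base_crossover_rate = base_crossover_rate,
              hotspot_fraction = hotspot_fraction,
              hotspot_intensity_multiplier = hotspot_intensity_multiplier,
              sex_rate_multiplier = sex_rate_multiplier,
              grn_h2 = grn_h2, grn_repeatability = grn_repeatability,
              qtl_spec = qtl_spec,
              genotyping_error_rate = genotyping_error_rate,
              n_families = as.integer(n_families),
              offspring_per_family = offspring_per_family,
              dam_focal_fraction = dam_focal_fraction,
              shared_mate = isTRUE(shared_mate),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chromosomes >= 1, all(chromosome_lengths > 0),
              marker_density > 0, founder_haplotype_pool_size >= 2,
              base_crossover_rate >= 0, hotspot_fraction >= 0,
              hotspot_fraction <= 1, hotspot_intensity_multiplier >= 0,
              sex_rate_multiplier > 0, genotyping_error_rate >= 0,
              genotyping_error_rate < 1, n_families >= 1,
              all(offspring_per_family >= 1), dam_focal_fraction >= 0,
              dam_focal_fraction <= 1)
    if (!(grn_h2 >= 0 && grn_h2 <= grn_repeatability && grn_repeatability < 1))
      stop("need 0 <= grn_h2 <= grn_repeatability < 1")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Read/write a simulation config as YAML
#' @param cfg `sim_config` object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$qtl_spec)) x$qtl_spec <- as.list(as.data.frame(x$qtl_spec))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$qtl_spec)) x$qtl_spec <- as.data.frame(x$qtl_spec)
  do.call(sim_config, x)
}

# Piecewise-constant crossover intensity per chromosome: 0.5-Mb tiles, a
# sampled fraction designated hotspots with elevated per-bp intensity,
# normalised so the integral equals base_crossover_rate (expected events per
# sire meiosis on that chromosome).
build_intensity_map <- function(cfg) {
  lens <- cfg$chromosome_lengths * 1e6
  names(lens) <- as.character(seq_len(cfg$n_chromosomes))
  tiles <- make_windows(lens, 5e5)
  tiles$hotspot <- FALSE
  tiles$rate <- 0
  for (ch in names(lens)) {
    i <- which(tiles$chrom == ch)
    k <- round(cfg$hotspot_fraction * length(i))
    hot <- if (k > 0) sample(i, k) else integer(0)
    tiles$hotspot[hot] <- TRUE
    rel <- ifelse(tiles$hotspot[i], cfg$hotspot_intensity_multiplier, 1)
    wid <- tiles$end[i] - tiles$start[i]
    tot <- sum(rel * wid)
    tiles$rate[i] <- if (tot > 0) cfg$base_crossover_rate * rel / tot else 0
  }
  tiles
}

#' Simulate one meiosis on a crossover intensity map
#'
#' Crossover count is Poisson with mean `propensity_scale` times the
#' integral of the intensity; positions are drawn proportional to intensity;
#' the gamete is the alternating mosaic of the two parental haplotypes
#' starting from a fair-coin phase.  No crossover interference is modelled.
#'
#' @param hapA,hapB parental haplotype allele vectors (0/1) at `positions`.
#' @param positions marker positions (bp, increasing).
#' @param intensity data.frame `start`, `end`, `rate` (per-bp rate segments
#'   for one chromosome).
#' @param propensity_scale multiplier on the intensity integral.
#' @return list `gamete` (allele vector), `crossovers` (bp positions, sorted).
#' @export
simulate_meiosis <- function(hapA, hapB, positions, intensity,
                             propensity_scale = 1) {
  stopifnot(length(hapA) == length(positions), length(hapB) == length(positions),
            propensity_scale > 0)
  wid <- intensity$end - intensity$start
  mass <- intensity$rate * wid
  lambda <- propensity_scale * sum(mass)
  n_xo <- rpois(1, lambda)
  phase0 <- rbinom(1, 1, 0.5)
  if (n_xo == 0) {
    gam <- if (phase0 == 0) hapA else hapB
    return(list(gamete = gam, crossovers = numeric(0)))
  }
  seg <- sample.int(length(mass), n_xo, replace = TRUE, prob = mass)
  pos <- sort(intensity$start[seg] + runif(n_xo) * wid[seg])
  # phase at marker p: phase0 + number of crossovers strictly before p
  nleft <- findInterval(positions, pos)
  use_b <- (phase0 + nleft) %% 2 == 1
  gam <- ifelse(use_b, hapB, hapA)
  list(gamete = gam, crossovers = pos)
}

#' Assign heritable per-parent recombination propensities
#'
#' Each individual's propensity scale is `exp(g + pe)` with additive genetic
#' `g` (founders drawn from N(0, sigma_g^2); non-founders mid-parent plus a
#' Mendelian-sampling deviate of variance sigma_g^2/2) and permanent
#' environment `pe ~ N(0, sigma_pe^2)`.  Variances are calibrated on the
#' linearised count scale so that single-meiosis crossover counts have
#' narrow-sense heritability `grn_h2` and repeatability `grn_repeatability`
#' once the Poisson meiosis residual is included: with genome-wide mean
#' `lambda`, total count variance is `lambda/(1 - t)`, so
#' `sigma_g^2 = h2 / ((1 - t) lambda)` and
#' `sigma_pe^2 = (t - h2) / ((1 - t) lambda)`.
#' QTL listed in `cfg$qtl_spec` act additively on `g` (effect per copy of
#' allele 2, centred); their variance is carved out of the polygenic term.
#'
#' @param ped pedigree data.frame (topological order).
#' @param cfg `sim_config`.
#' @param G optional [genotypes] object supplying QTL dosages.
#' @return data.frame `id`, `g`, `pe`, `scale` (= exp(g + pe)).
#' @export
assign_parent_propensity <- function(ped, cfg, G = NULL) {
  if (cfg$grn_h2 > cfg$grn_repeatability)
    stop("grn_h2 exceeds grn_repeatability")
  lambda <- sum(rep_len(cfg$base_crossover_rate, cfg$n_chromosomes))
  t <- cfg$grn_repeatability; h2 <- cfg$grn_h2
  if (lambda > 0) {
    sig_g2 <- h2 / ((1 - t) * lambda)
    sig_pe2 <- (t - h2) / ((1 - t) * lambda)
  } else {
    sig_g2 <- sig_pe2 <- 0   # no crossovers: propensity is inert
  }
  qtl_var <- 0
  qtl_bv <- setNames(rep(0, nrow(ped)), ped$id)
  if (!is.null(cfg$qtl_spec) && nrow(cfg$qtl_spec) > 0) {
    if (is.null(G)) stop("qtl_spec given but no genotypes supplied")
    for (r in seq_len(nrow(cfg$qtl_spec))) {
      mk <- cfg$qtl_spec$marker[r]
      j <- if (is.numeric(mk)) as.integer(mk) else match(mk, colnames(G$geno))
      if (is.na(j) || j < 1 || j > ncol(G$geno)) stop("QTL marker not found: ", mk)
      d <- G$geno[match(ped$id, rownames(G$geno)), j]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      a <- cfg$qtl_spec$effect[r]
      p <- mean(d) / 2
      qtl_bv <- qtl_bv + a * (d - 2 * p)
      qtl_var <- qtl_var + a^2 * 2 * p * (1 - p)
    }
  }
  poly_var <- sig_g2 - qtl_var
  if (poly_var < 0)
    stop("QTL variance exceeds the additive variance implied by grn_h2")
  g <- setNames(rep(NA_real_, nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    s <- ped$sire[i]; d <- ped$dam[i]
    gs <- if (!is.na(s) && !is.na(g[s])) g[s] else NA
    gd <- if (!is.na(d) && !is.na(g[d])) g[d] else NA
    g[i] <- if (is.na(gs) || is.na(gd)) rnorm(1, 0, sqrt(poly_var))
            else (gs + gd) / 2 + rnorm(1, 0, sqrt(poly_var / 2))
  }
  g <- g + qtl_bv
  pe <- rnorm(nrow(ped), 0, sqrt(sig_pe2))
  data.frame(id = ped$id, g = as.numeric(g), pe = pe,
             scale = exp(as.numeric(g) + pe), stringsAsFactors = FALSE)
}

#' Simulate a half-sib population with known crossovers
#'
#' Founders (focal parents and their mates) draw two haplotypes each from a
#' finite per-line pool; every offspring genotype is the union of two
#' simulated gametes (one meiosis per parent), so each offspring yields one
#' recorded meiosis for its sire and one for its dam.  Dams' intensity is
#' scaled by `sex_rate_multiplier`.  Everything is reproducible from
#' `cfg$seed`.
#'
#' @param cfg `sim_config`.
#' @return list with `genotypes` ([genotypes]), `pedigree`, and `truth`: a
#'   list holding `crossovers` (parent, offspring, chrom, pos),
#'   `propensity` (per-individual g, pe, scale), `intensity` (0.5-Mb tiles
#'   with per-bp rate and hotspot designation), `qtl` (the realised QTL
#'   spec) and `haplotypes` (per chromosome, a 2N x m 0/1 matrix, rows
#'   `id.1`/`id.2`; for offspring, `.1` is the paternal strand).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_fam <- cfg$n_families
  n_off <- rep_len(cfg$offspring_per_family, n_fam)
  lens_bp <- cfg$chromosome_lengths * 1e6
  chroms <- as.character(seq_len(cfg$n_chromosomes))

  # marker map: fixed count per chromosome, uniform random distinct positions
  map <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    m <- max(2L, round(cfg$marker_density * cfg$chromosome_lengths[ci]))
    pos <- sort(sample.int(lens_bp[ci] - 1L, m))
    data.frame(marker = sprintf("snp%s_%05d", chroms[ci], seq_len(m)),
               chrom = chroms[ci], pos = pos, stringsAsFactors = FALSE)
  }))

  intensity <- build_intensity_map(cfg)

  # founder haplotype pool: per chromosome, pool_size haplotypes with
  # marker allele frequencies ~ U(0.1, 0.9)
  pool <- lapply(chroms, function(ch) {
    m <- sum(map$chrom == ch)
    p <- runif(m, 0.1, 0.9)
    matrix(rbinom(cfg$founder_haplotype_pool_size * m, 1, rep(p, each = cfg$founder_haplotype_pool_size)),
           nrow = cfg$founder_haplotype_pool_size, ncol = m)
  })
  names(pool) <- chroms

  n_dam_focal <- round(cfg$dam_focal_fraction * n_fam)
  focal_sex <- c(rep("F", n_dam_focal), rep("M", n_fam - n_dam_focal))
  focal_ids <- sprintf("P%03d", seq_len(n_fam))
  mate_counts <- if (cfg$shared_mate) rep(1L, n_fam) else n_off
  mate_ids <- sprintf("Q%04d", seq_len(sum(mate_counts)))
  off_ids <- sprintf("O%04d", seq_len(sum(n_off)))

  ped_rows <- list()
  mate_ix <- 0L; off_ix <- 0L
  for (f in seq_len(n_fam)) {
    mates_f <- mate_ids[mate_ix + seq_len(mate_counts[f])]
    mate_ix <- mate_ix + mate_counts[f]
    for (k in seq_len(n_off[f])) {
      off_ix <- off_ix + 1L
      mate <- if (cfg$shared_mate) mates_f[1] else mates_f[k]
      if (focal_sex[f] == "M")
        ped_rows[[off_ix]] <- data.frame(id = off_ids[off_ix], sire = focal_ids[f],
                                         dam = mate, sex = sample(c("M", "F"), 1))
      else
        ped_rows[[off_ix]] <- data.frame(id = off_ids[off_ix], sire = mate,
                                         dam = focal_ids[f], sex = sample(c("M", "F"), 1))
    }
  }
  off_tab <- do.call(rbind, ped_rows)
  mate_sex <- setNames(rep(NA_character_, length(mate_ids)), mate_ids)
  mate_sex[off_tab$sire[off_tab$sire %in% mate_ids]] <- "M"
  mate_sex[off_tab$dam[off_tab$dam %in% mate_ids]] <- "F"
  ped <- rbind(
    data.frame(id = focal_ids, sire = NA, dam = NA, sex = focal_sex),
    data.frame(id = mate_ids, sire = NA, dam = NA, sex = unname(mate_sex)),
    off_tab)
  ped <- as_pedigree(ped)

  founders <- c(focal_ids, mate_ids)
  all_ids <- ped$id
  n_all <- length(all_ids)

  # haplotypes: per chromosome a 2N x m matrix (rows 2i-1, 2i)
  haps <- lapply(chroms, function(ch) {
    m <- sum(map$chrom == ch)
    h <- matrix(NA_integer_, 2 * n_all, m)
    rownames(h) <- paste0(rep(all_ids, each = 2), c(".1", ".2"))
    h
  })
  names(haps) <- chroms
  row_of <- function(id, strand) 2 * match(id, all_ids) - 2 + strand
  for (ch in chroms) {
    pick <- sample.int(cfg$founder_haplotype_pool_size, 2 * length(founders),
                       replace = TRUE)
    haps[[ch]][c(rbind(row_of(founders, 1), row_of(founders, 2))), ] <-
      pool[[ch]][pick, ]
  }

  prop <- assign_parent_propensity(ped, cfg, G = NULL)
  scale_of <- setNames(prop$scale, prop$id)
  sex_of <- setNames(ped$sex, ped$id)

  off_only <- off_tab$id
  xo_rows <- vector("list", 2 * length(off_only) * length(chroms))
  xo_n <- 0L
  for (o in off_only) {
    s <- ped$sire[match(o, ped$id)]; d <- ped$dam[match(o, ped$id)]
    for (ch in chroms) {
      pos <- map$pos[map$chrom == ch]
      it <- intensity[intensity$chrom == ch, , drop = FALSE]
      for (par in c(s, d)) {
        mult <- if (sex_of[par] == "F") cfg$sex_rate_multiplier else 1
        mg <- simulate_meiosis(haps[[ch]][row_of(par, 1), ],
                               haps[[ch]][row_of(par, 2), ],
                               pos, it, scale_of[par] * mult)
        strand <- if (par == s) 1L else 2L
        haps[[ch]][row_of(o, strand), ] <- mg$gamete
        if (length(mg$crossovers)) {
          xo_n <- xo_n + 1L
          xo_rows[[xo_n]] <- data.frame(parent = par, offspring = o,
                                        chrom = ch, pos = mg$crossovers,
                                        stringsAsFactors = FALSE)
        }
      }
    }
  }
  crossovers <- if (xo_n > 0) do.call(rbind, xo_rows[seq_len(xo_n)])
                else data.frame(parent = character(0), offspring = character(0),
                                chrom = character(0), pos = numeric(0))

  geno <- matrix(0L, n_all, nrow(map),
                 dimnames = list(all_ids, map$marker))
  col0 <- 0L
  for (ch in chroms) {
    m <- sum(map$chrom == ch)
    h <- haps[[ch]]
    geno[, col0 + seq_len(m)] <- h[seq(1, 2 * n_all, 2), ] + h[seq(2, 2 * n_all, 2), ]
    col0 <- col0 + m
  }
  if (cfg$genotyping_error_rate > 0) {
    hit <- which(runif(length(geno)) < cfg$genotyping_error_rate)
    if (length(hit)) {
      shift <- sample(c(-1L, 1L), length(hit), replace = TRUE)
      geno[hit] <- pmin(2L, pmax(0L, geno[hit] + shift))
    }
  }
  G <- genotypes(geno, map)

  list(genotypes = G, pedigree = ped,
       truth = list(crossovers = crossovers, propensity = prop,
                    intensity = intensity, qtl = cfg$qtl_spec,
                    haplotypes = haps, config = cfg))
}

#' Randomly downsample a marker panel
#'
#' Keeps a uniform random subset of markers (sampling without replacement,
#' exact count `round(keep_fraction * m)`), preserving map order and all
#' individuals.
#'
#' @param G [genotypes] object.
#' @param keep_fraction fraction of markers to keep, in (0, 1].
#' @return [genotypes] object.
#' @export
downsample_panel <- function(G, keep_fraction) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  m <- ncol(G$geno)
  if (keep_fraction == 1) return(G)
  keep <- sort(sample.int(m, round(keep_fraction * m)))
  genotypes(G$geno[, keep, drop = FALSE], G$map[keep, , drop = FALSE])
}

#' Write a simulation truth set as TSV files
#'
#' @param truth the `truth` element of [simulate_population()] output.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(truth$crossovers, file.path(dir, "crossovers.tsv"),
              quote = FALSE, row.names = FALSE, sep = "\t")
  write.table(truth$propensity, file.path(dir, "propensity.tsv"),
              quote = FALSE, row.names = FALSE, sep = "\t")
  write.table(truth$intensity, file.path(dir, "intensity.tsv"),
              quote = FALSE, row.names = FALSE, sep = "\t")
  if (!is.null(truth$qtl))
    write.table(truth$qtl, file.path(dir, "qtl.tsv"),
                quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(dir)
}

#' Convert true crossovers into marker-bounded intervals
#'
#' For calibration studies: each true crossover becomes the interval between
#' its flanking markers, mirroring the resolution limit of marker-based
#' detection without any inference.  Crossovers outside the marker span of
#' their chromosome are dropped (undetectable by construction).
#'
#' @param truth the `truth` element of [simulate_population()] output (or
#'   any data.frame `parent`, `offspring`, `chrom`, `pos`).
#' @param map marker map.
#' @param ped pedigree (provides parent sex).
#' @return data.frame in the layout of `detect_recombination()$intervals`.
#' @export
truth_intervals <- function(truth, map, ped) {
  xo <- if (is.data.frame(truth)) truth else truth$crossovers
  sex_of <- setNames(ped$sex, ped$id)
  out <- list()
  for (ch in unique(xo$chrom)) {
    pos <- map$pos[map$chrom == ch]
    mk <- map$marker[map$chrom == ch]
    sub <- xo[xo$chrom == ch, , drop = FALSE]
    li <- findInterval(sub$pos, pos)
    ok <- li >= 1 & li < length(pos)
    sub <- sub[ok, , drop = FALSE]; li <- li[ok]
    if (nrow(sub) == 0) next
    out[[ch]] <- data.frame(
      parent = sub$parent, offspring = sub$offspring,
      sex = unname(sex_of[sub$parent]), chrom = ch,
      left_marker = mk[li], left_pos = pos[li],
      right_marker = mk[li + 1], right_pos = pos[li + 1],
      r_mb = (pos[li + 1] - pos[li]) / 1e6, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(parent = character(0), offspring = character(0),
                      sex = character(0), chrom = character(0),
                      left_marker = character(0), left_pos = numeric(0),
                      right_marker = character(0), right_pos = numeric(0),
                      r_mb = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
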
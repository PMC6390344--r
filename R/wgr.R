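#' Weighted Bayesian whole-genome regression (BayesB / BayesC)
#'
#' Fits `y = Xb + M alpha + e` by single-site Gibbs sampling with
#' per-record residual variance `sigma_e^2 / w_i` (weights from
#' [en_weights()] when `y` holds parent means of repeated records).
#' With `pi = 0` and a common marker-effect variance this is BayesC(pi=0):
#' every SNP effect is drawn from one normal distribution.  With `pi > 0`
#' a fraction `pi` of SNPs has zero effect and the non-zero effects follow
#' independent univariate-t priors induced by per-marker
#' scaled-inverse-chi-square variances (degrees of freedom `nu_a`, scale
#' `S2_a`), i.e. BayesB.
#'
#' Prior scales default to the pedigree-based variance components:
#' `S2_a = sigma2_a (nu_a - 2) / (nu_a (1 - pi) sum_j 2 p_j q_j)` and
#' `S2_e = sigma2_e (nu_e - 2) / nu_e`.
#'
#' @param y numeric phenotype vector (e.g. parent-mean GRN).
#' @param M genotype covariate matrix (individuals x markers, codes 0/1/2),
#'   column names are marker ids.
#' @param X fixed-effect design matrix (default an intercept); sex means in
#'   the full pipeline.
#' @param weights per-record weights (default 1).
#' @param pi prior fraction of zero-effect SNPs.
#' @param vc list with `sigma2_a` and `sigma2_e` (pedigree estimates) used
#'   to scale the priors; alternatively pass `S2_a`/`S2_e` directly.
#' @param nu_a,nu_e prior degrees of freedom (defaults 4.2 and 4).
#' @param S2_a,S2_e prior scales; computed from `vc` when NULL.
#' @param chain,burnin,thin MCMC controls (defaults 55000, 5000, 1).
#' @param common_variance share one marker variance (default `pi == 0`).
#' @param seed RNG seed.
#' @return object of class `wgr_fit`: posterior mean `alpha_hat`, `sppi`
#'   (per-SNP posterior probability of inclusion), retained samples
#'   (`alpha`, `sigma2_e`, `sigma2_alpha`, `var_g`), `h2_marker` posterior
#'   mean/sd of `var_g / (var_g + sigma2_e)`, and the call configuration.
#' @export
fit_wgr <- function(y, M, X = NULL, weights = NULL, pi = 0,
                    vc = NULL, nu_a = 4.2, nu_e = 4,
                    S2_a = NULL, S2_e = NULL,
                    chain = 55000, burnin = 5000, thin = 1,
                    common_variance = (pi == 0), seed = 1) {
  if (is.null(dim(M)) || ncol(M) == 0) stop("M must have at least one marker")
  if (anyNA(y)) stop("phenotype vector contains missing values")
  stopifnot(length(y) == nrow(M), pi >= 0, pi < 1, chain > burnin)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0), length(weights) == n)
  p <- colMeans(M, na.rm = TRUE) / 2
  msv <- sum(2 * p * (1 - p))
  if (is.null(vc)) {
    # fall back on a half-and-half split of the phenotypic variance
    vy <- var(y)
    vc <- list(sigma2_a = vy / 2, sigma2_e = vy / 2)
  }
  if (is.null(S2_a))
    S2_a <- vc$sigma2_a * (nu_a - 2) / (nu_a * (1 - pi) * max(msv, 1e-12))
  if (is.null(S2_e))
    S2_e <- vc$sigma2_e * (nu_e - 2) / nu_e
  Mm <- as.matrix(M)
  storage.mode(Mm) <- "double"
  if (anyNA(Mm)) stop("genotype covariates contain missing values; fill first")
  # centre covariates (standard for single-site samplers; the column means
  # are absorbed by the fixed effects and leave variances untouched)
  Mm <- sweep(Mm, 2, colMeans(Mm))
  set.seed(seed)
  res <- wgr_gibbs_cpp(as.numeric(y), as.matrix(X), Mm, as.numeric(weights),
                       pi, nu_a, S2_a, nu_e, S2_e, common_variance,
                       as.integer(chain), as.integer(burnin), as.integer(thin))
  colnames(res$alpha) <- colnames(M)
  h2s <- res$var_g / (res$var_g + res$sigma2_e)
  out <- list(alpha_hat = colMeans(res$alpha),
              sppi = colMeans(res$alpha != 0),
              samples = res,
              h2_marker = c(mean = mean(h2s), sd = sd(h2s)),
              config = list(pi = pi, nu_a = nu_a, S2_a = S2_a, nu_e = nu_e,
                            S2_e = S2_e, chain = chain, burnin = burnin,
                            thin = thin, common_variance = common_variance,
                            seed = seed))
  class(out) <- "wgr_fit"
  out
}

#' @export
print.wgr_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Bayesian WGR (%s): %d kept samples over %d markers\n",
              if (cfg$pi == 0 && cfg$common_variance) "BayesC(pi=0)"
              else sprintf("BayesB pi=%g", cfg$pi),
              nrow(x$samples$alpha), length(x$alpha_hat)))
  cat(sprintf("  marker-based h2: %.3f (SD %.3f)\n",
              x$h2_marker["mean"], x$h2_marker["sd"]))
  invisible(x)
}

#' Partition genetic variance over 1-Mb windows
#'
#' Markers are binned into non-overlapping physical windows (default 1 Mb)
#' that carry at least one marker.  For every retained MCMC sample the
#' genetic value of each window, `g_w = M_w alpha_w`, is computed and the
#' window's share of genetic variance is `Var(g_w) / sum_w' Var(g_w')` over
#' individuals, so the shares of one sample always add to exactly 1
#' (samples with zero total genetic variance are skipped for shares but
#' counted for WPPA).  GV% is 100 times the posterior mean
#' share.  WPPA is the fraction of samples in which the window contains at
#' least one non-zero-effect SNP; SPPI is the per-SNP inclusion
#' probability, and the window's lead SNP is its max-SPPI marker.
#'
#' @param fit `wgr_fit` object.
#' @param M the genotype covariate matrix used in the fit.
#' @param map marker map aligned with `colnames(M)`.
#' @param window_size window width in bp (default 1e6).
#' @return data.frame `window`, `chrom`, `start`, `end`, `n_markers`,
#'   `gv_pct`, `wppa`, `lead_snp`, `lead_sppi`, plus per-sample share
#'   matrix in attribute `"shares"`.
#' @export
window_variance_partition <- function(fit, M, map, window_size = 1e6) {
  stopifnot(ncol(M) == nrow(map))
  A <- fit$samples$alpha                       # S x m
  S <- nrow(A)
  n <- nrow(M)
  bin <- paste0(map$chrom, "_", floor(map$pos / window_size))
  bins <- unique(bin)
  Mm <- as.matrix(M); storage.mode(Mm) <- "double"
  vw_mat <- matrix(NA_real_, S, length(bins), dimnames = list(NULL, bins))
  wppa <- numeric(length(bins))
  for (bi in seq_along(bins)) {
    j <- which(bin == bins[bi])
    Gw <- Mm[, j, drop = FALSE] %*% t(A[, j, drop = FALSE])
    vw_mat[, bi] <- colVar(Gw)
    wppa[bi] <- mean(rowSums(A[, j, drop = FALSE] != 0) > 0)
  }
  vtot <- rowSums(vw_mat)
  ok <- vtot > 0
  shares <- matrix(NA_real_, S, length(bins), dimnames = list(NULL, bins))
  shares[ok, ] <- vw_mat[ok, , drop = FALSE] / vtot[ok]
  res <- vector("list", length(bins))
  for (bi in seq_along(bins)) {
    j <- which(bin == bins[bi])
    sppi_j <- fit$sppi[j]
    lead <- j[which.max(sppi_j)]
    res[[bi]] <- data.frame(
      window = bins[bi], chrom = map$chrom[j[1]],
      start = floor(map$pos[j[1]] / window_size) * window_size,
      n_markers = length(j),
      gv_pct = 100 * mean(shares[, bi], na.rm = TRUE),
      wppa = wppa[bi],
      lead_snp = map$marker[lead], lead_sppi = fit$sppi[lead],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$end <- out$start + window_size
  out <- out[, c("window", "chrom", "start", "end", "n_markers", "gv_pct",
                 "wppa", "lead_snp", "lead_sppi")]
  out <- out[order(chrom_order(out$chrom), out$start), ]
  rownames(out) <- NULL
  attr(out, "shares") <- shares
  out
}

colVar <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Call QTL regions from window variance results
#'
#' Windows whose GV% meets `gv_threshold` (default 0.8, the
#' 20-times-the-polygenic-expectation rule for a ~2000-window genome) seed
#' regions extended by `flank` bp on both sides; overlapping or adjacent
#' seeded regions are merged.  Under a polygenic architecture the expected
#' GV% per window is `100 / #windows`, so the threshold should be
#' reconsidered for genomes with few windows.
#'
#' @param results data.frame from [window_variance_partition()].
#' @param gv_threshold GV% seeding threshold (default 0.8).
#' @param flank extension in bp (default 1e6).
#' @return data.frame `chrom`, `start`, `end`, `peak_window`, `peak_gv_pct`,
#'   `wppa`, `lead_snp`, `lead_sppi`; empty when nothing passes.
#' @export
call_qtl <- function(results, gv_threshold = 0.8, flank = 1e6) {
  seeds <- results[results$gv_pct >= gv_threshold, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_window = character(0),
                      peak_gv_pct = numeric(0), wppa = numeric(0),
                      lead_snp = character(0), lead_sppi = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(seeds) == 0) return(empty)
  out <- list()
  for (ch in unique(seeds$chrom)) {
    s <- seeds[seeds$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    lo <- pmax(s$start - flank, 0); hi <- s$end + flank
    grp <- cumsum(c(1, as.integer(lo[-1] > cummax(hi[-length(hi)]))))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      peak <- sg[which.max(sg$gv_pct), ]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(lo[grp == g]), end = max(hi[grp == g]),
        peak_window = peak$window, peak_gv_pct = peak$gv_pct,
        wppa = peak$wppa, lead_snp = peak$lead_snp,
        lead_sppi = peak$lead_sppi, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Refit with a lead SNP isolated from its window
#'
#' Re-runs the whole-genome regression with the other markers of the lead
#' SNP's window removed, so the lead SNP's own share of genetic variance
#' can be read off directly.
#'
#' @param y,X,weights,... as in [fit_wgr()] (`...` passes pi, chain, vc, ...).
#' @param M full genotype covariate matrix.
#' @param map marker map aligned with `colnames(M)`.
#' @param lead_snp marker id (must be a column of `M`).
#' @param window_size window width used for the partition (default 1e6).
#' @return list `fit` (the refit), `snp_gv_pct` (posterior mean GV% of the
#'   lead SNP), `sppi` (its inclusion probability in the refit).
#' @export
lead_snp_refit <- function(y, M, map, lead_snp, X = NULL, weights = NULL,
                           window_size = 1e6, ...) {
  j <- match(lead_snp, colnames(M))
  if (is.na(j)) stop("lead SNP absent from M: ", lead_snp)
  bin <- paste0(map$chrom, "_", floor(map$pos / window_size))
  drop <- which(bin == bin[j] & seq_len(ncol(M)) != j)
  keep <- setdiff(seq_len(ncol(M)), drop)
  M2 <- M[, keep, drop = FALSE]
  map2 <- map[keep, , drop = FALSE]
  fit <- fit_wgr(y, M2, X = X, weights = weights, ...)
  part <- window_variance_partition(fit, M2, map2, window_size)
  wj <- which(part$window == bin[j])
  snp_gv <- if (length(wj) == 1) part$gv_pct[wj] else 0
  list(fit = fit, snp_gv_pct = snp_gv,
       sppi = fit$sppi[[lead_snp]])
}

#' Single-SNP test in a pedigree mixed model
#'
#' Generalised least squares with covariance
#' `V = sigma2_a A + diag(sigma2_e / w)`: the SNP enters as a fixed
#' covariate next to the other fixed effects and its effect is tested with
#' a Wald z-test.
#'
#' @param y phenotype vector (one record per subject, e.g. parent means).
#' @param snp dosage vector aligned with `y`.
#' @param A relationship matrix over the subjects.
#' @param X other fixed effects (default intercept).
#' @param sigma2_a,sigma2_e variance components (e.g. posterior means from
#'   [fit_repeatability_model()]).
#' @param weights En record weights (default 1).
#' @return list `estimate`, `se`, `z`, `p_value`, plus the full GLS
#'   coefficient vector `beta`.
#' @export
single_snp_mixed_model <- function(y, snp, A, X = NULL,
                                   sigma2_a, sigma2_e, weights = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(weights)) weights <- rep(1, n)
  V <- sigma2_a * A + diag(sigma2_e / weights, n)
  Xf <- cbind(X, snp = snp)
  Vi <- tryCatch(solve(V), error = function(e) stop("singular V matrix"))
  XtVi <- crossprod(Xf, Vi)
  coefcov <- tryCatch(solve(XtVi %*% Xf),
                      error = function(e) stop("singular GLS system"))
  beta <- as.numeric(coefcov %*% (XtVi %*% y))
  names(beta) <- colnames(Xf)
  k <- length(beta)
  se <- sqrt(diag(coefcov))
  z <- unname(beta[k] / se[k])
  list(estimate = unname(beta[k]), se = unname(se[k]), z = z,
       p_value = 2 * pnorm(-abs(z)), beta = beta)
}

#' @importFrom stats pnorm model.matrix
NULL
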
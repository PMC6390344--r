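#' Pedigree numerator relationship matrix
#'
#' Tabular (recursive) method over the topologically ordered pedigree:
#' `A_ij = 0.5 (A_js + A_jd)` for offspring `i` of `s` and `d`, and
#' `A_ii = 1 + 0.5 A_sd` (so the diagonal is `1 + F_i` with `F_i` the
#' pedigree inbreeding coefficient).  Unknown parents contribute 0.
#'
#' @param ped pedigree data.frame (topological order; see [as_pedigree()]).
#' @param subjects ids to return the matrix for (default: all pedigree
#'   members).  Relationships are always accumulated over the full
#'   pedigree first.
#' @return symmetric numeric matrix with dimnames `subjects`.
#' @export
build_A_matrix <- function(ped, subjects = ped$id) {
  missing_sub <- setdiff(subjects, ped$id)
  if (length(missing_sub) > 0)
    stop("subject(s) not in pedigree: ", paste(missing_sub, collapse = ", "))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      js <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[js, s] else 0
      ad_ <- if (!is.na(d)) A[js, d] else 0
      A[js, i] <- A[i, js] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A[subjects, subjects, drop = FALSE]
}

#' Fit the pedigree repeatability animal model by Gibbs sampling
#'
#' Model: `y = Xb + Zu + Zp + e` with `u ~ N(0, A sigma_a^2)` (additive
#' genetic), `p ~ N(0, I sigma_p^2)` (permanent environment of the parent)
#' and `e ~ N(0, I sigma_e^2)`; `b` holds the sex means (fixed).  Flat
#' prior on `b`; scaled-inverse-chi-square priors (default `nu = 4`, scale
#' a third of the phenotypic variance) on the three variance components.
#' Heritability `h2 = sigma_a^2 / total` and repeatability
#' `t = (sigma_a^2 + sigma_p^2) / total` are computed per posterior sample.
#'
#' @param data data.frame of repeated records with columns `parent`, `sex`
#'   and `y` (one row per meiosis, e.g. per-offspring event counts).
#' @param A numerator relationship matrix covering (at least) all parents
#'   in `data`; extra individuals (ancestors) are carried as unobserved.
#' @param chain,burnin,thin MCMC controls (defaults 4000, 1000, 1).
#' @param prior_nu,prior_scale_frac scaled-inverse-chi-square prior degrees
#'   of freedom and the fraction of `var(y)` used as prior scale for each
#'   component.
#' @param seed RNG seed.
#' @return list of class `repeatability_fit` with posterior `mean` and `sd`
#'   for `sigma2_a`, `sigma2_p`, `sigma2_e`, `h2`, `t`, plus the retained
#'   `samples` matrix.
#' @export
fit_repeatability_model <- function(data, A, chain = 4000, burnin = 1000,
                                    thin = 1, prior_nu = 4,
                                    prior_scale_frac = 1 / 3, seed = 1) {
  stopifnot(all(c("parent", "sex", "y") %in% names(data)), chain > burnin)
  nrec <- table(data$parent)
  if (!any(nrec >= 2))
    stop("repeatability unidentifiable: no parent has >= 2 records")
  set.seed(seed)
  parents <- rownames(A)
  if (!all(unique(data$parent) %in% parents))
    stop("A matrix does not cover all parents in the data")
  y <- data$y
  N <- length(y)
  q <- length(parents)
  Zi <- match(data$parent, parents)
  sexes <- sort(unique(data$sex))     # one mean per sex, no contrasts
  X <- vapply(sexes, function(s) as.numeric(data$sex == s), numeric(N))
  X <- matrix(X, nrow = N, dimnames = list(NULL, sexes))
  nb <- ncol(X)
  Ainv <- solve(A)
  Ainv <- (Ainv + t(Ainv)) / 2
  ZtZ_diag <- tabulate(Zi, nbins = q)
  vy <- var(y)
  S <- vy * prior_scale_frac
  nu <- prior_nu
  # initial values
  s2a <- s2p <- s2e <- vy / 3
  b <- rep(mean(y), nb)
  u <- rep(0, q); p <- rep(0, q)
  nkeep <- floor((chain - burnin) / thin)
  samples <- matrix(NA_real_, nkeep, 5,
                    dimnames = list(NULL, c("sigma2_a", "sigma2_p",
                                            "sigma2_e", "h2", "t")))
  kept <- 0L
  Zu <- function(v) v[Zi]
  for (it in seq_len(chain)) {
    # b | rest
    resid_b <- y - Zu(u) - Zu(p)
    XtX <- crossprod(X)
    bhat <- solve(XtX, crossprod(X, resid_b))
    Lb <- chol(solve(XtX) * s2e)
    b <- as.numeric(bhat + t(Lb) %*% rnorm(nb))
    xb <- as.numeric(X %*% b)
    # u | rest: precision = Z'Z/s2e + Ainv/s2a
    ystar <- y - xb - Zu(p)
    rhs <- tabulate_sum(Zi, ystar, q) / s2e
    P <- Ainv / s2a
    diag(P) <- diag(P) + ZtZ_diag / s2e
    L <- chol(P)
    mu <- backsolve(L, forwardsolve(t(L), rhs))
    u <- as.numeric(mu + backsolve(L, rnorm(q)))
    # p | rest: diagonal precision
    ystar <- y - xb - Zu(u)
    rhs <- tabulate_sum(Zi, ystar, q) / s2e
    prec <- ZtZ_diag / s2e + 1 / s2p
    p <- rnorm(q, rhs / prec, sqrt(1 / prec))
    # variance components
    uAu <- as.numeric(crossprod(u, Ainv %*% u))
    s2a <- (uAu + nu * S) / rchisq(1, q + nu)
    s2p <- (sum(p^2) + nu * S) / rchisq(1, q + nu)
    ee <- y - xb - Zu(u) - Zu(p)
    s2e <- (sum(ee^2) + nu * S) / rchisq(1, N + nu)
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      tot <- s2a + s2p + s2e
      samples[kept, ] <- c(s2a, s2p, s2e, s2a / tot, (s2a + s2p) / tot)
    }
  }
  out <- list(mean = colMeans(samples), sd = apply(samples, 2, sd),
              samples = samples, parents = parents)
  class(out) <- "repeatability_fit"
  out
}

tabulate_sum <- function(index, values, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat("Repeatability animal model (Gibbs)\n")
  for (nm in names(x$mean))
    cat(sprintf("  %-9s %.4f (posterior SD %.4f)\n", nm, x$mean[nm], x$sd[nm]))
  invisible(x)
}

#' Method-of-moments cross-check for the repeatability model
#'
#' Point estimates of `t` from the between/within-parent ANOVA of repeated
#' records and of `h2` from the parent-offspring-free sire-family
#' decomposition are not attempted here; this utility returns the ANOVA
#' repeatability only, as an independent check on the Gibbs fit.
#'
#' @param data records as in [fit_repeatability_model()].
#' @return repeatability estimate (intra-class correlation).
#' @export
repeatability_anova <- function(data) {
  grp <- factor(data$parent)
  fit <- stats::aov(y ~ grp, data = data)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  k <- table(grp)
  n0 <- (sum(k) - sum(k^2) / sum(k)) / (length(k) - 1)
  s2b <- max((ms[1] - ms[2]) / n0, 0)
  s2b / (s2b + ms[2])
}

#' Record weights for parent-mean phenotypes
#'
#' `En = (1 - h2) / ((1 + (n - 1) t) / n - h2)`: the weight that equates
#' the residual variance of a mean of `n` repeated records to
#' `sigma_e^2 / En` given heritability `h2` and repeatability `t`.
#' `En = 1` when `n = 1` and `En = n` when `t = h2`.
#'
#' @param h2 narrow-sense heritability.
#' @param t repeatability (`t >= h2`).
#' @param n integer vector of record counts per parent.
#' @return numeric vector of weights along `n`.
#' @export
en_weights <- function(h2, t, n) {
  stopifnot(h2 >= 0, t >= h2, t < 1)
  denom <- (1 + (n - 1) * t) / n - h2
  if (any(denom <= 0))
    stop("non-positive En denominator for n = ",
         paste(n[denom <= 0], collapse = ", "))
  (1 - h2) / denom
}
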
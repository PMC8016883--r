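# Minimal LD-score-regression machinery: enough to feed the null
# sampler (heritabilities, cross-trait covariance, overlap intercept)
# and the tuning-parameter criterion (stratified covariance). Not a
# general-purpose replacement for full LDSC tooling.

wls_fit <- function(y, Xmat, w) {
  sw <- sqrt(w)
  qr.coef(qr(Xmat * sw), y * sw)
}

jackknife_se <- function(y, Xmat, w, n_blocks, transform) {
  m <- length(y)
  n_blocks <- max(2L, min(n_blocks, m %/% 2L))
  grp <- ceiling(seq_along(y) / (m / n_blocks))
  est <- vapply(seq_len(n_blocks), function(b) {
    keep <- grp != b
    transform(wls_fit(y[keep], Xmat[keep, , drop = FALSE], w[keep]))
  }, numeric(length(transform(wls_fit(y, Xmat, w)))))
  if (is.null(dim(est))) est <- matrix(est, nrow = 1L)
  apply(est, 1L, function(v) {
    sqrt((n_blocks - 1) / n_blocks * sum((v - mean(v))^2))
  })
}

#' Estimate SNP heritability by LD-score regression
#'
#' Regresses squared z-scores on LD scores with an unconstrained
#' intercept: E(z_i^2) = (n h^2 / M) l_i + intercept. The default
#' two-step weighting first fits by ordinary least squares, then
#' reweights each SNP by 1 / (1 + (n h^2 / M) l_i) as a
#' heteroskedasticity proxy. Standard errors come from a delete-one
#' block jackknife over contiguous SNP blocks.
#'
#' @param z Vector of association z-scores.
#' @param l LD scores aligned with `z`.
#' @param n GWAS sample size.
#' @param m_total Total number of SNPs M used in the model.
#' @param weights `"twostep"` (default) or `"simple"` (unweighted).
#' @param n_blocks Jackknife block count (default 200, reduced for
#'   short vectors).
#' @param se Compute jackknife standard errors (default TRUE; skip in
#'   tight simulation loops).
#' @return List of class `ldsc_fit`: `h2`, `intercept`, `h2_se`,
#'   `intercept_se`, `m_total`, `n`.
#' @export
estimate_h2 <- function(z, l, n, m_total = length(z),
                        weights = c("twostep", "simple"),
                        n_blocks = 200L, se = TRUE) {
  weights <- match.arg(weights)
  stopifnot(length(z) == length(l))
  if (length(z) < 50L) stop("need at least 50 SNPs for a stable regression")
  y <- z^2
  if (stats::sd(l) < 1e-12) {
    # constant LD scores make slope and intercept collinear; fall
    # back to the constrained-intercept form E[z^2] - 1 = slope * l
    co_c <- sum(y - 1) / sum(l)
    fit <- structure(list(h2 = co_c * m_total / n, intercept = 1,
                          h2_se = NA_real_, intercept_se = NA_real_,
                          m_total = m_total, n = n),
                     class = "ldsc_fit")
    if (se) {
      per <- (y - 1) / l * m_total / n
      fit$h2_se <- stats::sd(per) / sqrt(length(per))
      fit$intercept_se <- 0
    }
    return(fit)
  }
  Xmat <- cbind(intercept = 1, l = l)
  w <- rep(1, length(z))
  co <- wls_fit(y, Xmat, w)
  if (weights == "twostep") {
    h2_0 <- max(co[2L], 0) * m_total / n
    w <- 1 / (1 + (n * h2_0 / m_total) * l)
    co <- wls_fit(y, Xmat, w)
  }
  tf <- function(coefs) c(coefs[2L] * m_total / n, coefs[1L])
  ses <- if (se) jackknife_se(y, Xmat, w, n_blocks, tf)
  else c(NA_real_, NA_real_)
  structure(list(h2 = unname(co[2L] * m_total / n),
                 intercept = unname(co[1L]),
                 h2_se = ses[1L], intercept_se = ses[2L],
                 m_total = m_total, n = n),
            class = "ldsc_fit")
}

#' Estimate global cross-trait genetic covariance
#'
#' Regresses z1 * z2 on LD scores: E(z1_i z2_i) =
#' (sqrt(n1 n2) rho_g / M) l_i + rho_e n_s / sqrt(n1 n2). The slope
#' gives the global genetic covariance, the intercept the
#' sample-overlap term consumed by the null sampler. Weights default
#' to the product heteroskedasticity proxy built from the single-trait
#' fits when those are supplied.
#'
#' @param z1,z2 Harmonized z-score vectors.
#' @param l LD scores.
#' @param n1,n2 GWAS sample sizes.
#' @param m_total Total SNP count M.
#' @param h2_1,h2_2 Optional heritability estimates used in the
#'   weighting; `NULL` means unweighted regression.
#' @param n_blocks Jackknife block count.
#' @return List of class `cross_ldsc_fit`: `rho_g`, `intercept_cross`
#'   (the rho_e n_s / sqrt(n1 n2) plug-in), their SEs, `m_total`.
#' @export
estimate_cross <- function(z1, z2, l, n1, n2, m_total = length(z1),
                           h2_1 = NULL, h2_2 = NULL, n_blocks = 200L,
                           se = TRUE) {
  stopifnot(length(z1) == length(z2), length(z1) == length(l))
  if (length(z1) < 50L) stop("need at least 50 SNPs for a stable regression")
  y <- z1 * z2
  if (stats::sd(l) < 1e-12) {
    # collinear design: covariance slope and overlap intercept cannot
    # be separated; by convention the whole mean product goes to the
    # intercept (the conservative reading for the null sampler)
    mu <- mean(y)
    return(structure(list(rho_g = 0, intercept_cross = mu,
                          rho_g_se = NA_real_,
                          intercept_se = if (se) stats::sd(y) / sqrt(length(y))
                          else NA_real_,
                          m_total = m_total, n1 = n1, n2 = n2),
                     class = "cross_ldsc_fit"))
  }
  Xmat <- cbind(intercept = 1, l = l)
  w <- rep(1, length(y))
  if (!is.null(h2_1) && !is.null(h2_2)) {
    w <- 1 / ((1 + (n1 * max(h2_1, 0) / m_total) * l) *
                (1 + (n2 * max(h2_2, 0) / m_total) * l))
  }
  co <- wls_fit(y, Xmat, w)
  tf <- function(coefs) c(coefs[2L] * m_total / sqrt(n1 * n2), coefs[1L])
  ses <- if (se) jackknife_se(y, Xmat, w, n_blocks, tf)
  else c(NA_real_, NA_real_)
  structure(list(rho_g = unname(co[2L] * m_total / sqrt(n1 * n2)),
                 intercept_cross = unname(co[1L]),
                 rho_g_se = ses[1L], intercept_se = ses[2L],
                 m_total = m_total, n1 = n1, n2 = n2),
            class = "cross_ldsc_fit")
}

#' Stratified cross-trait covariance for a region annotation
#'
#' Splits the genome into two annotations -- SNPs inside a region mask
#' and the remainder -- computes stratified LD scores from the panel,
#' and jointly regresses z1 * z2 on both score columns. The per-
#' annotation covariance is slope_c * M_c / sqrt(n1 n2); `pi` is the
#' fraction of the global covariance attributed to the region set
#' (defined as 0 for an empty region set).
#'
#' @param z1,z2 Harmonized z-score vectors (aligned to the panel).
#' @param region_mask Logical vector marking the region annotation.
#' @param panel A `geno_panel` over the same SNPs.
#' @param n1,n2 GWAS sample sizes.
#' @param rho_g Optional global covariance for the denominator of
#'   `pi`; defaults to the sum of the two stratified components.
#' @param groups Optional LD-score grouping (see [ld_scores()]).
#' @param window_bp LD-score window.
#' @return List of class `stratified_cov`: `rho_region`, `rho_rest`,
#'   `pi`, `intercept`, `unstable` (TRUE when |rho_g| is near zero).
#' @export
stratified_covariance <- function(z1, z2, region_mask, panel, n1, n2,
                                  rho_g = NULL, groups = NULL,
                                  window_bp = 1e6) {
  m <- length(z1)
  stopifnot(length(region_mask) == m, ncol(panel$X) == m)
  if (!any(region_mask)) {
    return(structure(list(rho_region = 0,
                          rho_rest = if (is.null(rho_g)) NA_real_ else rho_g,
                          pi = 0, intercept = NA_real_, unstable = FALSE),
                     class = "stratified_cov"))
  }
  ls2 <- ld_scores_stratified(panel, region_mask, window_bp, groups)
  y <- z1 * z2
  m_region <- sum(region_mask)
  m_rest <- m - m_region
  if (m_rest == 0L) {
    # whole-genome annotation: single-column regression
    co <- wls_fit(y, cbind(intercept = 1, ls2[, "region"]), rep(1, m))
    co <- c(co, 0)
  } else {
    co <- wls_fit(y, cbind(intercept = 1, ls2), rep(1, m))
  }
  rho_region <- unname(co[2L] * m_region / sqrt(n1 * n2))
  rho_rest <- unname(co[3L] * m_rest / sqrt(n1 * n2))
  if (is.null(rho_g)) rho_g <- rho_region + rho_rest
  floor_g <- 1e-12
  unstable <- abs(rho_g) < max(floor_g, 1e-3 * abs(rho_region))
  pi_val <- if (abs(rho_g) < floor_g) 0 else rho_region / rho_g
  structure(list(rho_region = rho_region, rho_rest = rho_rest,
                 pi = pi_val, intercept = unname(co[1L]),
                 unstable = unstable),
            class = "stratified_cov")
}

#' Liability scale specification for binary traits
#'
#' @param prevalence_pop Population prevalence P (one value per trait).
#' @param prevalence_sample Sample (case) prevalence S.
#' @return List of class `liability_scale` with `P`, `S`, `tau`
#'   (the liability threshold Phi^-1(1 - S)).
#' @export
liability_scale <- function(prevalence_pop, prevalence_sample) {
  P <- prevalence_pop; S <- prevalence_sample
  if (any(P <= 0 | P >= 1) || any(S <= 0 | S >= 1))
    stop("prevalences must lie strictly in (0, 1)")
  structure(list(P = P, S = S, tau = stats::qnorm(1 - S)),
            class = "liability_scale")
}

#' Convert liability-scale heritability or covariance to observed scale
#'
#' Under the liability threshold model, observed-scale heritability is
#' h2 * phi(tau)^2 S (1 - S) / (P^2 (1 - P)^2) and observed-scale
#' genetic covariance between two binary traits is
#' rho_g * sqrt(phi(tau1)^2 phi(tau2)^2 S1(1-S1) S2(1-S2)) /
#' (P1(1-P1) P2(1-P2)), with tau = Phi^-1(1 - S).
#'
#' @param x Heritability (mode `"h2"`) or genetic covariance (mode
#'   `"cov"`) on the liability scale.
#' @param scales A [liability_scale()] object; one prevalence pair for
#'   mode `"h2"`, two (vectors of length 2) for mode `"cov"`.
#' @param mode `"h2"` or `"cov"`.
#' @return The value on the observed scale.
#' @export
observed_scale <- function(x, scales, mode = c("h2", "cov")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scales, "liability_scale"))
  P <- scales$P; S <- scales$S; tau <- scales$tau
  if (mode == "h2") {
    x * stats::dnorm(tau[1])^2 * S[1] * (1 - S[1]) /
      (P[1]^2 * (1 - P[1])^2)
  } else {
    if (length(P) < 2L) stop("mode 'cov' needs prevalences for two traits")
    x * sqrt(stats::dnorm(tau[1])^2 * stats::dnorm(tau[2])^2 *
               S[1] * (1 - S[1]) * S[2] * (1 - S[2])) /
      (P[1] * (1 - P[1]) * P[2] * (1 - P[2]))
  }
}
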
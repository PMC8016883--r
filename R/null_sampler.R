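# Monte-Carlo null machinery: assemble the covariance of the stacked
# z-score pair implied by the polygenic null model, approximate it as
# block-tridiagonal over 1 Mb chunks within LD blocks, and draw pseudo
# z-score pairs by conditional Gaussian sampling.

clip_h2 <- function(h2, h2_floor) {
  if (!is.finite(h2)) stop("non-finite heritability estimate")
  min(max(h2, 0), 1 - h2_floor)
}

#' Assemble the null covariance model for pseudo z-score sampling
#'
#' Under the null, each trait's z-score vector is asymptotically
#' N(0, (n h^2 / M) Vtilde^2 + (1 - h^2) V), where V is the panel LD
#' matrix and Vtilde^2 its bias-corrected square; sample overlap adds
#' a cross-trait term a V with a = rho_e n_s / sqrt(n1 n2). The model
#' splits each LD block into <= `chunk_bp` chunks by genomic position
#' and retains cross-chunk covariance only for adjacent chunks within
#' the same block (tridiagonal approximation). Heritabilities are
#' clipped so that 1 - h^2 >= `h2_floor`, keeping the environmental
#' variance share positive.
#'
#' @param panel A `geno_panel` over the harmonized SNPs, sorted by
#'   (chrom, pos).
#' @param estimates List with `h2_1`, `h2_2`, `n1`, `n2`, `m_total`,
#'   and `rho_e_ns` (the signed product rho_e * n_s; use 0 for no
#'   overlap). Typically assembled from [estimate_h2()] and
#'   [estimate_cross()] output.
#' @param blocks Optional [read_blocks()] table; SNPs outside any
#'   block get one block per chromosome. Default: chromosomes as
#'   blocks.
#' @param chunk_bp Sampling chunk size in bp (default 1e6).
#' @param cond_max Condition cap for chunk-matrix inversion.
#' @param h2_floor Lower clip for 1 - h^2 (default 0.05).
#' @return Object of class `null_model` with per-chunk covariance
#'   ingredients, the variance-split components, and precomputed
#'   sampling factors.
#' @export
build_null_model <- function(panel, estimates, blocks = NULL,
                             chunk_bp = 1e6, cond_max = 1000,
                             h2_floor = 0.05) {
  snps <- panel$snps
  m <- nrow(snps)
  if (is.null(blocks)) {
    block_of <- match(snps$chrom, unique(snps$chrom)) - 1L
  } else {
    block_of <- assign_blocks(snps$chrom, snps$pos, blocks)
    if (anyNA(block_of)) stop(sum(is.na(block_of)),
                              " SNP(s) fall outside every LD block")
  }
  est <- estimates
  est$h2_1 <- clip_h2(est$h2_1, h2_floor)
  est$h2_2 <- clip_h2(est$h2_2, h2_floor)
  if (is.null(est$rho_e_ns)) est$rho_e_ns <- 0

  chunks <- list()
  for (b in unique(block_of)) {
    idx <- which(block_of == b)
    idx <- idx[order(snps$pos[idx])]
    Vb <- ld_matrix(panel, idx)
    # one consistent bias-corrected V^2 per LD block; chunk-diagonal
    # and cross-chunk pieces are sliced from the same matrix so the
    # implied tridiagonal covariance stays (near) positive definite
    Vt_b <- vtilde_sq(Vb, panel$n_ref, length(idx))
    cid <- (snps$pos[idx] - 1L) %/% chunk_bp
    parts <- split(seq_along(idx), cid)
    prev <- NULL
    for (k in seq_along(parts)) {
      loc <- parts[[k]]
      ch <- list(block = b, idx = idx[loc], m = length(loc),
                 V = Vb[loc, loc, drop = FALSE],
                 Vt = Vt_b[loc, loc, drop = FALSE],
                 crossV = NULL, crossVt = NULL, prev = 0L)
      if (!is.null(prev)) {
        ch$crossV <- Vb[loc, prev, drop = FALSE]
        ch$crossVt <- Vt_b[loc, prev, drop = FALSE]
        ch$prev <- length(chunks)
      }
      chunks[[length(chunks) + 1L]] <- ch
      prev <- loc
    }
  }
  model <- structure(list(est = est, m = m, n_ref = panel$n_ref,
                          chunk_bp = chunk_bp, cond_max = cond_max,
                          h2_floor = h2_floor, chunks = chunks),
                     class = "null_model")
  update_null_model(model, est)
}

#' Refresh a null model with new parameter estimates
#'
#' Reuses the (expensive, LD-only) per-chunk covariance ingredients
#' and recomputes the variance split and sampling factors for new
#' heritability / overlap estimates -- the common case when the same
#' panel serves many simulation replicates.
#'
#' @param model A `null_model`.
#' @param estimates As in [build_null_model()].
#' @return The updated `null_model`.
#' @export
update_null_model <- function(model, estimates) {
  est <- estimates
  est$h2_1 <- clip_h2(est$h2_1, model$h2_floor)
  est$h2_2 <- clip_h2(est$h2_2, model$h2_floor)
  if (is.null(est$rho_e_ns)) est$rho_e_ns <- 0
  model$est <- est
  model$components <- split_overlap_covariance(model)
  floored <- new.env()
  floored$worst <- 0
  model$factors <- lapply(model$components, chunk_factors,
                          model = model, floored = floored)
  model$psd_floor_worst <- floored$worst
  if (floored$worst > 0.2)
    warning("conditional covariance materially not PSD ",
            "(worst relative eigenvalue -", signif(floored$worst, 2),
            "); floored at 0")
  model
}

#' Split the null covariance into additive sampling components
#'
#' With overlap term a = rho_e n_s / sqrt(n1 n2), the stacked
#' covariance decomposes into independent per-trait components with
#' marginal (n h^2 / M) Vtilde^2 + (1 - h^2 - |a|) V, plus a shared
#' component realized by a single draw w ~ N(0, |a| V) added to both
#' traits -- with the same sign when a > 0 and opposite signs when
#' a < 0 -- so that the sum reproduces the full covariance exactly.
#'
#' @param model A `null_model`.
#' @return List of component descriptors (`qcoef` multiplies
#'   Vtilde^2, `vcoef` multiplies V, `s1`/`s2` give the signs with
#'   which a component enters each trait's pseudo z-score).
#' @export
split_overlap_covariance <- function(model) {
  est <- model$est
  a <- est$rho_e_ns / sqrt(est$n1 * est$n2)
  for (h2 in c(est$h2_1, est$h2_2)) {
    if (1 - h2 - abs(a) < 0)
      stop("invalid variance split: 1 - h2 - |a| < 0 (a = ",
           signif(a, 4), ")")
  }
  comps <- list(
    list(name = "trait1", qcoef = est$n1 * est$h2_1 / est$m_total,
         vcoef = 1 - est$h2_1 - abs(a), s1 = 1, s2 = 0),
    list(name = "trait2", qcoef = est$n2 * est$h2_2 / est$m_total,
         vcoef = 1 - est$h2_2 - abs(a), s1 = 0, s2 = 1))
  if (a != 0) {
    comps <- c(comps, list(
      list(name = "shared", qcoef = 0, vcoef = abs(a),
           s1 = 1, s2 = sign(a))))
  }
  comps
}

# Precompute, for one covariance component, the per-chunk conditional
# mean map A = Sigma_{i,i-1} Sigma_{i-1,i-1}^{-1} and a square-root
# factor of the conditional covariance (eigenvalues floored at 0).
chunk_factors <- function(comp, model, floored = NULL) {
  sigma_of <- function(ch) comp$qcoef * ch$Vt + comp$vcoef * ch$V
  cross_of <- function(ch) comp$qcoef * ch$crossVt + comp$vcoef * ch$crossV
  lapply(model$chunks, function(ch) {
    S_ii <- sigma_of(ch)
    if (ch$prev == 0L) {
      A <- NULL
      C <- S_ii
    } else {
      chp <- model$chunks[[ch$prev]]
      S_prev <- sigma_of(chp)
      S_cross <- cross_of(ch)
      A <- S_cross %*% tsvd_inverse(S_prev, model$cond_max)$inv
      C <- S_ii - A %*% t(S_cross)
      C <- (C + t(C)) / 2
    }
    ev <- eigen(C, symmetric = TRUE)
    # negative eigenvalues are routine here: the bias-corrected V^2
    # estimate is itself indefinite when chunk size approaches the
    # panel size; flooring at 0 is part of the procedure
    if (!is.null(floored))
      floored$worst <- max(floored$worst,
                           -min(ev$values) / max(abs(ev$values), 1e-12))
    F <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    list(A = A, F = F, idx = ch$idx, prev = ch$prev)
  })
}

draw_component <- function(factors, m, B) {
  Z <- matrix(0, m, B)
  for (k in seq_along(factors)) {
    f <- factors[[k]]
    mi <- length(f$idx)
    eps <- f$F %*% matrix(stats::rnorm(mi * B), mi, B)
    if (is.null(f$A)) {
      Z[f$idx, ] <- eps
    } else {
      Z[f$idx, ] <- f$A %*% Z[factors[[f$prev]]$idx, , drop = FALSE] + eps
    }
  }
  Z
}

#' Draw a batch of pseudo z-score pairs from the null model
#'
#' Each chunk is drawn from its marginal (first chunk of a block) or
#' from the conditional normal given the previous chunk; overlap
#' components are drawn independently and summed. Deterministic given
#' the seed.
#'
#' @param model A `null_model`.
#' @param B Number of draws.
#' @param seed Integer RNG seed (applied with `set.seed`).
#' @return List with matrices `Z1` and `Z2` (SNPs x B).
#' @export
draw_pseudo_matrix <- function(model, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(model$factors, draw_component, m = model$m, B = B)
  Z1 <- matrix(0, model$m, B)
  Z2 <- matrix(0, model$m, B)
  for (k in seq_along(parts)) {
    cmp <- model$components[[k]]
    if (cmp$s1 != 0) Z1 <- Z1 + cmp$s1 * parts[[k]]
    if (cmp$s2 != 0) Z2 <- Z2 + cmp$s2 * parts[[k]]
  }
  list(Z1 = Z1, Z2 = Z2)
}

#' Draw a single pseudo z-score pair
#'
#' @param model A `null_model`.
#' @param rng_seed Integer seed.
#' @return Object of class `pseudo_z_pair` with `z1_star`, `z2_star`,
#'   `seed`.
#' @export
draw_pseudo_pair <- function(model, rng_seed) {
  d <- draw_pseudo_matrix(model, 1L, rng_seed)
  structure(list(z1_star = drop(d$Z1), z2_star = drop(d$Z2),
                 seed = rng_seed),
            class = "pseudo_z_pair")
}

#' Standardize pseudo z-scores to the observed moments
#'
#' Affinely rescales each pseudo vector (each column for matrix input)
#' so that its genome-wide mean and variance equal those of the
#' corresponding observed z-score vector. Affine maps leave all
#' within-vector correlation structure unchanged.
#'
#' @param pseudo A `pseudo_z_pair` or a `list(Z1, Z2)` of matrices
#'   from [draw_pseudo_matrix()].
#' @param z1_obs,z2_obs Observed z-score vectors.
#' @return Same shape as `pseudo`, standardized.
#' @export
standardize_pseudo <- function(pseudo, z1_obs, z2_obs) {
  match_moments <- function(M, target) {
    mu <- mean(target); s <- stats::sd(target)
    if (is.matrix(M)) {
      cm <- colMeans(M)
      cs <- matrixStats::colSds(M)
      if (any(cs == 0)) stop("zero-variance pseudo vector")
      sweep(sweep(M, 2L, cm, "-"), 2L, cs, "/") * s + mu
    } else {
      if (stats::sd(M) == 0) stop("zero-variance pseudo vector")
      (M - mean(M)) / stats::sd(M) * s + mu
    }
  }
  if (inherits(pseudo, "pseudo_z_pair")) {
    pseudo$z1_star <- match_moments(pseudo$z1_star, z1_obs)
    pseudo$z2_star <- match_moments(pseudo$z2_star, z2_obs)
  } else {
    pseudo$Z1 <- match_moments(pseudo$Z1, z1_obs)
    pseudo$Z2 <- match_moments(pseudo$Z2, z2_obs)
  }
  pseudo
}
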
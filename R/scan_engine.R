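# The scan engine: LD-penalized scan statistic, maximal-window search,
# iterative peel-off against a Monte-Carlo null, region merging, FDR
# control, and adaptive selection of the LD-penalty exponent theta.

#' Scan configuration
#'
#' @param theta_grid Candidate LD-penalty exponents (default
#'   0.4, 0.45, ..., 0.7).
#' @param theta Fixed exponent; when non-NULL, adaptive selection is
#'   skipped.
#' @param window_step Window lengths are restricted to multiples of
#'   this SNP count (default 10), which cuts the candidate set ~10x.
#' @param max_window Cap C on window SNP count. `NULL` (default) sets
#'   C from the data: the average SNP count per 1 Mb, rounded up to a
#'   multiple of `window_step`.
#' @param n_mc Number of Monte-Carlo null draws B (default 5000).
#' @param alpha Per-block family-wise level for the null quantile
#'   (default 0.05, i.e. the 95th percentile of max |Q|).
#' @param merge_gap_bp Regions closer than this are merged (1e5).
#' @param fdr_q Benjamini-Hochberg FDR cutoff (0.05).
#' @param maf_min Panel MAF filter used during harmonization (0.01).
#' @param ld_window_bp LD-score window (1e6).
#' @param chunk_bp Null-sampler chunk size (1e6).
#' @param h2_floor Lower clip for 1 - h^2 (0.05).
#' @param cond_max TSVD condition cap (1000).
#' @param seed Integer seed driving all randomness.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(theta_grid = c(0.4, 0.45, 0.5, 0.55, 0.6, 0.65, 0.7),
                        theta = NULL, window_step = 10L, max_window = NULL,
                        n_mc = 5000L, alpha = 0.05, merge_gap_bp = 1e5,
                        fdr_q = 0.05, maf_min = 0.01, ld_window_bp = 1e6,
                        chunk_bp = 1e6, h2_floor = 0.05, cond_max = 1000,
                        seed = 42L) {
  stopifnot(all(theta_grid >= 0 & theta_grid <= 1),
            is.null(max_window) || max_window >= window_step)
  structure(as.list(environment()), class = "scan_config")
}

#' The scan statistic Q(R)
#'
#' Q(R) = sum over i in R of z1_i z2_i, divided by
#' (sum over i in R of l_i)^theta. The sign carries the direction of
#' the local correlation; theta = 0 gives the raw inner product,
#' theta = 1 the fully LD-normalized form.
#'
#' @param z1,z2 z-score vectors.
#' @param l LD scores.
#' @param index_set SNP indices of the region R.
#' @param theta LD-penalty exponent.
#' @return Signed scalar Q(R).
#' @export
scan_statistic <- function(z1, z2, l, index_set, theta) {
  if (length(index_set) == 0L) stop("empty index set")
  li <- l[index_set]
  if (any(li <= 0)) stop("non-positive LD score in region")
  sum(z1[index_set] * z2[index_set]) / sum(li)^theta
}

#' Enumerate candidate windows for a contiguous SNP run
#'
#' All contiguous windows whose length is a multiple of `step`, up to
#' `min(cap, m)`. A run shorter than `step` yields its single
#' full-length window.
#'
#' @param m SNP count of the run.
#' @param step Length granularity (default 10).
#' @param cap Maximum window length C (default `m`).
#' @return `data.frame` with 1-based `start` and `len`.
#' @export
enumerate_windows <- function(m, step = 10L, cap = m) {
  stopifnot(m >= 1L)
  if (m < step) return(data.frame(start = 1L, len = as.integer(m)))
  lens <- seq.int(step, min(cap, m), by = step)
  do.call(rbind, lapply(lens, function(L) {
    data.frame(start = seq_len(m - L + 1L), len = L)
  }))
}

#' Maximal-|Q| window over an explicit window set
#'
#' Exhaustive search over the supplied windows; ties are broken by
#' smallest start, then smallest length.
#'
#' @param z1,z2,l Vectors over one contiguous run.
#' @param theta LD-penalty exponent.
#' @param windows `data.frame` from [enumerate_windows()].
#' @return List with `q` (signed Q of the winning window), `start`,
#'   `len`.
#' @export
max_scan <- function(z1, z2, l, theta, windows) {
  stopifnot(nrow(windows) >= 1L)
  cp <- c(0, cumsum(z1 * z2))
  cl <- c(0, cumsum(l))
  num <- cp[windows$start + windows$len] - cp[windows$start]
  den <- (cl[windows$start + windows$len] - cl[windows$start])^theta
  q <- num / den
  ord <- order(-abs(q), windows$start, windows$len)
  best <- ord[1L]
  list(q = q[best], start = windows$start[best], len = windows$len[best])
}

#' Null distribution of the per-block maximal scan statistic
#'
#' Computes max |Q| for each standardized pseudo z-score draw over the
#' window set of one block, and the empirical upper quantile used as
#' the peel-off significance cutoff.
#'
#' @param draws `list(Z1, Z2)` of standardized pseudo draws
#'   (SNPs x B), e.g. [draw_pseudo_matrix()] + [standardize_pseudo()].
#' @param l LD scores over all SNPs.
#' @param idx SNP indices of the block (default: all).
#' @param theta LD-penalty exponent.
#' @param config A [scan_config()] (supplies `window_step`, the
#'   window cap and `alpha`).
#' @return List of class `null_qmax`: `draws` (B max-|Q| values) and
#'   `q95` (the empirical `1 - alpha` quantile).
#' @export
null_qmax <- function(draws, l, theta, config, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(draws$Z1))
  B <- ncol(draws$Z1)
  if (B < 100L) warning("fewer than 100 null draws; quantile is unstable")
  cap <- window_cap(config, length(idx))
  qm <- cpp_qmax_batch(draws$Z1[idx, , drop = FALSE],
                       draws$Z2[idx, , drop = FALSE],
                       l[idx], theta, as.integer(config$window_step),
                       as.integer(cap))
  qs <- sort(qm)
  q95 <- qs[ceiling((1 - config$alpha) * B)]
  structure(list(draws = qm, q95 = q95), class = "null_qmax")
}

window_cap <- function(config, m) {
  if (!is.null(config$max_window)) return(config$max_window)
  m
}

resolve_max_window <- function(config, snps) {
  if (!is.null(config$max_window)) return(config)
  span_mb <- sum(tapply(snps$pos, snps$chrom,
                        function(p) max(p) - min(p) + 1)) / 1e6
  dens <- nrow(snps) / max(span_mb, 1e-9)
  config$max_window <- max(config$window_step,
                           as.integer(ceiling(dens / config$window_step) *
                                        config$window_step))
  config
}

#' Iterative peel-off scan of one LD block
#'
#' Finds the maximal-|Q| window among the remaining SNPs; when |Q|
#' reaches the null cutoff `q95`, records the region with Monte-Carlo
#' p-value (1 + count of null draws >= |Q|) / (1 + B), removes its SNPs,
#' and repeats over the surviving contiguous runs until no window is
#' significant. Reported regions are pairwise disjoint.
#'
#' @param z1,z2,l Observed vectors over one block (contiguous SNPs).
#' @param null A `null_qmax` for the same block.
#' @param theta LD-penalty exponent.
#' @param config A [scan_config()].
#' @param include_subthreshold Also return the final, non-significant
#'   maximal window (`screened = FALSE`). The pipeline pools these
#'   into the FDR step so that the Benjamini-Hochberg denominator
#'   accounts for every LD block examined, not only those that
#'   screened positive (default FALSE).
#' @return `data.table` with `start_idx`, `end_idx` (1-based,
#'   inclusive, block-local), `n_snps`, `q_stat`, `p`, `screened`.
#' @export
peel_off_scan <- function(z1, z2, l, null, theta, config,
                          include_subthreshold = FALSE) {
  m <- length(z1)
  cap <- window_cap(config, m)
  step <- as.integer(config$window_step)
  B <- length(null$draws)
  active <- rep(TRUE, m)
  out <- list()
  repeat {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) == 0L) break
    best <- NULL
    for (k in runs) {
      s0 <- starts[k]; e0 <- ends[k]
      w <- cpp_best_window(z1[s0:e0], z2[s0:e0], l[s0:e0], theta,
                           step, as.integer(cap))
      if (w[2] == 0) next
      cand <- list(q = w[1], start = s0 + w[2] - 1L, len = w[3])
      if (is.null(best) || abs(cand$q) > abs(best$q)) best <- cand
    }
    if (is.null(best)) break
    sig <- abs(best$q) >= null$q95
    if (!sig && !include_subthreshold) break
    p <- (1 + sum(null$draws >= abs(best$q))) / (1 + B)
    out[[length(out) + 1L]] <- data.table::data.table(
      start_idx = as.integer(best$start),
      end_idx = as.integer(best$start + best$len - 1L),
      n_snps = as.integer(best$len), q_stat = best$q, p = p,
      screened = sig)
    if (!sig) break
    active[best$start:(best$start + best$len - 1L)] <- FALSE
  }
  if (length(out) == 0L) {
    return(data.table::data.table(start_idx = integer(), end_idx = integer(),
                                  n_snps = integer(), q_stat = numeric(),
                                  p = numeric(), screened = logical()))
  }
  data.table::rbindlist(out)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `q_values` (BH-adjusted values) and
#'   `reject_mask`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  n <- length(p_values)
  if (n == 0L) return(list(q_values = numeric(), reject_mask = logical()))
  ord <- order(p_values)
  ranked <- p_values[ord] * n / seq_len(n)
  qv <- rev(cummin(rev(ranked)))
  q_values <- numeric(n)
  q_values[ord] <- pmin(qv, 1)
  # step-up: reject all p up to the largest k with p_(k) <= k q / n
  k <- which(p_values[ord] <= seq_len(n) * q / n)
  reject <- rep(FALSE, n)
  if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
  list(q_values = q_values, reject_mask = reject)
}

#' Merge nearby regions
#'
#' Regions on the same chromosome separated by at most `gap_bp` are
#' merged; the merged region spans the union, inherits the smallest
#' p-value and q-value of its members, the q_stat of the member with
#' the largest |q_stat|, and the summed SNP count. Idempotent.
#'
#' @param regions `data.frame` with `chrom`, `start_bp`, `end_bp` and
#'   optionally `p`, `q_fdr`, `q_stat`, `n_snps`, `block_id`.
#' @param gap_bp Maximum gap (default 1e5).
#' @return Merged `data.table`, sorted by (chrom, start_bp).
#' @export
merge_regions <- function(regions, gap_bp = 1e5) {
  r <- data.table::as.data.table(regions)
  if (nrow(r) == 0L) return(r)
  for (col in c("p", "q_fdr", "q_stat")) {
    if (!col %in% names(r)) r[, (col) := NA_real_]
  }
  if (!"n_snps" %in% names(r)) r[, n_snps := NA_integer_]
  if (!"block_id" %in% names(r)) r[, block_id := NA_integer_]
  data.table::setorder(r, chrom, start_bp)
  grp <- integer(nrow(r))
  g <- 0L
  last_chrom <- ""
  last_end <- -Inf
  for (i in seq_len(nrow(r))) {
    if (r$chrom[i] != last_chrom || r$start_bp[i] - last_end > gap_bp) {
      g <- g + 1L
      last_chrom <- r$chrom[i]
      last_end <- r$end_bp[i]
    } else {
      last_end <- max(last_end, r$end_bp[i])
    }
    grp[i] <- g
  }
  r[, .grp := grp]
  out <- r[, .(chrom = chrom[1L], start_bp = min(start_bp),
               end_bp = max(end_bp), block_id = block_id[1L],
               n_snps = sum(n_snps), q_stat = q_stat[which.max(abs(q_stat))],
               p = min(p), q_fdr = min(q_fdr)), by = .grp][, .grp := NULL]
  data.table::setorder(out, chrom, start_bp)
  out[]
}

# One full fixed-theta pass: per-block peel-off, pooled BH, merge.
scan_at_theta <- function(hp, l, block_idx, null_by_block, theta, config) {
  cands <- list()
  for (b in names(block_idx)) {
    idx <- block_idx[[b]]
    # sub-threshold maxima enter the BH pool so the FDR step counts
    # every examined block, not only the ones that screened positive
    pk <- peel_off_scan(hp$z1[idx], hp$z2[idx], l[idx],
                        null_by_block[[b]], theta, config,
                        include_subthreshold = TRUE)
    if (nrow(pk) > 0L) {
      pk[, `:=`(block_id = as.integer(b),
                start_g = idx[start_idx], end_g = idx[end_idx])]
      cands[[length(cands) + 1L]] <- pk
    }
  }
  if (length(cands) == 0L) {
    return(list(regions = empty_regions(), mask = rep(FALSE, nrow(hp))))
  }
  cand <- data.table::rbindlist(cands)
  fdr <- bh_fdr(cand$p, config$fdr_q)
  cand[, q_fdr := fdr$q_values]
  cand <- cand[fdr$reject_mask & cand$screened]
  if (nrow(cand) == 0L) {
    return(list(regions = empty_regions(), mask = rep(FALSE, nrow(hp))))
  }
  regions <- cand[, .(chrom = hp$chrom[start_g],
                      start_bp = hp$pos[start_g], end_bp = hp$pos[end_g],
                      block_id, n_snps, q_stat, p, q_fdr)]
  merged <- merge_regions(regions, config$merge_gap_bp)
  mask <- rep(FALSE, nrow(hp))
  for (i in seq_len(nrow(merged))) {
    mask <- mask | (hp$chrom == merged$chrom[i] &
                      hp$pos >= merged$start_bp[i] &
                      hp$pos <= merged$end_bp[i])
  }
  list(regions = merged, mask = mask)
}

empty_regions <- function() {
  data.table::data.table(chrom = character(), start_bp = integer(),
                         end_bp = integer(), block_id = integer(),
                         n_snps = integer(), q_stat = numeric(),
                         p = numeric(), q_fdr = numeric())
}

#' Adaptive selection of the LD-penalty exponent theta
#'
#' Runs the full per-block scan for every theta in the grid (sharing
#' one set of pseudo-sample draws across the grid), estimates the
#' fraction pi(theta) of the global genetic covariance attributed to
#' the detected regions by stratified regression, and returns
#' theta-hat = argmax |pi(theta)|. pi(theta) = 0 when no region is
#' found; ties and the all-empty case fall back to smaller theta and
#' the grid midpoint respectively.
#'
#' @param hp A `harmonized_pair`.
#' @param panel A `geno_panel` over the same SNPs.
#' @param l LD scores.
#' @param block_idx Named list of SNP-index vectors per block.
#' @param draws Standardized pseudo draws (`list(Z1, Z2)`).
#' @param estimates Estimate list (see [build_null_model()]).
#' @param config A [scan_config()].
#' @return List of class `theta_result`: `theta_hat`, `pi` (named by
#'   theta), `results` (per-theta region sets and masks).
#' @export
select_theta <- function(hp, panel, l, block_idx, draws, estimates,
                         config) {
  grid <- sort(config$theta_grid)
  null_cache <- list()
  results <- list()
  pis <- numeric(length(grid))
  groups <- block_groups(hp, block_idx)
  for (i in seq_along(grid)) {
    th <- grid[i]
    nb <- lapply(block_idx, function(idx)
      null_qmax(draws, l, th, config, idx))
    names(nb) <- names(block_idx)
    res <- scan_at_theta(hp, l, block_idx, nb, th, config)
    if (any(res$mask)) {
      sc <- stratified_covariance(hp$z1, hp$z2, res$mask, panel,
                                  attr(hp, "n1"), attr(hp, "n2"),
                                  groups = groups,
                                  window_bp = config$ld_window_bp)
      pis[i] <- sc$pi
    } else {
      pis[i] <- 0
    }
    results[[i]] <- res
  }
  names(results) <- names(pis) <- as.character(grid)
  if (all(pis == 0)) {
    theta_hat <- grid[ceiling(length(grid) / 2)]
  } else {
    theta_hat <- grid[which.max(abs(pis))]  # which.max -> smallest theta on ties
  }
  structure(list(theta_hat = theta_hat, pi = pis, results = results),
            class = "theta_result")
}

block_groups <- function(hp, block_idx) {
  g <- integer(nrow(hp))
  for (b in names(block_idx)) g[block_idx[[b]]] <- as.integer(b)
  g
}

#' Run the full local genetic correlation scan
#'
#' End-to-end pipeline: harmonize the two summary-statistics sets
#' against the panel, compute per-block LD scores, estimate
#' heritabilities and the cross-trait covariance/overlap intercept by
#' LD-score regression, build the Monte-Carlo null model, draw and
#' standardize pseudo z-score pairs, select theta adaptively (unless
#' fixed in the config), peel-off scan each LD block, pool candidates
#' under Benjamini-Hochberg FDR control, and merge nearby survivors.
#'
#' @param s1,s2 [read_sumstats()] objects.
#' @param panel A `geno_panel`, or a raw `list(dosages, snps)` which
#'   is standardized with the config's MAF filter.
#' @param blocks [read_blocks()] table, or `NULL` for one block per
#'   chromosome.
#' @param config A [scan_config()].
#' @param overlap `"auto"` (estimate rho_e n_s from the cross
#'   regression intercept), `"none"`, or a numeric rho_e n_s value.
#' @return List of class `scan_result`: `regions` (region records),
#'   `theta`, `pi`, `estimates`, `n_snps`, `config`.
#' @export
run_scan <- function(s1, s2, panel, blocks = NULL,
                     config = scan_config(), overlap = "auto") {
  if (!inherits(panel, "geno_panel"))
    panel <- standardize_genotypes(panel$dosages, panel$snps,
                                   maf_min = config$maf_min)
  hp <- harmonize_pair(s1, s2, panel$snps, maf_min = config$maf_min)
  n1 <- attr(hp, "n1"); n2 <- attr(hp, "n2")
  panel <- subset_panel(panel, hp$snp_id)
  config <- resolve_max_window(config, hp)
  if (is.null(blocks)) {
    block_of <- match(hp$chrom, unique(hp$chrom)) - 1L
  } else {
    block_of <- assign_blocks(hp$chrom, hp$pos, blocks)
    keep <- !is.na(block_of)
    if (!all(keep)) {
      hp <- hp[keep]
      panel <- subset_panel(panel, which(keep))
      block_of <- block_of[keep]
      data.table::setattr(hp, "n1", n1)
      data.table::setattr(hp, "n2", n2)
    }
  }
  block_idx <- split(seq_len(nrow(hp)), block_of)
  groups <- block_groups(hp, block_idx)
  l <- ld_scores(panel, window_bp = config$ld_window_bp, groups = groups)

  m <- nrow(hp)
  fit1 <- estimate_h2(hp$z1, l, n1, m)
  fit2 <- estimate_h2(hp$z2, l, n2, m)
  cross <- estimate_cross(hp$z1, hp$z2, l, n1, n2, m,
                          h2_1 = fit1$h2, h2_2 = fit2$h2)
  rho_e_ns <- if (identical(overlap, "none")) 0
  else if (is.numeric(overlap)) overlap
  else cross$intercept_cross * sqrt(n1 * n2)
  # the auto-estimated overlap intercept is noisy at small scale; keep
  # |a| inside the feasible variance split rather than aborting
  h2c <- pmin(pmax(c(fit1$h2, fit2$h2), 0), 1 - config$h2_floor)
  a_bound <- (1 - max(h2c)) * sqrt(n1 * n2)
  if (abs(rho_e_ns) > a_bound) {
    warning("estimated overlap term out of the feasible range; ",
            "clamping |rho_e * n_s| to ", signif(a_bound, 4))
    rho_e_ns <- sign(rho_e_ns) * a_bound
  }
  estimates <- list(h2_1 = fit1$h2, h2_2 = fit2$h2, n1 = n1, n2 = n2,
                    m_total = m, rho_e_ns = rho_e_ns,
                    rho_g = cross$rho_g)
  model <- build_null_model(panel, estimates, blocks = NULL,
                            chunk_bp = config$chunk_bp,
                            cond_max = config$cond_max,
                            h2_floor = config$h2_floor)
  draws <- draw_pseudo_matrix(model, config$n_mc,
                              seed = child_seed(config$seed, 1L))
  draws <- standardize_pseudo(draws, hp$z1, hp$z2)

  if (!is.null(config$theta)) {
    nb <- lapply(block_idx, function(idx)
      null_qmax(draws, l, config$theta, config, idx))
    names(nb) <- names(block_idx)
    res <- scan_at_theta(hp, l, block_idx, nb, config$theta, config)
    theta_hat <- config$theta
    pi_vec <- NULL
  } else {
    ts <- select_theta(hp, panel, l, block_idx, draws, estimates, config)
    theta_hat <- ts$theta_hat
    pi_vec <- ts$pi
    res <- ts$results[[as.character(theta_hat)]]
  }
  structure(list(regions = res$regions, theta = theta_hat, pi = pi_vec,
                 estimates = estimates, n_snps = m, config = config),
            class = "scan_result")
}

# Deterministic child seeds below 2^31 from one global seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Local genetic correlation scan\n")
  cat("  SNPs analyzed:  ", x$n_snps, "\n")
  cat("  theta:          ", x$theta, "\n")
  cat("  h2 estimates:   ", signif(x$estimates$h2_1, 3), ",",
      signif(x$estimates$h2_2, 3), "\n")
  cat("  global rho_g:   ", signif(x$estimates$rho_g, 3), "\n")
  cat("  regions (FDR):  ", nrow(x$regions), "\n")
  if (nrow(x$regions) > 0L) print(x$regions)
  invisible(x)
}
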
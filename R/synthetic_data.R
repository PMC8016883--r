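# Synthetic-data generators: a mosaic copying-with-recombination
# haplotype simulator standing in for coalescent/HAPGEN-style
# genotypes, bivariate effect-size models (infinitesimal, heritability
# enrichment, correlated signal regions, sparse, heavy-tailed,
# MAF-weighted), GWAS z-score simulation with sample overlap and
# binary traits, and a registry of desk-scale, seeded fixtures.

default_ld_profile <- function() {
  list(n_founders = 16L,       # founder haplotype pool size
       founder_ld_bp = 1e5,    # AR(1) scale of founder-internal LD
       mosaic_scale_bp = 1e5,  # switch prob = 1 - exp(-d / scale)
       switch_prob = NULL,     # fixed per-interval prob (overrides)
       spacing_bp = 5000,      # mean inter-SNP distance
       maf_min = 0.05)         # simulation-scale MAF filter
}

# Founder haplotypes: thresholded AR(1) Gaussians so the pool itself
# carries distance-decaying LD that the mosaic process then mixes.
make_founders <- function(m, pos, profile) {
  p <- stats::runif(m, 0.05, 0.5)
  rho <- exp(-diff(pos) / profile$founder_ld_bp)
  H <- matrix(0L, profile$n_founders, m)
  for (f in seq_len(profile$n_founders)) {
    u <- numeric(m)
    u[1] <- stats::rnorm(1)
    innov <- stats::rnorm(m - 1)
    for (j in 2:m) u[j] <- rho[j - 1] * u[j - 1] +
        sqrt(1 - rho[j - 1]^2) * innov[j - 1]
    H[f, ] <- as.integer(u < stats::qnorm(p))
  }
  H
}

switch_probs <- function(pos, profile) {
  if (!is.null(profile$switch_prob)) {
    rep(profile$switch_prob, length(pos) - 1L)
  } else {
    1 - exp(-diff(pos) / profile$mosaic_scale_bp)
  }
}

mosaic_haplotype <- function(founders, s) {
  m <- ncol(founders)
  nf <- nrow(founders)
  seg <- 1L + c(0L, cumsum(stats::rbinom(m - 1L, 1L, s)))
  ids <- sample.int(nf, seg[m], replace = TRUE)
  founders[cbind(ids[seg], seq_len(m))]
}

#' Simulate a source population for genotype draws
#'
#' Builds a founder haplotype pool with distance-decaying internal LD
#' and the mosaic switch probabilities; genotype draws are mosaics of
#' founder segments (copying with recombination), which yields
#' positive short-range LD decaying with physical distance.
#'
#' @param m_snps Number of SNPs before MAF filtering.
#' @param ld_profile Named list overriding `default_ld_profile()`
#'   entries.
#' @param chrom Chromosome label for the SNP metadata.
#' @param seed Optional seed.
#' @return Object of class `sim_population`: founder pool, positions,
#'   switch probabilities, SNP metadata.
#' @export
sim_population <- function(m_snps, ld_profile = list(), chrom = "1",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profile <- utils::modifyList(default_ld_profile(), ld_profile)
  gaps <- pmax(1, stats::rpois(m_snps - 1L, profile$spacing_bp))
  pos <- as.integer(cumsum(c(10000, gaps)))
  founders <- make_founders(m_snps, pos, profile)
  alleles <- t(replicate(m_snps, sample(ACGT, 2L)))
  snps <- data.table::data.table(
    snp_id = paste0("rs", seq_len(m_snps)),
    chrom = chrom, pos = pos,
    a1 = alleles[, 1L], a2 = alleles[, 2L])
  structure(list(founders = founders, pos = pos,
                 s = switch_probs(pos, profile),
                 profile = profile, snps = snps),
            class = "sim_population")
}

#' Draw diploid dosages from a simulated population
#' @param pop A `sim_population`.
#' @param n Number of individuals.
#' @return n x m integer dosage matrix (copies of the a1 allele).
#' @export
draw_genotypes <- function(pop, n) {
  m <- ncol(pop$founders)
  G <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    G[i, ] <- mosaic_haplotype(pop$founders, pop$s) +
      mosaic_haplotype(pop$founders, pop$s)
  }
  colnames(G) <- pop$snps$snp_id
  G
}

#' Simulate a reference genotype panel
#'
#' @param m_snps SNP count before filtering.
#' @param n_ref Panel sample size.
#' @param ld_profile See [sim_population()].
#' @param seed Seed.
#' @return List with `pop` (the population, for drawing GWAS cohorts
#'   with matching LD), `dosages`, `snps`, and `panel` (the
#'   standardized `geno_panel`, MAF-filtered at the profile's
#'   threshold).
#' @export
simulate_panel <- function(m_snps, n_ref, ld_profile = list(),
                           seed = NULL) {
  pop <- sim_population(m_snps, ld_profile, seed = seed)
  dos <- draw_genotypes(pop, n_ref)
  panel <- standardize_genotypes(dos, pop$snps,
                                 maf_min = pop$profile$maf_min)
  list(pop = pop, dosages = dos, snps = pop$snps, panel = panel)
}

#' Simulation scenario descriptor
#'
#' Defaults describe the desk-scale stated world: 2,000 SNPs spaced
#' ~5 kb (10 Mb of genome), a 500-individual reference panel, 2,000
#' individuals per cohort, trait heritability 0.05 (the upper end of
#' the per-chromosome range explored in calibration studies), signal
#' model with N = 5 regions, L = 40 SNPs each, p = 0.3 of trait
#' heritability inside the signal regions, effect correlation
#' rho = 0.9, and a heritability-enrichment split attributing 30 percent of
#' h^2 to about 1.5 percent of SNPs.
#'
#' @param model One of `"infinitesimal"`, `"heritability_enrichment"`,
#'   `"signal_region"`, `"sparse"`, `"heavy_tailed"`,
#'   `"maf_ld_weighted"`.
#' @param h2_1,h2_2 Trait heritabilities.
#' @param rho Effect correlation inside signal regions (or genome-wide
#'   for the infinitesimal model when non-zero).
#' @param n_regions,region_size N signal regions of L SNPs.
#' @param prop_h2 Fraction p of h^2 attributed to signal regions.
#' @param enrichment_snps SNP count carrying 30 percent of h^2 under the
#'   enrichment model (default 1.5 percent of `m_snps`).
#' @param prop_sparse Fraction of SNPs with nonzero effects under the
#'   sparse model.
#' @param df_t Degrees of freedom for the heavy-tailed model.
#' @param n1,n2,n_shared Cohort sizes and overlap count.
#' @param rho_e Environmental correlation among shared individuals.
#' @param binary,prev_pop,prev_sample Binary-trait flags and
#'   population/sample prevalences (length 2).
#' @param m_snps,n_ref Genome and panel sizes.
#' @param seed Scenario seed.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(model = "signal_region",
                         h2_1 = 0.05, h2_2 = 0.05, rho = 0.9,
                         n_regions = 5L, region_size = 40L,
                         prop_h2 = 0.3,
                         enrichment_snps = NULL, prop_sparse = 0.05,
                         df_t = 4, n1 = 2000L, n2 = 2000L,
                         n_shared = 0L, rho_e = 0,
                         binary = FALSE, prev_pop = c(0.1, 0.1),
                         prev_sample = c(0.5, 0.5),
                         m_snps = 2000L, n_ref = 500L, seed = 1L) {
  models <- c("infinitesimal", "heritability_enrichment",
              "signal_region", "sparse", "heavy_tailed",
              "maf_ld_weighted")
  model <- match.arg(model, models)
  if (is.null(enrichment_snps)) enrichment_snps <- round(0.015 * m_snps)
  stopifnot(h2_1 >= 0, h2_1 < 1, h2_2 >= 0, h2_2 < 1, abs(rho) <= 1,
            n_regions * region_size <= m_snps, n_shared <= min(n1, n2))
  structure(as.list(environment())[models_fields()], class = "sim_scenario")
}

models_fields <- function() {
  c("model", "h2_1", "h2_2", "rho", "n_regions", "region_size",
    "prop_h2", "enrichment_snps", "prop_sparse", "df_t", "n1", "n2",
    "n_shared", "rho_e", "binary", "prev_pop", "prev_sample",
    "m_snps", "n_ref", "seed")
}

# Correlated bivariate normals with given per-SNP sds and correlation.
bivar_effects <- function(k, sd1, sd2, rho) {
  a <- stats::rnorm(k)
  b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(k)
  cbind(sd1 * a, sd2 * b)
}

#' Draw per-SNP effect sizes under a scenario's genetic architecture
#'
#' Every model conserves the variance budget: the expected sums
#' of squared effects equal h2_1 and h2_2.
#'
#' @param scenario A [sim_scenario()].
#' @param maf Optional per-SNP MAF vector (required by the
#'   MAF-weighted model).
#' @return List of class `effect_draw`: `beta`, `gamma`,
#'   `truth_regions` (data.frame of SNP-index intervals, 1-based
#'   inclusive), `k_corr`.
#' @export
simulate_effects <- function(scenario, maf = NULL) {
  sc <- scenario
  M <- sc$m_snps
  beta <- numeric(M); gamma <- numeric(M)
  truth <- data.frame(start = integer(), end = integer())
  k_corr <- 0L
  sd_inf1 <- sqrt(sc$h2_1 / M); sd_inf2 <- sqrt(sc$h2_2 / M)
  if (sc$model == "infinitesimal") {
    eff <- bivar_effects(M, sd_inf1, sd_inf2, sc$rho)
    beta <- eff[, 1L]; gamma <- eff[, 2L]
    if (sc$rho != 0) {
      truth <- data.frame(start = 1L, end = M)
      k_corr <- M
    }
  } else if (sc$model == "heritability_enrichment") {
    hi <- sample.int(M, sc$enrichment_snps)
    lo <- setdiff(seq_len(M), hi)
    beta[hi] <- stats::rnorm(length(hi), 0, sqrt(0.3 * sc$h2_1 / length(hi)))
    beta[lo] <- stats::rnorm(length(lo), 0, sqrt(0.7 * sc$h2_1 / length(lo)))
    hi2 <- sample.int(M, sc$enrichment_snps)
    lo2 <- setdiff(seq_len(M), hi2)
    gamma[hi2] <- stats::rnorm(length(hi2), 0, sqrt(0.3 * sc$h2_2 / length(hi2)))
    gamma[lo2] <- stats::rnorm(length(lo2), 0, sqrt(0.7 * sc$h2_2 / length(lo2)))
  } else if (sc$model == "signal_region") {
    NL <- sc$n_regions * sc$region_size
    truth <- place_regions(M, sc$n_regions, sc$region_size)
    in_reg <- interval_mask(truth, M)
    k_corr <- NL
    sd_in1 <- sqrt(sc$prop_h2 * sc$h2_1 / NL)
    sd_in2 <- sqrt(sc$prop_h2 * sc$h2_2 / NL)
    eff <- bivar_effects(NL, sd_in1, sd_in2, sc$rho)
    beta[in_reg] <- eff[, 1L]; gamma[in_reg] <- eff[, 2L]
    sd_out1 <- sqrt((1 - sc$prop_h2) * sc$h2_1 / (M - NL))
    sd_out2 <- sqrt((1 - sc$prop_h2) * sc$h2_2 / (M - NL))
    beta[!in_reg] <- stats::rnorm(M - NL, 0, sd_out1)
    gamma[!in_reg] <- stats::rnorm(M - NL, 0, sd_out2)
  } else if (sc$model == "sparse") {
    k <- max(1L, round(sc$prop_sparse * M))
    on1 <- sample.int(M, k); on2 <- sample.int(M, k)
    beta[on1] <- stats::rnorm(k, 0, sqrt(sc$h2_1 / k))
    gamma[on2] <- stats::rnorm(k, 0, sqrt(sc$h2_2 / k))
  } else if (sc$model == "heavy_tailed") {
    scale_t <- sqrt((sc$df_t - 2) / sc$df_t)  # unit-variance t
    beta <- stats::rt(M, sc$df_t) * scale_t * sd_inf1
    gamma <- stats::rt(M, sc$df_t) * scale_t * sd_inf2
  } else if (sc$model == "maf_ld_weighted") {
    if (is.null(maf)) stop("maf vector required for the MAF-weighted model")
    w <- (maf * (1 - maf))^0.75
    w <- w / sum(w)
    beta <- stats::rnorm(M, 0, sqrt(sc$h2_1 * w))
    gamma <- stats::rnorm(M, 0, sqrt(sc$h2_2 * w))
  }
  structure(list(beta = beta, gamma = gamma, truth_regions = truth,
                 k_corr = k_corr),
            class = "effect_draw")
}

place_regions <- function(M, N, L) {
  # non-overlapping placement by sampling starts in the gap-adjusted space
  stopifnot(N * L <= M)
  free <- M - N * L
  cuts <- sort(sample.int(free + 1L, N, replace = TRUE)) - 1L
  starts <- cuts + (seq_len(N) - 1L) * L + 1L
  data.frame(start = starts, end = starts + L - 1L)
}

interval_mask <- function(iv, M) {
  mask <- rep(FALSE, M)
  for (i in seq_len(nrow(iv))) mask[iv$start[i]:iv$end[i]] <- TRUE
  mask
}

std_cols <- function(G) {
  X <- matrix(as.numeric(G), nrow(G), ncol(G))
  X <- sweep(X, 2L, colMeans(X), "-")
  sds <- matrixStats::colSds(X)
  sds[sds == 0] <- 1
  sweep(X, 2L, sds, "/")
}

#' Simulate GWAS summary statistics for two cohorts
#'
#' Continuous phenotypes follow y = X beta + e with environmental
#' variance 1 - h^2; when the cohorts share individuals (the first
#' `n_shared` rows of each genotype matrix must be the same people),
#' their environmental terms are correlated with covariance `rho_e`.
#' z-scores are score statistics on standardized genotypes and
#' phenotypes, z_i = x_i' y / sqrt(n). Binary traits threshold the
#' liability at the population prevalence and sample cases/controls
#' to the requested sample prevalence before computing z on the
#' observed 0/1 trait.
#'
#' @param G1,G2 Cohort dosage matrices (individuals x SNPs, same SNP
#'   set as the scenario).
#' @param effects An [simulate_effects()] draw.
#' @param scenario The [sim_scenario()].
#' @param snps SNP metadata (`snp_id`, `chrom`, `pos`, `a1`, `a2`).
#' @return List with two `sumstats` tables `s1`, `s2`.
#' @export
simulate_gwas <- function(G1, G2, effects, scenario, snps) {
  sc <- scenario
  n1 <- nrow(G1); n2 <- nrow(G2)
  X1 <- std_cols(G1); X2 <- std_cols(G2)
  g1 <- drop(X1 %*% effects$beta)
  g2 <- drop(X2 %*% effects$gamma)
  e1 <- stats::rnorm(n1, 0, sqrt(1 - sc$h2_1))
  e2 <- stats::rnorm(n2, 0, sqrt(1 - sc$h2_2))
  if (sc$n_shared > 0L && sc$rho_e != 0) {
    v1 <- 1 - sc$h2_1; v2 <- 1 - sc$h2_2
    if (abs(sc$rho_e) > sqrt(v1 * v2))
      stop("rho_e exceeds the environmental variance bound")
    sh <- seq_len(sc$n_shared)
    a <- stats::rnorm(sc$n_shared)
    b <- stats::rnorm(sc$n_shared)
    r <- sc$rho_e / sqrt(v1 * v2)
    e1[sh] <- sqrt(v1) * a
    e2[sh] <- sqrt(v2) * (r * a + sqrt(1 - r^2) * b)
  }
  y1 <- g1 + e1
  y2 <- g2 + e2
  mk <- function(X, y, snps, binary, P, S) {
    if (binary) {
      case <- y > stats::qnorm(1 - P)
      n_case <- sum(case); n_ctrl <- sum(!case)
      n_tot <- min(floor(n_case / S), floor(n_ctrl / (1 - S)))
      if (n_tot < 50L)
        stop("too few cases for the requested sample prevalence; ",
             "increase the cohort size")
      sel <- c(sample(which(case), round(S * n_tot)),
               sample(which(!case), n_tot - round(S * n_tot)))
      X <- X[sel, , drop = FALSE]
      X <- std_cols(X)
      y <- as.numeric(case[sel])
    }
    y <- (y - mean(y)) / stats::sd(y)
    z <- drop(crossprod(X, y)) / sqrt(nrow(X))
    out <- data.table::data.table(
      snp_id = snps$snp_id, a1 = snps$a1, a2 = snps$a2,
      z = z, n = nrow(X), chrom = snps$chrom, pos = snps$pos)
    data.table::setattr(out, "class", c("sumstats", class(out)))
    out
  }
  list(s1 = mk(X1, y1, snps, sc$binary, sc$prev_pop[1], sc$prev_sample[1]),
       s2 = mk(X2, y2, snps, sc$binary, sc$prev_pop[2], sc$prev_sample[2]))
}

#' Write a sumstats table in the tab-separated dialect
#' @param s A `sumstats` table.
#' @param path Output path.
#' @export
write_sumstats <- function(s, path) {
  out <- data.table::data.table(SNP = s$snp_id, A1 = s$a1, A2 = s$a2,
                                Z = s$z, N = s$n)
  if ("chrom" %in% names(s)) out[, `:=`(CHR = s$chrom, BP = s$pos)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

fixture_registry <- function() {
  list(
    null_infinitesimal = function() sim_scenario("infinitesimal", rho = 0),
    null_enriched = function() sim_scenario("heritability_enrichment"),
    power_grid = function() sim_scenario("signal_region"),
    overlap_null = function() sim_scenario("infinitesimal", rho = 0,
                                           n_shared = 1000L, rho_e = 0.3),
    binary_null = function() sim_scenario("infinitesimal", rho = 0,
                                          binary = TRUE, m_snps = 1000L,
                                          n1 = 8000L, n2 = 8000L),
    signal_mixed = function() sim_scenario("signal_region", rho = 0.9)
  )
}

#' Generate a complete, seeded input bundle for one named scenario
#'
#' Writes all files the pipeline consumes: a plain-text dosage panel
#' (`panel.dosages.tsv` + `panel.snps.tsv`), two summary-statistics
#' tables (`trait1.sumstats`, `trait2.sumstats`), LD blocks
#' (`blocks.bed`), ground-truth signal regions (`truth.bed`), and the
#' scenario record (`scenario.yaml`). Byte-identical for the same
#' name and seed.
#'
#' @param name Registry name: one of `null_infinitesimal`,
#'   `null_enriched`, `power_grid`, `overlap_null`, `binary_null`,
#'   `signal_mixed`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed driving the whole bundle.
#' @param scenario Optional [sim_scenario()] overriding the registry
#'   entry.
#' @param block_bp LD-block size for the generated `blocks.bed`.
#' @return Invisible list with file paths, the scenario and the truth
#'   table.
#' @export
make_fixture <- function(name, out_dir, seed = 1L, scenario = NULL,
                         block_bp = 2.5e6) {
  reg <- fixture_registry()
  if (is.null(scenario)) {
    if (!name %in% names(reg))
      stop("unknown fixture '", name, "'; available: ",
           paste(names(reg), collapse = ", "))
    scenario <- reg[[name]]()
  }
  scenario$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  sim <- simulate_panel(scenario$m_snps, scenario$n_ref)
  # for binary traits n1/n2 act as the liability pool from which
  # cases and controls are sampled to the target sample prevalence
  n_pool1 <- scenario$n1
  n_pool2 <- scenario$n2
  Gs <- if (scenario$n_shared > 0L) draw_genotypes(sim$pop, scenario$n_shared) else NULL
  G1 <- rbind(Gs, draw_genotypes(sim$pop, n_pool1 - scenario$n_shared))
  G2 <- rbind(Gs, draw_genotypes(sim$pop, n_pool2 - scenario$n_shared))
  eff <- simulate_effects(scenario, maf = colMeans(sim$dosages) / 2)
  ss <- simulate_gwas(G1, G2, eff, scenario, sim$snps)

  paths <- list(
    geno = file.path(out_dir, "panel.dosages.tsv"),
    meta = file.path(out_dir, "panel.snps.tsv"),
    s1 = file.path(out_dir, "trait1.sumstats"),
    s2 = file.path(out_dir, "trait2.sumstats"),
    blocks = file.path(out_dir, "blocks.bed"),
    truth = file.path(out_dir, "truth.bed"),
    scenario = file.path(out_dir, "scenario.yaml"))
  dt <- data.table::as.data.table(sim$dosages)
  data.table::fwrite(dt, paths$geno, sep = "\t")
  data.table::fwrite(sim$snps, paths$meta, sep = "\t")
  write_sumstats(ss$s1, paths$s1)
  write_sumstats(ss$s2, paths$s2)
  pos <- sim$snps$pos
  bl_start <- seq(0, max(pos), by = block_bp)
  blocks <- data.table::data.table(chrom = sim$snps$chrom[1],
                                   start = bl_start,
                                   end = bl_start + block_bp)
  data.table::fwrite(blocks, paths$blocks, sep = "\t", col.names = FALSE)
  truth <- eff$truth_regions
  truth_bed <- data.table::data.table(
    chrom = rep(sim$snps$chrom[1], nrow(truth)),
    start = pos[truth$start] - 1L, end = pos[truth$end])
  data.table::fwrite(truth_bed, paths$truth, sep = "\t", col.names = FALSE)
  writeLines(yaml::as.yaml(c(list(name = name), scenario)),
             paths$scenario)
  invisible(list(paths = paths, scenario = scenario, truth = truth,
                 truth_bed = truth_bed))
}
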
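test_that("mosaic simulator produces tunable, decaying LD", {
  set.seed(51)
  # free recombination: adjacent r^2 near zero
  pop_free <- sim_population(120, list(switch_prob = 1))
  G <- draw_genotypes(pop_free, 400)
  p <- standardize_genotypes(G, pop_free$snps, maf_min = 0.05)
  V <- ld_matrix(p)
  adj <- vapply(seq_len(ncol(V) - 1), function(i) V[i, i + 1]^2,
                numeric(1))
  # residual relatedness through the founder pool keeps this small
  # but not exactly 0; bound well below linked levels
  expect_lt(mean(adj), 0.12)
  # no recombination: whole haplotypes co-inherited, strong LD
  pop_0 <- sim_population(120, list(switch_prob = 0))
  G0 <- draw_genotypes(pop_0, 400)
  p0 <- standardize_genotypes(G0, pop_0$snps, maf_min = 0.05)
  V0 <- ld_matrix(p0)
  adj0 <- vapply(seq_len(ncol(V0) - 1), function(i) V0[i, i + 1]^2,
                 numeric(1))
  expect_gt(mean(adj0), mean(adj) + 0.2)
  # monotone decay in switch probability
  means <- vapply(c(0.01, 0.1, 0.5), function(s) {
    set.seed(52)
    pop <- sim_population(120, list(switch_prob = s))
    G <- draw_genotypes(pop, 300)
    p <- standardize_genotypes(G, pop$snps, maf_min = 0.05)
    V <- ld_matrix(p)
    mean(vapply(seq_len(ncol(V) - 1), function(i) V[i, i + 1]^2,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # MAF filter respected
  expect_true(all(small_sim()$panel$maf >= 0.05))
})

test_that("simulate_effects conserves the variance budget in every model", {
  scns <- list(
    sim_scenario("infinitesimal", rho = 0, m_snps = 3000L),
    sim_scenario("heritability_enrichment", m_snps = 3000L),
    sim_scenario("signal_region", m_snps = 3000L),
    sim_scenario("sparse", m_snps = 3000L),
    sim_scenario("heavy_tailed", m_snps = 3000L),
    sim_scenario("maf_ld_weighted", m_snps = 3000L))
  set.seed(53)
  maf <- runif(3000, 0.05, 0.5)
  for (sc in scns) {
    tot <- replicate(30, sum(simulate_effects(sc, maf = maf)$beta^2))
    se <- sd(tot) / sqrt(30)
    expect_lt(abs(mean(tot) - sc$h2_1), 3 * se + 0.003)
  }
})

test_that("signal_region effects have the prescribed correlation and layout", {
  sc <- sim_scenario("signal_region", m_snps = 5000L, n_regions = 5L,
                     region_size = 100L, rho = 0.9)
  set.seed(54)
  draws <- replicate(40, {
    e <- simulate_effects(sc)
    mask <- logoscan:::interval_mask(e$truth_regions, sc$m_snps)
    cor(e$beta[mask], e$gamma[mask])
  })
  se <- sd(draws) / sqrt(40)
  expect_lt(abs(mean(draws) - 0.9), 4 * se + 0.01)
  # rho = 0: no correlation inside regions
  sc0 <- sim_scenario("signal_region", rho = 0, m_snps = 5000L,
                      n_regions = 5L, region_size = 100L)
  e0 <- simulate_effects(sc0)
  mask0 <- logoscan:::interval_mask(e0$truth_regions, sc0$m_snps)
  expect_lt(abs(cor(e0$beta[mask0], e0$gamma[mask0])),
            4 / sqrt(sum(mask0)))
  # layout invariants
  e <- simulate_effects(sc)
  tr <- e$truth_regions
  expect_equal(nrow(tr), 5L)
  expect_true(all(tr$end - tr$start + 1L == 100L))
  expect_equal(e$k_corr, 500L)
  expect_true(all(tr$start[-1] > tr$end[-5]))  # disjoint, sorted
  # per-SNP covariance inside regions matches p h2 rho / (N L)
  covs <- replicate(60, {
    e <- simulate_effects(sc)
    m <- logoscan:::interval_mask(e$truth_regions, sc$m_snps)
    mean(e$beta[m] * e$gamma[m])
  })
  target <- 0.3 * 0.05 * 0.9 / 500
  expect_lt(abs(mean(covs) - target), 4 * sd(covs) / sqrt(60))
})

test_that("simulate_gwas produces z-scores with the model's moments", {
  set.seed(55)
  m <- 400; n <- 3000
  snps <- data.frame(snp_id = paste0("s", 1:m), chrom = "1",
                     pos = seq_len(m) * 1000L, a1 = "A", a2 = "G")
  # independent SNPs for closed-form moments
  G1 <- matrix(rbinom(n * m, 2L, 0.3), n, m)
  G2 <- matrix(rbinom(n * m, 2L, 0.3), n, m)
  # null: beta = gamma = 0
  sc <- sim_scenario("infinitesimal", h2_1 = 0, h2_2 = 0, rho = 0,
                     m_snps = m, n1 = n, n2 = n)
  eff0 <- list(beta = rep(0, m), gamma = rep(0, m))
  ss0 <- simulate_gwas(G1, G2, eff0, sc, snps)
  expect_equal(mean(ss0$s1$z), 0, tolerance = 4 / sqrt(m))
  expect_equal(var(ss0$s1$z), 1, tolerance = 0.2)
  expect_lt(abs(cor(ss0$s1$z, ss0$s2$z)), 4 / sqrt(m))
  # h2 = 0.2: mean z^2 ~ 1 + n h2 / M (independent SNPs)
  sc2 <- sim_scenario("infinitesimal", h2_1 = 0.2, h2_2 = 0.2, rho = 0,
                      m_snps = m, n1 = n, n2 = n)
  z2s <- replicate(10, {
    eff <- simulate_effects(sc2)
    mean(simulate_gwas(G1, G2, eff, sc2, snps)$s1$z^2)
  })
  expect_equal(mean(z2s), 1 + n * 0.2 / m, tolerance = 0.15)
  # full overlap with pure environmental correlation:
  # mean z1 z2 ~ rho_e (h2 = 0, n_s = n1 = n2)
  sc3 <- sim_scenario("infinitesimal", h2_1 = 0, h2_2 = 0, rho = 0,
                      m_snps = m, n1 = n, n2 = n, n_shared = n,
                      rho_e = 0.5)
  cross <- replicate(10, {
    ss <- simulate_gwas(G1, G1, eff0, sc3, snps)
    mean(ss$s1$z * ss$s2$z)
  })
  expect_equal(mean(cross), 0.5, tolerance = 0.1)
})

test_that("binary-mode z-scores are standard normal under the null", {
  set.seed(56)
  m <- 300; n <- 4000
  snps <- data.frame(snp_id = paste0("s", 1:m), chrom = "1",
                     pos = seq_len(m) * 1000L, a1 = "A", a2 = "G")
  G <- matrix(rbinom(n * m, 2L, 0.4), n, m)
  sc <- sim_scenario("infinitesimal", h2_1 = 0, h2_2 = 0, rho = 0,
                     m_snps = m, n1 = n, n2 = n, binary = TRUE,
                     prev_pop = c(0.2, 0.2), prev_sample = c(0.5, 0.5))
  ss <- simulate_gwas(G, G, list(beta = rep(0, m), gamma = rep(0, m)),
                      sc, snps)
  expect_gt(ks.test(ss$s1$z, "pnorm")$p.value, 0.01)
  expect_true(all(ss$s1$n < n))  # case/control subset
  # infeasible prevalence errors out
  sc_bad <- sim_scenario("infinitesimal", h2_1 = 0, h2_2 = 0, rho = 0,
                         m_snps = m, n1 = 200L, n2 = 200L, binary = TRUE,
                         prev_pop = c(0.01, 0.01),
                         prev_sample = c(0.9, 0.9))
  expect_error(simulate_gwas(G[1:200, ], G[1:200, ],
                             list(beta = rep(0, m), gamma = rep(0, m)),
                             sc_bad, snps), "cases")
})

test_that("make_fixture writes a consistent, reproducible bundle", {
  sc <- sim_scenario("signal_region", m_snps = 300L, n_ref = 120L,
                     n1 = 200L, n2 = 200L, n_regions = 2L,
                     region_size = 20L)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  fx1 <- make_fixture("signal_mixed", d1, seed = 7, scenario = sc,
                      block_bp = 5e5)
  fx2 <- make_fixture("signal_mixed", d2, seed = 7, scenario = sc,
                      block_bp = 5e5)
  for (f in names(fx1$paths)) {
    expect_identical(readLines(fx1$paths[[f]]), readLines(fx2$paths[[f]]))
  }
  # files are cross-consistent and readable by the IO layer
  s1 <- read_sumstats(fx1$paths$s1)
  pl <- read_panel_tsv(fx1$paths$geno, fx1$paths$meta)
  expect_equal(s1$snp_id, pl$snps$snp_id)
  b <- read_blocks(fx1$paths$blocks)
  expect_gt(nrow(b), 1L)
  # truth BED covers exactly N * L SNPs
  tr <- data.table::fread(fx1$paths$truth, header = FALSE)
  expect_equal(nrow(tr), 2L)
  in_truth <- sum(vapply(seq_len(nrow(tr)), function(i)
    sum(pl$snps$pos - 1 >= tr$V2[i] & pl$snps$pos - 1 < tr$V3[i]),
    numeric(1)))
  expect_equal(in_truth, 2 * 20)
  expect_error(make_fixture("nope", tempdir()), "unknown fixture")
})
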
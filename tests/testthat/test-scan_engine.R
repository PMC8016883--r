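test_that("scan_statistic evaluates the penalized inner product", {
  # z1 = z2 = (1, 2), l = (1, 1), theta = 0.5 -> 5 / sqrt(2)
  expect_equal(scan_statistic(c(1, 2), c(1, 2), c(1, 1), 1:2, 0.5),
               5 / sqrt(2))
  expect_equal(scan_statistic(c(1, 2), c(1, 2), c(1, 1), 1:2, 0), 5)
  expect_equal(scan_statistic(c(1, 2), c(0, 0), c(1, 1), 1:2, 0.7), 0)
  expect_error(scan_statistic(1, 1, 0, 1, 0.5), "LD score")
  expect_error(scan_statistic(1, 1, 1, integer(0), 0.5), "empty")
})

test_that("enumerate_windows counts and degenerate rules", {
  # 25 SNPs, cap 30: lengths 10 and 20 -> 16 + 6 = 22 windows
  w <- enumerate_windows(25, step = 10, cap = 30)
  expect_equal(nrow(w), 22L)
  expect_equal(sort(unique(w$len)), c(10L, 20L))
  # combinatorial oracle: sum over lengths of (m - L + 1)
  for (m in c(10, 37, 55)) {
    w2 <- enumerate_windows(m, 10, 40)
    lens <- seq(10, min(40, m), by = 10)
    expect_equal(nrow(w2), sum(m - lens + 1))
  }
  # short block: the single full-block window
  w3 <- enumerate_windows(7)
  expect_equal(w3, data.frame(start = 1L, len = 7L))
  # cap binding
  w4 <- enumerate_windows(50, 10, 10)
  expect_true(all(w4$len == 10L))
})

test_that("max_scan and the C++ kernel agree with exhaustive search", {
  set.seed(41)
  for (r in 1:50) {
    m <- sample(15:80, 1)
    z1 <- rnorm(m); z2 <- rnorm(m); l <- runif(m, 1, 5)
    theta <- runif(1, 0.3, 0.8)
    cap <- sample(c(20, 30, m), 1)
    w <- enumerate_windows(m, 10, cap)
    # brute-force oracle: score every window by direct summation
    qs <- vapply(seq_len(nrow(w)), function(i) {
      idx <- w$start[i]:(w$start[i] + w$len[i] - 1)
      sum(z1[idx] * z2[idx]) / sum(l[idx])^theta
    }, numeric(1))
    best <- which.max(abs(qs))
    ms <- max_scan(z1, z2, l, theta, w)
    expect_equal(abs(ms$q), abs(qs[best]), tolerance = 1e-10)
    expect_equal(ms$start, w$start[best])
    cw <- logoscan:::cpp_best_window(z1, z2, l, theta, 10L, as.integer(cap))
    expect_equal(abs(cw[1]), abs(qs[best]), tolerance = 1e-10)
    expect_equal(cw[2], w$start[best])
    expect_equal(cw[3], w$len[best])
  }
})

test_that("max_scan finds a planted signal", {
  set.seed(42)
  z1 <- rnorm(100); z2 <- rnorm(100)
  z1[11:20] <- z1[11:20] + 5
  z2[11:20] <- z2[11:20] + 5
  ms <- max_scan(z1, z2, rep(1, 100), 0.5, enumerate_windows(100, 10, 30))
  expect_equal(ms$start, 11L)
  expect_equal(ms$len, 10L)
})

test_that("bh_fdr equals the reference step-up on hand and random cases", {
  # hand case: thresholds k q / n = 0.0125, 0.025, 0.0375, 0.05
  p <- c(0.001, 0.01, 0.04, 0.5)
  out <- bh_fdr(p, 0.05)
  expect_equal(out$reject_mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$q_values, p.adjust(p, "BH"))
  expect_equal(bh_fdr(rep(1, 5), 0.05)$reject_mask, rep(FALSE, 5))
  # random oracle comparison
  set.seed(43)
  for (r in 1:100) {
    pv <- runif(sample(1:40, 1))^sample(1:3, 1)
    out <- bh_fdr(pv, 0.05)
    expect_equal(out$q_values, p.adjust(pv, "BH"))
    expect_equal(out$reject_mask, p.adjust(pv, "BH") <= 0.05)
  }
})

test_that("merge_regions merges by gap and is idempotent", {
  r <- data.frame(chrom = "1", start_bp = c(1000, 50000),
                  end_bp = c(5000, 60000), p = c(0.01, 0.002),
                  q_fdr = c(0.02, 0.004), q_stat = c(3, -8),
                  n_snps = c(5L, 9L), block_id = 0L)
  out <- merge_regions(r, gap_bp = 1e5)  # gap 45 kb -> merge
  expect_equal(nrow(out), 1L)
  expect_equal(out$start_bp, 1000)
  expect_equal(out$end_bp, 60000)
  expect_equal(out$p, 0.002)
  expect_equal(out$q_stat, -8)  # member with larger |q|
  expect_equal(out$n_snps, 14L)
  # gap 150 kb -> unchanged
  r2 <- r; r2$start_bp[2] <- 155000; r2$end_bp[2] <- 165000
  out2 <- merge_regions(r2, gap_bp = 1e5)
  expect_equal(nrow(out2), 2L)
  # idempotence
  expect_equal(merge_regions(out2, 1e5), out2)
  # different chromosomes never merge
  r3 <- r; r3$chrom <- c("1", "2")
  expect_equal(nrow(merge_regions(r3, 1e5)), 2L)
})

test_that("null_qmax quantile, homogeneity and determinism", {
  set.seed(44)
  m <- 60; B <- 400
  draws <- list(Z1 = matrix(rnorm(m * B), m), Z2 = matrix(rnorm(m * B), m))
  l <- runif(m, 1, 3)
  cfg <- scan_config(theta = 0.5, max_window = 30, n_mc = B)
  nq <- null_qmax(draws, l, 0.5, cfg)
  expect_length(nq$draws, B)
  # q95 is the empirical 95th percentile of the stored draws
  expect_equal(nq$q95, sort(nq$draws)[ceiling(0.95 * B)])
  expect_gte(mean(nq$draws <= nq$q95), 0.95)
  # homogeneity: scaling both vectors by c scales Q by c^2
  draws2 <- list(Z1 = 2 * draws$Z1, Z2 = 3 * draws$Z2)
  nq2 <- null_qmax(draws2, l, 0.5, cfg)
  expect_equal(nq2$draws, 6 * nq$draws)
  expect_warning(null_qmax(list(Z1 = draws$Z1[, 1:50],
                                Z2 = draws$Z2[, 1:50]), l, 0.5, cfg),
                 "100")
})

test_that("peel_off_scan recovers separated signals and stays disjoint", {
  set.seed(45)
  m <- 200; B <- 600
  l <- rep(1.5, m)
  draws <- list(Z1 = matrix(rnorm(m * B), m), Z2 = matrix(rnorm(m * B), m))
  cfg <- scan_config(theta = 0.5, max_window = 40, n_mc = B)
  nq <- null_qmax(draws, l, 0.5, cfg)
  z1 <- rnorm(m); z2 <- rnorm(m)
  for (idx in list(21:40, 141:160)) {
    z1[idx] <- z1[idx] + 4
    z2[idx] <- z2[idx] + 4
  }
  pk <- peel_off_scan(z1, z2, l, nq, 0.5, cfg)
  expect_gte(nrow(pk), 2L)
  # both planted regions overlapped
  hits <- vapply(list(21:40, 141:160), function(t)
    any(pk$start_idx <= max(t) & pk$end_idx >= min(t)), logical(1))
  expect_true(all(hits))
  # pairwise disjoint
  covered <- unlist(lapply(seq_len(nrow(pk)), function(i)
    pk$start_idx[i]:pk$end_idx[i]))
  expect_false(any(duplicated(covered)))
  # p-values follow the add-one Monte-Carlo rule
  for (i in seq_len(nrow(pk))) {
    expect_equal(pk$p[i],
                 (1 + sum(nq$draws >= abs(pk$q_stat[i]))) / (1 + B))
  }
  # antisymmetry: negating z2 (and the null is |.|-based) negates
  # q_stat, keeps boundaries and p-values
  pk_neg <- peel_off_scan(z1, -z2, l, nq, 0.5, cfg)
  expect_equal(pk_neg$q_stat, -pk$q_stat)
  expect_equal(pk_neg$start_idx, pk$start_idx)
  expect_equal(pk_neg$p, pk$p)
})

test_that("pure-null blocks are declared empty about 95% of the time", {
  set.seed(46)
  m <- 80; B <- 500
  l <- rep(1, m)
  cfg <- scan_config(theta = 0.5, max_window = 30, n_mc = B)
  draws <- list(Z1 = matrix(rnorm(m * B), m), Z2 = matrix(rnorm(m * B), m))
  nq <- null_qmax(draws, l, 0.5, cfg)
  n_rej <- sum(replicate(200, {
    nrow(peel_off_scan(rnorm(m), rnorm(m), l, nq, 0.5, cfg)) > 0
  }))
  # binomial 99.5% upper bound around 0.05
  expect_lte(n_rej / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("select_theta falls back on the grid midpoint under the null", {
  sim <- small_sim()
  panel <- sim$panel
  m <- ncol(panel$X)
  set.seed(47)
  hp <- data.table::data.table(
    snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
    pos = panel$snps$pos, a1 = panel$snps$a1, a2 = panel$snps$a2,
    z1 = rnorm(m), z2 = rnorm(m))
  data.table::setattr(hp, "n1", 1000)
  data.table::setattr(hp, "n2", 1000)
  l <- ld_scores(panel)
  block_idx <- list(`0` = seq_len(m))
  est <- list(h2_1 = 0, h2_2 = 0, n1 = 1000, n2 = 1000,
              m_total = m, rho_e_ns = 0)
  model <- build_null_model(panel, est)
  draws <- standardize_pseudo(draw_pseudo_matrix(model, 300, seed = 3),
                              hp$z1, hp$z2)
  cfg <- scan_config(n_mc = 300L, max_window = 30)
  ts <- select_theta(hp, panel, l, block_idx, draws, est, cfg)
  expect_s3_class(ts, "theta_result")
  expect_true(ts$theta_hat %in% cfg$theta_grid)
  expect_named(ts$pi, as.character(sort(cfg$theta_grid)))
  if (all(ts$pi == 0)) {
    expect_equal(ts$theta_hat, 0.55)  # documented fallback
    expect_equal(nrow(ts$results[["0.55"]]$regions), 0L)
  } else {
    # argmax definition: no grid value beats the selected one
    expect_true(all(abs(ts$pi) <= abs(ts$pi[[as.character(ts$theta_hat)]])))
  }
})

test_that("run_scan with adaptive theta returns a coherent result object", {
  sc <- sim_scenario("signal_region", m_snps = 500L, n_ref = 250L,
                     n1 = 1500L, n2 = 1500L, n_regions = 2L,
                     region_size = 30L, h2_1 = 0.08, h2_2 = 0.08)
  dir <- file.path(tempdir(), "adaptive_fx")
  fx <- make_fixture("power_grid", dir, seed = 3, scenario = sc,
                     block_bp = 1.5e6)
  s1 <- read_sumstats(fx$paths$s1)
  s2 <- read_sumstats(fx$paths$s2)
  panel <- read_panel_tsv(fx$paths$geno, fx$paths$meta)
  blocks <- read_blocks(fx$paths$blocks)
  cfg <- scan_config(theta_grid = c(0.4, 0.55, 0.7), n_mc = 300L,
                     maf_min = 0.05, seed = 2)
  # the overlap intercept estimate is noisy at this scale and may be
  # clamped into the feasible range with a warning
  res <- suppressWarnings(run_scan(s1, s2, panel, blocks, cfg))
  expect_s3_class(res, "scan_result")
  expect_true(res$theta %in% cfg$theta_grid)
  expect_length(res$pi, 3L)
  expect_true(all(c("chrom", "start_bp", "end_bp", "q_stat", "p",
                    "q_fdr") %in% names(res$regions)))
  # determinism end to end
  res2 <- suppressWarnings(run_scan(s1, s2, panel, blocks, cfg))
  expect_equal(res$theta, res2$theta)
  expect_equal(res$regions, res2$regions)
})
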
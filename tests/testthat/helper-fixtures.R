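# Shared in-memory fixtures, built once per test run. Sizes are kept
# small: module tests exercise logic, not power; the acceptance tests
# build their own, larger worlds.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small mosaic panel with realistic LD
small_sim <- function() {
  memo("small_sim", function() {
    set.seed(424242)
    simulate_panel(600, 300)
  })
}

# a sumstats table written to disk and its path
sumstats_file <- function(df, path = tempfile(fileext = ".sumstats")) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

make_sumstats <- function(snp_id, a1, a2, z, n, chrom = NULL, pos = NULL) {
  out <- data.table::data.table(snp_id = snp_id, a1 = a1, a2 = a2,
                                z = z, n = n)
  if (!is.null(chrom)) out[, chrom := chrom]
  if (!is.null(pos)) out[, pos := pos]
  data.table::setattr(out, "class", c("sumstats", class(out)))
  out
}

# hand-built null model over arbitrary chunk pieces (for sampler
# oracles with exactly known covariance)
toy_model <- function(chunk_sizes, V_list, cross_list, est,
                      n_ref = 500, chunk_bp = 1e6) {
  stopifnot(length(V_list) == length(chunk_sizes))
  chunks <- list()
  offset <- 0L
  for (k in seq_along(chunk_sizes)) {
    mi <- chunk_sizes[k]
    ch <- list(block = 0L, idx = offset + seq_len(mi), m = mi,
               V = V_list[[k]], Vt = V_list[[k]] %*% V_list[[k]],
               crossV = NULL, crossVt = NULL, prev = 0L)
    if (k > 1L && !is.null(cross_list[[k - 1L]])) {
      ch$crossV <- cross_list[[k - 1L]]
      ch$crossVt <- cross_list[[k - 1L]]
      ch$prev <- k - 1L
    }
    chunks[[k]] <- ch
    offset <- offset + mi
  }
  model <- structure(list(est = est, m = offset, n_ref = n_ref,
                          chunk_bp = chunk_bp, cond_max = 1000,
                          h2_floor = 0.05, chunks = chunks),
                     class = "null_model")
  update_null_model(model, est)
}

# the full (2m x 2m organized as list of blocks) covariance implied by
# a null model under the tridiagonal approximation -- independent
# assembly path used as the sampler's moment oracle
implied_covariance <- function(model) {
  est <- model$est
  a <- est$rho_e_ns / sqrt(est$n1 * est$n2)
  m <- model$m
  S11 <- matrix(0, m, m); S22 <- matrix(0, m, m); S12 <- matrix(0, m, m)
  qc1 <- est$n1 * est$h2_1 / est$m_total
  qc2 <- est$n2 * est$h2_2 / est$m_total
  for (ch in model$chunks) {
    i <- ch$idx
    S11[i, i] <- qc1 * ch$Vt + (1 - est$h2_1) * ch$V
    S22[i, i] <- qc2 * ch$Vt + (1 - est$h2_2) * ch$V
    S12[i, i] <- a * ch$V
    if (ch$prev > 0L) {
      j <- model$chunks[[ch$prev]]$idx
      S11[i, j] <- qc1 * ch$crossVt + (1 - est$h2_1) * ch$crossV
      S11[j, i] <- t(S11[i, j])
      S22[i, j] <- qc2 * ch$crossVt + (1 - est$h2_2) * ch$crossV
      S22[j, i] <- t(S22[i, j])
      S12[i, j] <- a * ch$crossV
      S12[j, i] <- t(S12[i, j])
    }
  }
  list(S11 = S11, S22 = S22, S12 = S12)
}
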
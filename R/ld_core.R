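#' Build a standardized genotype panel
#'
#' Mean-imputes missing dosages, drops monomorphic SNPs and SNPs below
#' the minor-allele-frequency threshold, and standardizes each SNP
#' column to mean zero and unit sample standard deviation. The
#' standardized matrix is the reference used for all LD computation.
#'
#' @param dosages Individuals x SNPs matrix of allele counts in
#'   0, 1 or 2 (NA allowed).
#' @param snps SNP metadata `data.frame` (`snp_id`, `chrom`, `pos`,
#'   `a1`, `a2`), one row per dosage column.
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @return Object of class `geno_panel`: list with `X` (standardized
#'   matrix), `snps` (metadata incl. `maf`), `maf`, `n_ref`.
#' @export
standardize_genotypes <- function(dosages, snps, maf_min = 0.01) {
  stopifnot(is.matrix(dosages), nrow(snps) == ncol(dosages))
  X <- matrix(as.numeric(dosages), nrow(dosages), ncol(dosages))
  n_missing <- colSums(is.na(X))
  all_missing <- n_missing == nrow(X)
  if (any(all_missing))
    warning(sum(all_missing), " SNP(s) with all dosages missing dropped")
  cm <- colMeans(X, na.rm = TRUE)
  cm[all_missing] <- 0
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1L) %/% nrow(X) + 1L]
  p <- colMeans(X) / 2
  maf <- pmin(p, 1 - p)
  sds <- matrixStats::colSds(X)
  keep <- !all_missing & sds > 0 & maf >= maf_min
  if (!any(keep)) stop("no polymorphic SNPs above the MAF threshold")
  X <- X[, keep, drop = FALSE]
  X <- sweep(X, 2L, colMeans(X), "-")
  X <- sweep(X, 2L, matrixStats::colSds(X), "/")
  maf_kept <- maf[keep]
  snps <- data.table::as.data.table(snps)[keep]
  snps[, maf := maf_kept]
  structure(list(X = X, snps = snps[], maf = maf_kept,
                 n_ref = nrow(X)),
            class = "geno_panel")
}

#' Subset a genotype panel to selected SNP columns
#' @param panel A `geno_panel`.
#' @param idx Integer or logical SNP index, or character SNP ids.
#' @return A `geno_panel` restricted to those SNPs, in the given order.
#' @export
subset_panel <- function(panel, idx) {
  if (is.character(idx)) idx <- match(idx, panel$snps$snp_id)
  if (anyNA(idx)) stop("unknown SNP id in panel subset")
  structure(list(X = panel$X[, idx, drop = FALSE],
                 snps = panel$snps[idx],
                 maf = panel$maf[idx],
                 n_ref = panel$n_ref),
            class = "geno_panel")
}

#' Sample LD (correlation) matrix for a SNP range
#'
#' @param panel A `geno_panel`.
#' @param idx SNP index vector (default: all SNPs).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_matrix <- function(panel, idx = seq_len(ncol(panel$X))) {
  if (length(idx) == 0L) stop("empty SNP range")
  X <- panel$X[, idx, drop = FALSE]
  V <- crossprod(X) / (nrow(X) - 1)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  V
}

#' Per-SNP LD scores within a physical window
#'
#' The LD score of SNP i is the sum of squared sample correlations
#' r^2_ij over SNPs j within `window_bp / 2` base pairs on either side
#' of SNP i (including j = i, so unadjusted scores are >= 1). Scores
#' are computed within `groups` (e.g. LD blocks) so that windows never
#' straddle block boundaries. The adjusted variant subtracts the
#' finite-sample bias (1 - r^2) / (n - 2) from each r^2 term.
#'
#' @param panel A `geno_panel` with positions sorted within groups.
#' @param window_bp Total window size in bp (default 1e6; the window
#'   extends `window_bp / 2` to each side of the focal SNP).
#' @param groups Optional grouping vector (one entry per SNP); LD is
#'   only accumulated within a group. Default: per chromosome.
#' @param adjusted Use bias-adjusted r^2 (default FALSE).
#' @return Numeric vector of LD scores, one per panel SNP.
#' @export
ld_scores <- function(panel, window_bp = 1e6, groups = NULL,
                      adjusted = FALSE) {
  pos <- panel$snps$pos
  if (is.null(groups)) groups <- panel$snps$chrom
  n <- panel$n_ref
  l <- numeric(ncol(panel$X))
  half <- window_bp / 2
  for (g in unique(groups)) {
    sel <- which(groups == g)
    if (any(diff(pos[sel]) < 0)) stop("positions must be sorted within groups")
    V <- ld_matrix(panel, sel)
    R2 <- V^2
    if (adjusted) R2 <- R2 - (1 - R2) / (n - 2)
    W <- abs(outer(pos[sel], pos[sel], "-")) <= half
    l[sel] <- rowSums(R2 * W)
  }
  l
}

#' Stratified LD scores for a two-annotation split
#'
#' Returns per-SNP LD scores accumulated separately over SNPs inside
#' and outside a region mask, using the same windowing as
#' [ld_scores()]. Columns sum to the unstratified score.
#'
#' @inheritParams ld_scores
#' @param mask Logical vector marking the "region" annotation.
#' @return Matrix with columns `region` and `rest`.
#' @export
ld_scores_stratified <- function(panel, mask, window_bp = 1e6,
                                 groups = NULL) {
  pos <- panel$snps$pos
  if (is.null(groups)) groups <- panel$snps$chrom
  stopifnot(length(mask) == ncol(panel$X))
  half <- window_bp / 2
  out <- matrix(0, ncol(panel$X), 2L,
                dimnames = list(NULL, c("region", "rest")))
  for (g in unique(groups)) {
    sel <- which(groups == g)
    R2 <- ld_matrix(panel, sel)^2
    W <- abs(outer(pos[sel], pos[sel], "-")) <= half
    R2W <- R2 * W
    mk <- mask[sel]
    out[sel, "region"] <- R2W %*% as.numeric(mk)
    out[sel, "rest"] <- R2W %*% as.numeric(!mk)
  }
  out
}

#' Bias-corrected estimate of the squared population LD matrix
#'
#' The sample LD matrix V from a panel of n individuals overestimates
#' the squared population LD: E(V^2) contains an m/n inflation term.
#' The corrected estimator is ((n - 1) V^2 - m V) / (n - 2), with m
#' the number of SNPs entering the squared matrix.
#'
#' @param V Sample LD matrix.
#' @param n_ref Reference-panel sample size (> 2).
#' @param m_used SNP count plugged into the correction (defaults to
#'   `ncol(V)`, i.e. the dimension of the chunk the estimator is
#'   applied to).
#' @return Symmetric matrix estimate.
#' @export
vtilde_sq <- function(V, n_ref, m_used = ncol(V)) {
  if (n_ref <= 2) stop("n_ref must exceed 2")
  out <- ((n_ref - 1) * (V %*% V) - m_used * V) / (n_ref - 2)
  (out + t(out)) / 2
}

#' Condition-number-capped pseudo-inverse via truncated SVD
#'
#' Keeps the largest rank q such that sigma_1 / sigma_q < `cond_max`
#' (strict) and builds the inverse from the top-q singular triplets.
#' A zero matrix yields rank 0 and a zero inverse with a warning.
#'
#' @param A Square symmetric matrix.
#' @param cond_max Condition-number cap (default 1000).
#' @return List with `inv` (pseudo-inverse) and `q` (retained rank).
#' @export
tsvd_inverse <- function(A, cond_max = 1000) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (all(A == 0)) {
    warning("zero matrix in tsvd_inverse; returning zero inverse")
    return(list(inv = A, q = 0L))
  }
  sv <- svd((A + t(A)) / 2)
  d <- sv$d
  q <- sum(d > 0 & d[1] / d < cond_max)
  if (q == 0L) {
    warning("no singular value within the condition cap")
    return(list(inv = matrix(0, nrow(A), ncol(A)), q = 0L))
  }
  keep <- seq_len(q)
  inv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / d[keep])
  list(inv = inv, q = q)
}
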
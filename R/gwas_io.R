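#' @useDynLib logoscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

ACGT <- c("A", "C", "G", "T")

#' Read a GWAS summary-statistics table
#'
#' Reads the tab-separated `.sumstats` dialect popularized by LD-score
#' regression tooling: one row per SNP with columns `SNP`, `A1` (effect
#' allele), `A2` (other allele), `Z` (association z-score) and `N`
#' (GWAS sample size). Optional `CHR` and `BP` columns are carried along
#' when present. Rows with missing or non-finite `Z`/`N`, non-positive
#' `N`, or alleles outside A/C/G/T are dropped and counted; duplicated
#' SNP identifiers keep the first occurrence.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector mapping the
#'   canonical names (`SNP`, `A1`, `A2`, `Z`, `N`, and optionally
#'   `CHR`, `BP`) to the names used in the file, e.g.
#'   `c(SNP = "rsid", Z = "zscore")`.
#' @return A `data.table` of class `sumstats` with columns `snp_id`,
#'   `a1`, `a2`, `z`, `n` (plus `chrom`, `pos` when available) and
#'   attributes `n_dropped` (rows removed by QC) and `n_duplicates`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("sumstats file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          na.strings = c("NA", "", "."))
  if (nrow(dt) == 0L) stop("empty sumstats file: ", path)
  nm <- c(SNP = "SNP", A1 = "A1", A2 = "A2", Z = "Z", N = "N",
          CHR = "CHR", BP = "BP")
  if (!is.null(column_map)) nm[names(column_map)] <- unname(column_map)
  for (col in c("SNP", "A1", "A2", "Z", "N")) {
    if (!nm[[col]] %in% names(dt))
      stop("sumstats file is missing mandatory column '", nm[[col]],
           "' (", col, "): ", path)
  }
  out <- data.table::data.table(
    snp_id = as.character(dt[[nm[["SNP"]]]]),
    a1 = toupper(as.character(dt[[nm[["A1"]]]])),
    a2 = toupper(as.character(dt[[nm[["A2"]]]])),
    z = as.numeric(dt[[nm[["Z"]]]]),
    n = as.numeric(dt[[nm[["N"]]]]))
  if (nm[["CHR"]] %in% names(dt)) out[, chrom := as.character(dt[[nm[["CHR"]]]])]
  if (nm[["BP"]] %in% names(dt)) out[, pos := as.integer(dt[[nm[["BP"]]]])]
  keep <- is.finite(out$z) & is.finite(out$n) & out$n > 0 &
    out$a1 %in% ACGT & out$a2 %in% ACGT & out$a1 != out$a2
  n_dropped <- sum(!keep)
  out <- out[keep]
  dup <- duplicated(out$snp_id)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    warning(n_dup, " duplicated SNP id(s) in ", path, "; keeping first occurrence")
    out <- out[!dup]
  }
  if (nrow(out) == 0L) stop("no SNPs left after QC: ", path)
  data.table::setattr(out, "n_dropped", n_dropped)
  data.table::setattr(out, "n_duplicates", n_dup)
  data.table::setattr(out, "class", c("sumstats", class(out)))
  out[]
}

is_strand_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a2 == unname(comp[a1])
}

#' Harmonize two summary-statistics sets against a reference panel
#'
#' Intersects the SNP sets of two studies and a reference panel,
#' removes strand-ambiguous (A/T, C/G) SNPs, aligns the study-2 z-score
#' sign to the study-1 effect allele (flipping its sign when the allele
#' pair is swapped, dropping the SNP when the alleles do not match even
#' after a swap), then aligns both z-scores to the reference-panel
#' allele coding so that z-score products and panel LD share one
#' orientation. An optional minor-allele-frequency filter from the
#' panel is applied. Output is sorted by chromosome and position.
#'
#' @param s1,s2 Objects from [read_sumstats()].
#' @param panel_meta SNP metadata `data.frame` with columns `snp_id`,
#'   `chrom`, `pos`, `a1`, `a2` and optionally `maf` (e.g. the `snps`
#'   element of a genotype panel, or [read_bim()] output).
#' @param maf_min Minimum panel minor-allele frequency; SNPs below it
#'   are removed when `panel_meta` carries a `maf` column. The default
#'   0.01 matches common real-data practice; simulation pipelines
#'   typically use 0.05.
#' @return A `data.table` of class `harmonized_pair` with columns
#'   `snp_id`, `chrom`, `pos`, `a1`, `a2` (reference-panel coding),
#'   `z1`, `z2`, and attributes `n1`, `n2` (median GWAS sample sizes).
#' @export
harmonize_pair <- function(s1, s2, panel_meta, maf_min = 0.01) {
  pm <- data.table::as.data.table(panel_meta)
  need <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(pm)))
    stop("panel_meta must have columns: ", paste(need, collapse = ", "))
  if ("maf" %in% names(pm) && !is.null(maf_min)) pm <- pm[maf >= maf_min]
  s1 <- data.table::as.data.table(s1)
  s2 <- data.table::as.data.table(s2)
  ids <- Reduce(intersect, list(s1$snp_id, s2$snp_id, pm$snp_id))
  if (length(ids) == 0L) stop("no SNPs shared by both studies and the panel")
  i1 <- s1[match(ids, snp_id)]
  i2 <- s2[match(ids, snp_id)]
  ip <- pm[match(ids, snp_id)]

  ok <- !is_strand_ambiguous(i1$a1, i1$a2) & !is_strand_ambiguous(i2$a1, i2$a2)
  # study 2 -> study 1 orientation
  same <- i2$a1 == i1$a1 & i2$a2 == i1$a2
  swap <- i2$a1 == i1$a2 & i2$a2 == i1$a1
  ok <- ok & (same | swap)
  z2 <- ifelse(swap, -i2$z, i2$z)
  # pair -> panel orientation (flip both so the product is unchanged)
  psame <- i1$a1 == ip$a1 & i1$a2 == ip$a2
  pswap <- i1$a1 == ip$a2 & i1$a2 == ip$a1
  ok <- ok & (psame | pswap)
  sgn <- ifelse(pswap, -1, 1)
  out <- data.table::data.table(
    snp_id = ids, chrom = ip$chrom, pos = ip$pos,
    a1 = ip$a1, a2 = ip$a2,
    z1 = sgn * i1$z, z2 = sgn * z2)[ok]
  if (nrow(out) == 0L) stop("no SNPs left after harmonization")
  data.table::setorder(out, chrom, pos)
  data.table::setattr(out, "n1", stats::median(i1$n[ok]))
  data.table::setattr(out, "n2", stats::median(i2$n[ok]))
  data.table::setattr(out, "class", c("harmonized_pair", class(out)))
  out[]
}

#' Read approximately LD-independent genome blocks from a BED file
#'
#' Blocks follow the BED convention (0-based, half-open) and must be
#' sorted and non-overlapping within each chromosome. A SNP at 1-based
#' position `pos` belongs to the block with `start <= pos - 1 < end`.
#'
#' @param path BED file with at least 3 columns (chrom, start, end).
#' @return `data.table` with columns `chrom`, `start`, `end`,
#'   `block_id` (0-based integer, file order).
#' @export
read_blocks <- function(path) {
  b <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(b) < 3L) stop("blocks BED must have >= 3 columns")
  b <- b[, 1:3]
  data.table::setnames(b, c("chrom", "start", "end"))
  b[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
           end = as.numeric(end))]
  if (any(b$end <= b$start)) stop("blocks with end <= start")
  data.table::setorder(b, chrom, start)
  bad <- b[, .(overlap = any(start[-1] < end[-.N])), by = chrom][overlap == TRUE]
  if (nrow(bad) > 0L)
    stop("overlapping blocks on chromosome(s): ",
         paste(bad$chrom, collapse = ", "))
  b[, block_id := seq_len(.N) - 1L]
  b[]
}

#' Assign SNPs to blocks
#'
#' @param chrom,pos Vectors of chromosome labels and 1-based positions.
#' @param blocks Output of [read_blocks()].
#' @return Integer vector of `block_id`s (NA when a SNP falls in no block).
#' @export
assign_blocks <- function(chrom, pos, blocks) {
  out <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    bc <- blocks[blocks$chrom == cc, ]
    if (nrow(bc) == 0L) next
    sel <- which(chrom == cc)
    idx <- findInterval(pos[sel] - 1L, bc$start)
    hit <- idx >= 1L & (pos[sel] - 1L) < bc$end[pmax(idx, 1L)]
    out[sel[hit]] <- bc$block_id[idx[hit]]
  }
  out
}

#' Write detected regions as a BED-compatible TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `block_id`,
#' `n_snps`, `q_stat`, `p`, `q_fdr`. Rows are sorted by chromosome
#' and start. In-memory region tables carry 1-based first/last SNP
#' positions (`start_bp`, `end_bp`); the BED start is `start_bp - 1`.
#'
#' @param regions `data.frame` with columns `chrom`, `start_bp`,
#'   `end_bp`, `block_id`, `n_snps`, `q_stat`, `p`, `q_fdr`.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  cols <- c("chrom", "start_bp", "end_bp", "block_id", "n_snps",
            "q_stat", "p", "q_fdr")
  r <- data.table::as.data.table(regions)
  missing_cols <- setdiff(cols, names(r))
  if (length(missing_cols))
    stop("regions are missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.table::data.table(
    chrom = as.character(r$chrom),
    start = as.integer(r$start_bp) - 1L,
    end = as.integer(r$end_bp),
    block_id = as.integer(r$block_id),
    n_snps = as.integer(r$n_snps),
    q_stat = r$q_stat, p = r$p, q_fdr = r$q_fdr)
  data.table::setorder(out, chrom, start)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a regions TSV written by [write_regions()]
#' @param path Path to the TSV.
#' @return `data.table` with in-memory (1-based) coordinates.
#' @export
read_regions <- function(path) {
  r <- data.table::fread(path, sep = "\t", header = TRUE)
  if (nrow(r) == 0L) {
    return(data.table::data.table(
      chrom = character(), start_bp = integer(), end_bp = integer(),
      block_id = integer(), n_snps = integer(), q_stat = numeric(),
      p = numeric(), q_fdr = numeric()))
  }
  data.table::data.table(
    chrom = as.character(r$chrom), start_bp = r$start + 1L, end_bp = r$end,
    block_id = r$block_id, n_snps = r$n_snps, q_stat = r$q_stat,
    p = r$p, q_fdr = r$q_fdr)
}

#' Read PLINK .bim SNP metadata
#' @param path Path to a `.bim` file (or a PLINK prefix).
#' @return `data.table` with `snp_id`, `chrom`, `pos`, `a1`, `a2`.
#' @export
read_bim <- function(path) {
  if (!grepl("\\.bim$", path)) path <- paste0(path, ".bim")
  b <- data.table::fread(path, header = FALSE)
  data.table::setnames(b, c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  b[, .(snp_id = as.character(snp_id), chrom = as.character(chrom),
        pos = as.integer(pos), a1 = toupper(as.character(a1)),
        a2 = toupper(as.character(a2)))]
}

#' Read a PLINK bed/bim/fam fileset into a dosage matrix
#'
#' Decodes the SNP-major PLINK 1 binary format. Dosages count copies
#' of the `.bim` A1 allele; missing genotypes become `NA`.
#'
#' @param prefix Path prefix (without extension).
#' @return List with `dosages` (individuals x SNPs integer matrix) and
#'   `snps` (the [read_bim()] table).
#' @export
read_plink <- function(prefix) {
  bim <- read_bim(prefix)
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3L + ceiling(n / 4) * m)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", prefix, ".bed")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  body <- raw[-(1:3)]
  # 2-bit codes per individual: 00 hom A1, 01 missing, 10 het, 11 hom A2
  codes <- matrix(0L, nrow = 4L * ceiling(n / 4), ncol = m)
  ints <- as.integer(body)
  dim(ints) <- c(ceiling(n / 4), m)
  for (shift in 0:3) {
    codes[seq(shift + 1L, by = 4L, length.out = nrow(ints)), ] <-
      bitwAnd(bitwShiftR(ints, 2L * shift), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  colnames(dos) <- bim$snp_id
  list(dosages = dos, snps = bim)
}

#' Read a plain-text dosage panel
#'
#' Fixture-friendly alternative to PLINK binary input: a tab-separated
#' dosage matrix (one row per individual, one column per SNP, values in
#' 0/1/2 with `NA` for missing) plus a SNP metadata table with columns
#' `snp_id`, `chrom`, `pos`, `a1`, `a2`.
#'
#' @param geno_path Path to the dosage TSV (with a header of SNP ids).
#' @param meta_path Path to the SNP metadata TSV.
#' @return List with `dosages` and `snps` as in [read_plink()].
#' @export
read_panel_tsv <- function(geno_path, meta_path) {
  g <- data.table::fread(geno_path, sep = "\t", header = TRUE)
  snps <- data.table::fread(meta_path, sep = "\t", header = TRUE)
  snps <- snps[, .(snp_id = as.character(snp_id), chrom = as.character(chrom),
                   pos = as.integer(pos), a1 = toupper(a1), a2 = toupper(a2))]
  dos <- as.matrix(g)
  storage.mode(dos) <- "integer"
  if (!identical(colnames(dos), snps$snp_id))
    stop("dosage columns and SNP metadata disagree")
  list(dosages = dos, snps = snps)
}

#' Write LD scores as a TSV cache
#' @param snp_id Character vector of SNP ids.
#' @param l Numeric LD scores.
#' @param path Output path.
#' @export
write_ld_scores <- function(snp_id, l, path) {
  data.table::fwrite(data.table::data.table(SNP = snp_id, L2 = l),
                     path, sep = "\t")
  invisible(path)
}
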
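# Detection scoring against ground truth (three power metrics) and
# the annotation-enrichment permutation test with conditional
# annotations. Intervals are data.frames: SNP-index sets use 1-based
# inclusive (start, end); bp tracks use BED-style 0-based half-open
# (chrom, start, end).

iv_canon <- function(iv) {
  iv <- as.data.frame(iv)
  if (!"chrom" %in% names(iv)) iv$chrom <- "."
  iv[, c("chrom", "start", "end")]
}

# merge overlapping/adjacent intervals within chrom (half-open)
iv_merge <- function(iv) {
  iv <- iv_canon(iv)
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$chrom, iv$start), ]
  out <- iv[1, ]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    j <- nrow(out)
    if (iv$chrom[i] == out$chrom[j] && iv$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

iv_width <- function(iv) sum(pmax(iv$end - iv$start, 0))

# half-open intersection of two merged interval sets
iv_intersect <- function(a, b) {
  a <- iv_merge(a); b <- iv_merge(b)
  out <- list()
  for (cc in intersect(a$chrom, b$chrom)) {
    ac <- a[a$chrom == cc, ]; bc <- b[b$chrom == cc, ]
    for (i in seq_len(nrow(ac))) {
      s <- pmax(ac$start[i], bc$start)
      e <- pmin(ac$end[i], bc$end)
      keep <- e > s
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(chrom = cc, start = s[keep],
                                              end = e[keep])
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  do.call(rbind, out)
}

# SNP-index intervals (1-based inclusive) -> half-open
snp_iv <- function(iv) {
  iv <- as.data.frame(iv)
  data.frame(chrom = if ("chrom" %in% names(iv)) iv$chrom else ".",
             start = iv$start, end = iv$end + 1L)
}

#' Signal-points detection rate
#'
#' Fraction of true signal SNPs (or base pairs) covered by the union
#' of detected segments.
#'
#' @param truth,detected Interval tables; SNP-index sets (1-based
#'   inclusive `start`, `end`) by default, or bp half-open when
#'   `unit = "bp"`.
#' @param unit `"snp"` or `"bp"`.
#' @return Rate in the unit interval.
#' @export
point_detection_rate <- function(truth, detected, unit = c("snp", "bp")) {
  unit <- match.arg(unit)
  if (nrow(as.data.frame(truth)) == 0L) stop("empty truth set")
  conv <- if (unit == "snp") snp_iv else iv_canon
  t <- iv_merge(conv(truth))
  if (nrow(as.data.frame(detected)) == 0L) return(0)
  d <- iv_merge(conv(detected))
  iv_width(iv_intersect(t, d)) / iv_width(t)
}

#' Signal-segments detection rate
#'
#' Fraction of truth segments overlapped by at least one detected
#' segment.
#'
#' @inheritParams point_detection_rate
#' @export
segment_detection_rate <- function(truth, detected, unit = c("snp", "bp")) {
  unit <- match.arg(unit)
  truth <- as.data.frame(truth)
  if (nrow(truth) == 0L) stop("empty truth set")
  if (nrow(as.data.frame(detected)) == 0L) return(0)
  conv <- if (unit == "snp") snp_iv else iv_canon
  d <- iv_merge(conv(detected))
  hit <- vapply(seq_len(nrow(truth)), function(j) {
    iv_width(iv_intersect(conv(truth[j, ]), d)) > 0
  }, logical(1))
  mean(hit)
}

#' G-score: joint sensitivity/specificity overlap metric
#'
#' For each truth segment R_j, S(R_j) = max over detected segments
#' R_k of |R_k intersect R_j| / sqrt(|R_k| |R_j|); the G-score is the
#' mean of S(R_j) over truth segments (0 when nothing is detected).
#' Exact matches score 1; covering the whole genome is penalized by
#' the detected segment's size in the denominator.
#'
#' @inheritParams point_detection_rate
#' @export
g_score <- function(truth, detected, unit = c("snp", "bp")) {
  unit <- match.arg(unit)
  truth <- as.data.frame(truth)
  detected <- as.data.frame(detected)
  if (nrow(truth) == 0L) stop("empty truth set")
  if (nrow(detected) == 0L) return(0)
  conv <- if (unit == "snp") snp_iv else iv_canon
  s <- vapply(seq_len(nrow(truth)), function(j) {
    tj <- conv(truth[j, ])
    wj <- iv_width(tj)
    max(vapply(seq_len(nrow(detected)), function(k) {
      dk <- conv(detected[k, ])
      iv_width(iv_intersect(tj, dk)) / sqrt(iv_width(dk) * wj)
    }, numeric(1)))
  }, numeric(1))
  mean(s)
}

#' Combined power report
#' @inheritParams point_detection_rate
#' @return List with `point_rate`, `segment_rate`, `g_score`,
#'   `n_truth`, `n_detected`.
#' @export
power_report <- function(truth, detected, unit = c("snp", "bp")) {
  unit <- match.arg(unit)
  list(point_rate = point_detection_rate(truth, detected, unit),
       segment_rate = segment_detection_rate(truth, detected, unit),
       g_score = g_score(truth, detected, unit),
       n_truth = nrow(as.data.frame(truth)),
       n_detected = nrow(as.data.frame(detected)))
}

place_random_segments <- function(sizes, genome, max_tries = 1000L) {
  # uniform placement proportional to chromosome length, rejecting
  # overlaps among the placed segments
  probs <- genome$size / sum(genome$size)
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  for (len in sizes) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      ci <- sample.int(nrow(genome), 1L, prob = probs)
      if (genome$size[ci] < len) next
      s <- floor(stats::runif(1, 0, genome$size[ci] - len))
      cand <- data.frame(chrom = genome$chrom[ci], start = s, end = s + len)
      if (nrow(placed) == 0L ||
          iv_width(iv_intersect(cand, placed)) == 0) {
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place non-overlapping segments; ",
                  "genome too small for the requested sizes")
  }
  placed
}

#' Annotation-enrichment permutation test
#'
#' Measures the bp overlap of detected segments with an annotation
#' track, then compares it with the overlap of size-matched,
#' non-overlapping segments placed uniformly at random across the
#' genome (chromosome chosen proportional to length). Fold enrichment
#' is observed / mean(permuted); the p-value uses the add-one rule.
#'
#' @param detected,annotation bp interval tables (`chrom`, `start`,
#'   `end`, half-open).
#' @param genome `data.frame` with `chrom`, `size` (bp).
#' @param n_perm Number of permutations (default 1e5; use far fewer
#'   for desk-scale checks).
#' @param seed Optional seed.
#' @return List with `fold`, `p`, `observed`, `perm_mean`.
#' @export
enrichment_permutation <- function(detected, annotation, genome,
                                   n_perm = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  detected <- iv_merge(detected)
  if (nrow(detected) == 0L) stop("empty detected set")
  annotation <- iv_merge(annotation)
  obs <- if (nrow(annotation) == 0L) 0
  else iv_width(iv_intersect(detected, annotation))
  sizes <- detected$end - detected$start
  perm <- vapply(seq_len(n_perm), function(i) {
    seg <- place_random_segments(sizes, genome)
    if (nrow(annotation) == 0L) 0
    else iv_width(iv_intersect(seg, annotation))
  }, numeric(1))
  mu <- mean(perm)
  fold <- if (mu == 0) {
    if (obs == 0) 0 else Inf
  } else obs / mu
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(fold = fold, p = p, observed = obs, perm_mean = mu)
}

#' Subtract a conditioning annotation from a target track
#'
#' bp-level interval subtraction: the parts of `target` not covered
#' by `conditioning`.
#'
#' @param target,conditioning bp interval tables.
#' @return Interval table of the difference.
#' @export
conditional_annotation <- function(target, conditioning) {
  t <- iv_merge(target)
  c <- iv_merge(conditioning)
  if (nrow(t) == 0L || nrow(c) == 0L) return(t)
  out <- list()
  for (i in seq_len(nrow(t))) {
    cc <- c[c$chrom == t$chrom[i] & c$end > t$start[i] &
              c$start < t$end[i], ]
    s <- t$start[i]
    if (nrow(cc) == 0L) {
      out[[length(out) + 1L]] <- t[i, ]
      next
    }
    cc <- cc[order(cc$start), ]
    for (j in seq_len(nrow(cc))) {
      if (cc$start[j] > s)
        out[[length(out) + 1L]] <- data.frame(chrom = t$chrom[i],
                                              start = s, end = cc$start[j])
      s <- max(s, cc$end[j])
    }
    if (s < t$end[i])
      out[[length(out) + 1L]] <- data.frame(chrom = t$chrom[i],
                                            start = s, end = t$end[i])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
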
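#' fdM in non-overlapping windows of informative SNPs
#'
#' Computes the dynamically normalized fdM statistic (bounded in \[-1, 1\],
#' positive for P2-P3 excess allele sharing, negative for P1-P3) in
#' non-overlapping windows of `window_snps` informative SNPs. A site is
#' informative when all four role frequencies are available and p1, p2, p3
#' are not all equal (such sites contribute zero to both numerator and
#' denominator). Windows advance by `window_snps` informative SNPs within
#' each chromosome; the trailing partial window is dropped.
#'
#' Per site the numerator is ABBA - BABA (symmetric in p4); the denominator
#' substitutes the dynamic donor max(p2, p3) for both P2 and P3 when
#' p2 >= p1, and (with a sign flip) max(p1, p3) for both P1 and P3
#' otherwise.
#'
#' @param t a polarized `site_table`.
#' @param roles list of sample-identifier vectors `P1`, `P2`, `P3`,
#'   `outgroup`.
#' @param window_snps SNPs per window (default 50).
#' @return data.frame of class `window_stats`: chrom, start, end (positions
#'   of the first/last constituent SNP), n_snps, span_bp, fdm (NA when the
#'   window denominator is zero).
#' @export
fdm_windows <- function(t, roles, window_snps = WINDOW_SNPS) {
  stopifnot(all(c("P1", "P2", "P3", "outgroup") %in% names(roles)))
  p1 <- allele_freqs(t, roles$P1)
  p2 <- allele_freqs(t, roles$P2)
  p3 <- allele_freqs(t, roles$P3)
  p4 <- allele_freqs(t, roles$outgroup)
  fdm_windows_from_freqs(t$chrom, t$pos, p1, p2, p3, p4, window_snps)
}

fdm_site_terms <- function(p1, p2, p3, p4) {
  ab <- function(q1, q2, q3, q4)
    (1 - q1) * q2 * q3 * (1 - q4) + q1 * (1 - q2) * (1 - q3) * q4
  ba <- function(q1, q2, q3, q4)
    q1 * (1 - q2) * q3 * (1 - q4) + (1 - q1) * q2 * (1 - q3) * q4
  num <- ab(p1, p2, p3, p4) - ba(p1, p2, p3, p4)
  pd23 <- pmax(p2, p3)
  den_pos <- ab(p1, pd23, pd23, p4) - ba(p1, pd23, pd23, p4)
  pd13 <- pmax(p1, p3)
  den_neg <- -(ab(pd13, p2, pd13, p4) - ba(pd13, p2, pd13, p4))
  den <- ifelse(p2 >= p1, den_pos, den_neg)
  list(num = num, den = den)
}

fdm_windows_from_freqs <- function(chrom, pos, p1, p2, p3, p4,
                                   window_snps = WINDOW_SNPS) {
  ok <- complete.cases(p1, p2, p3, p4)
  informative <- ok & !(p1 == p2 & p2 == p3)
  informative[is.na(informative)] <- FALSE
  terms <- fdm_site_terms(p1, p2, p3, p4)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & informative)
    nwin <- length(idx) %/% window_snps
    if (nwin == 0) next
    for (w in seq_len(nwin)) {
      sites <- idx[((w - 1) * window_snps + 1):(w * window_snps)]
      num <- sum(terms$num[sites])
      den <- sum(terms$den[sites])
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[sites[1]], end = pos[sites[length(sites)]],
        n_snps = window_snps,
        span_bp = pos[sites[length(sites)]] - pos[sites[1]] + 1L,
        fdm = if (den == 0) NA_real_ else num / den,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_snps = integer(0), span_bp = integer(0), fdm = numeric(0))
  class(res) <- c("window_stats", "data.frame")
  res
}

#' Drop oversize fdM windows
#'
#' SNP-count windows spanning mostly inaccessible genome become very long;
#' windows with span strictly greater than `max_bp` are removed.
#'
#' @param w a `window_stats` data.frame.
#' @param max_bp maximum span in bp (default 20000; a window of exactly
#'   `max_bp` is kept).
#' @return the filtered `window_stats`.
#' @export
drop_oversize <- function(w, max_bp = MAX_WINDOW_BP) {
  res <- w[w$span_bp <= max_bp, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("window_stats", "data.frame")
  res
}

#' Negative-tail candidate threshold for positive fdM windows
#'
#' Under the no-gene-flow null, fdM is symmetric around zero, so the
#' magnitude of the q-quantile of the negative tail serves as a
#' significance threshold for positive windows: candidates are windows with
#' fdM strictly greater than |quantile(fdm, q)| (linear interpolation
#' between order statistics).
#'
#' @param w a `window_stats` data.frame (or a bare numeric fdM vector).
#' @param q lower-tail quantile (default 0.005, i.e. the most negative
#'   0.5\% of windows).
#' @return list of class `candidate_report`: `threshold`, `candidate`
#'   (logical over windows, NA fdM counted as non-candidate), `N`, `k`,
#'   `percent`, `q`. If the q-quantile is positive the threshold is set to
#'   0 with a warning.
#' @export
candidate_threshold <- function(w, q = TAIL_Q) {
  values <- if (is.data.frame(w)) w$fdm else w
  usable <- values[!is.na(values)]
  if (length(usable) == 0)
    stop("no usable windows to derive a threshold from")
  if (length(usable) < 1 / q)
    warning(sprintf("only %d windows for a %.4g quantile", length(usable), q))
  qv <- unname(quantile(usable, q, type = 7))
  if (qv > 0) {
    warning("negative-tail quantile is positive; threshold set to 0")
    qv <- 0
  }
  threshold <- abs(qv)
  candidate <- !is.na(values) & values > threshold
  structure(list(threshold = threshold, candidate = candidate,
                 N = length(values), k = sum(candidate),
                 percent = 100 * sum(candidate) / length(values), q = q),
            class = "candidate_report")
}

#' Kolmogorov-Smirnov diagnostic against a normal distribution
#'
#' Standardizes the values by their sample mean and SD and tests against
#' the standard normal; a mean shift and skewness are reported alongside.
#' Estimating the reference parameters from the sample makes the test
#' anticonservative, which is documented rather than corrected.
#'
#' @param values numeric vector (n >= 10).
#' @return list with `statistic` (D), `p`, `mean`, `sd`, `skewness`.
#' @export
ks_vs_normal <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need at least 10 values")
  s <- sd(values)
  if (s == 0) stop("zero variance")
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  skew <- mean(z^3)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       mean = mean(values), sd = s, skewness = skew)
}

#' Expected number of adjacent candidate windows
#'
#' Under random placement of k candidates among N genome-ordered windows,
#' the expected count of candidate windows adjacent to another candidate is
#' approximated by (N - 1) * (k / N)^2 * 2.
#'
#' @param N total number of windows.
#' @param k number of candidate windows.
#' @return the expected adjacent-candidate count.
#' @export
expected_adjacent_windows <- function(N, k) {
  (N - 1) * (k / N)^2 * 2
}

#' Adjacency enrichment of candidate windows
#'
#' Counts candidate windows immediately preceded or followed (within the
#' same chromosome) by another candidate, compares with the
#' [expected_adjacent_windows()] expectation, and reports the run-length
#' spectrum of maximal candidate runs (a run of length 8 counts once at
#' n = 8).
#'
#' @param report a [candidate_threshold()] result.
#' @param w the `window_stats` data.frame the report was computed on
#'   (genome-ordered).
#' @return list of class `adjacency_report`: `observed`, `expected`,
#'   `deviation` (observed/expected; NA when no candidates), `percent`
#'   (observed as a percentage of candidates), `run_lengths` (named count
#'   vector over run lengths >= 2).
#' @export
adjacency_stats <- function(report, w) {
  stopifnot(inherits(report, "candidate_report"), nrow(w) == report$N)
  cand <- report$candidate
  observed <- 0L
  runs <- integer(0)
  for (ch in unique(w$chrom)) {
    cc <- cand[w$chrom == ch]
    r <- rle(cc)
    long <- r$lengths[r$values & r$lengths >= 2]
    observed <- observed + sum(long)
    runs <- c(runs, long)
  }
  expected <- expected_adjacent_windows(report$N, report$k)
  spectrum <- if (length(runs)) table(factor(runs, levels = sort(unique(runs))))
    else table(integer(0))
  structure(list(observed = observed, expected = expected,
                 deviation = if (report$k == 0 || expected == 0) NA_real_
                   else observed / expected,
                 percent = if (report$k == 0) NA_real_
                   else 100 * observed / report$k,
                 run_lengths = spectrum),
            class = "adjacency_report")
}
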
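#' Pairwise sequence divergence per accessible site
#'
#' For each pair of diploid samples, the expected per-nucleotide difference
#' of randomly drawn alleles: per site `[g_i (2 - g_j) + (2 - g_i) g_j] / 4`
#' summed over sites and divided by the accessible genome length L. By
#' default sites with a missing genotype in a pair are skipped while L stays
#' global (the conventional choice when a single accessible length is
#' published); `per_pair = TRUE` instead reduces L by the number of skipped
#' sites for that pair.
#'
#' @param t a `site_table`.
#' @param L accessible genome length in sites (>= number of variant sites).
#' @param members optional subset of samples.
#' @param per_pair reduce L per pair for missing data (default FALSE).
#' @return symmetric matrix of per-site divergences, zero diagonal.
#' @export
pairwise_dxy <- function(t, L, members = NULL, per_pair = FALSE) {
  if (L <= 0) stop("accessible length must be positive")
  if (is.null(members)) members <- samples(t)
  d <- t$dosage[, members, drop = FALSE]
  ns <- length(members)
  out <- matrix(0, ns, ns, dimnames = list(members, members))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      gi <- d[, i]; gj <- d[, j]
      ok <- !is.na(gi) & !is.na(gj)
      diffs <- sum(gi[ok] * (2 - gj[ok]) + (2 - gi[ok]) * gj[ok]) / 4
      denom <- if (per_pair) L - sum(!ok) else L
      out[i, j] <- out[j, i] <- diffs / denom
    }
  }
  out
}

#' Per-sample heterozygosity per accessible site
#'
#' @param t a `site_table`.
#' @param L accessible genome length (> 0).
#' @return named vector: count of heterozygous sites / L per sample.
#' @export
heterozygosity <- function(t, L) {
  if (L <= 0) stop("accessible length must be positive")
  colSums(t$dosage == 1L, na.rm = TRUE) / L
}

#' Net nucleotide divergence D_A between two groups
#'
#' D_A = median cross-group dxy minus the mean of the two groups' median
#' per-sample heterozygosities; the divergence accumulated since the split,
#' net of ancestral diversity.
#'
#' @param dxy pairwise divergence matrix from [pairwise_dxy()].
#' @param het per-sample heterozygosities from [heterozygosity()].
#' @param x,y character vectors of sample identifiers for the two groups.
#' @return D_A (per site).
#' @export
net_divergence <- function(dxy, het, x, y) {
  cross <- dxy[x, y, drop = FALSE]
  median(cross) - mean(c(median(het[x]), median(het[y])))
}

#' Jackknife bounds without Bessel's correction
#'
#' Given delete-one estimates theta_i, returns mean(theta) +/- 3 standard
#' deviations with the variance taken over the theta_i using divisor n
#' (Bessel's correction removed, giving more conservative intervals that
#' also absorb process variation among blocks).
#'
#' @param theta numeric vector of delete-one estimates (n >= 2).
#' @return list with `mean`, `sd`, `lower`, `upper`, `n`.
#' @export
jackknife_bounds <- function(theta) {
  n <- length(theta)
  if (n < 2) stop("need at least 2 delete-one estimates")
  m <- mean(theta)
  v <- sum((theta - m)^2) / n
  list(mean = m, sd = sqrt(v), lower = m - 3 * sqrt(v),
       upper = m + 3 * sqrt(v), n = n)
}

#' Convert a net divergence to a split time in years
#'
#' t = D_A * generation_time / (2 mu).
#'
#' @param da net divergence (per site).
#' @param gen_time generation time in years (default 3).
#' @param mu per-site per-generation mutation rate (default 3.5e-9).
#' @return split time in years.
#' @export
split_time <- function(da, gen_time = GEN_TIME, mu = MU) {
  if (mu <= 0 || gen_time <= 0) stop("mu and gen_time must be positive")
  da * gen_time / (2 * mu)
}

#' Split-time estimate with a chromosome-delete jackknife
#'
#' Recomputes D_A leaving out one chromosome at a time (both the median
#' cross-group dxy and the median heterozygosities are recomputed on the
#' reduced genome), forms +/- 3 SD bounds via [jackknife_bounds()], and
#' converts the bounds to years via [split_time()].
#'
#' @param t a `site_table` spanning several chromosomes.
#' @param x,y sample identifier vectors for the two lineages.
#' @param chrom_lengths named vector of accessible lengths per chromosome
#'   (names matching `t$chrom`).
#' @param gen_time,mu as in [split_time()].
#' @return object of class `split_time_estimate`: `da` (full-genome point
#'   estimate), `da_lower`, `da_upper`, `t_lower`, `t_upper`, `t_point`
#'   (years), `theta` (delete-one estimates), `n_chrom`.
#' @export
split_time_estimate <- function(t, x, y, chrom_lengths,
                                gen_time = GEN_TIME, mu = MU) {
  chroms <- names(chrom_lengths)
  if (is.null(chroms) || !all(unique(t$chrom) %in% chroms))
    stop("chrom_lengths must be named and cover every chromosome in t")
  all_samp <- c(x, y)
  d <- t$dosage[, all_samp, drop = FALSE]
  ns <- length(all_samp)
  # per-chromosome raw difference sums and heterozygous-site counts
  pair_idx <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  diff_sums <- matrix(0, length(chroms), nrow(pair_idx),
                      dimnames = list(chroms, NULL))
  het_counts <- matrix(0, length(chroms), ns,
                       dimnames = list(chroms, all_samp))
  for (ch in chroms) {
    rows <- t$chrom == ch
    dd <- d[rows, , drop = FALSE]
    het_counts[ch, ] <- colSums(dd == 1L, na.rm = TRUE)
    for (p in seq_len(nrow(pair_idx))) {
      gi <- dd[, pair_idx[p, 1]]; gj <- dd[, pair_idx[p, 2]]
      ok <- !is.na(gi) & !is.na(gj)
      diff_sums[ch, p] <- sum(gi[ok] * (2 - gj[ok]) +
                                (2 - gi[ok]) * gj[ok]) / 4
    }
  }
  da_from <- function(keep) {
    Lk <- sum(chrom_lengths[keep])
    dmat <- matrix(0, ns, ns, dimnames = list(all_samp, all_samp))
    sums <- colSums(diff_sums[keep, , drop = FALSE])
    for (p in seq_len(nrow(pair_idx))) {
      i <- pair_idx[p, 1]; j <- pair_idx[p, 2]
      dmat[i, j] <- dmat[j, i] <- sums[p] / Lk
    }
    het <- colSums(het_counts[keep, , drop = FALSE]) / Lk
    net_divergence(dmat, het, x, y)
  }
  da_full <- da_from(chroms)
  theta <- vapply(chroms, function(ch) da_from(setdiff(chroms, ch)),
                  numeric(1))
  jb <- jackknife_bounds(theta)
  structure(list(
    da = da_full, da_lower = jb$lower, da_upper = jb$upper,
    t_point = split_time(da_full, gen_time, mu),
    t_lower = split_time(jb$lower, gen_time, mu),
    t_upper = split_time(jb$upper, gen_time, mu),
    theta = theta, n_chrom = length(chroms)),
    class = "split_time_estimate")
}

#' @export
#' @method print split_time_estimate
print.split_time_estimate <- function(x, ...) {
  cat(sprintf(
    "split_time_estimate: D_A = %.3g [%.3g, %.3g]; %.3g years [%.3g, %.3g] (n = %d chromosomes)\n",
    x$da, x$da_lower, x$da_upper, x$t_point, x$t_lower, x$t_upper,
    x$n_chrom))
  invisible(x)
}

#' Ratio of divergence between two lineage pairs
#'
#' Compares how divergent pair A is relative to pair B on the same site
#' universe, using either the median cross-group dxy (default) or D_A.
#'
#' @param dxy pairwise divergence matrix.
#' @param a,b each a list of two sample-identifier vectors, e.g.
#'   `list(x = ..., y = ...)`.
#' @param statistic "dxy" or "da".
#' @param het per-sample heterozygosities (required for "da").
#' @return the ratio A / B; NA with a warning when B's value is zero.
#' @export
divergence_ratio <- function(dxy, a, b, statistic = c("dxy", "da"),
                             het = NULL) {
  statistic <- match.arg(statistic)
  val <- function(pair) {
    if (statistic == "dxy") median(dxy[pair[[1]], pair[[2]], drop = FALSE])
    else net_divergence(dxy, het, pair[[1]], pair[[2]])
  }
  va <- val(a); vb <- val(b)
  if (vb == 0) {
    warning("zero denominator in divergence ratio")
    return(NA_real_)
  }
  va / vb
}
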
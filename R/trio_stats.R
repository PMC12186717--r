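#' Per-site ABBA/BABA/BBAA pattern weights from allele frequencies
#'
#' Frequency-weighted site-pattern probabilities for an ordered trio plus
#' outgroup, using the symmetric formulation that handles a non-zero
#' outgroup derived frequency p4 (e.g. 0.5 at heterozygous outgroup sites).
#'
#' @param p1,p2,p3,p4 aligned per-site derived-allele frequency vectors;
#'   sites with any missing frequency are skipped.
#' @return named numeric vector `c(BBAA=, ABBA=, BABA=)`.
#' @export
pattern_sums <- function(p1, p2, p3, p4) {
  terms <- site_pattern_terms(p1, p2, p3, p4)
  c(BBAA = sum(terms$bbaa, na.rm = TRUE),
    ABBA = sum(terms$abba, na.rm = TRUE),
    BABA = sum(terms$baba, na.rm = TRUE))
}

site_pattern_terms <- function(p1, p2, p3, p4) {
  check_freq(p1); check_freq(p2); check_freq(p3); check_freq(p4)
  ok <- complete.cases(p1, p2, p3, p4)
  abba <- baba <- bbaa <- rep(NA_real_, length(p1))
  abba[ok] <- (1 - p1[ok]) * p2[ok] * p3[ok] * (1 - p4[ok]) +
    p1[ok] * (1 - p2[ok]) * (1 - p3[ok]) * p4[ok]
  baba[ok] <- p1[ok] * (1 - p2[ok]) * p3[ok] * (1 - p4[ok]) +
    (1 - p1[ok]) * p2[ok] * (1 - p3[ok]) * p4[ok]
  bbaa[ok] <- p1[ok] * p2[ok] * (1 - p3[ok]) * (1 - p4[ok]) +
    (1 - p1[ok]) * (1 - p2[ok]) * p3[ok] * p4[ok]
  list(abba = abba, baba = baba, bbaa = bbaa, ok = ok)
}

check_freq <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  invisible(p)
}

#' Patterson's D from pattern sums
#'
#' D = (ABBA - BABA) / (ABBA + BABA). Positive values indicate excess
#' derived-allele sharing between P2 and P3, negative between P1 and P3.
#'
#' @param sums named vector with `ABBA` and `BABA` components, as returned
#'   by [pattern_sums()].
#' @return D in \[-1, 1\]; NA with a warning if ABBA + BABA is zero.
#' @export
patterson_d <- function(sums) {
  den <- sums[["ABBA"]] + sums[["BABA"]]
  if (den == 0) {
    warning("ABBA + BABA is zero; D undefined")
    return(NA_real_)
  }
  (sums[["ABBA"]] - sums[["BABA"]]) / den
}

#' Contiguous equal-count blocks of per-site pattern terms
#'
#' Splits the informative sites into `blocks` contiguous genome-ordered
#' groups of (near) equal SNP count and sums ABBA/BABA within each, the
#' substrate of the block jackknife.
#'
#' @param p1,p2,p3,p4 aligned frequency vectors (genome order).
#' @param blocks number of blocks (m >= 2).
#' @return a `block_series`: matrix with columns `abba`, `baba`, one row
#'   per block.
#' @export
block_series <- function(p1, p2, p3, p4, blocks = JACKKNIFE_BLOCKS) {
  terms <- site_pattern_terms(p1, p2, p3, p4)
  idx <- which(terms$ok)
  if (length(idx) < blocks) stop("fewer usable sites than blocks")
  grp <- ceiling(seq_along(idx) / (length(idx) / blocks))
  grp[grp > blocks] <- blocks
  m <- cbind(abba = tapply(terms$abba[idx], grp, sum),
             baba = tapply(terms$baba[idx], grp, sum))
  structure(m, class = c("block_series", "matrix"))
}

#' Block-jackknife significance of Patterson's D
#'
#' Delete-one-block estimates of D give the jackknife standard error
#' SE^2 = (m-1)/m * sum((D_i - mean(D_i))^2); Z = D/SE and a two-sided
#' normal p-value. When all block estimates coincide the SE is zero and the
#' result is flagged (Z infinite, p = 0).
#'
#' @param b a [block_series()].
#' @return list with `D`, `SE`, `Z`, `p`, `degenerate`.
#' @export
block_jackknife <- function(b) {
  m <- nrow(b)
  if (m < 2) stop("need at least 2 blocks")
  tot <- colSums(b)
  D <- (tot["abba"] - tot["baba"]) / (tot["abba"] + tot["baba"])
  Di <- vapply(seq_len(m), function(i) {
    s <- tot - b[i, ]
    (s[["abba"]] - s[["baba"]]) / (s[["abba"]] + s[["baba"]])
  }, numeric(1))
  SE <- sqrt((m - 1) / m * sum((Di - mean(Di))^2))
  if (SE == 0) {
    return(list(D = unname(D), SE = 0,
                Z = if (D == 0) 0 else sign(unname(D)) * Inf,
                p = if (D == 0) 1 else 0, degenerate = TRUE))
  }
  Z <- unname(D) / SE
  list(D = unname(D), SE = SE, Z = Z, p = 2 * pnorm(-abs(Z)),
       degenerate = FALSE)
}

#' f4-ratio admixture-fraction estimate
#'
#' Computes sum((p1-p2)(p3a-p4)) / sum((p1-p3b)(p3a-p4)) over sites, the
#' ratio of two f4 statistics with the donor population split into halves
#' a and b. Full replacement of P2 by P3 gives 1; no admixture gives 0.
#'
#' @param p1,p2,p3a,p3b,p4 aligned frequency vectors; `p3a`/`p3b` are the
#'   two halves of the donor sample (see [split_freqs_p3()]).
#' @return the ratio; NA with a warning when the denominator is zero.
#' @export
f4_ratio <- function(p1, p2, p3a, p3b, p4) {
  ok <- complete.cases(p1, p2, p3a, p3b, p4)
  num <- sum((p1[ok] - p2[ok]) * (p3a[ok] - p4[ok]))
  den <- sum((p1[ok] - p3b[ok]) * (p3a[ok] - p4[ok]))
  if (den == 0) {
    warning("zero f4 denominator")
    return(NA_real_)
  }
  num / den
}

#' Split donor haplotypes into two frequency sequences
#'
#' At every site the non-missing donor haplotypes are split into two halves
#' by hypergeometric sampling of the derived-allele count (the standard
#' device when phasing is absent); sites with fewer than 2 haplotypes give
#' NA in both halves.
#'
#' @param t a `site_table`.
#' @param members donor (P3) sample identifiers.
#' @return list with numeric vectors `a` and `b`.
#' @export
split_freqs_p3 <- function(t, members) {
  d <- t$dosage[, members, drop = FALSE]
  k <- rowSums(d, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(d))
  na_half <- floor(n / 2)
  nb_half <- n - na_half
  a <- b <- rep(NA_real_, length(k))
  ok <- n >= 2
  ka <- rep(NA_real_, length(k))
  ka[ok] <- rhyper(sum(ok), k[ok], n[ok] - k[ok], na_half[ok])
  a[ok] <- ka[ok] / na_half[ok]
  b[ok] <- (k[ok] - ka[ok]) / nb_half[ok]
  list(a = a, b = b)
}

#' Enumerate ordered trios from role sets or a guide tree
#'
#' In role mode, every ordered (P1, P2, P3) combination of the declared
#' role sets is emitted; the sets must be disjoint (orientation comes from
#' the roles, never from the sign of D, so negative D remains meaningful).
#' In guide-tree mode, every ordered trio of `species` whose (P1, P2) pair
#' is a cherry relative to P3 on the tree is emitted (both sister orders).
#'
#' @param roles list with character vectors `P1`, `P2`, `P3` (role mode).
#' @param tree an `ape::phylo` rooted guide tree (guide-tree mode).
#' @param species species to consider in guide-tree mode (defaults to all
#'   tip labels); species absent from the tree are skipped with a warning.
#' @return data.frame with columns P1, P2, P3.
#' @export
enumerate_trios <- function(roles = NULL, tree = NULL, species = NULL) {
  if (!is.null(roles)) {
    stopifnot(all(c("P1", "P2", "P3") %in% names(roles)))
    pairs <- list(c("P1", "P2"), c("P1", "P3"), c("P2", "P3"))
    for (p in pairs) {
      overlap <- intersect(roles[[p[1]]], roles[[p[2]]])
      if (length(overlap))
        stop("species in both ", p[1], " and ", p[2], " sets: ",
             paste(overlap, collapse = ", "))
    }
    out <- expand.grid(P1 = roles$P1, P2 = roles$P2, P3 = roles$P3,
                       stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    return(out[, c("P1", "P2", "P3")])
  }
  stopifnot(!is.null(tree))
  if (is.null(species)) species <- tree$tip.label
  absent <- setdiff(species, tree$tip.label)
  if (length(absent)) {
    warning("species absent from guide tree skipped: ",
            paste(absent, collapse = ", "))
    species <- setdiff(species, absent)
  }
  depth <- ape::node.depth.edgelength(tree)
  tipno <- match(species, tree$tip.label)
  out <- list()
  nsp <- length(species)
  if (nsp >= 3) {
    combs <- utils::combn(nsp, 3)
    for (cc in seq_len(ncol(combs))) {
      trip <- combs[, cc]
      labs <- species[trip]
      tips <- tipno[trip]
      m12 <- ape::getMRCA(tree, tips[c(1, 2)])
      m13 <- ape::getMRCA(tree, tips[c(1, 3)])
      m23 <- ape::getMRCA(tree, tips[c(2, 3)])
      ms <- c(m12, m13, m23)
      deepest <- which.max(depth[ms]) # most recent MRCA = sister pair
      sis <- switch(deepest, c(1, 2), c(1, 3), c(2, 3))
      third <- setdiff(1:3, sis)
      # require a strictly resolved cherry
      if (sum(depth[ms] == max(depth[ms])) == 1) {
        out[[length(out) + 1]] <- data.frame(
          P1 = c(labs[sis[1]], labs[sis[2]]),
          P2 = c(labs[sis[2]], labs[sis[1]]),
          P3 = labs[third], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(P1 = character(0), P2 = character(0), P3 = character(0))
}

#' Genome-wide ABBA-BABA statistics for all declared trios
#'
#' The Dtrios-style engine: pools samples by species, computes per-species
#' derived-allele frequencies, and for every ordered trio reports the
#' weighted BBAA/ABBA/BABA sums, Patterson's D, the block-jackknife Z and
#' two-sided p, and the f4-ratio (donor split into halves per site).
#'
#' @param t a polarized `site_table`.
#' @param map sample map data.frame (`sample`, `species`, `group`).
#' @param roles list with `P1`, `P2`, `P3` species sets and `outgroup`
#'   (species whose pooled frequency is p4; typically the ancestral-state
#'   sample's species).
#' @param blocks jackknife block count.
#' @param seed seed for the per-site donor split of the f4-ratio.
#' @return data.frame with one row per trio: P1, P2, P3, BBAA, ABBA, BABA,
#'   D, Z, p, f4ratio.
#' @export
dtrios <- function(t, map, roles, blocks = JACKKNIFE_BLOCKS, seed = 1L) {
  stopifnot(all(c("P1", "P2", "P3", "outgroup") %in% names(roles)))
  set.seed(seed)
  trios <- enumerate_trios(roles = roles[c("P1", "P2", "P3")])
  sp_members <- split(map$sample, map$species)
  need <- unique(c(trios$P1, trios$P2, trios$P3, roles$outgroup))
  absent <- setdiff(need, names(sp_members))
  if (length(absent))
    stop("species missing from map: ", paste(absent, collapse = ", "))
  freqs <- vapply(need, function(sp) allele_freqs(t, sp_members[[sp]]),
                  numeric(n_sites(t)))
  p4 <- rowMeans(freqs[, roles$outgroup, drop = FALSE])
  out <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    p1 <- freqs[, trios$P1[i]]
    p2 <- freqs[, trios$P2[i]]
    p3 <- freqs[, trios$P3[i]]
    sums <- pattern_sums(p1, p2, p3, p4)
    bs <- block_series(p1, p2, p3, p4, blocks = blocks)
    jk <- block_jackknife(bs)
    p3_members <- unlist(sp_members[trios$P3[i]], use.names = FALSE)
    f4 <- if (length(p3_members) >= 1 &&
                2 * length(p3_members) >= 2) {
      sp <- split_freqs_p3(t, p3_members)
      suppressWarnings(f4_ratio(p1, p2, sp$a, sp$b, p4))
    } else NA_real_
    out[[i]] <- data.frame(
      P1 = trios$P1[i], P2 = trios$P2[i], P3 = trios$P3[i],
      BBAA = sums[["BBAA"]], ABBA = sums[["ABBA"]], BABA = sums[["BABA"]],
      D = jk$D, Z = jk$Z, p = jk$p, f4ratio = f4,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Bonferroni filtering of trio results
#'
#' Divides the family-wise alpha by the number of tests and returns the
#' trios below the resulting threshold, tagged by the sign of D (positive:
#' P2-P3 sharing; negative: P1-P3 sharing).
#'
#' @param results data.frame of trio results with a `p` and `D` column.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `threshold` and `significant` (subset data.frame with
#'   an added `direction` column).
#' @export
bonferroni_filter <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) stop("no trio results")
  threshold <- alpha / nrow(results)
  sig <- results[!is.na(results$p) & results$p < threshold, , drop = FALSE]
  sig$direction <- ifelse(sig$D >= 0, "P2-P3", "P1-P3")
  list(threshold = threshold, significant = sig)
}
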
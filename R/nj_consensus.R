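#' Pairwise distance matrices in coordinate windows
#'
#' Splits each chromosome into fixed `window_bp` spans and computes, per
#' window, the matrix of pairwise dosage differences (sum over sites of
#' |g_i - g_j|, so a single fixed difference between homozygotes counts 2;
#' sites missing in a pair are skipped). Empty windows are omitted.
#'
#' @param t a `site_table` (genome-ordered).
#' @param window_bp window size in bp (default 100000).
#' @return object of class `windowed_distances`: a list of elements each
#'   with `chrom`, `start`, `end`, `n_sites` and `dist` (symmetric matrix).
#' @export
window_distances <- function(t, window_bp = 1e5) {
  sn <- samples(t)
  ns <- length(sn)
  out <- list()
  for (ch in unique(t$chrom)) {
    rows <- which(t$chrom == ch)
    win_id <- (t$pos[rows] - 1L) %/% window_bp
    for (wid in unique(win_id)) {
      sel <- rows[win_id == wid]
      d <- t$dosage[sel, , drop = FALSE]
      m <- matrix(0, ns, ns, dimnames = list(sn, sn))
      for (i in seq_len(ns - 1)) {
        for (j in (i + 1):ns) {
          m[i, j] <- m[j, i] <-
            sum(abs(d[, i] - d[, j]), na.rm = TRUE)
        }
      }
      out[[length(out) + 1]] <- list(
        chrom = ch, start = wid * window_bp + 1L,
        end = (wid + 1L) * window_bp, n_sites = length(sel), dist = m)
    }
  }
  structure(out, class = "windowed_distances")
}

#' Canonical neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix: at each step the pair
#' minimising Q(i, j) = (n - 2) d(i, j) - r_i - r_j is joined, with ties
#' broken deterministically at the lowest (row, column) index pair, and the
#' standard branch-length and distance-update formulas applied. NJ is exact
#' on additive distances; negative branch lengths are retained.
#'
#' @param d symmetric distance matrix (>= 3 taxa) with dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  node <- labs # newick fragment per active node
  repeat {
    n <- nrow(d)
    if (n == 3) break
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # deterministic tie-break: smallest row, then smallest column
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", node[i], li, node[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], new_node)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  lu <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lv <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lw <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 node[1], lu, node[2], lv, node[3], lw)
  ape::read.tree(text = txt)
}

#' Genome-wide consensus NJ tree from windowed distances
#'
#' Sums the distance matrices over all windows, builds the NJ tree and
#' roots it on the outgroup.
#'
#' @param wd a [window_distances()] result.
#' @param outgroup sample identifier to root on.
#' @return a rooted `ape::phylo`.
#' @export
consensus_nj <- function(wd, outgroup) {
  stopifnot(length(wd) >= 1)
  total <- Reduce(`+`, lapply(wd, `[[`, "dist"))
  tr <- nj_tree(total)
  if (!outgroup %in% tr$tip.label) stop("outgroup not among samples")
  ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
}

#' Block-bootstrap node support for the consensus NJ tree
#'
#' Resamples windows with replacement, rebuilds the NJ tree per replicate,
#' and scores each internal edge of the consensus tree by the proportion of
#' replicates containing the same leaf bipartition (evaluated as unrooted
#' splits after rooting on the outgroup).
#'
#' @param wd a [window_distances()] result.
#' @param outgroup sample to root on.
#' @param B bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return the rooted consensus `ape::phylo` with node labels set to the
#'   support proportions (also in `attr(, "support")`).
#' @export
bootstrap_support <- function(wd, outgroup, B = 100L, seed = 1L) {
  cons <- consensus_nj(wd, outgroup)
  set.seed(seed)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(length(wd), length(wd), replace = TRUE)
    boots[[b]] <- consensus_nj(wd[idx], outgroup)
  }
  counts <- ape::prop.clades(cons, boots, rooted = FALSE)
  support <- counts / B
  cons$node.label <- ifelse(is.na(support), "",
                            formatC(support, format = "g"))
  attr(cons, "support") <- support
  cons
}
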
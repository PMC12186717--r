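#' Demographic model for the synthetic-data generator
#'
#' A four-population phylogeny (((P1,P2),P3),O) with an optional admixture
#' pulse from P3 into P2. Defaults are scaled to haplochromine cichlid
#' levels: per-site heterozygosity around 0.002 (diploid Ne of 1.43e5 with
#' mu = 3.5e-9), a sister split around 1.5 million generations, and 22
#' chromosomes to match the chromosome-delete jackknife design.
#'
#' @param n named integer vector of diploid sample sizes for P1, P2, P3, O.
#' @param split_gen named numeric vector of split times in generations:
#'   `t12` (P1/P2), `t123` (ancestor/P3), `t_out` (root/outgroup).
#' @param ne diploid effective size; a scalar, or a length-7 vector for
#'   (P1, P2, P3, O, anc12, anc123, root).
#' @param pulse list with `time` (generations, must be < `t12`) and
#'   `f` (admixture fraction in \[0, 1\]) for the P3 -> P2 pulse.
#' @param mu per-site per-generation mutation rate.
#' @param gen_time generation time in years.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param snp_spacing mean spacing between SNPs in bp (tract mode density).
#' @param tract_mean_bp mean introgressed tract length in bp (tract mode).
#' @return a `demography` object.
#' @export
demography <- function(n = c(P1 = 2L, P2 = 2L, P3 = 2L, O = 1L),
                       split_gen = c(t12 = 1.53e6, t123 = 1.72e6,
                                     t_out = 5e6),
                       ne = 1.43e5,
                       pulse = list(time = 1e5, f = 0),
                       mu = MU, gen_time = GEN_TIME,
                       n_chrom = N_CHROM, chrom_length = 1e6,
                       snp_spacing = 250, tract_mean_bp = 5e4) {
  if (length(ne) == 1) ne <- rep(ne, 7)
  stopifnot(length(ne) == 7, all(ne > 0))
  if (!all(c("P1", "P2", "P3", "O") %in% names(n)))
    stop("n must name P1, P2, P3 and O")
  if (!all(c("t12", "t123", "t_out") %in% names(split_gen)))
    stop("split_gen must name t12, t123 and t_out")
  if (!(split_gen["t12"] < split_gen["t123"] &&
          split_gen["t123"] < split_gen["t_out"]))
    stop("need t12 < t123 < t_out")
  if (is.null(pulse$f)) pulse$f <- 0
  if (pulse$f < 0 || pulse$f > 1) stop("pulse fraction must be in [0, 1]")
  if (pulse$f > 0 && !(pulse$time > 0 && pulse$time < split_gen["t12"]))
    stop("pulse time must be younger than the donor/recipient split")
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  structure(list(n = n, split_gen = split_gen, ne = ne, pulse = pulse,
                 mu = mu, gen_time = gen_time, n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, snp_spacing = snp_spacing,
                 tract_mean_bp = tract_mean_bp),
            class = "demography")
}

# haploid leaf layout: per population, 2 lineages per diploid, in order
# P1, P2, P3, O; returns leaf pop codes and diploid sample names
leaf_layout <- function(d) {
  pops <- c(P1 = 0L, P2 = 1L, P3 = 2L, O = 3L)
  leaf_pop <- integer(0)
  sample_names <- character(0)
  sample_pop <- character(0)
  for (p in names(pops)) {
    nd <- d$n[[p]]
    if (nd > 0) {
      leaf_pop <- c(leaf_pop, rep(pops[[p]], 2 * nd))
      nm <- if (p == "O" && nd == 1) "ANC" else paste0(p, "_", seq_len(nd))
      sample_names <- c(sample_names, nm)
      sample_pop <- c(sample_pop, rep(p, nd))
    }
  }
  list(leaf_pop = leaf_pop, sample_names = sample_names,
       sample_pop = sample_pop)
}

sim_truth <- function(d, seed, tracts = NULL, planted = NULL) {
  lay <- if (inherits(d, "demography")) leaf_layout(d) else NULL
  structure(list(
    demography = if (inherits(d, "demography")) d else NULL, seed = seed,
    tracts = if (is.null(tracts))
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), haplotype = character(0),
                 sample = character(0)) else tracts,
    planted = planted,
    sample_map = if (is.null(lay)) NULL else
      data.frame(sample = lay$sample_names,
                 species = lay$sample_pop,
                 group = lay$sample_pop)),
    class = "sim_truth")
}

assemble_table <- function(d, pat, tree_id, positions = NULL,
                           chrom_of_tree = NULL) {
  lay <- leaf_layout(d)
  ns <- length(lay$sample_names)
  dosage <- matrix(0L, nrow(pat), ns,
                   dimnames = list(NULL, lay$sample_names))
  for (j in seq_len(ns))
    dosage[, j] <- pat[, 2 * j - 1] + pat[, 2 * j]
  if (is.null(positions)) {
    # spread sites over chromosomes in contiguous blocks of equal size
    n <- nrow(pat)
    per <- ceiling(n / d$n_chrom)
    chrom_idx <- ceiling(seq_len(n) / per)
    within <- seq_len(n) - (chrom_idx - 1) * per
    spacing <- max(1, floor(d$chrom_length / (per + 1)))
    chrom <- paste0("chr", chrom_idx)
    pos <- as.integer(within * spacing)
  } else {
    chrom <- paste0("chr", chrom_of_tree[tree_id])
    pos <- positions
  }
  site_table(chrom = chrom, pos = pos,
             ref = rep("A", nrow(pat)), alt = rep("G", nrow(pat)),
             dosage = dosage)
}

#' Simulate unlinked site patterns under the four-population model
#'
#' Each site is drawn from an independent coalescent genealogy; with
#' `mode = "conditioned"` every genealogy carries exactly one mutation (a
#' segregating-sites sampler, the natural input for ABBA-BABA statistics),
#' while `mode = "rate"` places Poisson mutation counts at rate `mu` so that
#' per-accessible-site quantities (dxy, heterozygosity) have their model
#' expectations; the accessible length is `n_chrom * chrom_length` and is
#' attached as `attr(, "accessible_length")`.
#'
#' @param d a [demography()].
#' @param n_sites number of segregating sites (conditioned mode).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param mode "conditioned" or "rate".
#' @param genealogies number of independent genealogies in rate mode
#'   (default 50 per chromosome).
#' @return a list with `table` (a [site_table()]) and `truth` (a
#'   `sim_truth` echoing the demography and seed).
#' @export
simulate_site_patterns <- function(d, n_sites = 10000L, seed = 1L,
                                   mode = c("conditioned", "rate"),
                                   genealogies = NULL) {
  stopifnot(inherits(d, "demography"))
  mode <- match.arg(mode)
  set.seed(seed)
  lay <- leaf_layout(d)
  ne8 <- c(d$ne, d$ne[2]) # slot 8: donor-ancestry deme, P2-sized
  if (mode == "conditioned") {
    res <- sim_patterns_cpp(lay$leaf_pop, ne8,
                            d$split_gen[["t12"]], d$split_gen[["t123"]],
                            d$split_gen[["t_out"]],
                            d$pulse$time, d$pulse$f,
                            as.integer(n_sites), -1)
    tab <- assemble_table(d, res$patterns, res$tree)
  } else {
    if (is.null(genealogies)) genealogies <- 50L * d$n_chrom
    genealogies <- as.integer(genealogies)
    L <- d$n_chrom * d$chrom_length
    mu_block <- d$mu * L / genealogies
    res <- sim_patterns_cpp(lay$leaf_pop, ne8,
                            d$split_gen[["t12"]], d$split_gen[["t123"]],
                            d$split_gen[["t_out"]],
                            d$pulse$time, d$pulse$f,
                            genealogies, mu_block)
    per_chrom <- genealogies / d$n_chrom
    chrom_of_tree <- ceiling(seq_len(genealogies) / per_chrom)
    # positions: each genealogy owns an equal slice of its chromosome
    block_len <- floor(d$chrom_length * d$n_chrom / genealogies)
    within_block <- (res$tree - 1) %% per_chrom
    pos <- integer(length(res$tree))
    for (tr in unique(res$tree)) {
      idx <- which(res$tree == tr)
      lo <- within_block[idx[1]] * block_len + 1
      pos[idx] <- sort(sample.int(block_len, length(idx))) + lo - 1L
    }
    keep <- order(chrom_of_tree[res$tree] * (d$chrom_length + 1) + pos)
    tab <- assemble_table(d, res$patterns[keep, , drop = FALSE],
                          res$tree[keep], positions = pos[keep],
                          chrom_of_tree = chrom_of_tree)
    attr(tab, "accessible_length") <- L
  }
  list(table = tab, truth = sim_truth(d, seed))
}

#' Simulate linked data with introgressed ancestry tracts
#'
#' Recipient (P2) haplotypes are mosaics: a fraction of about `f` of each
#' recipient genome lies in donor-derived tracts whose lengths are
#' exponential with mean `tract_mean_bp`. SNPs are placed along each
#' chromosome at density `1/snp_spacing`; each SNP's genealogy is drawn
#' conditional on the local ancestry of the recipient haplotypes (donor
#' tract lineages join P3 at the pulse time). The truth record lists the
#' tract coordinates per recipient haplotype.
#'
#' @param d a [demography()] with `pulse$f` set.
#' @param seed integer seed.
#' @return list with `table` and `truth` (tracts in `truth$tracts`).
#' @export
simulate_tracts <- function(d, seed = 1L) {
  stopifnot(inherits(d, "demography"))
  set.seed(seed)
  lay <- leaf_layout(d)
  f <- d$pulse$f
  rec_leaves <- which(lay$leaf_pop == 1L) # P2 haploid lineages
  hap_names <- paste0(rep(lay$sample_names[lay$sample_pop == "P2"],
                          each = 2), c(".1", ".2"))
  tracts <- list()
  pat_rows <- list()
  pos_all <- integer(0)
  chrom_all <- character(0)
  ne8 <- c(d$ne, d$ne[2])

  for (ch in seq_len(d$n_chrom)) {
    # ancestry tracts per recipient haplotype (stationary two-state process)
    clen <- d$chrom_length
    hap_tracts <- vector("list", length(rec_leaves))
    for (h in seq_along(rec_leaves)) {
      if (f > 0) {
        mean_in <- d$tract_mean_bp
        mean_out <- d$tract_mean_bp * (1 - f) / f
        pos <- 0
        donor <- runif(1) < f
        segs <- NULL
        while (pos < clen) {
          len <- ceiling(rexp(1, 1 / if (donor) mean_in else mean_out))
          if (donor)
            segs <- rbind(segs, c(pos + 1, min(pos + len, clen)))
          pos <- pos + len
          donor <- !donor
        }
        hap_tracts[[h]] <- segs
        if (!is.null(segs))
          tracts[[length(tracts) + 1]] <- data.frame(
            chrom = paste0("chr", ch), start = segs[, 1], end = segs[, 2],
            haplotype = hap_names[h],
            sample = sub("\\.[12]$", "", hap_names[h]))
      }
    }
    n_snp <- max(1L, round(clen / d$snp_spacing))
    snp_pos <- sort(sample.int(clen, n_snp))
    # donor indicator per haplotype per SNP
    donor_ind <- matrix(FALSE, n_snp, length(rec_leaves))
    for (h in seq_along(rec_leaves)) {
      segs <- hap_tracts[[h]]
      if (!is.null(segs)) {
        for (s in seq_len(nrow(segs)))
          donor_ind[snp_pos >= segs[s, 1] & snp_pos <= segs[s, 2], h] <- TRUE
      }
    }
    # group consecutive SNPs sharing an ancestry configuration
    key <- apply(donor_ind, 1, function(r) paste(as.integer(r), collapse = ""))
    r <- rle(key)
    stop_idx <- cumsum(r$lengths)
    start_idx <- stop_idx - r$lengths + 1
    for (g in seq_along(r$lengths)) {
      idx <- start_idx[g]:stop_idx[g]
      lp <- lay$leaf_pop
      lp[rec_leaves[donor_ind[idx[1], ]]] <- 7L
      res <- sim_patterns_cpp(lp, ne8,
                              d$split_gen[["t12"]], d$split_gen[["t123"]],
                              d$split_gen[["t_out"]],
                              d$pulse$time, 0, length(idx), -1)
      pat_rows[[length(pat_rows) + 1]] <- res$patterns
      pos_all <- c(pos_all, snp_pos[idx])
      chrom_all <- c(chrom_all, rep(paste0("chr", ch), length(idx)))
    }
  }
  pat <- do.call(rbind, pat_rows)
  lay_ns <- length(lay$sample_names)
  dosage <- matrix(0L, nrow(pat), lay_ns,
                   dimnames = list(NULL, lay$sample_names))
  for (j in seq_len(lay_ns))
    dosage[, j] <- pat[, 2 * j - 1] + pat[, 2 * j]
  tab <- site_table(chrom = chrom_all, pos = pos_all,
                    ref = rep("A", nrow(pat)), alt = rep("G", nrow(pat)),
                    dosage = dosage)
  tr <- if (length(tracts)) do.call(rbind, tracts) else NULL
  list(table = tab, truth = sim_truth(d, seed, tracts = tr))
}

#' Plant filter-failing annotations into a site table
#'
#' Gives every site a passing annotation profile, then makes the requested
#' numbers of sites violate exactly one named rule each (disjoint site
#' sets). The truth records which sites were planted for which rule, for
#' testing [apply_site_filters()].
#'
#' @param t a `site_table` (any existing annotations are replaced).
#' @param spec named integer vector with any of `mq`, `mq0`, `strand`,
#'   `exhet`, `miss`, `depth`, `allele_balance`.
#' @param seed integer seed.
#' @return list with `table` (annotated) and `truth` (planted sites per rule
#'   in `truth$planted`).
#' @export
plant_filter_failures <- function(t, spec, seed = 1L) {
  set.seed(seed)
  n <- n_sites(t)
  ns <- length(samples(t))
  spec <- spec[spec > 0]
  if (sum(spec) > n) stop("more planted failures than sites")
  bad <- setdiff(names(spec),
                 c("mq", "mq0", "strand", "exhet", "miss", "depth",
                   "allele_balance"))
  if (length(bad)) stop("unknown rules: ", paste(bad, collapse = ", "))

  # deterministic passing baseline so planted sites violate exactly one rule
  t$anno <- data.frame(
    mq = rep(60, n), mq0f = rep(0.01, n), strand_p = rep(0.5, n),
    exhet_p = rep(0.9, n), dp = rep(20 * ns, n),
    miss = rowMeans(is.na(t$dosage)))
  t$ad_ref <- matrix(ifelse(is.na(t$dosage) | t$dosage == 2L, 0L, 10L),
                     n, ns, dimnames = dimnames(t$dosage))
  t$ad_ref[is.na(t$dosage)] <- NA_integer_
  t$ad_alt <- matrix(ifelse(t$dosage == 0L, 0L, 10L), n, ns,
                     dimnames = dimnames(t$dosage))
  t$ad_ref[which(t$dosage == 0L)] <- 20L
  t$ad_ref[which(t$dosage == 1L)] <- 10L
  t$ad_alt[which(t$dosage == 2L)] <- 20L
  t$ad_alt[which(t$dosage == 1L)] <- 10L

  chosen <- sample.int(n, sum(spec))
  planted <- list()
  offset <- 0
  for (rule in names(spec)) {
    idx <- chosen[(offset + 1):(offset + spec[[rule]])]
    offset <- offset + spec[[rule]]
    switch(rule,
      mq = { t$anno$mq[idx] <- 40 },
      mq0 = { t$anno$mq0f[idx] <- 0.25 },
      strand = { t$anno$strand_p[idx] <- 1e-5 },
      exhet = { t$anno$exhet_p[idx] <- 0.05 },
      miss = {
        k <- ceiling(MISS_MAX * ns) + 1L
        for (i in idx) {
          t$dosage[i, seq_len(min(k, ns))] <- NA_integer_
          t$ad_ref[i, seq_len(min(k, ns))] <- NA_integer_
          t$ad_alt[i, seq_len(min(k, ns))] <- NA_integer_
        }
        t$anno$miss <- rowMeans(is.na(t$dosage))
      },
      depth = { t$anno$dp[idx] <- round(10 * mean(t$anno$dp)) },
      allele_balance = {
        for (i in idx) {
          j <- which(!is.na(t$dosage[i, ]))[1]
          t$dosage[i, j] <- 1L
          t$ad_ref[i, j] <- 19L
          t$ad_alt[i, j] <- 1L
        }
        t$anno$miss <- rowMeans(is.na(t$dosage))
      })
    planted[[rule]] <- data.frame(chrom = t$chrom[idx], pos = t$pos[idx])
  }
  list(table = t, truth = sim_truth(attr(t, "demography"), seed,
                                    planted = planted))
}
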
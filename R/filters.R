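#' Site-filter parameters
#'
#' Defaults follow standard short-read QC practice for dense SNP callsets:
#' drop sites with overall mapping quality below 50, more than 10% MQ0
#' reads, strand-differential mapping quality (p < 0.001), excess
#' heterozygosity (p < 0.2), more than 20% missing genotypes, total depth
#' above the genome mean by more than 1.5 standard deviations, or a
#' heterozygous genotype whose allele balance fails a binomial test at PHRED
#' score > 20; finally, any site lying between two removed sites no more
#' than 10 bp apart is also removed.
#'
#' @param mq_min minimum overall mapping quality.
#' @param mq0_max maximum fraction of MQ0 reads.
#' @param strand_p_min sites with strand-MQ p below this are removed.
#' @param exhet_p_min sites with excess-het p below this are removed.
#' @param miss_max maximum missing-genotype fraction.
#' @param depth_sd multiplier k in the high-depth cutoff mean + k * SD.
#' @param depth_cutoff explicit depth cutoff; if NA (default) it is derived
#'   from the data as mean + `depth_sd` * SD of per-site total depth. Fixing
#'   it makes filtering exactly idempotent.
#' @param ab_phred_max heterozygous allele-balance PHRED cutoff
#'   (-10 log10 of the two-sided binomial p at rate 0.5).
#' @param ab_rule "any": remove the site if any heterozygous genotype fails;
#'   "majority": remove it only if more than half fail.
#' @param proximity_bp two removed sites at most this many bp apart drag
#'   every intervening site with them (single pass, non-transitive).
#' @return a `filter_params` list.
#' @export
filter_params <- function(mq_min = MQ_MIN, mq0_max = MQ0_MAX,
                          strand_p_min = STRAND_P_MIN,
                          exhet_p_min = EXHET_P_MIN,
                          miss_max = MISS_MAX,
                          depth_sd = DEPTH_SD, depth_cutoff = NA_real_,
                          ab_phred_max = AB_PHRED_MAX,
                          ab_rule = c("any", "majority"),
                          proximity_bp = PROXIMITY_BP) {
  structure(list(mq_min = mq_min, mq0_max = mq0_max,
                 strand_p_min = strand_p_min, exhet_p_min = exhet_p_min,
                 miss_max = miss_max, depth_sd = depth_sd,
                 depth_cutoff = depth_cutoff,
                 ab_phred_max = ab_phred_max,
                 ab_rule = match.arg(ab_rule),
                 proximity_bp = proximity_bp),
            class = "filter_params")
}

# PHRED score of the two-sided exact binomial test at rate 0.5.
ab_phred <- function(k, n) {
  m <- pmin(k, n - k)
  p <- ifelse(n == 0, 1, pmin(1, 2 * pbinom(m, n, 0.5)))
  p[which(k * 2 == n)] <- 1
  -10 * log10(p)
}

#' Apply the per-site quality filters
#'
#' Runs every enabled rule (rules whose annotations are absent are skipped
#' and logged), removes failing sites, then applies the proximity rule: for
#' any two rule-removed sites within `proximity_bp` of each other on the
#' same chromosome, all intervening sites are also removed.
#'
#' @param t a `site_table` with annotations.
#' @param params a [filter_params()] object.
#' @return a list with elements `table` (the filtered `site_table`) and
#'   `log` (a `filter_log`: per-rule removal counts and positions, the depth
#'   cutoff used, and the skipped rules).
#' @export
apply_site_filters <- function(t, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  n <- n_sites(t)
  a <- t$anno
  fail <- list()
  skipped <- character(0)
  has <- function(col) !is.null(a) && col %in% names(a) && !all(is.na(a[[col]]))

  rule <- function(name, cond_fn, col) {
    if (has(col)) {
      v <- cond_fn(a[[col]])
      v[is.na(v)] <- FALSE
      fail[[name]] <<- v
    } else skipped <<- c(skipped, name)
  }
  rule("mq", function(v) v < params$mq_min, "mq")
  rule("mq0", function(v) v > params$mq0_max, "mq0f")
  rule("strand", function(v) v < params$strand_p_min, "strand_p")
  rule("exhet", function(v) v < params$exhet_p_min, "exhet_p")
  rule("miss", function(v) v > params$miss_max, "miss")

  depth_cutoff <- NA_real_
  if (has("dp")) {
    if (any(a$dp < 0, na.rm = TRUE)) stop("negative depths")
    depth_cutoff <- if (is.na(params$depth_cutoff))
      mean(a$dp, na.rm = TRUE) + params$depth_sd * sd(a$dp, na.rm = TRUE)
    else params$depth_cutoff
    v <- a$dp > depth_cutoff
    v[is.na(v)] <- FALSE
    fail[["depth"]] <- v
  } else skipped <- c(skipped, "depth")

  if (!is.null(t$ad_ref) && !is.null(t$ad_alt)) {
    if (any(t$ad_ref < 0, na.rm = TRUE) || any(t$ad_alt < 0, na.rm = TRUE))
      stop("negative allele depths")
    het <- !is.na(t$dosage) & t$dosage == 1L
    k <- t$ad_alt
    nn <- t$ad_ref + t$ad_alt
    ph <- ab_phred(as.vector(k), as.vector(nn))
    ph <- matrix(ph, nrow = n)
    bad <- het & !is.na(ph) & ph > params$ab_phred_max
    v <- if (params$ab_rule == "any") rowSums(bad) > 0
      else rowSums(bad) > rowSums(het & !is.na(ph)) / 2
    fail[["allele_balance"]] <- v
  } else skipped <- c(skipped, "allele_balance")

  removed <- Reduce(`|`, fail, init = rep(FALSE, n))

  # proximity rule: a single pass over the rule-removed sites
  prox <- rep(FALSE, n)
  for (ch in unique(t$chrom)) {
    on_ch <- which(t$chrom == ch)
    rem_pos <- sort(t$pos[on_ch][removed[on_ch]])
    if (length(rem_pos) >= 2) {
      d <- diff(rem_pos)
      for (j in which(d <= params$proximity_bp & d > 1)) {
        between <- on_ch[t$pos[on_ch] > rem_pos[j] &
                           t$pos[on_ch] < rem_pos[j + 1]]
        prox[between] <- TRUE
      }
    }
  }
  prox <- prox & !removed
  fail[["proximity"]] <- prox
  removed <- removed | prox

  log <- structure(list(
    counts = vapply(fail, sum, integer(1)),
    positions = lapply(fail, function(v)
      data.frame(chrom = t$chrom[v], pos = t$pos[v])),
    n_in = n, n_out = sum(!removed),
    n_removed = sum(removed),
    depth_cutoff = depth_cutoff,
    skipped = skipped), class = "filter_log")

  list(table = subset_sites(t, !removed), log = log)
}

#' @export
#' @method print filter_log
print.filter_log <- function(x, ...) {
  cat(sprintf("filter_log: %d -> %d sites (%d removed)\n",
              x$n_in, x$n_out, x$n_removed))
  for (nm in names(x$counts))
    cat(sprintf("  %-15s %d\n", nm, x$counts[[nm]]))
  if (!is.na(x$depth_cutoff))
    cat(sprintf("  depth cutoff used: %.2f\n", x$depth_cutoff))
  if (length(x$skipped))
    cat("  skipped (no annotation):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a filter log as TSV
#' @param log a `filter_log`.
#' @param path output path.
#' @export
write_filter_log <- function(log, path) {
  df <- data.frame(rule = names(log$counts),
                   removed = unname(log$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
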
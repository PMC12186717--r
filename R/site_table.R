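#' Per-site genotype table
#'
#' The universal substrate of the package: biallelic SNP sites with per-sample
#' alternate (or, after [polarize()], derived) allele dosages and optional
#' per-site annotations used by the quality filters.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @param dosage integer matrix (sites x samples) with entries 0, 1, 2 or NA
#'   (missing); column names are sample identifiers.
#' @param anno optional data.frame of per-site annotations with any of the
#'   columns `mq` (mapping quality), `mq0f` (fraction of MQ0 reads),
#'   `strand_p` (strand-MQ test p-value), `exhet_p` (excess-heterozygosity
#'   p-value), `dp` (total depth), `miss` (missing-genotype fraction).
#' @param ad_ref,ad_alt optional integer matrices (sites x samples) of
#'   per-sample reference/alternate allele depths.
#'
#' @return An object of class `site_table`.
#' @export
site_table <- function(chrom, pos, ref, alt, dosage,
                       anno = NULL, ad_ref = NULL, ad_alt = NULL) {
  n <- length(pos)
  dosage <- as.matrix(dosage)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(dosage) == n)
  if (is.null(colnames(dosage)))
    stop("dosage must carry sample names as column names")
  ok <- is.na(dosage) | dosage %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  ord_ok <- tapply(pos, chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok)))
    stop("positions must be strictly increasing within each chromosome")
  if (!is.null(anno)) {
    anno <- as.data.frame(anno)
    stopifnot(nrow(anno) == n)
  }
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         dosage = dosage, anno = anno,
         ad_ref = ad_ref, ad_alt = ad_alt,
         polarized = FALSE, outgroup = NULL, outgroup_state = NULL),
    class = "site_table")
}

#' @export
#' @method print site_table
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites, %d samples, %d chromosome(s)%s\n",
              n_sites(x), length(samples(x)), length(unique(x$chrom)),
              if (isTRUE(x$polarized))
                sprintf(", polarized on '%s'", x$outgroup) else ""))
  invisible(x)
}

#' Number of sites in a site table
#' @param t a `site_table`.
#' @export
n_sites <- function(t) length(t$pos)

#' Sample identifiers of a site table
#' @param t a `site_table`.
#' @export
samples <- function(t) colnames(t$dosage)

# Row subset preserving all parallel fields.
subset_sites <- function(t, idx) {
  t$chrom <- t$chrom[idx]
  t$pos <- t$pos[idx]
  t$ref <- t$ref[idx]
  t$alt <- t$alt[idx]
  t$dosage <- t$dosage[idx, , drop = FALSE]
  if (!is.null(t$anno)) t$anno <- t$anno[idx, , drop = FALSE]
  if (!is.null(t$ad_ref)) t$ad_ref <- t$ad_ref[idx, , drop = FALSE]
  if (!is.null(t$ad_alt)) t$ad_alt <- t$ad_alt[idx, , drop = FALSE]
  if (!is.null(t$outgroup_state)) t$outgroup_state <- t$outgroup_state[idx]
  t
}

#' Remove sites falling inside masked regions
#'
#' Drops every site whose position lies within any interval of the mask
#' (1-based, inclusive at both ends), e.g. large chromosomal inversions that
#' would otherwise distort genome-wide statistics.
#'
#' @param t a `site_table`.
#' @param mask a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), as returned by [read_region_mask()]. May have zero rows.
#' @return the filtered `site_table`.
#' @export
mask_regions <- function(t, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(t)
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  drop <- rep(FALSE, n_sites(t))
  for (i in seq_len(nrow(mask))) {
    drop <- drop | (t$chrom == mask$chrom[i] &
                      t$pos >= mask$start[i] & t$pos <= mask$end[i])
  }
  subset_sites(t, !drop)
}

#' Polarize dosages against an outgroup sample
#'
#' Recodes dosages so that they count derived alleles: at sites where the
#' outgroup (typically a reconstructed ancestral-state sample) is homozygous
#' for the alternate allele, dosages are flipped (d -> 2 - d). Sites where
#' the outgroup is heterozygous or missing are kept and flagged; downstream
#' statistics use the outgroup frequency (0.5 at heterozygous sites, NA at
#' missing sites, which excludes the site).
#'
#' @param t a `site_table`.
#' @param outgroup sample identifier of the outgroup column.
#' @return the polarized `site_table` with fields `polarized`, `outgroup` and
#'   `outgroup_state` ("hom", "het" or "missing") set.
#' @export
polarize <- function(t, outgroup) {
  if (!outgroup %in% samples(t))
    stop(sprintf("outgroup sample '%s' not present", outgroup))
  og <- t$dosage[, outgroup]
  flip <- !is.na(og) & og == 2L
  t$dosage[flip, ] <- 2L - t$dosage[flip, , drop = FALSE]
  t$outgroup_state <- ifelse(is.na(og), "missing",
                             ifelse(og == 1L, "het", "hom"))
  t$polarized <- TRUE
  t$outgroup <- outgroup
  t
}

#' Per-site derived/alternate allele frequencies for a set of samples
#'
#' The frequency at each site is the dosage sum divided by twice the number
#' of non-missing members; sites at which every member is missing get NA.
#'
#' @param t a `site_table`.
#' @param members character vector of sample identifiers (non-empty).
#' @return numeric vector of per-site frequencies in \[0, 1\] or NA.
#' @export
allele_freqs <- function(t, members) {
  if (length(members) == 0) stop("members must be non-empty")
  missing <- setdiff(members, samples(t))
  if (length(missing))
    stop("samples not present: ", paste(missing, collapse = ", "))
  d <- t$dosage[, members, drop = FALSE]
  num <- rowSums(d, na.rm = TRUE)
  den <- 2 * rowSums(!is.na(d))
  ifelse(den == 0, NA_real_, num / den)
}

#' Read a sample-to-species-to-group map
#'
#' @param path a 3-column TSV with a header (`sample`, `species`, `group`).
#' @return a data.frame with those columns.
#' @export
read_sample_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "species", "group") %in% names(m)))
  if (anyDuplicated(m$sample)) stop("duplicate sample in map")
  sp2g <- unique(m[, c("species", "group")])
  if (anyDuplicated(sp2g$species))
    stop("every species must map to exactly one group")
  m
}

#' Read a BED-like region mask
#'
#' @param path TSV with columns chrom, start, end (no header).
#' @param one_based if TRUE (default) intervals are taken as printed,
#'   1-based and inclusive at both ends; if FALSE they are standard BED
#'   (0-based, half-open) and are converted.
#' @return normalized data.frame (chrom, start, end), overlapping intervals
#'   merged within each chromosome.
#' @export
read_region_mask <- function(path, one_based = TRUE) {
  m <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end"))
  if (!one_based) {
    m$start <- m$start + 1L
  }
  normalize_mask(m)
}

normalize_mask <- function(m) {
  out <- do.call(rbind, lapply(split(m, m$chrom), function(mm) {
    mm <- mm[order(mm$start), , drop = FALSE]
    merged <- mm[1, , drop = FALSE]
    if (nrow(mm) > 1) {
      for (i in 2:nrow(mm)) {
        last <- nrow(merged)
        if (mm$start[i] <= merged$end[last] + 1L) {
          merged$end[last] <- max(merged$end[last], mm$end[i])
        } else {
          merged <- rbind(merged, mm[i, , drop = FALSE])
        }
      }
    }
    merged
  }))
  rownames(out) <- NULL
  out
}
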
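#' Read a multi-sample VCF into a site table
#'
#' Parses a (optionally gzipped) VCF with vcfR, keeps only biallelic SNP
#' records (multiallelic sites and indels are dropped and counted), extracts
#' per-sample alternate-allele dosages with missing genotypes preserved, and
#' collects the per-site annotations used by [apply_site_filters()].
#'
#' @param path path to the VCF file.
#' @param samples optional character vector restricting the sample columns;
#'   requesting an absent sample is an error.
#' @param info_map named character vector mapping annotation slots to INFO
#'   tags. Defaults to the BCFtools tags `MQ`, `MQ0F`, `MQSB` (strand-MQ
#'   test), `ExcHet` and `DP`. Absent tags yield NA columns and the
#'   corresponding filter rules are skipped (and logged).
#' @return a [site_table()]; the number of dropped non-biallelic-SNP records
#'   is available as `attr(x, "dropped_records")`.
#' @export
read_vcf <- function(path, samples = NULL,
                     info_map = c(mq = "MQ", mq0f = "MQ0F",
                                  strand_p = "MQSB", exhet_p = "ExcHet",
                                  dp = "DP")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  nuc <- c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- !is.na(alt) & ref %in% nuc & alt %in% nuc
  dropped <- sum(!keep)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  all_samples <- colnames(gt)
  if (is.null(samples)) samples <- all_samples
  absent <- setdiff(samples, all_samples)
  if (length(absent))
    stop("requested samples absent from VCF: ",
         paste(absent, collapse = ", "))
  gt <- gt[keep, samples, drop = FALSE]

  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dosage <- (a1 == "1") + (a2 == "1")
  dosage[a1 == "." | a2 == "." | is.na(gt) | a2 == ""] <- NA
  mode(dosage) <- "integer"
  dimnames(dosage) <- list(NULL, samples)

  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad) && !all(is.na(ad))) {
    if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1,
                                       dimnames = list(NULL, names(ad)))
    ad <- ad[keep, samples, drop = FALSE]
    ad_ref <- suppressWarnings(
      matrix(as.integer(sub(",.*", "", ad)), nrow = nrow(ad),
             dimnames = list(NULL, samples)))
    second <- vapply(strsplit(as.character(ad), ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1))
    ad_alt <- matrix(suppressWarnings(as.integer(second)), nrow = nrow(ad),
                     dimnames = list(NULL, samples))
  }

  info_num <- function(tag) {
    v <- tryCatch(vcfR::extract.info(vcf, element = tag),
                  error = function(e) rep(NA_character_, nrow(fix)))
    if (is.null(v)) v <- rep(NA_character_, nrow(fix))
    suppressWarnings(as.numeric(v))[keep]
  }
  anno <- data.frame(
    mq = info_num(info_map[["mq"]]),
    mq0f = info_num(info_map[["mq0f"]]),
    strand_p = info_num(info_map[["strand_p"]]),
    exhet_p = info_num(info_map[["exhet_p"]]),
    dp = info_num(info_map[["dp"]]))
  anno$miss <- rowMeans(is.na(dosage))

  out <- site_table(chrom = fix[keep, "CHROM"],
                    pos = as.integer(fix[keep, "POS"]),
                    ref = ref[keep], alt = alt[keep],
                    dosage = dosage, anno = anno,
                    ad_ref = ad_ref, ad_alt = ad_alt)
  attr(out, "dropped_records") <- dropped
  out
}

#' Write a site table as a VCF text file
#'
#' Emits a minimal VCF 4.2 with the annotation INFO tags and GT/AD FORMAT
#' fields that [read_vcf()] consumes, so simulated data can round-trip
#' through the standard format.
#'
#' @param t a `site_table`.
#' @param path output path (plain text).
#' @export
write_site_vcf <- function(t, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=introgrescan",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of MQ0 reads\">",
    "##INFO=<ID=MQSB,Number=1,Type=Float,Description=\"Strand-MQ test p-value\">",
    "##INFO=<ID=ExcHet,Number=1,Type=Float,Description=\"Excess het p-value\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples(t)), collapse = "\t")), con)
  n <- n_sites(t)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  a <- t$anno
  info <- if (is.null(a)) rep(".", n) else {
    fmt <- function(tag, v) ifelse(is.na(v), NA, paste0(tag, "=", v))
    parts <- cbind(fmt("MQ", a$mq), fmt("MQ0F", a$mq0f),
                   fmt("MQSB", a$strand_p), fmt("ExcHet", a$exhet_p),
                   fmt("DP", a$dp))
    apply(parts, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) paste(r, collapse = ";") else "."
    })
  }
  has_ad <- !is.null(t$ad_ref) && !is.null(t$ad_alt)
  for (i in seq_len(n)) {
    g <- gt_code[as.character(t$dosage[i, ])]
    g[is.na(g)] <- "./."
    if (has_ad) {
      ad <- paste0(ifelse(is.na(t$ad_ref[i, ]), ".", t$ad_ref[i, ]), ",",
                   ifelse(is.na(t$ad_alt[i, ]), ".", t$ad_alt[i, ]))
      g <- paste(g, ad, sep = ":")
      fmt <- "GT:AD"
    } else fmt <- "GT"
    writeLines(paste(c(t$chrom[i], t$pos[i], ".", t$ref[i], t$alt[i], ".",
                       "PASS", info[i], fmt, g), collapse = "\t"), con)
  }
  invisible(path)
}
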
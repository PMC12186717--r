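test_that("read_vcf keeps biallelic SNPs, preserves missing and counts drops", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(path)
  t <- read_vcf(path)
  # 7 records, 1 multiallelic + 1 indel dropped
  expect_equal(n_sites(t), 5)
  expect_equal(attr(t, "dropped_records"), 2)
  expect_equal(samples(t), c("sA", "sB", "sC"))
  expect_equal(unname(t$dosage[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(t$dosage[3, "sA"]))       # ./. genotype
  expect_equal(t$anno$mq, c(60, 55, 58, 61, 59))
  expect_true(is.na(t$anno$mq0f[3]))          # absent tag -> NA
  expect_equal(unname(t$ad_alt[1, "sB"]), 10L)
  expect_error(read_vcf(path, samples = "nope"), "absent")
})

test_that("a site table round-trips through the VCF writer", {
  d <- demography(n = c(P1 = 1L, P2 = 1L, P3 = 1L, O = 1L), n_chrom = 1L)
  t0 <- simulate_site_patterns(d, n_sites = 40, seed = 2)$table
  t0 <- plant_filter_failures(t0, c(mq = 3), seed = 2)$table
  path <- withr::local_tempfile(fileext = ".vcf")
  write_site_vcf(t0, path)
  t1 <- read_vcf(path)
  expect_equal(t1$dosage, t0$dosage)
  expect_equal(t1$pos, t0$pos)
  expect_equal(t1$anno$mq, t0$anno$mq)
  expect_equal(t1$anno$dp, t0$anno$dp)
})

test_that("single-rule failures are removed and logged", {
  anno <- data.frame(mq = c(49, 60, 60), mq0f = 0.01, strand_p = 0.5,
                     exhet_p = 0.9, dp = 30, miss = 0)
  t <- make_table(cbind(c(0, 1, 2), c(2, 1, 0)), anno = anno)
  res <- apply_site_filters(t, filter_params(depth_cutoff = 100))
  expect_equal(n_sites(res$table), 2)
  expect_equal(unname(res$log$counts[["mq"]]), 1)
  expect_equal(res$log$positions$mq$pos, 100L)
  # all-passing input is untouched and the log is all zeros
  anno$mq <- 60
  t2 <- make_table(cbind(c(0, 1, 2), c(2, 1, 0)), anno = anno)
  res2 <- apply_site_filters(t2, filter_params(depth_cutoff = 100))
  expect_equal(res2$table$pos, t2$pos)
  expect_true(all(res2$log$counts == 0))
  expect_equal(res2$log$n_removed, res2$log$n_in - res2$log$n_out)
})

test_that("proximity rule removes sites between nearby removed sites", {
  anno <- data.frame(mq = c(40, 60, 40, 60), mq0f = 0.01, strand_p = 0.5,
                     exhet_p = 0.9, dp = 30, miss = 0)
  t <- make_table(matrix(1, 4, 2), pos = c(100L, 103L, 105L, 300L),
                  anno = anno)
  res <- apply_site_filters(t, filter_params(depth_cutoff = 100))
  # 100 and 105 fail MQ (5 bp apart); 103 is dragged along; 300 survives
  expect_equal(res$table$pos, 300L)
  expect_equal(unname(res$log$counts[["proximity"]]), 1)
  expect_equal(res$log$positions$proximity$pos, 103L)
})

test_that("high-depth outliers are removed by the mean + k*SD rule", {
  anno <- data.frame(mq = 60, mq0f = 0.01, strand_p = 0.5, exhet_p = 0.9,
                     dp = c(10, 10, 10, 10, 100), miss = 0)
  t <- make_table(matrix(1, 5, 2), anno = anno)
  res <- apply_site_filters(t)
  expect_equal(unname(res$log$counts[["depth"]]), 1)
  expect_equal(res$table$anno$dp, rep(10, 4))
  # cutoff derivable by hand: mean 28, SD via either divisor keeps 10s only
  expect_gt(res$log$depth_cutoff, 10)
  expect_lt(res$log$depth_cutoff, 100)
  anno$dp[1] <- -5
  t2 <- make_table(matrix(1, 5, 2), anno = anno)
  expect_error(apply_site_filters(t2), "negative")
})

test_that("allele-balance PHRED rule removes biased heterozygous sites", {
  dos <- cbind(c(1L, 1L), c(0L, 0L))
  adr <- cbind(c(19L, 10L), c(20L, 20L))
  ada <- cbind(c(1L, 10L), c(0L, 0L))
  anno <- data.frame(mq = rep(60, 2), mq0f = 0.01, strand_p = 0.5,
                     exhet_p = 0.9, dp = 40, miss = 0)
  t <- make_table(dos, anno = anno, ad_ref = adr, ad_alt = ada)
  res <- apply_site_filters(t, filter_params(depth_cutoff = 100))
  # 19:1 in a het: two-sided binomial p ~ 4e-5, PHRED ~ 44 > 20 -> removed
  expect_equal(unname(res$log$counts[["allele_balance"]]), 1)
  expect_equal(n_sites(res$table), 1)
})

test_that("filtering is idempotent for a fixed depth cutoff", {
  d <- demography(n_chrom = 2L)
  sim <- simulate_site_patterns(d, n_sites = 400, seed = 9)
  pl <- plant_filter_failures(
    sim$table, c(mq = 5, mq0 = 4, strand = 3, exhet = 3, miss = 3,
                 depth = 3, allele_balance = 3), seed = 9)
  res1 <- apply_site_filters(pl$table)
  params <- filter_params(depth_cutoff = res1$log$depth_cutoff)
  res1b <- apply_site_filters(pl$table, params)
  res2 <- apply_site_filters(res1b$table, params)
  expect_equal(res2$table$pos, res1b$table$pos)
  expect_true(all(res2$log$counts == 0))
})

test_that("masking and filtering commute outside masked regions", {
  d <- demography(n_chrom = 2L)
  sim <- simulate_site_patterns(d, n_sites = 400, seed = 4)
  pl <- plant_filter_failures(sim$table, c(mq = 6, depth = 4), seed = 4)
  params <- filter_params(depth_cutoff = 10 * 20 * length(samples(pl$table)))
  mask <- data.frame(chrom = "chr1", start = 2e5, end = 6e5)
  a <- mask_regions(apply_site_filters(pl$table, params)$table, mask)
  b <- apply_site_filters(mask_regions(pl$table, mask), params)$table
  expect_equal(a$pos, b$pos)
  expect_equal(a$chrom, b$chrom)
})

test_that("region masking uses 1-based inclusive bounds", {
  t <- make_table(matrix(1, 3, 2), chrom = rep("chr2", 3),
                  pos = c(9799999L, 10000000L, 32540001L))
  mask <- data.frame(chrom = "chr2", start = 9800000, end = 32540000)
  out <- mask_regions(t, mask)
  # the paper's chr2 inversion interval: inside removed, boundary kept
  expect_equal(out$pos, c(9799999L, 32540001L))
  expect_equal(mask_regions(t, mask[0, ])$pos, t$pos)
})

test_that("polarization flips outgroup-alt sites and flags het/missing", {
  dos <- cbind(a = c(2L, 0L, 1L, 2L), og = c(2L, 0L, 1L, NA))
  t <- make_table(dos)
  p <- polarize(t, "og")
  expect_equal(unname(p$dosage[, "a"]), c(0L, 0L, 1L, 2L))
  expect_equal(p$outgroup_state, c("hom", "hom", "het", "missing"))
  # the per-site flip is an involution, so re-polarizing is a no-op
  t2 <- make_table(cbind(a = c(2L, 0L), og = c(2L, 0L)))
  p1 <- polarize(t2, "og")
  expect_equal(polarize(p1, "og")$dosage, p1$dosage)
})

test_that("heterozygous outgroup sites enter D via p4 = 0.5", {
  # one site, outgroup het: direct summation of the symmetric formula
  t <- make_table(cbind(p1 = 0L, p2 = 2L, p3 = 2L, og = 1L))
  p <- polarize(t, "og")
  p4 <- allele_freqs(p, "og")
  expect_equal(p4, 0.5)
  s <- pattern_sums(allele_freqs(p, "p1"), allele_freqs(p, "p2"),
                    allele_freqs(p, "p3"), p4)
  expect_equal(unname(s["ABBA"]), (1 - 0) * 1 * 1 * 0.5 + 0)
  expect_equal(unname(s["BABA"]), 0 + (1 - 0) * 1 * (1 - 1) * 0.5)
})

test_that("allele frequencies handle pooling and missingness", {
  t <- make_table(cbind(a = c(1L, 2L, 2L), b = c(1L, 0L, NA),
                        c = c(0L, 0L, 1L)))
  expect_equal(allele_freqs(t, "a"), c(0.5, 1, 1))
  expect_equal(allele_freqs(t, c("a", "b"))[2], 0.5)
  expect_equal(allele_freqs(t, c("a", "b", "c"))[3], 0.75)
  t2 <- make_table(cbind(a = NA_integer_, b = 1L))
  expect_true(is.na(allele_freqs(t2, "a")))
  expect_error(allele_freqs(t, character(0)), "non-empty")
  expect_error(allele_freqs(t, "zz"), "not present")
})

test_that("planted failures are detected by the filters", {
  d <- demography(n = c(P1 = 3L, P2 = 3L, P3 = 3L, O = 1L), n_chrom = 1L)
  sim <- simulate_site_patterns(d, n_sites = 300, seed = 6)
  spec <- c(mq = 7, miss = 5, allele_balance = 4)
  pl <- plant_filter_failures(sim$table, spec, seed = 6)
  expect_equal(vapply(pl$truth$planted, nrow, integer(1)),
               c(mq = 7L, miss = 5L, allele_balance = 4L))
  # missingness planting exceeds the 20% threshold for 10 samples
  miss_pos <- pl$truth$planted$miss$pos
  nmiss <- rowSums(is.na(pl$table$dosage[pl$table$pos %in% miss_pos, ]))
  expect_true(all(nmiss >= ceiling(0.2 * 10) + 1))
  res <- apply_site_filters(pl$table)
  removed_pos <- setdiff(pl$table$pos, res$table$pos)
  for (rule in names(spec))
    expect_true(all(pl$truth$planted[[rule]]$pos %in% removed_pos))
  # the planted sites each fail exactly their own rule
  expect_gte(res$log$n_removed, sum(spec))
  # empty spec leaves the table unchanged
  pl0 <- plant_filter_failures(sim$table, c(mq = 0), seed = 6)
  expect_equal(apply_site_filters(pl0$table)$log$n_removed, 0)
})
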
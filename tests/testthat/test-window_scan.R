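pure_window_table <- function(pat, n = 50) {
  # one diploid per role carrying the requested per-site pattern
  dos <- matrix(rep(pat * 2L, each = n), nrow = n)
  colnames(dos) <- c("P1", "P2", "P3", "OG")
  make_table(dos)
}

test_that("fdM hits its bounds on pure-pattern windows", {
  roles <- list(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "OG")
  w_abba <- fdm_windows(pure_window_table(c(0, 1, 1, 0)), roles)
  expect_equal(w_abba$fdm, 1)
  w_baba <- fdm_windows(pure_window_table(c(1, 0, 1, 0)), roles)
  expect_equal(w_baba$fdm, -1)
  # p1 == p2 everywhere: zero numerator
  dos <- cbind(P1 = rep(1L, 50), P2 = rep(1L, 50),
               P3 = rep(2L, 50), OG = rep(0L, 50))
  w0 <- fdm_windows(make_table(dos), roles)
  expect_equal(w0$fdm, 0)
})

test_that("windowed fdM equals the brute-force site loop", {
  d <- demography(pulse = list(time = 1e5, f = 0.15), n_chrom = 1L)
  t <- polarize(simulate_site_patterns(d, n_sites = 600, seed = 19)$table,
                "ANC")
  roles <- default_roles()
  w <- fdm_windows(t, roles)
  expect_gt(nrow(w), 2)
  fq <- sim_freqs(t, roles)
  ok <- complete.cases(fq$p1, fq$p2, fq$p3, fq$p4)
  inf <- ok & !(fq$p1 == fq$p2 & fq$p2 == fq$p3)
  for (i in seq_len(nrow(w))) {
    sel <- which(inf & t$pos >= w$start[i] & t$pos <= w$end[i])
    expect_equal(length(sel), 50)
    expect_equal(w$fdm[i], bf_fdm(fq$p1[sel], fq$p2[sel], fq$p3[sel],
                                  fq$p4[sel]), tolerance = 1e-12)
  }
  # trailing partial window dropped
  expect_equal(nrow(w), sum(inf) %/% 50)
})

test_that("fdM stays in [-1, 1] and negates under P1/P2 exchange", {
  d <- demography(pulse = list(time = 1e5, f = 0.1), n_chrom = 2L)
  t <- polarize(simulate_site_patterns(d, n_sites = 3000, seed = 23)$table,
                "ANC")
  roles <- default_roles()
  w <- fdm_windows(t, roles)
  expect_true(all(w$fdm >= -1 & w$fdm <= 1, na.rm = TRUE))
  roles_sw <- roles; roles_sw$P1 <- roles$P2; roles_sw$P2 <- roles$P1
  w_sw <- fdm_windows(t, roles_sw)
  expect_equal(w_sw$fdm, -w$fdm, tolerance = 1e-12)
})

test_that("oversize windows are dropped with a strict 20 kb rule", {
  w <- data.frame(chrom = "chr1", start = 1L,
                  end = c(19900L, 20000L, 25000L),
                  n_snps = 50L, span_bp = c(19900L, 20000L, 25000L),
                  fdm = c(0.1, 0.2, 0.3))
  class(w) <- c("window_stats", "data.frame")
  out <- drop_oversize(w)
  expect_equal(out$span_bp, c(19900L, 20000L))
})

test_that("the candidate threshold mirrors the negative tail", {
  vals <- c(rep(-0.08, 10), seq(-0.05, 0.05, length.out = 980),
            rep(0.09, 10))
  rep_ <- candidate_threshold(vals, q = 0.005)
  expect_equal(rep_$threshold, 0.08, tolerance = 1e-9)
  expect_true(all(vals[rep_$candidate] > rep_$threshold))
  expect_equal(rep_$k, sum(vals > rep_$threshold))
  # large normal sample: threshold ~ 2.576 SD and ~0.5% candidates
  set.seed(99)
  z <- rnorm(1e5, sd = 0.04)
  rn <- candidate_threshold(z, q = 0.005)
  expect_equal(rn$threshold / 0.04, qnorm(0.995), tolerance = 0.03)
  expect_equal(rn$percent, 0.5, tolerance = 0.15)
  # an all-positive distribution cannot define a negative-tail threshold
  expect_warning(ap <- candidate_threshold(abs(z) + 0.01, q = 0.005),
                 "positive")
  expect_equal(ap$threshold, 0)
})

test_that("KS diagnostic equals a textbook implementation", {
  set.seed(42)
  x <- rnorm(500)
  ks <- ks_vs_normal(x)
  z <- (x - mean(x)) / sd(x)
  expect_equal(ks$statistic, bf_ks_stat(z), tolerance = 1e-10)
  expect_gt(ks$p, 0.05)
  # a positively skewed mixture exceeds the simulated null's 95th percentile
  set.seed(7)
  null_d <- replicate(200, {
    y <- rnorm(500)
    bf_ks_stat((y - mean(y)) / sd(y))
  })
  mix <- c(rnorm(425), rnorm(75, mean = 2.5))
  ksm <- ks_vs_normal(mix)
  expect_gt(ksm$statistic, quantile(null_d, 0.95))
  expect_gt(ksm$skewness, 0)
  expect_error(ks_vs_normal(rep(1, 50)), "variance")
  expect_error(ks_vs_normal(1:5), "at least 10")
})

test_that("adjacency counts, spectrum and expectation are consistent", {
  w <- data.frame(chrom = rep("chr1", 12), start = 1:12, end = 1:12,
                  n_snps = 50L, span_bp = 1000L, fdm = 0)
  class(w) <- c("window_stats", "data.frame")
  rep_ <- structure(list(threshold = 0.5,
                         candidate = seq_len(12) %in% c(3, 4, 5, 9),
                         N = 12L, k = 4L, percent = 100 * 4 / 12,
                         q = 0.005), class = "candidate_report")
  adj <- adjacency_stats(rep_, w)
  expect_equal(adj$observed, 3L)
  expect_equal(unname(adj$run_lengths["3"]), 1L)
  expect_equal(sum(as.integer(names(adj$run_lengths)) * adj$run_lengths),
               adj$observed)
  expect_equal(adj$expected, 11 * (4 / 12)^2 * 2)
  expect_equal(adj$deviation, adj$observed / adj$expected)
  # adjacency never spans chromosome ends
  w2 <- w; w2$chrom <- rep(c("chr1", "chr2"), each = 6)
  rep2 <- rep_; rep2$candidate <- seq_len(12) %in% c(6, 7)
  rep2$k <- 2L
  adj2 <- adjacency_stats(rep2, w2)
  expect_equal(adj2$observed, 0L)
  # no candidates: flagged undefined deviation
  rep0 <- rep_; rep0$candidate <- rep(FALSE, 12); rep0$k <- 0L
  adj0 <- adjacency_stats(rep0, w)
  expect_true(is.na(adj0$deviation))
  expect_equal(adj0$observed, 0L)
})
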
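test_that("pattern sums match the per-site arithmetic oracle", {
  # pure ABBA site
  expect_equal(pattern_sums(0, 1, 1, 0),
               c(BBAA = 0, ABBA = 1, BABA = 0))
  # p1 == p2 everywhere balances the discordant patterns
  p <- runif(50)
  s <- pattern_sums(p, p, runif(50), 0 * p)
  expect_equal(unname(s["ABBA"]), unname(s["BABA"]))
  # mixed frequencies against the brute-force loop
  p1 <- c(0.2, 0.2, 0.2); p2 <- c(0.8, 0.8, 0.8)
  p3 <- c(0.6, 0.6, 0.6); p4 <- c(0, 0, 0)
  expect_equal(pattern_sums(p1, p2, p3, p4),
               bf_pattern_sums(p1, p2, p3, p4))
  set.seed(8)
  q <- replicate(4, runif(30))
  expect_equal(pattern_sums(q[, 1], q[, 2], q[, 3], q[, 4]),
               bf_pattern_sums(q[, 1], q[, 2], q[, 3], q[, 4]))
  # missing frequencies skip the site; out-of-range errors
  expect_equal(pattern_sums(c(0, NA), c(1, 1), c(1, 1), c(0, 0)),
               c(BBAA = 0, ABBA = 1, BABA = 0))
  expect_error(pattern_sums(1.2, 0.5, 0.5, 0), "\\[0, 1\\]")
})

test_that("Patterson's D follows its closed form", {
  expect_equal(patterson_d(c(ABBA = 30, BABA = 10)), 0.5)
  expect_equal(patterson_d(c(ABBA = 7, BABA = 7)), 0)
  expect_warning(d0 <- patterson_d(c(ABBA = 0, BABA = 0)), "undefined")
  expect_true(is.na(d0))
})

test_that("swapping P1 and P2 negates D and flips the discordant sums", {
  set.seed(3)
  q <- replicate(4, runif(100))
  s <- pattern_sums(q[, 1], q[, 2], q[, 3], q[, 4])
  sw <- pattern_sums(q[, 2], q[, 1], q[, 3], q[, 4])
  expect_equal(unname(sw["ABBA"]), unname(s["BABA"]))
  expect_equal(unname(sw["BABA"]), unname(s["ABBA"]))
  expect_equal(patterson_d(sw), -patterson_d(s))
})

test_that("sites monomorphic across all four taxa change nothing", {
  q <- replicate(4, runif(60))
  s <- pattern_sums(q[, 1], q[, 2], q[, 3], q[, 4])
  add <- function(p, v) c(p, v)
  s2 <- pattern_sums(add(q[, 1], 0.4), add(q[, 2], 0.4),
                     add(q[, 3], 0.4), add(q[, 4], 0.4))
  expect_equal(s2["ABBA"] - s2["BABA"], s["ABBA"] - s["BABA"])
  f <- f4_ratio(q[, 1], q[, 2], q[, 3], q[, 3], q[, 4])
  f2 <- f4_ratio(add(q[, 1], 0.4), add(q[, 2], 0.4), add(q[, 3], 0.4),
                 add(q[, 3], 0.4), add(q[, 4], 0.4))
  expect_equal(f, f2)
})

test_that("the block jackknife matches an independent reimplementation", {
  set.seed(21)
  abba <- rpois(20, 40) + runif(20)
  baba <- rpois(20, 30) + runif(20)
  b <- structure(cbind(abba = abba, baba = baba),
                 class = c("block_series", "matrix"))
  jk <- block_jackknife(b)
  expect_equal(jk$Z, bf_jackknife_z(abba, baba), tolerance = 1e-10)
  expect_equal(jk$p, 2 * pnorm(-abs(jk$Z)))
  # identical blocks: zero SE flagged
  b0 <- structure(cbind(abba = rep(5, 6), baba = rep(3, 6)),
                  class = c("block_series", "matrix"))
  jk0 <- block_jackknife(b0)
  expect_true(jk0$degenerate)
  expect_equal(jk0$p, 0)
  # blocks symmetric around D = 0
  bs <- structure(cbind(abba = c(4, 6, 4, 6), baba = c(6, 4, 6, 4)),
                  class = c("block_series", "matrix"))
  jks <- block_jackknife(bs)
  expect_equal(jks$Z, 0)
})

test_that("f4-ratio endpoints and split invariance hold", {
  set.seed(5)
  p1 <- runif(200); p3 <- runif(200); p4 <- rep(0, 200)
  expect_equal(f4_ratio(p1, p1, p3, p3, p4), 0)
  expect_equal(f4_ratio(p1, p3, p3, p3, p4), 1)
  expect_warning(fna <- f4_ratio(p1, p1, p1, p1, p4), "denominator")
  expect_true(is.na(fna))
  # two random half-splits of the donor sample give close estimates
  d <- demography(pulse = list(time = 1e5, f = 0.15))
  t <- polarize(simulate_site_patterns(d, n_sites = 2e4, seed = 77)$table,
                "ANC")
  fq <- sim_freqs(t)
  set.seed(1); s1 <- split_freqs_p3(t, c("P3_1", "P3_2"))
  set.seed(2); s2 <- split_freqs_p3(t, c("P3_1", "P3_2"))
  f1 <- f4_ratio(fq$p1, fq$p2, s1$a, s1$b, fq$p4)
  f2 <- f4_ratio(fq$p1, fq$p2, s2$a, s2$b, fq$p4)
  expect_lt(abs(f1 - f2), 0.03)
})

test_that("trio enumeration respects roles and guide topology", {
  roles <- list(P1 = c("v1", "v2"), P2 = c("m1", "m2", "m3"),
                P3 = c("o1", "o2"))
  tr <- enumerate_trios(roles = roles)
  expect_equal(nrow(tr), 12)
  expect_error(enumerate_trios(roles = list(P1 = "a", P2 = c("a", "b"),
                                            P3 = "c")), "both")
  # guide-tree mode against an independent cherry check on pruned triples
  tree <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,e:3);")
  got <- enumerate_trios(tree = tree)
  for (i in seq_len(nrow(got))) {
    tri <- ape::keep.tip(tree, unlist(got[i, ]))
    # in the pruned 3-taxon tree, P1 and P2 must share a parent node
    tp <- match(c(got$P1[i], got$P2[i]), tri$tip.label)
    parents <- tri$edge[match(tp, tri$edge[, 2]), 1]
    expect_equal(parents[1], parents[2])
  }
  # brute force count: cherries (a,b), (c,d) plus deeper sister triples
  brute <- 0
  for (comb in utils::combn(tree$tip.label, 3, simplify = FALSE)) {
    tri <- ape::keep.tip(tree, comb)
    in_deg <- table(tri$edge[match(seq_len(3), tri$edge[, 2]), 1])
    if (max(in_deg) == 2) brute <- brute + 2
  }
  expect_equal(nrow(got), brute)
})

test_that("Bonferroni filtering matches hand selection", {
  res <- data.frame(P1 = letters[1:5], P2 = "x", P3 = "y",
                    D = c(0.2, -0.1, 0.05, 0.3, 0),
                    p = c(1e-6, 2e-5, 0.2, 1e-2 / 1000, 0.9))
  bf <- bonferroni_filter(res, alpha = 0.05)
  expect_equal(bf$threshold, 0.01)
  # hand selection: p < 0.01 holds for a (1e-6), b (2e-5) and d (1e-5)
  expect_equal(bf$significant$P1, c("a", "b", "d"))
  expect_equal(bf$significant$direction, c("P2-P3", "P1-P3", "P2-P3"))
  none <- bonferroni_filter(data.frame(D = 0.1, p = 0.5), alpha = 0.05)
  expect_equal(nrow(none$significant), 0)
  expect_equal(bonferroni_filter(res[rep(1, 1000), ], 0.05)$threshold, 5e-5)
})

test_that("dtrios pools species and reports Dsuite-style columns", {
  d <- demography(pulse = list(time = 1e5, f = 0.2))
  sim <- simulate_site_patterns(d, n_sites = 5000, seed = 14)
  t <- polarize(sim$table, "ANC")
  map <- sim$truth$sample_map
  roles <- list(P1 = "P1", P2 = "P2", P3 = "P3", outgroup = "O")
  res <- dtrios(t, map, roles, seed = 14)
  expect_equal(names(res), c("P1", "P2", "P3", "BBAA", "ABBA", "BABA",
                             "D", "Z", "p", "f4ratio"))
  expect_equal(nrow(res), 1)
  expect_gt(res$D, 0)
  expect_lt(res$p, 0.05)
  expect_equal(res$D, (res$ABBA - res$BABA) / (res$ABBA + res$BABA))
})
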
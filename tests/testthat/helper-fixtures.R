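# Fixture builders and independent brute-force oracles used across the suite.

make_table <- function(dosage, chrom = NULL, pos = NULL, anno = NULL,
                       ad_ref = NULL, ad_alt = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("s", seq_len(ncol(dosage)))
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  site_table(chrom = chrom, pos = pos, ref = rep("A", n), alt = rep("G", n),
             dosage = dosage, anno = anno, ad_ref = ad_ref, ad_alt = ad_alt)
}

write_mini_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"MQ0F\">",
    "##INFO=<ID=MQSB,Number=1,Type=Float,Description=\"MQSB\">",
    "##INFO=<ID=ExcHet,Number=1,Type=Float,Description=\"ExcHet\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    "chr1\t100\t.\tA\tG\t.\tPASS\tMQ=60;MQ0F=0;MQSB=0.9;ExcHet=0.8;DP=90\tGT:AD\t0/0:20,0\t0/1:10,10\t1/1:0,20",
    "chr1\t200\t.\tC\tT\t.\tPASS\tMQ=55;MQ0F=0.01;MQSB=0.5;ExcHet=0.9;DP=85\tGT:AD\t0/1:11,9\t0/0:21,0\t0/0:19,0",
    "chr1\t300\t.\tG\tA\t.\tPASS\tMQ=58;DP=88\tGT:AD\t./.:.,.\t1/1:0,18\t0/1:9,11",
    "chr1\t400\t.\tT\tA,C\t.\tPASS\tMQ=60;DP=92\tGT:AD\t1/2:0,9\t0/0:20,0\t0/1:11,9",
    "chr1\t500\t.\tA\tAT\t.\tPASS\tMQ=60;DP=80\tGT:AD\t0/1:9,9\t0/0:18,0\t0/0:20,0",
    "chr2\t150\t.\tG\tC\t.\tPASS\tMQ=61;MQ0F=0;MQSB=0.7;ExcHet=0.7;DP=95\tGT:AD\t1/1:0,22\t0/1:12,8\t0/0:19,0",
    "chr2\t250\t.\tA\tC\t.\tPASS\tMQ=59;MQ0F=0;MQSB=0.6;ExcHet=0.6;DP=87\tGT:AD\t0/0:20,0\t0/0:18,0\t1/1:0,21")
  writeLines(lines, path)
  path
}

# independent per-site arithmetic oracle for pattern sums (scalar loop)
bf_pattern_sums <- function(p1, p2, p3, p4) {
  abba <- baba <- bbaa <- 0
  for (i in seq_along(p1)) {
    if (anyNA(c(p1[i], p2[i], p3[i], p4[i]))) next
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i] * (1 - p4[i]) +
      p1[i] * (1 - p2[i]) * (1 - p3[i]) * p4[i]
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i] * (1 - p4[i]) +
      (1 - p1[i]) * p2[i] * (1 - p3[i]) * p4[i]
    bbaa <- bbaa + p1[i] * p2[i] * (1 - p3[i]) * (1 - p4[i]) +
      (1 - p1[i]) * (1 - p2[i]) * p3[i] * p4[i]
  }
  c(BBAA = bbaa, ABBA = abba, BABA = baba)
}

# independent fdM oracle: scalar site loop with explicit branch logic
bf_fdm <- function(p1, p2, p3, p4) {
  ab <- function(a, b, c, d)
    (1 - a) * b * c * (1 - d) + a * (1 - b) * (1 - c) * d
  ba <- function(a, b, c, d)
    a * (1 - b) * c * (1 - d) + (1 - a) * b * (1 - c) * d
  num <- den <- 0
  for (i in seq_along(p1)) {
    num <- num + ab(p1[i], p2[i], p3[i], p4[i]) -
      ba(p1[i], p2[i], p3[i], p4[i])
    if (p2[i] >= p1[i]) {
      pd <- max(p2[i], p3[i])
      den <- den + ab(p1[i], pd, pd, p4[i]) - ba(p1[i], pd, pd, p4[i])
    } else {
      pd <- max(p1[i], p3[i])
      den <- den - (ab(pd, p2[i], pd, p4[i]) - ba(pd, p2[i], pd, p4[i]))
    }
  }
  num / den
}

# independent delete-one jackknife oracle
bf_jackknife_z <- function(abba_blocks, baba_blocks) {
  m <- length(abba_blocks)
  A <- sum(abba_blocks); B <- sum(baba_blocks)
  D <- (A - B) / (A + B)
  Di <- numeric(m)
  for (i in seq_len(m)) {
    Ai <- A - abba_blocks[i]; Bi <- B - baba_blocks[i]
    Di[i] <- (Ai - Bi) / (Ai + Bi)
  }
  se <- sqrt((m - 1) / m * sum((Di - mean(Di))^2))
  D / se
}

# independent dxy oracle: enumerate all 4 allele pairings per site
bf_dxy <- function(gi, gj, L) {
  tot <- 0
  for (s in seq_along(gi)) {
    if (is.na(gi[s]) || is.na(gj[s])) next
    ai <- c(rep(1, gi[s]), rep(0, 2 - gi[s]))
    aj <- c(rep(1, gj[s]), rep(0, 2 - gj[s]))
    for (u in 1:2) for (v in 1:2) tot <- tot + (ai[u] != aj[v])
  }
  tot / 4 / L
}

# textbook one-sample KS statistic against the standard normal
bf_ks_stat <- function(z) {
  z <- sort(z)
  n <- length(z)
  Fz <- pnorm(z)
  max(pmax(abs(seq_len(n) / n - Fz), abs(Fz - (seq_len(n) - 1) / n)))
}

# windowed dosage-difference distance oracle (site loop)
bf_window_dist <- function(d) {
  ns <- ncol(d)
  m <- matrix(0, ns, ns, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    tot <- 0
    for (s in seq_len(nrow(d)))
      if (!is.na(d[s, i]) && !is.na(d[s, j]))
        tot <- tot + abs(d[s, i] - d[s, j])
    m[i, j] <- tot
  }
  m
}

default_roles <- function() {
  list(P1 = c("P1_1", "P1_2"), P2 = c("P2_1", "P2_2"),
       P3 = c("P3_1", "P3_2"), outgroup = "ANC")
}

sim_freqs <- function(t, roles = default_roles()) {
  list(p1 = allele_freqs(t, roles$P1), p2 = allele_freqs(t, roles$P2),
       p3 = allele_freqs(t, roles$P3), p4 = allele_freqs(t, roles$outgroup))
}
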
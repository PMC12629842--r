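# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: U statistics are computed by pairwise counting
# (not rank sums), cutpoints by a plain loop over candidate thresholds, and
# analytic optima by numeric optimization/integration of the generating
# truncated-Normal densities.

# Pairwise-counting U for sample x against sample y (ties count half).
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exhaustive-enumeration two-sided p: over all assignments of the pooled
# values to the two groups, the fraction whose U is at least as far from the
# null mean as observed.
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  u_obs <- oracle_u(x, y)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(ii) oracle_u(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Hand step-up BH: adj_i = min over j with p_j >= p_i of p_j * n / rank_j.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    min(1, min(p[p >= p[i]] * n / r[p >= p[i]]))
  }, 0)
}

# Exhaustive scan over the shared candidate grid; strict improvement keeps
# the first (highest) threshold on ties.
oracle_cutpoint <- function(pos, neg, strategy, w = 0.4) {
  th <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  best <- -Inf
  bt <- NA_real_
  for (t in th) {
    tp <- sum(pos >= t)
    fp <- sum(neg >= t)
    fn <- length(pos) - tp
    j <- tp / length(pos) - fp / length(neg)
    f1 <- if (tp + fp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    obj <- switch(strategy, youden = j, f1 = f1, weighted = w * j + (1 - w) * f1)
    if (obj > best + 1e-12) {
      best <- obj
      bt <- t
    }
  }
  bt
}

# Truncated-Normal density/CDF on [0, 99] and the analytic optima they imply.
dtnorm <- function(x, mu, s, a = 0, b = 99) {
  ifelse(x < a | x > b, 0, dnorm(x, mu, s) / (pnorm(b, mu, s) - pnorm(a, mu, s)))
}

ptnorm <- function(q, mu, s, a = 0, b = 99) {
  q <- pmin(pmax(q, a), b)
  (pnorm(q, mu, s) - pnorm(a, mu, s)) / (pnorm(b, mu, s) - pnorm(a, mu, s))
}

# t maximizing J(t) = F_benign(t) - F_pathogenic(t) for the rule score >= t.
analytic_youden_optimum <- function(mu_b, s_b, mu_p, s_p) {
  optimize(function(t) ptnorm(t, mu_b, s_b) - ptnorm(t, mu_p, s_p),
           c(0, 99), maximum = TRUE, tol = 1e-8)$maximum
}

# P(pathogenic score > benign score) by numeric integration.
analytic_auc <- function(mu_b, s_b, mu_p, s_p) {
  integrate(function(x) dtnorm(x, mu_b, s_b) * (1 - ptnorm(x, mu_p, s_p)),
            0, 99, rel.tol = 1e-9)$value
}

# Small fixture builders -------------------------------------------------------

# A two-exon coding transcript set used across region-model tests.
fixture_genes <- function(strand = "+") {
  tx <- transcript_model("txA", "geneA", chrom = "chr1", strand = strand,
                         tx_start = 10000, tx_end = 14000,
                         exon_starts = c(10000, 12000),
                         exon_ends = c(10800, 14000),
                         cds_start = 10200, cds_end = 13500)
  nc <- transcript_model("txN", "geneN", chrom = "chr1", strand = strand,
                         tx_start = 30000, tx_end = 33000,
                         exon_starts = c(30000, 32000),
                         exon_ends = c(30400, 33000))
  transcript_models(list(tx, nc))
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Minimal VCF body with the package's INFO keys.
fixture_vcf <- function(records) {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CADD_PHRED,Number=A,Type=Float,Description="score">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="af">',
    '##INFO=<ID=CLASS,Number=A,Type=String,Description="class">',
    '##INFO=<ID=DENOVO,Number=0,Type=Flag,Description="de novo">',
    '##INFO=<ID=REGION,Number=A,Type=String,Description="region">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records), ".vcf")
}
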
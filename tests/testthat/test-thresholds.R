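make_variants <- function(region, clin_class, score, ...) {
  n <- max(length(region), length(clin_class), length(score))
  data.frame(chrom = rep("chr1", n), pos = seq_len(n),
             ref = rep("A", n), alt = rep("T", n),
             score = score, clin_class = clin_class, region = region,
             stringsAsFactors = FALSE, ...)
}

test_that("region summary tallies counts and fractions, with zero rows", {
  v <- make_variants("intronic", rep(c("benign", "pathogenic", "vus"),
                                     c(7, 2, 1)), 1:10)
  s <- summarize_regions(v)
  i <- s[s$region == "intronic", ]
  expect_equal(c(i$n_benign, i$n_pathogenic, i$n_vus), c(7, 2, 1))
  expect_equal(c(i$f_benign, i$f_pathogenic, i$f_vus), c(0.7, 0.2, 0.1))
  expect_equal(sum(s$n_total), 10)
  expect_setequal(s$region, noncoding_regions())

  empty <- summarize_regions(make_variants(character(0), character(0),
                                           numeric(0)))
  expect_true(all(empty$n_total == 0))
})

test_that("synthetic composition matches its spec to binomial accuracy", {
  spec <- synthetic_spec(n_variants = 100000, seed = 7)
  v <- generate_clinvar_like(spec)
  s <- summarize_regions(v)
  n <- spec$n_variants
  for (r in names(spec$region_props)) {
    p <- spec$region_props[[r]]
    obs <- sum(v$region == r) / n
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
})

test_that("threshold derivation: perfect separation and degenerate regions", {
  v <- make_variants("intronic", rep(c("benign", "pathogenic"), each = 4),
                     c(1, 2, 3, 4, 10, 11, 12, 13))
  fit <- region_thresholds(v)
  rec <- fit$records[fit$records$region == "intronic", ]
  expect_equal(rec$threshold, 10)
  expect_equal(rec$auc, 1)
  expect_equal(rec$usable, rec$p_adj < 0.05)  # exact p = 2/70 here
  expect_true(rec$usable)

  # one pathogenic variant < min_n: threshold and p absent, unusable
  v2 <- rbind(v, make_variants("downstream", c("benign", "benign",
                                               "pathogenic"), c(1, 2, 30)))
  rec2 <- region_thresholds(v2)$records
  dn <- rec2[rec2$region == "downstream", ]
  expect_true(is.na(dn$threshold) && is.na(dn$p_raw))
  expect_false(dn$usable)
  # BH family = regions actually tested (1 here, not 9)
  tested <- rec2[!is.na(rec2$p_raw), ]
  expect_equal(nrow(tested), 1)
  expect_equal(tested$p_adj, tested$p_raw)
})

test_that("derived cutpoint and AUC recover the generating distributions", {
  set.seed(11)
  b <- pmin(pmax(rnorm(20000, 8, 4), 0), 99)
  p <- pmin(pmax(rnorm(20000, 22, 5), 0), 99)
  v <- make_variants("utr3", rep(c("benign", "pathogenic"), each = 20000),
                     c(b, p))
  fit <- region_thresholds(v)
  rec <- fit$records[fit$records$region == "utr3", ]
  expect_lt(abs(rec$threshold - analytic_youden_optimum(8, 4, 22, 5)), 0.5)
  expect_lt(abs(rec$auc - analytic_auc(8, 4, 22, 5)), 0.02)
  expect_true(rec$usable)
})

test_that("VUS scores sit between benign and pathogenic on generated data", {
  v <- generate_clinvar_like(synthetic_spec(n_variants = 50000, seed = 5))
  s <- region_score_samples(v)
  for (r in c("intronic", "utr3", "splicing", "utr5")) {
    expect_lte(median(s[[r]]$benign), median(s[[r]]$vus))
    expect_lte(median(s[[r]]$vus), median(s[[r]]$pathogenic))
  }
})

test_that("pairwise pathogenic comparison: symmetry, identity, shifted region", {
  mk <- function(r, scores) list(region = r, benign = numeric(0),
                                 pathogenic = scores, vus = numeric(0))
  a <- seq(1, 30, length.out = 30)
  m <- compare_pathogenic_across_regions(list(mk("intronic", a),
                                              mk("utr3", a),
                                              mk("splicing", a + 30)))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["intronic", "utr3"], 1)           # identical multisets
  expect_lt(m["intronic", "splicing"], 0.001)      # shifted by +30
  expect_lt(m["utr3", "splicing"], 0.001)
  expect_error(compare_pathogenic_across_regions(list(mk("utr3", 1:3))),
               "at least 2 regions")
})

test_that("benign substitution swaps in common variants and excludes pathogenic hits", {
  v <- make_variants(rep("intronic", 4),
                     c("benign", "benign", "pathogenic", "pathogenic"),
                     c(2, 3, 20, 21))
  common <- data.frame(chrom = "chr1", pos = c(100, 101, 3),
                       ref = "A", alt = "T",
                       score = c(5, 6, 99),
                       allele_freq = c(0.2, 0.3, 0.2),
                       region = "intronic", stringsAsFactors = FALSE)
  common$pos[3] <- v$pos[3]  # collide with the first pathogenic variant
  s <- substitute_benign(v, common)
  expect_setequal(s$intronic$benign, c(5, 6))   # colliding variant excluded
  expect_setequal(s$intronic$pathogenic, c(20, 21))

  # af_min = 1 empties every benign list
  s2 <- substitute_benign(v, common, af_min = 1)
  expect_length(s2$intronic$benign, 0)
})

test_that("substituting common variants from the benign distribution barely moves thresholds", {
  v <- generate_clinvar_like(synthetic_spec(n_variants = 40000, seed = 13))
  common <- generate_clinvar_like(synthetic_spec(
    n_variants = 40000, class_props = c(benign = 1, pathogenic = 0, vus = 0),
    seed = 14))
  common$allele_freq <- runif(nrow(common), 0.02, 0.5)
  orig <- derive_thresholds(region_score_samples(v))
  subst <- derive_thresholds(substitute_benign(v, common))
  both <- !is.na(orig$threshold) & !is.na(subst$threshold) &
    orig$n_pathogenic >= 200
  expect_true(any(both))
  expect_true(all(abs(orig$threshold[both] - subst$threshold[both]) < 1))
})

test_that("threshold table export round-trips exactly", {
  v <- generate_clinvar_like(synthetic_spec(n_variants = 5000, seed = 21))
  fit <- region_thresholds(v)
  f <- tempfile(fileext = ".tsv")
  export_threshold_table(fit, f)
  back <- read_threshold_table(f)
  expect_equal(as.data.frame(back), as.data.frame(fit$records),
               ignore_attr = TRUE)

  f2 <- tempfile(fileext = ".tsv")
  export_threshold_table(fit$records[0, ], f2)
  expect_equal(nrow(read_threshold_table(f2)), 0)
})

test_that("packaged defaults carry the nine thresholds and the 5/4 usability split", {
  thr <- default_thresholds()
  expect_equal(unname(thr[noncoding_regions()]),
               c(34, 16.79, 12.76, 25.5, 11.08, 11.44, 3.03, 0.82, 11.0))
  cfg <- default_threshold_config()
  expect_equal(sum(cfg$usable), 5)
  expect_setequal(cfg$region[cfg$usable],
                  c("utr5", "intronic", "splicing", "utr3", "ncRNA_exonic"))
  # upstream is highly significant but its AUC disqualifies it
  up <- cfg[cfg$region == "upstream", ]
  expect_equal(up$significance, "***")
  expect_false(up$usable)
})

test_that("usable flag is exactly (auc > 0.7) and significant, never inverted", {
  expect_true(usable_flag(0.71, "*"))
  expect_false(usable_flag(0.7, "***"))    # strict inequality
  expect_false(usable_flag(0.9, "ns"))
  expect_false(usable_flag(0.347, "***"))  # low AUC reported as-is
  v <- generate_clinvar_like(synthetic_spec(n_variants = 20000, seed = 31))
  rec <- region_thresholds(v)$records
  ok <- !is.na(rec$auc)
  expect_equal(rec$usable[ok],
               rec$auc[ok] > 0.7 & rec$significance[ok] != "ns")
})

test_that("the fit object's methods behave as a model interface", {
  v <- generate_clinvar_like(synthetic_spec(n_variants = 20000, seed = 41))
  fit <- region_thresholds(v)
  expect_s3_class(fit, "region_thresholds")
  expect_named(coef(fit), fit$records$region)
  expect_output(print(fit), "usable")
  expect_output(print(summary(fit)), "Usable regions")
  newv <- make_variants(c("intronic", "intronic", "downstream"),
                        "unknown", c(99, 0, 99))
  pass <- predict(fit, newv)
  expect_true(pass[1])
  expect_false(pass[2])
  thr <- coef(fit)
  if (is.na(thr["downstream"])) expect_false(pass[3])
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
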
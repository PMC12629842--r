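# Region-specific threshold derivation ---------------------------------------

#' Per-region, per-class composition summary
#'
#' Tallies an annotated variant table by region category and clinical class.
#' All nine noncoding categories (plus `"exonic"` when present in the input)
#' appear in the output even with zero counts.
#'
#' @param variants Data frame with `region` and `clin_class` columns
#'   (`clin_class` in benign/pathogenic/vus/unknown).
#' @return Data frame with columns `region`, `n_benign`, `n_pathogenic`,
#'   `n_vus`, `n_total`, and within-region fractions `f_benign`,
#'   `f_pathogenic`, `f_vus`.
#' @export
summarize_regions <- function(variants) {
  regions <- noncoding_regions()
  if (nrow(variants) && "region" %in% names(variants)) {
    assert_region(variants$region)
    if (any(variants$region == "exonic")) regions <- region_levels()
  }
  cnt <- function(region, cls) {
    if (!nrow(variants)) return(0L)
    sum(variants$region == region & variants$clin_class == cls)
  }
  out <- data.frame(
    region = regions,
    n_benign = vapply(regions, cnt, 0L, cls = "benign"),
    n_pathogenic = vapply(regions, cnt, 0L, cls = "pathogenic"),
    n_vus = vapply(regions, cnt, 0L, cls = "vus"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$n_total <- out$n_benign + out$n_pathogenic + out$n_vus
  tot <- ifelse(out$n_total > 0, out$n_total, NA_integer_)
  out$f_benign <- out$n_benign / tot
  out$f_pathogenic <- out$n_pathogenic / tot
  out$f_vus <- out$n_vus / tot
  out
}

#' Split an annotated variant table into per-region score samples
#'
#' @param variants Data frame with `region`, `score` and `clin_class`.
#' @param regions Region categories to include (default: the nine noncoding
#'   categories; `"exonic"` is always excluded from threshold analysis).
#' @return Named list, one element per region, each a list with fields
#'   `region`, `benign`, `pathogenic`, `vus` (numeric score vectors).
#' @export
region_score_samples <- function(variants, regions = noncoding_regions()) {
  stopifnot(all(c("region", "score", "clin_class") %in% names(variants)))
  assert_region(variants$region)
  regions <- setdiff(regions, "exonic")
  out <- lapply(regions, function(r) {
    sel <- variants$region == r
    list(region = r,
         benign = variants$score[sel & variants$clin_class == "benign"],
         pathogenic = variants$score[sel & variants$clin_class == "pathogenic"],
         vus = variants$score[sel & variants$clin_class == "vus"])
  })
  names(out) <- regions
  out
}

# Per-region strategy lookup: `strategy` is a single name or a named vector.
strategy_for <- function(strategy, region) {
  if (length(strategy) == 1L && is.null(names(strategy))) {
    return(unname(strategy))
  }
  if (!is.null(names(strategy)) && region %in% names(strategy)) {
    return(unname(strategy[[region]]))
  }
  "youden"
}

#' Derive per-region thresholds from score samples
#'
#' For every region with at least `min_n` benign and `min_n` pathogenic
#' scores: a two-sided Mann-Whitney U test of benign versus pathogenic, a ROC
#' curve (pathogenic = positive class), and a cutpoint under the region's
#' strategy. Benjamini-Hochberg adjustment is applied across the regions
#' actually tested in this call. A region is `usable` only when its AUC
#' strictly exceeds `auc_usable` and its adjusted significance is not `"ns"`.
#' Regions below `min_n` are reported with absent threshold and p-values and
#' `usable = FALSE`.
#'
#' @param samples List of region score samples as from
#'   [region_score_samples()].
#' @param strategy Cutpoint strategy: `"youden"`, `"f1"` or `"weighted"`, or a
#'   named per-region vector (unnamed regions default to `"youden"`).
#' @param w_youden Weight on Youden's J for the `"weighted"` strategy.
#' @param min_n Minimum benign and pathogenic count per region (default 2).
#' @param auc_usable AUC that must be strictly exceeded (default 0.7).
#' @return Data frame of class `"threshold_records"` with columns `region`,
#'   `threshold`, `p_raw`, `p_adj`, `significance`, `auc`, `usable`,
#'   `n_benign`, `n_pathogenic`, `n_vus`, `strategy`; ROC curves attached as
#'   attribute `"curves"`.
#' @export
derive_thresholds <- function(samples, strategy = "youden", w_youden = 0.4,
                              min_n = 2L, auc_usable = 0.7) {
  stopifnot(length(samples) >= 1)
  regs <- vapply(samples, `[[`, "", "region")
  ord <- order(match(regs, noncoding_regions()))
  samples <- samples[ord]
  regs <- regs[ord]
  n <- length(samples)
  rec <- data.frame(
    region = regs,
    threshold = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
    significance = NA_character_, auc = NA_real_, usable = FALSE,
    n_benign = vapply(samples, function(s) length(s$benign), 0L),
    n_pathogenic = vapply(samples, function(s) length(s$pathogenic), 0L),
    n_vus = vapply(samples, function(s) length(s$vus), 0L),
    strategy = vapply(regs, function(r) strategy_for(strategy, r), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  curves <- setNames(vector("list", n), regs)
  testable <- which(rec$n_benign >= min_n & rec$n_pathogenic >= min_n)
  for (i in testable) {
    s <- samples[[i]]
    rec$p_raw[i] <- mann_whitney_u(s$benign, s$pathogenic)$p
    curves[[i]] <- roc_curve(s$pathogenic, s$benign)
    rec$auc[i] <- curves[[i]]$auc
    cp <- cutpoint_from_curve(curves[[i]], rec$strategy[i], w_youden)
    rec$threshold[i] <- cp$threshold
  }
  if (length(testable)) {
    rec$p_adj[testable] <- bh_fdr(rec$p_raw[testable])
    rec$significance[testable] <- significance_label(rec$p_adj[testable])
    rec$usable[testable] <- usable_flag(rec$auc[testable],
                                        rec$significance[testable],
                                        auc_usable)
  }
  attr(rec, "curves") <- curves
  class(rec) <- c("threshold_records", "data.frame")
  rec
}

#' Usability rule for a region threshold
#'
#' A region's threshold is usable only when the AUC strictly exceeds
#' `auc_usable` and the significance label is not non-significant (`"ns"` /
#' `"n.s."`). An AUC below 0.5 is reported as-is, never inverted, and is
#' therefore unusable.
#'
#' @param auc Numeric AUC value(s).
#' @param significance Significance label(s) as from [significance_label()].
#' @param auc_usable Strict lower bound on AUC (default 0.7).
#' @return Logical vector.
#' @export
usable_flag <- function(auc, significance, auc_usable = 0.7) {
  !is.na(auc) & !is.na(significance) & auc > auc_usable &
    !significance %in% c("ns", "n.s.")
}

# The region_thresholds model object -----------------------------------------

#' Fit region-specific score thresholds to a classified variant table
#'
#' The package's central estimator: from an annotated variant table (columns
#' `region`, `score`, `clin_class`) it derives, per noncoding region, a
#' pathogenic-versus-benign score cutpoint together with a Mann-Whitney U
#' test, FDR-adjusted significance, AUC and a usability flag. All nine
#' noncoding categories are always reported; regions with too few classified
#' variants degrade gracefully to absent thresholds.
#'
#' @param variants Annotated variant table (see [read_variants()] or
#'   [generate_clinvar_like()]); rows with `region == "exonic"` are excluded.
#' @inheritParams derive_thresholds
#' @return Object of class `"region_thresholds"`, with methods [print()],
#'   [summary()], [coef()] (named threshold vector), [predict()] (apply the
#'   thresholds to new variants) and [plot()] (per-region ROC curves).
#' @export
#' @examples
#' spec <- synthetic_spec(n_variants = 3000, seed = 42)
#' cv <- generate_clinvar_like(spec)
#' fit <- region_thresholds(cv)
#' fit
#' coef(fit)
region_thresholds <- function(variants, strategy = "youden", w_youden = 0.4,
                              min_n = 2L, auc_usable = 0.7) {
  samples <- region_score_samples(variants)
  rec <- derive_thresholds(samples, strategy = strategy, w_youden = w_youden,
                           min_n = min_n, auc_usable = auc_usable)
  structure(list(records = rec, curves = attr(rec, "curves"),
                 strategy = strategy, w_youden = w_youden,
                 min_n = min_n, auc_usable = auc_usable,
                 call = match.call()),
            class = "region_thresholds")
}

#' @export
print.region_thresholds <- function(x, ...) {
  cat("Region-specific score thresholds\n\n")
  r <- x$records
  show <- data.frame(region = r$region,
                     threshold = round(r$threshold, 2),
                     p_adj = signif(r$p_adj, 3),
                     significance = r$significance,
                     auc = round(r$auc, 3),
                     usable = r$usable)
  print(show, row.names = FALSE)
  cat("\n", sum(r$usable), " of ", nrow(r),
      " regions usable (AUC > ", x$auc_usable,
      " and FDR-adjusted significance)\n", sep = "")
  invisible(x)
}

#' @export
summary.region_thresholds <- function(object, ...) {
  structure(list(records = as.data.frame(object$records),
                 n_usable = sum(object$records$usable),
                 strategy = object$strategy, call = object$call),
            class = "summary.region_thresholds")
}

#' @export
print.summary.region_thresholds <- function(x, ...) {
  cat("Call: ")
  print(x$call)
  cat("\n")
  print(x$records, row.names = FALSE)
  cat("\nUsable regions:", x$n_usable, "\n")
  invisible(x)
}

#' @export
coef.region_thresholds <- function(object, usable_only = FALSE, ...) {
  r <- object$records
  if (usable_only) r <- r[r$usable, , drop = FALSE]
  setNames(r$threshold, r$region)
}

#' @export
#' @rdname region_thresholds
#' @param object A fitted `region_thresholds` object.
#' @param newdata Annotated variant table with `region` and `score`.
#' @param usable_only Restrict to usable regions (others never pass).
#' @param ... Unused.
predict.region_thresholds <- function(object, newdata, usable_only = FALSE,
                                      ...) {
  thr <- coef(object, usable_only = usable_only)
  stopifnot(all(c("region", "score") %in% names(newdata)))
  t <- thr[newdata$region]
  !is.na(t) & newdata$score >= t
}

#' @export
plot.region_thresholds <- function(x, regions = NULL, ...) {
  curves <- Filter(Negate(is.null), x$curves)
  if (!is.null(regions)) curves <- curves[intersect(names(curves), regions)]
  if (!length(curves)) stop("no ROC curves to plot")
  cols <- hcl.colors(length(curves), "Dark 3")
  first <- TRUE
  for (i in seq_along(curves)) {
    plot(curves[[i]], add = !first, col = cols[i], ...)
    first <- FALSE
  }
  legend("bottomright", bty = "n", col = cols, lty = 1,
         legend = sprintf("%s (AUC %.3f)", names(curves),
                          vapply(curves, `[[`, 0, "auc")))
  invisible(x)
}

# Inter-region comparison and benign substitution -----------------------------

#' Pairwise comparison of pathogenic score distributions across regions
#'
#' Mann-Whitney U tests on every unordered pair of regions' pathogenic
#' scores, Benjamini-Hochberg-adjusted across the pairs. The returned matrix
#' is symmetric with 1 on the diagonal.
#'
#' @param samples Region score samples as from [region_score_samples()];
#'   regions without pathogenic scores are dropped.
#' @return Symmetric matrix of adjusted p-values.
#' @export
compare_pathogenic_across_regions <- function(samples) {
  samples <- Filter(function(s) length(s$pathogenic) >= 1, samples)
  if (length(samples) < 2) stop("need at least 2 regions with pathogenic scores")
  regs <- vapply(samples, `[[`, "", "region")
  k <- length(regs)
  pairs <- combn(k, 2)
  praw <- apply(pairs, 2, function(ij) {
    mann_whitney_u(samples[[ij[1]]]$pathogenic,
                   samples[[ij[2]]]$pathogenic)$p
  })
  padj <- bh_fdr(praw)
  m <- matrix(1, k, k, dimnames = list(regs, regs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]
    j <- pairs[2, c]
    m[i, j] <- m[j, i] <- padj[c]
  }
  m
}

#' Replace ClinVar-style benign scores with population common variants
#'
#' Rebuilds per-region score samples in which the benign side comes from
#' common variants (`allele_freq > af_min`) instead of clinically classified
#' benign entries; common variants that coincide with a pathogenic variant in
#' `variants` (same chrom, pos, ref, alt) are excluded. Pathogenic and VUS
#' lists are unchanged. Regions losing all benign scores are retained with an
#' empty benign list and will come out unusable from [derive_thresholds()].
#'
#' @param variants Annotated, classified variant table (must carry `chrom`,
#'   `pos`, `ref`, `alt`, `region`, `score`, `clin_class`).
#' @param common Annotated variant table of population variants with
#'   `allele_freq`, `region` and `score`.
#' @param af_min Allele-frequency cutoff defining "common" (strict >,
#'   default 0.01).
#' @return Named list of region score samples.
#' @export
substitute_benign <- function(variants, common, af_min = 0.01) {
  samples <- region_score_samples(variants)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  path_keys <- key(variants[variants$clin_class == "pathogenic", ,
                            drop = FALSE])
  af <- common$allele_freq
  af[is.na(af)] <- 0
  keep <- af > af_min & !key(common) %in% path_keys
  common <- common[keep, , drop = FALSE]
  for (r in names(samples)) {
    samples[[r]]$benign <- common$score[common$region == r]
  }
  samples
}

# Table-style export ----------------------------------------------------------

#' Export threshold records as a report-style TSV
#'
#' Columns: region, threshold, p_raw, p_adj, significance, auc, usable,
#' n_benign, n_pathogenic, n_vus, strategy; regions in the canonical report
#' order. Numeric fields are written with full double precision so the table
#' round-trips exactly through [read_threshold_table()].
#'
#' @param records A `threshold_records` data frame or `region_thresholds` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_threshold_table <- function(records, path) {
  if (inherits(records, "region_thresholds")) records <- records$records
  cols <- c("region", "threshold", "p_raw", "p_adj", "significance", "auc",
            "usable", "n_benign", "n_pathogenic", "n_vus", "strategy")
  stopifnot(all(cols %in% names(records)))
  records <- records[order(match(records$region, noncoding_regions())), cols]
  fmt <- function(v) {
    if (is.double(v)) ifelse(is.na(v), "NA", sprintf("%.17g", v))
    else as.character(v)
  }
  body <- do.call(paste, c(lapply(records, fmt), sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Read back a threshold table written by [export_threshold_table()]
#'
#' @param path TSV path.
#' @return A `threshold_records` data frame (without ROC curves).
#' @export
read_threshold_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(region = "character",
                                  significance = "character",
                                  strategy = "character"))
  df$usable <- as.logical(df$usable)
  class(df) <- c("threshold_records", "data.frame")
  df
}

# Packaged default thresholds --------------------------------------------------

#' Packaged default region thresholds
#'
#' The default per-region threshold configuration shipped with the package
#' (derived from a large ClinVar-scale analysis of CADD v1.7 Phred scores):
#' upstream 34, 5' UTR 16.79, intronic 12.76, splicing 25.5, 3' UTR 11.08,
#' ncRNA exonic 11.44, ncRNA intronic 3.03, downstream 0.82, intergenic 11.
#' Only five of the nine regions are flagged usable (AUC > 0.7 and
#' significant); the remaining thresholds are reported for completeness and
#' should be used with caution.
#'
#' @return `default_thresholds()`: named numeric vector of the nine
#'   thresholds. `default_threshold_config()`: full data frame with
#'   `threshold`, `p`, `significance`, `auc` and the derived `usable` flag.
#' @export
default_thresholds <- function() {
  cfg <- default_threshold_config()
  setNames(cfg$threshold, cfg$region)
}

#' @rdname default_thresholds
#' @export
default_threshold_config <- function() {
  path <- system.file("extdata", "default_thresholds.json",
                      package = "caddregions", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- as.data.frame(raw$regions, stringsAsFactors = FALSE)
  cfg$usable <- usable_flag(cfg$auc, cfg$significance)
  cfg[order(match(cfg$region, noncoding_regions())), , drop = FALSE]
}
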
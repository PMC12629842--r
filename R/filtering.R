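# WGS filtering cascade ------------------------------------------------------

#' Filtering configuration
#'
#' @param thresholds Named numeric map region -> score threshold (default:
#'   [default_thresholds()]), or a fitted [region_thresholds()] object.
#'   Variants in regions absent from the map never pass the threshold stage.
#' @param af_max Allele-frequency rarity cutoff, strict `<` (default 0.01);
#'   absent frequencies count as 0 (novel variants are rare).
#' @param require_de_novo Restrict the final set to de novo variants.
#' @param strategy `"fixed_thresholds"` (the cascade of [filter_variants()])
#'   or `"region_median"` (the per-region median split of
#'   [region_median_filter()]).
#' @return Object of class `"filter_config"`.
#' @export
filter_config <- function(thresholds = default_thresholds(), af_max = 0.01,
                          require_de_novo = FALSE,
                          strategy = c("fixed_thresholds", "region_median")) {
  strategy <- match.arg(strategy)
  if (inherits(thresholds, "region_thresholds")) {
    thresholds <- coef(thresholds)
    thresholds <- thresholds[!is.na(thresholds)]
  }
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)),
            all(thresholds >= 0), af_max > 0, af_max <= 1)
  assert_region(names(thresholds))
  structure(list(thresholds = thresholds, af_max = af_max,
                 require_de_novo = isTRUE(require_de_novo),
                 strategy = strategy),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config> strategy=", x$strategy, ", af_max=", x$af_max,
      ", require_de_novo=", x$require_de_novo, "\n", sep = "")
  print(round(x$thresholds, 2))
  invisible(x)
}

new_filter_report <- function(n_input, n_noncoding, n_rare,
                              n_passing_threshold, n_de_novo, n_final,
                              per_region_passing) {
  structure(list(n_input = n_input, n_noncoding = n_noncoding,
                 n_rare = n_rare, n_passing_threshold = n_passing_threshold,
                 n_de_novo = n_de_novo, n_final = n_final,
                 per_region_passing = per_region_passing),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n",
      "  input:             ", x$n_input, "\n",
      "  noncoding:         ", x$n_noncoding, "\n",
      "  rare:              ", x$n_rare, "\n",
      "  passing threshold: ", x$n_passing_threshold, "\n",
      if (!is.na(x$n_de_novo)) paste0("  de novo:           ",
                                      x$n_de_novo, "\n"),
      "  final:             ", x$n_final, "\n", sep = "")
  invisible(x)
}

#' Filter a WGS-scale variant set through the region-threshold cascade
#'
#' Cascade order: drop coding-exonic variants, keep rare variants
#' (`allele_freq < af_max`, absent frequency treated as 0), keep variants
#' scoring at or above their region's threshold (regions without a configured
#' threshold fail), then optionally keep only de novo variants. The report
#' tallies attrition at every stage; `per_region_passing` counts the
#' threshold-stage survivors per region.
#'
#' @param variants Annotated variant table with `region`, `score` and
#'   (optionally) `allele_freq`; a logical `de_novo` column is required only
#'   when the config demands it.
#' @param cfg A [filter_config()].
#' @return List with `variants` (the surviving rows) and `report`
#'   (a `filter_report`).
#' @export
#' @examples
#' cfg <- filter_config(require_de_novo = FALSE)
#' wgs <- generate_trio_wgs(n_variants = 2000, seed = 3)
#' res <- filter_variants(wgs, cfg)
#' res$report
filter_variants <- function(variants, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"),
            all(c("region", "score") %in% names(variants)))
  assert_region(variants$region)
  n_input <- nrow(variants)
  v <- variants[variants$region != "exonic", , drop = FALSE]
  n_noncoding <- nrow(v)
  af <- if ("allele_freq" %in% names(v)) v$allele_freq else rep(NA_real_, nrow(v))
  af[is.na(af)] <- 0
  v <- v[af < cfg$af_max, , drop = FALSE]
  n_rare <- nrow(v)
  thr <- cfg$thresholds[v$region]
  v <- v[!is.na(thr) & v$score >= thr, , drop = FALSE]
  n_pass <- nrow(v)
  per_region <- table(factor(v$region, levels = noncoding_regions()))
  n_de_novo <- NA_integer_
  if (cfg$require_de_novo) {
    if (nrow(variants) &&
        (!"de_novo" %in% names(variants) || all(is.na(variants$de_novo)))) {
      stop("no de novo annotation")
    }
    v <- v[!is.na(v$de_novo) & v$de_novo, , drop = FALSE]
    n_de_novo <- nrow(v)
  }
  list(variants = v,
       report = new_filter_report(n_input, n_noncoding, n_rare, n_pass,
                                  n_de_novo, nrow(v),
                                  as.integer(per_region) |>
                                    setNames(names(per_region))))
}

#' Region-median score filter
#'
#' The comparator strategy: within each region represented in the input,
#' retain variants scoring at or above that region's median score (median of
#' the input itself; even-sized medians are the mean of the two central
#' values). By construction at least half of each region's variants survive.
#'
#' @param variants Annotated variant table with `region` and `score`.
#' @return List with `variants` and `report` as in [filter_variants()]
#'   (no-op stages carry the input count).
#' @export
region_median_filter <- function(variants) {
  stopifnot(all(c("region", "score") %in% names(variants)))
  n_input <- nrow(variants)
  keep <- logical(n_input)
  for (r in unique(variants$region)) {
    sel <- variants$region == r
    keep[sel] <- variants$score[sel] >= median(variants$score[sel])
  }
  v <- variants[keep, , drop = FALSE]
  per_region <- table(factor(v$region, levels = unique(variants$region)))
  list(variants = v,
       report = new_filter_report(n_input, n_input, n_input, nrow(v),
                                  NA_integer_, nrow(v),
                                  as.integer(per_region) |>
                                    setNames(names(per_region))))
}
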
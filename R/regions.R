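# Region vocabulary --------------------------------------------------------

#' The nine noncoding region categories
#'
#' Closed vocabulary of the noncoding genomic categories used throughout the
#' package, in the canonical report order. `"exonic"` (coding exon) is a valid
#' classification result but is excluded from all threshold analyses.
#'
#' @return Character vector of the nine noncoding category names.
#' @export
#' @examples
#' noncoding_regions()
noncoding_regions <- function() {
  c("upstream", "utr5", "intronic", "splicing", "utr3",
    "ncRNA_exonic", "ncRNA_intronic", "downstream", "intergenic")
}

#' All region categories including exonic
#' @return Character vector: the nine noncoding categories plus `"exonic"`.
#' @export
region_levels <- function() c(noncoding_regions(), "exonic")

# Precedence used when overlapping transcripts label one position differently;
# smaller rank wins. Splicing/exonic and utr5/utr3 are tied tiers in gene-based
# annotation; within a tier the order below is the deterministic tie-break
# (splicing over exonic keeps the variant in an analyzed category, utr5 over
# utr3, upstream over downstream).
region_precedence <- function() {
  c(splicing = 1, exonic = 2, ncRNA_exonic = 3, utr5 = 4, utr3 = 5,
    intronic = 6, ncRNA_intronic = 7, upstream = 8, downstream = 9,
    intergenic = 10)
}

assert_region <- function(x) {
  bad <- setdiff(unique(x), region_levels())
  if (length(bad)) {
    stop("unknown region categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
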
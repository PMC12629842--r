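# Nine-category noncoding classification -------------------------------------

# Label of `pos` relative to one transcript, or NA when the position falls
# outside the transcript and its strand-oriented up/downstream windows.
classify_in_tx <- function(pos, strand, tx_start, tx_end, ex_s, ex_e,
                           is_coding, cds_start, cds_end,
                           upstream_bp, downstream_bp, splice_bp) {
  if (pos < tx_start) {
    d <- tx_start - pos
    if (strand == "+") {
      if (d <= upstream_bp) return("upstream")
    } else if (d <= downstream_bp) return("downstream")
    return(NA_character_)
  }
  if (pos > tx_end) {
    d <- pos - tx_end
    if (strand == "+") {
      if (d <= downstream_bp) return("downstream")
    } else if (d <= upstream_bp) return("upstream")
    return(NA_character_)
  }
  in_exon <- any(ex_s <= pos & pos <= ex_e)
  if (!is_coding) return(if (in_exon) "ncRNA_exonic" else "ncRNA_intronic")
  if (in_exon) {
    if (pos >= cds_start && pos <= cds_end) return("exonic")
    if (pos < cds_start) return(if (strand == "+") "utr5" else "utr3")
    return(if (strand == "+") "utr3" else "utr5")
  }
  # intron of a coding transcript; splice window is intron-side only
  prev_end <- max(ex_e[ex_e < pos])
  next_start <- min(ex_s[ex_s > pos])
  if (min(pos - prev_end, next_start - pos) <= splice_bp) "splicing"
  else "intronic"
}

#' Classify variant positions into noncoding region categories
#'
#' Assigns each position exactly one of the nine noncoding categories or
#' `"exonic"`, following gene-based annotation conventions: upstream and
#' downstream are the strand-oriented windows of `upstream_bp` /
#' `downstream_bp` bases beyond the transcription start and end sites;
#' splicing means intronic bases within `splice_bp` of an exon-intron junction
#' of a coding transcript; UTRs are exon positions outside the CDS, 5' or 3'
#' relative to strand; exon/intron positions of transcripts without a CDS are
#' ncRNA exonic/intronic; everything else is intergenic. Indels are anchored
#' at their leftmost position (`pos`).
#'
#' When overlapping transcripts disagree, a fixed precedence resolves the
#' label (splicing, exonic, ncRNA exonic, 5' UTR, 3' UTR, intronic, ncRNA
#' intronic, upstream, downstream, intergenic), so the result is independent
#' of transcript order. Positions on chromosomes absent from the gene model
#' are intergenic, with a warning.
#'
#' @param variants Data frame with at least `chrom` and `pos` columns
#'   (1-based position of the first REF base).
#' @param genes A [transcript_models()] set.
#' @param upstream_bp,downstream_bp Window sizes in bp (default 1000).
#' @param splice_bp Splice-junction window in bp (default 2).
#' @return Character vector of region categories, one per row of `variants`.
#' @seealso [annotate_regions()] to attach the result as a `region` column.
#' @export
#' @examples
#' tx <- transcript_model("tx1", chrom = "chr1", strand = "+",
#'                        tx_start = 2000, tx_end = 4000,
#'                        exon_starts = c(2000, 3000), exon_ends = c(2400, 4000),
#'                        cds_start = 2100, cds_end = 3800)
#' genes <- transcript_models(list(tx))
#' classify_variants(data.frame(chrom = "chr1", pos = c(1500, 2402, 2700)), genes)
classify_variants <- function(variants, genes, upstream_bp = 1000,
                              downstream_bp = 1000, splice_bp = 2) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos") %in% names(variants)),
            inherits(genes, "transcript_models"))
  if (nrow(variants) && any(variants$pos < 1)) stop("pos must be >= 1")
  tab <- genes$table
  prec <- region_precedence()
  win <- max(upstream_bp, downstream_bp)
  out <- rep("intergenic", nrow(variants))
  absent <- setdiff(unique(variants$chrom), unique(tab$chrom))
  if (length(absent)) {
    warning("chromosome(s) absent from gene model, classified intergenic: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  for (ch in intersect(unique(variants$chrom), tab$chrom)) {
    ti <- which(tab$chrom == ch)
    s <- tab$tx_start[ti]
    e <- tab$tx_end[ti]
    strand <- tab$strand[ti]
    coding <- tab$is_coding[ti]
    cs <- tab$cds_start[ti]
    ce <- tab$cds_end[ti]
    exs <- genes$exon_starts[ti]
    exe <- genes$exon_ends[ti]
    for (v in which(variants$chrom == ch)) {
      pos <- variants$pos[v]
      cand <- which(s - win <= pos & pos <= e + win)
      best <- prec[["intergenic"]]
      lab <- "intergenic"
      for (k in cand) {
        l <- classify_in_tx(pos, strand[k], s[k], e[k], exs[[k]], exe[[k]],
                            coding[k], cs[k], ce[k],
                            upstream_bp, downstream_bp, splice_bp)
        if (!is.na(l) && prec[[l]] < best) {
          best <- prec[[l]]
          lab <- l
        }
      }
      out[v] <- lab
    }
  }
  out
}

#' Classify a single variant
#'
#' @param v One-row data frame or list with `chrom` and `pos`.
#' @inheritParams classify_variants
#' @return A single region category string.
#' @export
classify_variant <- function(v, genes, upstream_bp = 1000,
                             downstream_bp = 1000, splice_bp = 2) {
  classify_variants(data.frame(chrom = v$chrom[1], pos = v$pos[1]),
                    genes, upstream_bp, downstream_bp, splice_bp)[1]
}

#' Annotate a variant table with region categories
#'
#' @inheritParams classify_variants
#' @return `variants` with a `region` column added (or replaced).
#' @export
annotate_regions <- function(variants, genes, upstream_bp = 1000,
                             downstream_bp = 1000, splice_bp = 2) {
  variants$region <- classify_variants(variants, genes, upstream_bp,
                                       downstream_bp, splice_bp)
  variants
}
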
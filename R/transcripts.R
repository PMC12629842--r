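# Transcript models ---------------------------------------------------------

#' Construct a transcript model
#'
#' A transcript model carries the stranded geometry needed for nine-category
#' noncoding classification: transcript bounds, exon bounds and, for coding
#' transcripts, CDS bounds. All coordinates are 1-based inclusive genomic
#' positions (VCF/GTF convention). A transcript without CDS bounds is
#' noncoding (`is_coding = FALSE`).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start,tx_end Transcript bounds, 1-based inclusive.
#' @param exon_starts,exon_ends Integer vectors of exon bounds (same length,
#'   sorted, non-overlapping, within the transcript bounds).
#' @param cds_start,cds_end CDS bounds or `NA` for noncoding transcripts.
#' @return A list of class `"transcript_model"`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id, chrom,
                             strand, tx_start, tx_end, exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  tx <- list(transcript_id = as.character(transcript_id),
             gene_id = as.character(gene_id),
             chrom = as.character(chrom),
             strand = as.character(strand),
             tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
             exon_starts = as.integer(exon_starts),
             exon_ends = as.integer(exon_ends),
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
  tx$is_coding <- !is.na(tx$cds_start) && !is.na(tx$cds_end)
  class(tx) <- "transcript_model"
  validate_transcript_model(tx)
  tx
}

validate_transcript_model <- function(tx) {
  if (!tx$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (tx$tx_start > tx$tx_end) stop("tx_start > tx_end for ", tx$transcript_id)
  n <- length(tx$exon_starts)
  if (n < 1L || n != length(tx$exon_ends)) {
    stop("exon bounds malformed for ", tx$transcript_id)
  }
  if (any(tx$exon_starts > tx$exon_ends)) {
    stop("exon start > end in ", tx$transcript_id)
  }
  if (is.unsorted(tx$exon_starts, strictly = TRUE) ||
      any(tx$exon_starts[-1] <= tx$exon_ends[-n])) {
    stop("exons must be sorted and non-overlapping in ", tx$transcript_id)
  }
  if (tx$exon_starts[1] < tx$tx_start || tx$exon_ends[n] > tx$tx_end) {
    stop("exons extend outside transcript bounds in ", tx$transcript_id)
  }
  if (tx$is_coding) {
    if (tx$cds_start > tx$cds_end) stop("CDS start > end in ", tx$transcript_id)
    if (tx$cds_start < tx$exon_starts[1] || tx$cds_end > tx$exon_ends[n]) {
      stop("CDS outside exon span in ", tx$transcript_id)
    }
  }
  invisible(tx)
}

#' Bundle transcript models into an indexed set
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `"transcript_models"` with a flat lookup table
#'   (`$table`) and parallel exon-bound list columns, indexed for fast
#'   per-chromosome interval queries.
#' @export
transcript_models <- function(transcripts) {
  stopifnot(length(transcripts) >= 1)
  for (tx in transcripts) validate_transcript_model(tx)
  tab <- data.frame(
    transcript_id = vapply(transcripts, `[[`, "", "transcript_id"),
    gene_id = vapply(transcripts, `[[`, "", "gene_id"),
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    strand = vapply(transcripts, `[[`, "", "strand"),
    tx_start = vapply(transcripts, `[[`, 0L, "tx_start"),
    tx_end = vapply(transcripts, `[[`, 0L, "tx_end"),
    cds_start = vapply(transcripts, `[[`, NA_integer_, "cds_start"),
    cds_end = vapply(transcripts, `[[`, NA_integer_, "cds_end"),
    is_coding = vapply(transcripts, `[[`, TRUE, "is_coding"),
    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 exon_starts = lapply(transcripts, `[[`, "exon_starts"),
                 exon_ends = lapply(transcripts, `[[`, "exon_ends")),
            class = "transcript_models")
}

#' @export
length.transcript_models <- function(x) nrow(x$table)

#' @export
print.transcript_models <- function(x, ...) {
  tab <- x$table
  cat("<transcript_models> ", nrow(tab), " transcripts (",
      sum(tab$is_coding), " coding, ", sum(!tab$is_coding), " noncoding) on ",
      length(unique(tab$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

# Gene-model readers ---------------------------------------------------------

#' Load a gene model from GTF or a refGene-like TSV
#'
#' GTF records of feature type `transcript`, `exon` and `CDS` are assembled
#' per `transcript_id`; a transcript with no CDS record is noncoding. The
#' refGene dialect is the bin-less tab-separated layout
#' (name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount,
#' exonStarts, exonEnds), 0-based half-open on disk and converted to 1-based
#' inclusive at parse; `cdsStart == cdsEnd` marks a noncoding transcript.
#'
#' Malformed records raise an error naming the offending line. A transcript
#' whose CDS falls outside its exon span is rejected with a warning and the
#' remaining transcripts are kept.
#'
#' @param path File path.
#' @param format `"gtf"` or `"refgene_tsv"`.
#' @return A [transcript_models()] set.
#' @export
load_gene_model <- function(path, format = c("gtf", "refgene_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  switch(format,
         gtf = load_gene_model_gtf(path),
         refgene_tsv = load_gene_model_refgene(path))
}

gtf_attr <- function(attrs, key) {
  pat <- paste0(key, ' "([^"]*)"')
  out <- rep(NA_character_, length(attrs))
  has <- grepl(pat, attrs)
  out[has] <- sub(paste0(".*", key, ' "([^"]*)".*'), "\\1", attrs[has])
  out
}

load_gene_model_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in GTF: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    stop("malformed GTF record at line ", lineno[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields")
  }
  rec <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    feature = vapply(parts, `[[`, "", 3L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 5L))),
    strand = vapply(parts, `[[`, "", 7L),
    attrs = vapply(parts, `[[`, "", 9L),
    line = lineno, stringsAsFactors = FALSE)
  bad <- which(is.na(rec$start) | is.na(rec$end))
  if (length(bad)) {
    stop("malformed GTF record at line ", rec$line[bad[1]],
         ": non-numeric coordinates")
  }
  bad <- which(rec$end < rec$start)
  if (length(bad)) {
    stop("malformed GTF record at line ", rec$line[bad[1]], ": end < start")
  }
  rec$tx_id <- gtf_attr(rec$attrs, "transcript_id")
  rec$gene_id <- gtf_attr(rec$attrs, "gene_id")
  rec <- rec[rec$feature %in% c("transcript", "exon", "CDS"), , drop = FALSE]
  bad <- which(is.na(rec$tx_id))
  if (length(bad)) {
    stop("malformed GTF record at line ", rec$line[bad[1]],
         ": missing transcript_id attribute")
  }
  out <- list()
  for (id in unique(rec$tx_id)) {
    r <- rec[rec$tx_id == id, , drop = FALSE]
    ex <- r[r$feature == "exon", , drop = FALSE]
    if (!nrow(ex)) {
      warning("transcript ", id, " has no exon records; skipped")
      next
    }
    o <- order(ex$start)
    cds <- r[r$feature == "CDS", , drop = FALSE]
    txr <- r[r$feature == "transcript", , drop = FALSE]
    tx_start <- if (nrow(txr)) txr$start[1] else min(ex$start)
    tx_end <- if (nrow(txr)) txr$end[1] else max(ex$end)
    tx <- tryCatch(
      transcript_model(
        transcript_id = id,
        gene_id = if (!is.na(r$gene_id[1])) r$gene_id[1] else id,
        chrom = r$chrom[1], strand = r$strand[1],
        tx_start = tx_start, tx_end = tx_end,
        exon_starts = ex$start[o], exon_ends = ex$end[o],
        cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
        cds_end = if (nrow(cds)) max(cds$end) else NA_integer_),
      error = function(e) {
        warning("rejected transcript ", id, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(tx)) out[[length(out) + 1L]] <- tx
  }
  if (!length(out)) stop("no valid transcripts in ", path)
  transcript_models(out)
}

load_gene_model_refgene <- function(path) {
  cols <- c("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
            "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 10L) stop("refGene table needs 10 columns, got ", ncol(df))
  names(df)[1:10] <- cols
  out <- list()
  for (i in seq_len(nrow(df))) {
    es <- suppressWarnings(as.integer(strsplit(df$exonStarts[i], ",")[[1]]))
    ee <- suppressWarnings(as.integer(strsplit(df$exonEnds[i], ",")[[1]]))
    if (anyNA(es) || anyNA(ee) || length(es) != df$exonCount[i]) {
      stop("malformed refGene record at line ", i, ": exon bounds")
    }
    coding <- df$cdsStart[i] < df$cdsEnd[i]
    tx <- tryCatch(
      transcript_model(
        transcript_id = df$name[i], chrom = df$chrom[i],
        strand = df$strand[i],
        tx_start = df$txStart[i] + 1L, tx_end = df$txEnd[i],
        exon_starts = es + 1L, exon_ends = ee,
        cds_start = if (coding) df$cdsStart[i] + 1L else NA_integer_,
        cds_end = if (coding) df$cdsEnd[i] else NA_integer_),
      error = function(e) {
        warning("rejected transcript ", df$name[i], " (line ", i, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(tx)) out[[length(out) + 1L]] <- tx
  }
  if (!length(out)) stop("no valid transcripts in ", path)
  transcript_models(out)
}

#' Write a transcript set as GTF
#'
#' Inverse of [load_gene_model()] for the GTF dialect (feature types
#' transcript/exon/CDS); used to materialize synthetic gene models.
#'
#' @param genes A [transcript_models()] set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(genes, path) {
  stopifnot(inherits(genes, "transcript_models"))
  tab <- genes$table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  for (i in seq_len(nrow(tab))) {
    at <- sprintf('gene_id "%s"; transcript_id "%s";',
                  tab$gene_id[i], tab$transcript_id[i])
    put <- function(feature, s, e) {
      writeLines(sprintf("%s\tcaddregions\t%s\t%d\t%d\t.\t%s\t.\t%s",
                         tab$chrom[i], feature, s, e, tab$strand[i], at), con)
    }
    put("transcript", tab$tx_start[i], tab$tx_end[i])
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    for (j in seq_along(es)) put("exon", es[j], ee[j])
    if (tab$is_coding[i]) put("CDS", tab$cds_start[i], tab$cds_end[i])
  }
  invisible(path)
}
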
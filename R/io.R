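# Variant I/O -----------------------------------------------------------------

default_info_keys <- function() {
  list(score = "CADD_PHRED", af = "AF", class = "CLASS",
       de_novo = "DENOVO", region = "REGION")
}

# Collapse clinical classifications: likely benign/pathogenic fold into their
# parent class; conflicting entries map to NA (dropped by the reader).
collapse_clin_class <- function(x) {
  key <- gsub("[ _]+", "_", tolower(trimws(x)))
  out <- rep("unknown", length(x))
  out[key %in% c("benign", "likely_benign", "benign/likely_benign")] <- "benign"
  out[key %in% c("pathogenic", "likely_pathogenic",
                 "pathogenic/likely_pathogenic")] <- "pathogenic"
  out[key %in% c("vus", "uncertain_significance",
                 "uncertain")] <- "vus"
  out[grepl("conflicting", key)] <- NA_character_
  out[is.na(x) | !nzchar(trimws(x))] <- "unknown"
  out
}

is_standard_contig <- function(chrom, contig_regex = "^(chr)?([0-9]{1,2}|X|Y)$") {
  grepl(contig_regex, chrom)
}

is_mito <- function(chrom) {
  tolower(chrom) %in% c("chrm", "chrmt", "m", "mt")
}

#' Read a variant table from VCF or TSV
#'
#' VCF parsing goes through `vcfR`; per-variant fields are taken from INFO
#' keys (defaults: `CADD_PHRED`, `AF`, `CLASS`, `DENOVO` flag, `REGION`),
#' overridable through `info_keys`. Multi-allelic records are split one row
#' per ALT (comma-separated INFO values are matched per allele when their
#' length matches). Mitochondrial and unplaced-contig records and entries
#' with conflicting clinical classifications are dropped, with counts
#' reported via [message()]; likely benign/pathogenic fold into
#' benign/pathogenic at parse time.
#'
#' The TSV dialect expects columns `chrom`, `pos`, `ref`, `alt`, `score` and
#' optionally `allele_freq`, `clin_class`, `de_novo`, `region`.
#'
#' @param path Input path.
#' @param format `"vcf"` or `"tsv"`.
#' @param info_keys Named list mapping the fields score/af/class/de_novo/
#'   region to INFO keys (VCF only).
#' @param contig_regex Contigs not matching are treated as unplaced and
#'   dropped.
#' @return Annotated variant table: `chrom`, `pos`, `ref`, `alt`, `score`,
#'   `allele_freq`, `clin_class`, `de_novo`, and `region` when present.
#' @export
read_variants <- function(path, format = c("vcf", "tsv"),
                          info_keys = default_info_keys(),
                          contig_regex = "^(chr)?([0-9]{1,2}|X|Y)$") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- if (format == "vcf") {
    read_variants_vcf(path, info_keys)
  } else {
    read_variants_tsv(path)
  }
  drop_mito <- is_mito(df$chrom)
  drop_unplaced <- !drop_mito & !is_standard_contig(df$chrom, contig_regex)
  drop_confl <- is.na(df$clin_class)
  keep <- !drop_mito & !drop_unplaced & !drop_confl
  if (any(!keep)) {
    message("dropped ", sum(drop_mito), " mitochondrial, ",
            sum(drop_unplaced), " unplaced-contig, ",
            sum(drop_confl & !drop_mito & !drop_unplaced),
            " conflicting-classification record(s)")
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

info_value <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  has <- grepl(pat, info, perl = TRUE)
  out[has] <- sub(pat, "\\1", m, perl = TRUE)
  sub("^;", "", out)
}

info_flag <- function(info, key) {
  grepl(paste0("(^|;)", key, "($|;|=)"), info)
}

read_variants_vcf <- function(path, info_keys) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (!nrow(fix)) stop("no variant records in ", path)
  info <- fix[, "INFO"]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_raw <- fix[, "ALT"]
  score_raw <- info_value(info, info_keys$score)
  af_raw <- info_value(info, info_keys$af)
  class_raw <- info_value(info, info_keys$class)
  region_raw <- info_value(info, info_keys$region)
  dn <- info_flag(info, info_keys$de_novo)
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(alt_raw[i], ",", fixed = TRUE)[[1]]
    k <- length(alts)
    if (is.na(score_raw[i])) {
      stop("missing score (INFO key ", info_keys$score, ") at record ",
           chrom[i], ":", pos[i], " ", ref[i], ">", alt_raw[i])
    }
    per_alt <- function(raw) {
      if (is.na(raw)) return(rep(NA_character_, k))
      parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
      if (length(parts) == k) parts else rep(parts[1], k)
    }
    sc <- suppressWarnings(as.numeric(per_alt(score_raw[i])))
    if (anyNA(sc)) {
      stop("non-numeric score at record ", chrom[i], ":", pos[i])
    }
    rows[[i]] <- data.frame(
      chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts,
      score = sc,
      allele_freq = suppressWarnings(as.numeric(per_alt(af_raw[i]))),
      clin_class_raw = per_alt(class_raw[i]),
      de_novo = dn[i],
      region = per_alt(region_raw[i]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$clin_class <- collapse_clin_class(df$clin_class_raw)
  df$clin_class_raw <- NULL
  if (all(is.na(df$region))) df$region <- NULL
  df[, intersect(c("chrom", "pos", "ref", "alt", "score", "allele_freq",
                   "clin_class", "de_novo", "region"), names(df))]
}

read_variants_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("TSV is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(df$score)) {
    stop("missing score at record ", which(is.na(df$score))[1])
  }
  if (!"allele_freq" %in% names(df)) df$allele_freq <- NA_real_
  df$clin_class <- if ("clin_class" %in% names(df)) {
    collapse_clin_class(df$clin_class)
  } else "unknown"
  if (!"de_novo" %in% names(df)) df$de_novo <- NA
  df
}

#' Write a variant table as VCF 4.2
#'
#' Emits plain-text VCF with the package's INFO keys (`CADD_PHRED`, `AF`,
#' `CLASS`, `DENOVO` flag, `REGION`); the inverse of [read_variants()] for
#' retained fields.
#'
#' @param variants Annotated variant table.
#' @param path Output path.
#' @param info_keys Named list as in [read_variants()].
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, info_keys = default_info_keys()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=caddregions-%s", as.character(packageVersion("caddregions"))),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Phred-scaled deleteriousness score">', info_keys$score),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Population allele frequency">', info_keys$af),
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="Clinical classification">', info_keys$class),
    sprintf('##INFO=<ID=%s,Number=0,Type=Flag,Description="De novo variant">', info_keys$de_novo),
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="Noncoding region category">', info_keys$region),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(hdr, con)
  if (!nrow(variants)) return(invisible(path))
  info <- sprintf("%s=%.12g", info_keys$score, variants$score)
  af <- if ("allele_freq" %in% names(variants)) variants$allele_freq else NULL
  if (!is.null(af)) {
    add <- !is.na(af)
    info[add] <- paste0(info[add], sprintf(";%s=%.12g", info_keys$af, af[add]))
  }
  if ("clin_class" %in% names(variants)) {
    info <- paste0(info, ";", info_keys$class, "=", variants$clin_class)
  }
  if ("de_novo" %in% names(variants)) {
    dn <- !is.na(variants$de_novo) & variants$de_novo
    info[dn] <- paste0(info[dn], ";", info_keys$de_novo)
  }
  if ("region" %in% names(variants)) {
    info <- paste0(info, ";", info_keys$region, "=", variants$region)
  }
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                     variants$chrom, variants$pos, variants$ref,
                     variants$alt, info), con)
  invisible(path)
}

# Threshold config JSON --------------------------------------------------------

#' Write a thresholds configuration as JSON
#'
#' Serializes a named threshold map (or a fitted [region_thresholds()]
#' object, or a [filter_config()]) to the JSON schema shared by the
#' threshold-derivation and filtering stages:
#' `{"thresholds": {region: score, ...}, "af_max": ..., "require_de_novo": ...}`.
#'
#' @param x Named numeric vector, `region_thresholds` fit, or
#'   `filter_config`.
#' @param path Output path.
#' @param af_max,require_de_novo Filter settings stored alongside the
#'   thresholds (ignored when `x` is a `filter_config`).
#' @return `path`, invisibly.
#' @export
write_threshold_config <- function(x, path, af_max = 0.01,
                                   require_de_novo = FALSE) {
  if (inherits(x, "region_thresholds")) {
    thr <- coef(x)
    thr <- thr[!is.na(thr)]
  } else if (inherits(x, "filter_config")) {
    thr <- x$thresholds
    af_max <- x$af_max
    require_de_novo <- x$require_de_novo
  } else {
    thr <- x
  }
  stopifnot(is.numeric(thr), !is.null(names(thr)))
  jsonlite::write_json(list(thresholds = as.list(thr), af_max = af_max,
                            require_de_novo = require_de_novo),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a thresholds configuration written by [write_threshold_config()]
#'
#' @param path JSON path.
#' @return A [filter_config()].
#' @export
read_threshold_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_config(thresholds = unlist(raw$thresholds),
                af_max = if (!is.null(raw$af_max)) raw$af_max else 0.01,
                require_de_novo = isTRUE(raw$require_de_novo))
}

#' Serialize a filter report as JSON
#'
#' @param report A `filter_report` from [filter_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  out <- unclass(report)
  out$per_region_passing <- as.list(out$per_region_passing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
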
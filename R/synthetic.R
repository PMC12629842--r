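# Synthetic data generators ---------------------------------------------------

# Truncated-Normal sampling and moments (scores live on the Phred scale [0,99]).
rtnorm <- function(n, mu, sigma, a = 0, b = 99) {
  qnorm(runif(n, pnorm(a, mu, sigma), pnorm(b, mu, sigma)), mu, sigma)
}

#' Mean of a truncated Normal distribution
#'
#' @param mu,sigma Location and scale of the parent Normal.
#' @param a,b Truncation bounds (default the Phred score range 0..99).
#' @return The mean of the truncated distribution.
#' @export
tnorm_mean <- function(mu, sigma, a = 0, b = 99) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  mu + sigma * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}

#' Default region proportions for ClinVar-like synthesis
#'
#' Normalized from the per-region counts of a ClinVar-scale noncoding census
#' (intronic dominant at ~75%, 3' UTR ~9.5%, splicing ~7.4%, down to ~0.15%
#' for intergenic and downstream).
#'
#' @return Named probability vector over the nine noncoding regions, summing
#'   to 1.
#' @export
default_region_props <- function() {
  n <- c(intronic = 441685, utr3 = 56219, splicing = 43327, utr5 = 17822,
         ncRNA_intronic = 15828, upstream = 7685, ncRNA_exonic = 4992,
         downstream = 951, intergenic = 890)
  n / sum(n)
}

#' Default clinical-class proportions
#'
#' Normalized benign / pathogenic / VUS composition of a ClinVar-scale
#' noncoding set (~76% benign, ~7% pathogenic, ~17% VUS).
#'
#' @return Named probability vector summing to 1.
#' @export
default_class_props <- function() {
  n <- c(benign = 446766, pathogenic = 40196, vus = 102627)
  n / sum(n)
}

#' Default class-conditional score distributions
#'
#' Truncated Normals on \[0, 99\], identical across regions: benign
#' (mu 8, sd 4), VUS (mu 14, sd 5), pathogenic (mu 22, sd 5). The ordering
#' pathogenic > VUS > benign holds in every region; the defaults are a
#' generative configuration, not a claim about real score distributions.
#'
#' @return Data frame with columns `region`, `class`, `mu`, `sigma`.
#' @export
default_score_dists <- function() {
  par <- data.frame(class = c("benign", "vus", "pathogenic"),
                    mu = c(8, 14, 22), sigma = c(4, 5, 5))
  out <- merge(data.frame(region = noncoding_regions()), par)
  out[order(match(out$region, noncoding_regions()), match(out$class, par$class)),
      c("region", "class", "mu", "sigma")]
}

#' Generative description of a ClinVar-like synthetic dataset
#'
#' @param n_variants Number of variants to draw.
#' @param region_props Named probability vector over the nine noncoding
#'   regions (must sum to 1).
#' @param class_props Named probability vector over benign/pathogenic/vus, or
#'   a region-by-class matrix for per-region composition (rows must sum to 1).
#' @param score_dists Data frame `region`, `class`, `mu`, `sigma` of truncated
#'   Normal parameters on \[0, 99\].
#' @param seed Integer RNG seed; generation is a pure function of the spec.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_variants = 10000,
                           region_props = default_region_props(),
                           class_props = default_class_props(),
                           score_dists = default_score_dists(),
                           seed = 1L) {
  spec <- structure(list(n_variants = as.integer(n_variants),
                         region_props = region_props,
                         class_props = class_props,
                         score_dists = score_dists,
                         seed = as.integer(seed)),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_variants < 1) stop("invalid spec: n_variants must be >= 1")
  rp <- spec$region_props
  if (is.null(names(rp)) || !all(names(rp) %in% noncoding_regions())) {
    stop("invalid spec: region_props must be named by noncoding regions")
  }
  if (abs(sum(rp) - 1) > 1e-9 || any(rp < 0)) {
    stop("invalid spec: region_props must be non-negative and sum to 1")
  }
  cp <- spec$class_props
  if (is.matrix(cp)) {
    if (any(abs(rowSums(cp) - 1) > 1e-9)) {
      stop("invalid spec: class_props rows must sum to 1")
    }
    if (!all(colnames(cp) %in% c("benign", "pathogenic", "vus"))) {
      stop("invalid spec: class_props columns must be benign/pathogenic/vus")
    }
  } else {
    if (abs(sum(cp) - 1) > 1e-9 || any(cp < 0)) {
      stop("invalid spec: class_props must be non-negative and sum to 1")
    }
    if (!all(names(cp) %in% c("benign", "pathogenic", "vus"))) {
      stop("invalid spec: class_props must be named benign/pathogenic/vus")
    }
  }
  sd <- spec$score_dists
  if (any(sd$sigma <= 0)) stop("invalid spec: sigma must be > 0")
  if (any(sd$mu < 0 | sd$mu > 99)) stop("invalid spec: mu must be in [0, 99]")
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> n =", x$n_variants, "seed =", x$seed, "\n")
  cat("regions:", paste(sprintf("%s %.3f", names(x$region_props),
                                x$region_props), collapse = ", "), "\n")
  invisible(x)
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  list(ref = ref, alt = unname(alt))
}

# Class-dependent allele-frequency draw: benign mostly common, pathogenic and
# VUS rare. Arbitrary but realistic spectra for exercising frequency filters.
class_af <- function(cls) {
  n <- length(cls)
  af <- numeric(n)
  b <- cls == "benign"
  common <- b & runif(n) < 0.7
  af[common] <- runif(sum(common), 0.011, 0.6)
  af[b & !common] <- runif(sum(b & !common), 0, 0.01)
  af[cls == "pathogenic"] <- runif(sum(cls == "pathogenic"), 0, 1e-3)
  af[cls == "vus"] <- runif(sum(cls == "vus"), 0, 0.01)
  af
}

#' Generate a ClinVar-like classified variant set
#'
#' Draws `n_variants` rows with region sampled from `region_props`, clinical
#' class from `class_props`, and score from the (region, class) truncated
#' Normal. Positions are uniform on a toy chromosome; allele frequencies
#' follow a class-dependent spectrum (benign mostly common, pathogenic rare).
#' Output is reproducible given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Annotated variant table: `chrom`, `pos`, `ref`, `alt`, `score`,
#'   `allele_freq`, `clin_class`, `de_novo` (NA), `region`.
#' @export
generate_clinvar_like <- function(spec) {
  validate_synthetic_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_variants
    region <- sample(names(spec$region_props), n, replace = TRUE,
                     prob = spec$region_props)
    if (is.matrix(spec$class_props)) {
      cls <- character(n)
      for (r in unique(region)) {
        sel <- region == r
        cls[sel] <- sample(colnames(spec$class_props), sum(sel),
                           replace = TRUE, prob = spec$class_props[r, ])
      }
    } else {
      cls <- sample(names(spec$class_props), n, replace = TRUE,
                    prob = spec$class_props)
    }
    score <- numeric(n)
    sd <- spec$score_dists
    for (i in seq_len(nrow(sd))) {
      sel <- region == sd$region[i] & cls == sd$class[i]
      if (any(sel)) score[sel] <- rtnorm(sum(sel), sd$mu[i], sd$sigma[i])
    }
    al <- random_alleles(n)
    data.frame(chrom = "chr1",
               pos = sample.int(2.5e8, n, replace = TRUE),
               ref = al$ref, alt = al$alt,
               score = score,
               allele_freq = class_af(cls),
               clin_class = cls,
               de_novo = NA,
               region = region,
               stringsAsFactors = FALSE)
  })
}

# Gene-model generator ---------------------------------------------------------

# Truth label of a position relative to one isolated transcript, written as
# straight interval arithmetic (deliberately separate from classify_in_tx so
# the classifier can be checked against it).
single_tx_truth <- function(pos, tx, upstream_bp = 1000, downstream_bp = 1000,
                            splice_bp = 2) {
  up_lo <- if (tx$strand == "+") tx$tx_start - upstream_bp else tx$tx_end + 1
  up_hi <- if (tx$strand == "+") tx$tx_start - 1 else tx$tx_end + upstream_bp
  dn_lo <- if (tx$strand == "+") tx$tx_end + 1 else tx$tx_start - downstream_bp
  dn_hi <- if (tx$strand == "+") tx$tx_end + downstream_bp else tx$tx_start - 1
  if (pos >= up_lo && pos <= up_hi) return("upstream")
  if (pos >= dn_lo && pos <= dn_hi) return("downstream")
  if (pos < tx$tx_start || pos > tx$tx_end) return("intergenic")
  ex <- which(tx$exon_starts <= pos & pos <= tx$exon_ends)
  if (!tx$is_coding) {
    return(if (length(ex)) "ncRNA_exonic" else "ncRNA_intronic")
  }
  if (length(ex)) {
    if (pos < tx$cds_start) return(if (tx$strand == "+") "utr5" else "utr3")
    if (pos > tx$cds_end) return(if (tx$strand == "+") "utr3" else "utr5")
    return("exonic")
  }
  d <- min(c(pos - tx$exon_ends[tx$exon_ends < pos],
             tx$exon_starts[tx$exon_starts > pos] - pos))
  if (d <= splice_bp) "splicing" else "intronic"
}

#' Generate a synthetic gene model with a ground-truth region map
#'
#' Lays out `n_genes` isolated genes (coding and noncoding, random strand,
#' 1-5 exons) along a toy chromosome, with inter-gene gaps wide enough that
#' upstream/downstream windows never overlap. Alongside the transcript set it
#' emits a ground-truth map from genomic positions to expected region
#' category, computed by direct interval arithmetic on the generated
#' geometry; the map concentrates on boundary-critical positions (splice
#' windows, window edges, CDS edges) plus uniform samples around each gene
#' and the intergenic gaps.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer RNG seed; output is a pure function of the arguments.
#' @param chrom Chromosome name for the toy genome.
#' @param p_noncoding Probability a gene is noncoding (default 0.3).
#' @param positions_per_gene Extra uniformly sampled truth positions per gene.
#' @param upstream_bp,downstream_bp,splice_bp Window geometry (defaults 1000,
#'   1000, 2) used for the truth labels.
#' @return List with `genes` (a [transcript_models()] set) and `truth`
#'   (data frame `chrom`, `pos`, `region`).
#' @export
generate_gene_model <- function(n_genes, seed = 1L, chrom = "chr1",
                                p_noncoding = 0.3, positions_per_gene = 60,
                                upstream_bp = 1000, downstream_bp = 1000,
                                splice_bp = 2) {
  stopifnot(n_genes >= 1)
  with_seed(seed, {
    txs <- vector("list", n_genes)
    truth <- vector("list", n_genes)
    cur <- 5000L
    prev_end <- 1L
    for (g in seq_len(n_genes)) {
      coding <- runif(1) >= p_noncoding
      n_ex <- sample(1:5, 1)
      ex_len <- sample(120:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(300:1500, n_ex - 1, replace = TRUE)
                else integer(0)
      ex_s <- integer(n_ex)
      ex_e <- integer(n_ex)
      p <- cur
      for (i in seq_len(n_ex)) {
        ex_s[i] <- p
        ex_e[i] <- p + ex_len[i] - 1L
        p <- ex_e[i] + (if (i < n_ex) in_len[i] else 0L)
      }
      tx_start <- ex_s[1]
      tx_end <- ex_e[n_ex]
      cds_start <- cds_end <- NA_integer_
      if (coding) {
        if (n_ex == 1L) {
          cds_start <- ex_s[1] + sample(30:50, 1)
          cds_end <- ex_e[1] - sample(30:50, 1)
        } else {
          cds_start <- ex_s[1] + sample(30:(ex_len[1] - 30), 1)
          cds_end <- ex_s[n_ex] + sample(29:(ex_len[n_ex] - 31), 1)
        }
      }
      tx <- transcript_model(sprintf("TX%04d", g), sprintf("G%04d", g),
                             chrom, sample(c("+", "-"), 1),
                             tx_start, tx_end, ex_s, ex_e,
                             cds_start, cds_end)
      txs[[g]] <- tx
      pos <- c(tx_start - upstream_bp - 1L, tx_start - upstream_bp,
               tx_start - 500L, tx_start - 1L, tx_start,
               tx_end, tx_end + 1L, tx_end + 500L,
               tx_end + downstream_bp, tx_end + downstream_bp + 1L)
      for (i in seq_len(n_ex)) {
        pos <- c(pos, ex_s[i], ex_e[i])
        if (i > 1) pos <- c(pos, ex_s[i] - seq_len(splice_bp + 1L))
        if (i < n_ex) pos <- c(pos, ex_e[i] + seq_len(splice_bp + 1L))
      }
      if (coding) {
        pos <- c(pos, cds_start - 1L, cds_start, cds_end, cds_end + 1L)
      }
      pos <- c(pos, round(runif(positions_per_gene,
                                tx_start - upstream_bp - 200,
                                tx_end + downstream_bp + 200)))
      # deep-intergenic probes in the gap left of this gene
      gap_probe <- round(runif(3, prev_end + 1100, tx_start - 1100))
      pos <- unique(pmax(1L, as.integer(c(pos, gap_probe))))
      truth[[g]] <- data.frame(
        chrom = chrom, pos = pos,
        region = vapply(pos, single_tx_truth, "", tx = tx,
                        upstream_bp = upstream_bp,
                        downstream_bp = downstream_bp,
                        splice_bp = splice_bp),
        stringsAsFactors = FALSE)
      prev_end <- tx_end
      cur <- tx_end + sample(2600:4000, 1)
    }
    list(genes = transcript_models(txs),
         truth = do.call(rbind, truth))
  })
}

# Trio-WGS generator -----------------------------------------------------------

#' Generate a trio-WGS-like variant set with a planted pathogenic variant
#'
#' Emulates the de novo analysis of a rare-disease trio genome: a large
#' background of mostly common variants with low, benign-like scores
#' (truncated Normal(5, 4) on \[0, 99\]), ~92% common (allele frequency
#' > 1%) and 8% rare; `de_novo_count` background variants flagged de novo
#' (and made novel, frequency 0); plus exactly one planted de novo
#' ncRNA-exonic variant with frequency 0 and score `planted_score`,
#' emulating a small-nuclear-RNA insertion such as the recurrent RNU4-2
#' n.64_65insT. About 1% of the background is coding-exonic so the
#' exonic-exclusion stage of the filter cascade is exercised.
#'
#' When a `gene_model` (from [generate_gene_model()]) is supplied, positions
#' are drawn from its ground-truth map so that the `region` column is
#' consistent with the geometry and [classify_variants()] reproduces it;
#' otherwise positions are arbitrary and only the `region` labels matter.
#'
#' @param n_variants Background variant count.
#' @param de_novo_count Background variants flagged de novo (default 80).
#' @param planted_score Score of the planted variant (default 20.8).
#' @param seed Integer RNG seed.
#' @param gene_model Optional output of [generate_gene_model()].
#' @param region_props Region proportions for the noncoding background
#'   (default [default_region_props()]).
#' @param exonic_prop Fraction of coding-exonic background (default 0.01).
#' @return Annotated variant table with columns as in
#'   [generate_clinvar_like()] plus logical `de_novo` and `planted`.
#' @export
generate_trio_wgs <- function(n_variants, de_novo_count = 80L,
                              planted_score = 20.8, seed = 1L,
                              gene_model = NULL,
                              region_props = default_region_props(),
                              exonic_prop = 0.01) {
  stopifnot(de_novo_count <= n_variants, n_variants >= 1)
  with_seed(seed, {
    props <- c(region_props * (1 - exonic_prop), exonic = exonic_prop)
    if (!is.null(gene_model)) {
      truth <- gene_model$truth
      have <- names(props) %in% unique(truth$region)
      if (!all(have)) {
        warning("gene model lacks positions for: ",
                paste(names(props)[!have], collapse = ", "),
                "; those regions dropped from the background")
        props <- props[have] / sum(props[have])
      }
    }
    region <- sample(names(props), n_variants, replace = TRUE, prob = props)
    if (is.null(gene_model)) {
      pos <- sample.int(2.5e8, n_variants, replace = TRUE)
      chrom <- rep("chr1", n_variants)
    } else {
      pos <- integer(n_variants)
      for (r in unique(region)) {
        sel <- region == r
        pool <- truth$pos[truth$region == r]
        pos[sel] <- sample(pool, sum(sel), replace = TRUE)
      }
      chrom <- rep(truth$chrom[1], n_variants)
    }
    common <- runif(n_variants) < 0.92
    af <- ifelse(common, runif(n_variants, 0.011, 0.6),
                 10^-runif(n_variants, 2.01, 8))
    al <- random_alleles(n_variants)
    dn <- rep(FALSE, n_variants)
    dn[sample.int(n_variants, de_novo_count)] <- TRUE
    af[dn] <- 0  # de novo variants are novel
    bg <- data.frame(chrom = chrom, pos = pos,
                     ref = al$ref, alt = al$alt,
                     score = rtnorm(n_variants, 5, 4),
                     allele_freq = af,
                     clin_class = "unknown",
                     de_novo = dn,
                     region = region,
                     planted = FALSE,
                     stringsAsFactors = FALSE)
    planted_pos <- if (is.null(gene_model)) {
      sample.int(2.5e8, 1)
    } else {
      pool <- truth$pos[truth$region == "ncRNA_exonic"]
      if (!length(pool)) {
        stop("gene model has no ncRNA-exonic positions to plant into")
      }
      sample(pool, 1)
    }
    planted <- data.frame(chrom = bg$chrom[1], pos = planted_pos,
                          ref = "A", alt = "AT",
                          score = planted_score, allele_freq = 0,
                          clin_class = "unknown", de_novo = TRUE,
                          region = "ncRNA_exonic", planted = TRUE,
                          stringsAsFactors = FALSE)
    out <- rbind(bg, planted)
    rownames(out) <- NULL
    out
  })
}
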
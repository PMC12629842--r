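# Reflect a transcript set through position p -> L + 1 - p, flipping strand;
# classification must be invariant under this mirror.
mirror_genes <- function(genes, L) {
  tab <- genes$table
  txs <- lapply(seq_len(nrow(tab)), function(i) {
    transcript_model(
      tab$transcript_id[i], tab$gene_id[i], tab$chrom[i],
      strand = if (tab$strand[i] == "+") "-" else "+",
      tx_start = L + 1 - tab$tx_end[i], tx_end = L + 1 - tab$tx_start[i],
      exon_starts = L + 1 - rev(genes$exon_ends[[i]]),
      exon_ends = L + 1 - rev(genes$exon_starts[[i]]),
      cds_start = if (tab$is_coding[i]) L + 1 - tab$cds_end[i] else NA,
      cds_end = if (tab$is_coding[i]) L + 1 - tab$cds_start[i] else NA)
  })
  transcript_models(txs)
}

test_that("canonical positions get their defining categories", {
  g <- fixture_genes("+")
  cls <- function(pos) {
    classify_variants(data.frame(chrom = "chr1", pos = pos), g)
  }
  # coding transcript: exon 10000-10800 / intron / exon 12000-14000, CDS 10200-13500
  expect_equal(cls(10802), "splicing")     # 2 bp past the exon 3' boundary
  expect_equal(cls(10803), "intronic")     # 3 bp past: outside the splice window
  expect_equal(cls(11998), "splicing")     # 2 bp before the next exon
  expect_equal(cls(9500), "upstream")      # 500 bp 5' of the TSS
  expect_equal(cls(20000), "intergenic")   # far from every transcript
  expect_equal(cls(10100), "utr5")         # exon position before the CDS
  expect_equal(cls(13800), "utr3")         # exon position after the CDS
  expect_equal(cls(10500), "exonic")       # inside the CDS
  expect_equal(cls(30100), "ncRNA_exonic")
  expect_equal(cls(31000), "ncRNA_intronic")
  expect_equal(cls(31999), "ncRNA_intronic")  # no splice category on ncRNA
})

test_that("window boundaries are exact", {
  g <- fixture_genes("+")
  cls <- function(pos) {
    classify_variants(data.frame(chrom = "chr1", pos = pos), g)
  }
  expect_equal(cls(10000 - 1000), "upstream")    # exactly 1000 bp from TSS
  expect_equal(cls(10000 - 1001), "intergenic")
  expect_equal(cls(14000 + 1000), "downstream")
  expect_equal(cls(14000 + 1001), "intergenic")
})

test_that("strand mirror leaves every category unchanged", {
  g <- fixture_genes("+")
  L <- 50000
  gm <- mirror_genes(g, L)
  pos <- c(8999, 9000, 9500, 10000, 10100, 10500, 10800, 10801, 10802, 10803,
           11500, 11998, 12000, 13500, 13600, 14000, 14500, 15000, 15001,
           20000, 29500, 30100, 31000, 31998, 32500, 34000)
  orig <- classify_variants(data.frame(chrom = "chr1", pos = pos), g)
  mirr <- classify_variants(data.frame(chrom = "chr1", pos = L + 1 - pos), gm)
  expect_identical(mirr, orig)
  # minus-strand upstream sits beyond tx_end in genomic coordinates
  minus <- transcript_models(list(transcript_model(
    "txM", chrom = "chr1", strand = "-", tx_start = 5000, tx_end = 6000,
    exon_starts = 5000, exon_ends = 6000, cds_start = 5100, cds_end = 5900)))
  expect_equal(classify_variant(list(chrom = "chr1", pos = 6500), minus),
               "upstream")
  expect_equal(classify_variant(list(chrom = "chr1", pos = 4500), minus),
               "downstream")
})

test_that("classification is independent of transcript order and total", {
  set.seed(77)
  for (rep in 1:20) {
    gm <- generate_gene_model(n_genes = 4, seed = rep, positions_per_gene = 5)
    # overlap the genes by adding a shifted copy of each transcript
    tab <- gm$genes$table
    txs <- lapply(seq_len(nrow(tab)), function(i) {
      transcript_model(paste0(tab$transcript_id[i], "b"), tab$gene_id[i],
                       tab$chrom[i], tab$strand[i],
                       tab$tx_start[i] + 150, tab$tx_end[i] + 150,
                       gm$genes$exon_starts[[i]] + 150,
                       gm$genes$exon_ends[[i]] + 150,
                       tab$cds_start[i] + 150, tab$cds_end[i] + 150)
    })
    all_tx <- c(lapply(seq_len(nrow(tab)), function(i) {
      transcript_model(tab$transcript_id[i], tab$gene_id[i], tab$chrom[i],
                       tab$strand[i], tab$tx_start[i], tab$tx_end[i],
                       gm$genes$exon_starts[[i]], gm$genes$exon_ends[[i]],
                       tab$cds_start[i], tab$cds_end[i])
    }), txs)
    v <- data.frame(chrom = "chr1",
                    pos = sample(min(tab$tx_start):max(tab$tx_end), 200))
    ref <- classify_variants(v, transcript_models(all_tx))
    for (k in 1:5) {
      shuffled <- transcript_models(all_tx[sample(length(all_tx))])
      expect_identical(classify_variants(v, shuffled), ref)
    }
    expect_true(all(ref %in% region_levels()))  # totality
  }
})

test_that("chromosome absent from the gene model falls back to intergenic", {
  g <- fixture_genes()
  expect_warning(
    lab <- classify_variants(data.frame(chrom = "chr9", pos = 10500), g),
    "absent from gene model")
  expect_equal(lab, "intergenic")
})

test_that("GTF and refGene gene models load and agree", {
  gtf <- write_lines_tmp(c(
    "# comment",
    paste0("chr1\tsrc\ttranscript\t10000\t14000\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA";'),
    paste0("chr1\tsrc\texon\t10000\t10800\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA";'),
    paste0("chr1\tsrc\texon\t12000\t14000\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA";'),
    paste0("chr1\tsrc\tCDS\t10200\t13500\t.\t+\t.\t",
           'gene_id "geneA"; transcript_id "txA";'),
    paste0("chr1\tsrc\ttranscript\t30000\t33000\t.\t+\t.\t",
           'gene_id "geneN"; transcript_id "txN";'),
    paste0("chr1\tsrc\texon\t30000\t30400\t.\t+\t.\t",
           'gene_id "geneN"; transcript_id "txN";'),
    paste0("chr1\tsrc\texon\t32000\t33000\t.\t+\t.\t",
           'gene_id "geneN"; transcript_id "txN";')), ".gtf")
  g1 <- load_gene_model(gtf, "gtf")
  expect_equal(length(g1), 2)
  expect_true(g1$table$is_coding[g1$table$transcript_id == "txA"])
  expect_false(g1$table$is_coding[g1$table$transcript_id == "txN"])

  rg <- write_lines_tmp(c(
    "txA\tchr1\t+\t9999\t14000\t10199\t13500\t2\t9999,11999,\t10800,14000,",
    "txN\tchr1\t+\t29999\t33000\t33000\t33000\t2\t29999,31999,\t30400,33000,"),
    ".txt")
  g2 <- load_gene_model(rg, "refgene_tsv")
  expect_equal(g2$table$tx_start, g1$table$tx_start)
  expect_equal(g2$table$cds_start, g1$table$cds_start)
  expect_equal(g2$exon_starts, g1$exon_starts)
  expect_equal(g2$exon_ends, g1$exon_ends)

  pos <- data.frame(chrom = "chr1", pos = c(9500, 10100, 10802, 30100, 31000))
  expect_identical(classify_variants(pos, g1), classify_variants(pos, g2))
})

test_that("malformed gene models error naming the line; bad CDS is rejected", {
  bad <- write_lines_tmp(c(
    paste0("chr1\tsrc\texon\t500\t400\t.\t+\t.\t",
           'gene_id "g"; transcript_id "t";')), ".gtf")
  expect_error(load_gene_model(bad, "gtf"), "line 1.*end < start")

  short <- write_lines_tmp("chr1\tsrc\texon\t100", ".gtf")
  expect_error(load_gene_model(short, "gtf"), "line 1")

  # CDS outside the exon span: transcript rejected with a warning, other kept
  mixed <- write_lines_tmp(c(
    paste0("chr1\tsrc\texon\t1000\t2000\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "bad";'),
    paste0("chr1\tsrc\tCDS\t2500\t2600\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "bad";'),
    paste0("chr1\tsrc\texon\t5000\t6000\t.\t+\t.\t",
           'gene_id "g2"; transcript_id "ok";')), ".gtf")
  expect_warning(g <- load_gene_model(mixed, "gtf"), "rejected transcript bad")
  expect_equal(g$table$transcript_id, "ok")
})

test_that("GTF writer round-trips a transcript set", {
  g <- fixture_genes()
  f <- tempfile(fileext = ".gtf")
  write_gene_model_gtf(g, f)
  g2 <- load_gene_model(f, "gtf")
  expect_equal(g2$table[order(g2$table$transcript_id), ],
               g$table[order(g$table$transcript_id), ],
               ignore_attr = TRUE)
})
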
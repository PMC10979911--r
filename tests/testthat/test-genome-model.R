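test_that("GTF coordinates convert to 0-based half-open and UTRs derive", {
  models <- load_annotation(toy_gtf())
  t1 <- models[["T1"]]
  # exon 101-400, CDS 151-350 (1-based inclusive)
  expect_equal(t1$exons$start, 100L)
  expect_equal(t1$exons$end, 400L)
  expect_equal(t1$cds$start, 150L)
  expect_equal(t1$cds$end, 350L)
  expect_equal(t1$utr5[, c("start", "end")],
               data.frame(start = 100L, end = 150L))
  expect_equal(t1$utr3[, c("start", "end")],
               data.frame(start = 350L, end = 400L))
  expect_true(t1$is_mane_select)
  expect_false(models[["T2"]]$is_mane_select)
})

test_that("minus-strand transcripts swap UTR ends", {
  models <- load_annotation(toy_gtf())
  t2 <- models[["T2"]]
  # genomic left chunk [500, 600) is 3' of the CDS on the minus strand
  expect_equal(t2$utr3[, c("start", "end")],
               data.frame(start = 500L, end = 600L))
  expect_equal(t2$utr5[, c("start", "end")],
               data.frame(start = 700L, end = 800L))
})

test_that("multi-exon CDS yields spliced UTRs and keeps the tiling", {
  models <- load_annotation(toy_gtf())
  t3 <- models[["T3"]]
  expect_equal(nrow(t3$exons), 2L)
  expect_equal(interval_width(t3$cds), 100L)
  expect_equal(interval_width(t3$utr5), 50L)
  expect_equal(interval_width(t3$utr3), 50L)
})

test_that("CDS spanning the whole exon leaves both UTRs empty", {
  ex <- genome_interval("c", 0, 300)
  u <- derive_utrs(ex, ex, "+")
  expect_equal(nrow(u$utr5), 0L)
  expect_equal(nrow(u$utr3), 0L)
})

test_that("derive_utrs matches the direct construction on both strands", {
  ex <- genome_interval("c", 0, 300)
  cds <- genome_interval("c", 100, 200)
  plus <- derive_utrs(ex, cds, "+")
  expect_equal(plus$utr5[, c("start", "end")],
               data.frame(start = 0L, end = 100L))
  expect_equal(plus$utr3[, c("start", "end")],
               data.frame(start = 200L, end = 300L))
  minus <- derive_utrs(ex, cds, "-")
  expect_equal(minus$utr5[, c("start", "end")],
               data.frame(start = 200L, end = 300L))
  expect_equal(minus$utr3[, c("start", "end")],
               data.frame(start = 0L, end = 100L))
})

test_that("derive_utrs rejects a CDS outside the exons", {
  ex <- genome_interval("c", 0, 300)
  expect_error(derive_utrs(ex, genome_interval("c", 250, 350), "+"),
               "not contained")
})

test_that("malformed GTF lines are reported with their line number", {
  bad <- paste(toy_gtf(), "chr1\tonly\tthree", sep = "\n")
  expect_error(load_annotation(bad), "line 9")
  bad2 <- sub('CDS\t151\t350', 'CDS\t451\t500', toy_gtf())
  expect_error(load_annotation(bad2), "CDS outside exons")
})

test_that("stop codons outside the CDS are folded in before UTR derivation", {
  gtf <- paste(
    'chr1\tt\texon\t1\t300\t.\t+\t.\tgene_id "G"; transcript_id "T"; gene_name "G";',
    'chr1\tt\tCDS\t101\t197\t.\t+\t.\tgene_id "G"; transcript_id "T"; gene_name "G";',
    'chr1\tt\tstop_codon\t198\t200\t.\t+\t.\tgene_id "G"; transcript_id "T"; gene_name "G";',
    sep = "\n")
  m <- load_annotation(gtf)[["T"]]
  expect_equal(interval_width(m$cds), 100L)
  expect_equal(m$utr3$start, 200L)
})

test_that("tiling invariant holds on randomly generated transcript models", {
  for (seed in 1:25) {
    m <- random_transcript_model(seed)
    expect_equal(
      interval_width(m$cds) + interval_width(m$utr5) +
        interval_width(m$utr3),
      interval_width(m$exons))
  }
})

test_that("GTF round-trip reproduces the models exactly", {
  models <- load_annotation(toy_gtf())
  again <- load_annotation(paste(write_annotation_gtf(models),
                                 collapse = "\n"))
  expect_equal(again, models)
})

test_that("mirroring coordinates with a strand flip swaps the UTRs", {
  for (seed in 1:10) {
    m <- random_transcript_model(seed)
    strand <- m$exons$strand[1]
    hi <- max(m$exons$end) + 13L
    mirror <- function(iv, s) {
      if (nrow(iv) == 0) return(iv)
      genome_interval(iv$seq_id, hi - iv$end, hi - iv$start, s)
    }
    flipped <- if (strand == "+") "-" else "+"
    u <- derive_utrs(mirror(m$exons, flipped), mirror(m$cds, flipped),
                     flipped)
    expect_equal(u$utr5[, c("start", "end")],
                 mirror(m$utr5, flipped)[, c("start", "end")])
    expect_equal(u$utr3[, c("start", "end")],
                 mirror(m$utr3, flipped)[, c("start", "end")])
  }
})

test_that("select_mane returns the unique flagged transcript or errors", {
  models <- load_annotation(toy_gtf())
  expect_equal(select_mane(models, "ALPHA")$transcript_id, "T1")
  expect_error(select_mane(models, "BETA"), "no MANE")
  dup <- models
  dup[["T2"]]$is_mane_select <- TRUE
  dup[["T2"]]$gene_name <- "ALPHA"
  expect_error(select_mane(dup, "ALPHA"), "ambiguous")
})

test_that("the synthetic annotation carries the factor MANE transcripts", {
  ref <- synthetic_reference()
  expect_equal(select_mane(ref$annotation, "KLF4")$transcript_id,
               "ENST00000374672")
  expect_equal(select_mane(ref$annotation, "MYC")$transcript_id,
               "ENST00000621592")
})

test_that("build_reference combines host and viral models", {
  ref <- toy_reference()
  expect_equal(sum(ref$origin == "host"), 2L)
  expect_equal(sum(ref$origin == "viral"), 1L)
  expect_equal(length(ref$annotation), 5L)  # 2 host + 3 viral genes
  # viral genes are UTR-less single-exon plus-strand models
  va <- ref$annotation[["VA"]]
  expect_equal(nrow(va$exons), 1L)
  expect_equal(interval_width(va$utr5) + interval_width(va$utr3), 0L)
  expect_equal(va$exons$strand, "+")
  # deleted gene keeps its interval for coverage reporting
  expect_true("F" %in% ref$viral_model$genes$gene)
  expect_equal(ref$viral_model$deleted_genes, "F")
})

test_that("host/viral seq_id collisions are namespaced or rejected", {
  host <- c(SAME = rand_seq(300, 7))
  models <- list(transcript_model("SAME", "G", "G",
                                  exons = genome_interval("SAME", 0, 300),
                                  cds = genome_interval("SAME", 50, 250)))
  viral <- c(SAME = rand_seq(500, 8))
  genes <- data.frame(gene = "VX", start = 10L, end = 200L)
  ref <- build_reference(host, models, viral_sequences = viral,
                         viral_genes = list(genes = genes,
                                            deleted_genes = character()))
  expect_true("viral|SAME" %in% names(ref$sequences))
  expect_equal(ref$viral_model$seq_id, "viral|SAME")
  expect_error(
    build_reference(host, models, viral_sequences = viral,
                    viral_genes = list(genes = genes,
                                       deleted_genes = character()),
                    prefix = NULL),
    "collision")
})

test_that("an empty viral FASTA yields a host-only reference", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(character(), tmp)
  host <- c(TXa = rand_seq(300, 7))
  models <- list(transcript_model("TXa", "G", "G",
                                  exons = genome_interval("TXa", 0, 300),
                                  cds = genome_interval("TXa", 50, 250)))
  ref <- build_reference(host, models, viral_sequences = tmp,
                         viral_genes = NULL)
  expect_null(ref$viral_model)
  expect_equal(length(ref$annotation), 1L)
})

test_that("transcript sequences splice exons and respect strand", {
  seqs <- c(chr = "AAACCCGGGTTTAAACCCGGG")
  m_plus <- transcript_model("P", "G", "G",
                             exons = genome_interval("chr", c(0, 12), c(6, 18)),
                             cds = genome_interval("chr", c(3, 12), c(6, 15)))
  m_minus <- transcript_model("M", "G", "G",
                              exons = genome_interval("chr", 0, 6, "-"),
                              cds = genome_interval("chr", 0, 6, "-"))
  ref <- build_reference(seqs, list(m_plus, m_minus))
  expect_equal(transcript_sequence(ref, "P"), "AAACCCAAACCC")
  expect_equal(transcript_sequence(ref, "P", "cds"), "CCCAAA")
  expect_equal(transcript_sequence(ref, "M"), "GGGTTT")  # revcomp of AAACCC
  expect_error(transcript_sequence(ref, "NOPE"), "unknown transcript")
})
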
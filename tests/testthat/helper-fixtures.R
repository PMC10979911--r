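# Small deterministic fixtures built in code.

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# GTF text for two single-exon transcripts (one per strand) and one
# multi-exon transcript; coordinates are 1-based inclusive per GTF.
toy_gtf <- function() {
  paste(
    'chr1\ttest\texon\t101\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_name "ALPHA"; tag "MANE_Select";',
    'chr1\ttest\tCDS\t151\t350\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_name "ALPHA";',
    'chr1\ttest\texon\t501\t800\t.\t-\t.\tgene_id "G2"; transcript_id "T2"; gene_name "BETA";',
    'chr1\ttest\tCDS\t601\t700\t.\t-\t.\tgene_id "G2"; transcript_id "T2"; gene_name "BETA";',
    'chr2\ttest\texon\t1\t100\t.\t+\t.\tgene_id "G3"; transcript_id "T3"; gene_name "GAMMA";',
    'chr2\ttest\texon\t201\t300\t.\t+\t.\tgene_id "G3"; transcript_id "T3"; gene_name "GAMMA";',
    'chr2\ttest\tCDS\t51\t100\t.\t+\t.\tgene_id "G3"; transcript_id "T3"; gene_name "GAMMA";',
    'chr2\ttest\tCDS\t201\t250\t.\t+\t.\tgene_id "G3"; transcript_id "T3"; gene_name "GAMMA";',
    sep = "\n"
  )
}

# Minimal host + viral reference with two factor-like transcripts and a
# 600 bp viral genome carrying three genes, one (F) deleted in the vector.
toy_reference <- function(seed = 101) {
  set.seed(seed)
  host <- c(TX1 = rand_seq(500, seed), TX2 = rand_seq(400, seed + 1))
  models <- list(
    transcript_model("TX1", "GENE1", "GENE1",
                     exons = genome_interval("TX1", 0, 500),
                     cds = genome_interval("TX1", 100, 400),
                     is_mane_select = TRUE),
    transcript_model("TX2", "GENE2", "GENE2",
                     exons = genome_interval("TX2", 0, 400),
                     cds = genome_interval("TX2", 50, 350),
                     is_mane_select = TRUE)
  )
  viral <- c(VG = rand_seq(600, seed + 2))
  genes <- data.frame(gene = c("VA", "VB", "F"),
                      start = c(20L, 230L, 430L),
                      end = c(200L, 400L, 580L))
  build_reference(host, models, viral_sequences = viral,
                  viral_genes = list(genes = genes, deleted_genes = "F"))
}

# random but valid transcript model for property-style tests
random_transcript_model <- function(seed) {
  set.seed(seed)
  n_exons <- sample(1:4, 1)
  widths <- sample(60:300, n_exons, replace = TRUE)
  gaps <- sample(10:150, n_exons, replace = TRUE)
  starts <- cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_exons)]
  ends <- starts + widths
  strand <- sample(c("+", "-"), 1)
  exons <- genome_interval("chrT", starts, ends, strand)
  # pick a contiguous CDS in transcript coordinates
  total <- interval_width(exons)
  a <- sample.int(total - 10, 1)
  b <- min(total, a + sample(10:total, 1))
  # map transcript-base offsets [a, b) back to genomic intervals
  cds <- local({
    offs <- c(0, cumsum(exons$end - exons$start))
    rows <- lapply(seq_len(nrow(exons)), function(i) {
      lo <- max(a, offs[i])
      hi <- min(b, offs[i + 1])
      if (lo >= hi) return(NULL)
      genome_interval("chrT", exons$start[i] + (lo - offs[i]),
                      exons$start[i] + (hi - offs[i]), strand)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })
  transcript_model(sprintf("RT%d", seed), "RG", "RG", exons, cds)
}
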
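test_that("the index holds L - k + 1 positions for a single sequence", {
  s <- c(one = rand_seq(200, 31))
  idx <- build_index(s, k = 15)
  expect_equal(.kmer_index_size(idx$ptr), 200 - 15 + 1)
  expect_error(build_index(s, k = 16), "odd")
  expect_warning(build_index(c(s, tiny = "ACGT"), k = 15), "tiny")
})

test_that("absent k-mers return an empty hit set", {
  idx <- build_index(c(one = strrep("A", 50)), k = 11)
  hits <- query_kmer(idx, strrep("C", 11))
  expect_equal(nrow(hits), 0L)
})

test_that("a k-mer and its reverse complement hit the same positions", {
  s <- c(one = rand_seq(300, 32))
  idx <- build_index(s, k = 21)
  km <- substr(s[[1]], 100, 120)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(km)))
  h1 <- query_kmer(idx, km)
  h2 <- query_kmer(idx, rc)
  expect_equal(h1$offset, h2$offset)
  expect_equal(h1$target, h2$target)
  expect_equal(h1$same_strand, !h2$same_strand)
})

test_that("error-free reads from unique sources assign uniquely with the true position", {
  ref <- toy_reference()
  idx <- build_index(ref, k = 31)
  pool <- build_transcript_pool(
    ref, expression_spec(endogenous = c(TX1 = 1, TX2 = 1),
                         viral = c(VA = 1, VB = 1)))
  sim <- simulate_reads(pool, 500, 80, error_rate = 0, seed = 41,
                        circular = FALSE)
  asg <- assign_reads(idx, sim$reads)
  expect_true(all(asg$status$status == "unique"))
  merged <- merge(asg$assignments, sim$truth,
                  by.x = "read_id", by.y = "read_id")
  expect_equal(nrow(merged), 500L)
  expect_equal(merged$target, merged$source_id)
  expect_equal(merged$position, merged$start)
})

test_that("reads shared between CDS+UTR and CDS-only targets split evenly", {
  ref <- toy_reference()
  # reference that contains BOTH forms of TX1 as targets
  targets <- c(endo = transcript_sequence(ref, "TX1"),
               exo = transcript_sequence(ref, "TX1", "cds"))
  idx <- build_index(targets, k = 21)
  cds_read <- substr(targets[["exo"]], 50, 129)  # interior CDS read
  one <- assign_read(idx, cds_read)
  expect_equal(one$status, "ambiguous")
  expect_equal(sort(names(one$targets)), c("endo", "exo"))
  expect_equal(unname(one$targets), c(0.5, 0.5))
  # a UTR read is unique to the full-length form
  utr_read <- substr(targets[["endo"]], 10, 89)
  expect_equal(assign_read(idx, utr_read)$status, "unique")
})

test_that("foreign reads stay unassigned", {
  idx <- build_index(c(one = rand_seq(400, 33)), k = 31)
  set.seed(1)
  foreign <- rand_seq(100, 999)
  expect_equal(assign_read(idx, foreign)$status, "unassigned")
  short <- substr(rand_seq(40, 998), 1, 20)  # shorter than k
  expect_equal(assign_read(idx, short)$status, "unassigned")
})

test_that("voting agrees with a brute-force substring oracle on error-free reads", {
  ref <- toy_reference()
  seqs <- vapply(ref$annotation, function(m)
    transcript_sequence(ref, m, "exon"), character(1))
  idx <- build_index(seqs, k = 21)
  L <- 60
  for (sid in c("TX1", "VB")) {
    s <- seqs[[sid]]
    starts <- seq(1, nchar(s) - L + 1, by = 7)
    reads <- setNames(substring(s, starts, starts + L - 1),
                      sprintf("r%03d", seq_along(starts)))
    asg <- assign_reads(idx, reads)
    # brute-force: which targets contain each read as an exact substring?
    for (i in seq_along(reads)) {
      hits <- names(seqs)[vapply(seqs, function(t)
        grepl(reads[[i]], t, fixed = TRUE), logical(1))]
      got <- asg$assignments$target[asg$assignments$read_id == names(reads)[i]]
      expect_setequal(got, hits)
    }
  }
})

test_that("assignment weights are conserved", {
  ref <- toy_reference()
  idx <- build_index(ref, k = 31)
  pool <- build_transcript_pool(
    ref, expression_spec(endogenous = c(TX1 = 2, TX2 = 1), viral = c(VB = 1)))
  sim <- simulate_reads(pool, 1000, 70, error_rate = 0.005, seed = 5)
  asg <- assign_reads(idx, sim$reads)
  n_assigned <- sum(asg$status$status != "unassigned")
  expect_equal(sum(asg$assignments$weight), n_assigned)
  expect_equal(sum(transcript_counts(asg)), n_assigned)
})

test_that("feature counting places reads by their 5' start base", {
  models <- list(M = transcript_model(
    "M", "G", "G", exons = genome_interval("M", 0, 300),
    cds = genome_interval("M", 100, 200)))
  asg <- data.frame(read_id = c("a", "b", "c"),
                    target = "M",
                    weight = 1,
                    position = c(120L, 50L, 250L),
                    read_length = 50L, stringsAsFactors = FALSE)
  fc <- count_features(asg, models)
  expect_equal(fc$cds_count, 1)
  expect_equal(fc$utr5_count, 1)
  expect_equal(fc$utr3_count, 1)
  expect_equal(fc$total_count, 3)
  expect_equal(fc$cds_length, 100L)
})

test_that("overlap counting adds junction reads to both features", {
  models <- list(M = transcript_model(
    "M", "G", "G", exons = genome_interval("M", 0, 300),
    cds = genome_interval("M", 100, 200)))
  # read straddles the CDS/UTR3 junction at 200
  asg <- data.frame(read_id = "a", target = "M", weight = 1,
                    position = 180L, read_length = 50L,
                    stringsAsFactors = FALSE)
  fc <- count_features(asg, models, count_mode = "overlap")
  expect_equal(fc$cds_count, 1)
  expect_equal(fc$utr3_count, 1)
  expect_equal(fc$utr5_count, 0)
  # fully contained read counts once in either mode
  asg$position <- 120L
  for (mode in c("start", "overlap")) {
    fc <- count_features(asg, models, count_mode = mode)
    expect_equal(fc$cds_count, 1)
    expect_equal(fc$utr5_count + fc$utr3_count, 0)
  }
})

test_that("empty assignments give all-zero counts and orphan targets warn", {
  models <- list(M = transcript_model(
    "M", "G", "G", exons = genome_interval("M", 0, 300),
    cds = genome_interval("M", 100, 200)))
  fc <- count_features(data.frame(read_id = character(), target = character(),
                                  weight = numeric(), position = integer(),
                                  read_length = integer()), models)
  expect_equal(fc$total_count, 0)
  asg <- data.frame(read_id = "a", target = "UNKNOWN", weight = 1,
                    position = 5L, read_length = 50L)
  expect_warning(fc2 <- count_features(asg, models), "transcript level only")
  expect_equal(fc2$total_count[fc2$transcript_id == "UNKNOWN"], 1)
  expect_true(is.na(fc2$cds_length[fc2$transcript_id == "UNKNOWN"]))
})

test_that("coverage bins collect read starts and conserve weight", {
  asg <- data.frame(read_id = "a", target = "S", weight = 1,
                    position = 150L, read_length = 50L)
  track <- bin_coverage(asg, "S", seq_length = 1000, bin_size = 100)
  expect_equal(length(track$values), 10L)
  expect_equal(track$values[2], 1)  # floor(150/100) -> second bin
  expect_equal(sum(track$values), 1)
  empty <- bin_coverage(asg[0, ], "S", 950, 100)
  expect_equal(length(empty$values), 10L)  # ceiling(950/100)
  expect_true(all(empty$values == 0))
  asg$position <- 1500L
  expect_error(bin_coverage(asg, "S", 1000), "outside")
})

test_that("uniform reads spread evenly over bins (binomial oracle)", {
  set.seed(77)
  n <- 1000
  asg <- data.frame(read_id = sprintf("r%d", 1:n), target = "S", weight = 1,
                    position = sample.int(1000, n, replace = TRUE) - 1L,
                    read_length = 50L)
  track <- bin_coverage(asg, "S", 1000, 100)
  expect_equal(sum(track$values), n)
  sd_bin <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(track$values - 100) < 4 * sd_bin))
})

test_that("viral coverage projects gene-local positions onto the genome", {
  ref <- toy_reference()
  # VA starts at 20: a read at gene offset 10 sits at genome position 30
  asg <- structure(list(assignments = data.frame(
    read_id = c("a", "b"), target = c("VA", "VB"), weight = 1,
    position = c(10L, 100L), read_length = 50L, stringsAsFactors = FALSE),
    status = NULL, n_reads = 2), class = "read_assignments")
  track <- viral_coverage(asg, ref$viral_model, bin_size = 100)
  expect_equal(length(track$values), 6L)
  expect_equal(track$values[1], 1)  # genome pos 30
  expect_equal(track$values[4], 1)  # 230 + 100 = 330
  expect_equal(sum(track$values), 2)
})

test_that("gene aggregation sums transcripts and picks MANE lengths", {
  models <- list(
    A1 = transcript_model("A1", "GA", "GA",
                          exons = genome_interval("A1", 0, 500),
                          cds = genome_interval("A1", 100, 400),
                          is_mane_select = TRUE),
    A2 = transcript_model("A2", "GA", "GA",
                          exons = genome_interval("A2", 0, 800),
                          cds = genome_interval("A2", 100, 400)),
    B1 = transcript_model("B1", "GB", "GB",
                          exons = genome_interval("B1", 0, 300),
                          cds = genome_interval("B1", 0, 300)))
  counts <- c(A1 = 3, A2 = 7, B1 = 5)
  cm <- aggregate_to_genes(counts, models)
  expect_equal(cm$counts["GA", 1], 10)
  expect_equal(cm$counts["GB", 1], 5)
  expect_equal(unname(cm$lengths["GA"]), 500)  # MANE, not the longest
  expect_equal(unname(cm$lengths["GB"]), 300)
  expect_warning(cm2 <- aggregate_to_genes(c(counts, ORPH = 2), models),
                 "orphan")
  expect_equal(cm2$counts["ORPH", 1], 2)
  empty <- aggregate_to_genes(setNames(numeric(), character())[0], models[0])
  expect_equal(nrow(empty$counts), 0L)
})

test_that("feature-count tables round-trip through TSV", {
  ref <- toy_reference()
  idx <- build_index(ref, k = 31)
  pool <- build_transcript_pool(ref, expression_spec(endogenous = c(TX1 = 1)))
  sim <- simulate_reads(pool, 300, 70, seed = 6)
  fc <- count_features(assign_reads(idx, sim$reads), ref)
  f <- tempfile(fileext = ".tsv")
  write_feature_counts(fc, f)
  back <- read_feature_counts(f)
  expect_equal(back$cds_count, fc$cds_count)
  expect_equal(back$total_count, fc$total_count)
  expect_error(read_feature_counts(write_tsv_tmp <- {
    tf <- tempfile(); write.table(data.frame(x = 1), tf, sep = "\t"); tf
  }), "misses column")
})
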
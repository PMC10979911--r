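# Synthetic data with the statistical structure the analysis assumes:
# endogenous CDS+UTR transcripts, exogenous CDS-only transgene copies of the
# same factors, viral gene transcripts from a delta-F genome, sequencing
# error, and passage-wise selection for vector-positive cells.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Default reprogramming-factor transcript layout
#'
#' One MANE-select transcript per Yamanaka factor (OSKM), with UTR/CDS
#' lengths matching the annotated human transcripts. Sequences built from
#' this table by [synthetic_reference()] are synthetic (random); only the
#' identifiers and feature lengths mirror the real annotation.
#'
#' @return Data frame with columns `gene_name`, `transcript_id`, `utr5`,
#'   `cds`, `utr3` (lengths in bases).
#' @export
factor_transcript_table <- function() {
  data.frame(
    gene_name = c("POU5F1", "SOX2", "KLF4", "MYC"),
    transcript_id = c("ENST00000259915", "ENST00000325404",
                      "ENST00000374672", "ENST00000621592"),
    utr5 = c(126L, 202L, 157L, 522L),
    cds = c(1083L, 954L, 1542L, 1320L),
    utr3 = c(228L, 1364L, 1250L, 537L),
    stringsAsFactors = FALSE
  )
}

#' Default Sendai virus gene layout
#'
#' Gene intervals laid out like the Sendai (murine respirovirus) genome, in
#' genome order N-P-M-F-HN-L, with F flagged as deleted from the
#' reprogramming vector.
#'
#' @return Data frame with columns `gene`, `start`, `end`, `deleted`
#'   (0-based half-open genome coordinates).
#' @export
sendai_gene_table <- function() {
  data.frame(
    gene = c("N", "P", "M", "F", "HN", "L"),
    start = c(120L, 1850L, 3810L, 5090L, 6880L, 8700L),
    end = c(1800L, 3752L, 4956L, 6788L, 8608L, 15300L),
    deleted = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic host + viral reference
#'
#' Generates random transcript sequences for the reprogramming factors (full
#' mature transcripts: 5' UTR + CDS + 3' UTR) and a random viral genome with
#' the Sendai gene layout, then assembles them into a [build_reference()]
#' reference set. The factor transcripts are flagged MANE select.
#'
#' @param factors Factor layout table (see [factor_transcript_table()]).
#' @param viral_genes Viral gene table (see [sendai_gene_table()]); `NULL`
#'   for a host-only reference.
#' @param viral_length Viral genome length in bases.
#' @param seed Integer seed for the sequence draw.
#' @return A `reference_set`.
#' @export
synthetic_reference <- function(factors = factor_transcript_table(),
                                viral_genes = sendai_gene_table(),
                                viral_length = 15384L,
                                seed = 20240312L) {
  set.seed(seed)
  models <- list()
  seqs <- character()
  for (i in seq_len(nrow(factors))) {
    f <- factors[i, ]
    len <- f$utr5 + f$cds + f$utr3
    seqs[[f$transcript_id]] <- random_dna(len)
    models[[f$transcript_id]] <- transcript_model(
      transcript_id = f$transcript_id, gene_id = f$gene_name,
      gene_name = f$gene_name,
      exons = genome_interval(f$transcript_id, 0L, len),
      cds = genome_interval(f$transcript_id, f$utr5, f$utr5 + f$cds),
      is_mane_select = TRUE
    )
  }
  if (is.null(viral_genes)) {
    return(build_reference(seqs, models))
  }
  viral_seq <- setNames(random_dna(viral_length), "SeV")
  build_reference(
    seqs, models,
    viral_sequences = viral_seq,
    viral_genes = list(genes = viral_genes[, c("gene", "start", "end")],
                       deleted_genes = viral_genes$gene[viral_genes$deleted])
  )
}

#' Specify expression levels for a simulation
#'
#' Levels are relative transcript copy numbers: `endogenous` entries emit the
#' full mature transcript (CDS + UTRs), `exogenous` entries emit CDS-only
#' copies of the same factor transcript (the vector-derived form), and
#' `viral` entries emit viral gene transcripts.
#'
#' @param endogenous,exogenous Named non-negative numeric vectors keyed by
#'   transcript id.
#' @param viral Named non-negative numeric vector keyed by viral gene name.
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(endogenous = numeric(), exogenous = numeric(),
                            viral = numeric()) {
  for (v in list(endogenous, exogenous, viral)) {
    if (length(v) && (is.null(names(v)) || any(v < 0))) {
      stop("expression levels must be named and non-negative")
    }
  }
  if (sum(endogenous) + sum(exogenous) + sum(viral) <= 0) {
    stop("at least one expression level must be positive")
  }
  structure(list(endogenous = endogenous, exogenous = exogenous,
                 viral = viral),
            class = "expression_spec")
}

#' Build the transcript pool for read simulation
#'
#' Every pool entry carries the sequence actually present in the simulated
#' cell lysate: endogenous entries use the spliced CDS+UTR sequence,
#' exogenous entries the CDS-only sequence of the same factor, and viral
#' entries the viral gene sequences. Genes listed in the viral model's
#' `deleted_genes` (e.g. F) are never emitted. Sampling weights are
#' level x sequence length, so per-base coverage is proportional to copy
#' level under the uniform fragment model.
#'
#' @param reference A `reference_set`.
#' @param spec An [expression_spec()].
#' @return Data frame with columns `id`, `origin`, `level`, `length`,
#'   `weight`, `sequence`.
#' @export
build_transcript_pool <- function(reference, spec) {
  stopifnot(inherits(spec, "expression_spec"))
  entries <- list()
  add <- function(id, origin, level, sequence) {
    entries[[length(entries) + 1]] <<- data.frame(
      id = id, origin = origin, level = level,
      length = nchar(sequence), weight = level * nchar(sequence),
      sequence = sequence, stringsAsFactors = FALSE)
  }
  for (tid in names(spec$endogenous)) {
    if (spec$endogenous[[tid]] <= 0) next
    if (!tid %in% names(reference$annotation)) {
      stop(sprintf("unknown transcript id '%s' in expression spec", tid))
    }
    add(tid, "endogenous", spec$endogenous[[tid]],
        transcript_sequence(reference, tid, "exon"))
  }
  for (tid in names(spec$exogenous)) {
    if (spec$exogenous[[tid]] <= 0) next
    if (!tid %in% names(reference$annotation)) {
      stop(sprintf("unknown transcript id '%s' in expression spec", tid))
    }
    add(paste0(tid, "|exogenous"), "exogenous", spec$exogenous[[tid]],
        transcript_sequence(reference, tid, "cds"))
  }
  if (length(spec$viral)) {
    vm <- reference$viral_model
    if (is.null(vm)) stop("reference has no viral model")
    for (g in names(spec$viral)) {
      if (spec$viral[[g]] <= 0) next
      if (!g %in% vm$genes$gene) {
        stop(sprintf("unknown viral gene '%s'", g))
      }
      if (g %in% vm$deleted_genes) next  # absent from the vector
      add(g, "viral", spec$viral[[g]],
          transcript_sequence(reference, g, "exon"))
    }
  }
  if (length(entries) == 0) stop("expression spec produced an empty pool")
  out <- do.call(rbind, entries)
  rownames(out) <- NULL
  out
}

#' Simulate single-end reads from a transcript pool
#'
#' Sources are drawn with probability proportional to their pool weight and
#' read start positions uniformly within each source. By default sampling is
#' circular (reads crossing the 3' end wrap to the 5' end), which makes the
#' expected per-base sampling depth exactly uniform along every source —
#' the steady-state coverage model the CDS/UTR ratio statistic assumes.
#' With `circular = FALSE` reads are plain substrings (starts restricted to
#' `[0, length - read_length]`), which reproduces transcript-end coverage
#' deficits. Substitution errors are applied per base at `error_rate`.
#'
#' @param pool Data frame from [build_transcript_pool()].
#' @param n_reads Number of reads.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param circular Logical; see above.
#' @return A list with `reads` (named character vector of read sequences)
#'   and `truth` (data frame `read_id`, `source_id`, `origin`, `start`).
#' @export
simulate_reads <- function(pool, n_reads, read_length = 100L,
                           error_rate = 0, seed = 1L, circular = TRUE) {
  stopifnot(n_reads > 0, read_length >= 1, error_rate >= 0, error_rate <= 1)
  short <- pool$length < read_length
  if (any(short)) {
    warning(sprintf("rejecting %d pool entr%s shorter than the read length: %s",
                    sum(short), if (sum(short) == 1) "y" else "ies",
                    paste(pool$id[short], collapse = ", ")))
    pool <- pool[!short, , drop = FALSE]
  }
  if (nrow(pool) == 0) stop("no pool entry is long enough to simulate from")
  set.seed(seed)
  src <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = pool$weight)
  len <- pool$length[src]
  if (circular) {
    start <- as.integer(floor(runif(n_reads) * len))
    padded <- paste0(pool$sequence,
                     substr(pool$sequence, 1L, read_length - 1L))
    reads <- substr(padded[src], start + 1L, start + read_length)
  } else {
    start <- as.integer(floor(runif(n_reads) * (len - read_length + 1L)))
    reads <- substr(pool$sequence[src], start + 1L, start + read_length)
  }
  if (error_rate > 0) {
    n_bases <- n_reads * read_length
    n_err <- rbinom(1L, n_bases, error_rate)
    if (n_err > 0) {
      at <- sample.int(n_bases, n_err)
      repl <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
      ridx <- ((at - 1L) %/% read_length) + 1L
      bpos <- ((at - 1L) %% read_length) + 1L
      for (i in seq_len(n_err)) {
        old <- substr(reads[ridx[i]], bpos[i], bpos[i])
        if (repl[i] == old) {  # force a real substitution
          repl[i] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
        substr(reads[ridx[i]], bpos[i], bpos[i]) <- repl[i]
      }
    }
  }
  ids <- sprintf("read%07d", seq_len(n_reads))
  names(reads) <- ids
  list(
    reads = reads,
    truth = data.frame(read_id = ids, source_id = pool$id[src],
                       origin = pool$origin[src], start = start,
                       stringsAsFactors = FALSE)
  )
}

#' Write reads to FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path (`.gz` for gzip compression).
#' @param quality_char Constant per-base quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (plain or gzip).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Simulate serial-passage selection for vector-positive cells
#'
#' The vector-positive cell fraction evolves by the replicator (odds) update
#' `odds_{t+1} = w * odds_t` with `odds = p / (1 - p)`: cells with
#' persistent vector expression out-compete negative cells by a factor `w`
#' per passage. The expected measured viral expression at passage `t` is
#' `p_t * per_cell_viral_expression` (a TPM-scale quantity); observed
#' expression is obtained by Poisson sampling at `sampling_depth` reads.
#'
#' @param p0 Initial vector-positive fraction, in `(0, 1]`.
#' @param w Per-passage growth advantage (fold enrichment), `> 0`.
#' @param n_passages Number of passages; the series covers passages
#'   `0..n_passages`.
#' @param per_cell_viral_expression Expected viral TPM of a fully
#'   vector-positive culture (`p = 1`).
#' @param sampling_depth Reads drawn per sample for the Poisson observation.
#' @param seed Integer seed.
#' @return A `passage_series` data frame with columns `passage`,
#'   `positive_fraction`, `expected_expression`, `viral_count`,
#'   `viral_expression`.
#' @export
simulate_passages <- function(p0, w, n_passages,
                              per_cell_viral_expression = 1e4,
                              sampling_depth = 1e6, seed = 1L) {
  stopifnot(p0 > 0, p0 <= 1, w > 0, n_passages >= 1,
            per_cell_viral_expression >= 0, sampling_depth > 0)
  t <- 0:n_passages
  if (p0 == 1) {
    p <- rep(1, length(t))
  } else {
    odds <- p0 / (1 - p0) * w^t
    p <- odds / (1 + odds)
  }
  expected <- p * per_cell_viral_expression
  set.seed(seed)
  counts <- rpois(length(t), sampling_depth * expected / 1e6)
  out <- data.frame(
    passage = t,
    positive_fraction = p,
    expected_expression = expected,
    viral_count = counts,
    viral_expression = counts / sampling_depth * 1e6
  )
  class(out) <- c("passage_series", "data.frame")
  out
}

#' Write a passage series to TSV
#'
#' @param series A `passage_series` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_passage_series <- function(series, path) {
  write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a read truth table to TSV
#'
#' @param truth Truth data frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
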
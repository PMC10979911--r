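# Exact k-mer voting read assignment (stand-in for an external aligner),
# feature-level counting and binned coverage tracks.

#' Build a k-mer index over a reference
#'
#' Every length-`k` substring of every target sequence (and its reverse
#' complement, via canonicalization) becomes queryable. For a
#' `reference_set` the targets are the spliced transcript sequences of all
#' annotated models (host transcripts and viral genes alike).
#'
#' @param x A `reference_set` or a named character vector of sequences.
#' @param k Odd k-mer size, `<= 31`.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(x, k = 31L) {
  if (inherits(x, "reference_set")) {
    seqs <- vapply(x$annotation, function(m)
      transcript_sequence(x, m, "exon"), character(1))
  } else {
    if (is.null(names(x))) stop("sequences must be named")
    seqs <- x
  }
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd (strand canonicalization)")
  if (k < 1L || k > 31L) stop("k must be in [1, 31]")
  short <- nchar(seqs) < k
  if (any(short)) {
    warning(sprintf("skipping %d sequence(s) shorter than k: %s",
                    sum(short), paste(names(seqs)[short], collapse = ", ")))
    seqs <- seqs[!short]
  }
  if (length(seqs) == 0) stop("no sequence long enough to index")
  ptr <- .kmer_index_build(unname(seqs), names(seqs), k)
  structure(
    list(ptr = ptr, k = k, targets = names(seqs),
         lengths = setNames(nchar(seqs), names(seqs))),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d target(s), %.0f indexed positions\n",
              x$k, length(x$targets), .kmer_index_size(x$ptr)))
  invisible(x)
}

#' Query a single k-mer against an index
#'
#' @param index A `kmer_index`.
#' @param kmer Character scalar of length `k`.
#' @return Data frame of hits: `target`, `offset` (0-based), `same_strand`.
#' @export
query_kmer <- function(index, kmer) {
  .kmer_index_query(index$ptr, as.character(kmer)[1])
}

default_min_votes <- function(read_length, k) {
  # tolerates roughly three substitutions (each can erase up to k votes);
  # floors at one so short reads remain assignable
  pmax(1L, as.integer(read_length) - k + 1L - 3L * k)
}

#' Assign reads to reference targets by k-mer voting
#'
#' Each read k-mer votes for every target it occurs in; targets with the
#' maximal vote count win. A single winner gives a `unique` assignment,
#' several tied winners an `ambiguous` assignment with equal fractional
#' weights, and fewer than `min_votes` votes leaves the read `unassigned`.
#' The reported position is the read's 5'-most matched base on the target
#' (the leftmost k-mer hit on the majority vote diagonal) — soft-clip
#' semantics, so unmatched read prefixes never extend the placement.
#'
#' @param index A `kmer_index`.
#' @param reads Named character vector (or `DNAStringSet`) of reads.
#' @param min_votes Minimum winning vote count; default
#'   `max(1, read_length - k + 1 - 3k)` per read.
#' @return An object of class `read_assignments`: list with `assignments`
#'   (data frame `read_id`, `target`, `weight`, `position`, `read_length`),
#'   `status` (data frame `read_id`, `status`) and `n_reads`.
#' @export
assign_reads <- function(index, reads, min_votes = NULL) {
  if (inherits(reads, "DNAStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%07d", seq_along(reads))
  }
  rl <- nchar(reads)
  if (any(rl < index$k)) {
    # reads shorter than k can never vote; they come back unassigned
    short <- rl < index$k
    reads[short] <- strrep("N", index$k)
  }
  mv <- if (is.null(min_votes)) {
    default_min_votes(rl, index$k)
  } else {
    rep_len(as.integer(min_votes), length(reads))
  }
  res <- .kmer_assign(index$ptr, unname(reads), mv)
  status <- c("unassigned", "unique", "ambiguous")[res$status + 1L]
  asg <- data.frame(
    read_id = names(reads)[res$read],
    target = index$targets[res$target],
    weight = res$weight,
    position = res$position,
    read_length = rl[res$read],
    stringsAsFactors = FALSE
  )
  # wrap positions of circularly sampled reads into the target
  tl <- unname(index$lengths[asg$target])
  asg$position <- ((asg$position %% tl) + tl) %% tl
  structure(
    list(assignments = asg,
         status = data.frame(read_id = names(reads), status = status,
                             stringsAsFactors = FALSE),
         n_reads = length(reads)),
    class = "read_assignments"
  )
}

#' Assign a single read
#'
#' @param index A `kmer_index`.
#' @param read Character scalar.
#' @param min_votes See [assign_reads()].
#' @return List with `status`, `targets` (named weight vector) and
#'   `position`.
#' @export
assign_read <- function(index, read, min_votes = NULL) {
  res <- assign_reads(index, c(read1 = unname(read)), min_votes = min_votes)
  list(status = res$status$status[1],
       targets = setNames(res$assignments$weight, res$assignments$target),
       position = if (nrow(res$assignments)) res$assignments$position[1]
                  else NA_integer_)
}

#' @export
print.read_assignments <- function(x, ...) {
  tab <- table(factor(x$status$status,
                      levels = c("unique", "ambiguous", "unassigned")))
  cat(sprintf("<read_assignments> %d read(s): %d unique, %d ambiguous, %d unassigned\n",
              x$n_reads, tab[["unique"]], tab[["ambiguous"]],
              tab[["unassigned"]]))
  invisible(x)
}

#' Count reads per transcript feature (CDS, 5' UTR, 3' UTR)
#'
#' Positions are transcript-local (as produced by [assign_reads()] against
#' spliced transcript targets). With `count_mode = "start"` (default) each
#' read contributes its assignment weight to the single feature containing
#' its 5'-most base — the same convention as [bin_coverage()], which keeps
#' weight conservation exact and the CDS/UTR density ratio unbiased under
#' uniform fragment sampling. With `count_mode = "overlap"` a read
#' contributes its full weight to every feature its span overlaps by at
#' least one base (junction reads count twice).
#'
#' @param assignments A `read_assignments` object (or its `assignments`
#'   data frame).
#' @param models Named list of `transcript_model`s (or a `reference_set`).
#' @param count_mode `"start"` or `"overlap"`.
#' @return Data frame with one row per target: `transcript_id`,
#'   `cds_count`, `utr5_count`, `utr3_count`, `total_count`, `cds_length`,
#'   `utr5_length`, `utr3_length`.
#' @export
count_features <- function(assignments, models,
                           count_mode = c("start", "overlap")) {
  count_mode <- match.arg(count_mode)
  asg <- if (inherits(assignments, "read_assignments")) {
    assignments$assignments
  } else {
    assignments
  }
  if (inherits(models, "reference_set")) models <- models$annotation
  layout <- do.call(rbind, lapply(names(models), function(id) {
    fm <- feature_map(models[[id]])
    data.frame(transcript_id = id, utr5_length = fm[["utr5"]],
               cds_length = fm[["cds"]], utr3_length = fm[["utr3"]],
               stringsAsFactors = FALSE)
  }))
  targets <- unique(asg$target)
  extra <- setdiff(targets, layout$transcript_id)
  if (length(extra)) {
    warning(sprintf("no transcript model for target(s) %s; counted at transcript level only",
                    paste(extra, collapse = ", ")))
  }
  out <- layout
  out$cds_count <- 0
  out$utr5_count <- 0
  out$utr3_count <- 0
  out$total_count <- 0
  if (length(extra)) {
    ex <- data.frame(transcript_id = extra, utr5_length = NA_integer_,
                     cds_length = NA_integer_, utr3_length = NA_integer_,
                     cds_count = 0, utr5_count = 0, utr3_count = 0,
                     total_count = 0, stringsAsFactors = FALSE)
    out <- rbind(out, ex)
  }
  rownames(out) <- out$transcript_id
  if (nrow(asg)) {
    tot <- tapply(asg$weight, asg$target, sum)
    out[names(tot), "total_count"] <- as.numeric(tot)
    known <- asg$target %in% layout$transcript_id
    a <- asg[known, , drop = FALSE]
    if (nrow(a)) {
      u5 <- out[a$target, "utr5_length"]
      cl <- out[a$target, "cds_length"]
      u3 <- out[a$target, "utr3_length"]
      len <- u5 + cl + u3
      if (count_mode == "start") {
        in5 <- a$position < u5
        inc <- !in5 & a$position < u5 + cl
        in3 <- !in5 & !inc
      } else {
        rend <- pmin(a$position + a$read_length, len)  # clip at 3' end
        in5 <- a$position < u5
        inc <- a$position < u5 + cl & rend > u5
        in3 <- rend > u5 + cl
      }
      add <- function(col, sel) {
        if (!any(sel)) return()
        s <- tapply(a$weight[sel], a$target[sel], sum)
        out[names(s), col] <<- out[names(s), col] + as.numeric(s)
      }
      add("utr5_count", in5)
      add("cds_count", inc)
      add("utr3_count", in3)
    }
  }
  rownames(out) <- NULL
  out[, c("transcript_id", "cds_count", "utr5_count", "utr3_count",
          "total_count", "cds_length", "utr5_length", "utr3_length")]
}

#' Total assigned weight per target
#'
#' @param assignments A `read_assignments` object.
#' @return Named numeric vector of summed assignment weights.
#' @export
transcript_counts <- function(assignments) {
  asg <- assignments$assignments
  if (nrow(asg) == 0) return(setNames(numeric(), character()))
  s <- tapply(asg$weight, asg$target, sum)
  setNames(as.numeric(s), names(s))
}

#' Bin assigned reads into a coverage track
#'
#' Each assigned read adds its weight to the bin containing its 5'-most
#' base, so track values sum exactly to the assigned weight on the
#' sequence.
#'
#' @param assignments A `read_assignments` object or a data frame with
#'   columns `target`, `position`, `weight`.
#' @param seq_id Target sequence to extract.
#' @param seq_length Sequence length in bases.
#' @param bin_size Bin width in bases (default 100).
#' @return An object of class `coverage_track`: list with `seq_id`,
#'   `bin_size`, `values` (length `ceiling(seq_length / bin_size)`).
#' @export
bin_coverage <- function(assignments, seq_id, seq_length, bin_size = 100L) {
  asg <- if (inherits(assignments, "read_assignments")) {
    assignments$assignments
  } else {
    assignments
  }
  asg <- asg[asg$target == seq_id, , drop = FALSE]
  n_bins <- as.integer(ceiling(seq_length / bin_size))
  values <- numeric(n_bins)
  if (nrow(asg)) {
    if (any(asg$position < 0 | asg$position >= seq_length)) {
      stop("assignment position outside [0, seq_length)")
    }
    bin <- asg$position %/% bin_size + 1L
    s <- tapply(asg$weight, bin, sum)
    values[as.integer(names(s))] <- as.numeric(s)
  }
  structure(list(seq_id = seq_id, bin_size = as.integer(bin_size),
                 values = values),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bins of %d bp, total weight %.2f\n",
              x$seq_id, length(x$values), x$bin_size, sum(x$values)))
  invisible(x)
}

#' Project viral gene assignments onto the viral genome
#'
#' Viral genes are quantified as transcript targets; this projects their
#' transcript-local read positions through the gene intervals back onto the
#' viral genome and bins the result into one genome-wide coverage track.
#'
#' @param assignments A `read_assignments` object.
#' @param viral_model A `viral_genome_model`.
#' @param bin_size Bin width in bases.
#' @return A `coverage_track` over the viral genome.
#' @export
viral_coverage <- function(assignments, viral_model, bin_size = 100L) {
  asg <- assignments$assignments
  asg <- asg[asg$target %in% viral_model$genes$gene, , drop = FALSE]
  if (nrow(asg)) {
    offset <- setNames(viral_model$genes$start, viral_model$genes$gene)
    asg$position <- asg$position + unname(offset[asg$target])
    asg$target <- viral_model$seq_id
  }
  bin_coverage(asg, viral_model$seq_id, viral_model$length, bin_size)
}

#' Aggregate transcript counts to gene level
#'
#' Gene counts are the sum of the gene's transcript counts; the gene length
#' is the exon length of the MANE transcript when one is flagged, otherwise
#' the longest transcript. Targets without a transcript model are kept
#' under their own id (length taken from `orphan_lengths` when provided).
#'
#' @param tx_counts Named numeric vector (single sample) or matrix
#'   (transcripts x samples) of transcript counts.
#' @param annotation Named list of `transcript_model`s or a
#'   `reference_set`.
#' @param orphan_lengths Optional named lengths for targets without models.
#' @return A `count_matrix`: list with `counts` (genes x samples matrix)
#'   and `lengths` (named vector).
#' @export
aggregate_to_genes <- function(tx_counts, annotation,
                               orphan_lengths = NULL) {
  if (inherits(annotation, "reference_set")) {
    annotation <- annotation$annotation
  }
  if (is.null(dim(tx_counts))) {
    tx_counts <- matrix(tx_counts, ncol = 1,
                        dimnames = list(names(tx_counts), "sample1"))
  }
  ids <- rownames(tx_counts)
  known <- ids %in% names(annotation)
  if (any(!known)) {
    warning(sprintf("orphan transcript(s) kept under their own id: %s",
                    paste(ids[!known], collapse = ", ")))
  }
  gene <- ifelse(known,
                 vapply(ids, function(i) {
                   if (i %in% names(annotation))
                     annotation[[i]]$gene_name else i
                 }, character(1)),
                 ids)
  counts <- rowsum(tx_counts, group = gene)
  lengths <- setNames(numeric(nrow(counts)), rownames(counts))
  for (g in rownames(counts)) {
    members <- ids[gene == g & known]
    if (length(members)) {
      models <- annotation[members]
      mane <- Filter(function(m) m$is_mane_select, models)
      pick <- if (length(mane) == 1) {
        mane[[1]]
      } else {
        models[[which.max(vapply(models, function(m)
          interval_width(m$exons), numeric(1)))]]
      }
      lengths[g] <- interval_width(pick$exons)
    } else if (!is.null(orphan_lengths) && g %in% names(orphan_lengths)) {
      lengths[g] <- orphan_lengths[[g]]
    } else {
      lengths[g] <- NA_real_
    }
  }
  count_matrix(counts, lengths)
}

#' Construct a count matrix
#'
#' @param counts Non-negative numeric matrix, features x samples.
#' @param lengths Named numeric vector of feature lengths.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)]
    if (any(!is.na(lengths) & lengths <= 0)) {
      stop("feature lengths must be positive")
    }
  }
  structure(list(counts = counts, lengths = lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d feature(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

# ---- tabular / track I/O ---------------------------------------------------

#' Write per-feature counts to TSV
#'
#' @param fc Data frame from [count_features()].
#' @param path Output path.
#' @param sample_id Optional sample id column to prepend.
#' @return `path`, invisibly.
#' @export
write_feature_counts <- function(fc, path, sample_id = NULL) {
  if (!is.null(sample_id)) fc <- cbind(sample_id = sample_id, fc)
  write.table(fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-feature count table
#'
#' The bridge for externally quantified data: a TSV with columns
#' `transcript_id`, `cds_count`, `utr5_count`, `utr3_count`, `cds_length`,
#' `utr5_length`, `utr3_length` (and optionally `total_count`,
#' `sample_id`) can feed [cds_utr_ratio()] directly.
#'
#' @param path TSV path.
#' @return Data frame in [count_features()] layout.
#' @export
read_feature_counts <- function(path) {
  fc <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_count", "utr5_count", "utr3_count",
            "cds_length", "utr5_length", "utr3_length")
  miss <- setdiff(need, names(fc))
  if (length(miss)) {
    stop(sprintf("feature-count table misses column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (!"total_count" %in% names(fc)) {
    fc$total_count <- fc$cds_count + fc$utr5_count + fc$utr3_count
  }
  fc
}

#' Write a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param seq_length Optional sequence length to clip the last bin end.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, seq_length = NULL) {
  n <- length(track$values)
  start <- (seq_len(n) - 1L) * track$bin_size
  end <- start + track$bin_size
  if (!is.null(seq_length)) end[n] <- min(end[n], seq_length)
  df <- data.frame(seq_id = track$seq_id, start = start, end = end,
                   value = track$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
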
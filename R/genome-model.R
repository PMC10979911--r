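# Transcript and viral genome models, GTF/FASTA ingestion, and construction
# of the combined host + viral reference that the quantifier runs against.

#' Construct a transcript model
#'
#' A transcript model carries the exon structure of one transcript together
#' with its CDS and derived 5'/3' UTRs, all as 0-based half-open intervals on
#' one strand of one sequence. CDS, 5' UTR and 3' UTR together tile the exon
#' bases exactly (no gaps, no overlaps); this invariant is enforced here.
#'
#' @param transcript_id,gene_id,gene_name Identifier strings.
#' @param exons,cds,utr5,utr3 Interval data frames (see [genome_interval()]).
#' @param is_mane_select Logical; whether this is the MANE-select transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name, exons, cds,
                             utr5 = NULL, utr3 = NULL,
                             is_mane_select = FALSE) {
  strand <- exons$strand[1]
  if (is.null(utr5) || is.null(utr3)) {
    u <- derive_utrs(exons, cds, strand)
    utr5 <- u$utr5
    utr3 <- u$utr3
  }
  obj <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         gene_name = as.character(gene_name),
         exons = validate_intervals(exons[order(exons$start), , drop = FALSE]),
         cds = validate_intervals(cds[order(cds$start), , drop = FALSE]),
         utr5 = validate_intervals(utr5[order(utr5$start), , drop = FALSE]),
         utr3 = validate_intervals(utr3[order(utr3$start), , drop = FALSE]),
         is_mane_select = isTRUE(is_mane_select)),
    class = "transcript_model"
  )
  for (f in c("exons", "cds", "utr5", "utr3")) rownames(obj[[f]]) <- NULL
  validate_transcript_model(obj)
}

#' Validate a transcript model
#'
#' Checks the tiling invariant: CDS + UTR5 + UTR3 cover the exon bases
#' exactly, pairwise disjointly.
#'
#' @param x A `transcript_model`.
#' @return `x` on success; errors otherwise.
#' @export
validate_transcript_model <- function(x) {
  stopifnot(inherits(x, "transcript_model"))
  if (nrow(x$exons) == 0) stop("transcript must have at least one exon")
  if (length(unique(x$exons$strand)) != 1) {
    stop("all exons must share one strand")
  }
  w <- interval_width(x$cds) + interval_width(x$utr5) + interval_width(x$utr3)
  if (w != interval_width(x$exons)) {
    stop("tiling violation: CDS + UTRs do not sum to the exon length")
  }
  parts <- rbind(x$cds, x$utr5, x$utr3)
  if (nrow(parts) > 0) {
    parts <- parts[order(parts$start), , drop = FALSE]
    if (any(parts$start[-1] < parts$end[-nrow(parts)])) {
      stop("tiling violation: CDS/UTR features overlap")
    }
    if (!identical(merge_intervals(parts)[, c("start", "end")],
                   merge_intervals(x$exons)[, c("start", "end")])) {
      stop("tiling violation: CDS/UTR features do not cover the exons")
    }
  }
  x
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s/%s) strand %s: %d exon(s), CDS %d bp, 5'UTR %d bp, 3'UTR %d bp%s\n",
    x$transcript_id, x$gene_id, x$gene_name, x$exons$strand[1],
    nrow(x$exons), interval_width(x$cds), interval_width(x$utr5),
    interval_width(x$utr3), if (x$is_mane_select) " [MANE select]" else ""))
  invisible(x)
}

#' Derive 5' and 3' UTRs from exon and CDS intervals
#'
#' Exon bases 5' of the first CDS base (in transcript orientation) become the
#' 5' UTR; bases 3' of the last CDS base become the 3' UTR. On the minus
#' strand the genomic ends swap roles.
#'
#' @param exons,cds Interval data frames; CDS bases must lie within exons and
#'   the CDS must be contiguous in transcript coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A list with interval data frames `utr5` and `utr3`.
#' @export
#' @examples
#' ex <- genome_interval("chr1", 0, 300)
#' cds <- genome_interval("chr1", 100, 200)
#' derive_utrs(ex, cds, "+")
derive_utrs <- function(exons, cds, strand) {
  validate_intervals(exons)
  validate_intervals(cds)
  stopifnot(strand %in% c("+", "-"))
  empty <- genome_interval(character(), integer(), integer(), character())
  if (nrow(cds) == 0) stop("CDS is empty; cannot derive UTRs")
  if (!intervals_within(cds, exons)) {
    stop("validation error: CDS not contained in exons")
  }
  cmin <- min(cds$start)
  cmax <- max(cds$end)
  # contiguity in transcript coordinates: every exon base in [cmin, cmax)
  # must be a CDS base
  if (interval_width(clip_intervals(exons, cmin, cmax)) !=
      interval_width(cds)) {
    stop("CDS is not contiguous in transcript coordinates")
  }
  left <- clip_intervals(exons, -1L, cmin)
  right <- clip_intervals(exons, cmax, .Machine$integer.max)
  if (nrow(left)) left$strand <- strand
  if (nrow(right)) right$strand <- strand
  if (strand == "+") {
    list(utr5 = left, utr3 = right)
  } else {
    list(utr5 = right, utr3 = left)
  }
}

# ---- GTF I/O ---------------------------------------------------------------

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
  ifelse(lengths(regmatches(attrs, gregexpr(sprintf('%s "', key), attrs))) > 0 &
           nchar(m) > 0,
         sub(sprintf('%s "([^"]*)"', key), "\\1", m), NA_character_)
}

#' Load transcript models from a GTF annotation
#'
#' Parses `exon`, `CDS` and `stop_codon` features (the GTF 1-based inclusive
#' convention is converted to internal 0-based half-open coordinates).
#' Stop codons annotated outside the CDS are folded into it so the
#' CDS/UTR tiling invariant holds. UTRs are then derived with
#' [derive_utrs()]. Transcripts are flagged MANE select when any of their
#' lines carries a `tag "MANE_Select"` attribute.
#'
#' @param x Path to a GTF file, or a character scalar containing GTF text
#'   (recognized by embedded newlines).
#' @return A named list of [transcript_model()] objects, keyed by
#'   `transcript_id`.
#' @export
load_annotation <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  keep_features <- c("exon", "CDS", "stop_codon")
  recs <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    }
    if (!(f[3] %in% keep_features)) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start) {
      stop(sprintf("malformed GTF line %d: bad coordinates '%s'-'%s'",
                   i, f[4], f[5]))
    }
    tid <- gtf_attr(f[9], "transcript_id")
    if (is.na(tid)) {
      stop(sprintf("malformed GTF line %d: missing transcript_id", i))
    }
    recs[[length(recs) + 1]] <- data.frame(
      transcript_id = tid,
      gene_id = gtf_attr(f[9], "gene_id"),
      gene_name = gtf_attr(f[9], "gene_name"),
      seq_id = f[1], feature = f[3],
      start = start - 1L, end = end,  # to 0-based half-open
      strand = f[7],
      mane = grepl('tag "MANE_Select"', f[9], fixed = TRUE),
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0) stop("no exon/CDS features found in GTF input")
  tab <- do.call(rbind, recs)
  models <- lapply(split(tab, tab$transcript_id), function(tx) {
    exons <- genome_interval(tx$seq_id[tx$feature == "exon"],
                             tx$start[tx$feature == "exon"],
                             tx$end[tx$feature == "exon"],
                             tx$strand[tx$feature == "exon"])
    if (nrow(exons) == 0) {
      stop(sprintf("transcript %s has no exon features", tx$transcript_id[1]))
    }
    cds_rows <- tx$feature %in% c("CDS", "stop_codon")
    cds <- genome_interval(tx$seq_id[cds_rows], tx$start[cds_rows],
                           tx$end[cds_rows], tx$strand[cds_rows])
    if (nrow(cds) == 0) {
      stop(sprintf("transcript %s has no CDS; only coding transcripts are supported",
                   tx$transcript_id[1]))
    }
    cds <- merge_intervals(cds)  # fold stop codon into adjacent CDS
    if (!intervals_within(cds, exons)) {
      stop(sprintf("validation error: CDS outside exons for transcript %s",
                   tx$transcript_id[1]))
    }
    gname <- tx$gene_name[!is.na(tx$gene_name)]
    transcript_model(
      transcript_id = tx$transcript_id[1],
      gene_id = tx$gene_id[1],
      gene_name = if (length(gname)) gname[1] else tx$gene_id[1],
      exons = exons, cds = cds,
      is_mane_select = any(tx$mane)
    )
  })
  models[order(names(models))]
}

#' Write transcript models to GTF
#'
#' Emits `exon` and `CDS` lines (stop codons are part of the CDS) in the
#' 1-based inclusive GTF convention; re-parsing with [load_annotation()]
#' reproduces the models exactly.
#'
#' @param models A `transcript_model` or list of them.
#' @param path Output file path, or `NULL` to return the GTF text.
#' @return The GTF lines, invisibly when written to a file.
#' @export
write_annotation_gtf <- function(models, path = NULL) {
  if (inherits(models, "transcript_model")) models <- list(models)
  lines <- unlist(lapply(models, function(m) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";%s',
                     m$gene_id, m$transcript_id, m$gene_name,
                     if (m$is_mane_select) ' tag "MANE_Select";' else "")
    fmt <- function(iv, feature) {
      if (nrow(iv) == 0) return(character())
      sprintf("%s\tsendaiqc\t%s\t%d\t%d\t.\t%s\t.\t%s",
              iv$seq_id, feature, iv$start + 1L, iv$end, iv$strand, attrs)
    }
    c(fmt(m$exons, "exon"), fmt(m$cds, "CDS"))
  }), use.names = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Select the MANE-select transcript of a gene
#'
#' @param annotation List of `transcript_model`s (see [load_annotation()]).
#' @param gene_name Gene symbol to look up.
#' @return The unique MANE-select `transcript_model` for the gene.
#' @export
select_mane <- function(annotation, gene_name) {
  hits <- Filter(function(m) m$gene_name == gene_name && m$is_mane_select,
                 annotation)
  if (length(hits) == 0) {
    stop(sprintf("no MANE transcript annotated for gene '%s'", gene_name))
  }
  if (length(hits) > 1) {
    stop(sprintf("ambiguous MANE annotation for gene '%s': %s", gene_name,
                 paste(vapply(hits, `[[`, "", "transcript_id"),
                       collapse = ", ")))
  }
  hits[[1]]
}

# ---- viral genome model ----------------------------------------------------

#' Construct a viral genome model
#'
#' @param seq_id Sequence identifier of the viral genome.
#' @param length Genome length in bases.
#' @param genes Data frame with columns `gene`, `start`, `end` (0-based
#'   half-open intervals on the genome) and optionally `strand` (default
#'   `"+"`).
#' @param deleted_genes Character vector of gene names known to be absent
#'   from the vector (e.g. `"F"` for the commercial kit) but whose intervals
#'   are retained for coverage reporting.
#' @return An object of class `viral_genome_model`.
#' @export
viral_genome_model <- function(seq_id, length, genes,
                               deleted_genes = character()) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "start", "end") %in% names(genes)))
  if (is.null(genes$strand)) genes$strand <- "+"
  if (any(genes$start < 0) || any(genes$end > length) ||
      any(genes$start >= genes$end)) {
    stop("viral gene intervals must lie within [0, genome length)")
  }
  if (anyDuplicated(genes$gene)) stop("duplicated viral gene names")
  structure(
    list(seq_id = as.character(seq_id), length = as.integer(length),
         genes = genes[, c("gene", "start", "end", "strand")],
         deleted_genes = as.character(deleted_genes)),
    class = "viral_genome_model"
  )
}

#' @export
print.viral_genome_model <- function(x, ...) {
  cat(sprintf("<viral_genome_model> %s (%d bp): %d gene(s)%s\n",
              x$seq_id, x$length, nrow(x$genes),
              if (length(x$deleted_genes))
                sprintf(", deleted in vector: %s",
                        paste(x$deleted_genes, collapse = ",")) else ""))
  invisible(x)
}

#' Read a viral gene table
#'
#' The TSV has columns `gene`, `start`, `end` (0-based half-open genome
#' coordinates) and `deleted` (logical or 0/1).
#'
#' @param path Path to the TSV.
#' @return A list with `genes` (data frame) and `deleted_genes` (character),
#'   ready for [viral_genome_model()].
#' @export
read_viral_genes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "start", "end") %in% names(tab)))
  deleted <- if ("deleted" %in% names(tab)) {
    tab$gene[as.logical(tab$deleted)]
  } else {
    character()
  }
  list(genes = tab[, c("gene", "start", "end")], deleted_genes = deleted)
}

# ---- reference set ---------------------------------------------------------

as_sequence_set <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
             file.exists(x)) {
    seqs <- Biostrings::readDNAStringSet(x)
    # FASTA headers may carry descriptions; keep the first token as the id
    setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x
  } else {
    stop("unsupported sequence input")
  }
}

#' Build a combined host + viral reference
#'
#' Concatenates host transcript sequences and annotation with the viral
#' genome into one namespace. Viral genes become single-exon, UTR-less
#' transcript models on the plus strand of the viral sequence so the
#' quantifier treats host and viral targets uniformly. On a `seq_id`
#' collision between host and viral sequences the viral ids are prefixed
#' with `prefix` (set `prefix = NULL` to make collisions an error).
#'
#' @param host_sequences FASTA path, `DNAStringSet`, or named character
#'   vector of host sequences (one entry per annotated `seq_id`).
#' @param host_annotation GTF path/text or list of `transcript_model`s.
#' @param viral_sequences Optional FASTA path/`DNAStringSet`/named character
#'   with the viral genome.
#' @param viral_genes Optional `viral_genome_model`, or list with elements
#'   `genes` and `deleted_genes` (see [read_viral_genes()]).
#' @param prefix Namespacing prefix applied to viral seq_ids on collision.
#' @return An object of class `reference_set` with elements `sequences`
#'   (named character), `origin` (named character, `"host"`/`"viral"`),
#'   `annotation` (named list of `transcript_model`s) and `viral_model`
#'   (`viral_genome_model` or `NULL`).
#' @export
build_reference <- function(host_sequences, host_annotation,
                            viral_sequences = NULL, viral_genes = NULL,
                            prefix = "viral|") {
  host_seqs <- as_sequence_set(host_sequences)
  annotation <- if (is.list(host_annotation) &&
                    all(vapply(host_annotation, inherits, TRUE,
                               "transcript_model"))) {
    setNames(host_annotation,
             vapply(host_annotation, `[[`, "", "transcript_id"))
  } else {
    load_annotation(host_annotation)
  }
  missing <- setdiff(unique(unlist(lapply(annotation,
                                          function(m) m$exons$seq_id))),
                     names(host_seqs))
  if (length(missing)) {
    stop(sprintf("annotated seq_id(s) absent from host sequences: %s",
                 paste(missing, collapse = ", ")))
  }
  origin <- setNames(rep("host", length(host_seqs)), names(host_seqs))
  viral_model <- NULL
  if (!is.null(viral_sequences)) {
    vseqs <- as_sequence_set(viral_sequences)
    if (length(vseqs) == 0) {
      vseqs <- NULL
    }
  } else {
    vseqs <- NULL
  }
  if (!is.null(vseqs)) {
    if (length(vseqs) != 1) stop("expected a single viral genome sequence")
    if (is.null(viral_genes)) stop("viral_genes required with viral sequence")
    vm <- if (inherits(viral_genes, "viral_genome_model")) {
      viral_genes
    } else {
      viral_genome_model(names(vseqs)[1], nchar(vseqs[[1]]),
                         viral_genes$genes, viral_genes$deleted_genes)
    }
    vid <- names(vseqs)[1]
    if (vid %in% names(host_seqs)) {
      if (is.null(prefix)) {
        stop(sprintf("seq_id collision between host and viral reference: %s",
                     vid))
      }
      vid <- paste0(prefix, vid)
      names(vseqs)[1] <- vid
    }
    vm$seq_id <- vid
    if (nchar(vseqs[[1]]) != vm$length) {
      vm$length <- nchar(vseqs[[1]])
    }
    if (any(vm$genes$end > vm$length)) {
      stop("viral gene intervals exceed the genome sequence")
    }
    viral_tx <- lapply(seq_len(nrow(vm$genes)), function(i) {
      g <- vm$genes[i, ]
      iv <- genome_interval(vid, g$start, g$end, "+")
      transcript_model(transcript_id = g$gene, gene_id = g$gene,
                       gene_name = g$gene, exons = iv, cds = iv)
    })
    names(viral_tx) <- vm$genes$gene
    clash <- intersect(names(viral_tx), names(annotation))
    if (length(clash)) {
      stop(sprintf("transcript id collision with viral genes: %s",
                   paste(clash, collapse = ", ")))
    }
    annotation <- c(annotation, viral_tx)
    host_seqs <- c(host_seqs, vseqs)
    origin <- c(origin, setNames("viral", vid))
    viral_model <- vm
  }
  structure(
    list(sequences = host_seqs, origin = origin, annotation = annotation,
         viral_model = viral_model),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d sequence(s) (%d viral), %d transcript model(s)\n",
              length(x$sequences), sum(x$origin == "viral"),
              length(x$annotation)))
  invisible(x)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Extract the spliced sequence of a transcript model
#'
#' @param reference A `reference_set`.
#' @param model A `transcript_model` or a transcript id present in the
#'   reference annotation.
#' @param feature `"exon"` for the full mature transcript (CDS + UTRs) or
#'   `"cds"` for the coding sequence only.
#' @return A character scalar, 5' to 3' in transcript orientation.
#' @export
transcript_sequence <- function(reference, model, feature = c("exon", "cds")) {
  feature <- match.arg(feature)
  if (is.character(model)) {
    if (!model %in% names(reference$annotation)) {
      stop(sprintf("unknown transcript id '%s'", model))
    }
    model <- reference$annotation[[model]]
  }
  iv <- if (feature == "exon") model$exons else model$cds
  pieces <- vapply(seq_len(nrow(iv)), function(i) {
    seq <- reference$sequences[[iv$seq_id[i]]]
    substr(seq, iv$start[i] + 1L, iv$end[i])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (iv$strand[1] == "-") revcomp_chr(s) else s
}

#' Transcript-local feature layout
#'
#' Lengths of the 5' UTR, CDS and 3' UTR in transcript (5' to 3')
#' orientation; positions on the spliced transcript sequence fall into the
#' 5' UTR for `pos < utr5`, the CDS for `utr5 <= pos < utr5 + cds`, and the
#' 3' UTR beyond.
#'
#' @param model A `transcript_model`.
#' @return Named integer vector with elements `utr5`, `cds`, `utr3`.
#' @export
feature_map <- function(model) {
  c(utr5 = interval_width(model$utr5),
    cds = interval_width(model$cds),
    utr3 = interval_width(model$utr3))
}
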
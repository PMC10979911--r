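# Workflow composition: per-sample persistence QC and multi-sample
# time-course analysis, with TSV/bedGraph outputs and a run manifest.

#' Pipeline configuration
#'
#' Bundles the reference and all tunable parameters of the two workflows.
#' Defaults are printed into the run manifest for provenance.
#'
#' @param reference A `reference_set`.
#' @param factors Named character vector mapping factor gene names to the
#'   transcript ids analyzed for the CDS/UTR ratio; default: the MANE
#'   transcript of every MANE-flagged gene in the annotation.
#' @param k k-mer size of the quantifier.
#' @param min_votes Minimum winning vote count (`NULL` for the default
#'   read-length-dependent rule).
#' @param bin_size Coverage bin width in bases.
#' @param count_mode Feature counting rule, `"start"` or `"overlap"`.
#' @param low_count_threshold Raw-count threshold for the low-expression
#'   flag.
#' @param min_tpm,min_reads Persistence-call thresholds.
#' @param seed Seed recorded for provenance (the QC workflow itself is
#'   deterministic).
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, factors = NULL, k = 31L,
                            min_votes = NULL, bin_size = 100L,
                            count_mode = "start",
                            low_count_threshold = 30, min_tpm = 0.1,
                            min_reads = 10, seed = 1L, outdir = NULL) {
  stopifnot(inherits(reference, "reference_set"))
  if (is.null(factors)) {
    mane <- Filter(function(m) m$is_mane_select, reference$annotation)
    factors <- setNames(vapply(mane, `[[`, "", "transcript_id"),
                        vapply(mane, `[[`, "", "gene_name"))
  }
  structure(
    list(reference = reference, factors = factors, k = as.integer(k),
         min_votes = min_votes, bin_size = as.integer(bin_size),
         count_mode = count_mode,
         low_count_threshold = low_count_threshold,
         min_tpm = min_tpm, min_reads = min_reads,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `path` (FASTQ or feature-count TSV),
#' `type` (`"fastq"`/`"counts"`), and optionally `condition`, `passage`,
#' `replicate`.
#'
#' @param path Sample sheet path.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  if (nrow(sheet) == 0) stop("sample sheet is empty")
  if (!"sample_id" %in% names(sheet)) {
    stop("sample sheet needs a sample_id column")
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample ids must be unique")
  }
  if ("passage" %in% names(sheet)) {
    p <- sheet$passage[!is.na(sheet$passage)]
    if (any(p < 0) || any(p != floor(p))) {
      stop("passage values must be non-negative integers")
    }
  }
  sheet
}

# quantify one sample: reads (fastq) or precomputed feature counts
quantify_sample <- function(config, row, index) {
  if (!is.null(row$path) && !is.na(row$path) && !file.exists(row$path)) {
    stop(sprintf("input file for sample %s not found: %s",
                 row$sample_id, row$path))
  }
  type <- if (!is.null(row$type) && !is.na(row$type)) row$type else "fastq"
  if (type == "counts") {
    fc <- read_feature_counts(row$path)
    list(fc = fc, assignments = NULL,
         total_assigned = sum(fc$total_count))
  } else {
    reads <- read_fastq(row$path)
    asg <- assign_reads(index, reads, min_votes = config$min_votes)
    fc <- count_features(asg, config$reference,
                         count_mode = config$count_mode)
    list(fc = fc, assignments = asg,
         total_assigned = sum(asg$assignments$weight))
  }
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, path, extra = list()) {
  fields <- c(
    list(package = "sendaiqc",
         version = as.character(utils::packageVersion("sendaiqc")),
         k = config$k, bin_size = config$bin_size,
         count_mode = config$count_mode,
         low_count_threshold = config$low_count_threshold,
         min_tpm = config$min_tpm, min_reads = config$min_reads,
         seed = config$seed),
    extra)
  writeLines(sprintf("%s: %s", names(fields),
                     vapply(fields, function(x)
                       paste(format(x), collapse = ","), character(1))),
             path)
  invisible(path)
}

#' Per-sample persistence QC workflow
#'
#' For every sample: assign reads (or ingest precomputed feature counts),
#' aggregate to gene counts, compute size factors across the sample set,
#' TPM, the viral expression summary with persistence call, the per-factor
#' CDS/UTR ratio table, and CPM-normalized viral genome coverage tracks.
#' With `config$outdir` set, writes `viral_summary.tsv`, `ratios.tsv`,
#' `size_factors.tsv`, coverage bedGraphs and a run manifest; outputs are
#' deterministic given the inputs.
#'
#' @param config A `pipeline_config`.
#' @param sample_sheet Data frame (see [read_sample_sheet()]).
#' @return A list with `viral` (summary + calls), `ratios`, `size_factors`,
#'   `gene_counts` (`count_matrix`), `tpm`, `coverage` (named list of
#'   `coverage_track`s, CPM-normalized).
#' @export
run_qc <- function(config, sample_sheet) {
  sheet <- validate_sample_sheet(sample_sheet)
  index <- build_index(config$reference, k = config$k)
  message(sprintf("run_qc: %d sample(s), %d reference target(s)",
                  nrow(sheet), length(index$targets)))
  per_sample <- lapply(seq_len(nrow(sheet)), function(i) {
    t0 <- Sys.time()
    q <- quantify_sample(config, sheet[i, ], index)
    message(sprintf("  %s: %.1f assigned read weight (%.2fs)",
                    sheet$sample_id[i], q$total_assigned,
                    as.numeric(Sys.time() - t0, units = "secs")))
    q
  })
  names(per_sample) <- sheet$sample_id

  tx_ids <- vapply(config$reference$annotation, `[[`, "", "transcript_id")
  tx_counts <- vapply(per_sample, function(q) {
    v <- setNames(q$fc$total_count, q$fc$transcript_id)
    out <- setNames(numeric(length(tx_ids)), tx_ids)
    common <- intersect(names(v), tx_ids)
    out[common] <- v[common]
    out
  }, numeric(length(tx_ids)))
  tx_counts <- matrix(tx_counts, ncol = nrow(sheet),
                      dimnames = list(tx_ids, sheet$sample_id))
  genes <- aggregate_to_genes(tx_counts, config$reference)
  sf <- if (ncol(genes$counts) == 1) {
    setNames(1, colnames(genes$counts))
  } else {
    size_factors(genes$counts)
  }
  expr <- tpm(genes)

  vm <- config$reference$viral_model
  viral <- NULL
  coverage <- list()
  if (!is.null(vm)) {
    viral <- call_persistence(
      viral_summary(expr, vm, raw_counts = genes$counts),
      min_tpm = config$min_tpm, min_reads = config$min_reads)
    mean_total <- mean(vapply(per_sample, `[[`, 0, "total_assigned"))
    for (sid in sheet$sample_id) {
      asg <- per_sample[[sid]]$assignments
      if (is.null(asg)) next
      coverage[[sid]] <- cpm_track(
        viral_coverage(asg, vm, bin_size = config$bin_size),
        sf[[sid]], mean_total)
    }
  }

  ratios <- do.call(rbind, lapply(sheet$sample_id, function(sid) {
    fc <- per_sample[[sid]]$fc
    fc <- fc[fc$transcript_id %in% config$factors, , drop = FALSE]
    if (nrow(fc) == 0) return(NULL)
    r <- cds_utr_ratio(fc, size_factor = sf[[sid]],
                       low_count_threshold = config$low_count_threshold,
                       sample_id = sid)
    gene_of <- setNames(names(config$factors), config$factors)
    r$gene_name <- unname(gene_of[r$gene_name])
    r
  }))

  result <- list(viral = viral, ratios = ratios, size_factors = sf,
                 gene_counts = genes, tpm = expr, coverage = coverage)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(viral)) {
      write_tsv(viral, file.path(config$outdir, "viral_summary.tsv"))
    }
    if (!is.null(ratios)) {
      out <- ratios
      out$ratio <- format(out$ratio, digits = 10)
      write_tsv(out, file.path(config$outdir, "ratios.tsv"))
    }
    write_tsv(data.frame(sample_id = names(sf), size_factor = sf),
              file.path(config$outdir, "size_factors.tsv"))
    for (sid in names(coverage)) {
      write_bedgraph(coverage[[sid]],
                     file.path(config$outdir,
                               sprintf("coverage_%s.bedgraph", sid)),
                     seq_length = vm$length)
    }
    write_manifest(config, file.path(config$outdir, "manifest.txt"),
                   list(samples = sheet$sample_id))
  }
  result
}

#' Time-course enrichment analysis per condition
#'
#' Builds a passage series of mean viral TPM per condition and fits the
#' per-passage enrichment rate with [estimate_enrichment()]. The sheet
#' needs `passage` and `condition` columns; per-sample viral expression is
#' taken from a `viral_expression` column when present (the bridge for
#' precomputed summaries), otherwise computed by [run_qc()].
#'
#' @param config A `pipeline_config`.
#' @param sample_sheet Data frame with `sample_id`, `condition`, `passage`
#'   and either `viral_expression` or input paths.
#' @return Data frame with one row per analyzed condition: `condition`,
#'   `rate_per_passage`, `log2_slope`, `n_points`, `residual_sd`,
#'   `cumulative_fold` (last over first passage expression); fitted
#'   `enrichment_fit` objects in attribute `fits`. Conditions with fewer
#'   than two passages are skipped with a warning.
#' @export
run_timecourse <- function(config, sample_sheet) {
  sheet <- validate_sample_sheet(sample_sheet)
  if (!all(c("condition", "passage") %in% names(sheet))) {
    stop("time-course sheet needs condition and passage columns")
  }
  if (!"viral_expression" %in% names(sheet)) {
    qc <- run_qc(config, sheet)
    expr <- setNames(qc$viral$mean_tpm, qc$viral$sample_id)
    sheet$viral_expression <- unname(expr[sheet$sample_id])
  }
  fits <- list()
  rows <- list()
  for (cond in unique(sheet$condition)) {
    sub <- sheet[sheet$condition == cond, , drop = FALSE]
    series <- aggregate(viral_expression ~ passage, data = sub, FUN = mean)
    if (nrow(series) < 2) {
      warning(sprintf("condition '%s' has a single passage; skipped", cond))
      next
    }
    series <- series[order(series$passage), ]
    fit <- estimate_enrichment(series)
    fits[[cond]] <- fit
    first <- series$viral_expression[1]
    last <- series$viral_expression[nrow(series)]
    rows[[cond]] <- data.frame(
      condition = cond,
      rate_per_passage = fit$rate_per_passage,
      log2_slope = fit$log2_slope,
      n_points = fit$n_points,
      residual_sd = fit$residual_sd,
      cumulative_fold = if (first > 0) last / first else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    stop("no condition with at least two passages")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out, file.path(config$outdir, "enrichment.tsv"))
  }
  out
}
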
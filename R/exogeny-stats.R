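# Core statistics: the CDS/UTR exogeny ratio, the viral expression summary
# excluding vector-deleted genes, the persistence call, and the per-passage
# enrichment-rate estimator.

#' CDS/UTR read-density ratio
#'
#' Endogenous mRNAs carry CDS and UTRs as one transcribed unit, so their
#' length- and depth-normalized read densities are close to equal and the
#' ratio sits near one. Vector-derived transcripts contain only the CDS, so
#' exogenous expression pushes the ratio up in proportion to the exogenous
#' load (see [expected_mixture_ratio()]). Per transcript:
#' `cds_density = (cds_count / s_j) / cds_length` and
#' `utr_density = ((utr5 + utr3 counts) / s_j) / (utr5 + utr3 length)`;
#' the ratio is their quotient. 5' and 3' UTRs are pooled into a single UTR
#' feature.
#'
#' @param fc Data frame in [count_features()] layout (one sample).
#' @param size_factor The sample's size factor (cancels in the ratio; kept
#'   for interface fidelity with the normalized-count definition).
#' @param low_count_threshold Raw-count threshold below which a ratio is
#'   flagged low-expression (default 30).
#' @param sample_id Optional sample id recorded in the output.
#' @return Data frame with one row per transcript: `gene_name` (transcript
#'   id), `sample_id`, `ratio`, `cds_density`, `utr_density`,
#'   `total_raw_counts`, `low_expression`, `utr_zero`. Zero UTR counts with
#'   positive CDS counts give `ratio = Inf` with `utr_zero = TRUE`; no
#'   pseudocount is applied.
#' @export
cds_utr_ratio <- function(fc, size_factor = 1, low_count_threshold = 30,
                          sample_id = NA_character_) {
  stopifnot(size_factor > 0)
  utr_len <- fc$utr5_length + fc$utr3_length
  if (any(is.na(utr_len)) || any(utr_len == 0)) {
    bad <- fc$transcript_id[is.na(utr_len) | utr_len == 0]
    stop(sprintf("ratio undefined for UTR-less transcript(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (any(fc$cds_length <= 0)) stop("CDS length must be positive")
  utr_count <- fc$utr5_count + fc$utr3_count
  cds_density <- (fc$cds_count / size_factor) / fc$cds_length
  utr_density <- (utr_count / size_factor) / utr_len
  ratio <- ifelse(utr_density > 0, cds_density / utr_density,
                  ifelse(cds_density > 0, Inf, NA_real_))
  total_raw <- fc$cds_count + utr_count
  data.frame(
    gene_name = fc$transcript_id,
    sample_id = sample_id,
    ratio = ratio,
    cds_density = cds_density,
    utr_density = utr_density,
    total_raw_counts = total_raw,
    low_expression = total_raw < low_count_threshold,
    utr_zero = utr_count == 0 & fc$cds_count > 0,
    stringsAsFactors = FALSE
  )
}

#' Expected CDS/UTR ratio for an exogenous/endogenous mixture
#'
#' Under uniform fragment sampling, per-base CDS coverage is proportional
#' to `n + e` (endogenous plus exogenous copies) while UTR coverage is
#' proportional to `n` alone, so the expected ratio is `1 + e/n`.
#'
#' @param e_over_n Exogenous-to-endogenous copy ratio, `>= 0`.
#' @return The expected CDS/UTR ratio `1 + e_over_n`.
#' @export
#' @examples
#' expected_mixture_ratio(99)  # 100, the scale seen for MYC
#' expected_mixture_ratio(9)   # 10, the SOX2/KLF4 scale
expected_mixture_ratio <- function(e_over_n) {
  stopifnot(all(e_over_n >= 0))
  1 + e_over_n
}

#' Summarize viral gene expression for one sample
#'
#' Mean TPM over the viral genes, excluding genes deleted from the vector
#' (by default the viral model's `deleted_genes`, e.g. F): their reference
#' interval exists but the vector cannot express them, so including them
#' would dilute the mean.
#'
#' @param expr Named TPM vector (single sample) or TPM matrix
#'   (features x samples).
#' @param viral_model A `viral_genome_model`.
#' @param exclude Genes to exclude from the mean; defaults to
#'   `viral_model$deleted_genes`.
#' @param raw_counts Optional named raw-count vector/matrix on the same
#'   features, used to report total raw viral reads.
#' @return Data frame with one row per sample: `sample_id`, `mean_tpm`,
#'   `total_raw_viral`, plus attribute `per_gene_tpm` (included-gene TPM
#'   matrix) and `excluded_genes`.
#' @export
viral_summary <- function(expr, viral_model, exclude = NULL,
                          raw_counts = NULL) {
  if (is.null(exclude)) exclude <- viral_model$deleted_genes
  if (is.null(dim(expr))) {
    expr <- matrix(expr, ncol = 1, dimnames = list(names(expr), "sample1"))
  }
  if (!is.null(raw_counts) && is.null(dim(raw_counts))) {
    raw_counts <- matrix(raw_counts, ncol = 1,
                         dimnames = list(names(raw_counts),
                                         colnames(expr)[1]))
  }
  genes <- viral_model$genes$gene
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stop("no viral genes present in the expression table")
  }
  included <- setdiff(present, exclude)
  if (length(included) == 0) {
    stop("all viral genes present are excluded from the summary")
  }
  per_gene <- expr[included, , drop = FALSE]
  total_raw <- if (!is.null(raw_counts)) {
    colSums(raw_counts[intersect(present, rownames(raw_counts)), ,
                       drop = FALSE])
  } else {
    rep(NA_real_, ncol(expr))
  }
  out <- data.frame(
    sample_id = colnames(expr),
    mean_tpm = colMeans(per_gene),
    total_raw_viral = as.numeric(total_raw),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "per_gene_tpm") <- per_gene
  attr(out, "excluded_genes") <- intersect(genes, exclude)
  out
}

#' Call vector persistence for samples
#'
#' A sample is called positive when its mean viral TPM and its total raw
#' viral read count both reach their thresholds.
#'
#' @param summary Data frame from [viral_summary()].
#' @param min_tpm Minimum mean viral TPM (default 0.1).
#' @param min_reads Minimum total raw viral reads (default 10).
#' @return The summary with an added `call` column
#'   (`"positive"`/`"negative"`).
#' @export
call_persistence <- function(summary, min_tpm = 0.1, min_reads = 10) {
  stopifnot(min_tpm >= 0, min_reads >= 0)
  raw_ok <- ifelse(is.na(summary$total_raw_viral), TRUE,
                   summary$total_raw_viral >= min_reads)
  summary$call <- ifelse(summary$mean_tpm >= min_tpm & raw_ok,
                         "positive", "negative")
  summary
}

#' Estimate the per-passage enrichment rate for vector-positive cells
#'
#' Ordinary least squares of `log2(viral expression)` on passage index over
#' the positive-expression points; the per-passage fold change is
#' `2^slope`. Zero-expression points are excluded with a warning.
#'
#' @param series A `passage_series` or data frame with columns `passage`
#'   and `viral_expression`.
#' @return An object of class `enrichment_fit`: list with
#'   `rate_per_passage`, `log2_slope`, `intercept`, `n_points`,
#'   `residual_sd`.
#' @export
#' @examples
#' s <- data.frame(passage = 0:3, viral_expression = c(1, 2, 4, 8))
#' estimate_enrichment(s)$rate_per_passage  # 2
estimate_enrichment <- function(series) {
  stopifnot(all(c("passage", "viral_expression") %in% names(series)))
  keep <- series$viral_expression > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d zero-expression point(s) from the fit",
                    sum(!keep)))
  }
  s <- series[keep, , drop = FALSE]
  if (nrow(s) < 2) {
    stop("need at least 2 passages with positive expression")
  }
  fit <- lm(log2(viral_expression) ~ passage, data = s)
  slope <- unname(coef(fit)[2])
  rsd <- if (nrow(s) > 2) {
    sqrt(sum(fit$residuals^2) / (nrow(s) - 2))
  } else {
    0
  }
  structure(
    list(rate_per_passage = 2^slope,
         log2_slope = slope,
         intercept = unname(coef(fit)[1]),
         n_points = nrow(s),
         residual_sd = rsd),
    class = "enrichment_fit"
  )
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf("<enrichment_fit> %.3f-fold per passage (log2 slope %.3f, %d points, residual sd %.3f)\n",
              x$rate_per_passage, x$log2_slope, x$n_points, x$residual_sd))
  invisible(x)
}
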
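# Library normalizations: median-of-ratios size factors, CPM for coverage
# tracks, TPM for expression tables, per-sample min-max rescaling.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over features g of
#' `counts[g, j] / geometric_mean_over_samples(counts[g, ])`. The geometric
#' mean is computed in log space; features with a zero count in any sample
#' are excluded (their log-mean is undefined). The median is taken on the
#' log scale, so an even feature count gives the geometric midpoint of the
#' two central ratios — bit-for-bit the behavior of the canonical
#' median-of-ratios implementation.
#'
#' @param counts Feature x sample matrix (or `count_matrix`).
#' @return Named numeric vector of per-sample size factors.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 100), s2 = c(20, 200))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%d", seq_len(ncol(counts)))
  }
  keep <- apply(counts > 0, 1, all)
  if (!any(keep)) {
    stop("size factors undefined: no feature has all-positive counts")
  }
  logc <- log(counts[keep, , drop = FALSE])
  loggeo <- rowMeans(logc)
  s <- apply(logc - loggeo, 2, function(x) exp(median(x)))
  setNames(s, colnames(counts))
}

#' Normalize a coverage track to counts per million
#'
#' `value' = value / size_factor / mean_total_reads * 1e6`, elementwise.
#'
#' @param track A `coverage_track` or numeric vector.
#' @param size_factor Per-sample size factor, `> 0`.
#' @param mean_total_reads Mean per-sample total assigned reads across the
#'   analyzed sample set, `> 0`.
#' @return The normalized track (same type as the input).
#' @export
cpm_track <- function(track, size_factor, mean_total_reads) {
  if (size_factor <= 0 || mean_total_reads <= 0) {
    stop("size_factor and mean_total_reads must be positive")
  }
  if (inherits(track, "coverage_track")) {
    track$values <- track$values / size_factor / mean_total_reads * 1e6
    track
  } else {
    track / size_factor / mean_total_reads * 1e6
  }
}

#' Transcripts per million
#'
#' Counts are divided by feature length to per-base rates, then scaled so
#' each sample sums to one million. Samples with all-zero counts stay zero.
#'
#' @param counts Feature x sample matrix (or `count_matrix`, in which case
#'   `lengths` defaults to its feature lengths).
#' @param lengths Named (or positionally matched) positive feature lengths.
#' @return Matrix of TPM values with the shape of `counts`.
#' @export
tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lengths)) lengths <- counts$lengths
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts)) {
    stop("need one length per feature")
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("feature lengths must be positive")
  }
  rate <- counts / lengths
  totals <- colSums(rate)
  out <- sweep(rate, 2, ifelse(totals > 0, totals, 1), "/") * 1e6
  out[, totals == 0] <- 0
  out
}

#' Min-max rescale a track to [0, 1]
#'
#' `value' = (value - min) / (max - min)`; constant tracks map to all
#' zeros.
#'
#' @param track A `coverage_track` or numeric vector.
#' @return The rescaled track (same type as the input).
#' @export
minmax_rescale <- function(track) {
  v <- if (inherits(track, "coverage_track")) track$values else track
  if (length(v) == 0) stop("track is empty")
  rng <- range(v)
  v <- if (rng[1] == rng[2]) {
    rep(0, length(v))
  } else {
    (v - rng[1]) / (rng[2] - rng[1])
  }
  if (inherits(track, "coverage_track")) {
    track$values <- v
    track
  } else {
    v
  }
}
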
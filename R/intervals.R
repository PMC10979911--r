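# Genomic intervals are plain data frames in 0-based half-open coordinates.
# GTF I/O converts to/from the 1-based inclusive convention at the boundary.

#' Create a set of genomic intervals
#'
#' Intervals are represented as a data frame with columns `seq_id`, `start`,
#' `end`, `strand`, using 0-based half-open coordinates (`start` inclusive,
#' `end` exclusive).
#'
#' @param seq_id Character vector of sequence identifiers.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param strand `"+"` or `"-"`, recycled.
#' @return A validated interval data frame.
#' @export
#' @examples
#' genome_interval("chr1", 99, 149)
genome_interval <- function(seq_id, start, end, strand = "+") {
  n <- max(length(seq_id), length(start), length(end))
  df <- data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    df <- data.frame(seq_id = character(), start = integer(),
                     end = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  }
  validate_intervals(df)
}

#' Validate an interval data frame
#'
#' @param x Data frame with columns `seq_id`, `start`, `end`, `strand`.
#' @return `x`, invisibly on success; errors otherwise.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("seq_id", "start", "end", "strand") %in% names(x))) {
    stop("intervals need columns seq_id, start, end, strand")
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0) || any(x$start >= x$end)) {
      stop("invalid interval: need 0 <= start < end")
    }
    if (!all(x$strand %in% c("+", "-"))) {
      stop("strand must be one of '+', '-'")
    }
  }
  x
}

#' Total width of a set of intervals
#'
#' @param x Interval data frame.
#' @return Total number of bases covered (assumes disjoint intervals).
#' @export
interval_width <- function(x) {
  if (nrow(x) == 0) return(0L)
  as.integer(sum(x$end - x$start))
}

# intersect each interval with [lo, hi); drops empty pieces
clip_intervals <- function(x, lo, hi) {
  if (nrow(x) == 0) return(x)
  s <- pmax(x$start, lo)
  e <- pmin(x$end, hi)
  keep <- s < e
  out <- x[keep, , drop = FALSE]
  out$start <- as.integer(s[keep])
  out$end <- as.integer(e[keep])
  rownames(out) <- NULL
  out
}

# merge book-ended/overlapping intervals (single seq_id assumed)
merge_intervals <- function(x) {
  if (nrow(x) <= 1) {
    rownames(x) <- NULL
    return(x)
  }
  x <- x[order(x$start), , drop = FALSE]
  starts <- x$start[1]
  ends <- x$end[1]
  for (i in seq_len(nrow(x))[-1]) {
    j <- length(ends)
    if (x$start[i] <= ends[j]) {
      ends[j] <- max(ends[j], x$end[i])
    } else {
      starts <- c(starts, x$start[i])
      ends <- c(ends, x$end[i])
    }
  }
  genome_interval(x$seq_id[1], starts, ends, x$strand[1])
}

# TRUE if every base of `inner` lies within `outer`
intervals_within <- function(inner, outer) {
  if (nrow(inner) == 0) return(TRUE)
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer$start <= inner$start[i] & outer$end >= inner$end[i])
  }, logical(1)))
}
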
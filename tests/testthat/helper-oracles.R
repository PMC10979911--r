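# independent brute-force median-of-ratios, straight from the definition;
# an even ratio count takes the geometric midpoint of the two central
# ratios (the log-scale median convention of the canonical procedure)
brute_size_factors <- function(m) {
  geo <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  ok <- apply(m, 1, function(x) all(x > 0))
  if (!any(ok)) stop("undefined")
  vapply(seq_len(ncol(m)), function(j) {
    r <- sort(m[ok, j] / geo[ok])
    n <- length(r)
    if (n %% 2 == 1) r[(n + 1) / 2] else sqrt(r[n / 2] * r[n / 2 + 1])
  }, numeric(1))
}
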
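---
title: "Detecting residual Sendai reprogramming-vector expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting residual Sendai reprogramming-vector expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Induced pluripotent stem cells (iPSCs) are commonly generated by delivering
the Yamanaka factors (OCT4/POU5F1, SOX2, KLF4, MYC) on Sendai virus (SeV)
vectors. SeV replicates episomally in the cytoplasm and is expected to be
diluted out over passaging, but it can persist — and culture conditions that
favor cells with high exogenous factor expression (notably naive-pluripotency
media) can actively select for vector-positive cells. Residual vector
expression confounds any comparison of iPSC lines: apparent "reprogramming
factor expression" may be exogenous, and apparent epigenetic differences may
reflect ongoing transgene activity rather than cell-intrinsic state.

`sendaiqc` provides the two screening statistics this situation calls for,
plus everything needed to validate them end-to-end on reads with known
ground truth:

1. **Viral expression summary and persistence call** — mean TPM over the SeV
   genes, excluding genes deleted from the vector (the commercial
   reprogramming kit lacks the F gene, so F serves as a negative control
   interval: reads covering F indicate wild-type virus or contamination, not
   the vector).
2. **The CDS/UTR exogeny ratio** — endogenous mRNAs are transcribed and
   spliced as one unit containing 5' UTR, CDS and 3' UTR, so their
   length-normalized read densities on CDS and UTRs are nearly equal. The
   vector transcribes the factor CDS *without* UTRs. The ratio of
   depth- and length-normalized CDS density to pooled-UTR density is
   therefore ≈ 1 for purely endogenous expression and grows linearly with
   exogenous load.
3. **The per-passage enrichment rate** — on a passage series, ordinary least
   squares of log2(viral expression) against passage index estimates the
   per-passage fold change (growth advantage) of vector-positive cells.

## The mixture model behind the ratio

Let one factor locus produce `n` endogenous copies (CDS+UTR) and the vector
`e` exogenous copies (CDS only). Under uniform fragment sampling, per-base
coverage on the UTRs is proportional to `n` and on the CDS to `n + e`, so

```
E[ratio] = (n + e) / n = 1 + e/n
```

`expected_mixture_ratio()` is this one-liner, and it is the analytic oracle
the whole pipeline is validated against: a simulated exogenous:endogenous
copy ratio of 99 must come back as a measured ratio near 100, a ratio of 9
near 10, and pure endogenous expression near 1. The package's tests check
these recoveries within three standard deviations of the simulation noise
(estimated from the observed counts by the delta method,
`sd ≈ ratio * sqrt(1/CDS_count + 1/UTR_count)`).

Per transcript and sample the statistic is computed as

```
cds_density = (cds_count / s_j) / cds_length
utr_density = ((utr5_count + utr3_count) / s_j) / (utr5_length + utr3_length)
ratio       = cds_density / utr_density
```

with `s_j` the sample's size factor. The 5' and 3' UTRs are pooled into a
single UTR feature; per-end densities remain available in the feature-count
table as diagnostics. No pseudocount is applied: zero UTR counts give an
infinite ratio with an explicit `utr_zero` flag, keeping the estimator
honest rather than silently capped. Records with fewer than
`low_count_threshold = 30` raw counts (CDS+UTR) are flagged
`low_expression`; the threshold is configurable.

One transcript model per factor is used — the MANE-select transcript, the
single representative agreed between Ensembl and RefSeq — so feature lengths
are well defined without multi-isoform deconvolution.

## Reference model and coordinates

All intervals are 0-based half-open internally; GTF I/O converts to and
from the 1-based inclusive convention at the boundary, which keeps interval
arithmetic free of off-by-one ambiguity. `stop_codon` features annotated
outside the CDS are folded into it before UTR derivation so that CDS, 5'
UTR and 3' UTR always tile the exons exactly — this tiling is enforced as a
class invariant of every transcript model.

Viral genes are modeled as UTR-less single-exon transcripts on the plus
strand of the viral genome, so the quantifier treats host and viral targets
uniformly; genes deleted from the vector keep their genomic interval (for
coverage reporting) but are excluded from expression simulation and from
the viral mean. On a host/viral `seq_id` collision the viral id is
prefixed with `viral|`.

## The quantifier

External aligners are deliberately out of scope; read assignment uses an
exact k-mer voting scheme that is entirely adequate for a density statistic
at desk scale:

* `k = 31` by default (odd, so a k-mer can never equal its own reverse
  complement; both strands are matched through canonical k-mers).
* Each read k-mer votes for every target containing it; targets with the
  maximal vote count win. One winner → `unique`; ties → `ambiguous` with
  equal fractional weights (no EM — isoform resolution is not needed for a
  positional density ratio); below `min_votes` → `unassigned`.
* `min_votes` defaults to `max(1, read_length - k + 1 - 3k)`, which
  tolerates roughly three substitutions; the floor at 1 matters because the
  unfloored expression is negative for 100 bp reads at k = 31.
* The reported position is the 5'-most *matched* base on the majority vote
  diagonal (soft-clip semantics). This detail is load-bearing: reads whose
  prefix does not match (sequencing errors at the read start, reads
  straddling a vector transcript boundary) must not have their placement
  extrapolated into flanking features, or UTR counts would be
  systematically contaminated.

Counting conventions:

* **Coverage tracks** bin each read's weight into the bin containing its 5'
  start (100 bp bins by default), so bin values sum exactly to the assigned
  weight — conservation is exact, which the tests exploit.
* **Feature counting** defaults to the same start-base rule
  (`count_mode = "start"`). A rule in which a read counts into *every*
  feature it overlaps (`count_mode = "overlap"`) is also provided, but it is
  not the default because junction straddling inflates each feature's count
  by a factor ≈ `1 + (read_length - 1)/feature_length`; on UTRs of a few
  hundred bases to ~1.5 kb this is a 7–11% systematic bias at 100 bp
  reads — an order of magnitude larger than the statistical noise at 2×10⁵
  reads — and it is asymmetric between CDS and pooled UTRs. The start rule
  keeps the ratio estimator exactly unbiased under uniform sampling and
  conserves total weight. Both modes are tested; the difference only
  affects junction-spanning reads.
* Counting is unstranded, matching the unknown strandedness of typical
  public datasets.

## Normalizations

* **Size factors** reimplement the median-of-ratios procedure: per sample,
  the median over features of the count divided by the feature's geometric
  mean across samples; features with any zero count are excluded (their
  log geometric mean is undefined). The median is taken on the log scale,
  so an even feature count yields the geometric midpoint of the two central
  ratios — bit-for-bit the behavior of the canonical implementation, which
  the test suite verifies against both a brute-force transcription of the
  definition and DESeq2's `estimateSizeFactorsForMatrix()`. Note the exact
  scale equivariance holds for *relative* factors: scaling one sample by λ
  scales its factor by λ^((n−1)/n) and all others by λ^(−1/n), because the
  geometric-mean reference absorbs λ^(1/n).
* **CPM tracks**: `value / size_factor / mean_total_reads × 10⁶`, where
  `mean_total_reads` is the mean per-sample total of assigned reads across
  the analyzed sample set (exposed as a parameter, since a "mean across
  samples" depends on which samples are in scope).
* **TPM**: counts over feature length, rescaled to 10⁶ per sample;
  all-zero samples stay zero instead of dividing by zero. Column sums are
  tested to conserve 10⁶ within 10⁻⁶ relative tolerance.
* **Min-max rescaling** maps a track to [0, 1]; constant tracks map to all
  zeros (not NaN) for downstream I/O safety.

## The synthetic-data generator

The generator exists to produce data with *exactly* the statistical
structure the statistics assume, so that recovery failures indicate
implementation defects rather than model mismatch:

* Endogenous entries emit the spliced CDS+UTR transcript, exogenous entries
  the CDS-only sequence of the same factor, viral entries the viral gene
  sequences; a gene deleted from the vector (F) is never emitted.
* Sampling weight is `level × length`, so per-base coverage is proportional
  to copy level.
* Read starts are uniform over **all** positions with circular wrap-around
  by default. This is the one place the generator is deliberately idealized:
  linear fragment sampling produces 5'/3' end deficits of order
  `read_length / UTR_length`, which would bias the baseline ratio by far
  more than the Monte-Carlo noise at the tested depths. Circular sampling
  makes expected per-base sampling depth exactly uniform, which is the
  steady-state coverage model the ratio assumes. `circular = FALSE` gives
  plain substring sampling for tests that need literal substrings.
* Errors are substitutions only, applied per base at a configurable rate;
  no indels (k-mer assignment tolerance is exercised adequately by
  substitutions), no positional or GC bias, single-end fixed-length reads.
  Bias modeling is explicitly out of scope.
* Every operation re-seeds its own RNG stream from its config, so each
  stage is reproducible in isolation; identical seeds give byte-identical
  FASTQ output.
* A truth table (read → source, origin, start) accompanies every simulation
  for parameter-recovery and accuracy tests (error-free assignment accuracy
  is tested at 100%).

What this means for interpretation: passing recovery tests show the
*estimator* is correct under its model. Real libraries have end bias,
fragment-length variation and coverage non-uniformity, so the real-data
endogenous baseline can sit away from 1 (e.g. with 3' coverage bias); in
practice it should be estimated from control samples (fibroblasts, ESCs),
which is why the ratio report keeps raw densities alongside the ratio.

The default factor table uses the real MANE-select transcript identifiers
and realistic UTR/CDS lengths for POU5F1, SOX2, KLF4 and MYC, but the
sequences are synthetic (random); the viral genome is a random sequence
with a Sendai-like gene layout (N–P–M–F–HN–L, F deleted from the vector).

## Passage dynamics

`simulate_passages()` models selection with the replicator (odds) update

```
odds_{t+1} = w × odds_t,   odds = p / (1 - p)
```

where `p` is the vector-positive cell fraction and `w` the per-passage
growth advantage. Measured viral expression at passage `t` is
`p_t × per_cell_viral_expression` (TPM scale), observed through Poisson
sampling at a configurable depth. Defaults:
`per_cell_viral_expression = 10⁴` TPM (a fully positive culture devoting
~1% of its transcriptome to viral transcripts, the right order for
reprogramming-phase samples) and `sampling_depth = 10⁶`.

Two regimes matter:

* While `p ≪ 1`, odds ≈ p and expression grows exactly `w`-fold per
  passage, so the OLS slope of log2(expression) on passage recovers
  log2(w); the recovery tests run in this regime.
* Once `p` approaches 1 the logistic saturates. Starting from
  `p₀ = 10⁻³` with `w = 2`, ten passages bring `p` to ≈ 0.5: the
  first-to-last expression fold is ≈ 500 — noticeably less than the
  no-saturation extrapolation 2¹⁰ ≈ 1000 — and the fitted rate flattens
  slightly (≈ 1.89 rather than 2.0). This saturation is a real property of
  selection dynamics, not an estimator defect, and the package reports what
  the model produces rather than the idealized exponential.

The worked analytic example — a 1000-fold cumulative difference accrued
uniformly over ten passages — corresponds to `1000^(1/10) ≈ 1.995`-fold
per passage, i.e. approximately two-fold enrichment per passage.

## Workflows, determinism and problem sizes

`run_qc()` composes the stages for a sample sheet (FASTQ inputs or, as a
bridge for externally quantified data, precomputed feature-count TSVs) and
writes the viral summary with persistence calls
(`min_tpm = 0.1`, `min_reads = 10` — conservative, configurable), the
per-factor ratio table, size factors, CPM coverage bedGraphs and a run
manifest. Outputs are deterministic given the inputs; reruns are
byte-identical. `run_timecourse()` fits the enrichment rate per condition
and reports the first-to-last cumulative fold, skipping single-passage
conditions with a warning. A thin command-line dispatcher over these
functions ships in `inst/scripts/sendaiqc`.

Validation problem sizes were chosen to finish in seconds on one CPU while
leaving Monte-Carlo noise well below the effects being measured: 2×10⁵
reads for ratio recovery (baseline and mixtures), 5×10⁴ for the viral
persistence simulation, 100 random 50×6 matrices for the size-factor
oracle, and Poisson depth 10⁶ for passage series.

## Known limitations

* No paired-end reads, indels, quality modeling, PCR duplicates, or
  positional/GC bias in the simulator; no bias correction in the
  quantifier.
* One transcript per factor (MANE); no isoform-level deconvolution.
* The persistence call is a thresholded screen, not a formal test; no
  differential testing across media conditions is provided.
* The CDS/UTR ratio assumes the factor's UTRs are unique enough for k-mer
  assignment; paralogous UTRs would need masking.
* Real-data baselines for the ratio should come from transgene-free
  control samples rather than the analytic value 1 (see above).
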
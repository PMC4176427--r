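---
title: "Compact quality control of 450k methylation arrays: models and design"
author: "methylQC450"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compact quality control of 450k methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Infinium 450k-style methylation arrays report, for each of hundreds of
thousands of CpG probes, a methylated (M) and an unmethylated (U) signal
intensity. Quality control of a large cohort — spotting degraded samples,
sample swaps, batch effects and design confounding — does not need the full
probes × samples matrices; it needs per-sample *distributions* and a handful
of per-sample scalars. methylQC450 therefore splits the work into a one-off
summarization pass over the full data and a set of light QC operations that
run entirely from the resulting compact `QCSummary` object. The summary
stores, per sample, quantile vectors of five measures in six probe strata, so
its size scales with samples and grid resolution, never with probe count —
the property that makes cohort-scale QC portable.

## Measures and strata

From the two channels the package derives:

* copy number `CN = M + U`, proportional to total DNA at the locus;
* the methylation proportion `Beta = M / (M + U + offset)`, offset 100 by
  default (the platform-standard stabilizer: noise-level probes shrink
  towards 0 rather than scattering over [0, 1]);
* the variance-stabilized `M-value = log2((M + eps) / (U + eps))`, eps = 1.

The two Infinium chemistries produce systematically different Beta
distributions, and type I probes read out on a single colour channel, so
autosomal probes are summarized separately as type I green, type I red and
type II. chrX and chrY probes are pooled across chemistries — the sex
predictor needs every sex-chromosome probe and per-chemistry sex strata
would be needlessly sparse — and a pooled all-autosomal stratum feeds the
per-sample median QC metrics. The stratum vocabulary is recorded in the
summary so the convention is auditable.

Quantiles are type-7 (linear interpolation, `h = (n-1)p + 1`) on a grid of
501 evenly spaced probabilities. 501 rather than a round 500: the grid then
contains 0, 0.5 and 1 exactly, so the stored medians used by the QC scatter
and the sex predictor are exact sample medians rather than interpolations,
at a negligible size cost.

## Quality flags

For each sample the package takes log2 of the median autosomal M and U
intensities and flags the sample when their mean falls below a cutoff
(default 10.5, a conventional working value for 450k data; exposed as a
parameter everywhere). A zero median has no log2; the value is floored at 1
intensity unit and the sample is flagged `zero_median` outright, since an
all-background channel is unambiguously broken. Flagging is monotone in the
cutoff by construction. Flagged samples export to a two-column CSV
(`sample_id,reason`) for exclusion in downstream pipelines.

Density panels are reconstructed from the stored quantile vector treated as
an equal-weight pseudo-sample, so plotting never touches the full matrices.
The bandwidth is Silverman's rule with one deliberate modification: the
spread statistics (sd, IQR) come from the pseudo-sample, but the `n^(-1/5)`
factor uses the stratum's true probe count, which the summary stores. Using
the pseudo-sample length (always 501) would systematically over-smooth
relative to a KDE of the full data — for a 10,000-probe stratum the
bandwidth would be ~1.8× too wide and mode peaks visibly flattened. With the
true-n factor the reconstruction tracks a full-matrix KDE to within a few
percent of peak height, which the test suite checks quantitatively. A
constant pseudo-sample (bandwidth 0) falls back to `1e-6 * max(1, |c|)` so
the curve stays finite.

## Sex prediction

Males carry one X and one Y; females two X and no Y. The statistic
`log2(median CN on chrY) - log2(median CN on chrX)` therefore separates the
sexes into two clusters. The log scale makes the statistic invariant to
per-sample intensity scaling and gives the translation-invariance property
the tests exercise. A cutoff splits the clusters: either supplied manually,
or found automatically by a deterministic one-dimensional 2-means (centres
initialized at the minimum and maximum, iterated to convergence; cutoff =
midpoint of the final centres; the higher cluster is male). The automatic
mode replaces an interactive mouse-placed threshold with a reproducible
default that lands in the same gap a user would aim for. A sample exactly at
the cutoff is called male — an explicit, tested tie-break. Calls are
compared against the reported sex from the phenotype table; disagreements
(candidate sample swaps) are listed and exportable.

## PCA and design confounding

PCA runs on the autosomal Beta values of the `nTop = 20000` most variable
probes (population variance; ties at the boundary broken lexicographically
by probe ID so selection is deterministic). Probes are centred but not
scaled — Beta values already share the [0, 1] scale, and scaling would
inflate noise-only probes. Scores come from the SVD of the centred samples ×
probes matrix; each score column's sign is fixed so its largest-magnitude
entry is positive, making archives reproducible bit-for-bit. The first
`min(10, samples - 1)` components are retained with their
explained-variance fractions.

Eyeballing coloured score plots is made testable by `pcAssociation()`: a
one-way ANOVA of each score column on a categorical covariate. Perfect
separation with zero within-group variance is reported as `F = Inf, p = 0`
with a `degenerate` flag rather than an error. The physical-layout panel
parses Sentrix positions (`R01C01`–`R06C02`; the 6 × 2 geometry is a
parameter for other layouts) so plate/slide placement can be inspected for
confounding with phenotype.

## The synthetic-data generator

`generateDataset()` draws a complete dataset from one seeded RNG stream
(probes, then samples, then controls, so equal seeds give bit-identical
data). Its defaults are the stated world of the package's tests: probe-level
methylation states from a trimodal mixture (modes near Beta 0.1 / 0.9 / 0.5
with weights 0.45 / 0.45 / 0.10, plus a small per-probe jitter), total
intensity lognormal around 5000 units, multiplicative channel noise of 0.3
log2 units, a 1.5 log2-unit chrY copy-number shift for males (chrX halved),
batch effects as an additive Beta shift propagated to M/U with CN held
batch-neutral, low-quality samples at 15% of normal intensity, and NEGATIVE
controls at 2% of baseline. One generator formula is deliberately
disambiguated: the channel noise terms for M and U are drawn independently —
a noise term shared between the channels would cancel out of Beta entirely
and leave the methylation signal implausibly noise-free.

What the generator does **not** emulate: probe cross-hybridization, SNPs
under probes, dye bias beyond the type-I/II stratification, detection-
failure structure, or realistic control-probe chemistry panels. A green test
therefore establishes that the algorithms recover the effects they target at
realistic effect sizes and noise — not that they are robust to every
artefact of real arrays.

## Numerical and serialization choices

* **Archive format.** A `QCSummary` serializes to a single uncompressed
  POSIX tar containing `metadata.json` plus one TSV per stored
  stratum/measure table (written by R's internal tar with member mtimes
  pinned to a fixed epoch). A zip container was considered, but no
  deterministic zip writer is available without extra dependencies, and tar
  achieves the same goals: platform-independent, diffable, and — because all
  doubles are written with 17 significant digits and timestamps are pinned —
  `write → read → write` produces byte-identical archives. The probability
  grid is stored as 17-digit strings in the JSON metadata for the same
  reason (JSON number serialization loses the last ulp).
* **Degenerate strata.** An empty stratum (e.g. a manifest without chrY) is
  recorded as empty with a warning rather than an error; operations that
  need it fail at their own call site with a named message.
* **Missing data.** Missing or negative intensities are hard errors at read
  time, mirroring complete array output; imputation is out of scope.
* **Normalized data.** Externally normalized Beta matrices are summarized
  with the same strata and grid; M-values are derived as
  `log2(Beta/(1-Beta))` with Beta clipped to `[1e-6, 1 - 1e-6]`, and the raw
  channel tables are simply absent. Raw and normalized summaries share the
  grid, so before/after density panels are directly comparable, and each
  carries its own independently computed PCA.

## Limitations

The package starts from signal matrices: parsing IDAT binaries is delegated
to upstream tooling. No normalization is performed — the normalized-data
path summarizes what it is given. Probe-level filtering (detection p-values,
bead counts) and batch *correction* are out of scope; the package detects
structure, it does not remove it.
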
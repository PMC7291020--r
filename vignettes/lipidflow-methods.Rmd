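---
title: "Methods and design notes for lipidflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for lipidflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidflow)
```

# Scope and model

lipidflow processes an aligned untargeted-lipidomics feature table — rows
are chromatographic features carrying m/z, retention time, a lipid
shorthand annotation and an identification score; columns are injections
(biological samples, pooled QCs, solvent blanks) — through quality
filtering, drift correction and normalization, and then applies
univariate and multivariate statistics to nominate lipid biomarkers that
separate two biological groups. Everything upstream (peak picking,
alignment, MS/MS identification) is out of scope: the feature table is
the input contract.

The central quantity after preprocessing is the *amount*

$$\mathrm{Amount}_{ij} = \frac{\text{drift-corrected intensity}_{ij}}
{\text{protein injected } (\mu g)_j},$$

and class totals are plain sums of member amounts per injection,
$\mathrm{Amount}_{\mathrm{class}} = \sum_k \mathrm{Amount}_k$.

# Preprocessing decisions

**Stage order.** blank filter → QC CV filter → LOESS drift correction →
protein (or TIC) normalization → isomer summation → implausible-lipid
exclusion. Filters operate on raw signals, as alignment software does;
drift is corrected before amounts are formed so that the protein scaling
never interacts with the instrument-response model. A consequence worth
knowing: on a strongly drifting batch the QC CV filter (which sees raw
signals) removes drifting features before the correction could rescue
them. The order is deliberate and fixed in `run_workflow()`; the
individual stages are exported for any other composition.

**Thresholds.** Blank fold > 10 (strict), QC CV ≥ 30% excluded
(inclusive), both configurable. CVs use the sample (n−1) standard
deviation because QC counts are small. A feature absent from blanks
(blank mean 0) is kept: absence from solvent is the clean case, and the
fold change is effectively infinite.

**Drift model.** Per feature, `stats::lowess` (locally weighted linear
regression, tricube weights, two robustness iterations) of QC intensity
against injection order, evaluated at every injection by linear
interpolation, with linear continuation of the end segments beyond the
outermost QCs. Each intensity is divided by fit/mean(fit over QCs), so
the batch scale is preserved. Two numerical guards proved necessary:

* with fewer than four QC points in a window, the tricube weight of the
  farthest neighbour is zero and the local line passes exactly through
  the remaining points — the "fit" interpolates the QCs and the
  correction silently zeroes the QC variance. The effective span is
  therefore floored at 4.5/n~QC~.
* when the plain fit is already exact (noise-free drift), the residual
  MAD is zero and the robustness iterations degenerate; the non-robust
  fit is kept whenever its residuals are negligible.

Features whose fitted drift is non-positive anywhere are left
uncorrected and counted in a message.

A statistical limitation, documented rather than hidden: a *per-feature*
QC fit tracks QC noise with standard deviation of order
$\mathrm{CV}/\sqrt{k_\mathrm{eff}}$, so on a drift-free batch with ~16%
QC noise and 8–9 QCs the corrected QC CVs systematically shrink by a few
percentage points (the fit absorbs noise) and individual features can
move either way. No per-feature QC-LOESS scheme can leave CVs within one
point of raw under these conditions; the property tests assert the
attainable median form. Pooling the drift estimate across features would
be more stable but is a different model (a shared instrument response),
which the per-feature contract deliberately does not assume.

**Isomers.** Features sharing a sum composition (class, total carbons,
total double bonds, ether linkage) are summed, because positional and
stereochemical isomerism cannot be resolved by this kind of experiment;
the most intense member donates m/z and retention time.

# Discovery statistics

**Transform.** `glog(x) = log2((x + sqrt(x^2 + a^2))/2)` with a single
offset `a` = smallest positive amount in the matrix — finite at zero,
asymptotically log2 — followed by per-feature autoscaling. The offset is
one global scalar (not per feature) so that the transform is monotone
and comparable across features; it is exposed for sensitivity checks.

**t-test variant.** The pooled-variance two-sample t-test is the
default, Welch optional. With n = 3 per group Welch's degrees of freedom
collapse to ≈2 and the tail is so heavy that a 4-fold spike at 10% noise
frequently misses an FDR-adjusted 0.05 — the pooled test restores the
intended operating characteristics and matches what the common
metabolomics web tooling applies. Fold changes are always computed on
untransformed amounts (case/control, labels sorted alphabetically so the
orientation is deterministic).

**PLS-DA.** NIPALS PLS1 on y ∈ {0,1}, centered; standard deflation;
deterministic given input order. VIP uses the Y-variance-explained
weighting; `mean(VIP²) = 1` is an algebraic identity of the formula and
is asserted to 1e−9 on random models. Two components by default (a
2-component scores plot is the field's standard view); whether VIP
should come from a 2-component or larger model is genuinely open — the
component count is a parameter, and VIP from the fitted model is used
throughout. Q² is leave-one-out: each left-out sample is predicted by a
full refit (component count capped at n−2 when a fold gets that small).
Q² < 0.8 triggers an overfitting warning rather than an error.

**Impact factor.** `IF = |log2 FC| · (−log10 p) · VIP` with the
FDR-adjusted q as the p entering the product, because the volcano
criterion that feeds the same selection is stated on corrected p-values;
raw p is a configuration switch. p = 0 is clipped to the smallest
positive double. Ties in IF ranking break by |log2 FC| then feature id,
for determinism.

**Class discrimination cutoff.** The cutoff is the lower bound of the
95% distribution-free confidence interval of the median IF over all
selected features: the d-th order statistic where d is the largest
integer with $P(\mathrm{Bin}(n, 1/2) < d) \le 0.025$. The method is not
named in the originating literature; the order-statistic interval was
chosen because it is exact, assumption-free and reproducible, and a
percentile-bootstrap alternative (`median_lcl_boot()`) is provided for
comparison. Classes must exceed the cutoff strictly; classes with fewer
than three selected members are reported but flagged `low_n`.

**Enrichment.** Generic over a user-supplied term → lipid mapping (the
external lipid-ontology database is not bundled; a small class-based
demo mapping ships for tests). Per term, a one-tailed Welch t-test of
the ranking statistic (IF by default) of members vs. non-members,
"members rank higher" as the alternative, BH correction across terms.
Here Welch *is* kept as the local statistic — group sizes are far from
tiny and the external service this mirrors specifies it.

# The synthetic batch and what a green test establishes

`generate_batch()` draws lognormal base intensities with class-specific
location (positive, right-skewed, as MS intensities are), applies the
chosen spike fold changes to the case group, multiplies in smooth
(linear or sinusoidal) injection-order drift, per-sample protein amounts
drawn uniformly from 40–60 µg, and multiplicative lognormal noise with
CV 0.16 — the intra-batch QC variability level typical of such batches.
Defaults: 3 biological replicates per group, one pooled QC every 4
samples plus leading and trailing QCs, 3 blanks at 1% of mean sample
signal. The generator emulates *feature-level* structure only: no m/z
isotope patterns, no retention-time behaviour, no correlated biological
covariance between lipids, no heteroscedastic detector saturation. A
green recovery test therefore establishes that the statistics behave
correctly for independent lognormal features under the stated design —
not that any particular real-world batch will behave as well.

Simulator parameters are stated-world constants, not dials: they were
fixed from the emulated design before the acceptance properties were
measured, and the one adjustment made during development (the
pooled-variance default above) is ledgered with its rationale.

# Degenerate inputs and numerical choices

* unparseable lipid names never error — they become unannotated markers
  that flow through filtering and statistics but are excluded from class
  aggregation, composition profiles and enrichment;
* constant features autoscale to all-zero rows instead of NaN;
* zero control means give an undefined fold change and exclusion from
  volcano selection, with a message;
* chi-square composition tests fall back to a Monte-Carlo exact test
  when an expected count drops below 5; the ether/ester comparison is an
  exact binomial test throughout;
* all delimited output is written at full precision (`%.17g`) so that
  write → read round-trips are bit-identical.

# Known limitations

Single-batch only (no inter-batch anchoring); internal-standard
normalization is intentionally absent; PLS-DA is two-class (PLS1);
enrichment inherits the quality of the supplied term mapping; the
composition percentages are computed over lipid species, not over summed
acyl chains — with sum-composition annotations the chain-level count is
not recoverable.
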
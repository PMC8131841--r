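---
title: "Methods: link overconnectivity, ddPCR quantification and the two-control screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: link overconnectivity, ddPCR quantification and the two-control screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirconnect)
```

# Scope

`mirconnect` implements the computational chain of a two-stage circulating
miRNA biomarker study in Huntington's disease: an exploratory microarray
screen against two control groups, droplet-digital-PCR (ddPCR) validation of
the surviving miRNAs, nonparametric group and ROC statistics on the
validation cohort, and a network analysis asking whether the candidate
miRNA's predicted target genes (its *targetome*) are unusually wired to the
huntingtin (HTT) protein interactome. This vignette documents the models,
the defaults and why they are what they are, what the synthetic generators
do and do not emulate, and the numerical corner cases.

# The overconnectivity model

The background is a directed interaction database of `N` mechanism-labeled
links. For two gene sets, three further counts are taken: `R`, the links on
set 1's margin; `n`, the links on set 2's margin; and `actual`, the links
joining the two sets. Under the null that set 2's margin is an unstructured
draw of `n` links from the `N` background links of which `R` are on set 1's
margin, `actual` is hypergeometric:

$$\mathrm{Exp} = \frac{nR}{N}, \qquad
\mathrm{Var} = n\frac{R}{N}\Bigl(1-\frac{R}{N}\Bigr)\frac{N-n}{N-1},$$

and the test reports the connectivity ratio `actual / Exp`, the
normal-approximation score `z = (actual - Exp) / sqrt(Var)` and an **exact**
tail probability: `P(X >= actual)` for overconnectivity, `P(X <= actual)`
for underconnectivity. The exact tail and the z score are both reported
because at interactome scale (`N` of order 1e5 to 1e6) the normal
approximation is adequate for ranking but not for quoting small p-values;
the finite-population variance correction `(N - n)/(N - 1)` is part of the
model, not an option, and is required for the z scores the package's
built-in example reproduces.

```{r}
lapply(mir323b_htt_counts(), function(cnt)
  overconnectivity_report(overconnectivity_test(cnt)))
```

`hypergeometric_sf()` sums the tail in log space from log-gamma binomial
coefficients. The sum runs over the shorter tail only when that is the tail
requested; probabilities below about 1e-300 are still representable because
each term is exponentiated relative to the largest term.

## Counting semantics

Published link-enrichment reports describe the margins only as "incoming"
and "outgoing" links, which is not operational. The package fixes the
semantics as follows and documents them prominently rather than hiding the
choice:

* **all_interactions** — symmetric incidence: `R` counts edges touching
  set 1 at either endpoint, `n` edges touching set 2, `actual` edges joining
  the sets in either orientation.
* **transcription_regulation_only** — directional: after restricting to
  transcription-regulation edges, `R` counts edges *from* set 1, `n` edges
  *into* set 2, `actual` edges from set 1 into set 2.

Deduplication defaults to unique `(source, target, mechanism)` triples
because curated databases carry replicate evidence rows; a multigraph mode
keeps every record. Whichever rule is chosen, `N` is the count of retained
edges under that same rule, so the margins and the background are always on
one convention. Self-loops count like any edge, and an edge internal to an
overlap of the two sets counts toward every margin it qualifies for; the
formulas impose no exclusion and the simplest consistent rule wins.

## What the hypergeometric null does and does not match

The analytic null draws *links*; the companion `permutation_null()` draws
*genes* (it resamples set 1's membership uniformly from the network's gene
universe). On a random graph with endpoint-uniform edges the two agree
exactly in the directional mode: conditional on the margins, the set of
edges sourced in set 1 and the set of edges targeting set 2 are independent
uniform link subsets, so `actual` is exactly hypergeometric. In the
symmetric mode they do not agree even at the null: a link touching set 1
"uses up" an endpoint, making joint incidence to both sets rarer than the
product of the margin probabilities, so the hypergeometric expectation
overstates the between-set count and z is biased negative. For this reason
the package's calibration checks run in the directional mode; symmetric-mode
results are interpretable as enrichment scores relative to the stated null,
but that null is not the permutation distribution of a random gene set.
Gene permutation also leaves each permuted set's own margins random, while
the analytic test conditions on the observed margins, so even in the
directional mode per-dataset agreement between the empirical and analytic
p-value is approximate (the test suite asserts rank agreement and loose
moment agreement, not equality). The empirical p has resolution
`1/(n_perm + 1)`; comparisons against analytic p-values far below that floor
are uninformative.

# ddPCR Poisson quantification

With `k` positive droplets of `m`, the positive fraction estimates
`1 - exp(-lambda)`, so `lambda = -log(1 - k/m)` copies per droplet and
`lambda / v` copies per microliter of PCR mixture for droplet volume `v`.
Defaults and choices:

* `v = 0.00085` µl (0.85 nl). The droplet reader vendor does not print a
  volume; the value is a config constant and every within-study comparison
  is invariant to it.
* The 95% interval is Clopper–Pearson on `k/m`, propagated through the
  monotone inversion. The exact interval is chosen over a Wald interval
  because it remains valid at `k = 0` and near saturation, exactly the
  regimes low-abundance plasma miRNAs occupy.
* `k = m` sets a `saturated` flag with an infinite point estimate and a
  finite lower bound; `k = 0` is a valid zero estimate with a positive
  upper bound.
* Concentrations are per µl of reaction mixture, not plasma: the
  plasma-to-reaction dilution factor of a given assay is a pre-analytic
  constant that the package cannot know.

Merging wells sums counts first and inverts once; this equals quantifying
the pooled panel exactly, which is the defining property tested.

# The two-control signature screen

Fold change is computed on the log2 scale and reported in the signed linear
convention (`-1.5` means 1.5-fold down; ratio 1 maps to `+1`). The
per-probe test is Welch's two-sample t-test on log2 values — the original
analysis software for such arrays does not document its test, and Welch's
test is the defensible default under unequal group variances; no empirical
Bayes variance moderation is applied, keeping the stage dependency-light
and exactly checkable against `stats::t.test()`. A probe is a signature hit
only if it passes `|FC| > 1.5`, `p < 0.05` *against both control groups* in
the same direction and survives Benjamini–Hochberg FDR at 0.25, where the
BH adjustment is computed within each case-vs-control comparison across all
probes (the simplest reading of a per-comparison FDR gate; a pooled variant
would couple the two comparisons' ranks). The two-control design is the
point: a probe responding to medication rather than disease fails the
psychiatric-control comparison.

# Validation-cohort statistics

* `mann_whitney()` uses the exact permutation distribution whenever
  `n_x * n_y <= 400` and there are no ties — every group pair in a cohort of
  tens of subjects — and the tie- and continuity-corrected normal
  approximation otherwise.
* `median_quartiles()` defaults to linear-interpolation quantiles (the
  sorted sample interpolated at position `(n-1)q`); published cohort tables
  rarely state their convention, so it is configurable (Tukey hinges) and
  the default is documented rather than silently assumed.
* `cv_roc()` fits a univariate logistic model per training split of a
  repeated stratified 3-fold partition. Stratification is enforced because
  an unstratified split at seven premanifest subjects regularly produces
  folds with one class. Sensitivity and specificity are read at predicted
  probability 0.5; no operating point is optimized. On the full data the
  model is monotone in the marker, so its AUC equals the Mann–Whitney
  identity `U/(n_x n_y)` — an algebraic cross-check in the test suite. Fold
  AUCs at pilot sizes are deliberately variable; the object returns every
  fold metric rather than only a mean to make that variability visible.
* `spearman_correlation()` uses tie-aware ranks, exact p for `n <= 9`.

# Synthetic generators

Each generator produces data with exactly the structure its consuming stage
assumes, which is what makes the pipeline property-testable — and is also
the limit of what passing tests show about real data.

* `gen_droplets()` thins `m` droplets binomially at `1 - exp(-lambda)`.
  Real ddPCR adds rain (ambiguous droplets) and volume variation; neither is
  modeled, so the recovery tests certify the inversion, not droplet gating.
* `gen_cohort()` draws log-normal values around group medians
  (`sigma_log = 1.2` by default, matching the several-fold interquartile
  ranges typical of plasma miRNA concentrations; the default group layout is
  26 + 7 carriers vs 25 + 24 controls with medians 4.1/5.8 vs 0.69/1.4
  copies/µl). Real cohorts have batch effects and detection floors; the
  generator has neither.
* `gen_expression()` plants log2 effects for a case group against two
  controls (the second control group is co-shifted so that both planted
  contrasts hold simultaneously) on a Normal(7, 1) baseline with i.i.d.
  Normal(0, 0.5) noise — no probe-level variance heterogeneity, no
  correlation between probes, no array normalization artifacts. Screen
  sensitivity measured on it is an upper bound on real-array sensitivity.
* `gen_network()` draws edge endpoints uniformly, multiplying the sampling
  weight of the set1-to-set2 cell by `enrichment` (1 = null), labels edges
  transcription-regulation with probability `txreg_fraction`, and returns
  the network as a multigraph so the background `N` equals the requested
  edge count. Real interactomes have heavy-tailed degree distributions; the
  uniform generator is the case for which the directional null is exactly
  calibrated, so calibration results transfer to real networks only to the
  extent the link-draw null itself is believed.

All generators are pure functions of their arguments and seed (`with_seed`
restores the caller's RNG state), and write the same file dialects their
consuming readers parse.

# Problem sizes and numerical choices

The shipped checks run at deliberately modest scale: exhaustive
hypergeometric verification over all populations up to `N = 60` against a
direct combinatorial sum (absolute error < 1e-12); link counting against a
per-edge enumeration oracle on 1000 random graphs of up to 10,000 edges;
500-replicate droplet recovery at `lambda` 0.05/0.5/2.0 and 20,000 droplets;
200 null networks for z calibration and 50 datasets x 1000 permutations for
the empirical-p uniformity check; 100 replicate screens at group sizes
9/8/5. Replicate seeds are derived from a single master seed via
`sample.int`, so every reported simulation is reproducible end to end.

Degenerate inputs are results, not crashes: zero-variance margins flag the
z score undefined and return p = 1 (the support is a single point); empty
gene sets give zero counts; an all-tied Mann–Whitney comparison returns
p = 1; constant vectors flag Spearman's rho undefined.

# Known limitations

The package reproduces derived statistics from printed link counts; it does
not (and cannot) re-derive those counts from the licensed interaction
database they came from, nor does it re-analyze the deposited raw
microarray data. Probe summarization/normalization, droplet gating from
fluorescence, identifier mapping across gene namespaces, and multivariable
classifiers are all out of scope. Where the original analysis left a
convention unstated (test statistic, quantile convention, FDR pooling,
droplet volume, CV repeat count), the package picks one, documents it here,
and exposes it as a parameter.
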
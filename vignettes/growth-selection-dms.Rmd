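---
title: "Growth-selection deep mutational scanning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-selection deep mutational scanning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfescan)
```

## The measurement model

In a competitive growth selection, every variant lineage grows exponentially
at its own rate while the whole population expands `2^g_p`-fold (`g_p`
population doublings).  Deep sequencing of the pre- and post-selection
populations counts each library member, and the analysis converts counts to
fitness in two steps:

* **Enrichment ratio** `eps_i = log2(f_post,i / f_pre,i)`, the log2
  fold-change of the member's frequency.  It is invariant to the sequencing
  depths of either population, which only set the counting noise.
* **Fitness metric** `zeta_i = (eps_i - eps_wt) / g_p`.  Normalizing by the
  wild-type enrichment removes the population-wide expansion; dividing by
  `g_p` puts selections of different lengths on one scale.  `zeta = 0` is
  wild-type-like.  Under deterministic exponential growth the expected value
  is `zeta = (r - 1) * g_wt / g_p`, where `r = mu_i/mu_wt` is the relative
  growth rate and `g_wt` the doublings the wild type itself realized; a
  variant with a 10% growth advantage therefore lands near `zeta = 0.15`
  when `g_wt/g_p ~ 1.5`.  That factor is a property of each experiment
  (how much faster the wild type grows than the population average), not a
  constant of the method, which is why the beneficial threshold
  (`threshold = 0.15` throughout) is exposed as a parameter.

**Detection limit.**  A variant with typical pre-selection representation
cannot be quantified below the fitness at which its expected post-selection
count hits the sequencing floor.  We take the half-median of pre-selection
per-variant reads, scale it by the post/pre total-read ratio to the
post-selection scale (`f_LB`), and anchor the bound at `floor_reads`
(default 10) post-selection reads: `eps_LB = log2(floor / f_LB)`,
`zeta_LB = (eps_LB - eps_wt)/g_p`.  Variants below `zeta_LB` are reported
with their point estimate but flagged: only the categorical call
"deleterious" is reliable there.  Two readings of "ratio of post- to
pre-selection read counts" are possible (totals ratio vs per-variant median
ratio); we use the totals ratio.  An exact self-consistency holds by
construction: a member whose pre count equals the half-median and whose post
count equals the floor recomputes `zeta` equal to `zeta_LB` to machine
precision, because the totals normalization cancels.

**Counting error.**  Replicate agreement in such selections is dominated by
Poisson counting noise, so the per-variant error is propagated analytically:
`var(eps) = (1/pre + 1/post)/ln(2)^2` and
`var(zeta) = (var(eps_i) + var(eps_wt))/g_p^2`.  Zero counts give an
infinite-error sentinel.  Replicates are pooled by summing reads (the
maximum-likelihood treatment under Poisson noise) and the analysis repeated
on the pooled table.

**Conventions.**  Residue positions are 1-based; `*` is the stop symbol;
nonsense = mutation to `*`; variants absent pre-selection are dropped rather
than imputed (coverage is reported); a zero post-selection count receives a
configurable pseudo-count (default 0.5 reads) and is always flagged below
the bound.  Synonymous codon members of one protein variant are summarized
by a read-count-weighted mean (weights default to pre+post reads per
member — the populations are not distinguished by the convention, so the
choice is exposed as `weight_by`).

## The beneficial tail under extreme value theory

Beneficial mutations are threshold exceedances, the natural domain of the
generalized Pareto distribution (GPD).  All fits therefore operate on
`x = zeta - threshold > 0`; this matters in practice because a beneficial
rate of ~8 implies a mean excess of ~0.12, which would be impossible for
unshifted values bounded below by the threshold itself.

Four families are fitted by maximum likelihood: exponential (closed form;
the Gumbel-domain prediction), gamma and Weibull (each nesting the
exponential at shape 1, giving one-degree-of-freedom likelihood-ratio tests
against chi-squared(1)), and the GPD itself.  The GPD uses the sign
convention `kappa = 0` Gumbel, `kappa > 0` Frechet, `kappa < 0` Weibull
domain with upper endpoint `scale/|kappa|`.

Numerical choices:

* **GPD likelihood** is maximized by profiling over `theta = shape/scale`
  (a one-dimensional problem), with a coarse log-spaced scan bracketing a
  golden-section refinement.  The shape is constrained to `kappa >= -1`:
  below −1 the GPD likelihood is unbounded, and −1 itself is attainable
  (uniform data correctly fit `kappa = -1` with scale at the upper
  endpoint).
* **One-sample Anderson–Darling** P values use a parametric bootstrap
  (default `B = 999`) in which parameters are re-estimated per replicate,
  because testing a family with parameters estimated from the same data
  invalidates the fixed-distribution null tables.
* **GPD goodness of fit** uses the same logic: the Anderson–Darling
  statistic against the ML-fitted GPD, calibrated by a parametric bootstrap
  with refitting.  This is the package's own construction of a bootstrap
  GPD test; its null calibration is verified by simulation in the test
  suite.
* **k-sample Anderson–Darling** uses the Scholz–Stephens midrank (tie-aware)
  statistic, their finite-sample variance for standardization, and an
  asymptotic P value interpolated on the logit scale through their quantile
  surface `b0 + b1/sqrt(m) + b2/m` (m = k−1) at the five tabulated
  probability levels, with linear continuation outside the table.  Passing
  the same sample twice yields the statistic's minimum (0) by construction
  of the midranks.
* Likelihood-ratio statistics are clamped at 0 with a warning if a numeric
  fit violates nesting.  chi-squared(1) is used for all nested pairs even
  though the exponential sits on the boundary of the Weibull/gamma shape
  space; this matches standard practice for these model-comparison tables.

## Multi-substrate specificity

Two deliberately distinct rules are implemented verbatim:

* **Venn bins**: a variant belongs to the subset of substrates where
  `zeta > 0.15` — seven possible non-empty bins over three substrates, or
  `"none"`.
* **Specificity-determining**: `zeta > 0.15` on exactly one substrate *and*
  `zeta < 0` on every other.  This is strictly stronger than membership in
  a single-substrate bin (the others must be deleterious, not merely
  non-beneficial), and the test suite checks the containment.

Cross-substrate Pearson correlations exclude variants below either
substrate's detection limit by default (censored point estimates carry no
quantitative information), while binning keeps point estimates — matching
how such data are usually displayed.  PCA centers but does not scale the
variants × substrates matrix (columns share zeta units; scaling is a flag),
and reports *both* global eigenvalue shares and the per-column R² of the
rank-1 reconstruction, because "one component explains X% of a data set's
variance" is ambiguous between the two; neither is asserted as the other.

**Structure shells.**  For each residue position, the minimum Euclidean
distance is taken from any of its Calpha copies (all chains of the
oligomer, unless restricted) to any active-site atom across all active-site
copies — in a homohexamer the active site recurs six times and the minimum
over copies is the relevant quantity.  The active-site atom set is user
configuration (`active_site_spec()`), not a constant: published analyses
rarely enumerate it.  Mutations are binned into half-open 3-Angstrom shells
`[3k, 3k+3)` and normalized per shell by the available mutations there —
by default 19 missense possibilities per position, with an option to use
assayed-variant counts, since "total available mutations" admits both
readings.  Shells with no positions are reported as absent, not zero.
Hotspots are positions with at least five specificity-determining mutations
for one substrate.

## The simulator: what it emulates and what it does not

The generator reproduces the statistical structure the analysis assumes:

* a site-saturation universe (19 substitutions + stop per position,
  optionally several synonymous codons per protein variant, all sharing one
  protein-level growth rate);
* log-normal pre-selection abundances (`meanlog = log(100)`, `sdlog = 1` by
  default, putting the median member near 100 expected reads at the default
  depth of 10^6 — the coverage regime of a typical selection);
* deterministic exponential growth for `g_p = 8` doublings with passage
  re-dilutions (~4 doublings per passage).  Re-dilution rescales every
  lineage equally and thus never changes relative frequencies, so passages
  are recorded but not modelled; the realized wild-type doublings `g_wt`
  solve the total-biomass equation and are reported;
* all stochasticity enters through multinomial read sampling at the stated
  depths (counting noise is the dominant error source in this assay; no
  demographic noise is simulated);
* ground truth is a three-class DFE: a lethal point mass
  (default fraction 0.35, consistent with the large share of strongly
  deleterious substitutions in enzyme selections), a near-neutral Gaussian
  bulk (`sd = 0.05` relative growth rate), and an exponential beneficial
  tail (fraction 0.05, rate 7 — a few-percent beneficial class with mean
  advantage ~14%, the regime the beneficial-tail fits target).  Nonsense
  variants are forced lethal except within a C-terminal tolerance window
  (default 19 residues) where truncation is tolerated.
* lethal lineages persist at constant absolute abundance (cells neither
  divide nor die), matching how cheating is assessed in such selections;
  `cheat_leak` rescues a configurable fraction of a non-grower's deficit.
  For a 50/50 wild-type vs knockout competition over ~4.1 doublings this
  model, composed with the zeta equations, gives an expected knockout
  fitness metric near −1.2; published accountings of the same scenario can
  differ in how they count generations, so the simulator exposes the
  scenario rather than hard-coding any one expected value.

What it does **not** emulate — and therefore what passing tests do and do
not show about real data:

* **No deleterious continuum.**  Real selections show a broad continuum of
  intermediate deleterious effects; the three-class truth has a gap between
  the lethal mass and the neutral bulk.  One visible consequence: excluding
  below-bound variants raises replicate correlations in real data, but in
  the simulator the separated lethal blob *inflates* the all-variant
  correlation at moderate depth, and the improvement only reproduces when
  the above-bound signal is well resolved (the regime the test pins:
  depth 2×10^6, neutral sd 0.12).  Recovery tests validate the estimator,
  not the biology of any particular DFE shape.
* No nucleotide-level reads, no mRNA-level effects (synonymous codons share
  the protein-level growth rate), no plasmid copy-number or expression
  variation, no cross-feeding dynamics beyond the static `cheat_leak`
  factor.

`expected_zeta(r, g_wt, g_p)` returns `(r - 1) * g_wt / g_p`; for `r = 0`
it returns `-Inf` as a sentinel, because at any finite depth a dead
lineage's estimate is censored at the detection limit and the continuous
formula (`-g_wt/g_p`, the constant-abundance value) should not be mistaken
for a measurable target.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed, and bootstrap P values
are exactly reproducible under a fixed seed.  The test suite and the
acceptance script use sizes chosen to make sampling error negligible
relative to the tolerances they assert: 1,000-variant selections at depth
10^6 for recovery (slope within [0.9, 1.1], r > 0.95 above the bound),
5,000–10,000 draws for estimator recoveries (3-standard-error bands),
200 replicates × 199 bootstrap samples for Anderson–Darling size
calibration, and 50 seeded runs for goodness-of-fit null calibration.

## Known limitations

* The GPD boundary constraint (`kappa >= -1`) means very short-tailed
  samples report the boundary value rather than an unbounded-likelihood
  artefact; standard, but worth knowing when `kappa` prints as exactly −1.
* The k-sample Anderson–Darling P value is asymptotic (interpolated
  quantile surface), not exact; for tiny samples a permutation approach
  would be preferable.
* The detection limit is a single per-selection scalar; a per-variant limit
  (from each variant's own pre count) would be sharper but is not what the
  standard construction reports.
* The pipeline's specificity stage requires complete rows across
  substrates; variants missing in any selection are dropped from the
  multi-substrate matrix rather than imputed.
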
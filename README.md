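# dfescan

Analysis of deep mutational scanning (DMS) experiments read out by
**competitive growth selection**: thousands of enzyme variants compete in a
medium where growth requires the enzyme's activity, and deep sequencing of
the population before and after selection turns each variant's enrichment
into a quantitative fitness measurement.  `dfescan` is written for protein
engineers and molecular evolution researchers who have pre-/post-selection
variant count tables (the output of read-processing tools such as Enrich)
and want, on one or several substrates:

1. **Normalized fitness metrics with detection limits.**  For library member
   *i* with pre- and post-selection frequencies *f*₀ᵢ and *f*ƒᵢ,

   - enrichment ratio: ε*ᵢ* = log₂(*f*ƒᵢ / *f*₀ᵢ)
   - fitness metric: ζ*ᵢ* = (ε*ᵢ* − ε_WT) / *g*ₚ

   where *g*ₚ is the number of population doublings and ε_WT the wild-type
   enrichment ratio, so ζ = 0 is wild-type-like and ζ > 0.15 ("beneficial")
   corresponds to roughly a 10% growth-rate advantage.  The sequencing
   detection limit ζ_LB — below which a variant is only categorically
   "deleterious" — is anchored to a floor of post-selection reads (default
   10) via ε_LB = log₂(floor / *f*_LB), with *f*_LB the half-median
   pre-selection read count normalized by the post/pre read-count ratio.
   Poisson counting error is propagated through both equations
   (var ε = (1/pre + 1/post)/ln²2; var ζ = (var εᵢ + var ε_WT)/*g*ₚ²).

2. **Extreme-value analysis of the beneficial tail.**  Threshold exceedances
   x = ζ − 0.15 are fitted by maximum likelihood to the exponential (the
   Gumbel-domain prediction for beneficial DFEs), gamma, Weibull and
   generalized Pareto (GPD) families; nested families are compared by
   likelihood-ratio tests against χ²(1), fits are checked with one-sample
   Anderson–Darling tests calibrated by parametric bootstrap and with a
   bootstrap GPD goodness-of-fit test, and selections are compared with the
   Scholz–Stephens k-sample Anderson–Darling test.  The GPD shape κ places
   the tail in its domain of attraction (κ = 0 Gumbel, κ > 0 Fréchet,
   κ < 0 bounded Weibull).

3. **Multi-substrate specificity.**  Cross-substrate correlations above the
   detection limits, PCA of the variants × substrates fitness matrix,
   seven-bin Venn classification of beneficial mutations, the
   specificity-determining call (ζ > 0.15 on exactly one substrate, ζ < 0 on
   the others), hotspot positions, and distance-shell analysis of beneficial
   mutations around the active site of a (multimeric) structure.

4. **A growth-selection simulator** with known per-variant relative growth
   rates, so every stage of the analysis can be validated end to end against
   ground truth without any external data.

## Worked example

Simulate a 1,000-variant site-saturation selection (50 residues × 20
substitutions, sequencing depth 10⁶, eight population doublings, two
replicates), then analyse it:

```r
library(dfescan)

spec  <- library_spec(protein_length = 50, sequencing_depth_pre = 1e6,
                      sequencing_depth_post = 1e6)
lib   <- make_library(spec, seed = 101)
truth <- sample_true_dfe(lib, true_dfe_spec(seed = 102))
counts <- simulate_selection(lib, truth, selection_scenario(g_p = 8),
                             seed = 103, replicates = 2)

fit <- compute_fitness(combine_replicates(counts), g_p = 8, label = "ACT")
fit
#> fitness_table: 1001 members (ACT)
#>   eps_wt = 0.2919, zeta_lb = -0.702, g_p = 8, coverage = 100%
#>   variant position wt_aa mut_aa codon     type pre_count post_count     epsilon
#> 1      WT       NA  <NA>   <NA>     1       wt    600080     734661  0.29192384
#> 2     K1A        1     K      A     1 missense       397        382 -0.05556637
#> 3     K1C        1     K      C     1 missense       144          1 -7.16992500
#> ...
```

The wild type sits exactly at ζ = 0; K1C collapsed to a single
post-selection read and is flagged below the detection limit
(ζ_LB ≈ −0.70); every other ζ is a quantitative estimate with its
counting-noise standard deviation.  Fitting the beneficial tail:

```r
tail_fit <- fit_dfe_models(extract_exceedances(fit), ad_bootstrap = 199,
                           gof_bootstrap = 199, seed = 1)
tail_fit$fits$exponential
#> dfe_fit [exponential], n = 20
#>   rate
#> 8.0551
#> log-likelihood: 21.726
#> Anderson-Darling A2 = 0.4047 , P = 0.665
tail_fit$lrt$exp_vs_gamma
#> LRT exponential vs gamma: LLR = 0.1164, P = 0.733 (chi-squared, df = 1)
```

The 20 beneficial exceedances fit an exponential with rate ≈ 8.1 (mean
advantage ≈ 0.12 ζ units, close to the simulator's true exponential tail of
rate 7), the Anderson–Darling test does not reject it, and the gamma
generalization adds nothing (LRT P = 0.73) — the behaviour expected of a
Gumbel-domain beneficial DFE.

`run_pipeline()` chains these stages over several substrates, adds the
specificity classification (and, given a PDB structure plus an
`active_site_spec()`, the distance-shell analysis) and writes
plotting-ready TSV/JSON outputs with a provenance manifest.

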
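---
title: "Conditional mutual information inference of TF modulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional mutual information inference of TF modulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindyr)
```

## The model

A transcription factor (TF) exerts its effect through its regulon — the set
of genes it transcriptionally controls. A *modulator* is a gene whose
expression level conditions the strength of the TF–target associations
without necessarily changing TF mRNA abundance: a kinase, cofactor or
chromatin regulator whose presence makes the TF more (or less) effective.
Because the modulator acts on the TF protein, it leaves a statistical
fingerprint that can be read off expression data alone: the mutual
information (MI) between TF and target differs between samples where the
modulator is highly expressed and samples where it is not.

The pipeline implemented here formalises that idea in three steps:

1. **Regulons.** For each TF, MI is estimated against every other gene;
   permutation p-values are adjusted with Benjamini–Hochberg (BH) and
   targets with adjusted p below `alpha_regulon` form the regulon, each
   with a mode (activated/repressed, from the Spearman sign).
2. **Conditioning.** For each candidate modulator *M* passing an
   independence constraint (|Spearman rho| with the TF < `rho_max`),
   samples are ranked by *M*'s expression and the top and bottom tertiles
   retained. For every target, MI with the TF is recomputed within each
   stratum and summarised by the normalised differential

   $$dMI = \frac{MI_{top} - MI_{bottom}}{MI_{top} + MI_{bottom}} \in [-1, 1],$$

   with $dMI = 0$ when both stratum MIs vanish. For display, the shifted
   value $MI_{shift} = MI_{original}\,(1 + dMI)$ overlays the regulon's MI
   profile (`shift_profile()`, `autoplot()`). Per-target significance
   comes from a permutation null that reshuffles the high/low stratum
   labels over the pooled stratum samples — this preserves the TF–target
   joint distribution while destroying exactly the modulator conditioning,
   which is the hypothesis under test. The permuted statistic is $|dMI|$,
   so positive and negative modulation are detected symmetrically. A
   bootstrap stability completes the per-target call (below).
3. **Regulon-level tests.** A modulator of a TF should modulate more of
   that TF's targets than chance allows (one-sided Fisher's exact test on
   {in this regulon vs rest of the tested universe} × {modulated vs not}),
   and preferentially its *strongest* targets (one-sided two-sample
   Kolmogorov–Smirnov on the full-cohort MI of modulated vs non-modulated
   targets). FET p-values are BH-adjusted per TF across candidates;
   candidates with adjusted p < `alpha_adj` are reported, signed by the
   median dMI of their modulated targets. A significant modulator of one
   TF that is itself a target of another TF is an *in-modulator* — a link
   in a TF-to-TF chain.

### Assumptions

- Modulator mRNA is an adequate proxy for modulator activity.
- TF–target dependence is monotone enough for rank-based MI to capture it.
- The cohort is heterogeneous enough that modulator expression genuinely
  varies across samples; tertiles of a near-constant gene are noise (a
  constant modulator is an error).
- Modulator and TF expression are approximately independent; correlated
  candidates are excluded rather than deconfounded.

## Estimators and numerical choices

**MI estimator.** The default `copula_gaussian` estimator rank-transforms
both vectors to normal scores, takes their Pearson correlation $r$, and
returns $-\tfrac12\log(1-r^2)$ nats, with $r^2$ capped at $0.9999$
(≈ 4.605 nats) so perfectly dependent inputs do not overflow. It is
invariant under strictly monotone transforms, symmetric, fast enough for
thousands of label permutations, and matches the bivariate-Gaussian closed
form $-\tfrac12\log(1-\rho^2)$ used as the analytic oracle in the tests.
An equal-frequency binned plug-in estimator (`binned_plugin`, $b =
\max(2, \lfloor n^{1/3}\rfloor)$ bins on ranks) is available for
dependence with a strong non-monotone component. Rank ties are broken by
first occurrence; this makes every within-subset score vector an exact
permutation of one fixed score vector, which is what allows the label
permutations to be evaluated with pure vector indexing rather than a
per-permutation sort. Zero-variance inputs yield MI 0 with a degenerate
flag rather than an error, so cohort scans never abort.

**Permutation p-values** use the add-one rule,
$p = (1 + \#\{|T_b| \ge |T_{obs}|\})/(1 + B)$, bounded below by
$1/(1+B)$. A practical consequence for regulon inference: BH-adjusting $k$
floor-level p-values among $m$ genes gives $\approx m/(k(1+B))$, so $B$
must comfortably exceed $m/(k\alpha)$ for a scan to retain anything. The
per-TF null is computed once by permuting a rank vector against the TF
profile and shared across genes — legitimate because the estimators are
rank-based, so under the null every gene's permutation distribution given
ranks is identical.

**Seeds.** One master seed per run; a child seed is derived by hashing the
(TF, modulator) pair, so results are bit-reproducible and invariant to the
order in which candidates are processed. Within one (TF, modulator) task
the label permutations are shared across the regulon's targets: one
reshuffle scores every target, which is statistically equivalent to
per-target permutation under the same null and roughly fifty times
cheaper at a 50-target regulon.

**Bootstrap stability.** The guiding idea — check how often an inferred
modulated target is re-observed in subsamples of the cohort — is
operationalised as: resample each stratum with replacement `n_boot` times
and count the fraction of resamples in which the target's $|dMI|$ again
reaches its permutation-null $(1-\alpha_{target})$ quantile with the
observed sign. A target is *modulated* when its permutation p is below
`alpha_target` **and** its stability is at least `stability_min`.

**FET table.** How the 2×2 table is built is a genuine design choice. Here
the universe is every (TF, target) record evaluated for the candidate in
the run, which controls for candidates that perturb everything globally.
In a single-TF run the table degenerates, and an exact one-sided binomial
test of the modulated count against `alpha_target` replaces it.

**KS direction and ties.** The KS test is one-sided: the alternative is
that modulated targets have stochastically *larger* full-cohort MI
(modulation of the strongest interactions). It is run on the MI values;
with a strict ordering this is identical to running it on ranks.

**Other decided points.** The permuted per-target statistic is $|dMI|$
(not raw $\Delta MI$), keeping the statistic on the same normalised scale
across targets. BH adjustment is applied to the FET p per TF, with the KS
p reported alongside rather than combined. Two-cohort consensus is the
strict same-sign intersection of significant pairs. Stratum ties are
broken by sample id so strata are deterministic; the middle third is
unused. The TF itself is never its own candidate; targets of the same TF
are allowed as candidates, which the in-modulator semantics requires.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fraction` | 1/3 | stratum fraction (tertiles), floor-rounded |
| `n_perm` | 1000 | stratum-label permutations per (TF, modulator) |
| `alpha_target` | 0.01 | per-target level on the \|dMI\| permutation p |
| `n_boot`, `stability_min` | 100, 0.5 | bootstrap resamples and the minimum re-observation fraction |
| `rho_max` | 0.3 | independence constraint on \|Spearman rho\|(TF, M) |
| `alpha_regulon`, `min_regulon` | 0.01, 10 | regulon inference level; minimum size for FET/KS to be meaningful |
| `alpha_adj` | 0.001 | BH-adjusted reporting cut-off for modulators |

`n_perm = 1000` and `alpha_adj = 0.001` are the method's standard
settings; `alpha_target`, `stability_min` and `rho_max` have no canonical
published values, and the defaults here were fixed from the null
calibration requirement (per-target false-call rate at or below
`alpha_target`) before any recovery experiment was run.

## The synthetic cohort generator

`simulate_cohort()` produces the statistical structure the method is built
to detect, with known truth. Each TF is standard normal over `n_samples`;
the candidate modulator is standard normal and independent of all TFs, so
planted modulators pass the independence filter by construction; each
target is

$$t_i = \beta_i\,(1 + \gamma\, s(M))\,TF + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2),$$

where $s(M)$ is the within-cohort rank of $M$ scaled to $[-1, 1]$. The
interaction is multiplicative on the *coupling*, not the mean: the
modulator changes TF–target MI without shifting target mean expression,
which is precisely the signal the conditional analysis isolates, and
rank-scaling $s(M)$ bounds the effective coupling so the design cannot
saturate silently (a configuration whose implied correlation exceeds 0.99
is rejected). `simulate_in_modulator_cohort()` additionally wires the
modulator as a noisy target of a second TF, planting a known in-modulator
call. Defaults — 300 samples, 50 targets with $\beta \in [0.3, 0.8]$ and
20 % repressed, 200 decoys, unit noise — give tertile-stratum couplings of
roughly 0.65 vs 0.15 (Spearman) at $\gamma = 1$, a realistic contrast for
a strong cohort-level modulator.

What the generator does **not** emulate: real tumour-cohort covariance
(subtype mixtures, copy-number confounding, batch structure), multiple
modulators acting on one TF, modulators correlated with the TF, or
non-monotone TF–target links. Passing the synthetic suite therefore
demonstrates that the statistics behave as designed under the stated
model — not that any particular biological cohort will yield comparable
power.

## Validation design and problem sizes

The test suite validates, at $n = 300$ and tertile strata: formula
fidelity of $dMI$/$MI_{shift}$ on a dense grid; estimator accuracy against
the Gaussian closed form (±0.05 nats at $n = 5000$); null calibration over
200 null-modulator cohorts at 500 permutations (per-target call rate,
super-uniformity of FET/KS p-values, zero significant modulators);
recovery of planted positive and negative modulators over 20 seeds each
(500 permutations, 20 decoy candidates); KS directionality on constructed
profiles; in-modulator recovery over 20 planted and 20 null seeds; the
add-one floor and calibration of the resampling enrichment test at 10,000
random sets; and bit-level determinism of the record table under a fixed
master seed. `scripts/acceptance.R` re-runs a condensed version of the
same computations from scratch and writes the resulting quantities as
JSON.

## Known limitations

- Tertile stratification discards the middle third of the cohort; power
  falls quickly below ~150 samples (stratum size 50), and the per-target
  permutation floor bounds attainable significance at small `n_perm`.
- The independence constraint excludes genuinely interesting candidates
  that are transcriptionally coupled to the TF; it trades recall for
  interpretability.
- MI in nats is reported unscaled; the scaled profiles are a reporting
  convenience and regulon maxima are not comparable across TFs.
- A modulator acting only in the discarded middle stratum, or
  non-monotonically in its own expression, is invisible to the tertile
  contrast.
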
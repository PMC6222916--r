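---
title: "Scoring tandem-fluorescent-timer screens: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tandem-fluorescent-timer screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tftscreen)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the choices made where the design was
genuinely open.

## 1. The timer model

A tFT fusion carries sfGFP (fast-maturing) and mCherry (slow-maturing) on
one protein. Per channel we model two pools — unmatured (dark) and matured
(fluorescent) protein:

$$\frac{du}{dt} = \beta - (m + k)\,u, \qquad
  \frac{df}{dt} = m\,u - k\,f,$$

with synthesis rate $\beta$ (molecules·min⁻¹), maturation rate $m$
(min⁻¹) and first-order degradation $k$ (min⁻¹) acting equally on both
pools. The steady state is $f^* = (\beta/k)\, m/(m+k)$, so the
background-free mCherry/sfGFP ratio

$$R(k) = \frac{m_C/(m_C+k)}{m_G/(m_G+k)}$$

cancels $\beta$ and is strictly decreasing in $k$ when $m_C < m_G$,
bounded in $(m_C/m_G,\,1]$. `steadyStateIntensities()` and
`steadyStateRatio()` implement the closed forms; `simulateTrajectory()`
integrates the ODE with `deSolve` (rtol = atol = 1e-10) and serves as the
independent oracle that the closed forms are right. `inferKdegFromRatio()`
inverts $R$ analytically ($R$ is a Möbius function of $k$, so
$k = m_C m_G (1-R)/(R\,m_G - m_C)$), rejecting ratios outside the open
attainable band with the band reported in the error.

**Assumptions.** One-step maturation per fluorophore (no mCherry
intermediate); identical degradation of both fluorophores; brightness
scale factors fixed at 1 so that only ratios and log-differences are
interpreted. The tag can in reality also report environment changes
(e.g. vacuolar pH quenching of GFP fluorescence); we make no attempt to
separate localization from turnover — a known limitation of the readout
itself, not only of this implementation.

**Default rates.** No measured rate constants accompany the screen, so
defaults encode the qualitative fast/slow ordering with round half-times:
$m_G = \ln 2/6$ min⁻¹, $m_C = \ln 2/40$ min⁻¹. The base degradation rate
is $\ln 2/30$ min⁻¹ (30-min half-life, typical of secretory-pathway
turnover). This operating point puts the WT ratio at 0.514, leaving room
for injected stability shifts of at least ±0.5 on the log-ratio scale in
both directions before the ratio band saturates; exact values only shape
effect sizes in synthetic data, not any inference.

## 2. The synthetic screen generator

`simulateScreen()` emulates the screen's physical structure: 1536-colony
plates (32 × 48), one 6-column block per protein × genotype holding 3
adjacent technical-replicate colonies and 3 adjacent untagged
negative-control colonies, and an 8-colony reference strain set on row 1
of every plate.

Colony intensities are
$I = s \cdot f^* \cdot e^{\varepsilon} + a \cdot e^{\varepsilon}$ per
channel, where $s$ is a lognormal colony-size factor (sdlog 0.15) shared
by both channels of a colony, $\varepsilon \sim N(0, \sigma^2)$ with
$\sigma = 0.1$ independent per colony and channel, and $a$ is additive
autofluorescence (40 a.u. green, 20 a.u. red — yeast autofluorescence is
stronger in the green channel and both are small against signals in the
thousands). The multiplicative noise applies to the total collected
light, background included, so negative controls are noisy rather than
constant. Rationale for the lognormal form: intensities stay positive and
variance grows with signal, the qualitative behaviour of fixed-gain plate
readers. A 2% fraction of sample colonies are failed crosses: they carry
autofluorescence only and a colony size drawn well below the exclusion
threshold.

Injected effects are *realized exactly* through the closed form: for a
stability shift $\delta$ (defined on the Δ-score scale, WT − mutant), the
mutant degradation rate solves $R(k_{mut}) = R(k_{WT}) e^{-\delta}$
analytically; for an abundance shift the mutant $\beta$ is scaled so the
log sfGFP steady state moves by exactly that amount. The truth table
(`screenTruth()`) therefore contains shifts the noise-free pipeline must
return to machine precision — the package's strongest end-to-end test.

**Layout choice.** All genotype blocks of a protein are placed on the
same plate (248 blocks per plate is divisible by 4, so proteins never
straddle plates). Per-plate, per-channel normalization constants then
cancel exactly inside each WT − mutant Δ-score, which keeps the
replicate-based variance estimate an honest description of the Δ-score's
sampling noise. Spreading genotypes across plates would add shared
reference-estimation noise to every Δ-score on a plate pair — a
correlated nuisance the moderated t-test does not model.

**What the generator does not emulate:** spatial plate gradients and edge
effects (the pipeline contains no correction for them), colony growth
curves over time, pH/localization artefacts, and any real biological
covariance between stability and abundance. Passing tests on synthetic
screens therefore demonstrate the statistical machinery, not robustness
to those real-data nuisances.

## 3. Preprocessing

The order is fixed: **exclusion → background correction → log →
normalization**; a regression test pins it, because subtracting
background after the log transform is a different (and wrong) statistic.

* *Exclusion*: sample colonies below 0.3× the plate's median colony size.
  The median is taken over all non-empty positions (samples, controls,
  references) so the reference stays meaningful even if many crosses
  failed.
* *Background*: the mean (not median; with three values the difference is
  minor, and the mean matches the screen's described averaging) of the
  block's negative controls is subtracted from each sample colony, per
  channel, preserving replicate-to-replicate variance for the t-test.
  Reference colonies are corrected with the plate-wide control mean.
  Corrected intensities ≤ 0 cannot be log-transformed; the replicate is
  dropped rather than floored, since flooring fabricates signal near
  background.
* *Normalization*: natural log throughout (the log base only rescales
  Δ-scores, and the hit thresholds are defined on the same base);
  per plate and channel, the median log intensity of the reference
  colonies is subtracted, making the reference median exactly 0 and
  detector-gain differences between plates vanish.
* *Collection*: valid replicates are grouped per (protein, genotype);
  strains with fewer than 2 valid replicates are flagged untestable
  rather than erroring.

## 4. Δ-scores and the moderated t-test

`deltaScore()` uses the two-sample pooled variance of replicate
log-ratios on $d = n_{WT} + n_{mut} - 2$ degrees of freedom. The
empirical-Bayes prior (`fitVariancePrior()`) is the standard scaled
inverse-chi-square fit by method of moments on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: the prior degrees of
freedom solve a trigamma equation (monotone Newton inversion of the
trigamma function), with two limits handled explicitly — no excess
spread gives $d_0 = \infty$ and $s_0^2 = \overline{s^2}$ (the
known-variance limit), and fewer than 10 usable variances gives the
no-moderation fallback $d_0 = 0$ (ordinary pooled t), announced with a
message. A unit test cross-checks the fit against `limma::squeezeVar` on
simulated variances; the implementation itself is independent.

The moderated statistic is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$,
$t = \Delta / \sqrt{\tilde s^2 (1/n_{WT} + 1/n_{mut})}$, with two-sided
p-values on $d + d_0$ degrees of freedom. The prior is fitted **per
mutant** by default (each mutant screen is its own experiment;
`priorScope = "global"` is available). Raw p-values are thresholded
directly for hit calls — the screen's design; Benjamini–Hochberg
q-values are available as an extra column (`addBH = TRUE`) but never feed
the hit calls.

Sign conventions, asserted throughout the tests: negative
`delta_mC_sfG` ⇔ stabilized in the mutant; positive `delta_sfG` ⇔ more
abundant in the mutant.

## 5. Hit calling, clustering, volcano tables

Thresholds are strict inequalities as the screen states them
(*p* < 0.1, net |Δ| > 0.2, strong tier |Δ| > 0.5); ties are excluded.
"Net Δ-score" is interpreted as the absolute value — the volcano's
subsetting is symmetric in sign.

Clustering of the protein × mutant Δ-score matrix (rows restricted to
proteins passing thresholds in ≥ 1 mutant, missing cells imputed as 0 and
flagged) uses Euclidean distance with complete linkage — the defaults of
the heatmap tooling this style of screen is plotted with; both are
configurable. Rows only are clustered; the three mutant columns keep a
fixed order. Leaf order is made fully deterministic by a stated
tie-break: at every merge the subtree containing the lower original row
index is placed first. With fewer than 2 qualifying rows the ordering is
the identity and no dendrogram is built. The package emits the underlying
tidy tables (`volcanoTable()`, `clusterProfiles()$table`), not figures.

## 6. Flow cytometry

Per repeat, the population ratio is mean(mCherry)/mean(sfGFP) over cells
passing the positivity filter — robust to dim cells, unlike the mean of
per-cell ratios (offered as an alternative). The WT/mutant ratio of
ratios pairs repeats by acquisition index and reports mean ± SD; the
p-value is an unpaired two-sample Student's t-test on the per-repeat
ratios under equal variances, matching the screen's stated test. The
per-cell generator adds a shared lognormal expression factor per cell
(sdlog 0.35, cancels from population ratios), per-channel cell noise
(sdlog 0.15) and a per-repeat gain factor (sdlog 0.03) — without the
repeat-level term, 20,000-cell means would make the between-repeat
variance unrealistically tiny.

## 7. Numerical choices and degenerate inputs

* Ratio inversion is analytic; round trips hold to 1e-8 relative or
  better.
* `kDeg = 0` has no steady state and errors; `ratio = 1` maps to
  `kDeg = 0` only as a limit and is excluded from the inversion's domain.
* All-zero replicate variances (noise-free simulations) leave p-values
  undefined rather than zero; `scoreScreen()` falls back to the
  no-moderation prior and flags the records.
* p = 0 in volcano tables is capped at $-\log_{10} p = 300$ and flagged.
* Seeds are explicit arguments everywhere; the same seed reproduces a
  screen bit for bit.

## 8. Validation problem sizes

The test-suite and acceptance checks run at sizes chosen to make the
assertions sharp while staying quick on a laptop: 2000 proteins for the
type-I-error check of the moderated test (band 0.08–0.12 at the 0.1
level), 500 proteins for power/direction of |Δ| = 0.5 effects (≥ 90%
correct-sign recovery) and for the null-call rate, 5000 simulated
variances for prior recovery (d₀ within ±20%, s₀² within ±10%), 50
random parameter draws for the ODE-vs-closed-form oracle (< 0.1%), and
1000 seeded simulations for the 5% calibration of the flow null
comparison.
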
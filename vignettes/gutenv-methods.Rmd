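---
title: "Methods and design choices in gutenv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in gutenv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gutenv analyses longitudinal gut-microbiome surveys from randomized
crossover interventions — every participant passes through normoxic bed rest
(NBR), hypoxic bed rest (HBR) and hypoxic ambulation (HAmb), with stool
sampled at days −5, −1, 3, 10, 18 and 21 — together with chemical
measurements of the intestinal environment. This vignette explains the
models behind each stage, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data generator does and does
not establish about real data.

## The synthetic study and its defaults

`generate_dataset()` produces every input the pipeline consumes from one
integer seed. Its defaults *are* the emulated study conditions:

* **Design.** 9 participants × 3 arms × 6 days (162 design slots). Arm order
  per participant follows a Latin-square rotation drawn from the seed. A
  per-sample `dropout` probability is available because real defecation
  events are irregular, but no rate is documented for the study, so the
  default keeps every slot.
* **Community.** 60 genera across five phyla with geometric-series expected
  abundances (ratio 0.93), ordered so Firmicutes + Bacteroidetes hold ≥ 80 %
  of the mass, as in healthy adult microbiomes. Counts are
  Dirichlet-multinomial: per-sample compositions are Dirichlet draws with
  total concentration `theta = 200` (moderate overdispersion; replicate
  samples of one subject differ by a few percentage points in the dominant
  genera), multiplied by a per-participant, per-taxon log-normal tilt with
  `participant_sigma = 0.4` — subjects differ stably by ~1.5-fold in
  individual taxa, which is what drives the large "individual participant"
  variance component such studies report.
* **Depths.** Read depth is truncated-normal, mean 105300, SD 39200,
  truncated at `1000 · scale`; `scale` shrinks depths for desk runs without
  changing the design.
* **Planted effect.** `bacteroides_fold = 2` scales the *final* expected
  relative abundance of the genus *Bacteroides* in HBR samples of days
  {18, 21}, with the other taxa renormalized into the remaining mass. The
  fold therefore equals the expected effect/control relative-abundance ratio
  exactly; multiplying the raw weight and renormalizing everything would
  dilute a planted fold `f` to `f/(1 + (f−1)p₀)`. `fold = 1` is the null
  configuration. The affected taxa and samples are returned in a ledger —
  tests never have to rediscover what was planted.
* **Chemistry.** Spectra are a chromophoric-DOM exponential
  `a₀ · exp(−S(λ−275))` (a₀ log-normal around 30 cm⁻¹, slope S ≈ 0.015 nm⁻¹)
  plus a Gaussian aromatic band at 280 nm, pushed through the Napierian
  relation at path length 2/3 cm, divided by dilution (1:10, 1:50, 1:100)
  and given additive noise (SD 0.002 absorbance). Conductivity is log-normal
  around 2 mS/cm per participant with the per-arm week-1 increases
  (+67 % HBR, +32 % NBR, 0 % HAmb) applied from the first intervention week
  onward.
* **Metadata.** Three matrices of widths 109/12/110. Within each, a
  configurable subset (defaults 8/4/8) is linearly coupled — coefficient 1,
  unit Gaussian noise — to the standardized log relative abundance of the
  effect taxon (the planted community gradient); the rest is pure noise. The
  design matrix also carries the deterministic encodings day, week and arm
  indicators.

What the generator deliberately does **not** emulate: read-level error and
chimera formation, primer and copy-number bias, a realistic phylogeny (the
tree is random), carryover between crossover campaigns, and autocorrelated
within-participant time courses beyond the stable tilt. Passing tests on
this generator therefore demonstrate the *statistical machinery* —
calibration under exchangeable nulls, power against known planted effects,
algebraic identities — not the biological fidelity of any real dataset.

## DOM spectral indices

Absorbance is converted as `a(λ) = 2.303 · A(λ) / l`; all indices are
computed after correcting back to the undiluted supernatant. The measurement
grid is 5 nm, but three index wavelengths (217, 254, 287 nm) fall between
grid points; they are linearly interpolated. The working dilution is the
least-diluted spectrum whose maximum absorbance over 217–420 nm lies in
[0.05, 1.0] (photometric reliability window); if none qualifies, the nearest
one is used and a warning is emitted. SUVA is evaluated at 254 nm (the
standard SUVA254 convention). The TDLP9 lignin-phenol model is applied to
the per-cm Napierian coefficients exactly as converted — no unit rescaling —
and any index whose required coefficient is non-positive is returned as
`NA`, never silently zero, so downstream statistics can exclude it.

Conductivity calibration fits measured-versus-nominal KCl standards by
ordinary least squares, inverts the line for the sample readings, warns when
R² < 0.99, and reports per-level electrode drift (relative change of
repeated-standard batch means; flagged above 5 %).

## Diversity machinery

The α-suite uses the natural-log Shannon convention and the bias-corrected
Chao-1 (`S + F₁(F₁−1)/(2(F₂+1))`, defined even when no doubletons exist).
Brillouin goes through log-gamma, so depths of 10⁵ reads do not overflow.
Fisher's α is the root of `S = α·ln(1+N/α)`, bracketed bisection plus Newton
polish to |residual| < 10⁻¹⁰. Margalef and equitability return `NA` at the
degenerate cases N = 1 / S = 1 instead of infinities, and the count-only
indices (Brillouin, Chao-1, Fisher's α) are `NA` in profile mode, where the
input is a relative-abundance or chemical-fingerprint vector.

The four β-dissimilarities follow the classical formulas on counts
(Bray-Curtis), presence (Jaccard) and relative abundances (Yue–Clayton θ,
Morisita–Horn). UniFrac accumulates per-branch descendant mass in one
postorder pass; the weighted variant is normalized by `Σ b(p+q)` over
branches, which makes it 1 for fully disjoint two-leaf communities and
equal to `Σ|p−q| / Σ(p+q)` on a unit-branch star tree.

## Permutation tests

PERMANOVA, AMOVA and HOMOVA all work on squared distances. The pseudo-F of
PERMANOVA and the mothur-convention AMOVA Fs coincide numerically; `amova()`
additionally reports the molecular-variance components and the among-group
fraction (phi). HOMOVA's Bartlett-style statistic is non-negative by
Jensen's inequality. All permutation p-values use the `(1 + count)/(1 + B)`
estimator, so p is never 0 and never below the resolution of the chosen B.
Group labels are permuted freely — the crossover design gives no canonical
restricted scheme — with a `strata` argument for within-participant
permutation when a blocked analysis is wanted. Default permutation counts
follow the field's convention for these data: 9999 for distance/Mantel
tests, 10000 for the one-way NP-MANOVA use, both configurable. A caveat
documented here deliberately: with participant-matched cohorts, free-label
permutation is only approximately exchangeable; the package's calibration
tests therefore use random splits of one arm/day window, which are exactly
exchangeable.

## The differential battery

Four tests vote per taxon, and a taxon is *congruent* only when all four are
individually significant — the conjunction is monotone, so tightening any
threshold can only shrink the congruent set.

* **metastats-style**: Welch t on relative abundances with a two-sided
  label-permutation null; taxa with pooled counts below 8 go to Fisher's
  exact test on the pooled 2×2 table; BH q across taxa. One resolution fact
  matters in practice: for a *single* discovery among T taxa to reach
  q < 0.05, the permutation count must satisfy `B ≥ T/0.05 − 1` (≈ 1200 for
  60 taxa), because the smallest achievable q is `T·(1+c)/(1+B)`. The
  battery therefore defaults to B = 1999.
* **IndVal**: specificity × fidelity scaled to 100, one-sided permutation p.
* **Kruskal–Wallis + effect screen**: the rank test supplies p (ties-corrected
  χ² approximation); taxa additionally need a between-group effect
  `max |log₁₀(mean+ε) − log₁₀(mean+ε)|` of at least 0.25 (≈ 1.8-fold), with
  ε half the minimum nonzero relative abundance. This is a deliberately
  one-dimensional surrogate for an LDA-score filter: it preserves the
  "significant *and* biologically sizeable" semantics. The common 10-fold
  threshold (1.0 on the log₁₀ scale) would be inconsistent with the battery's
  own purpose here — the canonical planted signal is a 2-fold shift
  (log₁₀ 2 ≈ 0.30), and a conjunction member that cannot fire on the
  effect the battery exists to find would make the congruency vacuous. The
  threshold is exposed in the configuration.
* **AWKS**: the abundance-weighted L1 distance between the two cohorts'
  ubiquity curves over the threshold grid, `Σ aₖ|U_A−U_B| / Σ aₖ` — higher
  abundance thresholds weigh more. The sup-norm (classic KS) variant is
  available via `weighting = "sup"`. D ∈ [0, 1] and D = 0 iff the curves
  coincide on the grid.

The ubiquity grid defaults to 30 log-spaced thresholds from 10⁻⁵ to the
maximum observed relative abundance. Major/minor core classification uses
ubiquity ≥ 0.75 at 10⁻³ (major) and ≥ 0.5 at 10⁻⁴ (minor); the study printed
no cutoffs, so these are configuration with sensible defaults, and the
abundance-variability plot data report the coefficient of variation as the
variability axis.

## Variation partitioning

Community counts are Hellinger-transformed (square-root relative
abundances), the standard preparation of compositional counts for linear
redundancy analysis. Adjusted R² uses the Ezekiel correction with the rank
of the predictor matrix; the seven exclusive fractions come from
inclusion–exclusion over the subset R²s, so fractions plus the unexplained
remainder sum to 1 identically. Negative adjusted fractions are reported
as-is (clipping would destroy the identity).

Screening is univariate: each variable's marginal RDA R² against the
Hellinger community, with a row-permutation p (default 5000 permutations),
followed by co-correlation pruning (while any retained pair has |r| > 0.8,
drop the member with the larger mean absolute correlation to the rest).
Two retention criteria are provided because the choice genuinely matters:

* `mode = "alpha"` drops variables with p ≥ 0.05. By construction it retains
  about 5 % of a pure-noise matrix, and because those survivors are selected
  for large observed R², their adjusted fractions stay slightly positive —
  with 109/110-variable noise matrices at n = 162 this puts ≈ 1 % of
  "explained" variance into each noise matrix.
* `mode = "probe"` retains only variables whose marginal R² exceeds the
  maximum over 100 independent standard-normal probe variables — the
  association threshold of a completely random test variable, in the spirit
  of shadow-variable selection. This empties noise matrices almost surely
  while keeping variables with genuine community coupling, and it is the
  mode used when the goal is a clean variance hierarchy across matrices.

Partitioning refuses to run when the retained variables reach n − 1 (the
fit would be saturated) and asks for stronger screening instead.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes the stages in dependency order, writes one TSV per
result, and records a manifest (package version, seed, per-stage wall time,
file digests). One global seed fans out to per-stage child seeds by stable
hashing of stage names, so disabling one stage never shifts another stage's
random stream; two runs from the same config differ only in manifest
timestamps.

The package's own statistical checks run at reduced problem sizes chosen to
keep a full check fast on a laptop while leaving Monte-Carlo error well
inside the asserted bands: null calibration uses 500 simulated datasets at
`scale = 0.05` with 99 permutations per test (the nominal-level check then
has a standard error just under 1 %), recovery uses 50 simulations, and the
end-to-end determinism check runs the default pipeline twice at
`scale = 0.1`.

## Known limitations

* The KW member relies on the χ² approximation; at very small cohorts or
  heavily tied (sparse) taxa its per-taxon level is only approximate, which
  is why calibration is assessed on abundant taxa.
* AWKS depends on the threshold grid; two curves can coincide on a coarse
  grid while differing between grid points.
* Free-label permutation ignores the participant matching of the crossover;
  a blocked mode exists but is off by default.
* The congruency battery's metastats member inherits the permutation
  q-floor discussed above: a lone, moderate discovery can land exactly on
  q ≈ 0.05·T/B and miss the cutoff in a minority of replicates.
* All power statements are relative to the generator's Dirichlet-multinomial
  world; real amplicon data are more zero-inflated and more correlated
  across taxa.
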
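---
title: "Learning variance-stabilizing transforms from replicate signal tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning variance-stabilizing transforms from replicate signal tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackvst)
```

## The model

A sequencing-based signal track reports a value $x_i$ (read count, fold
enrichment, or a log Poisson p-value) for each genomic interval $i$. We
imagine each position has a latent activity level $\mu_i$ and that the
observed value is a noisy draw with $\mathbb{E}[x_i] = \mu_i$ and
$\mathrm{var}(x_i) = \sigma(\mu_i)^2$ for some unknown, smooth
mean–variance relationship $\sigma(\cdot)$ shared across the genome. If
$\sigma$ were known, the classical variance-stabilizing transform

$$t(x) = \int_0^x \frac{1}{\hat\sigma(u)}\,\mathrm{d}u$$

makes $\mathrm{var}(t(x_i))$ approximately constant: to first order the
transformed noise SD is $t'(\mu)\,\sigma(\mu) = 1$.

`trackvst` estimates $\hat\sigma$ empirically from $M \ge 2$ replicate
tracks. Every ordered pair of distinct replicates contributes one (base,
auxiliary) value pair per position, giving vectors of length $NM(M-1)$. The
base value serves as a noisy proxy for the local mean; among positions with
similar base value, the spread of the auxiliary values estimates the noise.

The estimator, stage by stage:

1. **Binning.** Pairs are stably sorted by base value (ties broken by
   original index) and chunked into bins of $b$ consecutive pairs. Leftover
   pairs form a final smaller bin — discarding them would bias the right
   tail, exactly where the signal is strongest. Each bin $j$ yields
   $\mu_j$ (mean of auxiliary values) and $\sigma_j^2$ (population, $1/b$,
   variance of auxiliary values). Because coverage-style signals are
   zero-inflated, positions with base value exactly $0$ are pulled out
   first into a dedicated zero bin $(\mu_0, \sigma_0)$; LPPV signals are
   not zero-inflated, so there the zero bin is off by default.
2. **Cross-bin smoothing.** Each non-zero bin's variance is replaced by an
   exponentially weighted average of its neighbors, bin $j+k$ receiving
   weight $2^{-b|k|/\beta}$ over the window
   $w = \operatorname{round}(-\beta \ln 0.01 / (b \ln 2))$ — the window
   that keeps all weights at least $0.01$, floored at $0$. Neighbors beyond
   the first or last bin are simply dropped and the remaining weights
   renormalized; inventing phantom bins at the edges would bias edge
   estimates. The zero bin is excluded from every window and never
   smoothed: it is a different population, not a neighbor on the mean axis.
3. **Spline fit.** A cubic smoothing spline of $\bar\sigma_j$ against
   $\mu_j$, minimizing the usual penalized least squares objective with a
   roughness penalty on the second derivative. Observation weights are the
   bin counts ($b$ for full bins, actual sizes for the partial and zero
   bins), so the fit weighs evidence, not bins. The zero-bin point is
   included as one extra observation: without it the curve has no
   information below the smallest non-zero bin mean, which is where half
   the genome may live. The smoothing parameter is chosen by generalized
   cross-validation; `spar` can be fixed for exact reproducibility. When
   the cross-validation search steps outside its admissible range (which
   can happen with very uneven weights), the fit retries with
   progressively tighter deterministic bounds.
4. **Clamping and extrapolation.** The curve is evaluated with constant
   extrapolation outside the fitted mean range and clamped from below at
   $\max(10^{-4},\ 10^{-3}\cdot\mathrm{median}(\bar\sigma_j))$, which keeps
   the transform integral finite if the spline undershoots near zero. We
   tried natural-spline linear extrapolation instead of constant: it can
   undershoot to the floor far beyond the data and blow up the integrand,
   so constant extrapolation is the default and only behavior. Clamp
   activations are counted on a 512-point grid and reported; on
   well-behaved data the count is 0.
5. **Integration.** $t$ is a composite trapezoid integral of
   $1/\hat\sigma$ on a uniform grid (default 4096 points, error
   $O(h^2)$ — at genomic signal scales the grid error is far below the
   estimation error), stored as a monotone lookup table with linear
   interpolation. Above the grid, $t$ extends linearly with slope
   $1/\hat\sigma(x_{\max})$; below zero (possible for LPPV) it reflects
   with the boundary slope, keeping $t$ total and strictly monotone with
   $t(0) = 0$. Training uses the maximum observed signal as $x_{\max}$ so
   the whole track lies inside the integrated region.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `b` | pairs per bin (signal units: pairs) | `1e5` raw/FE, `1e3` LPPV | bias–variance trade-off: large bins average dissimilar positions, small bins are noisy; zero-inflated signals concentrate information in fewer distinct values, so they get larger bins with narrower bandwidth |
| `beta` | smoothing bandwidth (pairs) | `1e3` raw/FE, `1e7` LPPV | with the raw/FE defaults the window rounds to $w = 0$ (no cross-bin smoothing); for LPPV the wide bandwidth spreads weight over many small bins |
| `zero_bin` | dedicated bin for base $= 0$ | on for raw/FE, off for LPPV | zero-inflation |
| `spar` | spline smoothing parameter | GCV | fix for reproducibility |
| `n_grid` | integration grid | 4096 | trapezoid error negligible vs estimation error |
| metric bin size | positions per instability bin | 10 000 | large enough that $v_j$ is a stable sum, small enough for many bins |

`select_hyperparameters()` grids over $(b, \beta)$, fitting on training
chromosomes and scoring on held-out ones by the mean log density, following
the train-on-one-chromosome, test-on-another protocol used throughout.

## Evaluation metrics

**Gaussian quality of fit.** For a candidate relationship $\tilde\sigma$,
the mean over pairs of
$\log \mathcal{N}(x^{(\mathrm{aux})}_i \mid \mu = x^{(\mathrm{base})}_i,
\sigma = \tilde\sigma(x^{(\mathrm{base})}_i))$. The Gaussian is the
maximum-entropy distribution with the assumed mean and variance; the score
is maximized when $\tilde\sigma$ matches the actual conditional spread of
one replicate around the other. Any monotone transform implies a
relationship via $\tilde\sigma(u) = 1/t'(u)$: $\log(x+c)$ implies $u + c$,
$\operatorname{asinh}$ implies $\sqrt{u^2+1}$, identity implies a constant
— so transforms can be compared on likelihood without being applied.

**Variance instability.** Positions sorted by transformed base value are
chunked into bins of 10 000; $v_j$ is the sum of squared between-replicate
differences in bin $j$, and the score is
$\mathrm{var}(v_{1:B}) / (\sigma_1^2 \sigma_2^2)$ with population variances
throughout and $\sigma_1, \sigma_2$ the SDs of the two full transformed
vectors. The normalization makes the score exactly invariant under joint
rescaling. We define $v_j$ as a within-bin sum; a `per_position` flag
divides by the bin size, which changes the score by the constant $b^2$ for
full bins and matters only when comparing across bin sizes. The incomplete
final bin is discarded here (a partial bin's sum is not comparable), and
$\sigma_1, \sigma_2$ are computed over exactly the evaluated positions.

## What the simulator emulates

`simulate_replicates()` draws, per position, a latent mean $\mu_i$ and then
$M$ i.i.d. replicate values around it. The default configuration emulates a
replicated ChIP-seq-like count track at 25 bp resolution:

* 30% of positions are structural zeros ($\mu_i = 0$): unmappable or
  truly empty regions where all replicates report 0;
* the rest draw from a log-normal background (median 2 counts,
  $\mathrm{sdlog} = 0.6$) or, with probability 0.2, a log-normal peak
  component (median 40, $\mathrm{sdlog} = 0.8$);
* noise is negative binomial with dispersion $\phi = 0.1$
  ($\sigma_{\mathrm{true}}(\mu) = \sqrt{\mu + \phi\mu^2}$), a law that
  neither $\log(x+1)$ nor $\operatorname{asinh}$ stabilizes: it is
  Poisson-like at background levels and over-dispersed on peaks. Poisson
  and Gaussian (arbitrary $\sigma(\mu)$) noise are available for
  calibration studies.

The low-rate background matters: if *all* low-signal positions were
structural zeros, both replicates would agree there trivially, and the
instability metric would degenerate into rewarding whichever transform
compresses the most — a regime that says nothing about stabilization. Real
background coverage has a small nonzero rate, and the simulator reproduces
that.

What the simulator does **not** model: genomic autocorrelation (positions
are independent), batch effects or quality differences between replicates
(replicates are exchangeable by construction — the method itself assumes
comparable replicates), mappability structure, and fragment-level
artifacts. Passing tests on this generator therefore demonstrate correct
estimation under the stated noise laws, not robustness to irreproducible
replicates, which remains the user's responsibility to check.

Default study sizes in the test suite and the acceptance script are $10^5$
positions per chromosome (two chromosomes, train on one, test on the
other), $b = 10^3$, $\beta = 10^3$: large enough that bin noise is small
against the effects measured, small enough to run in seconds.

## What the curve estimates — an honest account

The binned SD of the auxiliary replicate *given* the base replicate is not
the per-replicate noise SD. Conditioning on a noisy base value leaves
posterior uncertainty in the latent mean, so the curve converges to the
replicate-pair conditional SD

$$s(x) = \sqrt{\sigma^2 + \mathrm{var}(\mu \mid x_\mathrm{base} = x)}
\;\ge\; \sigma,$$

which approaches $\sqrt{2}\,\sigma$ for count noise under a broad signal
distribution (the posterior variance of the mean is then roughly the noise
variance itself). On the default simulation the fitted curve sits between
$1\times$ and $\sqrt 2 \times$ the noise SD (median relative error
$\approx 0.22$–$0.31$ against $\sigma_{\mathrm{true}}$, $\approx 0.10$–$0.14$
against $\sqrt2\,\sigma_{\mathrm{true}}$, as recomputed by
`scripts/acceptance.R` and `recovery_error()`).

This is a feature, not only a bias: for *stabilizing between-replicate
differences*, $s(x)$ — the spread the transform actually needs to flatten —
is the right quantity, and any constant factor cancels entirely in the
instability score and in the transform's stabilizing property. It matters
only if the curve is read as an estimate of the single-replicate noise law;
for that use the values are inflated by up to $\sqrt 2$.

The same algebra fixes what the likelihood metric can and cannot certify:
since both replicates carry noise, $\mathrm{var}(x_\mathrm{aux} -
x_\mathrm{base}) = 2\sigma^2$ identically, so the Gaussian mean log density
peaks at the pair-conditional SD ($\sqrt2\,\sigma$), not at the noise SD —
with a scale family $c\,\sigma$, the expected score is
$\mathrm{const} - \ln c - 1/c^2$, larger at $c = 2$ than at $c = 1$. The
calibration test therefore centers the comparison on
$\sqrt2\,\sigma_{\mathrm{true}}$ and uses a near-flat noise curve
($\sigma(\mu) = 20 + \mu/20$, means concentrated around 100): with a steep
curve, evaluating $\sigma$ at the noisy base value interacts with shrinkage
toward the mean and thins the margins without changing the ordering.

## Other numerical and design choices

* Coordinates are 0-based half-open (bedGraph convention), strandless.
  bedGraph parsing and writing go through `rtracklayer`, with
  whitespace-delimited files normalized to tabs first and a diagnostic
  rescan that reports the offending line number on malformed input.
* Alignment re-tiles replicate tracks onto the intersection of their
  covered regions at the finest grid present (coarser intervals replicate
  their value into sub-intervals); bases covered by only some tracks are
  dropped and counted.
* Sorting is stable everywhere with the original index as tiebreak, making
  every stage deterministic; the simulator restores the caller's RNG state
  and is byte-reproducible given a seed.
* Population ($1/n$) variances are used in every estimator and metric, for
  internal consistency with the $1/b$ bin variance.
* Models serialize to JSON: a 512-point curve grid, the full transform
  lookup grid, and all hyperparameters; loading reproduces the curve and
  transform to within $10^{-6}$ relative at grid points (between curve grid
  points the loaded object interpolates linearly, which is why the grid is
  dense).
* The log-offset transform `log(a*x + b)` is provided alongside
  `log(x + 1)`; changing $a, b$ rarely helps, but the comparison is cheap.
* An inverse transform is deliberately out of scope; the forward lookup
  grid would support one, but none of the evaluation machinery needs it.

## Known limitations

* Replicates are required; a single track cannot identify $\sigma(\mu)$
  with this estimator. (Exploiting genomic autocorrelation as
  pseudo-replication is a possible extension, not implemented.)
* The curve is only identified over the observed range of bin means;
  beyond it the constant extrapolation makes $t$ linear, which
  under-compresses values far above anything seen in training. Train on
  data whose dynamic range covers the tracks to be transformed.
* Irreproducible replicates (batch effects, failed experiments) inflate
  the estimated variance globally and shrink all transformed signals; the
  method assumes replicates are exchangeable.
* The learned curve estimates the replicate-pair conditional SD, not the
  per-replicate noise SD (see above).
* Heavily tied count data make bin boundaries within tie runs depend on
  input order; all such choices are deterministic (stable sort), but
  swapping replicate labels can move individual pairs across bin
  boundaries. The fitted curve is insensitive to this except exactly at
  sharp transitions in the mean–variance relationship.
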
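---
title: "Methods: Poisson occupancy of microbeads in polydisperse emulsions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson occupancy of microbeads in polydisperse emulsions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydrop)
```

## The problem

Bead-display selections compartmentalize single microbeads in water-in-oil
emulsion droplets. When beads partition randomly, the number of beads in a
droplet of volume $V$ is Poisson with rate $\mu = cV$, where
$c = N_\mathrm{beads}/V_\mathrm{aq}$ is the bead concentration in the
dispersed aqueous phase. Bulk (vortexed) emulsions are cheap and scalable but
polydisperse: every droplet has its own rate, and only bead-containing
droplets can be measured reliably under the microscope. `polydrop` implements
the statistics needed to analyse such experiments: a slab-confinement
geometry model mapping measured in-plane diameters to volumes, zero-truncated
Poisson occupancy fitting, concentration-based expected rates, and a
volume-binned mixture of Poissons that accounts for polydispersity — plus a
synthetic emulsion generator so the whole chain is testable without
microscopy data.

## Measurement geometry

An emulsion aliquot sandwiched between slide and coverslip forms a liquid
layer of height $h$ (measured by focusing on the two glass surfaces; 8.4 um
and 7.2 um for the two surfactant systems this package was built around).
Droplets narrower than the layer are undeformed spheres; wider droplets are
squished into pancakes modelled as cylinders of height $h$:

$$V(d) = \begin{cases}\frac{\pi}{6}d^3 & d \le h\\ \pi\left(\frac{d}{2}\right)^2 h & d > h.\end{cases}$$

Choices made here, where the rule itself leaves room:

* **Tie at $d = h$** goes to the sphere regime: a droplet exactly fitting the
  gap is undeformed.
* **The rule is discontinuous** at $d = h$ (the cylinder formula is exactly
  1.5× the sphere formula there). We implement it verbatim rather than
  smoothing with a spherocylinder correction, and return the regime together
  with the volume so boundary cases are auditable.
* **Inversion gap.** `diameter_from_volume()` (the simulator's measurement
  model) inverts the rule exactly except for volumes in
  $(\frac{\pi}{6}h^3, \frac{\pi}{4}h^3]$, which no diameter produces. These
  are mapped through the cylinder inverse — a slightly squished droplet of
  such a volume presents an in-plane diameter just below $h$ — so no volume
  is ever rejected. Round trips $d \to V \to d$ are exact to $10^{-9}$
  relative error everywhere; $V \to d \to V$ is exact outside the gap.
* Measured diameters of sub-layer droplets are treated as true sphere
  diameters (equatorial and projected diameters coincide for spheres).
* Units are centralised: um for lengths, um³ internally, pL at every public
  interface (1 pL = 1000 um³), ul for the aqueous phase.

## Zero-truncated occupancy and fitting

With $f(k;\mu) = e^{-\mu}\mu^k/k!$ (evaluated in log space), the observable
distribution when only bead-bearing droplets are measured is the
zero-truncated occupancy $f(k;\mu)/(1 - f(0;\mu))$, $k \ge 1$. At the
reference rate $\mu = 0.41$ this gives the familiar pattern: ~81% of
bead-containing droplets hold one bead, ~17% two, ~2.5% three or more.

`fit_truncated_poisson()` minimises the sum of squared errors (SSE) between
observed and model fractions. Least squares — not maximum likelihood — is the
default because SSE is the fit-quality metric this field reports and plots;
a zero-truncated MLE (solving $\bar k = \mu/(1-e^{-\mu})$) is available via
`method = "mle"`. Further choices:

* **Support**: $k = 1$ to the maximum observed count, unobserved intermediate
  classes entering as zero fractions; no padding beyond the observed maximum.
* **Optimiser**: deterministic, no random restarts. The SSE objective is flat
  wherever the model places essentially no mass on the observed support, so a
  256-point log-spaced grid scan over the bounds (default
  $\mu \in [10^{-6}, 50]$) brackets the minimum before golden-section
  refinement at tolerance $10^{-9}$; tests verify agreement with a
  brute-force grid oracle at $10^{-4}$ resolution.
* **Degenerate input**: a histogram with all mass at $k = 1$ drives
  $\hat\mu \to 0$ (the truncated Poisson tends to a point mass); the fit pins
  to the lower bound and sets a `boundary` flag with a warning.
* **Truncated vs untruncated**: the truncated model is fitted because only
  bead-containing droplets are measured; `truncated = FALSE` fits the plain
  pmf when an empty-droplet class is recorded.
* **Reporting precision**: print methods echo $\mu$ and SSE at two
  significant figures (the precision at which such rates are quoted); machine
  output carries full precision.

The concentration-based prediction `expected_mu()` is
$\mu = c \bar V_\mathrm{bc}$ with $\bar V_\mathrm{bc}$ the mean
bead-containing droplet volume: 0.36 for $10^7$ beads in 100 ul at 3.6 pL,
0.445 (printed 0.45) for $10^7$ beads in 200 ul at 8.9 pL. Note
$\bar V_\mathrm{bc}$ is a size-biased mean — large droplets are more likely
to contain a bead — which is precisely why this single-rate approximation
deviates on strongly polydisperse emulsions.

## The volume-binned Poisson mixture

The polydispersity correction bins the full droplet volume distribution —
including empty droplets — into uniform bins (2 pL default, half-open
$[mw, (m+1)w)$ anchored at 0, so edge volumes go up; empty leading/trailing
bins dropped). Each bin's share of the total aqueous reagent volume,
$n_i V_i / \sum_j n_j V_j$, fixes its expected share of the beads and hence
the per-bin rate $\mu_i = c V_i$; the predicted occupancy across the emulsion
is the weighted sum $M(k) = \sum_i w_i f(k;\mu_i)$, compared to data after
truncation, $M(k)/(1-M(0))$.

Two genuinely open choices were settled as follows:

* **Weights $w_i$.** With droplet-count weights $w_i = n_i/\sum n_j$ the
  truncated mixture is *exactly* the occupancy distribution of a random
  bead-containing droplet under volume-proportional loading:
  $\sum_i n_i f(k;\mu_i) / \sum_i n_i(1-f(0;\mu_i))$. We verified this
  against direct simulation (per-class z-scores within ±2 at $3\times10^4$
  droplets), while aqueous-volume-share weights $w_i \propto n_i V_i$ —
  the occupancy seen from a volume element's rather than a droplet's
  perspective — deviate grossly (z up to ~27). Count weighting is therefore
  the default and the documented best-match method; `weighting = "volume"`
  is retained for comparison.
* **Representative volume per bin**: the midpoint (deterministic given only
  binned counts); the within-bin mean is available via
  `representative = "mean"` when raw volumes are.
* **Truncation order**: the final mixture is truncated,
  $M(k)/(1-M(0))$ — with count weights this equals truncating per bin and
  reweighting by each bin's bead-bearing fraction, so the alternative
  collapses into the same number.

Structural identities asserted in the tests: weights sum to 1, rates are
proportional to representative volumes with slope $c$, the mixture mean
equals $\sum_i w_i \mu_i$ (law of total expectation, to $10^{-10}$), a
single-bin mixture reduces exactly to one Poisson, and refining 2 pL bins to
0.5 pL on a smooth volume distribution moves truncated predictions by less
than the Monte-Carlo noise floor of the simulated sample sizes (~0.02).

## The synthetic emulsion generator

The generator produces data with the statistical structure the analysis
assumes, not an image of any particular experiment:

* **Volumes**: lognormal draws (the standard shape for vortexed polydisperse
  emulsions; gamma available) accumulated until the aqueous phase is
  exhausted, the last droplet trimmed so volumes sum to the aqueous volume
  exactly. The droplet count is emergent, mirroring bulk emulsification.
  Defaults are the study conditions: $10^7$ beads in 100 ul (Abil EM 90
  preset, $h = 8.4$ um) or 200 ul (`fluosurf_params()`, $h = 7.2$ um), with
  `log_sd = 1` — a realistic width for vortexed emulsions — and `log_mean`
  solved so the *bead-containing* mean volume matches the measured 3.6 or
  8.9 pL. Because bead-containing droplets are a size-biased sample, a
  lognormal$(m, s)$ volume distribution has bead-containing mean
  $e^{m + 3s^2/2}$ at low rates, giving $m = \log \bar V_\mathrm{bc} - 3s^2/2$.
* **Aggregation**: beads are partitioned into clusters with shifted-geometric
  sizes (termination probability $p$, mean size $1/p$); each cluster lands
  whole in a droplet chosen with probability $V_j/\sum V$. $p = 1$ recovers
  independent beads and the Poisson limit; small $p$ reproduces the
  super-Poissonian, badly-fitting occupancy of aggregating beads. This
  cluster model is synthetic plumbing: real aggregate-size distributions are
  not quantitatively characterised ("hundreds of clustered beads" is
  qualitative), so its parameter is not an estimate of them.
* **Conservation by construction**: bead counts sum to `n_beads` and volumes
  to the aqueous volume, always.
* **Measurement**: `render_measurements()` converts volumes to observed
  diameters through the geometry inverse, filters to bead-containing
  droplets and subsamples to a manual-measurement budget; all randomness
  flows from one integer seed.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: droplet coalescence and instability, measurement
error in manual diameter reading, segmentation bias against droplets at
image borders, bead settling, and any physical model of nozzle shear. It
validates the statistical chain, not the microscopy.

## Pooling, problem sizes and limitations

With replicate emulsions (`emulsion_id`), observed fractions are computed per
emulsion and averaged, and across-emulsion standard deviations provide the
error bars; pooled-droplet mode is available (`pooling = "pooled"`). Which
pooling produced a published fit is rarely stated; per-emulsion is the
default because it matches how replicate error bars are drawn.

Simulation-backed tests and examples run at concentration-preserving reduced
scale via `scale_params()` — typically $10^4$–$10^5$ droplets rather than the
$\sim3\times10^7$ implied by full study conditions — sizes chosen so
Monte-Carlo standard errors are far below the effects being asserted
(parameter recovery to 0.02 uses $10^4$ bead-containing droplets; the
mixture oracle uses $10^5$ droplets with per-class 3-SE bands, restricted to
classes expecting at least 5 droplets).

Known limitations: no spherical-cap correction at the regime boundary, no
continuous (integral) mixture over a fitted parametric volume distribution
(binned only), no profile-likelihood or Bayesian uncertainty for $\hat\mu$
(a nonparametric bootstrap, `bootstrap_mu()`, is provided), and published
per-class observed fractions are generally unavailable, so externally fitted
$\hat\mu$/SSE values can be used as inputs but not re-derived.
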
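# polydrop

Poisson occupancy statistics for microbead encapsulation in polydisperse
water-in-oil emulsions.

Bead-display selections (directed evolution, in vitro compartmentalization)
encapsulate single microbeads in emulsion droplets. Bulk vortexed emulsions
are cheap and scalable but polydisperse, and only bead-containing droplets
can be measured under the microscope. `polydrop` is for experimentalists who
measure droplet diameters and bead counts on a slide and want to answer:
*are my beads Poisson-distributed, at what rate, and does the droplet size
distribution explain the multi-bead droplets I see?*

## The model

Beads partitioning randomly into a droplet of volume $V$ give a Poisson bead
count, $f(k;\mu) = e^{-\mu}\mu^k/k!$ with rate $\mu = cV$, where
$c = N_\mathrm{beads}/V_\mathrm{aq}$ is the bead concentration in the
aqueous phase. The package implements:

* **Slab-confinement geometry** — measured in-plane diameter $d$ under a
  liquid layer of height $h$ maps to volume via the sphere formula
  ($d \le h$) or the cylinder formula $\pi(d/2)^2h$ ($d > h$), and back.
* **Zero-truncated occupancy** — $f(k;\mu)/(1-f(0;\mu))$, the distribution
  observable when only bead-bearing droplets are measured, fitted to
  observed fractions by least squares (reported as $\hat\mu$ with its SSE).
* **Expected rate from dose** — $\mu = c\,\bar V_\mathrm{bc}$ from the bead
  dose and the mean bead-containing droplet volume.
* **Volume-binned Poisson mixture** — the polydispersity correction: bin all
  droplet volumes (2 pL default), give each bin the rate $\mu_i = cV_i$
  implied by its share of the aqueous phase, and predict occupancy as the
  count-weighted mixture $M(k)=\sum_i w_i f(k;\mu_i)$, truncated for
  comparison with bead-bearing fractions.
* **A synthetic emulsion generator** — lognormal droplet volumes conserving
  the aqueous phase, volume-proportional bead loading, an optional
  bead-aggregation (cluster) model, and the slab measurement model, so the
  entire analysis chain is testable end to end.

## Worked example

Simulate a FluoSurf-like polydisperse emulsion at 1/2000 scale (same bead
concentration as 10^7 beads in 200 ul), analyse it, and compare the three
occupancy models:

```r
library(polydrop)

params <- scale_params(fluosurf_params(seed = 42), 5e-4)
em <- simulate_emulsion(params)
em
#> Synthetic emulsion: 30290 droplets, 5,000 beads in 5000 clusters
#>   bead-containing droplets: 4151 (mean volume 7.18 pL)

tab <- render_measurements(em, only_bead_containing = FALSE)
cfg <- experiment_config(layer_height_um = 7.2, n_beads = params$n_beads,
                         aqueous_volume_ul = params$aqueous_volume_ul)
analyze_emulsion(tab, cfg)
#> Emulsion occupancy analysis
#>   droplets analysed: 30290 ( 4151 bead-containing, 1 emulsion(s) )
#>   mean bead-containing droplet volume: 7.18 pL
#>   fitted mu = 0.32 (SSE 0.00032)
#>   expected mu (dose x mean volume) = 0.36 (SSE 0.0009)
#>   volume-binned mixture SSE = 8.9e-06 (76 bins of 2 pL)
```

Reading the report: 4151 of 30290 droplets contain beads and average 7.18 pL
(a size-biased mean — larger droplets catch more beads). The single-rate fit
gives $\hat\mu = 0.32$; the dose-based expectation from the mean volume is
0.36 but fits the observed fractions worse (SSE 9e-4 vs 3.2e-4), because a
single rate cannot represent a polydisperse emulsion. The volume-binned
mixture, which models each 2 pL size class with its own rate, matches the
observed occupancy an order of magnitude better (SSE 8.9e-6) — the same
ranking seen in real polydisperse emulsion data.

Closed-form anchors:

```r
expected_mu(bead_dose(1e7, 200), 8.9)
#> [1] 0.445
round(100 * truncated_occupancy(1:3, 0.41), 1)
#> [1] 80.9 16.6  2.3
```

At a fitted rate of 0.41 beads per droplet, ~81% of bead-containing droplets
hold a single bead, ~17% two, and ~2.5% three or more — and no rate can put
more than $e^{-1} \approx 37\%$ of *all* droplets in the single-bead class.

A thin command-line wrapper over these functions (subcommands `simulate`,
`analyze`, `expect`) is installed at `inst/cli/polydrop.R`.

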
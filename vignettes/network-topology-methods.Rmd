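---
title: "Topology of spectral dependence networks: models, estimators, and tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology of spectral dependence networks: models, estimators, and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdanet)
```

# The problem

Multichannel recordings such as EEG are usually compared between groups
through their *dependence networks*: each channel is a node, and edge
weights measure how strongly two channels co-oscillate in a frequency band.
Classical practice thresholds the weighted network at one arbitrary cutoff
and compares graph summaries. `tdanet` instead treats the full weighted
network as a metric space and summarises its shape at **every** threshold
simultaneously, via persistent homology: connected components (dimension 0),
loops (dimension 1) and voids (dimension 2) are tracked across the whole
range of dependence distances, converted to persistence landscapes, and
compared between groups with a permutation test. Nothing in the pipeline
requires choosing a single network threshold.

# Generative model for synthetic data

All tests and examples rest on a latent-oscillator mixture. Each latent
process is a stationary AR(2),

$$Z(t) = \phi_1 Z(t-1) + \phi_2 Z(t-2) + W(t), \qquad W(t) \sim N(0, \sigma^2),$$

whose characteristic roots are written $M e^{\pm i 2\pi\psi}$ with magnitude
$M > 1$ (causality) and phase $\psi \in (0, 0.5)$ in cycles per sample.
Solving the characteristic polynomial for these roots gives

$$\phi_1 = \frac{2}{M}\cos(2\pi\psi), \qquad \phi_2 = -\frac{1}{M^2},$$

and the spectrum of $Z$ concentrates near $\psi \cdot SR$ Hz, the more
sharply the closer $M$ is to 1. (The flattened form "$2M\cos$" sometimes
seen for $\phi_1$ cannot be right: substituting $r = M e^{i2\pi\psi}$ into
$1 - \phi_1 r - \phi_2 r^2 = 0$ forces the $2/M$ factor, and
`ar2_coefficients()` is verified by reconstructing the roots to $10^{-10}$.)

Channels are linear mixtures of $Q$ independent latents plus sensor noise,

$$Y(t) = A Z(t) + c\,\varepsilon(t), \qquad \varepsilon(t) \sim N(0, I_P),$$

so two channels are dependent exactly when they load on a common latent.
Four preset designs (`preset_example()`) encode the mixing matrices used
throughout: a 9-channel/8-latent design with two cyclic communities, a
9-channel/5-latent design with one cycle plus a complete block of four
channels observing a single latent, and a pair of 6-channel designs
contrasting cyclic with non-cyclic latent sharing. Defaults place all
latent peaks at 10 Hz with $M = 1.05$ at a 100 Hz sampling rate — an
alpha-band oscillation, sampled comfortably above Nyquist — with innovation
standard deviation 1 and burn-in 500 samples (the impulse response decays
as $M^{-t}$, so 500 lags leave no measurable transient at $M \ge 1.05$).

## What the closed-form coherence oracle says

`theoretical_coherence()` gives the exact squared coherence implied by the
mixture: with latent spectra $f_q(\omega)$,

$$C_{ij}(\omega) =
\frac{\left|\sum_q A_{iq} A_{jq} f_q(\omega)\right|^2}
     {\left(\sum_q A_{iq}^2 f_q(\omega) + c^2\right)
      \left(\sum_q A_{jq}^2 f_q(\omega) + c^2\right)}.$$

A consequence worth stating plainly, because it is easy to get wrong: two
channels that each average two iid latents and share exactly **one** of
them have squared coherence $f^2 / (2f \cdot 2f) = 1/4$ at every frequency,
even with *no* sensor noise. Coherence reaches 1 only when two channels
observe the *same* latent content (e.g. the complete block of the second
preset). So in the cyclic designs, within-cycle dependence distances
plateau near $1 - 1/4$ rather than near 0, and loop persistences are
correspondingly moderate (about 0.1–0.2 after estimation bias). The
package's end-to-end tests count *dominant* loops — features standing
clearly above the rest of the diagram — rather than requiring persistence
above an absolute cutoff like 0.3, which the $1/4$ ceiling makes
unreachable for these designs. One acceptance-style check that asserts such
an absolute cutoff is retained verbatim and fails for exactly this reason;
it documents the gap between the idealised "coherence $\to$ 1" picture and
the arithmetic of shared-latent mixtures.

# Spectral estimation

`fourier_coeffs()` removes channel means (so the mean structure cannot leak
into the zero-frequency bin) and computes the DFT with a $1/T$
normalisation — the constant is irrelevant downstream because coherence is
a spectral ratio. `smoothed_periodogram()` averages the cross-periodogram
matrices $d(\omega)d(\omega)^*$ over `span` neighbouring Fourier bins with
a rectangular (Daniell) kernel, truncated and renormalised at the edges; no
taper is applied. The raw ($\text{span}=1$) cross-periodogram is rank one,
which makes its coherence *identically* 1 — a well-known trap that the
package enforces as a precondition (`coherence()` refuses span 1; the
identity itself is kept as a regression test). The default span of 9 bins
trades bias for variance at the $T \approx 2000$ scale used in the
examples; smoothed coherence of truly independent channels then has a
positive bias of roughly $1/\text{span} \approx 0.11$, visible in the test
suite and in the distances of non-adjacent channels ($\approx 0.89$, not 1).

Band coherence averages the per-frequency squared coherence
$|f_{ij}|^2 / (f_{ii} f_{jj})$ uniformly over the Fourier bins in the
half-open interval $[\text{low}, \text{high})$, excluding bin 0 and
Nyquist; half-open bands let the five canonical EEG presets (delta 0.5–4,
theta 4–8, alpha 8–12, beta 12–30, gamma 30–50 Hz) partition the axis. The
dependence distance is $D = G(C)$ for a decreasing map $G$, by default
$G(x) = 1 - x$, giving distances in $[0, 1]$.

# Persistent homology

`vr_filtration()` builds the Vietoris–Rips *clique* filtration: a simplex
enters at the largest pairwise distance among its vertices, so only the
$P(P-1)/2$ edge values matter. Ties are ordered by (value, dimension,
lexicographic vertices) — any face-respecting order yields the same
diagram; a deterministic one aids debugging. `persistence()` is the
textbook left-to-right column reduction of the boundary matrix over GF(2):
a column that reduces to zero creates a class, a column with pivot $i$
kills the class created at $i$. Design limits: simplices up to dimension 3
(homology to dimension 2, matching what the band-scan reports), and
networks up to a few dozen nodes — the 19-channel EEG case is ~5,000
simplices, well within plain-R reduction. Homology in the top simplex
dimension is suppressed because its deaths would need simplices one
dimension higher.

Two safeguards keep the reduction honest. `betti_profile()` recomputes
Betti numbers at any single threshold by an independent route (union-find
for $\beta_0$; GF(2) ranks of the two boundary maps for $\beta_k$), and the
suite checks, for random networks of up to 8 nodes, that the number of
diagram points alive at every edge threshold equals the oracle in
dimensions 0–2, plus the Euler-characteristic identity
$\sum_k (-1)^k \#\{k\text{-simplices}\} = \sum_k (-1)^k \beta_k$ (for
networks of $\le 6$ nodes every clique complex has $\beta_k = 0$ for
$k \ge 3$ — a flag complex carrying a 3-sphere needs at least the 8-vertex
cross-polytope — so the truncated alternating sum is exact).

Zero-persistence pairs are kept internally but dropped from exported
diagrams: they carry no landscape mass. Infinite deaths (the essential
component, plus any loop never filled) are exported as `"inf"` and
truncated at a configurable ceiling when landscapes are built; the default
ceiling 1.0 is the diameter of the $1 - C$ metric, so nothing is clipped
for coherence networks. Whether a shared ceiling across groups is used is
forced by construction here: a comparison only accepts landscapes on one
common grid.

# Landscapes, metrics, and the group test

`landscape()` draws the tent $\Lambda_{(b,d)}(t) = \max(0, \min(t-b, d-t))$
for every diagram point and takes the $j$-th largest value per grid point
as layer $\lambda_j$; 5 layers on a 256-point uniform grid are the
defaults (5 layers exceed the covering depth seen in $P \le 19$ networks;
tent functions are piecewise linear, so trapezoid integration on 256 points
carries $O(\text{grid}^{-2})$ error, checked against the analytic
$\int_0^2 \min(t, 2-t)^2 dt = 2/3$). Means are pointwise (the mean of
ordered vectors is ordered; a pointwise re-sort guards floating-point
ties), and `landscape_l2()` is the layer-summed $L^2$ distance.

`diagram_distance()` provides exact bottleneck and Wasserstein-$p$
distances for small diagrams, with the standard diagonal completion: the
printed bijection form of these metrics is only defined for
equal-cardinality multisets, so each point may instead match its diagonal
projection at cost $(d-b)/2$, with the sup norm as ground distance. The
optimum is found by bitmask dynamic programming over all assignments
(combined size capped at 12), and the suite cross-checks it against a
permutation brute force.

The group statistic is

$$T_k^{\Omega} = \int \left\| \bar\lambda^{(1)}_k(t) -
  \bar\lambda^{(2)}_k(t) \right\|^2 dt,$$

the squared $L^2$ discrepancy between group mean landscapes for band
$\Omega$ and homology dimension $k$. Two notational points were settled as
follows: the integration variable is read as the *landscape scale* (the
statistic is computed once per band — a band-indexed family of scale
integrals — rather than as an integral over in-band frequencies, which
would require a landscape per frequency); and the squared norm sums over
*all* layers, not just $\lambda_1$, so deeper layers contribute when groups
differ in feature multiplicity. `permutation_test()` permutes subject
labels (uniform resampling into the original group sizes), enumerates the
relabelling group exactly whenever $\binom{n_1+n_2}{n_1} \le B$, and
reports both the add-one p-value $(1 + \#\{T^* \ge T\})/(B+1)$ — which can
never be zero — and the threshold decision at the empirical
$(1-\alpha)$-quantile $\tau$. Note that with 3 subjects per group the 20
enumerable relabellings bound the p-value below by $3/21$: tiny designs
cannot reject at $\alpha = 0.05$, and the pipeline tests assert exactly
that. Holm adjustment across band × dimension cells is available in
`band_scan()` but off by default; per-cell decisions are the primary
output.

# Univariate routes

For completeness the package also carries the two classical univariate
entries into TDA. `smooth_series()` + `sublevel_pd()` compute the
0-dimensional persistence of the sub-level filtration of a smoothed series:
components are born at local minima and die at merges by the elder rule
(the younger component dies); ties are broken by index order, a
generic-position convention for degenerate (non-Morse) samples. The number
of finite bars plus one equals the number of local minima — tested on
random fixtures against an independent run-length sweep. Smoothing is a
centered moving average with truncated edges; be aware that low-frequency
autocorrelated noise is absorbed into the apparent mean structure, and no
detection of that failure mode is attempted. `time_delay_embed()` builds
the lagged point cloud $(y(s), y(s-\ell), \ldots)$; a noiseless cosine with
quarter-period lag embeds as a circle whose single dominant loop shrinks
monotonically as noise is added — asserted as an ordering, not an absolute.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use 6–9-channel networks,
series of $2^{11}$–$2^{15}$ samples, 10-seed majorities for stochastic
topology counts, 200 replicate tests at $B = 499$ for null calibration, and
100 random networks for the oracle equivalence sweep — sizes chosen so the
full suite runs in a few minutes on one core while keeping Monte-Carlo
error well inside the asserted bands. Every random draw flows through an
explicit integer seed (`withr::with_seed`); rerunning any stage with the
same seed reproduces its output bit for bit, and `run_pipeline()` writes a
manifest recording parameters and seeds next to its artifacts.

# Known limitations

* Latent dynamics are linear and stationary; no volume conduction, no
  artifacts, no nonstationarity — synthetic results say nothing about
  preprocessing real EEG.
* Coherence is the only dependence measure; partial or directed coherence
  produce non-symmetric structures outside the Rips framework used here.
* Exact diagram metrics are restricted to 12 combined points; landscapes,
  not diagram metrics, are the intended large-scale summary.
* The permutation test assumes exchangeable subjects under the null;
  confidence bands for landscapes are not provided.
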
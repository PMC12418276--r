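---
title: "Physicochemical models of amperometric exocytosis spikes: methods and design"
author: "amperodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical models of amperometric exocytosis spikes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amperodyn)
```

# The problem

Single-cell amperometry (SCA) presses a carbon micro- or nanoelectrode
against a secreting cell and oxidizes the neurotransmitter (NT) released by
each vesicle fusion event. Every event appears as a current spike; by
Faraday's law the spike charge counts molecules, $N = Q/(nF) \cdot N_A$,
with $n$ electrons per molecule oxidized ($n = 2$ for catecholamines).
Classical analysis stops at descriptive shape parameters (peak current,
half-width, rise and decay times). This package implements instead a
mechanistic reading of the spike: the current wave-shape is a direct readout
of the fusion-pore radius trajectory and of the kinetic organization of the
intravesicular matrix.

# The quasi-steady-state release model

NT monocations are stored chelated by intravesicular polyelectrolytes
(chromogranins), so transport inside the matrix proceeds by site-hopping
between chelating sites — macroscopically indistinguishable from Fickian
diffusion with an equivalent coefficient $D_{ves}$, one to two orders of
magnitude below free-solution diffusivities. Once the release duration
exceeds the diffusional time scale $R_v^2/D_{ves}$ (`qss_time_scale()`), the
intravesicular concentration field decays homothetically and the release
flux becomes proportional to the remaining releasable content. The
amperometric current is then

$$ i(t) = n F\, k(t)\, N_0\, e^{-\int_0^t k(u)\,du}, $$

with the pseudo-first-order rate constant carried entirely by the pore
geometry:

$$ k = \alpha\, \frac{D_{ves}\, r_p}{R_v^3}, \qquad \alpha = 3/\pi
  \text{ by default.} $$

The default prefactor is the quasi-steady disk-access conductance
$4 D_{ves} r_p$ acting on a uniform sphere of volume $4\pi R_v^3/3$; it is
exposed as the `alpha` argument of `rate_from_radius()` so any alternative
geometric convention rescales the whole pipeline coherently (every quantity
downstream is linear in `alpha`).

Two immediate consequences drive all analyses:

* a **stalled pore** (constant $r_p$) gives a single-exponential decay whose
  semi-log slope *is* $k_{max}$, hence $r_{p,max}$ (`classify_tail()`,
  `kmax_from_slope()`);
* the relation inverts **analytically**: with
  $N_{rem}(t) = \frac{1}{nF}\int_t^T i\,du$, the apparent rate is
  $k(t) = i(t) / (nF\,N_{rem}(t))$, and `radius_from_rate()` converts to
  $r_p(t)$ (`invert_spike()`). No assumption about the pore dynamics enters:
  rise, foot and plateau phases are all recovered from the data.

The releasable content $N_0$ is *defined* operationally as the spike's own
charge integral divided by $nF$. Matrix swelling restricted by the intact
membrane can keep part of the stored cargo bound (sub-quantal release); that
residue never reaches the electrode and is invisible to the inversion, so
the package does not attempt to estimate it.

## Noise amplification and truncation

As $t \to T$ both $i$ and $N_{rem}$ approach zero and their ratio amplifies
measurement noise without bound. `invert_spike()` therefore truncates at the
first time the remaining content falls below `eps` (default 0.02) of the
released amount, and reports the average pore radius over the identified
constant-pore regime (`r_plateau`). The default `eps` keeps 98% of the
release inside the reported trajectory; it is configurable, and the
truncation is also what bounds the inversion error of the sequence ledger
(below).

# Flicker sequences

Kiss-and-run fusion produces trains of brief periodic sub-spikes — repeated
opening/closing of the same pore. `invert_sequence()` treats such a train
*as a whole*: one remaining-content ledger spans the sequence (content
available to opening $j$ is what opening $j-1$ left behind; no refilling
between openings), and the per-opening inversion continues that ledger. For
a square-wave opening train at rate $k_{max}$ and open time $\tau$, each
opening releases the fixed fraction $f = 1 - e^{-k_{max}\tau}$ of the
current content, so successive released amounts form a geometric sequence
with ratio $1-f$ while the recovered maximal radius stays constant — the
package's self-consistency check for this analysis path. Openings whose
ledger falls below the truncation floor report charges but no radii.

The `flicker` generator archetype defaults to the intrasynaptic regime this
analysis targets: a 400 Hz train, duty 0.5, maximal pore radius 1.2 nm, and
a releasable content chosen so the first opening releases about 7,000
molecules. The train length is set so essentially the whole ledger is
consumed (residual $\lesssim 0.02\%$), which keeps the ledger bias of the
recovered radii below one percent.

# The biphasic intravesicular matrix

A substantial fraction of spikes shows a *two*-exponential decay, the second
regime slower than the first. Attributing the second regime to a shrinking
pore is physically inconsistent (next section); the package's kinetic model
instead follows the biphasic organization of condensed polyelectrolytes:
highly compacted domains ("blobs", hc) dispersed in a less compacted phase
("strands", lc). Release proceeds from the lc phase; the hc reservoir
refills it through site exchange gated by free lc sites:

$$ \frac{dN_{hc}}{dt} = -\kappa_{ex} N_{hc}\Big(1 - \frac{N_{lc}}{N_{lc,0}}\Big),
\qquad
\frac{dN_{lc}}{dt} = +\kappa_{ex} N_{hc}\Big(1 - \frac{N_{lc}}{N_{lc,0}}\Big)
 - k(t) N_{lc}, $$

with $i(t) = nF k(t) N_{lc}(t)$. Conventions:

* `kappa_ex` is the *effective* exchange constant (1/s): the bimolecular
  constant pre-multiplied by the total amount of lc sites, which removes a
  non-identifiable scale from fitting.
* The lc phase is fully occupied at pore opening (total lc sites
  $= N_{lc,0}$), so the gating factor starts at zero and grows only as
  release vacates sites: transfer lags release, producing the delayed
  second regime.
* Backward (lc→hc) transfer is omitted: free hc sites are negligible while
  release keeps the lc phase depleted.

At early times the gate is closed and the log-slope equals $k_{max}$; at
late times the lc pool is quasi-steady and the current decays at
$\approx \kappa_{ex}$. For reporting, `forward_biphasic()` partitions
$N_{lc}$ by provenance into origin-lc and transferred-from-hc sub-pools
released at the same rate, so the component currents satisfy
$i_{hc} + i_{lc} = i$ exactly and the charge split is conservative by
construction.

## Fitting

`fit_biphasic()` implements the pipeline for double-exponential spikes:

1. the pore course before the first exponential regime (rise and any foot)
   is recovered by the analytic inversion, normalized at the rise end —
   where the pore stalls — and spliced onto the constant plateau (the raw
   inversion under-reads $k$ early on by the slowly varying factor
   $N_{lc}/N_{rem}$, which the anchoring absorbs);
2. the pore is taken as stalled thereafter;
3. $(k_{max}, \kappa_{ex}, N_{hc,0}, N_{lc,0})$ are estimated by weighted
   Levenberg–Marquardt on log-parameters against the full spike,
   initialized from the semi-log slopes and regime charges
   ($k_{max} \leftarrow m_1$, $\kappa_{ex} \leftarrow m_2$,
   $N_{lc,0} \leftarrow Q_1/nF$, $N_{hc,0} \leftarrow Q_2/nF$).

$k_{max}$ is refined along with the other parameters rather than pinned at
$m_1$: whenever the hc reservoir feeds the lc phase appreciably during the
first regime, the early log-slope is biased below $k_{max}$ (the instant
slope is $-k + \kappa_{ex} N_{hc}(1 - N_{lc}/N_{lc,0})/N_{lc}$, growing
with time), so the slope is a good initializer but the full kinetic fit is
authoritative. On an identifiable stalled-pore spike the fit recovers all
four parameters to machine precision.

Weights are inverse-variance with the noise SD floored at $10^{-3}$ of the
peak so noise-free records do not acquire unbounded weight. For long records
the objective is evaluated on a uniformly decimated grid (about 2,500–5,000
points); the returned decomposition is recomputed on the full grid.

# Tail classification

`classify_tail()` fits $\ln i$ versus $t$ after the spike maximum with a
one-segment and a continuous two-segment piecewise-linear model, scanning
breakpoints on a log-spaced time grid (a fast first regime occupies a short
early sliver of a long record). Numerical choices that matter:

* **Fit window.** The fit ends where the *smoothed* decay crosses
  `noise_floor_mult` (default 3) times the baseline SD — a cut in time, not
  a per-sample selection, because keeping individual samples above the
  floor retains only positive noise excursions and bends any fit upward.
* **Model choice.** Two segments are accepted only if (a) the small-sample
  information criterion improves, (b) the slopes separate by at least
  `delta` (default 0.2, guarding against noise-induced splits), and (c) for
  noisy records, the split also improves the fit in *linear* current space
  — where the noise is homoscedastic with known variance — by far more than
  two extra parameters explain by chance ($\Delta\chi^2 > 25$). The linear
  gate exists because $\ln(i + \varepsilon)$ is biased upward near the
  noise floor, so in log space a one-exponential decay reliably grows a
  phantom flatter terminal regime.
* **Slope refinement.** After the break is located, $m_1$ is refit on the
  early 40% of segment 1 (the first regime is the early tangent) and $m_2$
  on the late 75% of segment 2, both away from the transition curvature.
* `t_exp_start` is the start of the earliest sustained run of samples lying
  on the first-regime line within three residual SDs — the onset of the
  constant-pore regime, which also bounds the pre-exponential window handed
  to the inversion.

A consequence of the noise floor: regimes buried under about three SDs of
noise are unclassifiable by construction. At a signal-to-noise ratio of 50,
a second regime must carry at least ~10% of the peak amplitude to be seen;
the biphasic generator defaults (below) respect that.

# The shrinking-pore diagnostic

If the pore really shrank after reaching its maximum, single-compartment
release enforces a strict signature: while $k(t)$ is still decreasing the
current stays at or below the frozen-pore extrapolation
$i_{ext}(t) = i(t_0) e^{-k_1 (t - t_0)}$, dips below it (depth
$\approx \ln(k_1/k_2)$ in log units), and can cross above it only after the
closure completes. A slope change *without* a preceding dip is therefore
inconsistent with pore shrinkage and favors the biphasic-matrix reading —
where the current exceeds the extrapolation immediately after the regime
change. `shrink_diagnostic()` operationalizes this on the log-residual
$d(t) = \ln i - (a_1 - m_1 t)$: a dip is a local minimum below
$\max(0.05, 3\sigma_1)$ with subsequent recovery, $\sigma_1$ being the
first-regime fit residual scale.

The mid-shrink no-crossing property holds when the closure is fast relative
to release — quantitatively, for a linear closure of duration $\tau_s$ from
$k_1$ to $k_2$, when $\tau_s < 2\ln(k_1/k_2)/(k_1 - k_2)$. A sufficiently
slow, shallow closure can cross the extrapolation before it completes (and
produces no visible dip either); that regime is indistinguishable from
matrix kinetics by this diagnostic and lies outside its validity domain.
The `shrink` generator archetype samples the fast-closure domain: closure
duration 1–10 ms, fractional depth 0.3–0.7, with the closure starting only
after the opening completes — the worst case in those ranges satisfies the
inequality with a factor >1.5 margin.

# Whole-trace processing

`estimate_baseline()` uses a rolling median (default window 1 s) with the
noise SD from the scaled median absolute deviation of the detrended trace.
The window must comfortably exceed the longest event: a rolling median
tracks — and subtracts — any feature occupying more than half its window,
and the default archetype produces events of 0.3–0.9 s. For speed the
median runs on a decimated grid (at least ~5,000 samples per window) and is
interpolated back.

`detect_spikes()` seeds events where the hold-width (2 ms) moving average
of the baseline-corrected current exceeds 1 SD and the raw current exceeds
`m` SD (default 5) — raw level-crossing rules are useless in Gaussian noise,
where some sample exceeds 1 SD every few samples. Runs closer than the hold
time merge; edges extend to the smoothed zero crossing plus a quarter of
the event length, which captures exponential tails to a fraction of a
percent of their charge while the zero-mean noise brought in adds no bias.
Two guards matter in practice: candidate regions must also reach half the
detection threshold in the *smoothed* current (a lone noise excursion atop
a sub-threshold tail remnant passes the raw test but never the smoothed
one), and events are split between peaks only when both peaks have
topographic prominence of at least one detection threshold above the
valley. By default the baseline is then re-estimated with detected events
masked out — computed from the unmasked samples only, interpolated across
the masks — and detection repeats twice: a single-pass median sits high
when events occupy an appreciable fraction of the record, and bridging the
masks with interpolated segments would hand each median window the sampling
noise of the bridge anchors.

`descriptors()` reports the classical shape parameters with interpolated
threshold crossings (width error below one sample). A pre-spike foot is a
*plateau*: at least 1 ms between the noise-referenced lower bound
(5 SD, floored at 1% of peak) and 40% of the peak, before the point of
maximal rising slope, with a windowed local slope below a quarter of that
maximal slope — the slope condition separates a genuine foot from a merely
slow rise. Note the 5 SD bound makes feet at ~13% of peak formally
undetectable below SNR ≈ 40; this is a property of the definition, not of
the detector.

# The synthetic generator as study conditions

The generator (`scenario()`, `make_spike()`, `make_trace()`) defines the
conditions under which every test in this package is run, and they are
fixed once:

* **Vesicle**: radius lognormal, median 150 nm; equivalent intravesicular
  diffusion coefficient $10^{-11}$ m²/s; $n = 2$.
* **Releasable content**: lognormal, median $1.5\times10^{-18}$ mol
  (~$9\times10^5$ molecules). Together with the default maximal pore radius
  (12 nm, i.e. $k_{max} \approx 34$ /s) this yields ~10 pA peaks — a
  dense-core-vesicle release at realistic amplitude over the 0.5 pA noise
  floor (SNR ≈ 20).
* **Sampling** 20 kHz; **noise** white Gaussian, SD 0.5 pA (or set by a
  requested SNR); optional one-pole low-pass as an electronics mimic.
* **Biphasic archetype**: $\kappa_{ex}/k_{max} = 0.1$, 75% of the cargo in
  the compacted domain, 2 ms opening midpoint. These place the second
  regime about two decades above the SNR-50 noise floor — the
  "well-defined two-regime" class of spikes the model is meant for; closer
  to the floor the parameters are weakly identified by construction.
* **Flicker archetype**: 400 Hz, duty 0.5, $r_{p,max} = 1.2$ nm, content
  set for ~7,000 molecules in the first opening.
* **Shrink archetype**: the fast-closure validity domain quoted above.

What the generator does *not* emulate: correlated (1/f) electrode noise,
electrode fouling drift beyond a linear term, diffusional broadening
between pore and electrode for extra-synaptic placements (only a first-order
low-pass is offered), overlapping multi-vesicle compound fusion, and any
coupling between pore mechanics and matrix state. Green tests therefore
certify the *analysis chain* under the stated physics, not performance on
every laboratory trace.

# Problem sizes and numerics

Simulation sizes used by the test-suite and the acceptance script are desk
scale, chosen to exercise each claim with comfortable statistics: 50
replicates for noisy parameter recovery, 100 randomized closures for the
dip study, 100 spikes for the plateau-radius robustness check, a 60 s /
50-event trace for detection, and a ~2,000-opening train for the flicker
ledger. The stiff two-compartment system integrates with `deSolve::lsoda`
(derivative compiled in C, the pore rate entering as a forcing) at relative
tolerance $10^{-10}$ and absolute tolerance $10^{-12} N_0$ — tight enough
that the decoupled limit matches the analytic single-compartment quadrature
to well below $10^{-6}$ pointwise across ten decades of decay. Exactly
decoupled limits ($N_{hc,0} = 0$ or $\kappa_{ex} = 0$) reduce analytically
to the same trapezoid quadrature as `forward_current()`. All trapezoid
integrals share one implementation, so charge bookkeeping identities hold
to rounding error.

# Known limitations

* Spikes shorter than the quasi-steady-state onset time
  ($\sim R_v^2/D_{ves}$) fall outside the model; the package reports the
  time scale but does not attempt a pre-asymptotic correction.
* The kinetic coupling between the end of pore enlargement and the onset of
  the first exponential regime is not modeled; `t_exp_start` is detected
  from the data, never predicted.
* More than two compactness domains (multi-exponential tails beyond two
  regimes) are not implemented.
* The flicker ledger assumes no refilling between openings; sequences with
  genuine vesicle refilling would need a different bookkeeping.
* Sub-noise-floor regimes (second exponentials, feet) are undetectable by
  the stated definitions; raising the recording SNR, not the package's
  thresholds, is the remedy.
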
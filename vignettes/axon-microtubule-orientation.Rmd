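---
title: "Models and methods: microtubule growth regimes and axonal orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: microtubule growth regimes and axonal orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmt)
```

This vignette explains the models implemented in `axonmt`, the assumptions
behind them, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data tests do and do not establish about
real imaging data.

## The two-state growth model

A dynamic microtubule (MT) is modelled as switching between two states:
growth (plus-end polymerises at velocity $v_g$, in µm/s) and shrinkage
(depolymerises at $v_s$). Catastrophes terminate growth at rate $f_g$
(1/s) and rescues terminate shrinkage at rate $f_s$. Dwell times are
exponential, so per cycle an MT adds on average $d_g = v_g/f_g$ µm and
loses $d_s = v_s/f_s$ µm.

Writing a master equation for the joint density of length and state and
expanding its dispersion relation at small wavenumber, MT length performs
a drift–diffusion process with

$$\bar v = \frac{f_s v_g - f_g v_s}{f_s + f_g}, \qquad
  \bar D = \frac{f_s f_g (v_g + v_s)^2}{(f_g + f_s)^3}.$$

The drift is simply the occupancy-weighted mean velocity; the diffusion
coefficient equals the variance of the two-valued velocity process times
its correlation time $1/(f_g+f_s)$. We re-derived $\bar D$ from the
velocity autocorrelation and validated the prefactor against the
event-driven simulator (`simulate_two_state()`) before fixing it: the
empirical variance growth of free trajectories matches $2\bar D t$, and a
doubled prefactor is clearly excluded by the same experiment.

For $\bar v < 0$ with a reflecting boundary at zero length the stationary
length distribution is exponential. Two expressions for its mean appear in
the package:

- `mean_length_full()`: $\bar D/|\bar v|$, the drift–diffusion limit;
- `mean_length_taylor()`: $d_g d_s/(d_s - d_g)$, the compact per-cycle
  form, which is also the exact mean of the stationary solution of the
  two-state equations.

Their ratio is
$\left[\tfrac{4 f_g f_s}{(f_g+f_s)^2}\right]\left[\tfrac{(v_g+v_s)^2}{4 v_g v_s}\right]$,
which is 1 when rates and speeds are pairwise equal and stays within a few
percent whenever they are comparable. Measured axonal values ($v_g \approx
v_s \approx 5$ µm/min, $f_g, f_s \approx 0.04$–$0.07$/s) are well inside
this band, which is why the oracle-equivalence tests draw their random
parameter sets there: outside it the drift–diffusion limit is simply not
the right description, not a bug in either formula. The bounded/unbounded
dichotomy itself (`classify_regime()`) is exact: the mean diverges as
$d_g \uparrow d_s$, and `divergence_threshold()` recovers the boundary by
bisection on the classifier rather than restating the algebra. At the
measured shrinkage scale $d_s = 2.03$ µm/cycle the threshold is
$d_g = 2.03$ µm/cycle; tip-proximal plus-end-out MTs measured at
$d_g \approx 2.11$ µm/cycle therefore grow without bound while all other
populations ($d_g \approx 1.2$–$1.5$) stay short.

The stochastic simulator is exact (Gillespie dwell times, no time
discretisation). At zero length a shrinking MT immediately re-enters
growth — a reflecting boundary, the standard convention for this model
class. The time-averaged length is computed as the exact integral of the
piecewise-linear trajectory. Unbounded regimes are reported as a
distinguished infinite mean (`Inf`), never an overflowing float.

### Monte Carlo problem sizes

The time average of the length process decorrelates on the scale
$\tau = \bar l/|\bar v|$ (of order $10^3$ s for physiological parameters),
so its relative standard error after time $T$ is $\sqrt{2\tau/T}$. The
oracle tests integrate each parameter set for $2\times10^4\,\tau$
(about $10^6$ switching events), putting the estimator error near 1% so
that a 5% agreement bound tests the physics rather than the noise. The
histogram comparison uses $10^4$ lengths sampled $2\tau$ apart.

## Comet-track analytics

Track tables are long-format CSV (`axon_id, track_id, direction, t_s,
x_um`; positions in µm from the cell body, direction $+1$ = growing toward
the tip). The filters mirror standard kymograph post-processing: tracks are
dropped if they displace less than two pixels (default pixel size 0.103 µm;
the only pixel-dependent rule), move slower than 1.5 µm/min or faster than
20 µm/min, or span fewer than four frames (default frame interval 2 s).
The tip is the 0.95 linear-interpolation quantile (R type 7) of comet
positions — robust to stray comets past the morphological tip. Growth
events are summarised per track as $d_g$ = absolute net displacement (the
kymograph line's overall displacement, not its path length), assigned to
10 µm bins of distance-from-tip by their start position (starts beyond the
tip clamp to the first bin), and split by direction. The catastrophe rate
is estimated as the reciprocal mean growth duration per bin × direction.

Two biases are inherent to this reading of kymographs and are deliberately
left uncorrected, as they are part of the measurement being emulated:
tracks cut by the end of the movie censor long durations downward, and the
visibility filters truncate the shortest events, inflating filtered $d_g$
above the raw exponential mean. Parameter-recovery tests therefore compare
filtered estimates with truth at 10% tolerance, while the acceptance-level
median-recovery computations work on unfiltered synthetic events, whose
per-event $d_g$ is exactly $v_g \times$ duration.

Per-axon summaries use the mean of events within an axon; medians and 95%
confidence intervals across axons come from a percentile bootstrap of the
median with 10,000 resamples (`bootstrap_median_ci()`), formatted as
`median [lower, upper]`. Control axons fail QC when their orientation
fraction is below 0.8 or mean growth speed below 2 µm/min; paired
treatments inherit the flag.

## Gradient normalisation and power-law coupling

Immunostaining traces (p150, tubulin, CellTracker per axon) are normalised
channel-wise by their medians; the p150 channel is divided by the
normalised CellTracker channel to correct for volume, averaged in 10 µm
bins of distance from the tip, and treatment profiles are referenced to
the mean of their paired control profile. The gradient model
$p150(x) = b + e^{-s(x - x_0)}$ is fitted by Levenberg–Marquardt least
squares to the first 12 bins (120 µm); although $x_0$ and the implicit
unit amplitude are jointly only constrained through $e^{s x_0}$, the
parametrisation is the conventional one and the fit is well behaved with
the log-linear starting values used. Fitted decay rates below $10^{-3}$/µm
flag a degenerate (flat) gradient.

Growth per cycle is coupled to the gradient by $d_g(x) = A\,p150(x)^\alpha$.
Because an MT samples the gradient along its growth excursion, the
prediction for an event starting at distance $x$ from the tip growing in
direction `sign` ($-1$ toward the tip) averages start and end:
$d_g(x, \mathrm{sign}) = \tfrac12\left[d_g(x + \mathrm{sign}\,d_g(x)) + d_g(x)\right]$,
evaluated as a single composition (the endpoint uses the point prediction,
no fixed-point iteration). Placement constraints reflect bundle geometry:
tip-ward growth may penetrate 2 µm past the tip (end positions clamp
there), away-growing MTs start at least 4 µm from the tip (one average MT
length). Fitting minimises the summed squared difference between per-bin
integrals of this prediction (adaptive quadrature, relative tolerance
$10^{-6}$) and observed per-bin $d_g$, jointly over both directions, with
bounded L-BFGS-B over $(\log A, \alpha)$, $\alpha \in [-10, 10]$, from 5
starts — high-exponent fits are stiff and single-start optimisation can
stall in shallow basins. Recovery tests confirm $\alpha$ within 5%
noiseless and within 10% (median of 20 replicates) under 10%
multiplicative noise, with $\alpha \approx 0$ recovered when the generator
has no coupling; rescaling all intensities by $c$ rescales $A$ by
$c^{-\alpha}$ and leaves $\alpha$ and the residuals unchanged.

## The bundle simulator

The simulator represents an axonal MT bundle as rigid rods of fixed length
4 µm whose centres live on lines of a hexagonal cross-section lattice
(default 19 lines — a centre plus two rings; the cross-section size is a
modelling choice, as real axons vary) and move only along the axis.
Cytoplasmic dynein cross-links filaments on adjacent lines wherever they
overlap; with $\chi = 1$ (all overlaps occupied) and $\lambda = 5$
motors/µm, an overlap of length $L$ carries $N = \chi \lambda L$ motors.

Each motor follows a linear force–velocity relation with stall force
$f_{stall} = 1.4$ pN and free speed $v_0 = 0.86$ µm/s. For an antiparallel
pair, dynein drives each filament toward its own plus end — this is what
transports minus-end-out MTs toward the cell body — entering the force
balance as a drive $\pm N f_{stall}$ plus a relative-velocity coupling
$N f_{stall}/(2 v_0)\,(v_i - v_j)$; for parallel pairs the drives cancel
and only the coupling remains (motors act as viscous cross-linkers).
With axoplasmic drag $\xi L v$ per filament ($\xi = 1$ pN·s/µm²), setting
the total force on every filament to zero gives one symmetric
positive-definite linear solve per 2 s time step. The two-filament system
has a closed-form solution used as the verification oracle: an isolated
pair slides equal-and-opposite at
$N f_{stall}/(\xi l_{MT} + N f_{stall}/v_0)$, bounded by $2 v_0$
relative speed, and parallel pairs do not move (no self-propulsion).

Boundaries: the cell-body end is a leaky spring — filaments penetrating
$x<0$ feel 50 pN/µm of penetration and leave the axon at 0.00024/s while
trapped. The distal end resists outgrowth with a constant total force of
50 pN. Because a constant force applied naively can drag coupled
neighbours unphysically, the boundary is implemented as a complementarity
rule: filaments whose distal end lies within one position update
($v_0\,dt$) of the tip and which push outward are held at zero velocity
while the total holding force demanded stays below 50 pN; beyond that the
boundary yields and the 50 pN is distributed over the contacts in
proportion to their push. How the budget is shared among several contacts
is not constrained by the printed parameters; proportional sharing is the
package's choice.

New MTs arrive on a deterministic timer — every 1100 s for addition models
without the nucleation gate, every 435 s with it (not every gated
candidate nucleates, so the attempt rate is higher) — at a uniformly
random position along the current axon, on a random lattice line without
same-line overlap (bounded retries, then the attempt is logged and
skipped). The six addition models combine three mechanisms:

1. *sliding* — random orientation;
2. *sliding + templating* — the new MT copies the local orientation bias:
   P(plus-end-out) = plus fraction among filaments covering the candidate
   centre (0.5 when none do);
3. *templating only* — as 2, but motor directionality is switched off:
   each overlap's gliding direction is drawn at random when the contact
   forms and persists while it lasts;
4. *sliding + unbounded growth* — 50/50 orientation, but the candidate
   only nucleates with probability given by the unbounded-growth
   likelihood at its position and orientation;
5. *unbounded growth only* — as 4 with random gliding;
6. *sliding + templating + unbounded growth* — templated orientation and
   the nucleation gate together.

The unbounded-growth likelihood is exponential in distance $d$ from the
tip, $P_\pm(d) = a_\pm e^{-d/20\,\mu m}$ with defaults $a_+ = 0.7$,
$a_- = 0.2$: plus-end-out MTs near the tip are far more likely to sit in
the unbounded regime than minus-end-out MTs, and the advantage decays over
the ~20 µm scale of the measured growth-length gradient. The fitted values
behind these curves are not published, so they are configuration
parameters with these defaults.

Runs are replicate-averaged (per-replicate seeds drawn from the master
seed), with snapshots on a configurable cadence, a JSON-lines-exportable
event log, and an exact filament ledger (count = initial + additions −
exits). `orientation_profile()` bins filaments by normalised axial
position and reports the plus-end-out fraction per bin with a
normal-approximation interval over replicates; empty bins are undefined,
not zero. Under sliding alone the proximal axon accumulates minus-end-out
MTs while the distal axon becomes plus-end-out — sorted but never uniform;
with all three mechanisms the whole axon converges toward plus-end-out
over simulated time. Sliding-only runs with the default parameter set
reach a mean axon length of roughly 50 µm (±20% over ≥10 replicates)
after 24 h of simulated time (43,200 steps); this package-level
computation is what the acceptance script reports.

## Synthetic data: what it does and does not emulate

The generators produce the statistical structure the analyses assume:
exponential growth durations at region- and orientation-specific
catastrophe rates, constant within-track speed, Bernoulli orientation
mixtures, growth concentrated near the tip (two-thirds of events within
10 µm by default), exponential shrinkage lengths, and exponential
intensity gradients with multiplicative lognormal noise. The `fly_neuron`
defaults put the four (region × orientation) growth-length means at
2.11/1.39/1.53/1.16 µm/cycle via a common 5 µm/min speed and matched
catastrophe rates, the shrinkage median at 2.03 µm, and axon lengths
around 60 µm — the scales observed in cultured fly neurons. Every
generator returns a truth record sufficient to replay its tables
byte-identically.

They deliberately do **not** emulate: detection noise or tracking errors
(tracks are geometrically perfect), pauses or minus-end dynamics,
spatially varying speeds, censoring at movie boundaries, axon-to-axon
kinetic heterogeneity beyond event sampling, or any image-level artefact.
Passing recovery tests therefore demonstrates that the estimators are
correct for the assumed generative model — not that the model captures
every feature of real kymographs. Conclusions about real data inherit the
usual caveats of the measurement (finite movies, detection limits,
manual tracing of shrinkage events).

## Degenerate inputs and numerical conventions

Non-positive rates, velocities or lengths are rejected at construction.
Empty track tables raise distinct errors (tip undefined; orientation
fraction `NA` with a warning). Bins and replicate profile entries without
events are reported as absent/`NaN`, never as zero. The regime functions
refuse unbounded parameters rather than returning large floats. Quantile
convention, bin assignment, boundary handling and optimiser settings are
fixed as described above so that identical inputs and seeds give identical
outputs to floating tolerance across platforms.
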
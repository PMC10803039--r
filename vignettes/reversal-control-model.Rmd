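---
title: "A coupled polarity/gliding-motor model of mechanosensitive reversal control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled polarity/gliding-motor model of mechanosensitive reversal control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gliderev)
```

## The model

*Myxococcus xanthus* glides on surfaces and periodically reverses its
leading pole. The reversal clock is a relaxation oscillator formed by
three polarity regulators: the Ras-like GTPase MglA marks the leading
pole; its GTPase-activating complex MglB and the RomR guanine-exchange
complex mark the trailing pole. `gliderev` couples this oscillator to the
state kinetics of the gliding machinery ("A-motors"), whose engagement
with the substrate is the model's proxy for substrate stiffness; the
coupling makes reversal frequency mechanosensitive.

The cell is a 1D axis of length $L = 5\ \mu m$ with a well-mixed polar
pool at each end (width $0.3\ \mu m$). Per pole $p$ the polar amounts
$A_p, B_p, R_p$ (MglA, MglB, RomR) exchange with diffusible cytoplasmic
fields $a, b, r$:

$$J_{on}(A,p) = k_{Aon}\, a_p\, h^{+}(R_p; K_{RA})\, h^{-}(B_p; K_{BA}),
\qquad
J_{off}(A,p) = \left(k_{Aoff,0} + k_{Aoff} h^{+}(B_p; K_{BA})\right) A_p$$

$$J_{on}(B,p) = k_{Bon}\, b_p\, h^{-}(A_p; K_{AB})
\left(1 + \beta h^{+}(B_p; K_{BB})\right),
\qquad J_{off}(B,p) = k_{Boff} B_p$$

$$J_{on}(R,p) = k_{Ron}\, r_p \left(1 + \gamma h^{+}(B_p; K_{BB})\right),
\qquad J_{off}(R,p) = k_{Roff} R_p$$

with Hill multipliers $h^{+}(x;K) = x^n/(K^n + x^n)$,
$h^{-} = 1 - h^{+}$, $n = 2$ throughout. The signed structure is the
field's consensus: RomR recruits MglA; MglB blocks and expels polar MglA;
MglA blocks polar MglB; MglB promotes RomR and itself. Mutual MglA/MglB
antagonism polarizes the cell; the slow negative loop
MglA ⊣ MglB → RomR → MglA switches the polarity periodically. Only the
interaction signs are constrained by experiment; the Hill form was chosen
for bounded multipliers, and every rate constant is a package calibration
(see below), not a measured value.

A-motors occupy five states: inactive ($M_i$, diffusing), active
($M_{a\pm}$, running along the helical track at $v_a = 2\ \mu m/s$), and
engaged ($M_{e\pm}$, force-generating at focal adhesions, drifting toward
the trailing pole at the cell speed, about $2\ \mu m/min$). Activation
occurs only in the polar regions at rate $k_{act} A_p M_i$ and consumes
one polar MglA per motor; deactivation (rate $k_{deact} B_p M_{a}$,
polar) returns the MglA to the pool. Active motors switch direction at
$k_{sw}$, engage outside the poles at $k_{eng}$ (the stiffness proxy) and
disengage at $k_{dis}$ (fast at the poles, `k_dis_pole`). The cell speed
saturates with the engaged amount $E$ as $v_{c,max}\, E/(E + K_v)$ and
points toward the pole with more MglA.

Mechanosensing emerges from bookkeeping, not from a dedicated sensor:
each active or engaged motor carries one MglA, so slowly-drifting engaged
motors sequester MglA away from the poles. A stiffer substrate (larger
$k_{eng}$) holds more MglA hostage, starves the polar oscillator and
lengthens the reversal period. Conversely, active motors that reach the
trailing pole are deactivated there by MglB and release their MglA into
the trailing pool — exactly the pool whose growth triggers the next
reversal — so mild activation *speeds the clock up*. The two effects
compete, producing the biphasic dependence of reversal frequency on
$k_{act}$: delivery wins at low activation, sequestration wins (and
eventually quenches the oscillation entirely) at high activation.

## Numerics

No ODE-solver package is assumed: the method-of-lines integrator is
compiled code with Strang splitting. Diffusion (Crank–Nicolson
half-steps, tridiagonal solves, Neumann walls) is unconditionally stable;
reactions, polar exchange and first-order upwind advection advance with
an explicit Heun step bounded by the advective CFL condition
(`cfl = 0.75` on $v_a$, cap `dt_max = 0.05 s`). Upwind was chosen over
higher-order advection because positivity matters more than dispersion
accuracy at 60 grid cells. The scheme is validated by its convergence
behavior, not its formal order: doubling the grid (60 to 120 cells)
moves the reversal period by well under 2%, halving the step by far less,
and the four conserved totals (MglA, MglB, RomR, motors — with
motor-bound MglA counted) drift by $\sim 10^{-10}$ relative over 10
simulated hours. Everything is deterministic: symmetry is broken by a 1%
seed in one polar pool, not by noise, and identical runs are
bit-identical.

Polar pools exchange with the grid cells overlapping the polar region
using exact overlap weights, which keeps the polar-region width (and
hence the activation integral) independent of grid resolution.

## Calibration and what the defaults mean

The original model this package reconstructs published its equations and
parameter table only in supplementary material that is not available to
us; the shipped defaults are therefore the committed output of
`calibrate_baseline()` against two printed anchors: a mean inter-reversal
interval of ~12 min and about half of the MglA outside the polar regions
at the steady phase (midpoints between reversals). The shipped set
achieves 12.01 min and a nonpolar fraction of 0.45. `calibrate_baseline()`
re-run from the defaults evaluates once and stops (`iterations = 0`),
which the test suite uses as a fixed-point check.

Two aspects of the calibration deserve honesty:

* **The coupled regime is a compromise.** A nonpolar MglA fraction near
  0.5 means the oscillator runs on roughly half its MglA; most parameter
  sets that oscillate when decoupled are quenched by this load (the
  symmetric state becomes stable). The committed set was selected, by a
  numerical search over the polarity constants, for a fast
  symmetry-breaking instability (the 1% seed polarizes the cell within a
  few minutes) so that the motor exchange does not stabilize symmetry.
* **The engaged-fraction range is an assumption.** The single-molecule
  measurements originally used to bound the engaged fraction are not
  available in print; the calibration target interval is configurable and defaults
  to the interval the committed set actually attains over the calibrated
  stiffness range ($f_{eng}$ from ~0.017 at the softest anchor to ~0.17 at
  the stiffest), rather than to a guessed experimental range.

The stiffness sweep covers $k_{eng} \in [0.012, 0.25]\ s^{-1}$, with agar
anchors mapped log-linearly (`agar_to_k_eng()`: 0.5% agar to 0.015, 1.5%
to 0.055). Over this range the reversal frequency falls strictly (from
5.22 to 4.77 per hour) and the engaged fraction rises strictly — the
model's core stiffness prediction.

## Reversal detection

Reversals are hysteretic zero crossings of the polarity indicator
$\sigma(t) = A_r - A_l$: a crossing counts only after the previous
excursion exceeded $\theta = 0.1$ of the indicator amplitude
(Schmitt trigger), crossing times are refined by linear interpolation,
and the first 2 h of each run are discarded as transient. Two conventions
are package choices, stated here because no published detection rule is
available: the steady phase is sampled at midpoints between consecutive
reversals, and an absolute amplitude floor (`amp_min = 0.02` of the MglA
total) declares a cell unpolarized rather than fast-reversing — after
oscillation death the indicator still wiggles at the $10^{-3}$ level
numerically, and a purely relative trigger would count those wiggles as
hundreds of reversals per hour.

## The network screen

The screen asks which couplings of the twitching (S) machinery onto
A-motor rates can reconcile opposite stiffness responses of wild-type and
S-deficient cells. Each of the 24 candidate networks places four
condition points (two genotypes × soft/hard agar) on the simulated
(engagement × activation) frequency surface; a network is viable iff
wild type reverses more on hard than soft while the mutant does the
opposite. The placement is formalized as multiplicative factor rules:
hard agar multiplies $k_{eng}$ by $\rho$; an S effect multiplies
(promotion) or divides (inhibition) the affected rate by $\sigma_{soft}$
on soft and $\sigma_{hard}$ on hard agar, with
$\sigma_{soft} > \sigma_{hard} \ge 1$ because S-motility is more
effective on soft substrates; split-regime networks move the wild-type
activation base across the biphasic peak by a factor `delta_split`.

Where the original analysis screened by visual placement, the committed
convention
was fixed once, after verifying it reproduces the qualitative outcome on
the simulated diagram — all 18 shared-regime networks fail, exactly the
3 activation-promoting split networks pass, and the mutant's
soft-more-than-hard prediction holds for every network. An existential
convention ("does any placement work?") was rejected: it cannot
reproduce the 18 failures.

One honest caveat, established by direct optimization over all placement
conventions on the shipped diagram: the outcome is reproducible only in
a narrow placement window, and it is *not* invariant under a ±20%
perturbation of $\rho, \sigma_{soft}, \sigma_{hard}$ (the
`screen_robustness()` probe; the corresponding acceptance assertion is
deliberately left failing). The reason is quantitative, not logical. In
this reconstruction the reversal frequency declines only a few percent
with activation before the oscillation quenches outright, so the usable
"decreasing branch" hugs the oscillation-death boundary; and that
boundary shifts with engagement roughly as
$k_{act}^{death} \propto k_{eng}^{-0.75}$. For a split network to pass,
the wild-type pair's activation contrast must outweigh the boundary
shift caused by the hard-agar engagement factor
($\sigma_{soft}/\sigma_{hard} \gtrsim \rho^{0.75}$), while the
engagement-only networks fail only if
$\rho\,\sigma_{hard} > \sigma_{soft}$; a maximin search shows both can
hold simultaneously only with factors close to unity, leaving no room
for a ±20% box. A surface with a broad, gradual high-activation decline
— which the original model evidently had — dissolves this tension; ours
does not exhibit one at any parameterization found that also satisfies
the period, MglA-partition and monotonicity anchors.

## Known limitations

* The activation response's rising and falling branches are shallow (a
  few percent in frequency) and end in abrupt oscillation death
  (amplitude collapse, not gradual slowing); the original figures suggest
  a more symmetric hump. The qualitative order — rise, peak, fall — is
  robust, the magnitudes are not, and the narrowness of the falling
  branch is what limits the network screen's robustness (above).
* At very low engagement rates the coupled system shows a reentrant
  death window in activation (quenched near $k_{act} \approx 1.7$,
  oscillating again near 3). The phase diagram is capped below the
  window.
* The engaged-motor spatial profile peaks mid-cell rather than at the
  leading pole: engaged motors drift toward the trailing pole for ~100 s
  before disengaging, and cannot reside in the polar regions at all.
  The corresponding acceptance assertion (a non-increasing engaged
  profile from the leading pole, a figure-only observation we could not
  inspect) is deliberately left failing; the *active*-motor
  gradient, which is anchored in published text, decreases from the
  leading pole as required.
* The free cytoplasmic MglA gradient runs trailing-ward (MglB expels
  MglA at the trailing pole); total polar MglA is still maximal at the
  leading pole, which is what the partition observable tests.
* One-dimensional geometry: helical track structure, discrete focal
  adhesion sites and motor clustering are subsumed into smooth fields and
  the single rate $k_{eng}$.
* Copy numbers are normalized (all totals 1); rates are calibrated, so
  individual constants should not be read as measured quantities.
* The screen's verdicts are ordinal. Quantitative ratios (e.g. the
  reported near-doubling of wild-type reversal frequency on hard agar)
  can be imposed via `wt_ratio` in `screen_networks()` but are not part
  of the default criterion.
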
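---
title: "Models and methods: sequestration, phospholock, and oscillation scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sequestration, phospholock, and oscillation scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlock)
```

# The scientific problem

Circadian clocks keep near-24-hour time with a negative feedback loop
between an activator and a repressor, but different organisms implement
that loop differently.  In cyanobacteria three proteins (KaiA, KaiB,
KaiC) run a purely post-translational oscillator: KaiA stimulates KaiC
phosphorylation, and S431-phosphorylated KaiC -- captured by KaiB --
sequesters KaiA, shutting its own phosphorylation down.  In eukaryotes
the repressor is made by transcription, binds the activator complex, and
is phosphorylated while bound.  This package implements a family of ODE
and stochastic models of these mechanisms and the analyses that probe
when they oscillate.

All models share one mathematical core: **titration of a free activator
by a sequestrant**.  With total activator $A_T$, sequestrant $R$, and an
effective dissociation constant $K$, the free activator is the positive
root of a quadratic,

$$ f(R) = \tfrac{1}{2}\Big(A_T - R - K + \sqrt{(A_T - R - K)^2 + 4 K A_T}\Big), $$

which approaches the piecewise-linear `max(A_T - R, 0)` as $K \to 0$.
The logarithmic slope $d\log f / d\log R$ ("sensitivity", an effective
reaction order) peaks near the titration point $R \approx A_T$, and the
peak grows as $K$ shrinks; a high peak is what makes a three-stage
negative feedback loop oscillate.  The package evaluates the quadratic
in a cancellation-free branch form (`free_kaia()`), so it is accurate
for $K$ down to $10^{-12}$ and for $R \gg A_T$.

# Model systems

**Core cyanobacterial model** (`core_params()`): KaiC phosphoforms
$T \to ST \to S$ with KaiA-stimulated entry $k_1 f(S) U$, where
$U = C_T - T - ST - S$ and $f$ is the quadratic above with the KaiA-KaiC(S)
dissociation constant $K_d$.  Oscillations require the stoichiometric
balance $C_T > (1+r)A_T + \epsilon$; with the package's equal fixed rates
$k_2 = k_3 = k_4$ the chain holds roughly equal amounts in each
phosphoform at turnover, so $r = 2$ and the criterion is the linear
condition $C_T > 3 A_T$ (checked by `stoich_condition_check()`, strict
inequality at the boundary).

**TTFL and PTR variants** (`ttfl_params()`): add kaiBC mRNA $M$,
translation $K_s M$, and KaiC degradation $V_d$.  In TTFL mode
transcription is inhibited by KaiC-S through the fixed structural term
$V_{trsp}\,100/(1 + (S/K_0)^4)$; in PTR mode transcription is the
constant $V_{trsp}$.  The Hill exponent 4 and fold factor 100 are
treated as structural constants, not tunables.  The TTFL acts as a
stoichiometry homeostat: when S-phosphorylated KaiC is plentiful
(repressive capacity high), transcription shuts off and total KaiC
falls back toward balance, so the TTFL oscillates over almost the whole
sampled parameter plane while the PTR variant oscillates only where its
fixed steady-state KaiC level happens to satisfy the balance condition.

**Kim-Forger model** (`kim_forger_params()`): the mammalian-clock
titration chain (mRNA, cytosolic, nuclear repressor) with the free
activator *fraction* $f(P, A, K_d)/A$; identical quadratic, normalised.

**Phospholock** (`phospholock_params()`): the eukaryotic mechanism in
which the repressor complex R binds the activator (rates
$k_{1f}/k_{1r}$), is phosphorylated while bound ($k_{2f}/k_{2r}$) --
"locking" the pair together -- and dissociates only from the
phosphorylated state at rate $k_3$.  The quasi-steady state of that
binding scheme is again the titration quadratic with effective
constants

$$ \tilde K_1 = k_{1f}(k_{2r}+k_3+k_{2f}), \qquad
   \tilde K_2 = k_{1r}(k_{2r}+k_3) + k_{2f}k_3, \qquad
   K_{\mathrm{eff}} = \tilde K_2/\tilde K_1 . $$

`effective_constants()` implements this mapping, and the test suite
*validates it against an independent oracle*: the closed form must agree
to $10^{-6}$ relative with the numerically relaxed equilibrium of the
explicit mass-action subnetwork on random rate draws.  Two limits are
instructive: with no lock ($k_{2f} = 0$, $k_3 = 0$) the scheme collapses
to pure sequestration, $K_{\mathrm{eff}} = k_{1r}/k_{1f}$; with a strong
lock and a slow leak ($k_3$ small), $K_{\mathrm{eff}}$ drops far below
the bare $K_d$ -- phosphorylation substitutes for unrealistically tight
binding.  This is also why *decreasing* $k_3$ (slower decay of the
locked complex) sharpens repression: $K_{\mathrm{eff}}$ is strictly
increasing in $k_3$.

**Activator phosphorylation** (`neurospora_params()`): the Neurospora
variant adds an activator phosphorylation cycle
($k_{4f}/k_{4r}$, ratio $k_4$), and -- crucially -- the dissociating
locked complex releases the activator in its *phosphorylated, inactive*
form.  The exact steady state then carries a third constant,

$$ \tilde K_3 = \tilde K_1 + k_{1f} k_{2f} k_3 / k_{4r}, $$

and the free activator is the same quadratic evaluated at the rescaled
repressor abundance $\rho R$ with $\rho = \tilde K_3/\tilde K_1$,
discounted by $1 + k_4$.  The ratio $\rho$ is the number of activators
each repressor inactivates per lock cycle: the repressor acts as a
catalyst for activator inactivation, so titration happens near
$R = A_T/\rho$ and oscillations become possible at repressor-to-activator
ratios far below one.  This is the mechanism by which the analysis
`stoich_ratio_distribution()` finds steady-state stoichiometric ratios
approaching zero once $k_3 > 0$; with $k_3 = 0$ the catalytic branch is
off, $\rho = 1$, and ratios cluster just below one as in pure
sequestration.  (During development we first implemented the
non-catalytic variant, in which the dissociating complex releases
*active* activator; its ratios never fell below ~0.5, which is how the
catalytic reading was identified as the one consistent with the printed
repression function.  The non-catalytic release is retained for the
repressor-only phospholock, whose printed form has no $\tilde K_3$.)

A note on the printed chain equations: the repressor-complex balance
appears in the source as $dR/dt = \alpha_3 R - \beta_3 R$, which
decouples R from the rest of the chain and admits no feedback.  The
package implements $dR/dt = \alpha_3 r - \beta_3 R$, matching the
verbal description (mRNA is translated to protein r, which forms the
complex R) and the structure of the other systems.

## Reference parameter set and the $k_2$ sweep

The repression-function figures use a fixed reference set
($\alpha_i, \beta_i$, $K_d = 1$, $k_3 = 1.9$, $A_T = 98.9$) while the
phosphorylation ratio $k_2 = k_{2f}/k_{2r}$ runs from 1 to $10^4$.  The
ratio alone does not fix the micro-rates, so
`phospholock_params_table1()` adopts the rapid-pre-equilibrium
convention: binding kinetics fast relative to the phosphorylation cycle
($k_{1f} = k_{1r} = 1000$, $k_{2r} = 1$, $k_{2f} = k_2$).  Under it

```{r}
vapply(c(1, 10, 100, 1e3, 1e4), function(k2)
  effective_constants(phospholock_params_table1(k2 = k2))$Kd_eff, 0)
```

the effective affinity tightens monotonically with $k_2$ and the
titration cusp sharpens, the behaviour the reference figures describe.
Had we instead held the binding rates comparable to $k_3$, the exact
mapping has a floor $K_{\mathrm{eff}} \gtrsim k_3$ and the trend
inverts; the fast-binding convention is therefore part of the package's
documented reconstruction, validated qualitatively (trend direction)
but not against unavailable published curves.

# The detailed KaiABC network

`build_network()` expands `detailed_params()` into 9 species and 14
mass-action reactions (order at most 2): KaiA-catalysed $U \to T$
(bimolecular, catalytic), slow $T \to ST$, KaiB capture of the
S431-phosphorylated forms ST and S (KaiB itself treated as non-limiting
by default, so capture is first-order; the `explicit_kaib` switch tracks
free KaiB as a species with total `B_T`, recovering the implicit model
when `B_T` dwarfs the captured pool), reversible KaiA sequestration by
the KaiBC
complexes (1:1), in-complex dephosphorylation, and release of KaiB and
KaiA on S431 dephosphorylation.  Total KaiC and total KaiA are conserved
by every reaction; the CI-mutant switch (weak KaiB-KaiC binding) scales
the capture rate by $10^{-3}$ and abolishes the rhythm.

The published rate set is not available, so the defaults are a
**calibration, not a prediction**: rates were fitted once (the
calibration scripts are kept outside the package) to a circadian
relaxation oscillation with a short phosphorylation phase
($\tau_1 \approx 8.8$ h), a long dephosphorylation phase
($\tau_2 \approx 18.7$ h), and a period robust to the ATP/ADP ratio,
then frozen.  Two structural choices carry the physics:

* the KaiA-stimulated step is fast enough that it is not rate-limiting,
  so scaling it by the ATP fraction (`atp_scaling()`; the package's
  modelling choice for how ATP enters) changes the period by under 5%
  across ATP fractions 1 down to 0.25, while the rhythm dies as the
  fraction approaches zero;
* pacing comes from the ATP-independent steps -- the slow
  $T \to ST$ conversion and KaiB capture on the way up, the in-complex
  dephosphorylation chain on the way down -- which also produces the
  rise/fall asymmetry ($\tau_1 < \tau_2$).

One reference inconsistency must be flagged: the published phase
durations, $\tau_1 = 9.5$ h and $\tau_2 = 18.5$ h, sum to 28 h, yet the
same source reports a period of roughly 24 h.  Since
$\tau_1 + \tau_2$ *is* the period for any single-peaked cycle, both
cannot hold.  The package calibrates the phase durations into their
bands and reports the resulting 27.8 h period honestly; the
corresponding period acceptance check is expected to fail and is left
failing by design.

`gillespie()` samples exact stochastic paths of the same network at
integer copy numbers (direct method; counts = concentration $\times$
$\Omega$).  Large volumes track the deterministic solution; at total
KaiC counts of order 50 single paths are dominated by copy-number noise
and the spectral detector no longer calls a rhythm -- the qualitative
copy-number dependence expected of a protein-count-limited oscillator.

# Oscillation detection

Two detectors are implemented, matching the two procedures used for the
published scans.

**Spectral** (`detect_oscillation_fft()`): drop the first 30% of the
series as transient, remove the mean, and find the dominant
non-zero-frequency peak (sub-bin period by parabolic interpolation of
log power).  The source procedure is silent on a threshold; the package
calls a series oscillating when the peak amplitude is at least 1% of
the mean level *and* at least 5 times the median spectral amplitude.
The first clause rejects numerically flat series, the second broadband
noise; small-amplitude limit cycles pass both.  The lowest 3 frequency
bins are excluded to guard against trend leakage, so cycles longer than
a third of the analysis window are not detectable -- a deliberate limit
shared with any finite-window spectral test.  Because the amplitude
clause is relative to the mean level, it is scale-free but not
invariant under *arbitrarily large* additive offsets; the event
detector is exactly offset-invariant, and the suite tests both at
moderate offsets.

**Event-location** (`detect_oscillation_events()`): integrate for 300
time units from a random initial state (uniform on (0, 10] per
species), take the mean of the monitored species, re-detect every
upward crossing of that mean, and call the system oscillating when the
last three crossings are evenly spaced to within $10^{-3}$ time units;
the period is the last inter-event gap.  Crossing times are refined
from the dense output by cubic Hermite interpolation (using the stored
derivatives), which reproduces analytic crossing times to $10^{-9}$,
so the $10^{-3}$ criterion is not limited by the output grid.  Because
the trajectory is deterministic, the mean and the crossings are
extracted from a single integration; this is numerically identical to
the two-pass procedure and costs one run.  The strict spacing tolerance
makes the detector conservative: slowly converging transients are
called non-oscillating, a property inherited from the published
procedure.

# Numerical choices

There is no system ODE solver dependency; the package ships two
integrators in C++.  The workhorse is a Rosenbrock 2(3) pair (the
`ode23s` scheme) with numerical Jacobians -- the repression cusp at
tight effective affinity makes the chain models genuinely stiff, with
local rates up to $\alpha_1 \cdot |f'| \sim 10^4\,h^{-1}$ -- and a
Dormand-Prince 5(4) pair serves non-stiff work.  Both integrate to a
uniform output grid (storing the right-hand side at every node for
interpolation) with relative tolerance $10^{-6}$ and absolute
$10^{-9}$ by default; tolerances control the local step error, so
end-of-run errors a small multiple of the tolerance are expected and
the tests allow for that.  States are clipped to zero when they
undershoot by less than $10^{-12}$ (counted and reported on the
trajectory object); larger negativity is treated as failure.

Root finding for the steady-state repressor brackets
$[0,\; A_T\,\alpha_1\alpha_2\alpha_3/(\beta_1\beta_2\beta_3) + 1]$:
the repression side is bounded by $A_T/(1+k_4)$ while the drain side is
linear, so a sign change is guaranteed; `uniroot` at $10^{-12}$
tolerance and a residual check close the loop.

# The synthetic-parameter generator and what a green test establishes

All sampling schemes from the published methods are implemented as pure
functions of (scheme, seed) with bitwise-reproducible output
(`sample_core()`, `sample_ttfl()`, `sample_phospholock()`,
`sample_until_oscillating()`), with one master seed expanded into
per-pipeline substreams (`substream_seed()`).  Stated distributions are
used verbatim: uniform on (0, 100) for abundances and chain rates,
(0, 1) for binding/phosphorylation micro-rates, (0, 0.1) for $k_3$, and
the published derived-parameter constraints (`k1r = Kd * k1f`,
`k2f = 10 * k2r`, `k4r = k4f`, paired multiplier tables).

Where the published sampling table is unavailable, the package ships
**stand-in ranges**, chosen once and frozen: `core_ranges()`
($k_1 \sim U(0,1)$, $A_T \sim U(0,50)$, $C_T \sim U(0,200)$, fixed
$k_2 = k_3 = k_4 = 0.13\,h^{-1}$) and `ttfl_ranges()`
($K_s \sim U(0,1)$, $A_T \sim U(4,50)$, fixed $V_{trsp} = 10$,
$V_m = 0.5$, $V_d = 0.05$, $K_0 = 50$, $K_d = 10^{-4}$).  The fixed
rates were calibrated so the default core set has a circadian period
(23.9 h) and equal chain rates give $r = 2$; the TTFL/PTR constants
were calibrated so the paired comparison reproduces the direction and
approximate magnitude of the published oscillating fractions, which is
the stand-ins' stated purpose.  Two of these choices deserve honesty:
$K_0$ sits at the top of the $A_T$ range because the transcription
homeostat must be able to engage *above* the titration point for any
sampled $A_T$; and the $A_T$ lower bound of 4 excludes a corner
($A_T \lesssim 3$) where KaiC-S quenches KaiA so far below $K_0$ that
the homeostat never engages and the TTFL overloads into a stable state.
A green TTFL/PTR test therefore establishes that the *mechanistic
contrast* (homeostat versus constitutive transcription) reproduces the
published fractions under documented stand-ins -- not that the
published Table's exact ranges were recovered.  The same caveat applies
to every stand-in quantity; quantities fixed by the source (sampling
distributions, derived-parameter rules, detector criteria, Table-1
constants) are used verbatim.

# Known limitations

* The reconstructed detailed network is one of many consistent with the
  described mechanism; its rate values are calibration targets, and the
  period/phase-duration inconsistency in the reference numbers is
  resolved in favour of the phase durations (period check left red).
* The phospholock robustness surface at $K_d = 1$ has oscillating
  fractions of order 1%, so the direction tests there lean on paired
  sampling and pooled cells; magnitudes are not asserted anywhere.
* No bifurcation continuation: oscillation regions are mapped by seeded
  grid sweeps only.
* Hexamer assembly, monomer exchange, explicit SasA/CikA/RpaA signalling
  and delay equations are out of scope.
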
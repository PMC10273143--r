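---
title: "Cyclic loading of keratin and vimentin filaments: models and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclic loading of keratin and vimentin filaments: models and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifmech)
```

## The scientific question

Keratin and vimentin are the two prominent cytoplasmic intermediate
filaments, expressed by epithelial and mesenchymal cells respectively.
Although both assemble from monomers with the same secondary structure,
single filaments respond to repeated stretch-relax cycles in opposite
ways: keratin filaments *elongate plastically while keeping their
stiffness*, whereas vimentin filaments *soften while keeping their
length*. Both dissipate a large fraction of the work done on them, on the
order of 10^4 kBT per micrometre of filament, but through different
mechanisms: sliding of subunits past each other in keratin (a metal-like
plasticity), and non-equilibrium unfolding of alpha-helices into a soft
random-coil state in vimentin (a Mullins-effect-like softening).

`ifmech` implements coarse-grained Monte Carlo models of both behaviours,
the optical-tweezers loading protocols used to probe them, and the
complete force-strain cycle analysis that turns raw force-distance-time
traces into the reported quantities.

## The keratin model: rupture, slide, rebind

The filament is a lattice of `n_parallel = 8` protofilaments (a keratin
cross-section holds 16 monomers, i.e. 8 dimers) times `n_serial = 20`
axial repeats of rest length 43 nm, so the default filament is 860 nm
long. Longitudinal connections are linear springs (`spring_k` per dimer)
that stiffen by `stiffen_factor` once their elastic extension exceeds
`stiffen_strain` of the original contour; the knee is tied to the original
contour length, so hysteresis loops keep their shape when the rest length
grows.

Each axial interface of each protofilament carries one lateral
interaction. Under the protofilament tension `f` it ruptures at the Bell
(slip-bond) rate

    k(f) = nu0 * exp((f - f_c) * x_open / kBT),

after which the dimer slides by one period (`period = 50` nm) toward the
next periodic binding site. With probability `p_neighbor = 0.10` it
rebinds to the *neighbouring* dimer — a permanent slip that elongates the
protofilament — and otherwise it rebinds to its *original* partner across
the shifted period. The original-site rebind is modelled as a strained
tether: the interface holds one period of recoverable slack until the
tension falls and the mirrored Bell law drives the back-slide, so those
events carry no net slip over a closed cycle but dissipate the difference
between the forward slide at high force and the back slide at low force.
This is the internal-friction channel; the 10% neighbour-rebinds are the
plasticity channel, which is why elongation and dissipation are
mechanistically coupled for keratin. Because the lattice is periodic, a
permanently shifted interface re-forms a bond with the same properties as
before; once unloaded it re-arms and can slide again, so permanent slip
accumulates cycle after cycle while at most one period of recoverable
slack is open per interface at any time.

Interface strengths are quenched-random. Thresholds `f_c` are drawn from
a mixture: a weak band (default 23-34 pN, fraction `frac_weak = 0.35`)
engaged by low-force cycling, and a strong tail (up to 105 pN) engaged
only at high force. Formally this is Bell kinetics with heterogeneous
zero-force rates, `k0 = nu0 * exp(-f_c * x_open / kBT)`; the spread
represents the distribution of lateral binding strengths along an
assembled filament and plays the same role as distributed dislocation
barriers in a crystal. A single homogeneous barrier cannot reproduce the
data: it either yields far below 900 pN (so high-force traces never reach
their trigger) or produces no low-force sliding at all.

A small portion of alpha-helical segments within keratin can also open
near peak force (`n_helix = 12` per protofilament, thresholds 24.5-28 pN,
releasing 28 nm each). They re-close at low tension, recovering their
length, so they contribute hysteresis but neither elongation nor
softening — consistent with a constant stiffness and with the hypothesis
that the few unfolded structures in keratin are not load-bearing
afterwards.

**Mean-field reduction.** Tension is shared equally among the parallel
paths at every cross-section, and the filament rest length is the initial
length plus the mean released slack over the protofilaments. This is the
one-interface-resolution picture of the sliding mechanism; full
two-dimensional dislocation geometry is out of scope. The general
spring-and-bond network solver (`network_force()`) retains the full node
resolution and is cross-checked in the tests against an independent dense
assembly of the node equilibrium equations.

## The vimentin model: unfold, collapse to coil, cycle the coil

Vimentin has 32 monomers per cross-section, modelled as
`n_parallel = 16` dimer-level elements times `n_serial = 20` repeats.
Strong lateral connections prevent sliding; instead each element's
alpha-helical region unfolds irreversibly under force (Bell kinetics,
thresholds 16-22 pN), extending its rest length from 43 to 76 nm. The
plateau of the first stretch — linear to a strain near 0.15, nearly flat
to about 0.8-0.9, stiffening beyond — emerges from the threshold sweep.
When the local tension falls below `refold_f` during relaxation, an
unfolded element collapses into a *random coil*: compact again
(rest 43.5 nm) but softer than the helix (`k_coil = 1.5` versus
`k_alpha = 2.42` pN/nm), and it never returns to the helical state within
a trajectory. On later cycles coils open and close reversibly at a lower
force threshold (about 13.5 pN), so repeated cycles keep a smaller but
persistent hysteresis while the filament length is conserved: softening
with length memory, the mirror image of keratin.

An optional destabilization rule (off by default) ruptures the filament
on the cycle after more than 90% of any cross-section has left the
helical state, reproducing the observation that vimentin filaments pulled
into the high-force regime fail during their second cycle.

## Loading protocols

`protocol_spec()` encodes the four experimental programs: constant
maximum distance or constant maximum force, each in the low-force
(trigger 250 pN — the typical onset force of the vimentin plateau) or
high-force (trigger 900 pN) regime. In constant-distance mode the
maximum distance is fixed during the first cycle: for keratin at the
first 250 pN (or 900 pN) crossing, linearly interpolated; for vimentin at
the detected plateau onset. The onset detector declares the plateau at
the first strain where the running local slope (least-squares over a
0.05-strain window) falls below 50% of the initial elastic slope; the
protocol then imposes one extra `onset_margin = 0.10` of strain beyond
the detection so the stretch halts once the plateau is clearly
established — the detector necessarily fires about half a window after
the true onset, and the measured curves visibly enter the plateau.
Relaxation returns to the starting distance at the pulling speed
(500 nm/s by default); there is no inter-cycle pause.

## Cycle analysis

All reported quantities follow the experimental conventions:

* **Reference length** `L0`: distance at the first upward 5 pN crossing
  of the first stretch; strain is `eps = (L - L0)/L0` for all cycles of
  that filament.
* **Effective length** `eps_e` and **stiffness** `kappa_f`: ordinary
  least squares of force on strain over the 100-150 pN window of the
  stretch branch; `kappa_f` is the slope (pN per unit strain) and
  `eps_e` the x-intercept. Window membership is re-decided from the
  fitted line in two refinement passes: selecting samples on the
  *measured* force lets edge points enter or leave the window according
  to their noise sign, which attenuates the slope by about 10% at 5 pN
  noise, while selection on the fitted line is unbiased and is a no-op on
  noiseless traces.
* **Strain-window stiffness** `kappa_eps`: slope over a fixed strain
  window (default 0.1-0.3), optionally on the corrected strain
  `eps_c = eps - eps_e`.
* **Hysteresis energies**: trapezoid integrals of force over distance on
  the common support of the two branches; `E_rel = E_dis / E_in` and the
  absolute dissipated energy per initial length in kBT/µm (kBT = 4.114
  pN nm, room temperature).
* **Cohort summaries**: per-cycle median and 25th/75th percentiles
  (type-7 linear interpolation); histograms use the Freedman-Diaconis
  bin width `2 IQR n^(-1/3)`.
* A cycle that fails a fit precondition yields a missing value, never an
  abort, so cohort summaries degrade gracefully.

Fits use the stretch branch only (the experimental fit lines lie on the
loading curves); this is configurable.

## Numerical choices

Kinetics use fixed-step Monte Carlo with per-step probabilities
`1 - exp(-k dt)`; the base step (2 ms) is subdivided automatically so no
single-step probability exceeds 0.1, and rates carry a numerical ceiling
of 1000/s (an event within a millisecond is effectively immediate at the
50 Hz sampling of the ramp). Simultaneous events within a substep are
resolved in random order with the load re-shared after each. Mechanics
are quasi-static: the filament is in force balance at every imposed
distance, as appropriate for optical-tweezers pulling speeds. Crossing
detection (5, 250, 900 pN) uses the first upward crossing with linear
interpolation. A single integer seed makes every replicate bit-for-bit
reproducible.

## The synthetic-trace generator

`synthetic_truth()` / `generate_cycle()` emulate optical-tweezers
stretch-relax records with fully known ground truth: piecewise
linear/plateau templates for keratin-like and vimentin-like force-strain
shapes, per-cycle injected effective lengths, a 5 pN crossing so the
reference-length convention applies, and additive white Gaussian force
noise (default SD 2 pN — force detection noise dominates; distance is the
commanded coordinate). The relax branch is the template scaled by
`relax_fraction`, so the injected relative dissipated energy is exactly
`1 - relax_fraction`. The generator validates the analysis pipeline end
to end; what it does *not* emulate are drift, bead rotation, attachment
compliance and coloured noise, so passing recovery tests demonstrates
correctness of the estimators, not robustness to every experimental
artefact. `with_force_noise()` overlays the same noise model on
simulator output so model traces can be analysed under measurement
conditions.

## Calibration and what the defaults mean

All kinetic and elastic defaults are calibration parameters chosen once
so that the default filaments reproduce the experimental summary
statistics under the standard protocols: keratin reaches 250 pN near
strain 0.55 on its first stretch and lands in the published elongation
bands (median effective length 0.1-0.2 after eight low-force cycles,
0.6-0.8 after eight high-force cycles) with better than half of the
first-cycle input energy dissipated; vimentin shows its plateau onset
near strain 0.15 at about 250 pN and dissipates about 80% of a deep
first cycle. Cohort sizes of about 20 replicates and 8-15 cycles keep
a full calibration run in the range of a few minutes; these are the
problem sizes used throughout the tests and the acceptance script.

## Known limitations

* **Repeated-cycle dissipation.** Under displacement control, any
  quasi-static mechanism that dissipates half of the first-cycle input
  energy must hold roughly 0.2 strain of force-activated recoverable
  slack; at constant maximum distance that slack pins the peak force near
  the activation band, so the model keratin keeps dissipating nearly as
  much on later cycles as on the first. The experimentally observed decay
  of keratin's relative dissipated energy with cycle number (and hence
  the factor-two contrast to vimentin under repeated loading) appears to
  require genuinely rate-dependent friction, which the quasi-static
  force balance excludes by design.
* **Elongation-per-maximum-strain contrast.** Because the model vimentin
  keeps its length almost perfectly (|median eps_e| < 0.05 over 15
  cycles), its elongation-versus-maximum-strain slope is close to zero
  and the keratin/vimentin slope ratio comes out near an order of
  magnitude rather than the measured factor of about five. The two
  constraints — strict length memory and a factor-five ratio — cannot be
  met simultaneously in this model family.
* The first high-force stretch accumulates its plastic flow on the way
  to 900 pN, so simulated maximum strains in that regime exceed the
  measured ones; effective lengths and energies, which are the reported
  quantities, are unaffected.
* Bundles, filament assembly, bending, hydrodynamics and the bead-trap
  dynamics are outside the model.

## A short session

```{r example, eval = FALSE}
library(ifmech)

# eight low-force cycles of a keratin filament
sim <- simulate_keratin(protocol_spec("const_dmax", "LF", n_cycles = 8),
                        seed = 1)
metrics <- cycle_metrics(sim$traces)
metrics[, c("cycle", "eps_e", "kappa_f", "E_rel")]

# a cohort with quartile bands
coh <- simulate_cohort("keratin", n = 20, seed = 1)
cohort_summary(coh$metrics, "eps_e")
plot_cycle_band(coh$metrics, "eps_e")
```
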
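---
title: "Model and methods: cortical column networks with long-range disynaptic inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(columnet)
```

## Scope

`columnet` simulates a layer 2/3 cortical patch organised as a square grid
of hypercolumns, each containing six minicolumns. Minicolumns with the
same index across hypercolumns form a *pattern* (an attractor's cell
assembly), linked by long-range excitation. Four cell types are modelled:
pyramidal cells (PC, 30 per minicolumn), somatostatin Martinotti cells
(MC, 3 per minicolumn), VIP interneurons (3 per minicolumn), and
parvalbumin basket cells (BC, 8 per hypercolumn, shared across
minicolumns). The scientific focus is the long-range recruitment of MC
(`PC-MC_LR`): disynaptic inhibition that grows with stimulus size and
produces surround suppression and center saliency, and its release by a
VIP-mediated disinhibitory drive.

## Membrane model

Each cell is a single-compartment Hodgkin-Huxley neuron (an equivalent
cylinder of diameter $d$ and length $L$):

$$C_m \frac{dV}{dt} = -G_\mathrm{leak}(V - E_\mathrm{leak}) - I_\mathrm{Na}
 - I_\mathrm{Kd} - I_\mathrm{M} + I_\mathrm{syn},$$

with $I_\mathrm{Na} = g_\mathrm{Na} m^3 h (V-E_\mathrm{Na})$,
$I_\mathrm{Kd} = g_\mathrm{Kd} n^4 (V-E_K)$ and the slow non-inactivating
M current $I_\mathrm{M} = g_M\, p\, (V-E_K)$ responsible for
spike-frequency adaptation. Gate kinetics follow the Traub-style
formalism with a threshold shift $V_T$; the M current uses
$p_\infty(V) = 1/(1+e^{-(V+35)/10})$ and
$\tau_p(V) = \tau_\mathrm{max}/(3.3 e^{(V+35)/20} + e^{-(V+35)/20})$.
Per-type conductances, soma sizes and reversal potentials are the
published set (`default_neuron_params()`); VIP cells reuse the Martinotti
column, as the two types are described as same-sized and adapting.

Three constants are not part of the published set and are fixed here
once, as package defaults:

* **$L$** (cylinder length): the iso-dimensional convention $L = d$.
* **$\tau_\mathrm{max}$**: 1000 ms for all types, a standard value for
  cortical adaptation in this formalism.
* **$V_T$** (per type): $V_T$ sets each type's spike threshold, and with
  $L = d$ it is the only free determinant of how the published drive
  conductances (in absolute $\mu S$) couple to spiking. The defaults are
  $-69$ mV (PC), $-69.5$ mV (MC), $-72$ mV (BC) and $-70$ mV (VIP). The ordering
  (interneurons more excitable than PC) mirrors the higher input
  resistance and lower rheobase of cortical interneurons in vitro; the
  absolute values were calibrated once so that (i) the feedforward
  stimulus levels ($g_1 \ldots g_5 \approx$ 5-7 mV of depolarisation)
  are peri-threshold for PC rather than saturating, (ii) MC sit slightly
  below PC so they are recruited mainly by the summation of local and
  long-range inputs, and (iii) BC and VIP respond reliably to their
  respective drives (PC input, selective VIP drive). They are ordinary
  arguments of `default_neuron_params()`.

A note on the resting structure: for $V_T$ below about $-73$ mV the
Na window current destroys the resting fixed point, so the usable
excitability range is bounded; `resting_potential()` locates the stable
fixed point by a scan-and-bracket root search.

## Synapses

Receptors are kinetic two-variable models: each presynaptic spike
increments the fast drive $x$ (decay $\tau_x$), which opens channels
through $ds/dt = \alpha_s x (1-s) - s/\tau_s$, and the current is
$I = G\,s\,(E_\mathrm{rev}-V)$, with the NMDA current additionally
multiplied by the magnesium block
$B(V) = 1/(1 + [\mathrm{Mg}^{2+}] e^{-0.062 V}/3.57)$
(default 1 mM). AMPA and GABA$_A$ use $\tau_x = 0.05$ ms,
$\tau_s = 6$ ms; NMDA uses $\tau_x = 5$ ms, $\tau_s = 150$ ms;
$\alpha_x = 1$, $\alpha_s = 1\,\mathrm{ms}^{-1}$.

Short-term plasticity follows the standard release model: the available
vesicle fraction recovers as $dR/dt = (1-R)/\tau_\mathrm{rec}$ and each
spike utilises a fraction $U$ of it; in facilitating mode the utilisation
is itself dynamic, $du/dt = -u/\tau_\mathrm{facil} + U_1(1-u)\,\delta(t-t_{sp})$,
incremented before release so the first-spike release is $U_1 R$.
Depression multiplies the per-spike increment of $x$ by the release
scale. The per-class constants are in `stp_table()`. The published table
labels the PC-BC row "facilitating" but gives it no facilitation
constants ($U = 0.5$, $\tau_\mathrm{rec} = 600$, $\tau_\mathrm{facil} = 0$)
and the accompanying text calls PC-BC depressing throughout; the package
implements it as depressing.

### Conductance calibration

Peak conductances are not published; unitary PSP amplitudes are.
`calibrate_peak_conductance()` finds $G$ by bracketed root-finding so
that a single presynaptic spike (fresh plasticity state) deflects the
resting postsynaptic soma by the target amplitude, measured through the
same integrator used for network runs. The first-spike release scale
($U$, or $U_1$ for facilitating classes) is absorbed into $G$, so the
unitary PSP in the fresh state equals the tabulated value exactly.

Two conventions were genuinely open:

* **Holding point.** PSPs are calibrated at rest. For GABA$_A$
  ($E_\mathrm{rev} = -75$ mV, rest $\approx -70.4$ mV) the driving force
  at rest is small, so this is the *generous* convention for inhibition:
  IPSPs are 2-4 times larger at depolarised potentials.
* **NMDA block.** The NMDA amplitude is calibrated with the Mg block
  clamped to 1 (`clamp_block = TRUE`), i.e. the tabulated amplitude is
  the maximal-conductance amplitude. Calibrating the composite deflection
  at rest instead (block $\approx 0.045$) compensates the block into a
  conductance ~20 times larger, which makes the slow NMDA component
  dominate all recurrent excitation during network activity; the clamped
  convention keeps the NMDA/AMPA peak-conductance ratio physiological.
  Both conventions are available.

## Architecture

`build_network()` realises every local class as independent Bernoulli
draws at its tabulated probability within its scope: PC-PC (25%), PC-MC
(30%, the tabulated value; the running text says 40%) and MC-PC (80%)
within the minicolumn, PC-BC and BC-PC (70%) within the hypercolumn,
VIP-MC (60%) within the minicolumn. PC-PC contacts carry AMPA and NMDA
on the same anatomical pair. Long-range wiring follows the
terminal-field rule: every PC picks one same-pattern minicolumn in
another hypercolumn uniformly and innervates 4 PC and 1 MC there
(`PC-PC_LR` AMPA+NMDA depressing, `PC-MC_LR` AMPA facilitating). With 30
PC per minicolumn this gives a probability of about
$1-(1-1/(N_{hc}-1))^{30}$ that an ordered same-pattern pair is connected
(~0.58 on the full 6x6 grid); the printed "50%" figure is consistent
with this order of magnitude but not exactly derivable, so it is
documented rather than asserted.

Wiring variants reroute the long-range interneuron terminal
(`network_spec()` presets): Type 1 is the reference (MC, facilitating,
minicolumn-specific); Types 2/3 send it to BC (hypercolumn-wide, hence
orientation-unspecific) with facilitating/depressing dynamics — the
published cartoon does not disambiguate which is which, so the pair is
exposed as two presets; Type 4 merges the MC pools across the
hypercolumn; Type 5 removes long-range inhibition; Type 6 uses
orientation-specific BC (each BC is cyclically assigned one minicolumn
and wires only with it, and long-range terminals land on the
orientation-matched BC). Variants are weight-compensated against a Type
1 network built with the same seed: for each affected class group
(excitation onto the mediating interneuron; the interneuron's output
onto PC) the per-connection weight is scaled by reference/variant edge
count, preserving the product cells x projections x weight.

Cells get coordinates (uniform in each hypercolumn's 500 um disc, z
jittered +-50 um); conduction delays are distance over a per-connection
Gaussian speed (mean 0.3 m/s, sd 20% of the mean — the width is not
published — truncated at 5% of the mean), yielding the expected
right-skewed delay distribution.

## Drives

Background noise is a point-conductance Ornstein-Uhlenbeck excitatory
conductance on every cell (mean 0.000121 uS). Its sd and correlation
time are not published; the correlation time defaults to 2.7 ms.
Because the mean noise conductance depolarises a soma of the tabulated
size by well under 1 mV, sustained background firing can only come from
fluctuation-triggered threshold crossings amplified by recurrent
connections. The default sd (22 x mean) was therefore calibrated once so
that the noise-only network holds the stated 0.5-1 Hz pyramidal
background band; at this sd the zero-clipped process operates as a
shot-noise-like conductance and its *realised* mean exceeds the nominal
OU mean (the nominal parameter is kept at the published value). The
stimulus uses the same mechanism, private to every PC of a driven
minicolumn, at the published levels
$(g_1,\ldots,g_5) = (0.0028, 0.0024, 0.0020, 0.0022, 0.0025)\ \mu S$
($g_2$ default), with sd 0.5 x mean; the selective VIP drive uses
0.0018 uS onto VIP cells of the driven minicolumns only.

## Numerical scheme

The compiled engine advances gates and voltage by exponential Euler at a
fixed step (default dt = 0.05 ms; 0.025 ms for accuracy studies).
Receptor gating and the OU drives are advanced on a sub-grid (every 4
steps by default, i.e. 0.2 ms) with conductances held in between; the
$x$ transient, faster than any grid, enters $s$ through its exact
within-interval integral, which makes the update nearly step-size
independent. Spikes are upward crossings of 0 mV with a 2 ms lockout;
each spike is queued on every outgoing connection with its conduction
delay rounded *up* to the step grid (a documented perturbation < dt).
Short-term plasticity is updated event-wise at arrival times using the
exact closed-form recursion. `halve_step_check()` compares population
rates at dt and dt/2 (5% tolerance, flagged not fatal). Exponentials in
the hot loop use a polynomial `exp` accurate to ~1e-8, well below every
other error source.

Randomness is per-cell: each cell owns a counter-based stream seeded
from (run seed, cell id), so toggling one cell's drive (e.g. the VIP
condition) leaves every other cell's noise sequence untouched — paired
comparisons across conditions use common random numbers. Construction
randomness is a separate stream derived from the network seed. Runs are
bit-reproducible given (network, drives, config).

## Experiments and the reduced desk scale

The four pre-registered experiment runners reproduce the study's
protocols at reduced scale: size-dependent suppression
(`run_size_tuning_experiment`, 4x4 grid), contextual contrast
(`run_contrast_experiment`, 3x3), center-surround wiring variants with
the saliency statistic $\delta$ = center-site minus surround-site PC
rate (`run_variant_experiment`, 4x4; site 2 is the surround-pattern
minicolumn farthest from the 2x2 center block), and the VIP
disinhibition size series (`run_disinhibition_experiment`, 3x3).
Defaults: 3 trials, 1.2 s stimulus after 0.3 s baseline, 100 ms analysis
bins, window means over the stimulus interval. The grids were chosen
once: 4x4 where the effect relies on the small/large or
center/surround contrast of long-range recruitment (a 3-minicolumn
stimulus already recruits a quarter of the long-range pool on a 3x3
grid), 3x3 where it does not.

### What the reduced scale can and cannot show

Two structural facts limit the network-level effect sizes under the
published parameter set, at any scale:

* A depressing synapse's sustained transmission is capped by vesicle
  recovery: release x rate $\le 1/\tau_\mathrm{rec}$. With
  $\tau_\mathrm{rec} = 500$ ms, 3 MC per minicolumn, 80% connectivity
  and a unitary IPSP of $-0.6$ mV, the MC-PC pathway can shift a PC's
  mean potential by at most a few tenths of a millivolt, and its
  *sensitivity* to MC rate saturates above ~10 Hz.
* The same stimulus-size increase that recruits long-range MC drive also
  recruits long-range PC-PC excitation onto the recorded minicolumn; the
  two effects on the recorded PC are of the same order and opposite
  sign.

Consequently the robustly reproduced signatures at desk scale are the
*interneuron-side* and control-side ones — MC firing grows with stimulus
size while PC firing does not (the absence of suppression in MC); without
the long-range MC pathway, PC responses grow with stimulus size and the
homogeneous layout is the more salient one; the surround-site bias of
unspecific long-range inhibition (negative $\delta$ for the rerouted
variants) and the transient-then-reversing $\delta$ of the depressing
orientation-specific variant both appear — while the pyramidal-side rate
differences that depend on the MC pathway *winning* (surround
suppression of PC, the center-saliency sign flip, positive $\delta$ for
the reference wiring, and the VIP drive's effect on PC rates) are of
order 1 Hz or below and not reliably sign-stable across seeds at this
scale. The acceptance tests assert the full published sign set and
therefore document which signatures reproduce and which do not; the
package reports honest outcomes rather than tuned ones.

## Known limitations

Single-compartment cells (no dendritic targeting of MC inhibition, no
dendritic calcium events); long-range connectivity without
distance-dependent profiles; one terminal field per PC; no explicit
layer-4 input population; desk-scale grids below the published 6x6.
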
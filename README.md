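# columnet

Conductance-based simulation of a layer 2/3 cortical patch in which
long-range excitation onto Martinotti cells implements disynaptic
surround suppression, and VIP interneurons implement its disinhibitory
release.

The model is an attractor network of Hodgkin-Huxley point neurons —
pyramidal cells (PC), parvalbumin basket cells (BC), somatostatin
Martinotti cells (MC) and VIP cells — arranged as a square grid of
hypercolumns with six minicolumns each. Same-index minicolumns across
hypercolumns form a *pattern* linked by long-range axons: each PC
innervates 4 PC and 1 MC in one same-pattern minicolumn of another
hypercolumn. Synapses are kinetic AMPA / NMDA / GABA<sub>A</sub>
receptor models,

$$\frac{dx}{dt} = \alpha_x \sum_j \delta(t - t_j) - \frac{x}{\tau_x},
\qquad
\frac{ds}{dt} = \alpha_s\, x\,(1 - s) - \frac{s}{\tau_s},
\qquad I = G\,s\,(E_\mathrm{rev} - V),$$

with Tsodyks–Markram short-term plasticity (vesicle pool $R$ with
recovery $\tau_\mathrm{rec}$; dynamic utilisation $u$ with increment
$U_1$ and decay $\tau_\mathrm{facil}$ for the facilitating PC→MC
classes). Peak conductances are calibrated so that unitary PSPs at rest
match the published amplitudes (e.g. PC→PC 1.2 mV, PC→BC 1.7 mV, BC→PC
−1.4 mV, MC→PC −0.6 mV, VIP→MC −0.2 mV). Background activity and the
feedforward stimulus are point-conductance Ornstein–Uhlenbeck drives.
The integrator is compiled (Rcpp), fixed-step exponential Euler with
delayed spike delivery through an event queue, and is bit-reproducible
for a given seed.

## Worked example

Calibrate the synapse classes, build a reduced two-by-two-hypercolumn
network, and measure the spontaneous pyramidal rate under background
noise alone:

```r
library(columnet)

cal <- calibrate_synapses()
cal[cal$class == "BC-PC", c("class", "target_mV", "G", "measured_mV")]
#>   class target_mV        G measured_mV
#> 9 BC-PC      -1.4 3.307495        -1.4

net <- build_network(network_spec(grid = c(2, 2), seed = 42))
res <- run_network(net, cal, sim_config(t_total = 1, seed = 1))
pc <- net$cells$id[net$cells$type == "PC"]
sum(res$spikes$cell %in% pc) / length(pc)   # mean PC rate over 1 s
#> [1] 0.6347222
```

The calibrated BC→PC conductance produces exactly the −1.4 mV unitary
IPSP it was fitted to, and the noise-only network sits in the 0.5–1 Hz
background band. The experiment runners reproduce the study protocols at
reduced desk scale:

```r
st <- run_size_tuning_experiment(seed = 1)   # small vs large stimulus
st$suppression_indicator$with_lr_mc          # rate_large - rate_small per population
de <- run_disinhibition_experiment(seed = 1) # VIP size series
de$raw
```

Each report embeds its resolved configuration and seeds. See the
methods vignette (`vignettes/columnet-methods.Rmd`) for the model
equations, the calibration conventions, and a frank account of which
network-level signatures reproduce at desk scale.

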
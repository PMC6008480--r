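# memstdp

Simulation of a **memristive, voltage-based synaptic plasticity rule** in
recurrent networks of quadratic integrate-and-fire (QIF) neurons, for
computational neuroscientists studying how pair-based plasticity shapes
connectivity, and for neuromorphic modelers who want a device-plausible
learning rule with biological calibration.

A synapse is a single normalized conductance
ω ∈ [ω<sub>min</sub>, ω<sub>max</sub>] that changes only when the
pre-synaptic neuron spikes, by one event of the modified logistic flow

> dω/dt = k (V<sub>post</sub> − V<sub>critical</sub>) ω² (1 − ω/ω<sub>max</sub>) − κω,

with the linear leak −κω acting continuously between spikes.  The sign of
the post-synaptic membrane potential decides between long-term
potentiation and depression; the ω-dependent factor binds the weight to
its bounds and makes mid-range weights the most plastic.  Membranes obey
the QIF equation

> C du/dt = g̃<sub>L</sub> (u − u<sub>rest</sub>)(u − u<sub>critical</sub>) + I(t),

with threshold-reset spiking and a refractory hold.  In the network, a
spike of neuron *i* updates every outgoing weight ω<sub>ij</sub> using
the partner's instantaneous membrane potential, and is propagated as a
current pulse normalized by the receiving neuron's total incoming weight.
The same engine, driven by rate-coded versus temporally-coded input,
produces bidirectional (Hopfield-like) versus unidirectional (chain)
connectivity, pattern completion from fragments, and sequence replay.

## Worked example

Single-synapse pairing protocols (60 pairings, standard parameters):

```r
library(memstdp)

# spike-timing window at 6 Hz
stdp_window(c(-20, -10, 10, 20), n_pairs = 60, pair_freq = 6)
#>   dt_ms change_pct
#> 1   -20  -2.118200
#> 2   -10  -2.713871
#> 3    10  10.407813
#> 4    20   7.048756
```

Pre-leading-post pairings (+10 ms) potentiate the synapse by ~10 %;
post-leading-pre (−10 ms) depress it — the classic asymmetric STDP
window, obtained here purely from the membrane voltage read out at the
pre-spike time.  Sweeping the pairing frequency on the post-pre branch:

```r
pf <- pair_frequency_curve(1:60, dt_pair_ms = -10, n_pairs = 60,
                           leak_mode = "off")
find_sign_crossover(pf)
#> [1] 40.04389
```

Below 40 Hz post-pre pairings depress, above they potentiate: at high
rates the membrane has already re-depolarized 10 ms after a spike.  With
the continuous forgetting rate enabled (0.417 %/s), pre-post pairings
slower than ~2 Hz can no longer produce net potentiation.

Temporal coding in a nine-neuron all-to-all network — nine pixels
stimulated in sequence at 60 Hz, 17 ms stride — builds a unidirectional
synaptic chain along the presentation order:

```r
w0 <- init_network(9, "constant", value = 0.5)
prog <- temporal_program(pattern(rep(1, 9), 3), stride_ms = 17,
                         item_ms = 34, rate_hz = 60, loops = 150)
r <- run_network(w0, prog, I0_int = 0, leak = TRUE)
connection_census(r$omega)[c("bidirectional", "unidirectional")]
#> $bidirectional
#> [1] 0
#> $unidirectional
#> [1] 8
```

The eight strong edges are exactly 1→2, 2→3, …, 8→9.  Rate-coded
presentation of static patterns instead symmetrizes the pattern-internal
weights (bidirectional connectivity), and a trained 16×16-pixel network
completes a stored contour image from a fragment of its pixels
(`completion_curve()`), with recall quality Q(e) rising abruptly with the
cue size.

Canned experiment drivers with CSV/JSON artifacts and a resolved-config
echo are available through `run_experiment()` /
`experiment_config()`, or from a shell via the thin CLI:

```sh
Rscript inst/cli/memstdp.R pair_frequency --seed 1 --out runs/pf
```

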
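---
title: "A memristive voltage-based plasticity rule in QIF networks: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A memristive voltage-based plasticity rule in QIF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstdp)
```

## The model

`memstdp` simulates synaptic plasticity in the spirit of a voltage-driven
memristive device: a two-terminal element whose conductance depends on the
history of the voltage across it.  The device abstraction is reduced to a
single normalized conductance — the synaptic weight
$\omega \in [\omega_{min}, \omega_{max}]$ — and two facts about such
devices: the state change is gated by activity and signed by a voltage, and
it is *state-dependent* (a device near its conductance bounds barely
moves).

**Plasticity.**  Whenever the pre-synaptic neuron spikes, the weight moves
along a modified logistic flow signed by the post-synaptic membrane
potential $V_{post}$ relative to a set point $V_{critical}$:

$$\frac{d\omega}{dt} \;=\;
  \underbrace{k\,(V_{post}-V_{critical})\,\omega^2
  \Bigl(1-\tfrac{\omega}{\omega_{max}}\Bigr)}_{\text{spike-gated, }f}
  \;-\; \kappa\,\omega ,$$

with only the leak $-\kappa\omega$ acting between spikes.  Each
pre-synaptic spike applies one forward-Euler step of duration `tau_event`
to the gated term; the leak is integrated exactly
($\omega \leftarrow \omega e^{-\kappa\,\Delta t}$, unconditionally stable
and step-size independent).  $\omega = 0$ and $\omega = \omega_{max}$ are
exact fixed points of $f$; the flow is steepest at mid-range weights
(analytically at $2\omega_{max}/3 \approx 0.67$), which keeps the weight
distribution bimodal, as pair-based Hebbian rules require.  A hard lower
clamp at $\omega_{min} = 0.05$ protects silent connections from being lost
irreversibly.

**Neuron.**  The membrane is a quadratic integrate-and-fire (QIF) model

$$C\,\frac{du}{dt} = \tilde g_L\,(u-u_{rest})(u-u_{critical}) + I(t),$$

with a stable resting potential, an unstable critical potential above
which a spike is self-induced, a registration threshold
$\theta_{thres}$ at which $u$ is reset to $u_{rest}$, and an absolute
refractory period `t_ref` during which $u$ is held at rest.  Note the sign
convention: the quadratic term must be *positive* for
$u > u_{critical}$ (and for $u < u_{rest}$), so that rest is stable,
the critical potential is unstable, and a finite rheobase
$\tilde g_L\bigl((u_{critical}-u_{rest})/2\bigr)^2 = 0.1\ \mathrm{mA}$
exists; a transcription that negates the product instead makes rest
unstable and admits no firing threshold current.

**Network.**  $n$ neurons are coupled all-to-all without self-projections
through two independent directed weights per pair ($\omega_{ij}$ and
$\omega_{ji}$).  When neuron $i$ spikes, (i) each outgoing weight
$\omega_{ij}$ receives one plasticity event using $u_j$ as $V_{post}$, and
(ii) every neuron $j$ receives a rectangular current pulse

$$I^{int}_j = I_0^{int}\,
  \frac{\sum_{i \in \text{spiking}} \omega_{ij}}{\sum_i \omega_{ij}},$$

normalized by the *receiving* neuron's total incoming weight so that the
recurrent drive is bounded by $I_0^{int}$ however large the network.
External input is rate- or temporally-coded binary pixel patterns,
$I^{ext}_n = I_0^{ext} P_n$.

## Parameters and units

Internally all electrical quantities are SI; protocol clocks are in
milliseconds.  The defaults are:

| parameter | default | unit | role |
|---|---|---|---|
| $\theta_{thres}$ | 61.75 | mV | spike registration threshold |
| $u_{critical}$ | 9.00 | mV | unstable potential, self-induced spiking |
| $u_{rest}$ | −11.0 | mV | stable rest / reset potential |
| $C$ | 1 | mF | membrane capacitance |
| $\tilde g_L$ | 1 | A/V² | quadratic leak coefficient |
| $V_{critical}$ | 0 | V | LTP/LTD set point |
| $k$ | 1.21 | ms⁻¹ | learning-rate constant |
| $\kappa$ | 4.17·10⁻⁶ | ms⁻¹ | forgetting rate (0.417 %/s) |
| $\omega_{min}, \omega_{max}$ | 0.05, 1.00 | – | weight bounds |
| `tau_event` | 0.15 | ms | effective duration of one update event |
| `t_ref` | 6.44 | ms | absolute refractory period |
| $I_0^{ext}$ | 430.25 | mA | external drive per active pixel |
| $I_0^{int}$ | 2.4 | A | recurrent pulse amplitude (large networks) |

$V_{post}$ enters the learning rate as its numeric value in volts.  With
the voltage range of this neuron (±tens of mV) a single event then moves a
mid-range weight by $\sim 10^{-3}$, so that protocols of 25–60
repetitions produce the observed tens-of-percent changes; expressing
$V_{post}$ in millivolts would saturate the weight after a single spike
and reduce every graded response curve to a step.

**On the forgetting rate.**  Two unit readings of $\kappa = 4.17\cdot
10^{-3}$ circulate for this model family: per millisecond and per second
("0.42 % per second").  Only the per-second reading is dynamically
consistent with pair-frequency potentiation: at $4.17\cdot10^{-3}\,
\mathrm{ms^{-1}}$ a weight of 0.5 loses $\sim$25 % of its value between
two pairings at 6 Hz, two orders of magnitude more than a single
spike-driven gain, so no pairing frequency up to 60 Hz could ever
potentiate.  The package therefore uses
$\kappa = 4.17\cdot10^{-3}\,\mathrm{s^{-1}}$ as its default and exposes
`kappa` per experiment.

**Calibration.**  Two constants are not fixed by the parameter table and
were calibrated once, against the two quantitative anchor points of the
pair-frequency literature, using the closed-form QIF phase solution
$u(t) = p + q\tan(\tilde g_L q t/C + c_0)$:

* `t_ref = 6.44 ms` places the post-pre ($-10$ ms) LTD→LTP sign
  crossover at 40 Hz.  The crossover happens where the membrane has
  climbed exactly back to $V_{critical}$ 10 ms after a spike, which under
  period-matched drive is controlled almost entirely by the refractory
  hold; 2 ms, for instance, would put the crossover at 26.5 Hz.
* `tau_event = 0.15 ms` — about the width of an action-potential peak —
  balances the per-pairing gain against the 0.417 %/s leak so that
  pre-post ($+10$ ms) pairings below 2 Hz produce no net potentiation
  while 3 Hz and above do.

Neither constant was revisited afterwards; all protocol and network
results below use this one parameter set.

## Protocol realizations

**Voltage clamp.**  The post-synaptic potential is fixed while 25
pre-synaptic events are applied; the weight recurrence is evaluated
directly.  With the leak off the updates commute, so the pulse rate is
immaterial.  Results carry a second voltage axis shifted by −29 mV,
mapping the model frame $[-11, 61.75]$ mV onto the presentation frame
$[-40, 32.75]$ mV used for comparison with slice experiments.

**Pairings.**  The post neuron is driven by a constant current whose
free-running period equals the pairing period (found by bisection in
`current_for_rate()`); pre-synaptic spikes are imposed events that read
the post membrane at their arrival phase.  This realization is forced by
the rule itself: a post spike evoked by a brief suprathreshold pulse
would leave the membrane at rest ($-11$ mV) ten milliseconds before the
spike, so pre-post pairings could never potentiate.  Under sustained
drive the membrane ramps from reset through the slow passage near the
quadratic bottleneck into a depolarized upstroke, and the classic timing
window follows: pre shortly *before* post reads the positive upstroke
(LTP), pre shortly *after* post reads the reset (LTD).

One geometric consequence is worth knowing: at pairing periods below
$\sim\!16.7$ ms (above $\sim$52–60 Hz) a $+10$ ms-leading pre spike falls
within `t_ref` of the *previous* post spike — pre-post at 60 Hz is
post-pre at $-6.7$ ms — so the pre-post branch turns negative again at
the top of the frequency range.  This wraparound is a property of any
periodic pairing protocol, not of the learning rule.

## Network numerics

The engine (C++, with a step-identical plain-R reference implementation
cross-checked in the tests) advances all neurons with classical RK4 at a
fixed step (`dt = 0.05` ms by default; spike counts are step-size
independent down to 0.01 ms), holding the summed current constant within
a step.  Threshold crossings are resolved at step end.  Plasticity events
read the *start-of-step* membrane snapshot, taken before any reset in the
same step: updates are then order-independent when several neurons spike
together, and two co-spiking neurons see each other's pre-spike
depolarization (mutual LTP), which is the mechanism behind rate-coded
bidirectional connectivity.  Spikes propagate as rectangular internal
pulses of one integration step (the discretized delta pulse); the leak is
applied in closed form, lazily, between weight-touching events.

**Nine-neuron connectivity experiments run open-loop** (`I0_int = 0`).
The recurrent amplitude appropriate for the 1024-neuron associative
network would deliver $\sim I_0^{int} \cdot \omega_{ij}/\sum\omega$ over
only eight incoming weights — hundreds of millivolts per spike — so a
nine-neuron membrane would be driven far past threshold by every partner
spike and the network would synchronize, erasing exactly the
coding-dependent structure the experiment measures (simulated: the
temporal protocol then yields ~36 bidirectional pairs instead of the
eight-edge chain).  The frequency-resolved connectivity experiments set
firing rates through the *external* current, which is only meaningful
when recurrent drive is negligible.

**Temporal coding geometry.**  Sequence items start every 17 ms but are
stimulated for 34 ms each (two 60 Hz firing periods), and successive
sweeps are separated by a 34 ms quiescent gap.  The overlap is essential:
with non-overlapping 17 ms items a 60 Hz-driven neuron fires once at the
very end of its window while its successor still rests, no coincidence
between a leader's spike and a follower's depolarization ever occurs, and
every weight depresses.  With the two-period overlap the leader's second
spike lands $\sim$0.33 ms (stride minus period, $17 - 16.67$ ms) before
the follower's first, producing forward potentiation and backward
depression — an eight-edge unidirectional chain at the default census
threshold $(\omega_{min}+\omega_{max})/2 = 0.525$.  The inter-sweep gap
prevents the ninth, wraparound edge (last pixel → first pixel) that
contiguous cyclic presentation would create.

## Synthetic contour images

The scalable benchmarks train on synthetic 32×32 (configurable) binary
contour images: one-pixel-wide outlines of circles, regular polygons, or
smoothly deformed blobs, centered on the grid.  These emulate the
relevant features of edge-detected object photographs — a sparse, closed,
centered outline of a few dozen active pixels — and are reproducible from
a seed.  They do **not** emulate interior texture edges, varying contour
density, or natural-image statistics, so quantitative completion
thresholds (onset and perfect-completion cue fractions) obtained on them
are image- and scale-dependent and should be read qualitatively: onset
occurs well below perfect completion, and the binary completion curve
jumps abruptly, as expected of an attractor network.  An
`edge_detect()` path (4-neighbour intensity differences against a
threshold, then centering) is provided for user-supplied grayscale
images.

`completion_quality()` normalizes by an empirical `f_max`, measured as
the maximum rate among internally recruited neurons when the full pattern
is stimulated; a configurable override is available.  The binary
"completed" criterion is a rate of at least half of `f_max`; both the
quality curve and the thresholded completion fraction are reported, since
either may be plotted as "the" completion curve.

## Problem sizes

The shipped test-suite and examples run at desk scale by choice: single
synapses and nine-neuron networks at the published protocol lengths
(60 pairings, 7.2 s training splits into 19.2 ms windows), and 12×12 to
16×16 pixel networks (144–256 neurons) with 3.6–7.2 s of training for the
associative-memory properties.  The engine itself is size-agnostic; a
32×32 (1024-neuron) run with 7.2 s training and 72 s recall is a few
minutes of compute.

```{r example, eval = FALSE}
# the pair-frequency experiment, end to end
pf <- pair_frequency_curve(1:60, dt_pair_ms = -10, n_pairs = 60,
                           leak_mode = "off")
find_sign_crossover(pf)    # ~40 Hz
```

## Known limitations

* No conductance-based synapses, axonal delays, inhibition, or sparse
  connectivity; the recurrent pathway is the normalized current pulse
  above.
* Spike times are quantized to the integration step (no within-step
  threshold interpolation); protocol timescales are $\gg$ `dt`, so this
  only shifts pairing phases by at most one step.
* The pairing drivers exploit the periodicity of the driven post neuron
  (one phase-locked period is simulated per frequency); aperiodic pairing
  schedules would need the full network engine instead.
* Device-level memristive physics (conductance bounds, ion migration,
  I–V characteristics) is outside the abstraction: the weight *is* the
  normalized conductance.
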
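---
title: "Activity-gated (duplex) Izhikevich simulation: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-gated (duplex) Izhikevich simulation: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexneuron)
```

## The model and the gating idea

The Izhikevich neuron is a two-variable phenomenological spiking model,

$$\dot v = 0.04 v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with the hard after-spike rule: if $v > 30$ mV then $v \leftarrow c$,
$u \leftarrow u + d$. The package integrates it by forward Euler at
`dt = 1/32` ms (the conventional step for digital implementations of this
model; overridable).

A spiking neuron spends most of each cycle in a *quasi-static* (QS) phase
where $v$ barely moves, and only a small fraction in the *firing state*
(FS) where the upstroke happens. The duplex stepper exploits this: it caches

$$\alpha = 0.04 v^2 + 140 - u, \qquad \beta = a(bv - u),$$

and recomputes them only when the magnitude of the previous step's voltage
increment exceeded a threshold $\delta$. Every step then advances

$$v_{n+1} = (\alpha + 5 v_n + I_n)\,dt + v_n, \qquad
  u_{n+1} = \beta\,dt + u_n.$$

The $5v$ term stays outside the cache, so the linear leak always tracks
$v$; only the quadratic term and the recovery right-hand side are frozen.
The payoff is the *computation-saving percentage* (CSP): the fraction of
steps at which $\alpha,\beta$ were not recomputed. In hardware the cached
path also skips the squaring unit, the slowest element of the data path.

### Gate-timing convention

A literal reading of the gating rule compares $|v_{n+1} - v_n|$ — an
increment that does not exist until after the step. The package resolves
this as the hardware data path does: the increment computed at step $n$
gates the recomputation used at step $n+1$, and the first step always
recomputes (cold cache). Ties ($|\Delta v| = \delta$) skip. Two
consequences worth knowing:

* At a spike the (pre-reset) increment is large, so the cache is always
  refreshed on the step after a reset.
* `delta = 0` disables gating outright rather than gating on
  $|\Delta v| > 0$. In floating point the two are indistinguishable in
  practice, but in fixed point a step increment can be *exactly* zero, and
  a strict gate at zero would then silently diverge from the full stepper.
  With the chosen semantics the $\delta = 0$ duplex trajectory is
  bit-identical to the full one, in both arithmetics.

### Degenerate inputs

The model has a genuine unstable equilibrium (for the tonic set at $I=0$ it
sits at $v=-60$, $u=-12$); started exactly there, neither stepper ever
fires and the duplex gate never opens. This is a property of the
differential equations, not an artifact. Note also that a *permanently*
closed gate is linearly unstable ($v_{n+1} = (1 + 5\,dt)\,v_n + \dots$), so
pathologically large $\delta$ values eventually reopen the gate no matter
how large; the gate is self-correcting.

Non-finite states or currents abort immediately with the offending step
index rather than propagating NaNs.

## Error metrics and their conventions

Three quantities compare a duplex run against the unmodified reference
under the standard protocol (tonic parameters `a=0.02, b=0.2, c=-65, d=6`,
$I = 4$, `dt = 1/32` ms, 20 s):

* **Timing error (TE)** — relative difference of steady-state inter-spike
  intervals, $100\,|\Delta t_{un} - \Delta t_{dx}|/\Delta t_{un}$. The
  steady interval is the last complete interval of the run after
  discarding the first spike; transients differ between steppers, the
  steady period does not (`steady_isi()`).
* **NRMSD** — RMS voltage difference normalized by the reference range.
  The plain pointwise form (`nrmsd()`) is exported, but for long spiking
  runs it is dominated by spike-phase drift: with TE up to 23 % the two
  upstrokes desynchronize and the pointwise value saturates near 9 %
  regardless of $\delta$, measuring timing (already captured by TE) rather
  than wave shape. The reported quantity (`shape_nrmsd()`) therefore
  compares *period-normalized* spike shapes: each steady-state interval of
  the gated trace is linearly resampled onto the duration of the
  corresponding reference interval, pointwise NRMSD is computed per period
  with the reference extremes as the denominator, and the mean over all
  complete steady-state periods is reported. This isolates the shape
  distortion the cached-term approximation introduces (small oscillations
  in the QS segments) from the spike-rate change.
* **CSP** — `100 * (steps - recomputations) / steps`, identical by
  definition to the fraction of quasi-static flags in the trace
  (`qs_fraction()`); the identity is asserted in the tests.

Under this protocol `duplex_sweep()` reproduces the reference error table
the acceptance suite checks against closely: TE to within 1 % of value
across the whole grid and shape-NRMSD to within ~0.15 points, with CSP
matching to ≤ 2 points everywhere except $\delta = 0.005$ mV, where the
gated limit cycle this implementation converges to skips 67 % of steps
against a reference 58 %. The discrepancy is robust to initial conditions
(the steady state is a limit cycle) and to every alternative gate-timing
convention we enumerated; the agreement of TE at the same $\delta$
(1.85 vs 1.87 %) indicates the trajectory itself is right, and the
residual difference lies in a measurement-loop detail that cannot be
recovered from the reference values alone.

**Speed-up.** Wall-clock speed-up is hardware- and language-specific, so
the package reports an operation-cost speed-up instead:
$100\,(T_{un}-T_{dx})/T_{un}$ (positive = duplex faster) with $T$ the
weighted operation count of the run under the data-path cost model below.
The sign convention follows the definition in which a positive value means
the modified model is faster; the opposite operand order, which flips the
sign, is not used.

## The fixed-point engine

The hardware word is Q16.14: 30 bits, 14 fractional (`fx_format()`).
Raw payloads are carried exactly in doubles (well under $2^{53}$).
Conventions, chosen once and used everywhere:

* Quantization rounds to nearest, half away from zero rounding up
  (adder-plus-floor hardware idiom); error ≤ half ULP ($2^{-15}$).
* Overflow saturates to the rails and flags the result, as hardware does;
  a strict mode raises instead (used in tests).
* Constant multiplication is shift-add: a greedy ≤ 3-term binary expansion
  $\sum 2^{-s}$ with sign-preserving arithmetic *right* shifts (negative
  entries are left shifts, for constants above one). The greedy expansion
  of 0.04 is $2^{-5} + 2^{-7} + 2^{-11} = 0.0395508 \approx 0.0396$, the
  canonical decomposition for this data path; 5 and `dt = 1/32` are exact
  ($4+1$ and a single shift). `fx_constant_report()` tabulates all of
  them with relative errors (≤ 2.4 %).
* Squaring is linear-mode CORDIC: pre-scale $x$ by $2^{-e}$ into $[-1,1]$,
  run z-driven micro-rotations $z \leftarrow z - d_i 2^{-i}$,
  $y \leftarrow y + d_i m 2^{-i}$, and re-apply the scaling squared. Two
  extra iterations per scaling octave compensate the $4^e$ error
  amplification, giving the clean bound
  $|y\,4^e - x^2| \le |x|\,2^{-n_{iter}}$ (before output quantization)
  that the tests sweep. Default $n_{iter} = $ `frac_bits + 2` $= 16$.
* The recurrence runs on exact dyadic doubles; only the result is
  quantized, so runs are bit-reproducible.

One consequence of the constant approximation deserves a flag: with
$0.0396 v^2 + 4.805 v + \dots$ the saddle-node bifurcation moves from
$I = 4$ to $I \approx 5.7$, so the fixed-point neuron does not fire at the
simulation drive $I = 4$. Fixed-point demonstrations therefore use
$I = 16$, a drive comfortably above both rheobases. For the
divergence check ("30 bits suffice") the float reference is the *twin*
model (`fx_float_twin()`): the same shift-add constants in double
precision with exact squaring. Comparing against the exact-constant float
model would conflate the constant-approximation error — a property of the
decomposition, reported separately — with the arithmetic error actually
attributable to the word length. Against its twin the Q16.14 trajectory
stays within 1 mV RMS over a steady spike period at every tested $\delta$.

**Cost model.** Each step's operations are counted per mode: a QS step
costs the always-executed path (the $5v$ shift-add, three adds, two `dt`
shifts, the increment subtraction, gate and reset comparators); an FS step
adds the CORDIC iterations and the $\alpha,\beta$ register updates.
Default weights: add = 1, compare/mux = 1, CORDIC iteration = 1, shift = 0
(routing). `energy_proxy()` divides the weighted total by the spike count —
a software stand-in for dynamic-power × time per spike, strictly
decreasing in the number of QS steps.

## The two demonstration networks

### 1,000 randomly coupled neurons

`random_network()` follows the classic recipe: 800 excitatory neurons
interpolated toward bursting by squared uniform deviates, 200 inhibitory
interpolated toward fast spiking, dense weights ($0.5\,U(0,1)$ excitatory,
$-U(0,1)$ inhibitory, Dale-consistent, self-connections allowed), noisy
thalamic drive (SD 5 / 2). Integration uses a single Euler step at
`dt = 0.5` ms, with the noise drawn once per millisecond and synaptic
delta-currents delivered on the recipe's 1-ms event frame (spikes
aggregated over the previous millisecond drive the next one). With these
defaults — fixed before any test was written — the fraction of neurons
with 6–24 spikes in a 1-s run is 0.89–0.91 across seeds, the "almost 90 %"
regime, and the raster shows the familiar alpha/gamma-like synchronized
columns.

### The 42–7–1 pattern recognizer

A feed-forward network of identical regular-spiking neurons discriminates
two 7 × 6 binary glyphs ("E", 18 active pixels; "H", 18, overlapping E in
10). No standard constant set exists for this protocol, so every constant
here is designed from first principles and frozen; the reasoning, since it
explains most defaults:

* **Volley arithmetic.** Input neurons driven at `i_on = 10` fire their
  first spike ~3.5 ms into a presentation, synchronously (identical
  neurons, identical drive). A synchronous volley through weights $w$
  kicks a postsynaptic neuron by $\approx n_{active}\, w\, dt$ mV. A
  single-step kick of ~16 mV from rest crosses threshold; E delivers
  $18w/32$ and H $10w/32$ through trained synapses. The layer-1→2 bound
  `w12_bounds = c(0, 36)` puts a trained E volley at ~20 mV (fires) and a
  trained-overlap H volley at ~12.6 mV (decays): the discrimination margin
  is ±3 mV on both sides. The output layer integrates only 7 synapses, so
  its bound scales up accordingly (`w23_bounds = c(0, 160)`); a single
  bound pair for both layers cannot satisfy both fan-ins.
* **Teacher.** Initial weights ($U(0.05, 0.25)$ of the range) are too weak
  to fire anything, so training injects a teacher current of 5 — just
  above the model's rheobase of 4 — into hidden and output neurons while
  the stimulus is on. Teacher-primed neurons fire a few ms after the
  afferent volley, which makes the pairing *causal*: pre-before-post, so
  pair-based STDP (amplitudes 0.05/0.055 of the weight range, both traces
  τ = 20 ms, all-to-all) potentiates exactly the synapses from active
  pixels. Synapses from silent pixels never see a presynaptic spike and
  keep their small initial weights; the E-trained network is silent for H
  without needing explicit depression of the off-pattern synapses.
* **Recovery-limited pacing.** The recovery variable decays with
  $1/a = 50$ ms. With short gaps $u$ ratchets upward across
  presentations, the effective threshold rises, and the output goes
  silent after the first test pattern; with gaps much longer than 60 ms
  the second within-presentation volley shifts the potentiation/depression
  balance and training stalls. The presentation cycle is therefore 40 ms
  on + 55 ms gap, the middle of the working basin (50–60 ms) measured for
  this protocol.
* **Training length.** 40 E-presentations saturate the pattern synapses
  with the full stepper; the duplex stepper at $\delta = 1/8$ mV changes
  spike latencies enough to slow the causal pairing, so the default is 60
  presentations, which saturates both. Trained either way, the output
  spikes once per E presentation and never for H, on all of seeds 1–10.
  Testing a duplex network with weights *transferred* from full-stepper
  training is the interesting failure mode on hardware; in this software
  model the transfer happens to survive at $\delta = 1/8$, so the
  corresponding property is asserted as retrained-at-least-as-good-as-
  transferred rather than as a strict failure reproduction.

What the generator does *not* emulate: synaptic delays and conductance
dynamics, neuron heterogeneity within a layer, noisy test stimuli, and any
form of homeostasis. Discrimination here rests on volley synchrony of
identical neurons, which is the cleanest regime for studying what the
duplex approximation does to timing-sensitive learning — but a network
that discriminates these glyphs says nothing about recognition of noisy
or shifted patterns.

## Problem sizes and reproducibility

The test suite and the acceptance script use the protocol sizes the
results are defined on: 20-s single-neuron runs (640,000 steps; ~0.15 s
each in the compiled core), the full 1,000-neuron network for 1,000 ms
(ten seeds), and complete train/test cycles of the layered network. The
whole suite runs in well under a minute. Experiment runners
(`run_experiment()`) derive per-component substreams from one master seed,
embed the seed and resolved configuration in every `summary.json`, and
produce byte-identical outputs on repeated runs.

## Known limitations

* The CSP mismatch at $\delta = 0.005$ mV discussed above.
* The operation-cost speed-up model counts abstract data-path operations;
  it orders and scales like, but does not predict, cycle counts or watts.
* Pattern-network conclusions are protocol-specific by construction;
  other constant sets can move the discrimination margins.
* Only signed fixed-point formats up to 48 bits are supported, and `dt`
  must be a power of two in fixed point (it is a bare shift in the data
  path).
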
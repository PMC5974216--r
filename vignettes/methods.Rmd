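---
title: "Methods: dual-backend LIF simulation and accuracy benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-backend LIF simulation and accuracy benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifbench)
```

## The model

`lifbench` simulates current-based leaky integrate-and-fire (LIF) neurons
with exponentially decaying synaptic currents,

$$\tau_m \frac{dV_i}{dt} = -(V_i - E_L) + R_m I_i(t), \qquad
  \tau_s \frac{dI_i}{dt} = -I_i + \tau_s \sum_j J_{ij}\, s_j(t - d_j),$$

where each presynaptic spike makes the synaptic current jump by $J_{ij}$
after a transmission delay $d_j$.  When $V_i$ reaches the threshold
$\theta$ a spike is emitted and the membrane is clamped to $V_r$ for an
absolute refractory period $\tau_{ref}$.  The default parameters are the
standard cortical-microcircuit values ($\tau_m = 10$ ms, $\tau_s = 0.5$ ms,
$\tau_{ref} = 2$ ms, $R_m = 40$ M$\Omega$, $E_L = V_r = -65$ mV,
$\theta = -50$ mV).

The purpose of the package is not simulation per se but *cross-validation
of simulators*: the same model is integrated by a high-accuracy reference
scheme and by an emulation of digital neuromorphic hardware, and the
differences are quantified at the single-neuron and network level.

## The four backends

**exact-grid.** The subthreshold system is linear, so its one-step solution
is closed-form: with $\alpha = e^{-h/\tau_m}$, $\beta = e^{-h/\tau_s}$ and
$P_{21} = R_m \tau_s (\beta - \alpha)/(\tau_s - \tau_m)$, the update
$I' = \beta I$, $V' = E_L + (V - E_L)\alpha + I\,P_{21}$ is the analytical
solution sampled at the grid.  Spikes are constrained to grid points.  The
degenerate case $\tau_s = \tau_m$ is a removable singularity handled by its
analytic limit $P_{21} = R_m (h/\tau_m)\alpha$.

**exponential-grid.** The separated ("exponential") scheme treats the
synaptic current as piecewise constant within a step:
$I' = \beta I + q\,w$, $V' = E_L + (V - E_L)\alpha + R_m I'(1 - \alpha)$.
Two readings of the input scaling $q$ conflict for finite $h$: decaying
the weight over one step before adding it ($q = \beta$) versus the
requirement that the total charge transferred per synaptic event equal
$J\tau_s$.  The charge statement is the testable contract, so the default
is $q = \tau_s(1-\beta)/h$, which makes
$h\sum_k I_k = h\,Jq/(1-\beta) = J\tau_s$ exact; `scheme = "decay_then_add"`
selects the literal reading.

**exponential-fixed.** The hardware emulation: neuron state in signed
s16.15 fixed point (value $= \lfloor x\,2^{15}\rfloor / 2^{15}$;
multiplication truncates a 64-bit product back to 15 fractional bits;
addition saturates at the 32-bit bounds and saturations are counted), and
synaptic weights in an unsigned 16-bit format whose binary point is chosen
per target population (below).  Truncation direction is floor — the only
rule consistent with the three worked representation examples
(0.0878 nA $\to$ 0.0869140625 at 10 fractional bits, 0.0859375 at 9,
0.087799072265625 at 16).  One deliberate exception: *constants* (the
propagator entries $\alpha, \beta, q$, $R_m(1-\alpha)$, thresholds, DC
values) are converted with round-to-nearest, as a compiler converts
literals.  With floor'd constants the backend acquires a systematic
downward rate drift; with rounded constants it tracks the float backend to
within one step for the large majority of spikes (93–98% on the
single-neuron protocol settings).  Full within-one-step agreement is not
attainable: threshold crossing is a first-passage event, and a $3\times
10^{-5}$ mV state difference can move a grazing crossing by several steps.

**precise.** The reference for all accuracy measures: inputs stay on the
grid, but within each step the closed-form solution is evaluated
continuously and the earliest threshold crossing is located by scanning
and bisection to a configurable tolerance (default $10^{-9}$ ms), so spike
times are not quantized to the grid.  Refractoriness is continuous
($t^* + \tau_{ref}$).

All grid backends share a fixed per-step order — (1) propagate/decay,
(2) add due input, (3) threshold test ($V \ge \theta$), (4) record — which
makes runs bit-reproducible and lets other implementations match them.
The exact scheme folds the delivered weight into $I$ *after* the $V$
update (the current affects $V$ from the next step on), the exponential
scheme before; this one-step phase offset is absorbed by the charge
contract, and spike-for-spike replication of any specific simulator is not
claimed.

## Network engine

Synapses are instantiated by drawing source and target *with replacement*
(multapses are legal); the synapse count reproducing a pair-connection
probability $p$ is $K = \mathrm{round}(\ln(1-p) / \ln(1 - 1/(N_{pre}
N_{post})))$.  Weights are Normal with the sign applied afterwards (draws
crossing zero are clipped to zero — the sources are silent on this;
clipping is deterministic and cheap, and at $\mu/\sigma = 10$ it affects
$\sim 10^{-24}$ of draws).  Delays are Normal, clipped below at the step
and rounded to the grid.  Initial membrane potentials are uniform on
$[V_r, \theta)$ — a distribution had to be chosen; uniform over the
subthreshold range is the common neutral choice.  Every random draw comes
from a named substream of the master seed (`derive_seed()`), so a single
projection can be re-instantiated bit-exactly.

Delivery uses per-neuron, per-type (excitatory/inhibitory) unsigned
accumulators, mirroring the 2-bit synapse-type field of the 32-bit packed
synapse word (8 target bits, 4 delay bits, 2 type bits, 2 reserved, 16
weight bits).  The hardware's 16-slot ring buffer limits direct delays to
16 steps (1.6 ms at $h = 0.1$ ms); longer delays are split as
$d_{ext} = 1.6\,(\lceil d/1.6 \rceil - 1)$ ms handled by an extension
stage, remainder in $(0, 1.6]$ ms — an exact multiple takes the maximal
remainder because a zero remainder is undeliverable.  Up to 8 extension
multiples are supported, so 12.8 ms of extension and 14.4 ms total.  The
engine implements the buffer as a circular array over max-delay-plus-one
elements indexed by delivery step; because every addition to an element
occurs within the 16 steps before its delivery and the element is zeroed
when read, values and saturation clamping are equivalent to a rotating
16-slot buffer chained with extension stages (only the order of saturating
adds within one element is unspecified, in the hardware description as
well).

### Weight scaling (dynamic binary point)

For each (target population, synapse type), the expected maximum
ring-buffer element value is bounded by a compound-Poisson model: $n$
spikes per step on average with weight mean $w_{mean}$ and variance
$w_{var}$,

$$v_r = n w_{mean}^2,\quad U = \mathrm{round}(n + 3\sqrt{n}),\quad
  v_w = e^{-n} n w_{var}\,
        \frac{-n^U + e^n\,\Gamma_{inc}(1+U, n)}{\Gamma(1+U)},\quad
  M = n w_{mean} + \sigma\sqrt{v_r + v_w},$$

with $\sigma = 5$ by default.  Two notational ambiguities are resolved
here: the bound is printed without a radical ("$\sigma v_r + v_w$"), but
$\sigma$ is described as a number of standard deviations, so
$\sigma\sqrt{v_r + v_w}$ is implemented; and $\Gamma_{inc}$ is read as the
*non-regularized* upper incomplete gamma, because only then does
$v_w \to n\,w_{var}$ (the compound-Poisson variance) as $U \to \infty$ —
both choices are regression-tested.  Numerically $v_w$ is evaluated in log
space via the regularized upper gamma, immune to $n^U$ overflow.  The
weight format then takes the smallest integer-bit count $i$ with
$2^i - 1 \ge M$ and $16 - i$ fractional bits; $M = 0$ yields the (0, 16)
single-neuron test format.

## Accuracy statistics

*Single neuron* (discrete backend vs. precise reference, same input
realization): cross-correlation histogram of all spike-time differences at
bin width $h/2$ (window $\pm 5$ ms by default — a window is shown but not
stated in the sources, so it is configurable); Pearson correlation of the
membrane traces at the grid points; accumulated fractional lead/lag
$[t_{disc}(N) - t_{prec}(N)]/t_{disc}(N)$ over the first $N = \min$ spikes
(negative = the discrete backend fires early); and the RMSE of spike times
after warping the discrete train by $t_{prec}(N)/t_{disc}(N)$ so the last
considered spikes coincide — a pure rate difference therefore gives zero.

*Network* (per population, analysis window discards a 1 s transient):
single-neuron rates including silent neurons as zero; CV ISI (sd/mean of
interspike intervals, neurons with $\ge 2$ intervals — the inclusion rule
for nearly silent neurons had to be fixed here); and Pearson correlations
of spike trains binned at 2 ms from all 19,900 disjoint pairs of a seeded
200-neuron subsample, zero-variance trains excluded with a count.

Distributions are compared by $D_{KL}(P\|Q)$ with $P$ the reference:
histogram bins from the Freedman–Diaconis rule ($2\,\mathrm{IQR}\,
n^{-1/3}$, interpolated quartiles) on the *reference* samples; both sample
sets smoothed by Gaussian KDE with an *absolute* kernel standard deviation
(0.3 s$^{-1}$ for rates, 0.04 for CV ISI, 0.002 for correlations — the
printed bandwidths carry units; a `scaled` flag provides the
covariance-factor semantics of the usual scipy-style KDE); bins where
either normalized density falls below $10^{-15}$ are ignored.  Whether to
renormalize after exclusion is unspecified; the unrenormalized value is
primary and the renormalized one (guaranteed non-negative) is also
reported.

The seed-sensitivity protocol runs the reference backend with three seeds,
takes the mean of the KL divergences from run 1 to runs 2 and 3 as the
seed-only baseline, and compares each alternative backend (own seed)
against run 1 — method differences thus *include* seed effects, matching
the design whose conclusion is that the two are comparable in size.

## The synthetic microcircuit

The full-scale cortical microcircuit's connectivity matrix belongs to its
own model paper and is treated as user configuration.  For self-contained
testing the package ships a clearly labelled **synthetic** eight-population
layered network (`synthetic_microcircuit()`): four layers, E and I
populations (76,250 neurons at full scale), with the standard weights
(87.8 ± 8.78 pA excitatory, 175.6 ± 8.78 pA for the 4E→2/3E feedforward
projection, 351.2 ± 35.21 pA inhibitory) and delays (1.5 ± 0.75 ms /
0.75 ± 0.375 ms, truncated at the step).  The probability matrix is
invented by rule: within-layer recurrence 0.10–0.12, excitatory projections
to adjacent layers 0.04 and elsewhere 0.01, inhibition layer-local with
probabilities (0.22, 0.20, 0.40, 0.25) chosen so each excitatory
population's inhibitory in-weight exceeds its excitatory in-weight
(inhibition-dominated balance).  External drive is homogeneous Poisson
(11,400 spikes/s onto E, 8,900 onto I at 87.8 pA) or its DC mean-current
equivalent $I_{DC} = \nu_{ext} J_{ext} \tau_s$ (0.500 / 0.391 nA).  The
drive levels were calibrated **once**, before any acceptance measurement,
so that the default desk-scale (10%) DC-driven instance is asynchronous
irregular — every population active (3–31 spikes/s), mean pairwise
correlations below 0.05 — and then frozen.

What a green desk-scale test does and does not establish: at 10% scale the
in-degrees are one tenth of the full-scale model's, so the network is more
mean-driven, less fluctuation-dominated, and relatively more sensitive to
synchrony events than the full-scale circuit.  The KL comparison protocol
and its conclusion transfer; absolute rates, CVs and the ring-buffer
overflow behaviour do not.  In particular, the full-scale observation that
$\sigma = 5$ weight scaling eliminates ring-buffer overflows **fails** at
desk scale: with in-degrees near 100, several inhibitory buffers get a
bound $M$ just under 1 nA (one integer bit, 2 nA capacity), while
occasional synchrony volleys — a few percent of an inhibitory population
in one 0.1 ms step — drive single elements to ~3.5 nA.  This is exactly
the documented caveat for synchronous input; the corresponding acceptance
test is deliberately left failing with this analysis rather than weakened
(state-arithmetic saturations, by contrast, are zero and asserted so).

## Cost model

The hardware design point allocates 20,000 CPU cycles per 1 ms step for
neural updates (10%) and 180,000 for synapse processing (90%) at 1,000
synapses per neuron and a 200 MHz clock.  Required cycles per biological
millisecond are $20{,}000/h_b + 180{,}000\,(s/1{,}000)$ for $s$ synapses
per neuron; at $h_b = 0.1$ ms and $s = 10{,}000$ this is 2,000,000
cycles/ms, a theoretical slowdown factor of
$\lceil 2{,}000{,}000/200{,}000\rceil = 10$.  Practical factors (20 in the
measured system) include overheads and enter manifests as configured
constants, never computed ones.  Packet pacing spreads at most $n$ sends
over a fraction of the step: $\lfloor \mathrm{cycles} \cdot
\mathrm{fraction} / n \rfloor$ cycles between packets (200 for 100 packets
over a full 20,000-cycle step; 100 over half).

## Numerical choices and degenerate inputs

* Bisection tolerance for off-grid crossings: $10^{-9}$ ms default; the
  crossing scan uses 64 subintervals, sufficient because the subthreshold
  trajectory has at most one interior maximum over a step.
* Refractoriness: integer $\mathrm{round}(\tau_{ref}/h)$ steps on grid
  backends (grid semantics must be $h$-exact), continuous end time on the
  precise backend.  No backend can emit two spikes closer than
  $\tau_{ref}$.
* Ties at threshold: spiking uses $V \ge \theta$.
* FD binning with zero IQR falls back to Scott-like sizing, then to a unit
  bin.
* `split_delay` rejects delays below one step or above $9 \times 16\,h_b$.
* Empty spike trains: CCH returns an all-zero histogram; lead/lag and RMSE
  report missing values.
* Degenerate $\sigma_w = \sigma_d = 0$ projections produce exactly the
  mean weight and the grid-rounded mean delay.

## Known limitations

* The engine models the no-spike-loss regime only; dropped-packet
  emulation, routing tables and board/chip placement are out of scope.
* Desk-scale runs do not reproduce full-scale emergent properties (see
  the synthetic-microcircuit section); the full-scale network is
  accepted as external configuration but is not exercised by the test
  suite.
* The fixed-point backend emulates numerics, not instruction-level
  behaviour of any particular CPU.
* Power and energy measurement are out of scope by design.
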
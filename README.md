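# lifbench

Dual-backend simulation of leaky integrate-and-fire (LIF) neural networks
and the statistic suite needed to cross-validate simulators against a
high-accuracy reference — the comparison methodology used when porting a
full-density cortical microcircuit model from simulation software to
digital neuromorphic hardware.

**Who it is for.** Computational neuroscientists and neuromorphic
engineers who need to answer: *if I run the same spiking network on a
fixed-point, piecewise-constant-current hardware backend instead of a
double-precision exact integrator, how much do the results change — and is
that change larger than the effect of the random seed?*

## What is inside

* **LIF core** — exact propagation of the subthreshold system
  (`I' = βI`, `V' = E_L + (V−E_L)α + I·P21` with `α = e^(−h/τ_m)`,
  `β = e^(−h/τ_s)`, `P21 = R_m τ_s (β−α)/(τ_s−τ_m)`), separated
  ("exponential") integration with the charge contract `∫I dt = Jτ_s` per
  synaptic event, off-grid threshold crossing for precise spike times, and
  an s16.15 fixed-point emulation with 16-bit quantized weights.
* **Network engine** (Rcpp) — with-replacement connectivity with
  multapses, normal weight/delay draws, Poisson or DC external drive,
  16-slot delay ring buffers with saturation counting, delay extension
  (up to 12.8 ms extension, 14.4 ms total at h = 0.1 ms), 32-bit packed
  synapse words, and a CPU-cycle cost model
  (`cycles/ms = 20000/h_b + 180000·s/1000`, slowdown = ⌈cycles/clock⌉).
* **Weight scaling** — the closed-form compound-Poisson bound
  `M = n·w_mean + σ·sqrt(v_r + v_w)` on ring-buffer element values, and
  the dynamic binary-point allocation it implies.
* **Accuracy statistics** — cross-correlation histograms at h/2 bins,
  membrane-potential Pearson correlations, accumulated spike-time
  lead/lag, warped RMSE; population firing-rate / CV ISI / pairwise
  correlation distributions compared by Kullback–Leibler divergence on
  Freedman–Diaconis grids after Gaussian-kernel smoothing, with a 1e-15
  low-probability floor.
* **Workbench** — seeded grid-Poisson generators, a synthetic
  eight-population layered microcircuit for desk-scale benchmarking, TSV
  and JSON I/O, protocol orchestration, and CLI scripts under
  `inst/cli/`.

## Worked example

Drive one LIF neuron (τ_m = 10 ms, τ_s = 0.5 ms, θ = −50 mV) with
grid-constrained Poisson input at 10,000 spikes/s and 87.8 pA weights for
4 s, and compare the grid-based and hardware-emulation backends with the
precise (off-grid spike time) reference:

```r
library(lifbench)
p <- neuron_params()
input <- generate_grid_poisson(10000, h = 0.1, duration = 4000, seed = 42)

precise <- run_single_neuron(p, "precise", input, h = 0.1)
grid    <- run_single_neuron(p, "exact-grid", input, h = 0.1)
fixed   <- run_single_neuron(p, "exponential-fixed", input, h = 0.1)

report_g <- compare_single(precise, grid, h = 0.1)
report_f <- compare_single(precise, fixed, h = 0.1)
```

This prints (seed 42):

```
n spikes (precise/grid/fixed): 181 / 181 / 181
grid  : r = 0.94677, lead/lag = +5.86e-05, warped RMSE = 0.4921 ms
fixed : r = 0.96719, lead/lag = +3.36e-05, warped RMSE = 0.4725 ms
```

Read: both discrete backends fire 181 spikes (about 45 spikes/s, matching
the ~47 spikes/s operating point of this protocol); membrane traces
correlate with the reference at r ≈ 0.95–0.97; the positive lead/lag
fractions say both backends accumulate a slight *lag* (grid spikes round
up to the next grid point), a few hundredths of a percent of elapsed time;
and after removing that accumulated rate difference the residual spike-time
scatter is about half a millisecond, i.e. a handful of 0.1 ms steps.

Desk-scale network benchmarking, e.g. the seed-vs-method protocol on the
synthetic microcircuit at 10% scale:

```r
spec <- scale_network(synthetic_microcircuit("dc"), 0.1)
res  <- seed_sensitivity_protocol(spec,
          test_backends = c("exponential-grid", "exponential-fixed"))
seed_sensitivity_summary(res)
```

which reports the median KL divergence per comparison; the package's
acceptance suite checks that the method-induced divergence stays within a
factor 5 of the seed-induced baseline.

## CLI

`inst/cli/` ships `simulate-neuron.R`, `simulate-network.R`,
`compare-single.R`, `compare-network.R`, `seed-sensitivity.R` and
`cost-report.R`; each accepts `--seed`/`--out` style options, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","simulate-network.R",package="lifbench"))')" \
  --drive dc --scale 0.05 --backend exponential-fixed --duration-ms 1000 \
  --seed 1234 --out runs/
```
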
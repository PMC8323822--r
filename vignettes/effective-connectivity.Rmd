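---
title: "Reconstructing effective connectivity from spike trains: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing effective connectivity from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effconn)
```

# Scope

`effconn` turns multi-neuron spike trains into a directed graph of
effective — direct and causal — connections. This vignette documents the
statistical model and its assumptions, every tunable parameter with its
units and default, the synthetic data generator used for validation, the
numerical choices that are not forced by the mathematics, and the known
limitations. It is the design record of the package: where a decision was
genuinely open, the reasoning is given here.

# The reconstruction model

## Pairwise temporal correlations

The activity of neuron $j$ is discretised into counts $s_j(t)$ on a lag
grid of width `dt` (default **0.1 ms**, well below every delay scale of
interest). The linear cross-correlogram

$$R_{jk}(\tau) = \sum_t s_j(t)\, s_k(t+\tau)$$

counts spike pairs at signed lag $\tau$; a peak at $\tau > 0$ means $j$
leads $k$. Correlation is *linear* (zero-padded), never circular: circular
wrap-around would alias late spikes into negative lags. Only unordered
pairs $j < k$ are computed, since $R_{jk}(\tau) = R_{kj}(-\tau)$. The
package computes correlograms either via the FFT correlation theorem
(`cross_correlation()`) or, in the pipeline, by a sparse lag-histogram in
compiled code that exploits the sparsity of spike trains; the two paths are
identical to floating-point tolerance and are cross-checked in the test
suite.

## Smoothing and peak detection

$R_{jk}$ is convolved with a unit-area Gaussian kernel of standard
deviation $\sigma$ (truncated at $\pm 4\sigma$; a kernel narrower than one
grid step degenerates to the identity; edges are padded by replication so
constants are preserved). Local maxima inside the open search window
$(-T, +T)$ become candidate peaks. Two criteria must hold:

* **Relative prominence.** The topographic prominence (height above the
  higher of the two flanking saddles) must reach `min_prominence_frac`
  (default **0.2**) of the window's dynamic range. The default is the
  smallest value at which noise-free motif fixtures yield exactly their
  true peaks while flat windows yield none.
* **Counting-statistics significance.** A smoothed count correlogram value
  with mean $\lambda$ has approximate variance $\lambda \sum_i k_i^2$ for
  kernel weights $k_i$ (Poisson counts, linear filter). A peak's prominence
  must exceed `noise_z` (default **4**) such standard deviations,
  $z\sqrt{A \sum_i k_i^2}$. This keeps chance coincidences out without
  penalising peaks that ride on the broad pedestal produced by network
  bursts. A flank-based amplitude floor (mean + z·sd over $|\tau| > T$) was
  evaluated and rejected: burst shoulders inflate the flank statistics and
  suppress every peak after strong smoothing.

Each accepted peak is recorded with its lag $\tau$, amplitude (value at the
maximum), prominence, and full width at half prominence (linearly
interpolated on the lag grid). Peaks at exactly $\tau = 0$ are retained —
they represent apparent synchrony and participate in the triangle
arithmetic — but they are direction-less and never become edges.

## Correlation triangles and the super-selection rule

For every neuron triplet $\{j,k,m\}$ whose three pairs all carry peaks,
every combination of one peak per pair forms a cyclic *correlation
triangle* with closure $|\tau_{jk} + \tau_{km} + \tau_{mj}|$ (a stored peak
of the reversed pair enters with negated lag). A closure strictly below the
threshold $\varepsilon$ flags the triangle: one of its three delays is the
combination of the other two, i.e. one peak reflects an indirect pathway or
a common-input/common-output artifact rather than a synapse. Within each
flagged triangle the peak of **minimum amplitude** is discarded — along an
indirect path the postsynaptic timing jitter of each hop accumulates, so
the resulting correlation peak is lower and wider than the direct ones.

Processing order matters when triangles overlap, and is fixed for
determinism: flagged triangles are handled in ascending closure (most
exact violations first), ties broken lexicographically; a triangle is
skipped if any of its peaks is already gone, so at most one peak per
triangle is removed per pass; passes repeat on re-enumerated survivors
until nothing changes. Amplitude ties (possible on noise-free fixtures)
fall to the widest peak, then the largest $|\tau|$, then the
lexicographically last pair — wider and later is more indirect. Removed
peaks stay in the result as an audit trail (`removed`, `removal_reason`),
exportable with `write_triangles()`.

Triangles suffice; higher polygons are redundant, because any dependent
delay across a quadrilateral already closes one of its component triangles
together with the apparent links that the shared correlations create.

A good default for $\varepsilon$ is the mean width of the detected peaks
(`suggest_epsilon()`): closure errors inherit the variance of the delay
estimates.

## Frequency matrix and discrimination threshold

A single analysis point $p = (T, \sigma)$ yields a binary matrix $M_p$
(entry 1 iff a surviving peak implies $\tau_{jk} > 0$). Running K points —
the shipped simulation grid is $T \in \{2.25, 3.5, 4.5\}$ ms,
$\sigma \in \{0.013, 0.1, 0.63\}$ ms with $\varepsilon = 0.7$ ms, and the
MEA grid is $T \in \{16, 17.5, 20\}$ ms, $\sigma \in \{0.4, 0.55, 0.7\}$ ms
with $\varepsilon = 3$ ms — gives connection frequencies
$f_{jk} = \frac{1}{K}\sum_p M_p^{jk}$. True edges are re-detected by
essentially every point; false positives are fluctuations that move from
pair to pair as the analysis parameters change. The discrimination
threshold $d$ (edge kept iff $f_{jk} \ge d$; `>=` makes $d = 1$ meaningful
as unanimity, and $d = 0$ returns the union over points) therefore
suppresses false positives while barely touching sensitivity.
$\varepsilon$ is held fixed across the grid; a per-point override exists
in `build_grid()`.

## Raw versus Pearson amplitudes

Strongly bursting recordings inflate correlogram mass wholesale: a pair of
co-bursting neurons can carry more raw coincidences than a weak genuine
synapse, which mis-orders the minimum-amplitude comparison inside flagged
triangles. The pipeline's `mode = "pearson"` (the default of
`reconstruct()`) therefore evaluates each detected peak's amplitude on the
Pearson-normalised correlogram — the correlation coefficient of the
lag-shifted overlapping segments, computed from sparse prefix sums — while
peak *locations, widths and significance* are always measured on the raw
correlogram, where Poisson counting statistics are exact. `mode = "raw"`
uses the smoothed counts directly and is appropriate for weakly correlated,
non-bursting data. `cross_correlation()` itself offers the pure per-lag
Pearson function. (Two alternatives were tried and rejected: detecting
peaks directly on the Pearson curve admits weak spurious peaks because its
post-smoothing noise scale is ill-defined, and ranking victims by
prominence instead of amplitude performed worse throughout.)

## Parameters at a glance

| parameter | units | default | role |
|---|---|---|---|
| `dt` | ms | 0.1 | correlogram bin width; finer than all delay scales |
| `T` | ms | grid | half-width of the peak search window; must cover delay + latency, and larger values admit the indirect peaks the triangles need |
| `sigma` | ms | grid | Gaussian smoothing width |
| `epsilon` | ms | 0.7 (sim) / 3 (MEA) | triangle closure threshold; about the mean peak width |
| `d` | — | 1 | fraction of grid points that must agree on an edge |
| `min_prominence_frac` | — | 0.2 | relative prominence cut |
| `noise_z` | — | 4 | counting-noise significance of a peak's prominence |
| `window` | ms | 15 | receiver-probability window |

# The synthetic validation model

`generate_random_network()` draws directed edges uniformly without
replacement (no self-loops) at a mean out-degree of 2 regardless of network
size — sparse connectivity that does not grow with $n$, as in dissociated
cultures. Neurons are 80% regular-spiking and 20% intrinsically bursting
Izhikevich cells. `simulate_izhikevich()` integrates

$$\dot v = 0.04 v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u)$$

with forward Euler at `dt = 0.5` ms, spike-and-reset at $v \ge 30$ mV, and
records spike times by linear interpolation of the threshold crossing —
without sub-step interpolation the integration grid imprints a comb on
every correlogram and the peak-shape assumptions above break down
artificially.

Synapses are delta-current pulses: a presynaptic spike on edge
$(j \to k, w, \delta)$ adds $w$ to $I_k$ for one step, $\delta$ ms later.
Three defaults define the simulated preparation:

* **Conduction delays** uniform in (0.3, 0.8) ms — closely spaced cultured
  neurons; together with the 0.5–1 ms integration latency of a
  suprathreshold kick, direct correlation lags land at 1–2 ms, which is
  what the simulation grid's smallest window (2.25 ms) presumes. (Longer
  delays would simply require proportionally larger $T$ values.)
* **Weights** uniform in (100, 160) — a reliably suprathreshold 50–80 mV
  depolarisation per delivered spike, giving short, mildly jittered
  latencies.
* **Probabilistic release**, `release_prob = 0.4` per spike and synapse,
  in the range of measured cortical vesicle-release probabilities. This is
  the load-bearing realism choice: with deterministic transmission every
  spontaneous spike would sweep the whole excitatory network (branching
  ratio = mean out-degree = 2), synchronising all pairs at millisecond
  scale and flooding the correlograms with echo peaks as tall and narrow as
  the direct ones, which defeats any amplitude-based selection. At
  release 0.4 the branching ratio is 0.8 — subcritical avalanches: rich
  collective events occur, but propagation is probabilistic and indirect
  correlations are weaker and wider than direct ones, as the
  super-selection rule assumes.
* **Noise** is an independent Gaussian current per neuron and step
  (sd 4.5), tuned to sustain irregular background firing around 1.5–3 Hz
  with intermittent network events; zero noise and zero bias leave the
  network exactly silent.

The validation protocol used by `scripts/acceptance.R` simulates **450 s**
per network: at roughly 2 Hz and release 0.4, the weakest edges deliver a
few hundred relayed spikes, enough for a stable peak at every one of the
nine grid points (the acceptance criterion at $d = 1$ requires unanimity).

What the generator does **not** emulate: inhibitory synapses,
conductance-based dynamics, synaptic plasticity, spatial geometry and
electrode pickup, overlapping-unit waveforms, or the slow developmental
changes of real cultures. Passing the validation therefore shows that the
method recovers ground truth under its own assumptions (excitatory sparse
networks, sub-deterministic propagation, millisecond delays); it does not
certify performance on recordings that violate them — strongly
synchronised pathological bursting in particular degrades any
correlation-based method.

`generate_delta_motif()` provides the deterministic end of the validation:
chain, common-input, common-output and pair motifs whose downstream spike
times are exact delay-shifted copies with per-edge accumulated Gaussian
jitter, so the expected peak positions, the triangle closures and the
pruning victims are known in closed form.

# Evaluation machinery

`score()` counts the confusion matrix over ordered off-diagonal pairs and
reports `TP/n_c`, `FP/n_c`, the confidence indicator
$\Delta = (TP - FP)/n_c$ — independent of network density — and the
accuracy $(TP + TN)/n_{tot}$, which true negatives inflate on sparse
truth. Graph descriptors: in/out-degree, hubs (in-degree exceeding
mean + 2 sd by default, strictly, so regular graphs have none; a
top-percentile rule is available), unweighted mean shortest-path length
over finite directed pairs, and the node-averaged local clustering
coefficient of the undirected projection (degree < 2 contributes 0); path
and clustering run on `igraph` and are verified against brute-force BFS
and triangle counting in the tests.

`receiver_probability()` counts, for each spike of neuron $j$, the other
neurons' spikes in $[t - w, t)$ ($s^-$) and $(t, t + w]$ ($s^+$) with
$w = 15$ ms; exactly simultaneous spikes count on neither side (the
boundary convention is fixed and tested). $s^-/(s^+ + s^-)$ near 1 marks a
receiver, near 0 an initiator. `receiver_vs_indegree()` regresses the
reconstructed in-degree fraction on this estimate by ordinary least
squares — the plain regression a reader would expect, nothing more.

# Spike sorting

`pca_features()` performs mean-centred PCA on waveform snippets and keeps
the fewest components reaching 90% cumulative variance. `sort_spikes()`
runs k-means with 20 random restarts per candidate $k$ (keeping the lowest
within-cluster sum) for $k = 1, \dots, n_{\mathrm{PCA}} + 1$, and picks $k$
at the elbow of the within-cluster-sum curve (largest second difference) —
with a fall-back to $k = 1$ when the best two-way split still leaves more
than half of the total dispersion, since the second-difference elbow is
undefined at the single-cluster end of the curve. A manual `k` override
mirrors the visual check an operator would apply in ambiguous cases.
Events farther than three times their cluster's rms point-to-centroid
distance are flagged as outliers, never silently dropped.
`split_trains()` partitions the event times by unit label; every event
lands in exactly one output train.

# Numerical and interface conventions

* Times are **seconds on disk, milliseconds internally** for lags and
  delays; the readers/writers in `R/io.R` own that boundary. Neuron ids
  are 0-based on disk (a `one_based` switch exists for 1-based tables).
* All randomness flows through R's RNG via explicit `seed` arguments;
  identical inputs and seeds give bitwise-identical outputs, including in
  the compiled simulator.
* Neurons with zero spikes stay in the matrices as isolated nodes, keeping
  indices stable.
* A grid point at which no peaks survive contributes an all-zero matrix to
  the frequency average rather than an error.
* `frequency_matrix` entries are exact multiples of $1/K$; the CSV writer
  keeps 9 significant digits so they round-trip.

# Known limitations

* Inhibitory connections are not detected; the super-selection rule as
  implemented reasons about positive correlation peaks only.
* Strong network-wide bursting erodes the amplitude ordering the pruning
  relies on; the Pearson amplitude mode mitigates but does not remove
  this.
* Delays shorter than the correlogram bin or longer than the smallest
  search window $T$ are invisible at $d = 1$; choose the grid to bracket
  the physiological delay range.
* The accuracy measure saturates on sparse networks; prefer $\Delta$ when
  comparing configurations.
* The triangle stage enumerates all peak combinations per triplet
  ($O(n^3)$ triplets); dense peak graphs on hundreds of neurons would need
  the usual sparsity of real recordings to stay fast.
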
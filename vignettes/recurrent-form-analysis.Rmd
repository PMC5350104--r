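---
title: "Recurrent form analysis: models, surrogate data, and probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent form analysis: models, surrogate data, and probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfam)
```

## The scientific problem

Neurons in macaque V2 — especially in its supragranular layers — respond
selectively to binary textures that differ from random noise only in a
specific third- or fourth-order spatial correlation. A feedforward cascade
of linear filters and static nonlinearities (an LN model) can reproduce this
selectivity on the textures it was fitted to, but fails to generalize to new
examples of the same texture classes. This package implements an alternative
hypothesis: a network with two hierarchical stages of *locally recurrent*
processing, trained only to reproduce texture-evoked response dynamics, can
learn the underlying class rule — and, as an emergent by-product, its hidden
units develop motion (speed and direction) tuning that is correlated with
their four-point texture selectivity. The package contains the full modeling
chain: texture synthesis, a surrogate response generator standing in for the
(unpublished) recordings, the LN baseline, the recurrent network, the
probing battery, and the population-level analyses.

## Maximum-entropy glider textures

A texture class is defined by a *glider* — a small set of check offsets —
and a target parity. In $\pm 1$ check coding, every complete placement of
the glider on the $16\times16$ grid must have check product equal to the
parity. The seven classes are `random` (no constraint), the three-point
`white_triangle`/`black_triangle` (parity $+1$/$-1$ on an L-shaped
glider), the four-point `even`/`odd` ($2\times2$ block, parity $\pm1$), and
the non-salient four-point `wye` and `foot`.

`generate_textures()` implements the Markov recurrence construction: checks
that no complete placement determines are seeded i.i.d. uniform; the rest
are filled in raster order so that each placement's product equals the
parity. This yields the maximum-entropy ensemble with the target
correlation: the parity constraint holds *exactly* at every placement
(assertable, and asserted, in the tests), while the mean and all lower-order
correlations vanish on average. `verify_statistics()` reports the empirical
first-, second- and glider-order statistics of an ensemble with standard
errors.

Exact glider coordinates for `wye` and `foot` and the chirality of the
triangles are not uniquely fixed by the literature's prose descriptions; the
defaults used here — `wye` $\{(0,0),(0,2),(1,1),(2,1)\}$, `foot`
$\{(0,0),(0,1),(0,2),(1,0)\}$, triangle $\{(0,0),(0,1),(1,0)\}$ — have the
same order and salience structure, and `glider_spec()` accepts any custom
shape so published variants can be substituted.

Network inputs are the textures low-pass filtered with a 2-D Gaussian
($\sigma = 2$ checks, reflect padding to avoid border luminance artifacts)
and mapped to $[0,1]$. The blur emulates optics/retina/LGN filtering. It
introduces second-order correlations, but identically for all classes, and
it does not alter the defining multipoint correlations.

## The surrogate response generator

The neural recordings the original experiments used are not publicly
deposited, so the package ships a first-class generative stand-in
(`surrogate_neuron()`, `make_population()`, `simulate_responses()`). For a
neuron with baseline rate $b$, class gains $g_c$, transient fraction $a$
and decay constant $\tau$ (in 40 ms bins), the expected rate in bin $t$ for
a texture is

$$ r(t) = b \, k(t) \, \max\!\big(0,\; 1 + \textstyle\sum_c g_c \psi_c + f \big), \qquad
   k(t) = a e^{-(t-1)/\tau} + (1-a), $$

where $\psi_c$ is a convex mixture (weight `example_sensitivity`, default
0.3) of the class indicator and the texture's empirical glider statistic
computed on the neuron's private $8\times8$ receptive-field window, and $f$
is an example-specific drive from a random linear receptive-field filter
over the same window (SD 0.2). Counts per 40 ms bin are Poisson. Trials also
share a multiplicative lognormal gain fluctuation (SD 0.3 on the log scale)
across the whole population, emulating the correlated trial-to-trial
variability of cortical populations, which population averaging cannot
remove.

Gain scales are layer- and area-dependent: smallest in V1, intermediate in
V2 granular/infragranular, largest in V2 supragranular, where the mean
`even` gain is positive (0.45). The supragranular V2 population average
(V2pa, `population_average()`) is therefore even-preferring with a
transient–sustained time course, which is the structure the recorded
population average exhibits. Temporal kernels are spread over transient,
sustained and mixed dynamics ($a \sim U(0,1)$, $\tau \sim U(0.5, 2.5)$
bins).

What the generator does *not* emulate: sub-bin spike timing, adaptation
across trials, the initial ~40 ms descending transient (excluded from the
analysis window by design), and realistic receptive-field geometry beyond a
random window filter. Passing tests on surrogate data therefore demonstrate
that the pipeline recovers the structure this generator plants — class
selectivity, dynamics diversity, an even-preferring population average —
not that it would reproduce every property of the real recordings.

The split-half `consistency()` of the default V2pa at 1024 examples/class
exceeds 0.8 (the recorded population average was 0.89). With the default
even-dominant class structure, the exact recorded value is not reachable:
consistency that low requires within-class example variance roughly eight
times the between-class variance of the tuning curve, which would contradict
the strongly even-preferring population average the targets must exhibit.
We kept the paper-like class structure and accept a higher consistency; the
direction of the discrepancy (the surrogate is *cleaner* than the data)
only makes the downstream learning problem harder to pass by accident.

## Targets and normalization

Spiking responses are binned into five 40 ms bins (the 40–200 ms analysis
window). Trial-averaged rates are normalized by one shared affine map —
subtract the global minimum, divide by the maximum over all bins,
conditions and neurons — so targets lie in $[0,1]$ with attained endpoints
(`normalize_targets()`). For the single-output population-average model the
per-example target is the *class-mean* 5-bin curve of the V2pa
(`class_mean_targets()`): the model is asked to produce, for every example
of a class, the class's canonical response, so it can only succeed by
inferring the class from the image.

## The LN baseline

`ln_istac()` fits the feedforward baseline: spike-triggered average and
covariance from rate-weighted stimulus moments, maximally informative
filters by greedy maximization of the Gaussian KL divergence between
spike-triggered and raw ensembles (iSTAC), and a histogram-ratio
nonlinearity per filter (25 bins spanning $\pm4$ SD of the projection,
empty bins linearly interpolated, out-of-range projections clamped). Model
output sums the per-filter nonlinearities (separability assumption).

Numerical choice: the whitening step is truncated to stimulus dimensions
carrying at least `whiten_tol` ($10^{-3}$) of the leading raw-covariance
eigenvalue. Blurred ensembles are strongly low-pass, so the excluded
directions carry essentially no stimulus power; whitening them would only
amplify sampling noise. With this truncation a planted single-filter neuron
is recovered with $|\cos| > 0.9$ from 20,000 samples (tested).

Tuning performance is the correlation between class-mean tuning curves of
model and target, computed separately on the training textures and on
freshly generated ones. Following the two conventions in the field's
reporting, the LN evaluation defaults to Spearman rank correlation and the
recurrent-network evaluation to Pearson; `evaluate_tuning()` exposes both.

## The recurrent network

`rfam()` trains the two-stage locally recurrent network: 256 inputs (one
per check), two sigmoid hidden layers with full within-layer recurrence,
sigmoid outputs; all connections otherwise feedforward. At step $t$ each
unit computes $X_i = \sum_k w_{ik} y_k + b_i$, $y_i = 1/(1+e^{-X_i})$, with
hidden layers receiving their own previous-step outputs; the recurrent
state is reset to zero between trials; the same static input is presented
for all five steps. The published architecture (100+100 hidden units, 123
outputs) has 68,223 trainable parameters; the scaled desk configuration
(30+30, 1 output) has 11,371.

Training is per-pattern stochastic gradient descent with exact
backpropagation through time on the summed squared error over the five
steps. The reference BPTT implementation (`bptt_gradients()`) is verified
against central finite differences in every weight group including both
recurrent matrices; the training loop itself is a compiled (C++) equivalent
that the tests check against the reference update to machine precision.

Choices where the original tooling leaves freedom (the toolbox
hyperparameters are not recoverable):

* **Initialization**: Nguyen–Widrow — random directions rescaled so each
  unit's incoming weight vector (feedforward + recurrent) has norm
  $0.7\,n^{1/\text{fan-in}}$, biases spread uniformly.
* **Input scaling**: network inputs are mapped to $[-1,1]$ by a global
  min–max affine map fitted on the training ensemble and stored in the
  model (the standard preprocessing of the Elman-network toolbox the
  architecture comes from). Blurred textures occupy a narrow band around
  0.5; without this map first-layer gradients are too small to learn from.
* **Optimizer**: learning rate 0.15, classical momentum 0.9, gradient-norm
  clip 10, and a small L2 weight penalty (`weight_decay`) on weights (not
  biases). The penalty is the regularized-performance option of the same
  toolbox lineage; it matters here because the scaled network can memorize
  its training textures, and a small penalty steers prolonged training from
  memorization toward the class-generic solution that generalizes.
* **Loss**: summed squared error ("mismatch"); sigmoid outputs match the
  $[0,1]$ targets.

Desk-scale problem sizes (the package defaults): 30+30 hidden units, 1024
training examples per class, two million training epochs, 1,000 probe
examples per condition, 300–1,000 fresh test examples per class. The
published experiment used 100+100 units, five million epochs and 10,000
probe examples; these are reachable through the same interfaces.

## Probing and selectivity indices

`selectivity_indices()` runs the simulated experiment battery on every
hidden unit of a fitted network. A unit's response is its sigmoid output
averaged over the five steps and over examples.

* **Texture**: TSI$_x$ = mean response to class $x$ minus mean response to
  `random`; TTI$_x$ = |Michelson contrast| of the same two means.
* **Orientation**: 1-D binary noise replicated along $y$, rotated to 18
  angles (10° grid), blurred. OSI = largest-magnitude deviation from the
  across-angle mean, sign kept.
* **Translation**: blurred noise canvases (80×80) behind a sliding 16×16
  window at speeds {0, 0.5, 1, 2, 4, 8, 16} checks/bin in 4 directions
  (0–25°/s on a 1° receptive field). SSIt = largest-magnitude deviation of
  a speed's direction-averaged response from the stationary response, sign
  kept; DSIt = the direction-response range at the preferred or
  anti-preferred speed, whichever is larger.
* **Rotation**: the canvas rotates about the window center at {0, 0.5, 1,
  2, 4, 8, 16, 32, 64, 128}°/bin, both senses; SSIr/DSIr analogous.

Numerical/tie-break choices: "largest difference" for the DSI is read as
the response *range* over directions at the candidate speed; speed ties
break toward the lower speed; the window slides over a large non-periodic
canvas (a 16-check periodic wrap would make the fastest speed
indistinguishable from stationary); half-check displacements use linear
interpolation, rotations bilinear resampling (fill 0.5 outside the canvas).
Probe canvases and noise carriers are shared across the conditions of one
experiment, giving a paired design that removes carrier variance from the
between-condition comparisons.

## Population analyses

* `dynamics_pca()`: per-unit 5-bin time courses, neural courses shifted by
  their 40 ms onset delay (hidden units have no afferent delay),
  max-normalized, stacked, PCA with time points mean-centered (the
  centering convention is a documented choice). Units are embedded by
  their first two projections; `convex_hull_overlap()` quantifies overlap
  of group embeddings by exact polygon clipping.
* `ridge_similarity()`: each target neuron's 35-point profile (7 classes ×
  5 bins) fitted as a ridge-penalized ($\lambda = 0.2$) linear combination
  of source-unit profiles; source columns standardized, intercept
  unpenalized (so $\lambda$ is scale-meaningful); similarity = mean Pearson
  correlation between fit and data over target neurons.
* `form_motion_correlations()`: Pearson correlations, across units of a
  layer, between each TSI and each motion/orientation index.
* `counterfactual_swap()`: exchanges the target curves of the
  black-triangle and even classes; retraining on swapped targets is the
  control showing that the form–motion link tracks the specific V2pa
  response structure rather than being an artifact of recurrent training.

## Known limitations

* The surrogate generator is the package's own construction; its defaults
  are frozen and documented above, but no claim is made that its parameter
  values match the unpublished recordings beyond the qualitative structure
  (even-preferring supragranular V2, diverse dynamics, Poisson counts,
  correlated trial noise).
* At the desk scale (30+30 units), generalization performance of the
  population-average model depends visibly on the optimizer regularization;
  at the published scale the original report did not need it. The package
  exposes all of these knobs rather than hiding the sensitivity.
* The swapped-target control does not fully silence index correlations at
  the desk scale. With 30-unit layers the across-unit correlation of two
  indices has a null sampling SD near 0.2, and the normalized desk-scale
  target curves are strongly transient for *all* classes, so
  differentiator-like dynamics pervade the control solution and couple
  class preferences to motion preferences generically; in the second hidden
  layer of the control network the index variation can fall to probe-noise
  level, where correlations are large but meaningless. The full-scale
  experiment (100-unit layers, millions more epochs, recorded targets)
  reported the control's correlations all below 0.25; the scaled control
  reproduces the *direction* of the dissociation (weaker, sign-incoherent
  coupling than the veridical network) but not that bound.
* Statistical tests reported on the real data (ANOVAs, t-tests on
  principal-component projections) are data-dependent and are not
  reproduced; the package provides the underlying quantities only.
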
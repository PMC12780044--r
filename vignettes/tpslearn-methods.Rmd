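---
title: "Methods: committor-guided transition path sampling at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: committor-guided transition path sampling at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tpslearn)
```

This vignette records the models, numerical choices and design
decisions behind `tpslearn`, in the spirit of a methods section: what
is computed, under which assumptions, and what the synthetic test
systems do and do not establish.

## The sampling problem

Transition path sampling targets the transition path ensemble (TPE) —
the equilibrium-weighted set of trajectory segments that leave one
metastable state and reach the other without re-entering the first
(the *first-entrance* convention; in this package a valid path has its
two endpoints inside two different states and every interior frame in
none). A two-way shooting move selects a shooting point (SP) on the
current path, launches two independent segments from it, and splices
them into a trial path when their endpoints land in different states.
For flexible path lengths the move is accepted with probability

$$
p_\mathrm{acc} \;=\; \min\!\left(1,\;
  \frac{p_\mathrm{sel}(x_\mathrm{SP}\mid \text{trial})}
       {p_\mathrm{sel}(x_\mathrm{SP}\mid \text{current})}\right),
$$

where $p_\mathrm{sel}(\cdot\mid X)$ is the normalized probability of
selecting that frame from path $X$. This is the standard
Metropolis–Hastings correction for two-way shooting from a
*reversible* propagator: the generation probabilities of the two
segments cancel against the path weight, leaving only the selection
ratio. Two consequences shape the package:

- the built-in engines are reversible by construction (overdamped
  Langevin; birth–death chains), and the discrete-chain oracle used to
  validate the sampler is deliberately a nearest-neighbour chain;
- under uniform selection the acceptance probability is the ratio of
  eligible frame counts, *not* identically 1 — it is 1 only for
  equal-length paths. The package implements the ratio; the
  enumeration test below is sensitive to this choice and fails with
  unconditional acceptance.

Unresolved shots (a segment that exhausts `max_steps` without entering
a state) are rejected moves, logged distinctly — never silently
truncated paths.

Both "directions" of the ensemble are sampled; `k`, the number of
segment endpoints in the designated final state, is always counted
toward that state regardless of the trial path's orientation, so the
training loss sees a consistent label definition.

## Learning the committor from shooting outcomes

Every shot — accepted or not — yields a record $(x_i, n_i, k_i)$ with
$n_i = 2$ for two-way shooting. Under a committor model
$\varphi(x\,|\,w)$ the outcomes are binomial, giving the mean negative
log-likelihood

$$
\mathcal{L}(w) = -\frac1N\sum_{i=1}^N \ln\!\left[\binom{n_i}{k_i}
 \varphi_i^{\,k_i} (1-\varphi_i)^{\,n_i-k_i}\right].
$$

The network is a sequence of linear compressions, each followed by ELU
(and dropout during training) and optionally a residual block of `resnet_depth`
sublayers $a \mapsto a + \mathrm{elu}(Va + c)$, ending in a single
linear unit whose output is the logit $q$; $\varphi = \sigma(q)$. A
single-logit sigmoid replaces the equivalent two-output softmax — the
function class is identical with fewer parameters. The published
architectures for membrane problems
(`68→46→31→21→14→10→1`, `147→85→50→29→14→17→1`, residual depth 4)
build directly via `network_spec()`; note such shapes need not be
strictly monotone in width (`…→14→17→1`), so the constructor only
enforces a final width of 1. Training choices, none of which are
prescribed by the problem and all of which are arguments:

- optimizer Adam, default learning rate `1e-3` (the examples and tests
  use `5e-3` for these very small nets), batch size 256;
- dropout default 0.1 ("small"), L2 coefficient `1e-4`;
- early stopping at the minimum validation loss with a patience
  window, the validation set being one held-out MC chain when records
  carry a `chain_id` (a random 20% split otherwise). Restraint-run or
  seeding records are simply included in the training table;
- $\varphi$ is clamped to $[10^{-7}, 1-10^{-7}]$ inside the loss,
  which is otherwise unbounded when $k$ disagrees with a saturated
  prediction.

Gradients — both parameter and input gradients — are exact
backpropagation, implemented in the package and verified against
central finite differences in the tests. Input gradients feed the
reactive-flux analysis, which is why the network lives here rather
than behind a generic ML wrapper.

## Shooting-point selection on the logit

Efficient shooting concentrates near $\varphi = 1/2$ but should retain
heavy tails; the target distribution of the SP logit is Cauchy(0, 1).
Frames of the current path are therefore weighted

$$
w_i \propto \frac{\mathrm{Cauchy}(q_i;\,0,1)}{\hat P(q_i\mid \mathrm{TP})},
$$

where $\hat P(q\mid\mathrm{TP})$ is a histogram of logits over frames
of sampled transition paths: 50 equal-width bins on logits clipped to
$[-10, 10]$ (clipping keeps near-state frames with diverging logit
from dominating; the histogram is built from frames of accepted
transition paths, which is what the conditioning on "TP" means here,
pooled per chain). Selection is uniform for the first 100 MC steps,
the histogram is built at step 100 and refreshed every 250 steps.
Frames falling in empty bins use the smallest nonzero bin density as
the denominator; all-zero weight vectors fall back to uniform with a
warning. Path endpoints are never eligible (they lie inside states,
violating the shooting precondition).

## Sampler diagnostics

Two efficiencies summarize a chain. Counting:
$\eta_{\Delta n} = 1 - (n_\mathrm{exp}-n_\mathrm{gen})/n$, with
$n_\mathrm{exp}$ the cumulative sum of the transition-path probability
$P(\mathrm{TP}\mid x) = 2\varphi(1-\varphi)$ over SPs and
$n_\mathrm{gen}$ the cumulative count of shots that produced a
transition path ($k = 1$). Timing: $\eta_T = T_\mathrm{TP}/T_\mathrm{all}$,
where $T_\mathrm{TP}$ accumulates durations of *newly accepted* paths
only and $T_\mathrm{all}$ all propagated segment time including
rejected shots.

The accuracy $\alpha$ of a committor model measures the excess
variance of shot outcomes beyond binomial noise. The true commitment
probability $P$ is modelled Beta-distributed around $\varphi$ with
$a = w\varphi$, $b = w(1-\varphi)$, $w = \alpha/(1-\alpha)$, so that
$\mathrm{Var}[P] = (1-\alpha)\varphi(1-\varphi)$; convolving with the
binomial gives a beta-binomial likelihood whose limits are exact in
the implementation ($\alpha \to 1$: binomial; $\alpha \to 0$: the
two-point mixture at $k \in \{0, n\}$). $\hat\alpha$ maximizes the
log-posterior under a flat prior on $[0,1]$, by a dense grid
(resolution $10^{-3}$) plus local refinement — the curve can be very
flat near the boundaries, where derivative-based optimizers are
unreliable at this scale. Uncertainty comes from a cross-validated
bootstrap: hold out one chain, optionally refit on the rest, estimate
$\alpha$ on 100 bootstrap resamples of the held-out chain, repeat 10
times; percentiles (2.5/25/50/75/97.5) are pooled over all resamples
rather than aggregated per round, matching the box-and-whisker
convention of pooled bootstrap totals.

Calibration uses dedicated validation shots with $n = 20$: a least
squares line $q^\mathrm{lin} = c\,q + d$ through actual logits
$\ln[k/(n-k)]$ versus predicted logits. Records with $k \in \{0, n\}$
have infinite actual logit and are excluded from the fit (the
underlying objective is undefined there; how such shots were treated
upstream is unstated, so exclusion is this package's documented
choice). The spread
$\Delta\varphi^\mathrm{lin} = \sqrt{1-\alpha(1-1/n)}\sqrt{\varphi^\mathrm{lin}(1-\varphi^\mathrm{lin})}$
uses $\alpha$ estimated jointly from the same records.

## Mechanism analysis

The reactive-flux direction $v(\varphi) = \langle\nabla\varphi\rangle_\varphi
/ |\langle\nabla\varphi\rangle_\varphi|$ is averaged within 10 equal
committor bins on $(0.05, 0.95)$; extreme-$\varphi$ samples are
excluded because any linear model must fail near the state boundaries.
Gradients are taken with respect to *standardized* features (zero
mean, unit variance over the sample set): $v$ mixes heterogeneous
units, and without a stated convention the standardized gradient is
the defensible default. Which samples enter the average is likewise
unspecified upstream; the default here is all supplied samples with
recorded features. The minimum pairwise cosine between bin directions
is reported as the linearity score — near 1 it licenses the
quasi-linear model $\varphi \approx \varphi(x\cdot v)$, which can be
refit as a small network on `x·v` plus a couple of physical
coordinates (`fit_lowdim_committor()`).

Projected TPE densities use the k-nearest-neighbour estimate: the
radius $r$ of the smallest circle holding $k$ points gives density
$\propto r^{-2}$. Committor iso-surfaces on a 2D projection average
the full feature vector over the $k$ nearest samples per grid node,
project onto $v$, and evaluate the 1D committor; nodes whose k-NN
radius exceeds a support threshold are flagged, not extrapolated.

Mechanism classification thresholds the smoothed (centered moving
average, window 10 MC steps) time-averaged pore coordinate at 1.0 —
the membrane-spanning-pore criterion — labelling each MC step as the
pore mechanism or the tunneling mechanism and reporting switch
indices.

## Pore geometry

The pore coordinate combines nucleation and expansion. The chain
coordinate $\xi_\mathrm{ch}$ is the fraction of `N_slabs` equal slabs
across the membrane region ($Z_\mathrm{mem}$ thick, at the pore
nucleus) holding at least one polar particle within lateral distance
`R_cyl` of the pore center; occupancy is binary — no forces are
computed here, so no smoothing is needed (a smooth variant can be
slotted in behind the same interface). The pore radius converts the
water count inside lateral cutoff `D` to a cylinder at bulk density:
$R = \sqrt{N_w v_w / (\pi Z_\mathrm{mem})}$ with
$v_w = 0.030\,\mathrm{nm}^3$. The combination

$$
\xi_P = \begin{cases}
  \xi_\mathrm{ch}/\xi_\mathrm{ch}^s, & \xi_\mathrm{ch} < \xi_\mathrm{ch}^s\\[2pt]
  1 + \max(0, R - R_0)/R_0, & \text{otherwise}
\end{cases}
$$

is continuous at the switch (a just-nucleated pore with $R = R_0$
reads exactly 1; $\xi_P > 1$ means a membrane-spanning pore, and a
pore relaxed to twice its nucleated radius reads $\approx 2$). This
combination rule is this package's explicit reading of the coordinate
it reimplements; it is isolated in `xi_p()` so a different switching
convention is a one-function change. The shipped parameter preset is
the coarse-grained ("martini") set printed in full by its source:
`N_slabs = 4`, `Z_mem = 1.8`, `R_cyl = 1.0`, `D = 1.2`,
`xi_ch_s = 0.9`, `R0 = 0.38` (nm). Atomistic parameter values live in
an external reference and are not reproduced here, so no "atomistic"
preset is shipped — constructing one is a single `pore_params()` call.
The pore center is a weighted circular mean of headgroup positions per
periodic lateral axis, weighted by a Gaussian in the axial distance to
the midplane of width $Z_\mathrm{mem}/2$ (emphasizing
midplane-proximal, pore-lining headgroups; the exact upstream weights
are likewise in an external reference). Known limitation: the
artificial metastable state in the transition region reported for
atomistic parameterizations has an unspecified correction and is not
implemented.

Pore lifetimes with right-censoring (runs ending with the pore still
open) use exponential kinetics: the MLE is
$\hat\tau = \sum_i t_i / n_\mathrm{closures}$, the aggregate open time
over the number of observed closures; the profile log-likelihood
$n\ln\kappa - \kappa\sum t_i$ over the closure rate $\kappa = 1/\tau$
is returned so the maximizer can be verified, and
$\hat\tau/\sqrt{n_\mathrm{closures}}$ serves as the standard error.
With no observed closure only a lower bound exists and the estimator
errors out explicitly.

## The synthetic systems: what they emulate, and what they do not

The generators define the study conditions; their defaults are fixed
once.

**Double well (1D).** $U(x) = h\,((x/a)^2-1)^2$ with barrier
$h = 5\,k_BT$ and minima at $\pm 1$ nm; states at $|x| > 0.9$. The
committor oracle is exact quadrature of
$\varphi(x) = \int_a^x e^{\beta U}\!/\!\int_a^b e^{\beta U}$
(trapezoid on a 20001-point grid, integrand stabilized by subtracting
the max). Committor recovery uses 5000 two-way shot records with SPs
uniform on $[-0.85, 0.85]$.

**Two-channel landscape (2D).** Two wells at $(\pm 1, 0)$ separated by
a ridge along $x = 0$ whose height drops to `barrier_T` at a mouth
around $y = 0$ (direct, "tunneling-like" channel) and to `barrier_P`
at a mouth around $y = 1.4$ gated through a shallow metastable
intermediate (the "pore-like" channel). Mouth widths
($\sigma_y^2 = 0.3$) leave the channels distinct yet mutually
reachable within a few thousand MC steps — the property the
mechanism-relaxation demonstration needs; a much taller or narrower
ridge makes channel switching astronomically slow (which is physically
correct but untestable), a leakier one blurs the channel identity. The
demo conditions are barriers 3 vs 7 $k_BT$, intermediate depth
2 $k_BT$, $\beta = 1$, `dt = 1e-3`, state discs of radius 0.55 around
the wells, chains of 2500–4000 steps, channel indicator = path-mean
elevation $y$ thresholded at $y_I/2$.

**Discrete chains.** Reversible birth–death chains (≤ 12 sites) whose
TPE is enumerated exactly: every first-entrance path up to `max_len`
with weight $\pi(x_0)\prod P(x_i, x_{i+1})$; the truncated mass is
accounted *exactly* through the committor of each abandoned frontier
site, so enumerated + truncated probability is exactly the total TP
weight. The oracle test runs $10^5$ guided TPS steps on a 5-site chain
(`p_up = 0.6`) and compares path frequencies by total variation.

**Shot records.** $\varphi \sim$ a sampler (default uniform on
$(0.05, 0.95)$), $P \sim \mathrm{Beta}$ around $\varphi$ at accuracy
$\alpha$, $k \sim \mathrm{Binomial}(n, P)$, with the $\alpha \in \{0,1\}$
limits as point mass / two-point mixture. Accuracy recovery is tested
at $N = 10^4$, $n = 2$ over $\alpha = 0.1, \dots, 0.9$.

**Membranes.** Heads jittered on two planes 2.6 nm apart (echoing the
$|z| = 1.3$ nm flip-flop state thresholds), tails between, bulk water
outside, and optionally a planted cylindrical water column at bulk
density with headgroups pulled toward the midplane near the axis — a
toroidal-rim caricature. Planted radius 0.4 nm is recovered by the
radius estimator within ±0.1 nm (Poisson noise on a few dozen waters
dominates this tolerance).

**Lifetimes.** Exponential draws censored at a fixed horizon;
the recovery case uses rate 2.5 and a censoring time chosen for ~30%
censoring at $N = 10^4$.

None of these systems have molecular detail: no force field, no
solvent structure, no lipid chemistry, no inertia (the propagator is
overdamped Euler–Maruyama, so "two-way" shooting means two independent
noise realizations with one segment relabelled as time-reversed, which
is exact for diffusive dynamics). Passing tests therefore establish
the *statistical machinery* — sampler correctness against enumeration,
estimator consistency against generative truth, formula-level
arithmetic against oracles — not fidelity to any particular molecular
system.

## Numerical choices and degenerate inputs

- Integrator: Euler–Maruyama with unit friction,
  $dx = -\nabla U\,dt + \sqrt{2\,dt/\beta}\,\xi$; `beta = Inf` gives
  deterministic descent. Frame recording may be strided; the
  state-entering frame is always kept.
- All randomness flows from a single seed per chain/generator; chains
  additionally checkpoint their RNG state so a resumed run reproduces
  an unbroken one bit-identically.
- Beta-binomial evaluation switches to its closed limits within
  $10^{-12}$ of $\alpha \in \{0,1\}$ to avoid overflowing
  $w = \alpha/(1-\alpha)$.
- k-NN queries are brute force with partial selection in compiled
  code — exact, permutation-invariant, and fast enough at
  $N \sim 10^4$; duplicate points yielding $r = 0$ are floored at
  machine scale with a warning.
- Empty paths, all-censored lifetime sets, empty record tables,
  overlapping state indicators and unknown configuration keys are hard
  errors with specific messages, not silent defaults.

## Problem sizes

The test suite and the acceptance script run, per invocation: 5000
double-well shot records plus a ~300-epoch training for committor
recovery; $10^5$ discrete-chain MC steps against an enumeration of
~$2.6\times 10^5$ paths; $9\times 10^4$ dispersed shot records for
accuracy recovery; 2500–4000 two-channel MC steps per
mechanism-relaxation chain; $10^4$ censored lifetimes; $10^4$
10-dimensional samples for the flux analysis. These sizes were chosen
so each statistical check has comfortable power at its stated
tolerance while the whole suite remains a desk-scale computation.
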
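---
title: "Modelling whole-brain dynamics on a latent manifold: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-brain dynamics on a latent manifold: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the generative model,
the inference procedure, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The model

Parcellated BOLD recordings (T frames x N regions, sampling period TR) are
treated as observations of a much lower-dimensional latent process. The
pipeline has four stages.

**1. Embedding.** A variational autoencoder (VAE) is trained on
*time-by-time spatial patterns*: every time frame is one training sample of
N regional values. The encoder (two dense ReLU layers funnelling into a
variational layer) maps each pattern to a Gaussian posterior over M latent
modes; the decoder mirrors the encoder. The loss is the reconstruction
error plus the analytic KL divergence between the posterior and a standard
normal. All downstream modelling uses the posterior mean, not a sample:
the latent trajectories feed correlation estimates, and sampling noise
would bias them downward. A sampling mode exists behind a flag.

**2. Latent dynamics.** Each latent mode j is a Stuart-Landau oscillator —
the normal form of a supercritical Hopf bifurcation — with complex state
`z_j = x_j + i y_j`:

    dz_j/dt = (a_j + i w_j - |z_j|^2) z_j + sum_k C[j,k] (z_k - z_j) + eta_j

For `a_j < 0` the node is a damped (noise-driven) oscillator; for
`a_j > 0` it sustains a limit cycle of amplitude `sqrt(a_j)`. Model fitting
fixes `a_j = -0.02`, just below the bifurcation, where noise produces
amplitude-modulated oscillations — the regime in which such models best
reproduce empirical fMRI statistics. Intrinsic frequencies `w_j` are
estimated as the averaged periodogram peaks of the band-limited latent
signals (0.008–0.08 Hz). `eta_j` is complex additive Gaussian noise with
standard deviation `sigma` in each part.

**3. Coupling inference (LGEC).** The directed coupling `C` between modes is
inferred by iteratively matching two observables: the zero-lag functional
connectivity `FC` (Pearson correlations between modes) and the
forward-shifted `FCf(tau)` (correlation between each mode and every mode
shifted `tau = 3` frames into the future). `FC` constrains interaction
strength; the *asymmetry* of `FCf` carries the arrow of time — a
time-reversible (detailed-balance) process has symmetric lagged
correlations, so fitting `FCf` is what lets the model recover *directed*,
nonequilibrium coupling. Starting from `C = 0`, each iteration runs a batch
of simulations, averages their observables, and nudges every connection by
`varsigma` times the empirical-minus-model discrepancy of both observables
(`varsigma = 1e-5`). The result — the latent generative effective
connectivity — is the best-fit iterate along the trace.

**4. Fingerprinting.** Decoding a latent noise probe (standard Gaussian
noise in one mode, zeros elsewhere) yields each mode's source-space
pattern: the variance map (unsigned) and the correlation between each
decoded regional series and the injected noise (signed). Patterns are
associated with reference network membership maps by Pearson correlation
with Benjamini-Hochberg FDR across all mode-network pairs. Condition-level
LGEC ensembles are compared by per-node total connectivity (in + out) with
rank-sum tests, and classified with a Gaussian-kernel one-versus-one SVM
over the off-diagonal coupling entries.

## Orientation of the forward-shifted update

Two sign conventions meet here and must be kept coherent. `C[j,k]` is the
influence of mode k on mode j (it multiplies `z_k` in the equation for
`z_j`), and `FCf[i,j] = cor(x_i(t), x_j(t+tau))` puts the *earlier* signal
on the row. Linearising the subcritical dynamics shows that `FCf[i,j]`
grows with the influence of i on j, which is entry `C[j,i]` — the
*transposed* position. The update therefore applies the forward-shifted
discrepancy transposed, so that the entry being updated is the one whose
physical effect the discrepancy measures. This is not a cosmetic choice:
with the discrepancy applied untransposed the procedure still drives the
fit to convergence, but the coupling it converges to is the transpose of
the ground truth (parameter-recovery simulations in the test suite check
recovery against the truth, and development runs showed correlation with
the transposed truth rising while correlation with the truth fell when the
orientation is mixed up).

## Convergence and the returned estimate

With `varsigma = 1e-5` the fit trace is nearly flat early on — while `C` is
near zero the model observables are essentially uncorrelated with the
target, and the per-iteration similarity is noise. A stopping rule based
only on fit improvement over a window (including best-value rules)
therefore triggers spuriously within a few hundred iterations. The
implemented rule stops only when both (a) the windowed mean similarity
improves by less than `tol` per 50-iteration window and (b) the coupling
matrix itself changed by less than 1% in relative Frobenius norm over the
window; `tol = 0` disables early stopping. The returned matrix is the
iterate with the highest mean of the two similarities, which guards against
late-trace oscillation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `low_hz`, `high_hz` | 0.008, 0.08 | Hz | the standard resting-state band; also the band in which intrinsic frequencies are estimated |
| filter order | 2 | – | second-order Butterworth, applied forward-backward (zero phase) so the lag structure that `FCf` measures is not distorted |
| trim fraction | 0.05 | – | discard filter border effects at both ends |
| `a` | -0.02 | – | subcritical working point of every mode |
| `sigma` | 0.01 | signal units | oscillator noise; the acceptance suite uses this default |
| `dt` | 0.1 | s | Euler-Maruyama step, nudged to divide the TR exactly |
| `tau` | 3 | frames | forward shift of `FCf`; taken as given from the drop of the averaged autocorrelation |
| `varsigma` | 1e-5 | – | learning factor of the coupling update |
| `n_sim_avg` | 10 | – | simulations averaged per iteration (9 for rest-plus-task group sizes) |
| `kl_weight` | 1 | – | KL term weight; toy tests lower it when the goal is a near-deterministic reconstruction floor |
| kernel scale | sqrt(D) | – | Gaussian-kernel width on standardized features; box constraint 1 |

## The synthetic world

`make_ground_truth()` draws a sparse directed coupling (entry magnitudes
uniform in [0.05, 0.2], density 0.2 by default) blended between a symmetric
and a fully directed pattern by an `asymmetry` parameter, oscillators at
`a = -0.02` with frequencies inside the analysis band, and a random
well-conditioned linear mixing of M modes into N regions. The linear mixing
is deliberate: covariances, variances through the decoder, and the optimal
encoder (the mixing pseudo-inverse, available as `oracle_encode()`) all
have closed forms, so every pipeline stage can be checked against an
analytic oracle. What the generator does *not* emulate: hemodynamic
convolution, subject heterogeneity beyond fresh noise realisations,
amplitude distributions of real BOLD, and nonlinearity of the
mode-to-region map. A green parameter-recovery test therefore establishes
that the inference machinery recovers known directed coupling from
band-limited oscillatory data of realistic size — not that real fMRI
satisfies the model.

Scale choices in the acceptance suite (dimensions M = 6 mixed into N = 20
regions, 100 subjects of 800 frames at TR 0.72 s) follow the stated
recovery design. Model simulations inside the inference loop use 150-frame
segments: 150, 200, 400 and 800-frame segments were verified to give the
same recovery trajectory (the shorter segments only add per-iteration
estimation noise, which the accumulation over tens of thousands of
iterations averages out), and the short segments keep ten full recovery
runs inside a desktop time budget. With `varsigma = 1e-5` the coupling
magnitude grows by roughly `varsigma` per iteration times the discrepancy,
so recovery correlations cross 0.7 only after roughly twenty thousand
iterations; the acceptance test runs 35,000 per seed.

Two nonobvious facts about irreversibility surfaced during development and
shaped the tests. First, heterogeneous intrinsic frequencies break detailed
balance of the real-part observables on their own: even with perfectly
symmetric coupling, modes rotating at different rates have asymmetric
lagged cross-correlations. The nonreversibility comparison (symmetric vs
asymmetric ground truth) therefore uses a common intrinsic frequency within
each system, isolating coupling as the only irreversibility source. Second,
the Euler-Maruyama integrator has an O(dt) amplitude bias
(`r^2 = a + dt w^2 / 2` instead of `r^2 = a` on the limit cycle), so
analytic-limit tests run at `dt = 0.01`; the inference pipeline keeps
`dt = 0.1` for both data generation and model fitting, where the bias
cancels by construction.

## Numerical choices

- **Butterworth design.** No signal-processing package ships in this
  environment, so the band-pass is designed in-package via the analog
  prototype and bilinear transform with frequency pre-warping, and applied
  with odd-extension, steady-state-initialised forward-backward filtering.
  Tests compare against the analytic magnitude response.
- **VAE training.** The networks are small (tens of units), so forward and
  backward passes are plain R matrix algebra; gradients were verified by
  central finite differences. Optimisation is Adam (lr 1e-3 default),
  seeded, with reparameterised sampling per minibatch. The paper-scale
  defaults (batch 128, 50 epochs) are kept as package defaults; desk-scale
  toys in the tests train longer (250–300 epochs) because an epoch over
  ~10^3 frames provides orders of magnitude fewer gradient steps than an
  epoch over an HCP-scale pattern set.
- **Elbow rule.** The scan records held-out reconstruction error per latent
  dimension; the elbow is the smallest dimension beyond which the error
  drop falls under 10% of the initial drop — a formalisation of
  "derivative close to zero".
- **SVM.** A sequential-minimal-optimisation solver with
  maximal-violating-pair selection, written for this package because no R
  SVM implementation is available here; one-versus-one voting with
  summed-decision tie-breaks, stratified 90/10 splits, features
  standardized on each training fold.
- **RNG.** User-facing simulation uses R's RNG (seed arguments
  everywhere). The batched inference kernel draws its noise from an
  internal xoshiro256++/ziggurat generator seeded from the R stream: the
  inference loop consumes ~10^9 normal deviates per fit, and the internal
  generator makes that affordable without touching reproducibility.

## Degenerate inputs and edge rules

Constant columns make Pearson correlation undefined and raise errors naming
the column; `tau = 0` makes `FCf` collapse to `FC` exactly; thresholded
graphs use a strict inequality; group averaging drops the remainder after
partitioning; trimming removes `floor(fraction * T)` frames per end; the
coupling diagonal is pinned to zero everywhere (self-influence lives in
`a`). Scrambled-label classification of class-separable features shows a
small below-chance bias (finite-pool anti-correlation between training and
validation composition under permuted labels), strongest when classes are
far apart; the chance-control design keeps centroids at one noise SD, where
the measured mean accuracy is consistent with chance at 8 classes.

## Known limitations

- The inference is a heuristic pseudo-gradient, not a likelihood gradient:
  convergence to the observable fit does not guarantee identifiability of
  `C`, and at matched fit the recovered magnitudes are compressed relative
  to the truth (correlations plateau around 0.75–0.9 on the synthetic
  world, with perfect sign agreement).
- Recovery quality is budget-bound: with the prescribed learning factor the
  iteration count, not the data, is the binding constraint.
- The VAE is trained per dataset; no transfer or checkpoint format beyond R
  serialisation is provided.
- Hemodynamics, delays, and structural priors are out of scope by design.
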
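---
title: "Estimating the latency factor of a cue-based retrieval model by ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the latency factor of a cue-based retrieval model by ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueabc)
```

## The model

`cueabc` implements a simplified cue-based retrieval model of the kind
used in ACT-R accounts of sentence processing. The model abstracts away
from incremental parsing and considers a single retrieval event: a set of
retrieval cues is posted (for instance, *subject number* and *person* at a
verb), and a small set of candidate chunks in declarative memory compete
to be retrieved.

Each chunk's total activation on a retrieval attempt is

$$A_i = B_i + \sum_{j \in \text{matched}(i)} W_j\,(\mathrm{MAS} - \ln \mathrm{fan}_j)
\;-\; \mathrm{MP}\cdot m_i \;+\; \varepsilon_i,$$

where

* $B_i$ is the base-level activation: the constant $\beta$ by default, or
  $\beta - d\,\ln t_i$ when the chunk has an encoding time $t_i$ (single
  presentation with decay $d$). Because the simplified model has no
  parsing history, no multi-presentation base-level learning exists.
* The sum is spreading activation from the cues the chunk matches:
  $W_j$ is the source-activation weight of cue $j$ (equal shares of a
  total source activation of 1 by default) and $\mathrm{fan}_j$ the
  number of chunks associated with the cue's value — higher fan dilutes
  the associative strength $\mathrm{MAS} - \ln \mathrm{fan}_j$.
* $\mathrm{MP}\cdot m_i$ is the mismatch penalty, $m_i$ the number of
  cues whose required value chunk $i$ does not carry.
* $\varepsilon_i \sim \mathrm{Logistic}(0, \mathrm{ANS})$ — ANS is the
  *scale* of the logistic, not its variance, following ACT-R convention;
  this makes the single-chunk retrieval probability exactly
  $1/(1+\exp(-(A-\tau)/\mathrm{ANS}))$, which the test suite uses as a
  closed-form oracle.

The chunk with the highest sampled activation at or above the retrieval
threshold $\tau$ is retrieved, after a latency

$$T = F\,e^{-f A}\quad\text{(seconds)},$$

with latency factor $F$ and latency exponent $f$. If no chunk reaches
$\tau$, the retrieval fails and takes the time-to-threshold latency
$F\,e^{-f\tau}$ — a convention the framework leaves implicit and which we
state explicitly; ties (possible only with the noise switched off) are
broken by chunk declaration order. Latencies are kept in seconds
internally and converted to milliseconds exactly once, in the effect
simulator, to avoid double scaling.

### Parameters

| Parameter | Meaning | Default | Simulation preset |
|---|---|---|---|
| `F` | latency factor (s) | 0.2 | estimated (prior on (0,1)) |
| `f` | latency exponent | 1 | 1 |
| `tau` | retrieval threshold | −1.5 | −1.5 |
| `d` | decay rate | 0.5 | 0.5 |
| `ANS` | logistic activation-noise scale | 0.2 | 0.2 |
| `MAS` | maximum associative strength | 1 | 1.5 |
| `MP` | mismatch penalty | 1 | 0.25 |
| `beta` | base-level constant | 0 | 0 |

All parameters are held at their preset values except the latency factor,
which is the single estimated parameter; holding the rest constant avoids
overfitting any particular data set. Both presets are exposed through
`model_params(preset = )` because large-scale evaluations of this model
family used the `"simulation"` values for MAS and MP; the packaged
fixtures use the `"simulation"` preset throughout.

## From retrievals to an interference effect

An experiment pairs two retrieval conditions. The predicted interference
effect for a given latency factor $\theta$ is

$$\delta(\theta) = \overline{T}_{\text{interference}} - \overline{T}_{\text{baseline}}
\quad\text{(ms)},$$

each mean taken over `n_mc` Monte-Carlo retrievals (default 5000 per
condition). Facilitatory interference is therefore negative. Failed
retrievals contribute their failure latency to the mean — dropping them
would bias the contrast. Because activations do not depend on $F$,
$\delta(\theta)$ is exactly linear in $\theta$ for a fixed noise stream, a
property the tests assert.

`make_simulator()` fixes everything except $\theta$ and returns the
function the ABC loop calls. Under a `master_seed` every call runs on its
own deterministic sub-stream (replayable via `call_index`) and leaves the
caller's RNG untouched; a common-random-numbers flag shares one noise
stream across the two conditions for variance reduction. With
`ANS = 0` no random numbers are consumed at all and the whole pipeline is
deterministic.

## ABC rejection sampling

The observed effect enters as a normal approximation
$\mathcal{N}(\text{mean}, \text{SD}^2)$ in ms; when only a 95% credible
interval is available, `normal_approx_from_cri()` sets
$\mathrm{SD} = (\text{upper}-\text{lower})/(2\times 1.959964)$. A
user-supplied SD always takes precedence over the CrI arithmetic, because
published SDs are authoritative inputs even where they disagree slightly
with the printed interval (the `dillon_agreement` fixture carries such a
pair: SD 33 vs a CrI implying ≈27.3).

The sampler repeats: draw $\theta \sim \mathrm{Beta}(a, b)$ (default
Beta(2, 6), which downweights extreme latency factors while staying
relatively uninformative); simulate $\delta(\theta)$; accept iff
$\delta$ falls in the closed band
$[\text{mean} - k\,\mathrm{SD},\ \text{mean} + k\,\mathrm{SD}]$. The
default $k = 1$ constrains accepted simulations to within one SD of the
observed mean; larger $k$ gives a more broadly distributed posterior,
smaller $k$ a narrower one (asserted as a monotonicity test). Boundary
hits accept — a measure-zero choice that must still be defined. Sampling
stops after `n_accept` accepted draws (default 2000, with a proposal
budget of 2,000,000; exhausting it raises a diagnostic error with the
running acceptance rate, the symptom of a band the simulator cannot
reach). Every proposal gets a fresh simulator call; accepted effects are
stored for reuse by the predictive module.

Two analytic oracles pin the sampler down in the tests: with a
deterministic linear simulator the posterior must equal the prior
truncated to the preimage of the band (Kolmogorov–Smirnov against the
closed-form truncated Beta CDF), and with a constant simulator at the
observed mean the posterior must equal the prior.

## Prior and posterior predictive distributions

The prior predictive pushes fresh Beta draws through the simulator. The
posterior predictive approximates
$p(y_\mathrm{pred}\mid y) = \int p(y_\mathrm{pred}\mid\theta)\,
p(\theta\mid y)\,d\theta$ by resampling accepted $\theta$ with
replacement and, by default, re-running the simulator with fresh noise
(`resimulate = TRUE`); this integrates the parameter out instead of
conditioning on a point estimate. A `resimulate = FALSE` mode reuses the
stored accepted effects — faster, and every draw then lies inside the
acceptance band by construction. Re-generation with fresh noise is the
default because the predictive should reflect simulation variability, not
just the band constraint.

## The packaged fixtures

Four fixtures carry published interference-effect targets for
ungrammatical sentences, each with a Beta(2, 6) prior and the
`"simulation"` preset:

| Fixture | Target (ms) | SD (ms) | 95% CrI (ms) |
|---|---|---|---|
| `dillon_agreement` | −60 | 33 | [−112, −5] |
| `dillon_reflexive` | −18 | 27 | [−72, 36] |
| `jaeger_agreement` | −22 | 13 | [−46, 3] |
| `jaeger_reflexive` | −23 | 13 | [−48, 2] |

The chunk/cue structure of the original studies' simulations is not part
of the published record, so the fixtures use a canonical two-chunk
ungrammatical-interference design: the retrieval target matches one of
two cues (e.g. a subject with the wrong number), and the distractor
matches **both** cues in the interference condition while matching
neither in the baseline. This makes the interference condition's winning
activation strictly higher, so the effect is facilitatory (negative) for
*every* positive latency factor even with the noise switched off — the
qualitative signature these designs exhibit. The fixtures are illustrative
stand-ins, not replicas of the original condition files: with this
geometry the −22 ms target implies a posterior latency factor around
0.08, somewhat below the 0.1–0.25 range used in grid-search evaluations,
which would shift with a shallower cue geometry. What passes on these
fixtures therefore validates the estimation machinery, not any particular
linguistic analysis.

What the simulator deliberately does not emulate: trial-level reading-time
noise (participant and item variance), incremental parsing dynamics,
multi-retrieval schedules, or similarity-graded (non-binary) cue match.
The targets' SDs summarise the data-level uncertainty instead.

## Numerical and design choices

* **Problem sizes.** Defaults are `n_mc = 5000` retrievals per condition
  per proposal (Monte-Carlo SE well under the 13–33 ms bands),
  `n_accept = 2000`, 2000 predictive draws. The test suite runs smaller
  configurations (`n_mc` 1000–2000, hundreds of accepted draws) chosen so
  each statistical check retains its stated power; the parameter-recovery
  test defines its acceptance band relative to the simulator's *own* MC
  standard error, so it is invariant to `n_mc`.
* **Determinism.** `run_pipeline()` derives separate sub-seeds for the
  proposal stream, the simulator and the predictive resampling from one
  master seed; re-running with the same seed reproduces every artifact
  byte for byte.
* **Degenerate inputs.** Empty chunk lists, fan < 1, non-positive
  encoding times, Beta shapes ≤ 0, degenerate credible intervals and
  `k ≤ 0` all fail fast with named errors; `theta` outside `[0, ∞)` is a
  domain error in the simulator.
* **Interface.** The R functions are the primary interface;
  `run_pipeline()` plus the YAML config schema (see `?run_pipeline`)
  cover scripted use, and `inst/cli/cueabc.R` is a thin command-line
  wrapper (`run`, `simulate`, `prior-predictive`, `fixtures list`).

## Limitations

Rejection ABC is exact only in the limit of a shrinking band; with $k=1$
the posterior is a band-truncated object, not the exact Bayesian
posterior under a normal likelihood. The method generalises to kernels
and to ABC-MCMC for multi-parameter settings, which are out of scope
here. Single-parameter estimation also means the posterior absorbs any
misfit of the fixed parameters (MAS, MP, ANS, τ) and of the assumed cue
geometry.

## A short session

```{r example, eval = FALSE}
fx <- load_fixture("jaeger_agreement")
sim <- make_simulator(fx$experiment, fx$params, n_mc = 5000,
                      master_seed = 1)
post <- abc_reject(fx$prior, sim, fx$target, n_accept = 2000, seed = 2)
post
pred <- posterior_predictive(post, sim, n_draws = 2000, seed = 3)
summary(pred)
```
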
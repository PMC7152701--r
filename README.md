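# cueabc

Likelihood-free estimation of the latency factor in a cue-based retrieval
model of sentence processing.

## The problem

Cue-based (ACT-R style) retrieval models explain reading-time
interference effects — e.g. faster reading at an ungrammatical verb when
a distractor noun matches the verb's retrieval cues — through competition
among memory chunks. Each chunk's activation is

```
A = B + Σ_j W_j (MAS − ln fan_j) − MP · (mismatched cues) + ε,
ε ~ Logistic(0, ANS)
```

and the retrieval latency of the winning chunk (highest activation at or
above the threshold τ) is `T = F · exp(−f · A)` seconds. The latency
factor `F` scales model time onto the millisecond reading-time scale and
is the one parameter estimated from data; the remaining parameters stay
at their conventional values.

Because this generative model has no tractable likelihood, `cueabc`
estimates `F` by **Approximate Bayesian Computation with rejection
sampling**: draw `θ ~ Beta(2, 6)`, simulate the model's mean interference
effect `δ(θ)` (interference − baseline, in ms, over thousands of
Monte-Carlo retrievals), and accept `θ` iff `δ(θ)` falls within `k` SDs
(default 1) of the observed effect, stated as a normal approximation
`Normal(mean, SD²)` — optionally derived from a 95% credible interval.
Accepted draws approximate the posterior of `F`, and pushing them back
through the simulator gives the posterior predictive distribution of the
effect, with the parameter uncertainty integrated out. It is written for
computational psycholinguists and cognitive modellers who want parameter
uncertainty, rather than a grid-search point estimate, out of this model
family.

## Worked example

Estimate the latency factor for the packaged large-sample agreement
fixture, whose observed interference effect is −22 ms (SD 13 ms):

```r
library(cueabc)

fx   <- load_fixture("jaeger_agreement")
sim  <- make_simulator(fx$experiment, fx$params, n_mc = 5000,
                       master_seed = 1)
post <- abc_reject(fx$prior, sim, fx$target, n_accept = 2000, seed = 2)
post
#> ABC posterior of the latency factor: 2000 draws (11831 proposals, acceptance rate 0.169)
#>   median 0.079, 95% interval [0.033, 0.112]
#>   acceptance band: [-35, -9] ms (k = 1)

pred <- posterior_predictive(post, sim, n_draws = 2000, seed = 3)
summary(pred)
#> posterior predictive distribution of the effect (2000 draws):
#>   mean -23.54 ms, SD 7.33 ms, 95% interval [-34.64, -10.16] ms
```

Reading the output: only latency factors around 0.03–0.11 produce mean
effects inside the one-SD acceptance band [−35, −9] ms, so the posterior
concentrates there (median 0.079). The posterior predictive mean of
−23.5 ms sits near the observed −22 ms and is clearly facilitatory
(negative), with its spread reflecting both the remaining parameter
uncertainty and simulation noise.

`run_pipeline("jaeger_agreement", out_dir = "out", seed = 1)` wires the
same stages together and writes `samples.csv`, `predictive.csv` and
`metadata.json`; it also accepts a YAML config describing your own
two-condition design (see `?run_pipeline` and the vignette). A thin CLI
lives at `inst/cli/cueabc.R`.

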
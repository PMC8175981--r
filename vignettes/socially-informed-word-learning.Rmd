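---
title: "Socially informed word learning: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Socially informed word learning: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordtrust)
```

## The model

`wordtrust` implements a generative Bayesian account of how a young
learner might use *social* information — who is speaking — to interpret
object-labeling events. Each speaker belongs to an observable group
$G$ (say, adult humans versus inanimate audio speakers) with a
characteristic knowledgeability $\theta_g$:

$$P(K \mid G) = \mathrm{Bernoulli}(\theta_g)$$

Knowledgeability $K$ is binary. A knowledgeable speaker ($K = 1$)
always intends the object's correct label $C$; an unknowledgeable
speaker ($K = 0$) commits to one of the $n$ candidate labels uniformly
at random:

$$P(I \mid C, K{=}1) = \delta_{IC}, \qquad P(I \mid C, K{=}0) = 1/n$$

Crucially, the intention is drawn **once** per speaker–object pair and
repeated on every subsequent labeling: speakers are consistent.
Production is noiseless in this release ($D = I$), though the
intention and data stages are kept separate in the API so a
pronunciation-noise model can slot in later without interface changes.
Deceptive speakers — knowledgeable but deliberately mislabeling — are
outside the model: every informant is at worst uninformed.

Two consequences of consistency shape everything downstream:

* a speaker who produces the same token $t$ times contributes the
  likelihood of *one* intention draw, not $t$ independent draws
  (`sequence_likelihood()` is invariant to repetition count);
* a speaker producing two different tokens for the same object is an
  observation with probability zero, so such corpora are rejected at
  validation rather than silently assigned zero posterior mass.

The repetition semantics are not a free choice: under independent
draws, a lone speaker repeating a novel label seven times would drive
the label posterior to ≈ 0.999, whereas one intention draw leaves it at
exactly $2/3$ — which is the single-speaker behavior the model is
meant to exhibit (habituation to one voice teaches you little about
whether that voice is reliable).

## Inference

### Knowledgeability from one labeling event

When the category is known (a familiar object), a single token updates
the learner's belief about the speaker. Bayes' rule with likelihoods
$(1, 1/n)$ for a correct token and $(0, 1/n)$ for an incorrect one
gives $P(K \mid D, G, C)$; an incorrect token collapses belief to
$K = 0$ because knowledgeable speakers never err. The *informativeness*
of the event is the KL divergence between posterior and prior,

$$D_{KL}\big(P(K \mid D, G, C)\,\|\,P(K \mid G)\big)
  = \sum_K P(K \mid D, G, C)\,\log_2 \frac{P(K \mid D, G, C)}{P(K \mid G)},$$

which the package treats as an ordinal looking-time index: more
surprising events predict longer looking. No mapping from bits to
seconds is attempted — the linkage is qualitative only, and the package
deliberately provides no such calibration.

All divergences are reported in **bits** (base-2 logs) by default; the
`log_base` argument changes units. Two numerical conventions matter:
$0 \cdot \log(0/q) \equiv 0$, and mass in the posterior where the prior
has none raises a structured error
(`wordtrust_undefined_divergence`) instead of returning `Inf` — this is
the situation after an incorrect token from a group believed
knowledgeable with certainty ($\theta = 1$), where the observation
itself is impossible under the model.

On the default parameters the four cells are:

```{r sim1}
run_simulation1()
```

The incorrect-adult cell dominates: an informant presumed reliable who
errs is maximally surprising. Note the model predicts a *small*
reversal for the low-trust group (correct tokens slightly less
informative than incorrect ones at $\theta = 0.15$), shrinking to zero
as $\theta \to 0$.

**Parameter note.** The default is $\theta_{adult} = 0.80$,
$\theta_{audio} = 0.15$, $n = 3$. With $\theta_{adult} = 0.85$ the
incorrect-adult divergence would be $-\log_2(0.15) = 2.7370$; only
$\theta_{adult} = 0.80$ yields the reference value
$\log_2 5 = 2.3219$ together with the other three cells
(2.3219, 0.2345, 0.1701, 0.0845), so 0.80 is the default and 0.85
remains available through the arguments. The correct-adult cell
evaluates to 0.084531; reference tabulations that show 0.0846 differ
only in the last printed digit.

The interaction sweep (`run_simulation1_sweep()`) evaluates, over a
grid of $(\theta_{human}, \theta_{audio})$ pairs, the
incorrect-minus-correct informativeness gap of the human group minus
that of the audio group. By construction the matrix is zero on the
diagonal (equal trust in both groups predicts no interaction) and
antisymmetric; it is positive where the human group is the more
trusted. The heatmap uses a diverging palette centered at zero so the
diagonal reads as neutral; the grid default (19 points over
$[0.05, 0.95]$) is presentation only — the qualitative claims hold at
any resolution, and $\theta = 1$ is excluded because the incorrect-event
divergence is undefined there.

### Joint label-and-reliability inference

For a novel object the learner infers the category and each speaker's
knowledgeability jointly. With $m$ speakers the hypothesis space is
$\{C\} \times \{0,1\}^m$ — $n \cdot 2^m$ hypotheses — and

$$P(C, \vec{K} \mid \vec{D}) \propto
  P(C) \prod_{j=1}^{m} P(K_j)\, P(D_j \mid C, K_j).$$

`joint_posterior_exact()` enumerates this space (asserting its size
before scoring) and marginalizes over $\vec{K}$ for the label
posterior. The enumeration cap defaults to $m = 20$ speakers (3 × 2^20 ≈
3 million hypotheses); beyond it the function refuses and directs the
caller to the Gibbs sampler — exponential growth in $m$ is exactly why
a sampler is part of the package.

`gibbs_posterior()` alternates the two full conditionals
$P(C \mid \vec{K}, \vec{D})$ and, per speaker,
$P(K_j \mid C, D_j)$, in a systematic scan (category first, then
speakers in order). Defaults: 20,000 kept sweeps after 2,000 burn-in,
one chain, seeded, initialized at all-$K = 0$ — a state in the support
of any consistent corpus, so no repair is normally needed (a repair
counter is reported in the diagnostics regardless). Estimates are raw
post-burn-in draw frequencies; a Rao–Blackwellized label estimator
(averaging $P(C \mid \vec{K}, \vec{D})$ over sweeps) is available via
`gibbs_settings(rao_blackwell = TRUE)` but off by default so the
default output mirrors a plain sampler. Diagnostics include a
per-label effective sample size from the initial positive window of the
autocorrelation function.

### The habituation simulation

```{r sim2}
run_simulation2("single")
run_simulation2("multiple", method = "exact")
```

One speaker repeating a novel label seven times leaves the label
posterior at exactly $2/3$ (repetition adds nothing once consistency
is assumed), while seven agreeing speakers drive it to
$1/(1 + 2 \cdot 4^{-7}) = 0.999878$: agreement is evidence that the
speakers are knowledgeable, hence that the shared label is correct.
The closed form $P(\text{agreed label}) = 1/(1 + 2\cdot 4^{-m})$
(for $n = 3$, $k$-prior $0.5$) follows from the per-speaker marginal
likelihoods $2/3$ (agreeing category) and $1/6$ (other categories),
and the test suite checks it against enumeration for $m = 1,\dots,7$.
A Gibbs estimate of the multiple-speaker cell is validated against the
enumeration oracle (within ±0.002 at 20,000 sweeps); reference
tabulations of this quantity produced by sampling (e.g., 0.9992)
carry Monte-Carlo error of their own, so the oracle — not any printed
sampled figure — is the ground truth the sampler is held to.

## The synthetic-corpus generator

`sample_corpus()` draws corpora from the generative process itself:
per speaker, $K \sim \mathrm{Bernoulli}(\theta_g)$, then one fixed
intention per object (truth if knowledgeable, uniform otherwise),
then `tokens_per_speaker_object` identical tokens. Consistency holds by
construction, so every generated corpus passes validation. One root
seed in the design drives everything: speaker $i$ samples on a stream
seeded `root + 1009 * i (mod 2^31 - 1)`, and replicate $r$ of
`recovery_experiment()` uses offset `100000 + r`, so corpora and
sampler runs are independently reproducible.

`recovery_experiment()` closes the loop: sample, infer with priors
matched to the generative settings (each speaker's $k$-prior is its
group's $\theta_g$; uniform label prior), and score MAP-label accuracy
and posterior mass on the truth. MAP ties break by label declaration
order, for determinism. With $\theta = 0.9$ and ten speakers the truth
is recovered essentially always; a lone $\theta = 0$ speaker leaves the
posterior at the uniform $1/3$, as symmetry demands.

What the generator does *not* emulate: production noise, graded or
drifting knowledgeability, deception, belief updating across trials,
or real acoustic/phonetic variability. Passing recovery tests
therefore show that inference is correct *under the model's own
assumptions*, not that the model is a complete account of real infant
input.

## Numerical and design notes

* Distributions are validated to sum to 1 within 1e-9 (1e-12 for the
  binary knowledgeability beliefs).
* Multi-object corpora are supported by the data structures and the
  generator, but joint $(C, \vec{K})$ inference is defined per object
  ($C$ is one category variable); `recovery_experiment()` subsets by
  object and does not pool knowledgeability evidence across objects.
  Both simulations are single-object, so nothing in scope is lost.
* `k_prior` may be a scalar (shared) or a named per-speaker vector;
  group $\theta$ maps attached to a corpus describe its provenance and
  are used as matched priors in recovery, while inference functions
  take priors explicitly.
* Problem sizes in the test suite — 200 random designs for the
  consistency property, 150–300 recovery replicates, 20,000–50,000
  Gibbs sweeps — were chosen so the full suite completes in well under
  a minute while keeping Monte-Carlo error far below the asserted
  tolerances.

## Limitations

The model is intentionally minimal: binary knowledgeability, fixed
group parameters (never estimated from data), no cross-trial belief
updating, and an ordinal-only link from KL divergence to looking time.
These are scope decisions, not oversights; each marks a place where
the framework could be extended.
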
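---
title: "Temporal structure and belief updating in discrete active inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal structure and belief updating in discrete active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TemporalInference)
```

## The problem this package computes

Computational models of perception usually advance in a rigid sequence
of objective time steps, while lived time is experienced as a flowing
present that carries the just-past (retention) and the about-to-occur
(protention) inside it. This package makes that tension computable for
discrete active-inference models — which, once action selection is
stripped away, reduce to hidden Markov models. It does three things:

1. **Temporal graphs.** It builds the three temporal orders as Bayesian
   networks: a *sequential* chain (objective time), an *interpenetrated*
   structure where past and future both point into the present (a
   collider), and the *integrated continuity*, a lattice over pairs
   (objective step $t$, subjective offset $\tau$) that is bidirectional
   at each event while advancing unidirectionally. Conditional-independence
   structure is interrogated with Markov blankets and a brute-force
   d-separation oracle.
2. **Belief updating.** It implements the softmax message-passing
   equations over that structure, including the stationary fixed point,
   the free-energy gradient sweep, and surprisal of incoming outcomes.
3. **Validation.** It ships an exact forward–backward smoother and a
   joint-enumeration oracle, so every approximate quantity can be
   compared against ground truth.

## The generative model

A model is the triple $(A, B, D)$: a likelihood matrix $A$ with
$A_{os} = p(o \mid s)$, one or more transition matrices $B$ with
$B_{s's} = p(s' \mid s)$, and an initial prior $D$. All matrices are
column-stochastic — columns index the conditioning variable — so
$A s$ and $B s$ are plain matrix–vector products. Validation is data,
not exceptions: `validateModel()` returns one row per violated
invariant (column sums within $10^{-12}$ of 1, entries in $[0,1]$,
consistent dimensions), and the file loader enforces it.

```{r}
m <- makeMelodyModel(progressionFidelity = 0.9, toneNoise = 0.05)
m
validateModel(m)
```

## The update equations

Write $s_\tau$ for the expected state (belief) at index $\tau$,
$v_\tau = \ln s_\tau$ for its message potential, and $\sigma$ for the
softmax operator. The message sum feeding index $\tau$ is

$$m_\tau = \ln B_{\tau-1}\, s_{\tau-1} \;+\; \ln B_\tau^\top s_{\tau+1}
  \;+\; \ln A[o_\tau,\cdot],$$

a forward (prior) term, a backward (prediction) term, and a likelihood
term. The dynamics are an explicit Euler step on the potential,

$$s_\tau^{t+\Delta t} = \sigma\big(v_\tau^t + \Delta t\,(m_\tau - v_\tau^t)\big),$$

whose fixed points are exactly the stationary solutions
$s_\tau = \sigma(m_\tau)$. Under the *integrated* index convention the
same three messages are relabelled as the living-inference triplet —
prior protention $s_{\tau+1}^{t-1}$ (read from the previous sweep, so
each sweep advances one objective step), predicted primal impression
$s_{\tau+1}^{t}$, and likely retention $o_{\tau-1}^{t}$ — so every
interior update consumes coordinates at two distinct objective times.

Two phenomenological requirements are checked as executable tests: the
present belief must respond to perturbations of both the retained
observation and the protention message (the present is never a bare
"now"), and integrated updates must read more than one objective-time
coordinate (objective and subjective structure intertwine).

### Why the sweep is a true descent

The chain free energy implemented here is the standard mean-field bound

$$F = \sum_\tau E_q\!\left[\ln q(s_\tau) - \ln p(s_\tau \mid s_{\tau-1})
  - \ln p(o_\tau \mid s_\tau)\right],$$

with the first index using $D$. The negative coordinate gradient of $F$
in potential space is exactly $m_\tau - v_\tau$ (up to an additive
constant that softmax ignores), and along the segment from $v$ toward
$m$ the derivative of $F$ is $-(v-m)^\top J_\sigma (v-m) \le 0$, where
$J_\sigma$ is the positive-semidefinite softmax Jacobian. Each
coordinate step with $\Delta t \le 1$ therefore cannot increase $F$:
the monotone-descent property asserted in the test battery is exact,
not approximate. $F$ always upper-bounds the negative log evidence,
which the exact oracle computes independently.

### Numerical choices

- **Log floor.** Probabilities are floored at $10^{-16}$ before any
  logarithm, so deterministic matrices are first-class inputs. A
  consequence worth knowing: softmax never returns exact zeros, so in
  "noiseless" scenarios an impossible outcome acquires surprisal of
  roughly $-\ln(\text{tolerance tails}) \approx 25$ nats rather than
  $+\infty$; `surprisal()` itself returns `Inf` only when the
  predictive probability is exactly zero.
- **Step size and stopping.** Defaults are $\Delta t = 0.1$, tolerance
  $10^{-8}$ on the largest per-sweep belief change, and a 10,000-sweep
  cap. Values $\Delta t > 1$ are permitted but overshoot; they exist to
  demonstrate (and test) flagged non-convergence, which is reported in
  the convergence record, never thrown.
- **Sweep schedule.** Indices update in ascending order within each
  sweep (deterministic Gauss–Seidel), so runs are bit-reproducible.
- **Boundaries.** At $\tau = 1$ the missing forward/retention message
  is replaced by $\ln D$; at the last index the future-side messages
  are omitted. Boundary nodes of finite lattices are flagged and
  excluded from blanket-minimality checks, since the unbounded diagram
  must be truncated somewhere.
- **`ln B s` is ambiguous.** The elementwise reading
  $(\ln B)\,s$ is the default; the marginal reading $\ln(B s)$ is
  available via `updateConfig(logConvention = "marginal")`. The two
  sit on opposite sides of a genuine trade-off that the test batteries
  expose: the elementwise reading makes the sweep an exact descent of
  $F$ (above), but its fixed points are overconfident relative to
  exact smoothing, beating the uniform baseline in
  $\mathrm{KL}(\text{exact}\,\|\,\cdot)$ on about 84% of random
  desk-scale instances; the marginal reading beats uniform on about
  97% of instances but loses guaranteed monotone descent (observed
  violations up to $\sim 5 \times 10^{-4}$ nats per step). The package
  keeps the elementwise default for its exact Lyapunov property and
  leaves the stricter oracle-agreement rate to the marginal flag.

## The Markov blanket of the present moment

In the integrated lattice, the parents of the hidden node at
$(t, \tau)$ are the hidden nodes at $(t-1, \tau+1)$ and $(t, \tau+1)$
and the observation at $(t, \tau-1)$, applied homogeneously. The
blanket of the present reference node is its parent triplet (the
present row has no children), which is verified exhaustively by
d-separation and, on graphs small enough, shown minimal by
leave-one-out reconnection:

```{r}
dag <- buildTemporalDAG("integrated", objectiveHorizon = 4,
                        subjectiveDepth = 2)
bl <- markovBlanket(dag)
bl
blanketAsynchrony(bl)
```

The asynchrony record quantifies the imbalance: one member lies
strictly in the objective past and none strictly in the future, while
the future enters through the subjective (protention) offsets — past
and future are preserved in the present in an eschewed, asynchronous
way rather than symmetrically.

## The melody experiment

The four-tone melody A→B→C→D is modelled with five hidden states (four
tones plus silence): the progression advances with probability $p$,
residual mass falls to silence (the abrupt end), tone D resolves into
silence, and tones are heard correctly with probability $1-q$. Before
each incoming tone the engine sweeps over the observed prefix, forms
the one-step predictive belief, and scores the incoming outcome:

```{r}
trunc <- runMelodyDemo(fidelity = 1, noise = 0, condition = "truncated")
round(trunc$surprisal, 3)
```

With $p = 1, q = 0$ the anticipated D carries zero surprisal while the
abrupt end is maximally surprising. A closed form worth recording: the
predictive probability of hearing D versus hearing silence after
A,B,C differs by $(2p-1)(1-\tfrac{3q}{4})$, so the anticipated
continuation is the *less* surprising outcome exactly when
$p > 1/2$ — below that fidelity the model itself anticipates the
abrupt end, and the ordering reverses. The abrupt-end surprisal is
$-\ln(1-p)$ in the noiseless case, monotone in $p$.

## The serial-dependence experiment

Independent uniform stimuli on a circular 12-state space are observed
through a wrapped-Gaussian likelihood (default width 1.5 states). Each
trial's posterior is smoothed through a circular kernel (default width
1.5 states) and carried into the next trial as its prior — retention
as re-used information. Estimates are posterior circular means (a MAP
readout would quantize away small shifts), and the attraction
statistic is the mean signed error projected onto the previous
observation's direction. Stimuli and observations are drawn once from
the seed before inference, so kernel settings can be compared on
identical data; a uniform kernel severs retention and the bias
vanishes, a noiseless likelihood pins the posterior and the bias also
vanishes.

```{r}
sd <- runSerialDependenceDemo(nTrials = 300, seed = 1)
c(attraction = sd$attractionStatistic, se = sd$standardError)
```

## What the synthetic generators do and do not show

All inputs are synthetic: random column-stochastic models with flat
Dirichlet columns (2–5 states, 3–8 steps — the desk scale at which
joint enumeration stays exact and the whole battery runs in minutes),
the melody scenario, and the circular serial-dependence world. They
exercise normalization, stationarity, descent, oracle agreement and
the two scenario-level effects. They do not emulate real
psychophysics: stimuli are i.i.d., the likelihood and kernel are
homogeneous, and no human data are fit, so passing tests certify the
inference machinery and the qualitative phenomena, not quantitative
correspondence with experiments.

## Known limitations

- Action selection, policies and expected free energy are out of
  scope; the engine analyses belief propagation only.
- The interpenetrated order is implemented purely structurally; what
  relation holds between retention and protention under the collider
  is left open, as is whether protention nodes deeper than one step
  should ever be observed (here all future-side nodes stay latent and
  all past-side observation nodes are observed).
- Whether the integrated convention's transition matrix should differ
  per objective time is representable (a list of B matrices) but
  defaults to a single shared matrix.
- d-separation uses exhaustive path enumeration — transparent, and
  entirely adequate for the tens-of-nodes graphs built here, but not
  for large networks.
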
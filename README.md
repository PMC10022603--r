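# TemporalInference

Tools for analysing the *temporal* structure of discrete
active-inference models — for computational-phenomenology and
computational-neuroscience researchers who want the relationship
between objective time and experienced (subjective) temporality to be
something they can compute with, not just diagram.

Once action selection is removed, a discrete active-inference agent is
a hidden Markov model with likelihood matrix **A** (`p(o | s)`,
outcomes × states, column-stochastic), transition matrices **B**
(`p(s' | s)`), and initial prior **D**. The package provides:

- **Temporal graphs.** Three conditional-dependency orders built as
  DAGs: the *sequential* chain of objective time; the
  *interpenetrated* order of subjective temporality, where past and
  future both point into the present (a collider); and the *integrated
  continuity*, a lattice over (objective step *t*, subjective offset
  *τ*) in which each hidden node at (t, τ) depends on hidden nodes at
  (t−1, τ+1) and (t, τ+1) and an observation at (t, τ−1). Markov
  blankets of the present are extracted by the parents/children/
  co-parents rule and verified (correctness *and* minimality) by an
  exhaustive d-separation oracle.
- **Belief updating.** The softmax message-passing scheme

  s<sub>τ</sub> = σ( ln B<sub>τ−1</sub> s<sub>τ−1</sub> + ln B<sub>τ</sub><sup>⊤</sup> s<sub>τ+1</sub> + ln A[o<sub>τ</sub>, ·] ),

  its relabelled "living-inference" form (prior protention, predicted
  primal impression, likely retention), an explicit-Euler gradient
  sweep on the variational free energy whose fixed points are exactly
  these stationary solutions (and which provably never increases F for
  Δt ≤ 1), free-energy decompositions, and outcome surprisal.
- **Exact oracles.** Scaled forward–backward smoothing and brute-force
  joint enumeration, for ground-truth marginals and log evidence.
- **Demos.** Two seeded experiments: melody surprise (protentional
  fulfilment vs. the surprising abrupt end) and serial dependence
  (attractive perceptual bias from retained priors), plus a CLI.

## Worked example

```r
library(TemporalInference)

## The integrated-continuity lattice and the blanket of the present
dag <- buildTemporalDAG("integrated", objectiveHorizon = 4, subjectiveDepth = 2)
bl  <- markovBlanket(dag)
bl
#> MarkovBlanket of s.t1.tau0: 3 members
#>   s.t0.tau1, s.t1.tau1, o.t1.tau-1
blanketAsynchrony(bl)
#> $objectiveSpan [1] 1   $pastCount [1] 1   $futureCount [1] 0
#> $imbalanced [1] TRUE
```

The blanket of the present hidden node is its living-inference
triplet: the protention carried from the previous objective step, the
predicted primal impression at the current step, and the retained
observation. One member lies strictly in the objective past and none
strictly in the future — the asynchronous imbalance through which past
states persist into the present.

```r
## Smoothing a melody and comparing against the exact oracle
m   <- makeMelodyModel(progressionFidelity = 0.9, toneNoise = 0.05)
fit <- gradientSweep(beliefLattice(m, c(1L, 2L, 3L, 4L)))
round(beliefs(fit$lattice), 3)
#>         tau1 tau2 tau3  tau4
#> A          1    0    0 0.000
#> B          0    1    0 0.000
#> C          0    0    1 0.000
#> D          0    0    0 0.999
#> silence    0    0    0 0.001
fb <- forwardBackward(m, c(1L, 2L, 3L, 4L))
c(freeEnergy(fit$lattice)$value, -logEvidence(fb))
#> [1] 0.5198 0.5198          # F attains its evidence bound here
```

```r
## Melody surprise: the abrupt end vs. the protended D (nats)
comp  <- runMelodyDemo(0.9, 0.05, "completed")
trunc <- runMelodyDemo(0.9, 0.05, "truncated")
rbind(completed = comp$surprisal, truncated = trunc$surprisal)
#> completed 0.051 0.155 0.157 0.157
#> truncated 0.051 0.155 0.157 2.230
```

Hearing D after A, B, C costs 0.157 nats; the abrupt end costs
2.230 nats — the violated protention is the surprising event. With a
deterministic progression (fidelity 1, noise 0) the anticipated D
costs exactly 0.

```r
## Serial dependence: retained priors attract the current estimate
sd <- runSerialDependenceDemo(nTrials = 1000, seed = 1)
c(attraction = sd$attractionStatistic, se = sd$standardError)
#> attraction 0.580   se 0.052      # sign-test p = 1.3e-45
```

With a uniform carry-over kernel (no retention) the statistic falls
within two standard errors of zero; with a noiseless likelihood it is
exactly zero.

## Command line

```sh
Rscript inst/scripts/temporal-inference graph --order integrated --horizon 4 --depth 2 --out out/
Rscript inst/scripts/temporal-inference infer --model inst/extdata/melody_model.yaml \
    --obs inst/extdata/melody_observations.csv --out out/
Rscript inst/scripts/temporal-inference demo serialdep --seed 1 --n-trials 1000 --out out/
```

`graph` writes DOT + JSON (including the present node's blanket),
`infer` writes belief trajectories, a convergence record, and an
exact-oracle comparison, `demo` writes result tables and a JSON
summary. Logs go to stderr; results go to files.

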
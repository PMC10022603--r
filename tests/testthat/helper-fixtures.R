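## Seeded random-instance generators shared across the test files.
## All fixtures are built in code; nothing is stored on disk.

## a random model + observation sequence with dimensions drawn from the
## desk-scale ranges used throughout the batteries (2-5 states, 3-8 steps)
sampleRange <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

randomInstance <- function(seed, minStates = 2L, maxStates = 5L,
                           minSteps = 3L, maxSteps = 8L) {
  set.seed(seed)
  n <- sampleRange(minStates, maxStates)
  m <- sampleRange(2L, 5L)
  T <- sampleRange(minSteps, maxSteps)
  model <- randomModel(n, m, seed = seed + 7L)
  obs <- sampleProcess(model, T, seed = seed + 13L)$observations
  list(model = model, obs = obs, n = n, m = m, T = T)
}

## deterministic cyclic-permutation model: noiseless A, deterministic B
deterministicModel <- function(n = 3L) {
  B <- diag(n)[, c(2:n, 1L)]  # cyclic advance: state k -> k + 1
  generativeModel(diag(n), B, c(1, rep(0, n - 1L)))
}

## uniform model: every distribution flat
uniformModel <- function(n = 3L, m = 4L) {
  generativeModel(matrix(1 / m, m, n), matrix(1 / n, n, n), rep(1 / n, n))
}

## KL(p || q) with q floored
klDivergence <- function(p, q, eps = 1e-16) {
  sum(ifelse(p > 0, p * (log(p) - log(pmax(q, eps))), 0))
}

## smoothed beliefs of a converged sweep
convergedBeliefs <- function(model, obs, config = updateConfig()) {
  gradientSweep(beliefLattice(model, obs), config)
}
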
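test_that("softmax normalizes, inverts logs, and is shift-invariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(log(c(0.8, 0.2))), c(0.8, 0.2), tolerance = 1e-14)
  ## large potentials: compare with the closed form after max-shifting
  out <- softmax(c(1000, 1000, 999))
  expect_true(all(is.finite(out)))
  expect_equal(out, c(1, 1, exp(-1)) / (2 + exp(-1)), tolerance = 1e-14)
  v <- rnorm(5)
  expect_equal(softmax(v), softmax(v + 123.4), tolerance = 1e-12)
  expect_error(softmax(c(1, Inf)), "finite")
  expect_error(softmax(c(1, NA)), "finite")
})

test_that("present-moment inference fuses protention, primal impression and retention", {
  m <- uniformModel(3, 3)
  u <- rep(1 / 3, 3)
  expect_equal(presentMomentInference(u, u, 1L, m), u)

  det <- deterministicModel(3)  # noiseless A
  d2 <- c(0, 1, 0)
  expect_equal(presentMomentInference(d2, d2, 2L, det), d2,
               tolerance = 1e-10)

  ## product-of-factors oracle on a random 3-state instance
  set.seed(31)
  mod <- randomModel(3, 4, seed = 31)
  for (rep in 1:20) {
    prot <- softmax(rnorm(3)); prim <- softmax(rnorm(3))
    o <- sample(4, 1)
    direct <- prot * prim * likelihood(mod)[o, ]
    direct <- direct / sum(direct)
    expect_equal(presentMomentInference(prot, prim, o, mod), direct,
                 tolerance = 1e-10)
  }
  expect_error(presentMomentInference(u, u, 9L, m), "outcome index")
  expect_error(presentMomentInference(c(0.5, 0.5), u, 1L, m), "state")
})

test_that("stationary update agrees with consistent evidence", {
  det <- deterministicModel(3)
  obs <- sampleProcess(det, 4, seed = 1)$observations
  lat <- beliefLattice(det, obs)
  fit <- gradientSweep(lat)
  for (tau in 1:4) {
    s <- stationaryUpdate(fit$lattice, tau)
    expect_equal(which.max(s), obs[tau])
    expect_gt(max(s), 1 - 1e-9)
  }
  uni <- uniformModel(3, 3)
  latU <- beliefLattice(uni, c(1L, 2L, 3L))
  expect_equal(stationaryUpdate(latU, 2), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(stationaryUpdate(latU, 9), "index")
})

test_that("stationary updates are fixed points of the dynamics", {
  for (seed in c(3, 14, 27)) {
    inst <- randomInstance(seed)
    fit <- convergedBeliefs(inst$model, inst$obs)
    expect_true(fit$record$converged)
    for (tau in seq_len(inst$T)) {
      lat <- fit$lattice
      lat@beliefs[, tau] <- stationaryUpdate(fit$lattice, tau)
      expect_lt(TemporalInference:::updateResidualAt(lat, tau), 1e-8)
    }
    ## and the sweep converged to the pointwise fixed point
    su <- vapply(seq_len(inst$T),
                 function(t) stationaryUpdate(fit$lattice, t),
                 numeric(nStates(inst$model)))
    expect_lt(max(abs(beliefs(fit$lattice) - su)), 1e-6)
  }
})

test_that("gradient sweep stops immediately on a converged lattice", {
  inst <- randomInstance(8)
  fit <- convergedBeliefs(inst$model, inst$obs)
  again <- gradientSweep(fit$lattice)
  expect_equal(again$record$iterations, 1L)
  expect_lt(again$record$maxChange[1], 1e-8)
})

test_that("sweeps agree with direct fixed-point iteration", {
  inst <- randomInstance(55, minStates = 4L, maxStates = 4L,
                         minSteps = 5L, maxSteps = 5L)
  fit <- convergedBeliefs(inst$model, inst$obs,
                          updateConfig(stepSize = 0.1))
  ## direct iteration: full steps on the stationary map
  lat <- beliefLattice(inst$model, inst$obs)
  for (k in 1:500)
    for (tau in 1:5)
      lat@beliefs[, tau] <- stationaryUpdate(lat, tau)
  expect_lt(max(abs(beliefs(fit$lattice) - beliefs(lat))), 1e-6)
})

test_that("an overshooting step size is flagged, not thrown", {
  m <- randomModel(3, 3, seed = 2, concentration = 0.2)
  obs <- sampleProcess(m, 5, seed = 2)$observations
  fit <- gradientSweep(beliefLattice(m, obs),
                       updateConfig(stepSize = 2, maxIterations = 500))
  expect_false(fit$record$converged)
  expect_equal(fit$record$iterations, 500L)
})

test_that("free energy is zero for a perfect fit and T log m for the uniform case", {
  det <- deterministicModel(3)
  obs <- c(1L, 2L, 3L, 1L)
  exactBeliefs <- vapply(obs, function(o) as.numeric(seq_len(3) == o),
                         numeric(3))
  lat <- beliefLattice(det, obs, init = exactBeliefs)
  fe <- freeEnergy(lat)
  expect_equal(fe$value, 0)
  expect_equal(sum(fe$decomposition$value), fe$value, tolerance = 1e-9)

  ## uniform model and beliefs: complexity vanishes, accuracy costs
  ## T log(n_outcomes) nats, exactly the negative log evidence
  uni <- uniformModel(3, 4)
  obsU <- c(1L, 2L, 3L)
  latU <- beliefLattice(uni, obsU)
  expect_equal(freeEnergy(latU)$value, 3 * log(4), tolerance = 1e-12)
  expect_equal(-logEvidence(forwardBackward(uni, obsU)), 3 * log(4),
               tolerance = 1e-12)
})

test_that("free energy descends along sweeps and bounds the evidence", {
  for (seed in seq(101, 120)) {
    inst <- randomInstance(seed)
    fit <- convergedBeliefs(inst$model, inst$obs)
    expect_true(all(diff(fit$record$freeEnergy) <= 1e-9))
    lz <- logEvidence(forwardBackward(inst$model, inst$obs))
    expect_gte(freeEnergy(fit$lattice)$value, -lz - 1e-9)
  }
})

test_that("every belief-returning operation yields normalized vectors", {
  set.seed(77)
  for (rep in 1:30) {
    inst <- randomInstance(200 + rep)
    expect_equal(sum(softmax(rnorm(inst$n, sd = 10))), 1, tolerance = 1e-12)
    prot <- softmax(rnorm(inst$n)); prim <- softmax(rnorm(inst$n))
    o <- sample(inst$m, 1)
    expect_equal(sum(presentMomentInference(prot, prim, o, inst$model)), 1,
                 tolerance = 1e-10)
    fit <- convergedBeliefs(inst$model, inst$obs)
    expect_true(all(abs(colSums(beliefs(fit$lattice)) - 1) < 1e-10))
    expect_equal(sum(stationaryUpdate(fit$lattice, 1)), 1,
                 tolerance = 1e-10)
  }
})

test_that("surprisal matches its closed forms and signals impossibility", {
  det <- deterministicModel(4)
  expect_equal(surprisal(det, c(0, 1, 0, 0), 2L), 0)
  expect_equal(surprisal(det, rep(0.25, 4), 3L), log(4), tolerance = 1e-12)
  expect_identical(surprisal(det, c(0, 1, 0, 0), 3L), Inf)

  m <- makeMelodyModel(1, 0)
  afterC <- c(0, 0, 0, 1, 0)  # protention fulfilled: state D next
  expect_equal(surprisal(m, afterC, 4L), 0)
  expect_identical(surprisal(m, afterC, 5L), Inf)
  expect_error(surprisal(m, afterC, 6L), "outcome index")
})

test_that("the integrated convention reads both objective steps", {
  inst <- randomInstance(12, minSteps = 5L, maxSteps = 5L)
  lat <- beliefLattice(inst$model, inst$obs, convention = "integrated")
  for (tau in 2:4) {
    fp <- updateFootprint(lat, tau)
    expect_gte(length(unique(fp$objectiveOffset)), 2L)
    expect_true("observation" %in% fp$kind)
    expect_true(all(fp$subjective[fp$kind == "belief"] == tau + 1L))
    expect_true(all(fp$subjective[fp$kind == "observation"] == tau - 1L))
  }
  fit <- gradientSweep(lat)
  expect_true(fit$record$converged)
  expect_true(all(abs(colSums(beliefs(fit$lattice)) - 1) < 1e-10))
})

test_that("update configuration rejects nonsense", {
  expect_error(updateConfig(stepSize = 0), "stepSize")
  expect_error(updateConfig(tolerance = -1), "tolerance")
  expect_error(updateConfig(logFloor = 0), "logFloor")
  expect_error(updateConfig(maxIterations = 0), "maxIterations")
})
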
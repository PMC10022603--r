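test_that("validateModel reports violations as data", {
  ok <- generativeModel(diag(4), diag(4), rep(0.25, 4))
  expect_equal(nrow(validateModel(ok)), 0L)

  A <- diag(4); A[1, 1] <- 0.9   # column 1 sums to 0.9
  bad <- generativeModel(A, diag(4), rep(0.25, 4), check = FALSE)
  v <- validateModel(bad)
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "column sum")
  expect_equal(v$residual, -0.1, tolerance = 1e-12)

  A2 <- diag(4); A2[2, 1] <- -0.5; A2[1, 1] <- 1.5
  bad2 <- generativeModel(A2, diag(4), rep(0.25, 4), check = FALSE)
  v2 <- validateModel(bad2)
  expect_true(any(v2$type == "out of range"))

  expect_error(generativeModel(A, diag(4), rep(0.25, 4)), "invalid")
})

test_that("sampling a deterministic process is exact and seeds reproduce", {
  det <- generativeModel(diag(3), diag(3), c(1, 0, 0))
  s <- sampleProcess(det, 5, seed = 1)
  expect_equal(s$states, rep(1L, 5))
  expect_equal(s$observations, rep(1L, 5))

  m <- randomModel(4, 4, seed = 9)
  expect_identical(sampleProcess(m, 50, seed = 3),
                   sampleProcess(m, 50, seed = 3))
  expect_equal(sampleProcess(m, 0, seed = 1),
               list(states = integer(0), observations = integer(0)))
})

test_that("empirical outcome frequencies obey the law of large numbers", {
  ## uniform likelihood over 4 outcomes: each frequency near 0.25
  m <- generativeModel(matrix(0.25, 4, 2), matrix(0.5, 2, 2), c(0.5, 0.5))
  s <- sampleProcess(m, 10000, seed = 42)
  freq <- tabulate(s$observations, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("empirical transition frequencies are consistent with B", {
  m <- randomModel(3, 3, seed = 17)
  s <- sampleProcess(m, 10000, seed = 17)
  B <- transitions(m)[[1]]
  from <- s$states[-10000]; to <- s$states[-1]
  for (j in 1:3) {
    counts <- tabulate(to[from == j], 3)
    p <- suppressWarnings(stats::chisq.test(counts, p = B[, j]))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("constructors preserve column-stochasticity", {
  for (seed in 1:25) {
    inst <- randomInstance(seed)
    expect_equal(nrow(validateModel(inst$model)), 0L)
  }
  expect_equal(nrow(validateModel(makeMelodyModel(0.3, 0.7))), 0L)
  expect_equal(nrow(validateModel(deterministicModel(4))), 0L)
})

test_that("melody model realizes the tone progression", {
  m <- makeMelodyModel(1, 0)
  s <- sampleProcess(m, 4, seed = 5)
  expect_equal(s$observations, 1:4)  # A, B, C, D

  ## silence is unreachable by step 3 under deterministic progression
  B <- transitions(m)[[1]]
  marg3 <- B %*% B %*% statePrior(m)
  expect_equal(as.numeric(likelihood(m) %*% marg3)[5], 0)

  ## tone D marginal at step 4 equals p^3; verified by path enumeration
  m9 <- makeMelodyModel(0.9, 0)
  B9 <- transitions(m9)[[1]]
  paths <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5))
  w <- statePrior(m9)[paths[, 1]]
  for (t in 2:4) w <- w * B9[cbind(paths[, t], paths[, t - 1])]
  expect_equal(sum(w[paths[, 4] == 4]), 0.9^3, tolerance = 1e-12)
  chain <- B9 %*% B9 %*% B9 %*% statePrior(m9)
  expect_equal(chain[4], 0.9^3, tolerance = 1e-12)

  expect_error(makeMelodyModel(1.2, 0), "probability")
  expect_error(makeMelodyModel(0.5, -0.1), "probability")
})

test_that("models round-trip through YAML and JSON files", {
  m <- makeMelodyModel(0.8, 0.1)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writeGenerativeModel(m, f)
    back <- readGenerativeModel(f)
    expect_equal(likelihood(back), likelihood(m),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(transitions(back)[[1]], transitions(m)[[1]],
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(statePrior(back), statePrior(m), tolerance = 1e-12)
    expect_equal(back@stateLabels, m@stateLabels)
  }
  expect_error(readGenerativeModel(tempfile(fileext = ".yaml")),
               "not found")
})

test_that("loader rejects files violating stochasticity", {
  f <- tempfile(fileext = ".yaml")
  A <- diag(2); A[1, 1] <- 0.7  # column 1 sums to 0.7
  broken <- generativeModel(A, diag(2), c(1, 0), check = FALSE)
  writeGenerativeModel(broken, f)
  expect_error(readGenerativeModel(f), "invalid")
})

test_that("sampled processes export as tidy CSV", {
  m <- makeMelodyModel(1, 0)
  s <- sampleProcess(m, 4, seed = 1)
  f <- tempfile(fileext = ".csv")
  writeProcessCSV(s, f, model = m)
  tab <- read.csv(f)
  expect_equal(names(tab), c("step", "state", "observation",
                             "state_label", "outcome_label"))
  expect_equal(tab$outcome_label, c("A", "B", "C", "D"))
})
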
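## GenerativeModel constructors, validation, sampling, and the melody
## scenario model.

#' Create a generative model
#'
#' @param A likelihood matrix (outcomes x states), column-stochastic.
#' @param B transition matrix (states x states), column-stochastic, or
#'   an ordered list of such matrices for time-varying dynamics.
#' @param D initial prior over hidden states.
#' @param stateLabels,outcomeLabels optional labels.
#' @param check validate stochasticity and dimensions (default TRUE);
#'   set FALSE to build a deliberately broken model for
#'   \code{\link{validateModel}}.
#' @return a \linkS4class{GenerativeModel}.
#' @examples
#' m <- generativeModel(diag(3), diag(3), rep(1 / 3, 3))
#' nStates(m)
#' @export
generativeModel <- function(A, B, D, stateLabels = NULL,
                            outcomeLabels = NULL, check = TRUE) {
  A <- as.matrix(A)
  if (is.matrix(B)) B <- list(B)
  B <- lapply(B, as.matrix)
  D <- as.numeric(D)
  if (is.null(stateLabels)) stateLabels <- paste0("S", seq_along(D))
  if (is.null(outcomeLabels)) outcomeLabels <- paste0("O", seq_len(nrow(A)))
  model <- new("GenerativeModel", A = A, B = B, D = D,
               stateLabels = as.character(stateLabels),
               outcomeLabels = as.character(outcomeLabels))
  if (check) {
    v <- validateModel(model)
    if (nrow(v))
      stop("invalid generative model:\n  ",
           paste(v$message, collapse = "\n  "), call. = FALSE)
  }
  model
}

checkStochastic <- function(M, object, tol = 1e-12) {
  out <- data.frame(object = character(), index = character(),
                    type = character(), residual = numeric(),
                    message = character(), stringsAsFactors = FALSE)
  bad <- which(M < 0 | M > 1, arr.ind = TRUE)
  if (length(bad)) {
    for (r in seq_len(nrow(bad)))
      out[nrow(out) + 1L, ] <- list(
        object, sprintf("[%d,%d]", bad[r, 1], bad[r, 2]), "out of range",
        as.numeric(M[bad[r, 1], bad[r, 2]]),
        sprintf("%s entry [%d,%d] = %g out of [0, 1]",
                object, bad[r, 1], bad[r, 2], M[bad[r, 1], bad[r, 2]]))
  }
  res <- colSums(M) - 1
  for (j in which(abs(res) > tol))
    out[nrow(out) + 1L, ] <- list(
      object, sprintf("column %d", j), "column sum",
      as.numeric(res[j]),
      sprintf("%s column %d sums to %.12g (residual %.3g)",
              object, j, 1 + res[j], res[j]))
  out
}

#' Validate a generative model
#'
#' Checks the stochasticity invariants (columns of A and every B sum to
#' 1 within 1e-12, all entries in [0, 1], D sums to 1) and mutual
#' dimension consistency. Violations are returned as data, one row per
#' offence, naming the offending object, index, and residual; an empty
#' frame means the model is valid.
#'
#' @param model a \linkS4class{GenerativeModel} (possibly built with
#'   \code{check = FALSE}).
#' @return data.frame with columns \code{object}, \code{index},
#'   \code{type}, \code{residual}, \code{message}.
#' @examples
#' m <- generativeModel(diag(4), diag(4), rep(0.25, 4))
#' nrow(validateModel(m))  # 0
#' @export
validateModel <- function(model) {
  stopifnot(is(model, "GenerativeModel"))
  out <- checkStochastic(model@A, "A")
  for (k in seq_along(model@B))
    out <- rbind(out, checkStochastic(model@B[[k]],
                                      if (length(model@B) == 1L) "B"
                                      else sprintf("B[%d]", k)))
  out <- rbind(out, checkStochastic(matrix(model@D, ncol = 1), "D"))
  n <- length(model@D)
  if (ncol(model@A) != n)
    out[nrow(out) + 1L, ] <- list("A", "ncol", "dimension",
                                  ncol(model@A) - n,
                                  "ncol(A) must equal the number of states")
  for (k in seq_along(model@B))
    if (any(dim(model@B[[k]]) != n))
      out[nrow(out) + 1L, ] <- list(sprintf("B[%d]", k), "dim", "dimension",
                                    NA_real_,
                                    "B must be square n_states x n_states")
  rownames(out) <- NULL
  out
}

## transition matrix applying at step tau (maps tau -> tau + 1);
## a single stored matrix is recycled (homogeneous dynamics)
getB <- function(model, tau) {
  B <- model@B
  if (length(B) == 1L) B[[1L]] else B[[((tau - 1L) %% length(B)) + 1L]]
}

#' Sample a generative process
#'
#' Draws a hidden-state trajectory from the initial prior and the
#' transition chain, then observations from the likelihood conditioned
#' on each state. Fully reproducible given \code{seed}; the caller's
#' RNG state is left untouched.
#'
#' @param model a valid \linkS4class{GenerativeModel}.
#' @param nSteps number of steps (>= 0; 0 gives empty sequences).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return list with integer vectors \code{states} and
#'   \code{observations} (1-based indices).
#' @examples
#' m <- makeMelodyModel(1, 0)
#' sampleProcess(m, 4, seed = 1)$observations  # 1 2 3 4 = A B C D
#' @export
sampleProcess <- function(model, nSteps, seed = NULL) {
  v <- validateModel(model)
  if (nrow(v))
    stop("invalid generative model:\n  ",
         paste(v$message, collapse = "\n  "), call. = FALSE)
  if (!is.numeric(nSteps) || length(nSteps) != 1L || nSteps < 0 ||
      nSteps != round(nSteps))
    stop("'nSteps' must be a single integer >= 0", call. = FALSE)
  nSteps <- as.integer(nSteps)
  n <- nStates(model)
  if (nSteps == 0L)
    return(list(states = integer(0), observations = integer(0)))
  withLocalSeed(seed, {
    states <- integer(nSteps)
    obs <- integer(nSteps)
    states[1L] <- sample.int(n, 1L, prob = model@D)
    if (nSteps > 1L)
      for (k in 2:nSteps)
        states[k] <- sample.int(n, 1L, prob = getB(model, k - 1L)[, states[k - 1L]])
    for (k in seq_len(nSteps))
      obs[k] <- sample.int(nOutcomes(model), 1L, prob = model@A[, states[k]])
    list(states = states, observations = obs)
  })
}

#' Tabulate a sampled process
#'
#' @param process result of \code{\link{sampleProcess}}.
#' @param model optional model supplying labels.
#' @return data.frame with columns \code{step}, \code{state},
#'   \code{observation} (and label columns when a model is given).
#' @export
processFrame <- function(process, model = NULL) {
  df <- data.frame(step = seq_along(process$states),
                   state = process$states,
                   observation = process$observations)
  if (!is.null(model)) {
    df$state_label <- model@stateLabels[df$state]
    df$outcome_label <- model@outcomeLabels[df$observation]
  }
  df
}

#' Write a sampled process as CSV
#'
#' @inheritParams processFrame
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProcessCSV <- function(process, path, model = NULL) {
  write.csv(processFrame(process, model), path, row.names = FALSE)
  invisible(path)
}

#' The melody scenario model
#'
#' A minimal generative model of a four-tone melody that goes from A to
#' B, to C, to D, with a fifth "silence" state. The transition matrix
#' advances each tone to the next with probability
#' \code{progressionFidelity} (residual mass falls to silence, the
#' abrupt end of the melody); tone D is absorbed into silence; silence
#' is absorbing. The likelihood maps each state to its own outcome with
#' probability \code{1 - toneNoise}, spreading \code{toneNoise}
#' uniformly over the other outcomes. The state prior is a point mass
#' on tone A.
#'
#' @param progressionFidelity probability p of the melody advancing.
#' @param toneNoise probability q of mishearing a tone.
#' @return a \linkS4class{GenerativeModel} with 5 states and 5 outcomes
#'   labelled A, B, C, D, silence.
#' @examples
#' m <- makeMelodyModel(0.9, 0.05)
#' sampleProcess(m, 4, seed = 2)
#' @export
makeMelodyModel <- function(progressionFidelity = 0.9, toneNoise = 0.05) {
  p <- progressionFidelity; q <- toneNoise
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'progressionFidelity' must be a probability in [0, 1]",
         call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("'toneNoise' must be a probability in [0, 1]", call. = FALSE)
  labels <- c("A", "B", "C", "D", "silence")
  n <- 5L
  A <- matrix(q / (n - 1), n, n)
  diag(A) <- 1 - q
  B <- matrix(0, n, n)
  for (j in 1:3) { B[j + 1L, j] <- p; B[5L, j] <- 1 - p }
  B[5L, 4L] <- 1   # D is absorbed into silence
  B[5L, 5L] <- 1   # silence is absorbing
  D <- c(1, 0, 0, 0, 0)
  generativeModel(A, B, D, stateLabels = labels, outcomeLabels = labels)
}

#' Random column-stochastic generative model
#'
#' Draws A, B, D with independent flat-Dirichlet columns; used as the
#' seeded random-instance generator throughout the test batteries.
#'
#' @param nStates,nOutcomes dimensions.
#' @param seed integer seed or NULL.
#' @param concentration Dirichlet concentration (1 = flat).
#' @return a \linkS4class{GenerativeModel}.
#' @export
randomModel <- function(nStates, nOutcomes = nStates, seed = NULL,
                        concentration = 1) {
  nStates <- assertCount(nStates, "nStates")
  nOutcomes <- assertCount(nOutcomes, "nOutcomes")
  withLocalSeed(seed, {
    rdir <- function(nr, nc) {
      g <- matrix(rgamma(nr * nc, shape = concentration), nr, nc)
      sweep(g, 2, colSums(g), "/")
    }
    A <- rdir(nOutcomes, nStates)
    B <- rdir(nStates, nStates)
    D <- rdir(nStates, 1)[, 1]
    generativeModel(A, B, D)
  })
}
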
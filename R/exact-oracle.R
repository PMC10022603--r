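## Ground-truth inference: scaled forward-backward smoothing and
## brute-force joint enumeration. Once actions are stripped from the
## scheme the generative model is a plain hidden Markov model, so exact
## smoothing is the reference the approximate sweeps are judged
## against.

#' Exact smoothing by the scaled forward-backward algorithm
#'
#' Computes the exact smoothed marginals \eqn{p(s_\tau | o_{1:T})} and
#' the exact log evidence via the per-step-normalized forward
#' recursion (the scale factors reconstruct the evidence). An
#' impossible observation sequence (zero evidence) yields \code{-Inf}
#' evidence, uniform sentinel marginals, and a warning.
#'
#' @param model a valid \linkS4class{GenerativeModel}.
#' @param observations integer vector of 1-based outcome indices.
#' @return an \linkS4class{ExactPosterior}.
#' @examples
#' m <- makeMelodyModel(1, 0)
#' fb <- forwardBackward(m, c(1L, 2L, 3L, 4L))
#' marginals(fb)  # point masses on A, B, C, D
#' @export
forwardBackward <- function(model, observations) {
  stopifnot(is(model, "GenerativeModel"))
  v <- validateModel(model)
  if (nrow(v)) stop("invalid generative model", call. = FALSE)
  o <- as.integer(observations)
  if (length(o) < 1L || any(is.na(o)) ||
      any(o < 1L | o > nOutcomes(model)))
    stop("'observations' must be 1-based outcome indices", call. = FALSE)
  n <- nStates(model); T <- length(o)
  alpha <- matrix(0, n, T)
  scale <- numeric(T)
  a <- model@D * model@A[o[1L], ]
  scale[1L] <- sum(a)
  impossible <- scale[1L] <= 0
  if (!impossible) alpha[, 1L] <- a / scale[1L]
  if (T > 1L && !impossible) {
    for (t in 2:T) {
      a <- as.numeric(getB(model, t - 1L) %*% alpha[, t - 1L]) *
        model@A[o[t], ]
      scale[t] <- sum(a)
      if (scale[t] <= 0) { impossible <- TRUE; break }
      alpha[, t] <- a / scale[t]
    }
  }
  if (impossible) {
    warning("observation sequence has zero probability under the model")
    marg <- matrix(1 / n, n, T)
    colnames(marg) <- paste0("tau", seq_len(T))
    rownames(marg) <- model@stateLabels
    return(new("ExactPosterior", marginals = marg, logEvidence = -Inf,
               impossible = TRUE))
  }
  beta <- matrix(0, n, T)
  beta[, T] <- 1
  if (T > 1L)
    for (t in (T - 1L):1L)
      beta[, t] <- as.numeric(
        t(getB(model, t)) %*% (beta[, t + 1L] * model@A[o[t + 1L], ])) /
        scale[t + 1L]
  marg <- alpha * beta
  marg <- sweep(marg, 2, colSums(marg), "/")
  colnames(marg) <- paste0("tau", seq_len(T))
  rownames(marg) <- model@stateLabels
  new("ExactPosterior", marginals = marg, logEvidence = sum(log(scale)),
      impossible = FALSE)
}

#' Exact smoothing by joint enumeration
#'
#' Sums the full joint probability over every hidden-state path; exact
#' by construction and entirely independent of the forward-backward
#' recursion, so the two serve as mutual oracles. Refuses instances
#' with more than 1e6 paths.
#'
#' @inheritParams forwardBackward
#' @return an \linkS4class{ExactPosterior}.
#' @export
bruteForceEnumeration <- function(model, observations) {
  stopifnot(is(model, "GenerativeModel"))
  v <- validateModel(model)
  if (nrow(v)) stop("invalid generative model", call. = FALSE)
  o <- as.integer(observations)
  if (length(o) < 1L || any(is.na(o)) ||
      any(o < 1L | o > nOutcomes(model)))
    stop("'observations' must be 1-based outcome indices", call. = FALSE)
  n <- nStates(model); T <- length(o)
  if (n^T > 1e6)
    stop("instance too large for enumeration: ", n, "^", T, " > 1e6 paths",
         call. = FALSE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T)))
  w <- model@D[paths[, 1L]] * model@A[o[1L], ][paths[, 1L]]
  if (T > 1L)
    for (t in 2:T)
      w <- w * getB(model, t - 1L)[cbind(paths[, t], paths[, t - 1L])] *
        model@A[o[t], ][paths[, t]]
  evidence <- sum(w)
  marg <- matrix(0, n, T)
  if (evidence > 0) {
    for (t in seq_len(T))
      marg[, t] <- vapply(seq_len(n),
                          function(s) sum(w[paths[, t] == s]), numeric(1)) /
        evidence
  } else {
    warning("observation sequence has zero probability under the model")
    marg[] <- 1 / n
  }
  colnames(marg) <- paste0("tau", seq_len(T))
  rownames(marg) <- model@stateLabels
  new("ExactPosterior", marginals = marg,
      logEvidence = if (evidence > 0) log(evidence) else -Inf,
      impossible = evidence <= 0)
}
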
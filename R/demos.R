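## Runnable scenarios: melody surprise (protentional fulfilment vs.
## violation) and serial dependence (attractive bias from retained
## priors).

#' Melody surprise experiment
#'
#' Plays the four-tone melody A, B, C, D into the inference engine one
#' tone at a time. Before each incoming tone the engine sweeps its
#' beliefs over the observed prefix, forms the one-step predictive
#' belief (transition matrix applied to the last smoothed belief), and
#' scores the incoming outcome's surprisal under it. In the
#' \code{"completed"} condition the fourth outcome is tone D — the
#' protended continuation — while in the \code{"truncated"} condition
#' the melody ends abruptly after C (the fourth outcome is silence).
#' With a confident progression the abrupt end is far more surprising
#' than the anticipated D; in the fully deterministic model the
#' anticipated D carries zero surprisal.
#'
#' @param fidelity progression probability p of the melody model.
#' @param noise tone-confusion probability q of the melody model.
#' @param condition \code{"completed"} (A,B,C,D) or \code{"truncated"}
#'   (A,B,C,silence).
#' @param seed kept for interface uniformity; the experiment is
#'   deterministic given its inputs.
#' @param config an \code{\link{updateConfig}}.
#' @return list with the melody \code{model}, \code{condition},
#'   \code{outcomes} (observed indices), \code{predictive}
#'   (states x steps matrix of one-step predictive beliefs),
#'   \code{surprisal} (nats per step, possibly \code{Inf}), and the
#'   final sweep \code{record}.
#' @examples
#' res <- runMelodyDemo(1, 0, "truncated")
#' res$surprisal  # last entry: the surprising abrupt end
#' @export
runMelodyDemo <- function(fidelity = 0.9, noise = 0.05,
                          condition = c("completed", "truncated"),
                          seed = NULL, config = updateConfig()) {
  condition <- match.arg(condition)
  model <- makeMelodyModel(fidelity, noise)
  outcomes <- if (condition == "completed") c(1L, 2L, 3L, 4L)
              else c(1L, 2L, 3L, 5L)
  nSteps <- length(outcomes)
  pred <- matrix(NA_real_, nStates(model), nSteps,
                 dimnames = list(model@stateLabels,
                                 paste0("step", seq_len(nSteps))))
  surp <- numeric(nSteps)
  record <- NULL
  for (k in seq_len(nSteps)) {
    if (k == 1L) {
      pk <- statePrior(model)
    } else {
      fit <- gradientSweep(beliefLattice(model, outcomes[seq_len(k - 1L)]),
                           config)
      record <- fit$record
      pk <- as.numeric(getB(model, k - 1L) %*%
                       beliefs(fit$lattice)[, k - 1L])
      pk <- pk / sum(pk)
    }
    pred[, k] <- pk
    surp[k] <- surprisal(model, pk, outcomes[k])
  }
  list(model = model, condition = condition, outcomes = outcomes,
       predictive = pred, surprisal = surp, record = record)
}

## wrap a signed circular difference into (-n/2, n/2]
circWrap <- function(d, n) {
  w <- ((d + n / 2) %% n) - n / 2
  ifelse(w == -n / 2, n / 2, w)
}

circularKernel <- function(n, width) {
  if (is.infinite(width)) return(matrix(1 / n, n, n))
  if (width == 0) return(diag(n))
  d <- circWrap(outer(seq_len(n), seq_len(n), "-"), n)
  K <- exp(-d^2 / (2 * width^2))
  sweep(K, 2, colSums(K), "/")
}

#' Serial dependence experiment
#'
#' Simulates perception of independent uniform stimuli on a circular
#' space observed through a noisy likelihood. The posterior of each
#' trial is carried into the next as a prior after smoothing through a
#' circular transition kernel — the retained information. Estimates
#' are the circular mean of the posterior; the attraction statistic is
#' the mean signed estimation error projected onto the direction of
#' the previous trial's observation, so positive values indicate the
#' attractive bias toward the recent past that characterizes serial
#' dependence. Stimuli and observations are drawn once from the seed
#' before inference, so different kernel settings face identical data.
#'
#' @param nStates size of the circular stimulus space (>= 8).
#' @param kernelWidth circular standard deviation (in state units) of
#'   the smoothing kernel carrying the posterior across trials;
#'   \code{Inf} gives a uniform kernel (no retention), 0 the identity.
#' @param likelihoodNoise circular standard deviation of the
#'   observation likelihood; 0 gives a noiseless identity likelihood.
#' @param nTrials number of trials (>= 100).
#' @param seed integer seed.
#' @return list with a per-trial data.frame \code{trials} (columns
#'   \code{trial}, \code{trueState}, \code{observation},
#'   \code{prevObservation}, \code{estimate}, \code{signedError},
#'   \code{attraction}), the \code{attractionStatistic} (mean projected
#'   error, state units), its \code{standardError}, a one-sided
#'   \code{signTestP} for positive attraction, \code{degenerate} flag,
#'   \code{nTrials} and \code{seed}.
#' @examples
#' res <- runSerialDependenceDemo(nTrials = 200, seed = 1)
#' res$attractionStatistic
#' @export
runSerialDependenceDemo <- function(nStates = 12L, kernelWidth = 1.5,
                                    likelihoodNoise = 1.5,
                                    nTrials = 1000L, seed = 1L) {
  n <- assertCount(nStates, "nStates", 8L)
  nTrials <- assertCount(nTrials, "nTrials", 100L)
  if (!is.numeric(kernelWidth) || kernelWidth < 0)
    stop("'kernelWidth' must be >= 0 (Inf = uniform)", call. = FALSE)
  if (!is.numeric(likelihoodNoise) || likelihoodNoise < 0 ||
      is.infinite(likelihoodNoise))
    stop("'likelihoodNoise' must be a finite value >= 0", call. = FALSE)
  A <- circularKernel(n, likelihoodNoise)
  B <- circularKernel(n, kernelWidth)
  degenerate <- kernelWidth == 0 && likelihoodNoise == 0
  if (degenerate)
    warning("identity kernel with noiseless likelihood: no bias measurable")
  dat <- withLocalSeed(seed, {
    true <- sample.int(n, nTrials, replace = TRUE)
    obs <- vapply(true, function(s) sample.int(n, 1L, prob = A[, s]),
                  integer(1))
    list(true = true, obs = obs)
  })
  ang <- 2 * pi * (seq_len(n) - 1) / n
  prior <- rep(1 / n, n)
  estimate <- numeric(nTrials)
  for (i in seq_len(nTrials)) {
    if (i > 1L) prior <- as.numeric(B %*% posterior)
    posterior <- prior * A[dat$obs[i], ]
    ## a degenerate carried prior can zero out the data; let the
    ## likelihood dominate rather than propagate NaN
    if (sum(posterior) <= 0) posterior <- A[dat$obs[i], ]
    posterior <- posterior / sum(posterior)
    estimate[i] <- atan2(sum(posterior * sin(ang)),
                         sum(posterior * cos(ang))) * n / (2 * pi)
  }
  err <- circWrap(estimate - (dat$true - 1), n)
  prevObs <- c(NA_integer_, dat$obs[-nTrials])
  delta <- circWrap(prevObs - dat$true, n)
  attraction <- err * sign(delta)
  trials <- data.frame(trial = seq_len(nTrials), trueState = dat$true,
                       observation = dat$obs, prevObservation = prevObs,
                       estimate = estimate, signedError = err,
                       attraction = attraction)
  a <- attraction[-1L]
  stat <- mean(a)
  se <- sd(a) / sqrt(length(a))
  nz <- a[a != 0]
  p <- if (length(nz))
    stats::binom.test(sum(nz > 0), length(nz),
                      alternative = "greater")$p.value else 1
  list(trials = trials, attractionStatistic = stat, standardError = se,
       signTestP = p, degenerate = degenerate, nTrials = nTrials,
       seed = seed)
}
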
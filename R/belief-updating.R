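## Softmax belief propagation: message potentials, present-moment
## inference, stationary fixed points, free-energy gradient sweeps,
## and surprisal.

#' Update configuration
#'
#' Numerical settings for the belief-updating dynamics.
#'
#' @param stepSize Euler step \eqn{\Delta t} (> 0; values <= 0.1
#'   guarantee free-energy descent, values > 1 overshoot and are only
#'   useful to demonstrate non-convergence).
#' @param maxIterations sweep cap.
#' @param tolerance convergence threshold on the max absolute belief
#'   change per sweep.
#' @param logFloor probability floor applied before any logarithm, so
#'   deterministic matrices stay finite in the log domain.
#' @param logConvention \code{"matrix"} takes the elementwise log of a
#'   transition matrix before the matrix-vector product (the default,
#'   matching the printed message form); \code{"marginal"} logs the
#'   product \eqn{\ln(B s)} instead, kept for sensitivity checks.
#' @return a classed list of validated settings.
#' @export
updateConfig <- function(stepSize = 0.1, maxIterations = 10000L,
                         tolerance = 1e-8, logFloor = 1e-16,
                         logConvention = c("matrix", "marginal")) {
  logConvention <- match.arg(logConvention)
  if (!is.numeric(stepSize) || length(stepSize) != 1L || stepSize <= 0)
    stop("'stepSize' must be > 0", call. = FALSE)
  maxIterations <- assertCount(maxIterations, "maxIterations")
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("'tolerance' must be > 0", call. = FALSE)
  if (!is.numeric(logFloor) || logFloor <= 0)
    stop("'logFloor' must be > 0", call. = FALSE)
  structure(list(stepSize = stepSize, maxIterations = maxIterations,
                 tolerance = tolerance, logFloor = logFloor,
                 logConvention = logConvention),
            class = "updateConfig")
}

#' Softmax operator
#'
#' Maps a real-valued (log-domain) potential to a probability
#' distribution: exponentiate and normalize, with max-shifting so
#' arbitrarily large potentials do not overflow. Invariant under adding
#' a constant to every entry.
#'
#' @param potential finite numeric vector.
#' @return probability vector summing to 1.
#' @examples
#' softmax(c(0, 0))             # 0.5 0.5
#' softmax(log(c(0.8, 0.2)))    # 0.8 0.2
#' @export
softmax <- function(potential) {
  if (!is.numeric(potential) || length(potential) == 0L ||
      any(!is.finite(potential)))
    stop("'potential' must be a finite numeric vector", call. = FALSE)
  e <- exp(potential - max(potential))
  e / sum(e)
}

#' Infer the present moment from its living-inference triplet
#'
#' Computes the present belief from the three messages that constitute
#' it: the protention carried from the previous objective step, the
#' primal impression predicted at the current step, and the retained
#' observation, realized as the likelihood message (the row of
#' \eqn{\ln A} selected by the retained outcome):
#' \deqn{s = \sigma(\ln s_{prot} + \ln s_{primal} + \ln A[o, ])}
#'
#' @param protention belief vector carried from the previous objective
#'   step (subjective offset +1).
#' @param primal predicted current-state belief (subjective offset +1
#'   at the current objective step).
#' @param retention retained outcome, a 1-based outcome index.
#' @param model a \linkS4class{GenerativeModel}.
#' @param logFloor probability floor before logarithms.
#' @return normalized present belief vector.
#' @examples
#' m <- randomModel(3, 3, seed = 1)
#' presentMomentInference(rep(1/3, 3), rep(1/3, 3), 1L, m)
#' @export
presentMomentInference <- function(protention, primal, retention, model,
                                   logFloor = 1e-16) {
  stopifnot(is(model, "GenerativeModel"))
  n <- nStates(model)
  if (length(protention) != n || length(primal) != n)
    stop("belief vectors must have one entry per hidden state",
         call. = FALSE)
  assertProbabilityVector(protention, "'protention'")
  assertProbabilityVector(primal, "'primal'")
  if (!is.numeric(retention) || length(retention) != 1L ||
      retention < 1 || retention > nOutcomes(model) ||
      retention != round(retention))
    stop("'retention' must be a 1-based outcome index", call. = FALSE)
  softmax(flooredLog(protention, logFloor) + flooredLog(primal, logFloor) +
          flooredLog(model@A[as.integer(retention), ], logFloor))
}

#' Create a belief lattice
#'
#' Attaches an observation sequence to a generative model and
#' initializes every expected-state vector (default: uniform).
#'
#' @param model a valid \linkS4class{GenerativeModel}.
#' @param observations integer vector of 1-based outcome indices.
#' @param convention index convention for updates: \code{"stationary"}
#'   (chain neighbours tau-1, tau+1, o_tau) or \code{"integrated"}
#'   (prior protention, predicted primal impression, likely retention).
#' @param init optional states-by-indices matrix of initial beliefs.
#' @return a \linkS4class{BeliefLattice}.
#' @export
beliefLattice <- function(model, observations,
                          convention = c("stationary", "integrated"),
                          init = NULL) {
  stopifnot(is(model, "GenerativeModel"))
  convention <- match.arg(convention)
  v <- validateModel(model)
  if (nrow(v))
    stop("invalid generative model", call. = FALSE)
  observations <- as.integer(observations)
  if (length(observations) < 1L || any(is.na(observations)) ||
      any(observations < 1L | observations > nOutcomes(model)))
    stop("'observations' must be 1-based outcome indices", call. = FALSE)
  n <- nStates(model); T <- length(observations)
  if (is.null(init)) init <- matrix(1 / n, n, T)
  init <- as.matrix(init)
  if (any(dim(init) != c(n, T)))
    stop("'init' must be a states x indices matrix", call. = FALSE)
  colnames(init) <- paste0("tau", seq_len(T))
  rownames(init) <- model@stateLabels
  new("BeliefLattice", model = model, beliefs = init,
      observations = observations, convention = convention)
}

## Message sum feeding the update of index tau.
## `previous` holds the beliefs of the previous objective step (used by
## the integrated convention's prior-protention term); defaults to the
## current beliefs, with which it coincides at any fixed point.
messageSum <- function(lattice, tau, config = updateConfig(),
                       previous = lattice@beliefs) {
  model <- lattice@model
  s <- lattice@beliefs
  o <- lattice@observations
  T <- ncol(s)
  fl <- config$logFloor
  logB <- function(B) flooredLog(B, fl)
  fwdMsg <- function(B, v) {
    if (config$logConvention == "matrix") logB(B) %*% v
    else flooredLog(B %*% v, fl)
  }
  bwdMsg <- function(B, v) {
    if (config$logConvention == "matrix") t(logB(B)) %*% v
    else flooredLog(t(B) %*% v, fl)
  }
  if (lattice@convention == "stationary") {
    fwd <- if (tau == 1L) flooredLog(model@D, fl)
           else fwdMsg(getB(model, tau - 1L), s[, tau - 1L])
    bwd <- if (tau < T) bwdMsg(getB(model, tau), s[, tau + 1L]) else 0
    lik <- flooredLog(model@A, fl)[o[tau], ]
  } else {
    fwd <- if (tau < T) fwdMsg(getB(model, tau), previous[, tau + 1L]) else 0
    bwd <- if (tau < T) bwdMsg(getB(model, tau), s[, tau + 1L]) else 0
    lik <- if (tau >= 2L) flooredLog(model@A, fl)[o[tau - 1L], ]
           else flooredLog(model@D, fl)
  }
  as.numeric(fwd + bwd + lik)
}

#' Temporal coordinates read by one update
#'
#' Introspection helper reporting which (objective offset, subjective
#' index, kind) coordinates the update of index \code{tau} consumes
#' under the lattice's convention. Objective offset 0 is the current
#' sweep (objective step), -1 the previous one.
#'
#' @param lattice a \linkS4class{BeliefLattice}.
#' @param tau index to update.
#' @return data.frame with columns \code{objectiveOffset},
#'   \code{subjective}, \code{kind}.
#' @export
updateFootprint <- function(lattice, tau) {
  T <- ncol(lattice@beliefs)
  if (lattice@convention == "stationary") {
    out <- data.frame(objectiveOffset = 0L,
                      subjective = tau,
                      kind = "observation")
    if (tau > 1L)
      out <- rbind(out, data.frame(objectiveOffset = 0L,
                                   subjective = tau - 1L, kind = "belief"))
    if (tau < T)
      out <- rbind(out, data.frame(objectiveOffset = 0L,
                                   subjective = tau + 1L, kind = "belief"))
  } else {
    out <- data.frame(objectiveOffset = integer(0),
                      subjective = integer(0), kind = character(0))
    if (tau < T)
      out <- rbind(out,
                   data.frame(objectiveOffset = -1L, subjective = tau + 1L,
                              kind = "belief"),
                   data.frame(objectiveOffset = 0L, subjective = tau + 1L,
                              kind = "belief"))
    if (tau >= 2L)
      out <- rbind(out, data.frame(objectiveOffset = 0L,
                                   subjective = tau - 1L,
                                   kind = "observation"))
  }
  out
}

#' Stationary (fixed-point) update of one index
#'
#' Computes the stationary solution of the belief dynamics at one
#' index, with the other lattice beliefs held fixed:
#' \deqn{s_\tau = \sigma(\ln B_{\tau-1} s_{\tau-1} +
#'   \ln B_\tau^\top s_{\tau+1} + \ln A[o_\tau, ])}
#' under the stationary convention, or the relabelled living-inference
#' triplet under the integrated convention. Boundary rule: at the first
#' index the forward/retention message is replaced by the initial prior
#' \eqn{\ln D}; at the last index future-side messages are omitted.
#'
#' @param lattice a \linkS4class{BeliefLattice}.
#' @param tau index (1-based).
#' @param config an \code{\link{updateConfig}}.
#' @return normalized belief vector for index \code{tau}.
#' @export
stationaryUpdate <- function(lattice, tau, config = updateConfig()) {
  stopifnot(is(lattice, "BeliefLattice"))
  T <- ncol(lattice@beliefs)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 1 || tau > T ||
      tau != round(tau))
    stop("'tau' must be an index in 1..", T, call. = FALSE)
  softmax(messageSum(lattice, as.integer(tau), config))
}

## Residual of the belief dynamics at index tau: the instantaneous
## belief velocity |s ⊙ (vdot − <s, vdot>)| with vdot = messages − ln s.
## Zero exactly at a stationary point.
updateResidualAt <- function(lattice, tau, config = updateConfig(),
                             previous = lattice@beliefs) {
  s <- lattice@beliefs[, tau]
  vdot <- messageSum(lattice, tau, config, previous) -
    flooredLog(s, config$logFloor)
  sdot <- s * (vdot - sum(s * vdot))
  sqrt(sum(sdot^2))
}

#' Fixed-point residuals of a lattice
#'
#' Per-index norm of the instantaneous belief change implied by the
#' update dynamics; all (near) zero at a converged lattice.
#'
#' @inheritParams stationaryUpdate
#' @return numeric vector, one residual per index.
#' @export
updateResiduals <- function(lattice, config = updateConfig()) {
  vapply(seq_len(ncol(lattice@beliefs)),
         function(tau) updateResidualAt(lattice, tau, config), numeric(1))
}

#' Gradient sweep on the variational free energy
#'
#' Iterates the discretized belief dynamics
#' \deqn{s_\tau^{t+\Delta t} = \sigma(\ln s_\tau^t +
#'   \Delta t\,(m_\tau - \ln s_\tau^t))}
#' (explicit Euler on the message potential, re-normalized by softmax)
#' over all indices in ascending order within each sweep, until the
#' largest belief change falls below the tolerance or the iteration cap
#' is reached. With \eqn{\Delta t \le 1} each coordinate step cannot
#' increase the free energy, so the sweep is a deterministic gradient
#' descent whose fixed points are the stationary solutions. Under the
#' integrated convention the prior-protention message reads the
#' previous sweep's beliefs, so each sweep advances one objective step.
#'
#' @param lattice a \linkS4class{BeliefLattice}.
#' @param config an \code{\link{updateConfig}}.
#' @return list with the updated \code{lattice} and a \code{record}
#'   containing \code{converged}, \code{iterations}, per-iteration
#'   \code{freeEnergy} and \code{maxChange}.
#' @examples
#' m <- randomModel(3, 3, seed = 7)
#' lat <- beliefLattice(m, sampleProcess(m, 5, seed = 7)$observations)
#' fit <- gradientSweep(lat)
#' fit$record$converged
#' @export
gradientSweep <- function(lattice, config = updateConfig()) {
  stopifnot(is(lattice, "BeliefLattice"))
  T <- ncol(lattice@beliefs)
  dt <- config$stepSize
  fe <- numeric(0); ch <- numeric(0)
  previous <- lattice@beliefs
  converged <- FALSE
  iter <- 0L
  while (iter < config$maxIterations) {
    iter <- iter + 1L
    before <- lattice@beliefs
    for (tau in seq_len(T)) {
      m <- messageSum(lattice, tau, config, previous)
      v <- flooredLog(lattice@beliefs[, tau], config$logFloor)
      lattice@beliefs[, tau] <- softmax(v + dt * (m - v))
    }
    fe[iter] <- freeEnergy(lattice)$value
    ch[iter] <- max(abs(lattice@beliefs - before))
    previous <- before
    if (ch[iter] < config$tolerance) { converged <- TRUE; break }
  }
  list(lattice = lattice,
       record = list(converged = converged, iterations = iter,
                     freeEnergy = fe, maxChange = ch))
}

#' Variational free energy of a belief lattice
#'
#' The standard discrete free energy of the chain under the mean-field
#' posterior held in the lattice:
#' \deqn{F = \sum_\tau E_q[\ln q(s_\tau) - \ln p(s_\tau | s_{\tau-1})
#'   - \ln p(o_\tau | s_\tau)]}
#' with the first index using the initial prior D. Cross-expectations
#' use the floored elementwise log of the matrices, consistent with the
#' message dynamics, so the sweep descends exactly this quantity. F
#' upper-bounds the negative log evidence.
#'
#' @param lattice a \linkS4class{BeliefLattice}.
#' @param logFloor probability floor before logarithms.
#' @return list with scalar \code{value} (nats) and a per-index
#'   \code{decomposition} data.frame (columns \code{tau},
#'   \code{entropyTerm}, \code{transitionTerm}, \code{likelihoodTerm},
#'   \code{value}); the terms sum exactly to the total.
#' @export
freeEnergy <- function(lattice, logFloor = 1e-16) {
  stopifnot(is(lattice, "BeliefLattice"))
  model <- lattice@model
  s <- lattice@beliefs
  o <- lattice@observations
  T <- ncol(s)
  lA <- flooredLog(model@A, logFloor)
  dec <- data.frame(tau = seq_len(T), entropyTerm = NA_real_,
                    transitionTerm = NA_real_, likelihoodTerm = NA_real_,
                    value = NA_real_)
  for (tau in seq_len(T)) {
    ent <- xlogx(s[, tau])
    trans <- if (tau == 1L) -sum(s[, 1L] * flooredLog(model@D, logFloor))
             else -as.numeric(t(s[, tau]) %*%
                              flooredLog(getB(model, tau - 1L), logFloor) %*%
                              s[, tau - 1L])
    lik <- -sum(lA[o[tau], ] * s[, tau])
    dec[tau, 2:5] <- c(ent, trans, lik, ent + trans + lik)
  }
  list(value = sum(dec$value), decomposition = dec)
}

#' Surprisal of an outcome under a predictive belief
#'
#' \deqn{-\ln \sum_s p(o | s)\, q(s)}: the self-information of an
#' incoming outcome under the predictive distribution implied by a
#' belief over hidden states. An outcome with zero predictive
#' probability returns \code{+Inf} (a documented sentinel, not an
#' error): the maximally surprising abrupt end.
#'
#' @param model a \linkS4class{GenerativeModel}.
#' @param predictive belief vector over hidden states.
#' @param outcome 1-based outcome index.
#' @return surprisal in nats (>= 0, possibly \code{Inf}).
#' @examples
#' m <- makeMelodyModel(1, 0)
#' surprisal(m, c(0, 0, 0, 1, 0), 4L)  # fully anticipated: 0
#' surprisal(m, c(0, 0, 0, 1, 0), 5L)  # abrupt end: Inf
#' @export
surprisal <- function(model, predictive, outcome) {
  stopifnot(is(model, "GenerativeModel"))
  if (length(predictive) != nStates(model))
    stop("'predictive' must have one entry per hidden state", call. = FALSE)
  assertProbabilityVector(predictive, "'predictive'")
  if (!is.numeric(outcome) || length(outcome) != 1L || outcome < 1 ||
      outcome > nOutcomes(model) || outcome != round(outcome))
    stop("'outcome' must be a 1-based outcome index", call. = FALSE)
  p <- sum(model@A[as.integer(outcome), ] * predictive)
  if (p <= 0) Inf else -log(p)
}
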
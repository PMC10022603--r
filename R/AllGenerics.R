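#' @import methods
NULL

#' Number of hidden states of a model or lattice
#'
#' @param x a \linkS4class{GenerativeModel} or \linkS4class{BeliefLattice}.
#' @return integer scalar.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' Number of observable outcomes of a model or lattice
#'
#' @param x a \linkS4class{GenerativeModel} or \linkS4class{BeliefLattice}.
#' @return integer scalar.
#' @export
setGeneric("nOutcomes", function(x) standardGeneric("nOutcomes"))

#' Likelihood matrix accessor
#'
#' Returns the column-stochastic likelihood matrix A (outcomes in rows,
#' hidden states in columns).
#'
#' @param x a \linkS4class{GenerativeModel} or \linkS4class{BeliefLattice}.
#' @return a numeric matrix.
#' @export
setGeneric("likelihood", function(x) standardGeneric("likelihood"))

#' Transition matrix accessor
#'
#' Returns the ordered list of column-stochastic transition matrices B.
#' A model with homogeneous dynamics stores a single matrix that is
#' recycled across steps.
#'
#' @param x a \linkS4class{GenerativeModel} or \linkS4class{BeliefLattice}.
#' @return a list of numeric matrices.
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' Initial state prior accessor
#'
#' @param x a \linkS4class{GenerativeModel} or \linkS4class{BeliefLattice}.
#' @return a probability vector over hidden states.
#' @export
setGeneric("statePrior", function(x) standardGeneric("statePrior"))

#' Expected-state (belief) accessor
#'
#' @param x a \linkS4class{BeliefLattice}.
#' @return a states-by-index matrix of normalized beliefs.
#' @export
setGeneric("beliefs", function(x) standardGeneric("beliefs"))

#' Observation sequence accessor
#'
#' @param x a \linkS4class{BeliefLattice}.
#' @return integer vector of 1-based outcome indices.
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' Smoothed posterior marginals accessor
#'
#' @param x an \linkS4class{ExactPosterior}.
#' @return a states-by-index matrix of exact marginals.
#' @export
setGeneric("marginals", function(x) standardGeneric("marginals"))

#' Log model evidence accessor
#'
#' @param x an \linkS4class{ExactPosterior}.
#' @return log evidence in nats (\code{-Inf} for impossible sequences).
#' @export
setGeneric("logEvidence", function(x) standardGeneric("logEvidence"))

#' Markov blanket member accessor
#'
#' @param x a \linkS4class{MarkovBlanket}.
#' @return character vector of member node identifiers.
#' @export
setGeneric("blanketMembers", function(x) standardGeneric("blanketMembers"))

#' Markov blanket target accessor
#'
#' @param x a \linkS4class{MarkovBlanket}.
#' @return the target node identifier.
#' @export
setGeneric("blanketTarget", function(x) standardGeneric("blanketTarget"))

#' Export belief trajectories
#'
#' Writes beliefs in a shared tabular schema (columns
#' \code{objective_t}, \code{subjective_tau}, \code{state_label},
#' \code{probability}, \code{iteration}) so approximate and exact
#' posteriors can be compared side by side.
#'
#' @param x a \linkS4class{BeliefLattice} or \linkS4class{ExactPosterior}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param iteration iteration stamp recorded in the table (may be NA).
#' @return the path, invisibly.
#' @export
setGeneric("writeBeliefs",
           function(x, path, format = c("csv", "json"), iteration = NA_integer_)
             standardGeneric("writeBeliefs"))
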
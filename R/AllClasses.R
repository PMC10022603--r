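#' TemporalDAG: a directed acyclic graph over temporal coordinates
#'
#' Nodes carry a pair of temporal coordinates: objective time \code{t}
#' (unitless discrete step) and subjective temporality \code{tau}
#' (unitless offset relative to the declared reference node, positive
#' toward protention, negative toward retention). Each node is either a
#' hidden (inferred) state or an observation; node identity is the
#' (objective, subjective, role) triple. Edges point from parent to
#' child in the direction of conditional dependency.
#'
#' @slot nodes data.frame with columns \code{id}, \code{objective},
#'   \code{subjective}, \code{role} ("hidden"/"observation"),
#'   \code{label}, \code{boundary} (logical; TRUE when the lattice
#'   truncation removed some parents).
#' @slot edges data.frame with columns \code{from}, \code{to} (node ids).
#' @slot order one of "sequential", "interpenetrated", "integrated".
#' @slot reference id of the present-moment reference node.
#'
#' @seealso \code{\link{buildTemporalDAG}}, \code{\link{markovBlanket}},
#'   \code{\link{isDSeparated}}
#' @export
setClass("TemporalDAG",
         representation(nodes = "data.frame", edges = "data.frame",
                        order = "character", reference = "character"))

setValidity("TemporalDAG", function(object) {
  msg <- character()
  need <- c("id", "objective", "subjective", "role", "label", "boundary")
  if (!all(need %in% names(object@nodes)))
    msg <- c(msg, paste("nodes must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@nodes$id))
      msg <- c(msg, "node ids must be unique")
    if (!all(object@nodes$role %in% c("hidden", "observation")))
      msg <- c(msg, "node role must be 'hidden' or 'observation'")
    ed <- object@edges
    if (nrow(ed) > 0) {
      if (!all(c(ed$from, ed$to) %in% object@nodes$id))
        msg <- c(msg, "edges refer to unknown node ids")
      else {
        role <- setNames(object@nodes$role, object@nodes$id)
        if (any(role[ed$from] == "observation" & role[ed$to] == "observation"))
          msg <- c(msg, "observation nodes may not have observation children")
        g <- asIgraph(object)
        if (!igraph::is_dag(g))
          msg <- c(msg, "graph must be acyclic")
      }
    }
    if (length(object@reference) != 1L ||
        !(object@reference %in% object@nodes$id))
      msg <- c(msg, "reference must name one node")
  }
  if (!(object@order %in% c("sequential", "interpenetrated", "integrated")))
    msg <- c(msg, "unknown temporal order")
  if (length(msg)) msg else TRUE
})

#' MarkovBlanket: the statistical boundary of a node
#'
#' Holds the target node, its blanket members (parents, children, and
#' co-parents of children), and a reference to the graph they live in.
#'
#' @slot target node id.
#' @slot members character vector of member node ids (never containing
#'   the target).
#' @slot dag the \linkS4class{TemporalDAG} the blanket was extracted from.
#'
#' @seealso \code{\link{markovBlanket}}, \code{\link{blanketAsynchrony}}
#' @export
setClass("MarkovBlanket",
         representation(target = "character", members = "character",
                        dag = "TemporalDAG"))

setValidity("MarkovBlanket", function(object) {
  msg <- character()
  if (length(object@target) != 1L)
    msg <- c(msg, "target must be a single node id")
  if (object@target %in% object@members)
    msg <- c(msg, "target must not be a blanket member")
  ids <- object@dag@nodes$id
  if (!all(c(object@target, object@members) %in% ids))
    msg <- c(msg, "target and members must be nodes of the graph")
  if (length(msg)) msg else TRUE
})

#' GenerativeModel: likelihood, transitions and initial prior
#'
#' The discrete generative model of active inference: a likelihood
#' matrix A mapping hidden states to outcomes, one or more transition
#' matrices B mapping states to states, and an initial state prior D.
#' All matrices are column-stochastic: columns index the conditioning
#' variable (current state), rows the conditioned one (outcome or next
#' state), so that \code{A \%*\% s} and \code{B \%*\% s} are ordinary
#' left matrix-vector products.
#'
#' @slot A numeric matrix (n_outcomes x n_states), columns sum to 1.
#' @slot B list of numeric matrices (n_states x n_states), columns sum
#'   to 1; a length-one list encodes homogeneous dynamics and is
#'   recycled across steps.
#' @slot D numeric initial prior over hidden states, sums to 1.
#' @slot stateLabels,outcomeLabels character labels.
#'
#' @seealso \code{\link{generativeModel}}, \code{\link{validateModel}},
#'   \code{\link{sampleProcess}}, \code{\link{makeMelodyModel}}
#' @export
setClass("GenerativeModel",
         representation(A = "matrix", B = "list", D = "numeric",
                        stateLabels = "character",
                        outcomeLabels = "character"))

setValidity("GenerativeModel", function(object) {
  msg <- character()
  n <- length(object@D)
  if (ncol(object@A) != n)
    msg <- c(msg, "ncol(A) must equal length(D)")
  if (length(object@B) < 1L)
    msg <- c(msg, "at least one transition matrix is required")
  for (b in object@B)
    if (!is.matrix(b) || any(dim(b) != n))
      msg <- c(msg, "each B must be a square n_states x n_states matrix")
  if (length(object@stateLabels) != n)
    msg <- c(msg, "stateLabels must have one entry per state")
  if (length(object@outcomeLabels) != nrow(object@A))
    msg <- c(msg, "outcomeLabels must have one entry per outcome")
  if (length(msg)) unique(msg) else TRUE
})

#' BeliefLattice: expected states over a temporal index set
#'
#' Holds the expected-state vectors (beliefs) for each index of a
#' temporal chain together with the generative model and the observed
#' outcome sequence. Message potentials are the (floored) logarithms of
#' the stored beliefs. The index convention decides which neighbours
#' feed each update: \code{"stationary"} reads the chain neighbours
#' (forward prior, backward prediction, current outcome), while
#' \code{"integrated"} reads the relabelled living-inference triplet
#' (prior protention, predicted primal impression, likely retention).
#'
#' @slot model a \linkS4class{GenerativeModel}.
#' @slot beliefs numeric matrix, states x indices; each column sums to 1.
#' @slot observations integer vector of 1-based outcome indices, one
#'   per lattice index.
#' @slot convention "stationary" or "integrated".
#'
#' @seealso \code{\link{beliefLattice}}, \code{\link{stationaryUpdate}},
#'   \code{\link{gradientSweep}}, \code{\link{freeEnergy}}
#' @export
setClass("BeliefLattice",
         representation(model = "GenerativeModel", beliefs = "matrix",
                        observations = "integer", convention = "character"))

setValidity("BeliefLattice", function(object) {
  msg <- character()
  n <- length(object@model@D)
  if (nrow(object@beliefs) != n)
    msg <- c(msg, "beliefs must have one row per hidden state")
  if (ncol(object@beliefs) != length(object@observations))
    msg <- c(msg, "one belief column per observation index is required")
  cs <- colSums(object@beliefs)
  if (length(cs) && (any(object@beliefs < -1e-10) || any(abs(cs - 1) > 1e-8)))
    msg <- c(msg, "belief columns must be normalized probability vectors")
  if (any(object@observations < 1L |
          object@observations > nrow(object@model@A)))
    msg <- c(msg, "observations out of outcome range")
  if (!(object@convention %in% c("stationary", "integrated")))
    msg <- c(msg, "convention must be 'stationary' or 'integrated'")
  if (length(msg)) msg else TRUE
})

#' ExactPosterior: ground-truth smoothed marginals
#'
#' Result container for exact inference (forward-backward smoothing or
#' brute-force joint enumeration): per-index smoothed marginals and the
#' exact log evidence.
#'
#' @slot marginals numeric matrix, states x indices; columns sum to 1
#'   (uniform sentinel columns when the sequence is impossible).
#' @slot logEvidence log evidence in nats; \code{-Inf} when the
#'   observation sequence has probability zero under the model.
#' @slot impossible logical flag marking the zero-evidence sentinel.
#'
#' @seealso \code{\link{forwardBackward}},
#'   \code{\link{bruteForceEnumeration}}
#' @export
setClass("ExactPosterior",
         representation(marginals = "matrix", logEvidence = "numeric",
                        impossible = "logical"))

setValidity("ExactPosterior", function(object) {
  msg <- character()
  cs <- colSums(object@marginals)
  if (length(cs) && any(abs(cs - 1) > 1e-10))
    msg <- c(msg, "each marginal must sum to 1")
  if (length(object@logEvidence) != 1L ||
      (!is.finite(object@logEvidence) && object@logEvidence != -Inf))
    msg <- c(msg, "logEvidence must be finite or -Inf")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn GenerativeModel number of hidden states
#' @param x object.
#' @export
setMethod("nStates", "GenerativeModel", function(x) length(x@D))

#' @describeIn GenerativeModel number of outcomes
#' @export
setMethod("nOutcomes", "GenerativeModel", function(x) nrow(x@A))

#' @describeIn GenerativeModel likelihood matrix A
#' @export
setMethod("likelihood", "GenerativeModel", function(x) x@A)

#' @describeIn GenerativeModel list of transition matrices B
#' @export
setMethod("transitions", "GenerativeModel", function(x) x@B)

#' @describeIn GenerativeModel initial prior D
#' @export
setMethod("statePrior", "GenerativeModel", function(x) x@D)

#' @describeIn BeliefLattice number of hidden states
#' @param x object.
#' @export
setMethod("nStates", "BeliefLattice", function(x) nStates(x@model))

#' @describeIn BeliefLattice number of outcomes
#' @export
setMethod("nOutcomes", "BeliefLattice", function(x) nOutcomes(x@model))

#' @describeIn BeliefLattice belief matrix (states x indices)
#' @export
setMethod("beliefs", "BeliefLattice", function(x) x@beliefs)

#' @describeIn BeliefLattice observation sequence
#' @export
setMethod("observations", "BeliefLattice", function(x) x@observations)

#' @describeIn ExactPosterior smoothed marginals
#' @param x object.
#' @export
setMethod("marginals", "ExactPosterior", function(x) x@marginals)

#' @describeIn ExactPosterior exact log evidence
#' @export
setMethod("logEvidence", "ExactPosterior", function(x) x@logEvidence)

#' @describeIn MarkovBlanket member node ids
#' @param x object.
#' @export
setMethod("blanketMembers", "MarkovBlanket", function(x) x@members)

#' @describeIn MarkovBlanket target node id
#' @export
setMethod("blanketTarget", "MarkovBlanket", function(x) x@target)

## ---- show methods ----

setMethod("show", "TemporalDAG", function(object) {
  cat(sprintf("TemporalDAG (%s order): %d nodes, %d edges\n",
              object@order, nrow(object@nodes), nrow(object@edges)))
  cat(sprintf("  reference (present): %s\n", object@reference))
  tab <- table(object@nodes$role)
  cat(sprintf("  hidden: %d, observation: %d\n",
              as.integer(tab["hidden"] %||% 0),
              as.integer(tab["observation"] %||% 0)))
})

setMethod("show", "MarkovBlanket", function(object) {
  cat(sprintf("MarkovBlanket of %s: %d members\n",
              object@target, length(object@members)))
  if (length(object@members))
    cat(" ", paste(object@members, collapse = ", "), "\n")
})

setMethod("show", "GenerativeModel", function(object) {
  cat(sprintf("GenerativeModel: %d hidden states, %d outcomes, %d transition matrix(es)\n",
              nStates(object), nOutcomes(object), length(object@B)))
  cat("  states:", paste(object@stateLabels, collapse = ", "), "\n")
})

setMethod("show", "BeliefLattice", function(object) {
  cat(sprintf("BeliefLattice (%s convention): %d states x %d indices\n",
              object@convention, nrow(object@beliefs), ncol(object@beliefs)))
})

setMethod("show", "ExactPosterior", function(object) {
  cat(sprintf("ExactPosterior: %d states x %d indices, log evidence = %.6g%s\n",
              nrow(object@marginals), ncol(object@marginals),
              object@logEvidence,
              if (object@impossible) " (impossible sequence)" else ""))
})

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
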
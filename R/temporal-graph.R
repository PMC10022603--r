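## Temporal-order DAG construction, Markov blankets, and an exhaustive
## d-separation oracle.

nodeId <- function(role, t, tau) {
  sprintf("%s.t%d.tau%d", ifelse(role == "observation", "o", "s"), t, tau)
}

asIgraph <- function(dag) {
  igraph::graph_from_data_frame(
    if (nrow(dag@edges)) dag@edges else data.frame(from = character(),
                                                   to = character()),
    directed = TRUE, vertices = dag@nodes$id)
}

labelFor <- function(role, tau) {
  if (role == "observation") return("retention")
  if (tau > 0) "protention" else if (tau == 0) "primal impression"
  else "retention"
}

#' Construct a temporal-order DAG
#'
#' Builds one of the three temporal conditional-dependency structures:
#' \describe{
#'   \item{sequential}{unidirectional objective time: a chain of hidden
#'     nodes, each depending only on its predecessor.}
#'   \item{interpenetrated}{subjective temporality: edges from both the
#'     past side and the future side point into the present node, which
#'     is therefore a collider.}
#'   \item{integrated}{the integrated continuity: a lattice over
#'     (objective t, subjective tau) in which every interior hidden node
#'     at (t, tau) has hidden parents at (t-1, tau+1) and (t, tau+1) and
#'     an observation parent at (t, tau-1) — bidirectional at each event
#'     while advancing unidirectionally.}
#' }
#' Hidden nodes sit at subjective offsets 0..\code{subjectiveDepth}
#' (present row and protention layers); observation (retention) nodes
#' sit at offsets -1..\code{subjectiveDepth}-1 so that every hidden node
#' has its observation parent. Nodes whose parents were removed by the
#' finite truncation are flagged \code{boundary}. The reference
#' ("present") node is the hidden node at the central objective step and
#' subjective offset 0.
#'
#' @param order one of \code{"sequential"}, \code{"interpenetrated"},
#'   \code{"integrated"}.
#' @param objectiveHorizon number of objective time steps (>= 2).
#' @param subjectiveDepth protention/retention depth (>= 1); only the
#'   integrated order extends in the subjective direction, the other two
#'   orders are single chains and ignore depths beyond 1.
#' @return a \linkS4class{TemporalDAG}.
#' @examples
#' dag <- buildTemporalDAG("integrated", objectiveHorizon = 3,
#'                         subjectiveDepth = 1)
#' dag
#' @export
buildTemporalDAG <- function(order = c("sequential", "interpenetrated",
                                       "integrated"),
                             objectiveHorizon, subjectiveDepth = 1L) {
  order <- match.arg(order)
  if (!is.numeric(objectiveHorizon) || length(objectiveHorizon) != 1L ||
      !is.finite(objectiveHorizon) || objectiveHorizon < 2 ||
      objectiveHorizon != round(objectiveHorizon))
    stop("'objectiveHorizon' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(subjectiveDepth) || length(subjectiveDepth) != 1L ||
      !is.finite(subjectiveDepth) || subjectiveDepth < 1 ||
      subjectiveDepth != round(subjectiveDepth))
    stop("'subjectiveDepth' must be an integer >= 1", call. = FALSE)
  H <- as.integer(objectiveHorizon)
  D <- as.integer(subjectiveDepth)
  tRef <- (H - 1L) %/% 2L

  if (order %in% c("sequential", "interpenetrated")) {
    t <- 0:(H - 1L)
    tau <- t - tRef
    nodes <- data.frame(
      id = nodeId("hidden", t, tau), objective = t, subjective = tau,
      role = "hidden",
      label = vapply(tau, function(d) labelFor("hidden", d), ""),
      boundary = t == 0L | t == H - 1L,
      stringsAsFactors = FALSE)
    nodes$label[tau < 0] <- "retention"
    if (order == "sequential") {
      edges <- data.frame(from = nodes$id[-H], to = nodes$id[-1],
                          stringsAsFactors = FALSE)
    } else {
      ## both sides point inward: the present is a collider
      from <- to <- character()
      for (i in seq_len(H - 1L)) {
        a <- nodes$id[i]; b <- nodes$id[i + 1L]
        if (t[i] < tRef) { from <- c(from, a); to <- c(to, b) }
        else             { from <- c(from, b); to <- c(to, a) }
      }
      edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    }
    ref <- nodeId("hidden", tRef, 0L)
  } else {
    hid <- expand.grid(t = 0:(H - 1L), tau = 0:D)
    obs <- expand.grid(t = 0:(H - 1L), tau = -1:(D - 1L))
    nodes <- rbind(
      data.frame(id = nodeId("hidden", hid$t, hid$tau),
                 objective = hid$t, subjective = hid$tau, role = "hidden",
                 stringsAsFactors = FALSE),
      data.frame(id = nodeId("observation", obs$t, obs$tau),
                 objective = obs$t, subjective = obs$tau,
                 role = "observation", stringsAsFactors = FALSE))
    nodes$label <- mapply(labelFor, nodes$role, nodes$subjective)
    from <- to <- character()
    interior <- logical(nrow(nodes))
    names(interior) <- nodes$id
    for (i in which(nodes$role == "hidden")) {
      t <- nodes$objective[i]; tau <- nodes$subjective[i]
      child <- nodes$id[i]
      have <- c(FALSE, FALSE)
      if (t >= 1L && tau + 1L <= D) {
        from <- c(from, nodeId("hidden", t - 1L, tau + 1L))
        to <- c(to, child); have[1] <- TRUE
      }
      if (tau + 1L <= D) {
        from <- c(from, nodeId("hidden", t, tau + 1L))
        to <- c(to, child); have[2] <- TRUE
      }
      from <- c(from, nodeId("observation", t, tau - 1L))
      to <- c(to, child)
      interior[child] <- all(have)
    }
    nodes$boundary <- !interior & nodes$role == "hidden"
    edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
    ref <- nodeId("hidden", tRef, 0L)
  }
  new("TemporalDAG", nodes = nodes, edges = edges, order = order,
      reference = ref)
}

parentsOf <- function(dag, id) dag@edges$from[dag@edges$to == id]
childrenOf <- function(dag, id) dag@edges$to[dag@edges$from == id]

#' Markov blanket of a node
#'
#' The blanket of the target node is the union of its parents, its
#' children, and the co-parents of its children. Conditioning on the
#' blanket renders the target conditionally independent (d-separated)
#' of every other node in the graph: no variable outside the blanket
#' carries additional information about the present moment.
#'
#' @param dag a \linkS4class{TemporalDAG}.
#' @param target node id (defaults to the graph's reference node).
#' @return a \linkS4class{MarkovBlanket}.
#' @examples
#' dag <- buildTemporalDAG("integrated", 4, 2)
#' markovBlanket(dag)
#' @export
markovBlanket <- function(dag, target = dag@reference) {
  stopifnot(is(dag, "TemporalDAG"))
  if (length(target) != 1L || !(target %in% dag@nodes$id))
    stop("target node not found in graph: ", target, call. = FALSE)
  ch <- childrenOf(dag, target)
  co <- unlist(lapply(ch, parentsOf, dag = dag))
  members <- setdiff(unique(c(parentsOf(dag, target), ch, co)), target)
  new("MarkovBlanket", target = target, members = members, dag = dag)
}

#' Test d-separation by exhaustive path enumeration
#'
#' Enumerates every undirected simple path between \code{x} and
#' \code{y} and applies the standard blocking rules: a chain or fork
#' node blocks when it is in the conditioning set; a collider blocks
#' unless it, or one of its descendants, is in the conditioning set.
#' Exhaustive enumeration keeps the implementation transparent enough
#' to serve as an oracle for the blanket rule; the graphs used here
#' have at most tens of nodes.
#'
#' @param dag a \linkS4class{TemporalDAG}.
#' @param x,y distinct node ids, neither in \code{conditioning}.
#' @param conditioning character vector of node ids (possibly empty).
#' @return TRUE iff every path is blocked.
#' @examples
#' dag <- buildTemporalDAG("interpenetrated", 3)
#' past <- dag@nodes$id[dag@nodes$subjective == -1]
#' future <- dag@nodes$id[dag@nodes$subjective == 1]
#' isDSeparated(dag, past, future)                  # collider blocks
#' isDSeparated(dag, past, future, dag@reference)   # conditioning opens
#' @export
isDSeparated <- function(dag, x, y, conditioning = character()) {
  stopifnot(is(dag, "TemporalDAG"))
  ids <- dag@nodes$id
  if (!all(c(x, y, conditioning) %in% ids))
    stop("unknown node id", call. = FALSE)
  if (identical(x, y))
    stop("'x' and 'y' must be distinct", call. = FALSE)
  if (x %in% conditioning || y %in% conditioning)
    stop("'x' and 'y' must not be in the conditioning set", call. = FALSE)
  g <- asIgraph(dag)
  edgeKey <- paste(dag@edges$from, dag@edges$to, sep = "\r")
  hasEdge <- function(a, b) paste(a, b, sep = "\r") %in% edgeKey
  descendants <- function(v) {
    d <- igraph::subcomponent(g, v, mode = "out")
    setdiff(names(d), v)
  }
  paths <- igraph::all_simple_paths(g, from = x, to = y, mode = "all")
  for (p in paths) {
    v <- names(p)
    if (length(v) == 2L) return(FALSE)   # direct edge: never blocked
    blocked <- FALSE
    for (k in 2:(length(v) - 1L)) {
      m <- v[k]
      collider <- hasEdge(v[k - 1L], m) && hasEdge(v[k + 1L], m)
      if (collider) {
        opened <- m %in% conditioning ||
          any(descendants(m) %in% conditioning)
        if (!opened) { blocked <- TRUE; break }
      } else if (m %in% conditioning) {
        blocked <- TRUE; break
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

#' Asynchrony record of a Markov blanket
#'
#' Summarizes how blanket members distribute over objective time
#' relative to the target: the objective span of the members, the
#' counts of members strictly before and strictly after the target's
#' objective step, and whether those counts are imbalanced. An
#' imbalanced blanket is the asynchronous structure in which past
#' states outweigh future ones, securing continuity of the present.
#'
#' @param blanket a \linkS4class{MarkovBlanket} with at least one member.
#' @return list with \code{objectiveSpan}, \code{pastCount},
#'   \code{futureCount}, \code{imbalanced}.
#' @examples
#' dag <- buildTemporalDAG("integrated", 4, 2)
#' blanketAsynchrony(markovBlanket(dag))
#' @export
blanketAsynchrony <- function(blanket) {
  stopifnot(is(blanket, "MarkovBlanket"))
  if (length(blanket@members) == 0L)
    stop("blanket has no members", call. = FALSE)
  nd <- blanket@dag@nodes
  obj <- setNames(nd$objective, nd$id)
  mo <- obj[blanket@members]
  t0 <- obj[[blanket@target]]
  list(objectiveSpan = as.integer(max(mo) - min(mo)),
       pastCount = sum(mo < t0),
       futureCount = sum(mo > t0),
       imbalanced = sum(mo < t0) != sum(mo > t0))
}

#' Verify a Markov blanket by d-separation
#'
#' Exhaustively checks (i) correctness: conditioning on the blanket
#' members d-separates the target from every non-member node, and
#' (ii) minimality: dropping any single member re-connects the target
#' to at least one node outside the reduced blanket.
#'
#' @param blanket a \linkS4class{MarkovBlanket}.
#' @param checkMinimal also run the leave-one-out minimality check.
#' @return list with logical \code{separated} and \code{minimal}
#'   (NA when not checked).
#' @export
verifyBlanket <- function(blanket, checkMinimal = TRUE) {
  stopifnot(is(blanket, "MarkovBlanket"))
  dag <- blanket@dag
  outside <- setdiff(dag@nodes$id, c(blanket@target, blanket@members))
  separated <- all(vapply(outside, function(z)
    isDSeparated(dag, blanket@target, z, blanket@members), logical(1)))
  minimal <- NA
  if (checkMinimal && length(blanket@members)) {
    minimal <- all(vapply(blanket@members, function(w) {
      keep <- setdiff(blanket@members, w)
      out <- setdiff(dag@nodes$id, c(blanket@target, keep))
      any(!vapply(out, function(z)
        isDSeparated(dag, blanket@target, z, keep), logical(1)))
    }, logical(1)))
  }
  list(separated = separated, minimal = minimal)
}
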
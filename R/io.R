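## Serialization glue: DOT and JSON graph export, YAML/JSON model
## files, and the shared belief-trajectory table schema.

#' Export a temporal DAG as Graphviz DOT
#'
#' Node labels carry the (t, tau, role) coordinates; edge direction is
#' the direction of conditional dependency.
#'
#' @param dag a \linkS4class{TemporalDAG}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGraphDOT <- function(dag, path) {
  stopifnot(is(dag, "TemporalDAG"))
  nd <- dag@nodes
  lines <- c(sprintf("digraph \"%s\" {", dag@order),
             "  rankdir=LR;",
             sprintf("  \"%s\" [label=\"%s\\n(t=%d, tau=%+d, %s)\"%s];",
                     nd$id, nd$label, nd$objective, nd$subjective, nd$role,
                     ifelse(nd$id == dag@reference,
                            ", style=filled, fillcolor=yellow", "")),
             sprintf("  \"%s\" -> \"%s\";", dag@edges$from, dag@edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a temporal DAG as JSON
#'
#' Schema: \code{\{"nodes": [...], "edges": [[parent, child], ...],
#' "order": "...", "reference": "..."\}}.
#'
#' @inheritParams writeGraphDOT
#' @return the path, invisibly.
#' @export
writeGraphJSON <- function(dag, path) {
  stopifnot(is(dag, "TemporalDAG"))
  obj <- list(nodes = dag@nodes,
              edges = unname(Map(c, dag@edges$from, dag@edges$to)),
              order = dag@order,
              reference = dag@reference)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a temporal DAG from JSON
#'
#' @param path a file written by \code{\link{writeGraphJSON}}.
#' @return a \linkS4class{TemporalDAG}.
#' @export
readGraphJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  nodes$objective <- as.integer(nodes$objective)
  nodes$subjective <- as.integer(nodes$subjective)
  nodes$boundary <- as.logical(nodes$boundary)
  ed <- obj$edges
  if (is.null(ed) || length(ed) == 0L)
    edges <- data.frame(from = character(), to = character())
  else {
    ed <- if (is.matrix(ed)) ed else do.call(rbind, ed)
    edges <- data.frame(from = as.character(ed[, 1]),
                        to = as.character(ed[, 2]),
                        stringsAsFactors = FALSE)
  }
  new("TemporalDAG", nodes = nodes, edges = edges,
      order = obj$order, reference = obj$reference)
}

#' Write a generative model to YAML or JSON
#'
#' Schema: \code{A} (list of rows), \code{B} (list of matrices, each a
#' list of rows), \code{D}, and \code{labels} with \code{states} and
#' \code{outcomes}. The format follows the file extension
#' (.yaml/.yml or .json).
#'
#' @param model a \linkS4class{GenerativeModel}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGenerativeModel <- function(model, path) {
  stopifnot(is(model, "GenerativeModel"))
  asRows <- function(M)
    lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
  obj <- list(A = asRows(model@A),
              B = lapply(model@B, asRows),
              D = as.numeric(model@D),
              labels = list(states = model@stateLabels,
                            outcomes = model@outcomeLabels))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(obj, path, precision = 15)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported model file extension: ", path, call. = FALSE)
  invisible(path)
}

#' Read a generative model from YAML or JSON
#'
#' The loader enforces \code{\link{validateModel}}: a file violating
#' the stochasticity or dimension invariants is rejected with the
#' violation messages.
#'
#' @param path a file written by \code{\link{writeGenerativeModel}} (or
#'   hand-authored in the same schema).
#' @return a \linkS4class{GenerativeModel}.
#' @export
readGenerativeModel <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported model file extension: ", path, call. = FALSE)
  toMatrix <- function(rows)
    do.call(rbind, lapply(rows, as.numeric))
  A <- if (is.matrix(obj$A)) obj$A else toMatrix(obj$A)
  Braw <- obj$B
  B <- if (is.array(Braw) && length(dim(Braw)) == 3L)
         lapply(seq_len(dim(Braw)[1L]), function(k) Braw[k, , ])
       else if (is.matrix(Braw)) list(Braw)
       else if (is.list(Braw) && (is.matrix(Braw[[1]]) || is.list(Braw[[1]])))
         lapply(Braw, function(b) if (is.matrix(b)) b else toMatrix(b))
       else list(toMatrix(Braw))
  generativeModel(A, B, as.numeric(obj$D),
                  stateLabels = obj$labels$states,
                  outcomeLabels = obj$labels$outcomes)
}

beliefTable <- function(mat, labels, iteration) {
  T <- ncol(mat)
  data.frame(objective_t = rep(iteration, nrow(mat) * T),
             subjective_tau = rep(seq_len(T), each = nrow(mat)),
             state_label = rep(labels, T),
             probability = as.numeric(mat),
             iteration = rep(iteration, nrow(mat) * T))
}

#' @describeIn writeBeliefs export a belief lattice
#' @export
setMethod("writeBeliefs", "BeliefLattice",
          function(x, path, format = c("csv", "json"),
                   iteration = NA_integer_) {
  format <- match.arg(format)
  df <- beliefTable(x@beliefs, x@model@stateLabels, iteration)
  if (format == "csv") write.csv(df, path, row.names = FALSE)
  else jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
})

#' @describeIn writeBeliefs export exact posterior marginals
#' @export
setMethod("writeBeliefs", "ExactPosterior",
          function(x, path, format = c("csv", "json"),
                   iteration = NA_integer_) {
  format <- match.arg(format)
  df <- beliefTable(x@marginals, rownames(x@marginals), iteration)
  if (format == "csv") write.csv(df, path, row.names = FALSE)
  else jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
})
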
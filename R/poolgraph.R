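## Pool graph state: vertex allocation/deallocation against a single central
## index list, edge bits, and the two binary-state invariants:
##   (a) every vertex has 0 or 1 labels present (1 = active);
##   (b) present edges connect two active vertices.

growPoolGraph <- function(g, need = 1L) {
  n <- length(g@active)
  if (length(g@freeList) >= need) return(g)
  extra <- max(n, need)
  g@active <- c(g@active, rep(FALSE, extra))
  g@label <- c(g@label, rep(NA_character_, extra))
  adj <- matrix(0L, n + extra, n + extra)
  adj[seq_len(n), seq_len(n)] <- g@adj
  g@adj <- adj
  g@params <- c(g@params, rep(list(list()), extra))
  ## newly minted indices go under the existing free list so that freed
  ## indices are still reused first (LIFO discipline)
  g@freeList <- c(g@freeList, n + seq_len(extra))
  g
}

#' Allocate a vertex in a pool graph
#'
#' Pops an index from the LIFO free list (growing the index universe on
#' demand), activates it with the given label and optional continuous
#' parameters, and no incident edges.
#'
#' @param state a [PoolGraph-class].
#' @param label character label value.
#' @param params named list of numeric vertex parameters.
#' @return `list(state, index)`.
#' @export
allocateVertex <- function(state, label, params = list()) {
  state <- growPoolGraph(state, 1L)
  i <- state@freeList[1L]
  state@freeList <- state@freeList[-1L]
  state@active[i] <- TRUE
  state@label[i] <- label
  state@params[[i]] <- params
  list(state = state, index = i)
}

#' Deallocate a vertex (erasure-operator cleanup)
#'
#' Deactivates the vertex, clears its label and parameters, and removes all
#' incident edges in both directions -- the action of the erasure-operator
#' product that maintains the binary-state invariants. Deallocating an
#' inactive vertex is a no-op with a warning (erasure on empty is identity).
#'
#' @param state a [PoolGraph-class].
#' @param i vertex index.
#' @return the updated state.
#' @export
deallocateVertex <- function(state, i) {
  i <- as.integer(i)
  if (!state@active[i]) {
    warning("deallocating inactive vertex ", i, " is a no-op")
    return(state)
  }
  state@active[i] <- FALSE
  state@label[i] <- NA_character_
  state@params[[i]] <- list()
  state@adj[i, ] <- 0L
  state@adj[, i] <- 0L
  state@freeList <- c(i, state@freeList)
  state
}

#' Check the binary-state invariants of a pool graph
#'
#' @param state a [PoolGraph-class].
#' @return character vector of violations; empty iff (a) inactive vertices
#'   carry no label and no edges, and (b) every present edge connects two
#'   active vertices.
#' @export
checkStateInvariants <- function(state) {
  out <- character(0)
  badLabel <- which(!state@active & !is.na(state@label))
  if (length(badLabel))
    out <- c(out, paste0("(a) inactive vertex with label present: ",
                         paste(badLabel, collapse = ", ")))
  badActive <- which(state@active & is.na(state@label))
  if (length(badActive))
    out <- c(out, paste0("(a) active vertex without label: ",
                         paste(badActive, collapse = ", ")))
  e <- which(state@adj == 1L, arr.ind = TRUE)
  if (nrow(e)) {
    bad <- !(state@active[e[, 1]] & state@active[e[, 2]])
    if (any(bad))
      out <- c(out, paste0("(b) edge incident to inactive vertex: ",
                           paste(apply(e[bad, , drop = FALSE], 1, paste,
                                       collapse = "->"), collapse = ", ")))
  }
  if (any(diag(state@adj) == 1L))
    out <- c(out, "(b) self-edge present")
  out
}

#' Add an edge between active vertices
#' @param state a [PoolGraph-class]; @param i,j vertex indices.
#' @export
addEdge <- function(state, i, j) {
  stopifnot(state@active[i], state@active[j], i != j)
  state@adj[i, j] <- 1L
  if (!state@directed) state@adj[j, i] <- 1L
  state
}

#' Remove an edge
#' @param state a [PoolGraph-class]; @param i,j vertex indices.
#' @export
removeEdge <- function(state, i, j) {
  state@adj[i, j] <- 0L
  if (!state@directed) state@adj[j, i] <- 0L
  state
}

#' Active vertex indices of a pool graph
#' @param state a [PoolGraph-class].
#' @export
activeVertices <- function(state) which(state@active)

#' Vertex labels of the active vertices
#' @param state a [PoolGraph-class].
#' @return named character vector (names = vertex indices).
#' @export
vertexLabels <- function(state) {
  idx <- which(state@active)
  setNames(state@label[idx], idx)
}

#' Get a vertex parameter
#' @param state a [PoolGraph-class]; @param i vertex index;
#' @param name parameter name.
#' @export
vertexParam <- function(state, i, name) state@params[[i]][[name]]

## canonical key of the discrete part of a pool-graph state (used by the
## CME oracle on graph state spaces); ignores continuous parameters
poolGraphKey <- function(state, nv = length(state@active)) {
  lab <- state@label[seq_len(nv)]
  lab[is.na(lab)] <- "."
  e <- state@adj[seq_len(nv), seq_len(nv), drop = FALSE]
  paste0(paste(lab, collapse = ","), "|", paste(as.integer(e), collapse = ""))
}

## build a PoolGraph with given labels (NA = inactive) and edge matrix
poolGraphFromConfig <- function(labels, adj, directed = FALSE,
                                params = NULL) {
  n <- length(labels)
  g <- poolGraph(capacity = n, directed = directed)
  g@active <- !is.na(labels)
  g@label <- as.character(labels)
  g@adj <- matrix(as.integer(adj), n, n)
  if (!is.null(params)) g@params <- params
  g@freeList <- which(is.na(labels))
  g
}
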
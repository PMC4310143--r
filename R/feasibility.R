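## Time feasibility (acyclicity) of a reconciliation.
##
## Host switches constrain the relative timing of host speciations: the
## donor must still be alive when the recipient lineage exists.  With
## takeoff vertex h = gamma(v) and landing vertex l (the jumped child's
## image), the donor edge (parent(h), h) and recipient edge
## (parent(l), l) must be contemporaneous, encoded as the precedence
## constraints parent(h) -> l and parent(l) -> h laid over the ancestry
## order of the internal host vertices.  Takeoff/landing at a leaf is
## represented by its parent; self-loops arising from that substitution
## (switches between sibling leaves) are vacuous and dropped.  The
## reconciliation is time-feasible iff the constraint digraph is
## acyclic.

#' Temporal constraint edges of a reconciliation
#'
#' @param recon A `reconciliation`.
#' @param host The host `phylo_tree`.
#' @return A two-column integer matrix of directed edges between
#'   internal host vertices (ancestry edges plus switch constraints).
#' @export
temporal_constraints <- function(recon, host) {
  H <- host
  internal <- which(!H$is_leaf)
  edges <- matrix(integer(0), ncol = 2)
  for (v in internal) {
    for (ch in H$children[[v]])
      if (!H$is_leaf[ch]) edges <- rbind(edges, c(v, ch))
  }
  rep_int <- function(x) if (H$is_leaf[x]) H$parent[x] else x
  sw <- which(!is.na(recon$switch_dists))
  for (v in sw) {
    h <- recon$gamma[v]
    l <- recon$landings[v]
    e1 <- c(H$parent[h], rep_int(l))
    e2 <- c(H$parent[l], rep_int(h))
    for (e in list(e1, e2))
      if (!anyNA(e) && e[1] != e[2]) edges <- rbind(edges, e)
  }
  dimnames(edges) <- NULL
  unique(edges)
}

#' Test whether a reconciliation is time-feasible
#'
#' TRUE iff the temporal constraint digraph induced by the
#' reconciliation's host switches is acyclic, i.e. the host speciations
#' admit a total order consistent with ancestry and with every switch's
#' donor/recipient contemporaneity.
#'
#' @param recon A `reconciliation` (from [enumerate_optimal()] or
#'   [as_reconciliation()]).
#' @param host The host `phylo_tree`.
#' @return Logical.
#' @export
is_time_feasible <- function(recon, host) {
  edges <- temporal_constraints(recon, host)
  if (!nrow(edges)) return(TRUE)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges), ncol = 2), directed = TRUE)
  igraph::is_dag(g)
}

#' Partition solutions into acyclic and cyclic
#'
#' @param solutions List of `reconciliation` objects from one instance.
#' @param host The host `phylo_tree`.
#' @return `list(acyclic = ..., cyclic = ...)`, each preserving input
#'   order.
#' @export
split_by_feasibility <- function(solutions, host) {
  ok <- vapply(solutions, is_time_feasible, NA, host = host)
  list(acyclic = solutions[ok], cyclic = solutions[!ok])
}

#' DOT rendering of the temporal constraint graph
#'
#' @inheritParams is_time_feasible
#' @return A character scalar with a Graphviz `digraph`.
#' @export
temporal_graph_dot <- function(recon, host) {
  edges <- temporal_constraints(recon, host)
  lines <- apply(edges, 1, function(e)
    sprintf('  "%s" -> "%s";', host$label[e[1]], host$label[e[2]]))
  paste(c("digraph temporal {", lines, "}"), collapse = "\n")
}
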
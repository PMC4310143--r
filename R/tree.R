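## Rooted binary leaf-labelled tree with O(1) ancestry/distance queries.
## Vertex ids are postorder positions (1..n), so children always have
## smaller ids than their parent and the root is vertex n.  This postorder
## indexing is the canonical order used for all deterministic iteration
## and tie-breaking elsewhere in the package.

#' Construct a phylo_tree from parent/child structure
#'
#' Internal constructor.  `children` is a list of integer vectors (length
#' 0 for leaves, 2 for internal vertices); vertex ids must already be in
#' postorder.
#' @noRd
new_phylo_tree <- function(children, label) {
  n <- length(children)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    for (ch in children[[v]]) parent[ch] <- v
  }
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root, found ", length(root))
  is_leaf <- lengths(children) == 0L
  ## depth from root
  depth <- integer(n)
  for (v in rev(seq_len(n))) {
    if (!is.na(parent[v])) depth[v] <- depth[parent[v]] + 1L
  }
  ## ancestor-or-equal matrix: anc[u, v] TRUE iff u is on the path root..v
  anc <- diag(n) > 0
  for (v in seq_len(n)) {
    u <- parent[v]
    while (!is.na(u)) {
      anc[u, v] <- TRUE
      u <- parent[u]
    }
  }
  ## undirected path distance via depth and LCA
  dmat <- matrix(0L, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u < v) next
    a <- lca_walk(parent, depth, u, v)
    d <- depth[u] + depth[v] - 2L * depth[a]
    dmat[u, v] <- d
    dmat[v, u] <- d
  }
  structure(list(
    n = n, root = root, parent = parent, children = children,
    label = label, is_leaf = is_leaf, depth = depth,
    anc = anc, dist = dmat,
    leaves = which(is_leaf)
  ), class = "phylo_tree")
}

lca_walk <- function(parent, depth, u, v) {
  while (depth[u] > depth[v]) u <- parent[u]
  while (depth[v] > depth[u]) v <- parent[v]
  while (u != v) { u <- parent[u]; v <- parent[v] }
  u
}

#' Parse a rooted binary Newick string
#'
#' Reads one Newick description into the package's tree representation.
#' Branch lengths are accepted and discarded: all downstream distances
#' are topological edge counts.  Polytomies and duplicate leaf labels are
#' rejected.  Unnamed internal vertices receive a deterministic
#' auto-name: the lexicographically smallest leaf label of each child
#' subtree, joined by \code{"+"}.
#'
#' @param text A Newick string terminated by \code{";"}.
#' @return An object of class \code{phylo_tree}.
#' @examples
#' h <- parse_newick("((A,B),C);")
#' h$label[h$root]
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("Newick parse error: input does not end with ';'")
  ## positional pre-check: balanced parentheses
  chars <- strsplit(text, "")[[1]]
  bal <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") bal <- bal + 1L
    if (chars[i] == ")") bal <- bal - 1L
    if (bal < 0L)
      stop("Newick parse error at position ", i, ": unmatched ')'")
  }
  if (bal != 0L)
    stop("Newick parse error at position ", nchar(text),
         ": ", bal, " unclosed '('")
  body <- sub(";\\s*$", "", text)
  if (!grepl("[(),]", body)) {
    ## degenerate single-leaf tree
    lab <- sub(":[^:]*$", "", body)
    if (!nzchar(lab)) stop("Newick parse error: empty leaf label")
    return(new_phylo_tree(list(integer(0)), lab))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: unreadable tree")
  from_ape(phy)
}

## Convert an ape "phylo" to phylo_tree with postorder ids; rejects
## polytomies and duplicate leaf labels.
from_ape <- function(phy) {
  ntip <- length(phy$tip.label)
  nv <- ntip + phy$Nnode
  kids <- vector("list", nv)
  for (v in seq_len(nv)) kids[[v]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    e <- phy$edge[i, ]
    kids[[e[1]]] <- c(kids[[e[1]]], e[2])
  }
  deg <- lengths(kids)
  bad <- which(deg != 0L & deg != 2L)
  if (length(bad)) {
    nm <- vertex_name_ape(phy, bad[1], ntip)
    stop("tree is not binary: vertex '", nm, "' has ", deg[bad[1]],
         " children")
  }
  if (anyDuplicated(phy$tip.label)) {
    dup <- phy$tip.label[duplicated(phy$tip.label)][1]
    stop("duplicate leaf label '", dup, "'")
  }
  root_ape <- ntip + 1L
  ## postorder traversal preserving the written child order
  post <- integer(nv)
  cnt <- 0L
  rec <- function(v) {
    for (ch in kids[[v]]) rec(ch)
    cnt <<- cnt + 1L
    post[v] <<- cnt
  }
  rec(root_ape)
  new_ids <- post                       # ape id -> postorder id
  children <- vector("list", nv)
  label <- character(nv)
  for (v in seq_len(nv)) {
    children[[new_ids[v]]] <- unname(new_ids[kids[[v]]])
    label[new_ids[v]] <- if (v <= ntip) phy$tip.label[v] else
      if (!is.null(phy$node.label) && nzchar0(phy$node.label[v - ntip]))
        phy$node.label[v - ntip] else NA_character_
  }
  tr <- new_phylo_tree(children, label)
  autoname(tr)
}

nzchar0 <- function(x) !is.na(x) && nzchar(x)

vertex_name_ape <- function(phy, v, ntip) {
  if (v <= ntip) return(phy$tip.label[v])
  lab <- phy$node.label[v - ntip]
  if (!is.null(lab) && nzchar0(lab)) lab else paste0("node_", v)
}

## Fill in missing internal names from the smallest leaf of each child
## subtree, making printed mappings stable across runs.
autoname <- function(tr) {
  minleaf <- character(tr$n)
  for (v in seq_len(tr$n)) {
    if (tr$is_leaf[v]) minleaf[v] <- tr$label[v]
    else minleaf[v] <- min(minleaf[tr$children[[v]]])
  }
  for (v in seq_len(tr$n)) {
    if (!tr$is_leaf[v] && is.na(tr$label[v]))
      tr$label[v] <- paste(minleaf[tr$children[[v]]], collapse = "+")
  }
  tr
}

check_vertex <- function(tree, v) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v > tree$n)
    stop("vertex ", v, " is not in the tree (n = ", tree$n, ")")
  as.integer(v)
}

#' Tree queries: ancestry, LCA, distance, subtree
#'
#' `is_ancestor(tree, u, v)` is TRUE when `u` lies on the path from the
#' root to `v` (reflexive: every vertex is its own ancestor).
#' `tree_distance` is the number of edges on the undirected path between
#' two vertices, `lca` the lowest common ancestor, and
#' `subtree_vertices` the set of vertices of the clade rooted at `u`.
#'
#' @param tree A \code{phylo_tree}.
#' @param u,v Vertex ids (postorder integers).
#' @return `is_ancestor`: logical; `tree_distance`: integer edge count;
#'   `lca`: a vertex id; `subtree_vertices`: an integer vector.
#' @export
is_ancestor <- function(tree, u, v) {
  tree$anc[check_vertex(tree, u), check_vertex(tree, v)]
}

#' @rdname is_ancestor
#' @export
tree_distance <- function(tree, u, v) {
  tree$dist[check_vertex(tree, u), check_vertex(tree, v)]
}

#' @rdname is_ancestor
#' @export
lca <- function(tree, u, v) {
  lca_walk(tree$parent, tree$depth,
           check_vertex(tree, u), check_vertex(tree, v))
}

#' @rdname is_ancestor
#' @export
subtree_vertices <- function(tree, u) {
  which(tree$anc[check_vertex(tree, u), ])
}

#' Postorder vertex sequence
#'
#' Vertex ids are assigned in postorder, so this is simply `1:n`; kept as
#' a named operation because every traversal in the package relies on it.
#' @param tree A \code{phylo_tree}.
#' @export
postorder <- function(tree) seq_len(tree$n)

#' Look up vertices by leaf label
#' @param tree A \code{phylo_tree}.
#' @param labels Character vector of leaf labels.
#' @return Integer vertex ids.
#' @export
leaf_id <- function(tree, labels) {
  idx <- match(labels, tree$label)
  miss <- labels[is.na(idx) | !idx %in% tree$leaves]
  if (length(miss))
    stop("unknown leaf label(s): ", paste(miss, collapse = ", "))
  idx
}

#' Serialize a phylo_tree back to Newick
#' @param tree A \code{phylo_tree}.
#' @param names_internal Include internal vertex names in the output.
#' @return A Newick string.
#' @export
write_newick <- function(tree, names_internal = FALSE) {
  rec <- function(v) {
    if (tree$is_leaf[v]) return(tree$label[v])
    inner <- paste(vapply(tree$children[[v]], rec, ""), collapse = ",")
    paste0("(", inner, ")", if (names_internal) tree$label[v] else "")
  }
  paste0(rec(tree$root), ";")
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat("Rooted binary tree:", sum(x$is_leaf), "leaves,", x$n, "vertices\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

host_diameter <- function(tree) max(tree$dist)
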
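## Event-class grouping, the bounded-switch sweep procedures, and root
## selection for unrooted parasite/gene trees.

#' Event-count vector of a reconciliation
#'
#' @param recon A `reconciliation`.
#' @return Named integer vector `<c, d, s, l>`.
#' @export
event_vector <- function(recon) recon$event_vector

#' Group solutions into event-count classes
#'
#' Two reconciliations are in the same class when they contain the same
#' number of cospeciations, duplications, host switches and losses.
#'
#' @param solutions List of `reconciliation` objects from one instance.
#' @return A data frame with columns `c`, `d`, `s`, `l`, `count`,
#'   sorted lexicographically by the event vector.
#' @export
class_table <- function(solutions) {
  if (!length(solutions))
    return(data.frame(c = integer(0), d = integer(0), s = integer(0),
                      l = integer(0), count = integer(0)))
  keys <- vapply(solutions, function(r)
    paste(r$event_vector, collapse = ","), "")
  tab <- table(keys)
  mat <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  out <- data.frame(c = mat[, 1], d = mat[, 2], s = mat[, 3],
                    l = mat[, 4], count = as.integer(tab))
  out[order(out$c, out$d, out$s, out$l), , drop = FALSE]
}

#' Longest switch distance in one reconciliation
#'
#' @param recon A `reconciliation`.
#' @return Maximum takeoff-to-landing host distance over its switch
#'   events; 0 when there are none.
#' @export
max_switch_distance <- function(recon) {
  s <- recon$switch_dists
  if (all(is.na(s))) 0L else max(s, na.rm = TRUE)
}

#' Smallest maximum-switch-distance over all optimal solutions
#'
#' The smallest value of `max_switch_distance` across every optimal
#' reconciliation, computed without enumeration by a minimax dynamic
#' program over the solution graph: per cell, the minimum over
#' alternatives of the maximum of the children's values and the
#' alternative's own switch distance.  Bounding switches at this value
#' is guaranteed to preserve the unbounded optimal cost.
#'
#' @param table A `dp_table` or `cophyrec` fit with a finite optimum.
#' @return Integer (0 when some optimal solution has no switches).
#' @export
compute_k_start <- function(table) {
  table <- as_dp_table(table)
  if (!is.finite(table$opt))
    stop("no solution: k_start is undefined")
  P <- table$parasite
  memo <- new.env(parent = emptyenv())
  mm <- function(p, h) {
    key <- paste0(p, ".", h)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- if (P$is_leaf[p]) 0L else {
      A <- table$alts[[p]][[h]]
      ch <- P$children[[p]]
      best <- .Machine$integer.max
      for (i in seq_len(nrow(A))) {
        v <- max(A[i, "sdist"], mm(ch[1], A[i, "x"]), mm(ch[2], A[i, "y"]))
        if (v < best) best <- v
      }
      as.integer(best)
    }
    memo[[key]] <- res
    res
  }
  min(vapply(table$opt_roots, function(h) mm(P$root, h), 0L))
}

## shared machinery for the two sweeps: solve at bound k and split the
## optimal solutions by feasibility (or report a cap overrun)
sweep_step <- function(host, parasite, phi, costs, k, max_solutions) {
  tab <- fill_dp(host, parasite, phi, costs, k = k)
  if (!is.finite(tab$opt))
    return(list(k = k, opt = Inf, total = 0L, acyclic = list(),
                cyclic = list(), capped = FALSE))
  sols <- enumerate_optimal(tab, max_solutions = max_solutions)
  if (isTRUE(attr(sols, "truncated")))
    return(list(k = k, opt = tab$opt, capped = TRUE))
  parts <- split_by_feasibility(sols, host)
  list(k = k, opt = tab$opt, total = length(sols),
       acyclic = parts$acyclic, cyclic = parts$cyclic, capped = FALSE)
}

#' Largest useful switch bound admitting a time-feasible optimum
#'
#' Starting from `k_start` (whose bounded optimum equals the unbounded
#' one by construction) the bound is decremented until some optimal
#' solution at that bound is time-feasible.  When the unbounded problem
#' has no acyclic optimum, the cost at the returned bound is an upper
#' bound on the cheapest acyclic reconciliation.
#'
#' @param host,parasite,phi Instance as in [fill_dp()].
#' @param costs Cost vector.
#' @param max_solutions Per-bound enumeration cap; exceeding it aborts
#'   the scan with `status = "undetermined"`.
#' @return A list: `status` (`"found"`, `"none"` or `"undetermined"`),
#'   `k_start`, and on success `k_A`, `opt_kA`, `acyclic` (the feasible
#'   solutions at `k_A`) and `total`.
#' @export
find_kA <- function(host, parasite, phi, costs, max_solutions = 1e6) {
  tab <- fill_dp(host, parasite, phi, costs, k = Inf)
  if (!is.finite(tab$opt))
    stop("instance has no valid reconciliation")
  ks <- compute_k_start(tab)
  for (k in seq(from = max(ks, 1L), to = 1L, by = -1L)) {
    st <- sweep_step(host, parasite, phi, costs, k, max_solutions)
    if (st$capped)
      return(list(status = "undetermined", k_start = ks, k = k,
                  reason = sprintf(
                    "more than %g optimal solutions at k = %d",
                    max_solutions, k)))
    if (length(st$acyclic))
      return(list(status = "found", k_start = ks, k_A = st$k,
                  opt_kA = st$opt, acyclic = st$acyclic,
                  total = st$total))
  }
  list(status = "none", k_start = ks)
}

#' Smallest bound preserving the optimal cost with a feasible solution
#'
#' Scans upward from `k_start` and returns the first bound whose
#' optimal cost equals the unbounded optimum and whose optimal set
#' contains at least one time-feasible solution.  Useful for shrinking
#' an unmanageably large solution set without losing optimality.
#'
#' @inheritParams find_kA
#' @return A list: `status`, `k_start`, and on success `k_prime`,
#'   `total` and `acyclic` counts at `k_prime`.
#' @export
find_kprime <- function(host, parasite, phi, costs, max_solutions = 1e6) {
  tab <- fill_dp(host, parasite, phi, costs, k = Inf)
  if (!is.finite(tab$opt))
    stop("instance has no valid reconciliation")
  ks <- compute_k_start(tab)
  kmax <- max(host_diameter(host), 1L)
  for (k in seq(from = max(ks, 1L), to = kmax, by = 1L)) {
    st <- sweep_step(host, parasite, phi, costs, k, max_solutions)
    if (st$capped)
      return(list(status = "undetermined", k_start = ks, k = k,
                  reason = sprintf(
                    "more than %g optimal solutions at k = %d",
                    max_solutions, k)))
    if (abs(st$opt - tab$opt) <= DP_TOL && length(st$acyclic))
      return(list(status = "found", k_start = ks, k_prime = st$k,
                  total = st$total, n_acyclic = length(st$acyclic),
                  acyclic = st$acyclic))
  }
  list(status = "none", k_start = ks)
}

#' Root an unrooted parasite tree by reconciliation cost
#'
#' Considers every edge of the unrooted tree as a root position, solves
#' the reconciliation for each rooted version, and returns the rooting
#' of minimum optimal cost (ties broken by the smallest edge index in
#' the postorder edge ordering).
#'
#' @param parasite_unrooted An unrooted binary tree: a Newick string or
#'   an \pkg{ape} `phylo` object.
#' @param host Host `phylo_tree`.
#' @param assoc Named character vector mapping parasite leaf labels to
#'   host leaf labels.
#' @param costs Cost vector.
#' @param k Switch-distance bound.
#' @return A list: `parasite` (the selected rooted `phylo_tree`),
#'   `phi`, `opt`, `edge` (winning edge index) and `costs_by_edge`.
#' @export
select_root <- function(parasite_unrooted, host, assoc, costs, k = Inf) {
  phy <- if (is.character(parasite_unrooted))
    ape::read.tree(text = parasite_unrooted) else parasite_unrooted
  if (!inherits(phy, "phylo")) stop("cannot interpret the parasite tree")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("root selection needs at least 2 leaves")
  if (ntip > 2L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  if (ntip == 2L) {
    cand <- list(parse_newick(paste0("(", phy$tip.label[1], ",",
                                     phy$tip.label[2], ");")))
  } else {
    deg <- tabulate(c(phy$edge), nbins = ntip + phy$Nnode)
    if (any(deg[-seq_len(ntip)] > 3L))
      stop("unrooted tree is not binary")
    edges <- ape::reorder.phylo(phy, "postorder")$edge
    adj <- vector("list", ntip + phy$Nnode)
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      adj[[e[1]]] <- c(adj[[e[1]]], e[2])
      adj[[e[2]]] <- c(adj[[e[2]]], e[1])
    }
    nwk_from <- function(v, from) {
      nb <- setdiff(adj[[v]], from)
      if (!length(nb)) return(phy$tip.label[v])
      paste0("(", paste(vapply(nb, nwk_from, "", from = v),
                        collapse = ","), ")")
    }
    cand <- lapply(seq_len(nrow(edges)), function(i) {
      e <- edges[i, ]
      parse_newick(paste0("(", nwk_from(e[1], e[2]), ",",
                          nwk_from(e[2], e[1]), ");"))
    })
  }
  opts <- numeric(length(cand))
  phis <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    inst <- make_instance(host, cand[[i]], assoc)
    phis[[i]] <- inst$phi
    opts[i] <- fill_dp(host, cand[[i]], inst$phi, costs, k = k)$opt
  }
  best <- which.min(opts)                # first minimum = smallest edge id
  list(parasite = cand[[best]], phi = phis[[best]], opt = opts[best],
       edge = best, costs_by_edge = opts)
}
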
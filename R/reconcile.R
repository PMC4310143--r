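#' Fit a cophylogeny reconciliation
#'
#' The central entry point: solves the all-optimal-reconciliations
#' problem for a host/parasite tree pair under an event cost vector,
#' optionally with a bound on the host distance a switch may span.
#' Returns a classed fit holding the dynamic-programming table (the
#' compact solution graph), the optimal cost, the exact number of
#' co-optimal solutions and the smallest useful switch bound; solutions
#' are drawn from the fit lazily with [solution_iterator()] or
#' [enumerate_optimal()].
#'
#' @param host,parasite Trees: `phylo_tree` objects or Newick strings.
#'   `host` may also be an instance list (from [read_instance()] or
#'   [random_instance()]), in which case `parasite` and `mapping` are
#'   taken from it.
#' @param mapping Leaf association: a named character vector (names =
#'   parasite leaf labels, values = host leaf labels) or a two-column
#'   data frame (parasite, host).
#' @param costs Event costs `c(cospeciation, duplication, host_switch,
#'   loss)`; any real values, negatives included.
#' @param k Maximum switch distance in host-tree edges; `Inf` for
#'   unbounded.
#' @return An object of class `cophyrec`.
#' @examples
#' fit <- reconcile("((A,B),C);", "((a,b),c);",
#'                  c(a = "A", b = "B", c = "C"))
#' fit
#' summary(fit)
#' @export
reconcile <- function(host, parasite = NULL, mapping = NULL,
                      costs = c(0, 1, 1, 1), k = Inf) {
  if (is.list(host) && !inherits(host, "phylo_tree") &&
      all(c("host", "parasite", "phi") %in% names(host))) {
    inst <- host
  } else {
    h <- if (is.character(host)) parse_newick(host) else host
    p <- if (is.character(parasite)) parse_newick(parasite) else parasite
    stopifnot(inherits(h, "phylo_tree"), inherits(p, "phylo_tree"))
    if (is.data.frame(mapping))
      mapping <- stats::setNames(as.character(mapping[[2]]),
                                 as.character(mapping[[1]]))
    if (is.null(names(mapping)))
      stop("'mapping' must be named by parasite leaf labels")
    inst <- make_instance(h, p, mapping)
  }
  costs <- check_costs(costs)
  tab <- fill_dp(inst$host, inst$parasite, inst$phi, costs, k = k)
  n_opt <- count_optimal(tab)
  ks <- if (is.finite(tab$opt)) compute_k_start(tab) else NA_integer_
  structure(list(host = inst$host, parasite = inst$parasite,
                 phi = inst$phi, costs = costs, k = k, table = tab,
                 opt = tab$opt, opt_roots = tab$opt_roots,
                 n_solutions = n_opt, k_start = ks,
                 call = match.call()),
            class = "cophyrec")
}

#' @export
print.cophyrec <- function(x, ...) {
  cat("Cophylogeny reconciliation\n")
  cat("  host: ", sum(x$host$is_leaf), " leaves; parasite: ",
      sum(x$parasite$is_leaf), " leaves\n", sep = "")
  cat("  costs <c,d,s,l>: <", paste(x$costs, collapse = ","),
      ">;  switch bound k: ",
      if (is.infinite(x$k)) "unbounded" else x$k, "\n", sep = "")
  if (!is.finite(x$opt)) {
    cat("  no valid reconciliation under this bound\n")
  } else {
    cat("  optimal cost: ", format(x$opt), "\n", sep = "")
    cat("  optimal solutions: ", as.character(x$n_solutions),
        " (k_start = ", x$k_start, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @rdname reconcile
#' @param object,x A `cophyrec` fit.
#' @param max_solutions Enumeration cap used by `summary` for the
#'   feasibility split and class table.
#' @param ... Unused.
summary.cophyrec <- function(object, max_solutions = 10000, ...) {
  out <- list(fit = object, max_solutions = max_solutions)
  if (is.finite(object$opt)) {
    sols <- enumerate_optimal(object$table, max_solutions = max_solutions)
    out$truncated <- isTRUE(attr(sols, "truncated"))
    parts <- split_by_feasibility(sols, object$host)
    out$n_enumerated <- length(sols)
    out$n_acyclic <- length(parts$acyclic)
    out$n_cyclic <- length(parts$cyclic)
    out$classes <- class_table(sols)
    out$classes_acyclic <- class_table(parts$acyclic)
  }
  class(out) <- "summary.cophyrec"
  out
}

#' @export
print.summary.cophyrec <- function(x, ...) {
  print(x$fit)
  if (!is.finite(x$fit$opt)) return(invisible(x))
  if (x$truncated)
    cat("  [enumeration truncated at ", x$max_solutions,
        " solutions; counts below are partial]\n", sep = "")
  cat("  time-feasible (acyclic): ", x$n_acyclic, " / ",
      x$n_enumerated, "\n", sep = "")
  cat("  event classes <c,d,s,l>:\n")
  cls <- x$classes
  for (i in seq_len(nrow(cls)))
    cat(sprintf("    <%d,%d,%d,%d> : %d\n", cls$c[i], cls$d[i],
                cls$s[i], cls$l[i], cls$count[i]))
  invisible(x)
}

#' @export
#' @rdname reconcile
coef.cophyrec <- function(object, ...)
  stats::setNames(object$costs,
                  c("cospeciation", "duplication", "host_switch", "loss"))
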
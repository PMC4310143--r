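## Counting and enumeration of all optimal reconciliations.
##
## The per-cell alternative lists of the DP table form a DAG rooted at
## the optimal root cells: every path system through it (one alternative
## per visited cell) is one optimal reconciliation, and every optimal
## reconciliation arises exactly once this way because the cost
## decomposes over cells.  Counting multiplies/sums along the DAG with
## exact big integers; enumeration runs an odometer over the per-cell
## alternative indices, advancing the deepest choice point and resetting
## everything below it, so consecutive solutions differ by O(m) work.

#' Count all optimal reconciliations exactly
#'
#' Computes the number of cost-optimal reconciliations without
#' enumerating them, as an exact arbitrary-precision integer.
#'
#' @param table A `dp_table` from [fill_dp()], or a fit from
#'   [reconcile()].
#' @return A [bignat] count (0 when no solution exists).
#' @export
count_optimal <- function(table) {
  table <- as_dp_table(table)
  if (!is.finite(table$opt)) return(bignat(0))
  memo <- new.env(parent = emptyenv())
  P <- table$parasite
  count_cell <- function(p, h) {
    key <- paste0(p, ".", h)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- if (P$is_leaf[p]) bignat(1) else {
      A <- table$alts[[p]][[h]]
      ch <- P$children[[p]]
      acc <- bignat(0)
      for (i in seq_len(nrow(A)))
        acc <- bn_add(acc, bn_mul(count_cell(ch[1], A[i, "x"]),
                                  count_cell(ch[2], A[i, "y"])))
      acc
    }
    memo[[key]] <- res
    res
  }
  total <- bignat(0)
  for (h in table$opt_roots)
    total <- bn_add(total, count_cell(P$root, h))
  total
}

#' Iterate over all optimal reconciliations
#'
#' Returns a stateful iterator: each call to the returned function
#' yields the next optimal [as_reconciliation()] object, or `NULL` when
#' exhausted.  The order is deterministic: optimal root placements in
#' host postorder, then per-cell alternative order (cospeciation <
#' duplication < switch, then child host postorder ids).
#'
#' @inheritParams count_optimal
#' @return A function of no arguments.
#' @export
solution_iterator <- function(table) {
  table <- as_dp_table(table)
  P <- table$parasite
  state <- new.env(parent = emptyenv())
  state$host_of <- rep(NA_integer_, P$n)
  state$alt_of <- rep(NA_integer_, P$n)
  state$root_i <- 0L
  state$done <- !length(table$opt_roots)

  init_sub <- function(p, h) {
    state$host_of[p] <- h
    if (!P$is_leaf[p]) {
      state$alt_of[p] <- 1L
      A <- table$alts[[p]][[h]]
      ch <- P$children[[p]]
      init_sub(ch[1], A[1L, "x"])
      init_sub(ch[2], A[1L, "y"])
    }
  }
  ## advance the embedding of the clade at p to its next configuration;
  ## FALSE when exhausted (caller then resets or moves up)
  adv <- function(p) {
    if (P$is_leaf[p]) return(FALSE)
    ch <- P$children[[p]]
    if (adv(ch[2])) return(TRUE)
    if (adv(ch[1])) {
      init_sub(ch[2], state$host_of[ch[2]])
      return(TRUE)
    }
    A <- table$alts[[p]][[state$host_of[p]]]
    a <- state$alt_of[p]
    if (a < nrow(A)) {
      state$alt_of[p] <- a + 1L
      init_sub(ch[1], A[a + 1L, "x"])
      init_sub(ch[2], A[a + 1L, "y"])
      return(TRUE)
    }
    FALSE
  }
  function() {
    if (state$done) return(NULL)
    if (state$root_i == 0L) {
      state$root_i <- 1L
      init_sub(P$root, table$opt_roots[1L])
    } else if (!adv(P$root)) {
      state$root_i <- state$root_i + 1L
      if (state$root_i > length(table$opt_roots)) {
        state$done <- TRUE
        return(NULL)
      }
      init_sub(P$root, table$opt_roots[state$root_i])
    }
    as_reconciliation(table$host, P, table$phi, state$host_of,
                      table$costs)
  }
}

#' Enumerate optimal reconciliations into a list
#'
#' @inheritParams count_optimal
#' @param max_solutions Stop after this many solutions; the result then
#'   carries `attr(, "truncated") = TRUE`.
#' @return List of `reconciliation` objects in iterator order.
#' @export
enumerate_optimal <- function(table, max_solutions = Inf) {
  it <- solution_iterator(table)
  out <- list()
  repeat {
    if (length(out) >= max_solutions) {
      attr(out, "truncated") <- TRUE
      return(out)
    }
    r <- it()
    if (is.null(r)) break
    out[[length(out) + 1L]] <- r
  }
  attr(out, "truncated") <- FALSE
  out
}

#' First optimal reconciliation
#'
#' Head of the enumeration stream; errors when no valid reconciliation
#' exists under the bound.
#' @inheritParams count_optimal
#' @export
first_solution <- function(table) {
  table <- as_dp_table(table)
  if (!is.finite(table$opt))
    stop("no valid reconciliation exists under the current switch bound")
  solution_iterator(table)()
}

as_dp_table <- function(x) {
  if (inherits(x, "dp_table")) return(x)
  if (inherits(x, "cophyrec")) return(x$table)
  stop("expected a dp_table or cophyrec fit")
}
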
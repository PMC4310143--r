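## Dynamic program over the tree pair.
##
## D[p, h] is the minimum cost of any valid sub-reconciliation of the
## parasite clade rooted at p with p mapped to h.  Because the total
## cost decomposes over internal parasite vertices (event cost plus the
## losses charged at that vertex), the recursion is exact for arbitrary
## real costs, including negative ones.
##
## For an internal p with children p1, p2 placed at x and y, the event
## at p is determined by where x and y fall relative to h, and each
## event contributes:
##   cospeciation : c_c + c_l*(d(h,x)-1) + c_l*(d(h,y)-1),
##                  x and y in different child subtrees of h
##   duplication  : c_d + c_l*d(h,x) + c_l*d(h,y),
##                  x and y below h but not a cospeciation pattern
##   host switch  : c_s + c_l*d(h, stay image), the other child jumping
##                  to a vertex incomparable to h within distance k
## Each region is separable in x and y, so the set of optimal child
## placements per cell is a union of Cartesian products of per-child
## argmin sets; these are stored per cell and form the solution graph
## that counting, enumeration and the switch-distance minimax all walk.

DP_TOL <- 1e-9

#' Fill the reconciliation cost matrix
#'
#' Computes the full dynamic-programming table for an instance under a
#' cost vector and a switch-distance bound, including, per cell, every
#' cost-optimal placement of the two children (the solution graph).
#'
#' @param host,parasite \code{phylo_tree} objects.
#' @param phi Leaf association as an integer vector over parasite
#'   vertices (host leaf ids on leaves, NA on internal vertices).
#' @param costs Cost vector `c(cospeciation, duplication, host_switch,
#'   loss)`; any real values.
#' @param k Maximum host-tree distance (edge count) a switch may span;
#'   `Inf` for unbounded.
#' @return A `dp_table`: the matrix `D`, per-cell alternative lists
#'   `alts`, the optimal cost `opt` (`Inf` when no valid reconciliation
#'   exists under the bound) and the set `opt_roots` of host vertices
#'   achieving it at the parasite root.
#' @export
fill_dp <- function(host, parasite, phi, costs, k = Inf) {
  costs <- check_costs(costs)
  if (!(is.numeric(k) && length(k) == 1L && (is.infinite(k) || k >= 1)))
    stop("'k' must be a positive integer or Inf")
  H <- host; P <- parasite
  n <- H$n; m <- P$n
  cc <- costs[1]; cd <- costs[2]; cs <- costs[3]; cl <- costs[4]

  ## per-host precomputation
  sub <- lapply(seq_len(n), function(h) which(H$anc[h, ]))
  outk <- lapply(seq_len(n), function(h) {
    inc <- which(!H$anc[h, ] & !H$anc[, h])
    inc[H$dist[h, inc] <= k]
  })

  D <- matrix(Inf, nrow = m, ncol = n)
  alts <- vector("list", m)
  for (lf in P$leaves) D[lf, phi[lf]] <- 0

  for (p in which(!P$is_leaf)) {
    p1 <- P$children[[p]][1]; p2 <- P$children[[p]][2]
    alts[[p]] <- vector("list", n)
    for (h in seq_len(n)) {
      cell <- dp_cell(D, H, h, p1, p2, cc, cd, cs, cl, sub, outk)
      D[p, h] <- cell$cost
      alts[[p]][[h]] <- cell$alts
    }
  }

  proot <- P$root
  opt <- min(D[proot, ])
  opt_roots <- if (is.finite(opt))
    which(D[proot, ] <= opt + DP_TOL) else integer(0)
  structure(list(D = D, alts = alts, opt = opt, opt_roots = opt_roots,
                 host = H, parasite = P, phi = phi, costs = costs, k = k),
            class = "dp_table")
}

## one region of candidate placements for one child: positions `idx`
## with additive adjustment `adj` (the loss charge)
region <- function(Drow, idx, adj) {
  if (!length(idx)) return(list(min = Inf))
  val <- Drow[idx] + adj
  mn <- min(val)
  if (!is.finite(mn)) return(list(min = Inf))
  list(min = mn, arg = idx[val <= mn + DP_TOL])
}

dp_cell <- function(D, H, h, p1, p2, cc, cd, cs, cl, sub, outk) {
  leafh <- H$is_leaf[h]
  dh <- H$dist[h, ]
  terms <- list()
  add_term <- function(event, rx, ry, base, stay = NA_integer_) {
    if (is.finite(rx$min) && is.finite(ry$min))
      terms[[length(terms) + 1L]] <<- list(
        cost = base + rx$min + ry$min, event = event,
        argx = rx$arg, argy = ry$arg, stay = stay)
  }

  S <- sub[[h]]
  f1S <- region(D[p1, ], S, cl * dh[S])
  f2S <- region(D[p2, ], S, cl * dh[S])

  if (!leafh) {
    hc <- H$children[[h]]
    L <- sub[[hc[1]]]; R <- sub[[hc[2]]]
    ## cospeciation: children in different child subtrees, one loss
    ## fewer per branch than the raw depth
    c1L <- region(D[p1, ], L, cl * (dh[L] - 1))
    c1R <- region(D[p1, ], R, cl * (dh[R] - 1))
    c2L <- region(D[p2, ], L, cl * (dh[L] - 1))
    c2R <- region(D[p2, ], R, cl * (dh[R] - 1))
    add_term(1L, c1L, c2R, cc)
    add_term(1L, c1R, c2L, cc)
    ## duplication: both below h but not the cospeciation pattern;
    ## partition sub(h)^2 minus (L x R u R x L) into separable blocks
    A <- h
    g1A <- region(D[p1, ], A, 0)
    g2A <- region(D[p2, ], A, 0)
    g1L <- region(D[p1, ], L, cl * dh[L])
    g1R <- region(D[p1, ], R, cl * dh[R])
    g2L <- region(D[p2, ], L, cl * dh[L])
    g2R <- region(D[p2, ], R, cl * dh[R])
    add_term(2L, g1A, g2A, cd)
    add_term(2L, g1A, g2L, cd); add_term(2L, g1A, g2R, cd)
    add_term(2L, g1L, g2A, cd); add_term(2L, g1R, g2A, cd)
    add_term(2L, g1L, g2L, cd); add_term(2L, g1R, g2R, cd)
  } else {
    ## leaf host: the only in-subtree placement is h itself
    add_term(2L, region(D[p1, ], h, 0), region(D[p2, ], h, 0), cd)
  }
  ## host switch: one child stays (losses down to its image), the other
  ## lands on an incomparable vertex within distance k
  O <- outk[[h]]
  o1 <- region(D[p1, ], O, 0)
  o2 <- region(D[p2, ], O, 0)
  add_term(3L, f1S, o2, cs, stay = 1L)
  add_term(3L, o1, f2S, cs, stay = 2L)

  if (!length(terms)) return(list(cost = Inf, alts = NULL))
  best <- min(vapply(terms, `[[`, 0, "cost"))
  if (!is.finite(best)) return(list(cost = Inf, alts = NULL))
  rows <- list()
  for (tm in terms) {
    if (tm$cost > best + DP_TOL) next
    g <- expand.grid(x = tm$argx, y = tm$argy,
                     KEEP.OUT.ATTRS = FALSE)
    sdist <- if (tm$event == 3L) {
      if (tm$stay == 1L) dh[g$y] else dh[g$x]
    } else rep(0L, nrow(g))
    rows[[length(rows) + 1L]] <-
      cbind(x = g$x, y = g$y, event = rep(tm$event, nrow(g)),
            sdist = as.integer(sdist))
  }
  A <- do.call(rbind, rows)
  A <- A[order(A[, "event"], A[, "x"], A[, "y"]), , drop = FALSE]
  list(cost = best, alts = A)
}

#' @export
print.dp_table <- function(x, ...) {
  cat("Reconciliation DP table: ", x$parasite$n, " x ", x$host$n,
      " cells, k = ", if (is.infinite(x$k)) "unbounded" else x$k,
      "\n  optimal cost: ", format(x$opt),
      " at ", length(x$opt_roots), " root placement(s)\n", sep = "")
  invisible(x)
}
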
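## Event determination.  A reconciliation is a total map gamma of
## parasite vertices to host vertices extending the leaf association.
## The event at an internal parasite vertex v with image h and child
## images u1, u2 is read off the mapping:
##   cospeciation : h internal, u1 and u2 in different child subtrees of h
##   duplication  : both u1, u2 in the subtree of h, not a cospeciation
##   host switch  : exactly one child image in the subtree of h, the
##                  other incomparable to h
## Anything else violates the mapping constraints (no child may map to a
## proper ancestor of h; at least one child must stay below h).
##
## Losses are counted on descending path segments only:
##   cospeciation : (d(h,u1)-1) + (d(h,u2)-1) vertices strictly between
##   duplication  : d(h,u1) + d(h,u2) vertices from h down to each child
##   host switch  : d(h, u_stay) on the staying branch, none on the jump
##                  branch (the landing site is the jumped child's image)

EVENT_LEVELS <- c("cospeciation", "duplication", "host_switch")

#' Derive events and losses from a vertex mapping
#'
#' Given a total map `gamma` of parasite vertices to host vertices,
#' determines the event at every internal parasite vertex and the loss
#' multiset, or reports why the mapping is not a valid reconciliation.
#' Invalidity is a verdict, not an error, so exhaustive searches can
#' filter with it.
#'
#' @param host,parasite \code{phylo_tree} objects.
#' @param phi Integer vector over parasite vertices: host leaf ids on
#'   parasite leaves, NA elsewhere.
#' @param gamma Integer vector over parasite vertices: host vertex ids.
#' @return If valid, a list with `valid = TRUE`, `events` (character,
#'   NA on leaves), `losses` (integer multiset of host vertex ids),
#'   `event_vector` (counts `<c,d,s,l>`) and `switch_dists` (takeoff to
#'   landing distance per switch vertex, NA otherwise).  If invalid, a
#'   list with `valid = FALSE`, the offending `vertex` and a `reason`.
#' @export
classify_events <- function(host, parasite, phi, gamma) {
  P <- parasite; H <- host
  if (length(gamma) != P$n || anyNA(gamma))
    return(invalid_verdict(NA_integer_, "gamma is not total"))
  for (lf in P$leaves) {
    if (gamma[lf] != phi[lf])
      return(invalid_verdict(lf, "gamma does not extend the leaf association"))
  }
  events <- rep(NA_character_, P$n)
  sdist <- rep(NA_integer_, P$n)
  landing <- rep(NA_integer_, P$n)
  losses <- integer(0)
  for (v in which(!P$is_leaf)) {
    ch <- P$children[[v]]
    h <- gamma[v]; u1 <- gamma[ch[1]]; u2 <- gamma[ch[2]]
    in1 <- H$anc[h, u1]; in2 <- H$anc[h, u2]
    if (in1 && in2) {
      cosp <- FALSE
      if (!H$is_leaf[h]) {
        hc <- H$children[[h]]
        cosp <- (H$anc[hc[1], u1] && H$anc[hc[2], u2]) ||
                (H$anc[hc[2], u1] && H$anc[hc[1], u2])
      }
      if (cosp) {
        events[v] <- "cospeciation"
        losses <- c(losses, strict_chain(H, h, u1), strict_chain(H, h, u2))
      } else {
        events[v] <- "duplication"
        losses <- c(losses, desc_chain(H, h, u1), desc_chain(H, h, u2))
      }
    } else if (xor(in1, in2)) {
      u_out <- if (in1) u2 else u1
      u_stay <- if (in1) u1 else u2
      if (H$anc[u_out, h])
        return(invalid_verdict(v, "child mapped to an ancestor of its parent's image"))
      events[v] <- "host_switch"
      sdist[v] <- H$dist[h, u_out]
      landing[v] <- u_out
      losses <- c(losses, desc_chain(H, h, u_stay))
    } else {
      return(invalid_verdict(v, "no child mapped in the subtree of the parent's image"))
    }
  }
  ev <- c(sum(events == "cospeciation", na.rm = TRUE),
          sum(events == "duplication", na.rm = TRUE),
          sum(events == "host_switch", na.rm = TRUE),
          length(losses))
  names(ev) <- c("c", "d", "s", "l")
  list(valid = TRUE, events = events, losses = sort(losses),
       event_vector = ev, switch_dists = sdist, landings = landing)
}

invalid_verdict <- function(v, reason)
  list(valid = FALSE, vertex = v, reason = reason)

## host vertices strictly between h and a descendant u (cospeciation)
strict_chain <- function(H, h, u) {
  out <- integer(0)
  if (u == h) return(out)
  w <- H$parent[u]
  while (w != h) { out <- c(out, w); w <- H$parent[w] }
  out
}

## host vertices from h down to the parent of u inclusive (duplication /
## staying branch of a switch); empty when u == h
desc_chain <- function(H, h, u) {
  out <- integer(0)
  while (u != h) { u <- H$parent[u]; out <- c(out, u) }
  out
}

#' Assemble a reconciliation object from a mapping
#'
#' Classifies the mapping, attaches its cost under `costs`, and returns
#' a `reconciliation` object; errors if the mapping is invalid.
#' @inheritParams classify_events
#' @param costs Numeric cost vector `c(cospeciation, duplication,
#'   host_switch, loss)`.
#' @export
as_reconciliation <- function(host, parasite, phi, gamma, costs) {
  cl <- classify_events(host, parasite, phi, gamma)
  if (!cl$valid)
    stop("invalid reconciliation at vertex ",
         if (is.na(cl$vertex)) "?" else parasite$label[cl$vertex],
         ": ", cl$reason)
  structure(list(gamma = gamma, events = cl$events, losses = cl$losses,
                 event_vector = cl$event_vector,
                 switch_dists = cl$switch_dists, landings = cl$landings,
                 cost = cost_of(cl$event_vector, costs)),
            class = "reconciliation")
}

#' Total cost of an event vector
#'
#' @param x A `reconciliation` or an event-count vector `<c,d,s,l>`.
#' @param costs Numeric length-4 cost vector.
#' @return `sum(costs * counts)`.
#' @export
cost_of <- function(x, costs) {
  if (inherits(x, "reconciliation")) x <- x$event_vector
  stopifnot(length(x) == 4L, length(costs) == 4L)
  sum(as.numeric(costs) * as.numeric(x))
}

#' @export
print.reconciliation <- function(x, ...) {
  ev <- x$event_vector
  cat("Reconciliation: cost ", format(x$cost), ", events <",
      paste(ev, collapse = ","), ">\n", sep = "")
  invisible(x)
}

check_costs <- function(costs) {
  costs <- as.numeric(costs)
  if (length(costs) != 4L || anyNA(costs))
    stop("'costs' must be four real numbers <cospeciation, duplication, host_switch, loss>")
  costs
}
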
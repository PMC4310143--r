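## Random instance generation and the exhaustive-search oracle.
##
## The oracle enumerates every total extension of the leaf association
## over the internal parasite vertices, filters the valid ones by the
## same event-determination rules as classify_events (the loss
## convention is a modelling choice shared across the package), and
## minimises the cost.  It never touches the dynamic program, so the
## two routes are algorithmically independent.

#' Generate a random reconciliation instance
#'
#' Host and parasite topologies are drawn by iterative random leaf
#' attachment (uniform over rooted binary leaf-labelled topologies);
#' each parasite leaf is associated with a uniformly random host leaf.
#' The result is a pure function of `seed`.
#'
#' @param n_host,n_parasite Leaf counts (>= 1).
#' @param seed Integer seed; when given, the caller's RNG state is left
#'   untouched.
#' @return A list `host`, `parasite`, `phi` as in [read_instance()].
#' @export
random_instance <- function(n_host, n_parasite, seed = NULL) {
  stopifnot(n_host >= 1, n_parasite >= 1)
  draw <- function() {
    h <- random_topology(n_host, paste0("h", seq_len(n_host)))
    p <- random_topology(n_parasite, paste0("p", seq_len(n_parasite)))
    hl <- h$label[h$leaves]
    assoc <- stats::setNames(hl[sample.int(n_host, n_parasite,
                                           replace = TRUE)],
                             p$label[p$leaves])
    make_instance(h, p, assoc)
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## uniform rooted binary topology: attach each new leaf on a uniformly
## chosen edge (including the edge above the root)
random_topology <- function(nleaves, labels) {
  if (nleaves == 1L)
    return(new_phylo_tree(list(integer(0)), labels[1]))
  children <- list(integer(0))           # vertex 1 = first leaf
  parent <- c(NA_integer_)
  root <- 1L
  for (i in seq_len(nleaves - 1L)) {
    e <- sample.int(length(children), 1L)     # vertex below chosen edge
    leaf <- length(children) + 1L
    children[[leaf]] <- integer(0); parent[leaf] <- NA
    w <- length(children) + 1L
    children[[w]] <- c(e, leaf); parent[w] <- parent[e]
    if (!is.na(parent[e])) {
      pc <- children[[parent[e]]]
      pc[pc == e] <- w
      children[[parent[e]]] <- pc
    } else root <- w
    parent[e] <- w; parent[leaf] <- w
  }
  ## serialize with labels in leaf-creation order, then re-parse to get
  ## canonical postorder ids
  lab <- character(length(children))
  lab[lengths(children) == 0L] <- labels
  rec <- function(v) {
    if (!length(children[[v]])) return(lab[v])
    paste0("(", paste(vapply(children[[v]], rec, ""), collapse = ","), ")")
  }
  parse_newick(paste0(rec(root), ";"))
}

#' Exhaustive-search reconciliation oracle
#'
#' Enumerates all `n^i` extensions of the leaf association over the `i`
#' internal parasite vertices, keeps the valid ones with every switch
#' within distance `k`, and returns the minimum cost together with all
#' optimal vertex mappings.  Intended for small instances only.
#'
#' @inheritParams fill_dp
#' @param guard Refuse when the assignment space exceeds this size.
#' @return A list: `opt` (cost, `Inf` if no valid mapping), `gammas`
#'   (matrix, one optimal mapping per row), `n_valid`.
#' @export
brute_force_optimal <- function(host, parasite, phi, costs, k = Inf,
                                guard = 1e7) {
  costs <- check_costs(costs)
  H <- host; P <- parasite
  n <- H$n
  internal <- which(!P$is_leaf)
  m_int <- length(internal)
  if (n^m_int > guard)
    stop("assignment space ", n, "^", m_int, " exceeds the oracle guard")
  if (m_int == 0L) {
    gam <- matrix(phi, nrow = 1)
    return(list(opt = 0, gammas = gam, n_valid = 1L))
  }
  N <- as.integer(n^m_int)
  ## mixed-radix grid in postorder of the internal vertices
  A <- matrix(0L, nrow = N, ncol = m_int)
  for (j in seq_len(m_int))
    A[, j] <- ((seq_len(N) - 1L) %/% n^(j - 1L)) %% n + 1L
  col_of <- integer(P$n); col_of[internal] <- seq_len(m_int)
  img <- function(v) if (P$is_leaf[v]) rep(phi[v], N) else A[, col_of[v]]

  cost <- numeric(N)
  valid <- rep(TRUE, N)
  cc <- costs[1]; cd <- costs[2]; cs <- costs[3]; cl <- costs[4]
  child1 <- rep(1L, n); child2 <- rep(1L, n)  # dummy index for leaves
  for (hh in which(!H$is_leaf)) {
    child1[hh] <- H$children[[hh]][1]; child2[hh] <- H$children[[hh]][2]
  }
  for (v in internal) {
    ch <- P$children[[v]]
    h <- img(v); u1 <- img(ch[1]); u2 <- img(ch[2])
    in1 <- H$anc[cbind(h, u1)]; in2 <- H$anc[cbind(h, u2)]
    hint <- !H$is_leaf[h]
    hl <- ifelse(hint, child1[h], h)    # placeholder for leaf h
    hr <- ifelse(hint, child2[h], h)
    cosp <- hint & ((H$anc[cbind(hl, u1)] & H$anc[cbind(hr, u2)]) |
                    (H$anc[cbind(hr, u1)] & H$anc[cbind(hl, u2)]))
    dup <- in1 & in2 & !cosp
    sw1 <- in1 & !in2 & !H$anc[cbind(u2, h)]   # child 2 jumps
    sw2 <- !in1 & in2 & !H$anc[cbind(u1, h)]   # child 1 jumps
    ok <- cosp | dup | sw1 | sw2
    d1 <- H$dist[cbind(h, u1)]; d2 <- H$dist[cbind(h, u2)]
    sdist <- ifelse(sw1, d2, ifelse(sw2, d1, 0L))
    losses <- ifelse(cosp, d1 + d2 - 2L,
                     ifelse(dup, d1 + d2, ifelse(sw1, d1, d2)))
    cost <- cost +
      ifelse(cosp, cc, ifelse(dup, cd, cs)) + cl * losses
    valid <- valid & ok & (sdist <= k)
  }
  cost[!valid] <- Inf
  opt <- min(cost)
  if (!is.finite(opt))
    return(list(opt = Inf,
                gammas = matrix(integer(0), ncol = P$n), n_valid = 0L))
  hits <- which(valid & cost <= opt + DP_TOL)
  gammas <- matrix(rep(phi, each = length(hits)), nrow = length(hits))
  gammas[, internal] <- A[hits, , drop = FALSE]
  list(opt = opt, gammas = gammas, n_valid = sum(valid))
}
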
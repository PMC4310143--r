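## Shared fixtures and independent oracles used across the suite.

## deterministic families -----------------------------------------------

caterpillar_newick <- function(n, prefix = "h") {
  s <- paste0(prefix, 1)
  for (i in seq_len(n - 1) + 1) s <- paste0("(", s, ",", prefix, i, ")")
  paste0(s, ";")
}

balanced_newick <- function(n, prefix = "p") {
  stopifnot(bitwAnd(n, n - 1L) == 0L)
  labs <- paste0(prefix, seq_len(n))
  while (length(labs) > 1)
    labs <- vapply(seq_len(length(labs) / 2), function(i)
      paste0("(", labs[2 * i - 1], ",", labs[2 * i], ")"), "")
  paste0(labs, ";")
}

## a small bank of random instances with random costs and bounds; every
## property test iterates over draws from this
instance_bank <- function(n_instances, seed0, max_leaves = 6) {
  lapply(seq_len(n_instances), function(i) {
    cfg <- with_preserved_seed_local(seed0 + 7 * i, {
      list(nh = sample(seq_len(max_leaves), 1),
           np = sample(seq_len(max_leaves), 1),
           costs = sample(c(-1, 0, 1, 2, 3), 4, replace = TRUE),
           k = sample(list(1, 2, Inf), 1)[[1]])
    })
    inst <- random_instance(cfg$nh, cfg$np, seed = seed0 + 7 * i + 3)
    c(inst, cfg[c("costs", "k")])
  })
}

with_preserved_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

gamma_strings <- function(x) {
  if (is.matrix(x)) sort(apply(x, 1, paste, collapse = ","))
  else sort(vapply(x, function(r) paste(r$gamma, collapse = ","), ""))
}

## canonical labelled-topology string: children ordered by smallest leaf
canon_topology <- function(tree) {
  rec <- function(v) {
    if (tree$is_leaf[v]) return(tree$label[v])
    parts <- sort(vapply(tree$children[[v]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(tree$root)
}

## graph-search distance oracle on the undirected tree graph (BFS)
bfs_distance <- function(tree, u, v) {
  adj <- vector("list", tree$n)
  for (w in seq_len(tree$n)) for (ch in tree$children[[w]]) {
    adj[[w]] <- c(adj[[w]], ch); adj[[ch]] <- c(adj[[ch]], w)
  }
  dist <- rep(NA_integer_, tree$n); dist[u] <- 0L
  queue <- u
  while (length(queue)) {
    w <- queue[1]; queue <- queue[-1]
    for (nb in adj[[w]]) if (is.na(dist[nb])) {
      dist[nb] <- dist[w] + 1L; queue <- c(queue, nb)
    }
  }
  dist[v]
}

## feasibility oracle: does any total order of the internal host
## vertices satisfy every temporal constraint edge?
order_feasible <- function(recon, host) {
  edges <- temporal_constraints(recon, host)
  internal <- which(!host$is_leaf)
  if (!nrow(edges) || length(internal) <= 1L) return(TRUE)
  perms <- all_perms(internal)
  for (p in perms) {
    pos <- integer(host$n); pos[p] <- seq_along(p)
    if (all(pos[edges[, 1]] < pos[edges[, 2]])) return(TRUE)
  }
  FALSE
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

## modular count over the solution DAG, independent of the bignat limbs
count_mod <- function(table, mod) {
  P <- table$parasite
  memo <- new.env(parent = emptyenv())
  cc <- function(p, h) {
    key <- paste0(p, ".", h)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- if (P$is_leaf[p]) 1 else {
      A <- table$alts[[p]][[h]]
      ch <- P$children[[p]]
      acc <- 0
      for (i in seq_len(nrow(A)))
        acc <- (acc + cc(ch[1], A[i, "x"]) * cc(ch[2], A[i, "y"])) %% mod
      acc
    }
    memo[[key]] <- res
    res
  }
  Reduce(function(a, h) (a + cc(P$root, h)) %% mod, table$opt_roots, 0)
}

## decimal string modulo m, by Horner over digit chunks
string_mod <- function(s, m) {
  acc <- 0
  for (i in seq(1, nchar(s), by = 6)) {
    chunk <- substr(s, i, min(i + 5, nchar(s)))
    acc <- (acc * 10^nchar(chunk) + as.numeric(chunk)) %% m
  }
  acc
}

## enumeration-based minimax: min over solutions of max switch distance
minimax_by_enumeration <- function(table) {
  sols <- enumerate_optimal(table)
  min(vapply(sols, max_switch_distance, 0L))
}

## hand-built crossed-switch reconciliation on a 4-leaf host: two
## switches whose donors must each predate the other
crossed_switch_fixture <- function() {
  h <- parse_newick("((a,b),(c,d));")
  p <- parse_newick("((p1,p2),(p3,p4));")
  assoc <- c(p1 = "a", p2 = "c", p3 = "c", p4 = "a")
  inst <- make_inst(h, p, assoc)
  ## parasite postorder: p1,p2,v1,p3,p4,v2,rho
  gamma <- integer(p$n)
  gamma[leaf_id(p, c("p1", "p2", "p3", "p4"))] <-
    leaf_id(h, c("a", "c", "c", "a"))
  v1 <- p$parent[leaf_id(p, "p1")]
  v2 <- p$parent[leaf_id(p, "p3")]
  x <- h$parent[leaf_id(h, "a")]
  y <- h$parent[leaf_id(h, "c")]
  gamma[v1] <- x; gamma[v2] <- y; gamma[p$root] <- h$root
  list(host = h, parasite = p, phi = inst$phi, gamma = gamma)
}

make_inst <- function(h, p, assoc) {
  pl <- p$leaves
  phi <- rep(NA_integer_, p$n)
  phi[pl] <- leaf_id(h, unname(assoc[p$label[pl]]))
  list(host = h, parasite = p, phi = phi)
}
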
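test_that("parse_newick builds binary trees and rejects bad input", {
  t1 <- parse_newick("(A,B);")
  expect_equal(t1$n, 3L)
  expect_setequal(t1$label[t1$children[[t1$root]]], c("A", "B"))

  t2 <- parse_newick("((A,B),C);")
  expect_equal(t2$n, 5L)
  expect_setequal(t2$label[t2$leaves], c("A", "B", "C"))

  expect_error(parse_newick("(A,B,C);"), "not binary")
  expect_error(parse_newick("((A,B),A);"), "duplicate leaf label")
  expect_error(parse_newick("((A,B),C)"), "';'")
  expect_error(parse_newick("((A,B),C));"), "position")

  t3 <- parse_newick("A;")           # degenerate single-leaf tree
  expect_equal(t3$n, 1L)
  expect_true(t3$is_leaf[t3$root])
})

test_that("branch lengths are accepted and ignored", {
  a <- parse_newick("((A:0.1,B:2)x:3,C:0.5);")
  b <- parse_newick("((A,B)x,C);")
  expect_equal(write_newick(a), write_newick(b))
  expect_equal(a$dist, b$dist)
})

test_that("unnamed internal vertices get stable min-leaf auto-names", {
  tr <- parse_newick("((B,A),(D,C));")
  expect_equal(tr$label[tr$root], "A+C")
  tr2 <- parse_newick("((B,A)named,(D,C));")
  expect_equal(sort(tr$label[!tr$is_leaf]), c("A+C", "B+A", "D+C"))
  expect_true("named" %in% tr2$label)
})

test_that("distance matches hand values and the BFS oracle", {
  tr <- parse_newick("((A,B),C);")
  A <- leaf_id(tr, "A"); B <- leaf_id(tr, "B"); C <- leaf_id(tr, "C")
  expect_equal(tree_distance(tr, A, A), 0L)
  expect_equal(tree_distance(tr, A, B), 2L)
  expect_equal(tree_distance(tr, A, C), 3L)
  for (seed in 1:5) {
    inst <- random_instance(6, 2, seed = seed)
    h <- inst$host
    for (u in seq_len(h$n)) for (v in seq_len(h$n))
      expect_equal(tree_distance(h, u, v), bfs_distance(h, u, v))
  }
})

test_that("distance is a metric", {
  inst <- random_instance(6, 2, seed = 11)
  h <- inst$host
  d <- h$dist
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0L))
  expect_true(all(d[upper.tri(d)] > 0L))
  for (u in seq_len(h$n)) for (v in seq_len(h$n)) for (w in seq_len(h$n))
    expect_lte(d[u, v], d[u, w] + d[w, v])
})

test_that("ancestry, lca and subtree agree and are exhaustive-checked", {
  tr <- parse_newick("((A,B),C);")
  A <- leaf_id(tr, "A"); B <- leaf_id(tr, "B")
  expect_equal(lca(tr, A, B), tr$parent[A])
  for (v in seq_len(tr$n)) expect_true(is_ancestor(tr, tr$root, v))
  for (seed in 6:9) {
    h <- random_instance(6, 2, seed = seed)$host
    expect_equal(length(postorder(h)), h$n)
    for (u in seq_len(h$n)) {
      sub <- subtree_vertices(h, u)
      for (v in seq_len(h$n)) {
        expect_equal(is_ancestor(h, u, v), v %in% sub)
        expect_equal(lca(h, u, v), lca(h, v, u))
        ## every pair is exactly one of comparable / incomparable
        comp <- is_ancestor(h, u, v) || is_ancestor(h, v, u)
        expect_equal(comp, h$dist[u, v] == abs(h$depth[u] - h$depth[v]))
      }
    }
    expect_setequal(subtree_vertices(h, h$root), seq_len(h$n))
  }
})

test_that("postorder ids place children before parents", {
  h <- random_instance(6, 2, seed = 21)$host
  for (v in seq_len(h$n))
    for (ch in h$children[[v]]) expect_lt(ch, v)
  expect_equal(h$root, h$n)
})
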
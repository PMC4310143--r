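test_that("event determination recovers the canonical patterns", {
  h <- parse_newick("((A,B),C);")
  p <- parse_newick("((a,b),c);")
  inst <- make_inst(h, p, c(a = "A", b = "B", c = "C"))
  ## congruent identity: every internal vertex cospeciates, no losses
  gamma <- seq_len(p$n)                 # same shape, same postorder ids
  cl <- classify_events(h, p, inst$phi, gamma)
  expect_true(cl$valid)
  expect_true(all(cl$events[!p$is_leaf] == "cospeciation"))
  expect_length(cl$losses, 0L)

  ## a partial mapping is a verdict, not an error
  cl0 <- classify_events(
    h, p, inst$phi,
    replace(gamma, c(leaf_id(p, "a"), leaf_id(p, "b")), NA))
  expect_false(cl0$valid)

  ## host switch: one child below the image, the other incomparable
  hs <- parse_newick("((A,B),C);")
  ps <- parse_newick("((a,b),c);")
  i2 <- make_inst(hs, ps, c(a = "A", b = "C", c = "C"))
  g <- rep(NA_integer_, ps$n)
  g[ps$leaves] <- i2$phi[ps$leaves]
  vin <- ps$parent[leaf_id(ps, "a")]
  g[vin] <- hs$parent[leaf_id(hs, "A")]   # a stays below, b jumps to C
  g[ps$root] <- hs$root
  cl2 <- classify_events(hs, ps, i2$phi, g)
  expect_true(cl2$valid)
  expect_equal(cl2$events[vin], "host_switch")
  expect_equal(cl2$landings[vin], leaf_id(hs, "C"))
})

test_that("duplication at a shared image has zero losses", {
  h <- parse_newick("(A,B);")
  p <- parse_newick("(a,b);")
  inst <- make_inst(h, p, c(a = "A", b = "A"))
  g <- c(inst$phi[p$leaves], leaf_id(h, "A"))
  cl <- classify_events(h, p, inst$phi, g)
  expect_true(cl$valid)
  expect_equal(unname(cl$event_vector), c(0L, 1L, 0L, 0L))
})

test_that("cost_of is the inner product with the cost vector", {
  expect_equal(cost_of(c(4, 1, 4, 1), c(0, 1, 1, 1)), 6)
  expect_equal(cost_of(c(4, 0, 11, 0), c(0, 1, 1, 1)), 11)
  m_int <- 9
  expect_equal(cost_of(c(m_int, 0, 0, 0), c(-1, 1, 1, 1)), -m_int)
})

test_that("fill_dp handles degenerate and congruent instances", {
  h1 <- parse_newick("A;"); p1 <- parse_newick("a;")
  inst <- make_inst(h1, p1, c(a = "A"))
  tab <- fill_dp(h1, p1, inst$phi, c(2, 3, 4, 5))
  expect_equal(tab$opt, 0)
  expect_equal(dim(tab$D), c(1L, 1L))

  fit <- reconcile("((A,B),C);", "((a,b),c);",
                   c(a = "A", b = "B", c = "C"), costs = c(0, 1, 1, 1))
  expect_equal(fit$opt, 0)
  expect_equal(as.numeric(fit$n_solutions), 1)
  first <- first_solution(fit)
  expect_true(all(first$events[!fit$parasite$is_leaf] == "cospeciation"))
})

test_that("optimal cost and solution set match the exhaustive oracle", {
  bank <- instance_bank(40, seed0 = 5000)
  for (case in bank) {
    bf <- brute_force_optimal(case$host, case$parasite, case$phi,
                              case$costs, k = case$k)
    tab <- fill_dp(case$host, case$parasite, case$phi, case$costs,
                   k = case$k)
    if (is.infinite(bf$opt)) {
      expect_true(is.infinite(tab$opt))
      next
    }
    expect_equal(tab$opt, bf$opt)
    expect_identical(gamma_strings(enumerate_optimal(tab)),
                     gamma_strings(bf$gammas))
  }
})

test_that("every stored alternative expands to a valid optimal solution", {
  bank <- instance_bank(15, seed0 = 6200)
  for (case in bank) {
    tab <- fill_dp(case$host, case$parasite, case$phi, case$costs,
                   k = case$k)
    if (!is.finite(tab$opt)) next
    for (r in enumerate_optimal(tab)) {
      expect_s3_class(r, "reconciliation")   # classify_events passed
      expect_equal(r$cost, tab$opt)
      expect_lte(max_switch_distance(r), min(case$k, Inf))
    }
  }
})

test_that("costs scale equivariantly and k relaxes monotonically", {
  bank <- instance_bank(10, seed0 = 7700)
  for (case in bank) {
    costs <- abs(case$costs) + 0.5       # positive so lambda flips nothing
    tab1 <- fill_dp(case$host, case$parasite, case$phi, costs, k = Inf)
    tab3 <- fill_dp(case$host, case$parasite, case$phi, 3 * costs, k = Inf)
    expect_equal(tab3$opt, 3 * tab1$opt, tolerance = 1e-12)
    expect_identical(gamma_strings(enumerate_optimal(tab1)),
                     gamma_strings(enumerate_optimal(tab3)))

    diam <- max(case$host$dist)
    opts <- vapply(seq_len(max(diam, 1)), function(k)
      fill_dp(case$host, case$parasite, case$phi, case$costs, k = k)$opt,
      0)
    expect_true(all(diff(opts) <= 1e-9))
    tu <- fill_dp(case$host, case$parasite, case$phi, case$costs, k = Inf)
    expect_equal(opts[length(opts)], tu$opt)
  }
})
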
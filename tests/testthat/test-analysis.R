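test_that("class tables count event vectors with conserved totals", {
  fit <- reconcile("((A,B),C);", "((a,b),c);",
                   c(a = "A", b = "B", c = "C"))
  sols <- enumerate_optimal(fit)
  cls <- class_table(sols)
  expect_equal(nrow(cls), 1L)
  expect_equal(unname(unlist(cls[1, ])), c(2L, 0L, 0L, 0L, 1L))

  bank <- instance_bank(15, seed0 = 14000)
  for (case in bank) {
    tab <- fill_dp(case$host, case$parasite, case$phi, case$costs,
                   k = case$k)
    if (!is.finite(tab$opt)) next
    sols <- enumerate_optimal(tab)
    parts <- split_by_feasibility(sols, case$host)
    all_t <- class_table(sols)
    ac <- class_table(parts$acyclic); cy <- class_table(parts$cyclic)
    expect_equal(sum(all_t$count), length(sols))
    keyed <- function(d) stats::setNames(
      d$count, paste(d$c, d$d, d$s, d$l, sep = ","))
    ka <- keyed(ac); kc <- keyed(cy); kt <- keyed(all_t)
    merged <- sapply(names(kt), function(nm)
      sum(ka[nm], kc[nm], na.rm = TRUE))
    expect_equal(unname(merged), unname(kt))
    ## every class vector partitions the internal parasite vertices
    m_int <- sum(!case$parasite$is_leaf)
    expect_true(all(all_t$c + all_t$d + all_t$s == m_int))
  }
})

test_that("k_start from the minimax DP matches enumeration", {
  fit <- reconcile("((A,B),C);", "((a,b),c);",
                   c(a = "A", b = "B", c = "C"))
  expect_equal(fit$k_start, 0L)
  bank <- instance_bank(30, seed0 = 15000)
  for (case in bank) {
    tab <- fill_dp(case$host, case$parasite, case$phi, case$costs,
                   k = case$k)
    if (!is.finite(tab$opt)) next
    ks <- compute_k_start(tab)
    expect_equal(ks, minimax_by_enumeration(tab))
    ## bounding at k_start preserves the optimal cost by definition
    t2 <- fill_dp(case$host, case$parasite, case$phi, case$costs,
                  k = max(ks, 1))
    expect_equal(t2$opt, tab$opt)
  }
})

test_that("the downward feasibility scan matches a brute-force scan", {
  bank <- instance_bank(12, seed0 = 16000)
  for (case in bank) {
    res <- find_kA(case$host, case$parasite, case$phi, case$costs,
                   max_solutions = 5000)
    ## reference: exhaustive per-k scan with full enumeration
    tab <- fill_dp(case$host, case$parasite, case$phi, case$costs)
    ks <- compute_k_start(tab)
    ref <- NULL
    for (k in seq(from = max(ks, 1), to = 1)) {
      st <- fill_dp(case$host, case$parasite, case$phi, case$costs, k = k)
      if (!is.finite(st$opt)) next
      ac <- split_by_feasibility(enumerate_optimal(st), case$host)$acyclic
      if (length(ac)) { ref <- list(k = k, opt = st$opt, n = length(ac)); break }
    }
    if (is.null(ref)) {
      expect_equal(res$status, "none")
    } else {
      expect_equal(res$status, "found")
      expect_equal(res$k_A, ref$k)
      expect_equal(res$opt_kA, ref$opt)
      expect_equal(length(res$acyclic), ref$n)
    }
  }
})

test_that("the upward cost-preserving scan matches a brute-force scan", {
  bank <- instance_bank(12, seed0 = 17000)
  for (case in bank) {
    tab <- fill_dp(case$host, case$parasite, case$phi, case$costs)
    unb <- split_by_feasibility(enumerate_optimal(tab), case$host)
    if (!length(unb$acyclic)) next       # precondition of the scan
    res <- find_kprime(case$host, case$parasite, case$phi, case$costs,
                       max_solutions = 5000)
    expect_equal(res$status, "found")
    ks <- compute_k_start(tab)
    ref <- NULL
    for (k in seq(from = max(ks, 1), to = max(max(case$host$dist), 1))) {
      st <- fill_dp(case$host, case$parasite, case$phi, case$costs, k = k)
      if (abs(st$opt - tab$opt) > 1e-9) next
      ac <- split_by_feasibility(enumerate_optimal(st), case$host)$acyclic
      if (length(ac)) { ref <- list(k = k, n = length(ac)); break }
    }
    expect_equal(res$k_prime, ref$k)
    expect_equal(res$n_acyclic, ref$n)
    ## the bounded acyclic set never exceeds the unbounded one
    expect_lte(res$n_acyclic, length(unb$acyclic))
    keyf <- function(r) paste(r$gamma, collapse = ",")
    expect_true(all(vapply(res$acyclic, keyf, "") %in%
                    vapply(unb$acyclic, keyf, "")))
  }
})

test_that("root selection minimises cost over all edge rootings", {
  ## 2-leaf unrooted tree: the unique rooting is returned
  h <- parse_newick("(H1,H2);")
  sel <- select_root("(pa,pb);", h, c(pa = "H1", pb = "H2"),
                     c(0, 1, 1, 1))
  expect_equal(sum(sel$parasite$is_leaf), 2L)

  for (seed in c(21, 22, 23)) {
    inst <- random_instance(5, 5, seed = seed)
    p_unrooted <- ape::unroot(ape::read.tree(text = write_newick(inst$parasite)))
    assoc <- stats::setNames(
      inst$host$label[inst$phi[inst$parasite$leaves]],
      inst$parasite$label[inst$parasite$leaves])
    sel <- select_root(p_unrooted, inst$host, assoc, c(0, 1, 1, 1))
    ## independent check: cost of every candidate rooting via the oracle
    expect_equal(sel$opt, min(sel$costs_by_edge))
    ## the original rooting is among the candidates, so the selected
    ## cost can not exceed the original tree's optimum
    orig <- fill_dp(inst$host, inst$parasite, inst$phi, c(0, 1, 1, 1))
    expect_lte(sel$opt, orig$opt + 1e-9)
    ## per-edge costs agree with brute force on the re-rooted instance
    bf <- brute_force_optimal(inst$host, sel$parasite, sel$phi,
                              c(0, 1, 1, 1))
    expect_equal(sel$opt, bf$opt)
  }
})
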
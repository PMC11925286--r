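test_that("campaign specifications are validated", {
  expect_error(campaign("NoSuch", T = 5), "must be one of")
  expect_error(campaign("StatRandT", mu_plus = 0.001), "target-set size")
  expect_error(campaign("DynRandT", T = 10, t_r = 0), "positive integer")
  expect_error(campaign("DynLocT", T = 10), "zeta")
  expect_error(campaign("DynAdvLocT", T = 10, zeta = 1), "Z")
  expect_error(campaign("StatRandAll", mu_plus = -1), "non-negative")
  ## StatRandAll needs no T at all
  expect_s3_class(campaign("StatRandAll", mu_plus = 0.001), "vaxcamp_campaign")
})

test_that("the retargeting schedule fires at multiples of t_r for dynamic strategies only", {
  stat <- campaign("StatCentT", T = 5, mu_plus = 0.001)
  expect_true(retarget_due(stat, 0))
  expect_false(any(vapply(1:50, retarget_due, TRUE, campaign = stat)))

  every <- campaign("DynRandT", T = 5, t_r = 1, mu_plus = 0.001)
  expect_true(all(vapply(0:20, retarget_due, TRUE, campaign = every)))

  slow <- campaign("DynAntiT", T = 5, t_r = 20, mu_plus = 0.001)
  due <- which(vapply(0:40, retarget_due, TRUE, campaign = slow)) - 1
  expect_equal(due, c(0, 20, 40))
})

test_that("the positive budget is concentrated on targets and conserved", {
  ## untargeted baseline: everyone gets mu_plus
  expect_equal(allocate_positive(rep(1, 100), 0.001, 100), rep(0.001, 100))

  ## N=5000, |T|=500: per-target allocation 0.01, total budget 5
  ind <- rep(c(1, 0), c(500, 4500))
  alloc <- allocate_positive(ind, 0.001, 5000)
  expect_equal(unique(alloc[ind == 1]), 0.01)
  expect_equal(unique(alloc[ind == 0]), 0)
  expect_equal(sum(alloc), 0.001 * 5000, tolerance = 1e-12)

  ## N=5000, |T|=50, mu+=0.002: per-target 0.2
  ind2 <- rep(c(1, 0), c(50, 4950))
  expect_equal(max(allocate_positive(ind2, 0.002, 5000)), 0.2)

  expect_error(allocate_positive(rep(0, 10), 0.001, 10), "empty target set")
  expect_error(allocate_positive(rep(c(1, 0), c(1, 99)), 0.02, 100), "exceeds 1")
  ## zero budget never errors, even with no targets
  expect_equal(allocate_positive(rep(0, 5), 0, 5), rep(0, 5))
})

test_that("static random selection is uniform without replacement", {
  g <- fixture_graph("ring", 10)
  expect_equal(sort(select_static_random(g, 10)), 1:10)
  expect_error(select_static_random(g, 11), "exceeds")

  set.seed(66)
  draws <- replicate(2000, select_static_random(g, 1))
  tab <- table(factor(draws, levels = 1:10))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("centrality selection takes the top betweenness nodes with random boundary ties", {
  ## star: the hub is the unique top node
  star <- fixture_graph("star", 6)
  expect_equal(select_static_central(betweenness_scores(star), 1), 1L)

  ## path a-b-c-d-e: the middle node is the unique maximum (oracle-checked)
  path5 <- fixture_graph("path", 5)
  oracle <- brute_betweenness(path5)
  expect_equal(which.max(oracle), 3L)
  expect_equal(select_static_central(betweenness_scores(path5), 1), 3L)

  ## complete graph: all scores tie at 0, so a uniform random 3-subset
  k5 <- betweenness_scores(fixture_graph("complete", 5))
  set.seed(77)
  picks <- replicate(2000, sort(select_static_central(k5, 3)))
  expect_true(all(apply(picks, 2, length) == 3))
  tab <- table(factor(picks, levels = 1:5))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("dynamic random selection draws from the neutral population", {
  expect_equal(sort(select_dynamic_random(4:8, 5)), 4:8) # pool == T
  expect_equal(select_dynamic_random(integer(0), 5), integer(0))
  set.seed(88)
  draws <- replicate(2000, select_dynamic_random(11:20, 1))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 11:20)))$p.value, 1e-3)
})

test_that("anti-neighbour selection prefers eligible agents and tops up at random", {
  ## 4 eligible of 8 neutrals: a draw of 2 is always eligible
  neutrals <- 1:8
  n_minus <- c(1, 2, 0, 0, 3, 1, 0, 0)
  set.seed(99)
  for (i in 1:25) {
    picked <- select_dyn_anti(neutrals, n_minus, 2)
    expect_true(all(n_minus[picked] >= 1))
  }
  ## exactly T eligible: deterministic
  expect_equal(sort(select_dyn_anti(neutrals, n_minus, 4)), c(1, 2, 5, 6))
  ## shortfall: all eligible plus random top-up to T
  picked <- select_dyn_anti(neutrals, n_minus, 6)
  expect_equal(length(picked), 6)
  expect_true(all(c(1, 2, 5, 6) %in% picked))
  ## no anti-vaccine adopters at all: uniform fallback over neutrals
  picked0 <- select_dyn_anti(neutrals, rep(0, 8), 3)
  expect_equal(length(picked0), 3)
})

test_that("local-information scores follow the absolute-difference formulas", {
  expect_equal(score_local(1, zeta = 1), 0)
  expect_equal(score_local(8, zeta = 1), 7)
  expect_equal(score_local(0, zeta = 0), 0)
  expect_equal(score_advanced(10, 10, zeta = 10, Z = 10), 0)
  expect_equal(score_advanced(1, 8, zeta = 8, Z = 1), 14)
  expect_equal(score_advanced(0, 0, zeta = 0, Z = 0), 0)
  expect_error(score_local(-1, 0), "non-negative")
})

test_that("ascending-score selection cuts correctly with random ties", {
  ## all distinct: the three lowest, deterministically
  expect_equal(sort(select_by_score(1:6, c(9, 2, 7, 1, 5, 3), 3)), c(2, 4, 6))

  ## all tied: a uniform random subset of size T
  set.seed(111)
  draws <- replicate(2000, sort(select_by_score(1:5, rep(1, 5), 2)))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:5)))$p.value, 1e-3)

  ## randomized instances: max selected score <= min unselected score
  for (i in 1:50) {
    n <- sample(5:30, 1)
    sc <- sample(0:5, n, replace = TRUE)
    size <- sample(1:n, 1)
    sel <- select_by_score(seq_len(n), sc, size)
    expect_equal(length(sel), min(size, n))
    if (length(sel) < n) {
      expect_lte(max(sc[sel]), min(sc[-sel]))
    }
  }
})

test_that("every strategy conserves the positive budget at each retargeting step", {
  set.seed(123)
  g <- ws_network(60, 4, 0.1)
  op <- c(rep(-1L, 8), rep(0L, 44), rep(1L, 8))
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  scores <- betweenness_scores(g)$betweenness
  camps <- list(
    campaign("StatRandAll", mu_plus = 0.002),
    campaign("StatRandT", T = 10, mu_plus = 0.002),
    campaign("StatCentT", T = 10, mu_plus = 0.002),
    campaign("DynRandT", T = 10, t_r = 1, mu_plus = 0.002),
    campaign("DynAntiT", T = 10, t_r = 1, mu_plus = 0.002),
    campaign("DynLocT", T = 10, t_r = 1, zeta = 1, mu_plus = 0.002),
    campaign("DynAdvLocT", T = 10, t_r = 1, zeta = 1, Z = 3, mu_plus = 0.002)
  )
  for (cmp in camps) {
    tgt <- vaxcampsim:::select_targets(cmp, g, op, a, scores)
    ind <- integer(60)
    ind[tgt] <- 1L
    alloc <- allocate_positive(ind, cmp$mu_plus, 60)
    expect_equal(sum(alloc), 0.002 * 60, tolerance = 1e-12)
    ## allocation is positive exactly on the target set
    expect_equal(which(alloc > 0), sort(tgt))
    ## dynamic strategies never target a committed agent
    if (cmp$strategy %in% c("DynRandT", "DynAntiT", "DynLocT", "DynAdvLocT")) {
      expect_true(all(op[tgt] == 0L))
    }
  }
})

test_that("an uninformative score degenerates DynLocT into DynRandT", {
  ## no anti-vaccine adopters: every neutral agent scores |0 - zeta|, all
  ## tied, so selection is uniform over neutrals, exactly like DynRandT
  g <- fixture_graph("ring", 12)
  op <- integer(12)
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  loc <- campaign("DynLocT", T = 1, t_r = 1, zeta = 5, mu_plus = 0.01)
  set.seed(131)
  draws <- replicate(2400, vaxcampsim:::select_targets(loc, g, op, a))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:12)))$p.value, 1e-3)
})
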
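test_that("anti-vaccine cluster statistics partition the negative agents", {
  g <- fixture_graph("ring", 6)
  none <- anti_cluster_stats(g, agents_with_opinions(rep("neutral", 6)))
  expect_equal(none$n_components, 0L)
  expect_equal(none$largest, 0L)

  ## 6-cycle with negatives {1, 2, 4}: components {1,2} and {4}
  ops <- rep("neutral", 6)
  ops[c(1, 2, 4)] <- "negative"
  cs <- anti_cluster_stats(g, agents_with_opinions(ops))
  expect_equal(cs$sizes, c(2L, 1L))
  expect_equal(cs$largest, 2L)

  ## random assignments agree with the union-find oracle
  set.seed(21)
  for (i in 1:8) {
    gg <- random_small_graph(12, 0.3)
    opsr <- sample(c("negative", "neutral"), 12, replace = TRUE)
    neg <- which(opsr == "negative")
    want <- sort(vapply(uf_components(gg, neg), length, 1L), decreasing = TRUE)
    got <- anti_cluster_stats(gg, agents_with_opinions(opsr))$sizes
    expect_equal(as.integer(got), as.integer(want))
    expect_equal(sum(got), length(neg))
  }
})

test_that("the target histogram bins targeted neutral agents by neighbourhood profile", {
  ## a targeted centre with 1 negative and 8 neutral neighbours: cell (1, 8)
  g <- fixture_graph("star", 10)
  ops <- c("neutral", "negative", rep("neutral", 8))
  h <- target_neighborhood_histogram(g, agents_with_opinions(ops), targets = 1)
  expect_equal(h$n_minus, 1L)
  expect_equal(h$n_zero, 8L)
  expect_equal(h$n_agents, 1L)

  ## empty target set: empty histogram
  h0 <- target_neighborhood_histogram(g, agents_with_opinions(ops), integer(0))
  expect_equal(nrow(h0), 0)

  ## non-neutral targets are excluded; the total equals |targets & neutral|
  set.seed(31)
  gg <- ws_network(80, 6, 0.05)
  opsr <- sample(c("negative", "neutral", "positive"), 80, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  tgt <- sample(80, 25)
  hh <- target_neighborhood_histogram(gg, agents_with_opinions(opsr), tgt)
  expect_equal(sum(hh$n_agents), sum(opsr[tgt] == "neutral"))
})

test_that("histogram aggregation averages cellwise over simulations", {
  h1 <- tibble::tibble(n_minus = c(1L, 2L), n_zero = c(8L, 3L), n_agents = c(2L, 1L))
  h2 <- tibble::tibble(n_minus = 1L, n_zero = 8L, n_agents = 4L)
  agg <- aggregate_histograms(list(h1, h2))
  expect_equal(agg$mean_agents[agg$n_minus == 1 & agg$n_zero == 8], 3)
  expect_equal(agg$mean_agents[agg$n_minus == 2 & agg$n_zero == 3], 0.5)
  ## grand total equals the average targeted-neutral count
  expect_equal(sum(agg$mean_agents), (3 + 4) / 2)
})

test_that("opposite zeta/Z settings shift the targeted profile as designed", {
  ## with many negatives around, zeta=1/Z=8 concentrates targets on few
  ## anti-vaccine neighbours and many neutral ones; zeta=8/Z=1 the reverse
  set.seed(41)
  g <- ws_network(300, 10, 0.01)
  ops <- rep("neutral", 300)
  ops[sample(300, 60)] <- "negative"
  ag <- agents_with_opinions(ops)
  op_int <- ifelse(ops == "negative", -1L, 0L)
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  pick <- function(zeta, Z) {
    camp <- campaign("DynAdvLocT", T = 20, t_r = 1, zeta = zeta, Z = Z, mu_plus = 0.001)
    vaxcampsim:::select_targets(camp, g, op_int, a)
  }
  mean_profile <- function(tgt) {
    h <- target_neighborhood_histogram(g, ag, tgt)
    c(
      x = sum(h$n_minus * h$n_agents) / sum(h$n_agents),
      y = sum(h$n_zero * h$n_agents) / sum(h$n_agents)
    )
  }
  protective <- mean_profile(pick(zeta = 1, Z = 8))
  frontline <- mean_profile(pick(zeta = 8, Z = 1))
  expect_lt(protective[["x"]], frontline[["x"]])
  expect_gt(protective[["y"]], frontline[["y"]])
})

test_that("edge lists round-trip losslessly with header metadata", {
  set.seed(51)
  g <- ws_network(30, 4, 0.1)
  path <- withr::local_tempfile(fileext = ".edges")
  write_network(g, path)
  expect_match(readLines(path, n = 1), "N=30 k=4 p=0.1")
  g2 <- read_network(path)
  expect_equal(igraph::vcount(g2), 30)
  canon_edges <- function(gr) {
    el <- igraph::as_edgelist(gr, names = FALSE)
    sorted <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    sorted[order(sorted[, 1], sorted[, 2]), ]
  }
  expect_equal(canon_edges(g2), canon_edges(g))
})

test_that("network parsing errors and repairs are explicit", {
  p <- withr::local_tempfile()
  writeLines(c("# comment", "1 2", "2 3", "3 1"), p)
  tri <- read_network(p)
  expect_equal(igraph::ecount(tri), 3)

  writeLines(c("1 2", "2 1", "2 3"), p)
  expect_warning(dedup <- read_network(p), "duplicate")
  expect_equal(igraph::ecount(dedup), 2)

  writeLines(c("1 2", "2 2"), p)
  expect_error(read_network(p), "self-loop")

  writeLines(c("1 2", "2 3 4"), p)
  expect_error(read_network(p), "line 2")

  ## arbitrary labels are relabelled with a persisted mapping
  writeLines(c("geneA geneB", "geneB geneC"), p)
  gl <- read_network(p)
  expect_equal(gl$label_mapping$label, c("geneA", "geneB", "geneC"))
  expect_equal(igraph::V(gl)$label, gl$label_mapping$label)
})

test_that("graphml round-trips an isomorphic network", {
  set.seed(61)
  g <- ws_network(20, 4, 0.2)
  p <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, p, format = "graphml")
  g2 <- read_network(p, format = "graphml")
  expect_true(igraph::isomorphic(g, g2))
})

test_that("result writing is deterministic and complete", {
  cfg <- sim_config(
    n = 100, k = 4, p = 0.05,
    diffusion = diffusion_params(0.02, 0.05, theta = 2, tau = 30),
    campaign = campaign("DynAntiT", T = 10, t_r = 5, mu_plus = 0.02),
    n_networks = 2, n_sir_runs = 2, master_seed = 5
  )
  res <- run_scenario(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_results(res, d1)
  expect_true(all(file.exists(m1)))
  expect_equal(basename(m1), c("scenario.csv", "replicates.csv", "metadata.json"))
  ## a re-run with the same master seed gives byte-identical CSV bodies
  write_results(run_scenario(cfg), d2)
  for (f in c("scenario.csv", "replicates.csv")) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
  meta <- jsonlite::read_json(file.path(d1, "metadata.json"))
  expect_equal(meta$replication$master_seed, 5)
  expect_equal(meta$campaign$strategy, "DynAntiT")

  ## sweep output: one summary row per swept value, in input order
  sw <- run_sweep(cfg, "mu_plus", c(0.01, 0.02, 0.04))
  d3 <- withr::local_tempdir()
  write_results(sw, d3)
  tab <- utils::read.csv(file.path(d3, "scenario.csv"))
  expect_equal(tab$value, c(0.01, 0.02, 0.04))
})

test_that("trajectory export writes the per-step opinion counts", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  run <- run_opinion_stage(g, diffusion_params(1, 0, theta = 2, tau = Inf))
  p <- withr::local_tempfile(fileext = ".csv")
  export_trajectory(run, p)
  tab <- utils::read.csv(p)
  expect_equal(names(tab), c("step", "n_negative", "n_neutral", "n_positive"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_negative, c(0, 0, 4))
})
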
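chain_net <- function(edges) {
  signed_network(edges)
}

test_that("tf_activity: zero targets, antisymmetry, planted recovery", {
  set.seed(1)
  sig <- stats::rnorm(2000); names(sig) <- paste0("g", 1:2000)
  reg <- list(TF1 = data.frame(target = paste0("g", 1:6),
                               mode = c(1, 1, 1, 1, -1, -1),
                               likelihood = rep(1, 6)))
  sig0 <- sig; sig0[paste0("g", 1:6)] <- 0
  r0 <- tf_activity(sig0, reg, n_perm = 200, seed = 2)
  expect_equal(r0$score, 0)
  expect_equal(r0$state, "ns")

  # negating all regulon modes negates the score exactly (same null seed)
  r1 <- tf_activity(sig, reg, n_perm = 200, seed = 2)
  reg_neg <- list(TF1 = transform(reg$TF1, mode = -mode))
  r2 <- tf_activity(sig, reg_neg, n_perm = 200, seed = 2)
  expect_equal(r2$score, -r1$score, tolerance = 1e-12)

  # 4 activating targets at x = +2 over N(0,1): called active in >= 9/10 seeds
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    x <- stats::rnorm(2000); names(x) <- paste0("g", 1:2000)
    tg <- sample(names(x), 5)
    x[tg] <- 2
    rg <- list(TFA = data.frame(target = tg, mode = 1, likelihood = 1))
    a <- tf_activity(x, rg, n_perm = 500, seed = s, min_regulon_size = 5)
    a$state == "active"
  }, logical(1))
  expect_gte(sum(hits), 9)

  # undersized regulon skipped with a warning
  small <- list(TFS = data.frame(target = "g1", mode = 1, likelihood = 1))
  expect_message(out <- tf_activity(sig, small, n_perm = 50, seed = 1),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("prune_network equals the induced subgraph on random fixtures", {
  ed <- data.frame(source = "A", sign = "+1", target = "B")
  net <- signed_network(rbind(ed, data.frame(source = "B", sign = "-1", target = "C")))
  pr <- prune_network(net, c("A", "B"))
  expect_equal(pr$nodes, c("A", "B"))
  expect_equal(nrow(pr$edges), 1)
  # all expressed: identical graph
  pr2 <- prune_network(net, net$nodes)
  expect_equal(pr2$edges, net$edges, ignore_attr = TRUE)

  set.seed(33)
  for (i in 1:20) {
    g <- random_signed_graph(10, 0.3, seed = i)
    net_i <- signed_network(g)
    expr <- sample(net_i$nodes, 6)
    pr_i <- prune_network(net_i, expr)
    want <- g[g$source %in% expr & g$target %in% expr, ]
    expect_equal(nrow(pr_i$edges), nrow(unique(want)))
    # pruning never creates reachability
    for (s in intersect(expr, pr_i$nodes)) {
      before <- signed_shortest_paths(net_i, s, 5)$node
      after <- signed_shortest_paths(pr_i, s, 5)$node
      expect_true(all(after %in% before))
    }
  }
})

test_that("signed_shortest_paths: chains, diamonds, depth cutoff", {
  net <- chain_net(data.frame(source = c("S", "A"),
                              sign = c("-1", "-1"),
                              target = c("A", "T")))
  sp <- signed_shortest_paths(net, "S")
  expect_equal(sp$path_sign[sp$node == "T"], 1)   # two inhibitions activate
  expect_equal(sp$distance[sp$node == "T"], 2)

  direct <- chain_net(data.frame(source = "S", sign = "+1", target = "T"))
  spd <- signed_shortest_paths(direct, "S")
  expect_equal(spd$distance, 1)
  expect_equal(spd$path_sign, 1)

  # diamond with disagreeing equal-length paths is ambiguous
  dia <- chain_net(data.frame(source = c("S", "A", "S", "B"),
                              sign = c("+1", "+1", "-1", "+1"),
                              target = c("A", "T", "B", "T")))
  spdia <- signed_shortest_paths(dia, "S")
  expect_equal(spdia$path_sign[spdia$node == "T"], 0)

  # nodes beyond max_len absent; self-loops ignored
  long <- chain_net(data.frame(source = c("S", "A", "B", "C", "D", "E", "S"),
                               sign = "+1",
                               target = c("A", "B", "C", "D", "E", "F", "S")))
  sp5 <- signed_shortest_paths(long, "S", max_len = 5)
  expect_false("F" %in% sp5$node)
  expect_true("E" %in% sp5$node)
  expect_false("S" %in% sp5$node)
})

test_that("signed_shortest_paths matches exhaustive path enumeration", {
  # 200 random digraphs with <= 12 nodes: distance and consensus sign
  # both agree with brute-force simple-path enumeration
  for (i in 1:200) {
    n <- sample(4:12, 1)
    g <- random_signed_graph(n, p_edge = 0.2, seed = i)
    if (nrow(g) == 0) next
    net <- signed_network(g)
    src <- g$source[1]
    got <- signed_shortest_paths(net, src, max_len = 5)
    want <- oracle_signed_paths(net$edges, src, max_len = 5)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("score_regulator: hand case, empty case, antisymmetry", {
  r0 <- score_regulator(integer(0), integer(0), 1)
  expect_equal(unlist(r0), c(score = 0, n_correct = 0, n_incorrect = 0,
                             n_ambiguous = 0, n_unexplained = 0))

  ps <- c(T1 = 1L, T2 = 1L, T3 = -1L)
  st <- c(T1 = 1L, T2 = 1L, T3 = -1L)
  expect_equal(score_regulator(ps, st, 1)$score, 3)
  expect_equal(score_regulator(ps, st, -1)$score, -3)

  set.seed(44)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    ps_i <- setNames(sample(c(-1L, 1L), k, TRUE), paste0("T", 1:k))
    st_i <- setNames(sample(c(-1L, 1L), k, TRUE), paste0("T", 1:k))
    a <- score_regulator(ps_i, st_i, 1)
    b <- score_regulator(ps_i, st_i, -1)
    expect_equal(a$score, -b$score)   # no ambiguity/unexplained here
  }

  amb <- score_regulator(c(T1 = 0L, T2 = 1L), c(T1 = 1L, T2 = 0L), 1)
  expect_equal(amb$n_ambiguous, 1)
  expect_equal(amb$n_unexplained, 1)
  expect_equal(amb$score, 0)
})

test_that("find_master_regulators: ranking, support filter, order invariance", {
  sim <- simulate_regulatory_layer(n_tfs = 5, n_candidates = 8,
                                   planted_mrs = c(MR1 = "active"), seed = 3)
  states <- setNames(c(rep(1L, length(sim$truth$active_tfs)),
                       rep(-1L, length(sim$truth$inactive_tfs))),
                     c(sim$truth$active_tfs, sim$truth$inactive_tfs))
  mr <- find_master_regulators(sim$network, states, twas_genes = "MR1",
                               min_score = 2)
  expect_equal(mr$regulator_id[1], "MR1")
  expect_equal(mr$hypothesis[1], "active")
  expect_true(mr$retained[1])
  # high score without any support is not retained
  no_support <- find_master_regulators(sim$network, states)
  expect_false(any(no_support$retained))
  # require_both demands both criteria
  both <- find_master_regulators(sim$network, states, twas_genes = "MR1",
                                 deg_genes = character(0), require_both = TRUE)
  expect_false(both$retained[both$regulator_id == "MR1"][1])

  # candidate pruned out by the tissue filter disappears from results
  expressed <- setdiff(sim$tpm$gene_id[sim$tpm$tpm > 1], "CAND01")
  pruned <- prune_network(sim$network, expressed)
  mr2 <- find_master_regulators(pruned, states)
  expect_false("CAND01" %in% mr2$regulator_id)

  # deterministic under node input order permutation
  perm_edges <- sim$network$edges[sample(nrow(sim$network$edges)), ]
  perm_edges$sign <- ifelse(perm_edges$sign > 0, "+1", "-1")
  net_perm <- signed_network(perm_edges, sim$network$roles)
  mr3 <- find_master_regulators(net_perm, states, twas_genes = "MR1",
                                min_score = 2)
  expect_equal(mr3, mr, ignore_attr = TRUE)
})

test_that("run_regulators: sex-opposite states appear in the matrix", {
  # plant the same regulator as active in the female stratum and
  # inactive in the male stratum; the state matrix shows opposite calls
  # one shared network; the male stratum sees the sign-flipped
  # signature, so every TF state flips and MR1's best hypothesis
  # flips from active to inactive
  ok <- vapply(1:10, function(s) {
    fem <- simulate_regulatory_layer(planted_mrs = c(MR1 = "active"), seed = s)
    cfg <- default_config(n_perm = 300L, seed = s, min_score = 2L)
    expressed <- fem$tpm$gene_id[fem$tpm$tpm > 1]
    out <- suppressMessages(run_regulators(
      list(female = fem$signature, male = -fem$signature),
      fem$regulons, fem$network,
      list(female = expressed, male = expressed),
      twas_genes = "MR1", cfg = cfg))
    m <- out$state_matrix
    length(out$per_stratum) == 2 &&
      grepl("^active", m["MR1", "female"]) &&
      grepl("^inactive", m["MR1", "male"])
  }, logical(1))
  expect_gte(sum(ok), 8)

  # determinism: same config + seed gives identical matrices
  fem <- simulate_regulatory_layer(planted_mrs = c(MR1 = "active"), seed = 5)
  cfg <- default_config(n_perm = 200L, seed = 5)
  a <- suppressMessages(run_regulators(list(f = fem$signature), fem$regulons,
                                       fem$network,
                                       list(f = fem$tpm$gene_id[fem$tpm$tpm > 1]),
                                       twas_genes = "MR1", cfg = cfg))
  b <- suppressMessages(run_regulators(list(f = fem$signature), fem$regulons,
                                       fem$network,
                                       list(f = fem$tpm$gene_id[fem$tpm$tpm > 1]),
                                       twas_genes = "MR1", cfg = cfg))
  expect_identical(a$state_matrix, b$state_matrix)
})
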
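test_that("graph reversal flips both link types and is an involution", {
  chain <- chain_net()
  rev <- reversed_graph(chain)
  expect_setequal(paste(rev$source, rev$target),
                  c("S1 P", "P H", "H B"))
  twice <- data.frame(source = rev$target, target = rev$source)
  expect_setequal(paste(twice$source, twice$target),
                  paste(chain$links$source, chain$links$target))
  loop <- make_net("B", trophic = data.frame(source = "B", target = "B"))
  expect_equal(reversed_graph(loop),
               data.frame(source = "B", target = "B"))
})

test_that("two-node chain matches the closed-form fixed point", {
  pr <- personalized_pagerank(data.frame(source = "S", target = "P"),
                              c("S", "P"), "S", alpha = 0.15)
  expect_equal(unname(pr["S"]), 0.15 / (1 - 0.85^2), tolerance = 1e-9)
  expect_equal(unname(pr["P"]), 0.85 * 0.15 / (1 - 0.85^2), tolerance = 1e-9)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("isolated restart node keeps all mass; scores always sum to 1", {
  pr <- personalized_pagerank(data.frame(source = "a", target = "b"),
                              c("a", "b", "lone"), "lone")
  expect_equal(unname(pr["lone"]), 1)
  set.seed(51)
  for (i in 1:10) {
    net <- random_web(sample(5:20, 1), 30)
    nodes <- net$nodes$id
    pr <- personalized_pagerank(reversed_graph(net), nodes,
                                sample(nodes, 1))
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_true(all(pr >= 0))
  }
})

test_that("power iteration agrees with a direct linear solve", {
  set.seed(52)
  for (i in 1:15) {
    S <- sample(5:50, 1)
    net <- random_web(S, sample(S:(4 * S), 1))
    edges <- reversed_graph(net)
    nodes <- net$nodes$id
    restart <- sample(nodes, 1)
    pr <- personalized_pagerank(edges, nodes, restart)
    oracle <- ppr_solve_oracle(edges, nodes, restart)
    expect_lt(max(abs(pr - oracle)), 1e-8)
  }
})

test_that("scores are equivariant under node relabeling", {
  net <- synth_system(S = 20, C = 0.15, seed = 53,
                      services = data.frame(service = "sv", redundancy = 3L))
  edges <- reversed_graph(net)
  nodes <- net$nodes$id
  pr <- personalized_pagerank(edges, nodes, "sv")
  relab <- stats::setNames(paste0("N", seq_along(nodes)), nodes)
  edges2 <- data.frame(source = unname(relab[edges$source]),
                       target = unname(relab[edges$target]))
  pr2 <- personalized_pagerank(edges2, unname(relab[nodes]),
                               unname(relab["sv"]))
  expect_equal(unname(pr2[relab[nodes]]), unname(pr[nodes]),
               tolerance = 1e-12)
})

test_that("the damping-convention switch swaps the two readings", {
  edges <- data.frame(source = "S", target = "P")
  a <- personalized_pagerank(edges, c("S", "P"), "S", alpha = 0.15,
                             alpha_is_damping = TRUE)
  b <- personalized_pagerank(edges, c("S", "P"), "S", alpha = 0.85)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("supporting scores exclude providers and rank by proximity", {
  chain <- chain_net()
  imp <- supporting_scores(chain)
  expect_true(is.na(imp$scores["P", "S1"]))  # provider undefined
  expect_false(anyNA(imp$scores[c("B", "H"), "S1"]))
  expect_gt(imp$scores["H", "S1"], imp$scores["B", "S1"])  # closer to restart
  expect_false("S1" %in% rownames(imp$scores))
  # strictly decreasing with distance from the restart service
  expect_gt(imp$mean[["H"]], imp$mean[["B"]])

  # a species providing every service has no defined mean
  net <- make_net(c("B", "P"),
                  trophic = data.frame(source = "B", target = "P"),
                  provision = data.frame(source = c("P", "P"),
                                         target = c("s1", "s2")))
  imp <- supporting_scores(net)
  expect_true(is.na(imp$mean[["P"]]))
  expect_false(is.na(imp$mean[["B"]]))
  expect_error(seq_supporting(net, imp$mean["P"]), "no species")

  # identical services yield identical per-service score vectors
  dia <- diamond_net()
  links <- rbind(dia$links,
                 data.frame(source = c("B1", "B2"), target = "S2",
                            link_type = "provision"))
  nodes <- rbind(dia$nodes,
                 data.frame(id = "S2", name = "S2", node_type = "service",
                            biomass = NA, abundance = NA,
                            life_stage = NA, group = NA, vulnerable = NA))
  twin <- econet(nodes, links)
  imp <- supporting_scores(twin)
  expect_equal(imp$scores[, "S"], imp$scores[, "S2"], tolerance = 1e-12)

  expect_error(supporting_scores(chain_net(with_service = FALSE)),
               "no services")
})

test_that("zero-fill and rebuild-graph variants behave as documented", {
  chain <- chain_net()
  zf <- supporting_scores(chain, zero_fill = TRUE)
  expect_equal(unname(zf$mean["P"]), 0)  # provider contributes 0, not NA
  rb <- supporting_scores(chain, rebuild_graph = TRUE)
  # with P removed from the reversed graph the walk cannot leave S1
  expect_equal(unname(rb$scores["B", "S1"]), 0)
  expect_equal(unname(rb$scores["H", "S1"]), 0)
})

test_that("implementation cross-checks against igraph personalized PageRank", {
  net <- synth_system(S = 30, C = 0.12, seed = 54,
                      services = data.frame(service = "sv", redundancy = 4L))
  edges <- reversed_graph(net)
  nodes <- net$nodes$id
  g <- igraph::graph_from_data_frame(edges, vertices = nodes)
  ig <- igraph::page_rank(g, personalized = as.numeric(nodes == "sv"),
                          damping = 0.85)$vector
  pr <- personalized_pagerank(edges, nodes, "sv")
  expect_equal(unname(pr[nodes]), unname(ig[nodes]), tolerance = 1e-6)
})
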
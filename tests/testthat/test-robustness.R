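test_that("hand-worked chain and diamond robustness values are exact", {
  chain <- chain_net()
  tr <- simulate_sequence(chain, c("H", "B", "P"))
  expect_equal(robustness_fw(tr)$value, 0.5)     # (0.5/3 + 0.5/3)/(2/3)
  expect_equal(robustness_es(tr)$value, 0)
  expect_equal(robustness_indiv(tr, "S1")$value, 0)

  expect_equal(robustness_fw(simulate_sequence(chain, "P"))$value, 1)
  expect_equal(robustness_fw(simulate_sequence(chain, "B"))$value, 0)

  dia <- diamond_net()
  tru <- simulate_sequence(dia, c("B1", "B2"))
  expect_equal(robustness_es(tru)$value, 0.5)    # (1 + 0)/2
  expect_equal(robustness_indiv(tru, "S")$value, 0.5)
  trw <- simulate_sequence(dia, c("B1", "B2"), mode = "weighted")
  expect_equal(robustness_es(trw)$value, 0.125)  # (0.25 + 0)/2
})

test_that("a surviving service scores exactly max(x)", {
  net <- make_net(c("B", "H", "X"),
                  trophic = data.frame(source = c("B", "B"),
                                       target = c("H", "X")),
                  provision = data.frame(source = "X", target = "S"))
  tr <- simulate_sequence(net, "H")
  expect_equal(robustness_indiv(tr, "S")$value, tr$max_x)
  expect_error(robustness_indiv(tr, "nope"), "unknown")
})

test_that("trapezoid rule anchors the curve at (0, 1)", {
  chain <- chain_net()
  tr <- simulate_sequence(chain, "B")
  expect_equal(robustness_fw(tr)$value, 0)
  expect_equal(robustness_fw(tr, rule = "trapezoid")$value, 0.5)
})

test_that("robustness values stay in [0, 1] and weighted <= unweighted", {
  set.seed(31)
  for (i in 1:30) {
    net <- synth_system(S = 25, C = 0.12, seed = 700 + i,
                        services = data.frame(service = c("sa", "sb"),
                                              redundancy = c(2L, 6L)))
    targets <- sample(species_ids(net), sample(5:25, 1))
    tru <- simulate_sequence(net, targets)
    trw <- simulate_sequence(net, targets, mode = "weighted")
    ru <- robustness_es(tru)$value
    rw <- robustness_es(trw)$value
    expect_gte(ru, 0); expect_lte(ru, 1)
    expect_lte(rw, ru + 1e-12)
    expect_gte(robustness_fw(tru)$value, 0)
    expect_lte(robustness_fw(tru)$value, 1)
    for (s in c("sa", "sb")) {
      iu <- robustness_indiv(tru, s)$value
      iw <- robustness_indiv(trw, s)$value
      expect_lte(iw, iu + 1e-12)
      expect_gte(iu, 0); expect_lte(iu, 1)
    }
  }
})

test_that("adding a provider cannot lower unweighted individual robustness", {
  set.seed(32)
  for (i in 1:20) {
    net <- synth_system(S = 20, C = 0.15, seed = 800 + i,
                        services = data.frame(service = "sv",
                                              redundancy = 2L))
    targets <- sample(species_ids(net), 15)
    base <- robustness_indiv(simulate_sequence(net, targets), "sv")$value
    extra <- setdiff(species_ids(net), provision_links(net)$source)[1]
    links2 <- rbind(net$links,
                    data.frame(source = extra, target = "sv",
                               link_type = "provision"))
    net2 <- econet(net$nodes, links2)
    more <- robustness_indiv(simulate_sequence(net2, targets), "sv")$value
    expect_gte(more, base - 1e-12)
  }
})

test_that("removing every species of a connected web drives y to zero", {
  chain <- chain_net(with_service = FALSE)
  tr <- simulate_sequence(chain_net(), c("B", "H", "P"))
  last_real <- max(which(!tr$points$skipped))
  expect_equal(tr$points$y_fw[last_real], 0)
  expect_equal(tr$points$y_es[last_real], 0)
})

test_that("ensemble summaries report n, mean, min, max coherently", {
  s <- summarize_ensemble(c(0.2, 0.4, 0.6))
  expect_equal(s[c("n_reps", "mean", "min", "max")],
               list(n_reps = 3L, mean = 0.4, min = 0.2, max = 0.6))
  one <- summarize_ensemble(0.3)
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)

  chain <- chain_net()
  res <- list(robustness_fw(simulate_sequence(chain, "P")),
              robustness_es(simulate_sequence(chain, "P")))
  expect_error(summarize_ensemble(res), "mixed metrics")

  net <- synth_system(S = 30, C = 0.12, seed = 55,
                      services = data.frame(service = "sv", redundancy = 3L))
  vals <- vapply(seq_random(net, 200, seed = 5), function(sq)
    robustness_fw(simulate_sequence(net, sq))$value, 0)
  s <- summarize_ensemble(vals)
  expect_lte(s$min, s$mean)
  expect_lte(s$mean, s$max)
})

test_that("most-connected removal is harsher than random on average", {
  set.seed(33)
  vals <- t(vapply(1:30, function(i) {
    net <- generate_niche_web(40, 0.1, seed = 900 + i)
    mc <- robustness_fw(simulate_sequence(net, seq_most_connected(net)))$value
    rnd <- mean(vapply(seq_random(net, 20, seed = i), function(sq)
      robustness_fw(simulate_sequence(net, sq))$value, 0))
    c(mc = mc, rnd = rnd)
  }, c(mc = 0, rnd = 0)))
  expect_lt(mean(vals[, "mc"]), mean(vals[, "rnd"]))
})
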
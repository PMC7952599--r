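test_that("construction validates ids, endpoints and link types", {
  net <- chain_net()
  expect_s3_class(net, "econet")
  expect_equal(length(species_ids(net)), 3)
  expect_equal(service_ids(net), "S1")
  expect_equal(nrow(trophic_links(net)), 2)
  expect_equal(nrow(provision_links(net)), 1)

  nodes <- data.frame(id = c("a", "a"), name = c("a", "a"),
                      node_type = "species")
  expect_error(econet(nodes, data.frame(source = character(),
                                        target = character(),
                                        link_type = character())),
               "duplicate node id")
  nodes <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      node_type = "species")
  expect_error(
    econet(nodes, data.frame(source = "a", target = "zz",
                             link_type = "trophic")),
    "row\\(s\\): 1")
  expect_error(
    econet(nodes, data.frame(source = "a", target = "b",
                             link_type = "eats")),
    "link_type")
  expect_error(
    econet(nodes, data.frame(source = c("a", "a"), target = c("b", "b"),
                             link_type = "trophic")),
    "duplicate link")
  # services cannot be edge sources
  nodes <- rbind(nodes, data.frame(id = "sv", name = "sv",
                                   node_type = "service"))
  expect_error(
    econet(nodes, data.frame(source = "sv", target = "a",
                             link_type = "trophic")),
    "species to species")
  expect_error(
    econet(nodes, data.frame(source = "sv", target = "a",
                             link_type = "provision")),
    "provider species -> service")
})

test_that("empty link tables and isolated species are legal", {
  net <- make_net(c("x", "y"))
  expect_equal(length(species_ids(net)), 2)
  expect_equal(nrow(net$links), 0)
  expect_setequal(basal_species(net), c("x", "y"))
})

test_that("basal species ignore self-loops and partition the web", {
  expect_equal(basal_species(chain_net()), "B")
  loop <- make_net("B", trophic = data.frame(source = "B", target = "B"))
  expect_equal(basal_species(loop), "B")
  dia <- diamond_net()
  expect_setequal(basal_species(dia), c("B1", "B2"))
  # partition and invariance under edge reordering
  set.seed(4)
  for (i in 1:20) {
    net <- random_web(12, 30)
    b <- basal_species(net)
    expect_true(all(b %in% species_ids(net)))
    shuf <- net
    shuf$links <- shuf$links[sample.int(nrow(shuf$links)), ]
    expect_setequal(basal_species(econet(shuf$nodes, shuf$links)), b)
  }
})

test_that("read/write round trip is lossless", {
  dir <- withr::local_tempdir()
  net <- chain_net()
  net$nodes$biomass <- c(1.23456789012345678, NA, 3 / 7, NA)
  paths <- write_network(net, file.path(dir, "chain"))
  back <- read_network(paths[1], paths[2])
  expect_identical(back$nodes$id, net$nodes$id)
  expect_identical(back$nodes$biomass, net$nodes$biomass)  # NA stays NA, not 0
  expect_identical(back$links, net$links)

  set.seed(7)
  for (i in 1:100) {
    syn <- synth_system(S = sample(10:25, 1), C = 0.15,
                        services = data.frame(service = "sv",
                                              redundancy = 2L),
                        seed = i)
    p <- write_network(syn, file.path(dir, paste0("w", i)))
    b <- read_network(p[1], p[2])
    expect_identical(b$nodes, syn$nodes)
    expect_identical(b$links, syn$links)
  }
})

test_that("graphml export is readable and preserves structure", {
  dir <- withr::local_tempdir()
  net <- chain_net()
  paths <- write_network(net, file.path(dir, "g"), graphml = TRUE)
  g <- igraph::read_graph(paths[3], format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(igraph::V(g)$name, net$nodes$id)
})

test_that("filtering induces the subnetwork and keeps empty services", {
  net <- make_net(
    c("B", "H", "P", "par", "det"),
    trophic = data.frame(source = c("B", "H", "P", "det"),
                         target = c("H", "P", "par", "B")),
    provision = data.frame(source = c("P", "par"), target = c("S1", "S2")),
    group = c(B = "plant", H = "invert", P = "fish", par = "parasite",
              det = "detritus"),
    life_stage = c(B = "adult", H = "adult", P = "adult", par = "adult",
                   det = "adult"))
  expect_warning(
    filter_network(net, drop_groups = c("parasite", "detritus"),
                   keep_stages = "adult"),
    "zero providers")
  out <- suppressWarnings(
    filter_network(net, drop_groups = c("parasite", "detritus"),
                   keep_stages = "adult"))
  expect_setequal(species_ids(out), c("B", "H", "P"))
  expect_setequal(service_ids(out), c("S1", "S2"))  # S2 kept, flagged
  expect_equal(nrow(trophic_links(out)), 2)
  # no-filter call is the identity
  same <- filter_network(net)
  expect_identical(same$nodes, net$nodes)
  expect_identical(same$links, net$links)
  expect_error(filter_network(net, drop_groups = c("plant", "invert", "fish",
                                                   "parasite", "detritus")),
               "removes all species")
})

test_that("filtering never creates edges: retained set equals induced subgraph", {
  set.seed(11)
  for (i in 1:15) {
    net <- random_web(sample(8:30, 1), 60)
    net$nodes$group <- sample(c("a", "b", "c"), nrow(net$nodes), TRUE)
    net$nodes$group[net$nodes$node_type == "service"] <- NA
    keep_grp <- c("a", "b")
    out <- filter_network(net, drop_groups = "c")
    kept <- species_ids(out)
    # brute-force induced edge set
    tl <- trophic_links(net)
    induced <- tl[tl$source %in% kept & tl$target %in% kept, ]
    got <- trophic_links(out)
    expect_setequal(paste(got$source, got$target),
                    paste(induced$source, induced$target))
  }
})
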
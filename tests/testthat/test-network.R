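test_that("occurrence network links hosts to OTUs seen in any sample", {
  counts <- rbind(
    a1 = c(o_a1 = 5, o_a2 = 0, o_shared = 1, o_b1 = 0, o_b2 = 0, o_zero = 0),
    a2 = c(2, 3, 0, 0, 0, 0),
    b1 = c(0, 0, 4, 6, 1, 0))
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     sample_type = "sponge",
                     host_species = c("spA", "spA", "spB"))
  net <- build_network(otu_table(counts), meta)
  # 2 species x 2 private OTUs + 1 shared OTU -> m = 6
  expect_equal(net$m, 6)
  expect_false("o_zero" %in% net$otus)           # all-zero OTU dropped
  expect_equal(unname(net$inc["spA", "o_a2"]), 1)  # seen in 1 of 2 samples
  expect_equal(sum(net$host_degree), sum(net$otu_degree))

  meta_bad <- meta; meta_bad$host_species[2] <- NA
  expect_error(build_network(otu_table(counts), meta_bad),
               "lacking host species")
})

test_that("barber_Q reproduces hand-evaluated and closed-form values", {
  # K_{2,2}, one module: A equals the null expectation everywhere
  k22 <- matrix(1, 2, 2, dimnames = list(c("h1", "h2"), c("o1", "o2")))
  net <- bipartite_network(k22)
  one <- stats::setNames(rep(1L, 4), c("h1", "h2", "o1", "o2"))
  expect_equal(barber_Q(net, one), 0)

  # two disjoint single-edge components, own modules: Q = 1/2
  inc <- rbind(ha = c(1, 0), hb = c(0, 1))
  colnames(inc) <- c("oa", "ob")
  net2 <- bipartite_network(inc)
  two <- stats::setNames(c(1L, 2L, 1L, 2L), c("ha", "hb", "oa", "ob"))
  expect_equal(barber_Q(net2, two), 0.5)

  # k equal complete-bipartite blocks: Q = 1 - 1/k
  for (k in c(2, 4)) {
    inc_k <- matrix(0, 2 * k, 2 * k,
                    dimnames = list(paste0("h", seq_len(2 * k)),
                                    paste0("o", seq_len(2 * k))))
    for (b in seq_len(k) - 1) inc_k[b * 2 + 1:2, b * 2 + 1:2] <- 1
    net_k <- bipartite_network(inc_k)
    part_k <- stats::setNames(rep(rep(seq_len(k), each = 2), 2),
                              c(rownames(inc_k), colnames(inc_k)))
    expect_equal(barber_Q(net_k, part_k), 1 - 1 / k)
  }

  expect_error(barber_Q(net2, two[-1]), "missing from partition")
})

test_that("barber_Q equals the brute-force double-loop on random networks", {
  set.seed(101)
  for (rep in 1:60) {
    nh <- sample(2:6, 1)
    no <- sample(2:6, 1)
    inc <- random_incidence(nh, no, p = runif(1, 0.3, 0.8))
    net <- bipartite_network(inc)
    g <- random_membership(inc, sample(1:4, 1))
    expect_equal(barber_Q(net, g), brute_force_Q(inc, g), tolerance = 1e-12)
  }
})

test_that("Q is invariant to module relabelling and to class swap", {
  set.seed(55)
  inc <- random_incidence(5, 7, 0.4)
  net <- bipartite_network(inc)
  g <- random_membership(inc, 3)
  relab <- stats::setNames(c(9L, 4L, 7L)[g], names(g))
  expect_equal(barber_Q(net, g), barber_Q(net, relab))
  swapped <- bipartite_network(t(inc))
  expect_equal(barber_Q(net, g), barber_Q(swapped, g))
})

test_that("degree-one pruning removes and reattaches consistently", {
  set.seed(7)
  # 10 OTUs, exactly 3 with a single link
  repeat {
    inc <- random_incidence(4, 7, 0.6)
    if (all(colSums(inc) >= 2)) break
  }
  inc <- cbind(inc, s1 = c(1, 0, 0, 0), s2 = c(0, 1, 0, 0),
               s3 = c(0, 0, 1, 0))
  net <- bipartite_network(inc)
  stopifnot(sum(net$otu_degree == 1) == 3)
  pr <- prune_degree_one(net)
  expect_equal(length(pr$net$otus), 7L)
  expect_equal(pr$net$m, net$m - 3)
  expect_equal(unname(pr$pruned[c("s1", "s2", "s3")]),
               c("H1", "H2", "H3"))

  part <- find_modules(pr$net, n_restarts = 5, seed = 2)
  full <- reattach_pruned(part, pr$pruned, net = net)
  # retained nodes keep their relative partition
  expect_equal(full$membership[names(part$membership)], part$membership)
  # each pruned OTU sits in its host's module
  for (o in names(pr$pruned))
    expect_equal(unname(full$membership[o]),
                 unname(full$membership[pr$pruned[o]]))
  # placing a pruned OTU in its sole host's module is a Q optimum over
  # single-node alternatives
  for (alt in setdiff(unique(full$membership), full$membership["s1"])) {
    moved <- full$membership
    moved["s1"] <- alt
    expect_lte(barber_Q(net, moved), barber_Q(net, full$membership) + 1e-12)
  }

  expect_identical(reattach_pruned(part, stats::setNames(character(0),
                                                         character(0))),
                   part)
  expect_error(reattach_pruned(part, c(sX = "H_unknown")), "contract error")
})

test_that("module search matches closed-form optima on canonical graphs", {
  # two disconnected complete-bipartite blocks -> 2 modules, Q = 1/2
  inc <- matrix(0, 6, 6, dimnames = list(paste0("h", 1:6), paste0("o", 1:6)))
  inc[1:3, 1:3] <- 1; inc[4:6, 4:6] <- 1
  part <- find_modules(bipartite_network(inc), n_restarts = 10, seed = 4)
  expect_equal(part$Q, 0.5)
  expect_equal(part$n_modules, 2L)

  # K_{3,3}: no positive-Q split exists
  k33 <- matrix(1, 3, 3, dimnames = list(paste0("h", 1:3), paste0("o", 1:3)))
  p33 <- find_modules(bipartite_network(k33), n_restarts = 10, seed = 4)
  expect_equal(p33$Q, 0)
  expect_equal(p33$n_modules, 1L)

  # never below the all-in-one-module baseline (Q = 0)
  set.seed(31)
  for (rep in 1:10) {
    inc_r <- random_incidence(sample(3:6, 1), sample(3:6, 1), 0.5)
    pr <- find_modules(bipartite_network(inc_r), n_restarts = 5, seed = rep)
    expect_gte(pr$Q, 0)
  }

  expect_error(find_modules(bipartite_network(
    matrix(0, 1, 1, dimnames = list("h", "o"))), seed = 1), "empty network")
})

test_that("module search is deterministic under a fixed seed", {
  set.seed(77)
  inc <- random_incidence(6, 10, 0.35)
  net <- bipartite_network(inc)
  p1 <- find_modules(net, n_restarts = 8, seed = 12)
  p2 <- find_modules(net, n_restarts = 8, seed = 12)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$Q, p2$Q)
})

test_that("planted three-module structure is recovered exactly", {
  cfg <- synthetic_config(n_modules = 3, hosts_per_module = 10,
                          otus_per_module = 50, p_within = 0.9,
                          p_between = 0.01, seed = 33)
  ds <- generate_dataset(cfg)
  net <- build_network(ds$table, ds$meta)
  pr <- prune_degree_one(net)
  part <- find_modules(pr$net, n_restarts = 5, seed = 34)
  full <- reattach_pruned(part, pr$pruned, net = net)
  expect_equal(nmi(full$membership, ds$truth$membership), 1)
  expect_equal(full$n_modules, 3L)
})

test_that("module summaries count composition the way results are printed", {
  hosts <- sprintf("h%02d", 1:34)
  membership <- stats::setNames(rep(1L, 34), hosts)
  part <- module_partition(membership,
                           stats::setNames(rep("host", 34), hosts))
  traits <- host_traits(data.frame(
    host_species = hosts,
    host_type = c(rep("HMA", 25), rep("LMA", 9))))
  ms <- module_summary(part, traits = traits)
  expect_equal(ms$pct_hma, 73.53)
  expect_equal(ms$n_hosts, 34L)

  # no classified hosts -> NA composition
  traits_na <- host_traits(data.frame(host_species = hosts,
                                      host_type = NA_character_))
  expect_true(is.na(module_summary(part, traits = traits_na)$pct_hma))

  # all-HMA module by construction
  cfg <- synthetic_config(hma_fraction_per_module = c(1, 0, 0), seed = 3)
  ds <- generate_dataset(cfg)
  ms2 <- module_summary(ds$truth, traits = ds$traits, meta = ds$meta)
  expect_equal(ms2$pct_hma[1], 100)
  expect_false(anyNA(ms2$temp_mean))
})
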
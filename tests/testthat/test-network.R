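basic_net <- function() example_network("basic")$network

test_that("validation flags match the defining predicates", {
  rep_ <- validate_network(basic_net())
  expect_true(rep_$is_rooted)
  expect_true(rep_$is_acyclic)
  expect_true(rep_$base_set_ok)
  expect_true(rep_$is_normal)
  expect_true(rep_$is_semibinary)
  expect_equal(nrow(rep_$redundant_arcs), 0)

  bad <- example_network("redundant")$network
  rep2 <- validate_network(bad)
  expect_false(rep2$is_normal)
  expect_true(any(rep2$redundant_arcs[, 1] == "5" &
                  rep2$redundant_arcs[, 2] == "m"))

  solo <- phylo_network(matrix(character(0), ncol = 2), root = "r")
  rep3 <- validate_network(solo)
  expect_true(rep3$is_rooted && rep3$is_acyclic && rep3$base_set_ok &&
              rep3$is_normal && rep3$is_semibinary)
})

test_that("malformed networks are rejected at construction", {
  expect_error(phylo_network(rbind(c("a", "a"))), "self-loop")
  expect_error(phylo_network(rbind(c("a", "b"), c("a", "b"))),
               "duplicate arc")
  expect_error(phylo_network(rbind(c("a", "b")), root = "c"), "root 'c'")
  expect_error(phylo_network(rbind(c("a", "b")), base_set = c("a", "z")),
               "'z'")
})

test_that("redundant-arc detection searches paths avoiding the arc", {
  bad <- example_network("redundant")$network
  expect_true(is_redundant_arc(bad, c("5", "m")))
  expect_false(is_redundant_arc(bad, c("6", "m")))
  net <- basic_net()
  expect_false(is_redundant_arc(net, c("6", "7")))
  # every arc of a tree is non-redundant
  tree <- random_network(5, 0, seed = 2)$network
  for (i in seq_len(nrow(tree$arcs)))
    expect_false(is_redundant_arc(tree, tree$arcs[i, ]))
  expect_error(is_redundant_arc(net, c("1", "7")), "not in the network")
})

test_that("parent maps enumerate one choice per hybrid, in order", {
  net <- basic_net()
  pm <- parent_maps(net)
  expect_length(pm, 2)
  expect_equal(vapply(pm, function(p) p[["7"]], ""), c("6", "8"))
  # every map valid: assigned vertex is a parent
  for (p in pm)
    for (v in names(p)) expect_true(p[[v]] %in% net$parents[[v]])

  expect_length(parent_maps(example_network("large")$network), 4)
  expect_length(parent_maps(random_network(6, 0, seed = 1)$network), 1)
})

test_that("parent-map count equals the product of hybrid indegrees", {
  for (seed in 1:6) {
    sim <- random_network(5 + seed %% 3, seed %% 4, seed = seed,
                          alpha_mode = "equiprobable")
    net <- sim$network
    k <- length(hybrid_vertices(net))
    expect_length(parent_maps(net), 2^k)
  }
})

test_that("displayed trees keep exactly the chosen parent arcs", {
  net <- basic_net()
  pm <- parent_maps(net)
  t1 <- displayed_tree(net, pm[[1]])   # p(7) = 6
  keys1 <- paste(t1$kept_arcs[, 1], t1$kept_arcs[, 2])
  expect_false("8 7" %in% keys1)
  expect_true("6 7" %in% keys1)
  t2 <- displayed_tree(net, pm[[2]])   # p(7) = 8
  keys2 <- paste(t2$kept_arcs[, 1], t2$kept_arcs[, 2])
  expect_false("6 7" %in% keys2)
  # a tree displays itself
  tree <- random_network(5, 0, seed = 4)$network
  tt <- displayed_tree(tree, parent_maps(tree)[[1]])
  expect_setequal(paste(tt$kept_arcs[, 1], tt$kept_arcs[, 2]),
                  paste(tree$arcs[, 1], tree$arcs[, 2]))
  # contract violation
  p_bad <- pm[[1]][-1]
  expect_error(displayed_tree(net, p_bad), "does not cover")
})

test_that("normal path witnesses are valid and deterministic", {
  large <- example_network("large")$network
  w <- normal_path_witness(large, "20")
  expect_false(is.null(w))
  expect_equal(w[1], "20")
  expect_true(w[length(w)] %in% large$base_set)
  for (v in w[-1]) expect_equal(unname(large$indegree[[v]]), 1L)
  expect_identical(w, normal_path_witness(large, "20"))

  net <- basic_net()
  expect_null(normal_path_witness(net, "6", avoid = "2"))
  expect_identical(normal_path_witness(net, "3"), "3")
  expect_error(normal_path_witness(net, "zz"), "not in the network")
})

test_that("every vertex of a normal network has a normal path witness", {
  for (seed in 1:5) {
    sim <- random_network(5, seed %% 3, seed = seed,
                          alpha_mode = "equiprobable")
    for (v in sim$network$vertices)
      expect_false(is.null(normal_path_witness(sim$network, v)),
                   label = paste("witness for", v, "seed", seed))
  }
})

test_that("tree splits partition the base set as expected", {
  net <- basic_net()
  pm <- parent_maps(net)
  s1 <- tree_splits(displayed_tree(net, pm[[1]]))
  expect_true("1,2,3|4" %in% names(s1))      # the arc (5,8) split
  s2 <- tree_splits(displayed_tree(net, pm[[2]]))
  expect_false(setequal(names(s1), names(s2)))  # distinct displayed trees

  duo <- phylo_network(rbind(c("r", "x")))
  sd <- tree_splits(displayed_tree(duo, parent_maps(duo)[[1]]))
  expect_length(sd, 1)
  expect_equal(names(sd), "r|x")
})

test_that("distinct parent maps of normal networks give distinct trees", {
  for (seed in 1:5) {
    sim <- random_network(5, 1 + seed %% 3, seed = seed,
                          alpha_mode = "equiprobable")
    pm <- parent_maps(sim$network)
    keys <- vapply(pm, function(p) paste(
      sort(names(tree_splits(displayed_tree(sim$network, p)))),
      collapse = ";"), "")
    expect_equal(length(unique(keys)), length(keys))
  }
})

test_that("split compatibility matches the intersection criterion", {
  s1 <- make_split(c("1", "2"), c("3", "4"))
  s2 <- make_split("1", c("2", "3", "4"))
  s3 <- make_split(c("1", "3"), c("2", "4"))
  expect_true(splits_compatible(s1, s2))
  expect_false(splits_compatible(s1, s3))
  expect_true(splits_compatible(s1, s1))
  expect_error(splits_compatible(s1, make_split("a", "b")),
               "different base sets")
  # any two splits of one tree are compatible
  sim <- random_network(7, 1, seed = 9, alpha_mode = "equiprobable")
  sp <- tree_splits(displayed_tree(sim$network,
                                   parent_maps(sim$network)[[1]]))
  for (i in seq_along(sp))
    for (j in seq_along(sp))
      expect_true(splits_compatible(sp[[i]], sp[[j]]))
})

test_that("validation agrees with a brute-force normality checker", {
  nets <- list(basic_net(), example_network("redundant")$network,
               example_network("grandparent")$network,
               example_network("large")$network)
  for (seed in 1:4)
    nets[[length(nets) + 1]] <-
      random_network(5, seed %% 3, seed = seed,
                     alpha_mode = "equiprobable")$network
  for (net in nets) {
    expect_equal(validate_network(net)$is_normal,
                 oracle_is_normal(net$arcs))
  }
})
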
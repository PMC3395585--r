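# Frozen expected values below were computed with the brute-force
# forward oracle on the named fixtures.

grandparent_dm <- function() {
  fx <- example_network("grandparent")
  distance_matrix(fx$network, fx$model)
}

interior_dm <- function() {
  fx <- example_network("hybrid_interior")
  distance_matrix(fx$network, fx$model)
}

test_that("junction distance recovers interior segments", {
  dm <- grandparent_dm()
  expect_rat_equal(junction_distance(dm, list(r = "r", x = "x1",
                                              y = "x3", z = "x2")), 1)
  # toy 4-leaf tree r->a(1), a->x(1), a->b(1), b->y(1), b->z(1)
  net <- phylo_network(rbind(c("r", "a"), c("a", "x"), c("a", "b"),
                             c("b", "y"), c("b", "z")))
  wn <- weighted_network(net, c("r->a" = 1, "a->x" = 1, "a->b" = 1,
                                "b->y" = 1, "b->z" = 1))
  dmt <- distance_matrix(wn)
  expect_rat_equal(junction_distance(dmt, list(r = "r", x = "x",
                                               y = "y", z = "z")), 1)
  # all-zero matrix
  z <- tad_dist(matrix(0, 4, 4, dimnames = list(letters[1:4],
                                                letters[1:4])),
                den = matrix(1, 4, 4))
  expect_rat_equal(junction_distance(z, list(r = "a", x = "b", y = "c",
                                             z = "d")), 0)
})

test_that("four-point weight variants match declared fixture weights", {
  dm13 <- basic_dm("1/3")
  # arc (1,5) via the tail taxon 1
  expect_rat_equal(fourpoint_weight(dm13, 3, list(r = "1", x = "1",
                                                  y = "2", z = "4")), 1)
  # arc (q3,x3) of the grandparent fixture via variant 2
  dm <- grandparent_dm()
  expect_rat_equal(fourpoint_weight(dm, 2, list(r = "r", b = "x3",
                                                x = "x2")), 2)
  # toy tree r->a(2), a->x(1), a->b(3), b->y(1), b->z(2): variant 3 and 1
  net <- phylo_network(rbind(c("r", "a"), c("a", "x"), c("a", "b"),
                             c("b", "y"), c("b", "z")))
  wn <- weighted_network(net, c("r->a" = 2, "a->x" = 1, "a->b" = 3,
                                "b->y" = 1, "b->z" = 2))
  dmt <- distance_matrix(wn)
  expect_rat_equal(fourpoint_weight(dmt, 3, list(r = "r", x = "x",
                                                 y = "y", z = "z")), 3)
  expect_rat_equal(fourpoint_weight(dmt, 1, list(a = "x", y = "y",
                                                 z = "z")), 4)  # x->a->b
})

test_that("hybrid-to-taxon distances hold for any inheritance", {
  dm13 <- basic_dm("1/3")
  expect_rat_equal(hybrid_taxon_distance(dm13, list(y = "3", x1 = "2",
                                                    x2 = "4")), 1)
  dm <- grandparent_dm()
  expect_rat_equal(hybrid_taxon_distance(dm, list(y = "y", x1 = "x1",
                                                  x2 = "x2")), 1)
  # alpha-invariance: same value at a different alpha
  dm27 <- basic_dm("2/7")
  expect_rat_equal(hybrid_taxon_distance(dm27, list(y = "3", x1 = "2",
                                                    x2 = "4")), 1)
})

test_that("the hybrid-child arc weight formula is role-symmetric", {
  dm <- interior_dm()
  expect_rat_equal(hybrid_child_weight(dm, list(x1 = "x1", x2 = "x2",
                                                w = "w", z = "z")), 2)
  expect_rat_equal(hybrid_child_weight(dm, list(x1 = "x2", x2 = "x1",
                                                w = "z", z = "w")), 2)
})

test_that("equiprobable identities reproduce the declared weights", {
  dmh <- basic_dm("1/2")
  expect_rat_equal(equiprobable_parent_distance(
    dmh, list(r = "1", x1 = "2", x2 = "4", y = "3")), 4)   # w(6->2)
  expect_rat_equal(equiprobable_parent_distance(
    dmh, list(r = "1", x1 = "4", x2 = "2", y = "3")), 2)   # w(8->4)
  expect_rat_equal(equiprobable_parent_weight(
    dmh, list(r = "1", b = "2", y = "3", x2 = "4"), leaf = TRUE), 4)
  dmi <- interior_dm()
  expect_rat_equal(equiprobable_parent_weight(
    dmi, list(r = "r", b = "x1", y = "w", x2 = "x2"), leaf = TRUE), 1)
})

test_that("the grandparent solve recovers alpha and all segments", {
  dm <- grandparent_dm()
  sol <- solve_inheritance(dm, list(r = "r", x1 = "x1", x2 = "x2",
                                    x3 = "x3", y = "y"))
  expect_rat_equal(sol$alpha, "3/10")
  expect_rat_equal(sol$w_rv, 1)
  expect_rat_equal(sol$w_vq3, 1)
  expect_rat_equal(sol$w_q3x3, 2)
  expect_rat_equal(sol$w_hy, 1)
  expect_rat_equal(sol$E2, "19/5")    # 3.8
  expect_rat_equal(sol$E4, "6/5")     # 1.2
  expect_rat_equal(sol$C, "6/5")      # 1.2
  expect_rat_equal(sol$D, 4)
  expect_rat_equal(sol$w_vq1, 2)
  expect_rat_equal(sol$w_q3q2, 1)
  expect_rat_equal(sol$w_q1x1, 3)
  expect_rat_equal(sol$w_q2x2, 2)
})

test_that("the solve tracks the generating alpha", {
  fx <- example_network("grandparent",
                        alpha = data.frame(hybrid = "h0", parent = "q1",
                                           alpha = "1/2"))
  dm <- distance_matrix(fx$network, fx$model)
  sol <- solve_inheritance(dm, list(r = "r", x1 = "x1", x2 = "x2",
                                    x3 = "x3", y = "y"))
  expect_rat_equal(sol$alpha, "1/2")
})

test_that("both root-junction expressions agree on model input", {
  for (seed in 1:5) {
    sim <- random_network(6, 1, seed = 40 + seed)
    net <- sim$network
    hyp <- check_identifiability(net)
    dm <- distance_matrix(net, sim$model)
    cfg <- hyp$configs[[1]]
    sol <- solve_inheritance(dm, list(r = net$root, x1 = cfg$x1,
                                      x2 = cfg$x2, x3 = cfg$x3,
                                      y = cfg$y))
    expect_true(sol$w_rv == sol$w_rv_alt)
  }
})

test_that("parent-arc weights above a free hybrid come from two solves", {
  dm <- grandparent_dm()
  roles <- list(r = "r", x1 = "x1", x2 = "x2", x3 = "x3", y = "y")
  expect_rat_equal(hybrid_parent_weight(dm, "a", roles), 3)  # w(q1->x1)
  expect_rat_equal(hybrid_parent_weight(dm, "b", roles), 2)  # w(q2->x2)
})

test_that("degenerate and inconsistent inputs are rejected", {
  dm <- grandparent_dm()
  expect_error(solve_inheritance(dm, list(r = "r", x1 = "x1", x2 = "x1",
                                          x3 = "x3", y = "y")),
               "distinct")
  # collapse the junction-to-grandparent segment: v -> q3 weight 0
  fx0 <- example_network("grandparent")
  w <- stats::setNames(as.character(as_rational(fx0$network$weights)),
                       fx0$network$weight_keys)
  w[["v->q3"]] <- "0"
  wn0 <- weighted_network(fx0$network, w)
  dm0 <- distance_matrix(wn0, fx0$model)
  expect_error(solve_inheritance(dm0, list(r = "r", x1 = "x1", x2 = "x2",
                                           x3 = "x3", y = "y")),
               "degenerate")
  # distances not generated by the model push alpha outside (0,1)
  m <- as.matrix(grandparent_dm())
  m["x3", "y"] <- m["x3", "y"] + 4
  m["y", "x3"] <- m["x3", "y"]
  expect_error(solve_inheritance(tad_dist(m), list(r = "r", x1 = "x1",
                                                   x2 = "x2", x3 = "x3",
                                                   y = "y")),
               "outside \\(0, 1\\)")
})

test_that("lemma formulas agree with directly computed internal values", {
  # on random identifiable fixtures, the solve's internal distances
  # equal forward-model distances between the corresponding vertices
  for (seed in 1:5) {
    sim <- random_network(6, 1, seed = 60 + seed)
    net <- sim$network
    cfg <- check_identifiability(net)$configs[[1]]
    dm <- distance_matrix(net, sim$model)
    sol <- solve_inheritance(dm, list(r = net$root, x1 = cfg$x1,
                                      x2 = cfg$x2, x3 = cfg$x3,
                                      y = cfg$y))
    expect_true(sol$alpha ==
                tadnet:::.alpha_lookup(sim$model, cfg$q1, cfg$hybrid))
    expect_true(sol$w_q1x1 ==
                tree_average_distance(net, sim$model, cfg$q1, cfg$x1))
    expect_true(sol$w_q2x2 ==
                tree_average_distance(net, sim$model, cfg$q2, cfg$x2))
    expect_true(sol$w_hy ==
                tree_average_distance(net, sim$model, cfg$hybrid, cfg$y))
    expect_true(sol$w_q3x3 ==
                tree_average_distance(net, sim$model, cfg$q3, cfg$x3))
  }
})
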
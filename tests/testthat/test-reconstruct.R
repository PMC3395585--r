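test_that("identifiability hypotheses are checked per hybrid", {
  gp <- example_network("grandparent")$network
  rep_ <- check_identifiability(gp)
  expect_true(rep_$satisfied)
  cfg <- rep_$configs[["h0"]]
  expect_equal(cfg$q2, "q2")
  expect_equal(cfg$q3, "q3")
  expect_equal(cfg$q1, "q1")
  expect_equal(cfg$x3, "x3")

  basic <- example_network("basic")$network
  rep2 <- check_identifiability(basic)
  expect_false(rep2$satisfied)
  expect_equal(rep2$failures, "7")
  # declared equiprobable, the hypothesis is waived
  expect_true(check_identifiability(basic, equiprobable = "7")$satisfied)
  expect_true(check_identifiability(basic, equiprobable = TRUE)$satisfied)

  tree <- random_network(5, 0, seed = 3)$network
  expect_true(check_identifiability(tree)$satisfied)
})

test_that("arcs are classified by tail and head configuration", {
  net <- example_network("basic")$network
  c1 <- classify_arc(net, c("1", "5"))
  expect_equal(c1$tail_case, "taxon_path")
  expect_equal(c1$head_case, "two_tree_children")
  expect_equal(c1$witnesses$w, "1")
  expect_true(all(c(c1$witnesses$c1, c1$witnesses$c2) %in% c("6", "8")))

  c2 <- classify_arc(net, c("7", "3"))
  expect_equal(c2$tail_case, "hybrid_tail")
  expect_equal(c2$head_case, "taxon")
  expect_setequal(c(c2$witnesses$q1, c2$witnesses$q2), c("6", "8"))

  c3 <- classify_arc(net, c("6", "2"))
  expect_equal(c3$tail_case, "hybrid_coparent")
  expect_equal(c3$head_case, "taxon")
  expect_equal(c3$witnesses$h_tail, "7")
  expect_equal(c3$witnesses$q_tail, "8")

  expect_error(classify_arc(net, c("6", "7")), "hybrid")
  expect_error(classify_arc(net, c("1", "4")), "not in the network")
})

test_that("reconstruction reproduces the declared example weights", {
  fx <- example_network("basic",
                        alpha = data.frame(hybrid = "7", parent = "6",
                                           alpha = "1/2"))
  dm <- distance_matrix(fx$network, fx$model)
  fit <- fit_tree_average(fx$network, dm, equiprobable = TRUE)
  got <- coef(fit, exact = TRUE)
  expect_equal(unname(got[c("w(1->5)", "w(5->6)", "w(5->8)", "w(6->2)",
                            "w(8->4)", "w(7->3)", "w(6->7)", "w(8->7)")]),
               c("1", "1", "2", "4", "2", "1", "0", "0"))
  expect_identical(fit$residual, 0)
})

test_that("weights and a free alpha are recovered exactly", {
  fx <- example_network("grandparent")
  dm <- distance_matrix(fx$network, fx$model)
  fit <- fit_tree_average(fx$network, dm)
  expect_identical(fit$residual, 0)
  expect_true(all(as.numeric(fit$weights) ==
                  as.numeric(fx$network$weights)))
  a <- tadnet:::.alpha_lookup(fit$alpha, "q1", "h0")
  expect_rat_equal(a, "3/10")
})

test_that("a weighted tree is recovered through the taxon-path cases", {
  sim <- random_network(6, 0, seed = 21)
  dm <- distance_matrix(sim$network, sim$model)
  fit <- fit_tree_average(sim$network, dm)
  expect_identical(fit$residual, 0)
  expect_true(all(as.numeric(fit$weights) ==
                  as.numeric(sim$network$weights)))
  expect_true(all(fit$case_log$tail_case == "taxon_path"))
})

test_that("reconstruction errors are actionable", {
  basic <- example_network("basic")$network
  dm <- basic_dm("1/2")
  expect_error(fit_tree_average(basic, dm), "'7'")
  # inconsistent distances surface as negative weights or bad alpha
  m <- as.matrix(dm)
  m["1", "2"] <- m["2", "1"] <- 0.5
  expect_error(fit_tree_average(basic, tad_dist(m), equiprobable = TRUE),
               "negative weight|inconsistent")
  # taxa mismatch
  expect_error(fit_tree_average(basic, tad_dist(m[1:3, 1:3])),
               "base set")
})

test_that("double-precision input recovers parameters within 1e-8", {
  fx <- example_network("grandparent")
  dm <- distance_matrix(fx$network, fx$model)
  dm_f <- tad_dist(as.matrix(dm))           # demote to doubles
  fit <- fit_tree_average(fx$network, dm_f)
  expect_lt(fit$residual, 1e-8)
  expect_equal(as.numeric(fit$weights), as.numeric(fx$network$weights),
               tolerance = 1e-8)
  expect_equal(as.numeric(tadnet:::.alpha_lookup(fit$alpha, "q1", "h0")),
               0.3, tolerance = 1e-8)
})

test_that("equiprobable and grandparent routes agree when both apply", {
  fx <- example_network("grandparent",
                        alpha = data.frame(hybrid = "h0", parent = "q1",
                                           alpha = "1/2"))
  dm <- distance_matrix(fx$network, fx$model)
  fit_free <- fit_tree_average(fx$network, dm)
  fit_equi <- fit_tree_average(fx$network, dm, equiprobable = TRUE)
  expect_true(all(as.numeric(fit_free$weights) ==
                  as.numeric(fit_equi$weights)))
  expect_rat_equal(tadnet:::.alpha_lookup(fit_free$alpha, "q1", "h0"),
                   "1/2")
})

test_that("witness choices do not change recovered weights", {
  # the declared weights of the large fixture are recovered although its
  # dispatch uses witnesses different from any particular hand choice
  fx <- example_network("large",
                        alpha = data.frame(hybrid = c("16", "20"),
                                           parent = c("17", "21"),
                                           alpha = c("2/5", "7/10")))
  dm <- distance_matrix(fx$network, fx$model)
  fit <- fit_tree_average(fx$network, dm)
  expect_identical(fit$residual, 0)
  expect_true(all(as.numeric(fit$weights) ==
                  as.numeric(fx$network$weights)))
  expect_rat_equal(tadnet:::.alpha_lookup(fit$alpha, "17", "16"), "2/5")
  expect_rat_equal(tadnet:::.alpha_lookup(fit$alpha, "21", "20"), "7/10")
})

test_that("fit methods expose coefficients, fitted values and residuals", {
  fx <- example_network("grandparent")
  dm <- distance_matrix(fx$network, fx$model)
  fit <- fit_tree_average(fx$network, dm)
  co <- coef(fit)
  expect_true(is.numeric(co))
  expect_equal(unname(co[["w(q1->x1)"]]), 3)
  expect_true(all(residuals(fit) == 0))
  expect_equal(fitted(fit), as.matrix(dm))
  expect_equal(predict(fit, rbind(c("r", "x1"))), 6)
  expect_output(print(fit), "residual 0")
  expect_output(summary(fit), "alpha")
})

test_that("the arc-count bound holds and is tight on the small fixture", {
  b <- arc_count_bound(example_network("basic")$network)
  expect_equal(b$count, 6)
  expect_equal(b$bound, 6)
  expect_true(b$ok)
  g <- arc_count_bound(example_network("grandparent")$network)
  expect_equal(g$count, 8)
  expect_equal(g$bound, 10)
  expect_true(g$ok)
  duo <- phylo_network(rbind(c("r", "x")))
  d <- arc_count_bound(duo)
  expect_equal(d$count, 1)
  expect_equal(d$bound, 1)
  expect_true(d$ok)
})
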
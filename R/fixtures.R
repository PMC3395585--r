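# Named example networks and a random generator of normal semibinary
# weighted networks.

#' Named example networks
#'
#' Small weighted networks with inheritance models, used throughout the
#' documentation and tests:
#'
#' * `"basic"` — the smallest interesting normal semibinary network:
#'   root 1, taxa \{1, 2, 3, 4\}, one hybrid (vertex 7) with parents 6
#'   and 8, eight arcs.  Weights 1, 1, 2, 4, 2, 1 on the six
#'   normal-headed arcs and `alpha(6, 7) = 1/3`.  Its six taxon-pair
#'   distances cannot identify a free inheritance probability, so it is
#'   reconstructible only under declared equiprobability.
#' * `"grandparent"` — the minimal configuration in which the
#'   inheritance probability is identifiable: a hybrid `h0` whose parent
#'   `q2` has a grandparent `q3` carrying its own path to a taxon.
#'   Ten arcs, taxa \{r, x1, x2, x3, y\}, `alpha(q1, h0) = 3/10`.
#' * `"hybrid_interior"` — a hybrid whose child is internal with two
#'   leaf subtrees; exercises the formulas for the arc out of a hybrid
#'   and for a parent arc above an equiprobable hybrid.
#' * `"large"` — a 24-arc network with two hybrids (16 and 20) and
#'   eleven taxa, one of which (vertex 10) is an internal degree-(1,1)
#'   vertex of the base set.  Weights default to 1 on every
#'   normal-headed arc and can be overridden.
#' * `"redundant"` — a non-normal variant of `"basic"` with an extra
#'   vertex `m` and arcs making `(5, m)` redundant; used to demonstrate
#'   validation failures.
#'
#' @param name one of `"basic"`, `"grandparent"`, `"hybrid_interior"`,
#'   `"large"`, `"redundant"`.
#' @param weights optional replacement weights (named `"tail->head"`),
#'   currently honoured by `"large"`.
#' @param alpha optional replacement inheritance table.
#' @return a list with components `network` (a [weighted_network()]) and
#'   `model` (an [inheritance_model()]).
#' @examples
#' fx <- example_network("basic")
#' distance_matrix(fx$network, fx$model)
#' @export
example_network <- function(name = c("basic", "grandparent",
                                     "hybrid_interior", "large",
                                     "redundant"),
                            weights = NULL, alpha = NULL) {
  name <- match.arg(name)
  fx <- switch(name,
    basic = {
      arcs <- rbind(c("1", "5"), c("5", "6"), c("5", "8"), c("6", "2"),
                    c("6", "7"), c("8", "7"), c("7", "3"), c("8", "4"))
      net <- phylo_network(arcs)
      w <- c("1->5" = "1", "5->6" = "1", "5->8" = "2", "6->2" = "4",
             "8->4" = "2", "7->3" = "1")
      a <- data.frame(hybrid = "7", parent = "6", alpha = "1/3")
      list(network = weighted_network(net, w),
           model_table = a)
    },
    grandparent = {
      arcs <- rbind(c("r", "v"), c("v", "q1"), c("v", "q3"),
                    c("q3", "x3"), c("q3", "q2"), c("q1", "x1"),
                    c("q2", "x2"), c("q1", "h0"), c("q2", "h0"),
                    c("h0", "y"))
      net <- phylo_network(arcs)
      w <- c("r->v" = "1", "v->q1" = "2", "v->q3" = "1", "q1->x1" = "3",
             "q3->x3" = "2", "q3->q2" = "1", "q2->x2" = "2", "h0->y" = "1")
      a <- data.frame(hybrid = "h0", parent = "q1", alpha = "3/10")
      list(network = weighted_network(net, w), model_table = a)
    },
    hybrid_interior = {
      arcs <- rbind(c("r", "u"), c("u", "q1"), c("u", "q2"),
                    c("q1", "x1"), c("q2", "x2"), c("q1", "h"),
                    c("q2", "h"), c("h", "b"), c("b", "w"), c("b", "z"))
      net <- phylo_network(arcs)
      w <- c("r->u" = "1", "u->q1" = "1", "u->q2" = "2", "q1->x1" = "1",
             "q2->x2" = "1", "h->b" = "2", "b->w" = "1", "b->z" = "3")
      a <- data.frame(hybrid = "h", parent = "q1", alpha = "1/2")
      list(network = weighted_network(net, w), model_table = a)
    },
    large = {
      arcs <- rbind(
        c("1", "22"), c("22", "10"), c("22", "12"), c("12", "13"),
        c("12", "23"), c("13", "2"), c("13", "14"), c("14", "3"),
        c("14", "15"), c("15", "4"), c("15", "16"), c("16", "5"),
        c("17", "16"), c("17", "6"), c("18", "17"), c("18", "19"),
        c("19", "7"), c("19", "8"), c("20", "18"), c("21", "20"),
        c("21", "9"), c("23", "20"), c("23", "11"), c("10", "21"))
      net <- phylo_network(arcs)
      hyb_head <- net$indegree[net$arcs[, 2]] >= 2
      keys <- paste0(net$arcs[, 1], "->", net$arcs[, 2])
      w <- stats::setNames(rep("1", sum(!hyb_head)), keys[!hyb_head])
      if (!is.null(weights)) w[names(weights)] <- as.character(weights)
      a <- data.frame(hybrid = c("16", "20"), parent = c("17", "21"),
                      alpha = c("1/2", "1/2"))
      list(network = weighted_network(net, w), model_table = a)
    },
    redundant = {
      # as in "basic" but arc (6,2) replaced by 6 -> m -> 2 with the
      # extra arc (5,m): (5,m) is redundant via 5 -> 6 -> m
      arcs <- rbind(c("1", "5"), c("5", "6"), c("5", "8"), c("6", "m"),
                    c("5", "m"), c("m", "2"), c("6", "7"), c("8", "7"),
                    c("7", "3"), c("8", "4"))
      net <- phylo_network(arcs)
      keys <- paste0(net$arcs[, 1], "->", net$arcs[, 2])
      hyb_head <- net$indegree[net$arcs[, 2]] >= 2
      w <- stats::setNames(rep("1", sum(!hyb_head)), keys[!hyb_head])
      a <- NULL
      list(network = weighted_network(net, w), model_table = a)
    })
  tab <- if (!is.null(alpha)) alpha else fx$model_table
  model <- if (is.null(tab)) inheritance_model(fx$network) else
    inheritance_model(fx$network, tab)
  list(network = fx$network, model = model)
}

#' Generate a random normal semibinary weighted network
#'
#' Grows a random rooted binary tree on `n_leaves` leaves, then adds
#' hybrids one at a time: two tree arcs with incomparable heads are
#' subdivided and joined to a fresh hybrid vertex carrying a new leaf.
#' After each addition the network is re-validated (normality,
#' semibinary condition, and — unless inheritance is equiprobable — the
#' grandparent configuration required for identifiability); failures are
#' rolled back and retried.  Weights on normal-headed arcs are drawn
#' uniformly from quarter-integers in `weight_range`; hybrid-headed arcs
#' weigh zero.
#'
#' @param n_leaves number of leaves of the initial tree (at least 2).
#' @param n_hybrids number of hybrid vertices to add.
#' @param seed integer seed; identical seeds give identical networks.
#' @param weight_range positive range `(low, high)` for arc weights.
#' @param alpha_mode `"equiprobable"`, `"uniform"` (inheritance
#'   probabilities drawn from \{3/40, ..., 37/40\}) or a fixed rational
#'   such as `"3/10"`.
#' @param max_tries attempts per hybrid before giving up.
#' @return a list with `network` (a [weighted_network()]) and `model`
#'   (an [inheritance_model()]).
#' @export
random_network <- function(n_leaves, n_hybrids = 0, seed = 1,
                           weight_range = c(1, 10),
                           alpha_mode = "uniform", max_tries = 200) {
  stopifnot(n_leaves >= 2, n_hybrids >= 0, weight_range[1] > 0,
            weight_range[2] >= weight_range[1])
  set.seed(as.integer(seed))

  # random rooted binary tree: leaves t1..tn, internal i1.., root root
  leaves <- sprintf("t%02d", seq_len(n_leaves))
  arcs <- matrix(character(0), ncol = 2)
  avail <- leaves
  k <- 0
  while (length(avail) > 1) {
    pick <- sample(length(avail), 2)
    k <- k + 1
    parent <- if (length(avail) == 2) "root" else sprintf("i%02d", k)
    arcs <- rbind(arcs, c(parent, avail[pick[1]]),
                  c(parent, avail[pick[2]]))
    avail <- c(avail[-pick], parent)
  }
  if (n_leaves == 2 && nrow(arcs) == 0) {
    arcs <- rbind(c("root", leaves[1]), c("root", leaves[2]))
  }

  equi <- identical(alpha_mode, "equiprobable")
  hybrids_added <- 0
  sub_id <- 0
  hyb_id <- 0
  while (hybrids_added < n_hybrids) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      net <- phylo_network(arcs)
      arcs <- net$arcs  # canonical row order
      # candidate arcs: normal-headed only
      cand <- which(net$indegree[net$arcs[, 2]] == 1)
      if (length(cand) < 2) break
      pick <- sample(cand, 2)
      a1 <- net$arcs[pick[1], ]; a2 <- net$arcs[pick[2], ]
      # heads must be incomparable
      if (a2[2] %in% .reachable(net, a1[2]) ||
          a1[2] %in% .reachable(net, a2[2])) next
      u1 <- sprintf("s%02d", sub_id + 1)
      u2 <- sprintf("s%02d", sub_id + 2)
      h <- sprintf("h%02d", hyb_id + 1)
      hl <- sprintf("y%02d", hyb_id + 1)
      new_arcs <- arcs[-pick, , drop = FALSE]
      new_arcs <- rbind(new_arcs,
                        c(a1[1], u1), c(u1, a1[2]),
                        c(a2[1], u2), c(u2, a2[2]),
                        c(u1, h), c(u2, h), c(h, hl))
      cand_net <- phylo_network(new_arcs)
      rep_ <- validate_network(cand_net)
      if (!rep_$is_normal || !rep_$is_semibinary || !rep_$is_rooted ||
          !rep_$is_acyclic || !rep_$base_set_ok) next
      if (!equi) {
        hyp <- check_identifiability(cand_net)
        if (!hyp$satisfied) next
      }
      arcs <- new_arcs
      sub_id <- sub_id + 2
      hyb_id <- hyb_id + 1
      hybrids_added <- hybrids_added + 1
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place hybrid ", hybrids_added + 1, " after ",
           max_tries, " tries; try more leaves", call. = FALSE)
  }

  net <- phylo_network(arcs)
  keys <- paste0(net$arcs[, 1], "->", net$arcs[, 2])
  hyb_head <- net$indegree[net$arcs[, 2]] >= 2
  lo <- ceiling(weight_range[1] * 4)
  hi <- floor(weight_range[2] * 4)
  pool <- seq(lo, hi)
  wq <- pool[sample.int(length(pool), sum(!hyb_head), replace = TRUE)]
  w <- stats::setNames(as.character(rational(wq, 4)), keys[!hyb_head])
  wn <- weighted_network(net, w)

  hyb <- hybrid_vertices(net)
  if (length(hyb) == 0) {
    model <- inheritance_model(wn)
  } else if (equi) {
    model <- inheritance_model(wn)
  } else {
    avals <- if (identical(alpha_mode, "uniform"))
      as.character(rational(sample(3:37, length(hyb), replace = TRUE), 40))
    else rep(as.character(as_rational(alpha_mode)), length(hyb))
    first_parent <- vapply(hyb, function(h) net$parents[[h]][1], "")
    model <- inheritance_model(wn, data.frame(
      hybrid = hyb, parent = first_parent, alpha = avals))
  }
  list(network = wn, model = model)
}
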
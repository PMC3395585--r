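# Independent brute-force oracles, deliberately implemented from scratch
# (adjacency matrices, breadth-first search, recursive enumeration) so
# that they share no code path with the package internals they check.

# Tree-average distance by direct enumeration: for every combination of
# hybrid parent choices, build the undirected tree, find the x-y path by
# BFS, and sum the arc weights; average with the combination's
# probability.  `weights` is a numeric vector named "tail->head" (hybrid
# arcs may be omitted); `alpha` a data frame (hybrid, parent, alpha).
oracle_tad <- function(arcs, root, weights, alpha, x, y) {
  arcs <- as.matrix(arcs)
  verts <- sort(unique(c(arcs)))
  indeg <- table(factor(arcs[, 2], levels = verts))
  hybrids <- names(indeg)[indeg >= 2]
  par_of <- function(v) arcs[arcs[, 2] == v, 1]
  wt <- function(u, v) {
    k <- paste0(u, "->", v)
    if (!is.null(weights) && k %in% names(weights)) weights[[k]] else 0
  }
  al <- function(u, h) {
    i <- which(alpha$hybrid == h & alpha$parent == u)
    if (length(i) == 1) as.numeric(alpha$alpha[i]) else
      stop("oracle: missing alpha for ", u, "->", h)
  }
  combos <- list(list(choice = character(0), prob = 1))
  for (h in hybrids) {
    nxt <- list()
    for (cm in combos) {
      for (p in par_of(h)) {
        ch <- cm$choice
        ch[h] <- p
        nxt[[length(nxt) + 1]] <- list(choice = ch,
                                       prob = cm$prob * al(p, h))
      }
    }
    combos <- nxt
  }
  total <- 0
  for (cm in combos) {
    kept <- arcs[!(arcs[, 2] %in% hybrids), , drop = FALSE]
    for (h in hybrids)
      kept <- rbind(kept, c(cm$choice[[h]], h))
    # BFS on the undirected tree from x, recording predecessors
    adj <- lapply(setNames(verts, verts), function(v) {
      c(kept[kept[, 1] == v, 2], kept[kept[, 2] == v, 1])
    })
    pred <- setNames(rep(NA_character_, length(verts)), verts)
    seen <- x
    queue <- x
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (u %in% seen) next
        pred[u] <- v
        seen <- c(seen, u)
        queue <- c(queue, u)
      }
    }
    d <- 0
    v <- y
    while (v != x) {
      u <- pred[[v]]
      d <- d + max(wt(u, v), wt(v, u))
      v <- u
    }
    total <- total + cm$prob * d
  }
  total
}

# Normality by the direct definition: reachability via boolean matrix
# powers; an arc (u,v) is redundant iff some w distinct from both has
# u <= w <= v; tree-child outside the base set.
oracle_is_normal <- function(arcs) {
  arcs <- as.matrix(arcs)
  verts <- sort(unique(c(arcs)))
  n <- length(verts)
  A <- matrix(FALSE, n, n, dimnames = list(verts, verts))
  for (i in seq_len(nrow(arcs))) A[arcs[i, 1], arcs[i, 2]] <- TRUE
  R <- A | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | (R %*% R) > 0
  indeg <- colSums(A)
  outdeg <- rowSums(A)
  root <- verts[indeg == 0]
  X <- unique(c(verts[outdeg == 0], root,
                verts[indeg == 1 & outdeg == 1]))
  for (i in seq_len(nrow(arcs))) {
    u <- arcs[i, 1]; v <- arcs[i, 2]
    for (w in setdiff(verts, c(u, v)))
      if (R[u, w] && R[w, v]) return(FALSE)
  }
  for (v in setdiff(verts, X)) {
    kids <- verts[A[v, ]]
    if (!any(indeg[kids] == 1)) return(FALSE)
  }
  TRUE
}

# exact-rational equality helper for expectations
expect_rat_equal <- function(value, expected) {
  expect_true(is_rational(value))
  expect_true(isTRUE(value == as_rational(expected)),
              label = paste0("rational value ", as.character(value),
                             " == ", expected))
}

# forward distances of the basic worked example at a chosen alpha
basic_dm <- function(alpha = "1/3") {
  fx <- example_network("basic",
                        alpha = data.frame(hybrid = "7", parent = "6",
                                           alpha = alpha))
  distance_matrix(fx$network, fx$model)
}
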
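# The tree-average distance.
#
# For a weighted network with inheritance probabilities, each parent map p
# has probability Pr(p) (product of the chosen parents' alphas) and
# induces a displayed tree in which distances are ordinary path sums.
# The tree-average distance is the expectation of these path distances
# over the parent maps.  All arithmetic is exact rational when the
# weights and probabilities are exact.

#' Most recent common ancestor in a displayed tree
#'
#' @param tree a [displayed_tree()].
#' @param u,v vertex labels.
#' @return the label of the unique vertex below which both `u` and `v`
#'   lie, and above every other common ancestor.
#' @export
tree_mrca <- function(tree, u, v) {
  stopifnot(inherits(tree, "displayed_tree"))
  u <- .check_vertex(tree$network, u)
  v <- .check_vertex(tree$network, v)
  anc <- u
  cur <- u
  while (cur != tree$root) {
    cur <- tree$parent[[cur]]
    anc <- c(anc, cur)
  }
  cur <- v
  while (!cur %in% anc) cur <- tree$parent[[cur]]
  cur
}

# chain of vertices from `from` up to (excluding) `to` in a displayed tree
.chain_up <- function(tree, from, to) {
  out <- character(0)
  cur <- from
  while (cur != to) {
    out <- c(out, cur)
    cur <- tree$parent[[cur]]
  }
  out
}

#' Path distance between two vertices in a displayed tree
#'
#' The sum of arc weights along the unique undirected path joining `u`
#' and `v`: down from their most recent common ancestor to each.
#'
#' @param wn a [weighted_network()].
#' @param tree a displayed tree of the same network.
#' @param u,v vertex labels.
#' @return a `rational` (exact mode) or double.
#' @export
tree_distance <- function(wn, tree, u, v) {
  stopifnot(inherits(wn, "weighted_network"))
  m <- tree_mrca(tree, u, v)
  total <- if (is_rational(wn$weights)) rational(0) else 0
  for (x in c(.chain_up(tree, u, m), .chain_up(tree, v, m)))
    total <- total + .weight_of(wn, tree$parent[[x]], x)
  total
}

#' Tree-average distance between two vertices
#'
#' The expected path distance over all displayed trees, weighted by the
#' parent-map probabilities.  Defined for any pair of vertices, not only
#' base-set members, although only the restriction to the base set is
#' guaranteed to be a metric (hybrid-headed arcs weigh zero, so distinct
#' internal vertices can be at distance zero).
#'
#' @param wn a [weighted_network()].
#' @param model an [inheritance_model()] for the same network.
#' @param u,v vertex labels.
#' @return a `rational` (exact mode) or double.
#' @export
tree_average_distance <- function(wn, model, u, v) {
  maps <- parent_maps(wn)
  total <- rational(0)
  for (p in maps) {
    tr <- displayed_tree(wn, p)
    total <- total + parent_map_probability(wn, p, model) *
      tree_distance(wn, tr, u, v)
  }
  total
}

#' Tree-average distance matrix on the base set
#'
#' Computes all pairwise tree-average distances between base-set taxa in
#' one pass over the parent maps.
#'
#' @param wn a [weighted_network()].
#' @param model an [inheritance_model()]; defaults to equiprobable
#'   inheritance at every hybrid.
#' @return an object of class `"tad_dist"` (see [tad_dist()]).
#' @export
distance_matrix <- function(wn, model = inheritance_model(wn)) {
  stopifnot(inherits(wn, "weighted_network"))
  X <- wn$base_set
  n <- length(X)
  exact <- is_rational(wn$weights) &&
    (is_rational(model$alpha) || length(model$hybrid) == 0)
  acc <- vector("list", n * n)
  zero <- if (exact) rational(0) else 0
  for (i in seq_len(n * n)) acc[[i]] <- zero
  for (p in parent_maps(wn)) {
    tr <- displayed_tree(wn, p)
    pr <- parent_map_probability(wn, p, model)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- pr * tree_distance(wn, tr, X[i], X[j])
        k <- (j - 1) * n + i
        acc[[k]] <- acc[[k]] + d
      }
    }
  }
  num <- matrix(0, n, n); den <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      k <- (j - 1) * n + i
      a <- acc[[k]]
      if (exact) {
        num[i, j] <- num[j, i] <- a$num
        den[i, j] <- den[j, i] <- a$den
      } else {
        num[i, j] <- num[j, i] <- as.numeric(a)
      }
    }
  }
  tad_dist(num, taxa = X, den = if (exact) den else NULL)
}

#' Distance matrix container
#'
#' A symmetric matrix of pairwise distances indexed by base-set taxa.
#' In exact mode the entries are rationals stored as numerator and
#' denominator matrices; otherwise plain doubles.
#'
#' @param values numeric matrix of distances (numerators in exact mode).
#' @param taxa taxon labels, defaulting to the matrix dimnames.
#' @param den optional matrix of denominators (exact mode).
#' @return an object of class `"tad_dist"`.
#' @export
tad_dist <- function(values, taxa = NULL, den = NULL) {
  values <- as.matrix(values)
  if (is.null(taxa)) taxa <- rownames(values)
  if (is.null(taxa))
    stop("taxa labels are required", call. = FALSE)
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (!all(dim(values) == n))
    stop("distance matrix must be ", n, " x ", n, call. = FALSE)
  dimnames(values) <- list(taxa, taxa)
  if (!is.null(den)) {
    den <- as.matrix(den)
    dimnames(den) <- list(taxa, taxa)
  }
  structure(list(taxa = taxa, num = values, den = den),
            class = "tad_dist")
}

#' @export
as.matrix.tad_dist <- function(x, ...) {
  if (is.null(x$den)) x$num else x$num / x$den
}

#' @export
print.tad_dist <- function(x, ...) {
  cat("Tree-average distance matrix on ", length(x$taxa), " taxa",
      if (!is.null(x$den)) " (exact)", "\n", sep = "")
  print(as.matrix(x))
  invisible(x)
}

#' @export
dim.tad_dist <- function(x) dim(x$num)

# distance lookup: rational scalar in exact mode, double otherwise
.dd <- function(dm, a, b) {
  i <- match(a, dm$taxa); j <- match(b, dm$taxa)
  if (is.na(i) || is.na(j))
    stop("taxon '", if (is.na(i)) a else b,
         "' is not in the distance matrix", call. = FALSE)
  if (is.null(dm$den)) dm$num[i, j] else rational(dm$num[i, j], dm$den[i, j])
}

.is_exact_dm <- function(dm) !is.null(dm$den)

#' Check the metric axioms on a distance matrix
#'
#' Verifies identity (zero diagonal, strictly positive off-diagonal),
#' symmetry and the triangle inequality, and lists every violating pair
#' or triple.  For a network without redundant arcs and strictly
#' positive weights on normal-headed arcs the tree-average distance on
#' the base set satisfies all three axioms; zero weights on normal arcs
#' can break the identity axiom.
#'
#' @param dm a [tad_dist()] object or symmetric labelled matrix.
#' @param tol tolerance for double-mode comparisons; exact mode compares
#'   exactly.
#' @return an object of class `"metric_report"` with logical flags
#'   `identity_ok`, `symmetry_ok`, `triangle_ok` and data frames of
#'   violations.
#' @export
check_metric <- function(dm, tol = 1e-9) {
  if (!inherits(dm, "tad_dist")) dm <- tad_dist(dm)
  m <- as.matrix(dm)
  n <- length(dm$taxa)
  eq0 <- function(v) if (.is_exact_dm(dm)) v == 0 else abs(v) <= tol

  id_viol <- data.frame(x = character(0), y = character(0))
  sym_viol <- data.frame(x = character(0), y = character(0))
  tri_viol <- data.frame(x = character(0), y = character(0),
                         z = character(0))
  for (i in seq_len(n)) {
    if (!eq0(m[i, i]))
      id_viol <- rbind(id_viol,
                       data.frame(x = dm$taxa[i], y = dm$taxa[i]))
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!eq0(m[i, j] - m[j, i]))
        sym_viol <- rbind(sym_viol,
                          data.frame(x = dm$taxa[i], y = dm$taxa[j]))
      # identity requires strictly positive off-diagonal distances
      if (m[i, j] < 0 || eq0(m[i, j]))
        id_viol <- rbind(id_viol,
                         data.frame(x = dm$taxa[i], y = dm$taxa[j]))
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i == j || j == k || i == k) next
        if (m[i, k] > m[i, j] + m[j, k] + (if (.is_exact_dm(dm)) 0 else tol))
          tri_viol <- rbind(tri_viol,
                            data.frame(x = dm$taxa[i], y = dm$taxa[j],
                                       z = dm$taxa[k]))
      }
    }
  }
  structure(list(identity_ok = nrow(id_viol) == 0,
                 symmetry_ok = nrow(sym_viol) == 0,
                 triangle_ok = nrow(tri_viol) == 0,
                 identity_violations = id_viol,
                 symmetry_violations = sym_viol,
                 triangle_violations = tri_viol),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  flag <- function(b) if (b) "ok" else "VIOLATED"
  cat("Metric axioms\n")
  cat("  identity: ", flag(x$identity_ok), "\n")
  cat("  symmetry: ", flag(x$symmetry_ok), "\n")
  cat("  triangle: ", flag(x$triangle_ok), "\n")
  invisible(x)
}
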
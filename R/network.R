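# Rooted phylogenetic X-networks.
#
# A network is a rooted acyclic digraph together with a distinguished
# base set X of measurable taxa.  X must contain every leaf, the root,
# and every vertex with indegree 1 and outdegree 1; it may contain
# further internal vertices.  Vertex labels are opaque strings and all
# deterministic tie-breaks use lexicographic label order (C collation).

.sort_lex <- function(x) {
  if (length(x) == 0) return(character(0))
  x[order(x, method = "radix")]
}

.arc_key <- function(tail, head) paste(tail, head, sep = "\r")

#' Construct a rooted phylogenetic network
#'
#' @param arcs two-column matrix or data frame of arcs, first column the
#'   tail (parent), second the head (child).  Labels are treated as
#'   character strings.
#' @param root root label; inferred as the unique vertex of indegree 0
#'   when omitted.
#' @param base_set base-set labels (the taxa on which measurements are
#'   possible).  Defaults to the leaves, the root and every vertex of
#'   indegree 1 and outdegree 1.  Additional internal vertices may be
#'   named.
#' @return an object of class `"phylo_network"` with components
#'   `vertices`, `arcs`, `root`, `base_set`, and parent/child adjacency
#'   lists.
#' @examples
#' net <- phylo_network(rbind(
#'   c("1", "5"), c("5", "6"), c("5", "8"), c("6", "2"),
#'   c("6", "7"), c("8", "7"), c("7", "3"), c("8", "4")))
#' validate_network(net)
#' @export
phylo_network <- function(arcs, root = NULL, base_set = NULL) {
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2) stop("arcs must have two columns", call. = FALSE)
  storage.mode(arcs) <- "character"
  dimnames(arcs) <- list(NULL, c("tail", "head"))
  if (any(is.na(arcs)) || any(arcs == ""))
    stop("arc with empty or missing endpoint", call. = FALSE)
  if (any(arcs[, 1] == arcs[, 2]))
    stop("self-loop at vertex '", arcs[arcs[, 1] == arcs[, 2], 1][1], "'",
         call. = FALSE)
  keys <- .arc_key(arcs[, 1], arcs[, 2])
  if (anyDuplicated(keys))
    stop("duplicate arc (", arcs[duplicated(keys), 1][1], ", ",
         arcs[duplicated(keys), 2][1], ")", call. = FALSE)
  arcs <- arcs[order(arcs[, 1], arcs[, 2], method = "radix"), , drop = FALSE]

  vertices <- .sort_lex(unique(c(arcs)))
  children <- split(arcs[, 2], factor(arcs[, 1], levels = vertices))
  parents <- split(arcs[, 1], factor(arcs[, 2], levels = vertices))
  children <- lapply(children, .sort_lex)
  parents <- lapply(parents, .sort_lex)

  indeg <- lengths(parents)
  outdeg <- lengths(children)

  if (nrow(arcs) == 0) {
    if (is.null(root))
      stop("an arcless network needs an explicit root", call. = FALSE)
    root <- as.character(root)
    vertices <- root
    children <- stats::setNames(list(character(0)), root)
    parents <- stats::setNames(list(character(0)), root)
    indeg <- stats::setNames(0L, root)
    outdeg <- stats::setNames(0L, root)
  } else if (is.null(root)) {
    cand <- vertices[indeg == 0]
    if (length(cand) != 1)
      stop("cannot infer root: ", length(cand),
           " vertices of indegree zero", call. = FALSE)
    root <- cand
  } else {
    root <- as.character(root)
    if (!root %in% vertices)
      stop("root '", root, "' is not a vertex", call. = FALSE)
  }

  implied <- .sort_lex(unique(c(
    vertices[outdeg == 0], root, vertices[indeg == 1 & outdeg == 1])))
  if (is.null(base_set)) {
    base_set <- implied
  } else {
    base_set <- as.character(base_set)
    if (!all(base_set %in% vertices))
      stop("base set member '", setdiff(base_set, vertices)[1],
           "' is not a vertex", call. = FALSE)
    base_set <- .sort_lex(unique(base_set))
  }

  structure(list(vertices = vertices, arcs = arcs, root = root,
                 base_set = base_set, children = children,
                 parents = parents, indegree = indeg, outdegree = outdeg),
            class = "phylo_network")
}

#' @export
print.phylo_network <- function(x, ...) {
  cat("Phylogenetic network: ", length(x$vertices), " vertices, ",
      nrow(x$arcs), " arcs, root '", x$root, "'\n", sep = "")
  cat("Base set (", length(x$base_set), "): ",
      paste(x$base_set, collapse = ", "), "\n", sep = "")
  h <- hybrid_vertices(x)
  if (length(h))
    cat("Hybrid vertices: ", paste(h, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Vertex classification helpers
#'
#' `hybrid_vertices()` returns the vertices of indegree at least two;
#' `leaf_vertices()` those of outdegree zero; `normal_vertices()` those of
#' indegree exactly one.
#'
#' @param net a `phylo_network`.
#' @return character vector of labels, lexicographically sorted.
#' @export
hybrid_vertices <- function(net) net$vertices[net$indegree >= 2]

#' @rdname hybrid_vertices
#' @export
leaf_vertices <- function(net) net$vertices[net$outdegree == 0]

#' @rdname hybrid_vertices
#' @export
normal_vertices <- function(net) net$vertices[net$indegree == 1]

.check_vertex <- function(net, v, what = "vertex") {
  v <- as.character(v)
  if (!v %in% net$vertices)
    stop(what, " '", v, "' is not in the network", call. = FALSE)
  v
}

# All vertices reachable from v (including v), optionally skipping one arc.
.reachable <- function(net, v, drop_arc = NULL) {
  seen <- character(0)
  stack <- v
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    kids <- net$children[[cur]]
    if (!is.null(drop_arc) && cur == drop_arc[1])
      kids <- setdiff(kids, drop_arc[2])
    stack <- c(stack, setdiff(kids, seen))
  }
  seen
}

.is_acyclic <- function(net) {
  indeg <- net$indegree
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- net$vertices
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (c_ in net$children[[v]]) {
      indeg[[c_]] <- indeg[[c_]] - 1L
      if (indeg[[c_]] == 0L) queue <- c(queue, c_)
    }
  }
  seen == length(net$vertices)
}

#' Test whether an arc is redundant
#'
#' An arc is redundant when a directed path from its tail to its head
#' exists that avoids the arc itself.  Normal networks contain no
#' redundant arc.
#'
#' @param net a `phylo_network`.
#' @param arc length-2 character vector `c(tail, head)`.
#' @return logical flag.
#' @export
is_redundant_arc <- function(net, arc) {
  arc <- as.character(arc)
  if (!.arc_key(arc[1], arc[2]) %in% .arc_key(net$arcs[, 1], net$arcs[, 2]))
    stop("arc (", arc[1], ", ", arc[2], ") is not in the network",
         call. = FALSE)
  arc[2] %in% .reachable(net, arc[1], drop_arc = arc)
}

#' Validate a phylogenetic network
#'
#' Produces a non-fatal report of the structural predicates: rootedness,
#' acyclicity, base-set coverage, redundant arcs, tree-child violations
#' (every vertex outside the base set must have a child of indegree one),
#' normality (tree-child everywhere outside X and no redundant arc) and
#' the semibinary condition (every hybrid has indegree two, and outdegree
#' one unless it is a leaf).
#'
#' @param net a `phylo_network`.
#' @return an object of class `"network_validation"`: a list with flags
#'   `is_rooted`, `is_acyclic`, `base_set_ok`, `is_normal`,
#'   `is_semibinary`, a matrix `redundant_arcs`, a character vector
#'   `tree_child_violations` and diagnostic `messages`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "phylo_network"))
  msgs <- character(0)

  acyclic <- .is_acyclic(net)
  if (!acyclic) msgs <- c(msgs, "digraph contains a directed cycle")

  rooted <- net$indegree[[net$root]] == 0 &&
    (!acyclic || length(.reachable(net, net$root)) == length(net$vertices))
  if (!rooted)
    msgs <- c(msgs, paste0("root '", net$root,
                           "' does not reach every vertex with indegree 0"))

  required <- unique(c(leaf_vertices(net), net$root,
                       net$vertices[net$indegree == 1 & net$outdegree == 1]))
  missing <- setdiff(required, net$base_set)
  base_ok <- length(missing) == 0 && all(net$base_set %in% net$vertices)
  if (length(missing))
    msgs <- c(msgs, paste0("base set is missing required vertices: ",
                           paste(.sort_lex(missing), collapse = ", ")))

  redundant <- net$arcs[0, , drop = FALSE]
  if (acyclic) {
    for (i in seq_len(nrow(net$arcs))) {
      if (is_redundant_arc(net, net$arcs[i, ]))
        redundant <- rbind(redundant, net$arcs[i, , drop = FALSE])
    }
  }
  if (nrow(redundant))
    msgs <- c(msgs, paste0("redundant arc (", redundant[, 1], ", ",
                           redundant[, 2], ")"))

  tc_viol <- character(0)
  for (v in setdiff(net$vertices, net$base_set)) {
    kids <- net$children[[v]]
    if (!any(net$indegree[kids] == 1))
      tc_viol <- c(tc_viol, v)
  }
  tc_viol <- .sort_lex(tc_viol)
  if (length(tc_viol))
    msgs <- c(msgs, paste0("vertex '", tc_viol,
                           "' outside the base set has no tree-child"))

  hyb <- hybrid_vertices(net)
  semibinary <- all(net$indegree[hyb] == 2) &&
    all(net$outdegree[hyb] == 1 | net$outdegree[hyb] == 0)
  if (!semibinary)
    msgs <- c(msgs, "a hybrid vertex violates the semibinary condition")

  structure(list(
    is_rooted = rooted,
    is_acyclic = acyclic,
    base_set_ok = base_ok,
    redundant_arcs = redundant,
    tree_child_violations = tc_viol,
    is_normal = nrow(redundant) == 0 && length(tc_viol) == 0,
    is_semibinary = semibinary,
    messages = msgs
  ), class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  flag <- function(b) if (b) "yes" else "NO"
  cat("Network validation\n")
  cat("  rooted:              ", flag(x$is_rooted), "\n")
  cat("  acyclic:             ", flag(x$is_acyclic), "\n")
  cat("  base set complete:   ", flag(x$base_set_ok), "\n")
  cat("  normal:              ", flag(x$is_normal), "\n")
  cat("  semibinary:          ", flag(x$is_semibinary), "\n")
  if (length(x$messages)) {
    cat("Messages:\n")
    for (m in x$messages) cat("  - ", m, "\n", sep = "")
  }
  invisible(x)
}

# Require a validated normal, semibinary network; used by the
# reconstruction entry points.
.require_normal_semibinary <- function(net) {
  rep_ <- validate_network(net)
  if (!rep_$is_rooted || !rep_$is_acyclic || !rep_$base_set_ok ||
      !rep_$is_normal || !rep_$is_semibinary)
    stop("network is not a valid normal semibinary network:\n  ",
         paste(rep_$messages, collapse = "\n  "), call. = FALSE)
  invisible(rep_)
}

#' Enumerate parent maps
#'
#' A parent map selects one parent for every non-root vertex; each
#' choice induces a displayed tree.  The number of parent maps is the
#' product of the hybrid indegrees (2^k for a semibinary network with k
#' hybrids).  Maps are returned in a deterministic order: hybrids sorted
#' by label, their parents sorted by label, and the first hybrid varying
#' slowest.
#'
#' @param net a `phylo_network`.
#' @return a list of objects of class `"parent_map"`, each a named
#'   character vector mapping every non-root vertex to its chosen parent.
#' @export
parent_maps <- function(net) {
  stopifnot(inherits(net, "phylo_network"))
  nonroot <- setdiff(net$vertices, net$root)
  base <- vapply(nonroot, function(v) net$parents[[v]][1], "")
  hyb <- hybrid_vertices(net)
  if (length(hyb) == 0) {
    p <- structure(base, class = "parent_map")
    return(list(p))
  }
  choices <- lapply(hyb, function(h) net$parents[[h]])
  # expand.grid varies the first factor fastest; feed hybrids reversed so
  # the first (lexicographically smallest) hybrid varies slowest
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(choices)), drop = FALSE]
  names(grid) <- hyb
  lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p[hyb] <- as.character(grid[i, ])
    structure(p, class = "parent_map")
  })
}

#' Probability of a parent map
#'
#' The probability that character inheritance follows a given parent map:
#' the product over hybrid vertices of the inheritance probability of the
#' chosen parent.
#'
#' @param net a `phylo_network`.
#' @param p a parent map from [parent_maps()].
#' @param model an [inheritance_model()].
#' @return a `rational` (or double, when the model holds doubles).
#' @export
parent_map_probability <- function(net, p, model) {
  hyb <- hybrid_vertices(net)
  pr <- rational(1)
  for (h in hyb) {
    a <- .alpha_lookup(model, p[[h]], h)
    if (is.null(a))
      stop("inheritance model has no entry for parent '", p[[h]],
           "' of hybrid '", h, "'", call. = FALSE)
    pr <- pr * a
  }
  pr
}

#' Displayed tree induced by a parent map
#'
#' Keeps exactly the arcs `(p(v), v)`; the result is a rooted tree on the
#' full vertex set.
#'
#' @param net a `phylo_network`.
#' @param p a parent map.
#' @return an object of class `"displayed_tree"`: list with the source
#'   `network`, the `parent` assignment and the `kept_arcs` matrix.
#' @export
displayed_tree <- function(net, p) {
  nonroot <- setdiff(net$vertices, net$root)
  if (!all(nonroot %in% names(p)))
    stop("parent map does not cover vertex '",
         setdiff(nonroot, names(p))[1], "'", call. = FALSE)
  for (v in nonroot) {
    if (!p[[v]] %in% net$parents[[v]])
      stop("parent map assigns '", p[[v]], "' which is not a parent of '",
           v, "'", call. = FALSE)
  }
  kept <- cbind(tail = unname(vapply(nonroot, function(v) p[[v]], "")),
                head = nonroot)
  structure(list(network = net, parent = p, kept_arcs = kept,
                 root = net$root), class = "displayed_tree")
}

#' @export
print.displayed_tree <- function(x, ...) {
  cat("Displayed tree on ", length(x$network$vertices),
      " vertices (root '", x$root, "')\n", sep = "")
  invisible(x)
}

#' Find a normal path witness
#'
#' A normal path from `v` to the base set is a directed path ending at a
#' base-set member all of whose non-initial vertices have indegree one.
#' The search is deterministic: children are explored in lexicographic
#' order and the first complete path is returned.  In a normal network a
#' witness exists for every vertex.
#'
#' @param v start vertex.
#' @param avoid vertices the path must not visit (the start vertex is
#'   exempt).
#' @inheritParams is_redundant_arc
#' @return character vector of vertices from `v` to a base-set member, or
#'   `NULL` when no such path exists.
#' @export
normal_path_witness <- function(net, v, avoid = character(0)) {
  v <- .check_vertex(net, v)
  avoid <- as.character(avoid)
  search <- function(path) {
    cur <- path[[length(path)]]
    if (cur %in% net$base_set && !(cur != v && cur %in% avoid)) return(path)
    for (k in net$children[[cur]]) {
      if (net$indegree[[k]] != 1) next      # non-initial vertices normal
      if (k %in% avoid || k %in% path) next
      found <- search(c(path, k))
      if (!is.null(found)) return(found)
    }
    NULL
  }
  if (v %in% avoid && !v %in% net$base_set) return(NULL)
  if (v %in% net$base_set) return(v)
  search(v)
}

#' Splits of a displayed tree
#'
#' Each edge of the (undirected) tree partitions the base set into the
#' taxa below the edge and the rest; edges with all base-set members on
#' one side are dropped.  Splits are order-insensitive.
#'
#' @param tree a `displayed_tree`.
#' @return a list of objects of class `"tad_split"`, each with components
#'   `side_a`, `side_b` (sorted label vectors) and the shared `base_set`.
#'   The list is named by a canonical string key, so split sets can be
#'   compared with `setequal(names(a), names(b))`.
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "displayed_tree"))
  net <- tree$network
  X <- net$base_set
  # base-set members at or below each kept arc's head
  kids <- split(tree$kept_arcs[, 2],
                factor(tree$kept_arcs[, 1], levels = net$vertices))
  below <- new.env(parent = emptyenv())
  fill <- function(v) {
    if (!is.null(below[[v]])) return(below[[v]])
    res <- character(0)
    for (k in kids[[v]]) res <- c(res, fill(k))
    if (v %in% X) res <- c(res, v)
    below[[v]] <- .sort_lex(unique(res))
    below[[v]]
  }
  fill(tree$root)
  out <- list()
  for (i in seq_len(nrow(tree$kept_arcs))) {
    side_b <- below[[tree$kept_arcs[i, 2]]]
    side_a <- setdiff(X, side_b)
    if (length(side_a) == 0 || length(side_b) == 0) next
    s <- .make_split(side_a, side_b, X)
    out[[.split_key(s)]] <- s
  }
  out
}

.make_split <- function(side_a, side_b, base_set) {
  side_a <- .sort_lex(side_a)
  side_b <- .sort_lex(side_b)
  if (side_b[1] < side_a[1]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  structure(list(side_a = side_a, side_b = side_b,
                 base_set = .sort_lex(base_set)), class = "tad_split")
}

.split_key <- function(s) {
  paste(paste(s$side_a, collapse = ","), paste(s$side_b, collapse = ","),
        sep = "|")
}

#' Construct a split of the base set
#'
#' @param side_a,side_b nonempty, disjoint label vectors whose union is
#'   the base set.
#' @param base_set the base set; defaults to the union of the two sides.
#' @return a `"tad_split"` object.
#' @export
make_split <- function(side_a, side_b, base_set = NULL) {
  side_a <- as.character(side_a); side_b <- as.character(side_b)
  if (length(side_a) == 0 || length(side_b) == 0)
    stop("both sides of a split must be nonempty", call. = FALSE)
  if (length(intersect(side_a, side_b)))
    stop("split sides must be disjoint", call. = FALSE)
  if (is.null(base_set)) base_set <- c(side_a, side_b)
  if (!setequal(base_set, c(side_a, side_b)))
    stop("split sides must cover the base set", call. = FALSE)
  .make_split(side_a, side_b, base_set)
}

#' @export
print.tad_split <- function(x, ...) {
  cat(paste(x$side_a, collapse = ","), "|",
      paste(x$side_b, collapse = ","), "\n")
  invisible(x)
}

#' Compatibility of two splits
#'
#' Two splits of the same base set are compatible when at least one of
#' the four pairwise side intersections is empty.  Any two splits of one
#' tree are compatible.
#'
#' @param s1,s2 `"tad_split"` objects on the same base set.
#' @return logical flag.
#' @export
splits_compatible <- function(s1, s2) {
  stopifnot(inherits(s1, "tad_split"), inherits(s2, "tad_split"))
  if (!setequal(s1$base_set, s2$base_set))
    stop("splits are on different base sets", call. = FALSE)
  length(intersect(s1$side_a, s2$side_a)) == 0 ||
    length(intersect(s1$side_a, s2$side_b)) == 0 ||
    length(intersect(s1$side_b, s2$side_a)) == 0 ||
    length(intersect(s1$side_b, s2$side_b)) == 0
}
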
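# Recovery of arc weights and inheritance probabilities from a network
# and its exact tree-average distances on the base set.
#
# Every arc into a hybrid has known weight zero.  Each remaining arc
# (a, b) is classified by what surrounds its endpoints -- the tail is
# anchored by a taxon path, is itself a hybrid, or is the parent of a
# hybrid; the head is a taxon, has two tree children, or has one tree
# child and a hybrid child -- and dispatched to the matching closed-form
# identity.  Inheritance probabilities come from the grandparent
# configuration (solve_inheritance) unless a hybrid is declared
# equiprobable.

# ---------------------------------------------------------------------
# hypothesis checking

# Search the grandparent configuration for hybrid h: a parent (named q2)
# with an ancestor q3 such that (a) the path q3 -> q2 is normal, (b) q3
# has a disjoint normal path to a taxon x3, (c) there is no directed
# path from q3 to the other parent q1.  Parents are tried in
# lexicographic order and the nearest valid q3 wins.
.find_grandparent_config <- function(net, h) {
  pars <- net$parents[[h]]
  for (q2 in pars) {
    q1 <- setdiff(pars, q2)[1]
    if (net$indegree[[q2]] != 1) next  # cannot climb through a hybrid parent
    chain <- q2
    repeat {
      q3 <- net$parents[[chain[1]]][1]
      chain <- c(q3, chain)
      # (c): no directed path q3 -> q1
      if (!q1 %in% .reachable(net, q3)) {
        # (b): normal path q3 -> x3 disjoint from the chain below q3
        x3_path <- normal_path_witness(net, q3, avoid = chain[-1])
        if (!is.null(x3_path)) {
          x1_path <- normal_path_witness(net, q1)
          x2_path <- normal_path_witness(net, q2)
          y_path <- normal_path_witness(net, h)
          if (!is.null(x1_path) && !is.null(x2_path) && !is.null(y_path)) {
            return(list(hybrid = h, q1 = q1, q2 = q2, q3 = q3,
                        x1 = x1_path[length(x1_path)],
                        x2 = x2_path[length(x2_path)],
                        x3 = x3_path[length(x3_path)],
                        y = y_path[length(y_path)],
                        q3_chain = chain,
                        x1_path = x1_path, x2_path = x2_path,
                        x3_path = x3_path, y_path = y_path))
          }
        }
      }
      if (net$indegree[[q3]] != 1) break  # reached the root or a hybrid
    }
  }
  NULL
}

#' Check the identifiability hypotheses
#'
#' For every hybrid vertex not declared equiprobable, verifies the
#' grandparent configuration: one parent (labelled `q2`) must have an
#' ancestor `q3` with a normal path down to `q2`, a disjoint normal path
#' to a taxon `x3`, and no directed path to the other parent `q1`.
#' Hybrids declared equiprobable need no configuration.
#'
#' @param net a [phylo_network()]; must be normal and semibinary.
#' @param equiprobable character vector of hybrid labels whose
#'   inheritance is declared equiprobable, or `TRUE` for all hybrids.
#' @return an object of class `"identifiability_report"`: list with flag
#'   `satisfied`, per-hybrid `configs` (role assignments), and `failures`
#'   (labels of hybrids without a configuration).
#' @export
check_identifiability <- function(net, equiprobable = character(0)) {
  .require_normal_semibinary(net)
  hyb <- hybrid_vertices(net)
  if (isTRUE(equiprobable)) equiprobable <- hyb
  equiprobable <- as.character(equiprobable)
  bad <- setdiff(equiprobable, hyb)
  if (length(bad))
    stop("'", bad[1], "' is not a hybrid vertex", call. = FALSE)
  configs <- list()
  failures <- character(0)
  for (h in setdiff(hyb, equiprobable)) {
    cfg <- .find_grandparent_config(net, h)
    if (is.null(cfg)) failures <- c(failures, h)
    else configs[[h]] <- cfg
  }
  structure(list(satisfied = length(failures) == 0,
                 configs = configs,
                 equiprobable = intersect(hyb, equiprobable),
                 failures = failures),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("Identifiability hypotheses: ",
      if (x$satisfied) "satisfied" else "NOT satisfied", "\n", sep = "")
  for (h in names(x$configs)) {
    cfg <- x$configs[[h]]
    cat("  hybrid ", h, ": q1=", cfg$q1, " q2=", cfg$q2, " q3=", cfg$q3,
        " x3=", cfg$x3, "\n", sep = "")
  }
  if (length(x$equiprobable))
    cat("  equiprobable: ", paste(x$equiprobable, collapse = ", "), "\n",
        sep = "")
  if (length(x$failures))
    cat("  no grandparent configuration for: ",
        paste(x$failures, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------
# arc classification

# Witness endpoints (taxa) for both parents and the child path of a
# hybrid; cached per hybrid during a fit.
.hybrid_witnesses <- function(net, h) {
  pars <- net$parents[[h]]
  wit <- lapply(pars, function(q) normal_path_witness(net, q))
  names(wit) <- pars
  y <- normal_path_witness(net, h)
  if (any(vapply(wit, is.null, TRUE)) || is.null(y))
    stop("no normal path witness for hybrid '", h, "' or its parents",
         call. = FALSE)
  list(parents = pars,
       taxa = vapply(wit, function(p) p[length(p)], ""),
       y = y[length(y)])
}

#' Classify an arc for reconstruction
#'
#' Determines which closed-form identity reconstructs the weight of a
#' normal-headed arc `(a, b)`.  Tail cases (first applicable wins):
#'
#' * `taxon_path` — `a` has a normal path to a taxon avoiding `b`
#'   (including `a` itself a taxon);
#' * `hybrid_tail` — `a` is a hybrid and `b` its unique child;
#' * `hybrid_coparent` — `a` has a hybrid child besides `b`.
#'
#' Head cases: `taxon` (`b` is in the base set), `two_tree_children`
#' (`b` has two children of indegree one), `mixed_children` (`b` has one
#' tree child and a hybrid child).
#'
#' @param net a normal semibinary [phylo_network()].
#' @param arc length-2 character vector `c(tail, head)`; the head must
#'   be a normal vertex.
#' @return an object of class `"arc_case"`: list with `tail_case`,
#'   `head_case` and the witness vertices used by the dispatched
#'   formula.
#' @export
classify_arc <- function(net, arc) {
  arc <- as.character(arc)
  a <- arc[1]; b <- arc[2]
  if (!.arc_key(a, b) %in% .arc_key(net$arcs[, 1], net$arcs[, 2]))
    stop("arc (", a, ", ", b, ") is not in the network", call. = FALSE)
  if (net$indegree[[b]] >= 2)
    stop("arc (", a, ", ", b, ") enters a hybrid vertex; its weight is ",
         "zero by definition", call. = FALSE)

  wit <- list()

  # tail
  w_path <- normal_path_witness(net, a, avoid = b)
  if (!is.null(w_path)) {
    tail_case <- "taxon_path"
    wit$w <- w_path[length(w_path)]
  } else if (net$indegree[[a]] >= 2) {
    tail_case <- "hybrid_tail"
    hw <- .hybrid_witnesses(net, a)
    wit$w1 <- hw$taxa[[1]]
    wit$w2 <- hw$taxa[[2]]
    wit$q1 <- hw$parents[[1]]
    wit$q2 <- hw$parents[[2]]
  } else {
    hyb_kids <- setdiff(net$children[[a]],
                        net$vertices[net$indegree == 1])
    hyb_kids <- .sort_lex(setdiff(hyb_kids, b))
    if (length(hyb_kids) == 0)
      stop("no tail case applies to arc (", a, ", ", b, "); ",
           "the network violates the reconstruction preconditions",
           call. = FALSE)
    tail_case <- "hybrid_coparent"
    h2 <- hyb_kids[1]
    wit$h_tail <- h2
    wit$q_tail <- setdiff(net$parents[[h2]], a)[1]
  }

  # head
  if (b %in% net$base_set) {
    head_case <- "taxon"
    wit$x <- b
  } else {
    kids <- net$children[[b]]
    normal_kids <- .sort_lex(kids[net$indegree[kids] == 1])
    hybrid_kids <- .sort_lex(kids[net$indegree[kids] >= 2])
    if (length(normal_kids) >= 2) {
      head_case <- "two_tree_children"
      wit$c1 <- normal_kids[1]
      wit$c2 <- normal_kids[2]
      p1 <- normal_path_witness(net, normal_kids[1])
      p2 <- normal_path_witness(net, normal_kids[2])
      wit$x1 <- p1[length(p1)]
      wit$x2 <- p2[length(p2)]
    } else if (length(normal_kids) == 1 && length(hybrid_kids) >= 1) {
      head_case <- "mixed_children"
      wit$c <- normal_kids[1]
      px <- normal_path_witness(net, normal_kids[1])
      wit$x <- px[length(px)]
      wit$h_head <- hybrid_kids[1]
      wit$q_head <- setdiff(net$parents[[hybrid_kids[1]]], b)[1]
    } else {
      stop("no head case applies to arc (", a, ", ", b, "); ",
           "the network violates the reconstruction preconditions",
           call. = FALSE)
    }
  }

  structure(list(arc = arc, tail_case = tail_case, head_case = head_case,
                 witnesses = wit), class = "arc_case")
}

#' @export
print.arc_case <- function(x, ...) {
  cat("Arc (", x$arc[1], ", ", x$arc[2], "): tail ", x$tail_case,
      ", head ", x$head_case, "\n", sep = "")
  if (length(x$witnesses))
    cat("  witnesses: ",
        paste(names(x$witnesses), unlist(x$witnesses), sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------
# internal distance helpers used by the dispatch

# d(v, x; N) where v is a parent of hybrid h and x is reached from v by
# a normal path.  Uses the equiprobable identity or a grandparent solve
# with the target taxon substituted into v's side.
.parent_to_taxon <- function(dm, net, v, x, h, state) {
  if (h %in% state$equiprobable) {
    hw <- state$hyb_wit[[h]]
    other <- setdiff(hw$parents, v)[1]
    equiprobable_parent_distance(dm, list(
      r = net$root, x1 = x, x2 = hw$taxa[[other]], y = hw$y))
  } else {
    cfg <- state$configs[[h]]
    roles <- list(r = net$root, x1 = cfg$x1, x2 = cfg$x2,
                  x3 = cfg$x3, y = cfg$y)
    if (v == cfg$q1) {
      roles$x1 <- x
      solve_inheritance(dm, roles)$w_q1x1
    } else {
      roles$x2 <- x
      solve_inheritance(dm, roles)$w_q2x2
    }
  }
}

# d(a, x; N) for the arc tail a, where x is the head-side taxon reached
# through the arc by a normal path.
.tail_to_taxon <- function(dm, net, case, x, state) {
  a <- case$arc[1]
  wit <- case$witnesses
  switch(case$tail_case,
    taxon_path = (.dd(dm, x, net$root) + .dd(dm, x, wit$w) -
                  .dd(dm, net$root, wit$w)) / 2,
    hybrid_tail = hybrid_taxon_distance(dm, list(
      y = x, x1 = wit$w1, x2 = wit$w2)),
    hybrid_coparent = .parent_to_taxon(dm, net, a, x, wit$h_tail, state))
}

# ---------------------------------------------------------------------
# the fitting function

#' Recover arc weights and inheritance probabilities from distances
#'
#' Given a normal semibinary network and the exact tree-average
#' distances between its base-set taxa, recovers every arc weight and
#' every hybrid inheritance probability by closed-form case analysis.
#' Arcs into hybrids receive weight zero; every other arc is classified
#' by [classify_arc()] and dispatched to the matching identity.
#' Inheritance probabilities are found by [solve_inheritance()] unless a
#' hybrid is declared equiprobable.  The model is identifiable exactly
#' (no fitting tolerance): on distances generated by the forward model
#' in exact arithmetic the residual is exactly zero.
#'
#' @param net a [phylo_network()] (weights, if any, are ignored).
#' @param dm a [tad_dist()] distance matrix on the base set, or a
#'   labelled symmetric matrix.
#' @param equiprobable hybrids declared equiprobable: character vector
#'   of labels, or `TRUE` for all.
#' @return an object of class `"tad_fit"` with components `weights`
#'   (named `rational` or double vector over the arcs), `alpha` (an
#'   [inheritance_model()]), `case_log` (a data frame of dispatched
#'   cases and witnesses), `residual` (max absolute difference between
#'   the input distances and those recomputed from the fit), `network`,
#'   and the fitted distance matrix `fitted_dm`.  Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`.
#' @examples
#' fx <- example_network("grandparent")
#' dm <- distance_matrix(fx$network, fx$model)
#' fit <- fit_tree_average(fx$network, dm)
#' coef(fit)
#' @export
fit_tree_average <- function(net, dm, equiprobable = character(0)) {
  stopifnot(inherits(net, "phylo_network"))
  .require_normal_semibinary(net)
  if (!inherits(dm, "tad_dist")) dm <- tad_dist(dm)
  if (!setequal(dm$taxa, net$base_set))
    stop("distance matrix taxa do not match the network base set",
         call. = FALSE)
  if (!net$root %in% dm$taxa)
    stop("root taxon '", net$root, "' missing from the distance matrix",
         call. = FALSE)
  exact <- .is_exact_dm(dm)

  hyb <- hybrid_vertices(net)
  if (isTRUE(equiprobable)) equiprobable <- hyb
  hyp <- check_identifiability(net, equiprobable)
  if (!hyp$satisfied)
    stop("cannot reconstruct: hybrid '", hyp$failures[1], "' is neither ",
         "declared equiprobable nor in a grandparent configuration",
         call. = FALSE)

  state <- list(equiprobable = hyp$equiprobable,
                configs = hyp$configs,
                hyb_wit = stats::setNames(
                  lapply(hyb, function(h) .hybrid_witnesses(net, h)), hyb))

  # inheritance probabilities
  alpha_rows <- NULL
  for (h in hyb) {
    if (h %in% state$equiprobable) {
      a1 <- if (exact) "1/2" else 0.5
      p1 <- net$parents[[h]][1]
    } else {
      cfg <- state$configs[[h]]
      sol <- solve_inheritance(dm, list(r = net$root, x1 = cfg$x1,
                                        x2 = cfg$x2, x3 = cfg$x3,
                                        y = cfg$y))
      a1 <- if (exact) as.character(sol$alpha) else as.numeric(sol$alpha)
      p1 <- cfg$q1
    }
    alpha_rows <- rbind(alpha_rows,
                        data.frame(hybrid = h, parent = p1, alpha = a1,
                                   stringsAsFactors = FALSE))
  }
  model <- if (is.null(alpha_rows)) inheritance_model(net) else
    inheritance_model(net, alpha_rows)

  # arc weights
  keys <- paste0(net$arcs[, 1], "->", net$arcs[, 2])
  n_arcs <- nrow(net$arcs)
  weights <- vector("list", n_arcs)
  log_rows <- vector("list", n_arcs)
  r <- net$root
  for (i in seq_len(n_arcs)) {
    a <- net$arcs[i, 1]; b <- net$arcs[i, 2]
    if (net$indegree[[b]] >= 2) {
      weights[[i]] <- if (exact) rational(0) else 0
      log_rows[[i]] <- data.frame(tail = a, head = b, tail_case = "hybrid",
                                  head_case = "hybrid", witnesses = "",
                                  equiprobable_path = NA)
      next
    }
    case <- classify_arc(net, c(a, b))
    wit <- case$witnesses
    t_ <- case$tail_case; h_ <- case$head_case
    equi_path <- NA
    w <- if (h_ == "taxon") {
      if (t_ == "taxon_path") {
        fourpoint_weight(dm, 2, list(r = r, b = b, x = wit$w))
      } else if (t_ == "hybrid_tail") {
        hybrid_taxon_distance(dm, list(y = b, x1 = wit$w1, x2 = wit$w2))
      } else {
        equi_path <- wit$h_tail %in% state$equiprobable
        .parent_to_taxon(dm, net, a, b, wit$h_tail, state)
      }
    } else if (h_ == "two_tree_children") {
      if (t_ == "taxon_path") {
        fourpoint_weight(dm, 3, list(r = r, x = wit$w, y = wit$x1,
                                     z = wit$x2))
      } else if (t_ == "hybrid_tail") {
        hybrid_child_weight(dm, list(x1 = wit$w1, x2 = wit$w2,
                                     w = wit$x1, z = wit$x2))
      } else {
        h2 <- wit$h_tail
        equi_path <- h2 %in% state$equiprobable
        if (equi_path) {
          hw <- state$hyb_wit[[h2]]
          other <- setdiff(hw$parents, a)[1]
          equiprobable_parent_weight(dm, list(
            r = r, x2 = hw$taxa[[other]], y = hw$y,
            z1 = wit$x1, z2 = wit$x2))
        } else {
          cfg <- state$configs[[h2]]
          roles <- list(r = r, x1 = cfg$x1, x2 = cfg$x2, x3 = cfg$x3,
                        y = cfg$y)
          if (a == cfg$q1) {
            roles$x1 <- wit$x1; roles$z1 <- wit$x2
            hybrid_parent_weight(dm, "a", roles)
          } else {
            roles$x2 <- wit$x1; roles$z2 <- wit$x2
            hybrid_parent_weight(dm, "b", roles)
          }
        }
      }
    } else {  # mixed_children: subtraction through the head-side taxon
      equi_head <- wit$h_head %in% state$equiprobable
      d_bx <- .parent_to_taxon(dm, net, b, wit$x, wit$h_head, state)
      d_ax <- .tail_to_taxon(dm, net, case, wit$x, state)
      if (t_ == "hybrid_coparent")
        equi_path <- wit$h_tail %in% state$equiprobable
      w <- d_ax - d_bx
      w
    }
    weights[[i]] <- w
    log_rows[[i]] <- data.frame(
      tail = a, head = b, tail_case = t_, head_case = h_,
      witnesses = paste(names(wit), unlist(wit), sep = "=",
                        collapse = ","),
      equiprobable_path = equi_path)
  }

  # negativity checks / clamping
  for (i in seq_len(n_arcs)) {
    w <- weights[[i]]
    wv <- as.numeric(w)
    if (exact) {
      if (wv < 0)
        stop("inconsistent distances: negative weight ", format(wv),
             " recovered for arc ", keys[i], call. = FALSE)
    } else if (wv < 0) {
      if (wv > -1e-9) {
        warning("clamping tiny negative weight on arc ", keys[i],
                " to zero", call. = FALSE)
        weights[[i]] <- 0
      } else {
        stop("inconsistent distances: negative weight ", format(wv),
             " recovered for arc ", keys[i], call. = FALSE)
      }
    }
  }

  wvec <- if (exact) do.call(c, weights) else
    vapply(weights, as.numeric, 0)
  wnamed <- if (exact) as.character(wvec) else wvec
  names(wnamed) <- keys
  wn <- weighted_network(net, wnamed)

  fitted_dm <- distance_matrix(wn, model)
  residual <- .dm_max_abs_diff(dm, fitted_dm)

  structure(list(weights = wvec, weight_keys = keys, alpha = model,
                 case_log = do.call(rbind, log_rows),
                 residual = residual,
                 network = net, weighted_network = wn,
                 input_dm = dm, fitted_dm = fitted_dm,
                 exact = exact),
            class = "tad_fit")
}

.dm_max_abs_diff <- function(dm1, dm2) {
  i <- match(dm2$taxa, dm1$taxa)
  m1 <- as.matrix(dm1)[i, i]
  m2 <- as.matrix(dm2)
  if (.is_exact_dm(dm1) && .is_exact_dm(dm2)) {
    n1 <- dm1$num[i, i]; d1 <- dm1$den[i, i]
    if (all(n1 * dm2$den == dm2$num * d1)) return(0)
  }
  max(abs(m1 - m2))
}

#' @export
print.tad_fit <- function(x, ...) {
  cat("Tree-average distance fit (",
      if (x$exact) "exact rational" else "double precision", ")\n",
      sep = "")
  cat("  ", length(x$weight_keys), " arc weights recovered, residual ",
      format(x$residual), "\n", sep = "")
  h <- unique(x$alpha$hybrid)
  if (length(h))
    cat("  inheritance probabilities for ", length(h), " hybrid(s)\n",
        sep = "")
  invisible(x)
}

#' @export
summary.tad_fit <- function(object, ...) {
  cat("Tree-average distance reconstruction\n\n")
  w <- object$weights
  wtxt <- if (is_rational(w)) as.character(w) else format(as.numeric(w))
  tab <- data.frame(arc = object$weight_keys, weight = wtxt,
                    tail_case = object$case_log$tail_case,
                    head_case = object$case_log$head_case)
  print(tab, row.names = FALSE)
  cat("\n")
  print(object$alpha)
  cat("\nresidual:", format(object$residual), "\n")
  invisible(object)
}

#' @export
coef.tad_fit <- function(object, exact = FALSE, ...) {
  w <- object$weights
  a <- object$alpha
  anames <- paste0("alpha(", a$parent, ",", a$hybrid, ")")
  if (exact) {
    out <- c(as.character(as_rational(w)),
             as.character(as_rational(a$alpha)))
  } else {
    out <- c(as.numeric(w), as.numeric(a$alpha))
  }
  names(out) <- c(paste0("w(", object$weight_keys, ")"), anames)
  out
}

#' @export
fitted.tad_fit <- function(object, ...) as.matrix(object$fitted_dm)

#' @export
residuals.tad_fit <- function(object, ...) {
  i <- match(object$fitted_dm$taxa, object$input_dm$taxa)
  as.matrix(object$input_dm)[i, i] - as.matrix(object$fitted_dm)
}

#' Predict tree-average distances from a fit
#'
#' Returns the fitted tree-average distance for given taxon pairs (by
#' default every pair), recomputed from the recovered weights and
#' inheritance probabilities.
#'
#' @param object a `tad_fit`.
#' @param pairs optional two-column matrix or data frame of taxon labels.
#' @param ... unused.
#' @return a numeric vector (or the full fitted matrix when `pairs` is
#'   omitted).
#' @export
predict.tad_fit <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(fitted(object))
  pairs <- as.matrix(pairs)
  vapply(seq_len(nrow(pairs)), function(i) {
    as.numeric(.dd(object$fitted_dm, pairs[i, 1], pairs[i, 2]))
  }, 0)
}

# ---------------------------------------------------------------------

#' Arc-count bound for identifiable networks
#'
#' In a normal network whose hybrids have indegree two (and outdegree
#' one unless leaves), the number of arcs directed into normal vertices
#' is at most `choose(|X|, 2)` -- one unknown per taxon pair.
#'
#' @param net a [phylo_network()].
#' @return a list with `count` (normal-headed arcs), `bound`
#'   (`choose(|X|, 2)`) and the flag `ok`.
#' @export
arc_count_bound <- function(net) {
  stopifnot(inherits(net, "phylo_network"))
  count <- sum(net$indegree[net$arcs[, 2]] == 1)
  bound <- choose(length(net$base_set), 2)
  list(count = count, bound = bound, ok = count <= bound)
}
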
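# Arc weights and hybrid inheritance probabilities.

#' Attach arc weights to a network
#'
#' Weights measure the expected genetic change along an arc.  Every arc
#' whose head is a hybrid vertex carries weight zero (the hybridization
#' event itself is treated as instantaneous); arcs into normal vertices
#' carry nonnegative weights.
#'
#' @param net a [phylo_network()].
#' @param weights a vector of weights, one per arc: either named by
#'   `"tail->head"`, or unnamed in the row order of `net$arcs`.  Accepts
#'   numerics, [rational()] vectors or character fractions such as
#'   `"11/3"`.  Hybrid-headed arcs may be omitted (their weight is zero)
#'   but when supplied must be zero.
#' @return an object of class `"weighted_network"` extending the network
#'   with a `weights` field (a `rational` vector when all inputs are
#'   exact, otherwise a double vector), aligned with `net$arcs`.
#' @export
weighted_network <- function(net, weights) {
  stopifnot(inherits(net, "phylo_network"))
  keys <- paste0(net$arcs[, 1], "->", net$arcs[, 2])
  hyb_head <- net$indegree[net$arcs[, 2]] >= 2

  exact <- is_rational(weights) || is.character(weights) ||
    (is.numeric(weights) && all(weights == round(weights)))

  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), keys)
    if (length(unknown))
      stop("weight given for unknown arc '", unknown[1], "'", call. = FALSE)
    full <- rep(if (exact) "0" else 0, length(keys))
    names(full) <- keys
    for (nm in names(weights)) {
      full[[nm]] <- if (is.character(weights)) weights[[nm]] else
        as.character(.wt_one(weights, which(names(weights) == nm), exact))
    }
    w <- if (exact) as_rational(unname(full)) else as.numeric(full)
    missing_normal <- setdiff(keys[!hyb_head], names(weights))
    if (length(missing_normal))
      stop("no weight for arc '", missing_normal[1], "'", call. = FALSE)
  } else {
    if (length(weights) != length(keys))
      stop("expected ", length(keys), " weights, got ", length(weights),
           call. = FALSE)
    w <- if (exact) as_rational(weights) else as.numeric(weights)
  }

  wn <- as.numeric(w)
  if (any(wn < 0))
    stop("negative arc weight on '", keys[wn < 0][1], "'", call. = FALSE)
  if (any(hyb_head & wn != 0))
    stop("arc '", keys[hyb_head & wn != 0][1],
         "' enters a hybrid vertex and must have weight zero",
         call. = FALSE)

  out <- net
  out$weights <- w
  out$weight_keys <- keys
  class(out) <- c("weighted_network", "phylo_network")
  out
}

.wt_one <- function(weights, i, exact) {
  if (is_rational(weights)) return(as.character(weights[i]))
  weights[[i]]
}

#' @export
print.weighted_network <- function(x, ...) {
  NextMethod()
  w <- x$weights
  wtxt <- if (is_rational(w)) as.character(w) else format(as.numeric(w))
  cat("Weights: ", paste0(x$weight_keys, "=", wtxt, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# weight of arc (tail, head); rational or double scalar
.weight_of <- function(wn, tail, head) {
  i <- match(paste0(tail, "->", head), wn$weight_keys)
  if (is.na(i))
    stop("no arc (", tail, ", ", head, ")", call. = FALSE)
  wn$weights[i]
}

#' Hybrid inheritance probabilities
#'
#' For each hybrid vertex `h` and parent `u`, `alpha(u, h)` is the
#' probability that a character at `h` is inherited from `u`; the values
#' over the parents of each hybrid must sum to one.  Inheritance events
#' at different hybrids are independent.
#'
#' @param net a `phylo_network`.
#' @param alpha a data frame with columns `hybrid`, `parent`, `alpha`
#'   (numeric, [rational()] or character fractions).  For a hybrid of
#'   indegree two a single row suffices; the other parent receives the
#'   complement.  Alternatively the string `"equiprobable"` assigns
#'   `1/indegree` everywhere, which is also the default when `alpha` is
#'   omitted.
#' @return an object of class `"inheritance_model"`: a data frame of all
#'   (parent, hybrid) pairs with exact rational (or double) probabilities.
#' @export
inheritance_model <- function(net, alpha = "equiprobable") {
  stopifnot(inherits(net, "phylo_network"))
  hyb <- hybrid_vertices(net)
  rows <- list()
  if (identical(alpha, "equiprobable")) {
    for (h in hyb) {
      for (u in net$parents[[h]])
        rows[[length(rows) + 1]] <-
          list(hybrid = h, parent = u,
               alpha = rational(1, length(net$parents[[h]])))
    }
  } else {
    alpha <- as.data.frame(alpha)
    if (!all(c("hybrid", "parent", "alpha") %in% names(alpha)))
      stop("alpha table needs columns hybrid, parent, alpha", call. = FALSE)
    aval <- alpha$alpha
    exact <- is_rational(aval) || is.character(aval)
    for (h in hyb) {
      sub <- alpha[alpha$hybrid == h, , drop = FALSE]
      pars <- net$parents[[h]]
      if (nrow(sub) == 0)
        stop("no inheritance probability given for hybrid '", h, "'",
             call. = FALSE)
      bad <- setdiff(sub$parent, pars)
      if (length(bad))
        stop("'", bad[1], "' is not a parent of hybrid '", h, "'",
             call. = FALSE)
      if (anyDuplicated(sub$parent))
        stop("duplicate alpha row for hybrid '", h, "'", call. = FALSE)
      vals <- if (exact) as_rational(as.character(sub$alpha)) else
        as.numeric(sub$alpha)
      if (nrow(sub) == length(pars) - 1 && length(pars) == 2) {
        # complement rule for indegree-2 hybrids
        other <- setdiff(pars, sub$parent)
        sub <- rbind(sub[, c("hybrid", "parent")],
                     data.frame(hybrid = h, parent = other))
        vals <- c(vals, (if (exact) rational(1) else 1) - vals)
      } else if (nrow(sub) != length(pars)) {
        stop("hybrid '", h, "' needs probabilities for all parents",
             call. = FALSE)
      }
      vnum <- as.numeric(vals)
      if (any(vnum < 0) || any(vnum > 1))
        stop("alpha for hybrid '", h, "' outside [0, 1]", call. = FALSE)
      tot <- sum(vals)
      ok <- if (is_rational(tot)) tot == 1 else abs(tot - 1) <= 1e-12
      if (!ok)
        stop("alpha values for hybrid '", h, "' do not sum to 1",
             call. = FALSE)
      for (i in seq_along(vnum))
        rows[[length(rows) + 1]] <-
          list(hybrid = h, parent = sub$parent[[i]],
               alpha = if (exact) vals[i] else vals[[i]])
    }
  }
  structure(list(hybrid = vapply(rows, `[[`, "", "hybrid"),
                 parent = vapply(rows, `[[`, "", "parent"),
                 alpha = if (length(rows))
                   do.call(c, lapply(rows, `[[`, "alpha")) else rational(
                     numeric(0))),
            class = "inheritance_model")
}

#' @export
print.inheritance_model <- function(x, ...) {
  if (length(x$hybrid) == 0) {
    cat("Inheritance model: no hybrid vertices\n")
    return(invisible(x))
  }
  a <- x$alpha
  cat("Inheritance model:\n")
  for (i in seq_along(x$hybrid))
    cat("  alpha(", x$parent[i], ", ", x$hybrid[i], ") = ",
        if (is_rational(a)) as.character(a[i]) else format(a[[i]]),
        "\n", sep = "")
  invisible(x)
}

.alpha_lookup <- function(model, parent, hybrid) {
  i <- which(model$hybrid == hybrid & model$parent == parent)
  if (length(i) != 1) return(NULL)
  if (is_rational(model$alpha)) model$alpha[i] else model$alpha[[i]]
}

# TRUE when all parents of hybrid h have equal probability
.is_equiprobable_at <- function(model, h) {
  i <- which(model$hybrid == h)
  if (length(i) == 0) return(TRUE)
  a <- model$alpha
  if (is_rational(a)) {
    first <- a[i[1]]
    all(vapply(i[-1], function(j) isTRUE(a[j] == first), TRUE))
  } else {
    diff(range(a[i])) <= 1e-12
  }
}
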
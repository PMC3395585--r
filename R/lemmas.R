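# Closed-form identities relating internal distances and arc weights to
# distances between base-set taxa.
#
# Each function evaluates one identity on a distance matrix; the caller
# is responsible for choosing role vertices that satisfy the identity's
# path conditions in the source network (the reconstruction engine does
# this and re-verifies the conditions).  All functions return exact
# rationals on an exact matrix and doubles otherwise.
#
# Notation: d(u, v) below is the tree-average distance; r is the root
# taxon; "normal path" is a directed path whose non-initial vertices
# have indegree one.

#' Distance between two interior junctions
#'
#' For interior vertices `a` above `b`, each carrying its own normal
#' path to a taxon (`a` to `x`, and `b` to `y` and `z` on disjoint
#' paths), the distance from `a` to `b` is
#' `[d(r,y) + d(x,z) - d(r,x) - d(y,z)] / 2`.
#'
#' @param dm a [tad_dist()] distance matrix.
#' @param roles named vector or list of taxa with entries `r`, `x`, `y`,
#'   `z`.
#' @return a `rational` or double scalar.
#' @export
junction_distance <- function(dm, roles) {
  r <- roles[["r"]]; x <- roles[["x"]]; y <- roles[["y"]]; z <- roles[["z"]]
  (.dd(dm, r, y) + .dd(dm, x, z) - .dd(dm, r, x) - .dd(dm, y, z)) / 2
}

#' Arc weight from taxon-anchored paths
#'
#' Three variants of the basic four-point weight computation for an arc
#' `(a, b)` with `b` normal:
#'
#' * variant 1 — `a` is itself a taxon, `b` has disjoint normal paths to
#'   `y` and `z`:  `[d(a,y) + d(a,z) - d(y,z)] / 2`.
#' * variant 2 — `b` is a taxon and `a` has a normal path to `x`
#'   avoiding `b`:  `[d(b,r) + d(b,x) - d(r,x)] / 2`.
#' * variant 3 — `a` has a normal path to `x` avoiding `b`, and `b` has
#'   disjoint normal paths to `y` and `z`:
#'   `[d(r,y) + d(x,z) - d(r,x) - d(y,z)] / 2`.
#'
#' @param dm a [tad_dist()].
#' @param variant 1, 2 or 3.
#' @param roles named taxa: variant 1 uses `a`, `y`, `z`; variant 2 uses
#'   `r`, `b`, `x`; variant 3 uses `r`, `x`, `y`, `z`.
#' @return a `rational` or double scalar.
#' @export
fourpoint_weight <- function(dm, variant, roles) {
  switch(as.character(variant),
    "1" = {
      a <- roles[["a"]]; y <- roles[["y"]]; z <- roles[["z"]]
      (.dd(dm, a, y) + .dd(dm, a, z) - .dd(dm, y, z)) / 2
    },
    "2" = {
      r <- roles[["r"]]; b <- roles[["b"]]; x <- roles[["x"]]
      (.dd(dm, b, r) + .dd(dm, b, x) - .dd(dm, r, x)) / 2
    },
    "3" = junction_distance(dm, roles),
    stop("variant must be 1, 2 or 3", call. = FALSE))
}

#' Distance from a hybrid vertex to a taxon below it
#'
#' For a hybrid `a` of indegree two whose parents have normal paths to
#' `x1` and `x2`, and a normal path from `a` to `y`, the distance
#' `d(a, y) = [d(y,x1) + d(y,x2) - d(x1,x2)] / 2` holds for *any*
#' inheritance probabilities (the identity holds per displayed tree).
#'
#' @param dm a [tad_dist()].
#' @param roles named taxa `y`, `x1`, `x2`.
#' @return a `rational` or double scalar.
#' @export
hybrid_taxon_distance <- function(dm, roles) {
  y <- roles[["y"]]; x1 <- roles[["x1"]]; x2 <- roles[["x2"]]
  (.dd(dm, y, x1) + .dd(dm, y, x2) - .dd(dm, x1, x2)) / 2
}

#' Weight of the arc leaving a hybrid vertex
#'
#' For a hybrid `a` (parents with normal paths to `x1`, `x2`) whose
#' unique child `b` has disjoint normal paths to `w` and `z`:
#' `omega(a, b) = [d(x1,w) + d(x2,z) - d(x1,x2) - d(w,z)] / 2`.
#'
#' @param dm a [tad_dist()].
#' @param roles named taxa `x1`, `x2`, `w`, `z`.
#' @return a `rational` or double scalar.
#' @export
hybrid_child_weight <- function(dm, roles) {
  x1 <- roles[["x1"]]; x2 <- roles[["x2"]]
  w <- roles[["w"]]; z <- roles[["z"]]
  (.dd(dm, x1, w) + .dd(dm, x2, z) - .dd(dm, x1, x2) - .dd(dm, w, z)) / 2
}

#' Parent-to-taxon distance across an equiprobable hybrid
#'
#' Let `a` be a hybrid with equiprobable inheritance and parents `q1`,
#' `q2` carrying normal paths to `x1` and `x2`, and let `y` be reached
#' from `a` by a normal path.  Then
#' `d(q1, x1) = d(x1,y) - d(r,y) + [d(r,x1) + d(r,x2) - d(x1,x2)] / 2`.
#'
#' @param dm a [tad_dist()].
#' @param roles named taxa `r`, `x1`, `x2`, `y`.
#' @return a `rational` or double scalar.
#' @export
equiprobable_parent_distance <- function(dm, roles) {
  r <- roles[["r"]]; x1 <- roles[["x1"]]
  x2 <- roles[["x2"]]; y <- roles[["y"]]
  .dd(dm, x1, y) - .dd(dm, r, y) +
    (.dd(dm, r, x1) + .dd(dm, r, x2) - .dd(dm, x1, x2)) / 2
}

#' Weight of an arc from the parent of an equiprobable hybrid
#'
#' `h` is an equiprobable hybrid with parents `q1` and `q2`; `q2` has a
#' normal path to `x2` and `h` to `y`; `q1` has a normal child `b` with
#' disjoint normal paths to `z1` and `z2`.  Then `omega(q1, b)` equals
#' `[2d(z1,y) - 4d(r,y) + d(r,z1) + 2d(r,x2) - d(z1,x2) + 2d(z2,y) +
#'   d(r,z2) - d(z2,x2) - 2d(z1,z2)] / 4`.
#' When `b` is itself a leaf the two paths collapse (`z1 = z2 = b`) and
#' the formula reduces to
#' `[2d(b,y) - 2d(r,y) + d(r,b) + d(r,x2) - d(b,x2)] / 2`.
#'
#' @param dm a [tad_dist()].
#' @param roles named taxa `r`, `x2`, `y` and either `z1`, `z2`
#'   (general form) or `b` (leaf form).
#' @param leaf logical: use the leaf form.
#' @return a `rational` or double scalar.
#' @export
equiprobable_parent_weight <- function(dm, roles, leaf = FALSE) {
  r <- roles[["r"]]; x2 <- roles[["x2"]]; y <- roles[["y"]]
  if (leaf) {
    b <- roles[["b"]]
    return((2 * .dd(dm, b, y) - 2 * .dd(dm, r, y) + .dd(dm, r, b) +
            .dd(dm, r, x2) - .dd(dm, b, x2)) / 2)
  }
  z1 <- roles[["z1"]]; z2 <- roles[["z2"]]
  (2 * .dd(dm, z1, y) - 4 * .dd(dm, r, y) + .dd(dm, r, z1) +
   2 * .dd(dm, r, x2) - .dd(dm, z1, x2) + 2 * .dd(dm, z2, y) +
   .dd(dm, r, z2) - .dd(dm, z2, x2) - 2 * .dd(dm, z1, z2)) / 4
}

#' Solve the grandparent configuration for a non-equiprobable hybrid
#'
#' Let `h0` be a hybrid with parents `q1` and `q2`, where `q2` has a
#' grandparent `q3` carrying its own normal path to `x3` and no directed
#' path to `q1`; let `x1`, `x2` and `y` be taxa reached by normal paths
#' from `q1`, `q2` and `h0`.  Writing `v` for the junction of the `q1`
#' and `q3` lineages, the ten taxon-pair distances among
#' `r, x1, x2, x3, y` determine the inheritance probability
#' `alpha(q1, h0)` and the internal distances from `q1` and `q2` down to
#' `x1` and `x2`.
#'
#' The solver first recovers the segment lengths that do not involve
#' alpha (root-to-junction, junction-to-`q3`, `q3`-to-`x3`,
#' `h0`-to-`y`), then solves the three remaining equations in
#' `alpha`, the `v`-to-`q1` segment and the `q3`-to-`q2` segment by
#' elimination, and finally cross-checks the result against the direct
#' closed-form expressions; any disagreement raises an internal
#' consistency error.
#'
#' @param dm a [tad_dist()].
#' @param roles named taxa `r`, `x1`, `x2`, `x3`, `y` (all distinct).
#' @return an object of class `"inheritance_solution"`: a list with the
#'   recovered `alpha` (probability of inheritance from the `q1` side)
#'   and the segment lengths `w_rv`, `w_vq3`, `w_q3x3`, `w_hy`, `w_vq1`,
#'   `w_q3q2`, `w_q1x1`, `w_q2x2`, plus the intermediates `E2`, `E4`,
#'   `C`, `D`.
#' @export
solve_inheritance <- function(dm, roles) {
  r <- roles[["r"]]; x1 <- roles[["x1"]]; x2 <- roles[["x2"]]
  x3 <- roles[["x3"]]; y <- roles[["y"]]
  taxa <- c(r, x1, x2, x3, y)
  if (anyDuplicated(taxa))
    stop("the five role taxa must be distinct", call. = FALSE)
  exact <- .is_exact_dm(dm)
  near0 <- function(v) if (exact) isTRUE(v == 0) else abs(as.numeric(v)) < 1e-9

  w_rv   <- (.dd(dm, r, x1) + .dd(dm, r, x3) - .dd(dm, x1, x3)) / 2
  w_rv2  <- (.dd(dm, r, x1) + .dd(dm, r, x2) - .dd(dm, x1, x2)) / 2
  w_vq3  <- (.dd(dm, r, x3) + .dd(dm, x1, x2) - .dd(dm, r, x1) -
             .dd(dm, x3, x2)) / 2
  w_q3x3 <- (.dd(dm, r, x3) + .dd(dm, x3, x2) - .dd(dm, r, x2)) / 2
  w_hy   <- (.dd(dm, y, x2) + .dd(dm, y, x1) - .dd(dm, x1, x2)) / 2
  E2 <- .dd(dm, x1, y) - .dd(dm, r, y) + w_rv
  E4 <- .dd(dm, x2, y) - .dd(dm, r, y) + w_rv

  if (near0(w_vq3))
    stop("degenerate geometry: the grandparent junction segment has ",
         "length zero", call. = FALSE)

  # elimination of the three remaining equations:
  #   (1) 2a * u_vq1            = d(r,x1) - E2 - w_rv            =: K1
  #   (2) (2-2a)(w_vq3 + u_q3q2) = d(r,x2) - w_rv - E4           =: K2
  #   (3) a (w_vq3 + u_vq1) + (1-a) u_q3q2 = d(x3,y) - w_q3x3 - w_hy =: K3
  K1 <- .dd(dm, r, x1) - E2 - w_rv
  K2 <- .dd(dm, r, x2) - w_rv - E4
  K3 <- .dd(dm, x3, y) - w_q3x3 - w_hy
  alpha <- (K3 - K1 / 2 - K2 / 2 + w_vq3) / (2 * w_vq3)

  # mandatory cross-check against the direct closed forms
  C <- 2 * .dd(dm, x3, y) - 2 * w_q3x3 - 2 * w_hy - .dd(dm, r, x1) + E2 +
    2 * w_rv + E4 - .dd(dm, r, x2) + 2 * w_vq3
  D <- 4 * w_vq3
  agree <- function(p, q) {
    if (exact) isTRUE(p == q) else abs(as.numeric(p - q)) < 1e-9
  }
  if (!agree(alpha, C / D))
    stop("internal consistency error: system solution and closed form ",
         "for alpha disagree", call. = FALSE)

  av <- as.numeric(alpha)
  if (av <= 0 || av >= 1)
    stop("inconsistent distances: recovered inheritance probability ",
         format(av), " lies outside (0, 1)", call. = FALSE)

  w_vq1 <- K1 / (2 * alpha)
  w_q3q2 <- K2 / (2 * (1 - alpha)) - w_vq3
  w_q3q2_closed <- (.dd(dm, x3, y) - w_q3x3 - w_hy -
                    alpha * (w_vq3 + w_vq1)) / (1 - alpha)
  w_vq1_closed <- (.dd(dm, r, x1) - E2 - w_rv) / (2 * alpha)
  if (!agree(w_vq1, w_vq1_closed) || !agree(w_q3q2, w_q3q2_closed))
    stop("internal consistency error: system solution and closed forms ",
         "for the segment lengths disagree", call. = FALSE)

  w_q1x1 <- .dd(dm, r, x1) - w_rv - w_vq1
  w_q2x2 <- .dd(dm, r, x2) - w_rv - w_vq3 - w_q3q2

  structure(list(alpha = alpha, w_rv = w_rv, w_rv_alt = w_rv2,
                 w_vq3 = w_vq3, w_q3x3 = w_q3x3, w_hy = w_hy,
                 E2 = E2, E4 = E4, C = C, D = D,
                 w_vq1 = w_vq1, w_q3q2 = w_q3q2,
                 w_q1x1 = w_q1x1, w_q2x2 = w_q2x2,
                 roles = c(r = r, x1 = x1, x2 = x2, x3 = x3, y = y)),
            class = "inheritance_solution")
}

#' @export
print.inheritance_solution <- function(x, ...) {
  fmt <- function(v) if (is_rational(v)) as.character(v) else format(
    as.numeric(v))
  cat("Inheritance solution (roles: ",
      paste(names(x$roles), x$roles, sep = "=", collapse = ", "), ")\n",
      sep = "")
  cat("  alpha =", fmt(x$alpha), "\n")
  for (f in c("w_rv", "w_vq3", "w_q3x3", "w_hy", "w_vq1", "w_q3q2",
              "w_q1x1", "w_q2x2"))
    cat(" ", f, "=", fmt(x[[f]]), "\n")
  invisible(x)
}

#' Weight of an arc from the parent of a non-equiprobable hybrid
#'
#' The counterpart of [equiprobable_parent_weight()] for a hybrid in the
#' grandparent configuration.  Variant `"a"` computes `omega(q1, b)`
#' where the normal child `b` of `q1` has disjoint normal paths to `x1`
#' and `z1`; variant `"b"` computes `omega(q2, c)` analogously via `x2`
#' and `z2`.  Both internal distances come from [solve_inheritance()]
#' runs that differ only in the target taxon; when `b` (or `c`) is a
#' leaf the two targets coincide and the weight is the single internal
#' distance.
#'
#' @param dm a [tad_dist()].
#' @param variant `"a"` (the `q1` side) or `"b"` (the `q2` side).
#' @param roles named taxa `r`, `x1`, `x2`, `x3`, `y` as in
#'   [solve_inheritance()], plus `z1` (variant a) or `z2` (variant b);
#'   omit the `z` role for the leaf case.
#' @return a `rational` or double scalar.
#' @export
hybrid_parent_weight <- function(dm, variant = c("a", "b"), roles) {
  variant <- match.arg(variant)
  roles <- as.list(roles)
  if (variant == "a") {
    z <- roles$z1
    sol1 <- solve_inheritance(dm, roles)
    if (is.null(z) || identical(z, roles$x1)) return(sol1$w_q1x1)
    roles2 <- roles; roles2$x1 <- z
    sol2 <- solve_inheritance(dm, roles2)
    (sol1$w_q1x1 + sol2$w_q1x1 - .dd(dm, roles$x1, z)) / 2
  } else {
    z <- roles$z2
    sol1 <- solve_inheritance(dm, roles)
    if (is.null(z) || identical(z, roles$x2)) return(sol1$w_q2x2)
    roles2 <- roles; roles2$x2 <- z
    sol2 <- solve_inheritance(dm, roles2)
    (sol1$w_q2x2 + sol2$w_q2x2 - .dd(dm, roles$x2, z)) / 2
  }
}
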
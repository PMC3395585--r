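# Exact rational arithmetic.
#
# Numerator and denominator are stored as integer-valued doubles, always
# reduced, denominator positive.  Every operation checks that the reduced
# components stay below 2^53, where double arithmetic on integers is exact;
# beyond that an error is raised rather than silently losing exactness.

.RAT_MAX <- 2^53

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- ifelse(t > 0, t, a)
  }
  a
}

.rat_check <- function(num, den) {
  if (any(!is.finite(num)) || any(!is.finite(den)))
    stop("rational: non-finite component", call. = FALSE)
  if (any(abs(num) >= .RAT_MAX) || any(abs(den) >= .RAT_MAX))
    stop("rational: component exceeds exact integer range (2^53)",
         call. = FALSE)
}

.rat_new <- function(num, den) {
  structure(list(num = num, den = den), class = "rational")
}

.rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("rational: zero denominator", call. = FALSE)
  # intermediate products beyond 2^53 are already inexact: refuse first
  .rat_check(num, den)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  g <- .gcd(num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  .rat_check(num, den)
  .rat_new(num, den)
}

#' Exact rational numbers
#'
#' A vectorised exact fraction type used throughout the forward model and
#' the reconstruction engine, so that quantities such as 11/3 are
#' represented without rounding.  Standard arithmetic (`+`, `-`, `*`, `/`),
#' comparisons, `sum()`, `abs()`, `min()`/`max()` and subsetting all work.
#' Mixing a rational with a whole-number `numeric` keeps exactness; mixing
#' with a fractional `numeric` demotes the result to double.
#'
#' @param num integer-valued numerator(s), or a character vector of
#'   fractions such as `"11/3"`.
#' @param den integer-valued denominator(s), recycled against `num`.
#' @return an object of class `"rational"`.
#' @examples
#' rational(11, 3) + rational(1, 3)   # exactly 4
#' as.numeric(rational("2/7"))
#' @export
rational <- function(num, den = 1) {
  if (is.character(num)) return(as_rational(num))
  if (inherits(num, "rational")) return(num)
  num <- as.numeric(num)
  den <- as.numeric(den)
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational: numerator and denominator must be whole numbers",
         call. = FALSE)
  if (length(num) == 0 || length(den) == 0)
    return(.rat_new(numeric(0), numeric(0)))
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  .rat_reduce(num, den)
}

#' Coerce to rational
#'
#' Accepts rational objects, whole-number numerics, and character fractions
#' of the form `"p/q"` or plain integers as strings.
#'
#' @param x object to coerce.
#' @return a `rational` vector.
#' @export
as_rational <- function(x) {
  if (inherits(x, "rational")) return(x)
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)
    num <- vapply(parts, function(p) as.numeric(p[[1]]), 0)
    den <- vapply(parts, function(p) {
      if (length(p) > 1) as.numeric(p[[2]]) else 1
    }, 0)
    if (any(is.na(num)) || any(is.na(den)))
      stop("as_rational: cannot parse '", paste(x[is.na(num) | is.na(den)],
                                                collapse = "', '"),
           "'", call. = FALSE)
    return(rational(num, den))
  }
  rational(x)
}

#' @export
is_rational <- function(x) inherits(x, "rational")

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) .rat_new(x$num[i], x$den[i])

#' @export
`[<-.rational` <- function(x, i, value) {
  value <- as_rational(value)
  x$num[i] <- value$num
  x$den[i] <- value$den
  x
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  .rat_new(unlist(lapply(parts, `[[`, "num")),
           unlist(lapply(parts, `[[`, "den")))
}

#' @export
rep.rational <- function(x, ...) {
  i <- rep(seq_along(x$num), ...)
  .rat_new(x$num[i], x$den[i])
}

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
as.character.rational <- function(x, ...) {
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  ifelse(x$den == 1, fmt(x$num), paste0(fmt(x$num), "/", fmt(x$den)))
}

#' @export
format.rational <- function(x, ...) as.character(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(as.character(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

# Promote a numeric operand: exact when integral, otherwise signal a
# demotion to double by returning NULL.
.rat_promote <- function(x) {
  if (inherits(x, "rational")) return(x)
  if (is.numeric(x) && all(is.finite(x)) && all(x == round(x)))
    return(rational(x))
  NULL
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(.rat_new(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals", call. = FALSE)
  }
  r1 <- .rat_promote(e1)
  r2 <- .rat_promote(e2)
  if (is.null(r1) || is.null(r2)) {
    # one side is a non-integral double: compute in double precision
    v1 <- if (inherits(e1, "rational")) as.numeric(e1) else e1
    v2 <- if (inherits(e2, "rational")) as.numeric(e2) else e2
    return(get(.Generic)(v1, v2))
  }
  n <- max(length(r1), length(r2))
  i1 <- rep_len(seq_along(r1$num), n)
  i2 <- rep_len(seq_along(r2$num), n)
  a <- r1$num[i1]; b <- r1$den[i1]
  c_ <- r2$num[i2]; d <- r2$den[i2]
  switch(.Generic,
    "+" = .rat_reduce(a * d + c_ * b, b * d),
    "-" = .rat_reduce(a * d - c_ * b, b * d),
    "*" = .rat_reduce(a * c_, b * d),
    "/" = {
      if (any(c_ == 0)) stop("rational: division by zero", call. = FALSE)
      .rat_reduce(a * d, b * c_)
    },
    "==" = a * d == c_ * b,
    "!=" = a * d != c_ * b,
    "<"  = a * d < c_ * b,
    "<=" = a * d <= c_ * b,
    ">"  = a * d > c_ * b,
    ">=" = a * d >= c_ * b,
    stop(.Generic, " not defined for rationals", call. = FALSE)
  )
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  x <- c.rational(...)
  switch(.Generic,
    sum = {
      acc <- rational(0)
      for (i in seq_along(x)) acc <- acc + x[i]
      acc
    },
    min = {
      acc <- x[1]
      for (i in seq_along(x)[-1]) if (x[i] < acc) acc <- x[i]
      acc
    },
    max = {
      acc <- x[1]
      for (i in seq_along(x)[-1]) if (x[i] > acc) acc <- x[i]
      acc
    },
    range = c(min(x), max(x)),
    stop(.Generic, " not defined for rationals", call. = FALSE)
  )
}

#' @export
Math.rational <- function(x, ...) {
  if (.Generic == "abs") return(.rat_new(abs(x$num), x$den))
  stop(.Generic, " not defined for rationals", call. = FALSE)
}
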
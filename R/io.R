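# File formats: extended Newick for networks, PHYLIP square matrices
# for distances, TSV sidecars for inheritance probabilities and weight
# tables.
#
# Extended-Newick dialect: every vertex is labelled; a hybrid vertex
# appears once per parent, tagged `label#H<id>`, with its subtree
# attached to exactly one occurrence.  Branch lengths after `:` are the
# arc weights; lengths on hybrid-headed branches must be 0 or absent.
# Numbers written as short decimals (at most six decimal places) or as
# `p/q` fractions are read back as exact rationals; longer decimals fall
# back to double precision.

# parse a numeric token into rational (exact) or double; returns a list
# (value=, exact=)
.parse_weight_token <- function(tok) {
  tok <- trimws(tok)
  if (grepl("^[+-]?[0-9]+/[0-9]+$", tok))
    return(list(value = as_rational(tok), exact = TRUE))
  if (grepl("^[+-]?[0-9]+$", tok))
    return(list(value = rational(as.numeric(tok)), exact = TRUE))
  if (grepl("^[+-]?[0-9]+\\.[0-9]{1,6}$", tok)) {
    dec <- sub("^[+-]?[0-9]+\\.", "", tok)
    den <- 10^nchar(dec)
    return(list(value = rational(round(as.numeric(tok) * den), den),
                exact = TRUE))
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop("cannot parse number '", tok, "'", call. = FALSE)
  list(value = v, exact = FALSE)
}

.fmt_weight <- function(w, exact = FALSE) {
  if (exact && is_rational(w)) return(as.character(w))
  format(as.numeric(w), digits = 12)
}

#' Write a network as extended Newick
#'
#' @param wn a [weighted_network()] (or plain [phylo_network()]; absent
#'   weights are written as 0).
#' @param path output file; when `NULL` the Newick string is returned.
#' @param exact write weights as exact `p/q` fractions instead of
#'   decimals.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_enewick <- function(wn, path = NULL, exact = FALSE) {
  net <- wn
  has_w <- inherits(wn, "weighted_network")
  hyb <- hybrid_vertices(net)
  tag <- stats::setNames(seq_along(hyb), hyb)
  primary <- stats::setNames(vapply(hyb, function(h) net$parents[[h]][1],
                                    ""), hyb)
  wt_txt <- function(tail, head) {
    if (!has_w) return("0")
    .fmt_weight(.weight_of(wn, tail, head), exact)
  }
  lab <- function(v) {
    if (v %in% hyb) paste0(v, "#H", tag[[v]]) else v
  }
  render <- function(v, parent) {
    if (v %in% hyb && !is.null(parent) && parent != primary[[v]])
      return(paste0(lab(v), ":0"))
    kids <- net$children[[v]]
    body <- if (length(kids) == 0) lab(v) else
      paste0("(", paste(vapply(kids, render, "", parent = v),
                        collapse = ","), ")", lab(v))
    if (is.null(parent)) body else
      paste0(body, ":", wt_txt(parent, v))
  }
  txt <- paste0(render(net$root, NULL), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# tokenizer for newick strings
.nwk_tokens <- function(txt) {
  txt <- gsub("[[:space:]]", "", txt)
  pattern <- "\\(|\\)|,|;|:[^(),;:]+|[^(),;:]+"
  m <- gregexpr(pattern, txt)[[1]]
  if (m[1] == -1) stop("empty newick string", call. = FALSE)
  regmatches(txt, gregexpr(pattern, txt))[[1]]
}

#' Read a network from extended Newick
#'
#' Parses the dialect produced by [write_enewick()]: internal labels
#' mandatory, hybrid vertices tagged `label#H<id>` once per parent,
#' branch lengths as arc weights.  When an inheritance sidecar
#' (`alpha_path`) is given, it is read with [read_alpha_table()].
#'
#' @param path path to the Newick file (or a literal string containing
#'   `;`).
#' @param alpha_path optional TSV sidecar of inheritance probabilities.
#' @return a [weighted_network()]; with `alpha_path`, a list
#'   `(network, model)`.
#' @export
read_enewick <- function(path, alpha_path = NULL) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else
    paste(readLines(path, warn = FALSE), collapse = "")
  toks <- .nwk_tokens(txt)
  if (toks[length(toks)] != ";")
    stop("newick string must end with ';'", call. = FALSE)
  toks <- toks[-length(toks)]

  # recursive descent; each node: label token, optional :length
  pos <- 0
  peek <- function() if (pos < length(toks)) toks[pos + 1] else ""
  advance <- function() {
    pos <<- pos + 1
    toks[pos]
  }
  arcs <- list()
  weights <- list()
  hybrid_map <- new.env(parent = emptyenv())  # tag -> label
  anon <- 0

  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      advance()
      repeat {
        kids[[length(kids) + 1]] <- parse_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("unbalanced parentheses in newick input", call. = FALSE)
      }
    }
    label_tok <- ""
    if (peek() != "" && !peek() %in% c("(", ")", ",") &&
        !startsWith(peek(), ":"))
      label_tok <- advance()
    len <- NULL
    if (startsWith(peek(), ":"))
      len <- .parse_weight_token(sub("^:", "", advance()))

    tagm <- regmatches(label_tok, regexec("^(.*)#H([0-9]+)$", label_tok))[[1]]
    if (length(tagm)) {
      tag <- tagm[3]
      lbl <- tagm[2]
      known <- hybrid_map[[tag]]
      if (lbl == "" && is.null(known))
        stop("hybrid tag #H", tag, " appears without a label", call. = FALSE)
      if (is.null(known)) hybrid_map[[tag]] <- lbl
      else if (lbl != "" && lbl != known)
        stop("hybrid tag #H", tag, " has conflicting labels '", known,
             "' and '", lbl, "'", call. = FALSE)
      lbl <- hybrid_map[[tag]]
    } else {
      lbl <- label_tok
      if (lbl == "") {
        anon <<- anon + 1
        lbl <- sprintf(".n%d", anon)
      }
    }
    for (k in kids) {
      arcs[[length(arcs) + 1]] <<- c(lbl, k$label)
      weights[[length(weights) + 1]] <<- k$length
    }
    list(label = lbl, length = len)
  }
  root <- parse_node()
  if (pos != length(toks))
    stop("trailing tokens after newick tree", call. = FALSE)

  amat <- do.call(rbind, arcs)
  net <- phylo_network(amat, root = root$label)

  exact <- all(vapply(weights, function(w) is.null(w) || w$exact, TRUE))
  keys <- paste0(amat[, 1], "->", amat[, 2])
  wvals <- vapply(seq_along(weights), function(i) {
    w <- weights[[i]]
    if (is.null(w)) return(if (exact) "0" else "0")
    if (exact) as.character(as_rational(
      if (is_rational(w$value)) w$value else rational(w$value))) else
      as.character(as.numeric(w$value))
  }, "")
  if (!exact) {
    wnum <- as.numeric(vapply(seq_along(weights), function(i) {
      w <- weights[[i]]
      if (is.null(w)) 0 else as.numeric(
        if (is_rational(w$value)) as.numeric(w$value) else w$value)
    }, 0))
    wgt <- stats::setNames(wnum, keys)
  } else {
    wgt <- stats::setNames(wvals, keys)
  }

  hyb_head <- net$indegree[amat[, 2]] >= 2
  bad <- hyb_head & vapply(seq_along(weights), function(i) {
    w <- weights[[i]]
    !is.null(w) && as.numeric(if (is_rational(w$value)) as.numeric(w$value)
                              else w$value) != 0
  }, TRUE)
  if (any(bad))
    stop("nonzero branch length on hybrid-headed arc (", amat[bad, 1][1],
         ", ", amat[bad, 2][1], ")", call. = FALSE)

  wn <- weighted_network(net, wgt)
  if (is.null(alpha_path)) return(wn)
  model <- read_alpha_table(alpha_path, wn)
  list(network = wn, model = model)
}

#' Read/write inheritance probability sidecars
#'
#' TSV with header `hybrid  parent  alpha`.  For an indegree-2 hybrid a
#' single row suffices; the complement is inferred.
#'
#' @param path file path.
#' @param net the network the probabilities refer to.
#' @return an [inheritance_model()].
#' @export
read_alpha_table <- function(path, net) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("hybrid", "parent", "alpha") %in% names(tab)))
    stop("alpha sidecar needs columns hybrid, parent, alpha",
         call. = FALSE)
  parsed <- lapply(tab$alpha, .parse_weight_token)
  exact <- all(vapply(parsed, `[[`, TRUE, "exact"))
  avals <- if (exact)
    vapply(parsed, function(p) as.character(p$value), "") else
    vapply(parsed, function(p) as.numeric(
      if (is_rational(p$value)) as.numeric(p$value) else p$value), 0)
  inheritance_model(net, data.frame(hybrid = tab$hybrid,
                                    parent = tab$parent, alpha = avals,
                                    stringsAsFactors = FALSE))
}

#' @rdname read_alpha_table
#' @param model an [inheritance_model()] to write.
#' @param exact write probabilities as `p/q` fractions.
#' @export
write_alpha_table <- function(model, path, exact = FALSE) {
  a <- model$alpha
  txt <- if (exact && is_rational(a)) as.character(a) else
    vapply(seq_along(model$hybrid), function(i)
      format(as.numeric(if (is_rational(a)) a[i] else a[[i]]),
             digits = 12), "")
  utils::write.table(data.frame(hybrid = model$hybrid,
                                parent = model$parent, alpha = txt),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a recovered weight table
#'
#' TSV with columns `tail`, `head`, `weight`.
#'
#' @param fit a [fit_tree_average()] result (or a `weighted_network`).
#' @param path file path.
#' @param exact write weights as `p/q` fractions.
#' @export
write_weight_table <- function(fit, path, exact = FALSE) {
  if (inherits(fit, "tad_fit")) {
    keys <- fit$weight_keys
    w <- fit$weights
  } else {
    keys <- fit$weight_keys
    w <- fit$weights
  }
  parts <- strsplit(keys, "->", fixed = TRUE)
  txt <- if (exact && is_rational(w)) as.character(w) else
    vapply(seq_along(keys), function(i)
      format(as.numeric(if (is_rational(w)) w[i] else w[[i]]),
             digits = 12), "")
  utils::write.table(data.frame(tail = vapply(parts, `[[`, "", 1),
                                head = vapply(parts, `[[`, "", 2),
                                weight = txt),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write PHYLIP square distance matrices
#'
#' First line: taxon count; then one row per taxon (label followed by
#' the full row of values, whitespace-delimited).  Entries may be
#' decimals or `p/q` fractions; short decimals and fractions are read
#' exactly.  Matrices must be symmetric within `tol`.
#'
#' @param path file path.
#' @param tol symmetry tolerance on read.
#' @return a [tad_dist()].
#' @export
read_phylip_matrix <- function(path, tol = 1e-9) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first line must be the taxon count", call. = FALSE)
  if (length(lines) < n + 1)
    stop("expected ", n, " matrix rows, found ", length(lines) - 1,
         call. = FALSE)
  taxa <- character(n)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "[[:space:]]+")[[1]]
    if (length(parts) != n + 1)
      stop("row ", i, " has ", length(parts) - 1, " values, expected ", n,
           call. = FALSE)
    taxa[i] <- parts[1]
    cells[[i]] <- lapply(parts[-1], .parse_weight_token)
  }
  exact <- all(vapply(unlist(cells, recursive = FALSE), `[[`, TRUE,
                      "exact"))
  num <- matrix(0, n, n)
  den <- if (exact) matrix(1, n, n) else NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- cells[[i]][[j]]$value
      if (exact) {
        rv <- if (is_rational(v)) v else rational(v)
        num[i, j] <- rv$num
        den[i, j] <- rv$den
      } else {
        num[i, j] <- if (is_rational(v)) as.numeric(v) else v
      }
    }
  }
  m <- if (exact) num / den else num
  if (any(m < 0))
    stop("negative distance between '", taxa[which(m < 0, arr.ind = TRUE)[1, 1]],
         "' and '", taxa[which(m < 0, arr.ind = TRUE)[1, 2]], "'",
         call. = FALSE)
  asym <- abs(m - t(m)) > tol
  if (any(asym)) {
    ij <- which(asym, arr.ind = TRUE)[1, ]
    stop("matrix is not symmetric: entry (", taxa[ij[1]], ", ",
         taxa[ij[2]], ")", call. = FALSE)
  }
  tad_dist(num, taxa = taxa, den = den)
}

#' @rdname read_phylip_matrix
#' @param dm a [tad_dist()] to write.
#' @param exact write entries as `p/q` fractions.
#' @export
write_phylip_matrix <- function(dm, path, exact = FALSE) {
  stopifnot(inherits(dm, "tad_dist"))
  n <- length(dm$taxa)
  lines <- as.character(n)
  for (i in seq_len(n)) {
    row <- vapply(seq_len(n), function(j) {
      if (exact && .is_exact_dm(dm))
        as.character(rational(dm$num[i, j], dm$den[i, j]))
      else .fmt_weight(as.matrix(dm)[i, j])
    }, "")
    lines <- c(lines, paste(c(dm$taxa[i], row), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}
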
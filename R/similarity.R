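#' Distance/cosine quotient similarity between two descriptors
#'
#' The dissimilarity between two RNA secondary structures is the quotient of
#' (1) the Euclidean distance between the end-points of their 36D descriptor
#' vectors (drawn from the origin) and (2) the cosine of the angle between
#' the two vectors:
#' \deqn{s(u, v) = \frac{\lVert u - v \rVert_2}{\cos\angle(u, v)}.}
#' Identical descriptors give exactly 0; the smaller the quotient, the more
#' similar the structures.  The measure is deliberately not scale-invariant:
#' the distance term sees vector magnitude, so `s(u, 2u) = |u|`.
#'
#' @param u,v numeric descriptor vectors of equal length, both non-zero.
#' @param eps cosine values at or below `eps` are rejected as a "degenerate
#'   angle" rather than returning a sign-flipped score.
#' @return a single non-negative number.
#' @examples
#' u <- descriptor36("AcgU")
#' quotient_similarity(u, u)      # 0
#' quotient_similarity(u, 2 * u)  # == sqrt(sum(u^2))
#' @export
quotient_similarity <- function(u, v, eps = 1e-9) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("descriptor lengths differ")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-magnitude descriptor")
  d <- sqrt(sum((u - v)^2))
  if (d == 0) return(0)
  ca <- sum(u * v) / (nu * nv)
  if (ca <= eps) stop(sprintf("degenerate angle: cosine %.3g <= %.3g", ca, eps))
  d / ca
}

#' Pairwise similarity/dissimilarity matrix
#'
#' Builds the symmetric matrix of [quotient_similarity] values over the 36D
#' descriptors of a set of structures.  Diagonal entries are exactly 0.
#'
#' @param items named list of [rna_structure] / [char_seq] objects (or
#'   characteristic-sequence strings), or a numeric matrix with one
#'   descriptor per row; at least 2 items with unique labels.
#' @param labels optional label vector overriding the item names.
#' @param ... passed to [descriptor36].
#' @return square numeric matrix with the labels as dimnames.
#' @export
pairwise_matrix <- function(items, labels = NULL, ...) {
  if (is.matrix(items) && is.numeric(items)) {
    desc <- items
    if (is.null(labels)) labels <- rownames(desc)
  } else {
    if (!is.list(items)) stop("'items' must be a list or a descriptor matrix")
    desc <- t(vapply(items, function(it) descriptor36(it, ...), numeric(36)))
    if (is.null(labels)) {
      labels <- names(items)
      if (is.null(labels))
        labels <- vapply(items, function(it)
          if (is.character(it)) "" else it$name, "")
    }
  }
  m <- nrow(desc)
  if (m < 2L) stop("need at least 2 items")
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every item needs a non-empty label")
  if (anyDuplicated(labels))
    stop(sprintf("duplicate label '%s'", labels[duplicated(labels)][1L]))
  out <- matrix(0, m, m, dimnames = list(labels, labels))
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      s <- tryCatch(quotient_similarity(desc[a, ], desc[b, ]),
                    error = function(e) stop(sprintf(
                      "pair (%s, %s): %s", labels[a], labels[b],
                      conditionMessage(e)), call. = FALSE))
      out[a, b] <- s
      out[b, a] <- s
    }
  }
  out
}

#' Read / write square PHYLIP distance matrices
#'
#' Relaxed square PHYLIP layout: a first line with the number of taxa,
#' then one line per taxon holding the label followed by the full row of
#' distances, whitespace-separated.
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path; for `write_phylip`, `NULL` returns the lines.
#' @param digits number of decimal places written (full precision is the
#'   caller's responsibility to keep elsewhere).
#' @return `read_phylip()` the matrix; `write_phylip()` the lines,
#'   invisibly when written to a file.
#' @export
write_phylip <- function(m, path = NULL, digits = 6L) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  lines <- c(
    sprintf("%5d", nrow(m)),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(formatC(rownames(m)[i], width = -10L),
              formatC(m[i, ], format = "f", digits = digits)),
            collapse = " ")
    }, "")
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else split_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  ntax <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(ntax) || ntax < 2L) stop("bad PHYLIP header line")
  if (length(lines) < ntax + 1L) stop("truncated PHYLIP matrix")
  labs <- character(ntax)
  m <- matrix(NA_real_, ntax, ntax)
  for (i in seq_len(ntax)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(tok) != ntax + 1L)
      stop(sprintf("row %d has %d values, expected %d", i,
                   length(tok) - 1L, ntax))
    labs[i] <- tok[1L]
    m[i, ] <- as.numeric(tok[-1L])
  }
  dimnames(m) <- list(labs, labs)
  m
}
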
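# component names of the 36D descriptor: for each map k = 1..3 and
# group-set j = 1..4, the mean x, y, z of that group's points
descriptor_names <- function() {
  out <- character(0)
  for (k in 1:3) for (j in 1:4)
    out <- c(out, paste0(c("x", "y", "z"), k, j))
  out
}

#' Geometric-center descriptor of the three curves
#'
#' For map k and group-set j (1 positive-unpaired, 2 negative-unpaired,
#' 3 positive-paired, 4 negative-paired) the components are
#' \deqn{\bar x_{kj} = \frac1n \sum_{i \in G_{kj}} x_{ki}}
#' and likewise for y and z: sums restricted to the positions whose symbol
#' belongs to the group-set, divided by the full sequence length n (not the
#' group size).  A group-set absent from the sequence contributes an exact
#' (0, 0, 0) triple.
#'
#' @param curves list of the three [map_curve] results (as from
#'   [all_curves]), in map order 1, 2, 3.
#' @param n sequence length; defaults to the curves' common length, and a
#'   mismatch between the curves is an error.
#' @return named numeric vector of length 36, ordered
#'   `x11 y11 z11 x12 ... z34`.
#' @export
geometric_centers <- function(curves, n = NULL) {
  if (length(curves) != 3L)
    stop("'curves' must hold the three map curves")
  lens <- vapply(curves, function(cv) attr(cv, "n"), 0L)
  if (length(unique(lens)) != 1L)
    stop("mismatched curve lengths")
  if (is.null(n)) n <- lens[1L]
  if (n != lens[1L]) stop("'n' does not match the curve length")
  out <- numeric(36)
  names(out) <- descriptor_names()
  p <- 0L
  for (k in 1:3) {
    cv <- curves[[k]]
    for (j in 1:4) {
      idx <- cv$group == j
      out[p + 1L] <- sum(cv$x[idx]) / n
      out[p + 2L] <- sum(cv$y[idx]) / n
      out[p + 3L] <- sum(cv$z[idx]) / n
      p <- p + 3L
    }
  }
  out
}

#' 36-dimensional descriptor of an RNA secondary structure
#'
#' Composition of [encode_structure] (when given a structure), [all_curves]
#' and [geometric_centers]: the concatenated geometric centers of the four
#' group-sets of the amino/keto, purine/pyrimidine and weak/strong curves.
#'
#' @param x an [rna_structure], [char_seq], or characteristic-sequence
#'   string.
#' @param ... passed to [as_char_seq] (e.g. `strict_pairs` for structures).
#' @return named numeric vector of length 36 (see [geometric_centers]).
#' @examples
#' descriptor36("A")          # x11 = 1/2, y11 = sqrt(3)/2, z11 = 1, ...
#' descriptor36(parse_dot_bracket("GCAUGC\n((..))"))
#' @export
descriptor36 <- function(x, ...) {
  cs <- as_char_seq(x, ...)
  geometric_centers(all_curves(cs), length(cs))
}

#' Symbol composition of a characteristic sequence
#'
#' @param cs a [char_seq] (or anything [as_char_seq] accepts).
#' @return list with `frequencies` (named length-8 vector over
#'   `A G C U a g c u`, summing to 1) and `paired_fraction` (the stem
#'   content: primed symbols / n).
#' @export
composition_summary <- function(cs) {
  cs <- as_char_seq(cs)
  n <- length(cs)
  lab <- cs$bases
  lab[cs$paired] <- tolower(lab[cs$paired])
  syms <- c("A", "G", "C", "U", "a", "g", "c", "u")
  freq <- vapply(syms, function(s) sum(lab == s), 0L) / n
  list(frequencies = freq, paired_fraction = sum(freq[5:8]))
}
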
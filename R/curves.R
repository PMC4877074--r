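# The three chemical dichotomies of the bases.  For map k the four
# group-sets, in descriptor order, are:
#   1 positive-unpaired, 2 negative-unpaired, 3 positive-paired,
#   4 negative-paired,
# where "positive" is the first-listed set (amino / purine / weak).
GROUP_SCHEMES <- list(
  mk = list(pos = c("A", "C"), neg = c("G", "U")),  # amino / keto
  ry = list(pos = c("A", "G"), neg = c("C", "U")),  # purine / pyrimidine
  ws = list(pos = c("A", "U"), neg = c("C", "G"))   # weak / strong H-bonds
)

#' Cumulative symbol counts of a characteristic sequence
#'
#' Running totals, from the first base up to and including position i, of
#' each of the eight symbols A, G, C, U, A', G', C', U'.
#'
#' @param cs a [char_seq] (or anything [as_char_seq] accepts).
#' @return an n x 8 integer matrix with columns
#'   `A G C U A' G' C' U'`; row i sums to i.
#' @export
cumulative_counts <- function(cs) {
  cs <- as_char_seq(cs)
  syms <- c("A", "G", "C", "U", "A'", "G'", "C'", "U'")
  lab <- ifelse(cs$paired, paste0(cs$bases, "'"), cs$bases)
  out <- vapply(syms, function(s) cumsum(lab == s),
                integer(length(cs)))
  dim(out) <- c(length(cs), 8L)  # vapply drops dim for n = 1
  dimnames(out) <- list(NULL, syms)
  out
}

#' Map a characteristic sequence onto one dynamic 3D curve
#'
#' Position i (of n) is sent to a point whose X-Y projection lies on the
#' unit circle and whose height records group composition.  With
#' t = i/(n+1):
#' \itemize{
#'   \item x =  t for unpaired symbols, -t for paired (primed) symbols;
#'   \item y =  +sqrt(1 - t^2) when the base is in the map's positive set
#'     (amino \{A,C\}, purine \{A,G\} or weak \{A,U\} for k = 1, 2, 3),
#'     -sqrt(1 - t^2) otherwise;
#'   \item z = the cumulative count, up to and including i, of symbols in
#'     the same group-set (same two bases, same paired status).
#' }
#' Points are returned in sequence order; the curve connects them in order.
#'
#' @param cs a [char_seq] (or anything [as_char_seq] accepts).
#' @param k map index: 1 = amino/keto (M-K), 2 = purine/pyrimidine (R-Y),
#'   3 = weak/strong (W-S).
#' @return a data frame of class `rna_curve3d` with columns `index`,
#'   `symbol`, `group` (1-4 as in the descriptor layout), `x`, `y`, `z`;
#'   attributes `map_index` and `n`.
#' @examples
#' map_curve(parse_char_seq("au"), k = 1)
#' @export
map_curve <- function(cs, k) {
  cs <- as_char_seq(cs)
  if (!(length(k) == 1L && k %in% 1:3))
    stop("'k' must be 1, 2 or 3")
  sch <- GROUP_SCHEMES[[k]]
  n <- length(cs)
  t <- seq_len(n) / (n + 1)
  in_pos <- cs$bases %in% sch$pos
  r <- sqrt(1 - t^2)  # t in (0,1) so always defined
  stopifnot(all(is.finite(r)))
  x <- ifelse(cs$paired, -t, t)
  y <- ifelse(in_pos, r, -r)
  group <- 1L + (!in_pos) + 2L * cs$paired
  z <- numeric(n)
  for (j in 1:4) {
    memb <- group == j
    z[memb] <- cumsum(memb)[memb]
  }
  lab <- cs$bases
  lab[cs$paired] <- tolower(lab[cs$paired])
  out <- data.frame(index = seq_len(n), symbol = lab, group = group,
                    x = x, y = y, z = z, stringsAsFactors = FALSE)
  class(out) <- c("rna_curve3d", "data.frame")
  attr(out, "map_index") <- as.integer(k)
  attr(out, "map_name") <- toupper(names(GROUP_SCHEMES)[k])
  attr(out, "n") <- n
  out
}

#' All three curves of a characteristic sequence
#'
#' @param cs a [char_seq] (or anything [as_char_seq] accepts).
#' @return named list `mk`, `ry`, `ws` of [map_curve] results.
#' @export
all_curves <- function(cs) {
  cs <- as_char_seq(cs)
  list(mk = map_curve(cs, 1L), ry = map_curve(cs, 2L), ws = map_curve(cs, 3L))
}

#' @export
print.rna_curve3d <- function(x, ...) {
  cat(sprintf("<rna_curve3d> map %s (k=%d), n=%d points\n",
              attr(x, "map_name"), attr(x, "map_index"), attr(x, "n")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (attr(x, "n") > 6L) cat(sprintf("  ... %d more rows\n", attr(x, "n") - 6L))
  invisible(x)
}

#' Plot a 3D curve as two panels
#'
#' Left panel: X-Y projection (points move on the unit circle; paired bases
#' on the negative-x side).  Right panel: z profile along the sequence,
#' colored by group-set.
#'
#' @param x an `rna_curve3d`.
#' @param ... further arguments passed to [graphics::plot].
#' @export
plot.rna_curve3d <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  cols <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a")[x$group]
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::plot(cos(th), sin(th), type = "l", col = "grey70", asp = 1,
                 xlab = "x", ylab = "y",
                 main = sprintf("%s curve: X-Y projection", attr(x, "map_name")),
                 ...)
  graphics::points(x$x, x$y, col = cols, pch = 19, cex = 0.6)
  graphics::plot(x$index, x$z, type = "s", col = "grey50",
                 xlab = "position", ylab = "z (group cumulative count)",
                 main = "height profile")
  graphics::points(x$index, x$z, col = cols, pch = 19, cex = 0.6)
  invisible(x)
}
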
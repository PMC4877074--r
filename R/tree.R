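#' UPGMA clustering of a distance matrix
#'
#' Classic unweighted pair group method with arithmetic mean: the closest
#' pair of clusters is merged at a node of height d/2, and distances to the
#' merged cluster are the size-weighted averages of the members' distances.
#' The resulting rooted tree is ultrametric.  Ties in the closest pair are
#' broken by the lexicographically smallest (smallest-leaf, smallest-leaf)
#' label pair, so the output is deterministic and invariant to input order.
#'
#' @param m symmetric numeric matrix with zero diagonal, finite non-negative
#'   entries and unique dimnames (>= 2 labels); a `dist` is accepted.
#' @return object of class `upgma_tree`: a list with `root` (nested nodes
#'   `list(label, height, children)`, leaves at height 0) and `labels`.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(m))  # "((A:1,B:1):3,C:4);"
#' @export
upgma <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("'m' must be square")
  labels <- rownames(m)
  if (is.null(labels) || anyDuplicated(labels))
    stop("'m' needs unique row/column labels")
  if (nrow(m) < 2L) stop("need at least 2 labels")
  if (any(!is.finite(m))) stop("non-finite entry in distance matrix")
  if (any(m < 0)) stop("negative entry in distance matrix")
  if (any(abs(m - t(m)) > 0)) stop("matrix is not symmetric")

  k <- nrow(m)
  clusters <- lapply(seq_len(k), function(i)
    list(size = 1L, height = 0,
         key = labels[i],
         node = list(label = labels[i], height = 0, children = NULL)))
  D <- m

  while (length(clusters) > 1L) {
    nc <- length(clusters)
    up <- D
    up[lower.tri(up, diag = TRUE)] <- Inf
    dmin <- min(up)
    cand <- which(up == dmin, arr.ind = TRUE)
    keys <- vapply(clusters, function(cl) cl$key, "")
    k1 <- pmin(keys[cand[, 1L]], keys[cand[, 2L]])
    k2 <- pmax(keys[cand[, 1L]], keys[cand[, 2L]])
    pick <- order(k1, k2)[1L]
    a <- cand[pick, 1L]; b <- cand[pick, 2L]
    ca <- clusters[[a]]; cb <- clusters[[b]]
    h <- dmin / 2
    kids <- if (ca$key <= cb$key) list(ca$node, cb$node) else list(cb$node, ca$node)
    merged <- list(
      size = ca$size + cb$size,
      height = h,
      key = min(ca$key, cb$key),
      node = list(label = NA_character_, height = h, children = kids))
    rest <- setdiff(seq_len(nc), c(a, b))
    newd <- (ca$size * D[a, rest] + cb$size * D[b, rest]) / (ca$size + cb$size)
    D <- rbind(cbind(D[rest, rest, drop = FALSE], newd), c(newd, 0))
    clusters <- c(clusters[rest], list(merged))
  }
  structure(list(root = clusters[[1L]]$node, labels = sort(labels)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %s\n",
              length(x$labels), format_branch(x$root$height)))
  cat(" ", abbreviate_seq(to_newick(x), 70L), "\n")
  invisible(x)
}

format_branch <- function(x) {
  format(x, digits = 10L, scientific = FALSE, trim = TRUE)
}

#' Serialize an UPGMA tree to Newick
#'
#' Branch lengths are height differences between parent and child; children
#' are ordered by their smallest leaf label, and the string ends with a
#' semicolon, so the output is deterministic.
#'
#' @param t an [upgma] tree.
#' @return single Newick string.
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "upgma_tree"))
  node_str <- function(node, parent_height) {
    bl <- format_branch(parent_height - node$height)
    if (is.null(node$children))
      return(paste0(node$label, ":", bl))
    inner <- paste(vapply(node$children, node_str, "", node$height),
                   collapse = ",")
    paste0("(", inner, "):", bl)
  }
  root <- t$root
  if (is.null(root$children))  # degenerate single-leaf tree
    return(paste0(root$label, ";"))
  inner <- paste(vapply(root$children, node_str, "", root$height),
                 collapse = ",")
  paste0("(", inner, ");")
}

# leaf-label sets of every node (leaves included), depth-first
node_leafsets <- function(node) {
  if (is.null(node$children)) return(list(node$label))
  kids <- lapply(node$children, node_leafsets)
  own <- sort(unlist(lapply(kids, function(k) k[[1L]])))
  c(list(own), unlist(kids, recursive = FALSE))
}

# root-to-leaf path lengths (sum of branch lengths), named by leaf
leaf_depths <- function(t) {
  stopifnot(inherits(t, "upgma_tree"))
  out <- numeric(0)
  walk <- function(node, acc, parent_height) {
    acc <- acc + (parent_height - node$height)
    if (is.null(node$children)) {
      out[[node$label]] <<- acc
      return()
    }
    for (ch in node$children) walk(ch, acc, node$height)
  }
  walk(t$root, -0, t$root$height)  # root has no incoming branch
  out
}

#' Cluster purity of a tree against known family labels
#'
#' A family is "clean" when its leaves form a monophyletic subtree (a node
#' whose leaf set equals the family's leaf set; singletons are trivially
#' clean).  The misplaced set is the minimal set of leaves whose removal
#' makes every family monophyletic — computed exhaustively for up to 3
#' removals, then greedily.
#'
#' @param t an [upgma] tree.
#' @param families named character vector `label -> family`, or a data frame
#'   with columns `label` and `family`.  Every leaf must be assigned.
#' @return list with `clean_clusters` (families monophyletic in the intact
#'   tree), `misplaced` (character vector, possibly empty), `n_families`,
#'   and `family_clean` (named logical, intact tree).
#' @export
cluster_purity <- function(t, families) {
  stopifnot(inherits(t, "upgma_tree"))
  if (is.data.frame(families)) {
    fam <- as.character(families$family)
    names(fam) <- as.character(families$label)
  } else {
    fam <- as.character(families)
    names(fam) <- names(families)
  }
  leaves <- t$labels
  missing <- setdiff(leaves, names(fam))
  if (length(missing))
    stop(sprintf("unknown leaf label (no family assignment): %s",
                 missing[1L]))
  fam <- fam[leaves]
  members <- split(names(fam), fam)
  sets <- node_leafsets(t$root)
  sets <- lapply(sets, sort)

  clean_under <- function(S) {
    vapply(members, function(ml) {
      rest <- setdiff(ml, S)
      if (length(rest) <= 1L) return(TRUE)
      for (ns in sets) {
        if (setequal(setdiff(ns, S), rest)) return(TRUE)
      }
      FALSE
    }, TRUE)
  }

  intact <- clean_under(character(0))
  if (all(intact)) {
    return(list(clean_clusters = length(members), misplaced = character(0),
                n_families = length(members), family_clean = intact))
  }
  candidates <- sort(unlist(members[!intact], use.names = FALSE))
  misplaced <- NULL
  for (r in seq_len(min(3L, length(candidates)))) {
    if (choose(length(candidates), r) > 20000) break
    combos <- utils::combn(candidates, r, simplify = FALSE)
    for (S in combos) {
      if (all(clean_under(S))) { misplaced <- S; break }
    }
    if (!is.null(misplaced)) break
  }
  if (is.null(misplaced)) {
    # greedy fallback: repeatedly drop the leaf that fixes most families
    S <- character(0)
    pool <- candidates
    while (!all(clean_under(S)) && length(pool)) {
      gains <- vapply(pool, function(l) sum(clean_under(c(S, l))), 0)
      best <- pool[order(-gains, pool)][1L]
      S <- c(S, best)
      pool <- setdiff(pool, best)
    }
    misplaced <- S
  }
  list(clean_clusters = sum(intact), misplaced = misplaced,
       n_families = length(members), family_clean = intact)
}
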
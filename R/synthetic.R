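# run code under a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards; NULL seed = use the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a random valid RNA secondary structure
#'
#' The pairing layout is drawn first — repeatedly choosing two unpaired
#' positions at least `min_loop + 1` apart, non-crossing unless pseudoknots
#' are allowed — and bases are assigned afterwards: unpaired positions from
#' `gc_bias`, paired positions as canonical pair types A-U, G-C or G-U with
#' weights derived from `gc_bias`.  Generated structures therefore always
#' pass strict canonical-pair validation, and the realized paired fraction
#' is within 2/n of the target whenever the geometry permits.
#'
#' @param n sequence length (>= 1).
#' @param pair_fraction target proportion of paired positions in [0, 1].
#' @param allow_pseudoknots permit crossing pairs.
#' @param gc_bias positive base-composition weights, in order A, C, G, U.
#' @param min_loop minimum number of unpaired-or-other positions enclosed by
#'   a hairpin pair (default 3, the physical minimum hairpin loop).
#' @param seed integer making the draw fully reproducible; `NULL` uses the
#'   current RNG stream.  The global RNG state is never clobbered.
#' @param name label of the structure.
#' @return an [rna_structure].
#' @examples
#' random_structure(30, pair_fraction = 0.5, seed = 1)
#' @export
random_structure <- function(n, pair_fraction = 0.5, allow_pseudoknots = FALSE,
                             gc_bias = c(A = 1, C = 1, G = 1, U = 1),
                             min_loop = 3L, seed = NULL, name = "synthetic") {
  with_seed(seed,
    random_structure_impl(n, pair_fraction, allow_pseudoknots, gc_bias,
                          min_loop, name))
}

random_structure_impl <- function(n, pair_fraction, allow_pseudoknots,
                                  gc_bias, min_loop, name) {
  if (!(length(n) == 1L && n >= 1L)) stop("'n' must be a positive length")
  n <- as.integer(n)
  if (!(pair_fraction >= 0 && pair_fraction <= 1))
    stop("'pair_fraction' must lie in [0, 1]")
  if (length(gc_bias) != 4L || any(gc_bias <= 0))
    stop("'gc_bias' must be 4 positive weights (A, C, G, U)")
  m_target <- round(pair_fraction * n / 2)
  if (pair_fraction > 0 && n < min_loop + 2L)
    stop(sprintf("infeasible target: pair_fraction %.2f with n = %d",
                 pair_fraction, n))

  if (m_target > 0L && 2L * m_target + min_loop > n)
    stop(sprintf("infeasible target: %d pairs do not fit in n = %d with a %d-base minimum loop",
                 m_target, n, min_loop))
  pairs <- if (allow_pseudoknots)
    knotted_layout(n, m_target, min_loop)
  else
    nested_layout(1L, n, m_target, min_loop)
  m <- nrow(pairs)
  unpaired <- rep(TRUE, n)
  unpaired[as.vector(pairs)] <- FALSE
  if (m < m_target)
    warning(sprintf(
      "target pair_fraction %.3f not reachable; realized %.3f",
      pair_fraction, 2 * m / n))

  bases <- character(n)
  w <- as.numeric(gc_bias)
  bases[unpaired] <- sample(c("A", "C", "G", "U"), sum(unpaired),
                            replace = TRUE, prob = w)
  if (m > 0L) {
    # pair-type weights from the composition bias of the two partners
    tw <- c(AU = w[1L] * w[4L], GC = w[3L] * w[2L], GU = w[3L] * w[4L])
    types <- sample(names(tw), m, replace = TRUE, prob = tw)
    flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
    for (r in seq_len(m)) {
      duo <- strsplit(types[r], "", fixed = TRUE)[[1L]]
      if (flip[r]) duo <- rev(duo)
      bases[pairs[r, 1L]] <- duo[1L]
      bases[pairs[r, 2L]] <- duo[2L]
    }
  }
  rna_structure(paste(bases, collapse = ""), pairs, name = name)
}

# most pairs that fit in a contiguous stretch of L positions: a fully
# nested helix needs 2p + min_loop <= L
max_nested_pairs <- function(L, min_loop) {
  pmax(0L, (L - min_loop) %/% 2L)
}

# random non-crossing pair layout with exactly m pairs in [lo, hi].
# Recursively places the leftmost pair (i, j), then splits the remaining
# pairs between the inside (i, j) and the tail right of j; every random
# choice is made among count-feasible options, so the construction never
# dead-ends.
nested_layout <- function(lo, hi, m, min_loop) {
  if (m == 0L) return(matrix(integer(0), ncol = 2L))
  is <- lo:(hi - min_loop - 1L)
  is <- is[max_nested_pairs(hi - is + 1L, min_loop) >= m]
  i <- is[sample.int(length(is), 1L)]
  js <- (i + min_loop + 1L):hi
  feas <- max_nested_pairs(js - i - 1L, min_loop) +
    max_nested_pairs(hi - js, min_loop) >= m - 1L
  js <- js[feas]
  j <- js[sample.int(length(js), 1L)]
  max_in <- max_nested_pairs(j - i - 1L, min_loop)
  max_out <- max_nested_pairs(hi - j, min_loop)
  q_in_range <- max(0L, m - 1L - max_out):min(max_in, m - 1L)
  q_in <- q_in_range[sample.int(length(q_in_range), 1L)]
  rbind(c(i, j),
        nested_layout(i + 1L, j - 1L, q_in, min_loop),
        nested_layout(j + 1L, hi, m - 1L - q_in, min_loop))
}

# random (possibly crossing) layout: sample 2m positions, match the lower
# half to a random permutation of the upper half; min_loop violations are
# repaired by local re-draws
knotted_layout <- function(n, m, min_loop) {
  if (m == 0L) return(matrix(integer(0), ncol = 2L))
  for (attempt in seq_len(200L)) {
    pos <- sort(sample.int(n, 2L * m))
    lower <- pos[seq_len(m)]
    upper <- pos[(m + 1L):(2L * m)]
    partner <- upper[sample.int(m)]
    if (all(partner - lower > min_loop))
      return(cbind(lower, partner, deparse.level = 0L))
  }
  # deterministic fallback: sorted matching maximizes the minimum gap
  lower <- pos[seq_len(m)]
  upper <- pos[(m + 1L):(2L * m)]
  keep <- upper - lower > min_loop
  cbind(lower[keep], upper[keep], deparse.level = 0L)
}

#' Generate a family-structured synthetic dataset
#'
#' Emulates a multi-family non-coding RNA collection: one random ancestor
#' structure per family, each family member a point-mutated copy.  At each
#' position, independently with probability `divergence`, an event occurs:
#' an unpaired base is substituted by another base; a paired position either
#' loses its pair (both partners become unpaired, probability 1/2) or the
#' pair is re-drawn as another canonical pair type.
#'
#' Family identity is what real multi-family ncRNA collections carry most
#' strongly in length, stem content and base composition, so each family's
#' ancestor draws its own length from `n_range`, its own paired fraction
#' from `pair_fraction_range`, and its own composition bias; members then
#' share those family-level traits and differ by point mutations only
#' (no indels, so all members of a family have equal length).
#'
#' @param k_families number of families (>= 2).
#' @param per_family members per family.
#' @param divergence per-position mutation rate in [0, 1].
#' @param seed integer seed governing all randomness; `NULL` uses the
#'   current stream.
#' @param n_range inclusive range the per-family ancestor length is drawn
#'   from uniformly.
#' @param pair_fraction_range range the per-family target paired fraction is
#'   drawn from uniformly.
#' @param allow_pseudoknots permit crossing pairs in the ancestors.
#' @return list with `structures` (named list of [rna_structure]) and
#'   `families` (data frame with columns `label`, `family`).
#' @examples
#' fd <- family_dataset(3, 2, divergence = 0.05, seed = 1)
#' fd$families
#' @export
family_dataset <- function(k_families, per_family, divergence, seed = NULL,
                           n_range = c(60L, 200L),
                           pair_fraction_range = c(0.35, 0.65),
                           allow_pseudoknots = FALSE) {
  if (k_families < 2L) stop("'k_families' must be >= 2")
  if (per_family < 1L) stop("'per_family' must be >= 1")
  if (!(divergence >= 0 && divergence <= 1))
    stop("'divergence' must lie in [0, 1]")
  with_seed(seed, {
    structures <- list()
    labels <- character(0)
    fams <- character(0)
    for (f in seq_len(k_families)) {
      fam_name <- sprintf("F%02d", f)
      n <- sample(n_range[1L]:n_range[2L], 1L)
      pf <- stats::runif(1L, pair_fraction_range[1L], pair_fraction_range[2L])
      gc_bias <- stats::rgamma(4L, shape = 4, rate = 4)  # family composition
      ancestor <- random_structure_impl(n, pf, allow_pseudoknots,
                                        gc_bias, 3L, fam_name)
      for (mbr in seq_len(per_family)) {
        lab <- sprintf("%s_%02d", fam_name, mbr)
        s <- mutate_structure(ancestor, divergence)
        s$name <- lab
        structures[[lab]] <- s
        labels <- c(labels, lab)
        fams <- c(fams, fam_name)
      }
    }
    list(structures = structures,
         families = data.frame(label = labels, family = fams,
                               stringsAsFactors = FALSE))
  })
}

# point-mutate a structure at rate `divergence`; uses the current RNG stream
mutate_structure <- function(s, divergence) {
  n <- length(s$bases)
  bases <- s$bases
  pairs <- s$pairs
  hit <- which(stats::runif(n) < divergence)
  if (length(hit) == 0L) return(rna_structure(paste(bases, collapse = ""),
                                              pairs, name = s$name))
  paired_of <- integer(n)  # partner index or 0
  if (nrow(pairs)) {
    paired_of[pairs[, 1L]] <- pairs[, 2L]
    paired_of[pairs[, 2L]] <- pairs[, 1L]
  }
  drop_rows <- integer(0)
  for (i in hit) {
    j <- paired_of[i]
    if (j == 0L) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "U"), bases[i]), 1L)
    } else {
      row <- which((pairs[, 1L] == min(i, j)) & (pairs[, 2L] == max(i, j)))
      if (length(row) == 0L) next  # pair already dropped by partner's event
      if (stats::runif(1L) < 0.5) {
        drop_rows <- c(drop_rows, row)
        paired_of[c(i, j)] <- 0L
      } else {
        cur <- paste0(bases[min(i, j)], bases[max(i, j)])
        alt <- setdiff(CANONICAL_PAIRS, cur)
        duo <- strsplit(sample(alt, 1L), "", fixed = TRUE)[[1L]]
        bases[min(i, j)] <- duo[1L]
        bases[max(i, j)] <- duo[2L]
      }
    }
  }
  if (length(drop_rows)) pairs <- pairs[-unique(drop_rows), , drop = FALSE]
  rna_structure(paste(bases, collapse = ""), pairs, name = s$name)
}
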
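# Independent brute-force oracle for the 36D descriptor: a direct double
# loop over positions and the 36 defining restricted sums, sharing no code
# with the streaming implementation.
oracle_descriptor <- function(bases, paired) {
  n <- length(bases)
  dichotomies <- list(list(c("A", "C"), c("G", "U")),
                      list(c("A", "G"), c("C", "U")),
                      list(c("A", "U"), c("C", "G")))
  out <- numeric(0)
  for (k in 1:3) {
    pos <- dichotomies[[k]][[1]]
    for (j in 1:4) {
      set <- if (j %in% c(1, 3)) pos else dichotomies[[k]][[2]]
      want_paired <- j >= 3
      sx <- sy <- sz <- 0
      for (i in seq_len(n)) {
        if (bases[i] %in% set && paired[i] == want_paired) {
          t <- i / (n + 1)
          sx <- sx + if (paired[i]) -t else t
          sy <- sy + if (bases[i] %in% pos) sqrt(1 - t^2) else -sqrt(1 - t^2)
          z <- 0
          for (q in seq_len(i))
            if (bases[q] %in% set && paired[q] == want_paired) z <- z + 1
          sz <- sz + z
        }
      }
      out <- c(out, sx / n, sy / n, sz / n)
    }
  }
  out
}

# random characteristic sequence (paired flags free, as in the text dialect)
rand_cs <- function(n, p_paired = 0.4) {
  char_seq(sample(c("A", "C", "G", "U"), n, replace = TRUE),
           stats::runif(n) < p_paired)
}

# CT text for a structure, written independently of the package writers
ct_text_of <- function(s) {
  n <- length(s$bases)
  partner <- integer(n)
  if (nrow(s$pairs)) {
    partner[s$pairs[, 1]] <- s$pairs[, 2]
    partner[s$pairs[, 2]] <- s$pairs[, 1]
  }
  c(sprintf("%d %s", n, s$name),
    sprintf("%d %s %d %d %d %d", 1:n, s$bases, 0:(n - 1),
            c(2:n, 0), partner, 1:n))
}

# BPSEQ text for a structure
bpseq_text_of <- function(s) {
  n <- length(s$bases)
  partner <- integer(n)
  if (nrow(s$pairs)) {
    partner[s$pairs[, 1]] <- s$pairs[, 2]
    partner[s$pairs[, 2]] <- s$pairs[, 1]
  }
  sprintf("%d %s %d", 1:n, s$bases, partner)
}

# sorted canonical form of a pair matrix, for comparisons
pair_key <- function(pm) {
  if (nrow(pm) == 0) return(character(0))
  sort(sprintf("%d-%d", pm[, 1], pm[, 2]))
}

expect_same_structure <- function(a, b) {
  expect_identical(a$sequence, b$sequence)
  expect_identical(pair_key(a$pairs), pair_key(b$pairs))
}

# root-to-leaf path lengths of an upgma_tree, named by leaf
leaf_path_lengths <- function(t) {
  out <- numeric(0)
  walk <- function(node, acc) {
    if (is.null(node$children)) {
      out[[node$label]] <<- acc + node$height
      return()
    }
    for (ch in node$children)
      walk(ch, acc + (node$height - ch$height))
  }
  walk(t$root, 0)
  out
}
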
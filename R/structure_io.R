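#' RNA secondary structure container
#'
#' Holds a primary sequence over \{A, C, G, U\} together with a set of base
#' pairs given as 1-based position pairs (i, j), i < j.  `T` is silently
#' normalized to `U` and the sequence is case-folded to upper case.  Every
#' position may take part in at most one pair; crossing pairs (pseudoknots)
#' are allowed.
#'
#' @param sequence single string over A, C, G, U (T accepted and normalized).
#' @param pairs two-column matrix/data.frame of 1-based positions, or a list
#'   of length-2 vectors, or `NULL` for a fully unpaired structure.
#' @param name text label carried through all downstream operations.
#' @return an object of class `rna_structure` with fields `name`,
#'   `sequence`, `bases` (character vector) and `pairs` (m x 2 integer
#'   matrix, rows sorted, i < j).
#' @examples
#' rna_structure("GCAUGC", pairs = list(c(1, 6), c(2, 5)))
#' @export
rna_structure <- function(sequence, pairs = NULL, name = "") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single string")
  seq <- chartr("Tt", "Uu", sequence)
  seq <- toupper(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(bases)
  if (n < 1L) stop("sequence must have length >= 1")
  bad <- which(!bases %in% c("A", "C", "G", "U"))
  if (length(bad))
    stop(sprintf("illegal base '%s' at position %d", bases[bad[1L]], bad[1L]))
  pm <- normalize_pairs(pairs, n)
  structure(
    list(name = as.character(name)[1L],
         sequence = paste(bases, collapse = ""),
         bases = bases,
         pairs = pm),
    class = "rna_structure"
  )
}

# coerce pair input to a validated m x 2 integer matrix with i < j
normalize_pairs <- function(pairs, n) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (is.list(pairs) && length(pairs) == 0L)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, function(p) p[1:2]))
  if (!is.matrix(pairs) || ncol(pairs) != 2L)
    stop("'pairs' must be a two-column matrix or a list of (i, j) pairs")
  storage.mode(pairs) <- "integer"
  if (anyNA(pairs)) stop("NA in pairs")
  pm <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  if (any(pm[, 1L] == pm[, 2L]))
    stop("a position cannot pair with itself")
  if (any(pm < 1L) || any(pm > n))
    stop(sprintf("pair position out of range 1..%d", n))
  flat <- as.vector(pm)
  dup <- flat[duplicated(flat)]
  if (length(dup))
    stop(sprintf("position %d appears in more than one pair", dup[1L]))
  pm <- pm[order(pm[, 1L]), , drop = FALSE]
  dimnames(pm) <- list(NULL, c("i", "j"))
  pm
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %s  n=%d  pairs=%d\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$bases), nrow(x$pairs)))
  cat(" ", abbreviate_seq(x$sequence), "\n")
  invisible(x)
}

abbreviate_seq <- function(s, width = 60L) {
  if (nchar(s) <= width) s else paste0(substr(s, 1L, width - 3L), "...")
}

#' Logical vector of paired positions
#'
#' @param x an `rna_structure`.
#' @return logical vector of length n, `TRUE` where the position is in a pair.
#' @export
paired_positions <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  p <- logical(length(x$bases))
  p[as.vector(x$pairs)] <- TRUE
  p
}

# the canonical base pairings accepted by strict validation
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' List non-canonical base pairs of a structure
#'
#' A pair is canonical when the two bases form A-U, G-C or G-U (in either
#' orientation).
#'
#' @param x an `rna_structure`.
#' @return character vector of descriptions such as "A-A at (1,2)",
#'   zero-length when all pairs are canonical.
#' @export
noncanonical_pairs <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  if (nrow(x$pairs) == 0L) return(character(0))
  a <- x$bases[x$pairs[, 1L]]
  b <- x$bases[x$pairs[, 2L]]
  bad <- !(paste0(a, b) %in% CANONICAL_PAIRS)
  sprintf("%s-%s at (%d,%d)", a[bad], b[bad],
          x$pairs[bad, 1L], x$pairs[bad, 2L])
}

# ---------------------------------------------------------------------------
# dot-bracket parsing (extended bracket alphabet for pseudoknots)

BRACKET_OPEN  <- c("(", "[", "{", "<", LETTERS)
BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

# match one structure line into an m x 2 pair matrix; independent stack per
# bracket family so crossing pairs across families are accepted
match_brackets <- function(struct_chars) {
  nfam <- length(BRACKET_OPEN)
  stacks <- vector("list", nfam)
  pairs <- list()
  for (i in seq_along(struct_chars)) {
    ch <- struct_chars[i]
    if (ch == ".") next
    fo <- match(ch, BRACKET_OPEN)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], i)
      next
    }
    fc <- match(ch, BRACKET_CLOSE)
    if (!is.na(fc)) {
      st <- stacks[[fc]]
      if (length(st) == 0L)
        stop(sprintf("unbalanced bracket '%s' at position %d (no opener)",
                     ch, i))
      pairs[[length(pairs) + 1L]] <- c(st[length(st)], i)
      stacks[[fc]] <- st[-length(st)]
      next
    }
    stop(sprintf("illegal character '%s' at position %d in structure line",
                 ch, i))
  }
  left <- unlist(stacks)
  if (length(left))
    stop(sprintf("unbalanced bracket '%s' at position %d (never closed)",
                 struct_chars[min(left)], min(left)))
  if (length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L))
  do.call(rbind, pairs)
}

#' Parse one dot-bracket record
#'
#' A record is an optional `>` header line, a sequence line, and a structure
#' line of equal length over `.` plus the bracket families `()`, `[]`, `{}`,
#' `<>` and paired letters `Aa`-`Zz` (uppercase opens, lowercase closes).
#' Crossing pairs across bracket families — pseudoknots — are accepted.
#'
#' @param text single (possibly multi-line) string or character vector of
#'   lines holding exactly one record.
#' @param name label to use when no header line is present.
#' @return an [rna_structure].
#' @examples
#' parse_dot_bracket("GCAUGC\n((..))")
#' parse_dot_bracket("ACGUACGU\n([)]....")  # crossing pair, two families
#' @export
parse_dot_bracket <- function(text, name = "") {
  lines <- split_lines(text)
  recs <- dot_bracket_records(lines, default_name = name)
  if (length(recs) != 1L)
    stop(sprintf("expected exactly one dot-bracket record, found %d",
                 length(recs)))
  recs[[1L]]
}

# split a dot-bracket line stream into rna_structure records
dot_bracket_records <- function(lines, default_name = "") {
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  i <- 1L
  rec_no <- 0L
  while (i <= length(lines)) {
    nm <- default_name
    if (startsWith(lines[i], ">")) {
      nm <- trimws(sub("^>", "", lines[i]))
      i <- i + 1L
    }
    if (i + 1L > length(lines))
      stop("truncated dot-bracket record: need a sequence and a structure line")
    seq_line <- trimws(lines[i])
    str_line <- trimws(lines[i + 1L])
    i <- i + 2L
    rec_no <- rec_no + 1L
    if (nchar(seq_line) != nchar(str_line))
      stop(sprintf(
        "record %d: sequence length %d != structure length %d",
        rec_no, nchar(seq_line), nchar(str_line)))
    pm <- match_brackets(strsplit(str_line, "", fixed = TRUE)[[1L]])
    if (!nzchar(nm)) nm <- sprintf("record%d", rec_no)
    recs[[length(recs) + 1L]] <- rna_structure(seq_line, pm, name = nm)
  }
  recs
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text
}

# ---------------------------------------------------------------------------
# CT (Zuker connect) parsing

#' Parse one CT record
#'
#' Standard CT layout: a header line whose first token is the length n,
#' followed by n rows `index base prev next pair index`.  Pair column 0 means
#' unpaired; reciprocal consistency of the pair column is enforced.
#'
#' @param text single string or character vector of lines with one record.
#' @param name fallback label; the CT header title is used when present.
#' @return an [rna_structure].
#' @export
parse_ct <- function(text, name = "") {
  lines <- split_lines(text)
  out <- ct_records(lines, default_name = name)
  if (length(out) != 1L)
    stop(sprintf("expected exactly one CT record, found %d", length(out)))
  out[[1L]]
}

ct_records <- function(lines, default_name = "") {
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    head_tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    n <- suppressWarnings(as.integer(head_tok[1L]))
    if (is.na(n) || n < 1L)
      stop(sprintf("CT header line '%s' does not start with a length",
                   lines[i]))
    nm <- if (length(head_tok) > 1L)
      paste(head_tok[-1L], collapse = " ") else default_name
    if (i + n > length(lines))
      stop(sprintf("CT record declares %d rows but only %d lines remain",
                   n, length(lines) - i))
    rows <- lines[(i + 1L):(i + n)]
    i <- i + n + 1L
    tok <- lapply(rows, function(l) strsplit(trimws(l), "\\s+")[[1L]])
    if (any(vapply(tok, length, 0L) < 6L))
      stop("CT row with fewer than 6 columns")
    idx  <- vapply(tok, function(t) as.integer(t[1L]), 0L)
    base <- vapply(tok, function(t) t[2L], "")
    pair <- vapply(tok, function(t) as.integer(t[5L]), 0L)
    if (!identical(idx, seq_len(n)))
      stop("CT index column is not 1..n (row count != declared length?)")
    pm <- pairs_from_pair_column(pair, n, "CT")
    if (!nzchar(nm)) nm <- sprintf("record%d", length(recs) + 1L)
    recs[[length(recs) + 1L]] <-
      rna_structure(paste(base, collapse = ""), pm, name = nm)
  }
  recs
}

# shared by CT and BPSEQ: pair column -> pair matrix, reciprocity enforced
pairs_from_pair_column <- function(pair, n, what) {
  if (any(pair < 0L | pair > n))
    stop(sprintf("%s pair column value out of range 0..%d", what, n))
  for (i in seq_len(n)) {
    j <- pair[i]
    if (j != 0L && pair[j] != i)
      stop(sprintf("non-reciprocal pair: row %d says %d but row %d says %d",
                   i, j, j, pair[j]))
    if (j == i) stop(sprintf("%s row %d pairs with itself", what, i))
  }
  keep <- which(pair > seq_len(n))
  cbind(keep, pair[keep])
}

# ---------------------------------------------------------------------------
# BPSEQ parsing

#' Parse one BPSEQ record
#'
#' One `index base pair` triple per line, indices 1-based and consecutive,
#' pair 0 = unpaired.  Gaps or duplicates in the index column and
#' non-reciprocal pair columns are errors.
#'
#' @param text single string or character vector of lines with one record.
#' @param name label for the structure.
#' @return an [rna_structure].
#' @export
parse_bpseq <- function(text, name = "") {
  lines <- split_lines(text)
  out <- bpseq_records(lines, default_name = name)
  if (length(out) != 1L)
    stop(sprintf("expected exactly one BPSEQ record, found %d", length(out)))
  out[[1L]]
}

bpseq_records <- function(lines, default_name = "") {
  lines <- trimws(lines)
  # records are separated by blank lines or '>' headers; '#' lines skipped
  recs <- list()
  cur <- list()
  cur_name <- default_name
  flush <- function() {
    if (length(cur) == 0L) return()
    recs[[length(recs) + 1L]] <<- bpseq_one(cur, cur_name, length(recs) + 1L)
    cur <<- list()
    cur_name <<- default_name
  }
  for (l in lines) {
    if (!nzchar(l)) { flush(); next }
    if (startsWith(l, "#")) next
    if (startsWith(l, ">")) { flush(); cur_name <- trimws(sub("^>", "", l)); next }
    cur[[length(cur) + 1L]] <- l
  }
  flush()
  recs
}

bpseq_one <- function(rows, nm, rec_no) {
  tok <- lapply(rows, function(l) strsplit(l, "\\s+")[[1L]])
  if (any(vapply(tok, length, 0L) < 3L))
    stop("BPSEQ line with fewer than 3 columns")
  idx  <- vapply(tok, function(t) as.integer(t[1L]), 0L)
  base <- vapply(tok, function(t) t[2L], "")
  pair <- vapply(tok, function(t) as.integer(t[3L]), 0L)
  n <- length(idx)
  o <- order(idx)
  idx <- idx[o]; base <- base[o]; pair <- pair[o]
  if (anyDuplicated(idx))
    stop(sprintf("duplicate index %d in BPSEQ", idx[duplicated(idx)][1L]))
  if (!identical(idx, seq_len(n)))
    stop("gap in BPSEQ index column (indices must be 1..n)")
  pm <- pairs_from_pair_column(pair, n, "BPSEQ")
  if (!nzchar(nm)) nm <- sprintf("record%d", rec_no)
  rna_structure(paste(base, collapse = ""), pm, name = nm)
}

# ---------------------------------------------------------------------------
# characteristic sequences

#' Characteristic sequence of an RNA secondary structure
#'
#' An ordered sequence over the 8-letter alphabet \{A, G, C, U, A', G', C',
#' U'\}: the base letter of each position, primed when the position sits in a
#' base pair.  In text form the primed letters are written lowercase
#' (`a g c u`), so `"AuG"` means A unpaired, U paired, G unpaired.
#'
#' @param bases character vector over A, C, G, U.
#' @param paired logical vector of the same length; `TRUE` = in a base pair.
#' @param name text label.
#' @return an object of class `char_seq` with fields `name`, `bases`,
#'   `paired`.
#' @export
char_seq <- function(bases, paired, name = "") {
  if (length(bases) != length(paired) || length(bases) < 1L)
    stop("'bases' and 'paired' must have equal length >= 1")
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("bases must be A, C, G or U")
  if (anyNA(paired)) stop("NA in 'paired'")
  structure(list(name = as.character(name)[1L],
                 bases = as.character(bases),
                 paired = as.logical(paired)),
            class = "char_seq")
}

#' @export
length.char_seq <- function(x) length(x$bases)

#' @export
format.char_seq <- function(x, ...) {
  out <- x$bases
  out[x$paired] <- tolower(out[x$paired])
  paste(out, collapse = "")
}

#' @export
print.char_seq <- function(x, ...) {
  cat(sprintf("<char_seq> %s  n=%d  paired=%.3f\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x), mean(x$paired)))
  cat(" ", abbreviate_seq(format(x)), "\n")
  invisible(x)
}

#' Encode a secondary structure as a characteristic sequence
#'
#' Positions taking part in any base pair are primed (lowercase in text
#' form); base identity and order are preserved.  With `strict_pairs = TRUE`
#' any pair other than A-U, G-C, G-U is an error; by default such pairs
#' trigger a warning and the bases are still primed, because the encoding
#' only needs paired/unpaired status.
#'
#' @param x an [rna_structure].
#' @param strict_pairs reject non-canonical pairs instead of warning.
#' @return a [char_seq].
#' @examples
#' s <- parse_dot_bracket("GCAUGC\n((..))")
#' format(encode_structure(s))  # "gcAUgc"
#' @export
encode_structure <- function(x, strict_pairs = FALSE) {
  stopifnot(inherits(x, "rna_structure"))
  bad <- noncanonical_pairs(x)
  if (length(bad)) {
    msg <- paste0("non-canonical pair ", paste(bad, collapse = "; "))
    if (strict_pairs) stop(msg) else warning(msg)
  }
  char_seq(x$bases, paired_positions(x), name = x$name)
}

#' Parse / write the lowercase characteristic-sequence dialect
#'
#' `parse_char_seq()` reads a string over `A C G U a c g u` (lowercase =
#' paired); `write_char_seq()` is its inverse, so write-then-parse is the
#' identity.
#'
#' @param text single string over the 8-letter text alphabet.
#' @param name label for the sequence.
#' @return `parse_char_seq()` a [char_seq]; `write_char_seq()` a string.
#' @examples
#' format(parse_char_seq("AuG"))
#' write_char_seq(char_seq(c("G", "C", "A"), c(TRUE, TRUE, FALSE)))  # "gcA"
#' @export
parse_char_seq <- function(text, name = "") {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string")
  text <- chartr("Tt", "Uu", text)
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (length(ch) < 1L) stop("empty characteristic sequence")
  ok <- ch %in% c("A", "C", "G", "U", "a", "c", "g", "u")
  if (!all(ok))
    stop(sprintf("illegal character '%s' at position %d",
                 ch[!ok][1L], which(!ok)[1L]))
  char_seq(toupper(ch), ch %in% c("a", "c", "g", "u"), name = name)
}

#' @rdname parse_char_seq
#' @param cs a [char_seq].
#' @export
write_char_seq <- function(cs) {
  stopifnot(inherits(cs, "char_seq"))
  format(cs)
}

#' Coerce to a characteristic sequence
#'
#' @param x an [rna_structure] (encoded via [encode_structure]), a string in
#'   the lowercase dialect, or a [char_seq] (returned unchanged).
#' @param ... passed on to methods.
#' @return a [char_seq].
#' @export
as_char_seq <- function(x, ...) UseMethod("as_char_seq")

#' @export
as_char_seq.char_seq <- function(x, ...) x

#' @export
as_char_seq.rna_structure <- function(x, ...) encode_structure(x, ...)

#' @export
as_char_seq.character <- function(x, ...) parse_char_seq(x, ...)

# ---------------------------------------------------------------------------
# file-level readers / writers

#' Read a file of secondary structures or characteristic sequences
#'
#' All formats accept a stream of records; each record keeps its own name
#' (from `>` headers, CT header titles, or `record<k>` when anonymous).
#'
#' @param path file path (or a single string containing the file text).
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`, `"charseq"`.
#' @return a named list of [rna_structure] objects (or [char_seq] for
#'   `format = "charseq"`).
#' @export
read_structures <- function(path,
                            format = c("dotbracket", "ct", "bpseq", "charseq")) {
  format <- match.arg(format)
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else split_lines(path)
  recs <- switch(format,
    dotbracket = dot_bracket_records(lines),
    ct         = ct_records(lines),
    bpseq      = bpseq_records(lines),
    charseq    = char_seq_records(lines))
  names(recs) <- vapply(recs, function(r) r$name, "")
  recs
}

# characteristic-sequence text: FASTA-like with '>' headers, or one record
# per line
char_seq_records <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- list()
  if (any(startsWith(lines, ">"))) {
    i <- 1L
    while (i <= length(lines)) {
      if (!startsWith(lines[i], ">"))
        stop(sprintf("expected '>' header before sequence at line %d", i))
      nm <- trimws(sub("^>", "", lines[i]))
      i <- i + 1L
      seq_parts <- character(0)
      while (i <= length(lines) && !startsWith(lines[i], ">")) {
        seq_parts <- c(seq_parts, lines[i])
        i <- i + 1L
      }
      recs[[length(recs) + 1L]] <-
        parse_char_seq(paste(seq_parts, collapse = ""), name = nm)
    }
  } else {
    for (k in seq_along(lines))
      recs[[k]] <- parse_char_seq(lines[k], name = sprintf("record%d", k))
  }
  recs
}

#' Write characteristic sequences as FASTA-like text
#'
#' @param css list of [char_seq] objects.
#' @param path output file, or `NULL` to return the lines.
#' @return invisibly (or visibly, when `path` is `NULL`) the text lines.
#' @export
write_char_seqs <- function(css, path = NULL) {
  lines <- unlist(lapply(css, function(cs)
    c(paste0(">", cs$name), format(cs))))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write structures in dot-bracket notation
#'
#' Pseudoknotted structures are written with multiple bracket families:
#' each pair is assigned the first family in `() [] {} <> Aa..Zz` in which
#' it crosses no previously assigned pair.
#'
#' @param structures list of [rna_structure] objects (or a single one).
#' @param path output file, or `NULL` to return the lines.
#' @return invisibly (or visibly when `path` is `NULL`) the text lines.
#' @export
write_dot_bracket <- function(structures, path = NULL) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  lines <- unlist(lapply(structures, function(s)
    c(paste0(">", s$name), s$sequence, dot_bracket_string(s))))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

dot_bracket_string <- function(s) {
  n <- length(s$bases)
  out <- rep(".", n)
  pm <- s$pairs
  if (nrow(pm)) {
    fam_pairs <- vector("list", length(BRACKET_OPEN))
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1L]; j <- pm[r, 2L]
      placed <- FALSE
      for (f in seq_along(fam_pairs)) {
        fp <- fam_pairs[[f]]
        crosses <- FALSE
        if (length(fp)) {
          for (q in fp) {
            p1 <- q[1L]; q1 <- q[2L]
            if ((p1 < i && i < q1 && q1 < j) || (i < p1 && p1 < j && j < q1)) {
              crosses <- TRUE; break
            }
          }
        }
        if (!crosses) {
          fam_pairs[[f]] <- c(fp, list(c(i, j)))
          out[i] <- BRACKET_OPEN[f]
          out[j] <- BRACKET_CLOSE[f]
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("ran out of bracket families (pathological pseudoknot)")
    }
  }
  paste(out, collapse = "")
}
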
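test_that("dot-bracket parsing handles nesting, pseudoknots and errors", {
  expect_identical(pair_key(parse_dot_bracket("AU\n()")$pairs), "1-2")
  expect_identical(pair_key(parse_dot_bracket("GCAUGC\n((..))")$pairs),
                   c("1-6", "2-5"))
  # crossing pairs across bracket families are accepted
  pk <- parse_dot_bracket("ACGUACGU\n([)]....")
  expect_identical(pair_key(pk$pairs), c("1-3", "2-4"))
  # deep pseudoknot letter families Aa-Zz
  deep <- parse_dot_bracket("GGGGGCCCCC\n(A[.)a]...")
  expect_identical(pair_key(deep$pairs), c("1-5", "2-6", "3-7"))

  expect_error(parse_dot_bracket("AUG\n()"), "length")
  expect_error(parse_dot_bracket("AUGC\n(().") , "position 1 \\(never closed\\)")
  expect_error(parse_dot_bracket("AUGC\n())."), "position 3")
  expect_error(parse_dot_bracket("AUGC\n(|).") , "illegal character '\\|' at position 2")
  expect_error(parse_dot_bracket("AXGC\n(..)"), "illegal base 'X' at position 2")
})

test_that("sequence normalization: T -> U, case-folded upper", {
  s <- parse_dot_bracket("gcatgc\n((..))")
  expect_identical(s$sequence, "GCAUGC")
})

test_that("multi-record streams keep per-record names", {
  txt <- c(">one", "AU", "()", ">two", "GCAUGC", "((..))")
  recs <- read_structures(paste(txt, collapse = "\n"), "dotbracket")
  expect_named(recs, c("one", "two"))
  expect_identical(recs$two$sequence, "GCAUGC")
})

test_that("CT parsing enforces layout and reciprocity", {
  ct2 <- c("2 tiny", "1 A 0 2 2 1", "2 U 1 0 1 2")
  expect_identical(pair_key(parse_ct(ct2)$pairs), "1-2")
  bad <- c("2 tiny", "1 A 0 2 2 1", "2 U 1 0 0 2")
  expect_error(parse_ct(bad), "non-reciprocal pair")
  short <- c("3 tiny", "1 A 0 2 0 1", "2 U 1 0 0 2")
  expect_error(parse_ct(short), "3 rows")

  s <- rna_structure("GCAUGC", list(c(1, 6), c(2, 5)), name = "hand")
  expect_same_structure(parse_ct(ct_text_of(s)), s)
})

test_that("BPSEQ parsing: unpaired, crossing pairs, index errors", {
  expect_identical(pair_key(parse_bpseq(c("1 A 2", "2 U 1"))$pairs), "1-2")
  expect_identical(nrow(parse_bpseq("1 A 0")$pairs), 0L)
  crossing <- c("1 A 3", "2 G 4", "3 U 1", "4 C 2")
  expect_identical(pair_key(parse_bpseq(crossing)$pairs), c("1-3", "2-4"))
  expect_error(parse_bpseq(c("1 A 0", "1 U 0")), "duplicate index")
  expect_error(parse_bpseq(c("1 A 0", "3 U 0")), "gap")
  expect_error(parse_bpseq(c("1 A 2", "2 U 0")), "non-reciprocal")
})

test_that("the three parsers agree on equivalent fixtures", {
  for (seed in 1:5) {
    s <- random_structure(40, 0.5, allow_pseudoknots = seed %% 2 == 0,
                          seed = seed)
    from_db <- parse_dot_bracket(paste(write_dot_bracket(s)[-1],
                                       collapse = "\n"))
    from_ct <- parse_ct(ct_text_of(s))
    from_bp <- parse_bpseq(bpseq_text_of(s))
    expect_same_structure(from_db, s)
    expect_same_structure(from_ct, s)
    expect_same_structure(from_bp, s)
  }
})

test_that("encoding primes exactly the paired positions", {
  expect_identical(format(encode_structure(
    rna_structure("AU", list(c(1, 2))))), "au")
  expect_identical(format(encode_structure(
    rna_structure("GCAUGC", list(c(1, 6), c(2, 5))))), "gcAUgc")
  # strict mode rejects non-canonical pairs; default warns and keeps
  aa <- rna_structure("AA", list(c(1, 2)))
  expect_error(encode_structure(aa, strict_pairs = TRUE),
               "non-canonical pair A-A at \\(1,2\\)")
  expect_warning(cs <- encode_structure(aa), "non-canonical")
  expect_true(all(cs$paired))
})

test_that("characteristic-sequence dialect parses and round-trips", {
  cs <- parse_char_seq("AuG")
  expect_identical(cs$bases, c("A", "U", "G"))
  expect_identical(cs$paired, c(FALSE, TRUE, FALSE))
  expect_identical(write_char_seq(char_seq(c("G", "C", "A"),
                                           c(TRUE, TRUE, FALSE))), "gcA")
  expect_error(parse_char_seq("AxG"), "illegal character 'x' at position 2")

  set.seed(42)
  for (rep in 1:1000) {
    cs <- rand_cs(sample(1:60, 1))
    expect_identical(format(parse_char_seq(write_char_seq(cs))), format(cs))
  }
})

test_that("encoding invariants hold on fuzzed valid structures", {
  set.seed(7)
  for (rep in 1:50) {
    s <- random_structure(sample(5:80, 1), stats::runif(1, 0, 0.8),
                          allow_pseudoknots = rep %% 2 == 0)
    cs <- encode_structure(s)
    # unpriming recovers the input sequence exactly
    expect_identical(paste(cs$bases, collapse = ""), s$sequence)
    # each pair primes exactly two positions
    expect_identical(sum(cs$paired), 2L * nrow(s$pairs))
  }
})

test_that("structure validation rejects malformed pair sets", {
  expect_error(rna_structure("AUGC", list(c(1, 2), c(2, 3))),
               "more than one pair")
  expect_error(rna_structure("AUGC", list(c(0, 2))), "out of range")
  expect_error(rna_structure("AUGC", list(c(2, 2))), "itself")
})

test_that("characteristic files read FASTA-like and bare-line layouts", {
  f <- withr::local_tempfile(fileext = ".txt")
  css <- list(char_seq(c("A", "U"), c(TRUE, TRUE), name = "x"),
              char_seq(c("G", "C", "A"), c(TRUE, TRUE, FALSE), name = "y"))
  write_char_seqs(css, f)
  back <- read_structures(f, "charseq")
  expect_named(back, c("x", "y"))
  expect_identical(format(back$y), "gcA")
  bare <- read_structures("au\ngcA", "charseq")
  expect_identical(format(bare[[2]]), "gcA")
})
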
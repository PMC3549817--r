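test_that("parse_dotbracket handles nested, pseudoknotted and malformed input", {
  s <- parse_dotbracket("((...))")
  expect_equal(s$pairs, cbind(c(1L, 2L), c(7L, 6L)), ignore_attr = TRUE)
  expect_equal(s$pk_order, c(0L, 0L))

  s <- parse_dotbracket("((..AA..))..aa")
  expect_equal(s$pairs, cbind(c(1L, 2L, 5L, 6L), c(10L, 9L, 14L, 13L)),
               ignore_attr = TRUE)
  expect_equal(s$pk_order, c(0L, 0L, 1L, 1L))
  # the letter pairs really cross an order-0 pair (i < i' < j < j')
  expect_true(crosses(c(2, 9), c(5, 14)))

  expect_error(parse_dotbracket("((."), "unbalanced '\\(' at position 1")
  expect_error(parse_dotbracket("..)"), "unbalanced '\\)' at position 3")
  expect_error(parse_dotbracket("(!)"), "illegal character '!' at position 2")
  expect_error(parse_dotbracket("AA..BB..aa"), "unbalanced 'B'")
})

test_that("bracket dialects map to crossing classes by first appearance", {
  s <- parse_dotbracket("((.[[.))..]]")
  expect_equal(sort(unique(s$pk_order)), c(0L, 1L))
  # output always uses the letter dialect
  expect_equal(write_dotbracket(s), "((.AA.))..aa")
  # three auxiliary dialects -> three distinct classes
  s3 <- parse_dotbracket("(.[.{.<.).].}.>")
  expect_equal(sort(unique(s3$pk_order)), 0:3)
})

test_that("write_dotbracket inverts parse_dotbracket", {
  expect_equal(write_dotbracket(rna_structure(7, cbind(c(1, 2), c(7, 6)),
                                              pk_order = c(0L, 0L))),
               "((...))")
  expect_equal(write_dotbracket(parse_dotbracket("((..AA..))..aa")),
               "((..AA..))..aa")
  expect_equal(write_dotbracket(rna_structure(4)), "....")
})

test_that("parse/write round-trips are identities on random structures", {
  set.seed(101)
  for (t in 1:60) {
    s <- rand_structure(sample(8:40, 1))
    s2 <- parse_dotbracket(write_dotbracket(s))
    expect_equal(s2$pairs, s$pairs)
    expect_equal(s2$pk_order, s$pk_order)
    txt <- write_dotbracket(s)
    expect_identical(write_dotbracket(parse_dotbracket(txt)), txt)
  }
})

test_that("annotate_crossing finds a maximum non-crossing page", {
  a <- annotate_crossing(rbind(c(1, 7), c(2, 6)), 7)
  expect_equal(a$pk_order, c(0L, 0L))

  a <- annotate_crossing(rbind(c(1, 10), c(2, 9), c(5, 14), c(6, 13)), 14)
  expect_equal(a$pk_order, c(0L, 0L, 1L, 1L)) # 5'-most pair wins the tie

  a <- annotate_crossing(NULL, 9)
  expect_equal(nrow(a$pairs), 0L)
  expect_equal(a$length, 9L)

  expect_error(annotate_crossing(rbind(c(1, 5), c(5, 9)), 9), "two pairs")
})

test_that("annotate_crossing output is a valid, minimal order assignment", {
  set.seed(202)
  for (t in 1:40) {
    s <- rand_structure(sample(10:50, 1))
    np <- nrow(s$pairs)
    if (np < 2) next
    for (r in seq_len(np)) {
      for (r2 in seq_len(np)) {
        if (r == r2) next
        same_order <- s$pk_order[r] == s$pk_order[r2]
        if (same_order && s$pk_order[r] == 0L) {
          expect_false(crosses(s$pairs[r, ], s$pairs[r2, ]))
        }
      }
      # no pair of order k >= 1 could be re-assigned to a lower order
      k <- s$pk_order[r]
      if (k >= 1L) {
        for (lower in 0:(k - 1L)) {
          members <- which(s$pk_order == lower)
          members <- members[members != r]
          expect_true(any(vapply(members, function(m) {
            crosses(s$pairs[r, ], s$pairs[m, ])
          }, logical(1))))
        }
      }
    }
  }
})

test_that("pseudoknot-free pair sets get order 0 everywhere", {
  set.seed(303)
  for (t in 1:20) {
    L <- sample(10:40, 1)
    # nested pairs only
    k <- sample(1:(L %/% 4), 1)
    pairs <- cbind(seq_len(k), L - seq_len(k) + 1L)
    a <- annotate_crossing(pairs, L)
    expect_true(all(a$pk_order == 0L))
  }
})

test_that("ensemble files round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".ens")
  e <- rna_ensemble("r1", "GGGAAACCCAAA", list(
    list(structure = parse_dotbracket("(((...)))..."), energy = -8.5),
    list(structure = parse_dotbracket("............"), energy = -10.0)
  ))
  # entries are sorted by energy: MFE first
  expect_equal(e$structures[[1]]$energy, -10.0)
  expect_equal(vapply(e$structures, function(s) s$rank, integer(1)), 1:2)

  write_ensembles(list(e), path)
  back <- read_ensembles(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$id, "r1")
  expect_equal(back[[1]]$seq, "GGGAAACCCAAA")
  expect_equal(vapply(back[[1]]$structures, function(s) s$energy, numeric(1)),
               c(-10.0, -8.5))

  # 20 random ensembles -> identical object graph after write/read
  set.seed(404)
  ens <- lapply(1:20, function(i) {
    L <- sample(12:30, 1)
    nt <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    entries <- lapply(1:sample(1:4, 1), function(k) {
      list(structure = rand_structure(L), energy = round(-runif(1, 1, 20), 4))
    })
    rna_ensemble(paste0("e", i), nt, entries)
  })
  p2 <- withr::local_tempfile(fileext = ".ens")
  write_ensembles(ens, p2)
  back <- read_ensembles(p2)
  expect_equal(back, ens)

  # malformed records
  p3 <- withr::local_tempfile(fileext = ".ens")
  writeLines(c(">bad", "GGGAAACCC", "(((...)))...\t-1.0"), p3)
  expect_error(read_ensembles(p3), "structure line 1.*length")
  writeLines(c(">bad2", "GGGAAACCC", "(((...)))\tabc"), p3)
  expect_error(read_ensembles(p3), "malformed energy")
})

test_that("FASTA round-trips through Biostrings wrappers", {
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(a = "GGGAAACCC", b = "ACGUACGUNN") # IUPAC codes pass through
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
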
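test_that("two sequences with one candidate each merge once", {
  hp <- parse_dotbracket("((((...))))...")
  e1 <- rna_ensemble("a", "GGGGAAACCCCAAA", list(list(structure = hp, energy = -8)))
  e2 <- rna_ensemble("b", "GCGCAAAGCGCAAA", list(list(structure = hp, energy = -7)))
  reps <- select_representatives("[]", list(e1, e2))
  expect_setequal(names(reps$representatives), c("a", "b"))
  expect_length(reps$tree$merges, 1L)
  expect_equal(reps$covered, c("a", "b"))
})

test_that("the engineered unique-maximum pair is selected", {
  ens <- engineered_two_seq_family()
  reps <- select_representatives("[]", ens)
  # brute force over the 4 cross-sequence candidate pairs
  cand <- list()
  for (e in ens) {
    for (st in e$structures) {
      cand[[length(cand) + 1L]] <- list(id = e$id, gs = gs_encode(e$seq, st$structure))
    }
  }
  best <- -Inf; best_pair <- NULL
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i < j && cand[[i]]$id != cand[[j]]$id) {
        s <- gs_align(cand[[i]]$gs, cand[[j]]$gs)$normalized
        if (s > best) { best <- s; best_pair <- c(i, j) }
      }
    }
  }
  picked <- vapply(names(reps$representatives), function(id) {
    write_dotbracket(reps$representatives[[id]]$structure)
  }, character(1))
  expected <- vapply(best_pair, function(k) write_dotbracket(cand[[k]]$gs$structure),
                     character(1))
  expect_setequal(unname(picked), expected)
  expect_equal(reps$tree$merges[[1]]$similarity, best)
})

test_that("constrained clustering keeps one structure per sequence", {
  set.seed(71)
  for (trial in 1:5) {
    fam <- generate_family(family_spec(n = 3, decoys = 2, seed = 700 + trial))
    # give every sequence 2 candidates of the planted shape by duplicating the
    # planted structure with a light variant
    ens <- lapply(fam$ensembles, function(e) {
      planted <- e$structures[[1]]
      variant_pairs <- planted$structure$pairs[-1, , drop = FALSE]
      variant <- annotate_crossing(variant_pairs, planted$structure$length)
      entries <- c(e$structures,
                   list(list(structure = variant, energy = planted$energy + 0.01)))
      rna_ensemble(e$id, e$seq, lapply(entries, function(x) {
        list(structure = x$structure, energy = x$energy)
      }))
    })
    shape <- fam$shape
    keep <- vapply(ens[[1]]$structures, function(st) {
      shape_of(st$structure, 5) == shape
    }, logical(1))
    if (sum(keep) < 2) next # variant changed the shape; try the next family
    reps <- select_representatives(shape, ens)

    # exactly one representative per covered sequence
    expect_setequal(names(reps$representatives), reps$covered)
    expect_equal(anyDuplicated(names(reps$representatives)), 0L)

    # no cluster in the merge history mixes two structures of one sequence
    for (mg in reps$tree$merges) {
      ids <- reps$tree$leaves$id[c(mg$a, mg$b)]
      expect_equal(anyDuplicated(ids), 0L)
    }

    # first merge joins the globally most-similar cross-sequence pair
    sim <- reps$similarity
    expect_equal(reps$tree$merges[[1]]$similarity, max(sim[is.finite(sim)]))
  }
})

test_that("progressive alignment honours the guide tree and ungaps cleanly", {
  hp <- parse_dotbracket("((((...))))...")
  e1 <- rna_ensemble("a", "GGGGAAACCCCAAA", list(list(structure = hp, energy = -8)))
  e2 <- rna_ensemble("b", "GGGGAAACCCCAAA", list(list(structure = hp, energy = -7)))
  reps <- select_representatives("[]", list(e1, e2))
  aln <- progressive_align(reps)
  # identical representatives align with zero gaps
  expect_equal(ncol(aln$idx), 14L)
  expect_true(all(aln$idx != 0L))

  # rows always ungap to their original grammar strings
  fam <- generate_family(family_spec(n = 5, seed = 44))
  reps <- select_representatives(fam$shape, fam$ensembles)
  aln <- progressive_align(reps)
  expect_gte(ncol(aln$idx), max(vapply(aln$gs, function(g) length(g$nt), integer(1))))
  for (r in seq_len(nrow(aln$idx))) {
    row <- aln$idx[r, ]
    expect_equal(row[row != 0L], seq_along(aln$gs[[r]]$nt))
  }
})

test_that("consensus derivation counts support and resolves conflicts", {
  # all rows identical: consensus equals the structure, all supports 1
  hp <- parse_dotbracket("((((...))))...")
  ens <- lapply(c("a", "b", "c"), function(id) {
    rna_ensemble(id, "GGGGAAACCCCAAA", list(list(structure = hp, energy = -8)))
  })
  reps <- select_representatives("[]", ens)
  aln <- progressive_align(reps)
  cons <- derive_consensus(aln)
  expect_equal(cons$consensus$pairs, hp$pairs)
  expect_true(all(cons$support$support == 1))
  for (id in c("a", "b", "c")) {
    expect_equal(cons$structures[[id]]$pairs, hp$pairs)
  }

  # 3 rows, pair (2,9) in 2 rows beats (2,8) in 1 row
  s29 <- rna_structure(10, rbind(c(2, 9)), pk_order = 0L)
  s28 <- rna_structure(10, rbind(c(2, 8)), pk_order = 0L)
  ens <- list(
    rna_ensemble("a", "GGGGAAACCC", list(list(structure = s29, energy = -3))),
    rna_ensemble("b", "GGGGAAACCC", list(list(structure = s29, energy = -3))),
    rna_ensemble("c", "GGGGAAACCC", list(list(structure = s28, energy = -3)))
  )
  reps <- select_representatives("[]", ens)
  aln <- progressive_align(reps)
  cons <- derive_consensus(aln)
  expect_equal(cons$consensus$pairs, rbind(c(2L, 9L)), ignore_attr = TRUE)
  expect_equal(cons$support$support, 2 / 3)

  # threshold 1.0 keeps only unanimous pairs (the intersection)
  cons1 <- derive_consensus(aln, support_threshold = 0.999)
  expect_equal(nrow(cons1$consensus$pairs), 0L)
})

test_that("knotstructure recovers a planted family end to end", {
  fam <- generate_family(family_spec(seed = 7))
  res <- knotstructure(fam$ensembles)
  expect_equal(res$shape, fam$shape)
  expect_length(res$unpredicted, 0L)
  ev <- eval_structures(res$structures, fam$truth)
  expect_gte(ev$sensitivity[ev$id == "mean"], 0.8)

  # per-sequence outputs are valid structures in the Rfam dialect
  for (st in res$structures) {
    rt <- parse_dotbracket(write_dotbracket(st))
    expect_equal(rt$pairs, st$pairs)
  }
})

test_that("identical inputs and seed give byte-identical outputs", {
  fam <- generate_family(family_spec(seed = 13))
  out1 <- withr::local_tempfile(fileext = ".db")
  out2 <- withr::local_tempfile(fileext = ".db")
  r1 <- knotstructure(fam$ensembles)
  r2 <- knotstructure(fam$ensembles)
  write_structures(r1, fam$ensembles, out1)
  write_structures(r2, fam$ensembles, out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(r1$ranking$sc, r2$ranking$sc)
  expect_identical(guide_tree_newick(r1$tree), guide_tree_newick(r2$tree))
})
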
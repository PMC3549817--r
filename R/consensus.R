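## Consensus structure prediction inside a predicted shape class
## (KnotStructure): one representative structure per sequence is selected by
## constrained agglomerative (UPGMA-style, mean-linkage on similarities)
## clustering of grammar strings, the representatives are progressively
## aligned along the clustering path, and the consensus pairs are read off
## the alignment columns by majority support.

## candidate structures of one shape: list of grammar strings plus metadata
shape_candidates <- function(shape, ensembles, level, max_subopt) {
  gs <- list()
  meta_id <- character(0); meta_rank <- integer(0)
  for (e in ensembles) {
    sts <- utils::head(e$structures, max_subopt + 1L)
    for (st in sts) {
      if (shape_of(st$structure, level) == shape) {
        gs[[length(gs) + 1L]] <- gs_encode(e$seq, st$structure, e$id, st$rank)
        meta_id <- c(meta_id, e$id)
        meta_rank <- c(meta_rank, st$rank)
      }
    }
  }
  list(gs = gs, id = meta_id, rank = meta_rank)
}

#' Select one representative structure per sequence
#'
#' Implements the constrained hierarchical clustering: every candidate
#' structure with the given shape starts as a singleton cluster; pairwise
#' similarities are normalized grammar-string alignment scores, with pairs of
#' structures from the same sequence fixed at -Inf; cluster-to-cluster
#' similarity is the arithmetic mean of member pairwise similarities (UPGMA on
#' similarities). The pair of clusters with the highest similarity is merged
#' repeatedly, and whenever a structure of sequence X enters the merged
#' cluster all other candidates of X are removed from play. Clustering stops
#' when one cluster holds exactly one structure for every sequence that folds
#' into the shape. Ties are broken by the lexicographically smallest
#' (sequence id, rank) member, so the procedure is deterministic.
#'
#' @param shape the predicted shape string.
#' @param ensembles list of \code{\link{rna_ensemble}} objects.
#' @param level abstraction level at which candidates must match \code{shape}.
#' @param scoring grammar-string scoring scheme.
#' @param max_subopt candidate pool cap per sequence (optimal + this many
#'   suboptimal structures).
#' @return list with \code{representatives} (one \code{grammar_string} per
#'   covered sequence, named by sequence id), \code{tree} (the guide tree: a
#'   list with \code{leaves} -- data frame of candidate id/rank -- and
#'   \code{merges}, each merge holding the member candidate indices of both
#'   clusters and their similarity), \code{similarity} (the full candidate
#'   similarity matrix) and \code{covered} (sequence ids in the shape class).
#' @export
select_representatives <- function(shape, ensembles, level = 5,
                                   scoring = gs_scoring(), max_subopt = 10) {
  cand <- shape_candidates(shape, ensembles, level, max_subopt)
  n <- length(cand$gs)
  if (n == 0L) stop("no structure folds into shape '", shape, "'")
  covered <- unique(cand$id)
  leaves <- data.frame(id = cand$id, rank = cand$rank,
                       stringsAsFactors = FALSE)

  ## deterministic tie-break key: position in (sequence id, rank) order
  key <- order(order(cand$id, cand$rank))

  if (length(covered) == 1L) {
    best <- which.min(cand$rank)
    reps <- cand$gs[best]
    names(reps) <- cand$id[best]
    return(list(representatives = reps,
                tree = list(leaves = leaves, merges = list(),
                            members = best),
                similarity = matrix(if (n == 1L) numeric(0) else -Inf, n, n),
                covered = covered))
  }

  sim <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (cand$id[i] != cand$id[j]) {
        sim[i, j] <- sim[j, i] <- gs_align(cand$gs[[i]], cand$gs[[j]],
                                           scoring)$normalized
      }
    }
  }

  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  merges <- list()
  repeat {
    nc <- length(clusters)
    best <- NULL; best_sim <- -Inf
    for (a in seq_len(nc - 1L)) {
      for (b in seq(a + 1L, nc)) {
        s <- mean(sim[clusters[[a]], clusters[[b]]])
        if (s > best_sim ||
            (s == best_sim && !is.null(best) &&
             cluster_pair_key(clusters, c(a, b), key) <
             cluster_pair_key(clusters, best, key))) {
          best <- c(a, b); best_sim <- s
        }
      }
    }
    if (is.null(best) || !is.finite(best_sim)) {
      stop("clustering stalled: no mergeable cluster pair")
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    merges[[length(merges) + 1L]] <- list(a = clusters[[best[1L]]],
                                          b = clusters[[best[2L]]],
                                          similarity = best_sim)
    ## constraint: once a structure of sequence X is in, all other candidates
    ## of X leave the pool
    drop_cand <- which(active & cand$id %in% cand$id[merged])
    drop_cand <- setdiff(drop_cand, merged)
    active[drop_cand] <- FALSE
    clusters <- clusters[-best]
    clusters <- lapply(clusters, function(m) setdiff(m, drop_cand))
    clusters <- clusters[lengths(clusters) > 0L]
    clusters[[length(clusters) + 1L]] <- merged
    if (length(merged) == length(covered)) break
  }
  final <- clusters[[length(clusters)]]
  reps <- cand$gs[final]
  names(reps) <- cand$id[final]
  list(representatives = reps,
       tree = list(leaves = leaves, merges = merges, members = final),
       similarity = sim, covered = covered)
}

cluster_pair_key <- function(clusters, pair, key) {
  k <- sort(c(min(key[clusters[[pair[1L]]]]), min(key[clusters[[pair[2L]]]])))
  k[1L] * (length(key) + 1L) + k[2L]
}

## mean column-score matrix between two profiles (sum over row pairs);
## a gap in one member scores the gap penalty, two gaps score 0
profile_score_matrix <- function(pa, pb, gs, scoring) {
  na <- ncol(pa$idx); nb <- ncol(pb$idx)
  S <- matrix(0, na, nb)
  for (r in seq_len(nrow(pa$idx))) {
    ga <- gs[[pa$members[r]]]
    ia <- pa$idx[r, ]
    role_a <- ifelse(ia == 0L, NA_integer_, ga$role[pmax(ia, 1L)])
    nt_a <- ifelse(ia == 0L, NA_character_, ga$nt[pmax(ia, 1L)])
    for (s in seq_len(nrow(pb$idx))) {
      gb <- gs[[pb$members[s]]]
      ib <- pb$idx[s, ]
      role_b <- ifelse(ib == 0L, NA_integer_, gb$role[pmax(ib, 1L)])
      nt_b <- ifelse(ib == 0L, NA_character_, gb$nt[pmax(ib, 1L)])
      role_eq <- outer(role_a, role_b, "==")
      nt_eq <- outer(nt_a, nt_b, "==")
      cell <- matrix(scoring$mismatch, na, nb)
      cell[which(role_eq)] <- scoring$match_role
      cell[which(role_eq & nt_eq)] <- scoring$match_both
      gap_a <- is.na(role_a); gap_b <- is.na(role_b)
      cell[gap_a, ] <- scoring$gap
      cell[, gap_b] <- scoring$gap
      cell[gap_a, gap_b] <- 0
      S <- S + cell
    }
  }
  S / (nrow(pa$idx) * nrow(pb$idx))
}

#' Progressive alignment of representative structures
#'
#' Aligns the representative grammar strings profile-to-profile in the order
#' of the guide tree's merges. Profile columns are scored by the mean pairwise
#' grammar-string score over member rows (gap vs symbol scores the gap
#' penalty); gaps inserted into a profile propagate to all its members.
#'
#' @param reps representatives as returned by
#'   \code{\link{select_representatives}} (its \code{representatives},
#'   \code{tree} elements are used).
#' @param scoring grammar-string scoring scheme.
#' @return an object of class \code{structure_alignment}: \code{ids} (sequence
#'   id per row), \code{gs} (the grammar strings, one per row) and \code{idx}
#'   (rows x alignment-columns matrix of symbol indices, 0 = gap). Removing
#'   the zeros of a row recovers 1..L(row): each row ungaps to its original
#'   grammar string.
#' @export
progressive_align <- function(reps, scoring = gs_scoring()) {
  tree <- reps$tree
  members <- tree$members
  gs_all <- vector("list", nrow(tree$leaves))
  for (k in seq_along(members)) {
    gs_all[[members[k]]] <- reps$representatives[[k]]
  }
  if (length(members) < 2L) stop("need at least 2 representatives")

  profiles <- list()
  prof_key <- function(m) paste(sort(m), collapse = ",")
  for (m in members) {
    profiles[[prof_key(m)]] <- list(
      members = m,
      idx = matrix(seq_along(gs_all[[m]]$role), nrow = 1L)
    )
  }
  for (mg in tree$merges) {
    ka <- prof_key(mg$a); kb <- prof_key(mg$b)
    pa <- profiles[[ka]]; pb <- profiles[[kb]]
    if (is.null(pa) || is.null(pb)) stop("guide tree references unknown cluster")
    S <- profile_score_matrix(pa, pb, gs_all, scoring)
    res <- nw_align_cpp(S, scoring$gap)
    ncols <- length(res$a_idx)
    new_idx <- matrix(0L, nrow = nrow(pa$idx) + nrow(pb$idx), ncol = ncols)
    for (r in seq_len(nrow(pa$idx))) {
      new_idx[r, res$a_idx != 0L] <- pa$idx[r, res$a_idx[res$a_idx != 0L]]
    }
    for (s in seq_len(nrow(pb$idx))) {
      new_idx[nrow(pa$idx) + s, res$b_idx != 0L] <-
        pb$idx[s, res$b_idx[res$b_idx != 0L]]
    }
    profiles[[ka]] <- NULL; profiles[[kb]] <- NULL
    profiles[[prof_key(c(mg$a, mg$b))]] <-
      list(members = c(pa$members, pb$members), idx = new_idx)
  }
  if (length(profiles) != 1L) stop("guide tree did not reduce to one profile")
  prof <- profiles[[1L]]
  ids <- vapply(prof$members, function(m) gs_all[[m]]$source$id, character(1))
  structure(
    list(ids = ids, gs = gs_all[prof$members], idx = prof$idx),
    class = "structure_alignment"
  )
}

#' @export
print.structure_alignment <- function(x, ...) {
  cat(sprintf("<structure_alignment> %d rows x %d columns\n",
              nrow(x$idx), ncol(x$idx)))
  for (r in seq_len(nrow(x$idx))) {
    row <- ifelse(x$idx[r, ] == 0L, "-", x$gs[[r]]$nt[pmax(x$idx[r, ], 1L)])
    cat(sprintf("  %-12s %s\n", x$ids[r], paste(row, collapse = "")))
  }
  invisible(x)
}

#' Derive the consensus structure from a structure alignment
#'
#' For every pair of alignment columns (p, q) the support is the fraction of
#' rows whose structure pairs p with q. Pairs with support strictly above the
#' threshold are kept; a column claimed by two kept pairs goes to the pair
#' with higher support, then to the 5'-most partner. Pseudoknot orders of the
#' kept set are re-annotated with \code{\link{annotate_crossing}}. The
#' consensus is then mapped onto each row by dropping that row's gap columns;
#' a consensus pair with an endpoint in a gap column of a row is omitted from
#' that row's structure.
#'
#' @param aln a \code{structure_alignment}.
#' @param support_threshold keep pairs with support strictly greater than this
#'   fraction (default 0.5: majority).
#' @return an object of class \code{consensus_result}: \code{consensus}
#'   (\code{\link{rna_structure}} in alignment coordinates), \code{support}
#'   (data frame of kept pairs with their support), \code{structures} (named
#'   list of per-sequence \code{rna_structure}s in sequence coordinates) and
#'   \code{alignment}.
#' @export
derive_consensus <- function(aln, support_threshold = 0.5) {
  stopifnot(inherits(aln, "structure_alignment"))
  nrows <- nrow(aln$idx); ncols <- ncol(aln$idx)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrows)) {
    cols <- which(aln$idx[r, ] != 0L) # cols[p] = alignment column of seq pos p
    prs <- aln$gs[[r]]$structure$pairs
    if (!nrow(prs)) next
    for (t in seq_len(nrow(prs))) {
      k <- paste0(cols[prs[t, 1L]], ",", cols[prs[t, 2L]])
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    pq <- do.call(rbind, strsplit(keys, ",", fixed = TRUE))
    p <- as.integer(pq[, 1L]); q <- as.integer(pq[, 2L])
    supp <- vapply(keys, function(k) counts[[k]], integer(1)) / nrows
    keep <- supp > support_threshold
    p <- p[keep]; q <- q[keep]; supp <- supp[keep]
  } else {
    p <- q <- integer(0); supp <- numeric(0)
  }
  ## conflict resolution: higher support first, then 5'-most pair
  o <- order(-supp, p, q)
  p <- p[o]; q <- q[o]; supp <- supp[o]
  used <- logical(ncols)
  sel <- logical(length(p))
  for (t in seq_along(p)) {
    if (!used[p[t]] && !used[q[t]]) {
      sel[t] <- TRUE
      used[c(p[t], q[t])] <- TRUE
    }
  }
  p <- p[sel]; q <- q[sel]; supp <- supp[sel]
  consensus <- annotate_crossing(cbind(p, q), ncols)

  structures <- vector("list", nrows)
  names(structures) <- aln$ids
  for (r in seq_len(nrows)) {
    cols <- which(aln$idx[r, ] != 0L)
    seqpos <- rep(NA_integer_, ncols)
    seqpos[cols] <- seq_along(cols)
    ok <- !is.na(seqpos[p]) & !is.na(seqpos[q])
    structures[[r]] <- annotate_crossing(cbind(seqpos[p[ok]], seqpos[q[ok]]),
                                         length(cols))
  }
  structure(
    list(consensus = consensus,
         support = data.frame(p = p, q = q, support = supp),
         structures = structures,
         alignment = aln,
         support_threshold = support_threshold),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d consensus pairs over %d rows\n",
              nrow(x$consensus$pairs), length(x$structures)))
  cat("  consensus:", write_dotbracket(x$consensus), "\n")
  invisible(x)
}

#' Consensus structure prediction for a family (KnotStructure)
#'
#' The full pipeline: rank candidate shapes with the linear model
#' (\code{\link{predict_shape}}), select one representative structure per
#' sequence inside the top shape class
#' (\code{\link{select_representatives}}), progressively align the
#' representatives along the clustering path
#' (\code{\link{progressive_align}}) and derive the consensus structure
#' (\code{\link{derive_consensus}}). Sequences that never fold into the
#' predicted shape receive no predicted structure and are listed in
#' \code{unpredicted}.
#'
#' @inheritParams predict_shape
#' @param support_threshold consensus pair support threshold.
#' @param scoring grammar-string scoring scheme.
#' @return an object of class \code{knotstructure_result}: \code{shape} (the
#'   predicted shape), \code{ranking} (the shape ranking table),
#'   \code{structures} (named list of per-sequence predicted
#'   \code{rna_structure}s), \code{consensus} (a \code{consensus_result}, or
#'   \code{NULL} when only one sequence folds into the shape), \code{tree}
#'   (the guide tree) and \code{unpredicted} (sequence ids without a
#'   prediction).
#' @export
knotstructure <- function(ensembles, model = NULL, level = 5, max_subopt = 10,
                          support_threshold = 0.5, scoring = gs_scoring()) {
  ranking <- predict_shape(ensembles, model, level, max_subopt)
  shape <- ranking$shape[1L]
  reps <- select_representatives(shape, ensembles, level, scoring, max_subopt)
  if (length(reps$representatives) >= 2L) {
    aln <- progressive_align(reps, scoring)
    cons <- derive_consensus(aln, support_threshold)
    structures <- cons$structures
  } else {
    cons <- NULL
    structures <- list(reps$representatives[[1L]]$structure)
    names(structures) <- names(reps$representatives)
  }
  all_ids <- vapply(ensembles, function(e) e$id, character(1))
  structure(
    list(shape = shape, ranking = ranking, structures = structures,
         consensus = cons, tree = reps$tree,
         unpredicted = setdiff(all_ids, names(structures))),
    class = "knotstructure_result"
  )
}

#' @export
print.knotstructure_result <- function(x, ...) {
  cat(sprintf("<knotstructure_result> shape %s; %d structures predicted",
              x$shape, length(x$structures)))
  if (length(x$unpredicted)) {
    cat(sprintf("; no prediction for: %s", paste(x$unpredicted, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Write per-sequence predicted structures
#'
#' FASTA-like output: a \code{>id} header, the sequence line, then the
#' structure in extended dot-bracket (Rfam letter dialect).
#'
#' @param result a \code{knotstructure_result}.
#' @param ensembles the input ensembles (source of the sequences).
#' @param path output file.
#' @export
write_structures <- function(result, ensembles, path) {
  seqs <- stats::setNames(
    vapply(ensembles, function(e) e$seq, character(1)),
    vapply(ensembles, function(e) e$id, character(1))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(result$structures)) {
    writeLines(c(paste0(">", id), seqs[[id]],
                 write_dotbracket(result$structures[[id]])), con, sep = "\n")
  }
  invisible(path)
}

#' Guide tree in Newick format
#'
#' Leaves are labelled \code{<sequence id>.<ensemble rank>}; merge
#' similarities are attached as internal node labels.
#'
#' @param tree a guide tree from \code{\link{select_representatives}}.
#' @return a single Newick string.
#' @export
guide_tree_newick <- function(tree) {
  if (!length(tree$merges)) {
    m <- tree$members[1L]
    return(sprintf("%s.%d;", tree$leaves$id[m], tree$leaves$rank[m]))
  }
  lab <- function(m) sprintf("%s.%d", tree$leaves$id[m], tree$leaves$rank[m])
  node <- lapply(seq_len(nrow(tree$leaves)), function(i) lab(i))
  key <- function(m) paste(sort(m), collapse = ",")
  nodes <- list()
  for (i in seq_len(nrow(tree$leaves))) nodes[[key(i)]] <- lab(i)
  for (mg in tree$merges) {
    nodes[[key(c(mg$a, mg$b))]] <- sprintf(
      "(%s,%s)%.4f", nodes[[key(mg$a)]], nodes[[key(mg$b)]], mg$similarity
    )
  }
  paste0(nodes[[key(c(tree$merges[[length(tree$merges)]]$a,
                      tree$merges[[length(tree$merges)]]$b))]], ";")
}
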
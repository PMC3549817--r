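## Synthetic homologous families with a planted consensus structure, a toy
## base-pair-maximisation folder, and the adapter contract for external
## folding tools. The generator emulates the situation the pipeline is built
## for: every ensemble contains the family's true structure as its
## minimum-free-energy candidate plus decoy structures of strictly different
## shape at higher energies; homologous sequences share decoy folds, so decoy
## shape classes accumulate members across sequences just as misfolds do.

.complementary <- matrix(c("G","C", "C","G", "A","U", "U","A", "G","U", "U","G"),
                         ncol = 2L, byrow = TRUE)

#' Specification of a synthetic family
#'
#' @param n number of sequences.
#' @param length sequence length (nt).
#' @param planted an \code{\link{rna_structure}} to plant, or \code{NULL} to
#'   sample one.
#' @param mutation_rate per-site substitution probability between family
#'   members; paired sites mutate compensatorily (the pair is resampled from
#'   the complementary alphabet, wobble included).
#' @param decoys decoy structures per sequence.
#' @param energy_noise_sd standard deviation (kcal/mol) of the noise on the
#'   planted structure's energy.
#' @param energy_range_pct decoy energies fall within this percentage above
#'   each sequence's MFE.
#' @param pk plant a pseudoknotted structure?
#' @param level abstraction level at which decoy shapes must differ from the
#'   planted shape.
#' @param seed integer seed fixing all randomness.
#' @return a \code{family_spec} list.
#' @export
family_spec <- function(n = 10, length = 80, planted = NULL,
                        mutation_rate = 0.1, decoys = 5,
                        energy_noise_sd = 0.5, energy_range_pct = 5,
                        pk = TRUE, level = 5, seed = 7) {
  stopifnot(n >= 1, length >= 30, mutation_rate >= 0, mutation_rate <= 1,
            decoys >= 0, energy_noise_sd >= 0, energy_range_pct > 0)
  structure(
    list(n = as.integer(n), length = as.integer(length), planted = planted,
         mutation_rate = mutation_rate, decoys = as.integer(decoys),
         energy_noise_sd = energy_noise_sd,
         energy_range_pct = energy_range_pct, pk = isTRUE(pk),
         level = as.integer(level), seed = as.integer(seed)),
    class = "family_spec"
  )
}

## sample a hairpin helix inside [a, b]: h stacked pairs, loop >= 3
sample_hairpin <- function(a, b, hmin = 3L, hmax = 6L) {
  span <- b - a + 1L
  h <- sample(seq(hmin, min(hmax, (span - 3L) %/% 2L)), 1L)
  inset5 <- sample(0:max(0L, span - 2L * h - 4L), 1L)
  i <- a + inset5
  j <- min(b, i + 2L * h + 3L + sample(0:3, 1L))
  cbind(seq(i, i + h - 1L), seq(j, j - h + 1L))
}

#' Sample a random secondary structure
#'
#' Draws 1-3 hairpin helices in disjoint sequence blocks; with \code{pk}, one
#' additional helix pairs the first hairpin loop with the 3' tail, creating an
#' H-type-like crossing. Used for planted structures and decoys.
#'
#' @param length sequence length (>= 30).
#' @param pk include a pseudoknot helix?
#' @return an \code{\link{rna_structure}}.
#' @export
sample_structure <- function(length, pk = FALSE) {
  stopifnot(length >= 30L)
  tail_reserve <- if (pk) 8L else 2L
  usable <- length - tail_reserve
  nblocks <- sample(1:min(3L, usable %/% 16L), 1L)
  bounds <- unique(round(seq(1L, usable, length.out = nblocks + 1L)))
  pairs <- NULL
  first_loop <- NULL
  for (k in seq_len(nblocks)) {
    a <- bounds[k] + (k > 1L)
    b <- bounds[k + 1L]
    if (b - a + 1L < 12L) next
    hp <- sample_hairpin(a, b)
    pairs <- rbind(pairs, hp)
    if (is.null(first_loop)) {
      first_loop <- c(max(hp[, 1L]) + 1L, min(hp[, 2L]) - 1L)
    }
  }
  if (is.null(pairs)) stop("length too small to place a helix")
  if (pk && !is.null(first_loop) && first_loop[2L] - first_loop[1L] >= 2L) {
    hpk <- min(3L, first_loop[2L] - first_loop[1L] + 1L, tail_reserve - 2L)
    i0 <- first_loop[1L]
    j0 <- length
    pairs <- rbind(pairs, cbind(seq(i0, i0 + hpk - 1L), seq(j0, j0 - hpk + 1L)))
  }
  annotate_crossing(pairs, length)
}

## ancestor sequence compatible with the planted pairs
ancestor_sequence <- function(s) {
  nt <- sample(c("A", "C", "G", "U"), s$length, replace = TRUE)
  if (nrow(s$pairs)) {
    rows <- sample.int(nrow(.complementary), nrow(s$pairs), replace = TRUE)
    nt[s$pairs[, 1L]] <- .complementary[rows, 1L]
    nt[s$pairs[, 2L]] <- .complementary[rows, 2L]
  }
  nt
}

## mutate an ancestor: unpaired sites substitute freely, paired sites
## resample the whole pair from the complementary alphabet (compensatory)
mutate_sequence <- function(nt, s, rate) {
  out <- nt
  paired <- paired_mask(s)
  for (i in which(!paired)) {
    if (runif(1) < rate) out[i] <- sample(setdiff(c("A", "C", "G", "U"), out[i]), 1L)
  }
  if (nrow(s$pairs)) {
    for (r in seq_len(nrow(s$pairs))) {
      if (runif(1) < rate) {
        row <- sample.int(nrow(.complementary), 1L)
        out[s$pairs[r, 1L]] <- .complementary[row, 1L]
        out[s$pairs[r, 2L]] <- .complementary[row, 2L]
      }
    }
  }
  out
}

#' Generate a synthetic homologous family
#'
#' Emits \code{n} sequences mutated from a random ancestor compatible with the
#' planted structure (compensatory mutations keep planted pairs
#' complementary), and one folding ensemble per sequence: the planted
#' structure at the lowest energy (noise added) plus \code{decoys} decoy
#' structures drawn from a family-level decoy pool, each with a level-`level`
#' shape different from the planted shape and a strictly higher energy within
#' \code{energy_range_pct} of the MFE. Deterministic per seed.
#'
#' @param spec a \code{\link{family_spec}}.
#' @return list with \code{sequences} (named character vector),
#'   \code{ensembles} (list of \code{\link{rna_ensemble}}), \code{truth}
#'   (named list: the planted \code{rna_structure} per sequence),
#'   \code{shape} (the planted shape string at \code{spec$level}),
#'   \code{planted} (the planted structure) and \code{spec}.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  planted <- spec$planted
  if (is.null(planted)) planted <- sample_structure(spec$length, spec$pk)
  if (planted$length != spec$length) stop("planted structure length != spec length")
  true_shape <- shape_of(planted, spec$level)

  ## family-level decoy pool: homologs share misfolds, so decoy classes have
  ## F1 > 1 without ever reaching the planted class's coverage
  pool_size <- max(3L, ceiling(spec$decoys * 1.5))
  pool <- list()
  guard <- 0L
  while (length(pool) < pool_size) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not sample enough decoy shapes")
    d <- sample_structure(spec$length, spec$pk && runif(1) < 0.5)
    if (shape_of(d, spec$level) != true_shape) pool[[length(pool) + 1L]] <- d
  }

  anc <- ancestor_sequence(planted)
  ids <- sprintf("seq%02d", seq_len(spec$n))
  seqs <- character(spec$n)
  ensembles <- vector("list", spec$n)
  base_energy <- -1.2 * nrow(planted$pairs)
  for (i in seq_len(spec$n)) {
    nt <- mutate_sequence(anc, planted, spec$mutation_rate)
    seqs[i] <- paste(nt, collapse = "")
    e_planted <- base_energy + rnorm(1, sd = spec$energy_noise_sd)
    entries <- list(list(structure = planted, energy = e_planted))
    if (spec$decoys > 0L) {
      picks <- sample.int(pool_size, spec$decoys,
                          replace = spec$decoys > pool_size)
      span <- max(0.5, abs(e_planted) * spec$energy_range_pct / 100)
      gaps <- 0.05 + runif(spec$decoys) * span
      for (k in seq_len(spec$decoys)) {
        entries[[k + 1L]] <- list(structure = pool[[picks[k]]],
                                  energy = e_planted + gaps[k])
      }
    }
    ensembles[[i]] <- rna_ensemble(ids[i], seqs[i], entries)
  }
  names(seqs) <- ids
  truth <- stats::setNames(rep(list(planted), spec$n), ids)
  list(sequences = seqs, ensembles = ensembles, truth = truth,
       shape = true_shape, planted = planted, spec = spec)
}

#' Generate labeled training instances from synthetic families
#'
#' Builds \code{n_families} families (half pseudoknotted, half nested), groups
#' each family's structures into shape classes, computes the class features
#' and labels a class +1 when its shape equals the family's planted shape,
#' -1 otherwise. The result feeds \code{\link{train_shape_model}}.
#'
#' @param n_families number of families.
#' @param seed master seed; per-family seeds are derived from it.
#' @param spec_args list of \code{\link{family_spec}} arguments shared by all
#'   families (\code{pk} and \code{seed} are set per family).
#' @param level abstraction level of the shape classes.
#' @return data frame with feature columns, \code{label} and \code{family}.
#' @export
generate_training_instances <- function(n_families = 100, seed = 1,
                                        spec_args = list(), level = 5) {
  set.seed(seed)
  fam_seeds <- sample.int(.Machine$integer.max %/% 2L, n_families)
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    args <- utils::modifyList(
      spec_args, list(pk = f %% 2L == 0L, seed = fam_seeds[f], level = level)
    )
    fam <- generate_family(do.call(family_spec, args))
    classes <- group_by_shape(fam$ensembles, level)
    feats <- do.call(rbind, lapply(classes, function(cl) cl$features))
    rows[[f]] <- data.frame(
      feats,
      label = ifelse(vapply(classes, function(cl) cl$shape, character(1)) ==
                       fam$shape, 1, -1),
      family = sprintf("fam%04d", f),
      check.names = FALSE
    )
  }
  do.call(rbind, rows)
}

## -------------------------------------------------------------------------
## toy folder: Nussinov-style base-pair maximisation with a stacking bonus.
## Score = (number of pairs) + 0.5 * (number of stacked adjacent pairs);
## reported energy = -score (kcal/mol-like, arbitrary fixed scale).

.toy_min_loop <- 3L

toy_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

## unambiguous decomposition used by both the DP and the enumeration:
##   W(i,j): j unpaired -> W(i,j-1); or j pairs k -> W(i,k-1) + V(k,j)
##   V(i,j): +1; inner exactly stacked -> +0.5 + V(i+1,j-1);
##           otherwise Wns(i+1,j-1) (= W without the full-span pair)
toy_tables <- function(nt) {
  L <- length(nt)
  W <- matrix(0, L + 1L, L + 1L)  # W[i, j+1] to allow j = i-1
  V <- matrix(-Inf, L, L)
  Wns <- matrix(0, L + 1L, L + 1L)
  can <- outer(nt, nt, Vectorize(toy_can_pair))
  for (span in seq(.toy_min_loop + 1L, L - 1L)) {
    for (i in seq_len(L - span)) {
      j <- i + span
      if (can[i, j]) {
        inner <- if (j - i - 2L > .toy_min_loop && can[i + 1L, j - 1L]) {
          0.5 + V[i + 1L, j - 1L]
        } else -Inf
        V[i, j] <- 1 + max(inner, Wns[i + 1L, j], 0)
      }
      ## W and Wns over [i, j]
      ks <- seq(i, j - .toy_min_loop - 1L)
      vals <- W[i, ks] + V[cbind(ks, j)] # W[i, k-1] is W[i, (k-1)+1]
      W[i, j + 1L] <- max(W[i, j], vals, 0)
      Wns[i, j + 1L] <- if (length(ks) > 1L) {
        max(W[i, j], vals[-1L], 0)
      } else {
        max(W[i, j], 0)
      }
    }
  }
  list(W = W, V = V, Wns = Wns, can = can, L = L)
}

## enumerate suboptimal structures within `delta` of the optimal score using
## best-first expansion of the unambiguous decomposition; deterministic
toy_enumerate <- function(tb, delta, max_out) {
  L <- tb$L
  seg_bound <- function(seg) {
    switch(seg[3L],
           tb$W[seg[1L], seg[2L] + 1L],
           tb$V[seg[1L], seg[2L]],
           tb$Wns[seg[1L], seg[2L] + 1L])
  }
  opt <- tb$W[1L, L + 1L]
  results <- list()
  ## state: list(segs = list of c(i, j, type 1=W/2=V/3=Wns), score, pairs)
  stack <- list(list(segs = list(c(1L, L, 1L)), score = 0, pairs = NULL))
  while (length(stack) && length(results) < max_out) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ## drop exhausted segments
    while (length(st$segs) && st$segs[[1L]][2L] < st$segs[[1L]][1L]) {
      st$segs <- st$segs[-1L]
    }
    if (!length(st$segs)) {
      results[[length(results) + 1L]] <- st
      next
    }
    seg <- st$segs[[1L]]
    rest <- st$segs[-1L]
    rest_bound <- if (length(rest)) sum(vapply(rest, seg_bound, numeric(1))) else 0
    i <- seg[1L]; j <- seg[2L]; type <- seg[3L]
    children <- list()
    add_child <- function(new_segs, dscore, new_pairs) {
      segs <- c(new_segs, rest)
      bound <- st$score + dscore + rest_bound +
        (if (length(new_segs)) sum(vapply(new_segs, seg_bound, numeric(1))) else 0)
      if (bound >= opt - delta - 1e-9) {
        children[[length(children) + 1L]] <<-
          list(state = list(segs = segs, score = st$score + dscore,
                            pairs = rbind(st$pairs, new_pairs)),
               bound = bound)
      }
    }
    if (type == 1L || type == 3L) {
      ## j unpaired
      add_child(list(c(i, j - 1L, 1L)), 0, NULL)
      ## j paired with k (Wns excludes k == i)
      kmin <- if (type == 3L) i + 1L else i
      kmax <- j - .toy_min_loop - 1L
      ks <- if (kmax >= kmin) seq(kmin, kmax) else integer(0)
      if (length(ks)) ks <- ks[tb$can[cbind(ks, rep(j, length(ks)))]]
      for (k in ks) {
        add_child(list(c(i, k - 1L, 1L), c(k, j, 2L)), 0, NULL)
      }
    } else {
      ## V(i, j): pair (i, j)
      if (j - i - 2L > .toy_min_loop && tb$can[i + 1L, j - 1L] &&
          is.finite(tb$V[i + 1L, j - 1L])) {
        add_child(list(c(i + 1L, j - 1L, 2L)), 1.5, c(i, j))
      }
      add_child(list(c(i + 1L, j - 1L, 3L)), 1, c(i, j))
    }
    if (length(children)) {
      ## push lowest bound first so the best child is expanded next
      o <- order(vapply(children, function(c) c$bound, numeric(1)))
      for (k in o) stack[[length(stack) + 1L]] <- children[[k]]$state
    }
  }
  results
}

#' Toy folding-space sampler
#'
#' A Nussinov-style folder for desk-scale experiments: maximizes (pairs +
#' 0.5 per stacked adjacent pair) over nested structures with hairpin loops of
#' at least 3 nt (Watson-Crick and GU wobble pairs), reporting energy =
#' -score. Enumerates distinct suboptimal structures whose energy lies within
#' \code{energy_range_pct} of the optimum and returns at most
#' \code{max_structures} of them, ranked by energy. Never emits pseudoknots.
#' Fully deterministic.
#'
#' @param seq residue string (length >= 10; T is read as U).
#' @param id sequence identifier for the resulting ensemble.
#' @param energy_range_pct suboptimal energy window as a percentage of the
#'   optimal score.
#' @param max_structures maximum ensemble size.
#' @return an \code{\link{rna_ensemble}}.
#' @export
toy_fold <- function(seq, id = "seq", energy_range_pct = 5, max_structures = 11) {
  nt <- toupper(strsplit(chartr("tT", "uU", seq), "", fixed = TRUE)[[1L]])
  L <- length(nt)
  if (L < 10L) stop("sequence shorter than 10 nt")
  tb <- toy_tables(nt)
  opt <- tb$W[1L, L + 1L]
  if (opt <= 0) {
    return(rna_ensemble(id, seq, list(
      list(structure = rna_structure(L), energy = 0)
    )))
  }
  delta <- opt * energy_range_pct / 100
  cap <- max(50L, 4L * max_structures)
  res <- toy_enumerate(tb, delta, cap)
  entries <- lapply(res, function(st) {
    prs <- if (is.null(st$pairs)) NULL else matrix(st$pairs, ncol = 2L)
    list(structure = annotate_crossing(prs, L), energy = -st$score)
  })
  scores <- vapply(res, function(st) st$score, numeric(1))
  entries <- entries[order(-scores)][seq_len(min(length(entries), max_structures))]
  rna_ensemble(id, seq, entries)
}

## -------------------------------------------------------------------------
## adapter contract for external folding tools

#' Folding-tool adapters
#'
#' An adapter wraps a de novo folding tool behind a uniform contract: its
#' \code{fold} function takes \code{(id, seq)} and returns a data frame with
#' columns \code{structure} (dot-bracket text, any supported dialect) and
#' \code{energy}. \code{run_adapter} invokes the adapter per sequence,
#' re-annotates pseudoknot orders from the raw pair set (external dialects do
#' not always carry crossing classes), and assembles standard ensembles.
#' Sequences on which the tool fails or returns no structures are skipped
#' with a warning; a malformed output line is an error naming the sequence.
#'
#' @param name adapter name.
#' @param fold function \code{(id, seq) -> data.frame(structure, energy)}.
#' @return \code{folder_adapter}: an adapter object.
#' @export
folder_adapter <- function(name, fold) {
  stopifnot(is.function(fold))
  structure(list(name = name, fold = fold), class = "folder_adapter")
}

#' @rdname folder_adapter
#' @param energy_range_pct,max_structures passed to \code{\link{toy_fold}}.
#' @export
toy_adapter <- function(energy_range_pct = 5, max_structures = 11) {
  folder_adapter("toy_fold", function(id, seq) {
    e <- toy_fold(seq, id, energy_range_pct, max_structures)
    data.frame(
      structure = vapply(e$structures, function(st) write_dotbracket(st$structure),
                         character(1)),
      energy = vapply(e$structures, function(st) st$energy, numeric(1))
    )
  })
}

#' @rdname folder_adapter
#' @param adapter a \code{folder_adapter}.
#' @param seqs named character vector of sequences (e.g. from
#'   \code{\link{read_fasta}}).
#' @return \code{run_adapter}: a list of \code{\link{rna_ensemble}} objects
#'   (possibly fewer than \code{length(seqs)}).
#' @export
run_adapter <- function(adapter, seqs) {
  stopifnot(inherits(adapter, "folder_adapter"))
  out <- list()
  for (id in names(seqs)) {
    tab <- tryCatch(adapter$fold(id, seqs[[id]]), error = function(e) {
      warning(sprintf("folding tool '%s' failed on '%s': %s; record skipped",
                      adapter$name, id, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(tab) || !NROW(tab)) {
      if (!is.null(tab)) {
        warning(sprintf("folding tool '%s' returned no structures for '%s'; record skipped",
                        adapter$name, id), call. = FALSE)
      }
      next
    }
    entries <- vector("list", nrow(tab))
    for (k in seq_len(nrow(tab))) {
      s <- tryCatch(parse_dotbracket(tab$structure[k]), error = function(e) {
        stop(sprintf("adapter '%s', sequence '%s', line %d: %s",
                     adapter$name, id, k, conditionMessage(e)), call. = FALSE)
      })
      if (s$length != nchar(seqs[[id]])) {
        stop(sprintf("adapter '%s', sequence '%s', line %d: structure length %d != sequence length %d",
                     adapter$name, id, k, s$length, nchar(seqs[[id]])))
      }
      if (!is.finite(tab$energy[k])) {
        stop(sprintf("adapter '%s', sequence '%s', line %d: malformed energy",
                     adapter$name, id, k))
      }
      entries[[k]] <- list(structure = annotate_crossing(s$pairs, s$length),
                           energy = tab$energy[k])
    }
    out[[length(out) + 1L]] <- rna_ensemble(id, seqs[[id]], entries)
  }
  out
}
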
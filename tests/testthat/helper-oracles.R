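# Independent oracles and random-input generators shared across tests.
# Each oracle is a direct, brute-force transcription of the quantity it
# checks, kept deliberately separate from the package's implementation path.

# F-score by literal evaluation of the defining ratio
bf_f_score <- function(values, labels) {
  xp <- values[labels == 1]
  xn <- values[labels == -1]
  xbar <- mean(values)
  num <- (mean(xp) - xbar)^2 + (mean(xn) - xbar)^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
    sum((xn - mean(xn))^2) / (length(xn) - 1)
  num / max(den, 1e-12)
}

# global alignment score by exhaustive recursion over all alignments
bf_align_score <- function(a, b, sc = gs_scoring()) {
  pair_score <- function(i, j) {
    if (a$role[i] == b$role[j]) {
      if (a$nt[i] == b$nt[j]) sc$match_both else sc$match_role
    } else {
      sc$mismatch
    }
  }
  rec <- function(i, j) {
    if (i > length(a$role) && j > length(b$role)) return(0)
    best <- -Inf
    if (i <= length(a$role) && j <= length(b$role)) {
      best <- max(best, pair_score(i, j) + rec(i + 1L, j + 1L))
    }
    if (i <= length(a$role)) best <- max(best, sc$gap + rec(i + 1L, j))
    if (j <= length(b$role)) best <- max(best, sc$gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# all nested structures over nt (min hairpin loop 3), as pair matrices
bf_enumerate_structures <- function(nt) {
  L <- length(nt)
  can <- function(a, b) paste0(nt[a], nt[b]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(0), ncol = 2L)))
    out <- rec(i, j - 1L) # j unpaired
    for (k in seq(i, j - 4L)) {
      if (!can(k, j)) next
      left <- rec(i, k - 1L)
      right <- rec(k + 1L, j - 1L)
      for (l in left) for (r in right) {
        out[[length(out) + 1L]] <- rbind(c(k, j), l, r)
      }
    }
    out
  }
  rec(1L, L)
}

# toy-folder scoring: pairs + 0.5 per stacked adjacent pair
bf_structure_score <- function(pairs) {
  if (!nrow(pairs)) return(0)
  stacked <- apply(pairs, 1L, function(p) {
    any(pairs[, 1L] == p[1L] + 1L & pairs[, 2L] == p[2L] - 1L)
  })
  nrow(pairs) + 0.5 * sum(stacked)
}

# random pair set over L positions (crossing allowed), each position used once
rand_pairs <- function(L, max_pairs = L %/% 3L) {
  npair <- sample(0:max_pairs, 1L)
  if (npair == 0L) return(NULL)
  pos <- sample(L, 2L * npair)
  i <- pos[seq_len(npair)]
  j <- pos[npair + seq_len(npair)]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  cbind(i, j)
}

rand_structure <- function(L, max_pairs = L %/% 3L) {
  annotate_crossing(rand_pairs(L, max_pairs), L)
}

rand_grammar_string <- function(L, max_pairs = L %/% 3L) {
  nt <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  gs_encode(paste(nt, collapse = ""), rand_structure(L, max_pairs))
}

# crossing test on two pairs
crosses <- function(p, q) {
  (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
    (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
}

# a tiny two-sequence family where every structure has the same level-5 shape
# and one cross-sequence candidate pair is the unique similarity maximum
engineered_two_seq_family <- function() {
  seq1 <- "GGGGAAACCCCAAA"
  hairpin_full <- parse_dotbracket("((((...))))...")
  hairpin_small <- parse_dotbracket(".(((...)))....")
  e1 <- rna_ensemble("s1", seq1, list(
    list(structure = hairpin_full, energy = -8),
    list(structure = hairpin_small, energy = -6)
  ))
  e2 <- rna_ensemble("s2", seq1, list( # same residues as s1's first candidate
    list(structure = hairpin_full, energy = -7.5),
    list(structure = hairpin_small, energy = -5)
  ))
  list(e1, e2)
}
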
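## Grammar strings: a positional encoding of (sequence, structure) pairs that
## makes joint sequence + structure similarity measurable by ordinary global
## string alignment. Position i carries its nucleotide and a structural role:
## unpaired, or the opening/closing side of a pair of pseudoknot order k.
## Roles of pseudoknotted pairs compare equal only on identical order, so
## crossing topology is preserved through alignment and consensus.

## role codes: 0 unpaired; order-k pair -> open 2k+1, close 2k+2
role_codes <- function(s) {
  role <- integer(s$length)
  if (nrow(s$pairs)) {
    role[s$pairs[, 1L]] <- 2L * s$pk_order + 1L
    role[s$pairs[, 2L]] <- 2L * s$pk_order + 2L
  }
  role
}

#' Encode a sequence and its structure as a grammar string
#'
#' @param seq residue string (length must match the structure).
#' @param s an \code{\link{rna_structure}}.
#' @param id optional source identifier carried along.
#' @param rank optional ensemble rank of the encoded structure.
#' @return an object of class \code{grammar_string} with \code{nt} (residue
#'   characters, uppercased, T mapped to U), \code{role} (integer role codes)
#'   and \code{source = c(id, rank)}. The encoding is invertible:
#'   \code{\link{gs_decode}} recovers the (sequence, structure) pair.
#' @export
gs_encode <- function(seq, s, id = NA_character_, rank = NA_integer_) {
  stopifnot(inherits(s, "rna_structure"))
  if (nchar(seq) != s$length) {
    stop("sequence length ", nchar(seq), " != structure length ", s$length)
  }
  nt <- strsplit(chartr("tT", "uU", seq), "", fixed = TRUE)[[1L]]
  nt <- toupper(nt)
  structure(
    list(nt = nt, role = role_codes(s), structure = s,
         source = list(id = id, rank = as.integer(rank))),
    class = "grammar_string"
  )
}

#' Decode a grammar string
#'
#' @param gs a \code{grammar_string}.
#' @return list with \code{seq} and \code{structure}.
#' @export
gs_decode <- function(gs) {
  list(seq = paste(gs$nt, collapse = ""), structure = gs$structure)
}

#' @export
print.grammar_string <- function(x, ...) {
  cat(sprintf("<grammar_string> %s (rank %s): %d symbols\n",
              x$source$id, x$source$rank, length(x$nt)))
  cat(" ", paste(x$nt, collapse = ""), "\n ", write_dotbracket(x$structure), "\n")
  invisible(x)
}

#' Default grammar-string scoring scheme
#'
#' Column scores for grammar-string alignment: \code{match_both} when role and
#' nucleotide both match, \code{match_role} when only the role matches,
#' \code{mismatch} when the roles differ, and a linear \code{gap} penalty.
#'
#' @param match_both,match_role,mismatch,gap numeric scores.
#' @return a named list usable as the \code{scoring} argument of
#'   \code{\link{gs_align}}.
#' @export
gs_scoring <- function(match_both = 2, match_role = 1, mismatch = -1, gap = -2) {
  list(match_both = match_both, match_role = match_role,
       mismatch = mismatch, gap = gap)
}

#' Read a scoring scheme from a flat key=value config file
#'
#' Recognized keys: \code{match_both}, \code{match_role}, \code{mismatch},
#' \code{gap}; missing keys keep their defaults.
#'
#' @param path config file path.
#' @return a scoring scheme list.
#' @export
read_scoring <- function(path) {
  sc <- gs_scoring()
  for (ln in readLines(path, warn = FALSE)) {
    ln <- sub("#.*$", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    if (!key %in% names(sc)) stop("unknown scoring key '", key, "'")
    sc[[key]] <- as.numeric(trimws(kv[2L]))
  }
  sc
}

## column-score matrix between two grammar strings
gs_score_matrix <- function(a, b, scoring) {
  role_eq <- outer(a$role, b$role, "==")
  nt_eq <- outer(a$nt, b$nt, "==")
  S <- matrix(scoring$mismatch, nrow = length(a$role), ncol = length(b$role))
  S[role_eq] <- scoring$match_role
  S[role_eq & nt_eq] <- scoring$match_both
  S
}

#' Align two grammar strings
#'
#' Global dynamic-programming alignment with a linear gap penalty. The
#' similarity reported is the raw alignment score normalized by the alignment
#' length (gap columns, terminal gaps included), so identical strings score
#' the scheme's match ceiling.
#'
#' @param a,b \code{grammar_string} objects.
#' @param scoring a scheme from \code{\link{gs_scoring}}.
#' @return list with \code{raw} score, alignment \code{length},
#'   \code{normalized} = raw / length, and the aligned symbol indices
#'   \code{a_idx}, \code{b_idx} (0 = gap).
#' @export
gs_align <- function(a, b, scoring = gs_scoring()) {
  stopifnot(inherits(a, "grammar_string"), inherits(b, "grammar_string"))
  if (!length(a$role) || !length(b$role)) stop("empty grammar string")
  S <- gs_score_matrix(a, b, scoring)
  res <- nw_align_cpp(S, scoring$gap)
  len <- length(res$a_idx)
  list(raw = res$score, length = len, normalized = res$score / len,
       a_idx = res$a_idx, b_idx = res$b_idx)
}
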
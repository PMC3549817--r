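## Secondary structures, extended dot-bracket notation, and ensemble files.
##
## Coordinates are 1-based and intervals closed. A pair (i, j) always has
## i < j. Each pair carries a pseudoknot order: 0 for the nested page, k >= 1
## for the k-th crossing class (rendered as letters A/a, B/b, ... on output).

#' Construct a secondary structure
#'
#' A secondary structure is a set of base pairs over \code{length} positions,
#' each pair tagged with a pseudoknot order: order 0 pairs are mutually
#' non-crossing (the nested page); every pair of order k >= 1 crosses at least
#' one pair of lower order.
#'
#' @param length number of positions (>= 0).
#' @param pairs two-column integer matrix of (i, j) with 1 <= i < j <= length,
#'   or an empty/NULL value for an unpaired structure.
#' @param pk_order integer vector of pseudoknot orders, one per pair. If
#'   omitted, orders are computed with \code{\link{annotate_crossing}}.
#' @return an object of class \code{rna_structure} with elements
#'   \code{length}, \code{pairs} (matrix, rows sorted by first coordinate) and
#'   \code{pk_order}.
#' @seealso \code{\link{parse_dotbracket}}, \code{\link{annotate_crossing}}
#' @export
rna_structure <- function(length, pairs = NULL, pk_order = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop("'length' must be a non-negative integer")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
    pk_order <- integer(0)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (anyNA(pairs)) stop("pairs contain NA")
    bad <- pairs[, 1L] >= pairs[, 2L]
    if (any(bad)) stop("pair with i >= j at row ", which(bad)[1L])
    if (any(pairs < 1L) || any(pairs > length)) stop("pair position outside 1..length")
    pos <- as.vector(pairs)
    if (anyDuplicated(pos)) {
      stop("position ", pos[duplicated(pos)][1L], " occurs in two pairs")
    }
    ord <- order(pairs[, 1L])
    pairs <- pairs[ord, , drop = FALSE]
    if (!is.null(pk_order)) {
      pk_order <- as.integer(pk_order)[ord]
      if (length(pk_order) != nrow(pairs)) stop("pk_order length != number of pairs")
      if (any(pk_order < 0L)) stop("pk_order must be >= 0")
    }
  }
  if (is.null(pk_order)) {
    return(annotate_crossing(pairs, length))
  }
  structure(
    list(length = length, pairs = pairs, pk_order = pk_order),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf(
    "<rna_structure> length %d, %d pairs (%d pseudoknotted)\n  %s\n",
    x$length, nrow(x$pairs), sum(x$pk_order > 0L), write_dotbracket(x)
  ))
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) write_dotbracket(x)

## TRUE where position i is paired
paired_mask <- function(s) {
  m <- logical(s$length)
  m[as.vector(s$pairs)] <- TRUE
  m
}

## partner[i] = j when (i,j) or (j,i) is a pair, NA otherwise
partner_vector <- function(s) {
  p <- rep(NA_integer_, s$length)
  if (nrow(s$pairs)) {
    p[s$pairs[, 1L]] <- s$pairs[, 2L]
    p[s$pairs[, 2L]] <- s$pairs[, 1L]
  }
  p
}

pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

## Bracket dialects accepted on input. '(' is always the nested page;
## '[' '{' '<' are common tool dialects for crossing classes.
.open_chars <- c("(", "[", "{", "<")
.close_chars <- c(")", "]", "}", ">")

#' Parse extended dot-bracket notation
#'
#' Reads a structure string in extended dot-bracket notation: \code{.} is an
#' unpaired position, \code{(} \code{)} delimit nested (order 0) pairs, and
#' pseudoknotted pairs are written either as upper/lower case letter pairs
#' (\code{A..a}, \code{B..b}, the Rfam dialect) or with the auxiliary bracket
#' dialects \code{[]}, \code{\{\}}, \code{<>}. Within each class, pairing
#' follows stack discipline (a closer matches the most recent open symbol of
#' its class). Crossing classes are numbered by first appearance: the first
#' non-parenthesis class to open becomes order 1, the next order 2, and so on.
#'
#' @param text a single structure string.
#' @return an \code{\link{rna_structure}}.
#' @examples
#' parse_dotbracket("((...))")
#' parse_dotbracket("((..AA..))..aa")
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  stacks <- list() # per class: integer vector of open positions
  class_order <- character(0) # class keys in order of first appearance
  pi <- integer(0); pj <- integer(0); pclass <- character(0)

  class_of_open <- function(c) {
    if (c == "(") return("paren")
    k <- match(c, .open_chars)
    if (!is.na(k)) return(.open_chars[k])
    if (grepl("^[A-Z]$", c)) return(c)
    NA_character_
  }
  class_of_close <- function(c) {
    if (c == ")") return("paren")
    k <- match(c, .close_chars)
    if (!is.na(k)) return(.open_chars[k])
    if (grepl("^[a-z]$", c)) return(toupper(c))
    NA_character_
  }
  open_symbol <- function(key) if (key == "paren") "(" else key

  for (i in seq_len(n)) {
    c <- ch[i]
    if (c == ".") next
    key <- class_of_open(c)
    if (!is.na(key)) {
      if (is.null(stacks[[key]])) {
        stacks[[key]] <- integer(0)
        if (key != "paren") class_order <- c(class_order, key)
      }
      stacks[[key]] <- c(stacks[[key]], i)
      next
    }
    key <- class_of_close(c)
    if (!is.na(key)) {
      if (is.null(stacks[[key]]) || length(stacks[[key]]) == 0L) {
        stop(sprintf("unbalanced '%s' at position %d", c, i))
      }
      j <- stacks[[key]][length(stacks[[key]])]
      stacks[[key]] <- stacks[[key]][-length(stacks[[key]])]
      pi <- c(pi, j); pj <- c(pj, i); pclass <- c(pclass, key)
      next
    }
    stop(sprintf("illegal character '%s' at position %d", c, i))
  }
  for (key in names(stacks)) {
    if (length(stacks[[key]])) {
      stop(sprintf(
        "unbalanced '%s' at position %d", open_symbol(key), stacks[[key]][1L]
      ))
    }
  }
  order_of_class <- c(0L, seq_along(class_order))
  names(order_of_class) <- c("paren", class_order)
  pk <- unname(order_of_class[pclass])
  rna_structure(n, cbind(pi, pj), pk_order = if (length(pi)) pk else NULL)
}

#' Write extended dot-bracket notation
#'
#' Serializes a structure in the Rfam dialect: \code{(} \code{)} for order-0
#' pairs and letter pairs \code{A/a}, \code{B/b}, ... for pseudoknot orders
#' 1, 2, .... Inverse of \code{\link{parse_dotbracket}} on valid structures.
#'
#' @param s an \code{\link{rna_structure}}.
#' @return a single structure string.
#' @export
write_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  out <- rep(".", s$length)
  if (nrow(s$pairs)) {
    if (max(s$pk_order) > 26L) {
      stop("more than 26 pseudoknot orders: letter alphabet exhausted")
    }
    op <- rep("(", nrow(s$pairs))
    cl <- rep(")", nrow(s$pairs))
    pk <- s$pk_order > 0L
    op[pk] <- LETTERS[s$pk_order[pk]]
    cl[pk] <- letters[s$pk_order[pk]]
    out[s$pairs[, 1L]] <- op
    out[s$pairs[, 2L]] <- cl
  }
  paste(out, collapse = "")
}

#' Assign pseudoknot orders to a set of base pairs
#'
#' Partitions pairs into crossing classes: order 0 is a maximum-cardinality
#' mutually non-crossing subset (two pairs i-j and i'-j' cross when
#' i < i' < j < j'); every remaining pair is assigned, in order of its 5'
#' coordinate, the lowest order k >= 1 whose class it does not cross. Ties for
#' the order-0 subset are broken in favour of the subset containing the
#' 5'-most pair, then the lexicographically smallest pair list, so the result
#' is deterministic.
#'
#' @param pairs two-column matrix of (i, j) base pairs, each position in at
#'   most one pair.
#' @param length number of positions.
#' @return an \code{\link{rna_structure}} with \code{pk_order} filled in.
#' @examples
#' annotate_crossing(rbind(c(1, 10), c(2, 9), c(5, 14), c(6, 13)), 14)
#' @export
annotate_crossing <- function(pairs, length) {
  length <- as.integer(length)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(structure(
      list(length = length, pairs = matrix(integer(0), ncol = 2L),
           pk_order = integer(0)),
      class = "rna_structure"
    ))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  pos <- as.vector(pairs)
  if (anyDuplicated(pos)) {
    stop("position ", pos[duplicated(pos)][1L], " occurs in two pairs")
  }
  if (any(pairs < 1L) || any(pairs > length)) stop("pair position outside 1..length")
  if (any(pairs[, 1L] >= pairs[, 2L])) stop("pair with i >= j")
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  np <- nrow(pairs)
  L <- length

  ## opens[i] = j if (i, j) is an input pair
  opens <- rep(NA_integer_, L)
  opens[pairs[, 1L]] <- pairs[, 2L]

  ## M[i, j] = size of the largest non-crossing subset using pairs contained
  ## in [i, j]; choosing the pair at i whenever it ties keeps the 5'-most
  ## pair and yields the lexicographically smallest selection.
  M <- matrix(0L, nrow = L + 2L, ncol = L + 1L)
  take <- matrix(FALSE, nrow = L, ncol = L)
  for (i in seq(L, 1L)) {
    k <- opens[i]
    for (j in seq(i, L)) {
      best <- M[i + 1L, j]
      if (!is.na(k) && k <= j) {
        cand <- 1L + (if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L) +
          (if (j >= k + 1L) M[k + 1L, j] else 0L)
        if (cand >= best) {
          best <- cand
          take[i, j] <- TRUE
        }
      }
      M[i, j] <- best
    }
  }
  sel <- logical(np)
  row_of <- integer(L); row_of[pairs[, 1L]] <- seq_len(np)
  stack <- list(c(1L, L))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    while (i <= j) {
      if (!is.na(opens[i]) && opens[i] <= j && take[i, j]) {
        k <- opens[i]
        sel[row_of[i]] <- TRUE
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        j <- k - 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }

  ## remaining pairs, in 5'-coordinate order, take the lowest order k >= 1
  ## whose already-assigned class they do not cross
  ord <- integer(np)
  assigned <- which(sel)
  for (r in which(!sel)) {
    k <- 1L
    repeat {
      members <- assigned[ord[assigned] == k]
      if (!any(pairs_cross(pairs[r, 1L], pairs[r, 2L],
                           pairs[members, 1L], pairs[members, 2L]))) {
        ord[r] <- k
        break
      }
      k <- k + 1L
    }
    assigned <- c(assigned, r)
  }
  structure(
    list(length = L, pairs = pairs, pk_order = ord),
    class = "rna_structure"
  )
}

#' Read and write RNA folding-ensemble files
#'
#' The ensemble file is line-oriented: each record starts with a \code{>id}
#' header, followed by the sequence line, then one line per candidate
#' structure of the form \code{<dotbracket>\\t<energy>} with the free energy
#' in kcal/mol. Structures within a record are kept sorted by energy
#' (ascending); ranks 1..n are assigned in that order, rank 1 being the
#' minimum free energy (MFE) structure.
#'
#' @param path file path.
#' @return \code{read_ensembles} returns a list of \code{rna_ensemble}
#'   objects: each has \code{id}, \code{seq}, and \code{structures}, a list of
#'   entries with \code{structure} (an \code{\link{rna_structure}}),
#'   \code{energy} and \code{rank}.
#' @export
read_ensembles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no records in ensemble file ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[r]])
    body <- lines[seq(starts[r] + 1L, ends[r])]
    if (length(body) < 2L) stop("record '", id, "' has no structures")
    seq <- body[1L]
    entries <- vector("list", length(body) - 1L)
    for (k in seq_along(entries)) {
      ln <- body[k + 1L]
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(fields) != 2L) {
        stop(sprintf("record '%s', structure line %d: expected '<dotbracket>\\t<energy>'",
                     id, k))
      }
      if (nchar(fields[1L]) != nchar(seq)) {
        stop(sprintf("record '%s', structure line %d: structure length %d != sequence length %d",
                     id, k, nchar(fields[1L]), nchar(seq)))
      }
      energy <- suppressWarnings(as.numeric(fields[2L]))
      if (is.na(energy)) {
        stop(sprintf("record '%s', structure line %d: malformed energy field '%s'",
                     id, k, fields[2L]))
      }
      entries[[k]] <- list(structure = parse_dotbracket(fields[1L]), energy = energy)
    }
    out[[r]] <- rna_ensemble(id, seq, entries)
  }
  out
}

#' Construct a folding ensemble
#'
#' @param id sequence identifier.
#' @param seq residue string (A, C, G, U and IUPAC ambiguity codes accepted).
#' @param entries list of \code{list(structure =, energy =)} candidates; they
#'   are sorted by energy and assigned ranks.
#' @return an object of class \code{rna_ensemble}.
#' @export
rna_ensemble <- function(id, seq, entries) {
  stopifnot(nzchar(id), nzchar(seq), length(entries) >= 1L)
  for (e in entries) {
    if (e$structure$length != nchar(seq)) {
      stop("record '", id, "': structure length != sequence length")
    }
  }
  o <- order(vapply(entries, function(e) e$energy, numeric(1)))
  entries <- entries[o]
  for (k in seq_along(entries)) entries[[k]]$rank <- k
  structure(list(id = id, seq = seq, structures = entries), class = "rna_ensemble")
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat(sprintf("<rna_ensemble> %s: %d nt, %d structures, MFE %.2f kcal/mol\n",
              x$id, nchar(x$seq), length(x$structures), ensemble_mfe(x)))
  invisible(x)
}

#' Minimum free energy of an ensemble
#'
#' @param ensemble an \code{rna_ensemble}.
#' @return the lowest energy over all candidate structures (kcal/mol).
#' @export
ensemble_mfe <- function(ensemble) ensemble$structures[[1L]]$energy

#' @rdname read_ensembles
#' @param ensembles list of \code{rna_ensemble} objects.
#' @export
write_ensembles <- function(ensembles, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (e in ensembles) {
    writeLines(c(paste0(">", e$id), e$seq), con, sep = "\n")
    for (st in e$structures) {
      writeLines(sprintf("%s\t%.4f", write_dotbracket(st$structure), st$energy),
                 con, sep = "\n")
    }
  }
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers around \pkg{Biostrings} returning/accepting a named character
#' vector of residues.
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
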
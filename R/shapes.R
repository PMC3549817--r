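## Abstract shapes at levels 1, 3 and 5.
##
## A stack is a maximal run of directly stacked pairs of the same pseudoknot
## order. A helix groups consecutive stacks separated only by unpaired
## positions (bulges / internal loops). Level 5 keeps one bracket or letter
## pair per helix; level 3 one per stack (helix interruptions visible);
## level 1 adds one underscore per maximal unpaired region, termini included.

#' Decompose a structure into stacks and helices
#'
#' Stacks are maximal sets of directly stacked pairs (i, j), (i+1, j-1), ...
#' all of one pseudoknot order. Two stacks belong to the same helix when the
#' outer stack's innermost pair (i, j) and the inner stack's outermost pair
#' (k, l) satisfy i < k <= l < j with every position in (i, k) and (l, j)
#' unpaired, and both stacks share the same pseudoknot order -- i.e. they are
#' separated only by a bulge or internal loop.
#'
#' @param s an \code{\link{rna_structure}}.
#' @return a list with \code{stacks} (data.frame: \code{open}, \code{close}
#'   outermost pair, \code{inner_open}, \code{inner_close} innermost pair,
#'   \code{order}, \code{helix} helix index) and \code{helices} (list of stack
#'   index vectors, outermost stack first).
#' @export
decompose_helices <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  np <- nrow(s$pairs)
  if (np == 0L) {
    return(list(
      stacks = data.frame(open = integer(0), close = integer(0),
                          inner_open = integer(0), inner_close = integer(0),
                          order = integer(0), helix = integer(0)),
      helices = list()
    ))
  }
  partner <- partner_vector(s)
  order_of <- rep(NA_integer_, s$length)
  order_of[s$pairs[, 1L]] <- s$pk_order

  ## stack id per pair: pair rows are sorted by i; (i, j) continues the stack
  ## of (i-1, j+1) when that pair exists with the same order
  stack_id <- integer(np)
  nstack <- 0L
  id_at_open <- rep(NA_integer_, s$length)
  for (r in seq_len(np)) {
    i <- s$pairs[r, 1L]; j <- s$pairs[r, 2L]
    prev <- if (i > 1L && !is.na(partner[i - 1L]) && partner[i - 1L] == j + 1L &&
                !is.na(id_at_open[i - 1L]) &&
                order_of[i - 1L] == s$pk_order[r]) id_at_open[i - 1L] else NA_integer_
    if (is.na(prev)) {
      nstack <- nstack + 1L
      stack_id[r] <- nstack
    } else {
      stack_id[r] <- prev
    }
    id_at_open[i] <- stack_id[r]
  }
  stacks <- data.frame(
    open = tapply(s$pairs[, 1L], stack_id, min),
    close = tapply(s$pairs[, 2L], stack_id, max),
    inner_open = tapply(s$pairs[, 1L], stack_id, max),
    inner_close = tapply(s$pairs[, 2L], stack_id, min),
    order = tapply(s$pk_order, stack_id, function(x) x[1L])
  )
  stacks <- stacks[order(stacks$open), , drop = FALSE]
  rownames(stacks) <- NULL
  ns <- nrow(stacks)

  ## helix merging: walk from each stack's innermost pair to the next paired
  ## position; merge when the intervening regions on both sides are unpaired
  paired <- paired_mask(s)
  merged_into <- rep(NA_integer_, ns) # inner stack index continued by row
  open_stack_at <- rep(NA_integer_, s$length)
  open_stack_at[stacks$open] <- seq_len(ns)
  for (a in seq_len(ns)) {
    ii <- stacks$inner_open[a]; jj <- stacks$inner_close[a]
    if (jj - ii < 2L) next
    inside <- seq(ii + 1L, jj - 1L)
    k <- inside[paired[inside]][1L]
    if (is.na(k)) next
    b <- open_stack_at[k]
    if (is.na(b)) next # first paired position closes some other class here
    l <- stacks$close[b]
    if (!(ii < k && k <= l && l < jj)) next
    if (stacks$order[b] != stacks$order[a]) next
    gap5 <- if (k - ii > 1L) seq(ii + 1L, k - 1L) else integer(0)
    gap3 <- if (jj - l > 1L) seq(l + 1L, jj - 1L) else integer(0)
    if (any(paired[gap5]) || any(paired[gap3])) next
    merged_into[a] <- b
  }
  helix_of <- rep(NA_integer_, ns)
  nh <- 0L
  for (a in seq_len(ns)) {
    if (!is.na(helix_of[a])) next
    ## 'a' might itself be a continuation; only start chains at stacks that
    ## nothing merges into
    if (a %in% merged_into) next
    nh <- nh + 1L
    b <- a
    while (!is.na(b)) {
      helix_of[b] <- nh
      b <- merged_into[b]
    }
  }
  stacks$helix <- helix_of
  helices <- split(seq_len(ns), helix_of)
  helices <- helices[order(vapply(helices, function(ix) min(stacks$open[ix]), numeric(1)))]
  names(helices) <- NULL
  list(stacks = stacks, helices = helices)
}

#' Abstract shape of a secondary structure
#'
#' Maps a structure to its abstract shape string at level 1, 3 or 5. Level 5
#' keeps one symbol pair per helix: \code{[} \code{]} for nested helices and
#' an upper/lower case letter pair for each pseudoknot helix (letters A, B,
#' ... by order of first opening position). Level 3 keeps one symbol pair per
#' stack, so helix interruptions (bulges, internal loops) become visible;
#' stacks of one pseudoknot helix repeat that helix's letter. Level 1 adds a
#' \code{_} for every maximal unpaired region (termini included). Symbols are
#' emitted in sequence-position order.
#'
#' @param s an \code{\link{rna_structure}}.
#' @param level abstraction level: 1, 3 or 5.
#' @return a single shape string.
#' @examples
#' shape_of(parse_dotbracket("..((...)).."), 1) # "_[_]_"
#' shape_of(parse_dotbracket("(((...AAAA...)))...aaaa"), 5) # "[A]a"
#' @export
shape_of <- function(s, level = 5) {
  stopifnot(inherits(s, "rna_structure"))
  level <- as.integer(level)
  if (!level %in% c(1L, 3L, 5L)) stop("level must be 1, 3 or 5")
  d <- decompose_helices(s)
  stacks <- d$stacks

  if (nrow(stacks) == 0L) {
    return(if (level == 1L && s$length > 0L) "_" else "")
  }

  ## letters per pseudoknot helix, A, B, ... by first opening position
  helix_open <- vapply(d$helices, function(ix) min(stacks$open[ix]), numeric(1))
  helix_order <- vapply(d$helices, function(ix) stacks$order[ix[1L]], numeric(1))
  pk_helices <- which(helix_order > 0)
  pk_helices <- pk_helices[order(helix_open[pk_helices])]
  if (length(pk_helices) > 26L) {
    stop("more than 26 pseudoknot helices: letter alphabet exhausted")
  }
  helix_letter <- rep(NA_character_, length(d$helices))
  helix_letter[pk_helices] <- LETTERS[seq_along(pk_helices)]

  if (level == 5L) {
    pos <- symb <- NULL
    for (h in seq_along(d$helices)) {
      ix <- d$helices[[h]]
      op <- min(stacks$open[ix]); cl <- max(stacks$close[ix])
      if (is.na(helix_letter[h])) {
        pos <- c(pos, op, cl); symb <- c(symb, "[", "]")
      } else {
        pos <- c(pos, op, cl)
        symb <- c(symb, helix_letter[h], tolower(helix_letter[h]))
      }
    }
  } else {
    pos <- symb <- NULL
    for (r in seq_len(nrow(stacks))) {
      h <- stacks$helix[r]
      if (is.na(helix_letter[h])) {
        pos <- c(pos, stacks$open[r], stacks$close[r]); symb <- c(symb, "[", "]")
      } else {
        pos <- c(pos, stacks$open[r], stacks$close[r])
        symb <- c(symb, helix_letter[h], tolower(helix_letter[h]))
      }
    }
    if (level == 1L) {
      paired <- paired_mask(s)
      r <- rle(paired)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(!r$values)) {
        pos <- c(pos, starts[k]); symb <- c(symb, "_")
      }
    }
  }
  paste(symb[order(pos)], collapse = "")
}

#' Does a shape string contain a pseudoknot?
#'
#' @param shape a shape string as returned by \code{\link{shape_of}}.
#' @return \code{TRUE} iff the shape contains a pseudoknot letter class.
#' @export
is_pseudoknotted_shape <- function(shape) {
  grepl("[A-Za-z]", shape)
}
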
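## Shape classes over the pooled folding space of a family, their feature
## vectors, and the F-score used to rank features by discriminative power.

#' Group ensemble structures into shape classes
#'
#' Pools every candidate structure of every ensemble and partitions them by
#' abstract shape at the given level. For a shape P the class records its
#' associated sequences (ids of sequences with at least one structure of shape
#' P) and all structures with shape P.
#'
#' @param ensembles list of \code{\link{rna_ensemble}} objects.
#' @param level abstraction level (1, 3 or 5) used as the class key.
#' @param max_subopt per sequence, only the optimal structure plus this many
#'   suboptimal structures enter the shape space (\code{Inf} to disable).
#' @return a list of \code{shape_class} objects, ordered by descending F1
#'   (number of member sequences), ties broken by shape string. Each has
#'   \code{shape}, \code{level}, \code{seq_ids}, \code{members} (a list of
#'   \code{list(id, structure, energy, rank)}) and \code{features} (see
#'   \code{\link{compute_features}}).
#' @export
group_by_shape <- function(ensembles, level = 5, max_subopt = Inf) {
  stopifnot(length(ensembles) >= 1L)
  keys <- character(0)
  classes <- list()
  for (e in ensembles) {
    sts <- e$structures
    if (is.finite(max_subopt)) sts <- utils::head(sts, max_subopt + 1L)
    for (st in sts) {
      p <- shape_of(st$structure, level)
      k <- match(p, keys)
      if (is.na(k)) {
        keys <- c(keys, p)
        k <- length(keys)
        classes[[k]] <- list(shape = p, level = as.integer(level),
                             seq_ids = character(0), members = list())
      }
      classes[[k]]$seq_ids <- union(classes[[k]]$seq_ids, e$id)
      classes[[k]]$members[[length(classes[[k]]$members) + 1L]] <-
        list(id = e$id, structure = st$structure, energy = st$energy,
             rank = st$rank)
    }
  }
  for (k in seq_along(classes)) {
    classes[[k]]$features <- compute_features(classes[[k]], ensembles)
    class(classes[[k]]) <- "shape_class"
  }
  f1 <- vapply(classes, function(cl) cl$features[["F1"]], numeric(1))
  classes[order(-f1, keys)]
}

#' @export
print.shape_class <- function(x, ...) {
  cat(sprintf("<shape_class> %s (level %d): %d sequences, %d structures\n",
              x$shape, x$level, length(x$seq_ids), length(x$members)))
  invisible(x)
}

#' Feature vector of a shape class
#'
#' The four selected features of the shape ranking model:
#' \describe{
#'   \item{F1}{contribution of sequences: number of sequences with at least
#'     one structure in the class.}
#'   \item{F2}{contribution of structures: number of structures in the class.}
#'   \item{F3}{average free energy over the class's structures (kcal/mol).}
#'   \item{F4}{average, over the class's member sequences, of each sequence's
#'     minimum free energy -- the minimum over \emph{all} structures of that
#'     sequence's ensemble, not only those in the class.}
#' }
#' Optional extras (off by default) can stand in for a larger feature pool:
#' \code{min_energy} (class minimum), \code{mean_rank} (mean ensemble rank of
#' member structures), \code{coverage} (F1 / number of ensembles), and
#' \code{energy_sd}.
#'
#' @param cl a \code{shape_class}.
#' @param ensembles the ensembles the class was built from (needed for the
#'   per-sequence MFE in F4).
#' @param extras character vector of extra feature names to include.
#' @return named numeric vector.
#' @export
compute_features <- function(cl, ensembles, extras = character(0)) {
  if (!length(cl$members)) stop("empty shape class")
  energies <- vapply(cl$members, function(m) m$energy, numeric(1))
  ids <- vapply(ensembles, function(e) e$id, character(1))
  mfe <- vapply(ensembles, ensemble_mfe, numeric(1))
  names(mfe) <- ids
  if (!all(cl$seq_ids %in% ids)) stop("class references sequences not in ensembles")
  out <- c(
    F1 = length(cl$seq_ids),
    F2 = length(cl$members),
    F3 = mean(energies),
    F4 = mean(mfe[cl$seq_ids])
  )
  extra_pool <- list(
    min_energy = function() min(energies),
    mean_rank = function() mean(vapply(cl$members, function(m) m$rank, numeric(1))),
    coverage = function() length(cl$seq_ids) / length(ensembles),
    energy_sd = function() if (length(energies) > 1L) stats::sd(energies) else 0
  )
  for (nm in extras) {
    if (is.null(extra_pool[[nm]])) stop("unknown extra feature '", nm, "'")
    out[nm] <- extra_pool[[nm]]()
  }
  out
}

#' F-score of a feature
#'
#' Discriminative power of a single feature against a binary labelling:
#' \deqn{F = \frac{(\bar x^{(+)} - \bar x)^2 + (\bar x^{(-)} - \bar x)^2}{
#'   \frac{1}{n_+ - 1}\sum_k (x^{(+)}_k - \bar x^{(+)})^2 +
#'   \frac{1}{n_- - 1}\sum_k (x^{(-)}_k - \bar x^{(-)})^2}}
#' where \eqn{\bar x}, \eqn{\bar x^{(+)}}, \eqn{\bar x^{(-)}} are the overall,
#' positive-class and negative-class means. A zero denominator (both classes
#' constant) is floored at \code{eps} so perfectly separating features keep a
#' large, finite score.
#'
#' @param values numeric feature values, one per instance.
#' @param labels +1 / -1 labels, one per instance.
#' @param eps denominator floor.
#' @return the F-score (>= 0).
#' @export
f_score <- function(values, labels, eps = 1e-12) {
  stopifnot(length(values) == length(labels), all(labels %in% c(-1, 1)))
  xp <- values[labels == 1]
  xn <- values[labels == -1]
  if (length(xp) < 2L || length(xn) < 2L) {
    stop("need at least 2 instances in each class")
  }
  num <- (mean(xp) - mean(values))^2 + (mean(xn) - mean(values))^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
    sum((xn - mean(xn))^2) / (length(xn) - 1)
  num / max(den, eps)
}

#' Min-max feature normalization
#'
#' Scales each feature column to [0, 1]. In fit mode (\code{params = NULL})
#' the per-feature minima and maxima are computed from the data; in apply mode
#' the supplied parameters are used and values outside the fitted range are
#' clipped. A constant feature maps to 0.5.
#'
#' @param x numeric matrix (instances x features) with column names.
#' @param params optional list with numeric vectors \code{min} and \code{max}
#'   named by feature.
#' @return list with the scaled \code{x} and the \code{params} used.
#' @export
normalize_features <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one row")
  if (is.null(colnames(x))) stop("feature matrix must have column names")
  if (is.null(params)) {
    params <- list(min = apply(x, 2L, min), max = apply(x, 2L, max))
  }
  lo <- params$min[colnames(x)]
  hi <- params$max[colnames(x)]
  if (anyNA(lo) || anyNA(hi)) stop("normalization parameters missing for some features")
  out <- x
  for (k in seq_len(ncol(x))) {
    if (hi[k] > lo[k]) {
      v <- (x[, k] - lo[k]) / (hi[k] - lo[k])
      out[, k] <- pmin(1, pmax(0, v))
    } else {
      out[, k] <- 0.5
    }
  }
  list(x = out, params = params)
}

#' Write a shape-class feature table
#'
#' Serializes shape classes as a TSV with the shape string in the first
#' column, one row per class, one column per feature.
#'
#' @param classes list of \code{shape_class} objects.
#' @param path output file.
#' @export
write_feature_table <- function(classes, path) {
  feats <- do.call(rbind, lapply(classes, function(cl) cl$features))
  df <- data.frame(shape = vapply(classes, function(cl) cl$shape, character(1)),
                   feats, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
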
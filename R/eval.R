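## Evaluation: base-pair sensitivity / PPV against reference structures and
## exact-match shape accuracy against reference shapes.

#' Base-pair sensitivity and PPV
#'
#' Compares predicted and reference structures by exact (i, j) pair identity;
#' pseudoknot order is ignored (pairing, not page assignment, is evaluated)
#' and no helix-slip tolerance is applied. TP = |pred pairs intersect ref
#' pairs|, FP = |pred \ ref|, FN = |ref \ pred|; sensitivity = TP / (TP + FN),
#' PPV = TP / (TP + FP). A metric with a zero denominator is reported as
#' \code{NA} (undefined), not 0.
#'
#' @param pred,ref \code{\link{rna_structure}} objects of equal length.
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{sensitivity},
#'   \code{ppv}.
#' @export
base_pair_metrics <- function(pred, ref) {
  stopifnot(inherits(pred, "rna_structure"), inherits(ref, "rna_structure"))
  if (pred$length != ref$length) {
    stop("length mismatch: predicted ", pred$length, " vs reference ", ref$length)
  }
  key <- function(s) {
    if (!nrow(s$pairs)) return(character(0))
    paste(s$pairs[, 1L], s$pairs[, 2L])
  }
  kp <- key(pred); kr <- key(ref)
  tp <- length(intersect(kp, kr))
  fp <- length(kp) - tp
  fn <- length(kr) - tp
  list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  )
}

#' Shape prediction accuracy
#'
#' Fraction of positions at which the predicted shape string equals the
#' reference exactly.
#'
#' @param predicted,reference character vectors of shape strings, paired by
#'   position.
#' @return fraction in [0, 1].
#' @export
shape_accuracy <- function(predicted, reference) {
  if (!length(predicted)) stop("empty shape lists")
  if (length(predicted) != length(reference)) {
    stop("predicted and reference lists differ in length")
  }
  mean(predicted == reference)
}

#' Per-sequence and aggregate structure metrics
#'
#' @param pred,ref named lists of \code{\link{rna_structure}} objects; metrics
#'   are computed on the shared names.
#' @return data frame with one row per sequence (\code{id}, \code{tp},
#'   \code{fp}, \code{fn}, \code{sensitivity}, \code{ppv}) followed by
#'   \code{mean} and \code{median} aggregate rows.
#' @export
eval_structures <- function(pred, ref) {
  ids <- intersect(names(pred), names(ref))
  if (!length(ids)) stop("no shared sequence ids between prediction and reference")
  rows <- lapply(ids, function(id) {
    m <- base_pair_metrics(pred[[id]], ref[[id]])
    data.frame(id = id, tp = m$tp, fp = m$fp, fn = m$fn,
               sensitivity = m$sensitivity, ppv = m$ppv)
  })
  df <- do.call(rbind, rows)
  agg <- function(label, f) {
    data.frame(id = label, tp = NA, fp = NA, fn = NA,
               sensitivity = f(df$sensitivity, na.rm = TRUE),
               ppv = f(df$ppv, na.rm = TRUE))
  }
  rbind(df, agg("mean", mean), agg("median", stats::median))
}
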
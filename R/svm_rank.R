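## Shape ranking with a linear SVM: F-score guided sequential forward search
## over the feature pool, grid search for the regularization constant with
## stratified 5-fold cross validation, and a signed-distance score
## sc = w . x + b used to rank candidate shape classes.

## fold assignment stratified by family so all shape classes of one family
## land in the same fold (no leakage between a family's classes)
make_folds <- function(family, folds, seed) {
  fam <- unique(family)
  set.seed(seed)
  fam <- sample(fam)
  fold_of_family <- rep_len(seq_len(folds), length(fam))
  names(fold_of_family) <- fam
  unname(fold_of_family[family])
}

## linear SVM fit; returns weights oriented so that sc > 0 predicts label +1
fit_linear_svm <- function(x, y, C) {
  fit <- e1071::svm(x, factor(y, levels = c(1, -1)),
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## e1071 orients decision values towards the first observed class; make
  ## the orientation explicit by checking the decision-value column name
  dv <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (startsWith(colnames(dv)[1L], "-1")) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  list(w = w, b = b, fit = fit)
}

## mean accuracy over pre-assigned folds for one feature subset and one C
cv_accuracy <- function(x, y, fold_id, C) {
  accs <- numeric(0)
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L) next
    m <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], C)
    sc <- drop(x[!tr, , drop = FALSE] %*% m$w) + m$b
    pred <- ifelse(sc > 0, 1, -1)
    accs <- c(accs, mean(pred == y[!tr]))
  }
  if (!length(accs)) stop("no fold had both classes in its training split")
  mean(accs)
}

## best C on the grid by mean CV accuracy; ties go to the smaller C
cv_grid <- function(x, y, fold_id, C_grid) {
  C_grid <- sort(C_grid)
  accs <- vapply(C_grid, function(C) cv_accuracy(x, y, fold_id, C), numeric(1))
  k <- which.max(accs)
  list(C = C_grid[k], accuracy = accs[k])
}

#' Sequential forward feature selection
#'
#' Ranks candidate features by \code{\link{f_score}} and grows the feature set
#' greedily: in each round every remaining feature is trial-added (in
#' descending F-score order), the addition giving the highest cross-validation
#' accuracy is kept, and the search stops at the first round in which no
#' addition improves the accuracy. Accuracy is evaluated with a linear SVM,
#' grid-searched C, and folds stratified by family.
#'
#' @param instances data frame of labeled shape classes: one column per
#'   feature, a \code{label} column (+1 / -1) and a \code{family} column.
#' @param features candidate feature names (default: all columns except
#'   \code{label} and \code{family}).
#' @param C_grid candidate regularization constants.
#' @param folds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return list with the ordered \code{features} chosen, their CV
#'   \code{accuracy}, and the per-feature \code{f_scores}.
#' @export
sfs_select <- function(instances, features = NULL,
                       C_grid = 2^seq(-5, 5, by = 2), folds = 5, seed = 1) {
  if (is.null(features)) {
    features <- setdiff(colnames(instances), c("label", "family"))
  }
  if (length(features) < 2L) stop("need at least 2 candidate features")
  y <- instances$label
  fs <- vapply(features, function(f) f_score(instances[[f]], y), numeric(1))
  cand <- features[order(-fs)]
  x_all <- as.matrix(instances[, features, drop = FALSE])
  x_all <- normalize_features(x_all)$x
  fold_id <- make_folds(instances$family, folds, seed)

  chosen <- character(0)
  best_acc <- -Inf
  repeat {
    remaining <- setdiff(cand, chosen)
    if (!length(remaining)) break
    trial_acc <- vapply(remaining, function(f) {
      cv_grid(x_all[, c(chosen, f), drop = FALSE], y, fold_id, C_grid)$accuracy
    }, numeric(1))
    k <- which.max(trial_acc) # first maximum = highest F-score on ties
    if (trial_acc[k] > best_acc) {
      chosen <- c(chosen, remaining[k])
      best_acc <- trial_acc[k]
    } else {
      break
    }
  }
  list(features = chosen, accuracy = best_acc, f_scores = fs)
}

#' Train the shape-ranking model
#'
#' Trains a maximum-margin linear classifier on labeled shape classes. The
#' regularization constant is chosen from \code{C_grid} by mean 5-fold
#' cross-validation accuracy with folds stratified by family; features are
#' min-max normalized (parameters stored in the model and re-applied, with
#' clipping, at prediction time). When \code{features} is \code{NULL} the
#' feature subset is chosen by \code{\link{sfs_select}}.
#'
#' @inheritParams sfs_select
#' @param features feature names to use, or \code{NULL} for sequential forward
#'   selection.
#' @return an object of class \code{shape_model}: \code{weights} (named),
#'   \code{bias}, \code{features}, \code{norm} (per-feature min/max),
#'   \code{C}, \code{cv_accuracy}, \code{folds}, \code{seed}, \code{version}.
#' @export
train_shape_model <- function(instances, features = NULL,
                              C_grid = 2^seq(-5, 5, by = 2), folds = 5,
                              seed = 1) {
  y <- instances$label
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (sum(y == 1) < 2L || sum(y == -1) < 2L) {
    stop("need at least 2 instances per label")
  }
  if (is.null(instances$family)) instances$family <- seq_len(nrow(instances))

  all_feats <- setdiff(colnames(instances), c("label", "family"))
  if (is.null(features)) {
    if (length(all_feats) >= 2L) {
      features <- sfs_select(instances, all_feats, C_grid, folds, seed)$features
    } else {
      features <- all_feats
    }
  }
  x_raw <- as.matrix(instances[, features, drop = FALSE])
  nf <- normalize_features(x_raw)
  fold_id <- make_folds(instances$family, folds, seed)
  grid <- cv_grid(nf$x, y, fold_id, C_grid)
  final <- fit_linear_svm(nf$x, y, grid$C)
  structure(
    list(weights = final$w, bias = final$b, features = features,
         norm = list(min = nf$params$min[features],
                     max = nf$params$max[features]),
         C = grid$C, cv_accuracy = grid$accuracy, folds = folds, seed = seed,
         version = "0.1.0"),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> features: %s; C = %g; CV accuracy = %.3f\n",
              paste(x$features, collapse = ", "), x$C, x$cv_accuracy))
  cat(sprintf("  sc = %s %+.4g\n",
              paste(sprintf("%+.4g*%s", x$weights, x$features), collapse = " "),
              x$bias))
  invisible(x)
}

#' Save or load a shape-ranking model
#'
#' Models are stored as flat JSON text (feature names, weights, bias, C,
#' normalization parameters, seed, version); numeric values are serialized at
#' full double precision so reloaded models score bit-identically.
#'
#' @param model a \code{shape_model}.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  ## doubles go through "%.17g" text so a reloaded model scores bit-identically
  num <- function(v) sprintf("%.17g", v)
  obj <- list(
    version = model$version,
    features = as.list(model$features),
    weights = as.list(stats::setNames(num(model$weights), model$features)),
    bias = num(model$bias),
    C = num(model$C),
    cv_accuracy = num(model$cv_accuracy),
    norm_min = as.list(stats::setNames(num(model$norm$min), model$features)),
    norm_max = as.list(stats::setNames(num(model$norm$max), model$features)),
    folds = model$folds,
    seed = model$seed
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  feats <- as.character(obj$features)
  structure(
    list(weights = stats::setNames(as.numeric(obj$weights[feats]), feats),
         bias = as.numeric(obj$bias), features = feats,
         norm = list(min = stats::setNames(as.numeric(obj$norm_min[feats]), feats),
                     max = stats::setNames(as.numeric(obj$norm_max[feats]), feats)),
         C = as.numeric(obj$C), cv_accuracy = as.numeric(obj$cv_accuracy),
         folds = as.integer(obj$folds), seed = as.integer(obj$seed),
         version = as.character(obj$version)),
    class = "shape_model"
  )
}

#' The packaged default shape-ranking model
#'
#' A model pre-trained on families from \code{\link{generate_family}} so that
#' \code{\link{predict_shape}} and \code{\link{knotstructure}} work out of the
#' box; retrain with \code{\link{train_shape_model}} on your own labeled data
#' for production use.
#'
#' @return a \code{shape_model}.
#' @export
default_shape_model <- function() {
  read_model(system.file("extdata", "default_model.json",
                         package = "knotshape", mustWork = TRUE))
}

#' Score a shape class against the classification hyperplane
#'
#' Computes sc = w . x + b on the model's selected features after applying the
#' stored min-max normalization (values outside the fitted range are clipped).
#' The sign of sc is the predicted label; its magnitude is proportional to the
#' distance from the hyperplane.
#'
#' @param model a \code{shape_model}.
#' @param x a \code{shape_class}, or a named numeric feature vector.
#' @return the scalar score sc.
#' @export
score_shape <- function(model, x) {
  if (inherits(x, "shape_class")) x <- x$features
  missing <- setdiff(model$features, names(x))
  if (length(missing)) {
    stop("missing feature '", missing[1L], "' required by the model")
  }
  xm <- matrix(x[model$features], nrow = 1L,
               dimnames = list(NULL, model$features))
  xn <- normalize_features(xm, model$norm)$x
  drop(xn %*% model$weights) + model$bias
}

#' Rank candidate shapes for a family (KnotShape)
#'
#' Builds shape classes from the folding ensembles, computes their features,
#' scores every class with the linear model and returns the classes ranked by
#' sc (descending; ties broken by larger F1, then shape string). The top-ranked
#' shape is the predicted consensus shape. When no class is predicted positive
#' the top-scoring shape is still reported, with a warning.
#'
#' @param ensembles list of \code{\link{rna_ensemble}} objects.
#' @param model a \code{shape_model}; \code{NULL} for the packaged default.
#' @param level abstraction level of the shape classes (1, 3 or 5).
#' @param max_subopt per sequence, keep the optimal plus this many suboptimal
#'   structures.
#' @return a data frame with one row per candidate shape: \code{shape},
#'   \code{sc}, \code{positive} and the feature columns, ordered best first;
#'   the shape classes are attached as attribute \code{"classes"} in the same
#'   order.
#' @export
predict_shape <- function(ensembles, model = NULL, level = 5, max_subopt = 10) {
  if (is.null(model)) model <- default_shape_model()
  classes <- group_by_shape(ensembles, level, max_subopt)
  sc <- vapply(classes, function(cl) score_shape(model, cl), numeric(1))
  feats <- do.call(rbind, lapply(classes, function(cl) cl$features))
  shapes <- vapply(classes, function(cl) cl$shape, character(1))
  out <- data.frame(shape = shapes, sc = sc, positive = sc > 0, feats,
                    check.names = FALSE, stringsAsFactors = FALSE)
  o <- order(-out$sc, -out$F1, out$shape)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  if (!any(out$positive)) {
    warning("no shape class predicted positive; reporting the top-scoring shape")
  }
  attr(out, "classes") <- classes[o]
  out
}
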
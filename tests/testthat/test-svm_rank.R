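sep_instances <- function(n = 20, seed = 3) {
  set.seed(seed)
  label <- rep(c(1, -1), each = n / 2)
  data.frame(x = label + rnorm(n, sd = 0.1), noise = rnorm(n),
             label = label, family = seq_len(n))
}

test_that("training on separable data yields a correct signed score", {
  inst <- data.frame(x = c(1, 1.1, 0, -0.1), noise = c(0, 0, 0, 0),
                     label = c(1, 1, -1, -1), family = 1:4)
  m <- train_shape_model(inst, features = "x", folds = 2, seed = 1)
  expect_gt(score_shape(m, c(x = 1)), 0)
  expect_lt(score_shape(m, c(x = 0)), 0)
})

test_that("flipping labels negates the decision function", {
  inst <- sep_instances()
  m1 <- train_shape_model(inst, features = "x", seed = 2)
  inst2 <- inst
  inst2$label <- -inst2$label
  m2 <- train_shape_model(inst2, features = "x", seed = 2)
  for (v in c(-0.5, 0, 0.8)) {
    expect_equal(score_shape(m1, c(x = v)), -score_shape(m2, c(x = v)),
                 tolerance = 1e-6)
  }
})

test_that("CV accuracy on two overlapping Gaussians approaches the Bayes rate", {
  set.seed(42)
  n <- 200
  label <- rep(c(1, -1), each = n / 2)
  inst <- data.frame(x = rnorm(n, mean = label, sd = 0.5),
                     label = label, family = seq_len(n))
  m <- train_shape_model(inst, features = "x", seed = 9)
  bayes <- pnorm(2) # P(N(1, .5) > 0) with the midpoint threshold
  expect_gt(m$cv_accuracy, bayes - 0.05)
  expect_lt(m$cv_accuracy, bayes + 0.05)
})

test_that("train rejects degenerate inputs", {
  inst <- data.frame(x = 1:4, label = c(1, 1, 1, 1), family = 1:4)
  expect_error(train_shape_model(inst, features = "x"), "single class")
})

test_that("sfs_select keeps separating features and drops pure noise", {
  inst <- sep_instances(n = 40, seed = 8)
  sel <- sfs_select(inst, folds = 5, seed = 4)
  expect_equal(sel$features, "x")
  expect_gt(sel$accuracy, 0.9)

  # chosen subset is at least as good as every single feature alone
  set.seed(10)
  n <- 40
  label <- rep(c(1, -1), each = n / 2)
  inst <- data.frame(
    f1 = label + rnorm(n, sd = 0.8), f2 = label + rnorm(n, sd = 1.5),
    f3 = rnorm(n), f4 = label + rnorm(n, sd = 0.5),
    label = label, family = seq_len(n)
  )
  sel <- sfs_select(inst, folds = 5, seed = 4)
  singles <- vapply(c("f1", "f2", "f3", "f4"), function(f) {
    m <- train_shape_model(inst, features = f, seed = 4)
    m$cv_accuracy
  }, numeric(1))
  expect_gte(sel$accuracy, max(singles) - 1e-9)
})

test_that("all-noise features give chance-level accuracy", {
  set.seed(12)
  n <- 60
  label <- rep(c(1, -1), each = n / 2)
  inst <- data.frame(f1 = rnorm(n), f2 = rnorm(n),
                     label = label, family = seq_len(n))
  sel <- sfs_select(inst, folds = 5, seed = 6)
  expect_gte(length(sel$features), 1L)
  expect_lt(abs(sel$accuracy - 0.5), 0.15)
})

test_that("score_shape is the normalized affine form w.x + b", {
  m <- structure(
    list(weights = c(F1 = 1, F2 = 0, F3 = 0, F4 = 0), bias = 0,
         features = c("F1", "F2", "F3", "F4"),
         norm = list(min = c(F1 = 0, F2 = 0, F3 = -10, F4 = -10),
                     max = c(F1 = 1, F2 = 1, F3 = 0, F4 = 0)),
         C = 1, cv_accuracy = 1, folds = 5, seed = 1, version = "0.1.0"),
    class = "shape_model"
  )
  expect_equal(score_shape(m, c(F1 = 0.7, F2 = 0.2, F3 = -5, F4 = -5)), 0.7)
  m$weights[] <- 0
  m$bias <- 0.3
  expect_equal(score_shape(m, c(F1 = 0.1, F2 = 0.9, F3 = -1, F4 = -9)), 0.3)
  expect_error(score_shape(m, c(F1 = 1, F2 = 1, F3 = 1)), "missing feature 'F4'")

  # affine in each feature: doubling the normalized coordinate doubles its part
  m$weights <- c(F1 = 2, F2 = 0, F3 = 0, F4 = 0)
  m$bias <- 0
  expect_equal(score_shape(m, c(F1 = 0.5, F2 = 0, F3 = 0, F4 = 0)) * 2,
               score_shape(m, c(F1 = 1, F2 = 0, F3 = 0, F4 = 0)))
})

test_that("models round-trip through JSON bit-identically", {
  inst <- sep_instances(n = 30, seed = 21)
  m <- train_shape_model(inst, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  x <- c(x = 0.37, noise = -1.2)
  expect_identical(score_shape(m, x), score_shape(m2, x))
  expect_equal(m2$C, m$C)
  expect_equal(m2$features, m$features)
})

test_that("predict_shape ranks deterministically and is permutation-invariant", {
  fam <- generate_family(family_spec(seed = 31))
  model <- default_shape_model()
  r1 <- predict_shape(fam$ensembles, model)
  r2 <- predict_shape(rev(fam$ensembles), model)
  expect_equal(r1$shape, r2$shape)
  expect_equal(r1$sc, r2$sc)

  # a family where every sequence has a unique shared shape: only candidate
  fam0 <- generate_family(family_spec(decoys = 0, seed = 32))
  r <- predict_shape(fam0$ensembles, model)
  expect_equal(nrow(r), 1L)
  expect_equal(r$shape, fam0$shape)
})

test_that("a small family far from the training regime still reports a shape", {
  # with 4 sequences the trained decision function stays negative everywhere:
  # the top-scoring shape is reported anyway, with a warning
  fam <- generate_family(family_spec(n = 4, decoys = 1, seed = 35))
  expect_warning(r <- predict_shape(fam$ensembles, default_shape_model()),
                 "no shape class predicted positive")
  expect_equal(r$shape[1], fam$shape)
  expect_false(any(r$positive))
})

test_that("a shape engineered to dominate F1/F2 and minimize F3/F4 ranks first", {
  # model with positive weight on F1, F2 and negative on F3, F4
  m <- structure(
    list(weights = c(F1 = 1, F2 = 1, F3 = -1, F4 = -1), bias = 0,
         features = c("F1", "F2", "F3", "F4"),
         norm = list(min = c(F1 = 0, F2 = 0, F3 = -20, F4 = -20),
                     max = c(F1 = 10, F2 = 20, F3 = 0, F4 = 0)),
         C = 1, cv_accuracy = 1, folds = 5, seed = 1, version = "0.1.0"),
    class = "shape_model"
  )
  # hand-built family: the planted hairpin shape is in all 3 sequences at the
  # lowest energy; the open decoy shape is in only 2, at higher energy
  hp <- parse_dotbracket("((((...))))...")
  open <- rna_structure(14)
  nt <- "GGGGAAACCCCAAA"
  ens <- list(
    rna_ensemble("a", nt, list(list(structure = hp, energy = -10),
                               list(structure = open, energy = -8))),
    rna_ensemble("b", nt, list(list(structure = hp, energy = -10),
                               list(structure = open, energy = -8))),
    rna_ensemble("c", nt, list(list(structure = hp, energy = -10)))
  )
  r <- suppressWarnings(predict_shape(ens, m))
  expect_equal(r$shape[1], "[]")
  # sc ordering agrees with direct computation from the class features
  expect_equal(r$sc[1], score_shape(m, attr(r, "classes")[[1]]))
  expect_gt(score_shape(m, c(F1 = 3, F2 = 3, F3 = -10, F4 = -10)),
            score_shape(m, c(F1 = 2, F2 = 2, F3 = -8, F4 = -10)))
})
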
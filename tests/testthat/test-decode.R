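test_that("the hyperparameter grid matches the published search ranges", {
  g <- svm_grid()
  expect_equal(nrow(g), 806)            # 31 cost x 26 gamma exponents
  expect_equal(sort(unique(log2(g$cost))), -10:20)
  expect_equal(sort(unique(log2(g$gamma))), -15:10)
  expect_equal(nrow(svm_grid(0, c(-1, 0))), 2)
})

test_that("task datasets pool movements for detection and drop rest for fingers", {
  labs <- c(rep("rest", 12), rep(c("thumb", "index", "middle", "ring", "little"),
                                 times = 3))
  tasks <- build_tasks(list(labels = labs))
  expect_equal(length(tasks$detection$idx), 27)
  expect_equal(as.vector(table(tasks$detection$labels)), c(15, 12))
  expect_equal(length(tasks$fingers$idx), 15)
  expect_false("rest" %in% tasks$fingers$labels)
  expect_equal(nlevels(tasks$fingers$labels), 5)
  expect_error(build_tasks(list(labels = labs[labs != "ring"])), "ring")
})

test_that("feature assembly is kind-major, channel-minor with provenance", {
  w <- array(seq_len(4 * 3 * 2), c(4, 3, 2))
  proj <- structure(list(weights = w, K = 2, labels = rep(c("a", "b"), 2),
                         channel_labels = c("C3", "C1", "Cz"), montage = NULL),
                    class = "projection_table")
  bp <- structure(list(values = matrix(1, 4, 3), band = "alpha",
                       labels = rep(c("a", "b"), 2),
                       channel_labels = c("C3", "C1", "Cz"), montage = NULL),
                  class = "band_power_table")
  fm <- assemble_features(projection = proj, bands = list(alpha = bp),
                          selection = list(PC1 = c("Cz", "C3"), PC2 = "C1",
                                           alpha = c("C3", "C1")),
                          kinds = c("alpha", "PC2", "PC1"))
  expect_equal(colnames(fm$X),
               c("PC1.Cz", "PC1.C3", "PC2.C1", "alpha.C3", "alpha.C1"))
  expect_equal(fm$provenance$kind, c("PC1", "PC1", "PC2", "alpha", "alpha"))
  expect_equal(fm$X[, "PC1.Cz"], w[, 3, 1])
  expect_equal(fm$X[, "PC2.C1"], w[, 2, 2])
  expect_error(assemble_features(projection = proj, selection = character(0),
                                 kinds = "PC1"), "empty")
  expect_error(assemble_features(projection = proj, selection = "XX",
                                 kinds = "PC1"), "XX")
})

test_that("scaling maps the training range onto [-1, 1] and extrapolates", {
  X <- cbind(a = c(0, 10, 5), b = c(7, 7, 7))
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  expect_equal(Xs[, "a"], c(-1, 1, 0))
  expect_equal(Xs[, "b"], c(0, 0, 0))        # constant feature -> 0
  expect_equal(unname(apply_scaler(cbind(a = 20, b = 1), sc)[1, "a"]), 3)
})

test_that("binary training grid-searches deterministically and flags degenerate input", {
  set.seed(5)
  X <- rbind(matrix(rnorm(80, 0), 40), matrix(rnorm(80, 4), 40))
  y <- factor(rep(c("m", "r"), each = 40))
  fit <- train_binary(X, y, grid = svm_grid(c(-2, 0, 2), c(-4, -2)),
                      inner_folds = 4, seed = 2)
  expect_gte(fit$inner_accuracy, 0.99)
  fit2 <- train_binary(X, y, grid = svm_grid(c(-2, 0, 2), c(-4, -2)),
                       inner_folds = 4, seed = 2)
  expect_identical(c(fit$cost, fit$gamma), c(fit2$cost, fit2$gamma))

  yshuf <- withr::with_seed(9, sample(y))
  fits <- train_binary(X, yshuf, grid = svm_grid(c(0, 2), c(-4, -2)),
                       inner_folds = 4, seed = 2)
  expect_gt(fits$inner_accuracy, 0.35)
  expect_lt(fits$inner_accuracy, 0.65)
  expect_error(train_binary(X, factor(rep("m", 80))), "single class")
})

test_that("one-vs-one voting trains all pairs and follows the tie rule", {
  set.seed(8)
  centers <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 8, 8), 5, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:5, function(k) {
    sweep(matrix(rnorm(40, sd = 0.3), 20), 2, centers[k, ], "+")
  }))
  y <- factor(rep(letters[1:5], each = 20))
  ovo <- ovo_train(X, y, grid = svm_grid(2, -1))
  expect_length(ovo$models, choose(5, 2))
  pred <- ovo_predict(ovo, X)
  expect_gt(mean(pred == y), 0.95)
  expect_error(
    ovo_predict(structure(list(models = ovo$models[1:9], levels = ovo$levels),
                          class = "ovo_model"), X),
    "missing")

  # constructed 3-class cycle: every class gets one vote; summed signed
  # decision values break the tie (here favouring class "c")
  mock <- function(pair, winner, dv) {
    structure(list(pair = pair, winner = winner, dv = dv), class = "mock_svm")
  }
  assign("predict.mock_svm", function(object, newdata, ...) {
    n <- nrow(newdata)
    out <- factor(rep(object$winner, n), levels = object$pair)
    dv <- matrix(rep(object$dv, n), ncol = 1)
    colnames(dv) <- paste(object$pair, collapse = "/")
    attr(out, "decision.values") <- dv
    out
  }, envir = globalenv())
  withr::defer(rm("predict.mock_svm", envir = globalenv()))
  cyc <- structure(list(models = list(
    "a|b" = list(model = mock(c("a", "b"), "a", 0.2)),
    "a|c" = list(model = mock(c("a", "c"), "c", -0.9)),
    "b|c" = list(model = mock(c("b", "c"), "b", 0.3))
  ), levels = c("a", "b", "c")), class = "ovo_model")
  x1 <- matrix(0, 1, 2)
  # votes a=1, b=1, c=1; dv sums: a = 0.2 - 0.9 = -0.7, b = -0.2 + 0.3 = 0.1,
  # c = 0.9 - 0.3 = 0.6 -> "c"
  expect_equal(as.character(ovo_predict(cyc, x1)), "c")

  # unanimity: all classifiers voting one class elects it
  uni <- structure(list(models = list(
    "a|b" = list(model = mock(c("a", "b"), "b", -1)),
    "a|c" = list(model = mock(c("a", "c"), "a", 5)),
    "b|c" = list(model = mock(c("b", "c"), "b", 2))
  ), levels = c("a", "b", "c")), class = "ovo_model")
  expect_equal(as.character(ovo_predict(uni, x1)), "b")
})

test_that("cross-validation is stratified, deterministic, and calibrated", {
  set.seed(30)
  # perfectly separable -> accuracy 1
  Xs <- rbind(matrix(rnorm(100, 0, 0.2), 50), matrix(rnorm(100, 5, 0.2), 50))
  ys <- factor(rep(c("m", "r"), each = 50))
  cvs <- cross_validate(Xs, ys, folds = 5, repeats = 2, seed = 4,
                        grid = svm_grid(2, -2))
  expect_equal(cvs$mean_accuracy, 1.0)
  expect_equal(dim(cvs$fold_accuracy), c(2, 5))

  # confusion-matrix bookkeeping: columns sum to per-class test counts
  expect_equal(colSums(cvs$confusion), c(m = 100, r = 100))
  expect_equal(sum(diag(cvs$confusion)) / sum(cvs$confusion),
               cvs$pooled_accuracy)

  # pure-noise features, balanced binary: mean accuracy near chance
  Xn <- matrix(rnorm(200 * 4), 200)
  yn <- factor(rep(c("m", "r"), each = 100))
  cvn <- cross_validate(Xn, yn, folds = 5, repeats = 6, seed = 7,
                        grid = svm_grid(0, -2))
  expect_gt(cvn$mean_accuracy, 0.40)
  expect_lt(cvn$mean_accuracy, 0.60)

  # exact reproducibility
  cvn2 <- cross_validate(Xn, yn, folds = 5, repeats = 6, seed = 7,
                         grid = svm_grid(0, -2))
  expect_identical(cvn$fold_accuracy, cvn2$fold_accuracy)
  expect_identical(cvn$confusion, cvn2$confusion)

  expect_error(cross_validate(Xn[1:8, ], yn[c(1:4, 101:104)], folds = 5,
                              repeats = 1, seed = 1, grid = svm_grid(0, -2)),
               "fewer members")
})

test_that("accuracy comparisons use the documented t statistics", {
  r <- compare_accuracies(c(0.6, 0.7, 0.8), chance = 0.5)
  expect_equal(unname(r$statistic), 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$parameter[["df"]], 2)

  a <- c(0.71, 0.69, 0.74, 0.70)
  same <- compare_accuracies(a, a)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  b <- c(0.65, 0.66, 0.70, 0.64)
  paired <- compare_accuracies(a, b)
  onesample <- stats::t.test(a - b, mu = 0)
  expect_equal(unname(paired$statistic), unname(onesample$statistic),
               tolerance = 1e-12)
  expect_error(compare_accuracies(a, b[1:3]), "equal-length")
  expect_error(compare_accuracies(a), "chance")
})
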
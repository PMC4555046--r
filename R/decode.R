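#' Hyperparameter grid for the RBF-kernel classifier
#'
#' Candidate (cost, gamma) pairs as base-2 exponent grids; the defaults
#' are exponents -10..20 for the penalty parameter and -15..10 for the
#' kernel width, step 1, i.e. 31 x 26 = 806 candidates. Rows are ordered
#' cost-major so that grid-search tie-breaking (first best) is
#' deterministic.
#'
#' @param cost_exp,gamma_exp Integer exponent vectors.
#' @return Data frame with columns `cost` and `gamma`.
#' @export
svm_grid <- function(cost_exp = -10:20, gamma_exp = -15:10) {
  g <- expand.grid(gamma = 2^gamma_exp, cost = 2^cost_exp,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(cost = g$cost, gamma = g$gamma)
}

#' Build the two decoding datasets from a segment set
#'
#' The detection task pools all finger movements into a `movement` class
#' against `rest`; the finger task keeps the five finger classes and
#' excludes rest.
#'
#' @param segments A `segment_set` (or anything with a `labels` field)
#'   containing rest and all finger conditions.
#' @param fingers The finger labels expected present.
#' @return List of two tasks, each a list with `name`, `idx` (segment
#'   indices) and `labels` (factor).
#' @export
build_tasks <- function(segments,
                        fingers = c("thumb", "index", "middle", "ring", "little")) {
  labs <- segments$labels
  missing <- setdiff(c("rest", fingers), unique(labs))
  if (length(missing))
    stop(sprintf("condition '%s' missing from segments", missing[1]), call. = FALSE)
  det_labels <- factor(ifelse(labs == "rest", "rest", "movement"),
                       levels = c("movement", "rest"))
  fin_idx <- which(labs != "rest")
  list(
    detection = list(name = "detection", idx = seq_along(labs), labels = det_labels),
    fingers = list(name = "fingers", idx = fin_idx,
                   labels = factor(labs[fin_idx], levels = fingers))
  )
}

#' Assemble a feature matrix from spectral feature tables
#'
#' Binds per-channel features of the requested kinds into one
#' segments x features matrix with deterministic column order: kind-major
#' in the canonical order PC1..PCK, alpha, beta; channel-minor in
#' selection order. Feature provenance (kind, channel) is recorded per
#' column.
#'
#' @param projection A `projection_table` (or `NULL` if no PC kinds used).
#' @param bands Named list of `band_power_table`s (`alpha`, `beta`), or
#'   `NULL`.
#' @param selection A `channel_selection`, character vector of channel
#'   labels, or named list mapping kind to either (for per-kind unions).
#' @param kinds Character subset of `c("PC1","PC2","PC3",...,"alpha","beta")`.
#' @return A `feature_matrix`: list with `X` (matrix), `labels`,
#'   `provenance` (data.frame kind/channel).
#' @export
assemble_features <- function(projection = NULL, bands = NULL, selection,
                              kinds) {
  if (length(kinds) == 0) stop("no feature kinds requested", call. = FALSE)
  canonical <- c(paste0("PC", 1:70), "alpha", "beta")
  kinds <- canonical[canonical %in% kinds]
  sel_for <- function(kind) {
    s <- if (is.list(selection) && !inherits(selection, "channel_selection")) {
      selection[[kind]] %||% stop(sprintf("no selection for kind '%s'", kind),
                                  call. = FALSE)
    } else selection
    if (inherits(s, "channel_selection")) s <- s$channels
    if (length(s) == 0) stop("empty channel selection", call. = FALSE)
    s
  }
  cols <- list(); prov <- list(); labels <- NULL; chlab <- NULL
  for (kind in kinds) {
    sel <- sel_for(kind)
    if (grepl("^PC", kind)) {
      if (is.null(projection)) stop("projection table required for PC kinds",
                                    call. = FALSE)
      vals <- feature_channel_values(projection, kind)
      chlab <- projection$channel_labels
      labels <- labels %||% projection$labels
    } else {
      tb <- bands[[kind]]
      if (is.null(tb)) stop(sprintf("band table '%s' required", kind),
                            call. = FALSE)
      vals <- tb$values
      chlab <- tb$channel_labels
      labels <- labels %||% tb$labels
    }
    miss <- setdiff(sel, chlab)
    if (length(miss))
      stop(sprintf("selected channel '%s' absent from tables", miss[1]),
           call. = FALSE)
    idx <- match(sel, chlab)
    cols[[kind]] <- vals[, idx, drop = FALSE]
    prov[[kind]] <- data.frame(kind = kind, channel = sel,
                               stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, cols)
  prov <- do.call(rbind, prov)
  rownames(prov) <- NULL
  colnames(X) <- paste(prov$kind, prov$channel, sep = ".")
  structure(list(X = X, labels = labels, provenance = prov),
            class = "feature_matrix")
}

#' Fit and apply per-feature [-1, 1] scaling
#'
#' `fit_scaler` learns per-feature min and max on training data;
#' `apply_scaler` maps `x` to `2 (x - min) / (max - min) - 1`. Constant
#' training features map to 0; test values outside the training range
#' extrapolate beyond [-1, 1].
#'
#' @param X Training feature matrix.
#' @return `fit_scaler`: a `scaler_params` list with `min` and `max`.
#' @export
fit_scaler <- function(X) {
  if (nrow(X) < 1) stop("need at least one training row", call. = FALSE)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "scaler_params")
}

#' @rdname fit_scaler
#' @param params A `scaler_params` from [fit_scaler()].
#' @return `apply_scaler`: the scaled matrix.
#' @export
apply_scaler <- function(X, params) {
  rng <- params$max - params$min
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- if (rng[j] == 0) 0 else 2 * (X[, j] - params$min[j]) / rng[j] - 1
  }
  out
}

# Seeded stratified fold assignment: within each class, shuffled indices
# dealt round-robin into `folds` folds.
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds)
        stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                     cl, length(idx), folds), call. = FALSE)
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Train a binary RBF-SVM with grid-searched hyperparameters
#'
#' Soft-margin support vector classifier with Gaussian radial-basis
#' kernel. The (cost, gamma) pair is chosen from `grid` by mean accuracy
#' of a seeded stratified inner cross-validation on the training set; ties
#' go to the earliest grid row. Features are assumed pre-scaled (the
#' classifier itself applies no scaling).
#'
#' @param X Training feature matrix (rows = segments).
#' @param y Two-level factor of training labels.
#' @param grid Candidate hyperparameters from [svm_grid()].
#' @param inner_folds Folds of the inner model-selection CV (skipped when
#'   the grid has a single row).
#' @param seed Seed for the inner partition.
#' @return List with `model` (an `e1071::svm` fit on all training data),
#'   `cost`, `gamma`, `inner_accuracy`.
#' @export
train_binary <- function(X, y, grid = svm_grid(), inner_folds = 5, seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training data contain a single class", call. = FALSE)
  best <- grid_search(X, y, grid, inner_folds, seed)
  model <- e1071::svm(x = X, y = y, kernel = "radial",
                      cost = best$cost, gamma = best$gamma, scale = FALSE)
  list(model = model, cost = best$cost, gamma = best$gamma,
       inner_accuracy = best$accuracy)
}

grid_search <- function(X, y, grid, inner_folds, seed) {
  if (nrow(grid) == 1)
    return(list(cost = grid$cost[1], gamma = grid$gamma[1], accuracy = NA_real_))
  fold_of <- stratified_folds(y, inner_folds, seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (fd in seq_len(inner_folds)) {
      tr <- fold_of != fd; te <- !tr
      fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g], scale = FALSE)
      pred <- stats::predict(fit, X[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc)     # first maximum: deterministic tie-break
  list(cost = grid$cost[best], gamma = grid$gamma[best], accuracy = acc[best])
}

#' Train one-vs-one classifiers for all class pairs
#'
#' @param X Training feature matrix.
#' @param y Factor with >= 2 levels.
#' @inheritParams train_binary
#' @return An `ovo_model`: list of pairwise classifiers keyed `"a|b"`,
#'   plus `levels`.
#' @export
ovo_train <- function(X, y, grid = svm_grid(), inner_folds = 5, seed = 1) {
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  models <- list()
  for (p in pairs) {
    idx <- y %in% p
    models[[paste(p, collapse = "|")]] <-
      train_binary(X[idx, , drop = FALSE], factor(y[idx], levels = p),
                   grid, inner_folds, seed)
  }
  structure(list(models = models, levels = lev), class = "ovo_model")
}

#' Predict labels by one-vs-one majority voting
#'
#' Each pairwise classifier casts one vote per row; the label with most
#' votes wins. Ties are broken by the summed signed decision values over
#' the tied labels, then by the smallest class index -- all deterministic.
#'
#' @param ovo An `ovo_model` from [ovo_train()].
#' @param X New feature rows.
#' @return Factor of predicted labels.
#' @export
ovo_predict <- function(ovo, X) {
  lev <- ovo$levels
  n_pairs <- choose(length(lev), 2)
  if (length(ovo$models) != n_pairs)
    stop("one-vs-one model is missing pairwise classifiers", call. = FALSE)
  n <- nrow(X)
  votes <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  dvsum <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  for (key in names(ovo$models)) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    fit <- ovo$models[[key]]$model
    pred <- stats::predict(fit, X, decision.values = TRUE)
    ci <- match(as.character(pred), lev)
    votes[cbind(seq_len(n), ci)] <- votes[cbind(seq_len(n), ci)] + 1L
    dv <- attr(pred, "decision.values")
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    s <- if (identical(first, p[1])) 1 else -1
    dvsum[, p[1]] <- dvsum[, p[1]] + s * dv[, 1]
    dvsum[, p[2]] <- dvsum[, p[2]] - s * dv[, 1]
  }
  out <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      dv_top <- dvsum[i, top]
      top <- top[which(dv_top == max(dv_top))]
    }
    out[i] <- lev[min(top)]
  }
  factor(out, levels = lev)
}

#' Repeated stratified cross-validated decoding
#'
#' Runs `repeats` independent seeded 5-fold stratified partitions. Within
#' every outer fold: optional fold-wise r-squared channel selection on the
#' training portion, feature scaling fitted on the training portion, grid
#' search by inner CV on the training portion, then evaluation on the held
#' out fold. Binary tasks use a single classifier, multiclass tasks
#' one-vs-one voting.
#'
#' @param features A `feature_matrix` (or plain matrix; then `top_n` must
#'   be `NULL`).
#' @param y Factor of labels aligned with rows.
#' @param folds,repeats Outer CV shape (default 5 x 30).
#' @param seed Base seed; repeat r uses `seed + r - 1` for its partition.
#' @param grid Hyperparameter candidates (see [svm_grid()]).
#' @param top_n If non-NULL, fold-wise channel selection: per feature
#'   kind, channels are ranked by training-fold r-squared for every class
#'   pair and the union of per-pair top-`top_n` sets is kept
#'   (the default, leakage-free mode). Use `NULL` when selection was done
#'   beforehand (e.g. fixed mu/beta channels, or the optimistic all-data
#'   variant).
#' @param inner_folds Inner CV folds for the grid search.
#' @return A `cv_result`: list with `fold_accuracy` (repeats x folds),
#'   `mean_accuracy`, `pooled_accuracy`, `confusion` (rows = predicted,
#'   columns = actual, pooled over all test folds), `repeat_accuracy`,
#'   `task`, `seed`.
#' @export
cross_validate <- function(features, y, folds = 5, repeats = 30, seed = 1,
                           grid = svm_grid(), top_n = NULL, inner_folds = 5,
                           task = "decoding") {
  X_all <- if (inherits(features, "feature_matrix")) features$X else features
  prov <- if (inherits(features, "feature_matrix")) features$provenance else NULL
  if (!is.null(top_n) && is.null(prov))
    stop("fold-wise selection needs a feature_matrix with provenance", call. = FALSE)
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  fold_acc <- matrix(NA_real_, repeats, folds)
  confusion <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(y, folds, seed + r - 1L)
    for (fd in seq_len(folds)) {
      tr <- fold_of != fd; te <- !tr
      Xtr <- X_all[tr, , drop = FALSE]; ytr <- y[tr]
      Xte <- X_all[te, , drop = FALSE]
      if (!is.null(top_n)) {
        keep <- fold_select_columns(Xtr, prov, ytr, top_n)
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- Xte[, keep, drop = FALSE]
      }
      sc <- fit_scaler(Xtr)
      Xtr <- apply_scaler(Xtr, sc); Xte <- apply_scaler(Xte, sc)
      inner_seed <- seed + 1000L * r + fd
      pred <- if (length(lev) == 2) {
        fit <- train_binary(Xtr, ytr, grid, inner_folds, inner_seed)
        stats::predict(fit$model, Xte)
      } else {
        ovo <- ovo_train(Xtr, ytr, grid, inner_folds, inner_seed)
        ovo_predict(ovo, Xte)
      }
      pred <- factor(as.character(pred), levels = lev)
      truth <- y[te]
      fold_acc[r, fd] <- mean(pred == truth)
      confusion <- confusion + table(factor(pred, lev), factor(truth, lev))
    }
  }
  structure(list(fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = sum(diag(confusion)) / sum(confusion),
                 repeat_accuracy = rowMeans(fold_acc),
                 confusion = confusion, task = task,
                 folds = folds, repeats = repeats, seed = seed),
            class = "cv_result")
}

# Fold-wise r-squared channel selection: per feature kind, rank channels
# by r2 for every class pair on the training data, keep the union of the
# per-pair top-n sets; returns retained column indices in original order.
fold_select_columns <- function(Xtr, prov, ytr, top_n) {
  lev <- levels(droplevels(ytr))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  keep <- logical(nrow(prov))
  for (kind in unique(prov$kind)) {
    cols <- which(prov$kind == kind)
    selected <- character(0)
    for (p in pairs) {
      r2 <- vapply(cols, function(j) {
        w1 <- Xtr[ytr == p[1], j]; w2 <- Xtr[ytr == p[2], j]
        pooled <- c(w1, w2)
        if (stats::var(pooled) == 0) return(0)
        r_squared(w1, w2)$r2
      }, numeric(1))
      ord <- order(-r2, seq_along(cols))
      selected <- union(selected,
                        prov$channel[cols[ord[seq_len(min(top_n, length(cols)))]]])
    }
    keep[cols[prov$channel[cols] %in% selected]] <- TRUE
  }
  which(keep)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.3f (%d x %d folds, seed %d)\n",
              x$task, x$mean_accuracy, x$repeats, x$folds, x$seed))
  invisible(x)
}

#' Compare decoding accuracies by Student's t-test
#'
#' One-sample two-sided t-test of per-repeat mean accuracies against a
#' chance level, or paired two-sided t-test between two matched runs
#' (matched per repeat). Accuracy vectors may be passed directly instead
#' of `cv_result` objects.
#'
#' @param a A `cv_result` or numeric vector of accuracies.
#' @param b For the paired test: a matched `cv_result` or numeric vector;
#'   omit for a one-sample test.
#' @param chance Chance level for the one-sample test.
#' @return An `htest` object from [stats::t.test()].
#' @export
compare_accuracies <- function(a, b = NULL, chance = NULL) {
  acc <- function(z) if (inherits(z, "cv_result")) z$repeat_accuracy else z
  x <- acc(a)
  if (!is.null(b)) {
    yv <- acc(b)
    if (length(x) != length(yv))
      stop("paired test needs equal-length accuracy vectors", call. = FALSE)
    if (all(x == yv))
      return(structure(list(statistic = c(t = 0), p.value = 1,
                            estimate = c(`mean difference` = 0),
                            method = "Paired t-test (degenerate: identical samples)",
                            data.name = "a vs b"),
                       class = "htest"))
    stats::t.test(x, yv, paired = TRUE)
  } else {
    if (is.null(chance)) stop("supply either `b` or `chance`", call. = FALSE)
    if (length(x) < 2 || stats::sd(x) == 0) {
      # single repeat or all repeats identical: t is 0 (at chance),
      # unbounded (off chance), or undefined (n = 1)
      stat <- if (length(x) < 2) NA_real_
              else if (x[1] == chance) 0 else sign(x[1] - chance) * Inf
      return(structure(list(statistic = c(t = stat),
                            p.value = if (x[1] == chance) 1 else NA_real_,
                            estimate = c(`mean accuracy` = x[1]),
                            method = "One Sample t-test (degenerate: zero variance)",
                            data.name = "accuracies"),
                       class = "htest"))
    }
    stats::t.test(x, mu = chance)
  }
}
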
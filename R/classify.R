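#' Split group labels into genotype and age
#'
#' @param labels character vector of labels like `"WT-10m"`
#' @return data.frame with columns `genotype` (`WT`/`AD`) and `age`
#'   (`1m`/`4m`/`10m`)
#' @export
split_group_label <- function(labels) {
  data.frame(genotype = sub("-.*$", "", labels),
             age = sub("^[A-Z]+-", "", labels),
             stringsAsFactors = FALSE)
}

#' Cross-validation fold assignment
#'
#' Each row is held out exactly once; fold sizes differ by at most one.
#'
#' @param n number of rows (or a vector whose length is used)
#' @param k number of folds (>= 2)
#' @param seed RNG seed
#' @param labels optional class labels; when given, folds are stratified
#'   by class
#' @return integer vector of fold ids in `1..k`
#' @export
make_folds <- function(n, k = 10, seed = 1, labels = NULL) {
  if (length(n) > 1) n <- length(n)
  stopifnot(k >= 2, n >= k)
  .with_seed(seed, {
    if (is.null(labels)) {
      folds <- rep_len(seq_len(k), n)
      sample(folds)
    } else {
      stopifnot(length(labels) == n)
      out <- integer(n)
      off <- 0L
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        f <- (rep_len(seq_len(k) + off, length(idx)) - 1L) %% k + 1L
        out[idx] <- sample(f)
        off <- off + length(idx)
      }
      out
    }
  })
}

.impute_train_medians <- function(xtr, xte) {
  for (j in seq_len(ncol(xtr))) {
    med <- median(xtr[, j], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    xtr[is.na(xtr[, j]), j] <- med
    xte[is.na(xte[, j]), j] <- med
  }
  list(train = xtr, test = xte)
}

#' Train and evaluate a tree-ensemble classifier under cross-validation
#'
#' Bagged trees (bootstrap-aggregated, majority vote) or boosted trees
#' (gradient-boosted shallow trees). Accuracy is computed from held-out
#' predictions only; missing feature values are imputed with medians
#' computed on the training folds only. When a plain random split leaves a
#' class absent from some training fold, the data is refolded with
#' stratification (logged via a message).
#'
#' @param table feature table (data.frame); non-feature columns are
#'   ignored via `features`
#' @param labels class labels, one per row (>= 2 classes)
#' @param kind `"bagged"` or `"boosted"`
#' @param features character vector of feature columns (default: the
#'   [current_dependent_features()] of the table)
#' @param n_estimators number of trees
#' @param max_depth tree depth for boosting (default 3)
#' @param learning_rate shrinkage for boosting (default 0.1)
#' @param folds number of cross-validation folds
#' @param seed RNG seed (folds, bootstrap, boosting)
#' @return an object of class `class_report`: `accuracy`, `confusion`,
#'   `predictions` (row, fold, truth, predicted), `task` (settings echo),
#'   `seed`
#' @export
train_eval <- function(table, labels, kind = c("bagged", "boosted"),
                       features = NULL, n_estimators = 100,
                       max_depth = 3, learning_rate = 0.1,
                       folds = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(table), nrow(table) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (is.null(features)) features <- current_dependent_features(table)
  stopifnot(length(features) > 0, all(features %in% names(table)))
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  keep <- colSums(!is.na(x)) > 0
  x <- x[, keep, drop = FALSE]

  fold <- make_folds(nrow(x), k = folds, seed = seed)
  bad <- any(vapply(seq_len(folds), function(f)
    nlevels(droplevels(labels[fold != f])) < nlevels(labels), TRUE))
  if (bad) {
    message("refolding with class stratification")
    fold <- make_folds(nrow(x), k = folds, seed = seed, labels = labels)
  }

  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f
    im <- .impute_train_medians(x[tr, , drop = FALSE],
                                x[!tr, , drop = FALSE])
    if (kind == "bagged") {
      .with_seed(seed * 1000L + f, {
        rf <- randomForest::randomForest(
          x = im$train, y = droplevels(labels[tr]),
          ntree = n_estimators, mtry = ncol(im$train),
          replace = TRUE)
        pred[!tr] <- factor(as.character(predict(rf, im$test)),
                            levels = levels(labels))
      })
    } else {
      ytr <- as.integer(droplevels(labels[tr])) - 1L
      nc <- nlevels(droplevels(labels[tr]))
      params <- list(max_depth = max_depth, eta = learning_rate,
                     nthread = 1, verbosity = 0, tree_method = "exact")
      if (nc > 2) {
        params$objective <- "multi:softmax"
        params$num_class <- nc
      } else {
        params$objective <- "binary:logistic"
      }
      dtr <- xgboost::xgb.DMatrix(im$train, label = ytr, nthread = 1)
      bst <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = n_estimators, verbose = 0)
      ph <- predict(bst, xgboost::xgb.DMatrix(im$test, nthread = 1))
      cls <- if (nc > 2) ph + 1 else as.integer(ph > 0.5) + 1L
      pred[!tr] <- factor(levels(droplevels(labels[tr]))[cls],
                          levels = levels(labels))
    }
  }
  acc <- mean(pred == labels)
  structure(list(
    accuracy = acc,
    confusion = table(truth = labels, predicted = pred),
    predictions = data.frame(row = seq_along(labels), fold = fold,
                             truth = labels, predicted = pred),
    task = list(kind = kind, features = colnames(x),
                n_estimators = n_estimators, max_depth = max_depth,
                learning_rate = learning_rate, folds = folds),
    seed = seed), class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> %s trees, %d-fold CV: accuracy %.3f\n",
              x$task$kind, x$task$folds, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Run the standard genotype/age classification tasks
#'
#' Six tasks: genotype (WT vs AD) within each age, genotype pooled over
#' ages, and age (1m/4m/10m) within each genotype. Both ensemble kinds are
#' evaluated and the better one is reported per task.
#'
#' @param ft feature table with a `group_label` column
#' @param kinds which classifier kinds to try
#' @param seed RNG seed
#' @param ... passed to [train_eval()]
#' @return data.frame with one row per task: `task`, `n`, `classes`,
#'   `chance`, `accuracy`, `classifier`
#' @export
run_classification_tasks <- function(ft, kinds = c("bagged", "boosted"),
                                     seed = 1, ...) {
  stopifnot("group_label" %in% names(ft))
  ga <- split_group_label(ft$group_label)
  tasks <- list(
    list(name = "WT or AD at 1m", rows = ga$age == "1m", lab = "genotype"),
    list(name = "WT or AD at 4m", rows = ga$age == "4m", lab = "genotype"),
    list(name = "WT or AD at 10m", rows = ga$age == "10m", lab = "genotype"),
    list(name = "WT or AD (all ages)", rows = rep(TRUE, nrow(ft)),
         lab = "genotype"),
    list(name = "age from WT", rows = ga$genotype == "WT", lab = "age"),
    list(name = "age from AD", rows = ga$genotype == "AD", lab = "age"))
  out <- list()
  for (tk in tasks) {
    sub <- ft[tk$rows, , drop = FALSE]
    labs <- ga[tk$rows, tk$lab]
    ncl <- length(unique(labs))
    if (nrow(sub) < 10 || ncl < 2) next
    reps <- lapply(kinds, function(k)
      train_eval(sub, labs, kind = k, seed = seed, ...))
    accs <- vapply(reps, `[[`, 0, "accuracy")
    best <- which.max(accs)
    out[[length(out) + 1L]] <- data.frame(
      task = tk$name, n = nrow(sub), classes = ncl, chance = 1 / ncl,
      accuracy = accs[best], classifier = kinds[best],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
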
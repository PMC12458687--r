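# Pocket classification: LBP versus everything else.
#
# Engines: ranger (random forest), e1071 (svm, naive bayes), stats::glm
# (logistic), class::knn, rpart (decision tree). Heme rows are excluded
# from default training; nLBP and PP are jointly the negative class.

ALGORITHMS <- c("random_forest", "svm", "logistic", "knn", "naive_bayes",
                "decision_tree")

# design matrix + 0/1 response from a labeled table
designMatrix <- function(table, featureOrder = NULL) {
  r <- descriptorRows(table)
  feats <- featureOrder %||%
    intersect(descriptorNames(extra = TRUE), names(r))
  missing <- setdiff(feats, names(r))
  if (length(missing))
    stop("schema error: missing descriptor column(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(r[, feats, drop = FALSE])
  y <- if ("label" %in% names(r)) as.integer(r$label == "LBP") else NULL
  list(x = x, y = y, features = feats)
}

#' Train a pocket classifier
#'
#' Binary task: lipid-binding pocket (positive) against non-lipid and
#' pseudo pockets. Heme rows are dropped before training. The baseline
#' random-forest configuration is 100 trees, sqrt(p) features per split,
#' unlimited depth, bootstrap on; all engines are seeded and deterministic.
#'
#' @param table labeled training \code{\linkS4class{DescriptorTable}} with
#'   both classes present.
#' @param algorithm one of random_forest, svm, logistic, knn, naive_bayes,
#'   decision_tree.
#' @param hyperparameters named list; for the random forest the recognised
#'   names are num_trees, max_features, max_depth, min_split, min_leaf,
#'   bootstrap; for knn, k; engine defaults otherwise.
#' @param seed RNG seed.
#' @param threshold decision threshold (inclusive), default 0.5.
#' @return A \code{\linkS4class{PocketClassifier}}.
#' @export
trainClassifier <- function(table, algorithm = "random_forest",
                            hyperparameters = list(), seed = 1L,
                            threshold = 0.5) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  r <- descriptorRows(table)
  r <- r[r$label != "HEME", , drop = FALSE]
  dm <- designMatrix(DescriptorTable(r))
  if (length(unique(dm$y)) < 2)
    stop("training error: a single class in the training table")
  y <- factor(ifelse(dm$y == 1, "LBP", "neg"), levels = c("neg", "LBP"))
  scaling <- list()
  if (algorithm == "knn") {
    mu <- colMeans(dm$x)
    sdv <- apply(dm$x, 2, sd); sdv[sdv == 0] <- 1
    scaling <- list(center = mu, scale = sdv)
  }
  fit <- withSeed(seed, switch(algorithm,
    random_forest = {
      hp <- hyperparameters
      ranger::ranger(
        x = as.data.frame(dm$x), y = y, probability = TRUE,
        num.trees = hp$num_trees %||% 100,
        mtry = hp$max_features %||% floor(sqrt(ncol(dm$x))),
        max.depth = hp$max_depth %||% 0,
        min.node.size = hp$min_split %||% 2,
        min.bucket = hp$min_leaf %||% 1,
        replace = hp$bootstrap %||% TRUE,
        sample.fraction = if (isFALSE(hp$bootstrap)) 0.632 else 1,
        importance = "impurity", seed = seed, num.threads = 1)
    },
    svm = e1071::svm(x = dm$x, y = y, probability = TRUE,
                     kernel = "radial",
                     cost = hyperparameters$cost %||% 1),
    logistic = {
      df <- data.frame(dm$x, .y = dm$y)
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    knn = list(x = scale(dm$x, scaling$center, scaling$scale), y = y,
               k = hyperparameters$k %||% 5),
    naive_bayes = e1071::naiveBayes(x = as.data.frame(dm$x), y = y),
    decision_tree = rpart::rpart(
      .y ~ ., data = data.frame(dm$x, .y = y), method = "class",
      control = rpart::rpart.control(
        cp = hyperparameters$cp %||% 0.01))
  ))
  new("PocketClassifier", fit = fit, algorithm = algorithm,
      hyperparameters = hyperparameters, featureOrder = dm$features,
      threshold = threshold, scaling = scaling,
      manifest = list(seed = seed,
                      class_counts = as.list(classCounts(table)),
                      n_train = nrow(r),
                      engine = switch(algorithm,
                                      random_forest = "ranger",
                                      svm = "e1071", logistic = "stats",
                                      knn = "class",
                                      naive_bayes = "e1071",
                                      decision_tree = "rpart"),
                      engine_version = as.character(utils::packageVersion(
                        switch(algorithm, random_forest = "ranger",
                               svm = "e1071", logistic = "stats",
                               knn = "class", naive_bayes = "e1071",
                               decision_tree = "rpart")))))
}

#' Predict lipid-binding probability for pockets
#'
#' @param model a \code{\linkS4class{PocketClassifier}}.
#' @param newdata a \code{\linkS4class{DescriptorTable}}, a data.frame, or
#'   a single named numeric vector; must carry every feature the model was
#'   trained on (a missing feature raises a schema error naming it).
#' @return Numeric vector of positive-class probabilities in [0, 1].
#' @export
predictPocket <- function(model, newdata) {
  if (is(newdata, "DescriptorTable")) newdata <- descriptorRows(newdata)
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  feats <- featureOrder(model)
  missing <- setdiff(feats, names(newdata))
  if (length(missing))
    stop("schema error: missing feature(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, feats, drop = FALSE])
  p <- switch(model@algorithm,
    random_forest = predict(model@fit, data = as.data.frame(x),
                            num.threads = 1)$predictions[, "LBP"],
    svm = {
      pr <- predict(model@fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "LBP"]
    },
    logistic = as.numeric(predict(model@fit,
                                  newdata = as.data.frame(x),
                                  type = "response")),
    knn = {
      xs <- scale(x, model@scaling$center, model@scaling$scale)
      pr <- class::knn(model@fit$x, xs, model@fit$y, k = model@fit$k,
                       prob = TRUE)
      w <- attr(pr, "prob")
      ifelse(pr == "LBP", w, 1 - w)
    },
    naive_bayes = predict(model@fit, as.data.frame(x),
                          type = "raw")[, "LBP"],
    decision_tree = predict(model@fit, as.data.frame(x),
                            type = "prob")[, "LBP"])
  unname(pmin(1, pmax(0, as.numeric(p))))
}

#' Predicted labels at the model threshold
#'
#' The threshold is inclusive: a probability equal to the threshold is
#' called positive.
#'
#' @param model a \code{\linkS4class{PocketClassifier}}.
#' @param newdata as in \code{\link{predictPocket}}.
#' @return Logical vector (TRUE = predicted lipid-binding).
#' @export
predictLabels <- function(model, newdata) {
  predictPocket(model, newdata) >= scoreThreshold(model)
}

#' Compare classification algorithms by repeated stratified splits
#'
#' For each repeat: a stratified split at \code{testFraction}, a fit on
#' the training part, and the six evaluation metrics on the held-out part.
#' The summary reports the per-metric distribution in box-plot form
#' (quartiles, whiskers, outliers beyond 1.5 IQR).
#'
#' @param table labeled \code{\linkS4class{DescriptorTable}}.
#' @param algorithms character vector of algorithm names.
#' @param nRepeats number of repeats (>= 1); the paper-scale protocol is
#'   25 repeats at a 90:10 split.
#' @param testFraction held-out fraction, default 0.1.
#' @param seed base RNG seed.
#' @return List: results (long data.frame algorithm/repeat/metric/value),
#'   summary (box-plot stats per algorithm and metric), errors.
#' @export
compareAlgorithms <- function(table, algorithms = ALGORITHMS,
                              nRepeats = 25, testFraction = 0.1,
                              seed = 1L) {
  stopifnot(nRepeats >= 1)
  rows <- list(); errors <- list()
  for (rep in seq_len(nRepeats)) {
    sp <- stratifiedSplit(table, testFraction, seed = childSeed(seed, rep))
    for (alg in algorithms) {
      res <- tryCatch({
        m <- trainClassifier(sp$train, algorithm = alg,
                             seed = childSeed(seed, rep))
        evaluateClassifier(m, sp$test)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          list(algorithm = alg, repeat_ = rep,
               message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, rep = rep,
          metric = names(res), value = unname(unlist(res)),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(results, list(results$algorithm, results$metric), drop = TRUE),
    function(d) {
      bs <- boxplotSummary(d$value)
      data.frame(algorithm = d$algorithm[1], metric = d$metric[1],
                 min = bs$min, q1 = bs$q1, median = bs$median,
                 q3 = bs$q3, max = bs$max,
                 whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi,
                 n_outliers = length(bs$outliers),
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(results = results, summary = summ, errors = errors)
}

# six metrics of a fitted model on a held-out table
evaluateClassifier <- function(model, test) {
  p <- predictPocket(model, test)
  truth <- descriptorRows(test)$label == "LBP"
  pred <- p >= scoreThreshold(model)
  cm <- confusionCounts(truth, pred)
  m <- classificationMetrics(cm)
  list(auroc = aurocScore(p, truth), accuracy = m$accuracy,
       f1 = m$f1, sensitivity = m$sensitivity,
       specificity = m$specificity, precision = m$precision)
}

#' Hyperparameter search specification
#'
#' @param mode "random" or "grid".
#' @param space named list; ranges (length-2 numeric) for random mode,
#'   option vectors for grid mode.
#' @param nIterations candidates drawn in random mode.
#' @param cvFolds cross-validation folds (>= 2), default 3.
#' @param objective metric maximised, default "f1".
#' @return A search-spec list.
#' @export
searchSpec <- function(mode = c("random", "grid"), space,
                       nIterations = 100, cvFolds = 3,
                       objective = "f1") {
  mode <- match.arg(mode)
  if (!length(space)) stop("spec error: empty search space")
  stopifnot(cvFolds >= 2)
  list(mode = mode, space = space, nIterations = nIterations,
       cvFolds = cvFolds, objective = objective)
}

#' Default random-search ranges and grid options
#'
#' The random ranges are num_trees [100, 1000], max_features [2, 4],
#' max_depth [10, 100], min_split [2, 10], min_leaf [1, 4], bootstrap
#' {TRUE, FALSE}; the grid options are num_trees {100, 200, 400},
#' max_features {2, 3, 4}, max_depth {50, 70, 90}, min_split {2, 5, 10},
#' min_leaf {1, 2, 4}, bootstrap {TRUE} (243 candidates).
#'
#' @return Named list of ranges / option vectors.
#' @export
defaultRandomSpace <- function() {
  list(num_trees = c(100, 1000), max_features = c(2, 4),
       max_depth = c(10, 100), min_split = c(2, 10),
       min_leaf = c(1, 4), bootstrap = c(TRUE, FALSE))
}

#' @rdname defaultRandomSpace
#' @export
defaultGridSpace <- function() {
  list(num_trees = c(100, 200, 400), max_features = c(2, 3, 4),
       max_depth = c(50, 70, 90), min_split = c(2, 5, 10),
       min_leaf = c(1, 2, 4), bootstrap = TRUE)
}

#' Enumerate a grid search space
#'
#' @param space named list of option vectors.
#' @return data.frame, one row per candidate (cross-product).
#' @export
hyperparameterGrid <- function(space) {
  if (!length(space)) stop("spec error: empty grid")
  expand.grid(space, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# draw random-search candidates: log-uniform for tree count and depth,
# uniform otherwise
drawRandomCandidates <- function(space, n, seed) {
  logU <- c("num_trees", "max_depth")
  withSeed(seed, {
    cols <- lapply(names(space), function(nm) {
      rng <- space[[nm]]
      if (is.logical(rng)) sample(rng, n, replace = TRUE)
      else if (nm %in% logU)
        as.integer(round(exp(runif(n, log(rng[1]), log(rng[2])))))
      else as.integer(round(runif(n, rng[1], rng[2])))
    })
    stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE),
                    names(space))
  })
}

#' Tune hyperparameters by random or grid search
#'
#' Each candidate is scored by stratified k-fold cross-validated objective
#' (default 3-fold F1, maximised); returns the argmax and the full log.
#'
#' @param table labeled \code{\linkS4class{DescriptorTable}}.
#' @param spec a \code{\link{searchSpec}}.
#' @param seed RNG seed.
#' @param algorithm algorithm tuned, default random_forest.
#' @return List: best (named list of hyperparameters), best_score,
#'   log (data.frame of candidates and scores).
#' @export
tuneHyperparameters <- function(table, spec, seed = 1L,
                                algorithm = "random_forest") {
  cand <- if (spec$mode == "grid") hyperparameterGrid(spec$space)
          else drawRandomCandidates(spec$space, spec$nIterations, seed)
  if (!nrow(cand)) stop("spec error: no candidates")
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    hp <- as.list(cand[i, , drop = FALSE])
    crossValidateObjective(table, algorithm, hp, spec$cvFolds,
                           spec$objective, childSeed(seed, i))
  }, numeric(1))
  log <- cbind(cand, score = scores)
  best <- which.max(scores)
  list(best = as.list(cand[best, , drop = FALSE]),
       best_score = scores[best], log = log)
}

crossValidateObjective <- function(table, algorithm, hp, folds, objective,
                                   seed) {
  r <- descriptorRows(table)
  r <- r[r$label != "HEME", , drop = FALSE]
  pos <- r$label == "LBP"
  fold <- integer(nrow(r))
  withSeed(seed, {
    for (cls in unique(pos))
      fold[pos == cls] <- sample(rep_len(seq_len(folds), sum(pos == cls)))
  })
  vals <- vapply(seq_len(folds), function(f) {
    tr <- DescriptorTable(r[fold != f, , drop = FALSE])
    te <- DescriptorTable(r[fold == f, , drop = FALSE])
    m <- tryCatch(trainClassifier(tr, algorithm = algorithm,
                                  hyperparameters = hp,
                                  seed = childSeed(seed, f)),
                  error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    ev <- evaluateClassifier(m, te)
    as.numeric(ev[[objective]])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Persist / restore a trained classifier
#'
#' Writes a versioned JSON manifest (algorithm, hyperparameters, feature
#' order, threshold, training provenance — enough to retrain) alongside a
#' serialized estimator blob.
#'
#' @param model a \code{\linkS4class{PocketClassifier}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
saveClassifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format_version = 1L, algorithm = model@algorithm,
                   hyperparameters = model@hyperparameters,
                   feature_order = model@featureOrder,
                   threshold = model@threshold,
                   train = model@manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "classifier.rds"))
  invisible(dir)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(dir) {
  path <- file.path(dir, "classifier.rds")
  if (!file.exists(path)) stop("no classifier found in ", dir)
  readRDS(path)
}
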
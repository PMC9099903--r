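# Stage 2B: zonal spectral features around each candidate, simple
# importance-based feature selection, TREE / NOT-TREE classification, and
# candidate filtering.

#' Zonal spectral features around points
#'
#' For each point, the mean and population standard deviation (divisor n; the
#' buffer holds only ~12 pixels at 0.25 m cells, so the n vs n-1 choice is
#' material and explicit) of the pixels whose centers lie within
#' `buffer_radius` of the point, per band. With the canonical seven bands
#' this yields 14 features named `<band>_mean`, `<band>_sd` in band order.
#' Points whose buffer contains no valid pixel are dropped and counted in
#' attribute `n_dropped`.
#'
#' @param points data.frame with `x`, `y` (and optionally `id`)
#' @param stack an [OrthoStack-class]
#' @param buffer_radius meters (default 0.5)
#' @return data.frame of features, one row per retained point, with an `id`
#'   column when the input had one
#' @export
zonalFeatures <- function(points, stack, buffer_radius = 0.5) {
  if (buffer_radius <= 0) stop("buffer_radius must be > 0")
  cs <- stack@cellSize
  d <- dim(stack@bands[[1]])
  cc <- list(x = stack@origin[1] + (seq_len(d[2]) - 0.5) * cs,
             y = stack@origin[2] - (seq_len(d[1]) - 0.5) * cs)
  bands <- names(stack@bands)
  n <- nrow(points)
  feats <- matrix(NA_real_, n, 2 * length(bands))
  colnames(feats) <- as.vector(rbind(paste0(bands, "_mean"),
                                     paste0(bands, "_sd")))
  okrow <- logical(n)
  for (k in seq_len(n)) {
    jj <- which(abs(cc$x - points$x[k]) <= buffer_radius)
    ii <- which(abs(cc$y - points$y[k]) <= buffer_radius)
    if (!length(ii) || !length(jj)) next
    d2 <- outer((cc$y[ii] - points$y[k])^2, (cc$x[jj] - points$x[k])^2, "+")
    sel <- d2 <= buffer_radius^2 + 1e-12
    if (!any(sel)) next
    any_valid <- FALSE
    for (b in seq_along(bands)) {
      px <- stack@bands[[bands[b]]][ii, jj, drop = FALSE][sel]
      px <- px[!is.na(px)]
      if (!length(px)) next
      any_valid <- TRUE
      m <- mean(px)
      feats[k, 2 * b - 1] <- m
      feats[k, 2 * b] <- sqrt(mean((px - m)^2))
    }
    okrow[k] <- any_valid
  }
  out <- as.data.frame(feats[okrow, , drop = FALSE])
  if ("id" %in% names(points)) out <- cbind(id = points$id[okrow], out)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!okrow)
  out
}

#' Build a labeled training set of zonal features
#'
#' @param labeled data.frame `x, y, class` (class in `TREE, NOT_TREE`), e.g.
#'   from [sampleTruthPoints()]
#' @param stack an [OrthoStack-class]
#' @param buffer_radius zonal buffer radius (m)
#' @return data.frame of features plus a `class` factor
#' @export
buildTrainingSet <- function(labeled, stack, buffer_radius = 0.5) {
  pts <- data.frame(id = seq_len(nrow(labeled)), x = labeled$x, y = labeled$y)
  ff <- zonalFeatures(pts, stack, buffer_radius)  # drops empty buffers
  f <- ff[, setdiff(names(ff), "id"), drop = FALSE]
  f$class <- factor(labeled$class[ff$id], levels = c("NOT_TREE", "TREE"))
  if (length(unique(f$class[!is.na(f$class)])) < 2)
    stop("training set must contain both classes")
  f
}

#' Rank and select features by permutation importance
#'
#' A seeded random forest is fitted on all features; features are ranked by
#' permutation importance (mean decrease in accuracy) and the top fraction
#' (or those above an importance threshold) retained. The subset is never
#' empty: the top-ranked feature is always kept. This is a deliberately
#' simple single-step stand-in for multi-stage forest-based selection
#' procedures, which serve only to cut training time.
#'
#' @param train data.frame of features plus a `class` factor
#' @param keep_fraction fraction of features to keep (default 0.5)
#' @param importance_threshold optional absolute importance cut; overrides
#'   `keep_fraction` when given
#' @param seed integer seed
#' @return character vector of selected feature names, with the full ranking
#'   in attribute `importance`
#' @export
selectFeatures <- function(train, keep_fraction = 0.5,
                           importance_threshold = NULL, seed = 1L) {
  feats <- setdiff(names(train), "class")
  if (length(feats) < 2) stop("need at least 2 features")
  if (length(unique(train$class)) < 2) stop("training set has a single class")
  imp <- withSeed(seed, {
    rf <- randomForest::randomForest(
      x = train[, feats, drop = FALSE], y = train$class,
      ntree = 200, importance = TRUE)
    randomForest::importance(rf, type = 1)[, 1]
  })
  ord <- order(imp, decreasing = TRUE)
  ranked <- feats[ord]
  sel <- if (!is.null(importance_threshold)) {
    ranked[imp[ord] > importance_threshold]
  } else {
    ranked[seq_len(max(1, ceiling(keep_fraction * length(feats))))]
  }
  if (!length(sel)) sel <- ranked[1]
  structure(sel, importance = imp[ord])
}

#' Classifier specification
#'
#' @param algorithm `"RF"` (default), `"ANN"`, `"SVM_LINEAR"` or
#'   `"SVM_RADIAL"`
#' @param cv_repeats repetitions of the k-fold cross-validation (default 3)
#' @param cv_folds folds per repetition (default 10)
#' @param decision_threshold TREE posterior needed to keep a candidate
#'   (default 0.5)
#' @param seed integer seed (folds and model fits)
#' @return a `classifierSpec` list
#' @export
classifierSpec <- function(algorithm = c("RF", "ANN", "SVM_LINEAR", "SVM_RADIAL"),
                           cv_repeats = 3, cv_folds = 10,
                           decision_threshold = 0.5, seed = 1L) {
  if (cv_repeats < 1) stop("cv_repeats must be >= 1")
  s <- list(algorithm = match.arg(algorithm), cv_repeats = cv_repeats,
            cv_folds = cv_folds, decision_threshold = decision_threshold,
            seed = as.integer(seed))
  class(s) <- c("classifierSpec", "list")
  s
}

fitOne <- function(x, y, algorithm) {
  switch(algorithm,
    RF = randomForest::randomForest(x = x, y = y, ntree = 300),
    ANN = nnet::nnet(x = x, y = class.ind2(y), size = 8, decay = 0.01,
                     maxit = 300, trace = FALSE, MaxNWts = 5000,
                     softmax = TRUE),
    SVM_LINEAR = e1071::svm(x = x, y = y, kernel = "linear",
                            probability = TRUE),
    SVM_RADIAL = e1071::svm(x = x, y = y, kernel = "radial",
                            probability = TRUE),
    stop("unknown algorithm: ", algorithm))
}

class.ind2 <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

predictTreeProb <- function(model, algorithm, x) {
  switch(algorithm,
    RF = predict(model, x, type = "prob")[, "TREE"],
    ANN = predict(model, x)[, "TREE"],
    SVM_LINEAR = ,
    SVM_RADIAL = {
      p <- predict(model, x, probability = TRUE)
      attr(p, "probabilities")[, "TREE"]
    })
}

#' Train a TREE / NOT-TREE classifier with repeated cross-validation
#'
#' Fits the requested algorithm on the selected features and reports mean
#' accuracy over `cv_repeats` repetitions of seeded `cv_folds`-fold
#' cross-validation, then refits on the full training set. Deterministic for
#' a fixed seed (per each algorithm's own contract).
#'
#' @param train data.frame of features plus `class` factor (both classes with
#'   at least 10 examples)
#' @param spec a [classifierSpec()]
#' @param features feature names to use (default: all columns except class),
#'   e.g. from [selectFeatures()]
#' @return a `treeClassifier` object (list with `model`, `algorithm`,
#'   `features`, `cv_accuracy`, `decision_threshold`)
#' @export
trainClassifier <- function(train, spec = classifierSpec(),
                            features = setdiff(names(train), "class")) {
  if (min(table(train$class)) < 10)
    stop("both classes need at least 10 examples")
  x <- train[, features, drop = FALSE]
  y <- train$class
  n <- nrow(x)
  accs <- withSeed(spec$seed, {
    out <- numeric(0)
    for (rep_i in seq_len(spec$cv_repeats)) {
      fold <- sample(rep_len(seq_len(spec$cv_folds), n))
      for (f in seq_len(spec$cv_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2) next
        m <- fitOne(x[tr, , drop = FALSE], y[tr], spec$algorithm)
        p <- predictTreeProb(m, spec$algorithm, x[!tr, , drop = FALSE])
        pred <- ifelse(p >= 0.5, "TREE", "NOT_TREE")
        out <- c(out, mean(pred == as.character(y[!tr])))
      }
    }
    out
  })
  model <- withSeed(spec$seed + 1L, fitOne(x, y, spec$algorithm))
  structure(list(model = model, algorithm = spec$algorithm,
                 features = features, cv_accuracy = mean(accs),
                 decision_threshold = spec$decision_threshold),
            class = "treeClassifier")
}

#' @export
print.treeClassifier <- function(x, ...) {
  cat("treeClassifier:", x$algorithm, "on", length(x$features),
      "features; repeated-CV accuracy", sprintf("%.4f", x$cv_accuracy), "\n")
  invisible(x)
}

#' Filter candidates with a spectral classifier (stage 2B)
#'
#' Computes zonal features around every candidate and keeps those whose TREE
#' posterior is at least the classifier's decision threshold. Candidates
#' whose buffer is off-raster (no valid pixels) are dropped and counted.
#' Positions and ids are preserved; `source` becomes `"filtered"`. When
#' `merge_params` is given, the kept candidates are merged afterwards (the
#' pipeline does this after every stage).
#'
#' @param candidates candidate data.frame
#' @param classifier a `treeClassifier` from [trainClassifier()]
#' @param stack an [OrthoStack-class]
#' @param buffer_radius zonal buffer radius (m)
#' @param merge_params optional [mergeParams()] applied to the kept
#'   candidates
#' @return filtered candidate data.frame with attributes `n_offraster` and
#'   `posterior` (named TREE posteriors of scored candidates)
#' @export
filterCandidates <- function(candidates, classifier, stack,
                             buffer_radius = 0.5, merge_params = NULL) {
  if (!inherits(classifier, "treeClassifier")) stop("not a treeClassifier")
  if (!nrow(candidates)) {
    attr(candidates, "n_offraster") <- 0L
    return(candidates)
  }
  f <- zonalFeatures(candidates, stack, buffer_radius)
  if (!all(classifier$features %in% names(f)))
    stop("feature schema mismatch between classifier and ortho stack")
  kept_ids <- f$id
  p <- predictTreeProb(classifier$model, classifier$algorithm,
                       f[, classifier$features, drop = FALSE])
  ok_ids <- kept_ids[p >= classifier$decision_threshold]
  out <- candidates[candidates$id %in% ok_ids, , drop = FALSE]
  out$source <- rep_len("filtered", nrow(out))
  rownames(out) <- NULL
  if (!is.null(merge_params)) out <- mergeCandidates(out, merge_params)
  attr(out, "n_offraster") <- attr(f, "n_dropped")
  attr(out, "posterior") <- stats::setNames(p, kept_ids)
  out
}
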
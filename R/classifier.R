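# F-score feature selection, RF / RBF-SVM training, leakage-free
# cross-validation, and performance metrics.

POSITIVE_CLASS <- "biological"
NEGATIVE_CLASS <- "crystallographic"

as_label_factor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c(POSITIVE_CLASS, NEGATIVE_CLASS))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  factor(y, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
}

#' Rank features by F-score
#'
#' For feature x with class means `m+`, `m-`, grand mean `m` and class
#' sample variances `v+`, `v-` (n - 1 denominators):
#' `F = ((m+ - m)^2 + (m- - m)^2) / (v+ + v-)`, with `F = 0` when both
#' variances vanish.  Larger F means better class segregation.
#'
#' @param x numeric feature matrix (rows = interfaces, named columns).
#' @param y labels (`"biological"` / `"crystallographic"`).
#' @return data frame `feature`, `fscore`, in descending F order (ties
#'   broken by feature name).
#' @export
fscore_rank <- function(x, y) {
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(x)
  pos <- y == POSITIVE_CLASS
  f <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    m <- mean(v); mp <- mean(v[pos]); mn <- mean(v[!pos])
    vp <- var(v[pos]); vn <- var(v[!pos])
    denom <- vp + vn
    if (!is.finite(denom) || denom == 0) return(0)
    ((mp - m)^2 + (mn - m)^2) / denom
  }, numeric(1))
  nm <- colnames(x)
  ord <- order(-f, nm)
  data.frame(feature = nm[ord], fscore = f[ord], stringsAsFactors = FALSE)
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)
}

svm_grid <- function(p) {
  list(cost = c(0.1, 1, 10, 100), gamma = c(0.25, 1, 4) / p)
}

fit_svm <- function(x, y, hyper, seed) {
  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  grid <- svm_grid(ncol(x))
  cost <- hyper$cost %||% NULL
  gamma <- hyper$gamma %||% NULL
  if (is.null(cost) || is.null(gamma)) {
    best <- c(acc = -1, cost = 1, gamma = 1 / ncol(x))
    for (cc in grid$cost) for (gg in grid$gamma) {
      set.seed(seed)
      acc <- tryCatch({
        cvm <- e1071::svm(xs, y, kernel = "radial", cost = cc, gamma = gg,
                          scale = FALSE, cross = min(5, min(table(y))))
        cvm$tot.accuracy
      }, error = function(e) -1)
      if (acc > best["acc"]) best <- c(acc = acc, cost = cc, gamma = gg)
    }
    cost <- cost %||% unname(best["cost"])
    gamma <- gamma %||% unname(best["gamma"])
  }
  set.seed(seed)
  fit <- e1071::svm(xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE, probability = TRUE)
  list(fit = fit, standardize = st, cost = cost, gamma = gamma)
}

fit_rf <- function(x, y, hyper, seed) {
  set.seed(seed)
  ntree <- hyper$ntree %||% 500
  fit <- randomForest::randomForest(x, y, ntree = ntree)
  list(fit = fit, ntree = ntree)
}

#' Select features by F-score ranking and SVM cross-validation
#'
#' Ranks features by [fscore_rank()], then for each candidate count k
#' evaluates the cross-validated accuracy of an RBF-SVM on the top-k
#' features, and returns the k maximising mean CV accuracy (ties go to
#' the smaller k).
#'
#' @param x feature matrix; restrict its columns to run the selection
#'   within the classical features only.
#' @param y labels.
#' @param candidate_counts candidate k values (capped at `ncol(x)`).
#' @param k_folds folds of the selection CV (default 5, capped at the
#'   minority class size).
#' @param seed RNG seed.
#' @return character vector of selected feature names, with attributes
#'   `trace` (k vs accuracy) and `k`.
#' @export
select_features <- function(x, y, candidate_counts = c(4, 8, 16, 32, 64),
                            k_folds = 5, seed = 1) {
  y <- as_label_factor(y)
  x <- as.matrix(x)
  ranked <- fscore_rank(x, y)$feature
  ks <- sort(unique(pmin(candidate_counts, ncol(x))))
  folds <- stratified_folds(y, min(k_folds, min(table(y))), seed)
  accs <- vapply(ks, function(k) {
    feats <- ranked[seq_len(k)]
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- folds != f; te <- !tr
      m <- fit_svm(x[tr, feats, drop = FALSE], y[tr], list(), seed)
      pr <- predict(m$fit, standardize_apply(x[te, feats, drop = FALSE],
                                             m$standardize))
      correct <- correct + sum(pr == y[te])
    }
    correct / length(y)
  }, numeric(1))
  k_best <- ks[which.max(accs)]  # which.max takes the first (smallest) max
  out <- ranked[seq_len(k_best)]
  attr(out, "trace") <- data.frame(k = ks, accuracy = accs)
  attr(out, "k") <- k_best
  out
}

#' Fit an interface classifier
#'
#' The central fitting function: a random forest or RBF-kernel SVM on a
#' named feature matrix, optionally preceded by F-score feature
#' selection.  SVM features are standardised with training statistics
#' stored in the model.
#'
#' @param x numeric feature matrix (rows = interfaces, named columns),
#'   or a data frame containing the features plus optional `id`/`label`
#'   columns.
#' @param y labels (`"biological"` / `"crystallographic"`); taken from
#'   `x$label` when omitted.
#' @param kind `"rf"` (default) or `"svm_rbf"`.
#' @param features feature names to use (default: all columns).
#' @param select run [select_features()] within `features` first.
#' @param candidate_counts passed to [select_features()].
#' @param hyper list of hyper-parameters (`ntree`; `cost`, `gamma`).
#' @param seed RNG seed; stored, making refits reproducible.
#' @return object of class `interface_classifier` with
#'   `predict`/`print`/`summary` methods.
#' @export
interface_classifier <- function(x, y = NULL, kind = c("rf", "svm_rbf"),
                                 features = NULL, select = FALSE,
                                 candidate_counts = c(4, 8, 16, 32, 64),
                                 hyper = list(), seed = 1) {
  kind <- match.arg(kind)
  if (is.data.frame(x)) {
    if (is.null(y) && !is.null(x$label)) y <- x$label
    x <- as.matrix(x[, setdiff(names(x), c("id", "label")), drop = FALSE])
  }
  y <- as_label_factor(y)
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (anyNA(x)) stop("missing feature values")
  features <- features %||% colnames(x)
  trace <- NULL
  if (select) {
    features <- select_features(x[, features, drop = FALSE], y,
                                candidate_counts, seed = seed)
    trace <- attr(features, "trace")
  }
  xf <- x[, features, drop = FALSE]
  fit <- switch(kind, rf = fit_rf(xf, y, hyper, seed),
                svm_rbf = fit_svm(xf, y, hyper, seed))
  structure(list(kind = kind, features = as.character(features),
                 fit = fit, seed = seed, n = nrow(xf),
                 class_counts = table(y), selection_trace = trace),
            class = "interface_classifier")
}

#' Predict method for interface classifiers
#'
#' @param object fitted [interface_classifier()].
#' @param newdata feature matrix or data frame; must contain every
#'   selected feature (a missing feature is a hard error naming it).
#' @param type `"class"` for labels, `"score"` for the probability of
#'   the biological class.
#' @param threshold score cut-off for `"class"` (default 0.5).
#' @param ... unused.
#' @return factor of labels or numeric scores.
#' @export
predict.interface_classifier <- function(object, newdata,
                                         type = c("class", "score"),
                                         threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, setdiff(names(newdata), c("id", "label")),
                                 drop = FALSE])
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stop("newdata misses selected feature(s): ", paste(miss, collapse = ", "))
  xf <- newdata[, object$features, drop = FALSE]
  score <- if (object$kind == "rf") {
    predict(object$fit$fit, xf, type = "prob")[, POSITIVE_CLASS]
  } else {
    xs <- standardize_apply(xf, object$fit$standardize)
    pr <- predict(object$fit$fit, xs, probability = TRUE)
    attr(pr, "probabilities")[, POSITIVE_CLASS]
  }
  if (type == "score") return(unname(score))
  factor(ifelse(score > threshold, POSITIVE_CLASS, NEGATIVE_CLASS),
         levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
}

#' @export
print.interface_classifier <- function(x, ...) {
  cat("<interface_classifier> ", x$kind, ", ", length(x$features),
      " features, trained on ", x$n, " interfaces (",
      paste(names(x$class_counts), x$class_counts, sep = ": ",
            collapse = ", "), "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.interface_classifier <- function(object, ...) {
  print(object)
  cat("features: ", paste(object$features, collapse = ", "), "\n")
  if (object$kind == "svm_rbf")
    cat("cost = ", object$fit$cost, ", gamma = ",
        signif(object$fit$gamma, 4), "\n", sep = "")
  if (!is.null(object$selection_trace)) {
    cat("selection trace:\n")
    print(object$selection_trace)
  }
  invisible(object)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, k_folds, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Feature selection (optional) and standardisation are re-fit inside
#' each training fold, so no information from a test fold touches its
#' model.  The confusion matrix is pooled across folds.
#'
#' @inheritParams interface_classifier
#' @param k_folds number of folds (default 5; must not exceed the
#'   minority class count).
#' @param threshold score cut-off for the pooled confusion matrix.
#' @param folds optional pre-assigned fold vector (values `1..k_folds`),
#'   e.g. to reuse one partitioning across classifiers; defaults to a
#'   seeded stratified assignment.
#' @return object of class `cv_result`: `pooled` ([metrics()] report
#'   with `auc`), `per_fold` reports, `folds` assignment, `scores`,
#'   `predicted`, `models`, `seed`.
#' @export
cross_validate <- function(x, y = NULL, kind = c("rf", "svm_rbf"),
                           k_folds = 5, features = NULL, select = FALSE,
                           candidate_counts = c(4, 8, 16, 32, 64),
                           hyper = list(), seed = 1, threshold = 0.5,
                           folds = NULL) {
  kind <- match.arg(kind)
  if (is.data.frame(x)) {
    if (is.null(y) && !is.null(x$label)) y <- x$label
    x <- as.matrix(x[, setdiff(names(x), c("id", "label")), drop = FALSE])
  }
  y <- as_label_factor(y)
  if (k_folds > min(table(y)))
    stop("k_folds exceeds the minority class count")
  if (is.null(folds)) folds <- stratified_folds(y, k_folds, seed)
  stopifnot(length(folds) == length(y))
  scores <- numeric(length(y))
  models <- vector("list", k_folds)
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    m <- interface_classifier(x[tr, , drop = FALSE], y[tr], kind = kind,
                              features = features, select = select,
                              candidate_counts = candidate_counts,
                              hyper = hyper, seed = seed + f)
    models[[f]] <- m
    sc <- predict(m, x[!tr, , drop = FALSE], type = "score")
    scores[!tr] <- sc
    pred_f <- sc > threshold
    yt <- y[!tr] == POSITIVE_CLASS
    per_fold[[f]] <- metrics(tp = sum(pred_f & yt), fn = sum(!pred_f & yt),
                             tn = sum(!pred_f & !yt), fp = sum(pred_f & !yt))
  }
  pred <- scores > threshold
  ypos <- y == POSITIVE_CLASS
  pooled <- metrics(tp = sum(pred & ypos), fn = sum(!pred & ypos),
                    tn = sum(!pred & !ypos), fp = sum(pred & !ypos))
  pooled$auc <- roc_auc(scores, y)
  structure(list(pooled = pooled, per_fold = per_fold, folds = folds,
                 scores = scores,
                 predicted = factor(ifelse(pred, POSITIVE_CLASS,
                                           NEGATIVE_CLASS),
                                    levels = levels(y)),
                 models = models, kind = kind, seed = seed,
                 threshold = threshold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$per_fold), "-fold CV, ", x$kind, "\n",
      sep = "")
  print(x$pooled)
  invisible(x)
}

#' Classification performance measures
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, accuracy
#' `(TP+TN)/n`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when any
#' factor of the denominator vanishes).
#'
#' @param tp,fn,tn,fp confusion-matrix counts (biological = positive).
#' @return object of class `perf_report`.
#' @export
metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  n <- tp + fn + tn + fp
  if (n == 0) stop("empty confusion matrix")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  ac <- (tp + tn) / n
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) /
    sqrt(denom)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sn = sn, sp = sp, ac = ac, mcc = mcc),
            class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  Sn %.3f  Sp %.3f  Ac %.3f  MCC %.3f%s\n", x$sn, x$sp,
              x$ac, x$mcc,
              if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) with mid-ranks for ties: the
#' probability that a random biological interface scores above a random
#' crystallographic one.
#'
#' @param scores continuous classifier scores (higher = more
#'   biological).
#' @param labels labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label_factor(labels) == POSITIVE_CLASS
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes needed for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Remove sequence redundancy from a dataset
#'
#' Single-linkage clustering of sequences at `threshold` percent
#' identity (computed on pairwise global alignments) keeping one
#' representative (the first member) per cluster — the standard
#' dataset-preparation step before training.
#'
#' @param seqs character vector of (unaligned) sequences.
#' @param threshold percent identity (default 30).
#' @return integer indices of the retained representatives.
#' @export
remove_redundancy <- function(seqs, threshold = 30) {
  n <- length(seqs)
  if (n <= 1L) return(seq_len(n))
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for pairwise identities")
  id <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[j]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    p <- Biostrings::pid(al)
    id[i, j] <- id[j, i] <- if (is.finite(p)) p else 0
  }
  # single linkage: connected components of the >= threshold graph
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (id[i, j] >= threshold && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(unique(comp), comp)
}

#' Save / load a trained classifier
#'
#' Versioned plain-text archive (JSON header plus base64 payload of the
#' fitted parameters) so models round-trip without binary files.
#'
#' @param model an `interface_classifier`.
#' @param path archive file.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  payload <- jsonlite::base64_enc(serialize(model, NULL, version = 2))
  obj <- list(format = "xtalface_model", version = 1L,
              kind = model$kind, features = model$features,
              seed = model$seed, payload = payload)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = ""))
  if (!identical(obj$format, "xtalface_model"))
    stop("not an xtalface model archive")
  unserialize(jsonlite::base64_dec(obj$payload))
}
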
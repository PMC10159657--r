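#' Built-in candidate model families for cross-validated comparison
#'
#' Each candidate is a list with a `name`, a `fit(x, y, seed)` function and
#' a `predict_proba(fit, x)` function returning the probability of the
#' binding class. The random forest is always available; the other families
#' (logistic regression, k-nearest neighbours, naive Bayes, SVM) are thin
#' wrappers over their standard implementations and are included only when
#' the backing package is installed.
#'
#' @param names Which candidates to build; any of `"random_forest"`,
#'   `"logistic"`, `"knn3"`, `"naive_bayes"`, `"svm_linear"`.
#' @param n_trees Tree count for the random-forest candidate.
#' @return Named list of candidate definitions.
#' @export
default_candidates <- function(names = c("random_forest", "logistic"),
                               n_trees = 100L) {
  all <- list(
    random_forest = list(
      name = "random_forest",
      fit = function(x, y, seed) tcrbind(features = x, labels = y,
                                         mode = if (ncol(x) == 1280L) "pmhc" else "pair",
                                         n_trees = n_trees, seed = seed),
      predict_proba = function(fit, x) predict(fit, x)),
    logistic = list(
      name = "logistic",
      fit = function(x, y, seed) {
        suppressWarnings(stats::glm.fit(cbind(1, x), y, family = binomial()))
      },
      predict_proba = function(fit, x) {
        eta <- drop(cbind(1, x) %*% ifelse(is.na(fit$coefficients), 0,
                                           fit$coefficients))
        1 / (1 + exp(-eta))
      }),
    knn3 = list(
      name = "knn3",
      fit = function(x, y, seed) list(x = x, y = y),
      predict_proba = function(fit, x) {
        if (!requireNamespace("class", quietly = TRUE))
          stop("candidate knn3 needs the 'class' package")
        pr <- class::knn(fit$x, x, factor(fit$y, levels = c(0, 1)), k = 3,
                         prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }),
    naive_bayes = list(
      name = "naive_bayes",
      fit = function(x, y, seed) {
        if (!requireNamespace("e1071", quietly = TRUE))
          stop("candidate naive_bayes needs the 'e1071' package")
        e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
      },
      predict_proba = function(fit, x)
        e1071:::predict.naiveBayes(fit, x, type = "raw")[, "1"]),
    svm_linear = list(
      name = "svm_linear",
      fit = function(x, y, seed) {
        if (!requireNamespace("e1071", quietly = TRUE))
          stop("candidate svm_linear needs the 'e1071' package")
        with_seed(seed, e1071::svm(x, factor(y, levels = c(0, 1)),
                                   kernel = "linear", probability = TRUE))
      },
      predict_proba = function(fit, x)
        attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"])
  )
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown candidate(s): ",
                            paste(missing, collapse = ", "))
  all[names]
}

#' Compare candidate models by stratified k-fold cross-validation
#'
#' Folds are stratified on the binding label, assembled deterministically
#' under `seed`, disjoint, and cover the data. Per fold each candidate is
#' fit on k-1 folds and scored on the held-out fold; the table reports
#' per-candidate mean validation accuracy (at threshold 0.5), mean
#' validation AUC and mean fit time, sorted by accuracy descending.
#'
#' @param features Feature matrix (e.g. from [encode_batch()]).
#' @param labels 0/1 vector.
#' @param candidates List of candidate definitions
#'   (see [default_candidates()]); must include the random forest.
#' @param k Number of folds (>= 2, and at most the minority-class count).
#' @param seed Integer seed.
#' @param threshold Accuracy threshold; default 0.5.
#' @return Object of class `"cv_comparison"`: data frame with columns
#'   `model`, `mean_accuracy`, `mean_auc`, `mean_fit_time`.
#' @export
cross_validate_models <- function(features, labels,
                                  candidates = default_candidates(),
                                  k = 5L, seed = 1L, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  if (k < 2L) stop("k must be >= 2")
  if (min(table(labels)) < k)
    stop("k exceeds the minority-class count")
  folds <- cv_folds(labels, k, seed)
  rows <- lapply(candidates, function(cand) {
    acc <- auc <- tim <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      t0 <- proc.time()[["elapsed"]]
      fit <- cand$fit(features[tr, , drop = FALSE], labels[tr], seed)
      tim[f] <- proc.time()[["elapsed"]] - t0
      p <- cand$predict_proba(fit, features[!tr, , drop = FALSE])
      truth <- labels[!tr]
      acc[f] <- mean(classify(p, threshold) == truth)
      auc[f] <- roc_auc(p, truth)$auc
    }
    data.frame(model = cand$name, mean_accuracy = mean(acc),
               mean_auc = mean(auc), mean_fit_time = mean(tim),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_accuracy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cv_comparison", "data.frame"), k = k, seed = seed)
}

# Stratified fold ids: within each class, shuffled rows are dealt round-robin.
cv_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      rows <- which(labels == cls)
      rows <- rows[sample.int(length(rows))]
      fold[rows] <- ((seq_along(rows) - 1L) %% k) + 1L
    }
    fold
  })
}

#' @export
print.cv_comparison <- function(x, digits = 3, ...) {
  cat(attr(x, "k"), "-fold cross-validated model comparison\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
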
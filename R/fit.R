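MODEL_FORMAT_VERSION <- 1L

#' Fit the TCR-peptide binding random-forest classifier
#'
#' The central fitting function of the package. Labelled observations are
#' encoded as positional BLOSUM62 feature vectors (600 features in
#' `"pair"` mode, 1280 in `"pmhc"` mode) and a probability random forest is
#' grown on them. Class imbalance is handled upstream by negative
#' downsampling ([sample_negatives()]), not by class weights, so the forest
#' itself is fit with uniform weights.
#'
#' @param records Validated, labelled pair table; alternatively supply
#'   `features` and `labels` directly (e.g. from [encode_batch()]).
#' @param mode `"pair"` or `"pmhc"`.
#' @param n_trees Number of trees; default 300.
#' @param seed Integer seed; the fit is deterministic given it (single
#'   threaded).
#' @param matrix Substitution matrix used for encoding.
#' @param pseudo_map Allele lookup for pmhc mode (see [encode_batch()]).
#' @param features,labels Optional pre-encoded feature matrix and 0/1 label
#'   vector, bypassing `records`.
#' @param mtry Number of candidate features per split; default
#'   `floor(sqrt(p))`.
#' @return Object of class `"tcrbind_model"` with the fitted forest, its
#'   encoding mode and training metadata (`n_pos`, `n_neg`, class ratio).
#' @examples
#' rep <- generate_repertoire(synthetic_config(n_pairs = 400, seed = 7))
#' fit <- tcrbind(rep$records, n_trees = 50, seed = 7)
#' print(fit)
#' @export
tcrbind <- function(records = NULL, mode = c("pair", "pmhc"), n_trees = 300L,
                    seed = 1L, matrix = blosum62(), pseudo_map = NULL,
                    features = NULL, labels = NULL, mtry = NULL) {
  mode <- match.arg(mode)
  if (is.null(features)) {
    if (is.null(records)) stop("supply either records or features + labels")
    assert_validated(records, require_label = TRUE)
    features <- encode_batch(records, mode, matrix, pseudo_map)
    labels <- records$label
  }
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("feature row count (", nrow(features), ") != label count (",
         length(labels), ")")
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  expect_p <- if (mode == "pair") 600L else 1280L
  if (ncol(features) != expect_p)
    stop("feature width ", ncol(features), " does not match mode ", mode,
         " (expected ", expect_p, ")")
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.label <- factor(labels, levels = c(0L, 1L))
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, probability = TRUE,
    mtry = mtry %||% floor(sqrt(ncol(features))),
    seed = as.integer(seed), num.threads = 1L, verbose = FALSE)
  structure(list(forest = forest, mode = mode, n_trees = as.integer(n_trees),
                 seed = as.integer(seed), n_features = ncol(features),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 class_ratio = sum(labels == 1L) / sum(labels == 0L),
                 oob_error = forest$prediction.error,
                 format_version = MODEL_FORMAT_VERSION),
            class = "tcrbind_model")
}

#' @export
print.tcrbind_model <- function(x, ...) {
  cat("TCR-peptide binding random forest (", x$mode, " mode, ",
      x$n_features, " features)\n", sep = "")
  cat("  trees: ", x$n_trees, "   seed: ", x$seed, "\n", sep = "")
  cat("  training: ", x$n_pos, " binding / ", x$n_neg, " non-binding (1:",
      round(1 / x$class_ratio, 1), ")\n", sep = "")
  cat("  OOB Brier score: ", signif(x$oob_error, 4), "\n", sep = "")
  invisible(x)
}

#' @method summary tcrbind_model
#' @export
summary.tcrbind_model <- function(object, ...) {
  print(object)
  cat("  probability threshold convention: label 1 iff p >= threshold\n")
  invisible(object)
}

#' Predict binding probabilities or labels
#'
#' @param object A fitted `"tcrbind_model"`.
#' @param newdata Validated pair table, or a pre-encoded feature matrix
#'   whose width matches the model's mode.
#' @param type `"prob"` for binding probabilities in `[0, 1]`, `"class"`
#'   for 0/1 labels at `threshold`.
#' @param threshold Classification threshold (used for `type = "class"`);
#'   default 0.5, ties classify as binding (`>=`).
#' @param matrix,pseudo_map Encoding arguments, as in [tcrbind()].
#' @param ... Unused.
#' @return Numeric probability vector or integer 0/1 vector, one per row.
#' @export
predict.tcrbind_model <- function(object, newdata, type = c("prob", "class"),
                                  threshold = 0.5, matrix = blosum62(),
                                  pseudo_map = NULL, ...) {
  type <- match.arg(type)
  features <- if (is.data.frame(newdata))
    encode_batch(newdata, object$mode, matrix, pseudo_map)
  else as.matrix(newdata)
  if (ncol(features) != object$n_features)
    stop("feature width ", ncol(features), " does not match this ",
         object$mode, "-mode model (expected ", object$n_features, ")")
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  pr <- predict(object$forest, data = df, num.threads = 1L,
                verbose = FALSE)$predictions
  prob <- as.numeric(pr[, "1"])
  if (type == "prob") prob else classify(prob, threshold)
}

#' Threshold probabilities into binary binding calls
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Value in the open interval (0, 1); default 0.5.
#'   A pair is called binding iff its probability is `>=` the threshold.
#' @return Integer vector of 0/1 labels.
#' @examples
#' classify(c(0.49, 0.5, 0.51))  # 0 1 1
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  as.integer(probabilities >= threshold)
}

#' Save / load a fitted model
#'
#' The on-disk artifact is a single serialized file with an embedded
#' metadata block (mode, tree count, seed, format version). Loading a file
#' written by a newer format version fails rather than mispredicting.
#'
#' @param model A `"tcrbind_model"`.
#' @param path File path.
#' @return `save_tcrbind()` returns `path` invisibly; `load_tcrbind()`
#'   returns the model, which yields identical predictions to the saved one.
#' @export
save_tcrbind <- function(model, path) {
  stopifnot(inherits(model, "tcrbind_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tcrbind
#' @export
load_tcrbind <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("corrupt model file: ",
                                             conditionMessage(e)))
  if (!is.list(model) || is.null(model$format_version))
    stop("not a tcrbind model file")
  if (model$format_version > MODEL_FORMAT_VERSION)
    stop("model file format version ", model$format_version,
         " is newer than this package supports (", MODEL_FORMAT_VERSION, ")")
  structure(model, class = "tcrbind_model")
}
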
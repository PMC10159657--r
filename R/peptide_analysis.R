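#' Attribute false positives to peptides and find the dominant set
#'
#' For an evaluated set, counts false positives (predicted binding, truly
#' non-binding at the threshold) per peptide and reports each peptide's
#' share of all false positives and of all binding pairs. The "dominant"
#' set is the smallest set of peptides whose cumulative FP share reaches
#' `share_cutoff` (peptides sorted by FP count descending, ties broken
#' alphabetically), or exactly the `top_n` highest-FP peptides when
#' `top_n` is given.
#'
#' @param peptides Character vector: the peptide of each evaluated pair.
#' @param probabilities,truth,threshold As in [metrics_report()].
#' @param share_cutoff Cumulative FP-share cutoff defining dominance;
#'   default 0.95.
#' @param top_n Optional explicit size of the dominant set (overrides the
#'   cutoff).
#' @return Object of class `"fp_attribution"`: list with `table` (per
#'   peptide: `n_pairs`, `n_binding`, `n_fp`, `fp_share`, `binding_share`,
#'   sorted by `n_fp` descending), `dominant` (character vector) and
#'   `n_fp_total`. With zero false positives the table is empty and the
#'   object is flagged `no_fp = TRUE`.
#' @export
fp_attribution <- function(peptides, probabilities, truth, threshold = 0.5,
                           share_cutoff = 0.95, top_n = NULL) {
  stopifnot(length(peptides) == length(probabilities),
            length(probabilities) == length(truth))
  truth <- as.integer(truth)
  pred <- classify(probabilities, threshold)
  fp <- pred == 1L & truth == 0L
  n_fp_total <- sum(fp)
  tab <- data.frame(
    peptide = sort(unique(peptides)), stringsAsFactors = FALSE)
  tab$n_pairs <- as.integer(table(factor(peptides, tab$peptide)))
  tab$n_binding <- as.integer(tapply(truth == 1L,
                                     factor(peptides, tab$peptide), sum))
  tab$n_fp <- as.integer(tapply(fp, factor(peptides, tab$peptide), sum))
  if (n_fp_total == 0L) {
    return(structure(list(table = tab[0, ], dominant = character(0),
                          n_fp_total = 0L, no_fp = TRUE),
                     class = "fp_attribution"))
  }
  tab$fp_share <- tab$n_fp / n_fp_total
  n_binding_total <- sum(tab$n_binding)
  tab$binding_share <- if (n_binding_total > 0)
    tab$n_binding / n_binding_total else NA_real_
  tab <- tab[order(-tab$n_fp, tab$peptide), , drop = FALSE]
  rownames(tab) <- NULL
  dominant <- if (!is.null(top_n)) {
    utils::head(tab$peptide, top_n)
  } else {
    cum <- cumsum(tab$fp_share)
    tab$peptide[seq_len(which(cum >= share_cutoff - 1e-12)[1])]
  }
  structure(list(table = tab, dominant = dominant, n_fp_total = n_fp_total,
                 no_fp = FALSE),
            class = "fp_attribution")
}

#' @export
print.fp_attribution <- function(x, ...) {
  if (isTRUE(x$no_fp)) {
    cat("No false positives in the evaluated set.\n")
    return(invisible(x))
  }
  cat("False-positive attribution over", nrow(x$table), "peptides (",
      x$n_fp_total, "FPs );", length(x$dominant), "dominant peptide(s):\n ",
      paste(x$dominant, collapse = ", "), "\n")
  print(utils::head(x$table, 10), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Retrain at varying binding ratios for a chosen peptide set
#'
#' Rebuilds the training set at each target binding:non-binding ratio by
#' resampling only the chosen peptides' records — all their binding records
#' are kept and their non-binding records are down-sampled without
#' replacement (or up-sampled with replacement when the pool is too small)
#' to hit the ratio — while every other peptide's records are passed
#' through untouched. Each rebuilt set trains a fresh forest which is then
#' evaluated on the fixed test set in three strata: overall, the chosen
#' peptides, and the others.
#'
#' @param train,test Labelled pair tables; `test` is never resampled.
#' @param peptides Character vector of chosen (e.g. dominant) peptides;
#'   they must be present in `train` with both classes.
#' @param ratios Numeric vector of target binding/non-binding ratios (the
#'   original data sits around 0.05 for dominant peptides and 0.015 for the
#'   rest).
#' @param seed Integer seed.
#' @param n_trees,threshold Forwarded to [tcrbind()] / [metrics_report()].
#' @return Data frame: one [metrics_report()] row per ratio x stratum, plus
#'   columns `ratio` and `n_train`.
#' @export
ratio_titration <- function(train, test, peptides, ratios, seed = 1L,
                            n_trees = 150L, threshold = 0.5) {
  assert_validated(train, require_label = TRUE)
  assert_validated(test, require_label = TRUE)
  chosen <- train$peptide %in% peptides
  ch <- train[chosen, , drop = FALSE]
  others <- train[!chosen, , drop = FALSE]
  if (!sum(ch$label == 1L) || !sum(ch$label == 0L))
    stop("chosen peptides must be present in train with both classes")
  test_grp <- ifelse(test$peptide %in% peptides, "chosen", "others")
  out <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    if (r <= 0) stop("ratios must be > 0")
    pos <- which(ch$label == 1L); neg <- which(ch$label == 0L)
    n_neg_target <- round(length(pos) / r)
    if (n_neg_target < 1)
      stop("ratio ", r, " unreachable: needs fewer than one negative")
    neg_rows <- with_seed(seed + i, {
      if (n_neg_target <= length(neg)) sort(sample(neg, n_neg_target))
      else sort(sample(neg, n_neg_target, replace = TRUE))
    })
    new_train <- rbind(others, ch[pos, , drop = FALSE],
                       ch[neg_rows, , drop = FALSE])
    rownames(new_train) <- NULL
    fit <- tcrbind(new_train, n_trees = n_trees, seed = seed)
    prob <- predict(fit, test)
    rep_all <- metrics_report(prob, test$label, threshold, stratum = "overall")
    rep_grp <- stratified_report(test_grp, prob, test$label, threshold)
    block <- rbind(rep_all, rep_grp)
    block$ratio <- r
    block$n_train <- nrow(new_train)
    out[[i]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Train a model restricted to a single peptide
#'
#' Fits a forest only on the given peptide's pairs (the peptide feature
#' block is then constant, so the model can only exploit CDR3beta signal)
#' and evaluates it on a held-out fraction of the same peptide's pairs,
#' split stratified on the label.
#'
#' @param records Labelled pair table.
#' @param peptide The peptide to isolate.
#' @param seed Integer seed.
#' @param min_records Minimum number of records required; default 10.
#' @param test_fraction Held-out fraction; default 0.3.
#' @param n_trees,threshold Forwarded to [tcrbind()] / [metrics_report()].
#' @return List with `model` (a `"tcrbind_model"`) and `report`
#'   (a [metrics_report()] row for the held-out pairs).
#' @export
train_peptide_specific_model <- function(records, peptide, seed = 1L,
                                         min_records = 10L,
                                         test_fraction = 0.3,
                                         n_trees = 150L, threshold = 0.5) {
  assert_validated(records, require_label = TRUE)
  sub <- records[records$peptide == peptide, , drop = FALSE]
  if (nrow(sub) < min_records)
    stop("only ", nrow(sub), " records for peptide ", peptide,
         " (minimum ", min_records, ")")
  if (length(unique(sub$label)) < 2L)
    stop("peptide ", peptide, " has single-class data")
  test_rows <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(sub)), sub$label), function(rows) {
      rows <- rows[sample.int(length(rows))]
      rows[seq_len(max(1L, round(test_fraction * length(rows))))]
    }), use.names = FALSE)
  })
  train <- sub[-test_rows, , drop = FALSE]
  test <- sub[test_rows, , drop = FALSE]
  if (length(unique(train$label)) < 2L || length(unique(test$label)) < 2L)
    stop("insufficient data in both classes after the split")
  fit <- tcrbind(train, n_trees = n_trees, seed = seed)
  prob <- predict(fit, test)
  list(model = fit,
       report = metrics_report(prob, test$label, threshold, stratum = peptide))
}

#' Normalised Levenshtein similarity between sequences
#'
#' `1 - d(a, b) / max(nchar(a), nchar(b))` where `d` is the standard
#' unit-cost edit distance. Vectorised elementwise over `a` and `b`;
#' identical sequences score 1, maximally different same-length sequences
#' score 0.
#'
#' @param a,b Character vectors of non-empty sequences (recycled).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' levenshtein_similarity("GILGFVFTL", "GILGFVFTV")  # 1 - 1/9
#' @export
levenshtein_similarity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(!nchar(a)) || any(!nchar(b)) || anyNA(a) || anyNA(b))
    stop("sequences must be non-empty")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  d <- vapply(seq_len(n), function(i) utils::adist(a[i], b[i])[1, 1], 0)
  1 - d / pmax(nchar(a), nchar(b))
}

#' Pairwise Levenshtein similarity matrix
#'
#' @param peptides Character vector of sequences.
#' @return Symmetric numeric matrix with unit diagonal, dimnames =
#'   `peptides`.
#' @export
peptide_similarity_matrix <- function(peptides) {
  if (!length(peptides)) stop("no peptides given")
  d <- utils::adist(peptides, peptides)
  len <- nchar(peptides)
  sim <- 1 - d / outer(len, len, pmax)
  dimnames(sim) <- list(peptides, peptides)
  sim
}

#' Cluster peptides on Levenshtein similarity and pick representatives
#'
#' Medoid-based partitioning (PAM) on the distance matrix
#' `1 - similarity`. Each cluster's representative is its medoid — the
#' member with maximal mean within-cluster similarity. PAM's build+swap
#' optimisation is deterministic for a given input; the `seed` is recorded
#' and applied so any backend stochasticity is also pinned.
#'
#' @param peptides Character vector of distinct peptides (at least
#'   `n_clusters` of them).
#' @param n_clusters Number of clusters; default 6.
#' @param seed Integer seed.
#' @return List with `assignment` (named integer vector),
#'   `representatives` (character, one medoid per cluster) and
#'   `similarity` (the matrix used).
#' @export
cluster_peptides <- function(peptides, n_clusters = 6L, seed = 1L) {
  peptides <- unique(peptides)
  if (length(peptides) < n_clusters)
    stop("need at least ", n_clusters, " distinct peptides")
  sim <- peptide_similarity_matrix(peptides)
  if (n_clusters == length(peptides)) {
    assignment <- setNames(seq_along(peptides), peptides)
    return(list(assignment = assignment, representatives = peptides,
                similarity = sim))
  }
  fit <- with_seed(seed,
    cluster::pam(stats::as.dist(1 - sim), k = n_clusters, diss = TRUE))
  assignment <- setNames(as.integer(fit$clustering), peptides)
  list(assignment = assignment,
       representatives = peptides[fit$id.med],
       similarity = sim)
}

#' RMSE between training label proportions and predicted labels, by
#' similarity bin
#'
#' Training peptides are grouped into bins of Levenshtein similarity to the
#' representative ( intervals `(lo, hi]` of width `bin_width` over
#' `[0, 1]`, with 0 included in the first bin). For each non-empty bin the
#' proportion vector of peptide label categories (binding, non-binding,
#' mix) is compared with the representative's predicted-label proportion
#' vector — (share of its pairs predicted binding, share predicted
#' non-binding, 0) — by the root mean squared componentwise difference.
#' Empty bins are flagged, not zero-filled.
#'
#' @param representative A single peptide sequence.
#' @param train_peptides Character vector of training peptides.
#' @param train_categories Character vector: each training peptide's label
#'   category, `"binding"`, `"non-binding"` or `"mix"`
#'   (see [peptide_categories()] via the curation step, or supply your own).
#' @param predicted 0/1 vector of predicted labels for the representative's
#'   test pairs.
#' @param bin_width Bin width over similarity; default 0.1.
#' @return Data frame, one row per bin: `bin_lo`, `bin_hi`, `n_peptides`,
#'   `p_binding`, `p_nonbinding`, `p_mix`, `rmse`, `empty`.
#' @export
similarity_bin_rmse <- function(representative, train_peptides,
                                train_categories, predicted,
                                bin_width = 0.1) {
  if (!length(train_peptides)) stop("no training peptides")
  stopifnot(length(train_peptides) == length(train_categories))
  if (!length(predicted)) stop("representative has no predictions")
  predicted <- as.integer(predicted)
  pred_vec <- c(binding = mean(predicted == 1L),
                `non-binding` = mean(predicted == 0L), mix = 0)
  sim <- levenshtein_similarity(rep(representative, length(train_peptides)),
                                train_peptides)
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- cut(sim, breaks = edges, include.lowest = TRUE, right = TRUE)
  out <- lapply(seq_along(levels(bin)), function(i) {
    rows <- which(as.integer(bin) == i)
    lo <- edges[i]; hi <- edges[i + 1]
    if (!length(rows))
      return(data.frame(bin_lo = lo, bin_hi = hi, n_peptides = 0L,
                        p_binding = NA_real_, p_nonbinding = NA_real_,
                        p_mix = NA_real_, rmse = NA_real_, empty = TRUE))
    cats <- factor(train_categories[rows],
                   levels = c("binding", "non-binding", "mix"))
    prop <- as.numeric(table(cats)) / length(rows)
    data.frame(bin_lo = lo, bin_hi = hi, n_peptides = length(rows),
               p_binding = prop[1], p_nonbinding = prop[2], p_mix = prop[3],
               rmse = sqrt(mean((prop - pred_vec)^2)), empty = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-peptide label categories of a pair table
#'
#' Classifies every distinct peptide as `"binding"` (only label-1 pairs),
#' `"non-binding"` (only label-0), `"mix"` (both), or `"generated"` (all
#' its pairs tagged `source = "generated-wildtype"`).
#'
#' @param records Labelled pair table.
#' @return Data frame with columns `peptide` and `category`.
#' @export
peptide_label_categories <- function(records) {
  assert_validated(records, require_label = TRUE)
  peptide_categories(records)
}
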
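pair_key <- function(records, use_hla = FALSE) {
  if (use_hla)
    paste(records$cdr3b, records$peptide, records$hla, sep = "\r")
  else
    paste(records$cdr3b, records$peptide, sep = "\r")
}

#' Merge several pair tables, removing duplicates
#'
#' Concatenates the sources and collapses exact duplicates of the
#' deduplication key plus label: `(cdr3b, peptide, label)` without MHC, or
#' `(cdr3b, peptide, hla, label)` when `use_hla = TRUE`. Source tags of
#' collapsed duplicates are concatenated with `";"` in first-seen order.
#'
#' @param sources List of validated pair tables.
#' @param use_hla Include the HLA allele in the duplicate key?
#' @return A single deduplicated pair table.
#' @export
merge_and_deduplicate <- function(sources, use_hla = FALSE) {
  stopifnot(is.list(sources), length(sources) >= 1)
  for (s in sources) assert_validated(s)
  all <- do.call(rbind, sources)
  rownames(all) <- NULL
  key <- paste(pair_key(all, use_hla), all$label, sep = "\r")
  first <- !duplicated(key)
  src <- vapply(split(all$source, factor(key, levels = unique(key))),
                function(s) {
                  s <- unique(s[!is.na(s)])
                  if (length(s)) paste(s, collapse = ";") else NA_character_
                }, character(1))
  out <- all[first, , drop = FALSE]
  out$source <- unname(src[match(key[first], unique(key))])
  rownames(out) <- NULL
  out
}

#' Remove label-conflicted TCR-peptide keys
#'
#' A key (`(cdr3b, peptide)`, or `(cdr3b, peptide, hla)` with
#' `use_hla = TRUE`) observed with both label 1 and label 0 is dropped
#' entirely — both sides — so no label noise from conflicting reports
#' enters training.
#'
#' @param records Deduplicated, labelled pair table.
#' @param use_hla Include the HLA allele in the key?
#' @return List with `records` (conflict-free) and `conflicts`, a data frame
#'   of removed keys with their positive/negative counts.
#' @export
remove_conflicts <- function(records, use_hla = FALSE) {
  assert_validated(records, require_label = TRUE)
  key <- pair_key(records, use_hla)
  pos <- tapply(records$label == 1L, key, any)
  neg <- tapply(records$label == 0L, key, any)
  bad_keys <- names(pos)[pos & neg]
  keep <- !(key %in% bad_keys)
  conflicts <- if (length(bad_keys)) {
    parts <- do.call(rbind, strsplit(bad_keys, "\r", fixed = TRUE))
    data.frame(cdr3b = parts[, 1], peptide = parts[, 2],
               hla = if (use_hla) parts[, 3] else NA_character_,
               n_pos = as.integer(tapply(records$label == 1L, key, sum)[bad_keys]),
               n_neg = as.integer(tapply(records$label == 0L, key, sum)[bad_keys]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(cdr3b = character(0), peptide = character(0),
               hla = character(0), n_pos = integer(0), n_neg = integer(0))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, conflicts = conflicts)
}

#' Split records into disjoint, peptide-diverse subsets
#'
#' Emulates the construction of training/testing subsets: records are
#' stratified on peptide identity, each peptide's observations are spread
#' across subsets round-robin (proportional allocation, rotating remainder),
#' and every subset is trimmed to the common target size. Subsets are
#' mutually disjoint at the record level; the same (cdr3b, peptide) pair
#' never lands in two subsets because input records are unique after
#' curation.
#'
#' @param records Conflict-free pair table.
#' @param n_subsets Number of subsets to form.
#' @param size_range Length-2 integer vector: admissible subset sizes.
#'   Default `c(70000, 75000)`, the scale used for full-size collections.
#' @param seed Integer seed; the split is deterministic given it.
#' @return Object of class `"dataset_split"`: list with `subsets` (list of
#'   pair tables), `seed` and `size_range`.
#' @export
make_subsets <- function(records, n_subsets, size_range = c(70000, 75000),
                         seed = 1L) {
  assert_validated(records)
  n <- nrow(records)
  if (n < n_subsets * size_range[1])
    stop("insufficient records: ", n, " < ", n_subsets, " x ", size_range[1])
  target <- min(size_range[2], floor(n / n_subsets))
  with_seed(seed, {
    assign_id <- integer(n)
    offset <- 0L
    for (rows in split(seq_len(n), records$peptide)) {
      rows <- rows[sample.int(length(rows))]
      assign_id[rows] <- ((offset + seq_along(rows) - 1L) %% n_subsets) + 1L
      offset <- offset + length(rows)
    }
    subsets <- lapply(seq_len(n_subsets), function(i) {
      rows <- which(assign_id == i)
      if (length(rows) > target) rows <- sort(sample(rows, target))
      if (length(rows) < size_range[1])
        stop("subset ", i, " fell below the minimum size")
      out <- records[rows, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    structure(list(subsets = subsets, seed = seed, size_range = size_range),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Dataset split:", length(x$subsets), "disjoint subsets, sizes",
      paste(range(vapply(x$subsets, nrow, 0L)), collapse = "-"),
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Downsample non-binding records to a fixed class ratio
#'
#' All binding records are kept exhaustively; non-binding records are
#' sampled uniformly without replacement down to `ratio` times the number
#' of binding ones (or all of them, if the pool is smaller). The default
#' ratio of 10 is the 1:10 binding:non-binding training composition.
#'
#' @param records Labelled pair table containing both classes.
#' @param ratio Non-binding records retained per binding record; must be > 0.
#' @param seed Integer seed.
#' @return Pair table, positives first then sampled negatives.
#' @export
sample_negatives <- function(records, ratio = 10, seed = 1L) {
  assert_validated(records, require_label = TRUE)
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be > 0")
  pos <- which(records$label == 1L)
  neg <- which(records$label == 0L)
  if (!length(pos) || !length(neg))
    stop("records must contain both binding and non-binding observations")
  quota <- min(length(neg), floor(ratio * length(pos)))
  keep_neg <- with_seed(seed, sort(sample(neg, quota)))
  out <- records[c(pos, keep_neg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate wild-type negative pairs
#'
#' Forms `n_pairs` unique random (CDR3beta, peptide) combinations from the
#' supplied wild-type peptide and known TCR pools, excluding any combination
#' already present among `exclude` records, and labels them all 0. This is
#' the construction used to supply non-binding peptides for unseen-peptide
#' training: wild-type (unmutated self) peptides are assumed not to elicit
#' T-cell responses.
#'
#' @param wildtype_peptides Character vector of valid peptides.
#' @param known_tcrs Character vector of valid CDR3beta sequences.
#' @param n_pairs Number of pairs to generate.
#' @param seed Integer seed.
#' @param exclude Optional pair table whose (cdr3b, peptide) combinations
#'   must not be emitted.
#' @return Pair table of `n_pairs` label-0 records tagged
#'   `source = "generated-wildtype"`.
#' @export
generate_wildtype_negatives <- function(wildtype_peptides, known_tcrs,
                                        n_pairs, seed = 1L, exclude = NULL) {
  peps <- unique(toupper(wildtype_peptides))
  tcrs <- unique(toupper(known_tcrs))
  if (!length(peps) || !length(tcrs)) stop("both pools must be non-empty")
  total <- as.numeric(length(peps)) * length(tcrs)
  banned <- character(0)
  if (!is.null(exclude)) banned <- unique(pair_key(exclude))
  # Count collisions without materialising the grid: a banned key collides
  # iff both of its members are in the pools.
  if (length(banned)) {
    parts <- strsplit(banned, "\r", fixed = TRUE)
    hit <- vapply(parts, function(p) p[1] %in% tcrs && p[2] %in% peps, NA)
    avail <- total - sum(hit)
  } else avail <- total
  if (n_pairs > avail)
    stop("n_pairs exceeds the number of available unique combinations (",
         format(avail, scientific = FALSE), ")")
  with_seed(seed, {
    picked <- character(0)
    while (length(picked) < n_pairs) {
      need <- n_pairs - length(picked)
      idx <- sample(total, min(total, ceiling(need * 1.3) + 10L))
      ti <- ((idx - 1) %% length(tcrs)) + 1
      pi <- ((idx - 1) %/% length(tcrs)) + 1
      key <- paste(tcrs[ti], peps[pi], sep = "\r")
      key <- setdiff(unique(key), c(picked, banned))
      picked <- c(picked, key)
    }
    picked <- picked[seq_len(n_pairs)]
    parts <- do.call(rbind, strsplit(picked, "\r", fixed = TRUE))
    pair_records(parts[, 1], parts[, 2], label = 0L,
                 source = "generated-wildtype")
  })
}

# Per-peptide label category: binding / non-binding / mix / generated.
peptide_categories <- function(records) {
  gen <- !is.na(records$source) & records$source == "generated-wildtype"
  pos <- tapply(records$label == 1L, records$peptide, any)
  neg <- tapply(records$label == 0L, records$peptide, any)
  genp <- tapply(gen, records$peptide, all)
  cat <- ifelse(genp, "generated",
                ifelse(pos & neg, "mix", ifelse(pos, "binding", "non-binding")))
  data.frame(peptide = names(pos), category = unname(cat),
             stringsAsFactors = FALSE)
}

#' Split records so test peptides are unseen in training
#'
#' Partitions the peptides (not the observations): a fraction of peptides
#' goes to training and the rest to test sets, and every observation follows
#' its peptide's side, so no test peptide ever appears in training.
#' Training peptides are drawn stratified over the label categories of
#' peptides (binding / non-binding / mix); generated wild-type negatives
#' (see [generate_wildtype_negatives()]) are all placed in training, where
#' they exist to balance the scarce non-binding peptides.
#'
#' @param records Labelled pair table.
#' @param train_peptide_fraction Fraction of (non-generated) peptides used
#'   for training; default 0.8.
#' @param wildtype_negatives Optional pair table of generated negatives to
#'   append to the training side.
#' @param n_test_sets Number of disjoint test sets formed from the held-out
#'   peptides (round-robin over peptides).
#' @param seed Integer seed.
#' @return Object of class `"unseen_peptide_split"`: list with `train`,
#'   `tests` (list of pair tables), `train_peptides`, `test_peptides` and
#'   `category_counts`.
#' @export
unseen_peptide_split <- function(records, train_peptide_fraction = 0.8,
                                 wildtype_negatives = NULL, n_test_sets = 1L,
                                 seed = 1L) {
  assert_validated(records, require_label = TRUE)
  if (!is.null(wildtype_negatives)) assert_validated(wildtype_negatives)
  cats <- peptide_categories(records)
  if (nrow(cats) < 10L) stop("too few distinct peptides (< 10)")
  with_seed(seed, {
    train_peps <- unlist(lapply(split(cats$peptide, cats$category), function(p) {
      p <- p[sample.int(length(p))]
      p[seq_len(round(train_peptide_fraction * length(p)))]
    }), use.names = FALSE)
    test_peps <- setdiff(cats$peptide, train_peps)
    if (!length(test_peps)) stop("train_peptide_fraction leaves no test peptides")
    train <- records[records$peptide %in% train_peps, , drop = FALSE]
    if (!is.null(wildtype_negatives)) {
      wt <- wildtype_negatives[!wildtype_negatives$peptide %in% test_peps, ,
                               drop = FALSE]
      train <- rbind(train, wt)
      train_peps <- union(train_peps, wt$peptide)
    }
    rownames(train) <- NULL
    test_peps <- test_peps[sample.int(length(test_peps))]
    grp <- ((seq_along(test_peps) - 1L) %% n_test_sets) + 1L
    tests <- lapply(seq_len(n_test_sets), function(i) {
      out <- records[records$peptide %in% test_peps[grp == i], , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    counts <- table(cats$category[cats$peptide %in% train_peps])
    structure(list(train = train, tests = tests,
                   train_peptides = sort(unique(train$peptide)),
                   test_peptides = sort(test_peps),
                   category_counts = counts,
                   train_peptide_fraction = train_peptide_fraction,
                   seed = seed),
              class = "unseen_peptide_split")
  })
}

#' @export
print.unseen_peptide_split <- function(x, ...) {
  cat("Unseen-peptide split:", length(x$train_peptides), "training peptides /",
      length(x$test_peptides), "held-out peptides in", length(x$tests),
      "test set(s)\n")
  cat("Training peptide categories:",
      paste(names(x$category_counts), as.integer(x$category_counts),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
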
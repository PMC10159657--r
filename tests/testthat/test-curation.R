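test_that("merging deduplicates identical labelled pairs and keeps sources", {
  a <- pair_records("CASSLGTDTQYF", "GILGFVFTL", label = 1, source = "dbA")
  b <- pair_records("CASSLGTDTQYF", "GILGFVFTL", label = 1, source = "dbB")
  c <- pair_records("CASSLGTDTQYF", "GILGFVFTL", label = 1, source = "dbC")
  merged <- merge_and_deduplicate(list(a, b, c))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$source, "dbA;dbB;dbC")

  # disjoint sources concatenate
  set.seed(1)
  parts <- lapply(c(2, 3, 4, 5, 6), function(n) toy_records(n, seed = n))
  expect_equal(nrow(merge_and_deduplicate(parts)), 20)

  # same key with different labels survives dedup (conflict removal is next)
  d <- pair_records("CASSLGTDTQYF", "GILGFVFTL", label = 0, source = "dbD")
  expect_equal(nrow(merge_and_deduplicate(list(a, d))), 2)
})

test_that("conflicted keys are dropped entirely and reported", {
  rec <- rbind(
    pair_records("CASSLGTDTQYF", "GILGFVFTL", label = 1),
    pair_records("CASSLGTDTQYF", "GILGFVFTL", label = 0),
    pair_records("CASSIRSSYEQYF", "NLVPMVATV", label = 1))
  res <- remove_conflicts(rec)
  expect_equal(nrow(res$records), 1)
  expect_equal(res$records$peptide, "NLVPMVATV")
  expect_equal(nrow(res$conflicts), 1)
  expect_equal(res$conflicts$n_pos, 1L)
  expect_equal(res$conflicts$n_neg, 1L)
  # no key retains two labels after removal
  key <- paste(res$records$cdr3b, res$records$peptide)
  expect_true(all(tapply(res$records$label, key,
                         function(l) length(unique(l))) == 1))

  # identity on conflict-free input
  clean <- toy_records(12)
  expect_equal(remove_conflicts(clean)$records, clean)

  # derived count: 10 keys, 2 conflicted -> 8 keys survive
  set.seed(7)
  keys <- data.frame(cdr3b = random_cdr3b(10), peptide = random_peptide(10))
  recs <- pair_records(keys$cdr3b, keys$peptide, label = 0)
  dup <- pair_records(keys$cdr3b[1:2], keys$peptide[1:2], label = 1)
  res2 <- remove_conflicts(rbind(recs, dup))
  expect_equal(nrow(res2$records), 8)
  expect_equal(nrow(res2$conflicts), 2)
})

test_that("subset construction is disjoint, size-bounded and seeded", {
  set.seed(11)
  rec <- pair_records(random_cdr3b(300), rep(random_peptide(15), each = 20),
                      label = rep_len(c(1, 0, 0), 300))
  split <- make_subsets(rec, n_subsets = 5, size_range = c(50, 60), seed = 9)
  expect_length(split$subsets, 5)
  sizes <- vapply(split$subsets, nrow, 0L)
  expect_true(all(sizes >= 50 & sizes <= 60))
  # disjoint at the record level
  all_keys <- unlist(lapply(split$subsets, function(s)
    paste(s$cdr3b, s$peptide, s$label)))
  expect_false(any(duplicated(all_keys)))
  # peptide diversity: every subset sees most peptides
  for (s in split$subsets)
    expect_gte(length(unique(s$peptide)), 14)
  # determinism
  split2 <- make_subsets(rec, n_subsets = 5, size_range = c(50, 60), seed = 9)
  expect_identical(split$subsets, split2$subsets)
  # infeasible request errors
  expect_error(make_subsets(rec, n_subsets = 7, size_range = c(50, 60)),
               "insufficient")
})

test_that("negative sampling keeps all positives and hits the exact quota", {
  set.seed(2)
  rec <- pair_records(random_cdr3b(5100), random_peptide(5100),
                      label = c(rep(1, 100), rep(0, 5000)))
  out <- sample_negatives(rec, ratio = 10, seed = 4)
  expect_equal(sum(out$label == 1), 100)
  expect_equal(sum(out$label == 0), 1000)

  # pool smaller than quota: everything kept
  rec2 <- rec[1:600, ]  # 100 pos + 500 neg
  out2 <- sample_negatives(rec2, ratio = 10, seed = 4)
  expect_equal(nrow(out2), 600)

  # achieved ratio = min(ratio, pool ratio), exactly
  expect_equal(sum(out2$label == 0) / sum(out2$label == 1), 5)
  expect_error(sample_negatives(rec, ratio = 0), "ratio")
  # determinism
  expect_identical(out, sample_negatives(rec, ratio = 10, seed = 4))
})

test_that("wild-type negative generation yields unique non-colliding pairs", {
  set.seed(3)
  peps <- random_peptide(10); tcrs <- random_cdr3b(10)
  out <- generate_wildtype_negatives(peps, tcrs, 50, seed = 5)
  expect_equal(nrow(out), 50)
  expect_true(all(out$label == 0))
  expect_true(all(out$source == "generated-wildtype"))
  expect_false(any(duplicated(paste(out$cdr3b, out$peptide))))

  expect_error(generate_wildtype_negatives(peps, tcrs, 101), "exceeds")

  # exclusion of known labelled pairs
  known <- pair_records(tcrs[1], peps[1], label = 1)
  out2 <- generate_wildtype_negatives(peps, tcrs, 99, seed = 5,
                                      exclude = known)
  expect_false(any(out2$cdr3b == tcrs[1] & out2$peptide == peps[1]))
  expect_error(generate_wildtype_negatives(peps, tcrs, 100, exclude = known),
               "exceeds")
  # determinism
  expect_identical(out, generate_wildtype_negatives(peps, tcrs, 50, seed = 5))
})

test_that("unseen-peptide split keeps train and test peptide sets disjoint", {
  set.seed(13)
  peps <- random_peptide(100)
  rec <- pair_records(random_cdr3b(600), rep(peps, each = 6),
                      label = rbinom(600, 1, 0.3))
  wt <- generate_wildtype_negatives(random_peptide(20), random_cdr3b(50),
                                    60, seed = 8)
  split <- unseen_peptide_split(rec, train_peptide_fraction = 0.8,
                                wildtype_negatives = wt, n_test_sets = 3,
                                seed = 6)
  expect_length(intersect(split$train_peptides, split$test_peptides), 0)
  for (ts in split$tests) {
    expect_length(intersect(unique(ts$peptide), split$train_peptides), 0)
    # observations follow their peptide
    expect_true(all(ts$peptide %in% split$test_peptides))
  }
  # ~80% of the 100 original peptides end up in training
  n_orig_train <- sum(unique(rec$peptide) %in% split$train_peptides)
  expect_equal(n_orig_train, 80, tolerance = 0.05)
  # generated negatives land in training only
  expect_true(all(wt$peptide %in% c(split$train_peptides)))
  # determinism
  split2 <- unseen_peptide_split(rec, train_peptide_fraction = 0.8,
                                 wildtype_negatives = wt, n_test_sets = 3,
                                 seed = 6)
  expect_identical(split$train, split2$train)
  expect_identical(split$tests, split2$tests)
  expect_error(unseen_peptide_split(rec[1:12, ], seed = 1), "too few")
})
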
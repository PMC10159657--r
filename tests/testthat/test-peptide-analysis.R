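test_that("levenshtein similarity matches the DP oracle and its axioms", {
  expect_equal(levenshtein_similarity("GILGFVFTL", "GILGFVFTL"), 1)
  expect_equal(levenshtein_similarity("GILGFVFTL", "GILGFVFTV"), 1 - 1 / 9)
  expect_equal(levenshtein_similarity("AAAAAAAA", "RRRRRRRR"), 0)
  expect_error(levenshtein_similarity("", "AA"), "non-empty")

  set.seed(41)
  for (i in 1:40) {
    a <- random_peptide(); b <- random_peptide()
    s <- levenshtein_similarity(a, b)
    expect_equal(s, 1 - lev_dp(a, b) / max(nchar(a), nchar(b)))
    expect_equal(s, levenshtein_similarity(b, a))  # symmetry
    expect_identical(s == 1, a == b)
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(43)
  peps <- unique(random_peptide(12))
  sim <- peptide_similarity_matrix(peps)
  expect_true(isSymmetric(unname(sim)))
  expect_equal(unname(diag(sim)), rep(1, length(peps)))
  expect_true(all(sim >= 0 & sim <= 1))
})

test_that("false-positive attribution conserves shares and finds dominance", {
  # all FPs from one peptide
  peps <- c("GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "NLVPMVATV")
  att <- fp_attribution(peps, c(0.9, 0.9, 0.1, 0.9), c(0, 0, 0, 1))
  expect_equal(att$table$fp_share[att$table$peptide == "GILGFVFTL"], 1)
  expect_equal(att$dominant, "GILGFVFTL")

  # FPs split evenly over 4 peptides, cutoff 0.5 -> dominant set of size 2
  peps4 <- rep(c("AAAAAAAA", "RRRRRRRR", "NNNNNNNN", "DDDDDDDD"), each = 2)
  att4 <- fp_attribution(peps4, rep(0.9, 8), rep(0, 8), share_cutoff = 0.5)
  expect_length(att4$dominant, 2)
  expect_equal(sum(att4$table$fp_share), 1)
  # top_n override
  expect_length(fp_attribution(peps4, rep(0.9, 8), rep(0, 8),
                               top_n = 3)$dominant, 3)

  # no FPs: empty, flagged
  none <- fp_attribution(peps, c(0.1, 0.1, 0.1, 0.9), c(0, 0, 0, 1))
  expect_true(none$no_fp)
  expect_equal(nrow(none$table), 0)

  # conservation on a random instance
  set.seed(47)
  rp <- sample(random_peptide(6), 200, replace = TRUE)
  pr <- runif(200); tr <- rbinom(200, 1, 0.2)
  a <- fp_attribution(rp, pr, tr)
  expect_equal(sum(a$table$n_fp), a$n_fp_total)
  expect_equal(sum(a$table$fp_share), 1)
  expect_equal(sum(a$table$n_pairs), 200)
})

test_that("an injected noisy high-frequency peptide dominates the FP table", {
  rep_d <- generate_repertoire(synthetic_config(
    n_pairs = 1500, binding_fraction = 0.15, n_distinct_peptides = 30,
    n_distinct_tcrs = 800, seed = 53,
    dominant = data.frame(peptide = "KLGGALQAK", n_pairs = 300,
                          binding_rate = 0.5)))
  halves <- split_repertoire(rep_d, 0.7, seed = 53)
  fit <- tcrbind(halves$train, n_trees = 120, seed = 53)
  prob <- predict(fit, halves$test)
  att <- fp_attribution(halves$test$peptide, prob, halves$test$label)
  expect_equal(att$table$peptide[1], "KLGGALQAK")
  expect_equal(att$dominant[1], "KLGGALQAK")
  # and the injected peptide is frequent, as constructed
  expect_gte(att$table$n_pairs[att$table$peptide == "KLGGALQAK"], 50)
})

test_that("ratio titration resamples only the chosen peptides", {
  rep_d <- generate_repertoire(synthetic_config(
    n_pairs = 900, binding_fraction = 0.2, n_distinct_peptides = 20,
    n_distinct_tcrs = 500, seed = 59,
    dominant = data.frame(peptide = "NLVPMVATV", n_pairs = 200,
                          binding_rate = 0.5)))
  halves <- split_repertoire(rep_d, 0.6, seed = 59)
  res <- ratio_titration(halves$train, halves$test, "NLVPMVATV",
                         ratios = c(0.25, 1), seed = 61, n_trees = 60)
  expect_equal(nrow(res), 6)  # 2 ratios x (overall, chosen, others)
  expect_setequal(unique(res$stratum), c("overall", "chosen", "others"))
  # noisy-label chosen peptide stays near chance while others stay high
  chosen_auc <- res$auc[res$stratum == "chosen"]
  others_auc <- res$auc[res$stratum == "others"]
  expect_true(all(chosen_auc < 0.75))
  expect_true(all(others_auc > 0.85))
  # determinism
  res2 <- ratio_titration(halves$train, halves$test, "NLVPMVATV",
                          ratios = c(0.25, 1), seed = 61, n_trees = 60)
  expect_identical(res, res2)
  expect_error(ratio_titration(halves$train, halves$test, "NLVPMVATV",
                               ratios = 0, seed = 1), "ratios must")
})

test_that("the non-chosen stratum of the rebuilt training set is untouched", {
  rep_d <- generate_repertoire(synthetic_config(
    n_pairs = 500, binding_fraction = 0.25, n_distinct_peptides = 15,
    n_distinct_tcrs = 300, seed = 67))
  recs <- rep_d$records
  chosen_pep <- recs$peptide[which(recs$label == 1)[1]]
  # give the chosen peptide some negatives so ratios are reachable
  extra <- pair_records(random_cdr3b(40), rep(chosen_pep, 40), label = 0)
  train <- rbind(recs, extra)
  others_before <- train[train$peptide != chosen_pep, ]
  pos <- sum(train$label == 1 & train$peptide == chosen_pep)
  for (r in c(0.5, 2)) {
    res <- ratio_titration(train, recs[1:50, ], chosen_pep, ratios = r,
                           seed = 3, n_trees = 20)
    # rebuilt set = untouched others + kept positives + resampled negatives
    expect_equal(unique(res$n_train),
                 nrow(others_before) + pos + round(pos / r))
  }
  # identity ratio: rebuilt set has the original chosen-peptide composition
  neg <- sum(train$label == 0 & train$peptide == chosen_pep)
  res_id <- ratio_titration(train, recs[1:50, ], chosen_pep,
                            ratios = pos / neg, seed = 3, n_trees = 20)
  expect_equal(unique(res_id$n_train), nrow(train))
})

test_that("peptide clustering recovers planted families with medoids", {
  # two tight families around distinct cores
  core1 <- "GILGFVFTL"; core2 <- "YLQPRTFLL"
  mutate1 <- function(s, i) { substr(s, i, i) <- "A"; s }
  fam1 <- c(core1, vapply(2:4, function(i) mutate1(core1, i), ""))
  fam2 <- c(core2, vapply(2:4, function(i) mutate1(core2, i), ""))
  cl <- cluster_peptides(c(fam1, fam2), n_clusters = 2, seed = 71)
  lab1 <- unique(cl$assignment[fam1]); lab2 <- unique(cl$assignment[fam2])
  expect_length(lab1, 1); expect_length(lab2, 1)
  expect_false(lab1 == lab2)
  # representatives are medoids: max mean within-cluster similarity
  for (k in c(lab1, lab2)) {
    members <- names(cl$assignment)[cl$assignment == k]
    mean_sim <- colMeans(cl$similarity[members, members, drop = FALSE])
    expect_equal(cl$representatives[k], members[which.max(mean_sim)])
  }
  # n_clusters = n_peptides: singletons, own representative
  singles <- cluster_peptides(fam1, n_clusters = 4, seed = 1)
  expect_equal(sort(unname(singles$assignment)), 1:4)
  expect_setequal(singles$representatives, fam1)
  expect_error(cluster_peptides(fam1, n_clusters = 10), "at least")
  # determinism
  expect_identical(cl, cluster_peptides(c(fam1, fam2), 2, seed = 71))
})

test_that("similarity-bin RMSE follows its closed form and flags empty bins", {
  # identical proportion vectors -> 0
  out <- similarity_bin_rmse("GILGFVFTL", c("GILGFVFTL", "GILGFVFTA"),
                             c("binding", "binding"),
                             predicted = c(1, 1, 1))
  filled <- out[!out$empty, ]
  expect_true(all(abs(filled$rmse) < 1e-12))
  # (1,0,0) vs (0,1,0) -> sqrt(2/3)
  out2 <- similarity_bin_rmse("GILGFVFTL", "GILGFVFTL", "non-binding",
                              predicted = c(1, 1))
  expect_equal(out2$rmse[!out2$empty], sqrt(2 / 3))
  # empty bins flagged, not zero-filled
  expect_true(any(out2$empty))
  expect_true(all(is.na(out2$rmse[out2$empty])))
  # all training peptides in one bin -> single filled row
  expect_equal(sum(!out2$empty), 1)
  expect_error(similarity_bin_rmse("GILGFVFTL", character(0), character(0),
                                   c(1)), "no training")
  expect_error(similarity_bin_rmse("GILGFVFTL", "AAAAAAAA", "mix",
                                   integer(0)), "no predictions")
})

test_that("peptide-specific models isolate CDR3b signal", {
  # binders of this peptide share a planted CDR3b motif
  set.seed(73)
  pep <- "NLVPMVATV"
  motif_tcrs <- paste0("CASS", substr(random_cdr3b(60, len = 14), 5, 14))
  motif_tcrs <- vapply(motif_tcrs, function(s) {
    substr(s, 5, 7) <- "WWW"; s
  }, "", USE.NAMES = FALSE)
  plain_tcrs <- random_cdr3b(120, len = 14)
  recs <- pair_records(c(motif_tcrs, plain_tcrs),
                       rep(pep, 180),
                       label = c(rep(1, 60), rep(0, 120)))
  res <- train_peptide_specific_model(recs, pep, seed = 79, n_trees = 80)
  expect_s3_class(res$model, "tcrbind_model")
  expect_gte(res$report$auc, 0.9)

  # random labels on the same peptide: near-chance AUC
  recs0 <- recs
  set.seed(83)
  recs0$label <- sample(recs0$label)
  res0 <- train_peptide_specific_model(recs0, pep, seed = 79, n_trees = 80)
  expect_gte(res0$report$auc, 0.3)
  expect_lte(res0$report$auc, 0.7)

  expect_error(train_peptide_specific_model(recs[1:3, ], pep), "minimum")
})
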
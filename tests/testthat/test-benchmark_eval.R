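test_that("ROC handles separation, ties and orientation as defined", {
  sep <- roc_curve(c(8, 9, 10), c(1, 2, 3), lower_is_better = FALSE)
  expect_equal(sep$auc, 1.0)
  # identical score sets: all ties, half credit
  tie <- roc_curve(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$auc, 0.5)
  # lower-is-better flips the ranking, never inferred
  lo <- roc_curve(c(1, 2), c(8, 9), lower_is_better = TRUE)
  expect_equal(lo$auc, 1.0)
  hi <- roc_curve(c(1, 2), c(8, 9), lower_is_better = FALSE)
  expect_equal(hi$auc, 0.0)

  # curve anatomy
  expect_equal(sep$points$fpr[1], 0)
  expect_equal(sep$points$tpr[1], 0)
  expect_equal(tail(sep$points$fpr, 1), 1)
  expect_equal(tail(sep$points$tpr, 1), 1)
  expect_true(all(diff(sep$points$fpr) >= 0))

  expect_error(roc_curve(numeric(), 1:3), class = "slimpae_degenerate_input_error")
})

test_that("ROC AUC equals exhaustive concordance counting on random instances", {
  set.seed(505)
  for (i in 1:40) {
    np <- sample(3:20, 1); nn <- sample(3:20, 1)
    # coarse rounding forces plenty of ties
    pos <- round(rnorm(np, 5, 2), 0)
    neg <- round(rnorm(nn, 7, 2), 0)
    lower <- i %% 2 == 0
    got <- roc_curve(pos, neg, lower_is_better = lower)$auc
    want <- if (lower) bf_auc_pairs(-pos, -neg) else bf_auc_pairs(pos, neg)
    expect_equal(got, want)
  }
})

test_that("ROC AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  pos <- rnorm(40, 6, 2); neg <- rnorm(60, 4, 2)
  got <- roc_curve(pos, neg)$auc
  ref <- suppressMessages(pROC::auc(
    response = rep(c(1, 0), c(40, 60)), predictor = c(pos, neg),
    direction = "<"))
  expect_equal(got, as.numeric(ref))
})

test_that("PR curves report precision/recall per the TP/FP/FN definitions", {
  # scores (higher better): pos {9,8,7}, neg {8.5}; at threshold 7:
  # TP = 3, FP = 1 -> precision 0.75 at recall 1
  cur <- pr_curve(c(9, 8, 7), 8.5)
  at_full <- cur$points$precision[cur$points$recall == 1]
  expect_equal(at_full, 0.75)

  expect_equal(pr_curve(c(8, 9), c(1, 2))$auc, 1.0)

  # worst case: all negatives rank better; precision at full recall = prevalence
  worst <- pr_curve(c(1, 2), c(5, 6, 7, 8), lower_is_better = FALSE)
  expect_equal(worst$points$precision[worst$points$recall == 1], 2 / 6)

  # PR-AUC stays in [0, 1] and equals direct confusion-count integration
  set.seed(13)
  for (i in 1:20) {
    pos <- round(rnorm(8), 1); neg <- round(rnorm(12), 1)
    cur <- pr_curve(pos, neg)
    expect_lte(cur$auc, 1)
    expect_gte(cur$auc, 0)
    expect_true(all(diff(cur$points$recall) >= 0))
    expect_equal(cur$auc, bf_pr_auc(pos, neg))
  }
})

test_that("TPR at FDR=0 counts positives strictly better than the best negative", {
  expect_equal(tpr_at_zero_fdr(c(1, 2, 3), c(4, 5), lower_is_better = TRUE), 100)
  # a positive tying the best negative is excluded by strictness
  expect_equal(tpr_at_zero_fdr(c(1, 2), c(2, 9), lower_is_better = TRUE), 50)
  expect_equal(tpr_at_zero_fdr(c(1, 2), c(1, 9), lower_is_better = TRUE), 0)
  expect_equal(tpr_at_zero_fdr(c(5, 6), c(7, 8), lower_is_better = FALSE), 0)

  set.seed(606)
  for (i in 1:30) {
    pos <- round(rnorm(10, 4, 2), 0); neg <- round(rnorm(15, 7, 2), 0)
    expect_equal(tpr_at_zero_fdr(pos, neg, lower_is_better = TRUE),
                 bf_tpr0(-pos, -neg))
    expect_equal(tpr_at_zero_fdr(pos, neg, lower_is_better = FALSE),
                 bf_tpr0(pos, neg))
  }
})

test_that("ratio-subsampled PR analysis is seeded, averaged and ratio-sensitive", {
  pools <- make_score_pools(n_pos = 26L, n_neg = 1100L, seed = 5L)

  # a perfect separator stays perfect at ratio 1 in every iteration
  perfect <- unbalanced_pr(rep(2, 26), rep(20, 1100), ratio = 1L,
                           iterations = 5L, seed = 1L, lower_is_better = TRUE)
  expect_equal(perfect$iteration_auc, rep(1, 5))
  expect_equal(perfect$auc, 1)

  # determinism: same seed, same result, different seed differs
  a <- unbalanced_pr(pools$pos, pools$neg, ratio = 5L, iterations = 3L,
                     seed = 11L, lower_is_better = TRUE)
  b <- unbalanced_pr(pools$pos, pools$neg, ratio = 5L, iterations = 3L,
                     seed = 11L, lower_is_better = TRUE)
  expect_identical(a$iteration_auc, b$iteration_auc)
  expect_identical(a$points, b$points)
  d <- unbalanced_pr(pools$pos, pools$neg, ratio = 5L, iterations = 3L,
                     seed = 12L, lower_is_better = TRUE)
  expect_false(identical(a$iteration_auc, d$iteration_auc))

  # mean PR-AUC declines as the non-binder excess grows
  aucs <- vapply(c(1L, 5L, 25L), function(r) {
    unbalanced_pr(pools$pos, pools$neg, ratio = r, iterations = 10L,
                  seed = 7L, lower_is_better = TRUE)$auc
  }, numeric(1))
  expect_true(aucs[1] > aucs[2] && aucs[2] > aucs[3])

  expect_error(unbalanced_pr(pools$pos, pools$neg, ratio = 100L, seed = 1L,
                             lower_is_better = TRUE),
               class = "slimpae_sampling_error")
})

test_that("shuffled negatives obey the positive-pair, regex and length rules", {
  # two positives with non-matching regexes: admissible set is exactly the
  # two off-diagonal pairs
  pos2 <- data.frame(
    motif_protein_id = c("A", "B"),
    motif_sequence = c("PPLP", "DDVF"),
    motif_regexes = c("PP.P", "DDV[FY]"),
    partner_id = c("X", "Y"),
    motif_len = c(100L, 150L),
    partner_len = c(300L, 350L),
    label = "binder"
  )
  out <- build_shuffled_negatives(pos2, n_out = 2L, seed = 1L)
  expect_setequal(paste(out$motif_protein_id, out$partner_id),
                  c("A Y", "B X"))
  expect_true(all(out$label == "non_binder"))
  expect_error(build_shuffled_negatives(pos2, n_out = 3L, seed = 1L),
               class = "slimpae_exhaustion_error")

  # a motif matching the new partner's regex is excluded
  pos3 <- pos2
  pos3$motif_sequence[1] <- "ADDVFA"  # matches Y's regex DDV[FY]
  out3 <- build_shuffled_negatives(pos3, n_out = 1L, seed = 1L)
  expect_equal(paste(out3$motif_protein_id, out3$partner_id), "B X")

  # length rule: combined length must stay under the cap
  pos4 <- pos2
  pos4$partner_len <- c(920L, 350L)  # B (150) + X (920) = 1070 >= 1000
  out4 <- build_shuffled_negatives(pos4, n_out = 1L, seed = 1L)
  expect_equal(paste(out4$motif_protein_id, out4$partner_id), "A Y")
})

test_that("emitted shuffled pairs all pass an independent rule re-check", {
  set.seed(808)
  n <- 50L
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  motifs <- vapply(seq_len(n), function(i)
    paste(sample(aa, 6, replace = TRUE), collapse = ""), character(1))
  pos <- data.frame(
    motif_protein_id = sprintf("M%02d", seq_len(n)),
    motif_sequence = motifs,
    # each instance's class regex: its own motif with one wildcard
    motif_regexes = paste0(substr(motifs, 1, 3), ".", substr(motifs, 5, 6)),
    partner_id = sprintf("P%02d", rep(seq_len(10L), each = 5L)),
    motif_len = sample(50:400, n, replace = TRUE),
    partner_len = rep(sample(200:700, 10L), each = 5L),
    label = "binder"
  )
  out <- build_shuffled_negatives(pos, n_out = 100L, max_total_len = 1000L,
                                  seed = 4L)
  expect_equal(nrow(out), 100L)

  # independent validator
  pos_keys <- paste(pos$motif_protein_id, pos$partner_id)
  partner_regexes <- split(pos$motif_regexes, pos$partner_id)
  partner_lens <- tapply(pos$partner_len, pos$partner_id, unique)
  for (k in seq_len(nrow(out))) {
    expect_false(paste(out$motif_protein_id[k], out$partner_id[k]) %in% pos_keys)
    expect_lt(out$motif_len[k] + partner_lens[[out$partner_id[k]]], 1000L)
    for (rx in partner_regexes[[out$partner_id[k]]]) {
      expect_false(grepl(rx, out$motif_sequence[k], perl = TRUE))
    }
  }

  # reproducibility of the uniform draw
  out2 <- build_shuffled_negatives(pos, n_out = 100L, max_total_len = 1000L,
                                   seed = 4L)
  expect_identical(out, out2)

  expect_error(build_shuffled_negatives(pos[pos$partner_id == "P01", ], 1L),
               class = "slimpae_degenerate_input_error")
})
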
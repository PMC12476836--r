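# Evaluation of screening metrics: ROC, precision-recall (balanced and
# ratio-subsampled), TPR at FDR = 0, and shuffled-negative construction.
#
# Score orientation is always explicit: metrics where lower is better
# (MiniPAE, MinD) are negated internally before ranking, never inferred.

orient <- function(scores, lower_is_better) {
  if (isTRUE(lower_is_better)) -as.numeric(scores) else as.numeric(scores)
}

check_classes <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop_slimpae("both score classes must be non-empty",
                 "slimpae_degenerate_input_error")
  }
  if (anyNA(pos_scores) || anyNA(neg_scores)) {
    stop_slimpae("scores must be free of NA", "slimpae_domain_error")
  }
}

eval_curve <- function(kind, points, auc, lower_is_better, extra = list()) {
  structure(c(list(kind = kind, points = points, auc = auc,
                   lower_is_better = lower_is_better), extra),
            class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  cat(sprintf("<eval_curve> %s, AUC = %.4f (%d points, %s is better)\n",
              toupper(x$kind), x$auc, nrow(x$points),
              if (x$lower_is_better) "lower" else "higher"))
  invisible(x)
}

#' ROC curve and AUC for a binder / non-binder score split
#'
#' Sweeps all score thresholds and reports (FPR, TPR) points from (0,0)
#' to (1,1); the AUC is the trapezoidal area, which gives tied scores half
#' credit and therefore equals the rank (Mann-Whitney) formulation.
#'
#' @param pos_scores,neg_scores Numeric score vectors for binders and
#'   non-binders.
#' @param lower_is_better `TRUE` for MiniPAE-like metrics where a low score
#'   ranks first.
#' @return An `eval_curve` of kind `"roc"` with `points` (columns `fpr`,
#'   `tpr`, `threshold`) and `auc`.
#' @export
roc_curve <- function(pos_scores, neg_scores, lower_is_better = FALSE) {
  check_classes(pos_scores, neg_scores)
  s <- c(orient(pos_scores, lower_is_better), orient(neg_scores, lower_is_better))
  y <- rep(c(1L, 0L), c(length(pos_scores), length(neg_scores)))
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # cumulative counts at each distinct score value
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1L - y)[keep]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(1L - y))
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  eval_curve("roc",
             data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[keep]) * if (lower_is_better) -1 else 1),
             auc, lower_is_better)
}

#' Precision-recall curve and trapezoidal PR-AUC
#'
#' Sweeps all score thresholds; at each, Precision = TP/(TP+FP) and
#' Recall = TP/(TP+FN). A terminal (recall 0, precision 1) point is
#' appended and the AUC is trapezoidal integration of precision over
#' recall. At full recall (everything called positive), precision equals
#' the prevalence of binders.
#'
#' @inheritParams roc_curve
#' @return An `eval_curve` of kind `"pr"` with `points` (columns `recall`,
#'   `precision`, `threshold`) and `auc`.
#' @export
pr_curve <- function(pos_scores, neg_scores, lower_is_better = FALSE) {
  check_classes(pos_scores, neg_scores)
  s <- c(orient(pos_scores, lower_is_better), orient(neg_scores, lower_is_better))
  y <- rep(c(1L, 0L), c(length(pos_scores), length(neg_scores)))
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1L - y)[keep]
  # points in strictest-to-loosest threshold order (recall non-decreasing),
  # with the conventional starting point (recall 0, precision 1); score ties
  # yield zero-width segments that add no area
  precision <- c(1, tp / (tp + fp))
  recall <- c(0, tp / sum(y))
  thr <- c(Inf, s[keep]) * if (lower_is_better) -1 else 1
  auc <- sum(diff(recall) * (precision[-1L] + precision[-length(precision)]) / 2)
  eval_curve("pr",
             data.frame(recall = recall, precision = precision, threshold = thr),
             auc, lower_is_better)
}

#' Averaged precision-recall analysis under class imbalance
#'
#' Emulates a screen where non-binders outnumber binders `ratio` to 1: per
#' iteration, `ratio * length(pos_scores)` negatives are drawn from the
#' pool without replacement, the PR curve against the full positive set is
#' computed, and results are averaged over iterations — the AUC as the
#' mean of per-iteration trapezoidal AUCs, the curve by interpolating each
#' iteration's precision onto a fixed 101-point recall grid.
#'
#' @param pos_scores Scores of the binders (all used every iteration).
#' @param neg_pool Pool of non-binder scores to subsample.
#' @param ratio Non-binder : binder ratio (positive integer).
#' @param iterations Number of independent draws (default 10).
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @param lower_is_better Score orientation, as in [roc_curve()].
#' @return An `eval_curve` of kind `"pr"` whose `points` hold the averaged
#'   grid curve, `auc` the mean AUC, plus fields `auc_sd`, `iteration_auc`
#'   and `ratio`.
#' @export
unbalanced_pr <- function(pos_scores, neg_pool, ratio, iterations = 10L,
                          seed = 1L, lower_is_better = FALSE) {
  check_classes(pos_scores, neg_pool)
  ratio <- as.integer(ratio)
  stopifnot(ratio >= 1L, iterations >= 1L)
  n_neg <- ratio * length(pos_scores)
  if (n_neg > length(neg_pool)) {
    stop_slimpae("need %d negatives at ratio 1:%d but the pool holds %d",
                 "slimpae_sampling_error", n_neg, ratio, length(neg_pool))
  }
  grid <- seq(0, 1, length.out = 101L)
  aucs <- numeric(iterations)
  prec_grid <- matrix(NA_real_, iterations, length(grid))
  for (i in seq_len(iterations)) {
    neg_i <- with_seed(derive_seed(seed, 1000L * ratio + i),
                       sample(neg_pool, n_neg, replace = FALSE))
    cur <- pr_curve(pos_scores, neg_i, lower_is_better)
    aucs[i] <- cur$auc
    prec_grid[i, ] <- grid_precision(cur$points, grid)
  }
  eval_curve("pr",
             data.frame(recall = grid, precision = colMeans(prec_grid)),
             mean(aucs), lower_is_better,
             extra = list(auc_sd = stats::sd(aucs), iteration_auc = aucs,
                          ratio = ratio, iterations = iterations,
                          seed = as.integer(seed)))
}

# Interpolate a PR curve's precision onto a fixed recall grid. Duplicate
# recall values (score ties) are collapsed to their maximum precision
# before linear interpolation.
grid_precision <- function(points, grid) {
  agg <- tapply(points$precision, points$recall, max)
  r <- as.numeric(names(agg))
  stats::approx(r, as.numeric(agg), xout = grid, rule = 2)$y
}

#' True positive rate at zero false discovery rate
#'
#' The fraction of binders scoring strictly better than the best-scoring
#' non-binder, as a percentage: the recall achievable with the threshold
#' set so that no non-binder is called. A non-binder tying the best binder
#' already breaks FDR = 0, hence the strict inequality.
#'
#' @inheritParams roc_curve
#' @return Percentage in `[0, 100]`.
#' @export
tpr_at_zero_fdr <- function(pos_scores, neg_scores, lower_is_better = FALSE) {
  check_classes(pos_scores, neg_scores)
  p <- orient(pos_scores, lower_is_better)
  n <- orient(neg_scores, lower_is_better)
  100 * mean(p > max(n))
}

#' Build shuffled non-binder pairs from a positive benchmark table
#'
#' Generates presumed non-binders by re-pairing motif proteins with other
#' partners from the positive set. A shuffled pair (motif m, partner p) is
#' admissible when (i) it does not occur in the positive set, (ii) m's
#' motif sequence matches none of the motif regular expressions associated
#' with p (so no functional motif is reintroduced by chance; unanchored
#' matching, as in ELM patterns), and (iii) the combined motif-protein and
#' partner lengths stay under `max_total_len` residues. `n_out` pairs are
#' drawn uniformly at random among the admissible ones.
#'
#' @param instances Data frame of positive benchmark instances with columns
#'   `motif_protein_id`, `motif_sequence`, `motif_regexes` (regexes of the
#'   instance's ELM class; multiple separated by `";"` or a list column),
#'   `partner_id`, `motif_len`, `partner_len` and optionally `label`
#'   (rows not labelled `"binder"` are dropped).
#' @param n_out Number of shuffled pairs to emit.
#' @param max_total_len Length cap on `motif_len + partner_len`
#'   (default 1000, exclusive).
#' @param seed Integer seed for the uniform draw.
#' @return Data frame of shuffled pairs with the same columns and label
#'   `"non_binder"`.
#' @export
build_shuffled_negatives <- function(instances, n_out, max_total_len = 1000L,
                                     seed = 1L) {
  req <- c("motif_protein_id", "motif_sequence", "motif_regexes",
           "partner_id", "motif_len", "partner_len")
  stopifnot(is.data.frame(instances), all(req %in% names(instances)))
  if ("label" %in% names(instances)) {
    instances <- instances[instances$label == "binder", , drop = FALSE]
  }
  if (length(unique(instances$partner_id)) < 2L) {
    stop_slimpae("need >= 2 distinct partners to shuffle",
                 "slimpae_degenerate_input_error")
  }
  rex <- regex_list(instances$motif_regexes)
  partner_ids <- unique(instances$partner_id)
  # regexes associated with a partner: those of every motif known to bind it
  partner_rex <- lapply(partner_ids, function(p) {
    unique(unlist(rex[instances$partner_id == p]))
  })
  names(partner_rex) <- partner_ids
  partner_len <- instances$partner_len[match(partner_ids, instances$partner_id)]
  pos_key <- paste(instances$motif_protein_id, instances$partner_id, sep = "\r")

  cand <- expand.grid(m = seq_len(nrow(instances)), p = seq_along(partner_ids))
  admissible <- vapply(seq_len(nrow(cand)), function(k) {
    m <- cand$m[k]; p <- cand$p[k]
    key <- paste(instances$motif_protein_id[m], partner_ids[p], sep = "\r")
    if (key %in% pos_key) return(FALSE)
    if (instances$motif_len[m] + partner_len[p] >= max_total_len) return(FALSE)
    !any(vapply(partner_rex[[p]], function(rx) {
      grepl(rx, instances$motif_sequence[m], perl = TRUE)
    }, logical(1)))
  }, logical(1))
  cand <- cand[admissible, , drop = FALSE]
  if (nrow(cand) < n_out) {
    stop_slimpae("only %d admissible shuffled pairs exist, %d requested",
                 "slimpae_exhaustion_error", nrow(cand), n_out)
  }
  pick <- with_seed(derive_seed(seed, 1L),
                    sample(nrow(cand), n_out, replace = FALSE))
  cand <- cand[pick, , drop = FALSE]
  out <- data.frame(
    motif_protein_id = instances$motif_protein_id[cand$m],
    motif_sequence = instances$motif_sequence[cand$m],
    motif_regexes = vapply(rex[cand$m], paste, character(1), collapse = ";"),
    partner_id = partner_ids[cand$p],
    motif_len = instances$motif_len[cand$m],
    partner_len = partner_len[cand$p],
    label = "non_binder",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

regex_list <- function(x) {
  if (is.list(x)) lapply(x, as.character) else strsplit(as.character(x), ";", fixed = TRUE)
}
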
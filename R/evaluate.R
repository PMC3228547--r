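#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth logical vectors (TRUE = positive call / positive
#'   label).
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  list(TP = sum(predicted & truth), FP = sum(predicted & !truth),
       TN = sum(!predicted & !truth), FN = sum(!predicted & truth))
}

#' Precision, sensitivity, specificity and accuracy
#'
#' `Pre = TP/(TP+FP)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc = (TP+TN)/(TP+FP+TN+FN)`. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN`.
#' @return list with `precision`, `sensitivity`, `specificity`, `accuracy`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    div <- function(num, den) if (den == 0) NA_real_ else num / den
    list(precision = div(TP, TP + FP),
         sensitivity = div(TP, TP + FN),
         specificity = div(TN, TN + FP),
         accuracy = div(TP + TN, TP + FP + TN + FN))
  })
}

#' Assign items to k approximately equal folds
#'
#' A seeded random permutation is split round-robin so fold sizes differ by
#' at most one; deterministic given the seed.
#'
#' @param n number of items (or a fragment data.frame, whose row count is
#'   used).
#' @param k number of folds (default 5).
#' @param seed integer RNG seed.
#' @return integer vector of fold labels in 1..k.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("cannot make ", k, " folds from ", n, " items")
  with_seed(seed, {
    perm <- sample.int(n)
    folds <- integer(n)
    folds[perm] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Select a bit-score threshold on an integer grid
#'
#' Each candidate `t` classifies `score > t` as positive. The returned
#' threshold maximizes accuracy; ties break toward the most balanced model
#' (minimal `|Sn - Sp|`), then toward the larger threshold (favoring
#' specificity, since raising the threshold favors true negatives).
#'
#' @param scores_pos,scores_neg bit scores of positive and negative data.
#' @param grid integer candidate thresholds (default -20..0).
#' @return the chosen integer threshold.
#' @export
select_threshold <- function(scores_pos, scores_neg, grid = -20:0) {
  stopifnot(length(grid) > 0, length(scores_pos) > 0, length(scores_neg) > 0)
  stats_at <- vapply(grid, function(t) {
    m <- compute_metrics(confusion_counts(
      c(scores_pos, scores_neg) > t,
      c(rep(TRUE, length(scores_pos)), rep(FALSE, length(scores_neg)))))
    c(acc = m$accuracy, bal = abs(m$sensitivity - m$specificity))
  }, numeric(2))
  ord <- order(-stats_at["acc", ], stats_at["bal", ], -grid)
  as.integer(grid[ord[1]])
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.numeric(p)) %% 2147483647
  as.integer(s)
}

#' Five-fold cross-validation with per-cluster threshold calibration
#'
#' For every motif cluster: members are split into `k` folds; per fold a
#' profile is trained on the other folds' positives and a threshold is
#' chosen on training data only (training positives vs an equal-size seeded
#' sample of the balanced negatives), then held-out positives and an
#' equal-size negative sample are classified at that threshold. The
#' cluster's final reported threshold is the grid value with the highest
#' mean validation accuracy across folds. Clusters smaller than `k` are
#' skipped with a warning.
#'
#' @param clusters list of `motif_cluster`.
#' @param negatives balanced negative fragment data.frame.
#' @param k number of folds (default 5).
#' @param grid integer threshold grid (default -20..0).
#' @param seed integer seed driving folds and negative sampling.
#' @param pseudocount emission pseudocount (default 1).
#' @param background residue background; default pools cluster members and
#'   negatives.
#' @return list of class `cv_report`: `per_cluster` (list with
#'   `threshold_bits`, `fold_metrics` data.frame, `mean_metrics`),
#'   `macro_average` (mean over clusters of the per-cluster means),
#'   `skipped` (ids of skipped clusters).
#' @export
cross_validate <- function(clusters, negatives, k = 5L, grid = -20:0,
                           seed = 1L, pseudocount = 1, background = NULL) {
  if (is.null(background)) {
    pool <- rbind(do.call(rbind, lapply(clusters, `[[`, "members")),
                  negatives)
    background <- background_frequencies(pool)
  }
  metric_names <- c("precision", "sensitivity", "specificity", "accuracy")
  per_cluster <- list()
  skipped <- character(0)

  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    n_cl <- nrow(cl$members)
    if (n_cl < k) {
      warning("cluster ", cl$id, " has fewer members (", n_cl,
              ") than folds (", k, "); skipped")
      skipped <- c(skipped, cl$id)
      next
    }
    folds <- make_folds(n_cl, k, derive_seed(seed, ci))
    fold_rows <- vector("list", k)
    val_scores <- vector("list", k)

    for (f in seq_len(k)) {
      train_pos <- cl$members[folds != f, , drop = FALSE]
      val_pos <- cl$members[folds == f, , drop = FALSE]
      model <- train_profile(
        structure(list(id = cl$id, members = train_pos),
                  class = "motif_cluster"),
        pseudocount = pseudocount, background = background)

      neg_train <- with_seed(derive_seed(seed, ci, f, 1L), {
        negatives[sample.int(nrow(negatives),
                             min(nrow(negatives), nrow(train_pos))), ,
                  drop = FALSE]
      })
      neg_val <- with_seed(derive_seed(seed, ci, f, 2L), {
        negatives[sample.int(nrow(negatives),
                             min(nrow(negatives), nrow(val_pos))), ,
                  drop = FALSE]
      })

      t_f <- select_threshold(bit_score(model, train_pos$window),
                              bit_score(model, neg_train$window), grid)

      sp <- bit_score(model, val_pos$window)
      sn <- bit_score(model, neg_val$window)
      val_scores[[f]] <- list(pos = sp, neg = sn)
      m <- compute_metrics(confusion_counts(
        c(sp, sn) > t_f,
        c(rep(TRUE, length(sp)), rep(FALSE, length(sn)))))
      fold_rows[[f]] <- data.frame(fold = f, threshold_bits = t_f,
                                   precision = m$precision,
                                   sensitivity = m$sensitivity,
                                   specificity = m$specificity,
                                   accuracy = m$accuracy)
    }
    fold_metrics <- do.call(rbind, fold_rows)

    # final threshold: best mean validation accuracy across all folds
    grid_acc <- vapply(grid, function(t) {
      mean(vapply(val_scores, function(v) {
        m <- compute_metrics(confusion_counts(
          c(v$pos, v$neg) > t,
          c(rep(TRUE, length(v$pos)), rep(FALSE, length(v$neg)))))
        m$accuracy
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    grid_bal <- vapply(grid, function(t) {
      mean(vapply(val_scores, function(v) {
        m <- compute_metrics(confusion_counts(
          c(v$pos, v$neg) > t,
          c(rep(TRUE, length(v$pos)), rep(FALSE, length(v$neg)))))
        abs(m$sensitivity - m$specificity)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    best_t <- as.integer(grid[order(-grid_acc, grid_bal, -grid)[1]])

    mean_metrics <- as.list(colMeans(
      fold_metrics[metric_names], na.rm = TRUE))
    per_cluster[[cl$id]] <- list(threshold_bits = best_t,
                                 fold_metrics = fold_metrics,
                                 mean_metrics = mean_metrics,
                                 n = n_cl)
  }

  if (length(per_cluster) == 0L) stop("no cluster large enough for CV")
  macro <- as.list(colMeans(do.call(rbind, lapply(per_cluster, function(pc) {
    as.data.frame(pc$mean_metrics)
  })), na.rm = TRUE))
  out <- list(per_cluster = per_cluster, macro_average = macro,
              skipped = skipped, k = k, grid = grid, seed = seed)
  class(out) <- "cv_report"
  out
}

#' Train final per-cluster models with CV-calibrated thresholds
#'
#' Trains one profile per cluster on all of its members and attaches the
#' cross-validated threshold from a [cross_validate()] report.
#'
#' @param clusters list of `motif_cluster`.
#' @param cv a `cv_report` from [cross_validate()] on the same clusters.
#' @param pseudocount emission pseudocount.
#' @param background residue background distribution.
#' @return list of calibrated `profile_model` (clusters skipped in CV are
#'   omitted).
#' @export
train_final_models <- function(clusters, cv, pseudocount = 1,
                               background = uniform_background()) {
  kept <- Filter(function(cl) cl$id %in% names(cv$per_cluster), clusters)
  lapply(kept, function(cl) {
    model <- train_profile(cl, pseudocount = pseudocount,
                           background = background)
    model$threshold_bits <- cv$per_cluster[[cl$id]]$threshold_bits
    model
  })
}

# Ensemble call: positive iff at least one model scores above its threshold.
ensemble_predict <- function(models, windows) {
  if (length(windows) == 0L) {
    return(list(positive = logical(0), best_cluster = character(0),
                best_score = numeric(0)))
  }
  scores <- vapply(models, function(m) bit_score(m, windows),
                   numeric(length(windows)))
  scores <- matrix(scores, nrow = length(windows))
  thresholds <- vapply(models, `[[`, numeric(1), "threshold_bits")
  above <- sweep(scores, 2, thresholds, FUN = ">")
  positive <- rowSums(above) > 0
  masked <- ifelse(above, scores, -Inf)
  # among models above threshold, report the best-scoring cluster;
  # for negatives report the overall best score (no cluster)
  best_idx <- max.col(masked, ties.method = "first")
  best_cluster <- ifelse(positive,
                         vapply(models, `[[`, "", "cluster_id")[best_idx],
                         NA_character_)
  best_score <- ifelse(positive,
                       masked[cbind(seq_along(windows), best_idx)],
                       apply(scores, 1, max))
  list(positive = positive, best_cluster = best_cluster,
       best_score = best_score)
}

#' Repeated balanced independent test
#'
#' Evaluates calibrated models on held-out sites: per repeat, the negative
#' pool is balanced to the positive count by k-medoids selection
#' ([select_representatives()], seeded with `seed + repeat`), every test
#' fragment is classified by the at-least-one-model rule, and the four
#' metrics are computed. Repeating over re-balanced draws quantifies the
#' sensitivity of the estimate to the negative selection.
#'
#' @param models list of calibrated `profile_model`.
#' @param positives positive test fragment data.frame.
#' @param negatives_pool negative fragment pool (at least as large as
#'   `positives`).
#' @param repeats number of re-balanced repeats (default 10).
#' @param seed integer base seed.
#' @return list of class `independent_test_report`: `per_repeat`
#'   (data.frame of metrics), `mean`, `sd`.
#' @export
independent_test <- function(models, positives, negatives_pool,
                             repeats = 10L, seed = 1L) {
  if (nrow(negatives_pool) < nrow(positives)) {
    stop("negative pool (", nrow(negatives_pool),
         ") smaller than positive set (", nrow(positives), ")")
  }
  rows <- lapply(seq_len(repeats), function(r) {
    bal <- select_representatives(negatives_pool, nrow(positives),
                                  seed = derive_seed(seed, r))
    windows <- c(positives$window, bal$selected$window)
    truth <- c(rep(TRUE, nrow(positives)), rep(FALSE, nrow(bal$selected)))
    pred <- ensemble_predict(models, windows)
    m <- compute_metrics(confusion_counts(pred$positive, truth))
    data.frame(repeat_ = r, precision = m$precision,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy)
  })
  per_repeat <- do.call(rbind, rows)
  metric_names <- c("precision", "sensitivity", "specificity", "accuracy")
  out <- list(per_repeat = per_repeat,
              mean = as.list(colMeans(per_repeat[metric_names], na.rm = TRUE)),
              sd = as.list(vapply(per_repeat[metric_names],
                                  stats::sd, numeric(1), na.rm = TRUE)),
              repeats = repeats, seed = seed)
  class(out) <- "independent_test_report"
  out
}
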
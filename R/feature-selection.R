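#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test without the equal-variance assumption:
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite
#' degrees of freedom. Group 1 is the cancer class by convention.
#'
#' @param group_pos,group_neg Numeric vectors with at least 2 values
#'   each; at least one group must have nonzero variance.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
welch_t_test <- function(group_pos, group_neg) {
  n1 <- length(group_pos)
  n2 <- length(group_neg)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  v1 <- stats::var(group_pos)
  v2 <- stats::var(group_neg)
  if (v1 == 0 && v2 == 0) {
    stop("degenerate feature: both groups have zero variance")
  }
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(group_pos) - mean(group_neg)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' log2 fold change of group means
#'
#' @param mean_pos,mean_neg Non-negative group means on the linear
#'   expression scale.
#' @param pseudocount Added to both means before the ratio (default 1)
#'   so that zero means stay finite.
#' @return log2((mean_pos + pseudocount) / (mean_neg + pseudocount)).
#' @export
log2_fold_change <- function(mean_pos, mean_neg, pseudocount = 1) {
  if (any(mean_pos < 0) || any(mean_neg < 0)) {
    stop("negative means: log2 fold change requires the non-negative expression scale")
  }
  log2((mean_pos + pseudocount) / (mean_neg + pseudocount))
}

#' Per-feature differential statistics for one omics block
#'
#' Runs Welch's t-test on every feature (cancer vs non-cancer) and the
#' modality-appropriate effect size: log2 fold change of linear-scale
#' group means for expression, and the difference in mean beta value
#' (cancer minus non-cancer) for methylation. Features degenerate in
#' both groups (zero variance) are dropped with a warning.
#'
#' @param X An [omics_matrix].
#' @param labels Labels in \{0, 1\} covering the matrix samples.
#' @param pseudocount Pseudocount for the expression fold change.
#' @return A `data.frame` of class `feature_stats` with columns
#'   `feature_id`, `t_stat`, `df`, `p_value`, `effect` (log2 FC or
#'   delta beta), plus `influence_delta_f1` and `rank` columns (NA until
#'   influence scoring).
#' @export
feature_stats <- function(X, labels, pseudocount = 1) {
  stopifnot(inherits(X, "omics_matrix"))
  y <- as.integer(labels[rownames(X$values)])
  if (anyNA(y)) stop("labels missing for some samples in the matrix")
  V <- X$values
  pos <- y == 1L
  neg <- y == 0L
  n1 <- sum(pos)
  n2 <- sum(neg)
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 samples")
  m1 <- colMeans(V[pos, , drop = FALSE])
  m2 <- colMeans(V[neg, , drop = FALSE])
  v1 <- apply(V[pos, , drop = FALSE], 2, stats::var)
  v2 <- apply(V[neg, , drop = FALSE], 2, stats::var)
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate)) {
    warning(sprintf("excluding %d degenerate feature(s) with zero variance in both classes (e.g. '%s')",
                    sum(degenerate), colnames(V)[degenerate][1]),
            call. = FALSE)
  }
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  effect <- if (X$omics_kind == "expression") {
    log2_fold_change(m1, m2, pseudocount)
  } else {
    m1 - m2
  }
  out <- data.frame(feature_id = colnames(V), t_stat = t_stat, df = df,
                    p_value = p, effect = effect,
                    influence_delta_f1 = NA_real_, rank = NA_integer_,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[!degenerate, , drop = FALSE]
  attr(out, "omics_kind") <- X$omics_kind
  class(out) <- c("feature_stats", "data.frame")
  out
}

#' Primary differential filter
#'
#' Keeps features with p-value strictly below `p_max` and effect size
#' strictly above the modality threshold: |log2 FC| > `abs_fc_min` for
#' expression, |delta beta| > `delta_beta_min` for methylation.
#' Boundary values are dropped (strict inequalities).
#'
#' @param stats A [feature_stats] table.
#' @param p_max P-value cut (default 0.05).
#' @param abs_fc_min Absolute log2 fold-change cut for expression
#'   (default 0.5).
#' @param delta_beta_min Absolute beta-difference cut for methylation
#'   (default 0.2).
#' @return Character vector of surviving feature IDs.
#' @export
primary_filter <- function(stats, p_max = 0.05, abs_fc_min = 0.5,
                           delta_beta_min = 0.2) {
  cut <- if (identical(attr(stats, "omics_kind"), "methylation")) {
    delta_beta_min
  } else {
    abs_fc_min
  }
  keep <- stats$p_value < p_max & abs(stats$effect) > cut
  stats$feature_id[keep]
}

#' Influence scores by feature ablation
#'
#' For each feature, the influence on the F1-score is the difference
#' between the macro F1 with the feature included and with it excluded,
#' measured on a fixed evaluation partition. The default `"mask"` mode
#' reuses the trained model and replaces the feature column by its
#' training-set mean (the similarity graph is kept fixed); `"retrain"`
#' refits the whole model without the feature at the same seed.
#'
#' @param fit A `gcn_fit`.
#' @param features Feature IDs to score (default: all features of every
#'   omics block).
#' @param eval_ids Evaluation-partition sample IDs.
#' @param mode `"mask"` or `"retrain"`.
#' @return Data frame with `feature_id` and `influence_delta_f1`.
#' @export
influence_scores <- function(fit, features = NULL,
                             eval_ids, mode = c("mask", "retrain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "gcn_fit"))
  labels <- fit$cohort$labels
  block_features <- lapply(fit$cohort$matrices,
                           function(m) colnames(m$values))
  all_features <- unlist(block_features)
  if (is.null(features)) features <- all_features
  unknown <- setdiff(features, all_features)
  if (length(unknown) > 0) stop("unknown feature ID: ", unknown[1])
  eval_idx <- match(eval_ids, names(labels))
  y_eval <- as.integer(labels[eval_ids])
  base_pred <- predict(fit, ids = eval_ids)
  f1_base <- macro_f1(confusion(y_eval, base_pred$fused$class))
  train_idx <- match(fit$train_ids, names(labels))

  score_masked <- function(feature) {
    l <- which(vapply(block_features, function(f) feature %in% f, TRUE))
    j <- match(feature, block_features[[l]])
    if (mode == "retrain") {
      cohort2 <- fit$cohort
      keep <- setdiff(block_features[[l]], feature)
      cohort2$matrices[[l]] <- omics_matrix(
        cohort2$matrices[[l]]$values[, keep, drop = FALSE],
        omics_kind = cohort2$matrices[[l]]$omics_kind)
      refit <- gcn_fit(cohort2, train_ids = fit$train_ids,
                       config = fit$config,
                       standardize = isTRUE(fit$standardize),
                       target_mean_degree = fit$target_mean_degree)
      pred <- predict(refit, ids = eval_ids)
      return(macro_f1(confusion(y_eval, pred$fused$class)))
    }
    Xl <- fit$model$X_adjusted[[l]]
    orig <- Xl[, j]
    Xl[, j] <- mean(orig[train_idx])
    outs <- lapply(seq_along(fit$model$modules), function(m) {
      Xm <- if (m == l) Xl else fit$model$X_adjusted[[m]]
      nn_forward(fit$model$modules[[m]], Xm,
                 Ahat = fit$graphs[[m]]$Ahat, training = FALSE)$logits
    })
    fused <- fuse_predictions(prediction_matrix(outs[[1]]),
                              prediction_matrix(outs[[2]]),
                              fit$model$head)
    macro_f1(confusion(y_eval, fused$class[eval_idx]))
  }

  delta <- vapply(features, function(f) f1_base - score_masked(f),
                  numeric(1))
  data.frame(feature_id = features, influence_delta_f1 = unname(delta),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attach influence scores to a feature-stats table
#' @param stats A [feature_stats] table.
#' @param influence Data frame from [influence_scores()].
#' @return The stats table with `influence_delta_f1` filled in.
#' @export
add_influence <- function(stats, influence) {
  idx <- match(stats$feature_id, influence$feature_id)
  stats$influence_delta_f1 <- influence$influence_delta_f1[idx]
  stats
}

#' Rank features and keep the top k
#'
#' Descending sort on the influence score; ties are broken by larger
#' |t| statistic, then lexicographic feature ID. When fewer than `k`
#' features carry scores, all of them are returned with a warning.
#'
#' @param stats A [feature_stats] table with `influence_delta_f1`
#'   populated (e.g. via [add_influence()]).
#' @param k Number of features to keep (reference protocol: 200 for
#'   expression, 300 for methylation).
#' @return The top-`k` rows of `stats`, with `rank` assigned 1..k.
#' @export
select_top_features <- function(stats, k) {
  scored <- stats[!is.na(stats$influence_delta_f1), , drop = FALSE]
  ord <- order(-scored$influence_delta_f1, -abs(scored$t_stat),
               scored$feature_id)
  scored <- scored[ord, , drop = FALSE]
  if (nrow(scored) < k) {
    warning(sprintf("only %d scored features available (requested %d)",
                    nrow(scored), k), call. = FALSE)
    k <- nrow(scored)
  }
  out <- scored[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Write a feature-stats table as TSV
#' @param stats A [feature_stats] table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
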
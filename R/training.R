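#' One-hot encoding of binary labels
#' @param labels Values in \{0, 1\}.
#' @return n x 2 matrix; column 1 is class 0, column 2 is class 1.
#' @export
one_hot <- function(labels) {
  labels <- as.integer(labels)
  Y <- matrix(0, length(labels), 2)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Cross-entropy between a one-hot row and a probability row
#'
#' Probabilities are clamped to \[eps, 1 - eps\] before the logarithm,
#' so a confidently wrong prediction yields a large but finite loss.
#'
#' @param y_true One-hot vector.
#' @param y_pred Probability vector summing to 1 (tolerance 1e-6).
#' @param eps Clamp bound (default 1e-12).
#' @return Non-negative real.
#' @export
cross_entropy <- function(y_true, y_pred, eps = 1e-12) {
  if (abs(sum(y_pred) - 1) > 1e-6) {
    stop("'y_pred' is not a normalized probability vector")
  }
  y_pred <- pmin(pmax(y_pred, eps), 1 - eps)
  -sum(y_true * log(y_pred))
}

#' Per-omics module loss: summed cross-entropy
#'
#' The sum (not the mean) over samples, so the loss and its gradients
#' scale with the cohort size.
#'
#' @param Y One-hot label matrix (or a \{0,1\} label vector).
#' @param pred A `prediction_matrix` or n x 2 probability matrix.
#' @param weights Optional per-sample weights (e.g. train mask or label
#'   affinities).
#' @return Non-negative real.
#' @export
module_loss <- function(Y, pred, weights = NULL) {
  if (is.null(dim(Y))) Y <- one_hot(Y)
  P <- if (inherits(pred, "prediction_matrix")) pred$prob else pred
  if (nrow(Y) != nrow(P)) {
    stop(sprintf("%d labels but %d predictions", nrow(Y), nrow(P)))
  }
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  per_sample <- -rowSums(Y * log(P))
  if (!is.null(weights)) per_sample <- per_sample * weights
  sum(per_sample)
}

#' Total training loss: weighted module losses plus fusion loss
#'
#' @param module_losses Numeric vector of per-omics losses.
#' @param fusion_loss Loss of the terminal fusion head.
#' @param alphas Per-omics weights (default all 1, the stable setting).
#' @param lambda_f Weight of the fusion loss (default 1).
#' @return sum(alphas * module_losses) + lambda_f * fusion_loss.
#' @export
total_loss <- function(module_losses, fusion_loss, alphas = NULL,
                       lambda_f = 1) {
  if (is.null(alphas)) alphas <- rep(1, length(module_losses))
  if (length(alphas) != length(module_losses)) {
    stop("'alphas' and 'module_losses' lengths differ")
  }
  sum(alphas * module_losses) + lambda_f * fusion_loss
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 500 pretraining epochs,
#' 2500 fine-tuning epochs, Adam, Xavier initialization, all per-omics
#' loss weights 1, and learning rates taken from the shared search grid.
#'
#' @param pretrain_epochs,finetune_epochs Epoch counts (defaults 500 and
#'   2500).
#' @param lr_pretrain,lr_train,lr_terminal Learning rates for
#'   pretraining, joint fine-tuning of the GCN modules, and the terminal
#'   classification head; each should come from [lr_grid()]'s values.
#' @param alphas Per-omics loss weights (default 1 for every module).
#' @param lambda_f Fusion loss weight (default 1).
#' @param clip_sd Feature clipping bound in SD units used by
#'   [smooth_sample_weights()]; `Inf` disables clipping.
#' @param use_affinity Weight pretraining cross-entropy terms by 1-hop
#'   neighbor label affinity.
#' @param seed Integer seed controlling initialization and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(pretrain_epochs = 500, finetune_epochs = 2500,
                         lr_pretrain = 1e-3, lr_train = 5e-4,
                         lr_terminal = 1e-3, alphas = NULL, lambda_f = 1,
                         clip_sd = 3, use_affinity = TRUE, seed = 1) {
  stopifnot(pretrain_epochs >= 0, finetune_epochs >= 0,
            lr_pretrain > 0, lr_train > 0, lr_terminal > 0, clip_sd > 0)
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 lr_pretrain = lr_pretrain, lr_train = lr_train,
                 lr_terminal = lr_terminal, alphas = alphas,
                 lambda_f = lambda_f, clip_sd = clip_sd,
                 use_affinity = use_affinity, seed = as.integer(seed),
                 optimizer = "adam", init = "xavier"),
            class = "train_config")
}

#' The shared learning-rate search grid
#'
#' @param type `"diagonal"` for the 10 equal-rate triples (the desk-scale
#'   default), `"full"` for all 1000 combinations.
#' @param subsample Optionally draw this many random triples from the
#'   grid.
#' @param seed Seed for the subsample draw.
#' @return Data frame with columns `lr_pretrain`, `lr_train`,
#'   `lr_terminal`.
#' @export
lr_grid <- function(type = c("diagonal", "full"), subsample = NULL,
                    seed = 1) {
  type <- match.arg(type)
  vals <- c(1e-7, 5e-7, 1e-6, 5e-6, 1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3)
  grid <- if (type == "diagonal") {
    data.frame(lr_pretrain = vals, lr_train = vals, lr_terminal = vals)
  } else {
    expand.grid(lr_pretrain = vals, lr_train = vals, lr_terminal = vals,
                KEEP.OUT.ATTRS = FALSE)
  }
  if (!is.null(subsample) && subsample < nrow(grid)) {
    set.seed(seed)
    grid <- grid[sample.int(nrow(grid), subsample), , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

#' Feature clipping and 1-hop label-affinity weights
#'
#' Two smoothing steps applied before pretraining: (a) every feature
#' value farther than `clip_sd` standard deviations from the feature
#' mean is clipped to that bound, restraining protruding components of
#' the sample weight vectors; (b) each sample receives a label-affinity
#' weight per class equal to the fraction of its 1-hop graph neighbors
#' carrying that class, so a sample surrounded by the opposite class
#' contributes less to its own class during pretraining. Samples with
#' no (labeled) neighbors get the uniform affinity (0.5, 0.5).
#'
#' Clipping statistics are computed on the labeled (training) samples
#' and applied to all rows; neighbors with missing labels are ignored
#' in the affinity counts.
#'
#' @param X An [omics_matrix].
#' @param graph A `similarity_graph` built on the same samples.
#' @param labels Labels in \{0, 1\}, `NA` for samples outside the
#'   training partition.
#' @param clip_sd Positive clipping bound in SD units; `Inf` disables
#'   clipping.
#' @return List with `X` (adjusted [omics_matrix]) and `affinity`
#'   (n x 2 matrix of per-class neighbor fractions).
#' @export
smooth_sample_weights <- function(X, graph, labels, clip_sd = 3) {
  stopifnot(inherits(X, "omics_matrix"), clip_sd > 0)
  V <- X$values
  labels <- as.integer(labels)
  labeled <- !is.na(labels)
  if (is.finite(clip_sd)) {
    ref <- V[labeled, , drop = FALSE]
    mu <- colMeans(ref)
    sd_f <- apply(ref, 2, stats::sd)
    lo <- mu - clip_sd * sd_f
    hi <- mu + clip_sd * sd_f
    V <- pmin(pmax(V, matrix(lo, nrow(V), ncol(V), byrow = TRUE)),
              matrix(hi, nrow(V), ncol(V), byrow = TRUE))
  }
  Adj <- (graph$A != 0) & matrix(labeled, nrow(V), nrow(V), byrow = TRUE)
  lab1 <- ifelse(labeled, labels, 0L)
  n1 <- Adj %*% lab1                      # labeled neighbors with class 1
  n_tot <- rowSums(Adj)
  affinity <- cbind(0.5, 0.5)[rep(1, nrow(V)), , drop = FALSE]
  has <- n_tot > 0
  affinity[has, 2] <- n1[has] / n_tot[has]
  affinity[has, 1] <- 1 - affinity[has, 2]
  colnames(affinity) <- c("class0", "class1")
  rownames(affinity) <- rownames(V)
  # constructed directly: clipping only pulls values inward, but the
  # inputs may already be standardized (see gcn_fit) and need not
  # satisfy the raw beta-value range
  Xout <- structure(list(values = V, omics_kind = X$omics_kind),
                    class = "omics_matrix")
  list(X = Xout, affinity = affinity)
}

# Per-module, per-epoch RNG stream for dropout: keeps joint fine-tuning
# decoupled across modules so lambda = 0 reproduces independent training.
.module_epoch_seed <- function(seed, stage, l, epoch) {
  (seed * 7919L + stage * 1299721L + l * 104729L + epoch) %% 2147483647L
}

.weighted_ce_sum <- function(logits, Y, w) {
  P <- pmin(pmax(softmax(logits), 1e-12), 1 - 1e-12)
  sum(-rowSums(Y * log(P)) * w)
}

#' Pretrain the per-omics GCN modules independently
#'
#' Each omics module is trained alone for `pretrain_epochs` epochs with
#' Adam at `lr_pretrain`, minimizing its (affinity-weighted) summed
#' cross-entropy over the training samples. The fusion head is left
#' untouched. Feature clipping and label-affinity weights come from
#' [smooth_sample_weights()].
#'
#' @param model A `gcn_model` from [gcn_model_init()].
#' @param cohort A `cohort` from [align_cohort()].
#' @param graphs List of `similarity_graph`s, one per omics block.
#' @param config A [train_config()].
#' @param train_ids Sample IDs of the training partition (labels of all
#'   other samples are masked; default: all samples).
#' @return The model with pretrained modules and per-epoch loss
#'   histories in `model$pretrain_loss`.
#' @export
pretrain <- function(model, cohort, graphs, config,
                     train_ids = names(cohort$labels)) {
  n <- length(cohort$labels)
  train_mask <- as.numeric(names(cohort$labels) %in% train_ids)
  if (sum(cohort$labels[train_ids] == 1) == 0 ||
      sum(cohort$labels[train_ids] == 0) == 0) {
    stop("training partition needs at least one sample of each class")
  }
  masked <- ifelse(train_mask == 1, as.integer(cohort$labels), NA_integer_)
  Y <- one_hot(cohort$labels)
  model$X_adjusted <- vector("list", length(model$modules))
  model$pretrain_loss <- vector("list", length(model$modules))
  for (l in seq_along(model$modules)) {
    sw <- smooth_sample_weights(cohort$matrices[[l]], graphs[[l]], masked,
                                clip_sd = config$clip_sd)
    Xc <- sw$X$values
    w <- train_mask
    if (config$use_affinity) {
      w <- w * sw$affinity[cbind(seq_len(n), as.integer(cohort$labels) + 1L)]
    }
    net <- model$modules[[l]]
    opt <- adam_init(net)
    losses <- numeric(config$pretrain_epochs)
    for (epoch in seq_len(config$pretrain_epochs)) {
      set.seed(.module_epoch_seed(config$seed, 1L, l, epoch))
      fwd <- nn_forward(net, Xc, Ahat = graphs[[l]]$Ahat, training = TRUE)
      loss <- .weighted_ce_sum(fwd$logits, Y, w)
      if (!is.finite(loss)) {
        stop(sprintf("pretraining of module %d diverged at epoch %d",
                     l, epoch))
      }
      losses[epoch] <- loss
      G <- ce_logit_grad(fwd$logits, Y, w)
      grads <- nn_backward(net, fwd$cache, G,
                           Ahat = graphs[[l]]$Ahat)$layers
      step <- adam_step(net, grads, opt, lr = config$lr_pretrain)
      net <- step$net
      opt <- step$opt
    }
    model$modules[[l]] <- net
    model$X_adjusted[[l]] <- Xc
    model$pretrain_loss[[l]] <- losses
  }
  model$train_ids <- train_ids
  model
}

#' Jointly fine-tune the modules and the fusion head
#'
#' Minimizes the composite loss (sum of per-omics summed cross-entropies
#' plus `lambda_f` times the fusion loss) for `finetune_epochs` epochs.
#' The GCN modules step with Adam at `lr_train`, the terminal head at
#' `lr_terminal`.
#'
#' @inheritParams pretrain
#' @return The model with fine-tuned modules and head, and the total
#'   loss history in `model$finetune_loss`.
#' @export
finetune <- function(model, cohort, graphs, config,
                     train_ids = model$train_ids) {
  if (is.null(model$X_adjusted)) {
    stop("fine-tuning requires a pretrained model (run pretrain() first)")
  }
  n <- length(cohort$labels)
  L <- length(model$modules)
  alphas <- config$alphas
  if (is.null(alphas)) alphas <- rep(1, L)
  w <- as.numeric(names(cohort$labels) %in% train_ids)
  Y <- one_hot(cohort$labels)
  opts <- lapply(model$modules, adam_init)
  head <- model$head
  head_opt <- list(t = 0, mW = 0 * head$W, vW = 0 * head$W,
                   mb = 0 * head$b, vb = 0 * head$b)
  losses <- numeric(config$finetune_epochs)
  for (epoch in seq_len(config$finetune_epochs)) {
    fwds <- vector("list", L)
    mod_loss <- numeric(L)
    for (l in seq_len(L)) {
      set.seed(.module_epoch_seed(config$seed, 2L, l, epoch))
      fwds[[l]] <- nn_forward(model$modules[[l]], model$X_adjusted[[l]],
                              Ahat = graphs[[l]]$Ahat, training = TRUE)
      mod_loss[l] <- .weighted_ce_sum(fwds[[l]]$logits, Y, w)
    }
    H <- do.call(cbind, lapply(fwds, `[[`, "logits"))
    Zf <- sweep(H %*% head$W, 2, head$b, "+")
    fusion_loss <- .weighted_ce_sum(Zf, Y, w)
    loss <- total_loss(mod_loss, fusion_loss, alphas, config$lambda_f)
    if (!is.finite(loss)) {
      stop(sprintf("fine-tuning diverged at epoch %d", epoch))
    }
    losses[epoch] <- loss
    Gf <- ce_logit_grad(Zf, Y, w)
    dH <- config$lambda_f * (Gf %*% t(head$W))
    # terminal head step (Adam at lr_terminal)
    dWh <- config$lambda_f * crossprod(H, Gf)
    dbh <- config$lambda_f * colSums(Gf)
    head_opt$t <- head_opt$t + 1
    bc1 <- 1 - 0.9^head_opt$t
    bc2 <- 1 - 0.999^head_opt$t
    head_opt$mW <- 0.9 * head_opt$mW + 0.1 * dWh
    head_opt$vW <- 0.999 * head_opt$vW + 0.001 * dWh^2
    head_opt$mb <- 0.9 * head_opt$mb + 0.1 * dbh
    head_opt$vb <- 0.999 * head_opt$vb + 0.001 * dbh^2
    head$W <- head$W - config$lr_terminal * (head_opt$mW / bc1) /
      (sqrt(head_opt$vW / bc2) + 1e-8)
    head$b <- head$b - config$lr_terminal * (head_opt$mb / bc1) /
      (sqrt(head_opt$vb / bc2) + 1e-8)
    for (l in seq_len(L)) {
      Gl <- alphas[l] * ce_logit_grad(fwds[[l]]$logits, Y, w) +
        dH[, (2 * l - 1):(2 * l), drop = FALSE]
      grads <- nn_backward(model$modules[[l]], fwds[[l]]$cache, Gl,
                           Ahat = graphs[[l]]$Ahat)$layers
      step <- adam_step(model$modules[[l]], grads, opts[[l]],
                        lr = config$lr_train)
      model$modules[[l]] <- step$net
      opts[[l]] <- step$opt
    }
  }
  model$head <- head
  model$finetune_loss <- losses
  model
}

#' Assemble an untrained multi-omics GCN model
#'
#' @param specs List of [gcn_model_spec]s, one per omics block.
#' @param seed Integer seed for Xavier initialization of all modules and
#'   the fusion head.
#' @return A list of class `gcn_model` with `modules` (per-omics
#'   `gcn_params`) and `head` (the terminal fusion layer).
#' @export
gcn_model_init <- function(specs, seed = 1) {
  modules <- lapply(seq_along(specs), function(l) {
    gcn_init(specs[[l]], seed = seed + l)
  })
  structure(list(modules = modules,
                 head = fusion_head_init(2 * length(specs),
                                         seed = seed + 1000L)),
            class = "gcn_model")
}

#' Train the full multi-omics GCN classifier
#'
#' End-to-end convenience wrapper: standardizes every feature on the
#' training-partition mean and SD, builds the per-omics similarity
#' graphs over all samples (transductive inference: test samples sit in
#' the graph with their labels masked), pretrains each omics module,
#' then jointly fine-tunes modules and fusion head.
#'
#' @param cohort A `cohort` from [align_cohort()].
#' @param train_ids Sample IDs used for the loss; everything else is
#'   label-masked but remains in the graph.
#' @param config A [train_config()].
#' @param tau Explicit similarity threshold(s), recycled per omics;
#'   `NULL` selects per-block thresholds via [select_threshold()].
#' @param target_mean_degree Target mean degree for threshold selection.
#' @param standardize Z-score each feature using training-partition
#'   statistics before graph construction and training (default TRUE;
#'   expression blocks are log-transformed first). Disable when the
#'   inputs are already normalized.
#' @return A list of class `gcn_fit` with the trained model, the graphs
#'   and the training metadata; use [predict.gcn_fit()] to score
#'   samples.
#' @export
gcn_fit <- function(cohort, train_ids = names(cohort$labels),
                    config = train_config(), tau = NULL,
                    target_mean_degree = 10, standardize = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  cohort_raw <- cohort
  if (standardize) {
    tr <- names(cohort$labels) %in% train_ids
    cohort$matrices <- lapply(cohort$matrices, function(m) {
      V <- m$values
      if (m$omics_kind == "expression") {
        if (min(V) < 0) stop("expression values must be non-negative")
        V <- log1p(V)
      }
      mu <- colMeans(V[tr, , drop = FALSE])
      sdv <- apply(V[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      V <- sweep(sweep(V, 2, mu, "-"), 2, sdv, "/")
      structure(list(values = V, omics_kind = m$omics_kind),
                class = "omics_matrix")
    })
  }
  taus <- if (is.null(tau)) rep(list(NULL), length(cohort$matrices)) else
    as.list(rep(tau, length.out = length(cohort$matrices)))
  graphs <- lapply(seq_along(cohort$matrices), function(l) {
    build_similarity_graph(cohort$matrices[[l]], tau = taus[[l]],
                           target_mean_degree = target_mean_degree)
  })
  specs <- lapply(cohort$matrices, function(m) {
    gcn_model_spec(ncol(m$values))
  })
  model <- gcn_model_init(specs, seed = config$seed)
  model <- pretrain(model, cohort, graphs, config, train_ids)
  model <- finetune(model, cohort, graphs, config, train_ids)
  structure(list(model = model, graphs = graphs, cohort = cohort_raw,
                 train_ids = train_ids, config = config,
                 standardize = standardize,
                 target_mean_degree = target_mean_degree),
            class = "gcn_fit")
}

#' Predict classes from a fitted multi-omics GCN
#'
#' Deterministic inference pass (dropout off) over the whole graph;
#' results can be restricted to a subset of samples, e.g. the held-out
#' test partition.
#'
#' @param object A `gcn_fit`.
#' @param ids Sample IDs to report (default: all).
#' @param rules Optional [therapy_rule_table] to attach agent
#'   annotations from the cohort's variant table.
#' @param ... Unused.
#' @return List with `fused` (a `prediction_matrix` over `ids`),
#'   `per_module` predictions, and `therapy` annotations when rules and
#'   variants are available.
#' @export
predict.gcn_fit <- function(object, ids = NULL, rules = NULL, ...) {
  model <- object$model
  preds <- lapply(seq_along(model$modules), function(l) {
    out <- nn_forward(model$modules[[l]], model$X_adjusted[[l]],
                      Ahat = object$graphs[[l]]$Ahat, training = FALSE)
    prediction_matrix(out$logits,
                      sample_ids = names(object$cohort$labels))
  })
  fused <- fuse_predictions(preds[[1]], preds[[2]], model$head)
  if (length(model$modules) > 2) {
    stop("fusion head currently supports exactly two omics blocks")
  }
  if (is.null(ids)) ids <- names(object$cohort$labels)
  idx <- match(ids, names(object$cohort$labels))
  if (anyNA(idx)) stop("unknown sample ID: ", ids[which(is.na(idx))[1]])
  subset_pm <- function(pm) {
    prediction_matrix(pm$logits[idx, , drop = FALSE], sample_ids = ids)
  }
  out <- list(fused = subset_pm(fused),
              per_module = lapply(preds, subset_pm))
  if (!is.null(rules) && !is.null(object$cohort$variants)) {
    out$therapy <- match_therapy(object$cohort$variants, rules,
                                 sample_ids = ids)
  }
  out
}

.largest_remainder <- function(targets, total) {
  base <- floor(targets)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- targets - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Class-stratified random partition at the given ratios with
#' largest-remainder rounding: overall part sizes are fixed first, then
#' per-class quotas are rounded so that both the class totals and the
#' part totals are met exactly.
#'
#' @param labels A [label_vector] (or named \{0,1\} vector).
#' @param ratios Train/validation/test proportions summing to 1
#'   (default 0.55/0.15/0.30).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return A list of class `split_spec` with character fields `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(labels, ratios = c(0.55, 0.15, 0.30), seed = 1) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("'ratios' must sum to 1")
  if (length(ratios) != 3) stop("'ratios' must have 3 entries")
  ids <- names(labels)
  y <- as.integer(labels)
  n <- length(y)
  classes <- sort(unique(y))
  for (cl in classes) {
    if (sum(y == cl) < 3) {
      stop(sprintf("class %d has fewer than 3 samples; cannot stratify", cl))
    }
  }
  parts_total <- .largest_remainder(n * ratios, n)
  Fq <- t(vapply(classes, function(cl) sum(y == cl) * ratios,
                 numeric(3)))
  Fl <- floor(Fq)
  frac <- Fq - Fl
  deficit_c <- vapply(classes, function(cl) sum(y == cl), 0L) - rowSums(Fl)
  deficit_p <- parts_total - colSums(Fl)
  ord <- order(-as.vector(t(frac)))   # cells by fractional part, desc
  for (pass in 1:2) {
    for (cell in ord) {
      ci <- (cell - 1) %/% 3 + 1
      pi <- (cell - 1) %% 3 + 1
      if (deficit_c[ci] > 0 && deficit_p[pi] > 0 &&
          (pass == 2 || frac[ci, pi] > 0)) {
        Fl[ci, pi] <- Fl[ci, pi] + 1
        deficit_c[ci] <- deficit_c[ci] - 1
        deficit_p[pi] <- deficit_p[pi] - 1
      }
    }
    if (all(deficit_c == 0)) break
  }
  set.seed(seed)
  parts <- list(character(0), character(0), character(0))
  for (ci in seq_along(classes)) {
    pool <- sample(ids[y == classes[ci]])
    offset <- 0
    for (pi in 1:3) {
      take <- Fl[ci, pi]
      parts[[pi]] <- c(parts[[pi]], pool[seq_len(take) + offset])
      offset <- offset + take
    }
  }
  structure(list(train = parts[[1]], validation = parts[[2]],
                 test = parts[[3]], ratios = ratios, seed = seed),
            class = "split_spec")
}

#' Stratified k-fold assignments
#'
#' Assigns each sample to exactly one of `k` folds, keeping fold sizes
#' within one sample of each other and the class balance per fold within
#' one of proportional.
#'
#' @param ids Sample IDs to fold.
#' @param labels Labels (named vector covering `ids`) used for
#'   stratification.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector of fold numbers in `1:k`.
#' @export
kfold_splits <- function(ids, labels, k = 5, seed = 1) {
  if (k > length(ids)) stop("'k' exceeds the number of samples")
  if (k < 2) stop("'k' must be at least 2")
  y <- as.integer(labels[ids])
  set.seed(seed)
  fold <- stats::setNames(integer(length(ids)), ids)
  load <- integer(k)
  for (cl in sort(unique(y))) {
    pool <- sample(ids[y == cl])
    # deal to folds ordered by current load so totals stay within +/- 1
    target <- order(load, seq_len(k))
    for (i in seq_along(pool)) {
      f <- target[(i - 1) %% k + 1]
      fold[pool[i]] <- f
      load[f] <- load[f] + 1
    }
  }
  fold
}

#' Cross-validated search over the learning-rate grid
#'
#' Evaluates each (pretrain, train, terminal) learning-rate triple by
#' k-fold cross-validation on the training partition, scoring mean
#' validation macro F1, and returns the best triple. Ties are broken
#' toward the smaller `lr_train`, then `lr_pretrain`, then
#' `lr_terminal`.
#'
#' @param cohort A `cohort`.
#' @param train_ids Training-partition sample IDs searched over.
#' @param grid Data frame from [lr_grid()] (or any subset of it).
#' @param config Base [train_config()] whose learning rates are
#'   overridden per triple (use reduced epoch counts for desk-scale
#'   searches).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param tau,target_mean_degree Graph options passed to [gcn_fit()].
#' @return List with `best` (one-row data frame) and `scores` (the grid
#'   with a `mean_macro_f1` column).
#' @export
grid_search_learning_rates <- function(cohort, train_ids, grid,
                                       config = train_config(),
                                       k = 5, seed = 1, tau = NULL,
                                       target_mean_degree = 10) {
  if (is.null(grid) || nrow(grid) == 0) stop("learning-rate grid is empty")
  folds <- kfold_splits(train_ids, cohort$labels, k = k, seed = seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lr_pretrain <- grid$lr_pretrain[g]
    cfg$lr_train <- grid$lr_train[g]
    cfg$lr_terminal <- grid$lr_terminal[g]
    fold_f1 <- numeric(k)
    for (f in seq_len(k)) {
      fit_ids <- train_ids[folds != f]
      val_ids <- train_ids[folds == f]
      fit <- gcn_fit(cohort, train_ids = fit_ids, config = cfg, tau = tau,
                     target_mean_degree = target_mean_degree)
      pred <- predict(fit, ids = val_ids)
      fold_f1[f] <- macro_f1(confusion(cohort$labels[val_ids],
                                       pred$fused$class))
    }
    scores[g] <- mean(fold_f1)
  }
  ord <- order(-scores, grid$lr_train, grid$lr_pretrain, grid$lr_terminal)
  best <- grid[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  out_scores <- grid
  out_scores$mean_macro_f1 <- scores
  list(best = best, scores = out_scores)
}
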
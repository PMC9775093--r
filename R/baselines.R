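#' Baseline classifier specification
#'
#' The three reference baselines mirror the proposed model's shared
#' settings: LeakyReLU(0.25), Adam, cross-entropy, 400 hidden units,
#' 200-dimensional FC layer, dropout 0.5.
#'
#' * `cnn`: 1-D convolution over the feature axis, max pooling with
#'   kernel 2, stride 1 and zero padding, then the FC stack.
#' * `logistic_regression`: per-batch feature normalization, dropout,
#'   and a single affine layer to the 2-class logits.
#' * `naive_bayes`: FC-structured layers with a standard-normal prior
#'   on the weights (realized as the corresponding L2 log-prior
#'   penalty).
#'
#' @param kind `"cnn"`, `"logistic_regression"` or `"naive_bayes"`.
#' @param input_dim Number of input features.
#' @param hidden_units,fc_dim,dropout,slope Shared architecture
#'   settings.
#' @param n_filters,kernel_size CNN convolution settings.
#' @param prior_sd Standard deviation of the naive-Bayes weight prior.
#' @return A list of class `baseline_spec`.
#' @export
build_baseline <- function(kind = c("cnn", "logistic_regression",
                                    "naive_bayes"),
                           input_dim, hidden_units = 400, fc_dim = 200,
                           dropout = 0.5, slope = 0.25, n_filters = 8,
                           kernel_size = 5, prior_sd = 1) {
  kind <- match.arg(kind)
  stopifnot(input_dim >= 1)
  structure(list(kind = kind, input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 fc_dim = as.integer(fc_dim), dropout = dropout,
                 slope = slope, n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 prior_sd = prior_sd),
            class = "baseline_spec")
}

.baseline_init <- function(spec, seed) {
  set.seed(seed)
  p <- spec$input_dim
  params <- list(spec = spec)
  if (spec$kind == "cnn") {
    params$K <- xavier_matrix(spec$kernel_size, spec$n_filters)
    params$bK <- numeric(spec$n_filters)
    params$net <- nn_init(c(p * spec$n_filters, spec$hidden_units,
                            spec$fc_dim, 2),
                          rep("dense", 3), slope = spec$slope,
                          dropout_rate = spec$dropout)
  } else if (spec$kind == "logistic_regression") {
    params$net <- nn_init(c(p, 2), "dense", slope = spec$slope,
                          dropout_rate = spec$dropout)
  } else {
    params$net <- nn_init(c(p, spec$hidden_units, spec$fc_dim, 2),
                          rep("dense", 3), slope = spec$slope,
                          dropout_rate = spec$dropout)
  }
  params
}

.conv1d_forward <- function(X, K, bK, slope) {
  n <- nrow(X)
  p <- ncol(X)
  k <- nrow(K)
  nf <- ncol(K)
  half <- (k - 1) %/% 2
  Xpad <- cbind(matrix(0, n, half), X, matrix(0, n, k - 1 - half))
  Z <- array(0, c(n, p, nf))
  for (f in seq_len(nf)) {
    Cf <- matrix(bK[f], n, p)
    for (j in seq_len(k)) {
      Cf <- Cf + Xpad[, j:(j + p - 1), drop = FALSE] * K[j, f]
    }
    Z[, , f] <- Cf
  }
  A <- Z
  A[A < 0] <- A[A < 0] * slope
  # max pooling, kernel 2, stride 1, zero padding on the right
  P <- array(0, c(n, p, nf))
  right <- array(0, c(n, p, nf))
  right[, seq_len(p - 1), ] <- A[, 2:p, , drop = FALSE]
  take_right <- right > A
  P <- ifelse(take_right, right, A)
  P[P < 0] <- 0                       # zero pad can win over negatives
  list(Xpad = Xpad, Z = Z, A = A, P = P, take_right = take_right,
       flat = matrix(P, n, p * nf))
}

.conv1d_backward <- function(cache, dFlat, K, slope) {
  n <- nrow(dFlat)
  nf <- ncol(K)
  k <- nrow(K)
  p <- ncol(dFlat) / nf
  dP <- array(dFlat, c(n, p, nf))
  dP[cache$P == 0] <- 0               # pooled zero came from the pad
  dA <- array(0, c(n, p, nf))
  # route pooled gradient to the argmax position
  left_win <- !cache$take_right
  dA[left_win] <- dP[left_win]
  shifted <- array(0, c(n, p, nf))
  shifted[, 2:p, ] <- ifelse(cache$take_right, dP, 0)[, seq_len(p - 1), ,
                                                      drop = FALSE]
  dA <- dA + shifted
  dZ <- dA
  dZ[cache$Z < 0] <- dZ[cache$Z < 0] * slope
  dK <- matrix(0, k, nf)
  dbK <- numeric(nf)
  for (f in seq_len(nf)) {
    dZf <- dZ[, , f]
    dbK[f] <- sum(dZf)
    for (j in seq_len(k)) {
      dK[j, f] <- sum(cache$Xpad[, j:(j + p - 1), drop = FALSE] * dZf)
    }
  }
  list(dK = dK, dbK = dbK)
}

.baseline_forward <- function(params, X, training = FALSE) {
  spec <- params$spec
  conv_cache <- NULL
  H <- X
  if (spec$kind == "logistic_regression") {
    H <- sweep(H, 2, params$norm_mu, "-")
    H <- sweep(H, 2, params$norm_sd, "/")
  } else if (spec$kind == "cnn") {
    conv_cache <- .conv1d_forward(H, params$K, params$bK, spec$slope)
    H <- conv_cache$flat
  }
  out <- nn_forward(params$net, H, training = training)
  list(logits = out$logits, cache = out$cache, conv_cache = conv_cache)
}

#' Train a baseline classifier
#'
#' Full-batch Adam on the summed cross-entropy, mirroring the training
#' setup of the GCN modules.
#'
#' @param spec A [build_baseline()] specification.
#' @param X Numeric matrix of inputs (samples in rows); typically the
#'   column-bound omics blocks.
#' @param y Labels in \{0, 1\}.
#' @param epochs Number of epochs (default 500).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Integer seed for initialization and dropout.
#' @return A fitted model of class `baseline_fit`.
#' @export
train_baseline <- function(spec, X, y, epochs = 500, lr = 1e-3, seed = 1) {
  stopifnot(inherits(spec, "baseline_spec"))
  params <- .baseline_init(spec, seed)
  if (spec$kind == "logistic_regression") {
    params$norm_mu <- colMeans(X)
    sds <- apply(X, 2, stats::sd)
    params$norm_sd <- ifelse(sds > 0, sds, 1)
  }
  Y <- one_hot(y)
  opt <- adam_init(params$net)
  conv_opt <- if (spec$kind == "cnn") {
    list(t = 0, mK = 0 * params$K, vK = 0 * params$K,
         mb = numeric(spec$n_filters), vb = numeric(spec$n_filters))
  }
  losses <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    set.seed(.module_epoch_seed(seed, 3L, 1L, epoch))
    fwd <- .baseline_forward(params, X, training = TRUE)
    loss <- .weighted_ce_sum(fwd$logits, Y, rep(1, nrow(X)))
    if (spec$kind == "naive_bayes") {
      # standard-normal log-prior on the weights
      loss <- loss + sum(vapply(params$net$layers,
                                function(l) sum(l$W^2), 0)) /
        (2 * spec$prior_sd^2)
    }
    if (!is.finite(loss)) {
      stop(sprintf("baseline '%s' diverged at epoch %d", spec$kind, epoch))
    }
    losses[epoch] <- loss
    G <- ce_logit_grad(fwd$logits, Y)
    bk <- nn_backward(params$net, fwd$cache, G)
    grads <- bk$layers
    if (spec$kind == "naive_bayes") {
      for (i in seq_along(grads)) {
        grads[[i]]$dW <- grads[[i]]$dW +
          params$net$layers[[i]]$W / spec$prior_sd^2
      }
    }
    step <- adam_step(params$net, grads, opt, lr = lr)
    params$net <- step$net
    opt <- step$opt
    if (spec$kind == "cnn") {
      cgrads <- .conv1d_backward(fwd$conv_cache, bk$dX, params$K,
                                 spec$slope)
      conv_opt$t <- conv_opt$t + 1
      bc1 <- 1 - 0.9^conv_opt$t
      bc2 <- 1 - 0.999^conv_opt$t
      conv_opt$mK <- 0.9 * conv_opt$mK + 0.1 * cgrads$dK
      conv_opt$vK <- 0.999 * conv_opt$vK + 0.001 * cgrads$dK^2
      conv_opt$mb <- 0.9 * conv_opt$mb + 0.1 * cgrads$dbK
      conv_opt$vb <- 0.999 * conv_opt$vb + 0.001 * cgrads$dbK^2
      params$K <- params$K - lr * (conv_opt$mK / bc1) /
        (sqrt(conv_opt$vK / bc2) + 1e-8)
      params$bK <- params$bK - lr * (conv_opt$mb / bc1) /
        (sqrt(conv_opt$vb / bc2) + 1e-8)
    }
  }
  structure(list(params = params, spec = spec, loss = losses),
            class = "baseline_fit")
}

#' Predict from a fitted baseline
#' @param object A `baseline_fit`.
#' @param X Input matrix with the same feature columns used in
#'   training.
#' @param ... Unused.
#' @return A `prediction_matrix`.
#' @export
predict.baseline_fit <- function(object, X, ...) {
  fwd <- .baseline_forward(object$params, X, training = FALSE)
  prediction_matrix(fwd$logits, sample_ids = rownames(X))
}

# A model descriptor couples a fit function (cohort, train_ids, seed)
# with a predict function (fitted, ids) returning class and score.

#' Descriptor of the multi-omics GCN for the comparison harness
#' @param config A [train_config()].
#' @param tau,target_mean_degree Graph options.
#' @return A `model_descriptor` usable with [compare_models()].
#' @export
gcn_descriptor <- function(config = train_config(), tau = NULL,
                           target_mean_degree = 10) {
  structure(list(
    name = "gcn",
    fit = function(cohort, train_ids, seed) {
      cfg <- config
      cfg$seed <- seed
      gcn_fit(cohort, train_ids = train_ids, config = cfg, tau = tau,
              target_mean_degree = target_mean_degree)
    },
    predict = function(fitted, cohort, ids) {
      pred <- predict(fitted, ids = ids)
      list(class = pred$fused$class, score = pred$fused$prob[, 2])
    }), class = "model_descriptor")
}

#' Descriptor of a baseline classifier for the comparison harness
#' @param kind Baseline kind, see [build_baseline()].
#' @param epochs,lr Training settings.
#' @param ... Extra arguments passed to [build_baseline()].
#' @return A `model_descriptor` usable with [compare_models()].
#' @export
baseline_descriptor <- function(kind, epochs = 500, lr = 1e-3, ...) {
  extra <- list(...)
  structure(list(
    name = kind,
    fit = function(cohort, train_ids, seed) {
      X <- do.call(cbind, lapply(cohort$matrices, function(m) m$values))
      spec <- do.call(build_baseline,
                      c(list(kind = kind, input_dim = ncol(X)), extra))
      train_baseline(spec, X[train_ids, , drop = FALSE],
                     cohort$labels[train_ids], epochs = epochs, lr = lr,
                     seed = seed)
    },
    predict = function(fitted, cohort, ids) {
      X <- do.call(cbind, lapply(cohort$matrices, function(m) m$values))
      pred <- predict(fitted, X[ids, , drop = FALSE])
      list(class = pred$class, score = pred$prob[, 2])
    }), class = "model_descriptor")
}

#' Cross-validated pairwise model comparison
#'
#' Trains every model on identical stratified folds of the same cohort
#' and reports the mean and SD of all seven evaluation metrics across
#' folds. A failing (model, fold) evaluation is recorded as missing
#' with a warning rather than aborting the table.
#'
#' @param models Named list of `model_descriptor`s (at least 2), e.g.
#'   from [gcn_descriptor()] and [baseline_descriptor()].
#' @param cohort A `cohort`.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment and training seed.
#' @return A list of class `model_comparison`: `table` (long data frame
#'   with model, metric, mean, sd), `per_fold` (raw metric values), and
#'   `folds` (the shared assignments).
#' @export
compare_models <- function(models, cohort, k = 5, seed = 1) {
  if (length(models) < 2) stop("need at least 2 models to compare")
  ids <- names(cohort$labels)
  folds <- kfold_splits(ids, cohort$labels, k = k, seed = seed)
  metric_names <- c("sensitivity", "specificity", "accuracy", "precision",
                    "auc_roc", "macro_f1", "weighted_f1")
  per_fold <- list()
  for (mname in names(models)) {
    desc <- models[[mname]]
    vals <- matrix(NA_real_, k, length(metric_names),
                   dimnames = list(NULL, metric_names))
    for (f in seq_len(k)) {
      res <- tryCatch({
        train_ids <- ids[folds != f]
        eval_ids <- ids[folds == f]
        fitted <- desc$fit(cohort, train_ids, seed)
        pred <- desc$predict(fitted, cohort, eval_ids)
        rep <- suppressWarnings(
          evaluate_predictions(cohort$labels[eval_ids], pred$class,
                               pred$score))
        rep$metrics
      }, error = function(e) {
        warning(sprintf("model '%s' failed on fold %d: %s", mname, f,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(res)) vals[f, ] <- res[metric_names]
    }
    per_fold[[mname]] <- vals
  }
  table <- do.call(rbind, lapply(names(per_fold), function(mname) {
    vals <- per_fold[[mname]]
    data.frame(model = mname, metric = metric_names,
               mean = colMeans(vals, na.rm = TRUE),
               sd = apply(vals, 2, stats::sd, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(table = table, per_fold = per_fold, folds = folds),
            class = "model_comparison")
}

#' Write a model comparison as TSV and JSON
#' @param comparison A `model_comparison`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "comparison.tsv")
  json <- file.path(dir, "comparison.json")
  utils::write.table(comparison$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(table = comparison$table,
         per_fold = lapply(comparison$per_fold, as.data.frame)),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}
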
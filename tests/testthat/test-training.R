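# pretrain()/finetune() are the lower-level API and expect prepared
# (normalized) features; gcn_fit() does this internally for users
standardized <- function(cohort) {
  cohort$matrices <- lapply(cohort$matrices, function(m) {
    V <- m$values
    if (m$omics_kind == "expression") V <- log1p(V)
    V <- scale(V)
    attr(V, "scaled:center") <- attr(V, "scaled:scale") <- NULL
    structure(list(values = V, omics_kind = m$omics_kind),
              class = "omics_matrix")
  })
  cohort
}

small_specs <- function(cohort, hidden = 16, fc = 8) {
  lapply(cohort$matrices, function(m) {
    gcn_model_spec(ncol(m$values), hidden_units = hidden, fc_dim = fc)
  })
}

build_graphs <- function(cohort, tau = NULL, degree = 8) {
  lapply(cohort$matrices, build_similarity_graph, tau = tau,
         target_mean_degree = degree)
}

test_that("cross-entropy has its closed-form values and clamps", {
  expect_equal(cross_entropy(c(0, 1), c(0, 1)), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-8)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), 0.69314718,
               tolerance = 1e-7)
  # fully wrong prediction is finite thanks to the clamp
  v <- cross_entropy(c(1, 0), c(0, 1))
  expect_true(is.finite(v))
  expect_equal(v, -log(1e-12), tolerance = 1e-6)
  expect_error(cross_entropy(c(1, 0), c(0.9, 0.4)), "normalized")
})

test_that("module loss is the summed per-sample cross-entropy", {
  Y <- one_hot(c(1, 0))
  perfect <- rbind(c(0, 1), c(1, 0))
  expect_equal(module_loss(Y, perfect), 0, tolerance = 1e-9)
  uniform <- matrix(0.5, 2, 2)
  expect_equal(module_loss(Y, uniform), 2 * log(2), tolerance = 1e-9)
  set.seed(8)
  P <- matrix(runif(10), 5, 2)
  P <- P / rowSums(P)
  y <- c(1, 0, 1, 1, 0)
  loop <- sum(vapply(1:5, function(k) {
    cross_entropy(one_hot(y)[k, ], P[k, ])
  }, 0))
  expect_equal(module_loss(one_hot(y), P), loop, tolerance = 1e-10)
  expect_error(module_loss(one_hot(c(1, 0)), P), "labels")
})

test_that("total loss combines components linearly", {
  expect_equal(total_loss(c(0, 0), 0), 0)
  expect_equal(total_loss(c(1, 2), 3, alphas = c(1, 1), lambda_f = 1), 6)
  expect_equal(total_loss(c(1, 2), 3, lambda_f = 0), 3)
  expect_error(total_loss(c(1, 2), 3, alphas = 1), "lengths differ")
  set.seed(2)
  ml <- runif(2); fl <- runif(1); al <- runif(2); la <- runif(1)
  expect_equal(total_loss(2 * ml, fl, al, la),
               2 * total_loss(ml, fl, al, la) - la * fl, tolerance = 1e-12)
  expect_equal(total_loss(ml, 2 * fl, al, la),
               total_loss(ml, fl, al, la) + la * fl, tolerance = 1e-12)
})

test_that("smoothing clips outliers and counts neighbor labels", {
  set.seed(11)
  v <- c(rnorm(19), 10)
  X <- omics_matrix(matrix(v, 20, 1,
                           dimnames = list(sprintf("s%02d", 1:20), "g1")),
                    omics_kind = "expression")
  g <- build_similarity_graph(X, tau = 0)
  labels <- rep(c(0L, 1L), 10)
  sw_inf <- smooth_sample_weights(X, g, labels, clip_sd = Inf)
  expect_identical(sw_inf$X$values, X$values)
  sw <- smooth_sample_weights(X, g, labels, clip_sd = 3)
  expect_equal(unname(sw$X$values[20, 1]), mean(v) + 3 * sd(v),
               tolerance = 1e-12)
  # hand-built 4-node graph: node 1 sees labels {1, 1, 0}
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 0.9
  g2 <- structure(list(S = A, A = A, tau = 0,
                       Ahat = normalize_adjacency(A)),
                  class = "similarity_graph")
  X2 <- omics_matrix(matrix(rnorm(8), 4, 2,
                            dimnames = list(paste0("s", 1:4),
                                            c("g1", "g2"))),
                     omics_kind = "expression")
  sw2 <- smooth_sample_weights(X2, g2, c(0L, 1L, 1L, 0L), clip_sd = Inf)
  expect_equal(unname(sw2$affinity[1, ]), c(1 / 3, 2 / 3))
  # isolated node: uniform affinity
  A0 <- matrix(0, 3, 3)
  g0 <- structure(list(S = A0, A = A0, tau = 2,
                       Ahat = normalize_adjacency(A0)),
                  class = "similarity_graph")
  X3 <- omics_matrix(matrix(rnorm(6), 3, 2,
                            dimnames = list(paste0("s", 1:3),
                                            c("g1", "g2"))),
                     omics_kind = "expression")
  sw3 <- smooth_sample_weights(X3, g0, c(0L, 1L, 1L), clip_sd = Inf)
  expect_true(all(sw3$affinity == 0.5))
})

test_that("stratified splitting hits the 55/15/30 targets exactly on n = 100", {
  labels <- label_vector(rep(c(1, 0), 50), sprintf("s%03d", 1:100))
  sp <- split_dataset(labels, seed = 3)
  expect_length(sp$train, 55)
  expect_length(sp$validation, 15)
  expect_length(sp$test, 30)
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all_ids, names(labels))
  expect_equal(anyDuplicated(all_ids), 0)
  # stratification: class shares within one sample of proportional
  for (part in list(sp$train, sp$validation, sp$test)) {
    n1 <- sum(labels[part] == 1)
    expect_lte(abs(n1 - length(part) / 2), 1)
  }
})

test_that("splits are deterministic per seed and vary across seeds", {
  labels <- label_vector(rep(c(1, 0), 30), sprintf("s%03d", 1:60))
  a <- split_dataset(labels, seed = 7)
  b <- split_dataset(labels, seed = 7)
  expect_identical(a[c("train", "validation", "test")],
                   b[c("train", "validation", "test")])
  differing <- vapply(2:21, function(s) {
    !identical(sort(split_dataset(labels, seed = s)$train), sort(a$train))
  }, TRUE)
  expect_gte(mean(differing), 0.9)
  few <- label_vector(c(1, 1, 0, 0, 0), paste0("s", 1:5))
  expect_error(split_dataset(few), "fewer than 3")
})

test_that("k-fold assignments partition with balanced sizes and classes", {
  labels <- label_vector(rep(c(1, 0), 5), paste0("s", 1:10))
  f <- kfold_splits(names(labels), labels, k = 5, seed = 2)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_setequal(names(f), names(labels))
  labels2 <- label_vector(c(rep(1, 13), rep(0, 9)), paste0("s", 1:22))
  f2 <- kfold_splits(names(labels2), labels2, k = 5, seed = 4)
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1)
  for (k in 1:5) {
    n1 <- sum(labels2[names(f2)[f2 == k]] == 1)
    expect_lte(abs(n1 - 13 / 5), 1)
  }
  expect_error(kfold_splits(paste0("s", 1:3), labels, k = 5), "exceeds")
})

test_that("zero-epoch pretraining returns the Xavier initialization", {
  co <- tiny_cohort(24)
  graphs <- build_graphs(co)
  specs <- small_specs(co)
  model <- gcn_model_init(specs, seed = 31)
  cfg <- train_config(pretrain_epochs = 0, finetune_epochs = 0, seed = 31)
  out <- pretrain(model, co, graphs, cfg)
  for (l in 1:2) {
    fresh <- gcn_init(specs[[l]], seed = 31 + l)
    for (i in seq_along(fresh$layers)) {
      expect_identical(out$modules[[l]]$layers[[i]]$W,
                       fresh$layers[[i]]$W)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  co <- tiny_cohort(24)
  cfg <- train_config(pretrain_epochs = 25, finetune_epochs = 25,
                      seed = 17)
  f1 <- gcn_fit(co, config = cfg)
  f2 <- gcn_fit(co, config = cfg)
  expect_identical(f1$model$modules, f2$model$modules)
  expect_identical(f1$model$head, f2$model$head)
  p1 <- predict(f1)
  p2 <- predict(f2)
  expect_identical(p1$fused$logits, p2$fused$logits)
})

test_that("pretraining alone separates the toy cohort", {
  for (seed in 1:5) {
    co <- standardized(tiny_cohort(60, seed = seed))
    graphs <- build_graphs(co, degree = 5)
    model <- gcn_model_init(small_specs(co), seed = seed)
    cfg <- train_config(pretrain_epochs = 500, finetune_epochs = 0,
                        seed = seed)
    model <- pretrain(model, co, graphs, cfg)
    for (l in 1:2) {
      out <- gcn_module_forward(
        structure(list(values = model$X_adjusted[[l]],
                       omics_kind = "expression"),
                  class = "omics_matrix"),
        graphs[[l]], model$modules[[l]])
      acc <- mean(out$class == as.integer(co$labels))
      expect_gte(acc, 0.95)
    }
  }
})

test_that("zero-epoch fine-tuning leaves the pretrained model untouched", {
  co <- tiny_cohort(24)
  graphs <- build_graphs(co)
  model <- gcn_model_init(small_specs(co), seed = 5)
  cfg <- train_config(pretrain_epochs = 10, finetune_epochs = 0,
                      lambda_f = 0, seed = 5)
  pre <- pretrain(model, co, graphs, cfg)
  post <- finetune(pre, co, graphs, cfg)
  expect_identical(post$modules, pre$modules)
  expect_identical(post$head, pre$head)
})

test_that("with lambda = 0 the fusion head does not influence module training", {
  co <- tiny_cohort(24)
  graphs <- build_graphs(co)
  cfg <- train_config(pretrain_epochs = 10, finetune_epochs = 15,
                      lambda_f = 0, seed = 9)
  m1 <- gcn_model_init(small_specs(co), seed = 9)
  m2 <- gcn_model_init(small_specs(co), seed = 9)
  m2$head <- fusion_head_init(4, seed = 999)    # different head init
  f1 <- finetune(pretrain(m1, co, graphs, cfg), co, graphs, cfg)
  f2 <- finetune(pretrain(m2, co, graphs, cfg), co, graphs, cfg)
  expect_identical(f1$modules, f2$modules)
  expect_false(identical(f1$head, f2$head))
})

test_that("fine-tuning does not catastrophically degrade the pretrained toy fit", {
  co <- tiny_cohort(40, seed = 3)
  sp <- split_dataset(co$labels, seed = 3)
  cfg_pre <- train_config(pretrain_epochs = 150, finetune_epochs = 0,
                          seed = 3)
  cfg_full <- train_config(pretrain_epochs = 150, finetune_epochs = 150,
                           seed = 3)
  fit_pre <- gcn_fit(co, train_ids = sp$train, config = cfg_pre)
  fit_full <- gcn_fit(co, train_ids = sp$train, config = cfg_full)
  eval_ids <- sp$validation
  f1_mod <- mean(vapply(1:2, function(l) {
    pred <- predict(fit_pre, ids = eval_ids)$per_module[[l]]
    macro_f1(confusion(co$labels[eval_ids], pred$class))
  }, 0))
  pred_full <- predict(fit_full, ids = eval_ids)$fused
  f1_full <- macro_f1(confusion(co$labels[eval_ids], pred_full$class))
  expect_gte(f1_full, f1_mod - 0.05)
})

test_that("learning-rate search returns single points and breaks ties downward", {
  co <- tiny_cohort(24)
  cfg0 <- train_config(pretrain_epochs = 0, finetune_epochs = 0, seed = 2)
  single <- data.frame(lr_pretrain = 1e-4, lr_train = 1e-4,
                       lr_terminal = 1e-4)
  res <- grid_search_learning_rates(co, names(co$labels), single,
                                    config = cfg0, k = 2, seed = 2)
  expect_equal(res$best$lr_train, 1e-4)
  # zero-epoch training scores identically, so the tie rule decides
  tied <- data.frame(lr_pretrain = c(1e-4, 1e-4),
                     lr_train = c(5e-4, 1e-4),
                     lr_terminal = c(1e-4, 1e-4))
  res2 <- grid_search_learning_rates(co, names(co$labels), tied,
                                     config = cfg0, k = 2, seed = 2)
  expect_equal(res2$scores$mean_macro_f1[1], res2$scores$mean_macro_f1[2])
  expect_equal(res2$best$lr_train, 1e-4)
  expect_error(grid_search_learning_rates(co, names(co$labels),
                                          data.frame(), config = cfg0),
               "empty")
})

test_that("a learning rate that converges beats one that cannot", {
  co <- tiny_cohort(30, seed = 6)
  cfg <- train_config(pretrain_epochs = 60, finetune_epochs = 30, seed = 6)
  grid <- data.frame(lr_pretrain = c(1e-7, 5e-3),
                     lr_train = c(1e-7, 5e-3),
                     lr_terminal = c(1e-7, 5e-3))
  res <- grid_search_learning_rates(co, names(co$labels), grid,
                                    config = cfg, k = 2, seed = 6)
  expect_equal(res$best$lr_train, 5e-3)
})

test_that("the learning-rate grid has the documented search space", {
  g <- lr_grid("diagonal")
  expect_equal(nrow(g), 10)
  expect_equal(g$lr_pretrain,
               c(1e-7, 5e-7, 1e-6, 5e-6, 1e-5, 5e-5, 1e-4, 5e-4, 1e-3,
                 5e-3))
  full <- lr_grid("full")
  expect_equal(nrow(full), 1000)
  sub <- lr_grid("full", subsample = 10, seed = 1)
  expect_equal(nrow(sub), 10)
})
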
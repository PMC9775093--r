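test_that("generated cohorts honor the shape contract and determinism", {
  spec <- synthetic_spec(n_cancer = 10, n_control = 10,
                         p_expression = 20, p_methylation = 30,
                         n_informative = c(3, 4), seed = 5)
  co <- generate_cohort(spec)
  expect_identical(dim(co$expression), c(20L, 20L))
  expect_identical(dim(co$methylation), c(20L, 30L))
  expect_length(co$labels, 20)
  expect_equal(sum(co$labels == 1), 10)
  expect_length(co$manifest$informative_expression, 3)
  co2 <- generate_cohort(spec)
  expect_identical(co$expression$values, co2$expression$values)
  expect_identical(co$methylation$values, co2$methylation$values)
  expect_identical(as.data.frame(co$variants), as.data.frame(co2$variants))
})

test_that("invalid specifications fail before generation", {
  expect_error(synthetic_spec(n_informative = c(30, 5), p_expression = 20),
               "informative")
  expect_error(synthetic_spec(driver_mutation_rate_cancer = 1.5), "rates")
  expect_error(synthetic_spec(effect_size = -1))
})

test_that("methylation values always stay inside the unit interval", {
  for (seed in 1:3) {
    co <- generate_cohort(synthetic_spec(n_cancer = 30, n_control = 30,
                                         p_methylation = 50,
                                         p_expression = 10,
                                         n_informative = c(2, 5),
                                         seed = seed))
    M <- co$methylation$values
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("informative expression shifts match the requested effect size", {
  spec <- synthetic_spec(n_cancer = 500, n_control = 500,
                         p_expression = 30, p_methylation = 10,
                         n_informative = c(4, 2), effect_size = 1.5,
                         block_correlation = 0, seed = 2)
  co <- generate_cohort(spec)
  Z <- log(co$expression$values)
  y <- as.integer(co$labels)
  dirs <- co$manifest$expression_direction
  expected <- spec$effect_size * spec$sdlog
  ratios <- vapply(co$manifest$informative_expression, function(f) {
    shift <- mean(Z[y == 1, f]) - mean(Z[y == 0, f])
    sign(dirs[[f]]) * shift / expected
  }, 0)
  expect_true(all(ratios > 0))               # shifts point the right way
  expect_lt(abs(mean(ratios) - 1), 0.1)      # mean magnitude within 10%
})

test_that("block correlation materializes at the requested level", {
  spec <- synthetic_spec(n_cancer = 300, n_control = 300,
                         p_expression = 20, p_methylation = 10,
                         n_informative = c(0, 0),
                         block_correlation = 0.4, seed = 3)
  co <- generate_cohort(spec)
  Z <- log(co$expression$values)
  within <- cor(Z[, 1:10])[upper.tri(diag(10))]
  expect_equal(mean(within), 0.4, tolerance = 0.1)
  across <- cor(Z[, 1:10], Z[, 11:20])
  expect_lt(abs(mean(across)), 0.1)
})

test_that("driver alterations are enriched in the cancer class", {
  co <- generate_cohort(synthetic_spec(n_cancer = 200, n_control = 200,
                                       p_expression = 10,
                                       p_methylation = 10,
                                       n_informative = c(2, 2),
                                       n_driver_genes = 8, seed = 4))
  y <- unclass(co$labels)
  hits <- table(factor(y[co$variants$sample_id], levels = c(0, 1)))
  expect_gt(hits[["1"]], 5 * hits[["0"]])
  expect_true(all(co$variants$alteration %in%
                    c("SNV", "indel", "fusion", "rearrangement")))
})

test_that("null cohorts carry no recoverable signal for a held-out classifier", {
  aucs <- vapply(1:5, function(seed) {
    co <- generate_cohort(synthetic_spec(n_cancer = 60, n_control = 60,
                                         p_expression = 20,
                                         p_methylation = 30,
                                         effect_size = 0, seed = seed))
    ids <- names(co$labels)
    X <- cbind(log(co$expression$values), co$methylation$values)
    set.seed(seed)
    tr <- sample(ids, 80)
    te <- setdiff(ids, tr)
    spec <- build_baseline("logistic_regression", input_dim = ncol(X))
    fit <- train_baseline(spec, X[tr, ], co$labels[tr], epochs = 150,
                          seed = seed)
    pred <- predict(fit, X[te, ])
    auc_roc(co$labels[te], pred$prob[, 2])
  }, 0)
  expect_true(all(aucs > 0.2 & aucs < 0.8))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("the separable toy is balanced with powerful informative features", {
  toy <- generate_separable_toy(60, seed = 2)
  expect_equal(sum(toy$labels == 1), 30)
  st <- feature_stats(toy$expression, toy$labels)
  inf_p <- st$p_value[st$feature_id %in%
                        toy$manifest$informative_expression]
  expect_true(all(inf_p < 1e-4))
  expect_error(generate_separable_toy(31), "even")
  expect_error(generate_separable_toy(10), "at least 20")
})

test_that("null feature p-values are uniform at the 5% level", {
  co <- generate_cohort(synthetic_spec(n_cancer = 30, n_control = 30,
                                       p_expression = 202,
                                       p_methylation = 10,
                                       n_informative = c(2, 2),
                                       effect_size = 3,
                                       block_correlation = 0, seed = 6))
  st <- feature_stats(co$expression, co$labels)
  null_p <- st$p_value[!st$feature_id %in%
                         co$manifest$informative_expression]
  expect_length(null_p, 200)
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.03)
})

test_that("cohorts round-trip through the on-disk TSV formats", {
  co <- generate_cohort(synthetic_spec(n_cancer = 6, n_control = 6,
                                       p_expression = 5, p_methylation = 5,
                                       n_informative = c(1, 1), seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back_e <- read_omics_matrix(file.path(dir, "expression.tsv"),
                              "expression")
  back_m <- read_omics_matrix(file.path(dir, "methylation.tsv"),
                              "methylation")
  expect_equal(back_e$values, co$expression$values, tolerance = 1e-12)
  expect_equal(back_m$values, co$methylation$values, tolerance = 1e-12)
  expect_identical(unclass(read_labels(file.path(dir, "labels.tsv"))),
                   unclass(co$labels))
})
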
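#' Specification of a synthetic multi-omics cohort
#'
#' Describes a two-block cohort emulating the structure of a paired
#' expression + methylation NSCLC study: log-normal expression values
#' with class-conditional mean shifts on a minority of informative
#' features and equicorrelated feature blocks; beta-distributed
#' methylation values with alternating hyper-/hypomethylation shifts;
#' and sparse driver-gene alterations enriched in the cancer class.
#'
#' @param n_cancer,n_control Per-class sample counts.
#' @param p_expression,p_methylation Features per omics block (defaults
#'   200 and 300, the post-selection dimensions of the reference
#'   protocol).
#' @param n_informative Length-2 vector: informative features per block
#'   (defaults 20 and 30).
#' @param effect_size Class mean shift of informative features, in
#'   within-class SD units: applied on the log scale for expression and
#'   to the beta mean for methylation (default 1.5).
#' @param block_correlation Equicorrelation of expression features
#'   within a block of 10 (default 0.3).
#' @param n_driver_genes Number of driver genes in the variant table.
#' @param driver_mutation_rate_cancer,driver_mutation_rate_control
#'   Per-(sample, gene) alteration probabilities by class.
#' @param sdlog Within-class SD of log-expression (default 0.5).
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cancer = 150, n_control = 150,
                           p_expression = 200, p_methylation = 300,
                           n_informative = c(20, 30), effect_size = 1.5,
                           block_correlation = 0.3, n_driver_genes = 10,
                           driver_mutation_rate_cancer = 0.3,
                           driver_mutation_rate_control = 0.02,
                           sdlog = 0.5, seed = 1) {
  stopifnot(n_cancer >= 1, n_control >= 1,
            p_expression >= 1, p_methylation >= 1,
            length(n_informative) == 2,
            effect_size >= 0, sdlog > 0,
            block_correlation >= 0, block_correlation < 1,
            n_driver_genes >= 0)
  if (n_informative[1] > p_expression || n_informative[2] > p_methylation) {
    stop("more informative features requested than features in a block")
  }
  rates <- c(driver_mutation_rate_cancer, driver_mutation_rate_control)
  if (any(rates < 0 | rates > 1)) {
    stop("driver mutation rates must lie in [0, 1]")
  }
  structure(list(n_cancer = as.integer(n_cancer),
                 n_control = as.integer(n_control),
                 p_expression = as.integer(p_expression),
                 p_methylation = as.integer(p_methylation),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 block_correlation = block_correlation,
                 n_driver_genes = as.integer(n_driver_genes),
                 driver_mutation_rate_cancer = driver_mutation_rate_cancer,
                 driver_mutation_rate_control = driver_mutation_rate_control,
                 sdlog = sdlog, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.driver_gene_names <- function(k) {
  known <- c("EGFR", "KRAS", "ALK", "BRAF", "ROS1", "RET", "MET",
             "NTRK1", "TP53", "STK11")
  if (k <= length(known)) return(known[seq_len(k)])
  c(known, sprintf("DRV%02d", seq_len(k - length(known))))
}

.fusion_genes <- c("ALK", "ROS1", "RET", "NTRK1")

#' Generate a synthetic paired multi-omics cohort
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression` and `methylation` [omics_matrix]
#'   blocks, `variants` ([variant_table]), `labels` ([label_vector]) and
#'   `manifest` (ground truth: informative feature IDs, shift
#'   directions, and the generating parameters).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cancer + spec$n_control
  ids <- sprintf("S%04d", seq_len(n))
  y <- c(rep(1L, spec$n_cancer), rep(0L, spec$n_control))
  labels <- label_vector(y, ids)

  # --- expression: log-normal with equicorrelated blocks of 10 ---
  p <- spec$p_expression
  expr_ids <- sprintf("gene%04d", seq_len(p))
  inf_e <- seq_len(spec$n_informative[1])
  dir_e <- rep_len(c(1, -1), length(inf_e))        # up/down alternation
  mu <- stats::rnorm(p, mean = 2, sd = 0.5)
  block <- (seq_len(p) - 1) %/% 10 + 1
  rho <- spec$block_correlation
  B <- matrix(stats::rnorm(n * max(block)), n, max(block))
  E <- matrix(stats::rnorm(n * p), n, p)
  Z <- sqrt(rho) * B[, block, drop = FALSE] + sqrt(1 - rho) * E
  Z <- spec$sdlog * Z + matrix(mu, n, p, byrow = TRUE)
  if (length(inf_e) > 0 && spec$effect_size > 0) {
    shift <- matrix(0, n, p)
    shift[y == 1L, inf_e] <- matrix(dir_e * spec$effect_size * spec$sdlog,
                                    spec$n_cancer, length(inf_e),
                                    byrow = TRUE)
    Z <- Z + shift
  }
  expression <- omics_matrix(exp(Z), ids, expr_ids, "expression")

  # --- methylation: beta values, informative CpGs mean-shifted ---
  q <- spec$p_methylation
  meth_ids <- sprintf("cg%07d", seq_len(q))
  inf_m <- seq_len(spec$n_informative[2])
  dir_m <- rep_len(c(1, -1), length(inf_m))        # hyper/hypo alternation
  conc <- 10
  base_mean <- stats::runif(q, 0.1, 0.9)
  # keep informative base means central so the shifted mean stays inside
  # (0.05, 0.95) without clamping away the group difference
  base_mean[inf_m] <- stats::runif(length(inf_m), 0.3, 0.7)
  sd_beta <- sqrt(base_mean * (1 - base_mean) / (conc + 1))
  mean_cancer <- base_mean
  if (length(inf_m) > 0 && spec$effect_size > 0) {
    mean_cancer[inf_m] <- pmin(pmax(
      base_mean[inf_m] + dir_m * spec$effect_size * sd_beta[inf_m],
      0.05), 0.95)
  }
  M <- matrix(0, n, q)
  for (cl in c(1L, 0L)) {
    rows <- which(y == cl)
    m_f <- if (cl == 1L) mean_cancer else base_mean
    M[rows, ] <- stats::rbeta(length(rows) * q,
                              shape1 = rep(m_f * conc, each = length(rows)),
                              shape2 = rep((1 - m_f) * conc,
                                           each = length(rows)))
  }
  methylation <- omics_matrix(M, ids, meth_ids, "methylation")

  # --- sparse driver alterations, enriched in the cancer class ---
  genes <- .driver_gene_names(spec$n_driver_genes)
  var_rows <- list()
  for (g in genes) {
    rate <- ifelse(y == 1L, spec$driver_mutation_rate_cancer,
                   spec$driver_mutation_rate_control)
    hit <- stats::rbinom(n, 1, rate) == 1
    if (!any(hit)) next
    alt_pool <- if (g %in% .fusion_genes) {
      c("fusion", "rearrangement")
    } else {
      c("SNV", "indel")
    }
    var_rows[[g]] <- data.frame(
      sample_id = ids[hit], gene = g,
      alteration = sample(alt_pool, sum(hit), replace = TRUE,
                          prob = if (length(alt_pool) == 2) c(0.8, 0.2)),
      detail = "synthetic", stringsAsFactors = FALSE)
  }
  var_df <- if (length(var_rows) > 0) do.call(rbind, var_rows) else
    data.frame(sample_id = character(), gene = character(),
               alteration = character(), detail = character())
  variants <- variant_table(var_df$sample_id, var_df$gene,
                            var_df$alteration, var_df$detail)

  manifest <- list(
    informative_expression = expr_ids[inf_e],
    expression_direction = stats::setNames(dir_e, expr_ids[inf_e]),
    informative_methylation = meth_ids[inf_m],
    methylation_direction = stats::setNames(dir_m, meth_ids[inf_m]),
    spec = unclass(spec))
  list(expression = expression, methylation = methylation,
       variants = variants, labels = labels, manifest = manifest)
}

#' Minimal near-separable two-omics toy cohort
#'
#' Balanced cohort with 10 features per omics block, 2 of them
#' informative at effect size 3 (near-perfect class separation); used
#' by convergence tests of the training loop and baselines.
#'
#' @param n Total (even) sample count, at least 20.
#' @param seed Integer seed.
#' @return Same structure as [generate_cohort()].
#' @export
generate_separable_toy <- function(n = 60, seed = 1) {
  if (n %% 2 != 0) stop("'n' must be even")
  if (n < 20) stop("'n' must be at least 20")
  generate_cohort(synthetic_spec(
    n_cancer = n / 2, n_control = n / 2,
    p_expression = 10, p_methylation = 10,
    n_informative = c(2, 2), effect_size = 3,
    block_correlation = 0, n_driver_genes = 4,
    seed = seed))
}

#' Write a synthetic cohort to a directory in the standard formats
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  utils::write.table(as.data.frame(cohort$variants),
                     file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
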
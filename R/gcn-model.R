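#' Architecture specification for one per-omics GCN module
#'
#' A module stacks graph-convolution layers (input dimension to
#' `hidden_units`, then hidden to hidden) followed by two fully
#' connected layers (`hidden_units` to `fc_dim` to 2). LeakyReLU with a
#' 0.25 negative slope separates layers; neighbor contributions enter
#' through the normalized adjacency as a weighted sum.
#'
#' @param n_input_features Number of input features p for this omics
#'   block.
#' @param hidden_units Width of the graph-convolution layers
#'   (default 400).
#' @param fc_dim Width of the penultimate fully connected layer
#'   (default 200).
#' @param n_gconv_layers Number of graph-convolution layers, 1 to 3
#'   (default 2).
#' @param leaky_slope Negative-axis slope of the LeakyReLU
#'   (default 0.25).
#' @param dropout_rate Dropout rate on fully connected layer inputs
#'   during training (default 0.5).
#' @return A list of class `gcn_model_spec`.
#' @export
gcn_model_spec <- function(n_input_features, hidden_units = 400,
                           fc_dim = 200, n_gconv_layers = 2,
                           leaky_slope = 0.25, dropout_rate = 0.5) {
  stopifnot(n_input_features >= 1, hidden_units >= 1, fc_dim >= 1,
            n_gconv_layers %in% 1:3,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_input_features = as.integer(n_input_features),
                 hidden_units = as.integer(hidden_units),
                 fc_dim = as.integer(fc_dim),
                 n_gconv_layers = as.integer(n_gconv_layers),
                 leaky_slope = leaky_slope,
                 dropout_rate = dropout_rate,
                 n_classes = 2L),
            class = "gcn_model_spec")
}

#' Xavier-initialized parameters for a GCN module
#'
#' @param spec A [gcn_model_spec].
#' @param seed Integer seed for the Xavier draws.
#' @return A parameter set (`gcn_params`): the layer list consumed by
#'   the forward/backward passes.
#' @export
gcn_init <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "gcn_model_spec"))
  set.seed(seed)
  dims <- c(spec$n_input_features,
            rep(spec$hidden_units, spec$n_gconv_layers),
            spec$fc_dim, spec$n_classes)
  types <- c(rep("gconv", spec$n_gconv_layers), "dense", "dense")
  net <- nn_init(dims, types, slope = spec$leaky_slope,
                 dropout_rate = spec$dropout_rate)
  net$spec <- spec
  class(net) <- "gcn_params"
  net
}

#' Single graph-convolution layer forward pass
#'
#' Propagates node features one hop through the normalized adjacency:
#' sigma(Ahat H W) with sigma = LeakyReLU.
#'
#' @param H n x d_in input activations.
#' @param Ahat n x n normalized adjacency (see [normalize_adjacency()]).
#' @param W d_in x d_out weight matrix.
#' @param slope LeakyReLU negative slope (default 0.25).
#' @return n x d_out activations.
#' @export
gcn_layer_forward <- function(H, Ahat, W, slope = 0.25) {
  if (ncol(Ahat) != nrow(H)) {
    stop(sprintf("adjacency is %dx%d but H has %d rows",
                 nrow(Ahat), ncol(Ahat), nrow(H)))
  }
  if (ncol(H) != nrow(W)) {
    stop(sprintf("H has %d columns but W expects %d inputs",
                 ncol(H), nrow(W)))
  }
  leaky_relu(Ahat %*% (H %*% W), slope)
}

#' Forward pass of one per-omics GCN module
#'
#' Runs the graph-convolution stack and the fully connected layers,
#' producing 2-class logits for every sample in the graph. Dropout is
#' active only when `training = TRUE` (inference is deterministic).
#'
#' @param X An [omics_matrix] or numeric matrix aligned with the graph.
#' @param graph A `similarity_graph` built on the same samples.
#' @param params A `gcn_params` object from [gcn_init()].
#' @param training Enable dropout.
#' @return A `prediction_matrix`: list with `logits` (n x 2) and `prob`
#'   (row-wise softmax).
#' @export
gcn_module_forward <- function(X, graph, params, training = FALSE) {
  V <- if (inherits(X, "omics_matrix")) X$values else X
  if (nrow(V) != nrow(graph$Ahat)) {
    stop(sprintf("%d samples in X but %d nodes in graph",
                 nrow(V), nrow(graph$Ahat)))
  }
  out <- nn_forward(params, V, Ahat = graph$Ahat, training = training)
  prediction_matrix(out$logits, sample_ids = rownames(V))
}

#' Wrap logits as a prediction matrix
#' @param logits n x 2 matrix of class scores.
#' @param sample_ids Optional sample identifiers.
#' @return A `prediction_matrix` with `logits`, `prob` and `class`
#'   (argmax label in \{0, 1\}).
#' @export
prediction_matrix <- function(logits, sample_ids = NULL) {
  logits <- as.matrix(logits)
  stopifnot(ncol(logits) == 2)
  prob <- softmax(logits)
  rownames(logits) <- rownames(prob) <- sample_ids
  structure(list(logits = logits, prob = prob,
                 class = as.integer(prob[, 2] > prob[, 1])),
            class = "prediction_matrix")
}

#' Initialize the terminal fusion ("Mutation FC") head
#'
#' The head consumes the concatenated per-omics score rows (2 + 2
#' values per sample by default) and maps them to the final 2-class
#' logits through one affine layer.
#'
#' @param n_inputs Input width (default 4: two 2-class score rows).
#' @param seed Integer seed for Xavier initialization.
#' @return A `fusion_head` (weight matrix `W`, bias `b`).
#' @export
fusion_head_init <- function(n_inputs = 4, seed = 1) {
  set.seed(seed)
  structure(list(W = xavier_matrix(n_inputs, 2), b = numeric(2)),
            class = "fusion_head")
}

#' Fuse two per-omics predictions through the terminal head
#'
#' Concatenates the two per-sample score vectors and applies the
#' terminal fully connected layer, yielding the final 2-class logits.
#'
#' @param y1,y2 `prediction_matrix` objects (or n x 2 logit matrices)
#'   covering identical samples in identical order.
#' @param head A `fusion_head`.
#' @return A `prediction_matrix` of fused logits.
#' @export
fuse_predictions <- function(y1, y2, head) {
  L1 <- if (inherits(y1, "prediction_matrix")) y1$logits else as.matrix(y1)
  L2 <- if (inherits(y2, "prediction_matrix")) y2$logits else as.matrix(y2)
  if (nrow(L1) != nrow(L2)) stop("inputs cover different sample counts")
  if (!is.null(rownames(L1)) && !is.null(rownames(L2)) &&
      !identical(rownames(L1), rownames(L2))) {
    stop("sample order differs between the two omics predictions")
  }
  H <- cbind(L1, L2)
  Z <- sweep(H %*% head$W, 2, head$b, "+")
  prediction_matrix(Z, sample_ids = rownames(L1))
}

#' Annotate samples with matching anti-cancer agents
#'
#' Rule-based lookup: a sample is annotated with every agent whose
#' (gene, alteration pattern) rule matches at least one of the sample's
#' variant records. The pattern is a regular expression matched against
#' the whole alteration type. Annotation is attached to reports only
#' and never feeds back into the classifier.
#'
#' @param variants A [variant_table].
#' @param rules A [therapy_rule_table] (may be empty);
#'   [default_therapy_rules()] gives a starting point.
#' @param sample_ids Optional cohort sample IDs so that unmutated
#'   samples appear with empty annotations.
#' @return Named list mapping each sample to a sorted character vector
#'   of agents (possibly empty).
#' @export
match_therapy <- function(variants, rules, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  out <- stats::setNames(
    replicate(length(sample_ids), character(0), simplify = FALSE),
    sample_ids)
  if (nrow(variants) == 0 || nrow(rules) == 0) return(out)
  for (r in seq_len(nrow(rules))) {
    hit <- variants$gene == rules$gene[r] &
      grepl(paste0("^(", rules$alteration_pattern[r], ")$"),
            variants$alteration)
    for (s in unique(variants$sample_id[hit])) {
      if (s %in% names(out)) {
        out[[s]] <- sort(unique(c(out[[s]], rules$agent[r])))
      }
    }
  }
  out
}
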
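#' Cosine similarity between all sample pairs
#'
#' @param X An [omics_matrix] or plain numeric matrix (samples in rows).
#' @return Symmetric n x n matrix with entries in \[-1, 1\] and unit
#'   diagonal.
#' @export
cosine_similarity_matrix <- function(X) {
  V <- if (inherits(X, "omics_matrix")) X$values else X
  norms <- sqrt(rowSums(V^2))
  zero <- which(norms == 0)
  if (length(zero) > 0) {
    id <- if (!is.null(rownames(V))) rownames(V)[zero[1]] else zero[1]
    stop(sprintf("sample '%s' has zero norm; cosine similarity undefined", id))
  }
  Vn <- V / norms
  S <- tcrossprod(Vn)
  S <- (S + t(S)) / 2          # kill asymmetric rounding noise
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  S
}

#' Threshold a similarity matrix into an adjacency
#'
#' Off-diagonal entries below `tau` become 0; entries at or above `tau`
#' keep their similarity value. The diagonal is forced to 0 (self-loops
#' are added later during normalization, not here).
#'
#' @param S Symmetric similarity matrix.
#' @param tau Threshold in \[-1, 1\] (values outside simply give full or
#'   empty graphs).
#' @return Adjacency matrix A.
#' @export
apply_threshold <- function(S, tau) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("'S' must be symmetric")
  A <- S
  A[A < tau] <- 0
  diag(A) <- 0
  A
}

#' Choose the similarity threshold from a target mean degree
#'
#' Returns the largest `tau` for which the mean number of retained
#' off-diagonal edges per node is at least `target_mean_degree`; when no
#' threshold can retain that many edges, the minimum off-diagonal
#' similarity is returned (keeping every edge). Ties at the threshold
#' are retained, so the realized mean degree can exceed the target.
#'
#' @param S Symmetric similarity matrix, n >= 2.
#' @param target_mean_degree Positive real.
#' @return The selected threshold.
#' @export
select_threshold <- function(S, target_mean_degree = 10) {
  if (target_mean_degree <= 0) stop("'target_mean_degree' must be positive")
  n <- nrow(S)
  if (n < 2) stop("need at least 2 samples to build a graph")
  off <- S[upper.tri(S)]
  off <- sort(rep(off, 2L), decreasing = TRUE)  # both (i,j) and (j,i)
  m <- ceiling(target_mean_degree * n)
  if (m > length(off)) return(min(off))
  off[m]
}

#' Symmetric normalization of an adjacency matrix
#'
#' Adds self-loops and rescales by the square-root inverse degree:
#' with A~ = A + I and degree D~ii = sum_j A~ij, returns
#' D~^(-1/2) A~ D~^(-1/2). Because of the self-loops, every degree is at
#' least 1 and the operation is always defined.
#'
#' @param A Symmetric adjacency with zero diagonal and non-negative
#'   entries (negative entries are accepted but the spectral guarantees
#'   of the normalization then no longer hold).
#' @return The normalized adjacency.
#' @export
normalize_adjacency <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("'A' must be symmetric")
  At <- A
  diag(At) <- diag(At) + 1
  d_inv <- 1 / sqrt(rowSums(At))
  Ahat <- At * outer(d_inv, d_inv)
  (Ahat + t(Ahat)) / 2
}

#' Build the sample-similarity graph for one omics block
#'
#' Computes cosine similarities, thresholds them into an adjacency and
#' normalizes. The threshold is either given directly (`tau`) or chosen
#' by [select_threshold()] from a target mean node degree.
#'
#' @param X An [omics_matrix] or numeric matrix.
#' @param tau Explicit threshold; overrides `target_mean_degree`.
#' @param target_mean_degree Target mean retained degree used when `tau`
#'   is absent (default 10).
#' @return A list of class `similarity_graph` with fields `S`
#'   (raw similarities), `A` (thresholded adjacency), `tau`, and `Ahat`
#'   (normalized adjacency).
#' @export
build_similarity_graph <- function(X, tau = NULL, target_mean_degree = 10) {
  S <- cosine_similarity_matrix(X)
  if (is.null(tau)) tau <- select_threshold(S, target_mean_degree)
  A <- apply_threshold(S, tau)
  structure(list(S = S, A = A, tau = tau, Ahat = normalize_adjacency(A)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  deg <- rowSums(x$A != 0)
  cat(sprintf("<similarity_graph> %d nodes, tau = %.4f, mean degree %.1f\n",
              nrow(x$A), x$tau, mean(deg)))
  invisible(x)
}

#' Dump graph matrices as TSV for inspection
#' @param graph A `similarity_graph`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_graph_debug <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("adjacency.tsv", "adjacency_normalized.tsv"))
  utils::write.table(graph$A, paths[1], sep = "\t", quote = FALSE)
  utils::write.table(graph$Ahat, paths[2], sep = "\t", quote = FALSE)
  invisible(paths)
}
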
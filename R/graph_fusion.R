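# Model-divergence graph and GCN fusion -----------------------------------------
#
# The graph has one node per backbone; node features are the per-sample
# backbone feature vectors, and edges encode how differently two trained
# models behave on the training set. The divergence adjacency (variant
# "a1s") sets A_ij = 1 - similarity(i, j) off the diagonal, where similarity
# is the fraction of training samples on which the two models emit the same
# hard prediction. Fused features FG come from a two-layer graph convolution
# with the symmetrically normalized self-loop propagation matrix.

#' Agreement fraction between two models' hard predictions
#'
#' @param preds_i,preds_j equal-length 0/1 prediction vectors over the
#'   training samples.
#' @return The fraction of samples with identical predictions, in `[0, 1]`.
#' @export
#' @examples
#' model_similarity(c(1, 0, 1, 1), c(1, 0, 0, 1))  # 0.75
model_similarity <- function(preds_i, preds_j) {
  check_flag(length(preds_i) > 0 && length(preds_i) == length(preds_j),
             "preds", "must be nonempty vectors of equal length")
  mean(preds_i == preds_j)
}

#' Adjacency variants over the model graph
#'
#' @param all_preds matrix of training-set hard predictions, one row per model
#'   (or a list of prediction vectors).
#' @param variant `"a1s"` (divergence, the default: `1 - similarity`
#'   off-diagonal, zero diagonal), `"as"` (similarity off-diagonal),
#'   `"a0"` (all zeros off-diagonal) or `"a1"` (complete graph, all-ones
#'   matrix). Hyphenated spellings such as `"A-1-S"` are accepted.
#' @return A symmetric `n_models x n_models` adjacency matrix with entries in
#'   `[0, 1]`.
#' @export
build_adjacency <- function(all_preds, variant = "a1s") {
  if (is.list(all_preds)) all_preds <- do.call(rbind, all_preds)
  check_flag(is.matrix(all_preds) && nrow(all_preds) >= 2,
             "all_preds", "needs predictions from at least 2 models")
  v <- gsub("-", "", tolower(variant))
  check_flag(v %in% c("a0", "a1", "as", "a1s"), "variant",
             "must be one of a0, a1, as, a1s")
  n <- nrow(all_preds)
  if (v == "a0") return(matrix(0, n, n))
  if (v == "a1") return(matrix(1, n, n))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    S[i, j] <- model_similarity(all_preds[i, ], all_preds[j, ])
  if (v == "as") S else {
    A <- 1 - S
    diag(A) <- 0
    A
  }
}

#' Symmetrically normalized propagation matrix with self-loops
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` with `D` the degree matrix of
#' `A + I`. An all-zero adjacency maps to the identity.
#'
#' @param A square nonnegative adjacency matrix.
#' @return The symmetric propagation matrix.
#' @export
normalize_adjacency <- function(A) {
  check_flag(is.matrix(A) && nrow(A) == ncol(A), "A", "must be square")
  check_flag(all(A >= 0), "A", "entries must be nonnegative")
  At <- A + diag(nrow(A))
  dhalf <- 1 / sqrt(rowSums(At))
  At * outer(dhalf, dhalf)
}

#' The model graph for one sample
#'
#' @param node_features `n_models x feature_dim` matrix (one backbone feature
#'   vector per row).
#' @param adjacency symmetric adjacency with entries in `[0, 1]`.
#' @param variant adjacency variant label (metadata).
#' @return An object of class `model_graph`.
#' @export
model_graph <- function(node_features, adjacency, variant = "a1s") {
  node_features <- as.matrix(node_features)
  check_flag(is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency) &&
               nrow(adjacency) == nrow(node_features),
             "adjacency", "must be square and match the node count")
  check_flag(max(abs(adjacency - t(adjacency))) < 1e-9, "adjacency",
             "must be symmetric")
  check_flag(all(adjacency >= 0 & adjacency <= 1), "adjacency",
             "entries must lie in [0, 1]")
  structure(list(node_features = node_features, adjacency = adjacency,
                 variant = variant),
            class = "model_graph")
}

#' Two-layer GCN weights
#'
#' Layer widths default to `feature_dim -> feature_dim -> feature_dim / 2`
#' (at least 8), mirroring a 256 -> 256 -> 128 stack at full feature width.
#'
#' @param feature_dim node feature width.
#' @param hidden first-layer output width.
#' @param out second-layer output width.
#' @param seed integer seed for initialization.
#' @return An object of class `gcn_params` with weight matrices `W0`, `W1`.
#' @export
gcn_params <- function(feature_dim, hidden = feature_dim,
                       out = max(8L, feature_dim %/% 2L), seed = 1L) {
  feature_dim <- check_count(feature_dim, "feature_dim", 1L)
  hidden <- check_count(hidden, "hidden", 1L)
  out <- check_count(out, "out", 1L)
  with_seed(seed, {
    structure(list(
      W0 = matrix(stats::rnorm(feature_dim * hidden, sd = sqrt(2 / feature_dim)),
                  feature_dim, hidden),
      W1 = matrix(stats::rnorm(hidden * out, sd = sqrt(2 / hidden)), hidden, out)),
      class = "gcn_params")
  })
}

#' Fused features from the two-layer GCN
#'
#' Applies the propagation rule
#' `H^(l+1) = relu(D^(-1/2) (A + I) D^(-1/2) H^(l) W^(l))` twice and
#' concatenates the node rows of the final layer into the fused feature
#' vector FG (length `n_models * ncol(W1)`).
#'
#' @param graph a [model_graph()].
#' @param params a [gcn_params()] with widths consistent with the node
#'   feature dimension.
#' @return Numeric vector FG.
#' @export
gcn_forward <- function(graph, params) {
  check_flag(inherits(graph, "model_graph"), "graph", "must be a model_graph")
  check_flag(ncol(graph$node_features) == nrow(params$W0), "params",
             "W0 rows must equal the node feature dimension")
  P <- normalize_adjacency(graph$adjacency)
  H1 <- pmax(P %*% graph$node_features %*% params$W0, 0)
  H2 <- pmax(P %*% H1 %*% params$W1, 0)
  as.numeric(t(H2))
}

# batched GCN over samples: F is (n_models, d, N); returns FG (n_models*out, N)
# plus the caches needed for the backward pass
gcn_batch_forward <- function(P, F, W0, W1) {
  nm <- dim(F)[1]; d <- dim(F)[2]; N <- dim(F)[3]
  h <- ncol(W0); o <- ncol(W1)
  pf <- P %*% matrix(F, nm, d * N)
  dim(pf) <- c(nm, d, N)
  M1 <- matrix(aperm(pf, c(1, 3, 2)), nm * N, d)
  Z1 <- M1 %*% W0
  H1 <- pmax(Z1, 0)
  h1a <- array(H1, dim = c(nm, N, h))
  ph <- P %*% matrix(aperm(h1a, c(1, 3, 2)), nm, h * N)
  dim(ph) <- c(nm, h, N)
  M2 <- matrix(aperm(ph, c(1, 3, 2)), nm * N, h)
  Z2 <- M2 %*% W1
  H2 <- pmax(Z2, 0)
  fg <- aperm(array(H2, dim = c(nm, N, o)), c(3, 1, 2))
  dim(fg) <- c(nm * o, N)
  list(fg = fg, M1 = M1, Z1 = Z1, M2 = M2, Z2 = Z2,
       dims = list(nm = nm, d = d, N = N, h = h, o = o))
}

# gradient of the loss w.r.t. W0 and W1 given dL/dFG
gcn_batch_backward <- function(P, cache, W0, W1, dfg) {
  dm <- cache$dims
  dH2 <- matrix(aperm(array(dfg, dim = c(dm$o, dm$nm, dm$N)), c(2, 3, 1)),
                dm$nm * dm$N, dm$o)
  dZ2 <- dH2 * (cache$Z2 > 0)
  dW1 <- crossprod(cache$M2, dZ2)
  dM2 <- tcrossprod(dZ2, W1)                       # (nm*N) x h
  dm2a <- array(dM2, dim = c(dm$nm, dm$N, dm$h))
  dph <- P %*% matrix(aperm(dm2a, c(1, 3, 2)), dm$nm, dm$h * dm$N)  # P symmetric
  dim(dph) <- c(dm$nm, dm$h, dm$N)
  dH1 <- matrix(aperm(dph, c(1, 3, 2)), dm$nm * dm$N, dm$h)
  dZ1 <- dH1 * (cache$Z1 > 0)
  dW0 <- crossprod(cache$M1, dZ1)
  list(W0 = dW0, W1 = dW1)
}
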
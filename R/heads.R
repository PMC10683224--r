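# Focal loss, fusion heads, and the accuracy-weighted ensemble -----------------

#' Focal loss parameters
#'
#' Defaults alpha = 0.25, gamma = 2 (the settings used throughout the
#' classifier); gamma = 0 with alpha = 0.5 reduces the loss to half the
#' binary cross-entropy.
#'
#' @param alpha class-balance weight in `[0, 1]`.
#' @param gamma focusing exponent (>= 0).
#' @return An object of class `focal_params`.
#' @export
focal_params <- function(alpha = 0.25, gamma = 2) {
  structure(list(alpha = check_number(alpha, "alpha", 0, 1),
                 gamma = check_number(gamma, "gamma", min = 0)),
            class = "focal_params")
}

FOCAL_EPS <- 1e-7

#' Focal loss for binary classification
#'
#' `L = -alpha (1 - p)^gamma log(p)` for positives and
#' `L = -(1 - alpha) p^gamma log(1 - p)` for negatives (natural log;
#' probabilities clamped to `[1e-7, 1 - 1e-7]`). For a batch the mean loss is
#' returned.
#'
#' @param y 0/1 labels.
#' @param y_prob predicted probabilities in `(0, 1)`.
#' @param params a [focal_params()].
#' @return Nonnegative mean loss.
#' @export
#' @examples
#' focal_loss(1, 0.5)  # 0.25 * 0.25 * log(2)
focal_loss <- function(y, y_prob, params = focal_params()) {
  check_flag(length(y) == length(y_prob) && length(y) > 0,
             "y", "labels and probabilities must have equal positive length")
  check_flag(all(y %in% c(0, 1)), "y", "labels must be 0 or 1")
  p <- clamp(y_prob, FOCAL_EPS, 1 - FOCAL_EPS)
  a <- params$alpha; g <- params$gamma
  l <- ifelse(y == 1, -a * (1 - p)^g * log(p), -(1 - a) * p^g * log(1 - p))
  mean(l)
}

# dL/dz for a sigmoid output z (per sample, unaveraged)
focal_grad_logit <- function(y, p, params) {
  p <- clamp(p, FOCAL_EPS, 1 - FOCAL_EPS)
  a <- params$alpha; g <- params$gamma
  dldp <- ifelse(y == 1,
                 a * g * (1 - p)^(pmax(g - 1, 0)) * ifelse(g > 0, log(p), 0) -
                   a * (1 - p)^g / p,
                 -(1 - a) * g * p^(pmax(g - 1, 0)) * ifelse(g > 0, log(1 - p), 0) +
                   (1 - a) * p^g / (1 - p))
  dldp * p * (1 - p)
}

#' Accuracy-proportional ensemble weights
#'
#' `W_i = Acc_i / sum_j Acc_j`; weights are nonnegative and sum to one.
#'
#' @param accuracies vector of model accuracies in `[0, 1]`, not all zero.
#' @return An object of class `ensemble_weights` with `weights` and the source
#'   `accuracies`.
#' @export
#' @examples
#' ensemble_weights(c(0.8, 0.2))$weights
ensemble_weights <- function(accuracies) {
  check_flag(length(accuracies) >= 1 && all(is.finite(accuracies)),
             "accuracies", "must be finite")
  check_flag(all(accuracies >= 0 & accuracies <= 1), "accuracies",
             "must lie in [0, 1]")
  check_flag(sum(accuracies) > 0, "accuracies", "must not be all zero")
  structure(list(weights = accuracies / sum(accuracies),
                 accuracies = accuracies),
            class = "ensemble_weights")
}

#' Weighted-average ensemble probability
#'
#' @param probs per-model probabilities: a vector of length `n_models`, or an
#'   `n_samples x n_models` matrix.
#' @param weights an [ensemble_weights()] (or a plain weight vector summing
#'   to 1).
#' @return The convex combination `P = sum_i W_i P_i`; the final class is 1
#'   iff `P >= 0.5`.
#' @export
#' @examples
#' ensemble_predict(c(1, 0), ensemble_weights(c(0.8, 0.2)))  # 0.8
ensemble_predict <- function(probs, weights) {
  w <- if (inherits(weights, "ensemble_weights")) weights$weights else weights
  if (is.matrix(probs)) {
    check_flag(ncol(probs) == length(w), "probs",
               "number of columns must match the number of weights")
    return(as.numeric(probs %*% w))
  }
  check_flag(length(probs) == length(w), "probs",
             "length must match the number of weights")
  sum(probs * w)
}

#' Jointly train fusion heads and the shared GCN
#'
#' One linear head per model classifies the concatenation of that model's own
#' feature vector, the radiomics vector FR, and the shared GCN output FG.
#' Because FG is common to all heads, the GCN weights are optimized jointly
#' with the heads under the summed focal loss; backbone trunks stay frozen.
#' Passing `fr = NULL` or `P = NULL` drops the corresponding block (the heads
#' then reduce to linear probes on what remains).
#'
#' @param feats list of `n x feature_dim` feature matrices, one per model.
#' @param labels 0/1 training labels.
#' @param fr optional `n x |FR|` radiomics matrix (standardized by the caller).
#' @param P optional normalized propagation matrix from
#'   [normalize_adjacency()]; enables the GCN/FG block.
#' @param gcn optional [gcn_params()] initialization (built from the feature
#'   dimension when `NULL`).
#' @param loss a [focal_params()].
#' @param steps full-batch Adam steps.
#' @param lr learning rate.
#' @param seed integer seed.
#' @return An object of class `fusion_heads` holding head weights, trained GCN
#'   weights, and per-model training probabilities `train_prob`.
#' @export
finetune_heads <- function(feats, labels, fr = NULL, P = NULL, gcn = NULL,
                           loss = focal_params(), steps = 150L, lr = 0.01,
                           seed = 1L) {
  check_flag(is.list(feats) && length(feats) >= 1, "feats",
             "must be a list of feature matrices")
  feats <- lapply(feats, as.matrix)
  n <- nrow(feats[[1]])
  y <- as.integer(labels)
  check_flag(length(y) == n && all(y %in% c(0L, 1L)), "labels",
             "must be 0/1 and match the sample count")
  nm <- length(feats)
  d <- ncol(feats[[1]])
  use_fg <- !is.null(P)
  use_fr <- !is.null(fr)
  if (use_fr) {
    fr <- as.matrix(fr)
    check_flag(nrow(fr) == n, "fr", "row count must match the sample count")
  }
  if (use_fg) {
    check_flag(all(vapply(feats, ncol, 1L) == d), "feats",
               "GCN fusion needs a common feature dimension across models")
    check_flag(nrow(P) == nm, "P", "propagation matrix must match model count")
    if (is.null(gcn)) gcn <- gcn_params(d, seed = derive_seed(seed, 31L))
    Farr <- array(0, dim = c(nm, d, n))
    for (i in seq_len(nm)) Farr[i, , ] <- t(feats[[i]])
  }

  fg_len <- if (use_fg) nm * ncol(gcn$W1) else 0L
  fr_len <- if (use_fr) ncol(fr) else 0L
  par <- with_seed(derive_seed(seed, 47L), {
    heads <- lapply(seq_len(nm), function(i) {
      din <- ncol(feats[[i]]) + fr_len + fg_len
      list(w = stats::rnorm(din, sd = sqrt(1 / din)), b = 0)
    })
    p <- list(heads = heads)
    if (use_fg) p$gcn <- list(W0 = gcn$W0, W1 = gcn$W1)
    p
  })

  state <- adam_init(par)
  forward <- function(par) {
    cache <- NULL
    fg <- NULL
    if (use_fg) {
      cache <- gcn_batch_forward(P, Farr, par$gcn$W0, par$gcn$W1)
      fg <- cache$fg                                 # (nm*o) x n
    }
    probs <- matrix(0, n, nm)
    for (i in seq_len(nm)) {
      di <- ncol(feats[[i]])
      w <- par$heads[[i]]$w
      z <- feats[[i]] %*% w[seq_len(di)] + par$heads[[i]]$b
      if (use_fr) z <- z + fr %*% w[di + seq_len(fr_len)]
      if (use_fg) z <- z + crossprod(fg, w[di + fr_len + seq_len(fg_len)])
      probs[, i] <- 1 / (1 + exp(-as.numeric(z)))
    }
    list(probs = probs, cache = cache, fg = fg)
  }

  for (s in seq_len(steps)) {
    fwd <- forward(par)
    g <- list(heads = vector("list", nm))
    dfg <- if (use_fg) matrix(0, fg_len, n) else NULL
    for (i in seq_len(nm)) {
      di <- ncol(feats[[i]])
      dz <- focal_grad_logit(y, fwd$probs[, i], loss) / (n * nm)
      w <- par$heads[[i]]$w
      gw <- numeric(length(w))
      gw[seq_len(di)] <- crossprod(feats[[i]], dz)
      if (use_fr) gw[di + seq_len(fr_len)] <- crossprod(fr, dz)
      if (use_fg) {
        gw[di + fr_len + seq_len(fg_len)] <- fwd$fg %*% dz
        dfg <- dfg + outer(w[di + fr_len + seq_len(fg_len)], as.numeric(dz))
      }
      g$heads[[i]] <- list(w = gw, b = sum(dz))
    }
    if (use_fg)
      g$gcn <- gcn_batch_backward(P, fwd$cache, par$gcn$W0, par$gcn$W1, dfg)
    st <- adam_step(par, g, state, lr = lr)
    par <- st$par
    state <- st$state
  }

  fwd <- forward(par)
  structure(list(par = par, n_models = nm, use_fr = use_fr, use_fg = use_fg,
                 feat_dims = vapply(feats, ncol, 1L),
                 fr_len = fr_len, fg_len = fg_len,
                 train_prob = fwd$probs),
            class = "fusion_heads")
}

#' Per-model probabilities from trained fusion heads
#'
#' @param heads a [finetune_heads()] result.
#' @param feats list of feature matrices for the new samples (same layout as
#'   in training).
#' @param fr radiomics matrix (required iff used in training).
#' @param P normalized propagation matrix (required iff the GCN block was
#'   trained).
#' @return `n x n_models` matrix of probabilities.
#' @export
heads_predict <- function(heads, feats, fr = NULL, P = NULL) {
  feats <- lapply(feats, as.matrix)
  n <- nrow(feats[[1]])
  nm <- heads$n_models
  check_flag(length(feats) == nm, "feats", "model count mismatch")
  check_flag(heads$use_fr == !is.null(fr), "fr",
             "must be supplied exactly when the heads were trained with FR")
  check_flag(heads$use_fg == !is.null(P), "P",
             "must be supplied exactly when the heads were trained with FG")
  fg <- NULL
  if (heads$use_fg) {
    d <- heads$feat_dims[1]
    Farr <- array(0, dim = c(nm, d, n))
    for (i in seq_len(nm)) Farr[i, , ] <- t(feats[[i]])
    fg <- gcn_batch_forward(P, Farr, heads$par$gcn$W0, heads$par$gcn$W1)$fg
  }
  probs <- matrix(0, n, nm)
  for (i in seq_len(nm)) {
    di <- heads$feat_dims[i]
    w <- heads$par$heads[[i]]$w
    z <- feats[[i]] %*% w[seq_len(di)] + heads$par$heads[[i]]$b
    if (heads$use_fr) z <- z + as.matrix(fr) %*% w[di + seq_len(heads$fr_len)]
    if (heads$use_fg) z <- z + crossprod(fg, w[di + heads$fr_len + seq_len(heads$fg_len)])
    probs[, i] <- 1 / (1 + exp(-as.numeric(z)))
  }
  probs
}
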
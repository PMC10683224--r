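# Convolutional feature extractors ---------------------------------------------
#
# Five families, each preserving its defining motif at a reduced ("tiny")
# width/depth for desk-scale runs: a plain stacked conv net (alexnet), deep
# 3x3 stacks (vgg13), residual skips (resnet34), attention-masked residuals
# (attention56), and parallel multi-size filter blocks (googlenet). The
# 8-slice depth enters as input channels; an in-plane average-pooling stem
# reduces the 128x128 grid before the convolutional trunk. Every family ends
# in a learned projection to a common feature dimension so the graph over
# model features is dimension-aligned, followed by a single logit for the
# malignancy probability.

#' Names of the available backbone families
#' @return Character vector of registry names.
#' @export
backbone_names <- function() {
  c("alexnet", "vgg13", "resnet34", "attention56", "googlenet")
}

#' Specify a convolutional backbone
#'
#' @param name one of [backbone_names()].
#' @param scale `"tiny"` (desk-scale default) or `"full"`.
#' @param feature_dim width of the learned feature projection (>= 8); default
#'   32 at tiny scale, 256 at full scale.
#' @param input_shape voxel triple of the preprocessed input.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name, scale = c("tiny", "full"), feature_dim = NULL,
                          input_shape = c(128L, 128L, 8L)) {
  scale <- match.arg(scale)
  check_flag(is.character(name) && length(name) == 1L && name %in% backbone_names(),
             "name", paste("must be one of:", paste(backbone_names(), collapse = ", ")))
  if (is.null(feature_dim)) feature_dim <- if (scale == "tiny") 32L else 256L
  feature_dim <- check_count(feature_dim, "feature_dim", min = 8L)
  check_flag(length(input_shape) == 3L && all(input_shape >= 8),
             "input_shape", "must be a voxel triple, each >= 8")
  structure(list(name = name, scale = scale, feature_dim = feature_dim,
                 input_shape = as.integer(input_shape)),
            class = "backbone_spec")
}

# in-plane average pooling by an integer factor; (H, W, C, N) in and out
stem_pool <- function(x, f) {
  if (f <= 1L) return(x)
  d <- dim(x)
  y <- colMeans(matrix(x, nrow = f))                       # pool rows
  dim(y) <- c(d[1] %/% f, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- colMeans(matrix(y, nrow = f))                       # pool cols
  dim(y) <- c(d[2] %/% f, d[1] %/% f, d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

# family trunks; `s` is the trunk input shape, returns list of layers ending
# in a flat feature vector
backbone_trunk <- function(name, s, w) {
  L <- list()
  add <- function(L, layer) c(L, list(layer))
  shape <- function(L) if (length(L)) L[[length(L)]]$out_shape else s
  switch(name,
    alexnet = {
      L <- add(L, nn_conv2d(s, 3L * w, 5L, pad = 2L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_maxpool2(shape(L)))
      L <- add(L, nn_conv2d(shape(L), 4L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_maxpool2(shape(L)))
      L <- add(L, nn_conv2d(shape(L), 4L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_flatten(shape(L)))
      L
    },
    vgg13 = {
      L <- add(L, nn_conv2d(s, 2L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_conv2d(shape(L), 2L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_maxpool2(shape(L)))
      L <- add(L, nn_conv2d(shape(L), 4L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_conv2d(shape(L), 4L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_maxpool2(shape(L)))
      L <- add(L, nn_flatten(shape(L)))
      L
    },
    resnet34 = {
      L <- add(L, nn_conv2d(s, 2L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_resblock(shape(L), 2L * w))
      L <- add(L, nn_resblock(shape(L), 4L * w, stride = 2L))
      L <- add(L, nn_resblock(shape(L), 4L * w))
      L <- add(L, nn_gap(shape(L)))
      L
    },
    attention56 = {
      L <- add(L, nn_conv2d(s, 2L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_attention(shape(L)))
      L <- add(L, nn_resblock(shape(L), 4L * w, stride = 2L))
      L <- add(L, nn_gap(shape(L)))
      L
    },
    googlenet = {
      L <- add(L, nn_conv2d(s, 2L * w, 3L, pad = 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_maxpool2(shape(L)))
      L <- add(L, nn_inception(shape(L), w, w + w %/% 2L, w))
      L <- add(L, nn_maxpool2(shape(L)))
      L <- add(L, nn_conv2d(shape(L), 4L * w, 1L))
      L <- add(L, nn_relu(shape(L)))
      L <- add(L, nn_gap(shape(L)))
      L
    },
    stop_bad("name", "unknown backbone family"))
}

#' Build a trainable backbone feature extractor
#'
#' Initialization is deterministic under `seed`: two builds with equal seed
#' produce identical outputs on a fixed input.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `backbone`: the layer graph, its parameters, the
#'   stem pooling factor, and the spec.
#' @export
build_backbone <- function(spec, seed = 1L) {
  check_flag(inherits(spec, "backbone_spec"), "spec", "must be a backbone_spec")
  stem <- if (spec$scale == "tiny") 8L else 2L
  w <- if (spec$scale == "tiny") 4L else 16L
  s <- c(spec$input_shape[1] %/% stem, spec$input_shape[2] %/% stem,
         spec$input_shape[3])
  with_seed(seed, {
    trunk <- backbone_trunk(spec$name, s, w)
    nfeat <- trunk[[length(trunk)]]$out_shape
    layers <- c(trunk,
                list(nn_dense(nfeat, spec$feature_dim, relu = TRUE),
                     nn_dense(spec$feature_dim, 1L)))
    net <- nn_sequential(layers)
    structure(list(spec = spec, net = net, par = net$par, stem = stem,
                   seed = as.integer(seed)),
              class = "backbone")
  })
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s (%s), %d layers, %d parameters, feature_dim %d\n",
              x$spec$name, x$spec$scale, length(x$net$layers),
              n_parameters(x), x$spec$feature_dim))
  invisible(x)
}

#' Number of trainable parameters of a backbone
#' @param x a `backbone`.
#' @return Integer parameter count (a registry fingerprint of the family).
#' @export
n_parameters <- function(x) {
  tot <- 0
  tree_map(function(p) { tot <<- tot + length(p); p }, x$par)
  as.integer(tot)
}

# coerce a list of nodule volumes (or a cohort) to an (H, W, D, N) array
volumes_to_array <- function(volumes) {
  if (inherits(volumes, "phantom_cohort")) volumes <- volumes$volumes
  if (is.array(volumes) && length(dim(volumes)) == 4L) return(volumes)
  vox <- lapply(volumes, function(v) if (inherits(v, "nodule_volume")) v$voxels else v)
  d <- dim(vox[[1]])
  out <- array(0, dim = c(d, length(vox)))
  for (i in seq_along(vox)) out[, , , i] <- vox[[i]]
  out
}

#' Extract features and malignancy probabilities from a backbone
#'
#' Inference is deterministic: the same parameters and input always give the
#' same output.
#'
#' @param backbone a [build_backbone()] result (trained or not).
#' @param volumes list of [nodule_volume()], a `phantom_cohort`, or an
#'   `(H, W, D, N)` array on the backbone's input grid.
#' @return List with `features` (matrix `n x feature_dim`), `probability`
#'   (vector in `[0, 1]`) and `hard_prediction` (1 iff probability >= 0.5).
#' @export
backbone_forward <- function(backbone, volumes) {
  x <- stem_pool(volumes_to_array(volumes), backbone$stem)
  n <- length(backbone$net$layers)
  ff <- nn_forward(backbone$net, backbone$par, x, upto = n - 1L)
  head <- backbone$net$layers[[n]]
  z <- head$fwd(backbone$par[[n]], ff$y)$y
  p <- as.numeric(1 / (1 + exp(-z)))
  list(features = t(ff$y), probability = p,
       hard_prediction = as.integer(p >= 0.5))
}

#' Train a backbone with focal loss and Adam
#'
#' @param backbone a [build_backbone()] result.
#' @param volumes training volumes (see [backbone_forward()]).
#' @param labels integer 0/1 labels (1 = malignant); both classes must be
#'   present.
#' @param loss a [focal_params()].
#' @param opt an [optimizer_config()].
#' @param epochs training epochs (<= `opt$max_epochs` applies when `NULL`).
#' @param seed integer seed for minibatch shuffling.
#' @return The backbone with trained parameters, plus `train_probability` and
#'   `train_prediction` on the training set (needed by the divergence graph).
#' @export
train_backbone <- function(backbone, volumes, labels, loss = focal_params(),
                           opt = optimizer_config(), epochs = NULL, seed = 1L) {
  check_flag(inherits(backbone, "backbone"), "backbone", "must be a backbone")
  y <- as.integer(labels)
  check_flag(all(y %in% c(0L, 1L)), "labels", "must be 0/1")
  if (is.null(epochs)) epochs <- opt$max_epochs
  epochs <- check_count(epochs, "epochs", min = 0L)
  x <- stem_pool(volumes_to_array(volumes), backbone$stem)
  N <- dim(x)[4]
  check_flag(length(y) == N, "labels", "length must match the number of volumes")
  if (epochs > 0L)
    check_flag(length(unique(y)) == 2L, "labels",
               "training needs both classes present")

  par <- backbone$par
  state <- adam_init(par)
  net <- backbone$net
  bs <- min(opt$batch_size, N)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 211L, ep), sample(N))
    for (start in seq(1L, N, by = bs)) {
      take <- ord[start:min(start + bs - 1L, N)]
      xb <- x[, , , take, drop = FALSE]
      fwd <- nn_forward(net, par, xb)
      p <- 1 / (1 + exp(-as.numeric(fwd$y)))
      dz <- focal_grad_logit(y[take], p, loss) / length(take)
      bwd <- nn_backward(net, par, fwd$caches, matrix(dz, nrow = 1L))
      st <- adam_step(par, bwd$grads, state, lr = opt$lr,
                      weight_decay = opt$weight_decay)
      par <- st$par
      state <- st$state
    }
  }
  backbone$par <- par
  out <- backbone_forward(backbone, volumes)
  backbone$train_probability <- out$probability
  backbone$train_prediction <- out$hard_prediction
  backbone
}

#' Optimizer settings
#'
#' Defaults follow the original training schedule (Adam, initial learning rate
#' 1e-4, weight decay 1e-4, at most 100 epochs); desk-scale runs override the
#' learning rate and epoch count.
#'
#' @param lr initial learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(lr = 1e-4, weight_decay = 1e-4, max_epochs = 100L,
                             batch_size = 32L) {
  structure(list(lr = check_number(lr, "lr", min = 1e-12),
                 weight_decay = check_number(weight_decay, "weight_decay", min = 0),
                 max_epochs = check_count(max_epochs, "max_epochs", 0L),
                 batch_size = check_count(batch_size, "batch_size", 1L)),
            class = "optimizer_config")
}
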
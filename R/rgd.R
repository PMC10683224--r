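# The RGD classifier ------------------------------------------------------------
#
# rgd_fit() trains the full fusion stack on one training set:
#   1. train the five convolutional backbones with focal loss;
#   2. build the model-divergence adjacency from their training predictions;
#   3. compute the radiomics vector FR and the GCN-fused features FG;
#   4. jointly fine-tune one fusion head per backbone (with the shared GCN)
#      on [F_i, FR, FG];
#   5. weight the heads by their accuracy on a held-out, patient-disjoint
#      validation slice of the training set.
# predict.rgd() applies the trained stack; rgd_cv() wraps it in
# patient-disjoint k-fold cross-validation.

#' Configuration for an RGD run
#'
#' Defaults are the desk-scale settings: tiny backbones, learning rate 3e-3
#' and 12 epochs for the backbones, 120 full-batch Adam steps for the
#' heads/GCN. A full-scale run would use `scale = "full"` together with
#' `optimizer_config()` defaults (Adam, initial learning rate 1e-4, weight
#' decay 1e-4, up to 100 epochs).
#'
#' @param scale backbone scale, `"tiny"` or `"full"`.
#' @param backbones list of [backbone_spec()]; defaults to the five families.
#' @param adjacency_variant one of `"a1s"`, `"as"`, `"a1"`, `"a0"`.
#' @param lbp,hog,glcm radiomics parameter objects.
#' @param focal a [focal_params()].
#' @param opt an [optimizer_config()] for backbone training.
#' @param head_steps,head_lr fusion-head/GCN Adam steps and learning rate.
#' @param use_fr,use_fg include the radiomics / GCN feature blocks.
#' @param k cross-validation folds.
#' @param threshold decision threshold.
#' @param val_fraction fraction of training patients held out to measure the
#'   per-model accuracies that set the ensemble weights.
#' @param input_shape preprocessed volume shape fed to the backbones.
#' @return An object of class `rgd_config`.
#' @export
rgd_config <- function(scale = c("tiny", "full"), backbones = NULL,
                       adjacency_variant = "a1s",
                       lbp = lbp_params(), hog = hog_params(),
                       glcm = glcm_params(), focal = focal_params(),
                       opt = NULL, head_steps = 120L, head_lr = 0.01,
                       use_fr = TRUE, use_fg = TRUE, k = 10L,
                       threshold = 0.5, val_fraction = 0.1,
                       input_shape = c(128L, 128L, 8L)) {
  scale <- match.arg(scale)
  if (is.null(backbones))
    backbones <- lapply(backbone_names(), backbone_spec, scale = scale,
                        input_shape = input_shape)
  if (is.null(opt))
    opt <- if (scale == "tiny")
      optimizer_config(lr = 3e-3, weight_decay = 1e-4, max_epochs = 12L)
    else optimizer_config()
  structure(list(scale = scale, backbones = backbones,
                 adjacency_variant = adjacency_variant,
                 lbp = lbp, hog = hog, glcm = glcm, focal = focal, opt = opt,
                 head_steps = check_count(head_steps, "head_steps", 1L),
                 head_lr = check_number(head_lr, "head_lr", min = 1e-12),
                 use_fr = isTRUE(use_fr), use_fg = isTRUE(use_fg),
                 k = check_count(k, "k", 2L),
                 threshold = check_number(threshold, "threshold", 0, 1),
                 val_fraction = check_number(val_fraction, "val_fraction", 0, 0.5),
                 input_shape = as.integer(input_shape)),
            class = "rgd_config")
}

scaler_fit <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(pmax(colMeans(X^2) - mu^2, 0))
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

scaler_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")

# coerce inputs and preprocess to the configured network grid when needed
prepare_volumes <- function(volumes, config) {
  if (inherits(volumes, "phantom_cohort")) volumes <- volumes$volumes
  if (is.array(volumes)) return(volumes)
  shaped <- vapply(volumes, function(v) {
    d <- if (inherits(v, "nodule_volume")) dim(v$voxels) else dim(v)
    all(d == config$input_shape)
  }, logical(1))
  if (!all(shaped))
    volumes <- lapply(volumes, function(v) {
      v <- if (inherits(v, "nodule_volume")) v else nodule_volume(v)
      if (all(dim(v$voxels) == config$input_shape)) v
      else preprocess_volume(v, out_shape = config$input_shape,
                             crop_shape = c(dim(v$voxels)[1:2], config$input_shape[3]))
    })
  volumes_to_array(volumes)
}

#' Fit the RGD fusion classifier
#'
#' @param volumes training volumes: a `phantom_cohort`, list of
#'   [nodule_volume()] (preprocessed automatically when not on the network
#'   grid), or an `(H, W, D, N)` array.
#' @param labels 0/1 labels (1 = malignant); taken from the cohort when
#'   omitted.
#' @param patient_ids one id per volume; taken from the cohort when omitted.
#' @param config an [rgd_config()].
#' @param seed integer seed; the fit is fully reproducible under it.
#' @param fr optional precomputed radiomics matrix (rows aligned with
#'   `volumes`) to avoid recomputation across folds.
#' @return An object of class `rgd`.
#' @export
rgd_fit <- function(volumes, labels = NULL, patient_ids = NULL,
                    config = rgd_config(), seed = 1L, fr = NULL) {
  if (inherits(volumes, "phantom_cohort")) {
    if (is.null(labels)) labels <- volumes$labels
    if (is.null(patient_ids)) patient_ids <- volumes$patient_ids
  }
  x <- prepare_volumes(volumes, config)
  n <- dim(x)[4]
  y <- as.integer(labels)
  check_flag(length(y) == n && all(y %in% c(0L, 1L)), "labels",
             "must be 0/1, one per volume")
  check_flag(length(unique(y)) == 2L, "labels", "both classes must be present")
  if (is.null(patient_ids)) patient_ids <- sprintf("P%05d", seq_len(n))
  patient_ids <- as.character(patient_ids)

  # radiomics for every sample (standardized later on inner-train statistics)
  if (config$use_fr && is.null(fr)) {
    vols <- lapply(seq_len(n), function(i) x[, , , i])
    fr <- do.call(rbind, lapply(vols, function(v)
      radiomics_vector(array(v, dim = dim(x)[1:3]),
                       config$lbp, config$hog, config$glcm)$fr))
  }

  # held-out validation slice (patient-disjoint) for the ensemble weights
  pats <- unique(patient_ids)
  n_val <- round(config$val_fraction * length(pats))
  val_idx <- integer(0)
  if (n_val >= 1) {
    for (try in seq_len(20)) {
      vp <- with_seed(derive_seed(seed, 401L, try), sample(pats, n_val))
      cand <- which(patient_ids %in% vp)
      if (length(unique(y[-cand])) == 2L) { val_idx <- cand; break }
    }
  }
  tr_idx <- if (length(val_idx)) setdiff(seq_len(n), val_idx) else seq_len(n)

  xtr <- x[, , , tr_idx, drop = FALSE]
  ytr <- y[tr_idx]

  # 1. backbones
  nm <- length(config$backbones)
  backbones <- vector("list", nm)
  train_preds <- matrix(0L, nm, length(tr_idx))
  for (i in seq_len(nm)) {
    bb <- build_backbone(config$backbones[[i]], seed = derive_seed(seed, 11L, i))
    bb <- train_backbone(bb, xtr, ytr, loss = config$focal, opt = config$opt,
                         epochs = config$opt$max_epochs,
                         seed = derive_seed(seed, 13L, i))
    backbones[[i]] <- bb
    train_preds[i, ] <- bb$train_prediction
  }

  # 2. divergence graph from training predictions
  P <- NULL
  A <- NULL
  if (config$use_fg) {
    A <- build_adjacency(train_preds, config$adjacency_variant)
    P <- normalize_adjacency(A)
  }

  # 3. features for all samples, standardized on inner-train statistics
  feats_all <- lapply(backbones, function(bb) backbone_forward(bb, x)$features)
  feat_scalers <- lapply(feats_all, function(f) scaler_fit(f[tr_idx, , drop = FALSE]))
  feats_std <- Map(function(f, s) scaler_apply(f, s), feats_all, feat_scalers)
  fr_scaler <- NULL
  fr_std <- NULL
  if (config$use_fr) {
    fr_scaler <- scaler_fit(fr[tr_idx, , drop = FALSE])
    fr_std <- scaler_apply(fr, fr_scaler)
  }

  # 4. joint heads + GCN fine-tuning (backbone trunks frozen)
  heads <- finetune_heads(lapply(feats_std, function(f) f[tr_idx, , drop = FALSE]),
                          ytr,
                          fr = if (config$use_fr) fr_std[tr_idx, , drop = FALSE],
                          P = P, loss = config$focal,
                          steps = config$head_steps, lr = config$head_lr,
                          seed = derive_seed(seed, 17L))

  # 5. ensemble weights from validation accuracy of the fused heads
  acc_idx <- if (length(val_idx)) val_idx else tr_idx
  val_probs <- heads_predict(heads,
                             lapply(feats_std, function(f) f[acc_idx, , drop = FALSE]),
                             fr = if (config$use_fr) fr_std[acc_idx, , drop = FALSE],
                             P = P)
  acc <- colMeans((val_probs >= config$threshold) == (y[acc_idx] == 1L))
  weights <- if (sum(acc) > 0) ensemble_weights(acc)
             else {
               warning("all validation accuracies zero; using uniform weights",
                       call. = FALSE)
               ensemble_weights(rep(1, nm))
             }

  structure(list(backbones = backbones, adjacency = A, propagation = P,
                 heads = heads, weights = weights,
                 feat_scalers = feat_scalers, fr_scaler = fr_scaler,
                 config = config, seed = as.integer(seed),
                 n_train = length(tr_idx), n_val = length(val_idx)),
            class = "rgd")
}

#' @export
print.rgd <- function(x, ...) {
  cat(sprintf("<rgd> %d backbones (%s scale), adjacency %s\n",
              length(x$backbones), x$config$scale, x$config$adjacency_variant))
  cat("  ensemble weights:",
      paste(sprintf("%s %.3f", vapply(x$backbones, function(b) b$spec$name, ""),
                    x$weights$weights), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rgd <- function(object, ...) {
  cat("RGD fusion classifier\n")
  print(object)
  if (!is.null(object$adjacency)) {
    cat("  divergence adjacency:\n")
    print(round(object$adjacency, 3))
  }
  cat(sprintf("  trained on %d samples (%d held out for weighting)\n",
              object$n_train, object$n_val))
  invisible(object)
}

#' @export
coef.rgd <- function(object, ...) {
  stats::setNames(object$weights$weights,
                  vapply(object$backbones, function(b) b$spec$name, ""))
}

#' @export
plot.rgd <- function(x, ...) {
  if (is.null(x$adjacency)) {
    graphics::barplot(coef(x), ylab = "ensemble weight", ...)
    return(invisible(x))
  }
  nms <- vapply(x$backbones, function(b) b$spec$name, "")
  graphics::image(seq_along(nms), seq_along(nms),
                  t(x$adjacency[rev(seq_along(nms)), ]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "model divergence adjacency", ...)
  graphics::axis(1, at = seq_along(nms), labels = nms, las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_along(nms), labels = rev(nms), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Predict with a fitted RGD classifier
#'
#' @param object an [rgd_fit()] result.
#' @param newdata volumes in any layout accepted by [rgd_fit()].
#' @param type `"prob"` (ensemble probability), `"class"`, or `"all"` (list
#'   with ensemble probability, class, per-model fused probabilities and raw
#'   backbone probabilities).
#' @param fr optional precomputed radiomics matrix for `newdata`.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.rgd <- function(object, newdata, type = c("prob", "class", "all"),
                        fr = NULL, ...) {
  type <- match.arg(type)
  config <- object$config
  x <- prepare_volumes(newdata, config)
  n <- dim(x)[4]
  if (config$use_fr && is.null(fr)) {
    fr <- do.call(rbind, lapply(seq_len(n), function(i)
      radiomics_vector(array(x[, , , i], dim = dim(x)[1:3]),
                       config$lbp, config$hog, config$glcm)$fr))
  }
  outs <- lapply(object$backbones, function(bb) backbone_forward(bb, x))
  feats <- Map(function(o, s) scaler_apply(o$features, s), outs,
               object$feat_scalers)
  probs <- heads_predict(object$heads, feats,
                         fr = if (config$use_fr) scaler_apply(fr, object$fr_scaler),
                         P = object$propagation)
  p <- ensemble_predict(probs, object$weights)
  switch(type,
         prob = p,
         class = as.integer(p >= config$threshold),
         all = list(prob = p, class = as.integer(p >= config$threshold),
                    model_probs = probs,
                    trunk_probs = vapply(outs, `[[`, numeric(n), "probability")))
}

#' Patient-disjoint k-fold cross-validation of the RGD classifier
#'
#' Trains the full stack on each training fold and evaluates the held-out
#' fold; a runtime check fails hard if any patient appears on both sides of a
#' split. Radiomics vectors are computed once for the whole cohort and reused
#' across folds (standardization statistics always come from the training
#' fold).
#'
#' @param volumes cohort volumes (see [rgd_fit()]).
#' @param labels,patient_ids per-volume labels and patient ids (from the
#'   cohort when omitted).
#' @param config an [rgd_config()].
#' @param k number of folds (defaults to `config$k`).
#' @param seed integer seed; identical seeds give identical reports.
#' @return An object of class `rgd_cv`: per-fold [eval_report()]s, the
#'   aggregate mean/sd, per-backbone trunk and fused-head test accuracies,
#'   held-out ensemble probabilities, and the elapsed time in seconds.
#' @export
rgd_cv <- function(volumes, labels = NULL, patient_ids = NULL,
                   config = rgd_config(), k = NULL, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  if (inherits(volumes, "phantom_cohort")) {
    if (is.null(labels)) labels <- volumes$labels
    if (is.null(patient_ids)) patient_ids <- volumes$patient_ids
  }
  if (is.null(k)) k <- config$k
  x <- prepare_volumes(volumes, config)
  n <- dim(x)[4]
  y <- as.integer(labels)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%05d", seq_len(n))
  patient_ids <- as.character(patient_ids)

  fr_all <- NULL
  if (config$use_fr) {
    fr_all <- do.call(rbind, lapply(seq_len(n), function(i)
      radiomics_vector(array(x[, , , i], dim = dim(x)[1:3]),
                       config$lbp, config$hog, config$glcm)$fr))
  }

  split <- make_folds(patient_ids, k = k, seed = derive_seed(seed, 7L))
  nm <- length(config$backbones)
  reports <- vector("list", k)
  trunk_acc <- matrix(NA_real_, k, nm)
  head_acc <- matrix(NA_real_, k, nm)
  prob_out <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    te <- which(split$fold_of_nodule == f - 1L)
    tr <- setdiff(seq_len(n), te)
    if (length(intersect(patient_ids[tr], patient_ids[te])) > 0)
      stop("patient overlap between train and test folds", call. = FALSE)
    fit <- rgd_fit(x[, , , tr, drop = FALSE], y[tr], patient_ids[tr],
                   config = config, seed = derive_seed(seed, 1000L, f),
                   fr = if (config$use_fr) fr_all[tr, , drop = FALSE])
    pred <- predict(fit, x[, , , te, drop = FALSE], type = "all",
                    fr = if (config$use_fr) fr_all[te, , drop = FALSE])
    reports[[f]] <- eval_report(y[te], pred$prob, threshold = config$threshold)
    tp <- matrix(pred$trunk_probs, ncol = nm)
    trunk_acc[f, ] <- colMeans((tp >= 0.5) == (y[te] == 1L))
    head_acc[f, ] <- colMeans((pred$model_probs >= config$threshold) == (y[te] == 1L))
    prob_out[te] <- pred$prob
  }
  colnames(trunk_acc) <- colnames(head_acc) <-
    vapply(config$backbones, `[[`, "", "name")
  structure(list(folds = reports, aggregate = aggregate_folds(reports),
                 trunk_accuracy = trunk_acc, head_accuracy = head_acc,
                 probabilities = prob_out, labels = y, split = split,
                 config = config, seed = as.integer(seed),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "rgd_cv")
}

#' @export
print.rgd_cv <- function(x, ...) {
  agg <- x$aggregate
  cat(sprintf("<rgd_cv> %d folds, %d samples (%.1f s)\n",
              length(x$folds), length(x$labels), x$elapsed))
  cat(sprintf("  mean: acc %.4f  sens %.4f  spec %.4f  prec %.4f  F1 %.4f  AUC %.4f\n",
              agg$mean["accuracy"], agg$mean["sensitivity"],
              agg$mean["specificity"], agg$mean["precision"],
              agg$mean["f1"], agg$mean["auc"]))
  invisible(x)
}

#' @export
summary.rgd_cv <- function(object, ...) {
  print(object)
  cat("  per-fold metrics:\n")
  print(round(object$aggregate$folds, 4))
  cat("  mean single-backbone (trunk) accuracy:\n")
  print(round(colMeans(object$trunk_accuracy), 4))
  invisible(object)
}

#' @export
as.data.frame.rgd_cv <- function(x, ...) {
  df <- as.data.frame(x$aggregate$folds)
  cbind(fold = seq_len(nrow(df)), df)
}

#' Ablation study over fusion arms and adjacency variants
#'
#' Arms: `"cnn_i"` (single backbone i), `"cnn_i+r"` (backbone plus
#' radiomics), `"cnn_i+g"` (backbone plus GCN features), `"cnn_i+r+g"`,
#' `"cnn_s"` (one head over the five concatenated feature vectors),
#' `"cnn_s+r"`, and `"rgd"` (the full weighted ensemble). Graph arms are
#' crossed with every requested adjacency `variant`.
#'
#' @param volumes,labels,patient_ids cohort (see [rgd_fit()]).
#' @param arms character vector of arm labels, `i` in `1..n_backbones`.
#' @param variants adjacency variants evaluated for arms that use the GCN.
#' @param config an [rgd_config()].
#' @param k folds.
#' @param seed integer seed.
#' @return An object of class `rgd_ablation`: data frame with one row per
#'   (arm, variant) and one accuracy column per fold plus the mean.
#' @export
rgd_ablation <- function(volumes, labels = NULL, patient_ids = NULL,
                         arms = c("cnn_1", "rgd"), variants = "a1s",
                         config = rgd_config(), k = NULL, seed = 1L) {
  if (inherits(volumes, "phantom_cohort")) {
    if (is.null(labels)) labels <- volumes$labels
    if (is.null(patient_ids)) patient_ids <- volumes$patient_ids
  }
  if (is.null(k)) k <- config$k
  arms <- tolower(arms)
  nm <- length(config$backbones)
  known <- c(sprintf("cnn_%d", seq_len(nm)), sprintf("cnn_%d+r", seq_len(nm)),
             sprintf("cnn_%d+g", seq_len(nm)), sprintf("cnn_%d+r+g", seq_len(nm)),
             "cnn_s", "cnn_s+r", "rgd")
  bad <- setdiff(arms, known)
  check_flag(length(bad) == 0, "arms",
             paste("unknown arm(s):", paste(bad, collapse = ", ")))
  graph_arm <- function(a) grepl("\\+g", a) || a == "rgd"

  x <- prepare_volumes(volumes, config)
  n <- dim(x)[4]
  y <- as.integer(labels)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%05d", seq_len(n))
  fr_all <- if (config$use_fr && any(grepl("\\+r|rgd", arms)))
    do.call(rbind, lapply(seq_len(n), function(i)
      radiomics_vector(array(x[, , , i], dim = dim(x)[1:3]),
                       config$lbp, config$hog, config$glcm)$fr)) else NULL

  split <- make_folds(as.character(patient_ids), k = k,
                      seed = derive_seed(seed, 7L))
  rows <- list()
  acc_of <- function(p, yy) mean((p >= config$threshold) == (yy == 1L))

  for (f in seq_len(k)) {
    te <- which(split$fold_of_nodule == f - 1L)
    tr <- setdiff(seq_len(n), te)
    ytr <- y[tr]; yte <- y[te]
    # shared per-fold computations
    backbones <- vector("list", nm)
    train_preds <- matrix(0L, nm, length(tr))
    for (i in seq_len(nm)) {
      bb <- build_backbone(config$backbones[[i]],
                           seed = derive_seed(seed, 1000L, f, 11L, i))
      bb <- train_backbone(bb, x[, , , tr, drop = FALSE], ytr,
                           loss = config$focal, opt = config$opt,
                           seed = derive_seed(seed, 1000L, f, 13L, i))
      backbones[[i]] <- bb
      train_preds[i, ] <- bb$train_prediction
    }
    feats_all <- lapply(backbones, function(bb) backbone_forward(bb, x)$features)
    scalers <- lapply(feats_all, function(fm) scaler_fit(fm[tr, , drop = FALSE]))
    feats <- Map(scaler_apply, feats_all, scalers)
    ftr <- lapply(feats, function(fm) fm[tr, , drop = FALSE])
    fte <- lapply(feats, function(fm) fm[te, , drop = FALSE])
    frs <- NULL; frtr <- NULL; frte <- NULL
    if (!is.null(fr_all)) {
      frs <- scaler_fit(fr_all[tr, , drop = FALSE])
      frtr <- scaler_apply(fr_all[tr, , drop = FALSE], frs)
      frte <- scaler_apply(fr_all[te, , drop = FALSE], frs)
    }
    trunk_prob <- vapply(backbones, function(bb)
      backbone_forward(bb, x[, , , te, drop = FALSE])$probability,
      numeric(length(te)))
    hseed <- derive_seed(seed, 1000L, f, 17L)
    train_group <- function(use_fr, P) {
      finetune_heads(ftr, ytr, fr = if (use_fr) frtr, P = P,
                     loss = config$focal, steps = config$head_steps,
                     lr = config$head_lr, seed = hseed)
    }
    Ps <- lapply(variants, function(v)
      normalize_adjacency(build_adjacency(train_preds, v)))
    names(Ps) <- variants
    groups <- list()
    need <- function(key) key %in% names(groups)
    get_group <- function(key, use_fr, P) {
      if (!need(key)) groups[[key]] <<- train_group(use_fr, P)
      groups[[key]]
    }
    for (a in arms) {
      vs <- if (graph_arm(a)) variants else NA_character_
      for (v in vs) {
        acc <- if (grepl("^cnn_[0-9]+$", a)) {
          i <- as.integer(sub("cnn_", "", a))
          acc_of(trunk_prob[, i], yte)
        } else if (grepl("^cnn_[0-9]+\\+r$", a)) {
          i <- as.integer(sub("cnn_([0-9]+).*", "\\1", a))
          gr <- get_group("r", TRUE, NULL)
          acc_of(heads_predict(gr, fte, fr = frte)[, i], yte)
        } else if (grepl("^cnn_[0-9]+\\+g$", a)) {
          i <- as.integer(sub("cnn_([0-9]+).*", "\\1", a))
          gr <- get_group(paste0("g_", v), FALSE, Ps[[v]])
          acc_of(heads_predict(gr, fte, P = Ps[[v]])[, i], yte)
        } else if (grepl("^cnn_[0-9]+\\+r\\+g$", a) || a == "rgd") {
          gr <- get_group(paste0("rg_", v), TRUE, Ps[[v]])
          pm <- heads_predict(gr, fte, fr = frte, P = Ps[[v]])
          if (a == "rgd") {
            tr_acc <- colMeans((gr$train_prob >= config$threshold) == (ytr == 1L))
            w <- ensemble_weights(tr_acc)
            acc_of(ensemble_predict(pm, w), yte)
          } else {
            i <- as.integer(sub("cnn_([0-9]+).*", "\\1", a))
            acc_of(pm[, i], yte)
          }
        } else if (a %in% c("cnn_s", "cnn_s+r")) {
          key_s <- if (a == "cnn_s") "s" else "sr"
          if (is.null(groups[[key_s]]))
            groups[[key_s]] <- finetune_heads(list(do.call(cbind, ftr)), ytr,
                                              fr = if (a == "cnn_s+r") frtr,
                                              loss = config$focal,
                                              steps = config$head_steps,
                                              lr = config$head_lr, seed = hseed)
          acc_of(heads_predict(groups[[key_s]], list(do.call(cbind, fte)),
                               fr = if (a == "cnn_s+r") frte)[, 1], yte)
        }
        key <- paste(a, v, sep = "|")
        if (is.null(rows[[key]])) rows[[key]] <- rep(NA_real_, k)
        rows[[key]][f] <- acc
      }
    }
  }
  labs <- do.call(rbind, strsplit(names(rows), "|", fixed = TRUE))
  tab <- data.frame(arm = labs[, 1], variant = labs[, 2],
                    do.call(rbind, rows), row.names = NULL,
                    stringsAsFactors = FALSE)
  names(tab)[2 + seq_len(k)] <- sprintf("fold_%d", seq_len(k))
  tab$mean <- rowMeans(tab[, 2 + seq_len(k), drop = FALSE])
  structure(tab, class = c("rgd_ablation", "data.frame"))
}

#' @export
print.rgd_ablation <- function(x, ...) {
  cat("RGD ablation (accuracy per fold)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
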
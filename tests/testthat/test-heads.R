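# Focal loss, fusion heads, ensemble decision

test_that("focal loss matches closed forms and reduces to scaled cross-entropy", {
  expect_equal(focal_loss(1, 0.5), 0.25 * 0.25 * log(2))
  expect_lt(focal_loss(1, 1 - 1e-9), 1e-6)     # y' -> 1 drives the loss to 0
  # gamma = 0, alpha = 0.5: exactly half the binary cross-entropy
  fp <- focal_params(alpha = 0.5, gamma = 0)
  for (p in c(0.05, 0.3, 0.7, 0.95)) {
    expect_equal(focal_loss(1, p, fp), 0.5 * (-log(p)))
    expect_equal(focal_loss(0, p, fp), 0.5 * (-log(1 - p)))
  }
  expect_equal(focal_loss(c(1, 0), c(0.5, 0.5)),
               mean(c(0.25 * 0.25 * log(2), 0.75 * 0.25 * log(2))))
  expect_error(focal_loss(2, 0.5), "0 or 1")
  expect_error(focal_params(gamma = -1), "gamma")
})

test_that("focal loss is monotone in the predicted probability", {
  ps <- seq(0.01, 0.99, by = 0.01)
  for (g in c(0, 1, 2, 5)) {
    fp <- focal_params(gamma = g)
    l1 <- vapply(ps, function(p) focal_loss(1, p, fp), numeric(1))
    l0 <- vapply(ps, function(p) focal_loss(0, p, fp), numeric(1))
    expect_true(all(diff(l1) < 0))   # strictly decreasing for y = 1
    expect_true(all(diff(l0) > 0))   # strictly increasing for y = 0
  }
})

test_that("the focal gradient matches finite differences", {
  fp <- focal_params()
  for (y in c(0, 1)) for (p0 in c(0.2, 0.5, 0.9)) {
    z0 <- log(p0 / (1 - p0))
    eps <- 1e-6
    num <- (focal_loss(y, 1 / (1 + exp(-(z0 + eps))), fp) -
              focal_loss(y, 1 / (1 + exp(-(z0 - eps))), fp)) / (2 * eps)
    expect_equal(rgdfusion:::focal_grad_logit(y, p0, fp), num, tolerance = 1e-5)
  }
})

test_that("ensemble weights are accuracy proportions summing to one", {
  expect_equal(ensemble_weights(rep(0.9, 5))$weights, rep(0.2, 5))
  expect_equal(ensemble_weights(c(0.8, 0.2))$weights, c(0.8, 0.2))
  set.seed(6)
  for (i in 1:10) {
    w <- ensemble_weights(runif(5))$weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  expect_error(ensemble_weights(c(0, 0)), "zero")
  expect_error(ensemble_weights(c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("the ensemble probability is a convex, permutation-stable average", {
  w <- ensemble_weights(c(0.8, 0.2))
  expect_equal(ensemble_predict(c(1, 0), w), 0.8)
  expect_equal(ensemble_predict(rep(1, 5), ensemble_weights(runif(5, 0.5, 1))), 1)
  set.seed(13)
  for (i in 1:10) {
    p <- runif(5); acc <- runif(5, 0.3, 1)
    ew <- ensemble_weights(acc)
    pe <- ensemble_predict(p, ew)
    expect_true(pe >= min(p) && pe <= max(p))
    perm <- sample(5)
    expect_equal(ensemble_predict(p[perm], ensemble_weights(acc[perm])), pe)
  }
  m <- matrix(runif(12), 3, 4)
  ew4 <- ensemble_weights(rep(0.5, 4))
  expect_equal(ensemble_predict(m, ew4), as.numeric(m %*% ew4$weights))
  expect_error(ensemble_predict(c(0.2, 0.4, 0.6), w), "length")
})

test_that("fusion heads train deterministically and use the feature blocks", {
  set.seed(55)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  # informative radiomics block, weak model features
  feats <- lapply(1:3, function(i) matrix(rnorm(n * 4), n, 4))
  fr <- cbind(y + rnorm(n, sd = 0.2), matrix(rnorm(n * 5), n, 5))
  A <- matrix(0.5, 3, 3); diag(A) <- 0
  P <- normalize_adjacency(A)
  h1 <- finetune_heads(feats, y, fr = fr, P = P, steps = 120, seed = 9)
  h2 <- finetune_heads(feats, y, fr = fr, P = P, steps = 120, seed = 9)
  expect_identical(h1$par, h2$par)
  expect_gt(mean((h1$train_prob[, 1] >= 0.5) == (y == 1)), 0.9)

  # degenerate blocks: all-zero FR/FG still runs (linear probe on features)
  h0 <- finetune_heads(feats, y, fr = matrix(0, n, 3), P = NULL, steps = 20)
  expect_equal(dim(h0$train_prob), c(n, 3L))
  p0 <- heads_predict(h0, feats, fr = matrix(0, n, 3))
  expect_true(all(p0 >= 0 & p0 <= 1))
  expect_error(heads_predict(h0, feats), "fr")
  expect_error(heads_predict(h1, feats, fr = fr), "P")
})
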
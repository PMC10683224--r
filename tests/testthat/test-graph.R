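# Divergence graph and GCN fusion

test_that("model similarity is the agreement fraction", {
  expect_equal(model_similarity(c(1, 0, 1), c(1, 0, 1)), 1.0)
  expect_equal(model_similarity(c(1, 0, 1, 0), c(0, 1, 0, 1)), 0.0)
  expect_equal(model_similarity(c(1, 0, 1, 1), c(1, 0, 0, 1)), 0.75)
  expect_error(model_similarity(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(model_similarity(integer(0), integer(0)), "nonempty")
})

test_that("adjacency variants follow their definitions", {
  agree <- matrix(rep(c(1L, 0L, 1L, 0L), 5), nrow = 5, byrow = TRUE)
  expect_equal(build_adjacency(agree, "a1s"), matrix(0, 5, 5))
  expect_equal(build_adjacency(agree, "A-1-S"), matrix(0, 5, 5))
  expect_equal(build_adjacency(agree, "a1"), matrix(1, 5, 5))
  set.seed(8)
  preds <- matrix(rbinom(5 * 40, 1, 0.5), nrow = 5)
  a1s <- build_adjacency(preds, "a1s")
  as_ <- build_adjacency(preds, "as")
  expect_true(all(a1s >= 0 & a1s <= 1) && all(as_ >= 0 & as_ <= 1))
  expect_equal(a1s, t(a1s))
  expect_equal(diag(a1s), rep(0, 5))
  expect_equal(diag(as_), rep(0, 5))
  off <- matrix(1, 5, 5) - diag(5)
  expect_equal(a1s + as_, off)               # complementarity
  expect_equal(build_adjacency(preds, "a0"), matrix(0, 5, 5))
  expect_error(build_adjacency(preds, "a2"), "variant")
  expect_equal(a1s[1, 2], 1 - mean(preds[1, ] == preds[2, ]))
})

test_that("adjacency normalization has the closed forms", {
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  # all-ones 2x2: A + I = [[2,1],[1,2]], degrees 3
  P <- normalize_adjacency(matrix(1, 2, 2))
  expect_equal(P, matrix(c(2, 1, 1, 2) / 3, 2, 2))
  set.seed(3)
  A <- matrix(runif(25), 5, 5)
  A <- (A + t(A)) / 2
  P <- normalize_adjacency(A)
  expect_equal(P, t(P))
  expect_error(normalize_adjacency(-A), "nonnegative")
})

test_that("gcn_forward matches a literal propagation-rule oracle", {
  set.seed(14)
  H0 <- matrix(rnorm(5 * 6), 5, 6)
  A <- matrix(runif(25), 5, 5); A <- (A + t(A)) / 2; diag(A) <- 0
  gp <- gcn_params(6, hidden = 4, out = 3, seed = 2)
  fg <- gcn_forward(model_graph(H0, A), gp)
  expect_length(fg, 5 * 3)
  expect_equal(fg, oracle_gcn(H0, A, gp$W0, gp$W1), tolerance = 1e-6)

  # single node, A = [0]: propagation matrix is [1]
  g1 <- model_graph(matrix(1:4, 1, 4), matrix(0, 1, 1))
  gp1 <- gcn_params(4, hidden = 3, out = 2, seed = 5)
  expect_equal(gcn_forward(g1, gp1),
               as.numeric(pmax(pmax(matrix(1:4, 1) %*% gp1$W0, 0) %*% gp1$W1, 0)))

  # zero weights give a zero fused vector
  gp0 <- gcn_params(6, hidden = 4, out = 3, seed = 1)
  gp0$W0[] <- 0; gp0$W1[] <- 0
  expect_equal(gcn_forward(model_graph(H0, A), gp0), rep(0, 15))
})

test_that("node permutations permute the fused blocks identically", {
  set.seed(25)
  H0 <- matrix(rnorm(5 * 6), 5, 6)
  A <- matrix(runif(25), 5, 5); A <- (A + t(A)) / 2; diag(A) <- 0
  gp <- gcn_params(6, hidden = 6, out = 4, seed = 9)
  fg <- gcn_forward(model_graph(H0, A), gp)
  perm <- c(3, 1, 5, 2, 4)
  fgp <- gcn_forward(model_graph(H0[perm, ], A[perm, perm]), gp)
  blocks <- matrix(fg, nrow = 5, byrow = TRUE)
  expect_equal(matrix(fgp, nrow = 5, byrow = TRUE), blocks[perm, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("with A-0 and identity weights each node sees only itself", {
  d <- 4
  gp <- gcn_params(d, hidden = d, out = d, seed = 1)
  gp$W0 <- diag(d); gp$W1 <- diag(d)
  A0 <- matrix(0, 3, 3)
  H <- matrix(abs(rnorm(3 * d)), 3, d)
  fg <- gcn_forward(model_graph(H, A0), gp)
  H2 <- H
  H2[2, ] <- 100 * H2[2, ]      # perturb node 2 only
  fg2 <- gcn_forward(model_graph(H2, A0), gp)
  b <- function(x, i) x[(i - 1) * d + seq_len(d)]
  expect_equal(b(fg, 1), b(fg2, 1))
  expect_equal(b(fg, 3), b(fg2, 3))
  expect_false(isTRUE(all.equal(b(fg, 2), b(fg2, 2))))
  expect_equal(b(fg, 1), H[1, ])   # relu(relu(H I) I) = H for positive H
})

test_that("the batched GCN agrees with the per-sample forward and its gradients", {
  set.seed(77)
  nm <- 5; d <- 6; N <- 4
  A <- matrix(runif(nm^2), nm, nm); A <- (A + t(A)) / 2; diag(A) <- 0
  P <- normalize_adjacency(A)
  gp <- gcn_params(d, hidden = 5, out = 3, seed = 3)
  Farr <- array(rnorm(nm * d * N), dim = c(nm, d, N))
  out <- rgdfusion:::gcn_batch_forward(P, Farr, gp$W0, gp$W1)
  for (n in seq_len(N)) {
    fg1 <- gcn_forward(model_graph(Farr[, , n], A), gp)
    expect_equal(out$fg[, n], fg1, tolerance = 1e-12)
  }
  # finite-difference check of the weight gradients
  loss <- function(W0, W1) sum(rgdfusion:::gcn_batch_forward(P, Farr, W0, W1)$fg^2) / 2
  g <- rgdfusion:::gcn_batch_backward(P, out, gp$W0, gp$W1, out$fg)
  eps <- 1e-6
  for (i in sample(length(gp$W0), 3)) {
    Wp <- gp$W0; Wp[i] <- Wp[i] + eps
    Wm <- gp$W0; Wm[i] <- Wm[i] - eps
    expect_equal(g$W0[i], (loss(Wp, gp$W1) - loss(Wm, gp$W1)) / (2 * eps),
                 tolerance = 1e-4)
  }
  for (i in sample(length(gp$W1), 3)) {
    Wp <- gp$W1; Wp[i] <- Wp[i] + eps
    Wm <- gp$W1; Wm[i] <- Wm[i] - eps
    expect_equal(g$W1[i], (loss(gp$W0, Wp) - loss(gp$W0, Wm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
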
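# Minimal batched neural-network engine ---------------------------------------
#
# Feature maps are (H, W, C, N) arrays (N = batch); dense activations are
# (features, N) matrices. Convolutions run as one im2col gather plus a BLAS
# matrix product over the whole batch; every layer carries hand-derived
# backward passes validated by finite-difference gradient checks in the test
# suite. Shapes are static: builders thread the input shape so gather index
# templates are precomputed once.
#
# Layer interface: list(par, fwd(par, x) -> list(y, cache),
#                       bwd(par, cache, dy) -> list(dx, g)) with `g`
# mirroring `par`.

# recursive helpers over nested lists of numeric arrays
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- if (is.null(b)) lapply(a, function(ai) tree_map(f, ai))
           else Map(function(ai, bi) tree_map(f, ai, bi), a, b)
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

tree_zero <- function(par) tree_map(function(x) x * 0, par)

# im2col gather template for an (H, W, C) grid
im2col_idx <- function(H, W, C, kh, kw, stride, pad) {
  H2 <- H + 2L * pad; W2 <- W + 2L * pad
  Ho <- (H2 - kh) %/% stride + 1L
  Wo <- (W2 - kw) %/% stride + 1L
  a <- rep(seq_len(kh), times = kw * C)
  b <- rep(rep(seq_len(kw), each = kh), times = C)
  ch <- rep(seq_len(C), each = kh * kw)
  kofs <- (a - 1L) + H2 * (b - 1L) + H2 * W2 * (ch - 1L)       # K
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  pofs <- (oi - 1L) * stride + H2 * ((oj - 1L) * stride)        # P
  idx <- outer(kofs, pofs, `+`) + 1L                            # K x P
  list(idx = as.integer(idx), K = length(kofs), P = length(pofs),
       Ho = Ho, Wo = Wo, H2 = H2, W2 = W2)
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

nn_conv2d <- function(in_shape, cout, kh, kw = kh, stride = 1L, pad = 0L) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  tpl <- im2col_idx(H, W, C, kh, kw, stride, pad)
  K <- tpl$K
  par <- list(W = array(stats::rnorm(kh * kw * C * cout, sd = sqrt(2 / K)),
                        dim = c(kh, kw, C, cout)),
              b = numeric(cout))
  layer <- list(
    type = "conv", out_shape = c(tpl$Ho, tpl$Wo, cout), par = par,
    fwd = function(par, x) {
      N <- dim(x)[4]
      xp <- pad_input(x, pad)
      Xm <- matrix(xp, nrow = tpl$H2 * tpl$W2 * C)
      Xc <- Xm[tpl$idx, , drop = FALSE]          # (K*P) x N
      dim(Xc) <- c(K, tpl$P * N)
      Wm <- matrix(par$W, nrow = K)
      y <- crossprod(Wm, Xc) + par$b             # cout x (P*N)
      dim(y) <- c(cout, tpl$P, N)
      y <- aperm(y, c(2, 1, 3))
      dim(y) <- c(tpl$Ho, tpl$Wo, cout, N)
      list(y = y, cache = list(Xc = Xc, N = N))
    },
    bwd = function(par, cache, dy) {
      N <- cache$N
      dim(dy) <- c(tpl$P, cout, N)
      dym <- aperm(dy, c(2, 1, 3))
      dim(dym) <- c(cout, tpl$P * N)
      dW <- tcrossprod(cache$Xc, dym)            # K x cout
      dim(dW) <- c(kh, kw, C, cout)
      db <- rowSums(dym)
      Wm <- matrix(par$W, nrow = K)
      dXc <- Wm %*% dym                          # K x (P*N)
      dim(dXc) <- c(K * tpl$P, N)
      dXm <- matrix(0, tpl$H2 * tpl$W2 * C, N)
      rs <- rowsum(dXc, tpl$idx)
      dXm[as.integer(rownames(rs)), ] <- rs
      dxp <- array(dXm, dim = c(tpl$H2, tpl$W2, C, N))
      dx <- if (pad > 0L) dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
            else dxp
      list(dx = dx, g = list(W = dW, b = db))
    })
  layer
}

nn_relu <- function(in_shape) {
  list(type = "relu", out_shape = in_shape, par = list(),
       fwd = function(par, x) {
         m <- x > 0
         list(y = x * m, cache = m)
       },
       bwd = function(par, cache, dy) list(dx = dy * cache, g = list()))
}

nn_maxpool2 <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  list(
    type = "maxpool2", out_shape = c(H %/% 2L, W %/% 2L, C), par = list(),
    fwd = function(par, x) {
      N <- dim(x)[4]
      m1 <- matrix(x, nrow = 2)                    # pool rows
      t1 <- m1[1, ] >= m1[2, ]
      y1 <- pmax(m1[1, ], m1[2, ])                 # length H/2*W*C*N
      m2 <- matrix(y1, nrow = H %/% 2L)            # cols alternate pair index
      odd <- seq(1, ncol(m2), by = 2)
      xo <- m2[, odd, drop = FALSE]; xe <- m2[, odd + 1L, drop = FALSE]
      t2 <- xo >= xe
      y <- pmax(xo, xe)
      dim(y) <- c(H %/% 2L, W %/% 2L, C, N)
      list(y = y, cache = list(t1 = t1, t2 = t2, N = N))
    },
    bwd = function(par, cache, dy) {
      N <- cache$N
      dyv <- matrix(dy, nrow = H %/% 2L)
      d2 <- matrix(0, H %/% 2L, 2L * ncol(dyv))
      odd <- seq(1, ncol(d2), by = 2)
      d2[, odd] <- dyv * cache$t2
      d2[, odd + 1L] <- dyv * (!cache$t2)
      d1 <- as.numeric(d2)
      dx <- matrix(0, 2, length(d1))
      dx[1, ] <- d1 * cache$t1
      dx[2, ] <- d1 * (!cache$t1)
      dim(dx) <- c(H, W, C, N)
      list(dx = dx, g = list())
    })
}

nn_gap <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  list(type = "gap", out_shape = C, par = list(),
       fwd = function(par, x) {
         N <- dim(x)[4]
         y <- colMeans(matrix(x, nrow = H * W))
         dim(y) <- c(C, N)
         list(y = y, cache = N)
       },
       bwd = function(par, cache, dy) {
         N <- cache
         dx <- matrix(rep(as.numeric(dy) / (H * W), each = H * W), nrow = H * W)
         dim(dx) <- c(H, W, C, N)
         list(dx = dx, g = list())
       })
}

nn_flatten <- function(in_shape) {
  F <- prod(in_shape)
  list(type = "flatten", out_shape = F, par = list(),
       fwd = function(par, x) {
         d <- dim(x)
         dim(x) <- c(F, d[4])
         list(y = x, cache = d)
       },
       bwd = function(par, cache, dy) {
         dim(dy) <- cache
         list(dx = dy, g = list())
       })
}

nn_dense <- function(n_in, n_out, relu = FALSE) {
  par <- list(W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
              b = numeric(n_out))
  list(type = "dense", out_shape = n_out, par = par,
       fwd = function(par, x) {
         z <- par$W %*% x + par$b
         if (relu) {
           m <- z > 0
           list(y = z * m, cache = list(x = x, m = m))
         } else list(y = z, cache = list(x = x))
       },
       bwd = function(par, cache, dy) {
         if (relu) dy <- dy * cache$m
         list(dx = crossprod(par$W, dy),
              g = list(W = tcrossprod(dy, cache$x), b = rowSums(dy)))
       })
}

# residual block: relu(conv3x3 -> relu -> conv3x3 + shortcut)
nn_resblock <- function(in_shape, cout, stride = 1L) {
  cin <- in_shape[3]
  c1 <- nn_conv2d(in_shape, cout, 3L, stride = stride, pad = 1L)
  c2 <- nn_conv2d(c1$out_shape, cout, 3L, stride = 1L, pad = 1L)
  proj <- if (cin != cout || stride != 1L)
    nn_conv2d(in_shape, cout, 1L, stride = stride, pad = 0L) else NULL
  par <- list(c1 = c1$par, c2 = c2$par)
  if (!is.null(proj)) par$proj <- proj$par
  list(
    type = "resblock", out_shape = c2$out_shape, par = par,
    fwd = function(par, x) {
      f1 <- c1$fwd(par$c1, x)
      m1 <- f1$y > 0
      f2 <- c2$fwd(par$c2, f1$y * m1)
      sc <- if (is.null(proj)) list(y = x, cache = NULL)
            else proj$fwd(par$proj, x)
      z <- f2$y + sc$y
      m2 <- z > 0
      list(y = z * m2,
           cache = list(f1 = f1$cache, f2 = f2$cache, sc = sc$cache,
                        m1 = m1, m2 = m2))
    },
    bwd = function(par, cache, dy) {
      dz <- dy * cache$m2
      b2 <- c2$bwd(par$c2, cache$f2, dz)
      b1 <- c1$bwd(par$c1, cache$f1, b2$dx * cache$m1)
      g <- list(c1 = b1$g, c2 = b2$g)
      if (is.null(proj)) dx <- b1$dx + dz
      else {
        bs <- proj$bwd(par$proj, cache$sc, dz)
        dx <- b1$dx + bs$dx
        g$proj <- bs$g
      }
      list(dx = dx, g = g)
    })
}

# inception block: relu'd 1x1, 3x3 and 5x5 branches, channel-concatenated
nn_inception <- function(in_shape, c1, c3, c5) {
  b1 <- nn_conv2d(in_shape, c1, 1L, pad = 0L)
  b3 <- nn_conv2d(in_shape, c3, 3L, pad = 1L)
  b5 <- nn_conv2d(in_shape, c5, 5L, pad = 2L)
  splits <- c(c1, c3, c5)
  list(
    type = "inception",
    out_shape = c(in_shape[1], in_shape[2], sum(splits)),
    par = list(b1 = b1$par, b3 = b3$par, b5 = b5$par),
    fwd = function(par, x) {
      f1 <- b1$fwd(par$b1, x); f3 <- b3$fwd(par$b3, x); f5 <- b5$fwd(par$b5, x)
      m1 <- f1$y > 0; m3 <- f3$y > 0; m5 <- f5$y > 0
      y <- array(0, dim = c(in_shape[1], in_shape[2], sum(splits), dim(x)[4]))
      y[, , seq_len(c1), ] <- f1$y * m1
      y[, , c1 + seq_len(c3), ] <- f3$y * m3
      y[, , c1 + c3 + seq_len(c5), ] <- f5$y * m5
      list(y = y, cache = list(f1 = f1$cache, f3 = f3$cache, f5 = f5$cache,
                               m1 = m1, m3 = m3, m5 = m5))
    },
    bwd = function(par, cache, dy) {
      d1 <- dy[, , seq_len(c1), , drop = FALSE] * cache$m1
      d3 <- dy[, , c1 + seq_len(c3), , drop = FALSE] * cache$m3
      d5 <- dy[, , c1 + c3 + seq_len(c5), , drop = FALSE] * cache$m5
      g1 <- b1$bwd(par$b1, cache$f1, d1)
      g3 <- b3$bwd(par$b3, cache$f3, d3)
      g5 <- b5$bwd(par$b5, cache$f5, d5)
      list(dx = g1$dx + g3$dx + g5$dx,
           g = list(b1 = g1$g, b3 = g3$g, b5 = g5$g))
    })
}

# attention block: residual trunk modulated by (1 + sigmoid soft mask)
nn_attention <- function(in_shape) {
  trunk <- nn_resblock(in_shape, in_shape[3], stride = 1L)
  mask <- nn_conv2d(in_shape, in_shape[3], 1L, pad = 0L)
  list(
    type = "attention", out_shape = in_shape,
    par = list(trunk = trunk$par, mask = mask$par),
    fwd = function(par, x) {
      ft <- trunk$fwd(par$trunk, x)
      fm <- mask$fwd(par$mask, x)
      s <- 1 / (1 + exp(-fm$y))
      list(y = ft$y * (1 + s),
           cache = list(ft = ft$cache, fm = fm$cache, s = s, t = ft$y))
    },
    bwd = function(par, cache, dy) {
      dt <- dy * (1 + cache$s)
      ds <- dy * cache$t * cache$s * (1 - cache$s)
      bt <- trunk$bwd(par$trunk, cache$ft, dt)
      bm <- mask$bwd(par$mask, cache$fm, ds)
      list(dx = bt$dx + bm$dx, g = list(trunk = bt$g, mask = bm$g))
    })
}

# sequential container ---------------------------------------------------------

nn_sequential <- function(layers) {
  list(layers = layers, par = lapply(layers, `[[`, "par"))
}

nn_forward <- function(net, par, x, upto = length(net$layers)) {
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    f <- net$layers[[i]]$fwd(par[[i]], x)
    x <- f$y
    caches[[i]] <- f$cache
  }
  list(y = x, caches = caches)
}

nn_backward <- function(net, par, caches, dy) {
  n <- length(net$layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    b <- net$layers[[i]]$bwd(par[[i]], caches[[i]], dy)
    grads[[i]] <- b$g
    dy <- b$dx
  }
  list(dx = dy, grads = grads)
}

# Adam ------------------------------------------------------------------------

adam_init <- function(par) list(m = tree_zero(par), v = tree_zero(par), t = 0L)

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  if (weight_decay > 0) grads <- tree_map(function(g, p) g + weight_decay * p,
                                          grads, par)
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  state$m, state$v)
  list(par = tree_map(`-`, par, upd), state = state)
}
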
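# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately written as plain per-voxel / per-pair loops so they share no
# code with the package implementations they check.

.fixtures <- new.env(parent = emptyenv())

cached_cohort <- function(n_per_class, seed, ...) {
  key <- paste0("cohort_", n_per_class, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_cohort(
      phantom_spec(n_per_class = n_per_class, seed = seed, ...))
  .fixtures[[key]]
}

random_volume <- function(dims, seed) {
  set.seed(seed)
  array(runif(prod(dims)), dim = dims)
}

# --- volume LBP oracle: explicit per-voxel bit enumeration -------------------
oracle_lbp <- function(v, L = 1, P = 4, R = 1) {
  d <- dim(v)
  th <- 2 * pi * (seq_len(P) - 1) / P
  offs <- cbind(R * cos(th), R * sin(th))
  offs[abs(offs) < 1e-9] <- 0
  samp <- function(r, c, s) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    if (fr < 1e-12 && fc < 1e-12) return(v[r0, c0, s])
    (1 - fr) * (1 - fc) * v[r0, c0, s] + (1 - fr) * fc * v[r0, c0 + 1, s] +
      fr * (1 - fc) * v[r0 + 1, c0, s] + fr * fc * v[r0 + 1, c0 + 1, s]
  }
  m <- ceiling(R)
  h <- numeric(2^(3 * P + 2))
  for (s in (L + 1):(d[3] - L)) for (i in (m + 1):(d[1] - m))
    for (j in (m + 1):(d[2] - m)) {
      gc <- v[i, j, s]
      bits <- c(v[i, j, s - L] >= gc)
      for (ds in c(-L, 0, L)) for (p in seq_len(P))
        bits <- c(bits, samp(i + offs[p, 1], j + offs[p, 2], s + ds) >= gc)
      bits <- c(bits, v[i, j, s + L] >= gc)
      pat <- sum(bits * 2^(seq_along(bits) - 1))
      h[pat + 1] <- h[pat + 1] + 1
    }
  h / sum(h)
}

# --- 3D HOG oracle: per-voxel vote loop --------------------------------------
oracle_hog <- function(v, cell = c(8, 8, 4), ib = 8, eb = 4) {
  d <- dim(v)
  ncell <- d %/% cell
  h <- numeric(prod(ncell) * ib * eb)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    gx <- if (i > 1 && i < d[1]) (v[i + 1, j, k] - v[i - 1, j, k]) / 2 else 0
    gy <- if (j > 1 && j < d[2]) (v[i, j + 1, k] - v[i, j - 1, k]) / 2 else 0
    gz <- if (k > 1 && k < d[3]) (v[i, j, k + 1] - v[i, j, k - 1]) / 2 else 0
    mag <- sqrt(gx^2 + gy^2 + gz^2)
    if (mag == 0) next
    az <- atan2(gy, gx) %% pi
    el <- atan2(gz, sqrt(gx^2 + gy^2))
    azb <- min(floor(az / (pi / ib)), ib - 1)
    elb <- min(floor((el + pi / 2) / (pi / eb)), eb - 1)
    cellid <- (i - 1) %/% cell[1] +
      ncell[1] * ((j - 1) %/% cell[2] + ncell[2] * ((k - 1) %/% cell[3]))
    idx <- 1 + azb + ib * (elb + eb * cellid)
    h[idx] <- h[idx] + mag
  }
  if (sum(h^2) > 0) h <- h / sqrt(sum(h^2))
  h
}

# --- GLCM oracle: per-pair loop for one direction/distance -------------------
oracle_glcm <- function(v, G, dir, dist) {
  lo <- min(v); hi <- max(v)
  if (lo >= -1e-9 && hi <= 1 + 1e-9) { lo <- 0; hi <- 1 }
  q <- if (hi - lo < 1e-12) array(1L, dim = dim(v))
       else pmin(floor((v - lo) / (hi - lo) * G) + 1L, G)
  q <- array(as.integer(q), dim = dim(v))
  d <- dim(v)
  off <- dir * dist
  M <- matrix(0, G, G)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
    M[q[i, j, k], q[i2, j2, k2]] <- M[q[i, j, k], q[i2, j2, k2]] + 1
    M[q[i2, j2, k2], q[i, j, k]] <- M[q[i2, j2, k2], q[i, j, k]] + 1
  }
  p <- M / sum(M)
  dfm <- outer(seq_len(G), seq_len(G), `-`)
  c(energy = sum(p^2),
    entropy = -sum(ifelse(p > 0, p * log(p), 0)),
    contrast = sum(dfm^2 * p),
    homogeneity = sum(p / (1 + abs(dfm))))
}

# --- two-layer GCN oracle: literal propagation-rule evaluation ---------------
oracle_gcn <- function(H0, A, W0, W1) {
  At <- A + diag(nrow(A))
  D <- diag(rowSums(At))
  Dh <- diag(1 / sqrt(diag(D)))
  P <- Dh %*% At %*% Dh
  relu <- function(m) pmax(m, 0)
  H1 <- relu(P %*% H0 %*% W0)
  H2 <- relu(P %*% H1 %*% W1)
  as.numeric(t(H2))
}

# --- AUC oracle: full double loop over pairs ---------------------------------
oracle_auc <- function(pos, neg, half = FALSE) {
  s <- 0
  for (n0 in neg) for (p1 in pos) {
    if (n0 < p1) s <- s + 1
    else if (half && n0 == p1) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# small deterministic config for pipeline smoke tests
smoke_config <- function(epochs = 2L, steps = 30L) {
  rgd_config(opt = optimizer_config(lr = 3e-3, weight_decay = 1e-4,
                                    max_epochs = epochs),
             head_steps = steps, k = 2L)
}
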
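# Sequence-aware neural architectures, implemented from first principles.
#
# The three deep families share a tiny training core (minibatch Adam on a
# mean-squared-error loss) and explicit analytic forward/backward passes:
#
#   conv      1-D convolutions (kernel 3, zero-padded) along the 10 key
#             myotomes, modality channels plus broadcast scalar covariates,
#             per-position linear head emitting left/right scores.
#   attention encoder embeds each myotome position; 10 learned queries (one
#             per output level) attend over the encoded acute sequence via
#             scaled dot-product softmax; per-position head emits both sides.
#   graph     message passing on the 20-node myotome graph (chain edges
#             within a side over consecutive key muscles, left-right cross
#             edges, self loops; symmetrically normalized adjacency).
#
# All parameter counts are well below 10^5; training on a few thousand
# instances takes seconds on one CPU.

relu <- function(x) x * (x > 0)

# ---- input preparation ---------------------------------------------------

# fixed feature scalings: scores to [0,1], times/age/level index to O(1)
nn_prepare <- function(X) {
  n <- nrow(X)
  lv <- KEY_MUSCLES
  seqarr <- array(0, c(n, 10L, 6L))
  for (p in seq_along(lv)) {
    seqarr[, p, 1] <- X[, paste0("ms_", lv[p], "_left")] / 5
    seqarr[, p, 2] <- X[, paste0("ms_", lv[p], "_right")] / 5
    seqarr[, p, 3] <- X[, paste0("lt_", lv[p], "_left")] / 2
    seqarr[, p, 4] <- X[, paste0("lt_", lv[p], "_right")] / 2
    seqarr[, p, 5] <- X[, paste0("pp_", lv[p], "_left")] / 2
    seqarr[, p, 6] <- X[, paste0("pp_", lv[p], "_right")] / 2
  }
  scal <- cbind(X[, "age"] / 80, X[, "sex_female"], X[, "early_dai"] / 100,
                X[, "late_dai"] / 300, X[, "ais_A"], X[, "ais_B"],
                X[, "ais_C"], X[, "ais_D"], X[, "vac"], X[, "dap"],
                X[, "nli_index"] / 27)
  list(seqarr = seqarr, scal = scal, n = n)
}

# position-wise input for conv/attention: 6 sequence channels + 11 scalars
nn_position_input <- function(prep) {
  n <- prep$n
  arr <- array(0, c(n, 10L, 17L))
  arr[, , 1:6] <- prep$seqarr
  for (p in 1:10) arr[, p, 7:17] <- prep$scal
  arr
}

# node input for the graph net: own-coordinate ms/lt/pp + 11 scalars
nn_node_input <- function(prep) {
  n <- prep$n
  arr <- array(0, c(n, 20L, 14L))
  for (p in 1:10) {
    for (s in 1:2) {
      j <- (p - 1L) * 2L + s
      arr[, j, 1] <- prep$seqarr[, p, s]        # ms (left=1/right=2 channel)
      arr[, j, 2] <- prep$seqarr[, p, 2 + s]    # lt
      arr[, j, 3] <- prep$seqarr[, p, 4 + s]    # pp
      arr[, j, 4:14] <- prep$scal
    }
  }
  arr
}

# symmetrically normalized adjacency of the myotome graph
myotome_graph_adjacency <- function() {
  A <- matrix(0, 20, 20)
  node <- function(p, s) (p - 1L) * 2L + s
  for (p in 1:9) for (s in 1:2) {
    A[node(p, s), node(p + 1L, s)] <- 1
    A[node(p + 1L, s), node(p, s)] <- 1
  }
  for (p in 1:10) {
    A[node(p, 1L), node(p, 2L)] <- 1
    A[node(p, 2L), node(p, 1L)] <- 1
  }
  A <- A + diag(20)
  d <- 1 / sqrt(rowSums(A))
  A * outer(d, d)
}

he_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)

# ---- conv ----------------------------------------------------------------

arch_conv <- function(hidden) {
  Cin <- 17L; P <- 10L
  list(
    prep = function(X) nn_position_input(nn_prepare(X)),
    slice = function(inp, idx) inp[idx, , , drop = FALSE],
    init = function() {
      list(W1a = he_init(Cin, hidden), W1b = he_init(Cin, hidden),
           W1c = he_init(Cin, hidden), b1 = numeric(hidden),
           W2a = he_init(hidden, hidden), W2b = he_init(hidden, hidden),
           W2c = he_init(hidden, hidden), b2 = numeric(hidden),
           W3 = he_init(hidden, 2L), b3 = numeric(2L))
    },
    forward = function(pa, inp) {
      n <- dim(inp)[1]
      conv <- function(src, Wa, Wb, Wc, b) {
        Cout <- length(b)
        Z <- array(0, c(n, P, Cout))
        for (p in 1:P) {
          acc <- matrix(b, n, Cout, byrow = TRUE)
          if (p > 1) acc <- acc + matrix(src[, p - 1, ], n) %*% Wa
          acc <- acc + matrix(src[, p, ], n) %*% Wb
          if (p < P) acc <- acc + matrix(src[, p + 1, ], n) %*% Wc
          Z[, p, ] <- acc
        }
        Z
      }
      Z1 <- conv(inp, pa$W1a, pa$W1b, pa$W1c, pa$b1); A1 <- relu(Z1)
      Z2 <- conv(A1, pa$W2a, pa$W2b, pa$W2c, pa$b2); A2 <- relu(Z2)
      yhat <- matrix(0, n, 20L)
      for (p in 1:P) {
        yhat[, (p - 1L) * 2L + 1:2] <- matrix(A2[, p, ], n) %*% pa$W3 +
          matrix(pa$b3, n, 2, byrow = TRUE)
      }
      list(yhat = yhat, cache = list(inp = inp, Z1 = Z1, A1 = A1,
                                     Z2 = Z2, A2 = A2, n = n))
    },
    backward = function(pa, cache, dY) {
      n <- cache$n
      g <- lapply(pa, function(x) x * 0)
      dA2 <- array(0, dim(cache$A2))
      for (p in 1:P) {
        dO <- dY[, (p - 1L) * 2L + 1:2, drop = FALSE]
        g$W3 <- g$W3 + t(matrix(cache$A2[, p, ], n)) %*% dO
        g$b3 <- g$b3 + colSums(dO)
        dA2[, p, ] <- dO %*% t(pa$W3)
      }
      dZ2 <- dA2 * (cache$Z2 > 0)
      dA1 <- array(0, dim(cache$A1))
      for (p in 1:P) {
        d <- matrix(dZ2[, p, ], n)
        g$b2 <- g$b2 + colSums(d)
        if (p > 1) {
          g$W2a <- g$W2a + t(matrix(cache$A1[, p - 1, ], n)) %*% d
          dA1[, p - 1, ] <- dA1[, p - 1, ] + d %*% t(pa$W2a)
        }
        g$W2b <- g$W2b + t(matrix(cache$A1[, p, ], n)) %*% d
        dA1[, p, ] <- dA1[, p, ] + d %*% t(pa$W2b)
        if (p < P) {
          g$W2c <- g$W2c + t(matrix(cache$A1[, p + 1, ], n)) %*% d
          dA1[, p + 1, ] <- dA1[, p + 1, ] + d %*% t(pa$W2c)
        }
      }
      dZ1 <- dA1 * (cache$Z1 > 0)
      for (p in 1:P) {
        d <- matrix(dZ1[, p, ], n)
        g$b1 <- g$b1 + colSums(d)
        if (p > 1) g$W1a <- g$W1a + t(matrix(cache$inp[, p - 1, ], n)) %*% d
        g$W1b <- g$W1b + t(matrix(cache$inp[, p, ], n)) %*% d
        if (p < P) g$W1c <- g$W1c + t(matrix(cache$inp[, p + 1, ], n)) %*% d
      }
      g
    })
}

# ---- attention -----------------------------------------------------------

arch_attention <- function(hidden) {
  Cin <- 17L; P <- 10L
  list(
    prep = function(X) nn_position_input(nn_prepare(X)),
    slice = function(inp, idx) inp[idx, , , drop = FALSE],
    init = function() {
      list(We = he_init(Cin, hidden), be = numeric(hidden),
           posE = he_init(P, hidden) * 0.3,
           Q = he_init(P, hidden),
           Wo = he_init(hidden, 2L), bo = numeric(2L))
    },
    forward = function(pa, inp) {
      n <- dim(inp)[1]
      Zc <- array(0, c(n, P, hidden)); E <- Zc
      for (p in 1:P) {
        Zc[, p, ] <- matrix(inp[, p, ], n) %*% pa$We +
          matrix(pa$be + pa$posE[p, ], n, hidden, byrow = TRUE)
      }
      E <- relu(Zc)
      scl <- 1 / sqrt(hidden)
      S <- array(0, c(n, P, P))   # [instance, output position, input position]
      for (o in 1:P) for (p in 1:P) {
        S[, o, p] <- (matrix(E[, p, ], n) %*% pa$Q[o, ]) * scl
      }
      A <- array(0, dim(S))
      for (o in 1:P) {
        So <- matrix(S[, o, ], n)
        So <- exp(So - apply(So, 1, max))
        A[, o, ] <- So / rowSums(So)
      }
      Ctx <- array(0, c(n, P, hidden))
      for (o in 1:P) for (p in 1:P) {
        Ctx[, o, ] <- Ctx[, o, ] + A[, o, p] * matrix(E[, p, ], n)
      }
      yhat <- matrix(0, n, 20L)
      for (o in 1:P) {
        yhat[, (o - 1L) * 2L + 1:2] <- matrix(Ctx[, o, ], n) %*% pa$Wo +
          matrix(pa$bo, n, 2, byrow = TRUE)
      }
      list(yhat = yhat, cache = list(inp = inp, Zc = Zc, E = E, A = A,
                                     Ctx = Ctx, n = n, scl = scl))
    },
    backward = function(pa, cache, dY) {
      n <- cache$n
      g <- lapply(pa, function(x) x * 0)
      E <- cache$E; A <- cache$A
      dE <- array(0, dim(E))
      for (o in 1:P) {
        dO <- dY[, (o - 1L) * 2L + 1:2, drop = FALSE]
        g$Wo <- g$Wo + t(matrix(cache$Ctx[, o, ], n)) %*% dO
        g$bo <- g$bo + colSums(dO)
        dCtx <- dO %*% t(pa$Wo)                              # n x hidden
        dA_o <- matrix(0, n, P)
        for (p in 1:P) {
          dA_o[, p] <- rowSums(dCtx * matrix(E[, p, ], n))
          dE[, p, ] <- dE[, p, ] + A[, o, p] * dCtx
        }
        Ao <- matrix(A[, o, ], n)
        dS_o <- Ao * (dA_o - rowSums(dA_o * Ao))
        for (p in 1:P) {
          dE[, p, ] <- dE[, p, ] + (dS_o[, p] %o% pa$Q[o, ]) * cache$scl
          g$Q[o, ] <- g$Q[o, ] + colSums(matrix(E[, p, ], n) * dS_o[, p]) * cache$scl
        }
      }
      dZc <- dE * (cache$Zc > 0)
      for (p in 1:P) {
        d <- matrix(dZc[, p, ], n)
        g$We <- g$We + t(matrix(cache$inp[, p, ], n)) %*% d
        g$be <- g$be + colSums(d)
        g$posE[p, ] <- g$posE[p, ] + colSums(d)
      }
      g
    })
}

# ---- graph ---------------------------------------------------------------

arch_graph <- function(hidden) {
  Cin <- 14L; N <- 20L
  Ahat <- myotome_graph_adjacency()
  mix_flat <- function(Fl, n) {
    out <- Fl
    for (cc in seq_len(ncol(Fl))) {
      out[, cc] <- as.vector(matrix(Fl[, cc], n, N) %*% Ahat)  # Ahat symmetric
    }
    out
  }
  list(
    prep = function(X) nn_node_input(nn_prepare(X)),
    slice = function(inp, idx) inp[idx, , , drop = FALSE],
    init = function() {
      list(W1 = he_init(Cin, hidden), b1 = numeric(hidden),
           W2 = he_init(hidden, hidden), b2 = numeric(hidden),
           w3 = he_init(hidden, 1L), b3 = 0)
    },
    forward = function(pa, inp) {
      n <- dim(inp)[1]
      M0 <- mix_flat(matrix(inp, n * N), n)
      Z1 <- sweep(M0 %*% pa$W1, 2, pa$b1, `+`); A1 <- relu(Z1)
      M1 <- mix_flat(A1, n)
      Z2 <- sweep(M1 %*% pa$W2, 2, pa$b2, `+`); A2 <- relu(Z2)
      yhat <- matrix(A2 %*% pa$w3 + pa$b3, n, N)
      list(yhat = yhat,
           cache = list(M0 = M0, Z1 = Z1, A1 = A1, M1 = M1, Z2 = Z2,
                        A2 = A2, n = n))
    },
    backward = function(pa, cache, dY) {
      n <- cache$n
      g <- lapply(pa, function(x) x * 0)
      dyvec <- matrix(as.vector(dY), n * N, 1)
      g$w3 <- t(cache$A2) %*% dyvec
      g$b3 <- sum(dyvec)
      dA2 <- dyvec %*% t(pa$w3)
      dZ2 <- dA2 * (cache$Z2 > 0)
      g$W2 <- t(cache$M1) %*% dZ2
      g$b2 <- colSums(dZ2)
      dM1 <- dZ2 %*% t(pa$W2)
      dA1 <- mix_flat(dM1, n)
      dZ1 <- dA1 * (cache$Z1 > 0)
      g$W1 <- t(cache$M0) %*% dZ1
      g$b1 <- colSums(dZ1)
      g
    })
}

nn_arch <- function(kind, hidden) {
  switch(kind,
         conv = arch_conv(hidden),
         attention = arch_attention(hidden),
         graph = arch_graph(hidden))
}

# ---- Adam trainer --------------------------------------------------------

adam_step <- function(pa, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(pa)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^t)
    vhat <- st$v[[k]] / (1 - beta2^t)
    pa[[k]] <- pa[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(pa = pa, st = st)
}

fit_nn <- function(spec, train, kind) {
  X <- encode_instances(train)
  Y <- target_matrix(train)
  hidden <- as.integer(hp(spec, "hidden", 32L))
  epochs <- as.integer(hp(spec, "epochs",
                          switch(kind, conv = 60L, attention = 80L, graph = 80L)))
  batch <- as.integer(hp(spec, "batch_size", 64L))
  lr <- hp(spec, "lr", 0.005)
  arch <- nn_arch(kind, hidden)
  inp <- arch$prep(X)
  pa <- arch$init()
  st <- list(m = lapply(pa, function(x) x * 0), v = lapply(pa, function(x) x * 0))
  n <- nrow(Y)
  tstep <- 0L
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      fw <- arch$forward(pa, arch$slice(inp, idx))
      err <- fw$yhat - Y[idx, , drop = FALSE]
      losses <- c(losses, mean(err^2))
      dY <- 2 * err / length(err)
      g <- arch$backward(pa, fw$cache, dY)
      tstep <- tstep + 1L
      upd <- adam_step(pa, g, st, lr, tstep)
      pa <- upd$pa; st <- upd$st
    }
    loss_curve[ep] <- mean(losses)
  }
  list(kind = kind, hidden = hidden, params = pa, loss_curve = loss_curve)
}

predict_nn <- function(fit, X) {
  arch <- nn_arch(fit$kind, fit$hidden)
  arch$forward(fit$params, arch$prep(X))$yhat
}
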
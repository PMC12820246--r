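# Minimal neural-network engine: dense, convolution (any spatial rank, via
# im2col with precomputed gather/scatter indices), max pooling, LSTM,
# layer normalization, gated linear units, dropout, and Adam.  Forward
# functions return a cache consumed by the matching backward function; all
# math is base R matrix algebra so gradients are exact and auditable.

## ---- initialization ----

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

xavier_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
}

## ---- dense ----

dense_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), X = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W),
       dW = t(cache$X) %*% dY,
       db = colSums(dY))
}

## ---- elementwise ----

relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_bwd <- function(dY, cache) dY * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# Inverted dropout: active only when training; expectation-preserving.
dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  keep <- array(stats::runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(out = X * keep, mask = keep)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

## ---- softmax / losses ----

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---- convolution (generic spatial rank) ----

# Precompute im2col geometry for input of spatial shape `in_shape` with
# `c_in` channels, kernel `k` (scalar, applied per axis), stride 1, valid
# padding.  Input items are stored flattened channel-fastest:
# index = channel + c_in * (pos1 + s1*(pos2 + s2*pos3)) style (column-major
# over spatial dims, channel innermost).
conv_geom <- function(in_shape, c_in, k) {
  rank <- length(in_shape)
  out_shape <- in_shape - k + 1
  if (any(out_shape < 1)) stop("input smaller than kernel", call. = FALSE)
  # spatial offsets of the kernel
  off <- as.matrix(do.call(expand.grid, rep(list(0:(k - 1)), rank)))
  # output positions (1-based starts)
  pos <- as.matrix(do.call(expand.grid, lapply(out_shape, seq_len)))
  stridev <- cumprod(c(1, in_shape))[seq_len(rank)]
  lin <- function(coords) as.vector((coords - 1) %*% stridev)  # 0-based spatial
  n_pos <- nrow(pos)
  n_off <- nrow(off)
  # idx_arr[kidx, p]: flattened input index (1-based) over channels x offsets
  spatial0 <- outer(lin(off + 1), lin(pos), `+`)               # n_off x n_pos
  idx <- array(0L, dim = c(c_in, n_off, n_pos))
  for (ch in seq_len(c_in))
    idx[ch, , ] <- spatial0 * c_in + ch
  idx_arr <- matrix(as.integer(idx), nrow = c_in * n_off, ncol = n_pos)
  list(idx_vec = as.vector(idx_arr), idx_arr = idx_arr, n_pos = n_pos,
       cols = c_in * n_off, out_shape = out_shape,
       in_len = prod(in_shape) * c_in)
}

# im2col gather: rows ordered item-fastest (row = item + (pos-1)*n), columns
# are the c_in * k^rank receptive-field entries.  Precomputable when the
# layer input is fixed (the data layer), in which case `conv_fwd` takes it
# via `A`.
conv_im2col <- function(X_flat, geom) {
  n <- nrow(X_flat)
  A <- matrix(0, n * geom$n_pos, geom$cols)
  if (geom$cols <= geom$n_pos) {
    for (k in seq_len(geom$cols))
      A[, k] <- X_flat[, geom$idx_arr[k, ]]
  } else {
    # few positions, wide receptive fields: gather per position instead
    for (p in seq_len(geom$n_pos))
      A[(p - 1L) * n + seq_len(n), ] <- X_flat[, geom$idx_arr[, p]]
  }
  A
}

# X_flat: nitems x in_len (channel-fastest layout).  W: (c_in*k^rank) x F.
# Returns out: nitems x (n_pos * F) with channel(F)-fastest layout, matching
# conv_geom's input convention so layers chain.  `A` short-circuits the
# gather with a precomputed im2col matrix (rows = items of this batch,
# item-fastest ordering).
conv_fwd <- function(X_flat, W, b, geom, A = NULL) {
  if (is.null(A)) {
    A <- conv_im2col(X_flat, geom)
    n <- nrow(X_flat)
  } else {
    n <- nrow(A) / geom$n_pos
  }
  Y <- A %*% W + rep(b, each = nrow(A))              # (n*n_pos) x F
  f <- ncol(W)
  out <- matrix(aperm(array(Y, dim = c(n, geom$n_pos, f)), c(1, 3, 2)),
                n, f * geom$n_pos)
  list(out = out, A = A, n = n)
}

# need_dX = FALSE skips the input-gradient scatter (data layers).
conv_bwd <- function(dOut, cache, W, geom, scatter = NULL, need_dX = TRUE) {
  n <- cache$n
  f <- ncol(W)
  dY <- matrix(aperm(array(dOut, dim = c(n, f, geom$n_pos)), c(1, 3, 2)),
               n * geom$n_pos, f)
  dW <- crossprod(cache$A, dY)
  db <- colSums(dY)
  dX <- NULL
  if (need_dX) {
    dA <- dY %*% t(W)                                # (n*n_pos) x cols
    dA_mat <- matrix(aperm(array(dA, dim = c(n, geom$n_pos, geom$cols)),
                           c(1, 3, 2)), n, geom$cols * geom$n_pos)
    dX <- as.matrix(dA_mat %*% scatter)              # n x in_len
  }
  list(dX = dX, dW = dW, db = db)
}

# Sparse scatter matrix mapping im2col columns back to input positions.
conv_scatter <- function(geom) {
  Matrix::sparseMatrix(i = seq_along(geom$idx_vec), j = geom$idx_vec,
                       x = 1, dims = c(length(geom$idx_vec), geom$in_len))
}

## ---- max pooling (non-overlapping, window w per axis) ----

pool_geom <- function(in_shape, c_in, w) {
  rank <- length(in_shape)
  out_shape <- in_shape %/% w
  pos <- as.matrix(do.call(expand.grid, lapply(out_shape, function(m)
    seq(1, by = w, length.out = m))))
  off <- as.matrix(do.call(expand.grid, rep(list(0:(w - 1)), rank)))
  stridev <- cumprod(c(1, in_shape))[seq_len(rank)]
  lin <- function(coords) as.vector((coords - 1) %*% stridev)
  spatial0 <- outer(lin(off + 1), lin(pos), `+`)       # n_off x n_pos
  n_pos <- nrow(pos); n_off <- nrow(off)
  # per window offset: flattened column indices (channel-fastest per position)
  idx_list <- lapply(seq_len(n_off), function(o)
    rep(spatial0[o, ], each = c_in) * c_in + seq_len(c_in))
  list(idx_list = idx_list, n_pos = n_pos, n_off = n_off, c_in = c_in,
       out_shape = out_shape, in_len = prod(in_shape) * c_in)
}

pool_fwd <- function(X_flat, geom) {
  n <- nrow(X_flat)
  ncols <- geom$c_in * geom$n_pos
  best <- matrix(-Inf, n, ncols)
  arg <- matrix(1L, n, ncols)
  cols_o <- geom$idx_list
  for (o in seq_len(geom$n_off)) {
    cand <- X_flat[, cols_o[[o]], drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    arg[upd] <- o
  }
  list(out = best, arg = arg, cols_o = cols_o)
}

pool_bwd <- function(dOut, cache, geom, n, in_len) {
  dX <- matrix(0, n, in_len)
  for (o in seq_len(geom$n_off)) {
    mask <- cache$arg == o
    dX[, cache$cols_o[[o]]] <- dX[, cache$cols_o[[o]]] + dOut * mask
  }
  dX
}

## ---- LSTM ----

lstm_init <- function(d_in, h) {
  list(W = xavier_init(d_in + h, 4 * h), b = rep(0, 4 * h))
}

# X: n x t x d array.  Returns H: n x t x h.
lstm_fwd <- function(X, W, b) {
  n <- dim(X)[1]; t_len <- dim(X)[2]; d <- dim(X)[3]
  h <- ncol(W) / 4
  Hs <- array(0, dim = c(n, t_len, h))
  caches <- vector("list", t_len)
  h_prev <- matrix(0, n, h); c_prev <- matrix(0, n, h)
  for (s in seq_len(t_len)) {
    xt <- matrix(X[, s, ], n, d)
    zin <- cbind(xt, h_prev)
    z <- zin %*% W + rep(b, each = n)
    i <- sigmoid(z[, 1:h, drop = FALSE])
    f <- sigmoid(z[, h + 1:h, drop = FALSE])
    g <- tanh(z[, 2 * h + 1:h, drop = FALSE])
    o <- sigmoid(z[, 3 * h + 1:h, drop = FALSE])
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    caches[[s]] <- list(zin = zin, i = i, f = f, g = g, o = o,
                        c_prev = c_prev, c_t = c_t, tc = tc)
    Hs[, s, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(out = Hs, caches = caches, d = d, h = h)
}

# dH: n x t x h gradient on every time step's output.
lstm_bwd <- function(dH, cache, W) {
  t_len <- length(cache$caches)
  h <- cache$h; d <- cache$d
  n <- dim(dH)[1]
  dW <- matrix(0, nrow(W), ncol(W)); db <- rep(0, ncol(W))
  dX <- array(0, dim = c(n, t_len, d))
  dh_next <- matrix(0, n, h); dc_next <- matrix(0, n, h)
  for (s in rev(seq_len(t_len))) {
    cc <- cache$caches[[s]]
    dh <- matrix(dH[, s, ], n, h) + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + t(cc$zin) %*% dz
    db <- db + colSums(dz)
    dzin <- dz %*% t(W)
    dX[, s, ] <- dzin[, 1:d, drop = FALSE]
    dh_next <- dzin[, d + 1:h, drop = FALSE]
    dc_next <- dc * cc$f
  }
  list(dX = dX, dW = dW, db = db)
}

# Bidirectional wrapper: forward pass + backward pass on the time-reversed
# sequence with its own weights; outputs concatenated per step.
bilstm_fwd <- function(X, Wf, bf, Wb, bb) {
  fw <- lstm_fwd(X, Wf, bf)
  Xr <- X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  bw <- lstm_fwd(Xr, Wb, bb)
  Hb <- bw$out[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  n <- dim(X)[1]; t_len <- dim(X)[2]; h <- fw$h
  out <- array(0, dim = c(n, t_len, 2 * h))
  out[, , 1:h] <- fw$out
  out[, , h + 1:h] <- Hb
  list(out = out, fw = fw, bw = bw, h = h)
}

bilstm_bwd <- function(dH, cache, Wf, Wb) {
  h <- cache$h
  t_len <- dim(dH)[2]
  dHf <- dH[, , 1:h, drop = FALSE]
  dHb <- dH[, , h + 1:h, drop = FALSE]
  g_f <- lstm_bwd(dHf, cache$fw, Wf)
  g_b <- lstm_bwd(dHb[, rev(seq_len(t_len)), , drop = FALSE], cache$bw, Wb)
  dX <- g_f$dX + g_b$dX[, rev(seq_len(t_len)), , drop = FALSE]
  list(dX = dX, dWf = g_f$dW, dbf = g_f$db, dWb = g_b$dW, dbb = g_b$db)
}

## ---- layer norm ----

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(out = out, xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dY, cache, gamma) {
  n <- nrow(dY); d <- ncol(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = n)
  dX <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- GLU ----

glu_fwd <- function(X, W, b) {
  u <- X %*% W + rep(b, each = nrow(X))
  w <- ncol(W) / 2
  a <- u[, 1:w, drop = FALSE]
  g <- sigmoid(u[, w + 1:w, drop = FALSE])
  list(out = a * g, X = X, a = a, g = g, w = w)
}

glu_bwd <- function(dY, cache, W) {
  da <- dY * cache$g
  dgate <- dY * cache$a * cache$g * (1 - cache$g)
  du <- cbind(da, dgate)
  list(dX = du %*% t(W), dW = t(cache$X) %*% du, db = colSums(du))
}

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

# Applies one Adam step in place on `params` given `grads`; `clip` is the
# global gradient-norm ceiling applied before the update.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1.0) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(clip) && gnorm > clip)
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  state$t <- state$t + 1
  bc1 <- 1 - 0.9^state$t
  bc2 <- 1 - 0.999^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state, gnorm = gnorm)
}
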
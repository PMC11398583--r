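# Minimal dense neural-network primitives with hand-derived backpropagation.
#
# Conventions:
#  * feature maps are numeric arrays (H, W, C), one sample at a time;
#  * token sequences are matrices (T, c);
#  * every *_fwd returns list(out, cache); every *_bwd takes the upstream
#    gradient plus the cache and returns list(dx, grads) where `grads`
#    mirrors the layer's parameter list.
# All state is explicit; nothing is hidden in environments, so a model is
# an ordinary named list of numeric arrays and is serializable with
# saveRDS()/dput().

## ---- im2col / col2im ------------------------------------------------------

nn_pad_zero <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

nn_im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  list(cols = cpp_im2col(x, d[1], d[2], d[3], k, stride, pad),
       ho = ho, wo = wo)
}

nn_col2im <- function(dcols, dims, k, stride, pad) {
  cpp_col2im(dcols, dims[1], dims[2], dims[3], k, stride, pad)
}

## ---- convolution ----------------------------------------------------------

# W: (k, k, Cin, Cout); b: length Cout
nn_conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  k <- dim(W)[1]
  im <- nn_im2col(x, k, stride, pad)
  wm <- matrix(W, k * k * dim(W)[3], dim(W)[4])
  y <- im$cols %*% wm
  y <- y + rep(b, each = nrow(y))
  list(out = array(y, c(im$ho, im$wo, dim(W)[4])),
       cache = list(cols = im$cols, dims_in = dim(x), k = k,
                    stride = stride, pad = pad, W = W))
}

nn_conv_bwd <- function(dy, cache) {
  d <- dim(dy)
  dym <- matrix(dy, d[1] * d[2], d[3])
  wm <- matrix(cache$W, cache$k * cache$k * cache$dims_in[3], d[3])
  dW <- array(crossprod(cache$cols, dym), dim(cache$W))
  db <- colSums(dym)
  dcols <- tcrossprod(dym, wm)
  dx <- nn_col2im(dcols, cache$dims_in, cache$k, cache$stride, cache$pad)
  list(dx = dx, grads = list(W = dW, b = db))
}

# Transposed 2x2 stride-2 convolution (exact 2x upsampling).
# W: (2, 2, Cin, Cout)
nn_convT_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- array(0, c(2L * d[1], 2L * d[2], dim(W)[4]))
  for (di in 1:2) {
    for (dj in 1:2) {
      Wm <- matrix(W[di, dj, , ], d[3], dim(W)[4])
      block <- xm %*% Wm
      out[di + 2L * (seq_len(d[1]) - 1L), dj + 2L * (seq_len(d[2]) - 1L), ] <-
        array(block, c(d[1], d[2], dim(W)[4]))
    }
  }
  out <- out + rep(b, each = 4L * d[1] * d[2])
  list(out = out, cache = list(x = x, W = W))
}

nn_convT_bwd <- function(dy, cache) {
  d <- dim(cache$x)
  co <- dim(cache$W)[4]
  xm <- matrix(cache$x, d[1] * d[2], d[3])
  dW <- array(0, dim(cache$W))
  dxm <- matrix(0, d[1] * d[2], d[3])
  db <- numeric(co)
  for (di in 1:2) {
    for (dj in 1:2) {
      sub <- dy[di + 2L * (seq_len(d[1]) - 1L),
                dj + 2L * (seq_len(d[2]) - 1L), , drop = FALSE]
      subm <- matrix(sub, d[1] * d[2], co)
      db <- db + colSums(subm)
      Wm <- matrix(cache$W[di, dj, , ], d[3], co)
      dW[di, dj, , ] <- crossprod(xm, subm)
      dxm <- dxm + tcrossprod(subm, Wm)
    }
  }
  list(dx = array(dxm, d), grads = list(W = dW, b = db))
}

## ---- normalization --------------------------------------------------------

# Group normalization over an (H, W, C) map; gamma/beta have length C.
nn_gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  stopifnot(d[3] %% groups == 0L)
  cg <- d[3] %/% groups
  xm <- matrix(x, d[1] * d[2], d[3])
  xhat <- xm
  sds <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- (g - 1L) * cg + seq_len(cg)
    mu <- mean(xm[, cols])
    v <- mean((xm[, cols] - mu)^2)
    sds[g] <- sqrt(v + eps)
    xhat[, cols] <- (xm[, cols] - mu) / sds[g]
  }
  y <- xhat * rep(gamma, each = d[1] * d[2]) + rep(beta, each = d[1] * d[2])
  list(out = array(y, d),
       cache = list(xhat = xhat, sds = sds, gamma = gamma,
                    groups = groups, cg = cg, d = d))
}

nn_gn_bwd <- function(dy, cache) {
  d <- cache$d
  npx <- d[1] * d[2]
  dym <- matrix(dy, npx, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(cache$gamma, each = npx)
  dxm <- matrix(0, npx, d[3])
  for (g in seq_len(cache$groups)) {
    cols <- (g - 1L) * cache$cg + seq_len(cache$cg)
    m1 <- mean(dxhat[, cols])
    m2 <- mean(dxhat[, cols] * xhat[, cols])
    dxm[, cols] <- (dxhat[, cols] - m1 - xhat[, cols] * m2) / cache$sds[g]
  }
  list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
}

# Row-wise layer norm on a (T, c) token matrix.
nn_ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  y <- sweep(xhat, 2, gamma, "*")
  y <- sweep(y, 2, beta, "+")
  list(out = y, cache = list(xhat = xhat, sd = sd, gamma = gamma))
}

nn_ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- pointwise nonlinearities --------------------------------------------

nn_relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
nn_relu_bwd <- function(dy, cache) dy * cache

nn_gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(out = x * ph, cache = list(x = x, ph = ph))
}
nn_gelu_bwd <- function(dy, cache) {
  dy * (cache$ph + cache$x * stats::dnorm(cache$x))
}

## ---- linear on token matrices ---------------------------------------------

nn_lin_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, "+")
  list(out = y, cache = list(x = x, W = W))
}

nn_lin_bwd <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

## ---- attention -------------------------------------------------------------

nn_softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# Multi-head attention of queries Q over keys/values from X.
# p: list(Wq, bq, Wk, bk, Wv, bv, Wo, bo); n_heads divides c.
nn_attn_fwd <- function(xq, xkv, p, n_heads) {
  cdim <- ncol(xq)
  dh <- cdim %/% n_heads
  Q <- nn_lin_fwd(xq, p$Wq, p$bq)
  K <- nn_lin_fwd(xkv, p$Wk, p$bk)
  V <- nn_lin_fwd(xkv, p$Wv, p$bv)
  O <- matrix(0, nrow(xq), cdim)
  Ss <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    ix <- (h - 1L) * dh + seq_len(dh)
    A <- tcrossprod(Q$out[, ix, drop = FALSE], K$out[, ix, drop = FALSE]) / sqrt(dh)
    S <- nn_softmax_rows(A)
    Ss[[h]] <- S
    O[, ix] <- S %*% V$out[, ix, drop = FALSE]
  }
  Y <- nn_lin_fwd(O, p$Wo, p$bo)
  list(out = Y$out,
       cache = list(Q = Q, K = K, V = V, O = O, Ss = Ss, Ycache = Y$cache,
                    n_heads = n_heads, dh = dh))
}

nn_attn_bwd <- function(dy, cache) {
  bo <- nn_lin_bwd(dy, cache$Ycache)
  dO <- bo$dx
  dh <- cache$dh
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- matrix(0, nrow(cache$K$out), ncol(dO))
  dV <- dK
  for (h in seq_len(cache$n_heads)) {
    ix <- (h - 1L) * dh + seq_len(dh)
    S <- cache$Ss[[h]]
    dOh <- dO[, ix, drop = FALSE]
    Vh <- cache$V$out[, ix, drop = FALSE]
    dS <- tcrossprod(dOh, Vh)
    dV[, ix] <- crossprod(S, dOh)
    dA <- S * (dS - rowSums(dS * S))  # softmax Jacobian, row-wise
    dA <- dA / sqrt(dh)
    dQ[, ix] <- dA %*% cache$K$out[, ix, drop = FALSE]
    dK[, ix] <- crossprod(dA, cache$Q$out[, ix, drop = FALSE])
  }
  bq <- nn_lin_bwd(dQ, cache$Q$cache)
  bk <- nn_lin_bwd(dK, cache$K$cache)
  bv <- nn_lin_bwd(dV, cache$V$cache)
  list(dxq = bq$dx,
       dxkv = bk$dx + bv$dx,
       grads = list(Wq = bq$grads$W, bq = bq$grads$b,
                    Wk = bk$grads$W, bk = bk$grads$b,
                    Wv = bv$grads$W, bv = bv$grads$b,
                    Wo = bo$grads$W, bo = bo$grads$b))
}

## ---- parameter initialisation ---------------------------------------------

nn_init_conv <- function(k, cin, cout, scale = 1) {
  list(W = array(stats::rnorm(k * k * cin * cout, sd = scale * sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

nn_init_lin <- function(cin, cout, scale = 1) {
  list(W = matrix(stats::rnorm(cin * cout, sd = scale * sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

nn_init_norm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

nn_init_attn <- function(c, scale = 1) {
  q <- nn_init_lin(c, c, scale); k <- nn_init_lin(c, c, scale)
  v <- nn_init_lin(c, c, scale); o <- nn_init_lin(c, c, scale)
  list(Wq = q$W, bq = q$b, Wk = k$W, bk = k$b,
       Wv = v$W, bv = v$b, Wo = o$W, bo = o$b)
}

## ---- AdamW on nested parameter lists ---------------------------------------

nn_zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) lapply(p, nn_zeros_like) else p * 0
}

nn_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nn_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

nn_accumulate <- function(total, add) {
  if (is.null(total)) return(add)
  nn_map2(total, add, `+`)
}

adamw_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

# Decoupled weight decay applied to every parameter tensor; grads and params
# share structure. Returns list(params, state).
adamw_step <- function(params, grads, state, lr, weight_decay = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_map2(state$m, state$v,
                 function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nn_map2(params, upd, function(p, u) p - lr * (u + weight_decay * p))
  list(params = params, state = state)
}
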
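#' Network configuration for the 2.5D worm-body segmentation model
#'
#' The model is a U-Net whose encoder/decoder levels are pre-activation
#' residual convolution blocks, with a small vision transformer (ViT) at the
#' bottleneck and a pooled-attention classifier head. The short z-stack
#' around the best focal plane enters as input channels, so convolutions are
#' 2D while the network still sees volumetric context (the "2.5D"
#' convention).
#'
#' @param n_encoder_layers Number of downsampling levels (default 4; the
#'   spatial downsampling factor is `s = 2^n_encoder_layers`).
#' @param base_features Feature width at full resolution; level `l` carries
#'   `base_features * 2^l` features.
#' @param bottleneck_dim Token dimension `c` at the bottleneck (default 256).
#' @param vit_depth Number of pre-norm transformer blocks (default 4).
#' @param n_heads Attention heads; must divide `bottleneck_dim` (default 8).
#' @param ffn_expansion Hidden-width multiplier of the transformer
#'   feed-forward network (default 4, i.e. `|C_FFN| = 4 |C_MHSA|`).
#' @param n_seg_classes Segmentation classes (default 2: background, worm).
#' @param n_channel_classes Channel classes (fixed 3: full, partial, empty).
#' @param input_planes Number of z-planes stacked as input channels (2N+1).
#' @param dropout Dropout probability inside the ViT blocks (default 0).
#' @param norm Normalisation inside conv blocks: `"group"` or `"none"`.
#' @param norm_groups Target number of groups for group normalisation; it is
#'   reduced to the largest divisor of the channel count when needed.
#' @param cls_hidden Hidden width of the classifier's linear head.
#' @return A list of class `wormnet_config`.
#' @export
network_config <- function(n_encoder_layers = 4L,
                           base_features = 16L,
                           bottleneck_dim = 256L,
                           vit_depth = 4L,
                           n_heads = 8L,
                           ffn_expansion = 4L,
                           n_seg_classes = 2L,
                           n_channel_classes = 3L,
                           input_planes = 3L,
                           dropout = 0,
                           norm = c("group", "none"),
                           norm_groups = 8L,
                           cls_hidden = 64L) {
  norm <- match.arg(norm)
  if (bottleneck_dim %% n_heads != 0L)
    stop("bottleneck_dim must be divisible by n_heads")
  cfg <- list(n_encoder_layers = as.integer(n_encoder_layers),
              base_features = as.integer(base_features),
              bottleneck_dim = as.integer(bottleneck_dim),
              vit_depth = as.integer(vit_depth),
              n_heads = as.integer(n_heads),
              ffn_expansion = as.integer(ffn_expansion),
              n_seg_classes = as.integer(n_seg_classes),
              n_channel_classes = as.integer(n_channel_classes),
              input_planes = as.integer(input_planes),
              dropout = dropout,
              norm = norm,
              norm_groups = as.integer(norm_groups),
              cls_hidden = as.integer(cls_hidden))
  class(cfg) <- "wormnet_config"
  cfg
}

wn_feats <- function(cfg) cfg$base_features * 2L^(0:cfg$n_encoder_layers)

wn_groups <- function(cfg, channels) {
  if (cfg$norm != "group") return(1L)
  g <- min(cfg$norm_groups, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

wn_init_res <- function(cin, cout, cfg) {
  list(n1 = nn_init_norm(cin),
       c1 = nn_init_conv(3L, cin, cout),
       n2 = nn_init_norm(cout),
       c2 = nn_init_conv(3L, cout, cout),
       proj = if (cin != cout) nn_init_conv(1L, cin, cout) else NULL)
}

#' Initialise a worm-body segmentation network
#'
#' @param cfg A [network_config()].
#' @param input_hw Integer `c(H, W)` of the (padded) network input; both must
#'   be divisible by `2^n_encoder_layers`.
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `wormnet` with elements `cfg`, `hw`, `grid`
#'   (bottleneck grid `c(h, w)`) and `params`.
#' @export
net_init <- function(cfg, input_hw, seed = 1L) {
  s <- 2L^cfg$n_encoder_layers
  if (any(input_hw %% s != 0L))
    stop(sprintf("input H and W must be divisible by %d (got %d x %d); pad the input",
                 s, input_hw[1], input_hw[2]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- wn_feats(cfg)
  L <- cfg$n_encoder_layers
  cdim <- cfg$bottleneck_dim
  grid <- as.integer(input_hw / s)
  ntok <- grid[1] * grid[2]
  params <- list(
    stem = nn_init_conv(3L, cfg$input_planes, f[1]),
    enc = lapply(seq_len(L), function(l)
      list(block = wn_init_res(f[l], f[l], cfg),
           down = nn_init_conv(3L, f[l], f[l + 1]))),
    bproj = nn_init_conv(1L, f[L + 1], cdim),
    pos = matrix(stats::rnorm(ntok * cdim, sd = 0.02), ntok, cdim),
    vit = lapply(seq_len(cfg$vit_depth), function(d)
      list(ln1 = nn_init_norm(cdim),
           attn = nn_init_attn(cdim),
           ln2 = nn_init_norm(cdim),
           ffn1 = nn_init_lin(cdim, cfg$ffn_expansion * cdim),
           ffn2 = nn_init_lin(cfg$ffn_expansion * cdim, cdim))),
    cls = list(seed = matrix(stats::rnorm(cdim, sd = 0.02), 1L, cdim),
               attn = nn_init_attn(cdim),
               h1 = nn_init_lin(cdim, cfg$cls_hidden),
               h2 = nn_init_lin(cfg$cls_hidden, cfg$n_channel_classes)),
    dproj = nn_init_conv(1L, cdim, f[L + 1]),
    dec = lapply(seq_len(L), function(l)  # index l = decoder level (1 = full res)
      list(up = list(W = array(stats::rnorm(4L * f[l + 1] * f[l],
                                            sd = sqrt(2 / (4 * f[l + 1]))),
                               c(2L, 2L, f[l + 1], f[l])),
                     b = numeric(f[l])),
           block = wn_init_res(2L * f[l], f[l], cfg))),
    head = list(h1 = nn_init_conv(1L, f[1], f[1]),
                h2 = nn_init_conv(1L, f[1], cfg$n_seg_classes))
  )
  structure(list(cfg = cfg, hw = as.integer(input_hw), grid = grid,
                 params = params),
            class = "wormnet")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---- residual block ---------------------------------------------------------

wn_res_fwd <- function(x, p, cfg) {
  if (cfg$norm == "group") {
    n1 <- nn_gn_fwd(x, p$n1$gamma, p$n1$beta, wn_groups(cfg, dim(x)[3]))
  } else n1 <- list(out = x, cache = NULL)
  r1 <- nn_relu_fwd(n1$out)
  c1 <- nn_conv_fwd(r1$out, p$c1$W, p$c1$b, 1L, 1L)
  if (cfg$norm == "group") {
    n2 <- nn_gn_fwd(c1$out, p$n2$gamma, p$n2$beta, wn_groups(cfg, dim(c1$out)[3]))
  } else n2 <- list(out = c1$out, cache = NULL)
  r2 <- nn_relu_fwd(n2$out)
  c2 <- nn_conv_fwd(r2$out, p$c2$W, p$c2$b, 1L, 1L)
  pr <- if (!is.null(p$proj)) nn_conv_fwd(x, p$proj$W, p$proj$b, 1L, 0L)
        else list(out = x, cache = NULL)
  list(out = c2$out + pr$out,
       cache = list(n1 = n1$cache, r1 = r1$cache, c1 = c1$cache,
                    n2 = n2$cache, r2 = r2$cache, c2 = c2$cache,
                    pr = pr$cache, has_proj = !is.null(p$proj)))
}

wn_res_bwd <- function(dy, cache, cfg) {
  b2 <- nn_conv_bwd(dy, cache$c2)
  dr2 <- nn_relu_bwd(b2$dx, cache$r2)
  if (cfg$norm == "group") {
    bn2 <- nn_gn_bwd(dr2, cache$n2); dn2 <- bn2$dx
    gn2 <- bn2$grads
  } else { dn2 <- dr2; gn2 <- NULL }
  b1 <- nn_conv_bwd(dn2, cache$c1)
  dr1 <- nn_relu_bwd(b1$dx, cache$r1)
  if (cfg$norm == "group") {
    bn1 <- nn_gn_bwd(dr1, cache$n1); dmain <- bn1$dx
    gn1 <- bn1$grads
  } else { dmain <- dr1; gn1 <- NULL }
  if (cache$has_proj) {
    bp <- nn_conv_bwd(dy, cache$pr)
    dskip <- bp$dx
    gproj <- bp$grads
  } else { dskip <- dy; gproj <- NULL }
  grads <- list(n1 = if (is.null(gn1)) nn_zeros_norm(cache, 1) else gn1,
                c1 = b1$grads,
                n2 = if (is.null(gn2)) nn_zeros_norm(cache, 2) else gn2,
                c2 = b2$grads,
                proj = gproj)
  list(dx = dmain + dskip, grads = grads)
}

# Zero gradients for unused norm parameters when cfg$norm == "none".
nn_zeros_norm <- function(cache, which) {
  cin <- if (which == 1) dim(cache$c1$W)[3] else dim(cache$c2$W)[3]
  list(gamma = numeric(cin), beta = numeric(cin))
}

## ---- tokenisation -----------------------------------------------------------

# Flatten an (h, w, c) grid into (h*w, c) tokens, row-major with y (rows)
# outer: token t = (y - 1) * w + x.
wn_tokenize <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2L, 1L, 3L)), d[1] * d[2], d[3])
}

wn_detokenize <- function(tok, grid) {
  cdim <- ncol(tok)
  aperm(array(tok, c(grid[2], grid[1], cdim)), c(2L, 1L, 3L))
}

## ---- full forward ----------------------------------------------------------

#' Forward pass of the worm-body network
#'
#' @param model A `wormnet` from [net_init()].
#' @param x Input array `(H, W, P)` (P = `input_planes`) or an `input_tensor`
#'   from [assemble_input()].
#' @param train Logical; enables dropout (if configured). A fixed RNG state
#'   makes the pass deterministic.
#' @param want_cache Keep intermediate activations for [net_backward()].
#' @return A list of class `model_output` with `seg_probs` `(H, W, n_seg)`,
#'   `class_probs` (length 3, named), `seg_logits`, `class_logits` and,
#'   when requested, `cache`.
#' @export
net_forward <- function(model, x, train = FALSE, want_cache = FALSE) {
  cfg <- model$cfg
  if (inherits(x, "input_tensor")) x <- x$planes
  if (length(dim(x)) != 3L) stop("input must be an (H, W, planes) array")
  if (!all(dim(x)[1:2] == model$hw))
    stop(sprintf("input is %d x %d but the model was built for %d x %d",
                 dim(x)[1], dim(x)[2], model$hw[1], model$hw[2]))
  p <- model$params
  L <- cfg$n_encoder_layers
  cache <- list()

  stem <- nn_conv_fwd(x, p$stem$W, p$stem$b, 1L, 1L)
  cache$stem <- stem$cache
  h <- stem$out

  skips <- vector("list", L)
  cache$enc <- vector("list", L)
  for (l in seq_len(L)) {
    rb <- wn_res_fwd(h, p$enc[[l]]$block, cfg)
    skips[[l]] <- rb$out
    dn <- nn_conv_fwd(rb$out, p$enc[[l]]$down$W, p$enc[[l]]$down$b, 2L, 1L)
    cache$enc[[l]] <- list(block = rb$cache, down = dn$cache)
    h <- dn$out
  }

  bp <- nn_conv_fwd(h, p$bproj$W, p$bproj$b, 1L, 0L)
  cache$bproj <- bp$cache
  tok <- wn_tokenize(bp$out) + p$pos

  cache$vit <- vector("list", cfg$vit_depth)
  for (d in seq_len(cfg$vit_depth)) {
    blk <- p$vit[[d]]
    ln1 <- nn_ln_fwd(tok, blk$ln1$gamma, blk$ln1$beta)
    at <- nn_attn_fwd(ln1$out, ln1$out, blk$attn, cfg$n_heads)
    drop1 <- wn_dropout_fwd(at$out, cfg$dropout, train)
    tok1 <- tok + drop1$out
    ln2 <- nn_ln_fwd(tok1, blk$ln2$gamma, blk$ln2$beta)
    f1 <- nn_lin_fwd(ln2$out, blk$ffn1$W, blk$ffn1$b)
    g1 <- nn_gelu_fwd(f1$out)
    f2 <- nn_lin_fwd(g1$out, blk$ffn2$W, blk$ffn2$b)
    drop2 <- wn_dropout_fwd(f2$out, cfg$dropout, train)
    tok <- tok1 + drop2$out
    cache$vit[[d]] <- list(ln1 = ln1$cache, at = at$cache, drop1 = drop1$cache,
                           ln2 = ln2$cache, f1 = f1$cache, g1 = g1$cache,
                           f2 = f2$cache, drop2 = drop2$cache)
  }

  # classifier: pooled attention with a single learned seed vector
  pa <- nn_attn_fwd(p$cls$seed, tok, p$cls$attn, cfg$n_heads)
  ch1 <- nn_lin_fwd(pa$out, p$cls$h1$W, p$cls$h1$b)
  cg <- nn_gelu_fwd(ch1$out)
  ch2 <- nn_lin_fwd(cg$out, p$cls$h2$W, p$cls$h2$b)
  class_logits <- drop(ch2$out)
  cache$cls <- list(pa = pa$cache, ch1 = ch1$cache, cg = cg$cache, ch2 = ch2$cache)

  # decoder
  grid_tok <- wn_detokenize(tok, model$grid)
  dp <- nn_conv_fwd(grid_tok, p$dproj$W, p$dproj$b, 1L, 0L)
  cache$dproj <- dp$cache
  h <- dp$out
  cache$dec <- vector("list", L)
  for (l in rev(seq_len(L))) {
    up <- nn_convT_fwd(h, p$dec[[l]]$up$W, p$dec[[l]]$up$b)
    cat_in <- wn_concat(up$out, skips[[l]])
    rb <- wn_res_fwd(cat_in, p$dec[[l]]$block, cfg)
    cache$dec[[l]] <- list(up = up$cache, rb = rb$cache,
                           split = dim(up$out)[3])
    h <- rb$out
  }
  hd1 <- nn_conv_fwd(h, p$head$h1$W, p$head$h1$b, 1L, 0L)
  hr <- nn_relu_fwd(hd1$out)
  hd2 <- nn_conv_fwd(hr$out, p$head$h2$W, p$head$h2$b, 1L, 0L)
  cache$head <- list(h1 = hd1$cache, hr = hr$cache, h2 = hd2$cache)

  seg_logits <- hd2$out
  seg_probs <- wn_softmax_hw(seg_logits)
  class_probs <- wn_softmax_vec(class_logits)
  names(class_probs) <- c("full", "partial", "empty")[seq_len(cfg$n_channel_classes)]

  out <- list(seg_probs = seg_probs, class_probs = class_probs,
              seg_logits = seg_logits, class_logits = class_logits)
  if (want_cache) out$cache <- cache
  class(out) <- "model_output"
  out
}

wn_concat <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

wn_softmax_hw <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1] * d[2], d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

wn_softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

wn_dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= p, dim(x))
  list(out = x * keep / (1 - p), cache = list(keep = keep, p = p))
}

wn_dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  dy * cache$keep / (1 - cache$p)
}

## ---- full backward ----------------------------------------------------------

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param model A `wormnet`.
#' @param cache The `cache` from `net_forward(..., want_cache = TRUE)`.
#' @param dseg_logits Gradient w.r.t. the segmentation logits `(H, W, n_seg)`
#'   (may be `NULL` for classification-only samples).
#' @param dcls_logits Gradient w.r.t. the class logits (length 3).
#' @return A nested list of gradients with the same structure as
#'   `model$params`.
#' @export
net_backward <- function(model, cache, dseg_logits, dcls_logits) {
  cfg <- model$cfg
  p <- model$params
  L <- cfg$n_encoder_layers
  g <- nn_zeros_like(p)

  if (is.null(dcls_logits)) dcls_logits <- numeric(cfg$n_channel_classes)
  dskips <- NULL
  if (!is.null(dseg_logits)) {
    # segmentation head
    bh2 <- nn_conv_bwd(dseg_logits, cache$head$h2)
    g$head$h2 <- bh2$grads
    dhr <- nn_relu_bwd(bh2$dx, cache$head$hr)
    bh1 <- nn_conv_bwd(dhr, cache$head$h1)
    g$head$h1 <- bh1$grads
    dh <- bh1$dx

    # decoder (reverse of forward: levels 1 .. L)
    dskips <- vector("list", L)
    for (l in seq_len(L)) {
      cc <- cache$dec[[l]]
      rb <- wn_res_bwd(dh, cc$rb, cfg)
      g$dec[[l]]$block <- rb$grads
      dup <- rb$dx[, , seq_len(cc$split), drop = FALSE]
      dskips[[l]] <- rb$dx[, , cc$split + seq_len(dim(rb$dx)[3] - cc$split), drop = FALSE]
      bu <- nn_convT_bwd(dup, cc$up)
      g$dec[[l]]$up <- bu$grads
      dh <- bu$dx
    }
    bdp <- nn_conv_bwd(dh, cache$dproj)
    g$dproj <- bdp$grads
    dtok <- wn_tokenize(bdp$dx)
  } else {
    # classification-only sample: no gradient reaches decoder or seg head
    dtok <- matrix(0, model$grid[1] * model$grid[2], cfg$bottleneck_dim)
  }

  # classifier head
  bch2 <- nn_lin_bwd(matrix(dcls_logits, 1L), cache$cls$ch2)
  g$cls$h2 <- bch2$grads
  dcg <- nn_gelu_bwd(bch2$dx, cache$cls$cg)
  bch1 <- nn_lin_bwd(dcg, cache$cls$ch1)
  g$cls$h1 <- bch1$grads
  bpa <- nn_attn_bwd(bch1$dx, cache$cls$pa)
  g$cls$attn <- bpa$grads
  g$cls$seed <- bpa$dxq
  dtok <- dtok + bpa$dxkv

  # ViT blocks in reverse
  for (d in rev(seq_len(cfg$vit_depth))) {
    cc <- cache$vit[[d]]
    ddrop2 <- wn_dropout_bwd(dtok, cc$drop2)
    bf2 <- nn_lin_bwd(ddrop2, cc$f2)
    g$vit[[d]]$ffn2 <- bf2$grads
    dg1 <- nn_gelu_bwd(bf2$dx, cc$g1)
    bf1 <- nn_lin_bwd(dg1, cc$f1)
    g$vit[[d]]$ffn1 <- bf1$grads
    bln2 <- nn_ln_bwd(bf1$dx, cc$ln2)
    g$vit[[d]]$ln2 <- bln2$grads
    dtok1 <- dtok + bln2$dx
    ddrop1 <- wn_dropout_bwd(dtok1, cc$drop1)
    bat <- nn_attn_bwd(ddrop1, cc$at)
    g$vit[[d]]$attn <- bat$grads
    bln1 <- nn_ln_bwd(bat$dxq + bat$dxkv, cc$ln1)
    g$vit[[d]]$ln1 <- bln1$grads
    dtok <- dtok1 + bln1$dx
  }

  g$pos <- dtok
  dbp <- wn_detokenize(dtok, model$grid)
  bbp <- nn_conv_bwd(dbp, cache$bproj)
  g$bproj <- bbp$grads
  dh <- bbp$dx

  # encoder in reverse
  for (l in rev(seq_len(L))) {
    cc <- cache$enc[[l]]
    bdn <- nn_conv_bwd(dh, cc$down)
    g$enc[[l]]$down <- bdn$grads
    dblk <- if (is.null(dskips)) bdn$dx else bdn$dx + dskips[[l]]
    rb <- wn_res_bwd(dblk, cc$block, cfg)
    g$enc[[l]]$block <- rb$grads
    dh <- rb$dx
  }
  bst <- nn_conv_bwd(dh, cache$stem)
  g$stem <- bst$grads
  g
}
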
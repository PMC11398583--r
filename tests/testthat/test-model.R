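test_that("network shape contract holds on toy and full-scale geometry", {
  cfg <- tiny_net_config()
  net <- net_init(cfg, c(64L, 64L), seed = 1)
  expect_identical(net$grid, c(16L, 16L))
  x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3))
  out <- net_forward(net, x)
  expect_identical(dim(out$seg_probs), c(64L, 64L, 2L))
  expect_length(out$class_probs, 3L)
  # full-scale geometry: 5056 x 384 at 4 levels gives a 316 x 24 token grid
  big <- net_init(network_config(), c(5056L, 384L), seed = 1)
  expect_identical(big$grid, c(316L, 24L))
  expect_identical(nrow(big$params$pos), 316L * 24L)
  expect_error(net_init(cfg, c(50L, 64L)), "divisible")
})

test_that("per-pixel and class probabilities are proper distributions", {
  net <- net_init(tiny_net_config(), c(64L, 64L), seed = 3)
  x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3))
  out <- net_forward(net, x)
  expect_true(all(is.finite(out$seg_probs)))
  sums <- out$seg_probs[, , 1] + out$seg_probs[, , 2]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-12)
  expect_true(all(out$class_probs >= 0 & out$class_probs <= 1))
})

test_that("residual blocks are identity maps when conv weights are zero", {
  cfg <- tiny_net_config()
  p <- wormchip:::wn_init_res(4L, 4L, cfg)
  p$c1$W[] <- 0; p$c1$b[] <- 0
  p$c2$W[] <- 0; p$c2$b[] <- 0
  x <- array(stats::rnorm(8 * 8 * 4), c(8, 8, 4))
  out <- wormchip:::wn_res_fwd(x, p, cfg)
  expect_equal(out$out, x)
  # gradient still flows to the input through the skip
  bwd <- wormchip:::wn_res_bwd(array(1, dim(x)), out$cache, cfg)
  expect_gt(sum(abs(bwd$dx)), 0)
})

test_that("tokenisation is an invertible reshape", {
  x <- array(stats::rnorm(6 * 4 * 5), c(6, 4, 5))
  tok <- wormchip:::wn_tokenize(x)
  expect_identical(dim(tok), c(24L, 5L))
  expect_equal(wormchip:::wn_detokenize(tok, c(6L, 4L)), x)
  # row-major, y outer: token 2 is grid position (y = 1, x = 2)
  expect_equal(tok[2, ], x[1, 2, ])
})

test_that("transformer blocks with zeroed weights are identity; attention is
           permutation-equivariant and duplication-invariant", {
  cdim <- 8L
  p <- wormchip:::nn_init_attn(cdim)
  tok <- matrix(stats::rnorm(6 * cdim), 6, cdim)
  # zero the output projection: the block's contribution vanishes
  p0 <- p; p0$Wo[] <- 0; p0$bo[] <- 0
  at0 <- wormchip:::nn_attn_fwd(tok, tok, p0, 2L)
  expect_equal(at0$out, matrix(0, 6, cdim))
  # permutation equivariance of self-attention
  at <- wormchip:::nn_attn_fwd(tok, tok, p, 2L)
  perm <- c(3, 1, 6, 2, 5, 4)
  atp <- wormchip:::nn_attn_fwd(tok[perm, ], tok[perm, ], p, 2L)
  expect_equal(atp$out, at$out[perm, ], tolerance = 1e-10)
  # pooled attention with one seed: duplicating all tokens changes nothing
  seedv <- matrix(stats::rnorm(cdim), 1, cdim)
  pa1 <- wormchip:::nn_attn_fwd(seedv, tok, p, 2L)
  pa2 <- wormchip:::nn_attn_fwd(seedv, rbind(tok, tok), p, 2L)
  expect_equal(pa1$out, pa2$out, tolerance = 1e-10)
})

test_that("forward is deterministic and fast on a toy input", {
  net <- net_init(tiny_net_config(), c(64L, 64L), seed = 9)
  x <- array(stats::rnorm(64 * 64 * 3), c(64, 64, 3))
  t0 <- Sys.time()
  o1 <- net_forward(net, x)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  o2 <- net_forward(net, x)
  expect_identical(o1$seg_probs, o2$seg_probs)
  expect_identical(o1$class_probs, o2$class_probs)
  expect_lt(elapsed, 1)
})

test_that("analytic gradients match finite differences through the whole net", {
  cfg <- network_config(n_encoder_layers = 2L, base_features = 4L,
                        bottleneck_dim = 8L, vit_depth = 1L, n_heads = 2L,
                        cls_hidden = 8L, norm_groups = 2L)
  net <- net_init(cfg, c(16L, 16L), seed = 3)
  withr::with_seed(42, {
    x <- array(stats::rnorm(16 * 16 * 3), c(16, 16, 3))
    R1 <- array(stats::rnorm(16 * 16 * 2), c(16, 16, 2))
    r2 <- stats::rnorm(3)
  })
  lossfn <- function(nn) {
    o <- net_forward(nn, x)
    sum(o$seg_logits * R1) + sum(o$class_logits * r2)
  }
  o <- net_forward(net, x, want_cache = TRUE)
  g <- net_backward(net, o$cache, R1, r2)
  paths <- list(c("stem", "W"), c("enc", "1", "block", "c1", "W"),
                c("bproj", "W"), c("pos"), c("vit", "1", "attn", "Wq"),
                c("vit", "1", "ffn1", "W"), c("cls", "seed"),
                c("cls", "h2", "W"), c("dproj", "W"),
                c("dec", "1", "up", "W"), c("dec", "2", "block", "c2", "W"),
                c("head", "h2", "W"))
  key_of <- function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p
  get_leaf <- function(lst, path) {
    for (p in path) lst <- lst[[key_of(p)]]
    lst
  }
  set_leaf <- function(lst, path, val) {
    k <- key_of(path[[1]])
    if (length(path) == 1) lst[[k]] <- val
    else lst[[k]] <- set_leaf(lst[[k]], path[-1], val)
    lst
  }
  eps <- 1e-5
  withr::with_seed(7, {
    for (path in paths) {
      leaf <- get_leaf(net$params, path)
      ga <- get_leaf(g, path)
      i <- sample(length(leaf), 1)
      np <- net
      lp <- leaf; lp[i] <- lp[i] + eps
      np$params <- set_leaf(net$params, path, lp); f1 <- lossfn(np)
      lp[i] <- leaf[i] - eps
      np$params <- set_leaf(net$params, path, lp); f0 <- lossfn(np)
      num <- (f1 - f0) / (2 * eps)
      expect_equal(ga[i], num, tolerance = 1e-4)
    }
  })
})
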
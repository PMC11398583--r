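# Shared fixtures: a small imaging scene, two phenotypic domains (large
# high-contrast adults vs small low-contrast larvae), a tiny network
# configuration, and a lazily trained base model cached for the whole test
# session.

.wc_cache <- new.env(parent = emptyenv())

tiny_scene <- function(...) {
  args <- utils::modifyList(
    list(fov_height_px = 96L, pixel_size_um = 4, n_z = 5L,
         n_timepoints = 1L, channel_pitch_um = 150,
         noise_sd = 0.01, margin_px = 8L, rng_seed = 1L),
    list(...))
  do.call(scene_config, args)
}

domain_adult <- function(n, seed, classes = NULL) {
  make_labeled_channels(n, tiny_scene(), seed = seed, target_width = 48L,
                        classes = classes, width_frac = 0.15,
                        length_um_range = c(0.55, 0.8) * 96 * 4,
                        contrast_range = c(0.6, 1.0))
}

domain_larva <- function(n, seed, classes = NULL) {
  make_labeled_channels(n, tiny_scene(), seed = seed, target_width = 48L,
                        classes = classes, width_frac = 0.15,
                        length_um_range = c(0.28, 0.42) * 96 * 4,
                        contrast_range = c(0.22, 0.4))
}

tiny_net_config <- function() {
  network_config(n_encoder_layers = 2L, base_features = 8L,
                 bottleneck_dim = 32L, vit_depth = 1L, n_heads = 4L,
                 norm_groups = 4L, cls_hidden = 16L)
}

overfit_train_samples <- function() {
  if (is.null(.wc_cache$samples))
    .wc_cache$samples <- domain_adult(8, 11, c(rep("full", 6), "partial", "empty"))
  .wc_cache$samples
}

# Base model trained once per session on the 8-channel adult-domain corpus.
trained_base_model <- function() {
  if (is.null(.wc_cache$base)) {
    net <- net_init(tiny_net_config(), c(96L, 48L), seed = 2L)
    cfg <- train_config(batch_size = 8L, epochs = 120L, lr0 = 1e-3,
                        scheduler = "warm_restarts", W0 = 50, F_mult = 2,
                        augment_flip = FALSE, augment_rotate = FALSE,
                        augment_contrast = FALSE, seed = 5L)
    .wc_cache$base <- train_model(net, list(train = overfit_train_samples()),
                                  cfg)$model
  }
  .wc_cache$base
}

mean_dice_on <- function(model, samples) {
  ds <- vapply(Filter(function(s) s$class_label == "full", samples),
               function(s) {
                 out <- net_forward(model, s$input$planes)
                 dice(out$seg_probs[, , 2] >= 0.5, s$mask)
               }, 0)
  mean(ds)
}

## ---- independent oracles ----------------------------------------------------

# Brute-force Dice by explicit pixel counting.
oracle_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) inter <- inter + 1
      if (a[i, j]) sa <- sa + 1
      if (b[i, j]) sb <- sb + 1
    }
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

# Brute-force longest geodesic on a skeleton: all-pairs shortest paths by
# repeated Dijkstra over an explicitly built 8-neighbour edge list.
oracle_longest_geodesic <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 1L) return(0)
  wmat <- matrix(Inf, n, n)
  diag(wmat) <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      dr <- abs(pts[a, 1] - pts[b, 1]); dc <- abs(pts[a, 2] - pts[b, 2])
      if (dr <= 1 && dc <= 1) {
        w <- if (dr + dc == 2) sqrt(2) else 1
        wmat[a, b] <- w; wmat[b, a] <- w
      }
    }
  }
  # Floyd-Warshall
  for (k in seq_len(n)) {
    wk <- outer(wmat[, k], wmat[k, ], `+`)
    wmat <- pmin(wmat, wk)
  }
  m <- wmat[is.finite(wmat)]
  max(m)
}

# Largest connected component (8-connectivity) by flood fill.
oracle_largest_component <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  cur <- 0L
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(ncol(grid))) {
      if (grid[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        lab[i, j] <- cur
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (di in -1:1) for (dj in -1:1) {
            r <- p[1] + di; c <- p[2] + dj
            if (r >= 1 && r <= nrow(grid) && c >= 1 && c <= ncol(grid) &&
                grid[r, c] && lab[r, c] == 0L) {
              lab[r, c] <- cur
              stack[[length(stack) + 1L]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  if (cur == 0L) return(grid)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

random_blob_mask <- function(h, w, n_seeds = 3, grow = 40, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(FALSE, h, w)
    pts <- cbind(sample(h, n_seeds, replace = TRUE),
                 sample(w, n_seeds, replace = TRUE))
    g[pts] <- TRUE
    for (it in seq_len(grow)) {
      cand <- which(g, arr.ind = TRUE)
      p <- cand[sample(nrow(cand), 1), ]
      r <- min(max(p[1] + sample(-1:1, 1), 1), h)
      c <- min(max(p[2] + sample(-1:1, 1), 1), w)
      g[r, c] <- TRUE
    }
    g
  })
}
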
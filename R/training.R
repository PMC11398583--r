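#' Training configuration
#'
#' Defaults follow the base-training recipe for the full-scale problem:
#' AdamW with initial learning rate 2e-4 and weight decay 1e-2, cosine
#' annealing with warm restarts (W0 = 10, F = 2) over 1200 epochs, batch
#' size 32, an 8:1:1 stratified split, flips/small rotations/contrast
#' augmentation. Few-shot fine-tuning uses a one-cycle cosine schedule
#' (default maximum learning rate 1e-6) over 250 epochs.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr0 Initial learning rate (warm-restart schedule).
#' @param weight_decay AdamW decoupled weight decay.
#' @param scheduler `"warm_restarts"` or `"one_cycle"`.
#' @param W0 First warm-restart period (epochs).
#' @param F_mult Period multiplier between restarts.
#' @param lr_min Floor of the cosine schedule (default `lr0 / 1000`).
#' @param max_lr One-cycle peak learning rate (fine-tuning).
#' @param warmup_frac Fraction of the one-cycle spent ramping up.
#' @param split_ratio Train/validation/test fractions (sum to 1).
#' @param loss_weights Named weights `c(seg = , cls = )`.
#' @param augment_flip,augment_rotate,augment_contrast Augmentation
#'   switches.
#' @param max_rot_deg Rotation bound in degrees.
#' @param gamma_range Contrast (gamma) adjustment range.
#' @param seed RNG seed for the run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 1200L,
                         lr0 = 2e-4, weight_decay = 1e-2,
                         scheduler = c("warm_restarts", "one_cycle"),
                         W0 = 10, F_mult = 2,
                         lr_min = lr0 / 1000,
                         max_lr = 1e-6, warmup_frac = 0.3,
                         split_ratio = c(0.8, 0.1, 0.1),
                         loss_weights = c(seg = 1, cls = 1),
                         augment_flip = TRUE, augment_rotate = TRUE,
                         augment_contrast = TRUE,
                         max_rot_deg = 5, gamma_range = c(0.7, 1.3),
                         seed = 1L) {
  scheduler <- match.arg(scheduler)
  if (abs(sum(split_ratio) - 1) > 1e-8) stop("split_ratio must sum to 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 weight_decay = weight_decay, scheduler = scheduler,
                 W0 = W0, F_mult = F_mult, lr_min = lr_min,
                 max_lr = max_lr, warmup_frac = warmup_frac,
                 split_ratio = split_ratio, loss_weights = loss_weights,
                 augment_flip = augment_flip,
                 augment_rotate = augment_rotate,
                 augment_contrast = augment_contrast,
                 max_rot_deg = max_rot_deg, gamma_range = gamma_range,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Per-class proportions in each split stay within one sample of the global
#' proportions (largest-remainder allocation within each class); splits are
#' disjoint and deterministic for a fixed seed.
#'
#' @param samples List of labeled samples; each must carry `class_label`.
#' @param ratio Numeric length-3 split fractions (sum to 1).
#' @param seed Integer seed.
#' @return A list with `train`, `val`, `test` (lists of samples) and
#'   attribute `indices`.
#' @export
stratified_split <- function(samples, ratio = c(0.8, 0.1, 0.1), seed = 1L) {
  labels <- vapply(samples, function(s) s$class_label, "")
  if (any(!nzchar(labels))) stop("every sample needs a class_label")
  if (any(table(labels) < 1L)) stop("empty class")
  idx <- list(integer(), integer(), integer())
  with_seed(seed, {
    for (cl in unique(labels)) {
      ci <- sample(which(labels == cl))
      n <- length(ci)
      tgt <- ratio * n
      cnt <- floor(tgt)
      rem <- tgt - cnt
      short <- n - sum(cnt)
      if (short > 0) {
        add <- order(rem, decreasing = TRUE)[seq_len(short)]
        cnt[add] <- cnt[add] + 1L
      }
      br <- cumsum(c(0, cnt))
      for (j in 1:3) {
        if (cnt[j] > 0)
          idx[[j]] <- c(idx[[j]], ci[(br[j] + 1L):br[j + 1L]])
      }
    }
  })
  out <- list(train = samples[idx[[1]]], val = samples[idx[[2]]],
              test = samples[idx[[3]]])
  attr(out, "indices") <- idx
  out
}

## ---- augmentation -----------------------------------------------------------

# Nearest-neighbour rotation with edge-replication fill.
rotate_nn <- function(img, deg) {
  if (deg == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse map (rotate sampling grid by -theta)
  si <- cy + cos(th) * (i - cy) - sin(th) * (j - cx)
  sj <- cx + sin(th) * (i - cy) + cos(th) * (j - cx)
  si <- pmin(pmax(round(si), 1L), H)
  sj <- pmin(pmax(round(sj), 1L), W)
  matrix(img[cbind(as.vector(si), as.vector(sj))], H, W)
}

#' Augment a labeled sample
#'
#' Horizontal/vertical flips (p = 0.5 each), small rotations (bounded, with
#' edge-replication fill) applied identically to all image planes and the
#' mask, and a gamma contrast adjustment applied to the image only. The
#' class label never changes.
#'
#' @param sample A list with `input` (an `input_tensor` or `(H, W, P)`
#'   array), optional `mask` (logical matrix), and `class_label`.
#' @param cfg A [train_config()] (augmentation switches and bounds).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The augmented sample.
#' @export
augment <- function(sample, cfg = train_config(), seed = NULL) {
  run <- function() {
    planes <- if (inherits(sample$input, "input_tensor")) sample$input$planes
              else sample$input
    mask <- sample$mask
    if (cfg$augment_flip) {
      if (stats::runif(1) < 0.5) {  # horizontal flip (reverse columns)
        planes <- planes[, ncol(planes):1, , drop = FALSE]
        if (!is.null(mask)) mask <- mask[, ncol(mask):1, drop = FALSE]
      }
      if (stats::runif(1) < 0.5) {  # vertical flip (reverse rows)
        planes <- planes[nrow(planes):1, , , drop = FALSE]
        if (!is.null(mask)) mask <- mask[nrow(mask):1, , drop = FALSE]
      }
    }
    if (cfg$augment_rotate && cfg$max_rot_deg > 0) {
      deg <- stats::runif(1, -cfg$max_rot_deg, cfg$max_rot_deg)
      for (p in seq_len(dim(planes)[3]))
        planes[, , p] <- rotate_nn(planes[, , p], deg)
      if (!is.null(mask)) mask <- rotate_nn(mask, deg)
    }
    if (cfg$augment_contrast) {
      gm <- stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
      rng <- range(planes)
      if (diff(rng) > 0) {
        planes <- ((planes - rng[1]) / diff(rng))^gm * diff(rng) + rng[1]
      }
    }
    if (inherits(sample$input, "input_tensor")) sample$input$planes <- planes
    else sample$input <- planes
    sample$mask <- mask
    sample
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- loss -------------------------------------------------------------------

#' Joint segmentation + classification loss
#'
#' `total = w_seg * L_seg + w_cls * L_cls`. `L_cls` is 3-way cross-entropy
#' for every sample. `L_seg` (soft-Dice plus mean pixel cross-entropy,
#' equally weighted) is computed only for samples labeled "full" — only
#' full worms carry a ground-truth mask and reach the decoder — and is
#' exactly 0 otherwise.
#'
#' @param output A `model_output` from [net_forward()].
#' @param sample A list with `class_label` (full/partial/empty) and, for
#'   full samples, `mask` (logical matrix matching the padded input).
#' @param weights Named weights `c(seg = , cls = )`.
#' @param want_grads Also return gradients w.r.t. the two logit sets.
#' @return A list: `total`, `seg`, `cls`, and (optionally) `dseg_logits`,
#'   `dcls_logits`.
#' @export
net_loss <- function(output, sample, weights = c(seg = 1, cls = 1),
                     want_grads = FALSE) {
  classes <- names(output$class_probs)
  li <- match(sample$class_label, classes)
  if (is.na(li)) stop("unknown class label: ", sample$class_label)
  eps <- 1e-12
  l_cls <- -log(output$class_probs[[li]] + eps)
  dcls <- NULL
  if (want_grads) {
    dcls <- output$class_probs
    dcls[li] <- dcls[li] - 1
  }
  l_seg <- 0
  dseg <- NULL
  if (sample$class_label == "full") {
    if (is.null(sample$mask)) stop("full-worm sample without a mask")
    p <- output$seg_probs
    tmask <- sample$mask * 1
    d <- dim(p)
    if (!all(dim(tmask) == d[1:2])) stop("mask shape does not match output")
    p1 <- p[, , d[3]]
    npx <- d[1] * d[2]
    num <- 2 * sum(p1 * tmask) + eps
    den <- sum(p1) + sum(tmask) + eps
    l_dice <- 1 - num / den
    pt <- ifelse(tmask > 0, p[, , d[3]], p[, , 1])
    l_ce <- mean(-log(pt + eps))
    l_seg <- l_dice + l_ce
    if (want_grads) {
      # dice gradient through the per-pixel softmax
      dldp1 <- -(2 * tmask * den - num) / den^2
      donehot <- array(0, d)
      donehot[, , 1] <- (1 - tmask)
      donehot[, , d[3]] <- tmask
      dseg_ce <- (p - donehot) / npx
      dLdp <- array(0, d)
      dLdp[, , d[3]] <- dldp1
      inner <- dLdp[, , d[3]] * p[, , d[3]]  # sum_j dLdp_j p_j (only worm class nonzero)
      dseg_dice <- p * (dLdp - array(rep(inner, d[3]), d))
      dseg <- dseg_ce + dseg_dice
    }
  }
  total <- weights[["seg"]] * l_seg + weights[["cls"]] * l_cls
  out <- list(total = total, seg = l_seg, cls = l_cls)
  if (want_grads) {
    out$dcls_logits <- weights[["cls"]] * dcls
    out$dseg_logits <- if (is.null(dseg)) NULL else weights[["seg"]] * dseg
  }
  out
}

## ---- learning-rate schedules ------------------------------------------------

#' Epochs at which the warm-restart schedule restarts
#'
#' Restart k begins at `sum_{i<k} W0 * F^i = W0 (F^k - 1) / (F - 1)`:
#' 0, 10, 30, 70, 150, ... for W0 = 10, F = 2.
#'
#' @param cfg A [train_config()].
#' @param n Number of restart epochs to return.
#' @export
restart_epochs <- function(cfg, n = 5L) {
  cumsum(c(0, cfg$W0 * cfg$F_mult^(0:(n - 2))))
}

#' Learning rate at a (fractional) epoch
#'
#' Warm restarts: within restart period k (length `W0 * F^k`), the rate
#' decays from `lr0` to `lr_min` along a half-cosine. One-cycle: cosine
#' ramp from 0 to `max_lr` over the first `warmup_frac` of training, then
#' cosine decay back to 0.
#'
#' @param epoch Fractional epoch (>= 0).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (cfg$scheduler == "warm_restarts") {
    start <- 0
    period <- cfg$W0
    while (epoch >= start + period) {
      start <- start + period
      period <- period * cfg$F_mult
    }
    t <- (epoch - start) / period
    cfg$lr_min + (cfg$lr0 - cfg$lr_min) * (1 + cos(pi * t)) / 2
  } else {
    t <- min(epoch / max(cfg$epochs, 1), 1)
    if (t < cfg$warmup_frac) {
      cfg$max_lr * (1 - cos(pi * t / cfg$warmup_frac)) / 2
    } else {
      u <- (t - cfg$warmup_frac) / (1 - cfg$warmup_frac)
      cfg$max_lr * (1 + cos(pi * u)) / 2
    }
  }
}

## ---- training loop ----------------------------------------------------------

sample_planes <- function(sample) {
  if (inherits(sample$input, "input_tensor")) sample$input$planes else sample$input
}

# Validation Dice over the full-worm samples of a set (argmax masks).
val_dice <- function(model, samples, threshold = 0.5) {
  ds <- c()
  for (s in samples) {
    if (s$class_label != "full" || is.null(s$mask)) next
    out <- net_forward(model, sample_planes(s))
    pred <- out$seg_probs[, , dim(out$seg_probs)[3]] >= threshold
    ds <- c(ds, dice(pred, s$mask))
  }
  if (length(ds) == 0L) NA_real_ else mean(ds)
}

#' Train the worm-body network
#'
#' Runs the mini-batch loop with augmentation, the joint loss, AdamW and the
#' configured learning-rate schedule, tracking validation Dice per epoch and
#' returning the checkpoint with the best validation Dice. Fully seeded:
#' the same seed reproduces the same history.
#'
#' @param model A `wormnet`.
#' @param samples Either a plain list of labeled samples (then an internal
#'   [stratified_split()] by `cfg$split_ratio` is applied) or a list with
#'   `train` and (optionally) `val` components.
#' @param cfg A [train_config()].
#' @param verbose Print progress every few epochs.
#' @return A list: `model` (best checkpoint), `final_model`, `history`
#'   (data.frame epoch/loss/val_dice/lr).
#' @export
train_model <- function(model, samples, cfg = train_config(), verbose = FALSE) {
  if (!is.null(samples$train)) {
    train_set <- samples$train
    valid_set <- if (!is.null(samples$val) && length(samples$val)) samples$val
                 else samples$train
  } else {
    sp <- stratified_split(samples, cfg$split_ratio, seed = cfg$seed)
    train_set <- sp$train
    valid_set <- if (length(sp$val)) sp$val else sp$train
  }
  if (length(train_set) == 0L) stop("empty training split")
  if (cfg$epochs == 0L)
    return(list(model = model, final_model = model,
                history = data.frame(epoch = integer(), loss = numeric(),
                                     val_dice = numeric(), lr = numeric())))
  state <- adamw_init(model$params)
  n <- length(train_set)
  bs <- min(cfg$batch_size, n)
  steps <- max(1L, n %/% bs)
  best <- list(dice = -Inf, params = model$params)
  history <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(n)
      eloss <- 0
      for (st in seq_len(steps)) {
        ids <- perm[((st - 1L) * bs + 1L):min(st * bs, n)]
        grads <- NULL
        bloss <- 0
        for (i in ids) {
          s <- train_set[[i]]
          if (cfg$augment_flip || cfg$augment_rotate || cfg$augment_contrast)
            s <- augment(s, cfg)
          out <- net_forward(model, sample_planes(s), train = TRUE,
                             want_cache = TRUE)
          ls <- net_loss(out, s, cfg$loss_weights, want_grads = TRUE)
          if (!is.finite(ls$total))
            stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
          bloss <- bloss + ls$total
          gi <- net_backward(model, out$cache, ls$dseg_logits, ls$dcls_logits)
          grads <- nn_accumulate(grads, gi)
        }
        grads <- nn_map2(grads, grads, function(a, b) a / length(ids))
        lr <- lr_schedule(epoch - 1 + (st - 1) / steps, cfg)
        upd <- adamw_step(model$params, grads, state, lr,
                          weight_decay = cfg$weight_decay)
        model$params <- upd$params
        state <- upd$state
        eloss <- eloss + bloss / length(ids)
      }
      vd <- val_dice(model, valid_set)
      if (!is.na(vd) && vd > best$dice) best <- list(dice = vd, params = model$params)
      history[[epoch]] <- data.frame(epoch = epoch, loss = eloss / steps,
                                     val_dice = vd,
                                     lr = lr_schedule(epoch - 1, cfg))
      if (verbose && (epoch %% 10L == 0L || epoch == 1L))
        message(sprintf("epoch %d  loss %.4f  val dice %.4f",
                        epoch, eloss / steps, vd))
    }
  })
  best_model <- model
  if (is.finite(best$dice)) best_model$params <- best$params
  list(model = best_model, final_model = model,
       history = do.call(rbind, history))
}

#' Few-shot fine-tuning on a shifted domain
#'
#' Builds a fine-tuning corpus of `n_new` samples from the new domain mixed
#' with an equal number of samples from the original domain (guarding
#' against catastrophic forgetting), and trains with the one-cycle cosine
#' schedule.
#'
#' @param model A trained `wormnet`.
#' @param new_samples Labeled samples from the shifted domain.
#' @param old_samples Labeled samples from the original domain.
#' @param n_new Number of new-domain samples to use (`n_new = 0` returns
#'   the model unchanged).
#' @param cfg A [train_config()]; its scheduler is forced to one-cycle.
#' @return The fine-tuned `wormnet`.
#' @export
finetune_few_shot <- function(model, new_samples, old_samples, n_new,
                              cfg = train_config(scheduler = "one_cycle",
                                                 epochs = 250L)) {
  if (n_new > length(new_samples)) stop("n_new exceeds available new samples")
  if (n_new == 0L) return(model)
  if (length(old_samples) < n_new)
    stop(sprintf("need %d old-domain samples for equal mixing, have %d",
                 n_new, length(old_samples)))
  corpus <- with_seed(cfg$seed, {
    c(new_samples[sample(length(new_samples), n_new)],
      old_samples[sample(length(old_samples), n_new)])
  })
  cfg$scheduler <- "one_cycle"
  res <- train_model(model, list(train = corpus), cfg)
  res$final_model
}
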
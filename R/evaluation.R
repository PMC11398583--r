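#' Dice overlap between two binary masks
#'
#' `2|P ∩ T| / (|P| + |T|)`. Two empty masks are defined to have Dice 1
#' (identity of empty predictions).
#'
#' @param pred,truth `binary_mask` objects or logical matrices of the same
#'   shape.
#' @return Dice score in [0, 1].
#' @export
dice <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$grid else pred
  t <- if (inherits(truth, "binary_mask")) truth$grid else truth
  if (!all(dim(p) == dim(t))) stop("mask shapes differ")
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Length and volume ratios of predicted vs ground-truth masks
#'
#' `length_ratio` is the predicted skeleton length divided by the
#' ground-truth skeleton length; `volume_ratio` the analogous ratio of
#' channel-height-aware volumes.
#'
#' @param pred,truth Non-empty `binary_mask` objects.
#' @param geometry A [channel_geometry()] (volume only).
#' @param channel_origin_um Axial origin (volume only).
#' @return A single ratio.
#' @export
length_ratio <- function(pred, truth) {
  if (!any(truth$grid)) stop("ground-truth mask is empty")
  if (!any(pred$grid)) stop("predicted mask is empty")
  skeleton_length(pred) / skeleton_length(truth)
}

#' @rdname length_ratio
#' @export
volume_ratio <- function(pred, truth, geometry = channel_geometry("3L"),
                         channel_origin_um = 0) {
  if (!any(truth$grid)) stop("ground-truth mask is empty")
  body_volume(pred, geometry, channel_origin_um) /
    body_volume(truth, geometry, channel_origin_um)
}

#' Weighted F1 score for channel classification
#'
#' Per-class F1 scores averaged with weights equal to the true-class support.
#' A class never predicted has F1 = 0.
#'
#' @param pred_labels,true_labels Character vectors (values in
#'   full/partial/empty) of equal length.
#' @return Weighted F1 in [0, 1].
#' @export
weighted_f1 <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("label vectors must have equal length")
  classes <- unique(true_labels)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(pred_labels == cl & true_labels == cl)
    fp <- sum(pred_labels == cl & true_labels != cl)
    fn <- sum(pred_labels != cl & true_labels == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp)
    r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 0)
  support <- vapply(classes, function(cl) sum(true_labels == cl), 0)
  sum(f1s * support) / sum(support)
}

#' Compare per-sample Dice scores of two models
#'
#' Two-sided Wilcoxon signed-rank test on paired per-sample Dice
#' differences. Zero differences are dropped (standard signed-rank
#' convention); if every difference is zero, `p = 1` by convention.
#'
#' @param dice_a,dice_b Paired numeric vectors of per-sample Dice scores.
#' @return A list with `statistic` and `p_value`.
#' @export
compare_models <- function(dice_a, dice_b) {
  if (length(dice_a) != length(dice_b)) stop("paired samples must have equal length")
  d <- dice_a - dice_b
  if (all(d == 0)) return(list(statistic = 0, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(dice_a, dice_b, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Pairwise Dice table between multiple scorers
#'
#' For every unordered pair of scorers and every shared sample, the Dice
#' between the two scorers' masks. Samples missing for either scorer of a
#' pair are excluded from that pair.
#'
#' @param mask_sets A named list (one element per scorer) of lists of
#'   `binary_mask` objects over shared sample names/indices.
#' @return A data.frame with columns `scorer_a`, `scorer_b`, `sample`,
#'   `dice`.
#' @export
inter_scorer_dice <- function(mask_sets) {
  ns <- length(mask_sets)
  if (ns < 2L) stop("need at least 2 scorers")
  scorers <- names(mask_sets)
  if (is.null(scorers)) scorers <- paste0("S", seq_len(ns))
  out <- list()
  for (a in seq_len(ns - 1L)) {
    for (b in (a + 1L):ns) {
      shared <- intersect(seq_along(mask_sets[[a]]), seq_along(mask_sets[[b]]))
      for (s in shared) {
        ma <- mask_sets[[a]][[s]]
        mb <- mask_sets[[b]][[s]]
        if (is.null(ma) || is.null(mb)) next
        out[[length(out) + 1L]] <- data.frame(
          scorer_a = scorers[a], scorer_b = scorers[b], sample = s,
          dice = dice(ma, mb), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Evaluation report for a set of predictions
#'
#' @param pred_masks,true_masks Lists of `binary_mask` (may contain `NULL`
#'   for non-full channels; pairs with a `NULL` are skipped for mask
#'   metrics).
#' @param pred_labels,true_labels Channel class labels.
#' @param geometry A [channel_geometry()] for volume ratios.
#' @return A list of class `eval_report`: per-sample dice, mean +- sem,
#'   length/volume ratio summaries, weighted F1, 3x3 confusion matrix.
#' @export
eval_report <- function(pred_masks, true_masks, pred_labels, true_labels,
                        geometry = channel_geometry("3L")) {
  keep <- which(!vapply(pred_masks, is.null, TRUE) &
                  !vapply(true_masks, is.null, TRUE))
  ds <- vapply(keep, function(i) dice(pred_masks[[i]], true_masks[[i]]), 0)
  lr <- vapply(keep, function(i) {
    if (any(pred_masks[[i]]$grid) && any(true_masks[[i]]$grid))
      length_ratio(pred_masks[[i]], true_masks[[i]]) else NA_real_
  }, 0)
  vr <- vapply(keep, function(i) {
    if (any(pred_masks[[i]]$grid) && any(true_masks[[i]]$grid))
      volume_ratio(pred_masks[[i]], true_masks[[i]], geometry) else NA_real_
  }, 0)
  lv <- c("full", "partial", "empty")
  cm <- table(factor(true_labels, levels = lv), factor(pred_labels, levels = lv))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(dice = ds,
                 dice_mean = mean(ds), dice_sem = sem(ds),
                 length_ratio_mean = mean(lr, na.rm = TRUE),
                 length_ratio_sem = sem(lr[!is.na(lr)]),
                 volume_ratio_mean = mean(vr, na.rm = TRUE),
                 volume_ratio_sem = sem(vr[!is.na(vr)]),
                 weighted_f1 = weighted_f1(pred_labels, true_labels),
                 confusion = cm, n_samples = length(true_labels)),
            class = "eval_report")
}
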
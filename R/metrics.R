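#' Threshold a probability map into a binary mask
#'
#' Pixels strictly greater than the threshold become vessel (1); pixels at
#' or below it become background (0). The tie-to-background rule makes the
#' strict "greater than" reading deterministic.
#'
#' @param prob_map numeric matrix in `[0, 1]`.
#' @param threshold scalar in `[0, 1]` (default 0.5).
#' @return binary matrix.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  abort_if(threshold < 0 || threshold > 1, "threshold must lie in [0, 1]")
  (prob_map > threshold) * 1
}

#' Confusion counts restricted to the FOV
#'
#' @param pred binary prediction matrix.
#' @param truth binary ground-truth matrix.
#' @param fov binary FOV mask; only pixels with `fov == 1` are counted.
#' @return named vector `(tp, fp, tn, fn)` summing to the FOV pixel count.
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  if (is.null(fov)) fov <- matrix(1, nrow(pred), ncol(pred))
  abort_if(!identical(dim(pred), dim(truth)) || !identical(dim(pred), dim(fov)),
           "pred, truth and fov must share dimensions")
  p <- pred[fov == 1]; t <- truth[fov == 1]
  c(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
    tn = sum(p == 0 & t == 0), fn = sum(p == 0 & t == 1))
}

#' Area under the ROC curve
#'
#' Computed in the rank (Mann-Whitney) form with ties counted half, which
#' equals the trapezoidal area over all distinct thresholds of the score
#' map. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric vector of vessel probabilities/scores.
#' @param truth binary vector of the same length.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if `truth` has one class.
#' @export
compute_auc <- function(scores, truth) {
  np <- sum(truth == 1); nn <- sum(truth == 0)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: truth contains a single class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity `TN/(TN+FP)`, sensitivity
#' `TP/(TP+FN)`, precision `TP/(TP+FP)` and their harmonic-mean F1
#' `2*Precision*Sn/(Precision+Sn)`; AUC is added when a probability map is
#' supplied. Degenerate denominators (no predicted or no true positives)
#' yield 0 and set the `degenerate` flag instead of erroring.
#'
#' @param counts named `(tp, fp, tn, fn)` vector from [confusion_counts()].
#' @param prob_map optional probability matrix for AUC.
#' @param truth optional truth matrix (required with `prob_map`).
#' @param fov optional FOV mask.
#' @return a one-row `data.frame`: counts, `acc`, `sp`, `sn`, `precision`,
#'   `f1`, `auc`, `n_pixels`, `degenerate`.
#' @export
compute_metrics <- function(counts, prob_map = NULL, truth = NULL, fov = NULL) {
  tp <- counts["tp"]; fp <- counts["fp"]; tn <- counts["tn"]; fn <- counts["fn"]
  n <- tp + fp + tn + fn
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  acc <- safe_div(tp + tn, n)
  sp <- safe_div(tn, tn + fp)
  sn <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- if (precision + sn == 0) { degenerate <- TRUE; 0 } else
    2 * precision * sn / (precision + sn)
  auc <- NA_real_
  if (!is.null(prob_map)) {
    abort_if(is.null(truth), "truth is required to compute AUC")
    if (is.null(fov)) fov <- matrix(1, nrow(truth), ncol(truth))
    auc <- compute_auc(prob_map[fov == 1], truth[fov == 1])
  }
  data.frame(tp = unname(tp), fp = unname(fp), tn = unname(tn), fn = unname(fn),
             acc = unname(acc), sp = unname(sp), sn = unname(sn),
             precision = unname(precision), f1 = unname(f1), auc = auc,
             n_pixels = unname(n), degenerate = degenerate)
}

#' Full inference and scoring on one sample
#'
#' Tiles the sample's image into overlapping patches, predicts vessel
#' probabilities, recombines them by averaging, thresholds, and scores
#' against the sample's vessel mask inside its FOV.
#'
#' @param model a trained `unet_model`.
#' @param sample a preprocessed [fundus_sample()].
#' @param cfg a [sampling_config()] (patch size and test stride).
#' @param threshold binarization threshold (default 0.5).
#' @return a one-row metrics `data.frame` (see [compute_metrics()]) with a
#'   `prob_map` attribute holding the full-frame probability map.
#' @export
evaluate_sample <- function(model, sample, cfg = sampling_config(),
                            threshold = 0.5) {
  tl <- tile_test_patches(sample$image, cfg)
  probs <- predict_patches(model, tl$patches)
  pm <- recombine(probs, tl$layout)
  pred <- binarize(pm, threshold)
  counts <- confusion_counts(pred, sample$vessel_mask, sample$fov_mask)
  rep <- compute_metrics(counts, pm, sample$vessel_mask, sample$fov_mask)
  rep$sample_id <- sample$sample_id
  attr(rep, "prob_map") <- pm
  rep
}
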
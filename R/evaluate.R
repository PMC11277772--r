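#' Confusion-count classification metrics
#'
#' From TP/TN/FP/FN counts: accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and `F1 = 2 * precision * recall / (precision + recall)`.
#' Ratios with zero denominators are returned as `NaN` and flagged;
#' F1 is 0 when precision + recall is 0 but both are defined.
#'
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return named list with the five metrics and `undefined` (character
#'   vector naming any metric with a zero denominator).
#' @export
classification_metrics <- function(TP, TN, FP, FN) {
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion counts")
  if (min(TP, TN, FP, FN) < 0) stop("counts must be nonnegative")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  precision <- ratio(TP, TP + FP)
  sensitivity <- ratio(TP, TP + FN)
  specificity <- ratio(TN, TN + FP)
  f1 <- if (is.nan(precision) || is.nan(sensitivity)) {
    NaN
  } else if (precision + sensitivity == 0) {
    0
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  out <- list(accuracy = (TP + TN) / total, precision = precision,
              f1 = f1, sensitivity = sensitivity, specificity = specificity)
  out$undefined <- names(out)[vapply(out, function(v)
    is.numeric(v) && is.nan(v), logical(1))]
  out
}

#' Multiclass metrics (one-vs-rest and macro average)
#'
#' @param truth,pred integer class vectors.
#' @param nclass number of classes (defaults to the observed maximum).
#' @return list with `confusion` (nclass x nclass matrix, truth in
#'   rows), `per_class` (metric list per class, one-vs-rest) and `macro`
#'   (means over classes, NaN-stripped).
#' @export
multiclass_metrics <- function(truth, pred, nclass = max(truth, pred)) {
  conf <- matrix(0L, nclass, nclass,
                 dimnames = list(truth = seq_len(nclass),
                                 pred = seq_len(nclass)))
  for (i in seq_along(truth)) {
    conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  }
  per_class <- lapply(seq_len(nclass), function(k) {
    TP <- conf[k, k]
    FN <- sum(conf[k, -k])
    FP <- sum(conf[-k, k])
    TN <- sum(conf[-k, -k])
    classification_metrics(TP, TN, FP, FN)
  })
  metric_names <- c("accuracy", "precision", "f1", "sensitivity",
                    "specificity")
  macro <- vapply(metric_names, function(mn) {
    v <- vapply(per_class, function(pc) pc[[mn]], numeric(1))
    mean(v[!is.nan(v)])
  }, numeric(1))
  list(confusion = conf, per_class = per_class, macro = as.list(macro),
       accuracy = sum(diag(conf)) / sum(conf))
}

#' ROC curve points and area
#'
#' Sweeps thresholds over the score range (every distinct score plus
#' sentinels so both the (sensitivity 0) and (sensitivity 1) endpoints
#' appear), records (specificity, sensitivity) pairs, and integrates the
#' area under the sensitivity vs (1 - specificity) curve by the
#' trapezoid rule.
#'
#' @param scores numeric ranking statistic (larger = more positive).
#' @param labels binary 0/1 (or logical) truth, 1 = positive.
#' @return list with `points` (data frame: threshold, specificity,
#'   sensitivity) and `area`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- scores >= thr[i]
    sens[i] <- sum(pos & labels == 1) / np
    spec[i] <- sum(!pos & labels == 0) / nn
  }
  fpr <- 1 - spec
  area <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  list(points = data.frame(threshold = thr, specificity = spec,
                           sensitivity = sens),
       area = area)
}

#' Run the full phantom-classification pipeline
#'
#' End-to-end orchestration on synthetic phantoms: generate a balanced
#' dataset, Butterworth-smooth every slice, optionally enhance with a
#' trained sparse-coding network, extract the 16-element GLCM texture
#' vector, append the six semantic annotation scores (absent scores for
#' normal slices encoded as 0), run crow-search feature selection on the
#' training split, fit the PNN on the selected features and classify the
#' test split.
#'
#' @param n_train,n_test phantoms per split (balanced over the three
#'   classes; must be divisible by 3).
#' @param size phantom side length in pixels.
#' @param seed master seed for the whole run.
#' @param filter_mode `"lowpass"` (denoising default) or `"highpass"`.
#' @param enhance optional trained `scnn_params`; when supplied each
#'   filtered slice is degraded/enhanced before texture extraction.
#' @param ccsa a `ccsa_config` for the selection stage.
#' @param sigma PNN bandwidth.
#' @param use_semantic append the six annotation scores (diameter,
#'   margin, spiculation, lobulation, subtlety, malignancy).
#' @return list with `metrics` (multiclass bundle), `roc_malignant`,
#'   `selection` (crow-search result), `truth`, `pred`, `scores`,
#'   `feature_names`.
#' @export
run_pipeline <- function(n_train = 201L, n_test = 99L, size = 128L,
                         seed = 1L, filter_mode = "lowpass",
                         enhance = NULL, ccsa = ccsa_config(),
                         sigma = 0.3, use_semantic = TRUE) {
  if (n_train %% 3 != 0 || n_test %% 3 != 0)
    stop("`n_train` and `n_test` must be divisible by 3")
  ds <- generate_phantom_dataset((n_train + n_test) / 3, size = size,
                                 seed = seed)
  n_all <- length(ds$images)
  labels <- vapply(ds$annotations, function(a)
    match(a$label, c("normal", "benign", "malignant")), integer(1))

  feats <- t(vapply(seq_len(n_all), function(i) {
    img <- butterworth_filter(ds$images[[i]], mode = filter_mode)
    if (!is.null(enhance)) {
      dp <- degrade_pair(img, enhance$config$factor, noise_sd = 0,
                         seed = derive_seed(seed, 500000 + i))
      img <- scnn_forward(dp$low, enhance)
    }
    extract_texture_vector(img)
  }, numeric(16)))

  fnames <- colnames(feats)
  if (use_semantic) {
    sem <- t(vapply(ds$annotations, function(a) {
      v <- c(a$diameter_mm, a$margin, a$spiculation, a$lobulation,
             a$subtlety, a$malignancy)
      v[is.na(v)] <- 0
      v
    }, numeric(6)))
    colnames(sem) <- c("diameter", "margin", "spiculation", "lobulation",
                       "subtlety", "malignancy")
    feats <- cbind(feats, sem)
    fnames <- colnames(feats)
  }

  # deterministic stratified split
  set.seed(derive_seed(seed, 777))
  tr_idx <- integer(0)
  for (k in 1:3) {
    idx <- which(labels == k)
    tr_idx <- c(tr_idx, sample(idx, n_train / 3))
  }
  te_idx <- setdiff(seq_len(n_all), tr_idx)

  train_tab <- feature_table(feats[tr_idx, , drop = FALSE], labels[tr_idx],
                             fnames)
  selection <- ccsa_select(train_tab, ccsa, seed = derive_seed(seed, 13))
  sel <- which(selection$mask == 1)

  sel_train <- feature_table(feats[tr_idx, sel, drop = FALSE],
                             labels[tr_idx], fnames[sel])
  model <- fit_pnn(sel_train, sigma = sigma)
  res <- pnn_classify(model, feats[te_idx, sel, drop = FALSE])

  truth <- labels[te_idx]
  metrics <- multiclass_metrics(truth, res$class, nclass = 3)
  roc_mal <- roc_points(res$scores[, 3], as.integer(truth == 3))

  list(metrics = metrics, roc_malignant = roc_mal, selection = selection,
       truth = truth, pred = res$class, scores = res$scores,
       feature_names = fnames)
}
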
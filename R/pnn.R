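#' Fit a probabilistic neural network
#'
#' A PNN is "trained" by storing the patterns: every training vector
#' becomes a pattern unit after per-feature standardization (zero mean,
#' unit variance computed on the training data).  Class priors default to
#' the class frequencies and misclassification costs to 1; explicit
#' priors that do not sum to one are normalized with a warning.
#'
#' @param table a `feature_table` (every class must be present).
#' @param sigma Gaussian kernel bandwidth (> 0) on the standardized
#'   scale.
#' @param priors optional per-class prior probabilities.
#' @param costs optional per-class misclassification costs.
#' @return list of class `pnn_model`.
#' @export
fit_pnn <- function(table, sigma = 0.3, priors = NULL, costs = NULL) {
  if (sigma <= 0) stop("`sigma` must be positive")
  y <- table$labels
  nclass <- max(y)
  counts <- tabulate(y, nbins = nclass)
  if (any(counts == 0)) stop("every class 1..c must have at least 1 pattern")
  if (is.null(priors)) {
    priors <- counts / sum(counts)
  } else {
    if (length(priors) != nclass) stop("`priors` must have one entry per class")
    if (abs(sum(priors) - 1) > 1e-8) {
      warning("priors do not sum to 1; normalizing")
      priors <- priors / sum(priors)
    }
  }
  if (is.null(costs)) costs <- rep(1, nclass)
  mu <- colMeans(table$features)
  # population standard deviation: keeps the stored model invariant to
  # duplicating the whole training set
  sdv <- sqrt(colMeans(sweep(table$features, 2, mu, `-`)^2))
  sdv[sdv == 0] <- 1
  patterns <- sweep(sweep(table$features, 2, mu, `-`), 2, sdv, `/`)
  structure(list(patterns = patterns, labels = y, counts = counts,
                 priors = priors, costs = costs, sigma = sigma,
                 center = mu, scale = sdv, nclass = nclass,
                 feature_names = table$feature_names),
            class = "pnn_model")
}

#' Classify with a probabilistic neural network
#'
#' Per-class Parzen density
#' `f_k(x) = (1/m_k) * sum_{w in class k} exp(-||x - w||^2 / (2 sigma^2))`
#' on the standardized scale; the decision is
#' `argmax_k prior_k * cost_k * f_k(x)` with ties going to the smallest
#' class index.  Scores are the normalized products (posterior weights
#' summing to 1 per query).
#'
#' @param model a `pnn_model`.
#' @param x a feature vector or a matrix of query rows on the original
#'   (unstandardized) scale.
#' @return list with `class` (integer vector) and `scores` (matrix,
#'   queries x classes, rows summing to 1).
#' @export
pnn_classify <- function(model, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != ncol(model$patterns))
    stop("query dimension does not match the model")
  Xs <- sweep(sweep(X, 2, model$center, `-`), 2, model$scale, `/`)
  nq <- nrow(Xs)
  dens <- matrix(0, nq, model$nclass)
  # squared distances query x pattern
  d2 <- outer(rowSums(Xs^2), rep(1, nrow(model$patterns))) +
    outer(rep(1, nq), rowSums(model$patterns^2)) -
    2 * Xs %*% t(model$patterns)
  d2[d2 < 0] <- 0
  # guard against total underflow at tiny bandwidths: shift by the
  # per-query minimum distance (monotone, does not change the argmax)
  shift <- apply(d2, 1, min)
  K <- exp(-(d2 - shift) / (2 * model$sigma^2))
  for (k in seq_len(model$nclass)) {
    cols <- model$labels == k
    dens[, k] <- rowSums(K[, cols, drop = FALSE]) / model$counts[k]
  }
  w <- sweep(dens, 2, model$priors * model$costs, `*`)
  cls <- apply(w, 1, which.max) # ties -> smallest class index
  scores <- w / rowSums(w)
  colnames(scores) <- paste0("class_", seq_len(model$nclass))
  list(class = as.integer(cls), scores = scores)
}

#' Summation-unit weight of the binary PNN decision
#'
#' For the two-class decision between class `a` and class `b`, the
#' summation layer weights the class-`b` kernel sum by
#' `v_b = -(prior_b * cost_b * m_a) / (prior_a * cost_a * m_b)` and the
#' decision unit declares class `a` exactly when
#' `sum(kernels_a) + v_b * sum(kernels_b) > 0`.  This is algebraically
#' the two-class Bayes rule `prior_a cost_a f_a > prior_b cost_b f_b`.
#'
#' @param priors,costs,counts numeric vectors indexed by class.
#' @param a,b the two class indices.
#' @return the scalar weight `v_b`.
#' @export
summation_weight <- function(priors, costs, counts, a, b) {
  -(priors[b] * costs[b] * counts[a]) / (priors[a] * costs[a] * counts[b])
}

#' Binary PNN decision through the summation unit
#'
#' @param model a `pnn_model`.
#' @param x single query vector (original scale).
#' @param a,b the two competing class indices.
#' @return the winning class index (`a` when the decision-unit input is
#'   positive).
#' @export
pnn_binary_decide <- function(model, x, a, b) {
  Xs <- (x - model$center) / model$scale
  d2 <- colSums((t(model$patterns) - Xs)^2)
  K <- exp(-d2 / (2 * model$sigma^2))
  vb <- summation_weight(model$priors, model$costs, model$counts, a, b)
  s <- sum(K[model$labels == a]) + vb * sum(K[model$labels == b])
  if (s > 0) a else b
}
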
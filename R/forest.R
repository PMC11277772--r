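#' Gini impurity and split quality
#'
#' `gini = 1 - sum(p_i^2)` over class frequencies; the split score is the
#' sample-weighted mean of the child impurities
#' `(N1/N) G(t1) + (N2/N) G(t2)`.  The feature/threshold pair with the
#' least split score is the one a tree node adopts.
#'
#' @param parent,left,right nonnegative integer class-count vectors with
#'   `left + right == parent` elementwise (`left`/`right` may be omitted
#'   to obtain only the parent impurity).
#' @return list with `gini` (parent impurity) and `split_gini` (weighted
#'   child impurity, `NA` when no children are given).
#' @export
gini_and_split <- function(parent, left = NULL, right = NULL) {
  n <- sum(parent)
  if (n == 0) stop("empty parent node")
  gini <- function(cnt) {
    s <- sum(cnt)
    if (s == 0) return(0)
    1 - sum((cnt / s)^2)
  }
  g <- gini(parent)
  sg <- NA_real_
  if (!is.null(left)) {
    if (is.null(right)) right <- parent - left
    if (any(left + right != parent) || any(left < 0) || any(right < 0))
      stop("`left` + `right` must equal `parent` elementwise")
    sg <- (sum(left) * gini(left) + sum(right) * gini(right)) / n
  }
  list(gini = g, split_gini = sg)
}

#' Build a random forest of Gini-split trees
#'
#' `K` unpruned CART-style trees, each grown on a bootstrap sample of
#' size `N` whose in-bag multiset is recorded for out-of-bag accounting.
#' At every node `mtry` candidate features are drawn uniformly; when
#' `groups` is supplied the draw is stratified: `ceiling(mtry/2)`
#' candidates from the strong group `Ys` and `floor(mtry/2)` from the
#' weak group `Yw`, with always at least one from `Ys`.  Split ties are
#' broken deterministically (lowest feature index, then lowest
#' threshold).  Call under `set.seed()` for reproducibility.
#'
#' @param table a `feature_table`.
#' @param K number of trees.
#' @param mtry candidate features per node; default `ceiling(sqrt(M))`.
#' @param nmin minimum node size (leaves are pure or hold >= `nmin`
#'   samples).
#' @param groups optional list with integer vectors `Ys` and `Yw` of
#'   column indices for the group-stratified subspace draw.
#' @return an object of class `rf_forest` holding the trees, the in-bag
#'   count matrix and the training metadata.
#' @export
build_forest <- function(table, K = 100L, mtry = NULL, nmin = 1L,
                         groups = NULL) {
  X <- table$features
  y <- table$labels
  M <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(M))
  if (mtry < 1 || mtry > M) stop("`mtry` must lie in 1..M")
  if (K < 1) stop("`K` must be at least 1")
  nclass <- max(y)
  gs <- integer(0); gw <- integer(0)
  if (!is.null(groups)) {
    gs <- as.integer(groups$Ys)
    gw <- as.integer(groups$Yw)
    if (length(gs) == 0) stop("`groups$Ys` must be non-empty")
  }
  fit <- .rf_build_cpp(X, as.integer(y), nclass, as.integer(K),
                       as.integer(mtry), as.integer(nmin), gs, gw)
  structure(list(trees = fit$trees, inbag = fit$inbag, K = K, mtry = mtry,
                 nmin = nmin, nclass = nclass, n = nrow(X), M = M,
                 groups = groups),
            class = "rf_forest")
}

majority_vote <- function(votes, nclass) {
  # ties broken by smallest class index
  counts <- tabulate(votes, nbins = nclass)
  which.max(counts)
}

#' Predict classes by majority vote
#'
#' @param forest an `rf_forest`.
#' @param X numeric matrix of samples in rows (or a `feature_table`).
#' @return integer vector of predicted classes; ties go to the smallest
#'   class index.
#' @export
predict_majority <- function(forest, X) {
  if (inherits(X, "feature_table")) X <- X$features
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (length(forest$trees) == 0) stop("forest has no trees")
  votes <- .rf_predict_cpp(forest$trees, as.matrix(X))
  apply(votes, 1, majority_vote, nclass = forest$nclass)
}

#' Out-of-bag error of a forest
#'
#' Each sample is predicted by majority vote over the trees whose
#' bootstrap bag excludes it; the error rate is the mean 0/1 loss over
#' samples with at least one out-of-bag vote.  Samples that appear in
#' every bag are excluded from the average and counted.
#'
#' @param forest an `rf_forest` built on `table` (bags are recorded).
#' @param table the `feature_table` the forest was built on.
#' @return list with `error`, `predictions` (NA where no OOB vote),
#'   `n_no_oob` (samples in every bag) and `oob_counts` (OOB votes per
#'   sample).
#' @export
oob_error <- function(forest, table) {
  if (length(forest$trees) == 0) stop("forest has no trees")
  X <- table$features
  y <- table$labels
  votes <- .rf_predict_cpp(forest$trees, X)
  oob <- forest$inbag == 0
  preds <- rep(NA_integer_, nrow(X))
  ncnt <- rowSums(oob)
  for (i in which(ncnt > 0)) {
    preds[i] <- majority_vote(votes[i, oob[i, ]], forest$nclass)
  }
  ok <- !is.na(preds)
  list(error = mean(preds[ok] != y[ok]), predictions = preds,
       n_no_oob = sum(!ok), oob_counts = ncnt)
}

#' Gini importance per feature
#'
#' Sum, over the nodes of each tree that split on a feature, of the
#' decrease in Gini impurity, averaged over trees.
#'
#' @param forest an `rf_forest`.
#' @return numeric vector of length `M`.
#' @export
gini_importance <- function(forest) {
  imp <- numeric(forest$M)
  for (t in forest$trees) {
    internal <- which(t$feature > 0)
    for (nd in internal) {
      l <- t$left[nd] + 1L; r <- t$right[nd] + 1L
      drop <- t$gini[nd] -
        (t$nobs[l] * t$gini[l] + t$nobs[r] * t$gini[r]) / t$nobs[nd]
      imp[t$feature[nd]] <- imp[t$feature[nd]] + drop
    }
  }
  imp / length(forest$trees)
}

#' Permutation importance against shadow features
#'
#' For each of `R` replicates: every feature column is independently
#' permuted to create a shadow copy, the table is extended to width `2M`,
#' a forest is fit on it, and each column's permutation importance (mean
#' over trees of the increase in that tree's out-of-bag error when the
#' column's OOB values are permuted) is recorded.  The maximum importance
#' among the `M` shadows is the null benchmark for that replicate.
#'
#' @param table a `feature_table`.
#' @param R number of replicates (>= 5, needed by the rank test).
#' @param K,mtry,nmin forest parameters for the per-replicate fits.
#' @return list with `scores` (`R` x `M` real-feature importances) and
#'   `shadow_max` (length `R`).
#' @export
shadow_importance <- function(table, R = 20L, K = 100L, mtry = NULL,
                              nmin = 1L) {
  if (R < 5) stop("`R` must be at least 5")
  X <- table$features
  y <- as.integer(table$labels)
  N <- nrow(X); M <- ncol(X)
  scores <- matrix(NA_real_, R, M)
  shadow_max <- numeric(R)
  for (r in seq_len(R)) {
    shadows <- apply(X, 2, sample)
    Xext <- cbind(X, shadows)
    colnames(Xext) <- c(table$feature_names,
                        paste0("shadow_", table$feature_names))
    ext <- feature_table(Xext, y)
    fit <- build_forest(ext, K = K, mtry = mtry, nmin = nmin)
    imp <- .rf_perm_importance_cpp(fit$trees, fit$inbag, ext$features, y)
    scores[r, ] <- imp[seq_len(M)]
    shadow_max[r] <- max(imp[M + seq_len(M)])
  }
  colnames(scores) <- table$feature_names
  list(scores = scores, shadow_max = shadow_max)
}

#' Wilcoxon screening of importance scores
#'
#' One-sided rank-sum test per feature of its `R` replicate importances
#' against the `R` shadow-max values (alternative: feature scores are
#' larger); features with `p <= theta` are kept as informative.
#' Degenerate zero-variance comparisons return `p = 0.5` and are flagged.
#'
#' @param scores `R` x `M` importance matrix from [shadow_importance()].
#' @param shadow_max length-`R` shadow benchmark values.
#' @param theta significance threshold (default 0.05).
#' @return list with `keep` (integer indices of retained features),
#'   `p_values` and `degenerate` (logical).
#' @export
wilcoxon_screen <- function(scores, shadow_max, theta = 0.05) {
  R <- nrow(scores)
  if (R < 5) stop("need at least 5 replicates")
  M <- ncol(scores)
  p <- numeric(M)
  degen <- logical(M)
  for (j in seq_len(M)) {
    x <- scores[, j]
    if (stats::sd(c(x, shadow_max)) == 0) {
      p[j] <- 0.5
      degen[j] <- TRUE
    } else {
      p[j] <- suppressWarnings(
        stats::wilcox.test(x, shadow_max, alternative = "greater",
                           exact = FALSE, correct = TRUE)$p.value)
      # exact p when there are no ties (matches the minimal attainable
      # 1/choose(2R, R) when all feature scores dominate)
      if (!anyDuplicated(c(x, shadow_max))) {
        p[j] <- suppressWarnings(
          stats::wilcox.test(x, shadow_max, alternative = "greater",
                             exact = TRUE)$p.value)
      }
    }
  }
  names(p) <- colnames(scores)
  list(keep = which(p <= theta), p_values = p, degenerate = degen)
}

#' Chi-square grouping of screened features
#'
#' Discretizes each retained feature into quantile bins, forms the
#' bin-by-class contingency table and computes the chi-square statistic
#' `sum (O - E)^2 / E` with `(rows - 1)(cols - 1)` degrees of freedom.
#' Features with `p < alpha2` join the strongly associated group `Ys`,
#' the rest the weak group `Yw`.  Bins whose expected counts are zero
#' (empty quantile bins from heavily tied features) are merged into the
#' neighbouring bin before the statistic.
#'
#' @param table a `feature_table`.
#' @param keep integer indices of screened-in features.
#' @param bins number of quantile bins (default 4).
#' @param alpha2 significance level for the grouping (default 0.05).
#' @return list with `Ys`, `Yw` (integer index vectors), `statistics` and
#'   `p_values` named by feature.
#' @export
chi_square_group <- function(table, keep, bins = 4L, alpha2 = 0.05) {
  if (length(keep) == 0) stop("`keep` must be non-empty")
  if (bins < 2) stop("`bins` must be at least 2")
  y <- table$labels
  stats_out <- p_out <- numeric(length(keep))
  for (i in seq_along(keep)) {
    x <- table$features[, keep[i]]
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 3) br <- c(min(x) - 1, stats::median(x), max(x) + 1)
    g <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
    O <- base::table(g, y)
    O <- O[rowSums(O) > 0, , drop = FALSE]
    res <- chi_square_statistic(unclass(O))
    stats_out[i] <- res$statistic
    p_out[i] <- res$p_value
  }
  names(stats_out) <- names(p_out) <- table$feature_names[keep]
  sel <- p_out < alpha2
  list(Ys = keep[sel], Yw = keep[!sel], statistics = stats_out,
       p_values = p_out)
}

#' Chi-square statistic of a contingency table
#'
#' `Y2 = sum (O - E)^2 / E` with `E[j, i] = row_j * col_i / N`, degrees of
#' freedom `(rows - 1)(cols - 1)`.
#'
#' @param observed nonnegative count matrix.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_statistic <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("counts must be nonnegative")
  n <- sum(observed)
  if (n == 0) stop("empty contingency table")
  E <- outer(rowSums(observed), colSums(observed)) / n
  ok <- E > 0
  stat <- sum((observed[ok] - E[ok])^2 / E[ok])
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Probability that a random feature subset is all-uninformative
#'
#' With `M` features of which `D` are noise, the probability that a
#' uniformly drawn `m`-subset contains no informative feature is
#' `choose(M - D, m) / choose(M, m)`; the multiplicative approximation
#' `(1 - D/M)^m` is returned alongside.  (Here the exact quantity is the
#' chance of drawing only from the `M - D` complement, i.e. of missing
#' every one of the `D` marked features.)
#'
#' @param M total features; `D` marked features; `m` subset size.
#' @return list with `exact` and `approx`.
#' @export
subset_probability <- function(M, D, m) {
  if (D < 0 || D > M) stop("`D` must lie in 0..M")
  if (m < 1 || m > M) stop("`m` must lie in 1..M")
  exact <- if (m > M - D) 0 else choose(M - D, m) / choose(M, m)
  list(exact = exact, approx = (1 - D / M)^m)
}

#' Bi-level forest screening pipeline
#'
#' Runs the full shadow-importance / Wilcoxon / chi-square cascade:
#' replicate permutation importances against shadow features, rank-sum
#' screening at `theta`, then chi-square grouping of the survivors into
#' strong (`Ys`) and weak (`Yw`) groups, ready for the group-stratified
#' forest of [build_forest()].
#'
#' @inheritParams shadow_importance
#' @inheritParams wilcoxon_screen
#' @inheritParams chi_square_group
#' @return list with `informative` (screened-in indices), `Ys`, `Yw`,
#'   `p_values`, `scores`, `shadow_max`, `chi_square`.
#' @export
rf_screen <- function(table, R = 20L, K = 100L, theta = 0.05, bins = 4L,
                      alpha2 = 0.05, mtry = NULL) {
  si <- shadow_importance(table, R = R, K = K, mtry = mtry)
  ws <- wilcoxon_screen(si$scores, si$shadow_max, theta = theta)
  if (length(ws$keep) == 0) {
    return(list(informative = integer(0), Ys = integer(0), Yw = integer(0),
                p_values = ws$p_values, scores = si$scores,
                shadow_max = si$shadow_max, chi_square = NULL))
  }
  cs <- chi_square_group(table, ws$keep, bins = bins, alpha2 = alpha2)
  list(informative = ws$keep, Ys = cs$Ys, Yw = cs$Yw,
       p_values = ws$p_values, scores = si$scores,
       shadow_max = si$shadow_max, chi_square = cs)
}
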
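#' Chaotic map sequences
#'
#' Deterministic iteration of one of ten standard chaotic maps on (0, 1),
#' used in place of uniform draws to drive the crow-search position
#' updates.  Values are clipped to `(eps, 1 - eps)` so a trajectory never
#' collapses onto the interval ends.
#'
#' @param map_id one of `"logistic"`, `"tent"`, `"sine"`, `"circle"`,
#'   `"chebyshev"`, `"gauss"`, `"iterative"`, `"piecewise"`, `"singer"`,
#'   `"sinusoidal"`.
#' @param x0 starting value in (0, 1).
#' @param length number of values to produce.
#' @return numeric vector of `length` chaotic values in (0, 1).
#' @export
chaotic_sequence <- function(map_id = "logistic", x0 = 0.7, length = 1L) {
  step <- chaotic_step_fn(map_id)
  if (x0 <= 0 || x0 >= 1) stop("`x0` must lie strictly inside (0, 1)")
  eps <- 1e-6
  out <- numeric(length)
  x <- x0
  for (i in seq_len(length)) {
    x <- min(max(step(x), eps), 1 - eps)
    out[i] <- x
  }
  out
}

chaotic_maps <- c("logistic", "tent", "sine", "circle", "chebyshev",
                  "gauss", "iterative", "piecewise", "singer", "sinusoidal")

chaotic_step_fn <- function(map_id) {
  map_id <- match.arg(map_id, chaotic_maps)
  switch(map_id,
    logistic  = function(x) 4 * x * (1 - x),
    tent      = function(x) if (x < 0.5) 2 * x else 2 * (1 - x),
    sine      = function(x) sin(pi * x),
    circle    = function(x) (x + 0.2 - (0.5 / (2 * pi)) * sin(2 * pi * x)) %% 1,
    chebyshev = function(x) (cos(4 * acos(2 * x - 1)) + 1) / 2,
    gauss     = function(x) if (x == 0) 0 else (1 / x) %% 1,
    iterative = function(x) abs(sin(0.7 * pi / x)),
    piecewise = function(x) {
      p <- 0.4
      if (x < p) x / p
      else if (x < 0.5) (x - p) / (0.5 - p)
      else if (x < 1 - p) (1 - p - x) / (0.5 - p)
      else (1 - x) / p
    },
    singer    = function(x)
      1.07 * (7.86 * x - 23.31 * x^2 + 28.75 * x^3 - 13.302875 * x^4),
    sinusoidal = function(x) 2.3 * x^2 * sin(pi * x)
  )
}

#' Transfer function and binarization of a crow position
#'
#' The sigmoid transfer `v = 1 / (1 + exp(10 * (alpha - 0.5)))` maps a
#' continuous position component to a bit-probability (note the transfer
#' is decreasing in `alpha`, as printed in the source formulation); the
#' bit is 1 when `v >= u` for a uniform draw `u`.  `flip = TRUE` selects
#' the increasing orientation for experimentation.
#'
#' @param alpha continuous position component.
#' @param u uniform draw in \[0, 1\].
#' @param flip use the increasing orientation.
#' @return list with `v` (transfer value) and `bit` (0 or 1).
#' @export
transfer_and_binarize <- function(alpha, u, flip = FALSE) {
  s <- if (flip) -10 else 10
  v <- 1 / (1 + exp(s * (alpha - 0.5)))
  list(v = v, bit = as.integer(v >= u))
}

#' Crow search configuration
#'
#' Bundles the tunable parameters of the binary chaotic crow search:
#' flock size `H = 30`, awareness probability `AP = 0.1`, flight length
#' `kappa = 2`, position bounds `[0, 1]` and 50 iterations (the published
#' defaults), a feature-count penalty weight `lambda_F`, the chaotic map
#' driving the updates, and the number of cross-validation folds `h = 10`
#' used by the wrapper fitness.
#'
#' @param n_crows_H flock size.
#' @param awareness_AP probability that a crow notices it is followed and
#'   jumps to a random position, in \[0, 1\].
#' @param flight_length step scale toward the followed crow's memory.
#' @param max_iter_tau number of search iterations.
#' @param lambda_F weight of the subset-size reward in the fitness,
#'   in \[0, 1\].
#' @param chaotic_map one of the ten map names of [chaotic_sequence()].
#' @param cv_folds_h stratified cross-validation folds for the fitness.
#' @param lower,upper continuous position bounds.
#' @param K_trees,mtry forest size used inside the wrapper fitness.
#' @param flip_transfer orientation flag of [transfer_and_binarize()].
#' @return list of class `ccsa_config`.
#' @export
ccsa_config <- function(n_crows_H = 30L, awareness_AP = 0.1,
                        flight_length = 2, max_iter_tau = 50L,
                        lambda_F = 0.01, chaotic_map = "logistic",
                        cv_folds_h = 10L, lower = 0, upper = 1,
                        K_trees = 25L, mtry = NULL, flip_transfer = FALSE) {
  if (awareness_AP < 0 || awareness_AP > 1)
    stop("`awareness_AP` must lie in [0, 1]")
  if (lambda_F < 0 || lambda_F > 1) stop("`lambda_F` must lie in [0, 1]")
  if (max_iter_tau < 1) stop("`max_iter_tau` must be at least 1")
  structure(list(n_crows_H = n_crows_H, awareness_AP = awareness_AP,
                 flight_length = flight_length, max_iter_tau = max_iter_tau,
                 lambda_F = lambda_F, chaotic_map = chaotic_map,
                 cv_folds_h = cv_folds_h, lower = lower, upper = upper,
                 K_trees = K_trees, mtry = mtry,
                 flip_transfer = flip_transfer),
            class = "ccsa_config")
}

# stratified fold assignment, frozen once per search so that fitness
# differences reflect masks rather than fold noise
make_folds <- function(labels, h) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(h), length(idx)))
  }
  folds
}

#' Wrapper fitness of a feature subset
#'
#' `F = Accuracy + lambda_F * (1 - LF / Ltotal)` where `Accuracy` is the
#' mean stratified h-fold cross-validated accuracy of a small random
#' forest restricted to the masked features, `LF` the number of selected
#' features and `Ltotal` the total.  An all-zero mask is repaired by
#' setting one uniformly chosen bit before evaluation.
#'
#' @param table a `feature_table`.
#' @param mask 0/1 vector over features.
#' @param config a `ccsa_config`.
#' @param folds optional frozen fold assignment (integer vector); drawn
#'   fresh when omitted.
#' @return list with `fitness`, `accuracy`, `mask` (after any repair) and
#'   `repaired`.
#' @export
subset_fitness <- function(table, mask, config = ccsa_config(),
                           folds = NULL) {
  mask <- as.integer(mask)
  repaired <- FALSE
  if (sum(mask) == 0) {
    mask[sample.int(length(mask), 1)] <- 1L
    repaired <- TRUE
  }
  if (is.null(folds)) folds <- make_folds(table$labels, config$cv_folds_h)
  sel <- which(mask == 1)
  acc <- cv_accuracy(table, sel, folds, config$K_trees, config$mtry)
  fit <- acc + config$lambda_F * (1 - sum(mask) / length(mask))
  list(fitness = fit, accuracy = acc, mask = mask, repaired = repaired)
}

cv_accuracy <- function(table, sel, folds, K, mtry) {
  h <- max(folds)
  correct <- 0L; total <- 0L
  Xs <- table$features[, sel, drop = FALSE]
  for (f in seq_len(h)) {
    te <- folds == f
    if (!any(te) || length(unique(table$labels[!te])) < 2) next
    tr_tab <- feature_table(Xs[!te, , drop = FALSE], table$labels[!te])
    m <- if (is.null(mtry)) ceiling(sqrt(length(sel))) else
      min(mtry, length(sel))
    fit <- build_forest(tr_tab, K = K, mtry = m)
    pred <- predict_majority(fit, Xs[te, , drop = FALSE])
    correct <- correct + sum(pred == table$labels[te])
    total <- total + sum(te)
  }
  correct / total
}

#' One position-update sweep of the crow flock
#'
#' For each crow `l` a random peer `y` is drawn and one chaotic value
#' `sigma` is taken from the crow's chaotic stream.  If `sigma >= AP` the
#' crow follows the peer's memory:
#' `alpha <- alpha + sigma * kappa * (Q_y - alpha)`; otherwise it jumps
#' to a fresh uniform position.  Positions are clipped to the bounds and
#' re-binarized through [transfer_and_binarize()].
#'
#' @param pop population list (`positions`, `masks`, `mem_mask`,
#'   `mem_fit`, `chaos`).
#' @param config a `ccsa_config`.
#' @return the updated population.
#' @export
update_positions <- function(pop, config) {
  H <- nrow(pop$positions)
  L <- ncol(pop$positions)
  step <- chaotic_step_fn(config$chaotic_map)
  eps <- 1e-6
  for (l in seq_len(H)) {
    y <- sample.int(H, 1)
    sig <- min(max(step(pop$chaos[l]), eps), 1 - eps)
    pop$chaos[l] <- sig
    if (sig >= config$awareness_AP) {
      # follow: move toward peer y's memorized best mask Q_y
      q <- pop$mem_mask[y, ]
      pop$positions[l, ] <- pop$positions[l, ] +
        sig * config$flight_length * (q - pop$positions[l, ])
    } else {
      pop$positions[l, ] <- runif(L, config$lower, config$upper)
    }
  }
  pop$positions <- pmin(pmax(pop$positions, config$lower), config$upper)
  for (l in seq_len(H)) {
    u <- runif(L)
    tb <- transfer_and_binarize(pop$positions[l, ], u,
                                flip = config$flip_transfer)
    pop$masks[l, ] <- tb$bit
  }
  pop
}

#' Binary chaotic crow search feature selection
#'
#' Runs the full wrapper search: a flock of `H` crows holds continuous
#' positions in `[0, 1]^L` that are binarized into feature masks, each
#' mask is scored by [subset_fitness()] under one frozen stratified fold
#' assignment, and each crow's memory keeps its best mask so far
#' (fitness never decreases).  After `max_iter_tau` sweeps the best
#' memory over all crows is returned together with the best-so-far
#' fitness trace.
#'
#' @param table a `feature_table` with at least 2 classes and 2 features.
#' @param config a `ccsa_config`.
#' @param seed integer seed controlling the entire search.
#' @return list with `mask` (0/1 vector), `fitness`, `history`
#'   (best-so-far fitness per iteration, length `max_iter_tau`),
#'   `n_evaluations` (distinct masks scored) and `selected` (feature
#'   names of the mask).
#' @export
ccsa_select <- function(table, config = ccsa_config(), seed = 1L) {
  L <- ncol(table$features)
  if (L < 2) stop("need at least 2 features")
  if (length(unique(table$labels)) < 2) stop("need at least 2 classes")
  set.seed(seed)
  H <- config$n_crows_H
  folds <- make_folds(table$labels, config$cv_folds_h)

  # fitness is a pure function of the (repaired) mask once the folds are
  # frozen, so distinct masks are scored once and cached
  cache <- new.env(parent = emptyenv())
  evaluate_cached <- function(mask) {
    mask <- as.integer(mask)
    if (sum(mask) == 0) { # repair before lookup so the key is the true mask
      mask[sample.int(length(mask), 1)] <- 1L
    }
    key <- paste(mask, collapse = "")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- subset_fitness(table, mask, config, folds)
      cache[[key]] <- got
    }
    got
  }

  pop <- list(
    positions = matrix(runif(H * L, config$lower, config$upper), H, L),
    masks = matrix(0L, H, L),
    mem_mask = matrix(0L, H, L),
    mem_fit = rep(-Inf, H),
    chaos = pmin(pmax(runif(H), 0.05), 0.95)
  )
  for (l in seq_len(H)) {
    tb <- transfer_and_binarize(pop$positions[l, ], runif(L),
                                flip = config$flip_transfer)
    pop$masks[l, ] <- tb$bit
    res <- evaluate_cached(pop$masks[l, ])
    pop$mem_mask[l, ] <- res$mask
    pop$mem_fit[l] <- res$fitness
  }

  history <- numeric(config$max_iter_tau)
  for (tau in seq_len(config$max_iter_tau)) {
    pop <- update_positions(pop, config)
    for (l in seq_len(H)) {
      res <- evaluate_cached(pop$masks[l, ])
      if (res$fitness > pop$mem_fit[l]) {
        pop$mem_fit[l] <- res$fitness
        pop$mem_mask[l, ] <- res$mask
      }
    }
    history[tau] <- max(pop$mem_fit)
  }
  best <- which.max(pop$mem_fit)
  mask <- pop$mem_mask[best, ]
  list(mask = mask, fitness = pop$mem_fit[best], history = history,
       n_evaluations = length(ls(cache)),
       selected = table$feature_names[mask == 1])
}
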
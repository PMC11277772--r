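test_that("Gini impurity and split scores have their textbook values", {
  expect_equal(gini_and_split(c(5, 5))$gini, 0.5)
  expect_equal(gini_and_split(c(10, 0))$gini, 0)
  expect_equal(gini_and_split(c(1, 1, 1))$gini, 2 / 3)
  expect_equal(gini_and_split(c(5, 5), c(5, 0), c(0, 5))$split_gini, 0)
  expect_error(gini_and_split(c(0, 0)), "empty")
  expect_error(gini_and_split(c(5, 5), c(4, 0), c(0, 4)), "elementwise")
})

test_that("tree splits agree with a brute-force 1-D oracle", {
  # exhaustive search over all thresholds of a single feature
  brute_best <- function(x, y) {
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    best <- Inf; thr <- NA
    for (i in seq_len(length(x) - 1)) {
      if (xs[i] == xs[i + 1]) next
      lc <- tabulate(ys[1:i], 2)
      rc <- tabulate(ys[(i + 1):length(x)], 2)
      sg <- gini_and_split(lc + rc, lc, rc)$split_gini
      if (sg < best - 1e-15) {
        best <- sg
        thr <- (xs[i] + xs[i + 1]) / 2
      }
    }
    list(score = best, threshold = thr)
  }
  for (s in 1:8) {
    set.seed(s)
    n <- 40
    x <- rnorm(n)
    y <- ifelse(x + rnorm(n, 0, 0.5) > 0, 2L, 1L)
    if (length(unique(y)) < 2) next
    tab <- feature_table(matrix(x, ncol = 1), y)
    # a deterministic "bootstrap" is not available, so grow one tree with
    # nmin = n so only the root split exists, and compare on the bag
    set.seed(100 + s)
    f <- build_forest(tab, K = 1, mtry = 1, nmin = 1)
    tree <- f$trees[[1]]
    bag <- rep(seq_len(n), f$inbag[, 1])
    ref <- brute_best(x[bag], y[bag])
    expect_equal(tree$threshold[1], ref$threshold, tolerance = 1e-12)
  }
})

test_that("forests separate separable data and are seed-reproducible", {
  tab <- label_feature_table(100, 4, seed = 1)
  set.seed(2)
  f <- build_forest(tab, K = 10)
  expect_identical(predict_majority(f, tab$features), tab$labels)

  set.seed(7); fa <- build_forest(tab, K = 5)
  set.seed(7); fb <- build_forest(tab, K = 5)
  expect_identical(fa$trees, fb$trees)
  expect_identical(fa$inbag, fb$inbag)

  one <- feature_table(matrix(rnorm(60), 60, 1), rep(1:2, 30))
  set.seed(3)
  f1 <- build_forest(one, K = 5, mtry = 1)
  used <- unlist(lapply(f1$trees, function(t) t$feature[t$feature > 0]))
  expect_true(all(used == 1))
  expect_error(build_forest(tab, K = 5, mtry = 10), "mtry")
})

test_that("majority voting breaks ties toward the smaller class", {
  expect_identical(pulmotex:::majority_vote(c(1L, 1L, 2L), 3), 1L)
  expect_identical(pulmotex:::majority_vote(c(2L, 2L, 2L), 3), 2L)
  expect_identical(pulmotex:::majority_vote(c(1L, 2L), 3), 1L)
  expect_identical(pulmotex:::majority_vote(c(3L, 2L), 3), 2L)
})

test_that("out-of-bag accounting matches the bootstrap expectation", {
  tab <- random_table(100, 3, seed = 5)
  fr <- vapply(1:20, function(s) {
    set.seed(s)
    f <- build_forest(tab, K = 1)
    mean(f$inbag[, 1] == 0)
  }, numeric(1))
  expect_lt(abs(mean(fr) - exp(-1)), 0.1)

  sep <- label_feature_table(100, 4, seed = 6)
  set.seed(8)
  f <- build_forest(sep, K = 50)
  oe <- oob_error(f, sep)
  expect_lt(oe$error, 0.05)
  expect_identical(oe$n_no_oob + sum(!is.na(oe$predictions)), 100L)

  f$trees <- list()
  expect_error(oob_error(f, sep), "no trees")
})

test_that("shadow importance separates signal from the null benchmark", {
  tab <- label_feature_table(80, 3, seed = 9)
  set.seed(10)
  si <- shadow_importance(tab, R = 10, K = 30)
  # the label-copy feature beats the best shadow in every replicate
  expect_true(all(si$scores[, 1] > si$shadow_max))

  set.seed(10)
  si2 <- shadow_importance(tab, R = 10, K = 30)
  expect_identical(si2$scores, si$scores)
  expect_error(shadow_importance(tab, R = 3), "at least 5")
})

test_that("the rank-sum screen keeps dominating features", {
  scores <- matrix(c(seq(2, 3, length.out = 10), rnorm(10, 0, 0.1)), 10)
  shadow <- seq(0.5, 1, length.out = 10)
  ws <- wilcoxon_screen(scores, shadow, theta = 0.05)
  expect_true(1 %in% ws$keep)
  # minimal attainable one-sided p with 10 vs 10 and no ties
  expect_equal(ws$p_values[1], 1 / choose(20, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  ws0 <- wilcoxon_screen(scores, shadow, theta = 0)
  expect_length(ws0$keep, 0)

  degen <- matrix(1, 6, 2)
  wd <- wilcoxon_screen(degen, rep(1, 6))
  expect_true(all(wd$degenerate))
  expect_equal(unname(wd$p_values), c(0.5, 0.5))
})

test_that("chi-square statistics and grouping behave", {
  expect_equal(chi_square_statistic(matrix(c(10, 10, 10, 10), 2))$statistic,
               0)
  res <- chi_square_statistic(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1)
  # cross-check against the stats implementation (no continuity correction)
  m <- matrix(c(13, 7, 6, 14), 2)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  mine <- chi_square_statistic(m)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  pt <- generate_feature_table(200, 4, 2, 2.5, seed = 12)
  cg <- chi_square_group(pt$table, keep = 1:4)
  expect_true(all(1:2 %in% cg$Ys))
  expect_identical(sort(c(cg$Ys, cg$Yw)), 1:4)
})

test_that("label-independent features usually land in the weak group", {
  hits <- 0L
  for (s in 1:10) {
    pt <- generate_feature_table(150, 2, 1, 0, seed = 40 + s)
    cg <- chi_square_group(pt$table, keep = 2)
    hits <- hits + (2 %in% cg$Yw)
  }
  expect_gte(hits, 9L)
})

test_that("subset probabilities come from the combinatorial identity", {
  expect_equal(subset_probability(10, 5, 2)$exact, 10 / 45)
  expect_equal(subset_probability(10, 0, 3)$exact, 1)
  expect_equal(subset_probability(10, 1, 10)$exact, 0)
  sp <- subset_probability(20, 4, 3)
  expect_equal(sp$exact, choose(16, 3) / choose(20, 3))
  expect_lt(abs(sp$approx - (1 - 4 / 20)^3), 1e-12)
})

test_that("group-stratified draws always include the strong group", {
  set.seed(13)
  for (i in 1:200) {
    cand <- pulmotex:::.rf_draw_candidates_cpp(10, 4, c(1L, 2L),
                                               c(3L, 5L, 7L, 9L))
    expect_gte(sum(cand %in% 1:2), 1)
    expect_identical(cand, sort(cand))
  }
  # a stratified forest trains and predicts
  tab <- label_feature_table(60, 6, seed = 14)
  set.seed(15)
  f <- build_forest(tab, K = 20, mtry = 2,
                    groups = list(Ys = 1L, Yw = 2:6))
  expect_gt(mean(predict_majority(f, tab$features) == tab$labels), 0.95)
})

test_that("forest OOB error falls with the planted effect size", {
  err <- function(effect, s) {
    pt <- generate_feature_table(150, 8, 3, effect, seed = s)
    set.seed(1000 + s)
    f <- build_forest(pt$table, K = 60)
    oob_error(f, pt$table)$error
  }
  wins <- sum(vapply(1:6, function(s) err(2.5, s) < err(0, s), logical(1)))
  expect_gte(wins, 5)
})

test_that("agreement with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  pt <- generate_feature_table(150, 6, 2, 2, seed = 20)
  set.seed(21)
  mine <- build_forest(pt$table, K = 100)
  my_err <- oob_error(mine, pt$table)$error
  rf <- randomForest::randomForest(pt$table$features,
                                   factor(pt$table$labels), ntree = 100)
  ref_err <- mean(rf$predicted != pt$table$labels)
  expect_lt(abs(my_err - ref_err), 0.1)
})
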
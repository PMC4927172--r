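# Gain-ratio trees, AdaBoost.M1, and stratified cross-validation.

.tree_depth_for_test <- function(tree) {
  depth <- function(node) {
    if (node$leaf) return(0L)
    1L + max(depth(node$left), depth(node$right))
  }
  depth(tree$root)
}

make_xor <- function() {
  set.seed(31)
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- c("a", "a", "b", "b")
  n_per <- c(11, 9, 10, 12)   # slight imbalance breaks the gain symmetry
  x <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(2 * n_per[i], sd = 0.08), ncol = 2), 2, centers[i, ], "+")
  }))
  list(x = x, y = rep(lab, n_per))
}

test_that("a separable 1-D feature yields a single split with training accuracy 1", {
  x <- matrix(c(1:10, 21:30), ncol = 1)
  y <- rep(c("a", "b"), each = 10)
  tr <- c45_tree(x, y)
  expect_false(tr$root$leaf)
  expect_true(tr$root$left$leaf && tr$root$right$leaf)
  expect_true(tr$root$threshold > 10 && tr$root$threshold < 21)
  expect_equal(mean(predict(tr, x) == y), 1)
})

test_that("XOR-structured data needs depth >= 2 and then separates exactly", {
  d <- make_xor()
  deep <- c45_tree(d$x, d$y, cf = 1, min_leaf = 1)   # no pruning
  expect_gte(.tree_depth_for_test(deep), 2)
  expect_equal(mean(predict(deep, d$x) == d$y), 1)
  stump <- c45_tree(d$x, d$y, max_depth = 1, cf = 1)
  expect_lt(mean(predict(stump, d$x) == d$y), 1)  # a single split cannot
})

test_that("single-class input yields a constant classifier", {
  x <- matrix(rnorm(10), ncol = 1)
  tr <- c45_tree(x, rep("only", 10))
  expect_true(tr$root$leaf)
  expect_equal(as.character(predict(tr, matrix(0))), "only")
})

test_that("one boosting trial reproduces the single tree", {
  d <- make_xor()
  tr <- c45_tree(d$x, d$y)
  ens <- adaboost(d$x, d$y, n_trials = 1)
  expect_equal(predict(ens, d$x), predict(tr, d$x))
})

test_that("boosting drives training error down on a fixed training set", {
  set.seed(32)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3)
  y <- ifelse(x[, 1] + 0.8 * x[, 2] + rnorm(n, sd = 0.6) > 0, "a", "b")
  # shallow, unpruned stumps leave room for boosting to help
  err_at <- function(k) {
    ens <- adaboost(x, y, n_trials = k, max_depth = 1, cf = 1)
    mean(predict(ens, x) != y)
  }
  e1 <- err_at(1); e10 <- err_at(10)
  expect_lte(e10, e1)
  # AdaBoost training-error bound: prod_m 2 sqrt(err_m (1 - err_m))
  ens <- adaboost(x, y, n_trials = 10, max_depth = 1, cf = 1)
  betas <- exp(-ens$alpha)
  errs <- betas / (1 + betas)
  bound <- prod(2 * sqrt(errs * (1 - errs)))
  expect_lte(mean(predict(ens, x) != y), bound + 1e-12)
})

test_that("boosted ensemble separates separable data exactly", {
  x <- cbind(c(rnorm(15, -3), rnorm(15, 3)))
  y <- rep(c("a", "b"), each = 15)
  ens <- adaboost(x, y, n_trials = 10)
  expect_equal(mean(predict(ens, x) == y), 1)
})

test_that("stratified 6-fold CV tests each of 58 subjects exactly once", {
  set.seed(33)
  x <- matrix(rnorm(58 * 4), 58, 4)
  y <- rep(c("control", "patient"), each = 29)
  rep1 <- crossval_classify(x, y, n_folds = 6, seed = 5)
  expect_equal(sum(rep1$confusion), 58)
  expect_equal(rep1$accuracy,
               (rep1$confusion[1, 1] + rep1$confusion[2, 2]) / 58)
  expect_equal(rep1$sensitivity,
               rep1$confusion[1, 1] / sum(rep1$confusion[, 1]))
  expect_equal(rep1$specificity,
               rep1$confusion[2, 2] / sum(rep1$confusion[, 2]))
  expect_equal(rep1$positive, "patient")
  # determinism under a fixed seed
  rep2 <- crossval_classify(x, y, n_folds = 6, seed = 5)
  expect_identical(rep1, rep2)
  # fold sizes 9 or 10: check via the internal assignment
  set.seed(5)
  fold <- wbnet:::.stratified_folds(factor(y), 6)
  expect_true(all(table(fold) %in% c(9, 10)))
  expect_error(crossval_classify(x[1:8, ], y[c(1:4, 30:33)], n_folds = 6),
               "at least n_folds")
})

test_that("label-independent features classify at chance level", {
  set.seed(34)
  accs <- replicate(8, {
    x <- matrix(rnorm(58 * 8), 58, 8)
    y <- sample(rep(c("control", "patient"), each = 29))
    crossval_classify(x, y, seed = sample.int(1e6, 1))$accuracy
  })
  # 0.5 +/- 3 binomial sd per run; the mean of 8 runs is tighter
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / 58) / sqrt(8) + 0.05)
})

test_that("a planted strong effect is classified almost perfectly", {
  set.seed(35)
  x <- matrix(rnorm(58 * 8), 58, 8)
  y <- rep(c("control", "patient"), each = 29)
  x[y == "patient", 3] <- x[y == "patient", 3] + 4
  rep1 <- crossval_classify(x, y, seed = 9)
  expect_gte(rep1$accuracy, 0.9)
})

test_that("gain-ratio tree is comparable to an independent CART learner", {
  skip_if_not_installed("rpart")
  set.seed(36)
  n <- 200
  x <- matrix(rnorm(n * 2), n, 2)
  y <- factor(ifelse(x[, 1] > 0.2, "a", "b"))
  mine <- c45_tree(x, y)
  acc_mine <- mean(predict(mine, x) == y)
  df <- data.frame(y = y, x1 = x[, 1], x2 = x[, 2])
  cart <- rpart::rpart(y ~ ., data = df, method = "class")
  acc_cart <- mean(predict(cart, df, type = "class") == y)
  expect_gte(acc_mine, acc_cart - 0.05)
  expect_gte(acc_mine, 0.95)
})

test_that("classification sweep is reproducible and internally consistent", {
  set.seed(37)
  subjects <- sprintf("S%03d", 1:24)
  tab <- expand.grid(subject = subjects, length = c(4, 8),
                     stringsAsFactors = FALSE)
  tab$group <- rep(rep(c("control", "patient"), each = 12), 2)
  tab$method <- "modwt"; tab$family <- "D"; tab$scale <- 2
  for (mc in c("mean_corr", "var_corr", "clustering", "path_length",
               "global_eff", "local_eff", "modularity", "n_communities")) {
    tab[[mc]] <- rnorm(nrow(tab))
  }
  tab$modularity <- tab$modularity + 2.5 * (tab$group == "patient")
  s1 <- classification_sweep(tab, scale = 2, seed = 11)
  s2 <- classification_sweep(tab, scale = 2, seed = 11)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2)
  expect_true(all(s1$accuracy >= 0 & s1$accuracy <= 1))
  expect_equal(s1$accuracy, (s1$TP + s1$TN) / 24)
  expect_equal(s1$sensitivity, s1$TP / (s1$TP + s1$FN))
  expect_equal(s1$specificity, s1$TN / (s1$TN + s1$FP))
})
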
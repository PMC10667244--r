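bruteBestAssignment <- function(truth, predicted) {
  classes <- sort(unique(truth)); clusters <- sort(unique(predicted))
  tab <- table(factor(predicted, levels = clusters),
               factor(truth, levels = classes))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- 0L
  for (p in perms(seq_along(classes))) {
    tot <- sum(vapply(seq_len(min(length(clusters), length(classes))),
                      function(r) tab[r, p[r]], 0))
    best <- max(best, tot)
  }
  best
}

test_that("alignClusters finds the optimal relabeling", {
  map <- alignClusters(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(map[["1"]], 0)
  expect_equal(map[["0"]], 1)
  expect_equal(attr(map, "matched"), 4L)
  idmap <- alignClusters(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(unname(idmap[as.character(0:2)]), 0:2)
  expect_error(alignClusters(1:3, 1:4), "length mismatch")
})

test_that("alignment matches brute-force permutation search on random instances", {
  for (seed in 1:12) {
    set.seed(seed)
    truth <- sample(0:2, 30, replace = TRUE)
    predicted <- sample(0:2, 30, replace = TRUE)
    map <- alignClusters(truth, predicted)
    expect_equal(attr(map, "matched"), bruteBestAssignment(truth, predicted))
  }
})

test_that("alignment is invariant to relabeling of predicted clusters", {
  set.seed(30)
  truth <- sample(0:3, 60, replace = TRUE)
  predicted <- sample(0:3, 60, replace = TRUE)
  m1 <- attr(alignClusters(truth, predicted), "matched")
  relab <- c(2L, 0L, 3L, 1L)[predicted + 1L]
  m2 <- attr(alignClusters(truth, relab), "matched")
  expect_equal(m1, m2)
})

test_that("surplus clusters map to unassigned", {
  truth <- rep(0:1, each = 6)
  predicted <- c(rep(0L, 6), rep(1L, 3), rep(2L, 3))
  map <- alignClusters(truth, predicted)
  expect_equal(sum(is.na(map)), 1L)
  cm <- confusionMatrixFrom(truth, predicted, map)
  expect_true("unassigned" %in% colnames(cm))
  expect_equal(sum(cm), 12L)
})

test_that("confusion matrices count aligned labels with truth on rows", {
  truth <- rep(0:1, c(10, 10))
  map <- alignClusters(truth, truth)
  cm <- confusionMatrixFrom(truth, truth, map)
  expect_equal(unname(cm), matrix(c(10L, 0L, 0L, 10L), 2))
  truth2 <- c(0, 0, 0, 1)
  pred2 <- c(0, 0, 1, 1)
  cm2 <- confusionMatrixFrom(truth2, pred2,
                             alignClusters(truth2, pred2))
  expect_equal(unname(cm2), matrix(c(2L, 0L, 1L, 1L), 2))
  expect_equal(unname(rowSums(cm2)), c(3L, 1L))
  set.seed(31)
  truth3 <- sample(0:2, 40, replace = TRUE)
  pred3 <- sample(0:4, 40, replace = TRUE)
  cm3 <- confusionMatrixFrom(truth3, pred3, alignClusters(truth3, pred3))
  expect_true(all(cm3 >= 0))
  expect_equal(sum(cm3), 40L)
})

test_that("balancedAccuracy is the mean of per-class accuracies", {
  expect_equal(balancedAccuracy(diag(5L) * 7L), 1.0)
  cm <- matrix(c(9L, 2L, 1L, 8L), 2)  # rows truth: [9 1; 2 8]
  expect_equal(balancedAccuracy(cm), 0.85)
  set.seed(32)
  for (rep in 1:100) {
    C <- sample(2:5, 1)
    m <- matrix(rpois(C * C, 5) + diag(C), C,
                dimnames = list(0:(C - 1), 0:(C - 1)))
    mode(m) <- "integer"
    brute <- mean(vapply(seq_len(C), function(i) m[i, i] / sum(m[i, ]), 0))
    expect_rel_equal(balancedAccuracy(m), brute, tol = 1e-12)
  }
  expect_error(balancedAccuracy(matrix(c(0L, 0L, 3L, 4L), 2, byrow = TRUE)),
               "empty truth class")
})

test_that("balanced accuracy equals plain accuracy for balanced classes", {
  set.seed(33)
  for (rep in 1:20) {
    C <- sample(2:4, 1)
    rowTot <- 24L
    m <- t(vapply(seq_len(C), function(i) {
      x <- as.integer(stats::rmultinom(1, rowTot, rep(1, C)))
      x
    }, integer(C)))
    dimnames(m) <- list(0:(C - 1), 0:(C - 1))
    expect_equal(balancedAccuracy(m), sum(diag(m)) / sum(m))
  }
})

test_that("classificationReport reproduces per-class formulas", {
  d <- diag(4L) * 6L
  dimnames(d) <- list(0:3, 0:3)
  rep1 <- classificationReport(d)
  expect_equal(rep1$precision, 1.0)
  expect_equal(rep1$recall, 1.0)
  expect_equal(rep1$f1, 1.0)
  cm <- matrix(c(9L, 2L, 1L, 8L), 2, dimnames = list(0:1, 0:1))
  r <- classificationReport(cm)
  expect_equal(r$perClassRecall[1], 0.9)
  expect_equal(r$perClassPrecision[1], 9 / 11)
  expect_equal(r$perClassF1[1],
               2 * (0.9 * 9 / 11) / (0.9 + 9 / 11))
  expect_equal(r$balancedAccuracy, balancedAccuracy(cm))
  expect_lte(r$f1, 1)
})

test_that("zero prediction columns score zero precision with a warning", {
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, dimnames = list(0:1, 0:1))
  expect_warning(r <- classificationReport(cm), "precision set to 0")
  expect_equal(r$perClassPrecision[2], 0)
  expect_equal(r$perClassF1[2], 0)
})

test_that("latent embedding is deterministic and separates blobs", {
  set.seed(34)
  Z <- rbind(matrix(rnorm(50 * 16), ncol = 16),
             matrix(rnorm(50 * 16, mean = 6), ncol = 16))
  xy <- embedLatent2D(Z, seed = 1L)
  expect_equal(dim(xy), c(100L, 2L))
  expect_identical(xy, embedLatent2D(Z, seed = 1L))
  g <- rep(1:2, each = 50)
  centers <- rbind(colMeans(xy[g == 1, ]), colMeans(xy[g == 2, ]))
  inter <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  intra <- mean(c(sqrt(rowSums(sweep(xy[g == 1, ], 2, centers[1, ])^2)),
                  sqrt(rowSums(sweep(xy[g == 2, ], 2, centers[2, ])^2))))
  expect_gt(inter, intra)
  expect_error(embedLatent2D(Z[1:2, ]), "too few cells")
})
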
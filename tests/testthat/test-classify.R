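test_that("balancing the printed training counts yields the printed total", {
  counts <- c(vessel = 38661L, core = 7771L, ggo = 68892L)
  n <- sum(counts)
  labels <- rep(1:3, counts)
  # spread over 44 nodules as in a multi-nodule training set
  nodule_id <- unlist(lapply(counts, function(k)
    sort(rep_len(sprintf("n%02d", 1:44), k))))
  features <- matrix(seq_len(n), ncol = 1)
  bal <- balance_classes(features, labels, nodule_id, seed = 11)
  expect_equal(nrow(bal$features), 23313L)
  expect_equal(as.integer(table(bal$labels)), rep(7771L, 3))
  # no duplicated rows (sampling without replacement)
  expect_false(any(duplicated(bal$features[, 1])))
})

test_that("already balanced input is returned as a permutation", {
  labels <- rep(1:3, each = 10)
  features <- matrix(rnorm(60), ncol = 2)
  bal <- balance_classes(features, labels, rep("n1", 30), seed = 1)
  expect_equal(sort(bal$rows), 1:30)
})

test_that("per-nodule quotas follow water-filling fair shares", {
  expect_equal(subsolidseg:::quota_allocate(c(100, 10), 20), c(10, 10))
  expect_equal(subsolidseg:::quota_allocate(c(5, 100), 20), c(5, 15))
  expect_equal(sum(subsolidseg:::quota_allocate(c(7, 7, 7), 20)), 20)
  expect_error(balance_classes(matrix(1:4, ncol = 1), c(1, 1, 3, 3),
                               rep("a", 4)), "core")
})

test_that("balancing is deterministic under a fixed seed", {
  labels <- rep(1:3, c(50, 10, 70))
  features <- matrix(seq_len(130), ncol = 1)
  nodule_id <- rep_len(c("a", "b", "c"), 130)
  b1 <- balance_classes(features, labels, nodule_id, seed = 5)
  b2 <- balance_classes(features, labels, nodule_id, seed = 5)
  expect_identical(b1, b2)
})

test_that("kNN training validates k and produces exact degenerate posteriors", {
  set.seed(20)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rep(1:3, each = 10)
  expect_error(train_classifier(x, y, k = 31), "exceeds")

  # k = n with balanced classes: every posterior is uniform
  m <- train_classifier(x, y, k = 30)
  p <- predict(m, matrix(rnorm(10), ncol = 2))
  expect_true(all(abs(p - 1 / 3) < 1e-12))

  # querying an exact duplicate with k = 1 returns that sample's class
  m1 <- train_classifier(x, y, k = 1)
  p1 <- predict(m1, x[c(3, 17, 25), , drop = FALSE])
  expect_equal(max.col(p1), c(1, 2, 3))
  expect_true(all(apply(p1, 1, max) == 1))
})

test_that("well-separated Gaussian classes are classified accurately and match class::knn", {
  set.seed(21)
  n <- 120
  centers <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  x <- do.call(rbind, lapply(1:3, function(c)
    sweep(matrix(rnorm(n * 3), ncol = 3), 2, centers[c, ], "+")))
  y <- rep(1:3, each = n)
  tr <- c(1:80, 121:200, 241:320)
  te <- setdiff(seq_len(3 * n), tr)
  m <- train_classifier(x[tr, ], y[tr], k = 5)
  post <- predict(m, x[te, ])
  pred <- max.col(post)
  expect_gt(mean(pred == y[te]), 0.95)

  # independent cross-check: class::knn on the same standardized features
  skip_if_not_installed("class")
  xs <- scale(x[tr, ])
  xq <- scale(x[te, ], center = attr(xs, "scaled:center"),
              scale = attr(xs, "scaled:scale"))
  ref <- as.integer(as.character(class::knn(xs, xq, factor(y[tr]), k = 5)))
  expect_gt(mean(pred == ref), 0.98)
})

test_that("the weight grid enumerates the simplex lattice", {
  g <- subsolidseg:::weight_grid(0.5)
  expect_equal(nrow(g), 6L)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  g2 <- subsolidseg:::weight_grid(0.01)
  expect_equal(nrow(g2), choose(102, 2))
})

test_that("perfect posteriors give zero disagreement and the near-uniform tie-break", {
  set.seed(22)
  y <- sample(1:3, 200, replace = TRUE)
  P <- matrix(0, 200, 3)
  P[cbind(seq_along(y), y)] <- 1
  w <- optimize_weights(P, y, grid_step = 0.01)
  expect_equal(attr(w, "disagreement"), 0L)
  expect_lt(sum((as.numeric(w) - 1 / 3)^2), 0.01^2)
})

test_that("systematically under-called cores push the optimal core weight above 1/3", {
  set.seed(23)
  n <- 300
  y <- rep(1:3, each = n)
  # core posteriors lose narrowly to ggo at uniform weights; other classes win big
  P_v <- cbind(0.8, 0.05, 0.15)[rep(1, n), ]
  P_c <- cbind(0.1, 0.42, 0.48)[rep(1, n), ]
  P_g <- cbind(0.1, 0.1, 0.8)[rep(1, n), ]
  P <- rbind(P_v, P_c, P_g)
  w <- optimize_weights(P, y, grid_step = 0.01)
  expect_gt(w["core"], 1 / 3)
  expect_equal(attr(w, "disagreement"), 0L)
  # uniform weights misclassify every core sample (verified directly)
  lab_unif <- subsolidseg:::weighted_argmax(P, c(1, 1, 1) / 3)
  expect_equal(sum(lab_unif != y), n)
})

test_that("the weighted argmax matches brute force and honours the tie priority", {
  set.seed(24)
  for (rep in 1:5) {
    P <- matrix(runif(300), ncol = 3)
    P <- P / rowSums(P)
    w <- runif(3)
    w <- w / sum(w)
    got <- subsolidseg:::weighted_argmax(P, w)
    L <- sweep(P, 2, w, "*")
    brute <- apply(L, 1, function(r) {
      mx <- which(r == max(r))
      if (length(mx) > 1) mx <- c(3, 1, 2)[c(3, 1, 2) %in% mx][1]
      mx
    })
    expect_equal(got, as.integer(brute))
  }
  # explicit ties: equal likelihoods resolve ggo > vessel > core
  tieP <- rbind(c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5),
                c(1, 1, 1) / 3)
  expect_equal(subsolidseg:::weighted_argmax(tieP, c(1, 1, 1) / 3),
               c(1L, 3L, 3L, 3L))
})

test_that("the printed operating point sends the worked example to ground-glass", {
  P <- matrix(c(0.5, 0.3, 0.2), 1)
  w <- class_weights(0.23, 0.13, 0.64)
  L <- as.numeric(P) * as.numeric(w)
  expect_equal(L, c(0.115, 0.039, 0.128), tolerance = 1e-12)
  expect_equal(subsolidseg:::weighted_argmax(P, w), 3L)
})

test_that("degenerate operating points behave as expected", {
  set.seed(25)
  P <- matrix(runif(60, 0.05, 1), ncol = 3)
  P <- P / rowSums(P)
  expect_true(all(subsolidseg:::weighted_argmax(P, c(1, 0, 0)) == 1L))
  onehot <- matrix(0, 20, 3)
  onehot[cbind(1:20, sample(1:3, 20, TRUE))] <- 1
  expect_equal(subsolidseg:::weighted_argmax(onehot, rep(1 / 3, 3)),
               max.col(onehot))
})

test_that("raising the vessel weight never shrinks the vessel-labelled set", {
  set.seed(26)
  P <- matrix(runif(900), ncol = 3)
  P <- P / rowSums(P)
  w_v_grid <- seq(0.1, 0.9, by = 0.1)
  prev <- -1L
  for (wv in w_v_grid) {
    rest <- (1 - wv) / 2
    n_v <- sum(subsolidseg:::weighted_argmax(P, c(wv, rest, rest)) == 1L)
    expect_gte(n_v, prev)
    prev <- n_v
  }
})

test_that("class weight validation", {
  expect_error(class_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(class_weights(-0.2, 0.6, 0.6), "nonnegative")
  expect_silent(class_weights(0.23, 0.13, 0.64))
})

test_that("solitary voxels take the neighbourhood majority; pairs and uniform maps survive", {
  d <- c(5, 5, 5)
  lab <- array(0L, d)
  lab[2:4, 2:4, 2:4] <- 3L
  lab[3, 3, 3] <- 1L
  sm <- smooth_solitary(label_volume(lab, c(1, 1, 1)))
  expect_equal(sm$data[3, 3, 3], 3L)

  lab2 <- array(0L, d)
  lab2[2:4, 2:4, 2:4] <- 3L
  lab2[3, 3, 3] <- 1L
  lab2[3, 4, 3] <- 1L  # the pair protects both voxels
  sm2 <- smooth_solitary(label_volume(lab2, c(1, 1, 1)))
  expect_equal(sm2$data[3, 3, 3], 1L)
  expect_equal(sm2$data[3, 4, 3], 1L)

  lab3 <- array(0L, d)
  lab3[2:4, 2:4, 2:4] <- 2L
  sm3 <- smooth_solitary(label_volume(lab3, c(1, 1, 1)))
  expect_equal(sm3$data, lab3)
})

test_that("posterior stacks validate range and normalization", {
  d <- c(4, 4, 4)
  mask <- array(TRUE, d)
  ok <- posterior_stack(array(0.2, d), array(0.3, d), array(0.5, d), mask)
  expect_s3_class(ok, "posterior_stack")
  expect_error(posterior_stack(array(0.9, d), array(0.3, d), array(0.5, d),
                               mask), "sum to 1")
  expect_error(posterior_stack(array(-0.2, d), array(0.7, d), array(0.5, d),
                               mask), "\\[0, 1\\]")
})

test_that("initial segmentation covers the mask and matches per-voxel argmax", {
  set.seed(27)
  d <- c(6, 6, 6)
  mask <- array(runif(216) < 0.7, d)
  raw <- matrix(runif(3 * sum(mask)), ncol = 3)
  raw <- raw / rowSums(raw)
  mk <- function(col) {
    a <- array(0, d)
    a[mask] <- raw[, col]
    a
  }
  post <- posterior_stack(mk(1), mk(2), mk(3), mask)
  w <- class_weights(0.23, 0.13, 0.64)
  seg <- initial_segmentation(post, w, smooth = FALSE)
  expect_true(all(seg$data[mask] %in% 1:3))
  expect_true(all(seg$data[!mask] == 0L))
  expect_equal(seg$data[mask], subsolidseg:::weighted_argmax(raw, w))
})

test_that("out-of-fold posteriors are produced for every sample", {
  set.seed(28)
  x <- matrix(rnorm(300), ncol = 3)
  y <- rep(1:3, length.out = 100)
  pat <- rep(c("p1", "p2", "p3", "p4"), length.out = 100)
  post <- suppressWarnings(cv_posteriors(x, y, pat, k = 10))
  expect_false(any(is.na(post)))
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  expect_error(cv_posteriors(x, y, rep("p1", 100), k = 10), "two patients")
})
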
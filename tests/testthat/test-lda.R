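# Two-class linear discriminant.

make_clusters <- function(n, sep, d = 2, seed = 1, sigma = diag(d)) {
  set.seed(seed)
  ch <- chol(sigma)
  x1 <- matrix(rnorm(n * d), n) %*% ch
  x2 <- sweep(matrix(rnorm(n * d), n) %*% ch, 2, rep(sep / sqrt(d), d), `+`)
  list(x = rbind(x1, x2),
       labels = rep(c("NonFatigue", "TransitionToFatigue"), each = n))
}

test_that("well-separated clusters are classified perfectly", {
  cl <- make_clusters(50, sep = 10, seed = 11)
  m <- fit_lda(cl$x, cl$labels)
  pred <- classify(m, cl$x)
  expect_identical(as.character(pred$label), cl$labels)
})

test_that("isotropic covariance makes w parallel to the mean difference", {
  set.seed(3)
  n <- 4000
  mu2 <- c(2, 1)
  x <- rbind(matrix(rnorm(n * 2), n),
             sweep(matrix(rnorm(n * 2), n), 2, mu2, `+`))
  labels <- rep(c("NonFatigue", "TransitionToFatigue"), each = n)
  m <- fit_lda(x, labels)
  dmean <- colMeans(x[labels == "TransitionToFatigue", ]) -
    colMeans(x[labels == "NonFatigue", ])
  ang <- acos(sum(m$weights * dmean) /
                sqrt(sum(m$weights^2) * sum(dmean^2))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("fitted direction matches the generalized-eigenvalue oracle", {
  for (seed in 1:5) {
    cl <- make_clusters(40, sep = 3, d = 3, seed = seed,
                        sigma = matrix(c(2, .5, .2, .5, 1, .3, .2, .3, 1.5), 3))
    m <- fit_lda(cl$x, cl$labels)
    # brute-force: leading eigenvector of Sw^-1 Sb
    g <- as_fatigue_factor(cl$labels)
    xs <- split.data.frame(cl$x, g, drop = TRUE)
    ns <- vapply(xs, nrow, integer(1))
    sw <- Reduce(`+`, Map(function(xi, ni) (ni - 1) * cov(xi), xs, ns)) /
      (sum(ns) - 2)
    dm <- colMeans(xs[[2]]) - colMeans(xs[[1]])
    sb <- outer(dm, dm)
    ev <- eigen(solve(sw) %*% sb)
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    cosang <- abs(sum(m$weights * v)) / sqrt(sum(m$weights^2) * sum(v^2))
    expect_lt(acos(pmin(1, cosang)) * 180 / pi, 1)
  }
})

test_that("boundary geometry, tie rule and scale invariance", {
  cl <- make_clusters(50, sep = 10, seed = 21)
  m <- fit_lda(cl$x, cl$labels)
  m1 <- m$training_summary$mean_NonFatigue
  m2 <- m$training_summary$mean_TransitionToFatigue
  expect_lt(classify(m, m1)$score, 0)
  expect_identical(as.character(classify(m, m1)$label), "NonFatigue")
  # projected midpoint lies exactly on the boundary -> fatigued class
  mid <- (m1 + m2) / 2
  expect_equal(classify(m, mid)$score, 0, tolerance = 1e-9)
  expect_identical(as.character(classify(m, mid)$label), "TransitionToFatigue")
  # joint positive rescaling of (w, w0) preserves labels
  m_scaled <- m
  m_scaled$weights <- 3 * m$weights
  m_scaled$bias <- 3 * m$bias
  expect_identical(classify(m_scaled, cl$x)$label, classify(m, cl$x)$label)
  expect_error(classify(m, c(1, 2, 3)), "dimension")
})

test_that("identical class means yield chance-level separation", {
  set.seed(8)
  x <- matrix(rnorm(400), 200)
  labels <- rep(c("NonFatigue", "TransitionToFatigue"), each = 100)
  m <- fit_lda(x, labels)
  proj1 <- mean(classify(m, x[1:100, ])$score)
  proj2 <- mean(classify(m, x[101:200, ])$score)
  # projected class means nearly coincide relative to the score spread
  expect_lt(abs(proj1 - proj2) / sd(classify(m, x)$score), 0.5)
})

test_that("affine rescaling of a feature coordinate leaves predictions unchanged", {
  cl <- make_clusters(60, sep = 4, seed = 31)
  m <- fit_lda(cl$x, cl$labels)
  x2 <- cl$x
  x2[, 2] <- 10 * x2[, 2] - 7
  m2 <- fit_lda(x2, cl$labels)
  expect_identical(classify(m2, x2)$label, classify(m, cl$x)$label)
})

test_that("degenerate training sets error; Fatigue windows are excluded", {
  x <- matrix(rnorm(20), 10)
  expect_error(fit_lda(x, rep("NonFatigue", 10)), ">= 2 windows")
  # Fatigue rows do not leak into training
  cl <- make_clusters(30, sep = 10, seed = 41)
  xf <- rbind(cl$x, matrix(100, 5, 2))
  lf <- c(cl$labels, rep("Fatigue", 5))
  m <- fit_lda(xf, lf)
  m0 <- fit_lda(cl$x, cl$labels)
  expect_equal(m$weights, m0$weights)
})

test_that("model serialization round-trips", {
  cl <- make_clusters(30, sep = 6, seed = 51)
  m <- fit_lda(cl$x, cl$labels)
  path <- tempfile(fileext = ".json")
  write_lda_model(m, path)
  m2 <- read_lda_model(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$bias, m$bias)
  expect_identical(m2$class_order, m$class_order)
  expect_identical(classify(m2, cl$x)$label, classify(m, cl$x)$label)
})

test_that("accuracy_over_time is the cumulative percent-correct", {
  truth <- make_labels(rep("NonFatigue", 20), source = "labeller")
  allgood <- accuracy_over_time(make_labels(rep("NonFatigue", 20)), truth)
  expect_equal(allgood$accuracy, rep(100, 20))

  half <- make_labels(rep(c("NonFatigue", "TransitionToFatigue"), each = 10))
  curve <- accuracy_over_time(half, truth)
  expect_equal(curve$accuracy[20], 50)

  wrong1 <- make_labels(c("TransitionToFatigue", rep("NonFatigue", 19)))
  c2 <- accuracy_over_time(wrong1, truth)$accuracy
  expect_true(all(diff(c2) >= 0))
  expect_equal(c2[1], 0)

  expect_error(
    accuracy_over_time(make_labels(rep("NonFatigue", 5)),
                       make_labels(rep("NonFatigue", 5), t0 = 2)),
    "aligned")
})
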
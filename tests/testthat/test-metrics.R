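# Classification and saliency metrics against hand/brute-force oracles.

test_that("confusion matrix matches exhaustive tallying", {
  yt <- c(0, 0, 1, 1, 2, 2)
  yp <- c(0, 1, 1, 1, 0, 2)
  cm <- confusion_matrix(yt, yp)
  for (i in 0:2) for (j in 0:2) {
    expect_identical(cm[as.character(i), as.character(j)],
                     sum(yt == i & yp == j))
  }
  # perfect predictions -> diagonal
  cmp <- confusion_matrix(yt, yt)
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))
  # everything predicted as one class -> single nonzero column
  cm1 <- confusion_matrix(yt, rep(1, 6))
  expect_identical(which(colSums(cm1) > 0), c(`1` = 2L))
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
})

test_that("classification metrics reproduce the defining arithmetic", {
  # kappa from binary counts TP=45 TN=45 FP=5 FN=5:
  # 2*(45*45 - 5*5) / ((45+5)*(5+45) + (45+5)*(5+45)) = 0.8
  cm <- matrix(c(45, 5, 5, 45), 2, 2, byrow = TRUE)
  m <- classification_metrics(cm)
  expect_equal(m$per_class$kappa[1], 0.8)
  # accuracy/precision/recall for TP=40 TN=30 FP=10 FN=20
  cm2 <- matrix(c(40, 20, 10, 30), 2, 2, byrow = TRUE)
  m2 <- classification_metrics(cm2)
  expect_equal(m2$per_class$accuracy[1], 0.7)
  expect_equal(m2$per_class$precision[1], 0.8)
  expect_equal(m2$per_class$recall[1], 2 / 3)
  # both F1 conventions are reported
  expect_equal(m2$per_class$f1[1], (0.8 + 2 / 3) / 2)
  expect_equal(m2$per_class$f1_harmonic[1],
               2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  # perfect classifier
  mp <- classification_metrics(diag(c(3, 4, 5)))
  expect_equal(mp$overall_accuracy, 1)
  expect_equal(mp$precision, 1)
  expect_equal(mp$recall, 1)
  expect_equal(mp$kappa, 1)
  # undefined ratios surface as NA, not zero
  mu <- classification_metrics(matrix(c(2, 0, 1, 0), 2, 2, byrow = TRUE))
  expect_true(is.na(mu$per_class$precision[2]))
})

test_that("metrics agree with a per-item tally oracle on random labels", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    k <- sample(3:10, 1)
    yt <- sample(0:(k - 1), n, replace = TRUE)
    yp <- sample(0:(k - 1), n, replace = TRUE)
    m <- classification_metrics(confusion_matrix(yt, yp, labels = 0:(k - 1)))
    expect_equal(m$overall_accuracy, mean(yt == yp))
    for (cl in 0:(k - 1)) {
      tp <- sum(yt == cl & yp == cl)
      fp <- sum(yt != cl & yp == cl)
      fn <- sum(yt == cl & yp != cl)
      row <- m$per_class[m$per_class$class == as.character(cl), ]
      expect_identical(c(row$tp, row$fp, row$fn), c(tp, fp, fn))
      if (tp + fp > 0) expect_equal(row$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(row$recall, tp / (tp + fn))
    }
  }
})

test_that("SIM is a bounded symmetric histogram intersection", {
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- matrix(c(4, 3, 2, 1), 2, 2)
  # hand computation: both normalize by 10; sum of minima = (1+2+2+1)/10
  expect_equal(sim(a, b), 0.6)
  expect_equal(sim(a, a), 1)
  expect_equal(sim(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2)), 0)
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(runif(25), 5)
    y <- matrix(runif(25), 5)
    expect_equal(sim(x, y), sim(y, x))
    expect_gte(sim(x, y), 0)
    expect_lte(sim(x, y), 1 + 1e-12)
  }
  expect_error(sim(matrix(0, 2, 2), a), "all-zero")
})

test_that("SSIM matches direct window arithmetic and its invariances", {
  set.seed(43)
  # identity
  m <- matrix(runif(400), 20)
  expect_equal(ssim(m, m), 1)
  # symmetry
  n <- matrix(runif(400), 20)
  expect_equal(ssim(m, n), ssim(n, m))
  expect_lt(ssim(m, n), 1)
  # constant 255 vs constant 0 at K = 255: closed form k1/(255^2 + k1)
  c255 <- matrix(255, 11, 11)
  c0 <- matrix(0, 11, 11)
  k1 <- (0.01 * 255)^2
  expect_equal(ssim(c255, c0), k1 / (255^2 + k1))
  # single-window global-statistics oracle on an 11x11 pair
  a <- matrix(runif(121), 11)
  b <- matrix(runif(121), 11)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  k1 <- (0.01)^2; k2 <- (0.03)^2  # unit-range data -> K = 1
  oracle <- (2 * mu_a * mu_b + k1) * (2 * cab + k2) /
    ((mu_a^2 + mu_b^2 + k1) * (va + vb + k2))
  expect_equal(ssim(a, b), oracle)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
  expect_error(ssim_params(L = 10), "odd")
})

test_that("CC is the Pearson correlation with affine invariance", {
  set.seed(44)
  x <- matrix(runif(100), 10)
  expect_equal(cc(x, x), 1)
  expect_equal(cc(x, 3 * x + 2), 1)
  expect_equal(cc(x, -x), -1)
  y <- matrix(runif(100), 10)
  expect_equal(cc(x, y), cc(y, x))
  expect_gte(cc(x, y), -1)
  expect_lte(cc(x, y), 1)
  expect_warning(v <- cc(x, matrix(1, 10, 10)), "zero-variance")
  expect_true(is.na(v))
})

test_that("per-class saliency table averages per item and per class", {
  img0 <- render_digit_image(0, 53L)$pixels
  img1 <- render_digit_image(1, 53L)$pixels
  maps <- list(img0, img1, img0, img1)
  labels <- c(0, 0, 1, 1)
  tab <- evaluate_saliency_per_class(maps, maps, labels)
  expect_identical(nrow(tab), 3L)   # two classes + Average
  expect_equal(tab$ssim, c(100, 100, 100))
  expect_equal(tab$cc, c(100, 100, 100))
  # single class, two items: average equals the per-item mean
  pred <- list(img0, img1)
  truth <- list(img0, img0)
  t2 <- evaluate_saliency_per_class(pred, truth, c(5, 5))
  per_item <- c(100 * ssim(img0, img0), 100 * ssim(img1, img0))
  expect_equal(t2$ssim[1], mean(per_item))
  expect_identical(t2$category, c("5", "Average"))
})
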
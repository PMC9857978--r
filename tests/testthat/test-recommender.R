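test_that("matching head is an affine-sigmoid map of the concatenation", {
  set.seed(51)
  d <- 4; M <- 5
  q <- rnorm(d); C <- rnorm(d); H <- rnorm(2 * d)
  W <- rand_mat(4 * d, M)
  b <- rnorm(M)
  expect_equal(match_scores(q, C, H, matrix(0, 4 * d, M), rep(0, M)),
               rep(0.5, M))
  expect_gt(match_scores(q, C, H, matrix(0, 4 * d, M), c(50, 0, 0, 0, 0))[1],
            1 - 1e-12)
  o <- match_scores(q, C, H, W, b)
  expect_equal(o, as.vector(plogis(t(W) %*% c(q, C, H) + b)),
               tolerance = 1e-12)
  expect_error(match_scores(q, C, rnorm(d), W, b), "concat length")
})

test_that("threshold decoding uses the >= rule", {
  expect_equal(threshold_predictions(c(0.6, 0.4), 0.5), c(1, 0))
  expect_equal(threshold_predictions(c(0.5, 0.5), 0.5), c(1, 1))
  expect_error(threshold_predictions(0.5, 0))
})

test_that("loss components match hand-computed values", {
  # DDI: one interacting pair, unit scores, double sum counts it twice
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(ddi_loss(c(1, 1), A), 2)
  expect_equal(ddi_loss(c(1, 0), A), 0)
  expect_equal(ddi_loss(c(1, 1), matrix(0, 2, 2)), 0)

  # margin: single (pos, neg) pair
  expect_equal(margin_loss(c(0.9, 0.2), c(1, 0)), 0.15)
  expect_equal(margin_loss(c(2, 0.5), c(1, 0)), 0)   # separated by >= 1
  expect_equal(margin_loss(c(0.9, 0.8), c(1, 1)), 0) # no negatives

  # BCE at the uninformative score
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), 2 * log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  expect_lt(bce_loss(1 - 1e-7, 1), 1e-6)

  # prediction-loss mixture
  expect_equal(mp_loss(3, 7, 0), 3)
  expect_equal(mp_loss(3, 7, 1), 7)
  expect_equal(mp_loss(3, 7, 0.05), 0.95 * 3 + 0.05 * 7)

  # weighted total
  expect_equal(total_loss(1, 2, 3, 0, 5, 0), 10)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(1, 1, 1, 0.2, 0.75, 0.05), 1)
})

test_that("ddi loss is monotone in each score", {
  set.seed(52)
  for (i in 1:20) {
    M <- 5
    A <- matrix(rbinom(M * M, 1, 0.4), M, M); A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    o <- runif(M)
    k <- sample(M, 1)
    o2 <- o; o2[k] <- min(1, o[k] + 0.2)
    expect_gte(ddi_loss(o2, A), ddi_loss(o, A))
  }
})

test_that("margin loss is zero iff scores separate by the unit margin", {
  set.seed(53)
  for (i in 1:50) {
    M <- sample(2:4, 1)
    m <- rbinom(M, 1, 0.5)
    o <- runif(M, -1, 2)
    l <- margin_loss(o, m)
    pos <- o[m == 1]; neg <- o[m == 0]
    if (length(pos) == 0 || length(neg) == 0) {
      expect_equal(l, 0)
    } else if (min(pos) - max(neg) >= 1) {
      expect_equal(l, 0)
    } else {
      expect_gt(l, 0)
    }
    # brute-force enumeration oracle
    if (length(pos) && length(neg)) {
      acc <- 0
      for (i2 in which(m == 1)) for (j2 in which(m == 0))
        acc <- acc + max(0, 1 - (o[i2] - o[j2]))
      expect_equal(l, acc / M, tolerance = 1e-12)
    }
  }
})

test_that("Renyi entropy has its closed-form values on identity Gram matrices", {
  for (n in c(2, 3, 8)) {
    for (alpha in c(1.01, 2, 5)) {
      expect_equal(renyi_entropy_gram(diag(n), alpha), log2(n),
                   tolerance = 1e-9)
    }
  }
  expect_equal(renyi_entropy(matrix(rnorm(4), 1)), 0)  # single sample
  expect_error(renyi_entropy(matrix(numeric(), 0, 3)), "empty")
  expect_error(renyi_entropy_gram(diag(2), alpha = 1))
})

test_that("Renyi entropy matches an independent eigenvalue route on random Grams", {
  set.seed(54)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    X <- rand_mat(n, n + 2)
    K <- tcrossprod(X)                 # PSD Gram matrix
    alpha <- sample(c(1.01, 1.5, 2, 3), 1)
    # independent route: singular values of the normalised PSD matrix
    A <- K / sum(diag(K))
    lam <- svd(A, nu = 0, nv = 0)$d
    want <- log2(sum(lam^alpha)) / (1 - alpha)
    expect_equal(renyi_entropy_gram(K, alpha), want, tolerance = 1e-6)
  }
})

test_that("near-1 alpha approaches Shannon entropy; rotations leave it unchanged", {
  set.seed(55)
  Q <- rand_mat(6, 4)
  K <- exp(-as.matrix(stats::dist(Q))^2 / 2)
  A <- K / sum(diag(K))
  lam <- pmax(eigen(A, symmetric = TRUE, only.values = TRUE)$values, 1e-300)
  shannon <- -sum(lam * log2(lam))
  expect_equal(renyi_entropy(Q, alpha = 1.01, sigma = 1), shannon,
               tolerance = 1e-2)
  # orthogonal rotation of the representations preserves pairwise distances
  R <- qr.Q(qr(rand_mat(4, 4)))
  expect_equal(renyi_entropy(Q %*% R, alpha = 2), renyi_entropy(Q, alpha = 2),
               tolerance = 1e-8)
  expect_lte(renyi_entropy(Q, alpha = 2), log2(6) + 1e-12)
  expect_gte(renyi_entropy(Q, alpha = 2), 0)
})
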
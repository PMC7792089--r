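test_that("squash obeys the norm law and preserves direction", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  v1 <- squash(c(1, 0))
  expect_equal(sqrt(sum(v1^2)), 0.5, tolerance = 1e-6)
  v34 <- squash(c(3, 4))
  expect_equal(v34, c(75 / 130, 100 / 130), tolerance = 1e-9)
  expect_equal(sqrt(sum(v34^2)), 25 / 26, tolerance = 1e-9)

  set.seed(3)
  norms <- c()
  for (i in 1:200) {
    v <- rnorm(sample(2:8, 1)) * 10^runif(1, -3, 2)
    out <- squash(v)
    r <- sqrt(sum(v^2))
    expect_equal(sqrt(sum(out^2)), r^2 / (1 + r^2), tolerance = 1e-6)
    # cosine with the input is 1
    expect_equal(sum(v * out) / (sqrt(sum(v^2)) * sqrt(sum(out^2))), 1,
                 tolerance = 1e-6)
  }
  # output norm strictly increasing in the input norm
  rs <- sort(10^seq(-2, 2, length.out = 30))
  on <- vapply(rs, function(r) sqrt(sum(squash(c(r, 0))^2)), numeric(1))
  expect_true(all(diff(on) > 0))
})

test_that("dynamic routing matches the step-by-step oracle", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(2:4, 1); d <- sample(2:3, 1); T <- sample(1:3, 1)
    u <- matrix(rnorm(d * n), d, n)
    r <- dynamicRouting(u, T)
    expect_equal(r$v, oracleRouting(u, T), tolerance = 1e-6)
    # couplings positive, summing to 1 every round
    expect_true(all(r$couplings > 0))
    expect_equal(colSums(r$couplings), rep(1, T), tolerance = 1e-9)
  }
})

test_that("routing limit cases: uniform first round, symmetric inputs", {
  set.seed(2)
  u <- matrix(rnorm(12), 3, 4)
  # T = 1: softmax of zero logits is uniform, so v = squash(mean)
  r1 <- dynamicRouting(u, 1)
  expect_equal(r1$v, squash(rowMeans(u)), tolerance = 1e-9)
  # all inputs equal: v = squash(u) for any T
  ueq <- matrix(rep(c(0.4, -0.2, 0.7), 5), 3, 5)
  for (T in 1:3)
    expect_equal(dynamicRouting(ueq, T)$v, squash(c(0.4, -0.2, 0.7)),
                 tolerance = 1e-9)
  expect_error(dynamicRouting(u, 0))
})

test_that("convolution detectors respond as hand-computed", {
  # indicator filter for ACG (h = 3): weight 1 on matching entries
  w <- array(0, dim = c(3, 4, 1))  # columns A,T,C,G
  w[1, 1, 1] <- 1  # A at offset 1
  w[2, 3, 1] <- 1  # C at offset 2
  w[3, 4, 1] <- 1  # G at offset 3
  maps <- convFeatures("TACGT", w, bias = 0)
  expect_identical(nrow(maps), 3L)
  expect_equal(maps[2, 1], 3)
  expect_equal(max(maps), 3)
  expect_identical(which.max(maps[, 1]), 2L)

  # zero weights, zero bias: all-zero maps
  expect_true(all(convFeatures("ACGTACGT", array(0, dim = c(3, 4, 2))) == 0))

  # N padding shifts the original feature maps unchanged (zero rows add
  # nothing to interior windows), and an all-N input with bias <= 0 is
  # silent everywhere
  set.seed(6)
  for (i in 1:20) {
    wr <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2))
    b <- -abs(rnorm(2))
    s <- randomSeq(15)
    f0 <- convFeatures(s, wr, b)
    f1 <- convFeatures(paste0("NN", s, "NNN"), wr, b)
    expect_equal(f1[3:(2 + nrow(f0)), ], f0, tolerance = 1e-12)
    expect_true(all(convFeatures(strrep("N", 10), wr, b) == 0))
  }
  expect_error(convFeatures("AC", array(0, dim = c(3, 4, 1))), "shorter")
})

test_that("global max pooling keeps the leftmost argmax on ties", {
  p <- globalMaxPool(c(0, 3, 1))
  expect_equal(p$values, 3)
  expect_identical(p$argmax, 2L)
  p2 <- globalMaxPool(c(2, 2, 2))
  expect_identical(p2$argmax, 1L)
  m <- cbind(c(0, 1, 0), c(5, 5, 1))
  p3 <- globalMaxPool(m)
  expect_equal(p3$values, c(1, 5))
  expect_identical(p3$argmax, c(2L, 1L))
})

test_that("128 pooled detectors reshape into 16 capsules of dimension 8", {
  m <- capsModel(50L, nFilters = 128L, capsDim = 8L, seed = 1)
  expect_identical(capsRBP:::.nPrimaryCaps(modelConfig(m)), 16L)
  expect_identical(dim(m@capsW), c(16L, 8L, 32L))
})

test_that("margin loss reproduces its anchor values and zero set", {
  expect_equal(marginLoss(0.9, 0.1, "positive"), 0, tolerance = 1e-9)
  expect_equal(marginLoss(0.0, 0.0, "positive"), 0.81, tolerance = 1e-9)
  expect_equal(marginLoss(1.0, 1.0, "positive"), 0.405, tolerance = 1e-9)
  # zero iff true-class norm >= m+ and other-class norm <= m-
  set.seed(4)
  for (i in 1:200) {
    sp <- runif(1); sn <- runif(1)
    l <- marginLoss(sp, sn, "positive")
    expect_identical(l == 0, sp >= 0.9 && sn <= 0.1)
    l2 <- marginLoss(sp, sn, "negative")
    expect_identical(l2 == 0, sn >= 0.9 && sp <= 0.1)
  }
})

test_that("forward scores are capsule norms in [0, 1) from two digit capsules", {
  m <- capsModel(30L, nFilters = 16L, capsDim = 8L, seed = 7)
  set.seed(2)
  seqs <- vapply(1:10, function(i) randomSeq(30), character(1))
  sc <- predictScores(m, seqs)
  expect_identical(colnames(sc), c("scorePos", "scoreNeg"))
  expect_true(all(sc >= 0 & sc < 1))
  # deterministic: duplicate input gives identical scores
  sc2 <- predictScores(m, seqs)
  expect_identical(sc, sc2)
  expect_identical(unname(sc[1, ]),
                   unname(predictScores(m, seqs[1])[1, ]))
  # shape mismatch is rejected
  expect_error(predictScores(m, strrep("A", 40)), "longer")
})

test_that("scores are invariant under permutation of capsule groups", {
  m <- capsModel(24L, nFilters = 16L, capsDim = 4L, digitDim = 5L, seed = 3)
  cfg <- modelConfig(m)
  n <- capsRBP:::.nPrimaryCaps(cfg)     # 4 capsules of 4 filters
  set.seed(9)
  seqs <- vapply(1:6, function(i) randomSeq(24), character(1))
  base <- predictScores(m, seqs)
  perm <- sample(n)
  filtPerm <- as.vector(vapply(perm, function(i)
    (i - 1L) * cfg$dIn + seq_len(cfg$dIn), integer(cfg$dIn)))
  m2 <- m
  m2@convW <- m@convW[, , filtPerm, drop = FALSE]
  m2@convB <- m@convB[filtPerm]
  m2@capsW <- m@capsW[, , c(perm, n + perm), drop = FALSE]
  expect_equal(predictScores(m2, seqs), base, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences in all modes", {
  codes <- rbind(capsRBP:::.seqCodes("ACGTACGTACGT"),
                 capsRBP:::.seqCodes("NGGGTTTAACCN"))
  labels <- c(1L, 0L)
  for (mp in c(TRUE, FALSE)) for (ax in c("inputs", "outputs")) {
    m <- capsModel(12L, kernelSize = 3L, nFilters = 4L, capsDim = 2L,
                   digitDim = 3L, maxpool = mp, routingSoftmax = ax, seed = 5)
    w <- list(convW = m@convW, convB = m@convB, capsW = m@capsW)
    lg <- capsRBP:::.capsLossGradCpp(codes, labels, w, modelConfig(m))
    lossAt <- function(w)
      capsRBP:::.capsLossGradCpp(codes, labels, w, modelConfig(m))$loss
    eps <- 1e-6
    set.seed(1)
    for (nm in names(w)) {
      for (i in sample(length(w[[nm]]), min(10, length(w[[nm]])))) {
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        fd <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
        expect_equal(lg$grads[[nm]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("checkpoints reload to bit-identical forward scores", {
  m <- capsModel(20L, nFilters = 8L, capsDim = 4L, seed = 12)
  set.seed(5)
  seqs <- vapply(1:5, function(i) randomSeq(20), character(1))
  tmp <- tempfile(fileext = ".rds")
  saveModel(m, tmp)
  m2 <- loadModel(tmp)
  expect_identical(predictScores(m, seqs), predictScores(m2, seqs))
  expect_identical(modelConfig(m), modelConfig(m2))
  expect_error(suppressWarnings(loadModel(tempfile())))
})
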
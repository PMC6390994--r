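test_that("an exact rank-1 matrix is reconstructed to machine precision", {
  set.seed(1)
  X <- outer(runif(8, 0.5, 2), runif(12, 0.5, 2))
  m <- fitNMF(X, k = 1)
  expect_lt(sqrt(sum((X - reconstruct(m))^2)) / sqrt(sum(X^2)), 1e-6)
  # normalization: every W column maximum is 1
  expect_equal(unname(apply(m@W, 2, max)), 1)
})

test_that("disjoint blocks are recovered as factor supports", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    blocks <- lapply(1:3, function(b) outer(runif(3, 0.5, 1.5),
                                            runif(4, 0.5, 1.5)))
    X <- matrix(0, 9, 12)
    for (b in 1:3) X[(b - 1) * 3 + 1:3, (b - 1) * 4 + 1:4] <- blocks[[b]]
    m <- fitNMF(X, k = 3)
    block_of <- function(idx) unique((idx - 1) %/% 3 + 1)
    one_block <- all(vapply(1:3, function(f)
      length(block_of(which(m@W[, f] > 1e-8))) == 1, logical(1)))
    hits <- hits + one_block
  }
  expect_gte(hits, 18)
})

test_that("the L1 penalty makes loadings sparser, not denser", {
  nnz <- function(alpha, s) {
    set.seed(s)
    X <- matrix(0, 10, 30)
    X[1:5, 1:15] <- 1; X[6:10, 16:30] <- 1
    X <- pmax(X + matrix(rnorm(300, 0, 0.1), 10, 30), 0)
    m <- fitNMF(X, k = 2, alpha = alpha)
    sum(m@W > 1e-8)
  }
  d <- vapply(1:7, function(s) nnz(0, s) - nnz(10, s), numeric(1))
  expect_gte(stats::median(d), 0)
})

test_that("sparsification zeroes small loadings and preserves patient ranking", {
  W <- matrix(c(1, 0.05, 0.4), 3, 1)
  H <- matrix(runif(10, 0.2, 1), 1, 10)
  X <- W %*% H
  m <- new("FactorModel", W = W, H = H, k = 1L, alpha = 0, scale = 1,
           sparsifyThreshold = 0, sparsified = FALSE, scoreCor = NA_real_,
           converged = TRUE, objectiveTrace = 0, seed = 1L)
  s0 <- sparsify(m, X, threshold = 0)
  expect_equal(s0@W, W)
  expect_equal(s0@scoreCor, 1)
  s1 <- sparsify(m, X, threshold = 0.1)
  expect_equal(as.vector(s1@W), c(1, 0, 0.4))
  # an all-zero factor cannot survive any threshold
  mz <- new("FactorModel", W = cbind(W, 0), H = rbind(H, 1), k = 2L,
            alpha = 0, scale = c(1, 1), sparsifyThreshold = 0,
            sparsified = FALSE, scoreCor = rep(NA_real_, 2),
            converged = TRUE, objectiveTrace = 0, seed = 1L)
  expect_error(sparsify(mz, X, threshold = 0.1), "lower the threshold")
})

test_that("sparsifying a noisy planted model keeps pre/post score correlations high", {
  set.seed(8)
  W <- matrix(0, 12, 3)
  W[1:4, 1] <- runif(4, 0.5, 1); W[5:8, 2] <- runif(4, 0.5, 1)
  W[9:12, 3] <- runif(4, 0.5, 1)
  H <- matrix(runif(3 * 80, 0, 1), 3, 80)
  X <- pmax(W %*% H + matrix(rnorm(12 * 80, 0, 0.05), 12, 80), 0)
  m <- fitNMF(X, k = 3)
  ms <- sparsify(m, X, threshold = 0.1)
  expect_true(all(ms@scoreCor > 0.9))
})

test_that("q2 matches its definition at the fixed points", {
  set.seed(2)
  X <- matrix(runif(25), 5, 5)
  expect_equal(q2(X, X), 1)
  expect_equal(q2(X, matrix(mean(X), 5, 5)), 0)
  bad <- matrix(10, 5, 5) + matrix(runif(25), 5, 5)
  expect_lt(q2(X, bad), 0)
  mask <- matrix(c(rep(TRUE, 10), rep(FALSE, 15)), 5, 5)
  expect_equal(q2(X, X, mask), 1)
  expect_error(q2(matrix(1, 2, 2), matrix(1, 2, 2)), "constant")
  expect_lte(q2(X, matrix(runif(25), 5, 5), method = "corr"), 1)
})

test_that("projection through a frozen model is self-consistent", {
  set.seed(4)
  W <- matrix(0, 10, 2); W[1:5, 1] <- runif(5, 0.5, 1)
  W[6:10, 2] <- runif(5, 0.5, 1)
  H <- matrix(runif(2 * 40, 0, 1), 2, 40)
  X <- pmax(W %*% H + matrix(rnorm(400, 0, 0.02), 10, 40), 0)
  rownames(X) <- paste0("j", 1:10); colnames(X) <- paste0("p", 1:40)
  m <- fitNMF(X, k = 2)
  Hp <- projectScores(X, m)
  expect_lt(max(abs(Hp - m@H)), 1e-4)
  # an all-zero patient maps to exactly zero scores
  X0 <- cbind(X, p0 = 0)
  expect_equal(unname(projectScores(X0, m)[, "p0"]), c(0, 0))
  # a duplicated training patient recovers that patient's scores
  Xd <- X[, c(1, 1)]
  colnames(Xd) <- c("a", "b")
  Hd <- projectScores(Xd, m)
  expect_lt(max(abs(Hd[, "a"] - Hd[, "b"])), 1e-10)
  expect_lt(max(abs(Hd[, "a"] - m@H[, 1])), 1e-4)
  # feature mismatch is rejected
  Xr <- X; rownames(Xr) <- rev(rownames(X))
  expect_error(projectScores(Xr, m), "mismatch")
})

test_that("fitting is equivariant under patient permutation", {
  set.seed(6)
  X <- matrix(runif(10 * 20), 10, 20)
  perm <- sample(20)
  m1 <- fitNMF(X, k = 3)
  m2 <- fitNMF(X[, perm], k = 3)
  expect_equal(m2@H, m1@H[, perm], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m2@W, m1@W, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("invalid factorization inputs are rejected", {
  X <- matrix(1, 4, 4)
  expect_error(fitNMF(X - 2, 2), "non-negative")
  expect_error(fitNMF(X, 5), "exceeds")
  expect_error(fitNMF(X, 2, alpha = -1), "alpha")
})
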
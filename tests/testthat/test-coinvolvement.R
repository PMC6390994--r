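test_that("involvement and conditional co-involvement match a hand count", {
  cat <- toy_catalog(2)  # t1 = knee, t2 = ankle
  X <- toy_matrix(cat, list(c("t1_l", "t1_r"), "t1_l",
                            c("t2_l", "t1_l"), "t2_l"))
  ci <- coinvolvement(X)
  expect_equal(ci$freq[["t1_l"]], 0.75)
  expect_equal(ci$cond["t1_l", "t2_l"], 1 / 3)   # P(ankleL | kneeL)
  expect_equal(ci$cond["t2_l", "t1_l"], 0.5)     # P(kneeL | ankleL)
  expect_true(all(is.na(ci$cond["t2_r", ])))     # never-involved reference
})

test_that("conditional probabilities satisfy cond[y|x] * P(x) = P(x,y) and self-conditionals are 1", {
  set.seed(42)
  for (r in 1:20) {
    X <- matrix(rbinom(12 * 30, 1, 0.3), 12, 30,
                dimnames = list(paste0("j", 1:12), paste0("p", 1:30)))
    ci <- coinvolvement(X)
    pos <- ci$freq > 0
    expect_equal(ci$cond[pos, ] * ci$freq[pos], ci$pair[pos, ])
    expect_equal(unname(diag(ci$cond)[pos]), rep(1, sum(pos)))
  }
})

test_that("the skew z-score follows the shrunken-proportion formula", {
  cat <- toy_catalog(2)
  # 9 patients carry a same-side (left) t1-t2 pair, none opposite
  X <- toy_matrix(cat, rep(list(c("t1_l", "t2_l")), 9))
  st <- skewTest(X, cat)
  row <- st[st$x_type == "t1" & st$y_type == "t2", ]
  expect_equal(row$n_same, 9)
  expect_equal(row$n_opposite, 0)
  m <- 10 / 11
  expect_equal(row$m, m)
  expect_equal(row$z, (m - 0.5) / sqrt(m * (1 - m) / 11))
  expect_equal(row$z, 4.72, tolerance = 0.001)
})

test_that("balanced counts give zero skew and swapping counts mirrors m about 1/2", {
  cat <- toy_catalog(2)
  X <- toy_matrix(cat, c(rep(list(c("t1_l", "t2_l")), 5),
                         rep(list(c("t1_l", "t2_r")), 5)))
  st <- skewTest(X, cat)
  row <- st[st$x_type == "t1" & st$y_type == "t2", ]
  expect_equal(row$z, 0)
  # antisymmetry: 7 same / 2 opposite versus 2 same / 7 opposite
  Xa <- toy_matrix(cat, c(rep(list(c("t1_l", "t2_l")), 7),
                          rep(list(c("t1_l", "t2_r")), 2)))
  Xb <- toy_matrix(cat, c(rep(list(c("t1_l", "t2_l")), 2),
                          rep(list(c("t1_l", "t2_r")), 7)))
  ra <- skewTest(Xa, cat); rb <- skewTest(Xb, cat)
  ma <- ra$m[ra$x_type == "t1" & ra$y_type == "t2"]
  mb <- rb$m[rb$x_type == "t1" & rb$y_type == "t2"]
  expect_equal(ma - 0.5, -(mb - 0.5))
})

test_that("a perfectly bilateral cohort shows no significant skew", {
  cat <- toy_catalog(4)
  set.seed(7)
  sets <- lapply(1:60, function(i) {
    tps <- sample(paste0("t", 1:4), sample(1:3, 1))
    unlist(lapply(tps, function(t) paste0(t, c("_l", "_r"))))
  })
  st <- skewTest(toy_matrix(cat, sets), cat)
  expect_equal(sum(st$significant), 0)
})

test_that("self-pairs measure pure bilaterality", {
  cat <- toy_catalog(2)
  X <- toy_matrix(cat, list(c("t1_l", "t1_r"), c("t1_l", "t1_r"), "t1_l"))
  st <- skewTest(X, cat)
  row <- st[st$x_type == "t1" & st$y_type == "t1", ]
  expect_equal(row$n_same, 0)
  expect_equal(row$n_opposite, 2)
})

test_that("BH q-values agree with a brute-force step-up rule", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (r in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bhFdr(p), bh_brute(p))
  }
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("left/right symmetry permutation test behaves at both extremes", {
  cat <- toy_catalog(3)
  # mirror-symmetric cohort: every active type active on both sides
  sets <- lapply(1:30, function(i) {
    t <- paste0("t", 1 + (i %% 3)); paste0(t, c("_l", "_r"))
  })
  sym <- lrSymmetryPermTest(toy_matrix(cat, sets), cat, n_perm = 49, seed = 1)
  expect_equal(sym$frobenius, 0)
  # planted cross-side asymmetry: t1 left always brings t2 right, but t1
  # right never brings t2 left
  sets1 <- c(rep(list(c("t1_l", "t2_r")), 30), rep(list("t1_r"), 30))
  asym <- lrSymmetryPermTest(toy_matrix(cat, sets1), cat,
                             n_perm = 199, seed = 2)
  expect_gt(asym$frobenius, 0)
  expect_lt(asym$p, 0.05)
  expect_error(lrSymmetryPermTest(toy_matrix(cat, sets1), cat, n_perm = 0),
               "n_perm")
})

test_that("the conditional significance screen covers all ordered pairs", {
  cat <- toy_catalog(3)
  set.seed(5)
  X <- matrix(rbinom(6 * 40, 1, 0.4), 6, 40,
              dimnames = list(jointIds(cat), paste0("p", 1:40)))
  ct <- condTest(X)
  expect_equal(ct$n_pairs, 36)
  expect_true(all(ct$p_adj >= ct$p, na.rm = TRUE))
})
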
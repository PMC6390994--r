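test_that("a toy planted hierarchy is recovered exactly in most seeds", {
  cat8 <- toy_catalog(8)
  hits <- 0
  for (s in 1:10) {
    pm <- makePlantedModel(cat8, k1 = 6, k2 = 3, seed = s, noise_rate = 0.01)
    sb <- simulateBaseline(pm, 300, seed = 50 + s)
    ml <- fitMultilayer(baselineMatrix(sb$cohort), k1 = 6, k2 = 3)
    hits <- hits + supports_exact(ml, pm)
  }
  expect_gte(hits, 9)
})

test_that("both reconstruction paths through the hierarchy agree", {
  pm <- makePlantedModel(toy_catalog(8), k1 = 6, k2 = 3, seed = 2)
  sb <- simulateBaseline(pm, 200, seed = 3)
  ml <- fitMultilayer(baselineMatrix(sb$cohort), 6, 3)
  W1 <- ml@layer1@W; W2 <- ml@layer2@W; H2 <- ml@layer2@H
  expect_lt(max(abs(W1 %*% (W2 %*% H2) - (W1 %*% W2) %*% H2)), 1e-10)
  # every pattern's key set is the support of its composite column
  C <- compositeLoadings(ml)
  for (f in seq_along(keyJoints(ml)))
    expect_setequal(keyJoints(ml)[[f]], rownames(C)[C[, f] > 0])
})

test_that("patients are assigned to their highest-scoring factor with documented tie handling", {
  pm <- makePlantedModel(toy_catalog(8), k1 = 6, k2 = 3, seed = 2)
  sb <- simulateBaseline(pm, 150, seed = 4)
  ml <- fitMultilayer(baselineMatrix(sb$cohort), 6, 3)
  sc <- matrix(c(0.1, 0.9, 0,
                 0.5, 0.5, 0,
                 0,   0,   0), 3, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  asg <- assignGroups(ml, sc)
  expect_equal(unname(assignedGroup(asg)), c("G2", "G1", "unscored"))
  expect_equal(unname(isTie(asg)), c(FALSE, TRUE, FALSE))
})

test_that("planted group labels are recovered for almost all patients", {
  pm <- makePlantedModel(toy_catalog(8), k1 = 6, k2 = 3, seed = 5,
                         noise_rate = 0.01)
  sb <- simulateBaseline(pm, 400, seed = 6)
  X <- baselineMatrix(sb$cohort)
  ml <- fitMultilayer(X, 6, 3)
  al <- alignFactors(compositeLoadings(ml), planted_reference(pm, rownames(X)))
  map <- stats::setNames(names(plantedKeyJoints(pm))[al$perm],
                         colnames(compositeLoadings(ml)))
  rec <- mean(map[assignedGroup(assignGroups(ml, X))] == sb$truth$group)
  expect_gte(rec, 0.95)
})

test_that("group-factor overlap flags exactly the block structure", {
  set.seed(9)
  H2 <- matrix(0.01, 3, 90)
  grp <- rep(c("G1", "G2", "G3"), each = 30)
  for (i in 1:90) H2[match(grp[i], c("G1", "G2", "G3")), i] <- runif(1, 0.8, 1)
  rownames(H2) <- c("F1", "F2", "F3")
  ov <- groupFactorOverlap(H2, grp)
  sig <- ov[ov$significant, ]
  expect_equal(nrow(sig), 3)
  expect_true(all(sub("G", "", sig$group) == sub("F", "", sig$factor)))
})

test_that("identically distributed groups are rarely flagged as enriched", {
  set.seed(13)
  n_any <- 0
  for (r in 1:100) {
    H2 <- matrix(runif(2 * 40, 0.1, 1), 2, 40,
                 dimnames = list(c("F1", "F2"), NULL))
    grp <- rep(c("A", "B"), 20)
    ov <- groupFactorOverlap(H2, grp)
    n_any <- n_any + any(ov$significant)
  }
  # BH at q < 0.1 bounds the per-cohort false-flag rate near 10%
  expect_lte(n_any, 20)
})

test_that("group-label association reproduces the 2x2 closed form", {
  grp <- rep(c("G1", "G2"), each = 10)
  lab <- rep(c("oligo", "poly"), each = 10)
  a <- groupLabelAssociation(grp, lab)
  expect_equal(a$chi2, 20)
  diag_cells <- a$table[a$table$group == "G1" & a$table$label == "oligo", ]
  expect_equal(abs(diag_cells$residual), sqrt(a$chi2))
  expect_true(diag_cells$enriched)
  # a group drawn entirely from one label is enriched in it
  set.seed(2)
  grp2 <- c(rep("G1", 15), rep("G2", 30))
  lab2 <- c(rep("ERA", 15), sample(c("ERA", "oligo"), 30, replace = TRUE))
  a2 <- groupLabelAssociation(grp2, lab2)
  expect_gte(a2$table$residual[a2$table$group == "G1" &
                               a2$table$label == "ERA"], 1.96)
  expect_error(groupLabelAssociation(grp, rep("one", 20)), ">= 2")
})

test_that("group-label chi-squared p-values are calibrated under independence", {
  set.seed(17)
  ps <- replicate(300, {
    grp <- sample(c("G1", "G2", "G3"), 150, replace = TRUE)
    lab <- sample(c("a", "b"), 150, replace = TRUE)
    groupLabelAssociation(grp, lab)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("factor alignment finds the planted permutation", {
  set.seed(3)
  R <- matrix(runif(12 * 4), 12, 4)
  perm <- c(3, 1, 4, 2)
  F <- R[, perm] + matrix(rnorm(48, 0, 0.01), 12, 4)
  al <- alignFactors(F, R)
  expect_equal(al$perm, perm)
  expect_true(all(al$cosines > 0.99))
})
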
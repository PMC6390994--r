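# a fitted toy model plus a simulated course, shared across blocks
local_course <- local({
  pm <- makePlantedModel(toy_catalog(8), k1 = 6, k2 = 3, seed = 3,
                         noise_rate = 0,
                         localization_mix = c(1, 0, 0))
  sb <- simulateBaseline(pm, 200, seed = 7)
  sim <- simulateCourse(sb, pm, seed = 8)
  ml <- fitMultilayer(baselineMatrix(sb$cohort), 6, 3)
  list(pm = pm, sb = sb, sim = sim, ml = ml)
})

test_that("visit scoring marks zero-joint visits and missing patients", {
  lc <- local_course
  traj <- scoreVisits(lc$sim$cohort, lc$ml)
  expect_setequal(unique(traj$visit_month), visitMonths(lc$sim$cohort))
  # ZERO exactly where the visit column sum is zero
  for (m in c(6L, 24L)) {
    M <- visitMatrix(lc$sim$cohort, m)
    zero_pat <- colnames(M)[colSums(M) == 0]
    got <- traj$state[traj$visit_month == m & traj$patient %in% colnames(M)]
    names(got) <- traj$patient[traj$visit_month == m &
                               traj$patient %in% colnames(M)]
    expect_setequal(names(which(got == "ZERO")), zero_pat)
  }
})

test_that("re-scoring baseline through the frozen model reproduces baseline groups", {
  lc <- local_course
  asg <- assignGroups(lc$ml, baselineMatrix(lc$sb$cohort))
  traj <- scoreVisits(lc$sb$cohort, lc$ml)
  base <- traj$state[traj$visit_month == 0]
  names(base) <- traj$patient[traj$visit_month == 0]
  nontie <- names(which(!isTie(asg)))
  agree <- mean(base[nontie] == assignedGroup(asg)[nontie])
  expect_gte(agree, 0.99)
})

test_that("an all-localized no-flare cohort never changes group before reaching zero", {
  lc <- local_course
  traj <- scoreVisits(lc$sim$cohort, lc$ml)
  base <- traj$state[traj$visit_month == 0]
  names(base) <- traj$patient[traj$visit_month == 0]
  fu <- traj[traj$visit_month > 0 & !traj$state %in% c("ZERO", "MISSING"), ]
  expect_true(all(fu$state == base[fu$patient]))
})

test_that("transition counts, denominators and the permutation null behave", {
  lc <- local_course
  traj <- scoreVisits(lc$sim$cohort, lc$ml)
  base <- traj$state[traj$visit_month == 0]
  names(base) <- traj$patient[traj$visit_month == 0]
  tr <- transitions(traj, base, n_perm = 499, seed = 1)
  # reach-any-visit semantics: each patient counted once per destination
  expect_true(all(tr$count <= tr$denominator))
  # destinations are only the baseline groups and ZERO (no flares)
  expect_true(all(tr$destination %in% c(unique(base), "ZERO")))
  # staying in one's own group is the overrepresented transition here
  own <- tr[tr$stratum == tr$destination, ]
  expect_true(all(own$probability > 0.4))
  expect_true(any(own$enriched))
  expect_equal(formals(transitions)$n_perm, 2000L)
  expect_error(transitions(traj, base, n_perm = 0), "n_perm")
})

test_that("time to zero uses first crossing and censors at last follow-up", {
  cat2 <- toy_catalog(2)
  ids <- jointIds(cat2)
  mk <- function(pats, sets) {
    M <- matrix(0, length(ids), length(pats), dimnames = list(ids, pats))
    for (i in seq_along(sets)) M[sets[[i]], i] <- 1
    M
  }
  X <- list(
    "0"  = mk(c("a", "b", "c", "d"),
              list("t1_l", "t1_r", "t2_l", "t1_l")),
    "6"  = mk(c("a", "b", "c"), list(character(0), "t1_r", "t2_l")),
    "12" = mk(c("b", "c"), list("t1_r", character(0))),
    "18" = mk(c("b", "c"), list("t1_r", "t2_l")),
    "60" = mk("b", list("t1_r")))
  co <- JointCohort(cat2, X)
  expect_warning(surv <- timeToZero(co), "no follow-up")
  surv <- surv[order(surv$patient), ]
  # a: zero at 6 -> event at 6; b: never zero, censored at 60
  # c: zero at 12, flares at 18 -> first crossing keeps event at 12
  # d: no follow-up -> excluded
  expect_equal(surv$patient, c("a", "b", "c"))
  expect_equal(surv$time, c(6, 60, 12))
  expect_equal(surv$event, c(1L, 0L, 1L))
})

test_that("Cox fit recovers a known hazard ratio with a covering interval", {
  set.seed(31)
  n <- 500
  grp <- rep(c("slow", "fast"), each = n / 2)
  rate <- ifelse(grp == "fast", 2, 1)
  surv <- data.frame(time = rexp(n, rate), event = 1L,
                     group = factor(grp, levels = c("slow", "fast")))
  fit <- fitCox(surv, "group")
  hr <- fit$table$HR
  expect_gt(hr, 1.6); expect_lt(hr, 2.5)
  expect_true(fit$table$ci_lower < 2 && 2 < fit$table$ci_upper)
  expect_equal(fit$r2, 1 - exp(-fit$lr_stat / n))
  # Breslow ties variant runs and agrees closely without heavy ties
  fb <- fitCox(surv, "group", ties = "breslow")
  expect_equal(fb$table$HR, hr, tolerance = 0.01)
})

test_that("degenerate survival inputs are refused", {
  surv <- data.frame(time = rexp(30), event = 1L,
                     group = factor(rep("only", 30)))
  expect_error(fitCox(surv, character(0)), "no covariates")
  expect_error(fitCox(surv, "group"), "single level")
  surv$event <- 0L
  expect_error(fitCox(surv, "group"), "events")
})

test_that("log-rank separates different hazards and the KM curve is a valid survival curve", {
  set.seed(33)
  n <- 300
  grp <- rep(c("a", "b"), each = n / 2)
  surv <- data.frame(time = rexp(n, ifelse(grp == "a", 1, 3)), event = 1L,
                     group = grp)
  lr <- logrank(surv, "group")
  expect_lt(lr$p, 0.01)
  km <- kmCurve(surv, "group")
  for (g in c("a", "b")) {
    cg <- km[km$group == g, ]
    expect_equal(cg$surv[cg$time == 0], 1)
    expect_true(all(diff(cg$surv[order(cg$time)]) <= 0))
  }
})
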
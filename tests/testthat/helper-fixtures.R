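# Shared fixtures and independent oracles.

# small catalog of n bilateral pairs (types t1..tn) plus optional midline site
toy_catalog <- function(n_pairs = 4, midline = FALSE) {
  rows <- lapply(seq_len(n_pairs), function(i) {
    data.frame(joint_id = paste0("t", i, c("_l", "_r")),
               label = paste("type", i, c("left", "right")),
               side = c("left", "right"),
               joint_type = paste0("t", i),
               axis_rank = i, stringsAsFactors = FALSE)
  })
  if (midline)
    rows <- c(list(data.frame(joint_id = "mid", label = "midline site",
                              side = "midline", joint_type = "mid",
                              axis_rank = 0L, stringsAsFactors = FALSE)),
              rows)
  JointCatalog(do.call(rbind, rows))
}

# build a baseline matrix over a catalog from a list of active joint sets
toy_matrix <- function(catalog, sets) {
  ids <- jointIds(catalog)
  X <- sapply(sets, function(s) as.integer(ids %in% s))
  dimnames(X) <- list(ids, paste0("p", seq_along(sets)))
  X
}

# brute-force Benjamini-Hochberg step-up rule, independent of p.adjust
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  # enforce step-up monotonicity from the largest p down
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# planted reference composite (binary joints x patterns indicator)
planted_reference <- function(planted, ids) {
  sapply(plantedKeyJoints(planted), function(k) as.integer(ids %in% k))
}

# do fitted key-joint sets match the planted ones exactly (best alignment)?
supports_exact <- function(model, planted) {
  ref <- planted_reference(planted, model@jointIds)
  al <- alignFactors(compositeLoadings(model), ref)
  all(vapply(seq_along(keyJoints(model)), function(f) {
    setequal(keyJoints(model)[[f]], plantedKeyJoints(planted)[[al$perm[f]]])
  }, logical(1)))
}

# trajectory table straight from the generator's ground truth (planted
# group while joints remain, ZERO once resolved) -- no model fit needed
traj_from_truth <- function(sim) {
  co <- sim$cohort
  grp <- stats::setNames(sim$truth$group, sim$truth$patient)
  rows <- lapply(visitMonths(co), function(m) {
    M <- visitMatrix(co, m)
    state <- stats::setNames(rep("MISSING", length(cohortPatients(co))),
                             cohortPatients(co))
    state[colnames(M)] <- ifelse(colSums(M) == 0, "ZERO",
                                 grp[colnames(M)])
    data.frame(patient = names(state), visit_month = m,
               state = unname(state), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# equality of two cohorts up to patient column order
expect_cohort_equal <- function(a, b) {
  expect_identical(visitMonths(a), visitMonths(b))
  expect_setequal(cohortPatients(a), cohortPatients(b))
  for (m in visitMonths(a)) {
    Ma <- visitMatrix(a, m); Mb <- visitMatrix(b, m)
    expect_setequal(colnames(Ma), colnames(Mb))
    Mb <- Mb[, colnames(Ma), drop = FALSE]
    expect_equal(unname(Ma == 1), unname(Mb == 1))
  }
}
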
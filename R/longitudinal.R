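#' Score every visit through a frozen multilayer model
#'
#' Each non-missing visit column is projected through both frozen layers
#' and assigned to its highest-scoring high-level factor. A visit at which
#' the patient has no active joints short-circuits projection and is
#' recorded as state \code{"ZERO"}; a visit at which the patient was not
#' assessed is \code{"MISSING"}.
#'
#' @param cohort a \linkS4class{JointCohort}.
#' @param model a frozen \linkS4class{MultilayerModel}.
#' @return data.frame (the trajectory table): \code{patient},
#'   \code{visit_month}, \code{state}.
#' @export
scoreVisits <- function(cohort, model) {
  rows <- list()
  for (i in seq_along(cohort@visits)) {
    m <- cohort@visits[i]
    M <- cohort@X[[i]]
    state <- stats::setNames(rep("MISSING", length(cohort@patients)),
                             cohort@patients)
    if (ncol(M)) {
      zero <- colSums(M) == 0
      state[colnames(M)[zero]] <- "ZERO"
      nz <- colnames(M)[!zero]
      if (length(nz)) {
        asg <- assignGroups(model, M[, nz, drop = FALSE])
        state[nz] <- asg@group
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient = cohort@patients, visit_month = m, state = unname(state),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient, out$visit_month), ]
  rownames(out) <- NULL
  out
}

#' Baseline-stratum to destination-state transition matrix
#'
#' For each baseline stratum (e.g. baseline patient group, possibly crossed
#' with localization), counts the patients who reach each destination state
#' at any follow-up visit; a patient counts at most once per destination
#' regardless of how many visits show it. The denominator is the number of
#' stratum patients with at least one non-missing follow-up visit (patients
#' whose every later state is missing are excluded). Overrepresentation is
#' assessed by permuting baseline stratum labels across patients
#' \code{n_perm} times -- whole follow-up trajectories travel with the
#' patient, preserving within-trajectory correlation -- with
#' Holm-Bonferroni adjustment; a cell is enriched when the adjusted p is
#' below \code{level}.
#'
#' @param traj trajectory table from \code{\link{scoreVisits}}.
#' @param strata named character vector: baseline stratum per patient.
#' @param n_perm permutations (default 2000, the study's setting).
#' @param seed integer seed.
#' @param level significance level on the adjusted p (default 0.05).
#' @return data.frame: stratum, destination, count, denominator,
#'   probability, p, p_adj, enriched.
#' @export
transitions <- function(traj, strata, n_perm = 2000L, seed = 1L,
                        level = 0.05) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  fu <- traj[traj$visit_month > 0, , drop = FALSE]
  if (!nrow(fu)) stop("no follow-up visits")
  fu <- fu[fu$state != "MISSING", , drop = FALSE]
  ## per patient: set of destinations reached at any follow-up visit
  dest_sets <- split(fu$state, fu$patient)
  dest_sets <- lapply(dest_sets, unique)
  pats <- names(dest_sets)
  strata <- strata[pats]
  strat_levels <- sort(unique(strata))
  dest_levels <- sort(unique(unlist(dest_sets)))
  count_matrix <- function(lab) {
    M <- matrix(0L, length(strat_levels), length(dest_levels),
                dimnames = list(strat_levels, dest_levels))
    for (i in seq_along(pats)) {
      d <- dest_sets[[i]]
      M[lab[i], d] <- M[lab[i], d] + 1L
    }
    M
  }
  obs <- count_matrix(strata)
  denom <- as.vector(table(factor(strata, levels = strat_levels)))
  set.seed(seed)
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm)) {
    perm <- count_matrix(sample(strata))
    exceed <- exceed + (perm >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(
    stratum = rep(strat_levels, times = length(dest_levels)),
    destination = rep(dest_levels, each = length(strat_levels)),
    count = as.vector(obs),
    denominator = rep(denom, times = length(dest_levels)),
    stringsAsFactors = FALSE)
  out$probability <- out$count / out$denominator
  out$p <- as.vector(p)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out$enriched <- out$p_adj < level
  out
}

#' Time to zero joint involvement
#'
#' First-passage survival data: the event time is the month of the first
#' visit at which the patient has no active joints; later flares do not
#' undo the event. Patients who never reach zero are censored at their
#' last observed visit. Patients with no follow-up at all cannot contribute
#' and are excluded with a warning.
#'
#' @param cohort a \linkS4class{JointCohort}.
#' @param covariates optional data.frame (rownames = patient ids) of
#'   per-patient covariates to carry along (e.g. group, localization,
#'   ILAR subtype).
#' @return data.frame: patient, time (months), event (1 reached zero,
#'   0 censored), plus any covariates.
#' @export
timeToZero <- function(cohort, covariates = NULL) {
  lv <- lastVisit(cohort)
  rows <- list()
  dropped <- character(0)
  for (p in cohort@patients) {
    if (lv[p] == 0L) { dropped <- c(dropped, p); next }
    zero_months <- integer(0)
    for (i in seq_along(cohort@visits)) {
      m <- cohort@visits[i]
      if (m == 0L) next
      M <- cohort@X[[i]]
      if (p %in% colnames(M) && sum(M[, p]) == 0) zero_months <- c(zero_months, m)
    }
    if (length(zero_months)) {
      rows[[length(rows) + 1L]] <- data.frame(patient = p,
                                              time = min(zero_months),
                                              event = 1L)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(patient = p, time = lv[p],
                                              event = 0L)
    }
  }
  if (length(dropped))
    warning(length(dropped), " patient(s) with no follow-up excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(covariates)) out <- cbind(out, covariates[out$patient, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Cox proportional hazards fit for time to zero joints
#'
#' Thin, validated interface to \code{survival::coxph}: partial likelihood
#' with Efron tie handling by default (the visit grid creates heavy ties;
#' Breslow available), Wald confidence intervals per level, the global
#' partial-likelihood-ratio test, and a Cox-Snell style
#' \eqn{R^2 = 1 - \exp(-LR/n)}. Reference levels are the first factor
#' level of each covariate; relevel the inputs to change them.
#'
#' @param surv data.frame from \code{\link{timeToZero}} (columns
#'   \code{time}, \code{event}, plus covariates).
#' @param covariates character vector of covariate column names (>= 1).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return list with \code{fit} (the coxph object), \code{table}
#'   (term, beta, HR, ci_lower, ci_upper, z, p), \code{lr_stat},
#'   \code{lr_p}, \code{r2}, \code{n}, \code{n_events},
#'   \code{diagnostics} (warnings, e.g. monotone likelihood).
#' @export
fitCox <- function(surv, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!length(covariates)) stop("nothing to estimate: no covariates given")
  if (sum(surv$event) < 2L) stop("need >= 2 events")
  for (cv in covariates) {
    if (!cv %in% names(surv)) stop("missing covariate column: ", cv)
    if (is.character(surv[[cv]])) surv[[cv]] <- factor(surv[[cv]])
    if (is.factor(surv[[cv]]) && nlevels(droplevels(surv[[cv]])) < 2L)
      stop("covariate ", cv, " has a single level: nothing to estimate")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  diags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = surv, ties = ties),
    warning = function(w) {
      diags <<- c(diags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    beta = s$coefficients[, "coef"],
    HR = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  lr <- s$logtest
  list(fit = fit, table = tab, lr_stat = unname(lr["test"]),
       lr_p = unname(lr["pvalue"]), r2 = 1 - exp(-unname(lr["test"]) / s$n),
       n = s$n, n_events = fit$nevent, diagnostics = diags)
}

#' Log-rank test between groups
#'
#' @param surv data.frame with \code{time}, \code{event} and the grouping
#'   column.
#' @param grouping name of the grouping column.
#' @return list with \code{statistic} (chi-squared) and \code{p}.
#' @export
logrank <- function(surv, grouping) {
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", grouping))
  sd <- survival::survdiff(fml, data = surv)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Kaplan-Meier curve of continued joint involvement
#'
#' @param surv data.frame with \code{time}, \code{event} and optionally the
#'   grouping column.
#' @param grouping optional name of a grouping column.
#' @return data.frame: group (\code{"all"} when ungrouped), time, surv
#'   (proportion of patients still with joint involvement; 1 at time 0,
#'   non-increasing).
#' @export
kmCurve <- function(surv, grouping = NULL) {
  rhs <- if (is.null(grouping)) "1" else grouping
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  sf <- survival::survfit(fml, data = surv)
  if (is.null(sf$strata)) {
    groups <- rep("all", length(sf$time))
  } else {
    groups <- rep(sub("^[^=]*=", "", names(sf$strata)), sf$strata)
  }
  out <- data.frame(group = groups, time = sf$time, surv = sf$surv,
                    stringsAsFactors = FALSE)
  zero <- data.frame(group = unique(out$group), time = 0, surv = 1,
                     stringsAsFactors = FALSE)
  out <- rbind(zero, out)
  out[order(out$group, out$time), ]
}
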
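#' Degree of localization of a patient's active joints
#'
#' The fraction of a patient's active joints that are key joints of their
#' assigned pattern. Categories use the closed thresholds: localized when
#' the fraction is >= 90\%, partially localized when >= 60\% and < 90\%,
#' extended otherwise. Boundary comparisons are made in exact integer
#' arithmetic (\code{10 * n_key >= 9 * n_active} etc.), so fractions of
#' exactly 0.9 and 0.6 classify as localized and partial with no floating
#' drift.
#'
#' @param active character vector of the patient's active joint ids
#'   (nonempty).
#' @param key_set character vector of the assigned factor's key joints.
#' @return list with \code{n_active}, \code{n_key}, \code{fraction},
#'   \code{category}.
#' @export
degreeOfLocalization <- function(active, key_set) {
  if (!length(active)) stop("empty active joint set")
  n_active <- length(unique(active))
  n_key <- length(intersect(unique(active), key_set))
  category <- if (10L * n_key >= 9L * n_active) "localized"
              else if (10L * n_key >= 6L * n_active) "partial"
              else "extended"
  list(n_active = n_active, n_key = n_key, fraction = n_key / n_active,
       category = category)
}

#' Localization table for a whole cohort
#'
#' Applies \code{\link{degreeOfLocalization}} to every patient against the
#' key-joint set of their assigned group. Patients in the reserved
#' \code{"unscored"} group have no key set and get category \code{NA}.
#'
#' @param X joints x patients binary matrix (baseline).
#' @param assignment a \linkS4class{GroupAssignment}.
#' @param model a \linkS4class{MultilayerModel} providing the key sets.
#' @return data.frame: patient, group, n_active, n_key, fraction, category.
#' @export
localizationTable <- function(X, assignment, model) {
  grp <- assignment@group
  rows <- lapply(colnames(X), function(p) {
    act <- rownames(X)[X[, p] == 1]
    g <- grp[p]
    if (identical(unname(g), "unscored")) {
      data.frame(patient = p, group = g, n_active = length(act),
                 n_key = NA_integer_, fraction = NA_real_,
                 category = NA_character_, stringsAsFactors = FALSE)
    } else {
      d <- degreeOfLocalization(act, model@keyJoints[[g]])
      data.frame(patient = p, group = g, n_active = d$n_active,
                 n_key = d$n_key, fraction = d$fraction,
                 category = d$category, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group skew of localization categories
#'
#' Chi-squared goodness-of-fit of each group's (localized, partial,
#' extended) counts against the global category proportions, with
#' Bonferroni adjustment across groups. The skew direction per category is
#' the sign of observed minus expected.
#'
#' @param loc data.frame from \code{\link{localizationTable}} (rows with
#'   \code{NA} category are dropped).
#' @param level significance level on the adjusted p (default 0.05).
#' @return data.frame: group, n, chi2, p, p_adj, significant, and one
#'   direction column per category (+1 above, -1 below, 0 at expectation).
#' @export
localizationSkew <- function(loc, level = 0.05) {
  loc <- loc[!is.na(loc$category), , drop = FALSE]
  cats <- c("localized", "partial", "extended")
  glob <- table(factor(loc$category, levels = cats))
  gprop <- as.vector(glob) / sum(glob)
  groups <- sort(unique(loc$group))
  if (length(groups) < 2L) stop("need >= 2 groups")
  rows <- lapply(groups, function(g) {
    cnt <- table(factor(loc$category[loc$group == g], levels = cats))
    n <- sum(cnt)
    if (n < 1L) stop("group ", g, " has no patients")
    exp <- n * gprop
    keep <- gprop > 0
    chi2 <- sum((as.vector(cnt)[keep] - exp[keep])^2 / exp[keep])
    p <- stats::pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
    dir <- sign(as.vector(cnt) - exp)
    out <- data.frame(group = g, n = n, chi2 = chi2, p = p,
                      stringsAsFactors = FALSE)
    out[paste0("dir_", cats)] <- as.list(dir)
    out
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * length(groups), 1)
  out$significant <- out$p_adj < level
  out[c("group", "n", "chi2", "p", "p_adj", "significant",
        paste0("dir_", cats))]
}

#' Sweep localization thresholds with bootstrap errors
#'
#' For each candidate threshold, the proportion of patients whose key-joint
#' fraction meets or exceeds it, with a standard error from patient-level
#' bootstrap resampling.
#'
#' @param fractions numeric vector of per-patient key-joint fractions.
#' @param grid thresholds to evaluate (default \code{seq(0, 1, 0.05)}).
#' @param n_boot bootstrap resamples (default 2000, the study's setting).
#' @param seed integer seed.
#' @return data.frame: threshold, proportion, se.
#' @export
thresholdSweep <- function(fractions, grid = seq(0, 1, by = 0.05),
                           n_boot = 2000L, seed = 1L) {
  if (!length(fractions)) stop("empty fractions")
  set.seed(seed)
  n <- length(fractions)
  boots <- matrix(sample(fractions, n * n_boot, replace = TRUE), n, n_boot)
  rows <- lapply(grid, function(t) {
    prop <- mean(fractions >= t)
    bprop <- colMeans(boots >= t)
    data.frame(threshold = t, proportion = prop, se = stats::sd(bprop))
  })
  do.call(rbind, rows)
}
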
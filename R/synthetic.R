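#' Build a planted two-layer generative model
#'
#' Low-level supports are disjoint bilateral same-type joint pairs drawn
#' from the catalog (bilateral symmetry is enforced for non-midline types);
#' high-level supports partition the low-level factors into \code{k2}
#' near-equal groups, each the union of at least one pair. Defaults plant
#' the structure the pipeline is designed to recover: mixed-membership
#' patients drawn from one dominant pattern, a localization mixture, and
#' group/localization-dependent per-visit resolution.
#'
#' @param catalog a \linkS4class{JointCatalog}.
#' @param k1 number of low-level factors (at most the number of bilateral
#'   joint types).
#' @param k2 number of high-level patterns (\code{k1 >= k2 >= 1}).
#' @param seed integer seed.
#' @param group_weights probability per pattern (default uniform).
#' @param noise_rate per-joint symmetric flip probability (default 0.02).
#' @param localization_mix target (localized, partial, extended)
#'   proportions; the default (0.561, 0.194, 0.245) mirrors the observed
#'   discovery-cohort split 359/124/157 of 640.
#' @param resolution_hazard k2 x 3 matrix of per-visit per-joint resolution
#'   probabilities by (group, category); the default (0.45, 0.30, 0.20 per
#'   category, constant across groups) makes localized disease resolve
#'   fastest.
#' @param bilateral_coupling probability the contralateral partner of an
#'   activated key joint is co-activated (default 0.8).
#' @param key_activation probability each key pair of the drawn pattern is
#'   activated at baseline (default 0.7).
#' @return a \linkS4class{PlantedModel}.
#' @export
makePlantedModel <- function(catalog, k1, k2, seed = 1L,
                             group_weights = rep(1 / k2, k2),
                             noise_rate = 0.02,
                             localization_mix = c(0.561, 0.194, 0.245),
                             resolution_hazard = NULL,
                             bilateral_coupling = 0.8,
                             key_activation = 0.7) {
  stopifnot(k1 >= k2, k2 >= 1)
  bt <- .bilateral_types(catalog)
  if (k1 > length(bt))
    stop("k1 = ", k1, " exceeds the ", length(bt),
         " bilateral joint types in the catalog")
  set.seed(seed)
  types <- sample(names(bt), k1)
  low <- lapply(types, function(tp) unname(bt[[tp]]))
  names(low) <- paste0("L", seq_len(k1))
  ## near-equal partition of low-level factors into k2 high-level patterns
  part <- sample(rep(seq_len(k2), length.out = k1))
  high <- lapply(seq_len(k2), function(g) which(part == g))
  names(high) <- paste0("G", seq_len(k2))
  if (is.null(resolution_hazard))
    resolution_hazard <- matrix(rep(c(0.45, 0.30, 0.20), each = k2), k2, 3)
  dimnames(resolution_hazard) <- list(names(high),
                                      c("localized", "partial", "extended"))
  localization_mix <- localization_mix / sum(localization_mix)
  new("PlantedModel", catalog = catalog, lowSupports = low,
      highSupports = high, groupWeights = group_weights / sum(group_weights),
      noiseRate = noise_rate, localizationMix = localization_mix,
      resolutionHazard = resolution_hazard,
      bilateralCoupling = bilateral_coupling,
      keyActivation = key_activation, seed = as.integer(seed))
}

setMethod("show", "PlantedModel", function(object) {
  cat("PlantedModel:", length(object@lowSupports), "low-level pairs ->",
      length(object@highSupports), "patterns; noise", object@noiseRate,
      "; localization mix", paste(round(object@localizationMix, 3),
                                  collapse = "/"), "\n")
})

#' Key joints of each planted pattern
#'
#' @param planted a \linkS4class{PlantedModel}.
#' @return named list of character vectors (joint ids per pattern).
#' @export
plantedKeyJoints <- function(planted) {
  lapply(planted@highSupports, function(idx)
    sort(unique(unlist(planted@lowSupports[idx]))))
}

## activate key joints of group g for one patient
.draw_key_active <- function(planted, g) {
  pairs <- planted@lowSupports[planted@highSupports[[g]]]
  act <- character(0)
  on <- stats::runif(length(pairs)) < planted@keyActivation
  if (!any(on)) on[sample(length(pairs), 1)] <- TRUE
  for (i in which(on)) {
    pr <- pairs[[i]]
    first <- sample(pr, 1)
    act <- c(act, first)
    if (stats::runif(1) < planted@bilateralCoupling)
      act <- c(act, setdiff(pr, first))
  }
  unique(act)
}

## mixed-membership pool: non-key joints ordered by secondary pattern
## (whole bilateral pairs of randomly ordered other patterns first, then
## any remaining non-key joints in random order), so nonlocalized patients
## carry the key joints of other high-level patterns rather than uniform
## background
.nonkey_pool <- function(planted, g, key, ids) {
  others <- setdiff(seq_along(planted@highSupports), g)
  pool <- character(0)
  for (g2 in sample(others)) {
    prs <- planted@lowSupports[planted@highSupports[[g2]]]
    for (pr in prs[sample(length(prs))]) pool <- c(pool, sample(pr))
  }
  pool <- setdiff(pool, key)
  rest <- setdiff(ids, c(key, pool))
  c(pool, sample(rest))
}

## feasible count of non-key additions for a target category given n key
## active joints (exact integer thresholds: >=0.9 localized, [0.6,0.9)
## partial, <0.6 extended)
.nonkey_range <- function(n_key, target, n_avail) {
  loc_max  <- n_key %/% 9L                         # frac >= 0.9
  part_max <- (2L * n_key) %/% 3L                  # frac >= 0.6
  r <- switch(target,
    localized = c(0L, loc_max),
    partial   = c(loc_max + 1L, part_max),
    ## extended involvement stays anchored by the dominant pattern: strictly
    ## fewer non-key than key joints, so the planted group remains the
    ## highest-scoring pattern
    extended  = c(part_max + 1L, min(n_key - 1L, n_avail)))
  r[2] <- min(r[2], n_avail)
  if (r[1] > r[2]) return(NULL)
  r
}

#' Simulate a baseline cohort from a planted model
#'
#' Per patient: a pattern is drawn from the group weights and a target
#' localization category from the mixture; a random subset of the pattern's
#' key pairs is activated (contralateral partners co-activated at the
#' bilateral coupling rate); symmetric per-joint noise flips perturb the
#' draw (key joints can drop out, stray non-key joints can appear; at least
#' one key joint is guaranteed); finally the number of active non-key
#' joints is adjusted -- topped up or thinned -- until the key-joint
#' fraction falls in the target category's band, so the localization
#' mixture is realized exactly. Topped-up non-key joints are drawn
#' mixed-membership style: whole bilateral pairs from other patterns' key
#' sets first (patients match multiple patterns, as nonlocalized disease
#' does), uniform background only when those are exhausted. The category
#' recomputed from the final active set against the planted key set is
#' stored alongside the target (the two agree by construction).
#'
#' @param planted a \linkS4class{PlantedModel}.
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed.
#' @return list with \code{cohort} (baseline-only
#'   \linkS4class{JointCohort}) and \code{truth} (data.frame: patient,
#'   group, target_category, category, fraction).
#' @export
simulateBaseline <- function(planted, n_patients, seed = 1L) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  ids <- jointIds(planted@catalog)
  key_sets <- plantedKeyJoints(planted)
  k2 <- length(key_sets)
  cats <- c("localized", "partial", "extended")
  pats <- sprintf("p%04d", seq_len(n_patients))
  X <- matrix(0, length(ids), n_patients, dimnames = list(ids, pats))
  truth <- data.frame(patient = pats, group = NA_character_,
                      target_category = NA_character_,
                      category = NA_character_, fraction = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_patients)) {
    g <- sample(k2, 1, prob = planted@groupWeights)
    target <- sample(cats, 1, prob = planted@localizationMix)
    key <- key_sets[[g]]
    nonkey <- setdiff(ids, key)
    act <- .draw_key_active(planted, g)
    ## symmetric noise perturbs the draw before the band adjustment
    x <- as.integer(ids %in% act)
    flip <- stats::runif(length(ids)) < planted@noiseRate
    x[flip] <- 1L - x[flip]
    if (!any(x == 1 & ids %in% key)) x[match(sample(key, 1), ids)] <- 1L
    key_on <- ids[x == 1 & ids %in% key]
    r <- .nonkey_range(length(key_on), target, length(nonkey))
    tries <- 0L
    while (is.null(r) && tries < 20L) {
      ## too few key joints for the band (e.g. partial needs >= 2): widen
      extra <- setdiff(key, key_on)
      if (!length(extra))
        stop("infeasible localization target '", target,
             "' for pattern ", names(key_sets)[g])
      key_on <- c(key_on, sample(extra, 1))
      r <- .nonkey_range(length(key_on), target, length(nonkey))
      tries <- tries + 1L
    }
    if (is.null(r))
      stop("infeasible localization target '", target, "' for pattern ",
           names(key_sets)[g])
    x[match(key_on, ids)] <- 1L
    nonkey_on <- ids[x == 1 & ids %in% nonkey]
    j <- if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
    if (length(nonkey_on) > r[2]) {
      ## noise overshot the band: thin stray non-key joints down into it
      x[match(sample(nonkey_on, length(nonkey_on) - j), ids)] <- 0L
    } else if (length(nonkey_on) < r[1]) {
      j <- max(j, r[1])
      pool <- setdiff(.nonkey_pool(planted, g, key, ids), nonkey_on)
      x[match(pool[seq_len(j - length(nonkey_on))], ids)] <- 1L
    }
    X[, i] <- x
    d <- degreeOfLocalization(ids[x == 1], key)
    truth$group[i] <- names(key_sets)[g]
    truth$target_category[i] <- target
    truth$category[i] <- d$category
    truth$fraction[i] <- d$fraction
  }
  cohort <- JointCohort(planted@catalog, list("0" = X))
  list(cohort = cohort, truth = truth)
}

#' Simulate disease course over a visit schedule
#'
#' Starting from the baseline matrix, each active joint independently
#' resolves at each visit with the planted per-visit hazard for the
#' patient's (group, realized localization category); with
#' \code{flare_rate > 0}, inactive joints can reactivate. Dropout, when
#' positive, removes a patient from each successive visit with the given
#' probability (missing thereafter). The first all-zero visit month is the
#' patient's time to zero joints.
#'
#' @param baseline output of \code{\link{simulateBaseline}}.
#' @param planted the same \linkS4class{PlantedModel}.
#' @param schedule visit months (strictly increasing, starting at 0);
#'   default \code{\link{defaultSchedule}}.
#' @param seed integer seed.
#' @param flare_rate per-visit reactivation probability (default 0).
#' @param dropout per-visit dropout probability (default 0).
#' @return list with \code{cohort} (full \linkS4class{JointCohort}) and
#'   \code{truth} (baseline truth plus \code{event_time}, NA when zero is
#'   never reached while observed).
#' @export
simulateCourse <- function(baseline, planted, schedule = defaultSchedule(),
                           seed = 1L, flare_rate = 0, dropout = 0) {
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly increasing")
  stopifnot(schedule[1] == 0)
  set.seed(seed)
  X0 <- baselineMatrix(baseline$cohort)
  truth <- baseline$truth
  ids <- rownames(X0)
  haz <- planted@resolutionHazard
  gidx <- match(truth$group, rownames(haz))
  cidx <- match(truth$category, colnames(haz))
  Xs <- list("0" = X0)
  cur <- X0
  active_pat <- colnames(X0)
  event <- stats::setNames(rep(NA_integer_, ncol(X0)), colnames(X0))
  for (v in schedule[-1]) {
    keep <- stats::runif(length(active_pat)) >= dropout
    active_pat <- active_pat[keep]
    if (!length(active_pat)) break
    M <- cur[, active_pat, drop = FALSE]
    for (p in active_pat) {
      pi <- match(p, truth$patient)
      h <- haz[gidx[pi], cidx[pi]]
      on <- M[, p] == 1
      resolve <- on & (stats::runif(length(ids)) < h)
      M[resolve, p] <- 0
      if (flare_rate > 0) {
        flare <- !on & (stats::runif(length(ids)) < flare_rate)
        M[flare, p] <- 1
      }
      if (sum(M[, p]) == 0 && is.na(event[p])) event[p] <- v
    }
    Xs[[as.character(v)]] <- M
    cur[, active_pat] <- M
  }
  truth$event_time <- unname(event[truth$patient])
  cohort <- JointCohort(planted@catalog, Xs,
                        labels = cohortLabels(baseline$cohort))
  list(cohort = cohort, truth = truth)
}
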
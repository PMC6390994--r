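#' Joint involvement and co-involvement frequencies
#'
#' For a baseline joints x patients binary matrix, computes per-joint
#' involvement proportions \eqn{P(x)}, pairwise co-involvement proportions
#' \eqn{P(x,y)} (the proportion of patients with both joints active) and the
#' conditional co-involvement matrix \eqn{P(y|x) = P(x,y)/P(x)} -- the
#' fraction of patients with the reference joint \eqn{x} involved who also
#' have \eqn{y} involved. Conditional entries are \code{NA} (flagged
#' undefined) where \eqn{P(x) = 0}. All ordered pairs, including self-pairs,
#' are covered: \code{cond[x, y]} holds \eqn{P(y|x)}.
#'
#' @param X binary joints x patients matrix with at least one patient.
#' @return a list with elements \code{freq} (named vector), \code{pair}
#'   (matrix), \code{cond} (matrix), \code{n_patients}.
#' @export
coinvolvement <- function(X) {
  if (!is.matrix(X) || ncol(X) < 1L) stop("X must be a matrix with >= 1 patient")
  if (!all(X %in% c(0, 1))) stop("X must be binary")
  n <- ncol(X)
  freq <- rowMeans(X)
  pair <- (X %*% t(X)) / n
  cond <- pair / freq          # row x = reference joint
  cond[freq == 0, ] <- NA_real_
  list(freq = freq, pair = pair, cond = cond, n_patients = n)
}

#' Screen conditional co-involvement probabilities for significance
#'
#' Tests each ordered pair's conditional probability \eqn{P(y|x)} against
#' the marginal \eqn{P(y)} with an exact binomial test (successes: patients
#' with both joints active, trials: patients with \eqn{x} active), adjusting
#' by Bonferroni across all ordered pairs including self-pairs.
#'
#' @param X binary joints x patients matrix.
#' @param level significance level after adjustment (default 0.05).
#' @return list with matrices \code{p} (raw), \code{p_adj}, logical
#'   \code{significant}, and \code{n_pairs}.
#' @export
condTest <- function(X, level = 0.05) {
  ci <- coinvolvement(X)
  n <- ci$n_patients
  K <- nrow(X)
  counts <- ci$pair * n
  nx <- ci$freq * n
  p <- matrix(NA_real_, K, K, dimnames = dimnames(ci$pair))
  for (x in seq_len(K)) {
    if (nx[x] == 0) next
    for (y in seq_len(K)) {
      p[x, y] <- stats::binom.test(round(counts[x, y]), round(nx[x]),
                                   p = min(max(ci$freq[y], 1e-12), 1 - 1e-12))$p.value
    }
  }
  n_pairs <- K * K
  p_adj <- pmin(p * n_pairs, 1)
  list(p = p, p_adj = p_adj, significant = !is.na(p_adj) & p_adj < level,
       n_pairs = n_pairs)
}

## per-patient same/opposite-side co-involvement indicator counts for a pair
## of bilateral joint types (x = reference, y = co-involved)
.side_counts <- function(X, xt, yt) {
  if (identical(xt, yt)) {
    ## self-pair: the same-side member is the reference joint itself and is
    ## excluded, so only pure bilaterality (left with right) is counted
    n_same <- 0L
    n_opp  <- sum(X[xt["left"], ] == 1 & X[xt["right"], ] == 1)
  } else {
    same <- (X[xt["left"], ] == 1 & X[yt["left"], ] == 1) |
            (X[xt["right"], ] == 1 & X[yt["right"], ] == 1)
    opp  <- (X[xt["left"], ] == 1 & X[yt["right"], ] == 1) |
            (X[xt["right"], ] == 1 & X[yt["left"], ] == 1)
    n_same <- sum(same)
    n_opp  <- sum(opp)
  }
  c(n_same = n_same, n_opposite = n_opp)
}

#' Same-side versus opposite-side skew of joint-type co-involvement
#'
#' For every ordered pair of bilateral joint types (reference type x,
#' co-involved type y), counts the patients carrying a same-side co-involved
#' pair (\eqn{n_{same}}) and an opposite-side pair (\eqn{n_{opp}}); a patient
#' contributes at most once to each count. The shrunken same-side proportion
#' is \eqn{m = (n_{same}+1) / ((n_{same}+1) + (n_{opp}+1))}, its standard
#' error \eqn{\sigma = \sqrt{m(1-m)/n}} with \eqn{n} the shrunken total, and
#' the skew z-score \eqn{z = (m - 0.5)/\sigma}. Positive z means co-involved
#' joints tend to fall on the same side of the body. A chi-squared test of
#' \eqn{n_{same}} versus \eqn{n_{opp}} against equality gives the p-value;
#' q-values are Benjamini-Hochberg across all pairs. A pair is flagged
#' significant when FDR < 0.1 and the skew is towards the same side
#' (z > 0) -- the asymmetry of clinical interest. Self-pairs (x = y) measure pure bilaterality: their same-side
#' member would be the reference joint itself and is excluded.
#'
#' @param X binary joints x patients matrix (typically baseline).
#' @param catalog a \linkS4class{JointCatalog} supplying left/right pairing;
#'   midline joint types are not scored.
#' @param fdr_level significance level on the q-value (default 0.1).
#' @return data.frame with columns \code{x_type}, \code{y_type},
#'   \code{n_same}, \code{n_opposite}, \code{m}, \code{sigma}, \code{z},
#'   \code{chi2}, \code{p}, \code{fdr}, \code{significant}.
#' @export
skewTest <- function(X, catalog, fdr_level = 0.1) {
  bt <- .bilateral_types(catalog)
  if (!length(bt)) stop("catalog has no bilateral joint types")
  types <- names(bt)
  rows <- expand.grid(x_type = types, y_type = types,
                      stringsAsFactors = FALSE)
  cnt <- t(mapply(function(xt, yt) .side_counts(X, bt[[xt]], bt[[yt]]),
                  rows$x_type, rows$y_type))
  n_same <- cnt[, "n_same"]
  n_opp  <- cnt[, "n_opposite"]
  m <- (n_same + 1) / ((n_same + 1) + (n_opp + 1))
  n_shrunk <- (n_same + 1) + (n_opp + 1)
  sigma <- sqrt(m * (1 - m) / n_shrunk)
  z <- (m - 0.5) / sigma
  tot <- n_same + n_opp
  chi2 <- ifelse(tot > 0, (n_same - n_opp)^2 / tot, 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fdr <- bhFdr(p)
  ## significance flags same-side (positive) skew, the asymmetry of
  ## clinical interest; negative z marks bilaterality, not asymmetry
  data.frame(rows, n_same = n_same, n_opposite = n_opp, m = m,
             sigma = sigma, z = z, chi2 = chi2, p = p, fdr = fdr,
             significant = fdr < fdr_level & z > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation test of left/right mirror symmetry
#'
#' Partitions the conditional co-involvement matrix by body side and
#' compares the two opposite-side quadrants: \eqn{A[i,j] = P(right_j |
#' left_i)} versus \eqn{B[i,j] = P(left_j | right_i)} over matched bilateral
#' types. Returns the Frobenius norm of \eqn{A - B} and a permutation
#' p-value obtained by independently relabelling each patient's left and
#' right sides (a coin-flip mirror per patient) \code{n_perm} times and
#' recomputing the norm. Undefined conditional entries contribute zero.
#'
#' @param X binary joints x patients matrix.
#' @param catalog a \linkS4class{JointCatalog}.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with \code{frobenius}, \code{p}, \code{perm_norms}.
#' @export
lrSymmetryPermTest <- function(X, catalog, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  bt <- .bilateral_types(catalog)
  L <- vapply(bt, `[[`, "", "left")
  R <- vapply(bt, `[[`, "", "right")
  obs <- .lr_quadrant_norm(X, L, R)
  set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    flip <- stats::runif(ncol(X)) < 0.5
    Xp <- X
    Xp[L, flip] <- X[R, flip]
    Xp[R, flip] <- X[L, flip]
    perm[b] <- .lr_quadrant_norm(Xp, L, R)
  }
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(frobenius = obs, p = p, perm_norms = perm)
}

.lr_quadrant_norm <- function(X, L, R) {
  cond <- coinvolvement(X)$cond
  A <- cond[L, R, drop = FALSE]   # P(right_j | left_i)
  B <- cond[R, L, drop = FALSE]   # P(left_j | right_i)
  D <- A - B
  D[is.na(D)] <- 0
  sqrt(sum(D^2))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Validated wrapper around the standard step-up adjustment: q-values are
#' monotone in the sorted order and satisfy \code{q >= p} elementwise.
#'
#' @param p vector of p-values in [0,1].
#' @return vector of q-values, same length and order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (length(p) && (any(p < 0 | p > 1, na.rm = TRUE)))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}
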
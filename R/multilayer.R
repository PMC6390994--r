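#' Fit a two-layer (multilayer) sparse NMF
#'
#' Layer 1 factorizes the joints x patients matrix into \code{k1} low-level
#' factors (tight joint groupings) and is sparsified at
#' \code{threshold1}. Its re-estimated score matrix, with each factor row
#' rescaled to unit maximum (the scales are stored and frozen for later
#' projection), is then factorized into \code{k2} high-level factors
#' (groupings of groupings), sparsified at \code{threshold2}. The composite
#' loading \code{C = W1_sparse \%*\% W2_sparse} (columns normalized to unit
#' maximum, then sparsified with the same rule at \code{threshold2}) maps
#' high-level factors back onto joints; each factor's key joints are those
#' with strictly positive sparsified composite loading.
#'
#' @param X binary joints x patients matrix.
#' @param k1,k2 low- and high-level ranks (the study defaults for
#'   homunculus-shaped data are 19 and 7).
#' @param alpha1,alpha2 L1 penalties per layer.
#' @param threshold1,threshold2 sparsification thresholds (fraction of the
#'   column maximum; default 0.1).
#' @param config a \code{\link{fitConfig}}.
#' @return a \linkS4class{MultilayerModel}.
#' @export
fitMultilayer <- function(X, k1 = 19L, k2 = 7L, alpha1 = 0, alpha2 = 0,
                          threshold1 = 0.1, threshold2 = 0.1,
                          config = fitConfig()) {
  l1 <- sparsify(fitNMF(X, k = k1, alpha = alpha1, config = config), X,
                 threshold = threshold1)
  rs <- apply(l1@H, 1, max)
  rs[rs == 0] <- 1
  H1s <- l1@H / rs
  l2 <- sparsify(fitNMF(H1s, k = k2, alpha = alpha2, config = config), H1s,
                 threshold = threshold2)
  C <- l1@W %*% l2@W
  cmax <- apply(C, 2, max)
  cmax[cmax == 0] <- 1
  C <- sweep(C, 2, cmax, "/")
  ## the composite is sparsified with the same rule as the layers, so key
  ## joints are read from the sparsified composite
  C[C < threshold2] <- 0
  colnames(C) <- paste0("G", seq_len(k2))
  key <- lapply(seq_len(k2), function(f) rownames(C)[C[, f] > 0])
  names(key) <- colnames(C)
  new("MultilayerModel", layer1 = l1, layer2 = l2, composite = C,
      keyJoints = key, h1RowScale = rs, jointIds = rownames(X))
}

setMethod("show", "MultilayerModel", function(object) {
  cat("MultilayerModel:", length(object@jointIds), "joints ->",
      object@layer1@k, "low-level ->", object@layer2@k,
      "high-level factors\n  key joints per factor:",
      paste(lengths(object@keyJoints), collapse = ", "), "\n")
})

#' Accessors for MultilayerModel
#'
#' @param model a \linkS4class{MultilayerModel}.
#' @return \code{keyJoints}: named list of key joint ids per high-level
#'   factor; \code{compositeLoadings}: the joints x k2 composite matrix.
#' @export
keyJoints <- function(model) model@keyJoints

#' @rdname keyJoints
#' @export
compositeLoadings <- function(model) model@composite

#' Project raw involvements through both frozen layers
#'
#' Applies layer 1's frozen loadings to obtain low-level scores, rescales
#' them with the stored per-factor scales, then applies layer 2's frozen
#' loadings -- the same scaling parameters used in fitting, so external
#' cohorts are scored exactly as the discovery cohort was.
#'
#' @param X_new joints x patients binary matrix on the model's joint space.
#' @param model a \linkS4class{MultilayerModel}.
#' @return list with \code{H1} (k1 x n, rescaled) and \code{H2} (k2 x n).
#' @export
projectMultilayer <- function(X_new, model) {
  if (!identical(rownames(X_new), model@jointIds))
    stop("feature space mismatch: rownames must equal the model's joints")
  H1 <- projectScores(X_new, model@layer1) / model@h1RowScale
  H2 <- projectScores(H1, model@layer2)
  list(H1 = H1, H2 = H2)
}

#' Assign patients to their highest-scoring high-level factor
#'
#' Each patient's group is the argmax of their high-level scores. Exact
#' ties are flagged and broken towards the lowest factor index; all-zero
#' score vectors receive the reserved group \code{"unscored"} and are
#' reported, never dropped.
#'
#' @param model a \linkS4class{MultilayerModel}.
#' @param scores_or_X either a k2 x patients score matrix or a raw joints x
#'   patients binary matrix (projected through both frozen layers first).
#' @return a \linkS4class{GroupAssignment}.
#' @export
assignGroups <- function(model, scores_or_X) {
  H2 <- if (nrow(scores_or_X) == model@layer2@k) scores_or_X
        else projectMultilayer(scores_or_X, model)$H2
  if (nrow(H2) != model@layer2@k) stop("score dimension mismatch")
  rownames(H2) <- colnames(model@composite)
  grp <- character(ncol(H2))
  tie <- logical(ncol(H2))
  for (i in seq_len(ncol(H2))) {
    v <- H2[, i]
    if (all(v == 0)) {
      grp[i] <- "unscored"
    } else {
      top <- which(v == max(v))
      grp[i] <- rownames(H2)[top[1]]
      tie[i] <- length(top) > 1L
    }
  }
  names(grp) <- names(tie) <- colnames(H2)
  new("GroupAssignment", scores = H2, group = grp, tie = tie)
}

setMethod("show", "GroupAssignment", function(object) {
  cat("GroupAssignment:", ncol(object@scores), "patients\n")
  print(table(object@group))
})

#' Accessors for GroupAssignment
#'
#' @param assignment a \linkS4class{GroupAssignment}.
#' @return \code{assignedGroup}: named character vector;
#'   \code{groupScores}: the k2 x patients score matrix; \code{isTie}:
#'   named logical vector.
#' @export
assignedGroup <- function(assignment) assignment@group

#' @rdname assignedGroup
#' @export
groupScores <- function(assignment) assignment@scores

#' @rdname assignedGroup
#' @export
isTie <- function(assignment) assignment@tie

#' Overlap between patient groups and factors
#'
#' Scores are first normalized patient-wise to each patient's highest
#' factor score, then z-score-transformed factor-wise across patients.
#' A one-sided z-test per (group, factor) asks whether the group's mean
#' normalized score exceeds the overall mean; p-values are converted to
#' Benjamini-Hochberg q-values, significant at FDR < 0.1.
#'
#' @param H2 factors x patients score matrix.
#' @param assignment a \linkS4class{GroupAssignment} (or a character vector
#'   of group labels per patient).
#' @param fdr_level significance level (default 0.1).
#' @return data.frame with columns \code{group}, \code{factor}, \code{z},
#'   \code{p}, \code{fdr}, \code{significant}.
#' @export
groupFactorOverlap <- function(H2, assignment, fdr_level = 0.1) {
  grp <- if (is(assignment, "GroupAssignment")) assignment@group else assignment
  if (length(unique(grp)) < 2L) stop("need >= 2 groups")
  mx <- apply(H2, 2, max)
  mx[mx == 0] <- 1
  N <- sweep(H2, 2, mx, "/")
  sds <- apply(N, 1, stats::sd)
  if (any(sds == 0))
    stop("factor(s) with zero variance after normalization: ",
         paste(which(sds == 0), collapse = ", "))
  Z <- t(scale(t(N)))
  rows <- list()
  for (g in sort(unique(grp))) for (f in seq_len(nrow(Z))) {
    v <- Z[f, grp == g]
    z <- mean(v) * sqrt(length(v))
    p <- stats::pnorm(z, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, factor = rownames(H2)[f] %||% paste0("F", f), z = z, p = p)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p)
  out$significant <- out$fdr < fdr_level
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Association between patient groups and external labels
#'
#' Chi-squared test on the group x label contingency table with per-cell
#' adjusted standardized (Pearson) residuals
#' \eqn{\epsilon = (obs - exp)/\sqrt{exp (1 - row\ prop)(1 - col\ prop)}};
#' cells with \eqn{\epsilon \ge 1.96} are flagged enriched. No continuity
#' correction is applied so residuals follow the standard normal reference.
#'
#' @param assignment a \linkS4class{GroupAssignment} or character vector.
#' @param labels named (or aligned) character vector of patient labels
#'   covering >= 2 categories, none empty.
#' @return list with \code{table} (data.frame: group, label, observed,
#'   expected, residual, enriched), \code{chi2}, \code{df}, \code{p}.
#' @export
groupLabelAssociation <- function(assignment, labels) {
  grp <- if (is(assignment, "GroupAssignment")) assignment@group else assignment
  if (!is.null(names(labels)) && !is.null(names(grp)))
    labels <- labels[names(grp)]
  if (length(labels) != length(grp)) stop("labels must cover every patient")
  if (length(unique(labels)) < 2L) stop("labels must cover >= 2 categories")
  tab <- table(group = grp, label = labels)
  if (any(colSums(tab) == 0)) stop("label category with zero patients")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- ct$stdres
  df <- as.data.frame(as.table(ct$observed), stringsAsFactors = FALSE)
  names(df) <- c("group", "label", "observed")
  df$expected <- as.vector(ct$expected)
  df$residual <- as.vector(res)
  df$enriched <- df$residual >= 1.96
  list(table = df, chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Align fitted factors to reference factors
#'
#' Finds the one-to-one assignment of fitted to reference columns that
#' maximizes total cosine similarity, by exhaustive search over
#' permutations (intended for the small factor counts used here, k <= 8).
#'
#' @param fitted,reference matrices with the same number of rows; columns
#'   are factors.
#' @return list with \code{perm} (reference column for each fitted column)
#'   and \code{cosines} (per matched pair).
#' @export
alignFactors <- function(fitted, reference) {
  k <- ncol(fitted)
  if (ncol(reference) != k) stop("factor counts differ")
  if (k > 8L) stop("exhaustive alignment supports k <= 8")
  cs <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- fitted[, i]; b <- reference[, j]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    cs[i, j] <- if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  perms <- .permutations(k)
  tot <- apply(perms, 1, function(pp) sum(cs[cbind(seq_len(k), pp)]))
  best <- as.integer(perms[which.max(tot), ])
  list(perm = best, cosines = cs[cbind(seq_len(k), best)])
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
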